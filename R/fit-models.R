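# Maximum-likelihood fits of the model ladder: M0 (one ratio), MC /
# MCfixed (two-ratio branch models), FREE (free ratio), and branch-site
# model A with its fixed null.  Branch lengths are estimated once under M0
# and held fixed for the branch and branch-site models; the free-ratio
# model re-optimizes them jointly with the per-branch omegas.
#
# Parameters are optimized on transformed scales (log kappa, log omega,
# log t, logit proportions) with bounded quasi-Newton (L-BFGS-B).  All
# multi-start schedules are deterministic, so a fit is bit-reproducible.

.OM_LO <- 1e-4
.OM_HI <- 999
.T_LO <- 1e-7
.T_HI <- 20
.K_LO <- 0.05
.K_HI <- 100

fit_control <- function(control) {
  utils::modifyList(list(factr = 1e7, maxit = 500), control)
}

run_bounded <- function(par, fn, lower, upper, ctl) {
  stats::optim(par, fn, method = "L-BFGS-B", lower = lower, upper = upper,
               control = list(factr = ctl$factr, maxit = ctl$maxit))
}

# Root handling: a rooted binary tree has one unidentifiable degree of
# freedom at the root under a reversible model, so the second root-child
# branch is held at length 0 and the first carries the pair's total length
# (the unrooted equivalent).  Returns NA when the root is not binary.
tie_row_of <- function(eng) {
  if (length(eng$root_rows) == 2L) eng$root_rows[2] else NA_integer_
}

per_branch_table <- function(eng, tlen, omega_edge, kappa, pi,
                             omega_undefined = NULL) {
  code_id <- eng$genetic_code_id
  NS <- site_opportunity(codon_model_params(kappa, 1, pi, code_id))
  uo <- unique(omega_edge)
  dn_rate <- numeric(length(uo))
  ds_rate <- numeric(length(uo))
  for (k in seq_along(uo)) {
    rhoN <- nonsyn_flux_fraction(
      codon_model_params(kappa, uo[k], pi, code_id))
    dn_rate[k] <- rhoN / unname(NS["N"])
    ds_rate[k] <- (1 - rhoN) / unname(NS["S"])
  }
  idx <- match(omega_edge, uo)
  child <- eng$edge[, 2]
  lab <- ifelse(child <= eng$n_tip, eng$tree$tip.label[child], "")
  out <- data.frame(parent = eng$edge[, 1], child = child, label = lab,
                    t = tlen, omega = omega_edge,
                    dN = tlen * dn_rate[idx], dS = tlen * ds_rate[idx],
                    foreground = eng$fg,
                    stringsAsFactors = FALSE)
  out$omega_undefined <- if (is.null(omega_undefined))
    rep(FALSE, nrow(out)) else omega_undefined
  out$omega[out$omega_undefined] <- NaN
  out
}

new_model_fit <- function(model_id, eng, opt, lnL, n_free, kappa, pi,
                          freq_scheme, tlen, omega_edge, omega = NULL,
                          extra = list(), omega_undefined = NULL) {
  fit <- c(list(model_id = model_id, loglik = lnL, n_free_params = n_free,
                kappa = kappa, pi = pi, freq_scheme = freq_scheme,
                omega = omega,
                per_branch = per_branch_table(eng, tlen, omega_edge, kappa,
                                              pi, omega_undefined),
                tree = eng$tree, convergence = opt$convergence,
                counts = opt$counts, engine = eng),
           extra)
  class(fit) <- "codonsel_fit"
  fit
}

#' @export
print.codonsel_fit <- function(x, ...) {
  cat(sprintf("codonsel_fit %s: lnL = %.4f (%d free parameters, %d taxa)\n",
              x$model_id, x$loglik, x$n_free_params, x$engine$n_tip))
  if (!is.null(x$omega) && is.numeric(x$omega))
    cat("  omega:", paste(sprintf("%s=%.4g",
        names(x$omega) %||% rep("", length(x$omega)), x$omega),
        collapse = " "), "\n")
  if (!is.null(x$mixture))
    cat(sprintf("  site classes: p0=%.3f p1=%.3f p2a=%.3f p2b=%.3f omega0=%.3f omega2=%.3f\n",
                x$mixture$p0, x$mixture$p1, x$mixture$p2a, x$mixture$p2b,
                x$mixture$omega0, x$mixture$omega2))
  invisible(x)
}

check_informative <- function(aln) {
  varying <- apply(aln$states, 2, function(col) {
    length(unique(col[!is.na(col)])) > 1L
  })
  if (!any(varying))
    cs_stop("no information to estimate branch lengths (invariant alignment)")
}

#' Fit the one-ratio (M0) codon model
#'
#' Jointly maximizes the likelihood over kappa, a single omega shared by all
#' branches and sites, and all branch lengths.  The fitted branch lengths
#' are the ones reused (held fixed) by the branch and branch-site models.
#'
#' @param aln A `codon_alignment` (at least 3 taxa recommended).
#' @param tree A rooted `phylo`; any starting branch lengths are used as
#'   initial values.
#' @param freq_scheme Codon frequency scheme, see
#'   [estimate_codon_frequencies()].
#' @param pi Optional explicit frequency vector (overrides `freq_scheme`).
#' @param control List with optional `factr` and `maxit` for the optimizer.
#' @return A `codonsel_fit` with `loglik`, `kappa`, `omega`, and a
#'   `per_branch` table of (t, omega, dN, dS).
#' @export
fit_m0 <- function(aln, tree, freq_scheme = "F3x4", pi = NULL,
                   control = list()) {
  ctl <- fit_control(control)
  check_informative(aln)
  eng <- make_engine(aln, tree)
  pi <- pi %||% estimate_codon_frequencies(aln, freq_scheme)
  n_edge <- eng$n_edge
  tie <- tie_row_of(eng)
  free_rows <- if (is.na(tie)) seq_len(n_edge) else setdiff(seq_len(n_edge), tie)

  t0 <- eng$tree$edge.length
  if (!is.na(tie)) {
    t0[eng$root_rows[1]] <- t0[eng$root_rows[1]] + t0[tie]
    t0[tie] <- 0
  }
  t0f <- pmax(t0[free_rows], 1e-4)

  full_t <- function(tf) {
    tl <- numeric(n_edge)
    tl[free_rows] <- tf
    tl
  }
  negll <- function(kappa, omega, tf) {
    -eng$pat_loglik(kappa, pi, rep(omega, n_edge), full_t(tf))$total
  }

  # phase 1: kappa, omega and one global branch-length scale
  f1 <- function(p) negll(exp(p[1]), exp(p[2]), t0f * exp(p[3]))
  o1 <- run_bounded(c(log(2), log(0.4), 0), f1,
                    lower = c(log(.K_LO), log(.OM_LO), -6),
                    upper = c(log(.K_HI), log(.OM_HI), 4), ctl)
  # phase 2: all branch lengths free
  f2 <- function(p) negll(exp(p[1]), exp(p[2]), exp(p[-(1:2)]))
  p2 <- c(o1$par[1:2], log(pmax(t0f * exp(o1$par[3]), .T_LO)))
  o2 <- run_bounded(p2, f2,
                    lower = c(log(.K_LO), log(.OM_LO),
                              rep(log(.T_LO), length(free_rows))),
                    upper = c(log(.K_HI), log(.OM_HI),
                              rep(log(.T_HI), length(free_rows))), ctl)

  kappa <- exp(o2$par[1]); omega <- exp(o2$par[2])
  tlen <- full_t(exp(o2$par[-(1:2)]))
  new_model_fit("M0", eng, o2, -o2$value,
                n_free = length(free_rows) + 2L,
                kappa = kappa, pi = pi, freq_scheme = freq_scheme,
                tlen = tlen, omega_edge = rep(omega, n_edge),
                omega = c(omega = omega))
}

m0_branch_lengths <- function(eng, m0_fit) {
  tlen <- m0_fit$per_branch$t[match(eng$edge[, 2], m0_fit$per_branch$child)]
  if (anyNA(tlen))
    cs_stop("m0_fit does not cover this tree (branch mismatch)")
  tlen
}

#' Fit a two-ratio branch model (MC or MCfixed)
#'
#' Estimates kappa and separate background/foreground omegas with branch
#' lengths held at the M0 estimates.  With `fix_foreground_omega = TRUE`
#' the foreground omega is constrained to 1 (the MCfixed null against
#' which relaxation/deviation from neutrality is tested).
#'
#' @inheritParams fit_m0
#' @param fix_foreground_omega Constrain foreground omega to 1.
#' @param m0_fit The [fit_m0()] fit supplying fixed branch lengths,
#'   frequencies and the starting kappa.
#' @param null_fit Optional nested fit whose solution seeds an extra
#'   optimizer start (guarantees `lnL(alt) >= lnL(null)` up to tolerance).
#' @return A `codonsel_fit` with `omega = c(background, foreground)`.
#' @export
fit_branch_model <- function(aln, tree, fix_foreground_omega = FALSE,
                             m0_fit, null_fit = NULL, control = list()) {
  ctl <- fit_control(control)
  eng <- make_engine(aln, tree)
  if (!any(eng$fg))
    cs_stop("no foreground branches marked; use mark_clade() or #1 tags")
  pi <- m0_fit$pi
  tlen <- m0_branch_lengths(eng, m0_fit)
  w0 <- unname(m0_fit$omega["omega"])
  k0 <- m0_fit$kappa

  if (fix_foreground_omega) {
    fn <- function(p) {
      oe <- ifelse(eng$fg, 1, exp(p[2]))
      -eng$pat_loglik(exp(p[1]), pi, oe, tlen)$total
    }
    starts <- list(c(log(k0), log(w0)), c(log(k0), log(max(w0 / 2, .OM_LO * 2))))
    lower <- c(log(.K_LO), log(.OM_LO)); upper <- c(log(.K_HI), log(.OM_HI))
  } else {
    fn <- function(p) {
      oe <- ifelse(eng$fg, exp(p[3]), exp(p[2]))
      -eng$pat_loglik(exp(p[1]), pi, oe, tlen)$total
    }
    starts <- list(c(log(k0), log(w0), log(w0)),
                   c(log(k0), log(w0), log(1.0)),
                   c(log(k0), log(w0), log(3.0)))
    if (!is.null(null_fit))
      starts <- c(list(c(log(null_fit$kappa),
                         log(max(unname(null_fit$omega["background"]), .OM_LO)),
                         log(1 + 1e-6))), starts)
    lower <- c(log(.K_LO), log(.OM_LO), log(.OM_LO))
    upper <- c(log(.K_HI), log(.OM_HI), log(.OM_HI))
  }
  opts <- lapply(starts, function(s) run_bounded(s, fn, lower, upper, ctl))
  o <- opts[[which.min(vapply(opts, `[[`, 0, "value"))]]

  kappa <- exp(o$par[1])
  w_bg <- exp(o$par[2])
  w_fg <- if (fix_foreground_omega) 1 else exp(o$par[3])
  oe <- ifelse(eng$fg, w_fg, w_bg)
  new_model_fit(if (fix_foreground_omega) "MCfixed" else "MC",
                eng, o, -o$value,
                n_free = if (fix_foreground_omega) 2L else 3L,
                kappa = kappa, pi = pi, freq_scheme = m0_fit$freq_scheme,
                tlen = tlen, omega_edge = oe,
                omega = c(background = w_bg, foreground = w_fg))
}

#' Fit the free-ratio model (one omega per branch)
#'
#' Each branch gets its own omega; kappa is shared.  Branch lengths are
#' re-optimized jointly with the per-branch omegas.  Branches whose
#' estimated omega runs to the optimization ceiling (no synonymous change
#' left on the branch) are flagged `omega_undefined`; their dN and dS are
#' still reported.
#'
#' @inheritParams fit_branch_model
#' @return A `codonsel_fit`; the `per_branch` table carries per-branch
#'   (t, omega, dN, dS).
#' @export
fit_free_ratio <- function(aln, tree, m0_fit = NULL, freq_scheme = "F3x4",
                           control = list()) {
  ctl <- fit_control(control)
  if (is.null(m0_fit)) m0_fit <- fit_m0(aln, tree, freq_scheme,
                                        control = control)
  eng <- make_engine(aln, tree)
  pi <- m0_fit$pi
  n_edge <- eng$n_edge
  tie <- tie_row_of(eng)
  free_rows <- if (is.na(tie)) seq_len(n_edge) else setdiff(seq_len(n_edge), tie)
  nf <- length(free_rows)
  t0 <- pmax(m0_branch_lengths(eng, m0_fit)[free_rows], .T_LO * 2)
  w0 <- min(max(unname(m0_fit$omega["omega"]), 0.05), 10)

  assemble <- function(p) {
    oe <- rep(1, n_edge); tl <- numeric(n_edge)
    oe[free_rows] <- exp(p[2:(1 + nf)])
    tl[free_rows] <- exp(p[(2 + nf):(1 + 2 * nf)])
    if (!is.na(tie)) oe[tie] <- oe[eng$root_rows[1]]
    list(oe = oe, tl = tl)
  }
  fn <- function(p) {
    a <- assemble(p)
    -eng$pat_loglik(exp(p[1]), pi, a$oe, a$tl)$total
  }
  par0 <- c(log(m0_fit$kappa), rep(log(w0), nf), log(t0))
  o <- run_bounded(par0, fn,
                   lower = c(log(.K_LO), rep(log(.OM_LO), nf),
                             rep(log(.T_LO), nf)),
                   upper = c(log(.K_HI), rep(log(.OM_HI), nf),
                             rep(log(.T_HI), nf)), ctl)
  a <- assemble(o$par)
  undef <- a$oe >= 0.9 * .OM_HI
  new_model_fit("FREE", eng, o, -o$value, n_free = 1L + 2L * nf,
                kappa = exp(o$par[1]), pi = pi,
                freq_scheme = m0_fit$freq_scheme,
                tlen = a$tl, omega_edge = a$oe,
                omega_undefined = undef)
}

bs_class_table <- function(p0, p1, omega0, omega2) {
  th1 <- p0 + p1
  data.frame(class = c("0", "1", "2a", "2b"),
             proportion = c(p0, p1, (1 - th1) * p0 / th1,
                            (1 - th1) * p1 / th1),
             omega_background = c(omega0, 1, omega0, 1),
             omega_foreground = c(omega0, 1, omega2, omega2),
             stringsAsFactors = FALSE)
}

#' Fit branch-site model A (BS) or its fixed null (BSfixed)
#'
#' Model A mixes four site classes: 0 (omega0 < 1 everywhere), 1 (neutral
#' everywhere), 2a (omega0 on background, omega2 on foreground) and 2b
#' (neutral on background, omega2 on foreground).  The alternative (BS)
#' estimates omega2 >= 1 freely; the null (BSfixed) fixes omega2 = 1.
#' Branch lengths are held at the M0 estimates.  Deterministic multi-starts
#' guard against the model's well-known local optima.
#'
#' @inheritParams fit_branch_model
#' @param fix_omega2 Fix omega2 at 1 (the null).
#' @param n_starts Number of deterministic optimizer starts.
#' @return A `codonsel_fit` with a `mixture` element (class proportions and
#'   omegas) and `site_posterior` (naive empirical Bayes posterior of each
#'   class per codon site, at the MLE).
#' @export
fit_branch_site <- function(aln, tree, fix_omega2 = FALSE, m0_fit,
                            null_fit = NULL, n_starts = 5,
                            control = list()) {
  ctl <- fit_control(control)
  eng <- make_engine(aln, tree)
  if (!any(eng$fg))
    cs_stop("no foreground branches marked; use mark_clade() or #1 tags")
  pi <- m0_fit$pi
  tlen <- m0_branch_lengths(eng, m0_fit)
  logit <- stats::qlogis; expit <- stats::plogis

  unpack <- function(p) {
    th1 <- expit(p[2]); th2 <- expit(p[3]); w0 <- expit(p[4])
    w2 <- if (fix_omega2) 1 else 1 + exp(p[5])
    list(kappa = exp(p[1]), p0 = th1 * th2, p1 = th1 * (1 - th2),
         w0 = w0, w2 = w2)
  }
  class_pat_ll <- function(kappa, w0, w2) {
    tab <- bs_class_table(0.25, 0.25, w0, w2)
    vapply(seq_len(4), function(cl) {
      oe <- ifelse(eng$fg, tab$omega_foreground[cl], tab$omega_background[cl])
      eng$pat_loglik(kappa, pi, oe, tlen)$pat
    }, numeric(eng$n_patterns))
  }
  mix_loglik <- function(q, ll) {
    props <- pmax(c(q$p0, q$p1,
                    (1 - q$p0 - q$p1) * q$p0 / (q$p0 + q$p1),
                    (1 - q$p0 - q$p1) * q$p1 / (q$p0 + q$p1)), 1e-300)
    mixed <- logsumexp_rows(sweep(ll, 2, log(props), "+"))
    sum(eng$weights * mixed)
  }
  fn <- function(p) {
    q <- unpack(p)
    -mix_loglik(q, class_pat_ll(q$kappa, q$w0, q$w2))
  }

  k0 <- log(m0_fit$kappa)
  grid <- expand.grid(w0 = c(0.1, 0.5), th1 = c(0.8, 0.95),
                      th2 = 0.75, w2 = if (fix_omega2) NA else c(2, 5))
  starts <- lapply(seq_len(nrow(grid)), function(i) {
    s <- c(k0, logit(grid$th1[i]), logit(grid$th2[i]), logit(grid$w0[i]))
    if (!fix_omega2) s <- c(s, log(grid$w2[i] - 1))
    s
  })
  if (!is.null(null_fit) && !fix_omega2) {
    m <- null_fit$mixture
    th1 <- m$p0 + m$p1
    starts <- c(list(c(log(null_fit$kappa), logit(min(th1, 0.9999)),
                       logit(m$p0 / th1), logit(min(max(m$omega0, 1e-3),
                                                    0.999)),
                       log(1e-6))), starts)
  }
  starts <- starts[seq_len(min(length(starts),
                               n_starts + !is.null(null_fit)))]
  lower <- c(log(.K_LO), -9, -9, -9)
  upper <- c(log(.K_HI), 9, 9, 9)
  if (!fix_omega2) { lower <- c(lower, log(1e-6)); upper <- c(upper, log(.OM_HI - 1)) }

  opts <- lapply(starts, function(s) run_bounded(s, fn, lower, upper, ctl))
  vals <- vapply(opts, `[[`, 0, "value")
  o <- opts[[which.min(vals)]]
  q <- unpack(o$par)
  at_boundary <- expit(o$par[2]) > 0.9999
  if (at_boundary)
    warning("branch-site optimum at boundary p0+p1=1; see multi-start lnLs ",
            paste(sprintf("%.3f", -vals), collapse = ", "))

  tab <- bs_class_table(q$p0, q$p1, q$w0, q$w2)
  ll <- class_pat_ll(q$kappa, q$w0, q$w2)
  lnL <- mix_loglik(q, ll)
  # naive empirical Bayes class posteriors at the MLE
  lp <- sweep(ll, 2, log(pmax(tab$proportion, 1e-300)), "+")
  post_pat <- exp(lp - logsumexp_rows(lp))
  site_post <- post_pat[eng$pat_of_site, , drop = FALSE]
  colnames(site_post) <- tab$class

  oe_repr <- ifelse(eng$fg, q$w2, q$w0)  # representative (class 2a) rates
  fit <- new_model_fit(if (fix_omega2) "BSfixed" else "BS", eng, o, lnL,
                n_free = if (fix_omega2) 4L else 5L,
                kappa = q$kappa, pi = pi, freq_scheme = m0_fit$freq_scheme,
                tlen = tlen, omega_edge = oe_repr,
                extra = list(
                  mixture = list(p0 = tab$proportion[1],
                                 p1 = tab$proportion[2],
                                 p2a = tab$proportion[3],
                                 p2b = tab$proportion[4],
                                 omega0 = q$w0, omega1 = 1,
                                 omega2 = q$w2),
                  site_posterior = site_post,
                  class_pat_loglik = ll,
                  multi_start_loglik = -vals,
                  boundary = at_boundary))
  fit
}

#' Compare codon frequency schemes by AIC
#'
#' Fits the one-ratio model under each requested frequency scheme and
#' ranks the fits by AIC, counting the frequency parameters each scheme
#' estimates from the data (equal: 0, F1x4: 3, F3x4: 9, F61: 60) on top
#' of the model's free parameters.
#'
#' @inheritParams fit_m0
#' @param schemes Character vector of schemes to compare.
#' @return Data frame with `scheme`, `loglik`, `n_params`, `aic`,
#'   ordered best first; the corresponding fits are attached as
#'   attribute `"fits"`.
#' @export
compare_freq_schemes <- function(aln, tree,
                                 schemes = c("equal", "F1x4", "F3x4",
                                             "F61"),
                                 control = list()) {
  pi_params <- c(equal = 0L, F1x4 = 3L, F3x4 = 9L, F61 = 60L)
  fits <- lapply(schemes, function(s) fit_m0(aln, tree, freq_scheme = s,
                                             control = control))
  names(fits) <- schemes
  out <- data.frame(
    scheme = schemes,
    loglik = vapply(fits, `[[`, 0, "loglik"),
    n_params = vapply(fits, `[[`, 0L, "n_free_params") +
      pi_params[schemes],
    stringsAsFactors = FALSE)
  out$aic <- -2 * out$loglik + 2 * out$n_params
  out <- out[order(out$aic), ]
  rownames(out) <- NULL
  structure(out, fits = fits)
}
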