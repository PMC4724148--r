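# Likelihood ratio tests, the selection-regime decision table, per-branch
# dN/dS decomposition, the root-to-tip omega statistic, and detection of
# positively selected sites by (Bayes) empirical Bayes.

#' Likelihood ratio test between nested model fits
#'
#' @param fit_null,fit_alt `codonsel_fit` objects (or bare log-likelihoods)
#'   of nested models fitted to the same data.
#' @param df Degrees of freedom (number of extra free parameters in the
#'   alternative); 1 for M0 vs MC, MCfixed vs MC, and BSfixed vs BS.
#' @param mixture Use the 50:50 point-mass/chi-square(1) boundary null
#'   instead of the plain chi-square (relevant to the branch-site test).
#' @param tol If `lnL_alt < lnL_null - tol`, warn that the alternative is
#'   under-optimized; the statistic is clipped at 0 either way.
#' @return An `lrt_result`: list with `two_delta`, `df`, `p`.
#' @export
lrt <- function(fit_null, fit_alt, df = 1, mixture = FALSE, tol = 1e-5) {
  ln0 <- if (inherits(fit_null, "codonsel_fit")) fit_null$loglik
         else as.numeric(fit_null)
  ln1 <- if (inherits(fit_alt, "codonsel_fit")) fit_alt$loglik
         else as.numeric(fit_alt)
  if (ln1 < ln0 - tol)
    warning(sprintf("alternative under-optimized (lnL_alt - lnL_null = %.6g)",
                    ln1 - ln0))
  two_delta <- max(0, 2 * (ln1 - ln0))
  p <- stats::pchisq(two_delta, df, lower.tail = FALSE)
  if (mixture) p <- if (two_delta == 0) 1 else 0.5 * p
  structure(list(two_delta = two_delta, df = df, p = min(p, 1)),
            class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("LRT: 2*delta = %.4f, df = %d, p = %.4g\n",
              x$two_delta, x$df, x$p))
  invisible(x)
}

#' Classify the selection regime of a foreground clade
#'
#' Combines the M0-vs-MC test (does the foreground evolve at a different
#' rate than the background?) and the MCfixed-vs-MC test (is the foreground
#' rate different from 1?) into a regime label.  When M0 vs MC is not
#' significant the M0 omega is the effective rate reported; otherwise the
#' MC foreground omega is.
#'
#' Decision table (sig = p <= alpha):
#' \itemize{
#'   \item both significant: `positive` if foreground omega > 1 else
#'     `conserved`;
#'   \item M0-vs-MC significant only: `relaxed` (rate differs from the
#'     background but is indistinguishable from 1);
#'   \item MCfixed-vs-MC significant only: `positive`/`conserved` by the
#'     effective (M0) omega;
#'   \item neither significant: `relaxed`.
#' }
#'
#' @param lrt_m0_mc,lrt_mcfix_mc [lrt()] results for M0 vs MC and MCfixed
#'   vs MC on the same foreground marking.
#' @param omega_fg The MC foreground omega.
#' @param omega_m0 The M0 omega.
#' @param alpha Significance level, default 0.05.
#' @return A `regime_call`: list with `label` (one of `conserved`,
#'   `positive`, `relaxed`), `effective_omega`, `omega_source` (`"MC"` or
#'   `"M0"`), and the two tests.
#' @export
classify_regime <- function(lrt_m0_mc, lrt_mcfix_mc, omega_fg, omega_m0,
                            alpha = 0.05) {
  sig1 <- lrt_m0_mc$p <= alpha
  sig2 <- lrt_mcfix_mc$p <= alpha
  eff <- if (sig1) omega_fg else omega_m0
  label <- if (sig1 && sig2) {
    if (omega_fg > 1) "positive" else "conserved"
  } else if (sig1 && !sig2) {
    "relaxed"
  } else if (!sig1 && sig2) {
    if (eff > 1) "positive" else "conserved"
  } else {
    "relaxed"
  }
  structure(list(label = label, effective_omega = eff,
                 omega_source = if (sig1) "MC" else "M0",
                 lrt_m0_mc = lrt_m0_mc, lrt_mcfix_mc = lrt_mcfix_mc,
                 alpha = alpha),
            class = "regime_call")
}

#' Classify site-level selection from the branch-site test
#'
#' @param lrt_bsfix_bs [lrt()] result for BSfixed vs BS.
#' @param alpha Significance level.
#' @return `"positive"` when the test is significant, `"no_signal"`
#'   otherwise.
#' @export
classify_site_regime <- function(lrt_bsfix_bs, alpha = 0.05) {
  if (lrt_bsfix_bs$p <= alpha) "positive" else "no_signal"
}

#' @export
print.regime_call <- function(x, ...) {
  cat(sprintf("regime: %s (effective omega %.3f from %s)\n",
              x$label, x$effective_omega, x$omega_source))
  invisible(x)
}

#' Per-branch dN and dS from a branch length and omega
#'
#' Decomposes a branch length t (expected substitutions per codon) into
#' nonsynonymous and synonymous per-site rates: with rhoN the fraction of
#' equilibrium flux that is nonsynonymous under the branch's omega, and
#' (N, S) the site opportunities from [site_opportunity()],
#' `dN = t * rhoN / N` and `dS = t * (1 - rhoN) / S`, so that
#' `dN * N + dS * S = t` exactly.
#'
#' @param t Branch length, >= 0.
#' @param params A [codon_model_params()] carrying the branch's omega.
#' @return Named vector `c(dN = ..., dS = ...)`.
#' @export
branch_dn_ds <- function(t, params) {
  if (t < 0) cs_stop("branch length must be >= 0")
  NS <- site_opportunity(params)
  if (NS["S"] <= 0) cs_stop("degenerate code: no synonymous sites")
  rhoN <- nonsyn_flux_fraction(params)
  c(dN = unname(t * rhoN / NS["N"]), dS = unname(t * (1 - rhoN) / NS["S"]))
}

# child-node path from `tip` up to (not including) `from_node`
path_nodes <- function(tree, tip_node, from_node) {
  nodes <- integer(0)
  node <- tip_node
  repeat {
    if (node == from_node) break
    nodes <- c(nodes, node)
    parents <- tree$edge[tree$edge[, 2] == node, 1]
    if (length(parents) == 0L)
      cs_stop("tip is not a descendant of the given clade root")
    node <- parents[1]
  }
  nodes
}

#' Root-to-tip omega along a clade path
#'
#' Sums the free-ratio dN and dS over the branches from a clade's root down
#' to a terminal branch and takes the ratio of the sums.  The clade root's
#' own stem branch is included by default (clades are marked up to and
#' including their last common ancestor).
#'
#' @param free_fit A [fit_free_ratio()] fit covering all path branches.
#' @param tip Tip label.
#' @param clade_root Either an internal node id of `free_fit$tree` or a
#'   character vector of tip labels whose MRCA defines the clade root.
#' @param include_stem Include the stem branch above the clade root.
#' @return The ratio `sum(dN)/sum(dS)`; `NA` (with attribute `"reason"`)
#'   when the synonymous path sum is zero, in which case the value is
#'   excluded from downstream regressions.
#' @export
root_to_tip_omega <- function(free_fit, tip, clade_root,
                              include_stem = TRUE) {
  tree <- free_fit$tree
  if (is.character(clade_root)) {
    clade_root <- if (length(clade_root) == 1L)
      match(clade_root, tree$tip.label)
    else ape::getMRCA(tree, clade_root)
  }
  tip_node <- match(tip, tree$tip.label)
  if (is.na(tip_node)) cs_stop(paste0("tip not in tree: ", tip))
  children <- path_nodes(tree, tip_node, clade_root)
  if (include_stem && any(tree$edge[, 2] == clade_root))
    children <- c(children, clade_root)
  pb <- free_fit$per_branch
  rows <- match(children, pb$child)
  dn <- sum(pb$dN[rows])
  ds <- sum(pb$dS[rows])
  if (ds <= 0)
    return(structure(NA_real_, reason = "zero synonymous path change",
                     dn_sum = dn, ds_sum = ds))
  structure(dn / ds, dn_sum = dn, ds_sum = ds)
}

#' Root-to-tip omega table for marked clades
#'
#' @param free_fit A [fit_free_ratio()] fit.
#' @param clades Named list of tip-label sets defining clades.
#' @param include_stem Include each clade's stem branch in the path.
#' @return Data frame with `species`, `clade`, `dn_sum`, `ds_sum`,
#'   `omega_rtt` (NA when the synonymous sum is zero).
#' @export
root_to_tip_table <- function(free_fit, clades, include_stem = TRUE) {
  out <- do.call(rbind, lapply(names(clades), function(cl) {
    tips <- clades[[cl]]
    do.call(rbind, lapply(tips, function(tp) {
      w <- root_to_tip_omega(free_fit, tp, tips, include_stem)
      data.frame(species = tp, clade = cl,
                 dn_sum = attr(w, "dn_sum"), ds_sum = attr(w, "ds_sum"),
                 omega_rtt = as.numeric(w), stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}

# Bayes empirical Bayes posterior of the positive classes (2a + 2b) per
# site: kappa and branch lengths held at their MLEs, a uniform prior over
# a grid of (p0, p1) on the simplex, omega0 in (0,1) and omega2 in
# (1, 11), integrating the class posterior over the grid weighted by each
# grid point's posterior given the whole alignment.
beb_positive_posterior <- function(fit) {
  eng <- fit$engine
  pi <- fit$pi
  kappa <- fit$kappa
  tlen <- fit$per_branch$t
  pat_ll_for <- function(w_bg, w_fg) {
    eng$pat_loglik(kappa, pi, ifelse(eng$fg, w_fg, w_bg), tlen)$pat
  }
  gw0 <- (2 * seq_len(10) - 1) / 20          # 0.05 .. 0.95
  gw2 <- 1 + (2 * seq_len(10) - 1) / 2       # 1.5 .. 10.5
  ll0 <- vapply(gw0, function(w) pat_ll_for(w, w), numeric(eng$n_patterns))
  ll1 <- pat_ll_for(1, 1)
  ll2b <- vapply(gw2, function(w2) pat_ll_for(1, w2),
                 numeric(eng$n_patterns))
  ll2a <- array(0, c(eng$n_patterns, 10, 10))
  for (k in seq_len(10)) for (m in seq_len(10))
    ll2a[, k, m] <- pat_ll_for(gw0[k], gw2[m])

  gp <- (2 * seq_len(10) - 1) / 20
  pp <- expand.grid(i = seq_len(10), j = seq_len(10))
  pp <- pp[gp[pp$i] + gp[pp$j] < 1, ]
  combos <- expand.grid(ij = seq_len(nrow(pp)), k = seq_len(10),
                        m = seq_len(10))
  G <- nrow(combos)
  data_ll <- numeric(G)
  pos <- matrix(0, G, eng$n_patterns)
  for (g in seq_len(G)) {
    p0 <- gp[pp$i[combos$ij[g]]]
    p1 <- gp[pp$j[combos$ij[g]]]
    props <- c(p0, p1, (1 - p0 - p1) * p0 / (p0 + p1),
               (1 - p0 - p1) * p1 / (p0 + p1))
    lp <- cbind(ll0[, combos$k[g]], ll1,
                ll2a[, combos$k[g], combos$m[g]],
                ll2b[, combos$m[g]]) +
      rep(log(pmax(props, 1e-300)), each = eng$n_patterns)
    mixed <- logsumexp_rows(lp)
    data_ll[g] <- sum(eng$weights * mixed)
    pos[g, ] <- exp(lp[, 3] - mixed) + exp(lp[, 4] - mixed)
  }
  alpha <- exp(data_ll - max(data_ll))
  alpha <- alpha / sum(alpha)
  as.numeric(crossprod(pos, alpha))[eng$pat_of_site]
}

#' Detect positively selected sites from a branch-site fit
#'
#' Reports sites whose posterior probability of the positive-selection
#' classes (2a + 2b) on the foreground meets a threshold, in the
#' "64R"-style notation (1-based alignment codon site + reference-taxon
#' residue).
#'
#' @param bs_fit A [fit_branch_site()] alternative fit (`model_id "BS"`);
#'   requesting sites from the fixed null is an error.
#' @param threshold Posterior probability cutoff, default 0.95.
#' @param method `"BEB"` (default): Bayes empirical Bayes, integrating the
#'   mixture parameters over a grid; `"NEB"`: naive empirical Bayes at the
#'   MLE.
#' @param ref_taxon Taxon whose residues label the sites (default: first
#'   taxon of the alignment).
#' @return Data frame with `site`, `residue`, `posterior`, `label`; the
#'   full per-site posterior is attached as attribute `"posterior"`.
#' @export
detect_pss <- function(bs_fit, threshold = 0.95, method = c("BEB", "NEB"),
                       ref_taxon = NULL) {
  method <- match.arg(method)
  if (!identical(bs_fit$model_id, "BS"))
    cs_stop(paste0("positively selected sites require the BS alternative ",
                   "fit; the null has no positive class on the foreground"))
  post <- if (method == "BEB") beb_positive_posterior(bs_fit)
          else rowSums(bs_fit$site_posterior[, c("2a", "2b"), drop = FALSE])
  eng <- bs_fit$engine
  code <- genetic_code(eng$genetic_code_id)
  ref_row <- if (is.null(ref_taxon)) 1L
             else match(ref_taxon, eng$tree$tip.label)
  if (is.na(ref_row)) cs_stop(paste0("ref_taxon not in tree: ", ref_taxon))
  states <- eng$tipm[ref_row, eng$pat_of_site]
  residue <- ifelse(states > 0, code$aa[states], "-")
  hits <- which(post >= threshold)
  out <- data.frame(site = hits, residue = residue[hits],
                    posterior = post[hits],
                    label = paste0(hits, residue[hits]),
                    stringsAsFactors = FALSE)
  structure(out, posterior = post, method = method)
}
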