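# Phylogenetic generalized least squares with maximum-likelihood profiling
# of Pagel's lambda on [0,1], coefficient t-tests, R^2 in the whitened
# space, and boundary likelihood-ratio tests of lambda against 0 and 1.

#' Phylogenetic covariance matrix
#'
#' `C[i, j]` is the shared path length from the root to the most recent
#' common ancestor of species i and j; the diagonal holds root-to-tip
#' distances (Brownian-motion trait covariance up to a rate constant).
#'
#' @param tree A `phylo` with branch lengths.
#' @param species_subset Optional tip subset (order preserved).
#' @return Covariance matrix with species dimnames.
#' @export
phylo_covariance <- function(tree, species_subset = NULL) {
  if (is.null(tree$edge.length) || sum(tree$edge.length) <= 0)
    cs_stop("tree has no (or zero-length) branch lengths")
  C <- ape::vcv.phylo(tree)
  if (!is.null(species_subset)) {
    missing <- setdiff(species_subset, rownames(C))
    if (length(missing))
      cs_stop(paste0("species not in tree: ",
                     paste(missing, collapse = ", ")))
    C <- C[species_subset, species_subset, drop = FALSE]
  }
  C
}

#' Pagel's lambda transformation of a phylogenetic covariance
#'
#' Multiplies the off-diagonal entries by `lambda`, leaving the diagonal
#' unchanged: `lambda = 0` gives the independence (OLS) limit, `lambda = 1`
#' returns the Brownian covariance untouched.
#'
#' @param C Covariance matrix from [phylo_covariance()].
#' @param lambda Value in `[0, 1]`.
#' @return The transformed matrix.
#' @export
apply_lambda <- function(C, lambda) {
  if (!is.numeric(lambda) || lambda < 0 || lambda > 1)
    cs_stop("lambda must lie in [0, 1]")
  Cl <- lambda * C
  diag(Cl) <- diag(C)
  Cl
}

# GLS fit at fixed lambda; returns the pieces needed for the profile.
gls_at_lambda <- function(y, X, C, lambda, method) {
  n <- length(y)
  p <- ncol(X)
  Cl <- apply_lambda(C, lambda)
  L <- chol(Cl)
  yw <- backsolve(L, y, transpose = TRUE)
  Xw <- backsolve(L, X, transpose = TRUE)
  qx <- qr(Xw)
  if (qx$rank < p) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):p]]
    cs_stop(paste0("singular design; collinear column(s): ",
                   paste(bad, collapse = ", ")))
  }
  beta <- qr.coef(qx, yw)
  res <- yw - Xw %*% beta
  rss <- sum(res^2)
  logdetC <- 2 * sum(log(diag(L)))
  XtX <- crossprod(Xw)
  if (method == "REML") {
    s2 <- rss / (n - p)
    ll <- -0.5 * ((n - p) * log(2 * pi * s2) + (n - p) + logdetC +
                    determinant(XtX, logarithm = TRUE)$modulus)
  } else {
    s2 <- rss / n
    ll <- -0.5 * (n * log(2 * pi * s2) + n + logdetC)
  }
  list(beta = beta, rss = rss, loglik = as.numeric(ll), XtX = XtX,
       s2_reml = rss / (n - p), yw = yw, Xw = Xw)
}

#' Fit a phylogenetic generalized least squares regression
#'
#' GLS under a Pagel's-lambda-scaled Brownian covariance, with lambda
#' either fixed or profiled over `[0, 1]`.  Coefficient t-tests use
#' `n - p` degrees of freedom; R^2 compares the residual sum of squares to
#' an intercept-only GLS fit in the same whitened space; lambda is tested
#' against the fixed values 0 and 1 by likelihood ratio, using by default
#' the 50:50 point-mass/chi-square(1) boundary null.
#'
#' @param formula Model formula.
#' @param data Data frame; species labels from a `species` column or row
#'   names.
#' @param tree A `phylo` containing all species (extra tips are pruned).
#' @param lambda `"ML"` to profile, or a fixed value in `[0, 1]`.
#' @param method `"REML"` (default) or `"ML"` criterion for the profile.
#' @param mixture_null Use the boundary 50:50 mixture for the lambda LRTs;
#'   `FALSE` gives the plain chi-square(1).
#' @return A `pgls_fit`: coefficient table, `r_squared`, `lambda`,
#'   `lambda_lrt` (p-values vs 0 and 1), `loglik`, `n`.
#' @export
pgls_fit <- function(formula, data, tree, lambda = "ML",
                     method = c("REML", "ML"), mixture_null = TRUE) {
  method <- match.arg(method)
  species <- data$species %||% rownames(data)
  if (is.null(species)) cs_stop("data needs species row names or column")
  mf <- stats::model.frame(formula, data = data, na.action = stats::na.pass)
  keep <- stats::complete.cases(mf)
  mf <- mf[keep, , drop = FALSE]
  species <- species[keep]
  if (anyDuplicated(species)) cs_stop("duplicate species in data")
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  n <- length(y)
  p <- ncol(X)
  if (n < p + 2L)
    cs_stop(sprintf("insufficient data: n = %d with %d coefficients", n, p),
            "codonsel_insufficient_data")
  C <- phylo_covariance(prune_to_taxa(tree, species), species)

  profile_ll <- function(l) gls_at_lambda(y, X, C, l, method)$loglik
  if (identical(lambda, "ML")) {
    opt <- stats::optimize(profile_ll, c(0, 1), maximum = TRUE,
                           tol = 1e-8)
    cand <- c(opt$maximum, 0, 1)
    lls <- c(opt$objective, profile_ll(0), profile_ll(1))
    lambda_hat <- cand[which.max(lls)]
  } else {
    lambda_hat <- as.numeric(lambda)
  }
  fit <- gls_at_lambda(y, X, C, lambda_hat, method)

  vb <- fit$s2_reml * solve(fit$XtX)
  se <- sqrt(diag(vb))
  tval <- as.numeric(fit$beta) / se
  pval <- 2 * stats::pt(abs(tval), df = n - p, lower.tail = FALSE)
  coefs <- data.frame(term = colnames(X), estimate = as.numeric(fit$beta),
                      std_error = se, t = tval, p = pval,
                      stringsAsFactors = FALSE)

  null_fit <- gls_at_lambda(y, matrix(1, n, 1), C, lambda_hat, "ML")
  r2 <- 1 - fit$rss / null_fit$rss

  lam_lrt <- c(vs0 = NA_real_, vs1 = NA_real_)
  if (identical(lambda, "ML")) {
    for (k in c(0, 1)) {
      td <- 2 * (fit$loglik - profile_ll(k))
      td <- if (is.finite(td)) max(0, td) else NA_real_
      pp <- stats::pchisq(td, 1, lower.tail = FALSE)
      if (mixture_null && !is.na(td)) pp <- if (td == 0) 1 else 0.5 * pp
      lam_lrt[[if (k == 0) "vs0" else "vs1"]] <- min(pp, 1)
    }
  }
  structure(list(coefficients = coefs, r_squared = r2,
                 lambda = lambda_hat, lambda_lrt = lam_lrt,
                 loglik = fit$loglik, n = n, method = method,
                 formula = formula, species = species),
            class = "pgls_fit")
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat(sprintf("PGLS (%s): n = %d, lambda = %.3f, R2 = %.3f\n",
              x$method, x$n, x$lambda, x$r_squared))
  print(x$coefficients, row.names = FALSE, digits = 4)
  invisible(x)
}

lambda_superscript <- function(p, alpha = 0.05) {
  if (is.na(p)) "na" else if (p <= alpha) "*" else "ns"
}

#' Run the comparative regression suite
#'
#' Per clade and per domain, fits the standard model list: root-to-tip
#' omega against log body mass + log testes mass (the sperm-competition
#' proxy regression), mature-domain arginine content against the same
#' proxies, and relative head length, relative head width and head
#' elongation each against root-to-tip omega.  Rows with insufficient
#' complete cases are reported as skipped with a reason rather than
#' aborting the suite.
#'
#' @param omega_table Data frame with `species`, `clade`, `domain`,
#'   `omega_rtt` (see [root_to_tip_table()]); undefined omegas (`NA`) are
#'   dropped pairwise.
#' @param phenotypes Derived phenotype table (see [derive_traits()]).
#' @param tree A `phylo` covering the species.
#' @param seq_stats Optional per-species table with `arginine_pct_mature`
#'   (see [domain_sequence_stats()]).
#' @param alpha Significance level used for the lambda superscripts.
#' @param method `"REML"` or `"ML"` for the lambda profile.
#' @param log_base Base for the mass logarithms (default 10).
#' @return Data frame shaped like a regression report table: one row per
#'   (model, predictor) with `n`, `slope`, `t`, `r_squared`, `lambda`,
#'   `lambda_note`, `p`, plus `status`/`reason` for skipped rows.
#' @export
run_regression_suite <- function(omega_table, phenotypes, tree,
                                 seq_stats = NULL, alpha = 0.05,
                                 method = "REML", log_base = 10) {
  rows <- list()
  add_model <- function(domain, clade, dependent, formula, data) {
    fit <- tryCatch(pgls_fit(formula, data, tree, method = method),
                    error = function(e) e)
    terms_x <- setdiff(all.vars(formula)[-1], "")
    if (inherits(fit, "error")) {
      reason <- if (inherits(fit, "codonsel_insufficient_data"))
        "insufficient data" else conditionMessage(fit)
      return(data.frame(domain = domain, clade = clade,
                        dependent = dependent, independent = terms_x,
                        n = sum(stats::complete.cases(
                          data[, all.vars(formula), drop = FALSE])),
                        slope = NA, t = NA, r_squared = NA, lambda = NA,
                        lambda_note = NA, p = NA, status = "skipped",
                        reason = reason, stringsAsFactors = FALSE))
    }
    cf <- fit$coefficients[-1, , drop = FALSE]  # drop intercept row
    note <- sprintf("%.2g(%s,%s)", fit$lambda,
                    lambda_superscript(fit$lambda_lrt[["vs0"]], alpha),
                    lambda_superscript(fit$lambda_lrt[["vs1"]], alpha))
    data.frame(domain = domain, clade = clade, dependent = dependent,
               independent = cf$term, n = fit$n, slope = cf$estimate,
               t = cf$t, r_squared = fit$r_squared, lambda = fit$lambda,
               lambda_note = note, p = cf$p, status = "ok", reason = "",
               stringsAsFactors = FALSE)
  }

  ph <- phenotypes
  ph$log_body_mass <- log(ph$body_mass, log_base)
  ph$log_testes_mass <- log(ph$testes_mass, log_base)

  for (dom in unique(omega_table$domain)) {
    for (cl in unique(omega_table$clade)) {
      om <- omega_table[omega_table$domain == dom &
                          omega_table$clade == cl, ]
      dat <- merge(om[, c("species", "omega_rtt")], ph, by = "species")
      if (!is.null(seq_stats))
        dat <- merge(dat, seq_stats, by = "species", all.x = TRUE)
      rownames(dat) <- dat$species
      dep_omega <- paste0(dom, " omega_rtt")
      rows <- c(rows, list(
        add_model(dom, cl, dep_omega,
                  omega_rtt ~ log_body_mass + log_testes_mass, dat)))
      if (dom == "mature" && "arginine_pct_mature" %in% names(dat))
        rows <- c(rows, list(
          add_model(dom, cl, "arginine_pct_mature",
                    arginine_pct_mature ~ log_body_mass + log_testes_mass,
                    dat)))
      for (dep in c("relative_hl", "relative_hw", "elongation"))
        if (dep %in% names(dat))
          rows <- c(rows, list(
            add_model(dom, cl, dep,
                      stats::as.formula(paste(dep, "~ omega_rtt")), dat)))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
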