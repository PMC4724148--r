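# Goldman-Yang style codon substitution process: equilibrium frequencies,
# the instantaneous rate matrix in (kappa, omega) parameterization, its
# normalization to one expected substitution per codon per unit branch
# length, and the synonymous/nonsynonymous site decomposition.

#' Codon model parameters
#'
#' @param kappa Transition/transversion rate ratio (> 0).
#' @param omega dN/dS ratio (>= 0).
#' @param pi Equilibrium frequency vector over the sense codons (sums to 1).
#' @param genetic_code_id NCBI translation-table number.
#' @return A `codon_model_params` object.
#' @export
codon_model_params <- function(kappa, omega, pi,
                               genetic_code_id = 1L) {
  code <- genetic_code(genetic_code_id)
  if (!is.numeric(kappa) || kappa <= 0) cs_stop("kappa must be > 0")
  if (!is.numeric(omega) || omega < 0) cs_stop("omega must be >= 0")
  if (length(pi) != length(code$codons))
    cs_stop(sprintf("pi must have %d entries", length(code$codons)))
  if (any(pi < 0) || abs(sum(pi) - 1) > 1e-10)
    cs_stop("pi must be nonnegative and sum to 1 within 1e-10")
  structure(list(kappa = kappa, omega = omega, pi = as.numeric(pi),
                 genetic_code_id = genetic_code_id),
            class = "codon_model_params")
}

#' Estimate codon equilibrium frequencies from an alignment
#'
#' @param aln A `codon_alignment`.
#' @param scheme One of `"equal"` (uniform over sense codons), `"F1x4"`
#'   (products of overall nucleotide frequencies), `"F3x4"` (products of
#'   position-specific nucleotide frequencies), `"F61"` (observed codon
#'   frequencies).  For the product schemes, mass assigned to stop codons is
#'   renormalized over the sense codons.
#' @param floor Minimum frequency; entries below it are floored (with a
#'   warning when an observed codon would otherwise get zero mass) and the
#'   vector renormalized, keeping the likelihood finite.
#' @return Numeric frequency vector over the sense codons.
#' @export
estimate_codon_frequencies <- function(aln,
                                       scheme = c("F3x4", "equal",
                                                  "F1x4", "F61"),
                                       floor = 1e-6) {
  scheme <- match.arg(scheme)
  code <- genetic_code(aln$genetic_code_id)
  nc <- length(code$codons)
  if (length(aln$taxa) == 0L || n_codon_sites(aln) == 0L)
    cs_stop("empty alignment")
  obs <- aln$states[!is.na(aln$states)]
  if (scheme == "equal") {
    pi <- rep(1 / nc, nc)
  } else if (scheme == "F61") {
    cnt <- tabulate(obs, nbins = nc)
    pi <- cnt / sum(cnt)
  } else {
    codons <- code$codons[obs]
    mat <- do.call(rbind, strsplit(codons, ""))
    nt <- c("T", "C", "A", "G")
    if (scheme == "F1x4") {
      f <- table(factor(as.vector(mat), levels = nt))
      f <- as.numeric(f) / sum(f)
      fpos <- list(f, f, f)
    } else {
      fpos <- lapply(1:3, function(p) {
        f <- table(factor(mat[, p], levels = nt))
        as.numeric(f) / sum(f)
      })
    }
    cmat <- do.call(rbind, strsplit(code$codons, ""))
    pi <- fpos[[1]][match(cmat[, 1], nt)] *
      fpos[[2]][match(cmat[, 2], nt)] *
      fpos[[3]][match(cmat[, 3], nt)]
    pi <- pi / sum(pi)  # renormalize stop-codon mass over sense codons
  }
  low <- pi < floor
  if (any(low)) {
    if (any(low & tabulate(obs, nbins = nc) > 0))
      warning("scheme assigns ~zero frequency to an observed codon; flooring")
    pi[low] <- floor
    pi <- pi / sum(pi)
  }
  pi
}

#' Build the normalized codon rate matrix
#'
#' Off-diagonal rates follow the standard single-nucleotide-change
#' parameterization: 0 for multi-nucleotide changes, `pi_j` for synonymous
#' transversions, `kappa*pi_j` for synonymous transitions, with an extra
#' factor `omega` for nonsynonymous changes.  The matrix is rescaled so the
#' expected number of substitutions per codon per unit time is 1.
#'
#' @param params A [codon_model_params()].
#' @return A `rate_matrix` object: list with `Q` (normalized generator) and
#'   `scale` (the pre-normalization expected substitution rate).
#' @export
build_rate_matrix <- function(params) {
  code <- genetic_code(params$genetic_code_id)
  pairs <- codon_pair_table(code)
  nc <- length(code$codons)
  Q <- matrix(0, nc, nc, dimnames = list(code$codons, code$codons))
  rate <- params$pi[pairs$j] *
    ifelse(pairs$is_transition, params$kappa, 1) *
    ifelse(pairs$is_synonymous, 1, params$omega)
  Q[cbind(pairs$i, pairs$j)] <- rate
  diag(Q) <- -rowSums(Q)
  scale <- -sum(params$pi * diag(Q))
  if (scale <= 0) cs_stop("degenerate rate matrix (zero total flux)")
  structure(list(Q = Q / scale, scale = scale), class = "rate_matrix")
}

# Fraction of equilibrium substitution flux that is nonsynonymous under the
# given parameters (rho_N); rho_S = 1 - rho_N.
nonsyn_flux_fraction <- function(params) {
  code <- genetic_code(params$genetic_code_id)
  pairs <- codon_pair_table(code)
  w <- params$pi[pairs$i] * params$pi[pairs$j] *
    ifelse(pairs$is_transition, params$kappa, 1) *
    ifelse(pairs$is_synonymous, 1, params$omega)
  sum(w[!pairs$is_synonymous]) / sum(w)
}

#' Synonymous and nonsynonymous site opportunities per codon
#'
#' Mutational-opportunity decomposition: with omega forced to 1, the
#' fraction of equilibrium flux that is nonsynonymous defines N = 3*rhoN1
#' nonsynonymous sites and S = 3 - N synonymous sites per codon.
#'
#' @param params A [codon_model_params()] (its omega is ignored).
#' @return Named numeric vector `c(N = ..., S = ...)` with `N + S = 3`.
#' @export
site_opportunity <- function(params) {
  p1 <- codon_model_params(params$kappa, 1, params$pi,
                           params$genetic_code_id)
  rhoN1 <- nonsyn_flux_fraction(p1)
  N <- 3 * rhoN1
  c(N = N, S = 3 - N)
}

# Symmetric eigendecomposition of the normalized reversible generator.
# With D = diag(pi), A = D^{1/2} Q D^{-1/2} is symmetric; P(t) =
# D^{-1/2} V exp(Lambda t) V' D^{1/2}.  Frequencies must be positive
# (guaranteed by the frequency floor).
codon_decomp <- function(params) {
  rm <- build_rate_matrix(params)
  sqp <- sqrt(params$pi)
  A <- rm$Q * outer(sqp, 1 / sqp)
  A <- (A + t(A)) / 2  # symmetrize numerical residue
  e <- eigen(A, symmetric = TRUE)
  list(V = e$vectors, lambda = e$values, sqp = sqp, pi = params$pi)
}

#' Codon transition probability matrix
#'
#' @param Q A `rate_matrix` from [build_rate_matrix()], or a
#'   [codon_model_params()] object.
#' @param t Branch length (expected substitutions per codon), >= 0.
#' @param params The parameters used to build `Q` (needed for the
#'   equilibrium frequencies when `Q` is a `rate_matrix`).
#' @return The matrix exponential `P(t) = exp(Qt)`; rows sum to 1, tiny
#'   negative entries from finite arithmetic are clipped to 0.
#' @export
transition_matrix <- function(Q, t, params = NULL) {
  if (t < 0) cs_stop("branch length must be >= 0")
  if (inherits(Q, "codon_model_params")) {
    params <- Q
  } else if (is.null(params)) {
    cs_stop("supply `params` alongside a rate_matrix")
  }
  dec <- codon_decomp(params)
  decomp_pmat(dec, t)
}

decomp_pmat <- function(dec, t) {
  M <- dec$V %*% (exp(dec$lambda * t) * t(dec$V))
  P <- M * outer(1 / dec$sqp, dec$sqp)
  P[P < 0] <- 0
  P
}
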