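# Simulation of codon alignments under branch and branch-site selection
# regimes, and of continuous traits with lambda-structured phylogenetic
# noise.  All randomness flows from the seed argument; there is no hidden
# state.

# Per-edge omega assignment for a regime specification.  Regime types:
#   list(type = "M0", omega)
#   list(type = "branch", omega_background, omega_foreground)  (tree marks)
#   list(type = "branch_site", p0, p1, omega0, omega2)          (tree marks)
#   list(type = "custom", omega_by_child = named vector, child node id ->
#        omega; names are node ids as integers)
regime_edge_omega <- function(tree, regime) {
  fg <- foreground_edges(tree)
  n_edge <- nrow(tree$edge)
  switch(regime$type,
    M0 = rep(regime$omega, n_edge),
    branch = ifelse(fg, regime$omega_foreground, regime$omega_background),
    custom = {
      w <- regime$omega_by_child[as.character(tree$edge[, 2])]
      if (anyNA(w)) cs_stop("omega_by_child must cover every branch")
      unname(w)
    },
    cs_stop(paste0("unknown regime type: ", regime$type)))
}

#' Simulate a codon alignment along a tree
#'
#' Draws the root codon of each site from the equilibrium frequencies and
#' propagates states down every branch with the transition matrix for that
#' branch's (omega, t).  Under the branch-site regime each site is
#' assigned a model-A class at the root; classes 2a/2b switch to omega2 on
#' foreground branches only, and keep their background behaviour (omega0,
#' or neutral) elsewhere.
#'
#' @param tree A `phylo` with branch lengths (expected substitutions per
#'   codon) and, for branch/branch-site regimes, foreground marks.
#' @param n_codons Number of codon sites.
#' @param kappa Transition/transversion ratio.
#' @param pi Codon equilibrium frequencies, or `"equal"`.
#' @param regime Regime specification; see Details.
#' @param seed Integer seed (mandatory for reproducibility).
#' @param genetic_code_id NCBI translation-table number.
#' @details Regimes: `list(type = "M0", omega = )` one ratio everywhere;
#'   `list(type = "branch", omega_background = , omega_foreground = )`
#'   two-ratio on the marked foreground; `list(type = "branch_site",
#'   p0 = , p1 = , omega0 = , omega2 = )` model-A site classes;
#'   `list(type = "custom", omega_by_child = )` arbitrary per-branch
#'   omegas keyed by child node id.
#' @return A `codon_alignment` with attribute `"truth"`: list with
#'   `site_class` (per-site model-A class, branch-site regime only),
#'   `edge_omega` (per-branch background-class omega), `kappa`, `pi`,
#'   and the tree.
#' @export
simulate_codon_alignment <- function(tree, n_codons, kappa = 2,
                                     pi = "equal", regime, seed,
                                     genetic_code_id = 1L) {
  set.seed(seed)
  code <- genetic_code(genetic_code_id)
  nc <- length(code$codons)
  if (identical(pi, "equal")) pi <- rep(1 / nc, nc)
  tr <- stats::reorder(tree, "cladewise")  # parents before children
  n_tip <- length(tr$tip.label)
  n_node <- max(tr$edge)
  fg <- foreground_edges(tr)

  if (identical(regime$type, "branch_site")) {
    props <- c(regime$p0, regime$p1,
               (1 - regime$p0 - regime$p1) * regime$p0 /
                 (regime$p0 + regime$p1),
               (1 - regime$p0 - regime$p1) * regime$p1 /
                 (regime$p0 + regime$p1))
    site_class <- sample(c("0", "1", "2a", "2b"), n_codons, TRUE, props)
    omega_of <- function(edge_row, cls) {
      on_fg <- fg[edge_row]
      switch(cls,
             "0" = regime$omega0,
             "1" = 1,
             "2a" = if (on_fg) regime$omega2 else regime$omega0,
             "2b" = if (on_fg) regime$omega2 else 1)
    }
    edge_omega_bg <- ifelse(fg, regime$omega2, regime$omega0)
  } else {
    site_class <- NULL
    eo <- regime_edge_omega(tr, regime)
    omega_of <- function(edge_row, cls) eo[edge_row]
    edge_omega_bg <- eo
  }

  states <- matrix(NA_integer_, n_node, n_codons)
  states[n_tip + 1L, ] <- sample.int(nc, n_codons, TRUE, prob = pi)
  classes <- if (is.null(site_class)) "all" else c("0", "1", "2a", "2b")
  dec_cache <- new.env(parent = emptyenv())
  get_P <- function(w, t) {
    k <- sprintf("%.15g", w)
    d <- dec_cache[[k]]
    if (is.null(d)) {
      d <- codon_decomp(codon_model_params(kappa, w, pi, genetic_code_id))
      dec_cache[[k]] <- d
    }
    decomp_pmat(d, t)
  }
  for (e in seq_len(nrow(tr$edge))) {
    par_node <- tr$edge[e, 1]; child <- tr$edge[e, 2]
    t <- tr$edge.length[e]
    for (cls in classes) {
      sites <- if (identical(cls, "all")) seq_len(n_codons)
               else which(site_class == cls)
      if (!length(sites)) next
      P <- get_P(omega_of(e, cls), t)
      ps <- states[par_node, sites]
      out <- integer(length(sites))
      for (s in unique(ps)) {
        idx <- ps == s
        out[idx] <- sample.int(nc, sum(idx), TRUE, prob = P[s, ])
      }
      states[child, sites] <- out
    }
  }
  seqs <- apply(states[seq_len(n_tip), , drop = FALSE], 1, function(row) {
    paste(code$codons[row], collapse = "")
  })
  aln <- codon_alignment(seqs, tr$tip.label, genetic_code_id)
  attr(aln, "truth") <- list(site_class = site_class,
                             edge_omega = edge_omega_bg, kappa = kappa,
                             pi = pi, tree = tr)
  aln
}

#' Simulate continuous traits with phylogenetic noise
#'
#' `y = X beta + eps` with `eps ~ MVN(0, sigma^2 * C_lambda)`, where `C`
#' is the tree's Brownian covariance rescaled to unit mean diagonal (so
#' `sigma` is in trait units) and `C_lambda` its Pagel transformation.
#'
#' @param tree A `phylo` with branch lengths.
#' @param X Predictor matrix (rows = species, in `tree$tip.label` order)
#'   or `NULL` for an intercept-only (pure noise around `beta[1]`) model.
#' @param beta Coefficient vector (including intercept as first entry when
#'   `X` has an intercept column, or the mean when `X` is `NULL`).
#' @param lambda True Pagel's lambda in `[0, 1]`.
#' @param sigma Noise standard deviation.
#' @param seed Integer seed.
#' @return Named numeric vector of trait values (tip order).
#' @export
simulate_traits <- function(tree, X = NULL, beta, lambda, sigma, seed) {
  set.seed(seed)
  n <- length(tree$tip.label)
  C <- phylo_covariance(tree)[tree$tip.label, tree$tip.label]
  C <- C / mean(diag(C))
  Cl <- apply_lambda(C, lambda)
  mu <- if (is.null(X)) rep(beta[1], n) else as.numeric(X %*% beta)
  y <- mu + MASS::mvrnorm(1, rep(0, n), sigma^2 * Cl)
  stats::setNames(y, tree$tip.label)
}

# Brownian motion values at the tips (unit-depth-scaled covariance),
# around a root mean.
simulate_brownian <- function(tree, mean, sigma, seed) {
  simulate_traits(tree, NULL, mean, 1, sigma, seed)
}
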