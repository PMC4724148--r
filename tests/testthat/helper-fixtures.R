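# Shared fixtures and the exhaustive-enumeration likelihood oracle.

# Vectorized brute-force log-likelihood: sums the joint probability over
# every assignment of internal-node states.  Independent of the pruning
# engine (uses only transition_matrix and base R indexing).
brute_loglik <- function(aln, tree, kappa, pi, omega) {
  tr <- stats::reorder(tree, "postorder")
  params <- codon_model_params(kappa, omega, pi)
  Plist <- lapply(seq_len(nrow(tr$edge)), function(e)
    transition_matrix(params, tr$edge.length[e]))
  ntip <- length(tr$tip.label)
  nnode <- max(tr$edge)
  states <- aln$states[match(tr$tip.label, aln$taxa), , drop = FALSE]
  internals <- (ntip + 1):nnode
  grid <- as.matrix(expand.grid(rep(list(1:61), length(internals))))
  rootcol <- match(ntip + 1, internals)
  vapply(seq_len(ncol(states)), function(site) {
    pr <- pi[grid[, rootcol]]
    for (e in seq_len(nrow(tr$edge))) {
      pnode <- tr$edge[e, 1]; cnode <- tr$edge[e, 2]
      a <- grid[, match(pnode, internals)]
      if (cnode <= ntip) {
        b <- states[cnode, site]
        if (is.na(b)) next  # missing data contributes a factor of 1
        pr <- pr * Plist[[e]][cbind(a, b)]
      } else {
        pr <- pr * Plist[[e]][cbind(a, grid[, match(cnode, internals)])]
      }
    }
    log(sum(pr))
  }, numeric(1))
}

# Two-clade tree with marked cladeA, plus a cached alignment simulated
# under a two-ratio branch regime; several tests share it to avoid
# refitting from scratch.
.fixture_env <- new.env(parent = emptyenv())

fixture_tree <- function(n_per_clade = 4, depth = 0.3, stem = 0.15,
                         seed = 2) {
  tr <- codonsel:::toy_two_clade_tree(n_per_clade, seed = seed,
                                      depth = depth, stem = stem)
  mark_clade(tr, grep("^cladeA", tr$tip.label, value = TRUE))
}

fixture_branch_data <- function() {
  if (is.null(.fixture_env$branch)) {
    trm <- fixture_tree()
    aln <- simulate_codon_alignment(
      trm, 150, kappa = 2, pi = "equal",
      regime = list(type = "branch", omega_background = 0.4,
                    omega_foreground = 3), seed = 42)
    m0 <- fit_m0(aln, trm)
    .fixture_env$branch <- list(tree = trm, aln = aln, m0 = m0)
  }
  .fixture_env$branch
}

fixture_bs_fit <- function() {
  if (is.null(.fixture_env$bs)) {
    trm <- fixture_tree()
    aln <- simulate_codon_alignment(
      trm, 120, kappa = 2, pi = "equal",
      regime = list(type = "branch_site", p0 = 0.5, p1 = 0.3,
                    omega0 = 0.2, omega2 = 5), seed = 77)
    m0 <- fit_m0(aln, trm)
    bsfix <- fit_branch_site(aln, trm, TRUE, m0, n_starts = 2)
    bs <- fit_branch_site(aln, trm, FALSE, m0, null_fit = bsfix,
                          n_starts = 2)
    .fixture_env$bs <- list(tree = trm, aln = aln, m0 = m0,
                            bsfixed = bsfix, bs = bs)
  }
  .fixture_env$bs
}

random_pi <- function(seed) {
  set.seed(seed)
  p <- stats::rgamma(61, 2, 1) + 1e-3
  p / sum(p)
}

make_lrt <- function(two_delta, df = 1) {
  lrt(0, two_delta / 2, df = df)
}
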