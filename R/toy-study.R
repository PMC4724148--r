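# The bundled two-clade toy study: a 16-taxon precursor alignment whose
# cleaved domain evolves under purifying selection in both clades and
# whose mature domain is positively selected in clade A and effectively
# neutral (relaxed) in clade B; phenotypes carry a planted association
# between the cleaved-domain root-to-tip omega and relative sperm head
# width.  It is the package's end-to-end test and documentation dataset.

toy_two_clade_tree <- function(n_per_clade, seed, depth = 0.35,
                               stem = 0.15) {
  set.seed(seed)
  scale_depth <- function(tr, d) {
    tr$edge.length <- tr$edge.length * d / max(ape::node.depth.edgelength(tr))
    tr
  }
  tA <- scale_depth(ape::rcoal(n_per_clade,
                               sprintf("cladeA_sp%02d", seq_len(n_per_clade))),
                    depth)
  tB <- scale_depth(ape::rcoal(n_per_clade,
                               sprintf("cladeB_sp%02d", seq_len(n_per_clade))),
                    depth)
  nwk <- sprintf("(%s:%g,%s:%g);",
                 sub(";$", "", ape::write.tree(tA, digits = 10)), stem,
                 sub(";$", "", ape::write.tree(tB, digits = 10)), stem)
  ape::read.tree(text = nwk)
}

# Lognormal per-branch omega multipliers around clade-specific means.
toy_branch_omegas <- function(tree, clades, mean_bg, mean_by_clade, sdlog,
                              seed) {
  set.seed(seed)
  n_edge <- nrow(tree$edge)
  mu <- rep(mean_bg, n_edge)
  for (cl in names(mean_by_clade)) {
    nodes <- descendant_nodes(tree, ape::getMRCA(tree, clades[[cl]]))
    mu[tree$edge[, 2] %in% nodes] <- mean_by_clade[[cl]]
  }
  w <- mu * exp(stats::rnorm(n_edge, 0, sdlog))
  stats::setNames(w, as.character(tree$edge[, 2]))
}

# True root-to-tip omega per species from known per-branch omegas.
true_root_to_tip <- function(tree, omega_by_child, kappa, pi, clades) {
  out <- numeric(0)
  for (cl in names(clades)) {
    tips <- clades[[cl]]
    root <- ape::getMRCA(tree, tips)
    for (tp in tips) {
      children <- c(path_nodes(tree, match(tp, tree$tip.label), root), root)
      dn <- 0; ds <- 0
      for (ch in children) {
        e <- which(tree$edge[, 2] == ch)
        dd <- branch_dn_ds(tree$edge.length[e],
                           codon_model_params(kappa,
                                              omega_by_child[[as.character(ch)]],
                                              pi))
        dn <- dn + dd["dN"]; ds <- ds + dd["dS"]
      }
      out[tp] <- dn / ds
    }
  }
  out
}

#' Generate the bundled toy study
#'
#' Builds a deterministic two-clade dataset: precursor codon alignment
#' (cleaved + mature domains), rooted tree, phenotype table, domain
#' annotation and clade definitions.  The cleaved domain evolves under
#' purifying selection in both clades (branch omegas lognormal around
#' 0.3, sdlog 1.2 — strong among-branch heterogeneity, the protamine
#' pattern); the mature domain around omega 4 in clade A (positive
#' selection), around 1 in clade B (relaxed), and around 0.5 on the
#' stem/background branches.
#' Relative sperm head width is constructed as
#' `0.04 + 0.3 * omega_rtt(cleaved) + eps` with lambda = 0.9 phylogenetic
#' noise, so head width (and through it elongation) carries a real
#' association with the cleaved-domain evolutionary rate, while body and
#' testes mass are pure Brownian controls with no association.
#'
#' @param seed Integer master seed; the same seed reproduces the bundle
#'   byte for byte.
#' @param dir Optional directory: when given, writes `alignment.fasta`,
#'   `tree.nwk`, `phenotypes.tsv`, `domains.tsv` and `config.yml` there.
#' @param n_per_clade Tips per clade (default 8).
#' @param n_cleaved,n_mature Codon sites per domain (default 150 each).
#' @return List with `alignment`, `tree`, `phenotypes`, `boundary`,
#'   `clades`, `truth` (true branch omegas, true root-to-tip omegas,
#'   planted trait coefficients), and `paths` when `dir` is given.
#' @export
make_toy_study <- function(seed = 1, dir = NULL, n_per_clade = 8,
                           n_cleaved = 150, n_mature = 150) {
  tree <- toy_two_clade_tree(n_per_clade, seed)
  clades <- list(cladeA = grep("^cladeA", tree$tip.label, value = TRUE),
                 cladeB = grep("^cladeB", tree$tip.label, value = TRUE))
  kappa <- 2.5
  set.seed(seed + 1)
  pi <- as.numeric(stats::rgamma(61, 5, 1))
  pi <- pi / sum(pi)

  w_cleaved <- toy_branch_omegas(tree, clades, 0.3,
                                 list(cladeA = 0.3, cladeB = 0.3),
                                 sdlog = 1.2, seed = seed + 2)
  w_mature <- toy_branch_omegas(tree, clades, 0.5,
                                list(cladeA = 4, cladeB = 1),
                                sdlog = 0.25, seed = seed + 3)

  aln_cle <- simulate_codon_alignment(tree, n_cleaved, kappa, pi,
                                      list(type = "custom",
                                           omega_by_child = w_cleaved),
                                      seed = seed + 4)
  aln_mat <- simulate_codon_alignment(tree, n_mature, kappa, pi,
                                      list(type = "custom",
                                           omega_by_child = w_mature),
                                      seed = seed + 5)

  # clade-biased terminal truncations give the domains length variation
  # (cleaved longer in clade A, mature longer in clade B)
  set.seed(seed + 6)
  gap_tail <- function(codons, n_gap) {
    L <- length(codons)
    if (n_gap > 0) codons[(L - n_gap + 1):L] <- "---"
    codons
  }
  cle <- aln_cle$codons; mat <- aln_mat$codons
  for (i in seq_along(tree$tip.label)) {
    sp <- tree$tip.label[i]
    in_a <- sp %in% clades$cladeA
    cle[sp, ] <- gap_tail(cle[sp, ],
                          min(stats::rpois(1, if (in_a) 1 else 8), 20))
    mat[sp, ] <- gap_tail(mat[sp, ],
                          min(stats::rpois(1, if (in_a) 8 else 1), 20))
  }
  precursor <- codon_alignment(
    apply(cbind(cle, mat), 1, paste, collapse = ""),
    tree$tip.label, 1L)
  boundary <- n_cleaved + 1L

  omega_rtt_true <- true_root_to_tip(tree, as.list(w_cleaved), kappa, pi,
                                     clades)
  omega_rtt_true <- omega_rtt_true[tree$tip.label]

  beta_hw <- 0.3
  rel_hw <- simulate_traits(tree, cbind(1, omega_rtt_true),
                            c(0.04, beta_hw), lambda = 0.9, sigma = 0.006,
                            seed = seed + 7)
  rel_hl <- simulate_traits(tree, NULL, 0.10, lambda = 1, sigma = 0.01,
                            seed = seed + 8)
  total_len <- 120 * exp(simulate_traits(tree, NULL, 0, 1, 0.08,
                                         seed = seed + 9))
  log_body <- simulate_traits(tree, NULL, 2, 1, 0.5, seed = seed + 10)
  log_testes <- 0.9 * log_body - 1.6 +
    simulate_traits(tree, NULL, 0, 1, 0.25, seed = seed + 11)

  ph <- data.frame(species = tree$tip.label,
                   body_mass = 10^log_body,
                   testes_mass = 10^log_testes,
                   head_length = rel_hl * total_len,
                   head_width = rel_hw * total_len,
                   total_sperm_length = total_len,
                   stringsAsFactors = FALSE)
  set.seed(seed + 12)
  ph$head_width[match(c(sample(clades$cladeA, 1), sample(clades$cladeB, 1)),
                      ph$species)] <- NA

  bundle <- list(alignment = precursor, tree = tree, phenotypes = ph,
                 boundary = boundary, clades = clades,
                 truth = list(kappa = kappa, pi = pi,
                              omega_cleaved = w_cleaved,
                              omega_mature = w_mature,
                              omega_rtt_cleaved = omega_rtt_true,
                              beta_hw = beta_hw, lambda_hw = 0.9,
                              sigma_hw = 0.006))
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(alignment = file.path(dir, "alignment.fasta"),
                  tree = file.path(dir, "tree.nwk"),
                  phenotypes = file.path(dir, "phenotypes.tsv"),
                  domains = file.path(dir, "domains.tsv"),
                  config = file.path(dir, "config.yml"))
    write_codon_alignment(precursor, paths$alignment)
    write_tree(tree, paths$tree)
    utils::write.table(ph, paths$phenotypes, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(data.frame(species = tree$tip.label,
                                  boundary = boundary),
                       paths$domains, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    cfg <- list(alignment = paths$alignment, tree = paths$tree,
                phenotypes = paths$phenotypes,
                domain_annotation = paths$domains,
                clades = lapply(clades, as.list),
                alpha = 0.05, freq_scheme = "F3x4", seed = seed,
                outdir = file.path(dir, "results"))
    yaml::write_yaml(cfg, paths$config)
    bundle$paths <- paths
  }
  bundle
}
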