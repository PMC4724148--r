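test_that("codon frequency schemes behave as defined", {
  aln <- codon_alignment(c("AAAAAA", "AAAAAA"), c("a", "b"))
  expect_equal(estimate_codon_frequencies(aln, "equal"), rep(1 / 61, 61))

  # F61 on a single-codon alignment concentrates on that codon
  pi61 <- estimate_codon_frequencies(aln, "F61", floor = 0)
  code <- genetic_code()
  expect_equal(pi61[match("AAA", code$codons)], 1)
  expect_no_warning(pifl <- estimate_codon_frequencies(aln, "F61"))
  expect_equal(sum(pifl), 1, tolerance = 1e-12)

  # F3x4 with uniform nucleotide counts at every position -> uniform over
  # sense codons after stop renormalization (hand derivation: every codon
  # has probability (1/4)^3 before renormalizing over the 61 sense codons)
  aln_u <- codon_alignment(c("TTTCCCAAAGGG", "CCCAAAGGGTTT",
                             "AAAGGGTTTCCC", "GGGTTTCCCAAA"),
                           c("s1", "s2", "s3", "s4"))
  expect_equal(estimate_codon_frequencies(aln_u, "F3x4"), rep(1 / 61, 61),
               tolerance = 1e-9)
  # F1x4 agrees in the uniform case
  expect_equal(estimate_codon_frequencies(aln_u, "F1x4"), rep(1 / 61, 61),
               tolerance = 1e-9)
})

test_that("rate matrix structure: single-nucleotide moves, reversibility,
          normalization", {
  pi <- random_pi(11)
  params <- codon_model_params(kappa = 3.2, omega = 0.7, pi = pi)
  Q <- build_rate_matrix(params)$Q
  expect_equal(max(abs(rowSums(Q))), 0, tolerance = 1e-8)
  expect_equal(-sum(pi * diag(Q)), 1, tolerance = 1e-8)

  # zero rate for codon pairs differing at more than one position
  code <- genetic_code()
  mat <- do.call(rbind, strsplit(code$codons, ""))
  ndiff <- outer(seq_len(61), seq_len(61), Vectorize(function(i, j)
    sum(mat[i, ] != mat[j, ])))
  expect_true(all(Q[ndiff > 1] == 0))

  # detailed balance pi_i q_ij = pi_j q_ji over all entries
  flux <- pi * Q
  expect_equal(flux, t(flux), tolerance = 1e-12, ignore_attr = TRUE)

  # omega = 0 kills every nonsynonymous rate
  Q0 <- build_rate_matrix(codon_model_params(2, 0, pi))$Q
  aa <- code$aa
  nonsyn <- outer(aa, aa, "!=") & ndiff == 1
  expect_true(all(Q0[nonsyn] == 0))
  expect_true(any(Q0[!nonsyn & ndiff == 1] > 0))

  # neutral symmetric case: all single-change rates equal
  Q1 <- build_rate_matrix(codon_model_params(1, 1, rep(1 / 61, 61)))$Q
  offd <- Q1[ndiff == 1]
  expect_equal(max(offd), min(offd))
})

test_that("site opportunities match independent enumeration", {
  pi <- rep(1 / 61, 61)
  NS <- site_opportunity(codon_model_params(1, 1, pi))
  expect_equal(unname(NS["N"] + NS["S"]), 3, tolerance = 1e-12)

  # oracle: enumerate all ordered single-nucleotide codon pair moves with
  # seqinr translation, equal weights (equal pi, kappa = 1)
  code <- genetic_code()
  mat <- do.call(rbind, strsplit(code$codons, ""))
  syn <- 0; tot <- 0; syn_ti <- 0; tot_ti <- 0
  ti <- c(A = "G", G = "A", C = "T", T = "C")
  for (i in 1:61) for (pos in 1:3) for (nt in c("A", "C", "G", "T")) {
    if (nt == mat[i, pos]) next
    cod <- mat[i, ]; cod[pos] <- nt
    j <- match(paste(cod, collapse = ""), code$codons)
    if (is.na(j)) next  # stop codon
    is_syn <- code$aa[i] == code$aa[j]
    tot <- tot + 1; syn <- syn + is_syn
    if (ti[[mat[i, pos]]] == nt) { tot_ti <- tot_ti + 1
                                   syn_ti <- syn_ti + is_syn }
  }
  expect_equal(unname(NS["S"] / 3), syn / tot, tolerance = 1e-12)

  # kappa -> infinity: synonymous fraction approaches the transition-only
  # fraction
  NSk <- site_opportunity(codon_model_params(1e9, 1, pi))
  expect_equal(unname(NSk["S"] / 3), syn_ti / tot_ti, tolerance = 1e-6)

  # N + S = 3 for arbitrary parameters
  NS2 <- site_opportunity(codon_model_params(4.2, 2.5, random_pi(3)))
  expect_equal(unname(NS2["N"] + NS2["S"]), 3, tolerance = 1e-12)
})

test_that("transition matrices: identity at 0, stochastic rows,
          Chapman-Kolmogorov, equilibrium limit", {
  pi <- random_pi(7)
  params <- codon_model_params(2.5, 0.6, pi)
  P0 <- transition_matrix(params, 0)
  expect_equal(P0, diag(61), tolerance = 1e-10, ignore_attr = TRUE)

  Pa <- transition_matrix(params, 0.07)
  Pb <- transition_matrix(params, 0.19)
  expect_true(all(Pa >= 0))
  expect_equal(rowSums(Pa), rep(1, 61), tolerance = 1e-8)
  expect_equal(Pa %*% Pb, transition_matrix(params, 0.26),
               tolerance = 1e-8, ignore_attr = TRUE)

  # equilibrium limit; t large enough that even the slowest mode has died
  Pinf <- transition_matrix(params, 300)
  expect_equal(Pinf, matrix(pi, 61, 61, byrow = TRUE), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_error(transition_matrix(params, -1), ">= 0")
})

test_that("omega scales nonsynonymous flux monotonically, synonymous flux
          pattern fixed", {
  pi <- random_pi(13)
  rho <- vapply(c(0.1, 0.5, 1, 2, 5), function(w)
    codonsel:::nonsyn_flux_fraction(codon_model_params(2, w, pi)),
    numeric(1))
  expect_true(all(diff(rho) > 0))
  # dN increases with omega at fixed t while dN*N + dS*S stays t
  t <- 0.3
  dd <- vapply(c(0.2, 1, 4), function(w)
    branch_dn_ds(t, codon_model_params(2, w, pi)), numeric(2))
  expect_true(all(diff(dd["dN", ]) > 0))
  NS <- site_opportunity(codon_model_params(2, 1, pi))
  expect_equal(as.numeric(dd["dN", ] * NS["N"] + dd["dS", ] * NS["S"]),
               rep(t, 3), tolerance = 1e-10)
})
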