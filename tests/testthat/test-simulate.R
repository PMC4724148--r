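test_that("zero-length trees copy the root draw to every tip", {
  tr <- read_tree("((A:0,B:0):0,C:0);")
  aln <- simulate_codon_alignment(tr, 25, 2, "equal",
                                  list(type = "M0", omega = 0.5), seed = 1)
  expect_true(all(aln$states["A", ] == aln$states["B", ]))
  expect_true(all(aln$states["A", ] == aln$states["C", ]))
})

test_that("omega 0 forbids nonsynonymous change anywhere", {
  trm <- fixture_tree()
  aln <- simulate_codon_alignment(trm, 150, 2, "equal",
                                  list(type = "M0", omega = 0), seed = 2)
  code <- genetic_code()
  aa <- matrix(code$aa[aln$states], nrow = length(aln$taxa))
  expect_true(all(apply(aa, 2, function(col) length(unique(col)) == 1L)))
})

test_that("the same seed reproduces the alignment and the toy bundle", {
  trm <- fixture_tree()
  a1 <- simulate_codon_alignment(trm, 40, 2, "equal",
                                 list(type = "M0", omega = 0.5), seed = 9)
  a2 <- simulate_codon_alignment(trm, 40, 2, "equal",
                                 list(type = "M0", omega = 0.5), seed = 9)
  expect_identical(a1$codons, a2$codons)

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  b1 <- make_toy_study(seed = 3, dir = d1, n_per_clade = 3,
                       n_cleaved = 20, n_mature = 20)
  b2 <- make_toy_study(seed = 3, dir = d2, n_per_clade = 3,
                       n_cleaved = 20, n_mature = 20)
  expect_identical(readLines(b1$paths$alignment),
                   readLines(b2$paths$alignment))
  expect_identical(readLines(b1$paths$tree), readLines(b2$paths$tree))
  expect_identical(b1$phenotypes, b2$phenotypes)
  # a different seed changes the draw
  b3 <- make_toy_study(seed = 4, n_per_clade = 3, n_cleaved = 20,
                       n_mature = 20)
  expect_false(identical(b1$alignment$codons, b3$alignment$codons))
})

test_that("long-branch frequencies converge to the equilibrium pi", {
  tr <- read_tree("(A:50,B:50);")
  pi <- random_pi(66)
  aln <- simulate_codon_alignment(tr, 8000, 2, pi,
                                  list(type = "M0", omega = 0.8), seed = 5)
  counts <- tabulate(aln$states["A", ], nbins = 61)
  gof <- suppressWarnings(stats::chisq.test(counts, p = pi))
  expect_gt(gof$p.value, 1e-4)  # no gross deviation from pi
})

test_that("branch-site truth sidecar matches model-A semantics", {
  trm <- fixture_tree()
  aln <- simulate_codon_alignment(
    trm, 400, 2, "equal",
    list(type = "branch_site", p0 = 0.45, p1 = 0.35, omega0 = 0.1,
         omega2 = 8), seed = 12)
  truth <- attr(aln, "truth")
  expect_equal(length(truth$site_class), 400L)
  tab <- table(truth$site_class) / 400
  # expected class proportions: p2a = 0.2*0.45/0.8, p2b = 0.2*0.35/0.8
  expect_equal(as.numeric(tab[c("0", "1", "2a", "2b")]),
               c(0.45, 0.35, 0.1125, 0.0875), tolerance = 0.12)
  # class-0 sites never change amino acid faster than neutral sites on
  # average: coarse sanity via per-site amino-acid diversity
  code <- genetic_code()
  aa <- matrix(code$aa[aln$states], nrow = length(aln$taxa))
  div <- apply(aa, 2, function(col) length(unique(col)))
  expect_lt(mean(div[truth$site_class == "0"]),
            mean(div[truth$site_class == "2b"]))
})

test_that("trait simulation honours sigma and lambda", {
  tr <- codonsel:::toy_two_clade_tree(5, seed = 3)
  X <- cbind(1, seq_len(10))
  y0 <- simulate_traits(tr, X, c(2, 0.1), lambda = 0.5, sigma = 0,
                        seed = 1)
  expect_equal(unname(y0), as.numeric(X %*% c(2, 0.1)), tolerance = 1e-12)

  # lambda = 0: residuals uncorrelated across species (replicate check)
  sib <- codonsel:::clade_tips(tr, ape::getMRCA(tr, c("cladeA_sp01",
                                                      "cladeA_sp02")))[1:2]
  reps <- vapply(1:200, function(r)
    simulate_traits(tr, NULL, 0, lambda = 0, sigma = 1,
                    seed = 1000 + r)[sib],
    numeric(2))
  expect_lt(abs(stats::cor(reps[1, ], reps[2, ])), 0.2)
  # lambda = 1: sister species strongly correlated
  reps1 <- vapply(1:200, function(r)
    simulate_traits(tr, NULL, 0, lambda = 1, sigma = 1,
                    seed = 3000 + r)[sib],
    numeric(2))
  expect_gt(stats::cor(reps1[1, ], reps1[2, ]),
            abs(stats::cor(reps[1, ], reps[2, ])))
})
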