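test_that("likelihood ratio tests compute the chi-square tail correctly", {
  expect_equal(lrt(-100, -100)$two_delta, 0)
  expect_equal(lrt(-100, -100)$p, 1)
  # classic critical value: 2*delta = 3.84 at df 1 sits at p ~ 0.050
  r <- make_lrt(3.84)
  expect_equal(r$p, 0.05, tolerance = 1e-3)
  # the primate mature-domain branch statistic is far beyond the 1% point
  expect_lt(make_lrt(25.86)$p, 0.01)
  expect_warning(w <- lrt(-100, -100.5), "under-optimized")
  expect_equal(w$two_delta, 0)
  # boundary mixture halves the tail
  expect_equal(lrt(-100, -98, mixture = TRUE)$p,
               0.5 * stats::pchisq(4, 1, lower.tail = FALSE))
})

test_that("regime decision table is exhaustive and pure", {
  sig <- make_lrt(10)   # p ~ 0.0016
  ns <- make_lrt(0.5)   # p ~ 0.48
  cases <- list(
    list(sig, sig, 2.0, 0.9, "positive"),
    list(sig, sig, 0.5, 0.9, "conserved"),
    list(sig, ns, 2.0, 0.9, "relaxed"),
    list(sig, ns, 0.5, 0.9, "relaxed"),
    list(ns, sig, 2.0, 0.5, "conserved"),  # effective omega is M0's 0.5
    list(ns, sig, 0.5, 1.6, "positive"),   # effective omega is M0's 1.6
    list(ns, ns, 2.0, 0.9, "relaxed"),
    list(ns, ns, 0.5, 0.9, "relaxed"))
  for (cs in cases) {
    call1 <- classify_regime(cs[[1]], cs[[2]], cs[[3]], cs[[4]])
    call2 <- classify_regime(cs[[1]], cs[[2]], cs[[3]], cs[[4]])
    expect_identical(call1$label, cs[[5]])
    expect_identical(call1, call2)  # pure function
  }
  # effective omega source follows the reporting rule
  expect_equal(classify_regime(sig, sig, 3.1, 0.5)$effective_omega, 3.1)
  expect_equal(classify_regime(ns, sig, 3.1, 0.5)$effective_omega, 0.5)

  expect_identical(classify_site_regime(make_lrt(26.1)), "positive")
  expect_identical(classify_site_regime(make_lrt(0.8)), "no_signal")
})

test_that("regime calls reproduce the published branch-analysis labels", {
  # cleaved domain, primate foreground: (ns, sig, omega < 1) -> conserved
  c1 <- classify_regime(make_lrt(0.02), make_lrt(8.74), 0.530, 0.54)
  # cleaved domain, rodent foreground
  c2 <- classify_regime(make_lrt(1.94), make_lrt(15.42), 0.420, 0.54)
  # mature domain, primate foreground: (sig, sig, omega > 1) -> positive
  c3 <- classify_regime(make_lrt(25.86), make_lrt(25.60), 3.120, 1.18)
  # mature domain, rodent foreground: (ns, ns) -> relaxed, M0 omega reported
  c4 <- classify_regime(make_lrt(1.49), make_lrt(0.01), 0.980, 1.18)
  expect_identical(vapply(list(c1, c2, c3, c4), `[[`, "", "label"),
                   c("conserved", "conserved", "positive", "relaxed"))
  expect_equal(c4$effective_omega, 1.18)
})

test_that("branch dN/dS decomposition: neutrality, additivity, identity", {
  pi <- random_pi(21)
  p1 <- codon_model_params(2.7, 1, pi)
  dd <- branch_dn_ds(0.4, p1)
  expect_equal(dd[["dN"]], dd[["dS"]], tolerance = 1e-12)
  expect_equal(branch_dn_ds(0, p1), c(dN = 0, dS = 0))
  for (w in c(0.1, 0.9, 3)) {
    pp <- codon_model_params(1.8, w, pi)
    NS <- site_opportunity(pp)
    dd <- branch_dn_ds(0.73, pp)
    expect_equal(dd[["dN"]] * NS[["N"]] + dd[["dS"]] * NS[["S"]], 0.73,
                 tolerance = 1e-10)
  }
})

test_that("root-to-tip omega is path arithmetic over the free-ratio table", {
  tr <- read_tree("(((A:1,B:1):1,C:1):1,D:1);")
  pb <- data.frame(parent = tr$edge[, 1], child = tr$edge[, 2],
                   t = tr$edge.length, omega = 1,
                   dN = 0, dS = 1, foreground = FALSE,
                   omega_undefined = FALSE,
                   label = "")
  # path for tip A from the MRCA of {A,B,C}: branches A, (A,B), stem(A,B,C)
  nodes <- c(match("A", tr$tip.label),
             ape::getMRCA(tr, c("A", "B")), ape::getMRCA(tr, c("A", "B", "C")))
  pb$dN[match(nodes, pb$child)] <- c(0.1, 0.2, 0.1)
  pb$dS[match(nodes, pb$child)] <- c(0.2, 0.2, 0.4)
  fit <- structure(list(tree = tr, per_branch = pb), class = "codonsel_fit")
  w <- root_to_tip_omega(fit, "A", c("A", "B", "C"))
  expect_equal(as.numeric(w), 0.4 / 0.8)
  expect_equal(attr(w, "dn_sum"), 0.4)

  # single-branch path is that branch's ratio
  w1 <- root_to_tip_omega(fit, "A", "A")
  expect_equal(as.numeric(w1), 0.1 / 0.2)

  # zero synonymous path sum is flagged undefined
  pb0 <- pb; pb0$dS[] <- 0
  fit0 <- structure(list(tree = tr, per_branch = pb0),
                    class = "codonsel_fit")
  w0 <- root_to_tip_omega(fit0, "A", c("A", "B", "C"))
  expect_true(is.na(w0))
  expect_match(attr(w0, "reason"), "zero synonymous")

  expect_error(root_to_tip_omega(fit, "D", c("A", "B", "C")),
               "not a descendant")
})

test_that("root-to-tip omega is invariant to subdividing a branch", {
  mk <- function(tr, dn_rate, ds_rate) {
    pb <- data.frame(parent = tr$edge[, 1], child = tr$edge[, 2],
                     t = tr$edge.length, omega = 1,
                     dN = dn_rate * tr$edge.length,
                     dS = ds_rate * tr$edge.length,
                     foreground = FALSE, omega_undefined = FALSE, label = "")
    structure(list(tree = tr, per_branch = pb), class = "codonsel_fit")
  }
  # A's lineage as one branch of length 2, versus split in two by an extra
  # node (with a zero-length sister Z); same per-unit dN and dS rates
  tr_a <- read_tree("((A:2,B:1):1,C:1);")
  tr_b <- read_tree("(((A:1,Z:0):1,B:1):1,C:1);")
  wa <- root_to_tip_omega(mk(tr_a, 0.07, 0.11), "A", c("A", "B"),
                          include_stem = FALSE)
  wb <- root_to_tip_omega(mk(tr_b, 0.07, 0.11), "A", c("A", "Z", "B"),
                          include_stem = FALSE)
  expect_equal(as.numeric(wa), as.numeric(wb), tolerance = 1e-12)
  expect_equal(attr(wa, "dn_sum"), attr(wb, "dn_sum"), tolerance = 1e-12)
})

test_that("site detection reports the published notation and rejects nulls", {
  fx <- fixture_bs_fit()
  expect_error(detect_pss(fx$bsfixed), "null")
  pss <- detect_pss(fx$bs, threshold = 0, method = "NEB")
  expect_true(all(pss$label == paste0(pss$site, pss$residue)))
  # residue column matches the reference taxon's translated sequence
  ref <- codonsel:::translate_row(fx$aln, fx$bs$tree$tip.label[1])
  expect_identical(pss$residue, ref[pss$site])
  post <- attr(pss, "posterior")
  expect_true(all(post >= 0 & post <= 1))
  # BEB runs and returns a bounded posterior as well
  pb <- detect_pss(fx$bs, threshold = 0.5, method = "BEB")
  expect_true(all(attr(pb, "posterior") >= 0 &
                    attr(pb, "posterior") <= 1))
  # truly positive sites score higher on average than class-0 sites
  truth <- attr(fx$aln, "truth")
  postb <- attr(pb, "posterior")
  expect_gt(mean(postb[truth$site_class %in% c("2a", "2b")]),
            mean(postb[truth$site_class == "0"]))
})
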