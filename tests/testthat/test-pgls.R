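test_that("phylogenetic covariance is shared path length", {
  tr <- read_tree("((A:1,B:1):1,C:2);")
  C <- phylo_covariance(tr)
  expect_equal(C["A", "B"], 1)
  expect_equal(C["A", "C"], 0)
  expect_equal(C["A", "A"], 2)
  # star tree with unit branches -> identity
  star <- read_tree("(A:1,B:1,C:1,D:1);")
  expect_equal(phylo_covariance(star), diag(4), ignore_attr = TRUE)
  # symmetric positive semi-definite on random trees
  set.seed(12)
  for (k in 1:5) {
    rt <- ape::rtree(8)
    Ck <- phylo_covariance(rt)
    expect_equal(Ck, t(Ck))
    expect_true(min(eigen(Ck, symmetric = TRUE)$values) > -1e-10)
  }
  subset <- phylo_covariance(tr, c("C", "A"))
  expect_equal(rownames(subset), c("C", "A"))
  expect_error(phylo_covariance(tr, c("A", "Z")), "Z")
})

test_that("lambda transformation scales only the off-diagonal", {
  tr <- read_tree("((A:1,B:1):1,C:2);")
  C <- phylo_covariance(tr)
  expect_equal(apply_lambda(C, 1), C)
  expect_equal(apply_lambda(C, 0), diag(diag(C)), ignore_attr = TRUE)
  Ch <- apply_lambda(C, 0.5)
  expect_equal(Ch["A", "B"], 0.5)
  expect_equal(diag(Ch), diag(C))
  expect_error(apply_lambda(C, 1.2), "\\[0, 1\\]")
})

test_that("PGLS at lambda 0 reproduces ordinary least squares exactly", {
  set.seed(31)
  tr <- ape::rcoal(15)
  d <- data.frame(species = tr$tip.label, x = rnorm(15))
  d$y <- 1 + 0.5 * d$x + rnorm(15, 0, 0.4)
  f0 <- pgls_fit(y ~ x, d, tr, lambda = 0)
  ols <- stats::lm(y ~ x, d)
  expect_equal(f0$coefficients$estimate, unname(coef(ols)),
               tolerance = 1e-10)
  expect_equal(f0$coefficients$t,
               unname(summary(ols)$coefficients[, "t value"]),
               tolerance = 1e-10)
  expect_equal(f0$r_squared, summary(ols)$r.squared, tolerance = 1e-10)
})

test_that("ML lambda and coefficients agree with nlme::gls + corPagel", {
  skip_if_not_installed("nlme")
  set.seed(33)
  tr <- ape::rcoal(25)
  x <- rnorm(25)
  y <- simulate_traits(tr, cbind(1, x), c(1, 0.4), lambda = 0.7,
                       sigma = 0.5, seed = 14)
  d <- data.frame(species = tr$tip.label, x = x, y = as.numeric(y))
  ours <- pgls_fit(y ~ x, d, tr, method = "REML")
  ref <- nlme::gls(y ~ x, data = d,
                   correlation = ape::corPagel(0.5, tr, form = ~species),
                   method = "REML")
  lam_ref <- stats::coef(ref$modelStruct$corStruct, unconstrained = FALSE)
  expect_equal(ours$lambda, unname(lam_ref), tolerance = 1e-4)
  expect_equal(ours$coefficients$estimate, unname(coef(ref)),
               tolerance = 1e-6)
})

test_that("lambda profile maximum dominates the endpoints; boundary LRTs", {
  set.seed(35)
  tr <- ape::rcoal(20)
  y <- simulate_traits(tr, NULL, 0, lambda = 1, sigma = 1, seed = 20)
  d <- data.frame(species = tr$tip.label, y = as.numeric(y),
                  x = rnorm(20))
  fit <- pgls_fit(y ~ x, d, tr)
  for (l in c(0, 0.3, 0.7, 1)) {
    expect_gte(fit$loglik + 1e-6,
               pgls_fit(y ~ x, d, tr, lambda = l)$loglik)
  }
  expect_true(all(fit$lambda_lrt >= 0 & fit$lambda_lrt <= 1))
})

test_that("degenerate designs and short data error informatively", {
  set.seed(36)
  tr <- ape::rcoal(10)
  d <- data.frame(species = tr$tip.label, x = rnorm(10))
  d$z <- 2 * d$x                      # exactly collinear predictor
  d$y <- d$x + rnorm(10, 0, 0.1)
  expect_error(pgls_fit(y ~ x + z, d, tr), "collinear.*z")
  d2 <- d[1:3, ]
  expect_error(pgls_fit(y ~ x, d2, prune_to_taxa(tr, d2$species)),
               "insufficient", class = "codonsel_insufficient_data")
})

test_that("regression suite produces table rows and skips short models", {
  set.seed(40)
  tr <- ape::rcoal(12)
  sp <- tr$tip.label
  om <- data.frame(species = rep(sp, 2), clade = "all",
                   domain = rep(c("cleaved", "mature"), each = 12),
                   omega_rtt = runif(24, 0.2, 0.8))
  ph <- derive_traits(data.frame(
    species = sp, body_mass = 10^runif(12, 1, 3),
    testes_mass = 10^runif(12, -1, 1),
    head_length = runif(12, 5, 9), head_width = runif(12, 2, 4),
    total_sperm_length = runif(12, 80, 140)))
  st <- data.frame(species = sp, arginine_pct_mature = runif(12, 40, 60))
  out <- run_regression_suite(om, ph, tr, seq_stats = st)
  expect_true(all(c("n", "slope", "t", "r_squared", "lambda", "p")
                  %in% names(out)))
  # the omega ~ body + testes models yield two predictor rows each
  mom <- out[out$dependent == "cleaved omega_rtt", ]
  expect_equal(sort(mom$independent),
               c("log_body_mass", "log_testes_mass"))
  # row count after listwise deletion matches complete cases
  ok <- out$status == "ok" & out$dependent == "relative_hw" &
    out$domain == "cleaved"
  expect_equal(unique(out$n[ok]), 12)

  # starving one trait produces a skipped row with a reason
  ph2 <- ph; ph2$head_width[1:10] <- NA
  ph2$elongation <- NULL; ph2 <- derive_traits(ph2)
  out2 <- run_regression_suite(om, ph2, tr, seq_stats = st)
  sk <- out2[out2$dependent == "relative_hw" & out2$domain == "cleaved", ]
  expect_identical(unique(sk$status), "skipped")
  expect_match(sk$reason[1], "insufficient")
})

test_that("null trait simulations give roughly alpha-level false positives", {
  set.seed(55)
  tr <- ape::rcoal(20)
  x <- rnorm(20)
  hits <- 0
  n_rep <- 60
  for (r in seq_len(n_rep)) {
    y <- simulate_traits(tr, NULL, 0, lambda = 0.8, sigma = 1,
                         seed = 600 + r)
    d <- data.frame(species = tr$tip.label, x = x, y = as.numeric(y))
    f <- pgls_fit(y ~ x, d, tr)
    if (f$coefficients$p[2] <= 0.05) hits <- hits + 1
  }
  # 95% binomial envelope around 0.05 for 60 draws
  expect_lte(hits, stats::qbinom(0.995, n_rep, 0.05) + 1)
})
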