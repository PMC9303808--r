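test_that("profile log-likelihood matches hand and oracle evaluations", {
  # single included SNP at beta = 0, tau2 = 0, unit SEs: one standard-normal
  # log-density evaluated at a zero residual
  d1 <- mr_dataset("s1", 1, 1, 0, 1)
  for (vm in c("full", "profile")) {
    expect_equal(profile_loglik(0, 0, 1L, d1, vm), -0.5 * log(2 * pi),
                 tolerance = 1e-12)
  }
  # empty inclusion set contributes exactly zero
  d <- toy_dataset(L = 5, seed = 11)
  expect_identical(profile_loglik(0.7, 0.1, rep(0L, 5), d), 0)

  # randomized inputs against an independent term-by-term loop
  set.seed(202)
  for (i in 1:20) {
    d <- toy_dataset(L = 5, seed = 300 + i)
    beta <- rnorm(1); tau2 <- rexp(1, 10); I <- random_indicator(5)
    for (vm in c("full", "profile")) {
      expect_equal(profile_loglik(beta, tau2, I, d, vm),
                   oracle_loglik(beta, tau2, I, d, vm),
                   tolerance = 1e-12)
    }
  }
  expect_error(profile_loglik(0, -0.1, NULL, d), "tau2")
})

test_that("model-size penalty adds eta/2 per included SNP", {
  d <- toy_dataset(L = 8, seed = 21)
  I <- c(1L, 1L, 1L, 1L, 1L, 1L, 0L, 0L)
  base <- profile_loglik(0.2, 0.01, I, d)
  expect_identical(penalized_loglik(0.2, 0.01, I, d, eta = 0), base)
  expect_equal(penalized_loglik(0.2, 0.01, I, d, eta = 2), base + 6)
  I5 <- c(1L, 1L, 1L, 1L, 1L, 0L, 0L, 0L)
  base5 <- profile_loglik(0.2, 0.01, I5, d)
  expect_equal(penalized_loglik(0.2, 0.01, I5, d, eta = -2), base5 - 5)
})

test_that("two-component likelihood decomposes into one-component pieces", {
  d <- toy_dataset(L = 10, seed = 31)
  # no second component: reduces to the one-component likelihood
  I1 <- random_indicator(10)
  expect_equal(
    two_component_loglik(0.3, 0.01, 1.2, 0.05, I1, rep(0L, 10), d),
    profile_loglik(0.3, 0.01, I1, d), tolerance = 1e-15)
  expect_identical(
    two_component_loglik(0.3, 0.01, 1.2, 0.05, rep(0L, 10), rep(0L, 10), d), 0)

  # random disjoint partition equals the sum over the two subsets
  set.seed(77)
  for (i in 1:10) {
    s <- sample(0:2, 10, replace = TRUE)
    I1 <- as.integer(s == 1); I2 <- as.integer(s == 2)
    b1 <- rnorm(1); b2 <- rnorm(1); t1 <- rexp(1, 20); t2 <- rexp(1, 20)
    expect_equal(two_component_loglik(b1, t1, b2, t2, I1, I2, d),
                 profile_loglik(b1, t1, I1, d) + profile_loglik(b2, t2, I2, d),
                 tolerance = 1e-12)
  }
  expect_error(
    two_component_loglik(0, 0, 0, 0, rep(1L, 10), rep(1L, 10), d), "overlap")

  # two penalties
  s <- c(1, 1, 1, 1, 1, 2, 2, 2, 2, 2)
  I1 <- as.integer(s == 1); I2 <- as.integer(s == 2)
  base <- two_component_loglik(0.1, 0, 1, 0, I1, I2, d)
  expect_identical(penalized_two_component(0.1, 0, 1, 0, I1, I2, d, 0, 0), base)
  expect_equal(penalized_two_component(0.1, 0, 1, 0, I1, I2, d, 4, 0), base + 10)
  expect_equal(penalized_two_component(0.1, 0, 1, 0, I1, I2, d, -2, -2),
               base - 10)
})

test_that("likelihood is additive over SNPs and allele-recoding invariant", {
  d <- toy_dataset(L = 9, seed = 41)
  I <- random_indicator(9)
  sub <- d[I == 1, ]
  expect_equal(profile_loglik(0.4, 0.02, I, d),
               profile_loglik(0.4, 0.02, rep(1L, nrow(sub)), sub),
               tolerance = 1e-15)
  # joint sign flip of (gamma_hat, beta) leaves the likelihood unchanged
  flipped <- d
  flipped$gamma_hat <- -flipped$gamma_hat
  expect_equal(profile_loglik(-0.4, 0.02, I, flipped),
               profile_loglik(0.4, 0.02, I, d), tolerance = 1e-15)
})

test_that("Wald ratios and first-order SEs are correct", {
  d <- mr_dataset(c("a", "b", "c"), c(0.5, 1, -0.5), c(0.1, 0.1, 0.1),
                  c(0.1, 0, 0.3), c(0.05, 0.04, 0.02))
  wr <- wald_ratios(d)
  expect_equal(wr$ratio, c(0.2, 0, -0.6))
  expect_equal(wr$se, c(0.1, 0.04, 0.04))
  d0 <- mr_dataset(c("a", "zeroed"), c(1, 0), c(1, 1), c(0, 0), c(1, 1))
  expect_error(wald_ratios(d0), "zeroed")
})

test_that("DerSimonian-Laird tau2 matches hand and step-by-step oracles", {
  # identical ratios: Q = 0, truncation to 0
  expect_equal(as.numeric(dl_tau2(proportional_dataset())), 0)

  # ratios (0, 2, 4) with unit weights: beta_bar = 2, Q = 8, denom = 2
  d <- mr_dataset(c("a", "b", "c"), c(1, 1, 1), rep(0.1, 3), c(0, 2, 4),
                  c(1, 1, 1))
  t2 <- dl_tau2(d)
  expect_equal(as.numeric(t2), 3)
  expect_equal(attr(t2, "Q"), 8)

  # random input vs an independent recomputation
  set.seed(55)
  for (i in 1:10) {
    d <- toy_dataset(L = 10, seed = 500 + i, tau = 0.05)
    I <- random_indicator(10, min_on = 3)
    idx <- which(I == 1)
    r <- d$Gamma_hat[idx] / d$gamma_hat[idx]
    w <- d$gamma_hat[idx]^2 / d$se_y[idx]^2
    bb <- sum(w * r) / sum(w)
    Q <- sum(w * (r - bb)^2)
    expected <- max(0, (Q - (length(idx) - 1)) / (sum(w) - sum(w^2) / sum(w)))
    expect_equal(as.numeric(dl_tau2(d, I)), expected, tolerance = 1e-12)
  }
  expect_error(dl_tau2(d, c(1L, rep(0L, 9))), "at least 2")
})

test_that("exact Q is zero at a perfect fit and matches a grid search", {
  d <- proportional_dataset(c = 0.4)
  q <- exact_q(d)
  expect_equal(q$Q, 0, tolerance = 1e-10)
  expect_equal(q$beta, 0.4, tolerance = 1e-6)

  set.seed(66)
  for (i in 1:5) {
    d <- toy_dataset(L = 5, seed = 600 + i, tau = 0.05)
    q <- exact_q(d)
    grid <- seq(q$beta - 0.5, q$beta + 0.5, by = 1e-5)
    qg <- vapply(grid, function(b) {
      sum((d$Gamma_hat - b * d$gamma_hat)^2 / (d$se_y^2 + b^2 * d$se_x^2))
    }, numeric(1))
    expect_equal(q$Q, min(qg), tolerance = 1e-6)
  }
})
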