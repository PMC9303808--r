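test_that("IVW reproduces hand-computed weighted means", {
  # single SNP: the Wald ratio itself
  d1 <- mr_dataset("a", 0.5, 0.1, 0.2, 0.05)
  expect_equal(ivw(d1)$beta_hat, 0.4)
  # ratios (1, 2) with first-order weights (1, 4)
  d2 <- mr_dataset(c("a", "b"), c(1, 2), c(0.1, 0.1), c(1, 4), c(1, 1))
  f <- ivw(d2)
  expect_equal(f$beta_hat, 1.8)
  expect_equal(f$se, sqrt(1 / 5))
  expect_lt(f$ci_low, f$beta_hat)
  expect_gt(f$ci_high, f$beta_hat)
})

test_that("IVW is invariant to splitting a SNP into two half-weight copies", {
  d <- toy_dataset(L = 6, seed = 17)
  # duplicate the first SNP with its outcome SE inflated by sqrt(2): each
  # copy carries half the original weight
  dup <- mr_dataset(c(d$snp_id[-1], "dup1", "dup2"),
                    c(d$gamma_hat[-1], d$gamma_hat[1], d$gamma_hat[1]),
                    c(d$se_x[-1], d$se_x[1], d$se_x[1]),
                    c(d$Gamma_hat[-1], d$Gamma_hat[1], d$Gamma_hat[1]),
                    c(d$se_y[-1], d$se_y[1] * sqrt(2), d$se_y[1] * sqrt(2)))
  expect_equal(ivw(dup)$beta_hat, ivw(d)$beta_hat, tolerance = 1e-12)
  expect_equal(ivw(dup)$se, ivw(d)$se, tolerance = 1e-12)
})

test_that("mr_aps recovers a perfect proportional fit exactly", {
  d <- proportional_dataset(c = 0.4)
  f <- mr_aps(d)
  expect_equal(f$beta_hat, 0.4, tolerance = 1e-6)
  expect_equal(f$tau2_hat, 0, tolerance = 1e-8)
})

test_that("mr_aps matches a dense 2-D grid maximization of its objective", {
  d <- toy_dataset(L = 8, seed = 23, tau = 0.03)
  f <- mr_aps(d)
  betas <- seq(f$beta_hat - 0.05, f$beta_hat + 0.05, length.out = 101)
  tau2s <- seq(0, max(4 * f$tau2_hat, 0.004), length.out = 101)
  grid <- expand.grid(beta = betas, tau2 = tau2s)
  ll <- mapply(function(b, t2) profile_loglik(b, t2, NULL, d), grid$beta,
               grid$tau2)
  top <- grid[which.max(ll), ]
  expect_equal(f$beta_hat, top$beta, tolerance = 2 * diff(betas[1:2]))
  expect_equal(f$tau2_hat, top$tau2, tolerance = 2 * diff(tau2s[1:2]))
})

test_that("Huber mr_raps reduces to mr_aps when no residual is thresholded", {
  # near-zero exposure SEs and constant outcome SEs: in this limit the
  # profile likelihood's determinant is flat in beta and the L2 moment
  # condition coincides with the robust one, so the two estimators agree
  set.seed(31)
  L <- 15
  gamma <- runif(L, 0.5, 1)
  # residual noise well inside the claimed SE keeps every standardized
  # residual below the Huber threshold
  d <- mr_dataset(sprintf("s%02d", 1:L), gamma, rep(1e-8, L),
                  rnorm(L, 0.3 * gamma, 0.012), rep(0.02, L))
  aps <- mr_aps(d)
  raps <- mr_raps(d, loss = "huber")
  t_at_opt <- (d$Gamma_hat - aps$beta_hat * d$gamma_hat) /
    sqrt(aps$beta_hat^2 * d$se_x^2 + d$se_y^2 + aps$tau2_hat)
  expect_true(all(abs(t_at_opt) < 1.345)) # premise: nothing thresholded
  expect_equal(raps$beta_hat, aps$beta_hat, tolerance = 1e-6)
})

test_that("the robust loss resists a gross outlier better than L2", {
  set.seed(37)
  L <- 21
  gamma <- runif(L, 0.5, 1)
  sy <- rep(0.03, L)
  Gam <- rnorm(L, 0.3 * gamma, sy)
  Gam[L] <- 0.3 * gamma[L] + 10 * sy[L] # displaced by +10 SE
  d <- mr_dataset(sprintf("s%02d", 1:L), gamma, rep(0.04, L), Gam, sy)
  aps <- mr_aps(d)
  raps <- mr_raps(d, loss = "huber")
  expect_lt(abs(raps$beta_hat - 0.3), abs(aps$beta_hat - 0.3))
})

test_that("estimators are equivariant under allele recoding", {
  d <- toy_dataset(L = 10, seed = 43, tau = 0.02)
  flip <- d
  flip$gamma_hat <- -flip$gamma_hat
  for (fit in list(ivw, mr_aps, function(x) mr_raps(x, "huber"))) {
    a <- fit(d); b <- fit(flip)
    expect_equal(b$beta_hat, -a$beta_hat, tolerance = 1e-6)
    expect_equal(b$se, a$se, tolerance = 1e-4)
  }
})

test_that("mr_aps approaches first-order IVW as exposure SEs vanish with tau2 = 0", {
  set.seed(53)
  L <- 12
  gamma <- runif(L, 0.5, 1)
  sy <- runif(L, 0.02, 0.05)
  d <- mr_dataset(sprintf("s%02d", 1:L), gamma, rep(1e-9, L),
                  rnorm(L, 0.2 * gamma, sy), sy)
  f <- mr_aps(d)
  expect_equal(f$beta_hat, ivw(d)$beta_hat, tolerance = 1e-3)
})
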