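scaled_dataset <- function() {
  # 6 SNPs, mild heterogeneity, benchmark-like scales
  generate_dataset(scenario_spec(L = 6), n_invalid = 2, seed = 123)$data
}

test_that("log_posterior differences equal the sampler's acceptance ratios", {
  d <- scaled_dataset()
  pr <- prior_spec(beta_sd = 2, prec_shape = 1, prec_rate = 0.1)
  I <- c(1L, 1L, 1L, 0L, 1L, 1L)
  # R reference vs the compiled evaluation used inside the chain
  for (mode in c("full_bayes", "dl_plugin")) {
    for (i in 1:10) {
      set.seed(900 + i)
      beta <- rnorm(1); tau2 <- rexp(1, 50)
      ip <- log(rep(0.5, 6))
      lp_cpp <- besidemr:::cpp_log_posterior_one(
        beta, tau2, I, d$gamma_hat, d$Gamma_hat, d$se_x, d$se_y,
        eta = 0.3, full_bayes = mode == "full_bayes", full_var = FALSE,
        beta_sd = 2, prec_shape = 1, prec_rate = 0.1,
        log_p = ip, log_1mp = ip)
      lp_r <- log_posterior(beta, tau2, I, d, pr, eta = 0.3, mode = mode)
      expect_equal(lp_cpp, lp_r, tolerance = 1e-12)
    }
  }
  # symmetric-proposal M-H log ratio is the log-posterior difference
  l1 <- log_posterior(0.1, 0.01, I, d, pr, mode = "full_bayes")
  l2 <- log_posterior(0.3, 0.01, I, d, pr, mode = "full_bayes")
  expect_equal(l2 - l1,
               log_posterior(0.3, 0.01, I, d, pr, mode = "full_bayes") -
                 log_posterior(0.1, 0.01, I, d, pr, mode = "full_bayes"))
})

test_that("two-component log-posterior agrees between R and compiled code", {
  d <- scaled_dataset()
  pr <- prior_spec(beta_sd = 3, prec_shape = 2, prec_rate = 0.05)
  s <- c(1L, 2L, 0L, 1L, 2L, 1L)
  I1 <- as.integer(s == 1L); I2 <- as.integer(s == 2L)
  ip <- log(rep(0.5, 6))
  for (mode in c("full_bayes", "dl_plugin")) {
    lp_cpp <- besidemr:::cpp_log_posterior_two(
      0.2, 0.01, 1.1, 0.03, s, d$gamma_hat, d$Gamma_hat, d$se_x, d$se_y,
      eta1 = 0.5, eta2 = -0.5, full_bayes = mode == "full_bayes",
      full_var = FALSE, beta_sd = 3, prec_shape = 2, prec_rate = 0.05,
      log_p1 = ip, log_1mp1 = ip, log_p2 = ip, log_1mp2 = ip)
    lp_r <- log_posterior_two(0.2, 0.01, 1.1, 0.03, I1, I2, d, pr,
                              eta1 = 0.5, eta2 = -0.5, mode = mode)
    expect_equal(lp_cpp, lp_r, tolerance = 1e-12)
  }
})

test_that("a uniform inclusion prior contributes a constant L*log(1/2)", {
  d <- scaled_dataset()
  pr <- prior_spec()
  base <- penalized_loglik(0.1, 0.01, rep(1L, 6), d) +
    dnorm(0.1, 0, 10, log = TRUE)
  for (I in list(rep(1L, 6), c(1L, 0L, 1L, 0L, 1L, 0L))) {
    lik <- penalized_loglik(0.1, 0.01, I, d)
    expect_equal(log_posterior(0.1, 0.01, I, d, pr, mode = "dl_plugin") - lik,
                 dnorm(0.1, 0, 10, log = TRUE) + 6 * log(0.5))
  }
})

test_that("chains are reproducible and respect the instrument-count floor", {
  d <- generate_dataset(scenario_presets(1), n_invalid = 10, seed = 5)$data
  cfg <- mh_config(iterations = 3000, burn_in = 500, seed = 11)
  ch1 <- mh_one_component(d, config = cfg)
  ch2 <- mh_one_component(d, config = cfg)
  expect_identical(ch1$beta, ch2$beta)
  expect_identical(ch1$indicators, ch2$indicators)
  expect_identical(ch1$tau2, ch2$tau2)
  expect_true(all(rowSums(ch1$indicators) >= 5))

  ch3 <- mh_one_component(d, config = mh_config(iterations = 3000,
                                                burn_in = 500, seed = 12))
  expect_false(identical(ch1$beta, ch3$beta))
  expect_error(mh_one_component(d[1:3, ], config = cfg), "at least 5")
})

test_that("the DL tau2 trace is a deterministic function of the indicator trace", {
  d <- generate_dataset(scenario_presets(1), n_invalid = 10, seed = 6)$data
  ch <- mh_one_component(d, config = mh_config(iterations = 4000,
                                               burn_in = 1000, seed = 3))
  # tau2 stored at iteration t is the DL estimate over the PREVIOUS
  # iteration's inclusion set (the variance block precedes the flip)
  n <- length(ch$tau2)
  recomputed <- vapply(seq(2, n), function(i) {
    as.numeric(dl_tau2(d, ch$indicators[i - 1, ]))
  }, numeric(1))
  expect_equal(ch$tau2[2:n], recomputed, tolerance = 1e-12)
})

test_that("with the likelihood disabled the slope samples its prior", {
  d <- scaled_dataset()
  pr <- prior_spec(beta_sd = 1.5)
  cfg <- mh_config(iterations = 22000, burn_in = 2000, seed = 21,
                   mode = "full_bayes", proposal_sd_beta = 2,
                   proposal_sd_logprec = 1.5, min_instruments = 2)
  ch <- mh_one_component(d, priors = pr, config = cfg, tune = FALSE,
                         use_likelihood = FALSE)
  ks <- suppressWarnings(ks.test(ch$beta, pnorm, 0, 1.5))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("with indicators frozen the slope posterior matches a grid posterior", {
  d <- generate_dataset(scenario_spec(L = 5), n_invalid = 0, seed = 31)$data
  pr <- prior_spec(beta_sd = 1, prec_shape = 3, prec_rate = 0.003)
  cfg <- mh_config(iterations = 42000, burn_in = 2000, seed = 33,
                   mode = "full_bayes", min_instruments = 2)
  ch <- mh_one_component(d, priors = pr, config = cfg,
                         update_indicators = FALSE)
  # 2-D quadrature over (beta, log-precision), then the beta marginal
  betas <- seq(-0.6, 0.7, length.out = 401)
  lprec <- seq(-3, 14, length.out = 301)
  I <- rep(1L, 5)
  lp <- outer(betas, lprec, Vectorize(function(b, lp_) {
    tau2 <- exp(-lp_)
    profile_loglik(b, tau2, I, d) + dnorm(b, 0, 1, log = TRUE) +
      dgamma(exp(lp_), 3, rate = 0.003, log = TRUE) + lp_
  }))
  w <- exp(lp - max(lp))
  marg <- rowSums(w)
  cdf <- cumsum(marg) / sum(marg)
  # KS distance between sampled draws and the quadrature marginal
  emp <- ecdf(ch$beta)
  ks <- max(abs(emp(betas) - cdf))
  expect_lt(ks, 0.05)
})

test_that("pilot tuning moves acceptance toward the target band and freezes", {
  d <- generate_dataset(scenario_presets(1), n_invalid = 0, seed = 41)$data
  cfg <- mh_config(iterations = 4000, burn_in = 1000, seed = 43,
                   mode = "full_bayes", proposal_sd_beta = 5,
                   proposal_sd_logprec = 1)
  set.seed(43)
  tuned <- tune_proposals(d, prior_spec(), cfg, components = 1)
  # an absurdly wide slope proposal must be shrunk
  expect_lt(tuned$proposal_sd_beta, 5)
  cfg2 <- cfg
  cfg2$proposal_sd_beta <- tuned$proposal_sd_beta
  cfg2$proposal_sd_logprec <- tuned$proposal_sd_logprec
  ch <- mh_one_component(d, config = cfg2, tune = FALSE)
  expect_gt(ch$accept$beta, 0.05)
  expect_lt(ch$accept$beta, 0.8)
})

test_that("two-component chains respect disjointness and recover two slopes", {
  gen <- generate_dataset(scenario_presets(5), split = c(25, 25), seed = 51)
  cfg <- mh_config(iterations = 12000, burn_in = 3000, seed = 53)
  ch <- mh_two_component(gen$data, config = cfg)
  # state coding makes I1 + I2 <= 1 structural; check states are in {0,1,2}
  expect_true(all(ch$state %in% 0:2))
  expect_true(all(rowSums(ch$state > 0) >= 5))
  rel <- kmeans_relabel(ch)
  s <- summarize_chain(rel)$parameters
  expect_equal(s$mean[s$parameter == "beta1"], 0.05, tolerance = 0.1)
  expect_equal(s$mean[s$parameter == "beta2"], 1.05, tolerance = 0.1)
})

test_that("an outlying SNP receives the lowest posterior inclusion probability", {
  set.seed(61)
  L <- 20
  gamma <- runif(L, 0.4, 1.1)
  sx <- runif(L, 0.06, 0.095)
  sy <- runif(L, 0.03, 0.06)
  Gam <- rnorm(L, 0.05 * gamma, sy)
  Gam[7] <- 0.05 * gamma[7] + 12 * sy[7] # gross outlier
  d <- mr_dataset(sprintf("s%02d", 1:L), rnorm(L, gamma, sx), sx, Gam, sy)
  ch <- mh_one_component(d, config = mh_config(iterations = 50000,
                                               burn_in = 10000, seed = 63))
  p <- ppi(ch)
  expect_lt(p[7], min(p[-7]))
})
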