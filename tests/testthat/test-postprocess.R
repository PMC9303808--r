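# build a minimal two-component chain object by hand
fake_chain2 <- function(b1, b2, t1 = NULL, t2 = NULL, state = NULL) {
  n <- length(b1)
  L <- 4
  if (is.null(t1)) t1 <- rep(0.01, n)
  if (is.null(t2)) t2 <- rep(0.02, n)
  if (is.null(state)) {
    state <- matrix(rep(c(1L, 1L, 2L, 2L), each = n), nrow = n)
  }
  colnames(state) <- sprintf("s%d", 1:L)
  structure(list(components = 2, mode = "dl_plugin",
                 snp_id = colnames(state),
                 beta1 = b1, beta2 = b2, tau2_1 = t1, tau2_2 = t2,
                 state = state, chain_id = rep(1L, n),
                 log_post = rep(0, n), accept = list(), converged = TRUE,
                 geweke_z = 0,
                 config = mh_config(iterations = 2L * n, burn_in = n),
                 priors = prior_spec()),
            class = "beside_chain")
}

fake_chain1 <- function(beta, indicators) {
  n <- length(beta)
  structure(list(components = 1, mode = "dl_plugin",
                 snp_id = colnames(indicators),
                 beta = beta, tau2 = rep(0, n), indicators = indicators,
                 chain_id = rep(1L, n), log_post = rep(0, n),
                 accept = list(), converged = TRUE, geweke_z = 0,
                 config = mh_config(iterations = 2L * n, burn_in = n),
                 priors = prior_spec()),
            class = "beside_chain")
}

test_that("PPI is the per-SNP inclusion frequency", {
  ind <- cbind(always = rep(1L, 10), never = rep(0L, 10),
               some = c(1L, 1L, 1L, 0L, 0L, 0L, 0L, 1L, 0L, 1L))
  ch <- fake_chain1(rnorm(10), ind)
  p <- ppi(ch)
  expect_equal(unname(p), c(1, 0, 0.5))

  set.seed(61)
  ind2 <- matrix(rbinom(200, 1, 0.3), nrow = 20,
                 dimnames = list(NULL, sprintf("r%d", 1:10)))
  ch2 <- fake_chain1(rnorm(20), ind2)
  expect_equal(ppi(ch2), colSums(ind2) / 20)
})

test_that("kmeans relabeling restores randomly switched traces", {
  set.seed(71)
  n <- 4000
  true1 <- rnorm(n, 0.9, 0.05)
  true2 <- rnorm(n, -0.6, 0.05)
  swap <- runif(n) < 0.4 # switching occurs, but original labels hold a majority
  b1 <- ifelse(swap, true2, true1)
  b2 <- ifelse(swap, true1, true2)
  t1 <- ifelse(swap, 0.02, 0.01)
  t2 <- ifelse(swap, 0.01, 0.02)
  state <- matrix(0L, n, 4)
  state[, 1] <- ifelse(swap, 2L, 1L) # SNP 1 follows component 1's slope
  state[, 3] <- ifelse(swap, 1L, 2L)
  colnames(state) <- sprintf("s%d", 1:4)
  ch <- fake_chain2(b1, b2, t1, t2, state)
  out <- kmeans_relabel(ch)
  expect_equal(mean(out$beta1), 0.9, tolerance = 0.02)
  expect_equal(mean(out$beta2), -0.6, tolerance = 0.02)
  # variances and indicators swapped in tandem
  expect_equal(unique(out$tau2_1), 0.01)
  expect_equal(unique(out$tau2_2), 0.02)
  expect_true(all(out$state[, 1] == 1L))
  expect_true(all(out$state[, 3] == 2L))
  expect_equal(out$relabel$n_swapped, sum(swap))
})

test_that("relabeling is idempotent, conserving and a no-op without switching", {
  set.seed(73)
  n <- 1000
  ch <- fake_chain2(rnorm(n, 0.1, 0.03), rnorm(n, 1.1, 0.05))
  out <- kmeans_relabel(ch)
  expect_equal(out$beta1, ch$beta1) # well-separated, never switched
  expect_equal(out$beta2, ch$beta2)

  swapped <- ch
  sw <- seq(1, n, by = 3)
  swapped$beta1[sw] <- ch$beta2[sw]
  swapped$beta2[sw] <- ch$beta1[sw]
  once <- kmeans_relabel(swapped)
  twice <- kmeans_relabel(once)
  expect_equal(twice$beta1, once$beta1)
  expect_equal(twice$beta2, once$beta2)
  # pooled multiset of slope draws is unchanged
  expect_equal(sort(c(once$beta1, once$beta2)),
               sort(c(ch$beta1, ch$beta2)))
  # cluster sizes account for every pooled draw
  expect_equal(sum(once$relabel$sizes), 2 * n)
})

test_that("summaries match sort-based quantile oracles", {
  set.seed(79)
  x <- rnorm(10000)
  ch <- fake_chain1(x, matrix(1L, 10000, 2,
                              dimnames = list(NULL, c("a", "b"))))
  s <- summarize_chain(ch)
  b <- s$parameters[s$parameters$parameter == "beta", ]
  expect_equal(b$mean, mean(x))
  expect_equal(b$median, quantile(x, 0.5, names = FALSE))
  expect_equal(b$ci_low, quantile(x, 0.025, names = FALSE))
  expect_equal(b$ci_high, quantile(x, 0.975, names = FALSE))
  # 10000 iid normal draws: interval endpoints near +/- 1.96
  expect_equal(b$ci_low, -1.96, tolerance = 0.05)
  expect_equal(b$ci_high, 1.96, tolerance = 0.05)

  cc <- fake_chain1(rep(2.5, 50), matrix(1L, 50, 1,
                                         dimnames = list(NULL, "a")))
  sc <- summarize_chain(cc)$parameters[1, ]
  expect_equal(unlist(sc[c("mean", "median", "ci_low", "ci_high")]),
               c(mean = 2.5, median = 2.5, ci_low = 2.5, ci_high = 2.5))
})

test_that("split R-hat matches the textbook formula and flags disagreement", {
  set.seed(83)
  x <- rnorm(500); y <- rnorm(500)
  # independent oracle computation
  halves <- list(x[1:250], x[251:500], y[1:250], y[251:500])
  W <- mean(sapply(halves, var))
  B <- 250 * var(sapply(halves, mean))
  expected <- sqrt((249 / 250 * W + B / 250) / W)
  expect_equal(gelman_rubin(list(x, y)), expected, tolerance = 1e-10)

  expect_equal(gelman_rubin(list(x, x)), 1, tolerance = 0.01)
  expect_gt(gelman_rubin(list(rnorm(500, 0, 0.1), rnorm(500, 10, 0.1))), 10)
})

test_that("Geweke z is small for stationary traces and large under drift", {
  set.seed(89)
  expect_lt(abs(geweke_z(rnorm(5000))), 2.5)
  expect_gt(abs(geweke_z(c(rnorm(2500), rnorm(2500, 5)))), 5)
})
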