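# Shared fixtures, built in code.

# small deterministic dataset with mild heterogeneity
toy_dataset <- function(L = 8, seed = 101, beta = 0.3, tau = 0.02) {
  set.seed(seed)
  gamma <- runif(L, 0.4, 1)
  sx <- runif(L, 0.05, 0.1)
  sy <- runif(L, 0.03, 0.06)
  alpha <- rnorm(L, 0, tau)
  mr_dataset(sprintf("rs%03d", seq_len(L)),
             rnorm(L, gamma, sx), sx,
             rnorm(L, alpha + beta * gamma, sy), sy)
}

# dataset whose outcome effects are exactly proportional to the exposure
# effects (perfect fit at slope `c`)
proportional_dataset <- function(c = 0.4, L = 6) {
  gamma <- seq(0.4, 1.2, length.out = L)
  mr_dataset(sprintf("p%02d", seq_len(L)), gamma, rep(0.05, L),
             c * gamma, rep(0.04, L))
}

random_indicator <- function(L, min_on = 1) {
  I <- rbinom(L, 1, 0.6)
  if (sum(I) < min_on) I[sample.int(L, min_on)] <- 1L
  as.integer(I)
}

# independent term-by-term re-evaluation of the profile log-likelihood,
# written as an explicit loop (oracle for the vectorized implementation)
oracle_loglik <- function(beta, tau2, I, d, variance_mode = "profile") {
  total <- 0
  for (j in seq_len(nrow(d))) {
    if (I[j] == 0) next
    v_full <- beta^2 * d$se_x[j]^2 + d$se_y[j]^2 + tau2
    v_log <- if (variance_mode == "full") v_full else d$se_y[j]^2 + tau2
    r <- d$Gamma_hat[j] - beta * d$gamma_hat[j]
    total <- total - 0.5 * log(2 * pi) - 0.5 * (log(v_log) + r^2 / v_full)
  }
  total
}
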