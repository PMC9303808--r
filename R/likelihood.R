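# Likelihoods and heterogeneity statistics.
#
# The workhorse is the profile log-likelihood of the summary-data model
#   gamma_hat_j ~ N(gamma_j, se_x_j^2),  Gamma_hat_j ~ N(alpha_j + beta*gamma_j, se_y_j^2)
# with the per-SNP nuisance effects gamma_j profiled out and pleiotropy
# alpha_j ~ N(0, tau2) absorbed into the residual variance, extended with a
# binary inclusion vector I so that only SNPs with I_j = 1 contribute.

check_variance_mode <- function(variance_mode) {
  match.arg(variance_mode, c("profile", "full"))
}

# per-SNP contributions; excluded SNPs contribute exactly 0
profile_loglik_terms <- function(beta, tau2, I, data, variance_mode = "profile") {
  v_full <- beta^2 * data$se_x^2 + data$se_y^2 + tau2
  v_log <- if (variance_mode == "full") v_full else data$se_y^2 + tau2
  r <- data$Gamma_hat - beta * data$gamma_hat
  I * (-0.5 * log(2 * pi) - 0.5 * (log(v_log) + r^2 / v_full))
}

#' One-component profile log-likelihood with inclusion indicators
#'
#' Evaluates
#' \deqn{l(\beta,\tau^2,I) = \sum_j I_j\Big[-\tfrac12\log 2\pi
#'   - \tfrac12\Big(\log v_j + \frac{(\hat\Gamma_j-\beta\hat\gamma_j)^2}
#'   {\beta^2\sigma_{Xj}^2+\sigma_{Yj}^2+\tau^2}\Big)\Big]}
#' where the log-determinant variance is
#' \eqn{v_j = \sigma_{Yj}^2+\tau^2} under `variance_mode = "profile"` (the
#' default) and \eqn{v_j = \beta^2\sigma_{Xj}^2+\sigma_{Yj}^2+\tau^2} under
#' `"full"`. The `"profile"` form is the exact result of profiling the
#' nuisance SNP-exposure effects out of the joint normal likelihood: the
#' determinant is free of \eqn{\beta}, and only the quadratic term carries
#' the weak-instrument variance \eqn{\beta^2\sigma_{Xj}^2}. The `"full"`
#' variant, which repeats the quadratic variance inside the logarithm, is
#' retained for A/B comparison; its \eqn{\beta}-dependent determinant adds
#' a score term \eqn{-\beta\sum_j\sigma_{Xj}^2/v_j} that re-introduces
#' weak-instrument attenuation, so it is not the default. Both modes use
#' the full variance in the quadratic term, so heterogeneity from weak
#' instruments and pleiotropy is always accounted for. SNPs with
#' \eqn{I_j = 0} contribute exactly 0.
#'
#' @param beta Causal slope.
#' @param tau2 Pleiotropy variance (>= 0).
#' @param I Binary inclusion vector of length `nrow(data)` (or `NULL` for
#'   all ones).
#' @param data An [mr_dataset()].
#' @param variance_mode `"profile"` (default) or `"full"`; see Details.
#' @return The scalar log-likelihood.
#' @export
profile_loglik <- function(beta, tau2, I = NULL, data, variance_mode = "profile") {
  variance_mode <- check_variance_mode(variance_mode)
  data <- validate_mr_dataset(data)
  if (is.null(I)) I <- rep(1L, nrow(data))
  stopifnot(length(I) == nrow(data), all(I %in% c(0, 1)))
  if (!is.finite(tau2) || tau2 < 0) stop("tau2 must be >= 0", call. = FALSE)
  sum(profile_loglik_terms(beta, tau2, I, data, variance_mode))
}

#' Penalized one-component log-likelihood
#'
#' Adds the model-size penalty \eqn{(\eta/2)\sum_j I_j} to
#' [profile_loglik()]. Positive `eta` rewards larger instrument sets,
#' negative `eta` favours parsimony; `eta = 0` (the default throughout the
#' simulations) is a no-op.
#'
#' @inheritParams profile_loglik
#' @param eta Model-size penalty parameter.
#' @return The scalar penalized log-likelihood.
#' @export
penalized_loglik <- function(beta, tau2, I = NULL, data, eta = 0,
                             variance_mode = "profile") {
  if (is.null(I)) I <- rep(1L, nrow(data))
  profile_loglik(beta, tau2, I, data, variance_mode) + (eta / 2) * sum(I)
}

#' Two-component profile log-likelihood
#'
#' Sum of two one-component contributions over disjoint instrument sets:
#' SNPs with `I1_j = 1` contribute with slope `beta1` and pleiotropy
#' variance `tau2_1`, SNPs with `I2_j = 1` with `(beta2, tau2_2)`, and SNPs
#' in neither set (the S0 class) contribute 0. The sets must be disjoint:
#' `I1_j + I2_j <= 1` for every j.
#'
#' @param beta1,beta2 Component causal slopes.
#' @param tau2_1,tau2_2 Component pleiotropy variances (>= 0).
#' @param I1,I2 Binary inclusion vectors (disjoint).
#' @inheritParams profile_loglik
#' @return The scalar log-likelihood.
#' @export
two_component_loglik <- function(beta1, tau2_1, beta2, tau2_2, I1, I2, data,
                                 variance_mode = "profile") {
  variance_mode <- check_variance_mode(variance_mode)
  data <- validate_mr_dataset(data)
  stopifnot(length(I1) == nrow(data), length(I2) == nrow(data),
            all(I1 %in% c(0, 1)), all(I2 %in% c(0, 1)))
  if (any(I1 + I2 > 1)) {
    stop("inclusion vectors overlap: I1_j + I2_j must be <= 1", call. = FALSE)
  }
  if (tau2_1 < 0 || tau2_2 < 0) stop("tau2 must be >= 0", call. = FALSE)
  sum(profile_loglik_terms(beta1, tau2_1, I1, data, variance_mode)) +
    sum(profile_loglik_terms(beta2, tau2_2, I2, data, variance_mode))
}

#' Penalized two-component log-likelihood
#'
#' [two_component_loglik()] plus the two model-size penalties
#' \eqn{(\eta_1/2)\sum_j I_{1j} + (\eta_2/2)\sum_j I_{2j}}.
#'
#' @inheritParams two_component_loglik
#' @param eta1,eta2 Per-component model-size penalties.
#' @return The scalar penalized log-likelihood.
#' @export
penalized_two_component <- function(beta1, tau2_1, beta2, tau2_2, I1, I2,
                                    data, eta1 = 0, eta2 = 0,
                                    variance_mode = "profile") {
  two_component_loglik(beta1, tau2_1, beta2, tau2_2, I1, I2, data,
                       variance_mode) +
    (eta1 / 2) * sum(I1) + (eta2 / 2) * sum(I2)
}

#' Per-SNP Wald ratio estimates
#'
#' The Wald ratio for SNP j is `Gamma_hat_j / gamma_hat_j`, with the
#' first-order standard error `se_y_j / |gamma_hat_j|` (uncertainty in the
#' SNP-exposure association ignored, as in the standard IVW weighting).
#'
#' @param data An [mr_dataset()]; all `gamma_hat` must be nonzero.
#' @return A data frame with columns `snp_id`, `ratio`, `se`.
#' @export
wald_ratios <- function(data) {
  data <- validate_mr_dataset(data)
  zero <- which(data$gamma_hat == 0)
  if (length(zero) > 0) {
    stop("zero SNP-exposure estimate for SNP ", data$snp_id[zero[1L]],
         "; Wald ratio undefined", call. = FALSE)
  }
  data.frame(snp_id = data$snp_id,
             ratio = data$Gamma_hat / data$gamma_hat,
             se = data$se_y / abs(data$gamma_hat),
             stringsAsFactors = FALSE)
}

#' DerSimonian-Laird estimate of the pleiotropy variance
#'
#' Closed-form moment estimator of `tau2` computed from the Wald ratios of
#' the included SNPs with first-order weights `w_j = gamma_hat_j^2 / se_y_j^2`:
#' the first-order Cochran Q around the weighted mean ratio is compared with
#' its expectation `k - 1`, and the excess is scaled by
#' `sum(w) - sum(w^2)/sum(w)`; negative values are truncated to 0.
#'
#' @param data An [mr_dataset()].
#' @param I Binary inclusion vector (default: all SNPs). At least two SNPs
#'   must be included.
#' @return The estimate `tau2_hat >= 0`, with attributes `Q` (first-order
#'   Q-statistic) and `beta_fo` (first-order weighted mean ratio).
#' @export
dl_tau2 <- function(data, I = NULL) {
  data <- validate_mr_dataset(data)
  if (is.null(I)) I <- rep(1L, nrow(data))
  stopifnot(length(I) == nrow(data), all(I %in% c(0, 1)))
  k <- sum(I)
  if (k < 2) stop("DerSimonian-Laird estimate requires at least 2 included SNPs",
                  call. = FALSE)
  idx <- which(I == 1)
  sub <- data[idx, , drop = FALSE]
  r <- sub$Gamma_hat / sub$gamma_hat
  w <- sub$gamma_hat^2 / sub$se_y^2
  beta_fo <- sum(w * r) / sum(w)
  Q <- sum(w * (r - beta_fo)^2)
  denom <- sum(w) - sum(w^2) / sum(w)
  tau2 <- max(0, (Q - (k - 1)) / denom)
  structure(tau2, Q = Q, beta_fo = beta_fo)
}

#' Exact (weak-instrument-corrected) Q-statistic
#'
#' Minimizes over beta the heterogeneity statistic with exact weights,
#' \deqn{Q(\beta) = \sum_j \frac{(\hat\Gamma_j - \beta\hat\gamma_j)^2}
#'   {\sigma_{Yj}^2 + \beta^2\sigma_{Xj}^2},}
#' whose denominators propagate uncertainty from both GWAS, making the
#' statistic robust to weak-instrument inflation. Under the causal model
#' with no pleiotropy, the minimum is approximately chi-square with L - 1
#' degrees of freedom.
#'
#' @param data An [mr_dataset()] with at least 2 SNPs.
#' @param tol Convergence tolerance on beta for the one-dimensional
#'   minimization (default 1e-10).
#' @return A list with `Q` (the minimum) and `beta` (the minimizer).
#' @export
exact_q <- function(data, tol = 1e-10) {
  data <- validate_mr_dataset(data)
  if (nrow(data) < 2L) stop("exact Q requires at least 2 SNPs", call. = FALSE)
  qfun <- function(beta) {
    sum((data$Gamma_hat - beta * data$gamma_hat)^2 /
          (data$se_y^2 + beta^2 * data$se_x^2))
  }
  start <- ivw(data)$beta_hat
  half <- 10 * abs(start) + 1
  lo <- start - half
  hi <- start + half
  for (attempt in 1:6) {
    opt <- stats::optimize(qfun, lower = lo, upper = hi, tol = tol)
    # widen if the optimizer ran into a bracket edge
    at_edge <- (opt$minimum - lo) < 1e-6 * (hi - lo) ||
      (hi - opt$minimum) < 1e-6 * (hi - lo)
    if (!at_edge) break
    lo <- lo - (hi - lo)
    hi <- hi + (hi - lo)
  }
  if (at_edge) stop("failed to bracket the minimum of the exact Q-statistic",
                    call. = FALSE)
  list(Q = opt$objective, beta = opt$minimum)
}
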