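# Synthetic two-sample summary-data generator for the benchmark scenarios.
#
# Data are generated directly at the summary level: per SNP,
#   gamma_hat_j ~ N(gamma_j, sigma_xj^2),  Gamma_hat_j ~ N(alpha_j + beta*gamma_j, sigma_yj^2)
# with gamma_j = delta_j + kappa_x * psi_j and alpha_j = upsilon_j + kappa_y * psi_j,
# so a shared psi_j component ties instrument strength to the pleiotropic
# effect (InSIDE violation), while upsilon_j alone gives InSIDE-respecting
# pleiotropy.

#' Scenario specification for the summary-data simulator
#'
#' Builds a scenario description; [scenario_presets()] returns the six
#' benchmark configurations.
#'
#' @param L Number of SNPs.
#' @param beta True causal effect (component-1 slope in the two-cluster
#'   scenarios; the second cluster identifies `beta + 1`).
#' @param delta_range Uniform range for the direct SNP-exposure effects.
#' @param psi_range Uniform range for the confounder loadings of
#'   InSIDE-violating SNPs.
#' @param upsilon_sd SD of the mean-zero normal direct SNP-outcome effects
#'   of InSIDE-respecting pleiotropic SNPs.
#' @param mu_alpha,sd_alpha Mean and SD of the pleiotropic effects of
#'   invalid SNPs in the one-cluster scenarios (balanced: mean 0;
#'   directional: mean > 0).
#' @param sigma_x_range,sigma_y_range Uniform ranges for the SNP-exposure
#'   and SNP-outcome standard errors.
#' @param kappa_x,kappa_y Confounder loadings on exposure and outcome
#'   (default 1).
#' @param two_component `TRUE` for the two-cluster (S1/S2) scenarios.
#' @param f_target Nominal mean F-statistic implied by the ranges (for
#'   reporting only).
#' @param alpha_rng Optional function `(n, mu, sd)` generating the invalid
#'   SNPs' pleiotropic effects in the one-cluster scenarios (default
#'   normal), a hook for non-normal pleiotropy studies.
#' @param scenario Optional scenario id label.
#' @return A `scenario_spec` list.
#' @export
scenario_spec <- function(L = 50, beta = 0.05,
                          delta_range = c(0.34, 1.1),
                          psi_range = c(0.34, 1.1),
                          upsilon_sd = 0.04,
                          mu_alpha = 0, sd_alpha = 0.04,
                          sigma_x_range = c(0.06, 0.095),
                          sigma_y_range = c(0.03, 0.06),
                          kappa_x = 1, kappa_y = 1,
                          two_component = FALSE, f_target = NA_real_,
                          alpha_rng = NULL, scenario = NA_integer_) {
  stopifnot(L >= 1, diff(delta_range) >= 0, diff(psi_range) >= 0,
            diff(sigma_x_range) >= 0, diff(sigma_y_range) >= 0,
            upsilon_sd >= 0, sd_alpha >= 0)
  structure(list(L = as.integer(L), beta = beta, delta_range = delta_range,
                 psi_range = psi_range, upsilon_sd = upsilon_sd,
                 mu_alpha = mu_alpha, sd_alpha = sd_alpha,
                 sigma_x_range = sigma_x_range, sigma_y_range = sigma_y_range,
                 kappa_x = kappa_x, kappa_y = kappa_y,
                 two_component = two_component, f_target = f_target,
                 alpha_rng = alpha_rng, scenario = scenario),
            class = "scenario_spec")
}

#' Benchmark simulation scenarios
#'
#' Six encoded scenarios with 50 SNPs and true causal effect 0.05:
#' \itemize{
#' \item 1: strong instruments (mean F about 100), invalid SNPs carry
#'   balanced pleiotropy `N(0, sd 0.04)`;
#' \item 2: as 1 but weak instruments (mean F about 10,
#'   `sigma_x ~ U(0.06, 0.95)`);
#' \item 3: strong instruments, directional pleiotropy `N(0.05, sd 0.04)`;
#' \item 4: weak instruments, directional pleiotropy;
#' \item 5: two clusters with strong instruments: S1 SNPs are
#'   InSIDE-respecting (`delta ~ U(0.34, 1.1)`, `upsilon ~ N(0, sd 0.04)`,
#'   `psi = 0`, slope `beta`), S2 SNPs maximally violate InSIDE
#'   (`psi ~ U(0.34, 1.1)`, `delta = upsilon = 0`, identifying `beta + 1`);
#' \item 6: as 5 with weaker instruments (mean F about 25,
#'   `sigma_x ~ U(0.06, 0.4)`).
#' }
#' SNP-outcome standard errors are `U(0.03, 0.06)` throughout. The
#' weak-instrument `sigma_x` ranges are calibrated reconstructions that
#' reproduce the benchmark mean-F and heterogeneity levels.
#'
#' @param id Scenario id, 1 to 6.
#' @return A [scenario_spec()].
#' @export
scenario_presets <- function(id) {
  if (!is.numeric(id) || length(id) != 1L || !(id %in% 1:6)) {
    stop("unknown scenario id: ", paste(id, collapse = ","), call. = FALSE)
  }
  id <- as.integer(id)
  switch(id,
    scenario_spec(mu_alpha = 0, sigma_x_range = c(0.06, 0.095),
                  f_target = 100, scenario = 1L),
    scenario_spec(mu_alpha = 0, sigma_x_range = c(0.06, 0.95),
                  f_target = 10, scenario = 2L),
    scenario_spec(mu_alpha = 0.05, sigma_x_range = c(0.06, 0.095),
                  f_target = 100, scenario = 3L),
    scenario_spec(mu_alpha = 0.05, sigma_x_range = c(0.06, 0.95),
                  f_target = 10, scenario = 4L),
    scenario_spec(two_component = TRUE, sigma_x_range = c(0.06, 0.095),
                  f_target = 100, scenario = 5L),
    scenario_spec(two_component = TRUE, sigma_x_range = c(0.06, 0.4),
                  f_target = 25, scenario = 6L)
  )
}

runif_range <- function(n, range) stats::runif(n, range[1L], range[2L])

#' Generate a synthetic two-sample summary dataset
#'
#' Draws one dataset from a [scenario_spec()]. For the one-cluster
#' scenarios, `n_invalid` SNPs (positions chosen uniformly at random
#' without replacement) receive pleiotropic effects
#' `alpha ~ N(mu_alpha, sd_alpha)`; the rest have `alpha = 0`. For the
#' two-cluster scenarios, `split = c(n_S1, n_S2)` SNPs are assigned at
#' random to the InSIDE-respecting set S1 and the InSIDE-violating set S2.
#' Summary estimates are then drawn independently as
#' `gamma_hat ~ N(gamma, sigma_x^2)` and
#' `Gamma_hat ~ N(alpha + beta * gamma, sigma_y^2)`.
#'
#' @param spec A [scenario_spec()].
#' @param n_invalid Number of invalid SNPs (one-cluster scenarios).
#' @param split Length-2 vector `c(n_S1, n_S2)` summing to `spec$L`
#'   (two-cluster scenarios).
#' @param seed Optional integer seed (set before any draw).
#' @return A list with `data` (an [mr_dataset()]) and `truth` (data frame
#'   with per-SNP `cluster` label, pleiotropic effect `alpha`, true
#'   instrument strength `gamma_true`, and `beta_true`).
#' @export
generate_dataset <- function(spec, n_invalid = 0, split = NULL, seed = NULL) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (!is.null(seed)) set.seed(seed)
  L <- spec$L
  if (spec$two_component) {
    if (is.null(split)) split <- c(ceiling(L / 2), floor(L / 2))
    stopifnot(length(split) == 2L, sum(split) == L, all(split >= 0))
    s2_pos <- sample.int(L, split[2L])
    in_s2 <- seq_len(L) %in% s2_pos
    delta <- ifelse(in_s2, 0, runif_range(L, spec$delta_range))
    upsilon <- ifelse(in_s2, 0, stats::rnorm(L, 0, spec$upsilon_sd))
    psi <- ifelse(in_s2, runif_range(L, spec$psi_range), 0)
    cluster <- ifelse(in_s2, "S2", "S1")
  } else {
    stopifnot(n_invalid >= 0, n_invalid <= L)
    inv_pos <- if (n_invalid > 0) sample.int(L, n_invalid) else integer(0)
    invalid <- seq_len(L) %in% inv_pos
    delta <- runif_range(L, spec$delta_range)
    rng <- if (is.null(spec$alpha_rng)) stats::rnorm else spec$alpha_rng
    upsilon <- ifelse(invalid, rng(L, spec$mu_alpha, spec$sd_alpha), 0)
    psi <- rep(0, L)
    cluster <- ifelse(invalid, "invalid", "valid")
  }
  gamma <- delta + spec$kappa_x * psi
  alpha <- upsilon + spec$kappa_y * psi
  sx <- runif_range(L, spec$sigma_x_range)
  sy <- runif_range(L, spec$sigma_y_range)
  gamma_hat <- stats::rnorm(L, gamma, sx)
  Gamma_hat <- stats::rnorm(L, alpha + spec$beta * gamma, sy)
  ids <- sprintf("snp_%02d", seq_len(L))
  list(
    data = mr_dataset(ids, gamma_hat, sx, Gamma_hat, sy),
    truth = data.frame(snp_id = ids, cluster = cluster, alpha = alpha,
                       gamma_true = gamma, beta_true = spec$beta,
                       stringsAsFactors = FALSE)
  )
}

#' Write simulation truth labels to a TSV file
#'
#' @param truth The `truth` data frame from [generate_dataset()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_table <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a scenario specification as YAML
#'
#' @param spec A [scenario_spec()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scenario_yaml <- function(spec, path) {
  s <- unclass(spec)
  s$alpha_rng <- NULL
  yaml::write_yaml(s, path)
  invisible(path)
}

#' Read a scenario specification from YAML
#'
#' @param path YAML file written by [write_scenario_yaml()] (or edited by
#'   hand; unknown fields are rejected).
#' @return A [scenario_spec()].
#' @export
read_scenario_yaml <- function(path) {
  s <- yaml::read_yaml(path)
  s$scenario <- if (is.null(s$scenario)) NA_integer_ else s$scenario
  known <- names(formals(scenario_spec))
  extra <- setdiff(names(s), known)
  if (length(extra) > 0) {
    stop("unknown scenario field(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  s[vapply(s, is.null, logical(1))] <- NULL
  do.call(scenario_spec, s)
}
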