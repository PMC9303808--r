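# Metropolis-Hastings model-averaging samplers (R-level interface).

#' Prior specification for the model-averaging sampler
#'
#' @param beta_sd Standard deviation of the zero-centered normal prior on
#'   each causal slope. The default 10 is weakly informative on the
#'   standardized-effect scale of typical MR analyses.
#' @param prec_shape,prec_rate Shape and rate of the gamma prior on each
#'   precision `1/tau2` (vague defaults 0.01, 0.01). Ignored when the
#'   DerSimonian-Laird plug-in replaces the posterior update of `tau2`.
#' @param inclusion_prob Prior probability that a SNP is included in the
#'   valid set: a scalar in (0, 1) or a per-SNP vector for informative
#'   priors. The default 1/2 is indifferent, so inclusion is driven by the
#'   likelihood.
#' @return A `prior_spec` list.
#' @export
prior_spec <- function(beta_sd = 10, prec_shape = 0.01, prec_rate = 0.01,
                       inclusion_prob = 0.5) {
  stopifnot(beta_sd > 0, prec_shape > 0, prec_rate > 0,
            all(inclusion_prob > 0), all(inclusion_prob < 1))
  structure(list(beta_sd = beta_sd, prec_shape = prec_shape,
                 prec_rate = prec_rate, inclusion_prob = inclusion_prob),
            class = "prior_spec")
}

#' Sampler configuration
#'
#' @param iterations Total iterations per chain (default 50000).
#' @param burn_in Discarded initial iterations (default 10000).
#' @param seed Integer seed; every random draw in the run (tuning included)
#'   flows from it.
#' @param mode `"dl_plugin"` (default): `tau2` is set to the
#'   DerSimonian-Laird estimate over the currently included SNPs at each
#'   iteration; `"full_bayes"`: `tau2` is sampled via a random walk on the
#'   log-precision.
#' @param eta,eta1,eta2 Model-size penalties ((eta/2) per included SNP);
#'   `eta1`/`eta2` apply to the two components of the two-slope model.
#' @param min_instruments Indicator moves that would leave fewer than this
#'   many SNPs included (in total, summed over components) are rejected
#'   outright (default 5; must be >= 2 so the plug-in variance estimate is
#'   defined).
#' @param proposal_sd_beta,proposal_sd_logprec Random-walk proposal SDs; if
#'   `NULL` they are set by a pilot adaptation phase ([tune_proposals()])
#'   that freezes before the retained run.
#' @param n_chains Number of chains (initial slopes are jittered across
#'   chains; draws are pooled post burn-in and split R-hat is reported when
#'   `n_chains >= 2`).
#' @param variance_mode Passed to the likelihood; see [profile_loglik()].
#' @return An `mh_config` list.
#' @export
mh_config <- function(iterations = 50000, burn_in = 10000, seed = 1,
                      mode = c("dl_plugin", "full_bayes"),
                      eta = 0, eta1 = eta, eta2 = eta,
                      min_instruments = 5,
                      proposal_sd_beta = NULL, proposal_sd_logprec = NULL,
                      n_chains = 1, variance_mode = "profile") {
  mode <- match.arg(mode)
  stopifnot(burn_in < iterations, min_instruments >= 2, n_chains >= 1)
  structure(list(iterations = as.integer(iterations),
                 burn_in = as.integer(burn_in), seed = seed, mode = mode,
                 eta = eta, eta1 = eta1, eta2 = eta2,
                 min_instruments = as.integer(min_instruments),
                 proposal_sd_beta = proposal_sd_beta,
                 proposal_sd_logprec = proposal_sd_logprec,
                 n_chains = as.integer(n_chains),
                 variance_mode = check_variance_mode(variance_mode)),
            class = "mh_config")
}

incl_log_probs <- function(priors, L) {
  p <- priors$inclusion_prob
  if (length(p) == 1L) p <- rep(p, L)
  stopifnot(length(p) == L)
  list(log_p = log(p), log_1mp = log1p(-p))
}

#' Log-posterior of the one-component model (reference implementation)
#'
#' Penalized profile log-likelihood plus the log prior densities: normal on
#' `beta`, gamma on the precision `1/tau2` (omitted under the
#' DerSimonian-Laird plug-in, where `tau2` is not a sampled parameter), and
#' independent Bernoulli terms for the inclusion indicators. Used as the
#' M-H target; the difference at two parameter points is the log acceptance
#' ratio under symmetric proposals.
#'
#' @inheritParams profile_loglik
#' @param priors A [prior_spec()].
#' @param eta Model-size penalty.
#' @param mode `"full_bayes"` or `"dl_plugin"`.
#' @return The scalar unnormalized log posterior density.
#' @export
log_posterior <- function(beta, tau2, I, data, priors = prior_spec(),
                          eta = 0, mode = c("full_bayes", "dl_plugin"),
                          variance_mode = "profile") {
  mode <- match.arg(mode)
  data <- validate_mr_dataset(data)
  lp <- penalized_loglik(beta, tau2, I, data, eta, variance_mode) +
    stats::dnorm(beta, 0, priors$beta_sd, log = TRUE)
  if (mode == "full_bayes") {
    lp <- lp + stats::dgamma(1 / tau2, shape = priors$prec_shape,
                             rate = priors$prec_rate, log = TRUE)
  }
  ip <- incl_log_probs(priors, nrow(data))
  lp + sum(ifelse(I == 1, ip$log_p, ip$log_1mp))
}

#' Log-posterior of the two-component model (reference implementation)
#'
#' As [log_posterior()], for the two-slope model. Each SNP carries one
#' Bernoulli prior term per indicator set; membership of S0 (neither
#' component) contributes the "not included" mass for both sets.
#'
#' @inheritParams two_component_loglik
#' @inheritParams log_posterior
#' @param eta1,eta2 Per-component penalties.
#' @return The scalar unnormalized log posterior density.
#' @export
log_posterior_two <- function(beta1, tau2_1, beta2, tau2_2, I1, I2, data,
                              priors = prior_spec(), eta1 = 0, eta2 = 0,
                              mode = c("full_bayes", "dl_plugin"),
                              variance_mode = "profile") {
  mode <- match.arg(mode)
  data <- validate_mr_dataset(data)
  lp <- penalized_two_component(beta1, tau2_1, beta2, tau2_2, I1, I2, data,
                                eta1, eta2, variance_mode) +
    stats::dnorm(beta1, 0, priors$beta_sd, log = TRUE) +
    stats::dnorm(beta2, 0, priors$beta_sd, log = TRUE)
  if (mode == "full_bayes") {
    lp <- lp +
      stats::dgamma(1 / tau2_1, priors$prec_shape, priors$prec_rate, log = TRUE) +
      stats::dgamma(1 / tau2_2, priors$prec_shape, priors$prec_rate, log = TRUE)
  }
  ip <- incl_log_probs(priors, nrow(data))
  lp + sum(ifelse(I1 == 1, ip$log_p, ip$log_1mp)) +
    sum(ifelse(I2 == 1, ip$log_p, ip$log_1mp))
}

default_init_one <- function(data, config) {
  beta0 <- ivw(data)$beta_hat
  tau20 <- as.numeric(dl_tau2(data))
  if (config$mode == "full_bayes") tau20 <- max(tau20, 1e-4)
  list(beta = beta0, tau2 = tau20, I = rep(1L, nrow(data)))
}

default_init_two <- function(data, config) {
  wr <- wald_ratios(data)
  km <- split_2means(wr$ratio)
  # component 1 starts on the lower-slope cluster
  S0 <- ifelse(wr$ratio <= km$threshold, 1L, 2L)
  if (sum(S0 == 1L) < 2L || sum(S0 == 2L) < 2L) S0 <- rep(1L, nrow(data))
  t1 <- if (sum(S0 == 1L) >= 2) dl_on_subset(data, S0 == 1L) else 0
  t2 <- if (sum(S0 == 2L) >= 2) dl_on_subset(data, S0 == 2L) else 0
  if (config$mode == "full_bayes") { t1 <- max(t1, 1e-4); t2 <- max(t2, 1e-4) }
  list(beta1 = min(km$centers), beta2 = max(km$centers),
       tau2_1 = t1, tau2_2 = t2, S = S0)
}

dl_on_subset <- function(data, keep) {
  as.numeric(dl_tau2(data, as.integer(keep)))
}

run_cpp_one <- function(data, priors, config, init, iterations, burn_in,
                        sd_beta, sd_logprec, update_indicators, use_likelihood) {
  ip <- incl_log_probs(priors, nrow(data))
  cpp_mh_one(data$gamma_hat, data$Gamma_hat, data$se_x, data$se_y,
             as.integer(iterations), as.integer(burn_in),
             config$mode == "dl_plugin", config$variance_mode == "full",
             config$eta, config$min_instruments,
             priors$beta_sd, priors$prec_shape, priors$prec_rate,
             ip$log_p, ip$log_1mp, sd_beta, sd_logprec,
             init$beta, init$tau2, as.integer(init$I),
             update_indicators, use_likelihood)
}

run_cpp_two <- function(data, priors, config, init, iterations, burn_in,
                        sd_beta, sd_logprec, update_indicators, use_likelihood) {
  ip <- incl_log_probs(priors, nrow(data))
  cpp_mh_two(data$gamma_hat, data$Gamma_hat, data$se_x, data$se_y,
             as.integer(iterations), as.integer(burn_in),
             config$mode == "dl_plugin", config$variance_mode == "full",
             config$eta1, config$eta2, config$min_instruments,
             priors$beta_sd, priors$prec_shape, priors$prec_rate,
             ip$log_p, ip$log_1mp, ip$log_p, ip$log_1mp,
             sd_beta, sd_logprec,
             init$beta1, init$beta2, init$tau2_1, init$tau2_2,
             as.integer(init$S), update_indicators, use_likelihood)
}

#' Pilot adaptation of the random-walk proposal scales
#'
#' Runs short pilot batches, rescaling each proposal SD by
#' `exp(2.5 * (acceptance - 0.28))` (clamped to a factor of 4 per batch)
#' after each batch so continuous blocks land in the 20-40% acceptance
#' range. The adapted scales are returned and
#' frozen before the retained sampling phase; a warning is raised if a block
#' still accepts outside [0.05, 0.8].
#'
#' @param data An [mr_dataset()].
#' @param priors A [prior_spec()].
#' @param config An [mh_config()]; `components` selects the model.
#' @param components 1 or 2.
#' @param init Optional initial state (defaults to the data-driven
#'   initialization of the main samplers).
#' @param batch_size,n_batches Pilot design (default 8 batches of 400).
#' @return List with `proposal_sd_beta` and `proposal_sd_logprec`.
#' @export
tune_proposals <- function(data, priors = prior_spec(), config = mh_config(),
                           components = 1, init = NULL,
                           batch_size = 400L, n_batches = 8L) {
  sd_beta <- config$proposal_sd_beta
  sd_logprec <- config$proposal_sd_logprec
  if (is.null(sd_beta)) sd_beta <- 5 * ivw(data)$se + 1e-3
  if (is.null(sd_logprec)) sd_logprec <- 1.0
  if (is.null(init)) {
    init <- if (components == 1) default_init_one(data, config)
            else default_init_two(data, config)
  }
  for (b in seq_len(n_batches)) {
    if (components == 1) {
      out <- run_cpp_one(data, priors, config, init, batch_size, 0L,
                         sd_beta, sd_logprec, TRUE, TRUE)
      acc_beta <- out$accept$beta
      acc_prec <- out$accept$prec
      n <- batch_size
      init$beta <- out$beta[n]; init$tau2 <- out$tau2[n]
      init$I <- out$indicators[n, ]
    } else {
      out <- run_cpp_two(data, priors, config, init, batch_size, 0L,
                         sd_beta, sd_logprec, TRUE, TRUE)
      acc_beta <- mean(c(out$accept$beta1, out$accept$beta2))
      acc_prec <- mean(c(out$accept$prec1, out$accept$prec2))
      n <- batch_size
      init$beta1 <- out$beta1[n]; init$beta2 <- out$beta2[n]
      init$tau2_1 <- out$tau2_1[n]; init$tau2_2 <- out$tau2_2[n]
      init$S <- out$state[n, ]
    }
    sd_beta <- sd_beta * min(4, max(1 / 4, exp(2.5 * (acc_beta - 0.28))))
    if (config$mode == "full_bayes") {
      sd_logprec <- sd_logprec * min(4, max(1 / 4, exp(2.5 * (acc_prec - 0.28))))
    }
  }
  if (acc_beta < 0.05 || acc_beta > 0.8) {
    warning("slope acceptance rate ", signif(acc_beta, 3),
            " outside [0.05, 0.8] after tuning", call. = FALSE)
  }
  if (config$mode == "full_bayes" && (acc_prec < 0.05 || acc_prec > 0.8)) {
    warning("precision acceptance rate ", signif(acc_prec, 3),
            " outside [0.05, 0.8] after tuning", call. = FALSE)
  }
  list(proposal_sd_beta = sd_beta, proposal_sd_logprec = sd_logprec)
}

finalize_chain <- function(pieces, data, priors, config, components) {
  ch <- list(
    components = components,
    mode = config$mode,
    snp_id = data$snp_id,
    config = config, priors = priors,
    accept = pieces$accept,
    chain_id = pieces$chain_id,
    log_post = pieces$log_post
  )
  if (components == 1) {
    ch$beta <- pieces$beta; ch$tau2 <- pieces$tau2
    ch$indicators <- pieces$indicators
    colnames(ch$indicators) <- data$snp_id
  } else {
    ch$beta1 <- pieces$beta1; ch$beta2 <- pieces$beta2
    ch$tau2_1 <- pieces$tau2_1; ch$tau2_2 <- pieces$tau2_2
    ch$state <- pieces$state
    colnames(ch$state) <- data$snp_id
  }
  class(ch) <- "beside_chain"
  # convergence: split R-hat across chains if available, else Geweke z
  pars <- if (components == 1) list(beta = ch$beta)
          else list(beta1 = ch$beta1, beta2 = ch$beta2)
  if (config$n_chains >= 2) {
    rhat <- vapply(pars, function(x) {
      gelman_rubin(split(x, ch$chain_id))
    }, numeric(1))
    ch$rhat <- rhat
    ch$converged <- all(is.finite(rhat)) && all(rhat < 1.1)
  } else {
    z <- vapply(pars, geweke_z, numeric(1))
    ch$geweke_z <- z
    ch$converged <- all(is.finite(z)) && all(abs(z) <= 2.5)
  }
  ch
}

#' One-component model-averaging sampler
#'
#' Random-walk Metropolis-Hastings over `(beta, tau2, I)`. Each iteration
#' updates, in order: (a) `beta` by a normal random walk; (b) `tau2`, either
#' by the DerSimonian-Laird plug-in over the currently included SNPs
#' (`mode = "dl_plugin"`) or by a random walk on the log-precision with a
#' Metropolis correction (`mode = "full_bayes"`); (c) one inclusion
#' indicator chosen uniformly at random, flipped and accepted by
#' Metropolis-Hastings, with moves that would leave fewer than
#' `min_instruments` SNPs rejected outright. Post-burn-in draws are stored;
#' posterior inclusion probabilities follow via [ppi()].
#'
#' @param data An [mr_dataset()] with at least `min_instruments` SNPs.
#' @param priors A [prior_spec()].
#' @param config An [mh_config()].
#' @param tune If `TRUE` (default) and no proposal SDs are fixed in
#'   `config`, a pilot adaptation phase sets them before the retained run.
#' @param init Optional named list `(beta, tau2, I)` overriding the
#'   data-driven initialization (IVW slope, DerSimonian-Laird `tau2`, all
#'   SNPs included).
#' @param update_indicators,use_likelihood Diagnostic hooks: freeze the
#'   indicator vector, or remove the likelihood so the chain targets the
#'   prior.
#' @return A `beside_chain` object with pooled post-burn-in draws (`beta`,
#'   `tau2`, `indicators`), the log-posterior trace, acceptance rates, a
#'   convergence flag (split R-hat over chains, or Geweke z for one chain)
#'   and the configuration echo.
#' @export
mh_one_component <- function(data, priors = prior_spec(), config = mh_config(),
                             tune = TRUE, init = NULL,
                             update_indicators = TRUE, use_likelihood = TRUE) {
  data <- validate_mr_dataset(data)
  if (nrow(data) < config$min_instruments) {
    stop("need at least ", config$min_instruments, " instruments, got ",
         nrow(data), call. = FALSE)
  }
  set.seed(config$seed)
  base_init <- default_init_one(data, config)
  if (!is.null(init)) base_init[names(init)] <- init
  sd_beta <- config$proposal_sd_beta
  sd_logprec <- config$proposal_sd_logprec
  if (tune && (is.null(sd_beta) || is.null(sd_logprec))) {
    tuned <- tune_proposals(data, priors, config, components = 1,
                            init = base_init)
    if (is.null(sd_beta)) sd_beta <- tuned$proposal_sd_beta
    if (is.null(sd_logprec)) sd_logprec <- tuned$proposal_sd_logprec
  }
  if (is.null(sd_beta)) sd_beta <- 5 * ivw(data)$se + 1e-3
  if (is.null(sd_logprec)) sd_logprec <- 1.0

  pieces <- list(beta = numeric(0), tau2 = numeric(0),
                 indicators = NULL, log_post = numeric(0),
                 chain_id = integer(0), accept = NULL)
  for (ic in seq_len(config$n_chains)) {
    ci <- base_init
    if (ic > 1) ci$beta <- ci$beta + stats::rnorm(1, 0, 2 * sd_beta + 0.05)
    out <- run_cpp_one(data, priors, config, ci, config$iterations,
                       config$burn_in, sd_beta, sd_logprec,
                       update_indicators, use_likelihood)
    pieces$beta <- c(pieces$beta, out$beta)
    pieces$tau2 <- c(pieces$tau2, out$tau2)
    pieces$indicators <- rbind(pieces$indicators, out$indicators)
    pieces$log_post <- c(pieces$log_post, out$log_post)
    pieces$chain_id <- c(pieces$chain_id, rep(ic, length(out$beta)))
    pieces$accept <- out$accept
  }
  ch <- finalize_chain(pieces, data, priors, config, components = 1)
  ch$proposal_sd <- list(beta = sd_beta, logprec = sd_logprec)
  ch
}

#' Two-component model-averaging sampler
#'
#' As [mh_one_component()], with blocks for `(beta1, beta2)` and the two
#' pleiotropy variances, and an indicator move that picks one SNP uniformly
#' and proposes a uniformly chosen different state among S0 (excluded), S1
#' (component 1) and S2 (component 2), so `I1_j + I2_j <= 1` holds at every
#' draw. The minimum-instrument rule applies to the total number of included
#' SNPs; a component is allowed to empty, in which case its slope is
#' effectively sampled from the prior. Component 1 is initialized on the
#' lower-slope cluster of the Wald ratios. Under label switching, relabel
#' with [kmeans_relabel()] before summarizing.
#'
#' @inheritParams mh_one_component
#' @param init Optional named list `(beta1, beta2, tau2_1, tau2_2, S)` with
#'   `S` a per-SNP state vector in `{0, 1, 2}`.
#' @return A `beside_chain` with draws `beta1`, `beta2`, `tau2_1`, `tau2_2`
#'   and the per-iteration state matrix.
#' @export
mh_two_component <- function(data, priors = prior_spec(), config = mh_config(),
                             tune = TRUE, init = NULL,
                             update_indicators = TRUE, use_likelihood = TRUE) {
  data <- validate_mr_dataset(data)
  if (nrow(data) < config$min_instruments) {
    stop("need at least ", config$min_instruments, " instruments, got ",
         nrow(data), call. = FALSE)
  }
  set.seed(config$seed)
  base_init <- default_init_two(data, config)
  if (!is.null(init)) base_init[names(init)] <- init
  sd_beta <- config$proposal_sd_beta
  sd_logprec <- config$proposal_sd_logprec
  if (tune && (is.null(sd_beta) || is.null(sd_logprec))) {
    tuned <- tune_proposals(data, priors, config, components = 2,
                            init = base_init)
    if (is.null(sd_beta)) sd_beta <- tuned$proposal_sd_beta
    if (is.null(sd_logprec)) sd_logprec <- tuned$proposal_sd_logprec
  }
  if (is.null(sd_beta)) sd_beta <- 5 * ivw(data)$se + 1e-3
  if (is.null(sd_logprec)) sd_logprec <- 1.0

  pieces <- list(beta1 = numeric(0), beta2 = numeric(0),
                 tau2_1 = numeric(0), tau2_2 = numeric(0),
                 state = NULL, log_post = numeric(0),
                 chain_id = integer(0), accept = NULL)
  for (ic in seq_len(config$n_chains)) {
    ci <- base_init
    if (ic > 1) {
      ci$beta1 <- ci$beta1 + stats::rnorm(1, 0, 2 * sd_beta + 0.05)
      ci$beta2 <- ci$beta2 + stats::rnorm(1, 0, 2 * sd_beta + 0.05)
    }
    out <- run_cpp_two(data, priors, config, ci, config$iterations,
                       config$burn_in, sd_beta, sd_logprec,
                       update_indicators, use_likelihood)
    pieces$beta1 <- c(pieces$beta1, out$beta1)
    pieces$beta2 <- c(pieces$beta2, out$beta2)
    pieces$tau2_1 <- c(pieces$tau2_1, out$tau2_1)
    pieces$tau2_2 <- c(pieces$tau2_2, out$tau2_2)
    pieces$state <- rbind(pieces$state, out$state)
    pieces$log_post <- c(pieces$log_post, out$log_post)
    pieces$chain_id <- c(pieces$chain_id, rep(ic, length(out$beta1)))
    pieces$accept <- out$accept
  }
  ch <- finalize_chain(pieces, data, priors, config, components = 2)
  ch$proposal_sd <- list(beta = sd_beta, logprec = sd_logprec)
  ch
}

#' @export
print.beside_chain <- function(x, ...) {
  cat("BESIDE-MR chain (", x$components, "-component, ", x$mode, ")\n", sep = "")
  n <- if (x$components == 1) length(x$beta) else length(x$beta1)
  cat("  retained draws:", n, "over", max(x$chain_id), "chain(s)\n")
  cat("  converged:", x$converged, "\n")
  invisible(x)
}

#' Export a chain's draws to a CSV trace file and a JSON summary
#'
#' @param chain A `beside_chain`.
#' @param trace_path Optional CSV path for the per-iteration draws
#'   (parameters plus indicator columns).
#' @param summary_path Optional JSON path for the posterior summary
#'   ([summarize_chain()] plus acceptance rates and convergence flag).
#' @return Invisibly, the summary list.
#' @export
export_chain <- function(chain, trace_path = NULL, summary_path = NULL) {
  if (!is.null(trace_path)) {
    if (chain$components == 1) {
      df <- data.frame(chain = chain$chain_id, beta = chain$beta,
                       tau2 = chain$tau2, check.names = FALSE)
      df <- cbind(df, as.data.frame(chain$indicators))
    } else {
      df <- data.frame(chain = chain$chain_id, beta1 = chain$beta1,
                       beta2 = chain$beta2, tau2_1 = chain$tau2_1,
                       tau2_2 = chain$tau2_2, check.names = FALSE)
      df <- cbind(df, as.data.frame(chain$state))
    }
    utils::write.csv(df, trace_path, row.names = FALSE)
  }
  s <- summarize_chain(chain)
  if (!is.null(summary_path)) {
    jsonlite::write_json(
      list(parameters = s$parameters, ppi = s$ppi, accept = chain$accept,
           converged = chain$converged),
      summary_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(s)
}
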