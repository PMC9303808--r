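# Posterior summaries, inclusion probabilities, label-switching correction
# and convergence diagnostics.

#' Posterior probability of inclusion
#'
#' Fraction of retained draws in which each SNP is included in the valid
#' set (one-component chains) or in each component (two-component chains).
#'
#' @param chain A `beside_chain` from [mh_one_component()] or
#'   [mh_two_component()].
#' @return One-component: a named numeric vector of PPIs. Two-component: a
#'   list with `ppi_s1`, `ppi_s2` and `ppi_s0` (per-SNP probabilities of
#'   each state).
#' @export
ppi <- function(chain) {
  stopifnot(inherits(chain, "beside_chain"))
  if (chain$components == 1) {
    if (is.null(chain$indicators) || nrow(chain$indicators) == 0) {
      stop("empty chain: no retained draws", call. = FALSE)
    }
    colMeans(chain$indicators)
  } else {
    if (is.null(chain$state) || nrow(chain$state) == 0) {
      stop("empty chain: no retained draws", call. = FALSE)
    }
    list(ppi_s1 = colMeans(chain$state == 1L),
         ppi_s2 = colMeans(chain$state == 2L),
         ppi_s0 = colMeans(chain$state == 0L))
  }
}

# Exact 1-D 2-means on a scalar sample: the optimal 2-partition of sorted
# values is a threshold split, found by scanning all n-1 split points with
# prefix sums. Deterministic; no restarts needed.
split_2means <- function(x) {
  n <- length(x)
  stopifnot(n >= 2)
  xs <- sort(x)
  cs <- cumsum(xs)
  cs2 <- cumsum(xs^2)
  k <- seq_len(n - 1L)
  ss_left <- cs2[k] - cs[k]^2 / k
  ss_right <- (cs2[n] - cs2[k]) - (cs[n] - cs[k])^2 / (n - k)
  kbest <- which.min(ss_left + ss_right)
  thr <- (xs[kbest] + xs[kbest + 1L]) / 2
  centers <- c(cs[kbest] / kbest, (cs[n] - cs[kbest]) / (n - kbest))
  list(centers = centers, threshold = thr,
       sizes = c(kbest, n - kbest))
}

#' Correct label switching in a two-component chain by K-means
#'
#' Pools the `beta1` and `beta2` draws into one scalar sample, fits an
#' exact two-means clustering (in one dimension the optimal partition is a
#' threshold split, computed deterministically), and relabels each
#' iteration so that the draw nearer to the center of component 1 becomes
#' the relabeled `beta1`. Component 1 is taken to be the cluster containing
#' the majority of the pre-relabeling `beta1` draws, which makes the
#' operation the identity on chains that never switched. The pleiotropy
#' variance and indicator labels swap in tandem with their slope. Ties
#' (equidistant draws) keep the original labels.
#'
#' @param chain A two-component `beside_chain`.
#' @return The relabeled chain, with an added `relabel` element recording
#'   the cluster centers, the cluster sizes (summing to twice the number of
#'   retained iterations) and the number of swapped iterations.
#' @export
kmeans_relabel <- function(chain) {
  stopifnot(inherits(chain, "beside_chain"), chain$components == 2)
  b1 <- chain$beta1
  b2 <- chain$beta2
  km <- split_2means(c(b1, b2))
  in_low_1 <- b1 <= km$threshold
  # cluster holding the majority of original beta1 draws defines component 1
  low_is_1 <- mean(in_low_1) >= 0.5
  c1 <- if (low_is_1) min(km$centers) else max(km$centers)
  c2 <- if (low_is_1) max(km$centers) else min(km$centers)
  d_keep <- abs(b1 - c1) + abs(b2 - c2)
  d_swap <- abs(b1 - c2) + abs(b2 - c1)
  swap <- d_swap < d_keep # ties keep original labels
  out <- chain
  out$beta1 <- ifelse(swap, b2, b1)
  out$beta2 <- ifelse(swap, b1, b2)
  out$tau2_1 <- ifelse(swap, chain$tau2_2, chain$tau2_1)
  out$tau2_2 <- ifelse(swap, chain$tau2_1, chain$tau2_2)
  if (any(swap)) {
    st <- chain$state
    sw <- which(swap)
    s_sub <- st[sw, , drop = FALSE]
    s_new <- s_sub
    s_new[s_sub == 1L] <- 2L
    s_new[s_sub == 2L] <- 1L
    st[sw, ] <- s_new
    out$state <- st
  }
  sizes <- if (low_is_1) km$sizes else rev(km$sizes)
  out$relabel <- list(centers = c(c1, c2), sizes = sizes,
                      n_swapped = sum(swap))
  out
}

quantile_ci <- function(x) {
  stats::quantile(x, c(0.025, 0.5, 0.975), names = FALSE, type = 7)
}

#' Summarize a chain's posterior draws
#'
#' Mean, median and equal-tailed 95% credible interval (2.5%/97.5%
#' quantiles) for each parameter, per-SNP posterior inclusion
#' probabilities, effective sample sizes and (for multi-chain runs) split
#' R-hat.
#'
#' @param chain A `beside_chain`.
#' @return A `beside_summary` list with elements `parameters` (data frame),
#'   `ppi`, `ess`, `rhat` (or `geweke_z`), `converged`.
#' @export
summarize_chain <- function(chain) {
  stopifnot(inherits(chain, "beside_chain"))
  pars <- if (chain$components == 1) {
    list(beta = chain$beta, tau2 = chain$tau2)
  } else {
    list(beta1 = chain$beta1, beta2 = chain$beta2,
         tau2_1 = chain$tau2_1, tau2_2 = chain$tau2_2)
  }
  tab <- do.call(rbind, lapply(names(pars), function(nm) {
    x <- pars[[nm]]
    q <- quantile_ci(x)
    data.frame(parameter = nm, mean = mean(x), median = q[2L],
               ci_low = q[1L], ci_high = q[3L],
               stringsAsFactors = FALSE)
  }))
  rownames(tab) <- NULL
  structure(list(
    parameters = tab,
    ppi = ppi(chain),
    ess = vapply(pars, ess, numeric(1)),
    rhat = chain$rhat,
    geweke_z = chain$geweke_z,
    converged = chain$converged
  ), class = "beside_summary")
}

#' @export
print.beside_summary <- function(x, ...) {
  cat("Posterior summary:\n")
  print(x$parameters, row.names = FALSE, digits = 4)
  cat("converged:", x$converged, "\n")
  invisible(x)
}

# spectral density of x at frequency zero, via an AR fit (used by the
# Geweke diagnostic and the effective sample size)
spectrum0_ar <- function(x) {
  v <- stats::var(x)
  if (!is.finite(v) || v == 0) return(0)
  fit <- tryCatch(
    stats::ar(x, aic = TRUE, order.max = min(30L, floor(length(x) / 20))),
    error = function(e) NULL)
  if (is.null(fit) || length(fit$ar) == 0) return(v)
  fit$var.pred / (1 - sum(fit$ar))^2
}

#' Geweke convergence z-score
#'
#' Compares the mean of the first `frac1` of a trace with the mean of the
#' last `frac2`, standardized by AR-spectral estimates of the asymptotic
#' variance of each segment mean. |z| > 2.5 flags non-convergence.
#'
#' @param x Numeric trace.
#' @param frac1,frac2 Fractions of the trace to compare (defaults 0.1, 0.5).
#' @return The z statistic.
#' @export
geweke_z <- function(x, frac1 = 0.1, frac2 = 0.5) {
  n <- length(x)
  a <- x[seq_len(max(2L, floor(frac1 * n)))]
  b <- x[seq.int(n - max(2L, floor(frac2 * n)) + 1L, n)]
  va <- spectrum0_ar(a) / length(a)
  vb <- spectrum0_ar(b) / length(b)
  if (va + vb == 0) return(0)
  (mean(a) - mean(b)) / sqrt(va + vb)
}

#' Effective sample size of a trace
#'
#' `n * var(x) / spectral density at zero`, with the spectral density
#' estimated from an AR fit.
#'
#' @param x Numeric trace.
#' @return Estimated effective sample size.
#' @export
ess <- function(x) {
  s0 <- spectrum0_ar(x)
  if (s0 == 0) return(length(x))
  min(length(x), length(x) * stats::var(x) / s0)
}

#' Split R-hat (Gelman-Rubin) statistic
#'
#' Standard split potential-scale-reduction factor: each chain is split in
#' half, and R-hat is computed from the within- and between-half variances.
#' Values near 1 indicate the chains agree; > 1.1 conventionally flags
#' non-convergence.
#'
#' @param chains A list of numeric vectors (one trace per chain), or a list
#'   of `beside_chain` objects together with `parameter`.
#' @param parameter Name of the draw vector to extract when `chains` holds
#'   `beside_chain` objects (e.g. `"beta"`).
#' @return The R-hat value.
#' @export
gelman_rubin <- function(chains, parameter = NULL) {
  if (length(chains) > 0 && inherits(chains[[1L]], "beside_chain")) {
    stopifnot(!is.null(parameter))
    chains <- lapply(chains, function(ch) ch[[parameter]])
  }
  halves <- list()
  for (x in chains) {
    n2 <- floor(length(x) / 2)
    halves <- c(halves, list(x[seq_len(n2)], x[seq.int(n2 + 1L, 2L * n2)]))
  }
  m <- length(halves)
  n <- length(halves[[1L]])
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, stats::var, numeric(1))
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W == 0) return(if (B == 0) 1 else Inf)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Scatter plot of summary data colored by inclusion probability
#'
#' Plots the SNP-outcome against SNP-exposure associations, highlighting
#' SNPs whose posterior inclusion probability exceeds `threshold` (filled
#' points), in the style commonly used to display model-averaging results.
#' Requires ggplot2.
#'
#' @param data An [mr_dataset()].
#' @param chain A `beside_chain` fitted to `data`.
#' @param threshold PPI highlight threshold (default 0.75).
#' @return A ggplot object.
#' @export
plot_ppi <- function(data, chain, threshold = 0.75) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_ppi requires the ggplot2 package", call. = FALSE)
  }
  p <- ppi(chain)
  df <- as.data.frame(data)
  if (chain$components == 1) {
    df$group <- ifelse(p > threshold, "included", "uncertain")
  } else {
    df$group <- ifelse(p$ppi_s1 > threshold, "S1",
                       ifelse(p$ppi_s2 > threshold, "S2", "uncertain"))
  }
  ggplot2::ggplot(df, ggplot2::aes(x = gamma_hat, y = Gamma_hat,
                                   shape = group, color = group)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = Gamma_hat - 1.96 * se_y,
                                        ymax = Gamma_hat + 1.96 * se_y),
                           linewidth = 0.3, alpha = 0.5) +
    ggplot2::labs(x = "SNP-exposure association",
                  y = "SNP-outcome association", shape = NULL, color = NULL) +
    ggplot2::theme_minimal()
}
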