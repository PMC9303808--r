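# Classical two-sample summary MR estimators used as benchmarks.

estimate_result <- function(beta_hat, se, method, tau2_hat = NA_real_) {
  z <- stats::qnorm(0.975)
  structure(
    list(beta_hat = beta_hat, se = se,
         ci_low = beta_hat - z * se, ci_high = beta_hat + z * se,
         tau2_hat = tau2_hat, method = method),
    class = "mr_estimate"
  )
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("%s: beta_hat = %.4f (se %.4f), 95%% CI [%.4f, %.4f]\n",
              x$method, x$beta_hat, x$se, x$ci_low, x$ci_high))
  if (!is.na(x$tau2_hat)) cat(sprintf("  tau2_hat = %.6g\n", x$tau2_hat))
  invisible(x)
}

#' Inverse-variance weighted estimator
#'
#' Fixed-effect meta-analysis of the per-SNP Wald ratios with first-order
#' weights `w_j = gamma_hat_j^2 / se_y_j^2`, equivalently the weighted
#' regression slope `sum(gamma_hat * Gamma_hat / se_y^2) /
#' sum(gamma_hat^2 / se_y^2)`. The standard error is `sum(w)^(-1/2)` with no
#' overdispersion scaling, i.e. the naive IVW whose weak-instrument and
#' pleiotropy failure modes the model-averaging approach addresses.
#'
#' @param data An [mr_dataset()]; all `gamma_hat` must be nonzero.
#' @return An `mr_estimate` with point estimate, SE and 95% Wald interval.
#' @examples
#' d <- mr_dataset(c("a", "b"), c(1, 2), c(0.1, 0.1), c(1, 4), c(1, 1))
#' ivw(d)$beta_hat  # 1.8
#' @export
ivw <- function(data) {
  wr <- wald_ratios(data)
  w <- 1 / wr$se^2
  beta_hat <- sum(w * wr$ratio) / sum(w)
  estimate_result(beta_hat, sqrt(1 / sum(w)), method = "IVW")
}

#' Adjusted profile score estimator (L2 loss)
#'
#' Jointly maximizes the profile log-likelihood [profile_loglik()] in
#' `(beta, tau2)` with every SNP included and `tau2` constrained to be
#' non-negative. The standard error comes from the observed information of
#' the profile log-likelihood in `beta` at the optimum (with `tau2` held at
#' its estimate); intervals are 95% Wald. This is the robust adjusted
#' profile score estimator with a standard squared-error loss.
#'
#' @param data An [mr_dataset()] with at least 2 SNPs.
#' @param variance_mode Passed to [profile_loglik()].
#' @return An `mr_estimate` including `tau2_hat`.
#' @export
mr_aps <- function(data, variance_mode = "profile") {
  variance_mode <- check_variance_mode(variance_mode)
  data <- validate_mr_dataset(data)
  if (nrow(data) < 2L) stop("mr_aps requires at least 2 SNPs", call. = FALSE)
  I <- rep(1L, nrow(data))
  negll <- function(par) {
    -profile_loglik(par[1L], par[2L], I, data, variance_mode)
  }
  starts <- list(c(ivw(data)$beta_hat, as.numeric(dl_tau2(data))),
                 c(0, 0))
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      stats::optim(s, negll, method = "L-BFGS-B",
                   lower = c(-Inf, 0), upper = c(Inf, Inf),
                   control = list(factr = 1e5, maxit = 500)),
      error = function(e) NULL)
    if (is.null(fit) || fit$convergence != 0) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) {
    # fall back to Nelder-Mead on (beta, sqrt(tau2)), which enforces the
    # boundary smoothly when L-BFGS-B stalls in its line search
    negll_s <- function(par) negll(c(par[1L], par[2L]^2))
    for (s in starts) {
      fit <- tryCatch(
        stats::optim(c(s[1L], sqrt(s[2L])), negll_s, method = "Nelder-Mead",
                     control = list(maxit = 2000, reltol = 1e-12)),
        error = function(e) NULL)
      if (is.null(fit) || fit$convergence != 0) next
      fit$par <- c(fit$par[1L], fit$par[2L]^2)
      if (is.null(best) || fit$value < best$value) best <- fit
    }
  }
  if (is.null(best)) {
    stop("mr_aps optimizer failed to converge", call. = FALSE)
  }
  beta_hat <- best$par[1L]
  tau2_hat <- best$par[2L]
  # observed information in beta by central second difference
  h <- 1e-5 * max(1, abs(beta_hat))
  ll <- function(b) profile_loglik(b, tau2_hat, I, data, variance_mode)
  info <- -(ll(beta_hat + h) - 2 * ll(beta_hat) + ll(beta_hat - h)) / h^2
  if (!is.finite(info) || info <= 0) {
    stop("mr_aps: non-positive observed information at the optimum",
         call. = FALSE)
  }
  estimate_result(beta_hat, sqrt(1 / info), method = "MR-APS",
                  tau2_hat = tau2_hat)
}

# Huber / Tukey score functions and their standard-normal moments
robust_psi <- function(loss, tuning) {
  if (loss == "huber") {
    c_ <- tuning
    list(
      psi = function(t) pmin(pmax(t, -c_), c_),
      dpsi = function(t) as.numeric(abs(t) < c_),
      # E[psi'(Z)] and E[psi(Z)^2] for Z ~ N(0,1)
      c1 = 2 * stats::pnorm(c_) - 1,
      c2 = (2 * stats::pnorm(c_) - 1) - 2 * c_ * stats::dnorm(c_) +
        2 * c_^2 * (1 - stats::pnorm(c_))
    )
  } else { # tukey biweight
    c_ <- tuning
    psi <- function(t) ifelse(abs(t) < c_, t * (1 - (t / c_)^2)^2, 0)
    dpsi <- function(t) ifelse(abs(t) < c_,
                               (1 - (t / c_)^2) * (1 - 5 * (t / c_)^2), 0)
    gl <- function(f) { # Gauss-Legendre-free: fine trapezoid on [-c, c]
      x <- seq(-c_, c_, length.out = 4001L)
      sum(f(x) * stats::dnorm(x)) * (x[2L] - x[1L])
    }
    list(psi = psi, dpsi = dpsi,
         c1 = gl(dpsi), c2 = gl(function(t) psi(t)^2))
  }
}

#' Robust adjusted profile score estimator (MR-RAPS)
#'
#' Solves the robustified profile-score equations. With standardized
#' residuals
#' \eqn{t_j(\beta,\tau^2) = (\hat\Gamma_j - \beta\hat\gamma_j) /
#' \sqrt{\beta^2\sigma_{Xj}^2 + \sigma_{Yj}^2 + \tau^2}},
#' `beta` solves \eqn{\sum_j \psi(t_j)\, \partial t_j/\partial\beta = 0}
#' with \eqn{\psi} the derivative of the Huber or Tukey loss, and `tau2`
#' solves the consistency-corrected moment condition
#' \eqn{\mathrm{mean}_j\, \psi(t_j)^2 = E[\psi(Z)^2]}, \eqn{Z\sim N(0,1)}.
#' The bounded score caps the contribution of outlying (likely pleiotropic)
#' SNPs. The standard error is the asymptotic M-estimation sandwich
#' \eqn{\sqrt{E[\psi^2] / (E[\psi']^2 \sum_j (\partial t_j/\partial\beta)^2)}}
#' with standard-normal moments.
#'
#' @param data An [mr_dataset()] with at least 2 SNPs.
#' @param loss `"huber"` (default) or `"tukey"`.
#' @param tuning Loss tuning constant; defaults to 1.345 for Huber and
#'   4.685 for Tukey (95% Gaussian efficiency).
#' @param variance_mode Kept for interface symmetry; the residual variance
#'   is always the full `beta^2 se_x^2 + se_y^2 + tau2`.
#' @return An `mr_estimate` including `tau2_hat`.
#' @export
mr_raps <- function(data, loss = c("huber", "tukey"), tuning = NULL,
                    variance_mode = "profile") {
  loss <- match.arg(loss)
  data <- validate_mr_dataset(data)
  if (nrow(data) < 2L) stop("mr_raps requires at least 2 SNPs", call. = FALSE)
  if (is.null(tuning)) tuning <- if (loss == "huber") 1.345 else 4.685
  rp <- robust_psi(loss, tuning)
  L <- nrow(data)

  tfun <- function(beta, tau2) {
    v <- beta^2 * data$se_x^2 + data$se_y^2 + tau2
    list(t = (data$Gamma_hat - beta * data$gamma_hat) / sqrt(v), v = v)
  }
  dt_dbeta <- function(beta, tau2) {
    s <- tfun(beta, tau2)
    (-data$gamma_hat - s$t * beta * data$se_x^2 / sqrt(s$v)) / sqrt(s$v)
  }
  score_beta <- function(beta, tau2) {
    s <- tfun(beta, tau2)
    sum(rp$psi(s$t) * dt_dbeta(beta, tau2))
  }
  moment_tau <- function(beta, tau2) {
    mean(rp$psi(tfun(beta, tau2)$t)^2) - rp$c2
  }

  start <- ivw(data)
  beta <- start$beta_hat
  tau2 <- 0
  for (iter in 1:200) {
    beta_old <- beta; tau2_old <- tau2
    # beta given tau2: root of the robust score. The score decays to zero
    # for |beta| far from the data, so bracket by expanding outward from
    # the current estimate until a sign change is found.
    g <- function(b) score_beta(b, tau2)
    h <- 10 * start$se + 1e-6
    found <- FALSE
    for (e in 1:30) {
      lo <- beta - h; hi <- beta + h
      if (g(lo) * g(hi) <= 0) { found <- TRUE; break }
      h <- 2 * h
    }
    if (found) {
      beta <- stats::uniroot(g, lower = lo, upper = hi, tol = 1e-12)$root
    } else {
      # no sign change: settle for the least-|score| point near the start
      beta <- stats::optimize(function(b) g(b)^2,
                              lower = beta - 10 * start$se - 1,
                              upper = beta + 10 * start$se + 1,
                              tol = 1e-12)$minimum
    }
    # tau2 given beta: moment condition is decreasing in tau2
    h0 <- moment_tau(beta, 0)
    if (h0 <= 0) {
      tau2 <- 0
    } else {
      up <- 1
      while (moment_tau(beta, up) > 0 && up < 1e6) up <- up * 4
      tau2 <- stats::uniroot(function(x) moment_tau(beta, x),
                             lower = 0, upper = up, tol = 1e-14)$root
    }
    if (abs(beta - beta_old) < 1e-9 * max(1, abs(beta)) &&
        abs(tau2 - tau2_old) < 1e-10 * max(1e-4, tau2)) break
  }
  if (iter == 200) stop("mr_raps did not converge in 200 iterations",
                        call. = FALSE)
  d <- dt_dbeta(beta, tau2)
  se <- sqrt(rp$c2 / (rp$c1^2 * sum(d^2)))
  estimate_result(beta, se, method = paste0("MR-RAPS (", loss, ")"),
                  tau2_hat = tau2)
}
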