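# Generalized Pareto distribution: density, distribution, quantile and random
# generation, three classical parameter estimators (PWM, ML, MOM) and the
# Anderson-Darling goodness-of-fit test used to gate tail-based P-value
# estimation.
#
# Parameterization (peaks-over-threshold form, support starting at 0):
#   F(z) = 1 - (1 + shape * z / scale)^(-1/shape)      shape != 0
#   F(z) = 1 - exp(-z / scale)                         shape == 0
# shape > 0 gives a heavy (Pareto-like) tail, shape == 0 the exponential,
# shape < 0 a bounded tail with support [0, -scale/shape]. This is Hosking's
# parameterization with k = -shape.

check_gpd_args <- function(shape, scale) {
  if (!is.numeric(shape) || length(shape) != 1L || !is.finite(shape)) {
    pt_error("'shape' must be a finite numeric scalar", "permtail_parameter_error")
  }
  if (!is.numeric(scale) || length(scale) != 1L || !is.finite(scale) || scale <= 0) {
    pt_error("'scale' must be a positive finite numeric scalar",
             "permtail_parameter_error")
  }
  invisible(TRUE)
}

#' The generalized Pareto distribution
#'
#' Density, distribution function, quantile function and random generation
#' for the generalized Pareto distribution (GPD) with support starting at
#' zero, \eqn{F(z) = 1 - (1 + \xi z/\sigma)^{-1/\xi}} (\eqn{\xi \ne 0}) and
#' \eqn{F(z) = 1 - e^{-z/\sigma}} (\eqn{\xi = 0}), where \eqn{\xi} is the
#' shape and \eqn{\sigma > 0} the scale. For \eqn{\xi < 0} the support is
#' \eqn{[0, -\sigma/\xi]} and the distribution function is 1 beyond the
#' upper endpoint.
#'
#' @param x,q Vector of quantiles (nonnegative).
#' @param p Vector of probabilities.
#' @param n Number of draws.
#' @param shape Shape parameter \eqn{\xi} (dimensionless).
#' @param scale Scale parameter \eqn{\sigma > 0}, in the units of the data.
#' @param log,log.p Logical; if `TRUE`, probabilities/densities are returned
#'   on the log scale.
#' @param lower.tail Logical; if `TRUE` (default) probabilities are
#'   \eqn{P(X \le x)}, otherwise the survival probability \eqn{P(X > x)}.
#' @return `dgpd` gives the density, `pgpd` the distribution function,
#'   `qgpd` the quantile function and `rgpd` random deviates.
#' @examples
#' pgpd(log(2), shape = 0, scale = 1)   # 0.5, exponential special case
#' pgpd(2, shape = 0.5, scale = 1)      # 1 - (1 + 1)^(-2) = 0.75
#' qgpd(0.5, shape = 0, scale = 2)      # 2 * log(2)
#' @export
pgpd <- function(q, shape = 0, scale = 1, lower.tail = TRUE, log.p = FALSE) {
  check_gpd_args(shape, scale)
  z <- pmax(q, 0) / scale
  if (shape == 0) {
    logS <- -z
  } else {
    w <- shape * z
    logS <- rep(-Inf, length(w))
    ok <- 1 + w > 0
    logS[ok] <- -log1p(w[ok]) / shape
  }
  if (lower.tail) {
    if (log.p) log(-expm1(logS)) else -expm1(logS)
  } else {
    if (log.p) logS else exp(logS)
  }
}

#' @rdname pgpd
#' @export
dgpd <- function(x, shape = 0, scale = 1, log = FALSE) {
  check_gpd_args(shape, scale)
  z <- x / scale
  logf <- rep(-Inf, length(z))
  if (shape == 0) {
    ok <- z >= 0
    logf[ok] <- -log(scale) - z[ok]
  } else {
    w <- 1 + shape * z
    ok <- z >= 0 & w > 0
    logf[ok] <- -log(scale) - (1 + 1 / shape) * log(w[ok])
  }
  if (log) logf else exp(logf)
}

#' @rdname pgpd
#' @export
qgpd <- function(p, shape = 0, scale = 1, lower.tail = TRUE) {
  check_gpd_args(shape, scale)
  if (any(!is.finite(p)) ||
      (lower.tail && any(p < 0 | p >= 1)) ||
      (!lower.tail && any(p <= 0 | p > 1))) {
    pt_error("probabilities must lie in [0, 1) (survival: (0, 1])",
             "permtail_domain_error")
  }
  s <- if (lower.tail) 1 - p else p   # survival probability
  if (shape == 0) {
    -scale * log(s)
  } else {
    scale * expm1(-shape * log(s)) / shape
  }
}

#' @rdname pgpd
#' @export
rgpd <- function(n, shape = 0, scale = 1) {
  check_gpd_args(shape, scale)
  qgpd(stats::runif(n), shape = shape, scale = scale)
}

#' Construct a GPD parameter object
#'
#' @param shape,scale GPD shape and scale.
#' @param method Label of the estimator that produced the parameters
#'   (`"pwm"`, `"ml"`, `"mom"`), or `"fixed"` for hand-set parameters.
#' @return An object of class `gpd_params`.
#' @export
gpd_params <- function(shape, scale, method = "fixed") {
  check_gpd_args(shape, scale)
  structure(list(shape = shape, scale = scale, method = method),
            class = "gpd_params")
}

#' @export
print.gpd_params <- function(x, ...) {
  cat(sprintf("GPD parameters (%s): shape = %.4f, scale = %.4f\n",
              x$method, x$shape, x$scale))
  invisible(x)
}

#' Log-likelihood of a GPD sample
#'
#' @param x Positive sample values.
#' @param params A [gpd_params] object.
#' @return The log-likelihood (may be `-Inf` if any point falls outside the
#'   support implied by `params`).
#' @export
gpd_loglik <- function(x, params) {
  sum(dgpd(x, params$shape, params$scale, log = TRUE))
}

check_fit_sample <- function(x) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    pt_error("exceedances must be finite numeric values", "permtail_fit_error")
  }
  if (length(x) < 10L) {
    pt_error("at least 10 exceedances are required to fit the tail",
             "permtail_fit_error")
  }
  if (any(x <= 0)) {
    pt_error("exceedances must be strictly positive (threshold-shifted)",
             "permtail_fit_error")
  }
  if (stats::sd(x) == 0) {
    pt_error("degenerate sample: all exceedances are equal",
             "permtail_fit_error")
  }
  invisible(TRUE)
}

#' Fit a generalized Pareto distribution to threshold exceedances
#'
#' Estimates the shape and scale of a GPD from a sample of positive
#' exceedances using one of three classical estimators:
#'
#' * `"pwm"` — probability weighted moments (Hosking & Wallis 1987):
#'   with ascending order statistics \eqn{x_{(i)}}, plotting positions
#'   \eqn{p_i = (i - 0.375)/(n + 0.25)}, \eqn{b_0} the sample mean and
#'   \eqn{b_1 = \sum_i (1 - p_i) x_{(i)} / n}, the estimates are
#'   \eqn{\hat\xi = 2 - b_0 / (b_0 - 2 b_1)} and
#'   \eqn{\hat\sigma = 2 b_0 b_1 / (b_0 - 2 b_1)}.
#' * `"ml"` — numerical maximum likelihood over (shape, log scale) with the
#'   support constraint \eqn{1 + \xi x_i/\sigma > 0}, started from the PWM
#'   estimate (with deterministic restarts on failure), so the attained
#'   likelihood is never below the PWM starting value.
#' * `"mom"` — method of moments: with sample mean \eqn{m} and variance
#'   \eqn{s^2}, \eqn{\hat\xi = (1 - m^2/s^2)/2} and
#'   \eqn{\hat\sigma = m (1 + m^2/s^2)/2}; valid when the fitted shape is
#'   below 1/2 (finite variance).
#'
#' @param x Positive exceedances (length at least 10, nondegenerate).
#' @param method One of `"pwm"` (default), `"ml"`, `"mom"`.
#' @return A [gpd_params] object with additional fields `loglik` and `n`.
#' @examples
#' set.seed(1)
#' z <- rgpd(5000, shape = 0.2, scale = 1)
#' fit_gpd(z, "pwm")
#' @export
fit_gpd <- function(x, method = c("pwm", "ml", "mom")) {
  method <- match.arg(tolower(method[1L]), c("pwm", "ml", "mom"))
  check_fit_sample(x)
  fit <- switch(method,
                pwm = fit_gpd_pwm(x),
                ml  = fit_gpd_ml(x),
                mom = fit_gpd_mom(x))
  fit$loglik <- gpd_loglik(x, fit)
  fit$n <- length(x)
  fit
}

fit_gpd_pwm <- function(x) {
  n <- length(x)
  xs <- sort(x)
  p <- (seq_len(n) - 0.375) / (n + 0.25)
  b0 <- mean(xs)
  b1 <- sum((1 - p) * xs) / n
  d <- b0 - 2 * b1
  if (d <= 0) {
    pt_error("PWM estimate undefined for this sample (b0 - 2*b1 <= 0)",
             "permtail_fit_error")
  }
  shape <- 2 - b0 / d            # xi = -k, k = b0/(b0 - 2 b1) - 2
  scale <- 2 * b0 * b1 / d
  if (!is.finite(shape) || !is.finite(scale) || scale <= 0) {
    pt_error("PWM estimation failed: non-finite or nonpositive scale",
             "permtail_fit_error")
  }
  gpd_params(shape, scale, "pwm")
}

fit_gpd_mom <- function(x) {
  m <- mean(x)
  s2 <- stats::var(x)
  if (!is.finite(s2) || s2 <= 0) {
    pt_error("MOM estimation requires positive sample variance",
             "permtail_fit_error")
  }
  r <- m * m / s2
  shape <- (1 - r) / 2
  scale <- m * (1 + r) / 2
  if (!is.finite(shape) || scale <= 0) {
    pt_error("MOM estimation failed", "permtail_fit_error")
  }
  if (shape < 0 && max(x) > -scale / shape) {
    pt_error("MOM estimate places data outside the fitted support",
             "permtail_fit_error")
  }
  gpd_params(shape, scale, "mom")
}

fit_gpd_ml <- function(x, max_restarts = 5L) {
  n <- length(x)
  nll <- function(par) {
    shape <- par[1L]
    scale <- exp(par[2L])
    w <- 1 + shape * x / scale
    if (any(w <= 0) || !is.finite(scale)) return(1e10)
    if (abs(shape) < 1e-10) {
      n * par[2L] + sum(x) / scale
    } else {
      n * par[2L] + (1 + 1 / shape) * sum(log(w))
    }
  }
  start <- tryCatch({
    s <- fit_gpd_pwm(x)
    c(s$shape, log(s$scale))
  }, error = function(e) NULL)
  if (is.null(start)) {
    start <- tryCatch({
      s <- fit_gpd_mom(x)
      c(s$shape, log(s$scale))
    }, error = function(e) c(0.1, log(mean(x))))
  }
  if (nll(start) >= 1e10) start <- c(max(start[1L], 0.1), log(mean(x)))
  # deterministic perturbations, no RNG: restarts stay reproducible
  offsets <- rbind(c(0, 0), c(0.1, 0.1), c(-0.1, -0.1),
                   c(0.3, -0.2), c(-0.2, 0.3), c(0.5, 0.5))
  best <- NULL
  for (k in seq_len(min(max_restarts + 1L, nrow(offsets)))) {
    par0 <- start + offsets[k, ]
    if (nll(par0) >= 1e10) next
    opt <- stats::optim(par0, nll, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-12))
    if (opt$value < 1e9 && (is.null(best) || opt$value < best$value)) {
      best <- opt
    }
    if (!is.null(best) && k == 1L && best$convergence == 0L) break
  }
  if (is.null(best)) {
    pt_error("maximum-likelihood GPD fit did not converge after restarts",
             "permtail_fit_error")
  }
  gpd_params(best$par[1L], exp(best$par[2L]), "ml")
}

# Upper-tail percentage points of the Anderson-Darling statistic A^2 for the
# GPD with both parameters estimated (Choulakian & Stephens 2001, Table 2).
# Heavier tails (larger shape) have smaller percentage points; the mapping
# was verified by Monte Carlo simulation of ML-fitted GPD samples. Rows are
# indexed by shape (ascending), columns by significance level; linear
# interpolation in shape, clamped at the tabulated ends.
.gpd_ad_levels <- c(0.500, 0.250, 0.100, 0.050, 0.025, 0.010, 0.005, 0.001)
.gpd_ad_shapes <- c(-0.5, -0.4, -0.3, -0.2, -0.1, 0.0, 0.1, 0.2, 0.5, 0.9)
.gpd_ad_table <- matrix(c(
  0.496, 0.735, 1.061, 1.321, 1.590, 1.958, 2.243, 2.922,
  0.468, 0.688, 0.985, 1.221, 1.465, 1.799, 2.058, 2.674,
  0.445, 0.649, 0.924, 1.140, 1.365, 1.672, 1.909, 2.475,
  0.426, 0.617, 0.873, 1.074, 1.283, 1.567, 1.788, 2.314,
  0.410, 0.591, 0.831, 1.020, 1.215, 1.481, 1.687, 2.176,
  0.397, 0.569, 0.796, 0.974, 1.158, 1.409, 1.603, 2.064,
  0.386, 0.550, 0.766, 0.935, 1.110, 1.348, 1.532, 1.966,
  0.376, 0.534, 0.741, 0.903, 1.069, 1.296, 1.471, 1.893,
  0.356, 0.499, 0.685, 0.830, 0.978, 1.180, 1.336, 1.707,
  0.339, 0.471, 0.641, 0.771, 0.905, 1.086, 1.226, 1.559
), nrow = 10, byrow = TRUE)

gpd_ad_critical <- function(shape, level) {
  col <- which(abs(.gpd_ad_levels - level) < 1e-9)
  if (length(col) != 1L) {
    pt_error(sprintf("goodness-of-fit level must be one of %s",
                     paste(.gpd_ad_levels, collapse = ", ")),
             "permtail_parameter_error")
  }
  s <- min(max(shape, min(.gpd_ad_shapes)), max(.gpd_ad_shapes))
  stats::approx(.gpd_ad_shapes, .gpd_ad_table[, col], xout = s)$y
}

#' Anderson-Darling goodness-of-fit test for a fitted GPD tail
#'
#' Tests whether a sample of exceedances is consistent with the fitted
#' generalized Pareto distribution, i.e. whether the exceedances "look like
#' a tail". The statistic is the Anderson-Darling \eqn{A^2} computed from
#' the fitted probability integral transform; it is compared with the
#' shape-dependent upper percentage points of Choulakian & Stephens (2001)
#' for the case where both parameters are estimated, interpolated linearly
#' in the fitted shape. Rejection at the chosen level means the tail model
#' is not trusted and no tail-based P-value should be reported from these
#' exceedances.
#'
#' @param x The exceedances the parameters were fitted to (length >= 10).
#' @param params A [gpd_params] object fitted to `x`.
#' @param level Significance level; one of 0.5, 0.25, 0.1, 0.05 (default),
#'   0.025, 0.01, 0.005, 0.001.
#' @return An object of class `gpd_gof`: list with `statistic` (\eqn{A^2}),
#'   `critical`, `level` and `rejected`.
#' @export
gpd_gof <- function(x, params, level = 0.05) {
  if (length(x) < 10L) {
    pt_error("at least 10 exceedances are required for the goodness-of-fit test",
             "permtail_insufficient_data")
  }
  n <- length(x)
  z <- pgpd(sort(x), params$shape, params$scale)
  eps <- 1e-12
  z <- pmin(pmax(z, eps), 1 - eps)
  i <- seq_len(n)
  a2 <- -n - mean((2 * i - 1) * (log(z) + log1p(-rev(z))))
  crit <- gpd_ad_critical(params$shape, level)
  structure(list(statistic = a2, critical = crit, level = level,
                 rejected = a2 > crit),
            class = "gpd_gof")
}

#' @export
print.gpd_gof <- function(x, ...) {
  cat(sprintf("Anderson-Darling GPD test: A^2 = %.3f (critical %.3f at level %g) -> %s\n",
              x$statistic, x$critical, x$level,
              if (x$rejected) "rejected" else "not rejected"))
  invisible(x)
}
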