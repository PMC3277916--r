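# Bootstrap machinery: percentile confidence intervals, bootstrap variance,
# and the two heuristic convergence criteria (coefficient of variation of
# the log10 estimate, and a full-vs-subsample median comparison).

#' Bootstrap P-value estimates for a permutation column
#'
#' Draws `b` resamples of `ceiling(fraction * N)` permutation values (with
#' replacement), keeps the observed statistic fixed, and runs the full
#' estimator (switch rule included) on each resample. Replicates for which
#' no tail model is accepted are dropped and counted separately.
#'
#' @param column A [perm_column].
#' @param config A [perm_config] (estimation method and gate settings).
#' @param fraction Fraction of the permutation values drawn per replicate,
#'   in (0, 1]; 1 is the ordinary bootstrap, 0.1 the subsample arm of the
#'   convergence check.
#' @param b Number of bootstrap replicates (default
#'   `config$bootstrap_replicates`).
#' @param seed Seed for the resampling (0 = entropy).
#' @param power Power-transform exponent forwarded to the estimator.
#' @param indices Optional precomputed integer matrix of resample indices
#'   (`b` rows); used to share resamples across transform candidates.
#' @return An object of class `perm_bootstrap`: list with `estimates`
#'   (successful replicates only), `source_fraction`, `replicates`
#'   (`length(estimates)`) and `failures`.
#' @export
bootstrap_estimates <- function(column, config = perm_config(), fraction = 1,
                                b = config$bootstrap_replicates, seed = 0,
                                power = 1, indices = NULL) {
  stopifnot(inherits(column, "perm_column"))
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1) {
    pt_error("'fraction' must lie in (0, 1]", "permtail_input_error")
  }
  n <- column$n
  n_sub <- as.integer(ceiling(fraction * n))
  if (is.null(indices)) {
    indices <- with_seed(seed,
                         matrix(sample.int(n, n_sub * b, replace = TRUE),
                                nrow = b))
  }
  ests <- vapply(seq_len(nrow(indices)), function(i) {
    .estimate_p(column$x0, column$values[indices[i, ]], config$method,
                config$gof_level, config$n_exc_init, config$n_exc_step,
                config$min_exc, power = power)
  }, numeric(1))
  fails <- sum(is.na(ests))
  ests <- ests[!is.na(ests)]
  if (fails > nrow(indices) / 2) {
    pt_error(sprintf(
      "more than half of the bootstrap replicates (%d of %d) produced no estimate",
      fails, nrow(indices)), "permtail_bootstrap_error")
  }
  structure(list(estimates = ests, source_fraction = fraction,
                 replicates = length(ests), failures = fails),
            class = "perm_bootstrap")
}

#' Percentile bootstrap confidence interval
#'
#' The interval between the `(1 - level/100)/2` and `1 - (1 - level/100)/2`
#' quantiles of the bootstrap estimates (linear interpolation between order
#' statistics), widened if necessary so that it brackets the point
#' estimate.
#'
#' @param boot A `perm_bootstrap` from [bootstrap_estimates()].
#' @param level Confidence level in percent, between 10 and 99.
#' @param p_est Optional point estimate to bracket.
#' @return Numeric vector `c(lower, upper)`.
#' @export
confidence_interval <- function(boot, level = 95, p_est = NULL) {
  if (!is.numeric(level) || length(level) != 1L || level < 10 || level > 99) {
    pt_error("Confidence level must be between 10 and 99.",
             "permtail_validation_error")
  }
  if (length(boot$estimates) == 0L) {
    pt_error("bootstrap set is empty", "permtail_input_error")
  }
  alpha <- (1 - level / 100) / 2
  q <- unname(stats::quantile(boot$estimates, c(alpha, 1 - alpha), type = 7))
  if (!is.null(p_est) && is.finite(p_est)) {
    q[1] <- min(q[1], p_est)
    q[2] <- max(q[2], p_est)
  }
  c(lower = q[1], upper = q[2])
}

#' Coefficient-of-variation convergence criterion
#'
#' Measures the spread of the bootstrap estimates on the log10 scale
#' relative to the magnitude of the estimate itself:
#' \deqn{CV = \frac{1}{2}\,\frac{|\log_{10} P^{(16)} - \log_{10} P^{(84)}|}{-\log_{10} P_{est}}}
#' where \eqn{P^{(\alpha)}} is the \eqn{\alpha}-th percentile of the
#' bootstrap estimates (16th and 84th, i.e. plus/minus one standard
#' deviation under normality on the log scale). The criterion passes when
#' CV < 1.
#'
#' @param boot A `perm_bootstrap`.
#' @param p_est The point estimate (must be strictly inside (0, 1) for the
#'   CV to be defined).
#' @return List with `cv`, `pass` and possibly a `note`.
#' @export
cv_criterion <- function(boot, p_est) {
  if (length(boot$estimates) == 0L) {
    pt_error("bootstrap set is empty", "permtail_input_error")
  }
  if (!is.finite(p_est) || p_est <= 0 || p_est >= 1) {
    return(list(cv = NA_real_, pass = FALSE,
                note = "CV undefined for point estimates of 0 or 1"))
  }
  q <- unname(stats::quantile(boot$estimates, c(0.16, 0.84), type = 7))
  cv <- 0.5 * abs(log10(q[1]) - log10(q[2])) / (-log10(p_est))
  if (!is.finite(cv)) {
    return(list(cv = Inf, pass = FALSE,
                note = "bootstrap percentile of 0: log10 spread infinite"))
  }
  list(cv = cv, pass = cv < 1)
}

#' Full-vs-subsample median convergence criterion
#'
#' Compares bootstrap estimates derived from all permutation values with
#' estimates derived from a fraction (by default 10%) of them. If the
#' estimate has stabilised, the two sets should share a median; a two-sided
#' Wilcoxon rank-sum test on the log10 estimates (normal approximation with
#' continuity and tie correction) decides. Medians are said to differ —
#' and the criterion fails — when the test rejects at P < 0.001.
#'
#' @param full,sub `perm_bootstrap` sets from [bootstrap_estimates()] at
#'   fractions 1 and (typically) 0.1.
#' @return List with `p` (rank-sum P-value) and `pass`.
#' @export
median_criterion <- function(full, sub) {
  if (length(full$estimates) == 0L || length(sub$estimates) == 0L) {
    pt_error("both bootstrap sets must be nonempty", "permtail_input_error")
  }
  lf <- log10(full$estimates)
  ls <- log10(sub$estimates)
  p <- suppressWarnings(
    stats::wilcox.test(lf, ls, alternative = "two.sided",
                       exact = FALSE, correct = TRUE)$p.value)
  if (is.na(p)) p <- 1   # identical constant sets: no evidence of a shift
  list(p = p, pass = p >= 0.001)
}

#' Convergence diagnostics for a P-value estimate
#'
#' Runs both heuristic criteria: (a) the coefficient of variation of the
#' full bootstrap must be below one, and (b) bootstrap estimates from all
#' permutation values and from a 10% subsample must not differ in median
#' (rank-sum P >= 0.001). The estimate is declared converged only if both
#' criteria pass; otherwise more permutations are needed for a reliable
#' estimate.
#'
#' @param column A [perm_column].
#' @param config A [perm_config]; `bootstrap_replicates` sets B for both
#'   arms and `subsample_fraction` the subsample size.
#' @param seed Seed controlling both bootstrap arms (0 = entropy).
#' @param power Power-transform exponent forwarded to the estimator.
#' @return An object of class `perm_convergence`: list with `cv`,
#'   `cv_pass`, `median_test_p`, `median_pass`, `converged`
#'   (`cv_pass && median_pass`), the two bootstrap sets (`full`, `sub`)
#'   and `notes`.
#' @export
check_convergence <- function(column, config = perm_config(), seed = config$seed,
                              power = 1) {
  notes <- character()
  est <- tryCatch(
    estimate_pvalue(column, config, power = power, enforce_min_perm = FALSE),
    error = function(e) NULL)
  if (is.null(est) || is.na(est$p_value)) {
    return(structure(list(cv = NA_real_, cv_pass = FALSE,
                          median_test_p = NA_real_, median_pass = FALSE,
                          converged = FALSE, full = NULL, sub = NULL,
                          notes = "estimation failed; convergence undefined"),
                     class = "perm_convergence"))
  }
  full <- bootstrap_estimates(column, config, fraction = 1,
                              seed = derive_seed(seed, 1L), power = power)
  sub <- bootstrap_estimates(column, config,
                             fraction = config$subsample_fraction,
                             seed = derive_seed(seed, 2L), power = power)
  cvres <- cv_criterion(full, est$p_value)
  medres <- median_criterion(full, sub)
  if (!is.null(cvres$note)) notes <- c(notes, cvres$note)
  structure(list(cv = cvres$cv, cv_pass = isTRUE(cvres$pass),
                 median_test_p = medres$p, median_pass = isTRUE(medres$pass),
                 converged = isTRUE(cvres$pass) && isTRUE(medres$pass),
                 full = full, sub = sub, notes = notes),
            class = "perm_convergence")
}

#' @export
print.perm_convergence <- function(x, ...) {
  cat(sprintf("Convergence: %s (CV = %.3f [%s], rank-sum P = %.3g [%s])\n",
              if (isTRUE(x$converged)) "yes" else "no",
              x$cv, if (x$cv_pass) "pass" else "fail",
              x$median_test_p, if (x$median_pass) "pass" else "fail"))
  for (nt in x$notes) cat("  note:", nt, "\n")
  invisible(x)
}

#' Full per-column analysis pipeline
#'
#' Runs the estimator on one column and, as configured, the optimal power
#' transform search, the bootstrap confidence interval and the convergence
#' diagnostics. This is the unit of work behind each input column of
#' [run_estimation()].
#'
#' @param column A [perm_column].
#' @param config A [perm_config]; the flags `transform`, `ci` and
#'   `convergence` select the optional stages, and `seed` (via a
#'   content-derived per-column seed) makes them reproducible.
#' @return A `perm_estimate` with `ci_lower`/`ci_upper`, `converged`,
#'   `variance_log10` and `tail_fit$power` filled in as requested.
#' @export
analyze_column <- function(column, config = perm_config()) {
  seed <- column_seed(config$seed, column)
  power <- 1
  if (config$transform) {
    cfg_t <- config
    cfg_t$seed <- seed
    tr <- optimize_transform(column, cfg_t)
    res <- tr$result
    if (!is.na(tr$power)) power <- tr$power
  } else {
    res <- estimate_pvalue(column, config)
  }
  if (is.na(res$p_value)) return(res)
  if (config$ci || config$convergence) {
    if (config$ci) {
      boot <- tryCatch(
        bootstrap_estimates(column, config, fraction = 1,
                            seed = derive_seed(seed, 1L), power = power),
        error = function(e) NULL)
      if (is.null(boot)) {
        res$notes <- c(res$notes,
                       "confidence interval unavailable: too many bootstrap replicates failed")
      } else {
        ci <- confidence_interval(boot, config$confidence_level, res$p_value)
        res$ci_lower <- ci[["lower"]]
        res$ci_upper <- ci[["upper"]]
        lg <- log10(boot$estimates[boot$estimates > 0])
        if (length(lg) >= 2 && is.na(res$variance_log10)) {
          res$variance_log10 <- stats::var(lg)
        }
      }
    }
    if (config$convergence) {
      conv <- check_convergence(column, config, seed = seed, power = power)
      res$converged <- conv$converged
      res$convergence <- conv
    }
  }
  res
}
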