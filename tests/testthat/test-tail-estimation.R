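# The estimator: empirical path, threshold selection, GPD tail path,
# switch rule and the order-preserving power transform.

test_that("p_ecdf counts at-least-as-extreme values, ties included", {
  expect_equal(p_ecdf(-5, c(1, 2, 3)), 1)             # x0 below everything
  expect_equal(p_ecdf(2, c(1, 2, 3, 4)), 0.75)        # tie counts
  vals <- with_fixed_seed(7, rnorm(37))
  x0 <- vals[13]
  # brute-force counting oracle
  cnt <- 0
  for (v in vals) if (v >= x0) cnt <- cnt + 1
  expect_equal(p_ecdf(x0, vals), cnt / 37)
  expect_error(p_ecdf(1, numeric(0)), class = "permtail_input_error")
})

test_that("select_threshold uses order-statistic midpoints and resolves ties", {
  st <- select_threshold(1:1000, 250)
  expect_equal(st$threshold, 750.5)
  expect_equal(st$n_exc, 250)
  expect_equal(select_threshold(c(1, 2, 3), 1)$threshold, 2.5)
  # tie at the boundary: order statistics 5 and 6 from the top are equal,
  # so the count slides down to the largest strict cut
  vals <- c(10, 9, 8, 7, 6, 6, 6, 3, 2, 1)
  st <- select_threshold(vals, 6)
  expect_equal(st$n_exc, 4)
  expect_equal(st$threshold, (7 + 6) / 2)
  expect_equal(sum(vals > st$threshold), st$n_exc)
  expect_error(select_threshold(1:5, 5), class = "permtail_domain_error")
  expect_error(select_threshold(rep(2, 10), 4), class = "permtail_domain_error")
})

test_that("p_gpd reduces to N_exc/N at the threshold and tracks the fitted tail", {
  tail <- list(threshold = 2, n_exc = 250,
               params = gpd_params(0, 1), power = 1)
  expect_equal(p_gpd(2 + 1e-12, tail, 1000), 0.25, tolerance = 1e-9)
  # closed form: exponential tail at z = 3
  expect_equal(p_gpd(5, tail, 1000), 0.25 * exp(-3))
  expect_error(p_gpd(1.5, tail, 1000), class = "permtail_domain_error")
})

test_that("the GPD tail estimate is within an order of magnitude at p = 1e-5", {
  # true tail probability 1e-5 with only 1000 exponential permutation values:
  # the empirical estimator is blind here (floor 1/N = 1e-3)
  lr <- sapply(1:50, function(s) {
    col <- exp_column(seed = s)
    r <- estimate_pvalue(col)
    if (is.na(r$p_value) || r$p_value == 0) Inf else abs(log10(r$p_value / 1e-5))
  })
  expect_lt(median(lr), 1)
})

test_that("shifted-GPD columns recover their own tail point", {
  lr <- sapply(1:40, function(s) {
    col <- synthetic_column("gpd", 1000, 1e-4,
                            params = list(shape = 0.2, scale = 1), seed = s)
    r <- estimate_pvalue(col)
    if (is.na(r$p_value) || r$p_value == 0) Inf else abs(log10(r$p_value / 1e-4))
  })
  expect_lt(median(lr), 1)
})

test_that("the switch rule routes by the exceedance count of x0", {
  col10 <- column_with_m_exceedances(10, seed = 2)
  r10 <- estimate_pvalue(col10)
  expect_identical(r10$estimator, "empirical")
  expect_equal(r10$p_value, 0.01)
  col9 <- column_with_m_exceedances(9, seed = 2)
  r9 <- estimate_pvalue(col9)
  expect_identical(r9$estimator, "gpd")
  expect_true(r9$tail_fit$threshold < col9$x0)
  expect_gte(r9$tail_fit$n_exc, 10)
  expect_lte(r9$tail_fit$n_exc, 250)
})

test_that("degenerate and undersized columns are handled per the contract", {
  const <- perm_column(rep(1, 1000), x0 = 2)
  r <- estimate_pvalue(const)
  expect_identical(r$estimator, "none")
  expect_true(is.na(r$p_value))
  expect_gt(length(r$notes), 0)
  # below the 1000-value gate the tail path refuses
  small <- perm_column(with_fixed_seed(3, rexp(999)), x0 = 20)
  expect_error(estimate_pvalue(small), class = "permtail_validation_error")
  # ... but internal resamples may bypass the gate
  expect_s3_class(estimate_pvalue(small, enforce_min_perm = FALSE),
                  "perm_estimate")
})

test_that("light-tailed nulls can land beyond the fitted endpoint", {
  # normal tail at true p = 1e-9: fitted shapes are negative and the
  # observed statistic frequently exceeds the fitted support, giving the
  # designed point estimate 0 with an explanatory note
  rs <- lapply(1:10, function(s) {
    estimate_pvalue(synthetic_column("normal", 1000, 1e-9, seed = s))
  })
  est <- vapply(rs, function(r) r$estimator, character(1))
  expect_true(all(est %in% c("gpd", "none")))
  p <- vapply(rs, function(r) r$p_value, numeric(1))
  expect_true(all(is.na(p) | p < 1e-4))
  zero <- !is.na(p) & p == 0
  expect_true(any(zero))
  for (r in rs[zero]) expect_match(paste(r$notes, collapse = " "), "endpoint")
})

test_that("estimates are monotone nonincreasing in x0 within an estimator", {
  values <- with_fixed_seed(11, rexp(1000))
  vs <- sort(values, decreasing = TRUE)
  # empirical regime
  p_emp <- sapply(seq(0.5, 2, by = 0.25), function(x0) {
    estimate_pvalue(perm_column(values, x0))$p_value
  })
  expect_true(all(diff(p_emp) <= 0))
  # tail regime: same column, same accepted fit, increasing x0
  x0s <- seq(vs[5] + 0.5, vs[5] + 6, by = 0.5)
  p_gpd_path <- sapply(x0s, function(x0) {
    estimate_pvalue(perm_column(values, x0))$p_value
  })
  expect_true(all(diff(p_gpd_path) <= 0))
})

test_that("empirical and forced-GPD estimates agree in the bulk", {
  rel <- sapply(1:10, function(s) {
    col <- synthetic_column("exponential", 1000, 0.15, seed = s)
    pe <- p_ecdf(col$x0, col$values)
    rg <- estimate_pvalue(col, force_gpd = TRUE)
    abs(rg$p_value - pe) / pe
  })
  expect_lt(max(rel), 0.5)
})

test_that("power transforms preserve ranks for any positive exponent", {
  exc <- with_fixed_seed(23, rexp(200))
  for (pw in c(0.25, 0.5, 1, 2, 3, 4, 5)) {
    expect_identical(rank(exc^pw), rank(exc))
  }
})

test_that("optimize_transform returns the variance argmin over the grid", {
  col <- exp_column(seed = 3)
  cfg <- perm_config(bootstrap_replicates = 100, seed = 41)
  tr <- optimize_transform(col, cfg)
  expect_true(tr$power %in% cfg$power_grid)
  # the winner can be no worse than the untransformed variance
  v1 <- tr$variances[["1"]]
  if (!is.na(v1) && !is.na(tr$power)) {
    expect_lte(tr$variances[[as.character(tr$power)]], v1)
  }
  # exhaustive oracle: re-run the estimator per exponent on the shared
  # resample indices and recompute each variance independently
  n <- col$n
  b <- cfg$bootstrap_replicates
  idx <- permtail:::with_seed(permtail:::derive_seed(cfg$seed, 3L),
                              matrix(sample.int(n, n * b, replace = TRUE),
                                     nrow = b))
  var_manual <- sapply(cfg$power_grid, function(pw) {
    ests <- vapply(seq_len(b), function(i) {
      permtail:::.estimate_p(col$x0, col$values[idx[i, ]], cfg$method,
                             cfg$gof_level, cfg$n_exc_init, cfg$n_exc_step,
                             cfg$min_exc, power = pw)
    }, numeric(1))
    lg <- log10(ests[!is.na(ests) & ests > 0])
    if (length(lg) >= b / 2) var(lg) else NA_real_
  })
  jbest <- which.min(replace(var_manual, is.na(var_manual), Inf))
  expect_equal(tr$power, cfg$power_grid[jbest])
  expect_equal(unname(tr$variances), unname(var_manual), tolerance = 1e-12)
})

test_that("estimation with abundant exceedances short-circuits the transform", {
  col <- synthetic_column("exponential", 1000, 0.2, seed = 9)
  tr <- optimize_transform(col, perm_config(seed = 5, bootstrap_replicates = 20))
  expect_identical(tr$result$estimator, "empirical")
  expect_equal(tr$power, 1)
})
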