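# Bootstrap machinery: resampling, percentile intervals, the CV criterion
# and the full-vs-subsample median comparison.

test_that("bootstrap_estimates resamples reproducibly and reports its shape", {
  col <- exp_column(seed = 4, tail_p = 1e-4)
  cfg <- perm_config()
  b1 <- bootstrap_estimates(col, cfg, fraction = 1, b = 100, seed = 12)
  b2 <- bootstrap_estimates(col, cfg, fraction = 1, b = 100, seed = 12)
  expect_identical(b1$estimates, b2$estimates)
  expect_equal(b1$replicates, length(b1$estimates))
  expect_equal(b1$replicates + b1$failures, 100)
  expect_equal(b1$source_fraction, 1)
  expect_true(all(b1$estimates >= 0 & b1$estimates <= 1))
  # subsample arm draws ceil(fraction*N) values
  bs <- bootstrap_estimates(col, cfg, fraction = 0.1, b = 20, seed = 12)
  expect_equal(bs$source_fraction, 0.1)
  expect_error(bootstrap_estimates(col, cfg, fraction = 0, b = 10),
               class = "permtail_input_error")
})

test_that("a constant column bootstraps to all-ones", {
  col <- perm_column(rep(3.5, 1000), x0 = 2)   # x0 below every value
  boot <- bootstrap_estimates(col, perm_config(), fraction = 1, b = 50, seed = 3)
  expect_true(all(boot$estimates == 1))
})

test_that("bootstrap estimates centre near the point estimate", {
  col <- exp_column(seed = 21, tail_p = 1e-4)
  r <- estimate_pvalue(col)
  boot <- bootstrap_estimates(col, perm_config(), fraction = 1, b = 200, seed = 5)
  lg <- log10(boot$estimates[boot$estimates > 0])
  se <- sd(lg) / sqrt(length(lg))
  expect_lt(abs(mean(lg) - log10(r$p_value)), 3 * se + 0.3)
})

test_that("confidence_interval is a clamped percentile interval", {
  boot <- structure(list(estimates = (1:100) / 1000, source_fraction = 1,
                         replicates = 100L, failures = 0L),
                    class = "perm_bootstrap")
  ci <- confidence_interval(boot, 95)
  expect_equal(unname(ci), unname(quantile((1:100) / 1000, c(0.025, 0.975))),
               tolerance = 1e-12)
  # bracket the point estimate when it falls outside
  ci2 <- confidence_interval(boot, 95, p_est = 1e-4)
  expect_equal(ci2[["lower"]], 1e-4)
  # degenerate set collapses to a point
  bd <- structure(list(estimates = rep(0.01, 40), source_fraction = 1,
                       replicates = 40L, failures = 0L),
                  class = "perm_bootstrap")
  expect_equal(unname(confidence_interval(bd, 95)), c(0.01, 0.01))
  expect_error(confidence_interval(boot, 100), class = "permtail_validation_error")
  expect_error(confidence_interval(boot, 9), class = "permtail_validation_error")
})

test_that("the CV criterion implements the log10 percentile-spread formula", {
  # identical estimates: zero spread, passes
  bd <- block_bootstrap(-4, -4)
  expect_equal(cv_criterion(bd, 1e-4)$cv, 0)
  expect_true(cv_criterion(bd, 1e-4)$pass)
  # p = 1e-4, percentiles 1e-4.5 and 1e-3.5: CV = (1/2)(1)/4 = 0.125
  r <- cv_criterion(block_bootstrap(-4.5, -3.5), 1e-4)
  expect_equal(r$cv, 0.125, tolerance = 1e-10)
  expect_true(r$pass)
  # p = 1e-2, percentiles 1e-6 and 1e-0.5: CV = (1/2)(5.5)/2 = 1.375
  r2 <- cv_criterion(block_bootstrap(-6, -0.5), 1e-2)
  expect_equal(r2$cv, 1.375, tolerance = 1e-10)
  expect_false(r2$pass)
  # undefined at the boundary point estimates
  r3 <- cv_criterion(bd, 0)
  expect_false(r3$pass)
  expect_true(is.na(r3$cv))
})

test_that("median_criterion matches an independent rank-sum computation", {
  a <- c(0.2, 0.5, 0.8, 1.4, 2.2, 3.1)
  b <- c(0.9, 1.1, 1.8, 2.5, 3.4, 4.2, 5.0)
  ba <- structure(list(estimates = a / 10, replicates = 6L), class = "perm_bootstrap")
  bb <- structure(list(estimates = b / 10, replicates = 7L), class = "perm_bootstrap")
  got <- median_criterion(ba, bb)
  # independent normal-approximation rank-sum (continuity-corrected), no ties
  la <- log10(a / 10); lb <- log10(b / 10)
  rk <- rank(c(la, lb))
  w <- sum(rk[seq_along(la)]) - length(la) * (length(la) + 1) / 2
  mu <- length(la) * length(lb) / 2
  sg <- sqrt(length(la) * length(lb) * (length(la) + length(lb) + 1) / 12)
  p_ref <- 2 * pnorm((abs(w - mu) - 0.5) / sg, lower.tail = FALSE)
  expect_equal(got$p, p_ref, tolerance = 1e-10)
  # identical sets carry no evidence of a median shift
  same <- median_criterion(ba, ba)
  expect_true(same$pass)
  expect_gt(same$p, 0.5)
  expect_error(median_criterion(ba, structure(list(estimates = numeric(0)),
                                              class = "perm_bootstrap")),
               class = "permtail_input_error")
})

test_that("well-sampled estimates converge; starved ones do not", {
  cfg <- perm_config()
  # easy regime: N = 10^4 with true p = 0.01 (empirical path, stable)
  conv <- sapply(1:5, function(s) {
    col <- synthetic_column("exponential", 10000, 0.01, seed = s)
    check_convergence(col, cfg, seed = s + 300)$converged
  })
  expect_gte(sum(conv), 4)
  # hard regime: N = 1000 against true p = 1e-9
  hard <- sapply(1:10, function(s) {
    col <- synthetic_column("exponential", 1000, 1e-9, seed = s)
    check_convergence(col, cfg, seed = s + 100)$converged
  })
  expect_gte(sum(!hard), 6)
  # definitional identity and reproducibility of the flag
  col <- synthetic_column("exponential", 2000, 1e-4, seed = 8)
  r1 <- check_convergence(col, cfg, seed = 99)
  r2 <- check_convergence(col, cfg, seed = 99)
  expect_identical(r1$converged, r1$cv_pass && r1$median_pass)
  expect_identical(r1$converged, r2$converged)
  expect_identical(r1$cv, r2$cv)
})

test_that("the starved subsample arm shifts the bootstrap median", {
  cfg <- perm_config()
  fails <- sapply(1:10, function(s) {
    col <- synthetic_column("exponential", 1000, 1e-8, seed = s)
    !check_convergence(col, cfg, seed = s + 100)$median_pass
  })
  expect_gte(sum(fails), 5)
})

test_that("confidence intervals tighten as permutations accumulate", {
  cfg <- perm_config()
  width <- sapply(c(1000, 10000), function(n) {
    col <- synthetic_column("exponential", n, 1e-4, seed = 77)
    r <- estimate_pvalue(col)
    boot <- bootstrap_estimates(col, cfg, fraction = 1, b = 300, seed = 78)
    ci <- confidence_interval(boot, 95, r$p_value)
    log10(ci[[2]]) - log10(ci[[1]])
  })
  expect_lt(width[2], width[1])
})

test_that("interval calibration orders with the confidence level", {
  cfg <- perm_config()
  cover <- function(level, reps = 120) {
    hits <- 0
    for (s in seq_len(reps)) {
      col <- synthetic_column("exponential", 1000, 1e-4, seed = s)
      r <- estimate_pvalue(col)
      if (is.na(r$p_value)) next
      boot <- bootstrap_estimates(col, cfg, fraction = 1, b = 200,
                                  seed = s + 4000)
      ci <- confidence_interval(boot, level, r$p_value)
      if (ci[[1]] <= 1e-4 && 1e-4 <= ci[[2]]) hits <- hits + 1
    }
    hits / reps
  }
  c80 <- cover(80)
  c95 <- cover(95)
  expect_gt(c95, c80 - 0.02)
  expect_gt(c80, 0.70)
  expect_gt(c95, 0.85)
  expect_lte(c95, 1)
})
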