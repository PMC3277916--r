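# Synthetic permutation-value generators with closed-form tail
# probabilities, and exhaustively enumerable two-group permutation tests.
# These provide ground truth (true tail probabilities, exact P_perm) for
# validating the estimator.

.syn_families <- c("normal", "exponential", "gpd", "student_t", "lognormal")

syn_defaults <- function(family) {
  switch(family,
         normal      = list(mean = 0, sd = 1),
         exponential = list(rate = 1),
         gpd         = list(shape = 0.1, scale = 1),
         student_t   = list(df = 5),
         lognormal   = list(meanlog = 0, sdlog = 1))
}

syn_params <- function(family, params) {
  family <- match.arg(family, .syn_families)
  p <- syn_defaults(family)
  for (nm in names(params)) {
    if (!nm %in% names(p)) {
      pt_error(sprintf("unknown parameter '%s' for family '%s'", nm, family),
               "permtail_domain_error")
    }
    p[[nm]] <- params[[nm]]
  }
  bad <- switch(family,
                normal      = p$sd <= 0,
                exponential = p$rate <= 0,
                gpd         = p$scale <= 0,
                student_t   = p$df <= 0,
                lognormal   = p$sdlog <= 0)
  if (isTRUE(bad)) {
    pt_error(sprintf("invalid parameters for family '%s'", family),
             "permtail_domain_error")
  }
  p
}

#' True upper-tail probability of a synthetic null family
#'
#' Exact \eqn{P(X \ge x)} for the supported null families; the oracle
#' against which tail-based estimates are judged.
#'
#' @param family One of `"normal"`, `"exponential"`, `"gpd"`,
#'   `"student_t"`, `"lognormal"`.
#' @param x Quantile.
#' @param params Named list of family parameters (defaults: standard
#'   normal; rate-1 exponential; GPD shape 0.1, scale 1; t with 5 df;
#'   standard lognormal).
#' @return The upper-tail probability.
#' @examples
#' true_tail_p("exponential", log(2))       # 0.5
#' true_tail_p("gpd", 2, list(shape = 0.5)) # 0.25
#' @export
true_tail_p <- function(family, x, params = list()) {
  family <- match.arg(family, .syn_families)
  p <- syn_params(family, params)
  switch(family,
         normal      = stats::pnorm(x, p$mean, p$sd, lower.tail = FALSE),
         exponential = stats::pexp(x, p$rate, lower.tail = FALSE),
         gpd         = pgpd(x, p$shape, p$scale, lower.tail = FALSE),
         student_t   = stats::pt(x, p$df, lower.tail = FALSE),
         lognormal   = stats::plnorm(x, p$meanlog, p$sdlog, lower.tail = FALSE))
}

syn_tail_quantile <- function(family, tail_p, params) {
  p <- syn_params(family, params)
  switch(family,
         normal      = stats::qnorm(tail_p, p$mean, p$sd, lower.tail = FALSE),
         exponential = stats::qexp(tail_p, p$rate, lower.tail = FALSE),
         gpd         = qgpd(tail_p, p$shape, p$scale, lower.tail = FALSE),
         student_t   = stats::qt(tail_p, p$df, lower.tail = FALSE),
         lognormal   = stats::qlnorm(tail_p, p$meanlog, p$sdlog,
                                     lower.tail = FALSE))
}

syn_draw <- function(family, n, params) {
  p <- syn_params(family, params)
  switch(family,
         normal      = stats::rnorm(n, p$mean, p$sd),
         exponential = stats::rexp(n, p$rate),
         gpd         = rgpd(n, p$shape, p$scale),
         student_t   = stats::rt(n, p$df),
         lognormal   = stats::rlnorm(n, p$meanlog, p$sdlog))
}

#' Generate a synthetic permutation column with known true P-value
#'
#' Draws `n` permutation values from a null family and places the observed
#' statistic exactly at the point whose true upper-tail probability is
#' `x0_tail_p`, so the correct P-value of the simulated test is known in
#' closed form.
#'
#' @param family Null family (see [true_tail_p()]).
#' @param n Number of permutation values.
#' @param x0_tail_p True upper-tail probability at the observed statistic,
#'   in (0, 1).
#' @param params Named list of family parameters.
#' @param seed 0 for fresh entropy, or 1 to 1,000,000 for a reproducible
#'   column.
#' @param label Optional column label.
#' @return A [perm_column] with attribute `true_p = x0_tail_p`.
#' @examples
#' col <- synthetic_column("exponential", n = 1000, x0_tail_p = 1e-4, seed = 7)
#' col$x0  # log(1e4)
#' @export
synthetic_column <- function(family, n, x0_tail_p, params = list(),
                             seed = 0, label = NULL) {
  family <- match.arg(family, .syn_families)
  if (!is.numeric(x0_tail_p) || x0_tail_p <= 0 || x0_tail_p >= 1) {
    pt_error("'x0_tail_p' must lie strictly between 0 and 1",
             "permtail_domain_error")
  }
  if (seed < 0 || seed > 1e6) {
    pt_error("Random seed must be 0 (arbitrary) or an integer between 1 and 1,000,000.",
             "permtail_config_error")
  }
  x0 <- syn_tail_quantile(family, x0_tail_p, params)
  values <- with_seed(seed, syn_draw(family, n, params))
  col <- perm_column(values, x0, label = label)
  attr(col, "true_p") <- x0_tail_p
  col
}

#' Exact two-group permutation test by exhaustive enumeration
#'
#' Enumerates every assignment of the pooled observations into two groups
#' of the original sizes, computes the difference of means for each, and
#' returns the exact permutation P-value: the fraction of assignments whose
#' statistic is at least as large as the observed one (upper tail). The
#' observed assignment is included in the enumeration, so the P-value is
#' never zero.
#'
#' @param group_a,group_b Numeric vectors; combined length at most 14 so
#'   the enumeration stays feasible.
#' @return List with `p_exact`, `statistic` (observed difference of means
#'   `mean(group_a) - mean(group_b)`), `n_arrangements` and `stats` (the
#'   statistic under every arrangement).
#' @examples
#' exact_perm_test(c(3, 4, 5), c(0, 1, 2))$p_exact  # 1/20
#' @export
exact_perm_test <- function(group_a, group_b) {
  na <- length(group_a)
  nb <- length(group_b)
  n <- na + nb
  if (n > 14L) {
    pt_error("exhaustive enumeration is limited to 14 observations in total",
             "permtail_domain_error")
  }
  if (na < 1L || nb < 1L) {
    pt_error("both groups must be nonempty", "permtail_input_error")
  }
  pooled <- c(group_a, group_b)
  observed <- mean(group_a) - mean(group_b)
  total <- sum(pooled)
  idx <- utils::combn(n, na)
  sums_a <- colSums(matrix(pooled[idx], nrow = na))
  stats <- sums_a / na - (total - sums_a) / nb
  tol <- 1e-12 * max(1, abs(observed))
  list(p_exact = mean(stats >= observed - tol),
       statistic = observed,
       n_arrangements = ncol(idx),
       stats = stats)
}

#' Monte Carlo permutation column for a two-group test
#'
#' Builds a [perm_column] whose observed statistic is the difference of
#' group means and whose permutation values are the statistic recomputed
#' under `n_perms` uniformly random label rearrangements. Feeding the
#' column to [estimate_pvalue()] targets the exact enumeration P-value of
#' [exact_perm_test()].
#'
#' @param group_a,group_b Numeric vectors.
#' @param n_perms Number of random rearrangements.
#' @param seed 0 for entropy, 1 to 1,000,000 reproducible.
#' @param label Optional column label.
#' @return A [perm_column].
#' @export
perm_test_column <- function(group_a, group_b, n_perms, seed = 0,
                             label = NULL) {
  na <- length(group_a)
  nb <- length(group_b)
  pooled <- c(group_a, group_b)
  n <- na + nb
  total <- sum(pooled)
  observed <- mean(group_a) - mean(group_b)
  values <- with_seed(seed, {
    vapply(seq_len(n_perms), function(i) {
      sa <- sum(pooled[sample.int(n, na)])
      sa / na - (total - sa) / nb
    }, numeric(1))
  })
  perm_column(values, observed, label = label)
}

#' Write a file of synthetic permutation columns
#'
#' Emits a fixture table in the tool's input dialect: one synthetic column
#' per requested label, all sharing a family, size and true tail
#' probability. Per-column seeds are derived from `seed` so the file is
#' reproducible.
#'
#' @param path Output path (`.csv` for commas, else tabs).
#' @param n_columns Number of columns.
#' @param family,n,x0_tail_p,params Forwarded to [synthetic_column()].
#' @param seed 0 for entropy, otherwise reproducible.
#' @param header Write a header row of labels (default `TRUE`).
#' @return Invisibly, the path.
#' @export
write_synthetic_table <- function(path, n_columns = 1, family = "exponential",
                                  n = 1000, x0_tail_p = 1e-4, params = list(),
                                  seed = 0, header = TRUE) {
  cols <- lapply(seq_len(n_columns), function(j) {
    synthetic_column(family, n, x0_tail_p, params,
                     seed = if (seed == 0) 0 else ((seed + j - 1) %% 1000000) + 1,
                     label = if (header) sprintf("%s_%d", family, j) else NULL)
  })
  write_perm_table(cols, path)
  invisible(path)
}
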