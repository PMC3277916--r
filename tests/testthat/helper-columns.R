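# Shared fixture builders. All fixtures are generated in code under fixed
# seeds; nothing is read from disk except what the io tests write themselves.

# Exponential permutation column whose observed statistic sits at a known
# true upper-tail probability.
exp_column <- function(seed, n = 1000, tail_p = 1e-5) {
  synthetic_column("exponential", n = n, x0_tail_p = tail_p, seed = seed)
}

# Column with exactly m of its n values >= x0 (continuous values, no ties).
column_with_m_exceedances <- function(m, seed = 1, n = 1000) {
  values <- with_fixed_seed(seed, stats::rexp(n))
  vs <- sort(values, decreasing = TRUE)
  x0 <- if (m == 0) vs[1] + 1 else (vs[m] + vs[m + 1]) / 2
  perm_column(values, x0)
}

with_fixed_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

# Hand-built bootstrap set whose 16th/84th percentiles are exactly 10^a and
# 10^b (type-7 quantiles of two equal blocks hit the block values).
block_bootstrap <- function(a, b, m = 50) {
  structure(list(estimates = rep(c(10^a, 10^b), each = m),
                 source_fraction = 1, replicates = 2 * m, failures = 0L),
            class = "perm_bootstrap")
}

write_fixture_lines <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
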