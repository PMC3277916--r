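# Readers and writers for column-per-event permutation-value tables.
#
# Input dialect: tab-delimited text, or comma-separated when the file ends
# in .csv. Each column holds one tested event: an optional header label,
# then the observed test statistic, then its permutation values. A header
# row is auto-detected (any non-numeric cell in the first row). Empty,
# non-numeric, NaN and Inf cells are ignored per column, so columns may
# carry different numbers of permutation values.

table_sep <- function(path, dialect = c("auto", "tsv", "csv")) {
  dialect <- match.arg(dialect)
  if (dialect == "csv" ||
      (dialect == "auto" && grepl("\\.csv$", path, ignore.case = TRUE))) {
    ","
  } else {
    "\t"
  }
}

is_numeric_cell <- function(cell) {
  cell <- trimws(cell)
  if (is.na(cell) || !nzchar(cell)) return(NA)  # blank: neither
  if (toupper(cell) %in% c("NA", "NAN", "INF", "-INF", "+INF", "INFINITY")) {
    return(TRUE)  # numeric-ish token, later dropped as non-finite
  }
  !is.na(suppressWarnings(as.numeric(cell)))
}

#' Read a permutation-value table
#'
#' Parses a delimited text file with one tested event per column. Files
#' ending in `.csv` are comma-separated; everything else is read as
#' tab-delimited (or force the dialect explicitly). If any cell of the
#' first row is non-numeric the row is treated as a header of column
#' labels and the test statistics are taken from the second row; otherwise
#' the statistics are on the first row. All numeric cells below the
#' statistic are the permutation values; blank, non-numeric, NaN and Inf
#' cells are ignored cell-wise, so per-column counts may differ.
#'
#' @param path Path to the input file.
#' @param dialect `"auto"` (default, extension-based), `"tsv"` or `"csv"`.
#' @return An object of class `perm_table`: list with `columns` (a list of
#'   [perm_column]) and `has_header`.
#' @export
read_perm_table <- function(path, dialect = c("auto", "tsv", "csv")) {
  if (!file.exists(path)) {
    pt_error(sprintf("input file not found: %s", path), "permtail_io_error")
  }
  sep <- table_sep(path, dialect)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[cumsum(nzchar(trimws(lines))) > 0]        # leading blanks
  while (length(lines) && !nzchar(trimws(lines[length(lines)]))) {
    lines <- lines[-length(lines)]                         # trailing blanks
  }
  if (length(lines) == 0L) {
    pt_error("input file contains no data", "permtail_format_error")
  }
  cells <- strsplit(lines, sep, fixed = TRUE)
  ncol <- max(lengths(cells))
  mat <- t(vapply(cells, function(r) c(r, rep("", ncol - length(r))),
                  character(ncol)))
  if (!is.matrix(mat)) mat <- matrix(mat, nrow = length(cells))

  first_numeric <- vapply(mat[1L, ], is_numeric_cell, logical(1))
  has_header <- any(!first_numeric, na.rm = TRUE)
  labels <- NULL
  stat_row <- 1L
  if (has_header) {
    labels <- trimws(mat[1L, ])
    labels[!nzchar(labels)] <- paste0("column", which(!nzchar(labels)))
    stat_row <- 2L
  }
  if (nrow(mat) < stat_row) {
    pt_error("no numeric data row: the file holds a header but no test statistics",
             "permtail_format_error")
  }
  stats_raw <- suppressWarnings(as.numeric(mat[stat_row, ]))
  if (!any(is.finite(stats_raw))) {
    pt_error("no numeric data row: the test-statistic row contains no finite value",
             "permtail_format_error")
  }
  value_rows <- if (nrow(mat) > stat_row) {
    mat[seq(stat_row + 1L, nrow(mat)), , drop = FALSE]
  } else {
    matrix(character(0), nrow = 0, ncol = ncol)
  }
  columns <- vector("list", ncol)
  for (j in seq_len(ncol)) {
    lab <- if (has_header) labels[j] else NULL
    name <- if (!is.null(lab)) sprintf("'%s'", lab) else sprintf("#%d", j)
    if (!is.finite(stats_raw[j])) {
      pt_error(sprintf("column %s has no finite test statistic", name),
               "permtail_format_error")
    }
    vals <- suppressWarnings(as.numeric(value_rows[, j]))
    vals <- vals[is.finite(vals)]
    if (length(vals) == 0L) {
      pt_error(sprintf("column %s has a test statistic but no permutation values",
                       name), "permtail_format_error")
    }
    columns[[j]] <- perm_column(vals, stats_raw[j], label = lab)
  }
  structure(list(columns = columns, has_header = has_header),
            class = "perm_table")
}

#' @export
print.perm_table <- function(x, ...) {
  cat(sprintf("Permutation table: %d column(s)%s\n", length(x$columns),
              if (x$has_header) " (with header)" else ""))
  for (col in x$columns) print(col)
  invisible(x)
}

#' Write a permutation-value table
#'
#' Serializes columns in the input dialect (label row when any column is
#' labelled, then the statistic row, then permutation values). Used to emit
#' synthetic fixtures.
#'
#' @param table A `perm_table` (or list of [perm_column]).
#' @param path Output path; `.csv` selects commas, otherwise tabs.
#' @export
write_perm_table <- function(table, path) {
  columns <- if (inherits(table, "perm_table")) table$columns else table
  sep <- table_sep(path, "auto")
  labs <- vapply(columns, function(cl) cl$label %||% "", character(1))
  nmax <- max(vapply(columns, function(cl) cl$n, integer(1)))
  rows <- character(0)
  if (any(nzchar(labs))) rows <- paste(labs, collapse = sep)
  fmt <- function(x) formatC(x, digits = 11, format = "e")
  rows <- c(rows, paste(vapply(columns, function(cl) fmt(cl$x0), character(1)),
                        collapse = sep))
  body <- vapply(columns, function(cl) c(fmt(cl$values), rep("", nmax - cl$n)),
                 character(nmax))
  if (nmax == 1L) body <- matrix(body, nrow = 1L)
  rows <- c(rows, apply(body, 1, paste, collapse = sep))
  writeLines(rows, path)
  invisible(path)
}

#' Check which columns qualify for tail estimation
#'
#' Tail estimation requires at least `min_n` (default 1,000) permutation
#' values per column; columns below the cutoff may still be estimated
#' empirically but no tail model will be fitted for them.
#'
#' @param table A `perm_table`.
#' @param min_n Minimum permutation-value count (default 1000).
#' @return A data frame with one row per column: `label`, `n`, `eligible`.
#' @export
validate_for_tail <- function(table, min_n = 1000L) {
  columns <- if (inherits(table, "perm_table")) table$columns else table
  if (length(columns) == 0L) {
    return(data.frame(label = character(0), n = integer(0),
                      eligible = logical(0)))
  }
  labs <- vapply(seq_along(columns), function(j) {
    columns[[j]]$label %||% sprintf("column%d", j)
  }, character(1))
  n <- vapply(columns, function(cl) cl$n, integer(1))
  data.frame(label = labs, n = n, eligible = n >= min_n)
}

fmt_result_num <- function(x) {
  ifelse(is.na(x), "NA", formatC(x, digits = 11, format = "e"))
}

#' Write estimation results
#'
#' Tab-delimited layout mirroring the input orientation: an optional header
#' row with the original column labels, a row of P-value estimates, then —
#' if requested — two rows with the lower and upper confidence bounds, and
#' finally a row of binary convergence flags (1 converged, 0 not).
#' Failed estimates are written as `NA`.
#'
#' @param results List of `perm_estimate` objects.
#' @param path Output path.
#' @param with_ci Include the two confidence-bound rows (default `TRUE`).
#' @param with_convergence Include the flag row (default `FALSE`).
#' @export
write_results <- function(results, path, with_ci = TRUE,
                          with_convergence = FALSE) {
  if (length(results) == 0L) {
    pt_error("'results' must be nonempty", "permtail_input_error")
  }
  labs <- vapply(results, function(r) r$label %||% "", character(1))
  rows <- character(0)
  if (any(nzchar(labs))) rows <- paste(labs, collapse = "\t")
  p <- vapply(results, function(r) r$p_value, numeric(1))
  rows <- c(rows, paste(fmt_result_num(p), collapse = "\t"))
  if (with_ci) {
    lo <- vapply(results, function(r) r$ci_lower, numeric(1))
    hi <- vapply(results, function(r) r$ci_upper, numeric(1))
    rows <- c(rows, paste(fmt_result_num(lo), collapse = "\t"),
              paste(fmt_result_num(hi), collapse = "\t"))
  }
  if (with_convergence) {
    fl <- vapply(results, function(r) {
      if (is.na(r$converged)) "NA" else if (isTRUE(r$converged)) "1" else "0"
    }, character(1))
    rows <- c(rows, paste(fl, collapse = "\t"))
  }
  con <- tryCatch(file(path, "w"), error = function(e) {
    pt_error(sprintf("cannot open '%s' for writing", path), "permtail_io_error")
  })
  on.exit(close(con))
  writeLines(rows, con)
  invisible(path)
}

#' Plot estimated P-values with confidence bounds
#'
#' Writes a PNG showing each column's estimate as \eqn{-\log_{10} P} with
#' whiskers spanning the confidence interval (when present). Columns whose
#' estimation failed are skipped.
#'
#' @param results List of `perm_estimate` objects.
#' @param path Output PNG path.
#' @param width,height Device size in pixels.
#' @return Invisibly, a list with the y-axis range used (`ylim`).
#' @export
plot_results <- function(results, path, width = 720, height = 480) {
  if (length(results) == 0L) {
    pt_error("'results' must be nonempty", "permtail_input_error")
  }
  p <- vapply(results, function(r) r$p_value, numeric(1))
  lo <- vapply(results, function(r) r$ci_lower, numeric(1))
  hi <- vapply(results, function(r) r$ci_upper, numeric(1))
  labs <- vapply(seq_along(results), function(j) {
    results[[j]]$label %||% sprintf("col%d", j)
  }, character(1))
  nl <- function(x) ifelse(is.na(x) | x <= 0, NA_real_, -log10(x))
  y <- nl(p)
  ylo <- nl(hi)   # upper P bound = lower -log10
  yhi <- nl(lo)
  cap <- function(v) ifelse(is.na(v) & !is.na(y), y, v)
  finite_all <- c(y, ylo, yhi)
  ylim <- range(c(0, finite_all[is.finite(finite_all)]), na.rm = TRUE)
  grDevices::png(path, width = width, height = height)
  on.exit(grDevices::dev.off())
  x <- seq_along(y)
  plot(x, y, pch = 19, col = "steelblue4", xaxt = "n", xlab = "",
       ylab = expression(-log[10](hat(P))), ylim = ylim,
       main = "Estimated P-values with confidence bounds",
       xlim = c(0.5, length(y) + 0.5))
  graphics::axis(1, at = x, labels = labs, las = 2, cex.axis = 0.8)
  has_ci <- !is.na(ylo) & !is.na(yhi) & (yhi > ylo)
  if (any(has_ci)) {
    graphics::arrows(x[has_ci], cap(ylo)[has_ci], x[has_ci], cap(yhi)[has_ci],
                     angle = 90, code = 3, length = 0.05, col = "grey40")
  }
  invisible(list(ylim = ylim))
}
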