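# Internal helpers: condition constructors and scoped RNG control.

pt_error <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "permtail_error", "error"),
                      call = call))
}

#' Evaluate an expression under a temporary random seed
#'
#' Seed semantics follow the tool's input convention: a seed of 0 means
#' "use whatever entropy the session has" (no seeding, not reproducible);
#' a seed of 1 or larger seeds the generator locally and restores the
#' previous RNG state afterwards, so reproducible runs do not perturb the
#' caller's random stream.
#'
#' @param seed Integer scalar, 0 for no seeding.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed) || is.na(seed) || seed == 0) {
    return(force(code))
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic sub-seed derivation so that independent random stages
# (confidence-interval bootstrap, subsample bootstrap, transform search)
# use distinct, reproducible streams. Seed 0 stays 0 (entropy).
derive_seed <- function(seed, k) {
  if (is.null(seed) || seed == 0) return(0L)
  as.integer((as.numeric(seed) * 1009 + 97 * k) %% 2147483646 + 1)
}

# Content-addressed per-column seed: depends on the column's values, not its
# position in the table, so reordering input columns permutes outputs exactly.
column_seed <- function(seed, column) {
  if (is.null(seed) || seed == 0) return(0L)
  h <- sum(abs(column$values) %% 997) + abs(column$x0) %% 997
  as.integer((as.numeric(seed) * 2017 + floor(h * 1e4)) %% 2147483646 + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
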