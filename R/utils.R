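#' @keywords internal
"_PACKAGE"

# Deterministic sub-seed derivation: every stage draws its randomness from a
# seed derived from the global seed plus a short text tag, so stages can be
# re-run in isolation and results do not depend on call order.
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(tag))
  h <- 0
  for (k in utf8ToInt(paste(tag, collapse = "/"))) {
    h <- (h * 131 + k) %% 2147483399
  }
  s <- (as.double(seed) %% 2147483399) * 48271 + h
  as.integer(s %% 2147483399) + 1L
}

# Evaluate `expr` with the RNG set from a derived seed, restoring the caller's
# RNG state afterwards so library code never perturbs user-level randomness.
with_seed <- function(seed, tag, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(derive_seed(seed, tag))
  expr
}

# Stage-level logging. message() based so tests can capture/suppress it.
mr_log <- function(...) {
  message("[mrpipe] ", ...)
}

# Descending rank order with deterministic lexicographic tie-break on ids.
# radix method gives a platform-independent C-locale comparison.
rank_order <- function(score, id) {
  order(-score, id, method = "radix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("'%s' must be a single value in [0, 1]", name), call. = FALSE)
  }
  invisible(x)
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    stop(sprintf("'%s' must be a single integer >= %d", name, min), call. = FALSE)
  }
  invisible(as.integer(x))
}
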