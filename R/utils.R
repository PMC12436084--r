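# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG state, restoring the caller's state
# afterwards. Quasi-Monte-Carlo normal probabilities consume R's RNG; pinning
# the state makes every integration bit-reproducible.
with_fixed_rng <- function(expr, seed = 190701L) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(expr)
}

mvn_maxpts <- function() {
  getOption("mamsdelay.maxpts", 100000L)
}

mvn_abseps <- function() {
  getOption("mamsdelay.abseps", 1e-6)
}

stopifnot_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be positive", name), call. = FALSE)
  invisible(x)
}

# Small FNV-1a style hash of a config object, for provenance headers only.
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  h <- 216613626
  for (ch in utf8ToInt(s)) {
    h <- bitwXor(h, ch)
    h <- (h * 16777619) %% 2147483647
  }
  sprintf("%08x", h)
}

# Package-level memo for expensive calibrations. Keys are deterministic
# strings built from the design signature; values are pure function results,
# so memoisation never changes numbers, only avoids recomputation.
.mams_cache <- new.env(parent = emptyenv())

#' Clear the internal calibration cache
#'
#' Boundary, group-size and single-stage calibrations are memoised per design
#' signature to avoid recomputing identical root searches (e.g. across the
#' cells of a scenario grid). The cache is keyed on all inputs that affect the
#' result, so clearing it is never required for correctness.
#'
#' @return Invisibly, the number of entries removed.
#' @export
mams_cache_clear <- function() {
  n <- length(ls(.mams_cache))
  rm(list = ls(.mams_cache), envir = .mams_cache)
  invisible(n)
}

cache_get_or <- function(key, compute) {
  if (!is.null(.mams_cache[[key]])) return(.mams_cache[[key]])
  val <- compute()
  .mams_cache[[key]] <- val
  val
}

fmt_num <- function(x, digits = 4) formatC(x, format = "f", digits = digits)
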