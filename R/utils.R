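#' Gas constant in kcal mol-1 K-1
#'
#' All energies in this package are kcal/mol and all temperatures Kelvin;
#' this value of R keeps the two consistent.
#'
#' @export
RGAS <- 1.987204e-3

`%||%` <- function(a, b) if (is.null(a)) b else a

## classed conditions so the command-line wrapper can map them to exit codes
usageError <- function(msg, call. = FALSE) {
  stop(errorCondition(msg, class = c("dsfddg_usage_error", "error")))
}

dataError <- function(msg) {
  stop(errorCondition(msg, class = c("dsfddg_data_error", "error")))
}

#' Run code with a temporary RNG seed
#'
#' Sets the RNG seed, evaluates `expr`, and restores the previous RNG state,
#' so seeded simulation never disturbs the caller's random stream.
#'
#' @param seed integer seed
#' @param expr expression to evaluate
#' @return the value of `expr`
#' @keywords internal
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a well- or stream-specific seed from a master seed
#'
#' Deterministic 31-bit hash of a master seed plus a string key, used to give
#' every simulated well and every Monte-Carlo chain its own reproducible
#' stream. No hidden global state: identical (seed, key) always yields the
#' same stream seed.
#'
#' @param seed master integer seed
#' @param key character key identifying the stream (e.g. "WT:alpha-T:0:1")
#' @return an integer in [1, 2^31 - 2]
#' @keywords internal
deriveSeed <- function(seed, key) {
  m <- 2147483647  # 2^31 - 1, Mersenne prime
  h <- as.numeric(seed) %% m
  for (cp in utf8ToInt(paste0(key))) {
    h <- (h * 31 + cp) %% m
  }
  as.integer(h %% (m - 2L) + 1L)
}

## full-precision numeric formatting for deterministic text tables
fmtNum <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.17g", x))
}

stopifnotScalarNum <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    usageError(sprintf("'%s' must be a single finite number", name))
  }
}
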