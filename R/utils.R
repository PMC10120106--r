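#' @keywords internal
"_PACKAGE"

#' Evaluate an expression under a fixed RNG seed
#'
#' Sets the random seed for the duration of `expr` and restores the caller's
#' RNG state afterwards, so simulation functions are reproducible without
#' clobbering the session RNG.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
local_seed <- function(seed, expr) {
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
  set.seed(seed)
  expr
}

# Derive a deterministic sub-stream seed per output kind, so e.g. adding taxa
# to the community simulation does not reshuffle the gene trees. Kept below
# 2^31 - 1 (R integer range).
sub_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) %% 1000003) * 2011 + offset * 7919) %% 2147483647L
}

#' Format a count as a percentage of a total
#'
#' The single reporting path used for every fraction the package prints:
#' `100 * count / total`, rounded half-to-even at the requested number of
#' decimals (the behaviour of base [round()]).
#'
#' @param count Numerator count (non-negative).
#' @param total Denominator count (positive).
#' @param digits Decimals to keep (default 2).
#' @return Numeric percentage rounded to `digits` decimals.
#' @examples
#' fmt_percent(185, 24325)     # 0.76
#' fmt_percent(205, 3791, 1)   # 5.4
#' @export
fmt_percent <- function(count, total, digits = 2) {
  stopifnot(is.numeric(count), is.numeric(total), total > 0, count >= 0)
  round(100 * count / total, digits)
}

# stop() with a consistent condition class so callers/tests can distinguish
# bad configuration from bad data.
config_error <- function(msg) {
  stop(errorCondition(msg, class = c("endopan_config_error", "error")))
}

data_error <- function(msg) {
  stop(errorCondition(msg, class = c("endopan_data_error", "error")))
}
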