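#' Round half away from zero
#'
#' Rounds to `digits` decimal places with ties going away from zero
#' (so 0.05 -> 0.1 and -0.05 -> -0.1), the convention used for every
#' percentage printed by the reporting functions. Base R's `round()`
#' rounds half to even and would disagree on exact ties.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half away from zero.
#' @export
#' @examples
#' round_half_away(75.55, 1)  # 75.6, not 75.5
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Fixed one-decimal percentage
#'
#' @param numerator,denominator counts; `denominator` must be positive.
#' @param digits decimal places (default 1).
#' @return `100 * numerator / denominator` rounded half away from zero.
#' @export
#' @examples
#' percent(959, 1270)   # 75.5
#' percent(1201, 1264)  # 95.0
percent <- function(numerator, denominator, digits = 1) {
  if (any(denominator <= 0)) stop("percent(): denominator must be > 0")
  round_half_away(100 * numerator / denominator, digits)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# shared validation helper
.check_strand <- function(strand) {
  if (!all(strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  invisible(strand)
}
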