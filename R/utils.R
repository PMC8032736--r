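#' Derive a child seed from a master seed
#'
#' Each generator in the package draws from its own RNG stream, split off a
#' master seed, so adding or reordering one generator never perturbs the draws
#' of another. The split is a small multiplicative hash kept below 2^31 - 1 so
#' it is always a valid R integer seed.
#'
#' @param seed master seed (single integer).
#' @param stream stream label (character), e.g. `"climate"`.
#' @return An integer seed.
#' @export
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  h <- 0
  for (ch in utf8ToInt(stream)) h <- (h * 31 + ch) %% 2147483647
  as.integer((abs(seed) * 48271 + h) %% 2147483647)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# days since Jan 1 (day-of-year), for the inclusive summer compositing window
day_of_year <- function(date) {
  as.integer(strftime(as.Date(date), "%j"))
}
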