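#' Derive a named RNG sub-seed from a master seed
#'
#' Every stochastic output in the package draws from its own named stream so
#' that adding a stage to the pipeline never shifts the draws of another.
#' The sub-seed is the first 7 hex digits of the MD5 of `"<seed>/<name>"`,
#' which always fits a 32-bit R integer.
#'
#' @param seed integer master seed.
#' @param name character stream name, e.g. `"phantom/noise"`.
#' @return an integer usable with [set.seed()].
#' @export
sub_seed <- function(seed, name) {
  stopifnot(length(seed) == 1L, is.finite(seed), is.character(name))
  h <- digest::digest(paste(as.integer(seed), name, sep = "/"), algo = "md5")
  strtoi(substr(h, 1L, 7L), base = 16L)
}

#' Round half away from zero
#'
#' Unlike [round()] (banker's rounding), ties go away from zero, so that
#' e.g. 30.25 rounds to 30.3 at one decimal. This is the convention needed
#' to reproduce published one-decimal histology averages.
#'
#' @param x numeric.
#' @param digits integer number of decimal places.
#' @return rounded numeric.
#' @export
round_half_away <- function(x, digits = 1L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# stop() with a consistent prefix and no call
abort <- function(...) stop(..., call. = FALSE)

is_count <- function(x) length(x) == 1L && is.finite(x) && x == as.integer(x) && x >= 1
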