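# Shared numerical helpers.

# 97.5% normal quantile, fixed at full precision; display rounding happens
# only at the reporting layer.
Z975 <- 1.959964

#' Round half away from zero to integer
#'
#' Base R `round()` rounds half to even; summary-of-findings tables use the
#' conventional half-up rule (154.5 -> 155).
#'
#' @param x numeric vector.
#' @return integer-valued numeric vector.
#' @keywords internal
round_half_up <- function(x) floor(x + 0.5)

# Deterministic per-trial substream seed derived from a master seed, so any
# single trial can be regenerated in isolation.  Kept below 2^31 - 1.
substream_seed <- function(master_seed, index) {
  m <- 2147483647 # 2^31 - 1; keeps derived seeds valid 32-bit integers
  s <- (as.numeric(master_seed) %% m) * 48271 %% m
  as.integer((s + index * 7919) %% m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_binary_or_na <- function(x) all(is.na(x) | x %in% c(0, 1))
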