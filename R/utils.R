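#' @keywords internal
mod180 <- function(a) a %% 180

stop_if_not_finite <- function(x, what) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x)))
    stop(sprintf("%s must be finite numeric", what), call. = FALSE)
  invisible(x)
}

#' Derive a reproducible sub-seed from a master seed and a counter
#'
#' Counter-based splitting so that regenerating one element of a cohort does
#' not shift the random streams of the others. Kept below 2^31 - 1.
#'
#' @param seed master seed (integer)
#' @param counter non-negative integer index
#' @return an integer seed
#' @keywords internal
sub_seed <- function(seed, counter) {
  as.integer((as.numeric(seed) + 7919 * (as.numeric(counter) + 1)) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
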