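# Internal helpers shared across modules.

#' Clamp values into an interval
#' @noRd
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Shift a matrix along the y (first) dimension, zero-filling.
#'
#' `shift_y(m, k)[y, z]` equals `m[y + k, z]` where defined and 0 elsewhere,
#' so a positive `k` looks posteriorly.  Out-of-image neighbours therefore
#' contribute gray level 0 (air-like) to windowed fitness terms.
#' @noRd
shift_y <- function(m, k) {
  W <- nrow(m)
  out <- matrix(0, W, ncol(m))
  if (k == 0) return(m + 0)
  if (abs(k) >= W) return(out)
  if (k > 0) {
    out[seq_len(W - k), ] <- m[(k + 1):W, ]
  } else {
    out[(-k + 1):W, ] <- m[seq_len(W + k), ]
  }
  out
}

#' Centered moving average with window truncation at the ends
#' @noRd
moving_average <- function(x, width) {
  n <- length(x)
  half <- (width - 1) %/% 2
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Stop unless a condition holds
#' @noRd
assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}
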