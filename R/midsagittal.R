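# Symmetry-based selection of the midsagittal slice.
#
# The vertebral column and cord are bilaterally symmetric about the intact
# midsagittal plane, so the slice position k_MSP closest to it minimises the
# mean pairwise asymmetry over mirror-image pairs (j, 2k - j).

#' Asymmetry metric between two slices
#'
#' The difference between two images is quantified as the population
#' standard deviation of the per-pixel signed gray-level differences.  It is
#' symmetric, zero for identical images, and invariant to adding a constant
#' to every pixel of either image.
#'
#' @param a,b [gray_image()] slices of equal dimensions.
#' @return non-negative numeric scalar.
#' @export
image_difference <- function(a, b) {
  if (a$width_y != b$width_y || a$height_z != b$height_z)
    stop("image dimensions differ")
  d <- as.numeric(a$pixels) - as.numeric(b$pixels)
  sqrt(mean(d^2) - mean(d)^2)
}

# Mirror pairs (j, 2k - j) with j < 2k - j and both indices in [1, K].
mirror_pairs <- function(k, K) {
  j <- seq_len(K)
  j2 <- round(2 * k - j)
  keep <- j < j2 & j2 >= 1 & j2 <= K
  cbind(j = j[keep], j2 = j2[keep])
}

#' Select the midsagittal slice of a series
#'
#' Evaluates every integer and half-integer candidate position k for which
#' at least four mirror-image pairs are available (for the standard 13-slice
#' series this is the grid 4, 4.5, ..., 10, counting the degenerate self-pair
#' of an integer candidate toward availability but never toward the score).
#' Each candidate is scored by the mean [image_difference()] over its pairs
#' `(j, 2k - j)`; the candidate with the smallest mean asymmetry wins.  An
#' integer winner designates one slice, a half-integer winner the two slices
#' on either side of the symmetry plane.
#'
#' @param series a [sagittal_series()].
#' @return An object of class `msp_candidate` with fields `k_msp`, `score`,
#'   `m` (number of scored pairs), `indices` (one or two slice indices) and
#'   `score_table` (a data frame of all candidate scores).
#' @export
select_kmsp <- function(series) {
  K <- series$K
  ks <- seq(1, K, by = 0.5)
  avail <- vapply(ks, function(k) {
    nrow(mirror_pairs(k, K)) + as.integer(k == round(k))
  }, numeric(1))
  ks <- ks[avail >= 4]
  if (length(ks) == 0)
    stop("fewer than 4 mirror-image pairs available for every candidate")

  # cache D for the pairs we need
  dcache <- new.env(parent = emptyenv())
  D <- function(p, q) {
    key <- paste(p, q)
    if (!is.null(dcache[[key]])) return(dcache[[key]])
    v <- image_difference(series$slices[[p]], series$slices[[q]])
    dcache[[key]] <- v
    v
  }
  rows <- lapply(ks, function(k) {
    prs <- mirror_pairs(k, K)
    sc <- mean(vapply(seq_len(nrow(prs)),
                      function(i) D(prs[i, 1], prs[i, 2]), numeric(1)))
    data.frame(k = k, score = sc, m = nrow(prs))
  })
  tab <- do.call(rbind, rows)
  best <- which.min(tab$score)
  k_msp <- tab$k[best]
  indices <- if (k_msp == round(k_msp)) as.integer(k_msp)
             else as.integer(c(floor(k_msp), ceiling(k_msp)))
  structure(list(k_msp = k_msp, score = tab$score[best], m = tab$m[best],
                 indices = indices, score_table = tab),
            class = "msp_candidate")
}

#' @export
print.msp_candidate <- function(x, ...) {
  cat(sprintf("<msp_candidate> k_MSP = %g (slices %s), score = %.3f over %d pairs\n",
              x$k_msp, paste(x$indices, collapse = ", "), x$score, x$m))
  invisible(x)
}
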