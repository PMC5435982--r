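# Fitness functions f1-f5 and detection of the first five structures:
#   B1  coarse spinal cord  (longest isointense structure of sufficient depth)
#   B2  refined spinal cord (most homogeneous path near B1)
#   B3  posterior longitudinal ligament (PLL), anterior canal edge
#   B4  ligamentum flavum (LF), posterior canal edge
#   B5  anterior longitudinal ligament (ALL), anterior column edge
#
# All windowed fitness terms treat out-of-image neighbours as gray level 0
# (air-like) and as non-isointense: the image borders are air in this
# acquisition.

#' Isointense-run fitness (f1)
#'
#' Counts the isointense pixels among the five y-neighbours centred at each
#' pixel; values range 0..5.
#'
#' @param img a [gray_image()].
#' @param cmap class map from [class_map()].
#' @return A [fitness_field()].
#' @export
fitness_f1 <- function(img, cmap) {
  u <- (cmap == "iso") * 1
  v <- shift_y(u, -2) + shift_y(u, -1) + u + shift_y(u, 1) + shift_y(u, 2)
  fitness_field(v, "f1")
}

#' Detect the coarse cord path B1
#'
#' Full-image DP on [fitness_f1()]: the cord is the only isointense
#' structure traversing the image vertically, so the path collecting the
#' most isointense 5-pixel runs follows it.  A path with total 0 (no
#' isointense pixels anywhere) is flagged with attribute
#' `low_confidence = TRUE`.
#'
#' @inheritParams fitness_f1
#' @return A [path_curve()].
#' @export
detect_B1 <- function(img, cmap) {
  f <- fitness_f1(img, cmap)
  b <- band_bounds(1, img$height_z, 1, img$width_y)
  curve <- find_best_path(f, b)
  if (path_total(f, curve) == 0) attr(curve, "low_confidence") <- TRUE
  curve
}

#' Local-homogeneity fitness (f2)
#'
#' Sums, over the six consecutive-pixel pairs spanning y-3..y+3, the term
#' `65536 - (I[y+j+1] - I[y+j])^2`; the constant makes the field positive
#' everywhere, and locally constant intensity attains the maximum 393216.
#'
#' @param img a [gray_image()].
#' @return A [fitness_field()].
#' @export
fitness_f2 <- function(img) {
  I <- img$pixels + 0
  v <- matrix(0, nrow(I), ncol(I))
  for (j in -3:2) {
    d <- shift_y(I, j + 1) - shift_y(I, j)
    v <- v + (65536 - d^2)
  }
  fitness_field(v, "f2")
}

#' Detect the refined cord path B2
#'
#' DP on [fitness_f2()] restricted to the per-row band `B1 - 40 .. B1 + 40`:
#' the most homogeneous isointense structure near the coarse cord path.
#' Neither B1 nor B2 need be a centerline; B2 only has to stay inside the
#' cord.
#'
#' @param img a [gray_image()].
#' @param B1 coarse cord path from [detect_B1()].
#' @return A [path_curve()].
#' @export
detect_B2 <- function(img, B1) {
  f <- fitness_f2(img)
  b <- band_bounds(1, img$height_z, B1$values - 40L, B1$values + 40L)
  find_best_path(f, b)
}

#' Pick the more stable of two candidate midsagittal slices
#'
#' When symmetry selection returns a half-integer position, the two
#' neighbouring slices are arbitrated by the stability of the signal
#' intensity along their refined cord paths: for each candidate the absolute
#' deviations of the path pixels from their 31-point moving average are
#' summed over the lower two-thirds of the image, and the smaller sum wins
#' (ties go to the first candidate).
#'
#' @param imgs list of one or two [gray_image()] slices.
#' @param B2s list of matching refined cord paths.
#' @return index (1 or 2) of the chosen candidate.
#' @export
choose_candidate_slice <- function(imgs, B2s) {
  if (length(imgs) == 1) return(1L)
  stability <- vapply(seq_along(imgs), function(i) {
    img <- imgs[[i]]; B2 <- B2s[[i]]
    zs <- B2$z_sup:B2$z_inf
    si <- img$pixels[cbind(B2$values, zs)] + 0
    ma <- moving_average(si, 31L)
    lower <- zs >= ceiling(img$height_z / 3) + 1L
    sum(abs(si - ma)[lower])
  }, numeric(1))
  as.integer(which.min(stability))   # which.min: ties -> first
}

#' Darkness fitness for the ligaments (f3 = f4)
#'
#' `(256 - I)^2`: hypointense ligament pixels score high.
#'
#' @param img a [gray_image()].
#' @return A [fitness_field()].
#' @export
fitness_f3f4 <- function(img) {
  fitness_field((256 - (img$pixels + 0))^2, "f3f4")
}

#' Detect the PLL (B3) and LF (B4) paths
#'
#' Two DP runs on [fitness_f3f4()] in bands defined relative to the cord:
#' `B2 - 30 .. B2 - 1` anteriorly for the PLL and `B2 + 1 .. B2 + 30`
#' posteriorly for the LF, reflecting the normal canal depth of 22-30
#' pixels.  Anchoring the bands on the detected cord keeps other
#' hypointense structures from becoming the optimum.
#'
#' @param img a [gray_image()].
#' @param B2 refined cord path.
#' @return list with elements `B3` and `B4` ([path_curve()]s).
#' @export
detect_B3_B4 <- function(img, B2) {
  f <- fitness_f3f4(img)
  b3 <- band_bounds(1, img$height_z, B2$values - 30L, B2$values - 1L)
  b4 <- band_bounds(1, img$height_z, B2$values + 1L, B2$values + 30L)
  list(B3 = find_best_path(f, b3), B4 = find_best_path(f, b4))
}

#' Dark-line-plus-marrow fitness for the ALL (f5)
#'
#' The air-filled trachea lies just anterior to the ALL, so darkness alone
#' is ambiguous; the fitness adds the squared intensities of the 16 pixels
#' posterior to each candidate, rewarding positions backed by isointense
#' vertebral bone marrow: `(256 - I)^2 + sum_{j=1..16} I[y+j]^2`.
#'
#' @param img a [gray_image()].
#' @return A [fitness_field()].
#' @export
fitness_f5 <- function(img) {
  I <- img$pixels + 0
  v <- (256 - I)^2
  for (j in 1:16) v <- v + shift_y(I, j)^2
  fitness_field(v, "f5")
}

#' Detect the approximate ALL path B5
#'
#' DP on [fitness_f5()] in the band `B3 - 60 .. B3 - 21`, one vertebral-body
#' depth anterior to the PLL.
#'
#' @param img a [gray_image()].
#' @param B3 PLL path.
#' @return A [path_curve()].
#' @export
detect_B5 <- function(img, B3) {
  f <- fitness_f5(img)
  b <- band_bounds(1, img$height_z, B3$values - 60L, B3$values - 21L)
  find_best_path(f, b)
}

#' Detect the cord, canal-edge and column-edge structures on one slice
#'
#' Runs the B1..B5 chain and returns all curves together with the class map
#' used.  Row-wise anterior-to-posterior ordering B5 < B3 < B2 < B4 holds by
#' construction of the bands and is asserted.
#'
#' @param img a [gray_image()].
#' @param fit a classified, repaired `gmm_fit`.
#' @return An object of class `structure_set` with fields `B1`..`B5`,
#'   `cmap` and `fit`.
#' @export
detect_structures <- function(img, fit) {
  cmap <- class_map(img, fit)
  B1 <- detect_B1(img, cmap)
  B2 <- detect_B2(img, B1)
  lig <- detect_B3_B4(img, B2)
  B5 <- detect_B5(img, lig$B3)
  assert_that(all(B5$values < lig$B3$values) &&
              all(lig$B3$values < B2$values) &&
              all(B2$values < lig$B4$values),
              "structure ordering B5 < B3 < B2 < B4 violated")
  structure(list(B1 = B1, B2 = B2, B3 = lig$B3, B4 = lig$B4, B5 = B5,
                 cmap = cmap, fit = fit),
            class = "structure_set")
}
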