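# Median cord-intensity profile and the compound fitness functions f7/f8
# detecting the anterior (B7) and posterior (B8) edges of the spinal cord.

PROFILE_Y_HALFWIDTH <- 5L
PROFILE_Z_HALFWIDTH <- 15L
NONCORD_PENALTY <- 65536   # dominates any single squared-difference term

#' Median cord gray-level profile c_z
#'
#' Radiofrequency inhomogeneity, saturation bands and operator windowing
#' modulate the cord signal along its course, so the cord reference
#' intensity is taken per row as the median of the hypointense and
#' isointense pixels within an 11 x 31 window around the refined cord path
#' (B2 +/- 5 in y, z +/- 15 in z, truncated at the canal and image
#' borders).  The median suppresses noise and the occasional hyperintense
#' outlier.  Rows whose window holds no eligible pixel copy the value of
#' the nearest defined row, with a warning.
#'
#' @param img a [gray_image()].
#' @param B2 refined cord path.
#' @param cmap class map from [class_map()].
#' @param canal integer `(z_sup, z_inf)` canal extent.
#' @return An object of class `cord_profile`: numeric vector `c` indexed by
#'   canal row, plus the extent.
#' @export
median_cord_profile <- function(img, B2, cmap, canal) {
  z_sup <- canal[1]; z_inf <- canal[2]
  zs <- z_sup:z_inf
  cz <- rep(NA_real_, length(zs))
  for (i in seq_along(zs)) {
    z <- zs[i]
    ywin <- clamp((path_at(B2, z) - PROFILE_Y_HALFWIDTH):
                  (path_at(B2, z) + PROFILE_Y_HALFWIDTH), 1L, img$width_y)
    zwin <- clamp((z - PROFILE_Z_HALFWIDTH):(z + PROFILE_Z_HALFWIDTH),
                  z_sup, z_inf)
    vals <- img$pixels[ywin, zwin]
    cls <- cmap[ywin, zwin]
    pool <- vals[cls %in% c("hypo", "iso")]
    if (length(pool) > 0) cz[i] <- stats::median(pool)
  }
  if (anyNA(cz)) {
    warning("empty cord-pixel pool in some rows; copying nearest defined row")
    def <- which(!is.na(cz))
    if (length(def) == 0) stop("no cord pixels found anywhere in the canal")
    for (i in which(is.na(cz))) cz[i] <- cz[def[which.min(abs(def - i))]]
  }
  structure(list(c = cz, z_sup = z_sup, z_inf = z_inf), class = "cord_profile")
}

# c_z expanded to a full [y, z] matrix; rows outside the canal take the
# nearest canal value (only canal rows are ever used by the DP bands).
profile_matrix <- function(profile, W, H) {
  full <- numeric(H)
  full[profile$z_sup:profile$z_inf] <- profile$c
  if (profile$z_sup > 1) full[1:(profile$z_sup - 1)] <- profile$c[1]
  if (profile$z_inf < H) full[(profile$z_inf + 1):H] <- profile$c[length(profile$c)]
  matrix(full, W, H, byrow = TRUE)
}

# Shared builder for the compound edge fitness.  `dir = +1` builds f7 (the
# cord lies posterior to the path pixel, the outside pixel is anterior);
# `dir = -1` builds f8, the mirror image.
compound_edge_fitness <- function(img, profile, cmap, dir, name) {
  I <- img$pixels + 0
  C <- profile_matrix(profile, nrow(I), ncol(I))
  S <- function(k) shift_y(I, dir * k)
  fs <- 0.5 * (S(-1) - C)^2 - 3 * (S(0) - C)^2 -
    (S(1) - C)^2 - (S(2) - C)^2 - (S(3) - C)^2
  fh <- -(S(0) - S(1))^2 - (S(0) - S(2))^2 - (S(0) - S(3))^2
  fc <- 0.5 * (S(0) - S(-1))^2
  fp <- -NONCORD_PENALTY * (cmap %in% c("hyper", "air"))
  dim(fp) <- dim(I)
  v <- fs + fh + fc + fp
  # engine contract: offset so the field is non-negative everywhere; the
  # subtracted minimum is kept as an attribute so raw values are recoverable
  out <- fitness_field(v - min(v), name)
  attr(out, "offset") <- min(v)
  out
}

#' Anterior cord-edge fitness (f7)
#'
#' Sum of four terms evaluated with the cord assumed posterior to the path
#' pixel: similarity of the pixels at y..y+3 to the median cord level c_z
#' (with the outside pixel at y-1 rewarded for differing from it),
#' homogeneity among y..y+3, contrast across the edge, and a flat penalty
#' for letting the path pass through hyperintense or air pixels.  A
#' constant offset makes the field non-negative, as the DP engine requires.
#'
#' @param img a [gray_image()].
#' @param profile a `cord_profile` from [median_cord_profile()].
#' @param cmap class map.
#' @return A [fitness_field()].
#' @export
fitness_f7 <- function(img, profile, cmap) {
  compound_edge_fitness(img, profile, cmap, +1L, "f7")
}

#' Posterior cord-edge fitness (f8)
#'
#' Identical components to [fitness_f7()] with the constituent pixels in
#' reverse y-order: the cord lies anterior to the path pixel and the
#' outside pixel is posterior.
#'
#' @inheritParams fitness_f7
#' @return A [fitness_field()].
#' @export
fitness_f8 <- function(img, profile, cmap) {
  compound_edge_fitness(img, profile, cmap, -1L, "f8")
}

#' Detect the cord edges and build the cord mask
#'
#' B7 (anterior edge) is the DP best path on f7 over the canal rows in the
#' per-row band `B3 + 1 .. B2`; B8 (posterior edge) on f8 in `B2 .. B4 - 1`.
#' The bands are anchored on the detected ligaments and cord because the
#' cord lies between PLL and LF and the refined cord path runs inside it.
#' The segmented cord is the region between the two edges, inclusive.  Rows
#' where B7 would exceed B8 (degenerate stenosis) are clamped to B2 with a
#' warning.
#'
#' @param img a [gray_image()].
#' @param st a `structure_set` (for B2, B3, B4 and the class map).
#' @param profile a `cord_profile`.
#' @param canal integer `(z_sup, z_inf)`.
#' @return An object of class `cord_segmentation`: fields `B7`, `B8`
#'   ([path_curve()]s over the canal rows) and `mask` (a [seg_mask()]).
#' @export
detect_cord_edges <- function(img, st, profile, canal) {
  z_sup <- canal[1]; z_inf <- canal[2]
  rows <- z_sup:z_inf
  f7 <- fitness_f7(img, profile, st$cmap)
  f8 <- fitness_f8(img, profile, st$cmap)
  b2 <- st$B2$values[rows]; b3 <- st$B3$values[rows]; b4 <- st$B4$values[rows]
  B7 <- find_best_path(f7, band_bounds(z_sup, z_inf, b3 + 1L, b2))
  B8 <- find_best_path(f8, band_bounds(z_sup, z_inf, b2, b4 - 1L))
  bad <- B7$values > B8$values
  if (any(bad)) {
    warning(sprintf("B7 > B8 at %d row(s); clamped to B2 (degenerate stenosis)",
                    sum(bad)))
    B7$values[bad] <- b2[bad]
    B8$values[bad] <- b2[bad]
  }
  m <- matrix(FALSE, img$width_y, img$height_z)
  for (i in seq_along(rows)) m[B7$values[i]:B8$values[i], rows[i]] <- TRUE
  structure(list(B7 = B7, B8 = B8, mask = seg_mask(m, "spinal cord")),
            class = "cord_segmentation")
}
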