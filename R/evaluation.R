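# Segmentation agreement metrics: Jaccard overlap, Dice conversion,
# Hausdorff distance between edge curves, pixel/mm conversion, and a
# majority-vote reference builder.

#' Jaccard overlap between two masks
#'
#' `J = TP / (TP + FP + FN)` over aligned binary masks.  When comparing
#' cord masks the overlap is conventionally restricted to the canal rows,
#' which `canal` enables.
#'
#' @param auto,ref [seg_mask()] objects (or logical matrices) of equal size.
#' @param canal optional `(z_sup, z_inf)` row range to restrict the
#'   comparison to.
#' @return Jaccard index in `[0, 1]`.
#' @export
jaccard <- function(auto, ref, canal = NULL) {
  a <- if (inherits(auto, "seg_mask")) auto$mask else auto
  r <- if (inherits(ref, "seg_mask")) ref$mask else ref
  if (!all(dim(a) == dim(r))) stop("mask dimensions differ")
  if (!is.null(canal)) {
    rows <- canal[1]:canal[2]
    a <- a[, rows, drop = FALSE]
    r <- r[, rows, drop = FALSE]
  }
  tp <- sum(a & r); fp <- sum(a & !r); fn <- sum(!a & r)
  if (tp + fp + fn == 0) stop("Jaccard undefined: both masks empty")
  tp / (tp + fp + fn)
}

#' Convert a Jaccard index to a Dice coefficient
#'
#' `D = 2J / (1 + J)`.
#'
#' @param j Jaccard index in `[0, 1]`.
#' @return Dice coefficient.
#' @export
dice_from_jaccard <- function(j) {
  if (any(j < 0 | j > 1)) stop("Jaccard index must lie in [0, 1]")
  2 * j / (1 + j)
}

#' Symmetric Hausdorff distance between two curves
#'
#' Curves are rasterised as integer point sets `(b_z, z)` over their common
#' z-range; the distance is the maximum of the two directed max-min
#' Euclidean distances, in pixels.
#'
#' @param a,b [path_curve()] objects with overlapping row ranges.
#' @return non-negative distance in pixels.
#' @export
hausdorff <- function(a, b) {
  z_sup <- max(a$z_sup, b$z_sup)
  z_inf <- min(a$z_inf, b$z_inf)
  if (z_sup > z_inf) stop("curves share no rows")
  zs <- z_sup:z_inf
  pa <- cbind(path_at(a, zs), zs)
  pb <- cbind(path_at(b, zs), zs)
  d2 <- outer(pa[, 1], pb[, 1], "-")^2 + outer(pa[, 2], pb[, 2], "-")^2
  sqrt(max(apply(d2, 1, min), apply(d2, 2, min)))
}

#' Convert pixels to millimetres
#'
#' @param v value in pixels.
#' @param resolution_mm pixel size (default 0.6875 mm).
#' @return value in millimetres.
#' @export
px_to_mm <- function(v, resolution_mm = DEFAULT_RESOLUTION_MM) {
  if (resolution_mm <= 0) stop("`resolution_mm` must be positive")
  v * resolution_mm
}

#' Majority-vote reference mask from several manual segmentations
#'
#' A pixel belongs to the reference when more than half of the input masks
#' contain it.
#'
#' @param masks list of at least 3 [seg_mask()] objects (or logical
#'   matrices) of equal size.
#' @return A [seg_mask()].
#' @export
vote_masks <- function(masks) {
  if (length(masks) < 3) stop("voting needs at least 3 masks")
  ms <- lapply(masks, function(m) if (inherits(m, "seg_mask")) m$mask else m)
  tot <- Reduce(`+`, ms)
  seg_mask(tot > length(ms) / 2, "majority vote")
}

#' Full agreement report between an automatic and a reference segmentation
#'
#' @param auto_mask,ref_mask cord masks.
#' @param auto_curves,ref_curves optional lists with elements `anterior` and
#'   `posterior` ([path_curve()]s) for the Hausdorff distances.
#' @param canal optional canal extent for the overlap restriction.
#' @param resolution_mm pixel size for the mm conversions.
#' @return An object of class `agreement_report`.
#' @export
agreement_report <- function(auto_mask, ref_mask, auto_curves = NULL,
                             ref_curves = NULL, canal = NULL,
                             resolution_mm = DEFAULT_RESOLUTION_MM) {
  j <- jaccard(auto_mask, ref_mask, canal)
  rep <- list(jaccard = j, dice = dice_from_jaccard(j),
              n_auto = sum(if (inherits(auto_mask, "seg_mask"))
                auto_mask$mask else auto_mask),
              n_ref = sum(if (inherits(ref_mask, "seg_mask"))
                ref_mask$mask else ref_mask))
  if (!is.null(auto_curves) && !is.null(ref_curves)) {
    ha <- hausdorff(auto_curves$anterior, ref_curves$anterior)
    hp <- hausdorff(auto_curves$posterior, ref_curves$posterior)
    rep$hausdorff_anterior_px <- ha
    rep$hausdorff_posterior_px <- hp
    rep$hausdorff_anterior_mm <- px_to_mm(ha, resolution_mm)
    rep$hausdorff_posterior_mm <- px_to_mm(hp, resolution_mm)
  }
  structure(rep, class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report> J = %.3f, D = %.3f", x$jaccard, x$dice))
  if (!is.null(x$hausdorff_anterior_px))
    cat(sprintf(", Hausdorff ant/post = %.2f/%.2f px (%.2f/%.2f mm)",
                x$hausdorff_anterior_px, x$hausdorff_posterior_px,
                x$hausdorff_anterior_mm, x$hausdorff_posterior_mm))
  cat("\n")
  invisible(x)
}
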