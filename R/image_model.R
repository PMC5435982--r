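# Core raster types and readers/writers.
#
# Coordinate convention used throughout the package:
#   * y increases anterior -> posterior and indexes matrix ROWS,
#   * z increases superior -> inferior and indexes matrix COLUMNS,
#   * both are 1-based, matching the on-image coordinates 1 <= y, z <= 320.
# JSON sidecars written for interoperability store curves 0-based.

CONFORMANT_SIZE <- 320L
DEFAULT_RESOLUTION_MM <- 0.6875

#' Construct a grayscale sagittal slice
#'
#' A `gray_image` holds one 2D sagittal slice as an integer matrix `pixels`
#' indexed `[y, z]`, with y running anterior to posterior and z superior to
#' inferior.  Gray levels are 8-bit (0-255).
#'
#' @param pixels integer matrix of gray levels in `[0, 255]`, indexed `[y, z]`.
#' @param resolution_mm isotropic in-plane pixel size in millimetres.
#' @return An object of class `gray_image` with fields `pixels`,
#'   `width_y`, `height_z` and `resolution_mm`.
#' @export
gray_image <- function(pixels, resolution_mm = DEFAULT_RESOLUTION_MM) {
  if (!is.matrix(pixels)) stop("`pixels` must be a matrix")
  if (anyNA(pixels)) stop("`pixels` must not contain NA")
  if (min(pixels) < 0 || max(pixels) > 255)
    stop("pixel values must lie in [0, 255]")
  if (resolution_mm <= 0) stop("`resolution_mm` must be positive")
  storage.mode(pixels) <- "integer"
  if (nrow(pixels) != CONFORMANT_SIZE || ncol(pixels) != CONFORMANT_SIZE)
    message(sprintf("non-conformant image size %d x %d (expected 320 x 320)",
                    nrow(pixels), ncol(pixels)))
  structure(
    list(pixels = pixels,
         width_y = nrow(pixels),
         height_z = ncol(pixels),
         resolution_mm = resolution_mm),
    class = "gray_image")
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image> %d x %d px, %.4f mm/px, gray range [%d, %d]\n",
              x$width_y, x$height_z, x$resolution_mm,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Construct an ordered sagittal series
#'
#' @param slices list of [gray_image()] slices, ordered by acquisition index.
#' @param slice_thickness_mm,gap_mm acquisition geometry metadata.
#' @return An object of class `sagittal_series`.
#' @export
sagittal_series <- function(slices, slice_thickness_mm = 3, gap_mm = 0.33) {
  if (length(slices) < 1) stop("a series needs at least one slice")
  dims <- vapply(slices, function(s) c(s$width_y, s$height_z), numeric(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all slices in a series must share dimensions")
  structure(
    list(slices = slices, K = length(slices),
         slice_thickness_mm = slice_thickness_mm, gap_mm = gap_mm),
    class = "sagittal_series")
}

#' @export
print.sagittal_series <- function(x, ...) {
  cat(sprintf("<sagittal_series> K = %d slices of %d x %d px\n",
              x$K, x$slices[[1]]$width_y, x$slices[[1]]$height_z))
  invisible(x)
}

#' Construct a continuous path curve
#'
#' A path curve stores one y-coordinate per image row over an inclusive row
#' range `[z_sup, z_inf]`; consecutive values may differ by at most one pixel.
#'
#' @param z_sup,z_inf inclusive row range (superior, inferior).
#' @param values integer y-coordinates `b_z`, one per row.
#' @return An object of class `path_curve`.
#' @export
path_curve <- function(z_sup, z_inf, values) {
  z_sup <- as.integer(z_sup); z_inf <- as.integer(z_inf)
  if (z_sup > z_inf) stop("z_sup must not exceed z_inf")
  values <- as.integer(values)
  if (length(values) != z_inf - z_sup + 1L)
    stop("`values` must contain one y per row in [z_sup, z_inf]")
  if (length(values) > 1 && any(abs(diff(values)) > 1L))
    stop("path violates continuity: |b[z+1] - b[z]| must be <= 1")
  structure(list(z_sup = z_sup, z_inf = z_inf, values = values),
            class = "path_curve")
}

#' @export
print.path_curve <- function(x, ...) {
  cat(sprintf("<path_curve> rows %d..%d, y in [%d, %d]\n",
              x$z_sup, x$z_inf, min(x$values), max(x$values)))
  invisible(x)
}

#' Look up the y-coordinate of a path at given rows
#' @param curve a [path_curve()].
#' @param z integer row(s) within `[z_sup, z_inf]`.
#' @return integer y-coordinates.
#' @export
path_at <- function(curve, z) {
  if (any(z < curve$z_sup | z > curve$z_inf))
    stop("row outside the curve's range")
  curve$values[z - curve$z_sup + 1L]
}

#' Construct a binary segmentation mask
#'
#' @param mask logical matrix aligned with a [gray_image()] (indexed `[y, z]`).
#' @param label structure name.
#' @return An object of class `seg_mask`.
#' @export
seg_mask <- function(mask, label = "structure") {
  if (!is.matrix(mask)) stop("`mask` must be a matrix")
  mode(mask) <- "logical"
  structure(list(mask = mask, label = label), class = "seg_mask")
}

#' Read an ordered sagittal series from image files
#'
#' Reads a directory of PNG slices (sorted by the numeric index embedded in
#' their file names, falling back to lexicographic order) or a single PNG
#' file.  Color input is converted to grayscale with a warning.
#'
#' @param path directory containing PNG files, or one PNG file.
#' @param resolution_mm pixel size in millimetres.
#' @return A [sagittal_series()].
#' @export
read_series <- function(path, resolution_mm = DEFAULT_RESOLUTION_MM) {
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.png$", ignore.case = TRUE,
                        full.names = TRUE)
    if (length(files) == 0) stop("no images found in ", path)
    idx <- suppressWarnings(as.numeric(gsub("\\D", "", basename(files))))
    files <- if (anyNA(idx)) sort(files) else files[order(idx)]
  } else if (file.exists(path)) {
    files <- path
  } else stop("no images found at ", path)
  slices <- lapply(files, function(f) {
    arr <- png::readPNG(f)
    if (length(dim(arr)) == 3) {
      warning("non-grayscale input converted to grayscale: ", basename(f))
      arr <- apply(arr[, , 1:min(3, dim(arr)[3]), drop = FALSE], c(1, 2), mean)
    }
    gray_image(t(round(arr * 255)), resolution_mm = resolution_mm)
  })
  sagittal_series(slices)
}

#' Write a segmentation mask as a PNG with a JSON sidecar
#'
#' The mask is written as a lossless 8-bit image (0/255).  The sidecar
#' (`<path>.json`) records the structure label and, optionally, detected
#' curves (as 0-based integer arrays) and the canal extent.
#'
#' @param mask a [seg_mask()].
#' @param path output PNG path.
#' @param curves optional named list of [path_curve()] objects.
#' @param canal optional length-2 integer vector `(z_sup, z_inf)`.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path, curves = NULL, canal = NULL) {
  png::writePNG(t(ifelse(mask$mask, 1, 0)), target = path)
  sidecar <- list(label = mask$label)
  if (!is.null(curves)) {
    sidecar$curves <- lapply(curves, function(cv) list(
      z_sup = cv$z_sup - 1L, z_inf = cv$z_inf - 1L, b = cv$values - 1L))
  }
  if (!is.null(canal)) sidecar$canal <- as.integer(canal) - 1L
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a mask written by [write_mask()]
#' @param path PNG path previously passed to [write_mask()].
#' @return A [seg_mask()]; curves and canal from the sidecar are attached as
#'   attributes `curves` and `canal` (converted back to 1-based).
#' @export
read_mask <- function(path) {
  arr <- png::readPNG(path)
  m <- seg_mask(t(arr > 0.5))
  sidecar_path <- paste0(path, ".json")
  if (file.exists(sidecar_path)) {
    sc <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
    m$label <- sc$label
    if (!is.null(sc$curves))
      attr(m, "curves") <- lapply(sc$curves, function(cv)
        path_curve(cv$z_sup + 1L, cv$z_inf + 1L, cv$b + 1L))
    if (!is.null(sc$canal)) attr(m, "canal") <- as.integer(sc$canal) + 1L
  }
  m
}

#' Convert between on-image and 0-based coordinates
#'
#' The package works in the image's native 1-based `(y, z)` coordinates;
#' sidecar files use 0-based arrays.  These helpers are the documented
#' bijection between the two.
#'
#' @param y_paper,z_paper 1-based coordinates.
#' @param width_y,height_z image dimensions used for bounds checking.
#' @return `to_internal_coords`: integer vector `(y0, z0)` (0-based);
#'   `from_internal_coords`: integer vector `(y, z)` (1-based).
#' @export
to_internal_coords <- function(y_paper, z_paper,
                               width_y = CONFORMANT_SIZE,
                               height_z = CONFORMANT_SIZE) {
  if (y_paper < 1 || y_paper > width_y || z_paper < 1 || z_paper > height_z)
    stop("coordinates out of bounds")
  c(y0 = as.integer(y_paper) - 1L, z0 = as.integer(z_paper) - 1L)
}

#' @rdname to_internal_coords
#' @param y0,z0 0-based coordinates.
#' @export
from_internal_coords <- function(y0, z0,
                                 width_y = CONFORMANT_SIZE,
                                 height_z = CONFORMANT_SIZE) {
  if (y0 < 0 || y0 >= width_y || z0 < 0 || z0 >= height_z)
    stop("coordinates out of bounds")
  c(y = as.integer(y0) + 1L, z = as.integer(z0) + 1L)
}
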