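# End-to-end orchestration: midsagittal selection -> intensity
# classification -> structure detection -> vertebra labeling -> cord edge
# segmentation, with optional manual canal override.

#' Default pipeline configuration
#'
#' All tunable pixel constants with their defaults: the detection band
#' offsets (40 around B1 for the cord refinement, 30 on either side of the
#' cord for PLL/LF, 60/21 anterior to the PLL for the ALL, 20/16 posterior
#' window lengths of f6/f5), region floors (150 px for vertebral bodies,
#' 100 px for disks), the 70 px C2-C3 gap, the isointense threshold guard
#' rails (64/127/128/159), the 31-pixel stability window and 11 x 31
#' median-profile window, and the 0.6875 mm pixel size.  These are exposed
#' so they can be retuned for other anatomical regions or scanners; the
#' defaults are the cervical values baked into the detection functions.
#'
#' @param seed RNG seed recorded with the run.
#' @param canal_override optional `(z_sup, z_inf)` manual canal extent.
#' @param resolution_mm pixel size.
#' @return named list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, canal_override = NULL,
                            resolution_mm = DEFAULT_RESOLUTION_MM) {
  structure(list(
    seed = as.integer(seed), canal_override = canal_override,
    resolution_mm = resolution_mm,
    band_b2 = 40L, band_b3b4 = 30L, band_b5 = c(60L, 21L),
    f5_window = 16L, f6_window = 20L,
    vb_min_area = VB_MIN_AREA, disk_min_area = DISK_MIN_AREA,
    c2_gap_px = C2_GAP_PX,
    iso_guard = c(64L, 127L, 128L, 159L),
    stability_window = 31L,
    profile_window = c(2L * PROFILE_Y_HALFWIDTH + 1L,
                       2L * PROFILE_Z_HALFWIDTH + 1L)),
    class = "pipeline_config")
}

#' Run the full segmentation pipeline on a sagittal series
#'
#' Stages, in order: (1) symmetry-based midsagittal selection (skipped with
#' a notice for a single-slice input); (2) per-candidate EM histogram
#' classification with threshold repair and coarse/refined cord detection,
#' arbitrating two candidates by cord-signal stability; (3) PLL, LF and ALL
#' detection; (4) column thresholding, truncated-ALL path, vertebral-body
#' region growing, labeling and canal-extent estimation — or the manual
#' override, which skips labeling-derived extents; (5) median cord profile
#' and anterior/posterior cord edge detection.  If labeling fails and no
#' override is given, the run stops with a typed error naming the stage so
#' the caller can re-run with `canal_override`.
#'
#' @param series a [sagittal_series()] (or a single [gray_image()]).
#' @param config a [pipeline_config()].
#' @return list of class `cordscan_result` with the chosen slice index, the
#'   msp candidate, the gmm fit, the structure set, the labeled spine, disk
#'   regions, the cord profile and the cord segmentation.
#' @export
run_pipeline <- function(series, config = pipeline_config()) {
  if (inherits(series, "gray_image")) series <- sagittal_series(list(series))

  # stage 1: midsagittal selection
  if (series$K == 1) {
    message("single-slice input: midsagittal selection skipped")
    msp <- NULL
    cand_idx <- 1L
  } else {
    msp <- select_kmsp(series)
    cand_idx <- msp$indices
  }

  # stage 2: classification + cord detection per candidate
  cands <- lapply(cand_idx, function(i) {
    img <- series$slices[[i]]
    fit <- repair_iso_upper(classify_gray_levels(
      fit_histogram_gmm(img, seed = config$seed)))
    cmap <- class_map(img, fit)
    B1 <- detect_B1(img, cmap)
    B2 <- detect_B2(img, B1)
    list(img = img, fit = fit, cmap = cmap, B1 = B1, B2 = B2)
  })
  pick <- choose_candidate_slice(lapply(cands, `[[`, "img"),
                                 lapply(cands, `[[`, "B2"))
  chosen <- cands[[pick]]
  slice_index <- cand_idx[pick]
  img <- chosen$img

  # stage 3: ligaments and column edges
  lig <- detect_B3_B4(img, chosen$B2)
  B5 <- detect_B5(img, lig$B3)
  st <- structure(list(B1 = chosen$B1, B2 = chosen$B2, B3 = lig$B3,
                       B4 = lig$B4, B5 = B5, cmap = chosen$cmap,
                       fit = chosen$fit), class = "structure_set")

  # stage 4: vertebral bodies, disks, canal extent
  tvb <- compute_tvb(img, B5, lig$B3, chosen$fit)
  B6 <- detect_B6(img, B5, lig$B3, tvb)
  vb_regions <- segment_vb_regions(img, B6, lig$B3, tvb)
  spine <- label_vertebrae(vb_regions, config$resolution_mm)
  if (!is.null(config$canal_override)) {
    spine <- apply_manual_override(spine, config$canal_override[1],
                                   config$canal_override[2], img$height_z)
    message("canal extent overridden manually; labeling-derived extent skipped")
  }
  if (!spine$ok) {
    stop(structure(class = c("cordscan_labeling_error", "error", "condition"),
                   list(message = paste0(
                     "vertebra labeling failed (", spine$failure,
                     "); re-run with a manual canal override"),
                     call = sys.call())))
  }
  disks <- if (spine$manual_override) list()
           else segment_disks(img, spine, vb_regions)
  canal <- c(spine$canal_z_sup, spine$canal_z_inf)

  # stage 5: cord edges
  profile <- median_cord_profile(img, chosen$B2, chosen$cmap, canal)
  seg <- detect_cord_edges(img, st, profile, canal)

  structure(list(slice_index = slice_index, msp = msp, fit = chosen$fit,
                 structures = st, tvb = tvb, B6 = B6, spine = spine,
                 disks = disks, profile = profile, canal = canal,
                 segmentation = seg, config = config),
            class = "cordscan_result")
}

#' @export
print.cordscan_result <- function(x, ...) {
  cat(sprintf("<cordscan_result> slice %d, canal rows %d..%d, cord area %d px\n",
              x$slice_index, x$canal[1], x$canal[2],
              sum(x$segmentation$mask$mask)))
  invisible(x)
}

#' Write the artifacts of a pipeline run to a directory
#'
#' Writes the cord mask PNG with its JSON sidecar (curves and canal
#' extent), plus a machine-readable run log with the fit parameters, the
#' labeled regions and the configuration.
#'
#' @param result a `cordscan_result`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_result <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_mask(result$segmentation$mask, file.path(dir, "cord_mask.png"),
             curves = list(anterior = result$segmentation$B7,
                           posterior = result$segmentation$B8),
             canal = result$canal)
  comps <- lapply(result$fit$components, function(cp)
    cp[c("label", "mean", "variance", "weight")])
  regs <- lapply(Filter(function(r) !is.na(r$label), result$spine$regions),
                 function(r) r[c("label", "area", "z_center", "y_center",
                                 "height", "depth")])
  dsk <- lapply(result$disks, function(r) r[c("label", "area", "z_center")])
  log <- list(slice_index = result$slice_index,
              k_msp = if (!is.null(result$msp)) result$msp$k_msp else NA,
              iso_upper = result$fit$iso_upper,
              iso_adjusted = result$fit$adjusted,
              t_vb = result$tvb$t_vb,
              canal = result$canal,
              manual_override = result$spine$manual_override,
              vertebrae = regs, disks = dsk, gmm = comps,
              seed = result$config$seed)
  jsonlite::write_json(log, file.path(dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
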