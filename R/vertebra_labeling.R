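# Vertebral-column thresholding, the truncated-ALL path B6, region growing
# for vertebral bodies (VBs) and intervertebral disks, anatomical labeling
# and canal-extent estimation.

VB_MIN_AREA <- 150L    # strict: regions must exceed half a normal VB
DISK_MIN_AREA <- 100L
C2_GAP_PX <- 70L       # 50 mm at 0.6875 mm/px
C2_LARGE_FACTOR <- 1.3 # "large region" = height >= 1.3 x median below

#' Vertebral-column gray-level threshold t_VB
#'
#' Builds the histogram of the column pixels (rows of y between the ALL
#' path B5 and the PLL path B3), smooths it with a width-5 moving average,
#' finds the two most prominent peaks (local maxima with prominence at
#' least 5% of the largest bin), and places t_VB at the rounded midpoint of
#' their gray levels.  The hypointense peak collects cortex, end plates and
#' annulus; the isointense peak collects bone marrow.  If the histogram is
#' unimodal the EM-derived lower isointense threshold is used instead, with
#' a warning.
#'
#' @param img a [gray_image()].
#' @param B5,B3 column edge paths.
#' @param fit optional classified `gmm_fit` used for the unimodal fallback.
#' @return An object of class `column_threshold` with fields `t_vb`,
#'   `hypo_peak`, `iso_peak`, `fallback`.
#' @export
compute_tvb <- function(img, B5, B3, fit = NULL) {
  zs <- seq_len(img$height_z)
  pix <- unlist(lapply(zs, function(z) {
    ya <- clamp(path_at(B5, z), 1L, img$width_y)
    yp <- clamp(path_at(B3, z), 1L, img$width_y)
    img$pixels[ya:yp, z]
  }))
  counts <- tabulate(pix + 1L, nbins = 256)
  sm <- moving_average(counts, 5L)
  n <- length(sm)
  is_peak <- c(FALSE, sm[2:(n - 1)] > sm[1:(n - 2)] &
                      sm[2:(n - 1)] >= sm[3:n], FALSE)
  peaks <- which(is_peak)
  # prominence: height above the valley toward the nearest higher peak on
  # each side (or the global edge when none exists)
  prom <- vapply(peaks, function(p) {
    higher_l <- peaks[peaks < p & sm[peaks] >= sm[p]]
    higher_r <- peaks[peaks > p & sm[peaks] >= sm[p]]
    vl <- if (length(higher_l)) min(sm[max(higher_l):p]) else min(sm[1:p])
    vr <- if (length(higher_r)) min(sm[p:min(higher_r)]) else min(sm[p:n])
    sm[p] - max(min(vl, vr), 0)
  }, numeric(1))
  keep <- peaks[prom >= 0.05 * max(sm)]
  if (length(keep) < 2) {
    warning("column histogram unimodal; falling back to EM iso_lower")
    t_vb <- if (!is.null(fit) && !is.na(fit$iso_lower)) fit$iso_lower else 64L
    return(structure(list(t_vb = as.integer(t_vb), hypo_peak = NA_integer_,
                          iso_peak = NA_integer_, fallback = TRUE),
                     class = "column_threshold"))
  }
  ord <- keep[order(prom[match(keep, peaks)], decreasing = TRUE)][1:2]
  # smoothing flattens sharp peaks into plateaus; refine each peak to the
  # largest raw bin within the smoothing half-width
  refine <- vapply(ord, function(p) {
    win <- max(1, p - 2):min(n, p + 2)
    win[which.max(counts[win])]
  }, numeric(1))
  g1 <- min(refine) - 1L; g2 <- max(refine) - 1L
  structure(list(t_vb = as.integer(round((g1 + g2) / 2)),
                 hypo_peak = g1, iso_peak = g2, fallback = FALSE),
            class = "column_threshold")
}

#' Truncated-ALL fitness (f6)
#'
#' `(256 - I)^2 + 65536 * #\{sub-threshold pixels among the 20 posterior\}`:
#' connects as many hypointense cortex and annulus pixels as possible while
#' leaving the posterior half of each vertebral body intact for region
#' growing.
#'
#' @param img a [gray_image()].
#' @param t a `column_threshold` from [compute_tvb()].
#' @return A [fitness_field()].
#' @export
fitness_f6 <- function(img, t) {
  I <- img$pixels + 0
  v <- (I < t$t_vb) * 1
  f <- (256 - I)^2
  for (j in 1:20) f <- f + 65536 * shift_y(v, j)
  fitness_field(f, "f6")
}

#' Detect the truncated-ALL path B6
#'
#' DP on [fitness_f6()] in the band `B5 .. B3 - 1`.  B6 corresponds to no
#' single anatomical structure: it overlaps the ALL at the anterior edges of
#' the disks and cuts prevertebral soft tissue (and the anterior-most part
#' of the vertebral bodies) off the column elsewhere.
#'
#' @param img a [gray_image()].
#' @param B5,B3 column edge paths.
#' @param t a `column_threshold`.
#' @return A [path_curve()].
#' @export
detect_B6 <- function(img, B5, B3, t) {
  f <- fitness_f6(img, t)
  b <- band_bounds(1, img$height_z, B5$values, B3$values - 1L)
  find_best_path(f, b)
}

# 4-connected components of a logical matrix, via vectorised flood fill.
# Returns an integer label matrix (0 = background).
label_components_4 <- function(mask) {
  W <- nrow(mask); H <- ncol(mask)
  lab <- matrix(0L, W, H)
  fg <- which(mask)
  cur <- 0L
  for (s in fg) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    lab[s] <- cur
    frontier <- s
    while (length(frontier) > 0) {
      r <- (frontier - 1L) %% W + 1L
      up <- frontier[r > 1L] - 1L
      dn <- frontier[r < W] + 1L
      lf <- frontier[frontier > W] - W
      rt <- frontier[frontier <= W * (H - 1L)] + W
      nb <- unique(c(up, dn, lf, rt))
      nb <- nb[mask[nb] & lab[nb] == 0L]
      lab[nb] <- cur
      frontier <- nb
    }
  }
  lab
}

# Summarise one labeled region into a spine_region record.
region_record <- function(idx, W, kind = "VB") {
  ys <- (idx - 1L) %% W + 1L
  zs <- (idx - 1L) %/% W + 1L
  structure(list(
    indices = idx, area = length(idx),
    y_center = mean(ys), z_center = mean(zs),
    z_min = min(zs), z_max = max(zs),
    y_min = min(ys), y_max = max(ys),
    height = max(zs) - min(zs) + 1L,
    depth = max(ys) - min(ys) + 1L,
    kind = kind, label = NA_character_), class = "spine_region")
}

#' Segment candidate vertebral-body regions
#'
#' Thresholds the pixels between B6 and B3 (per row, inclusive of B6,
#' exclusive of the PLL pixel at B3) at t_VB and extracts 4-connected
#' components of the at-or-above-threshold pixels.  Components strictly
#' larger than 150 pixels — half a normal VB — are valid candidate VBs,
#' sorted superior to inferior by their z-centres (ties by y-centre).
#'
#' @param img a [gray_image()].
#' @param B6,B3 truncated-ALL and PLL paths.
#' @param t a `column_threshold`.
#' @return list of `spine_region` records (possibly empty).
#' @export
segment_vb_regions <- function(img, B6, B3, t) {
  W <- img$width_y
  sel <- matrix(FALSE, W, img$height_z)
  for (z in seq_len(img$height_z)) {
    ya <- clamp(path_at(B6, z), 1L, W)
    yp <- clamp(path_at(B3, z) - 1L, 1L, W)
    if (ya <= yp) sel[ya:yp, z] <- TRUE
  }
  fg <- sel & img$pixels >= t$t_vb
  lab <- label_components_4(fg)
  regions <- lapply(seq_len(max(lab, 0L)), function(i)
    region_record(which(lab == i), W, "VB"))
  regions <- Filter(function(r) r$area > VB_MIN_AREA, regions)
  ord <- order(vapply(regions, `[[`, numeric(1), "z_center"),
               vapply(regions, `[[`, numeric(1), "y_center"))
  regions <- regions[ord]
  attr(regions, "column_sel") <- sel
  regions
}

#' Label vertebral bodies and estimate the canal extent
#'
#' Scans the sorted candidate regions for C2: a "large" region (height at
#' least 1.3 times the median height of the valid regions below it, the
#' odontoid-plus-body complex being about 1.5 times a lower cervical VB)
#' followed inferiorly by more than 5 valid regions, whose z-centre lies
#' within 70 pixels (50 mm) of the next region's.  That region and the next
#' are labeled C2 and C3; labeling continues inferiorly (C4...C7, T1, T2...)
#' for every detected region.  The canal's superior edge is the superior
#' edge of the C2 region; its inferior edge is the inferior edge of the T1
#' extent, extrapolated on z from the C3 and C7 centres with the T1 height
#' taken as that of C7 (the T1 region itself is deliberately included so
#' the C7-T1 disk can be found).
#'
#' @param regions sorted list from [segment_vb_regions()].
#' @param resolution_mm pixel size (the 70-pixel gap rule assumes 0.6875).
#' @return An object of class `labeled_spine`: fields `regions` (labeled),
#'   `canal_z_sup`, `canal_z_inf`, `ok` (logical success flag) and
#'   `failure` (reason when labeling fails).
#' @export
label_vertebrae <- function(regions, resolution_mm = DEFAULT_RESOLUTION_MM) {
  fail <- function(reason) structure(
    list(regions = regions, canal_z_sup = NA_integer_,
         canal_z_inf = NA_integer_, ok = FALSE, failure = reason,
         manual_override = FALSE), class = "labeled_spine")
  n <- length(regions)
  if (n < 7) return(fail(sprintf("only %d valid regions (need C2 + >5 below)", n)))
  zc <- vapply(regions, `[[`, numeric(1), "z_center")
  ht <- vapply(regions, `[[`, numeric(1), "height")
  c2_idx <- NA_integer_
  for (i in seq_len(n - 6L)) {
    below <- (i + 1L):n
    if (length(below) <= 5L) break
    if (ht[i] < C2_LARGE_FACTOR * stats::median(ht[below])) next
    if (zc[i + 1L] - zc[i] >= C2_GAP_PX) return(fail(
      sprintf("C2 candidate found but gap to next region is %.0f px (>= %d)",
              zc[i + 1L] - zc[i], C2_GAP_PX)))
    c2_idx <- i
    break
  }
  if (is.na(c2_idx)) return(fail("no large C2 candidate with >5 regions below"))

  labels <- c("C2", "C3", "C4", "C5", "C6", "C7", "T1",
              paste0("T", 2:12))
  for (k in seq(c2_idx, n)) {
    regions[[k]]$label <- labels[k - c2_idx + 1L]
  }
  named <- vapply(regions, `[[`, character(1), "label")
  r_c3 <- regions[[which(named == "C3")]]
  r_c7idx <- which(named == "C7")
  if (length(r_c7idx) == 0) return(fail("fewer regions than C7"))
  r_c7 <- regions[[r_c7idx]]
  s <- (r_c7$z_center - r_c3$z_center) / 4   # mean inter-centre spacing
  est_t1_center <- r_c7$z_center + s
  canal_z_inf <- as.integer(round(est_t1_center + r_c7$height / 2))
  canal_z_sup <- regions[[c2_idx]]$z_min
  structure(list(regions = regions, canal_z_sup = canal_z_sup,
                 canal_z_inf = canal_z_inf, ok = TRUE, failure = NULL,
                 manual_override = FALSE),
            class = "labeled_spine")
}

#' @export
print.labeled_spine <- function(x, ...) {
  if (x$ok) {
    labs <- vapply(x$regions, `[[`, character(1), "label")
    cat(sprintf("<labeled_spine> %s; canal rows %d..%d%s\n",
                paste(labs[!is.na(labs)], collapse = " "),
                x$canal_z_sup, x$canal_z_inf,
                if (x$manual_override) " (manual)" else ""))
  } else {
    cat("<labeled_spine> labeling FAILED:", x$failure, "\n")
  }
  invisible(x)
}

#' Segment and label the intervertebral disks
#'
#' Removes the valid VB regions from the column pixels and extracts the
#' remaining 4-connected "void" components regardless of signal intensity
#' (which makes the rule robust to dehydrated, hypointense disks).
#' Components larger than 100 pixels lying between two labeled VBs are
#' disks, labeled by the adjacent VBs (e.g. "C3-4"); voids above the
#' topmost or below the lowest labeled VB are dropped.
#'
#' @param img a [gray_image()].
#' @param spine a `labeled_spine` with successful labels.
#' @param vb_regions the region list from [segment_vb_regions()] (its
#'   `column_sel` attribute supplies the column pixel set).
#' @return list of `spine_region` records with `kind = "disk"`.
#' @export
segment_disks <- function(img, spine, vb_regions) {
  sel <- attr(vb_regions, "column_sel")
  if (is.null(sel)) stop("vb_regions must carry the column_sel attribute")
  W <- img$width_y
  void <- sel
  for (r in vb_regions) void[r$indices] <- FALSE
  lab <- label_components_4(void)
  voids <- lapply(seq_len(max(lab, 0L)), function(i)
    region_record(which(lab == i), W, "disk"))
  voids <- Filter(function(r) r$area > DISK_MIN_AREA, voids)

  labeled <- Filter(function(r) !is.na(r$label), spine$regions)
  if (length(labeled) < 2) return(list())
  vb_zc <- vapply(labeled, `[[`, numeric(1), "z_center")
  vb_lab <- vapply(labeled, `[[`, character(1), "label")
  ord <- order(vb_zc)
  vb_zc <- vb_zc[ord]; vb_lab <- vb_lab[ord]
  out <- list()
  for (r in voids) {
    above <- which(vb_zc < r$z_center)
    below <- which(vb_zc > r$z_center)
    if (length(above) == 0 || length(below) == 0) next
    la <- vb_lab[max(above)]
    lb <- vb_lab[min(below)]
    # label like "C3-4": strip the letter of the lower VB when shared
    r$label <- if (substr(la, 1, 1) == substr(lb, 1, 1))
      paste0(la, "-", substring(lb, 2)) else paste0(la, "-", lb)
    out[[length(out) + 1L]] <- r
  }
  ord <- order(vapply(out, `[[`, numeric(1), "z_center"))
  out[ord]
}

#' Manually override the canal extent
#'
#' When VB detection or labeling fails, the superior and inferior canal
#' edges can be designated directly so that cord segmentation can proceed.
#'
#' @param spine a `labeled_spine` (possibly failed).
#' @param z_sup,z_inf canal extent rows, `z_sup < z_inf`.
#' @param height_z image height for bounds checking.
#' @return The spine with the overridden extent and
#'   `manual_override = TRUE`.
#' @export
apply_manual_override <- function(spine, z_sup, z_inf,
                                  height_z = CONFORMANT_SIZE) {
  z_sup <- as.integer(z_sup); z_inf <- as.integer(z_inf)
  if (z_sup >= z_inf) stop("override requires z_sup < z_inf")
  if (z_sup < 1 || z_inf > height_z) stop("override rows outside the image")
  spine$canal_z_sup <- z_sup
  spine$canal_z_inf <- z_inf
  spine$ok <- TRUE
  spine$manual_override <- TRUE
  spine
}
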