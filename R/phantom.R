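# Seeded synthetic sagittal cervical-spine phantom with full ground truth.
#
# The phantom emulates the features the pipeline relies on rather than MR
# physics: a T2-like intensity ordering (air << ligament/cortex < muscle <
# marrow/cord < CSF/nucleus), a vertebral column of C2..T2 bodies with
# hypointense end plates and annulus separating the marrow regions, a
# spinal canal bounded by PLL and LF with CSF around a cord that runs the
# full image height, a gentle lordotic in-plane curve, a superior-inferior
# cord intensity drift, and a 13-slice stack that is mirror-symmetric about
# a planted midsagittal position.  Marrow and muscle carry bounded
# deterministic texture (trabecular bone and muscle are heterogeneous on
# T2) while cord, CSF and ligaments are smooth; this is what makes the
# homogeneity-based cord refinement unambiguous, as on real images.

#' Phantom specification
#'
#' Defaults reproduce the study conditions the pipeline targets: 320 x 320
#' 8-bit slices at 0.6875 mm/px, 13 slices, vertebral bodies 22 px deep and
#' 18 px high (area 396 px, within the normal 300-600 px), a 24 px deep
#' canal, a C2 complex 1.5 times the height of a lower cervical body, and a
#' linear cord intensity drift whose size relative to the default noise
#' (sd 3) yields a gray-versus-z correlation of about -0.6 on cord pixels.
#'
#' @param seed integer RNG seed; the phantom is bit-reproducible given the
#'   spec.
#' @param size image side in pixels.
#' @param n_slices number of sagittal slices.
#' @param k_msp planted midsagittal position, integer or half-integer in
#'   `[4, 10]` for the default 13-slice stack.
#' @param noise_sd Gaussian noise standard deviation (gray levels).
#' @param cord_drift total superior-to-inferior decline of the cord gray
#'   level (gray levels over the full image height).
#' @param curve_amp amplitude (px) of the lordotic in-plane curve.
#' @param stenosis optional list of `list(level = "C5-6", severity = s)`
#'   entries with severity in `[0, 1]`; severity 1 removes the CSF at that
#'   level entirely while leaving the cord untouched.
#' @param tissue named list of tissue gray levels.
#' @param geom named list of geometry parameters (pixel units): `vb_depth`,
#'   `vb_height`, `disk_height`, `c2_factor`, `csf_ant`, `cord_depth`,
#'   `csf_post`, `lig_w`, `all_y` (anterior ligament start column),
#'   `c2_top` (superior edge row of C2), `muscle_ant_depth`.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(seed = 1L, size = 320L, n_slices = 13L, k_msp = 7,
                         noise_sd = 3, cord_drift = 8, curve_amp = 5,
                         stenosis = NULL,
                         tissue = list(air = 5, ligament = 25, cortex = 30,
                                       muscle = 48, marrow = 80, cord = 80,
                                       csf = 175, nucleus = 180),
                         geom = list()) {
  g <- utils::modifyList(list(
    vb_depth = 22L, vb_height = 18L, disk_height = 8L, c2_factor = 1.5,
    csf_ant = 6L, cord_depth = 12L, csf_post = 6L, lig_w = 2L,
    all_y = 78L, c2_top = 28L, muscle_ant_depth = 18L,
    marrow_texture = 3, marrow_ramp = 4, muscle_texture = 10,
    nucleus_depth = 8L, lateral_blend = 0.25), geom)
  canal_depth <- g$csf_ant + g$cord_depth + g$csf_post
  if (canal_depth > 2 * g$vb_depth)
    stop("inconsistent geometry: canal deeper than twice the vertebral column")
  if (g$cord_depth < 5) stop("cord depth below the 5 px compressed-cord floor")
  with(tissue, assert_that(
    air < ligament && ligament <= cortex && cortex < marrow &&
      marrow <= cord && cord < csf && csf <= nucleus,
    "tissue intensity ordering violated (air < ligament/cortex < marrow/cord < CSF/nucleus)"))
  if (k_msp < 1 || k_msp > n_slices || (k_msp * 2) != round(k_msp * 2))
    stop("k_msp must be an integer or half-integer slice position")
  structure(list(seed = as.integer(seed), size = as.integer(size),
                 n_slices = as.integer(n_slices), k_msp = k_msp,
                 noise_sd = noise_sd, cord_drift = cord_drift,
                 curve_amp = curve_amp, stenosis = stenosis,
                 tissue = tissue, geom = g),
            class = "phantom_spec")
}

# z-layout of the vertebral column: C2 then C3..C7, T1, T2.
column_layout <- function(spec) {
  g <- spec$geom
  labels <- c("C2", "C3", "C4", "C5", "C6", "C7", "T1", "T2")
  heights <- c(round(g$c2_factor * g$vb_height), rep(g$vb_height, 7L))
  v0 <- integer(8); v1 <- integer(8)
  top <- g$c2_top
  for (i in 1:8) {
    v0[i] <- top
    v1[i] <- top + heights[i] - 1L
    top <- v1[i] + g$disk_height + 1L
  }
  list(labels = labels, v0 = v0, v1 = v1, heights = heights)
}

#' Generate a synthetic sagittal series with ground truth
#'
#' @param spec a [phantom_spec()].
#' @return list with `series` (a [sagittal_series()]) and `truth`, a list
#'   holding the planted midsagittal position `k_msp`, the canal extent,
#'   cord/CSF masks, the true cord edge curves, labeled vertebral-body and
#'   disk records (with marrow areas as planted region areas) and the
#'   per-row curve offset.
#' @export
generate_phantom <- function(spec) {
  set.seed(spec$seed)
  W <- H <- spec$size
  g <- spec$geom
  ts <- spec$tissue

  # ---- y-layout (before the in-plane curve) -------------------------------
  # The ALL merges with the anterior vertebral cortex into a 2 px complex;
  # the PLL and LF are thin 1 px bands at this resolution.
  all_a <- g$all_y                          # anterior ligament complex
  all_p <- all_a + g$lig_w - 1L
  col_a <- all_p + 1L                       # column interior (marrow)
  col_p <- col_a + (g$vb_depth - g$lig_w) - 1L
  pll_a <- col_p + 1L
  pll_p <- pll_a                            # 1 px PLL
  csfa_a <- pll_p + 1L                      # anterior CSF
  csfa_p <- csfa_a + g$csf_ant - 1L
  cord_a <- csfa_p + 1L
  cord_p <- cord_a + g$cord_depth - 1L
  csfp_a <- cord_p + 1L
  csfp_p <- csfp_a + g$csf_post - 1L
  lf_a <- csfp_p + 1L
  lf_p <- lf_a                              # 1 px LF
  mus_a <- all_a - g$muscle_ant_depth       # prevertebral muscle band
  if (mus_a < 2 || lf_p >= W) stop("geometry does not fit the image width")

  lay <- column_layout(spec)
  nuc_a <- col_a + 6L                       # nucleus pulposus core columns
  nuc_p <- nuc_a + g$nucleus_depth - 1L     # depth 0: dehydrated disks

  # ---- midsagittal template -----------------------------------------------
  M <- matrix(ts$air, W, H)
  M[mus_a:(all_a - 1L), ] <- ts$muscle
  M[all_a:all_p, ] <- ts$ligament
  M[col_a:col_p, ] <- ts$cortex             # column strip; blocks overwrite
  M[pll_a:pll_p, ] <- ts$ligament
  M[csfa_a:csfa_p, ] <- ts$csf
  drift_row <- ts$cord - spec$cord_drift * ((seq_len(H) - 1) / (H - 1) - 0.5)
  M[cord_a:cord_p, ] <- matrix(drift_row, g$cord_depth, H, byrow = TRUE)
  M[csfp_a:csfp_p, ] <- ts$csf
  M[lf_a:lf_p, ] <- ts$ligament
  mus_post_p <- min(lf_p + 88L, W)          # posterior neck soft tissue,
  M[(lf_p + 1L):mus_post_p, ] <- ts$muscle  # then air behind the skin

  # marrow brightens slightly anterior -> posterior (fatty marrow gradient);
  # the darker anterior edge also pins the truncated-ALL path there
  marrow_col <- ts$marrow +
    g$marrow_ramp * (2 * (col_a:col_p - col_a) / (col_p - col_a) - 1)
  marrow_rows <- logical(H)
  for (i in seq_along(lay$labels)) {
    v0 <- lay$v0[i]; v1 <- lay$v1[i]
    M[col_a:col_p, v0:v1] <- ts$cortex      # end plates
    mr <- (v0 + 2L):(v1 - 2L)
    M[col_a:col_p, mr] <- marrow_col
    marrow_rows[mr] <- TRUE
    if (i < length(lay$labels)) {           # disk slab below
      d0 <- v1 + 1L; d1 <- d0 + g$disk_height - 1L
      M[col_a:col_p, d0:d1] <- ts$cortex    # annulus / end-plate cartilage
      if (g$nucleus_depth > 0)
        M[nuc_a:nuc_p, (d0 + 2L):(d1 - 2L)] <- ts$nucleus
    }
  }

  # bounded deterministic texture: trabecular bone, end plates and annulus
  # are all heterogeneous on T2, unlike cord and CSF
  tex_m <- matrix(stats::runif(length(col_a:col_p) * H,
                               -g$marrow_texture, g$marrow_texture),
                  length(col_a:col_p))
  M[col_a:col_p, ] <- M[col_a:col_p, ] + tex_m
  mus_cols <- c(mus_a:(all_a - 1L), (lf_p + 1L):mus_post_p)
  tex_u <- matrix(stats::runif(length(mus_cols) * H,
                               -g$muscle_texture, g$muscle_texture),
                  length(mus_cols))
  M[mus_cols, ] <- M[mus_cols, ] + tex_u

  # ---- stenosis: CSF replaced by bulging disk / thickened ligament --------
  csf_removed <- matrix(FALSE, W, H)
  for (st in spec$stenosis) {
    i <- match(sub("-.*", "", st$level), lay$labels)
    if (is.na(i) || i >= length(lay$labels))
      stop("unknown stenosis level: ", st$level)
    d0 <- lay$v1[i] + 1L; d1 <- d0 + g$disk_height - 1L
    rows <- max(1L, d0 - 3L):min(H, d1 + 3L)
    ka <- round(g$csf_ant * st$severity)
    kp <- round(g$csf_post * st$severity)
    if (ka > 0) {                           # disk/osteophyte bulge
      colsa <- (csfa_p - ka + 1L):csfa_p
      M[colsa, rows] <- ts$cortex
      csf_removed[colsa, rows] <- TRUE
    }
    if (kp > 0) {                           # ligamentum flavum hypertrophy
      colsp <- csfp_a:(csfp_a + kp - 1L)
      M[colsp, rows] <- ts$ligament
      csf_removed[colsp, rows] <- TRUE
    }
  }

  # ---- lordotic in-plane curve --------------------------------------------
  off <- as.integer(round(spec$curve_amp * sin(pi * (seq_len(H) - 1) / (H - 1))))
  shift_cols <- function(mat, fill) {
    out <- mat
    for (z in seq_len(H)) {
      o <- off[z]
      if (o > 0) out[, z] <- c(rep(fill, o), mat[seq_len(W - o), z])
    }
    out
  }
  M <- shift_cols(M, ts$air)

  # ---- slices: canal attenuated with lateral distance, noise added --------
  canal_cols <- pll_a:lf_p
  lateral_gray <- 55
  slices <- vector("list", spec$n_slices)
  for (k in seq_len(spec$n_slices)) {
    beta <- min(0.85, spec$geom$lateral_blend * abs(k - spec$k_msp))
    Sk <- M
    for (z in seq_len(H)) {
      cc <- clamp(canal_cols + off[z], 1L, W)
      Sk[cc, z] <- (1 - beta) * Sk[cc, z] + beta * lateral_gray
    }
    Sk <- Sk + stats::rnorm(W * H, 0, spec$noise_sd)
    slices[[k]] <- gray_image(matrix(clamp(round(Sk), 0, 255), W, H))
  }

  # ---- ground truth -------------------------------------------------------
  shift_mask <- function(mat) shift_cols(mat, FALSE)
  cord_mask <- matrix(FALSE, W, H); cord_mask[cord_a:cord_p, ] <- TRUE
  csf_mask <- matrix(FALSE, W, H)
  csf_mask[csfa_a:csfa_p, ] <- TRUE; csf_mask[csfp_a:csfp_p, ] <- TRUE
  csf_mask[csf_removed] <- FALSE
  cord_mask <- shift_mask(cord_mask)
  csf_mask <- shift_mask(csf_mask)

  vbs <- lapply(seq_along(lay$labels), function(i) list(
    label = lay$labels[i], z_sup = lay$v0[i], z_inf = lay$v1[i],
    z_center = (lay$v0[i] + lay$v1[i]) / 2,
    marrow_area = (g$vb_depth - g$lig_w) * (lay$heights[i] - 4L)))
  disks <- lapply(seq_len(length(lay$labels) - 1L), function(i) {
    la <- lay$labels[i]; lb <- lay$labels[i + 1L]
    list(label = if (substr(la, 1, 1) == substr(lb, 1, 1))
           paste0(la, "-", substring(lb, 2)) else paste0(la, "-", lb),
         z_sup = lay$v1[i] + 1L, z_inf = lay$v1[i] + g$disk_height)
  })
  t1 <- which(lay$labels == "T1")
  truth <- list(
    k_msp = spec$k_msp,
    canal = c(lay$v0[1], lay$v1[t1]),
    cord_mask = seg_mask(cord_mask, "cord (truth)"),
    csf_mask = seg_mask(csf_mask, "CSF (truth)"),
    cord_anterior = path_curve(1L, H, cord_a + off),
    cord_posterior = path_curve(1L, H, cord_p + off),
    column_anterior = path_curve(1L, H, all_a + off),
    vbs = vbs, disks = disks, offset = off,
    layout = list(all_a = all_a, all_p = all_p, col_a = col_a, col_p = col_p,
                  pll_a = pll_a, pll_p = pll_p, csfa_a = csfa_a,
                  csfa_p = csfa_p, cord_a = cord_a, cord_p = cord_p,
                  csfp_a = csfp_a, csfp_p = csfp_p, lf_a = lf_a, lf_p = lf_p),
    drift_row = drift_row)
  list(series = sagittal_series(slices), truth = truth)
}

#' Generate a matched normal/stenotic phantom pair
#'
#' Both phantoms share the seed, so noise and texture are identical; they
#' differ only inside the stenotic level's bounding box.  CSF is narrowed
#' or removed while the cord is untouched.
#'
#' @param spec a [phantom_spec()]; its `stenosis` field defines the
#'   stenotic member of the pair.
#' @return list with `normal` and `stenotic`, each as returned by
#'   [generate_phantom()].
#' @export
generate_stenotic_pair <- function(spec) {
  normal_spec <- spec
  normal_spec$stenosis <- NULL
  list(normal = generate_phantom(normal_spec),
       stenotic = generate_phantom(spec))
}

#' Apply a named degradation to a series
#'
#' Emulates acquisition artifacts: `"drift"` adds an extra linear
#' superior-to-inferior intensity decline of `magnitude` gray levels;
#' `"gibbs_lines"` adds thin longitudinal (vertical) hyperintense lines of
#' `+magnitude` gray levels every 37 columns; `"window_clip"` rescales
#' intensities by `1 + magnitude` so hyperintense pixels saturate at the
#' top gray levels, as aggressive display windowing does.
#'
#' @param series a [sagittal_series()].
#' @param kind one of `"drift"`, `"gibbs_lines"`, `"window_clip"`.
#' @param magnitude non-negative degradation strength; 0 is the identity.
#' @return the degraded [sagittal_series()].
#' @export
degrade <- function(series, kind = c("drift", "gibbs_lines", "window_clip"),
                    magnitude) {
  kind <- match.arg(kind)
  if (magnitude < 0) stop("`magnitude` must be non-negative")
  series$slices <- lapply(series$slices, function(img) {
    I <- img$pixels + 0
    H <- img$height_z; W <- img$width_y
    I <- switch(kind,
      drift = I - magnitude *
        matrix((seq_len(H) - 1) / (H - 1), W, H, byrow = TRUE),
      gibbs_lines = {
        cols <- seq(20L, W, by = 37L)
        I[cols, ] <- I[cols, ] + magnitude
        I
      },
      window_clip = I * (1 + magnitude))
    gray_image(matrix(clamp(round(I), 0, 255), W, H),
               resolution_mm = img$resolution_mm)
  })
  series
}
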