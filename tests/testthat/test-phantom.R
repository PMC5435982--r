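test_that("generation is deterministic for a fixed spec", {
  a <- generate_phantom(phantom_spec(seed = 81))
  b <- generate_phantom(phantom_spec(seed = 81))
  for (k in c(1, 7, 13))
    expect_identical(a$series$slices[[k]]$pixels, b$series$slices[[k]]$pixels)
  expect_identical(a$truth$canal, b$truth$canal)
})

test_that("planted tissue gray levels appear as histogram modes at zero noise", {
  ph <- phantom_fixture(seed = 82, noise_sd = 0)
  img <- ph$series$slices[[7]]
  counts <- tabulate(as.integer(img$pixels) + 1L, nbins = 256)
  # smooth tissues are exact modes; cord carries the drift so test its median
  expect_gt(counts[5 + 1], counts[10 + 1])     # air peak at 5
  expect_gt(counts[175 + 1], counts[160 + 1])  # CSF peak at 175
  cord_px <- img$pixels[ph$truth$cord_mask$mask]
  expect_equal(median(cord_px), 80, tolerance = 1)
})

test_that("cord intensity drifts downward with z at the planted correlation", {
  ph <- phantom_fixture(seed = 1)
  img <- ph$series$slices[[7]]
  idx <- which(ph$truth$cord_mask$mask, arr.ind = TRUE)
  r <- cor(img$pixels[idx], idx[, 2])
  expect_lt(r, -0.4)
  expect_gt(r, -0.8)
})

test_that("cord pixels are overwhelmingly isointense to an ideal classifier", {
  for (sd in c(3, 5)) {
    ph <- phantom_fixture(seed = 83, noise_sd = sd)
    img <- ph$series$slices[[7]]
    cord_px <- img$pixels[ph$truth$cord_mask$mask]
    expect_gte(mean(cord_px >= 60 & cord_px <= 100), 0.99)
  }
})

test_that("stenosis removes CSF but not cord, only inside its level", {
  sp <- phantom_spec(seed = 84, stenosis = list(list(level = "C5-6", severity = 1)))
  pr <- generate_stenotic_pair(sp)
  n <- pr$normal; s <- pr$stenotic
  d <- which(n$series$slices[[7]]$pixels != s$series$slices[[7]]$pixels,
             arr.ind = TRUE)
  expect_gt(nrow(d), 0)
  lvl <- Filter(function(x) x$label == "C5-6", n$truth$disks)[[1]]
  expect_true(all(d[, 2] >= lvl$z_sup - 3 & d[, 2] <= lvl$z_inf + 3))
  rows <- lvl$z_sup:lvl$z_inf
  expect_equal(sum(s$truth$csf_mask$mask[, rows]), 0)
  expect_identical(s$truth$cord_mask$mask, n$truth$cord_mask$mask)
  expect_equal(sum(s$truth$cord_mask$mask), sum(n$truth$cord_mask$mask))

  # severity 0 is bit-identical to the normal phantom
  sp0 <- phantom_spec(seed = 84, stenosis = list(list(level = "C5-6", severity = 0)))
  z <- generate_phantom(sp0)
  expect_identical(z$series$slices[[7]]$pixels, n$series$slices[[7]]$pixels)
})

test_that("degradations apply the named corruption and are identity at 0", {
  ph <- phantom_fixture(seed = 1)
  for (kind in c("drift", "gibbs_lines", "window_clip")) {
    d0 <- degrade(ph$series, kind, 0)
    expect_identical(d0$slices[[7]]$pixels, ph$series$slices[[7]]$pixels)
  }
  expect_error(degrade(ph$series, "blur", 1), "arg")
  expect_error(degrade(ph$series, "drift", -1), "non-negative")

  # window clipping saturates hyperintense pixels and triggers the
  # above-127 branch of the threshold repair
  clipped <- degrade(ph$series, "window_clip", 0.5)
  img <- clipped$slices[[7]]
  expect_gt(sum(img$pixels == 255), sum(ph$series$slices[[7]]$pixels == 255))
  fit <- repair_iso_upper(classify_gray_levels(fit_histogram_gmm(img)))
  expect_true(fit$adjusted)
  expect_match(fit$adjust_reason, "above 127")

  # mild Gibbs lines barely move the refined cord path
  gb <- degrade(ph$series, "gibbs_lines", 15)
  img_g <- gb$slices[[7]]
  fit_g <- repair_iso_upper(classify_gray_levels(fit_histogram_gmm(img_g)))
  cm <- class_map(img_g, fit_g)
  B2g <- detect_B2(img_g, detect_B1(img_g, cm))
  B2 <- structure_fixture(1)$st$B2
  expect_gte(mean(abs(B2g$values - B2$values) <= 2), 0.90)
})

test_that("inconsistent geometry is rejected", {
  expect_error(phantom_spec(geom = list(csf_ant = 30L, csf_post = 30L)),
               "inconsistent geometry")
  expect_error(phantom_spec(geom = list(cord_depth = 3L)), "5 px")
  expect_error(phantom_spec(k_msp = 5.3), "half-integer")
  expect_error(phantom_spec(tissue = list(air = 90, ligament = 25, cortex = 30,
                                          muscle = 48, marrow = 80, cord = 80,
                                          csf = 175, nucleus = 180)),
               "ordering")
})

test_that("planted vertebral bodies match the documented size ranges", {
  sp <- phantom_spec(seed = 1)
  g <- sp$geom
  expect_true(g$vb_depth >= 22 && g$vb_depth <= 30)
  expect_true(g$vb_height >= 14 && g$vb_height <= 22)
  area <- g$vb_depth * g$vb_height
  expect_true(area >= 300 && area <= 600)
  canal <- g$csf_ant + g$cord_depth + g$csf_post
  expect_true(canal >= 22 && canal <= 30)
})
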