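const_curve <- function(y, H) path_curve(1, H, rep(as.integer(y), H))

test_that("t_VB sits at the midpoint of the two column histogram peaks", {
  H <- 60
  # two delta peaks at 40 and 100 -> midpoint 70
  m <- matrix(0, 60, H)
  m[20:45, ] <- rep(c(40, 100), length.out = 26)
  img <- gray_image(m)
  t <- compute_tvb(img, const_curve(20, H), const_curve(45, H))
  expect_equal(t$t_vb, 70L)
  expect_false(t$fallback)

  # seeded bimodal draw around 30 and 90 -> midpoint within 60 +/- 2
  set.seed(51)
  m2 <- matrix(0, 60, H)
  m2[20:45, ] <- pmax(round(rnorm(26 * H, sample(c(30, 90), 26 * H, TRUE), 4)), 0)
  t2 <- compute_tvb(gray_image(m2), const_curve(20, H), const_curve(45, H))
  expect_lte(abs(t2$t_vb - 60), 2)

  # constant column: unimodal fallback to the EM lower threshold
  m3 <- matrix(80, 60, H)
  fit <- make_fit(c(5, 40, 80, 180), c(2, 8, 8, 15), c(.5, .2, .2, .1), 64, 100)
  expect_warning(
    t3 <- compute_tvb(gray_image(m3), const_curve(20, H), const_curve(45, H), fit),
    "unimodal")
  expect_true(t3$fallback)
  expect_equal(t3$t_vb, 64L)
})

test_that("f6 combines the dark term with the sub-threshold posterior count", {
  t <- structure(list(t_vb = 60L), class = "column_threshold")
  m <- matrix(0, 40, 2)          # everything sub-threshold
  f <- fitness_f6(gray_image(m), t)
  expect_equal(f$values[10, 1], 65536 + 20 * 65536)
  m2 <- matrix(255, 40, 2)       # nothing below
  f2 <- fitness_f6(gray_image(m2), t)
  expect_equal(f2$values[10, 1], 1)
  # mixed row hand-counted
  set.seed(52)
  m3 <- matrix(sample(0:255, 80, TRUE), 40, 2)
  f3 <- fitness_f6(gray_image(m3), t)
  y <- 12
  expect_equal(f3$values[y, 2],
               (256 - m3[y, 2])^2 + 65536 * sum(m3[(y + 1):(y + 20), 2] < 60))
})

test_that("region growing is 4-connected with a strict 150 px floor", {
  # two diagonal-touching blocks stay separate under 4-connectivity
  m <- matrix(0, 30, 40)
  m[5:10, 5:10] <- 100
  m[11:16, 11:16] <- 100
  img <- gray_image(m)
  t <- structure(list(t_vb = 50L), class = "column_threshold")
  regs <- segment_vb_regions(img, const_curve(2, 40), const_curve(29, 40), t)
  expect_length(regs, 0)   # each block is 36 px, below the floor

  # exactly 150 px is excluded; 151 px is kept
  m2 <- matrix(0, 30, 40)
  m2[3:12, 3:17] <- 100                 # 10 x 15 = 150
  r150 <- segment_vb_regions(gray_image(m2), const_curve(2, 40),
                             const_curve(29, 40), t)
  expect_length(r150, 0)
  m2[3, 18] <- 100                      # 151st pixel
  r151 <- segment_vb_regions(gray_image(m2), const_curve(2, 40),
                             const_curve(29, 40), t)
  expect_length(r151, 1)
  expect_equal(r151[[1]]$area, 151L)

  # empty column -> empty list
  r0 <- segment_vb_regions(gray_image(matrix(0, 30, 40)), const_curve(2, 40),
                           const_curve(29, 40), t)
  expect_length(r0, 0)
})

fake_region <- function(z_center, height = 14, area = 280) {
  structure(list(indices = integer(0), area = area, y_center = 90,
                 z_center = z_center, z_min = as.integer(round(z_center - height / 2)),
                 z_max = as.integer(round(z_center + height / 2)),
                 y_min = 80L, y_max = 99L, height = height, depth = 20L,
                 kind = "VB", label = NA_character_), class = "spine_region")
}

test_that("labeling needs a large C2, a close C3 and more than 5 regions below", {
  # success: tall first region, regular spacing
  regs <- c(list(fake_region(40, height = 23)),
            lapply(seq(70, 200, by = 26), fake_region))
  spine <- label_vertebrae(regs)
  expect_true(spine$ok)
  labs <- vapply(spine$regions, `[[`, character(1), "label")
  expect_equal(labs[1:7], c("C2", "C3", "C4", "C5", "C6", "C7", "T1"))
  # canal: sup = detected C2 superior edge; inf = extrapolated T1 extent
  expect_equal(spine$canal_z_sup, regs[[1]]$z_min)
  s <- (regs[[6]]$z_center - regs[[2]]$z_center) / 4
  expect_equal(spine$canal_z_inf,
               as.integer(round(regs[[6]]$z_center + s + 14 / 2)))

  # first-to-second gap of 75 px: labeling fails on the 70 px rule
  regs_far <- c(list(fake_region(40, height = 23)),
                lapply(seq(115, 245, by = 26), fake_region))
  far <- label_vertebrae(regs_far)
  expect_false(far$ok)
  expect_match(far$failure, "gap")

  # five regions only: too few
  five <- label_vertebrae(lapply(seq(40, 144, by = 26), fake_region))
  expect_false(five$ok)

  # no tall region: no C2 candidate
  flat <- label_vertebrae(lapply(seq(40, 222, by = 26), fake_region))
  expect_false(flat$ok)
  expect_match(flat$failure, "no large C2")
})

test_that("manual override replaces the canal extent and validates rows", {
  spine <- label_vertebrae(list())
  expect_false(spine$ok)
  over <- apply_manual_override(spine, 20, 250)
  expect_true(over$ok)
  expect_true(over$manual_override)
  expect_equal(c(over$canal_z_sup, over$canal_z_inf), c(20L, 250L))
  expect_error(apply_manual_override(spine, 100, 100), "z_sup < z_inf")
  expect_error(apply_manual_override(spine, 10, 999), "outside")
})

test_that("phantom vertebrae are recovered, labeled and sized correctly", {
  ch <- structure_fixture(1)
  ph <- ch$ph; st <- ch$st
  tvb <- compute_tvb(ch$img, st$B5, st$B3, ch$fit)
  B6 <- detect_B6(ch$img, st$B5, st$B3, tvb)
  # truncated-ALL shape: hugs the anterior column edge at disk rows and
  # retains the posterior half of each vertebral body elsewhere
  disk_rows <- unlist(lapply(ph$truth$disks, function(d) d$z_sup:d$z_inf))
  expect_gte(mean(abs(B6$values - st$B5$values)[disk_rows] <= 2), 0.90)
  expect_true(all(B6$values >= st$B5$values & B6$values < st$B3$values))
  regs <- segment_vb_regions(ch$img, B6, st$B3, tvb)
  expect_length(regs, length(ph$truth$vbs))
  planted <- vapply(ph$truth$vbs, `[[`, numeric(1), "marrow_area")
  expect_true(all(abs(vapply(regs, `[[`, numeric(1), "area") - planted)
                  <= 0.1 * planted))
  spine <- label_vertebrae(regs)
  expect_true(spine$ok)
  labs <- vapply(spine$regions, `[[`, character(1), "label")
  expect_equal(labs, vapply(ph$truth$vbs, `[[`, character(1), "label"))
  expect_lte(abs(spine$canal_z_sup - ph$truth$canal[1]), 3)
  expect_lte(abs(spine$canal_z_inf - ph$truth$canal[2]), 3)

  disks <- segment_disks(ch$img, spine, regs)
  expect_equal(vapply(disks, `[[`, character(1), "label"),
               vapply(ph$truth$disks, `[[`, character(1), "label"))
  expect_true(all(vapply(disks, `[[`, numeric(1), "area") > 100))

  # area conservation: VB + void pixels = column pixels
  sel <- attr(regs, "column_sel")
  vb_px <- sum(vapply(regs, `[[`, numeric(1), "area"))
  void <- sel
  for (r in regs) void[r$indices] <- FALSE
  expect_equal(vb_px + sum(void), sum(sel))
})

test_that("dehydrated disks without a bright nucleus are still detected", {
  ph <- phantom_fixture(seed = 53, geom = list(nucleus_depth = 0L))
  img <- ph$series$slices[[7]]
  fit <- repair_iso_upper(classify_gray_levels(fit_histogram_gmm(img)))
  st <- detect_structures(img, fit)
  tvb <- compute_tvb(img, st$B5, st$B3, fit)
  B6 <- detect_B6(img, st$B5, st$B3, tvb)
  regs <- segment_vb_regions(img, B6, st$B3, tvb)
  spine <- label_vertebrae(regs)
  expect_true(spine$ok)
  disks <- segment_disks(img, spine, regs)
  expect_equal(vapply(disks, `[[`, character(1), "label"),
               vapply(ph$truth$disks, `[[`, character(1), "label"))
})

test_that("labeling is deterministic on identical input", {
  ch <- structure_fixture(1)
  tvb <- compute_tvb(ch$img, ch$st$B5, ch$st$B3, ch$fit)
  B6 <- detect_B6(ch$img, ch$st$B5, ch$st$B3, tvb)
  r1 <- segment_vb_regions(ch$img, B6, ch$st$B3, tvb)
  r2 <- segment_vb_regions(ch$img, B6, ch$st$B3, tvb)
  expect_identical(label_vertebrae(r1)[c("canal_z_sup", "canal_z_inf")],
                   label_vertebrae(r2)[c("canal_z_sup", "canal_z_inf")])
})
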