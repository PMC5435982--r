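test_that("f1 counts isointense pixels in the 5-neighbour window", {
  img <- stripe_image(10, 4, bg = 20, stripes = list(list(cols = 4:8, value = 80)))
  cmap <- threshold_cmap(img)
  f <- fitness_f1(img, cmap)
  expect_equal(f$values[6, 1], 5)            # all five neighbours iso
  expect_equal(f$values[1, 1], 0)            # none
  expect_equal(f$values[4, 1], 3)            # 4,5,6 iso; 2,3 not
  # at the image edge, out-of-image neighbours count as non-iso
  img2 <- stripe_image(6, 3, bg = 20, stripes = list(list(cols = c(1, 3), value = 80)))
  f2 <- fitness_f1(img2, threshold_cmap(img2))
  expect_equal(f2$values[1, 1], 2)           # window {-,-,1,2,3}: iso at 1 and 3
})

test_that("f2 rewards local homogeneity with the stated constants", {
  img <- stripe_image(20, 3, bg = 100)
  f <- fitness_f2(img)
  expect_equal(f$values[10, 2], 6 * 65536)   # constant row -> 393216
  # one deviating pixel: hand-summed window
  m <- matrix(100, 20, 3); m[12, 2] <- 110
  fh <- fitness_f2(gray_image(m))
  expect_equal(fh$values[10, 2], 4 * 65536 + 2 * (65536 - 100))
  # maximal single-pair contrast nearly cancels its term
  m2 <- matrix(0, 20, 3); m2[12, ] <- 255
  f2 <- fitness_f2(gray_image(m2))
  expect_equal(f2$values[10, 1], 4 * 65536 + 2 * (65536 - 255^2))
})

test_that("f3/f4 and f5 implement the stated arithmetic", {
  img <- gray_image(matrix(c(0L, 255L, 128L), 3, 2))
  f34 <- fitness_f3f4(img)
  expect_equal(f34$values[, 1], c(65536, 1, 16384))

  m <- matrix(0, 30, 2); m[11:26, ] <- 128
  f5 <- fitness_f5(gray_image(m))
  expect_equal(f5$values[10, 1], 65536 + 16 * 16384)
  f5z <- fitness_f5(gray_image(matrix(0, 25, 2)))
  expect_equal(f5z$values[3, 1], 65536)
  # random row hand-summed
  set.seed(41)
  mr <- matrix(sample(0:255, 60, TRUE), 30, 2)
  f5r <- fitness_f5(gray_image(mr))
  y <- 7
  expect_equal(f5r$values[y, 2],
               (256 - mr[y, 2])^2 + sum(mr[(y + 1):(y + 16), 2]^2))
})

test_that("B1 follows the longest isointense structure", {
  # one continuous iso stripe against a broken competitor
  m <- matrix(20, 40, 30)
  m[10:16, ] <- 80                 # continuous stripe
  m[28:34, ] <- 80; m[28:34, 15:17] <- 200   # broken by hyper rows
  img <- gray_image(m)
  cmap <- threshold_cmap(img)
  B1 <- detect_B1(img, cmap)
  expect_true(all(B1$values >= 10 & B1$values <= 16))
  # all-hypo image: total 0, flagged low-confidence
  hypo <- gray_image(matrix(30L, 20, 20))
  B1h <- detect_B1(hypo, threshold_cmap(hypo))
  expect_true(isTRUE(attr(B1h, "low_confidence")))
})

test_that("B2 stays within 40 pixels of B1 and ties break deterministically", {
  ch <- structure_fixture(1)
  expect_true(all(abs(ch$st$B2$values - ch$st$B1$values) <= 40))
  # uniform image: f2 is flat away from the borders, so the tie-break gives
  # a straight path at the first column whose window is fully in-image
  img <- gray_image(matrix(50L, 30, 10))
  B1 <- path_curve(1, 10, rep(15L, 10))
  B2 <- detect_B2(img, B1)
  expect_equal(B2$values, rep(4L, 10))
})

test_that("candidate arbitration prefers the stabler cord signal", {
  base <- matrix(60, 30, 60)
  noisy <- base
  set.seed(42)
  noisy[15, ] <- 60 + sample(c(-20, 20), 60, TRUE)
  a <- gray_image(base); b <- gray_image(pmax(pmin(noisy, 255), 0))
  B2 <- path_curve(1, 60, rep(15L, 60))
  expect_equal(choose_candidate_slice(list(a, b), list(B2, B2)), 1L)
  expect_equal(choose_candidate_slice(list(b, a), list(B2, B2)), 2L)
  expect_equal(choose_candidate_slice(list(a, a), list(B2, B2)), 1L)  # tie
  expect_equal(choose_candidate_slice(list(a), list(B2)), 1L)
})

test_that("detected structures respect anatomical ordering and bands", {
  ch <- structure_fixture(1)
  st <- ch$st
  expect_true(all(st$B5$values < st$B3$values))
  expect_true(all(st$B3$values < st$B2$values))
  expect_true(all(st$B2$values < st$B4$values))
  expect_true(all(st$B4$values - st$B3$values <= 60))
  expect_true(all(st$B3$values - st$B5$values >= 21 &
                  st$B3$values - st$B5$values <= 60))
})

test_that("noise-free phantom: ligaments found within 1 px, ALL within 2 px", {
  ph <- phantom_fixture(seed = 50, noise_sd = 0)
  ch <- local({
    img <- ph$series$slices[[7]]
    fit <- repair_iso_upper(classify_gray_levels(fit_histogram_gmm(img)))
    detect_structures(img, fit)
  })
  L <- ph$truth$layout
  off <- ph$truth$offset
  expect_lte(max(abs(ch$B3$values - (L$pll_a + off))), 1)
  expect_lte(max(abs(ch$B4$values - (L$lf_a + off))), 1)
  # ALL is defined along the vertebral column; skip the 3-row transition at
  # the canal top where the band re-enters from the skull base
  rows <- (ph$truth$canal[1] + 4):ph$truth$canal[2]
  expect_lte(max(abs((ch$B5$values - (L$all_a + off))[rows])), 2)
  # cord paths inside the true cord at (virtually) every row
  in_cord <- ch$B2$values >= L$cord_a + off & ch$B2$values <= L$cord_p + off
  expect_gte(mean(in_cord), 0.95)
})

test_that("clean phantoms keep every curve inside its structure band", {
  for (s in c(1, 2, 3)) {
    ch <- structure_fixture(s)
    L <- ch$ph$truth$layout; off <- ch$ph$truth$offset
    in_cord <- function(B) mean(B$values >= L$cord_a + off &
                                B$values <= L$cord_p + off)
    expect_gte(in_cord(ch$st$B1), 0.95)
    expect_gte(in_cord(ch$st$B2), 0.95)
  }
})
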