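test_that("compute_cv is population SD over mean and scale invariant", {
  m <- matrix(1L, 2, 2)
  expect_equal(compute_cv(matrix(7, 2, 2), m, 1), 0)
  img <- matrix(c(2, 2, 4, 4), 2, 2)
  expect_equal(compute_cv(img, m, 1), 1 / 3)
  expect_equal(compute_cv(5.7 * img, m, 1), compute_cv(img, m, 1))
  expect_error(compute_cv(img, m, 9), "absent")
  expect_error(compute_cv(matrix(0, 2, 2), m, 1), "zero")
})

test_that("a bright cluster pixel strictly increases the CV", {
  mask <- matrix(1L, 10, 10)
  flat <- matrix(100, 10, 10)
  clustered <- flat
  clustered[5, 5] <- 400
  expect_gt(compute_cv(clustered, mask, 1), compute_cv(flat, mask, 1))
})

test_that("relative_cv normalizes to the first time point", {
  expect_equal(relative_cv(c(0.1, 0.2, 0.15)), c(1, 2, 1.5))
  expect_equal(relative_cv(rep(0.4, 5)), rep(1, 5))
  expect_equal(relative_cv(0.3), 1)
  expect_error(relative_cv(c(0, 1)), "positive")
})

test_that("LoG detector finds planted spots and nothing else", {
  cfg <- synthetic_config(seed = 51, image_size_px = 96, noise_sd = 0,
                          background_level = 100, spot_sigma_px = 1.5)
  bg <- render_fish_image(data.frame(x_um = numeric(0), y_um = numeric(0),
                                     peak_intensity = numeric(0)), cfg)
  expect_equal(nrow(detect_spots(bg$image, sigma_px = 1.5,
                                 min_response = 10)), 0L)

  psz <- cfg$pixel_size_um
  one <- render_fish_image(data.frame(x_um = 30.2 * psz, y_um = 47.7 * psz,
                                      peak_intensity = 300), cfg)
  det <- detect_spots(one$image, sigma_px = 1.5, min_response = 50,
                      pixel_size_um = psz)
  expect_equal(nrow(det), 1L)
  expect_lt(sqrt((det$x_um - 30.2 * psz)^2 + (det$y_um - 47.7 * psz)^2) / psz,
            1)

  # two spots separated by >= 4 sigma resolve separately
  two <- render_fish_image(data.frame(x_um = c(30, 30 + 7) * psz,
                                      y_um = c(40, 40) * psz,
                                      peak_intensity = c(300, 280)), cfg)
  expect_equal(nrow(detect_spots(two$image, sigma_px = 1.5,
                                 min_response = 50)), 2L)
})

test_that("detection count is monotone non-increasing in the threshold", {
  pf <- planted_field(seed = 61)
  counts <- vapply(c(20, 40, 60, 90, 1e4), function(thr) {
    nrow(detect_spots(pf$image, sigma_px = pf$sigma_px, min_response = thr))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_equal(counts[length(counts)], 0)
})

test_that("detections are restricted to labelled nuclei", {
  cfg <- synthetic_config(seed = 52, image_size_px = 96, noise_sd = 0)
  psz <- cfg$pixel_size_um
  img <- render_fish_image(data.frame(x_um = c(20, 70) * psz,
                                      y_um = c(20, 70) * psz,
                                      peak_intensity = c(300, 300)), cfg)
  mask <- matrix(0L, 96, 96)
  mask[1:48, 1:48] <- 3L  # only the first spot's region is labelled
  det <- detect_spots(img$image, mask = mask, sigma_px = 1.5,
                      min_response = 50, pixel_size_um = psz)
  expect_equal(nrow(det), 1L)
  expect_equal(det$nucleus_label, 3L)
})

test_that("phase correlation recovers planted shifts exactly", {
  set.seed(71)
  img <- matrix(stats::rnorm(128^2), 128, 128)
  r0 <- register_translation(img, img)
  expect_equal(unname(r0$shift), c(0, 0))
  expect_true(r0$ok)
  for (sh in list(c(5, -3), c(-12, 7))) {
    pr <- make_registration_pair(img, sh)
    expect_equal(unname(register_translation(pr$reference, pr$moving)$shift),
                 sh)
    expect_equal(unname(register_translation(pr$moving, pr$reference)$shift),
                 -sh)
  }
  expect_error(register_translation(img, matrix(0, 10, 10)), "shapes")
})

test_that("unrelated noise fields are flagged as failed registrations", {
  set.seed(72)
  a <- matrix(stats::rnorm(256^2), 256, 256)
  b <- matrix(stats::rnorm(256^2), 256, 256)
  r <- register_translation(a, b)
  expect_false(r$ok)
})

test_that("roi_mean uses the pixel-center disk with border clipping", {
  img <- matrix(9.5, 64, 64)
  psz <- 0.108
  center <- c(31.5 * psz, 31.5 * psz)  # a pixel center
  r <- roi_mean(img, center, 1.08, psz)
  expect_equal(r$mean, 9.5)
  # 1.08 um at 0.108 um/px is a 10-px-radius disk
  expect_equal(r$n_px, sum(outer((-20:20)^2, (-20:20)^2, `+`) <= 100))

  # corner: only the in-image quadrant remains
  rc <- roi_mean(img, c(0.5 * psz, 0.5 * psz), 1.08, psz)
  expect_equal(rc$n_px, sum(outer((0:10)^2, (0:10)^2, `+`) <= 100))
  expect_error(roi_mean(img, c(-50, -50), 1.08, psz), "outside")
  expect_error(roi_mean(img, c(1, 1), -1, psz), "radius_um > 0")
})

test_that("roi_mean decreases away from a rendered spot", {
  cfg <- synthetic_config(seed = 81, image_size_px = 96, noise_sd = 0,
                          background_level = 0)
  psz <- cfg$pixel_size_um
  ctr <- c(48.5, 48.5) * psz
  img <- render_fish_image(data.frame(x_um = ctr[1], y_um = ctr[2],
                                      peak_intensity = 500), cfg)$image
  means <- vapply(c(0, 0.3, 0.6, 1.2), function(off) {
    roi_mean(img, ctr + c(off, 0), 0.3, psz)$mean
  }, numeric(1))
  expect_true(all(diff(means) < 0))
})

test_that("region features report area, solidity and intensities", {
  m <- matrix(0L, 30, 30)
  m[5:14, 5:14] <- 1L              # 10x10 square
  m[20:28, 24] <- 2L               # plus shape
  m[24, 20:28] <- 2L
  ch <- matrix(2, 30, 30)
  ch[m == 2L] <- 10
  rf <- region_features(m, images = list(gfp = ch), pixel_size_um = 0.108)
  sq <- rf[rf$label == 1L, ]
  expect_equal(sq$area_um2, 100 * 0.108^2)
  expect_equal(sq$solidity, 1)
  expect_equal(sq$mean_intensity_gfp, 2)
  plus <- rf[rf$label == 2L, ]
  expect_lt(plus$solidity, 1)
  expect_equal(plus$mean_intensity_gfp, 10)
  expect_error(region_features(matrix(0L, 5, 5)), "no labels")
})
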