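test_that("Manders coefficients match hand-computed and limiting cases", {
  a <- array(stats::runif(4 * 4 * 4), c(4, 4, 4))
  m_id <- manders_coefficients(a, a)
  expect_equal(m_id$m1, 1)
  expect_equal(m_id$m2, 1)

  b <- array(0, dim(a)); b[1, 1, 1] <- 3
  d <- array(0, dim(a)); d[4, 4, 4] <- 2
  m_dis <- manders_coefficients(b, d)
  expect_equal(m_dis$m1, 0)
  expect_equal(m_dis$m2, 0)

  # 2x2 example: A = [[10, 0], [5, 0]], B = [[1, 1], [0, 0]]
  A <- matrix(c(10, 5, 0, 0), 2, 2)
  B <- matrix(c(1, 0, 1, 0), 2, 2)
  m <- manders_coefficients(A, B)
  expect_equal(m$m1, 10 / 15)
  expect_equal(m$m2, 1 / 2)

  expect_error(manders_coefficients(a, array(0, c(2, 2, 2))), "dimensions")
  expect_warning(mz <- manders_coefficients(b * 0, d), "undefined")
  expect_true(mz$undefined)
  expect_true(is.na(mz$m1))
})

test_that("M1 recovers the simulated colocalized signal fraction", {
  cs <- confocal_spec(shape = c(10, 64, 64), n_structures = 8,
                      fraction_colocalized = 0.5, psf_sigma = 0,
                      noise_sd = 0, seed = 17)
  st <- simulate_confocal_stack(cs)
  m <- manders_coefficients(st$channel_a, st$channel_b)
  expect_equal(m$m1, st$truth$coloc_signal_fraction_a, tolerance = 1e-9)
})

test_that("M1 and M2 rise with the generator's colocalized fraction", {
  fr <- c(0, 0.25, 0.5, 0.75, 1)
  res <- vapply(fr, function(f) {
    cs <- confocal_spec(shape = c(10, 64, 64), n_structures = 8,
                        fraction_colocalized = f, psf_sigma = 0,
                        noise_sd = 0, seed = 23)
    st <- simulate_confocal_stack(cs)
    m <- manders_coefficients(st$channel_a, st$channel_b)
    c(m$m1, m$m2)
  }, numeric(2L))
  expect_true(all(diff(res[1L, ]) >= 0))
  expect_true(all(diff(res[2L, ]) >= 0))
  expect_equal(res[1L, 1L], 0)
  expect_equal(res[1L, 5L], 1)
})

test_that("percent volume counts voxels above the two thresholds", {
  u <- array(10, c(2, 2, 2))
  expect_equal(percent_volume(u, low_threshold = 1, mt_threshold = 5), 100)
  v <- array(c(2, 2, 2, 2, 2, 2, 9, 9), c(2, 2, 2))
  expect_equal(percent_volume(v, low_threshold = 1, mt_threshold = 5), 25)
  expect_equal(percent_volume(v, low_threshold = 1, mt_threshold = 100), 0)
  expect_error(percent_volume(v, low_threshold = 5, mt_threshold = 1),
               "mt_threshold")
  expect_warning(pv <- percent_volume(v, low_threshold = 100,
                                      mt_threshold = 200), "undefined")
  expect_true(is.na(pv))
})

test_that("percent volume is invariant under monotone rescaling", {
  set.seed(31)
  v <- array(stats::rgamma(4 * 6 * 6, 2, 1), c(4, 6, 6))
  p1 <- percent_volume(v, low_threshold = 0.5, mt_threshold = 2)
  p2 <- percent_volume(exp(v), low_threshold = exp(0.5), mt_threshold = exp(2))
  expect_equal(p1, p2)
})

test_that("ROI boxes restrict every quantification", {
  st <- array(0, c(6, 10, 10))
  st[, 1:5, ] <- 100
  roi <- roi_box(c(1, 7), c(1, 6), c(1, 11), "tip")
  expect_equal(percent_volume(st, roi, low_threshold = -1, mt_threshold = 50),
               100)
  a <- st; b <- st
  b[, 6:10, ] <- 100   # B-only signal outside the ROI
  m <- manders_coefficients(a, b, roi = roi)
  expect_equal(m$m1, 1)
  expect_error(roi_box(c(1, 7), c(1, 20), c(1, 11)), NA)
  expect_error(percent_volume(st, roi_box(c(1, 20), c(1, 6), c(1, 11)),
                              low_threshold = -1, mt_threshold = 50),
               "bounds")
})

test_that("mean ROI intensity averages the requested medial planes", {
  st <- array(5, c(7, 4, 4))
  expect_equal(mean_roi_intensity(st), 5)
  st2 <- array(0, c(2, 3, 3)); st2[1, , ] <- 10; st2[2, , ] <- 20
  expect_equal(mean_roi_intensity(st2, planes = 1:2), 15)
  roi1 <- roi_box(c(1, 2), c(2, 3), c(2, 3), "shank")
  st2[1, 2, 2] <- 42
  expect_equal(mean_roi_intensity(st2, roi = roi1, planes = 1), 42)
  expect_error(mean_roi_intensity(st2, planes = 9), "planes outside")
  # default medial window: centre 5 planes of 7
  expect_equal(tubulemorph:::central_planes(7), 2:6)
  expect_equal(tubulemorph:::central_planes(16), 6:10)
})

test_that("micrometre ROI widths convert to voxels rounding half up", {
  expect_equal(um_to_voxels(5, 200), 25L)
  expect_equal(um_to_voxels(5, 300), 17L)
  expect_equal(um_to_voxels(0.05, 200), 1L)
})
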