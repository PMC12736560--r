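test_that("CSV reader handles both dialects, extras and format errors", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c('frame,"x [nm]","y [nm]","intensity [photon]","uncertainty [nm]"',
               "1,100.5,200.25,850,12",
               "2,300,400,900,10"), f)
  tab <- read_localizations(f)
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$x, c(100.5, 300))
  expect_equal(tab$uncertainty, c(12, 10))

  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c('frame,"x [nm]","y [nm]",chi2', "1,5,6,0.9"), f2)
  expect_warning(tab2 <- read_localizations(f2), "chi2")
  expect_equal(tab2$y, 6)

  f3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c('frame,"x [nm]"', "1,5"), f3)
  expect_error(read_localizations(f3), "x/y columns")

  f4 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("x,y", "1.5,2.5"), f4)
  expect_equal(read_localizations(f4)$x, 1.5)
})

test_that("writer/reader round-trip preserves coordinates and header", {
  sim <- random_tubule_field(2, seed = 5)
  f <- withr::local_tempfile(fileext = ".csv")
  write_localizations(sim$locs, f)
  expect_identical(
    readLines(f, n = 1L),
    'frame,"x [nm]","y [nm]","intensity [photon]","uncertainty [nm]"')
  back <- read_localizations(f)
  expect_equal(back$x, sim$locs$x, tolerance = 1e-12)
  expect_equal(back$y, sim$locs$y, tolerance = 1e-12)
  expect_equal(back$frame, sim$locs$frame)
})

test_that("histogram binning is half-open with floor indexing", {
  locs <- data.frame(x = c(10, 30), y = c(10, 10))
  img <- render_histogram(locs, 20, extent = c(0, 40, 0, 20))
  expect_equal(dim(img$counts), c(1L, 2L))
  expect_equal(img$counts[1L, ], c(1L, 1L))
  # a point exactly on a bin edge belongs to the upper bin
  img2 <- render_histogram(data.frame(x = 20, y = 0), 20,
                           extent = c(0, 40, 0, 20))
  expect_equal(img2$counts[1L, ], c(0L, 1L))
  # empty table renders an all-zero image, not an error
  img0 <- render_histogram(data.frame(x = numeric(0), y = numeric(0)), 20,
                           extent = c(0, 100, 0, 100))
  expect_true(all(img0$counts == 0L))
})

test_that("rendered counts conserve the number of in-extent localizations", {
  sim <- random_tubule_field(4, seed = 7, background_density = 5e-8)
  img <- render_histogram(sim$locs, 20)
  expect_equal(sum(img$counts), nrow(sim$locs))
  # restricting the extent drops exactly the out-of-extent points
  ext <- c(0, 2000, 0, 2000)
  img2 <- render_histogram(sim$locs, 20, extent = ext)
  inext <- sum(sim$locs$x >= 0 & sim$locs$x < 2000 &
                 sim$locs$y >= 0 & sim$locs$y < 2000)
  expect_equal(sum(img2$counts), inext)
})

test_that("uniform random points fill pixels multinomially", {
  set.seed(42)
  locs <- data.frame(x = stats::runif(1000, 0, 200),
                     y = stats::runif(1000, 0, 200))
  img <- render_histogram(locs, 20, extent = c(0, 200, 0, 200))
  gof <- stats::chisq.test(as.vector(img$counts),
                           p = rep(1 / 100, 100))
  expect_gt(gof$p.value, 0.001)
})

test_that("rotation is a rigid motion on the continuous list", {
  sim <- random_tubule_field(2, seed = 9)
  expect_equal(rotate_localizations(sim$locs, 0, c(5, 5)), sim$locs)
  p <- rotate_localizations(data.frame(x = 1, y = 0), pi / 2, c(0, 0))
  expect_equal(c(p$x, p$y), c(0, 1), tolerance = 1e-12)
  rot <- rotate_localizations(sim$locs, 0.7321, c(100, -50))
  i <- seq(1, min(200, nrow(sim$locs)))
  d0 <- dist(cbind(sim$locs$x[i], sim$locs$y[i]))
  d1 <- dist(cbind(rot$x[i], rot$y[i]))
  expect_equal(as.vector(d1), as.vector(d0), tolerance = 1e-9)
  # non-coordinate fields untouched
  expect_identical(rot$frame, sim$locs$frame)
  expect_identical(rot$intensity, sim$locs$intensity)
})

test_that("rendering after a quarter-turn permutes pixel counts exactly", {
  set.seed(3)
  locs <- data.frame(x = stats::runif(500, 0, 200),
                     y = stats::runif(500, 0, 200))
  px <- 20
  img <- render_histogram(locs, px, extent = c(0, 200, 0, 200))
  rot <- rotate_localizations(locs, pi / 2, c(100, 100))
  img90 <- render_histogram(rot, px, extent = c(0, 200, 0, 200))
  # (x,y) -> (cx - (y-cy), cy + (x-cx)): new row index = old column index,
  # new column index = n + 1 - old row index
  expected <- img$counts * 0L
  n <- nrow(img$counts)
  for (r in seq_len(n)) for (cc in seq_len(n))
    expected[cc, n + 1L - r] <- img$counts[r, cc]
  expect_identical(img90$counts, expected)
})
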