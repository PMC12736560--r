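test_that("specs validate their fields and name the offender", {
  expect_error(tubule_spec(rbind(c(0, 0)), 25), "centerline")
  expect_error(tubule_spec(rbind(c(0, 0), c(0, 0)), 25), "centerline")
  expect_error(tubule_spec(rbind(c(0, 0), c(10, 0)), -1), "outer_diameter")
  tb <- tubule_spec(rbind(c(0, 0), c(10, 0)), 25)
  expect_error(field_spec(c(-1, 100), list(tb), 0.1, 4), "field_size")
  expect_error(field_spec(c(100, 100), list(tb), -0.1, 4), "labeling_density")
  expect_error(field_spec(c(100, 100), list(tb), 0.1, 4,
                          loc_precision_sigma = -1), "loc_precision_sigma")
  expect_error(confocal_spec(fraction_colocalized = 1.2),
               "fraction_colocalized")
  expect_error(confocal_spec(shape = c(0, 4, 4)), "shape")
})

test_that("zero-rate processes give an empty localization table", {
  tb <- tubule_spec(rbind(c(100, 100), c(900, 100)), 25)
  fs <- field_spec(c(1000, 1000), list(tb), labeling_density = 0,
                   locs_per_emitter_mean = 4, background_density = 0,
                   seed = 4)
  sim <- simulate_tubule_field(fs)
  expect_equal(nrow(sim$locs), 0L)
  expect_equal(sim$truth$n_background, 0L)
})

test_that("fixed seed reproduces tables bitwise; seeds differ otherwise", {
  tb <- tubule_spec(rbind(c(100, 500), c(4900, 500)), 25)
  fs <- field_spec(c(5000, 1000), list(tb), 0.05, 4, 2, 1e-7, seed = 11)
  a <- simulate_tubule_field(fs)
  b <- simulate_tubule_field(fs)
  expect_identical(a$locs, b$locs)
  expect_identical(a$truth, b$truth)
  fs2 <- fs; fs2$seed <- 12L
  expect_false(identical(simulate_tubule_field(fs2)$locs, a$locs))
})

test_that("localization count follows the compound Poisson expectation", {
  # 10,000 nm tubule, 0.05 emitters/nm, 4 locs/emitter -> mean 2000,
  # var = E[N] var(L) + var(N) E[L]^2 = 500*4 + 500*16 = 10,000
  counts <- vapply(1:20, function(s) {
    tb <- tubule_spec(rbind(c(100, 500), c(10100, 500)), 25)
    fs <- field_spec(c(10200, 1000), list(tb), 0.05, 4, 2, 0, seed = s)
    nrow(simulate_tubule_field(fs)$locs)
  }, numeric(1L))
  se_mean <- sqrt(10000 / 20)
  expect_lt(abs(mean(counts) - 2000), 4 * se_mean)
})

test_that("counts are conserved between table and ground truth", {
  sim <- random_tubule_field(5, diameters = c(25, 75), seed = 3,
                             background_density = 2e-8)
  expect_equal(nrow(sim$locs),
               sum(sim$truth$tubules$n_localizations) + sim$truth$n_background)
  expect_equal(length(sim$truth$assignment), nrow(sim$locs))
  expect_true(all(stats::na.omit(sim$truth$assignment) %in%
                    sim$truth$tubules$label))
})

test_that("with zero precision all tubule localizations lie inside d/2", {
  tb <- tubule_spec(rbind(c(200, 300), c(1800, 900)), 60)
  fs <- field_spec(c(2000, 1200), list(tb), 0.1, 3, 0, 0, seed = 8)
  sim <- simulate_tubule_field(fs)
  d <- tubulemorph:::dist_to_polyline(cbind(sim$locs$x, sim$locs$y),
                                      tb$centerline)
  expect_true(all(d <= 30 + 1e-9))
  # ground-truth length is the arc length
  expect_equal(sim$truth$tubules$length_nm,
               sqrt(sum((c(1800, 900) - c(200, 300))^2)))
})

test_that("confocal channels obey the colocalization ground truth", {
  # full colocalization, no blur, no noise: identical channels
  cs1 <- confocal_spec(shape = c(8, 32, 32), n_structures = 4,
                       fraction_colocalized = 1, seed = 2)
  st1 <- simulate_confocal_stack(cs1)
  expect_identical(st1$channel_a, st1$channel_b)
  # no colocalization, no blur: empty intersection of supports
  cs0 <- confocal_spec(shape = c(8, 40, 40), n_structures = 3,
                       fraction_colocalized = 0, seed = 2)
  st0 <- simulate_confocal_stack(cs0)
  expect_equal(sum(st0$channel_a > 0 & st0$channel_b > 0), 0L)
  # fraction 0.5 of 10 structures: exactly 5 shared ids
  cs5 <- confocal_spec(shape = c(10, 72, 72), n_structures = 10,
                       fraction_colocalized = 0.5, structure_length = 400,
                       structure_radius = 120, seed = 6)
  st5 <- simulate_confocal_stack(cs5)
  expect_length(st5$truth$shared_ids, 5L)
  # clean channel equals amplitude * mask exactly when PSF and noise are 0
  expect_identical(st1$channel_a, 100 * (st1$truth$mask_a + 0))
})

test_that("confocal stacks are deterministic given the seed", {
  cs <- confocal_spec(shape = c(6, 64, 64), n_structures = 5,
                      fraction_colocalized = 0.4, structure_length = 400,
                      structure_radius = 120, psf_sigma = 150,
                      noise_sd = 2, seed = 13)
  expect_identical(simulate_confocal_stack(cs)$channel_b,
                   simulate_confocal_stack(cs)$channel_b)
})
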