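test_that("thinning keeps a single pixel and stays inside the mask", {
  m <- matrix(FALSE, 5, 5); m[3, 3] <- TRUE
  expect_identical(skeletonize_mask(m), m)
  set.seed(14)
  blob <- matrix(stats::runif(900) < 0.4, 30, 30)
  sk <- skeletonize_mask(blob)
  expect_true(all(blob[sk]))
})

test_that("a filled bar thins to a line in its middle row", {
  m <- matrix(FALSE, 7, 24)
  m[3:5, 3:22] <- TRUE
  sk <- skeletonize_mask(m)
  px <- which(sk, arr.ind = TRUE)
  expect_true(all(px[, "row"] == 4L))
  expect_gte(nrow(px), 16L)
  expect_lte(nrow(px), 20L)
  bs <- split_branches(sk)
  expect_length(bs$branches, 1L)
})

test_that("branch decomposition handles lines, Ys and cycles", {
  # straight 10-px line: one branch, two endpoints, length 9
  line <- matrix(FALSE, 5, 12)
  line[3, 2:11] <- TRUE
  bs <- split_branches(line)
  expect_length(bs$branches, 1L)
  b <- bs$branches[[1L]]
  expect_false(b$is_cycle)
  expect_equal(nrow(b$path), 10L)
  expect_equal(b$length_px, 9)
  expect_equal(sort(b$endpoints[, "col"]), c(2L, 11L))

  # Y: three 6-px arms meeting at one junction pixel -> 3 branches
  y <- matrix(FALSE, 15, 15)
  y[8, 2:7] <- TRUE
  for (k in 0:6) { y[8 - k, 8 + k] <- TRUE; y[8 + k, 8 + k] <- TRUE }
  bsy <- split_branches(y)
  expect_length(bsy$branches, 3L)
  expect_equal(nrow(bsy$junctions), 1L)

  # 12-px closed diamond ring: one cyclic branch, no junctions
  r <- matrix(FALSE, 9, 9)
  pts <- rbind(c(1, 4), c(2, 3), c(3, 2), c(4, 1), c(5, 2), c(6, 3),
               c(7, 4), c(6, 5), c(5, 6), c(4, 7), c(3, 6), c(2, 5))
  r[pts] <- TRUE
  bsr <- split_branches(r)
  expect_length(bsr$branches, 1L)
  expect_true(bsr$branches[[1L]]$is_cycle)
  expect_equal(nrow(bsr$branches[[1L]]$path), 12L)
  expect_equal(nrow(bsr$junctions), 0L)
})

test_that("straightness is chord over diagonal-aware path length", {
  line <- row_branch(3, 2:11)
  expect_equal(branch_straightness(line), 1)

  # right-angle L with two 5-step arms: chord 5*sqrt(2), path 10
  pm <- rbind(cbind(1L, 1:6), cbind(2:6, 6L))
  colnames(pm) <- c("row", "col")
  lbr <- structure(list(path = pm, endpoints = pm[c(1L, nrow(pm)), ],
                        is_cycle = FALSE, length_px = 10),
                   class = "branch")
  expect_equal(branch_straightness(lbr), 5 * sqrt(2) / 10, tolerance = 1e-12)

  # 8-connected digital quarter circle (greedy walk along the curve):
  # continuous chord/arc = 2*sqrt(2)/pi = 0.900; the chain-code path
  # length overestimates the arc by ~5% on average (the per-angle factor
  # cos(t) + (sqrt(2)-1) sin(t) integrates to ~1.054), so the digital
  # ratio is expected near 0.900 / 1.054 = 0.85
  R <- 30
  p <- c(0, R)                      # (row, col) offsets from the centre
  pts <- matrix(p, 1L)
  while (p[2L] > 0) {
    cand <- rbind(p + c(1, 0), p + c(1, -1), p + c(0, -1))
    ang <- atan2(cand[, 1L], cand[, 2L])
    okc <- ang > atan2(p[1L], p[2L]) + 1e-12
    cand <- cand[okc, , drop = FALSE]
    err <- abs(sqrt(rowSums(cand^2)) - R)
    p <- cand[which.min(err), ]
    pts <- rbind(pts, p)
  }
  pts <- cbind(row = pts[, 1L] + 1L, col = pts[, 2L] + 1L)
  steps <- sqrt(rowSums(diff(pts)^2))
  expect_true(all(steps <= sqrt(2) + 1e-9))   # 8-connected path
  arc <- structure(list(path = pts, endpoints = pts[c(1L, nrow(pts)), ],
                        is_cycle = FALSE, length_px = sum(steps)),
                   class = "branch")
  expect_equal(branch_straightness(arc), 2 * sqrt(2) / pi / 1.054,
               tolerance = 0.03)

  # cycles are rejected
  cyc <- structure(list(path = pts, endpoints = pts[c(1L, nrow(pts)), ],
                        is_cycle = TRUE, length_px = sum(steps)),
                   class = "branch")
  expect_error(branch_straightness(cyc), "cycle")
})

test_that("orientation is the principal axis mapped to (-pi/2, pi/2]", {
  expect_equal(branch_orientation(row_branch(3, 1:10)), 0)
  diag_pm <- cbind(row = 1:8, col = 1:8)
  dbr <- structure(list(path = diag_pm), class = "branch")
  expect_equal(branch_orientation(dbr), pi / 4, tolerance = 1e-9)
  vert <- structure(list(path = cbind(row = 1:9, col = rep(4L, 9))),
                    class = "branch")
  expect_equal(branch_orientation(vert), pi / 2)
  set.seed(21)
  jit <- cbind(row = 5L + sample(-1:1, 30, TRUE), col = 1:30)
  jbr <- structure(list(path = jit), class = "branch")
  expect_lt(abs(branch_orientation(jbr)), 0.1)
})
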