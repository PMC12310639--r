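test_that("edge indicator is 1 in flat regions and collapses at edges", {
  expect_equal(edge_indicator(matrix(4, 8, 8)), matrix(1, 8, 8))
  # unit ramp: |grad| = 1 by central differences, g = 0.5 in the interior
  ramp <- matrix(rep(0:9, each = 10), nrow = 10)
  g <- edge_indicator(ramp, smooth_sigma = 0)
  expect_equal(g[3:8, 3:8], matrix(0.5, 6, 6))
  # 8-bit step edge: smoothed slope ~ 0.4 * 255 makes g tiny at the edge
  step <- matrix(rep(c(0, 255), each = 80), 16, 10)
  gs <- edge_indicator(step, smooth_sigma = 1)
  expect_lt(min(gs[, 5:6]), 0.001)
  # range and monotonicity in |grad I|
  expect_true(all(gs > 0 & gs <= 1))
  ramp2 <- matrix(rep(seq(0, 27, by = 3), each = 10), nrow = 10)
  g2 <- edge_indicator(ramp2, smooth_sigma = 0)
  expect_true(all(g2[4, 4] < g[4, 4]))
})

test_that("level-set curvature flow shrinks a circle at rate mu*kappa", {
  st <- level_set_init(c(64, 64), "circle", center = c(32, 32), radius = 20,
                       mu = 0.2, lam = 0, v = 0)
  radii <- numeric(0)
  s <- st
  for (i in 1:8) {
    s <- evolve_level_set(s, matrix(0, 64, 64), 20)
    radii <- c(radii, sqrt(sum(level_set_mask(s)) / pi))
  }
  expect_true(all(diff(radii) < 0)) # monotone shrinkage
  pred <- sqrt(20^2 - 2 * 0.2 * (1:8) * 20 * st$dt) # dr/dt = -mu/r
  expect_equal(radii, pred, tolerance = 0.05)
})

test_that("level set converges onto a disk boundary", {
  d <- disk_image(96L, center = c(48, 48), radius = 20)
  st <- level_set_init(c(96L, 96L), "box", mask = d$mask, inflate = 10)
  s <- evolve_level_set(st, d$img, 350)
  expect_lte(mask_circle_deviation(level_set_mask(s), c(48, 48), 20), 2)
  # energy is non-increasing within 1% of its initial value
  e <- s$energy
  expect_lt(e[length(e)], e[1])
  expect_true(all(diff(e) <= 0.01 * abs(e[1])))
})

test_that("zero evolution steps leave the state unchanged", {
  st <- level_set_init(c(32, 32), "circle", center = c(16, 16), radius = 8)
  expect_identical(evolve_level_set(st, matrix(0, 32, 32), 0), st)
})

test_that("level-set mask is the negative-phi interior", {
  st <- level_set_init(c(16, 16), "circle", center = c(8, 8), radius = 4)
  st$phi <- matrix(1, 16, 16)
  expect_false(any(level_set_mask(st)))
  big <- level_set_init(c(128, 128), "circle", center = c(64, 64), radius = 25)
  area <- sum(level_set_mask(big))
  expect_equal(area, pi * 25^2, tolerance = 0.015)
})

test_that("balloon force sign controls interior growth", {
  img <- matrix(0, 64, 64) # g == 1 everywhere
  shrink <- level_set_init(c(64, 64), "circle", center = c(32, 32),
                           radius = 15, mu = 0, lam = 0, v = 1)
  grow <- level_set_init(c(64, 64), "circle", center = c(32, 32),
                         radius = 15, mu = 0, lam = 0, v = -1)
  a0 <- sum(level_set_mask(shrink))
  expect_lt(sum(level_set_mask(evolve_level_set(shrink, img, 40))), a0)
  expect_gt(sum(level_set_mask(evolve_level_set(grow, img, 40))), a0)
})

test_that("alignment canonicalizes centroid and principal axis", {
  # canonical: vertical bar centered on an odd-sized canvas
  mk <- matrix(FALSE, 65, 65)
  mk[21:45, 31:35] <- TRUE # centroid (32, 32) = canvas center
  t0 <- estimate_alignment(mk)
  expect_equal(unlist(t0[c("a", "b", "c", "d", "tx", "ty")]),
               c(a = 1, b = 0, c = 0, d = 1, tx = 0, ty = 0),
               tolerance = 1e-6)
  # translation recovery to sub-pixel
  mk2 <- matrix(FALSE, 65, 65)
  mk2[21:45 - 5, 31:35 + 10] <- TRUE # shifted by (10, -5)
  t1 <- estimate_alignment(mk2)
  expect_equal(c(t1$tx, t1$ty), c(-10, 5), tolerance = 1e-6)
  # rotation: 30-degree bar gets verticalized within 1 degree
  ang <- pi / 6
  xs <- seq(-15, 15, by = 0.25)
  pts <- unique(round(cbind(32 + xs * sin(ang), 32 + xs * cos(ang))))
  mk3 <- matrix(FALSE, 65, 65)
  mk3[pts[, 2] + 1 + 65 * pts[, 1]] <- TRUE
  t3 <- estimate_alignment(mk3)
  px <- which(mk3, arr.ind = TRUE)
  out <- hmir:::affine_apply(t3, cbind(px[, 2] - 1, px[, 1] - 1))
  cv <- stats::cov(out)
  major <- eigen(cv, symmetric = TRUE)$vectors[, 1]
  angle_from_vertical <- abs(atan2(major[1], major[2]))
  angle_from_vertical <- min(angle_from_vertical, pi - angle_from_vertical)
  expect_lt(angle_from_vertical, pi / 180)
  expect_error(estimate_alignment(matrix(FALSE, 10, 10)), "min_area")
})

test_that("depth gradient magnitude matches central differences", {
  expect_equal(depth_gradient_magnitude(matrix(9, 6, 6)), matrix(0, 6, 6))
  ramp <- matrix(rep(3 * (0:9), each = 6), nrow = 6)
  expect_equal(depth_gradient_magnitude(ramp)[, 3:8], matrix(3, 6, 6))
  step <- matrix(rep(c(0, 10), each = 30), 6, 10)
  gm <- depth_gradient_magnitude(step)
  expect_equal(max(gm), 5) # h/2 at the columns flanking the step
})

test_that("depth silhouettes segment cleanly and equivariantly", {
  sq <- make_sequence(default_class_specs(n_frames = 4L)$cough_like, seed = 5)
  truth <- sq$ground_truth$masks[[1]]
  m <- segment_depth_silhouette(sq$depth$frames[[1]])
  expect_gte(sum(m & truth) / sum(m | truth), 0.9)
  # idempotence on mask-consistent noise-free depth
  D2 <- ifelse(truth, 1400, 2000)
  m2 <- segment_depth_silhouette(D2)
  expect_gte(sum(m2 & truth) / sum(m2 | truth), 0.99)
  # translation equivariance (identity transform)
  sh <- 7L
  D3 <- D2[c((sh + 1):nrow(D2), rep(nrow(D2), sh)), ]
  m3 <- segment_depth_silhouette(D3)
  expect_equal(m3[1:(nrow(D2) - sh - 2), ], m2[(sh + 1):(nrow(D2) - 2), ])
  expect_error(segment_depth_silhouette(matrix(5, 20, 20)), "transitions")
})

test_that("affine transforms validate and invert", {
  expect_error(affine_transform(1, 2, 0.5, 1), "invertible")
  t1 <- affine_transform(0.8, -0.3, 0.3, 0.8, 5, -2)
  inv <- hmir:::affine_invert(t1)
  pts <- cbind(c(1, 10, -3), c(2, 0, 7))
  expect_equal(hmir:::affine_apply(inv, hmir:::affine_apply(t1, pts)), pts)
})
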