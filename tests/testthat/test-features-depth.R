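cloud_from <- function(pts) {
  structure(list(points = as.matrix(pts)), class = "point_cloud_25d")
}

test_that("depth lifts to one point per valid foreground pixel", {
  D <- matrix(1:4, 2, 2)
  pc <- depth_to_points(D, matrix(TRUE, 2, 2))
  expect_equal(nrow(pc$points), 4)
  D0 <- D; D0[1, 1] <- 0
  expect_equal(nrow(depth_to_points(D0, matrix(TRUE, 2, 2))$points), 3)
  set.seed(20)
  for (i in 1:5) {
    mk <- matrix(runif(100) < 0.5, 10, 10)
    D <- matrix(sample(0:3, 100, TRUE) * 500, 10, 10)
    n_expected <- sum(mk & D > 0)
    if (n_expected == 0) next
    expect_equal(nrow(depth_to_points(D, mk)$points), n_expected)
  }
  expect_error(depth_to_points(matrix(0, 2, 2), matrix(TRUE, 2, 2)), "valid")
})

test_that("point dynamics recover velocity, acceleration and curvature", {
  # static clouds on the same lattice
  pc <- cloud_from(cbind(1:4, 1, 5))
  dyn <- point_dynamics(pc, pc, pc, 1)
  expect_equal(dyn$v, pc$points * 0)
  expect_equal(dyn$kappa, rep(0, 4))
  # a 3-4-5 displacement at dt = 1
  a <- cloud_from(rbind(c(0, 0, 0)))
  b <- cloud_from(rbind(c(3, 4, 0)))
  d2 <- point_dynamics(a, b, b, 1)
  expect_equal(sqrt(sum(d2$v^2)), 5)
  # uniform circular motion: kappa = 1/r within 2% at 36 samples/revolution
  r <- 7
  th <- 2 * pi * (0:40) / 36
  circ <- cbind(r * cos(th), r * sin(th), 0)
  dyn3 <- point_dynamics(cloud_from(circ[12, , drop = FALSE]),
                         cloud_from(circ[11, , drop = FALSE]),
                         cloud_from(circ[10, , drop = FALSE]), 1)
  expect_equal(dyn3$kappa, 1 / r, tolerance = 0.02)
  # constant-velocity rigid translation leaves curvature unchanged
  off <- function(i) cbind(2 * i, -1 * i, 0)
  dyn4 <- point_dynamics(
    cloud_from(sweep(circ[12, , drop = FALSE], 2, -off(2))),
    cloud_from(sweep(circ[11, , drop = FALSE], 2, -off(1))),
    cloud_from(sweep(circ[10, , drop = FALSE], 2, -off(0))), 1)
  expect_false(isTRUE(all.equal(dyn4$kappa, dyn3$kappa))) # offset changes v
  # ... but pure translation of a static point has zero curvature
  p0 <- cloud_from(rbind(c(0, 0, 0)))
  p1 <- cloud_from(rbind(c(1, 1, 0)))
  p2 <- cloud_from(rbind(c(2, 2, 0)))
  expect_equal(point_dynamics(p2, p1, p0, 1)$kappa, 0)
  # misaligned lattices of unequal sizes error
  expect_error(point_dynamics(cloud_from(cbind(1:3, 1, 1)),
                              cloud_from(cbind(1:2, 5, 1)),
                              cloud_from(cbind(1:4, 9, 1)), 1),
               "pixel-aligned")
})

test_that("ROP features are seeded, sized and monotone", {
  mk <- matrix(FALSE, 16, 16); mk[4:12, 4:12] <- TRUE
  D <- ifelse(mk, 1400, 0)
  frames <- list(D, D, D)
  masks <- list(mk, mk, mk)
  f1 <- rop_features(frames, masks, sample_size = 32, seed = 9)
  expect_length(f1, 32 * 3)
  expect_identical(f1, rop_features(frames, masks, sample_size = 32, seed = 9))
  expect_false(identical(
    attr(f1, "sample"),
    attr(rop_features(frames, masks, sample_size = 32, seed = 10), "sample")))
  # empty masks: zero vector of the full length
  f0 <- rop_features(frames, list(mk * FALSE, mk * FALSE, mk * FALSE),
                     sample_size = 16, seed = 1)
  expect_equal(as.numeric(f0), rep(0, 48))
  # a single point in a known voxel sets exactly the expected frame entries
  mk1 <- matrix(FALSE, 8, 8); mk1[1, 1] <- TRUE
  D1 <- ifelse(mk1, 100, 0)
  dims <- c(4L, 4L, 2L)
  fs <- rop_features(list(D1, D1), list(mk1, mk1), dims = dims,
                     sample_size = prod(dims), seed = 3)
  S <- attr(fs, "sample")
  expect_equal(sum(fs), 2) # one voxel occupied per frame
  vox <- which(matrix(fs, nrow = prod(dims))[, 1] == 1)
  expect_equal(S[vox], 1L) # the (1,1,1) voxel has linear index 1
  # adding points never clears an occupancy bit (min_points = 1)
  mk2 <- mk1; mk2[5, 5] <- TRUE
  D2 <- ifelse(mk2, 100, 0)
  fs2 <- rop_features(list(D2, D2), list(mk2, mk2), dims = dims,
                      sample_size = prod(dims), seed = 3)
  expect_true(all(fs2[fs == 1] == 1))
  # permuting frames permutes the frame-major blocks
  fa <- rop_features(list(D1, D2), list(mk1, mk2), dims = dims,
                     sample_size = prod(dims), seed = 3)
  fb <- rop_features(list(D2, D1), list(mk2, mk1), dims = dims,
                     sample_size = prod(dims), seed = 3)
  nb <- prod(dims)
  expect_equal(as.numeric(fa), as.numeric(fb)[c((nb + 1):(2 * nb), 1:nb)])
  expect_error(rop_features(list(D1), list(mk1), sample_size = 1e6), "voxel")
})

test_that("movement polygons measure centroid distance profiles", {
  sqr <- rbind(c(0, 0), c(2, 0), c(2, 2), c(0, 2))
  mp <- movement_polygon(sqr)
  expect_equal(unname(mp$centroid), c(1, 1))
  expect_equal(mp$d, rep(sqrt(2), 4))
  expect_length(mp$d_theta, 360)
  # regular hexagon: max/min = 1/cos(pi/6), with vertices and edge midpoints
  # both on sampled integer degrees
  hexp <- cbind(cos(2 * pi * (0:5) / 6), sin(2 * pi * (0:5) / 6))
  mph <- movement_polygon(hexp)
  expect_equal(max(mph$d_theta) / min(mph$d_theta), 1 / cos(pi / 6),
               tolerance = 1e-6)
  # translation invariance (exact) and linear scaling of distances
  mp2 <- movement_polygon(sqr + 100)
  expect_equal(mp2$d, mp$d)
  expect_equal(mp2$d_theta, mp$d_theta)
  mp3 <- movement_polygon(sqr * 3.5)
  expect_equal(mp3$d, 3.5 * mp$d, tolerance = 1e-9)
  expect_equal(mp3$d_theta, 3.5 * mp$d_theta, tolerance = 1e-9)
  expect_error(movement_polygon(rbind(c(0, 0), c(1, 1), c(2, 2))),
               "collinear")
})

test_that("the most-moving joint drives the 20-value trajectory", {
  mk_seq <- function(tracks) {
    lapply(seq_len(nrow(tracks[[1]])), function(t) {
      lm <- do.call(rbind, lapply(tracks, function(tr) tr[t, ]))
      rownames(lm) <- names(tracks)
      build_skeleton(lm, edge_spec = list(), timestamp = t - 1)
    })
  }
  n <- 12
  still <- matrix(rep(c(5, 5), each = n), n, 2)
  osc <- cbind(5 + sin(1:n), rep(5, n))
  seqs <- mk_seq(list(a = still, b = osc, c = still))
  tr <- moving_joint_trajectory(seqs)
  expect_equal(attr(tr, "joint"), "b")
  expect_length(tr, 20)
  # motion along +x only: all angles zero
  px <- cbind(5 + (1:n), rep(3, n))
  tr2 <- moving_joint_trajectory(mk_seq(list(a = still, b = px)))
  expect_equal(as.numeric(tr2), rep(0, 20))
  # circular motion about the start sweeps monotonically once unwrapped
  th <- seq(0.3, 2.4, length.out = n)
  circ <- cbind(4 + 2 * cos(th) - 2, 4 + 2 * sin(th))
  circ <- sweep(circ, 2, circ[1, ]) + 10
  tr3 <- moving_joint_trajectory(mk_seq(list(a = still, b = circ)))
  expect_true(all(diff(as.numeric(tr3)[-1]) > -1e-9))
  # all-static input warns and returns zeros
  expect_warning(tr4 <- moving_joint_trajectory(mk_seq(list(a = still))),
                 "static")
  expect_equal(as.numeric(tr4), rep(0, 20))
})
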