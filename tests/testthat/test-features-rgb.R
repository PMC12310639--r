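test_that("trajectory and angular speeds follow finite differences", {
  static <- matrix(1, 5, 3)
  expect_equal(trajectory_velocities(static, 1), rep(0, 5))
  track <- cbind(3 * (0:4), 4 * (0:4), 0)
  expect_equal(trajectory_velocities(track, 1), c(0, 5, 5, 5, 5))
  expect_equal(trajectory_velocities(track, 0.5), 2 * c(0, 5, 5, 5, 5))
  expect_error(trajectory_velocities(track, 0), "dt")

  expect_equal(angular_velocities(cbind(rep(30, 4)), 1), rep(0, 4))
  expect_equal(angular_velocities(cbind(10 * (0:4)), 1), c(0, rep(10, 4)))
  # wraparound: 359 -> 1 unwraps to +2 degrees
  expect_equal(angular_velocities(cbind(c(359, 1)), 1)[2], 2)
})

test_that("kinetic energy sums linear and rotational segment terms", {
  mk_seq <- function(positions) {
    lapply(seq_along(positions), function(t) {
      build_skeleton(positions[[t]], edge_spec = list(c("a", "b")),
                     timestamp = t - 1)
    })
  }
  model <- data.frame(name = "seg", from = "a", to = "b",
                      mass = 2, k = 1, r = 1)
  # static: zero profile
  still <- mk_seq(replicate(4, rbind(a = c(0, 0), b = c(2, 0)),
                            simplify = FALSE))
  expect_equal(kinetic_energy_profile(still, model, 1)$total, rep(0, 4))
  # translation at speed 3: E = 1/2 * 2 * 9 = 9
  mov <- mk_seq(lapply(0:3, function(t) rbind(a = c(3 * t, 0),
                                              b = c(3 * t + 2, 0))))
  expect_equal(kinetic_energy_profile(mov, model, 1)$total, c(0, 9, 9, 9))
  # rotation about the midpoint at 2 rad/frame with I = k m r^2 = 1: E = 2
  model2 <- data.frame(name = "seg", from = "a", to = "b",
                       mass = 3, k = 1 / 3, r = 1)
  rot <- mk_seq(lapply(0:3, function(t) {
    th <- 2 * t
    rbind(a = -c(cos(th), sin(th)), b = c(cos(th), sin(th)))
  }))
  prof <- kinetic_energy_profile(rot, model2, 1)
  expect_equal(prof$total[-1], rep(2, 3), tolerance = 1e-9)
  # doubling displacement rates quadruples the linear term
  mov2 <- mk_seq(lapply(0:3, function(t) rbind(a = c(6 * t, 0),
                                               b = c(6 * t + 2, 0))))
  expect_equal(kinetic_energy_profile(mov2, model, 1)$linear[-1, 1],
               4 * kinetic_energy_profile(mov, model, 1)$linear[-1, 1])
  # missing landmark names frame and landmark
  broken <- mk_seq(replicate(3, rbind(a = c(0, 0), b = c(1, 0)),
                             simplify = FALSE))
  bad_model <- data.frame(name = "s", from = "a", to = "zz",
                          mass = 1, k = 0.5, r = 1)
  expect_error(kinetic_energy_profile(broken, bad_model, 1), "zz")
})

test_that("optical flow recovers known shifts and accepts plug-ins", {
  set.seed(10)
  a <- hmir:::gaussian_blur(matrix(runif(64 * 64), 64, 64), 1.5)
  expect_equal(estimate_flow(a, a)$u, matrix(0, 64, 64))
  b <- cbind(a[, 1:2], a[, 1:62]) # scene moves 2 px right
  fl <- estimate_flow(a, b)
  expect_equal(median(fl$u[17:48, 17:48]), 2, tolerance = 0.5)
  expect_equal(median(fl$v[17:48, 17:48]), 0, tolerance = 0.5)
  expect_error(estimate_flow(a, a[1:10, ]), "shape")
  # estimator plug-in keeps the downstream contract
  custom <- function(x, y) list(u = x * 0 + 1, v = x * 0)
  fl2 <- estimate_flow(a, b, method = custom)
  expect_s3_class(fl2, "flow_field")
  h <- hof(fl2, 8)
  expect_equal(as.numeric(h[1]), 64 * 64)
})

test_that("HOF bins conserve flow magnitude", {
  z <- structure(list(u = matrix(0, 4, 4), v = matrix(0, 4, 4)),
                 class = "flow_field")
  expect_equal(as.numeric(hof(z, 8)), rep(0, 8))
  one <- structure(list(u = matrix(1, 1, 1), v = matrix(1, 1, 1)),
                   class = "flow_field")
  h <- hof(one, 8)
  expect_equal(as.numeric(h), c(0, sqrt(2), 0, 0, 0, 0, 0, 0))
  # conservation on random fields
  set.seed(11)
  for (i in 1:10) {
    fl <- structure(list(u = matrix(rnorm(100), 10), v = matrix(rnorm(100), 10)),
                    class = "flow_field")
    K <- sample(c(4, 8, 12), 1)
    expect_equal(sum(hof(fl, K)), sum(sqrt(fl$u^2 + fl$v^2)),
                 tolerance = 1e-9)
  }
  # rotating bin-center vectors by one bin width permutes the bins cyclically
  K <- 8
  centers <- (seq_len(K) - 0.5) * (360 / K)
  u <- matrix(cos(centers * pi / 180) * seq_len(K), 1)
  v <- matrix(sin(centers * pi / 180) * seq_len(K), 1)
  h0 <- as.numeric(hof(structure(list(u = u, v = v), class = "flow_field"), K))
  rot <- 2 * pi / K
  u1 <- u * cos(rot) - v * sin(rot)
  v1 <- u * sin(rot) + v * cos(rot)
  h1 <- as.numeric(hof(structure(list(u = u1, v = v1), class = "flow_field"), K))
  expect_equal(h1, h0[c(K, 1:(K - 1))], tolerance = 1e-9)
  # region restriction
  fl <- structure(list(u = matrix(1, 4, 6), v = matrix(0, 4, 6)),
                  class = "flow_field")
  expect_equal(sum(hof(fl, 4, region = c(1, 1, 3, 2))), 6)
})

test_that("joint angles come from the clamped dot product", {
  expect_equal(joint_angle(c(1, 0), c(0, 0), c(0, 1)), 90)
  expect_equal(joint_angle(c(2, 0), c(0, 0), c(5, 0)), 0)
  expect_equal(joint_angle(c(2, 0), c(0, 0), c(-1, 0)), 180)
  expect_equal(joint_angle(c(2, 0), c(0, 0), c(1, sqrt(3))), 60)
  expect_error(joint_angle(c(0, 0), c(0, 0), c(1, 1)), "zero-length")
  # rigid + scale invariance
  set.seed(12)
  p <- matrix(rnorm(6), 3, 2)
  a0 <- joint_angle(p[1, ], p[2, ], p[3, ])
  th <- 1.1; R <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  p2 <- 3.7 * p %*% R + 5
  expect_equal(joint_angle(p2[1, ], p2[2, ], p2[3, ]), a0, tolerance = 1e-9)
})

test_that("angular feature set is an ordered 8-angle vector", {
  sk <- build_skeleton(base_landmarks())
  v <- angular_feature_set(sk)
  expect_length(v, 8)
  expect_identical(v, angular_feature_set(sk)) # deterministic order
  # a square-standing pose with straight arms gives 180-degree elbows
  lm <- base_landmarks()
  lm["elbow_l", ] <- c(46, 60); lm["wrist_l", ] <- 2 * lm["elbow_l", ] -
    lm["shoulder_l", ]
  sk2 <- build_skeleton(lm)
  expect_equal(unname(angular_feature_set(sk2)[1]), 180)
  expect_error(angular_feature_set(build_skeleton(lm[1:4, ],
                                                  edge_spec = list())),
               "missing landmark")
})

test_that("chain codes quantize contour directions into eight sectors", {
  run <- cbind(0:5, 0)
  cc <- eight_round_angles(run)
  expect_equal(cc$codes, rep(0L, 5))
  expect_equal(cc$delta_theta, rep(0, 4))
  # clockwise unit square (image coordinates): three interior +/-90 turns
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  cs <- eight_round_angles(sq, closed = TRUE)
  expect_length(cs$codes, 4)
  expect_true(all(abs(cs$delta_theta) == 90))
  expect_equal(length(unique(cs$delta_theta)), 1) # consistent turn direction
  # translation invariance
  expect_equal(eight_round_angles(sq + 100, closed = TRUE)$codes, cs$codes)
  # 90-degree rotation maps code c to (c + 2) mod 8
  rot <- cbind(-sq[, 2], sq[, 1])
  cr <- eight_round_angles(rot, closed = TRUE)
  expect_equal(cr$codes, (cs$codes + 2L) %% 8L)
  expect_equal(sum(cs$histogram), 4)
  expect_error(eight_round_angles(rbind(c(0, 0))), "2 points")
})

test_that("Moore tracing walks the silhouette boundary deterministically", {
  mk <- matrix(FALSE, 10, 10)
  mk[3:6, 4:8] <- TRUE
  ct <- trace_contour(mk)
  # starts at the topmost-leftmost foreground pixel
  expect_equal(unname(ct[1, ]), c(3, 2))
  # all contour points are foreground boundary pixels
  expect_true(all(mk[cbind(ct[, 2] + 1, ct[, 1] + 1)]))
  expect_equal(nrow(ct), 14) # perimeter pixels of a 4x5 rectangle
  expect_error(trace_contour(matrix(FALSE, 3, 3)), "empty")
})
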