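test_that("neck is the shoulder midpoint", {
  expect_equal(compute_neck(list(shoulder_l = c(2, 0), shoulder_r = c(4, 0))),
               c(3, 0))
  expect_equal(compute_neck(list(shoulder_l = c(5, 5), shoulder_r = c(5, 5))),
               c(5, 5))
  expect_equal(compute_neck(list(shoulder_l = c(0, 0), shoulder_r = c(1, 3))),
               c(0.5, 1.5))
  expect_error(compute_neck(list(shoulder_l = c(0, 0))), "shoulder_r")
})

test_that("skeleton assembly yields the 14-joint 13-edge tree", {
  sk <- build_skeleton(base_landmarks())
  expect_equal(nrow(sk$landmarks), 14)
  expect_length(sk$edges, 13)
  expect_true("neck" %in% rownames(sk$landmarks))
  # landmarks only with empty edges
  sk0 <- build_skeleton(base_landmarks(), edge_spec = list())
  expect_length(sk0$edges, 0)
  # dangling edge endpoint errors, naming the missing landmark
  lm <- base_landmarks()
  expect_error(build_skeleton(lm[rownames(lm) != "wrist_l", ]), "wrist_l")
})

test_that("point-cloud graphs sample the silhouette with kNN edges", {
  mk <- matrix(TRUE, 10, 10)
  D <- matrix(1400, 10, 10)
  g <- build_point_cloud_graph(mk, D, stride = 1, k = 4)
  expect_equal(nrow(g$points), 100)
  # grid kNN with k = 4 contains every unit-spaced grid edge; only border
  # nodes (whose 4th neighbor is diagonal) contribute longer edges
  expect_equal(sum(g$weights == 1), 180) # 2 * 10 * 9 undirected grid edges
  longer <- g$edges[g$weights > 1, , drop = FALSE]
  border <- which(g$points[, 1] %in% c(0, 9) | g$points[, 2] %in% c(0, 9))
  expect_true(all(longer[, 1] %in% border | longer[, 2] %in% border))
  expect_error(build_point_cloud_graph(matrix(FALSE, 5, 5), matrix(0, 5, 5)),
               "empty mask")
})

test_that("geodesic distances are exact shortest paths", {
  # chain a-b-c with unit weights
  g <- point_cloud_graph(cbind(0:2, 0, 0), rbind(c(1, 2), c(2, 3)))
  expect_equal(geodesic_distances(g, 1), c(0, 1, 2))
  expect_equal(geodesic_distances(g, 2)[2], 0)
  # oracle equivalence on random graphs (integer weights, exact)
  set.seed(5)
  for (i in 1:10) {
    n <- sample(5:30, 1)
    rg <- random_graph(n)
    D <- floyd_warshall(rg$W)
    for (src in sample(n, 2)) {
      expect_identical(geodesic_distances(rg$graph, src), D[src, ])
    }
  }
  bad <- point_cloud_graph(cbind(0:1, 0, 0), rbind(c(1, 2)), weights = 1)
  igraph::E(bad$graph)$weight <- -1
  expect_error(geodesic_distances(bad), "negative")
})

test_that("geodesics are invariant to rigid motion of the cloud", {
  set.seed(6)
  pts <- cbind(runif(25, 0, 10), runif(25, 0, 10), runif(25, 0, 3))
  edges <- cbind(1:24, 2:25)
  g1 <- point_cloud_graph(pts, edges)
  th <- 0.7
  Rz <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  g2 <- point_cloud_graph(pts %*% Rz + 5, edges)
  expect_equal(geodesic_distances(g1), geodesic_distances(g2),
               tolerance = 1e-9)
})

test_that("extremity detection walks geodesic maxima without repeats", {
  # star with arms of length 5, 4, 3: tips picked in decreasing arm order
  pts <- rbind(c(0, 0, 0))
  edges <- NULL
  id <- 1L
  for (arm in list(list(d = c(1, 0), L = 5), list(d = c(0, 1), L = 4),
                   list(d = c(-1, 0), L = 3))) {
    prev <- 1L
    for (i in seq_len(arm$L)) {
      id <- id + 1L
      pts <- rbind(pts, c(arm$d * i, 0))
      edges <- rbind(edges, c(prev, id))
      prev <- id
    }
  }
  g <- point_cloud_graph(pts, edges, torso_index = 1)
  expect_equal(detect_extremities(g, 3), c(6L, 10L, 13L))
  # single extremity on a path: the far endpoint
  chain <- point_cloud_graph(cbind(0:6, 0, 0), cbind(1:6, 2:7))
  expect_equal(detect_extremities(chain, 1), 7L)
  expect_error(detect_extremities(chain, 99), "node count")
  # no node selected twice on random graphs
  set.seed(7)
  for (i in 1:5) {
    rg <- random_graph(sample(8:25, 1))
    ex <- detect_extremities(rg$graph, 4)
    expect_equal(anyDuplicated(ex), 0L)
  }
})

test_that("body-part labels follow torso-to-tip paths", {
  pts <- rbind(c(0, 0, 0))
  edges <- NULL
  id <- 1L
  for (arm in list(c(1, 0), c(0, 1), c(-1, 0))) {
    prev <- 1L
    for (i in 1:4) {
      id <- id + 1L
      pts <- rbind(pts, c(arm * i, 0))
      edges <- rbind(edges, c(prev, id))
      prev <- id
    }
  }
  g <- point_cloud_graph(pts, edges, torso_index = 1)
  ex <- detect_extremities(g, 3)
  lab <- segment_body_parts(g, ex)
  expect_equal(lab$labels[1], 0L) # shared center is torso
  expect_equal(lab$labels[2:5], rep(which(ex == 5L), 4))
  # single extremity: only two labels appear
  lab1 <- segment_body_parts(g, ex[1])
  expect_lte(length(unique(lab1$labels)), 2)
  # equidistant off-path node goes to the lowest extremity index
  pts2 <- rbind(c(0, 0, 0), c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0))
  edges2 <- rbind(c(1, 2), c(1, 3), c(1, 4))
  g2 <- point_cloud_graph(pts2, edges2, torso_index = 1)
  lab2 <- segment_body_parts(g2, c(2L, 3L))
  expect_equal(lab2$labels[4], 1L)
})

test_that("kinematic joints sit at uniform arc lengths and refine safely", {
  pts <- cbind(0:12, 0, 0)
  g <- point_cloud_graph(pts, cbind(1:12, 2:13), torso_index = 1)
  lab <- segment_body_parts(g, detect_extremities(g, 1))
  sk <- fit_kinematic_skeleton(g, lab, 2)
  expect_equal(unname(sk$landmarks["limb1_j1", 1]), 4, tolerance = 0.1 * 12)
  expect_equal(unname(sk$landmarks["limb1_j2", 1]), 8, tolerance = 0.1 * 12)
  expect_equal(sk$landmarks["limb1_tip", ], c(12, 0, 0),
               ignore_attr = TRUE)
  # clean line: residual below the sampling stride (here, node spacing 1)
  expect_lte(attr(sk, "residual"), 1)
  # joints stay on the symmetry axis of a symmetric cloud
  sym <- rbind(cbind(0:8, 0, 0), cbind(1:8, 1, 0), cbind(1:8, -1, 0))
  edges <- rbind(cbind(1:8, 2:9), cbind(2:9, 10:17), cbind(2:9, 18:25))
  gs <- point_cloud_graph(sym, edges, torso_index = 1)
  labs <- segment_body_parts(gs, detect_extremities(gs, 1))
  sks <- fit_kinematic_skeleton(gs, labs, 2)
  expect_equal(unname(sks$landmarks[c("limb1_j1", "limb1_j2"), 2]), c(0, 0),
               tolerance = 1e-9)
})

test_that("extremities of a rendered body match the true limb tips", {
  sq <- make_sequence(default_class_specs(n_frames = 3L)$static_stretch,
                      seed = 2)
  mk <- sq$ground_truth$masks[[1]]
  D <- ifelse(mk, 1400, 0)
  g <- build_point_cloud_graph(mk, D, stride = 4, k = 8)
  ex <- detect_extremities(g, 5)
  tips <- sq$ground_truth$tracks[[1]][sq$ground_truth$limb_tips, ]
  found <- g$points[ex, 1:2, drop = FALSE]
  # every true tip has a detected extremity within ~2 sampled nodes
  for (i in seq_len(nrow(tips))) {
    dmin <- min(sqrt(rowSums(sweep(found, 2, tips[i, ])^2)))
    expect_lte(dmin, 12)
  }
})
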