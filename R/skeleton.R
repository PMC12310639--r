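# Skeleton assembly from pose landmarks and geodesic skeletonization of
# depth point clouds.

hmir_landmarks <- c("head", "shoulder_l", "shoulder_r", "elbow_l", "elbow_r",
                    "wrist_l", "wrist_r", "hip_l", "hip_r", "knee_l",
                    "knee_r", "ankle_l", "ankle_r")

#' Default skeleton edge list
#'
#' The 13-edge tree over the 14 retained landmarks (head, shoulders, elbows,
#' wrists, hips, knees, ankles plus the computed neck).
#' @return list of character pairs
#' @export
default_edge_spec <- function() {
  list(c("neck", "head"),
       c("neck", "shoulder_l"), c("neck", "shoulder_r"),
       c("shoulder_l", "elbow_l"), c("elbow_l", "wrist_l"),
       c("shoulder_r", "elbow_r"), c("elbow_r", "wrist_r"),
       c("neck", "hip_l"), c("neck", "hip_r"),
       c("hip_l", "knee_l"), c("knee_l", "ankle_l"),
       c("hip_r", "knee_r"), c("knee_r", "ankle_r"))
}

#' Compute the neck landmark
#'
#' Arithmetic midpoint of the left and right shoulder landmarks.
#'
#' @param landmarks named list or row-named matrix of coordinates
#' @return numeric coordinate vector
#' @export
compute_neck <- function(landmarks) {
  lm <- as_landmark_matrix(landmarks)
  for (s in c("shoulder_l", "shoulder_r")) {
    if (!s %in% rownames(lm)) stop(sprintf("missing landmark '%s'", s))
  }
  (lm["shoulder_l", ] + lm["shoulder_r", ]) / 2
}

as_landmark_matrix <- function(landmarks) {
  if (is.matrix(landmarks)) {
    stopifnot(!is.null(rownames(landmarks)))
    return(landmarks)
  }
  m <- do.call(rbind, landmarks)
  rownames(m) <- names(landmarks)
  m
}

#' Assemble a skeleton frame
#'
#' Adds the computed neck (when both shoulders are present and no neck was
#' given) and attaches the edge list. Every edge endpoint must name an
#' existing landmark.
#'
#' @param landmarks named list or row-named matrix of (x, y[, z]) coordinates
#' @param edge_spec list of landmark-name pairs (default [default_edge_spec()])
#' @param timestamp time in seconds
#' @return object of class `skeleton_frame` with fields `landmarks` (matrix),
#'   `edges`, `timestamp`
#' @export
build_skeleton <- function(landmarks, edge_spec = default_edge_spec(),
                           timestamp = 0) {
  lm <- as_landmark_matrix(landmarks)
  if (!"neck" %in% rownames(lm) &&
      all(c("shoulder_l", "shoulder_r") %in% rownames(lm))) {
    lm <- rbind(lm, neck = compute_neck(lm))
  }
  if (!all(is.finite(lm))) stop("landmark coordinates must be finite")
  used <- unique(unlist(edge_spec))
  missing <- setdiff(used, rownames(lm))
  if (length(missing)) {
    stop(sprintf("edge endpoints missing from landmarks: %s",
                 paste(missing, collapse = ", ")))
  }
  lm <- lm[order(rownames(lm)), , drop = FALSE] # deterministic ordering
  structure(list(landmarks = lm, edges = edge_spec, timestamp = timestamp),
            class = "skeleton_frame")
}

#' @export
print.skeleton_frame <- function(x, ...) {
  cat(sprintf("<skeleton_frame: %d landmarks, %d edges, t = %.3f s>\n",
              nrow(x$landmarks), length(x$edges), x$timestamp))
  invisible(x)
}

#' Build a k-nearest-neighbor graph over a depth point cloud
#'
#' Samples foreground pixels on a stride grid, lifts them to (x, y, z) with
#' `z = D(x, y)`, and connects each node to its `k` nearest neighbors with
#' Euclidean edge weights. The torso source node is the depth-weighted
#' centroid of the largest silhouette component snapped to the nearest
#' sampled node.
#'
#' Edges longer than `max_edge` are pruned (each node always keeps its
#' single nearest neighbor), so sparsely sampled limb tips do not acquire
#' shortcut edges to other body parts.
#'
#' @param mask binary matrix
#' @param D depth matrix (same shape)
#' @param stride sampling stride in pixels (default 4)
#' @param k neighbor count (default 8)
#' @param max_edge edge-length cap (default `3 * stride`)
#' @return object of class `point_cloud_graph` with `points` (n x 3 matrix),
#'   `edges` (m x 2 index matrix), `weights`, `torso_index` and the underlying
#'   igraph in `$graph`
#' @export
build_point_cloud_graph <- function(mask, D, stride = 4L, k = 8L,
                                    max_edge = 3 * stride) {
  stopifnot(all(dim(mask) == dim(D)), stride >= 1L)
  mask <- mask > 0
  if (!any(mask)) stop("empty mask")
  lab <- label_components(mask)
  sizes <- tabulate(lab[lab > 0])
  main <- which.max(sizes)
  px <- which(mask, arr.ind = TRUE)
  on_grid <- (px[, 1] - 1) %% stride == 0 & (px[, 2] - 1) %% stride == 0
  px <- px[on_grid, , drop = FALSE]
  if (nrow(px) == 0L) stop("stride too large: no sampled foreground pixels")
  pts <- cbind(x = px[, 2] - 1, y = px[, 1] - 1, z = D[px])
  n <- nrow(pts)
  k <- min(k, n - 1L)
  dm <- as.matrix(stats::dist(pts))
  edges <- NULL
  for (i in seq_len(n)) {
    nb <- order(dm[i, ])[seq_len(min(k + 1L, n))][-1]
    nb <- nb[c(TRUE, dm[i, nb[-1]] <= max_edge)] # keep >= 1 neighbor
    edges <- rbind(edges, cbind(pmin(i, nb), pmax(i, nb)))
  }
  edges <- unique(edges)
  w <- dm[edges]
  g <- igraph::make_graph(t(edges), n = n, directed = FALSE)
  igraph::E(g)$weight <- w
  # torso: depth-weighted centroid of the largest component, snapped
  mpx <- which(lab == main, arr.ind = TRUE)
  wz <- D[mpx]
  if (sum(wz) <= 0) wz <- rep(1, nrow(mpx))
  cx <- sum((mpx[, 2] - 1) * wz) / sum(wz)
  cy <- sum((mpx[, 1] - 1) * wz) / sum(wz)
  torso <- which.min((pts[, 1] - cx)^2 + (pts[, 2] - cy)^2)
  comp <- igraph::components(g)
  if (comp$membership[torso] != which.max(comp$csize)) {
    warning("torso node lies outside the largest graph component")
  }
  if (comp$no > 1L) {
    warning("point-cloud graph is disconnected; geodesics restricted to the torso component")
  }
  structure(list(points = pts, edges = edges, weights = w,
                 torso_index = as.integer(torso), graph = g),
            class = "point_cloud_graph")
}

#' @export
print.point_cloud_graph <- function(x, ...) {
  cat(sprintf("<point_cloud_graph: %d nodes, %d edges, torso = %d>\n",
              nrow(x$points), nrow(x$edges), x$torso_index))
  invisible(x)
}

#' Construct a point-cloud graph from explicit points and edges
#'
#' Lower-level constructor used by tests and by callers that already have a
#' graph structure. Weights default to Euclidean distances between endpoints.
#'
#' @param points n x 3 coordinate matrix
#' @param edges m x 2 index matrix
#' @param weights optional edge weights (>= 0)
#' @param torso_index source node for geodesics (default 1)
#' @return a `point_cloud_graph`
#' @export
point_cloud_graph <- function(points, edges, weights = NULL, torso_index = 1L) {
  points <- as.matrix(points)
  if (ncol(points) == 2L) points <- cbind(points, 0)
  edges <- as.matrix(edges)
  if (is.null(weights)) {
    weights <- sqrt(rowSums((points[edges[, 1], , drop = FALSE] -
                               points[edges[, 2], , drop = FALSE])^2))
  }
  if (any(weights < 0)) stop("negative edge weight")
  g <- igraph::make_graph(t(edges), n = nrow(points), directed = FALSE)
  igraph::E(g)$weight <- weights
  structure(list(points = points, edges = edges, weights = weights,
                 torso_index = as.integer(torso_index), graph = g),
            class = "point_cloud_graph")
}

#' Single-source geodesic distances on a point-cloud graph
#'
#' Exact shortest-path distances (Dijkstra) from `source` to every node;
#' unreachable nodes get `Inf`.
#'
#' @param g a `point_cloud_graph`
#' @param source node index (defaults to the torso node)
#' @return numeric vector of distances
#' @export
geodesic_distances <- function(g, source = g$torso_index) {
  stopifnot(inherits(g, "point_cloud_graph"))
  if (source < 1L || source > nrow(g$points)) stop("source not in graph")
  if (any(igraph::E(g$graph)$weight < 0)) stop("negative edge weight")
  as.numeric(igraph::distances(g$graph, v = source, algorithm = "dijkstra"))
}

#' Detect body extremities by iterated geodesic maxima
#'
#' Repeatedly selects the node with the largest finite geodesic distance from
#' the torso, then inserts a zero-weight edge from that node to the torso so
#' the next iteration finds a different extremity (the recomputed distance of
#' a detected tip collapses to zero).
#'
#' @param g a `point_cloud_graph`
#' @param n_extremities how many tips to detect (default 5: head + 4 limbs)
#' @return integer vector of node indices in selection order
#' @export
detect_extremities <- function(g, n_extremities = 5L) {
  stopifnot(inherits(g, "point_cloud_graph"), n_extremities >= 1L)
  if (n_extremities > nrow(g$points)) stop("n_extremities exceeds node count")
  gr <- g$graph
  picked <- integer(0)
  for (i in seq_len(n_extremities)) {
    d <- as.numeric(igraph::distances(gr, v = g$torso_index,
                                      algorithm = "dijkstra"))
    d[!is.finite(d)] <- -Inf
    d[picked] <- -Inf
    picked <- c(picked, which.max(d)) # which.max takes the lowest index on ties
    gr <- igraph::add_edges(gr, c(g$torso_index, picked[i]),
                            attr = list(weight = 0))
  }
  picked
}

#' Segment cloud nodes into body parts
#'
#' Each torso-to-extremity geodesic path defines a limb. Path nodes shared by
#' two or more paths (the trunk) and the torso node are labeled `torso`;
#' nodes on exactly one path take that limb's label; every other node joins
#' the limb whose path it is geodesically nearest to (ties resolved toward
#' the lowest extremity index).
#'
#' @param g a `point_cloud_graph`
#' @param extremities integer vector from [detect_extremities()]
#' @return object of class `body_part_labeling`: `labels` (integer vector, 0
#'   = torso, i = i-th extremity), `extremity_indices`, `paths`
#' @export
segment_body_parts <- function(g, extremities) {
  stopifnot(inherits(g, "point_cloud_graph"), length(extremities) >= 1L)
  n <- nrow(g$points)
  paths <- lapply(extremities, function(e) {
    p <- igraph::shortest_paths(g$graph, from = g$torso_index, to = e,
                                algorithm = "dijkstra")$vpath[[1]]
    as.integer(p)
  })
  membership <- integer(n) # how many paths each node lies on
  for (p in paths) membership[p] <- membership[p] + 1L
  labels <- rep(NA_integer_, n)
  labels[membership >= 2L] <- 0L
  labels[g$torso_index] <- 0L
  for (i in seq_along(paths)) {
    own <- paths[[i]][is.na(labels[paths[[i]]])]
    labels[own] <- i
  }
  todo <- which(is.na(labels))
  if (length(todo)) {
    # geodesic distance from every path to all nodes
    dmat <- vapply(paths, function(p) {
      dd <- igraph::distances(g$graph, v = p, algorithm = "dijkstra")
      apply(dd, 2, min)
    }, numeric(n))
    for (node in todo) {
      dists <- dmat[node, ]
      best <- min(dists)
      if (!is.finite(best)) { labels[node] <- 0L; next }
      cands <- which(dists == best)
      if (length(cands) == 1L) { labels[node] <- cands; next }
      # tie between distinct paths: lowest extremity index wins
      labels[node] <- cands[1]
    }
  }
  structure(list(labels = labels, extremity_indices = as.integer(extremities),
                 paths = paths),
            class = "body_part_labeling")
}

#' Fit a kinematic skeleton to labeled body parts
#'
#' Places `joints_per_limb` joints per limb at uniform fractional geodesic arc
#' lengths along each torso-to-extremity path, then refines each joint to the
#' centroid of the limb points inside its geodesic window (one least-squares
#' step, kept only when it does not increase the bone residual). The residual
#' is the mean distance from limb points to their nearest bone segment.
#'
#' @param g a `point_cloud_graph`
#' @param labeling a [segment_body_parts()] result
#' @param joints_per_limb joints per limb (default 2)
#' @return a `skeleton_frame` whose landmarks are `torso`, `limb<i>_j<k>` and
#'   `limb<i>_tip`, with attribute `residual`
#' @export
fit_kinematic_skeleton <- function(g, labeling, joints_per_limb = 2L) {
  stopifnot(inherits(g, "point_cloud_graph"),
            inherits(labeling, "body_part_labeling"))
  pts <- g$points
  dist_torso <- geodesic_distances(g)
  landmarks <- list(torso = pts[g$torso_index, ])
  edges <- list()
  limb_pts <- list()
  bones <- list()
  for (i in seq_along(labeling$paths)) {
    path <- labeling$paths[[i]]
    s <- dist_torso[path]
    L <- s[length(s)]
    J <- joints_per_limb
    if (length(path) < J + 1L) {
      J <- max(length(path) - 1L, 0L)
      warning(sprintf("limb %d has too few path nodes; placing %d joints", i, J))
    }
    prev <- "torso"
    chain <- pts[g$torso_index, , drop = FALSE]
    members <- which(labeling$labels == i)
    for (j in seq_len(J)) {
      target <- L * j / (J + 1L)
      # interpolate along the path polyline at arc length `target`
      seg <- findInterval(target, s, all.inside = TRUE)
      t0 <- s[seg]; t1 <- s[seg + 1L]
      f <- if (t1 > t0) (target - t0) / (t1 - t0) else 0
      pos <- (1 - f) * pts[path[seg], ] + f * pts[path[seg + 1L], ]
      # refinement: centroid of limb points within the geodesic window
      if (length(members)) {
        win <- L / (J + 1L)
        near <- members[abs(dist_torso[members] - target) <= win / 2]
        if (length(near) >= 1L) {
          cand <- colMeans(pts[near, , drop = FALSE])
          if (limb_residual(pts[members, , drop = FALSE],
                            rbind(chain, cand, pts[path[length(path)], ])) <=
              limb_residual(pts[members, , drop = FALSE],
                            rbind(chain, pos, pts[path[length(path)], ]))) {
            pos <- cand
          }
        }
      }
      nm <- sprintf("limb%d_j%d", i, j)
      landmarks[[nm]] <- pos
      edges[[length(edges) + 1L]] <- c(prev, nm)
      prev <- nm
      chain <- rbind(chain, pos)
    }
    tipnm <- sprintf("limb%d_tip", i)
    landmarks[[tipnm]] <- pts[path[length(path)], ]
    edges[[length(edges) + 1L]] <- c(prev, tipnm)
    chain <- rbind(chain, pts[path[length(path)], ])
    if (length(members)) {
      limb_pts[[i]] <- pts[members, , drop = FALSE]
      bones[[i]] <- chain
    }
  }
  res <- if (length(limb_pts)) {
    mean(unlist(Map(function(p, b) point_to_chain_distances(p, b),
                    limb_pts, bones)))
  } else NA_real_
  sk <- build_skeleton(landmarks, edge_spec = edges)
  attr(sk, "residual") <- res
  sk
}

# Mean distance from points to a polyline chain (rows of `chain`).
limb_residual <- function(points, chain) {
  mean(point_to_chain_distances(points, chain))
}

point_to_chain_distances <- function(points, chain) {
  n <- nrow(points)
  best <- rep(Inf, n)
  for (s in seq_len(nrow(chain) - 1L)) {
    a <- chain[s, ]; b <- chain[s + 1L, ]
    ab <- b - a
    len2 <- sum(ab^2)
    rel <- sweep(points, 2, a)
    t <- if (len2 > 0) pmin(pmax(rel %*% ab / len2, 0), 1) else rep(0, n)
    proj <- outer(as.numeric(t), ab)
    best <- pmin(best, sqrt(rowSums((rel - proj)^2)))
  }
  best
}
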