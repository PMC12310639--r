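# Depth feature families: 2.5D point-cloud dynamics, random occupancy
# patterns, movement polygons.

#' Lift a masked depth map to a 2.5D point cloud
#'
#' One point `(x, y, z = D(x, y))` per foreground pixel; invalid (zero) depth
#' pixels are skipped. Coordinates are 0-based pixels, depth in the raster's
#' units.
#'
#' @param D depth matrix
#' @param mask binary matrix of the same shape
#' @return object of class `point_cloud_25d`: list with `points` (n x 3
#'   matrix, columns x, y, z) and optional dynamics `v`, `a`, `kappa`
#' @export
depth_to_points <- function(D, mask) {
  stopifnot(all(dim(D) == dim(mask)))
  px <- which(mask > 0 & D > 0, arr.ind = TRUE)
  if (nrow(px) == 0L) stop("no valid foreground depth pixels")
  structure(list(points = cbind(x = px[, 2] - 1, y = px[, 1] - 1, z = D[px])),
            class = "point_cloud_25d")
}

#' @export
print.point_cloud_25d <- function(x, ...) {
  cat(sprintf("<point_cloud_25d: %d points%s>\n", nrow(x$points),
              if (!is.null(x$v)) ", with dynamics" else ""))
  invisible(x)
}

#' Per-point velocity, acceleration and curvature over three frames
#'
#' Computes `v = (P_t - P_{t-1}) / dt`, `a = (v_t - v_{t-1}) / dt` and the
#' trajectory curvature `kappa = ||v x a|| / ||v||^3` (`kappa = 0` where
#' `||v|| < eps`). Correspondence is pixel-wise (matching `(x, y)` rows;
#' points present in only some frames are dropped) when the clouds share a
#' lattice, or by point order when all three clouds have equal length —
#' the latter serves explicit trajectories.
#'
#' @param cloud_t,cloud_prev,cloud_prev2 `point_cloud_25d` objects at times
#'   t, t-1, t-2
#' @param dt frame interval in seconds
#' @param eps speed floor below which curvature is defined as 0 (default 1e-6)
#' @return a `point_cloud_25d` for time t with matrices `v`, `a` and vector
#'   `kappa` attached (rows follow `$points`)
#' @export
point_dynamics <- function(cloud_t, cloud_prev, cloud_prev2, dt, eps = 1e-6) {
  stopifnot(dt > 0)
  p0 <- cloud_t$points; p1 <- cloud_prev$points; p2 <- cloud_prev2$points
  key <- function(p) paste(p[, 1], p[, 2])
  k0 <- key(p0); k1 <- key(p1); k2 <- key(p2)
  if (identical(k0, k1) && identical(k0, k2)) {
    # identical lattice: pixel and index correspondence coincide
    m0 <- p0; m1 <- p1; m2 <- p2
  } else {
    common <- Reduce(intersect, list(k0, k1, k2))
    if (length(common) > 0L && !anyDuplicated(k0)) {
      # pixel mode on the intersection of the lattices
      m0 <- p0[match(common, k0), , drop = FALSE]
      m1 <- p1[match(common, k1), , drop = FALSE]
      m2 <- p2[match(common, k2), , drop = FALSE]
    } else if (nrow(p0) == nrow(p1) && nrow(p0) == nrow(p2)) {
      # index mode: ordered trajectories of equal length
      m0 <- p0; m1 <- p1; m2 <- p2
    } else {
      stop("clouds are not pixel-aligned and have unequal lengths")
    }
  }
  v_t <- (m0 - m1) / dt
  v_p <- (m1 - m2) / dt
  a <- (v_t - v_p) / dt
  cr <- cbind(v_t[, 2] * a[, 3] - v_t[, 3] * a[, 2],
              v_t[, 3] * a[, 1] - v_t[, 1] * a[, 3],
              v_t[, 1] * a[, 2] - v_t[, 2] * a[, 1])
  speed <- sqrt(rowSums(v_t^2))
  kappa <- ifelse(speed < eps, 0,
                  sqrt(rowSums(cr^2)) / pmax(speed, eps)^3)
  structure(list(points = m0, v = v_t, a = a, kappa = as.numeric(kappa)),
            class = "point_cloud_25d")
}

#' Random occupancy pattern features of a masked depth sequence
#'
#' Voxelizes each frame's 2.5D points into an `dims` grid spanning the
#' sequence's bounding volume, marks a voxel occupied when at least
#' `min_points` points fall inside it, and concatenates the occupancy bits of
#' a seeded random voxel subset `S` (uniform, without replacement) across all
#' frames in frame-major order.
#'
#' @param depth_frames list of depth matrices
#' @param masks list of binary matrices (same shapes)
#' @param dims voxel grid dimensions `c(nx, ny, nz)` (default `c(16, 16, 8)`)
#' @param sample_size size of the random voxel subset (default 128)
#' @param seed RNG seed for the voxel sample
#' @param min_points occupancy threshold per voxel (default 1)
#' @return numeric 0/1 vector of length `sample_size * T`, with attributes
#'   `sample` (the voxel indices S), `dims`, `seed`
#' @export
rop_features <- function(depth_frames, masks, dims = c(16L, 16L, 8L),
                         sample_size = 128L, seed = 1L, min_points = 1L) {
  T_ <- length(depth_frames)
  stopifnot(T_ >= 1L, length(masks) == T_)
  n_vox <- prod(dims)
  if (sample_size > n_vox) stop("sample_size exceeds the voxel count")
  S <- with_seed(seed, sample.int(n_vox, sample_size))
  clouds <- vector("list", T_)
  for (t in seq_len(T_)) {
    ok <- masks[[t]] > 0 & depth_frames[[t]] > 0
    if (any(ok)) {
      px <- which(ok, arr.ind = TRUE)
      clouds[[t]] <- cbind(px[, 2] - 1, px[, 1] - 1, depth_frames[[t]][ok])
    }
  }
  allp <- do.call(rbind, clouds)
  out <- numeric(sample_size * T_)
  if (!is.null(allp) && nrow(allp) > 0L) {
    lo <- apply(allp, 2, min)
    hi <- apply(allp, 2, max)
    span <- pmax(hi - lo, 1e-9)
    for (t in seq_len(T_)) {
      if (is.null(clouds[[t]])) next
      p <- clouds[[t]]
      ix <- pmin(floor((p[, 1] - lo[1]) / span[1] * dims[1]) + 1L, dims[1])
      iy <- pmin(floor((p[, 2] - lo[2]) / span[2] * dims[2]) + 1L, dims[2])
      iz <- pmin(floor((p[, 3] - lo[3]) / span[3] * dims[3]) + 1L, dims[3])
      vox <- (iz - 1L) * dims[1] * dims[2] + (iy - 1L) * dims[1] + ix
      counts <- tabulate(vox, nbins = n_vox)
      out[(t - 1L) * sample_size + seq_len(sample_size)] <-
        as.numeric(counts[S] >= min_points)
    }
  }
  structure(out, sample = S, dims = dims, seed = seed)
}

#' Movement polygon of a joint set
#'
#' Projects 3D joints to the image plane, orders them by polar angle around
#' the joint centroid (radius breaks ties), and derives the centroid, the
#' per-vertex centroid distances, and the boundary distance profile sampled
#' at integer degrees 1..360 by intersecting each ray with the polygon edge
#' spanning it.
#'
#' @param joints n x 2 or n x 3 matrix of joint positions (n >= 3)
#' @return object of class `movement_polygon`: `centroid` (Gx, Gy), `d`
#'   (per-vertex distances, boundary order), `d_theta` (length 360),
#'   `order` (vertex ordering used)
#' @export
movement_polygon <- function(joints) {
  joints <- as.matrix(joints)
  if (nrow(joints) < 3L) stop("need at least 3 joints")
  xy <- joints[, 1:2, drop = FALSE]
  G <- colMeans(xy)
  rel <- sweep(xy, 2, G)
  # collinearity check via the second singular value
  sv <- svd(scale(xy, center = TRUE, scale = FALSE))$d
  if (sv[2] < 1e-9 * max(sv[1], 1e-12)) stop("degenerate polygon: joints are collinear")
  ang <- atan2(rel[, 2], rel[, 1]) %% (2 * pi)
  rad <- sqrt(rowSums(rel^2))
  ord <- order(ang, rad)
  P <- xy[ord, , drop = FALSE]
  d <- sqrt(rowSums(sweep(P, 2, G)^2))
  va <- ang[ord]
  n <- nrow(P)
  d_theta <- numeric(360)
  for (deg in 1:360) {
    th <- deg2rad(deg %% 360)
    # find the edge whose angular span contains th
    nxt <- c(2:n, 1)
    for (i in seq_len(n)) {
      a1 <- va[i]; a2 <- va[nxt[i]]
      span <- (a2 - a1) %% (2 * pi)
      off <- (th - a1) %% (2 * pi)
      if (off <= span + 1e-12 || span == 0) {
        r <- ray_segment_distance(G, th, P[i, ], P[nxt[i], ])
        if (is.finite(r)) { d_theta[deg] <- r; break }
      }
    }
  }
  structure(list(centroid = c(Gx = G[1], Gy = G[2]), d = d,
                 d_theta = d_theta, order = ord),
            class = "movement_polygon")
}

# Distance from origin `G` along direction `th` to segment (p1, p2); Inf when
# the ray misses the segment.
ray_segment_distance <- function(G, th, p1, p2) {
  dir <- c(cos(th), sin(th))
  e <- p2 - p1
  denom <- dir[1] * (-e[2]) - dir[2] * (-e[1])
  if (abs(denom) < 1e-12) {
    # ray parallel to edge: fall back to the nearer endpoint along the ray
    t1 <- sum((p1 - G) * dir); t2 <- sum((p2 - G) * dir)
    cand <- c(t1, t2)[c(t1, t2) >= 0]
    return(if (length(cand)) min(cand) else Inf)
  }
  rhs <- p1 - G
  t <- (rhs[1] * (-e[2]) - rhs[2] * (-e[1])) / denom
  s <- (dir[1] * rhs[2] - dir[2] * rhs[1]) / denom
  if (t >= -1e-9 && s >= -1e-9 && s <= 1 + 1e-9) max(t, 0) else Inf
}

#' Trajectory of the most-moving joint
#'
#' Selects the joint with the largest trace of its coordinate covariance
#' across frames, tracks its angular displacement
#' `atan2(y_t - y_0, x_t - x_0)` per frame, unwraps the series, and linearly
#' resamples it to exactly 20 values (degrees).
#'
#' @param skeleton_seq list of `skeleton_frame`s (>= 2)
#' @param length_out output length (default 20)
#' @return numeric vector of `length_out` angles in degrees, with attribute
#'   `joint` naming the selected joint
#' @export
moving_joint_trajectory <- function(skeleton_seq, length_out = 20L) {
  stopifnot(length(skeleton_seq) >= 2L)
  names_ <- rownames(skeleton_seq[[1]]$landmarks)
  tr <- vapply(names_, function(nm) {
    xyz <- t(vapply(skeleton_seq, function(s) s$landmarks[nm, ],
                    numeric(ncol(skeleton_seq[[1]]$landmarks))))
    sum(apply(xyz, 2, stats::var))
  }, numeric(1))
  if (max(tr) < 1e-12) {
    warning("all joints are static; returning a zero trajectory")
    return(structure(numeric(length_out), joint = NA_character_))
  }
  joint <- names_[which.max(tr)]
  xy <- t(vapply(skeleton_seq, function(s) s$landmarks[joint, 1:2], numeric(2)))
  dx <- xy[-1, 1] - xy[1, 1]
  dy <- xy[-1, 2] - xy[1, 2]
  ang <- rad2deg(atan2(dy, dx))
  ang[dx == 0 & dy == 0] <- 0
  ang <- unwrap_deg(ang)
  res <- if (length(ang) == 1L) rep(ang, length_out) else {
    stats::approx(seq_along(ang), ang, n = length_out)$y
  }
  structure(res, joint = joint)
}
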