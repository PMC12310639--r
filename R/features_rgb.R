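# RGB feature families: kinetic energy, histogram of optical flow, angular
# geometric features, eight round angles (Freeman chain code).

#' Default anthropometric segment model
#'
#' Ten body segments with masses from standard anthropometric mass fractions
#' (total body mass `total_mass`), a shape constant `k` in (0, 1] and a
#' gyration radius `r` in pixels. The paper-level method needs only the
#' products `I = k m r^2`; the defaults are order-of-magnitude human values
#' and are fully configurable.
#'
#' @param total_mass body mass in kg (default 70)
#' @param gyration_px default gyration radius in pixels (default 10)
#' @return data.frame with columns `name, from, to, mass, k, r`
#' @export
default_segment_model <- function(total_mass = 70, gyration_px = 10) {
  seg <- function(name, from, to, frac, k) {
    data.frame(name = name, from = from, to = to,
               mass = frac * total_mass, k = k, r = gyration_px,
               stringsAsFactors = FALSE)
  }
  rbind(
    seg("head",        "neck",       "head",    0.081, 0.50),
    seg("trunk_l",     "neck",       "hip_l",   0.2485, 0.40),
    seg("trunk_r",     "neck",       "hip_r",   0.2485, 0.40),
    seg("upper_arm_l", "shoulder_l", "elbow_l", 0.028, 0.33),
    seg("upper_arm_r", "shoulder_r", "elbow_r", 0.028, 0.33),
    seg("forearm_l",   "elbow_l",    "wrist_l", 0.022, 0.33),
    seg("forearm_r",   "elbow_r",    "wrist_r", 0.022, 0.33),
    seg("thigh_l",     "hip_l",      "knee_l",  0.100, 0.33),
    seg("thigh_r",     "hip_r",      "knee_r",  0.100, 0.33),
    seg("shank_l",     "knee_l",     "ankle_l", 0.0605, 0.33),
    seg("shank_r",     "knee_r",     "ankle_r", 0.0605, 0.33))
}

#' Speeds along a position track
#'
#' `v(t) = ||(p_t - p_{t-1}) / dt||`; the first frame is 0 by convention.
#'
#' @param track n x d matrix of per-frame positions (d = 2 or 3)
#' @param dt frame interval in seconds
#' @return numeric vector of length n
#' @export
trajectory_velocities <- function(track, dt) {
  track <- as.matrix(track)
  stopifnot(nrow(track) >= 2L)
  if (dt <= 0) stop("dt must be > 0")
  d <- diff(track) / dt
  c(0, sqrt(rowSums(d^2)))
}

#' Angular speed from per-frame Euler angles
#'
#' `omega(t) = sqrt(thetadot^2 + phidot^2 + psidot^2)` by finite differences
#' on unwrapped angle series (jumps larger than 180 degrees are treated as
#' wraparound). First frame is 0.
#'
#' @param angles n x 3 matrix of angles in degrees (columns may be fewer than
#'   3; missing axes count as 0)
#' @param dt frame interval in seconds
#' @return angular speed per frame, degrees per second
#' @export
angular_velocities <- function(angles, dt = 1) {
  angles <- as.matrix(angles)
  stopifnot(nrow(angles) >= 2L)
  rates <- apply(angles, 2, function(a) c(0, diff(unwrap_deg(a)) / dt))
  rates <- matrix(rates, nrow = nrow(angles))
  sqrt(rowSums(rates^2))
}

#' Kinetic energy profile of a skeleton sequence
#'
#' Per frame, sums over body segments the linear term `1/2 m v^2` (v from the
#' segment-midpoint trajectory) and the rotational term `1/2 k m r^2 omega^2`
#' (omega from the in-plane segment orientation angle, converted to rad/s).
#' Energy units are `kg * (coordinate unit)^2 / s^2`.
#'
#' @param skeleton_seq list of `skeleton_frame`s
#' @param model segment model data.frame (see [default_segment_model()])
#' @param dt frame interval in seconds
#' @return object of class `kinetic_energy_profile`: list with `total` (per
#'   frame), `linear`, `rotational` (frame x segment matrices)
#' @export
kinetic_energy_profile <- function(skeleton_seq, model = default_segment_model(),
                                   dt = 1) {
  stopifnot(length(skeleton_seq) >= 2L, dt > 0)
  n <- length(skeleton_seq)
  ns <- nrow(model)
  get_lm <- function(frame, name) {
    lm <- skeleton_seq[[frame]]$landmarks
    if (!name %in% rownames(lm)) {
      stop(sprintf("frame %d is missing landmark '%s'", frame, name))
    }
    lm[name, ]
  }
  lin <- matrix(0, n, ns, dimnames = list(NULL, model$name))
  rot <- matrix(0, n, ns, dimnames = list(NULL, model$name))
  for (s in seq_len(ns)) {
    p1 <- t(vapply(seq_len(n), get_lm, numeric(ncol(skeleton_seq[[1]]$landmarks)),
                   name = model$from[s]))
    p2 <- t(vapply(seq_len(n), get_lm, numeric(ncol(skeleton_seq[[1]]$landmarks)),
                   name = model$to[s]))
    mid <- (p1 + p2) / 2
    v <- trajectory_velocities(mid, dt)
    seg_vec <- p2 - p1
    theta <- rad2deg(atan2(seg_vec[, 2], seg_vec[, 1]))
    omega_deg <- angular_velocities(cbind(theta), dt)
    omega <- deg2rad(omega_deg)
    lin[, s] <- 0.5 * model$mass[s] * v^2
    rot[, s] <- 0.5 * model$k[s] * model$mass[s] * model$r[s]^2 * omega^2
  }
  structure(list(total = rowSums(lin) + rowSums(rot),
                 linear = lin, rotational = rot),
            class = "kinetic_energy_profile")
}

#' Dense optical flow between two frames
#'
#' Default estimator is coarse-to-fine block matching: integer-displacement
#' SSD search on a downsampled pyramid, refined at full resolution. The
#' estimator is pluggable: pass a `function(a, b)` returning
#' `list(u = ..., v = ...)` as `method`.
#'
#' @param frame_a,frame_b numeric matrices of identical shape
#' @param method `"block"` or an estimator function
#' @param block block size in pixels (default 8)
#' @param search search radius in pixels per level (default 4)
#' @param levels pyramid levels (default 2)
#' @return object of class `flow_field`: list with matrices `u`, `v`
#'   (pixels/frame, x rightward along columns, y downward along rows)
#' @export
estimate_flow <- function(frame_a, frame_b, method = "block",
                          block = 8L, search = 4L, levels = 2L) {
  if (!all(dim(frame_a) == dim(frame_b))) stop("frame shapes differ")
  if (is.function(method)) {
    fl <- method(frame_a, frame_b)
    return(structure(list(u = fl$u, v = fl$v), class = "flow_field"))
  }
  u <- matrix(0, nrow(frame_a), ncol(frame_a))
  v <- matrix(0, nrow(frame_a), ncol(frame_a))
  for (lev in seq(levels - 1L, 0L)) {
    f <- 2L^lev
    a <- downsample2(frame_a, f)
    b <- downsample2(frame_b, f)
    u0 <- downsample2(u, f) / f
    v0 <- downsample2(v, f) / f
    fl <- block_match(a, b, u0, v0, block, search)
    u <- upsample_to(fl$u * f, dim(frame_a))
    v <- upsample_to(fl$v * f, dim(frame_a))
  }
  structure(list(u = u, v = v), class = "flow_field")
}

# Average-pool by an integer factor.
downsample2 <- function(m, f) {
  if (f <= 1L) return(m)
  nr <- (nrow(m) %/% f) * f
  nc <- (ncol(m) %/% f) * f
  m <- m[seq_len(nr), seq_len(nc), drop = FALSE]
  rs <- rowsum(m, rep(seq_len(nr %/% f), each = f))
  t(rowsum(t(rs), rep(seq_len(nc %/% f), each = f))) / f^2
}

# Nearest-neighbor upsample to an exact target dim.
upsample_to <- function(m, target) {
  ri <- pmin(pmax(ceiling(seq_len(target[1]) / (target[1] / nrow(m))), 1), nrow(m))
  ci <- pmin(pmax(ceiling(seq_len(target[2]) / (target[2] / ncol(m))), 1), ncol(m))
  m[ri, ci, drop = FALSE]
}

# Integer block matching with an initial flow guess: for each block of `a`,
# find the displacement (within the search window around the rounded guess)
# minimizing the SSD against `b`.
block_match <- function(a, b, u0, v0, block, search) {
  nr <- nrow(a); nc <- ncol(a)
  br <- ceiling(nr / block); bc <- ceiling(nc / block)
  row_id <- rep(pmin(ceiling(seq_len(nr) / block), br), times = nc)
  col_id <- rep(pmin(ceiling(seq_len(nc) / block), bc), each = nr)
  blk <- (col_id - 1L) * br + row_id
  nblk <- br * bc
  # per-block rounded initial guess (median of the guess field)
  fblk <- factor(blk, levels = seq_len(nblk))
  gu <- round(as.numeric(tapply(u0, fblk, stats::median)))
  gv <- round(as.numeric(tapply(v0, fblk, stats::median)))
  best <- rep(Inf, nblk)
  bu <- numeric(nblk); bv <- numeric(nblk)
  cand <- expand.grid(dx = -search:search, dy = -search:search)
  guesses <- unique(cbind(gu, gv))
  for (gi in seq_len(nrow(guesses))) {
    g_u <- guesses[gi, 1]; g_v <- guesses[gi, 2]
    sel <- which(gu == g_u & gv == g_v)
    sel_px <- blk %in% sel
    for (ci in seq_len(nrow(cand))) {
      dx <- cand$dx[ci] + g_u
      dy <- cand$dy[ci] + g_v
      # a(p) should match b(p + (dx, dy)) when the scene moves by (dx, dy)
      diff2 <- (a - shift_replicate(b, as.integer(dy), as.integer(dx)))^2
      ssd <- tapply(diff2[sel_px], blk[sel_px], sum)
      ids <- as.integer(names(ssd))
      upd <- ssd < best[ids] - 1e-12
      best[ids[upd]] <- ssd[upd]
      bu[ids[upd]] <- dx
      bv[ids[upd]] <- dy
    }
  }
  list(u = matrix(bu[blk], nr, nc), v = matrix(bv[blk], nr, nc))
}

#' Histogram of optical flow
#'
#' Magnitude-weighted histogram of flow directions over `K` bins partitioning
#' `[0, 360)` degrees half-open (bin k covers `[(k-1) 360/K, k 360/K)`), so
#' the bin masses sum exactly to the total flow magnitude of the region.
#'
#' @param flow a `flow_field`
#' @param K bin count (default 8)
#' @param region optional `c(x, y, w, h)` box (0-based, half-open) restricting
#'   the histogram
#' @return object of class `hof_descriptor`: numeric vector of length K with
#'   attributes `K` and `region`
#' @export
hof <- function(flow, K = 8L, region = NULL) {
  stopifnot(K >= 2L)
  u <- flow$u; v <- flow$v
  if (!is.null(region)) {
    rr <- (region[2] + 1):(region[2] + region[4])
    cc <- (region[1] + 1):(region[1] + region[3])
    u <- u[rr, cc, drop = FALSE]
    v <- v[rr, cc, drop = FALSE]
  }
  mag <- sqrt(u^2 + v^2)
  theta <- (rad2deg(atan2(v, u))) %% 360
  bin <- pmin(floor(theta / (360 / K)) + 1L, K)
  h <- vapply(seq_len(K), function(k) sum(mag[bin == k]), numeric(1))
  structure(h, K = K, region = region, class = "hof_descriptor")
}

#' Angle at the vertex of a point triple
#'
#' Angle at `P2` between vectors `P1 - P2` and `P3 - P2`, from the clamped
#' arccosine of the normalized dot product; in degrees, range [0, 180].
#'
#' @param P1,P2,P3 numeric coordinate vectors (2D or 3D)
#' @return angle in degrees
#' @export
joint_angle <- function(P1, P2, P3) {
  v1 <- P1 - P2
  v2 <- P3 - P2
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 == 0 || n2 == 0) stop("zero-length vector at the angle vertex")
  cosang <- sum(v1 * v2) / (n1 * n2)
  rad2deg(acos(pmin(pmax(cosang, -1), 1)))
}

#' Default landmark triples for angular geometric features
#'
#' Eight triples: elbow angles, knee angles, the shoulder-neck-shoulder and
#' hip-pelvis-hip torso pairs, and the two neck-shoulder-elbow angles.
#' @return list of character triples
#' @export
default_angle_triples <- function() {
  list(c("shoulder_l", "elbow_l", "wrist_l"),
       c("shoulder_r", "elbow_r", "wrist_r"),
       c("hip_l", "knee_l", "ankle_l"),
       c("hip_r", "knee_r", "ankle_r"),
       c("shoulder_l", "neck", "shoulder_r"),
       c("hip_l", "pelvis_center", "hip_r"),
       c("neck", "shoulder_l", "elbow_l"),
       c("neck", "shoulder_r", "elbow_r"))
}

#' Angular geometric feature vector of a skeleton frame
#'
#' [joint_angle()] evaluated over a fixed ordered list of landmark triples.
#' The `pelvis_center` landmark is derived as the hip midpoint when absent.
#'
#' @param skel a `skeleton_frame`
#' @param triples list of landmark-name triples (default
#'   [default_angle_triples()])
#' @return named numeric vector of angles in degrees
#' @export
angular_feature_set <- function(skel, triples = default_angle_triples()) {
  lm <- skel$landmarks
  if (!"pelvis_center" %in% rownames(lm) &&
      all(c("hip_l", "hip_r") %in% rownames(lm))) {
    lm <- rbind(lm, pelvis_center = (lm["hip_l", ] + lm["hip_r", ]) / 2)
  }
  out <- vapply(triples, function(tr) {
    miss <- setdiff(tr, rownames(lm))
    if (length(miss)) stop(sprintf("missing landmark '%s'", miss[1]))
    joint_angle(lm[tr[1], ], lm[tr[2], ], lm[tr[3], ])
  }, numeric(1))
  names(out) <- vapply(triples, paste, character(1), collapse = "-")
  out
}

#' Moore boundary trace of a binary mask
#'
#' Clockwise contour starting at the topmost-leftmost foreground pixel
#' (Moore-neighbor tracing with Jacob's stopping criterion). Coordinates are
#' 0-based `(x, y)` with y down.
#'
#' @param mask logical or 0/1 matrix
#' @return m x 2 matrix of boundary points
#' @export
trace_contour <- function(mask) {
  mask <- mask > 0
  if (!any(mask)) stop("empty mask")
  nr <- nrow(mask); nc <- ncol(mask)
  at <- function(r, c) r >= 1 && r <= nr && c >= 1 && c <= nc && mask[r, c]
  # neighbors in clockwise order starting West (image coordinates, y down)
  moves <- rbind(c(0, -1), c(-1, -1), c(-1, 0), c(-1, 1),
                 c(0, 1), c(1, 1), c(1, 0), c(1, -1))
  start <- which(mask, arr.ind = TRUE)
  start <- start[order(start[, 1], start[, 2]), , drop = FALSE][1, ]
  contour <- matrix(start, 1, 2)
  finish <- function(ct) {
    if (nrow(ct) > 1L && all(ct[nrow(ct), ] == ct[1, ])) {
      ct <- ct[-nrow(ct), , drop = FALSE]
    }
    cbind(x = ct[, 2] - 1, y = ct[, 1] - 1)
  }
  # enter from the West
  prev_dir <- 1L
  cur <- start
  max_steps <- 4L * sum(mask) + 8L
  first_move <- NA_integer_
  for (step in seq_len(max_steps)) {
    found <- FALSE
    # start scanning clockwise from the neighbor after the backtrack
    for (i in 0:7) {
      dir <- ((prev_dir - 1L + i) %% 8L) + 1L
      r <- cur[1] + moves[dir, 1]; c <- cur[2] + moves[dir, 2]
      if (at(r, c)) {
        if (all(c(r, c) == start) && !is.na(first_move) && dir == first_move) {
          return(finish(contour))
        }
        if (is.na(first_move)) first_move <- dir
        cur <- c(r, c)
        contour <- rbind(contour, cur)
        # backtrack: neighbor before the one we came from
        prev_dir <- ((dir - 1L + 5L) %% 8L) + 1L
        found <- TRUE
        break
      }
    }
    if (!found) break # isolated pixel
    if (all(cur == start) && step > 1L) break
  }
  finish(contour)
}

#' Eight round angles (Freeman chain code) of a contour
#'
#' Quantizes each step direction between successive contour points to the
#' nearest of the eight compass codes (0 = East, counterclockwise in the
#' coordinate frame of the input) and reports the signed turn angles between
#' successive steps, wrapped to (-180, 180] degrees, together with the code
#' histogram.
#'
#' @param contour m x 2 matrix of ordered (x, y) points
#' @param closed if `TRUE`, append the closing step from last to first point
#' @return object of class `chain_code`: list with `codes` (integers 0-7),
#'   `delta_theta` (degrees), `histogram` (counts per code 0-7)
#' @export
eight_round_angles <- function(contour, closed = FALSE) {
  contour <- as.matrix(contour)
  if (nrow(contour) < 2L) stop("contour needs at least 2 points")
  if (closed) contour <- rbind(contour, contour[1, ])
  steps <- diff(contour)
  keep <- rowSums(steps^2) > 0
  steps <- steps[keep, , drop = FALSE]
  theta <- rad2deg(atan2(steps[, 2], steps[, 1])) %% 360
  codes <- as.integer(round(theta / 45)) %% 8L
  ang <- codes * 45
  dtheta <- if (length(ang) >= 2L) wrap_angle(diff(ang)) else numeric(0)
  structure(list(codes = codes, delta_theta = dtheta,
                 histogram = tabulate(codes + 1L, nbins = 8L)),
            class = "chain_code")
}
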