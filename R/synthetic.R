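# Synthetic articulated stick-figure sequences: class-labeled skeletons,
# silhouette masks, depth maps and analytically consistent flow fields.

# Canonical standing pose on a 128x128 canvas (x along columns, y down).
base_pose <- function() {
  # arms slightly abducted and legs apart so limbs stay geodesically
  # separate at the default point-cloud sampling stride
  rbind(head = c(64, 30),
        shoulder_l = c(50, 44), shoulder_r = c(78, 44),
        elbow_l = c(40, 58), elbow_r = c(88, 58),
        wrist_l = c(32, 70), wrist_r = c(96, 70),
        hip_l = c(57, 78), hip_r = c(71, 78),
        knee_l = c(54, 96), knee_r = c(74, 96),
        ankle_l = c(53, 112), ankle_r = c(75, 112))
}

# Depth offset (mm) assigned to each skeleton bone; body sits in front of a
# far background plane.
bone_depths <- function() {
  c(1350, # neck-head
    1400, 1400,       # neck-shoulders
    1300, 1250,       # left arm
    1300, 1250,       # right arm
    1420, 1420,       # neck-hips (trunk)
    1450, 1480,       # left leg
    1450, 1480)       # right leg
}

#' Describe a synthetic motion class
#'
#' A motion class is a parametric animation of the 14-landmark stick figure:
#' sinusoidal oscillation of amplitude `amp` (pixels) at `freq` Hz applied to
#' `osc_joints` along `osc_dir`, a global drift of `drift` pixels/frame, and
#' Gaussian landmark/depth noise.
#'
#' @param name class label
#' @param amp oscillation amplitude, pixels
#' @param freq oscillation frequency, Hz
#' @param osc_joints landmark names receiving the oscillation
#' @param osc_dir unit-ish direction of the oscillation, `c(dx, dy)`
#' @param drift global drift `c(dx, dy)` in pixels/frame
#' @param noise_sd_px landmark jitter SD, pixels
#' @param depth_noise_sd depth noise SD, mm
#' @param n_frames frames per sequence
#' @param fps frames per second
#' @param start_offset initial whole-body offset `c(dx, dy)` in pixels
#' @return object of class `motion_class_spec`
#' @export
motion_class_spec <- function(name, amp = 0, freq = 0,
                              osc_joints = character(0),
                              osc_dir = c(0, 1), drift = c(0, 0),
                              noise_sd_px = 0.3, depth_noise_sd = 10,
                              n_frames = 20L, fps = 10,
                              start_offset = c(0, 0)) {
  stopifnot(amp >= 0, fps > 0, n_frames >= 1L)
  structure(list(name = name, amp = amp, freq = freq,
                 osc_joints = osc_joints, osc_dir = osc_dir, drift = drift,
                 noise_sd_px = noise_sd_px, depth_noise_sd = depth_noise_sd,
                 n_frames = as.integer(n_frames), fps = fps,
                 start_offset = start_offset),
            class = "motion_class_spec")
}

#' Default motion classes
#'
#' Three classes exercising the motion contrasts the features discriminate:
#' `fall_like` (fast global translation of the whole body), `cough_like`
#' (localized head/shoulder oscillation), `static_stretch` (a held posture
#' whose only motion is measurement noise).
#'
#' @param n_frames frames per sequence (default 20)
#' @param fps frames per second (default 10)
#' @return named list of [motion_class_spec()]s
#' @export
default_class_specs <- function(n_frames = 20L, fps = 10) {
  list(
    fall_like = motion_class_spec(
      "fall_like", amp = 1.5, freq = 1,
      osc_joints = c("wrist_l", "wrist_r", "elbow_l", "elbow_r"),
      osc_dir = c(1, 0), drift = c(0, 2), start_offset = c(0, -26),
      n_frames = n_frames, fps = fps),
    cough_like = motion_class_spec(
      "cough_like", amp = 3, freq = 1.5,
      osc_joints = c("head", "shoulder_l", "shoulder_r"),
      osc_dir = c(0, 1), drift = c(0, 0),
      n_frames = n_frames, fps = fps),
    static_stretch = motion_class_spec(
      "static_stretch", amp = 0, freq = 0, drift = c(0, 0),
      n_frames = n_frames, fps = fps))
}

# Deterministic landmark tracks for a spec (before noise): list of n_frames
# landmark matrices.
spec_tracks <- function(spec) {
  base <- base_pose()
  lapply(seq_len(spec$n_frames), function(t) {
    tt <- (t - 1) / spec$fps
    lm <- base
    lm <- lm + matrix(spec$start_offset + spec$drift * (t - 1),
                      nrow(lm), 2, byrow = TRUE)
    if (spec$amp > 0 && length(spec$osc_joints)) {
      osc <- spec$amp * sin(2 * pi * spec$freq * tt)
      for (j in spec$osc_joints) {
        lm[j, ] <- lm[j, ] + osc * spec$osc_dir
      }
    }
    lm
  })
}

# Render silhouette + depth for one landmark frame. Returns mask, depth and
# the per-pixel nearest-bone index and arc parameter (for analytic flow).
render_body <- function(lm, canvas = c(128L, 128L), radius = 4,
                        head_radius = 7, depth_bg = 2000) {
  edges <- default_edge_spec()
  lm <- rbind(lm, neck = (lm["shoulder_l", ] + lm["shoulder_r", ]) / 2)
  nr <- canvas[1]; nc <- canvas[2]
  xs <- matrix(rep(seq_len(nc) - 1, each = nr), nr, nc)
  ys <- matrix(rep(seq_len(nr) - 1, nc), nr, nc)
  best_d <- matrix(Inf, nr, nc)
  bone <- matrix(0L, nr, nc)
  tpar <- matrix(0, nr, nc)
  bdep <- bone_depths()
  depth_body <- matrix(Inf, nr, nc)
  for (e in seq_along(edges)) {
    p1 <- lm[edges[[e]][1], ]; p2 <- lm[edges[[e]][2], ]
    vx <- p2[1] - p1[1]; vy <- p2[2] - p1[2]
    len2 <- vx^2 + vy^2
    t_ <- if (len2 > 0) ((xs - p1[1]) * vx + (ys - p1[2]) * vy) / len2 else 0 * xs
    t_ <- pmin(pmax(t_, 0), 1)
    dx <- xs - (p1[1] + t_ * vx)
    dy <- ys - (p1[2] + t_ * vy)
    d <- sqrt(dx^2 + dy^2)
    r <- if (edges[[e]][2] == "head") head_radius else radius
    inside <- d <= r
    upd <- d < best_d
    best_d[upd] <- d[upd]
    bone[upd] <- e
    tpar[upd] <- t_[upd]
    depth_body[inside & bdep[e] < depth_body] <- bdep[e]
  }
  mask <- is.finite(depth_body)
  depth <- matrix(depth_bg, nr, nc)
  depth[mask] <- depth_body[mask]
  list(mask = mask, depth = depth, bone = bone, tpar = tpar,
       landmarks = lm)
}

#' Generate one synthetic motion sequence
#'
#' Animates the stick body per the class spec, renders per-frame silhouette
#' masks (capsules around each bone), depth maps (per-bone depth offsets over
#' a far background plane, with additive Gaussian noise), and flow fields
#' derived analytically from the landmark motion (each silhouette pixel moves
#' with the interpolated displacement of its supporting bone's endpoints).
#'
#' @param spec a [motion_class_spec()]
#' @param seed RNG seed for the landmark/depth noise
#' @param canvas canvas size `c(nrow, ncol)` (default 128 x 128)
#' @return list with `skeletons` (list of `skeleton_frame`), `masks`,
#'   `depth` (a depth [frame_sequence()]), `flows` (list of `flow_field`,
#'   length `n_frames - 1`), and `ground_truth` (true masks, noise-free
#'   landmark tracks, limb tip names, torso center, class label)
#' @export
make_sequence <- function(spec, seed = 1L, canvas = c(128L, 128L)) {
  stopifnot(inherits(spec, "motion_class_spec"))
  tracks <- spec_tracks(spec)
  n <- spec$n_frames
  noisy <- with_seed(seed, lapply(tracks, function(lm) {
    lm + matrix(stats::rnorm(length(lm), 0, spec$noise_sd_px), nrow(lm), 2)
  }))
  renders <- lapply(noisy, render_body, canvas = canvas)
  depth_noise <- with_seed(seed + 1L, lapply(seq_len(n), function(t) {
    matrix(stats::rnorm(prod(canvas), 0, spec$depth_noise_sd), canvas[1], canvas[2])
  }))
  depth_frames <- lapply(seq_len(n), function(t) {
    d <- renders[[t]]$depth + depth_noise[[t]]
    d[d < 1] <- 1
    d
  })
  skeletons <- lapply(seq_len(n), function(t) {
    build_skeleton(noisy[[t]], timestamp = (t - 1) / spec$fps)
  })
  flows <- vector("list", max(n - 1L, 0L))
  edges <- default_edge_spec()
  for (t in seq_len(max(n - 1L, 0L))) {
    lm0 <- renders[[t]]$landmarks
    lm1 <- rbind(noisy[[t + 1L]],
                 neck = (noisy[[t + 1L]]["shoulder_l", ] +
                           noisy[[t + 1L]]["shoulder_r", ]) / 2)
    disp <- lm1[rownames(lm0), , drop = FALSE] - lm0
    u <- matrix(0, canvas[1], canvas[2])
    v <- matrix(0, canvas[1], canvas[2])
    mk <- renders[[t]]$mask
    bone <- renders[[t]]$bone
    tp <- renders[[t]]$tpar
    for (e in seq_along(edges)) {
      sel <- mk & bone == e
      if (!any(sel)) next
      d1 <- disp[edges[[e]][1], ]; d2 <- disp[edges[[e]][2], ]
      u[sel] <- (1 - tp[sel]) * d1[1] + tp[sel] * d2[1]
      v[sel] <- (1 - tp[sel]) * d1[2] + tp[sel] * d2[2]
    }
    flows[[t]] <- structure(list(u = u, v = v), class = "flow_field")
  }
  gt_renders <- lapply(tracks, render_body, canvas = canvas)
  list(
    skeletons = skeletons,
    masks = lapply(renders, `[[`, "mask"),
    depth = frame_sequence(depth_frames, fps = spec$fps, depth = TRUE),
    flows = flows,
    ground_truth = list(
      masks = lapply(gt_renders, `[[`, "mask"),
      tracks = tracks,
      limb_tips = c("head", "wrist_l", "wrist_r", "ankle_l", "ankle_r"),
      torso_center = colMeans(tracks[[1]][c("shoulder_l", "shoulder_r",
                                            "hip_l", "hip_r"), ]),
      label = spec$name,
      seed = seed))
}

#' Generate a labeled synthetic dataset
#'
#' `n_per_class` sequences per class spec, each with a derived seed
#' `seed + index` so the dataset is a deterministic function of the master
#' seed. A manifest records id, class, seed and frame count per sequence.
#'
#' @param specs list of [motion_class_spec()]s (>= 2)
#' @param n_per_class sequences per class
#' @param seed master seed
#' @param canvas canvas size
#' @return list with `sequences` (list of [make_sequence()] outputs),
#'   `labels` (factor), `manifest` (data.frame)
#' @export
make_dataset <- function(specs, n_per_class = 20L, seed = 1L,
                         canvas = c(128L, 128L)) {
  stopifnot(length(specs) >= 2L)
  seqs <- list()
  manifest <- NULL
  idx <- 0L
  for (spec in specs) {
    for (i in seq_len(n_per_class)) {
      idx <- idx + 1L
      s <- seed + idx
      seqs[[idx]] <- make_sequence(spec, seed = s, canvas = canvas)
      manifest <- rbind(manifest,
                        data.frame(id = sprintf("seq%03d", idx),
                                   class = spec$name, seed = s,
                                   n_frames = spec$n_frames))
    }
  }
  list(sequences = seqs,
       labels = factor(manifest$class, levels = unique(manifest$class)),
       manifest = manifest)
}
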