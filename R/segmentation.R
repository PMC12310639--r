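# Silhouette segmentation: level sets for intensity frames, affine-aligned
# gradient thresholding for depth frames.

#' Edge indicator function
#'
#' `g = 1 / (1 + |grad I|^2)` computed on a Gaussian-smoothed copy of the
#' image (central differences, replicate borders). `g` is 1 in flat regions
#' and tends to 0 at strong edges.
#'
#' @param img numeric matrix (single channel)
#' @param smooth_sigma pre-smoothing Gaussian sigma in pixels (default 1; 0
#'   disables smoothing)
#' @return matrix with values in (0, 1]
#' @export
edge_indicator <- function(img, smooth_sigma = 1) {
  stopifnot(is.matrix(img))
  s <- gaussian_blur(img, smooth_sigma)
  gr <- central_gradient(s)
  1 / (1 + gr$gx^2 + gr$gy^2)
}

#' Initialize a level-set state
#'
#' The level-set function is a signed distance, negative inside the contour.
#' `init = "box"` starts from the tight bounding box of `mask` inflated by
#' `inflate` pixels (the default contour placement around an approximate
#' silhouette); `init = "circle"` starts from a circle given by `center` and
#' `radius`.
#'
#' @param dim image dimensions `c(nrow, ncol)`
#' @param init `"box"` or `"circle"`
#' @param mask binary matrix locating the approximate object (for `"box"`)
#' @param inflate box inflation in pixels (default 10)
#' @param center,radius circle parameters (for `"circle"`), `center = c(x, y)`
#' @param mu weight of the distance-regularization term (default 0.2)
#' @param lam weight of the edge-weighted contour-length term (default 1)
#' @param v balloon weight; positive shrinks the contour (default 1.5)
#' @param dt time step; defaults to the stability bound `0.25 / max(mu, lam)`
#' @param eps Heaviside smoothing width in grid units (default 1.5)
#' @return an object of class `level_set_state`
#' @export
level_set_init <- function(dim, init = c("box", "circle"), mask = NULL,
                           inflate = 10, center = NULL, radius = NULL,
                           mu = 0.2, lam = 1, v = 1.5, dt = NULL, eps = 1.5) {
  init <- match.arg(init)
  stopifnot(mu >= 0, lam >= 0)
  if (is.null(dt)) dt <- 0.25 / max(mu, lam, 1e-12)
  nr <- dim[1]; nc <- dim[2]
  xs <- matrix(rep(seq_len(nc) - 1, each = nr), nr, nc)
  ys <- matrix(rep(seq_len(nr) - 1, nc), nr, nc)
  if (init == "circle") {
    stopifnot(!is.null(center), !is.null(radius))
    phi <- sqrt((xs - center[1])^2 + (ys - center[2])^2) - radius
  } else {
    stopifnot(!is.null(mask))
    px <- which(mask > 0, arr.ind = TRUE)
    if (nrow(px) == 0L) stop("mask has no foreground to initialize from")
    x0 <- max(min(px[, 2]) - 1 - inflate, 0)
    x1 <- min(max(px[, 2]) - 1 + inflate, nc - 1)
    y0 <- max(min(px[, 1]) - 1 - inflate, 0)
    y1 <- min(max(px[, 1]) - 1 + inflate, nr - 1)
    # signed distance to the rectangle boundary (negative inside)
    dx <- pmax(x0 - xs, xs - x1, 0)
    dy <- pmax(y0 - ys, ys - y1, 0)
    outside <- sqrt(dx^2 + dy^2)
    inside <- pmin(pmin(xs - x0, x1 - xs), pmin(ys - y0, y1 - ys))
    phi <- ifelse(outside > 0, outside, -pmax(inside, 0))
  }
  structure(list(phi = phi, mu = mu, lam = lam, v = v, dt = dt, eps = eps,
                 energy = numeric(0)),
            class = "level_set_state")
}

# Smoothed Heaviside and its derivative (atan profile).
heaviside_eps <- function(phi, eps) 0.5 * (1 + (2 / pi) * atan(phi / eps))
delta_eps <- function(phi, eps) (1 / pi) * eps / (eps^2 + phi^2)

# Discretized contour energy: edge-weighted contour length (whose gradient
# flow is the curvature/advection motion) plus the edge-weighted interior
# area driven by the balloon term.
level_set_energy <- function(phi, g, mu, lam, v, eps) {
  gr <- central_gradient(phi)
  mag <- sqrt(gr$gx^2 + gr$gy^2)
  len <- g * delta_eps(phi, eps) * mag
  area <- g * heaviside_eps(-phi, eps)
  sum(max(mu, lam) * len + v * area)
}

# Signed distance to the current zero level set, exact within `band` grid
# units of the interface and clamped to +/-(band + 1) beyond; used for
# periodic reinitialization. The interface is located at subpixel accuracy by
# linear interpolation of phi along sign-changing 4-neighbor pairs, so
# reinitialization does not displace the contour. `band = Inf` gives the
# exact global distance.
reinit_signed_distance <- function(phi, band = Inf) {
  inside <- phi < 0
  nr <- nrow(phi); nc <- ncol(phi)
  # subpixel zero crossings along horizontal and vertical pixel edges
  cx <- c(); cy <- c()
  right <- cbind(phi[, -1], phi[, nc])
  chg <- (phi < 0) != (right < 0)
  chg[, nc] <- FALSE
  if (any(chg)) {
    ij <- which(chg, arr.ind = TRUE)
    f <- phi[chg] / (phi[chg] - right[chg])
    cx <- c(cx, ij[, 2] - 1 + f)
    cy <- c(cy, ij[, 1] - 1)
  }
  down <- rbind(phi[-1, ], phi[nr, ])
  chg <- (phi < 0) != (down < 0)
  chg[nr, ] <- FALSE
  if (any(chg)) {
    ij <- which(chg, arr.ind = TRUE)
    f <- phi[chg] / (phi[chg] - down[chg])
    cx <- c(cx, ij[, 2] - 1)
    cy <- c(cy, ij[, 1] - 1 + f)
  }
  if (length(cx) == 0L) return(phi)
  if (is.finite(band)) {
    # restrict the exact computation to a dilated interface neighborhood
    b <- inside != shift_replicate(inside, 0L, 1L) |
      inside != shift_replicate(inside, 0L, -1L) |
      inside != shift_replicate(inside, 1L, 0L) |
      inside != shift_replicate(inside, -1L, 0L)
    nbhd <- b
    for (i in seq_len(as.integer(ceiling(band)) + 1L)) {
      nbhd <- nbhd | shift_replicate(nbhd, 0L, 1L) | shift_replicate(nbhd, 0L, -1L) |
        shift_replicate(nbhd, 1L, 0L) | shift_replicate(nbhd, -1L, 0L)
    }
    target <- which(nbhd)
  } else {
    target <- seq_len(nr * nc)
  }
  tx <- ((target - 1L) %/% nr)
  ty <- ((target - 1L) %% nr)
  d2 <- rep(Inf, length(target))
  for (chunk in split(seq_along(cx), ceiling(seq_along(cx) / 512))) {
    dd <- outer(tx, cx[chunk], "-")^2 + outer(ty, cy[chunk], "-")^2
    d2 <- pmin(d2, apply(dd, 1, min))
  }
  out <- matrix(band + 1, nr, nc)
  out[target] <- pmin(sqrt(d2), if (is.finite(band)) band + 1 else Inf)
  out * ifelse(inside, -1, 1)
}

#' Evolve a level-set contour over an image
#'
#' Explicit-Euler evolution of the signed level-set function
#' `phi_t = g (mu kappa + v) |grad phi| + lam grad(g) . grad(phi)`:
#' edge-gated curvature smoothing (weight `mu`), an edge-attraction advection
#' term (weight `lam`), and a balloon force (weight `v`; positive shrinks the
#' interior under the negative-inside convention). With `g == 1` and `v = 0`
#' this reduces to mean-curvature motion at rate `mu * kappa`. The discrete
#' contour energy is recorded each step and is non-increasing up to
#' discretization error. `phi` is reinitialized to a signed distance every
#' `reinit_every` steps.
#'
#' Updates are restricted to a narrow band `|phi| <= band` around the
#' contour and `phi` is frequently rebuilt as a signed distance, so only the
#' contour moves: far-field pixels (where the balloon force never stops)
#' cannot detach the region from its boundary.
#'
#' @param state a [level_set_init()] state
#' @param img intensity image the contour segments
#' @param n_steps number of explicit update steps
#' @param reinit_every reinitialization period in steps (default 5)
#' @param smooth_sigma pre-smoothing for the edge indicator (default 1)
#' @param band narrow-band half-width in grid units (default 2)
#' @return the evolved `level_set_state`, with the per-step energy trace in
#'   `$energy`
#' @export
evolve_level_set <- function(state, img, n_steps, reinit_every = 5L,
                             smooth_sigma = 1, band = 2) {
  stopifnot(inherits(state, "level_set_state"), n_steps >= 0)
  if (n_steps == 0L) return(state)
  g <- edge_indicator(img, smooth_sigma)
  gg <- central_gradient(g)
  phi <- state$phi
  mu <- state$mu; lam <- state$lam; v <- state$v
  dt <- state$dt; eps <- state$eps
  reg_eps <- 1e-8
  energy <- c(state$energy,
              level_set_energy(phi, g, mu, lam, v, eps))
  for (step in seq_len(n_steps)) {
    gr <- central_gradient(phi)
    mag <- sqrt(gr$gx^2 + gr$gy^2 + reg_eps)
    nx <- gr$gx / mag
    ny <- gr$gy / mag
    # curvature = div(grad phi / |grad phi|)
    kappa <- central_gradient(nx)$gx + central_gradient(ny)$gy
    advect <- gg$gx * gr$gx + gg$gy * gr$gy
    in_band <- abs(phi) <= band
    phi <- phi + dt * in_band * (g * (mu * kappa + v) * mag + lam * advect)
    if (any(!is.finite(phi))) {
      stop(sprintf("level-set evolution diverged at step %d", step))
    }
    if (step %% reinit_every == 0L && step < n_steps) {
      phi <- reinit_signed_distance(phi, band = band + 2)
    }
    energy <- c(energy, level_set_energy(phi, g, mu, lam, v, eps))
  }
  state$phi <- phi
  state$energy <- energy
  state
}

#' Binary mask of the level-set interior
#'
#' @param state a `level_set_state`
#' @return logical matrix, `TRUE` where `phi < 0`
#' @export
level_set_mask <- function(state) {
  state$phi < 0
}

#' Affine transform record
#'
#' `x' = a x + b y + tx`, `y' = c x + d y + ty` on 0-based pixel coordinates
#' (`x` along columns, `y` along rows).
#'
#' @param a,b,c,d matrix entries (must be invertible)
#' @param tx,ty translation in pixels
#' @return object of class `affine_transform`
#' @export
affine_transform <- function(a = 1, b = 0, c = 0, d = 1, tx = 0, ty = 0) {
  if (abs(a * d - b * c) < 1e-12) stop("affine transform must be invertible")
  structure(list(a = a, b = b, c = c, d = d, tx = tx, ty = ty),
            class = "affine_transform")
}

#' @export
print.affine_transform <- function(x, ...) {
  cat(sprintf("<affine_transform [%.4g %.4g; %.4g %.4g] + (%.4g, %.4g)>\n",
              x$a, x$b, x$c, x$d, x$tx, x$ty))
  invisible(x)
}

# Apply / invert on n x 2 point matrices (columns x, y).
affine_apply <- function(t, pts) {
  cbind(t$a * pts[, 1] + t$b * pts[, 2] + t$tx,
        t$c * pts[, 1] + t$d * pts[, 2] + t$ty)
}

affine_invert <- function(t) {
  det <- t$a * t$d - t$b * t$c
  ia <- t$d / det; ib <- -t$b / det; ic <- -t$c / det; id <- t$a / det
  affine_transform(ia, ib, ic, id,
                   -(ia * t$tx + ib * t$ty), -(ic * t$tx + id * t$ty))
}

#' Estimate the canonicalizing alignment of a silhouette
#'
#' Computes the rigid + uniform-scale transform that maps the silhouette
#' centroid to the canvas center and its principal (second-moment) axis to
#' vertical. This supplies the affine matrix used to align depth silhouettes
#' into a common reference frame; the rotation is the smallest one that
#' verticalizes the major axis.
#'
#' @param mask binary matrix
#' @param min_area minimum foreground size (default 10)
#' @param scale uniform scale factor (default 1)
#' @return an [affine_transform()]
#' @export
estimate_alignment <- function(mask, min_area = 10L, scale = 1) {
  px <- which(mask > 0, arr.ind = TRUE)
  if (nrow(px) < min_area) stop("mask foreground below min_area")
  x <- px[, 2] - 1; y <- px[, 1] - 1
  cx <- mean(x); cy <- mean(y)
  cxx <- mean((x - cx)^2); cyy <- mean((y - cy)^2); cxy <- mean((x - cx) * (y - cy))
  # major-axis angle from the vertical (y) axis, in (-pi/2, pi/2]
  ev <- eigen(matrix(c(cxx, cxy, cxy, cyy), 2, 2), symmetric = TRUE)
  major <- ev$vectors[, 1]
  ang_from_vertical <- atan2(major[1], major[2]) # 0 when already vertical
  if (ang_from_vertical > pi / 2) ang_from_vertical <- ang_from_vertical - pi
  if (ang_from_vertical <= -pi / 2) ang_from_vertical <- ang_from_vertical + pi
  # R(th) maps (sin a, cos a) to (sin(a - th), cos(a - th)): th = a verticalizes
  th <- ang_from_vertical
  ca <- cos(th); sa <- sin(th)
  ctr <- c((ncol(mask) - 1) / 2, (nrow(mask) - 1) / 2)
  a <- scale * ca; b <- -scale * sa; cc <- scale * sa; d <- scale * ca
  tx <- ctr[1] - (a * cx + b * cy)
  ty <- ctr[2] - (cc * cx + d * cy)
  affine_transform(a, b, cc, d, tx, ty)
}

#' Depth gradient magnitude
#'
#' `|grad D| = sqrt((dD/dx)^2 + (dD/dy)^2)` by central differences with
#' replicate borders; highlights depth discontinuities at silhouette edges.
#'
#' @param D depth matrix
#' @return matrix of gradient magnitudes
#' @export
depth_gradient_magnitude <- function(D) {
  gr <- central_gradient(D)
  sqrt(gr$gx^2 + gr$gy^2)
}

# Warp a depth map by an affine transform using inverse mapping: bilinear
# interpolation on valid (> 0) depth, nearest neighbor for the validity flag.
warp_depth <- function(D, t) {
  nr <- nrow(D); nc <- ncol(D)
  inv <- affine_invert(t)
  xs <- rep(seq_len(nc) - 1, each = nr)
  ys <- rep(seq_len(nr) - 1, nc)
  src <- affine_apply(inv, cbind(xs, ys))
  sx <- src[, 1]; sy <- src[, 2]
  out <- numeric(nr * nc)
  inb <- sx >= 0 & sx <= nc - 1 & sy >= 0 & sy <= nr - 1
  # validity by nearest neighbor
  nnx <- pmin(pmax(round(sx), 0), nc - 1)
  nny <- pmin(pmax(round(sy), 0), nr - 1)
  valid_nn <- inb & (D[cbind(nny + 1, nnx + 1)] > 0)
  x0 <- floor(sx); y0 <- floor(sy)
  x1 <- pmin(x0 + 1, nc - 1); y1 <- pmin(y0 + 1, nr - 1)
  fx <- sx - x0; fy <- sy - y0
  ii <- which(valid_nn)
  if (length(ii)) {
    g <- function(yy, xx) D[cbind(yy[ii] + 1, xx[ii] + 1)]
    v00 <- g(y0, x0); v10 <- g(y0, x1); v01 <- g(y1, x0); v11 <- g(y1, x1)
    w00 <- (1 - fx[ii]) * (1 - fy[ii]); w10 <- fx[ii] * (1 - fy[ii])
    w01 <- (1 - fx[ii]) * fy[ii]; w11 <- fx[ii] * fy[ii]
    # exclude invalid corners from the interpolation
    m00 <- v00 > 0; m10 <- v10 > 0; m01 <- v01 > 0; m11 <- v11 > 0
    wsum <- w00 * m00 + w10 * m10 + w01 * m01 + w11 * m11
    val <- (w00 * v00 * m00 + w10 * v10 * m10 + w01 * v01 * m01 +
              w11 * v11 * m11) / ifelse(wsum > 0, wsum, 1)
    out[ii] <- ifelse(wsum > 0, val, 0)
  }
  matrix(out, nr, nc)
}

#' Segment a depth silhouette via alignment and gradient thresholding
#'
#' Warps the depth map into the reference frame given by `t` (inverse mapping,
#' bilinear interpolation on valid depth), thresholds the depth gradient
#' magnitude with Otsu's method to find silhouette boundaries, flood-fills the
#' enclosed region from the image border, and classifies the remaining
#' boundary ring by depth similarity to the foreground vs. background medians.
#'
#' @param D depth matrix (mm, 0 invalid)
#' @param t an [affine_transform()] (identity for no alignment)
#' @return logical foreground mask in the warped frame
#' @export
segment_depth_silhouette <- function(D, t = affine_transform()) {
  W <- warp_depth(D, t)
  gm <- depth_gradient_magnitude(W)
  if (!any(gm > 0)) {
    stop("no depth transitions found; review segmentation parameters")
  }
  # Otsu over the full gradient field separates edge responses from the
  # (possibly zero) background mode
  thr <- otsu_threshold(as.numeric(gm))
  boundary <- gm >= max(thr, .Machine$double.eps)
  # seal diagonal gaps so the border flood fill cannot leak inside
  boundary <- boundary | shift_replicate(boundary, 0L, 1L) |
    shift_replicate(boundary, 0L, -1L) | shift_replicate(boundary, 1L, 0L) |
    shift_replicate(boundary, -1L, 0L)
  bg <- border_reachable(!boundary)
  interior <- !bg & !boundary
  if (!any(interior)) {
    stop("empty foreground after hole filling; review segmentation parameters")
  }
  fg_med <- stats::median(W[interior & W > 0])
  bg_med <- stats::median(W[bg & W > 0])
  mask <- interior
  if (is.finite(fg_med) && is.finite(bg_med) && fg_med != bg_med) {
    bnd <- which(boundary)
    take <- abs(W[bnd] - fg_med) <= abs(W[bnd] - bg_med) & W[bnd] > 0
    mask[bnd[take]] <- TRUE
  }
  mask
}
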