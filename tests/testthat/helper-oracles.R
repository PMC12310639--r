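# Independent oracles and fixture builders used across the suite.

# Brute-force all-pairs shortest paths (Floyd-Warshall) on a weight matrix
# with Inf for missing edges; the oracle for Dijkstra-based geodesics.
floyd_warshall <- function(W) {
  n <- nrow(W)
  D <- W
  diag(D) <- 0
  for (k in seq_len(n)) {
    D <- pmin(D, outer(D[, k], D[k, ], "+"))
  }
  D
}

# Random connected undirected graph with n nodes; integer weights in 1..9 by
# default so path sums are exactly representable.
random_graph <- function(n, p_extra = 0.15, weights = NULL) {
  edges <- cbind(2:n, vapply(2:n, function(i) sample.int(i - 1L, 1L),
                             integer(1))) # random spanning tree
  extra <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  keep <- stats::runif(nrow(extra)) < p_extra
  edges <- unique(rbind(t(apply(edges, 1, sort)), extra[keep, , drop = FALSE]))
  w <- if (is.null(weights)) sample.int(9L, nrow(edges), replace = TRUE) else weights
  pts <- cbind(stats::runif(n), stats::runif(n), 0)
  g <- point_cloud_graph(pts, edges, weights = w, torso_index = 1L)
  Wm <- matrix(Inf, n, n)
  Wm[edges] <- w
  Wm[edges[, 2:1, drop = FALSE]] <- w
  list(graph = g, W = Wm)
}

# Binary disk image (8-bit contrast) plus its true mask.
disk_image <- function(nr = 128L, center = c(64, 64), radius = 30) {
  xs <- matrix(rep(0:(nr - 1), each = nr), nr, nr)
  ys <- matrix(rep(0:(nr - 1), nr), nr, nr)
  mask <- (xs - center[1])^2 + (ys - center[2])^2 <= radius^2
  list(img = ifelse(mask, 255, 0), mask = mask, xs = xs, ys = ys)
}

# Hausdorff-style deviation of a mask boundary from a circle of radius r.
mask_circle_deviation <- function(mask, center, radius) {
  nr <- nrow(mask)
  eroded <- mask & rbind(mask[-1, ], FALSE) & rbind(FALSE, mask[-nr, ]) &
    cbind(mask[, -1], FALSE) & cbind(FALSE, mask[, -nr])
  bp <- which(mask & !eroded, arr.ind = TRUE)
  r <- sqrt((bp[, 2] - 1 - center[1])^2 + (bp[, 1] - 1 - center[2])^2)
  max(abs(r - radius))
}

# Central-difference numerical gradient of the neuro-fuzzy loss for one
# parameter block, via getter/setter closures.
nf_numeric_gradient <- function(model, X, Tm, get, set, h = 1e-5) {
  th <- get(model)
  g <- th * 0
  for (i in seq_along(th)) {
    t1 <- th; t1[i] <- t1[i] + h
    t2 <- th; t2[i] <- t2[i] - h
    g[i] <- (hmir:::nf_loss_grad(set(model, t1), X, Tm)$loss -
               hmir:::nf_loss_grad(set(model, t2), X, Tm)$loss) / (2 * h)
  }
  g
}

# Random small two-layer neuro-fuzzy model + data for gradient checks.
random_nf_model <- function(d = 3L, R1 = 4L, R2 = 3L, C = 2L, n = 5L, m = 2) {
  X <- matrix(stats::rnorm(n * d), n, d)
  Tm <- diag(C)[sample.int(C, n, replace = TRUE), , drop = FALSE]
  model <- list(
    layers = list(
      list(C = matrix(stats::rnorm(R1 * d), R1, d),
           S = matrix(stats::runif(R1 * d, 0.5, 1.5), R1, d)),
      list(C = matrix(stats::runif(R2 * R1, 0, 0.6), R2, R1),
           S = matrix(stats::runif(R2 * R1, 0.3, 1), R2, R1))),
    W = matrix(stats::rnorm(R2 * C), R2, C), m = m, reg = 0.01)
  list(model = model, X = X, Tm = Tm)
}

# Relative error of an analytic gradient against its numeric oracle.
grad_rel_err <- function(analytic, numeric) {
  max(abs(analytic - numeric)) / max(max(abs(numeric)), 1e-8)
}

# Maximum relative error over every parameter block of a model.
nf_gradient_check <- function(rnd) {
  lg <- hmir:::nf_loss_grad(rnd$model, rnd$X, rnd$Tm)
  errs <- c(
    grad_rel_err(lg$gW, nf_numeric_gradient(
      rnd$model, rnd$X, rnd$Tm,
      function(m) m$W, function(m, v) { m$W <- v; m })))
  for (l in 1:2) {
    errs <- c(errs,
      grad_rel_err(lg$glayers[[l]]$gC, nf_numeric_gradient(
        rnd$model, rnd$X, rnd$Tm,
        function(m) m$layers[[l]]$C,
        function(m, v) { m$layers[[l]]$C <- v; m })),
      grad_rel_err(lg$glayers[[l]]$gS, nf_numeric_gradient(
        rnd$model, rnd$X, rnd$Tm,
        function(m) m$layers[[l]]$S,
        function(m, v) { m$layers[[l]]$S <- v; m })))
  }
  max(errs)
}

# Canonical 13-landmark standing pose (the generator's base body).
base_landmarks <- function() hmir:::base_pose()

# Small cached synthetic dataset shared by pipeline-level tests.
small_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- make_dataset(default_class_specs(n_frames = 8L),
                             n_per_class = 3L, seed = 11L)
    }
    cache
  }
})
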