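# Internal helpers shared across the pipeline.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded stages never disturb the
#' caller's RNG stream.
#' @param seed integer seed
#' @param code expression to evaluate
#' @return the value of `code`
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1) # materialize a seed so it can be restored
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Replicate-pad a matrix by `r` pixels on every side (clamp-to-edge).
pad_replicate <- function(m, r) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- c(rep(1L, r), seq_len(nr), rep(nr, r))
  ci <- c(rep(1L, r), seq_len(nc), rep(nc, r))
  m[ri, ci, drop = FALSE]
}

# Shift a matrix by (dy, dx) with replicate borders.
shift_replicate <- function(m, dy, dx) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- pmin(pmax(seq_len(nr) + dy, 1L), nr)
  ci <- pmin(pmax(seq_len(nc) + dx, 1L), nc)
  m[ri, ci, drop = FALSE]
}

# Central-difference gradients with replicate borders; returns list(gx, gy)
# where x runs along columns and y along rows.
central_gradient <- function(m) {
  gx <- (shift_replicate(m, 0L, 1L) - shift_replicate(m, 0L, -1L)) / 2
  gy <- (shift_replicate(m, 1L, 0L) - shift_replicate(m, -1L, 0L)) / 2
  list(gx = gx, gy = gy)
}

# Separable Gaussian blur, replicate borders. sigma in pixels.
gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  p <- pad_replicate(m, r)
  # rows then columns
  nr <- nrow(m); nc <- ncol(m)
  tmp <- matrix(0, nr + 2 * r, nc)
  for (i in seq_along(k)) {
    tmp <- tmp + k[i] * p[, (i - 1) + seq_len(nc), drop = FALSE]
  }
  out <- matrix(0, nr, nc)
  for (i in seq_along(k)) {
    out <- out + k[i] * tmp[(i - 1) + seq_len(nr), , drop = FALSE]
  }
  out
}

# Otsu's threshold on a numeric vector (maximizes between-class variance).
otsu_threshold <- function(x, n_bins = 256L) {
  x <- x[is.finite(x)]
  if (length(x) == 0L || diff(range(x)) == 0) return(NA_real_)
  br <- seq(min(x), max(x), length.out = n_bins + 1L)
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE), nbins = n_bins)
  p <- h / sum(h)
  omega <- cumsum(p)
  centers <- (br[-1] + br[-length(br)]) / 2
  mu <- cumsum(p * centers)
  mu_t <- mu[n_bins]
  denom <- omega * (1 - omega)
  sigma_b <- ifelse(denom > 0, (mu_t * omega - mu)^2 / denom, 0)
  centers[which.max(sigma_b)]
}

# 8-connected component labeling of a logical matrix. Returns an integer
# matrix (0 background, 1..n components), labels in raster-scan discovery
# order so results are deterministic.
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  fg <- which(mask)
  if (length(fg) == 0L) return(lab)
  cur <- 0L
  # offsets of the 8-neighborhood in (row, col)
  off_r <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
  off_c <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  for (start in fg) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    stack <- start
    lab[start] <- cur
    while (length(stack) > 0L) {
      p <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pr <- ((p - 1L) %% nr) + 1L
      pc <- ((p - 1L) %/% nr) + 1L
      nrr <- pr + off_r
      ncc <- pc + off_c
      ok <- nrr >= 1L & nrr <= nr & ncc >= 1L & ncc <= nc
      q <- (ncc[ok] - 1L) * nr + nrr[ok]
      q <- q[mask[q] & lab[q] == 0L]
      if (length(q)) {
        lab[q] <- cur
        stack <- c(stack, q)
      }
    }
  }
  lab
}

# Flood fill of FALSE cells reachable from the image border moving through
# cells where `open` is TRUE (4-connectivity, as used for hole filling).
border_reachable <- function(open) {
  nr <- nrow(open); nc <- ncol(open)
  reach <- matrix(FALSE, nr, nc)
  seeds <- unique(c(which(open[1, ]) * nr - nr + 1L,      # top row
                    which(open[nr, ]) * nr,               # bottom row
                    which(open[, 1]),                     # left col
                    (nc - 1L) * nr + which(open[, nc])))  # right col
  seeds <- seeds[open[seeds]]
  if (length(seeds) == 0L) return(reach)
  reach[seeds] <- TRUE
  stack <- seeds
  off_r <- c(-1L, 1L, 0L, 0L)
  off_c <- c(0L, 0L, -1L, 1L)
  while (length(stack) > 0L) {
    p <- stack[length(stack)]
    stack <- stack[-length(stack)]
    pr <- ((p - 1L) %% nr) + 1L
    pc <- ((p - 1L) %/% nr) + 1L
    nrr <- pr + off_r
    ncc <- pc + off_c
    ok <- nrr >= 1L & nrr <= nr & ncc >= 1L & ncc <= nc
    q <- (ncc[ok] - 1L) * nr + nrr[ok]
    q <- q[open[q] & !reach[q]]
    if (length(q)) {
      reach[q] <- TRUE
      stack <- c(stack, q)
    }
  }
  reach
}

# Convert a 3-channel array to grayscale by ITU-R 601 luma; pass matrices
# through unchanged.
to_gray <- function(img) {
  if (is.matrix(img)) return(img)
  if (length(dim(img)) == 3L && dim(img)[3] >= 3L) {
    return(0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3])
  }
  if (length(dim(img)) == 3L && dim(img)[3] == 1L) return(img[, , 1])
  stop("expected a matrix or an array with 1 or 3 channels")
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# Wrap angles (degrees) to (-180, 180].
wrap_angle <- function(x) {
  w <- (x + 180) %% 360 - 180
  w[w == -180] <- 180
  w
}

# Unwrap a degree series: remove jumps larger than 180 degrees.
unwrap_deg <- function(x) {
  if (length(x) < 2L) return(x)
  d <- wrap_angle(diff(x))
  cumsum(c(x[1], d))
}
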