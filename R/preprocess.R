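# Preprocessing: keyframe selection, denoising, normalization, ROI extraction.

#' Build a frame sequence object
#'
#' Ordered, time-stamped rasters shared by the RGB and depth branches. Frames
#' are numeric matrices (grayscale) or h x w x 3 arrays (RGB); depth frames
#' are matrices in millimeters with 0 marking invalid pixels.
#'
#' @param frames list of matrices/arrays, all with identical height and width
#' @param fps frames per second (timestamps are `(i-1)/fps`)
#' @param depth logical; `TRUE` marks a depth sequence (mm units, 0 invalid)
#' @return an object of class `frame_sequence`
#' @export
frame_sequence <- function(frames, fps = 30, depth = FALSE) {
  stopifnot(is.list(frames), length(frames) >= 1L, fps > 0)
  dims <- lapply(frames, function(f) dim(f)[1:2])
  if (length(unique(lapply(dims, as.integer))) != 1L) {
    stop("all frames must share height and width")
  }
  if (depth && any(vapply(frames, function(f) any(f < 0), logical(1)))) {
    stop("depth values must be >= 0 (0 marks invalid pixels)")
  }
  structure(list(frames = frames,
                 timestamps = (seq_along(frames) - 1) / fps,
                 fps = fps, depth = depth),
            class = "frame_sequence")
}

#' @export
length.frame_sequence <- function(x) length(x$frames)

#' @export
print.frame_sequence <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<frame_sequence: %d %s frames, %dx%d, %.3g fps>\n",
              length(x$frames), if (x$depth) "depth" else "intensity",
              d[1], d[2], x$fps))
  invisible(x)
}

# Intensity histogram of one frame on B equal-width bins over [0, 1]
# (frames with values > 1 are treated as 8-bit and scaled by 1/255).
frame_histogram <- function(img, n_bins) {
  g <- to_gray(img)
  if (max(g) > 1) g <- g / 255
  idx <- pmin(floor(g * n_bins) + 1L, n_bins) # half-open bins, last closed
  tabulate(idx, nbins = n_bins)
}

#' Select keyframes by inter-frame histogram variation
#'
#' Ranks frames by how much their intensity histogram changes relative to the
#' previous frame and keeps the `n_keep` highest-scoring ones. The default
#' score is the sum of squared bin differences
#' \eqn{\sum_k (H_i(k) - H_{i-1}(k))^2}; `method = "product"` uses the raw
#' product score \eqn{\sum_k H_i(k) H_{i-1}(k)^2} instead. Frame 1 has score 0
#' by convention but remains eligible.
#'
#' @param seq a [frame_sequence()]
#' @param n_keep number of keyframes to keep (default 20)
#' @param n_bins histogram bin count B (default 32)
#' @param method `"sqdiff"` (default) or `"product"`
#' @return sorted integer vector of `n_keep` frame indices, with the scores of
#'   all frames attached as attribute `"scores"`
#' @export
select_keyframes <- function(seq, n_keep = 20L, n_bins = 32L,
                             method = c("sqdiff", "product")) {
  method <- match.arg(method)
  stopifnot(inherits(seq, "frame_sequence"))
  n <- length(seq$frames)
  if (n == 0L) stop("empty sequence")
  if (n_keep > n) stop("n_keep exceeds the number of frames")
  if (n_bins < 2L) stop("n_bins must be >= 2")
  H <- vapply(seq$frames, frame_histogram, integer(n_bins), n_bins = n_bins)
  scores <- numeric(n)
  if (n >= 2L) {
    for (i in 2:n) {
      scores[i] <- if (method == "sqdiff") {
        sum((H[, i] - H[, i - 1])^2)
      } else {
        sum(H[, i] * H[, i - 1]^2)
      }
    }
  }
  keep <- order(scores, seq_len(n), decreasing = c(TRUE, FALSE),
                method = "radix")[seq_len(n_keep)]
  structure(sort(keep), scores = scores)
}

#' Median filter (salt-and-pepper denoising for RGB frames)
#'
#' Replaces each pixel by the median of its `kernel` x `kernel` neighborhood,
#' with replicate (clamp-to-edge) borders. RGB arrays are filtered per
#' channel.
#'
#' @param img numeric matrix or h x w x c array
#' @param kernel odd window size, >= 3
#' @return filtered raster, same shape as `img`
#' @export
median_filter <- function(img, kernel = 3L) {
  if (kernel %% 2 == 0 || kernel < 3) stop("kernel must be odd and >= 3")
  if (!is.matrix(img)) {
    out <- img
    for (ch in seq_len(dim(img)[3])) out[, , ch] <- median_filter(img[, , ch], kernel)
    return(out)
  }
  r <- (kernel - 1L) %/% 2L
  nr <- nrow(img); nc <- ncol(img)
  stack <- matrix(0, nr * nc, kernel^2)
  j <- 0L
  for (dy in -r:r) for (dx in -r:r) {
    j <- j + 1L
    stack[, j] <- shift_replicate(img, dy, dx)
  }
  # median of k^2 values per pixel via row-wise partial sort
  ord <- matrixStats_rowMedians(stack)
  matrix(ord, nr, nc)
}

# Row-wise median of a matrix without extra dependencies. For odd column
# counts (always the case for k^2 windows) this is the middle order statistic.
matrixStats_rowMedians <- function(m) {
  k <- ncol(m)
  mid <- (k + 1L) %/% 2L
  s <- apply(m, 1L, function(v) sort.int(v, partial = mid)[mid])
  as.numeric(s)
}

#' Bilateral filter (edge-preserving depth denoising)
#'
#' Weighted neighborhood average where weights decay with both spatial
#' distance (`sigma_s`, pixels) and radiometric difference (`sigma_r`, depth
#' units), so depth discontinuities are preserved. Borders replicate.
#'
#' @param depth numeric matrix
#' @param sigma_s spatial standard deviation, pixels (> 0)
#' @param sigma_r range standard deviation, depth units (> 0)
#' @param kernel odd window size (default `2*ceiling(2*sigma_s) + 1`)
#' @return filtered matrix, same shape
#' @export
bilateral_filter <- function(depth, sigma_s = 2, sigma_r = 30,
                             kernel = NULL) {
  if (sigma_s <= 0 || sigma_r <= 0) stop("sigma_s and sigma_r must be > 0")
  if (is.null(kernel)) kernel <- 2L * as.integer(ceiling(2 * sigma_s)) + 1L
  if (kernel %% 2 == 0) stop("kernel must be odd")
  r <- (kernel - 1L) %/% 2L
  num <- matrix(0, nrow(depth), ncol(depth))
  den <- matrix(0, nrow(depth), ncol(depth))
  for (dy in -r:r) for (dx in -r:r) {
    nb <- shift_replicate(depth, dy, dx)
    w <- exp(-(dy^2 + dx^2) / (2 * sigma_s^2) - (depth - nb)^2 / (2 * sigma_r^2))
    num <- num + w * nb
    den <- den + w
  }
  num / den
}

#' Min-max normalization to [0, 1]
#'
#' `(I - min) / (max - min)`; a constant image maps to all zeros.
#'
#' @param img numeric matrix or array
#' @return raster of the same shape with values in [0, 1]
#' @export
minmax_normalize <- function(img) {
  if (length(img) == 0L) stop("empty image")
  lo <- min(img); hi <- max(img)
  if (hi == lo) return(img * 0)
  (img - lo) / (hi - lo)
}

#' Z-score normalization (zero mean, unit population variance)
#'
#' `(I - mean) / sd` with the population (1/N) standard deviation; a constant
#' image maps to all zeros.
#'
#' @param depth numeric matrix or array
#' @return normalized raster, same shape
#' @export
zscore_normalize <- function(depth) {
  if (length(depth) == 0L) stop("empty image")
  mu <- mean(depth)
  sigma <- sqrt(mean((depth - mu)^2))
  if (sigma == 0) return(depth * 0)
  (depth - mu) / sigma
}

#' Extract regions of interest from a binary silhouette mask
#'
#' Finds 8-connected foreground components with area at least `min_area`,
#' returns one tight bounding box and crop per component. Box coordinates are
#' 0-based with half-open extent `[x, x+w) x [y, y+h)`; `x` runs along
#' columns, `y` along rows.
#'
#' @param mask logical or 0/1 matrix
#' @param min_area minimum component area in pixels (default 200)
#' @param img optional raster to crop from (defaults to `mask`)
#' @return list of `list(box = c(x, y, w, h), crop = matrix)`, ordered by
#'   component discovery order; empty list when no component qualifies
#' @export
extract_roi <- function(mask, min_area = 200L, img = NULL) {
  mask <- mask > 0
  if (is.null(img)) img <- mask * 1
  lab <- label_components(mask)
  n <- max(lab)
  out <- list()
  for (i in seq_len(n)) {
    px <- which(lab == i, arr.ind = TRUE)
    if (nrow(px) < min_area) next
    r0 <- min(px[, 1]); r1 <- max(px[, 1])
    c0 <- min(px[, 2]); c1 <- max(px[, 2])
    out[[length(out) + 1L]] <- list(
      box = c(x = c0 - 1L, y = r0 - 1L, w = c1 - c0 + 1L, h = r1 - r0 + 1L),
      crop = img[r0:r1, c0:c1, drop = FALSE])
  }
  out
}
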