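# Readers and writers for the pipeline's on-disk formats: PNG frames,
# plain-text depth rasters, JSON/CSV skeletons, CSV feature stores.

#' Write intensity frames as PNG files
#'
#' Frames are clamped to [0, 1] (values above 1 are treated as 8-bit and
#' scaled) and written as `frame_0001.png`, ... in `dir`.
#'
#' @param seq a [frame_sequence()] or list of matrices
#' @param dir output directory (created if needed)
#' @return invisibly, the written file paths
#' @export
write_frames_png <- function(seq, dir) {
  frames <- if (inherits(seq, "frame_sequence")) seq$frames else seq
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(length(frames))
  for (i in seq_along(frames)) {
    f <- frames[[i]]
    if (max(f) > 1) f <- f / 255
    f[f < 0] <- 0; f[f > 1] <- 1
    paths[i] <- file.path(dir, sprintf("frame_%04d.png", i))
    png::writePNG(f, paths[i])
  }
  invisible(paths)
}

#' Read a directory of PNG/JPEG frames as a frame sequence
#'
#' Files are ordered lexicographically; an optional manifest CSV with columns
#' `filename, timestamp` overrides order and timing. 16-bit PNGs are read
#' losslessly (values scaled to [0, 1]).
#'
#' @param dir directory of `.png` files
#' @param fps frames per second when no manifest is given (default 30)
#' @param manifest optional path to an index CSV
#' @return a [frame_sequence()]
#' @export
read_frames_png <- function(dir, fps = 30, manifest = NULL) {
  if (!is.null(manifest)) {
    idx <- utils::read.csv(manifest, stringsAsFactors = FALSE)
    files <- file.path(dir, idx$filename)
  } else {
    files <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  }
  if (length(files) == 0L) stop("no PNG frames found in ", dir)
  frames <- lapply(files, function(f) to_gray(png::readPNG(f)))
  frame_sequence(frames, fps = fps)
}

#' Write a depth sequence as plain-text rasters
#'
#' One whitespace-delimited text file per frame (`depth_0001.txt`, ...),
#' values in millimeters. This is the package's lossless native depth format.
#'
#' @param seq a depth [frame_sequence()] or list of matrices
#' @param dir output directory
#' @return invisibly, the written paths
#' @export
write_depth_txt <- function(seq, dir) {
  frames <- if (inherits(seq, "frame_sequence")) seq$frames else seq
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(length(frames))
  for (i in seq_along(frames)) {
    paths[i] <- file.path(dir, sprintf("depth_%04d.txt", i))
    utils::write.table(frames[[i]], paths[i], row.names = FALSE,
                       col.names = FALSE)
  }
  invisible(paths)
}

#' Read a depth sequence from plain-text rasters or 16-bit PNGs
#'
#' @param dir directory of `depth_*.txt` or 16-bit `.png` files
#' @param fps frames per second (default 30)
#' @param max_depth_mm full-scale depth used to rescale PNG input (default
#'   65535, i.e. raw 16-bit millimeter counts)
#' @return a depth [frame_sequence()]
#' @export
read_depth <- function(dir, fps = 30, max_depth_mm = 65535) {
  txt <- sort(list.files(dir, pattern = "\\.txt$", full.names = TRUE))
  if (length(txt)) {
    frames <- lapply(txt, function(f) as.matrix(utils::read.table(f)))
    frames <- lapply(frames, unname)
  } else {
    pngs <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
    if (length(pngs) == 0L) stop("no depth frames found in ", dir)
    frames <- lapply(pngs, function(f) png::readPNG(f) * max_depth_mm)
  }
  frame_sequence(frames, fps = fps, depth = TRUE)
}

#' Write a binary mask as an 8-bit PNG (0/255)
#'
#' @param mask logical or 0/1 matrix
#' @param path output file
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG((mask > 0) * 1, path)
  invisible(path)
}

#' Serialize a skeleton frame to JSON
#'
#' Layout: `{timestamp, landmarks: {name: [x, y, z?]}, edges: [[n1, n2], ...]}`.
#'
#' @param skel a `skeleton_frame`
#' @param path output file
#' @export
write_skeleton_json <- function(skel, path) {
  lm <- skel$landmarks
  obj <- list(timestamp = skel$timestamp,
              landmarks = stats::setNames(
                lapply(seq_len(nrow(lm)), function(i) as.numeric(lm[i, ])),
                rownames(lm)),
              edges = skel$edges)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a skeleton frame from JSON
#'
#' @param path file written by [write_skeleton_json()]
#' @return a `skeleton_frame`
#' @export
read_skeleton_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  lm <- do.call(rbind, obj$landmarks)
  edges <- if (is.matrix(obj$edges)) {
    lapply(seq_len(nrow(obj$edges)), function(i) obj$edges[i, ])
  } else obj$edges
  build_skeleton(lm, edge_spec = edges, timestamp = obj$timestamp)
}

#' Write a skeleton sequence as long-format CSV
#'
#' Columns: frame, landmark, x, y, z (z empty for 2D skeletons).
#'
#' @param skeleton_seq list of `skeleton_frame`s
#' @param path output CSV
#' @export
write_skeleton_csv <- function(skeleton_seq, path) {
  rows <- do.call(rbind, lapply(seq_along(skeleton_seq), function(i) {
    lm <- skeleton_seq[[i]]$landmarks
    data.frame(frame = i, landmark = rownames(lm),
               x = lm[, 1], y = lm[, 2],
               z = if (ncol(lm) >= 3) lm[, 3] else NA_real_)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Write ROI boxes to CSV
#'
#' @param rois result of [extract_roi()]
#' @param frame_idx frame index recorded per row
#' @param path output CSV (appends when it exists)
#' @export
write_roi_csv <- function(rois, frame_idx, path) {
  rows <- do.call(rbind, lapply(rois, function(r) {
    data.frame(frame_idx = frame_idx, x = r$box["x"], y = r$box["y"],
               w = r$box["w"], h = r$box["h"])
  }))
  utils::write.table(rows, path, sep = ",", row.names = FALSE,
                     col.names = !file.exists(path), append = file.exists(path))
  invisible(path)
}

#' Write a feature matrix with its block layout
#'
#' CSV mirror of the feature store plus a JSON sidecar with the block layout
#' and provenance (seed).
#'
#' @param X matrix from [assemble_features()]
#' @param labels class labels (optional)
#' @param path output CSV path; the sidecar is `<path>.meta.json`
#' @param seed seed recorded in the sidecar
#' @export
write_feature_store <- function(X, labels = NULL, path, seed = NA) {
  df <- as.data.frame(X)
  if (!is.null(labels)) df$label <- as.character(labels)
  utils::write.csv(df, path, row.names = FALSE)
  layout <- attr(X, "layout")
  jsonlite::write_json(list(layout = as.list(layout), seed = seed),
                       paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(path)
}
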