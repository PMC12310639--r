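# Feature assembly, SGD utilities and the supervised projection that
# optimizes the concatenated feature space.

hmir_blocks <- c("ke", "hof", "agf", "era", "pc25", "rop", "mp")

#' Compute the seven feature blocks of one sequence
#'
#' Maps a generated (or loaded) sequence to the named feature blocks:
#' \describe{
#'   \item{ke}{per-frame total kinetic energy (length `n_frames`).}
#'   \item{hof}{per-frame-pair 8-bin histograms of optical flow, concatenated.}
#'   \item{agf}{per-frame 8 joint angles, concatenated.}
#'   \item{era}{per-frame normalized 8-code chain-code histograms of the
#'     silhouette contour, concatenated.}
#'   \item{pc25}{per-frame mean/max speed, mean acceleration magnitude and
#'     mean curvature of the 2.5D cloud (4 values per frame from the third).}
#'   \item{rop}{random occupancy pattern bits, `rop_sample` per frame.}
#'   \item{mp}{time-averaged 360-degree polygon distance profile followed by
#'     the 20-value most-moving-joint trajectory.}
#' }
#'
#' @param seq_data a [make_sequence()] result (or an equivalently shaped list)
#' @param blocks character subset of the block names to compute
#' @param rop_seed seed for the ROP voxel sample
#' @param rop_sample ROP sample size per frame (default 128)
#' @param hof_bins HOF bin count (default 8)
#' @return named list of numeric vectors, in canonical block order
#' @export
sequence_features <- function(seq_data, blocks = hmir_blocks,
                              rop_seed = 1L, rop_sample = 128L,
                              hof_bins = 8L) {
  blocks <- intersect(hmir_blocks, blocks)
  n <- length(seq_data$skeletons)
  dt <- if (n >= 2L) {
    seq_data$skeletons[[2]]$timestamp - seq_data$skeletons[[1]]$timestamp
  } else 1
  out <- list()
  if ("ke" %in% blocks) {
    ke <- kinetic_energy_profile(seq_data$skeletons, dt = dt)
    out$ke <- as.numeric(ke$total)
  }
  if ("hof" %in% blocks) {
    out$hof <- as.numeric(unlist(lapply(seq_data$flows, function(f) {
      as.numeric(hof(f, K = hof_bins))
    })))
  }
  if ("agf" %in% blocks) {
    out$agf <- as.numeric(unlist(lapply(seq_data$skeletons, angular_feature_set)))
  }
  if ("era" %in% blocks) {
    out$era <- as.numeric(unlist(lapply(seq_data$masks, function(m) {
      cc <- eight_round_angles(trace_contour(m), closed = TRUE)
      h <- cc$histogram
      if (sum(h) > 0) h / sum(h) else h
    })))
  }
  if ("pc25" %in% blocks) {
    clouds <- lapply(seq_len(n), function(t) {
      depth_to_points(seq_data$depth$frames[[t]], seq_data$masks[[t]])
    })
    stats_t <- lapply(seq_len(n), function(t) {
      if (t < 3L) return(c(0, 0, 0, 0))
      dyn <- point_dynamics(clouds[[t]], clouds[[t - 1L]], clouds[[t - 2L]], dt)
      sp <- sqrt(rowSums(dyn$v^2))
      ac <- sqrt(rowSums(dyn$a^2))
      c(mean(sp), max(sp), mean(ac), mean(dyn$kappa))
    })
    out$pc25 <- as.numeric(unlist(stats_t[-(1:2)]))
  }
  if ("rop" %in% blocks) {
    out$rop <- as.numeric(rop_features(seq_data$depth$frames, seq_data$masks,
                                       sample_size = rop_sample,
                                       seed = rop_seed))
  }
  if ("mp" %in% blocks) {
    polys <- lapply(seq_data$skeletons, function(s) {
      movement_polygon(s$landmarks)$d_theta
    })
    traj <- moving_joint_trajectory(seq_data$skeletons)
    out$mp <- c(Reduce(`+`, polys) / length(polys), as.numeric(traj))
  }
  out[intersect(hmir_blocks, names(out))]
}

#' Assemble per-sequence feature blocks into a feature matrix
#'
#' Concatenates the enabled blocks in canonical order (`ke, hof, agf, era,
#' pc25, rop, mp`) for every sequence; the block layout must be identical
#' across sequences. Disabled blocks are omitted, which is how ablation runs
#' are expressed.
#'
#' @param block_list list (one element per sequence) of named block lists, as
#'   returned by [sequence_features()]
#' @param enabled_blocks blocks to keep (default: all present in the first
#'   sequence)
#' @return numeric matrix (sequences x features) with attribute `"layout"`
#'   (named block widths)
#' @export
assemble_features <- function(block_list,
                              enabled_blocks = names(block_list[[1]])) {
  enabled_blocks <- intersect(hmir_blocks, enabled_blocks)
  layout <- NULL
  rows <- lapply(seq_along(block_list), function(i) {
    bl <- block_list[[i]]
    miss <- setdiff(enabled_blocks, names(bl))
    if (length(miss)) {
      stop(sprintf("sequence %d is missing feature block '%s'", i, miss[1]))
    }
    v <- unlist(bl[enabled_blocks], use.names = FALSE)
    widths <- vapply(bl[enabled_blocks], length, integer(1))
    if (is.null(layout)) {
      layout <<- widths
    } else if (!identical(layout, widths)) {
      stop(sprintf("sequence %d has a different block layout", i))
    }
    v
  })
  X <- do.call(rbind, rows)
  colnames(X) <- unlist(lapply(enabled_blocks, function(b) {
    sprintf("%s_%03d", b, seq_len(layout[[b]]))
  }))
  attr(X, "layout") <- layout
  X
}

#' Single-example SGD update
#'
#' `theta <- theta - eta * grad`, elementwise.
#'
#' @param params numeric vector/matrix of parameters
#' @param grad gradient of the same shape
#' @param eta learning rate (> 0)
#' @return updated parameters
#' @export
sgd_update <- function(params, grad, eta) {
  if (eta <= 0) stop("eta must be > 0")
  if (!all(is.finite(grad))) stop("non-finite gradient")
  if (!identical(dim(params), dim(grad)) || length(params) != length(grad)) {
    stop("parameter and gradient shapes differ")
  }
  params - eta * grad
}

#' Mini-batch SGD update
#'
#' Applies [sgd_update()] with the arithmetic mean of the per-example
#' gradients.
#'
#' @param params numeric vector/matrix
#' @param grads list of per-example gradients
#' @param eta learning rate
#' @return updated parameters
#' @export
sgd_minibatch_update <- function(params, grads, eta) {
  if (length(grads) == 0L) stop("empty batch")
  g <- Reduce(`+`, grads) / length(grads)
  sgd_update(params, g, eta)
}

#' Fit a supervised linear feature-space projection by mini-batch SGD
#'
#' Learns a `d x p` linear projection jointly with a softmax classification
#' head by mini-batch SGD with an L1 penalty on the projection entries
#' (`method = "projection"`), or selects the top `p` input dimensions by the
#' learned weight magnitude (`method = "topk"`). Features are standardized
#' with training-set statistics before projection. Fully seeded, hence
#' bit-for-bit reproducible.
#'
#' @param x numeric feature matrix (sequences x features)
#' @param y class labels (factor or coercible)
#' @param p target dimension (default 64)
#' @param eta learning rate (default 0.01)
#' @param batch_size mini-batch size (default 32)
#' @param epochs maximum epochs (default 100)
#' @param patience early-stop patience in epochs of loss stagnation
#'   (default 10)
#' @param l1 L1 weight on the projection entries (default 1e-4)
#' @param seed RNG seed
#' @param method `"projection"` or `"topk"`
#' @return object of class `hmir_projection` with the projection matrix, the
#'   standardization statistics, the softmax head and the loss trace
#' @export
fit_projection <- function(x, y, p = 64L, eta = 0.01, batch_size = 32L,
                           epochs = 100L, patience = 10L, l1 = 1e-4,
                           seed = 1L, method = c("projection", "topk")) {
  method <- match.arg(method)
  x <- as.matrix(x)
  y <- factor(y)
  if (nlevels(y) < 2L) stop("need at least 2 classes")
  d <- ncol(x)
  if (p >= d && method == "topk") stop("p must be below the full dimension")
  p <- min(p, d)
  n <- nrow(x)
  C <- nlevels(y)
  mu <- colMeans(x)
  sd_ <- apply(x, 2, stats::sd)
  sd_[!is.finite(sd_) | sd_ < 1e-12] <- 1
  xs <- sweep(sweep(x, 2, mu), 2, sd_, "/")
  Tmat <- diag(C)[as.integer(y), , drop = FALSE]
  run <- with_seed(seed, {
    W <- matrix(stats::runif(d * p, -1, 1) / sqrt(d), d, p)
    V <- matrix(stats::runif(p * C, -1, 1) / sqrt(p), p, C)
    b <- numeric(C)
    loss_trace <- numeric(0)
    best <- Inf; stall <- 0L
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0; nb <- 0L
      for (start in seq(1L, n, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1L, n)]
        Xb <- xs[idx, , drop = FALSE]
        Tb <- Tmat[idx, , drop = FALSE]
        Z <- Xb %*% W
        logits <- sweep(Z %*% V, 2, b, "+")
        logits <- logits - apply(logits, 1, max)
        P <- exp(logits)
        P <- P / rowSums(P)
        loss <- -mean(log(pmax(rowSums(P * Tb), 1e-300))) + l1 * sum(abs(W))
        dlog <- (P - Tb) / nrow(Xb)
        dV <- t(Z) %*% dlog
        db <- colSums(dlog)
        dZ <- dlog %*% t(V)
        dW <- t(Xb) %*% dZ + l1 * sign(W)
        W <- W - eta * dW
        V <- V - eta * dV
        b <- b - eta * db
        ep_loss <- ep_loss + loss; nb <- nb + 1L
      }
      ep_loss <- ep_loss / nb
      loss_trace <- c(loss_trace, ep_loss)
      if (ep_loss < best - 1e-6) { best <- ep_loss; stall <- 0L } else {
        stall <- stall + 1L
        if (stall >= patience) break
      }
    }
    list(W = W, V = V, b = b, loss_trace = loss_trace)
  })
  keep <- NULL
  if (method == "topk") {
    score <- sqrt(rowSums(run$W^2))
    keep <- sort(order(score, decreasing = TRUE)[seq_len(p)])
  }
  structure(list(W = run$W, V = run$V, b = run$b, mu = mu, sd = sd_,
                 loss_trace = run$loss_trace, levels = levels(y),
                 method = method, keep = keep, p = p, seed = seed),
            class = "hmir_projection")
}

#' @export
print.hmir_projection <- function(x, ...) {
  cat(sprintf("<hmir_projection: %d -> %d (%s), %d classes, %d epochs>\n",
              nrow(x$W), x$p, x$method, length(x$levels),
              length(x$loss_trace)))
  invisible(x)
}

#' Project features with a fitted projection
#'
#' @param object an `hmir_projection`
#' @param newdata feature matrix with the training layout
#' @param type `"features"` (projected coordinates, the default) or
#'   `"class"` (softmax-head labels)
#' @param ... unused
#' @return matrix of projected features, or a factor of class labels
#' @export
predict.hmir_projection <- function(object, newdata,
                                    type = c("features", "class"), ...) {
  type <- match.arg(type)
  x <- as.matrix(newdata)
  xs <- sweep(sweep(x, 2, object$mu), 2, object$sd, "/")
  Z <- if (object$method == "topk") {
    xs[, object$keep, drop = FALSE]
  } else {
    xs %*% object$W
  }
  if (type == "features") return(Z)
  logits <- if (object$method == "topk") {
    stop("class prediction requires method = 'projection'")
  } else {
    sweep(Z %*% object$V, 2, object$b, "+")
  }
  factor(object$levels[max.col(logits, ties.method = "first")],
         levels = object$levels)
}
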