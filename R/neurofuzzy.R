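# Deep neuro-fuzzy classifier: generalized-bell memberships, product-T-norm
# rule strengths, weighted-average defuzzification, trained end-to-end by
# backpropagation with Adam.

#' Fuzzy membership degree
#'
#' Generalized bell membership `1 / (1 + |(x - c) / sigma|^(2m))`: maximal
#' (1) at the center `c`, 0.5 at `|x - c| = sigma`, symmetric about `c`, and
#' sharper for larger fuzzification factor `m`.
#'
#' @param x input value(s)
#' @param c center
#' @param sigma spread (> 0)
#' @param m fuzzification factor (> 1)
#' @return membership degree(s) in (0, 1]
#' @export
membership <- function(x, c, sigma, m = 2) {
  if (any(sigma <= 0)) stop("sigma must be > 0")
  if (any(m <= 1)) stop("m must be > 1")
  1 / (1 + abs((x - c) / sigma)^(2 * m))
}

#' Rule activation strength (product T-norm)
#'
#' @param memberships vector of membership degrees in (0, 1]
#' @return their product, in (0, 1]
#' @export
rule_strength <- function(memberships) {
  prod(memberships)
}

#' Mean squared error loss with optional L2 regularization
#'
#' `(1/N) sum((y - yhat)^2) + reg * sum(w^2)`; for matrix targets the mean
#' runs over all entries.
#'
#' @param targets numeric vector/matrix of true outputs
#' @param predictions numeric vector/matrix of the same shape
#' @param weights optional weights entering the penalty
#' @param reg regularization coefficient (default 0)
#' @return scalar loss
#' @export
mse_loss <- function(targets, predictions, weights = NULL, reg = 0) {
  if (length(targets) != length(predictions)) stop("length mismatch")
  if (length(targets) == 0L) stop("empty inputs")
  loss <- mean((targets - predictions)^2)
  if (reg > 0 && !is.null(weights)) loss <- loss + reg * sum(weights^2)
  loss
}

# ---- internal forward/backward machinery ------------------------------------

# One fuzzy layer: centers C (R x d), spreads S (R x d), factor m.
# Returns normalized strengths (n x R) plus caches for backprop. Strengths
# are computed in log space so products over many inputs do not underflow.
nf_layer_forward <- function(X, C, S, m) {
  n <- nrow(X); R <- nrow(C)
  logs <- matrix(0, n, R)
  for (k in seq_len(R)) {
    t_ <- abs(sweep(sweep(X, 2, C[k, ]), 2, S[k, ], "/"))
    logs[, k] <- -rowSums(log1p(t_^(2 * m)))
  }
  mx <- apply(logs, 1, max)
  es <- exp(logs - mx)
  rs <- rowSums(es)
  shat <- es / rs
  all_zero <- !is.finite(mx)
  if (any(all_zero)) shat[all_zero, ] <- 1 / R
  list(shat = shat, logs = logs)
}

# Backward through one layer. g_shat is dL/d(shat) (n x R). Returns gradients
# for C, S and the input X.
nf_layer_backward <- function(X, C, S, m, cache, g_shat) {
  n <- nrow(X); R <- nrow(C); d <- ncol(X)
  shat <- cache$shat
  # dL/dlog s_k = shat_k * (g_k - sum_l shat_l g_l)
  inner <- rowSums(shat * g_shat)
  h <- shat * (g_shat - inner) # n x R
  gC <- matrix(0, R, d)
  gS <- matrix(0, R, d)
  gX <- matrix(0, n, d)
  for (k in seq_len(R)) {
    diffk <- sweep(X, 2, C[k, ])                  # x - c
    t_ <- abs(sweep(diffk, 2, S[k, ], "/"))
    tp <- t_^(2 * m - 1)
    # d log mu / dt = -2m t^(2m-1) / (1 + t^(2m))
    dldt <- -2 * m * tp / (1 + t_ * tp)
    sgn <- sign(diffk)
    dt_dx <- sweep(sgn, 2, S[k, ], "/")           # dt/dx = sign/sigma
    dldx <- dldt * dt_dx                          # n x d
    dldc <- -dldx                                 # dt/dc = -sign/sigma
    dlds <- dldt * sweep(-t_, 2, S[k, ], "/")     # dt/dsigma = -t/sigma
    hk <- h[, k]
    gC[k, ] <- colSums(hk * dldc)
    gS[k, ] <- colSums(hk * dlds)
    gX <- gX + hk * dldx
  }
  list(gC = gC, gS = gS, gX = gX)
}

# Full forward pass: list of layers (each with C, S), final weights W
# (R_last x C classes). Returns scores and caches.
nf_forward <- function(model, X) {
  caches <- vector("list", length(model$layers))
  inp <- X
  for (l in seq_along(model$layers)) {
    ly <- model$layers[[l]]
    caches[[l]] <- nf_layer_forward(inp, ly$C, ly$S, model$m)
    caches[[l]]$input <- inp
    inp <- caches[[l]]$shat
  }
  scores <- inp %*% model$W # weighted average: shat rows sum to 1
  list(scores = scores, caches = caches)
}

# Loss + full analytic gradient for the current parameters.
nf_loss_grad <- function(model, X, Tmat) {
  fw <- nf_forward(model, X)
  n <- nrow(X); C <- ncol(Tmat)
  err <- fw$scores - Tmat
  loss <- mean(err^2) + model$reg * sum(model$W^2)
  dscore <- 2 * err / (n * C)
  shat_last <- fw$caches[[length(model$layers)]]$shat
  gW <- t(shat_last) %*% dscore + 2 * model$reg * model$W
  g_shat <- dscore %*% t(model$W)
  grads <- vector("list", length(model$layers))
  for (l in rev(seq_along(model$layers))) {
    ly <- model$layers[[l]]
    bk <- nf_layer_backward(fw$caches[[l]]$input, ly$C, ly$S, model$m,
                            fw$caches[[l]], g_shat)
    grads[[l]] <- list(gC = bk$gC, gS = bk$gS)
    g_shat <- bk$gX
  }
  list(loss = loss, gW = gW, glayers = grads, scores = fw$scores)
}

adam_step <- function(state, grad, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^t)
  vhat <- state$v / (1 - beta2^t)
  state$delta <- lr * mhat / (sqrt(vhat) + eps)
  state
}

# ---- user-facing fit --------------------------------------------------------

#' Fit a deep neuro-fuzzy classifier
#'
#' Stacked banks of fuzzy rules: each layer computes generalized-bell
#' memberships of its inputs, combines them with the product T-norm into rule
#' strengths, and normalizes the strengths (so they sum to one) before
#' feeding the next layer; the final layer's weighted average of per-class
#' consequent weights yields the class scores. Centers, spreads and weights
#' are trained jointly by backpropagated mean-squared-error against one-hot
#' targets, with L2 regularization of the consequent weights, using Adam.
#' Rule centers are initialized by seeded k-means on the (standardized)
#' training features, spreads at `sigma0`. Training stops early after
#' `patience` epochs without validation-loss improvement.
#'
#' @param x numeric feature matrix (samples x features)
#' @param y class labels (factor or coercible; >= 2 classes)
#' @param n_rules rules per layer (default 10)
#' @param m fuzzification factor (default 2)
#' @param sigma0 initial spread (default 0.5)
#' @param n_layers depth of the rule stack (default 2)
#' @param lr Adam learning rate (default 0.001)
#' @param reg L2 weight on the consequents (default 0.01)
#' @param epochs maximum epochs (default 100)
#' @param patience early-stop patience (default 10)
#' @param batch_size mini-batch size (default 32)
#' @param validation either a fraction of `x` held out for early stopping
#'   (default 0.2) or a `list(x = , y = )`
#' @param seed RNG seed controlling initialization, shuffling and the
#'   validation split
#' @return object of class `neurofuzzy` with the trained layers, consequent
#'   weights, standardization statistics and per-epoch `history`
#' @seealso [predict.neurofuzzy()], [nf_grid_search()]
#' @export
neurofuzzy <- function(x, y, n_rules = 10L, m = 2, sigma0 = 0.5,
                       n_layers = 2L, lr = 0.001, reg = 0.01,
                       epochs = 100L, patience = 10L, batch_size = 32L,
                       validation = 0.2, seed = 1L) {
  x <- as.matrix(x)
  y <- factor(y)
  if (nlevels(y) < 2L) stop("need at least 2 classes")
  if (sigma0 <= 0) stop("sigma0 must be > 0")
  if (m <= 1) stop("m must be > 1")
  n <- nrow(x); C <- nlevels(y)
  mu <- colMeans(x)
  sd_ <- apply(x, 2, stats::sd)
  sd_[!is.finite(sd_) | sd_ < 1e-12] <- 1
  xs <- sweep(sweep(x, 2, mu), 2, sd_, "/")
  Tfull <- diag(C)[as.integer(y), , drop = FALSE]
  fit <- with_seed(seed, {
    if (is.list(validation)) {
      xv <- sweep(sweep(as.matrix(validation$x), 2, mu), 2, sd_, "/")
      yv <- factor(validation$y, levels = levels(y))
      Tv <- diag(C)[as.integer(yv), , drop = FALSE]
      xt <- xs; Tt <- Tfull
    } else if (is.numeric(validation) && validation > 0) {
      hold <- sample.int(n, max(1L, round(validation * n)))
      xv <- xs[hold, , drop = FALSE]; Tv <- Tfull[hold, , drop = FALSE]
      xt <- xs[-hold, , drop = FALSE]; Tt <- Tfull[-hold, , drop = FALSE]
    } else {
      xv <- xs; Tv <- Tfull; xt <- xs; Tt <- Tfull
    }
    # sequential k-means initialization of each layer's centers
    layers <- list()
    inp <- xt
    for (l in seq_len(n_layers)) {
      k <- min(n_rules, nrow(unique(inp)))
      km <- suppressWarnings(stats::kmeans(inp, centers = k, nstart = 1L,
                                           iter.max = 25L))
      Cmat <- km$centers
      if (k < n_rules) {
        Cmat <- Cmat[rep(seq_len(k), length.out = n_rules), , drop = FALSE]
      }
      Smat <- matrix(sigma0, n_rules, ncol(inp))
      layers[[l]] <- list(C = unname(Cmat), S = Smat)
      inp <- nf_layer_forward(inp, layers[[l]]$C, layers[[l]]$S, m)$shat
    }
    W <- matrix(stats::runif(n_rules * C, -0.1, 0.1), n_rules, C)
    model <- list(layers = layers, W = W, m = m, reg = reg)
    opt <- list(W = list(m = 0 * W, v = 0 * W))
    for (l in seq_len(n_layers)) {
      opt[[paste0("C", l)]] <- list(m = 0 * layers[[l]]$C, v = 0 * layers[[l]]$C)
      opt[[paste0("S", l)]] <- list(m = 0 * layers[[l]]$S, v = 0 * layers[[l]]$S)
    }
    history <- NULL
    best_val <- Inf; stall <- 0L; step <- 0L
    best_model <- model
    nt <- nrow(xt)
    for (ep in seq_len(epochs)) {
      ord <- sample.int(nt)
      tr_loss <- 0; nb <- 0L
      for (start in seq(1L, nt, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1L, nt)]
        lg <- nf_loss_grad(model, xt[idx, , drop = FALSE],
                           Tt[idx, , drop = FALSE])
        if (!is.finite(lg$loss)) {
          stop(sprintf("training loss became non-finite at epoch %d", ep))
        }
        step <- step + 1L
        opt$W <- adam_step(opt$W, lg$gW, lr, step)
        model$W <- model$W - opt$W$delta
        for (l in seq_len(n_layers)) {
          cn <- paste0("C", l); sn <- paste0("S", l)
          opt[[cn]] <- adam_step(opt[[cn]], lg$glayers[[l]]$gC, lr, step)
          model$layers[[l]]$C <- model$layers[[l]]$C - opt[[cn]]$delta
          opt[[sn]] <- adam_step(opt[[sn]], lg$glayers[[l]]$gS, lr, step)
          model$layers[[l]]$S <- pmax(model$layers[[l]]$S - opt[[sn]]$delta,
                                      1e-3) # spread floor
        }
        tr_loss <- tr_loss + lg$loss; nb <- nb + 1L
      }
      vl <- nf_loss_grad(model, xv, Tv)$loss
      history <- rbind(history,
                       data.frame(epoch = ep, train_loss = tr_loss / nb,
                                  val_loss = vl))
      if (vl < best_val - 1e-8) {
        best_val <- vl; stall <- 0L; best_model <- model
      } else {
        stall <- stall + 1L
        if (stall >= patience) break
      }
    }
    list(model = best_model, history = history)
  })
  structure(list(layers = fit$model$layers, W = fit$model$W, m = m,
                 reg = reg, mu = mu, sd = sd_, levels = levels(y),
                 n_rules = n_rules, n_layers = n_layers,
                 history = fit$history, seed = seed,
                 call = match.call()),
            class = "neurofuzzy")
}

#' Neuro-fuzzy inference
#'
#' Propagates inputs through the rule-bank layers and returns the final
#' weighted-average class scores together with the argmax class (ties break
#' toward the lowest class index). Scores are convex combinations of the
#' consequent weights. If every rule strength underflows to zero for a
#' sample, uniform scores are returned with a warning.
#'
#' @param model a fitted [neurofuzzy()] object (or an unfitted model list
#'   with `layers`, `W`, `m`)
#' @param x feature matrix or single feature vector
#' @return list with `scores` (samples x classes) and `class` (factor)
#' @export
infer <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  x <- as.matrix(x)
  if (!is.null(model$mu)) {
    x <- sweep(sweep(x, 2, model$mu), 2, model$sd, "/")
  }
  if (ncol(x) != ncol(model$layers[[1]]$C)) {
    stop("input dimension does not match the first rule layer")
  }
  underflow <- FALSE
  inp <- x
  for (l in seq_along(model$layers)) {
    ly <- model$layers[[l]]
    fwd <- nf_layer_forward(inp, ly$C, ly$S, model$m)
    if (any(!is.finite(apply(fwd$logs, 1, max)))) underflow <- TRUE
    inp <- fwd$shat
  }
  if (underflow) warning("all rule strengths underflowed; using uniform scores")
  scores <- inp %*% model$W
  lev <- if (!is.null(model$levels)) model$levels else seq_len(ncol(scores))
  cls <- factor(lev[max.col(scores, ties.method = "first")], levels = lev)
  list(scores = scores, class = cls)
}

#' @export
print.neurofuzzy <- function(x, ...) {
  cat(sprintf("Deep neuro-fuzzy classifier: %d layer(s) x %d rules, m = %.3g\n",
              x$n_layers, x$n_rules, x$m))
  cat(sprintf("  classes: %s\n", paste(x$levels, collapse = ", ")))
  if (!is.null(x$history)) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("  trained %d epochs (final train loss %.4g, val loss %.4g)\n",
                last$epoch, last$train_loss, last$val_loss))
  }
  invisible(x)
}

#' @export
summary.neurofuzzy <- function(object, ...) {
  print(object)
  s1 <- object$layers[[1]]$S
  cat(sprintf("  layer-1 spreads: min %.4g, median %.4g, max %.4g\n",
              min(s1), stats::median(s1), max(s1)))
  cat(sprintf("  consequent weight range: [%.4g, %.4g]\n",
              min(object$W), max(object$W)))
  invisible(object)
}

#' @export
coef.neurofuzzy <- function(object, ...) {
  list(centers = lapply(object$layers, `[[`, "C"),
       spreads = lapply(object$layers, `[[`, "S"),
       weights = object$W)
}

#' Predict from a fitted neuro-fuzzy classifier
#'
#' @param object a [neurofuzzy()] fit
#' @param newdata feature matrix
#' @param type `"class"` (default) or `"score"`
#' @param ... unused
#' @return factor of classes or a score matrix
#' @export
predict.neurofuzzy <- function(object, newdata, type = c("class", "score"),
                               ...) {
  type <- match.arg(type)
  res <- infer(object, newdata)
  if (type == "class") res$class else res$scores
}

#' Plot neuro-fuzzy training history
#'
#' @param x a [neurofuzzy()] fit
#' @param ... passed to [graphics::matplot()]
#' @export
plot.neurofuzzy <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1:2, col = c("black", "red3"),
                    xlab = "epoch", ylab = "MSE loss", ...)
  graphics::legend("topright", c("train", "validation"), lty = 1:2,
                   col = c("black", "red3"), bty = "n")
  invisible(x)
}

#' Grid search over neuro-fuzzy hyperparameters by cross-validated accuracy
#'
#' Evaluates every combination of `rules`, `m` and `sigma` by k-fold
#' cross-validation mean accuracy; ties break toward fewer rules, then
#' smaller `m`, then smaller `sigma`.
#'
#' @param x feature matrix
#' @param y labels
#' @param rules candidate rule counts (default `c(5, 10, 20)`)
#' @param m candidate fuzzification factors (default `c(1.5, 2, 2.5)`)
#' @param sigma candidate initial spreads (default `c(0.2, 0.5, 1)`)
#' @param folds cross-validation folds (default 5)
#' @param seed RNG seed
#' @param ... further arguments to [neurofuzzy()] (e.g. `epochs`)
#' @return list with `best` (named list) and `table` (one row per config with
#'   mean CV accuracy)
#' @export
nf_grid_search <- function(x, y, rules = c(5L, 10L, 20L), m = c(1.5, 2, 2.5),
                           sigma = c(0.2, 0.5, 1), folds = 5L, seed = 1L,
                           ...) {
  stopifnot(length(rules) >= 1L, length(m) >= 1L, length(sigma) >= 1L)
  grid <- expand.grid(rules = rules, m = m, sigma = sigma,
                      KEEP.OUT.ATTRS = FALSE)
  y <- factor(y)
  n <- nrow(as.matrix(x))
  fold_id <- with_seed(seed, sample(rep_len(seq_len(folds), n)))
  acc <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    accs <- vapply(seq_len(folds), function(f) {
      tr <- fold_id != f
      fitted <- neurofuzzy(as.matrix(x)[tr, , drop = FALSE], y[tr],
                           n_rules = grid$rules[i], m = grid$m[i],
                           sigma0 = grid$sigma[i], seed = seed, ...)
      pred <- predict(fitted, as.matrix(x)[!tr, , drop = FALSE])
      mean(pred == y[!tr])
    }, numeric(1))
    acc[i] <- mean(accs)
  }
  grid$accuracy <- acc
  ord <- order(-grid$accuracy, grid$rules, grid$m, grid$sigma)
  best <- grid[ord[1], ]
  list(best = list(rules = best$rules, m = best$m, sigma = best$sigma,
                   accuracy = best$accuracy),
       table = grid)
}
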