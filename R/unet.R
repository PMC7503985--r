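# U-Net encoder-decoder for visible-nuclei region segmentation.
#
# Topology: an encoder of `depth` six-layer groups (two repetitions of
# 3x3 zero-padded convolution + batch norm + ReLU) with 2x2 maxpools between,
# channel plan base*{1,2,4,...}; a decoder of depth-1 stages, each a 2x2
# stride-2 transposed convolution that halves the channel depth, concatenation
# with the matching encoder output, and another six-layer group; finally a 1x1
# convolution down to the three class channels. Zero padding preserves spatial
# size, so the score map matches the network input size and the postprocessing
# upsample only restores the original image resolution.

#' U-Net architecture configuration
#'
#' @param input_size Network input side length in pixels; must be divisible by
#'   `2^(depth - 1)`.
#' @param base_channels Channels of the first encoder group (32 in the
#'   full-scale profile; 8 in the desk-scale profile used by the tests).
#' @param depth Number of encoder groups.
#' @param out_channels Output channels (3 classes).
#' @param batch_norm Include batch-normalization layers.
#' @return List of class `"unet_config"`.
#' @export
unet_config <- function(input_size = 512, base_channels = 32, depth = 5,
                        out_channels = 3, batch_norm = TRUE) {
  if (input_size %% 2^(depth - 1) != 0)
    stop("`input_size` must be divisible by 2^(depth - 1)")
  channels <- base_channels * 2^(seq_len(depth) - 1)
  structure(list(input_size = input_size, base_channels = base_channels,
                 depth = depth, out_channels = out_channels,
                 batch_norm = batch_norm, channels = channels),
            class = "unet_config")
}

# parameter names, shapes and initialization ---------------------------------

unet_init <- function(config, seed = 1L) {
  cs <- config$channels
  depth <- config$depth
  params <- list()
  he <- function(fan_in, ...) array(rnorm(prod(c(...)), 0, sqrt(2 / fan_in)), c(...))
  add_group <- function(params, prefix, cin, cout) {
    params[[paste0(prefix, ".conv1.W")]] <- he(9 * cin, 9 * cin, cout)
    params[[paste0(prefix, ".conv2.W")]] <- he(9 * cout, 9 * cout, cout)
    if (config$batch_norm) {
      for (b in c("bn1", "bn2")) {
        params[[paste0(prefix, ".", b, ".gamma")]] <- rep(1, cout)
        params[[paste0(prefix, ".", b, ".beta")]] <- rep(0, cout)
        params[[paste0(prefix, ".", b, ".mean")]] <- rep(0, cout)
        params[[paste0(prefix, ".", b, ".var")]] <- rep(1, cout)
      }
    }
    params
  }
  with_seed(seed, {
    for (i in seq_len(depth)) {
      cin <- if (i == 1) 1L else cs[i - 1]
      params <- add_group(params, paste0("enc", i), cin, cs[i])
    }
    for (i in rev(seq_len(depth - 1))) {
      params[[paste0("up", i, ".W")]] <- he(cs[i + 1], cs[i + 1], cs[i], 4)
      params <- add_group(params, paste0("dec", i), 2L * cs[i], cs[i])
    }
    params[["out.W"]] <- he(cs[1], cs[1], config$out_channels)
    params[["out.b"]] <- rep(0, config$out_channels)
    params
  })
}

unet_trainable <- function(params) {
  names(params)[grepl("\\.(W|b|gamma|beta)$", names(params))]
}

#' Number of learnable parameters of a U-Net
#'
#' Counts convolution kernels, the output bias and batch-norm scale/shift
#' (running statistics are not learnable).
#'
#' @param x A `"unet_config"`, a fitted `"hrme_unet"`, or a parameter list.
#' @return Integer parameter count.
#' @export
unet_count_params <- function(x) {
  params <- if (inherits(x, "unet_config")) unet_init(x, seed = 1L)
    else if (inherits(x, "hrme_unet")) x$params
    else x
  sum(vapply(params[unet_trainable(params)], length, numeric(1)))
}

# forward / backward ---------------------------------------------------------

group_fwd <- function(x, params, prefix, training, bn) {
  cache <- list()
  cv <- conv3_fwd(x, params[[paste0(prefix, ".conv1.W")]])
  cache$c1 <- cv$cache
  h <- cv$y
  if (bn) {
    r <- bn_fwd(h, params[[paste0(prefix, ".bn1.gamma")]],
                params[[paste0(prefix, ".bn1.beta")]],
                params[[paste0(prefix, ".bn1.mean")]],
                params[[paste0(prefix, ".bn1.var")]], training)
    cache$b1 <- r$cache
    params[[paste0(prefix, ".bn1.mean")]] <- r$run_mean
    params[[paste0(prefix, ".bn1.var")]] <- r$run_var
    h <- r$y
  }
  r <- relu_fwd(h); cache$r1 <- r$cache; h <- r$y
  cv <- conv3_fwd(h, params[[paste0(prefix, ".conv2.W")]])
  cache$c2 <- cv$cache
  h <- cv$y
  if (bn) {
    r <- bn_fwd(h, params[[paste0(prefix, ".bn2.gamma")]],
                params[[paste0(prefix, ".bn2.beta")]],
                params[[paste0(prefix, ".bn2.mean")]],
                params[[paste0(prefix, ".bn2.var")]], training)
    cache$b2 <- r$cache
    params[[paste0(prefix, ".bn2.mean")]] <- r$run_mean
    params[[paste0(prefix, ".bn2.var")]] <- r$run_var
    h <- r$y
  }
  r <- relu_fwd(h); cache$r2 <- r$cache; h <- r$y
  list(y = h, cache = cache, params = params)
}

group_bwd <- function(dy, cache, params, prefix, bn, grads) {
  dy <- relu_bwd(dy, cache$r2)
  if (bn) {
    r <- bn_bwd(dy, cache$b2, params[[paste0(prefix, ".bn2.gamma")]])
    grads[[paste0(prefix, ".bn2.gamma")]] <- r$dgamma
    grads[[paste0(prefix, ".bn2.beta")]] <- r$dbeta
    dy <- r$dx
  }
  r <- conv3_bwd(dy, cache$c2, params[[paste0(prefix, ".conv2.W")]])
  grads[[paste0(prefix, ".conv2.W")]] <- r$dW
  dy <- r$dx
  dy <- relu_bwd(dy, cache$r1)
  if (bn) {
    r <- bn_bwd(dy, cache$b1, params[[paste0(prefix, ".bn1.gamma")]])
    grads[[paste0(prefix, ".bn1.gamma")]] <- r$dgamma
    grads[[paste0(prefix, ".bn1.beta")]] <- r$dbeta
    dy <- r$dx
  }
  r <- conv3_bwd(dy, cache$c1, params[[paste0(prefix, ".conv1.W")]])
  grads[[paste0(prefix, ".conv1.W")]] <- r$dW
  list(dx = r$dx, grads = grads)
}

#' U-Net forward pass
#'
#' @param params Parameter list from `unet_init()` or a fitted model.
#' @param x Input array `(H, W, B, 1)` with `H = W = config$input_size`, or a
#'   single preprocessed matrix.
#' @param config The `"unet_config"`.
#' @param training Training mode (batch statistics, caches kept for backward).
#' @return List: `scores` array `(H, W, B, out_channels)`; in training mode
#'   also `caches` and `params` (with updated batch-norm running statistics).
#' @export
unet_forward <- function(params, x, config, training = FALSE) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L, 1L))
  d <- dim(x)
  if (d[1] != config$input_size || d[2] != config$input_size)
    stop("input spatial size does not match `config$input_size`")
  depth <- config$depth
  bn <- config$batch_norm
  caches <- list()
  enc_out <- list()
  h <- x
  for (i in seq_len(depth)) {
    if (i > 1) {
      p <- maxpool_fwd(h)
      caches[[paste0("pool", i)]] <- p$cache
      h <- p$y
    }
    g <- group_fwd(h, params, paste0("enc", i), training, bn)
    caches[[paste0("enc", i)]] <- g$cache
    params <- g$params
    h <- g$y
    enc_out[[i]] <- h
  }
  for (i in rev(seq_len(depth - 1))) {
    u <- upconv_fwd(h, params[[paste0("up", i, ".W")]])
    caches[[paste0("up", i)]] <- u$cache
    cc <- concat_fwd(u$y, enc_out[[i]])
    caches[[paste0("cat", i)]] <- list(ca = cc$ca, cb = cc$cb)
    g <- group_fwd(cc$y, params, paste0("dec", i), training, bn)
    caches[[paste0("dec", i)]] <- g$cache
    params <- g$params
    h <- g$y
  }
  o <- conv1_fwd(h, params[["out.W"]], params[["out.b"]])
  caches[["out"]] <- o$cache
  if (training) list(scores = o$y, caches = caches, params = params)
  else list(scores = o$y)
}

unet_backward <- function(dscores, caches, params, config) {
  depth <- config$depth
  bn <- config$batch_norm
  grads <- list()
  r <- conv1_bwd(dscores, caches[["out"]], params[["out.W"]])
  grads[["out.W"]] <- r$dW
  grads[["out.b"]] <- r$db
  dy <- r$dx
  denc <- vector("list", depth)  # gradients flowing into encoder outputs
  for (i in seq_len(depth - 1)) {
    g <- group_bwd(dy, caches[[paste0("dec", i)]], params, paste0("dec", i),
                   bn, grads)
    grads <- g$grads
    sp <- concat_bwd(g$dx, caches[[paste0("cat", i)]]$ca,
                     caches[[paste0("cat", i)]]$cb)
    denc[[i]] <- sp$db
    u <- upconv_bwd(sp$da, caches[[paste0("up", i)]],
                    params[[paste0("up", i, ".W")]])
    grads[[paste0("up", i, ".W")]] <- u$dW
    dy <- u$dx
  }
  for (i in rev(seq_len(depth))) {
    if (i < depth) dy <- dy + denc[[i]]
    g <- group_bwd(dy, caches[[paste0("enc", i)]], params, paste0("enc", i),
                   bn, grads)
    grads <- g$grads
    dy <- g$dx
    if (i > 1) dy <- maxpool_bwd(dy, caches[[paste0("pool", i)]])
  }
  grads
}

# data preparation ------------------------------------------------------------

#' Preprocess an image for the network
#'
#' Maps intensities from `[0, 1]` to `[-1, 1]` via `2 * (i - 0.5)` and
#' bilinearly resizes to the network input size.
#'
#' @param image An [hrme_image()] or intensity matrix in `[0, 1]`.
#' @param input_size Target side length.
#' @return `input_size x input_size` matrix in `[-1, 1]`.
#' @export
unet_preprocess <- function(image, input_size = 512) {
  px <- if (inherits(image, "hrme_image")) image$pixels else image
  rng <- range(px)
  if (rng[1] < 0 || rng[2] > 1) stop("intensities must lie in [0, 1]")
  bilinear_resize(2 * (px - 0.5), input_size, input_size)
}

#' Postprocess network scores into a region mask
#'
#' Bilinearly upsamples the three score channels to the original image size,
#' applies a two-class softmax over the visible-nuclei and no-visible-nuclei
#' channels, binarizes at probability 0.5 (a tie goes to no-visible-nuclei),
#' and forces every pixel outside the FOV to background.
#'
#' @param scores Array `(S, S, 1, 3)` or `(S, S, 3)` of class scores.
#' @param original_dim Output dimensions `c(H, W)`.
#' @param fov_mask Logical FOV matrix of dimensions `original_dim`.
#' @return A [region_mask()].
#' @export
unet_postprocess <- function(scores, original_dim, fov_mask) {
  if (length(dim(scores)) == 4) scores <- array(scores, dim(scores)[c(1, 2, 4)])
  s_vis <- bilinear_resize(scores[, , 1], original_dim[1], original_dim[2])
  s_no <- bilinear_resize(scores[, , 2], original_dim[1], original_dim[2])
  p_no <- 1 / (1 + exp(s_vis - s_no))
  lab <- matrix(REGION_CODES[["background"]], original_dim[1], original_dim[2])
  lab[fov_mask] <- ifelse(p_no[fov_mask] >= 0.5,
                          REGION_CODES[["no_visible_nuclei"]],
                          REGION_CODES[["visible_nuclei"]])
  region_mask(lab)
}

#' Composite ground truth from several rater masks
#'
#' A pixel is no-visible-nuclei iff at least two of the three raters marked it
#' no-visible-nuclei; all other non-background pixels are visible-nuclei.
#' Background must agree across raters and is passed through.
#'
#' @param rater_masks List of three [region_mask()]s with identical shapes and
#'   background.
#' @return A [region_mask()].
#' @export
composite_ground_truth <- function(rater_masks) {
  stopifnot(length(rater_masks) == 3)
  ms <- lapply(rater_masks, rm_labels)
  if (!identical(dim(ms[[1]]), dim(ms[[2]])) ||
      !identical(dim(ms[[1]]), dim(ms[[3]])))
    stop("rater masks must have identical shapes")
  bg <- lapply(ms, function(m) m == REGION_CODES[["background"]])
  if (!identical(bg[[1]], bg[[2]]) || !identical(bg[[1]], bg[[3]]))
    stop("rater masks must share the same background")
  votes_no <- (ms[[1]] == 2L) + (ms[[2]] == 2L) + (ms[[3]] == 2L)
  lab <- matrix(REGION_CODES[["visible_nuclei"]], nrow(ms[[1]]), ncol(ms[[1]]))
  lab[votes_no >= 2L] <- REGION_CODES[["no_visible_nuclei"]]
  lab[bg[[1]]] <- REGION_CODES[["background"]]
  region_mask(lab)
}

# pooled two-class IoU from predicted/true label codes (background excluded)
pooled_iou <- function(pred, truth) {
  pred <- as.integer(pred); truth <- as.integer(truth)
  keep <- truth != 0L
  pred <- pred[keep]; truth <- truth[keep]
  iou_of <- function(code) {
    tp <- sum(pred == code & truth == code)
    denom <- sum(pred == code | truth == code)
    if (denom == 0) NA_real_ else tp / denom
  }
  c(iou_visible = iou_of(1L), iou_no_visible = iou_of(2L))
}

# augmentation: reflections + random crop-with-resize; labels follow the image
augment_pair <- function(xi, yi, crop_min = 0.7) {
  if (runif(1) < 0.5) { xi <- xi[, rev(seq_len(ncol(xi)))]; yi <- yi[, rev(seq_len(ncol(yi)))] }
  if (runif(1) < 0.5) { xi <- xi[rev(seq_len(nrow(xi))), ]; yi <- yi[rev(seq_len(nrow(yi))), ] }
  s <- runif(1, crop_min, 1)
  S <- nrow(xi)
  cs <- max(8L, round(s * S))
  if (cs < S) {
    r0 <- sample.int(S - cs + 1L, 1L)
    c0 <- sample.int(S - cs + 1L, 1L)
    xi <- bilinear_resize(xi[r0:(r0 + cs - 1L), c0:(c0 + cs - 1L)], S, S)
    yi <- nearest_resize(yi[r0:(r0 + cs - 1L), c0:(c0 + cs - 1L)], S, S)
  }
  list(x = xi, y = yi)
}

#' Training settings for the U-Net
#'
#' Defaults follow the selected training protocol: Adam with `alpha = 1e-4`,
#' `beta1 = 0.9`, `beta2 = 0.999`, L2 penalty `1e-4` on convolution kernels,
#' learning rate decayed by 0.9 every 10 epochs, batches of five images, and
#' reflection + random-crop-with-resize augmentation.
#'
#' @param lr,beta1,beta2 Adam hyperparameters.
#' @param l2 L2 regularization penalty on convolution kernels.
#' @param lr_decay,lr_decay_every Learning-rate schedule.
#' @param batch_size Images per batch.
#' @param epochs Number of training epochs.
#' @param augment Enable data augmentation.
#' @param crop_min Lower bound of the random crop scale.
#' @param class_weights Optional fixed loss weights (visible, no-visible,
#'   background); by default inverse-prevalence weights are computed from the
#'   training labels (background always 0).
#' @param seed Seed governing initialization, shuffling and augmentation.
#' @param verbose Print per-epoch progress.
#' @return List of class `"unet_train_config"`.
#' @export
unet_train_config <- function(lr = 1e-4, beta1 = 0.9, beta2 = 0.999, l2 = 1e-4,
                              lr_decay = 0.9, lr_decay_every = 10,
                              batch_size = 5, epochs = 30, augment = TRUE,
                              crop_min = 0.7, class_weights = NULL, seed = 1L,
                              verbose = FALSE) {
  structure(as.list(environment()), class = "unet_train_config")
}

#' Fit the region-segmentation U-Net
#'
#' Trains with weighted pixel-wise cross-entropy (class weights inversely
#' proportional to training-set prevalence, background excluded), records the
#' training loss, validation loss and validation IoU at every epoch, and keeps
#' the checkpoint with the highest validation IoU (earliest epoch on ties).
#'
#' @param x List of training images ([hrme_image()] or intensity matrices).
#' @param y List of matching ground-truth [region_mask()]s.
#' @param config A [unet_config()].
#' @param control A [unet_train_config()].
#' @param val_x,val_y Validation images/masks; default to the training data
#'   (useful for overfitting sanity runs).
#' @return Object of class `"hrme_unet"`: `params` (selected checkpoint),
#'   `config`, `control`, `class_weights`, `history` (one row per epoch:
#'   `epoch`, `lr`, `train_loss`, `val_loss`, `val_iou`), `best_epoch`.
#' @export
unet_fit <- function(x, y, config = unet_config(), control = unet_train_config(),
                     val_x = NULL, val_y = NULL) {
  stopifnot(length(x) == length(y), length(x) >= 1)
  if (is.null(val_x)) { val_x <- x; val_y <- y }
  S <- config$input_size
  prep <- function(imgs, msks) {
    list(
      x = lapply(imgs, unet_preprocess, input_size = S),
      y = lapply(msks, function(m) nearest_resize(rm_labels(m), S, S)))
  }
  tr <- prep(x, y)
  va <- prep(val_x, val_y)

  cw <- control$class_weights
  if (is.null(cw)) {
    labs <- unlist(tr$y)
    prev <- c(mean(labs == 1L), mean(labs == 2L))
    prev <- pmax(prev, 1e-3)
    inv <- 1 / prev
    cw <- c(inv / mean(inv), 0)
  }

  params <- unet_init(config, seed = control$seed)
  trainable <- unet_trainable(params)
  l2_names <- trainable[grepl("\\.W$", trainable)]
  opt <- adam_init(params, trainable)

  n <- length(tr$x)
  history <- data.frame(epoch = integer(0), lr = numeric(0),
                        train_loss = numeric(0), val_loss = numeric(0),
                        val_iou = numeric(0))
  best_iou <- -Inf
  best_params <- params
  best_epoch <- NA_integer_

  eval_set <- function(params, set) {
    tl <- 0; wt <- 0
    pred_all <- integer(0); true_all <- integer(0)
    bs <- control$batch_size
    idx <- seq_along(set$x)
    for (b in split(idx, ceiling(seq_along(idx) / bs))) {
      xb <- array(unlist(set$x[b]), c(S, S, length(b), 1L))
      lab <- unlist(set$y[b])
      fw <- unet_forward(params, xb, config, training = FALSE)
      wl <- weighted_cross_entropy(fw$scores, lab, cw)
      nonbg <- sum(lab != 0L)
      tl <- tl + wl$loss * nonbg; wt <- wt + nonbg
      sc <- matrix(fw$scores, ncol = config$out_channels)
      pred <- ifelse(sc[, 2] >= sc[, 1], 2L, 1L)
      pred_all <- c(pred_all, pred[lab != 0L])
      true_all <- c(true_all, lab[lab != 0L])
    }
    iou <- pooled_iou(pred_all, true_all)
    list(loss = tl / wt, iou = mean(iou, na.rm = TRUE))
  }

  with_seed(control$seed + 7L, {
    for (epoch in seq_len(control$epochs)) {
      lr <- control$lr * control$lr_decay^((epoch - 1) %/% control$lr_decay_every)
      ord <- sample.int(n)
      batches <- split(ord, ceiling(seq_along(ord) / control$batch_size))
      ep_loss <- 0
      for (b in batches) {
        xs <- tr$x[b]; ys <- tr$y[b]
        if (control$augment) {
          for (j in seq_along(b)) {
            au <- augment_pair(xs[[j]], ys[[j]], control$crop_min)
            xs[[j]] <- au$x; ys[[j]] <- au$y
          }
        }
        xb <- array(unlist(xs), c(S, S, length(b), 1L))
        lab <- unlist(ys)
        fw <- unet_forward(params, xb, config, training = TRUE)
        params <- fw$params
        wl <- weighted_cross_entropy(fw$scores, lab, cw)
        grads <- unet_backward(wl$grad, fw$caches, params, config)
        st <- adam_step(params, grads, opt, lr, control$beta1, control$beta2,
                        l2 = control$l2, l2_names = l2_names)
        params <- st$params
        opt <- st$state
        ep_loss <- ep_loss + wl$loss * length(b)
      }
      ev <- eval_set(params, va)
      history[epoch, ] <- list(epoch, lr, ep_loss / n, ev$loss, ev$iou)
      if (control$verbose)
        message(sprintf("epoch %3d  lr %.2e  train %.4f  val %.4f  IoU %.3f",
                        epoch, lr, ep_loss / n, ev$loss, ev$iou))
      if (ev$iou > best_iou) {
        best_iou <- ev$iou
        best_params <- params
        best_epoch <- epoch
      }
    }
  })

  structure(list(params = best_params, config = config, control = control,
                 class_weights = cw, history = history,
                 best_epoch = best_epoch, best_val_iou = best_iou),
            class = "hrme_unet")
}

#' @export
print.hrme_unet <- function(x, ...) {
  cat(sprintf("<hrme_unet> input %dx%d, base %d channels, depth %d, %s parameters\n",
              x$config$input_size, x$config$input_size, x$config$base_channels,
              x$config$depth, format(unet_count_params(x), big.mark = ",")))
  cat(sprintf("  trained %d epochs; selected epoch %d (validation IoU %.3f)\n",
              nrow(x$history), x$best_epoch, x$best_val_iou))
  invisible(x)
}

#' @export
summary.hrme_unet <- function(object, ...) {
  print(object)
  cat("\nTraining history (last 5 epochs):\n")
  print(tail(object$history, 5), row.names = FALSE)
  invisible(object)
}

#' Plot U-Net training history
#' @param x A fitted `"hrme_unet"`.
#' @param ... Ignored.
#' @export
plot.hrme_unet <- function(x, ...) {
  h <- x$history
  op <- par(mfrow = c(1, 2)); on.exit(par(op))
  plot(h$epoch, h$train_loss, type = "l", lwd = 2, xlab = "Epoch",
       ylab = "Weighted cross-entropy",
       ylim = range(c(h$train_loss, h$val_loss)))
  lines(h$epoch, h$val_loss, lty = 2, lwd = 2)
  legend("topright", c("training", "validation"), lty = 1:2, lwd = 2, bty = "n")
  plot(h$epoch, h$val_iou, type = "l", lwd = 2, xlab = "Epoch",
       ylab = "Validation IoU")
  abline(v = x$best_epoch, lty = 3)
  invisible(x)
}

#' Predict a region mask for an image
#'
#' @param object A fitted `"hrme_unet"`.
#' @param image An [hrme_image()].
#' @param type `"mask"` for a [region_mask()], `"scores"` for the raw
#'   three-channel score array at network resolution.
#' @param ... Ignored.
#' @export
predict.hrme_unet <- function(object, image, type = c("mask", "scores"), ...) {
  type <- match.arg(type)
  px <- unet_preprocess(image, object$config$input_size)
  fw <- unet_forward(object$params, px, object$config, training = FALSE)
  if (type == "scores") return(fw$scores)
  stopifnot(inherits(image, "hrme_image"))
  unet_postprocess(fw$scores, dim(image$pixels), image$fov_mask)
}
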