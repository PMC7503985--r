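# Low-level neural-network primitives used by the U-Net.
#
# Feature maps are numeric arrays of dim (H, W, B, C): spatial rows/cols,
# batch, channels. With this layout a tensor reshapes to an (H*W*B) x C
# matrix without copying order, so every convolution becomes one BLAS GEMM on
# an im2col matrix, and batch-norm statistics are plain column means. All
# backward passes are hand-derived; gradient correctness is checked against
# finite differences in the test suite.

# ---- im2col for 3x3 zero-padded convolution --------------------------------

im2col3 <- function(x) {
  d <- dim(x); H <- d[1]; W <- d[2]; B <- d[3]; C <- d[4]
  xp <- array(0, c(H + 2L, W + 2L, B, C))
  xp[2:(H + 1), 2:(W + 1), , ] <- x
  N <- H * W * B
  out <- matrix(0, N, 9L * C)
  k <- 0L
  for (dc in 0:2) for (dr in 0:2) {
    k <- k + 1L
    out[, ((k - 1L) * C + 1L):(k * C)] <-
      xp[(1:H) + dr, (1:W) + dc, , , drop = FALSE]
    }
  out
}

col2im3 <- function(g, H, W, B, C) {
  gp <- array(0, c(H + 2L, W + 2L, B, C))
  k <- 0L
  for (dc in 0:2) for (dr in 0:2) {
    k <- k + 1L
    gp[(1:H) + dr, (1:W) + dc, , ] <-
      gp[(1:H) + dr, (1:W) + dc, , , drop = FALSE] +
      array(g[, ((k - 1L) * C + 1L):(k * C)], c(H, W, B, C))
  }
  gp[2:(H + 1), 2:(W + 1), , , drop = FALSE]
}

# 3x3 conv, zero padding, stride 1. W: (9*Cin) x Cout
conv3_fwd <- function(x, W) {
  d <- dim(x)
  X9 <- im2col3(x)
  y <- X9 %*% W
  list(y = array(y, c(d[1], d[2], d[3], ncol(W))),
       cache = list(X9 = X9, dims = d))
}

conv3_bwd <- function(dy, cache, W) {
  d <- cache$dims
  dY <- matrix(dy, nrow = d[1] * d[2] * d[3])
  dW <- crossprod(cache$X9, dY)
  dX9 <- dY %*% t(W)
  dx <- col2im3(dX9, d[1], d[2], d[3], d[4])
  list(dx = array(dx, d), dW = dW)
}

# 1x1 conv with bias. W: Cin x Cout, b: Cout
conv1_fwd <- function(x, W, b) {
  d <- dim(x)
  X <- matrix(x, nrow = d[1] * d[2] * d[3])
  y <- X %*% W
  y <- y + rep(b, each = nrow(y))
  list(y = array(y, c(d[1], d[2], d[3], ncol(W))), cache = list(X = X, dims = d))
}

conv1_bwd <- function(dy, cache, W) {
  d <- cache$dims
  dY <- matrix(dy, nrow = d[1] * d[2] * d[3])
  list(dx = array(dY %*% t(W), d),
       dW = crossprod(cache$X, dY),
       db = colSums(dY))
}

# ---- batch normalization ---------------------------------------------------

bn_fwd <- function(x, gamma, beta, run_mean, run_var, training,
                   momentum = 0.1, eps = 1e-5) {
  d <- dim(x)
  X <- matrix(x, nrow = d[1] * d[2] * d[3])
  if (training) {
    mu <- colMeans(X)
    xc <- X - rep(mu, each = nrow(X))
    v <- colMeans(xc * xc)
    run_mean <- (1 - momentum) * run_mean + momentum * mu
    run_var <- (1 - momentum) * run_var + momentum * v
  } else {
    mu <- run_mean
    v <- run_var
    xc <- X - rep(mu, each = nrow(X))
  }
  invstd <- 1 / sqrt(v + eps)
  xhat <- xc * rep(invstd, each = nrow(X))
  y <- xhat * rep(gamma, each = nrow(X)) + rep(beta, each = nrow(X))
  list(y = array(y, d),
       cache = list(xhat = xhat, invstd = invstd, dims = d, training = training),
       run_mean = run_mean, run_var = run_var)
}

bn_bwd <- function(dy, cache, gamma) {
  d <- cache$dims
  N <- d[1] * d[2] * d[3]
  dY <- matrix(dy, nrow = N)
  xhat <- cache$xhat
  dgamma <- colSums(dY * xhat)
  dbeta <- colSums(dY)
  dxhat <- dY * rep(gamma, each = N)
  if (cache$training) {
    m1 <- colMeans(dxhat)
    m2 <- colMeans(dxhat * xhat)
    dx <- (dxhat - rep(m1, each = N) - xhat * rep(m2, each = N)) *
      rep(cache$invstd, each = N)
  } else {
    dx <- dxhat * rep(cache$invstd, each = N)
  }
  list(dx = array(dx, d), dgamma = dgamma, dbeta = dbeta)
}

# ---- ReLU ------------------------------------------------------------------

relu_fwd <- function(x) list(y = pmax(x, 0), cache = x > 0)
relu_bwd <- function(dy, cache) dy * cache

# ---- 2x2 max pooling, stride 2 ---------------------------------------------

maxpool_fwd <- function(x) {
  d <- dim(x)
  ro <- seq(1L, d[1], 2L); co <- seq(1L, d[2], 2L)
  a <- x[ro, co, , , drop = FALSE]
  b <- x[ro + 1L, co, , , drop = FALSE]
  cc <- x[ro, co + 1L, , , drop = FALSE]
  dd <- x[ro + 1L, co + 1L, , , drop = FALSE]
  y <- pmax(a, b, cc, dd)
  m1 <- a == y
  m2 <- (b == y) & !m1
  m3 <- (cc == y) & !m1 & !m2
  m4 <- !m1 & !m2 & !m3
  list(y = y, cache = list(m = list(m1, m2, m3, m4), dims = d))
}

maxpool_bwd <- function(dy, cache) {
  d <- cache$dims
  dx <- array(0, d)
  ro <- seq(1L, d[1], 2L); co <- seq(1L, d[2], 2L)
  m <- cache$m
  dx[ro, co, , ] <- dy * m[[1]]
  dx[ro + 1L, co, , ] <- dy * m[[2]]
  dx[ro, co + 1L, , ] <- dy * m[[3]]
  dx[ro + 1L, co + 1L, , ] <- dy * m[[4]]
  dx
}

# ---- 2x2 transposed convolution, stride 2 ----------------------------------
# W: array (Cin, Cout, 4), one kernel tap per output sub-position.

upconv_fwd <- function(x, W) {
  d <- dim(x)
  X <- matrix(x, nrow = d[1] * d[2] * d[3])
  Cout <- dim(W)[2]
  y <- array(0, c(2L * d[1], 2L * d[2], d[3], Cout))
  ro <- seq(1L, 2L * d[1], 2L); co <- seq(1L, 2L * d[2], 2L)
  offs <- list(c(0L, 0L), c(1L, 0L), c(0L, 1L), c(1L, 1L))
  for (k in 1:4) {
    yk <- X %*% W[, , k]
    y[ro + offs[[k]][1], co + offs[[k]][2], , ] <-
      array(yk, c(d[1], d[2], d[3], Cout))
  }
  list(y = y, cache = list(X = X, dims = d))
}

upconv_bwd <- function(dy, cache, W) {
  d <- cache$dims
  N <- d[1] * d[2] * d[3]
  ro <- seq(1L, 2L * d[1], 2L); co <- seq(1L, 2L * d[2], 2L)
  offs <- list(c(0L, 0L), c(1L, 0L), c(0L, 1L), c(1L, 1L))
  dW <- array(0, dim(W))
  dX <- matrix(0, N, d[4])
  for (k in 1:4) {
    dYk <- matrix(dy[ro + offs[[k]][1], co + offs[[k]][2], , , drop = FALSE],
                  nrow = N)
    dW[, , k] <- crossprod(cache$X, dYk)
    dX <- dX + dYk %*% t(W[, , k])
  }
  list(dx = array(dX, d), dW = dW)
}

# ---- channel concatenation -------------------------------------------------

concat_fwd <- function(a, b) {
  da <- dim(a); db <- dim(b)
  y <- array(0, c(da[1], da[2], da[3], da[4] + db[4]))
  y[, , , seq_len(da[4])] <- a
  y[, , , da[4] + seq_len(db[4])] <- b
  list(y = y, ca = da[4], cb = db[4])
}

concat_bwd <- function(dy, ca, cb) {
  list(da = dy[, , , seq_len(ca), drop = FALSE],
       db = dy[, , , ca + seq_len(cb), drop = FALSE])
}

# ---- resampling ------------------------------------------------------------

#' Bilinear resize of a matrix
#'
#' Standard bilinear interpolation with half-pixel-centre alignment; constant
#' inputs resize to the same constant.
#'
#' @param x Numeric matrix.
#' @param out_h,out_w Output dimensions.
#' @return `out_h x out_w` matrix.
#' @export
bilinear_resize <- function(x, out_h, out_w) {
  in_h <- nrow(x); in_w <- ncol(x)
  coords <- function(n_out, n_in) {
    s <- n_in / n_out
    src <- (seq_len(n_out) - 0.5) * s - 0.5
    src <- pmin(pmax(src, 0), n_in - 1)
    i0 <- floor(src)
    w <- src - i0
    list(i0 = as.integer(i0) + 1L, i1 = pmin(as.integer(i0) + 2L, n_in), w = w)
  }
  rr <- coords(out_h, in_h)
  cc <- coords(out_w, in_w)
  wr <- rr$w; wc <- cc$w
  top <- x[rr$i0, cc$i0, drop = FALSE] * outer(1 - wr, 1 - wc) +
    x[rr$i0, cc$i1, drop = FALSE] * outer(1 - wr, wc)
  bot <- x[rr$i1, cc$i0, drop = FALSE] * outer(wr, 1 - wc) +
    x[rr$i1, cc$i1, drop = FALSE] * outer(wr, wc)
  top + bot
}

# nearest-neighbour resize (for label masks)
nearest_resize <- function(x, out_h, out_w) {
  ri <- pmin(pmax(ceiling((seq_len(out_h) - 0.5) * nrow(x) / out_h), 1L), nrow(x))
  ci <- pmin(pmax(ceiling((seq_len(out_w) - 0.5) * ncol(x) / out_w), 1L), ncol(x))
  x[ri, ci, drop = FALSE]
}

# ---- weighted softmax cross-entropy ----------------------------------------

#' Weighted pixel-wise cross-entropy loss
#'
#' Softmax cross-entropy over the class channels, averaged over pixels with a
#' weighted mean: `sum(w_i * ce_i) / sum(w_i)` where `w_i` is the class weight
#' of pixel `i`'s true label. Background pixels carry weight 0 and therefore
#' do not contribute.
#'
#' @param scores Array `(H, W, B, n_classes)` (or an `N x n_classes` matrix)
#'   of unnormalized class scores.
#' @param labels Integer vector/matrix of true labels using [REGION_CODES]
#'   (0 = background, 1 = visible nuclei, 2 = no visible nuclei), one per
#'   pixel, in the same pixel order as `scores`.
#' @param class_weights Numeric weights for classes 1..n_classes
#'   (visible, no-visible, background); the background weight must be 0.
#' @return List: `loss` (scalar), `grad` (same shape as `scores`,
#'   d loss / d scores).
#' @export
weighted_cross_entropy <- function(scores, labels,
                                   class_weights = c(1, 1, 0)) {
  d <- dim(scores)
  S <- if (length(d) == 4) matrix(scores, nrow = d[1] * d[2] * d[3]) else scores
  lab <- as.integer(labels)
  nc <- ncol(S)
  # map region codes to channel index: visible=1, no_visible=2, background=3
  ch <- ifelse(lab == 0L, nc, lab)
  w <- class_weights[ch]
  if (sum(w) <= 0) stop("no non-background pixels contribute to the loss")
  m <- do.call(pmax, lapply(seq_len(nc), function(j) S[, j]))
  E <- exp(S - m)
  Z <- rowSums(E)
  P <- E / Z
  logp <- (S - m) - log(Z)
  ce <- -logp[cbind(seq_len(nrow(S)), ch)]
  loss <- sum(w * ce) / sum(w)
  G <- P
  G[cbind(seq_len(nrow(S)), ch)] <- G[cbind(seq_len(nrow(S)), ch)] - 1
  G <- G * (w / sum(w))
  grad <- if (length(d) == 4) array(G, d) else G
  list(loss = loss, grad = grad)
}

# ---- Adam optimizer --------------------------------------------------------

adam_init <- function(params, trainable) {
  st <- list(t = 0L)
  st$m <- lapply(params[trainable], function(p) p * 0)
  st$v <- lapply(params[trainable], function(p) p * 0)
  st
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, l2 = 0, l2_names = character(0)) {
  state$t <- state$t + 1L
  t <- state$t
  for (nm in names(state$m)) {
    g <- grads[[nm]]
    if (l2 > 0 && nm %in% l2_names) g <- g + l2 * params[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}
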