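# Hand-written layers with analytic gradients. Each *_forward returns the
# output plus a cache; the matching *_backward consumes the cache and the
# upstream gradient. All layers operate on (H*W) x C matrices in row-major
# raster order (see utils.R); spatial structure enters only through
# precomputed index plans, so forward and backward are plain BLAS calls
# plus gathers/scatters.

# ---- convolution via im2col -------------------------------------------

# Plans (gather indices/weights) depend only on small integer tuples and
# are reused constantly during training; memoize them per session.
.plan_cache <- new.env(parent = emptyenv())

memo_plan <- function(key, build) {
  got <- .plan_cache[[key]]
  if (is.null(got)) {
    got <- build()
    .plan_cache[[key]] <- got
  }
  got
}

# Index plan for a k x k convolution with the given stride/padding.
# idx[p_out, tap] is the row-major linear index of the contributing input
# pixel (0 = zero padding). Tap order: row offset major, column offset minor;
# weight matrices use the same (k*k*Cin) x Cout layout.
conv_plan <- function(H, W, k, stride = 1L, pad = (k - 1L) %/% 2L) {
  memo_plan(sprintf("c%d_%d_%d_%d_%d", H, W, k, stride, pad), function()
    conv_plan_build(H, W, k, stride, pad))
}

conv_plan_build <- function(H, W, k, stride = 1L, pad = (k - 1L) %/% 2L) {
  Ho <- (H + 2L * pad - k) %/% stride + 1L
  Wo <- (W + 2L * pad - k) %/% stride + 1L
  ro <- rep(0:(Ho - 1L), each = Wo) * stride - pad
  co <- rep(0:(Wo - 1L), times = Ho) * stride - pad
  idx <- matrix(0L, Ho * Wo, k * k)
  t <- 0L
  for (i in 0:(k - 1L)) {
    for (j in 0:(k - 1L)) {
      t <- t + 1L
      r <- ro + i; c <- co + j
      ok <- r >= 0L & r < H & c >= 0L & c < W
      idx[, t] <- ifelse(ok, r * W + c + 1L, 0L)
    }
  }
  list(idx = idx, Hin = H, Win = W, Hout = Ho, Wout = Wo, k = k)
}

conv_forward <- function(X, plan, Wt, b) {
  K2 <- ncol(plan$idx)
  Xz <- rbind(0, X)                       # row 1 = zero padding
  P <- do.call(cbind, lapply(seq_len(K2), function(t)
    Xz[plan$idx[, t] + 1L, , drop = FALSE]))
  Y <- P %*% Wt
  Y <- sweep(Y, 2L, b, "+")
  list(Y = Y, cache = list(P = P, plan = plan, Cin = ncol(X)))
}

conv_backward <- function(dY, cache, Wt) {
  plan <- cache$plan; Cin <- cache$Cin
  K2 <- ncol(plan$idx)
  dW <- crossprod(cache$P, dY)
  db <- colSums(dY)
  dP <- tcrossprod(dY, Wt)
  dXz <- matrix(0, plan$Hin * plan$Win + 1L, Cin)
  for (t in seq_len(K2)) {
    ii <- plan$idx[, t] + 1L
    cols <- ((t - 1L) * Cin + 1L):(t * Cin)
    # within one tap the map output -> input pixel is injective
    dXz[ii, ] <- dXz[ii, ] + dP[, cols, drop = FALSE]
  }
  list(dX = dXz[-1L, , drop = FALSE], dW = dW, db = db)
}

conv_init <- function(k, Cin, Cout, gain = 1) {
  fan_in <- k * k * Cin
  list(W = matrix(rnorm(k * k * Cin * Cout, sd = gain * sqrt(2 / fan_in)),
                  k * k * Cin, Cout),
       b = rep(0, Cout))
}

# ---- 2x2 average pooling ----------------------------------------------

pool2_forward <- function(X, H, W) {
  plan <- conv_plan(H, W, 2L, stride = 2L, pad = 0L)
  Xz <- rbind(0, X)
  Y <- (Xz[plan$idx[, 1] + 1L, , drop = FALSE] +
        Xz[plan$idx[, 2] + 1L, , drop = FALSE] +
        Xz[plan$idx[, 3] + 1L, , drop = FALSE] +
        Xz[plan$idx[, 4] + 1L, , drop = FALSE]) / 4
  list(Y = Y, cache = plan)
}

pool2_backward <- function(dY, plan, Cin) {
  dXz <- matrix(0, plan$Hin * plan$Win + 1L, Cin)
  for (t in 1:4) {
    ii <- plan$idx[, t] + 1L
    dXz[ii, ] <- dXz[ii, ] + dY / 4
  }
  dXz[-1L, , drop = FALSE]
}

# ---- channelwise layer normalization ----------------------------------

layernorm_forward <- function(X, g, b, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  inv <- 1 / sqrt(rowMeans(xc * xc) + eps)
  xn <- xc * inv
  Y <- sweep(xn, 2L, g, "*")
  Y <- sweep(Y, 2L, b, "+")
  list(Y = Y, cache = list(xn = xn, inv = inv, g = g))
}

layernorm_backward <- function(dY, cache) {
  xn <- cache$xn; inv <- cache$inv
  dxn <- sweep(dY, 2L, cache$g, "*")
  dX <- inv * (dxn - rowMeans(dxn) - xn * rowMeans(dxn * xn))
  list(dX = dX, dg = colSums(dY * xn), db = colSums(dY))
}

# ---- bilinear resize ---------------------------------------------------

# Half-pixel-centre bilinear sampling plan from (Hin, Win) to (Hout, Wout).
resize_plan <- function(Hin, Win, Hout, Wout) {
  memo_plan(sprintf("r%d_%d_%d_%d", Hin, Win, Hout, Wout), function()
    resize_plan_build(Hin, Win, Hout, Wout))
}

resize_plan_build <- function(Hin, Win, Hout, Wout) {
  sy <- Hin / Hout; sx <- Win / Wout
  yo <- rep(0:(Hout - 1L), each = Wout)
  xo <- rep(0:(Wout - 1L), times = Hout)
  yc <- clamp((yo + 0.5) * sy - 0.5, 0, Hin - 1)
  xc <- clamp((xo + 0.5) * sx - 0.5, 0, Win - 1)
  y0 <- floor(yc); x0 <- floor(xc)
  y1 <- pmin(y0 + 1, Hin - 1); x1 <- pmin(x0 + 1, Win - 1)
  fy <- yc - y0; fx <- xc - x0
  idx <- cbind(y0 * Win + x0, y0 * Win + x1, y1 * Win + x0, y1 * Win + x1) + 1L
  w <- cbind((1 - fy) * (1 - fx), (1 - fy) * fx, fy * (1 - fx), fy * fx)
  list(idx = idx, w = w, Hin = Hin, Win = Win, Hout = Hout, Wout = Wout)
}

resize_forward <- function(X, plan) {
  Y <- 0
  for (j in 1:4)
    Y <- Y + plan$w[, j] * X[plan$idx[, j], , drop = FALSE]
  Y
}

resize_backward <- function(dY, plan, Cin) {
  dX <- matrix(0, plan$Hin * plan$Win, Cin)
  for (j in 1:4) {
    contrib <- rowsum(dY * plan$w[, j], plan$idx[, j])
    rows <- as.integer(rownames(contrib))
    dX[rows, ] <- dX[rows, ] + contrib
  }
  dX
}

# ---- activations -------------------------------------------------------

relu_forward <- function(X) list(Y = pmax(X, 0), cache = X > 0)
relu_backward <- function(dY, cache) dY * cache

sigmoid <- function(x) plogis(x)

# ---- Adam optimizer ----------------------------------------------------

adam_init <- function(n) list(m = numeric(n), v = numeric(n), t = 0L)

adam_step <- function(theta, grad, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mh <- state$m / (1 - beta1^state$t)
  vh <- state$v / (1 - beta2^state$t)
  list(theta = theta - lr * mh / (sqrt(vh) + eps), state = state)
}
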