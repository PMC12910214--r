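# Trainable SS2D block: pre-norm residual wrapper around a selective scan
# in four directions. Delta, B and C are input-dependent (selective) via
# learned linear maps from the normalized feature; Lambda is a learned
# per-channel constant initialized to the stable -1..-N pattern.
#
#   xn    = LN(x)
#   Delta = softplus(xn %*% Wd + bd)                (shared by directions)
#   per direction k: Bk = xn_perm %*% WB[k], Ck = xn_perm %*% WC[k]
#                    yk = scan(xn_perm, Delta_perm, Lambda[k], Bk, Ck)
#   out   = Concat[y1..y4] %*% Wo + bo + Dskip * xn
#   block(x) = x + out

ssm_block_init <- function(D, N, dt_min = 1e-3, dt_max = 1e-1) {
  dirs <- c("right", "left", "down", "up")
  # softplus^{-1} of log-uniform step sizes in [dt_min, dt_max]
  dt <- exp(runif(D, log(dt_min), log(dt_max)))
  p <- list(
    ln_g = rep(1, D), ln_b = rep(0, D),
    Wd = matrix(rnorm(D * D, sd = 1 / sqrt(D)) * 0.1, D, D),
    bd = log(expm1(dt)),
    Dskip = rep(1, D),
    Wo = matrix(rnorm(4 * D * D, sd = 1 / sqrt(4 * D)), 4 * D, D),
    bo = rep(0, D)
  )
  for (k in dirs) {
    p[[paste0("WB_", k)]] <- matrix(rnorm(D * N, sd = 1 / sqrt(D)), D, N)
    p[[paste0("WC_", k)]] <- matrix(rnorm(D * N, sd = 1 / sqrt(D)), D, N)
    p[[paste0("Lam_", k)]] <- matrix(rep(-(1:N), each = D), D, N)
  }
  p
}

ssm_block_forward <- function(X, H, W, p, train = FALSE) {
  dirs <- c("right", "left", "down", "up")
  ln <- layernorm_forward(X, p$ln_g, p$ln_b)
  Xn <- ln$Y
  pre <- sweep(Xn %*% p$Wd, 2L, p$bd, "+")
  Delta <- softplus(pre)
  perms <- lapply(dirs, function(dr) scan_permutation(H, W, dr))
  names(perms) <- dirs
  ys <- vector("list", 4L); names(ys) <- dirs
  scans <- vector("list", 4L); names(scans) <- dirs
  for (k in dirs) {
    pm <- perms[[k]]
    Xs <- Xn[pm, , drop = FALSE]
    Ds <- Delta[pm, , drop = FALSE]
    Bk <- Xs %*% p[[paste0("WB_", k)]]
    Ck <- Xs %*% p[[paste0("WC_", k)]]
    sc <- scan_forward_cpp(Xs, Ds, p[[paste0("Lam_", k)]], Bk, Ck)
    inv <- integer(length(pm)); inv[pm] <- seq_along(pm)
    ys[[k]] <- sc$Y[inv, , drop = FALSE]
    if (train) scans[[k]] <- list(Xs = Xs, Ds = Ds, Bk = Bk, Ck = Ck,
                                  H = sc$H, Abar = sc$Abar, G = sc$G,
                                  perm = pm, inv = inv)
  }
  Yc <- do.call(cbind, ys)
  out <- sweep(Yc %*% p$Wo, 2L, p$bo, "+") + sweep(Xn, 2L, p$Dskip, "*")
  Y <- X + out
  cache <- if (train) list(ln = ln$cache, Xn = Xn, pre = pre, Delta = Delta,
                           Yc = Yc, scans = scans, H = H, W = W) else NULL
  list(Y = Y, cache = cache)
}

ssm_block_backward <- function(dY, cache, p) {
  dirs <- c("right", "left", "down", "up")
  Xn <- cache$Xn
  g <- list()
  # out-projection path
  dYc <- tcrossprod(dY, p$Wo)
  g$Wo <- crossprod(cache$Yc, dY)
  g$bo <- colSums(dY)
  g$Dskip <- colSums(dY * Xn)
  dXn <- sweep(dY, 2L, p$Dskip, "*")
  dDelta <- matrix(0, nrow(Xn), ncol(Xn))
  D <- ncol(Xn)
  for (i in seq_along(dirs)) {
    k <- dirs[i]
    sc <- cache$scans[[k]]
    dyk <- dYc[, ((i - 1L) * D + 1L):(i * D), drop = FALSE]
    dyk_s <- dyk[sc$perm, , drop = FALSE]
    bk <- scan_backward_cpp(sc$Xs, sc$Ds, p[[paste0("Lam_", k)]],
                            sc$Bk, sc$Ck, sc$H, sc$Abar, sc$G, dyk_s)
    g[[paste0("Lam_", k)]] <- bk$dLambda
    g[[paste0("WB_", k)]] <- crossprod(sc$Xs, bk$dB)
    g[[paste0("WC_", k)]] <- crossprod(sc$Xs, bk$dC)
    dXs <- bk$dX + tcrossprod(bk$dB, p[[paste0("WB_", k)]]) +
      tcrossprod(bk$dC, p[[paste0("WC_", k)]])
    dXn <- dXn + dXs[sc$inv, , drop = FALSE]
    dDelta <- dDelta + bk$dDelta[sc$inv, , drop = FALSE]
  }
  # Delta = softplus(Xn Wd + bd)
  dpre <- dDelta * sigmoid(cache$pre)
  g$Wd <- crossprod(Xn, dpre)
  g$bd <- colSums(dpre)
  dXn <- dXn + tcrossprod(dpre, p$Wd)
  lnb <- layernorm_backward(dXn, cache$ln)
  g$ln_g <- lnb$dg
  g$ln_b <- lnb$db
  list(dX = dY + lnb$dX, grads = g)
}
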