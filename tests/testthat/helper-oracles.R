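# Independent oracles, written before the implementations they check.

# Position-by-position unrolled selective-scan recurrence: plain nested
# loops over (t, d, n), no vectorization shared with the package code.
naive_scan <- function(X, Delta, Lambda, B, C) {
  T_len <- nrow(X); D <- ncol(X); N <- ncol(Lambda)
  Y <- matrix(0, T_len, D)
  h <- matrix(0, D, N)
  for (t in seq_len(T_len)) {
    for (d in seq_len(D)) {
      for (n in seq_len(N)) {
        dl <- Delta[t, d] * Lambda[d, n]
        a <- exp(dl)
        g <- if (abs(dl) < 1e-6) Delta[t, d] * (1 + dl / 2) else
          (exp(dl) - 1) / Lambda[d, n]
        h[d, n] <- a * h[d, n] + g * B[t, n] * X[t, d]
      }
      Y[t, d] <- sum(C[t, ] * h[d, ])
    }
  }
  Y
}

# Dense matrix-exponential discretization oracle for diagonal A:
# Abar = expm(Delta*A), Bbar = (Delta*A)^{-1} (expm(Delta*A) - I) Delta*B.
expm_discretize <- function(lambda, B, delta) {
  A <- diag(lambda, nrow = length(lambda))
  dA <- delta * A
  eA <- as.matrix(Matrix::expm(Matrix::Matrix(dA)))
  list(A_bar = diag(eA),
       B_bar = as.vector(solve(dA) %*% (eA - diag(nrow(A))) %*% (delta * B)))
}

# Naive sliding-window 2D convolution (single output channel set), zero
# padding, used to check the im2col implementation. W is (k*k*Cin) x Cout
# with tap order: row offset major, col offset minor, channels fastest.
naive_conv <- function(img, W, b, k, stride, pad) {
  H <- dim(img)[1]; Wd <- dim(img)[2]; Cin <- dim(img)[3]
  Cout <- ncol(W)
  Ho <- (H + 2 * pad - k) %/% stride + 1
  Wo <- (Wd + 2 * pad - k) %/% stride + 1
  out <- array(0, c(Ho, Wo, Cout))
  for (ro in 1:Ho) for (co in 1:Wo) {
    acc <- rep(0, Cout)
    tap <- 0
    for (i in 0:(k - 1)) for (j in 0:(k - 1)) {
      tap <- tap + 1
      r <- (ro - 1) * stride - pad + i + 1
      c <- (co - 1) * stride - pad + j + 1
      v <- if (r >= 1 && r <= H && c >= 1 && c <= Wd) img[r, c, ] else rep(0, Cin)
      rows <- ((tap - 1) * Cin + 1):(tap * Cin)
      acc <- acc + as.vector(v %*% W[rows, , drop = FALSE])
    }
    out[ro, co, ] <- acc + b
  }
  out
}

# All-pairs brute-force directed/symmetric Hausdorff percentile between the
# boundary rims of two masks (O(n^2), for small instances only).
brute_hd <- function(pred, gt, spacing = 1, percentile = 0.95) {
  rim <- function(m) {
    H <- nrow(m); W <- ncol(m)
    out <- matrix(FALSE, H, W)
    for (r in 1:H) for (c in 1:W) {
      if (m[r, c] == 1) {
        inner <- TRUE
        for (dr in -1:1) for (dc in -1:1) {
          rr <- r + dr; cc <- c + dc
          v <- if (rr >= 1 && rr <= H && cc >= 1 && cc <= W) m[rr, cc] else 0
          if (v == 0) inner <- FALSE
        }
        if (!inner) out[r, c] <- TRUE
      }
    }
    out
  }
  pa <- which(rim(pred), arr.ind = TRUE)
  ga <- which(rim(gt), arr.ind = TRUE)
  dmat <- sqrt(outer(pa[, 1], ga[, 1], "-")^2 + outer(pa[, 2], ga[, 2], "-")^2)
  pooled <- c(apply(dmat, 1, min), apply(dmat, 2, min))
  as.numeric(quantile(pooled, percentile, names = FALSE)) * spacing
}

# Random blob-like binary mask for property tests.
random_mask <- function(H, W, p = 0.3) {
  m <- matrix(as.integer(runif(H * W) < p), H, W)
  m
}

# Random disk mask with given centre/radius.
disk_mask <- function(H, W, cy, cx, r) {
  y <- matrix(rep(1:H, W), H, W); x <- matrix(rep(1:W, each = H), H, W)
  matrix(as.integer((y - cy)^2 + (x - cx)^2 <= r^2), H, W)
}

# Shared tiny dataset for pipeline tests (generated once per test run).
tiny_dataset_dir <- local({
  path <- NULL
  function() {
    if (is.null(path) || !file.exists(file.path(path, "manifest.json"))) {
      path <<- file.path(tempdir(), "lcmamba-tiny-ds")
      unlink(path, recursive = TRUE)
      generate_dataset(16, c(0.625, 0.1875, 0.1875),
                       phantom_config(seed = 11L), path)
    }
    path
  }
})
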