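# Internal helpers: tensor layout, parameter flattening, seeded RNG scopes.
#
# Feature maps cross the public API as H x W x C arrays. Internally every
# layer works on an (H*W) x C matrix whose rows follow row-major raster
# order, p = (r-1)*W + c, i.e. the "->" scanning order.

fmap_to_mat <- function(a) {
  if (length(dim(a)) == 2L) a <- array(a, c(dim(a), 1L))
  d <- dim(a)
  matrix(aperm(a, c(2L, 1L, 3L)), nrow = d[1L] * d[2L], ncol = d[3L])
}

mat_to_fmap <- function(m, H, W) {
  m <- as.matrix(m)
  aperm(array(m, c(W, H, ncol(m))), c(2L, 1L, 3L))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

logit <- function(p) log(p / (1 - p))

softplus <- function(x) ifelse(x > 20, x, log1p(exp(x)))

# Evaluate `expr` with the global RNG seeded to `seed`, restoring the
# caller's RNG state afterwards. Keeps dataset generation order-independent.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Per-item sub-seed: seed XOR item index, kept inside 32-bit range.
item_seed <- function(seed, i) bitwXor(as.integer(seed %% 2^31), as.integer(i))

# ---- flat parameter vector <-> named list of arrays --------------------

flatten_params <- function(p) unlist(p, use.names = FALSE)

param_skeleton <- function(p) {
  rapply(p, function(x) list(len = length(x), dim = dim(x)),
         how = "list")
}

unflatten_params <- function(vec, skeleton) {
  pos <- 0L
  fill <- function(sk) {
    if (!is.null(sk$len) && is.numeric(sk$len)) {
      v <- vec[(pos + 1L):(pos + sk$len)]
      pos <<- pos + as.integer(sk$len)
      if (!is.null(sk$dim)) dim(v) <- sk$dim
      v
    } else lapply(sk, fill)
  }
  fill(skeleton)
}

n_params <- function(p) length(unlist(p, use.names = FALSE))

stopifnot_finite <- function(x, what) {
  if (!all(is.finite(x))) stop(sprintf("non-finite values in %s", what), call. = FALSE)
}
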