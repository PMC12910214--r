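# Selective state-space primitives: zero-order-hold discretization, the
# linear-time scan recurrence, four-direction 2D serialization and the SS2D
# merge. These are the computational core of the network; the trainable
# block wrapper lives in ssm-block.R.

#' Construct selective state-space parameters
#'
#' Bundles the continuous-time parameters of a diagonal selective SSM:
#' per-state decay rates \eqn{\Lambda} (so \eqn{A = \mathrm{diag}(\Lambda)}),
#' the input map \eqn{B}, the output map \eqn{C} and the step size
#' \eqn{\Delta}. Each of \code{B}, \code{C} and \code{delta} may be shared
#' across sequence positions or supplied per position, which is what makes
#' the model "selective".
#'
#' @param lambda decay rates: length-\code{state_dim} vector (shared across
#'   channels) or a \code{channel_dim x state_dim} matrix. Must be finite;
#'   negative values give decaying (stable) modes.
#' @param B input map: length-\code{state_dim} vector or a
#'   \code{T x state_dim} matrix of per-position maps.
#' @param C output map, same shapes as \code{B}.
#' @param delta step size(s): positive scalar, length-\code{channel_dim}
#'   vector, or \code{T x channel_dim} matrix.
#' @param state_dim,channel_dim dimensions \eqn{N} and \eqn{D}; inferred
#'   from \code{lambda} when possible.
#' @return an object of class \code{ssm_params}.
#' @export
ssm_params <- function(lambda, B, C, delta, state_dim = NULL,
                       channel_dim = NULL) {
  if (any(!is.finite(lambda))) stop("lambda must be finite", call. = FALSE)
  if (any(delta <= 0) || any(!is.finite(delta)))
    stop("delta must be positive and finite", call. = FALSE)
  if (is.null(state_dim))
    state_dim <- if (is.matrix(lambda)) ncol(lambda) else length(lambda)
  if (is.null(channel_dim))
    channel_dim <- if (is.matrix(lambda)) nrow(lambda) else 1L
  structure(list(lambda = lambda, B = B, C = C, delta = delta,
                 state_dim = as.integer(state_dim),
                 channel_dim = as.integer(channel_dim)),
            class = "ssm_params")
}

# Expand params to the dense kernel shapes for a length-T sequence:
# Lambda D x N, Delta T x D, B and C T x N.
expand_ssm_params <- function(p, T_len) {
  N <- p$state_dim; D <- p$channel_dim
  Lambda <- if (is.matrix(p$lambda)) p$lambda else
    matrix(p$lambda, D, N, byrow = TRUE)
  Delta <- if (is.matrix(p$delta)) p$delta else
    matrix(p$delta, T_len, D, byrow = (length(p$delta) == D))
  Bm <- if (is.matrix(p$B)) p$B else matrix(p$B, T_len, N, byrow = TRUE)
  Cm <- if (is.matrix(p$C)) p$C else matrix(p$C, T_len, N, byrow = TRUE)
  list(Lambda = Lambda, Delta = Delta, B = Bm, C = Cm)
}

#' Zero-order-hold discretization of diagonal SSM parameters
#'
#' For \eqn{A = \mathrm{diag}(\Lambda)} the matrix-exponential
#' discretization \eqn{\bar A = \exp(\Delta A)},
#' \eqn{\bar B = (\Delta A)^{-1}(\exp(\Delta A) - I)\,\Delta B} reduces
#' elementwise to \eqn{\bar a = e^{\Delta\lambda}} and
#' \eqn{\bar b = \frac{e^{\Delta\lambda} - 1}{\lambda} B} (the \eqn{\Delta}
#' in \eqn{(\Delta A)^{-1}} cancels). When \eqn{|\Delta\lambda| < 10^{-6}}
#' the series limit \eqn{\bar b = \Delta B} is used, the value the formula
#' approaches as \eqn{\lambda \to 0}.
#'
#' @param params an [ssm_params] object with shared (position-independent)
#'   \code{B} and \code{delta}.
#' @return list with \code{A_bar} and \code{B_bar}, shaped like
#'   \code{lambda} (per state, or channel x state).
#' @export
discretize <- function(params) {
  stopifnot(inherits(params, "ssm_params"))
  lam <- params$lambda
  delta <- params$delta
  if (is.matrix(delta) || is.matrix(params$B))
    stop("discretize() expects shared delta and B; per-position parameters are discretized inside selective_scan()",
         call. = FALSE)
  dl <- delta * lam
  A_bar <- exp(dl)
  gain <- ifelse(abs(dl) < 1e-6, delta * (1 + dl / 2), (exp(dl) - 1) / lam)
  B_bar <- if (is.matrix(gain) && !is.matrix(params$B))
    sweep(gain, 2L, params$B, "*") else gain * params$B
  list(A_bar = A_bar, B_bar = B_bar)
}

#' Create a scan sequence
#'
#' A 1-D serialization of a feature grid: an ordered \code{T x D} matrix of
#' per-position channel vectors plus the direction and source-grid shape
#' needed to deserialize it.
#'
#' @param values \code{T x D} numeric matrix (positions in rows).
#' @param direction one of \code{"right"}, \code{"left"}, \code{"down"},
#'   \code{"up"}.
#' @param origin_shape integer \code{c(H, W)} of the source grid.
#' @return object of class \code{scan_sequence}.
#' @export
scan_sequence <- function(values, direction = "right",
                          origin_shape = c(nrow(values), 1L)) {
  values <- as.matrix(values)
  direction <- match.arg(direction, c("right", "left", "down", "up"))
  stopifnot(nrow(values) == prod(origin_shape))
  structure(list(values = values, direction = direction,
                 origin_shape = as.integer(origin_shape)),
            class = "scan_sequence")
}

# Permutation taking row-major raster order to the given scan order.
scan_permutation <- function(H, W, direction) {
  memo_plan(sprintf("p%d_%d_%s", H, W, direction), function()
    scan_permutation_build(H, W, direction))
}

scan_permutation_build <- function(H, W, direction) {
  T_len <- H * W
  switch(direction,
         right = seq_len(T_len),
         left  = rev(seq_len(T_len)),
         down  = as.vector(matrix(seq_len(T_len), nrow = H, byrow = TRUE)),
         up    = rev(as.vector(matrix(seq_len(T_len), nrow = H, byrow = TRUE))))
}

#' Serialize a feature map along the four scan directions
#'
#' Produces the four 1-D orderings used by SS2D: \code{right} is row-major
#' raster order, \code{left} its reversal, \code{down} column-major order
#' (top-to-bottom, then next column) and \code{up} its reversal. Each
#' sequence has \eqn{H \cdot W} positions and deserializes back to the grid
#' exactly.
#'
#' @param fmap \code{H x W x C} array (or \code{H x W} matrix).
#' @return named list of four [scan_sequence] objects.
#' @export
serialize_directions <- function(fmap) {
  if (is.matrix(fmap)) fmap <- array(fmap, c(dim(fmap), 1L))
  d <- dim(fmap)
  if (d[1L] < 1L || d[2L] < 1L) stop("empty grid", call. = FALSE)
  X <- fmap_to_mat(fmap)
  dirs <- c("right", "left", "down", "up")
  out <- lapply(dirs, function(dr) {
    perm <- scan_permutation(d[1L], d[2L], dr)
    scan_sequence(X[perm, , drop = FALSE], dr, d[1:2])
  })
  names(out) <- dirs
  out
}

#' Deserialize a scan sequence back to its source grid
#'
#' @param seq a [scan_sequence].
#' @return \code{H x W x C} array.
#' @export
deserialize_sequence <- function(seq) {
  stopifnot(inherits(seq, "scan_sequence"))
  H <- seq$origin_shape[1L]; W <- seq$origin_shape[2L]
  perm <- scan_permutation(H, W, seq$direction)
  X <- matrix(0, H * W, ncol(seq$values))
  X[perm, ] <- seq$values
  mat_to_fmap(X, H, W)
}

#' Run the selective scan recurrence along a sequence
#'
#' Computes \eqn{h_t = \bar A h_{t-1} + \bar B x_t}, \eqn{y_t = C h_t} with
#' \eqn{h_0 = 0}, in time linear in the sequence length. \eqn{\bar A} and
#' \eqn{\bar B} come from the zero-order-hold discretization (see
#' [discretize]); per-position \code{delta}/\code{B}/\code{C} make the
#' recurrence selective.
#'
#' @param x_seq a [scan_sequence] (or a plain \code{T x D} matrix).
#' @param params an [ssm_params] object with \code{channel_dim} equal to the
#'   number of input channels.
#' @param keep_states if \code{TRUE} the hidden-state history is attached as
#'   attribute \code{"states"} (\code{T x (D*N)}).
#' @return a [scan_sequence] of outputs with the same length and direction.
#'   Attribute \code{"steps"} records the number of recurrence steps taken
#'   (equal to the sequence length; the scan is linear-time).
#' @export
selective_scan <- function(x_seq, params, keep_states = FALSE) {
  plain <- !inherits(x_seq, "scan_sequence")
  X <- if (plain) as.matrix(x_seq) else x_seq$values
  if (nrow(X) == 0L) stop("empty sequence", call. = FALSE)
  stopifnot(inherits(params, "ssm_params"))
  if (params$channel_dim != ncol(X))
    stop(sprintf("channel mismatch: sequence has %d channels, params %d",
                 ncol(X), params$channel_dim), call. = FALSE)
  ep <- expand_ssm_params(params, nrow(X))
  res <- scan_forward_cpp(X, ep$Delta, ep$Lambda, ep$B, ep$C)
  out <- if (plain) res$Y else
    scan_sequence(res$Y, x_seq$direction, x_seq$origin_shape)
  attr(out, "steps") <- nrow(X)
  if (keep_states) attr(out, "states") <- res$H
  out
}

#' SS2D: four-direction selective scan with merge
#'
#' Serializes the feature map along the four scan directions, runs the
#' selective scan independently in each, deserializes the results, and
#' merges them by channel concatenation followed by a learned linear
#' projection back to \eqn{C} channels:
#' \eqn{Y = \mathrm{Proj}(\mathrm{Concat}[Y_\rightarrow, Y_\leftarrow,
#' Y_\downarrow, Y_\uparrow])}. Output spatial shape equals input shape.
#'
#' @param fmap \code{H x W x C} array of finite values.
#' @param params_dirs list of four [ssm_params] (order right, left, down,
#'   up), or a single \code{ssm_params} shared by all directions.
#' @param proj list with projection weights \code{W} (\code{4C x C}) and
#'   optional bias \code{b} (length \code{C}).
#' @return \code{H x W x C} array.
#' @export
ss2d_forward <- function(fmap, params_dirs, proj) {
  if (is.matrix(fmap)) fmap <- array(fmap, c(dim(fmap), 1L))
  stopifnot_finite(fmap, "fmap")
  C <- dim(fmap)[3L]
  if (inherits(params_dirs, "ssm_params"))
    params_dirs <- rep(list(params_dirs), 4L)
  stopifnot(length(params_dirs) == 4L)
  for (p in params_dirs)
    if (p$channel_dim != C)
      stop(sprintf("channel mismatch: fmap has %d channels, params %d",
                   C, p$channel_dim), call. = FALSE)
  if (nrow(proj$W) != 4L * C)
    stop("projection weight must have 4*C rows", call. = FALSE)
  seqs <- serialize_directions(fmap)
  ys <- mapply(function(s, p) {
    fmap_to_mat(deserialize_sequence(selective_scan(s, p)))
  }, seqs, params_dirs, SIMPLIFY = FALSE)
  Yc <- do.call(cbind, ys)
  Y <- Yc %*% proj$W
  if (!is.null(proj$b)) Y <- sweep(Y, 2L, proj$b, "+")
  mat_to_fmap(Y, dim(fmap)[1L], dim(fmap)[2L])
}
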