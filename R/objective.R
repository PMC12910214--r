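# Composite training objective: weighted BCE + soft Dice over the whole
# image, plus a boundary-aware Dice term evaluated on a narrow band around
# the ground-truth lesion boundary. Gradients are analytic (the training
# loop consumes total_loss_grad).

#' Loss weights for the composite objective
#'
#' @param alpha weight of the binary cross-entropy term.
#' @param beta weight of the soft Dice term.
#' @param lam weight of the boundary-aware term.
#' @param epsilon smoothing constant added to numerator and denominator of
#'   both Dice-type terms.
#' @return list of class \code{loss_weights}.
#' @export
loss_weights <- function(alpha = 1, beta = 1, lam = 0.5, epsilon = 1e-6) {
  if (any(c(alpha, beta, lam) < 0)) stop("weights must be >= 0", call. = FALSE)
  if (alpha + beta <= 0) stop("alpha + beta must be positive", call. = FALSE)
  if (epsilon <= 0) stop("epsilon must be positive", call. = FALSE)
  structure(list(alpha = alpha, beta = beta, lam = lam, epsilon = epsilon),
            class = "loss_weights")
}

check_binary <- function(mask) {
  if (!all(mask %in% c(0, 1)))
    stop("mask must be binary (0/1)", call. = FALSE)
}

#' Boundary band of a binary mask
#'
#' The inner rim (mask XOR its one-pixel morphological erosion) dilated by
#' one pixel, giving a band of about three pixels straddling the lesion
#' boundary. Computed from the ground-truth mask only. An empty mask has an
#' empty boundary set.
#'
#' @param mask binary \code{H x W} matrix.
#' @return logical \code{H x W} matrix marking boundary-band pixels.
#' @export
boundary_set <- function(mask) {
  check_binary(mask)
  if (!any(mask == 1)) return(matrix(FALSE, nrow(mask), ncol(mask)))
  k <- EBImage::makeBrush(3L, "box")
  rim <- mask == 1 & erode_zeropad(mask, k) == 0
  EBImage::dilate(rim * 1, k) > 0
}

# Erosion treating everything outside the image as background (EBImage
# replicates the border, so pad with zeros and crop).
erode_zeropad <- function(mask, k) {
  H <- nrow(mask); W <- ncol(mask)
  pad <- matrix(0, H + 2L, W + 2L)
  pad[2:(H + 1L), 2:(W + 1L)] <- mask
  EBImage::erode(pad, k)[2:(H + 1L), 2:(W + 1L)]
}

#' Boundary-aware Dice loss
#'
#' Evaluates \eqn{1 - \frac{2\sum_{i \in B} y_i \hat y_i + \epsilon}
#' {\sum_{i \in B} y_i + \sum_{i \in B} \hat y_i + \epsilon}} over the
#' boundary pixel set \eqn{B}. Zero for a perfect prediction on the band,
#' approaching one for a disjoint one; an empty band gives 0.
#'
#' @param y binary ground-truth mask. @param y_hat probability map in
#'   \eqn{[0,1]}, same shape. @param B logical matrix from [boundary_set].
#' @param eps smoothing constant, > 0.
#' @return scalar loss in \eqn{[0, 1]}.
#' @export
boundary_loss <- function(y, y_hat, B = boundary_set(y), eps = 1e-6) {
  stopifnot(all(dim(y) == dim(y_hat)), eps > 0)
  yb <- y[B]; pb <- y_hat[B]
  1 - (2 * sum(yb * pb) + eps) / (sum(yb) + sum(pb) + eps)
}

soft_dice_loss <- function(y, y_hat, eps) {
  1 - (2 * sum(y * y_hat) + eps) / (sum(y) + sum(y_hat) + eps)
}

bce_loss <- function(y, y_hat, clampv = 1e-7) {
  p <- clamp(y_hat, clampv, 1 - clampv)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Composite segmentation loss
#'
#' \eqn{L = \alpha L_{BCE} + \beta L_{Dice} + \lambda L_{Boundary}}: BCE
#' and soft Dice over all pixels address overlap and class imbalance, the
#' boundary term sharpens the lesion rim. All terms use the same
#' \eqn{\epsilon} smoothing; probabilities are clamped inside BCE.
#'
#' @param y binary mask. @param y_hat probability map in \eqn{[0,1]}.
#' @param w a [loss_weights] object.
#' @param B optional precomputed boundary set (recomputed from \code{y}
#'   otherwise).
#' @return scalar loss \eqn{\ge 0}; attribute \code{"components"} carries
#'   the unweighted BCE/Dice/boundary values.
#' @export
total_loss <- function(y, y_hat, w = loss_weights(), B = NULL) {
  check_binary(y)
  if (is.null(B)) B <- boundary_set(y)
  comp <- c(bce = bce_loss(y, y_hat),
            dice = soft_dice_loss(y, y_hat, w$epsilon),
            boundary = boundary_loss(y, y_hat, B, w$epsilon))
  structure(w$alpha * comp[["bce"]] + w$beta * comp[["dice"]] +
              w$lam * comp[["boundary"]],
            components = comp)
}

# Analytic gradient of total_loss w.r.t. y_hat (same shape as y_hat).
total_loss_grad <- function(y, y_hat, w = loss_weights(), B = NULL) {
  if (is.null(B)) B <- boundary_set(y)
  clampv <- 1e-7
  p <- clamp(y_hat, clampv, 1 - clampv)
  g_bce <- (p - y) / (p * (1 - p)) / length(y)
  g_bce[y_hat <= clampv | y_hat >= 1 - clampv] <- 0
  num <- 2 * sum(y * y_hat) + w$epsilon
  den <- sum(y) + sum(y_hat) + w$epsilon
  g_dice <- (num - 2 * y * den) / den^2
  g_bnd <- y_hat * 0
  if (any(B)) {
    yb <- y[B]; pb <- y_hat[B]
    numB <- 2 * sum(yb * pb) + w$epsilon
    denB <- sum(yb) + sum(pb) + w$epsilon
    g_bnd[B] <- (numB - 2 * yb * denB) / denB^2
  }
  w$alpha * g_bce + w$beta * g_dice + w$lam * g_bnd
}
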