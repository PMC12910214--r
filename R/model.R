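# Model assembly: hierarchical SS2D encoder + LCAM decoder, with full
# forward and backward passes. Parameters live in a named nested list so
# they can be flattened into a single vector for the optimizer.

#' Variant configuration for the segmentation network
#'
#' Three presets are provided. \code{"T"} (tiny) and \code{"S"} (small) are
#' the deployment-scale variants: stem stride 4, stage channels
#' (96, 192, 384, 768), depths (2,2,4,2) for T and (2,2,8,2) plus one extra
#' SS2D block in the deepest stage for S (the \eqn{N = 1} configuration).
#' \code{"nano"} is a CPU-scale preset (stem stride 2, channels
#' (8, 16, 32, 64), depths (1,1,2,1)) used for tests and end-to-end training
#' demonstrations.
#'
#' @param name \code{"T"}, \code{"S"} or \code{"nano"}.
#' @return a list with fields \code{name}, \code{stem_stride},
#'   \code{channels}, \code{depths}, \code{state_dim}, \code{extra_blocks}
#'   and \code{gamma} (boundary-gradient weight of the attention map).
#' @export
variant_config <- function(name = c("nano", "T", "S")) {
  name <- match.arg(name)
  cfg <- switch(name,
    "T" = list(stem_stride = 4L, channels = c(96L, 192L, 384L, 768L),
               depths = c(2L, 2L, 4L, 2L), state_dim = 8L, extra_blocks = 0L),
    "S" = list(stem_stride = 4L, channels = c(96L, 192L, 384L, 768L),
               depths = c(2L, 2L, 8L, 2L), state_dim = 8L, extra_blocks = 1L),
    "nano" = list(stem_stride = 2L, channels = c(8L, 16L, 32L, 64L),
                  depths = c(1L, 1L, 2L, 1L), state_dim = 4L,
                  extra_blocks = 0L))
  cfg$name <- name
  cfg$gamma <- 0.5
  cfg$divisor <- cfg$stem_stride * 8L   # four stages halve three more times
  cfg
}

#' Dominant-term complexity estimate
#'
#' The operation count of the selective-scan architecture scales as
#' \eqn{O(HW) \cdot O(C^2) \cdot O(N)}: linear in pixel count, quadratic in
#' the maximum channel width, linear in the number of SSM blocks.
#'
#' @param H,W image dimensions. @param C maximum channel width.
#' @param N total number of SSM blocks.
#' @return the product \code{H * W * C^2 * N}.
#' @export
complexity_estimate <- function(H, W, C, N) {
  if (any(c(H, W, C, N) <= 0)) stop("all dimensions must be positive", call. = FALSE)
  H * W * C^2 * N
}

#' Instantiate a segmentation model
#'
#' Builds the full encoder-decoder with randomly initialized weights.
#' \eqn{\Lambda} is initialized to the stable \eqn{-1..-N} pattern, step
#' sizes to \eqn{[10^{-3}, 10^{-1}]} through a softplus parameterization,
#' convolutions with He-scaled Gaussians.
#'
#' @param variant \code{"T"}, \code{"S"}, \code{"nano"}, or a config list
#'   from [variant_config].
#' @param seed integer seed for weight initialization.
#' @param gamma boundary-gradient weight of the LCAM attention map.
#' @return object of class \code{lcmamba_model}: list with \code{params}
#'   (named nested list of arrays) and \code{cfg}.
#' @export
lcmamba_model <- function(variant = "nano", seed = 3407, gamma = NULL) {
  cfg <- if (is.list(variant)) variant else variant_config(variant)
  if (!is.null(gamma)) cfg$gamma <- gamma
  ch <- cfg$channels; N <- cfg$state_dim
  depths <- cfg$depths
  if (cfg$extra_blocks > 0L)
    depths[4L] <- depths[4L] + cfg$extra_blocks
  dec_ch <- pmax(ch %/% 2L, 4L)
  params <- with_seed(seed, {
    p <- list(stem = conv_init(3L, 3L, ch[1L]))
    p$stages <- lapply(1:4, function(i) {
      st <- list(blocks = lapply(seq_len(depths[i]), function(j)
        ssm_block_init(ch[i], N)))
      if (i < 4L) st$down <- conv_init(2L, ch[i], ch[i + 1L])
      st
    })
    # prediction heads start at the foreground prior (~10% of pixels are
    # lesion) instead of 0.5, avoiding an all-background collapse phase
    prior_bias <- -2.2
    p5 <- conv_init(1L, ch[4L], 1L); p5$b[] <- prior_bias
    p$decoder <- list(
      p5 = p5,
      levels = lapply(1:4, function(i) {
        hd <- conv_init(1L, dec_ch[i], 1L)
        list(delta = conv_init(3L, ch[i], dec_ch[i]),
             dln_g = rep(1, dec_ch[i]), dln_b = rep(0, dec_ch[i]),
             head = hd)
      })
    )
    p
  })
  cfg$depths_eff <- depths
  cfg$dec_channels <- dec_ch
  structure(list(params = params, cfg = cfg), class = "lcmamba_model")
}

check_input_dims <- function(H, W, cfg) {
  d <- cfg$divisor
  if (H %% d != 0L || W %% d != 0L)
    stop(sprintf("input dimensions must be divisible by %d (got %dx%d)",
                 d, H, W), call. = FALSE)
}

# Replicate grayscale to 3 channels; accept H x W or H x W x {1,3}.
as_input_array <- function(image) {
  if (is.matrix(image)) image <- array(image, c(dim(image), 1L))
  d <- dim(image)
  if (d[3L] == 1L) image <- array(rep(image, 3L), c(d[1L], d[2L], 3L))
  else if (d[3L] != 3L)
    stop(sprintf("expected 1 or 3 channels, got %d", d[3L]), call. = FALSE)
  image
}

# ---- encoder -----------------------------------------------------------

encoder_forward <- function(model, Xm, H, W, train = FALSE) {
  p <- model$params; cfg <- model$cfg
  s <- cfg$stem_stride
  stem_plan <- conv_plan(H, W, 3L, stride = s, pad = 1L)
  st <- conv_forward(Xm, stem_plan, p$stem$W, p$stem$b)
  X <- st$Y; Hc <- stem_plan$Hout; Wc <- stem_plan$Wout
  feats <- vector("list", 4L)
  caches <- list(stem = if (train) st$cache, stages = vector("list", 4L))
  for (i in 1:4) {
    bc <- vector("list", length(p$stages[[i]]$blocks))
    for (j in seq_along(p$stages[[i]]$blocks)) {
      bf <- ssm_block_forward(X, Hc, Wc, p$stages[[i]]$blocks[[j]], train)
      X <- bf$Y
      if (train) bc[[j]] <- bf$cache
    }
    feats[[i]] <- list(X = X, H = Hc, W = Wc)
    stg <- list(blocks = bc)
    if (i < 4L) {
      dpl <- conv_plan(Hc, Wc, 2L, stride = 2L, pad = 0L)
      dn <- conv_forward(X, dpl, p$stages[[i]]$down$W, p$stages[[i]]$down$b)
      X <- dn$Y; Hc <- dpl$Hout; Wc <- dpl$Wout
      if (train) stg$down <- dn$cache
    }
    if (train) caches$stages[[i]] <- stg
  }
  list(feats = feats, caches = if (train) caches)
}

encoder_backward <- function(model, caches, dfeats) {
  p <- model$params
  g <- list(stem = NULL, stages = vector("list", 4L))
  dX <- dfeats[[4L]]
  for (i in 4:1) {
    stg <- caches$stages[[i]]
    gst <- list(blocks = vector("list", length(p$stages[[i]]$blocks)))
    if (i < 4L) {
      # dX currently sits after stage i's downsample (input of stage i+1)
      cb <- conv_backward(dX, stg$down, p$stages[[i]]$down$W)
      gst$down <- list(W = cb$dW, b = cb$db)
      dX <- cb$dX + dfeats[[i]]
    }
    for (j in rev(seq_along(stg$blocks))) {
      bb <- ssm_block_backward(dX, stg$blocks[[j]], p$stages[[i]]$blocks[[j]])
      dX <- bb$dX
      gst$blocks[[j]] <- bb$grads
    }
    g$stages[[i]] <- gst
  }
  sb <- conv_backward(dX, caches$stem, p$stem$W)
  g$stem <- list(W = sb$dW, b = sb$db)
  g
}

# ---- LCAM decoder ------------------------------------------------------

# Gradient magnitude by central differences with edge replication, on a
# row-major vector over an H x W grid.
gradmag_rowmajor <- function(P, H, W) {
  Mt <- matrix(P, W, H)                 # Mt[c, r]
  if (W > 1L) {
    dx <- (rbind(Mt[-1L, , drop = FALSE], Mt[W, , drop = FALSE]) -
           rbind(Mt[1L, , drop = FALSE], Mt[-W, , drop = FALSE])) / 2
  } else dx <- Mt * 0
  if (H > 1L) {
    dy <- (cbind(Mt[, -1L, drop = FALSE], Mt[, H, drop = FALSE]) -
           cbind(Mt[, 1L, drop = FALSE], Mt[, -H, drop = FALSE])) / 2
  } else dy <- Mt * 0
  as.vector(sqrt(dx^2 + dy^2))
}

#' Reverse-attention map
#'
#' Computes \eqn{\Theta(P) = 1 - P + \gamma\,|\nabla P|}: high where the
#' current prediction is uncertain or absent, boosted along prediction
#' boundaries. \eqn{|\nabla P|} is the gradient magnitude by central
#' differences with edge replication. With \eqn{\gamma = 0} the map is the
#' pure reverse attention \eqn{1 - P \in [0, 1]}; positive \eqn{\gamma} can
#' push boundary values above 1.
#'
#' @param P probability map: \code{H x W} matrix (or vector with
#'   \code{dims}) with values in \eqn{[0, 1]}.
#' @param gamma boundary-gradient weight, \eqn{\ge 0}.
#' @param dims optional \code{c(H, W)} when \code{P} is a vector.
#' @return attention map, same shape as \code{P}.
#' @export
attention_map <- function(P, gamma = 0.5, dims = dim(P)) {
  if (gamma < 0) stop("gamma must be >= 0", call. = FALSE)
  if (any(P < 0 | P > 1))
    stop("P must lie in [0,1]; apply the sigmoid activation upstream", call. = FALSE)
  pm <- is.matrix(P)
  v <- if (pm) fmap_to_mat(P)[, 1L] else as.numeric(P)
  A <- 1 - v + gamma * gradmag_rowmajor(v, dims[1L], dims[2L])
  if (pm) matrix(A, dims[1L], dims[2L], byrow = TRUE) else A
}

decoder_forward <- function(model, feats, train = FALSE) {
  p <- model$params$decoder; cfg <- model$cfg
  eps <- 1e-4
  f4 <- feats[[4L]]
  pooled <- f4$H >= 2L && f4$W >= 2L
  pl <- if (pooled) pool2_forward(f4$X, f4$H, f4$W) else
    list(Y = f4$X, cache = NULL)
  H5 <- if (pooled) f4$H %/% 2L else f4$H
  W5 <- if (pooled) f4$W %/% 2L else f4$W
  plan5 <- conv_plan(H5, W5, 1L, 1L, 0L)
  hc <- conv_forward(pl$Y, plan5, p$p5$W, p$p5$b)
  P5 <- sigmoid(hc$Y[, 1L])
  pyr <- list(list(P = P5, H = H5, W = W5))
  lev_caches <- vector("list", 4L)
  P_next <- P5; Hn <- H5; Wn <- W5
  for (i in 4:1) {
    f <- feats[[i]]; lp <- p$levels[[i]]
    rp <- resize_plan(Hn, Wn, f$H, f$W)
    Pu <- resize_forward(matrix(P_next, ncol = 1L), rp)[, 1L]
    Puc <- clamp(Pu, eps, 1 - eps)
    q <- logit(Puc)
    A <- 1 - Pu + cfg$gamma * gradmag_rowmajor(Pu, f$H, f$W)
    if (isTRUE(cfg$lcam_off)) A <- rep(1, length(A))   # ablation switch
    dpl <- conv_plan(f$H, f$W, 3L, 1L, 1L)
    dc <- conv_forward(f$X, dpl, lp$delta$W, lp$delta$b)
    dl <- layernorm_forward(dc$Y, lp$dln_g, lp$dln_b)
    rl <- relu_forward(dl$Y)
    R <- rl$Y * A
    hpl <- conv_plan(f$H, f$W, 1L, 1L, 0L)
    hd <- conv_forward(R, hpl, lp$head$W, lp$head$b)
    z <- hd$Y[, 1L] + q
    P <- sigmoid(z)
    pyr[[length(pyr) + 1L]] <- list(P = P, H = f$H, W = f$W)
    if (train)
      lev_caches[[i]] <- list(rp = rp, Pu = Pu, Puc = Puc, A = A,
                              dconv = dc$cache, dln = dl$cache,
                              relu = rl$cache, Fd = rl$Y, R = R,
                              hconv = hd$cache, P = P, eps = eps)
    P_next <- P; Hn <- f$H; Wn <- f$W
  }
  names(pyr) <- paste0("P", 5:1)
  list(pyramid = pyr,
       caches = if (train) list(pool = pl$cache, pooled = pooled,
                                p5conv = hc$cache,
                                P5 = P5, levels = lev_caches,
                                f4dim = c(f4$H, f4$W)))
}

# dP: list of upstream gradients w.r.t. the probability maps P5..P1 (same
# order/names as the forward pyramid). The attention map is treated as a
# constant (stop-gradient); the prior path and feature path carry gradients.
decoder_backward <- function(model, feats, caches, dP) {
  p <- model$params$decoder
  g <- list(p5 = NULL, levels = vector("list", 4L))
  dfeats <- lapply(feats, function(f) matrix(0, nrow(f$X), ncol(f$X)))
  carry <- dP[["P1"]]
  for (i in 1:4) {
    lc <- caches$levels[[i]]; lp <- p$levels[[i]]
    f <- feats[[i]]
    dPi <- carry
    dz <- dPi * lc$P * (1 - lc$P)
    # head conv
    hb <- conv_backward(matrix(dz, ncol = 1L), lc$hconv, lp$head$W)
    g$levels[[i]]$head <- list(W = hb$dW, b = hb$db)
    dR <- hb$dX
    dFd <- dR * lc$A
    dRel <- relu_backward(dFd, lc$relu)
    lnb <- layernorm_backward(dRel, lc$dln)
    g$levels[[i]]$dln_g <- lnb$dg
    g$levels[[i]]$dln_b <- lnb$db
    cb <- conv_backward(lnb$dX, lc$dconv, lp$delta$W)
    g$levels[[i]]$delta <- list(W = cb$dW, b = cb$db)
    dfeats[[i]] <- dfeats[[i]] + cb$dX
    # prior path: q = logit(clamp(Pu))
    open <- lc$Pu > lc$eps & lc$Pu < 1 - lc$eps
    dPu <- ifelse(open, dz / (lc$Puc * (1 - lc$Puc)), 0)
    dPnext <- resize_backward(matrix(dPu, ncol = 1L), lc$rp, 1L)[, 1L]
    nm <- paste0("P", i + 1L)
    carry <- dPnext + if (!is.null(dP[[nm]])) dP[[nm]] else 0
  }
  # P5 head on pooled f4
  dP5 <- carry
  dz5 <- dP5 * caches$P5 * (1 - caches$P5)
  hb <- conv_backward(matrix(dz5, ncol = 1L), caches$p5conv, p$p5$W)
  g$p5 <- list(W = hb$dW, b = hb$db)
  dpool <- if (caches$pooled)
    pool2_backward(hb$dX, caches$pool, ncol(feats[[4L]]$X)) else hb$dX
  dfeats[[4L]] <- dfeats[[4L]] + dpool
  list(dfeats = dfeats, grads = g)
}

# ---- full model --------------------------------------------------------

model_forward <- function(model, image, train = FALSE) {
  img <- as_input_array(image)
  H <- dim(img)[1L]; W <- dim(img)[2L]
  check_input_dims(H, W, model$cfg)
  Xm <- fmap_to_mat(img)
  enc <- encoder_forward(model, Xm, H, W, train)
  dec <- decoder_forward(model, enc$feats, train)
  P1 <- dec$pyramid$P1
  fp <- resize_plan(P1$H, P1$W, H, W)
  prob <- matrix(resize_forward(matrix(P1$P, ncol = 1L), fp)[, 1L],
                 H, W, byrow = TRUE)
  list(prob = prob, pyramid = dec$pyramid, H = H, W = W,
       final_plan = fp, feats = enc$feats,
       caches = if (train) list(enc = enc$caches, dec = dec$caches))
}

# dP_full: list of gradients w.r.t. each pyramid level's probability map
# after upsampling to full resolution (deep supervision); entries are
# row-major vectors of length H*W, named P5..P1.
model_backward <- function(model, fwd, dP_full) {
  pyr <- fwd$pyramid
  dP <- list()
  for (nm in names(pyr)) {
    lev <- pyr[[nm]]
    rp <- resize_plan(lev$H, lev$W, fwd$H, fwd$W)
    dP[[nm]] <- resize_backward(matrix(dP_full[[nm]], ncol = 1L), rp, 1L)[, 1L]
  }
  dec <- decoder_backward(model, fwd$feats, fwd$caches$dec, dP)
  g_enc <- encoder_backward(model, fwd$caches$enc, dec$dfeats)
  list(stem = g_enc$stem, stages = g_enc$stages, decoder = dec$grads)
}

#' Encode an image slice into the four-stage feature hierarchy
#'
#' Runs the stem embedding and the four encoder stages. Spatial dimensions
#' halve at every stage transition while channel widths increase; with stem
#' stride 4 the deepest map is at stride 32 relative to the input.
#'
#' @param model an [lcmamba_model].
#' @param image \code{H x W} (grayscale, replicated to 3 channels) or
#'   \code{H x W x 3} array; dimensions must be divisible by the variant's
#'   overall stride.
#' @return list of four \code{H_i x W_i x C_i} feature arrays.
#' @export
encode <- function(model, image) {
  img <- as_input_array(image)
  H <- dim(img)[1L]; W <- dim(img)[2L]
  check_input_dims(H, W, model$cfg)
  enc <- encoder_forward(model, fmap_to_mat(img), H, W, FALSE)
  lapply(enc$feats, function(f) mat_to_fmap(f$X, f$H, f$W))
}

#' Stem embedding
#'
#' The initial 3x3 convolutional embedding that maps the input slice to the
#' stage-0 feature map at the configured stem stride.
#'
#' @inheritParams encode
#' @return \code{H/s x W/s x C_1} feature array.
#' @export
stem <- function(model, image) {
  img <- as_input_array(image)
  H <- dim(img)[1L]; W <- dim(img)[2L]
  check_input_dims(H, W, model$cfg)
  pl <- conv_plan(H, W, 3L, stride = model$cfg$stem_stride, pad = 1L)
  out <- conv_forward(fmap_to_mat(img), pl, model$params$stem$W,
                      model$params$stem$b)
  mat_to_fmap(out$Y, pl$Hout, pl$Wout)
}

#' Decode encoder features into a probability map
#'
#' Builds the coarse-to-fine prediction pyramid: an initial prediction from
#' the deepest features, then LCAM refinement at each level (reverse
#' attention modulating encoder features, with the coarser prediction as a
#' logit-space prior), and finally bilinear upsampling to the input grid.
#'
#' @param model an [lcmamba_model].
#' @param image input slice (see [encode]).
#' @return list with \code{prob} (\code{H x W} matrix in \eqn{[0,1]}) and
#'   \code{pyramid} (per-level probability maps, coarsest first).
#' @export
decode <- function(model, image) {
  fwd <- model_forward(model, image, train = FALSE)
  pyr <- lapply(fwd$pyramid, function(l)
    matrix(l$P, l$H, l$W, byrow = TRUE))
  list(prob = fwd$prob, pyramid = pyr)
}

#' One LCAM refinement step
#'
#' Applies the Liver Cancer Attention Module at a single level: upsamples
#' the coarser prediction, derives the reverse-attention map
#' \eqn{A = \Theta(\mathrm{Up}(P_{next}))}, modulates transformed encoder
#' features \eqn{R = A \odot \delta(f)}, and combines the refinement logits
#' with the upsampled prior in logit space.
#'
#' @param model an [lcmamba_model]. @param level decoder level 1-4.
#' @param f encoder feature array \code{H x W x C_level}.
#' @param P_next coarser probability map (\code{H/2 x W/2} matrix).
#' @return list with \code{R} (modulated features), \code{P} (refined
#'   probability map) and \code{A} (attention map).
#' @export
lcam_refine <- function(model, level, f, P_next) {
  lp <- model$params$decoder$levels[[level]]
  Hf <- dim(f)[1L]; Wf <- dim(f)[2L]
  if (!all(dim(P_next) * 2L == c(Hf, Wf)))
    stop("P_next must be at half the resolution of f", call. = FALSE)
  eps <- 1e-4
  rp <- resize_plan(nrow(P_next), ncol(P_next), Hf, Wf)
  Pu <- resize_forward(matrix(fmap_to_mat(P_next)[, 1L], ncol = 1L), rp)[, 1L]
  A <- 1 - Pu + model$cfg$gamma * gradmag_rowmajor(Pu, Hf, Wf)
  dpl <- conv_plan(Hf, Wf, 3L, 1L, 1L)
  dc <- conv_forward(fmap_to_mat(f), dpl, lp$delta$W, lp$delta$b)
  dl <- layernorm_forward(dc$Y, lp$dln_g, lp$dln_b)
  Fd <- pmax(dl$Y, 0)
  R <- Fd * A
  hd <- conv_forward(R, conv_plan(Hf, Wf, 1L, 1L, 0L), lp$head$W, lp$head$b)
  z <- hd$Y[, 1L] + logit(clamp(Pu, eps, 1 - eps))
  list(R = mat_to_fmap(R, Hf, Wf),
       P = matrix(sigmoid(z), Hf, Wf, byrow = TRUE),
       A = matrix(A, Hf, Wf, byrow = TRUE))
}

#' Segment new image slices
#'
#' Deterministic eval-mode forward pass; probabilities are thresholded with
#' ties going to foreground.
#'
#' @param object an [lcmamba_model].
#' @param images a single \code{H x W(x3)} array or a list of them.
#' @param threshold probability threshold (default 0.5); pixels with
#'   probability \eqn{\ge} threshold become foreground.
#' @param ... unused.
#' @return for a single image, list with \code{prob} and \code{mask};
#'   otherwise a list of such lists.
#' @export
predict.lcmamba_model <- function(object, images, threshold = 0.5, ...) {
  one <- function(img) {
    fwd <- model_forward(object, img, train = FALSE)
    list(prob = fwd$prob,
         mask = matrix(as.integer(fwd$prob >= threshold),
                       nrow(fwd$prob), ncol(fwd$prob)))
  }
  if (is.list(images)) lapply(images, one) else one(images)
}
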