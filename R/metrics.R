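# Evaluation suite: overlap metrics, HD95 via exact Euclidean distance
# transforms, lesion-size stratification, mean/SD/CI aggregation, paired
# Wilcoxon tests with Holm-Bonferroni correction, and the parameter/FLOP
# profiler.
#
# Empty-mask conventions (logged in every report): prediction and ground
# truth both empty -> dice = miou = recall = precision = f2 = 1, hd95 = 0;
# exactly one empty -> dice (and friends) = 0 and hd95 = image diagonal
# times spacing (a finite penalty).

#' Overlap metrics between a predicted and a ground-truth mask
#'
#' Dice \eqn{2|P \cap G| / (|P| + |G|)}, mean IoU (average of foreground
#' and background IoU), recall, precision and the recall-weighted F2 score
#' \eqn{5 \cdot prec \cdot rec / (4\,prec + rec)}.
#'
#' @param pred,gt binary matrices of equal shape.
#' @return named numeric vector \code{dice, miou, iou_fg, recall,
#'   precision, f2}, all in \eqn{[0, 1]}.
#' @export
overlap_metrics <- function(pred, gt) {
  if (!all(dim(pred) == dim(gt))) stop("shape mismatch", call. = FALSE)
  check_binary(pred); check_binary(gt)
  np <- sum(pred); ng <- sum(gt); ni <- sum(pred * gt)
  if (np == 0 && ng == 0)
    return(c(dice = 1, miou = 1, iou_fg = 1, recall = 1, precision = 1, f2 = 1))
  dice <- if (np + ng > 0) 2 * ni / (np + ng) else 1
  iou_fg <- if (np + ng - ni > 0) ni / (np + ng - ni) else 1
  nbg_i <- sum((1 - pred) * (1 - gt))
  nbg_u <- length(pred) - ni
  iou_bg <- if (nbg_u > 0) nbg_i / nbg_u else 1
  recall <- if (ng > 0) ni / ng else 0
  precision <- if (np > 0) ni / np else 0
  f2 <- if (4 * precision + recall > 0)
    5 * precision * recall / (4 * precision + recall) else 0
  c(dice = dice, miou = (iou_fg + iou_bg) / 2, iou_fg = iou_fg,
    recall = recall, precision = precision, f2 = f2)
}

# One-pixel boundary rim: mask XOR its erosion (outside-image treated as
# background).
mask_rim <- function(mask) {
  if (!any(mask == 1)) return(matrix(FALSE, nrow(mask), ncol(mask)))
  mask == 1 & erode_zeropad(mask, EBImage::makeBrush(3L, "box")) == 0
}

#' 95th-percentile Hausdorff distance
#'
#' Pools the nearest boundary-to-boundary distances in both directions
#' (prediction to ground truth and back) and returns their 95th percentile
#' in millimetres. Boundaries are the one-pixel rims (mask XOR erosion);
#' distances come from an exact Euclidean distance transform. With
#' \code{percentile = 1} this is the classical (maximum) Hausdorff
#' distance.
#'
#' @param pred,gt binary matrices of equal shape.
#' @param spacing_mm isotropic pixel spacing in mm.
#' @param percentile quantile of the pooled distances (default 0.95).
#' @return distance in mm; 0 for identical masks, image diagonal times
#'   spacing when exactly one mask is empty.
#' @export
hd95 <- function(pred, gt, spacing_mm = 1, percentile = 0.95) {
  if (!all(dim(pred) == dim(gt))) stop("shape mismatch", call. = FALSE)
  stopifnot(spacing_mm > 0)
  ep <- !any(pred == 1); eg <- !any(gt == 1)
  if (ep && eg) return(0)
  if (ep || eg) return(sqrt(sum(dim(pred)^2)) * spacing_mm)
  rp <- mask_rim(pred); rg <- mask_rim(gt)
  # distance of every pixel to the nearest rim pixel
  d_to_p <- EBImage::distmap(1 - rp)
  d_to_g <- EBImage::distmap(1 - rg)
  pooled <- c(d_to_g[rp], d_to_p[rg])
  as.numeric(quantile(pooled, percentile, names = FALSE)) * spacing_mm
}

#' Lesion-size stratification of a ground-truth mask
#'
#' Labels 8-connected components, converts each component's area to an
#' equivalent circular diameter \eqn{2\sqrt{area/\pi} \cdot spacing} in mm,
#' and assigns the clinical size class: Small (< 20 mm), Medium (20-50 mm,
#' both ends included), Large (> 50 mm).
#'
#' @param gt binary matrix. @param spacing_mm pixel spacing in mm.
#' @return data frame with one row per lesion: \code{component_id},
#'   \code{area_px}, \code{equiv_diameter_mm}, \code{size_class}.
#' @export
stratify_lesions <- function(gt, spacing_mm = 1) {
  check_binary(gt)
  stopifnot(spacing_mm > 0)
  lab <- label8_cpp(matrix(as.integer(gt), nrow(gt), ncol(gt)))
  k <- max(lab)
  if (k == 0L)
    return(data.frame(component_id = integer(), area_px = integer(),
                      equiv_diameter_mm = numeric(),
                      size_class = character(), stringsAsFactors = FALSE))
  area <- tabulate(lab[lab > 0L], nbins = k)
  d <- 2 * sqrt(area / pi) * spacing_mm
  cls <- ifelse(d < 20, "Small", ifelse(d <= 50, "Medium", "Large"))
  data.frame(component_id = seq_len(k), area_px = area,
             equiv_diameter_mm = d, size_class = cls,
             stringsAsFactors = FALSE)
}

#' Aggregate per-case scores
#'
#' Sample mean, sample SD (n-1 denominator) and a 95% confidence interval
#' for the mean. The default CI is Student-t,
#' \eqn{\bar x \pm t_{0.975, n-1}\, s/\sqrt n}; a bootstrap percentile CI
#' is available. A single case gives SD 0 and a degenerate CI at the mean.
#'
#' @param scores nonempty numeric vector of per-case scores.
#' @param ci \code{"t"} or \code{"bootstrap"}.
#' @param n_boot bootstrap replicates when \code{ci = "bootstrap"}.
#' @return named vector \code{mean, sd, ci95_low, ci95_high, n}.
#' @export
aggregate_stats <- function(scores, ci = c("t", "bootstrap"), n_boot = 2000L) {
  if (length(scores) == 0L) stop("empty score list", call. = FALSE)
  ci <- match.arg(ci)
  n <- length(scores)
  m <- mean(scores)
  s <- if (n > 1L) sd(scores) else 0
  if (n == 1L) {
    lo <- hi <- m
  } else if (ci == "t") {
    half <- qt(0.975, n - 1L) * s / sqrt(n)
    lo <- m - half; hi <- m + half
  } else {
    bm <- replicate(n_boot, mean(sample(scores, n, replace = TRUE)))
    qs <- quantile(bm, c(0.025, 0.975), names = FALSE)
    lo <- qs[1L]; hi <- qs[2L]
  }
  c(mean = m, sd = s, ci95_low = lo, ci95_high = hi, n = n)
}

#' Paired model comparison with family-wise error control
#'
#' Runs a two-sided paired Wilcoxon signed-rank test for each pair of
#' per-case score vectors (exact when sample size and ties allow, normal
#' approximation otherwise; zero differences are dropped per the standard
#' convention) and applies the Holm step-down adjustment across the family.
#'
#' @param pairs named list; each element is a list with components \code{a}
#'   and \code{b}, equal-length per-case score vectors paired by case.
#' @return data frame with \code{comparison}, \code{n}, \code{p_raw},
#'   \code{p_holm}, \code{significant} (at the 0.05 level).
#' @export
compare_paired <- function(pairs) {
  if (!is.null(names(pairs)) && all(c("a", "b") %in% names(pairs)))
    pairs <- list(comparison = pairs)
  raw <- vapply(pairs, function(pr) {
    stopifnot(length(pr$a) == length(pr$b))
    d <- pr$a - pr$b
    if (all(d == 0)) {
      message("all paired differences are zero; p set to 1")
      return(1)
    }
    suppressWarnings(wilcox.test(pr$a, pr$b, paired = TRUE))$p.value
  }, numeric(1))
  adj <- p.adjust(raw, method = "holm")
  data.frame(comparison = if (is.null(names(pairs)))
               paste0("pair", seq_along(pairs)) else names(pairs),
             n = vapply(pairs, function(pr) length(pr$a), integer(1)),
             p_raw = raw, p_holm = adj, significant = adj < 0.05,
             row.names = NULL, stringsAsFactors = FALSE)
}

# ---- efficiency profiling ----------------------------------------------

# Analytic multiply-accumulate count of one forward pass. Convention:
# 1 MAC = 1 FLOP; elementwise transcendentals count as one operation each.
flops_estimate <- function(cfg, H, W) {
  s <- cfg$stem_stride
  ch <- cfg$channels; N <- cfg$state_dim
  depths <- if (!is.null(cfg$depths_eff)) cfg$depths_eff else {
    d <- cfg$depths; d[4L] <- d[4L] + cfg$extra_blocks; d
  }
  dec_ch <- if (!is.null(cfg$dec_channels)) cfg$dec_channels else
    pmax(ch %/% 2L, 4L)
  Hc <- H %/% s; Wc <- W %/% s
  total <- (H %/% s) * (W %/% s) * 9 * 3 * ch[1L]      # stem
  Hs <- integer(4); Ws <- integer(4)
  for (i in 1:4) {
    Hs[i] <- Hc; Ws[i] <- Wc
    T <- Hc * Wc; D <- ch[i]
    per_block <- T * (2 * D +            # layer norm
                      D * D + D +        # delta map + softplus
                      4 * (2 * D * N) +  # B and C maps, four directions
                      4 * (6 * D * N) +  # scan recurrence
                      4 * D * D + D +    # merge projection + skip
                      2 * D)             # bias add + residual
    total <- total + depths[i] * per_block
    if (i < 4L) {
      total <- total + (Hc %/% 2L) * (Wc %/% 2L) * 4 * ch[i] * ch[i + 1L]
      Hc <- Hc %/% 2L; Wc <- Wc %/% 2L
    }
  }
  # decoder: coarse head on pooled f4, then LCAM at levels 4..1
  T5 <- (Hs[4L] %/% 2L) * (Ws[4L] %/% 2L)
  total <- total + T5 * (4 * ch[4L] + ch[4L])          # pool + 1x1 head
  for (i in 1:4) {
    T <- Hs[i] * Ws[i]; D <- ch[i]; Dd <- dec_ch[i]
    total <- total + T * (4 +                          # bilinear prior upsample
                          8 +                          # attention map ops
                          9 * D * Dd +                 # delta conv
                          2 * Dd +                     # layer norm
                          2 * Dd +                     # relu + modulation
                          Dd + 2)                      # head + logit combine
  }
  total + H * W * 4                                    # final upsample
}

#' Profile parameter count and forward FLOPs
#'
#' Counts every trainable parameter of the instantiated model exactly, and
#' estimates the multiply-accumulate count of a single forward pass at the
#' given input size analytically from the architecture (1 MAC counted as
#' 1 FLOP; elementwise transcendentals count one operation each).
#'
#' @param model an [lcmamba_model].
#' @param input_size integer \code{c(H, W)} (default \code{c(256, 256)},
#'   batch size 1).
#' @return list with \code{params_millions}, \code{flops_giga},
#'   \code{n_params}, \code{input_size} and the counting \code{convention}.
#' @export
efficiency_profile <- function(model, input_size = c(256L, 256L)) {
  np <- n_params(model$params)
  fl <- flops_estimate(model$cfg, input_size[1L], input_size[2L])
  list(params_millions = np / 1e6, flops_giga = fl / 1e9,
       n_params = np, input_size = input_size,
       convention = "1 MAC = 1 FLOP; transcendentals count 1; batch size 1")
}
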