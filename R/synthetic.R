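# Deterministic liver-phantom generator: an elliptical organ with
# band-limited parenchymal texture, inserted elliptical lesions of
# controlled equivalent diameter and contrast (optional hypointense
# necrotic core, smooth sigmoid margins), plus the training-time
# augmentation pipeline (rotation within +/-15 degrees, flips, resize).
# Intensities live in [0, 1]; masks are 0/1.

#' Phantom configuration
#'
#' @param image_size integer \code{c(H, W)}.
#' @param spacing_mm isotropic pixel spacing in mm.
#' @param n_lesions number of lesions to insert.
#' @param diameter_range_mm \code{c(lo, hi)} of lesion equivalent diameters.
#' @param lesion_contrast intensity offset of lesions relative to
#'   parenchyma, in \eqn{[-1, 1]} units of dynamic range (negative =
#'   hypointense, the typical CT appearance).
#' @param necrotic_core_prob probability that a lesion carries a darker
#'   central core.
#' @param noise_sd additive Gaussian noise SD.
#' @param texture_scale correlation length (pixels) of the parenchymal
#'   texture.
#' @param seed integer seed; all randomness flows from it.
#' @return list of class \code{phantom_config}.
#' @export
phantom_config <- function(image_size = c(64L, 64L), spacing_mm = 1,
                           n_lesions = 2L, diameter_range_mm = c(8, 24),
                           lesion_contrast = -0.35,
                           necrotic_core_prob = 0.2, noise_sd = 0.05,
                           texture_scale = 8, seed = 3407L) {
  stopifnot(all(diameter_range_mm > 0), spacing_mm > 0,
            necrotic_core_prob >= 0, necrotic_core_prob <= 1,
            abs(lesion_contrast) <= 1, noise_sd >= 0)
  structure(list(image_size = as.integer(image_size),
                 spacing_mm = spacing_mm, n_lesions = as.integer(n_lesions),
                 diameter_range_mm = diameter_range_mm,
                 lesion_contrast = lesion_contrast,
                 necrotic_core_prob = necrotic_core_prob,
                 noise_sd = noise_sd, texture_scale = texture_scale,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

# Normalized elliptical radius of grid points around (cy, cx), semi-axes
# (ay, ax), rotation phi. rho <= 1 is inside.
ellipse_rho <- function(H, W, cy, cx, ay, ax, phi = 0) {
  y <- matrix(rep(seq_len(H), W), H, W) - cy
  x <- matrix(rep(seq_len(W), each = H), H, W) - cx
  u <- cos(phi) * x + sin(phi) * y
  v <- -sin(phi) * x + cos(phi) * y
  sqrt((u / ax)^2 + (v / ay)^2)
}

#' Generate one liver phantom slice
#'
#' Draws the organ ellipse, adds band-limited texture, inserts
#' \code{n_lesions} elliptical lesions fully inside the organ (each with an
#' equivalent diameter sampled from \code{diameter_range_mm}, intensity
#' offset \code{lesion_contrast}, sigmoid margins and an optional darker
#' core), then adds Gaussian noise. The mask is the union of lesion
#' supports at the half-maximum of the margin profile. Lesion axes are
#' sampled as \eqn{r e} and \eqn{r / e} with \eqn{e \in [0.92, 1.08]}, so
#' the enclosed area (hence the equivalent diameter) matches the request up
#' to pixel discretization. Bitwise reproducible from \code{cfg$seed}.
#'
#' @param cfg a [phantom_config].
#' @return list with \code{image} (\code{H x W} matrix in \eqn{[0,1]}),
#'   \code{mask} (binary matrix) and \code{spacing_mm}.
#' @export
generate_phantom <- function(cfg) {
  stopifnot(inherits(cfg, "phantom_config"))
  H <- cfg$image_size[1L]; W <- cfg$image_size[2L]
  with_seed(cfg$seed, {
    cy <- H / 2 + runif(1, -0.03, 0.03) * H
    cx <- W / 2 + runif(1, -0.03, 0.03) * W
    ay <- H * runif(1, 0.36, 0.42)
    ax <- W * runif(1, 0.32, 0.40)
    phi <- runif(1, -0.35, 0.35)
    rho_org <- ellipse_rho(H, W, cy, cx, ay, ax, phi)
    organ <- rho_org <= 1
    # band-limited texture: blurred white noise, unit-normalized
    tx <- matrix(rnorm(H * W), H, W)
    tx <- EBImage::gblur(tx, sigma = max(cfg$texture_scale / 2, 0.5))
    tx <- tx / max(sd(as.vector(tx)), 1e-8)
    img <- matrix(0.15, H, W)
    img[organ] <- 0.55 + 0.04 * tx[organ]
    mask <- matrix(0L, H, W)
    r_px_max <- max(cfg$diameter_range_mm) / (2 * cfg$spacing_mm)
    if (r_px_max + 2 >= min(ay, ax))
      stop("lesion diameter exceeds organ size", call. = FALSE)
    for (l in seq_len(cfg$n_lesions)) {
      d_mm <- runif(1, cfg$diameter_range_mm[1L], cfg$diameter_range_mm[2L])
      r <- d_mm / (2 * cfg$spacing_mm)
      e <- runif(1, 0.92, 1.08)
      la <- r * e; lb <- r / e
      lphi <- runif(1, 0, pi)
      placed <- FALSE
      for (try in 1:200) {
        # candidate centre inside the organ, keeping the whole lesion
        # (plus a 2 px rim margin) away from the organ border
        t <- runif(1, 0, 2 * pi); rr <- sqrt(runif(1))
        py <- cy + rr * (ay - max(la, lb) - 2) * sin(t)
        px <- cx + rr * (ax - max(la, lb) - 2) * cos(t)
        rho_c <- ellipse_rho(1, 1, cy - py + 1, cx - px + 1, ay, ax, phi)[1, 1]
        if (rho_c <= 1 - (max(la, lb) + 2) / min(ay, ax)) {
          placed <- TRUE; break
        }
      }
      if (!placed) next
      rho <- ellipse_rho(H, W, py, px, la, lb, lphi)
      edge_w <- 0.15
      prof <- plogis((1 - rho) / edge_w)
      img <- img + cfg$lesion_contrast * prof
      if (runif(1) < cfg$necrotic_core_prob) {
        rho_core <- rho / 0.4
        img <- img - 0.15 * plogis((1 - rho_core) / edge_w)
      }
      mask[rho <= 1] <- 1L
    }
    if (cfg$noise_sd > 0)
      img <- img + matrix(rnorm(H * W, 0, cfg$noise_sd), H, W)
    list(image = clamp(img, 0, 1), mask = mask, spacing_mm = cfg$spacing_mm)
  })
}

largest_remainder_split <- function(n, fractions) {
  raw <- n * fractions
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    add <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[add] <- base[add] + 1
  }
  as.integer(base)
}

#' Generate a phantom dataset on disk
#'
#' Writes \code{n_slices} phantom images and masks plus a JSON manifest.
#' Item \code{i} is generated from the sub-seed \code{seed XOR i}, so
#' datasets are order-independent and any file can be regenerated from the
#' manifest alone. Split sizes follow largest-remainder rounding of the
#' requested fractions; items are assigned to splits contiguously.
#'
#' @param n_slices number of slices.
#' @param split numeric \code{c(train, val, test)} fractions summing to 1.
#' @param cfg a [phantom_config]; \code{cfg$seed} is the dataset seed
#'   (default 42 by convention for fixed splits).
#' @param out_dir output directory (created).
#' @param format \code{"png"} (8-bit grayscale + JSON spacing sidecar) or
#'   \code{"nifti"} (float32 with spacing in the header).
#' @return path of the written manifest (invisibly readable via
#'   [jsonlite::read_json]).
#' @export
generate_dataset <- function(n_slices, split = c(0.7, 0.15, 0.15), cfg,
                             out_dir, format = c("png", "nifti")) {
  format <- match.arg(format)
  if (abs(sum(split) - 1) > 1e-8) stop("split fractions must sum to 1", call. = FALSE)
  sizes <- largest_remainder_split(n_slices, split)
  if (any(sizes == 0L)) stop("zero-size split", call. = FALSE)
  dir.create(file.path(out_dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  splits <- rep(c("train", "val", "test"), times = sizes)
  ext <- if (format == "png") ".png" else ".nii"
  items <- vector("list", n_slices)
  for (i in seq_len(n_slices)) {
    ci <- cfg; ci$seed <- item_seed(cfg$seed, i)
    ph <- generate_phantom(ci)
    img_rel <- file.path("images", sprintf("img_%04d%s", i, ext))
    msk_rel <- file.path("masks", sprintf("msk_%04d%s", i, ext))
    write_image_slice(ph$image, file.path(out_dir, img_rel), format,
                      ph$spacing_mm)
    write_mask(ph$mask, file.path(out_dir, msk_rel), format, ph$spacing_mm)
    items[[i]] <- list(id = i, image = img_rel, mask = msk_rel,
                       split = splits[i], seed = ci$seed)
  }
  manifest <- list(seed = cfg$seed, format = format,
                   spacing_mm = cfg$spacing_mm,
                   image_size = cfg$image_size,
                   split_fractions = split, split_sizes = sizes,
                   generator = unclass(cfg), items = items)
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# Bilinear sample of `img` at fractional (row, col) coordinates; outside
# pixels read as `fill`.
bilinear_sample <- function(img, rs, cs, fill = 0) {
  H <- nrow(img); W <- ncol(img)
  r0 <- floor(rs); c0 <- floor(cs)
  fr <- rs - r0; fc <- cs - c0
  get <- function(r, c) {
    ok <- r >= 1 & r <= H & c >= 1 & c <= W
    v <- numeric(length(r)); v[] <- fill
    v[ok] <- img[cbind(r[ok], c[ok])]
    v
  }
  (1 - fr) * (1 - fc) * get(r0, c0) + (1 - fr) * fc * get(r0, c0 + 1) +
    fr * (1 - fc) * get(r0 + 1, c0) + fr * fc * get(r0 + 1, c0 + 1)
}

nearest_sample <- function(img, rs, cs, fill = 0L) {
  H <- nrow(img); W <- ncol(img)
  r <- round(rs); c <- round(cs)
  ok <- r >= 1 & r <= H & c >= 1 & c <= W
  v <- rep(fill, length(r))
  v[ok] <- img[cbind(r[ok], c[ok])]
  v
}

rotate_pair <- function(image, mask, angle_deg) {
  H <- nrow(image); W <- ncol(image)
  th <- angle_deg * pi / 180
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  ro <- matrix(rep(seq_len(H), W), H, W) - cy
  co <- matrix(rep(seq_len(W), each = H), H, W) - cx
  # inverse rotation of output coords gives source coords
  rs <- cy + cos(th) * ro - sin(th) * co
  cs <- cx + sin(th) * ro + cos(th) * co
  list(image = matrix(bilinear_sample(image, as.vector(rs), as.vector(cs)), H, W),
       mask = matrix(as.integer(nearest_sample(mask, as.vector(rs), as.vector(cs))), H, W))
}

resize_pair <- function(image, mask, size) {
  H <- nrow(image); W <- ncol(image)
  if (all(c(H, W) == size)) return(list(image = image, mask = mask))
  rp <- resize_plan(H, W, size[1L], size[2L])
  img <- matrix(resize_forward(matrix(fmap_to_mat(array(image, c(H, W, 1))), ncol = 1), rp)[, 1],
                size[1L], size[2L], byrow = TRUE)
  yo <- rep(seq_len(size[1L]), each = size[2L]); xo <- rep(seq_len(size[2L]), size[1L])
  rs <- (yo - 0.5) * H / size[1L] + 0.5; cs <- (xo - 0.5) * W / size[2L] + 0.5
  msk <- matrix(as.integer(nearest_sample(mask, rs, cs)), size[1L], size[2L],
                byrow = TRUE)
  list(image = img, mask = msk)
}

#' Training-time augmentation
#'
#' Samples a rotation angle uniformly in \eqn{[-15, +15]} degrees and
#' horizontal/vertical flips each with probability 0.5; the identical
#' geometric transform is applied to image (bilinear) and mask (nearest
#' neighbour, so it stays binary). An optional resize to the training
#' resolution is applied afterwards. Presets: \code{"none"} (identity),
#' \code{"basic"} (flips only), \code{"full"} (rotation + flips).
#'
#' @param image \code{H x W} intensity matrix. @param mask binary matrix.
#' @param seed integer seed for the sampled transform.
#' @param size optional \code{c(H, W)} resize target.
#' @param preset \code{"full"}, \code{"basic"} or \code{"none"}.
#' @return list with \code{image}, \code{mask}, and the sampled
#'   \code{angle}, \code{hflip}, \code{vflip}.
#' @export
augment <- function(image, mask, seed, size = NULL,
                    preset = c("full", "basic", "none")) {
  preset <- match.arg(preset)
  out <- with_seed(seed, {
    angle <- 0; hf <- FALSE; vf <- FALSE
    if (preset == "full") angle <- runif(1, -15, 15)
    if (preset != "none") {
      hf <- runif(1) < 0.5
      vf <- runif(1) < 0.5
    }
    im <- image; mk <- mask
    if (angle != 0) {
      rp <- rotate_pair(im, mk, angle)
      im <- rp$image; mk <- rp$mask
    }
    if (hf) { im <- im[, ncol(im):1]; mk <- mk[, ncol(mk):1] }
    if (vf) { im <- im[nrow(im):1, ]; mk <- mk[nrow(mk):1, ] }
    list(image = im, mask = mk, angle = angle, hflip = hf, vflip = vf)
  })
  if (!is.null(size)) {
    rs <- resize_pair(out$image, out$mask, size)
    out$image <- rs$image; out$mask <- rs$mask
  }
  out
}
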