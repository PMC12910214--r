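# Image, mask, manifest and checkpoint I/O. Intensities are [0, 1]; PNG
# files are 8-bit grayscale with a JSON sidecar carrying the pixel spacing,
# NIfTI files are float32 with spacing in the header. Mask PNGs must be
# strictly {0, 255}.

sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

#' Write an intensity slice
#'
#' @param image \code{H x W} matrix in \eqn{[0, 1]}.
#' @param path output path. @param format \code{"png"} or \code{"nifti"}.
#' @param spacing_mm pixel spacing stored in the sidecar (PNG) or header
#'   (NIfTI).
#' @export
write_image_slice <- function(image, path, format = c("png", "nifti"),
                              spacing_mm = 1) {
  format <- match.arg(format)
  if (format == "png") {
    png::writePNG(clamp(image, 0, 1), path)
    jsonlite::write_json(list(spacing_mm = spacing_mm), sidecar_path(path),
                         auto_unbox = TRUE, digits = NA)
  } else {
    im <- RNifti::asNifti(array(image, dim(image)))
    RNifti::pixdim(im) <- c(spacing_mm, spacing_mm)
    RNifti::writeNifti(im, path, datatype = "float")
  }
  invisible(path)
}

#' Write a binary mask
#'
#' PNG masks are written as \{0, 255\}; NIfTI masks as float 0/1.
#' @inheritParams write_image_slice
#' @param mask binary \code{H x W} matrix.
#' @export
write_mask <- function(mask, path, format = c("png", "nifti"),
                       spacing_mm = 1) {
  format <- match.arg(format)
  check_binary(mask)
  if (format == "png") {
    png::writePNG(mask * 1, path)
    jsonlite::write_json(list(spacing_mm = spacing_mm), sidecar_path(path),
                         auto_unbox = TRUE, digits = NA)
  } else {
    im <- RNifti::asNifti(array(as.numeric(mask), dim(mask)))
    RNifti::pixdim(im) <- c(spacing_mm, spacing_mm)
    RNifti::writeNifti(im, path, datatype = "float")
  }
  invisible(path)
}

read_any_slice <- function(path) {
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (ext == "png") {
    a <- png::readPNG(path)
    if (length(dim(a)) == 3L) a <- a[, , 1L]
    sp <- 1
    sc <- sidecar_path(path)
    if (file.exists(sc)) {
      sp <- jsonlite::read_json(sc)$spacing_mm
    } else {
      warning("no spacing sidecar for ", basename(path),
              "; defaulting to 1.0 mm")
    }
    list(data = a, spacing_mm = as.numeric(sp))
  } else if (ext %in% c("nii", "nifti")) {
    v <- RNifti::readNifti(path)
    list(data = matrix(as.numeric(v), dim(v)[1L], dim(v)[2L]),
         spacing_mm = RNifti::pixdim(v)[1L])
  } else {
    stop("unknown format '", ext, "'; supported formats: png, nii",
         call. = FALSE)
  }
}

#' Read an intensity slice (PNG or NIfTI)
#'
#' @param path input file.
#' @return list with \code{image} (\code{H x W} matrix in \eqn{[0,1]}) and
#'   \code{spacing_mm}.
#' @export
read_image_slice <- function(path) {
  r <- read_any_slice(path)
  list(image = r$data, spacing_mm = r$spacing_mm)
}

#' Read a binary mask (PNG or NIfTI)
#'
#' PNG values must be exactly \{0, 255\} (i.e. 0 or 1 after decoding);
#' anything else is rejected.
#'
#' @param path input file.
#' @return list with \code{mask} (binary matrix) and \code{spacing_mm}.
#' @export
read_mask <- function(path) {
  r <- read_any_slice(path)
  vals <- unique(round(as.vector(r$data) * 255))
  if (!all(vals %in% c(0, 255)) &&
      !all(unique(as.vector(r$data)) %in% c(0, 1)))
    stop("mask contains values other than {0, 255}: ",
         paste(utils::head(setdiff(vals, c(0, 255)), 5), collapse = ", "),
         call. = FALSE)
  list(mask = matrix(as.integer(r$data > 0.5), nrow(r$data), ncol(r$data)),
       spacing_mm = r$spacing_mm)
}

#' Load a dataset manifest
#'
#' @param manifest path to a \code{manifest.json} written by
#'   [generate_dataset] (or its directory).
#' @return list with \code{items} (each: image, mask, split, spacing) and
#'   the manifest metadata; images and masks are loaded into memory.
#' @export
load_manifest <- function(manifest) {
  if (dir.exists(manifest)) manifest <- file.path(manifest, "manifest.json")
  mf <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  root <- dirname(manifest)
  items <- lapply(seq_len(nrow(mf$items)), function(i) {
    it <- mf$items[i, ]
    img <- read_image_slice(file.path(root, it$image))
    msk <- read_mask(file.path(root, it$mask))
    list(id = it$id, image = img$image, mask = msk$mask,
         split = it$split, spacing_mm = img$spacing_mm)
  })
  list(items = items, meta = mf)
}

# ---- checkpoints -------------------------------------------------------

#' Save a model checkpoint
#'
#' Single-file archive holding the parameter arrays, the variant config and
#' optional metadata, so [load_checkpoint] needs no side config.
#' @param model an [lcmamba_model]. @param path output file.
#' @param extra optional metadata list (e.g. training history).
#' @export
save_checkpoint <- function(model, path, extra = list()) {
  saveRDS(list(params = model$params, cfg = model$cfg, extra = extra,
               package = "lcmamba", version = "1"), path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path checkpoint file from [save_checkpoint].
#' @return an [lcmamba_model] with attribute \code{"extra"}.
#' @export
load_checkpoint <- function(path) {
  ck <- tryCatch(readRDS(path), error = function(e)
    stop("corrupt checkpoint: ", conditionMessage(e), call. = FALSE))
  need <- c("params", "cfg")
  missing_keys <- setdiff(need, names(ck))
  if (length(missing_keys) > 0)
    stop("corrupt checkpoint: missing keys ",
         paste(missing_keys, collapse = ", "), call. = FALSE)
  m <- structure(list(params = ck$params, cfg = ck$cfg),
                 class = "lcmamba_model")
  attr(m, "extra") <- ck$extra
  m
}

#' Load pretrained encoder weights into a model
#'
#' Copies parameter arrays whose names and shapes match between the
#' checkpoint's encoder and the target model, skipping the rest with a
#' report. Useful as an initialization hook; no weights ship with the
#' package.
#'
#' @param model target [lcmamba_model]. @param path checkpoint file.
#' @return the model with matching encoder weights replaced; attribute
#'   \code{"load_report"} lists loaded and skipped entries.
#' @export
load_pretrained_encoder <- function(model, path) {
  src <- load_checkpoint(path)
  loaded <- character(); skipped <- character()
  copy <- function(dst, from, prefix) {
    if (is.null(from)) from <- list()
    for (nm in names(dst)) {
      key <- paste0(prefix, nm)
      if (is.list(dst[[nm]]) && !is.null(names(dst[[nm]]) )) {
        res <- copy(dst[[nm]], from[[nm]], paste0(key, "."))
        dst[[nm]] <- res
      } else if (is.list(dst[[nm]])) {
        for (j in seq_along(dst[[nm]])) {
          res <- copy(dst[[nm]][[j]], from[[nm]][[j]], sprintf("%s[%d].", key, j))
          dst[[nm]][[j]] <- res
        }
      } else if (!is.null(from[[nm]]) &&
                 length(from[[nm]]) == length(dst[[nm]])) {
        dst[[nm]] <- from[[nm]]
        loaded <<- c(loaded, key)
      } else {
        skipped <<- c(skipped, key)
      }
    }
    dst
  }
  enc_names <- c("stem", "stages")
  model$params[enc_names] <- copy(model$params[enc_names],
                                  src$params[enc_names], "")
  message(sprintf("loaded %d encoder arrays, skipped %d",
                  length(loaded), length(skipped)))
  attr(model, "load_report") <- list(loaded = loaded, skipped = skipped)
  model
}
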