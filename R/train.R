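# Training, inference and evaluation orchestration: Adam on the flattened
# parameter vector, deep supervision of the full prediction pyramid,
# plateau learning-rate scheduling on validation Dice, early stopping and
# best-checkpoint tracking. All randomness flows from the config seed.

#' Training configuration
#'
#' Defaults follow the training protocol: Adam with initial learning rate
#' 1e-4, ReduceLROnPlateau on validation Dice (factor 0.5, patience 5),
#' batch size 16, seed 3407, inputs resized to 256x256, full augmentation.
#' The \code{"nano"} variant overrides the CPU-scale preset: 64x64 inputs,
#' learning rate 1e-3, 20 epochs (a tiny model trained for a few hundred
#' steps needs the larger step size).
#'
#' @param variant \code{"T"}, \code{"S"} or \code{"nano"}.
#' @param ... overrides for any field: \code{lr}, \code{batch_size},
#'   \code{max_epochs}, \code{seed}, \code{image_size}, \code{augmentation}
#'   (\code{"none"}/\code{"basic"}/\code{"full"}), \code{loss_weights},
#'   \code{sched_factor}, \code{sched_patience}, \code{early_stop_patience},
#'   \code{gamma}, \code{lcam_off}, \code{checkpoint_dir}, \code{log_path}.
#' @return list of class \code{train_config}.
#' @export
train_config <- function(variant = "nano", ...) {
  cfg <- list(variant = variant, lr = 1e-4, batch_size = 16L,
              max_epochs = 100L, seed = 3407L,
              image_size = c(256L, 256L), augmentation = "full",
              loss_weights = loss_weights(),
              sched_factor = 0.5, sched_patience = 5L, sched_min_delta = 1e-4,
              early_stop_patience = 15L, gamma = 0.5, lcam_off = FALSE,
              threshold = 0.5, checkpoint_dir = NULL, log_path = NULL)
  if (variant == "nano") {
    cfg$image_size <- c(64L, 64L)
    cfg$lr <- 1e-3
    cfg$max_epochs <- 20L
  }
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad) > 0)
    stop("unknown config fields: ", paste(bad, collapse = ", "), call. = FALSE)
  cfg <- modifyList(cfg, over)
  if (cfg$lr <= 0) stop("lr must be positive", call. = FALSE)
  if (cfg$batch_size < 1) stop("batch_size must be >= 1", call. = FALSE)
  structure(cfg, class = "train_config")
}

# Plateau learning-rate scheduler (max mode): after `patience` consecutive
# non-improving epochs the rate is multiplied by `factor` exactly once,
# then the counter resets so each plateau triggers one reduction.
plateau_init <- function(factor = 0.5, patience = 5L, min_delta = 1e-4) {
  list(factor = factor, patience = patience, min_delta = min_delta,
       best = -Inf, bad = 0L)
}

plateau_step <- function(st, metric) {
  reduce <- FALSE
  if (metric > st$best + st$min_delta) {
    st$best <- metric; st$bad <- 0L
  } else {
    st$bad <- st$bad + 1L
    if (st$bad >= st$patience) {
      reduce <- TRUE
      st$bad <- 0L
    }
  }
  st$reduce <- reduce
  st
}

# Reorder a gradient structure to match the parameter structure exactly, so
# both flatten in the same order.
align_grads <- function(params, grads) {
  if (!is.list(params)) return(if (is.null(grads)) params * 0 else grads)
  nms <- names(params)
  if (is.null(nms)) {
    out <- lapply(seq_along(params), function(i)
      align_grads(params[[i]], grads[[i]]))
  } else {
    out <- lapply(nms, function(nm) align_grads(params[[nm]], grads[[nm]]))
    names(out) <- nms
  }
  out
}

# Deep-supervision loss over the prediction pyramid: every level upsampled
# to full resolution, losses averaged with equal weights. Works on
# row-major vectors throughout (y and B are converted once). Returns the
# loss value, its components, and per-level full-resolution gradients.
supervised_loss <- function(fwd, y, w, B) {
  yv <- as.vector(t(y))
  Bv <- as.vector(t(B))
  lv <- names(fwd$pyramid)
  nl <- length(lv)
  dP_full <- list(); tot <- 0; comp <- c(bce = 0, dice = 0, boundary = 0)
  for (nm in lv) {
    lev <- fwd$pyramid[[nm]]
    rp <- resize_plan(lev$H, lev$W, fwd$H, fwd$W)
    Pf <- resize_forward(matrix(lev$P, ncol = 1L), rp)[, 1L]
    l <- total_loss(yv, Pf, w, Bv)
    tot <- tot + as.numeric(l) / nl
    comp <- comp + attr(l, "components") / nl
    dP_full[[nm]] <- total_loss_grad(yv, Pf, w, Bv) / nl
  }
  list(loss = tot, components = comp, dP_full = dP_full)
}

mean_val_dice <- function(model, items, size, threshold) {
  mean(vapply(items, function(it) {
    rs <- resize_pair(it$image, it$mask, size)
    pr <- predict(model, rs$image, threshold = threshold)
    overlap_metrics(pr$mask, rs$mask)[["dice"]]
  }, numeric(1)))
}

#' Train a segmentation model
#'
#' Seeds all RNGs from the config seed, runs Adam over minibatches with the
#' configured augmentation preset, supervises every level of the prediction
#' pyramid, schedules the learning rate on validation Dice and tracks the
#' best-validation checkpoint. Deterministic given config and seed.
#'
#' @param data a manifest path/directory (see [generate_dataset]) or the
#'   list returned by [load_manifest].
#' @param cfg a [train_config].
#' @param quiet suppress per-epoch messages.
#' @return list with \code{model} (best validation weights),
#'   \code{history} (per-epoch data frame: loss components, val Dice, lr),
#'   \code{best_val_dice}, \code{best_epoch} and \code{checkpoint} (path or
#'   NULL).
#' @export
train <- function(data, cfg = train_config(), quiet = FALSE) {
  ds <- if (is.character(data)) load_manifest(data) else data
  tr <- Filter(function(it) it$split == "train", ds$items)
  va <- Filter(function(it) it$split == "val", ds$items)
  if (length(tr) == 0 || length(va) == 0)
    stop("train and val splits must be nonempty", call. = FALSE)
  size <- cfg$image_size
  model <- lcmamba_model(cfg$variant, seed = cfg$seed, gamma = cfg$gamma)
  model$cfg$lcam_off <- isTRUE(cfg$lcam_off)
  skel <- param_skeleton(model$params)
  theta <- flatten_params(model$params)
  opt <- adam_init(length(theta))
  sched <- plateau_init(cfg$sched_factor, cfg$sched_patience,
                        cfg$sched_min_delta)
  lr <- cfg$lr
  best <- list(dice = -Inf, theta = theta, epoch = 0L)
  hist <- list()
  logline <- function(...) {
    msg <- sprintf(...)
    if (!quiet) message(msg)
    if (!is.null(cfg$log_path))
      cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), msg, "\n",
          file = cfg$log_path, append = TRUE)
  }
  set.seed(cfg$seed)
  no_improve <- 0L
  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- sample(length(tr))
    ep_loss <- c(total = 0, bce = 0, dice = 0, boundary = 0)
    nb <- 0L
    for (start in seq(1L, length(ord), by = cfg$batch_size)) {
      ids <- ord[start:min(start + cfg$batch_size - 1L, length(ord))]
      gacc <- NULL
      bl <- 0
      for (id in ids) {
        it <- tr[[id]]
        aug_seed <- sample.int(2^30, 1L)
        au <- augment(it$image, it$mask, aug_seed, size = size,
                      preset = cfg$augmentation)
        fwd <- model_forward(model, au$image, train = TRUE)
        B <- boundary_set(au$mask)
        sl <- supervised_loss(fwd, au$mask, cfg$loss_weights, B)
        if (!is.finite(sl$loss))
          stop("non-finite loss at epoch ", epoch, call. = FALSE)
        bl <- bl + sl$loss
        g <- model_backward(model, fwd, sl$dP_full)
        gv <- flatten_params(align_grads(model$params, g))
        gacc <- if (is.null(gacc)) gv else gacc + gv
        ep_loss <- ep_loss + c(sl$loss, sl$components)
      }
      stp <- adam_step(theta, gacc / length(ids), opt, lr)
      theta <- stp$theta; opt <- stp$state
      model$params <- unflatten_params(theta, skel)
      nb <- nb + 1L
    }
    ep_loss <- ep_loss / length(tr)
    vd <- mean_val_dice(model, va, size, cfg$threshold)
    hist[[epoch]] <- data.frame(epoch = epoch, loss = ep_loss[["total"]],
                                bce = ep_loss[["bce"]],
                                dice_loss = ep_loss[["dice"]],
                                boundary = ep_loss[["boundary"]],
                                val_dice = vd, lr = lr)
    logline("epoch %3d  loss %.4f  val Dice %.4f  lr %.2g",
            epoch, ep_loss[["total"]], vd, lr)
    if (vd > best$dice + 1e-6) {
      best <- list(dice = vd, theta = theta, epoch = epoch)
      no_improve <- 0L
    } else no_improve <- no_improve + 1L
    sched <- plateau_step(sched, vd)
    if (sched$reduce) {
      lr <- lr * cfg$sched_factor
      logline("plateau: lr reduced to %.3g", lr)
    }
    if (no_improve >= cfg$early_stop_patience) {
      logline("early stop at epoch %d", epoch)
      break
    }
  }
  model$params <- unflatten_params(best$theta, skel)
  ck <- NULL
  if (!is.null(cfg$checkpoint_dir)) {
    dir.create(cfg$checkpoint_dir, recursive = TRUE, showWarnings = FALSE)
    ck <- file.path(cfg$checkpoint_dir, "best.rds")
    save_checkpoint(model, ck, extra = list(best_val_dice = best$dice,
                                            cfg = unclass(cfg)))
  }
  list(model = model, history = do.call(rbind, hist),
       best_val_dice = best$dice, best_epoch = best$epoch, checkpoint = ck)
}

#' Evaluate predicted masks against ground truth
#'
#' Computes per-case overlap metrics and HD95, aggregates them
#' (mean, SD, Student-t 95% CI), and — when \code{per_lesion} — reports
#' lesion-size-stratified Dice by matching each ground-truth lesion
#' component inside a bounding-box crop. Reports are optionally written as
#' CSV (per case) and JSON (aggregates plus conventions).
#'
#' @param pred_masks,gt_masks lists of binary matrices, paired by case.
#' @param spacing_mm scalar or per-case vector of pixel spacings.
#' @param out_dir optional output directory for \code{metrics.csv} and
#'   \code{summary.json}.
#' @param per_lesion include the stratified per-lesion analysis.
#' @return list with \code{per_case} (data frame), \code{aggregate} (data
#'   frame of mean/sd/CI per metric), \code{strata} (per size class) and
#'   \code{conventions}.
#' @export
evaluate_segmentation <- function(pred_masks, gt_masks, spacing_mm = 1,
                                  out_dir = NULL, per_lesion = TRUE) {
  if (length(pred_masks) != length(gt_masks))
    stop("prediction and ground-truth lists differ in length", call. = FALSE)
  n <- length(pred_masks)
  sp <- rep_len(spacing_mm, n)
  rows <- lapply(seq_len(n), function(i) {
    om <- overlap_metrics(pred_masks[[i]], gt_masks[[i]])
    data.frame(case = i, t(om),
               hd95_mm = hd95(pred_masks[[i]], gt_masks[[i]], sp[i]))
  })
  per_case <- do.call(rbind, rows)
  mets <- c("dice", "miou", "iou_fg", "recall", "precision", "f2", "hd95_mm")
  aggregate <- do.call(rbind, lapply(mets, function(m) {
    a <- aggregate_stats(per_case[[m]])
    data.frame(metric = m, t(a))
  }))
  strata <- NULL
  if (per_lesion) {
    les <- list()
    for (i in seq_len(n)) {
      lr <- stratify_lesions(gt_masks[[i]], sp[i])
      if (nrow(lr) == 0) next
      lab <- label8_cpp(matrix(as.integer(gt_masks[[i]]),
                               nrow(gt_masks[[i]]), ncol(gt_masks[[i]])))
      for (k in seq_len(nrow(lr))) {
        comp <- lab == lr$component_id[k]
        pos <- which(comp, arr.ind = TRUE)
        r0 <- max(1, min(pos[, 1]) - 5); r1 <- min(nrow(comp), max(pos[, 1]) + 5)
        c0 <- max(1, min(pos[, 2]) - 5); c1 <- min(ncol(comp), max(pos[, 2]) + 5)
        d <- overlap_metrics(pred_masks[[i]][r0:r1, c0:c1],
                             (comp * 1)[r0:r1, c0:c1])[["dice"]]
        les[[length(les) + 1]] <- data.frame(
          case = i, size_class = lr$size_class[k],
          equiv_diameter_mm = lr$equiv_diameter_mm[k], dice = d)
      }
    }
    if (length(les) > 0) {
      les <- do.call(rbind, les)
      strata <- do.call(rbind, lapply(split(les, les$size_class), function(s)
        data.frame(size_class = s$size_class[1], n_lesions = nrow(s),
                   t(aggregate_stats(s$dice)[1:4]))))
      rownames(strata) <- NULL
    }
  }
  conventions <- paste(
    "empty/empty: dice=miou=1, hd95=0; one empty: dice=0,",
    "hd95=diagonal*spacing; mIoU = mean(fg IoU, bg IoU);",
    "CI: Student-t; per-case = per-slice;",
    "stratified Dice: per-lesion on component-matched crops (+/-5 px)")
  out <- list(per_case = per_case, aggregate = aggregate, strata = strata,
              conventions = conventions)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(per_case, file.path(out_dir, "metrics.csv"),
                     row.names = FALSE)
    jsonlite::write_json(list(aggregate = aggregate, strata = strata,
                              conventions = conventions),
                         file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}

#' Profile a model variant
#'
#' Instantiates the variant and reports trainable parameters (millions) and
#' forward FLOPs (giga, 1 MAC = 1 FLOP) at the given input size.
#'
#' @param variant \code{"T"}, \code{"S"} or \code{"nano"}.
#' @param input_size integer \code{c(H, W)}, default 256x256.
#' @return the [efficiency_profile] list, plus \code{variant}.
#' @export
profile_variant <- function(variant, input_size = c(256L, 256L)) {
  model <- lcmamba_model(variant, seed = 1L)
  out <- efficiency_profile(model, input_size)
  out$variant <- if (is.list(variant)) variant$name else variant
  out
}
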