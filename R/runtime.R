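# Dataset I/O, training and evaluation loops, prediction, profiling report.
# Image files are read and written through EBImage (PNG/JPEG/TIFF); arrays
# inside the package are (rows, cols, channels) in [0, 1].

read_image_array <- function(path) {
  img <- EBImage::imageData(EBImage::readImage(path))
  d <- dim(img)
  if (length(d) == 2L) {
    out <- array(t(img), c(d[2], d[1], 1L))
    out <- out[, , c(1L, 1L, 1L), drop = FALSE]
  } else {
    out <- aperm(img[, , seq_len(min(3L, d[3])), drop = FALSE], c(2L, 1L, 3L))
    if (dim(out)[3] == 1L) out <- out[, , c(1L, 1L, 1L), drop = FALSE]
  }
  out
}

read_mask_array <- function(path) {
  m <- EBImage::imageData(EBImage::readImage(path))
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  m <- t(m)
  vals <- unique(as.vector(m))
  binary <- all(vals %in% c(0, 1))
  out <- matrix(as.numeric(m >= 127 / 255), nrow(m), ncol(m))
  if (!binary && any(!(vals * 255) %in% c(0, 255)))
    warning("mask ", basename(path), " contains non-binary values; ",
            "binarized at 127/255", call. = FALSE)
  out
}

write_image_file <- function(img, path) {
  EBImage::writeImage(EBImage::Image(aperm(img, c(2L, 1L, 3L)),
                                     colormode = "Color"), path)
}

write_mask_file <- function(mask, path) {
  EBImage::writeImage(EBImage::Image(t(mask)), path)
}

resize_image <- function(img, h, w) {
  x <- array(img, c(dim(img)[1], dim(img)[2], dim(img)[3], 1L))
  array(cpp_resize_bilinear_fw(x, as.integer(h), as.integer(w)),
        c(h, w, dim(img)[3]))
}

resize_mask <- function(mask, h, w) {
  H <- nrow(mask); W <- ncol(mask)
  iy <- pmin(H, pmax(1L, round((seq_len(h) - 0.5) * H / h + 0.5)))
  ix <- pmin(W, pmax(1L, round((seq_len(w) - 0.5) * W / w + 0.5)))
  mask[iy, ix, drop = FALSE]
}

#' Write a generated split to disk
#'
#' Creates `train/`, `val/` and `test/` directories, each with `images/`
#' and `masks/` subdirectories of PNG files, plus a `manifest.csv` at the
#' root recording path, split, seed and mask area fraction.
#'
#' @param split result of [generate_split()].
#' @param dir output directory (created if needed).
#' @return invisibly, the manifest data frame with a `path` column.
#' @export
write_dataset <- function(split, dir) {
  manifest <- split$manifest
  manifest$path <- NA_character_
  idx <- 1L
  for (part in c("train", "val", "test")) {
    imgdir <- file.path(dir, part, "images")
    maskdir <- file.path(dir, part, "masks")
    dir.create(imgdir, recursive = TRUE, showWarnings = FALSE)
    dir.create(maskdir, recursive = TRUE, showWarnings = FALSE)
    for (s in split[[part]]) {
      id <- manifest$id[idx]
      p <- file.path(part, "images", paste0(id, ".png"))
      write_image_file(s$image, file.path(dir, p))
      write_mask_file(s$mask, file.path(maskdir, paste0(id, ".png")))
      manifest$path[idx] <- p
      idx <- idx + 1L
    }
  }
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Load an image/mask dataset from disk
#'
#' Expects `images/` and `masks/` subdirectories with same-named files
#' (PNG/JPEG images, PNG masks); alternatively a flat directory where each
#' image `stem.png` has a mask `stem_mask.png`. Images are scaled to
#' [0, 1]; masks are binarized at 127/255 (with a warning when non-binary
#' values are present). Images without a mask are reported in the
#' `missing_masks` attribute, not silently dropped.
#'
#' @param root dataset directory.
#' @param input_size optional `(rows, cols)`; when given, images are resized
#'   bilinearly and masks nearest-neighbour.
#' @return list of samples (`image`, `mask`, `meta$path`), with attribute
#'   `missing_masks` listing image files lacking a mask.
#' @export
load_dataset <- function(root, input_size = NULL) {
  exts <- "\\.(png|jpg|jpeg)$"
  if (dir.exists(file.path(root, "images"))) {
    imgs <- list.files(file.path(root, "images"), pattern = exts,
                       ignore.case = TRUE, full.names = TRUE)
    find_mask <- function(p) {
      cand <- file.path(root, "masks",
                        paste0(tools::file_path_sans_ext(basename(p)), ".png"))
      if (file.exists(cand)) cand else NA_character_
    }
  } else {
    all_f <- list.files(root, pattern = exts, ignore.case = TRUE,
                        full.names = TRUE)
    imgs <- all_f[!grepl("_mask\\.", basename(all_f))]
    find_mask <- function(p) {
      cand <- file.path(root, paste0(tools::file_path_sans_ext(basename(p)),
                                     "_mask.png"))
      if (file.exists(cand)) cand else NA_character_
    }
  }
  if (!length(imgs)) stop("no image files found under ", root, call. = FALSE)
  masks <- vapply(imgs, find_mask, character(1))
  missing <- basename(imgs[is.na(masks)])
  if (length(missing))
    warning(length(missing), " image(s) lack a mask and were skipped: ",
            paste(missing, collapse = ", "), call. = FALSE)
  keep <- !is.na(masks)
  samples <- Map(function(ip, mp) {
    img <- read_image_array(ip)
    mask <- read_mask_array(mp)
    if (!is.null(input_size)) {
      img <- resize_image(img, input_size[1], input_size[2])
      mask <- resize_mask(mask, input_size[1], input_size[2])
    }
    list(image = img, mask = mask, meta = list(path = ip))
  }, imgs[keep], masks[keep])
  samples <- unname(samples)
  attr(samples, "missing_masks") <- missing
  samples
}

#' Training configuration
#'
#' Defaults follow the training protocol the network was designed around:
#' 200 epochs, batch size 8, Adam at an initial learning rate of 1e-4, and
#' a learning-rate decay factor of 0.5 applied when the validation loss
#' plateaus.
#'
#' @param epochs number of passes over the training set.
#' @param batch_size minibatch size.
#' @param initial_lr initial Adam learning rate.
#' @param lr_decay_factor multiplier in (0, 1) applied on plateau.
#' @param decay_patience_epochs epochs without validation improvement before
#'   the learning rate is decayed.
#' @param seed seed for shuffling (and anything stochastic downstream).
#' @param threshold binarization threshold used for validation metrics.
#' @return a `train_config` list.
#' @export
train_config <- function(epochs = 200L, batch_size = 8L, initial_lr = 1e-4,
                         lr_decay_factor = 0.5, decay_patience_epochs = 10L,
                         seed = 42L, threshold = 0.5) {
  stopifnot(epochs >= 1L, batch_size >= 1L,
            lr_decay_factor > 0, lr_decay_factor < 1)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 initial_lr = initial_lr,
                 lr_decay_factor = lr_decay_factor,
                 decay_patience_epochs = as.integer(decay_patience_epochs),
                 seed = as.integer(seed), threshold = threshold),
            class = "train_config")
}

stack_samples <- function(samples) {
  d <- dim(samples[[1]]$image)
  n <- length(samples)
  x <- array(0, c(d[1], d[2], d[3], n))
  y <- array(0, c(d[1], d[2], 1L, n))
  for (i in seq_len(n)) {
    x[, , , i] <- samples[[i]]$image
    y[, , 1L, i] <- samples[[i]]$mask
  }
  list(x = x, y = y)
}

#' Train a network
#'
#' Minibatch Adam on the combined BCE-Dice loss. When a validation set is
#' given, the validation loss is tracked each epoch and the learning rate
#' is halved (by `lr_decay_factor`) after `decay_patience_epochs` epochs
#' without improvement. Fully seeded: identical calls produce identical
#' loss curves.
#'
#' @param net an `afcf_net` (modified in place).
#' @param train_samples non-empty list of samples.
#' @param val_samples optional validation samples; `NULL` disables
#'   validation and learning-rate decay.
#' @param cfg a [train_config()].
#' @param verbose print one line per epoch?
#' @return list with `net` and `history` (data frame: epoch, train_loss,
#'   val_loss, val_iou, val_dsc, lr).
#' @export
train_network <- function(net, train_samples, val_samples = NULL,
                          cfg = train_config(), verbose = FALSE) {
  if (!length(train_samples)) stop("empty training set", call. = FALSE)
  tr <- stack_samples(train_samples)
  n <- dim(tr$x)[4]
  set.seed(cfg$seed)
  params <- collect_params(net)
  opt <- new_adam(params, lr = cfg$initial_lr)
  best_val <- Inf
  wait <- 0L
  hist <- vector("list", cfg$epochs)
  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    starts <- seq(1L, n, by = cfg$batch_size)
    losses <- numeric(length(starts))
    for (k in seq_along(starts)) {
      idx <- ord[starts[k]:min(starts[k] + cfg$batch_size - 1L, n)]
      ag_tape_reset()
      xb <- ag_tensor(tr$x[, , , idx, drop = FALSE])
      pred <- net_forward(net, xb, training = TRUE)
      loss <- ag_bce_dice(pred, tr$y[, , , idx, drop = FALSE])
      if (!is.finite(loss$value))
        stop("non-finite training loss at epoch ", epoch,
             " (value ", loss$value, "); aborting", call. = FALSE)
      ag_backward(loss)
      opt$step()
      opt$zero_grad()
      losses[k] <- loss$value
    }
    train_loss <- mean(losses)
    val_loss <- NA_real_
    val_iou <- NA_real_
    val_dsc <- NA_real_
    if (!is.null(val_samples) && length(val_samples)) {
      va <- stack_samples(val_samples)
      pv <- net_forward(net, va$x, training = FALSE)
      val_loss <- combined_loss(pv, va$y)
      cm <- confusion(pv, va$y, cfg$threshold)
      mt <- seg_metrics(cm)
      val_iou <- mt$iou
      val_dsc <- mt$dsc
      if (val_loss < best_val - 1e-8) {
        best_val <- val_loss
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= cfg$decay_patience_epochs) {
          opt$lr <- opt$lr * cfg$lr_decay_factor
          wait <- 0L
        }
      }
    }
    hist[[epoch]] <- data.frame(epoch = epoch, train_loss = train_loss,
                                val_loss = val_loss, val_iou = val_iou,
                                val_dsc = val_dsc, lr = opt$lr)
    if (verbose)
      message(sprintf("epoch %3d  train %.4f  val %.4f  lr %.2e",
                      epoch, train_loss, val_loss, opt$lr))
  }
  list(net = net, history = do.call(rbind, hist))
}

#' Evaluate a network on labeled samples
#'
#' Computes the per-image pixel confusion at the given threshold and
#' reports macro-averaged metrics (mean and standard deviation across
#' images) as well as micro-averaged ones (pooled counts).
#'
#' @param net an `afcf_net`.
#' @param samples non-empty list of samples.
#' @param threshold binarization threshold.
#' @param batch_size forward-pass chunk size.
#' @return list with `per_image` (data frame), `macro` (mean/sd per metric)
#'   and `micro` (metrics of the pooled confusion counts).
#' @export
evaluate_network <- function(net, samples, threshold = 0.5, batch_size = 8L) {
  if (!length(samples)) stop("empty evaluation set", call. = FALSE)
  n <- length(samples)
  rows <- vector("list", n)
  pooled <- list(tp = 0, fp = 0, fn = 0, tn = 0)
  i <- 1L
  while (i <= n) {
    idx <- i:min(i + batch_size - 1L, n)
    st <- stack_samples(samples[idx])
    prob <- net_forward(net, st$x, training = FALSE)
    for (j in seq_along(idx)) {
      cm <- confusion(prob[, , , j, drop = FALSE],
                      st$y[, , , j, drop = FALSE], threshold)
      mt <- seg_metrics(cm)
      pooled <- Map(`+`, pooled, cm)
      id <- samples[[idx[j]]]$meta$path %||% sprintf("sample_%04d", idx[j])
      rows[[idx[j]]] <- data.frame(image_id = basename(as.character(id)),
                                   iou = mt$iou, dsc = mt$dsc,
                                   acc = mt$acc, sen = mt$sen)
    }
    i <- i + batch_size
  }
  per_image <- do.call(rbind, rows)
  macro <- data.frame(
    metric = c("iou", "dsc", "acc", "sen"),
    mean = vapply(c("iou", "dsc", "acc", "sen"),
                  function(m) mean(per_image[[m]], na.rm = TRUE), numeric(1)),
    sd = vapply(c("iou", "dsc", "acc", "sen"),
                function(m) stats::sd(per_image[[m]], na.rm = TRUE), numeric(1)),
    row.names = NULL)
  list(per_image = per_image, macro = macro, micro = seg_metrics(pooled))
}

#' Predict a binary mask for an image file
#'
#' Reads the image, resizes it to the network's input size, runs the
#' forward pass, resizes the probability map back to the original
#' resolution, thresholds it and writes a `{0, 255}` PNG mask.
#'
#' @param net an `afcf_net`.
#' @param image_path input image (PNG/JPEG).
#' @param out_path output PNG path.
#' @param threshold binarization threshold.
#' @return invisibly, the binary mask matrix at the input resolution.
#' @export
predict_mask <- function(net, image_path, out_path, threshold = 0.5) {
  if (!file.exists(image_path))
    stop("cannot read ", image_path, call. = FALSE)
  img <- read_image_array(image_path)
  d <- dim(img)
  sz <- net$cfg$input_size
  x <- resize_image(img, sz[1], sz[2])
  prob <- net_forward(net, array(x, c(sz[1], sz[2], d[3], 1L)))
  prob_full <- resize_plane(array(prob[, , 1L, 1L], sz), d[1], d[2])
  mask <- matrix(as.numeric(prob_full >= threshold), d[1], d[2])
  write_mask_file(mask, out_path)
  invisible(mask)
}
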