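# Combined BCE-Dice training loss and pixel-level evaluation metrics.
#
# The loss is L = L_D + L_B / 2, with L_B the mean binary cross-entropy over
# pixels and L_D the soft Dice loss with squared terms in the denominator:
#   L_B = -(1/N) sum_i [ t_i log p_i + (1 - t_i) log(1 - p_i) ]
#   L_D = 1 - (2 sum_i p_i t_i + delta) / (sum_i p_i^2 + sum_i t_i^2 + delta)
# Probabilities are clipped to [eps, 1 - eps] before the logarithms. A
# rank-4 input is treated as a batch and the loss is the mean of per-image
# losses; lower-rank inputs are treated as a single image.

check_pair <- function(p, t) {
  if (!identical(dim(p) %||% length(p), dim(t) %||% length(t)))
    stop("prediction and target must have identical shape", call. = FALSE)
  if (length(p) == 0L) stop("empty prediction", call. = FALSE)
}

per_image <- function(p, t, f) {
  d <- dim(p)
  if (!is.null(d) && length(d) == 4L && d[4] > 1L) {
    mean(vapply(seq_len(d[4]),
                function(b) f(p[, , , b], t[, , , b]), numeric(1)))
  } else f(p, t)
}

#' Binary cross-entropy loss
#'
#' Mean over pixels of the negative log likelihood of the binary targets,
#' with predictions clipped to `[eps, 1 - eps]`.
#'
#' @param p predicted probabilities in `[0, 1]` (vector or array).
#' @param t binary targets, same shape.
#' @param eps clipping constant (default 1e-7).
#' @return nonnegative scalar.
#' @export
bce_loss <- function(p, t, eps = 1e-7) {
  check_pair(p, t)
  per_image(p, t, function(pi, ti) {
    pc <- pmin(pmax(pi, eps), 1 - eps)
    -mean(ti * log(pc) + (1 - ti) * log(1 - pc))
  })
}

#' Soft Dice loss
#'
#' `1 - (2 sum(p t) + smooth) / (sum(p^2) + sum(t^2) + smooth)`, computed on
#' raw probabilities without thresholding. The default smoothing of 1 keeps
#' the loss defined on empty images; pass `smooth = 0` for the exact
#' closed form.
#'
#' @inheritParams bce_loss
#' @param smooth smoothing constant added to numerator and denominator.
#' @return scalar in `[0, 1]` (up to smoothing).
#' @export
dice_loss <- function(p, t, smooth = 1) {
  check_pair(p, t)
  per_image(p, t, function(pi, ti) {
    1 - (2 * sum(pi * ti) + smooth) / (sum(pi^2) + sum(ti^2) + smooth)
  })
}

#' Combined BCE-Dice loss
#'
#' `dice_loss + bce_loss / 2`, the training objective.
#'
#' @inheritParams dice_loss
#' @param eps clipping constant for the cross-entropy term.
#' @return nonnegative scalar.
#' @export
combined_loss <- function(p, t, smooth = 1, eps = 1e-7) {
  dice_loss(p, t, smooth) + bce_loss(p, t, eps) / 2
}

#' Pixel confusion counts
#'
#' Binarizes the prediction at `threshold` (values >= threshold are
#' positive) and tallies true/false positives/negatives against a binary
#' truth mask.
#'
#' @param pred probability array.
#' @param truth binary array, same shape.
#' @param threshold binarization threshold in (0, 1).
#' @return list with integer fields `tp`, `fp`, `fn`, `tn`.
#' @export
confusion <- function(pred, truth, threshold = 0.5) {
  check_pair(pred, truth)
  if (threshold <= 0 || threshold >= 1)
    stop("`threshold` must lie in (0, 1)", call. = FALSE)
  pos <- pred >= threshold
  tru <- truth > 0.5
  list(tp = sum(pos & tru), fp = sum(pos & !tru),
       fn = sum(!pos & tru), tn = sum(!pos & !tru))
}

#' Segmentation metrics from confusion counts
#'
#' Intersection over union `TP / (TP + FP + FN)`, Dice similarity
#' coefficient `2 TP / (2 TP + FP + FN)`, accuracy and sensitivity. A
#' metric whose denominator is zero is undefined and reported as `NA`
#' rather than 0.
#'
#' @param counts list with `tp`, `fp`, `fn`, `tn` (from [confusion()]).
#' @return list with `iou`, `dsc`, `acc`, `sen`, each in `[0, 1]` or `NA`.
#' @export
seg_metrics <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn; tn <- counts$tn
  safe <- function(num, den) if (den > 0) num / den else NA_real_
  list(iou = safe(tp, tp + fp + fn),
       dsc = safe(2 * tp, 2 * tp + fp + fn),
       acc = safe(tp + tn, tp + tn + fp + fn),
       sen = safe(tp, tp + fn))
}

#' Write metric reports as CSV rows
#'
#' @param reports data frame with columns `image_id`, `iou`, `dsc`, `acc`,
#'   `sen` (as produced by [evaluate_network()]).
#' @param path output CSV file.
#' @return invisibly, `path`.
#' @export
write_metrics_csv <- function(reports, path) {
  utils::write.csv(reports, path, row.names = FALSE)
  invisible(path)
}

# Autograd node for the combined loss: mean over images of
# dice + bce/2, with the analytic gradient w.r.t. the predictions.
ag_bce_dice <- function(pred, target, smooth = 1, eps = 1e-7) {
  pv <- pred$value
  d <- dim(pv)
  B <- d[4]
  n_img <- prod(d[1:3])
  total <- 0
  grad <- array(0, d)
  for (b in seq_len(B)) {
    p <- pv[, , , b]
    t <- target[, , , b]
    pc <- pmin(pmax(p, eps), 1 - eps)
    bce <- -mean(t * log(pc) + (1 - t) * log(1 - pc))
    num <- 2 * sum(p * t) + smooth
    den <- sum(p^2) + sum(t^2) + smooth
    dice <- 1 - num / den
    total <- total + dice + bce / 2
    inrange <- (p > eps) & (p < 1 - eps)
    g_bce <- ((1 - t) / (1 - pc) - t / pc) / n_img * inrange
    g_dice <- -(2 * t) / den + num * 2 * p / den^2
    grad[, , , b] <- (g_dice + g_bce / 2) / B
  }
  loss <- total / B
  ag_op(loss, list(pred), function(g) list(g * grad))
}
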