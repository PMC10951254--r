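# Class-weighted focal loss and segmentation evaluation metrics.
#
# Vessel pixels are a tiny minority of an angiogram (typically a few percent),
# so plain cross-entropy is dominated by background. The training loss is a
# class-weighted focal loss: cross-entropy scaled by the true class weight
# (background 1, vessel 20 by default), modulated by (1 - p_t)^gamma to
# down-weight easy pixels, and scaled by alpha.

EPS_PROB <- 1e-7

#' Focal loss parameters
#'
#' @param alpha Global scale in (0, 1].
#' @param gamma Focusing exponent (>= 0); 0 recovers weighted cross-entropy.
#' @param class_weights Length-2 positive weights (background, vessel).
#' @return A `focal_loss_params` list.
#' @export
focal_loss_params <- function(alpha = 0.8, gamma = 2, class_weights = c(1, 20)) {
  stopifnot(alpha > 0, alpha <= 1, gamma >= 0, length(class_weights) == 2,
            all(class_weights > 0))
  structure(list(alpha = alpha, gamma = gamma, class_weights = class_weights),
            class = "focal_loss_params")
}

# Coerce probs to (H,W,2,N) and target to (H,W,N); return p_t and w_y.
true_class_prob <- function(probs, target, class_weights) {
  if (length(dim(probs)) == 3L) dim(probs) <- c(dim(probs), 1L)
  d <- dim(probs)
  if (is.matrix(target)) dim(target) <- c(dim(target), 1L)
  if (!all(dim(target) == d[c(1, 2, 4)])) stop("probs/target shape mismatch")
  if (!all(target %in% c(0, 1))) stop("target must be binary (0/1)")
  p_vessel <- probs[, , 2, , drop = FALSE]
  dim(p_vessel) <- d[c(1, 2, 4)]
  p_t <- target * p_vessel + (1 - target) * (1 - p_vessel)
  p_t <- pmin(pmax(p_t, EPS_PROB), 1)
  w <- class_weights[1] + (class_weights[2] - class_weights[1]) * target
  list(p_t = p_t, w = w)
}

#' Weighted cross-entropy
#'
#' Per-pixel value \eqn{-w_y \log p_y} where \eqn{y} is the true class and
#' \eqn{w_y} its class weight; the scalar is the plain mean over pixels of the
#' per-pixel weighted values (so the focal loss with `gamma = 0`, `alpha = 1`
#' reduces to it exactly).
#'
#' @param probs Class-probability array (H, W, 2) or (H, W, 2, N); channel 2
#'   is the vessel probability. Probabilities of the true class are clamped
#'   below at 1e-7.
#' @param target Binary mask (H, W) or (H, W, N); 1 = vessel.
#' @param class_weights Length-2 positive weights (background, vessel).
#' @return List with `per_pixel` (array like `target`) and `mean` (scalar).
#' @export
weighted_ce <- function(probs, target, class_weights = c(1, 1)) {
  tc <- true_class_prob(probs, target, class_weights)
  per_pixel <- -tc$w * log(tc$p_t)
  list(per_pixel = per_pixel, mean = mean(per_pixel))
}

#' Class-weighted focal loss
#'
#' Per-pixel loss \eqn{\alpha (1 - p_t)^\gamma \, w_y \, (-\log p_t)},
#' averaged over pixels, where \eqn{p_t} is the predicted probability of the
#' true class. With `literal = TRUE` the modulating factor and logarithm are
#' instead applied to the scalar weighted cross-entropy itself
#' (\eqn{-\alpha (1 - WCE)^\gamma \log(WCE)}), provided for comparison with
#' that alternative reading; the default per-pixel form is the standard one.
#'
#' @inheritParams weighted_ce
#' @param params A [focal_loss_params()].
#' @param literal Apply the modulation to the scalar weighted cross-entropy
#'   instead of the per-pixel true-class probability.
#' @return Scalar loss (>= 0 in the default form).
#' @export
focal_loss <- function(probs, target, params = focal_loss_params(),
                       literal = FALSE) {
  if (literal) {
    wce <- weighted_ce(probs, target, params$class_weights)$mean
    wce <- pmin(pmax(wce, EPS_PROB), 1 - EPS_PROB)
    return(-params$alpha * (1 - wce)^params$gamma * log(wce))
  }
  tc <- true_class_prob(probs, target, params$class_weights)
  mean(params$alpha * (1 - tc$p_t)^params$gamma * tc$w * (-log(tc$p_t)))
}

# Gradient of the (default-form) focal loss w.r.t. the two-class logits.
# logits: (H,W,2,N); target: (H,W,N). Mean-over-pixels reduction.
focal_loss_grad <- function(logits, target, params = focal_loss_params()) {
  d <- dim(logits)
  z1 <- logits[, , 1, , drop = FALSE]
  z2 <- logits[, , 2, , drop = FALSE]
  zm <- pmax(z1, z2)
  e1 <- exp(z1 - zm); e2 <- exp(z2 - zm)
  p2 <- e2 / (e1 + e2)
  dim(p2) <- d[c(1, 2, 4)]
  if (is.matrix(target)) dim(target) <- c(dim(target), 1L)
  p_t <- target * p2 + (1 - target) * (1 - p2)
  p_t <- pmin(pmax(p_t, EPS_PROB), 1 - 1e-12)
  cw <- params$class_weights
  w <- cw[1] + (cw[2] - cw[1]) * target
  a <- params$alpha; g <- params$gamma
  omp <- 1 - p_t
  dldp <- -a * w * (g * omp^pmax(g - 1, 0) * (-log(p_t)) * (g > 0) + omp^g / p_t)
  # dp_t/dz_vessel = +/- p2 (1 - p2); chain to both logits of the softmax pair
  dpdz2 <- (2 * target - 1) * p2 * (1 - p2)
  npix <- prod(d[c(1, 2, 4)])
  dz2 <- dldp * dpdz2 / npix
  out <- array(0, d)
  out[, , 2, ] <- dz2
  out[, , 1, ] <- -dz2
  out
}

#' Dice overlap between two binary masks
#'
#' \eqn{2 |X \cap Y| / (|X| + |Y|)}. Two empty masks score 1 (perfect
#' agreement on absence).
#'
#' @param pred,truth Binary masks of identical shape.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice_score <- function(pred, truth) {
  if (!all(dim(pred) == dim(truth))) stop("mask shape mismatch")
  p <- sum(pred != 0)
  t <- sum(truth != 0)
  if (p + t == 0) return(1)
  2 * sum(pred != 0 & truth != 0) / (p + t)
}

#' Pixel-wise confusion metrics (vessel = positive class)
#'
#' @param pred,truth Binary masks of identical shape.
#' @return List with `sensitivity`, `specificity`, `accuracy`, `precision`
#'   (each in `[0, 1]`, `NA` when its denominator is zero) and the raw counts
#'   `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_metrics <- function(pred, truth) {
  if (!all(dim(pred) == dim(truth))) stop("mask shape mismatch")
  p <- pred != 0
  t <- truth != 0
  tp <- sum(p & t); fp <- sum(p & !t); fn <- sum(!p & t); tn <- sum(!p & !t)
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  list(sensitivity = ratio(tp, tp + fn),
       specificity = ratio(tn, tn + fp),
       accuracy = (tp + tn) / (tp + fp + tn + fn),
       precision = ratio(tp, tp + fp),
       tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Area under the ROC curve (rank statistic)
#'
#' Mann-Whitney U normalized by n1 * n0; tied scores count one half.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary labels (1 = positive), same length.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels != 0)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("auc requires both classes present")
  r <- rank(scores)  # average ranks: ties count 1/2
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Per-image and aggregate segmentation metrics
#'
#' @param preds,truths Lists of binary masks (or single masks), pairwise
#'   identical shapes.
#' @param ids Optional image identifiers.
#' @return A `metrics_report`: data frame `per_image` (dice, accuracy,
#'   sensitivity, specificity, precision) and `aggregate` with mean and SD per
#'   metric (undefined per-image ratios are excluded from aggregation).
#' @export
metrics_report <- function(preds, truths, ids = NULL) {
  if (!is.list(preds)) preds <- list(preds)
  if (!is.list(truths)) truths <- list(truths)
  stopifnot(length(preds) == length(truths))
  if (is.null(ids)) ids <- sprintf("img%03d", seq_along(preds))
  rows <- lapply(seq_along(preds), function(i) {
    cm <- confusion_metrics(preds[[i]], truths[[i]])
    data.frame(id = ids[i], dice = dice_score(preds[[i]], truths[[i]]),
               accuracy = cm$accuracy, sensitivity = cm$sensitivity,
               specificity = cm$specificity, precision = cm$precision,
               stringsAsFactors = FALSE)
  })
  per_image <- do.call(rbind, rows)
  metric_cols <- c("dice", "accuracy", "sensitivity", "specificity", "precision")
  aggregate <- data.frame(
    metric = metric_cols,
    mean = vapply(metric_cols, function(m) mean(per_image[[m]], na.rm = TRUE), 0),
    sd = vapply(metric_cols, function(m) stats::sd(per_image[[m]], na.rm = TRUE), 0),
    row.names = NULL)
  structure(list(per_image = per_image, aggregate = aggregate),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report>", nrow(x$per_image), "image(s)\n")
  agg <- x$aggregate
  for (i in seq_len(nrow(agg))) {
    cat(sprintf("  %-12s %.4f (SD %.4f)\n", agg$metric[i], agg$mean[i],
                if (is.na(agg$sd[i])) 0 else agg$sd[i]))
  }
  invisible(x)
}

#' Write a metrics report to JSON and/or CSV
#'
#' The CSV holds one row per image plus an aggregate row; the JSON mirrors the
#' report structure.
#'
#' @param report A [metrics_report()].
#' @param json_path,csv_path Output paths (either may be `NULL`).
#' @return Invisibly, the report.
#' @export
write_metrics_report <- function(report, json_path = NULL, csv_path = NULL) {
  if (!is.null(json_path)) {
    jsonlite::write_json(list(per_image = report$per_image,
                              aggregate = report$aggregate),
                         json_path, auto_unbox = TRUE, digits = NA, na = "null")
  }
  if (!is.null(csv_path)) {
    per <- report$per_image
    agg <- per[0, ]
    means <- setNames(as.list(report$aggregate$mean), report$aggregate$metric)
    agg[1, names(means)] <- means
    agg$id <- "aggregate_mean"
    utils::write.csv(rbind(per, agg), csv_path, row.names = FALSE)
  }
  invisible(report)
}
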