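# Study protocol: 80/20 split plus five-fold cross-validation, and the
# preprocess -> classify side -> route-to-segmenter inference pipeline.

#' Held-out test split plus k-fold partition
#'
#' Deterministic given `seed`. When `patient` ids are supplied, all images of
#' one patient land in the same split (no leakage across frames); otherwise
#' splitting is image-level. Fold sizes differ by at most one unit.
#'
#' @param image_ids Character or integer ids.
#' @param test_fraction Fraction held out for the final test set.
#' @param k Number of cross-validation folds over the remainder.
#' @param seed Integer seed.
#' @param patient Optional patient id per image.
#' @param test_n Optional explicit test-set size (units), overriding
#'   `test_fraction` (useful when a protocol states exact counts).
#' @return A `fold_split`: list with `test_ids` and `folds` (list of k
#'   disjoint id vectors partitioning the non-test ids).
#' @export
make_splits <- function(image_ids, test_fraction = 0.2, k = 5L, seed = 1L,
                        patient = NULL, test_n = NULL) {
  n <- length(image_ids)
  if (n < k + 1) stop("need at least k + 1 images")
  if (anyDuplicated(image_ids)) stop("image_ids must be unique")
  units <- if (is.null(patient)) as.character(image_ids)
           else unique(as.character(patient))
  old <- rng_push(seed)
  on.exit(rng_pop(old))
  units <- sample(units)
  nu <- length(units)
  n_test <- if (is.null(test_n)) floor(test_fraction * nu) else as.integer(test_n)
  if (n_test < 0 || n_test > nu - k) stop("invalid test size")
  test_units <- units[seq_len(n_test)]
  rest <- units[setdiff(seq_len(nu), seq_len(n_test))]
  fold_of <- rep(seq_len(k), length.out = length(rest))
  unit_folds <- split(rest, fold_of)
  to_ids <- function(u) {
    if (is.null(patient)) u
    else as.character(image_ids)[as.character(patient) %in% u]
  }
  structure(list(test_ids = to_ids(test_units),
                 folds = lapply(unit_folds, to_ids),
                 seed = seed, k = as.integer(k)),
            class = "fold_split")
}

#' Five-fold cross-validation of the segmenter
#'
#' Each fold is held out once for validation while the others train a fresh
#' model; reports per-fold validation metrics and their mean/SD.
#'
#' @param data Named list of training samples (names are image ids), each
#'   `list(x, y)`; see [samples_to_data()].
#' @param seg_config A [seg_model_config()] used to build each fold's model.
#' @param config A [train_config()]; `config$folds` folds are used.
#' @param split Optional precomputed [make_splits()] over `names(data)`
#'   (its test ids are excluded). Default: a fresh split with no test set.
#' @param model_factory Function(fold_index) returning a model; defaults to
#'   `build_se_regunet(seg_config)`. Injectable for protocol tests.
#' @param trainer Function(model, train_data, val_data, config) returning
#'   `list(model, history)`; defaults to [train_segmenter()].
#' @param predict_fun Function(model, sample) returning a binary mask for one
#'   validation sample; defaults to thresholded [predict_prob()]. Injectable
#'   for protocol plumbing tests.
#' @return List of per-fold results `list(model, report, val_ids)` with
#'   attribute `aggregate` (mean/SD data frame across folds).
#' @export
cross_validate <- function(data, seg_config, config = train_config(),
                           split = NULL, model_factory = NULL,
                           trainer = train_segmenter,
                           predict_fun = NULL) {
  if (is.null(predict_fun)) {
    predict_fun <- function(model, sample) {
      prob_to_mask(predict_prob(model, sample$x))
    }
  }
  ids <- names(data)
  if (is.null(ids)) stop("data must be a named list (names = image ids)")
  if (is.null(split)) {
    split <- make_splits(ids, test_fraction = 0, k = config$folds,
                         seed = config$seed)
  }
  if (is.null(model_factory)) {
    model_factory <- function(i) build_se_regunet(seg_config,
                                                  init_seed = config$seed + i)
  }
  folds <- split$folds
  results <- lapply(seq_along(folds), function(i) {
    val_ids <- folds[[i]]
    train_ids <- setdiff(unlist(folds[-i]), split$test_ids)
    model <- model_factory(i)
    fit <- trainer(model, data[train_ids], data[val_ids], config)
    preds <- lapply(data[val_ids], function(s) predict_fun(fit$model, s))
    truths <- lapply(data[val_ids], `[[`, "y")
    list(model = fit$model, history = fit$history,
         report = metrics_report(preds, truths, ids = val_ids),
         val_ids = val_ids)
  })
  per_fold <- do.call(rbind, lapply(seq_along(results), function(i) {
    agg <- results[[i]]$report$aggregate
    data.frame(fold = i, metric = agg$metric, mean = agg$mean)
  }))
  agg <- do.call(rbind, lapply(split(per_fold, per_fold$metric), function(d) {
    data.frame(metric = d$metric[1], mean = mean(d$mean), sd = stats::sd(d$mean))
  }))
  attr(results, "aggregate") <- agg[order(match(agg$metric,
    c("dice", "accuracy", "sensitivity", "specificity", "precision"))), ]
  results
}

#' Bundle the routing classifier with per-side segmentation models
#'
#' @param classifier From [train_classifier()]/[build_classifier()].
#' @param lca_model,rca_model Segmentation models (may be the same object).
#' @param params A [preprocess_params()].
#' @return A `model_bundle` list.
#' @export
model_bundle <- function(classifier, lca_model, rca_model = lca_model,
                         params = preprocess_params()) {
  structure(list(classifier = classifier, lca_model = lca_model,
                 rca_model = rca_model, params = params),
            class = "model_bundle")
}

resize_channels <- function(x, h, w) {
  d <- dim(x)
  if (d[1] == h && d[2] == w) return(x)
  out <- array(0, c(h, w, d[3]))
  for (k in seq_len(d[3])) {
    out[, , k] <- EBImage::imageData(EBImage::resize(EBImage::Image(x[, , k]),
                                                     w = h, h = w,
                                                     filter = "bilinear"))
  }
  out
}

#' End-to-end inference on one angiogram
#'
#' Preprocess, classify the coronary side, route to that side's segmentation
#' model, and return the mask at the input resolution (probabilities are
#' computed at the model's input size and resampled back when needed).
#'
#' @param img Matrix or [angiogram()].
#' @param bundle A [model_bundle()].
#' @param truth Optional ground-truth mask for metrics.
#' @return A `segmentation_result`: `side`, `side_prob` (probability of the
#'   chosen side), `prob_map` (H, W, 2), `mask` (binary, input resolution),
#'   and `metrics` (a [metrics_report()], when truth is given).
#' @export
infer <- function(img, bundle, truth = NULL) {
  px <- as_pixels(img)
  pp <- unclass(preprocess_pipeline(px, bundle$params))
  if (max(pp) > 1) pp <- pp / 255
  attributes(pp) <- list(dim = dim(pp))
  H <- dim(pp)[1]; W <- dim(pp)[2]

  cls <- bundle$classifier
  cs <- cls$config$input_size
  p_lca <- predict_side_prob(cls, resize_channels(pp, cs, cs))
  side <- if (p_lca >= 0.5) "LCA" else "RCA"
  seg <- if (side == "LCA") bundle$lca_model else bundle$rca_model
  if (is.null(seg)) stop("no segmentation model available for side ", side)

  ss <- seg$config$input_size
  prob_small <- predict_prob(seg, resize_channels(pp, ss, ss))[, , , 1]
  prob <- resize_channels(prob_small, H, W)
  # renormalize after resampling
  tot <- prob[, , 1] + prob[, , 2]
  prob[, , 1] <- prob[, , 1] / tot
  prob[, , 2] <- prob[, , 2] / tot
  mask <- prob_to_mask(prob)
  metrics <- if (!is.null(truth)) metrics_report(mask, truth) else NULL
  structure(list(side = side,
                 side_prob = if (side == "LCA") p_lca else 1 - p_lca,
                 prob_map = prob, mask = mask, metrics = metrics),
            class = "segmentation_result")
}

#' Save / load a model (weights + config snapshot)
#'
#' Weights and buffers are serialized to an RDS file; the architecture and
#' training configuration snapshot is written alongside as YAML for human
#' inspection.
#'
#' @param model A model object.
#' @param path Output path (`.rds`).
#' @return `save_model`: the path, invisibly. `load_model`: the model.
#' @export
save_model <- function(model, path) {
  obj <- list(type = model$type, config = unclass(model$config),
              params = model$graph$params, buffers = model$graph$buffers)
  saveRDS(obj, path)
  yaml::write_yaml(list(type = model$type, config = unclass(model$config)),
                   paste0(tools::file_path_sans_ext(path), ".yaml"))
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  cfg <- structure(obj$config, class = "seg_model_config")
  model <- switch(obj$type,
    segmenter = build_se_regunet(cfg, init_seed = NULL),
    classifier = build_classifier(cfg, init_seed = NULL),
    encoder = build_encoder(cfg),
    stop("unknown model type in file: ", obj$type))
  model$graph$params <- obj$params
  model$graph$buffers <- obj$buffers
  model
}
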