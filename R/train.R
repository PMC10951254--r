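# Training: AdamW-based optimization with linear warm-up, cosine decay and
# gradient centralization (the headline components of the Ranger21-style
# composite optimizer), plus plain AdamW; epoch loops for the segmenter and
# the left/right classifier.

#' Training configuration
#'
#' Defaults mirror the full-scale study protocol (200 epochs, batch 8,
#' 512 px, learning rate 1e-3, five folds); desk-scale experiments override
#' epochs/batch/input_size. The `"ranger21_style"` optimizer is AdamW plus
#' linear warm-up, cosine decay and gradient centralization.
#'
#' @param epochs,batch_size,input_size,lr,folds,seed Protocol knobs.
#' @param optimizer `"ranger21_style"` or `"adamw"`.
#' @param loss A [focal_loss_params()].
#' @param weight_decay Decoupled weight decay on convolution kernels.
#' @param warmup_frac Fraction of total steps spent in linear warm-up.
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 200L, batch_size = 8L, input_size = 512L,
                         lr = 0.001, optimizer = "ranger21_style",
                         folds = 5L, seed = 1L, loss = focal_loss_params(),
                         weight_decay = 1e-4, warmup_frac = 0.1) {
  stopifnot(epochs >= 1, batch_size >= 1, folds >= 2, lr > 0,
            optimizer %in% c("ranger21_style", "adamw"))
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 input_size = as.integer(input_size), lr = lr,
                 optimizer = optimizer, folds = as.integer(folds),
                 seed = as.integer(seed), loss = loss,
                 weight_decay = weight_decay, warmup_frac = warmup_frac),
            class = "train_config")
}

make_optimizer <- function(model, config, total_steps) {
  st <- new.env(parent = emptyenv())
  st$t <- 0L
  st$m <- list(); st$v <- list()
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  gc_on <- config$optimizer == "ranger21_style"
  warm <- if (gc_on) max(1L, round(config$warmup_frac * total_steps)) else 0L
  step <- function(grads) {
    st$t <- st$t + 1L
    lr_t <- config$lr
    if (gc_on) {
      if (st$t <= warm) {
        lr_t <- config$lr * st$t / warm
      } else if (total_steps > warm) {
        prog <- (st$t - warm) / (total_steps - warm)
        lr_t <- config$lr * 0.5 * (1 + cos(pi * min(prog, 1)))
      }
    }
    g <- model$graph
    for (id in seq_along(grads$grads)) {
      gr <- grads$grads[[id]]
      if (is.null(gr)) next
      node <- g$nodes[[id]]
      for (pn in names(gr)) {
        gcur <- gr[[pn]]
        if (gc_on && pn == "w" && length(dim(gcur)) == 4L) {
          # gradient centralization: zero-mean per output filter
          d <- dim(gcur)
          fl <- prod(d[1:3])
          gm <- .colSums(gcur, fl, d[4]) / fl
          gcur <- gcur - rep(gm, each = fl)
          dim(gcur) <- d
        }
        key <- paste0(id, ".", pn)
        if (is.null(st$m[[key]])) {
          st$m[[key]] <- gcur * 0
          st$v[[key]] <- gcur * 0
        }
        st$m[[key]] <- beta1 * st$m[[key]] + (1 - beta1) * gcur
        st$v[[key]] <- beta2 * st$v[[key]] + (1 - beta2) * gcur^2
        mhat <- st$m[[key]] / (1 - beta1^st$t)
        vhat <- st$v[[key]] / (1 - beta2^st$t)
        upd <- mhat / (sqrt(vhat) + eps)
        p <- g$params[[id]][[pn]]
        if (pn == "w") upd <- upd + config$weight_decay * p
        g$params[[id]][[pn]] <- p - lr_t * upd
      }
    }
    invisible(lr_t)
  }
  list(step = step, state = st)
}

# Assemble a batch: xs list of (H,W,3) arrays in [0,1] -> (H,W,3,N)
stack_batch <- function(xs) {
  d <- dim(xs[[1]])
  out <- array(0, c(d[1], d[2], d[3], length(xs)))
  for (i in seq_along(xs)) out[, , , i] <- xs[[i]]
  out
}

stack_masks <- function(ms) {
  d <- dim(ms[[1]])
  array(unlist(ms, use.names = FALSE), c(d[1], d[2], length(ms)))
}

snapshot_params <- function(model) {
  list(params = model$graph$params, buffers = model$graph$buffers)
}

restore_params <- function(model, snap) {
  model$graph$params <- snap$params
  model$graph$buffers <- snap$buffers
  invisible(model)
}

#' Train a segmentation model
#'
#' Runs exactly `config$epochs` epochs of focal-loss training; records train
#' loss and validation Dice per epoch and retains the weights of the
#' best-validation-Dice epoch. Reproducible given config seed and data.
#'
#' @param model From [build_se_regunet()].
#' @param train_data List of samples, each `list(x = (H,W,3) array in [0,1],
#'   y = binary mask matrix)`; see [samples_to_data()].
#' @param val_data Like `train_data` (may be `NULL`).
#' @param config A [train_config()].
#' @param verbose Print per-epoch progress.
#' @return List with `model` (best-validation weights when validation data is
#'   given, else final), `history` (data frame epoch/train_loss/val_dice).
#' @export
train_segmenter <- function(model, train_data, val_data = NULL,
                            config = train_config(), verbose = FALSE) {
  if (length(train_data) == 0) stop("empty training set")
  old <- rng_push(config$seed)
  on.exit(rng_pop(old))
  n <- length(train_data)
  steps_per_epoch <- ceiling(n / config$batch_size)
  opt <- make_optimizer(model, config, steps_per_epoch * config$epochs)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_dice = numeric(0))
  best <- -Inf
  best_snap <- NULL
  for (ep in seq_len(config$epochs)) {
    ord <- sample(n)
    losses <- numeric(0)
    for (s in seq_len(steps_per_epoch)) {
      take <- ord[((s - 1) * config$batch_size + 1):min(s * config$batch_size, n)]
      xb <- stack_batch(lapply(train_data[take], `[[`, "x"))
      yb <- stack_masks(lapply(train_data[take], `[[`, "y"))
      pass <- nn_forward(model, xb, training = TRUE)
      probs <- softmax_channels(pass$out)
      loss <- focal_loss(probs, yb, config$loss)
      if (!is.finite(loss)) {
        stop("non-finite loss at epoch ", ep, ", step ", s,
             " (images ", paste(take, collapse = ","), ")")
      }
      losses <- c(losses, loss)
      dout <- focal_loss_grad(pass$out, yb, config$loss)
      grads <- nn_backward(model, pass, dout)
      opt$step(grads)
    }
    vd <- NA_real_
    if (!is.null(val_data) && length(val_data)) {
      vd <- mean(vapply(val_data, function(s) {
        pr <- predict_prob(model, s$x)
        dice_score(prob_to_mask(pr), s$y)
      }, 0))
      if (vd > best) {
        best <- vd
        best_snap <- snapshot_params(model)
      }
    }
    history <- rbind(history, data.frame(epoch = ep,
                                         train_loss = mean(losses),
                                         val_dice = vd))
    if (verbose) {
      message(sprintf("epoch %d/%d: loss %.4f val_dice %s", ep, config$epochs,
                      mean(losses), ifelse(is.na(vd), "-", sprintf("%.4f", vd))))
    }
  }
  if (!is.null(best_snap)) restore_params(model, best_snap)
  list(model = model, history = history)
}

#' Binarize a probability map
#'
#' Argmax over the class channel (equivalently, vessel probability > 0.5 for
#' two classes).
#'
#' @param prob Array (H, W, 2) or (H, W, 2, 1) of class probabilities.
#' @return Binary matrix (1 = vessel).
#' @export
prob_to_mask <- function(prob) {
  if (length(dim(prob)) == 4L) prob <- prob[, , , 1]
  (prob[, , 2] > prob[, , 1]) * 1L
}

#' Train the left/right coronary classifier
#'
#' Binary cross-entropy on the LCA logit with the same optimizer family as
#' the segmenter.
#'
#' @param model From [build_classifier()].
#' @param train_data List of samples `list(x = (H,W,3) array, side = "LCA"/"RCA")`.
#' @param val_data Like `train_data` (may be `NULL`).
#' @param config A [train_config()].
#' @param verbose Print per-epoch progress.
#' @return List with `model`, `history` (epoch/train_loss/val_auc).
#' @export
train_classifier <- function(model, train_data, val_data = NULL,
                             config = train_config(), verbose = FALSE) {
  if (length(train_data) == 0) stop("empty training set")
  old <- rng_push(config$seed)
  on.exit(rng_pop(old))
  n <- length(train_data)
  steps_per_epoch <- ceiling(n / config$batch_size)
  opt <- make_optimizer(model, config, steps_per_epoch * config$epochs)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_auc = numeric(0))
  for (ep in seq_len(config$epochs)) {
    ord <- sample(n)
    losses <- numeric(0)
    for (s in seq_len(steps_per_epoch)) {
      take <- ord[((s - 1) * config$batch_size + 1):min(s * config$batch_size, n)]
      xb <- stack_batch(lapply(train_data[take], `[[`, "x"))
      y <- as.numeric(vapply(train_data[take], `[[`, "", "side") == "LCA")
      pass <- nn_forward(model, xb, training = TRUE)
      z <- as.vector(pass$out)
      p <- 1 / (1 + exp(-z))
      pc <- pmin(pmax(p, 1e-7), 1 - 1e-7)
      loss <- mean(-y * log(pc) - (1 - y) * log(1 - pc))
      if (!is.finite(loss)) stop("non-finite loss at epoch ", ep, ", step ", s)
      losses <- c(losses, loss)
      dz <- array((p - y) / length(y), dim = dim(pass$out))
      grads <- nn_backward(model, pass, dz)
      opt$step(grads)
    }
    va <- NA_real_
    if (!is.null(val_data) && length(val_data)) {
      scores <- vapply(val_data, function(s) predict_side_prob(model, s$x), 0)
      labels <- vapply(val_data, `[[`, "", "side") == "LCA"
      va <- if (length(unique(labels)) > 1) auc_score(scores, labels) else NA_real_
    }
    history <- rbind(history, data.frame(epoch = ep, train_loss = mean(losses),
                                         val_auc = va))
    if (verbose) {
      message(sprintf("epoch %d/%d: loss %.4f val_auc %s", ep, config$epochs,
                      mean(losses), ifelse(is.na(va), "-", sprintf("%.4f", va))))
    }
  }
  list(model = model, history = history)
}

#' Convert synthetic samples to model-ready training data
#'
#' Applies the enhancement pipeline to each sample image, scales to `[0, 1]`,
#' and pairs it with its mask and side label.
#'
#' @param samples List of `synthetic_sample` objects (or any list with
#'   `image`, `mask`, `side`).
#' @param params A [preprocess_params()].
#' @return List of `list(x, y, side)` training samples.
#' @export
samples_to_data <- function(samples, params = preprocess_params()) {
  lapply(samples, function(s) {
    pp <- unclass(preprocess_pipeline(s$image, params))
    if (max(pp) > 1) pp <- pp / 255
    attributes(pp) <- list(dim = dim(pp))
    list(x = pp, y = s$mask, side = s$side)
  })
}
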