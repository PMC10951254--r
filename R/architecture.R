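# Segmentation architecture: RegNet-style encoder, U-Net decoder with
# squeeze-and-excitation gating, two-class softmax head; plus the binary
# left/right-coronary classifier and an analytic parameter/FLOP profiler.

#' Segmentation model configuration
#'
#' @param backbone Encoder preset: `"regnetz_4gf"`, `"regnety_16gf"`, or
#'   `"tiny"` (a desk-scale encoder for CPU experiments).
#' @param input_size Nominal square input side in pixels. Must be divisible by
#'   the encoder's total stride (32 for the RegNet presets, 16 for `"tiny"`).
#' @param num_classes Output classes (2: background, vessel).
#' @param decoder_channels Optional integer vector of decoder stage widths,
#'   deepest first, one per skip connection. Default: the deepest encoder
#'   width divided by 2, 4, 8, ... per stage.
#' @param decoder_scale Multiplier applied to the default decoder widths
#'   (e.g. `0.25` for a reduced-width model).
#' @param se_reduction Squeeze-and-excitation bottleneck reduction ratio.
#' @return A `seg_model_config` list.
#' @export
seg_model_config <- function(backbone = "regnetz_4gf", input_size = 512L,
                             num_classes = 2L, decoder_channels = NULL,
                             decoder_scale = 1, se_reduction = 16L) {
  enc <- regnet_config(backbone)
  if (input_size %% enc$total_stride != 0L) {
    stop("input_size must be divisible by the encoder total stride (",
         enc$total_stride, ")")
  }
  n_skip <- length(enc$widths)  # stem + all stages but the deepest
  c5 <- enc$widths[length(enc$widths)]
  if (is.null(decoder_channels)) {
    decoder_channels <- floor(c5 / 2^seq_len(n_skip) * decoder_scale)
  }
  decoder_channels <- pmax(2L, as.integer(decoder_channels))
  if (length(decoder_channels) != n_skip) {
    stop("decoder_channels must have one width per skip connection (",
         n_skip, ")")
  }
  final_w <- max(2L, as.integer(floor(c5 / 2^(n_skip + 1) * decoder_scale)))
  structure(list(backbone = backbone, input_size = as.integer(input_size),
                 in_channels = 3L, num_classes = as.integer(num_classes),
                 decoder_channels = decoder_channels, final_channels = final_w,
                 se_reduction = as.integer(se_reduction),
                 total_stride = enc$total_stride),
            class = "seg_model_config")
}

new_model <- function(graph, out_id, config, type, ...) {
  structure(c(list(graph = graph, out_id = out_id, config = config,
                   type = type), list(...)),
            class = "angio_model")
}

#' @export
print.angio_model <- function(x, ...) {
  cat("<angio_model> type:", x$type, " backbone:", x$config$backbone,
      " params:", format(count_parameters(x), big.mark = ","), "\n")
  invisible(x)
}

#' Build a RegNet-style encoder
#'
#' The encoder emits a feature pyramid at strides 2, 4, 8, ... relative to the
#' input, halving spatial size and growing channel width per stage. Run it
#' with [encoder_forward()].
#'
#' @param config A [seg_model_config()].
#' @return An encoder model object.
#' @export
build_encoder <- function(config) {
  cfg <- regnet_config(config$backbone)
  g <- nn_graph()
  x <- nn_add(g, "input", channels = 3L)
  enc <- g_encoder(g, x, cfg)
  new_model(g, enc$features[length(enc$features)], config, "encoder",
            input_id = x, feature_ids = enc$features,
            feature_widths = enc$widths)
}

#' Run an encoder, returning the feature pyramid
#'
#' @param encoder From [build_encoder()]. Must be initialized (weights are
#'   allocated lazily by [build_se_regunet()]; for a bare encoder call
#'   `angioseg:::nn_init_params(encoder, seed)` or train it).
#' @param x Input array of dim (H, W, 3) or (H, W, 3, N), values in `[0, 1]`.
#' @return List of feature arrays, shallowest (stride 2) first.
#' @export
encoder_forward <- function(encoder, x) {
  x <- as_batch(x, 3L)
  pass <- nn_forward(encoder, x, training = FALSE)
  pass$acts[encoder$feature_ids]
}

g_decode_block <- function(g, x, c_in, skip, c_skip, width, se_r) {
  h <- nn_add(g, "up2", x)
  h <- nn_add(g, "concat", c(h, skip))
  h <- g_conv_bn(g, h, c_in + c_skip, width, k = 3L, act = "relu")
  h <- g_conv_bn(g, h, width, width, k = 3L, act = "relu")
  g_se(g, h, width, max(1L, width %/% se_r))
}

#' Build the squeeze-and-excitation RegNet U-Net segmentation model
#'
#' Encoder features at each stride feed a U-Net decoder whose blocks are two
#' 3x3 conv + batch-norm + ReLU layers followed by a squeeze-and-excitation
#' gate; a final x2 upsampling restores full resolution and a 1x1 convolution
#' produces two-class logits. [predict_prob()] applies the softmax head.
#'
#' @param config A [seg_model_config()].
#' @param init_seed Seed for weight initialization (set `NULL` to defer
#'   allocation, e.g. when only profiling complexity).
#' @return A segmentation model object.
#' @export
build_se_regunet <- function(config = seg_model_config(), init_seed = 1L) {
  cfg <- regnet_config(config$backbone)
  g <- nn_graph()
  x <- nn_add(g, "input", channels = 3L)
  enc <- g_encoder(g, x, cfg)
  n <- length(enc$features)
  h <- enc$features[n]
  c_prev <- enc$widths[n]
  skips <- rev(enc$features[-n])
  skip_w <- rev(enc$widths[-n])
  for (i in seq_along(skips)) {
    w <- config$decoder_channels[i]
    h <- g_decode_block(g, h, c_prev, skips[i], skip_w[i], w,
                        config$se_reduction)
    c_prev <- w
  }
  h <- nn_add(g, "up2", h)
  h <- g_conv_bn(g, h, c_prev, config$final_channels, k = 3L, act = "relu")
  h <- nn_add(g, "conv", h, k = 1L, stride = 1L, pad = 0L, groups = 1L,
              cin = config$final_channels, cout = config$num_classes,
              bias = TRUE)
  m <- new_model(g, h, config, "segmenter", input_id = x)
  if (!is.null(init_seed)) nn_init_params(m, init_seed)
  m
}

#' Build the left/right coronary artery classifier
#'
#' Encoder backbone, global average pooling, and a linear head producing the
#' probability that the image shows a left coronary tree.
#'
#' @param config A [seg_model_config()]; only the backbone is used.
#' @param init_seed Seed for weight initialization.
#' @return A classifier model object.
#' @export
build_classifier <- function(config = seg_model_config(), init_seed = 1L) {
  cfg <- regnet_config(config$backbone)
  g <- nn_graph()
  x <- nn_add(g, "input", channels = 3L)
  enc <- g_encoder(g, x, cfg)
  deep <- enc$features[length(enc$features)]
  cw <- enc$widths[length(enc$widths)]
  h <- nn_add(g, "gap", deep)
  h <- nn_add(g, "conv", h, k = 1L, stride = 1L, pad = 0L, groups = 1L,
              cin = cw, cout = 1L, bias = TRUE)
  m <- new_model(g, h, config, "classifier", input_id = x)
  if (!is.null(init_seed)) nn_init_params(m, init_seed)
  m
}

# Coerce (H,W,C) or (H,W,C,N) input to a 4-D batch with C channels.
as_batch <- function(x, channels) {
  d <- dim(x)
  if (length(d) == 3L) dim(x) <- c(d, 1L)
  d <- dim(x)
  if (length(d) != 4L || d[3] != channels) {
    stop("expected input of dim (H, W, ", channels, "[, N])")
  }
  x
}

check_input_size <- function(model, x) {
  d <- dim(x)
  st <- model$config$total_stride
  if (d[1] %% st != 0L || d[2] %% st != 0L) {
    stop("input size ", d[1], "x", d[2],
         " must be divisible by the encoder total stride (", st, ")")
  }
}

#' Per-pixel class probabilities from a segmentation model
#'
#' Runs the model in evaluation mode and applies the softmax head, so each
#' pixel's probabilities lie in `[0, 1]` and sum to 1.
#'
#' @param model A segmentation model from [build_se_regunet()].
#' @param x Input array (H, W, 3) or (H, W, 3, N), values in `[0, 1]`.
#' @return Array (H, W, num_classes, N) of class probabilities.
#' @export
predict_prob <- function(model, x) {
  stopifnot(model$type == "segmenter")
  x <- as_batch(x, 3L)
  check_input_size(model, x)
  logits <- nn_forward(model, x, training = FALSE)$out
  softmax_channels(logits)
}

softmax_channels <- function(z) {
  d <- dim(z)
  C <- d[3]
  sl <- lapply(seq_len(C), function(k) {
    s <- z[, , k, , drop = FALSE]
    dim(s) <- d[c(1, 2, 4)]
    s
  })
  zm <- Reduce(pmax, sl)
  es <- lapply(sl, function(s) exp(s - zm))
  tot <- Reduce(`+`, es)
  out <- array(0, d)
  for (k in seq_len(C)) out[, , k, ] <- es[[k]] / tot
  out
}

#' Probability of the left coronary class from a classifier model
#'
#' @param model From [build_classifier()].
#' @param x Input array (H, W, 3) or (H, W, 3, N), values in `[0, 1]`.
#' @return Numeric vector (one probability per image) in `[0, 1]`.
#' @export
predict_side_prob <- function(model, x) {
  stopifnot(model$type == "classifier")
  x <- as_batch(x, 3L)
  check_input_size(model, x)
  logit <- nn_forward(model, x, training = FALSE)$out
  as.vector(1 / (1 + exp(-logit)))
}

#' Standalone squeeze-and-excitation block
#'
#' Gates each channel of a feature map by a scalar in (0, 1) computed from a
#' global-average-pool / bottleneck / sigmoid chain. Exposed mainly for
#' testing the channel-attention arithmetic; the builders embed the same
#' computation in the network graph.
#'
#' @param x Feature array (H, W, C) or (H, W, C, N).
#' @param reduction Bottleneck reduction ratio r; the hidden width is
#'   `max(1, C / r)` (rounded up).
#' @param weights Optional list(w1, b1, w2, b2) with w1 (C x Cmid),
#'   b1 (Cmid), w2 (Cmid x C), b2 (C). Random Gaussian weights if omitted.
#' @param seed Seed for the random weights when `weights` is `NULL`.
#' @return List with `out` (gated features, same shape as `x`) and `gate`
#'   (matrix C x N of per-channel gate values).
#' @export
se_block <- function(x, reduction = 16L, weights = NULL, seed = 1L) {
  d3 <- length(dim(x)) == 3L
  x <- as_batch(x, dim(x)[3])
  d <- dim(x)
  C <- d[3]; N <- d[4]
  c_mid <- max(1L, as.integer(ceiling(C / reduction)))
  if (is.null(weights)) {
    old <- rng_push(seed)
    on.exit(rng_pop(old))
    weights <- list(w1 = matrix(stats::rnorm(C * c_mid, sd = sqrt(2 / C)), C, c_mid),
                    b1 = numeric(c_mid),
                    w2 = matrix(stats::rnorm(c_mid * C, sd = sqrt(2 / c_mid)), c_mid, C),
                    b2 = numeric(C))
  }
  pooled <- matrix(.colSums(x, d[1] * d[2], C * N) / (d[1] * d[2]), C, N)
  h <- pmax(crossprod(weights$w1, pooled) + weights$b1, 0)   # Cmid x N
  gate <- 1 / (1 + exp(-(crossprod(weights$w2, h) + weights$b2)))  # C x N
  out <- x * cn_bcast(as.vector(gate), d)
  if (d3) dim(out) <- d[1:3]
  list(out = out, gate = gate)
}

# ---- complexity profiling ---------------------------------------------------

#' Analytic parameter and FLOP profile of a model
#'
#' Counts trainable parameters exactly and multiply-accumulate operations of
#' one forward pass at the given input size, walking the network graph
#' (convolution and linear layers only; one multiply-accumulate is counted as
#' one FLOP, the convention under which the encoder presets carry their
#' "gigaflop" names at 224 pixels).
#'
#' @param model A built model (weights need not be allocated).
#' @param input_size Square input side in pixels.
#' @return A `complexity_report` list: `trainable_parameters`, `flops`
#'   (raw MAC count), `gflops`, `params_million`, `model_size_mb` (fp32).
#' @export
profile_complexity <- function(model, input_size = model$config$input_size) {
  g <- model$graph
  shapes <- graph_shapes(g, c(input_size, input_size))
  macs <- 0
  params <- 0
  for (node in g$nodes) {
    ps <- node_param_shapes(node)
    if (!is.null(ps)) params <- params + sum(vapply(ps, prod, 0))
    if (node$op == "conv") {
      os <- shapes[[node$id]]
      macs <- macs + node$k^2 * (node$cin / node$groups) * node$cout *
        os[1] * os[2]
    }
  }
  structure(list(trainable_parameters = params,
                 params_million = params / 1e6,
                 flops = macs,
                 gflops = macs / 1e9,
                 model_size_mb = params * 4 / 2^20,
                 input_size = as.integer(input_size),
                 backbone = model$config$backbone),
            class = "complexity_report")
}

#' @export
print.complexity_report <- function(x, ...) {
  cat(sprintf("<complexity_report> %s @ %dpx: %.1fM params, %.1f GFLOPs, %.1f MB\n",
              x$backbone, x$input_size, x$params_million, x$gflops,
              x$model_size_mb))
  invisible(x)
}
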