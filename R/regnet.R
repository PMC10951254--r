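# RegNet-style encoder configurations.
#
# Stage widths and depths are generated from the quantized linear
# parameterization of the RegNet design space: per-block widths
# u_j = w0 + wa * j are snapped to the geometric grid w0 * wm^s, rounded to
# multiples of 8, grouped into stages of equal width, and finally adjusted for
# compatibility with the group width of the 3x3 convolution.

regnet_stage_plan <- function(depth, w0, wa, wm, group_w, bottle_ratio) {
  u <- w0 + wa * (seq_len(depth) - 1)
  s <- round(log(u / w0) / log(wm))
  w <- round(w0 * wm^s / 8) * 8
  r <- rle(w)
  ws <- r$values
  ds <- r$lengths
  # adjust widths/groups for divisibility of the bottleneck width
  wb <- round(ws * bottle_ratio)
  gs <- pmin(group_w, wb)
  wb <- round(wb / gs) * gs
  ws <- round(wb / bottle_ratio)
  list(widths = as.integer(ws), depths = as.integer(ds),
       bottleneck_widths = as.integer(wb), group_widths = as.integer(gs))
}

# Named presets. "regnety_16gf" is the classic Y-family 16-gigaflop design
# (residual bottleneck, squeeze-and-excitation, ReLU); "regnetz_4gf" is the
# Z-family 4-gigaflop design (inverted bottleneck x4, squeeze-and-excitation,
# SiLU, no projection shortcut). "tiny" is a desk-scale encoder with the same
# stage topology for CPU-sized experiments.
regnet_presets <- function() {
  list(
    regnetz_4gf = list(kind = "z", depth = 28L, w0 = 48, wa = 14.5,
                       wm = 2.226, group_w = 8L, bottle_ratio = 4,
                       se_ratio = 0.25, act = "silu", stem_w = 32L),
    regnety_16gf = list(kind = "y", depth = 18L, w0 = 200, wa = 106.23,
                        wm = 2.48, group_w = 112L, bottle_ratio = 1,
                        se_ratio = 0.25, act = "relu", stem_w = 32L),
    tiny = list(kind = "tiny", widths = c(16L, 32L, 64L), stem_w = 8L,
                act = "relu")
  )
}

regnet_config <- function(backbone) {
  presets <- regnet_presets()
  if (!backbone %in% names(presets)) {
    stop("unsupported backbone '", backbone, "'; available: ",
         paste(names(presets), collapse = ", "))
  }
  cfg <- presets[[backbone]]
  cfg$name <- backbone
  if (cfg$kind != "tiny") {
    cfg <- c(cfg, regnet_stage_plan(cfg$depth, cfg$w0, cfg$wa, cfg$wm,
                                    cfg$group_w, cfg$bottle_ratio))
  } else {
    cfg$depths <- rep(1L, length(cfg$widths))
  }
  cfg$total_stride <- 2L^(length(cfg$widths) + 1L)
  cfg
}

#' Stage widths and depths of a RegNet-style encoder preset
#'
#' @param backbone One of `"regnetz_4gf"`, `"regnety_16gf"`, `"tiny"`.
#' @return A list with `widths`, `depths` (per stage, excluding the stem) and
#'   `total_stride` of the deepest feature map.
#' @export
#' @examples
#' encoder_spec("regnety_16gf")$widths  # 224 448 1232 3024
encoder_spec <- function(backbone) {
  cfg <- regnet_config(backbone)
  list(widths = cfg$widths, depths = cfg$depths,
       stem_width = cfg$stem_w, total_stride = cfg$total_stride)
}

# ---- graph emission ---------------------------------------------------------

g_conv_bn <- function(g, x, cin, cout, k = 3L, stride = 1L, groups = 1L,
                      act = "relu") {
  id <- nn_add(g, "conv", x, k = as.integer(k), stride = as.integer(stride),
               pad = as.integer((k - 1L) %/% 2L), groups = as.integer(groups),
               cin = as.integer(cin), cout = as.integer(cout), bias = FALSE)
  id <- nn_add(g, "bn", id, c = as.integer(cout))
  if (!is.null(act)) id <- nn_add(g, act, id)
  id
}

# Squeeze-and-excitation gate appended to `x` (C channels): global average
# pool, bottleneck 1x1 convs, sigmoid gate, channel-wise rescale.
g_se <- function(g, x, c_feat, c_mid) {
  c_mid <- max(1L, as.integer(c_mid))
  p <- nn_add(g, "gap", x)
  p <- nn_add(g, "conv", p, k = 1L, stride = 1L, pad = 0L, groups = 1L,
              cin = as.integer(c_feat), cout = c_mid, bias = TRUE)
  p <- nn_add(g, "relu", p)
  p <- nn_add(g, "conv", p, k = 1L, stride = 1L, pad = 0L, groups = 1L,
              cin = c_mid, cout = as.integer(c_feat), bias = TRUE)
  p <- nn_add(g, "sigmoid", p)
  nn_add(g, "mul_chan", c(x, p))
}

# One RegNet block; returns the output node id.
g_regnet_block <- function(g, x, w_in, w_out, stride, cfg, stage_idx) {
  if (cfg$kind == "y") {
    wb <- cfg$bottleneck_widths[stage_idx]
    gw <- cfg$group_widths[stage_idx]
    h <- g_conv_bn(g, x, w_in, wb, k = 1L, act = cfg$act)
    h <- g_conv_bn(g, h, wb, wb, k = 3L, stride = stride,
                   groups = wb %/% gw, act = cfg$act)
    h <- g_se(g, h, wb, round(cfg$se_ratio * w_in))
    h <- g_conv_bn(g, h, wb, w_out, k = 1L, act = NULL)
    if (stride == 1L && w_in == w_out) sc <- x
    else sc <- g_conv_bn(g, x, w_in, w_out, k = 1L, stride = stride, act = NULL)
    nn_add(g, cfg$act, nn_add(g, "add", c(h, sc)))
  } else {  # "z": inverted bottleneck, linear output, identity shortcut only
    wb <- cfg$bottleneck_widths[stage_idx]
    gw <- cfg$group_widths[stage_idx]
    h <- g_conv_bn(g, x, w_in, wb, k = 1L, act = cfg$act)
    h <- g_conv_bn(g, h, wb, wb, k = 3L, stride = stride,
                   groups = wb %/% gw, act = cfg$act)
    h <- g_se(g, h, wb, round(cfg$se_ratio * w_in))
    h <- g_conv_bn(g, h, wb, w_out, k = 1L, act = NULL)
    if (stride == 1L && w_in == w_out) h <- nn_add(g, "add", c(h, x))
    h
  }
}

# Emit the full encoder into graph `g` from an input node.
# Returns list(features = node ids at strides 2, 4, ..., widths = channels).
g_encoder <- function(g, x_id, cfg) {
  feats <- integer(0)
  widths <- integer(0)
  act <- cfg$act
  stem <- g_conv_bn(g, x_id, 3L, cfg$stem_w, k = 3L, stride = 2L, act = act)
  feats <- c(feats, stem)
  widths <- c(widths, cfg$stem_w)
  w_prev <- cfg$stem_w
  for (i in seq_along(cfg$widths)) {
    w <- cfg$widths[i]
    if (cfg$kind == "tiny") {
      h <- g_conv_bn(g, feats[length(feats)], w_prev, w, k = 3L, stride = 2L,
                     act = act)
      h <- g_conv_bn(g, h, w, w, k = 3L, act = act)
    } else {
      h <- feats[length(feats)]
      for (b in seq_len(cfg$depths[i])) {
        h <- g_regnet_block(g, h, w_prev, w, if (b == 1L) 2L else 1L, cfg, i)
        w_prev <- w
      }
    }
    feats <- c(feats, h)
    widths <- c(widths, w)
    w_prev <- w
  }
  list(features = feats, widths = widths)
}
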