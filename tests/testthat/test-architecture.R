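test_that("RegNetY-16GF encoder stages match the published configuration", {
  sp <- encoder_spec("regnety_16gf")
  expect_equal(sp$widths, c(224L, 448L, 1232L, 3024L))
  expect_equal(sum(sp$depths), 18L)
  expect_equal(sp$total_stride, 32L)
  spz <- encoder_spec("regnetz_4gf")
  expect_equal(sum(spz$depths), 28L)
  expect_equal(spz$total_stride, 32L)
  expect_error(encoder_spec("resnet50"), "unsupported backbone")
})

test_that("feature pyramid shapes halve per stage and scale with input size", {
  cfg <- seg_model_config("regnetz_4gf", input_size = 512)
  enc <- build_encoder(cfg)
  shapes512 <- angioseg:::graph_shapes(enc$graph, c(512, 512))
  f512 <- shapes512[enc$feature_ids]
  sides <- vapply(f512, `[`, 0, 1)
  expect_equal(sides, 512 / c(2, 4, 8, 16, 32))
  expect_equal(vapply(f512, `[`, 0, 3), as.numeric(enc$feature_widths))
  # deepest map at 512 input is 16x16
  expect_equal(f512[[length(f512)]][1:2], c(16, 16))
  # halving the input side halves every pyramid side
  f256 <- angioseg:::graph_shapes(enc$graph, c(256, 256))[enc$feature_ids]
  expect_equal(vapply(f256, `[`, 0, 1), sides / 2)
})

test_that("encoder forward emits the feature pyramid", {
  cfg <- tiny_seg_config(32)
  enc <- build_encoder(cfg)
  angioseg:::nn_init_params(enc, 1)
  x <- array(runif(32 * 32 * 3), c(32, 32, 3))
  pyr <- encoder_forward(enc, x)
  expect_length(pyr, 4)  # strides 2, 4, 8, 16 for the tiny preset
  expect_equal(vapply(pyr, function(f) dim(f)[1], 0), c(16, 8, 4, 2))
  expect_equal(vapply(pyr, function(f) dim(f)[3], 0),
               as.numeric(enc$feature_widths))
})

test_that("segmentation head emits a per-pixel probability simplex", {
  m <- build_se_regunet(tiny_seg_config(32), init_seed = 2)
  set.seed(1)
  x <- array(runif(32 * 32 * 3 * 2), c(32, 32, 3, 2))
  p <- predict_prob(m, x)
  expect_equal(dim(p), c(32, 32, 2, 2))
  expect_true(all(p >= 0 & p <= 1))
  expect_lt(max(abs(p[, , 1, ] + p[, , 2, ] - 1)), 1e-5)
})

test_that("input sizes not divisible by the encoder stride are rejected", {
  expect_error(seg_model_config("regnetz_4gf", input_size = 500), "divisible")
  m <- build_se_regunet(tiny_seg_config(32), init_seed = 2)
  x <- array(runif(40 * 40 * 3), c(40, 40, 3))
  expect_error(predict_prob(m, x), "divisible")
})

test_that("classifier outputs a probability and is deterministic in eval mode", {
  m <- build_classifier(tiny_seg_config(32), init_seed = 4)
  set.seed(2)
  x <- array(runif(32 * 32 * 3), c(32, 32, 3))
  p1 <- predict_side_prob(m, x)
  p2 <- predict_side_prob(m, x)
  expect_identical(p1, p2)
  expect_gte(p1, 0)
  expect_lte(p1, 1)
})

test_that("complexity profiler closed forms on a single convolution", {
  g <- angioseg:::nn_graph()
  x <- angioseg:::nn_add(g, "input", channels = 1L)
  cv <- angioseg:::nn_add(g, "conv", x, k = 3L, stride = 1L, pad = 1L,
                          groups = 1L, cin = 1L, cout = 1L, bias = FALSE)
  m <- angioseg:::new_model(g, cv, list(backbone = "single_conv",
                                        input_size = 10L, total_stride = 1L),
                            "segmenter", input_id = x)
  rep <- profile_complexity(m, 10)
  expect_equal(rep$trainable_parameters, 9)
  expect_equal(rep$flops, 9 * 100)
  expect_equal(count_parameters(m), 9L)
})

test_that("doubling input side quadruples FLOPs; parameters are unchanged", {
  m <- build_se_regunet(seg_model_config("regnetz_4gf"), init_seed = NULL)
  r256 <- profile_complexity(m, 256)
  r512 <- profile_complexity(m, 512)
  expect_equal(r512$flops / r256$flops, 4, tolerance = 0.01)
  expect_equal(r512$trainable_parameters, r256$trainable_parameters)
})

test_that("decoder widths follow the deepest-width rule and scale down", {
  cfg <- seg_model_config("regnetz_4gf")
  expect_equal(cfg$decoder_channels, c(264L, 132L, 66L, 33L))
  cfg4 <- seg_model_config("tiny", input_size = 256)
  cfg4s <- seg_model_config("tiny", input_size = 256, decoder_scale = 0.25)
  expect_true(all(cfg4s$decoder_channels <= pmax(2, cfg4$decoder_channels / 4)))
})
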