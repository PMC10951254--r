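# Numerical checks of the network engine: C++ kernels against a naive
# convolution oracle and finite differences, and a whole-model gradient check.

conv_fw <- angioseg:::.conv2d_fw
conv_bw <- angioseg:::.conv2d_bw
up_fw <- angioseg:::.upsample2_fw
up_bw <- angioseg:::.upsample2_bw

test_that("conv2d forward matches the naive convolution oracle", {
  set.seed(42)
  cases <- expand.grid(stride = 1:2, pad = 0:1, groups = c(1, 2))
  for (i in seq_len(nrow(cases))) {
    st <- cases$stride[i]; pd <- cases$pad[i]; gr <- cases$groups[i]
    x <- array(rnorm(9 * 8 * 4 * 2), c(9, 8, 4, 2))
    w <- array(rnorm(3 * 3 * (4 / gr) * 6), c(3, 3, 4 / gr, 6))
    expect_equal(conv_fw(x, w, as.integer(st), as.integer(pd), as.integer(gr)),
                 naive_conv(x, w, st, pd, gr), tolerance = 1e-12,
                 label = sprintf("stride=%d pad=%d groups=%d", st, pd, gr))
  }
  # 1x1 convolution
  x <- array(rnorm(5 * 5 * 3 * 2), c(5, 5, 3, 2))
  w <- array(rnorm(3 * 4), c(1, 1, 3, 4))
  expect_equal(conv_fw(x, w, 1L, 0L, 1L), naive_conv(x, w, 1, 0, 1),
               tolerance = 1e-12)
})

test_that("conv2d and upsample backward match finite differences", {
  set.seed(7)
  x <- array(rnorm(7 * 7 * 4 * 2), c(7, 7, 4, 2))
  w <- array(rnorm(3 * 3 * 2 * 4), c(3, 3, 2, 4))
  for (st in 1:2) {
    y <- conv_fw(x, w, as.integer(st), 1L, 2L)
    r <- array(rnorm(length(y)), dim(y))
    bw <- conv_bw(x, w, r, as.integer(st), 1L, 2L, TRUE)
    fx <- function(a) sum(conv_fw(a, w, as.integer(st), 1L, 2L) * r)
    fw <- function(a) sum(conv_fw(x, a, as.integer(st), 1L, 2L) * r)
    expect_lt(max(abs(bw$dx - fd_grad(fx, x))), 1e-6)
    expect_lt(max(abs(bw$dw - fd_grad(fw, w))), 1e-6)
  }
  u <- up_fw(x)
  expect_equal(dim(u), c(14, 14, 4, 2))
  ru <- array(rnorm(length(u)), dim(u))
  fu <- function(a) sum(up_fw(a) * ru)
  expect_lt(max(abs(up_bw(ru) - fd_grad(fu, x))), 1e-6)
})

test_that("whole-model gradients match finite differences", {
  cfg <- tiny_seg_config(32)
  m <- build_se_regunet(cfg, init_seed = 3)
  set.seed(7)
  x <- array(runif(32 * 32 * 3 * 2), c(32, 32, 3, 2))
  y <- matrix(0L, 32, 32); y[10:20, 5:15] <- 1L
  yb <- array(c(y, y), c(32, 32, 2))
  fl <- focal_loss_params()
  loss_of <- function() {
    pass <- angioseg:::nn_forward(m, x, training = TRUE)
    focal_loss(angioseg:::softmax_channels(pass$out), yb, fl)
  }
  pass <- angioseg:::nn_forward(m, x, training = TRUE)
  dout <- angioseg:::focal_loss_grad(pass$out, yb, fl)
  gr <- angioseg:::nn_backward(m, pass, dout)
  check <- function(id, pn, idx) {
    p0 <- m$graph$params[[id]][[pn]]
    eps <- 1e-5
    m$graph$params[[id]][[pn]][idx] <- p0[idx] + eps
    l1 <- loss_of()
    m$graph$params[[id]][[pn]][idx] <- p0[idx] - eps
    l2 <- loss_of()
    m$graph$params[[id]][[pn]][idx] <- p0[idx]
    expect_equal(gr$grads[[id]][[pn]][idx], (l1 - l2) / (2 * eps),
                 tolerance = 1e-4,
                 label = sprintf("grad node %d %s[%d]", id, pn, idx))
  }
  convs <- which(vapply(m$graph$nodes, function(n) n$op == "conv", TRUE))
  bns <- which(vapply(m$graph$nodes, function(n) n$op == "bn", TRUE))
  check(convs[1], "w", 5)              # stem conv
  check(convs[length(convs)], "w", 1)  # head conv
  check(convs[length(convs)], "b", 2)
  check(bns[2], "gamma", 3)
  check(bns[5], "beta", 2)
})

test_that("squeeze-and-excitation block: gates in (0,1), zero in gives zero out", {
  set.seed(1)
  x <- array(rnorm(6 * 6 * 8 * 2), c(6, 6, 8, 2))
  r <- se_block(x, reduction = 4)
  expect_true(all(r$gate > 0 & r$gate < 1))
  expect_equal(dim(r$out), dim(x))
  z <- se_block(array(0, c(4, 4, 8, 1)), reduction = 4)
  expect_true(all(z$out == 0))
})

test_that("squeeze-and-excitation arithmetic matches a hand-computed chain", {
  # 1 image, 4 channels, 2x2; reduction 2 -> hidden width 2; hand-set weights
  x <- array(seq(0.1, by = 0.1, length.out = 16), c(2, 2, 4, 1))
  w1 <- matrix(c(1, 0, 0, 1,
                 0, 1, 1, 0), 4, 2)
  b1 <- c(0.1, -0.2)
  w2 <- matrix(c(1, -1, 0.5, 0,
                 0, 1, -0.5, 1), 2, 4, byrow = TRUE)
  b2 <- c(0, 0.1, -0.1, 0.2)
  pooled <- apply(x[, , , 1], 3, mean)
  h <- pmax(t(w1) %*% pooled + b1, 0)
  gate <- 1 / (1 + exp(-(t(w2) %*% h + b2)))
  r <- se_block(x, reduction = 2,
                weights = list(w1 = w1, b1 = b1, w2 = w2, b2 = b2))
  expect_equal(as.vector(r$gate), as.vector(gate), tolerance = 1e-12)
  expect_equal(r$out[1, 1, , 1], x[1, 1, , 1] * as.vector(gate),
               tolerance = 1e-12)
})

test_that("SE gating shrinks channel magnitude; unit gates recover the input", {
  set.seed(3)
  x <- array(rnorm(5 * 5 * 4 * 1), c(5, 5, 4, 1))
  r <- se_block(x, reduction = 2)
  for (k in 1:4) {
    expect_lte(sum(abs(r$out[, , k, ])), sum(abs(x[, , k, ])))
  }
  # sigmoid bias -> +inf forces gates to 1 and recovers the plain block input
  w <- list(w1 = matrix(0, 4, 2), b1 = c(0, 0),
            w2 = matrix(0, 2, 4), b2 = rep(1e4, 4))
  r1 <- se_block(x, reduction = 2, weights = w)
  expect_equal(r1$out, x, tolerance = 1e-12)
})

test_that("batch norm eval mode is an affine map using running statistics", {
  cfg <- tiny_seg_config(32)
  m <- build_se_regunet(cfg, init_seed = 5)
  x <- array(runif(32 * 32 * 3 * 2), c(32, 32, 3, 2))
  # training pass updates buffers; eval passes are then deterministic
  pass <- angioseg:::nn_forward(m, x, training = TRUE)
  e1 <- angioseg:::nn_forward(m, x, training = FALSE)$out
  e2 <- angioseg:::nn_forward(m, x, training = FALSE)$out
  expect_identical(e1, e2)
})
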