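# Shared fixtures and independent oracles used across test files.

# Brute-force dense convolution oracle (replicate padding), for checking the
# unsharp mask against an independent implementation.
bf_unsharp <- function(px, sigma, amount) {
  r <- ceiling(3 * sigma)
  g <- exp(-((-r):r)^2 / (2 * sigma^2))
  k <- outer(g, g)
  k <- k / sum(k)
  H <- nrow(px); W <- ncol(px)
  bl <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    s <- 0
    for (di in -r:r) for (dj in -r:r) {
      ii <- min(max(i + di, 1), H)
      jj <- min(max(j + dj, 1), W)
      s <- s + px[ii, jj] * k[di + r + 1, dj + r + 1]
    }
    bl[i, j] <- s
  }
  pmin(pmax(round(px + amount * (px - bl)), 0), 255)
}

# Global histogram equalization oracle (256 bins, 8-bit).
global_histeq <- function(px) {
  cum <- cumsum(tabulate(px + 1L, 256L))
  matrix(round(255 * cum[px + 1L] / length(px)), nrow(px), ncol(px))
}

# Naive direct convolution oracle for the C++ kernel (zero padding).
naive_conv <- function(x, w, stride, pad, groups) {
  d <- dim(x); k <- dim(w)[1]; cpg <- dim(w)[3]; cout <- dim(w)[4]
  coutpg <- cout / groups
  Ho <- (d[1] + 2 * pad - k) %/% stride + 1
  Wo <- (d[2] + 2 * pad - k) %/% stride + 1
  y <- array(0, c(Ho, Wo, cout, d[4]))
  for (n in seq_len(d[4])) for (co in seq_len(cout)) {
    g <- ceiling(co / coutpg)
    for (ho in seq_len(Ho)) for (wo in seq_len(Wo)) {
      s <- 0
      for (cl in seq_len(cpg)) for (kh in seq_len(k)) for (kw in seq_len(k)) {
        hi <- (ho - 1) * stride + kh - pad
        wi <- (wo - 1) * stride + kw - pad
        if (hi >= 1 && hi <= d[1] && wi >= 1 && wi <= d[2]) {
          s <- s + x[hi, wi, (g - 1) * cpg + cl, n] * w[kh, kw, cl, co]
        }
      }
      y[ho, wo, co, n] <- s
    }
  }
  y
}

# Central finite differences of f at a (slow; tiny tensors only).
fd_grad <- function(f, a, eps = 1e-6) {
  g <- a * 0
  for (i in seq_along(a)) {
    a1 <- a; a1[i] <- a[i] + eps
    a2 <- a; a2[i] <- a[i] - eps
    g[i] <- (f(a1) - f(a2)) / (2 * eps)
  }
  g
}

# Small deterministic test image (reproducible across runs).
fixture_image <- function(H = 64, W = 64, seed = 11) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  img <- matrix(sample(0:255, H * W, replace = TRUE), H, W)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  img
}

tiny_seg_config <- function(size = 32L, scale = 1) {
  seg_model_config(backbone = "tiny", input_size = size, decoder_scale = scale)
}
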