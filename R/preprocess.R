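# Dual-phase contrast enhancement for X-ray angiograms.
#
# Vessels filled with contrast medium are darker than their surroundings but
# the raw frames are low-contrast and noisy. The pipeline sharpens with an
# unsharp mask (adds back the high-frequency residual against a Gaussian
# blur), then applies two differently tuned contrast-limited adaptive
# histogram equalizations (CLAHE) to the sharpened image; the three results
# are stacked into one 3-channel image for the classifier and segmenter.
#
# All operations work internally on 8-bit intensities (0-255, the
# conventional 256 histogram bins); floating inputs in [0, 1] are rescaled in
# and back out. Coordinates are row-major, origin top-left.

#' Single-channel angiogram container
#'
#' @param pixels Numeric matrix, either 8-bit (0-255) or normalized (0-1);
#'   at least 32x32.
#' @param source_id Free-text provenance tag.
#' @return An `angiogram` object (list with `pixels` as 8-bit values,
#'   `source_id`, and `normalized` recording the input dialect).
#' @export
angiogram <- function(pixels, source_id = "") {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("pixels must be a numeric matrix (single channel)")
  }
  if (nrow(pixels) < 32 || ncol(pixels) < 32) {
    stop("angiogram must be at least 32x32 pixels")
  }
  if (min(pixels) < 0) stop("negative intensities")
  normalized <- max(pixels) <= 1
  px <- if (normalized) round(pixels * 255) else round(pixels)
  if (max(px) > 255) stop("intensities exceed 8-bit range")
  structure(list(pixels = px, source_id = source_id, normalized = normalized),
            class = "angiogram")
}

as_pixels <- function(img) {
  px <- if (inherits(img, "angiogram")) img$pixels
        else if (!is.matrix(img)) stop("expected a matrix or angiogram (2-D input)")
        else if (max(img) <= 1 && min(img) >= 0) round(img * 255)
        else round(img)
  storage.mode(px) <- "double"
  px
}

gaussian_kernel <- function(sigma) {
  r <- ceiling(3 * sigma)
  g <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

gaussian_blur_255 <- function(px, sigma) {
  k <- gaussian_kernel(sigma)
  r <- (nrow(k) - 1L) %/% 2L
  # replicate-pad by the kernel radius, filter, crop: edge-replication
  # semantics that also work when the kernel is larger than the image
  ri <- c(rep(1L, r), seq_len(nrow(px)), rep(nrow(px), r))
  ci <- c(rep(1L, r), seq_len(ncol(px)), rep(ncol(px), r))
  padded <- px[ri, ci]
  out <- EBImage::filter2(padded, k, boundary = "circular")
  out[r + seq_len(nrow(px)), r + seq_len(ncol(px))]
}

#' Unsharp masking
#'
#' Sharpens by adding back the residual of the image against its Gaussian
#' blur: `clip(img + amount * (img - blur(img, radius)))`. A constant image,
#' or `amount = 0`, returns the input unchanged.
#'
#' @param img Matrix or [angiogram()].
#' @param radius Gaussian sigma in pixels (> 0).
#' @param amount Unitless gain (>= 0).
#' @return 8-bit matrix of the sharpened image (same shape).
#' @export
unsharp_mask <- function(img, radius = 2, amount = 1.5) {
  if (!is.numeric(radius) || radius <= 0) stop("radius must be positive")
  if (!is.numeric(amount) || amount < 0) stop("amount must be >= 0")
  px <- as_pixels(img)
  if (amount == 0) return(px)
  blur <- gaussian_blur_255(px, radius)
  out <- round(px + amount * (px - blur))
  pmin(pmax(out, 0), 255)
}

#' Contrast-limited adaptive histogram equalization
#'
#' The image is divided into a grid of tiles; each tile's 256-bin histogram is
#' clipped at `clip_limit` times the uniform bin height (the excess is
#' redistributed uniformly), its CDF defines a monotone intensity mapping,
#' and every pixel is remapped by bilinear interpolation between the four
#' surrounding tile mappings. Images whose sides are not multiples of the
#' tile grid are mirror-padded and cropped back. With a single tile and an
#' effectively infinite clip limit this reduces to global histogram
#' equalization.
#'
#' @param img Matrix or [angiogram()].
#' @param clip_limit Histogram clip factor (> 0) relative to the uniform bin
#'   height.
#' @param tile_grid Integer (rows, cols) of the tile grid.
#' @return 8-bit matrix, same shape as input.
#' @export
clahe <- function(img, clip_limit = 2, tile_grid = c(8, 8)) {
  if (!is.numeric(clip_limit) || clip_limit <= 0) {
    stop("clip_limit must be positive")
  }
  tile_grid <- as.integer(tile_grid)
  if (length(tile_grid) != 2 || any(tile_grid < 1)) {
    stop("tile_grid must be two integers >= 1")
  }
  px <- as_pixels(img)
  H <- nrow(px); W <- ncol(px)
  tr <- tile_grid[1]; tc <- tile_grid[2]
  if (tr > H || tc > W) stop("tile_grid larger than the image")

  th <- ceiling(H / tr); tw <- ceiling(W / tc)
  Hp <- th * tr; Wp <- tw * tc
  if (Hp > H) px <- rbind(px, px[seq(H, H - (Hp - H) + 1), , drop = FALSE])
  if (Wp > W) px <- cbind(px, px[, seq(W, W - (Wp - W) + 1), drop = FALSE])

  area <- th * tw
  cl <- max(1, clip_limit * area / 256)
  # per-tile clipped-CDF mappings: M[v+1, i, j] in 0..255
  M <- array(0, c(256, tr, tc))
  for (i in seq_len(tr)) {
    for (j in seq_len(tc)) {
      tile <- px[(i - 1) * th + seq_len(th), (j - 1) * tw + seq_len(tw)]
      h <- tabulate(tile + 1L, 256)
      excess <- sum(pmax(h - cl, 0))
      h <- pmin(h, cl) + excess / 256
      M[, i, j] <- round(255 * cumsum(h) / area)
    }
  }

  # bilinear interpolation between tile mappings (tile-center anchored)
  yy <- (seq_len(Hp) - 0.5) / th + 0.5
  i0 <- pmin(pmax(floor(yy), 1), tr); fy <- pmin(pmax(yy - floor(yy), 0), 1)
  fy[floor(yy) < 1] <- 0; fy[floor(yy) >= tr] <- 1
  i1 <- pmin(i0 + 1, tr)
  fy[i0 == i1] <- 0
  xx <- (seq_len(Wp) - 0.5) / tw + 0.5
  j0 <- pmin(pmax(floor(xx), 1), tc); fx <- pmin(pmax(xx - floor(xx), 0), 1)
  fx[floor(xx) < 1] <- 0; fx[floor(xx) >= tc] <- 1
  j1 <- pmin(j0 + 1, tc)
  fx[j0 == j1] <- 0

  I0 <- matrix(i0, Hp, Wp); I1 <- matrix(i1, Hp, Wp)
  J0 <- matrix(j0, Hp, Wp, byrow = TRUE); J1 <- matrix(j1, Hp, Wp, byrow = TRUE)
  FY <- matrix(fy, Hp, Wp); FX <- matrix(fx, Hp, Wp, byrow = TRUE)
  look <- function(I, J) matrix(M[px + 1L + 256L * (I - 1L) + 256L * tr * (J - 1L)],
                                Hp, Wp)
  out <- (1 - FY) * (1 - FX) * look(I0, J0) + FY * (1 - FX) * look(I1, J0) +
    (1 - FY) * FX * look(I0, J1) + FY * FX * look(I1, J1)
  round(out[seq_len(H), seq_len(W)])
}

#' Preprocessing parameters
#'
#' Defaults suit 512x512 8-bit angiograms: moderate sharpening plus one
#' conservative and one aggressive local equalization. The two CLAHE settings
#' must differ in at least one field (otherwise two channels are redundant).
#'
#' @param usm_radius,usm_amount Unsharp-mask Gaussian sigma (px) and gain.
#' @param clahe_a,clahe_b Lists with `clip_limit` and `tile_grid`.
#' @return A `preprocess_params` list.
#' @export
preprocess_params <- function(usm_radius = 2, usm_amount = 1.5,
                              clahe_a = list(clip_limit = 2, tile_grid = c(8, 8)),
                              clahe_b = list(clip_limit = 4, tile_grid = c(16, 16))) {
  stopifnot(usm_radius > 0, usm_amount >= 0,
            clahe_a$clip_limit > 0, clahe_b$clip_limit > 0,
            all(clahe_a$tile_grid >= 1), all(clahe_b$tile_grid >= 1))
  if (identical(clahe_a$clip_limit, clahe_b$clip_limit) &&
      identical(as.integer(clahe_a$tile_grid), as.integer(clahe_b$tile_grid))) {
    stop("clahe_a and clahe_b must differ in at least one field")
  }
  structure(list(usm_radius = usm_radius, usm_amount = usm_amount,
                 clahe_a = clahe_a, clahe_b = clahe_b),
            class = "preprocess_params")
}

#' Dual-phase enhancement pipeline
#'
#' Channel 1 is the unsharp-masked image; channels 2 and 3 apply the two
#' CLAHE filters to that sharpened image. Deterministic: identical inputs and
#' parameters give bit-identical output.
#'
#' @param img Matrix or [angiogram()].
#' @param params A [preprocess_params()].
#' @return `preprocessed_image`: array (H, W, 3) of 8-bit intensities with
#'   attribute `channel_roles = c("usm", "clahe_a", "clahe_b")`. If the input
#'   was normalized (0-1), values are returned on that scale.
#' @export
preprocess_pipeline <- function(img, params = preprocess_params()) {
  normalized <- if (inherits(img, "angiogram")) img$normalized
                else (is.matrix(img) && max(img) <= 1)
  u <- unsharp_mask(img, params$usm_radius, params$usm_amount)
  a <- clahe(u, params$clahe_a$clip_limit, params$clahe_a$tile_grid)
  b <- clahe(u, params$clahe_b$clip_limit, params$clahe_b$tile_grid)
  out <- array(c(u, a, b), c(nrow(u), ncol(u), 3L))
  if (normalized) out <- out / 255
  structure(out, channel_roles = c("usm", "clahe_a", "clahe_b"),
            class = c("preprocessed_image", class(out)))
}

#' Mean vessel/background contrast
#'
#' Mean background intensity in an annulus around the mask minus mean vessel
#' intensity (positive when vessels are darker, as in contrast angiography).
#'
#' @param img Single-channel matrix (8-bit).
#' @param mask Binary vessel mask, same shape.
#' @param annulus Background annulus width in pixels.
#' @return Scalar contrast in intensity units.
#' @export
vessel_background_contrast <- function(img, mask, annulus = 5) {
  px <- as_pixels(img)
  m <- mask != 0
  brush <- EBImage::makeBrush(2L * annulus + 1L, shape = "disc")
  dil <- EBImage::dilate(EBImage::Image(m * 1), brush) > 0.5
  ring <- dil & !m
  mean(px[ring]) - mean(px[m])
}
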