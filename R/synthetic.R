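# Synthetic angiogram generator.
#
# Produces angiogram-like images with exact ground truth so the whole
# pipeline is testable offline: a branching vessel tree of smooth
# curvature-limited centerlines rooted at the left (LCA) or right (RCA)
# image border, drawn darker than background with per-branch contrast
# (uneven filling), over a mid-gray background with a low-frequency
# illumination gradient and Gaussian noise. Optional confounders mimic
# real failure modes: a high-contrast near-straight catheter touching the
# root (excluded from the ground-truth mask) and wide low-contrast
# diagonal rib bands.

#' Synthetic angiogram specification
#'
#' Ranges are sampled per image/branch. Vessels are darker than background
#' by `vessel_contrast` intensity units on a 0-255 scale.
#'
#' @param size Square image side (>= 64).
#' @param side `"LCA"`, `"RCA"`, or `"random"`.
#' @param n_branches Range of total branch count.
#' @param width_root Range of trunk width at the root (px).
#' @param taper Per-generation width decay factor range.
#' @param vessel_contrast Range of vessel darkening (0-255 units).
#' @param noise_sigma Gaussian pixel noise SD.
#' @param background Amplitude of the low-frequency background gradient.
#' @param catheter_prob,rib_prob Probability of the catheter / rib confounder.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(size = 256L, side = "random",
                           n_branches = c(3L, 7L), width_root = c(4, 9),
                           taper = c(0.6, 0.9), vessel_contrast = c(20, 60),
                           noise_sigma = 8, background = 30,
                           catheter_prob = 0.3, rib_prob = 0.3) {
  stopifnot(size >= 64, side %in% c("LCA", "RCA", "random"),
            n_branches[1] >= 1, diff(n_branches) >= 0,
            width_root[1] > 0, diff(width_root) >= 0,
            taper[1] > 0, taper[2] <= 1,
            vessel_contrast[1] > 0, noise_sigma >= 0, background >= 0,
            catheter_prob >= 0, catheter_prob <= 1,
            rib_prob >= 0, rib_prob <= 1)
  structure(list(size = as.integer(size), side = side,
                 n_branches = n_branches, width_root = width_root,
                 taper = taper, vessel_contrast = vessel_contrast,
                 noise_sigma = noise_sigma, background = background,
                 catheter_prob = catheter_prob, rib_prob = rib_prob),
            class = "synthetic_spec")
}

# Trace one smooth centerline as a curvature-limited walk.
# Returns a data frame of (r, c, heading) sampled at ~1 px steps.
trace_branch <- function(r0, c0, heading, len, size, inward_sign) {
  n <- max(2L, round(len))
  r <- numeric(n); cc <- numeric(n); hd <- numeric(n)
  r[1] <- r0; cc[1] <- c0; hd[1] <- heading
  curv <- stats::rnorm(n, 0, 0.06)
  curv <- stats::filter(curv, rep(1 / 5, 5), circular = TRUE)
  for (i in 2:n) {
    hd[i] <- hd[i - 1] + curv[i]
    r[i] <- r[i - 1] + sin(hd[i])
    cc[i] <- cc[i - 1] + inward_sign * cos(hd[i])
  }
  data.frame(r = r, c = cc, heading = hd)
}

disk_offsets <- function(radius) {
  r <- max(0L, as.integer(floor(radius)))
  g <- expand.grid(dr = -r:r, dc = -r:r)
  g[g$dr^2 + g$dc^2 <= radius^2 + 1e-9, ]
}

# Stamp disks of (possibly varying) radius along a path. Returns the stamped
# pixel indices plus, for each index row, the path sample it came from.
stamp_path <- function(path, widths, size, lo_col, hi_col) {
  rr <- pmin(pmax(round(path$r), 2L), size - 1L)
  cc <- pmin(pmax(round(path$c), lo_col), hi_col)
  out_r <- vector("list", nrow(path)); out_c <- out_r; out_p <- out_r
  for (i in seq_len(nrow(path))) {
    off <- disk_offsets(widths[i] / 2)
    out_r[[i]] <- rr[i] + off$dr
    out_c[[i]] <- cc[i] + off$dc
    out_p[[i]] <- rep(i, nrow(off))
  }
  r <- unlist(out_r); c <- unlist(out_c); p <- unlist(out_p)
  keep <- r >= 1 & r <= size & c >= lo_col & c <= hi_col
  list(idx = cbind(r[keep], c[keep]), point = p[keep])
}

#' Generate one synthetic angiogram with ground truth
#'
#' Deterministic given `(spec, seed)`. The catheter (when present) is drawn
#' into the image but excluded from the mask, mirroring clinical labeling
#' practice where the contrast-filled catheter is not a vessel.
#'
#' @param spec A [synthetic_spec()].
#' @param seed Integer seed.
#' @return A `synthetic_sample`: list with `image` ([angiogram()]), `mask`
#'   (binary matrix), `side`, `seed`, `spec`.
#' @export
generate_tree <- function(spec = synthetic_spec(), seed = 1L) {
  if (spec$n_branches[1] < 1) stop("degenerate spec: zero branches")
  old <- rng_push(seed)
  on.exit(rng_pop(old))
  S <- spec$size
  side <- if (spec$side == "random") sample(c("LCA", "RCA"), 1) else spec$side
  inward <- if (side == "LCA") 1 else -1
  # keep vessels off the opposite border so the side stays recoverable
  lo_col <- if (side == "RCA") 6L else 1L
  hi_col <- if (side == "LCA") S - 5L else S

  n_br <- if (diff(spec$n_branches) > 0)
    sample(spec$n_branches[1]:spec$n_branches[2], 1) else spec$n_branches[1]
  w_root <- stats::runif(1, spec$width_root[1], spec$width_root[2])

  root_r <- stats::runif(1, 0.25 * S, 0.75 * S)
  root_c <- if (side == "LCA") 1 else S
  trunk <- trace_branch(root_r, root_c, stats::runif(1, -0.5, 0.5),
                        stats::runif(1, 0.55, 0.8) * S, S, inward)
  branches <- list(list(path = trunk, w0 = w_root, gen = 1L))

  while (length(branches) < n_br) {
    parent <- branches[[sample(length(branches), 1)]]
    np <- nrow(parent$path)
    at <- sample(seq(max(2, round(0.15 * np)), max(3, round(0.85 * np))), 1)
    taper <- stats::runif(1, spec$taper[1], spec$taper[2])
    w_child <- max(1.6, parent$w0 * taper)
    h0 <- parent$path$heading[at] + sample(c(-1, 1), 1) * stats::runif(1, 0.4, 1.0)
    len <- stats::runif(1, 0.25, 0.55) * S
    child <- trace_branch(parent$path$r[at], parent$path$c[at], h0, len, S, inward)
    branches[[length(branches) + 1]] <- list(path = child, w0 = w_child,
                                             gen = parent$gen + 1L)
  }

  mask <- matrix(FALSE, S, S)
  atten <- matrix(0, S, S)
  for (b in branches) {
    np <- nrow(b$path)
    end_taper <- stats::runif(1, spec$taper[1], spec$taper[2])
    widths <- b$w0 * seq(1, end_taper, length.out = np)
    st <- stamp_path(b$path, widths, S, lo_col, hi_col)
    mask[st$idx] <- TRUE
    contrast <- stats::runif(1, spec$vessel_contrast[1], spec$vessel_contrast[2])
    # uneven filling: slow modulation along the branch
    modph <- stats::runif(1, 0, 2 * pi)
    vals <- contrast * (1 + 0.15 * sin(modph + 4 * pi * seq_len(np) / np))
    atten[st$idx] <- pmax(atten[st$idx], vals[st$point])
  }

  has_catheter <- stats::runif(1) < spec$catheter_prob
  if (has_catheter) {
    cat_r0 <- if (root_r > S / 2) S - 1 else 2
    cpath <- data.frame(
      r = seq(cat_r0, root_r, length.out = S %/% 2),
      c = seq(root_c, root_c + inward * stats::runif(1, 2, 10), length.out = S %/% 2))
    cpath$c <- cpath$c + 3 * sin(seq(0, pi, length.out = nrow(cpath)))
    cpath$heading <- 0
    cst <- stamp_path(cpath, rep(stats::runif(1, 3, 4.5), nrow(cpath)), S,
                      lo_col, hi_col)
    atten[cst$idx] <- pmax(atten[cst$idx], stats::runif(1, 70, 90))
  }

  # soften vessel edges (mask itself stays crisp)
  atten <- EBImage::filter2(atten, gaussian_kernel(0.8), boundary = "replicate")

  rc <- row(mask) / S; cc <- col(mask) / S
  ph <- stats::runif(2, 0, 2 * pi)
  fr <- stats::runif(2, 0.5, 1.5)
  bg <- 128 + spec$background *
    (0.5 * sin(2 * pi * fr[1] * rc + ph[1]) + 0.5 * sin(2 * pi * fr[2] * cc + ph[2]))

  if (stats::runif(1) < spec$rib_prob) {
    for (k in seq_len(sample(1:3, 1))) {
      th <- stats::runif(1, pi / 6, pi / 3) * sample(c(-1, 1), 1)
      d0 <- stats::runif(1, -0.3, 1.3)
      dist <- abs(cos(th) * rc + sin(th) * cc - d0)
      bg <- bg - stats::runif(1, 8, 18) * (dist < stats::runif(1, 0.05, 0.12))
    }
  }

  img <- bg - atten + stats::rnorm(S * S, 0, spec$noise_sigma)
  img <- matrix(pmin(pmax(round(img), 0), 255), S, S)
  structure(list(image = angiogram(img, sprintf("synthetic-%s-%d", side, seed)),
                 mask = mask * 1L, side = side, seed = seed, spec = spec,
                 has_catheter = has_catheter),
            class = "synthetic_sample")
}

#' Generate a synthetic dataset on disk
#'
#' Writes `n` samples (grayscale PNG image, 0/255 PNG mask) plus a manifest
#' CSV with columns `image_path, mask_path, patient_id, side` (one synthetic
#' patient per sample). With `side = "random"` the two sides are balanced to
#' within one image.
#'
#' @param n Number of samples (>= 1).
#' @param spec A [synthetic_spec()].
#' @param seed Integer seed; sample i uses `seed + i`.
#' @param out_dir Output directory (created if needed).
#' @return The manifest data frame (invisibly also written to
#'   `file.path(out_dir, "manifest.csv")`).
#' @export
generate_dataset <- function(n, spec = synthetic_spec(), seed = 1L,
                             out_dir) {
  stopifnot(n >= 1)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  sides <- if (spec$side == "random")
    rep(c("LCA", "RCA"), length.out = n) else rep(spec$side, n)
  rows <- lapply(seq_len(n), function(i) {
    sp <- spec
    sp$side <- sides[i]
    s <- generate_tree(sp, seed + i)
    ip <- file.path(out_dir, sprintf("img_%04d.png", i))
    mp <- file.path(out_dir, sprintf("mask_%04d.png", i))
    png::writePNG(s$image$pixels / 255, ip)
    png::writePNG(s$mask + 0, mp)
    data.frame(image_path = ip, mask_path = mp,
               patient_id = sprintf("synth%04d", i), side = s$side,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  manifest
}

#' Generate synthetic samples in memory
#'
#' Convenience for training experiments without touching disk.
#'
#' @inheritParams generate_dataset
#' @return List of `synthetic_sample` objects; sides balanced as in
#'   [generate_dataset()].
#' @export
generate_samples <- function(n, spec = synthetic_spec(), seed = 1L) {
  sides <- if (spec$side == "random")
    rep(c("LCA", "RCA"), length.out = n) else rep(spec$side, n)
  lapply(seq_len(n), function(i) {
    sp <- spec
    sp$side <- sides[i]
    generate_tree(sp, seed + i)
  })
}
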