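# Image and manifest input/output.
#
# Conventions: row-major pixel grids, origin top-left, (row, col) indexing.
# On disk, masks are 0 = background / 255 = vessel; in memory 0/1.

#' Load a grayscale image as an angiogram
#'
#' Reads PNG, PGM (P5) or TIFF. Multi-channel inputs are collapsed by
#' luminance (0.299 R + 0.587 G + 0.114 B).
#'
#' @param path File path.
#' @return An [angiogram()]; `source_id` records the path and original mode.
#' @export
load_image <- function(path) {
  if (!file.exists(path)) stop("cannot read image: ", path)
  ext <- tolower(tools::file_ext(path))
  a <- switch(ext,
    png = png::readPNG(path),
    pgm = read_pgm(path) / 255,
    tif = , tiff = {
      if (!requireNamespace("tiff", quietly = TRUE)) {
        stop("package 'tiff' required to read ", path)
      }
      tiff::readTIFF(path)
    },
    stop("unsupported image format '", ext, "' for ", path))
  mode <- "gray"
  if (length(dim(a)) == 3L) {
    mode <- paste0("channels:", dim(a)[3])
    if (dim(a)[3] >= 3L) {
      a <- 0.299 * a[, , 1] + 0.587 * a[, , 2] + 0.114 * a[, , 3]
    } else {
      a <- a[, , 1]
    }
  }
  angiogram(round(a * 255), source_id = paste0(path, " [", mode, "]"))
}

#' Write an 8-bit grayscale image or mask as PNG
#'
#' Masks (`0/1` matrices) are written as 0/255.
#'
#' @param img Matrix (0-255 intensities or 0/1 mask) or [angiogram()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_image <- function(img, path) {
  px <- if (inherits(img, "angiogram")) img$pixels else img
  if (all(px %in% c(0, 1))) px <- px * 255
  png::writePNG(px / 255, path)
  invisible(path)
}

# Minimal binary PGM (P5) reader/writer, maxval <= 255.
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  tok <- function() {
    repeat {
      ch <- readChar(con, 1, useBytes = TRUE)
      if (!length(ch)) stop("truncated PGM: ", path)
      if (ch == "#") {
        repeat {
          ch <- readChar(con, 1, useBytes = TRUE)
          if (!length(ch) || ch == "\n") break
        }
      } else if (!grepl("[[:space:]]", ch)) break
    }
    out <- ch
    repeat {
      ch <- readChar(con, 1, useBytes = TRUE)
      if (!length(ch) || grepl("[[:space:]]", ch)) break
      out <- paste0(out, ch)
    }
    out
  }
  if (tok() != "P5") stop("not a binary PGM (P5): ", path)
  w <- as.integer(tok()); h <- as.integer(tok()); maxv <- as.integer(tok())
  if (maxv > 255) stop("16-bit PGM not supported: ", path)
  raw <- readBin(con, "integer", n = w * h, size = 1, signed = FALSE)
  matrix(raw, nrow = h, ncol = w, byrow = TRUE)
}

write_pgm <- function(px, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(sprintf("P5\n%d %d\n255\n", ncol(px), nrow(px)), con, eos = NULL)
  writeBin(as.integer(t(px)), con, size = 1)
  invisible(path)
}

#' Load a DCA1-layout external validation dataset
#'
#' Expects the public 134-image layout: angiogram `<id>.pgm` (or `.png`)
#' paired with ground truth `<id>_gt.pgm`/`.png`. Subsets load with a
#' warning; unpaired files are reported, not silently dropped. Ground-truth
#' masks are binarized at intensity > 127.
#'
#' @param root_dir Dataset directory.
#' @return Data frame with `id`, `image_path`, `gt_path`, ordered
#'   lexicographically by id, with attribute `unpaired` listing problem files.
#' @export
load_dca1 <- function(root_dir) {
  files <- list.files(root_dir, pattern = "\\.(pgm|png)$", ignore.case = TRUE)
  base <- tools::file_path_sans_ext(files)
  is_gt <- grepl("_gt$", base)
  ids <- sort(base[!is_gt])
  gt_of <- function(id) {
    hit <- files[base == paste0(id, "_gt")]
    if (length(hit)) hit[1] else NA_character_
  }
  gt <- vapply(ids, gt_of, "")
  unpaired <- c(ids[is.na(gt)],
                setdiff(base[is_gt], paste0(ids, "_gt")))
  keep <- !is.na(gt)
  rec <- data.frame(id = ids[keep],
                    image_path = file.path(root_dir, files[match(ids[keep], base)]),
                    gt_path = file.path(root_dir, gt[keep]),
                    stringsAsFactors = FALSE)
  if (nrow(rec) == 0) warning("no paired angiogram/ground-truth files in ", root_dir)
  else if (nrow(rec) != 134) {
    warning("expected the full 134-image layout, found ", nrow(rec), " pairs")
  }
  if (length(unpaired)) {
    warning("unpaired files: ", paste(unpaired, collapse = ", "))
  }
  attr(rec, "unpaired") <- unpaired
  rec
}

#' Read a DCA1 record's mask, binarized at > 127
#'
#' @param gt_path Path to a ground-truth image.
#' @return Binary 0/1 matrix.
#' @export
load_dca1_mask <- function(gt_path) {
  (load_image(gt_path)$pixels > 127) * 1L
}

#' Read a dataset manifest CSV
#'
#' Required columns: `image_path`, `mask_path`; optional `patient_id`, `side`.
#' Relative paths are resolved against the manifest's directory.
#'
#' @param path Manifest CSV path.
#' @return Data frame.
#' @export
read_manifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("image_path", "mask_path")
  if (!all(need %in% names(m))) {
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  }
  root <- dirname(path)
  fix <- function(p) ifelse(file.exists(p), p, file.path(root, basename(p)))
  m$image_path <- fix(m$image_path)
  m$mask_path <- fix(m$mask_path)
  if (is.null(m$patient_id)) m$patient_id <- sprintf("p%04d", seq_len(nrow(m)))
  m
}

#' Load manifest rows as model-ready samples
#'
#' @param manifest Data frame from [read_manifest()].
#' @param params A [preprocess_params()].
#' @return Named list (by image path basename) of `list(x, y, side)`.
#' @export
manifest_to_data <- function(manifest, params = preprocess_params()) {
  samples <- lapply(seq_len(nrow(manifest)), function(i) {
    img <- load_image(manifest$image_path[i])
    mask <- (load_image(manifest$mask_path[i])$pixels > 127) * 1L
    list(image = img, mask = mask,
         side = if (!is.null(manifest$side)) manifest$side[i] else NA_character_)
  })
  data <- samples_to_data(samples, params)
  names(data) <- basename(manifest$image_path)
  data
}
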