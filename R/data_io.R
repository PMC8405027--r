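#' Write a dataset to PNG files plus a CSV manifest
#'
#' Images and masks are written as 8-bit grayscale PNG under `dir/images/`
#' and `dir/masks/`; the manifest (`manifest.csv`) has columns `id`,
#' `image_path`, `mask_path` (empty if the record has no mask), `label` and
#' `split` (empty if unassigned). Paths are relative to `dir`.
#'
#' @param data Dataset tibble as returned by [generate_dataset()] or
#'   [load_manifest()].
#' @param dir Output directory (created if missing).
#' @return The manifest path, invisibly.
#' @export
write_dataset <- function(data, dir) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  split_col <- if ("split" %in% names(data)) data$split else rep("", nrow(data))
  rows <- purrr::pmap(
    list(data$id, data$image, data$mask, data$label, split_col),
    function(id, image, mask, label, split) {
      ip <- file.path("images", paste0(id, ".png"))
      png::writePNG(pmin(pmax(image, 0), 1), file.path(dir, ip))
      mp <- ""
      if (!is.null(mask)) {
        mp <- file.path("masks", paste0(id, ".png"))
        png::writePNG(mask + 0, file.path(dir, mp))
      }
      tibble(id = id, image_path = ip, mask_path = mp,
             label = label, split = if (is.na(split)) "" else split)
    }
  )
  manifest <- purrr::list_rbind(rows)
  path <- file.path(dir, "manifest.csv")
  write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' Load a dataset from a CSV manifest
#'
#' Reads a manifest written by [write_dataset()] (or assembled by hand with
#' the same columns), materialises the referenced PNG tiles, and validates
#' each record: labels are parsed case-insensitively, an empty `mask_path`
#' yields an absent mask, and an image/mask size mismatch is an error naming
#' the offending record id. Masks are binarised by thresholding at 127/255.
#'
#' @param path Path to a manifest CSV.
#' @return A tibble with columns `id`, `label`, `split`, `has_mask` and
#'   list-columns `image`, `mask`.
#' @export
load_manifest <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("manifest not found: %s", path), class = "masskd_io_error")
  }
  raw <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  required <- c("id", "image_path", "mask_path", "label")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    abort(sprintf("manifest lacks column(s): %s",
                  paste(missing_cols, collapse = ", ")),
          class = "masskd_parse_error")
  }
  if (!"split" %in% names(raw)) raw$split <- ""
  base <- dirname(path)
  rows <- purrr::map(seq_len(nrow(raw)), function(i) {
    r <- raw[i, ]
    parse_fail <- function(what) {
      abort(sprintf("manifest row %d: %s", i, what),
            class = "masskd_parse_error")
    }
    if (is.na(r$id) || r$id == "") parse_fail("empty id")
    lab <- tolower(trimws(r$label))
    if (!lab %in% c("benign", "malignant", "")) {
      parse_fail(sprintf("unparseable label '%s'", r$label))
    }
    if (is.na(r$image_path) || r$image_path == "") parse_fail("empty image_path")
    img <- read_gray_png(file.path(base, r$image_path))
    mask <- NULL
    if (!is.na(r$mask_path) && r$mask_path != "") {
      mask <- read_gray_png(file.path(base, r$mask_path))
      mask <- matrix(as.integer(mask > 127 / 255), nrow(mask), ncol(mask))
      if (!identical(dim(img), dim(mask))) {
        abort(sprintf(
          "record '%s': image is %dx%d but mask is %dx%d", r$id,
          nrow(img), ncol(img), nrow(mask), ncol(mask)
        ), class = "masskd_validation_error")
      }
    }
    tibble(
      id = r$id, label = if (lab == "") NA_character_ else lab,
      split = if (is.na(r$split) || r$split == "") NA_character_ else r$split,
      has_mask = !is.null(mask),
      image = list(img), mask = list(mask)
    )
  })
  purrr::list_rbind(rows)
}

read_gray_png <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("image not found: %s", path), class = "masskd_io_error")
  }
  x <- png::readPNG(path)
  if (length(dim(x)) == 3) x <- x[, , 1] # drop colour/alpha channels
  unclass(x)
}

#' Preprocess a raw tile: breast-centred crop and intensity normalisation
#'
#' Produces a `target_size` x `target_size` tile in `[0, 1]`. The crop window
#' is centred on the centroid of the largest connected component above an
#' Otsu threshold (the breast region) and clamped inside the tile; tiles
#' smaller than the target are zero-padded. Intensity is min-max normalised
#' over the crop; a degenerate (constant) crop maps to all zeros with a
#' warning. Flipping is never applied here -- it is a training-time
#' augmentation (see [flip_horizontal()]), so evaluation tiles are untouched.
#'
#' @param image Single-channel nonnegative matrix.
#' @param target_size Output side length in pixels.
#' @return A `target_size` x `target_size` matrix in `[0, 1]`.
#' @export
preprocess <- function(image, target_size) {
  if (!is.matrix(image) || !is.numeric(image)) {
    stop_param("`image` must be a numeric matrix")
  }
  if (any(image < 0)) stop_param("`image` must be nonnegative")
  t <- as.integer(target_size)

  if (all(image == 0)) {
    warn("all-zero tile; returning zeros")
    return(matrix(0, t, t))
  }

  # zero-pad symmetrically up to the target in any deficient dimension
  if (nrow(image) < t || ncol(image) < t) {
    H <- max(nrow(image), t); W <- max(ncol(image), t)
    padded <- matrix(0, H, W)
    r0 <- (H - nrow(image)) %/% 2
    c0 <- (W - ncol(image)) %/% 2
    padded[r0 + seq_len(nrow(image)), c0 + seq_len(ncol(image))] <- image
    image <- padded
  }

  if (nrow(image) > t || ncol(image) > t) {
    centre <- breast_centroid(image)
    r0 <- min(max(1L, round(centre[1] - t / 2)), nrow(image) - t + 1L)
    c0 <- min(max(1L, round(centre[2] - t / 2)), ncol(image) - t + 1L)
    image <- image[r0:(r0 + t - 1L), c0:(c0 + t - 1L)]
  }

  rng <- range(image)
  if (rng[2] == rng[1]) {
    warn("degenerate intensity range; returning zeros")
    return(matrix(0, t, t))
  }
  (image - rng[1]) / (rng[2] - rng[1])
}

# Centroid (row, col) of the largest connected component above an Otsu
# threshold of the min-max normalised tile.
breast_centroid <- function(image) {
  rng <- range(image)
  if (rng[2] == rng[1]) {
    return(c(nrow(image) / 2, ncol(image) / 2))
  }
  norm <- (image - rng[1]) / (rng[2] - rng[1])
  th <- EBImage::otsu(EBImage::Image(norm))
  fg <- norm > th
  if (!any(fg)) {
    return(c(nrow(image) / 2, ncol(image) / 2))
  }
  labels <- EBImage::bwlabel(EBImage::Image(fg + 0))
  labels <- as.matrix(EBImage::imageData(labels))
  counts <- table(labels[labels > 0])
  biggest <- as.integer(names(counts)[which.max(counts)])
  idx <- which(labels == biggest, arr.ind = TRUE)
  colMeans(idx)
}

#' Horizontal flip of a tile (training-time augmentation)
#'
#' @param x Matrix (image or mask).
#' @return The matrix mirrored left-right.
#' @export
flip_horizontal <- function(x) {
  x[, rev(seq_len(ncol(x))), drop = FALSE]
}

#' Assign train/validation/test splits
#'
#' Uniform seeded random assignment; validation and test counts are floored
#' (`floor(n * fraction)`) and the remainder goes to training, so 1250
#' records at fractions (0.8, 0.1, 0.1) give exactly 1000/125/125.
#'
#' @param data Dataset tibble (one row per record).
#' @param fractions Length-3 numeric `(train, val, test)` summing to 1.
#' @param seed Integer seed controlling the assignment.
#' @return `data` with a `split` column (`"train"`, `"val"`, `"test"`).
#' @export
#' @examples
#' d <- generate_dataset(phantom_spec(seed = 1), n_weak = 0, n_full = 10)
#' table(split_dataset(d, seed = 1)$split)
split_dataset <- function(data, fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  if (length(fractions) != 3 || abs(sum(fractions) - 1) > 1e-9) {
    stop_param("`fractions` must be three proportions summing to 1")
  }
  n <- nrow(data)
  if (n < 3) stop_param("need at least 3 records to populate all splits")
  n_val <- floor(n * fractions[2])
  n_test <- floor(n * fractions[3])
  n_train <- n - n_val - n_test
  perm <- with_seed(seed, sample.int(n))
  split <- character(n)
  split[perm[seq_len(n_train)]] <- "train"
  split[perm[n_train + seq_len(n_val)]] <- "val"
  split[perm[n_train + n_val + seq_len(n_test)]] <- "test"
  data$split <- split
  data
}
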