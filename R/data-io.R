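# Slice I/O: loading, normalization, scan-level splitting and batching.
# No learning logic lives here.

#' Construct a slice/label pair
#'
#' @param image numeric `(H,W)` matrix, intensities in `[0, 1]`.
#' @param label optional integer `(H,W)` matrix with values in `0..C-1`.
#' @param scan_id identifier of the 3-D scan the slice belongs to.
#' @param slice_index position of the slice within its scan.
#' @return a `slice_pair` list.
#' @export
slice_pair <- function(image, label = NULL, scan_id = "scan", slice_index = 1L) {
  if (length(dim(image)) != 2L) stop("slice image must be 2-D")
  if (!is.null(label)) {
    if (!identical(dim(image), dim(label)))
      stop("image and label dimensions differ")
    storage.mode(label) <- "integer"
  }
  structure(list(image = image, label = label, scan_id = as.character(scan_id),
                 slice_index = as.integer(slice_index)),
            class = "slice_pair")
}

#' Resize and normalize a slice
#'
#' Resizes to `size x size` (bilinear for the image, nearest-neighbour for
#' the label so the label set is preserved) and min-max normalizes the image
#' per slice to `[0, 1]`; a constant-intensity slice maps to all zeros.
#' Idempotent on already-conforming input up to interpolation identity.
#'
#' @param pair a [slice_pair()].
#' @param size target height/width in pixels.
#' @return the preprocessed `slice_pair`.
#' @export
preprocess_slice <- function(pair, size) {
  img <- pair$image
  if (length(dim(img)) != 2L) stop("preprocess: non-2-D input")
  if (!identical(dim(img), c(size, size)))
    img <- EBImage::resize(img, w = size, h = size, filter = "bilinear")
  rng <- range(img)
  img <- if (rng[2] > rng[1]) (img - rng[1]) / (rng[2] - rng[1])
         else matrix(0, size, size)
  lab <- pair$label
  if (!is.null(lab) && !identical(dim(lab), c(size, size))) {
    lab <- EBImage::resize(lab, w = size, h = size, filter = "none")
    storage.mode(lab) <- "integer"
  }
  slice_pair(img, lab, pair$scan_id, pair$slice_index)
}

rgb_to_gray <- function(arr) {
  if (length(dim(arr)) == 2L) return(arr)
  # luminance weights for RGB rasters (polyp-style inputs)
  0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3]
}

read_slice_image <- function(path, rgb = c("luminance", "keep")) {
  rgb <- match.arg(rgb)
  if (!file.exists(path)) stop("unreadable file: ", path)
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 3L && rgb == "luminance") arr <- rgb_to_gray(arr)
  arr
}

read_label_image <- function(path) {
  if (!file.exists(path)) stop("missing label for labeled item: ", path)
  lab <- round(png::readPNG(path) * 255)
  if (length(dim(lab)) == 3L) lab <- lab[, , 1]
  storage.mode(lab) <- "integer"
  lab
}

#' Write a predicted class mask as PNG
#'
#' Class indices are stored as `uint8` gray levels (`value = class/255`);
#' [read_mask_png()] inverts exactly for up to 256 classes.
#' @param mask integer `(H,W)` class map.
#' @param path output file.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(mask / 255, path)
  invisible(path)
}

#' Read a class mask written by [write_mask_png()]
#' @param path PNG file.
#' @return integer `(H,W)` class map.
#' @export
read_mask_png <- function(path) read_label_image(path)

#' Write a stack of predicted masks as one NIfTI volume per scan
#' @param slices list of integer `(H,W)` masks in scan order, or an
#'   `(H,W,S)` array.
#' @param path output `.nii` or `.nii.gz` file.
#' @export
write_mask_nifti <- function(slices, path) {
  vol <- if (is.list(slices))
    array(unlist(slices), dim = c(dim(slices[[1]]), length(slices)))
  else slices
  RNifti::writeNifti(vol, path)
  invisible(path)
}

#' Read a NIfTI volume as a list of slices along the last axis
#' @param path `.nii`/`.nii.gz` file.
#' @return list of `(H,W)` matrices.
#' @export
read_nifti_slices <- function(path) {
  if (!file.exists(path)) stop("unreadable file: ", path)
  vol <- as.array(RNifti::readNifti(path))
  if (length(dim(vol)) == 2L) return(list(vol))
  lapply(seq_len(dim(vol)[3]), function(k) vol[, , k])
}

# scan id and slice index from "scanid_s012.png"
parse_slice_name <- function(fname) {
  base <- sub("\\.png$", "", basename(fname))
  m <- regmatches(base, regexec("^(.*)_s(\\d+)$", base))[[1]]
  if (length(m) != 3L) stop("file does not follow <scan>_s<idx>.png: ", fname)
  list(scan_id = m[2], slice_index = as.integer(m[3]))
}

#' Load a dataset directory and split it at the scan level
#'
#' The directory holds `images/<scan>_s<idx>.png` and matching
#' `labels/<scan>_s<idx>.png`. Scans (never individual slices) are shuffled
#' with the split seed and assigned to train/val/test; the labeled subset is
#' drawn from the training scans, so no scan contributes slices to two
#' subsets and the labeled fraction operates on scans. Unlabeled items carry
#' no label even when a label file exists.
#'
#' @param root dataset directory.
#' @param split_spec either a YAML file path or a list: ratio form
#'   `list(labeled_fraction=, val_fraction=, test_fraction=, seed=)` or
#'   explicit form `list(labeled_scans=, unlabeled_scans=, val_scans=,
#'   test_scans=)`.
#' @param rgb how to read 3-channel rasters (see [read_slice_image()]).
#' @return list of `slice_pair` lists: `labeled`, `unlabeled`, `val`, `test`.
#' @export
load_split <- function(root, split_spec, rgb = "luminance") {
  if (is.character(split_spec) && length(split_spec) == 1L)
    split_spec <- yaml::read_yaml(split_spec)
  img_dir <- file.path(root, "images")
  files <- sort(list.files(img_dir, pattern = "\\.png$"))
  if (length(files) == 0L) stop("no PNG slices under ", img_dir)
  info <- lapply(files, parse_slice_name)
  scan_of <- vapply(info, `[[`, character(1), "scan_id")
  scans <- sort(unique(scan_of))
  if (!is.null(split_spec$labeled_scans)) {
    sel <- list(labeled = split_spec$labeled_scans,
                unlabeled = split_spec$unlabeled_scans %||% character(0),
                val = split_spec$val_scans %||% character(0),
                test = split_spec$test_scans %||% character(0))
  } else {
    seed <- split_spec$seed %||% 0L
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    perm <- sample(scans)
    n <- length(scans)
    n_test <- round((split_spec$test_fraction %||% 0.2) * n)
    n_val <- round((split_spec$val_fraction %||% 0.1) * n)
    if (n_test + n_val >= n) stop("val/test fractions leave no training scans")
    test_s <- perm[seq_len(n_test)]
    val_s <- perm[n_test + seq_len(n_val)]
    train_s <- perm[(n_test + n_val + 1L):n]
    n_lab <- max(1L, round((split_spec$labeled_fraction %||% 0.1) * length(train_s)))
    sel <- list(labeled = train_s[seq_len(n_lab)],
                unlabeled = if (n_lab < length(train_s)) train_s[(n_lab + 1L):length(train_s)] else character(0),
                val = val_s, test = test_s)
  }
  load_subset <- function(scan_ids, with_label) {
    keep <- which(scan_of %in% scan_ids)
    lapply(keep, function(k) {
      img <- read_slice_image(file.path(img_dir, files[k]), rgb = rgb)
      lab <- if (with_label)
        read_label_image(file.path(root, "labels", files[k])) else NULL
      slice_pair(img, lab, info[[k]]$scan_id, info[[k]]$slice_index)
    })
  }
  list(labeled = load_subset(sel$labeled, TRUE),
       unlabeled = load_subset(sel$unlabeled, FALSE),
       val = load_subset(sel$val, TRUE),
       test = load_subset(sel$test, TRUE))
}

# stack a list of preprocessed slice_pairs into (C,H,W,B) images and
# (H,W,B) labels
stack_slices <- function(pairs, with_labels = FALSE) {
  H <- nrow(pairs[[1]]$image); W <- ncol(pairs[[1]]$image)
  B <- length(pairs)
  images <- array(0, dim = c(1L, H, W, B))
  for (b in seq_len(B)) images[1L, , , b] <- pairs[[b]]$image
  out <- list(images = images)
  if (with_labels) {
    labels <- array(0L, dim = c(H, W, B))
    for (b in seq_len(B)) {
      if (is.null(pairs[[b]]$label)) stop("slice without label in labeled stack")
      labels[, , b] <- pairs[[b]]$label
    }
    out$labels <- labels
  }
  out
}

#' Batch sampler over labeled and unlabeled pools
#'
#' Draws `labeled_per_batch` labeled items followed by
#' `batch_size - labeled_per_batch` unlabeled items (fixed layout: labeled
#' items first). Each pool is sampled without replacement and reshuffled on
#' exhaustion, using the session RNG (seed it for reproducible epochs).
#'
#' @param labeled,unlabeled lists of preprocessed `slice_pair`s.
#' @param batch_size total items per batch.
#' @param labeled_per_batch labeled items per batch (>= 1).
#' @return a `batch_sampler` environment for [next_batch()].
#' @export
batch_sampler <- function(labeled, unlabeled, batch_size, labeled_per_batch) {
  if (length(labeled) == 0L)
    stop("labeled pool empty: supervised loss undefined")
  stopifnot(labeled_per_batch >= 1L, labeled_per_batch <= batch_size)
  if (batch_size > labeled_per_batch && length(unlabeled) == 0L)
    stop("unlabeled pool empty but batch requires unlabeled items")
  e <- new.env(parent = emptyenv())
  e$labeled <- labeled
  e$unlabeled <- unlabeled
  e$batch_size <- as.integer(batch_size)
  e$labeled_per_batch <- as.integer(labeled_per_batch)
  e$lab_queue <- integer(0)
  e$unlab_queue <- integer(0)
  class(e) <- "batch_sampler"
  e
}

draw_from <- function(sampler, queue_name, pool_len, k) {
  idx <- integer(0)
  while (length(idx) < k) {
    if (length(sampler[[queue_name]]) == 0L)
      sampler[[queue_name]] <- sample.int(pool_len)
    take <- min(k - length(idx), length(sampler[[queue_name]]))
    idx <- c(idx, sampler[[queue_name]][seq_len(take)])
    sampler[[queue_name]] <- sampler[[queue_name]][-seq_len(take)]
  }
  idx
}

#' Draw the next batch from a sampler
#'
#' @param sampler a [batch_sampler()].
#' @return an `image_batch`: `images` `(1,H,W,B)`, `labels` `(H,W,B_l)` for
#'   the labeled half, `labeled_count`, and per-item `meta`.
#' @export
next_batch <- function(sampler) {
  nl <- sampler$labeled_per_batch
  nu <- sampler$batch_size - nl
  li <- draw_from(sampler, "lab_queue", length(sampler$labeled), nl)
  pairs <- sampler$labeled[li]
  if (nu > 0L) {
    ui <- draw_from(sampler, "unlab_queue", length(sampler$unlabeled), nu)
    pairs <- c(pairs, sampler$unlabeled[ui])
  }
  st <- stack_slices(pairs)
  labels <- array(0L, dim = c(dim(st$images)[2], dim(st$images)[3], nl))
  for (b in seq_len(nl)) labels[, , b] <- pairs[[b]]$label
  structure(list(images = st$images, labels = labels, labeled_count = nl,
                 meta = lapply(pairs, function(p)
                   list(scan_id = p$scan_id, slice_index = p$slice_index))),
            class = "image_batch")
}
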