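# Synthetic low-contrast segmentation fixtures.
#
# Emulates the regime the fusion branch targets - smooth organ-like blobs
# whose intensity differs only modestly from the background and whose
# boundaries are blurred - without claiming anatomical realism. Every other
# module is testable at desk scale against these fixtures with no downloads.

#' Specification of a synthetic dataset
#'
#' Defaults are the package's desk-scale study conditions: 20 scans of 10
#' slices at 64x64 with 2 classes, a foreground/background mean-intensity
#' gap of 0.2 (low contrast), 2 px boundary blur and additive Gaussian
#' noise of sd 0.15 - calibrated so a supervised-only baseline trained on a
#' 10 percent labeled split is clearly below ceiling, matching the regime
#' semi-supervised training targets.
#'
#' @param n_scans number of synthetic scans.
#' @param slices_per_scan slices per scan.
#' @param image_size square slice size in pixels (>= 16).
#' @param n_classes classes including background (>= 2).
#' @param contrast foreground/background mean-intensity gap in `(0, 1]`.
#' @param boundary_blur_sigma Gaussian blur sd at class boundaries (pixels).
#' @param noise_sigma additive Gaussian noise sd (intensity units).
#' @param seed RNG seed; the same spec yields a byte-identical dataset.
#' @return a `fixture_spec` list.
#' @export
fixture_spec <- function(n_scans = 20L, slices_per_scan = 10L,
                         image_size = 64L, n_classes = 2L, contrast = 0.2,
                         boundary_blur_sigma = 2, noise_sigma = 0.15,
                         seed = 1L) {
  stopifnot(contrast > 0, contrast <= 1, noise_sigma >= 0, n_classes >= 2)
  if (image_size < 16L) stop("image_size must be >= 16")
  structure(list(n_scans = as.integer(n_scans),
                 slices_per_scan = as.integer(slices_per_scan),
                 image_size = as.integer(image_size),
                 n_classes = as.integer(n_classes),
                 contrast = contrast,
                 boundary_blur_sigma = boundary_blur_sigma,
                 noise_sigma = noise_sigma,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

# paint the union of 1-3 random ellipses for one class; returns logical mask
paint_ellipses <- function(size, n_ell, r_scale = 1) {
  xs <- matrix(seq_len(size), size, size)
  ys <- matrix(seq_len(size), size, size, byrow = TRUE)
  mask <- matrix(FALSE, size, size)
  for (k in seq_len(n_ell)) {
    cx <- runif(1, 0.25 * size, 0.75 * size)
    cy <- runif(1, 0.25 * size, 0.75 * size)
    a <- runif(1, 0.08, 0.22) * size * r_scale
    b <- runif(1, 0.08, 0.22) * size * r_scale
    th <- runif(1, 0, pi)
    u <- (xs - cx) * cos(th) + (ys - cy) * sin(th)
    v <- -(xs - cx) * sin(th) + (ys - cy) * cos(th)
    mask <- mask | (u^2 / a^2 + v^2 / b^2 <= 1)
  }
  mask
}

# one slice: exact label map plus a low-contrast blurred noisy image.
# foreground fraction is kept in [0.02, 0.5] by rescaling and redrawing.
render_slice <- function(spec) {
  size <- spec$image_size
  C <- spec$n_classes
  for (try in 1:20) {
    label <- matrix(0L, size, size)
    for (cl in seq_len(C - 1L)) {
      m <- paint_ellipses(size, sample(1:3, 1))
      label[m] <- cl
    }
    frac <- mean(label > 0)
    if (frac >= 0.02 && frac <= 0.5) break
  }
  if (frac < 0.02 || frac > 0.5) { # pathological draw: force one mid ellipse
    label <- matrix(0L, size, size)
    label[paint_ellipses(size, 1L, r_scale = 1)] <- 1L
  }
  bg <- 0.5 - spec$contrast / 2
  img <- bg + spec$contrast * (label / (C - 1L))
  if (spec$boundary_blur_sigma > 0)
    img <- EBImage::gblur(img, sigma = spec$boundary_blur_sigma)
  if (spec$noise_sigma > 0)
    img <- img + matrix(rnorm(size * size, sd = spec$noise_sigma), size, size)
  img <- pmin(pmax(img, 0), 1)
  list(image = img, label = label)
}

#' Generate a synthetic dataset
#'
#' Writes (or returns) a dataset in the package's on-disk layout:
#' `images/scanNN_sMM.png` (8-bit grayscale), `labels/scanNN_sMM.png`
#' (class indices) and a `dataset.yaml` with the generating parameters.
#' Deterministic: the same spec produces byte-identical files.
#'
#' @param spec a [fixture_spec()].
#' @param out_dir output directory, created if needed; `NULL` keeps the
#'   dataset in memory only.
#' @return (invisibly) the list of `slice_pair`s.
#' @export
generate_fixture_dataset <- function(spec, out_dir = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)
  pairs <- list()
  for (sc in seq_len(spec$n_scans)) {
    for (sl in seq_len(spec$slices_per_scan)) {
      r <- render_slice(spec)
      pairs[[length(pairs) + 1L]] <-
        slice_pair(r$image, r$label, sprintf("scan%02d", sc), sl)
    }
  }
  if (!is.null(out_dir)) {
    dir.create(file.path(out_dir, "images"), recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(out_dir, "labels"), recursive = TRUE, showWarnings = FALSE)
    for (p in pairs) {
      fn <- sprintf("%s_s%03d.png", p$scan_id, p$slice_index)
      png::writePNG(p$image, file.path(out_dir, "images", fn))
      write_mask_png(p$label, file.path(out_dir, "labels", fn))
    }
    yaml::write_yaml(unclass(spec), file.path(out_dir, "dataset.yaml"))
  }
  invisible(pairs)
}

#' Hand-sized arrays for loss and decoupling unit tests
#'
#' Small confidence/score maps with values fixed in code:
#' \itemize{
#'   \item `uniform_conf`: 2x2, C = 2, every pixel (0.5, 0.5).
#'   \item `onehot_conf`: 2x2, C = 2, per-pixel max exactly 1.
#'   \item `mixed_pair`: two 2x2, C = 3 confidence maps whose per-pixel
#'     maxima are (0.9, 0.6, 0.55, 0.95) and (0.92, 0.7, 0.5, 0.4) -
#'     threshold/decoupling fixtures.
#'   \item `pfm_pixel`: single-pixel C = 2 feature vectors (2, -2) and
#'     (-1, 1) for the perspective-fusion arithmetic.
#' }
#' @return named list of arrays in the `(C,H,W,B)` layout.
#' @export
tiny_tensor_fixtures <- function() {
  conf2 <- function(maxes, C) {
    # per-pixel: max in class 1, remainder spread evenly over other classes
    arr <- array(0, dim = c(C, 2, 2, 1))
    for (p in seq_len(4)) {
      h <- (p - 1) %% 2 + 1; w <- (p - 1) %/% 2 + 1
      arr[1, h, w, 1] <- maxes[p]
      arr[2:C, h, w, 1] <- (1 - maxes[p]) / (C - 1)
    }
    arr
  }
  uniform <- array(0.5, dim = c(2, 2, 2, 1))
  onehot4 <- array(0, dim = c(2, 2, 2, 1))
  onehot4[1, , , 1] <- c(1, 0, 1, 0)
  onehot4[2, , , 1] <- c(0, 1, 0, 1)
  list(uniform_conf = uniform,
       onehot_conf = onehot4,
       mixed_pair = list(P_pos = conf2(c(0.9, 0.6, 0.55, 0.95), 3L),
                         P_rev = conf2(c(0.92, 0.7, 0.5, 0.4), 3L)),
       pfm_pixel = list(f_pos = array(c(2, -2), dim = c(2, 1, 1, 1)),
                        f_rev = array(c(-1, 1), dim = c(2, 1, 1, 1))))
}
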