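# Evaluation metrics: Dice, Jaccard, 95th-percentile Hausdorff distance and
# average surface distance, computed per class on scan volumes re-stacked
# from 2-D slices.

#' Dice and Jaccard coefficients of two binary masks
#'
#' Both masks empty is scored as perfect agreement (1, 1); exactly one empty
#' as complete disagreement (0, 0).
#' @param pred_mask,true_mask logical/0-1 arrays of identical shape.
#' @return named numeric vector `c(dice=, jaccard=)` in `[0, 1]`.
#' @export
dice_jaccard <- function(pred_mask, true_mask) {
  if (!identical(dim(pred_mask) %||% length(pred_mask),
                 dim(true_mask) %||% length(true_mask)))
    stop("dice_jaccard: shape mismatch")
  a <- as.logical(pred_mask); b <- as.logical(true_mask)
  na <- sum(a); nb <- sum(b)
  if (na == 0 && nb == 0) return(c(dice = 1, jaccard = 1))
  if (na == 0 || nb == 0) return(c(dice = 0, jaccard = 0))
  inter <- sum(a & b)
  c(dice = 2 * inter / (na + nb), jaccard = inter / (na + nb - inter))
}

# boundary voxels: mask voxels with at least one face neighbour outside the
# mask (voxels on the array edge count, matching erosion with zero padding)
boundary_coords <- function(mask) {
  d <- dim(mask)
  if (length(d) == 2L) { mask <- array(mask, c(d, 1L)); d <- dim(mask) }
  pad <- array(FALSE, d + 2L)
  pad[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- mask
  core <- pad[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)]
  er <- core &
    pad[1:d[1], 2:(d[2] + 1L), 2:(d[3] + 1L)] &
    pad[3:(d[1] + 2L), 2:(d[2] + 1L), 2:(d[3] + 1L)] &
    pad[2:(d[1] + 1L), 1:d[2], 2:(d[3] + 1L)] &
    pad[2:(d[1] + 1L), 3:(d[2] + 2L), 2:(d[3] + 1L)] &
    pad[2:(d[1] + 1L), 2:(d[2] + 1L), 1:d[3]] &
    pad[2:(d[1] + 1L), 2:(d[2] + 1L), 3:(d[3] + 2L)]
  bnd <- core & !er
  dim(bnd) <- d   # subsetting may have dropped a singleton axis
  which(bnd, arr.ind = TRUE)
}

# directed minimum distances from each row of A to the point set B (n x 3
# coordinate matrices, already scaled by spacing), chunked to bound memory
directed_min_dist <- function(A, B, chunk = 512L) {
  nb <- nrow(B)
  b2 <- rowSums(B * B)
  out <- numeric(nrow(A))
  i <- 1L
  while (i <= nrow(A)) {
    j <- min(i + chunk - 1L, nrow(A))
    Ac <- A[i:j, , drop = FALSE]
    d2 <- outer(rowSums(Ac * Ac), b2, "+") - 2 * tcrossprod(Ac, B)
    out[i:j] <- sqrt(pmax(apply(d2, 1L, min), 0))
    i <- j + 1L
  }
  out
}

#' Surface distance metrics between two binary masks
#'
#' Extracts the boundary voxels of each mask, pools the directed boundary
#' distances in both directions, and reports their 95th percentile (95HD)
#' and mean (ASD) in voxel units scaled by `spacing`. The pooled-percentile
#' convention (rather than the max of per-direction percentiles) is used.
#'
#' @param pred_mask,true_mask binary arrays (2-D or 3-D) of identical shape.
#' @param spacing voxel spacing per axis (length 1 or the array rank).
#' @return named numeric vector `c(hd95=, asd=)`.
#' @export
surface_distances <- function(pred_mask, true_mask, spacing = 1) {
  if (!identical(dim(pred_mask), dim(true_mask)))
    stop("surface_distances: shape mismatch")
  if (sum(pred_mask) == 0 || sum(true_mask) == 0)
    stop("surface_distances: empty mask; use evaluate_scan for scored ",
         "empty-case handling")
  A <- boundary_coords(pred_mask)
  B <- boundary_coords(true_mask)
  sp <- rep(spacing, length.out = 3L)
  A <- sweep(A, 2L, sp, "*")
  B <- sweep(B, 2L, sp, "*")
  d_ab <- directed_min_dist(A, B)
  d_ba <- directed_min_dist(B, A)
  pooled <- c(d_ab, d_ba)
  c(hd95 = unname(stats::quantile(pooled, 0.95, names = FALSE)),
    asd = mean(pooled))
}

#' Evaluate one scan (stacked slices) per class
#'
#' Stacks the 2-D slices of one scan into a 3-D volume (unit inter-slice
#' spacing unless given) and computes Dice/Jaccard (percent) and 95HD/ASD
#' (voxel) per non-background class. Empty prediction with non-empty truth
#' (or vice versa) scores Dice/Jaccard 0 and the surface metrics as the
#' volume diagonal, flagged in the result; both empty scores Dice/Jaccard
#' 100 and surface 0.
#'
#' @param pred_slices,true_slices lists of integer `(H,W)` class maps in
#'   scan order, or `(H,W,S)` arrays.
#' @param classes integer vector of class labels to score (default: all
#'   non-background classes present in the truth or prediction).
#' @param spacing voxel spacing (length 3).
#' @return data.frame with columns class, dice, jaccard, hd95, asd,
#'   empty_flag.
#' @export
evaluate_scan <- function(pred_slices, true_slices, classes = NULL,
                          spacing = c(1, 1, 1)) {
  tovol <- function(x) {
    if (is.list(x)) {
      stopifnot(length(x) > 0)
      array(unlist(x), dim = c(dim(x[[1]]), length(x)))
    } else if (length(dim(x)) == 2L) array(x, c(dim(x), 1L)) else x
  }
  pv <- tovol(pred_slices); tv <- tovol(true_slices)
  if (!identical(dim(pv), dim(tv))) stop("evaluate_scan: shape mismatch")
  if (is.null(classes)) {
    classes <- sort(setdiff(unique(c(as.integer(pv), as.integer(tv))), 0L))
    if (length(classes) == 0L) classes <- 1L
  }
  diag_len <- sqrt(sum((dim(pv) * rep(spacing, length.out = 3L))^2))
  rows <- lapply(classes, function(cl) {
    p <- pv == cl; t <- tv == cl
    dj <- dice_jaccard(p, t)
    np <- sum(p); nt <- sum(t)
    if (np > 0 && nt > 0) {
      sd <- surface_distances(p, t, spacing)
      flag <- ""
    } else if (np == 0 && nt == 0) {
      sd <- c(hd95 = 0, asd = 0); flag <- "both_empty"
    } else {
      sd <- c(hd95 = diag_len, asd = diag_len)
      flag <- if (np == 0) "empty_pred" else "empty_truth"
    }
    data.frame(class = cl, dice = 100 * dj[["dice"]],
               jaccard = 100 * dj[["jaccard"]],
               hd95 = sd[["hd95"]], asd = sd[["asd"]],
               empty_flag = flag, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Aggregate per-scan metric tables
#'
#' Unweighted mean over scans and classes of each metric.
#' @param reports list of [evaluate_scan()] data.frames (one per scan).
#' @return one-row data.frame with mean dice, jaccard, hd95, asd and the
#'   count of empty-case entries.
#' @export
aggregate_metrics <- function(reports) {
  all <- do.call(rbind, reports)
  data.frame(dice = mean(all$dice), jaccard = mean(all$jaccard),
             hd95 = mean(all$hd95), asd = mean(all$asd),
             n_empty = sum(all$empty_flag != ""))
}
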