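# Dynamic threshold and consistent/inconsistent decoupling.
#
# The confidence threshold gamma starts at 1/C and is updated every
# iteration as an exponential moving average of the batch's mean maximum
# confidence, separately per branch, with interpolation weight
# lambda = i/i_max; the final threshold is the minimum of the two branch
# values so that more pixels qualify early in training. Pixels where both
# branches' maximum confidences strictly exceed gamma form the consistent
# part; the remainder is the inconsistent part, further split per pixel by
# which branch is the more confident one.

#' Initialize the dynamic-threshold state
#'
#' @param n_classes number of classes C; the threshold starts at `1/C`.
#' @param i_max total number of training iterations (sets the EMA weight
#'   `lambda = i/i_max`).
#' @return a `threshold_state` list with fields `gamma`, `gamma_pos`,
#'   `gamma_rev`, `i`, `i_max`.
#' @export
threshold_state <- function(n_classes, i_max) {
  stopifnot(n_classes >= 2, i_max >= 1)
  structure(list(gamma = 1 / n_classes,
                 gamma_pos = 1 / n_classes,
                 gamma_rev = 1 / n_classes,
                 i = 0L, i_max = as.integer(i_max)),
            class = "threshold_state")
}

# batch statistic: mean over pixels and batch items of the per-pixel
# max-class confidence (a max over all pixels would saturate immediately)
mean_max_confidence <- function(P) mean(conf_max(P))

#' Advance the dynamic threshold by one iteration
#'
#' Per branch, `gamma_branch <- (1 - lambda) * gamma_branch + lambda * s`
#' where `s` is the batch mean of the per-pixel maximum confidence and
#' `lambda = i/i_max` for the new iteration count `i`. The combined threshold
#' is `min(gamma_pos, gamma_rev)`.
#'
#' @param state a [threshold_state()].
#' @param P_pos,P_rev confidence-map arrays `(C,H,W,B)` (class-normalized).
#' @return the updated `threshold_state`.
#' @export
update_threshold <- function(state, P_pos, P_rev) {
  stopifnot(inherits(state, "threshold_state"))
  if (state$i >= state$i_max)
    stop("threshold_state already at i_max iterations")
  i_new <- state$i + 1L
  lambda <- i_new / state$i_max
  s_pos <- mean_max_confidence(P_pos)
  s_rev <- mean_max_confidence(P_rev)
  state$gamma_pos <- (1 - lambda) * state$gamma_pos + lambda * s_pos
  state$gamma_rev <- (1 - lambda) * state$gamma_rev + lambda * s_rev
  state$gamma <- min(state$gamma_pos, state$gamma_rev)
  state$i <- i_new
  state
}

#' Partition pixels into consistent and inconsistent parts
#'
#' A pixel is consistent iff the maximum-class confidence of *both* branches
#' strictly exceeds `gamma`. Within the inconsistent part, `HM_pos` marks
#' pixels where the positive branch is strictly more confident than the
#' reverse branch and `HM_rev` the converse; ties belong to neither.
#'
#' @param P_pos,P_rev confidence-map arrays `(C,H,W,B)` of identical shape.
#' @param gamma scalar threshold in `[0, 1]`.
#' @return a `decouple_masks` list of logical arrays `(H,W,B)`:
#'   `M_con`, `M_incon`, `HM_pos`, `HM_rev`.
#' @export
decouple <- function(P_pos, P_rev, gamma) {
  if (!identical(dim(P_pos), dim(P_rev)))
    stop("decouple: P_pos and P_rev shapes differ")
  stopifnot(gamma >= 0, gamma <= 1)
  mp <- conf_max(P_pos)
  mr <- conf_max(P_rev)
  M_con <- (mp > gamma) & (mr > gamma)
  M_incon <- !M_con
  structure(list(M_con = M_con,
                 M_incon = M_incon,
                 HM_pos = M_incon & (mp > mr),
                 HM_rev = M_incon & (mr > mp)),
            class = "decouple_masks")
}

# expand an (H,W,B) logical mask to a (C,H,W,B) numeric multiplier
expand_mask_c <- function(mask, C) {
  d <- dim(mask)
  array(rep(as.numeric(mask), each = C), dim = c(C, d))
}

#' Split the inconsistent part into high/low-confidence counterparts
#'
#' At pixels where the positive branch wins (`HM_pos`), its confidences are
#' the high-confidence map `hP_pos` and the reverse branch's confidences at
#' the same pixels are the low-confidence counterpart `lP_rev` (and
#' symmetrically for `HM_rev`). All four outputs are full-shape maps, zero
#' outside their masks, so the direction-consistency distance compares maps
#' on shared support.
#'
#' @param P_pos,P_rev confidence-map arrays `(C,H,W,B)`.
#' @param masks a [decouple()] result for the same maps.
#' @return list of arrays `hP_pos`, `lP_pos`, `hP_rev`, `lP_rev`.
#' @export
split_confidence <- function(P_pos, P_rev, masks) {
  C <- dim(P_pos)[1]
  mp <- expand_mask_c(masks$HM_pos, C)
  mr <- expand_mask_c(masks$HM_rev, C)
  list(hP_pos = mp * P_pos,   # positive branch's winning confidences
       lP_rev = mp * P_rev,   # reverse branch at the same pixels
       hP_rev = mr * P_rev,
       lP_pos = mr * P_pos)
}
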