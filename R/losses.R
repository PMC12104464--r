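# Training objectives.
#
# Every loss accepts either plain numeric arrays (returning a numeric
# scalar; used by tests and oracles) or autodiff nodes (returning a scalar
# node; used by the trainer), through one shared implementation. All weights
# in the total objective are 1.

loss_scalar <- function(x) if (is_tnode(x)) x$value else x

maybe_value <- function(node, had_node) if (had_node) node else node$value

#' One-hot encode an integer label map
#' @param labels integer array `(H,W,B)` with values in `0..C-1`.
#' @param C number of classes.
#' @return numeric array `(C,H,W,B)`.
#' @export
onehot <- function(labels, C) {
  d <- dim(labels)
  out <- array(0, dim = c(C, d))
  flat <- as.integer(labels)
  if (any(flat < 0L | flat >= C)) stop("label values outside 0..C-1")
  idx <- (flat + 1L) + C * (seq_along(flat) - 1L)
  out[idx] <- 1
  out
}

#' Soft Dice loss
#'
#' `1 - (2*sum(P*g) + eps) / (sum(P) + sum(g) + eps)` computed per class and
#' per batch item, then averaged. Range `[0, 1]`; 0 for a perfect one-hot
#' match.
#'
#' @param P confidence map `(C,H,W,B)`, class-normalized (array or node).
#' @param gt_onehot one-hot target of the same shape (numeric array).
#' @param eps smoothing constant in numerator and denominator.
#' @return scalar (numeric or node, matching `P`).
#' @export
dice_loss <- function(P, gt_onehot, eps = 1e-5) {
  had_node <- is_tnode(P)
  Pn <- as_tnode(P)
  d <- dim(tn_value(Pn))
  if (!identical(d, dim(gt_onehot))) stop("dice_loss: shape mismatch")
  inter <- tn_cb_sum(tn_mul(Pn, gt_onehot))        # C x B
  psum <- tn_cb_sum(Pn)
  gsum <- apply(array(gt_onehot, c(d[1], d[2] * d[3], d[4])), c(1, 3), sum)
  dice <- tn_div(tn_add(tn_scale(inter, 2), eps),
                 tn_add(tn_add(psum, gsum), eps))
  loss <- tn_sub(1, tn_mean(dice))
  maybe_value(loss, had_node)
}

#' Per-branch supervised Dice losses on the labeled items
#'
#' The reverse branch is supervised through prediction-map inversion: its
#' confidence map is `softmax(-O_rev)` and the ground truth is untouched.
#' Under the `"ground_truth"` inversion ablation the raw `softmax(O_rev)` is
#' instead matched against the inverted one-hot target
#' `(1 - onehot)/(C - 1)`.
#'
#' @param outputs a [mp_forward()] result (or any list with `P_pos`, `P_rev`,
#'   `P_fus` maps restricted to the full batch).
#' @param labels integer label array `(H,W,B_l)` for the labeled items.
#' @param labeled_idx indices of the labeled items within the batch (labeled
#'   items come first by construction).
#' @param inversion `"prediction_map"` or `"ground_truth"`.
#' @return list with `sup_p`, `sup_r`, `sup_f` (0 for absent branches).
#' @export
supervised_losses <- function(outputs, labels, labeled_idx,
                              inversion = "prediction_map") {
  if (length(labeled_idx) == 0L) {
    warning("no labeled items in batch; supervised losses skipped")
    return(list(sup_p = 0, sup_r = 0, sup_f = 0))
  }
  C <- dim(tn_value(outputs$P_pos))[1]
  g <- onehot(labels, C)
  slice_l <- function(P) {
    if (is_tnode(P)) tn_slice_b(P, labeled_idx)
    else P[, , , labeled_idx, drop = FALSE]
  }
  sup_p <- dice_loss(slice_l(outputs$P_pos), g)
  sup_r <- 0
  if (!is.null(outputs$P_rev)) {
    if (inversion == "ground_truth") {
      g_inv <- (1 - g) / (C - 1)
      sup_r <- dice_loss(slice_l(outputs$P_rev), g_inv)
    } else {
      sup_r <- dice_loss(slice_l(outputs$P_rev), g)
    }
  }
  sup_f <- if (!is.null(outputs$P_fus)) dice_loss(slice_l(outputs$P_fus), g) else 0
  list(sup_p = sup_p, sup_r = sup_r, sup_f = sup_f)
}

# support size (pixel count) of a masked confidence map: pixels whose
# channel sum is nonzero (softmax confidences are strictly positive on the
# mask, exactly zero off it)
mask_support <- function(h) {
  v <- tn_value(h)
  d <- dim(v)
  s <- colSums(matrix(v, d[1], prod(d) / d[1]))
  sum(s > 0)
}

#' Direction consistency loss on the inconsistent part
#'
#' Pulls each branch's low-confidence predictions toward the other branch's
#' high-confidence predictions at the same pixels:
#' `L2(lP_rev, detach(hP_pos)) + L2(lP_pos, detach(hP_rev))`, each term the
#' mean squared difference over its supporting pixels and classes. The
#' high-confidence operands are detached (stop-gradient), so only the losing
#' branch is updated. Returns 0 when both supports are empty.
#'
#' @param hP_pos,lP_pos,hP_rev,lP_rev maps from [split_confidence()] (arrays
#'   or nodes), zero outside their masks.
#' @return scalar loss (numeric or node).
#' @export
direction_consistency_loss <- function(hP_pos, lP_pos, hP_rev, lP_rev) {
  had_node <- any(vapply(list(hP_pos, lP_pos, hP_rev, lP_rev), is_tnode,
                         logical(1)))
  C <- dim(tn_value(hP_pos))[1]
  term <- function(l, h) {
    n <- mask_support(h)
    if (n == 0) return(tn_const(0))
    diff <- tn_sub(as_tnode(l), tn_detach(h))
    tn_scale(tn_sum(tn_mul(diff, diff)), 1 / (n * C))
  }
  loss <- tn_add(term(lP_rev, hP_pos), term(lP_pos, hP_rev))
  maybe_value(loss, had_node)
}

#' Mean confidence of two branches
#'
#' Mean over all pixels and items of the average of the two per-pixel
#' maximum-class confidences; gates the cross-pseudo supervision arms at
#' 0.95.
#' @param P_pos,P_rev confidence arrays `(C,H,W,B)`.
#' @return scalar in `[1/C, 1]`.
#' @export
mean_confidence <- function(P_pos, P_rev) {
  mean((conf_max(tn_value(P_pos)) + conf_max(tn_value(P_rev))) / 2)
}

# cross-entropy of scores against an integer pseudo-label map, restricted to
# a pixel mask; mean over contributing pixels (fused kernel)
masked_ce <- function(O, PL, mask) {
  if (sum(mask) == 0) return(tn_const(0))
  On <- as_tnode(O)
  Ov <- tn_value(On)
  d <- dim(Ov)
  C <- as.integer(d[1]); n <- as.integer(prod(d) / C)
  lab <- as.integer(PL)
  mk <- as.logical(mask)
  fw <- cpp_masked_ce_fwd(Ov, lab, mk, C, n)
  new_tnode(fw$value, list(On), function(g) {
    gr <- cpp_masked_ce_bwd(as.numeric(g), fw$p, lab, mk, fw$n_masked, C, n)
    dim(gr) <- d
    list(gr)
  })
}

#' Confidence-gated pairwise cross-pseudo supervision on the consistent part
#'
#' Below mean confidence 0.95, only the positive/reverse pair exchanges
#' pseudo-labels (2 cross-entropy terms); at or above it, all enabled
#' perspective pairs do (up to 6 terms). Pseudo-labels are per-pixel argmaxes
#' of the comparator's confidence map and carry no gradient; each term is the
#' per-pixel cross-entropy after softmax, averaged over the consistent pixels
#' of the unlabeled items. The reverse branch participates through its
#' positively-oriented scores `-O_rev`.
#'
#' @param outputs list with score maps `O_pos`, `O_rev_neg`, optionally
#'   `O_fus`, and confidence maps `P_pos`, `P_rev`, `P_fus` (arrays or
#'   nodes), restricted to the unlabeled items.
#' @param masks a [decouple()] result for the same items.
#' @param m_confidence the gating statistic from [mean_confidence()].
#' @param pairs subset of `c("P-R", "P-F", "R-F")` enabled for the
#'   high-confidence arm (ablation switch).
#' @return scalar loss with attribute `n_terms` (number of CE terms
#'   evaluated). Returns 0 when the consistent part is empty.
#' @export
cps_loss <- function(outputs, masks, m_confidence,
                     pairs = c("P-R", "P-F", "R-F")) {
  had_node <- is_tnode(outputs$O_pos)
  M <- masks$M_con
  terms <- list()
  if (sum(M) > 0) {
    pl <- function(P) conf_argmax(tn_value(P))
    PL_pos <- pl(outputs$P_pos)
    PL_rev <- pl(outputs$P_rev)
    if (m_confidence < 0.95) {
      if ("P-R" %in% pairs) {
        terms <- list(masked_ce(outputs$O_pos, PL_rev, M),
                      masked_ce(outputs$O_rev_neg, PL_pos, M))
      }
    } else {
      if ("P-R" %in% pairs) {
        terms <- c(terms, list(masked_ce(outputs$O_pos, PL_rev, M),
                               masked_ce(outputs$O_rev_neg, PL_pos, M)))
      }
      if (!is.null(outputs$O_fus)) {
        PL_fus <- pl(outputs$P_fus)
        if ("P-F" %in% pairs) {
          terms <- c(terms, list(masked_ce(outputs$O_pos, PL_fus, M),
                                 masked_ce(outputs$O_fus, PL_pos, M)))
        }
        if ("R-F" %in% pairs) {
          terms <- c(terms, list(masked_ce(outputs$O_rev_neg, PL_fus, M),
                                 masked_ce(outputs$O_fus, PL_rev, M)))
        }
      }
    }
  }
  loss <- tn_const(0)
  for (t in terms) loss <- tn_add(loss, t)
  out <- maybe_value(loss, had_node)
  attr(out, "n_terms") <- length(terms)
  out
}

#' Channel compression of a feature map
#'
#' `(1/C_m) * sum_i |f_i|^p` over the channel axis (p = 2 by default),
#' mapping `(C_m,H,W,B)` to a non-negative `(1,H,W,B)` map.
#' @param f feature map (array or node).
#' @param p exponent.
#' @return compressed map, same type as `f`.
#' @export
channel_compress <- function(f, p = 2) {
  had_node <- is_tnode(f)
  fn <- as_tnode(f)
  C <- dim(tn_value(fn))[1]
  out <- tn_scale(tn_chan_sum(tn_abspow(fn, p)), 1 / C)
  maybe_value(out, had_node)
}

#' Feature consistency loss for one branch
#'
#' For each resolution level with both an encoder and a decoder feature map,
#' compresses both maps over channels and accumulates their squared
#' pixelwise difference; `reduce = "mean"` (default) averages each level
#' over its pixels so the loss is resolution-independent, `"sum"` keeps the
#' raw sum.
#'
#' @param enc_pyramid,dec_pyramid lists of feature maps (arrays or nodes),
#'   matching spatial sizes level by level.
#' @param p compression exponent.
#' @param reduce `"mean"` or `"sum"` per level.
#' @return scalar loss (numeric or node).
#' @export
feature_consistency_loss <- function(enc_pyramid, dec_pyramid, p = 2,
                                     reduce = c("mean", "sum")) {
  reduce <- match.arg(reduce)
  if (length(enc_pyramid) != length(dec_pyramid))
    stop("feature_consistency_loss: pyramids have different level counts")
  had_node <- any(vapply(c(enc_pyramid, dec_pyramid), is_tnode, logical(1)))
  loss <- tn_const(0)
  for (m in seq_along(enc_pyramid)) {
    de <- dim(tn_value(enc_pyramid[[m]]))
    dd <- dim(tn_value(dec_pyramid[[m]]))
    if (!identical(de[-1], dd[-1]))
      stop("feature_consistency_loss: spatial shape mismatch at level ", m)
    ce <- channel_compress(as_tnode(enc_pyramid[[m]]), p)
    cd <- channel_compress(as_tnode(dec_pyramid[[m]]), p)
    diff <- tn_sub(ce, cd)
    sq <- tn_mul(diff, diff)
    loss <- tn_add(loss, if (reduce == "mean") tn_mean(sq) else tn_sum(sq))
  }
  maybe_value(loss, had_node)
}

#' Assemble the loss bundle
#'
#' Unweighted sum of the six components; errors on any non-finite component.
#' @param components named list/vector with `sup_p`, `sup_r`, `sup_f`,
#'   `cps`, `dc`, `feat` (numeric scalars).
#' @return a `loss_bundle` list with the components and their `total`.
#' @export
total_loss <- function(components) {
  need <- c("sup_p", "sup_r", "sup_f", "cps", "dc", "feat")
  vals <- vapply(need, function(k) {
    v <- components[[k]]
    if (is.null(v)) 0 else as.numeric(loss_scalar(v))
  }, numeric(1))
  bad <- need[!is.finite(vals)]
  if (length(bad))
    stop("non-finite loss component: ", paste(bad, collapse = ", "))
  structure(c(as.list(vals), list(total = sum(vals))), class = "loss_bundle")
}
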