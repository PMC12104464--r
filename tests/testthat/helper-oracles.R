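# Independent scalar oracles used across the suite. These deliberately use
# plain loops / closed forms and share no code with the package internals.

softmax_ref <- function(v) {
  e <- exp(v - max(v))
  e / sum(e)
}

# channelwise softmax of a (C,H,W,B) array via the scalar reference
softmax_ref_arr <- function(x) {
  d <- dim(x)
  out <- array(0, dim = d)
  for (h in seq_len(d[2])) for (w in seq_len(d[3])) for (b in seq_len(d[4]))
    out[, h, w, b] <- softmax_ref(x[, h, w, b])
  out
}

# perspective fusion, one pixel at a time
pfm_ref_pixel <- function(fp, fv) {
  fp - softmax_ref(-fp) * softmax_ref(fv)
}

pfm_ref <- function(f_pos, f_rev) {
  d <- dim(f_pos)
  out <- array(0, dim = d)
  for (h in seq_len(d[2])) for (w in seq_len(d[3])) for (b in seq_len(d[4]))
    out[, h, w, b] <- pfm_ref_pixel(f_pos[, h, w, b], f_rev[, h, w, b])
  out
}

# soft Dice loss, scalar arithmetic per class and item
dice_ref <- function(P, g, eps = 1e-5) {
  d <- dim(P)
  acc <- 0
  for (b in seq_len(d[4])) for (cl in seq_len(d[1])) {
    p <- P[cl, , , b]; t <- g[cl, , , b]
    acc <- acc + (1 - (2 * sum(p * t) + eps) / (sum(p) + sum(t) + eps))
  }
  acc / (d[1] * d[4])
}

ce_ref_pixel <- function(scores, label0) {
  -log(softmax_ref(scores)[label0 + 1])
}

# per-pixel decoupling oracle
decouple_ref <- function(P_pos, P_rev, gamma) {
  d <- dim(P_pos)
  M_con <- array(FALSE, d[-1]); HM_pos <- array(FALSE, d[-1]); HM_rev <- array(FALSE, d[-1])
  for (h in seq_len(d[2])) for (w in seq_len(d[3])) for (b in seq_len(d[4])) {
    mp <- max(P_pos[, h, w, b]); mr <- max(P_rev[, h, w, b])
    if (mp > gamma && mr > gamma) {
      M_con[h, w, b] <- TRUE
    } else {
      if (mp > mr) HM_pos[h, w, b] <- TRUE
      if (mr > mp) HM_rev[h, w, b] <- TRUE
    }
  }
  list(M_con = M_con, M_incon = !M_con, HM_pos = HM_pos, HM_rev = HM_rev)
}

# exhaustive surface-distance oracle: all boundary voxel pairs, pooled
surface_ref <- function(pred, true, spacing = c(1, 1, 1)) {
  bnd <- function(m) {
    d <- dim(m)
    pts <- NULL
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
      if (!m[i, j, k]) next
      nb <- c(
        if (i > 1) m[i - 1, j, k] else FALSE,
        if (i < d[1]) m[i + 1, j, k] else FALSE,
        if (j > 1) m[i, j - 1, k] else FALSE,
        if (j < d[2]) m[i, j + 1, k] else FALSE,
        if (k > 1) m[i, j, k - 1] else FALSE,
        if (k < d[3]) m[i, j, k + 1] else FALSE)
      if (!all(nb)) pts <- rbind(pts, c(i, j, k))
    }
    pts
  }
  A <- bnd(pred); B <- bnd(true)
  dmin <- function(P, Q) {
    sapply(seq_len(nrow(P)), function(i)
      min(sqrt(colSums((t(Q) * spacing - P[i, ] * spacing)^2))))
  }
  da <- dmin(A, B); db <- dmin(B, A)
  pooled <- c(da, db)
  c(hd95 = unname(quantile(pooled, 0.95, names = FALSE)), asd = mean(pooled))
}

# random normalized confidence map (C,H,W,B)
rand_conf <- function(C, H, W, B) {
  v <- array(runif(C * H * W * B, 0.1, 1), dim = c(C, H, W, B))
  m <- v; dim(m) <- c(C, H * W * B)
  m <- sweep(m, 2, colSums(m), "/")
  dim(m) <- c(C, H, W, B)
  m
}

# a small preprocessed in-memory dataset for trainer tests
tiny_dataset <- function(n_scans = 6, slices = 2, size = 16, seed = 11) {
  spec <- fixture_spec(n_scans = n_scans, slices_per_scan = slices,
                       image_size = size, seed = seed)
  pp <- lapply(generate_fixture_dataset(spec), preprocess_slice, size = size)
  scan_of <- vapply(pp, function(p) p$scan_id, character(1))
  scans <- unique(scan_of)
  list(labeled = pp[scan_of == scans[1]],
       unlabeled = pp[scan_of %in% scans[2:4]],
       val = pp[scan_of == scans[5]],
       test = pp[scan_of == scans[6]])
}
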