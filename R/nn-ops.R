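# Layer operators for the segmentation engine.
#
# The pixel-loop kernels (3x3 convolution via im2col + GEMM, 2x2 transposed
# convolution, 2x2 max pooling, bilinear x2 upsampling, batch normalization)
# are compiled (src/kernels.cpp); these wrappers build the autodiff nodes
# around them. 1x1 convolutions are a plain GEMM and stay in R. Layout is
# (C,H,W,B), channel fastest.

# ---- conv 3x3 (pad 1, stride 1) --------------------------------------------
# w: matrix (Cout x Cin*9) with column index k = cin + Cin*(kh + 3*kw);
# optional bias b (omitted inside conv+norm blocks).
nn_conv3 <- function(x, w, b = NULL) {
  xv <- tn_value(x); wv <- tn_value(w)
  d <- dim(xv)
  fw <- cpp_conv3_fwd(xv, wv, d[1], d[2], d[3], d[4])
  OUT <- fw$out
  if (!is.null(b)) OUT <- OUT + tn_value(b)
  Cout <- nrow(wv)
  parents <- if (is.null(b)) list(x, w) else list(x, w, b)
  new_tnode(OUT, parents, function(g) {
    bw <- cpp_conv3_bwd(g, wv, fw$col, d[1], d[2], d[3], d[4])
    if (is.null(b)) list(bw$dx, bw$dw)
    else {
      gm <- g; dim(gm) <- c(Cout, length(g) / Cout)
      list(bw$dx, bw$dw, rowSums(gm))
    }
  })
}

# ---- conv 1x1 ---------------------------------------------------------------
nn_conv1 <- function(x, w, b) {
  xv <- tn_value(x); wv <- tn_value(w); bv <- tn_value(b)
  d <- dim(xv)
  Cin <- d[1]; n <- prod(d) / Cin
  Cout <- nrow(wv)
  X <- xv; dim(X) <- c(Cin, n)
  OUT <- wv %*% X + bv
  dim(OUT) <- c(Cout, d[2], d[3], d[4])
  new_tnode(OUT, list(x, w, b), function(g) {
    gm <- g; dim(gm) <- c(Cout, n)
    dW <- tcrossprod(gm, X)
    db <- rowSums(gm)
    dX <- crossprod(wv, gm)
    dim(dX) <- d
    list(dX, dW, db)
  })
}

# ---- transposed conv 2x2, stride 2 ------------------------------------------
# w: matrix ((Cout*4) x Cin), rows indexed (cout, dh, dw) with cout fastest.
nn_convT2 <- function(x, w, b) {
  xv <- tn_value(x); wv <- tn_value(w); bv <- tn_value(b)
  d <- dim(xv)
  OUT <- cpp_convT2_fwd(xv, wv, bv, d[1], d[2], d[3], d[4])
  new_tnode(OUT, list(x, w, b), function(g) {
    bw <- cpp_convT2_bwd(g, xv, wv, d[1], d[2], d[3], d[4])
    list(bw$dx, bw$dw, bw$db)
  })
}

# ---- max pool 2x2 -----------------------------------------------------------
nn_maxpool2 <- function(x) {
  xv <- tn_value(x)
  d <- dim(xv)
  fw <- cpp_maxpool2_fwd(xv, d[1], d[2], d[3], d[4])
  new_tnode(fw$out, list(x), function(g) {
    list(cpp_maxpool2_bwd(g, fw$which, d[1], d[2], d[3], d[4]))
  })
}

# ---- bilinear x2 upsampling (align_corners = FALSE) -------------------------
nn_upsample2 <- function(x) {
  xv <- tn_value(x)
  d <- dim(xv)
  OUT <- cpp_up2_fwd(xv, d[1], d[2], d[3], d[4])
  new_tnode(OUT, list(x), function(g) {
    list(cpp_up2_bwd(g, d[1], d[2], d[3], d[4]))
  })
}

# ---- batch normalization ----------------------------------------------------
# gamma, beta: parameter nodes of length C. rstate: environment with running
# mean/var (updated in training mode, used in eval mode).
new_bn_state <- function(C) {
  e <- new.env(parent = emptyenv())
  e$mean <- numeric(C)
  e$var <- rep(1, C)
  e
}

nn_batchnorm <- function(x, gamma, beta, rstate, training,
                         momentum = 0.1, eps = 1e-5) {
  xv <- tn_value(x); gv <- tn_value(gamma); bv <- tn_value(beta)
  d <- dim(xv)
  C <- d[1]; n <- as.integer(prod(d) / C)
  if (training) {
    st <- cpp_chan_stats(xv, C, n)
    mu <- st$mean; va <- st$var
    rstate$mean <- (1 - momentum) * rstate$mean + momentum * mu
    rstate$var <- (1 - momentum) * rstate$var + momentum * va
  } else {
    mu <- rstate$mean
    va <- rstate$var
  }
  fw <- cpp_bn_fwd(xv, gv, bv, mu, va, eps, C, n)
  out <- fw$out
  dim(out) <- d
  new_tnode(out, list(x, gamma, beta), function(g) {
    bw <- cpp_bn_bwd(g, fw$xhat, fw$invstd, gv, training, C, n)
    dx <- bw$dx
    dim(dx) <- d
    list(dx, bw$dgamma, bw$dbeta)
  })
}
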