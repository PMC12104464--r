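# Reverse-mode automatic differentiation over plain R arrays.
#
# The training engine needs gradients through convolutions, softmax, masked
# losses and stop-gradient (detach) operators. Nodes are environments holding
# a value, the parent nodes and a backward closure that maps the node's
# gradient to gradients for each parent. Node ids increase monotonically as
# the graph is built, so reachable-nodes-sorted-by-decreasing-id is a valid
# reverse topological order.
#
# Tensor layout convention throughout the package: dim = c(C, H, W, B) with
# the channel axis fastest, so matrix(x, C, H*W*B) exposes per-pixel channel
# vectors as columns (what softmax, batch-norm and the GEMM kernels need).

.tnode_counter <- new.env(parent = emptyenv())
.tnode_counter$id <- 0L

tnode_next_id <- function() {
  .tnode_counter$id <- .tnode_counter$id + 1L
  .tnode_counter$id
}

#' Create an autodiff graph node
#'
#' @param value numeric array (any shape; losses are length-1).
#' @param parents list of parent `tnode`s the value was computed from.
#' @param backward function(grad) returning a list of gradients, one per
#'   parent (NULL entries allowed for parents that need no gradient).
#' @param requires_grad force the node to participate in backpropagation
#'   (used for leaf parameters).
#' @return an object of class `tnode`.
#' @keywords internal
new_tnode <- function(value, parents = list(), backward = NULL,
                      requires_grad = FALSE) {
  rg <- requires_grad
  if (!rg) {
    for (p in parents) if (p$requires_grad) { rg <- TRUE; break }
  }
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$parents <- if (rg) parents else list()
  e$backward <- if (rg) backward else NULL
  e$requires_grad <- rg
  e$grad <- NULL
  e$id <- tnode_next_id()
  class(e) <- "tnode"
  e
}

#' Leaf parameter node (receives gradients)
#' @param value initial numeric array.
#' @keywords internal
tn_param <- function(value) new_tnode(value, requires_grad = TRUE)

#' Constant node (no gradient)
#' @param value numeric array.
#' @keywords internal
tn_const <- function(value) new_tnode(value)

is_tnode <- function(x) inherits(x, "tnode")

#' Coerce an array to a constant node; pass nodes through
#' @keywords internal
as_tnode <- function(x) if (is_tnode(x)) x else tn_const(x)

#' Value of a node (or the array itself)
#' @keywords internal
tn_value <- function(x) if (is_tnode(x)) x$value else x

#' Stop-gradient: a constant node carrying the same value
#' @keywords internal
tn_detach <- function(x) tn_const(tn_value(x))

#' Backpropagate from a scalar loss node
#'
#' Accumulates gradients into `$grad` of every reachable node that requires
#' one. Gradients of reachable nodes are reset first, so repeated calls do
#' not accumulate across graphs.
#' @param root scalar `tnode`.
#' @keywords internal
tn_backward <- function(root) {
  stopifnot(is_tnode(root), length(root$value) == 1L)
  seen <- new.env(hash = TRUE, parent = emptyenv())
  stack <- list(root)
  nodes <- vector("list", 64L); nn <- 0L
  while (length(stack)) {
    nd <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    key <- as.character(nd$id)
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    nn <- nn + 1L
    if (nn > length(nodes)) nodes <- c(nodes, vector("list", length(nodes)))
    nodes[[nn]] <- nd
    for (p in nd$parents) if (p$requires_grad) stack[[length(stack) + 1L]] <- p
  }
  nodes <- nodes[seq_len(nn)]
  ids <- vapply(nodes, function(n) n$id, integer(1))
  nodes <- nodes[order(ids, decreasing = TRUE)]
  for (nd in nodes) nd$grad <- NULL
  root$grad <- 1
  for (nd in nodes) {
    if (is.null(nd$backward) || is.null(nd$grad)) next
    gs <- nd$backward(nd$grad)
    ps <- nd$parents
    for (k in seq_along(ps)) {
      p <- ps[[k]]
      if (!p$requires_grad || k > length(gs) || is.null(gs[[k]])) next
      p$grad <- if (is.null(p$grad)) gs[[k]] else p$grad + gs[[k]]
    }
  }
  invisible(root)
}

# ---- elementwise arithmetic -------------------------------------------------
# One operand may be a plain numeric (scalar or same-shape array): it is
# treated as a constant. Scalar nodes broadcast against array nodes.

bcast_grad <- function(g, target_value) {
  if (length(target_value) == 1L && length(g) > 1L) sum(g) else g
}

tn_add <- function(a, b) {
  av <- tn_value(a); bv <- tn_value(b)
  an <- is_tnode(a); bn <- is_tnode(b)
  parents <- c(if (an) list(a), if (bn) list(b))
  new_tnode(av + bv, parents, function(g) {
    out <- list()
    if (an) out <- c(out, list(bcast_grad(g, av)))
    if (bn) out <- c(out, list(bcast_grad(g, bv)))
    out
  })
}

tn_sub <- function(a, b) {
  av <- tn_value(a); bv <- tn_value(b)
  an <- is_tnode(a); bn <- is_tnode(b)
  parents <- c(if (an) list(a), if (bn) list(b))
  new_tnode(av - bv, parents, function(g) {
    out <- list()
    if (an) out <- c(out, list(bcast_grad(g, av)))
    if (bn) out <- c(out, list(bcast_grad(-g, bv)))
    out
  })
}

tn_mul <- function(a, b) {
  av <- tn_value(a); bv <- tn_value(b)
  an <- is_tnode(a); bn <- is_tnode(b)
  parents <- c(if (an) list(a), if (bn) list(b))
  new_tnode(av * bv, parents, function(g) {
    out <- list()
    if (an) out <- c(out, list(bcast_grad(g * bv, av)))
    if (bn) out <- c(out, list(bcast_grad(g * av, bv)))
    out
  })
}

tn_div <- function(a, b) {
  av <- tn_value(a); bv <- tn_value(b)
  an <- is_tnode(a); bn <- is_tnode(b)
  parents <- c(if (an) list(a), if (bn) list(b))
  new_tnode(av / bv, parents, function(g) {
    out <- list()
    if (an) out <- c(out, list(bcast_grad(g / bv, av)))
    if (bn) out <- c(out, list(bcast_grad(-g * av / (bv * bv), bv)))
    out
  })
}

tn_neg <- function(a) {
  new_tnode(-tn_value(a), list(a), function(g) list(-g))
}

tn_scale <- function(a, k) {
  new_tnode(tn_value(a) * k, list(a), function(g) list(g * k))
}

tn_relu <- function(a) {
  av <- tn_value(a)
  v <- cpp_relu_fwd(av)
  dim(v) <- dim(av)
  new_tnode(v, list(a), function(g) {
    gi <- cpp_relu_bwd(g, av)
    dim(gi) <- dim(av)
    list(gi)
  })
}

# log with clamping away from 0 so CE on hard-saturated softmax stays finite
tn_log <- function(a, eps = 1e-12) {
  av <- tn_value(a)
  if (any(av < eps)) av[av < eps] <- eps
  new_tnode(log(av), list(a), function(g) list(g / av))
}

# ---- reductions -------------------------------------------------------------

tn_sum <- function(a) {
  av <- tn_value(a)
  new_tnode(sum(av), list(a), function(g) {
    gr <- array(as.numeric(g), dim = dim(av) %||% length(av))
    list(gr)
  })
}

tn_mean <- function(a) {
  av <- tn_value(a)
  n <- length(av)
  new_tnode(sum(av) / n, list(a), function(g) {
    gr <- array(as.numeric(g) / n, dim = dim(av) %||% length(av))
    list(gr)
  })
}

# per-class sums: (C,H,W,B) -> numeric length C
tn_class_sum <- function(a) {
  av <- tn_value(a)
  d <- dim(av)
  C <- d[1]
  m <- av; dim(m) <- c(C, prod(d) / C)
  new_tnode(rowSums(m), list(a), function(g) {
    gr <- matrix(g, C, prod(d) / C)
    dim(gr) <- d
    list(gr)
  })
}

# per-class, per-item sums: (C,H,W,B) -> C x B matrix
tn_cb_sum <- function(a) {
  av <- tn_value(a)
  d <- dim(av)
  C <- d[1]; HW <- d[2] * d[3]; B <- d[4]
  m <- av; dim(m) <- c(C, HW, B)
  v <- matrix(0, C, B)
  for (b in seq_len(B)) {
    mb <- m[, , b, drop = FALSE]
    dim(mb) <- c(C, HW)
    v[, b] <- rowSums(mb)
  }
  new_tnode(v, list(a), function(g) {
    gr <- array(0, dim = c(C, HW, B))
    for (b in seq_len(B)) gr[, , b] <- matrix(g[, b], C, HW)
    dim(gr) <- d
    list(gr)
  })
}

# |x|^p elementwise (p >= 1); p = 2 short-circuits to a square
tn_abspow <- function(a, p = 2) {
  av <- tn_value(a)
  if (p == 2) {
    return(new_tnode(av * av, list(a), function(g) list(2 * g * av)))
  }
  v <- abs(av)^p
  new_tnode(v, list(a), function(g) {
    list(g * p * abs(av)^(p - 1) * sign(av))
  })
}

# sum over the channel axis: (C,H,W,B) -> (1,H,W,B)
tn_chan_sum <- function(a) {
  av <- tn_value(a)
  d <- dim(av)
  C <- d[1]; n <- prod(d) / C
  m <- av; dim(m) <- c(C, n)
  v <- colSums(m)
  dim(v) <- c(1L, d[2], d[3], d[4])
  new_tnode(v, list(a), function(g) {
    gr <- matrix(rep(as.numeric(g), each = C), C, n)
    dim(gr) <- d
    list(gr)
  })
}

# ---- softmax over the channel axis -----------------------------------------

softmax_c_value <- function(v) {
  d <- dim(v)
  p <- cpp_softmax_fwd(v, as.integer(d[1]), as.integer(prod(d) / d[1]))
  dim(p) <- d
  p
}

tn_softmax_c <- function(a) {
  av <- tn_value(a)
  d <- dim(av)
  C <- as.integer(d[1]); n <- as.integer(prod(d) / C)
  p <- cpp_softmax_fwd(av, C, n)
  dim(p) <- d
  new_tnode(p, list(a), function(g) {
    gr <- cpp_softmax_bwd(g, p, C, n)
    dim(gr) <- d
    list(gr)
  })
}

# ---- structural ops ---------------------------------------------------------

# batch slice: keep items `idx` along the 4th axis
tn_slice_b <- function(a, idx) {
  av <- tn_value(a)
  d <- dim(av)
  v <- av[, , , idx, drop = FALSE]
  new_tnode(v, list(a), function(g) {
    gr <- array(0, dim = d)
    gr[, , , idx] <- g
    list(gr)
  })
}

# concatenate along the channel axis
tn_concat_c <- function(a, b) {
  av <- tn_value(a); bv <- tn_value(b)
  da <- dim(av); db <- dim(bv)
  stopifnot(all(da[-1] == db[-1]))
  v <- array(0, dim = c(da[1] + db[1], da[2], da[3], da[4]))
  v[seq_len(da[1]), , , ] <- av
  v[da[1] + seq_len(db[1]), , , ] <- bv
  new_tnode(v, list(a, b), function(g) {
    list(g[seq_len(da[1]), , , , drop = FALSE],
         g[da[1] + seq_len(db[1]), , , , drop = FALSE])
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
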