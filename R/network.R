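# Three-branch encoder-decoder segmentation network.
#
# Two independent U-Net-style encoders extract positive-perspective
# (foreground) and reverse-perspective (background) feature pyramids. Three
# decoders produce score maps: the positive decoder up-samples by bilinear
# interpolation + 1x1 convolution, the reverse and fusion decoders by 2x2
# transposed convolution. The fusion decoder consumes features combined by
# the perspective fusion module at every level. The reverse branch's scores
# are negated (reverse module) before softmax, so its confidence maps are
# oriented like the positive branch's while its features encode background.

#' Network configuration
#'
#' @param in_channels number of image channels (1 for grayscale slices).
#' @param n_classes number of segmentation classes C (>= 2), background = 0.
#' @param base_width channels at the full-resolution level; doubles per level.
#' @param depth number of resolution levels (>= 2); input height/width must be
#'   divisible by `2^(depth-1)`.
#' @param branches which branches to build: `"pos"` (supervised-only
#'   baseline), `"pos+rev"`, `"pos+pos+fus"` (second branch trained without
#'   score reversal) or `"pos+rev+fus"` (full model).
#' @param share_encoders if TRUE the two perspectives share one encoder
#'   (ablation; the default FALSE keeps them independent).
#' @param fuse_levels `"all"` fuses positive/reverse features at the
#'   bottleneck and every skip level; `"bottleneck_only"` fuses only the
#'   bottleneck and passes the positive branch's skips unfused.
#' @param inversion `"prediction_map"` (negate reverse scores before softmax)
#'   or `"ground_truth"` (softmax the raw reverse scores and invert the
#'   one-hot target in the supervised loss; ablation arm).
#' @param inference_head branch whose confidence map is used for prediction.
#' @return a `network_config` list.
#' @export
network_config <- function(in_channels = 1L, n_classes = 2L, base_width = 8L,
                           depth = 3L, branches = "pos+rev+fus",
                           share_encoders = FALSE, fuse_levels = "all",
                           inversion = "prediction_map",
                           inference_head = "pos") {
  stopifnot(depth >= 2L, base_width >= 4L, n_classes >= 2L)
  branches <- match.arg(branches, c("pos", "pos+rev", "pos+pos+fus",
                                    "pos+rev+fus"))
  fuse_levels <- match.arg(fuse_levels, c("all", "bottleneck_only"))
  inversion <- match.arg(inversion, c("prediction_map", "ground_truth"))
  inference_head <- match.arg(inference_head, c("pos", "rev", "fus"))
  structure(list(in_channels = as.integer(in_channels),
                 n_classes = as.integer(n_classes),
                 base_width = as.integer(base_width),
                 depth = as.integer(depth),
                 branches = branches,
                 share_encoders = isTRUE(share_encoders),
                 fuse_levels = fuse_levels,
                 inversion = inversion,
                 inference_head = inference_head),
            class = "network_config")
}

cfg_has_rev <- function(cfg) cfg$branches != "pos"
cfg_has_fus <- function(cfg) cfg$branches %in% c("pos+pos+fus", "pos+rev+fus")
cfg_branch2_reversed <- function(cfg) cfg$branches %in% c("pos+rev", "pos+rev+fus")

kaiming <- function(n, fan_in) rnorm(n) * sqrt(2 / fan_in)

# parameter collector: builds named tn_param nodes in deterministic order
new_collector <- function() {
  e <- new.env(parent = emptyenv())
  e$params <- list()
  e$bn <- list()
  e
}

add_param <- function(col, name, value) {
  p <- tn_param(value)
  col$params[[name]] <- p
  p
}

add_conv3 <- function(col, name, cin, cout) {
  add_param(col, paste0(name, ".w"),
            matrix(kaiming(cout * cin * 9L, cin * 9L), cout, cin * 9L))
  add_param(col, paste0(name, ".b"), numeric(cout))
}

add_conv1 <- function(col, name, cin, cout) {
  add_param(col, paste0(name, ".w"),
            matrix(kaiming(cout * cin, cin), cout, cin))
  add_param(col, paste0(name, ".b"), numeric(cout))
}

add_convT2 <- function(col, name, cin, cout) {
  add_param(col, paste0(name, ".w"),
            matrix(kaiming(cout * 4L * cin, cin * 4L), cout * 4L, cin))
  add_param(col, paste0(name, ".b"), numeric(cout))
}

add_bn <- function(col, name, c) {
  add_param(col, paste0(name, ".g"), rep(1, c))
  add_param(col, paste0(name, ".be"), numeric(c))
  col$bn[[name]] <- new_bn_state(c)
}

# convs inside a conv+norm block carry no bias (the norm's shift absorbs it)
add_double_conv <- function(col, name, cin, cout) {
  add_param(col, paste0(name, ".c1.w"),
            matrix(kaiming(cout * cin * 9L, cin * 9L), cout, cin * 9L))
  add_bn(col, paste0(name, ".n1"), cout)
  add_param(col, paste0(name, ".c2.w"),
            matrix(kaiming(cout * cout * 9L, cout * 9L), cout, cout * 9L))
  add_bn(col, paste0(name, ".n2"), cout)
}

#' Build the multi-perspective network
#'
#' Initializes all parameter sets (positive/reverse encoders, the three
#' decoders) with Kaiming-normal weights from a seeded RNG: the same seed
#' yields bitwise-identical parameters. When `share_encoders = TRUE` the
#' reverse encoder is the same parameter set as the positive encoder.
#'
#' @param config a [network_config()].
#' @param seed integer RNG seed for weight initialization.
#' @return a `mp_network` object (parameters, batch-norm states, config).
#' @export
mp_build <- function(config, seed = 1L) {
  stopifnot(inherits(config, "network_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  col <- new_collector()
  depth <- config$depth
  wd <- config$base_width * 2L^(0:(depth - 1L))
  enc_spec <- function(prefix) {
    for (m in seq_len(depth)) {
      cin <- if (m == 1L) config$in_channels else wd[m - 1L]
      add_double_conv(col, sprintf("%s.enc%d", prefix, m), cin, wd[m])
    }
  }
  dec_spec <- function(prefix, mode) {
    for (m in seq_len(depth - 1L)) {       # m counts from the bottleneck down
      lev <- depth - m                      # target level
      if (mode == "bilinear") {
        add_conv1(col, sprintf("%s.up%d", prefix, lev), wd[lev + 1L], wd[lev])
      } else {
        add_convT2(col, sprintf("%s.up%d", prefix, lev), wd[lev + 1L], wd[lev])
      }
      add_double_conv(col, sprintf("%s.dec%d", prefix, lev), 2L * wd[lev], wd[lev])
    }
    add_conv1(col, paste0(prefix, ".head"), wd[1L], config$n_classes)
  }
  enc_spec("encP")
  if (cfg_has_rev(config) && !config$share_encoders) enc_spec("encR")
  dec_spec("decP", "bilinear")
  if (cfg_has_rev(config)) dec_spec("decR", "convT")
  if (cfg_has_fus(config)) dec_spec("decF", "convT")
  net <- list(cfg = config, params = col$params, bn = col$bn, wd = wd)
  class(net) <- "mp_network"
  net
}

#' Elementwise score reversal (reverse module)
#'
#' Negates a score or feature map prior to softmax; applying it twice is the
#' identity.
#' @param x numeric array or graph node.
#' @return object of the same kind, negated.
#' @export
reverse_module <- function(x) {
  if (is_tnode(x)) tn_neg(x) else -x
}

pfm_node <- function(f_pos, f_rev) {
  f_r_pos <- tn_softmax_c(tn_neg(f_pos))
  f_mul <- tn_mul(f_r_pos, tn_softmax_c(f_rev))
  tn_sub(f_pos, f_mul)
}

#' Perspective fusion module
#'
#' Combines positive and reverse feature maps:
#' `f_fus = f_pos - softmax(-f_pos) * softmax(f_rev)` with the softmax taken
#' over the channel axis per pixel. The multiplicative term is large where
#' both perspectives agree, so subtracting it amplifies the response in
#' regions they disagree on (typically object boundaries).
#'
#' @param f_pos,f_rev feature maps of identical shape; plain numeric arrays
#'   with the channel axis first (a vector is treated as a single pixel) or
#'   graph nodes.
#' @return the fused map, same type and shape as the inputs.
#' @export
perspective_fusion <- function(f_pos, f_rev) {
  if (is_tnode(f_pos) || is_tnode(f_rev)) {
    return(pfm_node(as_tnode(f_pos), as_tnode(f_rev)))
  }
  if (!identical(dim(f_pos) %||% length(f_pos), dim(f_rev) %||% length(f_rev)))
    stop("perspective_fusion: shape mismatch between f_pos and f_rev")
  d0 <- dim(f_pos)
  a <- as4d(f_pos); b <- as4d(f_rev)
  out <- pfm_node(tn_const(a), tn_const(b))$value
  if (is.null(d0)) out <- as.numeric(out) else dim(out) <- d0
  out
}

# promote vector/2d/3d channel-first arrays to (C,H,W,B)
as4d <- function(x) {
  d <- dim(x)
  if (is.null(d)) d <- length(x)
  v <- array(x, dim = c(d, rep(1L, 4L - length(d))))
  v
}

run_double_conv <- function(net, name, x, training) {
  p <- net$params
  h <- nn_conv3(x, p[[paste0(name, ".c1.w")]])
  h <- nn_batchnorm(h, p[[paste0(name, ".n1.g")]], p[[paste0(name, ".n1.be")]],
                    net$bn[[paste0(name, ".n1")]], training)
  h <- tn_relu(h)
  h <- nn_conv3(h, p[[paste0(name, ".c2.w")]])
  h <- nn_batchnorm(h, p[[paste0(name, ".n2.g")]], p[[paste0(name, ".n2.be")]],
                    net$bn[[paste0(name, ".n2")]], training)
  tn_relu(h)
}

run_encoder <- function(net, prefix, x, training) {
  depth <- net$cfg$depth
  feats <- vector("list", depth)
  h <- x
  for (m in seq_len(depth)) {
    if (m > 1L) h <- nn_maxpool2(h)
    h <- run_double_conv(net, sprintf("%s.enc%d", prefix, m), h, training)
    feats[[m]] <- h
  }
  feats
}

run_decoder <- function(net, prefix, mode, bottom, skips, training) {
  p <- net$params
  depth <- net$cfg$depth
  feats <- vector("list", depth - 1L)
  h <- bottom
  for (lev in (depth - 1L):1L) {
    up_w <- p[[sprintf("%s.up%d.w", prefix, lev)]]
    up_b <- p[[sprintf("%s.up%d.b", prefix, lev)]]
    h <- if (mode == "bilinear") nn_conv1(nn_upsample2(h), up_w, up_b)
         else nn_convT2(h, up_w, up_b)
    h <- tn_concat_c(skips[[lev]], h)
    h <- run_double_conv(net, sprintf("%s.dec%d", prefix, lev), h, training)
    feats[[lev]] <- h
  }
  scores <- nn_conv1(h, p[[paste0(prefix, ".head.w")]],
                     p[[paste0(prefix, ".head.b")]])
  list(scores = scores, feats = feats)
}

#' Forward pass through all branches
#'
#' @param net a built [mp_build()] network.
#' @param images numeric array `(C_in, H, W, B)`; H and W must be divisible
#'   by `2^(depth-1)`.
#' @param training logical; TRUE uses batch statistics in the normalization
#'   layers (and updates their running averages), FALSE uses running
#'   statistics (deterministic evaluation).
#' @return a `perspective_outputs` list with score-map nodes `O_pos`,
#'   `O_rev`, `O_fus`, the negated reverse scores `O_rev_neg`, confidence-map
#'   nodes `P_pos`, `P_rev`, `P_fus` (each summing to 1 over classes), and
#'   per-branch encoder/decoder feature pyramids `enc_pyr`, `dec_pyr`.
#' @export
mp_forward <- function(net, images, training = TRUE) {
  cfg <- net$cfg
  d <- dim(images)
  stopifnot(length(d) == 4L, d[1] == cfg$in_channels)
  div <- 2L^(cfg$depth - 1L)
  if (d[2] %% div != 0L || d[3] %% div != 0L)
    stop(sprintf("image size %dx%d not divisible by 2^(depth-1) = %d",
                 d[2], d[3], div))
  x <- tn_const(images)
  depth <- cfg$depth
  e_pos <- run_encoder(net, "encP", x, training)
  e_rev <- NULL
  if (cfg_has_rev(cfg)) {
    enc_r_prefix <- if (cfg$share_encoders) "encP" else "encR"
    e_rev <- run_encoder(net, enc_r_prefix, x, training)
  }
  dP <- run_decoder(net, "decP", "bilinear", e_pos[[depth]], e_pos, training)
  out <- list(O_pos = dP$scores, P_pos = tn_softmax_c(dP$scores),
              enc_pyr = list(pos = e_pos[seq_len(depth - 1L)]),
              dec_pyr = list(pos = dP$feats))
  if (cfg_has_rev(cfg)) {
    dR <- run_decoder(net, "decR", "convT", e_rev[[depth]], e_rev, training)
    out$O_rev <- dR$scores
    out$O_rev_neg <- if (cfg_branch2_reversed(cfg)) tn_neg(dR$scores) else dR$scores
    # prediction-map inversion: confidences from the negated scores; the
    # ground-truth-inversion ablation softmaxes the raw scores instead
    out$P_rev <- if (cfg_branch2_reversed(cfg) && cfg$inversion == "prediction_map")
      tn_softmax_c(tn_neg(dR$scores)) else tn_softmax_c(dR$scores)
    out$enc_pyr$rev <- e_rev[seq_len(depth - 1L)]
    out$dec_pyr$rev <- dR$feats
  }
  if (cfg_has_fus(cfg)) {
    fus_bottom <- pfm_node(e_pos[[depth]], e_rev[[depth]])
    fus_skips <- if (cfg$fuse_levels == "all") {
      lapply(seq_len(depth - 1L), function(m) pfm_node(e_pos[[m]], e_rev[[m]]))
    } else {
      e_pos[seq_len(depth - 1L)]
    }
    dF <- run_decoder(net, "decF", "convT", fus_bottom, fus_skips, training)
    out$O_fus <- dF$scores
    out$P_fus <- tn_softmax_c(dF$scores)
  }
  class(out) <- "perspective_outputs"
  out
}

#' Predict class masks for a stack of slices
#'
#' Runs an evaluation-mode forward pass and takes the per-pixel argmax of the
#' configured inference head (positive branch by default).
#' @param net a trained network.
#' @param images array `(C_in, H, W, B)`.
#' @param head override the inference head ("pos", "rev" or "fus").
#' @return integer array `(H, W, B)` of 0-based class indices.
#' @export
mp_predict <- function(net, images, head = NULL) {
  head <- head %||% net$cfg$inference_head
  out <- mp_forward(net, images, training = FALSE)
  P <- switch(head, pos = out$P_pos, rev = out$P_rev, fus = out$P_fus)
  if (is.null(P)) stop("inference head '", head, "' not built in this network")
  conf_argmax(P$value)
}

# per-pixel argmax over the channel axis: (C,H,W,B) -> (H,W,B), 0-based
conf_argmax <- function(P) {
  d <- dim(P)
  m <- P; dim(m) <- c(d[1], prod(d) / d[1])
  am <- max.col(t(m), ties.method = "first") - 1L
  array(am, dim = d[-1])
}

# per-pixel max confidence: (C,H,W,B) -> (H,W,B)
conf_max <- function(P) {
  d <- dim(P)
  m <- P; dim(m) <- c(d[1], prod(d) / d[1])
  mx <- m[1, ]
  if (d[1] > 1L) for (cc in 2:d[1]) mx <- pmax.int(mx, m[cc, ])
  array(mx, dim = d[-1])
}
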