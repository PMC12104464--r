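# Training orchestration: batch assembly, augmentation, forward pass,
# threshold update, decoupling, losses, SGD, validation and checkpointing.

#' Training configuration
#'
#' Defaults mirror the reference protocol: SGD with learning rate 0.01,
#' momentum 0.9 and weight decay 5e-4; batches of 24 slices of which 12 are
#' labeled; random flips and 90-degree rotations. Desk-scale runs override
#' `iterations`, `batch_size` and the network size.
#'
#' @param iterations total optimization steps `i_max`.
#' @param lr,momentum,weight_decay SGD hyperparameters.
#' @param batch_size,labeled_per_batch batch composition (labeled first).
#' @param augment enable random flips / 90-degree rotations.
#' @param network a [network_config()].
#' @param threshold `"dynamic"` or a fixed numeric value in `[0, 1]`
#'   (ablation).
#' @param cps_pairs perspective pairs enabled for cross-pseudo supervision.
#' @param unsup_weight multiplier on the unsupervised components (1 = full
#'   model, 0 = supervised-only training).
#' @param feat_reduce per-level reduction of the feature-consistency loss.
#' @param val_every validation cadence in steps (0 disables).
#' @param seed global seed covering weight init, data order, augmentation.
#' @return a `train_config` list.
#' @export
train_config <- function(iterations = 50000L, lr = 0.01, momentum = 0.9,
                         weight_decay = 5e-4, batch_size = 24L,
                         labeled_per_batch = 12L, augment = TRUE,
                         network = network_config(),
                         threshold = "dynamic",
                         cps_pairs = c("P-R", "P-F", "R-F"),
                         unsup_weight = 1, feat_reduce = "mean",
                         val_every = 200L, seed = 1L) {
  stopifnot(iterations >= 1L, lr > 0, labeled_per_batch >= 1L,
            labeled_per_batch <= batch_size)
  if (is.numeric(threshold)) stopifnot(threshold >= 0, threshold <= 1)
  structure(list(iterations = as.integer(iterations), lr = lr,
                 momentum = momentum, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 labeled_per_batch = as.integer(labeled_per_batch),
                 augment = isTRUE(augment), network = network,
                 threshold = threshold, cps_pairs = cps_pairs,
                 unsup_weight = unsup_weight, feat_reduce = feat_reduce,
                 val_every = as.integer(val_every), seed = as.integer(seed)),
            class = "train_config")
}

# flips/rotations on one (H,W) plane
flip_h <- function(m) m[rev(seq_len(nrow(m))), , drop = FALSE]
flip_v <- function(m) m[, rev(seq_len(ncol(m))), drop = FALSE]
rot90k <- function(m, k) {
  k <- k %% 4
  if (k == 0) return(m)
  for (i in seq_len(k)) m <- t(m[rev(seq_len(nrow(m))), , drop = FALSE])
  m
}

#' Randomly flip/rotate a batch
#'
#' Per item: horizontal and vertical flips each with probability 0.5 and a
#' rotation by a uniformly drawn multiple of 90 degrees (interpolation-free,
#' so labels keep their exact value set). The identical transform is applied
#' to the image and, for labeled items, the label map; unlabeled items are
#' transformed too.
#'
#' @param batch an `image_batch` from [next_batch()].
#' @return the augmented batch.
#' @export
augment_batch <- function(batch) {
  B <- dim(batch$images)[4]
  for (b in seq_len(B)) {
    fh <- runif(1) < 0.5
    fv <- runif(1) < 0.5
    k <- sample(0:3, 1)
    tf <- function(m) {
      if (fh) m <- flip_h(m)
      if (fv) m <- flip_v(m)
      rot90k(m, k)
    }
    for (ch in seq_len(dim(batch$images)[1]))
      batch$images[ch, , , b] <- tf(batch$images[ch, , , b])
    if (b <= batch$labeled_count)
      batch$labels[, , b] <- tf(batch$labels[, , b])
  }
  batch
}

new_sgd <- function(params, lr, momentum, weight_decay) {
  e <- new.env(parent = emptyenv())
  e$lr <- lr; e$momentum <- momentum; e$wd <- weight_decay
  e$vel <- lapply(params, function(p) p$value * 0)  # preserves shape exactly
  names(e$vel) <- names(params)
  e
}

sgd_step <- function(opt, params) {
  for (nm in names(params)) {
    p <- params[[nm]]
    g <- p$grad
    if (is.null(g)) next
    g <- g + opt$wd * p$value
    v <- opt$momentum * opt$vel[[nm]] + g
    opt$vel[[nm]] <- v
    p$value <- p$value - opt$lr * v
    p$grad <- NULL
  }
  invisible(opt)
}

#' One training step
#'
#' Forward pass on the full batch; dynamic-threshold update and
#' consistent/inconsistent decoupling on the unlabeled half; supervised Dice
#' losses on the labeled half; cross-pseudo supervision on the consistent
#' part; direction-consistency on the inconsistent part; feature-consistency
#' on both perspective branches; one SGD step over all parameter sets.
#'
#' @param net a built network ([mp_build()]).
#' @param batch an `image_batch` (labeled items first).
#' @param tstate a [threshold_state()] (advanced in the returned value).
#' @param config a [train_config()].
#' @param opt optimizer state from a previous call, or NULL to create one.
#' @return list: `bundle` ([total_loss()] components), `tstate`, `opt`, and
#'   diagnostics `gamma`, `m`, `con_frac`, `n_cps_terms`.
#' @export
train_step <- function(net, batch, tstate, config, opt = NULL) {
  cfg <- net$cfg
  if (is.null(opt)) opt <- new_sgd(net$params, config$lr, config$momentum,
                                   config$weight_decay)
  out <- mp_forward(net, batch$images, training = TRUE)
  nl <- batch$labeled_count
  B <- dim(batch$images)[4]
  unlab <- if (nl < B) (nl + 1L):B else integer(0)

  sup <- supervised_losses(out, batch$labels, seq_len(nl),
                           inversion = cfg$inversion)
  cps_l <- tn_const(0); dc_l <- tn_const(0)
  gamma <- NA_real_; m_conf <- NA_real_; con_frac <- NA_real_
  n_terms <- 0L
  has_unsup <- config$unsup_weight > 0 && cfg_has_rev(cfg)
  if (has_unsup && length(unlab) > 0L) {
    Ppos_u <- tn_value(out$P_pos)[, , , unlab, drop = FALSE]
    Prev_u <- tn_value(out$P_rev)[, , , unlab, drop = FALSE]
    if (identical(config$threshold, "dynamic")) {
      if (tstate$i < tstate$i_max)
        tstate <- update_threshold(tstate, Ppos_u, Prev_u)
      gamma <- tstate$gamma
    } else {
      gamma <- config$threshold
    }
    masks <- decouple(Ppos_u, Prev_u, gamma)
    con_frac <- mean(masks$M_con)
    m_conf <- mean_confidence(Ppos_u, Prev_u)
    u_out <- list(O_pos = tn_slice_b(out$O_pos, unlab),
                  O_rev_neg = tn_slice_b(out$O_rev_neg, unlab),
                  P_pos = Ppos_u, P_rev = Prev_u)
    if (!is.null(out$O_fus)) {
      u_out$O_fus <- tn_slice_b(out$O_fus, unlab)
      u_out$P_fus <- tn_value(out$P_fus)[, , , unlab, drop = FALSE]
    }
    cps_l <- cps_loss(u_out, masks, m_conf, pairs = config$cps_pairs)
    n_terms <- attr(cps_l, "n_terms") %||% 0L
    # direction consistency: losers' node-maps vs winners' detached maps
    C <- cfg$n_classes
    mkP <- expand_mask_c(masks$HM_pos, C)
    mkR <- expand_mask_c(masks$HM_rev, C)
    Ppos_node_u <- tn_slice_b(out$P_pos, unlab)
    Prev_node_u <- tn_slice_b(out$P_rev, unlab)
    dc_l <- direction_consistency_loss(
      hP_pos = mkP * Ppos_u, lP_pos = tn_mul(Ppos_node_u, mkR),
      hP_rev = mkR * Prev_u, lP_rev = tn_mul(Prev_node_u, mkP))
  }
  feat_l <- tn_const(0)
  if (config$unsup_weight > 0) {
    feat_l <- feature_consistency_loss(out$enc_pyr$pos, out$dec_pyr$pos,
                                       reduce = config$feat_reduce)
    if (cfg_has_rev(cfg))
      feat_l <- tn_add(feat_l, feature_consistency_loss(
        out$enc_pyr$rev, out$dec_pyr$rev, reduce = config$feat_reduce))
  }
  w <- config$unsup_weight
  total_node <- tn_add(tn_add(tn_add(as_tnode(sup$sup_p), as_tnode(sup$sup_r)),
                              as_tnode(sup$sup_f)),
                       tn_scale(tn_add(tn_add(as_tnode(cps_l), as_tnode(dc_l)),
                                       as_tnode(feat_l)), w))
  bundle <- total_loss(list(sup_p = sup$sup_p, sup_r = sup$sup_r,
                            sup_f = sup$sup_f,
                            cps = tn_scale(as_tnode(cps_l), w),
                            dc = tn_scale(as_tnode(dc_l), w),
                            feat = tn_scale(as_tnode(feat_l), w)))
  if (!is.finite(total_node$value))
    stop("NaN/Inf total loss; gamma=", gamma, " m=", m_conf)
  tn_backward(total_node)
  sgd_step(opt, net$params)
  list(bundle = bundle, tstate = tstate, opt = opt, gamma = gamma,
       m = m_conf, con_frac = con_frac, n_cps_terms = n_terms)
}

# deep copy of parameter values + bn states for best-checkpoint keeping
snapshot_net <- function(net) {
  list(params = lapply(net$params, function(p) p$value),
       bn = lapply(net$bn, function(s) list(mean = s$mean, var = s$var)))
}

restore_net <- function(net, snap) {
  for (nm in names(snap$params)) net$params[[nm]]$value <- snap$params[[nm]]
  for (nm in names(snap$bn)) {
    net$bn[[nm]]$mean <- snap$bn[[nm]]$mean
    net$bn[[nm]]$var <- snap$bn[[nm]]$var
  }
  invisible(net)
}

#' Save a training checkpoint
#'
#' Stores parameters, batch-norm running statistics, optimizer velocities,
#' the threshold state, sampler queues, step counter and the RNG state, so
#' a resumed run continues bit-identically.
#' @param run a fit state (see [mpdc_fit()] internals) or list with the
#'   fields above.
#' @param path output `.rds` file.
#' @export
save_checkpoint <- function(run, path) {
  saveRDS(list(snap = snapshot_net(run$net),
               vel = run$opt$vel,
               tstate = run$tstate,
               step = run$step,
               lab_queue = run$sampler$lab_queue,
               unlab_queue = run$sampler$unlab_queue,
               rng = get(".Random.seed", globalenv())),
          path)
  invisible(path)
}

#' Restore a checkpoint saved by [save_checkpoint()]
#' @param run a fit state with matching net/opt/sampler objects.
#' @param path checkpoint file.
#' @return the updated run state.
#' @export
load_checkpoint <- function(run, path) {
  ck <- readRDS(path)
  restore_net(run$net, ck$snap)
  run$opt$vel <- ck$vel
  run$tstate <- ck$tstate
  run$step <- ck$step
  run$sampler$lab_queue <- ck$lab_queue
  run$sampler$unlab_queue <- ck$unlab_queue
  assign(".Random.seed", ck$rng, globalenv())
  run
}

# mean validation Dice (percent) of the inference head over slice pairs
val_dice <- function(net, pairs, n_classes) {
  if (length(pairs) == 0L) return(NA_real_)
  st <- stack_slices(pairs, with_labels = TRUE)
  pred <- mp_predict(net, st$images)
  ds <- vapply(seq_along(pairs), function(b) {
    per_class <- vapply(seq_len(n_classes - 1L), function(cl)
      dice_jaccard(pred[, , b] == cl, st$labels[, , b] == cl)[["dice"]],
      numeric(1))
    mean(per_class)
  }, numeric(1))
  100 * mean(ds)
}

#' Train the multi-perspective model
#'
#' Runs `config$iterations` steps of [train_step()] over batches drawn from
#' the labeled/unlabeled pools, validating every `val_every` steps (mean
#' Dice of the inference head on the validation split) and keeping the
#' best-validation parameters.
#'
#' @param config a [train_config()].
#' @param data a split list from [load_split()] (fields `labeled`,
#'   `unlabeled`, `val`), with slices already preprocessed, or a dataset
#'   directory (then `split_spec` must be given).
#' @param split_spec passed to [load_split()] when `data` is a directory.
#' @param image_size preprocessing size when loading from disk.
#' @param out_dir optional run directory: training log CSV, resolved config
#'   YAML and final/best checkpoints are written there.
#' @param verbose print progress lines.
#' @return a `mpdc_fit` list: `net` (final), `best` (snapshot + step +
#'   dice), `log` (data.frame per step), `tstate`, `opt`, `sampler`, `step`.
#' @export
mpdc_fit <- function(config, data, split_spec = NULL, image_size = NULL,
                     out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "train_config"))
  if (is.character(data)) {
    data <- load_split(data, split_spec)
    if (!is.null(image_size))
      data <- lapply(data, function(ps) lapply(ps, preprocess_slice, size = image_size))
  }
  set.seed(config$seed)
  net <- mp_build(config$network, seed = config$seed)
  sampler <- batch_sampler(data$labeled, data$unlabeled %||% list(),
                           config$batch_size, config$labeled_per_batch)
  tstate <- threshold_state(config$network$n_classes, config$iterations)
  opt <- new_sgd(net$params, config$lr, config$momentum, config$weight_decay)
  log_rows <- vector("list", config$iterations)
  best <- list(dice = -Inf, step = 0L, snap = NULL)
  run <- list(net = net, opt = opt, tstate = tstate, sampler = sampler, step = 0L)
  for (step in seq_len(config$iterations)) {
    batch <- next_batch(sampler)
    if (config$augment) batch <- augment_batch(batch)
    st <- train_step(net, batch, run$tstate, config, opt)
    run$tstate <- st$tstate
    b <- st$bundle
    vd <- NA_real_
    if (config$val_every > 0 && length(data$val %||% list()) > 0 &&
        (step %% config$val_every == 0L || step == config$iterations)) {
      vd <- val_dice(net, data$val, config$network$n_classes)
      if (!is.na(vd) && vd > best$dice)
        best <- list(dice = vd, step = step, snap = snapshot_net(net))
    }
    log_rows[[step]] <- data.frame(step = step, sup_p = b$sup_p,
                                   sup_r = b$sup_r, sup_f = b$sup_f,
                                   cps = b$cps, dc = b$dc, feat = b$feat,
                                   total = b$total, gamma = st$gamma,
                                   m = st$m, con_frac = st$con_frac,
                                   val_dice = vd)
    if (verbose && (step %% 50L == 0L || step == 1L))
      message(sprintf("step %d total %.4f gamma %.3f val %.1f",
                      step, b$total, st$gamma, vd))
  }
  run$step <- config$iterations
  log <- do.call(rbind, log_rows)
  fit <- list(net = net, best = best, log = log, tstate = run$tstate,
              opt = opt, sampler = sampler, step = run$step, config = config)
  class(fit) <- "mpdc_fit"
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(log, file.path(out_dir, "train_log.csv"), row.names = FALSE)
    yaml::write_yaml(list(train = unclass(config[setdiff(names(config), "network")]),
                          network = unclass(config$network)),
                     file.path(out_dir, "config.yaml"))
    save_checkpoint(fit, file.path(out_dir, "last.rds"))
    if (!is.null(fit$best$snap))
      saveRDS(fit$best, file.path(out_dir, "best.rds"))
  }
  fit
}

#' Evaluate a trained model on a test split
#'
#' Predicts every slice with the inference head, regroups slices into scans,
#' and reports the four metrics per scan (and their aggregate).
#' @param net trained network.
#' @param pairs list of labeled `slice_pair`s (one split).
#' @param use_best optional snapshot (from `fit$best$snap`) to evaluate
#'   instead of the final parameters.
#' @return list: `per_scan` (list of data.frames), `aggregate` (one row).
#' @export
evaluate_model <- function(net, pairs, use_best = NULL) {
  if (!is.null(use_best)) {
    keep <- snapshot_net(net)
    on.exit(restore_net(net, keep))
    restore_net(net, use_best)
  }
  scans <- split(pairs, vapply(pairs, `[[`, character(1), "scan_id"))
  C <- net$cfg$n_classes
  per_scan <- lapply(scans, function(ps) {
    ps <- ps[order(vapply(ps, `[[`, integer(1), "slice_index"))]
    st <- stack_slices(ps, with_labels = TRUE)
    pred <- mp_predict(net, st$images)
    pred_l <- lapply(seq_len(dim(pred)[3]), function(k) pred[, , k])
    true_l <- lapply(seq_len(dim(st$labels)[3]), function(k) st$labels[, , k])
    evaluate_scan(pred_l, true_l, classes = seq_len(C - 1L))
  })
  list(per_scan = per_scan, aggregate = aggregate_metrics(per_scan))
}
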