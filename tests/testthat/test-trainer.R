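# Training orchestration: augmentation, step mechanics, ablation switches,
# determinism and checkpoint resume.

small_cfg <- function(iters = 5, branches = "pos+rev+fus", ...) {
  train_config(iterations = iters, batch_size = 4, labeled_per_batch = 2,
               network = network_config(n_classes = 2, base_width = 4,
                                        depth = 2, branches = branches),
               val_every = 0, seed = 42, ...)
}

test_that("augmentation applies one transform to image and label alike", {
  data <- tiny_dataset()
  sm <- batch_sampler(data$labeled, data$unlabeled, 4, 2)
  set.seed(1)
  b <- next_batch(sm)
  set.seed(2)
  a <- augment_batch(b)
  # label sets survive (interpolation-free transforms)
  expect_true(all(unique(as.integer(a$labels)) %in%
                    unique(as.integer(b$labels))))
  # pixel multisets are permuted, never altered
  for (k in seq_len(4))
    expect_equal(sort(as.numeric(a$images[1, , , k])),
                 sort(as.numeric(b$images[1, , , k])))
  # same RNG state reproduces the transform
  set.seed(2)
  a2 <- augment_batch(b)
  expect_identical(a$images, a2$images)
  # labeled item: transformed label still matches transformed image support
  set.seed(3)
  img <- matrix(runif(256), 16, 16)
  lab <- matrix(0L, 16, 16); lab[3:6, 2:9] <- 1L
  pb <- list(images = array(img, c(1, 16, 16, 1)),
             labels = array(lab, c(16, 16, 1)), labeled_count = 1L)
  ab <- augment_batch(pb)
  expect_equal(sum(ab$labels), sum(lab))
})

test_that("a train step returns finite losses and advances the threshold", {
  data <- tiny_dataset()
  cfg <- small_cfg()
  net <- mp_build(cfg$network, seed = 42)
  ts <- threshold_state(2, i_max = 5)
  set.seed(42)
  sm <- batch_sampler(data$labeled, data$unlabeled, 4, 2)
  b <- next_batch(sm)
  st <- train_step(net, b, ts, cfg)
  expect_s3_class(st$bundle, "loss_bundle")
  expect_true(is.finite(st$bundle$total))
  expect_equal(st$tstate$i, 1L)
  expect_true(st$gamma >= 0.5 && st$gamma <= 1)
  # the step actually moved parameters
  net2 <- mp_build(cfg$network, seed = 42)
  expect_false(identical(net$params[["decP.head.w"]]$value,
                         net2$params[["decP.head.w"]]$value))
})

test_that("branch ablations disable the corresponding loss components", {
  data <- tiny_dataset()
  run_cfg <- function(branches, ...) {
    cfg <- small_cfg(iters = 3, branches = branches, ...)
    fit <- mpdc_fit(cfg, data)
    fit$log
  }
  log_pr <- run_cfg("pos+rev")
  expect_true(all(log_pr$sup_f == 0))
  expect_true(all(log_pr$sup_r > 0))
  log_sup <- run_cfg("pos", unsup_weight = 0)
  expect_true(all(log_sup$sup_r == 0 & log_sup$sup_f == 0 &
                    log_sup$cps == 0 & log_sup$dc == 0 & log_sup$feat == 0))
  # fixed threshold bypasses the dynamic update
  cfg_f <- small_cfg(iters = 3, threshold = 0.9)
  fit_f <- mpdc_fit(cfg_f, data)
  expect_true(all(fit_f$log$gamma == 0.9))
  expect_equal(fit_f$tstate$i, 0L)
})

test_that("gamma is 1/C before any update and logged from the first step", {
  data <- tiny_dataset()
  cfg <- small_cfg(iters = 2)
  ts <- threshold_state(cfg$network$n_classes, 10)
  expect_equal(ts$gamma, 0.5)
  fit <- mpdc_fit(cfg, data)
  # after the first update gamma has moved from its 1/C start
  expect_true(all(fit$log$gamma >= 0.5))
})

test_that("identical config and seed reproduce the loss log exactly", {
  data <- tiny_dataset()
  cfg <- small_cfg(iters = 8)
  f1 <- mpdc_fit(cfg, data)
  f2 <- mpdc_fit(cfg, data)
  expect_identical(f1$log$total, f2$log$total)
  expect_identical(f1$log$gamma, f2$log$gamma)
})

test_that("checkpoint save/load resumes bit-identically", {
  data <- tiny_dataset()
  cfg <- small_cfg(iters = 6)
  # uninterrupted reference run
  ref <- mpdc_fit(cfg, data)
  # manual loop: save at step 3, clobber, restore, continue
  set.seed(cfg$seed)
  net <- mp_build(cfg$network, seed = cfg$seed)
  sm <- batch_sampler(data$labeled, data$unlabeled, cfg$batch_size,
                      cfg$labeled_per_batch)
  ts <- threshold_state(2, cfg$iterations)
  opt <- NULL
  totals <- numeric(0)
  run <- list(net = net, opt = NULL, tstate = ts, sampler = sm, step = 0L)
  for (i in 1:3) {
    b <- augment_batch(next_batch(sm))
    st <- train_step(net, b, run$tstate, cfg, run$opt)
    run$opt <- st$opt; run$tstate <- st$tstate
    totals <- c(totals, st$bundle$total)
  }
  ck <- tempfile(fileext = ".rds")
  run$step <- 3L
  save_checkpoint(run, ck)
  # perturb state, then restore
  for (nm in names(net$params)) net$params[[nm]]$value <- net$params[[nm]]$value * 0
  run <- load_checkpoint(run, ck)
  for (i in 4:6) {
    b <- augment_batch(next_batch(sm))
    st <- train_step(net, b, run$tstate, cfg, run$opt)
    run$tstate <- st$tstate
    totals <- c(totals, st$bundle$total)
  }
  expect_equal(totals, ref$log$total, tolerance = 1e-12)
})
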