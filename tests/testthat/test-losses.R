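# Training objectives against scalar oracles, gating behaviour, and the
# stop-gradient contracts.

test_that("dice loss matches the scalar formula on canonical cases", {
  # perfect one-hot match
  g <- onehot(array(c(0, 1, 1, 0), dim = c(2, 2, 1)), 2)
  expect_lt(dice_loss(g, g), 1e-4)
  # uniform prediction vs all-class-1 single pixel: fg term 2*0.5/1.5,
  # bg term ~0 -> loss ~ 1 - mean(2/3, 0) = 0.667
  P <- array(0.5, dim = c(2, 1, 1, 1))
  gt <- onehot(array(1L, dim = c(1, 1, 1)), 2)
  expect_equal(dice_loss(P, gt), 2 / 3, tolerance = 1e-3)
  # random maps agree with the reference loop
  set.seed(4)
  for (i in 1:10) {
    Pr <- rand_conf(3, 4, 4, 2)
    gr <- onehot(array(sample(0:2, 32, TRUE), dim = c(4, 4, 2)), 3)
    expect_equal(dice_loss(Pr, gr), dice_ref(Pr, gr), tolerance = 1e-10)
  }
  # permutation invariance over pixels
  Pr <- rand_conf(2, 4, 4, 1)
  gr <- onehot(array(sample(0:1, 16, TRUE), dim = c(4, 4, 1)), 2)
  perm <- sample(16)
  Pp <- array(matrix(Pr, 2)[, perm], dim = dim(Pr))
  gp <- array(matrix(gr, 2)[, perm], dim = dim(gr))
  expect_equal(dice_loss(Pr, gr), dice_loss(Pp, gp), tolerance = 1e-12)
})

test_that("supervised losses use prediction-map inversion by default", {
  net <- mp_build(network_config(base_width = 4, depth = 2), seed = 9)
  x <- array(runif(1 * 8 * 8 * 4), dim = c(1, 8, 8, 4))
  labels <- array(sample(0:1, 8 * 8 * 2, TRUE), dim = c(8, 8, 2))
  out <- mp_forward(net, x, training = FALSE)
  sup <- supervised_losses(out, labels, 1:2)
  # P_rev is already softmax(-O_rev): identical orientation to P_pos
  g <- onehot(labels, 2)
  Pr <- out$P_rev$value[, , , 1:2, drop = FALSE]
  expect_equal(mpdc:::loss_scalar(sup$sup_r), dice_ref(Pr, g), tolerance = 1e-10)
  # ground-truth inversion arm: network softmaxes the raw reverse scores and
  # the loss inverts the one-hot target instead
  net_gt <- mp_build(network_config(base_width = 4, depth = 2,
                                    inversion = "ground_truth"), seed = 9)
  out_gt <- mp_forward(net_gt, x, training = FALSE)
  sup_gt <- supervised_losses(out_gt, labels, 1:2, inversion = "ground_truth")
  Pr_raw <- softmax_ref_arr(out_gt$O_rev$value[, , , 1:2, drop = FALSE])
  g_inv <- (1 - g) / (2 - 1)
  expect_equal(mpdc:::loss_scalar(sup_gt$sup_r), dice_ref(Pr_raw, g_inv),
               tolerance = 1e-10)
  # unlabeled items contribute nothing: losses depend only on labeled slices
  out2 <- out
  expect_equal(mpdc:::loss_scalar(supervised_losses(out2, labels, 1:2)$sup_p),
               dice_ref(out$P_pos$value[, , , 1:2, drop = FALSE], g),
               tolerance = 1e-10)
  # when O_pos equals -O_rev the two branch losses coincide
  fake <- list(P_pos = out$P_rev$value, P_rev = out$P_rev$value)
  s <- supervised_losses(fake, labels, 1:2)
  expect_equal(s$sup_p, s$sup_r)
})

test_that("direction consistency matches scalar arithmetic and detaches h", {
  # one HM_pos pixel, C=2: term = mean((0.25^2, 0.25^2)) = 0.0625
  hP_pos <- array(c(0.8, 0.2), dim = c(2, 1, 1, 1))
  lP_rev <- array(c(0.55, 0.45), dim = c(2, 1, 1, 1))
  z <- array(0, dim = c(2, 1, 1, 1))
  expect_equal(direction_consistency_loss(hP_pos, z, z, lP_rev), 0.0625,
               tolerance = 1e-10)
  # zero distance when maps agree on both supports
  expect_equal(direction_consistency_loss(hP_pos, z, z, hP_pos), 0)
  # empty masks give zero
  expect_equal(direction_consistency_loss(z, z, z, z), 0)
  # stop-gradient: the h-side operand receives no gradient, the l-side does
  ns <- asNamespace("mpdc")
  hp <- ns$tn_param(hP_pos)
  lp <- ns$tn_param(lP_rev)
  loss <- direction_consistency_loss(hp, ns$tn_const(z), ns$tn_const(z), lp)
  ns$tn_backward(loss)
  expect_null(hp$grad)
  expect_true(any(lp$grad != 0))
})

test_that("cps loss switches between 2 and 6 terms at mean confidence 0.95", {
  set.seed(10)
  C <- 2; H <- 4; W <- 4; B <- 2
  mk <- function() array(rnorm(C * H * W * B), dim = c(C, H, W, B))
  O_pos <- mk(); O_rev <- mk(); O_fus <- mk()
  outputs <- list(O_pos = O_pos, O_rev_neg = -O_rev, O_fus = O_fus,
                  P_pos = softmax_ref_arr(O_pos), P_rev = softmax_ref_arr(-O_rev),
                  P_fus = softmax_ref_arr(O_fus))
  masks <- decouple(outputs$P_pos, outputs$P_rev, gamma = 0)  # all consistent
  low <- cps_loss(outputs, masks, m_confidence = 0.94)
  high <- cps_loss(outputs, masks, m_confidence = 0.96)
  expect_equal(attr(low, "n_terms"), 2L)
  expect_equal(attr(high, "n_terms"), 6L)
  # pair ablation prunes the corresponding terms
  pr <- cps_loss(outputs, masks, 0.96, pairs = c("P-R", "P-F"))
  expect_equal(attr(pr, "n_terms"), 4L)
  # empty consistent part: zero loss, zero terms
  empty <- decouple(outputs$P_pos, outputs$P_rev, gamma = 1)
  expect_equal(as.numeric(cps_loss(outputs, empty, 0.96)), 0)
})

test_that("cps cross-entropy agrees with the scalar oracle", {
  # single consistent pixel, C=2, O_pos=(2,0), pseudo-label 0:
  # CE = -log(softmax(2,0)[1]) = 0.126928
  O_pos <- array(c(2, 0), dim = c(2, 1, 1, 1))
  O_rev_neg <- array(c(3, 0), dim = c(2, 1, 1, 1))  # argmax 0 either way
  P_pos <- softmax_ref_arr(O_pos); P_rev <- softmax_ref_arr(O_rev_neg)
  outputs <- list(O_pos = O_pos, O_rev_neg = O_rev_neg,
                  P_pos = P_pos, P_rev = P_rev)
  masks <- decouple(P_pos, P_rev, gamma = 0)
  val <- cps_loss(outputs, masks, m_confidence = 0.5)
  expect_equal(as.numeric(val),
               ce_ref_pixel(c(2, 0), 0) + ce_ref_pixel(c(3, 0), 0),
               tolerance = 1e-6)
  # agreeing, saturated branches: loss approaches zero
  O_big <- array(c(50, 0), dim = c(2, 1, 1, 1))
  out2 <- list(O_pos = O_big, O_rev_neg = O_big,
               P_pos = softmax_ref_arr(O_big), P_rev = softmax_ref_arr(O_big))
  m2 <- decouple(out2$P_pos, out2$P_rev, gamma = 0)
  expect_lt(as.numeric(cps_loss(out2, m2, 0.5)), 1e-10)
})

test_that("channel compression implements mean |f|^p over channels", {
  f <- array(c(3, -4), dim = c(2, 1, 1, 1))
  expect_equal(as.numeric(channel_compress(f, p = 2)), 12.5)
  z <- array(0, dim = c(4, 2, 2, 1))
  expect_true(all(channel_compress(z) == 0))
  # invariant to channel sign flips
  set.seed(11)
  f2 <- array(rnorm(3 * 2 * 2 * 2), dim = c(3, 2, 2, 2))
  expect_equal(channel_compress(f2), channel_compress(-f2))
})

test_that("feature consistency accumulates squared compressed differences", {
  enc <- list(array(1, dim = c(1, 1, 1, 1)))
  dec <- list(array(sqrt(3), dim = c(1, 1, 1, 1)))  # compressed values 1 vs 3
  expect_equal(feature_consistency_loss(enc, dec), 4)
  expect_equal(feature_consistency_loss(enc, enc), 0)
  # strictly increases under added noise
  set.seed(12)
  base <- list(array(rnorm(8), dim = c(2, 2, 2, 1)))
  l0 <- feature_consistency_loss(base, base)
  for (i in 1:10) {
    noisy <- list(base[[1]] + array(rnorm(8, sd = 0.5), dim = c(2, 2, 2, 1)))
    expect_gt(feature_consistency_loss(base, noisy), l0)
  }
  expect_error(feature_consistency_loss(base, list(array(0, c(2, 3, 3, 1)))),
               "mismatch")
})

test_that("total loss is the exact unweighted sum and rejects NaN", {
  b <- total_loss(list(sup_p = 0.1, sup_r = 0.2, sup_f = 0.3,
                       cps = 0.05, dc = 0.02, feat = 0.03))
  expect_equal(b$total, 0.7)
  expect_equal(total_loss(list(sup_p = 0, sup_r = 0, sup_f = 0,
                               cps = 0, dc = 0, feat = 0))$total, 0)
  expect_error(total_loss(list(sup_p = NaN, sup_r = 0, sup_f = 0,
                               cps = 0, dc = 0, feat = 0)), "sup_p")
})

test_that("losses are non-negative and finite on random inputs", {
  set.seed(13)
  for (i in 1:50) {
    P <- rand_conf(2, 4, 4, 2)
    g <- onehot(array(sample(0:1, 32, TRUE), dim = c(4, 4, 2)), 2)
    v <- dice_loss(P, g)
    expect_true(is.finite(v) && v >= 0 && v <= 1)
    P2 <- rand_conf(2, 4, 4, 2)
    m <- decouple(P, P2, runif(1))
    sp <- split_confidence(P, P2, m)
    dc <- direction_consistency_loss(sp$hP_pos, sp$lP_pos, sp$hP_rev, sp$lP_rev)
    expect_true(is.finite(dc) && dc >= 0)
  }
})

test_that("identical confident agreeing branches give cps + dc = 0", {
  lab <- array(sample(0:1, 16, TRUE), dim = c(4, 4, 1))
  O <- 60 * (2 * onehot(lab, 2) - 1)           # saturated logits
  P <- softmax_ref_arr(O)
  outputs <- list(O_pos = O, O_rev_neg = O, O_fus = O,
                  P_pos = P, P_rev = P, P_fus = P)
  masks <- decouple(P, P, gamma = 0.5)
  expect_true(all(masks$M_con))
  cps <- cps_loss(outputs, masks, mean_confidence(P, P))
  sp <- split_confidence(P, P, masks)
  dc <- direction_consistency_loss(sp$hP_pos, sp$lP_pos, sp$hP_rev, sp$lP_rev)
  expect_lt(as.numeric(cps) + as.numeric(dc), 1e-10)
})
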