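# Dynamic threshold EMA and consistent/inconsistent decoupling.

test_that("threshold starts at 1/C and follows the EMA recurrence", {
  st <- threshold_state(n_classes = 2, i_max = 2)
  expect_equal(st$gamma, 0.5)
  expect_equal(st$gamma_pos, 0.5)
  expect_equal(st$gamma_rev, 0.5)
  # one update at lambda = 1/2 with batch statistics 0.9 / 0.8:
  # gamma_pos = 0.5*0.5 + 0.5*0.9 = 0.7, gamma_rev = 0.65, gamma = min = 0.65
  P_pos <- array(c(0.9, 0.1), dim = c(2, 1, 1, 1))
  P_rev <- array(c(0.8, 0.2), dim = c(2, 1, 1, 1))
  st <- update_threshold(st, P_pos, P_rev)
  expect_equal(st$gamma_pos, 0.7)
  expect_equal(st$gamma_rev, 0.65)
  expect_equal(st$gamma, 0.65)
  # at i = i_max, lambda = 1: the EMA forgets history entirely
  st <- update_threshold(st, P_pos, P_rev)
  expect_equal(st$gamma_pos, 0.9)
  expect_equal(st$gamma_rev, 0.8)
  expect_error(update_threshold(st, P_pos, P_rev), "i_max")
})

test_that("threshold sequence stays within [1/C, 1] for random streams", {
  set.seed(3)
  for (C in c(2, 4)) {
    st <- threshold_state(C, i_max = 1000)
    in_range <- TRUE
    for (i in 1:1000) {
      st <- update_threshold(st, rand_conf(C, 3, 3, 2), rand_conf(C, 3, 3, 2))
      in_range <- in_range && st$gamma >= 1 / C - 1e-12 && st$gamma <= 1 + 1e-12
    }
    expect_true(in_range)
    expect_equal(st$gamma, min(st$gamma_pos, st$gamma_rev))
  }
})

test_that("decoupling splits the fixture maps as the hand oracle says", {
  fx <- tiny_tensor_fixtures()$mixed_pair
  m <- decouple(fx$P_pos, fx$P_rev, gamma = 0.65)
  # pixel maxes pos (.9,.6,.55,.95), rev (.92,.7,.5,.4), column-major 2x2
  expect_equal(as.logical(m$M_con), c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(as.logical(m$HM_pos), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(as.logical(m$HM_rev), c(FALSE, TRUE, FALSE, FALSE))
})

test_that("gamma boundaries: 1.0 empties M_con, 0 with one-hot fills it", {
  fx <- tiny_tensor_fixtures()
  m1 <- decouple(fx$mixed_pair$P_pos, fx$mixed_pair$P_rev, gamma = 1)
  expect_false(any(m1$M_con))
  oh <- fx$onehot_conf
  m0 <- decouple(oh, oh, gamma = 0)
  expect_true(all(m0$M_con))
})

test_that("masks partition the grid and HM masks are disjoint within M_incon", {
  set.seed(5)
  for (trial in 1:20) {
    P1 <- rand_conf(3, 4, 4, 2); P2 <- rand_conf(3, 4, 4, 2)
    m <- decouple(P1, P2, gamma = runif(1))
    expect_true(all(xor(m$M_con, m$M_incon)))
    expect_false(any(m$HM_pos & m$HM_rev))
    expect_true(all(!(m$HM_pos | m$HM_rev) | m$M_incon))
  }
})

test_that("raising gamma never adds a pixel to the consistent part", {
  set.seed(6)
  P1 <- rand_conf(2, 6, 6, 2); P2 <- rand_conf(2, 6, 6, 2)
  gammas <- sort(runif(5))
  prev <- NULL
  for (g in gammas) {
    m <- decouple(P1, P2, g)
    if (!is.null(prev)) expect_true(all(m$M_con <= prev))
    prev <- m$M_con
  }
})

test_that("decouple and split agree with the per-pixel brute-force oracle", {
  set.seed(8)
  masks_ok <- TRUE; worst <- 0
  for (trial in 1:100) {
    P1 <- rand_conf(2, 8, 8, 1); P2 <- rand_conf(2, 8, 8, 1)
    gamma <- runif(1, 0.4, 0.9)
    m <- decouple(P1, P2, gamma)
    ref <- decouple_ref(P1, P2, gamma)
    masks_ok <- masks_ok &&
      identical(as.logical(m$M_con), as.logical(ref$M_con)) &&
      identical(as.logical(m$HM_pos), as.logical(ref$HM_pos)) &&
      identical(as.logical(m$HM_rev), as.logical(ref$HM_rev))
    sp <- split_confidence(P1, P2, m)
    C <- 2
    mkP <- mpdc:::expand_mask_c(m$HM_pos, C)
    mkR <- mpdc:::expand_mask_c(m$HM_rev, C)
    worst <- max(worst, abs(sp$hP_pos - mkP * P1), abs(sp$lP_rev - mkP * P2),
                 abs(sp$hP_rev - mkR * P2), abs(sp$lP_pos - mkR * P1))
  }
  expect_true(masks_ok)
  expect_lt(worst, 1e-12)
})

test_that("split_confidence pairs winner and loser on shared support", {
  # one pixel where pos wins: hP_pos carries pos, lP_rev carries rev
  P_pos <- array(c(0.8, 0.2), dim = c(2, 1, 1, 1))
  P_rev <- array(c(0.55, 0.45), dim = c(2, 1, 1, 1))
  m <- decouple(P_pos, P_rev, gamma = 0.9)  # inconsistent, pos more confident
  sp <- split_confidence(P_pos, P_rev, m)
  expect_equal(as.numeric(sp$hP_pos), c(0.8, 0.2))
  expect_equal(as.numeric(sp$lP_rev), c(0.55, 0.45))
  expect_equal(as.numeric(sp$hP_rev), c(0, 0))
  expect_equal(as.numeric(sp$lP_pos), c(0, 0))
  # empty inconsistent part: all four maps vanish
  oh <- tiny_tensor_fixtures()$onehot_conf
  m2 <- decouple(oh, oh, gamma = 0.5)
  sp2 <- split_confidence(oh, oh, m2)
  expect_true(all(unlist(sp2) == 0))
})
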