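# Three-branch network: construction, forward contracts, fusion arithmetic,
# gradient routing.

test_that("reverse module negates elementwise and is an involution", {
  x <- matrix(c(1, -2, 0, 3), 2, 2)
  expect_equal(reverse_module(x), -x)
  expect_equal(reverse_module(reverse_module(x)), x)
})

test_that("negating two-class logits swaps the softmax probabilities", {
  set.seed(1)
  for (i in 1:10) {
    v <- rnorm(2)
    p <- softmax_ref(v)
    p_neg <- softmax_ref(-v)
    expect_equal(p_neg, rev(p), tolerance = 1e-12)
  }
})

test_that("perspective fusion reproduces the hand-computed pixel", {
  fx <- tiny_tensor_fixtures()$pfm_pixel
  out <- perspective_fusion(fx$f_pos, fx$f_rev)
  # f_r_pos = softmax(-2, 2) = (0.0180, 0.9820); softmax(f_rev) = (0.1192, 0.8808)
  # f_mul = (0.00214, 0.86497); f_fus = (1.99786, -2.86497)
  expect_equal(as.numeric(out), c(1.99786, -2.86497), tolerance = 1e-4)
  # all-zero features: uniform softmaxes give f_mul = 0.25 everywhere
  z <- array(0, dim = c(2, 3, 3, 1))
  expect_equal(perspective_fusion(z, z), array(-0.25, dim = dim(z)))
})

test_that("perspective fusion matches the per-pixel oracle on random maps", {
  set.seed(2)
  for (i in 1:10) {
    fp <- array(rnorm(3 * 4 * 4 * 2), dim = c(3, 4, 4, 2))
    fv <- array(rnorm(3 * 4 * 4 * 2), dim = c(3, 4, 4, 2))
    expect_equal(perspective_fusion(fp, fv), pfm_ref(fp, fv), tolerance = 1e-5)
    expect_equal(dim(perspective_fusion(fp, fv)), dim(fp))
  }
  expect_error(perspective_fusion(array(0, c(2, 2, 2, 1)), array(0, c(3, 2, 2, 1))),
               "shape")
})

test_that("builds are seed-deterministic and encoder sharing is honoured", {
  cfg <- network_config(base_width = 4, depth = 2)
  n1 <- mp_build(cfg, seed = 5)
  n2 <- mp_build(cfg, seed = 5)
  for (nm in names(n1$params))
    expect_identical(n1$params[[nm]]$value, n2$params[[nm]]$value)
  expect_true(any(grepl("^encR", names(n1$params))))
  shared <- mp_build(network_config(base_width = 4, depth = 2,
                                    share_encoders = TRUE), seed = 5)
  expect_false(any(grepl("^encR", names(shared$params))))
})

test_that("forward produces full-size score maps and normalized confidences", {
  cfg <- network_config(base_width = 4, depth = 3)
  net <- mp_build(cfg, seed = 1)
  x <- array(runif(1 * 16 * 16 * 2), dim = c(1, 16, 16, 2))
  out <- mp_forward(net, x, training = FALSE)
  for (nm in c("O_pos", "O_rev", "O_fus"))
    expect_equal(dim(out[[nm]]$value), c(2, 16, 16, 2))
  for (nm in c("P_pos", "P_rev", "P_fus")) {
    P <- out[[nm]]$value
    sums <- colSums(matrix(P, 2, length(P) / 2))
    expect_true(all(abs(sums - 1) < 1e-5))
  }
  expect_equal(out$O_rev_neg$value, -out$O_rev$value)
  # eval-mode forward is deterministic
  out2 <- mp_forward(net, x, training = FALSE)
  expect_identical(out$O_fus$value, out2$O_fus$value)
  # size must be divisible by 2^(depth-1)
  expect_error(mp_forward(net, array(0, dim = c(1, 18, 18, 1))), "divisible")
})

test_that("supervised losses reach exactly their own parameter sets", {
  ns <- asNamespace("mpdc")
  cfg <- network_config(base_width = 4, depth = 2)
  net <- mp_build(cfg, seed = 3)
  x <- array(runif(1 * 8 * 8 * 2), dim = c(1, 8, 8, 2))
  labels <- array(sample(0:1, 8 * 8 * 2, TRUE), dim = c(8, 8, 2))
  grads_of <- function(loss_name) {
    out <- mp_forward(net, x, training = TRUE)
    sup <- supervised_losses(out, labels, 1:2)
    ns$tn_backward(sup[[loss_name]])
    touched <- names(net$params)[vapply(net$params, function(p) {
      g <- p$grad
      ok <- !is.null(g) && any(g != 0)
      p$grad <- NULL
      ok
    }, logical(1))]
    touched
  }
  t_p <- grads_of("sup_p")
  expect_true(all(grepl("^(encP|decP)", t_p)))
  t_r <- grads_of("sup_r")
  expect_true(all(grepl("^(encR|decR)", t_r)))
  expect_true(any(grepl("^encR", t_r)))
  t_f <- grads_of("sup_f")
  expect_true(any(grepl("^encP", t_f)))   # fusion consumes both pyramids
  expect_true(any(grepl("^encR", t_f)))
  expect_true(any(grepl("^decF", t_f)))
  expect_false(any(grepl("^(decP|decR)\\.", t_f)))
})

test_that("prediction returns 0-based class maps from the configured head", {
  net <- mp_build(network_config(base_width = 4, depth = 2), seed = 2)
  x <- array(runif(1 * 8 * 8 * 3), dim = c(1, 8, 8, 3))
  pred <- mp_predict(net, x)
  expect_equal(dim(pred), c(8, 8, 3))
  expect_true(all(pred %in% 0:1))
})
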