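# Finite-difference gradient checks for the network engine. Each layer's
# analytic backward pass is compared against central differences of a
# scalar objective on a tiny input.

num_grad <- function(f, x, idx, eps = 1e-5) {
  vapply(idx, function(j) {
    xp <- x; xp[j] <- xp[j] + eps
    xm <- x; xm[j] <- xm[j] - eps
    (f(xp) - f(xm)) / (2 * eps)
  }, numeric(1))
}

# Objective sum((out - tgt)^2) with a fixed non-constant target, so layer
# outputs with internal cancellations (e.g. standardized batch-norm
# activations) still produce well-conditioned gradients.
check_layer_grads <- function(layer, x, idx = NULL, train = TRUE,
                              tol = 1e-6) {
  obj <- function(xx) {
    out <- dbtdualnet:::nn_forward(layer, xx, train = train)$out
    sum((out - sin(seq_along(out)))^2)
  }
  fw <- dbtdualnet:::nn_forward(layer, x, train = train)
  dout <- 2 * (fw$out - sin(seq_along(fw$out)))
  dim(dout) <- dim(fw$out)
  bk <- dbtdualnet:::nn_backward(layer, fw$cache, dout)
  if (is.null(idx)) idx <- unique(round(seq(1, length(x), length.out = 7)))
  expect_equal(unname(bk$dx[idx]), num_grad(obj, x, idx), tolerance = tol)
  bk
}

test_that("convolution gradients match finite differences", {
  set.seed(1)
  x <- array(rnorm(7 * 7 * 2 * 2), c(7, 7, 2, 2))
  for (cfg in list(list(k = 3, s = 1, p = 1, g = 1),
                   list(k = 3, s = 2, p = 0, g = 1),
                   list(k = 1, s = 1, p = 0, g = 2))) {
    l <- dbtdualnet:::layer_conv(2, 4, cfg$k, cfg$s, cfg$p, cfg$g)
    bk <- check_layer_grads(l, x)
    # weight and bias gradients against the same target objective
    obj_par <- function(field) function(v) {
      l2 <- l; l2[[field]] <- v
      out <- dbtdualnet:::nn_forward(l2, x)$out
      sum((out - sin(seq_along(out)))^2)
    }
    idx <- seq(1, length(l$W), length.out = 5)
    expect_equal(unname(bk$grads$W[idx]), num_grad(obj_par("W"), l$W, idx),
                 tolerance = 1e-6)
    expect_equal(unname(bk$grads$b),
                 num_grad(obj_par("b"), l$b, seq_along(l$b)),
                 tolerance = 1e-6)
  }
})

test_that("pooling and normalization gradients match finite differences", {
  set.seed(2)
  x <- array(rnorm(6 * 6 * 3 * 2), c(6, 6, 3, 2))
  check_layer_grads(dbtdualnet:::layer_maxpool(2), x)
  check_layer_grads(dbtdualnet:::layer_avgpool(2), x)
  check_layer_grads(dbtdualnet:::layer_adaptive_avgpool(1), x)
  check_layer_grads(dbtdualnet:::layer_adaptive_avgpool(2), x)
  bn <- dbtdualnet:::layer_bn(3)
  bn$gamma <- runif(3, 0.5, 1.5); bn$beta <- rnorm(3)
  check_layer_grads(bn, x, tol = 1e-5)
  check_layer_grads(dbtdualnet:::layer_relu6(), 3 * x)
})

test_that("composite blocks backpropagate correctly", {
  set.seed(3)
  x <- array(rnorm(6 * 6 * 4 * 2), c(6, 6, 4, 2))
  res <- dbtdualnet:::basic_block(4, 4, 1) # identity shortcut
  check_layer_grads(res, x, tol = 1e-5)
  res2 <- dbtdualnet:::basic_block(4, 8, 2) # projection shortcut
  check_layer_grads(res2, x, tol = 1e-5)
  db <- dbtdualnet:::nn_dense_block(list(dbtdualnet:::dense_unit(4, 2),
                                         dbtdualnet:::dense_unit(6, 2)))
  fw <- dbtdualnet:::nn_forward(db, x, train = TRUE)
  expect_equal(dim(fw$out)[3], 8) # 4 + 2 + 2 channels
  check_layer_grads(db, x, tol = 1e-5)
  ir <- dbtdualnet:::inverted_residual(4, 4, 1, 2) # linear residual
  check_layer_grads(ir, x, tol = 1e-5)
})

test_that("batch normalization switches between batch and running stats", {
  set.seed(4)
  bn <- dbtdualnet:::layer_bn(2)
  x <- array(rnorm(4 * 4 * 2 * 3, mean = 5, sd = 2), c(4, 4, 2, 3))
  fw <- dbtdualnet:::nn_forward(bn, x, train = TRUE)
  # batch mode: output standardized per channel
  m1 <- matrix(fw$out[, , 1, ], ncol = 1)
  expect_lt(abs(mean(m1)), 1e-10)
  expect_equal(sd(m1) * sqrt(47 / 48), 1, tolerance = 1e-3)
  # running stats updated toward the batch statistics
  expect_gt(fw$layer$rmean[1], 0)
  # eval mode uses running stats and is deterministic
  e1 <- dbtdualnet:::nn_forward(bn, x)$out
  e2 <- dbtdualnet:::nn_forward(bn, x)$out
  expect_identical(e1, e2)
})

test_that("Adam drives a least-squares objective downhill", {
  set.seed(5)
  l <- dbtdualnet:::layer_linear(3, 1)
  st <- dbtdualnet:::adam_init(l)
  x <- matrix(rnorm(30), 3)
  target <- matrix(c(1, -2, 0.5), 1) %*% x
  losses <- numeric(50)
  for (t in 1:50) {
    fw <- dbtdualnet:::nn_forward(l, x)
    losses[t] <- mean((fw$out - target)^2)
    bk <- dbtdualnet:::nn_backward(l, fw$cache, 2 * (fw$out - target) / 10)
    r <- dbtdualnet:::adam_step(l, bk$grads, st, lr = 0.05, t = t)
    l <- r$layer; st <- r$state
  }
  expect_lt(losses[50], losses[1] / 10)
})
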