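test_that("the registry pins categories and rejects misplaced backbones", {
  reg <- backbone_registry()
  expect_setequal(reg$name[reg$category == "shallow"],
                  c("MobileNetV2", "AlexNet", "ResNet18"))
  expect_setequal(reg$name[reg$category == "deep"],
                  c("ResNet50", "ResNeXt50", "DenseNet121", "DenseNet201"))
  expect_equal(reg$category[reg$name == "TinyCNN"], "any")
  expect_error(dual_net_config("ResNet50", "TinyCNN"), "shallow slot")
  expect_error(dual_net_config("TinyCNN", "AlexNet"), "deep slot")
  expect_error(dual_net_config("NoSuchNet", "ResNet50"), "available")
})

test_that("feature dimensions follow the configuration", {
  m <- tiny_model(proj_dim = 8)
  x <- random_patch_batch(2, side = 64)
  fw <- dual_net_forward(m, x)
  expect_equal(nrow(fw$z), 32 + 32) # z = [v_d; v_s]
  expect_equal(dim(fw$fhat_s), c(8L, 2L))
  expect_equal(dim(fw$fhat_d), c(8L, 2L))
  expect_equal(nrow(fw$z_proj), 16L) # 2d for the projected variant
  expect_true(all(fw$prob > 0 & fw$prob < 1))
  expect_error(dual_net_forward(m, array(0.1, c(32, 32, 1, 1))), "channels")
})

test_that("the reference backbone pair is constructible and runs forward", {
  cfg <- dual_net_config("AlexNet", "ResNet50", proj_dim = 16)
  m <- build_dual_net(cfg, seed = 2)
  x <- random_patch_batch(1, side = 64)
  fw <- dual_net_forward(m, x)
  expect_equal(nrow(fw$z), 2048 + 256)
  expect_equal(length(fw$prob), 1L)
  expect_true(is.finite(fw$logit))
})

test_that("remaining registry backbones build with the declared widths", {
  for (nm in c("MobileNetV2", "ResNet18", "DenseNet121")) {
    b <- dbtdualnet:::lookup_backbone(nm)
    net <- b$build()
    expect_equal(net$feature_dim, b$feature_dim)
    x <- random_patch_batch(1, side = 64)
    out <- dbtdualnet:::nn_forward(net$net, x)$out
    expect_equal(dim(out)[3], b$feature_dim)
  }
})

test_that("a hand-weighted stub reproduces the full forward arithmetic", {
  m <- stub_dual_net(w_s = 0.1, w_d = 0.2, proj_dim = 2)
  x <- array(0.5, c(4, 4, 3, 1))
  fw <- dual_net_forward(m, x)
  # conv (3x3 valid, all weights w, zero bias) on constant 0.5 input with 3
  # channels: every output value = 27 * w * 0.5; GAP leaves it unchanged
  v_s <- 27 * 0.1 * 0.5
  v_d <- 27 * 0.2 * 0.5
  expect_equal(as.numeric(fw$v_s), v_s, tolerance = 1e-12)
  expect_equal(as.numeric(fw$v_d), v_d, tolerance = 1e-12)
  expect_equal(as.numeric(fw$fhat_s), c(v_s + 0.5, -v_s), tolerance = 1e-12)
  expect_equal(as.numeric(fw$fhat_d), c(2 * v_d, v_d - 0.5), tolerance = 1e-12)
  logit <- 0.3 * v_d - 0.2 * v_s + 0.1
  expect_equal(fw$logit, logit, tolerance = 1e-12)
  expect_equal(fw$prob, 1 / (1 + exp(-logit)), tolerance = 1e-12)
  # projected variant: head sums all 2d projected entries * 0.25, b = -0.1
  p2 <- classify_variant(m, x, "concat_projected")
  logit2 <- 0.25 * (v_s + 0.5 - v_s + 2 * v_d + v_d - 0.5) - 0.1
  expect_equal(p2, 1 / (1 + exp(-logit2)), tolerance = 1e-12)
})

test_that("fusion variants agree when projections are the identity", {
  m <- stub_dual_net(proj_dim = 1)
  # make both projections identity maps and both heads identical
  m$proj_s$W <- matrix(1); m$proj_s$b <- 0
  m$proj_d$W <- matrix(1); m$proj_d$b <- 0
  m$head_proj$W <- m$head_raw$W[, 2:1, drop = FALSE] # [fhat_s; fhat_d] order
  m$head_proj$b <- m$head_raw$b
  x <- array(0.3, c(4, 4, 3, 1))
  expect_equal(classify_variant(m, x, "concat_raw"),
               classify_variant(m, x, "concat_projected"), tolerance = 1e-12)
})

test_that("a zero-weight head predicts exactly one half", {
  m <- tiny_model()
  m$head_raw$W[] <- 0; m$head_raw$b[] <- 0
  expect_equal(dual_net_forward(m, random_patch_batch(3))$prob,
               rep(0.5, 3))
})

test_that("batched prediction preserves order", {
  m <- tiny_model()
  x <- random_patch_batch(5, side = 64)
  pb <- predict_dual_net(m, x, batch_size = 2)
  one <- vapply(1:5, function(i)
    dual_net_forward(m, x[, , , i, drop = FALSE])$prob, numeric(1))
  expect_equal(pb, one, tolerance = 1e-12)
})

test_that("initialization and checkpointing are seed-reproducible", {
  m1 <- tiny_model(seed = 9)
  m2 <- tiny_model(seed = 9)
  expect_identical(m1$shallow, m2$shallow)
  expect_identical(m1$head_raw, m2$head_raw)
  expect_false(identical(m1$head_raw, tiny_model(seed = 10)$head_raw))
  f <- tempfile(fileext = ".rds")
  save_dual_net(m1, f)
  expect_identical(load_dual_net(f)$proj_s, m1$proj_s)
})

test_that("pretrained mode demands external weights", {
  cfg <- dual_net_config("TinyCNN", "TinyCNN", pretrained = TRUE)
  expect_error(build_dual_net(cfg), "not bundled")
})
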