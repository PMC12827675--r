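# Shared desk-scale fixtures, generated in code (no stored data).

# Small phantom cohort, memoised per (n, seed) within a test run.
.phantom_cache <- new.env(parent = emptyenv())
tiny_phantom <- function(n = 6, seed = 11, n_slices = 16, side = 128,
                         width_range_mm = c(5, 30), ...) {
  key <- paste(n, seed, n_slices, side, sep = "_")
  if (is.null(.phantom_cache[[key]])) {
    .phantom_cache[[key]] <- generate_phantom(phantom_spec(
      n_patients = n, n_slices = n_slices, side = side,
      width_range_mm = width_range_mm, seed = seed, ...))
  }
  .phantom_cache[[key]]
}

tiny_model <- function(proj_dim = 8, seed = 1, ...) {
  build_dual_net(dual_net_config("TinyCNN", "TinyCNN",
                                 proj_dim = proj_dim, ...), seed = seed)
}

random_patch_batch <- function(n = 2, side = 64, seed = 5) {
  dbtdualnet:::with_seed(seed, array(runif(side * side * 3 * n),
                                     c(side, side, 3, n)))
}

# A hand-weighted dual net whose full forward pass is computable on paper:
# each backbone is a single 3x3 valid convolution with constant weights.
stub_dual_net <- function(w_s = 0.1, w_d = 0.2, proj_dim = 2) {
  m <- tiny_model(proj_dim = proj_dim)
  conv_const <- function(w) {
    l <- dbtdualnet:::layer_conv(3, 1, 3)
    l$W[] <- w
    l$b[] <- 0
    l
  }
  m$shallow <- dbtdualnet:::nn_sequential(list(conv_const(w_s)))
  m$deep <- dbtdualnet:::nn_sequential(list(conv_const(w_d)))
  m$dims <- list(d_s = 1L, d_d = 1L)
  m$proj_s <- dbtdualnet:::layer_linear(1, proj_dim)
  m$proj_d <- dbtdualnet:::layer_linear(1, proj_dim)
  m$proj_s$W <- matrix(rep_len(c(1, -1), proj_dim), proj_dim, 1)
  m$proj_s$b <- rep_len(c(0.5, 0), proj_dim)
  m$proj_d$W <- matrix(rep_len(c(2, 1), proj_dim), proj_dim, 1)
  m$proj_d$b <- rep_len(c(0, -0.5), proj_dim)
  m$head_raw <- dbtdualnet:::layer_linear(2, 1)
  m$head_raw$W <- matrix(c(0.3, -0.2), 1, 2) # consumes [v_d; v_s]
  m$head_raw$b <- 0.1
  m$head_proj <- dbtdualnet:::layer_linear(2 * proj_dim, 1)
  m$head_proj$W <- matrix(0.25, 1, 2 * proj_dim)
  m$head_proj$b <- -0.1
  m
}
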