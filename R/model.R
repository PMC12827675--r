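## The dual-branch classifier: two parallel CNN feature extractors (one
## shallow, one deep), adaptive pooling + flattening to branch feature
## vectors, linear projections into a shared space (consumed by the
## feature-similarity loss), and a sigmoid classification head on the
## concatenated features.

#' Configure a dual-branch network
#'
#' @param shallow,deep backbone names from [backbone_registry()]. The shallow
#'   slot accepts backbones of category `shallow` (or `any`), the deep slot
#'   category `deep` (or `any`).
#' @param proj_dim dimension `d` of the shared projection space used by the
#'   feature-similarity loss (default 256).
#' @param pool_size adaptive-pooling output side for the shallow branch
#'   (the deep branch always pools to 1x1).
#' @param variant what the classification head consumes: `"concat_raw"`
#'   (default) concatenates the pooled branch features `[v_d; v_s]`;
#'   `"concat_projected"` concatenates the two d-dimensional projections.
#' @param pretrained logical; when `TRUE`, externally supplied backbone
#'   weights are expected via `weights_path` at build time (none are bundled).
#' @return a `dualnet_config` object.
#' @export
#' @examples
#' cfg <- dual_net_config("TinyCNN", "TinyCNN", proj_dim = 16)
dual_net_config <- function(shallow = "AlexNet", deep = "ResNet50",
                            proj_dim = 256L, pool_size = 1L,
                            variant = c("concat_raw", "concat_projected"),
                            pretrained = FALSE) {
  variant <- match.arg(variant)
  s <- lookup_backbone(shallow)
  d <- lookup_backbone(deep)
  if (!s$category %in% c("shallow", "any"))
    stop("backbone '", s$name, "' is registered as '", s$category,
         "' and cannot fill the shallow slot")
  if (!d$category %in% c("deep", "any"))
    stop("backbone '", d$name, "' is registered as '", d$category,
         "' and cannot fill the deep slot")
  proj_dim <- as.integer(proj_dim)
  pool_size <- as.integer(pool_size)
  stopifnot(proj_dim > 0, pool_size > 0)
  structure(list(shallow = s$name, deep = d$name, proj_dim = proj_dim,
                 pool_size = pool_size, variant = variant,
                 pretrained = isTRUE(pretrained)),
            class = "dualnet_config")
}

#' Build a dual-branch network
#'
#' Instantiates both backbone trunks, the per-branch adaptive pooling,
#' the linear projection heads into the shared `proj_dim`-dimensional space,
#' and the classification heads, all freshly initialized under `seed`.
#'
#' @param config a [dual_net_config()].
#' @param seed integer seed for weight initialization.
#' @param weights_path optional RDS file with externally trained backbone
#'   weights (a list with elements `shallow`, `deep`); required when
#'   `config$pretrained` is `TRUE`.
#' @return a `dualnet` model object.
#' @export
#' @examples
#' model <- build_dual_net(dual_net_config("TinyCNN", "TinyCNN",
#'                                         proj_dim = 8), seed = 1)
build_dual_net <- function(config, seed = 1L, weights_path = NULL) {
  stopifnot(inherits(config, "dualnet_config"))
  model <- with_seed(seed, {
    sb <- lookup_backbone(config$shallow)$build()
    db <- lookup_backbone(config$deep)$build()
    ds_eff <- sb$feature_dim * config$pool_size^2
    dd_eff <- db$feature_dim # deep branch pools to 1x1
    list(shallow = sb$net, deep = db$net,
         pool_s = layer_adaptive_avgpool(config$pool_size),
         pool_d = layer_adaptive_avgpool(1L),
         proj_s = layer_linear(ds_eff, config$proj_dim),
         proj_d = layer_linear(dd_eff, config$proj_dim),
         head_raw = layer_linear(dd_eff + ds_eff, 1L),
         head_proj = layer_linear(2L * config$proj_dim, 1L),
         dims = list(d_s = ds_eff, d_d = dd_eff),
         config = config, seed = as.integer(seed))
  })
  class(model) <- "dualnet"
  if (config$pretrained) {
    if (is.null(weights_path))
      stop("config requests pretrained backbones but no weights_path given ",
           "(pretrained weights are not bundled)")
    wts <- readRDS(weights_path)
    model$shallow <- wts$shallow
    model$deep <- wts$deep
  }
  model
}

#' @export
print.dualnet <- function(x, ...) {
  cat("Dual-branch classifier\n",
      "  shallow: ", x$config$shallow, " (d_s = ", x$dims$d_s, ")\n",
      "  deep:    ", x$config$deep, " (d_d = ", x$dims$d_d, ")\n",
      "  proj_dim = ", x$config$proj_dim,
      ", variant = ", x$config$variant, "\n", sep = "")
  invisible(x)
}

check_input_tensor <- function(x) {
  if (is.matrix(x)) stop("expected a 3-channel image tensor, got a matrix")
  d <- dim(x)
  if (length(d) == 3L) { dim(x) <- c(d, 1L); d <- dim(x) }
  if (length(d) != 4L || d[3] != 3L)
    stop("input must be [H, W, 3] or [H, W, 3, N]; got channels = ",
         if (length(d) >= 3) d[3] else NA)
  x
}

#' Forward pass of the dual-branch network
#'
#' Runs a batch of enhanced 3-channel patches through both branches and
#' returns the branch feature vectors, their shared-space projections, the
#' concatenated feature, and the predicted malignancy probability.
#'
#' @param model a `dualnet` from [build_dual_net()].
#' @param x input tensor `[H, W, 3]` or `[H, W, 3, N]`, values in `[0, 1]`.
#' @param train logical; enables batch-statistics mode in normalization
#'   layers (used internally by the trainer).
#' @param keep_cache keep per-layer caches (needed for backprop / Grad-CAM).
#' @return a list with `v_s`, `v_d` (matrices `[d, N]`), `fhat_s`, `fhat_d`
#'   (`[proj_dim, N]`), `z`, `logit`, `prob`, and (optionally) `cache`.
#' @export
dual_net_forward <- function(model, x, train = FALSE, keep_cache = FALSE) {
  stopifnot(inherits(model, "dualnet"))
  x <- check_input_tensor(x)
  rs <- nn_forward(model$shallow, x, train)
  rd <- nn_forward(model$deep, x, train)
  if (train) {
    if (!is.null(rs$layer)) model$shallow <- rs$layer
    if (!is.null(rd$layer)) model$deep <- rd$layer
  }
  ps <- nn_forward(model$pool_s, rs$out)
  pd <- nn_forward(model$pool_d, rd$out)
  n <- dim(x)[4]
  v_s <- matrix(ps$out, ncol = n)
  v_d <- matrix(pd$out, ncol = n)
  fs <- nn_forward(model$proj_s, v_s)
  fd <- nn_forward(model$proj_d, v_d)
  z <- rbind(v_d, v_s)
  z_proj <- rbind(fs$out, fd$out)
  if (model$config$variant == "concat_raw") {
    hr <- nn_forward(model$head_raw, z)
  } else {
    hr <- nn_forward(model$head_proj, z_proj)
  }
  logit <- as.numeric(hr$out)
  out <- list(v_s = v_s, v_d = v_d, fhat_s = fs$out, fhat_d = fd$out,
              z = z, z_proj = z_proj, logit = logit,
              prob = clamp(sigmoid(logit), 1e-12, 1 - 1e-12),
              model = if (train) model else NULL)
  if (keep_cache) {
    out$cache <- list(shallow = rs$cache, deep = rd$cache,
                      fmap_s = rs$out, fmap_d = rd$out,
                      pool_s = ps$cache, pool_d = pd$cache,
                      proj_s = fs$cache, proj_d = fd$cache, head = hr$cache)
  }
  out
}

#' Classify with a chosen fusion variant
#'
#' The default head consumes the concatenated pooled branch features
#' (`concat_raw`); `concat_projected` instead feeds the concatenation of the
#' two d-dimensional projections, so its head input length is `2 * proj_dim`.
#'
#' @inheritParams dual_net_forward
#' @param variant `"concat_raw"` or `"concat_projected"`.
#' @return numeric vector of probabilities, one per input patch.
#' @export
classify_variant <- function(model, x,
                             variant = c("concat_raw", "concat_projected")) {
  variant <- match.arg(variant)
  model$config$variant <- variant
  dual_net_forward(model, x)$prob
}

#' Predict slice-level probabilities in mini-batches
#'
#' @param model a trained `dualnet`.
#' @param x `[H, W, 3, N]` tensor of enhanced patches.
#' @param batch_size forward-pass batch size.
#' @return numeric vector of length `N`.
#' @export
predict_dual_net <- function(model, x, batch_size = 32L) {
  x <- check_input_tensor(x)
  n <- dim(x)[4]
  probs <- numeric(n)
  for (b in split(seq_len(n), ceiling(seq_len(n) / batch_size))) {
    probs[b] <- dual_net_forward(model, x[, , , b, drop = FALSE])$prob
  }
  probs
}
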