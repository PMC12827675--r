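## Explainability: gradient-weighted class activation maps (Grad-CAM)
## computed per branch on the final convolutional feature map (the input to
## each branch's adaptive pooling), fused across branches by direct
## summation of the un-normalized weighted maps, plus export of the fused
## feature vectors for 2-D embedding tools.

## Gradient of the classification logit with respect to each branch's final
## convolutional feature map, for a single patch.
cam_gradients <- function(model, fw) {
  n <- 1L
  d_d <- nrow(fw$v_d); d_s <- nrow(fw$v_s); pd <- nrow(fw$fhat_s)
  dlogit <- matrix(1, 1L, n)
  if (model$config$variant == "concat_raw") {
    hb <- nn_backward(model$head_raw, fw$cache$head, dlogit)
    dv_d <- hb$dx[seq_len(d_d), , drop = FALSE]
    dv_s <- hb$dx[d_d + seq_len(d_s), , drop = FALSE]
  } else {
    hb <- nn_backward(model$head_proj, fw$cache$head, dlogit)
    dfs <- hb$dx[seq_len(pd), , drop = FALSE]
    dfd <- hb$dx[pd + seq_len(pd), , drop = FALSE]
    dv_s <- nn_backward(model$proj_s, fw$cache$proj_s, dfs)$dx
    dv_d <- nn_backward(model$proj_d, fw$cache$proj_d, dfd)$dx
  }
  ps <- model$config$pool_size
  dmap_s <- nn_backward(model$pool_s, fw$cache$pool_s,
                        array(dv_s, c(ps, ps, d_s %/% ps^2, n)))$dx
  dmap_d <- nn_backward(model$pool_d, fw$cache$pool_d,
                        array(dv_d, c(1L, 1L, d_d, n)))$dx
  list(shallow = dmap_s, deep = dmap_d)
}

## Gradient-weighted channel combination (no rectification/normalization).
cam_weighted_map <- function(fmap, dmap) {
  d <- dim(fmap)
  alpha <- colMeans(matrix(dmap[, , , 1], nrow = d[1] * d[2])) # channel weights
  matrix(matrix(fmap[, , , 1], nrow = d[1] * d[2]) %*% alpha, d[1], d[2])
}

normalize_map <- function(heat) {
  rng <- range(heat)
  if (rng[2] > rng[1]) (heat - rng[1]) / (rng[2] - rng[1])
  else matrix(0.5, nrow(heat), ncol(heat)) # constant map: uninformative
}

upsample_map <- function(heat, side) {
  matrix(EBImage::resize(heat, w = side, h = side, filter = "bilinear"),
         side, side)
}

#' Grad-CAM attention map of one branch
#'
#' Weights the channels of the branch's final convolutional feature map by
#' the spatial mean of the logit gradient, sums, rectifies, upsamples to
#' the input resolution and min-max normalizes to `[0, 1]`.
#'
#' @param model a `dualnet`; @param patch one enhanced `[H, W, 3]` patch.
#' @param branch `"shallow"` or `"deep"`.
#' @return an `attention_map`: `list(heat, branch)` with `heat` in `[0, 1]`
#'   at the input resolution.
#' @export
branch_cam <- function(model, patch, branch = c("shallow", "deep")) {
  branch <- match.arg(branch)
  x <- check_input_tensor(patch)
  side <- dim(x)[1]
  fw <- dual_net_forward(model, x, keep_cache = TRUE)
  g <- cam_gradients(model, fw)
  fmap <- if (branch == "shallow") fw$cache$fmap_s else fw$cache$fmap_d
  heat <- pmax(cam_weighted_map(fmap, g[[branch]]), 0)
  structure(list(heat = normalize_map(upsample_map(heat, side)),
                 branch = branch), class = "attention_map")
}

#' Fused Grad-CAM across both branches
#'
#' Upsamples each branch's un-normalized gradient-weighted map to the input
#' resolution (so maps of different spatial sizes become compatible), sums
#' them directly, rectifies, and normalizes once — preserving the relative
#' magnitude of the two branches' evidence.
#'
#' @inheritParams branch_cam
#' @return an `attention_map` with `branch = "fused"`.
#' @export
fused_cam <- function(model, patch) {
  x <- check_input_tensor(patch)
  side <- dim(x)[1]
  fw <- dual_net_forward(model, x, keep_cache = TRUE)
  g <- cam_gradients(model, fw)
  ws <- upsample_map(cam_weighted_map(fw$cache$fmap_s, g$shallow), side)
  wd <- upsample_map(cam_weighted_map(fw$cache$fmap_d, g$deep), side)
  structure(list(heat = normalize_map(pmax(ws + wd, 0)), branch = "fused"),
            class = "attention_map")
}

#' Render an attention map over its patch as a PNG overlay
#'
#' @param map an `attention_map`; @param patch the grayscale or RGB patch it
#'   was computed on; @param path output PNG; @param alpha overlay opacity.
#' @export
write_cam_overlay <- function(map, patch, path, alpha = 0.5) {
  stopifnot(inherits(map, "attention_map"))
  if (length(dim(patch)) == 3L) patch <- patch[, , 1]
  h <- map$heat
  rgb <- array(0, c(nrow(h), ncol(h), 3))
  rgb[, , 1] <- (1 - alpha) * patch + alpha * h       # heat in red
  rgb[, , 2] <- (1 - alpha) * patch + alpha * 0.2 * h
  rgb[, , 3] <- (1 - alpha) * patch
  write_patch_png(rgb, path)
}

#' Export fused and per-branch feature vectors
#'
#' Runs patches through the network and writes one row per patch with the
#' concatenated feature vector `z` and the per-branch pooled vectors, ready
#' for downstream 2-D embedding (t-SNE/UMAP via standard tooling).
#'
#' @param model a `dualnet`; @param x `[H, W, 3, N]` patches.
#' @param labels optional per-patch labels; @param path optional CSV path.
#' @param batch_size forward batch size.
#' @return data.frame with columns `label` (if given), `z_*`, `vs_*`, `vd_*`.
#' @export
export_features <- function(model, x, labels = NULL, path = NULL,
                            batch_size = 32L) {
  x <- check_input_tensor(x)
  n <- dim(x)[4]
  zs <- NULL; vss <- NULL; vds <- NULL
  for (b in split(seq_len(n), ceiling(seq_len(n) / batch_size))) {
    fw <- dual_net_forward(model, x[, , , b, drop = FALSE])
    zs <- cbind(zs, fw$z); vss <- cbind(vss, fw$v_s); vds <- cbind(vds, fw$v_d)
  }
  out <- data.frame(t(zs))
  names(out) <- paste0("z_", seq_len(nrow(zs)))
  vs <- data.frame(t(vss)); names(vs) <- paste0("vs_", seq_len(nrow(vss)))
  vd <- data.frame(t(vds)); names(vd) <- paste0("vd_", seq_len(nrow(vds)))
  out <- cbind(out, vs, vd)
  if (!is.null(labels)) out <- cbind(data.frame(label = labels), out)
  rownames(out) <- NULL
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}
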