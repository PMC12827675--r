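## Trainer for the dual-branch classifier: Adam on the joint BCE +
## lambda * similarity objective, fully seeded and CPU-deterministic.

## One forward/backward pass on a batch. Returns the updated model (batch-
## norm running stats), the loss breakdown, and gradients per component.
dualnet_step <- function(model, xb, y, lambda = 0.3,
                         sim_reduction = c("mean", "sum")) {
  sim_reduction <- match.arg(sim_reduction)
  fw <- dual_net_forward(model, xb, train = TRUE, keep_cache = TRUE)
  if (!is.null(fw$model)) model <- fw$model
  n <- length(y)
  loss <- total_loss(fw$prob, y, fw$fhat_s, fw$fhat_d, lambda, sim_reduction)

  ## classifier head: d(total)/d(logit) for sigmoid + BCE averaged over batch
  dlogit <- matrix(fw$prob - y, nrow = 1L) / n
  grads <- list()
  d_d <- nrow(fw$v_d); d_s <- nrow(fw$v_s); pd <- nrow(fw$fhat_s)
  if (model$config$variant == "concat_raw") {
    hb <- nn_backward(model$head_raw, fw$cache$head, dlogit)
    grads$head_raw <- hb$grads
    dv_d <- hb$dx[seq_len(d_d), , drop = FALSE]
    dv_s <- hb$dx[d_d + seq_len(d_s), , drop = FALSE]
    dfs <- matrix(0, pd, n); dfd <- matrix(0, pd, n)
  } else {
    hb <- nn_backward(model$head_proj, fw$cache$head, dlogit)
    grads$head_proj <- hb$grads
    dfs <- hb$dx[seq_len(pd), , drop = FALSE]
    dfd <- hb$dx[pd + seq_len(pd), , drop = FALSE]
    dv_d <- matrix(0, d_d, n); dv_s <- matrix(0, d_s, n)
  }

  ## similarity term: lambda/N * d(sim_i)/d(fhat)
  diff <- fw$fhat_s - fw$fhat_d
  scale <- lambda * 2 / n / (if (sim_reduction == "mean") pd else 1)
  dfs <- dfs + scale * diff
  dfd <- dfd - scale * diff

  pb_s <- nn_backward(model$proj_s, fw$cache$proj_s, dfs)
  pb_d <- nn_backward(model$proj_d, fw$cache$proj_d, dfd)
  grads$proj_s <- pb_s$grads
  grads$proj_d <- pb_d$grads
  dv_s <- dv_s + pb_s$dx
  dv_d <- dv_d + pb_d$dx

  ## back through pooling into each backbone
  dmap_s <- array(dv_s, dim = c(model$config$pool_size, model$config$pool_size,
                                d_s %/% model$config$pool_size^2, n))
  dmap_d <- array(dv_d, dim = c(1L, 1L, d_d, n))
  pbk_s <- nn_backward(model$pool_s, fw$cache$pool_s, dmap_s)
  pbk_d <- nn_backward(model$pool_d, fw$cache$pool_d, dmap_d)
  grads$shallow <- nn_backward(model$shallow, fw$cache$shallow, pbk_s$dx)$grads
  grads$deep <- nn_backward(model$deep, fw$cache$deep, pbk_d$dx)$grads

  list(model = model, loss = loss, grads = grads, prob = fw$prob)
}

#' Train a dual-branch network
#'
#' Minimizes the joint objective (mean BCE plus `lambda` times the mean
#' feature-similarity penalty) with Adam. Identical seeds, data and model
#' give an identical loss trajectory on CPU.
#'
#' @param model a `dualnet` from [build_dual_net()].
#' @param x `[H, W, 3, N]` tensor of enhanced training patches.
#' @param y length-`N` 0/1 labels (1 = malignant).
#' @param epochs,lr,batch_size training budget; defaults follow the
#'   reference operating point (Adam, learning rate 3e-4).
#' @param lambda,sim_reduction joint-loss settings, see [total_loss()].
#' @param seed seed for batch shuffling.
#' @param log_path optional CSV path for the per-epoch loss breakdown
#'   (columns epoch, bce, sim, total).
#' @param verbose print per-epoch losses.
#' @return `list(model, history)`; `history` is a data.frame with one row
#'   per epoch.
#' @export
train_dual_net <- function(model, x, y, epochs = 10L, lr = 3e-4,
                           batch_size = 32L, lambda = 0.3,
                           sim_reduction = c("mean", "sum"), seed = 1L,
                           log_path = NULL, verbose = FALSE) {
  sim_reduction <- match.arg(sim_reduction)
  x <- check_input_tensor(x)
  n <- dim(x)[4]
  stopifnot(length(y) == n, n >= 1)
  comp <- c("shallow", "deep", "proj_s", "proj_d", "head_raw", "head_proj")
  states <- lapply(comp, function(cn) adam_init(model[[cn]]))
  names(states) <- comp
  t <- 0L
  history <- data.frame(epoch = integer(0), bce = numeric(0),
                        sim = numeric(0), total = numeric(0))
  for (ep in seq_len(epochs)) {
    ord <- with_seed(stage_seed(seed, paste0("epoch", ep)), sample.int(n))
    batches <- split(ord, ceiling(seq_along(ord) / batch_size))
    ep_loss <- c(bce = 0, sim = 0, total = 0)
    for (b in batches) {
      st <- dualnet_step(model, x[, , , b, drop = FALSE], y[b],
                         lambda, sim_reduction)
      model <- st$model
      t <- t + 1L
      for (cn in names(st$grads)) {
        r <- adam_step(model[[cn]], st$grads[[cn]], states[[cn]], lr, t)
        model[[cn]] <- r$layer
        states[[cn]] <- r$state
      }
      w <- length(b) / n
      ep_loss <- ep_loss + w * c(st$loss$bce, st$loss$sim, st$loss$total)
    }
    history <- rbind(history, data.frame(epoch = ep, bce = ep_loss[["bce"]],
                                         sim = ep_loss[["sim"]],
                                         total = ep_loss[["total"]]))
    if (verbose)
      message(sprintf("epoch %d: bce %.4f sim %.4f total %.4f", ep,
                      ep_loss[["bce"]], ep_loss[["sim"]], ep_loss[["total"]]))
  }
  if (!is.null(log_path))
    utils::write.csv(history, log_path, row.names = FALSE)
  list(model = model, history = history)
}

#' Save / load a dual-net checkpoint (weights plus embedded configuration).
#' @param model a `dualnet`; @param path file path.
#' @export
save_dual_net <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_dual_net
#' @export
load_dual_net <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "dualnet"))
  model
}
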