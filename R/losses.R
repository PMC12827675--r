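## Joint training objective: per-slice binary cross-entropy plus a
## mean-squared similarity penalty between the two branches' projected
## features, weighted by lambda and averaged over the batch:
##   L = (1/N) * sum_i [ BCE_i + lambda * Sim_i ].

#' Binary cross-entropy loss
#'
#' `-(y*log(p) + (1-y)*log(1-p))`, elementwise. Probabilities are clamped
#' to `[eps, 1-eps]` before the logarithm for numerical safety.
#'
#' @param y_true labels in {0, 1}; @param y_prob predicted probabilities.
#' @param eps clamping margin (default 1e-7).
#' @return numeric vector of per-slice losses (non-negative).
#' @export
#' @examples
#' bce_loss(1, 0.5) # log(2)
bce_loss <- function(y_true, y_prob, eps = 1e-7) {
  stopifnot(length(y_true) == length(y_prob))
  if (!all(y_true %in% c(0, 1))) stop("labels must be 0/1")
  if (any(y_prob < 0 | y_prob > 1)) stop("probabilities must lie in [0, 1]")
  p <- clamp(y_prob, eps, 1 - eps)
  -(y_true * log(p) + (1 - y_true) * log(1 - p))
}

#' Feature-similarity loss
#'
#' Squared difference between the two branches' projected feature vectors.
#' The reduction over the shared dimension is `mean` by default so that the
#' weight `lambda` is independent of the projection dimension; `sum` is the
#' alternative reading.
#'
#' @param fhat_s,fhat_d projected features: numeric vectors, or `[d, N]`
#'   matrices for a batch.
#' @param reduction `"mean"` or `"sum"` over the projection dimension.
#' @return scalar (vector input) or per-sample vector (matrix input); zero
#'   iff the projections are identical.
#' @export
similarity_loss <- function(fhat_s, fhat_d, reduction = c("mean", "sum")) {
  reduction <- match.arg(reduction)
  if (is.null(dim(fhat_s))) fhat_s <- matrix(fhat_s)
  if (is.null(dim(fhat_d))) fhat_d <- matrix(fhat_d)
  if (!all(dim(fhat_s) == dim(fhat_d)))
    stop("projected features must have identical dimensions")
  d2 <- (fhat_s - fhat_d)^2
  out <- if (reduction == "mean") colMeans(d2) else colSums(d2)
  if (length(out) == 1L) out[[1L]] else out
}

#' Joint loss over a batch
#'
#' @param y_prob,y_true aligned per-slice probabilities and 0/1 labels.
#' @param fhat_s,fhat_d `[d, N]` projected features for the same slices.
#' @param lambda similarity weight (>= 0); 0.3 is the default operating
#'   point, with `{0, 0.1, 0.3, 0.5}` the conventional grid.
#' @param sim_reduction passed to [similarity_loss()].
#' @return a `loss_breakdown` list: `bce`, `sim`, `total = bce + lambda*sim`,
#'   `lambda`, `n`.
#' @export
total_loss <- function(y_prob, y_true, fhat_s, fhat_d, lambda = 0.3,
                       sim_reduction = c("mean", "sum")) {
  sim_reduction <- match.arg(sim_reduction)
  n <- length(y_true)
  if (n == 0L) stop("empty batch")
  if (lambda < 0) stop("lambda must be non-negative")
  bce <- mean(bce_loss(y_true, y_prob))
  sim <- mean(similarity_loss(fhat_s, fhat_d, sim_reduction))
  structure(list(bce = bce, sim = sim, total = bce + lambda * sim,
                 lambda = lambda, n = n), class = "loss_breakdown")
}
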