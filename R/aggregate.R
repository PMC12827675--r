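## Slice-to-image aggregation. An image contributes n slice-level
## probabilities; majority voting takes the mode of the thresholded slice
## labels, average voting thresholds the mean probability, and the mean
## probability itself serves as the image-level score for threshold-free
## metrics such as AUC.

#' Majority vote over slice predictions
#'
#' Thresholds each slice probability at `threshold` and returns the modal
#' binary label. A tie (possible for even slice counts) resolves toward the
#' positive (malignant) class by default — the sensitivity-favoring policy —
#' and is configurable.
#'
#' @param probs numeric vector of slice probabilities in `[0, 1]`.
#' @param threshold slice-level decision threshold (default 0.5; the
#'   indicator is `p >= threshold`).
#' @param tie `"positive"` or `"negative"` tie resolution.
#' @return 0/1 image label.
#' @export
#' @examples
#' majority_vote(c(0.9, 0.8, 0.2)) # 1
majority_vote <- function(probs, threshold = 0.5,
                          tie = c("positive", "negative")) {
  tie <- match.arg(tie)
  if (length(probs) == 0L) stop("empty prediction set")
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  pos <- sum(probs >= threshold)
  neg <- length(probs) - pos
  if (pos > neg) 1L
  else if (pos < neg) 0L
  else if (tie == "positive") 1L else 0L
}

#' Average vote over slice predictions
#'
#' Image label is 1 iff the mean slice probability is at least `threshold`
#' (boundary inclusive).
#'
#' @inheritParams majority_vote
#' @return 0/1 image label.
#' @export
#' @examples
#' average_vote(c(0.9, 0.2, 0.2)) # mean 0.433 -> 0
average_vote <- function(probs, threshold = 0.5) {
  if (length(probs) == 0L) stop("empty prediction set")
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  as.integer(mean(probs) >= threshold)
}

#' Image-level probability
#'
#' Mean of the slice probabilities; the image-level score used for AUC and
#' other threshold-independent metrics.
#'
#' @inheritParams majority_vote
#' @return scalar in `[0, 1]`.
#' @export
image_probability <- function(probs) {
  if (length(probs) == 0L) stop("empty prediction set")
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  mean(probs)
}

#' Aggregate a slice-level prediction table to image level
#'
#' @param predictions data.frame with columns `image_id`, `slice_index`,
#'   `prob`, `y` (true 0/1 label, constant within an image).
#' @param vote `"majority"` or `"average"`.
#' @param threshold decision threshold.
#' @return data.frame with one row per image: `image_id`, `y`, `prob`
#'   (mean slice probability), `y_pred`.
#' @export
aggregate_predictions <- function(predictions, vote = c("majority", "average"),
                                  threshold = 0.5) {
  vote <- match.arg(vote)
  stopifnot(all(c("image_id", "prob", "y") %in% names(predictions)))
  ids <- unique(predictions$image_id)
  out <- lapply(ids, function(id) {
    p <- predictions$prob[predictions$image_id == id]
    y <- predictions$y[predictions$image_id == id][1]
    yp <- if (vote == "majority") majority_vote(p, threshold)
          else average_vote(p, threshold)
    data.frame(image_id = id, y = y, prob = image_probability(p), y_pred = yp)
  })
  do.call(rbind, out)
}
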