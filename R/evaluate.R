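## Evaluation: standard binary-classification metrics, rank-based AUC,
## patient-level stratified k-fold cross-validation, and the McNemar paired
## test for comparing two classifiers on the same cases.

#' Confusion table
#'
#' @param tp,fp,tn,fn non-negative counts.
#' @return a `confusion_table` object.
#' @export
confusion_table <- function(tp, fp, tn, fn) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0, tp + fp + tn + fn >= 1)
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn),
            class = "confusion_table")
}

#' Confusion table from label vectors
#'
#' @param truth,pred 0/1 vectors of equal length.
#' @return a [confusion_table()].
#' @export
confusion_from_labels <- function(truth, pred) {
  stopifnot(length(truth) == length(pred))
  confusion_table(tp = sum(truth == 1 & pred == 1),
                  fp = sum(truth == 0 & pred == 1),
                  tn = sum(truth == 0 & pred == 0),
                  fn = sum(truth == 1 & pred == 0))
}

#' Classification metrics from a confusion table
#'
#' Accuracy, precision, sensitivity (recall), specificity and F1. A ratio
#' with a zero denominator (e.g. sensitivity with no positive cases) is
#' reported as `NA` with a warning.
#'
#' @param ct a [confusion_table()].
#' @return named numeric vector `c(acc, prec, sens, spec, f1)`.
#' @export
#' @examples
#' classification_metrics(confusion_table(3, 1, 4, 2))
classification_metrics <- function(ct) {
  stopifnot(inherits(ct, "confusion_table"))
  total <- ct$tp + ct$fp + ct$tn + ct$fn
  ratio <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (zero denominator); reported as NA")
      NA_real_
    } else num / den
  }
  acc <- (ct$tp + ct$tn) / total
  prec <- ratio(ct$tp, ct$tp + ct$fp, "precision")
  sens <- ratio(ct$tp, ct$tp + ct$fn, "sensitivity")
  spec <- ratio(ct$tn, ct$tn + ct$fp, "specificity")
  f1 <- if (is.na(prec) || is.na(sens) || prec + sens == 0) {
    warning("F1 undefined; reported as NA")
    NA_real_
  } else 2 * prec * sens / (prec + sens)
  c(acc = acc, prec = prec, sens = sens, spec = spec, f1 = f1)
}

#' Rank-based AUC (Mann-Whitney with midrank ties)
#'
#' @param scores numeric scores; @param labels 0/1 labels (both classes
#'   must be present).
#' @return AUC in `[0, 1]`; 0.5 when all scores tie.
#' @export
auc_score <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0)
    stop("AUC requires both classes to be present")
  r <- rank(scores) # midranks for ties
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Patient-level stratified k-fold split
#'
#' Partitions patients (never slices or images) into `k` folds, stratified
#' by class, deterministically under `seed`. A patient with several
#' annotations is stratified by the malignant-majority label.
#'
#' @param annotations annotation data.frame with `PatientID` and `Class`
#'   columns (see [read_annotations()]).
#' @param k number of folds (default 5); @param seed RNG seed.
#' @return data.frame `patient_id`, `fold` (1..k).
#' @export
kfold_split <- function(annotations, k = 5L, seed = 1L) {
  pid <- unique(annotations$PatientID)
  if (length(pid) < k)
    stop("need at least k = ", k, " patients, got ", length(pid))
  plabel <- vapply(pid, function(p) {
    cl <- annotations$Class[annotations$PatientID == p]
    as.integer(sum(cl == "malignant") * 2 >= length(cl))
  }, integer(1))
  fold <- integer(length(pid))
  with_seed(seed, {
    start <- 0L # rotate the fold pointer across classes to balance sizes
    for (lab in unique(plabel)) {
      members <- which(plabel == lab)
      members <- members[sample.int(length(members))]
      fold[members] <- ((start + seq_along(members) - 1L) %% k) + 1L
      start <- start + length(members)
    }
  })
  data.frame(patient_id = pid, fold = fold, row.names = NULL)
}

#' McNemar paired test for two classifiers
#'
#' Compares two classifiers on the same cases via their discordant counts:
#' `b` cases only classifier A got right, `c` cases only classifier B got
#' right. The statistic is `chi2 = (b - c)^2 / (b + c)` (continuity
#' correction off by default) with an upper-tail p-value from the 1-df
#' chi-squared distribution.
#'
#' @param b,c discordant counts (`b + c >= 1`), or pass `b` as a 2x2 paired
#'   outcome matrix (rows: A correct/wrong, cols: B correct/wrong) and omit
#'   `c`.
#' @param correction apply the continuity correction `(|b-c|-1)^2/(b+c)`.
#' @return `list(statistic, p_value, b, c)`.
#' @export
#' @examples
#' mcnemar_test(15, 5) # chi2 = 5
mcnemar_test <- function(b, c = NULL, correction = FALSE) {
  if (is.matrix(b)) {
    stopifnot(all(dim(b) == c(2, 2)), is.null(c))
    cc <- b[2, 1]; b <- b[1, 2]; c <- cc
  }
  stopifnot(b >= 0, c >= 0)
  if (b + c < 1) stop("McNemar test undefined: no discordant pairs (b + c = 0)")
  d <- abs(b - c) - if (correction) 1 else 0
  stat <- max(d, 0)^2 / (b + c)
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       b = b, c = c)
}

#' Slice- and image-level metrics from a prediction table
#'
#' @param predictions data.frame with `image_id`, `slice_index`, `prob`, `y`.
#' @param vote image-level voting rule, see [aggregate_predictions()].
#' @return data.frame with columns `level` (slice/image), `metric`, `value`;
#'   image-level AUC uses the mean slice probability per image.
#' @export
evaluate_predictions <- function(predictions, vote = "majority") {
  auc_or_na <- function(scores, labels) {
    if (length(unique(labels)) < 2L) {
      warning("AUC undefined with a single class present; reported as NA")
      return(NA_real_)
    }
    auc_score(scores, labels)
  }
  slice_ct <- confusion_from_labels(predictions$y,
                                    as.integer(predictions$prob >= 0.5))
  sm <- classification_metrics(slice_ct)
  sm <- c(sm, auc = auc_or_na(predictions$prob, predictions$y))
  img <- aggregate_predictions(predictions, vote = vote)
  im <- classification_metrics(confusion_from_labels(img$y, img$y_pred))
  im <- c(im, auc = auc_or_na(img$prob, img$y))
  rbind(data.frame(level = "slice", metric = names(sm), value = unname(sm)),
        data.frame(level = "image", metric = names(im), value = unname(im)))
}
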