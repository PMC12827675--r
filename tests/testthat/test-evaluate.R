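test_that("classification metrics match hand arithmetic", {
  m <- classification_metrics(confusion_table(3, 1, 4, 2))
  expect_equal(unname(m["acc"]), 0.7)
  expect_equal(unname(m["prec"]), 0.75)
  expect_equal(unname(m["sens"]), 0.6)
  expect_equal(unname(m["spec"]), 0.8)
  expect_equal(unname(m["f1"]), 2 * 0.75 * 0.6 / 1.35, tolerance = 1e-12)
  perfect <- classification_metrics(confusion_table(5, 0, 5, 0))
  expect_true(all(perfect == 1))
  expect_warning(
    expect_warning(m2 <- classification_metrics(confusion_table(0, 2, 3, 0)),
                   "sensitivity undefined"),
    "F1 undefined")
  expect_true(is.na(m2["sens"]))
  # accuracy is the label-weighted mean of sensitivity and specificity
  ct <- confusion_table(7, 3, 11, 4)
  mm <- classification_metrics(ct)
  npos <- ct$tp + ct$fn; nneg <- ct$tn + ct$fp
  expect_equal(unname(mm["acc"]),
               unname((mm["sens"] * npos + mm["spec"] * nneg) / (npos + nneg)),
               tolerance = 1e-12)
})

test_that("rank AUC handles separation, ties and monotone transforms", {
  expect_equal(auc_score(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)), 1)
  expect_equal(auc_score(c(0.9, 0.8, 0.2, 0.1), c(0, 0, 1, 1)), 0)
  expect_equal(auc_score(rep(0.5, 10), rep(c(0, 1), 5)), 0.5) # midranks
  set.seed(21)
  s <- rnorm(50); y <- rbinom(50, 1, 0.5)
  expect_equal(auc_score(s, y), auc_score(exp(s), y), tolerance = 1e-12)
  expect_equal(auc_score(s, y), 1 - auc_score(s, 1 - y), tolerance = 1e-12)
  # independence: large-sample AUC near one half
  set.seed(33)
  s2 <- runif(2000); y2 <- rbinom(2000, 1, 0.5)
  expect_lt(abs(auc_score(s2, y2) - 0.5), 0.04)
  expect_error(auc_score(1:5, rep(1, 5)), "both classes")
})

test_that("rank AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(14)
  for (i in 1:5) {
    s <- round(runif(40), 2) # rounding induces ties
    y <- rbinom(40, 1, 0.5)
    if (length(unique(y)) < 2) next
    ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                          direction = "<")))
    expect_equal(auc_score(s, y), ref, tolerance = 1e-10)
  }
})

test_that("k-fold splits partition patients with stratification", {
  ph <- tiny_phantom(10, seed = 19)
  f1 <- kfold_split(ph$annotations, k = 5, seed = 2)
  f2 <- kfold_split(ph$annotations, k = 5, seed = 2)
  expect_identical(f1, f2)
  expect_setequal(f1$patient_id, unique(ph$annotations$PatientID))
  expect_equal(as.vector(table(f1$fold)), rep(2L, 5))
  # no patient appears in two folds (brute-force audit)
  for (p in f1$patient_id) {
    expect_length(unique(f1$fold[f1$patient_id == p]), 1)
  }
  # stratified: per-fold class counts differ by at most one
  cls <- ph$annotations$Class[match(f1$patient_id,
                                    ph$annotations$PatientID)]
  tab <- table(f1$fold, cls)
  for (j in seq_len(ncol(tab))) {
    expect_lte(max(tab[, j]) - min(tab[, j]), 1)
  }
  expect_error(kfold_split(ph$annotations[1:3, ], k = 5), "at least k")
})

test_that("McNemar statistic and tail probability are exact", {
  r <- mcnemar_test(15, 5)
  expect_equal(r$statistic, 5)
  expect_equal(r$p_value, pchisq(5, 1, lower.tail = FALSE))
  r0 <- mcnemar_test(7, 7)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)
  # matrix input: discordant cells are off-diagonal
  rm <- mcnemar_test(matrix(c(30, 4, 12, 10), 2, byrow = TRUE))
  expect_equal(rm$b, 4); expect_equal(rm$c, 12)
  expect_equal(rm$statistic, (4 - 12)^2 / 16)
  # cross-check against the stats implementation
  ref <- stats::mcnemar.test(matrix(c(30, 4, 12, 10), 2, byrow = TRUE),
                             correct = FALSE)
  expect_equal(rm$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(rm$p_value, ref$p.value, tolerance = 1e-12)
  # continuity correction
  rc <- mcnemar_test(15, 5, correction = TRUE)
  expect_equal(rc$statistic, 81 / 20)
  expect_error(mcnemar_test(0, 0), "b \\+ c = 0")
  # p is monotone decreasing in |b - c| for fixed b + c
  ps <- vapply(0:10, function(b) mcnemar_test(10 + b, 10 - b)$p_value,
               numeric(1))
  expect_true(all(diff(ps) < 0))
})

test_that("the reference paired comparison reproduces its printed tail", {
  # chi-square 27.04 on 1 df: upper tail 2.00e-7 at the printed rounding
  p <- pchisq(27.04, df = 1, lower.tail = FALSE)
  expect_equal(p, 2.00e-7, tolerance = 0.005)
  r <- mcnemar_test(52, 10)
  expect_equal(r$statistic, (52 - 10)^2 / 62)
  expect_equal(r$p_value, pchisq(r$statistic, 1, lower.tail = FALSE))
})

test_that("prediction tables evaluate at both levels", {
  df <- data.frame(image_id = rep(c("a", "b", "c", "d"), each = 3),
                   slice_index = rep(0:2, 4),
                   prob = c(0.9, 0.8, 0.7, 0.2, 0.3, 0.1,
                            0.6, 0.7, 0.4, 0.3, 0.2, 0.6),
                   y = rep(c(1, 0, 1, 0), each = 3))
  tab <- evaluate_predictions(df, vote = "majority")
  expect_setequal(unique(tab$level), c("slice", "image"))
  im_acc <- tab$value[tab$level == "image" & tab$metric == "acc"]
  expect_equal(im_acc, 1) # all four images vote correctly
  expect_true(all(tab$value[tab$metric == "auc"] > 0.5))
})
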