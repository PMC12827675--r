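## End-to-end orchestration: simulate -> preprocess -> train -> evaluate ->
## explain, from one declarative config, with per-stage seeds derived from
## the run seed so a completed run is bit-reproducible on CPU.

#' Default pipeline configuration
#'
#' Returns the full configuration with every tunable at its default. The
#' training profile is desk-scale (compact backbones, 10 epochs) so the
#' whole pipeline runs on one CPU; the enhancement, loss, window and voting
#' settings are the reference operating point (hue shift 30, saturation
#' scale 0.8, value scale 15, lambda 0.3, 10-slice window with m = 1,
#' majority voting, Adam at 3e-4).
#'
#' @return nested named list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    paths = list(out = NULL),
    phantom = list(n_patients = 100L, n_slices = 64L, side = 256L,
                   spacing_xy = 0.5, spacing_z = 1,
                   width_range_mm = c(5, 80), class_balance = 0.5,
                   background_noise = 0.05, benign_amplitude = 0.05,
                   malignant_amplitude = 0.35, contrast = 0.35),
    pce = list(enabled = "pce", delta_h = 30L, alpha = 0.8, beta = 15,
               colorize_mode = "intensity_to_hue"),
    window = list(total_slices = 10L, m = 1L),
    model = list(shallow = "TinyCNN", deep = "TinyCNN", proj_dim = 32L,
                 pool_size = 1L, variant = "concat_raw", pretrained = FALSE),
    loss = list(lambda = 0.3, sim_reduction = "mean"),
    train = list(epochs = 10L, lr = 3e-4, optimizer = "adam",
                 batch_size = 16L, augment = FALSE, test_fraction = 0.3),
    vote = "majority",
    evaluate = list(mode = "fixed", k = 5L)
  )
}

merge_config <- function(defaults, user, path = "") {
  for (key in names(user)) {
    full <- paste0(path, key)
    if (!key %in% names(defaults))
      stop("unknown config key '", full, "'; known keys here: ",
           paste(names(defaults), collapse = ", "))
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      if (!is.list(user[[key]]))
        stop("config key '", full, "' must be a section")
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]],
                                      paste0(full, "."))
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

#' Validate a pipeline configuration
#'
#' Merges the user configuration over [default_config()], rejects unknown
#' keys outright, checks domains and cross-field constraints, and returns
#' the fully populated configuration.
#'
#' @param config partial configuration list, or a YAML file path.
#' @return the validated, fully populated configuration.
#' @export
#' @examples
#' cfg <- validate_config(list(train = list(epochs = 2L)))
validate_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config)) config <- list()
  cfg <- merge_config(default_config(), config)
  if (cfg$loss$lambda < 0) stop("loss.lambda must be non-negative")
  if (cfg$train$lr <= 0) stop("train.lr must be positive")
  if (cfg$train$epochs < 1) stop("train.epochs must be at least 1")
  if (cfg$train$batch_size < 1) stop("train.batch_size must be at least 1")
  if (cfg$train$test_fraction <= 0 || cfg$train$test_fraction >= 1)
    stop("train.test_fraction must lie in (0, 1)")
  if (!cfg$vote %in% c("majority", "average"))
    stop("vote must be 'majority' or 'average'")
  if (!cfg$pce$enabled %in% c("off", "pce", "histeq"))
    stop("pce.enabled must be one of off, pce, histeq")
  if (!cfg$evaluate$mode %in% c("fixed", "cv"))
    stop("evaluate.mode must be 'fixed' or 'cv'")
  if (!identical(cfg$train$optimizer, "adam"))
    stop("only the adam optimizer is supported")
  slice_window_spec(cfg$window$total_slices, cfg$window$m) # cross-field check
  pce_params(cfg$pce$delta_h, cfg$pce$alpha, cfg$pce$beta,
             cfg$pce$colorize_mode) # domain check
  dual_net_config(cfg$model$shallow, cfg$model$deep, cfg$model$proj_dim,
                  cfg$model$pool_size, cfg$model$variant,
                  cfg$model$pretrained) # registry check
  do.call(phantom_spec, c(cfg$phantom, list(seed = 1L)))
  cfg
}

split_patients <- function(annotations, test_fraction, seed) {
  pats <- unique(annotations[, c("PatientID", "Class")])
  test_ids <- with_seed(seed, {
    unlist(lapply(split(pats$PatientID, pats$Class), function(ids) {
      ids <- ids[sample.int(length(ids))]
      ids[seq_len(max(1L, round(test_fraction * length(ids))))]
    }), use.names = FALSE)
  })
  list(train = setdiff(pats$PatientID, test_ids), test = test_ids)
}

## Stream the phantom cohort patient by patient: each volume is generated,
## orientation-standardized and reduced to its grayscale prediction patches,
## then discarded, so memory stays bounded by the patch store rather than
## the full voxel cohort. Bit-identical to generate_phantom +
## make_patch_dataset under the same seeds.
simulate_gray_cohort <- function(cfg, sim_seed, out_side = 224L) {
  spec_ph <- do.call(phantom_spec, c(cfg$phantom, list(seed = sim_seed)))
  wspec <- slice_window_spec(cfg$window$total_slices, cfg$window$m)
  G <- gauss_smoother(cfg$phantom$side, sigma = 3)
  gray <- list(); meta <- list(); anns <- list()
  k <- 0L
  for (i in seq_len(cfg$phantom$n_patients)) {
    p <- generate_phantom_patient(spec_ph, i, smoother = G)
    anns[[i]] <- p$annotation
    ann <- annotation_row(p$annotation, 1)
    gp <- gray_patches_for(p$volume, ann, wspec, out_side)
    for (j in seq_along(gp$slices)) {
      k <- k + 1L
      gray[[k]] <- gp$patches[[j]]
      meta[[k]] <- data.frame(
        patient_id = gp$ann$patient_id,
        image_id = paste(gp$ann$patient_id, gp$ann$view, sep = "_"),
        slice_index = gp$slices[j], label = gp$ann$label,
        y = as.integer(gp$ann$label == "malignant"))
    }
  }
  list(gray = gray, manifest = do.call(rbind, meta),
       annotations = do.call(rbind, anns))
}

## Enhance (and optionally augment) a subset of stored grayscale patches
## into the model-facing 3-channel tensor.
assemble_tensor <- function(cohort, rows, cfg, augment, aug_seed) {
  params <- pce_params(cfg$pce$delta_h, cfg$pce$alpha, cfg$pce$beta,
                       cfg$pce$colorize_mode)
  side <- nrow(cohort$gray[[1]])
  x <- array(0, c(side, side, 3L, length(rows)))
  for (j in seq_along(rows)) {
    r <- rows[j]
    patch <- cohort$gray[[r]]
    if (augment)
      patch <- augment_patch(patch, stage_seed(
        aug_seed, paste0(cohort$manifest$patient_id[r], "_",
                         cohort$manifest$slice_index[r])))
    x[, , , j] <- enhance_for_model(patch, cfg$pce$enabled, params)
  }
  list(x = x, manifest = cohort$manifest[rows, , drop = FALSE])
}

pipeline_fit_predict <- function(cfg, cohort, train_ids, test_ids,
                                 run_seed) {
  aug_seed <- stage_seed(run_seed, "augment")
  tr <- assemble_tensor(cohort,
                        which(cohort$manifest$patient_id %in% train_ids),
                        cfg, isTRUE(cfg$train$augment), aug_seed)
  te <- assemble_tensor(cohort,
                        which(cohort$manifest$patient_id %in% test_ids),
                        cfg, FALSE, aug_seed)
  mcfg <- dual_net_config(cfg$model$shallow, cfg$model$deep,
                          cfg$model$proj_dim, cfg$model$pool_size,
                          cfg$model$variant, cfg$model$pretrained)
  model <- build_dual_net(mcfg, seed = stage_seed(run_seed, "init"))
  fit <- train_dual_net(model, tr$x, tr$manifest$y,
                        epochs = cfg$train$epochs, lr = cfg$train$lr,
                        batch_size = cfg$train$batch_size,
                        lambda = cfg$loss$lambda,
                        sim_reduction = cfg$loss$sim_reduction,
                        seed = stage_seed(run_seed, "train"))
  prob <- predict_dual_net(fit$model, te$x,
                           batch_size = cfg$train$batch_size)
  predictions <- cbind(te$manifest, prob = prob)
  rownames(predictions) <- NULL
  list(model = fit$model, history = fit$history, predictions = predictions,
       test = te)
}

#' Run the full pipeline
#'
#' Executes simulate, preprocess, train, evaluate and explain in order on a
#' synthetic phantom cohort, and (when an output directory is configured)
#' persists the annotation table, prediction CSV, metric table, per-epoch
#' training log, feature export, a fused attention-map overlay and a
#' machine-readable run manifest.
#'
#' @param config configuration accepted by [validate_config()].
#' @return invisibly, `list(config, metrics, predictions, history, model)`.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- validate_config(config)
  run_seed <- as.integer(cfg$seed)
  t0 <- Sys.time()

  ## simulate + preprocess (streamed per patient)
  cohort <- simulate_gray_cohort(cfg, stage_seed(run_seed, "simulate"))

  ## patient-level split / cross-validation
  if (cfg$evaluate$mode == "fixed") {
    sp <- split_patients(cohort$annotations, cfg$train$test_fraction,
                         stage_seed(run_seed, "split"))
    fit <- pipeline_fit_predict(cfg, cohort, sp$train, sp$test, run_seed)
    predictions <- fit$predictions
    history <- fit$history
    model <- fit$model
    test <- fit$test
    metrics <- evaluate_predictions(predictions, vote = cfg$vote)
  } else {
    folds <- kfold_split(cohort$annotations, cfg$evaluate$k,
                         stage_seed(run_seed, "split"))
    predictions <- NULL; history <- NULL; model <- NULL; test <- NULL
    per_fold <- list()
    for (f in seq_len(cfg$evaluate$k)) {
      ids <- folds$patient_id[folds$fold == f]
      fit <- pipeline_fit_predict(
        cfg, cohort, setdiff(folds$patient_id, ids), ids,
        stage_seed(run_seed, paste0("fold", f)))
      per_fold[[f]] <- cbind(evaluate_predictions(fit$predictions,
                                                  vote = cfg$vote),
                             fold = f)
      predictions <- rbind(predictions, cbind(fit$predictions, fold = f))
      model <- fit$model; history <- fit$history; test <- fit$test
    }
    pf <- do.call(rbind, per_fold)
    metrics <- do.call(rbind, lapply(split(pf, pf[, c("level", "metric")]),
      function(g) data.frame(level = g$level[1], metric = g$metric[1],
                             value = mean(g$value, na.rm = TRUE),
                             sd = stats::sd(g$value, na.rm = TRUE))))
    rownames(metrics) <- NULL
  }

  ## explain: fused attention for the first test patch + feature export
  cam <- fused_cam(model, test$x[, , , 1])
  features <- export_features(model, test$x, labels = test$manifest$label)

  out <- cfg$paths$out
  if (!is.null(out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    write_annotations(cohort$annotations, file.path(out, "annotations.csv"))
    utils::write.csv(predictions, file.path(out, "predictions.csv"),
                     row.names = FALSE)
    utils::write.csv(metrics, file.path(out, "metrics.csv"),
                     row.names = FALSE)
    utils::write.csv(history, file.path(out, "training_log.csv"),
                     row.names = FALSE)
    utils::write.csv(features, file.path(out, "features.csv"),
                     row.names = FALSE)
    write_cam_overlay(cam, test$x[, , , 1], file.path(out, "cam_fused.png"))
    save_dual_net(model, file.path(out, "model.rds"))
    manifest <- list(config = cfg,
                     package_version = as.character(
                       utils::packageVersion("dbtdualnet")),
                     r_version = R.version.string,
                     elapsed_sec = as.numeric(difftime(Sys.time(), t0,
                                                       units = "secs")))
    jsonlite::write_json(manifest, file.path(out, "run_manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(list(config = cfg, metrics = metrics, predictions = predictions,
                 history = history, model = model))
}
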