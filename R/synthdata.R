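## Synthetic DBT phantom generator. Each patient receives one grayscale
## volume containing a single ellipsoidal lesion on a correlated-noise
## background with a mild laterality ramp (tissue denser toward the chest
## wall). Benign lesions have smooth, low-order margin undulations;
## malignant lesions have high-frequency, large-amplitude (spiculated)
## margin perturbations — the malignancy signal is geometric, not
## intensity-based. Annotations carry the exact center slice and a tight
## bounding box in the BCS-DBT CSV dialect.

#' Phantom specification
#'
#' Defaults are desk-scale: 64 slices of 256x256 pixels at 0.5 mm in-plane
#' spacing (the spacing is a free parameter, so mm-based logic is exercised
#' at any scale) and 1 mm slice spacing; lesion widths drawn uniformly from
#' 5-80 mm, the size range of screening-detected masses.
#'
#' @param n_patients number of patients (one volume and lesion each).
#' @param n_slices,side volume depth and in-plane side in pixels.
#' @param spacing_xy,spacing_z voxel spacing in mm.
#' @param width_range_mm lesion width range in mm.
#' @param class_balance probability of a malignant lesion, in (0, 1).
#' @param background_noise standard deviation of the correlated background
#'   texture (intensity units).
#' @param benign_amplitude,malignant_amplitude relative margin-perturbation
#'   amplitude per class.
#' @param contrast lesion-over-background intensity contrast.
#' @param seed RNG seed; generation is fully deterministic given the spec.
#' @return a `phantom_spec` object.
#' @export
phantom_spec <- function(n_patients = 100L, n_slices = 64L, side = 256L,
                         spacing_xy = 0.5, spacing_z = 1,
                         width_range_mm = c(5, 80), class_balance = 0.5,
                         background_noise = 0.05,
                         benign_amplitude = 0.05,
                         malignant_amplitude = 0.35,
                         contrast = 0.35, seed = 1L) {
  stopifnot(n_patients >= 1, n_slices >= 1, side >= 16,
            spacing_xy > 0, spacing_z > 0,
            length(width_range_mm) == 2L, width_range_mm[1] > 0,
            width_range_mm[2] >= width_range_mm[1],
            class_balance > 0, class_balance < 1,
            benign_amplitude >= 0, malignant_amplitude >= 0,
            benign_amplitude < 1, malignant_amplitude < 1, contrast > 0)
  structure(as.list(environment()), class = "phantom_spec")
}

## Margin-perturbed radius at polar angles theta: benign = smooth low-order
## undulation, malignant = high-frequency spiculation. sum(|a_k|) equals the
## class amplitude so the radius stays within r0 * (1 +/- amplitude).
lesion_radius <- function(theta, r0, malignant, amplitude, phases) {
  if (amplitude == 0) return(rep(r0, length(theta)))
  if (malignant) {
    k <- c(5, 7, 9, 11); w <- c(0.4, 0.3, 0.2, 0.1)
  } else {
    k <- c(2, 3); w <- c(0.6, 0.4)
  }
  pert <- rep(0, length(theta))
  for (i in seq_along(k))
    pert <- pert + amplitude * w[i] * cos(k[i] * theta + phases[i])
  r0 * (1 + pert)
}

## Row-normalized 1-D Gaussian smoothing matrix; G %*% Z %*% t(G) applies a
## separable Gaussian blur (used for the correlated background texture).
gauss_smoother <- function(n, sigma) {
  d <- outer(seq_len(n), seq_len(n), "-")
  G <- exp(-d^2 / (2 * sigma^2))
  G / rowSums(G)
}

## Geometric lesion mask on one slice (z-scale s in (0, 1]).
slice_lesion_mask <- function(side, cx, cy, r0, s, malignant, amplitude,
                              phases) {
  rmax <- r0 * (1 + amplitude) * s
  x0 <- max(0, floor(cx - rmax - 1)); x1 <- min(side - 1, ceiling(cx + rmax + 1))
  y0 <- max(0, floor(cy - rmax - 1)); y1 <- min(side - 1, ceiling(cy + rmax + 1))
  xs <- x0:x1; ys <- y0:y1
  dx <- matrix(xs - cx, nrow = length(ys), ncol = length(xs), byrow = TRUE)
  dy <- matrix(ys - cy, nrow = length(ys), ncol = length(xs))
  rho <- sqrt(dx^2 + dy^2)
  theta <- atan2(dy, dx)
  rt <- matrix(lesion_radius(as.vector(theta), r0, malignant, amplitude,
                             phases), nrow(rho), ncol(rho)) * s
  list(mask = rho <= rt, edge = clamp((rt - rho) / 2 + 0.5, 0, 1),
       xs = xs, ys = ys)
}

#' Generate one phantom patient
#'
#' Draws the patient's lesion class, size, position and texture from an RNG
#' stream derived from the cohort seed and the patient index, so patients
#' can be generated independently (and streamed without holding the whole
#' cohort in memory) while remaining bit-identical to [generate_phantom()].
#'
#' @param spec a [phantom_spec()]; @param i patient index (1-based).
#' @param smoother optional precomputed [gauss_smoother()] for the side.
#' @return `list(patient_id, volume, annotation)` with a one-row annotation
#'   data.frame.
#' @export
generate_phantom_patient <- function(spec, i, smoother = NULL) {
  stopifnot(inherits(spec, "phantom_spec"), i >= 1, i <= spec$n_patients)
  G <- if (is.null(smoother)) gauss_smoother(spec$side, sigma = 3)
       else smoother
  with_seed(stage_seed(spec$seed, paste0("patient", i)), {
    {
      pid <- sprintf("PH%03d", i)
      malignant <- stats::runif(1) < spec$class_balance
      amp <- if (malignant) spec$malignant_amplitude else spec$benign_amplitude
      width_mm <- stats::runif(1, spec$width_range_mm[1],
                               spec$width_range_mm[2])
      width_px <- width_mm / spec$spacing_xy
      rmax <- width_px / 2
      if (2 * rmax + 8 > spec$side)
        stop("lesion of ", round(width_mm, 1),
             " mm does not fit the volume cross-section")
      r0 <- rmax / (1 + amp)
      cx <- stats::runif(1, rmax + 4, spec$side - rmax - 5)
      cy <- stats::runif(1, rmax + 4, spec$side - rmax - 5)
      rz <- max(1, min(width_mm / 2 / spec$spacing_z,
                       (spec$n_slices - 4) / 2))
      cz <- sample(2:(spec$n_slices - 3), 1)
      phases <- stats::runif(4, 0, 2 * pi)
      view <- sample(c("lcc", "lmlo", "rcc", "rmlo"), 1)

      vol <- array(0, c(spec$n_slices, spec$side, spec$side))
      ramp <- 0.1 * (1 - (0:(spec$side - 1)) / (spec$side - 1))
      if (substr(view, 1, 1) == "r") ramp <- rev(ramp)
      ramp <- matrix(ramp, spec$side, spec$side, byrow = TRUE)
      bbox <- NULL
      for (z in seq_len(spec$n_slices) - 1L) {
        bg <- G %*% matrix(stats::rnorm(spec$side^2), spec$side) %*% t(G)
        bg <- bg / stats::sd(bg) * spec$background_noise
        sl <- 0.3 + ramp + bg
        s <- 1 - ((z - cz) / rz)^2
        if (s > 0) {
          s <- sqrt(s)
          lm <- slice_lesion_mask(spec$side, cx, cy, r0, s, malignant,
                                  amp, phases)
          sub <- sl[lm$ys + 1L, lm$xs + 1L]
          sl[lm$ys + 1L, lm$xs + 1L] <- sub + spec$contrast * lm$edge *
            (lm$edge > 0)
          if (z == cz) {
            mrows <- which(apply(lm$mask, 1, any))
            mcols <- which(apply(lm$mask, 2, any))
            bbox <- c(x = lm$xs[min(mcols)],
                      y = lm$ys[min(mrows)],
                      w = lm$xs[max(mcols)] - lm$xs[min(mcols)] + 1L,
                      h = lm$ys[max(mrows)] - lm$ys[min(mrows)] + 1L)
          }
        }
        vol[z + 1L, , ] <- clamp(sl, 0, 1)
      }
      ## mirror to the stored laterality so annotation and voxels agree
      if (substr(view, 1, 1) == "r") {
        vol <- vol[, , spec$side:1, drop = FALSE]
        bbox["x"] <- spec$side - bbox["x"] - bbox["w"]
      }
      list(patient_id = pid,
           volume = gray_volume(vol, spec$spacing_xy, spec$spacing_z, view),
           annotation = data.frame(
             PatientID = pid, StudyUID = sprintf("ST%03d", i), View = view,
             Slice = as.integer(cz),
             X = as.integer(bbox["x"]), Y = as.integer(bbox["y"]),
             Width = as.integer(bbox["w"]), Height = as.integer(bbox["h"]),
             Class = if (malignant) "malignant" else "benign"))
    }
  })
}

#' Generate a synthetic phantom cohort
#'
#' @param spec a [phantom_spec()].
#' @return `list(volumes, annotations)`: a named list of [gray_volume()]
#'   keyed by patient ID, and an annotation data.frame in the
#'   [read_annotations()] dialect.
#' @export
#' @examples
#' ph <- generate_phantom(phantom_spec(n_patients = 2, n_slices = 12,
#'                                     side = 96, width_range_mm = c(5, 20)))
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  G <- gauss_smoother(spec$side, sigma = 3)
  volumes <- list()
  rows <- vector("list", spec$n_patients)
  for (i in seq_len(spec$n_patients)) {
    p <- generate_phantom_patient(spec, i, smoother = G)
    volumes[[p$patient_id]] <- p$volume
    rows[[i]] <- p$annotation
  }
  list(volumes = volumes, annotations = do.call(rbind, rows))
}

#' Margin-irregularity separability of a phantom cohort
#'
#' Computes, for each lesion, the shape compactness statistic
#' `perimeter^2 / area` of the thresholded lesion mask on the annotated
#' center slice (cropped to the bounding box), and reports the AUC with
#' which this single statistic separates benign from malignant. At default
#' texture parameters the task must be solvable (AUC well above chance),
#' guaranteeing the learning problem posed to the classifier carries signal.
#'
#' @param volumes,annotations a cohort from [generate_phantom()].
#' @return `list(auc, table)`; `table` has one row per lesion with the
#'   statistic and label.
#' @export
separability_check <- function(volumes, annotations) {
  if (length(unique(annotations$Class)) < 2L)
    stop("separability check needs both classes")
  stat <- numeric(nrow(annotations))
  for (i in seq_len(nrow(annotations))) {
    ann <- annotation_row(annotations, i)
    vol <- volumes[[ann$patient_id]]
    sl <- vol$voxels[ann$center_slice + 1L, , ]
    m <- 5L
    y0 <- max(1, ann$bbox[2] + 1 - m); y1 <- min(nrow(sl), ann$bbox[2] + ann$bbox[4] + m)
    x0 <- max(1, ann$bbox[1] + 1 - m); x1 <- min(ncol(sl), ann$bbox[1] + ann$bbox[3] + m)
    crop <- sl[y0:y1, x0:x1]
    thr <- EBImage::otsu(EBImage::Image(crop), range = c(0, 1))
    lab <- EBImage::bwlabel(crop > thr)
    if (max(lab) == 0) { stat[i] <- NA; next }
    ft <- EBImage::computeFeatures.shape(lab)
    big <- which.max(ft[, "s.area"])
    stat[i] <- ft[big, "s.perimeter"]^2 / ft[big, "s.area"]
  }
  y <- as.integer(annotations$Class == "malignant")
  ok <- !is.na(stat)
  list(auc = auc_score(stat[ok], y[ok]),
       table = data.frame(patient_id = annotations$PatientID,
                          statistic = stat, label = annotations$Class))
}
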