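## Turning annotated DBT volumes into model-ready slice patches:
## orientation standardization, bounding-box ROI extraction with a fixed
## pixel margin, Z-window slice sampling around the annotated center slice,
## per-crop min-max normalization, resizing to 224x224, and training-time
## augmentation.
##
## Coordinate conventions (matching the BCS-DBT annotation dialect):
## 0-based pixel coordinates, bounding box (x, y, width, height) with
## (x, y) the top-left corner, y increasing downward, half-open extents.
## Slices are matrices indexed [row = y + 1, col = x + 1].

#' Construct a grayscale DBT volume
#'
#' @param voxels 3-D array indexed `[slice, row, col]`, values in `[0, 1]`.
#' @param spacing_xy,spacing_z voxel size in mm (reference acquisition:
#'   0.085 mm in-plane, 1 mm between slices).
#' @param view laterality/view tag such as `"lcc"`, `"rmlo"` (first letter
#'   encodes laterality).
#' @return a `gray_volume` object.
#' @export
gray_volume <- function(voxels, spacing_xy = 0.085, spacing_z = 1,
                        view = "lcc") {
  stopifnot(length(dim(voxels)) == 3L, dim(voxels)[1] >= 1,
            spacing_xy > 0, spacing_z > 0)
  structure(list(voxels = voxels, spacing_xy = spacing_xy,
                 spacing_z = spacing_z, view = view),
            class = "gray_volume")
}

#' Lesion annotation
#'
#' @param patient_id,view identifiers; @param label `"benign"` or
#'   `"malignant"`; @param center_slice 0-based index of the annotated
#'   center slice; @param bbox `c(x, y, width, height)` in pixels (0-based
#'   top-left corner, half-open extents).
#' @return a `lesion_annotation` object.
#' @export
lesion_annotation <- function(patient_id, view, label, center_slice, bbox) {
  label <- match.arg(label, c("benign", "malignant"))
  bbox <- as.numeric(bbox)
  stopifnot(length(bbox) == 4L, bbox[3] > 0, bbox[4] > 0, center_slice >= 0)
  structure(list(patient_id = as.character(patient_id),
                 view = as.character(view), label = label,
                 center_slice = as.integer(center_slice), bbox = bbox),
            class = "lesion_annotation")
}

#' Read / write a lesion annotation table
#'
#' The CSV dialect has columns `PatientID, StudyUID, View, Slice, X, Y,
#' Width, Height, Class` with 0-based `Slice`/`X`/`Y` and `Class` in
#' `{benign, malignant}`. Reading then writing is lossless field-by-field.
#'
#' @param path CSV file path; @param annotations a data.frame in this
#'   dialect.
#' @return `read_annotations` returns the data.frame.
#' @export
read_annotations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("PatientID", "StudyUID", "View", "Slice", "X", "Y",
            "Width", "Height", "Class")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("annotation table misses columns: ", paste(miss, collapse = ", "))
  if (!all(df$Class %in% c("benign", "malignant")))
    stop("Class must be 'benign' or 'malignant'")
  df[, need]
}

#' @rdname read_annotations
#' @export
write_annotations <- function(annotations, path) {
  utils::write.csv(annotations, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

annotation_row <- function(df, i) {
  lesion_annotation(df$PatientID[i], df$View[i], df$Class[i], df$Slice[i],
                    c(df$X[i], df$Y[i], df$Width[i], df$Height[i]))
}

#' Standardize volume orientation to left-aligned breast tissue
#'
#' Right-lateral volumes (view tag starting with "r") are mirrored about the
#' vertical axis so that tissue occupies the left side of every slice, and
#' bounding boxes are remapped with `x' = W - x - w`. When the view tag is
#' missing, a mass-centroid heuristic decides (with a warning).
#'
#' @param volume a [gray_volume()].
#' @param annotations optional list of [lesion_annotation()] (or a single
#'   one) to remap alongside.
#' @return `list(volume, annotations, flipped)`.
#' @export
standardize_orientation <- function(volume, annotations = NULL) {
  stopifnot(inherits(volume, "gray_volume"))
  single <- inherits(annotations, "lesion_annotation")
  if (single) annotations <- list(annotations)
  nx <- dim(volume$voxels)[3]
  lat <- tolower(substr(volume$view, 1, 1))
  if (lat %in% c("l", "r")) {
    flip <- lat == "r"
  } else {
    xw <- apply(volume$voxels, 3, sum)
    cx <- sum(xw * seq_along(xw)) / sum(xw)
    flip <- cx > (nx + 1) / 2
    warning("no laterality tag; using mass-centroid heuristic (flip = ",
            flip, ")")
  }
  if (flip) {
    volume$voxels <- volume$voxels[, , nx:1, drop = FALSE]
    volume$view <- paste0("l", substr(volume$view, 2, nchar(volume$view)))
    annotations <- lapply(annotations, function(a) {
      a$bbox[1] <- nx - a$bbox[1] - a$bbox[3]
      a$view <- volume$view
      a
    })
  }
  list(volume = volume,
       annotations = if (single) annotations[[1]] else annotations,
       flipped = flip)
}

#' Extract and normalize a lesion ROI from one slice
#'
#' Expands the annotated bounding box by `margin` pixels on each of the four
#' sides (20 px total per dimension at the default), clips the crop to the
#' image bounds, min-max normalizes the crop intensities to `[0, 1]`, and
#' resizes to `out_side x out_side` with bilinear interpolation.
#'
#' @param slice 2-D intensity matrix.
#' @param ann a [lesion_annotation()] or a bare `c(x, y, w, h)` box.
#' @param margin per-side expansion in pixels (default 10).
#' @param out_side output side length (default 224).
#' @return `list(patch, crop)`: the normalized patch and the pre-resize crop
#'   bounds `c(x0, x1, y0, y1)` (0-based, half-open).
#' @export
extract_roi <- function(slice, ann, margin = 10L, out_side = 224L) {
  bbox <- if (inherits(ann, "lesion_annotation")) ann$bbox else as.numeric(ann)
  stopifnot(length(bbox) == 4L)
  H <- nrow(slice); W <- ncol(slice)
  if (bbox[1] >= W || bbox[2] >= H ||
      bbox[1] + bbox[3] <= 0 || bbox[2] + bbox[4] <= 0)
    stop("bounding box lies fully outside the slice")
  x0 <- max(0, floor(bbox[1] - margin))
  y0 <- max(0, floor(bbox[2] - margin))
  x1 <- min(W, ceiling(bbox[1] + bbox[3] + margin))
  y1 <- min(H, ceiling(bbox[2] + bbox[4] + margin))
  crop <- slice[(y0 + 1):y1, (x0 + 1):x1, drop = FALSE]
  rng <- range(crop)
  if (rng[2] > rng[1]) {
    crop <- (crop - rng[1]) / (rng[2] - rng[1])
  } else {
    warning("zero-dynamic-range crop; normalized to all zeros")
    crop[] <- 0
  }
  patch <- EBImage::resize(crop, w = out_side, h = out_side,
                           filter = "bilinear", antialias = TRUE)
  patch <- clamp(matrix(patch, out_side, out_side), 0, 1)
  list(patch = patch, crop = c(x0 = x0, x1 = x1, y0 = y0, y1 = y1))
}

#' Slice-window specification
#'
#' @param total_slices Z-window size around the center slice (default 10,
#'   i.e. 10 mm at 1 mm slice spacing).
#' @param m adjacent-slice radius for prediction-time selection; `2m + 1`
#'   slices symmetric about the center are used (default `m = 1`).
#' @return a `slice_window_spec`.
#' @export
slice_window_spec <- function(total_slices = 10L, m = 1L) {
  total_slices <- as.integer(total_slices); m <- as.integer(m)
  stopifnot(total_slices >= 1, m >= 0)
  if (2L * m + 1L > total_slices)
    stop("2m + 1 exceeds the window size (m = ", m, ", total = ",
         total_slices, ")")
  structure(list(total_slices = total_slices, m = m),
            class = "slice_window_spec")
}

#' Sample slice indices around the annotated center slice
#'
#' The Z-window is the contiguous block `center - 5 ... center + 4` (for the
#' default 10-slice window), shifted minimally to stay inside the volume.
#' With `mode = "predict"` the `2m + 1` indices symmetric about the center
#' (within that window) are returned instead.
#'
#' @param volume a [gray_volume()] or an integer slice count.
#' @param ann a [lesion_annotation()] or a bare 0-based center-slice index.
#' @param spec a [slice_window_spec()].
#' @param mode `"window"` (the full window) or `"predict"` (`2m + 1` slices).
#' @return integer vector of 0-based, contiguous, in-bounds slice indices.
#' @export
#' @examples
#' sample_slices(60, 25, slice_window_spec(10, 1), mode = "predict") # 24:26
sample_slices <- function(volume, ann, spec = slice_window_spec(),
                          mode = c("window", "predict")) {
  mode <- match.arg(mode)
  n <- if (inherits(volume, "gray_volume")) dim(volume$voxels)[1]
       else as.integer(volume)
  center <- if (inherits(ann, "lesion_annotation")) ann$center_slice
            else as.integer(ann)
  stopifnot(center >= 0, center < n)
  total <- spec$total_slices
  if (n < total) {
    warning("volume has only ", n, " slices; using all of them")
    window <- 0:(n - 1L)
  } else {
    half_lo <- ceiling((total - 1L) / 2L) # -5/+4 split for even windows
    lo <- max(0L, min(center - half_lo, n - total))
    window <- lo + 0:(total - 1L)
  }
  if (mode == "window") return(window)
  k <- 2L * spec$m + 1L
  if (length(window) < k) return(window)
  lo2 <- max(window[1L], min(center - spec$m, window[length(window)] - k + 1L))
  lo2 + 0:(k - 1L)
}

#' Training-time augmentation of a patch
#'
#' Rotates by an angle drawn uniformly from +/-[10, 30] degrees (sign chosen
#' uniformly, exposed corners filled with zeros) and shifts horizontally and
#' vertically by integer offsets up to `shift_frac` of the side length.
#' Deterministic given `rng_seed`.
#'
#' @param patch square matrix in `[0, 1]`.
#' @param rng_seed integer seed.
#' @param angle_range rotation magnitude range in degrees.
#' @param shift_frac maximum translation as a fraction of the side.
#' @param enabled when `FALSE`, the patch is returned unchanged.
#' @return augmented patch, same shape, values in `[0, 1]`.
#' @export
augment_patch <- function(patch, rng_seed, angle_range = c(10, 30),
                          shift_frac = 0.1, enabled = TRUE) {
  if (!enabled) return(patch)
  side <- nrow(patch)
  with_seed(rng_seed, {
    ang <- sample(c(-1, 1), 1) * stats::runif(1, angle_range[1], angle_range[2])
    smax <- floor(shift_frac * side)
    dx <- sample(-smax:smax, 1)
    dy <- sample(-smax:smax, 1)
    out <- EBImage::rotate(patch, ang, filter = "bilinear",
                           output.dim = c(side, side), bg.col = 0)
    out <- EBImage::translate(out, v = c(dx, dy), bg.col = 0)
    clamp(matrix(out, side, side), 0, 1)
  })
}

## Expand a grayscale patch to the 3-channel tensor the model consumes,
## applying the configured enhancement.
enhance_for_model <- function(patch, enhancement = c("pce", "histeq", "off"),
                              params = pce_params()) {
  enhancement <- match.arg(enhancement)
  if (enhancement == "pce") return(enhance_patch(patch, params))
  if (enhancement == "histeq") patch <- histogram_equalize(patch)
  out <- array(0, c(nrow(patch), ncol(patch), 3))
  out[, , 1] <- patch; out[, , 2] <- patch; out[, , 3] <- patch
  out
}

## Grayscale prediction patches for one annotated lesion: orientation
## standardization, slice selection, ROI extraction. Shared by the batch
## dataset builder and the streaming pipeline so both are bit-identical.
gray_patches_for <- function(vol, ann, spec, out_side) {
  std <- standardize_orientation(vol, ann)
  idx <- sample_slices(std$volume, std$annotations, spec, mode = "predict")
  patches <- lapply(idx, function(z)
    extract_roi(std$volume$voxels[z + 1L, , ], std$annotations,
                out_side = out_side)$patch)
  list(patches = patches, slices = idx, ann = std$annotations)
}

#' Build a model-ready patch dataset from volumes and annotations
#'
#' For every annotation: standardizes orientation, samples the `2m + 1`
#' prediction slices inside the 10-slice Z-window, extracts and normalizes
#' the ROI on each slice, optionally augments (training mode), and applies
#' the configured enhancement.
#'
#' @param volumes named list of [gray_volume()] keyed by patient ID.
#' @param annotations annotation data.frame (see [read_annotations()]).
#' @param spec a [slice_window_spec()].
#' @param enhancement `"pce"`, `"histeq"`, or `"off"`.
#' @param params [pce_params()] for the `"pce"` mode.
#' @param augment logical; training-time augmentation of each patch.
#' @param seed seed for augmentation draws.
#' @param out_side patch side (default 224).
#' @return `list(x, manifest)`: a `[side, side, 3, K]` tensor and a
#'   data.frame (patient_id, image_id, slice_index, label, y).
#' @export
make_patch_dataset <- function(volumes, annotations,
                               spec = slice_window_spec(),
                               enhancement = "pce", params = pce_params(),
                               augment = FALSE, seed = 1L, out_side = 224L) {
  records <- list()
  meta <- list()
  k <- 0L
  for (i in seq_len(nrow(annotations))) {
    ann <- annotation_row(annotations, i)
    vol <- volumes[[ann$patient_id]]
    if (is.null(vol)) stop("no volume for patient ", ann$patient_id)
    gp <- gray_patches_for(vol, ann, spec, out_side)
    ann <- gp$ann
    for (j in seq_along(gp$slices)) {
      z <- gp$slices[j]
      patch <- gp$patches[[j]]
      if (augment)
        patch <- augment_patch(
          patch, stage_seed(seed, paste0(ann$patient_id, "_", z)))
      k <- k + 1L
      records[[k]] <- enhance_for_model(patch, enhancement, params)
      meta[[k]] <- data.frame(
        patient_id = ann$patient_id,
        image_id = paste(ann$patient_id, ann$view, sep = "_"),
        slice_index = z, label = ann$label,
        y = as.integer(ann$label == "malignant"))
    }
  }
  if (k == 0L) stop("no patches produced")
  x <- array(0, c(out_side, out_side, 3L, k))
  for (j in seq_len(k)) x[, , , j] <- records[[j]]
  list(x = x, manifest = do.call(rbind, meta))
}
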