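test_that("phantom generation is bit-deterministic given the spec", {
  sp <- phantom_spec(n_patients = 3, n_slices = 12, side = 96,
                     width_range_mm = c(5, 25), seed = 77)
  a <- generate_phantom(sp)
  b <- generate_phantom(sp)
  expect_identical(a$annotations, b$annotations)
  expect_identical(a$volumes[["PH002"]]$voxels, b$volumes[["PH002"]]$voxels)
  c <- generate_phantom(phantom_spec(n_patients = 3, n_slices = 12,
                                     side = 96, width_range_mm = c(5, 25),
                                     seed = 78))
  expect_false(identical(a$annotations, c$annotations))
})

test_that("voxels are in range with positive lesion contrast", {
  ph <- tiny_phantom(4, seed = 31)
  for (i in 1:4) {
    ann <- ph$annotations[i, ]
    vol <- ph$volumes[[ann$PatientID]]
    expect_true(all(vol$voxels >= 0 & vol$voxels <= 1))
    sl <- vol$voxels[ann$Slice + 1, , ]
    inside <- sl[(ann$Y + 1):(ann$Y + ann$Height),
                 (ann$X + 1):(ann$X + ann$Width)]
    expect_gt(mean(inside), mean(sl)) # lesion brighter than background
  }
})

test_that("lesion widths stay inside the screening size range", {
  # measure many lesions cheaply with shallow volumes
  widths <- c()
  for (s in 1:8) {
    ph <- generate_phantom(phantom_spec(n_patients = 25, n_slices = 6,
                                        side = 256, seed = 100 + s))
    widths <- c(widths, ph$annotations$Width * 0.5,
                ph$annotations$Height * 0.5)
  }
  expect_gte(length(widths), 400)
  expect_true(all(widths >= 2.5 & widths <= 81)) # nominal 5-80 mm draw;
  # the spiculated margin can pull the tight box slightly inside the
  # nominal envelope, never outside it
  expect_gt(max(widths), 55)
  expect_lt(min(widths), 12)
})

test_that("bounding boxes contain all supra-threshold lesion voxels", {
  # noise-free texture isolates the lesion signal for the audit
  ph <- generate_phantom(phantom_spec(n_patients = 6, n_slices = 10,
                                      side = 160, width_range_mm = c(8, 40),
                                      background_noise = 1e-6,
                                      contrast = 0.5, seed = 5))
  for (i in 1:6) {
    ann <- ph$annotations[i, ]
    vol <- ph$volumes[[ann$PatientID]]
    sl <- vol$voxels[ann$Slice + 1, , ]
    ramp_max <- 0.1
    supra <- which(sl > 0.3 + ramp_max + 0.5 * 0.5 + 0.01, arr.ind = TRUE)
    expect_gt(nrow(supra), 0)
    expect_true(all(supra[, "row"] >= ann$Y + 1 - 1 &
                    supra[, "row"] <= ann$Y + ann$Height + 1 &
                    supra[, "col"] >= ann$X + 1 - 1 &
                    supra[, "col"] <= ann$X + ann$Width + 1))
  }
})

test_that("jointly scaling spacing and sizes leaves pixel boxes unchanged", {
  base <- phantom_spec(n_patients = 3, n_slices = 10, side = 128,
                       spacing_xy = 0.5, spacing_z = 1,
                       width_range_mm = c(5, 25), seed = 9)
  scaled <- phantom_spec(n_patients = 3, n_slices = 10, side = 128,
                         spacing_xy = 1, spacing_z = 2,
                         width_range_mm = c(10, 50), seed = 9)
  a <- generate_phantom(base)$annotations
  b <- generate_phantom(scaled)$annotations
  expect_identical(a[, c("X", "Y", "Width", "Height", "Slice")],
                   b[, c("X", "Y", "Width", "Height", "Slice")])
})

test_that("oversized lesions are rejected", {
  expect_error(generate_phantom(phantom_spec(n_patients = 1, side = 64,
                                             width_range_mm = c(100, 100),
                                             seed = 1)),
               "does not fit")
})

test_that("margin irregularity separates the classes", {
  ph <- generate_phantom(phantom_spec(n_patients = 40, n_slices = 8,
                                      side = 192, width_range_mm = c(8, 60),
                                      seed = 41))
  sep <- separability_check(ph$volumes, ph$annotations)
  expect_gt(sep$auc, 0.9)
  # label swap maps the AUC to its complement
  flipped <- ph$annotations
  flipped$Class <- ifelse(flipped$Class == "malignant", "benign", "malignant")
  sep2 <- separability_check(ph$volumes, flipped)
  expect_equal(sep2$auc, 1 - sep$auc, tolerance = 1e-12)
})

test_that("no geometric signal means no separability", {
  ph <- generate_phantom(phantom_spec(n_patients = 30, n_slices = 8,
                                      side = 160, width_range_mm = c(8, 40),
                                      benign_amplitude = 0,
                                      malignant_amplitude = 0, seed = 13))
  if (length(unique(ph$annotations$Class)) == 2) {
    sep <- separability_check(ph$volumes, ph$annotations)
    expect_lt(abs(sep$auc - 0.5), 0.25)
  }
  ph1 <- ph
  ph1$annotations$Class <- "benign"
  expect_error(separability_check(ph1$volumes, ph1$annotations),
               "both classes")
})

test_that("phantom annotations feed straight into the preprocess reader", {
  ph <- tiny_phantom(3, seed = 11)
  f <- tempfile(fileext = ".csv")
  write_annotations(ph$annotations, f)
  back <- read_annotations(f)
  ds <- make_patch_dataset(ph$volumes, back, slice_window_spec(10, 1),
                           out_side = 32)
  expect_equal(dim(ds$x)[4], 3 * nrow(back))
})
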