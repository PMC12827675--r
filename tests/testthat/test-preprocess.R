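make_volume <- function(nz = 12, ny = 40, nx = 50, view = "lcc", seed = 2) {
  vox <- dbtdualnet:::with_seed(seed, array(runif(nz * ny * nx), c(nz, ny, nx)))
  gray_volume(vox, spacing_xy = 0.5, spacing_z = 1, view = view)
}

test_that("right-lateral volumes are mirrored and boxes remapped", {
  vol <- make_volume(view = "rcc")
  ann <- lesion_annotation("p1", "rcc", "benign", 5, c(10, 8, 30, 12))
  std <- standardize_orientation(vol, ann)
  expect_true(std$flipped)
  # mirror formula x' = W - x - w, verified against brute-force mirroring
  expect_equal(std$annotations$bbox[1], 50 - 10 - 30)
  expect_equal(std$volume$voxels[3, , ], vol$voxels[3, , 50:1])
  # pixels inside the box before == pixels inside the remapped box after
  before <- vol$voxels[6, 9:20, 11:40]
  after <- std$volume$voxels[6, 9:20, (std$annotations$bbox[1] + 1):
                                        (std$annotations$bbox[1] + 30)]
  expect_equal(after, before[, 30:1])
  # involution: flipping the flipped (now left) volume is the identity
  std2 <- standardize_orientation(std$volume, std$annotations)
  expect_false(std2$flipped)
  expect_identical(std2$volume$voxels, std$volume$voxels)
})

test_that("missing laterality falls back to a mass-centroid heuristic", {
  vol <- make_volume(view = "unknown")
  vol$voxels[, , 26:50] <- vol$voxels[, , 26:50] + 2 # mass on the right
  expect_warning(std <- standardize_orientation(vol), "centroid")
  expect_true(std$flipped)
})

test_that("ROI extraction expands 10 px per side, clips, and resizes to 224", {
  slice <- dbtdualnet:::with_seed(3, matrix(runif(500 * 500), 500, 500))
  r <- extract_roi(slice, c(100, 100, 50, 50))
  expect_equal(unname(r$crop), c(90, 160, 90, 160)) # 70x70 pre-resize
  expect_equal(dim(r$patch), c(224L, 224L))
  # corner box: clipped to a 40x40 crop anchored at the origin
  r2 <- extract_roi(slice, c(0, 0, 30, 30))
  expect_equal(unname(r2$crop), c(0, 40, 0, 40))
  expect_equal(unname(r2$crop[c(2, 4)] - r2$crop[c(1, 3)]), c(40, 40))
  # output patch contract holds for assorted boxes
  for (bb in list(c(480, 480, 30, 30), c(5, 400, 90, 60))) {
    p <- extract_roi(slice, bb)$patch
    expect_equal(dim(p), c(224L, 224L))
    expect_true(all(p >= 0 & p <= 1))
  }
  expect_error(extract_roi(slice, c(600, 600, 10, 10)), "outside")
  expect_warning(extract_roi(matrix(0.5, 100, 100), c(40, 40, 20, 20)),
                 "zero-dynamic-range")
})

test_that("ROI extraction commutes with mirroring", {
  slice <- dbtdualnet:::with_seed(8, matrix(runif(200 * 300), 200, 300))
  bb <- c(120, 60, 40, 50)
  mirrored <- slice[, 300:1]
  bb_m <- c(300 - bb[1] - bb[3], bb[2], bb[3], bb[4])
  a <- extract_roi(slice, bb)$patch[, 224:1]
  b <- extract_roi(mirrored, bb_m)$patch
  expect_lt(max(abs(a - b)), 0.02) # interpolation tolerance
})

test_that("slice sampling returns a contiguous centered window", {
  spec <- slice_window_spec(10, 1)
  expect_equal(sample_slices(60, 25, spec), 20:29)
  expect_length(sample_slices(60, 25, spec), 10)
  expect_equal(sample_slices(60, 25, spec, mode = "predict"), 24:26)
  expect_equal(sample_slices(60, 2, spec), 0:9) # shifted at the edge
  expect_equal(sample_slices(60, 58, spec), 50:59)
  expect_equal(sample_slices(60, 59, slice_window_spec(10, 3),
                             mode = "predict"), 53:59)
  # window contract, exhaustively over all centers
  for (center in 0:59) {
    w <- sample_slices(60, center, spec)
    expect_length(w, 10)
    expect_equal(w, w[1]:(w[1] + 9)) # contiguous
    expect_true(all(w >= 0 & w <= 59))
    expect_true(center %in% w)
    s <- sample_slices(60, center, spec, mode = "predict")
    expect_length(s, 3)
    expect_true(all(s %in% w))
  }
  expect_warning(w <- sample_slices(6, 3, spec), "slices")
  expect_equal(w, 0:5)
  expect_error(slice_window_spec(5, 3), "2m \\+ 1")
})

test_that("augmentation is seeded, shape- and range-preserving", {
  p <- dbtdualnet:::with_seed(1, matrix(runif(224^2), 224, 224))
  expect_identical(augment_patch(p, 3, enabled = FALSE), p)
  a1 <- augment_patch(p, 42)
  a2 <- augment_patch(p, 42)
  expect_identical(a1, a2)
  expect_false(identical(a1, augment_patch(p, 43)))
  for (seed in 1:25) {
    a <- augment_patch(p, seed)
    expect_equal(dim(a), c(224L, 224L))
    expect_true(all(a >= 0 & a <= 1))
  }
})

test_that("annotation tables round-trip losslessly", {
  ph <- tiny_phantom(4, seed = 11)
  f <- tempfile(fileext = ".csv")
  write_annotations(ph$annotations, f)
  back <- read_annotations(f)
  expect_identical(back, ph$annotations)
  bad <- ph$annotations[, -3]
  f2 <- tempfile(fileext = ".csv")
  utils::write.csv(bad, f2, row.names = FALSE)
  expect_error(read_annotations(f2), "misses columns")
})

test_that("patch datasets carry the window, labels and enhanced channels", {
  ph <- tiny_phantom(3, seed = 11)
  ds <- make_patch_dataset(ph$volumes, ph$annotations,
                           slice_window_spec(10, 1), out_side = 64)
  expect_equal(dim(ds$x), c(64L, 64L, 3L, 9L)) # 3 patients x (2m+1)
  expect_equal(nrow(ds$manifest), 9L)
  expect_setequal(unique(ds$manifest$patient_id), names(ph$volumes))
  expect_true(all(ds$x >= 0 & ds$x <= 1))
  expect_equal(ds$manifest$y,
               as.integer(ds$manifest$label == "malignant"))
  # per-image slice indices are the symmetric triple about the center slice
  for (i in seq_len(nrow(ph$annotations))) {
    got <- ds$manifest$slice_index[ds$manifest$patient_id ==
                                     ph$annotations$PatientID[i]]
    std <- standardize_orientation(
      ph$volumes[[ph$annotations$PatientID[i]]])
    expect_length(got, 3)
    expect_equal(got, got[1]:(got[1] + 2))
    expect_true(ph$annotations$Slice[i] %in% got)
  }
})
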