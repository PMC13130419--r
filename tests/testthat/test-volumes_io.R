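test_that("Dixon triplet round-trips through NIfTI bit-for-bit", {
  ph <- fast_phantom(seed = 2)
  dir <- withr::local_tempdir()
  paths <- write_dixon(ph$dixon, dir)
  back <- read_dixon(paths["in_phase"], paths["water"], paths["fat"], "S2")
  expect_identical(back$in_phase, ph$dixon$in_phase)
  expect_identical(back$water, ph$dixon$water)
  expect_identical(back$fat, ph$dixon$fat)
  expect_lt(max(abs(back$geometry$spacing - ph$dixon$geometry$spacing)), 1e-6)
  expect_lt(max(abs(back$geometry$origin - ph$dixon$geometry$origin)), 1e-6)
  # read volume satisfies the Dixon identity exactly
  expect_equal(max(abs(back$in_phase - (back$water + back$fat))), 0)
})

test_that("mismatched channel geometry raises an error naming the axis", {
  g1 <- geometry(c(6, 6, 4), c(0.94, 0.94, 1.95))
  g2 <- geometry(c(6, 6, 4), c(0.95, 0.94, 1.95))
  arr <- array(1, c(6, 6, 4))
  d <- withr::local_tempdir()
  ldq:::.write_nifti(arr, g1, file.path(d, "ip.nii.gz"))
  ldq:::.write_nifti(arr, g2, file.path(d, "w.nii.gz"))
  ldq:::.write_nifti(arr, g1, file.path(d, "f.nii.gz"))
  expect_error(read_dixon(file.path(d, "ip.nii.gz"), file.path(d, "w.nii.gz"),
                          file.path(d, "f.nii.gz")),
               "x axis")
  expect_error(read_dixon(file.path(d, "ip.nii.gz"), file.path(d, "missing.nii.gz"),
                          file.path(d, "f.nii.gz")),
               "not found")
})

test_that("label maps round-trip with their JSON code table", {
  ph <- fast_phantom(seed = 3)
  d <- withr::local_tempdir()
  p <- file.path(d, "labels.nii.gz")
  write_volume(ph$labels, path = p)
  expect_true(file.exists(paste0(p, ".codes.json")))
  back <- read_label_map(p)
  expect_identical(back$labels, ph$labels$labels)
  expect_identical(back$code_table, MUSCLE_CODES)
})

test_that("one-hot encoding is a bijection with exactly one hot channel per voxel", {
  # single-voxel map with code 3
  g <- geometry(c(4, 4, 4), c(1, 1, 1))
  lab <- array(0L, c(4, 4, 4)); lab[2, 3, 1] <- 3L
  lm <- label_map(lab, g)
  oh <- onehot_encode(lm)
  expect_equal(sum(oh[, , , 4]), 1)
  expect_equal(oh[2, 3, 1, 4], 1L)
  expect_equal(sum(oh[2, 3, 1, -4]), 0)
  # all-background map: background channel all 1
  lm0 <- label_map(array(0L, c(4, 4, 4)), g)
  oh0 <- onehot_encode(lm0)
  expect_true(all(oh0[, , , 1] == 1L))
  # random 8-code map: per-voxel channel sums all equal 1, decode inverts
  set.seed(11)
  lab <- array(sample(0:8, 16^3, replace = TRUE), c(16, 16, 16))
  storage.mode(lab) <- "integer"
  lm <- label_map(lab, geometry(c(16, 16, 16), c(1, 1, 1)))
  oh <- onehot_encode(lm)
  expect_true(all(apply(oh, 1:3, sum) == 1L))
  expect_identical(onehot_decode(oh, lm$geometry)$labels, lm$labels)
})

test_that("geometry constructor enforces its invariants", {
  expect_error(geometry(c(0, 4, 4), c(1, 1, 1)), "shape")
  expect_error(geometry(c(4, 4, 4), c(1, -1, 1)), "spacing")
})
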