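make_dixon <- function(w, f, spacing = c(1, 1, 1), id = "T") {
  g <- geometry(dim(w), spacing)
  dixon_volume(w + f, w, f, g, id)
}

test_that("ff_map computes fat/(water+fat) and flags invalid voxels", {
  d <- c(4, 4, 4)
  w <- array(1, d); f <- array(1, d)
  ffm <- ff_map(make_dixon(w, f))
  expect_true(all(ffm$ff == 0.5))
  ffm0 <- ff_map(make_dixon(w, array(0, d)))
  expect_true(all(ffm0$ff == 0))
  # single voxel (W, F) = (1, 3) -> 0.75; an air voxel is invalid, not 0/0
  w <- array(0, d); f <- array(0, d)
  w[1, 1, 1] <- 1; f[1, 1, 1] <- 3
  ffm <- ff_map(make_dixon(w, f))
  expect_equal(ffm$ff[1, 1, 1], 0.75)
  expect_true(is.na(ffm$ff[2, 2, 2]))
  expect_false(ffm$valid[2, 2, 2])
})

test_that("mean_ff averages masked valid voxels in percent with axial crops", {
  d <- c(2, 2, 4)
  f <- array(0, d); w <- array(1, d)
  f[1, 1, 1] <- 0.1; w[1, 1, 1] <- 0.9
  f[2, 1, 1] <- 0.3; w[2, 1, 1] <- 0.7
  lab <- array(0L, d); lab[1:2, 1, 1] <- 1L
  g <- geometry(d, c(1, 1, 1))
  ffm <- ff_map(dixon_volume(w + f, w, f, g))
  expect_equal(as.numeric(mean_ff(ffm, label_map(lab, g), 1)), 20)
  # two-compartment mask split along z; crop to the inferior half
  f2 <- array(0, d); w2 <- array(1, d)
  f2[, , 1:2] <- 0.1; w2[, , 1:2] <- 0.9
  f2[, , 3:4] <- 0.3; w2[, , 3:4] <- 0.7
  lab2 <- array(1L, d)
  ffm2 <- ff_map(dixon_volume(w2 + f2, w2, f2, g))
  lm2 <- label_map(lab2, g)
  expect_equal(as.numeric(mean_ff(ffm2, lm2, 1)), 20)
  expect_equal(as.numeric(mean_ff(ffm2, lm2, 1, crop = c(1, 2))), 10)
  expect_error(mean_ff(ffm2, lm2, 2), "no voxels")
  expect_error(mean_ff(ffm, label_map(lab, g), 1, crop = c(3, 4)), "no voxels")
})

test_that("mean_ff is invariant to relabeling outside the mask", {
  ph <- fast_phantom(seed = 6)
  ffm <- ff_map(ph$dixon)
  base <- as.numeric(mean_ff(ffm, ph$labels, 1))
  relab <- ph$labels$labels
  relab[relab == 5L] <- 6L
  relab[relab == 3L] <- 0L
  lm2 <- label_map(relab, ph$labels$geometry)
  expect_equal(as.numeric(mean_ff(ffm, lm2, 1)), base)
})

test_that("bilateral mean is unweighted and rejects mismatched sides", {
  recs <- data.frame(subject = "S1", muscle = "P", side = c("L", "R"),
                     mean_ff_pct = c(10, 14), n_voxels = c(1, 3),
                     n_invalid = 0, crop = "")
  l <- recs[1, ]; r <- recs[2, ]
  expect_equal(bilateral_mean(l, r), 12)
  # differs from the voxel-weighted mean when side volumes differ
  expect_equal(bilateral_mean(l, r, weighted = TRUE), (10 * 1 + 14 * 3) / 4)
  expect_error(bilateral_mean(l, l), "side mismatch")
  r2 <- r; r2$muscle <- "I"
  expect_error(bilateral_mean(l, r2), "same subject and muscle")
})

test_that("FF recovery on phantoms is within tolerance at default noise", {
  # noiseless: exact; default noise: within 2 percentage points
  ph <- fast_phantom(seed = 12, noise_sd = 0.02)
  ffm <- ff_map(ph$dixon)
  for (i in seq_len(nrow(ph$truth))) {
    m <- as.numeric(mean_ff(ffm, ph$labels, ph$truth$code[i]))
    expect_lt(abs(m - 100 * ph$truth$ff[i]), 2)
  }
})

test_that("measure_ff emits the fixed record schema and bilateral_table collapses it", {
  ph <- fast_phantom(seed = 13)
  rec <- measure_ff(ph$dixon, ph$labels,
                    covariates = data.frame(age = 50, male = 1,
                                            bmi = 24, active = 0))
  expect_setequal(names(rec), c("subject", "muscle", "side", "mean_ff_pct",
                                "n_voxels", "n_invalid", "crop",
                                "age", "male", "bmi", "active"))
  expect_equal(nrow(rec), 8)
  bt <- bilateral_table(rec)
  expect_equal(nrow(bt), 4)
  p <- rec[rec$muscle == "P", ]
  expect_equal(bt$ff_pct[bt$muscle == "P"],
               mean(p$mean_ff_pct))
  expect_true(all(c("age", "male") %in% names(bt)))
})
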