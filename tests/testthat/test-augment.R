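test_that("augmentation plan sizes match the study combinatorics", {
  ids18 <- sprintf("T%02d", 1:18)
  lp <- linear_plan(ids18)
  np <- nonlinear_plan(ids18)
  expect_equal(nrow(lp), 180)
  expect_equal(nrow(np), 306)
  expect_equal(nrow(augment_plan(ids18)), 486)
  expect_equal(nrow(linear_plan("a")), 10)
  expect_equal(nrow(linear_plan("a", linear_augment_spec(angles = numeric(0)))), 2)
  expect_equal(nrow(nonlinear_plan(c("a", "b"))), 2)
  expect_equal(nrow(nonlinear_plan(c("a", "b", "c"))), 6)
  expect_error(nonlinear_plan("a"), "two")
  # nonlinear records reference ordered pairs of distinct subjects
  expect_true(all(np$source != np$partner))
  expect_equal(anyDuplicated(np[, c("source", "partner")]), 0)
})

test_that("no augmentation record can reference a validation subject", {
  plan <- augment_plan(c("a", "b", "c"))
  expect_silent(assert_no_leakage(plan, c("x", "y")))
  expect_error(assert_no_leakage(plan, c("b")), "b")
  # structurally, for every CV fold of a plan built on its training ids
  cv <- mc_cv_plan(10, 3, 4, seed = 2)
  for (f in cv$folds) {
    p <- augment_plan(f$train)
    expect_silent(assert_no_leakage(p, f$val))
  }
})

test_that("flip is an involution that transfers voxels between sides", {
  ph <- fast_phantom(seed = 21)
  once <- apply_linear(ph$dixon, ph$labels, flip = TRUE, angle = 0)
  twice <- apply_linear(once$dixon, once$labels, flip = TRUE, angle = 0)
  expect_identical(twice$dixon$in_phase, ph$dixon$in_phase)
  expect_identical(twice$labels$labels, ph$labels$labels)
  # a phantom with only P_L maps to only P_R with the same voxel count
  only_left <- ph$labels$labels
  only_left[!only_left %in% 1L] <- 0L
  lm <- label_map(only_left, ph$labels$geometry)
  fl <- apply_linear(ph$dixon, lm, flip = TRUE, angle = 0)
  expect_equal(sum(fl$labels$labels == 2L), sum(only_left == 1L))
  expect_equal(sum(fl$labels$labels == 1L), 0)
})

test_that("rotating +5 then -5 degrees returns near the original image", {
  # band-limit the piecewise-constant phantom (as acquisition blur would)
  # so the interpolation error of the two resamplings is representative
  ph <- fast_phantom(seed = 22, noise_sd = 0)
  sm <- function(a) ldq:::.gaussian_smooth3_cpp(a, c(1, 1, 0.7))
  dv <- dixon_volume(sm(ph$dixon$in_phase), sm(ph$dixon$water),
                     sm(ph$dixon$fat), ph$dixon$geometry, "a")
  r1 <- apply_linear(dv, ph$labels, flip = FALSE, angle = 5)
  r2 <- apply_linear(r1$dixon, r1$labels, flip = FALSE, angle = -5)
  rng <- diff(range(dv$in_phase))
  mad <- mean(abs(r2$dixon$in_phase - dv$in_phase))
  expect_lt(mad, 0.02 * rng)
  expect_error(apply_linear(ph$dixon, ph$labels, angle = 7), "not in")
})

test_that("early-stopped pairwise registration yields intermediate anatomies", {
  a <- fast_phantom(seed = 31, noise_sd = 0.01)
  b <- fast_phantom(seed = 32, noise_sd = 0.01)
  # moving = fixed: output stays close to the input
  same <- synthesize_deformed(a, a$dixon,
                              registration_params(iterations = 30, samples = 512))
  rng <- diff(range(a$dixon$in_phase))
  expect_lt(mean(abs(same$dixon$in_phase - a$dixon$in_phase)), 0.01 * rng)
  # two different phantoms: similarity to the fixed image increases, and the
  # output differs from both inputs (a virtual anatomy)
  out <- synthesize_deformed(a, b$dixon,
                             registration_params(iterations = 60, samples = 512))
  expect_gt(out$ncc, ncc(a$dixon, b$dixon))
  expect_gt(mean(abs(out$dixon$in_phase - a$dixon$in_phase)), 0)
  expect_gt(mean(abs(out$dixon$in_phase - b$dixon$in_phase)), 0)
  # labels remain in the valid code set and each muscle stays connected
  expect_true(all(unique(as.vector(out$labels$labels)) %in% 0:8))
  for (code in 1:8) {
    bin <- out$labels$labels == code
    expect_equal(ldq:::.n_components3_cpp(bin), 1)
  }
})
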