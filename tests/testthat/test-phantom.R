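test_that("noiseless phantom satisfies the two-compartment construction", {
  ph <- fast_phantom(seed = 4, noise_sd = 0)
  # in-phase = water + fat voxel-wise, exactly
  expect_equal(max(abs(ph$dixon$in_phase - (ph$dixon$water + ph$dixon$fat))), 0)
  # measured mean FF equals the generative FF for every muscle, even with
  # the default nonzero deformation (analytic rasterisation)
  ffm <- ff_map(ph$dixon)
  for (i in seq_len(nrow(ph$truth))) {
    m <- mean_ff(ffm, ph$labels, ph$truth$code[i])
    expect_equal(as.numeric(m), 100 * ph$truth$ff[i], tolerance = 1e-9)
  }
})

test_that("an FF-zero muscle has a zero fat channel inside its mask", {
  ff0 <- c(P_L = 0, P_R = 0.15, I_L = 0.115, I_R = 0.115, QL_L = 0.145,
           QL_R = 0.145, ESM_L = 0.22, ESM_R = 0.22)
  ph <- generate_phantom(phantom_spec(muscle_ff = ff0, noise_sd = 0))
  expect_equal(max(ph$dixon$fat[ph$labels$labels == 1L]), 0)
})

test_that("phantoms are bit-identical under a fixed seed", {
  a <- fast_phantom(seed = 9)
  b <- fast_phantom(seed = 9)
  expect_identical(a$dixon$in_phase, b$dixon$in_phase)
  expect_identical(a$labels$labels, b$labels$labels)
  c <- fast_phantom(seed = 10)
  expect_false(identical(a$dixon$in_phase, c$dixon$in_phase))
})

test_that("overlapping muscle tubes are rejected", {
  bad <- phantom_muscle_layout()
  bad$cx[2] <- bad$cx[1] + 2
  expect_error(phantom_spec(muscles = bad), "overlap")
})

test_that("displacement fields respect the amplitude bound", {
  g <- geometry(c(32, 32, 16), c(2, 2, 3))
  set.seed(5)
  u <- ldq:::.random_displacement(g, 3, 12)
  mag <- sqrt(u[[1]]^2 + u[[2]]^2 + u[[3]]^2)
  expect_lte(max(mag), 3 + 1e-9)
  expect_gt(max(mag), 2)  # the bound is attained after rescaling
})

test_that("epimuscular fat shell is background-labelled high-fat tissue", {
  ph <- generate_phantom(phantom_spec(epimuscular_shell = TRUE, noise_sd = 0,
                                      deformation_amplitude = 0))
  ph0 <- generate_phantom(phantom_spec(epimuscular_shell = FALSE, noise_sd = 0,
                                       deformation_amplitude = 0))
  ffm <- ff_map(ph$dixon)
  shell <- which(ph$dixon$fat != ph0$dixon$fat)
  expect_gt(length(shell), 0)
  expect_true(all(ph$labels$labels[shell] == 0L))
  expect_equal(unique(round(ffm$ff[shell], 6)), 0.85)
  # muscle FF measurements are untouched by the shell
  expect_equal(as.numeric(mean_ff(ffm, ph$labels, 7)),
               as.numeric(mean_ff(ff_map(ph0$dixon), ph0$labels, 7)))
})

test_that("cohort generative model reduces to the intercept when effects vanish", {
  eff <- data.frame(muscle = c("P", "I", "QL", "ESM"),
                    intercept = c(0.15, 0.11, 0.14, 0.22),
                    b_age = 0, b_sex = 0, b_bmi = 0, b_active = 0)
  cs <- cohort_spec(n_subjects = 5, effects = eff, residual_sd = 0, seed = 3)
  co <- generate_cohort(cs, images = FALSE)
  for (m in eff$muscle)
    expect_true(all(co$truth$ff[co$truth$muscle == m] ==
                      eff$intercept[eff$muscle == m]))
})

test_that("cohort tables are deterministic and activity shifts FF as specified", {
  cs <- cohort_spec(n_subjects = 200, seed = 7, residual_sd = 0.02)
  a <- generate_cohort(cs, images = FALSE)
  b <- generate_cohort(cs, images = FALSE)
  expect_identical(a$truth, b$truth)
  # Monte-Carlo check of the activity effect on psoas (clipping negligible):
  # group difference approx b_active within 3 SE across seeds
  diffs <- vapply(1:5, function(s) {
    co <- generate_cohort(cohort_spec(n_subjects = 200, seed = s,
                                      residual_sd = 0.02), images = FALSE)
    tt <- co$truth[co$truth$muscle == "P" & co$truth$side == "L", ]
    # adjust for covariate imbalance via linear model
    unname(coef(lm(ff ~ I(age - 40) + male + I(bmi - 25) + active, tt))["active"])
  }, numeric(1))
  se <- sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs) - (-0.035)), 3 * max(se, 1e-4))
})
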