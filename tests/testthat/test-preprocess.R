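test_that("in-plane downsampling reproduces the acquisition geometry arithmetic", {
  g <- geometry(c(8, 8, 4), c(0.47, 0.47, 1.95))
  out <- downsample_inplane(array(1, c(8, 8, 4)), g, 2, "image")
  expect_equal(out$geom$spacing, c(0.94, 0.94, 1.95))
  expect_equal(prod(g$shape) / prod(out$geom$shape), 4)  # four-fold reduction
  expect_true(all(out$grid == 1))                        # constant stays constant
  expect_error(downsample_inplane(array(1, c(8, 8, 4)), g, 0), ">= 1")
})

test_that("block averaging and label block-mode behave as specified", {
  g <- geometry(c(4, 4, 1), c(1, 1, 1))
  img <- array(0, c(4, 4, 1))
  img[1:2, 1:2, 1] <- c(1, 2, 3, 4)
  out <- downsample_inplane(img, g, 2, "image")
  expect_equal(out$grid[1, 1, 1], 2.5)
  lab <- array(0L, c(4, 4, 1))
  lab[1:2, 1:2, 1] <- c(5L, 5L, 7L, 7L)   # tie -> lowest code
  outl <- downsample_inplane(lab, g, 2, "label")
  expect_equal(outl$grid[1, 1, 1], 5L)
  lab[1:2, 1:2, 1] <- c(7L, 7L, 7L, 2L)
  outl <- downsample_inplane(lab, g, 2, "label")
  expect_equal(outl$grid[1, 1, 1], 7L)
  # odd shape: trailing row/column cropped with a message
  expect_message(downsample_inplane(array(1, c(5, 5, 2)),
                                    geometry(c(5, 5, 2), c(1, 1, 1)), 2, "image"),
                 "cropping")
})

test_that("downsampling commutes with FF computation on piecewise-constant phantoms", {
  ph <- generate_phantom(phantom_spec(noise_sd = 0, deformation_amplitude = 0))
  g <- ph$dixon$geometry
  ff_then_ds <- downsample_inplane(ff_map(ph$dixon)$ff, g, 2, "image")$grid
  w <- downsample_inplane(ph$dixon$water, g, 2, "image")
  f <- downsample_inplane(ph$dixon$fat, g, 2, "image")
  ds_then_ff <- ff_map(dixon_volume(w$grid + f$grid, w$grid, f$grid, w$geom))$ff
  # compare on blocks that were FF-constant before downsampling (interior
  # blocks of a single tissue); elsewhere the ratio of block means differs
  # from the block mean of ratios
  lab_ds <- downsample_inplane(ph$labels$labels, g, 2, "label")
  interior <- ldq:::.block_downsample_image_cpp((ph$labels$labels == 1) + 0, 2) == 1
  expect_gt(sum(interior), 50)
  expect_lt(max(abs(ff_then_ds[interior] - ds_then_ff[interior])), 1e-6)
})

test_that("rigid registration recovers known transforms across seeds", {
  ph <- fast_phantom(seed = 41, noise_sd = 0.01)
  # moving = fixed: near-identity
  tr0 <- rigid_register(ph$dixon, ph$dixon,
                        registration_params(iterations = 60, samples = 512))
  expect_lt(max(abs(tr0$rotation_deg)), 0.1)
  expect_lt(max(abs(tr0$t)), 0.1)
  shift_ok <- rot_ok <- logical(0)
  shift <- rigid_transform(c(0, 0, 0), c(4, 0, 0))
  moved_s <- resample_dixon(ph$dixon, shift)
  rot <- rigid_transform(c(0, 0, 5), c(0, 0, 0),
                         ldq:::.geom_center(ph$dixon$geometry))
  moved_r <- resample_dixon(ph$dixon, rot)
  for (seed in 1:10) {
    p <- registration_params(iterations = 100, samples = 1024, seed = seed)
    tr <- rigid_register(moved_s, ph$dixon, p)
    shift_ok <- c(shift_ok, abs(tr$t[1] - (-4)) < 0.5 &&
                    max(abs(tr$t[2:3])) < 0.5)
    tr <- rigid_register(moved_r, ph$dixon, p)
    rot_ok <- c(rot_ok, abs(tr$rotation_deg[3] - (-5)) < 0.5)
  }
  expect_true(all(shift_ok))
  expect_true(all(rot_ok))
})

test_that("registration improves NCC and composing with the inverse is identity", {
  tr <- rigid_transform(c(3, -2, 10), c(5, -4, 2), c(10, 20, 30))
  inv <- invert_transform(tr)
  comp <- inv$A %*% tr$A
  expect_lt(max(abs(comp - diag(3))), 1e-6)
  expect_error(rigid_register(
    fast_phantom(1)$dixon,
    generate_phantom(phantom_spec(geom = geometry(c(8, 8, 8), c(1, 1, 1),
                                                  origin = c(1e4, 1e4, 1e4))))$dixon),
    "overlap")
})

test_that("homogenise aligns a pre-shifted duplicate onto the reference grid", {
  # acquisition-resolution in-plane sampling (0.47 mm), where the factor-2
  # downsampling is actually applied; muscle cross-sections are then many
  # voxels wide and block-mode label counts are stable
  g <- geometry(c(272, 272, 8), c(0.47, 0.47, 3))
  ph <- generate_phantom(phantom_spec(geom = g, seed = 43, noise_sd = 0), "a")
  shifted <- resample_dixon(ph$dixon, rigid_transform(c(0, 0, 0), c(4, 2, 0)))
  shifted$subject_id <- "S43shift"
  lab <- ph$labels
  h <- homogenise(list(ph$dixon, shifted), list(lab, lab),
                  reference_id = "a", factor = 2,
                  params = registration_params(iterations = 100, samples = 1024))
  expect_equal(format(h$volumes[[1]]$geometry), format(h$volumes[[2]]$geometry))
  expect_equal(h$geometry$spacing[1:2], c(0.94, 0.94))
  rng <- diff(range(h$volumes[[1]]$in_phase))
  expect_lt(mean(abs(h$volumes[[1]]$in_phase - h$volumes[[2]]$in_phase)),
            0.02 * rng)
  # label counts preserved within 5% under NN resampling (after the 4x
  # voxel-count reduction of the in-plane downsampling)
  for (code in c(1L, 7L)) {
    n_ref <- sum(ph$labels$labels == code)
    n_out <- sum(h$labels[[2]]$labels == code)
    expect_lt(abs(n_out - n_ref / 4) / (n_ref / 4), 0.05)
  }
  # single volume: a downsampled copy of itself
  ph2 <- fast_phantom(seed = 44, noise_sd = 0)
  h1 <- homogenise(list(ph2$dixon), factor = 2)
  ds <- downsample_inplane(ph2$dixon$in_phase, ph2$dixon$geometry, 2, "image")
  expect_equal(h1$volumes[[1]]$in_phase, ds$grid)
})
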