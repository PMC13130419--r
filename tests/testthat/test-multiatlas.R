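test_that("majority-vote fusion matches the exhaustive per-voxel vote oracle", {
  set.seed(8)
  g <- geometry(c(8, 8, 8), c(1, 1, 1))
  maps <- lapply(1:5, function(i) {
    lab <- array(sample(0:8, 512, replace = TRUE, prob = c(10, rep(1, 8))),
                 c(8, 8, 8))
    storage.mode(lab) <- "integer"
    label_map(lab, g)
  })
  fused <- fuse_majority(maps)
  flat <- sapply(maps, function(m) as.vector(m$labels))
  oracle <- apply(flat, 1, function(v) {
    counts <- table(factor(v[v != 0], levels = 1:8))
    cand <- which(counts > 5 / 2)
    if (length(cand) == 0) return(0L)
    best <- cand[counts[cand] == max(counts[cand])]
    as.integer(min(best))
  })
  expect_equal(as.vector(fused$labels), oracle)
})

test_that("fusion respects the strict-majority rule at the margin", {
  g <- geometry(c(2, 2, 2), c(1, 1, 1))
  mk <- function(code) {
    lab <- array(0L, c(2, 2, 2)); lab[1, 1, 1] <- as.integer(code)
    label_map(lab, g)
  }
  # 3 of 5 maps agree -> the code wins
  fused <- fuse_majority(list(mk(4), mk(4), mk(4), mk(0), mk(0)))
  expect_equal(fused$labels[1, 1, 1], 4L)
  # 2 of 5 only -> background
  fused <- fuse_majority(list(mk(4), mk(4), mk(0), mk(0), mk(0)))
  expect_equal(fused$labels[1, 1, 1], 0L)
  # degenerate fusion k = 1 returns the single map
  expect_equal(fuse_majority(list(mk(7)))$labels, mk(7)$labels)
})

test_that("post-processing removes high-FF voxels, fills holes and is idempotent", {
  ph <- fast_phantom(seed = 51, noise_sd = 0)
  # dilate the P_L mask into the subcutaneous ring by relabeling ring voxels
  lab <- ph$labels$labels
  ffm <- ff_map(ph$dixon)
  ring <- !is.na(ffm$ff) & abs(ffm$ff - 0.9) < 1e-9
  ring_idx <- which(ring)[1:50]
  lab[ring_idx] <- 1L
  # poke a 1-voxel hole inside P_L
  interior <- which(lab == 1L & !ring)
  mid <- interior[length(interior) %/% 2]
  lab[mid] <- 0L
  dirty <- label_map(lab, ph$labels$geometry)
  clean <- postprocess(dirty, ph$dixon)
  expect_true(all(clean$labels[ring_idx] == 0L))   # ring voxels removed
  expect_equal(clean$labels[[mid]], 1L)            # hole filled
  # interior (low-FF) voxels intact
  keep <- setdiff(which(ph$labels$labels == 1L), mid)
  expect_true(all(clean$labels[keep] == 1L))
  # idempotent
  twice <- postprocess(clean, ph$dixon)
  expect_identical(twice$labels, clean$labels)
})

test_that("atlas ranking puts a near-identical atlas first with NCC ~ 1", {
  target <- fast_phantom(seed = 61, noise_sd = 0.01)
  twin <- fast_phantom(seed = 61, noise_sd = 0.01)
  twin$dixon$subject_id <- "twin"
  others <- lapply(c(64, 65), function(s) {
    p <- fast_phantom(seed = s, noise_sd = 0.01, deformation = 5)
    p$dixon$subject_id <- paste0("far", s)
    p
  })
  lib <- atlas_library(c(list(twin$dixon), lapply(others, function(p) p$dixon)),
                       c(list(twin$labels), lapply(others, function(p) p$labels)))
  cfg <- fusion_config(k = 1, reg_params = registration_params(iterations = 40,
                                                               samples = 512))
  rk <- rank_atlases(target$dixon, lib, cfg)
  expect_equal(rk$id[1], "twin")
  expect_gt(rk$ncc[1], 0.99)
  expect_setequal(rk$id, lib$ids)  # a permutation of the surviving ids
})

test_that("a library of copies of the target segments it almost perfectly", {
  target <- fast_phantom(seed = 71, noise_sd = 0.005)
  lib_vols <- list(); lib_labs <- list()
  for (i in 1:6) {
    cp <- fast_phantom(seed = 71, noise_sd = 0.005)
    cp$dixon$subject_id <- paste0("copy", i)
    lib_vols[[i]] <- cp$dixon; lib_labs[[i]] <- cp$labels
  }
  lib <- atlas_library(lib_vols, lib_labs)
  cfg <- fusion_config(k = 5, reg_params = registration_params(iterations = 30,
                                                               samples = 512),
                       bspline_iterations = 30)
  pred <- segment_multiatlas(target$dixon, lib, cfg)
  for (code in 1:8) expect_gte(dice(pred, target$labels, code), 0.99)
})
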