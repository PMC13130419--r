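#' Registration parameters
#'
#' Contract for the intensity-based registration engine: normalised
#' cross-correlation similarity, optimised by a stochastic gradient method
#' with decaying gain (the adaptive stochastic gradient descent family),
#' with a Gaussian pyramid. Desk-scale defaults (150 iterations per level,
#' 1024 samples, pyramid 4/2/1) suit the 64 x 64 x 32 phantom grids;
#' full-resolution clinical volumes use 2000 iterations, 2048 samples and a
#' pyramid of 8/4/2/1 (see `full_scale = TRUE`).
#'
#' @param iterations Optimiser iterations per pyramid level (>= 1).
#' @param samples Random voxel samples per iteration (>= 1).
#' @param pyramid Integer downsampling factors, coarse to fine.
#' @param step Initial gain in scaled parameter units (mm / degrees).
#' @param bspline_spacing Control-point spacing in mm for deformable stages.
#' @param seed Seed for the stochastic sampler.
#' @param full_scale If `TRUE`, return the full-resolution defaults.
#' @return An object of class `registration_params`.
#' @export
registration_params <- function(iterations = 150, samples = 1024,
                                pyramid = c(4, 2, 1), step = 1.0,
                                bspline_spacing = 40, seed = 42L,
                                full_scale = FALSE) {
  if (full_scale) {
    iterations <- 2000; samples <- 2048; pyramid <- c(8, 4, 2, 1)
  }
  if (iterations < 1 || samples < 1) stop("iterations and samples must be >= 1")
  structure(list(metric = "ncc", optimiser = "asgd",
                 iterations = as.integer(iterations),
                 samples = as.integer(samples),
                 pyramid = as.integer(pyramid), step = step,
                 bspline_spacing = bspline_spacing, seed = as.integer(seed)),
            class = "registration_params")
}

# ---- transform objects -----------------------------------------------------

.identity_transform <- function(center = c(0, 0, 0)) {
  structure(list(kind = "identity", A = diag(3), t = c(0, 0, 0),
                 center = center, rotation_deg = c(0, 0, 0), bspline = NULL),
            class = "ldq_transform")
}

.rigid_matrix <- function(rot_deg) {
  r <- rot_deg * pi / 180
  cx <- cos(r[1]); sx <- sin(r[1])
  cy <- cos(r[2]); sy <- sin(r[2])
  cz <- cos(r[3]); sz <- sin(r[3])
  Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
  Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
  Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
  Rz %*% Ry %*% Rx
}

#' Build a rigid transform
#'
#' Maps fixed-space world points to moving-space points:
#' `y = R (x - c) + c + t` with `R = Rz Ry Rx` from the degree angles.
#'
#' @param rotation_deg Rotations about the x, y, z axes in degrees.
#' @param translation Translation in mm.
#' @param center Rotation centre in world mm.
#' @return An `ldq_transform`.
#' @export
rigid_transform <- function(rotation_deg = c(0, 0, 0),
                            translation = c(0, 0, 0),
                            center = c(0, 0, 0)) {
  structure(list(kind = "rigid", A = .rigid_matrix(rotation_deg),
                 t = as.numeric(translation), center = as.numeric(center),
                 rotation_deg = as.numeric(rotation_deg), bspline = NULL),
            class = "ldq_transform")
}

#' Invert a rigid (or general linear) transform
#'
#' Composing a transform with its inverse yields identity within numerical
#' tolerance.
#'
#' @param tr An `ldq_transform` without a deformable component.
#' @return The inverse `ldq_transform`.
#' @export
invert_transform <- function(tr) {
  if (!is.null(tr$bspline)) stop("deformable transforms are not invertible in closed form")
  Ai <- solve(tr$A)
  structure(list(kind = tr$kind, A = Ai, t = -as.vector(Ai %*% tr$t),
                 center = tr$center, rotation_deg = NULL, bspline = NULL),
            class = "ldq_transform")
}

#' @export
print.ldq_transform <- function(x, ...) {
  cat(sprintf("ldq transform (%s): t = (%.3f, %.3f, %.3f) mm%s\n", x$kind,
              x$t[1], x$t[2], x$t[3],
              if (!is.null(x$bspline)) " + B-spline FFD" else ""))
  invisible(x)
}

# apply a transform to resample a grid defined on moving geometry onto a
# fixed geometry lattice
.resample_grid <- function(grid, mgeom, fgeom, tr, label_mode = FALSE) {
  bs <- tr$bspline
  out <- .resample_cpp(grid, mgeom$spacing, mgeom$origin,
                       fgeom$shape, fgeom$spacing, fgeom$origin,
                       tr$A, tr$t, tr$center,
                       if (is.null(bs)) NULL else bs$coef,
                       if (is.null(bs)) NULL else bs$ctrl_dim,
                       if (is.null(bs)) NULL else bs$ctrl_origin,
                       if (is.null(bs)) NULL else bs$ctrl_spacing,
                       label_mode)
  out
}

#' Resample a Dixon volume through a transform
#'
#' All three channels are resampled with trilinear interpolation onto the
#' fixed geometry through the same transform.
#'
#' @param vol A [dixon_volume()] (the moving image).
#' @param tr An `ldq_transform` mapping fixed-space points into `vol`'s space.
#' @param fgeom Target (fixed) geometry; defaults to `vol$geometry`.
#' @return A resampled [dixon_volume()].
#' @export
resample_dixon <- function(vol, tr, fgeom = vol$geometry) {
  dixon_volume(.resample_grid(vol$in_phase, vol$geometry, fgeom, tr),
               .resample_grid(vol$water, vol$geometry, fgeom, tr),
               .resample_grid(vol$fat, vol$geometry, fgeom, tr),
               fgeom, vol$subject_id)
}

#' Resample a label map through a transform (nearest neighbour)
#'
#' @param lmap A [label_map()] (moving labels).
#' @param tr An `ldq_transform`.
#' @param fgeom Target geometry.
#' @return A resampled [label_map()].
#' @export
resample_label_map <- function(lmap, tr, fgeom = lmap$geometry) {
  lab <- .resample_grid(lmap$labels + 0, lmap$geometry, fgeom, tr, label_mode = TRUE)
  lab <- round(lab)
  storage.mode(lab) <- "integer"
  dim(lab) <- fgeom$shape
  label_map(lab, fgeom, lmap$code_table)
}

# Gaussian pyramid level: smooth (sigma = factor/2 voxels) and stride-sample
.pyramid_level <- function(arr, geom, factor) {
  if (factor <= 1) return(list(arr = arr, geom = geom))
  sm <- .gaussian_smooth3_cpp(arr, rep(factor / 2, 3))
  ix <- seq(1, geom$shape[1], by = factor)
  iy <- seq(1, geom$shape[2], by = factor)
  iz <- seq(1, geom$shape[3], by = factor)
  sub <- sm[ix, iy, iz, drop = FALSE]
  list(arr = sub,
       geom = geometry(dim(sub), geom$spacing * factor, geom$origin))
}

.check_overlap <- function(fgeom, mgeom) {
  lo_f <- fgeom$origin; hi_f <- fgeom$origin + (fgeom$shape - 1) * fgeom$spacing
  lo_m <- mgeom$origin; hi_m <- mgeom$origin + (mgeom$shape - 1) * mgeom$spacing
  if (any(hi_f < lo_m) || any(hi_m < lo_f))
    stop("registration failure: volumes do not overlap in physical space")
}

# shared pyramid driver for rigid ("rigid") and affine ("affine") stages
.register_linear <- function(moving_arr, mgeom, fixed_arr, fgeom, params,
                             mode = c("rigid", "affine"), init = NULL) {
  mode <- match.arg(mode)
  .check_overlap(fgeom, mgeom)
  center <- .geom_center(fgeom)
  p <- init
  if (is.null(p)) p <- if (mode == "rigid") rep(0, 6) else c(as.vector(t(diag(3))), 0, 0, 0)
  lv <- 0
  for (f in sort(params$pyramid, decreasing = TRUE)) {
    fx <- .pyramid_level(fixed_arr, fgeom, f)
    mv <- .pyramid_level(moving_arr, mgeom, f)
    res <- .register_linear_cpp(fx$arr, fx$geom$spacing, fx$geom$origin,
                                mv$arr, mv$geom$spacing, mv$geom$origin,
                                mode, p, center,
                                params$iterations, params$samples,
                                params$step / (2^lv), params$seed + lv)
    p <- res$params
    lv <- lv + 1
  }
  list(params = p, ncc = res$ncc, center = center)
}

#' Rigid registration of two Dixon volumes
#'
#' Registers the moving in-phase channel to the fixed in-phase channel by
#' maximising sampled NCC over rotations and translations with a decaying
#' stochastic gradient scheme and a Gaussian pyramid. The returned transform
#' maps fixed-space points into the moving volume's space (the convention
#' used by [resample_dixon()]). Backend-agnostic contract: any optimiser
#' honouring [registration_params()] is acceptable.
#'
#' @param moving,fixed [dixon_volume()] objects overlapping in space.
#' @param params A [registration_params()].
#' @return An `ldq_transform` with attributes `ncc` (final similarity).
#' @export
rigid_register <- function(moving, fixed, params = registration_params()) {
  res <- .register_linear(moving$in_phase, moving$geometry,
                          fixed$in_phase, fixed$geometry, params, "rigid")
  p <- res$params
  tr <- rigid_transform(p[1:3], p[4:6], res$center)
  attr(tr, "ncc") <- res$ncc
  tr
}

#' Affine registration (linear stage of the multi-atlas pipeline)
#'
#' @inheritParams rigid_register
#' @param init Optional initial 12-parameter vector (row-major 3x3 + t).
#' @return An `ldq_transform` of kind "affine" with attribute `ncc`.
#' @export
affine_register <- function(moving, fixed, params = registration_params(),
                            init = NULL) {
  res <- .register_linear(moving$in_phase, moving$geometry,
                          fixed$in_phase, fixed$geometry, params, "affine", init)
  p <- res$params
  tr <- structure(list(kind = "affine",
                       A = matrix(p[1:9], 3, 3, byrow = TRUE),
                       t = p[10:12], center = res$center,
                       rotation_deg = NULL, bspline = NULL),
                  class = "ldq_transform")
  attr(tr, "ncc") <- res$ncc
  tr
}

#' Deformable (B-spline) refinement of a linear registration
#'
#' Adds a cubic B-spline free-form deformation on the fixed domain,
#' composed as `y = Linear(x + u(x))`, optimised by stochastic gradient
#' ascent on sampled NCC. With `iterations` kept small the optimisation
#' stops early, which is exploited by the nonlinear augmentation to create
#' intermediate "virtual" anatomies.
#'
#' @param moving,fixed [dixon_volume()] objects.
#' @param init Linear `ldq_transform` to refine (default identity).
#' @param params A [registration_params()]; `bspline_spacing` sets the
#'   control-point spacing in mm.
#' @param iterations Override for the deformable iteration count.
#' @return An `ldq_transform` carrying the linear part plus `bspline`.
#' @export
bspline_register <- function(moving, fixed, init = NULL,
                             params = registration_params(),
                             iterations = params$iterations) {
  fgeom <- fixed$geometry; mgeom <- moving$geometry
  .check_overlap(fgeom, mgeom)
  if (is.null(init)) init <- .identity_transform(.geom_center(fgeom))
  sp <- params$bspline_spacing
  ext <- (fgeom$shape - 1) * fgeom$spacing
  nctrl <- pmax(ceiling(ext / sp) + 3L, 4L)
  corig <- fgeom$origin - sp
  coef <- numeric(prod(nctrl) * 3)
  res <- .register_bspline_cpp(fixed$in_phase, fgeom$spacing, fgeom$origin,
                               moving$in_phase, mgeom$spacing, mgeom$origin,
                               init$A, init$t, init$center,
                               as.integer(nctrl), corig, rep(sp, 3), coef,
                               as.integer(iterations), params$samples,
                               params$step, params$seed)
  out <- init
  out$kind <- paste0(init$kind, "+bspline")
  out$bspline <- list(coef = res$coef, ctrl_dim = as.integer(nctrl),
                      ctrl_origin = corig, ctrl_spacing = rep(sp, 3))
  out
}

#' Normalised cross-correlation between two volumes on the same lattice
#'
#' @param a,b 3D arrays (or [dixon_volume()]s, whose in-phase is used) with
#'   identical dimensions.
#' @return NCC in `[-1, 1]`.
#' @export
ncc <- function(a, b) {
  if (inherits(a, "dixon_volume")) a <- a$in_phase
  if (inherits(b, "dixon_volume")) b <- b$in_phase
  .ncc_cpp(as.vector(a), as.vector(b))
}

# ---- downsampling ----------------------------------------------------------

#' In-plane downsampling of a grid
#'
#' Reduces the in-plane (x, y) resolution by an integer factor, leaving the
#' slice axis untouched: images are block-averaged (anti-aliased), label
#' maps take the per-block mode with ties broken toward the lowest code.
#' A factor of 2 yields a four-fold reduction in voxel count.
#'
#' @param grid 3D array (image intensities or integer labels).
#' @param geom The grid's [geometry()].
#' @param factor Integer >= 1.
#' @param mode `"image"` (block average) or `"label"` (block mode).
#' @return List with `grid` and updated `geom`. If the in-plane shape is not
#'   divisible by `factor`, trailing rows/columns are cropped with a message.
#' @export
downsample_inplane <- function(grid, geom, factor = 2L,
                               mode = c("image", "label")) {
  mode <- match.arg(mode)
  factor <- as.integer(factor)
  if (factor < 1) stop("factor must be >= 1")
  if (factor == 1) return(list(grid = grid, geom = geom))
  nx <- geom$shape[1]; ny <- geom$shape[2]
  cx <- nx %% factor; cy <- ny %% factor
  if (cx > 0 || cy > 0) {
    message(sprintf("cropping %d trailing column(s) and %d row(s) for factor %d",
                    cx, cy, factor))
    grid <- grid[seq_len(nx - cx), seq_len(ny - cy), , drop = FALSE]
  }
  if (mode == "image") {
    out <- .block_downsample_image_cpp(grid + 0, factor)
  } else {
    g <- grid
    storage.mode(g) <- "integer"
    out <- .block_downsample_label_cpp(g, factor)
  }
  newgeom <- geometry(dim(out),
                      geom$spacing * c(factor, factor, 1),
                      geom$origin + c((factor - 1) / 2 * geom$spacing[1:2], 0))
  list(grid = out, geom = newgeom)
}

#' Homogenise a dataset of Dixon volumes
#'
#' Rigid-registers every volume's in-phase channel to a reference subject,
#' resamples all channels (and labels, nearest-neighbour) onto the
#' reference lattice, then downsamples in-plane, producing a geometrically
#' identical dataset.
#'
#' @param volumes List of [dixon_volume()]s.
#' @param labels Optional list of [label_map()]s aligned with `volumes`.
#' @param reference_id Subject id of the reference; default first by sorted
#'   id.
#' @param factor In-plane downsampling factor (default 2).
#' @param params [registration_params()].
#' @return List with `volumes`, `labels`, `geometry`, `transforms` and an
#'   `ncc_log` data.frame (similarity to the reference before/after).
#' @export
homogenise <- function(volumes, labels = NULL, reference_id = NULL,
                       factor = 2L, params = registration_params()) {
  if (length(volumes) < 1) stop("need at least one volume")
  ids <- vapply(volumes, function(v) v$subject_id, "")
  if (is.null(reference_id)) reference_id <- sort(ids)[1]
  ridx <- match(reference_id, ids)
  if (is.na(ridx)) stop("reference_id not found: ", reference_id)
  ref <- volumes[[ridx]]
  out_v <- vector("list", length(volumes))
  out_l <- if (is.null(labels)) NULL else vector("list", length(volumes))
  trs <- vector("list", length(volumes))
  log <- data.frame(subject = ids, ncc_before = NA_real_, ncc_after = NA_real_)
  for (i in seq_along(volumes)) {
    v <- volumes[[i]]
    if (i == ridx) {
      tr <- .identity_transform(.geom_center(ref$geometry))
      rv <- v
    } else {
      msg <- .geometry_mismatch(v$geometry, ref$geometry)
      log$ncc_before[i] <- if (is.null(msg)) ncc(v, ref) else NA_real_
      tr <- tryCatch(rigid_register(v, ref, params),
                     error = function(e) stop("registration failed for subject ",
                                              v$subject_id, ": ", conditionMessage(e)))
      rv <- resample_dixon(v, tr, ref$geometry)
      log$ncc_after[i] <- ncc(rv, ref)
    }
    trs[[i]] <- tr
    ds_ip <- downsample_inplane(rv$in_phase, ref$geometry, factor, "image")
    ds_w <- downsample_inplane(rv$water, ref$geometry, factor, "image")
    ds_f <- downsample_inplane(rv$fat, ref$geometry, factor, "image")
    out_v[[i]] <- dixon_volume(ds_ip$grid, ds_w$grid, ds_f$grid, ds_ip$geom,
                               v$subject_id)
    if (!is.null(labels)) {
      rl <- if (i == ridx) labels[[i]] else resample_label_map(labels[[i]], tr, ref$geometry)
      ds_l <- downsample_inplane(rl$labels, ref$geometry, factor, "label")
      out_l[[i]] <- label_map(ds_l$grid, ds_l$geom, labels[[i]]$code_table)
    }
  }
  list(volumes = out_v, labels = out_l, geometry = out_v[[1]]$geometry,
       transforms = trs, ncc_log = log)
}
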