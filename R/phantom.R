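#' Default muscle tube layout for the Dixon phantom
#'
#' Eight elliptical tubes emulating the bilateral lumbar compartments on a
#' 128 x 128 x 96 mm field of view: psoas (P) anterior-paramedian, iliacus
#' (I) lateral with reduced axial coverage (emulating limited inferior
#' psoas/iliacus coverage in some scans), quadratus lumborum (QL) small and
#' postero-lateral, erector spinae + multifidus (ESM) large and posterior.
#' Offsets are mm from the in-plane volume centre (x positive to the right),
#' and `z0`/`z1` are inclusive 1-based slice bounds on the default 32-slice
#' grid, expressed as fractions of the slice count so the layout scales.
#'
#' @return data.frame with one row per muscle compartment.
#' @export
phantom_muscle_layout <- function() {
  data.frame(
    name = c("P_L", "P_R", "I_L", "I_R", "QL_L", "QL_R", "ESM_L", "ESM_R"),
    code = 1:8,
    muscle = rep(c("P", "I", "QL", "ESM"), each = 2),
    side = rep(c("L", "R"), 4),
    cx = c(-14, 14, -30, 30, -22, 22, -9, 9),
    cy = c(-10, -10, -4, -4, 12, 12, 24, 24),
    rx = c(7, 7, 7, 7, 5.5, 5.5, 8, 8),
    ry = c(7, 7, 6, 6, 5.5, 5.5, 7, 7),
    z0_frac = c(0.08, 0.08, 0.08, 0.08, 0.26, 0.26, 0.08, 0.08),
    z1_frac = c(0.94, 0.94, 0.52, 0.52, 0.85, 0.85, 0.94, 0.94),
    stringsAsFactors = FALSE
  )
}

#' Background anatomy of the Dixon phantom
#'
#' Unlabelled structures that shape the in-phase image the way a lumbar
#' field of view does: a vertebral body (low proton density) on the
#' midline, the aorta left of the midline and the larger inferior vena
#' cava right of it (water-dominant blood pool). The vessels break the
#' phantom's left/right mirror symmetry, as in real anatomy.
#'
#' @return data.frame with one row per structure (mm offsets/radii,
#'   proton density, fat fraction, axial extent fractions).
#' @export
phantom_background_anatomy <- function() {
  data.frame(
    name = c("vertebra", "aorta", "ivc"),
    cx = c(0, -5, 6), cy = c(7, -2, -2),
    rx = c(8, 3, 4), ry = c(6, 3, 4),
    density = c(0.4, 0.9, 0.9),
    ff = c(0.3, 0.02, 0.02),
    z0_frac = c(0, 0, 0), z1_frac = c(1, 1, 1),
    stringsAsFactors = FALSE
  )
}

#' Specification of a synthetic Dixon phantom
#'
#' The phantom is a two-compartment (water/fat) tissue model: inside each
#' structure the proton density is split as fat = FF * density and
#' water = (1 - FF) * density. Muscles have unit proton density; the
#' surrounding interstitial body tissue has lower density (0.7) so that
#' muscle boundaries are visible on the in-phase image; a subcutaneous ring
#' of FF 0.9 surrounds the body; outside the body is air (zero signal).
#' Anatomy is deformed by a smooth random displacement field evaluated
#' identically for all channels and labels.
#'
#' @param geom Geometry; default 64 x 64 x 32 voxels at 2 x 2 x 3 mm.
#' @param muscle_ff Named numeric of length 8 (per label code, order
#'   [MUSCLE_CODES]): generative fat fraction in each muscle, in `[0, 1]`.
#' @param muscles Tube layout as in [phantom_muscle_layout()].
#' @param subcut_ff Fat fraction of the subcutaneous ring (default 0.9).
#' @param subcut_thickness Ring thickness in mm.
#' @param body_semiaxes In-plane semi-axes (mm) of the body ellipse.
#' @param body_ff,body_density FF and proton density of interstitial tissue.
#' @param background Unlabelled anatomy (vertebra and great vessels), see
#'   [phantom_background_anatomy()]; may be an empty data.frame.
#' @param epimuscular_shell If `TRUE`, add a thin high-fat shell posterior to
#'   each ESM tube, labelled background (fat external to the epimyseal
#'   border, to test its exclusion from muscle masks).
#' @param noise_sd SD of zero-mean Gaussian noise added independently to the
#'   water and fat channels (intensity units; tissue density is 1).
#' @param deformation_amplitude Maximum displacement magnitude in mm.
#' @param deformation_sigma Smoothing length (mm) of the random field.
#' @param seed Integer seed; phantoms are deterministic given the spec.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(geom = geometry(c(64, 64, 32), c(2, 2, 3)),
                         muscle_ff = c(P_L = 0.15, P_R = 0.15, I_L = 0.115,
                                       I_R = 0.115, QL_L = 0.145, QL_R = 0.145,
                                       ESM_L = 0.22, ESM_R = 0.22),
                         muscles = phantom_muscle_layout(),
                         subcut_ff = 0.9, subcut_thickness = 6,
                         body_semiaxes = c(52, 44),
                         body_ff = 0.3, body_density = 0.7,
                         background = phantom_background_anatomy(),
                         epimuscular_shell = FALSE,
                         noise_sd = 0.02,
                         deformation_amplitude = 3, deformation_sigma = 12,
                         seed = 1L) {
  if (any(muscle_ff < 0) || any(muscle_ff > 1)) stop("muscle_ff must lie in [0, 1]")
  if (subcut_ff < 0 || subcut_ff > 1 || body_ff < 0 || body_ff > 1)
    stop("fat fractions must lie in [0, 1]")
  if (any(muscles$rx <= 0) || any(muscles$ry <= 0)) stop("tube radii must be > 0")
  if (deformation_amplitude < 0 || noise_sd < 0) stop("negative noise/deformation")
  # pairwise disjointness (conservative bound: centre distance vs summed
  # largest semi-axes; tubes only collide if they overlap in-plane)
  n <- nrow(muscles)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- sqrt((muscles$cx[i] - muscles$cx[j])^2 + (muscles$cy[i] - muscles$cy[j])^2)
    if (d <= max(muscles$rx[i], muscles$ry[i]) + max(muscles$rx[j], muscles$ry[j]))
      stop(sprintf("muscle tubes overlap: %s and %s", muscles$name[i], muscles$name[j]))
  }
  # vessels must not intrude into muscle compartments
  for (i in seq_len(nrow(background))) for (j in seq_len(n)) {
    d <- sqrt((background$cx[i] - muscles$cx[j])^2 +
                (background$cy[i] - muscles$cy[j])^2)
    if (background$name[i] != "vertebra" &&
        d <= max(background$rx[i], background$ry[i]) +
        max(muscles$rx[j], muscles$ry[j]))
      stop(sprintf("background structure %s overlaps muscle %s",
                   background$name[i], muscles$name[j]))
  }
  structure(list(geom = geom, muscle_ff = muscle_ff, muscles = muscles,
                 background = background,
                 subcut_ff = subcut_ff, subcut_thickness = subcut_thickness,
                 body_semiaxes = body_semiaxes, body_ff = body_ff,
                 body_density = body_density,
                 epimuscular_shell = epimuscular_shell,
                 noise_sd = noise_sd,
                 deformation_amplitude = deformation_amplitude,
                 deformation_sigma = deformation_sigma,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# smooth random displacement field with max magnitude = amplitude (mm);
# returns list of three arrays (mm displacement per axis), or NULL if amp 0
.random_displacement <- function(geom, amplitude, sigma_mm) {
  if (amplitude <= 0) return(NULL)
  sig_vox <- sigma_mm / geom$spacing
  u <- lapply(1:3, function(a) {
    f <- array(rnorm(prod(geom$shape)), dim = geom$shape)
    .gaussian_smooth3_cpp(f, sig_vox)
  })
  mag <- sqrt(u[[1]]^2 + u[[2]]^2 + u[[3]]^2)
  mmax <- max(mag)
  if (mmax > 0) u <- lapply(u, function(x) x * (amplitude / mmax))
  u
}

#' Generate a synthetic Dixon phantom
#'
#' Rasterises the analytic anatomy of a [phantom_spec()] under its smooth
#' random displacement field: each voxel centre `x` is classified by the
#' anatomy evaluated at `x + u(x)`, so channels and labels are deformed by
#' the identical field and remain exactly consistent with each other (the
#' in-phase = water + fat identity holds voxel-wise, and with zero noise the
#' mean FF inside every ground-truth mask equals the generative FF to
#' machine precision at any deformation amplitude).
#'
#' @param spec A [phantom_spec()].
#' @param subject_id Subject identifier for the returned volume.
#' @return List with `dixon` ([dixon_volume()]), `labels` ([label_map()]) and
#'   `truth` (data.frame of generative FF per label).
#' @export
generate_phantom <- function(spec, subject_id = "phantom") {
  geom <- spec$geom
  set.seed(spec$seed)
  u <- .random_displacement(geom, spec$deformation_amplitude, spec$deformation_sigma)
  ctr <- .geom_center(geom)
  xs <- .axis_coords(geom, 1) - ctr[1]
  ys <- .axis_coords(geom, 2) - ctr[2]
  zs <- .axis_coords(geom, 3)
  nx <- geom$shape[1]; ny <- geom$shape[2]; nz <- geom$shape[3]
  qx <- array(rep(xs, times = ny * nz), dim = geom$shape)
  qy <- array(rep(rep(ys, each = nx), times = nz), dim = geom$shape)
  qz <- array(rep(zs, each = nx * ny), dim = geom$shape)
  if (!is.null(u)) {
    qx <- qx + u[[1]]; qy <- qy + u[[2]]; qz <- qz + u[[3]]
  }
  zmin <- min(zs); zext <- max(zs) - zmin
  lab <- array(0L, dim = geom$shape)
  ff <- array(0, dim = geom$shape)
  density <- array(0, dim = geom$shape)
  # body ellipse and subcutaneous ring
  ax <- spec$body_semiaxes[1]; ay <- spec$body_semiaxes[2]
  r2_out <- (qx / ax)^2 + (qy / ay)^2
  r2_in <- (qx / (ax - spec$subcut_thickness))^2 + (qy / (ay - spec$subcut_thickness))^2
  body <- r2_out <= 1
  ring <- body & r2_in > 1
  interior <- body & !ring
  density[interior] <- spec$body_density
  ff[interior] <- spec$body_ff
  density[ring] <- 1
  ff[ring] <- spec$subcut_ff
  # unlabelled background anatomy (vertebra, vessels), before muscles
  if (!is.null(spec$background) && nrow(spec$background) > 0) {
    for (i in seq_len(nrow(spec$background))) {
      s <- spec$background[i, ]
      z0 <- zmin + s$z0_frac * zext; z1 <- zmin + s$z1_frac * zext
      inside <- ((qx - s$cx) / s$rx)^2 + ((qy - s$cy) / s$ry)^2 <= 1 &
        qz >= z0 & qz <= z1 & interior
      density[inside] <- s$density
      ff[inside] <- s$ff
    }
  }
  # epimuscular fat shell posterior to ESM, before muscles so tubes win
  if (isTRUE(spec$epimuscular_shell)) {
    for (i in which(spec$muscles$muscle == "ESM")) {
      m <- spec$muscles[i, ]
      z0 <- zmin + m$z0_frac * zext; z1 <- zmin + m$z1_frac * zext
      shell <- ((qx - m$cx) / (m$rx + 3))^2 + ((qy - m$cy) / (m$ry + 3))^2 <= 1 &
        qy > m$cy & qz >= z0 & qz <= z1 & interior
      density[shell] <- 1
      ff[shell] <- 0.85
    }
  }
  for (i in seq_len(nrow(spec$muscles))) {
    m <- spec$muscles[i, ]
    z0 <- zmin + m$z0_frac * zext; z1 <- zmin + m$z1_frac * zext
    inside <- ((qx - m$cx) / m$rx)^2 + ((qy - m$cy) / m$ry)^2 <= 1 &
      qz >= z0 & qz <= z1 & body
    lab[inside] <- m$code
    density[inside] <- 1
    ff[inside] <- spec$muscle_ff[[m$code]]
  }
  water <- (1 - ff) * density
  fat <- ff * density
  if (spec$noise_sd > 0) {
    water <- pmax(water + rnorm(length(water), 0, spec$noise_sd), 0)
    fat <- pmax(fat + rnorm(length(fat), 0, spec$noise_sd), 0)
    dim(water) <- dim(fat) <- geom$shape
  }
  ip <- water + fat
  truth <- data.frame(spec$muscles[, c("name", "code", "muscle", "side")],
                      ff = as.numeric(spec$muscle_ff[spec$muscles$code]),
                      stringsAsFactors = FALSE)
  list(dixon = dixon_volume(ip, water, fat, geom, subject_id),
       labels = label_map(lab, geom),
       truth = truth)
}

#' Specification of a synthetic cohort with covariate-linked fat fractions
#'
#' Per subject and muscle, the generative FF follows the linear model
#' `FF = intercept + b_age (age - 40) + b_sex male + b_bmi (BMI - 25) +
#' b_active active + e`, `e ~ N(0, residual_sd^2)`, clipped to
#' `[0.01, 0.95]`; both sides of a muscle share the FF up to an optional
#' Gaussian asymmetry term. Default intercepts and effect directions emulate
#' a healthy adult cohort: higher FF with age, lower in the physically
#' active, ESM highest and iliacus lowest.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param effects data.frame with columns `muscle` (P, I, QL, ESM),
#'   `intercept`, `b_age` (per year), `b_sex` (male vs female), `b_bmi`
#'   (per kg/m^2), `b_active` (active vs sedentary), all on the FF scale.
#' @param residual_sd SD of the subject-level FF residual.
#' @param asymmetry_sd SD of the per-side FF deviation (default 0).
#' @param age_range,sex_prob_male,bmi_mean,bmi_sd,active_prob Covariate
#'   distributions (uniform age in years; Bernoulli male; Gaussian BMI
#'   truncated to `[16, 45]`; Bernoulli activity group).
#' @param phantom Template [phantom_spec()] supplying geometry, noise and
#'   deformation settings for the subject images.
#' @param seed Integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 173,
                        effects = data.frame(
                          muscle = c("P", "I", "QL", "ESM"),
                          intercept = c(0.155, 0.116, 0.143, 0.218),
                          b_age = c(0.0010, 0.0012, 0.0022, 0.0025),
                          b_sex = c(-0.005, -0.006, -0.010, -0.060),
                          b_bmi = c(0.0020, 0.0025, 0.0020, 0.0020),
                          b_active = c(-0.035, -0.035, -0.030, -0.050)),
                        residual_sd = 0.02, asymmetry_sd = 0,
                        age_range = c(20, 70), sex_prob_male = 0.47,
                        bmi_mean = 25.7, bmi_sd = 5.6, active_prob = 0.5,
                        phantom = phantom_spec(),
                        seed = 1L) {
  if (n_subjects < 1) stop("n_subjects must be >= 1")
  stopifnot(all(c("muscle", "intercept", "b_age", "b_sex", "b_bmi", "b_active")
                %in% names(effects)))
  structure(list(n_subjects = as.integer(n_subjects), effects = effects,
                 residual_sd = residual_sd, asymmetry_sd = asymmetry_sd,
                 age_range = age_range, sex_prob_male = sex_prob_male,
                 bmi_mean = bmi_mean, bmi_sd = bmi_sd,
                 active_prob = active_prob, phantom = phantom,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic Dixon cohort
#'
#' Draws covariates and generative per-muscle fat fractions for every
#' subject, then (optionally) rasterises one Dixon phantom per subject with
#' its own deformation/noise realisation. Deterministic given the spec seed.
#'
#' @param spec A [cohort_spec()].
#' @param images If `FALSE`, only the covariate/FF ground-truth table is
#'   generated (fast path for statistical simulations).
#' @return List with `truth` (data.frame: subject, age, sex, bmi, active,
#'   muscle, side, ff) and `subjects` (list of `generate_phantom()` outputs,
#'   or `NULL` when `images = FALSE`).
#' @export
generate_cohort <- function(spec, images = TRUE) {
  set.seed(spec$seed)
  n <- spec$n_subjects
  age <- runif(n, spec$age_range[1], spec$age_range[2])
  male <- rbinom(n, 1, spec$sex_prob_male)
  bmi <- pmin(pmax(rnorm(n, spec$bmi_mean, spec$bmi_sd), 16), 45)
  active <- rbinom(n, 1, spec$active_prob)
  eff <- spec$effects
  layout <- spec$phantom$muscles
  rows <- list()
  ff_mat <- matrix(NA_real_, nrow = n, ncol = nrow(layout),
                   dimnames = list(NULL, layout$name))
  for (s in seq_len(n)) {
    eps <- rnorm(nrow(eff), 0, spec$residual_sd)
    for (m in seq_len(nrow(eff))) {
      base <- eff$intercept[m] + eff$b_age[m] * (age[s] - 40) +
        eff$b_sex[m] * male[s] + eff$b_bmi[m] * (bmi[s] - 25) +
        eff$b_active[m] * active[s] + eps[m]
      for (side in c("L", "R")) {
        asym <- if (spec$asymmetry_sd > 0) rnorm(1, 0, spec$asymmetry_sd) else 0
        ffv <- min(max(base + asym, 0.01), 0.95)
        nm <- paste0(eff$muscle[m], "_", side)
        ff_mat[s, nm] <- ffv
        rows[[length(rows) + 1]] <- data.frame(
          subject = sprintf("S%03d", s), age = age[s], male = male[s],
          bmi = bmi[s], active = active[s], muscle = eff$muscle[m],
          side = side, ff = ffv, stringsAsFactors = FALSE)
      }
    }
  }
  truth <- do.call(rbind, rows)
  subjects <- NULL
  if (images) {
    subjects <- vector("list", n)
    for (s in seq_len(n)) {
      ps <- spec$phantom
      ps$muscle_ff <- setNames(ff_mat[s, layout$name], layout$name)
      ps$seed <- spec$seed + s
      subjects[[s]] <- generate_phantom(ps, subject_id = sprintf("S%03d", s))
    }
  }
  list(truth = truth, subjects = subjects)
}
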