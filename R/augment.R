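#' Linear augmentation specification
#'
#' Mirror flips across the medial-lateral (x) axis combined with small
#' in-plane rotations about the slice axis. The identity rotation is part of
#' the variant set, so each training image yields
#' `2 * length(angles)` linear records (10 with the default angles).
#'
#' @param angles Rotation angles in degrees; must be unique and contain 0.
#'   An empty vector is overridden to `{0}` (flip-only augmentation).
#' @param rotation_axis Axis of rotation: `"z"` (slice axis, in-plane
#'   rotation, the default) or `"x"` (medial-lateral).
#' @return An object of class `linear_augment_spec`.
#' @export
linear_augment_spec <- function(angles = c(0, 5, -5, 10, -10),
                                rotation_axis = c("z", "x")) {
  rotation_axis <- match.arg(rotation_axis)
  if (length(angles) == 0) angles <- 0
  if (anyDuplicated(angles)) stop("angles must be unique")
  if (!0 %in% angles) stop("the identity rotation (0 degrees) must be included")
  structure(list(angles = as.numeric(angles), flip_axis = "x",
                 rotation_axis = rotation_axis),
            class = "linear_augment_spec")
}

#' Plan the linear augmentation of a training set
#'
#' One record per (subject, flip, angle) combination:
#' `|angles| * 2` records per subject (10 by default, so 18 training ids
#' yield 180 linear records).
#'
#' @param train_ids Character vector of training subject ids (>= 1).
#' @param spec A [linear_augment_spec()].
#' @return data.frame (class `augment_plan`) with columns `source`, `kind`,
#'   `flip`, `angle`, `partner`.
#' @export
linear_plan <- function(train_ids, spec = linear_augment_spec()) {
  if (length(train_ids) < 1) stop("need at least one training id")
  grid <- expand.grid(angle = spec$angles, flip = c(FALSE, TRUE),
                      source = train_ids, stringsAsFactors = FALSE)
  plan <- data.frame(source = grid$source, kind = "linear", flip = grid$flip,
                     angle = grid$angle, partner = NA_character_,
                     stringsAsFactors = FALSE)
  class(plan) <- c("augment_plan", "data.frame")
  plan
}

#' Plan the nonlinear (virtual-anatomy) augmentation
#'
#' One record per ordered pair of distinct training subjects: the moving
#' subject is deformed toward the fixed partner by early-stopped B-spline
#' registration, producing `n (n - 1)` records (306 for 18 training ids).
#'
#' @param train_ids Character vector of >= 2 training subject ids.
#' @return data.frame (class `augment_plan`) with `source` (moving),
#'   `partner` (fixed) and `kind = "nonlinear"`.
#' @export
nonlinear_plan <- function(train_ids) {
  if (length(train_ids) < 2) stop("nonlinear augmentation needs at least two training ids")
  grid <- expand.grid(partner = train_ids, source = train_ids,
                      stringsAsFactors = FALSE)
  grid <- grid[grid$source != grid$partner, ]
  plan <- data.frame(source = grid$source, kind = "nonlinear", flip = FALSE,
                     angle = NA_real_, partner = grid$partner,
                     stringsAsFactors = FALSE)
  rownames(plan) <- NULL
  class(plan) <- c("augment_plan", "data.frame")
  plan
}

#' Full augmentation plan for a training fold
#'
#' @param train_ids Training subject ids.
#' @param linear_spec A [linear_augment_spec()].
#' @param nonlinear Include the nonlinear pairwise records.
#' @return Combined `augment_plan` (10 n linear + n (n - 1) nonlinear
#'   records with defaults; 486 for n = 18).
#' @export
augment_plan <- function(train_ids, linear_spec = linear_augment_spec(),
                         nonlinear = TRUE) {
  plan <- linear_plan(train_ids, linear_spec)
  if (nonlinear && length(train_ids) >= 2)
    plan <- rbind(plan, nonlinear_plan(train_ids))
  class(plan) <- c("augment_plan", "data.frame")
  plan
}

#' Assert that an augmentation plan is free of validation leakage
#'
#' No record may reference a validation subject, directly (source) or
#' indirectly (nonlinear partner).
#'
#' @param plan An `augment_plan`.
#' @param val_ids Validation subject ids.
#' @return Invisibly `TRUE`; errors listing offending ids otherwise.
#' @export
assert_no_leakage <- function(plan, val_ids) {
  bad <- union(intersect(plan$source, val_ids),
               intersect(plan$partner[!is.na(plan$partner)], val_ids))
  if (length(bad) > 0)
    stop("augmentation plan references validation subject(s): ",
         paste(sort(bad), collapse = ", "))
  invisible(TRUE)
}

#' Apply a linear augmentation (flip and/or rotation) to a volume and labels
#'
#' The flip mirrors the grid across the medial-lateral (x) axis and swaps
#' left/right label codes (P_L <-> P_R etc.), so flipping twice is the
#' identity. The rotation is about the image centre (in-plane about the
#' slice axis by default); images are interpolated trilinearly and labels
#' nearest-neighbour.
#'
#' @param vol A [dixon_volume()].
#' @param lmap A [label_map()] (or `NULL`).
#' @param flip Logical.
#' @param angle Rotation angle in degrees; must belong to `spec$angles`.
#' @param spec A [linear_augment_spec()].
#' @return List with `dixon` and `labels`.
#' @export
apply_linear <- function(vol, lmap = NULL, flip = FALSE, angle = 0,
                         spec = linear_augment_spec()) {
  if (!angle %in% spec$angles)
    stop("angle ", angle, " is not in the augmentation spec")
  out_v <- vol
  out_l <- lmap
  if (flip) {
    fl <- function(a) a[rev(seq_len(dim(a)[1])), , , drop = FALSE]
    out_v <- dixon_volume(fl(out_v$in_phase), fl(out_v$water), fl(out_v$fat),
                          out_v$geometry, out_v$subject_id)
    if (!is.null(out_l)) {
      lab <- fl(out_l$labels)
      nz <- lab != 0L
      lab[nz] <- .code_swap[lab[nz]]
      dim(lab) <- out_l$geometry$shape
      out_l <- label_map(lab, out_l$geometry, out_l$code_table)
    }
  }
  if (angle != 0) {
    ctr <- .geom_center(vol$geometry)
    rot <- if (spec$rotation_axis == "z") c(0, 0, angle) else c(angle, 0, 0)
    tr <- rigid_transform(rot, c(0, 0, 0), ctr)
    out_v <- resample_dixon(out_v, tr, vol$geometry)
    if (!is.null(out_l)) out_l <- resample_label_map(out_l, tr, vol$geometry)
  }
  list(dixon = out_v, labels = out_l)
}

#' Mirror-augment a training dataset
#'
#' Appends the medial-lateral flip (with left/right label codes swapped) of
#' every subject, doubling the training set. This is the linear
#' augmentation arm restricted to the flip — the desk-scale default, since
#' it both doubles the optimisation steps per epoch and presents every
#' structure's mirror image under the swapped label.
#'
#' @param dataset List of subjects (`dixon` + `labels`).
#' @return The dataset with `_flip` copies appended.
#' @export
mirror_augment <- function(dataset) {
  flipped <- lapply(dataset, function(s) {
    a <- apply_linear(s$dixon, s$labels, flip = TRUE, angle = 0)
    a$dixon$subject_id <- paste0(s$dixon$subject_id, "_flip")
    list(dixon = a$dixon, labels = a$labels)
  })
  c(dataset, flipped)
}

#' Expand a training dataset by the full linear augmentation
#'
#' Materialises every record of [linear_plan()] for the dataset's subjects:
#' {unflipped, flipped} x rotation angles, i.e. 10 variants per subject with
#' the default spec (the originals count as the identity variant and are
#' kept once).
#'
#' @param dataset List of subjects (`dixon` + `labels`).
#' @param spec A [linear_augment_spec()].
#' @return The expanded dataset (length `10 n` with defaults).
#' @export
linear_augment <- function(dataset, spec = linear_augment_spec()) {
  ids <- .dataset_ids(dataset)
  plan <- linear_plan(ids, spec)
  .apply_augment_plan(dataset, plan, spec, NULL)
}

#' Synthesize a virtual anatomy by early-stopped B-spline registration
#'
#' Registers the moving image toward the fixed image with a deliberately
#' small iteration budget, so the optimisation stops before convergence and
#' the warped output is an intermediate anatomy between the two subjects.
#' The same transform is applied to the moving labels (nearest-neighbour).
#'
#' @param moving List with `dixon` and `labels` (as from
#'   [generate_phantom()]), homogenised to the fixed geometry.
#' @param fixed_vol The fixed [dixon_volume()].
#' @param params [registration_params()]; `iterations` is the early-stop
#'   budget.
#' @return List with `dixon`, `labels` and `ncc` (NCC of output vs fixed).
#' @export
synthesize_deformed <- function(moving, fixed_vol,
                                params = registration_params(iterations = 60)) {
  stopifnot_same_geometry(moving$dixon$geometry, fixed_vol$geometry,
                          what = "moving and fixed volumes")
  tr <- tryCatch(
    bspline_register(moving$dixon, fixed_vol, params = params),
    error = function(e) stop("nonlinear augmentation failed for pair (",
                             moving$dixon$subject_id, ", ", fixed_vol$subject_id,
                             "): ", conditionMessage(e)))
  out_v <- resample_dixon(moving$dixon, tr, fixed_vol$geometry)
  out_l <- if (is.null(moving$labels)) NULL else
    resample_label_map(moving$labels, tr, fixed_vol$geometry)
  list(dixon = out_v, labels = out_l, ncc = ncc(out_v, fixed_vol))
}
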