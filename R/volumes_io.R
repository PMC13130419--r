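#' Construct a Dixon volume (in-phase / water / fat triplet)
#'
#' Bundles the three co-registered Dixon channels with their shared geometry.
#' All intensities must be non-negative and the three grids must share one
#' geometry; in-phase is physically water + fat (checked loosely, not
#' enforced, since vendor reconstructions may deviate).
#'
#' @param in_phase,water,fat 3D numeric arrays of identical dimensions.
#' @param geom An [geometry()] object matching the array dimensions.
#' @param subject_id Character scalar identifying the subject.
#' @return An object of class `dixon_volume` with fields `in_phase`, `water`,
#'   `fat`, `geometry`, `subject_id`.
#' @export
dixon_volume <- function(in_phase, water, fat, geom, subject_id = "subject") {
  for (ch in list(in_phase, water, fat)) {
    if (length(dim(ch)) != 3) stop("Dixon channels must be 3D arrays")
    if (!all(dim(ch) == geom$shape)) stop("channel dimensions do not match geometry")
    if (any(ch < 0)) stop("Dixon intensities must be non-negative")
  }
  if (!all(dim(water) == dim(in_phase)) || !all(dim(fat) == dim(in_phase)))
    stop("the three channels must have identical dimensions")
  structure(list(in_phase = in_phase, water = water, fat = fat,
                 geometry = geom, subject_id = as.character(subject_id)),
            class = "dixon_volume")
}

#' @export
print.dixon_volume <- function(x, ...) {
  cat(sprintf("Dixon volume '%s': %s\n", x$subject_id, format(x$geometry)))
  invisible(x)
}

#' Construct a multi-muscle label map
#'
#' Integer-coded segmentation sharing a Dixon volume's geometry. Code 0 is
#' background; the fixed muscle codes are [MUSCLE_CODES] (psoas, iliacus,
#' quadratus lumborum, erector spinae + multifidus; left before right).
#'
#' @param labels 3D integer array of codes.
#' @param geom An [geometry()] object matching the array dimensions.
#' @param code_table Named integer vector mapping structure names to codes;
#'   every nonzero code present in `labels` must appear here.
#' @return An object of class `label_map`.
#' @export
label_map <- function(labels, geom, code_table = MUSCLE_CODES) {
  if (length(dim(labels)) != 3) stop("labels must be a 3D array")
  if (!all(dim(labels) == geom$shape)) stop("label dimensions do not match geometry")
  storage.mode(labels) <- "integer"
  present <- setdiff(unique(as.vector(labels)), 0L)
  unknown <- setdiff(present, as.integer(code_table))
  if (length(unknown) > 0)
    stop("label codes not in code_table: ", paste(unknown, collapse = ", "))
  structure(list(labels = labels, geometry = geom, code_table = code_table),
            class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  present <- intersect(x$code_table, unique(as.vector(x$labels)))
  cat(sprintf("Label map: %s; %d/%d structures present\n",
              format(x$geometry), length(present), length(x$code_table)))
  invisible(x)
}

# ---- NIfTI I/O -------------------------------------------------------------

# Write a 3D array with its geometry as NIfTI-1. The sform carries
# diag(spacing) with the origin in the translation column.
.write_nifti <- function(arr, geom, path) {
  img <- RNifti::asNifti(arr)
  mat <- rbind(cbind(diag(geom$spacing), geom$origin), c(0, 0, 0, 1))
  img <- RNifti::`sform<-`(img, structure(mat, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

.read_nifti <- function(path) {
  if (!file.exists(path)) stop("cannot read NIfTI file (not found): ", path)
  img <- RNifti::readNifti(path)
  xf <- RNifti::xform(img)
  spacing <- abs(diag(xf[1:3, 1:3, drop = FALSE]))
  origin <- xf[1:3, 4]
  # the stored sform is axis-aligned with positive diagonal by construction
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr))
  list(arr = arr, geom = geometry(dim(arr), spacing, origin))
}

#' Read a Dixon triplet from three NIfTI files
#'
#' The three channels must share shape and spacing/origin within 1e-4 mm;
#' otherwise a geometry-mismatch error naming the offending axis is raised.
#'
#' @param in_phase_path,water_path,fat_path Paths to NIfTI-1 files
#'   (.nii or .nii.gz).
#' @param subject_id Character scalar.
#' @return A [dixon_volume()].
#' @export
read_dixon <- function(in_phase_path, water_path, fat_path, subject_id = "subject") {
  ip <- .read_nifti(in_phase_path)
  w <- .read_nifti(water_path)
  f <- .read_nifti(fat_path)
  stopifnot_same_geometry(ip$geom, w$geom, what = "in-phase and water channels")
  stopifnot_same_geometry(ip$geom, f$geom, what = "in-phase and fat channels")
  dixon_volume(ip$arr, w$arr, f$arr, ip$geom, subject_id)
}

#' Write a scalar volume or label map as NIfTI-1
#'
#' For a [label_map()] the integer grid is written and the code table is
#' serialized as a JSON sidecar (`<path>.codes.json`).
#'
#' @param x A 3D array, [dixon_volume()] channel, or [label_map()].
#' @param geom Geometry (ignored when `x` is a `label_map`).
#' @param path Output path (.nii or .nii.gz).
#' @return The path, invisibly.
#' @export
write_volume <- function(x, geom = NULL, path) {
  if (inherits(x, "label_map")) {
    .write_nifti(x$labels, x$geometry, path)
    jsonlite::write_json(as.list(x$code_table), paste0(path, ".codes.json"),
                         auto_unbox = TRUE)
    return(invisible(path))
  }
  if (is.null(geom)) stop("geom is required when writing a plain array")
  .write_nifti(x, geom, path)
}

#' Write a Dixon triplet to a directory
#'
#' @param vol A [dixon_volume()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the three file paths.
#' @export
write_dixon <- function(vol, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(vol$subject_id, "_", c("ip", "water", "fat"), ".nii.gz"))
  .write_nifti(vol$in_phase, vol$geometry, paths[1])
  .write_nifti(vol$water, vol$geometry, paths[2])
  .write_nifti(vol$fat, vol$geometry, paths[3])
  names(paths) <- c("in_phase", "water", "fat")
  paths
}

#' Read a label map written by [write_volume()]
#'
#' @param path NIfTI path; the `<path>.codes.json` sidecar is read if present.
#' @return A [label_map()].
#' @export
read_label_map <- function(path) {
  r <- .read_nifti(path)
  side <- paste0(path, ".codes.json")
  ct <- MUSCLE_CODES
  if (file.exists(side)) {
    lst <- jsonlite::read_json(side)
    ct <- setNames(as.integer(unlist(lst)), names(lst))
  }
  lab <- round(r$arr)
  storage.mode(lab) <- "integer"
  dim(lab) <- r$geom$shape
  label_map(lab, r$geom, ct)
}

# ---- one-hot encoding ------------------------------------------------------

#' One-hot encode a label map
#'
#' Produces a 4D binary stack with one channel per label code plus a leading
#' background channel, so that every voxel has exactly one hot channel.
#'
#' @param lmap A [label_map()].
#' @return 4D 0/1 array of dimension `c(shape, n_codes + 1)`; channel 1 is
#'   background, channel `c + 1` corresponds to code `c` in the code table
#'   order (codes are assumed to be 1..n).
#' @export
onehot_encode <- function(lmap) {
  codes <- sort(as.integer(lmap$code_table))
  if (!identical(codes, seq_along(codes)))
    stop("one-hot encoding expects consecutive codes 1..n")
  n <- length(codes)
  out <- array(0L, dim = c(lmap$geometry$shape, n + 1L))
  flat <- as.vector(lmap$labels)
  nv <- length(flat)
  for (c in 0:n) out[seq_len(nv) + c * nv] <- as.integer(flat == c)
  out
}

#' Decode a one-hot stack back to a label map
#'
#' @param stack 4D array as produced by [onehot_encode()].
#' @param geom Geometry of the output map.
#' @param code_table Code table of the output map.
#' @return A [label_map()].
#' @export
onehot_decode <- function(stack, geom, code_table = MUSCLE_CODES) {
  d <- dim(stack)
  nv <- prod(d[1:3])
  m <- matrix(stack, nrow = nv)
  lab <- max.col(m, ties.method = "first") - 1L
  dim(lab) <- d[1:3]
  label_map(lab, geom, code_table)
}
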