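#' Regular-grid geometry of a volumetric image
#'
#' Describes the sampling lattice shared by all channels of a Dixon triplet
#' and its label maps: voxel counts, voxel spacing in mm, and the world
#' coordinate (mm) of the first voxel centre. Axes are (x, y, z) with z the
#' superior-inferior slice axis and x the left-right (medial-lateral) axis.
#'
#' @param shape Integer vector of length 3, voxel counts per axis (all >= 1).
#' @param spacing Numeric vector of length 3, mm per voxel (all > 0).
#' @param origin Numeric vector of length 3, mm coordinate of voxel (1,1,1).
#' @return An object of class `ldq_geometry`.
#' @examples
#' geometry(c(64, 64, 32), c(2, 2, 3))
#' @export
geometry <- function(shape, spacing, origin = c(0, 0, 0)) {
  shape <- as.integer(shape)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(shape) != 3 || any(is.na(shape)) || any(shape < 1))
    stop("shape must be 3 positive voxel counts")
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive values (mm)")
  if (length(origin) != 3 || any(!is.finite(origin)))
    stop("origin must be 3 finite values (mm)")
  structure(list(shape = shape, spacing = spacing, origin = origin,
                 axes = "x=left-right, y=anterior-posterior, z=superior-inferior"),
            class = "ldq_geometry")
}

#' @export
print.ldq_geometry <- function(x, ...) {
  cat(sprintf("ldq geometry: %d x %d x %d voxels, %.4g x %.4g x %.4g mm, origin (%g, %g, %g)\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$spacing[1], x$spacing[2], x$spacing[3],
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' @export
format.ldq_geometry <- function(x, ...) {
  sprintf("%dx%dx%d @ %.4gx%.4gx%.4g mm", x$shape[1], x$shape[2], x$shape[3],
          x$spacing[1], x$spacing[2], x$spacing[3])
}

# Compare two geometries; returns NULL if equal within tol (mm), otherwise a
# message naming the first offending axis/field.
.geometry_mismatch <- function(a, b, tol = 1e-4) {
  ax <- c("x", "y", "z")
  for (i in 1:3) {
    if (a$shape[i] != b$shape[i])
      return(sprintf("shape differs on %s axis (%d vs %d voxels)", ax[i], a$shape[i], b$shape[i]))
    if (abs(a$spacing[i] - b$spacing[i]) > tol)
      return(sprintf("spacing differs on %s axis (%g vs %g mm)", ax[i], a$spacing[i], b$spacing[i]))
    if (abs(a$origin[i] - b$origin[i]) > tol)
      return(sprintf("origin differs on %s axis (%g vs %g mm)", ax[i], a$origin[i], b$origin[i]))
  }
  NULL
}

#' Check that two geometries agree
#'
#' @param a,b `ldq_geometry` objects.
#' @param tol Tolerance in mm for spacing/origin comparison.
#' @param what Label used in the error message.
#' @return Invisibly `TRUE`; errors with a geometry-mismatch message otherwise.
#' @export
stopifnot_same_geometry <- function(a, b, tol = 1e-4, what = "volumes") {
  msg <- .geometry_mismatch(a, b, tol)
  if (!is.null(msg)) stop("geometry mismatch between ", what, ": ", msg)
  invisible(TRUE)
}

# world coordinates (mm) of all voxel centres along one axis
.axis_coords <- function(geom, axis) {
  geom$origin[axis] + (seq_len(geom$shape[axis]) - 1) * geom$spacing[axis]
}

# centre of the volume in world mm
.geom_center <- function(geom) {
  geom$origin + (geom$shape - 1) / 2 * geom$spacing
}
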