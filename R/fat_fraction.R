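#' Voxel-wise fat-fraction map
#'
#' `FF = fat / (water + fat)` wherever the denominator exceeds a small
#' epsilon; elsewhere (air) the voxel is flagged invalid rather than
#' silently set to 0/0.
#'
#' @param dixon A [dixon_volume()].
#' @param epsilon Validity threshold on water + fat; default
#'   `1e-6 * max(water + fat)`.
#' @return Object of class `ff_map`: `ff` (3D array in `[0, 1]`, `NA` on
#'   invalid voxels), `valid` (logical array), `geometry`.
#' @export
ff_map <- function(dixon, epsilon = NULL) {
  denom <- dixon$water + dixon$fat
  if (is.null(epsilon)) epsilon <- 1e-6 * max(denom)
  valid <- denom > epsilon
  ff <- array(NA_real_, dim = dixon$geometry$shape)
  ff[valid] <- dixon$fat[valid] / denom[valid]
  structure(list(ff = ff, valid = valid, geometry = dixon$geometry),
            class = "ff_map")
}

#' Mean fat fraction within a muscle mask (percent)
#'
#' Arithmetic mean of the FF map over the valid voxels of one label code,
#' expressed in percent, optionally restricted to an inclusive axial slice
#' range (1-based) to compensate for limited axial coverage.
#'
#' @param ffm An [ff_map()].
#' @param lmap A [label_map()] on the same geometry.
#' @param code Label code to measure.
#' @param crop Optional `c(z0, z1)` inclusive slice range.
#' @return Mean FF in percent, with attributes `n_voxels` (valid voxels
#'   averaged) and `n_invalid` (masked voxels excluded as invalid).
#' @export
mean_ff <- function(ffm, lmap, code, crop = NULL) {
  stopifnot_same_geometry(ffm$geometry, lmap$geometry,
                          what = "FF map and label map")
  mask <- lmap$labels == code
  if (!is.null(crop)) {
    nz <- ffm$geometry$shape[3]
    z0 <- max(1L, as.integer(crop[1])); z1 <- min(nz, as.integer(crop[2]))
    if (z1 < z0) stop("empty crop range")
    keep <- array(FALSE, dim = ffm$geometry$shape)
    keep[, , z0:z1] <- TRUE
    mask <- mask & keep
  }
  if (!any(mask))
    stop(sprintf("no voxels for code %d%s", code,
                 if (is.null(crop)) "" else sprintf(" in slices [%d, %d]",
                                                    crop[1], crop[2])))
  vals <- ffm$ff[mask]
  n_invalid <- sum(is.na(vals))
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0)
    stop(sprintf("all voxels for code %d are invalid (no water+fat signal)", code))
  structure(100 * mean(vals), n_voxels = length(vals), n_invalid = n_invalid)
}

#' Per-muscle fat-fraction records for one subject
#'
#' Measures the mean FF of every structure present in the label map and
#' returns one row per muscle and side, in the fixed CSV schema used by the
#' pipeline.
#'
#' @param dixon A [dixon_volume()].
#' @param lmap A [label_map()].
#' @param crop Optional inclusive axial slice range `c(z0, z1)`.
#' @param covariates Optional one-row data.frame (e.g. age, male, bmi,
#'   active) replicated onto each record.
#' @return data.frame with columns subject, muscle, side, mean_ff_pct,
#'   n_voxels, n_invalid, crop.
#' @export
measure_ff <- function(dixon, lmap, crop = NULL, covariates = NULL) {
  ffm <- ff_map(dixon)
  rows <- list()
  for (nm in names(lmap$code_table)) {
    code <- lmap$code_table[[nm]]
    if (!any(lmap$labels == code)) next
    m <- mean_ff(ffm, lmap, code, crop)
    parts <- strsplit(nm, "_")[[1]]
    row <- data.frame(subject = dixon$subject_id,
                      muscle = paste(parts[-length(parts)], collapse = "_"),
                      side = parts[length(parts)],
                      mean_ff_pct = as.numeric(m),
                      n_voxels = attr(m, "n_voxels"),
                      n_invalid = attr(m, "n_invalid"),
                      crop = if (is.null(crop)) "" else paste(crop, collapse = ":"),
                      stringsAsFactors = FALSE)
    rows[[length(rows) + 1]] <- row
  }
  out <- do.call(rbind, rows)
  if (!is.null(covariates)) out <- cbind(out, covariates, row.names = NULL)
  out
}

#' Bilateral (left/right) mean fat fraction
#'
#' Unweighted mean of the two side means (not voxel-weighted), matching the
#' convention of reporting one value per muscle per subject. A
#' voxel-weighted alternative is available via `weighted = TRUE`.
#'
#' @param record_left,record_right One-row data.frames as produced by
#'   [measure_ff()], same subject and muscle, sides L and R.
#' @param weighted If `TRUE`, weight each side by its valid voxel count.
#' @return Bilateral mean FF in percent.
#' @export
bilateral_mean <- function(record_left, record_right, weighted = FALSE) {
  if (record_left$subject != record_right$subject ||
      record_left$muscle != record_right$muscle)
    stop("records must refer to the same subject and muscle")
  if (!(record_left$side == "L" && record_right$side == "R"))
    stop("side mismatch: expected one L and one R record")
  if (weighted) {
    w <- c(record_left$n_voxels, record_right$n_voxels)
    return(sum(c(record_left$mean_ff_pct, record_right$mean_ff_pct) * w) / sum(w))
  }
  (record_left$mean_ff_pct + record_right$mean_ff_pct) / 2
}

#' Collapse per-side FF records to bilateral means
#'
#' @param records data.frame from [measure_ff()] (possibly many subjects).
#' @param weighted Passed to [bilateral_mean()].
#' @return data.frame with one row per subject and muscle (`ff_pct` the
#'   bilateral mean); any extra covariate columns are carried through.
#' @export
bilateral_table <- function(records, weighted = FALSE) {
  keys <- unique(records[, c("subject", "muscle")])
  rows <- list()
  for (i in seq_len(nrow(keys))) {
    sub <- records[records$subject == keys$subject[i] &
                     records$muscle == keys$muscle[i], ]
    l <- sub[sub$side == "L", ]
    r <- sub[sub$side == "R", ]
    if (nrow(l) != 1 || nrow(r) != 1) next
    extra <- setdiff(names(records),
                     c("subject", "muscle", "side", "mean_ff_pct",
                       "n_voxels", "n_invalid", "crop"))
    row <- data.frame(subject = keys$subject[i], muscle = keys$muscle[i],
                      ff_pct = bilateral_mean(l, r, weighted),
                      stringsAsFactors = FALSE)
    if (length(extra) > 0) row <- cbind(row, l[, extra, drop = FALSE],
                                        row.names = NULL)
    rows[[length(rows) + 1]] <- row
  }
  do.call(rbind, rows)
}
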