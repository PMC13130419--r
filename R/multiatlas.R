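#' Atlas library for multi-atlas segmentation
#'
#' @param volumes List of [dixon_volume()]s, homogenised to one geometry.
#' @param labels List of matching [label_map()]s.
#' @return Object of class `atlas_library`.
#' @export
atlas_library <- function(volumes, labels) {
  if (length(volumes) < 1) stop("atlas library must contain at least one atlas")
  if (length(volumes) != length(labels)) stop("volumes and labels differ in length")
  ids <- vapply(volumes, function(v) v$subject_id, "")
  if (anyDuplicated(ids)) stop("atlas ids must be unique")
  for (i in seq_along(volumes)) {
    stopifnot_same_geometry(volumes[[i]]$geometry, volumes[[1]]$geometry,
                            what = "atlases")
    stopifnot_same_geometry(labels[[i]]$geometry, volumes[[i]]$geometry,
                            what = "atlas volume and labels")
  }
  structure(list(volumes = volumes, labels = labels, ids = ids),
            class = "atlas_library")
}

#' Multi-atlas fusion configuration
#'
#' @param k Number of most-similar atlases fused (default 5).
#' @param ff_threshold Soft-tissue mask: labelled voxels whose fat fraction
#'   exceeds this value are removed in post-processing (default 0.80).
#' @param reg_params [registration_params()] for the affine + B-spline
#'   registration of each atlas to the target.
#' @param bspline_iterations Deformable iteration budget per registration.
#' @param fill_holes Apply 3D per-code hole filling after the soft-tissue
#'   mask.
#' @return Object of class `fusion_config`.
#' @export
fusion_config <- function(k = 5L, ff_threshold = 0.80,
                          reg_params = registration_params(iterations = 60,
                                                           samples = 512),
                          bspline_iterations = 120L,
                          fill_holes = TRUE) {
  if (k < 1) stop("k must be >= 1")
  structure(list(k = as.integer(k), metric = "ncc",
                 ff_threshold = ff_threshold, reg_params = reg_params,
                 bspline_iterations = as.integer(bspline_iterations),
                 fill_holes = fill_holes),
            class = "fusion_config")
}

# register every usable atlas to the target; returns per-atlas transform,
# warped volume and NCC (descending), with failures excluded
.register_library <- function(target, library, config, exclude_id = NULL) {
  keep <- which(library$ids != (exclude_id %||% ""))
  res <- list()
  for (i in keep) {
    ok <- tryCatch({
      aff <- affine_register(library$volumes[[i]], target, config$reg_params)
      tr <- bspline_register(library$volumes[[i]], target, init = aff,
                             params = config$reg_params,
                             iterations = config$bspline_iterations)
      warped <- resample_dixon(library$volumes[[i]], tr, target$geometry)
      list(id = library$ids[i], index = i, transform = tr, warped = warped,
           ncc = ncc(warped, target))
    }, error = function(e) {
      warning("atlas ", library$ids[i], " excluded (registration failed): ",
              conditionMessage(e))
      NULL
    })
    if (!is.null(ok)) res[[length(res) + 1]] <- ok
  }
  if (length(res) == 0) stop("all atlas registrations failed")
  nccs <- vapply(res, function(r) r$ncc, numeric(1))
  # descending NCC; ties broken by library id order
  ord <- order(-nccs, vapply(res, function(r) r$index, numeric(1)))
  res[ord]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Rank atlases by post-registration similarity to a target
#'
#' Each atlas is registered (affine then B-spline) to the target and ranked
#' by descending NCC of the warped atlas against the target in-phase image.
#' Atlases whose registration fails are excluded with a warning.
#'
#' @param target A [dixon_volume()].
#' @param library An [atlas_library()].
#' @param config A [fusion_config()].
#' @return data.frame with `id` and `ncc`, in rank order.
#' @export
rank_atlases <- function(target, library, config = fusion_config()) {
  reg <- .register_library(target, library, config)
  data.frame(id = vapply(reg, function(r) r$id, ""),
             ncc = vapply(reg, function(r) r$ncc, numeric(1)),
             stringsAsFactors = FALSE)
}

#' Majority-vote fusion of propagated label maps
#'
#' Per muscle code and voxel, the code is a candidate if strictly more than
#' half of the `k` propagated maps assign it; among multiple candidate
#' codes the highest vote count wins, ties resolving to the lowest code;
#' voxels with no majority become background.
#'
#' @param propagated List of `k >= 1` [label_map()]s on one geometry.
#' @return The fused [label_map()].
#' @export
fuse_majority <- function(propagated) {
  k <- length(propagated)
  if (k < 1) stop("need at least one propagated label map")
  for (p in propagated)
    stopifnot_same_geometry(p$geometry, propagated[[1]]$geometry,
                            what = "propagated labels")
  codes <- sort(as.integer(propagated[[1]]$code_table))
  nv <- prod(propagated[[1]]$geometry$shape)
  counts <- matrix(0L, nrow = nv, ncol = length(codes))
  for (p in propagated) {
    flat <- as.vector(p$labels)
    for (ci in seq_along(codes))
      counts[, ci] <- counts[, ci] + (flat == codes[ci])
  }
  counts[counts <= k / 2] <- 0L
  win <- max.col(counts, ties.method = "first")   # lowest code on ties
  top <- counts[cbind(seq_len(nv), win)]
  lab <- ifelse(top > 0L, codes[win], 0L)
  dim(lab) <- propagated[[1]]$geometry$shape
  storage.mode(lab) <- "integer"
  label_map(lab, propagated[[1]]$geometry, propagated[[1]]$code_table)
}

#' Post-process a fused segmentation
#'
#' Applies a soft-tissue intensity mask (labelled voxels whose fat fraction
#' exceeds the threshold are removed, which strips subcutaneous fat picked
#' up by registration errors) followed by per-code 3D morphological hole
#' filling. Codes are preserved; filling only claims background voxels.
#'
#' @param mask A [label_map()].
#' @param dixon The target [dixon_volume()] (for the FF image).
#' @param config A [fusion_config()].
#' @return The post-processed [label_map()].
#' @export
postprocess <- function(mask, dixon, config = fusion_config()) {
  stopifnot_same_geometry(mask$geometry, dixon$geometry,
                          what = "mask and Dixon volume")
  ffm <- ff_map(dixon)
  lab <- mask$labels
  hot <- !is.na(ffm$ff) & ffm$ff > config$ff_threshold
  lab[lab != 0L & hot] <- 0L
  if (isTRUE(config$fill_holes)) {
    for (code in sort(as.integer(mask$code_table))) {
      bin <- lab == code
      if (!any(bin)) next
      filled <- .fill_holes3_cpp(bin)
      add <- filled & !bin & lab == 0L
      lab[add] <- code
    }
  }
  dim(lab) <- mask$geometry$shape
  storage.mode(lab) <- "integer"
  label_map(lab, mask$geometry, mask$code_table)
}

#' Multi-atlas segmentation of a target volume
#'
#' Registers every atlas to the target, ranks by NCC, propagates the labels
#' of the `k` most similar atlases (nearest-neighbour through the composed
#' affine + B-spline transform), fuses by majority voting and
#' post-processes. When the target's subject id is present in the library
#' it is excluded (leave-one-out).
#'
#' @param target A [dixon_volume()].
#' @param library An [atlas_library()].
#' @param config A [fusion_config()].
#' @return A [label_map()], with attribute `ranking` (the NCC table).
#' @export
segment_multiatlas <- function(target, library, config = fusion_config()) {
  reg <- .register_library(target, library, config,
                           exclude_id = target$subject_id)
  k <- min(config$k, length(reg))
  top <- reg[seq_len(k)]
  propagated <- lapply(top, function(r)
    resample_label_map(library$labels[[r$index]], r$transform, target$geometry))
  fused <- fuse_majority(propagated)
  out <- postprocess(fused, target, config)
  attr(out, "ranking") <- data.frame(
    id = vapply(reg, function(r) r$id, ""),
    ncc = vapply(reg, function(r) r$ncc, numeric(1)),
    used = seq_along(reg) <= k, stringsAsFactors = FALSE)
  out
}
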