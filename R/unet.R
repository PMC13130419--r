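#' 3D U-Net configuration
#'
#' Architecture family: a symmetric encoder-decoder with skip connections.
#' Each encoder level applies two 3x3x3 convolution blocks (convolution,
#' affine-free instance normalisation, leaky ReLU) and a 2x2x2 max pool;
#' the bottleneck applies two blocks; each decoder level upsamples
#' (nearest neighbour), convolves, concatenates the skip features and
#' applies two further blocks; a final 1x1x1 convolution produces one
#' sigmoid channel per label code plus background, trained with binary
#' cross-entropy against the one-hot target stack. Coarser decoder levels
#' carry auxiliary deep-supervision heads (1x1x1, BCE on stride-downsampled
#' targets, loss weights halving per level) used during training only.
#'
#' The full-scale defaults (4 levels, 16 base filters) give a parameter
#' count of the order of a few million; the exact count for any
#' configuration is reported by [build_unet()]. Desk-scale work on
#' 64 x 64 x 32 phantoms uses [desk_unet_config()].
#'
#' @param levels Encoder/decoder depth (>= 1).
#' @param base_filters Filters in the first level (>= 1).
#' @param growth Filter growth factor per level.
#' @param in_channels Input channels (1, the in-phase image).
#' @param out_channels Output channels; must equal number of label codes + 1.
#' @param kernel_size Odd convolution kernel size.
#' @param lr Adam learning rate.
#' @param batch_size Volumes per optimisation step (whole-volume, 1).
#' @param max_epochs Maximum training epochs.
#' @param patience Early-stopping patience in epochs (0 disables).
#' @param seed Seed for weight initialisation and epoch shuffling.
#' @return An object of class `unet_config`.
#' @export
unet_config <- function(levels = 4L, base_filters = 16L, growth = 2L,
                        in_channels = 1L, out_channels = 9L,
                        kernel_size = 3L, lr = 1e-4, batch_size = 1L,
                        max_epochs = 100L, patience = 5L, seed = 1L) {
  if (levels < 1 || base_filters < 1) stop("levels and base_filters must be >= 1")
  if (kernel_size %% 2 != 1) stop("kernel_size must be odd")
  if (lr <= 0) stop("learning rate must be positive")
  structure(list(levels = as.integer(levels),
                 base_filters = as.integer(base_filters),
                 growth = as.integer(growth),
                 in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 kernel_size = as.integer(kernel_size),
                 lr = lr, batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), seed = as.integer(seed)),
            class = "unet_config")
}

#' Desk-scale U-Net configuration
#'
#' Sized for 64 x 64 x 32 phantom volumes trained on a single CPU: 3 levels,
#' 8 base filters, learning rate 0.05 (desk-scale schedules take only a few
#' hundred optimisation steps and Adam moves each parameter by roughly the
#' learning rate per step, so a much larger step size than the full-scale
#' 1e-4 default is appropriate), and 30 epochs. The early-stopping abort is
#' disabled at desk scale (`patience = 0`) because the short schedules show
#' transient validation-loss spikes while late structures are still being
#' learned; the weights of the minimum-validation-loss epoch are still
#' restored at the end.
#'
#' @param ... Overrides passed to [unet_config()].
#' @return A `unet_config`.
#' @export
desk_unet_config <- function(...) {
  args <- modifyList(list(levels = 3L, base_filters = 8L, lr = 0.05,
                          max_epochs = 30L, patience = 0L), list(...))
  do.call(unet_config, args)
}

#' Build (initialise) a 3D U-Net model
#'
#' @param config A [unet_config()].
#' @return Object of class `unet_model` with fields `config`, `weights`,
#'   `biases` and `n_params` (deterministic function of the configuration).
#' @export
build_unet <- function(config = unet_config()) {
  init <- .unet_init_cpp(config, config$seed)
  structure(list(config = config, weights = init$weights,
                 biases = init$biases,
                 aux_weights = init$aux_weights,
                 aux_biases = init$aux_biases,
                 n_params = init$n_params,
                 geometry = NULL, history = NULL),
            class = "unet_model")
}

#' @export
print.unet_model <- function(x, ...) {
  cat(sprintf("3D U-Net: %d levels, %d base filters, %s parameters%s\n",
              x$config$levels, x$config$base_filters,
              format(x$n_params, big.mark = ","),
              if (is.null(x$history)) " (untrained)" else " (trained)"))
  invisible(x)
}

#' Count U-Net parameters for a configuration
#'
#' @param config A [unet_config()].
#' @return Total number of weights and biases.
#' @export
unet_param_count <- function(config) .unet_param_count_cpp(config)

.dataset_ids <- function(dataset)
  vapply(dataset, function(s) s$dixon$subject_id, "")

#' Train a 3D U-Net
#'
#' Whole-volume training with binary cross-entropy per sigmoid channel
#' against the one-hot targets, Adam optimiser, and early stopping that
#' restores the weights of the epoch with minimum validation loss. Training
#' and validation sets must be disjoint by subject id (leakage guard).
#'
#' @param model A [build_unet()] model.
#' @param train,val Lists of subjects, each a list with `dixon`
#'   ([dixon_volume()]) and `labels` ([label_map()]). Augmented copies may
#'   appear in `train`; their subject ids must still avoid `val`.
#' @param max_epochs,patience,lr Optional overrides of the config values.
#' @return The trained `unet_model`, with `history` (data.frame of per-epoch
#'   training/validation loss), `best_epoch` and `stopped_early`.
#' @export
train_unet <- function(model, train, val,
                       max_epochs = model$config$max_epochs,
                       patience = model$config$patience,
                       lr = model$config$lr) {
  train_ids <- .dataset_ids(train)
  val_ids <- .dataset_ids(val)
  leak <- intersect(unique(train_ids), unique(val_ids))
  if (length(leak) > 0)
    stop("training/validation leakage detected for subject(s): ",
         paste(sort(leak), collapse = ", "))
  nct <- length(train[[1]]$labels$code_table)
  if (model$config$out_channels != nct + 1L)
    stop("out_channels (", model$config$out_channels,
         ") must equal number of label codes + 1 (", nct + 1L, ")")
  tx <- lapply(train, function(s) s$dixon$in_phase)
  ty <- lapply(train, function(s) s$labels$labels)
  vx <- lapply(val, function(s) s$dixon$in_phase)
  vy <- lapply(val, function(s) s$labels$labels)
  res <- .unet_train_cpp(model$weights, model$biases,
                         model$aux_weights, model$aux_biases, model$config,
                         tx, ty, vx, vy,
                         as.integer(max_epochs), as.integer(patience),
                         lr, model$config$seed)
  model$weights <- res$weights
  model$biases <- res$biases
  model$aux_weights <- res$aux_weights
  model$aux_biases <- res$aux_biases
  model$history <- data.frame(epoch = seq_along(res$train_loss),
                              train_loss = res$train_loss,
                              val_loss = res$val_loss)
  model$best_epoch <- res$best_epoch
  model$stopped_early <- res$stopped_early
  model$geometry <- train[[1]]$dixon$geometry
  model$code_table <- train[[1]]$labels$code_table
  model
}

#' Segment a Dixon volume with a trained U-Net
#'
#' Per voxel, the label is the argmax over the sigmoid channel outputs
#' (background channel included; ties resolve toward background).
#'
#' @param model A trained `unet_model`.
#' @param vol A [dixon_volume()] homogenised to the model's training
#'   geometry.
#' @return A [label_map()] sharing the input geometry.
#' @export
predict_unet <- function(model, vol) {
  if (!is.null(model$geometry)) {
    msg <- .geometry_mismatch(vol$geometry, model$geometry)
    if (!is.null(msg))
      stop("input geometry does not match the model's training geometry (",
           msg, "); homogenise the volume first")
  }
  lab <- .unet_predict_cpp(model$weights, model$biases, model$config,
                           vol$in_phase)
  label_map(lab, vol$geometry,
            if (is.null(model$code_table)) MUSCLE_CODES else model$code_table)
}

# expand a training subset according to an augmentation plan
.apply_augment_plan <- function(dataset, plan, linear_spec, reg_params) {
  ids <- .dataset_ids(dataset)
  out <- dataset
  for (r in seq_len(nrow(plan))) {
    rec <- plan[r, ]
    src <- dataset[[match(rec$source, ids)]]
    if (rec$kind == "linear") {
      if (!rec$flip && rec$angle == 0) next  # the original is already present
      aug <- apply_linear(src$dixon, src$labels, rec$flip, rec$angle, linear_spec)
    } else {
      fixed <- dataset[[match(rec$partner, ids)]]
      aug <- synthesize_deformed(src, fixed$dixon, reg_params)
    }
    aug$dixon$subject_id <- paste0(rec$source, "_aug", r)
    out[[length(out) + 1]] <- list(dixon = aug$dixon, labels = aug$labels)
  }
  out
}

#' Monte-Carlo cross-validation of the U-Net
#'
#' Plans the fixed random train/validation splits with [mc_cv_plan()],
#' trains one model per fold (augmentation, when requested, is applied only
#' to the fold's training subset and checked structurally for validation
#' leakage), and pools the validation predictions of all folds
#' (`n_folds * n_val` segmentations).
#'
#' @param dataset List of subjects (`dixon` + `labels`).
#' @param n_folds,n_val Cross-validation layout (default 5 folds of 8).
#' @param config A [unet_config()].
#' @param seed Seed for the split plan.
#' @param augment `"none"`, `"mirror"` (flip copies via [mirror_augment()]),
#'   `"linear"` or `"full"` (linear + nonlinear).
#' @param linear_spec [linear_augment_spec()] used when augmenting.
#' @param reg_params [registration_params()] for nonlinear augmentation.
#' @param plan Optional pre-built `cv_plan` (defaults to [mc_cv_plan()]).
#' @return List with `plan` ([mc_cv_plan()]), `models` (per fold) and
#'   `pooled` (data.frame: fold, subject, and per-structure Dice), plus
#'   `predictions` (list of per-fold lists of [label_map()]s).
#' @export
mc_cross_validate <- function(dataset, n_folds = 5L, n_val = 8L,
                              config = desk_unet_config(), seed = 1L,
                              augment = c("none", "mirror", "linear", "full"),
                              linear_spec = linear_augment_spec(),
                              reg_params = registration_params(iterations = 60),
                              plan = NULL) {
  augment <- match.arg(augment)
  ids <- .dataset_ids(dataset)
  if (is.null(plan))
    plan <- mc_cv_plan(length(dataset), n_folds, n_val, seed = seed, ids = ids)
  n_folds <- plan$n_folds
  models <- vector("list", n_folds)
  preds <- vector("list", n_folds)
  rows <- list()
  for (f in seq_len(n_folds)) {
    tr_ids <- plan$folds[[f]]$train
    va_ids <- plan$folds[[f]]$val
    train <- dataset[match(tr_ids, ids)]
    val <- dataset[match(va_ids, ids)]
    if (augment == "mirror") {
      train <- mirror_augment(train)
    } else if (augment != "none") {
      ap <- augment_plan(tr_ids, linear_spec, nonlinear = (augment == "full"))
      assert_no_leakage(ap, va_ids)
      train <- .apply_augment_plan(train, ap, linear_spec, reg_params)
    }
    model <- build_unet(config)
    model <- train_unet(model, train, val)
    models[[f]] <- model
    preds[[f]] <- lapply(val, function(s) predict_unet(model, s$dixon))
    for (i in seq_along(val)) {
      dd <- vapply(seq_along(MUSCLE_CODES), function(code)
        dice(preds[[f]][[i]], val[[i]]$labels, code), numeric(1))
      rows[[length(rows) + 1]] <- data.frame(
        fold = f, subject = va_ids[i],
        structure = names(MUSCLE_CODES), code = seq_along(MUSCLE_CODES),
        dice = dd, stringsAsFactors = FALSE)
    }
  }
  list(plan = plan, models = models, predictions = preds,
       pooled = do.call(rbind, rows))
}
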