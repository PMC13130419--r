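#' Dice similarity coefficient for one label code
#'
#' `2 |A intersect B| / (|A| + |B|)` on the voxel sets of the code. When both
#' masks are empty the coefficient is defined as 1 (perfect agreement on
#' absence).
#'
#' @param a,b [label_map()]s (or logical 3D arrays) on one geometry.
#' @param code Label code (ignored for logical arrays).
#' @return Dice in `[0, 1]`.
#' @export
dice <- function(a, b, code = NULL) {
  m <- .as_code_masks(a, b, code)
  na <- sum(m$a); nb <- sum(m$b)
  if (na + nb == 0) return(1.0)
  2 * sum(m$a & m$b) / (na + nb)
}

.as_code_masks <- function(a, b, code) {
  if (inherits(a, "label_map") && inherits(b, "label_map")) {
    stopifnot_same_geometry(a$geometry, b$geometry, what = "label maps")
    if (is.null(code)) stop("code is required for label maps")
    list(a = a$labels == code, b = b$labels == code,
         spacing = a$geometry$spacing)
  } else {
    if (!all(dim(a) == dim(b))) stop("geometry mismatch between masks")
    list(a = a, b = b, spacing = c(1, 1, 1))
  }
}

#' Relative volume difference (signed percent)
#'
#' `(V_pred - V_truth) / V_truth * 100`; positive when the prediction is
#' larger than the ground truth.
#'
#' @param pred,truth [label_map()]s (or logical arrays).
#' @param code Label code.
#' @return Signed percent.
#' @export
rvd <- function(pred, truth, code = NULL) {
  m <- .as_code_masks(pred, truth, code)
  vt <- sum(m$b)
  if (vt == 0) stop("ground truth is empty for code ", code)
  (sum(m$a) - vt) / vt * 100
}

#' Hausdorff distance between two segmentations (mm)
#'
#' Maximum of the two directed max-min Euclidean distances between the
#' boundary voxel centres of the two masks, scaled by the voxel spacing.
#'
#' @param a,b [label_map()]s (or logical arrays).
#' @param code Label code.
#' @param spacing Voxel spacing in mm (taken from the geometry for label
#'   maps).
#' @return Distance in mm.
#' @export
hausdorff <- function(a, b, code = NULL, spacing = NULL) {
  m <- .as_code_masks(a, b, code)
  if (is.null(spacing)) spacing <- m$spacing
  if (!any(m$a) || !any(m$b)) stop("hausdorff requires non-empty masks")
  .hausdorff_cpp(m$a, m$b, as.numeric(spacing))
}

#' Compute all segmentation metrics for one prediction
#'
#' @param pred,truth [label_map()]s.
#' @param codes Codes to evaluate (default all in the truth code table).
#' @param crop Optional inclusive axial slice range applied to both masks
#'   before measuring (compensates for limited axial coverage).
#' @return data.frame: structure, code, dice, rvd_pct, hd_mm.
#' @export
seg_metrics <- function(pred, truth, codes = truth$code_table, crop = NULL) {
  p <- pred$labels; t <- truth$labels
  if (!is.null(crop)) {
    z <- seq(max(1L, crop[1]), min(dim(t)[3], crop[2]))
    p <- p[, , z, drop = FALSE]; t <- t[, , z, drop = FALSE]
  }
  rows <- lapply(seq_along(codes), function(i) {
    code <- codes[[i]]
    pa <- p == code; ta <- t == code
    data.frame(structure = names(codes)[i], code = code,
               dice = dice(pa, ta),
               rvd_pct = if (any(ta)) rvd(pa, ta) else NA_real_,
               hd_mm = if (any(pa) && any(ta))
                 hausdorff(pa, ta, spacing = truth$geometry$spacing)
               else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# ---- cross-validation planning --------------------------------------------

#' Monte-Carlo cross-validation plan (fixed random splits)
#'
#' Samples `n_folds` random validation sets of size `n_val` (without
#' replacement within a fold; repeats across folds allowed), resampling a
#' bounded number of times until every subject appears in at least one
#' validation set. The default layout (26 subjects, 5 folds of 8) gives 18
#' training subjects per fold and 40 pooled validation entries.
#'
#' @param n_subjects Number of subjects.
#' @param n_folds Number of random splits.
#' @param n_val Validation-set size per fold.
#' @param seed Integer seed.
#' @param ids Optional subject ids (default `S01..`).
#' @param max_tries Resampling attempts before giving up.
#' @return Object of class `cv_plan`: `folds` (list of `train`/`val` id
#'   vectors), `n_subjects`, `seed`.
#' @export
mc_cv_plan <- function(n_subjects = 26L, n_folds = 5L, n_val = 8L,
                       seed = 1L, ids = NULL, max_tries = 1000L) {
  if (n_val >= n_subjects) stop("n_val must be smaller than n_subjects")
  if (n_folds * n_val < n_subjects)
    stop(sprintf("infeasible plan: %d folds x %d validation slots < %d subjects (full coverage impossible)",
                 n_folds, n_val, n_subjects))
  if (is.null(ids)) ids <- sprintf("S%03d", seq_len(n_subjects))
  if (length(ids) != n_subjects) stop("ids length must equal n_subjects")
  set.seed(seed)
  for (try in seq_len(max_tries)) {
    folds <- lapply(seq_len(n_folds), function(f) {
      val <- sort(sample(ids, n_val))
      list(train = setdiff(ids, val), val = val)
    })
    covered <- unique(unlist(lapply(folds, `[[`, "val")))
    if (length(covered) == n_subjects) {
      return(structure(list(folds = folds, n_subjects = n_subjects,
                            n_folds = n_folds, n_val = n_val, seed = seed),
                       class = "cv_plan"))
    }
  }
  stop("could not achieve full validation coverage in ", max_tries, " tries")
}

#' @export
print.cv_plan <- function(x, ...) {
  cat(sprintf("Monte-Carlo CV plan: %d subjects, %d folds x %d validation (%d train per fold)\n",
              x$n_subjects, x$n_folds, x$n_val, x$n_subjects - x$n_val))
  invisible(x)
}

# ---- agreement -------------------------------------------------------------

#' Bland-Altman agreement analysis with regression
#'
#' Bias is `mean(y - x)`; the limits of agreement are
#' `bias +/- 1.96 sd(y - x)` with the sample (n-1) standard deviation. A
#' linear regression of `y` on `x` supplies slope, intercept and R^2.
#'
#' @param x,y Paired measurements (e.g. manual and automated FF), equal
#'   length >= 3.
#' @return Object of class `agreement_result`: `bias`, `loa` (lo, hi),
#'   `slope`, `intercept`, `r_squared`, `n`.
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 pairs")
  d <- y - x
  bias <- mean(d)
  s <- sd(d)
  fit <- lm(y ~ x)
  structure(list(bias = bias, loa = c(lo = bias - 1.96 * s, hi = bias + 1.96 * s),
                 slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
                 r_squared = summary(fit)$r.squared, n = length(x)),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("Bland-Altman: bias %.3f, LoA [%.3f, %.3f]; regression R^2 = %.3f (n = %d)\n",
              x$bias, x$loa[1], x$loa[2], x$r_squared, x$n))
  invisible(x)
}

#' Kruskal-Wallis rank test across groups
#'
#' Tie-corrected rank statistic H with a chi-square reference distribution
#' on g - 1 degrees of freedom (used even for two groups).
#'
#' @param groups List of >= 2 non-empty numeric vectors.
#' @return List with `H`, `df`, `p`.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2) stop("need at least two groups")
  if (any(vapply(groups, length, 0L) == 0)) stop("empty group")
  kt <- kruskal.test(groups)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value)
}

# ---- ANCOVA ----------------------------------------------------------------

#' Partial eta squared from an F statistic
#'
#' Algebraic identity `eta_p^2 = df1 F / (df1 F + df2)`, equivalent to
#' `SS_effect / (SS_effect + SS_residual)`; usable directly on published
#' (F, df) values.
#'
#' @param f F statistic.
#' @param df1,df2 Numerator and denominator degrees of freedom.
#' @return Partial eta squared.
#' @export
partial_eta_sq <- function(f, df1, df2) df1 * f / (df1 * f + df2)

#' Type III ANCOVA with partial eta squared
#'
#' Fits the full linear model with sum-to-zero contrasts for categorical
#' effects and computes, for each effect, the Type III sum of squares as
#' the increase in residual SS when that effect's columns are removed with
#' all other terms retained. Effect sizes are partial eta squared.
#'
#' @param data data.frame with the response and covariates; no missing
#'   values.
#' @param response Response column name (e.g. bilateral mean FF).
#' @param continuous Character vector of continuous covariate names.
#' @param categorical Character vector of categorical covariate names
#'   (coerced to factors; any number of levels).
#' @return Object of class `ancova_table`: data.frame with effect, df1,
#'   df2, sum_sq, F, p, partial_eta_sq; attribute `residual_df`.
#' @export
ancova_type3 <- function(data, response = "ff_pct",
                         continuous = c("age", "bmi"),
                         categorical = c("male", "active")) {
  vars <- c(response, continuous, categorical)
  missing_cols <- setdiff(vars, names(data))
  if (length(missing_cols) > 0)
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  d <- data[, vars]
  if (any(!complete.cases(d))) stop("missing values in model variables")
  for (v in categorical) d[[v]] <- factor(d[[v]])
  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old), add = TRUE)
  form <- as.formula(paste(response, "~",
                           paste(c(continuous, categorical), collapse = " + ")))
  X <- model.matrix(form, d)
  y <- d[[response]]
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient design; aliased term(s): ",
         paste(aliased, collapse = ", "))
  }
  n <- nrow(X)
  rss <- function(Xm) {
    fit <- lm.fit(Xm, y)
    sum(fit$residuals^2)
  }
  rss_full <- rss(X)
  df2 <- n - ncol(X)
  assign_idx <- attr(X, "assign")
  terms_lab <- attr(terms(form), "term.labels")
  rows <- lapply(seq_along(terms_lab), function(j) {
    drop <- which(assign_idx == j)
    rss_red <- rss(X[, -drop, drop = FALSE])
    ss <- rss_red - rss_full
    df1 <- length(drop)
    f <- (ss / df1) / (rss_full / df2)
    data.frame(effect = terms_lab[j], df1 = df1, df2 = df2, sum_sq = ss,
               F = f, p = pf(f, df1, df2, lower.tail = FALSE),
               partial_eta_sq = ss / (ss + rss_full),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  # estimated coefficients of the full fit, for effect-recovery checks
  fit_full <- lm(form, d)
  structure(out, class = c("ancova_table", "data.frame"),
            residual_df = df2, residual_ss = rss_full,
            coefficients = coef(fit_full),
            coef_se = sqrt(diag(vcov(fit_full))))
}

# ---- normative reference tables -------------------------------------------

#' Normative reference table of fat fractions
#'
#' Median and IQR (25th/75th percentiles, linear interpolation) of the
#' bilateral-mean FF per muscle, optionally stratified by activity group or
#' sex; empty cells are flagged with `NA` rather than fabricated.
#'
#' @param records data.frame with columns `muscle`, `ff_pct`, and (when
#'   stratifying) `active` (0/1) or `male` (0/1) — e.g. the output of
#'   [bilateral_table()] with covariates carried through.
#' @param strata `"none"`, `"activity"` or `"sex"`.
#' @param probs Percentile grid (default 25/50/75).
#' @return data.frame: muscle, stratum, n, and one column per requested
#'   percentile (`p25`, `median`, `p75` for the defaults).
#' @export
reference_table <- function(records, strata = c("none", "activity", "sex"),
                            probs = c(0.25, 0.5, 0.75)) {
  strata <- match.arg(strata)
  svar <- switch(strata, none = NULL, activity = "active", sex = "male")
  if (!is.null(svar) && !svar %in% names(records))
    stop("records lack the stratification column: ", svar)
  levels <- if (is.null(svar)) list(all = rep(TRUE, nrow(records))) else {
    vals <- sort(unique(records[[svar]]))
    nm <- if (strata == "activity") c("sedentary", "active")[vals + 1]
    else c("female", "male")[vals + 1]
    setNames(lapply(vals, function(v) records[[svar]] == v), nm)
  }
  pname <- function(p) if (p == 0.5) "median" else sprintf("p%g", 100 * p)
  rows <- list()
  for (mus in unique(records$muscle)) {
    for (st in names(levels)) {
      sel <- records$muscle == mus & levels[[st]]
      vals <- records$ff_pct[sel]
      q <- if (length(vals) > 0) quantile(vals, probs, type = 7, names = FALSE)
      else rep(NA_real_, length(probs))
      row <- data.frame(muscle = mus, stratum = st, n = sum(sel),
                        stringsAsFactors = FALSE)
      for (i in seq_along(probs)) row[[pname(probs[i])]] <- q[i]
      rows[[length(rows) + 1]] <- row
    }
  }
  do.call(rbind, rows)
}
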