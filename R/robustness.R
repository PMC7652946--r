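# Per-feature inter-reader robustness: relative change, MRC, ICC(2,1),
# agreement bands, and the robust-feature selection rule.

#' Paired feature table
#'
#' Per-lesion feature vectors from two readers, with matching rosters.
#'
#' @param reader1_values,reader2_values numeric matrices or data frames,
#'   lesions in rows, features in columns (same column names both sides).
#' @param lesion_ids optional row labels.
#' @param roi_mode `"3D"` or `"2D"`.
#' @return an object of class `paired_feature_table`.
#' @export
paired_feature_table <- function(reader1_values, reader2_values,
                                 lesion_ids = NULL, roi_mode = "3D") {
  r1 <- as.matrix(reader1_values); r2 <- as.matrix(reader2_values)
  if (!identical(dim(r1), dim(r2)))
    stop("reader tables must have identical dimensions")
  if (!identical(colnames(r1), colnames(r2)))
    stop("reader tables must share one feature roster")
  lesion_ids <- lesion_ids %||% sprintf("lesion%03d", seq_len(nrow(r1)))
  structure(list(reader1 = r1, reader2 = r2, lesion_ids = lesion_ids,
                 roi_mode = roi_mode),
            class = "paired_feature_table")
}

#' Relative change between two readers' feature values
#'
#' `(rf1 - rf2) / rf1`, signed, with reader 1 as the reference
#' denominator. Undefined (NaN) when `rf1 = 0` or either value is
#' non-finite; such lesions are excluded from the mean relative change.
#'
#' @param rf1,rf2 numeric vectors (reader 1 is the reference).
#' @return numeric vector of signed relative changes.
#' @export
relative_change <- function(rf1, rf2) {
  out <- (rf1 - rf2) / rf1
  out[rf1 == 0 | !is.finite(rf1) | !is.finite(rf2)] <- NaN
  out
}

#' Mean relative change per feature
#'
#' For each feature, the mean over lesions of the *absolute* relative
#' change, reported in percent. Individual changes are signed (negative
#' denominators are used as-is); the absolute value is applied only at
#' aggregation, the only reading consistent with reporting nonnegative MRC
#' percentages. Lesions with a zero or non-finite reference value are
#' excluded and counted.
#'
#' @param table a [paired_feature_table()].
#' @return data frame: feature, mrc (percent), n_valid, n_excluded.
#' @export
mean_relative_change <- function(table) {
  stopifnot(inherits(table, "paired_feature_table"))
  feats <- colnames(table$reader1)
  res <- lapply(feats, function(f) {
    rc <- relative_change(table$reader1[, f], table$reader2[, f])
    ok <- is.finite(rc)
    data.frame(feature = f,
               mrc = if (any(ok)) 100 * mean(abs(rc[ok])) else NA_real_,
               n_valid = sum(ok), n_excluded = sum(!ok),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Single-rater two-way random-effects ICC with absolute agreement
#'
#' ICC(2,1): with `n` lesions and `k = 2` readers, mean squares `MSR`
#' (between lesions), `MSC` (between readers) and `MSE` (residual) from the
#' two-way ANOVA decomposition give
#' `ICC = (MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))`.
#' The consistency form `(MSR - MSE) / (MSR + (k-1) MSE)` is available via
#' `type = "consistency"` but is not the default.
#'
#' @param x1,x2 paired numeric vectors (one value per lesion and reader).
#' @param type `"agreement"` (default) or `"consistency"`.
#' @return list with `icc`, `n_valid`, and the mean squares.
#' @export
icc_2_1 <- function(x1, x2, type = c("agreement", "consistency")) {
  type <- match.arg(type)
  ok <- is.finite(x1) & is.finite(x2)
  x1 <- x1[ok]; x2 <- x2[ok]
  n <- length(x1)
  if (n < 3L)
    return(list(icc = NA_real_, n_valid = n, msr = NA_real_, msc = NA_real_,
                mse = NA_real_))
  k <- 2
  x <- cbind(x1, x2)
  grand <- mean(x)
  rowm <- rowMeans(x); colm <- colMeans(x)
  msr <- k * sum((rowm - grand)^2) / (n - 1)
  msc <- n * sum((colm - grand)^2) / (k - 1)
  mse <- sum((x - outer(rowm, rep(1, k)) -
                outer(rep(1, n), colm) + grand)^2) / ((n - 1) * (k - 1))
  denom <- if (type == "agreement")
    msr + (k - 1) * mse + (k / n) * (msc - mse)
  else msr + (k - 1) * mse
  icc <- if (abs(denom) < 1e-300 || msr < 1e-300) NA_real_ else
    (msr - mse) / denom
  list(icc = icc, n_valid = n, msr = msr, msc = msc, mse = mse)
}

#' ICC agreement band
#'
#' Interpretation bands: poor for ICC <= 0.50, moderate for
#' 0.50 < ICC <= 0.75, good for 0.75 < ICC <= 0.90, excellent for
#' ICC > 0.90.
#'
#' @param icc numeric vector of ICC values.
#' @return character vector of bands (`NA` for non-finite input).
#' @export
classify_icc <- function(icc) {
  out <- rep(NA_character_, length(icc))
  fin <- is.finite(icc)
  out[fin & icc <= 0.50] <- "poor"
  out[fin & icc > 0.50 & icc <= 0.75] <- "moderate"
  out[fin & icc > 0.75 & icc <= 0.90] <- "good"
  out[fin & icc > 0.90] <- "excellent"
  out
}

feature_family <- function(feature) {
  ifelse(feature %in% glrlm_feature_names(), "GLRLM",
         ifelse(feature %in% glcm_feature_names(), "GLCM",
                ifelse(feature %in% morphology_feature_names(),
                       "morphology", "other")))
}

#' Per-feature robustness table
#'
#' Combines the mean relative change and ICC(2,1) of every feature into one
#' table with the agreement band and the robust-selection flag
#' (`ICC > 0.90` and `MRC < 10%`, strict inequalities).
#'
#' @param table a [paired_feature_table()].
#' @param icc_threshold,mrc_threshold robustness cutoffs (defaults 0.90 and
#'   10 percent).
#' @param icc_type passed to [icc_2_1()].
#' @return data frame of class `robustness_table`: feature, family, mrc,
#'   icc, n_valid_mrc, n_valid_icc, band, robust.
#' @export
robustness_table <- function(table, icc_threshold = 0.90, mrc_threshold = 10,
                             icc_type = "agreement") {
  stopifnot(inherits(table, "paired_feature_table"))
  mrc <- mean_relative_change(table)
  iccs <- vapply(mrc$feature, function(f)
    icc_2_1(table$reader1[, f], table$reader2[, f], type = icc_type)$icc,
    0)
  n_icc <- vapply(mrc$feature, function(f)
    sum(is.finite(table$reader1[, f]) & is.finite(table$reader2[, f])), 0L)
  out <- data.frame(feature = mrc$feature,
                    family = feature_family(mrc$feature),
                    mrc = mrc$mrc, icc = iccs,
                    n_valid_mrc = mrc$n_valid, n_valid_icc = n_icc,
                    band = classify_icc(iccs),
                    robust = is.finite(iccs) & is.finite(mrc$mrc) &
                      iccs > icc_threshold & mrc$mrc < mrc_threshold,
                    roi_mode = table$roi_mode,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("robustness_table", "data.frame")
  out
}

#' Select robust features
#'
#' Features with `ICC > icc_threshold` and `MRC < mrc_threshold`, strict
#' inequalities, so boundary values are rejected. Features with undefined
#' MRC or ICC are not selectable.
#'
#' @param robtable a [robustness_table()].
#' @inheritParams robustness_table
#' @return character vector of selected feature names.
#' @export
select_robust <- function(robtable, icc_threshold = 0.90, mrc_threshold = 10) {
  stopifnot(is.data.frame(robtable))
  sel <- is.finite(robtable$icc) & is.finite(robtable$mrc) &
    robtable$icc > icc_threshold & robtable$mrc < mrc_threshold
  robtable$feature[sel]
}
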