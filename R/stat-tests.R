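# Companion statistics: Wilcoxon signed-rank, Spearman correlation,
# size-versus-agreement analysis, circular-ROI comparison.

#' Wilcoxon signed-rank test for paired indices
#'
#' Two-sided signed-rank test on paired differences. Zero differences are
#' dropped; the exact distribution is used for up to 25 remaining pairs
#' (falling back to the normal approximation when absolute differences are
#' tied), and the normal approximation with continuity correction above.
#' If all differences are zero the test is undefined and `NA` is returned
#' with a flag.
#'
#' @param x,y paired numeric vectors.
#' @return list: `statistic` (V), `p_value`, `n_used`, `defined`.
#' @export
wilcoxon_signed_rank <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  d <- x[ok] - y[ok]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    return(list(statistic = NA_real_, p_value = NA_real_, n_used = 0L,
                defined = FALSE))
  wt <- suppressWarnings(
    stats::wilcox.test(d, exact = n <= 25L, correct = TRUE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       n_used = n, defined = TRUE)
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties; the p-value uses the
#' t-distribution approximation. A constant input vector makes the
#' correlation undefined (`NA`, flagged).
#'
#' @param x,y numeric vectors (n >= 3 after dropping non-finite pairs).
#' @return list: `rho`, `p_value`, `n_used`, `defined`.
#' @export
spearman_rho <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L || stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, p_value = NA_real_, n_used = n,
                defined = FALSE))
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n_used = n,
       defined = TRUE)
}

#' Evans interpretation of correlation strength
#'
#' `|rho|` < 0.20 very weak, 0.20-0.39 weak, 0.40-0.59 moderate, 0.60-0.79
#' strong, >= 0.80 very strong.
#'
#' @param rho numeric vector of correlations.
#' @return character vector of strength labels.
#' @export
evans_strength <- function(rho) {
  a <- abs(rho)
  out <- rep(NA_character_, length(rho))
  fin <- is.finite(a)
  out[fin & a < 0.20] <- "very weak"
  out[fin & a >= 0.20 & a < 0.40] <- "weak"
  out[fin & a >= 0.40 & a < 0.60] <- "moderate"
  out[fin & a >= 0.60 & a < 0.80] <- "strong"
  out[fin & a >= 0.80] <- "very strong"
  out
}

#' Lesion size versus contour agreement
#'
#' For each size parameter (manual axial diameter, max 3D diameter,
#' volume or area) against each similarity index (Dice, average Hausdorff),
#' reports the Spearman correlation with its p-value and Evans strength
#' label plus the ordinary least-squares slope and intercept.
#'
#' @param sizes data frame with columns `axial_diameter_mm`,
#'   `max_3d_diameter_mm`, `volume_or_area` (one row per lesion).
#' @param similarity data frame with columns `dice` and `avg_hausdorff_mm`,
#'   rows paired with `sizes`.
#' @param roi_mode label recorded in the output.
#' @return data frame: size_parameter, index, rho, p_value, strength,
#'   slope, intercept, n, roi_mode.
#' @export
size_agreement_analysis <- function(sizes, similarity, roi_mode = "3D") {
  stopifnot(nrow(sizes) == nrow(similarity))
  size_cols <- c("axial_diameter_mm", "max_3d_diameter_mm", "volume_or_area")
  idx_cols <- c("dice", "avg_hausdorff_mm")
  rows <- list()
  for (sc in size_cols) {
    for (ic in idx_cols) {
      s <- spearman_rho(sizes[[sc]], similarity[[ic]])
      fit <- if (s$defined)
        stats::coef(stats::lm(similarity[[ic]] ~ sizes[[sc]]))
      else c(NA_real_, NA_real_)
      rows[[length(rows) + 1L]] <- data.frame(
        size_parameter = sc, index = ic, rho = s$rho, p_value = s$p_value,
        strength = evans_strength(s$rho), slope = unname(fit[2L]),
        intercept = unname(fit[1L]), n = s$n_used, roi_mode = roi_mode,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Circular-ROI versus manual-ROI comparison
#'
#' For the main lesions, compares the inter-reader feature discrepancy
#' (reader 1 manual 2D ROI versus reader 2 manual 2D ROI) with the
#' discrepancy introduced by replacing reader 1's manual ROI with the
#' minimum enclosing or maximum inscribed circle, always taking reader 1
#' manual values as the reference denominator. A feature is flagged
#' `inter_reader_preponderant` when its inter-reader MRC is greater than or
#' equal to both circle-versus-manual MRCs.
#'
#' @param r1_manual,r2_manual,enclosing,inscribed numeric matrices or data
#'   frames (lesions x features, shared roster), feature values from reader
#'   1 manual 2D ROIs, reader 2 manual 2D ROIs and the two circular ROIs.
#' @return data frame: feature, family, mrc_inter_reader, mrc_enclosing,
#'   mrc_inscribed, inter_reader_preponderant.
#' @export
circular_roi_comparison <- function(r1_manual, r2_manual, enclosing, inscribed) {
  t_inter <- paired_feature_table(r1_manual, r2_manual, roi_mode = "2D")
  t_enc <- paired_feature_table(r1_manual, enclosing, roi_mode = "2D")
  t_ins <- paired_feature_table(r1_manual, inscribed, roi_mode = "2D")
  mi <- mean_relative_change(t_inter)
  me <- mean_relative_change(t_enc)
  ms <- mean_relative_change(t_ins)
  out <- data.frame(feature = mi$feature, family = feature_family(mi$feature),
                    mrc_inter_reader = mi$mrc,
                    mrc_enclosing = me$mrc, mrc_inscribed = ms$mrc,
                    inter_reader_preponderant =
                      is.finite(mi$mrc) & is.finite(me$mrc) & is.finite(ms$mrc) &
                      mi$mrc >= me$mrc & mi$mrc >= ms$mrc,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
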