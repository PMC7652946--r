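# Contour agreement: Dice coefficient and average Hausdorff distance.

# For 2D-axial masks comparisons are made in-plane: the two slices are
# overlaid regardless of their z index, matching how two readers' 2D ROIs
# of the same lesion are compared even when they picked adjacent slices.
slice_pair <- function(a, b) {
  za <- mask_slice_index(a); zb <- mask_slice_index(b)
  list(a = a$values[, , za], b = b$values[, , zb])
}

#' Dice coefficient
#'
#' `DC = 2|A n B| / (|A| + |B|)`: 0 for null overlap, 1 for perfect
#' overlap. Masks must share one grid; comparing two empty masks is
#' undefined and raises an error. Two 2D-axial masks are compared in-plane.
#'
#' @param a,b [roi_mask()] objects on the same grid.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice <- function(a, b) {
  stopifnot(inherits(a, "roi_mask"), inherits(b, "roi_mask"))
  check_same_grid(a, b)
  na <- sum(a$values); nb <- sum(b$values)
  if (na + nb == 0) stop("Dice coefficient undefined: both masks are empty")
  if (a$dimensionality == "2D-axial" && b$dimensionality == "2D-axial") {
    sl <- slice_pair(a, b)
    inter <- sum(sl$a & sl$b)
  } else {
    inter <- sum(a$values & b$values)
  }
  2 * inter / (na + nb)
}

boundary_points_mm <- function(mask) {
  bnd <- mask_boundary(mask)
  idx <- which(bnd, arr.ind = TRUE)
  pts <- sweep(sweep(idx - 1, 2L, mask$spacing, "*"), 2L, mask$origin, "+")
  if (mask$dimensionality == "2D-axial") pts[, 1:2, drop = FALSE] else pts
}

#' Average Hausdorff distance
#'
#' The average symmetric surface distance between the two contours:
#' boundary voxel centers (foreground voxels with a face-adjacent
#' background neighbour) are extracted in mm, and the result is
#' `[sum_{p in dA} min_q d(p,q) + sum_{q in dB} min_p d(p,q)] / (|dA| + |dB|)`,
#' symmetric in its arguments. For a pair of 2D-axial masks distances are
#' computed in-plane.
#'
#' @param a,b nonempty [roi_mask()] objects on the same grid.
#' @param spacing voxel spacing override (mm); defaults to the mask spacing.
#' @return average Hausdorff distance in mm.
#' @export
average_hausdorff <- function(a, b, spacing = NULL) {
  stopifnot(inherits(a, "roi_mask"), inherits(b, "roi_mask"))
  check_same_grid(a, b)
  stop_if_empty(a, "mask a"); stop_if_empty(b, "mask b")
  if (!is.null(spacing)) {
    a$spacing <- as.numeric(spacing); b$spacing <- as.numeric(spacing)
  }
  pa <- boundary_points_mm(a)
  pb <- boundary_points_mm(b)
  if (ncol(pa) == 3L) {
    sz <- a$spacing[3L]
    dsum <- sum(nearest_dist_sliced(pa, pb, sz)) +
      sum(nearest_dist_sliced(pb, pa, sz))
  } else {
    dsum <- sum(nearest_dist(pa, pb)) + sum(nearest_dist(pb, pa))
  }
  dsum / (nrow(pa) + nrow(pb))
}

# Quartiles by linear interpolation (type 7, R default), documented.
iqr_summary <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  c(q25 = q[1], median = q[2], q75 = q[3])
}

#' Cohort-level contour similarity
#'
#' Per-lesion Dice coefficient and average Hausdorff distance for paired
#' reader masks, with cohort medians and interquartile ranges (quartiles by
#' linear interpolation).
#'
#' @param reader1,reader2 equal-length lists of [roi_mask()] objects,
#'   paired by lesion.
#' @param mode label stored in the results (`"3D"` or `"2D"`); defaults to
#'   the dimensionality of the first mask.
#' @param lesion_ids optional labels.
#' @return list with `per_lesion` (data frame: lesion_id, mode, dice,
#'   avg_hausdorff_mm) and `summary` (median and IQR of both indices).
#' @export
cohort_similarity <- function(reader1, reader2, mode = NULL, lesion_ids = NULL) {
  if (length(reader1) != length(reader2))
    stop("reader1 and reader2 lists must have equal length")
  n <- length(reader1)
  if (n == 0L) stop("empty cohort")
  mode <- mode %||%
    if (reader1[[1L]]$dimensionality == "2D-axial") "2D" else "3D"
  lesion_ids <- lesion_ids %||% sprintf("lesion%03d", seq_len(n))
  dc <- hd <- numeric(n)
  for (i in seq_len(n)) {
    dc[i] <- dice(reader1[[i]], reader2[[i]])
    hd[i] <- average_hausdorff(reader1[[i]], reader2[[i]])
  }
  per <- data.frame(lesion_id = lesion_ids, mode = mode, dice = dc,
                    avg_hausdorff_mm = hd, stringsAsFactors = FALSE)
  list(per_lesion = per,
       summary = list(dice = iqr_summary(dc), avg_hausdorff_mm = iqr_summary(hd),
                      n = n, mode = mode))
}
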