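#' Intensity volume
#'
#' A 3D scalar grid of CT intensities (Hounsfield units) with physical voxel
#' spacing. Arrays are indexed `[x, y, z]` with `z` the axial (slice)
#' direction; voxel indices are 1-based in R but physical coordinates are
#' voxel-center based, so voxel `(i, j, k)` sits at
#' `origin + (i - 1, j - 1, k - 1) * spacing` millimetres.
#'
#' @param values numeric 3D array of intensities (HU).
#' @param spacing numeric length-3 vector, voxel spacing in mm `(x, y, z)`,
#'   all components strictly positive.
#' @param origin numeric length-3 vector, physical position (mm) of the
#'   center of voxel `(1, 1, 1)`.
#' @return an object of class `intensity_volume`.
#' @export
intensity_volume <- function(values, spacing, origin = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three positive numbers (mm)")
  origin <- as.numeric(origin)
  if (length(origin) != 3L) stop("`origin` must have length 3")
  structure(list(values = values, spacing = spacing, origin = origin,
                 axis_order = "xyz-axial-z"),
            class = "intensity_volume")
}

#' @export
print.intensity_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<intensity_volume> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  HU range [%.1f, %.1f]\n", min(x$values), max(x$values)))
  invisible(x)
}

#' Binary region-of-interest mask
#'
#' A binary labelmap congruent with a parent [intensity_volume()]. Any
#' nonzero value is coerced to foreground; a labelmap carrying more than two
#' distinct values triggers a warning before coercion. Masks are tagged with
#' a dimensionality (`"3D"` for whole-lesion volumes, `"2D-axial"` for a
#' single axial slice) and a shape tag distinguishing manual contours from
#' the derived circular ROIs.
#'
#' @param values logical or numeric 3D array; nonzero means foreground.
#' @param spacing voxel spacing in mm, as for [intensity_volume()].
#' @param dimensionality `"3D"` or `"2D-axial"`. For `"2D-axial"` masks all
#'   foreground voxels must share one z index.
#' @param shape_tag one of `"manual"`, `"circle_enclosing"`,
#'   `"circle_inscribed"`.
#' @param reader_id optional reader label.
#' @param origin physical position (mm) of the center of voxel `(1,1,1)`.
#' @return an object of class `roi_mask`.
#' @export
roi_mask <- function(values, spacing,
                     dimensionality = c("3D", "2D-axial"),
                     shape_tag = c("manual", "circle_enclosing", "circle_inscribed"),
                     reader_id = NA_character_, origin = c(0, 0, 0)) {
  dimensionality <- match.arg(dimensionality)
  shape_tag <- match.arg(shape_tag)
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array")
  if (!is.logical(values)) {
    u <- unique(as.vector(values))
    if (length(u) > 2L)
      warning("labelmap has more than two distinct values; coercing nonzero to foreground")
    values <- array(values != 0, dim(values))
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three positive numbers (mm)")
  if (dimensionality == "2D-axial" && any(values)) {
    zs <- unique(which(values, arr.ind = TRUE)[, 3L])
    if (length(zs) != 1L)
      stop("2D-axial mask must have all foreground voxels on one axial slice")
  }
  structure(list(values = values, spacing = spacing, origin = as.numeric(origin),
                 dimensionality = dimensionality, shape_tag = shape_tag,
                 reader_id = reader_id),
            class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<roi_mask %s/%s> %d x %d x %d grid, %d foreground voxels\n",
              x$dimensionality, x$shape_tag, d[1], d[2], d[3], sum(x$values)))
  invisible(x)
}

n_foreground <- function(mask) sum(mask$values)

stop_if_empty <- function(mask, what = "mask") {
  if (!any(mask$values)) stop(sprintf("%s is empty", what), call. = FALSE)
  invisible(mask)
}

# 1-based voxel indices of foreground voxels, n x 3.
mask_coords <- function(mask) which(mask$values, arr.ind = TRUE)

# Physical voxel-center coordinates (mm) of foreground voxels.
mask_points_mm <- function(mask) {
  idx <- mask_coords(mask)
  sweep(sweep(idx - 1, 2L, mask$spacing, "*"), 2L, mask$origin, "+")
}

check_same_grid <- function(a, b) {
  if (!identical(dim(a$values), dim(b$values)))
    stop("masks are not on the same grid (dimension mismatch)", call. = FALSE)
  if (!isTRUE(all.equal(a$spacing, b$spacing, tolerance = 1e-8)))
    stop("masks are not on the same grid (spacing mismatch)", call. = FALSE)
  invisible(TRUE)
}

check_alignment <- function(mask_dim, mask_spacing, volume) {
  if (!identical(as.integer(mask_dim), as.integer(dim(volume$values))))
    stop("labelmap grid does not match the parent volume grid", call. = FALSE)
  if (!isTRUE(all.equal(as.numeric(mask_spacing), volume$spacing, tolerance = 1e-6)))
    stop("labelmap spacing does not match the parent volume spacing", call. = FALSE)
  invisible(TRUE)
}

#' Boundary voxels of a mask
#'
#' Foreground voxels with at least one face-adjacent background neighbour
#' (6-connectivity for 3D masks, in-plane 4-connectivity for 2D-axial
#' masks). Voxels on the grid edge count as boundary.
#'
#' @param mask a [roi_mask()].
#' @return logical array of the same shape flagging boundary voxels.
#' @export
mask_boundary <- function(mask) {
  m <- mask$values
  axes <- if (mask$dimensionality == "2D-axial") 1:2 else 1:3
  all_nb <- array(TRUE, dim(m))
  for (ax in axes) {
    for (s in c(-1L, 1L)) {
      off <- c(0L, 0L, 0L); off[ax] <- s
      all_nb <- all_nb & shift_array(m, off, fill = FALSE)
    }
  }
  m & !all_nb
}

# Largest within-slice (axial) diameter in mm: max over slices of the max
# pairwise in-plane distance between foreground voxel centers. 0 for a
# single-voxel mask, -Inf never (empty handled by caller).
axial_diameter_mm <- function(mask) {
  stop_if_empty(mask)
  idx <- mask_coords(mask)
  sp <- mask$spacing
  best <- 0
  for (z in unique(idx[, 3L])) {
    pts <- idx[idx[, 3L] == z, 1:2, drop = FALSE]
    if (nrow(pts) < 2L) next
    pm <- sweep(pts - 1, 2L, sp[1:2], "*")
    h <- if (nrow(pm) > 3L) pm[grDevices::chull(pm), , drop = FALSE] else pm
    best <- max(best, max_pairwise_dist(h))
  }
  best
}

# Max 3D diameter in mm: max pairwise distance between surface voxel
# centers; pruned to per-line extreme voxels, which contain every convex
# hull vertex and hence the realizing pair.
max_3d_diameter_mm <- function(mask) {
  stop_if_empty(mask)
  idx <- extreme_voxels(mask_coords(mask))
  pts <- sweep(idx - 1, 2L, mask$spacing, "*")
  max_pairwise_dist(pts)
}
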