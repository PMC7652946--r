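# Derivation of 2D and circular ROIs from a 3D segmentation.

#' Largest axial cross-section of a 3D mask
#'
#' Returns the single axial slice with maximal foreground area (mm^2),
#' operationalizing the "largest and most representative" 2D ROI as the
#' largest-area slice. Ties are broken by the lowest z index.
#'
#' @param mask a nonempty 3D [roi_mask()].
#' @return a `2D-axial` [roi_mask()] on the same grid.
#' @export
largest_axial_cross_section <- function(mask) {
  stopifnot(inherits(mask, "roi_mask"))
  stop_if_empty(mask)
  counts <- apply(mask$values, 3L, sum)
  z <- which.max(counts)  # first maximum = lowest z on ties
  out <- array(FALSE, dim(mask$values))
  out[, , z] <- mask$values[, , z]
  roi_mask(out, mask$spacing, dimensionality = "2D-axial",
           shape_tag = "manual", reader_id = mask$reader_id,
           origin = mask$origin)
}

mask_slice_index <- function(mask) {
  stopifnot(mask$dimensionality == "2D-axial")
  unique(mask_coords(mask)[, 3L])
}

# --- minimum enclosing circle (Welzl, randomized incremental) -------------

circle_from2 <- function(p, q) {
  c0 <- (p + q) / 2
  list(center = c0, r = sqrt(sum((p - c0)^2)))
}

circle_from3 <- function(p, q, r) {
  ax <- p[1]; ay <- p[2]; bx <- q[1]; by <- q[2]; cx <- r[1]; cy <- r[2]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  if (abs(d) < 1e-12) return(NULL)  # collinear
  ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
           (cx^2 + cy^2) * (ay - by)) / d
  uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
           (cx^2 + cy^2) * (bx - ax)) / d
  ctr <- c(ux, uy)
  list(center = ctr, r = sqrt(sum((p - ctr)^2)))
}

in_circle <- function(circ, p, tol = 1e-9) {
  sqrt(sum((p - circ$center)^2)) <= circ$r + tol
}

# Welzl's move-to-front algorithm on a deterministic permutation.
min_enclosing_circle <- function(pts) {
  pts <- unique(as.matrix(pts))
  n <- nrow(pts)
  if (n == 1L) return(list(center = pts[1, ], r = 0))
  pts <- pts[with_seed(20201110L, sample.int(n)), , drop = FALSE]
  circ <- circle_from2(pts[1, ], pts[2, ])
  for (i in seq_len(n)) {
    if (in_circle(circ, pts[i, ])) next
    circ <- circle_from2(pts[1, ], pts[i, ])
    for (j in seq_len(i - 1L)) {
      if (in_circle(circ, pts[j, ])) next
      circ <- circle_from2(pts[i, ], pts[j, ])
      for (k in seq_len(j - 1L)) {
        if (in_circle(circ, pts[k, ])) next
        c3 <- circle_from3(pts[i, ], pts[j, ], pts[k, ])
        if (!is.null(c3)) circ <- c3
      }
    }
  }
  circ
}

rasterize_circle <- function(template, z, center, radius, spacing, origin) {
  d <- dim(template)
  xs <- origin[1] + (seq_len(d[1]) - 1) * spacing[1]
  ys <- origin[2] + (seq_len(d[2]) - 1) * spacing[2]
  d2 <- outer((xs - center[1])^2, (ys - center[2])^2, "+")
  out <- array(FALSE, d)
  out[, , z] <- d2 <= radius^2 + 1e-9
  out
}

#' Minimum enclosing circular ROI
#'
#' Rasterizes the minimum enclosing circle (in physical mm, in-plane) of the
#' foreground voxel centers of a 2D-axial mask: the smallest circular ROI
#' inclusive of the whole lesion cross-section. A voxel belongs to the
#' circle iff its center lies at distance <= radius, so the output is a
#' superset of the input foreground.
#'
#' @param mask2d a nonempty `2D-axial` [roi_mask()].
#' @return a `2D-axial` [roi_mask()] with `shape_tag = "circle_enclosing"`.
#'   The circle center (mm) and radius (mm) are attached as attributes
#'   `circle_center` and `circle_radius`.
#' @export
min_enclosing_circle_roi <- function(mask2d) {
  stopifnot(inherits(mask2d, "roi_mask"), mask2d$dimensionality == "2D-axial")
  stop_if_empty(mask2d)
  z <- mask_slice_index(mask2d)
  pts <- mask_points_mm(mask2d)[, 1:2, drop = FALSE]
  cand <- if (nrow(pts) > 3L) pts[grDevices::chull(pts), , drop = FALSE] else pts
  circ <- min_enclosing_circle(cand)
  vals <- rasterize_circle(mask2d$values, z, circ$center, circ$r,
                           mask2d$spacing, mask2d$origin)
  out <- roi_mask(vals, mask2d$spacing, dimensionality = "2D-axial",
                  shape_tag = "circle_enclosing", reader_id = mask2d$reader_id,
                  origin = mask2d$origin)
  attr(out, "circle_center") <- as.numeric(circ$center)
  attr(out, "circle_radius") <- circ$r
  out
}

#' Maximum inscribed circular ROI
#'
#' The largest circular ROI completely inside the lesion cross-section. The
#' center is the foreground voxel whose center maximizes the Euclidean
#' distance (mm) to the background (grid borders count as background); ties
#' are broken by lexicographic voxel index. The radius is that distance
#' minus half the smaller in-plane spacing, i.e. the distance to the nearest
#' background voxel *edge* rather than center, so a rasterized disc maps
#' approximately onto itself. The rasterization is intersected with the
#' input foreground, making the subset property structural.
#'
#' @param mask2d a nonempty `2D-axial` [roi_mask()].
#' @return a `2D-axial` [roi_mask()] with `shape_tag = "circle_inscribed"`
#'   and attributes `circle_center` / `circle_radius` (mm).
#' @export
max_inscribed_circle_roi <- function(mask2d) {
  stopifnot(inherits(mask2d, "roi_mask"), mask2d$dimensionality == "2D-axial")
  stop_if_empty(mask2d)
  z <- mask_slice_index(mask2d)
  m2 <- mask2d$values[, , z]
  d <- dim(m2)
  sp <- mask2d$spacing[1:2]
  orig <- mask2d$origin[1:2]
  # background voxel centers, including a one-voxel ring outside the grid
  gx <- orig[1] + (0:(d[1] + 1) - 1) * sp[1]
  gy <- orig[2] + (0:(d[2] + 1) - 1) * sp[2]
  inside <- matrix(FALSE, d[1] + 2L, d[2] + 2L)
  inside[2:(d[1] + 1L), 2:(d[2] + 1L)] <- m2
  bgidx <- which(!inside, arr.ind = TRUE)
  bgpts <- cbind(gx[bgidx[, 1L]], gy[bgidx[, 2L]])
  fgidx <- which(m2, arr.ind = TRUE)
  fgpts <- cbind(orig[1] + (fgidx[, 1L] - 1) * sp[1],
                 orig[2] + (fgidx[, 2L] - 1) * sp[2])
  dist_bg <- nearest_dist(fgpts, bgpts)
  best <- which.max(dist_bg)  # which.max takes the first (lexicographic) max
  center <- fgpts[best, ]
  radius <- dist_bg[best] - min(sp) / 2
  vals <- rasterize_circle(mask2d$values, z, center, radius,
                           mask2d$spacing, mask2d$origin)
  vals <- vals & mask2d$values
  out <- roi_mask(vals, mask2d$spacing, dimensionality = "2D-axial",
                  shape_tag = "circle_inscribed", reader_id = mask2d$reader_id,
                  origin = mask2d$origin)
  attr(out, "circle_center") <- as.numeric(center)
  attr(out, "circle_radius") <- radius
  out
}
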