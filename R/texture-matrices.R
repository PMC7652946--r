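# Grey level co-occurrence and run length matrices.

# Unique offset-1 directions up to sign: 13 in 3D, 4 in-plane in 2D.
texture_directions <- function(mode = c("3D", "2D")) {
  mode <- match.arg(mode)
  if (mode == "2D") {
    list(c(1L, 0L, 0L), c(0L, 1L, 0L), c(1L, 1L, 0L), c(1L, -1L, 0L))
  } else {
    list(c(1L, 0L, 0L), c(0L, 1L, 0L), c(0L, 0L, 1L),
         c(1L, 1L, 0L), c(1L, -1L, 0L),
         c(1L, 0L, 1L), c(1L, 0L, -1L),
         c(0L, 1L, 1L), c(0L, 1L, -1L),
         c(1L, 1L, 1L), c(1L, 1L, -1L), c(1L, -1L, 1L), c(-1L, 1L, 1L))
  }
}

# Integer co-occurrence counts for one direction (both orderings).
glcm_direction_counts <- function(labels, off, ng) {
  d <- dim(labels)
  rngs <- src <- vector("list", 3L)
  for (k in 1:3) {
    o <- off[k]
    if (abs(o) >= d[k]) return(matrix(0L, ng, ng))
    if (o >= 0) { src[[k]] <- seq.int(1L, d[k] - o) }
    else { src[[k]] <- seq.int(1L - o, d[k]) }
  }
  a <- labels[src[[1L]], src[[2L]], src[[3L]], drop = FALSE]
  b <- labels[src[[1L]] + off[1L], src[[2L]] + off[2L], src[[3L]] + off[3L],
              drop = FALSE]
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) return(matrix(0L, ng, ng))
  cnt <- tabulate((a[ok] - 1L) * ng + b[ok], nbins = ng * ng)
  m <- matrix(cnt, ng, ng, byrow = TRUE)
  m + t(m)
}

#' Build the grey level co-occurrence matrix
#'
#' Counts co-occurring bin pairs between foreground voxels at offset 1 over
#' all unique directions (13 in 3D mode, 4 in-plane in 2D mode), counting
#' both orderings of each pair (symmetric). Per-direction count matrices
#' are summed into one matrix before normalization by default; the
#' alternative `"average"` aggregation normalizes each direction first and
#' averages the probability matrices.
#'
#' @param d a [discretize()]d ROI.
#' @param mode `"3D"` or `"2D"` (in-plane directions only).
#' @param aggregate `"sum"` (default) or `"average"`.
#' @return an object of class `glcm_matrix`: `p` (Ng x Ng probabilities
#'   summing to 1), `counts` (integer pair counts), `directions`, `mode`.
#' @export
build_glcm <- function(d, mode = c("3D", "2D"), aggregate = c("sum", "average")) {
  stopifnot(inherits(d, "discretized_roi"))
  mode <- match.arg(mode)
  aggregate <- match.arg(aggregate)
  ng <- d$config$n_bins
  dirs <- texture_directions(mode)
  per_dir <- lapply(dirs, function(o) glcm_direction_counts(d$bin_labels, o, ng))
  counts <- Reduce(`+`, per_dir)
  if (sum(counts) == 0)
    stop("degenerate GLCM: ROI has no co-occurring voxel pairs")
  p <- if (aggregate == "sum") {
    counts / sum(counts)
  } else {
    probs <- lapply(per_dir[vapply(per_dir, sum, 0) > 0],
                    function(m) m / sum(m))
    Reduce(`+`, probs) / length(probs)
  }
  structure(list(p = p, counts = counts, directions = dirs, mode = mode,
                 aggregate = aggregate),
            class = "glcm_matrix")
}

# Run-length decomposition for one direction: maximal runs of equal bin
# label along lattice lines, truncated at the mask boundary.
glrlm_direction_runs <- function(coords, bins, off, dims) {
  dd <- sum(off^2)
  s <- as.vector(coords %*% off)
  keyv <- coords * dd - outer(s, off)
  base <- max(dims) * dd + 2 * dd * max(dims) + 1
  shift <- apply(keyv, 2L, min)
  keyv <- sweep(keyv, 2L, shift)
  key <- (keyv[, 1L] * base + keyv[, 2L]) * base + keyv[, 3L]
  ord <- order(key, s)
  k <- key[ord]; sv <- s[ord]; bv <- bins[ord]
  n <- length(k)
  newrun <- c(TRUE, k[-1L] != k[-n] | sv[-1L] != sv[-n] + dd | bv[-1L] != bv[-n])
  run_id <- cumsum(newrun)
  len <- tabulate(run_id)
  list(bin = bv[newrun], len = len)
}

#' Build the grey level run length matrix
#'
#' Decomposes the foreground voxels into maximal runs of equal bin label
#' along each direction (13 in 3D, 4 in-plane in 2D) and accumulates
#' `r(i, j)` = number of runs of grey level `i` and length `j`, summed over
#' directions. Each voxel belongs to exactly one run per direction, so
#' `sum_ij j * r(i, j) = n_directions * n_foreground`.
#'
#' @inheritParams build_glcm
#' @return an object of class `glrlm_matrix`: `r` (Ng x Nr counts),
#'   `n_voxels`, `n_directions`, `mode`.
#' @export
build_glrlm <- function(d, mode = c("3D", "2D")) {
  stopifnot(inherits(d, "discretized_roi"))
  mode <- match.arg(mode)
  ng <- d$config$n_bins
  dims <- dim(d$bin_labels)
  coords <- which(!is.na(d$bin_labels), arr.ind = TRUE)
  if (nrow(coords) == 0L) stop("empty ROI")
  bins <- d$bin_labels[!is.na(d$bin_labels)]
  dirs <- texture_directions(mode)
  runs <- lapply(dirs, function(o) glrlm_direction_runs(coords, bins, o, dims))
  nr <- max(vapply(runs, function(x) max(x$len), 0L))
  r <- matrix(0, ng, nr)
  for (rr in runs) {
    cnt <- tabulate((rr$bin - 1L) * nr + rr$len, nbins = ng * nr)
    r <- r + matrix(cnt, ng, nr, byrow = TRUE)
  }
  structure(list(r = r, n_voxels = nrow(coords), n_directions = length(dirs),
                 directions = dirs, mode = mode),
            class = "glrlm_matrix")
}

#' Aggregated texture matrices for one ROI
#'
#' Convenience wrapper building both the GLCM and the GLRLM of a
#' discretized ROI.
#'
#' @inheritParams build_glcm
#' @return an object of class `texture_matrices` with elements `glcm` and
#'   `glrlm`.
#' @export
texture_matrices <- function(d, mode = c("3D", "2D")) {
  mode <- match.arg(mode)
  structure(list(glcm = build_glcm(d, mode), glrlm = build_glrlm(d, mode),
                 mode = mode),
            class = "texture_matrices")
}
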