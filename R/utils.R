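# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the global random number generator seeded at `seed`,
#' restoring the caller's RNG state afterwards so that library calls do not
#' perturb user-level simulations.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(code)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Shift a 3D array by an integer offset, filling exposed voxels with `fill`.
shift_array <- function(m, off, fill = FALSE) {
  d <- dim(m)
  out <- array(fill, d)
  src <- dst <- vector("list", 3L)
  for (k in 1:3) {
    o <- off[k]
    if (abs(o) >= d[k]) return(out)
    if (o >= 0) {
      dst[[k]] <- seq.int(1L + o, d[k])
      src[[k]] <- seq.int(1L, d[k] - o)
    } else {
      dst[[k]] <- seq.int(1L, d[k] + o)
      src[[k]] <- seq.int(1L - o, d[k])
    }
  }
  out[dst[[1L]], dst[[2L]], dst[[3L]]] <- m[src[[1L]], src[[2L]], src[[3L]]]
  out
}

# Minimum Euclidean distance from each row of `a` to the point set `b`.
# Chunked BLAS formulation (|a|^2 + |b|^2 - 2 a.b) so that boundary sets of
# tens of thousands of voxels stay within memory.
nearest_dist <- function(a, b, chunk = 1024L) {
  a <- as.matrix(a); b <- as.matrix(b)
  stopifnot(ncol(a) == ncol(b), nrow(b) >= 1L)
  b2 <- rowSums(b * b)
  out <- numeric(nrow(a))
  i <- 1L
  while (i <= nrow(a)) {
    j <- min(i + chunk - 1L, nrow(a))
    ai <- a[i:j, , drop = FALSE]
    d2 <- tcrossprod(ai, b)
    d2 <- sweep(-2 * d2, 2L, b2, "+")
    # argmin via the C-level max.col scan, then the distance recomputed
    # directly from coordinates (the quadratic expansion loses precision)
    jmin <- max.col(-d2, ties.method = "first")
    out[i:j] <- sqrt(rowSums((ai - b[jmin, , drop = FALSE])^2))
    i <- j + 1L
  }
  out
}

# Slice-windowed nearest-neighbour distances for boundary point sets of 3D
# masks: for query points on axial slice z only target slices within a
# window |dz| <= w are compared; a computed minimum <= w is certified
# (points outside the window are farther than w by construction), otherwise
# the window is doubled for the uncertified points. Exact, and much faster
# than the dense search when the two surfaces are close.
nearest_dist_sliced <- function(a, b, slice_mm) {
  a <- as.matrix(a); b <- as.matrix(b)
  zb <- b[, 3L]
  uz <- sort(unique(zb))
  by_z <- split(seq_len(nrow(b)), factor(zb, levels = uz))
  out <- numeric(nrow(a))
  for (g in split(seq_len(nrow(a)), a[, 3L])) {
    z <- a[g[1L], 3L]
    w <- 2 * slice_mm
    repeat {
      full <- w >= max(abs(uz - z))  # window covers every target slice
      cand <- unlist(by_z[abs(uz - z) <= w + 1e-9], use.names = FALSE)
      if (length(cand)) {
        dmin <- nearest_dist(a[g, , drop = FALSE], b[cand, , drop = FALSE])
        certified <- full | dmin <= w + 1e-9
        out[g[certified]] <- dmin[certified]
        g <- g[!certified]
        if (!length(g)) break
      }
      w <- 2 * w
    }
  }
  out
}

# Maximum pairwise Euclidean distance within a point set (rows of `pts`).
# Candidates are pruned to per-line extremes beforehand by callers.
max_pairwise_dist <- function(pts, chunk = 512L) {
  pts <- as.matrix(pts)
  n <- nrow(pts)
  if (n < 2L) return(0)
  p2 <- rowSums(pts * pts)
  best <- 0
  i <- 1L
  while (i <= n) {
    j <- min(i + chunk - 1L, n)
    ai <- pts[i:j, , drop = FALSE]
    d2 <- outer(rowSums(ai * ai), p2, "+") - 2 * tcrossprod(ai, pts)
    best <- max(best, max(d2))
    i <- j + 1L
  }
  sqrt(max(best, 0))
}

# For the farthest-pair search only convex-hull vertices matter, and every
# hull vertex is an x-extreme voxel of its (y,z) grid line.  Returns the
# pruned candidate index matrix (1-based voxel indices, n x 3).
extreme_voxels <- function(idx) {
  if (nrow(idx) <= 2L) return(idx)
  key <- paste(idx[, 2L], idx[, 3L], sep = ",")
  lo <- tapply(seq_len(nrow(idx)), key, function(r) r[which.min(idx[r, 1L])])
  hi <- tapply(seq_len(nrow(idx)), key, function(r) r[which.max(idx[r, 1L])])
  idx[unique(c(unlist(lo), unlist(hi))), , drop = FALSE]
}

# Number of face-connected (6-neighbourhood) components of a logical 3D array.
# Frontier flood fill on the cropped bounding box; intended for validation on
# moderate masks, not as a performance-critical kernel.
count_components <- function(m) {
  stopifnot(is.logical(m), length(dim(m)) == 3L)
  if (!any(m)) return(0L)
  idx <- which(m, arr.ind = TRUE)
  lo <- apply(idx, 2L, min); hi <- apply(idx, 2L, max)
  m <- m[lo[1L]:hi[1L], lo[2L]:hi[2L], lo[3L]:hi[3L], drop = FALSE]
  dim(m) <- c(hi - lo + 1L)
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  remaining <- m
  ncomp <- 0L
  while (any(remaining)) {
    ncomp <- ncomp + 1L
    seedpos <- which(remaining)[1L]
    comp <- array(FALSE, dim(m))
    comp[seedpos] <- TRUE
    frontier <- comp
    while (any(frontier)) {
      grown <- array(FALSE, dim(m))
      for (r in seq_len(nrow(offs)))
        grown <- grown | shift_array(frontier, offs[r, ])
      frontier <- grown & remaining & !comp
      comp <- comp | frontier
    }
    remaining <- remaining & !comp
  }
  ncomp
}
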