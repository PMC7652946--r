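# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (voxel-by-voxel loops, all-pairs scans) so they cannot
# share a defect with the vectorized implementations they check.

make_volume <- function(values, spacing = c(1, 1, 1)) {
  if (length(dim(values)) == 2L) dim(values) <- c(dim(values), 1L)
  intensity_volume(values, spacing)
}

make_mask <- function(values, spacing = c(1, 1, 1), dimensionality = "3D", ...) {
  if (length(dim(values)) == 2L) dim(values) <- c(dim(values), 1L)
  roi_mask(values, spacing, dimensionality = dimensionality, ...)
}

# rasterized sphere mask on an n^3 grid (unit spacing)
sphere_mask <- function(n = 20L, radius = n / 3, spacing = c(1, 1, 1)) {
  cen <- (n + 1) / 2
  idx <- as.matrix(expand.grid(x = 1:n, y = 1:n, z = 1:n))
  d2 <- ((idx[, 1] - cen) * spacing[1])^2 + ((idx[, 2] - cen) * spacing[2])^2 +
    ((idx[, 3] - cen) * spacing[3])^2
  m <- array(d2 <= radius^2, c(n, n, n))
  roi_mask(m, spacing)
}

# single-slice disc mask (2D-axial)
disc_mask <- function(n = 21L, radius = 5, spacing = c(1, 1, 1), z = 1L,
                      nz = 1L, center = c((n + 1) / 2, (n + 1) / 2)) {
  m <- array(FALSE, c(n, n, nz))
  for (i in 1:n) for (j in 1:n) {
    d2 <- ((i - center[1]) * spacing[1])^2 + ((j - center[2]) * spacing[2])^2
    if (d2 <= radius^2) m[i, j, z] <- TRUE
  }
  roi_mask(m, spacing, dimensionality = "2D-axial")
}

# --- GLCM / GLRLM oracles -------------------------------------------------

oracle_glcm_counts <- function(labels, dirs, ng) {
  cnt <- matrix(0, ng, ng)
  d <- dim(labels)
  idx <- which(!is.na(labels), arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    for (o in dirs) {
      v <- idx[r, ] + o
      if (all(v >= 1) && all(v <= d)) {
        li <- labels[idx[r, 1], idx[r, 2], idx[r, 3]]
        lj <- labels[v[1], v[2], v[3]]
        if (!is.na(lj)) {
          cnt[li, lj] <- cnt[li, lj] + 1
          cnt[lj, li] <- cnt[lj, li] + 1
        }
      }
    }
  }
  cnt
}

oracle_glrlm_counts <- function(labels, dirs, ng) {
  d <- dim(labels)
  inb <- function(v) all(v >= 1) && all(v <= d)
  lab <- function(v) labels[v[1], v[2], v[3]]
  runs <- list()
  for (o in dirs) {
    idx <- which(!is.na(labels), arr.ind = TRUE)
    for (r in seq_len(nrow(idx))) {
      v <- idx[r, ]
      prev <- v - o
      # run start: predecessor invalid, outside mask, or different label
      if (inb(prev) && !is.na(lab(prev)) && lab(prev) == lab(v)) next
      len <- 1L
      nxt <- v + o
      while (inb(nxt) && !is.na(lab(nxt)) && lab(nxt) == lab(v)) {
        len <- len + 1L
        nxt <- nxt + o
      }
      runs[[length(runs) + 1L]] <- c(lab(v), len)
    }
  }
  runs <- do.call(rbind, runs)
  nr <- max(runs[, 2])
  m <- matrix(0, ng, nr)
  for (r in seq_len(nrow(runs))) m[runs[r, 1], runs[r, 2]] <-
      m[runs[r, 1], runs[r, 2]] + 1
  m
}

# --- boundary / Hausdorff oracle ------------------------------------------

oracle_boundary_points <- function(mask) {
  m <- mask$values
  d <- dim(m)
  axes <- if (mask$dimensionality == "2D-axial") 1:2 else 1:3
  pts <- NULL
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    if (!m[i, j, k]) next
    v <- c(i, j, k)
    isb <- FALSE
    for (ax in axes) for (s in c(-1L, 1L)) {
      w <- v; w[ax] <- w[ax] + s
      if (any(w < 1) || any(w > d) || !m[w[1], w[2], w[3]]) isb <- TRUE
    }
    if (isb) pts <- rbind(pts, (v - 1) * mask$spacing)
  }
  if (mask$dimensionality == "2D-axial") pts[, 1:2, drop = FALSE] else pts
}

oracle_avg_hausdorff <- function(a, b) {
  pa <- oracle_boundary_points(a)
  pb <- oracle_boundary_points(b)
  mind <- function(p, q) {
    vapply(seq_len(nrow(p)), function(i)
      min(sqrt(colSums((t(q) - p[i, ])^2))), 0)
  }
  (sum(mind(pa, pb)) + sum(mind(pb, pa))) / (nrow(pa) + nrow(pb))
}

# --- minimum enclosing circle oracle (all pairs and triples) --------------

oracle_mec <- function(pts) {
  pts <- unique(as.matrix(pts))
  n <- nrow(pts)
  if (n == 1L) return(list(center = pts[1, ], r = 0))
  covers <- function(c0, r) all(sqrt((pts[, 1] - c0[1])^2 +
                                       (pts[, 2] - c0[2])^2) <= r + 1e-9)
  best <- list(center = c(NA_real_, NA_real_), r = Inf)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    c0 <- (pts[i, ] + pts[j, ]) / 2
    r <- sqrt(sum((pts[i, ] - c0)^2))
    if (covers(c0, r) && (is.null(best) || r < best$r))
      best <- list(center = c0, r = r)
  }
  if (n >= 3) {
    for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
      p <- pts[i, ]; q <- pts[j, ]; s <- pts[k, ]
      dd <- 2 * (p[1] * (q[2] - s[2]) + q[1] * (s[2] - p[2]) +
                   s[1] * (p[2] - q[2]))
      if (abs(dd) < 1e-12) next
      ux <- (sum(p^2) * (q[2] - s[2]) + sum(q^2) * (s[2] - p[2]) +
               sum(s^2) * (p[2] - q[2])) / dd
      uy <- (sum(p^2) * (s[1] - q[1]) + sum(q^2) * (p[1] - s[1]) +
               sum(s^2) * (q[1] - p[1])) / dd
      r <- sqrt(sum((p - c(ux, uy))^2))
      if (covers(c(ux, uy), r) && r < best$r) best <- list(center = c(ux, uy), r = r)
    }
  }
  best
}

# --- ICC oracle via ANOVA mean squares ------------------------------------

oracle_icc_2_1 <- function(x1, x2) {
  n <- length(x1)
  df <- data.frame(y = c(x1, x2),
                   lesion = factor(rep(seq_len(n), 2L)),
                   reader = factor(rep(1:2, each = n)))
  ms <- summary(stats::aov(y ~ lesion + reader, data = df))[[1]][, "Mean Sq"]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  k <- 2
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

# --- shared study-scale fixtures (generated once per test run) ------------

.fixture_cache <- new.env(parent = emptyenv())

study_cohort <- function() {
  if (is.null(.fixture_cache$cohort))
    .fixture_cache$cohort <- generate_cohort(70, 101)
  .fixture_cache$cohort
}

study_features_3d <- function() {
  if (is.null(.fixture_cache$feat3)) {
    co <- study_cohort()
    f1 <- t(vapply(seq_along(co$volumes), function(i)
      unclass(extract_features(co$volumes[[i]], co$reader1_masks[[i]],
                               mode = "3D")), numeric(35)))
    f2 <- t(vapply(seq_along(co$volumes), function(i)
      unclass(extract_features(co$volumes[[i]], co$reader2_masks[[i]],
                               mode = "3D")), numeric(35)))
    .fixture_cache$feat3 <- list(r1 = f1, r2 = f2)
  }
  .fixture_cache$feat3
}

study_similarity <- function() {
  if (is.null(.fixture_cache$sim)) {
    co <- study_cohort()
    s1 <- lapply(co$reader1_masks, largest_axial_cross_section)
    s2 <- lapply(co$reader2_masks, largest_axial_cross_section)
    .fixture_cache$sim <- list(
      sim3 = cohort_similarity(co$reader1_masks, co$reader2_masks, mode = "3D"),
      sim2 = cohort_similarity(s1, s2, mode = "2D"))
  }
  .fixture_cache$sim
}
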