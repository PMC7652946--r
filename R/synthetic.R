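# Synthetic textured-lesion cohort: phantom CT volumes with a known truth
# contour and two simulated readers, standing in for clinical data that
# cannot be redistributed.

#' Lesion specification
#'
#' Parameters of one synthetic liver lesion phantom: a smoothly deformed
#' sphere of hypodense tissue embedded in brighter parenchyma-like
#' background, with stationary correlated Gaussian texture and a blurred
#' boundary. Defaults emulate a portal-venous-phase CT appearance
#' (background about 110 HU, lesion about 60 HU).
#'
#' @param target_diameter lesion diameter in mm (> 0).
#' @param lesion_mean_hu,background_mean_hu mean intensities (HU); must
#'   differ, otherwise the lesion would be undetectable by construction.
#' @param texture_correlation_length correlation length of the Gaussian
#'   texture field, mm.
#' @param noise_sd marginal standard deviation of the texture field, HU
#'   (>= 0).
#' @param boundary_blur_sigma Gaussian width of the lesion/background
#'   transition, mm (>= 0).
#' @param shape_irregularity amplitude in `[0, 1)` of the smooth low-order
#'   radial deformation applied to the sphere.
#' @param center optional lesion center in continuous 1-based voxel grid
#'   coordinates; defaults to the grid center at generation time.
#' @return an object of class `lesion_spec`.
#' @export
lesion_spec <- function(target_diameter,
                        lesion_mean_hu = 60,
                        background_mean_hu = 110,
                        texture_correlation_length = 4,
                        noise_sd = 15,
                        boundary_blur_sigma = 1.5,
                        shape_irregularity = 0.08,
                        center = NULL) {
  if (!is.numeric(target_diameter) || target_diameter <= 0)
    stop("target_diameter must be > 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (boundary_blur_sigma < 0) stop("boundary_blur_sigma must be >= 0")
  if (shape_irregularity < 0 || shape_irregularity >= 1)
    stop("shape_irregularity must lie in [0, 1)")
  if (lesion_mean_hu == background_mean_hu)
    stop("lesion_mean_hu must differ from background_mean_hu")
  if (texture_correlation_length <= 0)
    stop("texture_correlation_length must be > 0")
  structure(list(target_diameter = target_diameter,
                 lesion_mean_hu = lesion_mean_hu,
                 background_mean_hu = background_mean_hu,
                 texture_correlation_length = texture_correlation_length,
                 noise_sd = noise_sd,
                 boundary_blur_sigma = boundary_blur_sigma,
                 shape_irregularity = shape_irregularity,
                 center = center),
            class = "lesion_spec")
}

#' Reader perturbation specification
#'
#' How a simulated reader's contour deviates from the truth contour: the
#' boundary is displaced along the outward normal by a constant signed bias
#' plus a smooth zero-mean angular noise field.
#'
#' @param radial_bias systematic over- (positive) or under- (negative)
#'   segmentation, mm.
#' @param radial_jitter_sd standard deviation of the smooth zero-mean
#'   boundary noise, mm (>= 0).
#' @param jitter_smoothness angular correlation scale of the noise field,
#'   radians (larger = smoother contours).
#' @param partial_volume_scale amplitude of the additional slice-wise
#'   partial-volume noise on the peripheral (polar) parts of the lesion
#'   surface, in units of the slice thickness: its standard deviation is
#'   `partial_volume_scale * slice_thickness * |cos(theta)|`, maximal where
#'   the surface normal is axial and zero at the equator. Only active for
#'   readers with `radial_jitter_sd > 0` (a noise-free reader reproduces
#'   the truth exactly).
#' @param seed integer RNG seed for this reader's noise fields.
#' @param reader_id label attached to the produced masks.
#' @return an object of class `reader_perturbation`.
#' @export
reader_perturbation <- function(radial_bias = 0, radial_jitter_sd = 0.8,
                                jitter_smoothness = 0.8,
                                partial_volume_scale = 1.2, seed = 1L,
                                reader_id = NA_character_) {
  if (radial_jitter_sd < 0) stop("radial_jitter_sd must be >= 0")
  if (jitter_smoothness <= 0) stop("jitter_smoothness must be > 0")
  if (partial_volume_scale < 0) stop("partial_volume_scale must be >= 0")
  structure(list(radial_bias = radial_bias,
                 radial_jitter_sd = radial_jitter_sd,
                 jitter_smoothness = jitter_smoothness,
                 partial_volume_scale = partial_volume_scale,
                 seed = as.integer(seed), reader_id = reader_id),
            class = "reader_perturbation")
}

# --- smooth random fields on the unit sphere ------------------------------

# Deterministic Fibonacci point set on the sphere, used to normalize bump
# fields to zero mean / unit scale.
fibonacci_sphere <- function(n = 400L) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(1 - z^2, 0))
  phi <- pi * (1 + sqrt(5)) * i
  cbind(r * cos(phi), r * sin(phi), z)
}

# A smooth random scalar field on the sphere built from K Gaussian bumps at
# random directions; consumes RNG state. Returns a closure evaluating the
# *raw* field plus the affine normalization (centering/scale) computed on a
# fixed reference point set.
sphere_bump_field <- function(width, n_bumps = 12L) {
  w <- matrix(stats::rnorm(3 * n_bumps), n_bumps, 3)
  w <- w / sqrt(rowSums(w * w))
  a <- stats::rnorm(n_bumps)
  evalraw <- function(u) {
    # u: n x 3 unit vectors
    drop((exp(-(1 - tcrossprod(u, w)) / width^2)) %*% a)
  }
  ref <- fibonacci_sphere(400L)
  v <- evalraw(ref)
  list(eval_raw = evalraw, mean = mean(v), sd = stats::sd(v),
       max_abs = max(abs(v - mean(v))))
}

# Field scaled so that max |f| = 1 over the reference set (radial shape
# deformation).
eval_shape_field <- function(field, u) {
  if (field$max_abs < 1e-12) return(rep(0, nrow(u)))
  (field$eval_raw(u) - field$mean) / field$max_abs
}

# Field scaled to zero mean and unit sd over the reference set (boundary
# jitter).
eval_jitter_field <- function(field, u) {
  if (field$sd < 1e-12) return(rep(0, nrow(u)))
  (field$eval_raw(u) - field$mean) / field$sd
}

# --- separable Gaussian convolution ---------------------------------------

gauss_kernel <- function(sigma_vox, trunc = 4) {
  if (sigma_vox <= 0) return(1)
  h <- max(1L, as.integer(ceiling(trunc * sigma_vox)))
  t <- (-h):h
  exp(-t^2 / (2 * sigma_vox^2))
}

# Convolve a 3D array along one axis with kernel w (zero padding), using a
# banded sparse matrix so large anisotropic grids stay fast.
conv_axis <- function(arr, w, axis) {
  if (length(w) == 1L) return(arr * w)
  d <- dim(arr)
  perm <- switch(axis, c(1L, 2L, 3L), c(2L, 1L, 3L), c(3L, 1L, 2L))
  a <- if (axis == 1L) arr else aperm(arr, perm)
  da <- dim(a)
  n <- da[1L]
  h <- (length(w) - 1L) %/% 2L
  ks <- (-h):h
  keep <- abs(ks) < n
  K <- Matrix::bandSparse(n, n, k = ks[keep],
                          diagonals = lapply(which(keep), function(i)
                            rep(w[i], n - abs(ks[i]))))
  out <- as.matrix(K %*% matrix(a, n, prod(da[-1L])))
  dim(out) <- da
  if (axis == 1L) out else aperm(out, order(perm))
}

smooth_gaussian <- function(arr, sigma_vox, normalize = TRUE) {
  # sigma_vox: per-axis sigma in voxels; normalize=TRUE gives a unit-sum
  # kernel (plateau preserved), normalize=FALSE rescales so white-noise
  # input keeps unit marginal variance in the interior.
  var_mult <- 1
  for (ax in 1:3) {
    w <- gauss_kernel(sigma_vox[ax])
    if (normalize) w <- w / sum(w) else var_mult <- var_mult * sum(w^2)
    arr <- conv_axis(arr, w, ax)
  }
  if (!normalize) arr <- arr / sqrt(var_mult)
  arr
}

# --- lesion phantom -------------------------------------------------------

#' Generate a textured lesion phantom
#'
#' Builds an intensity volume equal to the background mean plus a
#' spatially correlated Gaussian texture field (correlation length
#' `texture_correlation_length`, marginal sd `noise_sd`), with intensities
#' inside the truth mask shifted toward the lesion mean and the
#' lesion/background transition smoothed by a Gaussian of width
#' `boundary_blur_sigma`. The truth mask is the smoothly deformed sphere
#' *before* blurring. All intensities are clamped to `[-1024, 3071]` HU.
#'
#' @param spec a [lesion_spec()].
#' @param grid_shape integer voxel triple; should leave about one lesion
#'   radius of margin around the lesion.
#' @param spacing voxel spacing in mm `(x, y, z)`.
#' @param seed integer seed; identical calls are bit-identical.
#' @return a list with elements `volume` ([intensity_volume()]) and `truth`
#'   (3D [roi_mask()]).
#' @export
generate_lesion_volume <- function(spec, grid_shape, spacing, seed) {
  stopifnot(inherits(spec, "lesion_spec"))
  grid_shape <- as.integer(grid_shape)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("spacing components must be positive")
  if (length(grid_shape) != 3L || any(grid_shape < 3L))
    stop("grid_shape must be three integers >= 3")
  center <- spec$center %||% ((grid_shape + 1) / 2)
  r0 <- spec$target_diameter / 2
  rmax <- r0 * (1 + spec$shape_irregularity)
  # sizing: lesion (plus a voxel of slack) must fit inside the grid
  lo_mm <- (center - 1) * spacing
  hi_mm <- (grid_shape - center) * spacing
  if (any(lo_mm < rmax + spacing) || any(hi_mm < rmax + spacing))
    stop("lesion does not fit in grid: enlarge grid_shape or shrink the lesion")

  dx <- (seq_len(grid_shape[1L]) - center[1L]) * spacing[1L]
  dy <- (seq_len(grid_shape[2L]) - center[2L]) * spacing[2L]
  dz <- (seq_len(grid_shape[3L]) - center[3L]) * spacing[3L]
  r2 <- outer(outer(dx^2, dy^2, "+"), dz^2, "+")

  out <- with_seed(seed, {
    shape <- sphere_bump_field(width = 0.9)
    if (spec$shape_irregularity == 0) {
      truth <- r2 <= r0^2
    } else {
      eps <- spec$shape_irregularity
      truth <- r2 <= (r0 * (1 - eps))^2
      shell <- which(r2 > (r0 * (1 - eps))^2 & r2 <= (r0 * (1 + eps))^2)
      if (length(shell)) {
        sidx <- arrayInd(shell, grid_shape)
        pv <- cbind(dx[sidx[, 1L]], dy[sidx[, 2L]], dz[sidx[, 3L]])
        rv <- sqrt(r2[shell])
        u <- pv / pmax(rv, 1e-12)
        rad <- r0 * (1 + eps * eval_shape_field(shape, u))
        truth[shell] <- rv <= rad
      }
    }
    dim(truth) <- grid_shape
    field <- 0
    if (spec$noise_sd > 0) {
      eps_arr <- array(stats::rnorm(prod(grid_shape)), grid_shape)
      sig_vox <- spec$texture_correlation_length / spacing
      field <- spec$noise_sd * smooth_gaussian(eps_arr, sig_vox, normalize = FALSE)
    }
    list(truth = truth, field = field)
  })

  memb <- array(as.numeric(out$truth), grid_shape)
  if (spec$boundary_blur_sigma > 0)
    memb <- smooth_gaussian(memb, spec$boundary_blur_sigma / spacing,
                            normalize = TRUE)
  values <- spec$background_mean_hu +
    (spec$lesion_mean_hu - spec$background_mean_hu) * memb + out$field
  values <- clamp(values, -1024, 3071)
  list(volume = intensity_volume(values, spacing),
       truth = roi_mask(out$truth, spacing, dimensionality = "3D"))
}

# --- reader simulation ----------------------------------------------------

# Estimated boundary radius of a star-shaped mask along a grid of
# directions, by ray marching from the centroid.
radial_profile <- function(mask, theta_g, phi_g) {
  sp <- mask$spacing
  idx <- mask_coords(mask)
  cen <- colMeans(sweep(idx - 1, 2L, sp, "*"))
  d <- dim(mask$values)
  dirs <- as.matrix(expand.grid(it = seq_along(theta_g), ip = seq_along(phi_g)))
  th <- theta_g[dirs[, 1L]]; ph <- phi_g[dirs[, 2L]]
  U <- cbind(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
  dt <- min(sp) / 2
  pts <- sweep(idx - 1, 2L, sp, "*")
  tmax <- sqrt(max(rowSums(sweep(pts, 2L, cen, "-")^2))) + 2 * max(sp)
  ts <- seq(0, tmax, by = dt)
  nd <- nrow(U); nt <- length(ts)
  inm <- matrix(FALSE, nd, nt)
  for (j in seq_len(nt)) {
    p <- sweep(U * ts[j], 2L, cen, "+")
    vi <- round(sweep(p, 2L, sp, "/")) + 1
    ok <- vi[, 1L] >= 1 & vi[, 1L] <= d[1L] &
      vi[, 2L] >= 1 & vi[, 2L] <= d[2L] &
      vi[, 3L] >= 1 & vi[, 3L] <= d[3L]
    lin <- (vi[ok, 3L] - 1) * d[1L] * d[2L] + (vi[ok, 2L] - 1) * d[1L] + vi[ok, 1L]
    inm[ok, j] <- mask$values[lin]
  }
  # consecutive in-mask steps from the centroid outward
  run <- rep(0L, nd)
  alive <- rep(TRUE, nd)
  for (j in seq_len(nt)) {
    alive <- alive & inm[, j]
    run <- run + alive
  }
  radius <- matrix(pmax(run - 0.5, 0.25) * dt, length(theta_g), length(phi_g))
  list(center = cen, radius = radius)
}

#' Simulate a reader's contour of a lesion
#'
#' Displaces the truth boundary along the outward radial direction by
#' `radial_bias` plus a smooth zero-mean angular noise field of standard
#' deviation `radial_jitter_sd`, emulating an independent human reader.
#' The perturbed region is star-shaped about the lesion centroid, which
#' keeps it a single connected component; if the perturbation would shrink
#' the boundary radius below one voxel anywhere (emptying or fragmenting
#' the mask), an error is raised. With zero bias and zero jitter the truth
#' mask is returned unchanged.
#'
#' @param truth a nonempty, single-component 3D [roi_mask()].
#' @param pert a [reader_perturbation()].
#' @param spacing voxel spacing in mm; defaults to the truth mask spacing.
#' @return a 3D [roi_mask()] on the same grid.
#' @export
simulate_reader <- function(truth, pert, spacing = truth$spacing) {
  stopifnot(inherits(truth, "roi_mask"), inherits(pert, "reader_perturbation"))
  stop_if_empty(truth, "truth mask")
  if (!isTRUE(all.equal(as.numeric(spacing), truth$spacing)))
    stop("spacing must match the truth mask spacing")
  if (pert$radial_bias == 0 && pert$radial_jitter_sd == 0) {
    out <- truth
    out$reader_id <- pert$reader_id
    return(out)
  }
  n_theta <- 48L; n_phi <- 96L
  theta_g <- (seq_len(n_theta) - 0.5) * pi / n_theta
  phi_g <- (seq_len(n_phi) - 0.5) * 2 * pi / n_phi
  prof <- radial_profile(truth, theta_g, phi_g)

  jit <- 0
  if (pert$radial_jitter_sd > 0) {
    fields <- with_seed(pert$seed, list(
      iso = sphere_bump_field(width = pert$jitter_smoothness),
      polar = sphere_bump_field(width = pert$jitter_smoothness)))
    dirs <- as.matrix(expand.grid(it = seq_along(theta_g), ip = seq_along(phi_g)))
    th <- theta_g[dirs[, 1L]]; ph <- phi_g[dirs[, 2L]]
    U <- cbind(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
    jv <- pert$radial_jitter_sd * eval_jitter_field(fields$iso, U)
    if (pert$partial_volume_scale > 0) {
      # peripheral axial slices suffer partial volume: extra boundary noise
      # where the surface normal approaches the slice axis
      pv_sd <- pert$partial_volume_scale * truth$spacing[3L] * abs(cos(th))
      jv <- jv + pv_sd * eval_jitter_field(fields$polar, U)
    }
    jit <- matrix(jv, n_theta, n_phi)
  }
  B <- prof$radius + pert$radial_bias + jit
  if (min(B) < 0.5 * min(truth$spacing))
    stop("perturbation too large: mask would empty or fragment")

  d <- dim(truth$values)
  sp <- truth$spacing
  cen <- prof$center
  dxv <- (seq_len(d[1L]) - 1) * sp[1L] - cen[1L]
  dyv <- (seq_len(d[2L]) - 1) * sp[2L] - cen[2L]
  dzv <- (seq_len(d[3L]) - 1) * sp[3L] - cen[3L]
  r2 <- outer(outer(dxv^2, dyv^2, "+"), dzv^2, "+")
  rmaxB <- max(B); rminB <- min(B)
  newmask <- r2 <= rminB^2
  shell <- which(r2 > rminB^2 & r2 <= rmaxB^2)
  if (length(shell)) {
    sidx <- arrayInd(shell, d)
    px <- dxv[sidx[, 1L]]; py <- dyv[sidx[, 2L]]; pz <- dzv[sidx[, 3L]]
    rv <- sqrt(r2[shell])
    thv <- acos(pmin(pmax(pz / pmax(rv, 1e-12), -1), 1))
    phv <- atan2(py, px) %% (2 * pi)
    # bilinear interpolation of B over the (theta, phi) grid, phi wrapping
    ti <- thv / (pi / n_theta) + 0.5
    i0 <- pmin(pmax(floor(ti), 1), n_theta - 1L); tf <- pmin(pmax(ti - i0, 0), 1)
    pj <- phv / (2 * pi / n_phi) + 0.5
    j0 <- floor(pj); pf <- pj - j0
    j0 <- ((j0 - 1L) %% n_phi) + 1L
    j1 <- (j0 %% n_phi) + 1L
    Bv <- (1 - tf) * ((1 - pf) * B[cbind(i0, j0)] + pf * B[cbind(i0, j1)]) +
      tf * ((1 - pf) * B[cbind(i0 + 1L, j0)] + pf * B[cbind(i0 + 1L, j1)])
    newmask[shell] <- rv <= Bv
  }
  dim(newmask) <- d
  if (!any(newmask)) stop("perturbation emptied the mask")
  roi_mask(newmask, sp, dimensionality = "3D", reader_id = pert$reader_id,
           origin = truth$origin)
}

# --- exclusion criteria ---------------------------------------------------

#' Apply lesion exclusion criteria
#'
#' Mirrors the reading-protocol rule excluding lesions whose maximum axial
#' (within-slice) diameter is lesser than `min_diameter`; a lesion of
#' exactly `min_diameter` is retained. Empty masks are excluded with reason
#' `"empty"`.
#'
#' @param masks list of 3D [roi_mask()] objects.
#' @param min_diameter threshold in mm (default 10).
#' @return list with `masks` (retained), `kept` (logical vector) and `log`
#'   (data frame: index, axial diameter mm, retained flag, reason).
#' @export
apply_exclusion_criteria <- function(masks, min_diameter = 10) {
  if (min_diameter <= 0) stop("min_diameter must be > 0")
  n <- length(masks)
  diam <- rep(NA_real_, n); keep <- logical(n); reason <- character(n)
  for (i in seq_len(n)) {
    if (!any(masks[[i]]$values)) {
      keep[i] <- FALSE; reason[i] <- "empty"
      next
    }
    diam[i] <- axial_diameter_mm(masks[[i]])
    if (diam[i] >= min_diameter) {
      keep[i] <- TRUE; reason[i] <- ""
    } else {
      keep[i] <- FALSE
      reason[i] <- sprintf("axial diameter %.2f mm < %.2f mm", diam[i], min_diameter)
    }
  }
  list(masks = masks[keep], kept = keep,
       log = data.frame(lesion = seq_len(n), axial_diameter_mm = diam,
                        retained = keep, reason = reason,
                        stringsAsFactors = FALSE))
}

# --- cohort ---------------------------------------------------------------

# A jitter draw extreme enough to collapse a small lesion's contour is not a
# plausible human reading; redraw deterministically (bounded attempts).
simulate_reader_retry <- function(truth, pert, seed, max_attempts = 20L) {
  for (att in seq_len(max_attempts)) {
    pert$seed <- as.integer((as.double(seed) + (att - 1) * 1000003) %%
                              (.Machine$integer.max - 1)) + 1L
    m <- tryCatch(simulate_reader(truth, pert), error = function(e) e)
    if (!inherits(m, "error")) return(m)
  }
  stop("reader simulation failed repeatedly: perturbation too strong for this lesion")
}

default_population_ranges <- function() {
  list(target_diameter = c(10, 80),
       lesion_mean_hu = c(50, 70),
       background_mean_hu = c(110, 110),
       texture_correlation_length = c(3, 6),
       noise_sd = c(10, 20),
       boundary_blur_sigma = c(1, 2),
       shape_irregularity = c(0.03, 0.08))
}

#' Generate a synthetic two-reader cohort
#'
#' Draws per-lesion phantom parameters uniformly from `population_ranges`
#' (defaults: diameters 10-80 mm, in-plane spacing 0.7-0.9 mm, slice
#' thickness 2.5 or 3 mm, hypodense lesions on a 110 HU background),
#' generates each lesion volume and truth mask, and simulates two readers
#' with independent per-reader noise seeds derived deterministically from
#' `master_seed`. Regeneration with the same master seed is bit-identical.
#'
#' @param n_lesions number of lesions (>= 1).
#' @param master_seed integer master seed.
#' @param population_ranges named list of `c(min, max)` intervals overriding
#'   the defaults; a degenerate interval (min > max) is an error.
#' @param reader1,reader2 [reader_perturbation()] templates (their `seed`
#'   fields are replaced by derived per-lesion seeds).
#' @return an object of class `synthetic_cohort` with parallel lists
#'   `volumes`, `truth_masks`, `reader1_masks`, `reader2_masks`,
#'   `lesion_specs` and bookkeeping (`spacings`, `seeds`, `master_seed`).
#' @export
generate_cohort <- function(n_lesions, master_seed,
                            population_ranges = list(),
                            reader1 = reader_perturbation(radial_bias = 0.3,
                                                          reader_id = "R1"),
                            reader2 = reader_perturbation(radial_bias = -0.3,
                                                          reader_id = "R2")) {
  if (n_lesions < 1) stop("n_lesions must be >= 1")
  ranges <- utils::modifyList(default_population_ranges(), population_ranges)
  for (nm in names(ranges)) {
    rg <- ranges[[nm]]
    if (length(rg) != 2L || rg[1] > rg[2])
      stop(sprintf("degenerate range for %s (min > max)", nm))
  }
  draws <- with_seed(master_seed, {
    pars <- lapply(ranges, function(rg) stats::runif(n_lesions, rg[1], rg[2]))
    inplane <- stats::runif(n_lesions, 0.7, 0.9)
    slice <- sample(c(2.5, 3), n_lesions, replace = TRUE)
    seeds <- matrix(sample.int(.Machine$integer.max - 1L, 3L * n_lesions),
                    n_lesions, 3L)
    list(pars = pars, inplane = inplane, slice = slice, seeds = seeds)
  })
  volumes <- truth <- r1 <- r2 <- specs <- vector("list", n_lesions)
  spacings <- matrix(NA_real_, n_lesions, 3L)
  for (i in seq_len(n_lesions)) {
    p <- lapply(draws$pars, `[`, i)
    spec <- lesion_spec(target_diameter = p$target_diameter,
                        lesion_mean_hu = p$lesion_mean_hu,
                        background_mean_hu = p$background_mean_hu,
                        texture_correlation_length = p$texture_correlation_length,
                        noise_sd = p$noise_sd,
                        boundary_blur_sigma = p$boundary_blur_sigma,
                        shape_irregularity = p$shape_irregularity)
    sp <- c(draws$inplane[i], draws$inplane[i], draws$slice[i])
    gs <- 2L * as.integer(ceiling(spec$target_diameter / sp)) + 3L
    gen <- generate_lesion_volume(spec, gs, sp, seed = draws$seeds[i, 1L])
    m1 <- simulate_reader_retry(gen$truth, reader1, draws$seeds[i, 2L])
    m2 <- simulate_reader_retry(gen$truth, reader2, draws$seeds[i, 3L])
    if (!any(m1$values & gen$truth$values) || !any(m2$values & gen$truth$values))
      stop("reader mask does not overlap truth; perturbation too strong")
    volumes[[i]] <- gen$volume; truth[[i]] <- gen$truth
    r1[[i]] <- m1; r2[[i]] <- m2; specs[[i]] <- spec
    spacings[i, ] <- sp
  }
  structure(list(volumes = volumes, truth_masks = truth,
                 reader1_masks = r1, reader2_masks = r2,
                 lesion_specs = specs, spacings = spacings,
                 seeds = draws$seeds, master_seed = as.integer(master_seed),
                 reader1 = reader1, reader2 = reader2),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d lesions, master seed %d\n",
              length(x$volumes), x$master_seed))
  invisible(x)
}

#' Write a cohort to NIfTI files plus a JSON manifest
#'
#' One volume and three labelmaps (truth, reader 1, reader 2) per lesion;
#' the manifest records file names, lesion parameters and seeds so the
#' cohort can be re-ingested by the labelmap-directory pipeline mode.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return path of the manifest file, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- length(cohort$volumes)
  lesions <- vector("list", n)
  for (i in seq_len(n)) {
    id <- sprintf("lesion%03d", i)
    fv <- sprintf("%s_volume.nii.gz", id)
    ft <- sprintf("%s_truth.nii.gz", id)
    f1 <- sprintf("%s_reader1.nii.gz", id)
    f2 <- sprintf("%s_reader2.nii.gz", id)
    write_nifti(cohort$volumes[[i]], file.path(dir, fv))
    write_nifti(cohort$truth_masks[[i]], file.path(dir, ft))
    write_nifti(cohort$reader1_masks[[i]], file.path(dir, f1))
    write_nifti(cohort$reader2_masks[[i]], file.path(dir, f2))
    lesions[[i]] <- list(id = id, volume = fv, truth = ft,
                         reader1_mask = f1, reader2_mask = f2,
                         spec = unclass(cohort$lesion_specs[[i]]),
                         seeds = cohort$seeds[i, ])
  }
  manifest <- list(master_seed = cohort$master_seed, n_lesions = n,
                   lesions = lesions)
  mf <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(mf)
}
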