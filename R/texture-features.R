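# The 32 GLCM/GLRLM texture features (IBSI reference formulas) plus
# morphology features.

#' Feature rosters
#'
#' Names of the 21 GLCM features, the 11 GLRLM features, and the morphology
#' features, in the stable column order used throughout the package.
#' `Homogeneity` is the IBSI inverse difference and `Homogeneity2` the IBSI
#' inverse difference moment (IBEX naming mapped onto IBSI definitions).
#'
#' @return character vector of feature names.
#' @export
glcm_feature_names <- function() {
  c("AutoCorrelation", "ClusterProminence", "ClusterShade", "ClusterTendency",
    "Contrast", "Correlation", "DifferenceEntropy", "Dissimilarity",
    "Energy", "Entropy", "Homogeneity", "Homogeneity2",
    "InformationMeasureCorrel1", "InformationMeasureCorrel2",
    "InverseDifferMomentNormal", "InverseDifferNormal", "InverseVariance",
    "MaxProbability", "SumAverage", "SumEntropy", "SumVariance")
}

#' @rdname glcm_feature_names
#' @export
glrlm_feature_names <- function() {
  c("GLNU", "HGLRE", "LRE", "LRHGLE", "LRLGLE", "LGLRE", "RLNU",
    "RunPercentage", "SRE", "SRHGLE", "SRLGLE")
}

#' @rdname glcm_feature_names
#' @export
morphology_feature_names <- function() {
  c("Max3DDiameter", "NumberOfVoxels", "Volume")
}

#' @rdname glcm_feature_names
#' @export
texture_feature_names <- function() c(glrlm_feature_names(), glcm_feature_names())

xlog2 <- function(p) ifelse(p > 0, p * log2(p), 0)

#' GLCM texture features
#'
#' Computes the 21 co-occurrence features from an aggregated, normalized
#' GLCM by the IBSI reference formulas, with all marginal quantities (row
#' means/variances, diagonal and cross-diagonal distributions, entropies)
#' derived from the same matrix. Entropies use base-2 logarithms. On a
#' zero-variance (single-grey-level) matrix, `Correlation`,
#' `InformationMeasureCorrel1`, `InformationMeasureCorrel2` and
#' `InverseVariance` are undefined and return `NaN` as the documented
#' sentinel.
#'
#' @param m a `glcm_matrix` (from [build_glcm()]) or `texture_matrices`.
#' @return named numeric vector of 21 features.
#' @export
glcm_features <- function(m) {
  if (inherits(m, "texture_matrices")) m <- m$glcm
  stopifnot(inherits(m, "glcm_matrix"))
  p <- m$p
  ng <- nrow(p)
  i <- row(p); j <- col(p)
  px <- rowSums(p); py <- colSums(p)
  lev <- seq_len(ng)
  mux <- sum(lev * px); muy <- sum(lev * py)
  sigx <- sqrt(sum((lev - mux)^2 * px)); sigy <- sqrt(sum((lev - muy)^2 * py))

  # diagonal p_{x-y} (k = 0..ng-1) and cross-diagonal p_{x+y} (k = 2..2ng)
  pdiff <- vapply(0:(ng - 1L), function(k) sum(p[abs(i - j) == k]), 0)
  psum <- vapply(2:(2L * ng), function(k) sum(p[(i + j) == k]), 0)
  ksum <- 2:(2L * ng)

  hxy <- -sum(xlog2(p))
  hx <- -sum(xlog2(px)); hy <- -sum(xlog2(py))
  pxpy <- outer(px, py)
  hxy1 <- -sum(p * ifelse(pxpy > 0, log2(pxpy), 0))
  hxy2 <- -sum(xlog2(pxpy))

  degenerate <- sigx < 1e-14 || sigy < 1e-14
  correlation <- if (degenerate) NaN else
    (sum(i * j * p) - mux * muy) / (sigx * sigy)
  imc1 <- if (degenerate) NaN else (hxy - hxy1) / max(hx, hy)
  imc2 <- if (degenerate) NaN else sqrt(pmax(1 - exp(-2 * (hxy2 - hxy)), 0))
  invvar <- if (degenerate) NaN else {
    off <- i != j
    sum(p[off] / (i[off] - j[off])^2)
  }

  sa <- sum(ksum * psum)
  mu_ij <- mux + muy
  c(AutoCorrelation = sum(i * j * p),
    ClusterProminence = sum((i + j - mu_ij)^4 * p),
    ClusterShade = sum((i + j - mu_ij)^3 * p),
    ClusterTendency = sum((i + j - mu_ij)^2 * p),
    Contrast = sum((i - j)^2 * p),
    Correlation = correlation,
    DifferenceEntropy = -sum(xlog2(pdiff)),
    Dissimilarity = sum(abs(i - j) * p),
    Energy = sum(p^2),
    Entropy = hxy,
    Homogeneity = sum(p / (1 + abs(i - j))),
    Homogeneity2 = sum(p / (1 + (i - j)^2)),
    InformationMeasureCorrel1 = imc1,
    InformationMeasureCorrel2 = imc2,
    InverseDifferMomentNormal = sum(p / (1 + (i - j)^2 / ng^2)),
    InverseDifferNormal = sum(p / (1 + abs(i - j) / ng)),
    InverseVariance = invvar,
    MaxProbability = max(p),
    SumAverage = sa,
    SumEntropy = -sum(xlog2(psum)),
    SumVariance = sum((ksum - sa)^2 * psum))
}

#' GLRLM texture features
#'
#' Computes the 11 run-length features from the direction-summed run
#' matrix. Under this convention `RunPercentage` divides the total number
#' of runs by `n_voxels * n_directions`, so it equals 1 for a fully
#' heterogeneous ROI regardless of direction count.
#'
#' @param m a `glrlm_matrix` (from [build_glrlm()]) or `texture_matrices`.
#' @param n_voxels foreground voxel count; defaults to the count recorded
#'   in `m`.
#' @return named numeric vector of 11 features.
#' @export
glrlm_features <- function(m, n_voxels = NULL) {
  if (inherits(m, "texture_matrices")) m <- m$glrlm
  stopifnot(inherits(m, "glrlm_matrix"))
  r <- m$r
  n_voxels <- n_voxels %||% m$n_voxels
  ns <- sum(r)
  if (ns == 0) stop("empty run length matrix")
  gl <- seq_len(nrow(r))   # grey level i
  rl <- seq_len(ncol(r))   # run length j
  ri <- rowSums(r); rj <- colSums(r)
  c(GLNU = sum(ri^2) / ns,
    HGLRE = sum(ri * gl^2) / ns,
    LRE = sum(rj * rl^2) / ns,
    LRHGLE = sum(r * outer(gl^2, rl^2)) / ns,
    LRLGLE = sum(r * outer(1 / gl^2, rl^2)) / ns,
    LGLRE = sum(ri / gl^2) / ns,
    RLNU = sum(rj^2) / ns,
    RunPercentage = ns / (n_voxels * m$n_directions),
    SRE = sum(rj / rl^2) / ns,
    SRHGLE = sum(r * outer(gl^2, 1 / rl^2)) / ns,
    SRLGLE = sum(r * outer(1 / gl^2, 1 / rl^2)) / ns)
}

#' Morphology features
#'
#' `NumberOfVoxels` is the foreground count, `Volume` the count times the
#' voxel volume in cm^3, and `Max3DDiameter` the maximum pairwise Euclidean
#' distance (mm) between surface voxel centers.
#'
#' @param mask a nonempty [roi_mask()].
#' @param spacing voxel spacing in mm; defaults to the mask spacing.
#' @return named numeric vector of 3 features.
#' @export
morphology_features <- function(mask, spacing = mask$spacing) {
  stop_if_empty(mask)
  n <- n_foreground(mask)
  c(Max3DDiameter = max_3d_diameter_mm(mask),
    NumberOfVoxels = n,
    Volume = n * prod(spacing) / 1000)
}

#' Extract the full feature vector of one ROI
#'
#' Discretizes the ROI, builds the aggregated GLCM and GLRLM, and returns
#' the 32 texture features (11 GLRLM + 21 GLCM) plus the morphology
#' features, with provenance recorded as attributes. Deterministic for
#' fixed inputs.
#'
#' @param volume an [intensity_volume()].
#' @param mask a nonempty [roi_mask()] aligned with `volume`.
#' @param config a [discretization_config()].
#' @param mode `"3D"` or `"2D"`; defaults to `"2D"` for 2D-axial masks.
#' @return named numeric vector of 35 values, class `feature_vector`, with
#'   attributes `reader_id`, `shape_tag`, `mode`, `n_clamped`.
#' @export
extract_features <- function(volume, mask, config = discretization_config(),
                             mode = NULL) {
  mode <- mode %||% if (mask$dimensionality == "2D-axial") "2D" else "3D"
  d <- discretize(volume, mask, config)
  tm <- texture_matrices(d, mode)
  out <- c(glrlm_features(tm), glcm_features(tm), morphology_features(mask))
  structure(out, class = "feature_vector",
            reader_id = mask$reader_id, shape_tag = mask$shape_tag,
            mode = mode, n_clamped = d$n_clamped)
}

#' @export
print.feature_vector <- function(x, ...) {
  cat(sprintf("<feature_vector> mode %s, shape %s, reader %s\n",
              attr(x, "mode"), attr(x, "shape_tag"), attr(x, "reader_id")))
  print(unclass(x), ...)
  invisible(x)
}
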