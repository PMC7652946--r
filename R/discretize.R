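#' Fixed-range intensity discretization configuration
#'
#' The default window spans 480 grey levels, from -200 to 279 HU, divided
#' into 32 uniform bins of 15 HU each; texture matrices use voxel offset 1
#' and symmetric pair counting. The number of grey levels
#' (`hu_max - hu_min + 1`) must be divisible by `n_bins`.
#'
#' @param hu_min,hu_max window bounds in HU (inclusive).
#' @param n_bins number of uniform bins (>= 2).
#' @param offset co-occurrence offset in voxel steps.
#' @param symmetric logical; count both orderings of each voxel pair.
#' @return an object of class `discretization_config`.
#' @export
discretization_config <- function(hu_min = -200, hu_max = 279, n_bins = 32L,
                                  offset = 1L, symmetric = TRUE) {
  if (hu_max <= hu_min) stop("hu_max must exceed hu_min")
  n_bins <- as.integer(n_bins)
  if (n_bins < 2L) stop("n_bins must be >= 2")
  n_levels <- hu_max - hu_min + 1
  if (n_levels %% n_bins != 0)
    stop(sprintf("%g grey levels are not divisible into %d uniform bins",
                 n_levels, n_bins))
  if (offset != 1L) stop("only offset = 1 is supported")
  structure(list(hu_min = hu_min, hu_max = hu_max, n_bins = n_bins,
                 bin_width = n_levels / n_bins, offset = as.integer(offset),
                 symmetric = isTRUE(symmetric)),
            class = "discretization_config")
}

#' Discretize ROI intensities into grey-level bins
#'
#' Bin label = `floor((clamp(HU) - hu_min) / bin_width) + 1`, with bins
#' left-closed/right-open and the last bin right-closed (HU = `hu_max`
#' maps to bin `n_bins`). Intensities outside the window are clamped to the
#' nearest bin and counted.
#'
#' @param volume an [intensity_volume()].
#' @param mask a nonempty [roi_mask()] aligned with `volume`.
#' @param config a [discretization_config()].
#' @return an object of class `discretized_roi`: `bin_labels` (integer
#'   array, `NA` outside the mask), `mask`, `config`, `n_clamped`.
#' @export
discretize <- function(volume, mask, config = discretization_config()) {
  stopifnot(inherits(volume, "intensity_volume"), inherits(mask, "roi_mask"),
            inherits(config, "discretization_config"))
  stop_if_empty(mask)
  check_alignment(dim(mask$values), mask$spacing, volume)
  fg <- which(mask$values)
  hu <- volume$values[fg]
  n_clamped <- sum(hu < config$hu_min | hu > config$hu_max)
  if (n_clamped == length(hu))
    warning("all foreground voxels fall outside the discretization window; texture is degenerate")
  hu <- clamp(hu, config$hu_min, config$hu_max)
  lab <- pmin(floor((hu - config$hu_min) / config$bin_width) + 1L, config$n_bins)
  labels <- array(NA_integer_, dim(mask$values))
  labels[fg] <- as.integer(lab)
  structure(list(bin_labels = labels, mask = mask, config = config,
                 n_clamped = n_clamped),
            class = "discretized_roi")
}
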