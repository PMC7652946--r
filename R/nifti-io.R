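# NIfTI input/output for intensity volumes and binary labelmaps (RNifti).

#' Read an intensity volume from NIfTI
#'
#' @param path path to a `.nii` or `.nii.gz` scalar image.
#' @return an [intensity_volume()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) > 3L) {
    if (prod(d[-(1:3)]) != 1L) stop("expected a 3D scalar NIfTI image")
    dim(img) <- d[1:3]
  } else if (length(d) < 3L) {
    stop("expected a 3D scalar NIfTI image")
  }
  pd <- RNifti::pixdim(img)[1:3]
  intensity_volume(array(as.numeric(img), dim(img)), spacing = pd)
}

#' Read a binary labelmap from NIfTI
#'
#' The labelmap grid and spacing must match the parent volume exactly;
#' nonzero voxels are treated as foreground (with a warning if the file
#' carries more than two distinct values).
#'
#' @param path path to a `.nii` or `.nii.gz` labelmap.
#' @param parent the parent [intensity_volume()] the mask annotates.
#' @inheritParams roi_mask
#' @return a [roi_mask()].
#' @export
read_labelmap <- function(path, parent, dimensionality = "3D",
                          shape_tag = "manual", reader_id = NA_character_) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) > 3L) {
    if (prod(d[-(1:3)]) != 1L) stop("expected a 3D labelmap")
    dim(img) <- d[1:3]
  }
  pd <- RNifti::pixdim(img)[1:3]
  check_alignment(dim(img), pd, parent)
  roi_mask(array(as.numeric(img), dim(img)), spacing = parent$spacing,
           dimensionality = dimensionality, shape_tag = shape_tag,
           reader_id = reader_id, origin = parent$origin)
}

#' Write a volume or mask to NIfTI
#'
#' Masks are written as unsigned 8-bit labelmaps (0/1), volumes as 32-bit
#' float; a write/read round trip reproduces a binary mask exactly.
#'
#' @param x an [intensity_volume()] or [roi_mask()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_nifti <- function(x, path) {
  if (inherits(x, "roi_mask")) {
    arr <- array(as.integer(x$values), dim(x$values))
    attr(arr, "pixdim") <- x$spacing
    img <- RNifti::asNifti(arr, datatype = "uint8")
  } else if (inherits(x, "intensity_volume")) {
    arr <- x$values
    attr(arr, "pixdim") <- x$spacing
    img <- RNifti::asNifti(arr, datatype = "float")
  } else stop("`x` must be an intensity_volume or roi_mask")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_nifti
#' @param mask a [roi_mask()] (alias kept for labelmap-specific call sites).
#' @export
write_labelmap <- function(mask, path) {
  stopifnot(inherits(mask, "roi_mask"))
  write_nifti(mask, path)
}
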