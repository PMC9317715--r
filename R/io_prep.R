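#' Pancreas volume container
#'
#' Bundles a 3D intensity grid with its binary pancreas mask, physical voxel
#' spacing and an orientation code. All downstream operations (feature
#' extraction, Bayes soft labels, the segmentation network) work on this
#' container.
#'
#' @param intensities 3D numeric array of voxel intensities.
#' @param mask 3D array (logical or 0/1) of the same shape; `TRUE`/1 marks
#'   pancreas voxels.
#' @param spacing numeric(3), physical voxel size per axis in mm.
#' @param orientation three-letter axis code (e.g. `"RAS"`); used by the
#'   laterality rule that places the pancreatic head on the patient's right
#'   (image left on the axial view).
#' @return An object of class `pancreas_volume`.
#' @export
pancreas_volume <- function(intensities, mask, spacing = c(1, 1, 1),
                            orientation = "RAS") {
  intensities <- as.array(intensities)
  mask <- as.array(mask)
  if (!identical(dim(intensities), dim(mask)))
    stop("intensities and mask must have identical shape")
  if (length(dim(intensities)) != 3L)
    stop("volumes must be 3D")
  storage.mode(intensities) <- "double"
  mask <- array(as.logical(mask), dim = dim(mask))
  if (anyNA(mask)) stop("mask must not contain NA")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive numbers")
  structure(list(intensities = intensities, mask = mask,
                 spacing = spacing, orientation = orientation),
            class = "pancreas_volume")
}

#' @export
print.pancreas_volume <- function(x, ...) {
  d <- dim(x$mask)
  cat(sprintf("<pancreas_volume> %dx%dx%d voxels, spacing %s mm, %d pancreas voxels\n",
              d[1], d[2], d[3], paste(format(x$spacing, digits = 3), collapse = "x"),
              sum(x$mask)))
  invisible(x)
}

validate_labels <- function(labels, mask = NULL) {
  labels <- as.array(labels)
  if (anyNA(labels)) stop("labels must not contain NA")
  if (any(labels != round(labels))) stop("non-integer label values")
  labels <- array(as.integer(labels), dim = dim(labels))
  bad <- setdiff(unique(as.vector(labels)), c(0L, unname(SUBREGIONS)))
  if (length(bad))
    stop("unknown label value(s): ", paste(bad, collapse = ", "))
  if (!is.null(mask)) {
    if (!identical(dim(labels), dim(mask)))
      stop("shape mismatch between image and labels")
    if (any((labels > 0L) != mask))
      stop("labels must be nonzero exactly on the pancreas mask")
  }
  labels
}

nifti_spacing <- function(img) {
  p <- attr(img, "pixdim")
  if (is.null(p)) p <- RNifti::pixdim(img)
  p <- as.numeric(p)[1:3]
  p[!is.finite(p) | p <= 0] <- 1
  p
}

#' Read a pancreas CT volume (and optional subregion labels) from NIfTI
#'
#' @param path NIfTI image file (.nii or .nii.gz).
#' @param mask_path optional NIfTI binary pancreas mask. When absent the
#'   mask is taken from `label_path` (labels > 0) or, failing that, from
#'   nonzero image intensities (the convention after background zeroing).
#' @param label_path optional NIfTI integer label volume
#'   (0 background, 1 head, 2 body, 3 tail).
#' @return A list with elements `volume` (a [pancreas_volume]) and
#'   `labels` (integer array or `NULL`).
#' @export
read_pancreas_volume <- function(path, mask_path = NULL, label_path = NULL) {
  if (!file.exists(path)) stop("missing file: ", path)
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim = dim(img))
  spacing <- nifti_spacing(img)
  orientation <- tryCatch(RNifti::orientation(img), error = function(e) "RAS")

  labels <- NULL
  if (!is.null(label_path)) {
    if (!file.exists(label_path)) stop("missing file: ", label_path)
    lab <- RNifti::readNifti(label_path)
    if (!identical(dim(lab)[1:3], dim(arr)))
      stop("shape mismatch between image and labels")
    labels <- validate_labels(array(as.numeric(lab), dim = dim(arr)))
  }
  if (!is.null(mask_path)) {
    if (!file.exists(mask_path)) stop("missing file: ", mask_path)
    msk <- RNifti::readNifti(mask_path)
    if (!identical(dim(msk)[1:3], dim(arr)))
      stop("shape mismatch between image and mask")
    mask <- array(as.numeric(msk) != 0, dim = dim(arr))
  } else if (!is.null(labels)) {
    mask <- labels > 0L
  } else {
    mask <- arr != 0
  }
  vol <- pancreas_volume(arr, mask, spacing = spacing, orientation = orientation)
  if (!is.null(labels)) labels <- validate_labels(labels, vol$mask)
  list(volume = vol, labels = labels)
}

as_nifti_with_spacing <- function(arr, spacing) {
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- spacing
  img
}

#' Write a pancreas volume (and optional mask/labels) as NIfTI
#'
#' @param vol a [pancreas_volume].
#' @param path output image file.
#' @param mask_path,label_path optional output files for the binary mask
#'   and the integer label volume.
#' @param labels integer label array (required when `label_path` is given).
#' @return Invisibly, `path`.
#' @export
write_pancreas_volume <- function(vol, path, mask_path = NULL,
                                  label_path = NULL, labels = NULL) {
  RNifti::writeNifti(as_nifti_with_spacing(vol$intensities, vol$spacing), path)
  if (!is.null(mask_path))
    RNifti::writeNifti(as_nifti_with_spacing(array(as.integer(vol$mask),
                                                   dim = dim(vol$mask)),
                                             vol$spacing), mask_path)
  if (!is.null(label_path)) {
    if (is.null(labels)) stop("labels required to write label_path")
    RNifti::writeNifti(as_nifti_with_spacing(labels, vol$spacing), label_path)
  }
  invisible(path)
}

# connected components of a binary mask under 26-connectivity,
# found by repeated Dijkstra floods (unit spacing)
mask_components <- function(mask) {
  comp <- array(0L, dim = dim(mask))
  remaining <- mask
  k <- 0L
  while (any(remaining)) {
    k <- k + 1L
    src <- which(remaining)[1L]
    d <- cpp_geodesic(as.vector(remaining), dim(mask), src, c(1, 1, 1))
    reached <- is.finite(d)
    comp[reached] <- k
    remaining[reached] <- FALSE
  }
  comp
}

#' Check that a pancreas mask is a single 26-connected component
#'
#' The subregion model assumes one whole pancreas. By default a mask with
#' several components is an error; `keep_largest = TRUE` instead drops all
#' but the largest component (useful for masks with stray islands).
#'
#' @param vol a [pancreas_volume].
#' @param keep_largest keep only the largest component instead of erroring.
#' @return The (possibly cleaned) volume, invisibly unchanged when already
#'   a single component.
#' @export
assert_connected_mask <- function(vol, keep_largest = FALSE) {
  if (!any(vol$mask)) stop("empty mask")
  comp <- mask_components(vol$mask)
  ncomp <- max(comp)
  if (ncomp == 1L) return(vol)
  if (!keep_largest)
    stop(sprintf("pancreas mask has %d connected components (expected 1)", ncomp))
  sizes <- tabulate(comp[comp > 0L], nbins = ncomp)
  keep <- which.max(sizes)
  vol$mask <- comp == keep
  vol$intensities[!vol$mask] <- 0
  vol
}

#' Crop a volume to the pancreas bounding box
#'
#' Crops image, mask and (optionally) labels to the tight bounding box of
#' the mask plus `padding` voxels per side, clipped at the volume bounds.
#' No pancreas voxel is ever removed. The returned offset allows exact
#' uncropping with [uncrop_array()].
#'
#' @param vol a [pancreas_volume].
#' @param labels optional integer label array of the same shape.
#' @param padding voxels of margin added on every side (default 8).
#' @param sidecar optional path: write offset/padding/original dimensions
#'   as a JSON sidecar for later uncropping.
#' @return list with `volume`, `labels` (or `NULL`), `offset` (1-based
#'   start index of the crop in the original grid) and `original_dim`.
#' @export
crop_to_pancreas <- function(vol, labels = NULL, padding = 8, sidecar = NULL) {
  if (!any(vol$mask)) stop("empty mask")
  d <- dim(vol$mask)
  idx <- which(vol$mask, arr.ind = TRUE)
  lo <- pmax(apply(idx, 2, min) - padding, 1L)
  hi <- pmin(apply(idx, 2, max) + padding, d)
  sel <- lapply(1:3, function(a) lo[a]:hi[a])
  cvol <- pancreas_volume(
    vol$intensities[sel[[1]], sel[[2]], sel[[3]], drop = FALSE],
    vol$mask[sel[[1]], sel[[2]], sel[[3]], drop = FALSE],
    spacing = vol$spacing, orientation = vol$orientation)
  clab <- NULL
  if (!is.null(labels)) {
    if (!identical(dim(labels), d)) stop("shape mismatch between image and labels")
    clab <- labels[sel[[1]], sel[[2]], sel[[3]], drop = FALSE]
  }
  out <- list(volume = cvol, labels = clab, offset = as.integer(lo),
              original_dim = as.integer(d))
  if (!is.null(sidecar))
    jsonlite::write_json(list(offset = out$offset, padding = padding,
                              original_dim = out$original_dim),
                         sidecar, auto_unbox = FALSE)
  out
}

#' Undo a pancreas crop
#'
#' Places a cropped array back at its original position; everything outside
#' the crop window is `fill`.
#'
#' @param arr cropped 3D array.
#' @param offset 1-based start index returned by [crop_to_pancreas()].
#' @param original_dim dimensions of the original grid.
#' @param fill value outside the crop window (0 by default).
#' @return 3D array of `original_dim`.
#' @export
uncrop_array <- function(arr, offset, original_dim, fill = 0) {
  out <- array(fill, dim = original_dim)
  d <- dim(arr)
  out[offset[1] + seq_len(d[1]) - 1L,
      offset[2] + seq_len(d[2]) - 1L,
      offset[3] + seq_len(d[3]) - 1L] <- arr
  out
}

#' Min-max normalize pancreas intensities
#'
#' Linearly rescales intensities to \[0, 1\] using the minimum and maximum
#' over pancreas voxels only, and sets every background voxel to exactly 0.
#' A constant-intensity pancreas maps to all zeros. Idempotent, and
#' invariant to affine rescaling `a*I + b` (a > 0) of the input.
#'
#' @param vol a [pancreas_volume].
#' @return The normalized [pancreas_volume].
#' @export
normalize_intensities <- function(vol) {
  if (!any(vol$mask)) stop("empty mask")
  v <- vol$intensities[vol$mask]
  rng <- range(v)
  out <- array(0, dim = dim(vol$intensities))
  if (rng[2] > rng[1])
    out[vol$mask] <- (v - rng[1]) / (rng[2] - rng[1])
  vol$intensities <- out
  vol
}

#' Standard preprocessing: connectivity check, crop, normalize
#'
#' Convenience wrapper applying the full preprocessing path: single
#' connected component check, crop to the padded pancreas bounding box,
#' background zeroing and min-max intensity normalization.
#'
#' @inheritParams crop_to_pancreas
#' @param keep_largest passed to [assert_connected_mask()].
#' @return As [crop_to_pancreas()], with the volume normalized.
#' @export
preprocess_volume <- function(vol, labels = NULL, padding = 8,
                              keep_largest = FALSE) {
  vol <- assert_connected_mask(vol, keep_largest = keep_largest)
  if (!is.null(labels)) labels <- validate_labels(labels, vol$mask)
  cr <- crop_to_pancreas(vol, labels, padding = padding)
  cr$volume <- normalize_intensities(cr$volume)
  cr
}
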