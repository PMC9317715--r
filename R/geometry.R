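# Anatomical geometry of the pancreas mask: mask-constrained (geodesic)
# distances, head endpoint y_f, organ length l, and the two normalized
# features used by the Bayes soft-label model:
#   alpha' = geodesic distance from y_f, as a fraction of the organ length l
#   beta'  = pancreas volume swept between y_f and the voxel, as a fraction
#            of the total pancreas volume A

lin_index <- function(coord, d) {
  as.integer(coord[1] + d[1] * (coord[2] - 1L) + d[1] * d[2] * (coord[3] - 1L))
}

coord_of <- function(lin, d) {
  lin <- lin - 1L
  x <- lin %% d[1]
  y <- (lin %/% d[1]) %% d[2]
  z <- lin %/% (d[1] * d[2])
  cbind(x + 1L, y + 1L, z + 1L)
}

# lexicographically smallest (x, y, z) among linear indices
lex_min <- function(lin, d) {
  co <- coord_of(lin, d)
  lin[order(co[, 1], co[, 2], co[, 3])[1L]]
}

#' Geodesic distance map inside a binary mask
#'
#' Shortest-path distance of every mask voxel from one or more source
#' voxels, where paths move between 26-connected neighbours and must stay
#' inside the mask. Edge weights are Euclidean step lengths in mm, so
#' anisotropic voxels are handled. Voxels outside the mask (or unreachable
#' from the sources) are `Inf`.
#'
#' @param mask 3D logical/binary array.
#' @param source voxel index of the source: integer(3) array index, or a
#'   matrix of such rows for a multi-source map, or 1-based linear indices.
#' @param spacing numeric(3) voxel size in mm.
#' @return 3D numeric array of distances (mm).
#' @export
geodesic_distance_map <- function(mask, source, spacing = c(1, 1, 1)) {
  mask <- array(as.logical(mask), dim = dim(mask))
  d <- dim(mask)
  if (is.matrix(source)) {
    src <- apply(source, 1, lin_index, d = d)
  } else if (length(source) == 3L && !is.null(dim(mask)) &&
             all(source >= 1) && all(source <= d)) {
    src <- lin_index(as.integer(source), d)
  } else {
    src <- as.integer(source)
  }
  if (any(!mask[src])) stop("source voxel lies outside the mask")
  dist <- cpp_geodesic(as.vector(mask), d, as.integer(src), as.numeric(spacing))
  array(dist, dim = d)
}

#' Locate the head endpoint y_f of the pancreas
#'
#' With training labels, y_f is the head voxel geodesically farthest from
#' any body or tail voxel (the anatomical start of the organ). Without
#' labels, the two endpoints of the organ's pseudo-diameter are found by a
#' double sweep (farthest voxel from an arbitrary start, then farthest from
#' that), and the head end is picked by the laterality convention: on the
#' axial view the head appears on the side given by `head_side` along
#' `head_axis` (default: low first-axis coordinate).
#'
#' @param mask 3D binary array (single 26-connected component).
#' @param labels optional integer label array (1 head, 2 body, 3 tail);
#'   all three subregions must be present.
#' @param spacing voxel size in mm.
#' @param head_axis,head_side laterality convention used without labels:
#'   the endpoint whose `head_axis` coordinate is lowest (`"low"`) or
#'   highest (`"high"`) is called the head.
#' @return integer(3) voxel index of y_f.
#' @export
find_head_endpoint <- function(mask, labels = NULL, spacing = c(1, 1, 1),
                               head_axis = 1L, head_side = c("low", "high")) {
  head_side <- match.arg(head_side)
  mask <- array(as.logical(mask), dim = dim(mask))
  d <- dim(mask)
  if (!any(mask)) stop("empty mask")

  if (!is.null(labels)) {
    labels <- validate_labels(labels, mask)
    present <- vapply(SUBREGIONS, function(s) any(labels == s), logical(1))
    if (!all(present))
      stop("labels missing subregion(s): ",
           paste(SUBREGION_NAMES[!present], collapse = ", "))
    sources <- which(labels == SUBREGIONS["body"] | labels == SUBREGIONS["tail"])
    dist <- cpp_geodesic(as.vector(mask), d, sources, as.numeric(spacing))
    head_idx <- which(labels == SUBREGIONS["head"])
    dh <- dist[head_idx]
    if (any(!is.finite(dh))) stop("disconnected mask")
    best <- head_idx[dh == max(dh)]
    return(as.integer(coord_of(lex_min(best, d), d)))
  }

  # double-sweep pseudo-diameter
  start <- lex_min(which(mask), d)
  d1 <- cpp_geodesic(as.vector(mask), d, start, as.numeric(spacing))
  if (any(!is.finite(d1[mask]))) stop("disconnected mask")
  a <- lex_min(which(d1 == max(d1[mask])), d)
  d2 <- cpp_geodesic(as.vector(mask), d, a, as.numeric(spacing))
  b <- lex_min(which(d2 == max(d2[mask])), d)
  ca <- coord_of(a, d)[1, ]
  cb <- coord_of(b, d)[1, ]
  pick_a <- if (head_side == "low") ca[head_axis] <= cb[head_axis]
            else ca[head_axis] >= cb[head_axis]
  as.integer(if (pick_a) ca else cb)
}

#' Pancreas length l and far endpoint z_f
#'
#' The organ length is the maximum geodesic distance from the head
#' endpoint y_f; z_f is the voxel attaining it (ties broken by the lowest
#' (x, y, z) lexicographic index).
#'
#' @param mask 3D binary array.
#' @param y_f head endpoint voxel index (integer(3)).
#' @param spacing voxel size in mm.
#' @return list with `l` (mm), `z_f` (integer(3)) and `dist` (the full
#'   geodesic map from y_f, reusable by the feature computations).
#' @export
pancreas_length <- function(mask, y_f, spacing = c(1, 1, 1)) {
  dist <- geodesic_distance_map(mask, y_f, spacing)
  d <- dim(dist)
  mvox <- which(as.logical(mask))
  dv <- dist[mvox]
  if (any(!is.finite(dv))) stop("disconnected mask")
  l <- max(dv)
  z_f <- as.integer(coord_of(lex_min(mvox[dv == l], d), d))
  list(l = l, z_f = z_f, dist = dist)
}

#' Normalized length feature alpha'
#'
#' Per-voxel geodesic distance from y_f divided by the organ length l,
#' clipped to \[0, 1\]. `NA` outside the mask. With
#' `metric = "euclidean"` the straight-line distance is used instead of
#' the mask-constrained path.
#'
#' @inheritParams pancreas_length
#' @param l organ length in mm (must be > 0).
#' @param metric `"geodesic"` (default) or `"euclidean"`.
#' @param dist optional precomputed geodesic map from y_f.
#' @return 3D numeric array, `NA` outside the mask.
#' @export
alpha_feature <- function(mask, y_f, l, spacing = c(1, 1, 1),
                          metric = c("geodesic", "euclidean"), dist = NULL) {
  metric <- match.arg(metric)
  if (l <= 0) stop("degenerate mask: l = 0")
  mask <- array(as.logical(mask), dim = dim(mask))
  if (metric == "geodesic") {
    if (is.null(dist)) dist <- geodesic_distance_map(mask, y_f, spacing)
  } else {
    co <- coord_of(which(mask), dim(mask))
    dv <- sqrt(((co[, 1] - y_f[1]) * spacing[1])^2 +
               ((co[, 2] - y_f[2]) * spacing[2])^2 +
               ((co[, 3] - y_f[3]) * spacing[3])^2)
    dist <- array(Inf, dim = dim(mask))
    dist[mask] <- dv
  }
  out <- array(NA_real_, dim = dim(mask))
  out[mask] <- pmin(pmax(dist[mask] / l, 0), 1)
  out
}

#' Normalized swept-volume feature beta'
#'
#' For each pancreas voxel, the number of pancreas voxels lying between the
#' head endpoint y_f and that voxel, as a fraction of the total pancreas
#' voxel count A. The default (`method = "cumulative"`) counts voxels whose
#' geodesic distance from y_f does not exceed the voxel's own, i.e. the
#' organ volume swept while travelling from y_f; this is well defined for
#' curved organs and reduces to the axis-aligned count on straight tubes.
#' `method = "bbox"` counts mask voxels in the axis-aligned bounding box
#' spanned by y_f and the voxel.
#'
#' @inheritParams alpha_feature
#' @param method `"cumulative"` (default) or `"bbox"`.
#' @return 3D numeric array in (0, 1\], `NA` outside the mask.
#' @export
beta_feature <- function(mask, y_f, spacing = c(1, 1, 1),
                         method = c("cumulative", "bbox"), dist = NULL) {
  method <- match.arg(method)
  mask <- array(as.logical(mask), dim = dim(mask))
  mvox <- which(mask)
  A <- length(mvox)
  out <- array(NA_real_, dim = dim(mask))
  if (method == "cumulative") {
    if (is.null(dist)) dist <- geodesic_distance_map(mask, y_f, spacing)
    dv <- dist[mvox]
    if (any(!is.finite(dv))) stop("disconnected mask")
    out[mvox] <- rank(dv, ties.method = "max") / A
  } else {
    co <- coord_of(mvox, dim(mask))
    for (i in seq_len(A)) {
      lo <- pmin(co[i, ], y_f); hi <- pmax(co[i, ], y_f)
      inside <- co[, 1] >= lo[1] & co[, 1] <= hi[1] &
                co[, 2] >= lo[2] & co[, 2] <= hi[2] &
                co[, 3] >= lo[3] & co[, 3] <= hi[3]
      out[mvox[i]] <- sum(inside) / A
    }
  }
  out
}

#' Compute the full anatomical feature set for one case
#'
#' Wires together [find_head_endpoint()], [pancreas_length()],
#' [alpha_feature()] and [beta_feature()]. With labels the training-mode
#' head endpoint is used; without labels the double-sweep endpoint with the
#' laterality convention.
#'
#' @param vol a [pancreas_volume] (or a bare 3D binary mask).
#' @param labels optional integer label array (training mode).
#' @param alpha_metric,beta_method passed to the feature computations.
#' @param head_axis,head_side laterality convention (inference mode).
#' @return An object of class `subregion_features`: list with 3D grids
#'   `alpha` and `beta` (`NA` outside the mask), endpoints `y_f`, `z_f`,
#'   `length_l` (mm), `area_A` (voxel count) and `spacing`.
#' @export
subregion_features <- function(vol, labels = NULL,
                               alpha_metric = "geodesic",
                               beta_method = "cumulative",
                               head_axis = 1L, head_side = "low") {
  if (inherits(vol, "pancreas_volume")) {
    mask <- vol$mask; spacing <- vol$spacing
  } else {
    mask <- array(as.logical(vol), dim = dim(vol)); spacing <- c(1, 1, 1)
  }
  y_f <- find_head_endpoint(mask, labels, spacing,
                            head_axis = head_axis, head_side = head_side)
  pl <- pancreas_length(mask, y_f, spacing)
  alpha <- alpha_feature(mask, y_f, pl$l, spacing, metric = alpha_metric,
                         dist = if (alpha_metric == "geodesic") pl$dist)
  beta <- beta_feature(mask, y_f, spacing, method = beta_method,
                       dist = if (beta_method == "cumulative") pl$dist)
  structure(list(alpha = alpha, beta = beta, y_f = y_f, z_f = pl$z_f,
                 length_l = pl$l, area_A = sum(mask), spacing = spacing,
                 mask = mask),
            class = "subregion_features")
}

#' @export
print.subregion_features <- function(x, ...) {
  cat(sprintf("<subregion_features> A = %d voxels, l = %.2f mm\n",
              x$area_A, x$length_l))
  cat(sprintf("  y_f = (%s), z_f = (%s)\n", paste(x$y_f, collapse = ","),
              paste(x$z_f, collapse = ",")))
  invisible(x)
}

#' Export feature maps and endpoint metadata for inspection
#'
#' @param feat a `subregion_features` object.
#' @param alpha_path,beta_path NIfTI output paths (float32 maps, `NA`
#'   replaced by -1 outside the mask).
#' @param meta_path optional JSON path for endpoints, length and volume.
#' @return Invisibly `NULL`.
#' @export
write_feature_maps <- function(feat, alpha_path, beta_path, meta_path = NULL) {
  a <- feat$alpha; a[is.na(a)] <- -1
  b <- feat$beta; b[is.na(b)] <- -1
  RNifti::writeNifti(as_nifti_with_spacing(a, feat$spacing), alpha_path,
                     datatype = "float")
  RNifti::writeNifti(as_nifti_with_spacing(b, feat$spacing), beta_path,
                     datatype = "float")
  if (!is.null(meta_path))
    jsonlite::write_json(list(y_f = feat$y_f, z_f = feat$z_f,
                              length_l = feat$length_l, area_A = feat$area_A),
                         meta_path, auto_unbox = FALSE, digits = NA)
  invisible(NULL)
}
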