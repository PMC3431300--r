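#' Nuclear center from the DAPI channel
#'
#' The nuclear center is the center of fluorescence intensity of the DAPI
#' channel: the intensity-weighted centroid over all above-threshold,
#' size-surviving DAPI voxels.
#'
#' @param dapi a [voxel_grid] (nuclear stain).
#' @param labels filtered DAPI label array from [segment_channel]; if
#'   missing, segmentation is run with the supplied parameters.
#' @param threshold,min_voxels,connectivity segmentation settings used when
#'   `labels` is missing.
#' @return Named numeric `(z, y, x)` in µm.
#' @export
nuclear_center <- function(dapi, labels = NULL, threshold = 25,
                           min_voxels = 10L, connectivity = 26L) {
  if (is.null(labels))
    labels <- segment_channel(dapi, threshold, min_voxels, connectivity)$labels
  idx <- which(labels > 0L)
  if (length(idx) == 0L) stop("no DAPI signal above threshold")
  w <- as.numeric(dapi$data[idx])
  sub0 <- arrayInd(idx, dim(labels)) - 1L
  ctr <- colSums(sub0 * w) / sum(w) * dapi$voxel_size
  names(ctr) <- c("z", "y", "x")
  ctr
}

#' Sphere-equivalent nuclear radius from the DAPI volume
#'
#' Assuming the nucleus is a sphere, the radius corresponding to a measured
#' DAPI volume `V` is `(3V / (4*pi))^(1/3)`.
#'
#' @param dapi_volume total DAPI volume in µm³ (> 0).
#' @return Radius in µm.
#' @export
radius_from_volume <- function(dapi_volume) {
  if (any(dapi_volume <= 0)) stop("dapi_volume must be > 0")
  (3 * dapi_volume / (4 * pi))^(1 / 3)
}

#' Nuclear radius from a circle fit to the widest z-slice
#'
#' Selects the z-slice with the largest above-threshold DAPI area and fits
#' a circle to that slice's mask boundary pixels by the algebraic
#' least-squares (Kasa) method, automating the manual widest-slice circle
#' fit. Boundary pixels are mask pixels with at least one 4-neighbour
#' outside the mask (image edges count as outside).
#'
#' Because the manual procedure fits the *outer* boundary of the DAPI
#' signal, interior gaps (interchromatin space, hollow-looking rims) are
#' filled slice-wise before the area is measured and the boundary
#' extracted, so only the rim determines the fit.
#'
#' @param dapi a [voxel_grid].
#' @param threshold DAPI intensity threshold.
#' @return Fitted radius in µm. Degenerate slices (< 3 boundary pixels)
#'   return half the mean in-plane voxel size, with a warning.
#' @export
radius_from_slice_fit <- function(dapi, threshold = 25) {
  mask <- threshold_mask(dapi, threshold)
  if (!any(mask)) stop("no DAPI signal above threshold")
  nz <- dim(mask)[1]
  filled <- lapply(seq_len(nz), function(zi) fill_holes_2d(mask[zi, , ]))
  areas <- vapply(filled, sum, numeric(1))
  zi <- which.max(areas)
  sl <- filled[[zi]]
  ny <- nrow(sl); nx <- ncol(sl)
  pad <- matrix(FALSE, ny + 2L, nx + 2L)
  pad[2:(ny + 1L), 2:(nx + 1L)] <- sl
  interior <- pad[1:ny, 2:(nx + 1L)] & pad[3:(ny + 2L), 2:(nx + 1L)] &
    pad[2:(ny + 1L), 1:nx] & pad[2:(ny + 1L), 3:(nx + 2L)]
  boundary <- sl & !interior
  pts <- which(boundary, arr.ind = TRUE)
  if (nrow(pts) < 3L) {
    warning("degenerate slice fit (< 3 boundary pixels); returning half a voxel")
    return(mean(dapi$voxel_size[2:3]) / 2)
  }
  y <- (pts[, 1] - 1) * dapi$voxel_size[2]
  x <- (pts[, 2] - 1) * dapi$voxel_size[3]
  # Kasa fit: minimise ||x^2 + y^2 - 2a x - 2b y - c||
  A <- cbind(2 * x, 2 * y, 1)
  b <- x^2 + y^2
  sol <- qr.solve(A, b)
  sqrt(sol[3] + sol[1]^2 + sol[2]^2)
}

# fill enclosed holes in a 2D logical mask: background components of the
# complement that do not touch the image border are part of the object
fill_holes_2d <- function(sl) {
  if (all(sl) || !any(sl)) return(sl)
  d <- dim(sl)
  comp <- label_components(array(!sl, c(1L, d[1], d[2])), 6L)$labels[1, , ]
  border <- unique(c(comp[1, ], comp[d[1], ], comp[, 1], comp[, d[2]]))
  border <- border[border > 0L]
  sl | (comp > 0L & !(comp %in% border))
}

#' Nuclear geometry model from the DAPI channel
#'
#' Combines the nuclear center, thresholded DAPI volume (above-threshold
#' size-surviving voxel count times voxel volume; interior gaps are not
#' filled), the sphere-equivalent radius, and the widest-slice circle-fit
#' radius into one model defining the nuclear radial coordinate system.
#'
#' @inheritParams nuclear_center
#' @param slice_fit also compute the slice-fit radius (default TRUE).
#' @return Object of class `nucleus_model`: list with `center` (µm),
#'   `dapi_volume` (µm³), `radius_volume`, `radius_fit` (µm or NA).
#' @export
fit_nucleus <- function(dapi, threshold = 25, min_voxels = 10L,
                        connectivity = 26L, slice_fit = TRUE) {
  labels <- segment_channel(dapi, threshold, min_voxels, connectivity)$labels
  n_vox <- sum(labels > 0L)
  if (n_vox == 0L) stop("no DAPI signal above threshold")
  vol <- n_vox * prod(dapi$voxel_size)
  structure(list(
    center = nuclear_center(dapi, labels = labels),
    dapi_volume = vol,
    radius_volume = radius_from_volume(vol),
    radius_fit = if (slice_fit) radius_from_slice_fit(dapi, threshold) else NA_real_),
    class = "nucleus_model")
}

#' @export
print.nucleus_model <- function(x, ...) {
  cat(sprintf("<nucleus_model> center (%.2f, %.2f, %.2f) µm; R_volume %.2f µm; R_fit %s µm; V %.1f µm³\n",
              x$center[1], x$center[2], x$center[3], x$radius_volume,
              ifelse(is.na(x$radius_fit), "NA", sprintf("%.2f", x$radius_fit)),
              x$dapi_volume))
  invisible(x)
}

#' Normalized radial position
#'
#' Distance of a point from the nuclear center divided by the nuclear
#' radius: 0 at the center, 1 at the periphery. Values above 1 (outside the
#' nominal sphere) are permitted and flagged via the `outside` attribute.
#'
#' @param point numeric `(z, y, x)` µm, or a matrix with one point per row.
#' @param nucleus a `nucleus_model` (or list with `center` and radii).
#' @param which_radius `"volume"` (sphere-equivalent, default) or `"fit"`.
#' @return Numeric fraction(s) with logical attribute `outside`.
#' @export
radial_fraction <- function(point, nucleus, which_radius = c("volume", "fit")) {
  which_radius <- match.arg(which_radius)
  r <- if (which_radius == "volume") nucleus$radius_volume else nucleus$radius_fit
  if (is.na(r) || r <= 0) stop("selected nuclear radius is unavailable or <= 0")
  pts <- if (is.matrix(point)) point else matrix(point, nrow = 1)
  d <- sqrt(colSums((t(pts) - nucleus$center)^2))
  out <- d / r
  attr(out, "outside") <- out > 1
  out
}
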