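#' @useDynLib nucfish, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Single-channel 3D intensity volume with physical calibration
#'
#' A `voxel_grid` wraps one fluorescence channel of a confocal stack: a 3D
#' array of non-negative integer intensities in `(z, y, x)` order together
#' with the physical voxel dimensions in micrometres. All downstream
#' measurements (centroids, distances, radii) are computed in micrometres
#' using this calibration; it is mandatory input because acquisition z-steps
#' vary between experiments and must never be assumed isotropic.
#'
#' The physical coordinate of a voxel refers to its *center*: array element
#' `[i, j, k]` (1-based) is centered at `((i-1)*dz, (j-1)*dy, (k-1)*dx)` µm.
#' Intensities are expected on an 8-bit scale (0-255) because the default
#' detection thresholds are absolute values on that scale; wider integer
#' ranges are accepted.
#'
#' @param data 3D numeric array of non-negative intensities, axes `(z, y, x)`.
#' @param voxel_size numeric length-3, `(dz, dy, dx)` in µm, all > 0.
#' @param channel_name label, e.g. `"DAPI"`, `"Alexa488"`.
#' @return An object of class `voxel_grid`.
#' @export
voxel_grid <- function(data, voxel_size, channel_name = "channel") {
  if (length(dim(data)) != 3L)
    stop("`data` must be a 3D array in (z, y, x) order")
  if (any(data < 0)) stop("intensities must be non-negative")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0))
    stop("`voxel_size` must be three positive values (dz, dy, dx) in µm")
  structure(
    list(data = data, voxel_size = voxel_size,
         channel_name = as.character(channel_name)[1]),
    class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<voxel_grid '%s'> %d x %d x %d voxels (z,y,x), voxel %s µm, max intensity %g\n",
              x$channel_name, d[1], d[2], d[3],
              paste(signif(x$voxel_size, 3), collapse = " x "),
              max(x$data)))
  invisible(x)
}

#' Multi-channel image stack
#'
#' Bundles the channels of one acquired (or simulated) nucleus. All channels
#' must share shape and voxel size; at most one channel is designated as the
#' DAPI/nuclear channel, which defines the nuclear coordinate system.
#'
#' @param channels named list of [voxel_grid] objects (names = channel labels).
#' @param stack_id label identifying the stack (one pre-cropped nucleus).
#' @param dapi_channel name of the nuclear-stain channel, or `NA` if none.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(channels, stack_id = "stack", dapi_channel = "DAPI") {
  if (length(channels) < 1L) stop("at least one channel is required")
  if (is.null(names(channels)))
    names(channels) <- vapply(channels, function(g) g$channel_name, "")
  shapes <- vapply(channels, function(g) paste(dim(g$data), collapse = "x"), "")
  if (length(unique(shapes)) != 1L)
    stop("all channels of a stack must share the same shape")
  vs <- vapply(channels, function(g) paste(g$voxel_size, collapse = ","), "")
  if (length(unique(vs)) != 1L)
    stop("all channels of a stack must share the same voxel size")
  if (!is.na(dapi_channel) && !dapi_channel %in% names(channels))
    stop(sprintf("dapi_channel '%s' not among channels: %s", dapi_channel,
                 paste(names(channels), collapse = ", ")))
  structure(
    list(channels = channels, stack_id = as.character(stack_id)[1],
         dapi_channel = dapi_channel,
         voxel_size = channels[[1]]$voxel_size),
    class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  cat(sprintf("<image_stack '%s'> %d channel(s): %s; DAPI = %s\n",
              x$stack_id, length(x$channels),
              paste(names(x$channels), collapse = ", "), x$dapi_channel))
  invisible(x)
}

#' Convert a voxel index to a physical point
#'
#' Maps a zero-based voxel index `(z, y, x)` to the µm coordinate of the
#' voxel center: each coordinate is the index times the corresponding voxel
#' dimension, so voxel `(0,0,0)` sits at the origin. This voxel-center
#' convention is fixed project-wide. For 1-based R array subscripts, pass
#' `subscript - 1`.
#'
#' @param index integer vector `(z, y, x)` (zero-based) or a matrix with one
#'   index per row.
#' @param voxel_size `(dz, dy, dx)` in µm.
#' @return µm coordinates, same shape as `index`.
#' @export
voxel_to_physical <- function(index, voxel_size) {
  voxel_size <- as.numeric(voxel_size)
  if (is.matrix(index)) {
    sweep(index, 2L, voxel_size, `*`)
  } else {
    as.numeric(index) * voxel_size
  }
}

#' Read a multi-channel 3D stack from a multi-page TIFF
#'
#' Pages are interpreted as z-slices of the named channels, either
#' channel-major (all slices of channel 1, then channel 2, ...) or
#' interleaved (channel 1 slice 1, channel 2 slice 1, ...). Intensities are
#' restored bit-exactly for 8- and 16-bit files.
#'
#' @param path TIFF file path.
#' @param channel_names character vector of channel labels; the page count
#'   must be divisible by its length.
#' @param voxel_size `(dz, dy, dx)` in µm.
#' @param layout `"channel_major"` or `"interleaved"`.
#' @param dapi_channel nuclear-channel name (`NA` for none).
#' @param stack_id label; defaults to the file name.
#' @return An [image_stack].
#' @export
load_stack <- function(path, channel_names, voxel_size,
                       layout = c("channel_major", "interleaved"),
                       dapi_channel = if ("DAPI" %in% channel_names) "DAPI" else NA,
                       stack_id = sub("\\.tiff?$", "", basename(path))) {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  nc <- length(channel_names)
  if (nc < 1L) stop("at least one channel name is required")
  if (length(pages) %% nc != 0L)
    stop(sprintf("page count (%d) is not divisible by channel count (%d)",
                 length(pages), nc))
  nz <- length(pages) %/% nc
  dims <- dim(pages[[1]])
  channels <- vector("list", nc)
  for (ci in seq_len(nc)) {
    page_idx <- if (layout == "channel_major") {
      (ci - 1L) * nz + seq_len(nz)
    } else {
      ci + (seq_len(nz) - 1L) * nc
    }
    vol <- array(0, dim = c(nz, dims[1], dims[2]))
    for (zi in seq_len(nz)) vol[zi, , ] <- pages[[page_idx[zi]]]
    channels[[ci]] <- voxel_grid(vol, voxel_size, channel_names[ci])
  }
  names(channels) <- channel_names
  image_stack(channels, stack_id = stack_id, dapi_channel = dapi_channel)
}

#' Write an image stack to a multi-page 8-bit TIFF
#'
#' Inverse of [load_stack]; intensities must lie in 0-255 and are written
#' losslessly as 8-bit pages.
#'
#' @param stack an [image_stack].
#' @param path output file path.
#' @param layout `"channel_major"` or `"interleaved"`.
#' @return `path`, invisibly.
#' @export
save_stack <- function(stack, path, layout = c("channel_major", "interleaved")) {
  layout <- match.arg(layout)
  nz <- dim(stack$channels[[1]]$data)[1]
  nc <- length(stack$channels)
  mx <- max(vapply(stack$channels, function(g) max(g$data), 0))
  if (mx > 255) stop("save_stack writes 8-bit TIFF; intensities must be <= 255")
  page_of <- function(ci, zi) stack$channels[[ci]]$data[zi, , ] / 255
  pages <- if (layout == "channel_major") {
    unlist(lapply(seq_len(nc), function(ci)
      lapply(seq_len(nz), function(zi) page_of(ci, zi))), recursive = FALSE)
  } else {
    unlist(lapply(seq_len(nz), function(zi)
      lapply(seq_len(nc), function(ci) page_of(ci, zi))), recursive = FALSE)
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 8L, compression = "none")
  invisible(path)
}

#' Read or write a stack manifest
#'
#' A manifest is a YAML list of stack entries, each with `path`,
#' `channel_names`, `voxel_size` (dz, dy, dx in µm), `dapi_channel`,
#' `layout`, and optional grouping labels (`genotype`, `stage`). Paths are
#' resolved relative to the manifest file.
#'
#' @param path manifest file path.
#' @return `read_manifest`: a list of entries with resolved paths.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop(sprintf("manifest not found: %s", path))
  entries <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  lapply(entries, function(e) {
    if (is.null(e$path) || is.null(e$channel_names) || is.null(e$voxel_size))
      stop("each manifest entry needs path, channel_names and voxel_size")
    if (!grepl("^/", e$path)) e$path <- file.path(base, e$path)
    e$voxel_size <- as.numeric(e$voxel_size)
    if (is.null(e$layout)) e$layout <- "channel_major"
    if (is.null(e$dapi_channel))
      e$dapi_channel <- if ("DAPI" %in% e$channel_names) "DAPI" else NA
    e
  })
}

#' @rdname read_manifest
#' @param entries list of manifest entries.
#' @export
write_manifest <- function(entries, path) {
  yaml::write_yaml(entries, path)
  invisible(path)
}
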