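#' Segmentation parameters
#'
#' Absolute per-channel intensity thresholds, minimum object size in voxels,
#' and 3D neighbourhood connectivity. Defaults follow the object-detection
#' settings used for nurse-cell stacks: DAPI 25, Alexa488/Alexa647 35,
#' Alexa546 55, objects smaller than 10 voxels ignored. Thresholds are
#' absolute intensities on the 8-bit scale, not fractions of the channel
#' maximum.
#'
#' @param thresholds named numeric vector, channel label -> threshold.
#' @param min_voxels minimum voxel count for an object to be kept (>= 1).
#' @param connectivity 6 (faces), 18 (faces+edges) or 26 (faces+edges+corners).
#' @param default_threshold threshold used for channels absent from
#'   `thresholds`.
#' @return An object of class `seg_params`.
#' @export
seg_params <- function(thresholds = c(DAPI = 25, Alexa488 = 35,
                                      Alexa546 = 55, Alexa647 = 35,
                                      GFP = 35),
                       min_voxels = 10L, connectivity = 26L,
                       default_threshold = 35) {
  if (any(thresholds < 0)) stop("thresholds must be >= 0")
  if (min_voxels < 1L) stop("min_voxels must be >= 1")
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("connectivity must be one of 6, 18, 26")
  structure(list(thresholds = thresholds,
                 min_voxels = as.integer(min_voxels),
                 connectivity = as.integer(connectivity),
                 default_threshold = default_threshold),
            class = "seg_params")
}

threshold_for <- function(params, channel) {
  if (channel %in% names(params$thresholds)) {
    unname(params$thresholds[[channel]])
  } else {
    params$default_threshold
  }
}

#' Threshold a channel into a binary mask
#'
#' A voxel is included iff its intensity is greater than or equal to the
#' threshold (inclusive boundary, fixed so object counts are reproducible).
#'
#' @param grid a [voxel_grid] or a bare 3D array.
#' @param threshold absolute intensity threshold (>= 0).
#' @return Logical 3D array of the same shape.
#' @export
threshold_mask <- function(grid, threshold) {
  if (threshold < 0) stop("threshold must be >= 0")
  data <- if (inherits(grid, "voxel_grid")) grid$data else grid
  data >= threshold
}

#' Label 3D connected components
#'
#' Every included voxel receives exactly one positive label; two voxels
#' share a label iff they are connected under the chosen neighbourhood.
#' Labels are contiguous from 1.
#'
#' @param mask logical 3D array.
#' @param connectivity 6, 18 or 26.
#' @return List with `labels` (integer 3D array, 0 = background) and
#'   `sizes` (integer vector of component voxel counts, index = label).
#' @export
label_components <- function(mask, connectivity = 26L) {
  if (length(dim(mask)) != 3L) stop("mask must be a 3D array")
  lab <- label3d_cpp(as.logical(mask), dim(mask), as.integer(connectivity))
  n <- attr(lab, "n_components")
  labels <- array(as.integer(lab), dim = dim(mask))
  sizes <- if (n > 0) tabulate(labels[labels > 0L], nbins = n) else integer(0)
  list(labels = labels, sizes = sizes)
}

#' Remove components smaller than a minimum voxel count
#'
#' Components with strictly fewer than `min_voxels` voxels are erased;
#' survivors are relabeled contiguously from 1 preserving order.
#'
#' @param labeled result of [label_components].
#' @param min_voxels minimum size (>= 1); a component of exactly this size
#'   survives.
#' @return Same structure as [label_components], filtered.
#' @export
filter_by_size <- function(labeled, min_voxels = 10L) {
  if (min_voxels < 1L) stop("min_voxels must be >= 1")
  sizes <- labeled$sizes
  keep <- which(sizes >= min_voxels)
  remap <- integer(length(sizes))
  remap[keep] <- seq_along(keep)
  labels <- labeled$labels
  pos <- labels > 0L
  labels[pos] <- remap[labels[pos]]
  list(labels = labels, sizes = sizes[keep])
}

#' Extract per-object features
#'
#' For each labeled component: voxel count, physical volume, total
#' fluorescence intensity, and the intensity-weighted centroid (the center
#' of total fluorescence intensity) in µm, over above-threshold member
#' voxels only.
#'
#' @param grid the [voxel_grid] the labels were derived from.
#' @param labels integer 3D label array (0 = background).
#' @param channel channel label recorded in the output (defaults to the
#'   grid's).
#' @return data.frame with one row per object: `object_id`, `channel`,
#'   `voxel_count`, `volume_um3`, `total_intensity`,
#'   `centroid_z_um`/`_y_um`/`_x_um`, and bounding-box voxel subscript
#'   ranges (1-based, `bbox_*`).
#' @export
extract_objects <- function(grid, labels,
                            channel = if (inherits(grid, "voxel_grid"))
                              grid$channel_name else "channel") {
  data <- if (inherits(grid, "voxel_grid")) grid$data else grid
  vs <- if (inherits(grid, "voxel_grid")) grid$voxel_size else
    stop("extract_objects needs a voxel_grid to know physical calibration")
  idx <- which(labels > 0L)
  if (length(idx) == 0L) return(empty_objects_df())
  lab <- labels[idx]
  n <- max(lab)
  inten <- as.numeric(data[idx])
  if (any(tabulate(lab, nbins = n) == 0L))
    stop("labels must be contiguous from 1 (a label references no voxels)")
  d <- dim(labels)
  sub0 <- arrayInd(idx, d) - 1L  # zero-based (z,y,x) voxel indices
  w_sum <- rowsum_by(inten, lab, n)
  cz <- rowsum_by(inten * sub0[, 1] * vs[1], lab, n) / w_sum
  cy <- rowsum_by(inten * sub0[, 2] * vs[2], lab, n) / w_sum
  cx <- rowsum_by(inten * sub0[, 3] * vs[3], lab, n) / w_sum
  counts <- tabulate(lab, nbins = n)
  data.frame(
    object_id = seq_len(n),
    channel = channel,
    voxel_count = counts,
    volume_um3 = counts * prod(vs),
    total_intensity = w_sum,
    centroid_z_um = cz, centroid_y_um = cy, centroid_x_um = cx,
    bbox_z_min = rowsum_by(sub0[, 1] + 1L, lab, n, min),
    bbox_z_max = rowsum_by(sub0[, 1] + 1L, lab, n, max),
    bbox_y_min = rowsum_by(sub0[, 2] + 1L, lab, n, min),
    bbox_y_max = rowsum_by(sub0[, 2] + 1L, lab, n, max),
    bbox_x_min = rowsum_by(sub0[, 3] + 1L, lab, n, min),
    bbox_x_max = rowsum_by(sub0[, 3] + 1L, lab, n, max),
    stringsAsFactors = FALSE)
}

rowsum_by <- function(x, group, n, fun = NULL) {
  if (is.null(fun)) {
    as.numeric(rowsum(x, group, reorder = TRUE))
  } else {
    out <- vapply(split(x, group), fun, numeric(1))
    as.numeric(out[as.character(seq_len(n))])
  }
}

empty_objects_df <- function() {
  data.frame(object_id = integer(0), channel = character(0),
             voxel_count = integer(0), volume_um3 = numeric(0),
             total_intensity = numeric(0),
             centroid_z_um = numeric(0), centroid_y_um = numeric(0),
             centroid_x_um = numeric(0),
             bbox_z_min = integer(0), bbox_z_max = integer(0),
             bbox_y_min = integer(0), bbox_y_max = integer(0),
             bbox_x_min = integer(0), bbox_x_max = integer(0),
             stringsAsFactors = FALSE)
}

#' Segment one channel: threshold, label, size-filter, extract
#'
#' @param grid a [voxel_grid].
#' @param threshold absolute intensity threshold.
#' @param min_voxels minimum object size in voxels.
#' @param connectivity 6, 18 or 26.
#' @return List with `objects` (data.frame, see [extract_objects]) and
#'   `labels` (filtered integer label array).
#' @export
segment_channel <- function(grid, threshold, min_voxels = 10L,
                            connectivity = 26L) {
  mask <- threshold_mask(grid, threshold)
  lab <- filter_by_size(label_components(mask, connectivity), min_voxels)
  list(objects = extract_objects(grid, lab$labels), labels = lab$labels)
}

#' Segment every channel of a stack
#'
#' @param stack an [image_stack].
#' @param params a [seg_params].
#' @return List with `objects` (one data.frame over all channels, with a
#'   `stack_id` column) and `labels` (named list of label arrays).
#' @export
segment_stack <- function(stack, params = seg_params()) {
  res <- lapply(names(stack$channels), function(ch) {
    segment_channel(stack$channels[[ch]], threshold_for(params, ch),
                    params$min_voxels, params$connectivity)
  })
  names(res) <- names(stack$channels)
  objects <- do.call(rbind, lapply(res, `[[`, "objects"))
  rownames(objects) <- NULL
  objects <- cbind(stack_id = rep(stack$stack_id, nrow(objects)), objects,
                   stringsAsFactors = FALSE)
  list(objects = objects, labels = lapply(res, `[[`, "labels"))
}
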