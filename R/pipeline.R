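#' Split a single-channel band pair and measure its separation
#'
#' For assays where both loci are tagged in one channel (e.g. two LacO/GFP
#' arrays), objects of that channel are partitioned into two bands: the two
#' objects with the largest centroid separation seed the bands, every other
#' object joins the nearer seed, and the distance between the two
#' intensity-weighted band centroids is returned. Deterministic.
#'
#' @param objects data.frame of segmented objects from one channel (>= 2
#'   rows).
#' @return List: `distance_um`, `centroid_a`, `centroid_b`, `assignment`
#'   (band index per object).
#' @export
pair_band_distance <- function(objects) {
  if (nrow(objects) < 2L)
    stop("band splitting needs at least 2 objects in the channel")
  pts <- as.matrix(objects[, c("centroid_z_um", "centroid_y_um",
                               "centroid_x_um")])
  dmat <- as.matrix(stats::dist(pts))
  seeds <- which(dmat == max(dmat), arr.ind = TRUE)[1, ]
  assign_band <- apply(cbind(
    sqrt(rowSums(sweep(pts, 2, pts[seeds[1], ])^2)),
    sqrt(rowSums(sweep(pts, 2, pts[seeds[2], ])^2))), 1, which.min)
  ca <- probeset_centroid(objects[assign_band == 1L, , drop = FALSE])
  cb <- probeset_centroid(objects[assign_band == 2L, , drop = FALSE])
  list(distance_um = centroid_distance(ca, cb), centroid_a = ca,
       centroid_b = cb, assignment = assign_band)
}

#' Read probe metadata
#'
#' Probe metadata is a YAML map `probe_id -> {channel, arm, mb, class,
#' divisor}` linking each FISH probe to its detection channel and genomic
#' coordinates. `class` defaults to `"locus"`, `divisor` (spot-count
#' normalization, e.g. 5 for a five-telomere probe) to 1.
#'
#' @param path YAML file path.
#' @return data.frame: `probe_id`, `channel`, `arm`, `mb`, `class`,
#'   `divisor`.
#' @export
read_probe_meta <- function(path) {
  raw <- yaml::read_yaml(path)
  out <- do.call(rbind, lapply(names(raw), function(id) {
    p <- raw[[id]]
    data.frame(probe_id = id, channel = p$channel,
               arm = if (is.null(p$arm)) NA_character_ else p$arm,
               mb = if (is.null(p$mb)) NA_real_ else as.numeric(p$mb),
               class = if (is.null(p$class)) "locus" else p$class,
               divisor = if (is.null(p$divisor)) 1 else as.numeric(p$divisor),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Measure one stack
#'
#' The per-nucleus measurement core: segments every channel, fits the
#' nuclear model from the DAPI channel, and derives probe centroids,
#' radial positions, spot counts, locus-pair distances and the
#' intensity-weighted PCA shape of each channel's objects.
#'
#' Probes are matched to segmented objects by channel. When several probes
#' share one channel they are resolved by [pair_band_distance] (two probes)
#' or skipped with a warning (more than two).
#'
#' @param stack an [image_stack].
#' @param probe_meta probe metadata data.frame (see [read_probe_meta]).
#' @param params a [seg_params].
#' @param pairs optional data.frame of requested locus pairs (`probe_a`,
#'   `probe_b`, optional `mb_separation`); defaults to all probe pairs.
#' @param genotype,stage grouping labels copied into outputs.
#' @return List of data.frames: `objects`, `nuclei`, `radial`, `spots`,
#'   `distances`, `shapes`.
#' @export
measure_stack <- function(stack, probe_meta, params = seg_params(),
                          pairs = NULL, genotype = NA_character_,
                          stage = NA_character_) {
  seg <- segment_stack(stack, params)
  objects <- seg$objects
  sid <- stack$stack_id

  if (is.na(stack$dapi_channel))
    stop("measure_stack requires a designated DAPI channel")
  nuc <- fit_nucleus(stack$channels[[stack$dapi_channel]],
                     threshold = threshold_for(params, stack$dapi_channel),
                     min_voxels = params$min_voxels,
                     connectivity = params$connectivity)
  nuclei <- data.frame(stack_id = sid, genotype = genotype, stage = stage,
                       center_z_um = nuc$center[1], center_y_um = nuc$center[2],
                       center_x_um = nuc$center[3],
                       radius_volume_um = nuc$radius_volume,
                       radius_fit_um = nuc$radius_fit,
                       dapi_volume_um3 = nuc$dapi_volume,
                       stringsAsFactors = FALSE)

  probe_objects <- function(ch)
    objects[objects$channel == ch & objects$channel != stack$dapi_channel, ,
            drop = FALSE]

  centroids <- list()
  spots <- list()
  band_records <- list()
  for (ch in unique(probe_meta$channel)) {
    pm <- probe_meta[probe_meta$channel == ch, , drop = FALSE]
    obj <- probe_objects(ch)
    if (nrow(pm) == 1L) {
      spots[[pm$probe_id]] <- data.frame(
        stack_id = sid, probe_id = pm$probe_id, channel = ch,
        n_objects = nrow(obj),
        spot_count = spot_count(obj, pm$divisor),
        stringsAsFactors = FALSE)
      if (nrow(obj) >= 1L) centroids[[pm$probe_id]] <- probeset_centroid(obj)
    } else if (nrow(pm) == 2L) {
      if (nrow(obj) >= 2L) {
        bd <- pair_band_distance(obj)
        centroids[[pm$probe_id[1]]] <- bd$centroid_a
        centroids[[pm$probe_id[2]]] <- bd$centroid_b
        band_records[[ch]] <- data.frame(
          stack_id = sid, genotype = genotype, stage = stage,
          probe_a = pm$probe_id[1], probe_b = pm$probe_id[2],
          mb_separation = abs(pm$mb[2] - pm$mb[1]),
          distance_um = bd$distance_um, stringsAsFactors = FALSE)
      } else {
        warning(sprintf("stack %s: channel %s has %d object(s), cannot split two probes",
                        sid, ch, nrow(obj)))
      }
      for (pid in pm$probe_id)
        spots[[pid]] <- data.frame(stack_id = sid, probe_id = pid,
                                   channel = ch, n_objects = nrow(obj),
                                   spot_count = NA_real_,
                                   stringsAsFactors = FALSE)
    } else {
      warning(sprintf("stack %s: %d probes share channel %s; skipped",
                      sid, nrow(pm), ch))
    }
  }

  radial <- do.call(rbind, lapply(names(centroids), function(pid) {
    rf <- radial_fraction(centroids[[pid]], nuc)
    data.frame(stack_id = sid, genotype = genotype, stage = stage,
               probe_id = pid, radial_fraction = as.numeric(rf),
               outside = attr(rf, "outside"), stringsAsFactors = FALSE)
  }))

  if (is.null(pairs)) {
    ids <- names(centroids)
    pairs <- if (length(ids) >= 2L) {
      cmb <- utils::combn(ids, 2L)
      mb <- stats::setNames(probe_meta$mb, probe_meta$probe_id)
      data.frame(probe_a = cmb[1, ], probe_b = cmb[2, ],
                 mb_separation = abs(mb[cmb[1, ]] - mb[cmb[2, ]]),
                 stringsAsFactors = FALSE)
    } else NULL
  }
  distances <- if (!is.null(pairs) && nrow(pairs) > 0L)
    locus_pair_table(centroids, pairs, stack_id = sid, genotype = genotype,
                     stage = stage)
  else do.call(rbind, band_records)
  # band-pair records measured via pair_band_distance, not yet in pairs
  if (!is.null(pairs) && length(band_records) > 0L) {
    have <- paste(distances$probe_a, distances$probe_b)
    extra <- do.call(rbind, band_records)
    extra <- extra[!paste(extra$probe_a, extra$probe_b) %in% have, ,
                   drop = FALSE]
    distances <- rbind(distances, extra)
  }

  shapes <- do.call(rbind, lapply(unique(probe_meta$channel), function(ch) {
    obj <- probe_objects(ch)
    if (nrow(obj) < 2L || nrow(unique(obj[, c("centroid_z_um",
                                              "centroid_y_um",
                                              "centroid_x_um")])) < 2L)
      return(NULL)
    sd3 <- weighted_pca(obj)
    data.frame(stack_id = sid, genotype = genotype, stage = stage,
               channel = ch, n_objects = nrow(obj),
               eig1 = sd3$eigenvalues[1], eig2 = sd3$eigenvalues[2],
               eig3 = sd3$eigenvalues[3], anisotropy = sd3$anisotropy,
               stringsAsFactors = FALSE)
  }))

  list(objects = objects, nuclei = nuclei,
       radial = if (is.null(radial)) data.frame() else radial,
       spots = do.call(rbind, spots),
       distances = if (is.null(distances)) data.frame() else distances,
       shapes = if (is.null(shapes)) data.frame() else shapes)
}

csv_header <- "# nucfish output; coordinates in µm, axis order (z,y,x), voxel-center convention"

write_pipeline_csv <- function(df, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  writeLines(csv_header, con)
  utils::write.csv(df, con, row.names = FALSE)
  close(con)
  invisible(path)
}

#' Read a pipeline CSV table
#'
#' @param path CSV written by [run_pipeline] (one `#` header comment line).
#' @return data.frame.
#' @export
read_pipeline_csv <- function(path)
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)

#' Run the full measurement pipeline over a stack manifest
#'
#' simulate/acquire -> segment -> measure -> summarize, as a batch: loads
#' every stack listed in the manifest, measures it (see [measure_stack]),
#' aggregates per-group summaries of distances and radial fractions, and
#' writes `objects.csv`, `nuclei.csv`, `distances.csv`, `radial.csv`,
#' `spots.csv`, `shapes.csv`, `summary.csv` plus a plain-text log to the
#' output directory. A failing stack is logged and skipped; the remaining
#' stacks are still processed.
#'
#' @param manifest_path YAML stack manifest (see [read_manifest]).
#' @param probe_meta_path YAML probe metadata (see [read_probe_meta]).
#' @param out_dir output directory (created if needed).
#' @param params a [seg_params].
#' @param pairs optional requested locus pairs (default: all).
#' @param seed seed recorded in the log (the measurement phase itself is
#'   deterministic).
#' @return Invisibly, the list of aggregated tables.
#' @export
run_pipeline <- function(manifest_path, probe_meta_path, out_dir,
                         params = seg_params(), pairs = NULL, seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  entries <- read_manifest(manifest_path)
  probe_meta <- read_probe_meta(probe_meta_path)
  log_path <- file.path(out_dir, "pipeline.log")
  logf <- function(fmt, ...) cat(sprintf("%s %s\n",
                                         format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                                         sprintf(fmt, ...)),
                                 file = log_path, append = TRUE)
  logf("pipeline start: %d stack(s); seed %d; thresholds [%s]; min_voxels %d; connectivity %d",
       length(entries), seed,
       paste(sprintf("%s=%g", names(params$thresholds), params$thresholds),
             collapse = ", "),
       params$min_voxels, params$connectivity)

  acc <- list(objects = list(), nuclei = list(), radial = list(),
              spots = list(), distances = list(), shapes = list())
  for (e in entries) {
    sid <- if (is.null(e$stack_id)) basename(e$path) else e$stack_id
    res <- tryCatch({
      stack <- load_stack(e$path, e$channel_names, e$voxel_size,
                          layout = e$layout, dapi_channel = e$dapi_channel,
                          stack_id = sid)
      measure_stack(stack, probe_meta, params, pairs = pairs,
                    genotype = if (is.null(e$genotype)) NA_character_ else e$genotype,
                    stage = if (is.null(e$stage)) NA_character_ else e$stage)
    }, error = function(err) err)
    if (inherits(res, "error")) {
      logf("SKIP stack %s: %s", sid, conditionMessage(res))
      next
    }
    for (nm in names(acc)) acc[[nm]][[sid]] <- res[[nm]]
    logf("ok stack %s: %d object(s), %d distance record(s)",
         sid, nrow(res$objects), nrow(res$distances))
  }
  tables <- lapply(acc, function(lst) {
    out <- do.call(rbind, lst)
    if (is.null(out)) data.frame() else { rownames(out) <- NULL; out }
  })

  summary_rows <- list()
  if (nrow(tables$distances) > 0L) {
    d <- tables$distances
    d$pair <- paste(d$probe_a, d$probe_b, sep = "-")
    summary_rows$distance <- summarize_metric(
      d, "distance_um", c("genotype", "stage", "pair"), metric = "distance_um")
  }
  if (nrow(tables$radial) > 0L) {
    summary_rows$radial <- summarize_metric(
      tables$radial, "radial_fraction", c("genotype", "stage", "probe_id"),
      metric = "radial_fraction")
  }
  tables$summary <- if (length(summary_rows) > 0L)
    do.call(rbind, summary_rows) else data.frame()
  rownames(tables$summary) <- NULL

  for (nm in c("objects", "nuclei", "distances", "radial", "spots",
               "shapes", "summary"))
    write_pipeline_csv(tables[[nm]], file.path(out_dir, paste0(nm, ".csv")))
  logf("pipeline done: %d stack(s) measured", length(acc$nuclei))
  invisible(tables)
}

#' Simulate a batch of nuclei to disk
#'
#' Renders `n` replicate nuclei from a preset (or a template
#' [synthetic_spec]), writing one multi-page TIFF and one ground-truth CSV
#' per nucleus plus a manifest and probe-metadata YAML ready for
#' [run_pipeline]. Replicate `i` uses seed `seed + i - 1`.
#'
#' @param preset preset name (see [preset_scenarios]) or a
#'   [synthetic_spec] used as template.
#' @param n number of nuclei.
#' @param out_dir output directory.
#' @param seed base seed.
#' @param genotype,stage grouping labels written into the manifest.
#' @return Invisibly, the manifest path.
#' @export
simulate_nuclei <- function(preset, n, out_dir, seed = 1L,
                            genotype = NA, stage = NA) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (n < 1L) {
    warning("n = 0: writing an empty manifest")
    write_manifest(list(), file.path(out_dir, "manifest.yaml"))
    return(invisible(file.path(out_dir, "manifest.yaml")))
  }
  entries <- vector("list", n)
  probe_meta <- NULL
  for (i in seq_len(n)) {
    spec <- if (is.character(preset)) {
      preset_scenarios(preset, seed = seed + i - 1L,
                       stack_id = sprintf("%s_%03d", preset, i))
    } else {
      s <- preset; s$seed <- seed + i - 1L
      s$stack_id <- sprintf("%s_%03d", s$stack_id, i); s
    }
    sim <- simulate_nucleus(spec)
    tif <- file.path(out_dir, paste0(spec$stack_id, ".tiff"))
    save_stack(sim$stack, tif)
    utils::write.csv(sim$truth$spots,
                     file.path(out_dir, paste0(spec$stack_id, "_truth.csv")),
                     row.names = FALSE)
    entries[[i]] <- list(path = basename(tif), stack_id = spec$stack_id,
                         channel_names = names(sim$stack$channels),
                         voxel_size = spec$voxel_size,
                         dapi_channel = "DAPI", layout = "channel_major",
                         genotype = if (is.na(genotype)) spec$configuration else genotype,
                         stage = if (is.na(stage)) "simulated" else stage)
    if (is.null(probe_meta)) {
      pm <- do.call(rbind, lapply(spec$chromosomes, `[[`, "probes"))
      probe_meta <- stats::setNames(lapply(seq_len(nrow(pm)), function(j)
        list(channel = pm$channel[j], mb = pm$mb[j], class = pm$class[j],
             divisor = 1)), pm$probe_id)
    }
  }
  manifest_path <- file.path(out_dir, "manifest.yaml")
  write_manifest(entries, manifest_path)
  yaml::write_yaml(probe_meta, file.path(out_dir, "probes.yaml"))
  invisible(manifest_path)
}
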