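# Independent oracles and small fixture builders used across tests.

# Frontier-based flood fill: an independent reference for 3D connected
# component labeling. Labels are assigned in raster-scan order of each
# component's first voxel, matching the contract of label_components().
flood_fill_oracle <- function(mask, connectivity) {
  d <- dim(mask)
  off <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  nzero <- abs(off$dz) + abs(off$dy) + abs(off$dx)
  max_nz <- c(`6` = 1, `18` = 2, `26` = 3)[[as.character(connectivity)]]
  off <- off[nzero > 0 & nzero <= max_nz, ]
  labels <- array(0L, d)
  next_lab <- 0L
  for (s in which(mask)) {
    if (labels[s] > 0L) next
    next_lab <- next_lab + 1L
    labels[s] <- next_lab
    frontier <- s
    while (length(frontier) > 0L) {
      sub <- arrayInd(frontier, d)
      nb <- do.call(rbind, lapply(seq_len(nrow(off)), function(k)
        cbind(sub[, 1] + off$dz[k], sub[, 2] + off$dy[k],
              sub[, 3] + off$dx[k])))
      ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
        nb[, 3] >= 1 & nb[, 3] <= d[3]
      nb <- nb[ok, , drop = FALSE]
      lin <- unique((nb[, 3] - 1L) * d[1] * d[2] + (nb[, 2] - 1L) * d[1] +
                      nb[, 1])
      lin <- lin[mask[lin] & labels[lin] == 0L]
      labels[lin] <- next_lab
      frontier <- lin
    }
  }
  labels
}

# voxel grid with a rasterized filled ball of given radius (µm), constant
# intensity, plus optional background value
ball_grid <- function(radius_um, voxel_size, level = 100, pad_um = 1,
                      hollow = FALSE, shell_um = 0.5) {
  extent <- 2 * (radius_um + pad_um)
  d <- as.integer(ceiling(extent / voxel_size)) + 1L
  ctr <- (d - 1L) * voxel_size / 2
  z2 <- ((0:(d[1] - 1)) * voxel_size[1] - ctr[1])^2
  y2 <- ((0:(d[2] - 1)) * voxel_size[2] - ctr[2])^2
  x2 <- ((0:(d[3] - 1)) * voxel_size[3] - ctr[3])^2
  dist2 <- outer(outer(z2, y2, `+`), x2, `+`)
  vol <- array(0, d)
  inside <- dist2 <= radius_um^2
  if (hollow) inside <- inside & dist2 >= (radius_um - shell_um)^2
  vol[inside] <- level
  voxel_grid(vol, voxel_size, "DAPI")
}

# tiny two-probe metadata table matching the preset probes
preset_probe_meta <- function(spec) {
  pm <- do.call(rbind, lapply(spec$chromosomes, `[[`, "probes"))
  pm$divisor <- 1
  pm$arm <- NA_character_
  pm
}

# simulate + measure one preset replicate; returns the measured pair
# distance in µm
measure_preset_once <- function(preset, seed) {
  spec <- preset_scenarios(preset, seed = seed)
  sim <- simulate_nucleus(spec)
  res <- measure_stack(sim$stack, preset_probe_meta(spec))
  stopifnot(nrow(res$distances) >= 1L)
  res$distances$distance_um[1]
}
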