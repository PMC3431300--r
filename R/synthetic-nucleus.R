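#' Chromosome specification for the nucleus simulator
#'
#' Describes one chromosome (all of its chromatids) inside a simulated
#' nucleus: genomic length, axial compaction (µm of backbone per Mb),
#' polyteny (number of chromatids and the fraction of them tracking the
#' common backbone), anchoring, and the FISH probes placed on it.
#'
#' Probes are given as a data.frame with columns `probe_id`, `channel`,
#' `mb` (genomic position) and optionally `class` (`"locus"`,
#' `"heterochromatin"` or `"telomere"`; the latter two always remain paired,
#' reflecting the retained allelic pairing of under-replicated repeats).
#'
#' When `pin_separation` is set the chromosome must carry exactly two
#' probes, at 0 Mb and `genomic_length` Mb; the backbone is then built as a
#' random smooth bridge whose endpoints are exactly `pin_separation` µm
#' apart and whose arc length is `genomic_length * compaction`, so the true
#' probe pair separation is programmed exactly.
#'
#' @param name chromosome label.
#' @param genomic_length length in Mb (> 0).
#' @param compaction axial extension in µm per Mb (> 0); small values =
#'   strongly compacted.
#' @param n_chromatids polyteny level (>= 1).
#' @param pairing fraction in `[0, 1]` of chromatids tracking the common
#'   backbone (1 = fully polytene).
#' @param territory_radius confinement radius (µm) in territorial mode.
#' @param probes probe data.frame (see Details).
#' @param pin_separation optional programmed Euclidean probe-pair
#'   separation in µm (see Details).
#' @param spread displacement SD (µm) for unpaired chromatid spots.
#' @return Object of class `chromosome_spec`.
#' @export
chromosome_spec <- function(name, genomic_length, compaction,
                            n_chromatids = 1L, pairing = 1,
                            territory_radius = 2, probes = NULL,
                            pin_separation = NULL, spread = 0.5) {
  if (genomic_length <= 0) stop("genomic_length must be > 0")
  if (compaction <= 0) stop("compaction (µm/Mb) must be > 0")
  if (pairing < 0 || pairing > 1) stop("pairing must be in [0, 1]")
  if (n_chromatids < 1) stop("n_chromatids must be >= 1")
  if (!is.null(probes)) {
    if (!all(c("probe_id", "channel", "mb") %in% names(probes)))
      stop("probes needs columns probe_id, channel, mb")
    if (any(probes$mb < 0 | probes$mb > genomic_length))
      stop("probe Mb positions must lie in [0, genomic_length]")
    if (is.null(probes$class)) probes$class <- "locus"
  }
  if (!is.null(pin_separation)) {
    if (is.null(probes) || nrow(probes) != 2L ||
        !isTRUE(all.equal(sort(probes$mb), c(0, genomic_length))))
      stop("pin_separation requires exactly two probes at 0 and genomic_length Mb")
    if (pin_separation > genomic_length * compaction)
      stop("pin_separation exceeds the backbone arc length")
  }
  structure(list(name = name, genomic_length = genomic_length,
                 compaction = compaction,
                 n_chromatids = as.integer(n_chromatids), pairing = pairing,
                 territory_radius = territory_radius, probes = probes,
                 pin_separation = pin_separation, spread = spread),
            class = "chromosome_spec")
}

#' Full generative description of a synthetic nucleus
#'
#' Everything needed to render one ground-truthed multi-channel stack: the
#' spherical nucleus, the chromosome configuration, optics (anisotropic
#' Gaussian PSF), intensity model (8-bit scale) and the seed. Defaults keep
#' a stack desk-scale (a few hundred thousand to a few million voxels).
#'
#' @param nuclear_radius µm.
#' @param voxel_size `(dz, dy, dx)` µm.
#' @param configuration `"territorial"`, `"polytene_rabl"` or `"custom"`.
#' @param chromosomes list of [chromosome_spec].
#' @param psf_sigma `(sigma_z, sigma_xy)` µm of the rendered Gaussian spots.
#' @param background_level,noise_sd intensity units (8-bit scale).
#' @param dapi_fill_level nucleoplasmic DAPI fill intensity; the DAPI
#'   channel is a filled ball at this level plus brighter chromatin along
#'   the backbones (`backbone_dapi_amp`).
#' @param backbone_dapi_amp extra DAPI amplitude deposited along backbones.
#' @param spot_amplitude peak probe-spot intensity; keep at least twice the
#'   channel detection threshold.
#' @param bit_depth bits per sample (8 by default; intensities are clipped
#'   and quantized to `2^bit_depth - 1`).
#' @param dims optional `(nz, ny, nx)`; computed from the radius when NULL.
#' @param margin_um clearance between nucleus and stack border when
#'   computing `dims`.
#' @param seed integer seed; all randomness of one nucleus flows from it.
#' @param stack_id label for the rendered stack.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(nuclear_radius, voxel_size = c(0.4, 0.2, 0.2),
                           configuration = c("territorial", "polytene_rabl",
                                             "custom"),
                           chromosomes = list(),
                           psf_sigma = c(0.6, 0.25),
                           background_level = 8, noise_sd = 3,
                           dapi_fill_level = 80, backbone_dapi_amp = 60,
                           spot_amplitude = 160, bit_depth = 8L,
                           dims = NULL, margin_um = 1.2, seed = 1L,
                           stack_id = "synthetic") {
  configuration <- match.arg(configuration)
  if (nuclear_radius <= 0) stop("nuclear_radius must be > 0")
  if (any(voxel_size <= 0)) stop("voxel sizes must be > 0")
  if (any(psf_sigma <= 0)) stop("psf_sigma must be > 0")
  if (is.null(dims)) {
    extent <- 2 * (nuclear_radius + margin_um)
    dims <- as.integer(ceiling(extent / voxel_size)) + 1L
  }
  phys <- (dims - 1L) * voxel_size
  if (any(phys < 2 * nuclear_radius))
    stop("stack dims too small to contain the nucleus")
  structure(list(nuclear_radius = nuclear_radius, voxel_size = voxel_size,
                 configuration = configuration, chromosomes = chromosomes,
                 psf_sigma = psf_sigma, background_level = background_level,
                 noise_sd = noise_sd, dapi_fill_level = dapi_fill_level,
                 backbone_dapi_amp = backbone_dapi_amp,
                 spot_amplitude = spot_amplitude,
                 bit_depth = as.integer(bit_depth), dims = dims,
                 seed = as.integer(seed), stack_id = stack_id),
            class = "synthetic_spec")
}

unit_vec <- function(v) v / sqrt(sum(v^2))

random_unit <- function() unit_vec(stats::rnorm(3))

# two unit vectors spanning the plane perpendicular to u
perp_basis <- function(u) {
  a <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- unit_vec(pracma_cross(u, a))
  e2 <- pracma_cross(u, e1)
  list(e1 = e1, e2 = e2)
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Random smooth bridge between two points with programmed arc length
#'
#' Builds a polyline from `a` to `b` whose total arc length equals
#' `arc_length`: a straight baseline plus a random low-frequency
#' perpendicular displacement field (vanishing at the endpoints) whose
#' amplitude is solved by bisection so the discrete arc length matches the
#' target to 0.1%. Used to emulate the curved path of a chromosome segment
#' whose end-to-end distance and contour length are both prescribed.
#'
#' @param a,b `(z, y, x)` µm endpoints.
#' @param arc_length target arc length, >= the chord length.
#' @param n_points number of polyline vertices.
#' @return n x 3 matrix of ordered `(z, y, x)` µm points.
#' @export
constrained_bridge <- function(a, b, arc_length, n_points = 200L) {
  chord <- sqrt(sum((b - a)^2))
  if (arc_length < chord)
    stop(sprintf("arc_length (%.3f) is below the chord length (%.3f)",
                 arc_length, chord))
  tt <- seq(0, 1, length.out = n_points)
  base <- outer(1 - tt, a) + outer(tt, b)
  if (arc_length - chord < 1e-9 * max(1, chord)) return(base)
  pb <- perp_basis(unit_vec(b - a))
  modes <- 4L
  c1 <- stats::rnorm(modes, sd = 1 / seq_len(modes))
  c2 <- stats::rnorm(modes, sd = 1 / seq_len(modes))
  shape <- sapply(seq_len(modes), function(k) sin(k * pi * tt))
  f1 <- as.numeric(shape %*% c1)
  f2 <- as.numeric(shape %*% c2)
  norm_max <- max(sqrt(f1^2 + f2^2))
  f1 <- f1 / norm_max; f2 <- f2 / norm_max
  curve_at <- function(alpha)
    base + alpha * (outer(f1, pb$e1) + outer(f2, pb$e2))
  arc_at <- function(alpha) path_length(curve_at(alpha))
  hi <- arc_length  # displacement of this magnitude always overshoots
  while (arc_at(hi) < arc_length) hi <- hi * 2
  alpha <- stats::uniroot(function(al) arc_at(al) - arc_length,
                          c(0, hi), tol = 1e-4 * arc_length)$root
  curve_at(alpha)
}

#' Generate a chromosome backbone inside a nucleus
#'
#' Produces an ordered polyline of total arc length
#' `genomic_length * compaction` (within 2%), plus the linear Mb-to-arc
#' map, in one of three modes:
#' \describe{
#'   \item{polytene_rabl}{persistent random walk whose first point (the
#'     centromeric end) is anchored on the nuclear surface at the
#'     designated pole and whose steps are biased toward the opposite
#'     pole, confined to the nucleus.}
#'   \item{territorial}{persistent random walk confined to a ball of
#'     `territory_radius` tangent to the nuclear envelope.}
#'   \item{pinned (either mode)}{when the chromosome carries
#'     `pin_separation`, a [constrained_bridge] between two points exactly
#'     that far apart, randomly oriented inside the nucleus.}
#' }
#'
#' @param cs a [chromosome_spec].
#' @param nuclear_radius µm.
#' @param center nucleus center `(z, y, x)` µm.
#' @param configuration `"territorial"` or `"polytene_rabl"`.
#' @param pole unit vector to the centromere pole (rabl mode); random if
#'   NULL.
#' @param step_um random-walk step length.
#' @param persistence direction persistence in `[0, 1)`.
#' @return List: `polyline` (n x 3 µm), `arc` (cumulative arc length per
#'   vertex), `arc_length`, `mb_to_arc` (µm per Mb), `territory_center`.
#' @export
generate_backbone <- function(cs, nuclear_radius, center,
                              configuration = c("territorial",
                                                "polytene_rabl"),
                              pole = NULL, step_um = 0.2,
                              persistence = 0.8) {
  configuration <- match.arg(configuration)
  target <- cs$genomic_length * cs$compaction
  region_r <- if (configuration == "territorial")
    min(cs$territory_radius, nuclear_radius) else nuclear_radius
  if (target > 400 * region_r)
    stop(sprintf(paste0("infeasible confinement: arc length %.1f µm cannot ",
                        "be packed in a region of radius %.1f µm at step %.2f"),
                 target, region_r, step_um))

  if (!is.null(cs$pin_separation)) {
    sep <- cs$pin_separation
    for (try in 1:20) {
      u <- random_unit()
      mid <- center + stats::rnorm(3, sd = 0.2 * nuclear_radius / 5)
      a <- mid - u * sep / 2
      b <- mid + u * sep / 2
      if (max(sqrt(sum((a - center)^2)), sqrt(sum((b - center)^2))) >
          0.85 * nuclear_radius) next
      pl <- constrained_bridge(a, b, target)
      if (all(sqrt(rowSums(sweep(pl, 2, center)^2)) < 0.97 * nuclear_radius))
        return(finish_backbone(pl, cs, territory_center = NULL))
    }
    stop("could not place pinned backbone inside the nucleus; ",
         "reduce pin_separation or arc length relative to the radius")
  }

  n_steps <- max(2L, as.integer(round(target / step_um)))
  step <- target / n_steps
  if (configuration == "polytene_rabl") {
    if (is.null(pole)) pole <- random_unit()
    start <- center + pole * nuclear_radius * 0.96
    region_center <- center
    bias <- -pole * 0.35
  } else {
    dir0 <- random_unit()
    region_center <- center + dir0 * max(0, nuclear_radius - region_r)
    start <- region_center
    bias <- c(0, 0, 0)
  }
  pts <- matrix(NA_real_, n_steps + 1L, 3L)
  pts[1L, ] <- start
  dir <- if (configuration == "polytene_rabl") -pole else random_unit()
  for (i in seq_len(n_steps)) {
    for (try in 1:60) {
      prop_dir <- unit_vec(persistence * dir +
                           (1 - persistence) * random_unit() + bias)
      cand <- pts[i, ] + prop_dir * step
      if (sqrt(sum((cand - region_center)^2)) <= region_r * 0.98) break
      # bounce inward when stuck at the region boundary
      if (try >= 40) prop_dir <- unit_vec(region_center - pts[i, ])
      cand <- pts[i, ] + prop_dir * step
      if (sqrt(sum((cand - region_center)^2)) <= region_r * 0.98) break
    }
    pts[i + 1L, ] <- cand
    dir <- prop_dir
  }
  finish_backbone(pts, cs, territory_center =
                    if (configuration == "territorial") region_center else NULL)
}

finish_backbone <- function(polyline, cs, territory_center) {
  seg <- sqrt(rowSums(diff(polyline)^2))
  arc <- c(0, cumsum(seg))
  list(polyline = polyline, arc = arc, arc_length = arc[length(arc)],
       mb_to_arc = arc[length(arc)] / cs$genomic_length,
       territory_center = territory_center)
}

# position on the backbone at a given arc-length coordinate
point_at_arc <- function(backbone, s) {
  s <- min(max(s, 0), backbone$arc_length)
  i <- findInterval(s, backbone$arc, rightmost.closed = TRUE)
  i <- min(i, nrow(backbone$polyline) - 1L)
  s0 <- backbone$arc[i]; s1 <- backbone$arc[i + 1L]
  w <- if (s1 > s0) (s - s0) / (s1 - s0) else 0
  backbone$polyline[i, ] * (1 - w) + backbone$polyline[i + 1L, ] * w
}

#' Place probe spots on a backbone
#'
#' Each probe maps to the backbone position at its genomic coordinate
#' (linear Mb-to-arc map). The paired chromatids contribute one spot at
#' that position; each of the remaining `n_chromatids - 1` chromatids
#' unpairs independently with probability `1 - pairing` and contributes a
#' spot displaced by an isotropic Gaussian offset of SD `spread`. Probes of
#' class `"heterochromatin"` or `"telomere"` are forced to remain fully
#' paired.
#'
#' @param backbone result of [generate_backbone].
#' @param cs the [chromosome_spec] carrying the probes.
#' @return data.frame of true spots: `probe_id`, `channel`, `class`,
#'   `spot`, `z_um`, `y_um`, `x_um`.
#' @export
place_probes <- function(backbone, cs) {
  if (is.null(cs$probes) || nrow(cs$probes) == 0L)
    return(data.frame(probe_id = character(0), channel = character(0),
                      class = character(0), spot = integer(0),
                      z_um = numeric(0), y_um = numeric(0),
                      x_um = numeric(0), stringsAsFactors = FALSE))
  rows <- lapply(seq_len(nrow(cs$probes)), function(i) {
    pr <- cs$probes[i, ]
    base <- point_at_arc(backbone, pr$mb * backbone$mb_to_arc)
    pairing <- if (pr$class %in% c("heterochromatin", "telomere")) 1 else cs$pairing
    n_extra <- if (cs$n_chromatids > 1L)
      sum(stats::runif(cs$n_chromatids - 1L) < (1 - pairing)) else 0L
  pos <- rbind(base,
               if (n_extra > 0)
                 sweep(matrix(stats::rnorm(3 * n_extra, sd = cs$spread),
                              ncol = 3), 2, base, `+`))
    data.frame(probe_id = pr$probe_id, channel = pr$channel,
               class = pr$class, spot = seq_len(nrow(pos)),
               z_um = pos[, 1], y_um = pos[, 2], x_um = pos[, 3],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# deposit an anisotropic Gaussian of given peak amplitude at a µm position
add_gaussian_spot <- function(vol, center_um, amplitude, sigma_zyx,
                              voxel_size) {
  d <- dim(vol)
  ext <- ceiling(4 * sigma_zyx / voxel_size)
  c_vox <- center_um / voxel_size  # zero-based fractional voxel coordinate
  lo <- pmax(floor(c_vox - ext), 0)
  hi <- pmin(ceiling(c_vox + ext), d - 1L)
  if (any(lo > hi)) return(vol)
  iz <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; ix <- lo[3]:hi[3]
  gz <- exp(-((iz - c_vox[1]) * voxel_size[1])^2 / (2 * sigma_zyx[1]^2))
  gy <- exp(-((iy - c_vox[2]) * voxel_size[2])^2 / (2 * sigma_zyx[2]^2))
  gx <- exp(-((ix - c_vox[3]) * voxel_size[3])^2 / (2 * sigma_zyx[3]^2))
  blob <- amplitude * (gz %o% gy %o% gx)
  vol[iz + 1L, iy + 1L, ix + 1L] <- vol[iz + 1L, iy + 1L, ix + 1L] + blob
  vol
}

#' Render a synthetic nucleus into a calibrated image stack
#'
#' The DAPI channel is a filled nuclear ball at `dapi_fill_level` (the
#' nucleoplasmic stain that defines nuclear volume) plus Gaussian chromatin
#' density deposited along every backbone; each probe channel receives an
#' anisotropic Gaussian spot of peak `spot_amplitude` at every true spot
#' position. All channels get `background_level`, additive Gaussian noise
#' of SD `noise_sd`, clipping and quantization to `bit_depth`. The same
#' spec and RNG state give a bit-identical stack.
#'
#' @param spec a [synthetic_spec].
#' @param truth result of [simulate_nucleus]'s generation phase: list with
#'   `center`, `spots`, `backbones`.
#' @return An [image_stack].
#' @export
render_stack <- function(spec, truth) {
  d <- spec$dims
  vs <- spec$voxel_size
  sigma <- c(spec$psf_sigma[1], spec$psf_sigma[2], spec$psf_sigma[2])
  maxval <- 2^spec$bit_depth - 1

  z2 <- ((0:(d[1] - 1)) * vs[1] - truth$center[1])^2
  y2 <- ((0:(d[2] - 1)) * vs[2] - truth$center[2])^2
  x2 <- ((0:(d[3] - 1)) * vs[3] - truth$center[3])^2
  dist2 <- outer(outer(z2, y2, `+`), x2, `+`)
  dapi <- array(0, d)
  dapi[dist2 <= spec$nuclear_radius^2] <- spec$dapi_fill_level
  for (bb in truth$backbones) {
    s_dep <- seq(0, bb$arc_length, by = max(min(vs), 0.15))
    for (s in s_dep)
      dapi <- add_gaussian_spot(dapi, point_at_arc(bb, s),
                                spec$backbone_dapi_amp, sigma, vs)
  }

  probe_channels <- unique(truth$spots$channel)
  channels <- vector("list", 1L + length(probe_channels))
  names(channels) <- c("DAPI", probe_channels)
  finish <- function(vol) {
    vol <- vol + spec$background_level +
      stats::rnorm(length(vol), sd = spec$noise_sd)
    array(pmin(pmax(round(vol), 0), maxval), d)
  }
  channels[["DAPI"]] <- voxel_grid(finish(dapi), vs, "DAPI")
  for (ch in probe_channels) {
    vol <- array(0, d)
    sp <- truth$spots[truth$spots$channel == ch, , drop = FALSE]
    for (i in seq_len(nrow(sp)))
      vol <- add_gaussian_spot(vol, c(sp$z_um[i], sp$y_um[i], sp$x_um[i]),
                               spec$spot_amplitude, sigma, vs)
    channels[[ch]] <- voxel_grid(finish(vol), vs, ch)
  }
  image_stack(channels, stack_id = spec$stack_id, dapi_channel = "DAPI")
}

#' Simulate one ground-truthed nucleus
#'
#' Runs the full generative model under the spec's seed: backbones, true
#' spot positions, true probe centroids and pairwise centroid distances,
#' then renders the multi-channel stack. The returned truth table is
#' internally consistent (distances are recomputable from positions).
#'
#' @param spec a [synthetic_spec].
#' @param render render the image stack (set FALSE to generate geometry
#'   only, e.g. for fast property checks).
#' @return List with `stack` (an [image_stack], or NULL), and `truth`: a
#'   list with `center`, `nuclear_radius`, `spots`, `centroids`,
#'   `pair_distances`, `backbones`, `seed`.
#' @export
simulate_nucleus <- function(spec, render = TRUE) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)

  center <- (spec$dims - 1L) * spec$voxel_size / 2
  config <- if (spec$configuration == "custom") "territorial" else
    spec$configuration
  pole <- random_unit()
  backbones <- lapply(spec$chromosomes, function(cs)
    generate_backbone(cs, spec$nuclear_radius, center,
                      configuration = config, pole = pole))
  spots <- do.call(rbind, Map(place_probes, backbones, spec$chromosomes))
  if (is.null(spots)) stop("spec contains no probes")
  rownames(spots) <- NULL

  cents <- do.call(rbind, lapply(split(spots, spots$probe_id), function(sp)
    data.frame(probe_id = sp$probe_id[1], channel = sp$channel[1],
               n_spots = nrow(sp), z_um = mean(sp$z_um),
               y_um = mean(sp$y_um), x_um = mean(sp$x_um),
               stringsAsFactors = FALSE)))
  rownames(cents) <- NULL
  ids <- cents$probe_id
  pairs <- if (length(ids) >= 2L) {
    cmb <- utils::combn(seq_along(ids), 2L)
    data.frame(probe_a = ids[cmb[1, ]], probe_b = ids[cmb[2, ]],
               distance_um = vapply(seq_len(ncol(cmb)), function(k) {
                 i <- cmb[1, k]; j <- cmb[2, k]
                 sqrt(sum((as.numeric(cents[i, c("z_um", "y_um", "x_um")]) -
                           as.numeric(cents[j, c("z_um", "y_um", "x_um")]))^2))
               }, numeric(1)),
               stringsAsFactors = FALSE)
  } else {
    data.frame(probe_a = character(0), probe_b = character(0),
               distance_um = numeric(0), stringsAsFactors = FALSE)
  }
  truth <- list(center = center, nuclear_radius = spec$nuclear_radius,
                spots = spots, centroids = cents, pair_distances = pairs,
                backbones = backbones, seed = spec$seed)
  list(stack = if (render) render_stack(spec, truth) else NULL,
       truth = truth)
}

#' Preset simulation scenarios
#'
#' Fully parameterized specs for the six measurement scenarios the package
#' is validated against, each programming the true probe-pair separation to
#' a published measurement on real nuclei:
#' \describe{
#'   \item{wt_stage4}{territorial nurse-cell nucleus, stage 4; 2 Mb X
#'     probe pair at 1.18 µm, compact backbone.}
#'   \item{wt_stage10}{territorial, stage 10 (large nucleus); pair at
#'     0.80 µm.}
#'   \item{mutant_stage4}{Condensin II mutant (polytene/Rabl), stage 4;
#'     pair at 2.17 µm.}
#'   \item{mutant_stage10}{polytene/Rabl, stage 10; pair at 9.88 µm with
#'     backbone arc length 12.87 µm (the directly traced curved path).}
#'   \item{salivary_control}{polytene salivary-gland nucleus; two LacO/GFP
#'     bands (one shared channel) at 14.2 µm.}
#'   \item{salivary_capH2}{Cap-H2-overexpressing salivary gland; LacO
#'     bands at 6.0 µm.}
#' }
#' Nuclear radii (5, 12, 18 µm) and voxel sizes are simulator choices.
#'
#' @param name preset name.
#' @param seed seed stored in the returned spec.
#' @param stack_id stack label.
#' @return A [synthetic_spec].
#' @export
preset_scenarios <- function(name, seed = 1L, stack_id = name) {
  presets <- list(
    wt_stage4 = list(radius = 5, sep = 1.18, arc = 1.7,
                     config = "territorial", voxel = c(0.4, 0.2, 0.2),
                     channels = c("Alexa488", "Alexa647"),
                     psf = c(0.6, 0.25)),
    wt_stage10 = list(radius = 12, sep = 0.80, arc = 1.3,
                      config = "territorial", voxel = c(0.5, 0.25, 0.25),
                      channels = c("Alexa488", "Alexa647"),
                      psf = c(0.6, 0.25)),
    mutant_stage4 = list(radius = 5, sep = 2.17, arc = 3.2,
                         config = "polytene_rabl", voxel = c(0.4, 0.2, 0.2),
                         channels = c("Alexa488", "Alexa647"),
                         psf = c(0.6, 0.25)),
    mutant_stage10 = list(radius = 12, sep = 9.88, arc = 12.87,
                          config = "polytene_rabl",
                          voxel = c(0.5, 0.25, 0.25),
                          channels = c("Alexa488", "Alexa647"),
                          psf = c(0.6, 0.25)),
    salivary_control = list(radius = 18, sep = 14.2, arc = 16.5,
                            config = "polytene_rabl",
                            voxel = c(0.6, 0.35, 0.35),
                            channels = c("GFP", "GFP"), psf = c(0.8, 0.5)),
    salivary_capH2 = list(radius = 18, sep = 6.0, arc = 7.0,
                          config = "territorial",
                          voxel = c(0.6, 0.35, 0.35),
                          channels = c("GFP", "GFP"), psf = c(0.8, 0.5)))
  if (!name %in% names(presets))
    stop(sprintf("unknown preset '%s'; available: %s", name,
                 paste(names(presets), collapse = ", ")))
  p <- presets[[name]]
  probe_ids <- if (p$channels[1] == p$channels[2])
    c("LacO_50F", "LacO_60F") else c("X_probe_A", "X_probe_B")
  cs <- chromosome_spec(
    name = "chr_pair", genomic_length = 2, compaction = p$arc / 2,
    n_chromatids = if (p$config == "polytene_rabl") 512L else 32L,
    pairing = 1,
    territory_radius = max(2, p$sep),
    probes = data.frame(probe_id = probe_ids, channel = p$channels,
                        mb = c(0, 2), class = "locus",
                        stringsAsFactors = FALSE),
    pin_separation = p$sep)
  synthetic_spec(nuclear_radius = p$radius, voxel_size = p$voxel,
                 configuration = p$config, chromosomes = list(cs),
                 psf_sigma = p$psf, seed = seed, stack_id = stack_id)
}
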