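two_probe_cs <- function(...) {
  chromosome_spec(name = "X", genomic_length = 2, compaction = 1.5,
                  probes = data.frame(probe_id = c("a", "b"),
                                      channel = c("Alexa488", "Alexa647"),
                                      mb = c(0, 2), class = "locus"),
                  ...)
}

test_that("free backbones honour the arc-length and confinement contracts", {
  set.seed(1)
  ctr <- c(8, 8, 8)
  cs <- chromosome_spec("X", genomic_length = 10, compaction = 0.9,
                        territory_radius = 2.5)
  bb_t <- generate_backbone(cs, nuclear_radius = 6, center = ctr,
                            configuration = "territorial")
  expect_lt(abs(bb_t$arc_length - 9) / 9, 0.02)
  d_to_tc <- sqrt(rowSums(sweep(bb_t$polyline, 2, bb_t$territory_center)^2))
  expect_true(all(d_to_tc <= 2.5 + 1e-9))

  pole <- c(0, 0, 1)
  bb_r <- generate_backbone(cs, nuclear_radius = 6, center = ctr,
                            configuration = "polytene_rabl", pole = pole)
  # centromeric end anchored at the pole, just inside the surface
  expect_lt(abs(sqrt(sum((bb_r$polyline[1, ] - ctr)^2)) - 6), 0.3)
  expect_gt(sum((bb_r$polyline[1, ] - ctr) * pole), 5.5)
  d_to_c <- sqrt(rowSums(sweep(bb_r$polyline, 2, ctr)^2))
  expect_true(all(d_to_c <= 6 + 1e-9))

  # infeasible confinement errors with a diagnostic
  bad <- chromosome_spec("X", genomic_length = 1000, compaction = 10,
                         territory_radius = 1)
  expect_error(generate_backbone(bad, 6, ctr, "territorial"),
               "infeasible confinement")
})

test_that("pinned backbones realize the programmed chord and arc length", {
  set.seed(2)
  cs <- chromosome_spec("X", genomic_length = 2, compaction = 12.87 / 2,
                        probes = data.frame(probe_id = c("a", "b"),
                                            channel = c("g", "r"),
                                            mb = c(0, 2), class = "locus"),
                        pin_separation = 9.88)
  ctr <- c(13, 13, 13)
  bb <- generate_backbone(cs, nuclear_radius = 12, center = ctr,
                          configuration = "polytene_rabl")
  chord <- sqrt(sum((bb$polyline[nrow(bb$polyline), ] - bb$polyline[1, ])^2))
  expect_equal(chord, 9.88, tolerance = 1e-9)
  expect_lt(abs(bb$arc_length - 12.87) / 12.87, 0.001)
  expect_error(
    chromosome_spec("X", genomic_length = 2, compaction = 1,
                    probes = data.frame(probe_id = c("a", "b"),
                                        channel = c("g", "r"), mb = c(0, 2)),
                    pin_separation = 5),
    "exceeds")
})

test_that("spot multiplicity follows the chromatid-pairing model", {
  set.seed(3)
  cs1 <- two_probe_cs(n_chromatids = 8, pairing = 1)
  bb <- generate_backbone(cs1, 6, c(8, 8, 8), "territorial")
  expect_equal(nrow(place_probes(bb, cs1)), 2)  # one spot per probe

  cs0 <- two_probe_cs(n_chromatids = 4, pairing = 0)
  sp0 <- place_probes(bb, cs0)
  expect_equal(as.numeric(table(sp0$probe_id)), c(4, 4))

  # heterochromatin probes stay paired regardless of the pairing fraction
  cs_het <- chromosome_spec("X", genomic_length = 2, compaction = 1.5,
                            n_chromatids = 16, pairing = 0,
                            probes = data.frame(probe_id = "het",
                                                channel = "g", mb = 0,
                                                class = "heterochromatin"))
  expect_equal(nrow(place_probes(bb, cs_het)), 1)

  # binomial expectation: pairing .5, 32 chromatids -> mean 16.5
  cs_half <- two_probe_cs(n_chromatids = 32, pairing = 0.5)
  counts <- replicate(200, nrow(place_probes(bb, cs_half)) / 2)
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - 16.5), 3 * se)
})

test_that("ground truth is self-consistent and seeded rendering is reproducible", {
  spec <- preset_scenarios("wt_stage4", seed = 7)
  sim1 <- simulate_nucleus(spec)
  # distances recomputable from positions, exactly
  cents <- sim1$truth$centroids
  d_re <- sqrt(sum((as.numeric(cents[1, c("z_um", "y_um", "x_um")]) -
                    as.numeric(cents[2, c("z_um", "y_um", "x_um")]))^2))
  expect_equal(sim1$truth$pair_distances$distance_um, d_re)
  expect_equal(d_re, 1.18, tolerance = 1e-9)

  sim2 <- simulate_nucleus(spec)
  expect_identical(sim1$stack$channels$DAPI$data,
                   sim2$stack$channels$DAPI$data)
  spec3 <- preset_scenarios("wt_stage4", seed = 8)
  sim3 <- simulate_nucleus(spec3)
  expect_false(identical(sim1$stack$channels$DAPI$data,
                         sim3$stack$channels$DAPI$data))
})

test_that("noise-free spots are recovered at the true position within half a voxel", {
  spec <- preset_scenarios("wt_stage4", seed = 11)
  spec$noise_sd <- 1e-6
  spec$background_level <- 0
  sim <- simulate_nucleus(spec)
  seg <- segment_channel(sim$stack$channels$Alexa488, 35)
  expect_equal(nrow(seg$objects), 1)
  true_pos <- unlist(sim$truth$spots[sim$truth$spots$channel == "Alexa488",
                                     c("z_um", "y_um", "x_um")])
  got <- unlist(seg$objects[1, c("centroid_z_um", "centroid_y_um",
                                 "centroid_x_um")])
  expect_true(all(abs(got - true_pos) <= spec$voxel_size / 2))
})

test_that("rendered DAPI recovers the spec nuclear radius within 5%", {
  spec <- preset_scenarios("wt_stage4", seed = 13)
  sim <- simulate_nucleus(spec)
  nm <- fit_nucleus(sim$stack$channels$DAPI, threshold = 25)
  expect_lt(abs(nm$radius_volume - spec$nuclear_radius) /
              spec$nuclear_radius, 0.05)
  expect_lt(abs(nm$radius_fit - spec$nuclear_radius) /
              spec$nuclear_radius, 0.05)
})

test_that("presets program the published separations; unknown names error", {
  expect_equal(preset_scenarios("wt_stage4")$chromosomes[[1]]$pin_separation,
               1.18)
  expect_equal(
    preset_scenarios("salivary_control")$chromosomes[[1]]$pin_separation,
    14.2)
  expect_equal(
    preset_scenarios("mutant_stage10")$chromosomes[[1]]$compaction * 2,
    12.87)
  expect_error(preset_scenarios("nope"), "wt_stage4")
})

test_that("separation grows with axial extension (µm/Mb) in expectation", {
  set.seed(17)
  sep_at <- function(compaction) {
    cs <- two_probe_cs(territory_radius = 6)
    cs$compaction <- compaction
    mean(replicate(30, {
      bb <- generate_backbone(cs, 8, c(10, 10, 10), "territorial")
      sp <- place_probes(bb, cs)
      sqrt(sum((unlist(sp[1, c("z_um", "y_um", "x_um")]) -
                unlist(sp[2, c("z_um", "y_um", "x_um")]))^2))
    }))
  }
  seps <- c(sep_at(0.5), sep_at(1.5), sep_at(4))
  expect_true(all(diff(seps) > 0))
})
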