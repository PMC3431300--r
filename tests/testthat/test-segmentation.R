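vs <- c(0.4, 0.2, 0.2)

test_that("threshold boundary is inclusive and degenerate cases behave", {
  vol <- array(0, c(1, 1, 3))
  vol[1, 1, ] <- c(24, 25, 26)
  g <- voxel_grid(vol, vs, "DAPI")
  expect_equal(as.logical(threshold_mask(g, 25)), c(FALSE, TRUE, TRUE))
  expect_false(any(threshold_mask(voxel_grid(array(0, c(4, 4, 4)), vs), 25)))
  expect_true(all(threshold_mask(g, 0)))
  expect_error(threshold_mask(g, -1), ">= 0")
})

test_that("raising the threshold never increases included voxel count", {
  set.seed(31)
  g <- voxel_grid(array(sample(0:255, 1000, TRUE), c(10, 10, 10)), vs)
  counts <- vapply(c(0, 25, 35, 55, 100, 255), function(th)
    sum(threshold_mask(g, th)), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("connectivity semantics: corner contact merges only under 26", {
  mask <- array(FALSE, c(3, 3, 3))
  mask[1, 1, 1] <- TRUE
  mask[2, 2, 2] <- TRUE  # corner neighbour of (1,1,1)
  expect_equal(length(label_components(mask, 26)$sizes), 1L)
  expect_equal(length(label_components(mask, 6)$sizes), 2L)
  # edge contact merges under 18 but not 6
  mask2 <- array(FALSE, c(3, 3, 3))
  mask2[1, 1, 1] <- TRUE
  mask2[1, 2, 2] <- TRUE
  expect_equal(length(label_components(mask2, 18)$sizes), 1L)
  expect_equal(length(label_components(mask2, 6)$sizes), 2L)
  # isolated voxel
  single <- array(FALSE, c(3, 3, 3)); single[2, 2, 2] <- TRUE
  lab <- label_components(single, 26)
  expect_equal(lab$sizes, 1L)
})

test_that("labeling matches the flood-fill oracle on random masks", {
  set.seed(97)
  for (i in 1:12) {
    mask <- array(runif(16^3) < runif(1, 0.1, 0.6), c(16, 16, 16))
    conn <- sample(c(6L, 18L, 26L), 1)
    expect_identical(label_components(mask, conn)$labels,
                     flood_fill_oracle(mask, conn))
  }
})

test_that("size filter keeps components of at least min_voxels", {
  vol <- array(0, c(4, 30, 4))
  vol[1:3, 1:1, 1:3] <- 50          # 9 voxels
  vol[1:2, 5:9, 1:1] <- 50          # 10 voxels
  vol[1:3, 12:16, 1:1] <- 50        # 15 voxels
  lab <- label_components(vol >= 50, 26)
  expect_setequal(lab$sizes, c(9L, 10L, 15L))
  kept <- filter_by_size(lab, 10)
  expect_setequal(kept$sizes, c(10L, 15L))
  expect_equal(max(kept$labels), 2L)
  # no-op filter and empty input
  expect_equal(filter_by_size(lab, 1)$sizes, lab$sizes)
  empty <- label_components(array(FALSE, c(2, 2, 2)), 26)
  expect_length(filter_by_size(empty, 10)$sizes, 0)
})

test_that("object features: weighted centroid, volume, conservation", {
  # two voxels on the x axis at 0 and 3 µm (dx = 1), intensities 1 and 3
  vol <- array(0, c(1, 1, 4))
  vol[1, 1, 1] <- 1; vol[1, 1, 4] <- 3
  g <- voxel_grid(vol, c(1, 1, 1), "p")
  obj <- extract_objects(g, array(1L, c(1, 1, 4)) * (vol > 0))
  expect_equal(obj$centroid_x_um, 2.25)
  expect_equal(obj$total_intensity, 4)
  expect_equal(obj$volume_um3, 2)

  # uniform cube: centroid at geometric center; equals unweighted mean
  cube <- array(0, c(7, 7, 7)); cube[3:5, 3:5, 3:5] <- 80
  gc <- voxel_grid(cube, vs, "p")
  seg <- segment_channel(gc, 40, min_voxels = 1)
  expect_equal(unlist(seg$objects[1, c("centroid_z_um", "centroid_y_um",
                                       "centroid_x_um")], use.names = FALSE),
               c(3 * vs[1], 3 * vs[2], 3 * vs[3]))

  # centroid invariant under positive intensity scaling
  seg2 <- segment_channel(voxel_grid(cube * 2.5, vs, "p"), 40, min_voxels = 1)
  expect_equal(seg2$objects$centroid_x_um, seg$objects$centroid_x_um)

  # conservation: total intensity over objects = sum over surviving voxels
  set.seed(5)
  noisy <- array(sample(0:255, 12^3, TRUE), c(12, 12, 12))
  gn <- voxel_grid(noisy, vs, "p")
  sg <- segment_channel(gn, 55, min_voxels = 3)
  expect_equal(sum(sg$objects$total_intensity),
               sum(noisy[sg$labels > 0]))
  # every surviving voxel belongs to exactly one object
  expect_equal(sum(sg$objects$voxel_count), sum(sg$labels > 0))
})

test_that("segment_stack applies per-channel thresholds and labels stacks", {
  vol_a <- array(0, c(6, 6, 6)); vol_a[2:4, 2:4, 2:4] <- 40
  vol_b <- array(0, c(6, 6, 6)); vol_b[2:4, 2:4, 2:4] <- 40
  stack <- image_stack(list(
    Alexa488 = voxel_grid(vol_a, vs, "Alexa488"),
    Alexa546 = voxel_grid(vol_b, vs, "Alexa546")), dapi_channel = NA)
  out <- segment_stack(stack, seg_params(min_voxels = 5))
  # 40 >= 35 passes Alexa488 threshold, fails the 55 Alexa546 threshold
  expect_equal(out$objects$channel, "Alexa488")
  expect_equal(out$objects$voxel_count, 27L)
  expect_equal(unique(out$objects$stack_id), "stack")
})
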