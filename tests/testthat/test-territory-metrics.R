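obj_df <- function(pos, inten) {
  data.frame(centroid_z_um = pos[, 1], centroid_y_um = pos[, 2],
             centroid_x_um = pos[, 3], total_intensity = inten)
}

test_that("probe-set centroid is the intensity-weighted mean of objects", {
  single <- obj_df(rbind(c(1, 2, 3)), 10)
  expect_equal(unname(probeset_centroid(single)), c(1, 2, 3))
  two <- obj_df(rbind(c(0, 0, 1), c(0, 0, 5)), c(7, 7))
  expect_equal(unname(probeset_centroid(two)["x"]), 3)
  weighted <- obj_df(rbind(c(0, 0, 0), c(0, 0, 4)), c(1, 3))
  expect_equal(unname(probeset_centroid(weighted)["x"]), 3)
  expect_error(probeset_centroid(obj_df(matrix(0, 0, 3), numeric(0))),
               "empty probe set")
})

test_that("centroid distances are Euclidean, symmetric and rigid-motion invariant", {
  a <- obj_df(rbind(c(0, 0, 0)), 1)
  expect_equal(centroid_distance(a, a), 0)
  expect_equal(centroid_distance(c(0, 0, 0), c(0, 3, 4)), 5)
  expect_equal(centroid_distance(c(0, 3, 4), c(0, 0, 0)), 5)
  # translation and rotation invariance on continuous coordinates
  set.seed(7)
  p1 <- rnorm(3); p2 <- rnorm(3)
  d0 <- centroid_distance(p1, p2)
  shift <- c(10, -4, 2)
  expect_equal(centroid_distance(p1 + shift, p2 + shift), d0)
  th <- 0.7
  rot <- rbind(c(1, 0, 0), c(0, cos(th), -sin(th)), c(0, sin(th), cos(th)))
  expect_equal(centroid_distance(as.numeric(rot %*% p1),
                                 as.numeric(rot %*% p2)), d0)
})

test_that("locus_pair_table builds one record per available pair", {
  cents <- list(p1 = c(0, 0, 0), p2 = c(0, 0, 2), p3 = c(0, 2, 0))
  pairs <- data.frame(probe_a = c("p1", "p1", "p2"),
                      probe_b = c("p2", "p3", "p3"),
                      mb_separation = c(2, 4, 2))
  tab <- locus_pair_table(cents, pairs, stack_id = "n1")
  expect_equal(nrow(tab), 3)
  expect_equal(tab$distance_um[1], 2)
  expect_equal(tab$mb_separation, c(2, 4, 2))
  # missing probe: skipped with a warning, not fatal
  expect_warning(
    tab2 <- locus_pair_table(cents[1:2],
                             data.frame(probe_a = "p1", probe_b = "p9")),
    "skipped")
  expect_equal(nrow(tab2), 0)
})

test_that("compaction folds reproduce the published worked examples", {
  f1 <- compaction_fold(9.88, 0.80)
  expect_equal(as.numeric(f1), 12.35)
  expect_equal(attr(f1, "direction"), "a/b")
  expect_equal(as.numeric(compaction_fold(3, 3)), 1)
  expect_equal(as.numeric(compaction_fold(144.3, 12.0)), 12.025)
  f2 <- compaction_fold(0.80, 9.88)
  expect_equal(as.numeric(f2), 12.35)
  expect_equal(attr(f2, "direction"), "b/a")
  expect_error(compaction_fold(0, 1), "> 0")
})

test_that("spot counts normalize by the probe-class divisor", {
  five <- obj_df(matrix(rnorm(15), 5, 3), rep(1, 5))
  expect_equal(as.numeric(spot_count(five, divisor = 5)), 1)
  expect_equal(as.numeric(spot_count(five[1, ], divisor = 1)), 1)
  zero <- spot_count(five[0, ])
  expect_equal(as.numeric(zero), 0)
  expect_true(attr(zero, "below_detection"))
  expect_error(spot_count(five, divisor = 0), "> 0")
})

test_that("weighted PCA: degeneracy, isotropy and weight-scale invariance", {
  # collinear points: second and third eigenvalues vanish
  line <- cbind(seq(0, 5, length.out = 10), 0, 0)
  sd_line <- weighted_pca(line)
  expect_equal(sd_line$eigenvalues[2:3], c(0, 0), tolerance = 1e-12)
  expect_error(weighted_pca(line[1, , drop = FALSE]), "2 distinct")

  # isotropic Gaussian cloud: anisotropy near 1 at n = 500
  set.seed(42)
  cloud <- matrix(rnorm(1500), ncol = 3)
  sd_iso <- weighted_pca(cloud)
  expect_lt(sd_iso$anisotropy, 1.5)
  expect_gte(sd_iso$anisotropy, 1)

  # doubling all weights changes nothing; unequal weights do
  w <- runif(500, 0.5, 2)
  a <- weighted_pca(cloud, w)
  b <- weighted_pca(cloud, 2 * w)
  expect_equal(a$eigenvalues, b$eigenvalues)
  expect_equal(abs(a$axes), abs(b$axes), tolerance = 1e-9)
  # axes are orthonormal
  expect_equal(crossprod(a$axes), diag(3), tolerance = 1e-9)
})

test_that("path_length integrates polylines to analytic arc lengths", {
  expect_equal(path_length(rbind(c(0, 0, 0), c(0, 3, 4))), 5)
  th <- seq(0, pi, length.out = 1000)
  r <- 2.5
  semi <- cbind(0, r * sin(th), r * cos(th))
  expect_lt(abs(path_length(semi) - pi * r) / (pi * r), 0.001)
  expect_error(path_length(rbind(c(0, 0, 0))), "at least 2")
})

test_that("mean random-point distance in a ball approaches 36R/35", {
  est <- mean_random_sphere_distance(1, n_samples = 2e5, seed = 99)
  expect_lt(abs(as.numeric(est) - 36 / 35), 3 * attr(est, "se"))
  # linear scaling with radius (same seed, exact)
  est2 <- mean_random_sphere_distance(2, n_samples = 1e4, seed = 123)
  est1 <- mean_random_sphere_distance(1, n_samples = 1e4, seed = 123)
  expect_equal(as.numeric(est2), 2 * as.numeric(est1))
  # the mean is within ~3% of the radius itself
  expect_lt(abs(as.numeric(est) - 1), 0.03)
})
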