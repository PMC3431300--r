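as_point <- function(x) {
  if (is.data.frame(x)) probeset_centroid(x) else {
    p <- as.numeric(x)
    if (length(p) != 3L) stop("a point must be (z, y, x) in µm")
    p
  }
}

#' Probe-set centroid
#'
#' The position of one FISH probe in one nucleus is the center of its total
#' fluorescence intensity: the intensity-weighted mean of its objects'
#' centroids, with weights equal to each object's total intensity. When a
#' probe yields several spots (unpaired chromatids), this single centroid
#' represents the locus.
#'
#' @param objects data.frame of segmented objects belonging to one probe
#'   (columns `centroid_z_um`, `centroid_y_um`, `centroid_x_um`,
#'   `total_intensity`).
#' @return Named numeric `(z, y, x)` in µm.
#' @export
probeset_centroid <- function(objects) {
  if (nrow(objects) == 0L) stop("empty probe set: no objects to average")
  w <- objects$total_intensity
  ctr <- c(
    z = sum(w * objects$centroid_z_um) / sum(w),
    y = sum(w * objects$centroid_y_um) / sum(w),
    x = sum(w * objects$centroid_x_um) / sum(w))
  ctr
}

#' Euclidean distance between two probe centroids
#'
#' @param a,b probe-set object data.frames or `(z, y, x)` µm points.
#' @return Distance in µm.
#' @export
centroid_distance <- function(a, b) {
  sqrt(sum((as_point(a) - as_point(b))^2))
}

#' Per-nucleus locus-pair distance records
#'
#' For each requested pair of probes present in a nucleus, records the 3D
#' centroid distance together with the genomic (Mb) separation from the
#' probe metadata. Pairs with a missing probe are skipped with a warning,
#' not an error.
#'
#' @param centroids named list of probe centroids (`probe_id` -> `(z,y,x)`
#'   µm) for one nucleus.
#' @param pairs data.frame with columns `probe_a`, `probe_b` and optional
#'   `mb_separation`.
#' @param stack_id,genotype,stage labels copied into the records.
#' @return data.frame of distance records (possibly 0 rows).
#' @export
locus_pair_table <- function(centroids, pairs, stack_id = NA_character_,
                             genotype = NA_character_, stage = NA_character_) {
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    a <- as.character(pairs$probe_a[i]); b <- as.character(pairs$probe_b[i])
    if (is.null(centroids[[a]]) || is.null(centroids[[b]])) {
      warning(sprintf("stack %s: pair (%s, %s) skipped, probe missing",
                      stack_id, a, b))
      return(NULL)
    }
    data.frame(stack_id = stack_id, genotype = genotype, stage = stage,
               probe_a = a, probe_b = b,
               mb_separation = if ("mb_separation" %in% names(pairs))
                 pairs$mb_separation[i] else NA_real_,
               distance_um = centroid_distance(centroids[[a]], centroids[[b]]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(stack_id = character(0), genotype = character(0),
                      stage = character(0), probe_a = character(0),
                      probe_b = character(0), mb_separation = numeric(0),
                      distance_um = numeric(0), stringsAsFactors = FALSE)
  out
}

#' Axial compaction fold between two conditions
#'
#' Ratio of two inter-locus distances measured under different conditions
#' (e.g. Condensin II mutant vs. wild type). By convention the longer
#' distance goes in the numerator so folds are >= 1; whether the arguments
#' were swapped is recorded in the `direction` attribute.
#'
#' @param distance_a,distance_b positive distances in µm.
#' @return Dimensionless fold (>= 1) with attribute `direction` (`"a/b"` or
#'   `"b/a"`).
#' @export
compaction_fold <- function(distance_a, distance_b) {
  if (distance_a <= 0 || distance_b <= 0)
    stop("distances must be > 0")
  if (distance_a >= distance_b) {
    structure(distance_a / distance_b, direction = "a/b")
  } else {
    structure(distance_b / distance_a, direction = "b/a")
  }
}

#' Spot count for a probe
#'
#' The spot count is simply the number of objects detected for the probe,
#' optionally divided by a normalization constant (5 for the telomeric
#' probe class, which targets five telomeres at once).
#'
#' @param objects probe object data.frame, or an integer count.
#' @param divisor positive normalization divisor (default 1).
#' @return Real-valued normalized count; 0 carries attribute
#'   `below_detection = TRUE`.
#' @export
spot_count <- function(objects, divisor = 1) {
  if (divisor <= 0) stop("divisor must be > 0")
  n <- if (is.data.frame(objects)) nrow(objects) else as.numeric(objects)
  out <- n / divisor
  if (n == 0) attr(out, "below_detection") <- TRUE
  out
}

#' Intensity-weighted principal component shape descriptor
#'
#' Eigen-decomposition of the weighted covariance of object centroids about
#' the weighted mean, with point weights equal to each object's total
#' fluorescence intensity. Describes the spatial shape of a set of FISH
#' signals: a Rabl-elongated chromosome has a dominant first axis, a
#' compact globular territory near-equal eigenvalues.
#'
#' @param points objects data.frame (centroid columns + `total_intensity`)
#'   or an n x 3 matrix of `(z, y, x)` µm points.
#' @param weights positive weights, required when `points` is a matrix
#'   (default equal weights).
#' @return List of class `shape_descriptor`: `eigenvalues` (descending,
#'   µm²), `axes` (3x3, columns = principal directions), `anisotropy`
#'   (largest/smallest eigenvalue; `Inf` when degenerate).
#' @export
weighted_pca <- function(points, weights = NULL) {
  if (is.data.frame(points)) {
    weights <- points$total_intensity
    points <- as.matrix(points[, c("centroid_z_um", "centroid_y_um",
                                   "centroid_x_um")])
  }
  points <- as.matrix(points)
  if (is.null(weights)) weights <- rep(1, nrow(points))
  if (nrow(points) < 2L || nrow(unique(points)) < 2L)
    stop("weighted_pca needs at least 2 distinct points")
  if (any(weights <= 0)) stop("weights must be > 0")
  w <- weights / sum(weights)
  mu <- colSums(points * w)
  centered <- sweep(points, 2L, mu)
  cov_w <- crossprod(centered * w, centered)  # sum_i w_i (p_i-mu)(p_i-mu)'
  eig <- eigen(cov_w, symmetric = TRUE)
  ev <- pmax(eig$values, 0)
  structure(list(eigenvalues = ev, axes = eig$vectors,
                 anisotropy = if (ev[3] > 0) ev[1] / ev[3] else Inf,
                 center = mu),
            class = "shape_descriptor")
}

#' Length of a traced 3D path
#'
#' Sum of Euclidean segment lengths along an ordered polyline, as used for
#' directly tracing the curved path of a polytene chromosome between two
#' loci.
#'
#' @param polyline n x 3 matrix of ordered `(z, y, x)` µm points, n >= 2.
#' @return Arc length in µm.
#' @export
path_length <- function(polyline) {
  polyline <- as.matrix(polyline)
  if (nrow(polyline) < 2L) stop("a path needs at least 2 points")
  seg <- diff(polyline)
  sum(sqrt(rowSums(seg^2)))
}

#' Mean distance between two random points in a ball
#'
#' Monte-Carlo estimate of the expected distance between two independent
#' uniform points inside a sphere of the given radius. The exact value is
#' `36 R / 35 ≈ 1.0286 R`, which is why the mean nuclear radius is a good
#' approximation for the expected separation of two unrelated loci.
#'
#' @param radius sphere radius in µm.
#' @param n_samples number of point pairs.
#' @param seed optional RNG seed (local to this call).
#' @return Estimated mean distance (µm) with attribute `se` (standard
#'   error).
#' @export
mean_random_sphere_distance <- function(radius, n_samples = 1e5, seed = NULL) {
  if (n_samples < 1) stop("n_samples must be >= 1")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  p1 <- runif_ball(n_samples, radius)
  p2 <- runif_ball(n_samples, radius)
  d <- sqrt(rowSums((p1 - p2)^2))
  structure(mean(d), se = stats::sd(d) / sqrt(n_samples))
}

# n uniform points in a ball of given radius, by direction x radial CDF
runif_ball <- function(n, radius = 1) {
  u <- matrix(stats::rnorm(3 * n), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  r <- radius * stats::runif(n)^(1 / 3)
  u * r
}
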