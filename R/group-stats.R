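#' Group summary: mean, SEM, n
#'
#' Aggregates per-nucleus measurements into the group summaries reported in
#' bar charts: mean, standard error of the mean (sample SD with n-1
#' denominator over sqrt(n)), and the number of nuclei. A single-value
#' group has an undefined SEM (returned as NA).
#'
#' @param values numeric per-nucleus measurements (NAs dropped).
#' @param group group label (e.g. genotype x stage).
#' @param metric metric name recorded in the output.
#' @return One-row data.frame: `group`, `metric`, `n`, `mean`, `sem`.
#' @export
summarize_group <- function(values, group = "group", metric = "metric") {
  values <- values[!is.na(values)]
  if (length(values) == 0L) stop("empty group: nothing to summarize")
  n <- length(values)
  data.frame(group = group, metric = metric, n = n, mean = mean(values),
             sem = if (n >= 2L) stats::sd(values) / sqrt(n) else NA_real_,
             stringsAsFactors = FALSE)
}

#' Significance stars for a p-value
#'
#' Star convention used throughout: one asterisk for p < .05, two for
#' p < .01, three for p < .001.
#'
#' @param p p-value in `[0, 1]`.
#' @return `""`, `"*"`, `"**"` or `"***"`.
#' @export
significance_stars <- function(p) {
  vapply(p, function(pi) {
    if (is.na(pi)) return(NA_character_)
    if (pi < 0.001) "***" else if (pi < 0.01) "**" else if (pi < 0.05) "*" else ""
  }, character(1))
}

#' Compare two groups of per-nucleus measurements
#'
#' Default is a two-sided Welch unequal-variance t-test on per-nucleus
#' values; a two-sided permutation test on the difference of means is
#' available for distance distributions that are far from normal. No
#' multiple-testing correction is applied: each pair is reported with its
#' own per-comparison p-value and stars, so families of many comparisons
#' should be interpreted accordingly.
#'
#' @param a,b numeric vectors, each with n >= 2.
#' @param method `"welch"` (default) or `"permutation"`.
#' @param n_perm permutation count for `method = "permutation"`.
#' @return List: `p_value`, `stars`, `method`, `estimate` (mean difference
#'   a - b).
#' @export
compare_groups <- function(a, b, method = c("welch", "permutation"),
                           n_perm = 10000L) {
  method <- match.arg(method)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 values")
  if (method == "welch") {
    ht <- stats::t.test(a, b, var.equal = FALSE)
    p <- unname(ht$p.value)
  } else {
    obs <- abs(mean(a) - mean(b))
    pooled <- c(a, b)
    na <- length(a)
    exceed <- sum(vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(length(pooled), na)
      abs(mean(pooled[idx]) - mean(pooled[-idx])) >= obs
    }, logical(1)))
    p <- (exceed + 1) / (n_perm + 1)
  }
  list(p_value = p, stars = significance_stars(p), method = method,
       estimate = mean(a) - mean(b))
}

#' Summarize a measurement table by group
#'
#' Convenience wrapper producing one [summarize_group] row per group for a
#' long table of per-nucleus values.
#'
#' @param df data.frame of per-nucleus measurements.
#' @param value_col name of the numeric value column.
#' @param group_cols character vector of grouping columns.
#' @param metric metric name for the output.
#' @return data.frame with one row per group.
#' @export
summarize_metric <- function(df, value_col, group_cols, metric = value_col) {
  if (nrow(df) == 0L)
    return(data.frame(group = character(0), metric = character(0),
                      n = integer(0), mean = numeric(0), sem = numeric(0),
                      stringsAsFactors = FALSE))
  key <- do.call(paste, c(lapply(group_cols, function(g) df[[g]]), sep = ":"))
  out <- do.call(rbind, lapply(split(df[[value_col]], key), function(v) {
    summarize_group(v, metric = metric)
  }))
  out$group <- names(split(df[[value_col]], key))
  rownames(out) <- NULL
  out[, c("group", "metric", "n", "mean", "sem")]
}
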