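#' Two-sided Wilcoxon rank-sum comparison of two groups
#'
#' Unpaired, two-sided rank-sum test.  The exact permutation distribution is
#' used when the smaller group has at most `exact_max` observations and the
#' pooled data are tie-free; otherwise the normal approximation with tie
#' correction (and continuity correction) is used.  If every pooled value is
#' identical the comparison is degenerate and p = 1 is returned with
#' `degenerate = TRUE`.
#'
#' @param x,y numeric vectors, each of length >= 2.
#' @param exact_max switch-over size for the exact distribution (default 10,
#'   so the small groups typical of resolution classes are handled exactly).
#' @param alpha significance level recorded in the result (default 0.05).
#' @return A `group_comparison` object: list with `test`, `statistic`,
#'   `p_value`, `n_per_group`, `exact`, `degenerate`, `alpha`,
#'   `two_sided = TRUE`.
#' @examples
#' wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))$p_value  # exact: 0.1
#' @export
wilcoxon_rank_sum <- function(x, y, exact_max = 10, alpha = 0.05) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 2 || length(y) < 2)
    stop("wilcoxon_rank_sum: need n >= 2 per group", call. = FALSE)
  pooled <- c(x, y)
  if (length(unique(pooled)) == 1L)
    return(structure(list(test = "wilcoxon_rank_sum", statistic = NA_real_,
                          p_value = 1, n_per_group = c(length(x), length(y)),
                          exact = FALSE, degenerate = TRUE, alpha = alpha,
                          two_sided = TRUE), class = "group_comparison"))
  ties <- anyDuplicated(pooled) > 0
  use_exact <- !ties && min(length(x), length(y)) <= exact_max
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = use_exact,
                       correct = TRUE))
  structure(list(test = "wilcoxon_rank_sum",
                 statistic = unname(ht$statistic), p_value = ht$p.value,
                 n_per_group = c(length(x), length(y)), exact = use_exact,
                 degenerate = FALSE, alpha = alpha, two_sided = TRUE),
            class = "group_comparison")
}

#' Two-sided F test for equality of variances
#'
#' `F = var(x)/var(y)` referred to the F distribution with
#' `(n_x - 1, n_y - 1)` degrees of freedom, two-sided.
#'
#' @param x,y numeric vectors, each of length >= 2; `y` must have non-zero
#'   variance.
#' @param alpha significance level recorded in the result.
#' @return A `group_comparison` object (see [wilcoxon_rank_sum]).
#' @export
variance_f_test <- function(x, y, alpha = 0.05) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 2 || length(y) < 2)
    stop("variance_f_test: need n >= 2 per group", call. = FALSE)
  if (stats::var(y) == 0)
    stop("variance_f_test: zero variance in denominator group",
         call. = FALSE)
  ht <- stats::var.test(x, y, alternative = "two.sided")
  structure(list(test = "variance_F", statistic = unname(ht$statistic),
                 p_value = ht$p.value,
                 n_per_group = c(length(x), length(y)), exact = TRUE,
                 degenerate = FALSE, alpha = alpha, two_sided = TRUE),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s: statistic %s, p = %.4g (n = %d vs %d)%s\n",
              x$test,
              if (is.na(x$statistic)) "NA" else format(x$statistic),
              x$p_value, x$n_per_group[1], x$n_per_group[2],
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Group-wise mean and standard deviation of a change table
#'
#' @param data data frame of per-lobe (or per-metric) changes.
#' @param value_col name of the numeric column to summarise.
#' @param group_col name of the grouping column.
#' @return Data frame with `group`, `n`, `mean`, `stdev` (sample, n-1;
#'   reported as 0 with `stdev_degenerate = TRUE` when n = 1).
#' @export
summarize_changes <- function(data, value_col, group_col) {
  stopifnot(value_col %in% names(data), group_col %in% names(data))
  sp <- split(data[[value_col]], data[[group_col]])
  out <- do.call(rbind, lapply(names(sp), function(g) {
    v <- sp[[g]]
    data.frame(group = g, n = length(v), mean = mean(v),
               stdev = if (length(v) > 1) stats::sd(v) else 0,
               stdev_degenerate = length(v) == 1)
  }))
  rownames(out) <- NULL
  out
}

#' Mean within-patient standard deviation across repeat scan pairings
#'
#' For patients with several baseline/followup pairings, computes the
#' standard deviation of the change across pairings within each patient,
#' then averages over patients with more than one pairing.
#'
#' @param data data frame with one row per (patient, pairing).
#' @param value_col numeric column of changes.
#' @param patient_col patient identifier column.
#' @return Mean intra-patient SD (NA if no patient has repeat pairings).
#' @export
intra_patient_sd <- function(data, value_col, patient_col = "patient") {
  sp <- split(data[[value_col]], data[[patient_col]])
  sds <- vapply(sp, function(v) if (length(v) > 1) stats::sd(v) else NA_real_,
                numeric(1))
  if (all(is.na(sds))) NA_real_ else mean(sds, na.rm = TRUE)
}
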