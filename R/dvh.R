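#' Dose-volume-histogram metrics
#'
#' Computes a single DVH metric for one structure: `D_max`, `D_mean` and
#' `D_min` are the extrema / mean dose over the structure's voxels (Gy);
#' `V_x` is the percentage of the structure volume receiving at least
#' `x_gy` Gy (closed lower bound, dose >= x); `V_Rx` is `V_x` at the
#' prescription dose.
#'
#' @param dose a [volume_grid] of dose in Gy.
#' @param mask non-empty logical array congruent with `dose`.
#' @param metric one of `"D_max"`, `"D_mean"`, `"D_min"`, `"V_x"`, `"V_Rx"`.
#' @param x_gy threshold for `V_x`, in Gy (> 0).
#' @param rx_gy prescription dose for `V_Rx`, in Gy.
#' @return Numeric scalar (Gy for D metrics, % structure volume for V).
#' @export
dvh_metric <- function(dose, mask, metric = c("D_max", "D_mean", "D_min",
                                              "V_x", "V_Rx"),
                       x_gy = NULL, rx_gy = NULL) {
  metric <- match.arg(metric)
  stopifnot(inherits(dose, "volume_grid"), is.logical(mask))
  if (!identical(dim(mask), dim(dose$data)))
    stop("dvh_metric: mask not congruent with dose grid", call. = FALSE)
  if (!any(mask)) stop("dvh_metric: empty structure", call. = FALSE)
  vals <- dose$data[mask]
  if (metric == "V_Rx") {
    if (is.null(rx_gy)) stop("dvh_metric: V_Rx needs rx_gy", call. = FALSE)
    x_gy <- rx_gy; metric <- "V_x"
  }
  switch(metric,
         D_max = max(vals),
         D_mean = mean(vals),
         D_min = min(vals),
         V_x = {
           if (is.null(x_gy) || x_gy <= 0)
             stop("dvh_metric: V_x needs x_gy > 0", call. = FALSE)
           100 * sum(vals >= x_gy) / length(vals)
         })
}

#' Default normal-tissue constraint set
#'
#' The default limits evaluated by [evaluate_constraints]: spinal cord
#' D_max 50.5 Gy; esophagus D_mean 34 Gy; heart V40 50% and V60 30%; and for
#' each lung definition (all lung, lung minus GTV, lung minus CTV)
#' D_mean 20 Gy, V20 30% and V30 20%.
#'
#' @return Data frame with columns `structure`, `metric`, `x_gy`, `limit`,
#'   `units`.
#' @export
default_constraints <- function() {
  lungs <- c("lungs", "lungs_minus_ctv", "lungs_minus_gtv")
  rbind(
    data.frame(structure = "spinal_cord", metric = "D_max", x_gy = NA,
               limit = 50.5, units = "Gy"),
    data.frame(structure = "esophagus", metric = "D_mean", x_gy = NA,
               limit = 34, units = "Gy"),
    data.frame(structure = "heart", metric = "V_x", x_gy = 40,
               limit = 50, units = "%"),
    data.frame(structure = "heart", metric = "V_x", x_gy = 60,
               limit = 30, units = "%"),
    data.frame(structure = rep(lungs, each = 3),
               metric = rep(c("D_mean", "V_x", "V_x"), 3),
               x_gy = rep(c(NA, 20, 30), 3),
               limit = rep(c(20, 30, 20), 3),
               units = rep(c("Gy", "%", "%"), 3))
  )
}

#' Compute a table of DVH metrics for a set of structures
#'
#' @param dose a [volume_grid] of dose in Gy.
#' @param structures named list of logical masks (e.g. OAR masks plus the
#'   [lung_definition] variants).
#' @param specs data frame with columns `structure`, `metric`, `x_gy` (and
#'   optionally more, carried through); defaults to [default_constraints].
#' @param rx_gy prescription dose for any `V_Rx` rows.
#' @return `specs` with a `value` column appended.
#' @export
dvh_table <- function(dose, structures, specs = default_constraints(),
                      rx_gy = NULL) {
  specs$value <- vapply(seq_len(nrow(specs)), function(i) {
    m <- structures[[specs$structure[i]]]
    if (is.null(m))
      stop("dvh_table: structure '", specs$structure[i], "' not supplied",
           call. = FALSE)
    dvh_metric(dose, m, specs$metric[i],
               x_gy = if (is.na(specs$x_gy[i])) NULL else specs$x_gy[i],
               rx_gy = rx_gy)
  }, numeric(1))
  specs
}

#' Evaluate constraint limits and baseline/followup transitions
#'
#' A metric meets its constraint when `value <= limit` (limits are maxima;
#' exact equality counts as met).  When baseline values are supplied, each
#' followup metric is additionally labelled `improved` (unmet at baseline,
#' met at followup), `worsened` (met at baseline, unmet at followup) or
#' `unchanged`.
#'
#' @param metrics data frame from [dvh_table] (must contain `value` and,
#'   unless `limits` provides them, `limit`).
#' @param limits optional data frame of limits to merge by
#'   `structure`/`metric`/`x_gy`; defaults to the limits already present.
#' @param baseline optional data frame of baseline metrics with the same
#'   rows (matched by structure/metric/x_gy).
#' @return The metrics data frame with `met`, `delta_from_baseline` and
#'   `transition` columns.
#' @export
evaluate_constraints <- function(metrics, limits = NULL, baseline = NULL) {
  if (!is.null(limits)) {
    key <- function(d) paste(d$structure, d$metric, d$x_gy)
    i <- match(key(metrics), key(limits))
    if (anyNA(i))
      stop("evaluate_constraints: no limit found for: ",
           paste(unique(key(metrics)[is.na(i)]), collapse = "; "),
           call. = FALSE)
    metrics$limit <- limits$limit[i]
    if (!is.null(limits$units)) metrics$units <- limits$units[i]
  }
  if (is.null(metrics$limit))
    stop("evaluate_constraints: metrics carry no limits", call. = FALSE)
  metrics$met <- metrics$value <= metrics$limit
  if (!is.null(baseline)) {
    key <- function(d) paste(d$structure, d$metric, d$x_gy)
    i <- match(key(metrics), key(baseline))
    if (anyNA(i))
      stop("evaluate_constraints: baseline rows do not match", call. = FALSE)
    bmet <- baseline$value[i] <= metrics$limit
    metrics$delta_from_baseline <- metrics$value - baseline$value[i]
    metrics$transition <- ifelse(!bmet & metrics$met, "improved",
                          ifelse(bmet & !metrics$met, "worsened",
                                 "unchanged"))
  }
  metrics
}

#' Cohort summary of dose-metric changes under both alignments
#'
#' Takes per-patient metric tables for the baseline plan and the two
#' followup alignments, computes per-metric deltas, and summarises them:
#' mean / stdev / min / max per metric and alignment, the fraction of all
#' changes exceeding 1, 2, 5 and 10 Gy-or-percent, and the number of
#' patients with at least one change of 5 Gy/5% or more.
#'
#' @param baseline,bone,carina data frames with columns `patient`,
#'   `structure`, `metric`, `x_gy`, `value` (e.g. stacked [dvh_table]
#'   outputs).
#' @return List with `deltas` (long data frame), `summary` (per metric and
#'   alignment; stdev is reported as 0 with `stdev_degenerate = TRUE` for
#'   single-patient groups), `exceedance` (per alignment, thresholds 1, 2,
#'   5, 10) and `patients_ge5` (count per alignment).
#' @export
metric_changes <- function(baseline, bone, carina) {
  key <- function(d) paste(d$patient, d$structure, d$metric, d$x_gy)
  out <- list()
  for (al in c("bone", "carina")) {
    f <- if (al == "bone") bone else carina
    i <- match(key(f), key(baseline))
    if (anyNA(i))
      stop("metric_changes: unmatched rows for ", al, " alignment",
           call. = FALSE)
    out[[al]] <- data.frame(f[c("patient", "structure", "metric", "x_gy")],
                            alignment = al,
                            delta = f$value - baseline$value[i])
  }
  deltas <- rbind(out$bone, out$carina)
  grp <- paste(deltas$structure, deltas$metric, deltas$x_gy,
               deltas$alignment)  # paste keeps NA x_gy rows grouped
  summ <- do.call(rbind, lapply(split(deltas, grp), function(d) {
    data.frame(structure = d$structure[1], metric = d$metric[1],
               x_gy = d$x_gy[1], alignment = d$alignment[1],
               n = nrow(d), mean = mean(d$delta),
               stdev = if (nrow(d) > 1) stats::sd(d$delta) else 0,
               stdev_degenerate = nrow(d) == 1,
               min = min(d$delta), max = max(d$delta))
  }))
  rownames(summ) <- NULL
  thresholds <- c(1, 2, 5, 10)
  exceedance <- do.call(rbind, lapply(c("bone", "carina"), function(al) {
    dd <- abs(deltas$delta[deltas$alignment == al])
    data.frame(alignment = al, threshold = thresholds,
               n_exceeding = vapply(thresholds,
                                    function(th) sum(dd >= th), numeric(1)),
               pct_exceeding = vapply(thresholds,
                                      function(th) 100 * mean(dd >= th),
                                      numeric(1)))
  }))
  patients_ge5 <- vapply(c("bone", "carina"), function(al) {
    d <- deltas[deltas$alignment == al, ]
    length(unique(d$patient[abs(d$delta) >= 5]))
  }, numeric(1))
  list(deltas = deltas, summary = summ, exceedance = exceedance,
       patients_ge5 = patients_ge5)
}
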