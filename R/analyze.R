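#' Analyse one baseline/followup image pair
#'
#' Runs the measurement pipeline on a phantom pair (or any object with the
#' same layout): calibrates each time point's raw image against its own
#' air/blood reference ROIs, removes the tumor from the lobe masks,
#' optionally erodes the combined lung from its exterior, measures relative
#' mass/density/volume per lobe and their percent changes, and classifies
#' atelectasis resolution from the measured atelectasis volumes.
#'
#' @param pair a `phantom_pair` (see [generate_pair]) or a list with
#'   `baseline`/`followup` elements each holding `raw` ([volume_grid]) and
#'   `labels` ([label_mask_set]).
#' @param eroded use exterior-eroded lobe masks for measurement (default
#'   TRUE, mirroring the delineation-noise guard used on real scans; set
#'   FALSE to measure on the full tumor-free lobes, e.g. when comparing to
#'   phantom analytic truth, where masks are exact by construction and a
#'   two-voxel shell is a large fraction of a small phantom lobe).
#' @param erosion_iterations,element passed to [erode_exterior].
#' @param config [resolution_config] for the classification.
#' @return An `atelectasis_analysis` object: list with `changes` (data frame,
#'   one row per measurable lobe), `atel_volume_baseline_ml`,
#'   `atel_volume_followup_ml`, `resolution`, `anchors` (per time point),
#'   `eroded`, and `dropped` (lobes whose analysis mask came out empty, e.g.
#'   a small lobe hollowed by tumor removal and consumed by the erosion).
#' @export
analyze_pair <- function(pair, eroded = TRUE, erosion_iterations = 2L,
                         element = "box", config = resolution_config()) {
  tp <- lapply(c(baseline = "baseline", followup = "followup"), function(w) {
    x <- pair[[w]]
    anchors <- fit_anchors(x$raw, x$labels)
    dens <- calibrate(x$raw, anchors)
    labs <- remove_tumor(x$labels)
    if (eroded) labs <- erode_exterior(labs, iterations = erosion_iterations,
                                       element = element)
    list(dens = dens, labs = labs, anchors = anchors, raw_labels = x$labels)
  })
  lobes <- intersect(LOBE_NAMES, names(tp$baseline$labs$masks))
  # a heavily eroded (or tumor-hollowed) small lobe can vanish entirely;
  # such lobes are unmeasurable and reported in `dropped`
  nonempty <- vapply(lobes, function(nm)
    any(tp$baseline$labs$masks[[nm]]) && any(tp$followup$labs$masks[[nm]]),
    logical(1))
  dropped <- lobes[!nonempty]
  if (length(dropped))
    warning("dropping unmeasurable (empty) lobe mask(s): ",
            paste(dropped, collapse = ", "), call. = FALSE)
  lobes <- lobes[nonempty]
  cls <- classify_lobes(pair$baseline$labels)
  changes <- do.call(rbind, lapply(lobes, function(nm) {
    b <- measure_roi(tp$baseline$dens, tp$baseline$labs$masks[[nm]])
    f <- measure_roi(tp$followup$dens, tp$followup$labs$masks[[nm]])
    ch <- measure_change(b, f, lobe_id = nm, lobe_class = cls[[nm]])
    data.frame(lobe = nm, lobe_class = ch$lobe_class,
               pct_mass_change = ch$pct_mass_change,
               pct_density_change = ch$pct_density_change,
               pct_volume_change = ch$pct_volume_change,
               mass_b = b$mass_mg, mass_f = f$mass_mg,
               density_b = b$density_mg_cc, density_f = f$density_mg_cc,
               volume_b = b$volume_ml, volume_f = f$volume_ml)
  }))
  vv_b <- voxel_volume_ml(tp$baseline$dens)
  vv_f <- voxel_volume_ml(tp$followup$dens)
  va_b <- sum(get_mask(pair$baseline$labels, "atelectasis")) * vv_b
  va_f <- sum(get_mask(pair$followup$labels, "atelectasis")) * vv_f
  structure(list(changes = changes,
                 atel_volume_baseline_ml = va_b,
                 atel_volume_followup_ml = va_f,
                 resolution = classify_resolution(va_b, va_f, config),
                 anchors = list(baseline = tp$baseline$anchors,
                                followup = tp$followup$anchors),
                 eroded = eroded, dropped = dropped),
            class = "atelectasis_analysis")
}

#' @export
print.atelectasis_analysis <- function(x, ...) {
  cat(sprintf("<atelectasis_analysis> atelectasis %.1f -> %.1f ml: %s resolution (%s lobes)\n",
              x$atel_volume_baseline_ml, x$atel_volume_followup_ml,
              x$resolution, if (x$eroded) "eroded" else "full"))
  print(x$changes[, c("lobe", "lobe_class", "pct_mass_change",
                      "pct_density_change", "pct_volume_change")],
        digits = 3)
  invisible(x)
}

#' Analyse a cohort of image pairs
#'
#' Applies [analyze_pair] to every patient, stacks the per-lobe change
#' records, and reproduces the cohort analysis: per-group means/SDs of mass,
#' density and volume change (atelectatic lobes split by resolution class,
#' healthy ipsilateral and contralateral lobes pooled across patients) and
#' two-sided Wilcoxon rank-sum comparisons of each resolution class against
#' the pooled healthy lobes.
#'
#' @param pairs list of pairs as accepted by [analyze_pair].
#' @param ... passed to [analyze_pair].
#' @return An `atelectasis_cohort` object: list with `changes` (long data
#'   frame with `patient` and `group` columns), `summary` (per group and
#'   quantity), `tests` (list of `group_comparison` per class and quantity),
#'   `resolutions` (per-patient labels).
#' @export
analyze_cohort <- function(pairs, ...) {
  res <- lapply(seq_along(pairs), function(i) {
    an <- analyze_pair(pairs[[i]], ...)
    ch <- an$changes
    ch$patient <- i
    ch$resolution <- an$resolution
    ch
  })
  changes <- do.call(rbind, res)
  changes$group <- ifelse(changes$lobe_class == "atelectatic",
                          changes$resolution, changes$lobe_class)
  quantities <- c("pct_mass_change", "pct_density_change",
                  "pct_volume_change")
  summary <- do.call(rbind, lapply(quantities, function(q) {
    s <- summarize_changes(changes, q, "group")
    s$quantity <- q
    s
  }))
  healthy <- changes[changes$lobe_class != "atelectatic", ]
  tests <- list()
  for (cl in intersect(c("full", "partial", "none"), changes$group)) {
    grp <- changes[changes$group == cl, ]
    if (nrow(grp) >= 2 && nrow(healthy) >= 2)
      for (q in quantities)
        tests[[paste(cl, "vs_healthy", q, sep = ".")]] <-
          wilcoxon_rank_sum(grp[[q]], healthy[[q]])
  }
  resolutions <- vapply(split(changes$resolution, changes$patient),
                        `[`, character(1), 1)
  structure(list(changes = changes, summary = summary, tests = tests,
                 resolutions = resolutions),
            class = "atelectasis_cohort")
}

#' @export
print.atelectasis_cohort <- function(x, ...) {
  n <- length(x$resolutions)
  cat(sprintf("<atelectasis_cohort> %d patients: %s\n", n,
              paste(sprintf("%s (n = %d)", names(table(x$resolutions)),
                            table(x$resolutions)), collapse = ", ")))
  cat("\nPercent density change by group:\n")
  print(x$summary[x$summary$quantity == "pct_density_change",
                  c("group", "n", "mean", "stdev")],
        digits = 3, row.names = FALSE)
  invisible(x)
}

#' @export
summary.atelectasis_cohort <- function(object, ...) {
  cat("Cohort of", length(object$resolutions), "patients\n\n")
  for (q in unique(object$summary$quantity)) {
    cat(q, ":\n")
    print(object$summary[object$summary$quantity == q,
                         c("group", "n", "mean", "stdev")],
          digits = 3, row.names = FALSE)
    cat("\n")
  }
  if (length(object$tests)) {
    cat("Wilcoxon rank-sum vs pooled healthy lobes:\n")
    for (nm in names(object$tests))
      cat(sprintf("  %-40s p = %.4g\n", nm, object$tests[[nm]]$p_value))
  }
  invisible(object)
}
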