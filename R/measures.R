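#' Relative mass, density and volume of a region
#'
#' On a calibrated density volume, the relative mass of a region is the sum
#' of voxel density times voxel volume, the relative density is the mean
#' voxel density, and the volume is voxel count times voxel volume.  The
#' identity mass = density x volume holds exactly.
#'
#' @param dens a [volume_grid] of densities in mg/cc (e.g. from [calibrate]).
#' @param mask logical 3D array congruent with `dens`; must be non-empty.
#' @return A `roi_measures` object: list with `mass_mg`, `density_mg_cc`,
#'   `volume_ml`, `n_voxels`.
#' @export
measure_roi <- function(dens, mask) {
  stopifnot(inherits(dens, "volume_grid"), is.logical(mask))
  if (!identical(dim(mask), dim(dens$data)))
    stop("measure_roi: mask is not congruent with the density volume",
         call. = FALSE)
  n <- sum(mask)
  if (n == 0L)
    stop("measure_roi: empty ROI (refusing to report zero measures)",
         call. = FALSE)
  vv_cc <- voxel_volume_ml(dens)  # 1 cc == 1 ml
  vals <- dens$data[mask]
  structure(list(mass_mg = sum(vals) * vv_cc,
                 density_mg_cc = mean(vals),
                 volume_ml = n * vv_cc,
                 n_voxels = n),
            class = "roi_measures")
}

#' @export
print.roi_measures <- function(x, ...) {
  cat(sprintf("<roi_measures> mass %.2f mg, density %.2f mg/cc, volume %.2f ml (%d voxels)\n",
              x$mass_mg, x$density_mg_cc, x$volume_ml, x$n_voxels))
  invisible(x)
}

#' Percent change between baseline and followup ROI measures
#'
#' Percent changes are 100 * (followup - baseline) / baseline for mass,
#' density and volume.  Baseline measures must be strictly positive.
#'
#' @param baseline,followup `roi_measures` objects.
#' @param lobe_id optional structure name carried through.
#' @param lobe_class optional class label: `"atelectatic"`,
#'   `"healthy_ipsilateral"` or `"contralateral"`.
#' @return A `change_record`: list with `pct_mass_change`,
#'   `pct_density_change`, `pct_volume_change`, `lobe_id`, `lobe_class`.
#' @export
measure_change <- function(baseline, followup, lobe_id = NA_character_,
                           lobe_class = NA_character_) {
  stopifnot(inherits(baseline, "roi_measures"),
            inherits(followup, "roi_measures"))
  if (baseline$mass_mg <= 0 || baseline$density_mg_cc <= 0 ||
      baseline$volume_ml <= 0)
    stop("measure_change: baseline measures must be positive", call. = FALSE)
  pct <- function(b, f) 100 * (f - b) / b
  structure(list(pct_mass_change = pct(baseline$mass_mg, followup$mass_mg),
                 pct_density_change = pct(baseline$density_mg_cc,
                                          followup$density_mg_cc),
                 pct_volume_change = pct(baseline$volume_ml,
                                         followup$volume_ml),
                 lobe_id = lobe_id, lobe_class = lobe_class),
            class = "change_record")
}

#' @export
print.change_record <- function(x, ...) {
  cat(sprintf("<change_record> %s [%s]: mass %+.1f%%, density %+.1f%%, volume %+.1f%%\n",
              x$lobe_id, x$lobe_class, x$pct_mass_change,
              x$pct_density_change, x$pct_volume_change))
  invisible(x)
}

#' Assign lobes to atelectatic / healthy ipsilateral / contralateral classes
#'
#' A lobe is `atelectatic` if it overlaps the atelectasis mask; otherwise it
#' is `healthy_ipsilateral` when on the same side as the tumor and
#' `contralateral` when on the opposite side.  Side is read from the lobe
#' name prefix (L*/R*); the tumor side is the side of the lobe(s) the tumor
#' overlaps.
#'
#' @param labels a [label_mask_set] with lobes, `tumor_gtv` and (optionally)
#'   `atelectasis`.
#' @return Named character vector over the lobes present.
#' @export
classify_lobes <- function(labels) {
  present <- intersect(LOBE_NAMES, names(labels$masks))
  atel <- labels$masks[["atelectasis"]]
  tumor <- labels$masks[["tumor_gtv"]]
  side <- substr(present, 1, 1)
  tumor_side <- if (!is.null(tumor) && any(tumor)) {
    ov <- vapply(labels$masks[present],
                 function(m) sum(m & tumor), numeric(1))
    if (all(ov == 0)) NA_character_ else side[which.max(ov)]
  } else NA_character_
  out <- vapply(seq_along(present), function(i) {
    m <- labels$masks[[present[i]]]
    if (!is.null(atel) && any(m & atel)) "atelectatic"
    else if (!is.na(tumor_side) && side[i] == tumor_side) "healthy_ipsilateral"
    else "contralateral"
  }, character(1))
  stats::setNames(out, present)
}

#' Enumerate baseline/followup scan pairings for repeat-scan sessions
#'
#' Sessions with repeat scans yield several images per time point.  Pairing
#' rule: matched scan index first -- scan `i` at baseline is paired with scan
#' `i` at followup, giving `min(n_baseline, n_followup)` pairs.
#'
#' @param n_baseline,n_followup number of scans at each time point.
#' @return Data frame with columns `baseline` and `followup` (scan indices).
#' @export
enumerate_pairings <- function(n_baseline, n_followup) {
  n <- min(n_baseline, n_followup)
  if (n < 1) stop("enumerate_pairings: need at least one scan per time point",
                  call. = FALSE)
  data.frame(baseline = seq_len(n), followup = seq_len(n))
}
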