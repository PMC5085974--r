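#' Two-point CT density calibration
#'
#' Raw CT intensities drift with scanner state, so each image is calibrated
#' individually against two internal references: air outside the body
#' (target 0 mg/cc) and blood in the descending aorta (target 1050 mg/cc).
#' The calibration is the unique affine map sending the mean raw intensity of
#' the air ROI to 0 and that of the blood ROI to 1050; calibrated voxel
#' values are then relative physical density in mg/cc.  Because the map is
#' refit per image from its own ROIs, any affine change in scanner output
#' cancels exactly.
#'
#' @param raw a [volume_grid] of raw scanner intensities.
#' @param labels a [label_mask_set] containing non-empty `air_ref` and
#'   `blood_ref` masks congruent with `raw`.
#' @return [fit_anchors]: an object of class `calibration_anchors` with the
#'   two ROI means and the fixed targets.  [calibrate]: a [volume_grid] of
#'   densities in mg/cc (class `density_volume` prepended).
#' @examples
#' v <- volume_grid(array(c(-1000, 50), c(2, 1, 1)))
#' labs <- label_mask_set(list(air_ref = array(c(TRUE, FALSE), c(2, 1, 1)),
#'                             blood_ref = array(c(FALSE, TRUE), c(2, 1, 1))), v)
#' calibrate(v, fit_anchors(v, labs))$data  # 0 and 1050
#' @export
fit_anchors <- function(raw, labels) {
  stopifnot(inherits(raw, "volume_grid"))
  stop_if_incongruent(raw, labels$grid, "raw image vs labels")
  air <- get_mask(labels, "air_ref"); blood <- get_mask(labels, "blood_ref")
  if (!any(air)) stop("fit_anchors: air_ref mask is empty", call. = FALSE)
  if (!any(blood)) stop("fit_anchors: blood_ref mask is empty", call. = FALSE)
  mu_air <- mean(raw$data[air]); mu_blood <- mean(raw$data[blood])
  if (!(mu_blood > mu_air))
    stop("fit_anchors: blood ROI mean (", format(mu_blood),
         ") must exceed air ROI mean (", format(mu_air), ")", call. = FALSE)
  structure(list(mu_air_raw = mu_air, mu_blood_raw = mu_blood,
                 target_air = 0, target_blood = 1050),
            class = "calibration_anchors")
}

#' @export
print.calibration_anchors <- function(x, ...) {
  cat("<calibration_anchors> air:", format(x$mu_air_raw), "-> 0 mg/cc;",
      "blood:", format(x$mu_blood_raw), "-> 1050 mg/cc\n")
  invisible(x)
}

#' @rdname fit_anchors
#' @param anchors a `calibration_anchors` object.
#' @export
calibrate <- function(raw, anchors) {
  stopifnot(inherits(raw, "volume_grid"),
            inherits(anchors, "calibration_anchors"))
  den <- anchors$mu_blood_raw - anchors$mu_air_raw
  if (!is.finite(den) || den <= 0)
    stop("calibrate: degenerate anchors", call. = FALSE)
  # No clamping: below-air noise stays negative so ROI means and mass sums
  # remain unbiased.
  d <- anchors$target_blood * (raw$data - anchors$mu_air_raw) / den
  out <- with_data(raw, d)
  class(out) <- c("density_volume", class(out))
  out
}
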