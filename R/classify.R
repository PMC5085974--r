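#' Configuration for atelectasis resolution classification
#'
#' Thresholds on the baseline-to-followup reduction of atelectasis volume:
#' a fractional reduction greater than `full_threshold` is full resolution,
#' between `partial_lower` and `full_threshold` (inclusive) is partial, and
#' anything below `partial_lower` -- or any absolute decrease smaller than
#' `absolute_floor_ml`, regardless of fraction -- is no resolution.  The
#' absolute floor guards against delineation noise dominating small volumes
#' and takes precedence over the fractional rule.
#'
#' @param full_threshold fractional reduction above which resolution is full
#'   (default 0.80; exactly 0.80 is partial).
#' @param partial_lower fractional reduction below which resolution is none
#'   (default 0.20; exactly 0.20 is partial).
#' @param absolute_floor_ml absolute decrease below which resolution is none
#'   (default 15 ml; exactly 15 ml is not floored).
#' @return A `resolution_config` object.
#' @export
resolution_config <- function(full_threshold = 0.80, partial_lower = 0.20,
                              absolute_floor_ml = 15) {
  if (!(0 < partial_lower && partial_lower < full_threshold &&
        full_threshold < 1))
    stop("resolution_config: need 0 < partial_lower < full_threshold < 1",
         call. = FALSE)
  if (absolute_floor_ml < 0)
    stop("resolution_config: absolute_floor_ml must be >= 0", call. = FALSE)
  structure(list(full_threshold = full_threshold,
                 partial_lower = partial_lower,
                 absolute_floor_ml = absolute_floor_ml),
            class = "resolution_config")
}

#' Classify atelectasis resolution between two scans
#'
#' @param v_baseline_ml baseline atelectasis volume(s) in ml; must be > 0.
#' @param v_followup_ml followup atelectasis volume(s) in ml; must be >= 0.
#' @param config a [resolution_config].
#' @return Character vector of labels: `"full"`, `"partial"` or `"none"`.
#'   Volume increases classify as `"none"`.
#' @examples
#' classify_resolution(200, 20)   # 90% reduction -> "full"
#' classify_resolution(200, 100)  # 50% -> "partial"
#' classify_resolution(200, 190)  # 10 ml decrease -> "none"
#' classify_resolution(10, 1)     # 90% but only 9 ml -> floored to "none"
#' @export
classify_resolution <- function(v_baseline_ml, v_followup_ml,
                                config = resolution_config()) {
  stopifnot(inherits(config, "resolution_config"))
  n <- max(length(v_baseline_ml), length(v_followup_ml))
  vb <- rep_len(as.numeric(v_baseline_ml), n)
  vf <- rep_len(as.numeric(v_followup_ml), n)
  if (any(!is.finite(vb)) || any(vb <= 0))
    stop("classify_resolution: baseline volumes must be positive",
         call. = FALSE)
  if (any(!is.finite(vf)) || any(vf < 0))
    stop("classify_resolution: followup volumes must be non-negative",
         call. = FALSE)
  delta <- vb - vf
  frac <- delta / vb
  out <- rep("partial", n)
  # absolute floor takes precedence over the fractional rule
  out[frac < config$partial_lower | delta < config$absolute_floor_ml] <- "none"
  out[frac > config$full_threshold & delta >= config$absolute_floor_ml] <- "full"
  out
}
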