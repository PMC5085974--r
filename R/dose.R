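#' Beam and plan geometry
#'
#' A plan is a set of coplanar divergent beams rotating about the z axis
#' through the isocenter.  Gantry angle 0 places the virtual source anterior
#' to the isocenter (along -y), 90 degrees to the patient's left (+x).  The
#' aperture is a polygon in beam's-eye-view coordinates (mm at the isocenter
#' plane): first axis lateral, second along z.
#'
#' @param gantry_angle_deg gantry angle in degrees.
#' @param aperture n x 2 numeric matrix, aperture polygon vertices in BEV mm;
#'   see [aperture_rect] for rectangles.
#' @param weight relative beam weight (> 0).
#' @param mu monitor units (> 0), a pure scale factor in the toy engine.
#' @return A `beam` / `plan_geometry` object.
#' @export
beam <- function(gantry_angle_deg, aperture, weight = 1, mu = 1) {
  aperture <- matrix(as.numeric(aperture), ncol = 2)
  if (nrow(aperture) < 3)
    stop("beam: aperture polygon needs >= 3 vertices", call. = FALSE)
  if (weight <= 0 || mu <= 0)
    stop("beam: weight and mu must be positive", call. = FALSE)
  structure(list(gantry_angle_deg = gantry_angle_deg, aperture = aperture,
                 weight = weight, mu = mu), class = "beam")
}

#' @rdname beam
#' @param half_width_mm,half_length_mm rectangle half-sizes in BEV mm.
#' @export
aperture_rect <- function(half_width_mm, half_length_mm) {
  w <- half_width_mm; l <- half_length_mm
  matrix(c(-w, -l,  w, -l,  w, l,  -w, l), ncol = 2, byrow = TRUE)
}

#' @rdname beam
#' @param isocenter_mm length-3 world position of the isocenter.
#' @param beams list of [beam] objects (non-empty).
#' @param prescription_dose_gy prescription dose in Gy (> 0).
#' @export
plan_geometry <- function(isocenter_mm, beams, prescription_dose_gy) {
  if (!length(beams)) stop("plan_geometry: no beams", call. = FALSE)
  stopifnot(all(vapply(beams, inherits, logical(1), "beam")))
  if (prescription_dose_gy <= 0)
    stop("plan_geometry: prescription must be positive", call. = FALSE)
  structure(list(isocenter_mm = as.numeric(isocenter_mm), beams = beams,
                 prescription_dose_gy = prescription_dose_gy),
            class = "plan_geometry")
}

#' @export
print.plan_geometry <- function(x, ...) {
  cat(sprintf("<plan_geometry> %d beam(s), Rx %.1f Gy, isocenter (%.1f, %.1f, %.1f) mm\n",
              length(x$beams), x$prescription_dose_gy,
              x$isocenter_mm[1], x$isocenter_mm[2], x$isocenter_mm[3]))
  invisible(x)
}

# even-odd point-in-polygon, vectorised over points
points_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

#' Toy radiological-depth dose engine
#'
#' A deliberately simple, deterministic exponential-attenuation model used
#' only to compare relative dose between anatomies.  It is NOT a clinical
#' dose algorithm: no scatter, no inverse-square law, no beam spectrum.  For
#' every voxel inside a beam's aperture, rays are traced from a virtual
#' source at distance `sad_mm` and the voxel receives
#' `weight * mu * exp(-mu_eff * radiological_depth)` where the radiological
#' depth is the water-equivalent path length
#' `sum(density/1000 * step_mm)` along the ray.  Beam contributions add.
#'
#' @param dens a [volume_grid] of density in mg/cc.
#' @param plan a [plan_geometry]; the isocenter must lie inside the grid.
#' @param mu_eff effective attenuation coefficient per mm of water
#'   (default 0.005).
#' @param sad_mm source-axis distance in mm (default 1000).
#' @param n_samples quadrature points per ray (default 64).
#' @return A [volume_grid] of dose in Gy (class `dose_grid` prepended).
#' @export
compute_toy_dose <- function(dens, plan, mu_eff = 0.005, sad_mm = 1000,
                             n_samples = 64L) {
  stopifnot(inherits(dens, "volume_grid"), inherits(plan, "plan_geometry"))
  d <- dim(dens$data)
  iso <- plan$isocenter_mm
  lo <- dens$origin; hi <- dens$origin + (d - 1) * dens$spacing
  if (any(iso < lo) || any(iso > hi))
    stop("compute_toy_dose: isocenter lies outside the density grid",
         call. = FALSE)
  pts <- voxel_world_coords(dens)
  dose <- numeric(nrow(pts))
  # midpoint quadrature along source -> voxel
  qf <- (seq_len(n_samples) - 0.5) / n_samples
  for (b in plan$beams) {
    th <- b$gantry_angle_deg * pi / 180
    dir <- c(-sin(th), cos(th), 0)           # source -> isocenter
    src <- iso - sad_mm * dir
    u <- c(dir[2], -dir[1], 0)               # lateral BEV axis
    v <- c(0, 0, 1)                          # longitudinal BEV axis
    w <- sweep(pts, 2, src, "-")
    tproj <- as.numeric(w %*% dir)
    ok <- tproj > 1e-6
    scale <- sad_mm / tproj[ok]
    bev_u <- as.numeric(w[ok, , drop = FALSE] %*% u) * scale
    bev_v <- as.numeric(w[ok, , drop = FALSE] %*% v) * scale
    infield <- points_in_polygon(bev_u, bev_v, b$aperture)
    idx <- which(ok)[infield]
    if (!length(idx)) next
    tgt <- pts[idx, , drop = FALSE]
    len <- sqrt(rowSums(sweep(tgt, 2, src, "-")^2))
    depth <- numeric(length(idx))
    for (q in qf) {
      sp <- sweep(sweep(tgt, 2, src, "-") * q, 2, src, "+")
      depth <- depth + trilinear_sample(dens, sp, fill = 0)
    }
    depth <- depth / n_samples * len / 1000   # water-equivalent mm
    dose[idx] <- dose[idx] + b$weight * b$mu * exp(-mu_eff * depth)
  }
  out <- with_data(dens, array(dose, d))
  class(out) <- c("dose_grid", class(out))
  out
}

#' Scale plan monitor units so the isocenter receives the prescription dose
#'
#' @param plan a [plan_geometry].
#' @param dens density volume used for the calibration calculation.
#' @param ... passed to [compute_toy_dose].
#' @return The plan with every beam's `mu` scaled by a common factor.
#' @export
normalize_plan <- function(plan, dens, ...) {
  dose <- compute_toy_dose(dens, plan, ...)
  idx <- round((plan$isocenter_mm - dens$origin) / dens$spacing) + 1
  d0 <- dose$data[idx[1], idx[2], idx[3]]
  if (d0 <= 0) stop("normalize_plan: zero dose at isocenter", call. = FALSE)
  s <- plan$prescription_dose_gy / d0
  plan$beams <- lapply(plan$beams, function(b) { b$mu <- b$mu * s; b })
  plan
}
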