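#' Synthetic thorax phantom specification
#'
#' Describes a baseline/midtreatment phantom pair: a body of soft tissue
#' containing five ellipsoidal lung lobes, a spherical tumor, an atelectatic
#' (collapsed) region inside one lobe, reference ROIs for density
#' calibration (exterior air, aortic blood), bony anatomy with landmarks,
#' and the effect parameters governing how the anatomy changes between the
#' two time points.
#'
#' The atelectasis model: at baseline a fraction `baseline_fraction_of_lobe`
#' (f) of the lobe is consolidated at `consolidated_density` (rho_c); the
#' rest is healthy parenchyma at `healthy_density` (rho_p).  At followup a
#' fraction `followup_resolution_fraction` (r) of the consolidated tissue
#' re-aerates: its non-edema mass re-expands to parenchyma density, so the
#' lobe boundary is displaced outwards and the lobe volume becomes
#' `V * (1 + f*r*(rho_c*u/rho_p - 1))` with `u = 1/(1 + e)` and
#' `e = edema_excess_mass_fraction` the fraction of consolidated mass that
#' is edema/infiltrate and simply disappears on resolution.  With `e = 0`
#' re-aeration conserves mass exactly.  An optional
#' `followup_density_scale` multiplies all followup densities inside the
#' affected lobe, decoupling mass change from volume change.
#'
#' Defaults produce a pure re-aeration pair (full resolution, no edema):
#' whole-lobe-scale collapse of the right lower lobe that re-aerates
#' completely, conserving mass while volume rises by ~180% and density falls
#' by ~64%.
#'
#' @param grid_shape voxels per axis (default `c(64, 64, 56)`).
#' @param spacing_mm voxel spacing (default `c(3.2, 3.2, 3.8)` mm).
#' @param lobe_geometry named list of `list(center, axes)` in mm for the five
#'   lobes; default [default_thorax_geometry]`()$lobes`.
#' @param atelectasis list: `lobe_id`, `baseline_fraction_of_lobe`,
#'   `followup_resolution_fraction`, `consolidated_density` (mg/cc),
#'   `edema_excess_mass_fraction`.
#' @param tumor list: `lobe_id`, `baseline_radius_mm`, `regression_fraction`,
#'   `ctv_margin_mm`.
#' @param healthy_density parenchyma density in mg/cc (default 250).
#' @param followup_density_scale multiplier on followup densities within the
#'   atelectatic lobe (default 1).
#' @param healthy_change mean/sd of the per-lobe fractional density change of
#'   healthy lobes between scans (default mean -0.04, sd 0.05).
#' @param noise_sd additive Gaussian noise, expressed in mg/cc (default 20);
#'   applied in raw units as `slope * noise_sd`.
#' @param raw_intensity_map affine map density -> raw units,
#'   `list(slope, intercept)`; default slope 1, intercept -1000 (HU-like).
#' @param misalignment_mm true rigid setup offset applied to the whole
#'   followup anatomy (translation; default `c(4, -3, 2)` mm).
#' @param growth_weights per-axis exponents (summing to 1) distributing the
#'   lobe volume growth factor over x/y/z.
#' @param seed integer seed making the pair fully reproducible.
#' @return A `phantom_spec` object (validated list).
#' @export
phantom_spec <- function(grid_shape = c(64, 64, 56),
                         spacing_mm = c(3.2, 3.2, 3.8),
                         lobe_geometry = NULL,
                         atelectasis = list(),
                         tumor = list(),
                         healthy_density = 250,
                         followup_density_scale = 1,
                         healthy_change = list(mean = -0.04, sd = 0.05),
                         noise_sd = 20,
                         raw_intensity_map = list(slope = 1, intercept = -1000),
                         misalignment_mm = c(4, -3, 2),
                         growth_weights = c(0.267, 0.400, 0.333),
                         seed = 1L) {
  geom <- default_thorax_geometry()
  if (!is.null(lobe_geometry)) geom$lobes <- lobe_geometry
  atel <- utils::modifyList(list(lobe_id = "RLL",
                                 baseline_fraction_of_lobe = 0.6,
                                 followup_resolution_fraction = 1,
                                 consolidated_density = 1000,
                                 edema_excess_mass_fraction = 0), atelectasis)
  tum <- utils::modifyList(list(lobe_id = "RUL", baseline_radius_mm = 19,
                                regression_fraction = 0.39,
                                ctv_margin_mm = 8), tumor)
  spec <- list(grid_shape = as.integer(grid_shape),
               spacing_mm = as.numeric(spacing_mm),
               geometry = geom, atelectasis = atel, tumor = tum,
               healthy_density = healthy_density,
               followup_density_scale = followup_density_scale,
               healthy_change = healthy_change,
               noise_sd = noise_sd, raw_intensity_map = raw_intensity_map,
               misalignment_mm = as.numeric(misalignment_mm),
               growth_weights = as.numeric(growth_weights),
               seed = as.integer(seed))
  validate_phantom_spec(spec)
  structure(spec, class = "phantom_spec")
}

validate_phantom_spec <- function(spec) {
  a <- spec$atelectasis
  if (any(spec$spacing_mm <= 0)) stop("phantom_spec: spacing must be > 0",
                                      call. = FALSE)
  if (length(spec$grid_shape) != 3L || any(spec$grid_shape < 8))
    stop("phantom_spec: grid_shape must be 3 values >= 8", call. = FALSE)
  if (a$followup_resolution_fraction < 0 || a$followup_resolution_fraction > 1)
    stop("phantom_spec: resolution fraction must be in [0, 1]", call. = FALSE)
  if (a$baseline_fraction_of_lobe <= 0 || a$baseline_fraction_of_lobe > 1)
    stop("phantom_spec: baseline atelectasis fraction must be in (0, 1]",
         call. = FALSE)
  if (a$edema_excess_mass_fraction <= -1)
    stop("phantom_spec: edema fraction must exceed -1", call. = FALSE)
  if (!a$lobe_id %in% LOBE_NAMES || !spec$tumor$lobe_id %in% LOBE_NAMES)
    stop("phantom_spec: atelectasis/tumor lobe_id must be a lobe name",
         call. = FALSE)
  if (a$lobe_id == spec$tumor$lobe_id)
    stop("phantom_spec: tumor and atelectasis must occupy different lobes ",
         "(the analytic truth model keeps them disjoint)", call. = FALSE)
  if (abs(sum(spec$growth_weights) - 1) > 1e-8)
    stop("phantom_spec: growth_weights must sum to 1", call. = FALSE)
  invisible(spec)
}

#' Default thorax geometry (world mm)
#'
#' Axis-aligned analytic shapes: ellipsoidal lobes and heart, cylindrical
#' aorta/esophagus/spine, box sternum and air-reference region.  Sizes are a
#' compact (~20 cm) thorax so that whole cohorts remain cheap to generate;
#' shapes are chosen so all painted structures are pairwise disjoint even at
#' maximal followup lobe expansion.
#'
#' @return Named list of geometric primitives.
#' @export
default_thorax_geometry <- function() {
  list(
    body = list(center = c(102, 102), radii = c(96, 90), z = c(6, 203)),
    lobes = list(
      LUL = list(center = c(58, 100, 150), axes = c(25, 30, 26)),
      LLL = list(center = c(60, 104, 72),  axes = c(26, 32, 28)),
      RUL = list(center = c(146, 100, 162), axes = c(25, 30, 24)),
      RML = list(center = c(146, 56, 140),  axes = c(18, 20, 14)),
      RLL = list(center = c(148, 112, 74),  axes = c(28, 34, 30))),
    heart = list(center = c(88, 58, 96), axes = c(22, 24, 26)),
    aorta = list(center = c(88, 134), radius = 9, z = c(30, 170)),
    esophagus = list(center = c(98, 118), radius = 5, z = c(30, 180)),
    spine = list(center = c(102, 150), radius = 10, z = c(6, 203)),
    cord = list(center = c(102, 150), radius = 4, z = c(6, 203)),
    sternum = list(x = c(94, 110), y = c(12, 22), z = c(40, 160)),
    carina = list(center = c(102, 96, 130), radius = 6),
    air_box = list(x = c(2, 16), y = c(2, 16), z = c(60, 140)),
    densities = list(body = 1000, heart = 1050, aorta = 1050,
                     esophagus = 1040, bone = 1600, tumor = 1050),
    landmarks = data.frame(
      name = c(paste0("spine_", 1:4), "sternum_1", "sternum_2", "carina"),
      x = c(102, 102, 102, 102, 102, 102, 102),
      y = c(150, 150, 150, 150, 17, 17, 96),
      z = c(50, 90, 130, 170, 70, 130, 130)),
    bone_box = list(
      spine = rbind(c(86, 134, 20), c(118, 166, 195)),
      sternum = rbind(c(86, 6, 30), c(118, 28, 170)))
  )
}

# ---- analytic helpers -------------------------------------------------------

ellipsoid_volume_ml <- function(axes) 4 / 3 * pi * prod(axes) / 1000

# Thomsen approximation to the ellipsoid surface area (mm^2)
ellipsoid_area_mm2 <- function(axes) {
  p <- 1.6075; a <- axes[1]; b <- axes[2]; c <- axes[3]
  4 * pi * (((a * b)^p + (a * c)^p + (b * c)^p) / 3)^(1 / p)
}

grid_axes_mm <- function(shape, spacing)
  lapply(1:3, function(a) (seq_len(shape[a]) - 1) * spacing[a])

mask_ellipsoid <- function(ax, center, axes) {
  dx2 <- ((ax[[1]] - center[1]) / axes[1])^2
  dy2 <- ((ax[[2]] - center[2]) / axes[2])^2
  dz2 <- ((ax[[3]] - center[3]) / axes[3])^2
  outer(outer(dx2, dy2, "+"), dz2, "+") <= 1
}

mask_cylinder_z <- function(ax, center, radius, zlim, ry = radius) {
  dx2 <- ((ax[[1]] - center[1]) / radius)^2
  dy2 <- ((ax[[2]] - center[2]) / ry)^2
  zin <- ax[[3]] >= zlim[1] & ax[[3]] <= zlim[2]
  outer(outer(dx2, dy2, "+") <= 1, zin, "&")
}

mask_box <- function(ax, xlim, ylim, zlim) {
  outer(outer(ax[[1]] >= xlim[1] & ax[[1]] <= xlim[2],
              ax[[2]] >= ylim[1] & ax[[2]] <= ylim[2], "&"),
        ax[[3]] >= zlim[1] & ax[[3]] <= zlim[2], "&")
}

shift_geom <- function(center, t) center + t[seq_along(center)]

#' Invert the phantom effect model for target density and mass changes
#'
#' Finds the re-aeration expansion factor `u` (the non-edema mass fraction of
#' the consolidated tissue) and the followup lobe density scale `s` that make
#' the atelectatic lobe realise given percent changes in density and mass.
#' Derivation: the ratio `Q = (1+m)/(1+d)` equals the lobe volume ratio
#' `V'/V = 1 + r*f*(rho_c*u/rho_p - 1)`, which is linear in `u`; `s` then
#' scales the followup mass to match `m`.  `u` is clamped to `u_range`
#' (values above 1 amount to "negative edema" and are tolerated within a
#' band so jittered targets stay representable).
#'
#' @param density_pct,mass_pct target percent changes of the lobe.
#' @param r resolution fraction of the atelectasis (0-1).
#' @param f baseline atelectasis fraction of the lobe (0-1).
#' @param rho_p,rho_c parenchyma and consolidated densities in mg/cc.
#' @param u_range allowed interval for `u`.
#' @return List with `u`, `s` and the implied edema excess mass fraction
#'   `e = 1/u - 1`.
#' @export
solve_effect_params <- function(density_pct, mass_pct, r, f,
                                rho_p = 250, rho_c = 1000,
                                u_range = c(0.02, 2.5)) {
  d <- density_pct / 100; m <- mass_pct / 100
  Q <- (1 + m) / (1 + d)
  u <- rho_p * ((Q - 1) / (r * f) + 1) / rho_c
  u <- min(max(u, u_range[1]), u_range[2])
  mass_ratio_prescale <- (rho_p * (1 - f) + rho_c * f * ((1 - r) + r * u)) /
    (rho_p * (1 - f) + rho_c * f)
  s <- (1 + m) / mass_ratio_prescale
  list(u = u, s = s, e = 1 / u - 1)
}

# Analytic truth for the atelectatic lobe, in the construction's own terms.
atelectatic_truth <- function(V_ml, f, r, u, s, rho_p, rho_c) {
  Va <- f * V_ml
  Vf <- V_ml * (1 + f * r * (rho_c * u / rho_p - 1))
  Va_f <- (1 - r) * Va
  mass_b <- rho_p * (V_ml - Va) + rho_c * Va
  mass_f <- s * (rho_p * (Vf - Va_f) + rho_c * Va_f)
  list(volume_b = V_ml, volume_f = Vf, atel_volume_b = Va,
       atel_volume_f = Va_f, mass_b = mass_b, mass_f = mass_f,
       density_b = mass_b / V_ml, density_f = mass_f / Vf)
}

# ---- pair generation --------------------------------------------------------

#' Generate a baseline/midtreatment phantom pair
#'
#' Builds both time points of a synthetic thorax according to a
#' [phantom_spec]: analytic structure masks, a noise-free density map, a raw
#' scanner image (affine map of density plus Gaussian noise), bone/carina
#' landmarks, and an analytic ground-truth record for every lobe.  The whole
#' followup anatomy is displaced by the spec's true misalignment.  Truth
#' values are computed from the spec's closed-form geometry, never from
#' voxel sums.  Generation is deterministic for a fixed seed.
#'
#' @param spec a [phantom_spec].
#' @param n_repeats number of repeat scans per time point (independent noise
#'   draws of the same anatomy; default 1).
#' @return A `phantom_pair`: list with `baseline` and `followup` (each
#'   `raw` ([volume_grid]), `labels` ([label_mask_set]), `landmarks`,
#'   and `repeats`, a list of `n_repeats` raw volumes), `truth` (per-lobe
#'   data frame, atelectasis volumes, true resolution label, true
#'   followup-to-baseline [rigid_transform]) and `spec`.
#' @export
generate_pair <- function(spec, n_repeats = 1L) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  g <- spec$geometry
  a <- spec$atelectasis
  rho_p <- spec$healthy_density
  rho_c <- a$consolidated_density
  f <- a$baseline_fraction_of_lobe
  r <- a$followup_resolution_fraction
  u <- 1 / (1 + a$edema_excess_mass_fraction)
  s <- spec$followup_density_scale
  lobe_names <- names(g$lobes)
  atel_lobe <- a$lobe_id

  # healthy-lobe followup density scales (atelectatic lobe uses s instead)
  h <- stats::rnorm(length(lobe_names), 1 + spec$healthy_change$mean,
                    spec$healthy_change$sd)
  names(h) <- lobe_names
  h[atel_lobe] <- NA

  V <- ellipsoid_volume_ml(g$lobes[[atel_lobe]]$axes)
  tru <- atelectatic_truth(V, f, r, u, s, rho_p, rho_c)
  growth <- (tru$volume_f / tru$volume_b)^spec$growth_weights

  tfu <- spec$misalignment_mm      # applied to followup anatomy
  build <- function(timepoint) {
    t <- if (timepoint == "baseline") c(0, 0, 0) else tfu
    ax <- grid_axes_mm(spec$grid_shape, spec$spacing_mm)
    dens <- array(0, spec$grid_shape)   # exterior air at 0 mg/cc
    body <- mask_cylinder_z(ax, shift_geom(g$body$center, t),
                            g$body$radii[1], g$body$z + t[3], g$body$radii[2])
    dens[body] <- g$densities$body
    masks <- list()
    for (nm in lobe_names) {
      lb <- g$lobes[[nm]]
      axes <- lb$axes
      if (timepoint == "followup" && nm == atel_lobe) axes <- axes * growth
      m <- mask_ellipsoid(ax, shift_geom(lb$center, t), axes)
      rho <- if (nm == atel_lobe) {
        if (timepoint == "baseline") rho_p else s * rho_p
      } else if (timepoint == "baseline") rho_p else h[nm] * rho_p
      dens[m] <- rho
      masks[[nm]] <- m
    }
    # atelectasis: concentric sub-ellipsoid of the (possibly grown) lobe
    lb <- g$lobes[[atel_lobe]]
    if (timepoint == "baseline") {
      sc <- f^(1 / 3)
      m_atel <- mask_ellipsoid(ax, shift_geom(lb$center, t), lb$axes * sc)
      dens[m_atel] <- rho_c
    } else {
      frac_f <- tru$atel_volume_f / tru$volume_f
      sc <- frac_f^(1 / 3)
      m_atel <- if (sc > 0)
        mask_ellipsoid(ax, shift_geom(lb$center, t), lb$axes * growth * sc)
      else array(FALSE, spec$grid_shape)
      dens[m_atel] <- s * rho_c
    }
    masks$atelectasis <- m_atel
    # tumor (in its own lobe) and CTV (baseline tumor + margin)
    tu <- spec$tumor
    tcen <- shift_geom(g$lobes[[tu$lobe_id]]$center, t)
    trad <- tu$baseline_radius_mm *
      if (timepoint == "baseline") 1 else (1 - tu$regression_fraction)^(1 / 3)
    masks$tumor_gtv <- mask_ellipsoid(ax, tcen, rep(trad, 3))
    masks$ctv <- mask_ellipsoid(ax, tcen,
                                rep(tu$baseline_radius_mm + tu$ctv_margin_mm, 3))
    dens[masks$tumor_gtv] <- g$densities$tumor
    # mediastinum and bone
    masks$heart <- mask_ellipsoid(ax, shift_geom(g$heart$center, t),
                                  g$heart$axes)
    dens[masks$heart] <- g$densities$heart
    masks$esophagus <- mask_cylinder_z(ax, shift_geom(g$esophagus$center, t),
                                       g$esophagus$radius,
                                       g$esophagus$z + t[3])
    dens[masks$esophagus] <- g$densities$esophagus
    masks$blood_ref <- mask_cylinder_z(ax, shift_geom(g$aorta$center, t),
                                       g$aorta$radius, g$aorta$z + t[3])
    dens[masks$blood_ref] <- g$densities$aorta
    spine <- mask_cylinder_z(ax, shift_geom(g$spine$center, t),
                             g$spine$radius, g$spine$z + t[3])
    sternum <- mask_box(ax, g$sternum$x + t[1], g$sternum$y + t[2],
                        g$sternum$z + t[3])
    dens[spine | sternum] <- g$densities$bone
    masks$bone <- spine | sternum
    masks$spinal_cord <- mask_cylinder_z(ax, shift_geom(g$cord$center, t),
                                         g$cord$radius, g$cord$z + t[3])
    masks$carina <- mask_ellipsoid(ax, shift_geom(g$carina$center, t),
                                   rep(g$carina$radius, 3))
    masks$air_ref <- mask_box(ax, g$air_box$x, g$air_box$y, g$air_box$z)
    check_phantom_layout(masks, body, lobe_names, atel_lobe, spec$tumor$lobe_id)
    grid <- volume_grid(dens, spec$spacing_mm, c(0, 0, 0))
    lm <- g$landmarks
    lm[, c("x", "y", "z")] <- sweep(as.matrix(lm[, c("x", "y", "z")]), 2, t, "+")
    list(density = grid, labels = label_mask_set(masks, grid), landmarks = lm)
  }

  bl <- build("baseline"); fu <- build("followup")
  map <- spec$raw_intensity_map
  make_raw <- function(dens_grid)
    with_data(dens_grid,
              map$slope * dens_grid$data + map$intercept +
                stats::rnorm(length(dens_grid$data),
                             sd = abs(map$slope) * spec$noise_sd))
  bl$repeats <- replicate(n_repeats, make_raw(bl$density), simplify = FALSE)
  fu$repeats <- replicate(n_repeats, make_raw(fu$density), simplify = FALSE)
  bl$raw <- bl$repeats[[1]]; fu$raw <- fu$repeats[[1]]

  # truth describes the tumor-free lobes the pipeline measures: the tumor
  # lobe loses its (regressing) GTV volume at each time point
  Vt_b <- ellipsoid_volume_ml(rep(spec$tumor$baseline_radius_mm, 3))
  Vt_f <- Vt_b * (1 - spec$tumor$regression_fraction)
  truth_lobes <- do.call(rbind, lapply(lobe_names, function(nm) {
    Vl <- ellipsoid_volume_ml(g$lobes[[nm]]$axes)
    if (nm == atel_lobe)
      data.frame(lobe = nm, lobe_class = "atelectatic",
                 mass_b = tru$mass_b, mass_f = tru$mass_f,
                 density_b = tru$density_b, density_f = tru$density_f,
                 volume_b = tru$volume_b, volume_f = tru$volume_f)
    else {
      side_t <- substr(spec$tumor$lobe_id, 1, 1)
      cls <- if (substr(nm, 1, 1) == side_t) "healthy_ipsilateral"
             else "contralateral"
      vb <- Vl - if (nm == spec$tumor$lobe_id) Vt_b else 0
      vf <- Vl - if (nm == spec$tumor$lobe_id) Vt_f else 0
      data.frame(lobe = nm, lobe_class = cls,
                 mass_b = rho_p * vb, mass_f = h[nm] * rho_p * vf,
                 density_b = rho_p, density_f = h[nm] * rho_p,
                 volume_b = vb, volume_f = vf)
    }
  }))
  truth_lobes$pct_mass_change <-
    100 * (truth_lobes$mass_f - truth_lobes$mass_b) / truth_lobes$mass_b
  truth_lobes$pct_density_change <-
    100 * (truth_lobes$density_f - truth_lobes$density_b) / truth_lobes$density_b
  truth_lobes$pct_volume_change <-
    100 * (truth_lobes$volume_f - truth_lobes$volume_b) / truth_lobes$volume_b

  truth <- list(
    lobes = truth_lobes,
    atel_volume_baseline_ml = tru$atel_volume_b,
    atel_volume_followup_ml = tru$atel_volume_f,
    resolution_label = classify_resolution(tru$atel_volume_b,
                                           tru$atel_volume_f),
    transform = rigid_transform(diag(3), -tfu),  # followup -> baseline
    effect = list(f = f, r = r, u = u, s = s))
  structure(list(baseline = bl, followup = fu, truth = truth, spec = spec),
            class = "phantom_pair")
}

check_phantom_layout <- function(masks, body, lobe_names, atel_lobe,
                                 tumor_lobe) {
  painted <- c(lobe_names, "heart", "esophagus", "blood_ref", "bone")
  cnt <- Reduce(`+`, lapply(masks[painted], function(m) m * 1L))
  if (any(cnt > 1L)) {
    bad <- painted[vapply(painted, function(nm)
      any(masks[[nm]] & cnt > 1L), logical(1))]
    stop("phantom geometry overlap between structures: ",
         paste(bad, collapse = ", "),
         " (", sum(cnt > 1L), " voxels); adjust the geometry", call. = FALSE)
  }
  if (any(masks$air_ref & body))
    stop("phantom geometry: air reference box intersects the body",
         call. = FALSE)
  if (any(masks$blood_ref & !body))
    stop("phantom geometry: aortic blood ROI leaves the body", call. = FALSE)
  if (any(masks$atelectasis & !masks[[atel_lobe]]))
    stop("phantom geometry: atelectasis not contained in lobe ", atel_lobe,
         call. = FALSE)
  if (any(masks$tumor_gtv & !masks[[tumor_lobe]]))
    stop("phantom geometry: tumor not contained in lobe ", tumor_lobe,
         call. = FALSE)
  invisible(TRUE)
}

#' @export
print.phantom_pair <- function(x, ...) {
  cat("<phantom_pair> grid", paste(x$spec$grid_shape, collapse = "x"),
      "| atelectasis", x$spec$atelectasis$lobe_id,
      sprintf("%.0f -> %.0f ml (true label: %s)\n",
              x$truth$atel_volume_baseline_ml,
              x$truth$atel_volume_followup_ml, x$truth$resolution_label))
  invisible(x)
}

#' Default treatment plan for a phantom
#'
#' Three equally weighted coplanar beams (gantry 0, 120, 240 degrees) with a
#' rectangular aperture covering the tumor, isocenter at the baseline tumor
#' centre.
#'
#' @param spec a [phantom_spec].
#' @param prescription_dose_gy prescription (default 60 Gy).
#' @param margin_mm aperture margin beyond the tumor radius (default 10).
#' @return A [plan_geometry].
#' @export
default_plan <- function(spec, prescription_dose_gy = 60, margin_mm = 10) {
  iso <- spec$geometry$lobes[[spec$tumor$lobe_id]]$center
  half <- spec$tumor$baseline_radius_mm + margin_mm
  beams <- lapply(c(0, 120, 240), function(ang)
    beam(ang, aperture_rect(half, half), weight = 1, mu = 1))
  plan_geometry(iso, beams, prescription_dose_gy)
}

# ---- cohort generation ------------------------------------------------------

#' Default per-class effect profile for cohort generation
#'
#' Class proportions 22/50/28% (full/partial/none) and per-class mean
#' percent changes in lobe density (-66.0, -25.6, -17.0) and mass
#' (-2.8, -24.4, -9.2), with the resolution-fraction ranges and atelectasis
#' fractions that realise them.
#'
#' @param density_sd,mass_sd between-patient SD of the drawn per-class
#'   density / mass percent changes (defaults 5 and 3 points).
#' @return Data frame with one row per class.
#' @export
default_effect_profile <- function(density_sd = 5, mass_sd = 3) {
  data.frame(class = c("full", "partial", "none"),
             proportion = c(0.22, 0.50, 0.28),
             density_mean = c(-66.0, -25.6, -17.0),
             density_sd = density_sd,
             mass_mean = c(-2.8, -24.4, -9.2),
             mass_sd = mass_sd,
             r_lo = c(0.85, 0.35, 0.17),
             r_hi = c(0.995, 0.65, 0.197),
             atel_fraction = c(0.70, 0.45, 0.50))
}

#' Generate a cohort of phantom pairs with programmed effects
#'
#' Assigns patients to full/partial/no-resolution classes in the profile's
#' proportions (largest-remainder rounding, so 18 patients under the default
#' split give 4 full, 9 partial and 5 none), draws per-patient density and
#' mass change targets around the class means, converts them to generator
#' parameters with [solve_effect_params], and generates one phantom pair per
#' patient.  Reproducible for a fixed seed.
#'
#' @param n_patients number of patients (>= 1).
#' @param effect_profile data frame as [default_effect_profile].
#' @param seed integer seed.
#' @param spec_args named list of arguments forwarded to [phantom_spec]
#'   (e.g. a smaller `grid_shape` for large cohorts).
#' @return List of `phantom_pair` objects with per-patient `class_target`
#'   attributes; attribute `classes` gives the assigned class labels.
#' @export
generate_cohort <- function(n_patients, effect_profile = default_effect_profile(),
                            seed = 1L, spec_args = list()) {
  stopifnot(n_patients >= 1)
  set.seed(seed)
  p <- effect_profile$proportion / sum(effect_profile$proportion)
  counts <- diff(c(0, round(cumsum(p * n_patients))))
  classes <- rep(effect_profile$class, counts)
  pair_seeds <- sample.int(.Machine$integer.max - 1, n_patients)
  pairs <- vector("list", n_patients)
  for (i in seq_len(n_patients)) {
    row <- effect_profile[effect_profile$class == classes[i], ]
    d <- stats::rnorm(1, row$density_mean, row$density_sd)
    m <- stats::rnorm(1, row$mass_mean, row$mass_sd)
    r <- stats::runif(1, row$r_lo, row$r_hi)
    f <- row$atel_fraction
    par <- solve_effect_params(d, m, r, f)
    args <- utils::modifyList(list(
      atelectasis = list(baseline_fraction_of_lobe = f,
                         followup_resolution_fraction = r,
                         edema_excess_mass_fraction = par$e),
      followup_density_scale = par$s,
      seed = pair_seeds[i]), spec_args)
    pairs[[i]] <- generate_pair(do.call(phantom_spec, args))
    attr(pairs[[i]], "class_target") <-
      list(class = classes[i], density_pct = d, mass_pct = m)
  }
  attr(pairs, "classes") <- classes
  pairs
}

#' Write a phantom pair to disk
#'
#' Writes, per time point, the raw image and the label set as NIfTI (with
#' JSON label sidecars), landmarks as CSV, and the analytic truth as JSON.
#'
#' @param pair a `phantom_pair`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_phantom_pair <- function(pair, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (tp in c("baseline", "followup")) {
    x <- pair[[tp]]
    write_volume(x$raw, file.path(dir, paste0(tp, "_raw.nii.gz")))
    # overlapping structures (ctv contains tumor; lobes overlap tumor) are
    # packed into separate label files
    write_labels(x$labels, file.path(dir, paste0(tp, "_labels.nii.gz")),
                 groups = list(
                   c(LOBE_NAMES, "heart", "esophagus", "blood_ref",
                     "air_ref", "bone"),
                   c("atelectasis", "tumor_gtv", "spinal_cord", "carina"),
                   "ctv"))
    write_landmarks(x$landmarks, file.path(dir, paste0(tp, "_landmarks.csv")))
  }
  truth <- pair$truth
  truth$transform <- list(rotation = truth$transform$R,
                          translation_mm = truth$transform$t)
  jsonlite::write_json(truth, file.path(dir, "truth.json"), digits = NA,
                       dataframe = "columns", matrix = "rowmajor",
                       auto_unbox = TRUE)
  invisible(dir)
}
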