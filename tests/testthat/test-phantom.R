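test_that("regeneration with the same seed is bit-identical", {
  a <- generate_pair(phantom_spec(seed = 17))
  b <- generate_pair(phantom_spec(seed = 17))
  expect_identical(a$baseline$raw$data, b$baseline$raw$data)
  expect_identical(a$followup$raw$data, b$followup$raw$data)
  expect_identical(a$baseline$labels$masks, b$baseline$labels$masks)
  expect_identical(a$truth, b$truth)
  c2 <- generate_pair(phantom_spec(seed = 18))
  expect_false(identical(a$baseline$raw$data, c2$baseline$raw$data))
})

test_that("zero resolution leaves the atelectasis volume unchanged", {
  sp <- phantom_spec(atelectasis = list(followup_resolution_fraction = 0),
                     seed = 2)
  p <- generate_pair(sp)
  expect_equal(p$truth$atel_volume_baseline_ml, p$truth$atel_volume_followup_ml)
  expect_equal(p$truth$resolution_label, "none")
  vv <- voxel_volume_ml(p$baseline$density)
  expect_equal(sum(p$followup$labels$masks$atelectasis) * vv,
               sum(p$baseline$labels$masks$atelectasis) * vv,
               tolerance = 0.02)
})

test_that("pure re-aeration conserves lobe mass while density falls", {
  p <- generate_pair(phantom_spec(seed = 2))   # defaults: r=1, e=0, s=1
  tr <- p$truth$lobes[p$truth$lobes$lobe_class == "atelectatic", ]
  expect_equal(tr$pct_mass_change, 0, tolerance = 1e-12)
  expect_lt(tr$pct_density_change, 0)
  expect_gt(tr$pct_volume_change, 0)
})

test_that("a 200 ml collapse resolving 90% sheds 180 ml and labels full", {
  # enlarge the collapsed lobe so the atelectasis reaches 200 ml, and use a
  # high edema fraction to keep the re-expansion modest
  g <- default_thorax_geometry()$lobes
  g$RLL$axes <- c(34, 40, 36)                  # ~205 ml
  V <- 4 / 3 * pi * prod(g$RLL$axes) / 1000
  f <- 200 / V
  sp <- phantom_spec(lobe_geometry = g,
                     atelectasis = list(baseline_fraction_of_lobe = f,
                                        followup_resolution_fraction = 0.9,
                                        edema_excess_mass_fraction = 2),
                     seed = 9)
  p <- generate_pair(sp)
  expect_equal(p$truth$atel_volume_baseline_ml, 200, tolerance = 1e-9)
  expect_equal(p$truth$atel_volume_baseline_ml -
                 p$truth$atel_volume_followup_ml, 180, tolerance = 1e-9)
  expect_equal(p$truth$resolution_label, "full")
  # voxelised masks track the analytic volumes
  vv <- voxel_volume_ml(p$baseline$density)
  expect_equal(sum(p$baseline$labels$masks$atelectasis) * vv, 200,
               tolerance = 0.02)
  expect_equal(sum(p$followup$labels$masks$atelectasis) * vv, 20,
               tolerance = 0.05)
})

test_that("voxelised mask volumes stay within a surface shell of the truth", {
  p <- generate_pair(phantom_spec(seed = 13))
  vv_ml <- voxel_volume_ml(p$baseline$density)
  g <- p$spec$geometry
  shell_tol <- function(axes)  # half-voxel shell around the surface, in ml
    atelect:::ellipsoid_area_mm2(axes) * max(p$spec$spacing_mm) / 2 / 1000
  for (nm in names(g$lobes)) {
    analytic <- atelect:::ellipsoid_volume_ml(g$lobes[[nm]]$axes)
    voxel <- sum(p$baseline$labels$masks[[nm]]) * vv_ml
    expect_lt(abs(voxel - analytic), shell_tol(g$lobes[[nm]]$axes))
  }
})

test_that("invalid or overlapping phantom requests are rejected with diagnostics", {
  expect_error(phantom_spec(atelectasis = list(followup_resolution_fraction = 1.2)),
               "resolution fraction")
  expect_error(phantom_spec(spacing_mm = c(0, 1, 1)), "spacing")
  expect_error(phantom_spec(atelectasis = list(lobe_id = "RUL")),
               "different lobes")
  # forcing two lobes onto the same centre must fail the overlap check
  g <- default_thorax_geometry()$lobes
  g$LUL$center <- g$LLL$center
  expect_error(generate_pair(phantom_spec(lobe_geometry = g, seed = 1)),
               "overlap")
})

test_that("the tumor regresses inside its lobe and stays contained", {
  p <- generate_pair(phantom_spec(seed = 21))
  vv <- voxel_volume_ml(p$baseline$density)
  vb <- sum(p$baseline$labels$masks$tumor_gtv) * vv
  vf <- sum(p$followup$labels$masks$tumor_gtv) * vv
  expect_equal(vf / vb, 1 - p$spec$tumor$regression_fraction,
               tolerance = 0.03)
  expect_true(all(!p$baseline$labels$masks$tumor_gtv |
                    p$baseline$labels$masks$RUL))
})

test_that("cohorts split 18 patients 4/9/5 and are seed-reproducible", {
  coh <- generate_cohort(18, seed = 31, spec_args = coarse_spec_args())
  cls <- attr(coh, "classes")
  expect_equal(sum(cls == "full"), 4)
  expect_equal(sum(cls == "partial"), 9)
  expect_equal(sum(cls == "none"), 5)
  coh2 <- generate_cohort(18, seed = 31, spec_args = coarse_spec_args())
  expect_identical(coh[[7]]$baseline$raw$data, coh2[[7]]$baseline$raw$data)
  one <- generate_cohort(1, seed = 31, spec_args = coarse_spec_args())
  expect_length(one, 1)
})

test_that("programmed density changes are realised in the generator truth", {
  profile <- default_effect_profile()
  profile <- profile[profile$class == "full", ]
  profile$proportion <- 1
  coh <- generate_cohort(50, effect_profile = profile, seed = 37,
                         spec_args = coarse_spec_args())
  truths <- vapply(coh, function(p)
    p$truth$lobes$pct_density_change[p$truth$lobes$lobe_class ==
                                       "atelectatic"], numeric(1))
  # law of large numbers: 50 draws at sd 5 around -66
  expect_lt(abs(mean(truths) + 66), 2)
  # and the drawn targets match the truths the generator realised
  targets <- vapply(coh, function(p) attr(p, "class_target")$density_pct,
                    numeric(1))
  expect_equal(truths, targets, tolerance = 1e-6)
})

test_that("repeat scans share anatomy but not noise", {
  p <- generate_pair(phantom_spec(seed = 3, grid_shape = c(48, 48, 40),
                                  spacing_mm = c(4.2, 4.2, 5)), n_repeats = 3)
  expect_length(p$baseline$repeats, 3)
  expect_false(identical(p$baseline$repeats[[1]]$data,
                         p$baseline$repeats[[2]]$data))
  expect_lt(max(abs(p$baseline$repeats[[1]]$data -
                      p$baseline$repeats[[2]]$data)),
            8 * p$spec$noise_sd)
})

test_that("phantom pairs round-trip to disk as NIfTI + CSV + JSON", {
  p <- generate_pair(phantom_spec(seed = 5, grid_shape = c(48, 48, 40),
                                  spacing_mm = c(4.2, 4.2, 5)))
  dir <- tempfile("pair")
  write_phantom_pair(p, dir)
  raw <- read_volume(file.path(dir, "baseline_raw.nii.gz"))
  expect_equal(raw$data, p$baseline$raw$data, tolerance = 1e-6,
               ignore_attr = TRUE)
  labs <- read_labels(file.path(dir, "baseline_labels_1.nii.gz"))
  expect_equal(labs$masks$RLL, p$baseline$labels$masks$RLL)
  lm <- read_landmarks(file.path(dir, "baseline_landmarks.csv"))
  expect_equal(lm, p$baseline$landmarks, ignore_attr = TRUE)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$resolution_label, p$truth$resolution_label)
})
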