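dose_on <- function(arr, sp = c(2, 2, 2)) volume_grid(arr, spacing = sp)

test_that("uniform and two-level structures give textbook DVH values", {
  d <- c(6, 6, 4)
  uni <- dose_on(array(10, d))
  m <- array(TRUE, d)
  expect_equal(dvh_metric(uni, m, "D_max"), 10)
  expect_equal(dvh_metric(uni, m, "D_mean"), 10)
  expect_equal(dvh_metric(uni, m, "D_min"), 10)
  expect_equal(dvh_metric(uni, m, "V_x", x_gy = 20), 0)

  half <- array(15, d); half[1:3, , ] <- 25
  dose <- dose_on(half)
  expect_equal(dvh_metric(dose, m, "V_x", x_gy = 20), 50)
  expect_equal(dvh_metric(dose, m, "D_mean"), 20)
  expect_equal(dvh_metric(dose, m, "V_Rx", rx_gy = 25), 50)
})

test_that("all metrics match the brute-force voxel oracle on random grids", {
  set.seed(14)
  for (i in 1:10) {
    dims <- sample(4:12, 3, replace = TRUE)
    dose <- dose_on(array(runif(prod(dims), 0, 70), dims))
    mask <- random_mask(dims, 0.5)
    if (!any(mask)) next
    o <- brute_dvh(dose$data, mask, x_gy = c(20, 30, 45))
    expect_equal(dvh_metric(dose, mask, "D_max"), o$D_max)
    expect_equal(dvh_metric(dose, mask, "D_mean"), o$D_mean)
    expect_equal(dvh_metric(dose, mask, "D_min"), o$D_min)
    expect_equal(dvh_metric(dose, mask, "V_x", x_gy = 20), o$V_x[1])
    expect_equal(dvh_metric(dose, mask, "V_x", x_gy = 30), o$V_x[2])
    expect_equal(dvh_metric(dose, mask, "V_x", x_gy = 45), o$V_x[3])
  }
})

test_that("DVH identities hold: V_x non-increasing, D_min <= D_mean <= D_max", {
  set.seed(15)
  dims <- c(10, 10, 8)
  dose <- dose_on(array(rgamma(prod(dims), 3, 0.1), dims))
  mask <- random_mask(dims, 0.6)
  vx <- vapply(seq(1, 70, by = 1),
               function(x) dvh_metric(dose, mask, "V_x", x_gy = x), numeric(1))
  expect_true(all(diff(vx) <= 0))
  expect_lte(dvh_metric(dose, mask, "D_min"), dvh_metric(dose, mask, "D_mean"))
  expect_lte(dvh_metric(dose, mask, "D_mean"), dvh_metric(dose, mask, "D_max"))
})

test_that("boundary dose counts toward V_x (closed lower bound)", {
  d <- c(4, 1, 1)
  dose <- dose_on(array(c(19.999, 20, 20.001, 10), d))
  m <- array(TRUE, d)
  expect_equal(dvh_metric(dose, m, "V_x", x_gy = 20), 50)
})

test_that("empty structures and bad specs are rejected", {
  dose <- dose_on(array(1, c(3, 3, 3)))
  expect_error(dvh_metric(dose, array(FALSE, c(3, 3, 3)), "D_max"), "empty")
  expect_error(dvh_metric(dose, array(TRUE, c(3, 3, 3)), "V_x"), "x_gy")
  expect_error(dvh_metric(dose, array(TRUE, c(3, 3, 3)), "V_x", x_gy = -2),
               "x_gy")
})

test_that("constraints are met at or below the limit, with Table-style transitions", {
  specs <- default_constraints()
  expect_equal(nrow(specs), 13)
  row <- specs[specs$structure == "spinal_cord", ]
  expect_equal(row$limit, 50.5)
  # met at 49 and exactly at the limit
  m1 <- data.frame(structure = "spinal_cord", metric = "D_max", x_gy = NA,
                   limit = 50.5, value = 49)
  expect_true(evaluate_constraints(m1)$met)
  m1$value <- 50.5
  expect_true(evaluate_constraints(m1)$met)
  m1$value <- 50.6
  expect_false(evaluate_constraints(m1)$met)
})

test_that("improved/worsened transitions enumerate exactly as defined", {
  lim <- data.frame(structure = "esophagus", metric = "D_mean", x_gy = NA,
                    limit = 34, units = "Gy")
  cases <- expand.grid(vb = c(33, 35), vf = c(33, 35))
  want <- c("unchanged", "improved", "worsened", "unchanged")
  for (i in seq_len(nrow(cases))) {
    b <- data.frame(structure = "esophagus", metric = "D_mean", x_gy = NA,
                    value = cases$vb[i])
    f <- data.frame(structure = "esophagus", metric = "D_mean", x_gy = NA,
                    value = cases$vf[i])
    res <- evaluate_constraints(f, limits = lim, baseline = b)
    expect_equal(res$transition, want[i],
                 info = sprintf("baseline %g followup %g", cases$vb[i],
                                cases$vf[i]))
    expect_equal(res$delta_from_baseline, cases$vf[i] - cases$vb[i])
  }
})

test_that("lung definitions nest when the CTV contains the GTV", {
  p <- generate_pair(phantom_spec(seed = 6))
  labs <- p$baseline$labels
  lungs <- lung_definition(labs, "lungs")
  no_gtv <- lung_definition(labs, "lungs_minus_gtv")
  no_ctv <- lung_definition(labs, "lungs_minus_ctv")
  expect_true(all(!no_ctv | no_gtv))
  expect_true(all(!no_gtv | lungs))
  expect_true(sum(no_ctv) < sum(no_gtv))
  # lungs include the atelectasis region by construction
  expect_true(all(!labs$masks$atelectasis | lungs))
})

test_that("metric change tables summarise deltas and exceedances correctly", {
  base <- expand.grid(patient = 1:3, structure = "lungs", metric = "D_mean",
                      x_gy = NA)
  base$value <- c(10, 12, 14)
  bone <- base; bone$value <- c(10, 18, 13)    # deltas 0, 6, -1
  carina <- base; carina$value <- c(11, 12, 14) # deltas 1, 0, 0
  mc <- metric_changes(base, bone, carina)
  sb <- mc$summary[mc$summary$alignment == "bone", ]
  expect_equal(sb$mean, mean(c(0, 6, -1)))
  expect_equal(sb$min, -1); expect_equal(sb$max, 6)
  ex <- mc$exceedance
  expect_equal(ex$n_exceeding[ex$alignment == "bone" & ex$threshold == 5], 1)
  expect_equal(ex$n_exceeding[ex$alignment == "bone" & ex$threshold == 1], 2)
  expect_equal(ex$n_exceeding[ex$alignment == "carina" & ex$threshold == 1], 1)
  expect_equal(unname(mc$patients_ge5["bone"]), 1)
  expect_equal(unname(mc$patients_ge5["carina"]), 0)
  # brute recount of the delta table
  dd <- mc$deltas[mc$deltas$alignment == "bone", "delta"]
  expect_equal(sum(abs(dd) >= 2), 1)

  # single-patient table: degenerate stdev flagged as 0
  one <- base[1, , drop = FALSE]
  oneb <- one; oneb$value <- 12
  mc1 <- metric_changes(one, oneb, oneb)
  expect_equal(mc1$summary$stdev, c(0, 0))
  expect_true(all(mc1$summary$stdev_degenerate))
  expect_equal(mc1$summary$min, mc1$summary$max)

  # identical dose grids: all deltas are zero
  mc0 <- metric_changes(base, base, base)
  expect_true(all(mc0$deltas$delta == 0))
})
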