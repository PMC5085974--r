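rot_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
}

lm_df <- function(pts, names = paste0("p", seq_len(nrow(pts))))
  data.frame(name = names, x = pts[, 1], y = pts[, 2], z = pts[, 3])

test_that("rigid transforms validate, compose and invert", {
  expect_error(rigid_transform(matrix(1, 3, 3)), "proper rotation")
  tf <- rigid_transform(rot_z(25), c(3, -1, 2))
  rt <- compose_transforms(invert_transform(tf), tf)
  expect_equal(rt$R, diag(3), tolerance = 1e-9)
  expect_equal(rt$t, c(0, 0, 0), tolerance = 1e-9)
  p <- matrix(rnorm(15), 5, 3)
  expect_equal(apply_transform(invert_transform(tf), apply_transform(tf, p)),
               p, tolerance = 1e-9)
})

test_that("bone alignment recovers rigid motion from landmarks", {
  set.seed(5)
  B <- matrix(runif(18, 0, 100), 6, 3)
  # identical landmarks: identity, zero residual
  tf <- align_bone(lm_df(B), lm_df(B))
  expect_equal(tf$R, diag(3), tolerance = 1e-9)
  expect_equal(tf$t, c(0, 0, 0), tolerance = 1e-9)
  expect_lt(attr(tf, "rms_mm"), 1e-9)
  # pure translation of followup by (5,0,0): recovered transform undoes it
  tf <- align_bone(lm_df(B), lm_df(sweep(B, 2, c(5, 0, 0), "+")))
  expect_equal(tf$t, c(-5, 0, 0), tolerance = 1e-9)
  expect_equal(tf$R, diag(3), tolerance = 1e-9)
})

test_that("bone alignment recovers a noisy rotation to within its noise", {
  set.seed(6)
  B <- matrix(runif(60, 0, 120), 20, 3)
  # followup positions are the baseline rotated by -10 deg, plus noise;
  # the alignment should recover the +10 deg correction
  Fm <- B %*% t(rot_z(-10)) + matrix(rnorm(60, 0, 0.1), 20, 3)
  tf <- align_bone(lm_df(B), lm_df(Fm))
  ang <- acos((sum(diag(tf$R)) - 1) / 2) * 180 / pi
  expect_lt(abs(ang - 10), 0.1)
  expect_lt(attr(tf, "rms_mm"), 0.3)
  # exact recovery without noise
  tf0 <- align_bone(lm_df(B), lm_df(B %*% t(rot_z(-10))))
  expect_equal(tf0$R, rot_z(10), tolerance = 1e-9)
})

test_that("degenerate landmark sets are rejected", {
  B <- matrix(runif(9, 0, 10), 3, 3)
  expect_error(align_bone(lm_df(B[1:2, , drop = FALSE]),
                          lm_df(B[1:2, , drop = FALSE])), "at least 3")
  line <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(align_bone(lm_df(line), lm_df(line)), "collinear")
})

test_that("the box region filters landmarks by baseline position", {
  set.seed(8)
  inside <- matrix(runif(12, 10, 20), 4, 3)
  outlier <- matrix(c(100, 100, 100), 1, 3)
  B <- rbind(inside, outlier)
  Fm <- sweep(B, 2, c(2, 0, 0), "+")
  Fm[5, ] <- Fm[5, ] + 50  # corrupt the outlier
  box <- rbind(c(5, 5, 5), c(25, 25, 25))
  tf <- align_bone(lm_df(B), lm_df(Fm), box_region = box)
  expect_equal(attr(tf, "n_landmarks"), 4)
  expect_equal(tf$t, c(-2, 0, 0), tolerance = 1e-9)
})

test_that("carina alignment is a pure translation matching mask centroids", {
  d <- c(16, 16, 12); sp <- c(2, 2, 3)
  grid <- volume_grid(array(0, d), spacing = sp)
  m <- array(FALSE, d); m[6:8, 7:9, 5:6] <- TRUE
  labs_b <- label_mask_set(list(carina = m), grid)
  # identical masks: zero translation
  tf <- align_carina(labs_b, labs_b)
  expect_equal(tf$t, c(0, 0, 0))
  expect_equal(tf$R, diag(3))
  # integer-voxel shift: exact world translation
  m2 <- array(FALSE, d); m2[7:9, 6:8, 6:7] <- TRUE
  labs_f <- label_mask_set(list(carina = m2), grid)
  tf <- align_carina(labs_b, labs_f)
  expect_equal(tf$t, c(-1, 1, -1) * sp)
  # irregular mask: centroid equals brute-force mean of world coordinates
  set.seed(3)
  mi <- random_mask(d, 0.1)
  labs_i <- label_mask_set(list(carina = mi), grid)
  idx <- which(mi, arr.ind = TRUE)
  brute <- colMeans(sweep((idx - 1), 2, sp, "*"))
  tf <- align_carina(labs_b, labs_i)
  cb <- colMeans(sweep(which(m, arr.ind = TRUE) - 1, 2, sp, "*"))
  expect_equal(tf$t, cb - brute, tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(align_carina(labs_b,
                            label_mask_set(list(carina = array(FALSE, d)),
                                           grid)), "empty")
})

test_that("resampling through the identity reproduces masks bit-identically", {
  p <- generate_pair(phantom_spec(seed = 12, misalignment_mm = c(0, 0, 0)))
  id <- rigid_transform()
  m <- p$followup$labels$masks$RLL
  rs <- resample_to_baseline(m, id, p$baseline$density,
                             followup_grid = p$followup$density)
  expect_identical(rs, m)
  v <- resample_to_baseline(p$followup$density, id, p$baseline$density)
  expect_equal(v$data, p$followup$density$data, tolerance = 1e-12)
})

test_that("a one-voxel translation becomes an index shift", {
  d <- c(8, 8, 6); sp <- c(2, 2, 3)
  set.seed(10)
  src <- volume_grid(array(rnorm(prod(d)), d), spacing = sp)
  tf <- rigid_transform(diag(3), c(sp[1], 0, 0))  # followup -> baseline shift +x
  out <- resample_to_baseline(src, tf, src)
  expect_equal(out$data[2:8, , ], src$data[1:7, , ], tolerance = 1e-12)
})

test_that("rigid round-trip resampling keeps smooth masks nearly intact", {
  d <- c(32, 32, 32); sp <- c(3, 3, 3)
  grid <- volume_grid(array(0, d), spacing = sp)
  ax <- lapply(1:3, function(a) (seq_len(d[a]) - 1) * sp[a])
  c0 <- (d - 1) * sp / 2   # centred ball, fully inside the field of view
  ball <- outer(outer((ax[[1]] - c0[1])^2, (ax[[2]] - c0[2])^2, "+"),
                (ax[[3]] - c0[3])^2, "+") <= 28^2
  tf <- rigid_transform(rot_z(7), c(5, -4, 6))
  fwd <- resample_to_baseline(ball, tf, grid, followup_grid = grid)
  back <- resample_to_baseline(fwd, invert_transform(tf), grid,
                               followup_grid = grid)
  dice <- 2 * sum(ball & back) / (sum(ball) + sum(back))
  expect_gte(dice, 0.98)
})

test_that("bone and carina schemes agree for a pure-translation phantom", {
  p <- generate_pair(phantom_spec(seed = 4))
  g <- default_thorax_geometry()
  tb <- align_bone(p$baseline$landmarks, p$followup$landmarks, g$bone_box)
  tc <- align_carina(p$baseline$labels, p$followup$labels)
  expect_equal(tb$R, diag(3), tolerance = 1e-9)
  expect_equal(tc$R, diag(3))
  expect_equal(tb$t, p$truth$transform$t, tolerance = 1e-9)
  # carina centroid is voxelised, so agreement is to within a voxel
  expect_lt(max(abs(tc$t - tb$t)), max(p$spec$spacing_mm))
})
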