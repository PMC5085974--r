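# Independent brute-force oracles used to cross-check the vectorised
# implementations.  These deliberately share no code with the package
# internals: plain per-voxel loops and exhaustive enumeration.

# neighbourhood-scan erosion: a voxel survives iff every structuring-element
# neighbour (incl. outside-image, which counts as background) is foreground
brute_erode <- function(mask, iterations = 1L, element = "box") {
  d <- dim(mask)
  for (it in seq_len(iterations)) {
    out <- array(FALSE, d)
    idx <- which(mask, arr.ind = TRUE)
    for (row in seq_len(nrow(idx))) {
      i <- idx[row, 1]; j <- idx[row, 2]; k <- idx[row, 3]
      if (i == 1 || i == d[1] || j == 1 || j == d[2] || k == 1 || k == d[3])
        next  # touches the border: outside counts as background
      if (element == "box") {
        out[i, j, k] <- all(mask[(i - 1):(i + 1), (j - 1):(j + 1),
                                 (k - 1):(k + 1)])
      } else {
        out[i, j, k] <- mask[i - 1, j, k] && mask[i + 1, j, k] &&
          mask[i, j - 1, k] && mask[i, j + 1, k] &&
          mask[i, j, k - 1] && mask[i, j, k + 1]
      }
    }
    mask <- out
  }
  mask
}

# per-voxel accumulation of ROI mass / density / volume
brute_roi <- function(dens_array, mask, spacing) {
  vv <- prod(spacing) / 1000  # ml
  s <- 0; n <- 0
  d <- dim(dens_array)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3]))
    if (mask[i, j, k]) { s <- s + dens_array[i, j, k]; n <- n + 1 }
  list(mass_mg = s * vv, density_mg_cc = s / n, volume_ml = n * vv)
}

# per-voxel DVH metrics
brute_dvh <- function(dose_array, mask, x_gy) {
  vals <- c()
  d <- dim(dose_array)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3]))
    if (mask[i, j, k]) vals <- c(vals, dose_array[i, j, k])
  list(D_max = max(vals), D_mean = mean(vals), D_min = min(vals),
       V_x = sapply(x_gy, function(x) 100 * sum(vals >= x) / length(vals)))
}

# exhaustive two-sided rank-sum p-value by enumerating all group assignments
brute_wilcoxon_p <- function(x, y) {
  n1 <- length(x); n <- n1 + length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(n, n1)
  w_all <- apply(combos, 2, function(ix) sum(r[ix]) - n1 * (n1 + 1) / 2)
  lo <- mean(w_all <= w_obs); hi <- mean(w_all >= w_obs)
  min(1, 2 * min(lo, hi))
}

random_mask <- function(dims, p = 0.4) array(runif(prod(dims)) < p, dims)

# small helper: a coarse-grid spec for cheap cohort work in tests
coarse_spec_args <- function()
  list(grid_shape = c(48, 48, 40), spacing_mm = c(4.2, 4.2, 5.0))
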