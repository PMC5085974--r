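#' Rigid transform in world coordinates
#'
#' Represents the map p -> R p + t (mm).  Throughout the package, alignment
#' transforms map followup world coordinates into the baseline frame.
#'
#' @param R 3x3 rotation matrix (orthonormal, det +1).
#' @param t length-3 translation in mm.
#' @return A `rigid_transform` object.
#' @export
rigid_transform <- function(R = diag(3), t = c(0, 0, 0)) {
  R <- matrix(as.numeric(R), 3, 3); t <- as.numeric(t)
  if (max(abs(crossprod(R) - diag(3))) > 1e-6 || abs(det(R) - 1) > 1e-6)
    stop("rigid_transform: R must be a proper rotation", call. = FALSE)
  structure(list(R = R, t = t), class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- acos(pmin(1, pmax(-1, (sum(diag(x$R)) - 1) / 2))) * 180 / pi
  cat(sprintf("<rigid_transform> rotation %.3f deg, translation (%.2f, %.2f, %.2f) mm\n",
              ang, x$t[1], x$t[2], x$t[3]))
  invisible(x)
}

#' Apply, compose and invert rigid transforms
#'
#' @param tf,a,b `rigid_transform` objects.
#' @param pts n x 3 matrix of world points (mm).
#' @return [apply_transform]: n x 3 matrix; [compose_transforms]: the
#'   transform applying `b` first then `a`; [invert_transform]: the inverse.
#' @export
apply_transform <- function(tf, pts) {
  pts <- matrix(as.numeric(pts), ncol = 3)
  sweep(pts %*% t(tf$R), 2, tf$t, "+")
}

#' @rdname apply_transform
#' @export
compose_transforms <- function(a, b)
  rigid_transform(a$R %*% b$R, as.numeric(a$R %*% b$t) + a$t)

#' @rdname apply_transform
#' @export
invert_transform <- function(tf)
  rigid_transform(t(tf$R), as.numeric(-t(tf$R) %*% tf$t))

in_any_box <- function(pts, boxes) {
  hit <- rep(FALSE, nrow(pts))
  for (b in boxes)
    hit <- hit | (pts[, 1] >= b[1, 1] & pts[, 1] <= b[2, 1] &
                  pts[, 2] >= b[1, 2] & pts[, 2] <= b[2, 2] &
                  pts[, 3] >= b[1, 3] & pts[, 3] <= b[2, 3])
  hit
}

#' Bone-based rigid alignment from landmarks
#'
#' Least-squares rigid fit (orthogonal Procrustes / Kabsch) of corresponding
#' bony landmarks, optionally restricted to a box region covering the
#' sternum and spine.  Returns the transform mapping followup points onto
#' baseline points, with the root-mean-square residual.
#'
#' @param baseline_landmarks,followup_landmarks data frames with columns
#'   `name,x,y,z` (world mm); rows are matched by `name`.
#' @param box_region optional box or list of boxes, each a 2 x 3 matrix
#'   (rows: lower, upper corner in mm); only landmarks whose *baseline*
#'   position falls inside some box are used.
#' @return A [rigid_transform] with attribute `rms_mm` (residual) and
#'   `n_landmarks`.
#' @export
align_bone <- function(baseline_landmarks, followup_landmarks,
                       box_region = NULL) {
  common <- intersect(baseline_landmarks$name, followup_landmarks$name)
  b <- baseline_landmarks[match(common, baseline_landmarks$name), ]
  f <- followup_landmarks[match(common, followup_landmarks$name), ]
  B <- as.matrix(b[, c("x", "y", "z")]); Fm <- as.matrix(f[, c("x", "y", "z")])
  if (!is.null(box_region)) {
    if (is.matrix(box_region)) box_region <- list(box_region)
    keep <- in_any_box(B, box_region)
    B <- B[keep, , drop = FALSE]; Fm <- Fm[keep, , drop = FALSE]
  }
  if (nrow(B) < 3)
    stop("align_bone: need at least 3 corresponding landmarks in the region",
         call. = FALSE)
  if (any(svd(scale(B, scale = FALSE))$d[2] < 1e-9))
    stop("align_bone: landmarks are collinear", call. = FALSE)
  k <- pracma::kabsch(t(Fm), t(B))   # U %*% followup + R == baseline
  tf <- rigid_transform(k$U, as.numeric(k$R))
  res <- apply_transform(tf, Fm) - B
  attr(tf, "rms_mm") <- sqrt(mean(rowSums(res^2)))
  attr(tf, "n_landmarks") <- nrow(B)
  tf
}

#' Carina-based translational alignment
#'
#' Mimics carina-based volumetric image-guided setup: a pure translation
#' matching the centroid of the followup carina mask to that of the baseline
#' mask.  Rotation is identity by construction.
#'
#' @param baseline_labels,followup_labels [label_mask_set]s containing a
#'   non-empty `carina` mask.
#' @return A [rigid_transform] (identity rotation).
#' @export
align_carina <- function(baseline_labels, followup_labels) {
  cb <- get_mask(baseline_labels, "carina")
  cf <- get_mask(followup_labels, "carina")
  if (!any(cb) || !any(cf))
    stop("align_carina: carina mask is empty", call. = FALSE)
  centroid <- function(mask, grid) {
    idx <- which(mask, arr.ind = TRUE)
    colMeans(voxel_world_coords(grid, idx))
  }
  rigid_transform(diag(3), centroid(cb, baseline_labels$grid) -
                             centroid(cf, followup_labels$grid))
}

# Vectorised trilinear interpolation of `vol` at world points (n x 3).
# Points outside the grid get `fill`.
trilinear_sample <- function(vol, pts, fill = 0) {
  d <- dim(vol$data)
  # continuous 1-based voxel coordinates
  cx <- (pts[, 1] - vol$origin[1]) / vol$spacing[1] + 1
  cy <- (pts[, 2] - vol$origin[2]) / vol$spacing[2] + 1
  cz <- (pts[, 3] - vol$origin[3]) / vol$spacing[3] + 1
  inside <- cx >= 1 & cx <= d[1] & cy >= 1 & cy <= d[2] & cz >= 1 & cz <= d[3]
  out <- rep(fill, nrow(pts))
  if (!any(inside)) return(out)
  cx <- cx[inside]; cy <- cy[inside]; cz <- cz[inside]
  x0 <- pmin(floor(cx), d[1] - 1); y0 <- pmin(floor(cy), d[2] - 1)
  z0 <- pmin(floor(cz), d[3] - 1)
  fx <- cx - x0; fy <- cy - y0; fz <- cz - z0
  at <- function(ix, iy, iz)
    vol$data[cbind(ix, iy, iz)]
  v <- at(x0,     y0,     z0)     * (1 - fx) * (1 - fy) * (1 - fz) +
       at(x0 + 1, y0,     z0)     * fx       * (1 - fy) * (1 - fz) +
       at(x0,     y0 + 1, z0)     * (1 - fx) * fy       * (1 - fz) +
       at(x0 + 1, y0 + 1, z0)     * fx       * fy       * (1 - fz) +
       at(x0,     y0,     z0 + 1) * (1 - fx) * (1 - fy) * fz +
       at(x0 + 1, y0,     z0 + 1) * fx       * (1 - fy) * fz +
       at(x0,     y0 + 1, z0 + 1) * (1 - fx) * fy       * fz +
       at(x0 + 1, y0 + 1, z0 + 1) * fx       * fy       * fz
  out[inside] <- v
  out
}

nearest_sample <- function(vol, pts, fill = 0) {
  d <- dim(vol$data)
  ix <- round((pts[, 1] - vol$origin[1]) / vol$spacing[1]) + 1
  iy <- round((pts[, 2] - vol$origin[2]) / vol$spacing[2]) + 1
  iz <- round((pts[, 3] - vol$origin[3]) / vol$spacing[3]) + 1
  inside <- ix >= 1 & ix <= d[1] & iy >= 1 & iy <= d[2] & iz >= 1 & iz <= d[3]
  out <- rep(fill, nrow(pts))
  out[inside] <- vol$data[cbind(ix[inside], iy[inside], iz[inside])]
  out
}

#' Resample a followup volume or mask onto the baseline grid
#'
#' Pulls followup values onto the baseline grid through a rigid alignment
#' transform: the value at baseline point p is the followup image sampled at
#' `invert_transform(tf)(p)`.  Scalars are interpolated trilinearly; masks
#' (logical arrays on the followup grid) use nearest neighbour.  Points that
#' map outside the followup field of view receive `fill` (default 0 mg/cc,
#' i.e. air-equivalent density) for scalars and background for masks.
#'
#' @param followup a [volume_grid] (scalar) or logical 3D array (mask; then
#'   `followup_grid` must give its geometry).
#' @param tf [rigid_transform] mapping followup coordinates to baseline.
#' @param baseline_grid [volume_grid] defining the output geometry.
#' @param followup_grid geometry of `followup` when it is a bare mask.
#' @param fill out-of-field value for scalar volumes.
#' @return A [volume_grid] on the baseline geometry, or a logical array for
#'   mask input.
#' @export
resample_to_baseline <- function(followup, tf, baseline_grid,
                                 followup_grid = NULL, fill = 0) {
  stopifnot(inherits(tf, "rigid_transform"),
            inherits(baseline_grid, "volume_grid"))
  pts <- voxel_world_coords(baseline_grid)
  pts <- apply_transform(invert_transform(tf), pts)
  if (is.logical(followup)) {
    stopifnot(inherits(followup_grid, "volume_grid"))
    src <- with_data(followup_grid, array(as.numeric(followup),
                                          dim(followup)))
    v <- nearest_sample(src, pts, fill = 0)
    return(array(v > 0.5, dim(baseline_grid$data)))
  }
  stopifnot(inherits(followup, "volume_grid"))
  v <- trilinear_sample(followup, pts, fill = fill)
  with_data(baseline_grid, array(v, dim(baseline_grid$data)))
}
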