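#' 3D scalar volume on a regular anisotropic grid
#'
#' The basic container for CT-like images, calibrated density maps and dose
#' grids: a 3D numeric array plus the geometry needed to place each voxel in
#' world (scanner) coordinates.  Axis order is (x, y, z) with world position
#' of voxel centre \code{(i, j, k)} (0-based) equal to
#' \code{origin + c(i, j, k) * spacing}.  Direction cosines are assumed
#' identity; oblique acquisitions are out of scope.
#'
#' @param data 3D numeric array of voxel values; all values must be finite.
#' @param spacing numeric length-3, voxel spacing in mm per axis (> 0).
#' @param origin numeric length-3, world position (mm) of the centre of the
#'   first voxel.
#' @return An object of class \code{volume_grid}.
#' @examples
#' v <- volume_grid(array(0, c(4, 4, 4)), spacing = c(1.17, 1.17, 3))
#' voxel_volume_ml(v)
#' @export
volume_grid <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("volume_grid: `data` must be a 3D array (got ",
         paste(dim(data), collapse = "x"), ")", call. = FALSE)
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("volume_grid: `spacing` must be 3 positive finite values", call. = FALSE)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("volume_grid: `origin` must be 3 finite values", call. = FALSE)
  if (any(!is.finite(data)))
    stop("volume_grid: `data` contains non-finite values", call. = FALSE)
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat("<volume_grid> ", paste(dim(x$data), collapse = " x "),
      " voxels, spacing (", paste(format(x$spacing), collapse = ", "),
      ") mm, origin (", paste(format(x$origin), collapse = ", "), ") mm\n",
      sep = "")
  cat("  value range: [", format(min(x$data)), ", ", format(max(x$data)), "]\n",
      sep = "")
  invisible(x)
}

#' @export
dim.volume_grid <- function(x) dim(x$data)

#' Voxel volume of a grid
#'
#' @param vol a [volume_grid].
#' @return Voxel volume in mm^3 (`voxel_volume_mm3`) or ml (`voxel_volume_ml`;
#'   1 ml = 1000 mm^3).
#' @export
voxel_volume_mm3 <- function(vol) prod(vol$spacing)

#' @rdname voxel_volume_mm3
#' @export
voxel_volume_ml <- function(vol) prod(vol$spacing) / 1000

#' Check that two grids share the same geometry
#'
#' Paired analyses (baseline vs followup, dose vs mask) require voxelwise
#' correspondence; this verifies shape, spacing and origin agree.
#'
#' @param a,b [volume_grid] objects.
#' @param tol tolerance in mm for spacing/origin agreement.
#' @return `TRUE` if shapes match and spacing and origin agree within `tol`.
#' @export
check_congruent <- function(a, b, tol = 1e-6) {
  stopifnot(inherits(a, "volume_grid"), inherits(b, "volume_grid"))
  identical(dim(a$data), dim(b$data)) &&
    all(abs(a$spacing - b$spacing) <= tol) &&
    all(abs(a$origin - b$origin) <= tol)
}

stop_if_incongruent <- function(a, b, what = "volumes") {
  if (!check_congruent(a, b))
    stop("grids are not congruent (", what,
         "): shapes/spacings/origins must agree", call. = FALSE)
  invisible(TRUE)
}

#' World coordinates of voxel centres
#'
#' @param vol a [volume_grid].
#' @param idx integer matrix (n x 3) of 1-based voxel indices; defaults to all
#'   voxels in array order.
#' @return n x 3 matrix of world coordinates in mm.
#' @export
voxel_world_coords <- function(vol, idx = NULL) {
  if (is.null(idx)) {
    d <- dim(vol$data)
    idx <- as.matrix(expand.grid(i = seq_len(d[1]), j = seq_len(d[2]),
                                 k = seq_len(d[3])))
  }
  sweep(sweep(idx - 1, 2, vol$spacing, "*"), 2, vol$origin, "+")
}

#' Replace the data array of a grid, keeping its geometry
#' @param vol a [volume_grid].
#' @param data replacement array with identical dimensions.
#' @return A new [volume_grid].
#' @export
with_data <- function(vol, data) {
  stopifnot(identical(dim(data), dim(vol$data)))
  volume_grid(data, vol$spacing, vol$origin)
}
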