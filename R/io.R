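#' Read and write volumes as NIfTI
#'
#' Volumes are stored as standard NIfTI-1 files.  Geometry is carried in the
#' NIfTI sform: spacing on the diagonal and origin in the translation column
#' (identity direction cosines; the reader rejects oblique files).  Label
#' images are written as integer volumes with a JSON sidecar mapping
#' structure names to label values (see [write_labels]).
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @return [read_volume] returns a [volume_grid]; [write_volume] returns
#'   `path` invisibly.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) { img <- img[, , , 1]; d <- dim(img) }
  if (length(d) != 3L)
    stop("read_volume: '", path, "' is not a 3D volume (dims: ",
         paste(d, collapse = "x"), ")", call. = FALSE)
  xf <- RNifti::xform(img)
  rot <- xf[1:3, 1:3]
  spacing <- sqrt(colSums(rot^2))
  dir <- sweep(rot, 2, spacing, "/")
  if (max(abs(abs(dir) - diag(3))) > 1e-3)
    stop("read_volume: oblique or flipped direction cosines are unsupported",
         call. = FALSE)
  origin <- xf[1:3, 4] * sign(diag(dir))  # undo any axis sign flip
  volume_grid(array(as.numeric(img), dim = d), spacing = spacing,
              origin = as.numeric(origin))
}

#' @rdname read_volume
#' @param vol a [volume_grid].
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "volume_grid"))
  img <- RNifti::asNifti(vol$data)
  img <- RNifti::`pixdim<-`(img, vol$spacing)
  xf <- diag(c(vol$spacing, 1))
  xf[1:3, 4] <- vol$origin
  img <- RNifti::`sform<-`(img, structure(xf, code = 2L))
  img <- RNifti::`qform<-`(img, structure(xf, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read and write label mask sets
#'
#' A [label_mask_set] is serialised as one integer NIfTI volume (each voxel
#' holds the label value of the structure that claimed it last; overlapping
#' non-lobe structures therefore need one file per overlap group, see
#' `groups`) plus a JSON sidecar `<path>.json` mapping names to label values.
#' Masks are written in the order given, so later structures overwrite
#' earlier ones in the packed image; on reading, each named label value is
#' expanded back to a binary mask.
#'
#' @param labels a [label_mask_set].
#' @param path path of the label NIfTI; sidecar written to `paste0(path, ".json")`.
#' @param groups optional list of character vectors splitting structures into
#'   separately-packed files (suffix `_<group index>` inserted); defaults to a
#'   single file containing everything.
#' @return [read_labels] returns a [label_mask_set].
#' @export
write_labels <- function(labels, path, groups = NULL) {
  stopifnot(inherits(labels, "label_mask_set"))
  if (is.null(groups)) groups <- list(names(labels$masks))
  paths <- character(0)
  for (gi in seq_along(groups)) {
    nm <- groups[[gi]]
    p <- if (length(groups) == 1) path else
      sub("(\\.nii(\\.gz)?)$", sprintf("_%d\\1", gi), path)
    lab <- array(0L, dim(labels$grid$data))
    codes <- seq_along(nm)
    for (i in seq_along(nm)) lab[labels$masks[[nm[i]]]] <- codes[i]
    write_volume(with_data(labels$grid, lab), p)
    jsonlite::write_json(as.list(stats::setNames(codes, nm)),
                         paste0(p, ".json"), auto_unbox = TRUE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  vol <- read_volume(path)
  side <- paste0(path, ".json")
  if (!file.exists(side))
    stop("read_labels: sidecar not found: ", side, call. = FALSE)
  codes <- jsonlite::read_json(side, simplifyVector = TRUE)
  masks <- lapply(codes, function(v) vol$data == v)
  label_mask_set(masks, vol)
}

#' Read and write landmark tables
#'
#' Landmarks are stored as CSV with columns `name,x,y,z` (world mm).
#'
#' @param landmarks data.frame with columns `name`, `x`, `y`, `z`.
#' @param path CSV path.
#' @export
write_landmarks <- function(landmarks, path) {
  stopifnot(all(c("name", "x", "y", "z") %in% names(landmarks)))
  utils::write.csv(landmarks[c("name", "x", "y", "z")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_landmarks
#' @export
read_landmarks <- function(path) {
  lm <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("name", "x", "y", "z") %in% names(lm)))
    stop("read_landmarks: need columns name,x,y,z", call. = FALSE)
  lm
}

#' Read and write rigid transforms as JSON
#'
#' @param tf a [rigid_transform].
#' @param path JSON path.
#' @export
write_transform <- function(tf, path) {
  stopifnot(inherits(tf, "rigid_transform"))
  jsonlite::write_json(list(rotation = tf$R, translation_mm = tf$t),
                       path, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  rot <- x$rotation
  if (!is.matrix(rot)) rot <- matrix(unlist(rot), 3, 3, byrow = TRUE)
  rigid_transform(R = rot, t = as.numeric(x$translation_mm))
}

#' Read a treatment-plan description from YAML
#'
#' Expected fields: `isocenter_mm` (length 3), `prescription_dose_gy`, and a
#' list `beams` each with `gantry_angle_deg`, `weight`, `mu` and `aperture`
#' (list with `half_width_mm`, `half_length_mm`, or an explicit `polygon`
#' n x 2 matrix in beam's-eye-view mm).
#'
#' @param path YAML file.
#' @return A [plan_geometry].
#' @export
read_plan <- function(path) {
  y <- yaml::read_yaml(path)
  beams <- lapply(y$beams, function(b) {
    ap <- b$aperture
    if (!is.null(ap$polygon))
      ap <- matrix(unlist(ap$polygon), ncol = 2, byrow = TRUE)
    else
      ap <- aperture_rect(ap$half_width_mm, ap$half_length_mm)
    beam(gantry_angle_deg = b$gantry_angle_deg, aperture = ap,
         weight = b$weight, mu = b$mu)
  })
  plan_geometry(isocenter_mm = as.numeric(y$isocenter_mm), beams = beams,
                prescription_dose_gy = y$prescription_dose_gy)
}
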