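#' Structure names understood by the analysis
#'
#' Controlled vocabulary for structure masks.  The five lung lobes are the
#' left upper (LUL), left lower (LLL), right upper (RUL), right middle (RML)
#' and right lower (RLL) lobes.
#' @format Character vectors.
#' @export
LOBE_NAMES <- c("LUL", "LLL", "RUL", "RML", "RLL")

#' @rdname LOBE_NAMES
#' @export
STRUCTURE_NAMES <- c(LOBE_NAMES, "tumor_gtv", "ctv", "atelectasis",
                     "spinal_cord", "esophagus", "heart",
                     "air_ref", "blood_ref", "carina", "bone")

#' Set of co-registered binary structure masks
#'
#' Binds named logical masks to the single [volume_grid] geometry they live
#' on.  All masks must have the grid's dimensions; lobe masks are expected to
#' be pairwise disjoint (checked).
#'
#' @param masks named list of logical 3D arrays.
#' @param grid the [volume_grid] the masks are defined on (its data array is
#'   only used for geometry).
#' @param check_disjoint_lobes verify that lobe masks do not overlap.
#' @return An object of class \code{label_mask_set}: list with `masks` and
#'   `grid`.
#' @export
label_mask_set <- function(masks, grid, check_disjoint_lobes = TRUE) {
  stopifnot(inherits(grid, "volume_grid"))
  if (is.null(names(masks)) || any(!nzchar(names(masks))))
    stop("label_mask_set: masks must be a named list", call. = FALSE)
  unknown <- setdiff(names(masks), STRUCTURE_NAMES)
  if (length(unknown))
    stop("label_mask_set: unknown structure name(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  d <- dim(grid$data)
  for (nm in names(masks)) {
    m <- masks[[nm]]
    if (!is.logical(m)) {
      m <- m != 0
      storage.mode(m) <- "logical"
      masks[[nm]] <- m
    }
    if (!identical(dim(m), d))
      stop("label_mask_set: mask '", nm, "' does not match grid dimensions",
           call. = FALSE)
  }
  if (check_disjoint_lobes) {
    present <- intersect(LOBE_NAMES, names(masks))
    if (length(present) > 1) {
      cnt <- Reduce(`+`, lapply(masks[present], function(m) m * 1L))
      if (any(cnt > 1L))
        stop("label_mask_set: lobe masks overlap (",
             sum(cnt > 1L), " voxels)", call. = FALSE)
    }
  }
  structure(list(masks = masks, grid = grid), class = "label_mask_set")
}

#' @export
print.label_mask_set <- function(x, ...) {
  cat("<label_mask_set> on ", paste(dim(x$grid$data), collapse = " x "),
      " grid\n", sep = "")
  vv <- voxel_volume_ml(x$grid)
  for (nm in names(x$masks))
    cat(sprintf("  %-12s %8d voxels  %8.1f ml\n", nm,
                sum(x$masks[[nm]]), sum(x$masks[[nm]]) * vv))
  invisible(x)
}

get_mask <- function(labels, name, required = TRUE) {
  m <- labels$masks[[name]]
  if (is.null(m) && required)
    stop("structure '", name, "' is not present in the label set",
         call. = FALSE)
  m
}

#' Lung definitions used for dose constraints
#'
#' Builds the three lung structures evaluated against dose limits: all lung
#' tissue (the union of the five lobes, which by construction includes any
#' atelectasis lying within them), lung minus the gross tumor volume, and
#' lung minus the clinical target volume.
#'
#' @param labels a [label_mask_set] containing the five lobes and, for the
#'   subtracted variants, `tumor_gtv` / `ctv`.
#' @param variant one of `"lungs"`, `"lungs_minus_gtv"`, `"lungs_minus_ctv"`.
#' @return Logical 3D mask.
#' @export
lung_definition <- function(labels, variant = c("lungs", "lungs_minus_gtv",
                                                "lungs_minus_ctv")) {
  variant <- match.arg(variant)
  present <- intersect(LOBE_NAMES, names(labels$masks))
  if (!length(present))
    stop("lung_definition: no lobe masks present", call. = FALSE)
  lungs <- Reduce(`|`, labels$masks[present])
  switch(variant,
         lungs = lungs,
         lungs_minus_gtv = lungs & !get_mask(labels, "tumor_gtv"),
         lungs_minus_ctv = lungs & !get_mask(labels, "ctv"))
}
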