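#' Binary erosion of a 3D mask
#'
#' Erodes a logical 3D array with either the full 3x3x3 box (26-connected
#' neighbourhood, "1 voxel in all dimensions" including diagonals) or the
#' 6-connected cross.  Space outside the image counts as background, so
#' foreground touching the array border is always eroded.
#'
#' @param mask logical 3D array.
#' @param iterations number of single-voxel erosion passes (>= 0).
#' @param element `"box"` (default, 3x3x3 full neighbourhood) or `"cross"`
#'   (6-connected).
#' @return Logical 3D array of the same dimensions.
#' @export
erode_mask <- function(mask, iterations = 1L, element = c("box", "cross")) {
  element <- match.arg(element)
  stopifnot(is.logical(mask), length(dim(mask)) == 3L, iterations >= 0)
  offs <- erosion_offsets(element)
  for (it in seq_len(iterations)) {
    if (!any(mask)) break
    out <- mask
    for (o in offs)
      out <- out & shift_mask(mask, o)
    mask <- out
  }
  mask
}

erosion_offsets <- function(element) {
  if (element == "box") {
    g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
    g <- g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ]
    lapply(seq_len(nrow(g)), function(i) as.integer(g[i, ]))
  } else {
    list(c(-1L, 0L, 0L), c(1L, 0L, 0L), c(0L, -1L, 0L),
         c(0L, 1L, 0L), c(0L, 0L, -1L), c(0L, 0L, 1L))
  }
}

# Shift a logical array by integer offset, padding with FALSE (background).
shift_mask <- function(mask, off) {
  d <- dim(mask)
  out <- array(FALSE, d)
  src <- dst <- vector("list", 3)
  for (a in 1:3) {
    o <- off[a]
    if (o >= 0) { src[[a]] <- seq_len(d[a] - o); dst[[a]] <- src[[a]] + o }
    else { src[[a]] <- seq.int(1 - o, d[a]); dst[[a]] <- src[[a]] + o }
    if (d[a] + ifelse(o >= 0, -o, o) <= 0) return(out)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- mask[src[[1]], src[[2]], src[[3]]]
  out
}

#' Remove the tumor from lobe masks
#'
#' Tumor regression is a separate process from atelectasis change, so the
#' gross tumor volume is excluded from every lobe before measurement.
#'
#' @param labels a [label_mask_set] with lobe masks and `tumor_gtv`.
#' @return A new [label_mask_set] with each lobe ANDed with NOT tumor.
#' @export
remove_tumor <- function(labels) {
  stopifnot(inherits(labels, "label_mask_set"))
  tumor <- get_mask(labels, "tumor_gtv")
  masks <- labels$masks
  for (nm in intersect(LOBE_NAMES, names(masks)))
    masks[[nm]] <- masks[[nm]] & !tumor
  label_mask_set(masks, labels$grid)
}

#' Erode lobe masks from the lung exterior only
#'
#' Lobe delineations can include extra-pleural tissue at the outer lung
#' surface, but the interlobar fissures are comparatively reliable.  The
#' combined lung (union of all lobes present) is therefore eroded as a whole
#' -- by default twice with the full 3x3x3 element -- and each lobe is
#' intersected with the eroded combined lung.  Voxels on a fissure between
#' two lobes survive (they are interior to the combined lung), while the
#' outer pleural shell is removed.
#'
#' @param labels a [label_mask_set]; typically after [remove_tumor].
#' @param iterations erosion passes (default 2).
#' @param element structuring element, `"box"` or `"cross"`.
#' @return A [label_mask_set] whose lobe masks are the exterior-eroded ones;
#'   non-lobe structures are passed through untouched.
#' @export
erode_exterior <- function(labels, iterations = 2L,
                           element = c("box", "cross")) {
  stopifnot(inherits(labels, "label_mask_set"))
  element <- match.arg(element)
  present <- intersect(LOBE_NAMES, names(labels$masks))
  if (!length(present))
    stop("erode_exterior: no lobe masks present", call. = FALSE)
  combined <- Reduce(`|`, labels$masks[present])
  eroded <- erode_mask(combined, iterations = iterations, element = element)
  masks <- labels$masks
  for (nm in present) masks[[nm]] <- masks[[nm]] & eroded
  label_mask_set(masks, labels$grid)
}
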