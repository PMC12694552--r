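#' Tissue label codes
#'
#' Integer codes used throughout the package for the hard five-class voxel
#' partition of a grain scan: background air outside the grain, the embryo
#' and endosperm of the caryopsis, the cavity (air gap between caryopsis and
#' hull) and the hull (lemma + palea).
#'
#' @format A named integer vector of length 5.
#' @export
TISSUE_LABELS <- c(
  BACKGROUND = 0L,
  EMBRYO     = 1L,
  ENDOSPERM  = 2L,
  CAVITY     = 3L,
  HULL       = 4L
)

#' The four grain tissues (everything but background)
#' @keywords internal
.TISSUES <- c("EMBRYO", "ENDOSPERM", "CAVITY", "HULL")

#' Construct a voxel volume
#'
#' A `voxel_volume` is a 3D array of non-negative integer grayscale
#' intensities with a physical voxel size. Axis order is
#' `(slice, row, column)` = `(z, y, x)`; physical coordinates are
#' `index * voxel_size_um`. Voxels are assumed isotropic.
#'
#' @param data 3D numeric array of non-negative integer intensities.
#' @param voxel_size_um positive scalar, edge length of a voxel in microns.
#' @param bit_depth 8 or 16; if `NULL`, inferred from the maximum intensity.
#' @return An object of class `voxel_volume`.
#' @export
voxel_volume <- function(data, voxel_size_um, bit_depth = NULL) {
  if (length(dim(data)) != 3L) stop("`data` must be a 3D array")
  if (any(dim(data) < 1L)) stop("all three dimensions must be >= 1")
  if (!is.numeric(voxel_size_um) || length(voxel_size_um) != 1L || voxel_size_um <= 0)
    stop("`voxel_size_um` must be a positive scalar")
  if (anyNA(data) || min(data) < 0) stop("intensities must be non-negative and finite")
  if (is.null(bit_depth)) bit_depth <- if (max(data) > 255) 16L else 8L
  if (!bit_depth %in% c(8L, 16L)) stop("`bit_depth` must be 8 or 16")
  if (max(data) > 2^bit_depth - 1)
    stop("intensities exceed the stated bit depth")
  structure(
    list(data = data, voxel_size_um = as.numeric(voxel_size_um),
         bit_depth = as.integer(bit_depth)),
    class = "voxel_volume"
  )
}

#' Construct a label volume
#'
#' A `label_volume` is a hard per-voxel partition of a scan into
#' background, embryo, endosperm, cavity and hull (see [TISSUE_LABELS]).
#'
#' @param labels 3D integer array of codes in `TISSUE_LABELS`.
#' @param voxel_size_um positive scalar, microns per voxel edge.
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(labels, voxel_size_um) {
  if (length(dim(labels)) != 3L) stop("`labels` must be a 3D array")
  if (!is.numeric(voxel_size_um) || length(voxel_size_um) != 1L || voxel_size_um <= 0)
    stop("`voxel_size_um` must be a positive scalar")
  storage.mode(labels) <- "integer"
  if (anyNA(labels) || !all(unique(as.vector(labels)) %in% TISSUE_LABELS))
    stop("labels must be codes in TISSUE_LABELS")
  structure(
    list(labels = labels, voxel_size_um = as.numeric(voxel_size_um)),
    class = "label_volume"
  )
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<voxel_volume> %d x %d x %d (z,y,x), %d-bit, voxel %.3g um\n",
              d[1], d[2], d[3], x$bit_depth, x$voxel_size_um))
  cat(sprintf("  intensity range [%g, %g]\n", min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<label_volume> %d x %d x %d (z,y,x), voxel %.3g um\n",
              d[1], d[2], d[3], x$voxel_size_um))
  tab <- tabulate(as.vector(x$labels) + 1L, nbins = 5L)
  names(tab) <- names(TISSUE_LABELS)
  print(tab)
  invisible(x)
}

#' Dice overlap coefficient between two label volumes
#'
#' `2|A_t & B_t| / (|A_t| + |B_t|)` per tissue label, the standard overlap
#' measure between a segmentation and its ground truth.
#'
#' @param a,b `label_volume` objects of identical shape.
#' @param labels which tissue names to score (default the four grain tissues).
#' @return Named numeric vector of Dice coefficients in `[0, 1]`
#'   (`NaN` when a label is absent from both volumes).
#' @export
dice_coefficient <- function(a, b, labels = .TISSUES) {
  stopifnot(inherits(a, "label_volume"), inherits(b, "label_volume"))
  if (!identical(dim(a$labels), dim(b$labels))) stop("shape mismatch")
  out <- vapply(labels, function(nm) {
    code <- TISSUE_LABELS[[nm]]
    ma <- a$labels == code
    mb <- b$labels == code
    denom <- sum(ma) + sum(mb)
    if (denom == 0) return(NaN)
    2 * sum(ma & mb) / denom
  }, numeric(1))
  out
}
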