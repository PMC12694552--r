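# Voxel morphometry: tissue volumes, surface areas and mean hull thickness.
#
# Surface areas use a Cauchy-Crofton line-intercept estimator: chords
# (maximal runs of in-mask voxels) are counted along the three grid axes and
# S = 4 * s^2 * mean(chord counts), with s the voxel edge. Each chord has
# two endpoints on the surface, so interior boundaries (a shell's inner
# wall) are counted automatically, and the estimator converges to the
# analytic area for smooth surfaces as the voxel size shrinks.
#
# Mean hull thickness is a local-thickness estimate: twice the mean of the
# Euclidean distance transform sampled on the mask's medial voxels (the
# 26-neighbourhood local maxima of the transform).

#' Canonical trait column names
#'
#' The fifteen structural traits: tissue volumes (mm^3), surface areas
#' (mm^2), average hull thickness (um) and tissue-to-grain volume ratios.
#' @export
TRAIT_COLUMNS <- c("K-Volume", "EM-Volume", "EN-Volume", "C-Volume", "H-Volume",
                   "K-Area", "EM-Area", "EN-Area", "C-Area", "H-Area",
                   "H-A-T", "EM-Ratio", "EN-Ratio", "C-Ratio", "H-Ratio")

label_mask <- function(lv, label) {
  if (is.character(label)) label <- TISSUE_LABELS[[label]]
  lv$labels == label
}

#' Tissue volume in mm^3
#'
#' Voxel count times the cubed voxel edge; an absent label gives 0.
#'
#' @param lv a [label_volume].
#' @param label tissue name or code.
#' @return Volume in mm^3.
#' @export
region_volume <- function(lv, label) {
  stopifnot(inherits(lv, "label_volume"))
  sum(label_mask(lv, label)) * (lv$voxel_size_um * 1e-3)^3
}

crofton_area_mm2 <- function(mask, voxel_size_um) {
  d <- dim(mask)
  runs <- 0
  runs <- runs + sum(mask[1, , ]) + sum(mask[-1, , ] & !mask[-d[1], , ])
  runs <- runs + sum(mask[, 1, ]) + sum(mask[, -1, ] & !mask[, -d[2], ])
  runs <- runs + sum(mask[, , 1]) + sum(mask[, , -1] & !mask[, , -d[3]])
  s_mm <- voxel_size_um * 1e-3
  4 * s_mm^2 * runs / 3
}

#' Tissue surface area in mm^2
#'
#' Cauchy-Crofton line-intercept estimate (see the file header); includes
#' interior boundary surfaces, so a hollow shell reports inner + outer area.
#'
#' @param lv a [label_volume].
#' @param label tissue name or code.
#' @return Area in mm^2.
#' @export
region_surface_area <- function(lv, label) {
  stopifnot(inherits(lv, "label_volume"))
  mask <- label_mask(lv, label)
  if (!any(mask)) stop("empty-region error: label has no voxels")
  crofton_area_mm2(mask, lv$voxel_size_um)
}

#' Mean hull thickness in um
#'
#' Twice the mean of the Euclidean distance transform of the hull mask
#' sampled on its medial voxels (26-neighbourhood local maxima of the
#' transform), times the voxel size.
#'
#' @param lv a [label_volume].
#' @return Mean thickness in um.
#' @export
hull_mean_thickness <- function(lv) {
  stopifnot(inherits(lv, "label_volume"))
  mask <- label_mask(lv, "HULL")
  if (!any(mask)) stop("empty-region error: no hull voxels")
  # embed with a 1-voxel background pad so hulls touching the array edge
  # still see background on all sides
  d <- dim(mask)
  padded <- array(FALSE, d + 2L)
  padded[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- mask
  edt <- sqrt(.cpp_edt3d_sq(padded, dim(padded)))
  medial <- .cpp_local_maxima3d(edt, dim(padded))
  2 * mean(edt[medial]) * lv$voxel_size_um
}

#' Compute the fifteen structural traits of a grain
#'
#' Whole-grain (K) quantities are computed on the union of the four tissue
#' masks, so `K-Volume` is exactly the sum of the tissue volumes and the
#' four ratios sum to exactly 1.
#'
#' @param lv a [label_volume]; all four tissues must be present.
#' @param line_id,grain_id optional identifiers stored in the output.
#' @return One-row data.frame of class `grain_traits` with columns
#'   `line_id`, `grain_id` and [TRAIT_COLUMNS].
#' @export
compute_traits <- function(lv, line_id = NA_character_, grain_id = NA_character_) {
  stopifnot(inherits(lv, "label_volume"))
  counts <- vapply(.TISSUES, function(t) sum(label_mask(lv, t)), numeric(1))
  if (any(counts == 0))
    stop("incomplete-segmentation error: missing tissue(s): ",
         paste(names(counts)[counts == 0], collapse = ", "))
  s_mm <- lv$voxel_size_um * 1e-3
  vols <- counts * s_mm^3
  k_vol <- sum(vols)
  union_mask <- lv$labels != TISSUE_LABELS[["BACKGROUND"]]
  areas <- vapply(.TISSUES, function(t) region_surface_area(lv, t), numeric(1))
  k_area <- crofton_area_mm2(union_mask, lv$voxel_size_um)
  hat <- hull_mean_thickness(lv)
  ratios <- vols / k_vol
  df <- data.frame(line_id = line_id, grain_id = grain_id,
                   k_vol, vols[["EMBRYO"]], vols[["ENDOSPERM"]],
                   vols[["CAVITY"]], vols[["HULL"]],
                   k_area, areas[["EMBRYO"]], areas[["ENDOSPERM"]],
                   areas[["CAVITY"]], areas[["HULL"]],
                   hat, ratios[["EMBRYO"]], ratios[["ENDOSPERM"]],
                   ratios[["CAVITY"]], ratios[["HULL"]],
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("line_id", "grain_id", TRAIT_COLUMNS)
  class(df) <- c("grain_traits", class(df))
  df
}

#' @export
print.grain_traits <- function(x, ...) {
  cat("<grain_traits>\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
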