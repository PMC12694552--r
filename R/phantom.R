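# Synthetic grain phantoms: nested ellipsoidal solids mimicking the four-part
# anatomy of a foxtail-millet grain (hull shell, air cavity, endosperm, and an
# embryo modelled as a polar cap of the caryopsis), with per-tissue mean
# intensities plus optional Gaussian noise. Ground-truth labels come for free.

#' Phantom specification
#'
#' Geometry and intensity model for a synthetic grain CT stack. Defaults
#' approximate a millet grain of ~3 mm^3 with an ~39 um hull and an
#' ~58 um caryopsis-hull air gap, an embryo occupying 22% of the long
#' axis from one pole, and 16-bit intensities ordered
#' background/cavity (air, darkest) < hull < endosperm < embryo.
#'
#' @param grain_semi_axes_um outer hull ellipsoid semi-axes (z, y, x) in um.
#' @param hull_thickness_um hull shell thickness (um); must be smaller than
#'   the smallest semi-axis.
#' @param cavity_gap_um air gap between hull inner wall and caryopsis (um).
#' @param embryo_fraction fraction of the caryopsis long (z) axis, measured
#'   from the +z pole, occupied by the embryo cap; in (0, 1).
#' @param tissue_mean_intensities named vector of mean intensities for
#'   BACKGROUND, EMBRYO, ENDOSPERM, CAVITY, HULL. The four tissue means must
#'   be pairwise distinct and cavity (air) darker than every solid tissue.
#' @param noise_sd additive Gaussian noise SD (intensity units), clipped to
#'   the bit range.
#' @param voxel_size_um isotropic voxel edge (um).
#' @param margin_vox background margin around the grain, in voxels.
#' @param seed integer RNG seed; phantoms are pure functions of (spec, seed).
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(grain_semi_axes_um = c(1100, 800, 700),
                         hull_thickness_um = 39,
                         cavity_gap_um = 58,
                         embryo_fraction = 0.22,
                         tissue_mean_intensities = c(
                           BACKGROUND = 3000, CAVITY = 3500, HULL = 26000,
                           ENDOSPERM = 39000, EMBRYO = 52000),
                         noise_sd = 0,
                         voxel_size_um = 10,
                         margin_vox = 5,
                         seed = 1L) {
  stopifnot(length(grain_semi_axes_um) == 3, all(grain_semi_axes_um > 0))
  if (hull_thickness_um <= 0 || hull_thickness_um >= min(grain_semi_axes_um))
    stop("hull_thickness_um must be positive and smaller than the smallest semi-axis")
  if (cavity_gap_um < 0) stop("cavity_gap_um must be non-negative")
  if (embryo_fraction <= 0 || embryo_fraction >= 1)
    stop("embryo_fraction must lie in (0, 1)")
  need <- names(TISSUE_LABELS)
  if (!all(need %in% names(tissue_mean_intensities)))
    stop("tissue_mean_intensities must name all of: ", paste(need, collapse = ", "))
  tiss <- tissue_mean_intensities[.TISSUES]
  if (anyDuplicated(tiss)) stop("tissue mean intensities must be pairwise distinct")
  solid <- tissue_mean_intensities[c("EMBRYO", "ENDOSPERM", "HULL")]
  if (any(tissue_mean_intensities[["CAVITY"]] >= solid))
    stop("cavity (air) must be darker than every solid tissue")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (voxel_size_um <= 0) stop("voxel_size_um must be positive")
  structure(list(
    grain_semi_axes_um = as.numeric(grain_semi_axes_um),
    hull_thickness_um = hull_thickness_um,
    cavity_gap_um = cavity_gap_um,
    embryo_fraction = embryo_fraction,
    tissue_mean_intensities = tissue_mean_intensities,
    noise_sd = noise_sd,
    voxel_size_um = voxel_size_um,
    margin_vox = margin_vox,
    seed = as.integer(seed)
  ), class = "phantom_spec")
}

# run code with a local, restored RNG state so generators are pure in (spec, seed)
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic grain CT stack with ground-truth labels
#'
#' Nested solids: the hull is an outer ellipsoidal shell of the stated
#' thickness, the cavity a shell of the stated gap inside it, and the inner
#' caryopsis ellipsoid is split into an embryo polar cap (at the +z pole,
#' covering `embryo_fraction` of the long axis) and endosperm. Intensities
#' are the tissue means plus seeded Gaussian noise, clipped to the 16-bit
#' range.
#'
#' @param spec a [phantom_spec()].
#' @return `list(volume = voxel_volume, labels = label_volume)`.
#' @export
make_grain_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  s <- spec$grain_semi_axes_um
  vox <- spec$voxel_size_um
  dims <- 2L * (as.integer(ceiling(s / vox)) + spec$margin_vox)
  centre <- (dims + 1) / 2                      # voxel index of the centre
  coord <- function(n, c0) (seq_len(n) - c0) * vox
  z <- coord(dims[1], centre[1]); y <- coord(dims[2], centre[2]); x <- coord(dims[3], centre[3])

  rho2 <- function(semi) {
    az2 <- (z / semi[1])^2; ay2 <- (y / semi[2])^2; ax2 <- (x / semi[3])^2
    outer(outer(az2, ay2, `+`), ax2, `+`)
  }
  s_hull_in <- s - spec$hull_thickness_um
  s_cary <- s_hull_in - spec$cavity_gap_um
  if (any(s_cary <= vox))
    stop("degenerate geometry: caryopsis vanishes at this voxel size")

  labels <- array(TISSUE_LABELS[["BACKGROUND"]], dim = dims)
  in_grain <- rho2(s) <= 1
  in_hull_in <- rho2(s_hull_in) <= 1
  in_cary <- rho2(s_cary) <= 1
  labels[in_grain] <- TISSUE_LABELS[["HULL"]]
  labels[in_hull_in] <- TISSUE_LABELS[["CAVITY"]]
  labels[in_cary] <- TISSUE_LABELS[["ENDOSPERM"]]
  # embryo: polar cap of the caryopsis beyond z = a_z * (1 - 2 f)
  zcut <- s_cary[1] * (1 - 2 * spec$embryo_fraction)
  cap <- in_cary & (slice_index(dims, 1L) - centre[1]) * vox > zcut
  labels[cap] <- TISSUE_LABELS[["EMBRYO"]]

  counts <- tabulate(labels + 1L, nbins = 5L)
  if (any(counts[TISSUE_LABELS[.TISSUES] + 1L] == 0L))
    stop("degenerate geometry: tissue(s) empty at this voxel size: ",
         paste(.TISSUES[counts[TISSUE_LABELS[.TISSUES] + 1L] == 0L], collapse = ", "))

  means <- spec$tissue_mean_intensities[names(TISSUE_LABELS)]
  vol <- array(means[labels + 1L], dim = dims)
  if (spec$noise_sd > 0) {
    vol <- with_seed(spec$seed, vol + stats::rnorm(length(vol), 0, spec$noise_sd))
  }
  vol <- round(pmin(pmax(vol, 0), 65535))
  list(volume = voxel_volume(vol, vox, bit_depth = 16L),
       labels = label_volume(labels, vox))
}

# array of the index along one axis (1 = z, 2 = y, 3 = x)
slice_index <- function(dims, axis) {
  switch(axis,
         array(rep(seq_len(dims[1]), times = dims[2] * dims[3]), dim = dims),
         aperm(array(rep(seq_len(dims[2]), times = dims[1] * dims[3]),
                     dim = dims[c(2, 1, 3)]), c(2, 1, 3)),
         aperm(array(rep(seq_len(dims[3]), times = dims[1] * dims[2]),
                     dim = dims[c(3, 1, 2)]), c(2, 3, 1)))
}

#' Generate a cohort of phantoms with between-grain size variation
#'
#' Per grain, the overall grain volume is scaled by a lognormal factor with
#' coefficient of variation `variation_cv` (applied to the semi-axes as its
#' cube root, so the K-Volume CV matches `variation_cv`); hull thickness and
#' cavity gap receive independent lognormal factors of the same CV.
#' Ground-truth traits are computed from the label volumes by exact voxel
#' accounting ([compute_traits()]).
#'
#' @param base a [phantom_spec()] giving the population mean geometry.
#' @param n number of grains.
#' @param variation_cv lognormal coefficient of variation (>= 0).
#' @param seed integer seed.
#' @param max_retries resampling attempts per grain when a drawn geometry is
#'   degenerate.
#' @return List of `n` elements, each `list(volume, labels, truth)` where
#'   `truth` is a one-row [compute_traits()] data.frame.
#' @export
make_phantom_cohort <- function(base, n, variation_cv = 0.10, seed = 1L,
                                max_retries = 5L) {
  stopifnot(inherits(base, "phantom_spec"), n >= 1, variation_cv >= 0)
  sdlog <- sqrt(log(1 + variation_cv^2))
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      for (attempt in seq_len(max_retries)) {
        f <- if (variation_cv > 0) stats::rlnorm(3, -sdlog^2 / 2, sdlog) else c(1, 1, 1)
        spec_i <- base
        spec_i$grain_semi_axes_um <- base$grain_semi_axes_um * f[1]^(1 / 3)
        spec_i$hull_thickness_um <- base$hull_thickness_um * f[2]
        spec_i$cavity_gap_um <- base$cavity_gap_um * f[3]
        spec_i$seed <- base$seed + i
        ph <- tryCatch(make_grain_phantom(spec_i), error = function(e) NULL)
        if (!is.null(ph)) {
          truth <- compute_traits(ph$labels)
          return(list(volume = ph$volume, labels = ph$labels, truth = truth))
        }
      }
      stop("could not draw a valid geometry for grain ", i,
           " after ", max_retries, " attempts")
    })
  })
}
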