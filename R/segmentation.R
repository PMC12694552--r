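# Segmentation chain: global Otsu thresholding, per-slice Canny edges,
# deterministic 3D region growing behind the edge barriers, rule-based
# tissue assignment, and manual-override refinement.

#' Segmentation parameters
#'
#' @param histogram_bins bins for the Otsu histogram (>= 2).
#' @param canny_sigma_vox Gaussian smoothing SD (voxels) inside the Canny
#'   detector.
#' @param canny_low_frac,canny_high_frac hysteresis thresholds as fractions
#'   of the maximum gradient magnitude, `0 < low < high < 1`.
#' @param growth_tolerance maximum `|intensity - region running mean|` for a
#'   voxel to join a region; `NULL` resolves to 5% of the volume's dynamic
#'   range at run time.
#' @param connectivity 6 (face) or 26 (face-edge-vertex) for 3D growth.
#' @param min_region_vox regions smaller than this are merged into the
#'   neighbouring region of nearest mean intensity (default 27, a 3^3
#'   speckle).
#' @param smooth_sigma_vox SD (voxels) of the Gaussian pre-smoothing applied
#'   before thresholding/growing inside [segment_grain()]; 0 disables.
#' @param sharpen_iters boundary-sharpening passes after tissue assignment
#'   (interface voxels reassigned by nearest class mean on the unsmoothed
#'   intensities); 0 disables.
#' @return A `segmentation_params` object.
#' @export
segmentation_params <- function(histogram_bins = 256,
                                canny_sigma_vox = 1.4,
                                canny_low_frac = 0.10,
                                canny_high_frac = 0.20,
                                growth_tolerance = NULL,
                                connectivity = 26,
                                min_region_vox = 27,
                                smooth_sigma_vox = 1.0,
                                sharpen_iters = 2) {
  stopifnot(histogram_bins >= 2, canny_sigma_vox > 0,
            canny_low_frac > 0, canny_high_frac < 1,
            canny_low_frac < canny_high_frac,
            connectivity %in% c(6, 26), min_region_vox >= 1,
            smooth_sigma_vox >= 0, sharpen_iters >= 0)
  if (!is.null(growth_tolerance)) stopifnot(growth_tolerance >= 0)
  structure(list(histogram_bins = histogram_bins,
                 canny_sigma_vox = canny_sigma_vox,
                 canny_low_frac = canny_low_frac,
                 canny_high_frac = canny_high_frac,
                 growth_tolerance = growth_tolerance,
                 connectivity = as.integer(connectivity),
                 min_region_vox = as.integer(min_region_vox),
                 smooth_sigma_vox = smooth_sigma_vox,
                 sharpen_iters = as.integer(sharpen_iters)),
            class = "segmentation_params")
}

#' Tissue assignment rule
#'
#' @param ordering the four tissue names in ascending order of mean
#'   intensity; the default reflects air (cavity) being darkest and the
#'   dense embryo brightest.
#' @param topology_checks enforce that only the hull may touch the outer
#'   background, reassigning violating regions.
#' @return A `tissue_rule` object.
#' @export
tissue_rule <- function(ordering = c("CAVITY", "HULL", "ENDOSPERM", "EMBRYO"),
                        topology_checks = TRUE) {
  if (!identical(sort(ordering), sort(.TISSUES)))
    stop("ordering must be a permutation of ", paste(.TISSUES, collapse = ", "))
  structure(list(ordering = ordering, topology_checks = isTRUE(topology_checks)),
            class = "tissue_rule")
}

as_intensity_array <- function(volume) {
  if (inherits(volume, "voxel_volume")) volume$data else volume
}

#' Otsu's automatic threshold
#'
#' Exhaustively maximizes the between-class variance
#' `sigma_b^2(t) = w0 w1 (mu0 - mu1)^2` over candidate thresholds; ties are
#' broken toward the lowest threshold. Voxels `<= t` form class 0. When the
#' data take at most `bins` distinct integer levels the histogram is exact
#' (thresholds are the levels themselves); otherwise `bins` equal-width bins
#' are used and bin upper edges are the candidates.
#'
#' @param volume a [voxel_volume], array, or numeric vector.
#' @param bins number of histogram bins.
#' @return The threshold (numeric scalar).
#' @export
otsu_threshold <- function(volume, bins = 256) {
  v <- as.numeric(as_intensity_array(volume))
  stopifnot(bins >= 2)
  lo <- min(v); hi <- max(v)
  if (lo == hi) stop("no-contrast error: volume is constant")
  integral <- all(v == round(v)) && (hi - lo + 1) <= bins
  if (integral) {
    levels <- lo:hi
    counts <- tabulate(v - lo + 1L, nbins = length(levels))
    cand <- levels[-length(levels)]
  } else {
    width <- (hi - lo) / bins
    bin <- pmin(pmax(ceiling((v - lo) / width), 1L), bins)
    counts <- tabulate(bin, nbins = bins)
    levels <- lo + (seq_len(bins) - 0.5) * width     # bin midpoints
    cand <- lo + seq_len(bins - 1) * width           # upper edges of bins 1..bins-1
  }
  n <- sum(counts)
  w0 <- cumsum(counts)[-length(counts)] / n
  w1 <- 1 - w0
  csum <- cumsum(counts * levels)[-length(counts)]
  mu <- sum(counts * levels) / n
  mu0 <- ifelse(w0 > 0, csum / (n * w0), 0)
  mu1 <- ifelse(w1 > 0, (mu - w0 * mu0) / w1, 0)
  sigma_b <- w0 * w1 * (mu0 - mu1)^2
  sigma_b[w0 == 0 | w1 == 0] <- -Inf
  cand[which.max(sigma_b)]                            # which.max takes first tie
}

# shift a 3D array by (dz, dy, dx), filling exposed planes with the original
# values (so out-of-range neighbours are no-ops for candidate comparisons)
shift_arr3 <- function(a, dz, dy, dx) {
  d <- dim(a)
  out <- a
  zs <- max(1, 1 + dz):min(d[1], d[1] + dz)
  ys <- max(1, 1 + dy):min(d[2], d[2] + dy)
  xs <- max(1, 1 + dx):min(d[3], d[3] + dx)
  out[zs, ys, xs] <- a[zs - dz, ys - dy, xs - dx]
  out
}

# boundary sharpening: reassign voxels at label interfaces to the 6-adjacent
# class whose mean (on the supplied intensity volume) is nearest; a few
# Jacobi passes undo the boundary blur introduced by pre-smoothing
sharpen_boundaries <- function(lv, raw, iters = 2) {
  labels <- lv$labels
  for (it in seq_len(iters)) {
    present <- sort(unique(as.vector(labels)))
    means <- vapply(present, function(code) mean(raw[labels == code]), numeric(1))
    cost <- abs(raw - means[match(labels, present)])
    best_lab <- labels
    for (sh in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                    c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))) {
      nb <- shift_arr3(labels, sh[1], sh[2], sh[3])
      cost_nb <- abs(raw - means[match(nb, present)])
      upd <- cost_nb < cost
      best_lab[upd] <- nb[upd]
      cost[upd] <- cost_nb[upd]
    }
    if (all(best_lab == labels)) break
    labels <- best_lab
  }
  label_volume(labels, lv$voxel_size_um)
}

# central-difference 3D gradient magnitude (one-sided at the array faces)
gradient_magnitude3d <- function(a) {
  d <- dim(a)
  g2 <- array(0, d)
  for (ax in 1:3) {
    if (d[ax] < 2) next
    df <- array(0, d)
    lo <- 2:(d[ax] - 1)
    if (d[ax] > 2) {
      if (ax == 1) df[lo, , ] <- (a[lo + 1, , ] - a[lo - 1, , ]) / 2
      if (ax == 2) df[, lo, ] <- (a[, lo + 1, ] - a[, lo - 1, ]) / 2
      if (ax == 3) df[, , lo] <- (a[, , lo + 1] - a[, , lo - 1]) / 2
    }
    if (ax == 1) { df[1, , ] <- a[2, , ] - a[1, , ]; df[d[1], , ] <- a[d[1], , ] - a[d[1] - 1, , ] }
    if (ax == 2) { df[, 1, ] <- a[, 2, ] - a[, 1, ]; df[, d[2], ] <- a[, d[2], ] - a[, d[2] - 1, ] }
    if (ax == 3) { df[, , 1] <- a[, , 2] - a[, , 1]; df[, , d[3]] <- a[, , d[3]] - a[, , d[3] - 1] }
    g2 <- g2 + df^2
  }
  sqrt(g2)
}

shift_mat <- function(m, dr, dc, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc, drop = FALSE]
  out
}

#' Canny edge detection on a 2D slice
#'
#' The standard four stages: Gaussian smoothing, Sobel gradients,
#' non-maximum suppression perpendicular to the edge, and double-threshold
#' hysteresis (weak edges kept only when 8-connected to a strong edge).
#' Thresholds are fractions of the maximum gradient magnitude, so the
#' output is invariant to a global intensity offset.
#'
#' @param slice 2D numeric matrix.
#' @param params a [segmentation_params()].
#' @return Logical matrix of edge pixels, same shape as `slice`.
#' @export
canny_edges <- function(slice, params = segmentation_params()) {
  stopifnot(is.matrix(slice))
  slice <- slice - min(slice)          # exact invariance to intensity offsets
  nr <- nrow(slice); nc <- ncol(slice)
  sm <- .cpp_gaussian_blur3d(as.double(array(slice, c(1, nr, nc))),
                             c(1L, nr, nc), 0, params$canny_sigma_vox,
                             params$canny_sigma_vox)
  sm <- matrix(sm, nr, nc)
  # Sobel gradients: gy along rows, gx along columns
  sob <- function(m, kr, kc) {
    acc <- matrix(0, nr, nc)
    for (i in 1:3) for (j in 1:3) {
      w <- kr[i] * kc[j]
      if (w != 0) acc <- acc + w * shift_mat(m, i - 2, j - 2, fill = 0)
    }
    acc
  }
  # replicate-pad borders by clamping the shifts: cheaper to just zero the 1-px frame later
  gx <- sob(sm, c(1, 2, 1), c(-1, 0, 1))
  gy <- sob(sm, c(-1, 0, 1), c(1, 2, 1))
  mag <- sqrt(gx^2 + gy^2)
  mag[c(1, nr), ] <- 0; mag[, c(1, nc)] <- 0
  if (max(mag) == 0) return(matrix(FALSE, nr, nc))
  ang <- (atan2(gy, gx) * 180 / pi) %% 180
  bin <- ifelse(ang < 22.5 | ang >= 157.5, 0L,
                ifelse(ang < 67.5, 45L, ifelse(ang < 112.5, 90L, 135L)))
  nms <- matrix(FALSE, nr, nc)
  pairs <- list(`0` = list(c(0, 1), c(0, -1)),
                `45` = list(c(1, 1), c(-1, -1)),
                `90` = list(c(1, 0), c(-1, 0)),
                `135` = list(c(-1, 1), c(1, -1)))
  for (b in c(0L, 45L, 90L, 135L)) {
    off <- pairs[[as.character(b)]]
    n1 <- shift_mat(mag, off[[1]][1], off[[1]][2])
    n2 <- shift_mat(mag, off[[2]][1], off[[2]][2])
    nms <- nms | (bin == b & mag >= n1 & mag > n2)
  }
  keep_mag <- ifelse(nms, mag, 0)
  low <- params$canny_low_frac * max(mag)
  high <- params$canny_high_frac * max(mag)
  weak <- keep_mag >= low
  strong <- keep_mag >= high
  matrix(.cpp_hysteresis2d(weak, strong, nr, nc), nr, nc)
}

#' Deterministic seeded region growing
#'
#' Seeds are non-barrier voxels visited in lexicographic `(z, y, x)` order;
#' a voxel joins the current region when connected, non-barrier, and within
#' `growth_tolerance` of the region's running mean intensity. Barrier
#' voxels and fragments smaller than `min_region_vox` are then merged into
#' the adjacent region with nearest mean intensity. The result is a total
#' partition into integer region ids (1-based, numbered in scan order).
#'
#' @param volume a [voxel_volume] or 3D numeric array.
#' @param barrier_mask 3D logical array of voxels no region may cross.
#' @param params a [segmentation_params()].
#' @return Integer 3D array of region ids.
#' @export
region_grow <- function(volume, barrier_mask, params = segmentation_params()) {
  v <- as_intensity_array(volume)
  stopifnot(identical(dim(v), dim(barrier_mask)))
  tol <- params$growth_tolerance
  if (is.null(tol)) tol <- 0.05 * (max(v) - min(v))
  .cpp_region_grow(as.double(v), as.logical(barrier_mask), dim(v),
                   tol, params$connectivity, params$min_region_vox)
}

# deterministic 1D Lloyd k-means with observation weights; centres are
# initialized at the k largest-weight distinct values so that the dominant
# regions anchor the tissue intensity bands
weighted_kmeans1d <- function(x, w, k, iter_max = 100) {
  ord <- order(-w, x)
  # anchor centres at the k largest-weight values that are mutually separated
  # in intensity (12% of the spread); interface remnants lie between tissue
  # bands and must not displace a genuine band's anchor
  sep <- 0.12 * (max(x) - min(x))
  centers <- numeric(0)
  for (i in ord) {
    if (all(abs(x[i] - centers) >= sep)) centers <- c(centers, x[i])
    if (length(centers) == k) break
  }
  if (length(centers) < k) {
    for (i in ord) {
      if (!any(abs(x[i] - centers) < 1e-12)) centers <- c(centers, x[i])
      if (length(centers) == k) break
    }
  }
  if (length(centers) < k) stop("fewer than ", k, " distinct values")
  centers <- sort(centers)
  for (it in seq_len(iter_max)) {
    cl <- max.col(-abs(outer(x, centers, `-`)), ties.method = "first")
    new_centers <- vapply(seq_len(k), function(j) {
      sel <- cl == j
      if (any(sel)) sum(x[sel] * w[sel]) / sum(w[sel]) else centers[j]
    }, numeric(1))
    new_centers <- sort(new_centers)
    if (max(abs(new_centers - centers)) < 1e-9) { centers <- new_centers; break }
    centers <- new_centers
  }
  cl <- max.col(-abs(outer(x, centers, `-`)), ties.method = "first")
  list(cluster = cl, centers = centers)
}

region_stats <- function(regions, v) {
  sizes <- tabulate(regions)
  sums <- as.vector(rowsum(as.double(v), as.vector(regions)))
  list(ids = seq_along(sizes), sizes = sizes, means = sums / sizes)
}

face_region_ids <- function(regions) {
  d <- dim(regions)
  unique(c(regions[c(1, d[1]), , ], regions[, c(1, d[2]), ], regions[, , c(1, d[3])]))
}

# region ids 6-adjacent to any voxel of `mask`
ids_adjacent_to_mask <- function(regions, mask) {
  d <- dim(regions)
  ids <- integer(0)
  if (d[1] > 1) {
    ids <- c(ids, regions[-d[1], , ][mask[-1, , ]], regions[-1, , ][mask[-d[1], , ]])
  }
  if (d[2] > 1) {
    ids <- c(ids, regions[, -d[2], ][mask[, -1, ]], regions[, -1, ][mask[, -d[2], ]])
  }
  if (d[3] > 1) {
    ids <- c(ids, regions[, , -d[3]][mask[, , -1]], regions[, , -1][mask[, , -d[3]]])
  }
  unique(ids)
}

#' Assign tissue classes to grown regions
#'
#' Background is the set of regions touching the stack's outer faces with
#' mean intensity at or below the global Otsu threshold. The remaining
#' regions are pooled into the four tissue classes by rank of region mean
#' intensity according to `rule$ordering` (k-means pooling when there are
#' more than four regions), then topology is enforced: only the hull may
#' border the outer background; violating regions are reassigned.
#'
#' @param regions integer 3D array from [region_grow()].
#' @param volume the intensity volume the regions were grown on.
#' @param rule a [tissue_rule()].
#' @param bins histogram bins for the Otsu threshold.
#' @return A [label_volume].
#' @export
assign_tissues <- function(regions, volume, rule = tissue_rule(), bins = 256) {
  v <- as_intensity_array(volume)
  vox <- if (inherits(volume, "voxel_volume")) volume$voxel_size_um else 1
  stopifnot(identical(dim(v), dim(regions)))
  st <- region_stats(regions, v)
  thr <- otsu_threshold(v, bins)
  face_ids <- face_region_ids(regions)
  bg <- intersect(face_ids, st$ids[st$means <= thr])
  tissue_ids <- setdiff(st$ids, bg)
  if (length(tissue_ids) < 4)
    stop("under-segmentation error: only ", length(tissue_ids),
         " non-background region(s); lower growth_tolerance or min_region_vox")
  m <- st$means[tissue_ids]
  if (length(tissue_ids) == 4) {
    cl <- rank(m, ties.method = "first")
    centers <- sort(m)
  } else {
    if (length(unique(m)) < 4)
      stop("under-segmentation error: fewer than 4 distinct region intensities")
    km <- weighted_kmeans1d(m, st$sizes[tissue_ids], k = 4)
    cl <- km$cluster
    centers <- km$centers
  }
  tissue_of_rank <- rule$ordering                          # rank 1 = darkest
  region_label <- integer(max(st$ids))
  region_label[bg] <- TISSUE_LABELS[["BACKGROUND"]]
  region_label[tissue_ids] <- TISSUE_LABELS[tissue_of_rank[cl]]

  if (rule$topology_checks && length(bg) > 0) {
    bg_mask <- array(regions %in% bg, dim = dim(regions))
    border_ids <- unique(c(ids_adjacent_to_mask(regions, bg_mask), face_ids))
    border_ids <- setdiff(border_ids, bg)
    hull_code <- TISSUE_LABELS[["HULL"]]
    inner_codes <- TISSUE_LABELS[c("EMBRYO", "ENDOSPERM", "CAVITY")]
    # inner-class regions touching background become hull
    offending <- intersect(border_ids, tissue_ids[region_label[tissue_ids] %in% inner_codes])
    region_label[offending] <- hull_code
    # hull regions nowhere near background become the nearest-mean inner class
    landlocked <- setdiff(tissue_ids[region_label[tissue_ids] == hull_code], border_ids)
    if (length(landlocked)) {
      rank_of <- match(c("EMBRYO", "ENDOSPERM", "CAVITY"), tissue_of_rank)
      for (rid in landlocked) {
        d <- abs(st$means[rid] - centers[rank_of])
        region_label[rid] <- inner_codes[which.min(d)]
      }
    }
  }
  labels <- array(region_label[regions], dim = dim(regions))
  label_volume(labels, vox)
}

#' Refine labels with manual intensity-range overrides
#'
#' Each override reassigns voxels currently holding `from` whose intensity
#' lies in `range` (inclusive) to `to`; overrides apply in list order and
#' re-application is idempotent.
#'
#' @param lv a [label_volume].
#' @param volume the intensity volume (same shape).
#' @param overrides list of `list(range = c(lo, hi), from = , to = )` with
#'   tissue names from [TISSUE_LABELS].
#' @return The refined [label_volume].
#' @export
refine_labels <- function(lv, volume, overrides = list()) {
  stopifnot(inherits(lv, "label_volume"))
  v <- as_intensity_array(volume)
  if (length(overrides) == 0) return(lv)
  for (ov in overrides) {
    stopifnot(length(ov$range) == 2, ov$range[1] <= ov$range[2],
              ov$from %in% names(TISSUE_LABELS), ov$to %in% names(TISSUE_LABELS))
  }
  # contradictory overrides: same source label, overlapping ranges, different targets
  if (length(overrides) > 1) {
    for (i in seq_along(overrides)) for (j in seq_along(overrides)) {
      if (j <= i) next
      a <- overrides[[i]]; b <- overrides[[j]]
      if (identical(a$from, b$from) && !identical(a$to, b$to) &&
          a$range[1] <= b$range[2] && b$range[1] <= a$range[2])
        stop("ambiguity error: overlapping contradictory overrides for ", a$from)
    }
  }
  labels <- lv$labels
  for (ov in overrides) {
    sel <- labels == TISSUE_LABELS[[ov$from]] & v >= ov$range[1] & v <= ov$range[2]
    labels[sel] <- TISSUE_LABELS[[ov$to]]
  }
  label_volume(labels, lv$voxel_size_um)
}

#' Segment a grain CT volume into the five-class tissue partition
#'
#' Composition of the whole chain: Gaussian pre-smoothing, global Otsu
#' threshold, per-slice Canny edge barriers, 3D region growing,
#' rule-based tissue assignment, and override refinement. Deterministic.
#'
#' @param volume a [voxel_volume].
#' @param params a [segmentation_params()].
#' @param rule a [tissue_rule()].
#' @param overrides optional list for [refine_labels()].
#' @return A [label_volume].
#' @export
segment_grain <- function(volume, params = segmentation_params(),
                          rule = tissue_rule(), overrides = list()) {
  stopifnot(inherits(volume, "voxel_volume"))
  v <- as.double(volume$data)
  dim(v) <- dim(volume$data)
  s <- params$smooth_sigma_vox
  sm <- if (s > 0) {
    array(.cpp_gaussian_blur3d(v, dim(v), s, s, s), dim(v))
  } else v
  d <- dim(sm)
  barrier <- array(FALSE, d)
  for (i in seq_len(d[1])) {
    sl <- matrix(sm[i, , ], d[2], d[3])
    barrier[i, , ] <- canny_edges(sl, params)
  }
  # widen the barrier to the full 3D gradient ramp around each interface:
  # ramp voxels are then absorbed voxel-by-voxel into the region of nearest
  # mean, which places the boundary at the intensity midpoint
  gm <- gradient_magnitude3d(sm)
  barrier <- barrier | (gm >= params$canny_low_frac * max(gm))
  regions <- region_grow(sm, barrier, params)
  lv <- assign_tissues(regions, voxel_volume(pmax(sm, 0), volume$voxel_size_um,
                                             bit_depth = volume$bit_depth),
                       rule, params$histogram_bins)
  if (params$sharpen_iters > 0)
    lv <- sharpen_boundaries(lv, v, params$sharpen_iters)
  refine_labels(lv, volume$data, overrides)
}
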