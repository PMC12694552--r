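test_that("otsu threshold separates a perfectly bimodal volume", {
  v <- array(c(rep(50, 1000), rep(200, 1000)), c(10, 10, 20))
  t <- otsu_threshold(v)
  expect_gte(t, 50); expect_lt(t, 200)
  expect_true(all((v <= t) == (v == 50)))
  expect_error(otsu_threshold(array(7, c(3, 3, 3))), "no-contrast")
})

test_that("otsu equals the exhaustive between-class-variance oracle", {
  # the 8-level toy histogram
  counts <- c(8, 7, 2, 1, 1, 2, 7, 8)
  v <- hist_to_values(counts, 0:7)
  expect_identical(otsu_threshold(array(v, c(1, 1, length(v))), bins = 8),
                   otsu_oracle(counts, 0:7))
  # seeded random histograms, exact integer levels
  set.seed(11)
  for (i in 1:20) {
    counts <- rpois(16, lambda = sample(3:40, 16, replace = TRUE))
    counts[counts == 0] <- 1
    v <- hist_to_values(counts, 0:15)
    expect_identical(otsu_threshold(array(v, c(1, 1, length(v))), bins = 16),
                     otsu_oracle(counts, 0:15))
  }
})

test_that("otsu respects intensity-inversion symmetry", {
  set.seed(12)
  for (i in 1:10) {
    counts <- rpois(12, 10) + 1
    v <- hist_to_values(counts, 0:11)
    t <- otsu_threshold(array(v, c(1, 1, length(v))), bins = 12)
    tm <- otsu_threshold(array(11 - v, c(1, 1, length(v))), bins = 12)
    # class 0 of the original = class 1 of the mirrored data
    expect_setequal(unique(v[v <= t]), unique(v[(11 - v) > tm]))
  }
})

test_that("otsu agrees with an independent implementation on 16-bit-like data", {
  set.seed(13)
  v <- c(round(rnorm(4000, 80, 12)), round(rnorm(4000, 170, 15)))
  v <- pmin(pmax(v, 0), 255)
  t_pkg <- otsu_threshold(array(v, c(20, 20, 20)), bins = 256)
  t_ref <- EBImage::otsu(EBImage::Image(v / 255, dim = c(80, 100)),
                         range = c(0, 1), levels = 256) * 255
  expect_lt(abs(t_pkg - t_ref), 2)
})

test_that("canny finds a step edge and is offset invariant", {
  sl <- matrix(0, 32, 32); sl[, 17:32] <- 100
  e <- canny_edges(sl, segmentation_params())
  cols <- unique(which(e, arr.ind = TRUE)[, 2])
  expect_true(all(abs(cols - 16.5) <= 1.5))       # within 1 px of the step
  rowsums <- rowSums(e[2:31, , drop = FALSE])
  expect_true(all(rowsums >= 1 & rowsums <= 2))   # ~one-pixel-wide line
  expect_identical(e, canny_edges(sl + 1234, segmentation_params()))
  expect_false(any(canny_edges(matrix(5, 16, 16), segmentation_params())))
})

test_that("region growing partitions blocks split by a barrier plane", {
  v <- array(10, c(5, 5, 11)); v[, , 7:11] <- 200
  barrier <- array(FALSE, dim(v)); barrier[, , 6] <- TRUE
  p <- segmentation_params(growth_tolerance = 5, min_region_vox = 1)
  r <- region_grow(v, barrier, p)
  expect_identical(sort(unique(as.vector(r))), c(1L, 2L))
  expect_true(all(r[, , 1:5] == 1))
  expect_true(all(r[, , 7:11] == 2))
  # barrier voxels merged to nearest-mean side: value 10 plane joins block 1
  expect_true(all(r[, , 6] == 1))

  u <- array(42, c(4, 4, 4))
  r1 <- region_grow(u, array(FALSE, dim(u)), p)
  expect_true(all(r1 == 1))
  expect_error(region_grow(u, array(TRUE, dim(u)), p), "barrier")
})

test_that("region count is non-increasing in growth tolerance", {
  set.seed(14)
  for (trial in 1:20) {
    v <- array(sample(0:9, 6^3, replace = TRUE), c(6, 6, 6))
    counts <- vapply(c(0, 1, 2, 4, 9), function(tol) {
      p <- segmentation_params(growth_tolerance = tol, min_region_vox = 1,
                               connectivity = 6)
      max(region_grow(v, array(FALSE, dim(v)), p))
    }, numeric(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("tissue assignment matches phantom truth outside a 1-voxel band", {
  ph <- make_grain_phantom(small_grain_spec())
  lv <- segment_grain(ph$volume)
  truth <- ph$labels$labels
  # boundary band: voxels with a 6-neighbour of a different true label
  band <- array(FALSE, dim(truth))
  d <- dim(truth)
  band[-d[1], , ] <- band[-d[1], , ] | (truth[-d[1], , ] != truth[-1, , ])
  band[-1, , ] <- band[-1, , ] | (truth[-d[1], , ] != truth[-1, , ])
  band[, -d[2], ] <- band[, -d[2], ] | (truth[, -d[2], ] != truth[, -1, ])
  band[, -1, ] <- band[, -1, ] | (truth[, -d[2], ] != truth[, -1, ])
  band[, , -d[3]] <- band[, , -d[3]] | (truth[, , -d[3]] != truth[, , -1])
  band[, , -1] <- band[, , -1] | (truth[, , -d[3]] != truth[, , -1])
  agree <- mean(lv$labels[!band] == truth[!band])
  expect_gte(agree, 0.999)
})

test_that("relabeling symmetry: swapped intensities with a swapped rule match", {
  base <- small_grain_spec()
  dice_a <- dice_coefficient(segment_grain(make_grain_phantom(base)$volume),
                             make_grain_phantom(base)$labels)
  swapped <- small_grain_spec(tissue_mean_intensities = c(
    BACKGROUND = 3000, CAVITY = 3500, HULL = 26000,
    ENDOSPERM = 52000, EMBRYO = 39000))
  ph2 <- make_grain_phantom(swapped)
  rule2 <- tissue_rule(ordering = c("CAVITY", "HULL", "EMBRYO", "ENDOSPERM"))
  dice_b <- dice_coefficient(segment_grain(ph2$volume, rule = rule2), ph2$labels)
  expect_equal(unname(dice_a), unname(dice_b), tolerance = 0.02)
  expect_true(all(dice_b > 0.95))
})

test_that("segment_grain is deterministic and degrades with noise", {
  spec <- small_grain_spec(noise_sd = 1500, seed = 21)
  ph <- make_grain_phantom(spec)
  a <- segment_grain(ph$volume)
  b <- segment_grain(ph$volume)
  expect_identical(a$labels, b$labels)

  # doubling the noise does not improve the median per-tissue Dice
  d_lo <- d_hi <- NULL
  for (i in 1:5) {
    p1 <- make_grain_phantom(small_grain_spec(noise_sd = 1500, seed = 30 + i))
    p2 <- make_grain_phantom(small_grain_spec(noise_sd = 3000, seed = 30 + i))
    d_lo <- rbind(d_lo, dice_coefficient(segment_grain(p1$volume), p1$labels))
    d_hi <- rbind(d_hi, dice_coefficient(segment_grain(p2$volume), p2$labels))
  }
  expect_true(all(apply(d_hi, 2, median) <= apply(d_lo, 2, median) + 1e-6))
})

test_that("refine_labels applies overrides in order and is idempotent", {
  ph <- make_grain_phantom(small_grain_spec())
  lv <- ph$labels
  expect_identical(refine_labels(lv, ph$volume$data, list())$labels, lv$labels)
  full <- list(list(range = c(0, 65535), from = "ENDOSPERM", to = "EMBRYO"))
  r1 <- refine_labels(lv, ph$volume$data, full)
  expect_identical(sum(r1$labels == TISSUE_LABELS[["ENDOSPERM"]]), 0L)
  expect_identical(refine_labels(r1, ph$volume$data, full)$labels, r1$labels)
  expect_error(refine_labels(lv, ph$volume$data, list(
    list(range = c(0, 100), from = "HULL", to = "EMBRYO"),
    list(range = c(50, 200), from = "HULL", to = "CAVITY"))),
    "ambiguity")
})

test_that("under-segmentation and no-contrast inputs raise errors", {
  v <- voxel_volume(array(rep(c(0L, 100L), each = 500), c(10, 10, 10)), 3)
  barrier <- array(FALSE, dim(v$data))
  r <- region_grow(v$data, barrier, segmentation_params(growth_tolerance = 5,
                                                        min_region_vox = 1))
  expect_error(assign_tissues(r, v), "under-segmentation")
})
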