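test_that("volumes follow the closed form and absent labels give zero", {
  arr <- array(0L, c(10, 10, 10))
  arr[1:10, 1:10, 1:10][seq_len(1000)] <- TISSUE_LABELS[["HULL"]]
  lv <- label_volume(array(TISSUE_LABELS[["HULL"]], c(10, 10, 10)), 3)
  expect_equal(region_volume(lv, "HULL"), 1000 * 0.003^3)
  expect_identical(region_volume(lv, "EMBRYO"), 0)
})

test_that("digitized sphere volume and area match the analytic values", {
  lv <- sphere_label_volume(100, 3)       # r = 300 um at 3 um voxels
  vol <- region_volume(lv, "ENDOSPERM")
  expect_lt(abs(vol - 4 / 3 * pi * 0.3^3) / (4 / 3 * pi * 0.3^3), 0.02)
  area <- region_surface_area(lv, "ENDOSPERM")
  expect_lt(abs(area - 4 * pi * 0.3^2) / (4 * pi * 0.3^2), 0.03)
})

test_that("a single voxel has bounded surface area", {
  arr <- array(0L, c(5, 5, 5)); arr[3, 3, 3] <- TISSUE_LABELS[["HULL"]]
  a <- region_surface_area(label_volume(arr, 3), "HULL")
  expect_gte(a, 0.5 * 6 * 0.003^2)
  expect_lte(a, 1.5 * 6 * 0.003^2)
  expect_error(region_surface_area(label_volume(array(0L, c(3, 3, 3)), 3), "HULL"),
               "empty-region")
})

test_that("a hollow shell reports inner plus outer surface area", {
  lv <- sphere_label_volume(100, 3, code = "HULL", inner_vox = 90)
  a <- region_surface_area(lv, "HULL")
  target <- 4 * pi * (0.3^2 + 0.27^2)
  expect_lt(abs(a - target) / target, 0.03)
})

test_that("hull thickness recovers shells and slabs, and scales linearly", {
  shell <- sphere_label_volume(100, 3, code = "HULL", inner_vox = 90)
  th <- hull_mean_thickness(shell)
  expect_lt(abs(th - 30) / 30, 0.10)

  slab <- array(0L, c(20, 20, 20)); slab[8:12, , ] <- TISSUE_LABELS[["HULL"]]
  th_slab <- hull_mean_thickness(label_volume(slab, 3))
  expect_lte(abs(th_slab - 15), 3)        # within one voxel

  # doubling all geometry doubles the estimate
  shell2 <- sphere_label_volume(100, 6, code = "HULL", inner_vox = 90)
  expect_equal(hull_mean_thickness(shell2), 2 * th, tolerance = 1e-9)
})

test_that("surface and thickness errors shrink with finer voxels", {
  target <- 4 * pi * 0.3^2
  err <- vapply(c(3, 6), function(s) {
    lv <- sphere_label_volume(round(300 / s), s)
    abs(region_surface_area(lv, "ENDOSPERM") - target) / target
  }, numeric(1))
  expect_lte(err[1], err[2])
})

test_that("compute_traits matches phantom ground truth and conserves the partition", {
  ph <- make_grain_phantom(small_grain_spec())
  tr <- compute_traits(ph$labels)
  expect_equal(sum(unlist(tr[c("EM-Volume", "EN-Volume", "C-Volume", "H-Volume")])),
               tr[["K-Volume"]], tolerance = 1e-12)
  expect_lt(abs(sum(unlist(tr[c("EM-Ratio", "EN-Ratio", "C-Ratio", "H-Ratio")])) - 1),
            1e-9)
  # analytic ellipsoid volume of the whole grain
  s <- small_grain_spec()$grain_semi_axes_um * 1e-3
  vol_analytic <- 4 / 3 * pi * prod(s)
  expect_lt(abs(tr[["K-Volume"]] - vol_analytic) / vol_analytic, 0.02)

  miss <- ph$labels
  miss$labels[miss$labels == TISSUE_LABELS[["EMBRYO"]]] <- TISSUE_LABELS[["ENDOSPERM"]]
  expect_error(compute_traits(miss), "incomplete-segmentation.*EMBRYO")
})

test_that("traits are invariant to axis permutation of an isotropic volume", {
  ph <- make_grain_phantom(phantom_spec(grain_semi_axes_um = c(300, 240, 200),
                                        hull_thickness_um = 35, cavity_gap_um = 40,
                                        voxel_size_um = 10))
  tr1 <- compute_traits(ph$labels)
  lv2 <- label_volume(aperm(ph$labels$labels, c(2, 3, 1)), ph$labels$voxel_size_um)
  tr2 <- compute_traits(lv2)
  for (cn in TRAIT_COLUMNS)
    expect_equal(tr1[[cn]], tr2[[cn]], tolerance = 1e-9, label = cn)
})
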