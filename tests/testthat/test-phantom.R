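test_that("sphere phantom ground truth matches analytic nested-shell volumes", {
  ph <- make_grain_phantom(sphere_spec(voxel_size_um = 3))
  hull_mm3 <- region_volume(ph$labels, "HULL")
  analytic <- 4 / 3 * pi * (0.300^3 - 0.270^3)
  expect_lt(abs(hull_mm3 - analytic) / analytic, 0.02)
  # convergence: finer voxels give smaller relative error
  ph6 <- make_grain_phantom(sphere_spec(voxel_size_um = 6))
  err3 <- abs(region_volume(ph$labels, "HULL") - analytic) / analytic
  err6 <- abs(region_volume(ph6$labels, "HULL") - analytic) / analytic
  expect_lte(err3, err6)
})

test_that("noise-free phantom intensities equal tissue means exactly; noise is seeded", {
  spec <- small_grain_spec(noise_sd = 0)
  ph <- make_grain_phantom(spec)
  means <- spec$tissue_mean_intensities[names(TISSUE_LABELS)]
  expect_true(all(ph$volume$data == array(means[ph$labels$labels + 1L],
                                          dim(ph$labels$labels))))
  spec_n <- small_grain_spec(noise_sd = 500, seed = 9L)
  a <- make_grain_phantom(spec_n)
  b <- make_grain_phantom(spec_n)
  expect_identical(a$volume$data, b$volume$data)     # same seed, bitwise equal
  spec_n2 <- small_grain_spec(noise_sd = 500, seed = 10L)
  expect_false(identical(a$volume$data, make_grain_phantom(spec_n2)$volume$data))
})

test_that("degenerate phantom geometry is rejected", {
  expect_error(phantom_spec(grain_semi_axes_um = c(100, 100, 100),
                            hull_thickness_um = 120),
               "hull_thickness_um")
  expect_error(make_grain_phantom(
    phantom_spec(grain_semi_axes_um = c(120, 100, 100), hull_thickness_um = 50,
                 cavity_gap_um = 60, voxel_size_um = 10)),
    "degenerate geometry")
})

test_that("phantom cohorts hit the requested size variation and partition to 1", {
  base <- phantom_spec(grain_semi_axes_um = c(300, 220, 200),
                       hull_thickness_um = 35, cavity_gap_um = 40,
                       voxel_size_um = 10)
  fixed <- make_phantom_cohort(base, 3, variation_cv = 0, seed = 1)
  kv <- vapply(fixed, function(g) g$truth[["K-Volume"]], numeric(1))
  expect_equal(length(unique(kv)), 1L)

  coh <- make_phantom_cohort(base, 50, variation_cv = 0.10, seed = 2)
  kv <- vapply(coh, function(g) g$truth[["K-Volume"]], numeric(1))
  cv <- sd(kv) / mean(kv)
  expect_gt(cv, 0.05); expect_lt(cv, 0.15)
  ratio_sums <- vapply(coh, function(g)
    sum(unlist(g$truth[c("EM-Ratio", "EN-Ratio", "C-Ratio", "H-Ratio")])), numeric(1))
  expect_true(all(abs(ratio_sums - 1) < 1e-12))
})

test_that("simulated RIL genotypes respect map distances and allele balance", {
  map <- make_genetic_map(3, 100, 5)
  pop <- simulate_ril_population(map, 100, NULL, heritability = 0, seed = 3)
  expect_identical(dim(pop$genotypes), c(100L, nrow(map)))
  freq <- colMeans(pop$genotypes == "A")
  expect_true(all(freq >= 0.35 & freq <= 0.65))
  # zero map distance means identical genotype columns
  map0 <- validate_genetic_map(data.frame(
    chrom = "1", marker = c("a", "b", "c"), cM = c(0, 0, 10), Mb = c(0, 0, 4)))
  pop0 <- simulate_ril_population(map0, 50, NULL, heritability = 0, seed = 4)
  expect_identical(pop0$genotypes[, "a"], pop0$genotypes[, "b"])
})

test_that("zero-heritability phenotypes are uncorrelated with planted QTLs", {
  map <- make_genetic_map(3, 100, 5)
  qtls <- data.frame(chrom = "2", pos_cM = 50, add = 1)
  pop <- simulate_ril_population(map, 100, qtls, heritability = 0, seed = 5)
  near <- which(map$chrom == "2" & map$cM == 50)
  g <- ifelse(pop$genotypes[, near] == "A", 1, -1)
  expect_lt(abs(cor(pop$phenotypes$trait, g)), 0.3)
})

test_that("realized single-QTL variance fraction tracks the target over replicates", {
  map <- make_genetic_map(3, 100, 5)
  qtls <- data.frame(chrom = "2", pos_cM = 50, add = 1)
  near <- which(map$chrom == "2" & map$cM == 50)
  pve <- vapply(1:50, function(i) {
    pop <- simulate_ril_population(map, 100, qtls, heritability = 0.15, seed = 50 + i)
    g <- ifelse(pop$genotypes[, near] == "A", 1, -1)
    cor(pop$phenotypes$trait, g)^2
  }, numeric(1))
  expect_lt(abs(mean(100 * pve) - 15), 5)
})

test_that("planted QTL positions outside the map are rejected", {
  map <- make_genetic_map(2, 60, 10)
  expect_error(simulate_ril_population(map, 20,
    data.frame(chrom = "1", pos_cM = 80, add = 1), 0.5, seed = 1),
    "outside the map range")
  expect_error(simulate_ril_population(map, 20, NULL, heritability = 1, seed = 1),
               "degenerate variance")
})

test_that("simulated DEG tables plant exactly the requested interval genes", {
  iv <- data.frame(chrom = "2", start_mb = 25.180, end_mb = 28.330)
  deg <- simulate_deg_table(500, iv, 7, seed = 6)
  expect_true(all(deg$pvalue > 0 & deg$pvalue <= 1))
  # exhaustive scan of the emitted table: the filter-and-intersect logic
  pass <- deg[abs(deg$log2fc) >= 1 & deg$pvalue < 0.05, ]
  inside <- pass[pass$chrom == "2" & pass$pos_mb >= 25.180 & pass$pos_mb <= 28.330, ]
  expect_identical(nrow(inside), 7L)
  expect_identical(nrow(pass), 7L)          # nothing passes outside the interval

  deg0 <- simulate_deg_table(200, iv, 0, seed = 7)
  pass0 <- deg0[abs(deg0$log2fc) >= 1 & deg0$pvalue < 0.05, ]
  expect_identical(nrow(pass0), 0L)

  expect_error(simulate_deg_table(100,
    data.frame(chrom = "2", start_mb = 30, end_mb = 99), 3, seed = 1),
    "coordinate error")
})
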