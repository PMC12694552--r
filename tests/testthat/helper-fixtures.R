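# Shared fixtures: small, fast phantoms and maps built in code.

# downsized millet-like grain (~1/8 volume of the default) for quick tests
small_grain_spec <- function(...) {
  phantom_spec(grain_semi_axes_um = c(550, 400, 350),
               hull_thickness_um = 40,
               cavity_gap_um = 60,
               embryo_fraction = 0.25,
               voxel_size_um = 8, ...)
}

# sphere phantom used against analytic oracles
sphere_spec <- function(voxel_size_um = 3, ...) {
  phantom_spec(grain_semi_axes_um = c(300, 300, 300),
               hull_thickness_um = 30, cavity_gap_um = 15,
               embryo_fraction = 0.3,
               voxel_size_um = voxel_size_um, ...)
}

# solid-sphere label volume of radius r_vox voxels, labelled `code`
sphere_label_volume <- function(r_vox, voxel_size_um, code = "ENDOSPERM",
                                inner_vox = 0) {
  d <- 2 * r_vox + 11
  cx <- (d + 1) / 2
  co <- (1:d) - cx
  r2 <- outer(outer(co^2, co^2, `+`), co^2, `+`)
  arr <- array(0L, c(d, d, d))
  sel <- r2 <= r_vox^2
  if (inner_vox > 0) sel <- sel & r2 > inner_vox^2
  arr[sel] <- TISSUE_LABELS[[code]]
  label_volume(arr, voxel_size_um)
}

tiny_map <- function(n_chr = 2, len = 60, sp = 10) {
  make_genetic_map(n_chr, len, sp)
}

# brute-force Otsu oracle: exhaustive between-class variance maximization
# over an integer-level histogram
otsu_oracle <- function(counts, levels) {
  n <- sum(counts)
  best_t <- NA; best_v <- -Inf
  for (k in seq_len(length(levels) - 1)) {
    w0 <- sum(counts[1:k]) / n
    w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(counts[1:k] * levels[1:k]) / sum(counts[1:k])
    mu1 <- sum(counts[(k + 1):length(levels)] * levels[(k + 1):length(levels)]) /
      sum(counts[(k + 1):length(levels)])
    v <- w0 * w1 * (mu0 - mu1)^2
    if (v > best_v) { best_v <- v; best_t <- levels[k] }
  }
  best_t
}

# expand an integer histogram into a data vector
hist_to_values <- function(counts, levels) rep(levels, counts)
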