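# grainscan

Three-dimensional phenotyping of cereal grain structure from micro-CT,
with QTL mapping and candidate-gene screening — built and validated
entirely on synthetic data, so the whole analysis is reproducible on a
laptop with no scans or sequencing downloads.

A millet-type grain resolves into four compartments in a CT scan: the
**embryo** and **endosperm** of the caryopsis, the **hull**
(lemma + palea), and the air **cavity** between caryopsis and hull.
`grainscan` provides:

* **Segmentation** of grayscale slice stacks into those tissues:
  global Otsu thresholding (exhaustive maximization of the between-class
  variance σ²ᵦ(t) = ω₀ω₁(μ₀−μ₁)²), per-slice Canny edge detection,
  deterministic 3D region growing behind the edge barriers, rank-based
  tissue assignment with topology checks, and boundary refinement.
* **Morphometry**: the 15 structural traits — K/EM/EN/C/H volumes (mm³),
  surface areas (mm²) via a Cauchy–Crofton line-intercept estimator,
  average hull thickness H-A-T (µm) via a distance-transform/medial-axis
  local-thickness estimate, and the four tissue-to-grain volume ratios
  (which sum to exactly 1 by construction).
* **Population statistics**: mean ± SD, CV = 100·SD/mean, bias-corrected
  G1 skewness / G2 kurtosis, Shapiro–Wilk, Pearson correlation matrix.
* **QTL mapping** by inclusive composite interval mapping (ICIM) for
  biparental RILs: stepwise cofactor selection (entry p ≤ PIN = 0.01),
  a 1-cM Haley–Knott scan of the cofactor-adjusted phenotype with
  Haldane/RIL-corrected genotype probabilities,
  LOD = n/2·log₁₀(RSS₀/RSS₁), permutation-based genome-wide thresholds,
  2-LOD-drop support intervals, PVE and additive effects.
* **Candidate genes**: differential-expression filtering
  (|log2FC| ≥ 1, p < 0.05) intersected with QTL physical intervals
  (closed at both ends).
* **Phantoms and simulators**: synthetic grain stacks with voxel-exact
  ground-truth labels, RIL populations with planted additive QTLs of
  chosen heritability, and DEG tables with planted interval genes.

## Worked example

Segment a noisy synthetic grain, score it against ground truth, and
measure its traits:

```r
library(grainscan)

spec <- phantom_spec(grain_semi_axes_um = c(550, 400, 350),
                     hull_thickness_um = 40, cavity_gap_um = 60,
                     embryo_fraction = 0.25, voxel_size_um = 8,
                     noise_sd = 1500, seed = 42)
ph <- make_grain_phantom(spec)
ph$volume
#> <voxel_volume> 148 x 110 x 98 (z,y,x), 16-bit, voxel 8 um
#>   intensity range [0, 58102]

lv <- segment_grain(ph$volume)
round(dice_coefficient(lv, ph$labels), 4)
#>    EMBRYO ENDOSPERM    CAVITY      HULL
#>    0.9997    0.9999    1.0000    1.0000

compute_traits(lv)
#> <grain_traits>
#>  line_id grain_id K-Volume EM-Volume EN-Volume C-Volume H-Volume K-Area EM-Area
#>     <NA>     <NA>   0.3225   0.02225    0.1191  0.09712  0.08399  2.315  0.4371
#>  EN-Area C-Area H-Area H-A-T EM-Ratio EN-Ratio C-Ratio H-Ratio
#>    1.149   3.25  4.215 43.99  0.06901   0.3694  0.3012  0.2605
```

The Dice row says each segmented tissue overlaps its ground truth almost
perfectly despite 5%-of-contrast noise. In the trait row, volumes are mm³,
areas mm², H-A-T µm (43.99 vs the planted 40 µm hull — within half a
voxel), and the four ratios sum to 1.

Map a planted QTL in a simulated 100-line RIL population:

```r
map <- make_genetic_map(n_chr = 9, chr_length_cM = 100, spacing_cM = 5)
pop <- simulate_ril_population(map, n_lines = 100,
                               qtls = data.frame(chrom = "3", pos_cM = 37, add = 1),
                               heritability = 0.15, seed = 42)
scan <- icim_scan(pop, "trait", scan_params(seed = 42))
scan
#> <icim_scan> trait 'trait': 909 positions on 9 chromosomes, n = 100
#>   max LOD 3.450 at chr 3, 34.0 cM; cofactors: m3_008, m8_018

call_qtls(scan, pop)
#>     qtl chromosome peak_cM ci_lo_cM ci_hi_cM ci_lo_Mb ci_hi_Mb trait  lod  pve_percent    add
#> 1 qTRA3          3      34       20       49        8     19.6 trait 3.45        13.53 0.9926
```

The planted locus (chromosome 3, 37 cM, additive effect +1, 15% of the
phenotypic variance) is recovered at 34 cM with LOD 3.45, a 2-LOD-drop
interval of 20–49 cM, estimated PVE 13.5% and additive effect +0.99.
`permutation_threshold(pop, "trait", scan_params(seed = 42))` gives the
genome-wide empirical threshold to use as `lod_min` for calibrated calls.

An end-to-end run (simulate → segment → traits → stats → qtl →
candidates) with a manifest of output digests:

```r
run_pipeline(read_run_config(), out_dir = "demo_run", seed = 1)
```

or from the shell via `Rscript inst/cli/grainscan.R run --out-dir demo_run`.

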