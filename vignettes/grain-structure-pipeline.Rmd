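---
title: "Methods: 3D grain-structure phenotyping, QTL mapping and candidate screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 3D grain-structure phenotyping, QTL mapping and candidate screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`grainscan` implements a complete desk-reproducible pipeline for
micro-CT-based grain structure analysis in cereals, with foxtail millet
(*Setaria italica*) as the motivating system. A millet grain has four
resolvable compartments in a CT scan: the embryo and endosperm of the
caryopsis, the hull (lemma + palea) that encloses it, and the air-filled
cavity between caryopsis and hull. The pipeline segments these tissues from
grayscale slice stacks, quantifies fifteen structural traits per grain,
summarizes them over a recombinant inbred line (RIL) population, maps
quantitative trait loci by inclusive composite interval mapping (ICIM),
and screens candidate genes by intersecting QTL support intervals with a
differential-expression table.

Raw scans and sequencing data are not required: a phantom module generates
synthetic CT stacks with voxel-exact ground truth, simulated RIL
populations with planted QTLs, and simulated differential-expression
tables, so every stage is testable end to end.

## The grain phantom

`make_grain_phantom()` builds nested ellipsoidal solids: an outer hull
shell of constant thickness, an air-gap shell (the cavity) inside it, and
an inner caryopsis ellipsoid split into an embryo — modelled as a polar cap
along the long axis — and endosperm. Voxels take their tissue's mean
intensity plus optional Gaussian noise, clipped to the 16-bit range.

The default geometry is chosen so that the phantom's traits sit at the
centre of the trait distributions a millet RIL population exhibits:
semi-axes (1100, 800, 700) µm give a whole-grain volume near 3 mm³; a
39 µm hull and 58 µm cavity gap give hull and cavity volume fractions near
0.13 and 0.19; an embryo cap covering 22% of the caryopsis long axis gives
an embryo volume fraction near 0.09 (a polar cap of depth fraction *t*
holds the fraction *t*²(3−2*t*) of an ellipsoid's volume, and
0.22²·(3−0.44) ≈ 0.124 of the caryopsis ≈ 0.086 of the grain). The default
intensity ordering is cavity/background (air, darkest) < hull < endosperm
< embryo; the ordering is a modelling choice and is user-overridable, and
the segmentation rule accepts any permutation.

The default voxel size is 10 µm, which puts the default stack at
~230 × 170 × 150 voxels. That size keeps a full segmentation around
20 s on one core while preserving the genuinely difficult feature of
real scans — a hull only ~4 voxels thick. Real micro-CT scans at 3 µm
resolution resolve the hull in ~13 voxels; every thin-structure result
below is therefore conservative relative to higher-resolution data.

Cohorts (`make_phantom_cohort()`) draw a per-grain lognormal volume factor
with coefficient of variation `variation_cv` (applied to the semi-axes as
its cube root, so the K-Volume CV equals `variation_cv` directly — the
observed trait CVs in such populations are 7–21%), with independent
lognormal factors on hull thickness and cavity gap.

What the phantom does *not* emulate: beam hardening, ring artifacts,
partial-volume blur beyond the segmentation's own smoothing, the thin
caryopsis coat (absorbed into endosperm, as it is too poorly contrasted to
segment in real scans), and hull surface ornamentation. Passing the
segmentation tests therefore demonstrates correctness of the algorithmic
chain, not robustness to every scanner artifact.

## Segmentation

`segment_grain()` composes six deterministic steps:

1. **Gaussian pre-smoothing** (`smooth_sigma_vox`, default 1 voxel).
   Suppresses voxel noise by ~6.5× before any thresholding; with 5%-of-range
   noise the residual in-tissue scatter is well below the smallest
   inter-tissue contrast.
2. **Global Otsu threshold** — exhaustive maximization of the between-class
   variance σ²ᵦ(t) = ω₀ω₁(μ₀−μ₁)², ties broken toward the lowest
   threshold. When the data take few integer levels the histogram is exact;
   otherwise 256 equal-width bins are used. This threshold separates air
   from solid tissue and later anchors the background definition.
3. **Canny edges per slice** — Gaussian smoothing, Sobel gradients,
   non-maximum suppression, and double-threshold hysteresis with
   thresholds expressed as fractions of the maximum gradient magnitude
   (hence offset-invariant). A 3D gradient-magnitude criterion
   (≥ `canny_low_frac` of the maximum) widens the barrier to the full
   interface ramp produced by smoothing, so ramp voxels never form
   spurious regions of intermediate mean intensity.
4. **3D region growing** behind the edge barrier: seeds visited in
   lexicographic (z, y, x) order, FIFO growth with a running-mean
   criterion (`growth_tolerance`, default 5% of the dynamic range),
   26-connectivity by default. Barrier voxels are then absorbed one by one
   into the adjacent region with nearest mean — this places each boundary
   at the intensity midpoint — and fragments below `min_region_vox`
   (default 27, a 3³ speckle) are merged the same way. The result is a
   total partition; determinism follows from the fixed seed and
   neighbourhood order.
5. **Tissue assignment**: background = face-touching regions at or below
   the Otsu threshold; remaining regions are pooled into four classes by a
   deterministic size-weighted 1D k-means whose centres are initialized at
   the largest regions subject to a mutual intensity separation (12% of
   the spread) — the large genuine tissues anchor the intensity bands and
   interface remnants cannot displace them. Classes map to tissue names by
   rank according to `tissue_rule()$ordering`. Topology is then enforced:
   only the hull may border the outer background; violating regions are
   reassigned.
6. **Boundary sharpening and overrides**: two Jacobi passes reassign
   interface voxels to the 6-adjacent class whose mean on the *unsmoothed*
   intensities is nearest, undoing the smoothing-induced boundary bias
   (without this, a 4-voxel hull cannot exceed Dice ≈ 0.85; with it the
   default phantom reaches Dice > 0.99 per tissue). Finally
   `refine_labels()` applies user-supplied intensity-range overrides — the
   programmatic equivalent of the manual threshold adjustments an
   interactive tool would allow — in list order, idempotently.

## Morphometry: the fifteen traits

Volumes are voxel counts × (voxel edge)³, reported in mm³. The whole-grain
(K) mask is defined as the union of the four tissue masks, which makes the
four volume ratios sum to exactly 1 and K-Volume exactly the sum of the
tissue volumes; population tables computed with an unsegmented coat
remainder instead sum to ≈0.99, a ≤1% definitional discrepancy worth
keeping in mind when comparing.

Surface areas use a Cauchy–Crofton line-intercept estimator: maximal runs
of in-mask voxels are counted along the three grid axes, and
S = 4·s²·(C₁+C₂+C₃)/3. Each chord contributes its two endpoints, so
interior boundaries are counted (a hollow shell reports inner + outer
area) and the estimate converges to the analytic area for smooth surfaces
(digitized sphere of r = 100 voxels: error < 0.1%; acceptance band 3%). A
triangulated mesher was considered and rejected: on binary data a
midpoint-vertex mesh bounds a single voxel by an octahedron of area
√3 s² — far below the ~6 s² any practitioner expects — while naive
face-counting overestimates smooth surfaces by ~50%. The Crofton estimator
is accurate in both regimes; its known weakness is a negative bias for
large axis-aligned flat faces, which do not occur in grain geometry.

Mean hull thickness (H-A-T, µm) is a local-thickness estimate: the
Euclidean distance transform (exact squared EDT, computed separably) of
the hull mask is sampled at its medial voxels (26-neighbourhood local
maxima), and the mean is doubled. A uniform 10-voxel shell is recovered
exactly; a 5-voxel slab is recovered within one voxel. H-A-T is reported
in µm — the only unit under which observed hull values (26–56) are
physically plausible.

## Population statistics

`summarize_trait()` reports min/max, mean ± SD (n−1), CV = 100·SD/mean,
the bias-corrected Fisher–Pearson G1 skewness and G2 excess kurtosis (the
SPSS convention), and the Shapiro–Wilk p-value. Normality is assessed two
ways on purpose: the Shapiro–Wilk test at α, and the practical moment rule
(|G1| < 3 and |G2| < 10) — with n = 100 grains the test rejects mild
tail-heaviness that the moment rule tolerates, and reporting both keeps
the decision transparent. Correlations are Pearson on complete cases with
two-sided t-test p-values.

## ICIM QTL mapping

The mapping model is additive-only, appropriate for fully inbred RILs
(codes A/B → ±1; no heterozygote or dominance terms). The implementation
is the two-step regression form of ICIM:

1. **Cofactor selection**: forward–backward stepwise regression of the
   phenotype on all marker codes; a marker enters when its partial-F
   p-value ≤ PIN (default 0.01) and leaves when it exceeds POUT = 2·PIN.
   Missing genotypes are mean-imputed per marker. Selection is
   deterministic with ties broken toward map order.
2. **Interval scan** at `step_cM` (default 1 cM, marker positions
   included): at each position the expected QTL dosage given the flanking
   genotypes is computed from conditional two-point probabilities, using
   Haldane's map function and the RIL correction R = 2r/(1+2r) for
   repeated selfing; the cofactor-adjusted phenotype is regressed on this
   dosage (Haley–Knott) and LOD = n/2·log₁₀(RSS₀/RSS₁). The adjustment
   excludes every cofactor within `window_cM` (default 10 cM) of the
   scanned interval; the flanking markers are the window = 0 special case.
   The EM-based mixture refinement of full ICIM is omitted — at RIL scale
   the regression approximation is standard and the LOD differences are
   negligible relative to the permutation resolution.

A design note on calibration: any composite-interval method that adjusts
the phenotype with data-selected cofactors is anticonservative against a
*fixed* LOD threshold, because the adjusted phenotype has smaller variance
than the raw one. In null simulations (n = 100, nine 100-cM chromosomes)
the genome-wide maximum LOD of the adjusted scan exceeds 4 in ~10% of
replicates, whereas the scan with selection disabled stays below 4
essentially always. This is why the package surfaces *both* thresholds:
the conventional fixed LOD 2.5, and `permutation_threshold()` — phenotype
permutations with full cofactor reselection per permutation, genome-wide
maxima, empirical 1−α quantile (type-7) — which inherits the selection
effect and therefore calibrates it away (false-call rate ≈ α by
exchangeability). Calls default to the fixed 2.5 for comparability;
calibrated analyses should pass the permutation threshold as `lod_min`.

`call_qtls()` takes profile local maxima above `lod_min`, merges peaks
closer than 20 cM (keeping the higher), and bounds each support interval
at the outermost contiguous grid positions within `lod_drop` (default 2)
of the peak. The additive effect is the dosage regression coefficient at
the peak — half the difference between genotype-class means, parent-A
allele positive (the sign convention is arbitrary and documented rather
than inferred). PVE is reported as 100 × (explained sum of squares at the
peak) / (total phenotypic sum of squares): "percent *phenotypic* variance
explained" refers to the raw phenotype, and using the adjusted-phenotype
denominator instead was measured to inflate the estimate by ≈1 point at
the 15%-PVE operating point. Physical (Mb) intervals come from
piecewise-linear cM→Mb interpolation between mapped markers, clamped at
chromosome ends. Names follow the convention q + trait abbreviation +
chromosome (e.g. `qKV2` for K-Volume on chromosome 2).

The RIL simulator draws chromosomes as two-state Markov chains with the
same Haldane/RIL transition probabilities the scan assumes. The
heritability contract is enforced on the *realized* sample: noise is
drawn, orthogonalized against the genetic values and rescaled so the
in-sample genetic variance fraction equals h² exactly. With
expectation-only scaling the realized fraction at n = 100 has a ~14%
relative scatter, and replicate batches of a detection-power experiment
then differ by ten percentage points for reasons that have nothing to do
with the mapping method; exact realization removes that nuisance
variation while leaving every other property (map-distance decay, allele
balance) untouched. At the reference operating point — one planted QTL of
15% PVE, n = 100, markers every 5 cM — detection (LOD > 2.5, right
chromosome, peak within 10 cM) runs at ~96% over 50 replicates with mean
estimated PVE ≈ 16.8 (a small residual Beavis-type upward bias from
maximizing over the genome is expected and documented rather than
corrected).

## Candidate genes

`filter_degs()` keeps genes with |log2FC| ≥ 1 (inclusive) and p < 0.05
(exclusive), on the raw p-value by default — an adjusted-p column is
honoured when requested. `intersect_qtl_degs()` treats QTL physical
intervals as closed at both ends and gene positions as midpoints in Mb;
one record is emitted per (gene, QTL) pair, and chromosome-naming
mismatches between the two tables produce an explicit warning listing the
unmatched names.

## Numerical and interface choices

* Axis convention (slice, row, column) = (z, y, x); physical coordinate =
  index × voxel size; isotropic voxels are assumed and enforced.
* All generators are pure functions of (parameters, seed); the RNG state
  is saved and restored around every seeded operation.
* Slice formats: PNG and TIFF (8/16-bit) via the standard readers, plus a
  minimal uncompressed 8-bit grayscale BMP reader/writer, since CT
  vendors commonly export plain BMP and no installed R package reads it.
  Label stacks round-trip losslessly as indexed PNG plus a key-value
  sidecar.
* `run_pipeline()` executes simulate → segment → traits → stats → qtl →
  candidates from a YAML configuration, aggregates per-grain traits to
  line level by the mean (median available), and writes a manifest with
  MD5 digests; identical configuration and seed reproduce identical
  digests for the deterministic stages. `inst/cli/grainscan.R` exposes
  each stage as a shell subcommand.
* Problem sizes in the test-suite and acceptance script: default phantom
  ~5.9 M voxels; spheres for the analytic oracles at r = 100 voxels; QTL
  experiments at n = 100 lines, 189 markers, 50 replicates, and 200
  permutations per null replicate. These sizes put every simulated
  experiment at the same operating point as a real 100-line study while
  keeping a full run in minutes on one core.

## Known limitations

* One grain per stack; multi-grain scenes are out of scope.
* The caryopsis coat is not segmented (absorbed into endosperm), so trait
  definitions differ by ≤1% from analyses that leave it unassigned.
* The Crofton area estimator is biased low for large axis-aligned flat
  surfaces (irrelevant for grains, relevant if repurposed for industrial
  parts).
* ICIM here is the regression form without EM mixture refinement, and
  epistasis, dominance and multi-environment models are not fitted.
* The fixed LOD 2.5 threshold is anticonservative for ICIM (see above);
  permutation thresholds are provided and recommended.
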