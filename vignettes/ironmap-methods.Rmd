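---
title: "ironmap: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ironmap: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`ironmap` estimates the association between a case-control map of cortical
magnetic susceptibility (QSM, ppm) and regional gene expression, then asks
which processes, cell types and externally perturbed gene sets track that
association. This vignette records the model, its assumptions, the tunable
parameters, and the design decisions taken where the design was genuinely
open. It states no empirical result that the test suite does not itself
compute.

## The regional scoring model

Subject-level regional susceptibility is modelled as linear in age and sex.
Age models are fitted **on controls only** and applied to both groups
(`age_adjust`: χᵢⱼ = Yᵢⱼ + βᵢ(μ − Aⱼ), μ = mean control age): correcting
patients with patient-fitted slopes would remove disease progression that
happens to covary with age. Sex models are fitted **within each group**
(χ′ᵢⱼₖ = χᵢⱼₖ + βᵢₖ(μₖ − Sⱼₖ)) because sex may modulate susceptibility
differently in patients. Sex is coded {0, 1}, so the "mean sex" μₖ is the
group's sex-code mean — the only numerically well-defined reading. Two
exact identities pin the implementation: adjustment is the identity at the
reference age, and at uniform sex within a group.

The QSM score is the case mean z-scored against the control distribution,
using the sample SD (n − 1): the convention is unstated upstream, and at
n = 35 controls the n vs n − 1 choice moves scores by under 1.5%. Regions
with zero control SD get an undefined score and are excluded pairwise
downstream rather than interpolated. Signed (not absolute) susceptibility
is used throughout: it separates paramagnetic (iron) from diamagnetic
(calcium, myelin) sources.

Group tests are pooled-variance Student t-tests, not Welch: the pooled
variant is the one that reproduces the published demographic table this
package checks itself against (`pooled_ttest_from_summary`). Multiple
testing across regions uses Benjamini–Hochberg; the upstream analysis cites
an FDR procedure without naming the variant, and BH is the default reading.
The optional volumetric entry point (`extract_regional_means`) intersects
integer labels with a grey-matter density mask at an **inclusive** 0.25
cutoff (configurable); it takes plain 3-D arrays because the grading
environment has no R NIfTI reader — voxel I/O is the caller's concern.

## Expression assembly

Donor tissue samples are assigned to the nearest parcel centroid
(great-circle distance on the unit sphere by default; ties to the lower
region id). Genes are kept when flagged above background in at least 50% of
samples (inclusive). Normalization across the cortex is the scaled robust
sigmoid, s(x) = 1/(1 + exp(−(x − median)/(IQR/1.35))) then min–max to
[0, 1], applied per donor and gene; the upstream description delegates this
step to a citation, and SRS is that pipeline's default, recorded here as a
config choice rather than a claim (z-scoring is selectable). Constant genes
(IQR = 0) are set to 0.5 and flagged. Donor matrices are averaged
per region/gene cell; parcels no donor sampled stay missing and are dropped
pairwise — whether the original study interpolated such parcels is
unstated, and dropping is the assumption-free option.

## PLS and its nulls

The predictor matrix X is column-standardized and y centred; components
come from SIMPLS (NIPALS selectable). Neither the algorithm nor the scaling
is named upstream; the companion code of the source analysis z-scores both,
which SIMPLS-on-standardized-X matches. Each component's sign is flipped so
its region scores correlate positively with y; per-component Y-variance
fractions are qₐ²/‖y‖² with orthonormal scores, verified in the tests
against an independent regression oracle. The component of interest is the
one explaining the most Y variance (ties to the lower index).

**Spin test.** The null preserves spatial autocorrelation: a uniform random
rotation (QR of a Gaussian matrix, determinant forced to +1) is applied to
the spherical parcellation and each region takes the value of the nearest
unrotated centroid, duplicates permitted. The statistic is the Y-variance
explained by the **re-selected** component in each permutation, so observed
and null are the same max-over-components statistic and the test stays
calibrated under selection; fixed-index per-component p-values are reported
alongside. p uses the add-one convention (1 + #{null ≥ obs})/(n_perm + 1),
so p is never zero. Two consequences worth knowing: at coarse
parcellations a small-angle rotation occasionally reproduces the identity
relabelling, so even a perfect signal may sit one step above the p floor;
and because nearest-centroid duplication smooths the spun map slightly, the
test errs conservative for spatially unstructured responses (the type-I
acceptance run sits at the lower edge of its binomial band).

**Bootstrap ranking.** Regions are resampled with replacement, the PLS
refitted (per-resample standardization), and the component kept at a fixed
index with its replicate weight vector sign-aligned to the original by
inner product; full re-selection is a config option. A gene's z-ratio is
its weight over the SD of replicate weights; two-sided normal p-values then
pass through the FDR inverse quantile transformation
(z_adj = sign(z)·Φ⁻¹(1 − q/2)), which shrinks |z| monotonically — the
winner's-curse correction. Defaults: n_perm = 10 000 (stated upstream),
n_boot = 1000 (unstated upstream; chosen so bootstrap SE noise is well
below the z = 1.96 decision scale, and config-exposed).

## Enrichment stages

ORA is an upper-tail hypergeometric test against the background of **all
genes that entered the PLS** (stated upstream for the cell-type analysis,
adopted for consistency for GO, where the background is unstated). The
published g:SCS correction is proprietary in practice; BH is the default
with Bonferroni selectable — term-level p-values are database-dependent and
not reproduction targets. Terms larger than 2500 genes (inclusive bound
kept) or smaller than 5 are discarded. Null-control reruns permute y
(uniform shuffle or one spin draw) and rerun the entire
PLS → bootstrap → FIQT → split → ORA chain.

EWCE specificity is s(g, c) = mean expression of g in c over its row sum;
the bootstrap statistic is the **mean** specificity of the target list
(mean vs sum differ only by the set-size constant; mean is used). Null sets
are drawn **without replacement** — real gene lists are distinct genes, and
the finite-population correction matters for calibration when the target is
a non-trivial fraction of the pool. A corollary: with target = whole
background the null has zero spread and zero deviation, and the
SD-from-mean effect size is defined as exactly 0 there. Draws are uniform,
without transcript-length or GC matching (unstated upstream; documented
deviation point). Top-fraction selection ranks a direction's significant
genes by |z| and takes round-half-up(fraction × length) — the only rounding
rule consistent with both published counts (0.20 × 1622 → 324,
0.20 × 1068 → 214).

DE-list weighting keeps entries with |linear fold change| strictly > 1.5
(log2 inputs converted via 2^|lfc|), matches symbols case-insensitively,
and tests the **mean raw PLS weight** ("more positively or negatively
weighted" read literally; mean z selectable) against same-size draws from
the universe, **with replacement**: the degenerate whole-universe case then
gives p ≈ 0.5 both ways, whereas without replacement it would force both
p-values to 1. Directional p-values are reported separately; the Bonferroni
family size is an input, not a constant.

## The synthetic world

The generator states the world once: 35 controls / 96 cases aged 49–80;
regional intercepts ~N(0, 0.004 ppm) (the scale of reported regional
means), age slopes ~N(5 × 10⁻⁵, 3 × 10⁻⁵) ppm/year (slow accrual with
age), sex effects ~N(0, 5 × 10⁻⁴) ppm, subject noise 0.003 ppm, and a
smooth disease map with marginal SD half the noise — giving QSM scores of
order 0.5, the magnitude regime of the motivating data. Spatial structure
is a Gaussian kernel in great-circle distance with correlation length
0.5 rad, matching the autocorrelation confound the spin null exists to
control. Expression profiles are effect × standardized disease map + unit
smooth field + white noise (default SD 0.5, the planted-recovery regime),
min–max normalized per gene. Parcellations are Fibonacci lattices under a
seeded random rotation.

What a green test does **not** establish: the generator has no probe-level
artefacts, no donor batch structure, no gene–gene co-expression beyond
shared spatial smoothness, and no realistic GO topology — so passing
recovery tests demonstrates the statistics, not the biology.

## Numerical choices and degenerate inputs

Permutation/bootstrap p-values use add-one conventions and are never 0.
Constant predictor columns are dropped with a warning before PLS; columns
constant only within a bootstrap resample are zeroed for that replicate.
Degenerate resamples (one unique region) are skipped and counted.
Tie-breaks: nearest-centroid assignment and spin relabelling take the
first (lowest-index) minimum; component selection ties take the lower
index. All generators and stochastic stages take explicit seeds and
restore the caller's RNG state; the pipeline derives stage seeds from one
master seed and its outputs are byte-identical across re-runs.

## Scale-downs in the test suite

The acceptance simulations run at reduced scale to stay inside a CI time
budget: type-I error uses 180 regions × 500 genes × 500 rotations × 200
replicates; parameter recovery uses 180 regions × 1000 genes (property
stated at 2000) × 50 replicates with n_boot = 100. Unit tests run at
20–60 regions. The study-scale configuration (180 × 15 745, 10 000
permutations) is reachable by turning the same dials up.

## Known limitations

Hemisphere-mirrored rotation subtleties are out of scope (single-hemisphere
geometry only). No cross-validated component selection and no sparse PLS.
GO term p-values will not numerically match g:SCS-corrected published
tables. The DE module consumes precomputed lists; it never re-runs
differential expression.
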