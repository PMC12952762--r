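---
title: "Quantifying induced chromatin loops from single-allele FISH: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying induced chromatin loops from single-allele FISH: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loopfish)
```

## The problem

Optogenetic looping tools tether a light-responsive clustering protein
(a CRY2 fusion of catalytically dead Cas9) to two genomic loci; blue light
drives CRY2 oligomerization, pulling the loci together. Two kinds of
measurements quantify such a system:

1. **Clustering kinetics in live cells.** Per-nucleus clustering is scored
   by the coefficient of variation (CV) of the fluorescence intensity —
   population SD over mean across the nucleus pixels — which rises as
   diffuse protein condenses into clusters. From each cell's CV time
   course after a single light pulse at $t = 0$, the half-maximal
   clustering time $t_c$ and the half-recovery (declustering) time $t_d$
   summarize the on and off kinetics.
2. **Loop formation and its transcriptional consequence in fixed cells.**
   DNA-FISH labels the two loci in two channels; the center-to-center
   distance of the paired signals at each allele measures proximity, with
   alleles closer than 0.27 µm called *proximal* (looped). Sequential
   RNA/DNA-FISH adds nascent-transcription calls per allele, and a
   binomial null model asks whether alleles loop independently within a
   cell.

`loopfish` implements this entire quantitative layer — image primitives,
kinetics, allele geometry, the independence model, transcription linkage,
and the study-level statistics — plus a seeded synthetic-data generator so
that every stage is verifiable against a known ground truth without any
external imaging data.

## Pixel-level primitives

* **CV** (`compute_cv`): population SD / mean over the masked nucleus
  pixels. Population (not sample) SD is fixed deliberately: nuclei span
  thousands of pixels so the distinction is immaterial, and a single
  definition keeps results deterministic. The CV is invariant under
  positive rescaling of intensities, so gain changes between sessions do
  not move it. `relative_cv` renormalizes a trace to its $t=0$ value.
* **Spot detection** (`detect_spots`): scale-normalized negative
  Laplacian-of-Gaussian response at a single user-set scale (default
  `sigma_px = 1.5`), local maxima above `min_response`, assignment to the
  nucleus label under the peak (background detections dropped), and an
  intensity-weighted centroid over the local support. A single scale
  suffices because diffraction-limited FISH spots are near-constant in
  size; for a Gaussian spot of matched sigma and amplitude $A$ the central
  response is $\approx A/2$, which makes `min_response` easy to set from
  the faintest spot one wants to keep. Whether the upstream segmentation
  tool uses binary or intensity-weighted centroids is not documented;
  intensity weighting was chosen because it is strictly more accurate on
  rendered ground truth (worst error well under 1 px at SNR 5).
* **Registration** (`register_translation`): integer-pixel translation
  from the peak of the inverse-transformed, magnitude-normalized
  cross-power spectrum of the two images. Sequentially imaged RNA- and
  DNA-FISH fields only need alignment good enough to re-identify alleles
  at a 2.5 µm tolerance, so no subpixel refinement is attempted. The
  normalized peak height is ~1 for a true cyclic shift and ~0.01–0.03 for
  unrelated 256² noise fields; the default acceptance gate
  `min_peak = 0.03` sits conservatively above that null distribution and
  is configurable.
* **ROI readout** (`roi_mean`): mean over pixels whose centers fall within
  the radius, clipped at borders; at the 0.108 µm pixel size the 1.08 µm
  reporter ROI is a 10-pixel-radius disk.
* **QC features** (`region_features`): area = pixel count × pixel size²;
  solidity = region pixels / pixels of the filled convex hull of the
  region's pixel centers, which makes a solid rectangle exactly 1.

## Allele geometry

Quality control removes nuclei below the minimum area (50 µm² for HeLa,
90 µm² for U2OS data), below 0.9 solidity, or whose spot count in either
DNA channel differs from the locus ploidy (2, 3 or 4 depending on cell
line and locus pair).

Within each surviving nucleus all cross-channel spot distances are
computed and matched **greedily on the ascending distance list**, each
spot used at most once, pairs at ≥ 2 µm discarded. Greedy matching was
chosen over mutual-nearest-neighbour or optimal assignment because it is
deterministic (exact ties broken by spot id), near-optimal at ploidies of
2–4, and is the most direct reading of taking "minimum distances below
2 µm" as the allele distances. The test suite compares it against
brute-force optimal assignment on small instances; greedy can return one
pair fewer in adversarial geometry, which at these ploidies is rare.
Proximity is a strict inequality: a pair at exactly 0.27 µm is *not*
proximal.

When a nucleus passes the spot-count QC but one candidate pair exceeds the
2 µm cap, its per-cell fraction of close alleles needs a denominator
choice. By default the realized pair count is used; `summarize_cells(...,
denominator = "ploidy")` switches to the expected allele number. The
choice is not documented in the source protocol; both modes are exposed
and the default affects well under 1% of generated cells.

## The allele-independence null

With $p_c$ the population frequency of close alleles and $n$ the ploidy,
independence predicts the fraction of cells with $k$ close alleles as the
binomial mass $\binom{n}{k} p_c^k (1-p_c)^{n-k}$. `independence_test`
compares observed cell counts with this expectation by Pearson
chi-squared, pooling categories with expected count below 1 into their
nearest neighbour (a standard validity guard).

Degrees of freedom deserve a note. The plain test uses
$\text{categories} - 1$, which is the default here for fidelity to the
source procedure. Because $p_c$ is estimated from the same cells, that
test is *conservative*: under the null the statistic follows a
chi-squared with one fewer dof, and simulated null rejection at nominal
5% comes out near 1.5%. `estimated_p_correction = TRUE` subtracts the
extra dof; in that mode the simulated null rejection rate is within 2
points of 5% and the p-value distribution is near-uniform. Calibration
checks in the test suite use the corrected mode; substantive comparisons
are insensitive to the choice because departures of interest (allele
coupling) move the statistic by orders of magnitude.

## Transcription linkage

RNA transcription-site spots are assigned to DNA alleles (anchored at the
channel-A spot) greedily one-to-one by ascending distance, capped at
2.5 µm; alleles without an assigned RNA spot are inactive. One-to-one
assignment prevents a single RNA focus from activating two alleles; a
`allow_reuse` switch restores plain nearest-within-threshold calls. Since
the source wording does not resolve whether per-cell transcription-site
counts include RNA spots not linked to a target allele, `cell_rna_summary`
counts all RNA spots per cell and the linkage table identifies the linked
subset, so either count can be formed.

Cells are binned on the fraction of close alleles (or on reporter
intensity) at equal counts by rank; tied values share a rank and are never
split across bins, so with a diploid locus the fraction takes values
{0, ½, 1} and bins degenerate gracefully (flagged via
`n_bins_effective`). Pooling the bins reproduces the unbinned population
summaries exactly.

The recruitment control (`gfp_control_at_locus`) reads the reporter ROI
mean at every allele anchor and Welch-tests active vs inactive alleles;
on a reporter unrelated to transcription the association is null at the
nominal rate.

## Study-level statistics

Two-factor comparisons (e.g. sgRNA × light) use a two-way ANOVA with
Tukey HSD post-hocs; type-II sums of squares are used because the
experiment designs are mildly unbalanced and main effects are the focus
(the source does not state a type). Paired condition means use a paired
two-tailed t-test. Proportions across ≥ 3 groups use Marascuilo's
procedure: pair $(i,j)$ is significant when
$|p_i - p_j| > \sqrt{\chi^2_{1-\alpha,k-1}}\sqrt{p_i(1-p_i)/n_i + p_j(1-p_j)/n_j}$.
Significance is encoded as `*`, `**`, `***` at 0.05/0.01/0.001.
Degenerate inputs are flagged rather than raised: a constant response
gives F = 0, p = 1; a nonzero constant paired difference has zero
variance and no defined t.

## The synthetic-data generator

`generate_population` draws, per condition arm (dark/light), `n_cells`
cells with:

* log-normal per-cell reporter expression (`expression_mu = log(100)`,
  `expression_sigma = 0.5`, arbitrary units);
* per-allele loop states, Bernoulli with baseline contact probability
  `p_contact_dark = 0.02` / `p_contact_light = 0.10`, the per-cell logit
  shifted by `expression_coupling = 0.5` times the centred
  log-expression (coupling on the logit keeps probabilities bounded and
  reproduces a monotone reporter–proximity relationship), and within-cell
  correlation `allele_correlation` implemented by mixing a shared
  per-cell draw with independent draws — at mixing weight
  $\sqrt{\rho}$ so that the parameter *is* the pairwise loop-state
  correlation;
* inter-locus distances drawn as 2D Rayleigh with scale 0.12 µm (looped)
  or 0.45 µm (unlooped) — the simplest isotropic 2D radial model, giving
  overlapping looped/unlooped distributions;
* transcription states with `base_active_prob = 0.4` for unlooped alleles
  and odds divided by `repression_odds_ratio = 4` when looped;
* RNA spots uniform in a 1 µm disk around active alleles' channel-A
  anchors (safely inside the 2.5 µm linkage radius), and nucleus QC
  features in realistic ranges.

Allele anchors sit on a jittered regular polygon at 55–70% of the nucleus
radius, so anchors of different alleles are separated by more than both
the 2 µm pairing cap and the 2.5 µm RNA radius: pairing and linkage are
exact by construction, and deviations measured downstream reflect the
analysis, not fixture ambiguity. All randomness flows from the single
config seed; identical configs reproduce byte-identical tables.

**What the defaults do and do not emulate.** The source distances are
only published as medians; the Rayleigh scales are stated placeholders,
not fits. With these scales an unlooped allele is already proximal 16.5%
of the time, so the generator cannot hit the published absolute proximal
fractions (15% dark with a diploid reporter pair); the defaults were
instead chosen to reproduce the *structure*: a small dark baseline and a
~5–6 point light-induced increase (about 18% → 24% pooled), a light-
shifted median distance (~0.52 → 0.49 µm), repression of transcription at
looped alleles, and independent alleles in the default mode. Rendered
images are 2D Gaussian blobs over flat Gaussian-noise background at
0.108 µm/px; there is no photobleaching, stage drift, chromatic
aberration, 3D structure, or chromatin polymer physics. Passing tests
therefore certify the analysis pipeline's arithmetic and statistical
behaviour on data with this structure — not detector performance on real
microscope noise.

## Numerical choices and degenerate inputs

* Half-times: the half level is defined relative to
  $(\mathrm{CV}_{max} - \mathrm{CV}_{t=0})$; $t_c$ is the *first* upward
  crossing, $t_d$ the first downward crossing after the peak (first
  crossings are robust to noise-induced re-crossings and match the visual
  convention). No smoothing is applied by default; a 3-point running
  median sits behind `smooth = TRUE` because any filter biases
  half-times. Flat or monotone traces leave the estimates `NA` with
  defined flags rather than erroring.
* The synthetic kinetic trace rises linearly to its peak at $2 t_c$ and
  decays linearly through the half level at $t_d$ — the simplest shape
  with exactly the two prescribed half-crossings (hence the requirement
  $t_d > 2 t_c$).
* Exact pairing-distance ties are broken by spot id order; registration
  peak ties resolve to the first index (both deterministic).
* Simulation sizes in the tests follow the study's own scales: 5000
  cells per condition (the published experiments analyze 2500–5000 cells
  and 5000–10 000 alleles per sample), 1000-cell experiments for
  calibration sweeps, 500 null replicates.

## Known limitations

* Distances are 2D, from maximum projections, as in the source analysis;
  true 3D separations are underestimated.
* Greedy pairing is maximal, not maximum: in rare geometries it returns
  fewer pairs than optimal assignment would.
* The generator's distance scales are placeholders (see above), so
  absolute proximal fractions are not comparable to published values —
  only their ordering and the induced contrasts are.
* Registration is integer-pixel; fields with rotation or scaling are out
  of scope.
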