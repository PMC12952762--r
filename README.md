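# loopfish

Quantitative analysis of optogenetically induced chromatin loops from
high-throughput DNA/RNA-FISH imaging, for labs that tether light-activated
clustering proteins (CRY2 fusions of dCas9) to genomic loci and read the
outcome at single-allele resolution.

The package covers the full analysis layer downstream of nucleus/spot
segmentation:

* **Clustering kinetics** — per-nucleus coefficient of variation
  CV = σ/μ of the fluorescence intensity as the clustering metric;
  half-maximal clustering and declustering times *t*<sub>c</sub> and
  *t*<sub>d</sub> from each cell's CV time course by linear interpolation
  to the level CV₀ + (CV<sub>max</sub> − CV₀)/2; logistic / exponential /
  linear population summary fits.
* **Image primitives** — Laplacian-of-Gaussian FISH spot detection,
  Fourier phase-correlation translation registration for sequentially
  imaged RNA/DNA fields, circular-ROI intensity readout, and per-nucleus
  region features (area, solidity) for quality control.
* **Allele geometry** — QC filtering (area, solidity, ploidy-matched spot
  counts), greedy one-to-one pairing of cross-channel DNA-FISH spots into
  alleles (2 µm cap), proximity calls at *d* < 0.27 µm, per-cell and
  per-condition summaries.
* **Allele-independence null** — the binomial model
  *f*(*k*) = C(*n*,*k*) *p*<sub>c</sub><sup>*k*</sup> (1 − *p*<sub>c</sub>)<sup>*n*−*k*</sup>
  for the fraction of cells with *k* of *n* close alleles, tested against
  observed distributions by Pearson chi-squared.
* **Transcription linkage** — RNA transcription sites assigned one-to-one
  to DNA alleles (< 2.5 µm), activity calls, equal-count binning of cells
  by fraction of close alleles or reporter level, and the reporter-ROI
  (1.08 µm) recruitment control.
* **Study statistics** — two-way ANOVA (type-II) with Tukey HSD, paired
  two-tailed *t*, Pearson chi-squared, and Marascuilo's procedure for
  multiple proportions.
* **Synthetic data** — a fully seeded generator producing
  segmentation-style nucleus/spot tables, latent truth tables, rendered
  Gaussian-spot images (0.108 µm/px) and CV kinetic traces, so every stage
  is testable against known ground truth.

See `vignettes/loopfish-methods.Rmd` for the models, parameter choices and
their rationale, and the `analysis/` scripts (`01_simulate_population.R` …
`05_transcription_linkage.R`) for the end-to-end narrative analyses; each
writes its tables under `results/`.

## Worked example

```r
library(loopfish)

cfg <- synthetic_config(seed = 42, n_cells = 2000)   # two light arms
pop <- generate_population(cfg)
res <- run_pipeline(pop$nuclei, pop$spots, tempfile("demo"), seed = 42)
print(res$condition_summary, row.names = FALSE)
#>  condition n_alleles n_proximal fraction_proximal median_distance_um
#>       dark      4000        701           0.17525          0.5269507
#>      light      4000        977           0.24425          0.4783031
```

Light raises the pooled fraction of proximal (< 0.27 µm) alleles from
17.5% to 24.4% and shifts the median inter-locus distance from 0.53 to
0.48 µm — the induced-looping signature the pipeline is built to measure.
Are alleles looping independently within cells?

```r
cells <- res$cells[res$cells$condition == "light" & res$cells$n_alleles == 2, ]
obs <- observed_distribution(cells, n = 2)
independence_test(obs$counts, obs$p_c, n = 2)
#> Allele-independence binomial null (n = 2 , p_c = 0.2442 )
#>   observed: 1147 729 124
#>   expected: 1142 738.4 119.3
#>   chi2 = 0.3219 dof = 2 p = 0.8513
```

The observed cell counts with 0/1/2 close alleles match the binomial
expectation (p = 0.85): no within-cell coupling, as configured. Kinetics
work the same way from CV traces:

```r
tr <- generate_kinetic_trace(t_c_true = 90, t_d_true = 420, cv_max = 3,
                             frame_interval = 30, noise_sd = 0.05, seed = 1)
estimate_kinetics(tr)
#>       t_c      t_d cv_initial   cv_max peak_time t_c_defined t_d_defined
#>  84.51021 429.7642  0.9686773 3.024371       180        TRUE        TRUE
```

The half-times land within about 10 s of the planted 90 s / 420 s truth
under 5% noise at a 30 s frame interval.

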