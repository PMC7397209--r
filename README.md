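# dimslipids

Processing and extraction-efficiency assessment for direct-infusion
mass-spectrometry (DI-MS) shotgun lipidomics.

## The problem

High-throughput lipidomics extracts lipids from biological samples (milk,
serum, tissue homogenates) in 96-well plates and infuses them directly into a
high-resolution mass spectrometer — no chromatography, one centroided
spectrum per sample per ionisation mode. Comparing extraction protocols
objectively requires (i) a reproducible way to turn raw peak lists into a
quality-filtered intensity matrix and (ii) a quantitative definition of
extraction efficiency. `dimslipids` implements both for R users working with
DI-MS data: analysts benchmarking extraction chemistry, and developers of
lipidomics processing pipelines who need a tested reference implementation.

## The method

**Annotation.** Sum-composition lipid species — `Class(C:D)`, e.g. `PC(32:0)`
— are enumerated per class from carbon/double-bond ranges; molecular formulas
follow linear backbone rules (diacyl-PC: C<sub>c+8</sub>
H<sub>2c−2d+16</sub>NO₈P), monoisotopic masses are summed from CODATA atomic
masses, and adduct shifts ([M+H]⁺, [M+NH₄]⁺, [M+Na]⁺; [M−H]⁻, [M+CH₃COO]⁻)
yield the expected m/z per polarity (~8.5k entries under the default
configuration). Peaks are assigned one-to-one to the nearest target by
absolute ppm error.

**Variable acceptance.** A variable (one species + adduct + polarity column)
is discarded when any rule fails:

* mass error > 9 ppm (no peak within tolerance);
* median signal/noise < 3;
* signals in fewer than 50% of study samples;
* Pearson correlation between QC intensity and QC dilution level
  (0.25/0.5/1.0×) below 0.75.

**Normalization.** Surviving intensities are divided by their sample's total
signal and expressed per mille (‰); zeros mean "not measured".

**Efficiency.** Extraction methods are compared by (1) the number of
variables identified, (2) the total uncorrected signal strength (mean ± sd
over ~20 replicates, Welch tests between methods), and (3) precision,
measured as the per-variable coefficient of variance CV = 100·sd/mean within
replicate groups, stratified into 0–10 / 10–20 / 20–30 / 30–50 / >50% bins.
Methods are ranked lexicographically (variables, then signal). PCA of the
normalized profiles visualises group structure.

A synthetic experiment generator with analytic ground truth (class profiles
per matrix, class-wise method recoveries, log-normal noise, dropout, a
detection floor, QC dilution series, blanks, both polarities) makes every
stage testable without instrument data.

## Worked example

```r
library(dimslipids)

tl <- build_target_list(polarity = "+")   # 5073 positive-mode entries
head(tl[, c("variable_id", "formula", "expected_mz")], 3)
#> 1 Chol [M+H]+   C27H46O        387.
#> 2 Chol [M+NH4]+ C27H46O        404.
#> 3 Chol [M+Na]+  C27H46O        409.

res <- run_pipeline(simulation_config(seed = 42), out_dir = "run")
tidy(res$polarity$pos$cascade)
#>   stage        candidates removed surviving
#> 1 annotation         5073    4715       358
#> 2 snr                 358     123       235
#> 3 presence            235     101       134
#> 4 qc_linearity        134      19       115

res$ranking[res$ranking$matrix == "serum", ]
#>   matrix polarity  rank method n_variables_mean total_signal_mean
#> 1 serum  +            1 DMT               102.            538033.
#> 2 serum  +            2 TBME               98.3           471478.
#> 3 serum  +            3 BuMe               95.9           368005.
#> 4 serum  +            4 XMI               90              255130.
```

Reading the output: of the 5073 positive-mode targets, 358 had a matching
peak somewhere in the simulated plate; the signal/noise, presence and
QC-linearity rules then reduced them to 115 accepted variables. In the serum
matrix the aqueous chlorinated-solvent method (DMT) yields both the most
variables (~102 per injection) and the highest total signal, so it ranks
first — the ordering the simulator's recovery parameters encode. `run/`
contains the peak tables, matrices, filter reports, CV strata, PCA scores,
ranking and a JSON run manifest with file hashes for reproducibility.

Figures: `plot_efficiency()`, `plot_class_abundance()`, `plot_cv_strata()`
and `autoplot()` on a `dims_pca` fit.

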