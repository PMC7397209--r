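---
title: "Processing DI-MS shotgun lipidomics and scoring extraction efficiency"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Processing DI-MS shotgun lipidomics and scoring extraction efficiency}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dimslipids)
library(dplyr)
```

## Scope and model

Direct-infusion MS produces, per sample and ionisation mode, one centroided
peak list: (m/z, intensity, noise). `dimslipids` starts there — peak picking
from raw spectra is out of scope — and carries the data through annotation,
variable acceptance, per-mille normalization and the three-layer efficiency
assessment (variable counts, total signal strength, CV stratification), with
PCA for group structure. Species are handled at sum-composition resolution
only: `PC(32:0)` is "a phosphatidylcholine with 34 acyl carbons and 0 double
bonds in total"; no isomer or chain-level identification is attempted, and
like species observed under different adducts are deliberately kept as
distinct variables because their response factors differ.

## The target list

Formulas are linear in total acyl carbons $c$ and double bonds $d$ per class
(diacyl-PC: $\mathrm{C}_{c+8}\mathrm{H}_{2c-2d+16}\mathrm{NO_8P}$; TG:
$\mathrm{C}_{c+3}\mathrm{H}_{2c-2d+2}\mathrm{O_6}$; see
`lipid_class_rules()`), with cholesterol as a fixed-formula species.
Monoisotopic masses are sums of CODATA/IUPAC atomic masses embedded to seven
decimals; two invariants pin the arithmetic down exactly — homologue spacing
of 28.0313 Da per C$_2$H$_4$ and 2.0157 Da per double bond. Adduct m/z is
$(M + \delta)/z$ with $z = 1$ throughout (multiply charged lipid adducts are
not observed under these infusion conditions) and $\delta$ including the
electron mass. The adduct set — protonated, ammoniated, sodiated;
deprotonated and acetate — is what an ammonium-acetate infusion buffer
supports.

The default class ranges were chosen so that (a) no composition violates
$d \le c/2$, which keeps entry counts exact products of the range sizes, and
(b) both polarities together hold 8,455 entries — the scale of a typical
DI-MS annotation list. The published lists this emulates are not public; the
configuration is therefore a documented, editable stand-in, and every test
asserts against the configuration's own combinatorics, never against a magic
count.

## Annotation

Each target is matched to the nearest peak by absolute ppm error, one-to-one,
using a sorted window search (`findInterval`) followed by a greedy assignment
in ascending $|\mathrm{ppm}|$ with ties broken towards the lower expected
m/z. The greedy order makes the assignment identical to repeatedly taking the
globally best remaining pair, which is what the test suite's exhaustive
all-pairs oracle does on random instances. A relative guard of $10^{-12}$ on
the search window and $10^{-6}$ ppm on the tolerance comparison keeps peaks
lying exactly on the 9 ppm boundary inside the accepted set regardless of
floating-point rounding; 9.5 ppm is rejected by a wide margin.

## The acceptance rules and their conventions

The four discard rules are variable-wise and combined by OR, so the cascade's
surviving set equals the intersection of the per-rule survivors (a tested
property; stage order only affects the bookkeeping of which rule is credited
with a removal). Boundary conventions follow the printed strict inequalities:
S/N **< 3** discards (exactly 3 passes), presence **< 50%** discards (exactly
half passes), mass error **> 9 ppm** discards, QC correlation **< 0.75**
discards (exactly 0.75 passes, with a $10^{-9}$ floating-point guard).

Decisions the rules' one-line definitions leave open, and what this package
does:

* **S/N aggregation.** Noise is per peak; the filter summarises per variable
  by the median S/N over samples where the variable was measured. The median
  is insensitive to a few saturated or noisy injections.
* **Presence denominator.** Blanks and QC injections are excluded: a lipid
  genuinely present in every study sample would otherwise be penalised for
  being absent from blanks. A `eligible_roles` argument exposes the choice.
* **QC gating.** QC reference materials differ per biological matrix. The
  default (`qc_mode = "per_material"`) computes the intensity-vs-level
  Pearson r within each material and accepts a variable that is linear in at
  least one material where it is measured; `"pooled"` computes one r over all
  QC injections. Pooling mixes materials with different base abundances and
  systematically depresses r for matrix-specific lipids, which is why it is
  not the default. Variables with zero variance across QCs have undefined r
  and are discarded.
* **Correlation type.** Pearson on raw intensities versus the nominal
  dilution factor — the statement being tested is that signal is linearly
  proportional to abundance, which is exactly Pearson's null.

## Normalization and the efficiency layers

Per-mille normalization divides each measured value by its sample's total
accepted signal and multiplies by 1000; every row with any signal sums to
1000‰ (machine precision), zeros stay zero, and all-zero rows are rejected by
name. Variable counts are zeros-excluded and invariant under normalization;
total signal strength is always reported from the *uncorrected* (raw) matrix,
since normalization erases exactly the between-method differences the metric
exists to show.

CV is $100 \cdot s/\bar{x}$ with the $n-1$ standard deviation, computed on
normalized values within replicate groups of 16–20. A variable measured in no
more than half of a group's replicates is excluded from that group's CV
(zeros-as-missing makes a CV over a mostly-missing vector a detection
statistic, not a precision statistic); the excluded count is reported. Strata
are half-open $[lo, hi)$ bins with breaks 10/20/30/50% and an open last bin —
a CV of exactly 10 falls in 10–20% — and fractions always sum to 100% over
defined CVs.

Group comparisons use the two-sided Welch $t$-test by default (robust to
unequal variances at these replicate counts; Mann–Whitney available via
`test = "wilcoxon"`), with significance tiers `^` ($p<0.05$), `*` ($p<0.01$),
`**` ($p<0.001$), all strict.

Methods are ranked per matrix and polarity lexicographically: mean variable
count first, mean total signal second. Exact ties are declared ties; when the
two criteria disagree in direction between adjacent methods the cell is
flagged `conflict = TRUE` rather than silently resolved, because the two
criteria measure different things (coverage versus recovered mass) and a
practitioner should see the tension.

## PCA

`dims_pca()` centres (default: also unit-variance scales, the common
metabolomics choice) and decomposes by SVD via `stats::prcomp`; the tests
verify it against an independent eigendecomposition of the covariance matrix,
up to the inherent per-component sign indeterminacy. Zeros are treated as
zero abundance by default; `zero_handling = "half_min"` offers the common
half-minimum imputation. Constant variables are dropped with a message
(under unit-variance scaling they would divide by zero); an all-constant
matrix is rejected as degenerate. Group separation is summarised by the mean
silhouette width (`cluster::silhouette`) in score space.

## The synthetic experiment generator

The generator emulates the study design the pipeline targets: four biological
matrices × four extraction methods × 20 replicate measurements (split over 4
subtypes per matrix), QC dilution series at 0.25/0.5/1.0× with 3 injections
per level and material, blanks, and two ionisation modes.

The intensity model is deliberately minimal:

$$I = \underbrace{a_{s,m}}_{\text{base abundance}} \times
      \underbrace{\rho_{\mathrm{method}}(\text{class})}_{\text{recovery}} \times
      \underbrace{e^{\varepsilon},\ \varepsilon \sim N(0, \sigma^2)}_{\text{multiplicative noise}},$$

dropped with a per-method Bernoulli probability, and *emitted as a peak only
if $I$ reaches the noise floor*. The floor plays two roles: it is the
per-peak noise estimate (so S/N is intensity/floor) and the detection limit.
The detection limit is what couples extraction recovery to variable counts —
a weaker method pushes low-abundance species below the floor — without any
extra parameter; it is the mechanism behind the count differences the
efficiency ranking detects. Observed m/z is jittered by a *bounded* uniform
error (default ±3 ppm) rather than a Gaussian so the 9 ppm boundary behaviour
is exactly testable. Two polarities arise from class-wise ionisation
preferences (glycerides and sterols ≈ 95–98% positive, PE mostly negative),
and adduct intensities follow fixed within-polarity weights.

Parameter defaults and why:

* **Milk profile**: TG 93.1%, DG 4.9%, PC 1.2%, PE 0.4%, SM 0.3%, sterols
  0.1% — fixed by the two stated constraints, glycerides ≈ 98% of milk signal
  and phospholipid:triglyceride = 1:49. Serum/liver/heart profiles are
  plausible tissue compositions, documented as invented and fully
  configurable.
* **Method recoveries**: the aqueous-wash methods (DMT 0.90, TBME 0.85/0.70
  for neutral/ionic classes) above the non-aqueous ones (BuMe 0.65,
  XMI 0.50), with dropout 0.04–0.15 — encoding the qualitative ordering the
  efficiency assessment should recover, with the ethereal solvent penalised
  on ionic phospholipids.
* **Noise** $\sigma = 0.25$ (log scale), giving a true per-variable CV of
  $100\sqrt{e^{\sigma^2}-1} \approx 25\%$, the middle of the realistic
  stratification range; **panel** of 15 species per class with geometric
  abundance decay 0.7 (≈ 2 orders of magnitude within a class, so some
  species sit in the stochastic detection zone); **floor** 100 against a
  per-sample total of $10^6$.
* **QC injections** carry no dropout (pooled reference extracts) and scale
  exactly with the dilution level, so in the $\sigma \to 0$ limit every
  variable that reaches the QC stage passes it — a tested identity.

Ground truth is analytic: expected variable count sums
$(1-\text{dropout}) \cdot P(I \ge \text{floor})$ over panel variables via the
log-normal CDF; expected total signal is the recovered-material expectation
$\sum a\rho\, e^{\sigma^2/2}$, which deliberately excludes dropout and
detection censoring so it stays exactly linear in recovery (it serves ratio
and monotonicity checks, not absolute prediction).

What the simulator does **not** model — and hence what passing tests do not
establish about real data: ion suppression and matrix effects, isotope
envelopes, in-source fragmentation, correlated (batch/drift) noise,
heteroscedastic per-variable CVs, and isobaric overlap beyond what the target
list itself produces. Conclusions about the pipeline's correctness transfer;
conclusions about instrument behaviour do not.

## Problem sizes and reproducibility

The shipped tests exercise the default full design (360 injections, 8,455
targets) end to end once, and run the property suites on reduced designs
(2 matrices × 2 methods, compact target lists) chosen to keep the whole suite
in a few minutes on one core. The recovery benchmark uses 100 seeded
repetitions of a 2-method × 2-matrix × 20-replicate design in which method
A's recoveries are exactly 1.5× method B's; recovery ratios are estimated per
class from mean raw class signal in each class's better-measured polarity
(per-mille normalization cancels a uniform recovery factor, and estimating a
poorly-ionising class in its weak mode is biased upward by detection
censoring — PE in positive mode being the textbook case).

Every stochastic component flows from a single integer seed: the simulator
seeds R's Mersenne–Twister locally (restoring the caller's RNG state), and
identical configuration plus seed reproduces byte-identical pipeline output,
which the run manifest's MD5 hashes make checkable.

## Known limitations

* One-to-one peak↔target assignment cannot represent a single unresolved peak
  shared by true isobars; at DI-MS resolution such overlaps are instead kept
  apart by the 9 ppm tolerance or absorbed into the nearest target.
* The QC per-material gate accepts a variable that is linear in any one
  material; a variable linear in milk but saturated in serum is retained.
* The efficiency ranking's lexicographic rule is a documented convention; the
  conflict flag, not the rank order, is the honest output when count and
  signal disagree.
* TSV is the only interchange dialect (tab, decimal point, UTF-8); vendor raw
  formats and mzML are out of scope.
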