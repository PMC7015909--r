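---
title: "Methods: SILAC-PRM kinome quantification and the quartile survival screen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SILAC-PRM kinome quantification and the quartile survival screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The measurement model

Parallel-reaction monitoring (PRM) quantifies a predefined set of tryptic
peptides by monitoring all fragment ions of each precursor and extracting
per-transition chromatograms (intensity versus retention time in a narrow
m/z window). Combined with SILAC metabolic labeling — light cells with
normal lysine/arginine, heavy cells with [13C6,15N2]-lysine and
[13C6]-arginine — each peptide appears as a co-eluting light/heavy pair
whose area ratio estimates the relative protein abundance between the two
cell states. `prmkinome` implements this workflow for kinome-scale
libraries (up to four peptides per kinase, 4–6 y-ion transitions per
peptide, at most one missed cleavage) and the downstream analyses: label
swap reconciliation, protein-level fold changes with RSD-based calls, a
cross-pair kinome matrix, and a quartile-stratified logrank survival
screen.

## Mass arithmetic

All masses are monoisotopic. A peptide's neutral mass is the sum of its
residue masses plus one water; y-ion m/z is
\((\sum_{\text{C-terminal } n \text{ residues}} m_r + m_{\mathrm{H_2O}} + z\,m_\mathrm{p})/z\)
with proton mass 1.007276 Da. Heavy-channel masses add +8.014199 Da per
lysine and +6.020129 Da per arginine (the exact isotopologue increments);
since tryptic peptides end in K/R, every y ion carries the label. Fixed
modifications are a configurable table, defaulting to carbamidomethyl
cysteine (+57.0215 Da): the filter-aided sample preparation that precedes
such experiments alkylates cysteines, although quantification ratios are
insensitive to this choice because both channels shift identically.
Fragment-ion matching uses a symmetric ±20 ppm window
(`ppm_window()`), the usual Orbitrap mass-accuracy gate.

# The synthetic experiment

Real PRM raw data are instrument-vendor binaries; the package instead
ships a generator whose output has the same structure as transition-level
chromatogram exports, with known ground truth so every downstream stage
can be tested quantitatively. `sim_config()` defaults define the study
conditions:

| parameter | default | why |
|---|---|---|
| `n_proteins` | 50 | enough proteins for stable regression/QC statistics while the full demo stays in seconds |
| `peptides_per_protein` | 1–4 | library design: up to four most abundant peptides per kinase |
| `transitions_per_peptide` | 4–6 | the 4–6 most abundant y ions per peptide |
| `peak_sigma`, `cycle_time` | 5 s, 2 s | ≥ 10 points per elution peak, adequate for trapezoidal integration |
| `abundance_log10_range` | 4 | targeted kinome assays span about four orders of magnitude of signal |
| `ratio_log2_sd` | 1.0 | roughly half the proteins exceed the 1.5-fold cutoff, matching the observed prevalence of differential kinase expression between matched primary/metastatic lines |
| `noise_relative_sd` | 0.25 | per-point multiplicative log-normal CV; see below |
| `baseline_level` | 1 | constant electronic/chemical background |
| `interference_fraction` | 0.10 | a minority of peptides suffer co-isolated matrix interference in whole-lysate digests |

Each peptide's transitions share one Gaussian apex and sigma across
transitions and channels — co-elution is physical in PRM, and interference
is deliberately the only mechanism that breaks profile agreement. The
peptide abundance is split between channels as
\(A_\mathrm{light} = A/(1+\rho)\), \(A_\mathrm{heavy} = A\rho/(1+\rho)\)
where \(\rho\) is the heavy/light ratio implied by the protein's true
log2(metastatic/primary) ratio and the labeling scheme; the reverse scheme
uses exactly \(1/\rho\), so forward × reverse = 1 holds identically in the
noiseless limit. Abundances are log-uniform over the configured range, so
the realized dynamic range of summed areas reaches the configured orders
of magnitude up to edge losses.

**Noise.** Each sampled point (signal + baseline) is multiplied by a
log-normal factor with unit mean and CV `noise_relative_sd`. With ~9
effective points per peak this yields area CVs near
\(0.25/\sqrt{9} \approx 8\%\) and replicate-level protein-ratio RSDs of a
few percent. Real whole-lysate PRM shows replicate RSDs near 17%,
dominated by sample preparation and biology rather than integration
noise; point-wise noise cannot reproduce that without destroying the
chromatography, so the generator is honest about what it emulates
(detection and integration noise) and what it does not (between-replicate
biochemical variability, retention-time drift, missing channels). Passing
tests therefore validate the estimator chain, not instrument-level
realism.

**Interference.** A configurable fraction of peptides receives an extra
Gaussian peak on a random subset of transitions of one channel, offset
3–6 sigmas from the true apex, with height five times the affected
channel's summed apex. This is the canonical failure mode of targeted
quantification in complex matrices, and it is what the dotp and
co-elution gates exist to catch.

# Quantification

For each peptide and channel the transitions are summed and the peak is
detected on the baseline-subtracted summed trace (baseline = median of
the trace; valid because the peak occupies a small fraction of the
scheduled window). The apex is the global maximum; boundaries are placed
where the trace first falls to 5% of the apex or reaches a local minimum,
whichever comes first, capped at ±4 estimated sigmas (sigma from the
FWHM). The integration window is taken from the channel with the larger
apex and applied to both channels, so light and heavy areas always cover
the same retention-time interval — the standard treatment for SILAC
pairs. Each transition is integrated by the trapezoidal rule above a
per-trace baseline (median intensity outside the window, clamped at
zero).

Quality gates, replacing the manual inspection step of interactive
tools:

* **dotp** — cosine similarity between the vector of integrated
  transition areas and the library's relative intensities, after unit
  normalization. It is scale-invariant, equals 1 for proportional
  vectors, and both channels must reach `dotp_min = 0.7`. Requiring both
  channels is the stricter of the possible readings; dotp is computed on
  areas rather than point-wise intensities (an equally defensible
  alternative) because areas are what the ratio uses.
* **co-elution** — the maximum pairwise apex difference across all
  transitions of both channels must be at most `rt_tolerance`
  (inclusive; default 5 s = one peak sigma). Per-transition apexes are
  estimated as the intensity-weighted RT centroid inside the shared
  window: the raw per-point argmax of a weak noisy transition jitters by
  several cycle times and would fail clean peptides, while the centroid
  is robust. Transitions contributing less than 5% of their channel's
  largest transition area carry no usable RT information and are
  excluded from this test.

The peak detector keeps a single candidate (the global apex) rather than
re-scoring alternative peaks by dotp. Candidate re-scoring can silently
rescue interference-corrupted peptides by integrating around the wrong
peak that happens to score well; with a single candidate, corruption
surfaces as a gate failure (`low_dotp` or `no_coelution`), which is the
behavior a reviewer of targeted data wants.

The peptide ratio is the summed heavy area over the summed light area
("sum of peak areas from all transitions... no other adjustments"). On
noiseless synthetic data this estimator is exact to machine precision
across the full four-order abundance range, because baseline subtraction
removes the only source of bias and both channels share shape and
window.

# Label-swap reconciliation and protein calls

Measured heavy/light ratios are oriented to a common
log2(metastatic/primary) axis: `+log2(ratio)` under forward labeling
(heavy = metastatic), `−log2(ratio)` under reverse. QC metrics over
peptides shared between schemes: the **consistency fraction** (same sign
of oriented log2, exact zeros counting as consistent — a measure-zero
convention) and the squared Pearson correlation **R²**. Both are exactly
1 in the noiseless limit and degrade gracefully with noise.

Protein roll-up averages peptide log2 ratios within each replicate, then
across replicates; log-scale averaging is symmetric under ratio
inversion, which matters for a label-swap design. The **RSD** is the
sample SD over mean (n−1 denominator) of the *linear-scale* replicate
protein ratios, in percent, undefined with a single replicate. Calls use
a 1.5-fold cutoff on the mean log2 — the cutoff that replicate RSDs of
kinase quantification motivate — with no per-protein p-value and no
multiple-testing adjustment, reproducing the screen's decision rule
as-is. The kinome matrix keeps only proteins quantified in every
cell-line pair; class counts tally all quantified proteins per pair by
kinase class (protein / lipid / nucleotide / carbohydrate / other).

# The survival screen

For each gene, samples are ranked by expression and the top and bottom
`ceiling(n/4)` form the high and low groups (ties broken by sample
identifier — the exact tie rule of public survival portals is
undocumented, so determinism is prioritized; group membership is
invariant under permutation of the input). Kaplan–Meier curves use the
product-limit estimator, and the two groups are compared with the
standard two-group logrank test — \((\sum(O-E))^2/\sum V\) with
hypergeometric expectations and variances, referred to chi-square with
1 df — computed via the `survival` package and verified in the test
suite against an independent brute-force summation. Zero total variance
(e.g. no events) is reported as statistic 0, p = 1, with a degeneracy
flag. P-values are deliberately unadjusted, so on null data about 5% of
genes are significant at α = 0.05; the tests verify exactly this
calibration. The reported direction (+1 = high expression protective) is
the sign of expected-minus-observed deaths in the high group, which is
always defined, unlike differences of possibly-undefined median
survivals.

# Numerical and degenerate-input conventions

* Boundary convention: co-elution and ppm windows are inclusive.
* `detect_peak` requires ≥ 5 points and returns nothing for flat traces,
  which `quantify_peptide` maps to a `missing_channel` failure (as do
  zero summed areas in either channel).
* An all-zero observed area vector has dotp 0 by definition; an all-zero
  library vector is a validation error.
* Empty integration windows integrate to 0.
* Constant-expression genes cannot be quartile-split and are excluded
  from the screen with `NA` p-values.
* All generator randomness flows from a single integer seed; two runs
  with the same configuration are bit-identical, and `run_demo()` output
  files are byte-identical across runs with the same seed.

# Problem sizes

The packaged demo simulates 50 proteins (~125 peptides) per cell-line
pair, three pairs with 2/1/1 replicates per labeling scheme (eight runs),
and a 200-sample survival cohort with 150 null genes plus one planted
driver (hazard ratio 3 between expression halves). The test suite uses
the same scale, with 1000 random peptides for the mass cross-check and
1000 null genes for screen calibration. These sizes give stable
statistics (binomial SE on a 5% rate at n = 1000 is 0.7%) while keeping
the whole pipeline interactive.

# Known limitations

* Replicate-level RSDs are smaller than in real whole-lysate
  experiments, as discussed under **Noise**.
* No retention-time drift between runs, no missing-channel dropout other
  than interference, no scan-level (mzML) synthesis, no b/precursor
  ions, neutral losses, or isotope envelopes.
* The dotp here is the plain cosine; interactive tools do not publish
  their exact transform, so the 0.7 gate is applied to a deliberate,
  possibly non-identical stand-in with the same invariances.
* The screen makes no claim about which direction real genes show; on
  public tumor data, direction is a biological finding, not a property
  of the method.
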