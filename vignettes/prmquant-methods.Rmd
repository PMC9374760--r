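---
title: "Absolute protein quantitation with prmquant: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Absolute protein quantitation with prmquant: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prmquant)
library(data.table)
```

## The measurement model

Targeted mass spectrometry with stable-isotope dilution (SID) measures the
absolute amount of a peptide by comparing the chromatographic peak areas of
the endogenous ("light") peptide with those of a spiked, quantitated,
heavy-isotope-labeled synthetic standard. The two forms are chemically
identical and co-elute, so instrument response cancels in the ratio. For one
peptide in one LC-MS run the estimator is

$$\mathrm{ratio} = \frac{\sum_{t \in C} A^{light}_t}{\sum_{t \in C} A^{heavy}_t},
\qquad \mathrm{fmol}_{light} = \mathrm{ratio} \times \mathrm{fmol}_{heavy},$$

where $C$ is the set of *common transitions*: fragment ions present and
flagged quantitative in **both** labels. Precursor (MS1) signals are never
used for quantitation. Summing areas before dividing weights each transition
by its intensity, which is what makes the ratio robust to weak transitions.

Copies per cell follow from the protein load of the injection and the bulk
protein mass per cell (BCA measurement; 230 pg/cell for bone marrow-derived
macrophages, 136 pg/cell for RAW264.7 cells):

$$\mathrm{copies/cell} = \frac{\mathrm{fmol} \times 10^{-15} \times N_A}
{\mathrm{\mu g\ injected} \times 10^{6} / \mathrm{pg\ per\ cell}}.$$

With 1 µg injected and 230 pg/cell, 1 fmol/injection is about
1.385×10⁵ copies/cell.

## Bleed-through correction

Heavy standards carry a small light impurity ("bleed-through"), visible as a
light/heavy ratio in blank runs that contain standards but no cell material
(observed range 0–1%). `estimate_bleedthrough()` takes the blank ratio per
peptide — level-matched when blanks exist at several spike levels, since the
impurity scales with the spike, with the pooled mean as fallback (both modes
are exposed) — and `correct_bleedthrough()` subtracts
$b \times \mathrm{fmol}_{heavy}$ from the raw light fmol. When the
bleed-through exceeds 20% of the light abundance the measurement is discarded
rather than corrected, so corrected values can never be negative. Peptides
whose light signal in blanks is a deliberate spike (the luciferase control,
see below) are excluded from bleed estimation: for them the blank ratio
measures the spike, not impurity.

## Quantitation Quality

Each (peptide, run) pair is classified `Good` unless any rule fires, in which
case it is `MaybePoor`:

* quantitated common transitions ≤ 2;
* summed peak area below the sensitivity floor of 10 000 — read
  disjunctively: *either* label's sum below the floor triggers the rule;
* an extreme ratio relative to the nominal spike level: heavy = 1 fmol and
  light > 10 fmol; heavy = 10 fmol and light > 500 fmol; heavy = 100 fmol and
  light < 2 fmol. The rules key on the *nominal* level, not the measured
  heavy amount, because they encode where each dilution point saturates or
  starves. At spike levels outside {1, 10, 100} no extreme-ratio rule fires.

Within one biological replicate, if a peptide has at least two `Good`
measurements, all `MaybePoor` measurements are dropped; otherwise both
classes are kept. "At least two" is the only monotone reading of "two
quantitation values" — having a third `Good` value must not reinstate the
poor ones.

## Replicate aggregation

All aggregation uses geometric means, the natural choice for positive,
multiplicatively-noisy quantities. Measurements are first normalized to fmol
per µg of injected cell protein so that the stable-isotope dilution series
(spike levels 1, 10, 100 fmol) can be pooled with the LC-MS technical
duplicates: up to 6 replicates per biological replicate. RADM
(`|x − mean| / mean`, with the arithmetic mean) and the technical CV are
recorded at this level; the geometric mean across the biological replicates
gives the peptide value and the biological CV.

Multiple quantified forms of one peptide (unmodified, oxidized, missed
forms) are merged: forms flagged as redundant lower-abundance forms are
dropped, the rest are summed. Peptides that are not unique to their target,
have low-confidence identifications, or are PTM-confounded are discarded
with logged reasons. The protein value is the geometric mean across its
retained peptides, with a peptide-to-protein consistency class from the
maximum pairwise fold difference — the thresholds (< 2× consistent, ≤ 4×
semi-consistent, > 4× inconsistent) are defaults and config-exposed, since
the original figure-level criteria are not printed. Inconsistent peptides
are retained in the geometric mean by default (the protein is only flagged);
an option excludes the worst outlier instead. Zero or negative corrected
values are discarded (with a reason) before any geometric mean, whose log is
otherwise undefined.

## The synthetic world

`generate_truth()` / `simulate_transitions()` implement the forward model the
estimator inverts, with defaults set to the stated experimental conditions,
not tuned to tests:

* true abundances log-uniform over 1,332 – 2.27×10⁸ copies/cell (the
  observed span; the generating *distribution* is a modeling choice — the
  data source does not state one);
* two peptides per protein, five transitions each, response factors
  log-uniform over two decades (a few transitions dominate, as in practice);
* technical CV 0.15 and biological CV 0.10 (the reported ~15% / ~10%);
* bleed-through uniform on [0, 0.01] (the reported 0–1% range);
* the dilution design: blanks at each nonzero level analyzed once, every
  (biological replicate × level) sample analyzed in duplicate — 11 samples,
  19 runs at the default levels {0, 1, 10, 100} fmol;
* firefly luciferase as a spiked positive control present in every sample at
  20 fmol/injection (1 pmol in the 50× preparation), simulated as an
  ordinary protein with known light amount and no biological noise.

**Noise placement.** Technical noise is lognormal and *shared across the
transitions of a peptide within one run and label* — injection-to-injection
variation dominates transition-level noise, and this keeps the
common-transition ratio well-defined. Each label receives an independent
lognormal factor with per-label log-variance `log(1+cv²)/2`, so that the
light/heavy *ratio* has CV exactly `tech_cv`: the reported ~15% technical CV
is a CV of ratio-derived abundances, and putting independent 15% noise on
each label would inflate the ratio CV to ~21%, contradicting the stated
parameter. A further shared injection-scale factor varies the raw areas but
cancels in the ratio. All lognormal factors have median 1 (log-mean 0), so
geometric-mean aggregation is unbiased on the log scale. The bleed-through
term in the light area is noise-free; with all CVs at zero the pipeline
returns the truth exactly, which is the basis of the end-to-end identity
test.

**What the generator does not emulate:** chromatographic interference and
co-elution, retention-time drift, transition-level dropout and censoring at
the detection limit, saturation nonlinearity, and digestion variability. A
green recovery test therefore establishes that the *estimator* inverts the
stated statistical model correctly — not that the model captures every
failure mode of real LC-MS data.

**Mass accounting.** Blank totals obey `total = L + level·p` (luciferase
mass plus standards mass); `infer_standards_masses()` solves it by least
squares (exact with two levels) and `predict_total_mass()` reproduces the
design-table totals, which doubles as a consistency check of the design
arithmetic.

## Transcript-based proteome-wide estimation

`compute_tpm()` computes transcripts-per-million from gene-level counts and
effective lengths (`rate = count/length`, scaled to sum to 10⁶; gene-level
lengths as provided — no isoform aggregation is attempted). `fit_loglog()`
is ordinary least squares of log10(copies/cell) on log10(TPM) over genes
positive in both (zeros are excluded and counted — their treatment is a
package choice). The fitted line predicts copies/cell for every expressed
gene; genes at TPM = 0 are reported as not estimable. Base-10 logarithms
are used throughout. Prediction error is summarized by symmetric fold
errors, `max(m/x, x/m) ≥ 1`, via their mean, geometric mean and median.

`simulate_rnaseq()` inverts the line: it derives log10(TPM) from the true
copies plus a N(0, scatter) residual, renormalizes TPM to sum to 10⁶
(recording the resulting *effective* intercept, against which recovery must
be checked), and converts TPM to integer counts through random effective
lengths and a library size. Two numerical consequences are worth stating.
First, integer rounding (the default, since reads are integers) breaks
exact-recovery identities; exactness checks use `round_counts = FALSE`.
Second, because the residual is attached to the *transcript* side during
inversion, it is correlated with the predictor, and OLS of copies on TPM on
such data is attenuated (regression dilution) — classical confidence
intervals cannot achieve nominal coverage there. The coverage test of
`fit_loglog()` therefore generates data in the regression-aligned direction
(exogenous TPM, copies = line + noise), which is the correct design for
testing the fitting code itself.

## Cross-dataset comparison

Two datasets are compared on copies/cell over their shared proteins: the
geometric mean of the per-protein A/B ratios should track the independently
measured bulk protein-mass ratio of the two cell types (e.g. 230/136 ≈ 1.69),
and `summarize_comparison()` reports both together with the log-log Pearson
correlation (OLS on log values; an orthogonal fit would also be defensible,
the choice is noted). The identity gm(ratios) = gm(A)/gm(B) and exact
antisymmetry under swapping A and B are tested properties.

## Peptide selection

`digest_tryptic()` applies the Keil rule (cleave after K/R except before P);
candidate evaluation distinguishes *hard* criteria — fully tryptic with no
missed cleavage and no internal KP/RP, and uniqueness to the target within
the I/L-collapsed proteome (peptides shared only within a declared homologue
group are allowed, for combined assays) — from *soft* "avoid/preferentially"
criteria: neighboring cleavage sites, multiple copies per protein copy,
length outside 5–20, modification-prone residues (C, M, N, Q, N-terminal
Gln) or protein termini or annotated PTM overlap, variant overlap, ortholog
compatibility, isoform coverage, and proteotypic evidence (accepted as an
input score; spectral libraries are not queried). The original ad-hoc
ranking score is unspecified, so the score here is a documented, weighted
count of soft failures (unit weights by default, configurable), with a
deterministic tie-break: length closest to 12.5 (the midpoint of the
preferred range), then lexicographic.

## Known limitations

* The QC extreme-ratio rules are tied to the {1, 10, 100} fmol level set;
  other designs fall back to the transition-count and area-floor rules only.
* Blank-based bleed estimation assumes blanks share the standards (and thus
  the impurity) of the samples; per-lot drift is not modeled.
* The mRNA–protein regression is a single global line; per-pathway or
  nonlinear structure is out of scope, and prediction errors above 10-fold
  for individual genes are expected from the reported scatter.
* Phosphopeptide data flow through the same pipeline and schema; site
  occupancy is not computed.
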