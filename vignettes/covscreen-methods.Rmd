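---
title: "Models and methods behind covscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind covscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(covscreen)
```

`covscreen` analyses competitive cysteine-profiling screens: covalent
fragments compete with a hyperreactive iodoacetamide-desthiobiotin (IA-DTB)
probe for cysteine thiols, and engagement is read out as a drop in the
MS intensity of the probe-labelled peptide. This vignette explains the
statistical models, the parameters that matter, the synthetic-data
generator, and the numerical choices — including where the design was
genuinely open and what we decided.

## From precursors to cysteine sites

DIA search engines export precursor-level intensities: one row per
(sample, modified peptide, charge). Precursors that differ only in charge
state or methionine-oxidation state are redundant observations of the same
peptide and are **summed** per sample (`collapse_precursors()`). Anything
else — a different stripped sequence, a different set of DTB-modified
cysteines, another variable modification such as N-terminal acetylation —
stays a separate quantity. Peptides with no DTB modification at all
(carbamidomethylated-only) are not part of the enriched cysteinome readout
and are dropped with a count.

Missingness is representational throughout: a peptide not detected in a
sample has no row, never a zero or a sentinel, and **no imputation is
performed anywhere**. The hit-calling filters below are the missing-data
policy.

Sites are keyed by (protein accession, 1-based cysteine residue index).
The peptide is located in the protein by exact substring match; a peptide
occurring more than once maps to the leftmost occurrence and carries an
`ambiguous` flag (deterministic, and the ambiguity stays visible), and an
unmappable peptide is flagged and excluded from site-level output. When
several cleavage forms (missed-cleavage variants) cover the same site,
only the most abundant is kept. "Most abundant" is not further specified
in the field's convention, so the default is the **highest mean intensity
over the samples where the form was detected** — robust to unequal
detection counts — with a summed-intensity alternative
(`most_abundant_total`) for sensitivity analysis. Exact ties break to the
shorter peptide, then lexicographically, so the choice is reproducible.

## Competition ratios and hit calling

Engagement is quantified as a competition ratio
`CR = I_DMSO / I_compound`. The printed quantity is the **mean log2 CR**,
which leaves two readings; the default (`cr_mode = "per_replicate_log"`)
computes one log-ratio per detected treated replicate against the control
mean and averages,

$$\overline{\log_2 \mathrm{CR}} = \frac{1}{n_t}\sum_{i=1}^{n_t}
  \left[\log_2 \bar I_{\mathrm{ctrl}} - \log_2 I_{\mathrm{trt},i}\right],$$

with `ratio_of_means` as the alternative. Significance is a two-sided
Welch's t-test of control vs treated intensities, by default on the
**log2 scale** — MS intensities are approximately lognormal, so the log
transform stabilises variance; the raw-scale option is retained because
the convention is not universal. Degenerate inputs follow fixed rules:
both groups constant and equal gives p = 1; constant and different gives
p = 0 with a `degenerate` flag.

A (compound, site) record is a **hit** only if

* `mean log2(CR) >= 1` (at least 50% competition) and
  `-log10(p) >= 1.3` (p <= 0.05), and
* none of the robustness flags is set: `low_treated_n` (< 2 detected
  treated replicates), `low_completeness` (detected in < 90% of *all*
  samples of the experiment — computed per `experiment_id` over the full
  design, controls and all compounds), `high_cv` (raw-scale CV of detected
  control replicates > 40%), `multi_dtb` (more than one DTB per peptide),
  `redundant_form` (not the selected cleavage form).

Fixed dual thresholds rather than FDR control are the screen's operating
convention; Benjamini-Hochberg q-values can be added as an extra column
(`report_qvalues = TRUE`) but play no part in the hit call.

## Concentration response

For dose-response designs, each peptide's per-concentration mean treated
intensity is expressed as a percentage of the mean control intensity and
fit against log10 concentration with the bounded variable-slope logistic

$$y(x) = E_\infty + \frac{E_0 - E_\infty}
  {1 + 10^{\,n\,(\log_{10}\mathrm{TE}_{50} - x)}},$$

with box constraints $60 \le E_0 \le 140$, $E_\infty \ge 0$,
$-50 \le n \le 0$, and $\log_{10}\mathrm{TE}_{50}$ within 3 log units of
the tested range. (The exponent is read as
$10^{\,n(\log_{10}\mathrm{TE}_{50} - x)}$; the typographically plausible
alternative — a constant factor $10^n$ — cannot produce a sigmoid in $x$
and is rejected.) The curve's midpoint satisfies
$y(\log_{10}\mathrm{TE}_{50}) = (E_0 + E_\infty)/2$ identically, and
`pTE50 = 6 - log10(TE50 [µM])` converts to molar units.

Fitting is box-constrained Levenberg-Marquardt (`minpack.lm::nlsLM`) on
the per-concentration means, unweighted. Initialisation is deterministic —
$E_0 = 100$, $E_\infty = 0$, $n = -1$, midpoint at the median tested
log-concentration — with a fixed ladder of fallback starts (data-driven
midpoint guess, shallower/steeper slopes at the quartiles) tried only if
the primary start fails or does not converge; the lowest-deviance
converged candidate wins. There are no random restarts, so fits are
reproducible. Standard errors come from the estimated parameter
covariance; parameters that end on a bound are flagged (`at_bound`) rather
than silently clipped.

Curve-quality filtering is genuinely open in the field, so the defaults
are this package's own operating point, all configurable: converged,
$r^2 \ge 0.8$, $\mathrm{se}(\log_{10}\mathrm{TE}_{50}) \le 1$, span
$E_0 - E_\infty \ge 30$ percentage points, midpoint no more than 0.5 log
units above the highest tested concentration, and at least 5
concentrations with data. Off-targets of a reference interaction are the
other passing sites with `pte50 >= pte50(ref) - 0.5`.

Recovery performance under the standard design (10-point two-fold series
200 → 0.39 µM, quadruplicate, 25 controls, intensity CV 25%) is
characterised in the test suite: median absolute pTE50 error is ≈ 0.10-0.15
depending on where the true midpoint falls in the series. A linearised
covariance analysis of the same estimator puts the asymptotic
$\mathrm{se}(\log_{10}\mathrm{TE}_{50})$ at 0.13-0.23 over true pTE50
4.5-5.5 — worst when the midpoint sits near the low end of the series and
few concentrations sample the top plateau — so the observed errors are at
the design's information limit, not an estimator artefact. Weighted
fitting would be more efficient under multiplicative noise but the
convention for this readout is unweighted means, which we follow.

## Selectivity

An interaction's selectivity is its value (mean log2 CR by default — log
scale keeps the deltas interpretable as fold-changes; raw CR optional)
minus the mean of the **five strongest other** interactions, computed both
across compounds at the same site (`delta_site`) and across sites for the
same compound (`delta_compound`); the score is the minimum of the two.
The record itself is excluded from both top-5 sets — the convention is
ambiguous, but self-exclusion makes a unique interaction maximally
selective instead of self-penalised. With fewer than five rivals the
available ones are used and counted (`n_used_*`); with none, the delta is
not computable and the record is flagged `unsupported` rather than scored
against an arbitrary zero. Two experiments (e.g. two cell-line lysates)
can be intersected by (compound, site), keeping the more conservative
score.

## Cysteinome and structures

In-silico tryptic digestion cleaves after K or R unless the next residue
is proline; the C-terminal peptide is always emitted. Two parameter
regimes matter and both are presets: **detectability classification**
(fully cleaved, 7-40 residues — the convention for calling a cysteine
MS-detectable) and **search-space emulation** (7-52 residues, up to two
missed cleavages, matching typical search settings). Detectability is
monotone in the length window by construction.

Pocket proximity consumes Fpocket output (run by the user with alpha-sphere
radii 3.0-5.0 Å) and a structure file: a cysteine is pocket-proximal when
its SG atom lies within 1.5 Å of the nearest alpha sphere. Whether that
distance is to the sphere *center* or *surface* is not standardised; the
default is the center convention, the surface convention
(distance − radius) is a flag, and the convention used is recorded in the
output so downstream consumers can tell them apart. Annotation tables
(PTM, disulfide, pPSE solvent exposure, IDG family and target development
level, protein abundance) are supplied by the user as TSVs and left-joined;
the package never downloads them, which keeps every analysis runnable
offline and pinned to the user's chosen releases.

## The synthetic-screen generator

`simulate_screen()` exists so that every downstream stage can be validated
against known ground truth. It emulates, with deliberately simple
mechanisms:

* **Design**: n = 4 treated vs n = 16 control replicates at a single 50 µM
  dose, or a 10-point two-fold dilution series (200 → 0.39 µM) in
  quadruplicate against n = 25 shared controls.
* **Intensities**: per-peptide baseline $\log_{10} I \sim N(4.5, 0.8)$;
  multiplicative lognormal noise with $\sigma^2 = \ln(1 + \mathrm{CV}^2)$
  so the raw-scale CV equals the configured value (default 0.25, the
  platform's replicate-CV regime).
* **Engagement**: a spiked (compound, site) pair at concentration $c$ has
  expected treated intensity
  $I_0 (1 - \mathrm{occ}(c) \cdot e_{\max})$ with
  $\mathrm{occ}(c) = c / (c + \mathrm{TE}_{50})$ — an equilibrium-style
  saturation model whose midpoint matches the fitted logistic. Every
  non-spiked pair has engagement factor exactly 1. One-hour-incubation
  kinetics are *not* modelled; this is an equilibrium simplification.
* **Detection**: intensity-dependent logistic,
  $P(\mathrm{detect}) = \mathrm{logit}^{-1}((\log_{10} I - 3.62)/0.30)$,
  i.e. missingness is MNAR-coupled to abundance, not uniform dropout. The
  midpoint 3.62 was calibrated once, analytically, so the expected mean
  pairwise Jaccard overlap of detected peptides between control replicates
  is 0.82 under the default baseline distribution (the completeness regime
  of the real platform); the resulting marginal detection is ≈ 0.86.
  `detect_midpoint = -Inf` forces complete detection for noiseless
  constructions.
* **Report shape**: each peptide is emitted as two charge-state precursors
  whose intensities sum to the peptide intensity, so the aggregation path
  is exercised end to end. Everything is deterministic given the seed.

What the generator does **not** reproduce — and what passing tests
therefore do not certify about real data: retention-time/ion-mobility
structure, interference and ratio compression, shared peptides across
proteins, reactivity differences between cysteines, batch effects, and
engagement kinetics. The simulator validates the *statistics*, not the
chromatography.

One consequence it does reproduce faithfully: strongly engaged,
low-abundance peptides fall below the detection midpoint in treated
samples and then fail the 90%-completeness filter — fully competed
peptides can vanish rather than appear as hits. The demo deliberately
leaves this visible instead of spiking only abundant peptides.

## Problem sizes and numerics

The validation suite runs at desk scale, chosen to keep the full suite in
the low minutes while leaving the statistical conclusions stable: null
screens of 5,000 sites × 10 compounds (≈ 50,000 records per seed) for the
specificity bound, 50 simulated screens for hit recovery, 50 seeds per
true pTE50 for dose-response recovery, 1,000 random inputs per oracle
comparison (Welch vs `stats::t.test`, digestion vs an independent
regex-based cutter), and 10 seeds for the detection-calibration check.
Tolerances: oracle agreement to 1e-10; noiseless 4PL recovery to 1e-3;
exact identities (intensity conservation, tie-breaks, flags) asserted
exactly.

Degenerate inputs have defined behaviour rather than errors wherever a
screen could plausibly produce them: empty record sets propagate as empty
tables; fewer than two detected controls skips a peptide with a logged
reason; zero treated detections yields a scored-but-unhittable record;
zero-variance Welch inputs follow the p = 1 / p = 0 conventions; a protein
with no pockets classifies all its cysteines as non-proximal with infinite
distance.

## Known limitations

* No protein inference or isoform remapping: sites are keyed to the
  accession the search engine reported.
* No normalisation is applied at read time (a median-normalisation switch
  exists but defaults off, since exported intensities are treated as
  final); systematic sample-loading differences should be handled upstream.
* The 90%-completeness filter is computed per `experiment_id` on the full
  sample table passed in — a literal reading; restrict the table first for
  per-subset analyses.
* Fpocket itself is not executed, and pPSE values are consumed, not
  computed.
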