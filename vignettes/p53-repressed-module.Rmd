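---
title: "Methods: screening, validating and characterizing a p53-repressed gene module"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening, validating and characterizing a p53-repressed gene module}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(p53repress)
```

This vignette is the package's account of its methods: the screening
criteria and their rationale, the synthetic-data model behind the test
suite, the numerical conventions, and the design choices made where the
procedure was genuinely open.

## The screening model

Genes repressed through p53 are harder to catalogue than induced genes:
repression is often indirect, cell-state dependent, and confounded by
proliferation arrest. The pipeline therefore demands *concordant*
repression across three orthogonal designs before a gene is even a
candidate, and three further experimental-style criteria before it joins
the module.

**Microarray ratio screen.** In a p53 wild-type (W) vs p53-null (K) cell
pair sampled at 0/12/24/48 h after an ADR pulse, a repressed target should
fall in treated wild-type cells and nowhere else. Per probe,

\[ A = \mathrm{median}(W_{12}, W_{24}, W_{48}), \qquad
   B = \min(W_0, K_0, K_{12}, K_{24}, K_{48}), \]

and the criterion is \(A/B < 0.5\), *strict*. The median over the three
treated timepoints tolerates one aberrant array; the minimum over the five
baselines is deliberately conservative — the treated signal must fall below
the *lowest* expression the gene ever shows without p53 activity. A probe
with \(B = 0\) has an undefined ratio; such probes are excluded from
evaluation with a logged count rather than treated as infinitely repressed.
Probe-level hits collapse to genes by the *any-probe* rule (a gene passes
if any of its probes passes), matching a probe-level filter feeding a
gene-level candidate list; a median-probe alternative is exposed as a
parameter.

**RNA-seq ratio screen.** The mouse design replaces the time course with
genotype × irradiation (W/WX/K/KX) per tissue. FPKM values contain zeros,
so a pseudocount of 1 is added to *every sample value before averaging* —
the order matters and is fixed by the stated procedure: with
\(A = \mathrm{mean}(WX + 1)\) and
\(B = \min(\mathrm{mean}(W+1), \mathrm{mean}(KX+1), \mathrm{mean}(K+1))\),
an all-zero gene has \(A = B = 1\) and ratio exactly 1, never a spurious
candidate. Candidate selection uses the mammary gland only; the remaining
tissues enter through `tissue_profile()`, which reports per-tissue log2
irradiated/control ratios for display.

**Cohort screen.** With tumors split by p53 mutation status, each gene gets
a two-tailed two-sample *t* test; an F test at 0.05 chooses the pooled or
Welch form (`variance_rule = "f_test_gate"`, with `welch_always` as the
alternative since the original global statement leaves the per-gene choice
ambiguous). A candidate needs \(p < 0.05\) *and* lower mean expression in
wild-type tumors. No multiplicity correction is applied — the downstream
intersection with two independent screens is the real false-positive
control, and the per-gene type-I rate of this screen is itself a tested
quantity (two-sided test × directional filter ≈ 0.025 under the null).
Zero-variance degenerate inputs are defined rather than erroneous: equal
constants give \(p = 1\), unequal constants \(p = 0\).

**Intersection.** Mouse candidates are translated through an ortholog map
before intersecting; symbols without orthologs are counted and reported,
never dropped silently. Symbols are case-normalized (upper for human,
capitalized for mouse) before any set operation.

## The ΔΔCt module call

Quantification follows the standard ΔΔCt scheme against a reference gene:
per replicate \(\Delta Ct = Ct_{target} - Ct_{ref}\), then
\(\Delta\Delta Ct = \overline{\Delta Ct}_{case} - \overline{\Delta Ct}_{ctrl}\),
\(\log_2 FC = -\Delta\Delta Ct\). Replicates are *not* paired across
conditions (group means), since the method statement implies no pairing
structure. The three stages:

1. **Panel**: repressed (\(\log_2 FC \le -2\), inclusive) in at least 2 of
   4 wild-type lines and 0 of 3 mutant lines. "Not in the mutant lines" is
   read at its strictest (`max_mut_lines = 0`), parameterized.
2. **Knockdown**: repressed under control siRNA + ADR *and* above the
   cutoff under si-p53 + ADR. Genes never repressed under the control arm
   are flagged vacuous, separately from ordinary failures.
3. **Exogenous p53**: repressed under Ad-p53 (vs untransduced cells) while
   the Ad-LacZ control stays above the cutoff. The LacZ gate is a design
   choice: a transduction-driven drop would confound attribution to p53;
   it is exposed as a toggle for the permissive reading.

Per-gene *t*-test p-values on ΔCt are reported for parity with
significance-marked figures but never enter the membership criteria, which
are threshold-based. The final call records, for every excluded candidate,
the first stage that removed it.

## TSS-window enrichment

TSS annotations carry one strand-aware TSS base per gene (0-based). A gene
is peak-positive within window half-width \(w\) iff any peak intersects
\([tss - w,\; tss + w + 1)\) — a ≥1 bp intersection rule on half-open
intervals, the simplest defensible convention, documented bit-exactly and
covered by boundary tests. Enlarging \(w\) can only add positives.

The two-sided Fisher p uses the probability-at-most-observed rule (the
convention of standard statistical software; mid-p and doubling variants
were considered and rejected), computed in log space via `lchoose` with a
\(1 + 10^{-7}\) relative tie tolerance. The test suite sweeps *every* 2×2
table with total ≤ 60 against an independent enumeration oracle built on
`choose()` ratios (maximum observed deviation ≈ 1e-14) and cross-checks
`stats::fisher.test`.

One bookkeeping subtlety is handled explicitly: in the reported
promoter/ADR configuration, the module percentage is printed over the 27
annotated module genes (1/27 = 3.7%) while the exact test is consistent
with the full 28-gene module as denominator ([[78,105],[1,27]] reproduces
the reported p = 1.54e-5 exactly; a 27-gene denominator does not). The
report API takes whatever gene sets are supplied and surfaces genes dropped
for missing annotation; `enrichment_from_counts()` takes counts as given so
both accountings can be reproduced.

## Survival analysis

Median dichotomization uses a fixed tie rule — strictly greater than the
median goes High, ties go Low — chosen once so results are reproducible
(the original leaves it unstated). Constant expression cannot be split and
is an error at the single-gene level; the module-wide screen catches it per
gene and reports `NA`. Kaplan–Meier estimation and the two-group log-rank
test stand on `survival::survfit`/`survdiff` (hypergeometric variance,
simultaneous-event tie convention); the package surface adds the
invariants, the direction call (restricted-mean survival comparison) and
the module-screen loop. The prognosis screen reports nominal p-values, as
in the original analysis; a Benjamini–Hochberg column is available but off
by default. The p53-status × High/Low association reuses the package's
exact Fisher test.

## The synthetic-data model

The generators exist so that every stage has a no-download test surface
with known ground truth. What they emulate, and deliberately do not:

* **Expression noise is lognormal** (multiplicative, sd `noise_sd_log`
  = 0.2 on the natural-log scale by default): abundances are positive and
  every screen criterion is scale-based. Real microarray/RNA-seq noise has
  heavier tails, probe effects and correlation structure that are not
  modeled, so passing recovery tests demonstrates criterion correctness,
  not robustness to real-data artifacts.
* **Planted effects are the study conditions**: fourfold repression
  (ratio 0.25 against the 0.5 cutoff), −3 log2 qPCR effect against the −2
  cutoff, a 28-gene module, 4 + 3 cell lines, a 795/298 wt/mut cohort,
  183 induced reference genes, promoter-peak probabilities (0.426, 0.037)
  matching the reported proportions. Within-condition variances are not
  reported anywhere in the source material, so the noise defaults are
  calibration choices of this package.
* **qPCR is simulated at the Ct level** (reference gene at 20 cycles
  nominal, targets 23–26, Gaussian cycle noise of 0.15 sd) so the ΔΔCt
  arithmetic — including reference normalization and replicate averaging —
  is genuinely exercised rather than short-circuited at the fold-change
  level.
* **Module genes are expressed by construction.** The RNA-seq generator
  keeps planted genes off the silent (all-zero) set and above ~5 FPKM: the
  pseudocount makes a fourfold drop invisible below ~2 FPKM, and a gene the
  screens could never see is not a meaningful planted truth. Null genes may
  be silent, exercising the pseudocount path.
* **Survival** uses exponential event times with uniform censoring — the
  simplest model with a controllable hazard ratio. A latent per-patient
  risk factor (hazard ratio 3 for its upper half) loads on 9 designated
  module genes (loading 0.3 on the log scale), so each prognostic gene's
  median split is marginally associated with survival while the remaining
  19 module genes are prognostically null.
* **One RNG stream per generator**, derived from the master seed by stable
  labels: adding a generator never perturbs the draws of another, and
  identical config + seed reproduces every dataset bit-identically.

## Numerical choices and problem sizes

* Strict `<` at the 0.5 ratio cutoffs and inclusive `≤` at the −2 log2FC
  cutoff, both boundary-tested.
* Fisher tie tolerance \(1+10^{-7}\) relative, matching common practice;
  the oracle sweep bounds the resulting error below 1e-12.
* The log-rank null-uniformity check simulates 60 patients per arm — large
  enough that the chi-square reference distribution of the statistic holds;
  at much smaller arms the discreteness of the statistic is visible to a
  Kolmogorov–Smirnov test at 500 replicates.
* Test-suite problem sizes: a 1000-gene universe with a 28-gene planted
  module for end-to-end recovery; 20-gene fixtures for oracle equivalence;
  a 4000-gene null cohort for the type-I-rate check; 500 null replicates
  and 200 power replicates (hazard ratio 3, 200/arm) for survival
  calibration.

## Known limitations

* The probe→gene collapse rule and the human–mouse ortholog mapping of the
  original analysis are unstated; both are explicit, parameterized
  components here, and the dataset-dependent candidate counts (1,739 / 373
  / 6,451 / 44 / 32 / 28 / 9) are not reproducible without the original
  GEO/DDBJ/TCGA/qPCR data — the synthetic planted-recovery properties stand
  in for them.
* No amplification-efficiency correction (Pfaffl), standard curves or
  melt-curve QC in the qPCR module; no peak calling, motif scanning or
  normalization upstream of the screens — expression and peak inputs are
  consumed as given.
* Cox modeling and hazard-ratio confidence intervals are out of scope; the
  survival module reports direction by restricted-mean comparison only.
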