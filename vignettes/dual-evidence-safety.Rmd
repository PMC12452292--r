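---
title: "Dual-evidence drug safety: disproportionality signals and drug-target MR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-evidence drug safety: disproportionality signals and drug-target MR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(signalmr)
```

## The question the pipeline answers

Spontaneous-report databases (FAERS and its kin) answer "is this adverse
event reported disproportionately often with this drug?", while drug-target
Mendelian randomization (MR) answers "does genetically proxied modulation of
the drug's target cause the outcome?". Neither source is sufficient alone —
reporting data carry duplication, stimulated reporting and confounding by
indication; MR rests on instrument validity assumptions — but when both
point the same way they make a far stronger safety case than either does
separately. The motivating use case is the neurocognitive safety of
PCSK9 inhibitors (evolocumab, alirocumab, inclisiran): memory-loss adverse
events on one side, variants in the PCSK9 cis region proxying LDL-C lowering
on the other, with coronary heart disease as the positive-control outcome
whose protective effect the instruments must reproduce before any outcome
analysis is trusted.

`signalmr` implements both arms as testable components around seeded
synthetic-data generators, so every stage — ETL, deduplication, the four
signal statistics, instrument selection, harmonization, the five MR
estimators — can be validated against known ground truth at desk scale,
without access to FAERS or any GWAS consortium.

## Spontaneous-report arm

### Deduplication

FAERS revisions of one case share a `CASEID`. The pipeline keeps, per
`CASEID`, the row with the latest `FDA_DT` (integer `YYYYMMDD`, compared
numerically — exact and locale-free) and breaks date ties by the highest
`PRIMARYID`. The operation is idempotent and order-independent; drug,
reaction and outcome rows of discarded versions are dropped with them.

### The 2×2 table and the four statistics

For a target drug set and target event set, the counting units of the
reporting universe are cross-classified as

|            | target event | other events |
|------------|--------------|--------------|
| target drug | a | b |
| other drugs | c | d |

with `n = a+b+c+d` and independence expectation `E = (a+b)(a+c)/n`.

* **Counting unit.** The default is *event-level*: each matched PT
  occurrence counts once, so a report listing two target PTs contributes
  two units. This mirrors the convention of safety tables that count more
  adverse events than patients (e.g. 389 events among 388 patients); a
  report-level switch is provided.
* **Backgrounds.** `full` uses every report; `lipid_lowering` first
  restricts the universe to reports matching a packaged, editable
  generic-name list standing in for ATC class C10. FAERS rows carry no ATC
  codes, so a name list is the only self-contained way to define the
  class background; the target terms must be a subset of it, which makes
  `a` identical under both backgrounds while `d` shrinks.
* **Drug roles.** All role codes (PS/SS/C/I) count by default — the least
  surprising choice when the provenance of a report's co-medication coding
  is unknown — with a `roles` switch for suspect-only analyses.
* **Strata.** Gender (male/female/missing) and age (18–64, ≥65, missing;
  under-18s form their own stratum so the non-missing universe is
  partitioned). `AGE_COD` units (DEC/YR/MON/WK/DY/HR) are converted to
  years; a blank unit is taken as years.

The four statistics and their significance criteria:

* **ROR** `= ad/bc`, Woolf CI
  `exp(log ROR ± 1.96·√(1/a+1/b+1/c+1/d))`; signal when the lower bound
  exceeds 1 *and* `a ≥ 3`. A zero cell is an error by default; the
  Haldane–Anscombe +0.5 correction is opt-in and always flagged, because a
  silent correction hides data problems.
* **PRR** `= [a/(a+b)]/[c/(c+d)]` with the Yates-corrected chi-square,
  each cell's `|O−E|−0.5` clipped at zero before squaring (the same
  convention as base R's `chisq.test`); the MHRA criterion is PRR ≥ 2 with
  χ² ≥ 4.
* **EBGM** — the gamma-Poisson shrinker. Counts are modelled as
  `a ~ Poisson(λE)` with a two-component gamma mixture prior on λ fitted
  by maximum marginal likelihood over *all* drug–event pairs of the
  universe (the marginal is a two-component negative-binomial mixture).
  Optimization is L-BFGS-B from `(α₁,β₁,α₂,β₂,π) = (0.2, 0.1, 2, 4, ⅓)`
  with box constraints `(10⁻⁶, 10⁶)` and tolerance 10⁻⁸, run on the
  log/logit scale where the likelihood is well conditioned (the
  constraints map to simple bounds there); non-convergence is an error
  carrying the optimizer trace, never a silent fallback. The
  posterior is a conjugate gamma mixture; `EBGM = 2^E[log₂λ|a]` has a
  digamma closed form and `EBGM05` is found by bisection on the mixture
  CDF to `|CDF − 0.05| < 10⁻⁸` (bracket `[10⁻⁸, 10·a/E + 10]`), with an
  abscissa tolerance so the quantile itself is tight. Signal when
  EBGM05 ≥ 2. Below 100 pairs the fit warns.
* **IC** — the observed-vs-expected shrinkage form
  `log₂((a+0.5)/(E+0.5))`, with `IC025 = log₂` of the 2.5th percentile of
  `Gamma(a+0.5, E+0.5)`. Signal when IC025 > 0. This closed form is
  reproducible and testable against quadrature; which IC variant a given
  legacy SAS analysis used cannot be adjudicated from printed outputs, so
  the package commits to this one.

A *positive* composite signal requires all four criteria simultaneously.

### What the report generator emulates — and what it does not

Each synthetic report is one case carrying one drug *family* (1–3
co-reported alias rows, e.g. brand + generic of one product) and 1–4 PT
occurrences drawn i.i.d. from the family-conditional event distribution
`q(e|f) ∝ q(e)·lift(f,e)`. Because the lift acts on rates inside the
conditional, the implied occurrence-level odds ratio equals the lift
exactly, and every expected 2×2 cell is available in closed form
(`faers_expectations()`), which is what makes recovery tests sharp.
Duplicates clone a case under a higher `PRIMARYID` with a receipt date
shifted +1 to +90 days and possibly one mutated demographic field, so
every branch of the deduplication rule is exercised. Demographics echo the
shape of a PCSK9-inhibitor safety cohort: age ≈ N(72, 9) truncated to
18–100, ~72% female, ~80% consumer-reported, ~90% US.

Deliberately *not* emulated: cross-family co-prescription (a report never
mixes families, so the ground truth stays closed-form), MedDRA hierarchy
above flat PTs, reporting-rate drift over quarters, and free-text drug
name noise. Passing recovery tests therefore shows the statistics and ETL
are correct, not that real FAERS name matching is complete — term lists
remain the analyst's responsibility on real data.

## Genetic arm

### Instrument selection and harmonization

Candidates are SNPs inside the configured cis region (default
chr1:55505221–55530525, the PCSK9 locus) with exposure `p < 5×10⁻⁸`.
Greedy clumping sorts by ascending p (position breaks ties, for
determinism), accepts the best, and discards SNPs within 100 kb of *any*
accepted SNP when `r² > 0.3` to it — the distance-to-any-accepted-SNP
semantics, since the alternative (distance to the index only) is not
better specified anywhere. LD comes from a user-supplied plain-text
matrix rather than a reference panel, which keeps the pipeline free of
external genotype data.

Harmonization aligns each outcome record to the exposure's effect allele:
swapped alleles flip the outcome beta (and complement its frequency);
strand flips are resolved by complementing alleles first. Palindromic
(A/T, C/G) SNPs cannot be resolved from alleles alone: with the exposure
EAF missing or inside (0.42, 0.58) they are dropped, otherwise the
orientation that best matches the two allele frequencies wins. Finally
every instrument is oriented so its exposure beta is positive — the sign
convention MR-Egger needs; reporting "per unit exposure lowering" (the
inhibitor framing) is a labelling layer that inverts the OR and changes
no statistics. Every flip and drop is logged into the instrument set.

### The five estimators

With per-SNP harmonized effects `(βX, βY)` and outcome weights
`w = 1/seY²`:

* **IVW** (primary): zero-intercept weighted regression,
  `θ̂ = Σw·βX·βY / Σw·βX²`, standard error scaled by the multiplicative
  random-effects factor `max(1, √(Q/(L−1)))` — inflating under
  heterogeneity, never deflating; Cochran's Q reported.
* **MR-Egger**: the same regression with a free intercept estimating
  average directional pleiotropy, valid under InSIDE; t-based p-values on
  `L−2` df, the same sigma floor.
* **Weighted median**: ratio estimates `θⱼ = βYⱼ/βXⱼ` weighted by
  `βXⱼ²/seYⱼ²`, combined by cumulative-weight interpolation at 50%;
  consistent when ≥ 50% of weight is valid.
* **Simple/weighted mode**: kernel-density modes of the `θⱼ` (unweighted
  and inverse-variance weighted) with bandwidth `φ ×` the modified
  Silverman rule `0.9·min(sd, mad)·L^(−1/5)`; consistent when the largest
  homogeneous cluster is valid.

Median and mode standard errors come from a seeded parametric bootstrap
(default 1000 draws of `βX, βY` from their sampling normals); the mode
uses the scaled MAD of bootstrap estimates because bootstrap mode
distributions are routinely multimodal, the median uses the SD. ORs and
CIs are the exact exponential map of the log-scale estimate. The positive
control runs the full battery and demands the configured IVW direction
(and significance) before outcomes are interpreted; failure raises the
dedicated condition class `positive_control_error`, which the
orchestrator propagates distinctly from generic stage failures.

### What the GWAS generator emulates — and what it does not

Per LD block (compound-symmetric correlation `r`, block-diagonal overall)
one SNP is causal for the exposure; its neighbours' marginal effects
follow the block correlation, and estimation noise is drawn with the same
block structure, so the written LD matrix is the true correlation of the
estimates. Standard errors use the per-allele approximation
`se = scale/√(2·MAF·(1−MAF)·n)`. The outcome is
`βY = θ·βX + α + noise` with `α ~ N(pleiotropy_mean, pleiotropy_sd²)` —
`pleiotropy_mean ≠ 0` creates directional pleiotropy (an Egger intercept),
`pleiotropy_sd > 0` balanced pleiotropy. The default 100 SNPs with
blocks of five at `r = 0.5` leave ~88–90 instruments after filtering,
the scale of a real cis-region analysis. Configurable fractions of
palindromic, allele-swapped, strand-flipped and negatively oriented
records force every harmonization branch.

Not emulated: individual-level genotypes, sample overlap between the two
GWAS, winner's-curse selection into the exposure GWAS, MAF-dependent
effect-size architecture, and realistic outcome-side case-control noise —
with the default sample sizes the synthetic standard errors are far
smaller than a real binary-trait GWAS would give, so synthetic CIs are
much tighter than published ones. Estimator *calibration* is checked
where the assumptions hold (independent instruments): the i.i.d.
pleiotropy draw breaks exact marginal consistency under LD, which is one
more reason the calibration experiments use `ld_block_size = 1`.

## Numerical and reporting conventions

* Percentages in descriptive tables use half-up rounding at two decimals
  (`round_half_up()`), matching clinical-table convention; the composite
  event row aggregates all target PTs at the event level. The serious-
  outcome denominator is the number of serious-outcome *mentions*, which
  is the only denominator under which published serious-outcome
  percentage blocks of this table style reproduce.
* Rendered signal tables drop groupings below 3 cases (the ROR
  criterion's minimum) and list them in an attribute; rendering is
  bijective at the printed precision.
* `run_all()` writes tab-separated tables plus a JSON manifest (package
  version, seeds, exclusion counters, md5 checksums, no timestamps or
  absolute paths), so a fixed-seed run is byte-identical across
  invocations — the determinism contract the test suite asserts.
* All stochastic stages take explicit integer seeds; sub-seeds derive
  linearly from the master seed modulo 2³¹−1.

## Problem sizes used in the validation suite

The test and acceptance experiments run at sizes chosen to make
Monte-Carlo error small relative to the tolerances they check: 200,000
synthetic reports for lift recovery (the occurrence-level ROR of a
lift-2 pair then has ~3% sampling error against a 10% band); 500
independence tables for criterion calibration (upper bound 7.5% against
a 2.5% nominal one-sided rate); 50,000 drug–event pairs for mixture-prior
recovery (π̂ within ±0.05 of 0.9); 50 random (table, prior) pairs for
EBGM-vs-quadrature agreement at 10⁻⁶; and 500/300 replicate GWAS pairs of
56 independent instruments for IVW coverage (93–97% band), θ recovery and
Egger-intercept recovery within two Monte-Carlo standard errors. The
directional-pleiotropy experiment fixes the generator's negative-
orientation fraction at zero because a constant direct effect is defined
relative to the exposure-raising allele; with random orientation the
flips would cancel it by construction.

## Known limitations

* Name matching is substring-based; on real data that can over-match
  (e.g. a term embedded in an unrelated product string) and the packaged
  class list is a curated stand-in for ATC C10, not a licensed mapping.
* The MGPS prior is the classical two-component mixture; richer
  hierarchical variants and multi-item (>2-way) shrinkage are out of
  scope.
* Weighted-median and mode standard errors are bootstrap-based and hence
  seed-dependent at the third decimal for the default 1000 draws.
* The clumping window is measured to any accepted SNP; analyses expecting
  index-only semantics will retain slightly fewer SNPs.
* Colocalization, Steiger filtering, multivariable MR and reference-panel
  LD computation are deliberately not implemented.

## A minimal end-to-end run

```{r, eval = FALSE}
cfg <- default_run_config("safety_run", seed = 1, n_reports = 20000)
res <- run_all(cfg)
res$signal$full$`Memory loss`     # composite signal under the full background
res$mr$control                    # positive-control estimator battery
```

The demonstration configuration encodes a mild negative association
(lift 0.8) between the target family and the lead memory PT, a protective
positive control (true OR ≈ 0.52 per unit exposure) and three null memory
outcomes — the qualitative pattern of the motivating safety question.
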