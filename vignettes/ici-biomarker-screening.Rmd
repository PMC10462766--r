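---
title: "Screening immune-checkpoint-inhibitor response biomarkers across heterogeneous expression cohorts"
author: "iciscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening ICI response biomarkers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iciscreen)
```

## The problem

Only a minority of patients respond to immune-checkpoint inhibitors (ICIs
— antibodies against PD-1, PD-L1 or CTLA-4), and few transcriptomic
biomarkers of response are established. Individual ICI trial cohorts are
small, so a practical screen pools many public cohorts: RNA-seq and
NanoString panel datasets, profiled on different platforms, annotated with
different outcome variables (RECIST categories, progression-free or overall
survival, or both), across many solid tumor types. `iciscreen` implements
that pooling-and-screening pipeline as a reusable package:

1. **Harmonization** — merge per-dataset matrices over the union gene
   space, quantile normalize all samples jointly, scale the table to a
   fixed overall mean of 1000.
2. **Dichotomization** — map each sample's clinical record onto
   responder / non-responder / unevaluable.
3. **Cohort building** — stratify into drug-class × biopsy-timing arms.
4. **Screening** — per-gene Mann–Whitney U test and ROC AUC with
   genome-wide Bonferroni control, plus fold change and direction.

A synthetic multi-cohort generator with planted markers of known AUC makes
every stage testable without any external download.

## The statistic

For one gene in one cohort, let $x_1,\dots,x_{n_1}$ be the normalized
expression values of non-responders and $y_1,\dots,y_{n_2}$ those of
responders. The screen's core identity connects the Mann–Whitney U
statistic (midranks for ties) to the empirical ROC AUC with non-responders
as the positive class:

$$\mathrm{AUC} \;=\; \frac{U}{n_1 n_2} \;=\;
\frac{\#\{(i,j): x_i > y_j\} + \tfrac12\,\#\{(i,j): x_i = y_j\}}{n_1 n_2}.$$

Both the ROC AUC and the U test therefore carry exactly the same ordering
information, and both are invariant under any strictly increasing
transformation of the pooled values — which is what makes a rank-based
screen robust to the residual scale differences of a multi-platform
database. The reported AUC is oriented, $\max(\mathrm{AUC}, 1 -
\mathrm{AUC})$, with an explicit `direction` field
(`higher_in_nonresponder` flags a candidate *resistance* marker,
`higher_in_responder` a *sensitivity* marker); `direction == "tie"` if and
only if the oriented AUC is exactly 0.5. The fold change is the oriented
ratio of class means, always ≥ 1. Because the AUC orientation is decided by
ranks and the fold change by means, the two can in principle disagree on
heavy-tailed data; the stored `direction` is always the rank-based one.

### p-values

Two-sided p-values use the exact Mann–Whitney null distribution when both
groups have ≤ 8 observations and the pooled values are tie-free (where the
exact distribution coincides with full permutation enumeration — the test
suite checks this identity exhaustively over the small-sample grid), and
otherwise a normal approximation with tie-corrected variance

$$\sigma^2 = \frac{n_1 n_2}{12}\left[(n+1) -
\frac{\sum_t (t^3 - t)}{n(n-1)}\right]$$

and a 0.5 continuity correction. Real screening cohorts have hundreds of
samples per class, far inside the asymptotic regime; the exact small-sample
path exists so that the function is well-defined and deterministic
everywhere. Constant pooled data return $U = n_1 n_2 / 2$, $p = 1$.

### Multiple testing

Family-wise error is controlled by Bonferroni at $\alpha = 0.05$ over
$m$ = the number of genes *actually tested in that cohort* — platforms
contribute different gene sets, so $m$ (and hence the threshold
$\alpha/m$) is arm-specific. Filtering always uses the exact threshold;
the display form truncates (floors) to two significant digits, matching
the convention of printing $0.05/29755 = 1.68\times10^{-6}$ as
`1.6E-06`. A gene enters the test set only if it has at least
`min_class_size` (default 3) non-missing values in *both* classes,
preventing degenerate AUCs on small panels. An optional `gene_filter`
(whitelist or predicate) supports restrictions such as protein-coding-only
screens; the Bonferroni family shrinks accordingly.

## Harmonization choices

**Quantile normalization** is performed once, globally, across all
datasets — the screen compares values across datasets, so they must share
one distribution. The reference distribution is the across-sample mean of
within-sample order statistics. Two details are pinned because dialects
differ between implementations:

* *Ties within a sample* receive the mean of the reference values their
  tied ranks span (for a 3-way tie at ranks 1–3, the mean of reference
  values 1–3 — not the reference value at the interpolated average rank).
* *Samples with platform-missing genes* are normalized over their
  non-missing values against the reference quantile function evaluated at
  their own empirical quantiles by linear interpolation. Restricting the
  database to the gene intersection was rejected: panel datasets would
  collapse the genome-wide screen to a few hundred genes, and per-arm
  tested-gene counts would no longer reflect each arm's platforms.

On complete-case data this reduces to classical quantile normalization
(verified against `limma::normalizeQuantiles` on tie-free data), is
idempotent, and preserves within-sample rank order.

**"Scaled to 1000"** is implemented as one global multiplicative constant
bringing the overall mean of the normalized table to 1000. A single global
constant is the only scaling that fixes the scale while leaving every rank
statistic and every fold change downstream exactly unchanged (the test
suite asserts field-by-field equality of screen results before and after
scaling). The target and the choice of the mean are arguments of
`scale_to_target()`.

## Dichotomization rules

`label_response()` applies, in order:

1. **RECIST present:** CR/PR → responder, SD/PD → non-responder. RECIST
   takes priority over survival when both exist (the response category is
   the primary endpoint; no conflict-resolution rule is otherwise
   defined). In particular SD with long PFS remains a non-responder.
2. **Else PFS present:** PFS > 12 months → responder (censored or not);
   PFS ≤ 12 months with a progression event → non-responder; censored at
   or before 12 months → unevaluable (the follow-up carries no
   information). The boundary is deterministic: exactly 12 months with an
   event is a non-responder, censored exactly at 12 months is
   unevaluable. RFS and PFI annotations are treated as PFS.
3. **Else OS present** (config-gated, default on): the same rule on
   overall survival. The fallback exists because some cohorts report only
   OS yet must be labelable; it is a `label_config()` switch
   (`allow_os_fallback`) because it is an extension of, not part of, the
   PFS rule.
4. **Else unevaluable.**

A PFS record censored short never falls through to OS: the PFS tier
claimed the sample and found it unevaluable. The cutoff (months) is
configurable; 12 is the default.

## Cohorts and arms

The six canonical cohorts are the three drug classes crossed with
pre-/on-treatment biopsy timing; only pre-treatment arms are screened in
practice (on-treatment arms are small), but `standard_cohorts()` builds
and reports all six. A combination-therapy sample (e.g. anti-PD-1 +
anti-CTLA-4) belongs to *every* arm it matches — arm sizes therefore sum
to more than the number of distinct samples, and
`arm_sum_check()` verifies the bookkeeping identity
`sum(arm sizes) − extra multi-arm memberships = distinct labeled samples`.
Unevaluable samples never enter a cohort. Patients with multiple biopsies
contribute each sample independently to its timing-matched cohort; arms
count samples, not patients.

## The synthetic generator

`simulate_database()` emulates the *structure* of a public multi-cohort
ICI database at desk scale. Defaults (chosen once as field-realistic, all
overridable through `synthetic_config()`):

| parameter | default | rationale |
|---|---|---|
| datasets | 6 (4 RNA-seq-like, 2 panel-like), 400 samples total | several platforms, panel gene subsets of 30–40% |
| responder fraction | 0.35 | typical ICI response rates |
| drug-class mix | 60/28/12% PD-1/PD-L1/CTLA-4, 4% combination | dominance of anti-PD-1 cohorts |
| on-treatment fraction | 0.10 | on-treatment biopsies are rare |
| censoring fraction | 0.10 | short-follow-up samples that must become unevaluable |
| noise | unit-variance log-normal around per-gene baselines | simplest null with realistic skew |

Markers are planted on the log scale via the **binormal model**: a
class-mean shift $\Delta = \sqrt{2}\,\Phi^{-1}(\mathrm{AUC})$ (unit
log-scale noise) yields the target AUC in closed form, so
parameter-recovery tests have analytic targets. Platform effects are
*monotone* (power warp plus scale, `v → s·v^e`): monotone by design, so
true within-dataset AUCs are untouched, and joint quantile normalization
should — and demonstrably does, within ±0.05 per-gene AUC — remove the
cross-dataset distortion. Panel-like datasets round values to integers,
deliberately stress-testing midrank tie handling. Survival times are drawn
uniformly on (12.5, 40) for responders and (0.5, 11.5) for
non-responders/censored samples — not realistic survival distributions,
just placement on the correct side of the 12-month rule.

What the generator does **not** emulate: gene–gene correlation, tumor-type
expression programs, batch effects that are not monotone per sample,
realistic hazard shapes, or annotation noise (RECIST mislabels). Passing
tests therefore demonstrate correctness of the *pipeline's statistics and
bookkeeping* under controlled conditions, not robustness to every artifact
of real public data.

## Validation problem sizes

The package validates itself at sizes chosen to exercise the asymptotics
while staying desk-scale: family-wise error over 200 replicate null
screens of 1000 genes at 40 + 40 samples (observed FWER is compared to
0.05 within three binomial standard errors); planted-marker calibration
and recovery over 50 replicate screens of 1000 genes at 300 + 300 samples
with target AUC 0.75 (per-run band ±0.04 ≈ two Hanley–McNeil standard
errors, mean band ±0.02, recovery rate ≥ 95%); and a fixed-seed paired
run for harmonization (400 genes, two 150-sample datasets, one warped).
`scripts/acceptance.R` recomputes all of these from scratch.

## Degenerate inputs and numerical corners

* A cohort with zero responders or zero non-responders raises a
  degenerate-cohort error from `build_cohort()`; `standard_cohorts()`
  reports instead of raising.
* Duplicate gene rows in an input file collapse by per-sample maximum
  (deterministic, and conservative for a screen in which higher
  expression flags resistance); a warning names the genes.
* Missing is not zero: a gene absent from a platform is `NA` for those
  samples and simply contributes fewer observations to that gene's test.
* Fold changes need positive class means; on all-zero means the screen
  stores `NA` rather than aborting (`fold_change()` itself errors).
* An all-constant gene is a tie: AUC 0.5, p = 1, never significant.

## Limitations

Gene identifiers are plain symbols; no alias mapping is attempted.
Deduplication of samples shared between source repositories is
manifest-driven (mark the record `include: false`), not inferred. There is
no batch-effect correction beyond quantile normalization, no
survival modelling (the rule consumes survival only to dichotomize), and
no FDR mode — family-wise Bonferroni control is the screen's contract.
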