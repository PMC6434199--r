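---
title: "Grading cumulative evidence for genetic associations: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grading cumulative evidence for genetic associations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evigrade)
```

## The problem

Candidate-gene association studies of complex diseases are individually
underpowered and collectively contradictory; field synopses resolve this by
collecting every meta-analysis and GWAS for one disease and grading how
credible each nominally significant association is. `evigrade` implements
such a synopsis pipeline for case-control odds-ratio summaries: the
false-positive report probability (FPRP), the Venice credibility criteria,
and the rules that combine them into a final strong/moderate/weak
cumulative-evidence level per variant. The packaged reference tables come
from an esophageal-cancer synopsis (38 significant meta-analysis variants,
17 GWAS hits) and anchor the test-suite.

## The FPRP model

For a record reporting OR with a 95% CI (L, U), everything derives from the
normal approximation on the log-odds scale:

* `se = (ln U − ln L) / (2 z*)`, `z* = Φ⁻¹((1 + ci_level)/2)` = 1.959964 at
  95%. Protective estimates are folded to the risk scale via |ln OR|
  before any computation, equivalent to targeting 1/θ.
* Observed two-sided p: `p = 2 Φ(−z_obs)`, `z_obs = |ln OR|/se`, evaluated
  with the complementary tail (`pnorm(..., lower.tail = FALSE)`), which
  stays relatively accurate until the tail probability leaves the double
  range near z ≈ 38; a naive `1 − Φ(z)` dies at z ≈ 8.
* Power to detect the target OR θ (default 1.5): the critical value is the
  **observed statistic**, i.e. power is evaluated at significance level
  α = p, giving `power = 1 − Φ(z_obs − z_t) + Φ(−z_obs − z_t)` with
  `z_t = ln θ / se`. This convention — not a fixed α = 0.05 — is the one
  that reproduces the published power columns of the reference tables
  (checked on every complete row, max deviation 0.009); it is the
  calibration-derived design decision of the package. The opposite-tail
  term matters for imprecise estimates (e.g. the OR 3.997, CI 1.614–9.900
  row, where it contributes 0.00005 of the printed 0.017... and for rows
  near the null it contributes several percent).
* `FPRP = p(1−π) / (p(1−π) + power·π)` with prior π = 0.001 by default.
  FPRP < 0.2 is noteworthy; bins < 0.05, 0.05–0.2, > 0.2 are labelled
  strong/moderate/weak. Both boundary values fall in the middle bin, and
  the same boundary convention drives the up/downgrade rules (exactly 0.05
  or 0.2 leaves the level unchanged).

Two analytic degeneracies are fixed by convention: at OR = 1 the observed
p is 1 and the power is exactly 1 (a critical value of zero always
rejects), so FPRP → 1−π as expected; if p and power are both exactly zero
the ratio is undefined and the engine returns 0 with a warning (the limit
along any admissible path).

## Venice criteria

* **Amount of evidence** bins the test allele/genotype count: A > 1000,
  B 100–1000 (boundaries inclusive in B), C < 100. When the count is
  unreported, the bracket `(round(n·maf), round(2n·maf))` — genotype- and
  allele-scale counts at the database MAF — substitutes, but only if its
  upper bound is ≥ 3000 (smaller calculated amounts are too unreliable to
  grade on); grading then uses the conservative lower bound. On the
  packaged table every usable bracket clears 1000 on both bounds, so the
  bound choice is unobservable but fixed.
* **Replication** bins I²: A < 25%, B 25–50%, C > 50%. The source states
  open intervals; both boundaries are assigned to B. No reference row sits
  on a boundary, so the choice is again unobservable but must be fixed.
* **Protection from bias**: C when Egger's p < 0.05, or when the effect is
  weak — `max(OR, 1/OR) < 1.15` — without prospective GWAS replication;
  X when no bias information exists at all; A otherwise. The magnitude
  rule is symmetrized so protective effects are treated like risk effects.
  B is reachable only through a per-record `bias_override`, which encodes
  the qualitative "bias could be present" judgement that summary columns
  cannot derive. The packaged table needs exactly two overrides, both A:
  MDM2 rs2279744 (diverse; OR 0.88 prints AAA against the literal rule)
  and MicroRNA124 rs531564 (OR 0.87, 1/OR = 1.149 < 1.15, also printed
  AAA) — evidently the source applied the magnitude rule to
  risk-direction ORs only; the package keeps the symmetric rule and makes
  the two exceptions explicit data rather than hidden logic.

Combination is the lattice: all A → strong, any C → weak, else moderate;
any X → ungraded, which blocks the FPRP adjustment and keeps the variant
out of the strong/moderate/weak tally (it is counted separately).

## Evidence combination and the per-variant tally

FPRP < 0.05 upgrades the Venice level one step; FPRP > 0.2 downgrades one
step; moves never exceed one step and always start from the Venice level.
The tally counts each distinct (gene, variant) once through its primary
analysis — the diverse-population row when present, else the sole
ethnicity, ties to the larger sample. Editorial choices in the source
(e.g. a subtype row versus the overall row) are pinned by an explicit
`headline` flag in the fixture rather than re-derived; with the published
grades and published FPRP values the tally is exactly 5 strong, 10
moderate, 18 weak, 5 ungraded over 38 variants. The switch between
published and recomputed FPRP exists precisely because printed CIs are
rounded: counts are asserted on published values, numeric engines on
recomputed ones.

## Reproduction tolerances, and what the verify report shows

Recomputation from printed (2–3 decimal) CIs carries irreducible rounding
noise, and FPRP amplifies it: FPRP depends on the Wald p, which is
exponential in z, so a ±0.005 perturbation of a CI bound legitimately
moves a mid-range FPRP cell by 0.01–0.1 while barely moving the power
column. Measured on the packaged tables:

* every printed **power** cell reproduces within ±0.01 (94.5% within
  ±0.005), except two GWAS rows whose printed powers (0.842, 0.709) are
  inconsistent with their own printed CIs (recomputed 0.987, 0.722) —
  presumably computed from unrounded inputs;
* the printed **FPRP** column reproduces within ±0.01 for 36 of 55
  complete rows; the remaining 19 form a frozen, documented drift list
  asserted as *reported deltas*, never silently corrected. The extreme is
  a row whose printed OR (1.146) is not even centred in its printed CI
  (1.106–1.293), an apparent typo in the source.
* two rows print replication grade B at I² = 68% and 61%, contradicting
  the stated bins; there is no override channel for the replication
  element, so these two rows are excluded from the exact grade-reproduction
  test and flagged by `cmd_verify()`.

`cmd_verify("meta")` regenerates the full per-row delta table on demand.

## Synthetic data: the stated world

`simulation_spec()` describes K independent case-control studies:

* per-study true log OR = ln(true_or) + Normal(0, tau²);
* control exposure probability from the control MAF under the genetic
  model — allelic: p (2n sampling units per subject group), dominant:
  1 − (1−p)² carriers under Hardy–Weinberg, recessive: p² homozygotes;
* case exposure probability = logit-shift of the control probability by
  the study log OR; exposed counts binomial;
* 2×2 log OR and SE with a 0.5 continuity correction applied only when a
  zero cell occurs, keeping small samples finite without biasing large
  ones;
* optional publication-bias emulation: non-significant studies below the
  median study size are censored — the minimal mechanism sufficient to
  push Egger's intercept away from zero in tests.

Defaults (k = 10 studies, 500/500 cases/controls, control MAF 0.30, true
OR 1.5, tau = 0) were chosen once to mirror the typical candidate-gene
meta-analysis scale in the reference synopsis — median 5–15 studies and
1500–6000 subjects per association, common MAF — and are not revisited.
Everything is a pure function of spec + seed (R's default RNG), so
identical inputs give byte-identical record tables.

The generator emulates sampling noise, heterogeneity and small-study
censoring, and *not*: covariate confounding, genotyping error, linkage
disequilibrium between variants, or Hardy–Weinberg violations. A green
calibration test therefore establishes internal statistical consistency of
the pipeline (unbiased pooling, calibrated null noteworthiness rates,
heterogeneity responding to tau), not robustness to those unmodelled
features of real data.

## Meta-analysis statistics

Fixed-effect inverse-variance pooling only: the synopsis consumes published
summaries and the generator needs a deterministic pooling target, so no
random-effects tau² estimator is included. Cochran's Q uses the chi-square
with k−1 df; I² = max(0, (Q−(k−1))/Q)·100. Egger's test is the regression
of θᵢ/seᵢ on 1/seᵢ, with the intercept tested two-sided against t(k−2);
when every study has identical SE the intercept is collinear with the
precision term and the test is refused (a summary wrapper degrades it to
NA) — a deliberate deviation from treating it as an ordinary regression,
since the asymmetry parameter is unidentifiable there.

## Numerical and interface choices

* Published tables use half-up rounding at 3 decimals; `round_half_up()`
  reproduces it (base `round()` is half-to-even).
* Censored p-values in the sources ("P > 0.05", "P < 0.001") are stored at
  their bound; every grading comparison against 0.05 classifies the bound
  exactly as the printed inequality does.
* Missing cells are the "Na" token in all record I/O; numbers may contain
  internal spaces ("22 935"); the combined "OR (L−U)" notation (any
  hyphen/dash variant) parses into the three numeric fields.
* The strict significance rule (CI excludes 1.0) is advisory: one
  reference row prints a bound of exactly 1.00 yet was classified
  significant from unrounded data, so fixtures carry a curated
  `significant` flag and `is_significant()` reports the strict rule.
* Four reference rows print case/control splits that do not sum to the
  printed total; the fixtures keep the total (used downstream) and drop
  the inconsistent split rather than invent numbers.

## Known limitations

* The bias element covers only what summary columns encode (Egger p,
  magnitude, GWAS replication, explicit overrides); sensitivity analyses
  and excess-significance tests of the source meta-analyses are out of
  scope.
* FPRP is computed at a single prior (default 0.001) — no prior grids and
  no Bayesian false-discovery alternatives.
* Genotype-level GWAS analysis, literature search/screening, and subtype
  inference beyond what rows state are out of scope.
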