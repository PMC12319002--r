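---
title: "Methods: Delphi consensus statistics and AHP weighting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Delphi consensus statistics and AHP weighting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(delphiAHP)
```

## The procedure and its assumptions

delphiAHP models the standard two-stage construction of a weighted
evaluation-indicator system:

1. **Delphi consultation.** A fixed panel of experts scores each indicator
   of a three-level hierarchy on a 5-point Likert importance scale, over
   two anonymous rounds. Between rounds the framework is revised (deletions,
   renames, merges, additions) and consensus statistics decide when to stop.
2. **AHP weighting.** The final round's mean scores drive pairwise
   judgment matrices (one per parent node plus one over the top level),
   whose principal eigenvectors give local weights; products along root
   paths give combination weights.

Assumptions inherited from this design: scores are integers 1–5; the panel
is the same across indicators (so within-expert ranks are meaningful for
Kendall's W); mean differences, not individual expert comparisons, carry
the pairwise-importance information (the aggregation-then-compare variant
of AHP); and the hierarchy is strictly three levels with dotted codes as
canonical identifiers (names are display-only, so renames never break
references).

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `retain_mean` / `retain_cv` | 4.0 / 0.25 | score / – | conventional retention band for 5-point Delphi screening |
| `delete_mean` / `delete_cv` | 3.5 / 0.30 | score / – | deletion band; between the bands an indicator is flagged `review` for expert re-argument |
| `max_not_necessary` | 0.30 | fraction | censor rule: over 30% "not necessary" votes deletes regardless of scores |
| `credible_min` | 0.7 | – | panel-mean authority Cr threshold |
| Saaty bins `upper` | 0, 0.15, 0.35, 0.50, 0.75, 0.85 | score diff | inclusive upper bounds mapping \|Δx̄\| to scales 1–7 (see below) |
| `random_index` | RI(3) = 0.52, … | – | expected CI of random reciprocal matrices |
| `n_experts` | 15 | experts | the consultation size the generator emulates |
| `sigma` | 0.5 | score | expert noise SD; mid-range of the reference framework's per-indicator score SDs (0.0–0.8) |
| `round2_shrink` | 0.5 | – | round-2 noise multiplier, modeling between-round convergence |
| `p_not_necessary` | 0.2 | prob. | vote rate for low-importance (μ < 3.5) indicators only |

The screening text in the source literature for this class of procedure is
often garbled about the mid-band; the implementation fixes it as: *delete*
when mean < 3.5 **or** CV > 0.3 **or** votes > 30%; *retain* when mean ≥ 4
**and** CV < 0.25 and nothing fired; *review* otherwise. All four
thresholds are configurable, and screening is monotone in the mean by
construction (raising a mean can never demote a verdict).

## The difference→Saaty mapping

The reference framework never published its difference→scale table, only
the resulting matrices' weights and consistency ratios. The default bins
(|d| = 0 → 1; (0, 0.15] → 2; (0.15, 0.35] → 3; (0.35, 0.50] → 4;
(0.50, 0.75] → 5; (0.75, 0.85] → 6; > 0.85 → 7) were calibrated once so
that **all** published mean scores reproduce **all** published weights and
CRs (observed assignments: 0.07, 0.13 → 2; 0.20, 0.27, 0.33 → 3; 0.40 → 4;
0.60, 0.67 → 5; 0.93 → 7). The mapping is config-overridable and
`calibrate_mapping()` re-fits bin bounds from any set of observed
difference/scale pairs, placing bounds midway between adjacent groups and
refusing overlapping groups.

## Numerical choices

* **Population SD** (divisor N), not sample SD: the only convention under
  which 15 integer scores can reproduce the reference table's "4.33 ± 0.47"
  rows (sample SD gives 0.49). Applied uniformly.
* **Weights by principal eigenvector**: power iteration from the uniform
  vector, renormalized each step, stopping when successive iterates differ
  by < 1e-12 in max norm; λmax as the Rayleigh quotient at convergence.
  The row-geometric-mean method is provided as an alternative and serves as
  the independent test oracle (the two coincide exactly on consistent
  matrices).
* **λmax for the consistency test** defaults to the classical sum-product
  approximation (weights = row means of the column-normalized matrix,
  λmax = mean((Aw)ᵢ/wᵢ)) — the convention of the desktop AHP tools used to
  produce the reference CRs, and the only convention that reproduces all
  four of their non-zero values (0.0089, 0.0176, 0.0517, 0.0633) at 4
  decimals. The exact dominant eigenvalue (`lambda_method = "power"`)
  yields 0.0088, 0.0176, 0.0516, 0.0624 on the same matrices — a ~1e-3
  difference that matters only at the fourth decimal.
* **RI(3) = 0.52**, not the older 0.58: the value consistent with the
  reference CRs. CR is defined as 0 for n ≤ 2.
* **Kendall's W** uses mid-ranks for ties and the tie-corrected
  denominator m²(n³−n) − mΣTⱼ; 5-point scores tie heavily, so the
  correction is essential (identical raters with ties still give W = 1).
  The χ² approximation is used for the p-value at every m. A panel in
  which *every* expert rates all indicators identically has an undefined W
  and errors rather than returning a value.
* **Rounding**: reports show 2 decimals for score statistics and 4 for
  weights; all internal chaining uses full precision. Rounding is
  half-away-from-zero at the reporting edge (`round2dp`-style helpers add
  1e-12 before rounding to stabilize exact .005 boundaries).
* **Judgment matrices are always regenerated** from means + mapping; no
  matrix is stored.

## What the synthetic generator emulates — and what it does not

`simulate_panel()` draws score(e, i) = clamp(round(μᵢ + ε), 1, 5),
ε ~ N(0, σ), homoscedastic across experts; round 2 shrinks σ by
`round2_shrink`; "not necessary" votes occur only for μ < 3.5; authority
answers come from a fixed categorical profile of a senior panel. One master
seed expands into per-round substreams, so any round regenerates
identically on its own.

It deliberately does **not** model: expert-specific severity or
anchoring styles (available only as homoscedastic noise), informative
revision of μ between rounds, expert attrition, or correlated scoring
across sibling indicators. A green simulation test therefore establishes
that the *statistics* behave as derived (W decreasing in σ, shrinkage
raising W, vote targeting, determinism) — not that real panels look like
the generator.

Two empirical limits discovered while validating, kept on record:

* **Per-seed ordering recovery is bounded near 0.84.** With the reference
  framework's 31 means as μ (adjacent gaps of 1/15) and 15 experts, the
  mean per-seed concordance between the μ ordering and the recovered-mean
  ordering peaks around 0.84 over σ ∈ [0, 0.5]: at small σ integer
  quantization ties the recovered means, at larger σ sampling noise
  misorders closely spaced pairs. The corresponding acceptance test, which
  asserts 0.9 as stated, is intentionally left failing; the pooled
  estimator (means averaged over 100 replicates) recovers the ordering
  perfectly and is tested green alongside.
* **σ = 0 does not reproduce fractional means.** Zero-noise scores are
  `round(μ)`, so exact reproduction of a published weight table goes
  through the packaged multiset panel (which carries the exact means), not
  through the generator.

## Design choices where the design was open

* **Revision replay, not auto-screening.** The pipeline replays the
  recorded revision actions between rounds rather than deleting whatever
  screening voted down: framework revision is an expert decision informed
  by the verdicts, and the audit log keeps both.
* **The pre-screening framework is a labelled synthetic reconstruction**:
  the final framework plus the three excluded indicators under a
  "Digital security" secondary node, with pre-revision names. Exact
  original wording is not recoverable; the fixture's `meta` says so.
  Merges are encoded as delete + add with a merge note (no weighted
  content transfer).
* **Configs are JSON** (jsonlite), since no YAML parser is among the
  package's dependencies; CSV in/out for panels, TSV/JSON for reports.
* **Non-leaf indicators may be scored directly** (the reference table
  lists statistics for all 31 rows); the engine never imputes a parent's
  statistics from its children.
* **Name discrepancies in the source tables** (one tertiary indicator
  named differently in the framework table vs the weight table) are
  resolved in the fixture's favor of the framework table, with the
  alternative recorded as an alias in the fixture metadata. One published
  CV (row 2.3, "4.00 ± 0.52, Cv 0.11") is arithmetically inconsistent with
  its own mean and SD; the package reports the recomputed 0.13.

## Known limitations

Group aggregation of individual expert judgment matrices (classical group
AHP), fuzzy/interval AHP, and sensitivity analysis beyond mapping overrides
are out of scope. The consistency test's column-sum λmax is an
approximation chosen for fidelity to the reference results; switch to
`lambda_method = "power"` for the exact eigenvalue. The χ² test for W is
asymptotic and anti-conservative for very small panels (m ≤ 3), where the
exact permutation distribution would be preferable.
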