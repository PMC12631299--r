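---
title: "Hybrid Z-number risk prioritization: models, conventions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid Z-number risk prioritization: models, conventions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zfmea)
library(dplyr)
```

## The problem

Drug supply chains — the packaged case study is an antiretroviral (HIV)
medicine chain — fail in many ways at once: customs delays, quantity errors,
price discrepancies, storage problems. Classical FMEA scores each failure
mode on Severity (S), Occurrence (O) and Detection (D) and ranks by the risk
priority number RPN = S x O x D, but a single crisp RPN hides both the
vagueness of expert ratings and the experts' unequal confidence in them.
This package implements a hybrid prioritization that keeps the uncertainty
explicit end to end:

1. judgments are *Z-numbers* — a triangular fuzzy rating plus a triangular
   fuzzy reliability;
2. criterion weights for S, O, D come from stepwise expert comparisons
   (Z-SWARA);
3. modes are ranked per objective by a weighted sum/product blend
   (Z-WASPAS);
4. an input-oriented super-efficiency DEA converts the de-fuzzified scores
   into a risk-to-impact efficiency per mode;
5. the three views are averaged into a hybrid score per objective and
   across objectives.

## Fuzzy arithmetic and Z-number conversion

A TFN $(l, m, u)$ with $l \le m \le u$ is defuzzified throughout by the
component mean $(l+m+u)/3$. A Z-number $(\tilde F, \tilde L)$ collapses its
reliability to the centroid $\alpha = (l_B + m_B + u_B)/3$ and folds it into
the restriction. Two scalings coexist in the source material and both are
implemented:

* **alpha** — $\tilde F \cdot \alpha$. The numeric pipeline (input averages,
  decision matrices) follows this: e.g. the Severity average for the first
  study mode is $\mathrm{mean}(2.0, 3.8, 5.5) \times 0.7 = 2.637$, matching
  the published input table.
* **sqrt_alpha** — $\tilde F \cdot \sqrt{\alpha}$, the Kang-style
  conversion. Only under this scaling does the published linguistic
  weighting table reproduce: (VLI, M) $\to (0.21, 0.24, 0.29)$.

The published tables are internally consistent only if the two stages use
different scalings, so the conversion mode is per-stage configuration:
`alpha` is the pipeline default, `sqrt_alpha` is hard-wired into
`linguistic_to_tfn()`. The equal-importance anchor (EI) is special-cased to
$(1,1,1)$ — the published conversion table leaves it unscaled for every
reliability grade.

Fuzzy division and exponentiation are not uniquely defined for TFNs.
`tfn_divide()` offers the ordering-safe *inverted* rule
$(l_1/u_2,\, m_1/m_2,\, u_1/l_2)$ and a *componentwise* rule with re-sorting;
`tfn_power()` raises matching components and re-sorts (needed when bases are
below 1, where a larger exponent shrinks the value — the rule degenerates
correctly to crisp powers).

## RPN

Following the published RPN table, `compute_rpn()` multiplies the three
*restriction* TFNs component-wise — reliability is not applied (the printed
values only reproduce unweighted; `use_reliability = TRUE` opts into the
weighted variant). Ranks are per objective, descending in the middle
component, ties broken lexicographically on the mode code. Two of the 126
printed RPN components in the source tables are inconsistent with their own
input panel (the study's comparison table agrees with the recomputed
values); the package reproduces the other 124 exactly and documents the two
misprints rather than patching them.

## Z-SWARA weighting

Criteria are ranked most-to-least important; each subsequent criterion gets
a step-down comparison TFN $s_j$ (numeric or linguistic). Coefficients
follow the standard stepwise recursion $q_1 = (1,1,1)$,
$q_j = q_{j-1} \oslash (s_j \oplus 1)$, normalized to weights
$w_j = q_j \oslash \sum q_j$. Since $s_j + 1 \ge 1$ component-wise, weights
are non-increasing down the ranking. The source's printed recursion
($q_j = s_j/s_{j-1} + 1$) would grow down the ranking, contradicting the
method's semantics and the published decreasing weights; it is kept behind
`recursion = "as_printed"` for audit. The published study weights themselves
are not derivable from their printed Z-numbers under either recursion, so
they ship verbatim as `study_weights()` and the pipeline computes fresh
weights only for user-supplied judgments.

## Z-WASPAS ranking

All three criteria are non-beneficial, so the reliability-weighted decision
matrix is normalized criterion-wise as $\hat h = \min_i \bar h / \bar h$.
The normalization uses componentwise division by default because the
least-risky mode then sits exactly at the $(1,1,1)$ anchor — the stated
anchor property of the method; the inverted style is available by
configuration. WSM is $\sum_j \hat h \otimes w_j$, WPM is
$\prod_j \hat h^{w_j}$, and with mixing weight $\lambda$ (default 0.5, the
conventional balance) the combined utility is
$K = \lambda \bar Q + (1-\lambda) \bar P$ on defuzzified means, with the
combined TFN mixed component-wise. Risk rank 1 goes to the *lowest* middle
$K$ (riskier modes sit further from the anchor). The published WSM/WPM stage
table cannot be re-derived bit-exactly from the raw panel under any
normalization convention tested; it ships as `study_waspas()` and the
combination step reproduces its combined column to within 0.001 from the
printed WSM/WPM pairs. For user data the whole chain is computed fresh.

## Super-efficiency DEA

Each failure mode under each objective is a DMU with inputs
$(S_{avg}, O_{avg})$ (de-fuzzified, reliability-weighted) and output
$1/K_{avg}$, so riskier modes produce more "criticality output". The
efficiency program is input-oriented VRS super-efficiency: minimize
$\theta$ subject to $\sum_k \lambda_k y_k \ge y_j$,
$\sum_k \lambda_k x_{ik} \le \theta x_{ij}$, $\sum_k \lambda_k = 1$,
$\lambda \ge 0$, with the evaluated DMU excluded from its own reference set.
Pools are per objective (21 peers each): that is the only convention under
which exactly the two modes whose output exceeds every peer's — Quantity
Errors under delivery, Pack Price Discrepancies under freight — are
VRS-infeasible, matching their published normalized score of exactly 1.
Raw scores are capped at 1.5 (infeasible counts as above-cap) and
normalized by the cap, following the published post-processing; orientation,
pool, and cap are configurable.

With this convention the fresh solver reproduces *all 42* published
normalized efficiencies to within $2 \times 10^{-4}$ — the study's
efficiency table is fully recoverable, not just its capped entries.

**Numerics.** No dedicated LP package is available in the target
environment, so each program is solved as a ridge-regularized quadratic
program (Goldfarb–Idnani active-set method, `quadprog`), with the ridge
escalated from $10^{-8}$ if a level is rejected, followed by an exact solve
of the active-constraint system (SVD pseudo-inverse, handling the duplicated
constraints of degenerate faces). This recovers LP optima to machine
precision; the test suite checks it against a brute-force enumeration of
basic feasible solutions at $10^{-9}$ on small pools. Input-orientation
infeasibility is decided analytically ($\max_k y_k < y_j$ under the
convexity constraint); output-orientation feasibility uses an auxiliary
program with the inequality slackened by the documented feasibility
tolerance $10^{-9}$, without which boundary-feasible programs are rejected
by roundoff.

## Hybrid aggregation

Per objective, the three views are put on $[0,1]$: RPN middles divided by
the pool maximum; $K$ middles min–max *inverted* (lowest $K$ = riskiest
$\to 1$); efficiency already cap-normalized. The hybrid score is their
equal-weight mean, and the study-level score averages the two objectives
(weights configurable, equal by default). A mode scores exactly 1 iff it is
simultaneously worst on all three views — which the top-ranked study mode
is, under the delivery objective. All normalization pools are per objective;
a degenerate $K$ spread (all middles equal) raises an error rather than a
silent 0/0. The published hybrid tables use RPN middles that deviate from
the published RPN table for five cells; the stage-wise reproduction path
therefore feeds the hybrid stage from `study_hybrid_rpn()` (those printed
middles), while fresh runs use the recomputed RPN.

## Synthetic panels

`simulate_panel()` generates the structure the framework assumes — it makes
no attempt to model real expert behavior, bias, or correlation. Choices,
fixed once:

* 5 experts (a typical elicitation panel; the study does not state its
  count);
* modal ratings uniform on the 1–10 scale the study's experts used;
* TFN half-widths uniform on [0.5, 2.5] rating units, clipped to the scale —
  the spread range observed in the published panel;
* reliability drawn uniformly from the published five-grade vocabulary
  (`linguistic_scale_reliability()`).

`aggregate_experts()` averages restriction and reliability TFNs
component-wise (means of valid TFNs are valid TFNs; no re-sorting). Passing
tests on synthetic panels demonstrates totality and invariants — every
generated panel yields scores in $[0,1]$ and a complete ranking — not
fidelity to any real elicitation.

## Problem sizes and determinism

The packaged study is desk-scale: 21 modes x 2 objectives, 42 efficiency
programs of at most 21 variables each; a full fresh run takes a few seconds.
Test simulations use 4–6 modes with 2–3 experts across 50 seeds. All stages
are deterministic given inputs and configuration; the only randomness in the
package is the panel generator, which is fully seeded.

## Known limitations

* The fuzzy division/power conventions are choices, not canon; results can
  shift slightly under the alternatives, which is why each stage exposes its
  convention.
* The published weighting and WSM/WPM stage tables are consumed as fixtures
  where they are not derivable; fresh computations are first-class but will
  not bit-match those tables.
* Super-efficiency under VRS is genuinely infeasible for frontier-extreme
  units; the cap treats infeasibility as "maximally efficient", which is the
  published convention but compresses differences above the cap.
* Beneficial criteria (where larger is better) are not implemented — the
  risk model has none.
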