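# zfmea

Hybrid multi-criteria risk prioritization for drug supply chains from
expert **Z-number** assessments.

Supply-chain failure modes — customs delays, quantity errors, price
discrepancies — are classically ranked in FMEA by the risk priority number
RPN = S × O × D (Severity, Occurrence, Detection). A crisp RPN discards two
kinds of uncertainty: the vagueness of an expert rating and the expert's
confidence in it. `zfmea` keeps both explicit end to end. Every judgment is
a Z-number: a triangular fuzzy rating (l, m, u) on a 1–10 scale paired with
a triangular fuzzy reliability on [0, 1]. The pipeline then blends three
complementary views of each failure mode under each objective:

1. **Fuzzy RPN** — component-wise product of the S, O, D rating TFNs;
2. **Z-SWARA / Z-WASPAS** — stepwise expert-derived criterion weights
   (`q_1 = (1,1,1)`, `q_j = q_{j-1} ⊘ (s_j ⊕ 1)`, normalized) feeding a
   weighted sum/product blend `K = λQ̄ + (1−λ)P̄` (λ = 0.5 by default),
   where a *lower* K middle flags higher risk;
3. **Super-efficiency DEA** — an input-oriented VRS program per mode with
   inputs (S_avg, O_avg) and output 1/K_avg, the evaluated mode excluded
   from its own frontier; infeasible or above-cap scores capped at 1.5 and
   normalized.

The hybrid score per objective is the equal-weight mean

    Q = (norm RPN + inverted norm K + θ_norm) / 3,

and the study-level score averages the objectives. The package ships the
published 21-failure-mode antiretroviral (HIV) supply-chain case study —
assessed under delivery-date and freight-cost objectives — as plain-text
fixtures, plus a seeded synthetic expert-panel generator.

Audience: supply-chain and healthcare risk analysts who want a tested,
configurable implementation of this hybrid ranking, and methodologists who
want its conventions (fuzzy division styles, Z-number scalings, DEA
orientation/pooling) exposed rather than hard-wired.

## Worked example

```r
library(zfmea)

fit <- zfmea(study_assessments(), study_weights(),
             fixtures = list(waspas = study_waspas(), dea = study_dea(),
                             rpn_middles = study_hybrid_rpn()))
fit
#> Z-number hybrid risk prioritization
#>   21 failure modes x 2 objectives; lambda = 0.5, DEA input/per_objective, cap 1.5
#>   stage fixtures: waspas, dea, rpn_middles
#> Top of the combined ranking:
#> # A tibble: 5 × 3
#>   mode_code q_total  rank
#>   <chr>       <dbl> <int>
#> 1 F14         0.937     1
#> 2 F16         0.843     2
#> 3 F13         0.726     3
#> 4 F20         0.688     4
#> 5 F04         0.674     5
```

F14 ("Quantity Errors") tops the combined ranking with Q_total ≈ 0.937: it
is simultaneously the highest fuzzy RPN, the lowest (riskiest) WASPAS
utility, and DEA-infeasible (maximally efficient at converting risk inputs
into criticality) under the delivery objective. F16 ("Pack Price
Discrepancies") leads the freight objective the same way. `tidy(fit)`
returns the combined table with per-objective scores, `glance(fit)` a
one-row summary, and `autoplot(fit)` / `plot_hybrid_scores(fit)` the
ranking charts.

The `fixtures` argument reproduces the published study stage-wise from its
printed intermediates. Omit it to compute every stage fresh from the raw
panel — the fresh run reproduces the published DEA table to ~2e-4 and the
same top-5 ordering:

```r
zfmea(study_assessments(), study_weights())   # fully fresh pipeline
```

Individual stages are plain functions on data frames: `compute_rpn()`,
`zswara()`, `zwaspas()`, `build_dmus()`, `dea_superefficiency()`,
`hybrid_scores()`, `combine_objectives()`. A file-level front end
(`run_pipeline()`) writes one CSV per stage; a thin CLI lives at
`inst/cli/zfmea.R` (`run-all`, `simulate`). Synthetic panels:

```r
panel <- simulate_panel(n_modes = 6, n_experts = 3, seed = 1)
fit <- zfmea(aggregate_experts(panel), study_weights())
```

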