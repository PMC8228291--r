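# tierdx

Diagnostic yield and cost-effectiveness of tiered genetic testing pathways.

## The problem

Clinical services diagnosing suspected monogenic disorders — the motivating
setting is epilepsy comorbid with neurodevelopmental disorders (NDD) or
developmental and epileptic encephalopathies (DEE) — increasingly sequence a
proband's exome once and interpret it "dynamically" through successively
wider virtual gene panels: a curated first-line panel, an expanded
reanalysis panel, and finally the full exome. Each tier adds diagnoses and,
depending on how the pathway is organised, reimbursable tests. `tierdx` is
for clinical geneticists, epileptologists and health-economics analysts who
want to quantify such a pathway: how much yield each tier adds, whether the
tiers differ significantly, and what each way of ordering the tests costs
per diagnosis.

## The model

Each of n probands contributes the tier at which a molecular diagnosis was
first reached (1…k, or 0 for none), under the monotone-diagnosis assumption
that a proband diagnosed at an early tier would also be diagnosed by any
later, more inclusive tier. From the n×k marginal indicator matrix the
package computes:

* **Yields** — marginal and cumulative yield per tier.
* **Cochran's Q** over the k paired proportions,
  Q = (k−1)·[k·ΣCⱼ² − (ΣCⱼ)²] / [k·ΣRᵢ − ΣRᵢ²] ~ χ²(k−1),
  with post hoc pairwise **McNemar** tests (b−c)²/(b+c) on discordant
  counts, uncorrected.
* **Pathway costs** at a per-analysis reimbursement (default 2072.74 €):
  a two-step-panels reference, panels-then-exome (model 1), and exome-first
  with free virtual reanalysis (model 2); cost per diagnosis and the
  incremental cost-effectiveness ratio (ICER) Δcost/Δdiagnoses.
* **A paired patient-level bootstrap** (default B = 500) of (Δdiagnoses,
  Δcost) per replicate, plotted on the cost-effectiveness plane with
  quadrant and dominance summaries.

A fully reconstructed 72-proband study cohort ships as `dee_cohort()`
(21/4/2 diagnosed at tiers 1/2/3, 45 undiagnosed), and
`simulate_cohort()` generates multinomial synthetic cohorts.

## Worked example

```r
library(tierdx)
co <- dee_cohort()
m  <- outcome_matrix(co)

yield_table(m)
#>   tier label count      yield cum_count cum_yield
#> 1    1 tier1    21 0.29166667        21 0.2916667
#> 2    2 tier2     4 0.05555556        25 0.3472222
#> 3    3 tier3     2 0.02777778        27 0.3750000

cochran_q(m)$statistic      # Q = 24.22222, p = 5.5e-06
pairwise_mcnemar(m)
#>   tier_a tier_b  b c  statistic      p_value significant
#> 1      1      2 21 4 11.5600000 6.738585e-04        TRUE
#> 2      1      3 21 2 15.6956522 7.439498e-05        TRUE
#> 3      2      3  4 2  0.6666667 4.142162e-01       FALSE

p <- standard_pathways(unit_cost = 2072.74)
apply_pathway(co, p$model2)
#> Pathway: model2   (n = 72 probands)
#> Tests per tier: exome_first=72
#> Total cost: 149237.28 EUR over 72 tests
#> Diagnoses: 27  Cost per diagnosis: 5527.31 EUR

incremental(apply_pathway(co, p$model2), apply_pathway(co, p$reference))
#> model2 vs reference: delta cost -105709.74 EUR, delta diagnoses 2
#> Dominant: no fewer diagnoses at no greater cost
```

Read: the overall yield is 37.5 % (27/72), of which 29.2 % comes from the
first panel, 5.6 % from reanalysis and 2.8 % from the full exome; the tiers
differ significantly overall (p < 0.01) and tier 1 differs from tiers 2 and
3, but tiers 2 and 3 do not differ (p = 0.414). Costing the pathways, the
panels-only reference spends 10,197.88 € per diagnosis, panels-then-exome
13,050.59 €, and exome-first 5,527.31 € — the exome-first strategy finds
two more diagnoses than the reference *and* saves 105,709.74 €, i.e. it is
dominant. `bootstrap_ce()` confirms that this dominance holds in 100 % of
500 resampled cohorts.

The whole analysis, with all outputs written to disk, is one call:

```r
run_analysis(run_config(fixture = TRUE, outdir = "results"))
```

or from a shell, `Rscript inst/cli/tierdx.R run --fixture --outdir results`.

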