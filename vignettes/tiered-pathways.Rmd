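---
title: "Evaluating tiered exome-reanalysis pathways: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating tiered exome-reanalysis pathways: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tierdx)
```

## The problem

When a patient with a suspected monogenic disorder — here, epilepsy comorbid
with a neurodevelopmental disorder or a developmental and epileptic
encephalopathy — undergoes exome sequencing, the laboratory does not have to
interpret every gene at once. A common "dynamic" strategy sequences the
exome once and interprets it through successively wider *virtual gene
panels*: a first curated panel of well-established disease genes, an
expanded reanalysis panel of more recently implicated genes, and finally the
full exome. Each interpretation step adds diagnoses; the question for a
clinical service (and its payer) is which *pathway* through these steps
maximises diagnoses per euro.

`tierdx` implements the complete evaluation for such a tiered pathway:

1. **Yields** — marginal and cumulative diagnostic yield at each tier.
2. **Paired tests** — Cochran's Q across all tiers and pairwise McNemar
   tests, treating each proband's per-tier outcomes as paired binary data.
3. **Costs** — a per-test reimbursement model comparing pathway strategies,
   with cost per diagnosis and incremental cost-effectiveness ratios.
4. **Uncertainty** — a paired patient-level bootstrap rendered on the
   cost-effectiveness plane.

The packaged worked example, `dee_cohort()`, is a 72-proband cohort in which
21 probands were diagnosed at the first tier, 4 at the second, 2 at the
third, and 45 remained undiagnosed.

## The outcome model and its central assumption

Each proband contributes a single categorical outcome: the tier at which a
molecular diagnosis was *first* reached (1, 2, 3, or 0 for none). From this,
`outcome_matrix()` builds the n×k binary matrix of marginal indicators,
entry (i, j) = 1 when proband i was first diagnosed at tier j; rows sum to
at most one.

Everything downstream rests on the **monotone-diagnosis assumption**: a
proband diagnosed at an early tier would also have been diagnosed by any
later, more inclusive analysis (later tiers interpret supersets of the
earlier gene lists on the same sequencing data). This is what lets per-tier
yields be evaluated on the full cohort of 72 rather than on the shrinking
set of still-undiagnosed probands, and what lets alternative pathway
orderings be costed from the observed tier-of-diagnosis alone. It is an
assumption, not an observation — a gene present in the wider panel could in
principle be missed by a different pipeline — and the package makes no
attempt to model departures from it.

## Paired-proportion tests

Whether the tiers contribute diagnoses at different rates is a question
about k paired proportions. With column sums $C_j$ and row sums $R_i$ of
the marginal matrix, Cochran's Q is

$$Q = (k-1)\,\frac{k\sum_j C_j^2 - \left(\sum_j C_j\right)^2}{k\sum_i R_i - \sum_i R_i^2},$$

referred to $\chi^2_{k-1}$. Post hoc pairs use McNemar's statistic
$(b-c)^2/(b+c)$ on the discordant counts, referred to $\chi^2_1$. Three
design choices matter and are deliberate:

* **Marginal, not cumulative, indicators.** The pairwise question is
  whether two tiers *contribute* diagnoses at different rates. Comparing
  cumulative indicators instead would make later tiers trivially
  non-inferior and changes the tier-2 vs tier-3 p-value from 0.414 to
  about 0.157.
* **No continuity correction.** With few discordant pairs the corrected
  statistic is markedly conservative (tier 2 vs 3 would give p ≈ 0.683
  instead of 0.414); the uncorrected asymptotic form is the default. An
  exact binomial variant (`mcnemar_pair(..., exact = TRUE)`) is provided
  for sensitivity analysis but small-sample exactness is not the default.
* **Degenerate inputs return p = 1, not an error.** A bootstrap replicate
  can contain no discordant probands at all; `cochran_q()` and
  `mcnemar_pair()` then return a zero statistic with p = 1 (with a warning
  in the interactive case) so that replicate loops stay total.

No multiplicity adjustment is applied across the three pairwise tests, and
no confidence intervals are attached to yields; both would be
straightforward extensions but are not part of the core evaluation.

```{r tests}
m <- outcome_matrix(dee_cohort())
cochran_q(m)
pairwise_mcnemar(m)
```

## The cost model

The reimbursement model has a single tunable monetary parameter: the
`unit_cost` of one NGS analysis, defaulting to **2072.74 €**, the Lombardia
regional tariff, which applies per analysis regardless of technique
(per-tier overrides are possible through `tier_definition()`). Three
strategies are compared by `standard_pathways()`:

* **reference** — two-step virtual panels only; each step is a separately
  reimbursed analysis and level-3 diagnoses are never reached (25/27
  diagnoses in the worked cohort).
* **model1** — the two panels followed by exome sequencing as a
  third-step test; three reimbursable steps.
* **model2** — exome sequencing from the start, interpreted through the
  same panel hierarchy. The defining modelling choice is that this is **one
  reimbursed act**: reanalysis of stored exome data through wider virtual
  panels incurs no new reimbursement, so a single tier resolves all levels
  at cost n × unit_cost.

A proband traverses tiers in order and exits at the first tier whose
cumulative detection set contains their diagnostic level; undiagnosed
probands undergo (and are reimbursed for) every tier. Costs are computed in
double precision and only rounded for display (euro amounts to 2 decimals);
an unrounded value is always retained in the result objects. A pathway that
diagnoses nobody has an explicitly undefined (`NA`) cost per diagnosis
rather than an infinite one, so replicate-level results serialise cleanly.

```{r costs}
co <- dee_cohort()
p <- standard_pathways()
lapply(p, function(pw) apply_pathway(co, pw))
incremental(apply_pathway(co, p$model2), apply_pathway(co, p$reference))
```

## Bootstrap and the cost-effectiveness plane

Uncertainty in the incremental comparisons is quantified by a
**patient-level, paired bootstrap** (`bootstrap_ce()`, default B = 500
replicates): each replicate resamples n probands with replacement and
evaluates the reference and every model on the *same* resampled cohort.
Resampling the whole proband (rather than tier indicators independently)
preserves the within-patient pairing that the incremental quantities
require. Each replicate yields one point (Δdiagnoses, Δcost) per model on
the cost-effectiveness plane; `classify_quadrant()` labels points by sign,
with any zero coordinate labelled `axis`, and `summarize_ce()` reports
quadrant proportions, means, nearest-rank 2.5/97.5 percentiles, and the
dominance proportion (no fewer diagnoses at no greater cost).

Two structural facts hold by construction and are verified over every
replicate in the test suite: both alternative strategies detect a superset
of the reference's levels, so Δdiagnoses ≥ 0 always; and relative to the
two-panel reference, adding an exome third step can only add cost while the
exome-first strategy can only remove it, so model1 points lie on or above
the x-axis and model2 points on or below it. The original-study bootstrap
seed is unknown, so individual point clouds are not bit-reproducible across
software; these structural properties, not point coordinates, are the
meaningful invariants. Nearest-rank percentiles (`quantile(type = 1)`) are
used so interval endpoints are always observed values, with no
interpolation ambiguity.

All randomness — simulation and bootstrap — is owned by the called function
through an explicit `seed` argument; the caller's global RNG stream is
saved and restored, and identical seeds reproduce identical results
bit-for-bit.

## The synthetic-cohort generator

`simulate_cohort(n, probs, seed)` draws each proband's outcome
independently from a multinomial over (tier 1, ..., tier k, undiagnosed).
Its defaults mirror the study conditions of the worked example: cohorts of
n = 72 with outcome probabilities (21, 4, 2, 45)/72 reproduce the fixture's
regime. The generator emulates exactly what the analysis consumes — the
tier-of-first-diagnosis distribution of independent probands. It does *not*
emulate gene-level heterogeneity, phenotype structure, relatedness, referral
bias, or temporal drift in panel content; a pass on simulated cohorts
therefore demonstrates the correctness of the accounting and the
statistics, not the clinical generalisability of any particular yield.

## Numerical and interface choices

* Undiagnosed outcomes are encoded as an explicit `diagnostic_level = 0`
  (never `NA`), so TSV files round-trip without sentinel ambiguity; the
  fixture's undiagnosed probands are `U01`–`U45` and diagnosed probands
  keep their published `#1`–`#27` identifiers.
* The number of tiers `k` defaults to 3 but is a parameter throughout; the
  engine generalises to any K-tier pathway with disjoint detection sets.
* Displayed percentages: `format_pct()` rounds half-up by default and can
  truncate at the last kept digit (`truncate = TRUE`), which is how a
  marginal yield of 5.555…% is displayed as 5.5%. Raw proportions are
  always carried alongside formatted ones. p-values display to three
  decimals with values below 0.001 shown as "<0.001".
* Gene symbols, genotype classes and phenotype labels in the fixture are
  opaque annotations: only membership checks (e.g. genotype ∈ {Het, Hom,
  Hemi}) are enforced, and no variant-nomenclature validation is attempted
  — variant-level analysis is out of scope.
* Problem sizes in the test suite: property checks use 50–100 randomised
  cohorts of up to ~60 probands, the law-of-large-numbers check uses
  n = 10⁵, and the bootstrap acceptance checks use the full B = 500; the
  whole suite completes in well under a minute.

## Limitations

The evaluation costs only the NGS reimbursement: no discounting, no QALYs,
no downstream-care offsets, and no pre-NGS workup costs (karyotype,
array-CGH) are modelled. The monotone-diagnosis assumption is untestable
from the observed data. The per-proband bootstrap treats the cohort as an
i.i.d. sample from its referral population; with n = 72 and 500 replicates
the plane's quadrant proportions are stable but its tails are not precise.
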