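# Shared generators and independent oracles used across test files.

# Random cohort with levels drawn uniformly from 0..k.
random_cohort <- function(n, k) {
  cohort(data.frame(
    patient_id = sprintf("r%03d", seq_len(n)),
    diagnostic_level = sample(0:k, n, replace = TRUE),
    stringsAsFactors = FALSE
  ))
}

# Random outcome matrix built from a random cohort (rows sum to at most 1).
random_outcome_matrix <- function(n, k) {
  outcome_matrix(random_cohort(n, k), k = k)
}

# Random pathway over levels 1..k: a random ordered partition of a random
# subset of levels into tiers, with random per-tier unit costs.
random_pathway <- function(k, name = "random") {
  covered <- sort(sample(seq_len(k), sample(k, 1)))
  n_tiers <- sample(length(covered), 1)
  split_groups <- sort(sample(seq_len(n_tiers), length(covered), replace = TRUE))
  tiers <- lapply(seq_len(n_tiers), function(t) {
    lv <- covered[split_groups == t]
    if (length(lv) == 0) NULL
    else tier_definition(paste0("t", t), stats::runif(1, 0, 5000), lv)
  })
  tiers <- Filter(Negate(is.null), tiers)
  pathway_model(name, tiers)
}

# Brute-force per-patient simulation of a pathway: an explicit loop over
# probands and tiers, independent of apply_pathway's vectorised accounting.
brute_force_pathway <- function(cohort, pathway) {
  total_cost <- 0
  n_diag <- 0
  tests <- integer(length(pathway$tiers))
  for (i in seq_len(nrow(cohort))) {
    lvl <- cohort$diagnostic_level[i]
    for (t in seq_along(pathway$tiers)) {
      tests[t] <- tests[t] + 1
      total_cost <- total_cost + pathway$tiers[[t]]$unit_cost
      if (lvl %in% pathway$tiers[[t]]$detects) {
        n_diag <- n_diag + 1
        break
      }
    }
  }
  list(tests = tests, total_cost = total_cost, n_diagnosed = n_diag)
}

# Chi-square upper-tail probability by numerical integration of the density,
# independent of pchisq.
chisq_tail_by_integration <- function(stat, df) {
  stats::integrate(function(x) stats::dchisq(x, df = df), lower = stat,
                   upper = Inf, rel.tol = 1e-12)$value
}

# The packaged cohort and its outcome matrix, loaded once per test run.
fixture_cohort <- function() dee_cohort()
fixture_matrix <- function() outcome_matrix(dee_cohort())
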