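# Reimbursement cost engine: pathway definitions, tests-performed accounting
# under the monotone-diagnosis assumption, cost per diagnosis, incremental
# comparisons.

#' Define one testing tier of a diagnostic pathway
#'
#' @param label tier name.
#' @param unit_cost reimbursement in euros for performing this tier on one
#'   proband (>= 0).
#' @param detects integer set of diagnostic levels this tier can resolve.
#' @return A `tier_definition` list.
#' @export
tier_definition <- function(label, unit_cost, detects) {
  stopifnot(is.character(label), length(label) == 1)
  stopifnot(length(unit_cost) == 1, unit_cost >= 0)
  detects <- as.integer(detects)
  if (length(detects) == 0) stop("a tier must detect at least one level", call. = FALSE)
  stopifnot(all(detects >= 1))
  structure(list(label = label, unit_cost = as.numeric(unit_cost),
                 detects = sort(unique(detects))),
            class = "tier_definition")
}

#' Define a diagnostic pathway as an ordered sequence of tiers
#'
#' A proband traverses the tiers in order and exits after the first tier
#' whose cumulative detection set contains their diagnostic level; every
#' tier performed is reimbursed at that tier's unit cost.  Detection sets of
#' distinct tiers must be disjoint so cumulative coverage is well defined.
#'
#' @param name pathway name.
#' @param tiers list of [tier_definition()]s.
#' @return A `pathway_model` list.
#' @export
pathway_model <- function(name, tiers) {
  stopifnot(is.character(name), length(name) == 1, length(tiers) >= 1)
  stopifnot(all(vapply(tiers, inherits, logical(1), "tier_definition")))
  all_detects <- unlist(lapply(tiers, `[[`, "detects"))
  if (anyDuplicated(all_detects)) {
    stop("detection sets of distinct tiers must be disjoint", call. = FALSE)
  }
  structure(list(name = name, tiers = tiers), class = "pathway_model")
}

#' The three standard pathway strategies
#'
#' Builds the strategies compared in a tiered exome-reanalysis evaluation,
#' all reimbursed at a single per-analysis tariff (the regional tariff does
#' not distinguish between NGS techniques):
#'
#' * `reference` -- two-step virtual panels only: a first panel resolving
#'   level-1 diagnoses, then an expanded panel resolving level-2 diagnoses.
#'   Each step is a separately reimbursed analysis.
#' * `model1` -- the two panels followed by exome sequencing as a
#'   third-step test, each step reimbursed.
#' * `model2` -- exome sequencing from the start: one reimbursed
#'   sequencing act whose stored data are reanalysed through successively
#'   wider virtual panels at no additional reimbursement, so the single
#'   tier resolves all three levels.
#'
#' @param unit_cost reimbursement per analysis in euros (default 2072.74,
#'   the Lombardia regional tariff for an NGS analysis).
#' @param k number of diagnostic levels (default 3).
#' @return Named list of three [pathway_model()]s:
#'   `reference`, `model1`, `model2`.
#' @examples
#' standard_pathways()$model2
#' @export
standard_pathways <- function(unit_cost = 2072.74, k = 3) {
  stopifnot(unit_cost >= 0, k >= 2)
  panel_tiers <- lapply(seq_len(k - 1), function(j) {
    tier_definition(paste0("panel", j), unit_cost, j)
  })
  list(
    reference = pathway_model("reference", panel_tiers),
    model1 = pathway_model("model1", c(panel_tiers, list(
      tier_definition("exome", unit_cost, k)
    ))),
    model2 = pathway_model("model2", list(
      tier_definition("exome_first", unit_cost, seq_len(k))
    ))
  )
}

#' Run a cohort through a diagnostic pathway and account its costs
#'
#' Every proband undergoes the tiers in order and stops after the first tier
#' whose cumulative detection set contains their diagnostic level; probands
#' whose level is never covered -- including the undiagnosed (level 0) --
#' undergo every tier and exit undiagnosed.  This implements the
#' monotone-diagnosis assumption: a proband diagnosed early would also have
#' been diagnosed by any later, more inclusive tier.
#'
#' @param cohort a [cohort()].
#' @param pathway a [pathway_model()].
#' @return A `cost_result` list: `pathway_name`, `n`, `tests_per_tier`,
#'   `total_tests`, `total_cost` (euros), `n_diagnosed`, and
#'   `cost_per_diagnosis` (`NA` when no proband is diagnosed).
#' @examples
#' apply_pathway(dee_cohort(), standard_pathways()$model2)
#' @export
apply_pathway <- function(cohort, pathway) {
  stopifnot(inherits(cohort, "tierdx_cohort"), inherits(pathway, "pathway_model"))
  n <- nrow(cohort)
  lvl <- cohort$diagnostic_level
  n_tiers <- length(pathway$tiers)
  # Probands still being tested at tier t: those not yet resolved by the
  # detection sets of tiers 1..t-1.
  tests <- integer(n_tiers)
  remaining <- rep(TRUE, n)
  diagnosed_at <- integer(n_tiers)
  for (t in seq_len(n_tiers)) {
    tests[t] <- sum(remaining)
    hit <- remaining & lvl %in% pathway$tiers[[t]]$detects
    diagnosed_at[t] <- sum(hit)
    remaining <- remaining & !hit
  }
  unit_costs <- vapply(pathway$tiers, `[[`, numeric(1), "unit_cost")
  labels <- vapply(pathway$tiers, `[[`, character(1), "label")
  total_cost <- sum(tests * unit_costs)
  n_diagnosed <- sum(diagnosed_at)
  structure(
    list(
      pathway_name = pathway$name,
      n = n,
      tests_per_tier = stats::setNames(tests, labels),
      diagnosed_per_tier = stats::setNames(diagnosed_at, labels),
      total_tests = sum(tests),
      total_cost = total_cost,
      n_diagnosed = n_diagnosed,
      cost_per_diagnosis = if (n_diagnosed > 0) total_cost / n_diagnosed else NA_real_
    ),
    class = "cost_result"
  )
}

#' @export
print.cost_result <- function(x, ...) {
  cat("Pathway:", x$pathway_name, "  (n =", x$n, "probands)\n")
  cat("Tests per tier:",
      paste(names(x$tests_per_tier), x$tests_per_tier, sep = "=", collapse = ", "),
      "\n")
  cat(sprintf("Total cost: %.2f EUR over %d tests\n", x$total_cost, x$total_tests))
  if (is.na(x$cost_per_diagnosis)) {
    cat("Diagnoses: 0 (cost per diagnosis undefined)\n")
  } else {
    cat(sprintf("Diagnoses: %d  Cost per diagnosis: %.2f EUR\n",
                x$n_diagnosed, x$cost_per_diagnosis))
  }
  invisible(x)
}

#' Incremental cost and diagnoses of one pathway over a reference
#'
#' Computes the cost difference, the difference in diagnoses, and the
#' incremental cost-effectiveness ratio (ICER, euros per additional
#' diagnosis) of `model` relative to `reference` evaluated on the same
#' cohort.  A strategy with at least as many diagnoses at no greater cost
#' (and not identical on both axes) is flagged `dominant`; the ICER is `NA`
#' when there is no change in diagnoses.
#'
#' @param model,reference `cost_result`s from [apply_pathway()] on the same
#'   cohort.
#' @return An `incremental_result` list: `model_name`, `reference_name`,
#'   `delta_cost`, `delta_diagnoses`, `icer`, `dominant`.
#' @examples
#' p <- standard_pathways()
#' co <- dee_cohort()
#' incremental(apply_pathway(co, p$model2), apply_pathway(co, p$reference))
#' @export
incremental <- function(model, reference) {
  stopifnot(inherits(model, "cost_result"), inherits(reference, "cost_result"))
  if (model$n != reference$n) {
    stop("cost results were computed on cohorts of different sizes (",
         model$n, " vs ", reference$n, ")", call. = FALSE)
  }
  dc <- model$total_cost - reference$total_cost
  dd <- model$n_diagnosed - reference$n_diagnosed
  dominant <- dc <= 0 && dd >= 0 && !(dc == 0 && dd == 0)
  icer <- if (dd != 0) dc / dd else NA_real_
  structure(
    list(
      model_name = model$pathway_name,
      reference_name = reference$pathway_name,
      delta_cost = dc,
      delta_diagnoses = dd,
      icer = icer,
      dominant = dominant
    ),
    class = "incremental_result"
  )
}

#' @export
print.incremental_result <- function(x, ...) {
  cat(sprintf("%s vs %s: delta cost %.2f EUR, delta diagnoses %d\n",
              x$model_name, x$reference_name, x$delta_cost, x$delta_diagnoses))
  if (x$dominant) {
    cat("Dominant: no fewer diagnoses at no greater cost\n")
  } else if (is.na(x$icer)) {
    cat("ICER undefined (no change in diagnoses)\n")
  } else {
    cat(sprintf("ICER: %.2f EUR per additional diagnosis\n", x$icer))
  }
  invisible(x)
}
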