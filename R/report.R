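# End-to-end analysis: configuration, orchestration of yields, paired tests,
# pathway costs and the bootstrap plane, and machine- plus human-readable
# outputs.

#' Configuration for a full pathway analysis run
#'
#' Exactly one cohort source must be given: a TSV `cohort_path`, the
#' packaged study cohort (`fixture = TRUE`), or a simulation described by
#' `sim_n`/`sim_probs`.  All randomness in the run (simulation and
#' bootstrap) derives from `seed`.
#'
#' @param cohort_path path to a cohort TSV (see [load_cohort()]).
#' @param fixture use the packaged 72-proband cohort ([dee_cohort()]).
#' @param sim_n,sim_probs simulate a cohort of `sim_n` probands with tier
#'   probabilities `sim_probs` (see [simulate_cohort()]).
#' @param unit_cost reimbursement per analysis in euros (default 2072.74).
#' @param k number of diagnostic tiers (default 3).
#' @param alpha significance level for pairwise flags (default 0.05).
#' @param B bootstrap replicates (default 500); `B = 0` skips the bootstrap.
#' @param seed integer master seed (default 20210948).
#' @param outdir output directory, created if needed.
#' @param figure also write the cost-effectiveness plane as `ce_plane.svg`
#'   (needs ggplot2 and `B > 0`).
#' @return A `run_config` list.
#' @export
run_config <- function(cohort_path = NULL, fixture = FALSE,
                       sim_n = NULL, sim_probs = NULL,
                       unit_cost = 2072.74, k = 3, alpha = 0.05,
                       B = 500, seed = 20210948,
                       outdir = "tierdx-results", figure = FALSE) {
  sources <- c(!is.null(cohort_path), isTRUE(fixture), !is.null(sim_n))
  if (sum(sources) != 1) {
    stop("specify exactly one cohort source: cohort_path, fixture, or sim_n",
         call. = FALSE)
  }
  if (!is.null(sim_n) && is.null(sim_probs)) {
    stop("sim_probs is required when simulating", call. = FALSE)
  }
  stopifnot(unit_cost >= 0, alpha > 0, alpha < 1, B >= 0, k >= 2)
  structure(
    list(cohort_path = cohort_path, fixture = isTRUE(fixture),
         sim_n = sim_n, sim_probs = sim_probs,
         unit_cost = unit_cost, k = k, alpha = alpha, B = B,
         seed = as.integer(seed), outdir = outdir, figure = isTRUE(figure)),
    class = "run_config"
  )
}

#' Run the full tiered-pathway analysis
#'
#' Loads (or simulates) the cohort, computes the per-tier yield table,
#' Cochran's Q and all pairwise McNemar tests, evaluates the three standard
#' pathway strategies and their incremental comparisons against the
#' two-step-panels reference, and -- unless `B = 0` -- runs the paired
#' patient-level bootstrap of the cost-effectiveness plane.  All results are
#' written under `config$outdir`:
#'
#' * `cohort.tsv` -- the cohort analysed
#' * `yields.csv`, `pairwise_tests.csv`, `costs.csv`, `incremental.csv`
#' * `results.json` -- everything machine readable in one document
#' * `bootstrap_points.csv`, `ce_summary.csv` (when `B > 0`)
#' * `ce_plane.svg` (when `figure = TRUE`)
#' * `summary.txt` -- human-readable restatement of the headline numbers
#'
#' The text summary is formatted from the already-computed results; nothing
#' is recomputed in the formatter, so the two views cannot disagree.  Two
#' runs with an identical configuration produce byte-identical non-figure
#' outputs.
#'
#' @param config a [run_config()].
#' @param quiet suppress progress messages.
#' @return Invisibly, a list with elements `cohort`, `yields`, `cochran`,
#'   `pairwise`, `costs`, `incremental`, `points`, `ce_summary`, `files`.
#' @examples
#' \donttest{
#' res <- run_analysis(run_config(fixture = TRUE, B = 50, outdir = tempfile()))
#' res$yields
#' }
#' @export
run_analysis <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message("[tierdx] ", ...)

  co <- if (!is.null(config$cohort_path)) {
    say("loading cohort from ", config$cohort_path)
    load_cohort(config$cohort_path)
  } else if (config$fixture) {
    say("using the packaged 72-proband study cohort")
    dee_cohort()
  } else {
    say("simulating cohort: n = ", config$sim_n, ", seed = ", config$seed)
    simulate_cohort(config$sim_n, config$sim_probs, seed = config$seed)
  }

  mat <- outcome_matrix(co, k = config$k)
  yields <- yield_table(mat)
  cochran <- cochran_q(mat)
  pairwise <- pairwise_mcnemar(mat, alpha = config$alpha)
  say(sprintf("overall yield %.1f%% (%d/%d); Cochran Q = %.3f, p = %.3g",
              100 * attr(yields, "overall_yield"),
              yields$cum_count[nrow(yields)], attr(yields, "n"),
              cochran$statistic, cochran$p.value))

  paths <- standard_pathways(config$unit_cost, k = config$k)
  costs <- lapply(paths, apply_pathway, cohort = co)
  incs <- list(
    model1 = incremental(costs$model1, costs$reference),
    model2 = incremental(costs$model2, costs$reference)
  )
  say(sprintf("cost per diagnosis: reference %.2f, model1 %.2f, model2 %.2f EUR",
              costs$reference$cost_per_diagnosis,
              costs$model1$cost_per_diagnosis,
              costs$model2$cost_per_diagnosis))

  points <- NULL
  ce_sum <- NULL
  if (config$B > 0) {
    say("bootstrapping cost-effectiveness plane: B = ", config$B)
    points <- bootstrap_ce(co, paths[c("model1", "model2")], paths$reference,
                           B = config$B, seed = config$seed)
    ce_sum <- summarize_ce(points)
  }

  files <- write_outputs(config, co, yields, cochran, pairwise, costs, incs,
                         points, ce_sum)
  say("outputs written to ", config$outdir)
  invisible(list(cohort = co, yields = yields, cochran = cochran,
                 pairwise = pairwise, costs = costs, incremental = incs,
                 points = points, ce_summary = ce_sum, files = files))
}

costs_frame <- function(costs) {
  do.call(rbind, lapply(costs, function(cr) {
    data.frame(
      pathway = cr$pathway_name,
      n = cr$n,
      total_tests = cr$total_tests,
      total_cost = cr$total_cost,
      n_diagnosed = cr$n_diagnosed,
      cost_per_diagnosis = cr$cost_per_diagnosis,
      stringsAsFactors = FALSE
    )
  }))
}

incremental_frame <- function(incs) {
  do.call(rbind, lapply(incs, function(x) {
    data.frame(
      model = x$model_name,
      reference = x$reference_name,
      delta_cost = x$delta_cost,
      delta_diagnoses = x$delta_diagnoses,
      icer = x$icer,
      dominant = x$dominant,
      stringsAsFactors = FALSE
    )
  }))
}

write_outputs <- function(config, co, yields, cochran, pairwise, costs, incs,
                          points, ce_sum) {
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(config$outdir, f)
  files <- character(0)

  write_cohort(co, p("cohort.tsv"))
  utils::write.csv(as.data.frame(yields), p("yields.csv"), row.names = FALSE)
  utils::write.csv(pairwise, p("pairwise_tests.csv"), row.names = FALSE)
  cdf <- costs_frame(costs)
  idf <- incremental_frame(incs)
  utils::write.csv(cdf, p("costs.csv"), row.names = FALSE)
  utils::write.csv(idf, p("incremental.csv"), row.names = FALSE)
  files <- c(files, p(c("cohort.tsv", "yields.csv", "pairwise_tests.csv",
                        "costs.csv", "incremental.csv")))

  doc <- list(
    n = attr(yields, "n"),
    overall_yield = attr(yields, "overall_yield"),
    yields = as.data.frame(yields),
    cochran_q = list(Q = unname(cochran$statistic),
                     df = unname(cochran$parameter),
                     p_value = cochran$p.value),
    pairwise_mcnemar = pairwise,
    alpha = config$alpha,
    unit_cost = config$unit_cost,
    costs = cdf,
    incremental = idf,
    seed = config$seed
  )
  if (!is.null(ce_sum)) doc$ce_summary <- as.data.frame(ce_sum)
  jsonlite::write_json(doc, p("results.json"), auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null", pretty = TRUE)
  files <- c(files, p("results.json"))

  if (!is.null(points)) {
    utils::write.csv(as.data.frame(points), p("bootstrap_points.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(ce_sum), p("ce_summary.csv"),
                     row.names = FALSE)
    files <- c(files, p(c("bootstrap_points.csv", "ce_summary.csv")))
    if (config$figure && requireNamespace("ggplot2", quietly = TRUE)) {
      fig <- plot_ce_plane(points)
      grDevices::svg(p("ce_plane.svg"), width = 7, height = 5)
      print(fig)
      grDevices::dev.off()
      files <- c(files, p("ce_plane.svg"))
    }
  }

  writeLines(text_summary(yields, cochran, pairwise, costs, incs, ce_sum),
             p("summary.txt"))
  files <- c(files, p("summary.txt"))
  files
}

# Human-readable restatement of already-computed numbers; no recomputation
# beyond formatting.
text_summary <- function(yields, cochran, pairwise, costs, incs, ce_sum) {
  n <- attr(yields, "n")
  lines <- c(
    "Tiered diagnostic pathway analysis",
    "==================================",
    "",
    sprintf("Cohort: %d probands, %d tiers", n, nrow(yields)),
    sprintf("Overall diagnostic yield: %s (%d/%d)",
            format_pct(attr(yields, "overall_yield")),
            yields$cum_count[nrow(yields)], n),
    "",
    "Per-tier yields (marginal):"
  )
  for (i in seq_len(nrow(yields))) {
    lines <- c(lines, sprintf("  %-8s %3d/%d  %s", yields$label[i],
                              yields$count[i], n,
                              format_pct(yields$yield[i], digits = 1,
                                         truncate = TRUE)))
  }
  lines <- c(
    lines, "",
    sprintf("Cochran's Q = %.3f (df = %d), p = %s",
            cochran$statistic, cochran$parameter, format_p(cochran$p.value)),
    "Pairwise McNemar (no continuity correction):"
  )
  for (i in seq_len(nrow(pairwise))) {
    lines <- c(lines, sprintf(
      "  tier %d vs %d: b = %d, c = %d, chi2 = %.3f, p = %s%s",
      pairwise$tier_a[i], pairwise$tier_b[i], pairwise$b[i], pairwise$c[i],
      pairwise$statistic[i], format_p(pairwise$p_value[i]),
      ifelse(pairwise$significant[i], " *", "")
    ))
  }
  lines <- c(lines, "", "Pathway costs:")
  for (cr in costs) {
    cpd <- if (is.na(cr$cost_per_diagnosis)) "undefined"
           else sprintf("%.2f EUR", cr$cost_per_diagnosis)
    lines <- c(lines, sprintf(
      "  %-10s %3d tests, total %12.2f EUR, %2d diagnoses, cost/diagnosis %s",
      cr$pathway_name, cr$total_tests, cr$total_cost, cr$n_diagnosed, cpd))
  }
  lines <- c(lines, "", "Incremental vs reference:")
  for (x in incs) {
    tail <- if (x$dominant) "dominant (cost saving, no fewer diagnoses)"
            else if (is.na(x$icer)) "ICER undefined"
            else sprintf("ICER %.2f EUR/additional diagnosis", x$icer)
    lines <- c(lines, sprintf(
      "  %-10s delta cost %12.2f EUR, delta diagnoses %d, %s",
      x$model_name, x$delta_cost, x$delta_diagnoses, tail))
  }
  if (!is.null(ce_sum)) {
    lines <- c(lines, "", sprintf("Bootstrap (B = %d per model):", ce_sum$B[1]))
    for (i in seq_len(nrow(ce_sum))) {
      lines <- c(lines, sprintf(
        "  %-10s mean delta diagnoses %.2f [%g, %g], mean delta cost %.2f EUR [%0.2f, %0.2f], dominance %.1f%%",
        ce_sum$model[i], ce_sum$mean_delta_diagnoses[i],
        ce_sum$lo_delta_diagnoses[i], ce_sum$hi_delta_diagnoses[i],
        ce_sum$mean_delta_cost[i], ce_sum$lo_delta_cost[i],
        ce_sum$hi_delta_cost[i], 100 * ce_sum$dominance_proportion[i]))
    }
  }
  lines
}
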