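# Patient-level bootstrap of incremental cost and incremental diagnoses,
# and the cost-effectiveness plane.

#' Bootstrap the cost-effectiveness plane
#'
#' For each of `B` replicates, `n` probands are drawn with replacement from
#' the cohort (patient-level resampling, so each proband's whole outcome is
#' kept intact), every pathway is evaluated on the *same* resampled cohort,
#' and the incremental cost and incremental number of diagnoses of each
#' model versus the reference are recorded as one point on the
#' cost-effectiveness plane (effect on the x-axis, cost on the y-axis).
#'
#' The paired design matters: incremental quantities are differences within
#' a replicate, so reference and models must see identical resampled data.
#' The run is fully reproducible from `seed` and leaves the caller's RNG
#' state untouched.
#'
#' @param cohort a [cohort()].
#' @param models named list of [pathway_model()]s to compare.
#' @param reference the reference [pathway_model()].
#' @param B number of bootstrap replicates (default 500).
#' @param seed integer seed owned by this call.
#' @return A data frame of class `ce_points` with one row per model per
#'   replicate: `replicate`, `model`, `delta_diagnoses`, `delta_cost`,
#'   `quadrant`.
#' @examples
#' p <- standard_pathways()
#' pts <- bootstrap_ce(dee_cohort(), p[c("model1", "model2")], p$reference,
#'                     B = 50, seed = 1)
#' table(pts$model, pts$quadrant)
#' @export
bootstrap_ce <- function(cohort, models, reference, B = 500, seed = 1) {
  stopifnot(inherits(cohort, "tierdx_cohort"), B >= 1)
  stopifnot(inherits(reference, "pathway_model"))
  if (inherits(models, "pathway_model")) models <- list(models)
  stopifnot(all(vapply(models, inherits, logical(1), "pathway_model")))
  n <- nrow(cohort)
  idx <- with_seed(seed, matrix(sample.int(n, n * B, replace = TRUE), nrow = n))
  rows <- vector("list", B)
  for (b in seq_len(B)) {
    resampled <- resample_cohort(cohort, idx[, b])
    ref_res <- apply_pathway(resampled, reference)
    rows[[b]] <- do.call(rbind, lapply(models, function(mod) {
      inc <- incremental(apply_pathway(resampled, mod), ref_res)
      data.frame(
        replicate = b,
        model = inc$model_name,
        delta_diagnoses = inc$delta_diagnoses,
        delta_cost = inc$delta_cost,
        stringsAsFactors = FALSE
      )
    }))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$quadrant <- classify_quadrant(out$delta_diagnoses, out$delta_cost)
  class(out) <- c("ce_points", "data.frame")
  out
}

# Resample rows of a cohort, keeping ids unique by suffixing the draw index.
resample_cohort <- function(cohort, idx) {
  out <- as.data.frame(cohort)[idx, , drop = FALSE]
  out$patient_id <- sprintf("%s.r%03d", out$patient_id, seq_along(idx))
  rownames(out) <- NULL
  class(out) <- c("tierdx_cohort", "data.frame")
  out
}

#' Classify points of the cost-effectiveness plane into quadrants
#'
#' Sign-based classification with effect (additional diagnoses) on the
#' x-axis and additional cost on the y-axis: `NE` (more diagnoses, more
#' cost), `SE` (more diagnoses, cost saving -- the dominant quadrant), `NW`,
#' `SW`; any point with a zero coordinate is labelled `axis`.
#'
#' @param delta_diagnoses,delta_cost numeric vectors of equal length.
#' @return Character vector of quadrant labels.
#' @examples
#' classify_quadrant(c(2, 2, 0), c(-105709.74, 97418.78, 0))
#' @export
classify_quadrant <- function(delta_diagnoses, delta_cost) {
  stopifnot(length(delta_diagnoses) == length(delta_cost))
  out <- rep("axis", length(delta_diagnoses))
  out[delta_diagnoses > 0 & delta_cost > 0] <- "NE"
  out[delta_diagnoses > 0 & delta_cost < 0] <- "SE"
  out[delta_diagnoses < 0 & delta_cost > 0] <- "NW"
  out[delta_diagnoses < 0 & delta_cost < 0] <- "SW"
  out
}

#' Summarise a bootstrap cost-effectiveness cloud
#'
#' Per model: the number of replicates, the proportion of points in each
#' quadrant (including `axis`), means and nearest-rank 2.5/97.5 percentiles
#' of the incremental cost and incremental diagnoses, and the dominance
#' proportion -- the fraction of replicates with no fewer diagnoses at no
#' greater cost (excluding points identical to the reference on both axes).
#'
#' @param points a `ce_points` data frame from [bootstrap_ce()].
#' @return A data frame of class `ce_summary`, one row per model.
#' @export
summarize_ce <- function(points) {
  stopifnot(inherits(points, "ce_points"))
  if (nrow(points) == 0) stop("no points to summarise", call. = FALSE)
  quadrants <- c("NE", "SE", "NW", "SW", "axis")
  pct <- function(x, p) unname(stats::quantile(x, p, type = 1))  # nearest rank
  rows <- lapply(split(points, points$model), function(d) {
    qprop <- vapply(quadrants, function(q) mean(d$quadrant == q), numeric(1))
    dom <- mean(d$delta_diagnoses >= 0 & d$delta_cost <= 0 &
                  !(d$delta_diagnoses == 0 & d$delta_cost == 0))
    cbind(
      data.frame(model = d$model[1], B = nrow(d), stringsAsFactors = FALSE),
      as.data.frame(as.list(stats::setNames(qprop, paste0("prop_", quadrants)))),
      data.frame(
        mean_delta_diagnoses = mean(d$delta_diagnoses),
        lo_delta_diagnoses = pct(d$delta_diagnoses, 0.025),
        hi_delta_diagnoses = pct(d$delta_diagnoses, 0.975),
        mean_delta_cost = mean(d$delta_cost),
        lo_delta_cost = pct(d$delta_cost, 0.025),
        hi_delta_cost = pct(d$delta_cost, 0.975),
        dominance_proportion = dom
      )
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("ce_summary", "data.frame")
  out
}

#' Plot the cost-effectiveness plane
#'
#' Scatter of bootstrap replicates with the additional number of diagnoses
#' on the x-axis and the additional cost (euros) on the y-axis, quadrant
#' axes drawn through the origin, and the cost-saving half-plane (below the
#' x-axis) shaded.  Requires ggplot2.
#'
#' @param points a `ce_points` data frame from [bootstrap_ce()].
#' @return A ggplot object.
#' @export
plot_ce_plane <- function(points) {
  stopifnot(inherits(points, "ce_points"))
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  ymin <- min(points$delta_cost, 0)
  xr <- range(points$delta_diagnoses, 0)
  ggplot2::ggplot(points,
                  ggplot2::aes(x = .data$delta_diagnoses,
                               y = .data$delta_cost,
                               colour = .data$model)) +
    ggplot2::annotate("rect", xmin = -Inf, xmax = Inf, ymin = -Inf, ymax = 0,
                      fill = "grey85", alpha = 0.5) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.3) +
    ggplot2::geom_jitter(width = 0.12, height = 0, alpha = 0.6, size = 1.4) +
    ggplot2::labs(x = "Additional diagnoses (effect)",
                  y = "Additional cost (EUR)",
                  colour = NULL,
                  title = "Cost-effectiveness plane",
                  subtitle = "Shaded half-plane is cost saving") +
    ggplot2::theme_minimal()
}
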