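# Diagnostic yields per tier and paired-proportion tests (Cochran's Q,
# McNemar) on the marginal tier indicators.

#' Marginal and cumulative diagnostic yields per tier
#'
#' For each tier j the marginal count d_j (probands first diagnosed at that
#' tier), the marginal yield d_j / n, and the cumulative count and yield over
#' tiers 1..j.  The overall diagnostic yield of the pathway is the cumulative
#' yield at the last tier.
#'
#' @param matrix an [outcome_matrix()].
#' @return A data frame of class `yield_table` with one row per tier and
#'   columns `tier`, `label`, `count`, `yield`, `cum_count`, `cum_yield`,
#'   plus attributes `n` (cohort size) and `overall_yield`.
#' @examples
#' yield_table(outcome_matrix(dee_cohort()))
#' @export
yield_table <- function(matrix) {
  stopifnot(inherits(matrix, "outcome_matrix"))
  n <- nrow(matrix)
  if (n == 0) stop("empty outcome matrix", call. = FALSE)
  d <- colSums(matrix)
  out <- data.frame(
    tier = seq_len(ncol(matrix)),
    label = colnames(matrix),
    count = as.integer(d),
    yield = as.numeric(d) / n,
    cum_count = as.integer(cumsum(d)),
    cum_yield = as.numeric(cumsum(d)) / n,
    stringsAsFactors = FALSE
  )
  attr(out, "n") <- n
  attr(out, "overall_yield") <- sum(d) / n
  class(out) <- c("yield_table", "data.frame")
  out
}

#' Format a proportion as a percentage string
#'
#' `truncate = FALSE` (default) rounds half-up at the last kept digit;
#' `truncate = TRUE` floors at the last kept digit, so 5.555...% becomes
#' "5.5%" rather than "5.6%".  Raw proportions should always be reported
#' alongside formatted ones; this helper only controls display.
#'
#' @param p proportion(s) in \[0, 1\].
#' @param digits decimal places kept on the percentage scale.
#' @param truncate floor instead of rounding at the last kept digit.
#' @return Character vector like `"37.5%"`.
#' @examples
#' format_pct(4 / 72, digits = 1, truncate = TRUE)  # "5.5%"
#' @export
format_pct <- function(p, digits = 1, truncate = FALSE) {
  x <- 100 * p
  scale <- 10^digits
  x <- if (truncate) floor(x * scale) / scale else floor(x * scale + 0.5) / scale
  paste0(formatC(x, format = "fg"), "%")
}

#' Cochran's Q test for equality of k paired binary proportions
#'
#' Tests whether the per-tier diagnosis proportions differ, treating the k
#' marginal indicators of each proband as paired observations.  With column
#' sums C_j and row sums R_i of the marginal matrix,
#' \deqn{Q = (k-1)\,\frac{k \sum_j C_j^2 - (\sum_j C_j)^2}{k \sum_i R_i - \sum_i R_i^2}}
#' and the p-value is the upper tail of the chi-square distribution on k - 1
#' degrees of freedom.  When every row is constant (no discordance) the
#' statistic is undefined; the test then returns Q = 0, p = 1 with a warning
#' rather than failing, so that resampled replicates always yield a result.
#'
#' @param matrix an [outcome_matrix()] with at least two tiers.
#' @return An object of class `htest` with components `statistic` (Q),
#'   `parameter` (df = k - 1) and `p.value`.
#' @examples
#' cochran_q(outcome_matrix(dee_cohort()))
#' @export
cochran_q <- function(matrix) {
  stopifnot(inherits(matrix, "outcome_matrix"))
  k <- ncol(matrix)
  if (k < 2) stop("Cochran's Q needs at least two tiers", call. = FALSE)
  m <- unclass(matrix)
  Cj <- colSums(m)
  Ri <- rowSums(m)
  denom <- k * sum(Ri) - sum(Ri^2)
  if (denom == 0) {
    warning("all probands have identical indicators across tiers; ",
            "Q is degenerate, returning Q = 0, p = 1", call. = FALSE)
    q <- 0
    p <- 1
  } else {
    q <- (k - 1) * (k * sum(Cj^2) - sum(Cj)^2) / denom
    p <- stats::pchisq(q, df = k - 1, lower.tail = FALSE)
  }
  structure(
    list(
      statistic = c(Q = q),
      parameter = c(df = k - 1),
      p.value = p,
      method = "Cochran's Q test for paired proportions",
      data.name = paste0(nrow(m), " probands x ", k, " tiers")
    ),
    class = "htest"
  )
}

#' McNemar test between two tiers
#'
#' Compares the marginal diagnosis indicators of tiers `j` and `m`.  With
#' discordant counts b (diagnosed at tier j only) and c (diagnosed at tier m
#' only), the statistic is (b - c)^2 / (b + c) with no continuity
#' correction, referred to chi-square on 1 degree of freedom.  When
#' b + c = 0 the statistic is 0 and p = 1.
#'
#' The test deliberately uses the tier-specific (marginal) indicators, not
#' the cumulative ones: the question is whether two tiers contribute
#' diagnoses at different rates, and the asymptotic uncorrected form is used
#' even at small discordant counts.  `exact = TRUE` gives the exact binomial
#' alternative (b successes in b + c trials at p = 1/2, two-sided) for
#' sensitivity checks.
#'
#' @param matrix an [outcome_matrix()].
#' @param j,m distinct tier indices.
#' @param exact use the exact binomial test instead of the asymptotic
#'   chi-square (default `FALSE`).
#' @return An object of class `htest`, with the discordant counts in
#'   `estimate` (named `b` and `c`).
#' @examples
#' mcnemar_pair(outcome_matrix(dee_cohort()), 2, 3)
#' @export
mcnemar_pair <- function(matrix, j, m, exact = FALSE) {
  stopifnot(inherits(matrix, "outcome_matrix"))
  k <- ncol(matrix)
  if (j == m) stop("tiers to compare must be distinct", call. = FALSE)
  stopifnot(j >= 1, j <= k, m >= 1, m <= k)
  x <- unclass(matrix)
  b <- sum(x[, j] == 1 & x[, m] == 0)
  c_ <- sum(x[, j] == 0 & x[, m] == 1)
  if (exact) {
    if (b + c_ == 0) {
      p <- 1
    } else {
      p <- min(1, 2 * stats::pbinom(min(b, c_), size = b + c_, prob = 0.5))
    }
    stat <- c(b = b)
    param <- c(`b + c` = b + c_)
    method <- "Exact McNemar test (binomial)"
  } else {
    stat <- c(`chi-squared` = if (b + c_ == 0) 0 else (b - c_)^2 / (b + c_))
    param <- c(df = 1)
    p <- if (b + c_ == 0) 1 else stats::pchisq(stat, df = 1, lower.tail = FALSE)
    method <- "McNemar test without continuity correction"
  }
  structure(
    list(
      statistic = stat,
      parameter = param,
      p.value = unname(p),
      estimate = c(b = b, c = c_),
      method = method,
      data.name = paste0("tiers ", j, " vs ", m)
    ),
    class = "htest"
  )
}

#' All pairwise McNemar comparisons between tiers
#'
#' One row per unordered tier pair in lexicographic order, flagged
#' significant when the p-value is at or below `alpha`.  No multiplicity
#' adjustment is applied across the pairs.
#'
#' @param matrix an [outcome_matrix()] with at least two tiers.
#' @param alpha significance level in (0, 1); default 0.05.
#' @param exact passed to [mcnemar_pair()].
#' @return Data frame with columns `tier_a`, `tier_b`, `b`, `c`,
#'   `statistic`, `p_value`, `significant`.
#' @examples
#' pairwise_mcnemar(outcome_matrix(dee_cohort()))
#' @export
pairwise_mcnemar <- function(matrix, alpha = 0.05, exact = FALSE) {
  stopifnot(inherits(matrix, "outcome_matrix"))
  stopifnot(alpha > 0, alpha < 1)
  k <- ncol(matrix)
  if (k < 2) stop("need at least two tiers", call. = FALSE)
  pairs <- utils::combn(k, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    j <- pairs[1, i]
    m <- pairs[2, i]
    res <- mcnemar_pair(matrix, j, m, exact = exact)
    data.frame(
      tier_a = j, tier_b = m,
      b = unname(res$estimate["b"]), c = unname(res$estimate["c"]),
      statistic = unname(res$statistic[1]),
      p_value = res$p.value,
      significant = res$p.value <= alpha,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "alpha") <- alpha
  out
}

#' Format a p-value in report style
#'
#' Three decimals, with values below 0.001 printed as `"<0.001"`.
#'
#' @param p p-value(s).
#' @return Character vector.
#' @export
format_p <- function(p) {
  ifelse(p < 0.001, "<0.001", formatC(round(p, 3), format = "f", digits = 3))
}
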