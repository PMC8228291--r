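# Cohort data model: validated patient-level tables, TSV I/O, the packaged
# study cohort, and a multinomial cohort simulator.

#' @keywords internal
"_PACKAGE"

# Canonical column order for a cohort table.  Only the first two are required;
# the rest are optional annotations carried through from the study table.
.cohort_cols <- c(
  "patient_id", "diagnostic_level", "sex", "age_years",
  "age_at_diagnosis_years", "gene", "genotype_class", "phenotype_label"
)
.required_cols <- c("patient_id", "diagnostic_level")

#' Construct and validate a cohort of probands
#'
#' A cohort is a data frame with one row per proband.  `diagnostic_level`
#' records the testing tier at which a molecular diagnosis was first reached:
#' `1`, `2`, ... up to the number of tiers, or `0` for a proband who remained
#' undiagnosed after the full pathway.  Undiagnosed probands are encoded with
#' an explicit `0` (never a missing value) so that tables round-trip through
#' TSV without sentinel ambiguity.
#'
#' Optional annotation columns (`sex`, `age_years`, `age_at_diagnosis_years`,
#' `gene`, `genotype_class`, `phenotype_label`) may be supplied; missing ones
#' are filled with `NA`.  Gene and variant annotations are carried as opaque
#' text; no nomenclature validation is attempted.
#'
#' @param records data frame with at least `patient_id` and
#'   `diagnostic_level` columns.
#' @return The validated cohort, a `data.frame` of class `tierdx_cohort` with
#'   the canonical column set.
#' @examples
#' cohort(data.frame(patient_id = c("a", "b"), diagnostic_level = c(1, 0)))
#' @export
cohort <- function(records) {
  stopifnot(is.data.frame(records))
  missing_cols <- setdiff(.required_cols, names(records))
  if (length(missing_cols) > 0) {
    stop("cohort table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(names(records), .cohort_cols)
  if (length(extra) > 0) {
    warning("ignoring unrecognised column(s): ", paste(extra, collapse = ", "),
            call. = FALSE)
  }
  out <- data.frame(
    patient_id = as.character(records$patient_id),
    diagnostic_level = as.integer(records$diagnostic_level),
    stringsAsFactors = FALSE
  )
  for (col in setdiff(.cohort_cols, .required_cols)) {
    value <- if (col %in% names(records)) records[[col]] else NA
    if (col %in% c("age_years", "age_at_diagnosis_years")) {
      out[[col]] <- as.numeric(value)
    } else {
      value <- as.character(value)
      value[!is.na(value) & !nzchar(value)] <- NA_character_
      out[[col]] <- value
    }
  }
  rownames(out) <- NULL
  validate_cohort(out)
  class(out) <- c("tierdx_cohort", "data.frame")
  out
}

validate_cohort <- function(x) {
  if (nrow(x) < 1) stop("a cohort must contain at least one proband", call. = FALSE)
  if (anyNA(x$patient_id) || !all(nzchar(x$patient_id))) {
    stop("every proband needs a non-empty patient_id", call. = FALSE)
  }
  if (anyDuplicated(x$patient_id)) {
    dup <- unique(x$patient_id[duplicated(x$patient_id)])
    stop("duplicate patient_id: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  bad <- which(is.na(x$diagnostic_level) | x$diagnostic_level < 0)
  if (length(bad) > 0) {
    stop("diagnostic_level must be a non-negative integer; offending row(s): ",
         paste(bad, collapse = ", "), " (patient ",
         paste(x$patient_id[bad], collapse = ", "), ")", call. = FALSE)
  }
  ages <- c(x$age_years, x$age_at_diagnosis_years)
  if (any(ages < 0, na.rm = TRUE)) {
    stop("ages must be non-negative", call. = FALSE)
  }
  gt <- x$genotype_class
  if (!all(is.na(gt) | gt %in% c("Het", "Hom", "Hemi"))) {
    stop("genotype_class must be one of Het, Hom, Hemi", call. = FALSE)
  }
  undx <- x$diagnostic_level == 0
  if (any(undx & (!is.na(x$gene) | !is.na(x$genotype_class) |
                  !is.na(x$age_at_diagnosis_years)))) {
    stop("undiagnosed probands (diagnostic_level = 0) cannot carry gene, ",
         "genotype_class or age_at_diagnosis_years", call. = FALSE)
  }
  invisible(x)
}

check_levels <- function(cohort, k) {
  bad <- which(cohort$diagnostic_level > k)
  if (length(bad) > 0) {
    stop("diagnostic_level exceeds the number of tiers (k = ", k,
         "); offending row(s): ", paste(bad, collapse = ", "), " (patient ",
         paste(cohort$patient_id[bad], collapse = ", "), ")", call. = FALSE)
  }
  invisible(cohort)
}

#' Read a cohort from a tab-separated file
#'
#' The file must be UTF-8 TSV with a header naming at least `patient_id` and
#' `diagnostic_level`; the optional annotation columns of [cohort()] are
#' picked up when present and empty strings are read as absent values.
#' Unrecognised columns are dropped with a warning.
#'
#' @param path path to a TSV file.
#' @return A validated [cohort()].
#' @seealso [write_cohort()] for the inverse; the pair round-trips exactly.
#' @export
load_cohort <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", na.strings = NULL,
                           check.names = FALSE, fileEncoding = "UTF-8")
  missing_cols <- setdiff(.required_cols, names(raw))
  if (length(missing_cols) > 0) {
    stop("cohort file ", path, " lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  lvl <- suppressWarnings(as.numeric(raw$diagnostic_level))
  bad <- which(is.na(lvl) | lvl != round(lvl))
  if (length(bad) > 0) {
    stop("non-integer diagnostic_level in row(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  raw$diagnostic_level <- as.integer(lvl)
  cohort(raw)
}

#' Write a cohort to a tab-separated file
#'
#' Absent optional values are written as empty strings, so
#' `load_cohort(write_cohort(x, f))` reproduces `x` exactly.
#'
#' @param cohort a [cohort()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "tierdx_cohort"))
  out <- as.data.frame(cohort)
  for (col in names(out)) {
    if (is.character(out[[col]])) out[[col]][is.na(out[[col]])] <- ""
    if (is.numeric(out[[col]])) {
      v <- out[[col]]
      out[[col]] <- ifelse(is.na(v), "", format(v, trim = TRUE, scientific = FALSE))
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' The packaged epilepsy/NDD study cohort
#'
#' Returns the 72-proband cohort of the tertiary-centre study of "dynamic"
#' exome reanalysis in epilepsy with neurodevelopmental disorders: 21
#' probands diagnosed at the first tier (a 135-gene virtual panel), 4 at the
#' second (expanded panel reanalysis), 2 at the third (full exome analysis),
#' and 45 who remained undiagnosed.  Diagnosed probands carry the published
#' per-proband annotations (sex, ages, gene, genotype class, phenotype
#' label); undiagnosed probands (`U01`-`U45`) carry only their outcome, as no
#' per-proband detail was published for them.
#'
#' @return A [cohort()] with 72 rows.
#' @examples
#' table(dee_cohort()$diagnostic_level)
#' @export
dee_cohort <- function() {
  path <- system.file("extdata", "dee_cohort.tsv", package = "tierdx",
                      mustWork = TRUE)
  load_cohort(path)
}

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards.  Keeps all randomness call-owned, never global.
with_seed <- function(seed, expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  expr
}

#' Simulate a cohort of independent probands
#'
#' Each proband's outcome (tier of first diagnosis, or none) is drawn
#' independently from a multinomial distribution over the `k` tiers and the
#' "undiagnosed" category.  The generator is fully seeded: an identical call
#' reproduces an identical cohort, and the caller's RNG state is left
#' untouched.
#'
#' @param n cohort size (>= 1).
#' @param probs numeric vector of `k + 1` probabilities
#'   `(p_tier1, ..., p_tierk, p_none)` summing to 1.
#' @param seed integer seed owned by this call.
#' @return A [cohort()] with `n` rows and synthetic ids `S0001`, `S0002`, ...
#' @examples
#' sim <- simulate_cohort(72, probs = c(21, 4, 2, 45) / 72, seed = 1)
#' table(sim$diagnostic_level)
#' @export
simulate_cohort <- function(n, probs, seed) {
  stopifnot(length(n) == 1, n >= 1, n == round(n))
  if (any(probs < 0)) stop("probabilities must be non-negative", call. = FALSE)
  if (abs(sum(probs) - 1) >= 1e-12) {
    stop("probabilities must sum to 1 (got ", format(sum(probs)), ")",
         call. = FALSE)
  }
  k <- length(probs) - 1L
  if (k < 1) stop("need at least one tier plus the undiagnosed category", call. = FALSE)
  levels <- c(seq_len(k), 0L)
  drawn <- with_seed(seed, sample(levels, size = n, replace = TRUE, prob = probs))
  cohort(data.frame(
    patient_id = sprintf("S%04d", seq_len(n)),
    diagnostic_level = drawn,
    stringsAsFactors = FALSE
  ))
}

#' Marginal tier-outcome indicator matrix
#'
#' Builds the n-by-k binary matrix whose entry (i, j) is 1 exactly when
#' proband i was first diagnosed at tier j.  Row sums are therefore at most 1
#' and column sums are the per-tier diagnosis counts.  The running row-wise
#' maximum of this matrix gives the cumulative indicator, which is monotone
#' along tiers: this encodes the working assumption that a proband diagnosed
#' at an early tier would also have been diagnosed by any later, more
#' inclusive tier.
#'
#' @param cohort a [cohort()].
#' @param k number of tiers (default 3); every `diagnostic_level` must be
#'   at most `k`.
#' @param tier_labels optional character vector of `k` tier names.
#' @return An integer matrix of class `outcome_matrix` with probands as rows
#'   and tiers as columns.
#' @examples
#' colSums(outcome_matrix(dee_cohort()))
#' @export
outcome_matrix <- function(cohort, k = 3, tier_labels = NULL) {
  stopifnot(inherits(cohort, "tierdx_cohort"), k >= 1)
  check_levels(cohort, k)
  if (is.null(tier_labels)) tier_labels <- paste0("tier", seq_len(k))
  stopifnot(length(tier_labels) == k)
  m <- vapply(seq_len(k),
              function(j) as.integer(cohort$diagnostic_level == j),
              integer(nrow(cohort)))
  m <- matrix(m, nrow = nrow(cohort), ncol = k,
              dimnames = list(cohort$patient_id, tier_labels))
  structure(m, class = c("outcome_matrix", class(m)))
}

#' Cumulative diagnosis indicators
#'
#' Running row-wise maximum of the marginal [outcome_matrix()]: entry (i, t)
#' is 1 when proband i has been diagnosed at tier t or earlier.
#'
#' @param matrix an [outcome_matrix()].
#' @return An integer matrix of the same shape, non-decreasing along rows.
#' @export
cumulative_matrix <- function(matrix) {
  stopifnot(inherits(matrix, "outcome_matrix"))
  out <- t(apply(unclass(matrix), 1, cummax))
  if (ncol(matrix) == 1) out <- t(out)  # apply() drops shape at k = 1
  dimnames(out) <- dimnames(matrix)
  out
}
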