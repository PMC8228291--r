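test_that("standard pathway strategies have the expected structure", {
  p <- standard_pathways(unit_cost = 2072.74)
  expect_named(p, c("reference", "model1", "model2"))
  expect_length(p$reference$tiers, 2)
  expect_length(p$model1$tiers, 3)
  expect_length(p$model2$tiers, 1)
  # two-step panels cover levels 1 and 2 only; exome-first covers all three
  expect_equal(sort(unlist(lapply(p$reference$tiers, `[[`, "detects"))), c(1L, 2L))
  expect_equal(p$model2$tiers[[1]]$detects, 1:3)

  expect_error(pathway_model("bad", list(
    tier_definition("a", 1, c(1, 2)), tier_definition("b", 1, 2)
  )), "disjoint")
})

test_that("pathway costs on the study cohort reproduce the published figures", {
  co <- fixture_cohort()
  p <- standard_pathways(2072.74)

  ref <- apply_pathway(co, p$reference)
  expect_equal(unname(ref$tests_per_tier), c(72, 51))
  expect_equal(ref$total_cost, 254947.02, tolerance = 1e-9)
  expect_equal(ref$n_diagnosed, 25)
  expect_equal(round(ref$cost_per_diagnosis, 2), 10197.88)

  m1 <- apply_pathway(co, p$model1)
  expect_equal(unname(m1$tests_per_tier), c(72, 51, 47))
  expect_equal(m1$total_cost, 352365.80, tolerance = 1e-9)
  expect_equal(m1$n_diagnosed, 27)
  expect_equal(round(m1$cost_per_diagnosis, 2), 13050.59)

  m2 <- apply_pathway(co, p$model2)
  expect_equal(unname(m2$tests_per_tier), 72)
  expect_equal(m2$total_cost, 149237.28, tolerance = 1e-9)
  expect_equal(m2$n_diagnosed, 27)
  expect_equal(round(m2$cost_per_diagnosis, 3), 5527.307)
})

test_that("cost-free and zero-diagnosis edge cases are handled explicitly", {
  co <- fixture_cohort()
  free <- apply_pathway(co, standard_pathways(0)$model1)
  expect_equal(free$total_cost, 0)
  expect_equal(free$n_diagnosed, 27)
  expect_equal(free$cost_per_diagnosis, 0)

  undx <- cohort(data.frame(patient_id = letters[1:5], diagnostic_level = 0))
  res <- apply_pathway(undx, standard_pathways(100)$reference)
  expect_equal(res$n_diagnosed, 0)
  expect_true(is.na(res$cost_per_diagnosis))
  # undiagnosed probands undergo every tier
  expect_equal(unname(res$tests_per_tier), c(5, 5))
})

test_that("pathway accounting agrees with a brute-force per-patient loop", {
  set.seed(13)
  for (i in 1:100) {
    k <- sample(2:5, 1)
    co <- random_cohort(n = sample(3:60, 1), k = k)
    pw <- random_pathway(k)
    fast <- apply_pathway(co, pw)
    slow <- brute_force_pathway(co, pw)
    expect_equal(unname(fast$tests_per_tier), slow$tests)
    expect_equal(fast$total_cost, slow$total_cost)
    expect_equal(fast$n_diagnosed, slow$n_diagnosed)
    # conservation and structure
    expect_equal(fast$n_diagnosed,
                 sum(co$diagnostic_level %in%
                       unlist(lapply(pw$tiers, `[[`, "detects"))))
    expect_true(all(diff(unname(fast$tests_per_tier)) <= 0))
    expect_equal(unname(fast$tests_per_tier)[1], nrow(co))
  }
})

test_that("costs scale linearly with the unit reimbursement", {
  co <- fixture_cohort()
  for (s in c(0.5, 2, 10)) {
    base <- standard_pathways(2072.74)
    scaled <- standard_pathways(2072.74 * s)
    for (nm in names(base)) {
      a <- apply_pathway(co, base[[nm]])
      b <- apply_pathway(co, scaled[[nm]])
      expect_equal(b$total_cost, s * a$total_cost)
      expect_equal(b$cost_per_diagnosis, s * a$cost_per_diagnosis)
    }
    ia <- incremental(apply_pathway(co, base$model1),
                      apply_pathway(co, base$reference))
    ib <- incremental(apply_pathway(co, scaled$model1),
                      apply_pathway(co, scaled$reference))
    expect_equal(ib$delta_cost, s * ia$delta_cost)
    expect_equal(ib$icer, s * ia$icer)
    expect_equal(ib$delta_diagnoses, ia$delta_diagnoses)
  }
})

test_that("adding a tier never decreases cost or diagnoses", {
  set.seed(31)
  for (i in 1:30) {
    k <- sample(2:4, 1)
    co <- random_cohort(n = sample(5:40, 1), k = k)
    pw <- random_pathway(k)
    covered <- unlist(lapply(pw$tiers, `[[`, "detects"))
    uncovered <- setdiff(seq_len(k), covered)
    if (length(uncovered) == 0) next
    extended <- pathway_model("ext", c(pw$tiers, list(
      tier_definition("extra", stats::runif(1, 0, 5000), uncovered)
    )))
    a <- apply_pathway(co, pw)
    b <- apply_pathway(co, extended)
    expect_gte(b$total_cost, a$total_cost)
    expect_gte(b$n_diagnosed, a$n_diagnosed)
  }
})

test_that("incremental comparisons report deltas, ICER, and dominance", {
  co <- fixture_cohort()
  p <- standard_pathways(2072.74)
  ref <- apply_pathway(co, p$reference)

  i1 <- incremental(apply_pathway(co, p$model1), ref)
  expect_equal(i1$delta_cost, 97418.78, tolerance = 1e-9)
  expect_equal(i1$delta_diagnoses, 2)
  expect_equal(round(i1$icer, 2), 48709.39)
  expect_false(i1$dominant)

  i2 <- incremental(apply_pathway(co, p$model2), ref)
  expect_equal(i2$delta_cost, -105709.74, tolerance = 1e-9)
  expect_equal(i2$delta_diagnoses, 2)
  expect_true(i2$dominant)

  self <- incremental(ref, ref)
  expect_equal(self$delta_cost, 0)
  expect_equal(self$delta_diagnoses, 0)
  expect_true(is.na(self$icer))
  expect_false(self$dominant)

  other <- apply_pathway(cohort(data.frame(patient_id = "z",
                                           diagnostic_level = 1)),
                         p$reference)
  expect_error(incremental(other, ref), "different sizes")
})
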