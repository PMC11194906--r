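test_that("defect profiles validate their rates and shapes", {
  expect_error(defect_profile(range_violation_rate = 1.2), "rates")
  expect_error(defect_profile(n_records = 0), "n_records")
  expect_error(defect_profile(outcome_prevalence = 0), "prevalence")
  p <- defect_profile(cell_missingness = 0.2)
  expect_equal(p$cell_missingness, list(inputs = 0.2, outcomes = 0.2))
  expect_error(
    generate_cohort(defect_profile(element_dropout = synthetic_plan()$inputs)),
    "contradictory")
})

test_that("the same profile and seed reproduce byte-identical CSV output", {
  prof <- defect_profile(n_records = 120, cell_missingness = 0.15,
                         creation_delay = list(kind = "exponential", mean_hours = 10),
                         seed = 33)
  d1 <- tempfile()
  d2 <- tempfile()
  write_emr_dataset(generate_cohort(prof)$dataset, d1)
  write_emr_dataset(generate_cohort(prof)$dataset, d2)
  for (f in c("records.csv", "measurements.csv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("ground-truth realized counts match an independent recount", {
  prof <- defect_profile(n_records = 800, cell_missingness = 0.1,
                         state_unavailable_rate = 0.15,
                         derived_corruption_rate = 0.2,
                         unit_inconsistency_rate = 0.1,
                         timestamp_missing_rate = 0.05, seed = 12)
  coh <- generate_cohort(prof)
  rec <- coh$dataset$records
  meas <- coh$dataset$measurements
  truth <- coh$truth$realized
  n_missing <- sum(vapply(coh$plan$inputs, function(cl) sum(is.na(rec[[cl]])),
                          integer(1)))
  expect_equal(n_missing, truth$input_cells_missing)
  expect_equal(sum(rec$state != "available"), truth$records_unavailable)
  canon <- vapply(meas$element, function(el) coh$schema$elements[[el]]$unit,
                  character(1))
  expect_equal(sum(meas$unit != canon), truth$unit_inconsistencies)
  expect_equal(sum(meas$time == ""), truth$measurement_timestamps_missing)
  bmi_true <- round(rec$weight_kg / (rec$height_cm / 100)^2, 1)
  ok <- !is.na(rec$bmi) & !is.na(bmi_true)
  expect_equal(sum(abs(rec$bmi[ok] - bmi_true[ok]) > 0.5), truth$derived_corrupted)
})

test_that("planted rates are recovered by the matching indicators", {
  # moderate n here; the 10,000-opportunity recovery runs in the
  # acceptance suite
  prof <- defect_profile(n_records = 1500, cell_missingness = 0.1, seed = 4)
  coh <- generate_cohort(prof)
  r <- compute_indicator(coh$dataset, coh$schema, coh$plan, "input_value_integrity")
  n_cells <- 1500 * length(coh$plan$inputs)
  expect_lt(abs(r$raw - 0.9), 3 * sqrt(0.09 / n_cells))
  # exponential delay with mean tau: timely fraction 1 - exp(-1)
  prof2 <- defect_profile(n_records = 400,
                          creation_delay = list(kind = "exponential",
                                                mean_hours = 24), seed = 5)
  coh2 <- generate_cohort(prof2)
  t1 <- compute_indicator(coh2$dataset, coh2$schema, coh2$plan,
                          "recording_timeliness")
  expect_lt(abs(t1$raw - (1 - exp(-1))), 0.01)
})

test_that("a defect sweep yields nested, strictly decreasing totals per seed", {
  sw <- defect_sweep(defect_profile(n_records = 500, outcome_prevalence = 0.5,
                                    seed = 2),
                     axis = "cell_missingness",
                     levels = c(0, 0.15, 0.3, 0.45), seeds = 2L)
  expect_equal(nrow(sw$manifest), 4L)
  totals <- vapply(sw$cohorts, function(coh) {
    score_dataset(coh$dataset, coh$schema, coh$plan)$total
  }, numeric(1))
  expect_true(all(diff(totals[order(sw$manifest$level)]) < 0))
  expect_error(defect_sweep(defect_profile(), axis = "no_such_axis", levels = 0.1),
               "invalid defect axis")
  empty <- defect_sweep(defect_profile(), axis = "label_noise_rate",
                        levels = numeric())
  expect_equal(nrow(empty$manifest), 0L)
  expect_length(empty$cohorts, 0L)
})

test_that("label noise degrades models but not the quality index", {
  clean <- generate_cohort(defect_profile(n_records = 1200,
                                          outcome_prevalence = 0.5, seed = 61))
  noisy <- generate_cohort(defect_profile(n_records = 1200,
                                          outcome_prevalence = 0.5,
                                          label_noise_rate = 0.35, seed = 61))
  t_clean <- score_dataset(clean$dataset, clean$schema, clean$plan)$total
  t_noisy <- score_dataset(noisy$dataset, noisy$schema, noisy$plan)$total
  expect_lt(abs(t_clean - t_noisy), 0.005)
  a_clean <- evaluate_models(clean$dataset, clean$plan,
                             list(seed = 61, models = "LR"))$auc
  a_noisy <- evaluate_models(noisy$dataset, noisy$plan,
                             list(seed = 61, models = "LR"))$auc
  expect_gt(a_clean - a_noisy, 0.05)
})

test_that("expert panels concentrate with consensus", {
  degen <- generate_expert_panel(10, 8, consensus = Inf, seed = 1)
  expect_equal(kendalls_w(degen$ratings)$W, 1)
  expect_true(all(coefficient_of_variation(degen$ratings)$cv == 0))
  spread <- generate_expert_panel(12, 8, consensus = 0.5, seed = 1)
  tight <- generate_expert_panel(12, 8, consensus = 5, seed = 1)
  expect_gt(kendalls_w(tight$ratings)$W, kendalls_w(spread$ratings)$W)
  expect_gt(mean(coefficient_of_variation(spread$ratings)$cv),
            mean(coefficient_of_variation(tight$ratings)$cv))
  # zero consensus: W stays below the acceptability threshold on average
  ws <- vapply(1:60, function(s) {
    kendalls_w(generate_expert_panel(8, 10, consensus = 0, seed = s)$ratings)$W
  }, numeric(1))
  expect_lt(mean(ws), 0.2)
  expect_error(generate_expert_panel(1, 5), ">= 2")
})
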