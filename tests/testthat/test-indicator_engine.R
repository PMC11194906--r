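test_that("value completeness counts cells over listed columns", {
  d <- toy_dataset(records_patch = list(wt = c(70, NA, 90, NA)))
  expect_equal(value_completeness_ratio(d, c("wt", "ht")), 6 / 8)
  expect_equal(value_completeness_ratio(d, "absent_col"), 0)
  # sentinels and empty strings are missing
  d2 <- toy_dataset(records_patch = list(sex = c("M", "", "-1", "F")))
  expect_equal(value_completeness_ratio(d2, "sex", missing_codes = "-1"), 0.5)
  expect_error(value_completeness_ratio(d, character()), "empty")
})

test_that("entropy balance spans degenerate and balanced distributions", {
  d5050 <- toy_dataset(records_patch = list(outcome = c(0, 1, 0, 1)))
  expect_equal(normalized_entropy_balance(d5050, "outcome"), 1)
  mono <- toy_dataset(records_patch = list(outcome = rep(1, 4)))
  expect_equal(normalized_entropy_balance(mono, "outcome"), 0)
  # 90/10 binary: 0.469 bits relative to 1 bit
  d91 <- emr_dataset(data.frame(patient_id = paste0("P", 1:10),
                                admission_id = paste0("A", 1:10),
                                outcome = c(rep(0, 9), 1)))
  expect_equal(round(as.numeric(normalized_entropy_balance(d91, "outcome")), 3), 0.469)
  allna <- toy_dataset(records_patch = list(outcome = rep(NA, 4)))
  expect_true(is.na(normalized_entropy_balance(allna, "outcome")))
})

test_that("range conformance counts in-range values and flags unparseable ones", {
  d <- toy_dataset(records_patch = list(wt = c(70, 500, 90, "oops")))
  # wt: 2 in range of 4; ht: 4 in; bmi: 4 in
  expect_equal(range_conformance_ratio(d, toy_schema()), 10 / 12)
  clean <- toy_dataset(measurements = toy_measurements())
  expect_equal(range_conformance_ratio(clean, toy_schema()), 1)
})

test_that("temporal order requires anchors and in-stay, non-future measurements", {
  clean <- toy_dataset(measurements = toy_measurements())
  expect_equal(temporal_order_compliance(clean, toy_schema()), 1)
  m <- toy_measurements()
  m$time[1] <- "2009-12-31T00:00:00"       # before admission for record A1
  expect_equal(temporal_order_compliance(toy_dataset(measurements = m),
                                         toy_schema()), 0.75)
  # a record lacking anchors is non-compliant
  d <- toy_dataset(records_patch = list(admission_time = c(NA, rep("2010-01-01T00:00:00", 3))))
  expect_equal(temporal_order_compliance(d, toy_schema()), 0.75)
  # future-dated discharge relative to extraction
  fut <- toy_dataset(records_patch = list(discharge_time = c("2012-06-01T00:00:00",
                                                             rep("2010-01-02T00:00:00", 3))))
  expect_equal(temporal_order_compliance(fut, toy_schema()), 0.75)
})

test_that("recording timeliness windows the entry delay at tau", {
  clean <- toy_dataset(measurements = toy_measurements())
  expect_equal(recording_timeliness(clean, toy_schema()), 1)
  m <- toy_measurements()
  late <- seq(1, nrow(m), by = 2)
  t0 <- .POSIXct(as.numeric(as.POSIXct(m$time[late], tz = "UTC")), tz = "UTC")
  m$recorded_time[late] <- format(t0 + 48 * 3600, "%Y-%m-%dT%H:%M:%S")
  half <- recording_timeliness(toy_dataset(measurements = m), toy_schema())
  expect_equal(as.numeric(half), 1 - length(late) / nrow(m))
  sch <- toy_schema()
  sch$timeliness_hours <- NULL
  expect_true(is.na(recording_timeliness(clean, sch)))
})

test_that("recording frequency compares observed counts with the required cadence", {
  clean <- toy_dataset(measurements = toy_measurements())
  expect_equal(recording_frequency_ratio(clean, toy_schema()), 1)
  # an 8-hourly series against a 4-hour requirement scores about one half
  m8 <- toy_measurements()
  m8 <- m8[rep(rep(c(TRUE, FALSE), length.out = 7), times = 4), ]
  r8 <- recording_frequency_ratio(toy_dataset(measurements = m8), toy_schema())
  expect_equal(as.numeric(r8), 4 / 6)  # 4 of ceiling(24/4) = 6 expected
  # brute-force recount oracle under random thinning
  set.seed(5)
  mth <- toy_measurements()
  keep <- runif(nrow(mth)) < 0.6
  mth <- mth[keep, ]
  got <- recording_frequency_ratio(toy_dataset(measurements = mth), toy_schema())
  oracle <- mean(vapply(paste0("A", 1:4), function(id) {
    min(1, sum(mth$admission_id == id) / 6)
  }, numeric(1)))
  expect_equal(as.numeric(got), oracle)
})

test_that("derived-value consistency recomputes the formula within tolerance", {
  clean <- toy_dataset()
  expect_equal(derived_value_consistency(clean, toy_schema()), 1)
  bad <- toy_dataset()
  bad$records$bmi[2] <- bad$records$bmi[2] + 5
  expect_equal(derived_value_consistency(bad, toy_schema()), 0.75)
  sch <- toy_schema()
  sch$derived <- list()
  expect_true(is.na(derived_value_consistency(clean, sch)))
})

test_that("mapping ratios cover keys, elements, units and terminology", {
  d <- toy_dataset()
  expect_equal(mapping_ratio(d, toy_schema(), "primary-key"), 1)
  nokey <- d
  nokey$records$patient_id <- NULL
  expect_equal(mapping_ratio(nokey, toy_schema(), "primary-key"), 0.5)
  # element aspect counts required schema elements resolvable in the data
  expect_equal(mapping_ratio(d, toy_schema(), "element"), 5 / 7) # hr, temperature absent
  with_m <- toy_dataset(measurements = toy_measurements())
  expect_equal(mapping_ratio(with_m, toy_schema(), "element"), 6 / 7)
  # synonym resolution
  syn <- toy_dataset()
  names(syn$records)[names(syn$records) == "ht"] <- "height"
  expect_equal(mapping_ratio(syn, toy_schema(), "element"), 5 / 7)
  # convertibility: off-table unit drags the element down
  off <- toy_dataset(measurements = toy_measurements())
  off$column_units[["wt"]] <- "stone"
  expect_equal(mapping_ratio(off, toy_schema(), "convertibility"), 2 / 3)
  # terminology: coded values inside the bound set
  bad <- toy_dataset(records_patch = list(sex = c("M", "F", "??", "F")))
  expect_equal(mapping_ratio(bad, toy_schema(), "terminology"), 7 / 8)
})

test_that("compute_indicator dispatches and applies the not-evaluable policy", {
  d <- toy_dataset()
  expect_error(compute_indicator(d, toy_schema(), toy_plan(), "nope"), "unknown")
  r <- compute_indicator(d, toy_schema(), toy_plan(), "input_value_integrity")
  expect_equal(r$raw, 1)
  # timeliness is not evaluable without measurements
  ne_b <- compute_indicator(d, toy_schema(), toy_plan(), "recording_timeliness")
  expect_false(ne_b$evaluable)
  expect_equal(ne_b$raw, 1)
  ne_z <- compute_indicator(d, toy_schema(), toy_plan(), "recording_timeliness",
                            na_policy = "zero")
  expect_equal(ne_z$raw, 0)
  ne_x <- compute_indicator(d, toy_schema(), toy_plan(), "recording_timeliness",
                            na_policy = "exclude")
  expect_true(is.na(ne_x$raw))
})

test_that("element dropout, migration mismatch and method tags are detected", {
  d <- toy_dataset()
  # 2 of 4 plan inputs dropped
  d2 <- d
  d2$records$wt <- NULL
  d2$records$bmi <- NULL
  r <- compute_indicator(d2, toy_schema(), toy_plan(), "input_element_integrity")
  expect_equal(r$raw, 0.5)
  # migration manifest mismatch scores binary zero
  d3 <- d
  d3$source_manifest <- list(n_records = 5, nonmissing = c(wt = 4))
  expect_equal(compute_indicator(d3, toy_schema(), toy_plan(), "reliable_migration")$raw, 0)
  d4 <- d
  d4$source_manifest <- list(n_records = 4, nonmissing = c(wt = 4, sex = 4))
  expect_equal(compute_indicator(d4, toy_schema(), toy_plan(), "reliable_migration")$raw, 1)
  # method selectivity against plan requirements
  plan <- toy_plan()
  plan$input_methods <- c(wt = "scale", ht = "stadiometer")
  d5 <- d
  d5$column_methods <- c(wt = "scale", ht = "self_report")
  expect_equal(compute_indicator(d5, toy_schema(), plan, "input_method_selectivity")$raw, 0.5)
})

test_that("every calculator stays in [0, 1] on adversarial inputs", {
  sys <- default_index_system()
  schema <- synthetic_schema()
  plan <- synthetic_plan()
  for (seed in 1:60) {
    ds <- adversarial_dataset(seed)
    ind <- compute_all_indicators(ds, schema, plan)
    expect_false(any(is.na(ind$raw)), info = paste("seed", seed))
    expect_true(all(ind$raw >= 0 & ind$raw <= 1), info = paste("seed", seed))
  }
})

test_that("raising a planted defect rate never raises the matching score", {
  pairs <- list(
    list(field = "cell_missingness", id = "C1.3"),
    list(field = "range_violation_rate", id = "R1.4"),
    list(field = "derived_corruption_rate", id = "R2.2"),
    list(field = "state_unavailable_rate", id = "C3.1"),
    list(field = "timestamp_missing_rate", id = "C2.2")
  )
  for (p in pairs) {
    scores <- vapply(c(0, 0.2, 0.4), function(rate) {
      args <- list(n_records = 400L, seed = 31L)
      args[[p$field]] <- rate
      coh <- generate_cohort(do.call(defect_profile, args))
      compute_indicator(coh$dataset, coh$schema, coh$plan,
                        default_index_system()$nodes$calculator[
                          default_index_system()$nodes$id == p$id])$raw
    }, numeric(1))
    expect_true(all(diff(scores) <= 0), info = p$id)
  }
})

test_that("identical dataset bytes give identical indicator sets", {
  coh1 <- generate_cohort(defect_profile(n_records = 150, cell_missingness = 0.2,
                                         seed = 77))
  coh2 <- generate_cohort(defect_profile(n_records = 150, cell_missingness = 0.2,
                                         seed = 77))
  i1 <- compute_all_indicators(coh1$dataset, coh1$schema, coh1$plan)
  i2 <- compute_all_indicators(coh2$dataset, coh2$schema, coh2$plan)
  expect_identical(i1, i2)
})
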