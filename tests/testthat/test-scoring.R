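test_that("a defect-free cohort scores at the weight ceiling", {
  coh <- generate_cohort(defect_profile(n_records = 1200,
                                        outcome_prevalence = 0.5, seed = 21))
  card <- score_dataset(coh$dataset, coh$schema, coh$plan)
  ind <- card$indicators
  balance <- ind$id %in% c("C4.2", "C4.3")
  expect_true(all(ind$raw[!balance] == 1))
  expect_true(all(ind$raw[balance] >= 0.99))   # empirical 50/50 entropy
  expect_gt(card$total, 0.995)
  expect_true(all(ind$weighted <= ind$weight + 1e-12))
})

test_that("rollups are additive and the total equals the weighted leaf sum", {
  coh <- generate_cohort(defect_profile(n_records = 300, cell_missingness = 0.25,
                                        state_unavailable_rate = 0.1, seed = 9))
  card <- score_dataset(coh$dataset, coh$schema, coh$plan)
  expect_equal(card$total, sum(card$indicators$weighted), tolerance = 1e-9)
  r2 <- card$rollups[card$rollups$level == 2L, ]
  for (i in seq_len(nrow(r2))) {
    kids <- card$indicators[card$indicators$parent == r2$id[i], ]
    expect_equal(r2$score[i], sum(kids$weighted), tolerance = 1e-12)
  }
  r1 <- card$rollups[card$rollups$level == 1L, ]
  expect_equal(sum(r1$score), card$total, tolerance = 1e-12)
})

test_that("a defect touching one dimension leaves the others unchanged", {
  clean <- generate_cohort(defect_profile(n_records = 400,
                                          outcome_prevalence = 0.5, seed = 13))
  slow <- generate_cohort(defect_profile(n_records = 400, outcome_prevalence = 0.5,
                                         creation_delay = list(kind = "constant",
                                                               mean_hours = 48),
                                         seed = 13))
  c1 <- score_dataset(clean$dataset, clean$schema, clean$plan)
  c2 <- score_dataset(slow$dataset, slow$schema, slow$plan)
  r1 <- setNames(c1$rollups$score[c1$rollups$level == 1L],
                 c1$rollups$id[c1$rollups$level == 1L])
  r2 <- setNames(c2$rollups$score[c2$rollups$level == 1L],
                 c2$rollups$id[c2$rollups$level == 1L])
  expect_equal(r2[["O"]], r1[["O"]])
  expect_equal(r2[["C"]], r1[["C"]])
  expect_equal(r2[["R"]], r1[["R"]])
  expect_lt(r2[["T"]], r1[["T"]])
  expect_equal(c1$total - c2$total, r1[["T"]] - r2[["T"]], tolerance = 1e-12)
})

test_that("rollup_total reproduces published totals and validates bounds", {
  scores <- mimic_study_scores()
  for (i in seq_len(nrow(scores))) {
    expect_equal(rollup_total(as.numeric(scores[i, 2:5])), scores$total[i],
                 tolerance = 1e-9)
  }
  expect_equal(rollup_total(c(0, 0, 0, 0)), 0)
  expect_error(rollup_total(c(0.5, 0.1, 0.1, 0.1)), "exceeds")
  expect_error(rollup_total(c(0.1, 0.1, 0.1)), "4 first-level")
})

test_that("scorecard comparison ranks published cohorts and localizes deltas", {
  make_card <- function(label, dims, total) {
    sys <- default_index_system()
    r1 <- data.frame(id = c("O", "C", "R", "T"),
                     name = c("Operability", "Completeness", "Correctness", "Timeliness"),
                     level = 1L, weight = c(0.251, 0.254, 0.264, 0.231),
                     score = dims, parent = NA_character_)
    structure(list(label = label, indicators = NULL,
                   rollups = r1, total = total, na_policy = "benefit",
                   warnings = character(),
                   system = c(sys$metadata, hash = sys$hash)),
              class = "emr_scorecard")
  }
  scores <- mimic_study_scores()
  cards <- lapply(seq_len(nrow(scores)), function(i) {
    make_card(scores$dataset[i], as.numeric(scores[i, 2:5]), scores$total[i])
  })
  cmp <- compare_scorecards(cards)
  expect_equal(cmp$label, c("LLOS", "Stroke", "Elderly", "CIR", "ARF"))
  # ties keep input order
  tie <- compare_scorecards(cards[c(1, 1)])
  expect_equal(tie$rank, c(1L, 2L))
  expect_equal(tie$total[1], tie$total[2])
  # version mismatch fails loudly
  bad <- cards
  bad[[2]]$system[["hash"]] <- "other"
  expect_error(compare_scorecards(bad), "different index-system")
  # a single-indicator difference localizes to its branch
  coh <- generate_cohort(defect_profile(n_records = 200, outcome_prevalence = 0.5,
                                        seed = 14))
  cardA <- score_dataset(coh$dataset, coh$schema, coh$plan)
  cohB <- generate_cohort(defect_profile(n_records = 200, outcome_prevalence = 0.5,
                                         state_unavailable_rate = 0.3, seed = 14))
  cardB <- score_dataset(cohB$dataset, cohB$schema, cohB$plan)
  d <- compare_scorecards(list(cardA, cardB))
  expect_equal(d$delta_Operability[2], 0)
  expect_equal(d$delta_Timeliness[2], 0)
  expect_lt(d$delta_Completeness[2], 0)
})

test_that("increasing one raw score never lowers a rollup (exclude policy too)", {
  # same seed, one defect rate lowered: the nested draws guarantee every
  # affected leaf raw score is at least as high, so all rollups are too
  worse <- generate_cohort(defect_profile(n_records = 200, cell_missingness = 0.3,
                                          seed = 15))
  better_coh <- generate_cohort(defect_profile(n_records = 200,
                                               cell_missingness = 0.1, seed = 15))
  base <- score_dataset(worse$dataset, worse$schema, worse$plan)
  better <- score_dataset(better_coh$dataset, better_coh$schema, better_coh$plan)
  expect_gte(better$total, base$total)
  # the value-integrity leaves rise, so their ancestors must too (the
  # entropy-balance leaves are deliberately excluded: empirical entropy
  # is not monotone in missingness)
  i_base <- setNames(base$indicators$raw, base$indicators$id)
  i_bet <- setNames(better$indicators$raw, better$indicators$id)
  expect_gte(i_bet[["C1.3"]], i_base[["C1.3"]])
  expect_gte(i_bet[["C1.4"]], i_base[["C1.4"]])
  r_base <- setNames(base$rollups$score, base$rollups$id)
  r_bet <- setNames(better$rollups$score, better$rollups$id)
  expect_gte(r_bet[["C1"]], r_base[["C1"]])
  expect_gte(r_bet[["C"]], r_base[["C"]])
  # exclude policy renormalizes to the same global weight mass
  d <- toy_dataset()
  card_x <- score_dataset(d, toy_schema(), toy_plan(), na_policy = "exclude")
  expect_equal(sum(card_x$indicators$weight),
               sum(default_index_system()$nodes$weight[
                 default_index_system()$nodes$level == 3L]), tolerance = 1e-9)
  expect_true(length(card_x$warnings) > 0)
})
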