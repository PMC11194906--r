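test_that("pearson matches its closed-form behavior and stats::cor", {
  x <- c(1, 3, 2, 5, 4)
  expect_equal(pearson_r(x, 2 * x + 1), 1)
  set.seed(6)
  for (k in 1:10) {
    a <- rnorm(8)
    b <- rnorm(8)
    expect_equal(pearson_r(a, b), cor(a, b))
    expect_equal(pearson_r(a, b), pearson_r(b, a))
    expect_equal(pearson_r(3 * a + 2, b), pearson_r(a, b))
    expect_equal(pearson_r(-a, b), -pearson_r(a, b))
  }
  expect_true(is.na(pearson_r(rep(1, 5), 1:5)))
  expect_error(pearson_r(1:3, 1:4), "lengths")
  expect_error(pearson_r(1:2, 1:2), "n >= 3")
})

test_that("spearman uses the rank-difference form and handles ties via ranks", {
  expect_equal(spearman_rho(1:5, 1:5), 1)
  # one adjacent swap at n = 5: 1 - 12/120
  expect_equal(spearman_rho(1:5, c(1, 2, 3, 5, 4)), 0.9)
  # with ties: equals Pearson on average ranks from an independent routine
  x <- c(1, 2, 2, 4, 5)
  y <- c(2, 1, 4, 4, 5)
  expect_equal(spearman_rho(x, y), cor(rank(x), rank(y)))
  expect_equal(spearman_rho(x, y), cor(x, y, method = "spearman"))
  expect_true(is.na(spearman_rho(rep(2, 4), 1:4)))
})

test_that("spearman equals pearson on ranks for all 120 permutations at n = 5", {
  perms <- emrqi:::.permutations(5)
  x <- 1:5
  for (i in seq_len(nrow(perms))) {
    y <- perms[i, ]
    expect_equal(spearman_rho(x, y), pearson_r(rank(x), rank(y)))
  }
})

test_that("the normality gate picks Pearson for Gaussian pairs, Spearman for skewed", {
  set.seed(50)
  g1 <- rnorm(50)
  g2 <- rnorm(50)
  expect_equal(normality_gate(g1, g2)$method, "pearson")
  skew <- rexp(50)^2
  expect_equal(normality_gate(g1, skew)$method, "spearman")
  # the decision flips exactly where min(p1, p2) crosses alpha
  gate <- normality_gate(g1, skew)
  pmin_ <- min(gate$p_x, gate$p_y)
  for (alpha in c(pmin_ / 2, pmin_ * 2)) {
    expect_equal(normality_gate(g1, skew, alpha)$method,
                 if (pmin_ > alpha) "pearson" else "spearman")
  }
})

test_that("right-tailed p follows the t transform with published examples", {
  expect_equal(one_sided_p(0, 10), 0.5)
  expect_equal(round(one_sided_p(0.866, 5), 3), 0.029)
  p_lr <- one_sided_p(0.639, 5)
  expect_equal(round(p_lr, 3), 0.123)
  expect_gt(p_lr, 0.05)
  expect_equal(one_sided_p(1, 5), 0)
  expect_equal(one_sided_p(-1, 5), 1)
  # permutation p agrees in direction with the t approximation
  x <- c(0.91, 0.95, 0.93, 0.9, 0.94)
  y <- c(0.6, 0.9, 0.7, 0.55, 0.8)
  r <- pearson_r(x, y)
  p_perm <- one_sided_p(r, 5, method = "permutation", x = x, y = y)
  expect_true(p_perm >= 0 && p_perm <= 1)
  expect_lt(p_perm, 0.2)
})

test_that("the association table reproduces the published validation pattern", {
  tab <- association_table(mimic_study_scores()[, c("dataset", "total")],
                           mimic_study_performance(), gate = FALSE)
  expect_equal(nrow(tab), 9L)
  published <- c(`RF-Accuracy` = 0.907, `RF-Precision` = 0.825, `RF-AUC` = 0.866,
                 `SVM-Accuracy` = 0.819, `SVM-Precision` = 0.933, `SVM-AUC` = 0.924,
                 `LR-Accuracy` = 0.932, `LR-Precision` = 0.639, `LR-AUC` = 0.905)
  got <- setNames(tab$coefficient, tab$combination)
  expect_equal(got[names(published)], published, tolerance = 0.006)
  expect_equal(sum(tab$significant), 8L)
  expect_false(tab$significant[tab$combination == "LR-Precision"])
  # identical performance across datasets: undefined, never significant
  flat <- mimic_study_performance()
  flat$value <- 0.7
  tf <- association_table(mimic_study_scores()[, c("dataset", "total")], flat,
                          gate = FALSE)
  expect_true(all(is.na(tf$coefficient)))
  expect_true(all(!tf$significant))
  # label mismatch errors with the unmatched labels
  expect_error(association_table(mimic_study_scores()[1:4, c("dataset", "total")],
                                 mimic_study_performance()), "without scores")
})

test_that("an independent recomputation confirms a synthetic association run", {
  set.seed(23)
  n <- 20
  scores <- data.frame(dataset = paste0("D", 1:n),
                       total = runif(n, 0.7, 1))
  perf <- data.frame(dataset = paste0("D", 1:n), model = "LR", metric = "AUC",
                     value = 0.3 * scores$total + rnorm(n, 0.5, 0.03))
  tab <- association_table(scores, perf, gate = FALSE)
  expect_gt(tab$coefficient, 0)
  expect_equal(tab$coefficient, cor(scores$total, perf$value))
})

test_that("the model harness behaves at the signal extremes", {
  # null signal: outcome independent of inputs
  set.seed(77)
  n <- 600
  rec <- data.frame(patient_id = paste0("P", 1:n), admission_id = paste0("A", 1:n),
                    x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n),
                    y = rbinom(n, 1, 0.5))
  ds <- emr_dataset(rec, label = "null")
  plan <- modeling_plan(inputs = c("x1", "x2", "x3"), outcomes = "y")
  perf <- evaluate_models(ds, plan, list(seed = 77, models = "LR"))
  expect_lt(abs(perf$auc - 0.5), 0.1)
  # separable data: perfect held-out accuracy
  rec2 <- rec
  rec2$y <- as.integer(rec2$x1 > 0)
  perf2 <- evaluate_models(emr_dataset(rec2), plan, list(seed = 77, models = "RF"))
  expect_equal(perf2$accuracy, 1)
  expect_equal(perf2$auc, 1)
  # single-class outcome is an error
  rec3 <- rec
  rec3$y <- 1L
  expect_error(evaluate_models(emr_dataset(rec3), plan), "single class")
})

test_that("a clean cohort outperforms a heavily defective one in most paired runs", {
  wins <- 0L
  for (s in 1:5) {
    clean <- generate_cohort(defect_profile(n_records = 900, seed = 100 + s))
    dirty <- generate_cohort(defect_profile(n_records = 900,
                                            cell_missingness = 0.5,
                                            label_noise_rate = 0.25,
                                            seed = 100 + s))
    a1 <- evaluate_models(clean$dataset, clean$plan,
                          list(seed = s, models = "LR"))$auc
    a2 <- evaluate_models(dirty$dataset, dirty$plan,
                          list(seed = s, models = "LR"))$auc
    wins <- wins + (a1 >= a2)
  }
  expect_gte(wins, 4L)
})
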