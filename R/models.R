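#' Baseline classifier evaluation harness
#'
#' Applies the study protocol to a dataset and reports held-out
#' performance per model: median imputation of missing predictor values,
#' undersampling of the majority class to a 1:1 ratio, a seeded random
#' 80/20 train/test split, predictor standardization by training
#' statistics, then training of the configured baseline classifiers.
#' Defaults mirror the published settings: logistic regression (LR),
#' an RBF-kernel support vector machine with `C = 1` (SVM), and a
#' 10-tree random forest with maximum depth 7 (RF).
#'
#' @param dataset An `emr_dataset` whose records hold the plan's input
#'   columns and a binary outcome column.
#' @param plan A `modeling_plan`.
#' @param protocol List of settings: `seed`, `split` (train fraction),
#'   `models` (subset of `"LR"`, `"SVM"`, `"RF"`), `balance`
#'   (undersample to 1:1), `impute` (`"median"` or `"none"`),
#'   `normalize`.
#' @return Data frame, one row per model: `model`, `accuracy`,
#'   `precision`, `auc` (all in `[0, 1]`; precision is `NA` when no
#'   positive predictions are made).
#' @export
evaluate_models <- function(dataset, plan,
                            protocol = list()) {
  proto <- modifyList(list(seed = 1L, split = 0.8,
                           models = c("LR", "SVM", "RF"),
                           balance = TRUE, impute = "median",
                           normalize = TRUE),
                      protocol)
  rec <- dataset$records
  inputs <- intersect(plan$inputs, names(rec))
  if (!length(inputs)) stop("dataset has none of the plan's input columns", call. = FALSE)
  outcome <- plan$outcomes[1]
  if (!outcome %in% names(rec)) stop("outcome column absent: ", outcome, call. = FALSE)
  y <- suppressWarnings(as.integer(as.character(rec[[outcome]])))
  X <- as.data.frame(lapply(rec[inputs], function(v) {
    if (is.numeric(v)) v else as.numeric(factor(v))
  }))
  keep <- !is.na(y)
  X <- X[keep, , drop = FALSE]
  y <- y[keep]
  if (length(unique(y)) < 2) stop("outcome has a single class", call. = FALSE)

  set.seed(proto$seed)
  if (identical(proto$impute, "median")) {
    for (j in seq_along(X)) {
      med <- median(X[[j]], na.rm = TRUE)
      if (is.na(med)) med <- 0
      X[[j]][is.na(X[[j]])] <- med
    }
  }
  if (isTRUE(proto$balance)) {
    n1 <- sum(y == 1)
    n0 <- sum(y == 0)
    minority <- if (n1 <= n0) 1L else 0L
    maj_idx <- which(y != minority)
    keep_maj <- sample(maj_idx, min(n1, n0))
    idx <- sort(c(which(y == minority), keep_maj))
    X <- X[idx, , drop = FALSE]
    y <- y[idx]
  }
  n <- length(y)
  train <- sample(seq_len(n), floor(proto$split * n))
  test <- setdiff(seq_len(n), train)
  if (length(unique(y[train])) < 2 || length(unique(y[test])) < 2) {
    stop("single-class outcome after preprocessing/split", call. = FALSE)
  }
  if (isTRUE(proto$normalize)) {
    mu <- vapply(X[train, , drop = FALSE], mean, numeric(1))
    sg <- vapply(X[train, , drop = FALSE], sd, numeric(1))
    sg[sg == 0 | is.na(sg)] <- 1
    X <- as.data.frame(scale(X, center = mu, scale = sg))
  }
  tr <- cbind(X[train, , drop = FALSE], .y = y[train])
  te_X <- X[test, , drop = FALSE]
  te_y <- y[test]

  prob_for <- function(model) {
    switch(model,
      LR = {
        fit <- suppressWarnings(glm(.y ~ ., data = tr, family = binomial()))
        as.numeric(predict(fit, te_X, type = "response"))
      },
      SVM = {
        fit <- e1071::svm(x = as.matrix(tr[, names(te_X), drop = FALSE]),
                          y = factor(tr$.y), kernel = "radial", cost = 1,
                          probability = TRUE, scale = FALSE)
        pr <- predict(fit, as.matrix(te_X), probability = TRUE)
        attr(pr, "probabilities")[, "1"]
      },
      RF = {
        fit <- ranger::ranger(x = tr[, names(te_X), drop = FALSE],
                              y = factor(tr$.y), num.trees = 10, max.depth = 7,
                              probability = TRUE, seed = proto$seed,
                              num.threads = 1)
        predict(fit, te_X, num.threads = 1)$predictions[, "1"]
      },
      stop("unknown model: ", model, call. = FALSE)
    )
  }

  rows <- lapply(proto$models, function(mod) {
    p <- prob_for(mod)
    pred <- as.integer(p >= 0.5)
    acc <- mean(pred == te_y)
    prec <- if (sum(pred == 1) == 0) NA_real_ else {
      sum(pred == 1 & te_y == 1) / sum(pred == 1)
    }
    auc <- as.numeric(pROC::auc(pROC::roc(te_y, p, levels = c(0, 1),
                                          direction = "<", quiet = TRUE)))
    data.frame(model = mod, accuracy = acc, precision = prec, auc = auc,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
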