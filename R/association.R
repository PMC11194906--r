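#' Pearson product-moment correlation
#'
#' Direct sum-of-products implementation:
#' `r = sum((x - mean(x)) (y - mean(y))) / sqrt(sum((x - mean(x))^2) sum((y - mean(y))^2))`.
#'
#' @param x,y Numeric vectors of equal length `n >= 3`.
#' @return The coefficient in `[-1, 1]`, or `NA` with a `reason`
#'   attribute when either series has zero variance.
#' @examples
#' pearson_r(1:5, 2 * (1:5) + 1) # 1
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("series lengths differ", call. = FALSE)
  if (length(x) < 3) stop("need n >= 3", call. = FALSE)
  dx <- x - mean(x)
  dy <- y - mean(y)
  den <- sqrt(sum(dx^2) * sum(dy^2))
  if (den == 0) return(structure(NA_real_, reason = "zero variance"))
  sum(dx * dy) / den
}

#' Spearman rank correlation
#'
#' Tie-free series use the rank-difference form
#' `rho = 1 - 6 sum(d^2) / (n (n^2 - 1))`; with ties the coefficient is
#' the Pearson correlation of the average ranks (the two coincide when
#' there are no ties).
#'
#' @inheritParams pearson_r
#' @return The coefficient in `[-1, 1]`, or `NA` with a reason for a
#'   constant series.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("series lengths differ", call. = FALSE)
  n <- length(x)
  if (n < 3) stop("need n >= 3", call. = FALSE)
  rx <- rank(x)
  ry <- rank(y)
  if (length(unique(x)) == 1 || length(unique(y)) == 1) {
    return(structure(NA_real_, reason = "constant series"))
  }
  ties <- anyDuplicated(x) || anyDuplicated(y)
  if (!ties) {
    1 - 6 * sum((rx - ry)^2) / (n * (n^2 - 1))
  } else {
    as.numeric(pearson_r(rx, ry))
  }
}

#' Choose Pearson or Spearman through a normality gate
#'
#' Each series is tested with Shapiro-Wilk; Pearson is chosen only when
#' both pass at `alpha`, otherwise Spearman (the conservative reading
#' when one passes and one fails).
#'
#' @inheritParams pearson_r
#' @param alpha Significance level of the normality test.
#' @return List: `method` (`"pearson"` or `"spearman"`), `p_x`, `p_y`.
#' @export
normality_gate <- function(x, y, alpha = 0.05) {
  if (length(x) < 3 || length(y) < 3) stop("need n >= 3", call. = FALSE)
  px <- shapiro.test(x)$p.value
  py <- shapiro.test(y)$p.value
  list(method = if (px > alpha && py > alpha) "pearson" else "spearman",
       p_x = px, p_y = py)
}

#' Right-tailed p-value of a correlation coefficient
#'
#' Uses the t transform `t = r sqrt((n - 2) / (1 - r^2))` on `n - 2`
#' degrees of freedom; the same approximation is applied to Spearman's
#' rho. A coefficient of +1 gives p = 0; -1 gives p = 1 (the test is
#' right-tailed). An exact permutation p-value over all `n!` orderings
#' is available for `n <= 8`.
#'
#' @param r Correlation coefficient.
#' @param n Sample size (>= 3).
#' @param method `"t"` (default) or `"permutation"`.
#' @param x,y The original series, required for `method =
#'   "permutation"`.
#' @return Right-tailed p-value.
#' @examples
#' one_sided_p(0.866, 5) # about 0.029
#' @export
one_sided_p <- function(r, n, method = c("t", "permutation"), x = NULL, y = NULL) {
  method <- match.arg(method)
  if (is.na(r)) return(NA_real_)
  if (n < 3) stop("need n >= 3", call. = FALSE)
  if (method == "permutation") {
    if (is.null(x) || is.null(y)) stop("permutation p needs x and y", call. = FALSE)
    if (n > 8) stop("permutation p limited to n <= 8", call. = FALSE)
    perms <- .permutations(n)
    rs <- apply(perms, 1, function(idx) as.numeric(pearson_r(x, y[idx])))
    return(mean(rs >= r - 1e-12))
  }
  if (r >= 1) return(0)
  if (r <= -1) return(1)
  t <- r * sqrt((n - 2) / (1 - r^2))
  pt(t, df = n - 2, lower.tail = FALSE)
}

.permutations <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- .permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

#' Score-versus-performance association table
#'
#' For each (model, metric) column of a performance table, correlates
#' the per-dataset total quality scores with the metric across datasets:
#' method chosen by the normality gate (or forced), coefficient,
#' right-tailed p, and a significance flag at `alpha`.
#'
#' @param scores Data frame with columns `dataset` and `total` (or a
#'   named numeric vector of totals).
#' @param performance Long data frame with columns `dataset`, `model`,
#'   `metric`, `value`.
#' @param gate `TRUE` to choose the method per pair via
#'   [normality_gate()]; `FALSE` forces Pearson (appropriate when
#'   reproducing published tables whose values are Pearson).
#' @param alpha Significance level for the flags.
#' @return Data frame of class `emr_association`: combination, model,
#'   metric, method, coefficient, p, significant.
#' @export
association_table <- function(scores, performance, gate = TRUE, alpha = 0.05) {
  if (is.numeric(scores)) {
    scores <- data.frame(dataset = names(scores), total = as.numeric(scores))
  }
  labs <- sort(unique(performance$dataset))
  missing_scores <- setdiff(labs, scores$dataset)
  extra <- setdiff(scores$dataset, labs)
  if (length(missing_scores)) {
    stop("performance datasets without scores: ",
         paste(missing_scores, collapse = ", "), call. = FALSE)
  }
  shared <- intersect(scores$dataset, labs)
  if (length(shared) < 3) stop("need at least 3 shared dataset labels", call. = FALSE)
  s <- scores$total[match(shared, scores$dataset)]
  combos <- unique(performance[, c("model", "metric")])
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    sel <- performance$model == combos$model[i] & performance$metric == combos$metric[i]
    perf <- performance$value[sel][match(shared, performance$dataset[sel])]
    method <- if (gate) normality_gate(s, perf, alpha)$method else "pearson"
    coef <- if (method == "pearson") pearson_r(s, perf) else spearman_rho(s, perf)
    p <- one_sided_p(as.numeric(coef), length(shared))
    data.frame(
      combination = paste0(combos$model[i], "-", combos$metric[i]),
      model = combos$model[i], metric = combos$metric[i],
      method = method, coefficient = as.numeric(coef), p = p,
      significant = !is.na(p) && p < alpha,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (length(extra)) attr(out, "unused_scores") <- extra
  class(out) <- c("emr_association", "data.frame")
  out
}
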