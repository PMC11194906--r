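#' Score a dataset under a weighted index system
#'
#' Computes all 33 raw leaf scores with the indicator engine, multiplies
#' each by its absolute weight, and rolls the weighted scores up the
#' tree: each level-2 and level-1 score is the sum of its children's
#' weighted scores, and the total is the sum of the level-1 scores (so
#' the total equals the sum of all weighted leaf scores exactly).
#'
#' Under `na_policy = "exclude"`, not-evaluable leaves are removed and
#' the remaining leaf weights are renormalized to the original global
#' sum before rollup.
#'
#' @inheritParams compute_all_indicators
#' @return An object of class `emr_scorecard`: `label`, `indicators`
#'   (leaf table with raw and weighted scores), `rollups` (level-1/2
#'   scores), `total`, `warnings`, `system` (metadata + hash).
#' @export
score_dataset <- function(dataset, schema, plan,
                          system = default_index_system(),
                          na_policy = c("benefit", "zero", "exclude")) {
  na_policy <- match.arg(na_policy)
  ind <- compute_all_indicators(dataset, schema, plan, system, na_policy)
  nodes <- system$nodes
  leaves <- nodes[nodes$level == 3L, ]
  ind$weight <- leaves$weight[match(ind$id, leaves$id)]
  ind$parent <- leaves$parent[match(ind$id, leaves$id)]
  if (na_policy == "exclude") {
    keep <- !is.na(ind$raw)
    if (!any(keep)) stop("no evaluable indicators to score", call. = FALSE)
    ind$weight[keep] <- ind$weight[keep] * sum(ind$weight) / sum(ind$weight[keep])
    ind$weight[!keep] <- 0
    ind$raw[!keep] <- 0
  }
  ind$weighted <- ind$raw * ind$weight
  lvl2 <- nodes[nodes$level == 2L, ]
  r2 <- data.frame(
    id = lvl2$id, name = lvl2$name, level = 2L, weight = lvl2$weight,
    score = vapply(lvl2$id, function(p) sum(ind$weighted[ind$parent == p]), numeric(1)),
    stringsAsFactors = FALSE
  )
  lvl1 <- nodes[nodes$level == 1L, ]
  r2$parent <- lvl2$parent
  r1 <- data.frame(
    id = lvl1$id, name = lvl1$name, level = 1L, weight = lvl1$weight,
    score = vapply(lvl1$id, function(p) sum(r2$score[r2$parent == p]), numeric(1)),
    stringsAsFactors = FALSE
  )
  r1$parent <- NA_character_
  warnings <- ind$id[!ind$evaluable]
  structure(
    list(label = dataset$label,
         indicators = ind,
         rollups = rbind(r1, r2),
         total = sum(r1$score),
         na_policy = na_policy,
         warnings = if (length(warnings)) {
           paste0(warnings, ": ", ind$reason[!ind$evaluable])
         } else character(),
         system = c(system$metadata, hash = system$hash)),
    class = "emr_scorecard"
  )
}

#' @export
print.emr_scorecard <- function(x, ...) {
  cat("<emr_scorecard> '", x$label, "'  total = ", sprintf("%.3f", x$total),
      "\n", sep = "")
  r1 <- x$rollups[x$rollups$level == 1L, ]
  for (i in seq_len(nrow(r1))) {
    cat(sprintf("  %-14s %.3f (weight %.3f)\n", r1$name[i], r1$score[i], r1$weight[i]))
  }
  if (length(x$warnings)) {
    cat("  not evaluable (policy '", x$na_policy, "'): ",
        paste(x$warnings, collapse = "; "), "\n", sep = "")
  }
  invisible(x)
}

#' Total score from four first-level dimension scores
#'
#' The overall score of a dataset is the sum of its first-level
#' indicator scores. Each dimension score is validated against its
#' weight: a score cannot exceed the weight (beyond rounding headroom).
#'
#' @param first_level_scores Numeric vector of the four dimension scores,
#'   in the system's dimension order or named by dimension id/name.
#' @param system The index system supplying the dimension weights.
#' @param tolerance Allowed excess of a score over its weight (printed
#'   scores are 3-decimal rounded).
#' @return The total score.
#' @examples
#' rollup_total(c(0.251, 0.227, 0.264, 0.224)) # 0.966
#' @export
rollup_total <- function(first_level_scores, system = default_index_system(),
                         tolerance = 0.002) {
  w <- system$nodes$weight[system$nodes$level == 1L]
  ids <- system$nodes$id[system$nodes$level == 1L]
  if (length(first_level_scores) != length(w)) {
    stop("expected ", length(w), " first-level scores", call. = FALSE)
  }
  if (!is.null(names(first_level_scores)) &&
      all(names(first_level_scores) %in% ids)) {
    first_level_scores <- first_level_scores[ids]
  }
  over <- first_level_scores > w + tolerance
  if (any(over)) {
    stop("first-level score exceeds its dimension weight: ",
         paste0(ids[over], " (", first_level_scores[over], " > ", w[over], ")",
                collapse = ", "), call. = FALSE)
  }
  sum(first_level_scores)
}

#' Compare scorecards produced under one index system
#'
#' Ranks the cards by total score (ties keep the input order) and
#' reports per-dimension scores and deltas from the top card.
#'
#' @param cards List of `emr_scorecard` objects (at least 2) scored
#'   under the same index-system version.
#' @return Data frame, one row per card, ordered best first: label,
#'   rank, total, one column per dimension, and per-dimension deltas to
#'   the leader.
#' @export
compare_scorecards <- function(cards) {
  if (length(cards) < 2) stop("need at least 2 scorecards", call. = FALSE)
  hashes <- vapply(cards, function(cd) cd$system[["hash"]], character(1))
  if (length(unique(hashes)) > 1) {
    stop("scorecards come from different index-system versions", call. = FALSE)
  }
  rows <- lapply(cards, function(cd) {
    r1 <- cd$rollups[cd$rollups$level == 1L, ]
    out <- data.frame(label = cd$label, total = cd$total, stringsAsFactors = FALSE)
    for (i in seq_len(nrow(r1))) out[[r1$name[i]]] <- r1$score[i]
    out
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(-tab$total), , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  dims <- setdiff(names(tab), c("label", "total", "rank"))
  for (d in dims) tab[[paste0("delta_", d)]] <- tab[[d]] - tab[[d]][1]
  rownames(tab) <- NULL
  tab[, c("rank", "label", "total", dims, paste0("delta_", dims))]
}
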