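#' Delphi consultation response rates
#'
#' The positive coefficient is the share of invited experts who responded;
#' the effective rate is the share of responses that met the credibility
#' criteria. A response rate of 70% or higher is conventionally considered
#' satisfactory.
#'
#' @param invited Number of experts invited (> 0).
#' @param responded Number who responded.
#' @param valid Number of valid (credible) responses.
#' @return List with `positive_coefficient` and `effective_rate`, both in
#'   percent, and `satisfactory` (positive coefficient >= 70).
#' @examples
#' response_rates(20, 17, 16) # 85.0 and 94.1
#' @export
response_rates <- function(invited, responded, valid) {
  if (invited <= 0 || valid < 0 || responded < valid || invited < responded) {
    stop("need 0 <= valid <= responded <= invited with invited > 0", call. = FALSE)
  }
  pos <- responded / invited * 100
  eff <- if (responded == 0) 0 else valid / responded * 100
  list(positive_coefficient = pos, effective_rate = eff,
       satisfactory = pos >= 70)
}

#' Default Delphi coefficient mapping tables
#'
#' The familiarity mapping assigns a score in `[0, 1]` to each ordinal
#' familiarity category; the judgment table assigns a per-basis score to
#' each influence level such that an expert with the maximum influence on
#' every basis scores 1. Both follow the common published Delphi
#' convention and are fully overridable.
#'
#' @return `delphi_familiarity_mapping()`: a named numeric vector.
#'   `delphi_judgment_table()`: a matrix (bases x influence levels).
#' @export
delphi_familiarity_mapping <- function() {
  c(very_familiar = 1.0, relatively_familiar = 0.8, somewhat_familiar = 0.6,
    unfamiliar = 0.4, very_unfamiliar = 0.2)
}

#' @rdname delphi_familiarity_mapping
#' @export
delphi_judgment_table <- function() {
  m <- rbind(
    practical_experience = c(high = 0.5, medium = 0.4, low = 0.3),
    theoretical_analysis = c(high = 0.3, medium = 0.2, low = 0.1),
    peer_knowledge       = c(high = 0.1, medium = 0.1, low = 0.1),
    intuition            = c(high = 0.1, medium = 0.1, low = 0.1)
  )
  m
}

#' Expert familiarity coefficient (Cs)
#'
#' Mean of the mapped per-expert familiarity scores.
#'
#' @param familiarity Character vector of per-expert familiarity
#'   categories.
#' @param mapping Named numeric vector mapping categories to scores in
#'   `[0, 1]`.
#' @return Cs, a fraction in `[0, 1]`.
#' @examples
#' familiarity_coefficient(c("very_familiar", "relatively_familiar"))
#' @export
familiarity_coefficient <- function(familiarity, mapping = delphi_familiarity_mapping()) {
  unknown <- setdiff(unique(familiarity), names(mapping))
  if (length(unknown)) {
    stop("unknown familiarity category: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  mean(mapping[familiarity])
}

#' Expert judgment coefficient (Ca)
#'
#' For each expert, the per-basis influence scores are summed; Ca is the
#' mean of these sums over experts. With the default table an expert with
#' high influence on every basis scores exactly 1.
#'
#' @param basis A data frame with one row per expert and one column per
#'   judgment basis (row names of `table`), holding influence categories
#'   (column names of `table`).
#' @param table Bases x influence-levels score matrix.
#' @return Ca, a fraction in `[0, 1]`.
#' @export
judgment_coefficient <- function(basis, table = delphi_judgment_table()) {
  miss <- setdiff(rownames(table), names(basis))
  if (length(miss)) stop("profiles missing judgment basis column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  per_expert <- vapply(seq_len(nrow(basis)), function(i) {
    sum(vapply(rownames(table), function(b) {
      lev <- as.character(basis[[b]][i])
      if (!lev %in% colnames(table)) {
        stop("unknown influence level '", lev, "' for basis '", b, "'", call. = FALSE)
      }
      table[b, lev]
    }, numeric(1)))
  }, numeric(1))
  mean(per_expert)
}

#' Expert authority coefficient (Cr)
#'
#' Average of the familiarity coefficient Cs and the judgment coefficient
#' Ca; a Cr of 0.7 or above is considered acceptable.
#'
#' @param Cs Familiarity coefficient in `[0, 1]`.
#' @param Ca Judgment coefficient in `[0, 1]`.
#' @return List with `Cr` and `acceptable` (Cr >= 0.7).
#' @examples
#' authority_coefficient(0.88, 0.90)$Cr # 0.89
#' @export
authority_coefficient <- function(Cs, Ca) {
  if (Cs < 0 || Cs > 1 || Ca < 0 || Ca > 1) {
    stop("Cs and Ca must lie in [0, 1]", call. = FALSE)
  }
  cr <- (Cs + Ca) / 2
  list(Cr = cr, acceptable = cr >= 0.7)
}

#' Per-indicator coefficient of variation of expert ratings
#'
#' Sample standard deviation over mean of each indicator's ratings,
#' computed pairwise over the non-missing entries. A CV below 0.25 is the
#' conventional consensus threshold; indicators at or above it are
#' flagged. A zero mean makes the CV undefined and is reported as `NA`
#' rather than dropped.
#'
#' @param ratings Numeric matrix, experts x indicators (missing entries
#'   `NA` allowed); column names identify indicators.
#' @param threshold Flagging threshold (default 0.25).
#' @return Data frame: indicator, n, mean, sd, cv, flagged.
#' @examples
#' m <- cbind(a = c(4, 5, 4, 5), b = c(4, 4, 4, 4))
#' coefficient_of_variation(m)
#' @export
coefficient_of_variation <- function(ratings, threshold = 0.25) {
  ratings <- as.matrix(ratings)
  if (is.null(colnames(ratings))) colnames(ratings) <- paste0("I", seq_len(ncol(ratings)))
  out <- lapply(colnames(ratings), function(j) {
    x <- ratings[, j]
    x <- x[!is.na(x)]
    if (length(x) < 2) stop("indicator '", j, "' has fewer than 2 ratings", call. = FALSE)
    m <- mean(x)
    s <- sd(x)
    cv <- if (m == 0) NA_real_ else s / m
    data.frame(indicator = j, n = length(x), mean = m, sd = s, cv = cv,
               flagged = is.na(cv) | cv >= threshold)
  })
  do.call(rbind, out)
}

#' Kendall's coefficient of concordance (W) with tie correction
#'
#' Agreement of m experts ranking n indicators, computed on within-expert
#' average ranks with the standard tie-correction term. Significance uses
#' the chi-square approximation `chi2 = m (n - 1) W` on `n - 1` degrees of
#' freedom. W above 0.2 is the conventional acceptability threshold.
#' Experts with any missing rating are excluded listwise.
#'
#' @param ratings Numeric matrix, experts x indicators.
#' @return List: `W`, `chi_square`, `df`, `p`, `m` (experts used),
#'   `n` (indicators), `acceptable` (W > 0.2).
#' @examples
#' m <- rbind(c(1, 2, 3, 4), c(1, 2, 3, 4))
#' kendalls_w(m)$W # 1
#' @export
kendalls_w <- function(ratings) {
  ratings <- as.matrix(ratings)
  keep <- complete.cases(ratings)
  ratings <- ratings[keep, , drop = FALSE]
  m <- nrow(ratings)
  n <- ncol(ratings)
  if (m < 2 || n < 2) stop("need at least 2 experts and 2 indicators", call. = FALSE)
  rk <- t(apply(ratings, 1, rank))        # average ranks within expert
  R <- colSums(rk)
  S <- sum((R - mean(R))^2)
  Tt <- sum(apply(rk, 1, function(r) {    # tie correction per expert
    tab <- table(r)
    sum(tab^3 - tab)
  }))
  denom <- m^2 * (n^3 - n) - m * Tt
  W <- if (denom <= 0) NA_real_ else 12 * S / denom
  chi2 <- m * (n - 1) * W
  p <- pchisq(chi2, df = n - 1, lower.tail = FALSE)
  list(W = W, chi_square = chi2, df = n - 1, p = p, m = m, n = n,
       acceptable = !is.na(W) && W > 0.2)
}

#' Packaged expert panel fixture
#'
#' Profiles of the sixteen valid consultation responses (seven experts
#' very familiar with the content, nine relatively familiar; two with a
#' low judgment basis). Under the default mapping tables the panel yields
#' Cs = 0.8875 (printed as 0.88 at two decimals) and Ca = 0.90 exactly.
#'
#' @return Data frame of expert profiles.
#' @export
expert_panel_fixture <- function() {
  read.csv(system.file("extdata", "expert_panel_profiles.csv",
                       package = "emrqi", mustWork = TRUE),
           stringsAsFactors = FALSE)
}

#' Full Delphi reliability report
#'
#' Convenience wrapper combining response rates, authority coefficients,
#' per-indicator CV and Kendall's W for one ratings matrix and panel.
#'
#' @param ratings Experts x indicators numeric matrix.
#' @param profiles Expert profile data frame (see
#'   [expert_panel_fixture()] for the layout).
#' @param invited,responded,valid Response counts.
#' @inheritParams familiarity_coefficient
#' @inheritParams judgment_coefficient
#' @return Nested list with all coefficients and flags.
#' @export
delphi_report <- function(ratings, profiles, invited, responded, valid,
                          mapping = delphi_familiarity_mapping(),
                          table = delphi_judgment_table()) {
  rates <- response_rates(invited, responded, valid)
  cs <- familiarity_coefficient(profiles$familiarity, mapping)
  ca <- judgment_coefficient(profiles[, rownames(table), drop = FALSE], table)
  cr <- authority_coefficient(cs, ca)
  list(
    response = rates,
    Cs = cs, Ca = ca, Cr = cr$Cr, authority_acceptable = cr$acceptable,
    cv = coefficient_of_variation(ratings),
    kendall = kendalls_w(ratings)
  )
}
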