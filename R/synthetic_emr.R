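# Seeded synthetic ICU-style cohorts with known, plantable quality
# defects: demographics, single-admission labs, 4-hourly vital-sign
# series, a derived BMI element, and a binary sepsis-like outcome from a
# logistic model. Defects are injected in a fixed order so rates compose
# predictably; every planted defect count is recorded for recounting.

#' Reference schema of the synthetic ICU cohort
#'
#' Declares the demographic, laboratory and vital-sign elements the
#' generator emits: types, canonical units, plausibility ranges, the
#' required 4-hourly recording cadence of vitals, the sex code set, the
#' BMI derived-value definition, and a 24-hour timeliness window.
#'
#' @return An `emr_schema`.
#' @export
synthetic_schema <- function() {
  emr_schema(
    elements = list(
      age = list(type = "integer", range = c(18, 100)),
      sex = list(type = "categorical", code_set = c("M", "F"), format = "^[MF]$"),
      height_cm = list(type = "numeric", unit = "cm", range = c(120, 220), decimals = 1),
      weight_kg = list(type = "numeric", unit = "kg", range = c(30, 250), decimals = 1),
      bmi = list(type = "numeric", range = c(10, 80), decimals = 1,
                 synonyms = "body_mass_index"),
      wbc = list(type = "numeric", unit = "10^9/L", range = c(0.1, 100),
                 method = "automated_analyzer"),
      hgb = list(type = "numeric", unit = "g/dL", range = c(3, 25),
                 method = "automated_analyzer"),
      platelets = list(type = "numeric", unit = "10^9/L", range = c(5, 1500),
                       method = "automated_analyzer"),
      creatinine = list(type = "numeric", unit = "mg/dL", range = c(0.1, 20)),
      bilirubin = list(type = "numeric", unit = "mg/dL", range = c(0.05, 60)),
      albumin = list(type = "numeric", unit = "g/dL", range = c(0.5, 7)),
      lactate = list(type = "numeric", unit = "mmol/L", range = c(0.1, 30),
                     method = "blood_gas"),
      sepsis = list(type = "categorical", code_set = c("0", "1"),
                    method = "chart_review"),
      heart_rate = list(type = "numeric", unit = "bpm", range = c(20, 300),
                        interval_hours = 4, method = "monitor"),
      sbp = list(type = "numeric", unit = "mmHg", range = c(40, 300),
                 interval_hours = 4, method = "monitor"),
      resp_rate = list(type = "numeric", unit = "breaths/min", range = c(4, 80),
                       interval_hours = 4, method = "monitor"),
      temperature = list(type = "numeric", unit = "C", convertible_units = "F",
                         range = c(30, 45), decimals = 1, interval_hours = 4,
                         method = "monitor"),
      spo2 = list(type = "numeric", unit = "%", range = c(50, 100),
                  interval_hours = 4, method = "monitor")
    ),
    derived = list(list(target = "bmi", components = c("weight_kg", "height_cm"),
                        formula = "weight_kg / (height_cm / 100)^2",
                        tolerance = 0.5)),
    timeliness_hours = 24
  )
}

#' Modeling plan of the synthetic sepsis-prediction task
#'
#' @param required_n Minimum required sample size (default 1000).
#' @return A `modeling_plan`: ten predictor elements, the binary sepsis
#'   outcome, and the measurement-method requirements of three elements.
#' @export
synthetic_plan <- function(required_n = 1000L) {
  modeling_plan(
    inputs = c("age", "sex", "wbc", "hgb", "platelets", "creatinine",
               "bilirubin", "albumin", "lactate", "bmi"),
    outcomes = "sepsis",
    required_n = required_n,
    input_methods = c(wbc = "automated_analyzer", lactate = "blood_gas"),
    outcome_methods = c(sepsis = "chart_review")
  )
}

#' Specify a defect profile for the synthetic generator
#'
#' All rates are per-opportunity probabilities in `[0, 1]`; realized
#' counts are recorded in the ground truth rather than forced exact.
#' Defects are injected in a fixed order: element dropout, frequency
#' thinning, cell missingness, timestamp loss, recording delays,
#' range/format/unit/derived corruption, temporal-order violations,
#' state flags, label noise.
#'
#' @param n_records Number of admissions.
#' @param cell_missingness Scalar rate, or list with `inputs` and
#'   `outcomes` rates, of cells blanked in the plan's columns.
#' @param timestamp_missing_rate Rate of lost measurement timestamps and
#'   record-creation timestamps.
#' @param creation_delay List: `kind` (`"none"`, `"constant"`,
#'   `"exponential"`) and `mean_hours`, the delay between measuring a
#'   value and entering it into the record.
#' @param frequency_thinning Named numeric vector of per-element keep
#'   fractions for the vital-sign series.
#' @param range_violation_rate Rate of values displaced outside their
#'   plausibility range.
#' @param format_error_rate Rate of sex values replaced with
#'   non-conforming strings.
#' @param unit_inconsistency_rate Rate of measurement rows relabeled
#'   with a non-canonical unit.
#' @param derived_corruption_rate Rate of stored BMI values displaced
#'   beyond the derived-value tolerance.
#' @param order_violation_rate Rate of records given a measurement
#'   timestamp before admission.
#' @param state_unavailable_rate Rate of records flagged voided/error.
#' @param outcome_prevalence Target outcome prevalence in `(0, 1)`.
#' @param label_noise_rate Rate of flipped outcome labels (a model-side
#'   defect the index system deliberately does not measure).
#' @param element_dropout Character vector of elements removed entirely.
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @return A list of class `defect_profile`.
#' @export
defect_profile <- function(n_records = 2500L,
                           cell_missingness = 0,
                           timestamp_missing_rate = 0,
                           creation_delay = list(kind = "none", mean_hours = 0),
                           frequency_thinning = numeric(),
                           range_violation_rate = 0,
                           format_error_rate = 0,
                           unit_inconsistency_rate = 0,
                           derived_corruption_rate = 0,
                           order_violation_rate = 0,
                           state_unavailable_rate = 0,
                           outcome_prevalence = 0.3,
                           label_noise_rate = 0,
                           element_dropout = character(),
                           seed = 1L) {
  if (is.numeric(cell_missingness) && length(cell_missingness) == 1) {
    cell_missingness <- list(inputs = cell_missingness, outcomes = cell_missingness)
  }
  prof <- list(n_records = as.integer(n_records),
               cell_missingness = cell_missingness,
               timestamp_missing_rate = timestamp_missing_rate,
               creation_delay = creation_delay,
               frequency_thinning = frequency_thinning,
               range_violation_rate = range_violation_rate,
               format_error_rate = format_error_rate,
               unit_inconsistency_rate = unit_inconsistency_rate,
               derived_corruption_rate = derived_corruption_rate,
               order_violation_rate = order_violation_rate,
               state_unavailable_rate = state_unavailable_rate,
               outcome_prevalence = outcome_prevalence,
               label_noise_rate = label_noise_rate,
               element_dropout = element_dropout,
               seed = as.integer(seed))
  rates <- c(unlist(prof$cell_missingness), prof$timestamp_missing_rate,
             prof$frequency_thinning, prof$range_violation_rate,
             prof$format_error_rate, prof$unit_inconsistency_rate,
             prof$derived_corruption_rate, prof$order_violation_rate,
             prof$state_unavailable_rate, prof$label_noise_rate)
  if (any(rates < 0 | rates > 1)) stop("all rates must lie in [0, 1]", call. = FALSE)
  if (prof$n_records < 1) stop("n_records must be >= 1", call. = FALSE)
  if (prof$outcome_prevalence <= 0 || prof$outcome_prevalence >= 1) {
    stop("outcome_prevalence must lie in (0, 1)", call. = FALSE)
  }
  structure(prof, class = "defect_profile")
}

.fmt_time <- function(t) format(t, "%Y-%m-%dT%H:%M:%S", tz = "UTC")

#' Generate a synthetic cohort with planted defects
#'
#' Draws a clean cohort first (demographics, labs, 4-hourly vitals at
#' the schema's required cadence, derived BMI, admission/discharge
#' anchors, outcome from a logistic model at the requested prevalence),
#' then injects the profile's defects in a fixed order. Fully
#' reproducible from the profile's seed.
#'
#' @param profile A [defect_profile()].
#' @param coefficients Named logistic coefficients on the standardized
#'   predictors `age`, `wbc`, `creatinine`, `lactate`, `albumin`.
#' @param label Dataset label.
#' @return List: `dataset` (an `emr_dataset`), `truth` (profile,
#'   outcome-model coefficients, realized per-defect counts), `schema`,
#'   `plan`.
#' @export
generate_cohort <- function(profile = defect_profile(),
                            coefficients = c(age = 0.5, wbc = 0.7,
                                             creatinine = 0.6, lactate = 1.1,
                                             albumin = -0.6),
                            label = paste0("synthetic-seed", profile$seed)) {
  stopifnot(inherits(profile, "defect_profile"))
  schema <- synthetic_schema()
  plan <- synthetic_plan()
  if (all(plan$inputs %in% profile$element_dropout)) {
    stop("contradictory profile: dropout removes all predictors", call. = FALSE)
  }
  n <- profile$n_records
  set.seed(profile$seed)
  clamp <- function(x, lo, hi) pmin(hi, pmax(lo, x))

  base <- as.POSIXct("2008-01-01 00:00:00", tz = "UTC")
  adm <- base + round(runif(n, 0, 4 * 365 * 86400))
  los_h <- clamp(rlnorm(n, log(72), 0.5), 6, 720)
  dis <- adm + round(los_h * 3600)

  rec <- data.frame(
    patient_id = sprintf("P%05d", seq_len(n)),
    admission_id = sprintf("A%05d", seq_len(n)),
    admission_time = .fmt_time(adm),
    discharge_time = .fmt_time(dis),
    record_created = .fmt_time(adm),
    state = rep("available", n),
    age = round(clamp(rnorm(n, 65, 15), 18, 100)),
    sex = sample(c("M", "F"), n, replace = TRUE),
    height_cm = round(clamp(rnorm(n, 170, 10), 140, 205), 1),
    weight_kg = round(clamp(rnorm(n, 78, 15), 40, 180), 1),
    wbc = round(clamp(rlnorm(n, log(9), 0.4), 0.5, 80), 2),
    hgb = round(clamp(rnorm(n, 11.5, 2), 4, 20), 1),
    platelets = round(clamp(rnorm(n, 220, 80), 10, 900)),
    creatinine = round(clamp(rlnorm(n, log(1.1), 0.5), 0.2, 15), 2),
    bilirubin = round(clamp(rlnorm(n, log(0.9), 0.7), 0.1, 40), 2),
    albumin = round(clamp(rnorm(n, 3.4, 0.6), 1, 5.5), 1),
    lactate = round(clamp(rlnorm(n, log(1.8), 0.5), 0.3, 20), 2),
    stringsAsFactors = FALSE
  )
  rec$bmi <- round(rec$weight_kg / (rec$height_cm / 100)^2, 1)

  # outcome: logistic in standardized predictors, intercept solved for
  # the requested prevalence
  Z <- scale(rec[, names(coefficients)])
  lp <- as.vector(Z %*% coefficients)
  a <- uniroot(function(a) mean(plogis(a + lp)) - profile$outcome_prevalence,
               c(-30, 30))$root
  rec$sepsis <- rbinom(n, 1, plogis(a + lp))

  # 4-hourly vitals over the stay
  k <- floor(los_h / 4) + 1L
  ridx <- rep(seq_len(n), times = k)
  hrs <- (sequence(k) - 1L) * 4
  t_meas <- adm[ridx] + hrs * 3600
  vit_spec <- list(
    heart_rate = function(m) round(clamp(rnorm(m, 85, 12), 35, 180), 1),
    sbp        = function(m) round(clamp(rnorm(m, 120, 18), 60, 220), 1),
    resp_rate  = function(m) round(clamp(rnorm(m, 18, 4), 6, 45), 1),
    temperature = function(m) round(clamp(rnorm(m, 37, 0.6), 34, 41.5), 1),
    spo2       = function(m) round(clamp(rnorm(m, 97, 2), 70, 100))
  )
  m1 <- length(ridx)
  meas <- data.frame(
    admission_id = rep(rec$admission_id[ridx], times = length(vit_spec)),
    element = rep(names(vit_spec), each = m1),
    value = unlist(lapply(vit_spec, function(f) f(m1)), use.names = FALSE),
    time = rep(.fmt_time(t_meas), times = length(vit_spec)),
    recorded_time = rep(.fmt_time(t_meas), times = length(vit_spec)),
    unit = rep(vapply(names(vit_spec), function(el) schema$elements[[el]]$unit,
                      character(1)), each = m1),
    method = "monitor",
    stringsAsFactors = FALSE
  )

  realized <- list()

  # 1. element dropout
  if (length(profile$element_dropout)) {
    rec <- rec[, setdiff(names(rec), profile$element_dropout), drop = FALSE]
    meas <- meas[!meas$element %in% profile$element_dropout, , drop = FALSE]
    realized$dropped_elements <- profile$element_dropout
  }

  # 2. frequency thinning (vital series)
  if (length(profile$frequency_thinning)) {
    drop <- rep(FALSE, nrow(meas))
    for (el in names(profile$frequency_thinning)) {
      keep <- profile$frequency_thinning[[el]]
      if (keep >= 1) next
      sel <- which(meas$element == el)
      drop[sel] <- runif(length(sel)) >= keep
    }
    realized$measurements_thinned <- sum(drop)
    meas <- meas[!drop, , drop = FALSE]
  }

  # 3. cell missingness in the plan's columns
  blank_cells <- function(cols, rate) {
    cnt <- 0L
    for (cl in intersect(cols, names(rec))) {
      hit <- runif(n) < rate
      rec[[cl]][hit] <<- NA
      cnt <- cnt + sum(hit)
    }
    cnt
  }
  if ((profile$cell_missingness$inputs %||% 0) > 0) {
    realized$input_cells_missing <- blank_cells(plan$inputs,
                                                profile$cell_missingness$inputs)
  }
  if ((profile$cell_missingness$outcomes %||% 0) > 0) {
    realized$outcome_cells_missing <- blank_cells(plan$outcomes,
                                                  profile$cell_missingness$outcomes)
  }

  # 4. timestamp loss
  if (profile$timestamp_missing_rate > 0) {
    hit_m <- runif(nrow(meas)) < profile$timestamp_missing_rate
    meas$time[hit_m] <- ""
    hit_r <- runif(n) < profile$timestamp_missing_rate
    rec$record_created[hit_r] <- ""
    realized$measurement_timestamps_missing <- sum(hit_m)
    realized$record_timestamps_missing <- sum(hit_r)
  }

  # 5. recording delays
  if (!identical(profile$creation_delay$kind, "none") &&
      (profile$creation_delay$mean_hours %||% 0) > 0) {
    mh <- profile$creation_delay$mean_hours
    delay_h <- switch(profile$creation_delay$kind,
                      constant = rep(mh, nrow(meas)),
                      exponential = rexp(nrow(meas), 1 / mh),
                      stop("unknown delay kind: ", profile$creation_delay$kind,
                           call. = FALSE))
    t0 <- .parse_time(meas$time)
    ok <- !is.na(t0)
    meas$recorded_time[ok] <- .fmt_time(t0[ok] + round(delay_h[ok] * 3600))
    realized$mean_delay_hours <- mean(delay_h)
  }

  # 6. range violations (labs and vitals pushed above their upper bound)
  if (profile$range_violation_rate > 0) {
    cnt <- 0L
    ranged_wide <- intersect(
      c("wbc", "hgb", "platelets", "creatinine", "bilirubin", "albumin", "lactate"),
      names(rec))
    for (cl in ranged_wide) {
      rg <- schema$elements[[cl]]$range
      ok <- !is.na(rec[[cl]])
      hit <- ok & runif(n) < profile$range_violation_rate
      rec[[cl]][hit] <- rg[2] + (rg[2] - rg[1])
      cnt <- cnt + sum(hit)
    }
    uel <- unique(meas$element)
    lo <- vapply(uel, function(el) schema$elements[[el]]$range[1], numeric(1))
    hi <- vapply(uel, function(el) schema$elements[[el]]$range[2], numeric(1))
    eidx <- match(meas$element, uel)
    hit <- runif(nrow(meas)) < profile$range_violation_rate
    meas$value[hit] <- hi[eidx[hit]] + (hi[eidx[hit]] - lo[eidx[hit]])
    cnt <- cnt + sum(hit)
    realized$range_violations <- cnt
  }

  # 7. format errors (sex strings outside the declared pattern)
  if (profile$format_error_rate > 0 && "sex" %in% names(rec)) {
    ok <- !is.na(rec$sex)
    hit <- which(ok & runif(n) < profile$format_error_rate)
    bad <- c("male", "female", "unknown", "M ")
    rec$sex[hit] <- bad[(seq_along(hit) - 1L) %% length(bad) + 1L]
    realized$format_errors <- length(hit)
  }

  # 8. unit inconsistencies (measurement rows relabeled off-canon)
  if (profile$unit_inconsistency_rate > 0) {
    hit <- runif(nrow(meas)) < profile$unit_inconsistency_rate
    alt <- ifelse(meas$element[hit] == "temperature", "F",
                  paste0(meas$unit[hit], "_alt"))
    meas$unit[hit] <- alt
    realized$unit_inconsistencies <- sum(hit)
  }

  # 9. derived-value corruption (BMI displaced past the tolerance)
  if (profile$derived_corruption_rate > 0 && "bmi" %in% names(rec)) {
    ok <- !is.na(rec$bmi)
    hit <- ok & runif(n) < profile$derived_corruption_rate
    rec$bmi[hit] <- rec$bmi[hit] + 3
    realized$derived_corrupted <- sum(hit)
  }

  # 10. temporal-order violations (one pre-admission measurement)
  if (profile$order_violation_rate > 0) {
    hit <- which(runif(n) < profile$order_violation_rate)
    first_row <- match(rec$admission_id[hit], meas$admission_id)
    hit <- hit[!is.na(first_row)]
    first_row <- first_row[!is.na(first_row)]
    meas$time[first_row] <- .fmt_time(adm[hit] - 48 * 3600)
    realized$order_violations <- length(hit)
  }

  # 11. state flags
  if (profile$state_unavailable_rate > 0) {
    hit <- which(runif(n) < profile$state_unavailable_rate)
    rec$state[hit] <- c("voided", "error")[(seq_along(hit) - 1L) %% 2L + 1L]
    realized$records_unavailable <- length(hit)
  }

  # 12. label noise
  if (profile$label_noise_rate > 0 && "sepsis" %in% names(rec)) {
    ok <- !is.na(rec$sepsis)
    hit <- ok & runif(n) < profile$label_noise_rate
    rec$sepsis[hit] <- 1L - as.integer(rec$sepsis[hit])
    realized$labels_flipped <- sum(hit)
  }

  units <- vapply(schema$elements, function(e) e$unit %||% NA_character_,
                  character(1))
  units <- units[!is.na(units)]
  wide_units <- units[intersect(names(units), names(rec))]
  methods <- c(wbc = "automated_analyzer", hgb = "automated_analyzer",
               platelets = "automated_analyzer", lactate = "blood_gas",
               sepsis = "chart_review")
  methods <- methods[intersect(names(methods), names(rec))]

  ds <- emr_dataset(
    records = rec, measurements = meas,
    column_units = wide_units, column_methods = methods,
    extracted_at = "2013-01-01T00:00:00",
    source_manifest = list(
      n_records = nrow(rec),
      nonmissing = vapply(setdiff(names(rec), RESERVED_COLUMNS), function(cl)
        sum(!.is_missing(rec[[cl]])), integer(1))
    ),
    label = label
  )
  list(dataset = ds,
       truth = list(profile = profile,
                    coefficients = c(intercept = a, coefficients),
                    realized = realized),
       schema = schema, plan = plan)
}

#' Sweep one defect axis over levels and seeds
#'
#' Produces one cohort profile per (level, seed) combination, holding
#' everything else at the base profile, with a manifest linking labels
#' to settings. Cohorts are generated eagerly by default; with
#' `materialize = FALSE` only the profiles and manifest are returned and
#' cohorts can be generated one at a time from `profiles`.
#'
#' @param base_profile The [defect_profile()] shared by all cohorts.
#' @param axis Name of the profile field to sweep.
#' @param levels Numeric rates in `[0, 1]`.
#' @param seeds Integer seeds.
#' @param materialize Generate the cohorts now (default `TRUE`).
#' @return List: `manifest` (data frame label/axis/level/seed),
#'   `profiles` (named list), and `cohorts` when materialized.
#' @export
defect_sweep <- function(base_profile, axis, levels, seeds = 1L,
                         materialize = TRUE) {
  if (!axis %in% names(base_profile)) {
    stop("invalid defect axis: ", axis, call. = FALSE)
  }
  grid <- expand.grid(level = levels, seed = seeds)
  if (!nrow(grid)) {
    return(list(manifest = data.frame(label = character(), axis = character(),
                                      level = numeric(), seed = integer()),
                profiles = list(), cohorts = list()))
  }
  profiles <- lapply(seq_len(nrow(grid)), function(i) {
    p <- unclass(base_profile)
    p[[axis]] <- if (axis == "cell_missingness") {
      list(inputs = grid$level[i], outcomes = base_profile$cell_missingness$outcomes)
    } else grid$level[i]
    p$seed <- as.integer(grid$seed[i])
    do.call(defect_profile, p)
  })
  labels <- sprintf("%s=%g_seed=%d", axis, grid$level, grid$seed)
  names(profiles) <- labels
  manifest <- data.frame(label = labels, axis = axis, level = grid$level,
                         seed = grid$seed, stringsAsFactors = FALSE)
  out <- list(manifest = manifest, profiles = profiles)
  if (materialize) {
    out$cohorts <- lapply(labels, function(lb) {
      generate_cohort(profiles[[lb]], label = lb)
    })
    names(out$cohorts) <- labels
  }
  out
}

#' Generate a synthetic expert consultation panel
#'
#' Draws 5-point Likert importance ratings around per-item latent
#' importances: higher `consensus` concentrates every expert on the
#' latent value (rating noise has standard deviation `1 / consensus`),
#' while `consensus = 0` gives uniform random ratings. Expert profiles
#' (familiarity and judgment-basis categories) are drawn from fixed
#' category frequencies.
#'
#' @param n_experts,n_items Panel dimensions (both >= 2).
#' @param consensus Non-negative concentration parameter.
#' @param seed Integer seed.
#' @param latent Optional numeric vector of latent importances on the
#'   1-5 scale; defaults to uniform draws in `[2, 4.5]`.
#' @return List: `ratings` (experts x items integer matrix), `profiles`
#'   (data frame), `latent`.
#' @export
generate_expert_panel <- function(n_experts, n_items, consensus = 2,
                                  seed = 1L, latent = NULL) {
  if (n_experts < 2 || n_items < 2) stop("need >= 2 experts and items", call. = FALSE)
  if (consensus < 0) stop("consensus must be non-negative", call. = FALSE)
  set.seed(seed)
  if (is.null(latent)) latent <- runif(n_items, 2, 4.5)
  if (length(latent) != n_items) stop("latent length must equal n_items", call. = FALSE)
  if (is.infinite(consensus)) {
    ratings <- matrix(rep(pmin(5, pmax(1, round(latent))), each = n_experts),
                      nrow = n_experts)
  } else if (consensus == 0) {
    ratings <- matrix(sample(1:5, n_experts * n_items, replace = TRUE),
                      nrow = n_experts)
  } else {
    noise <- matrix(rnorm(n_experts * n_items, 0, 1 / consensus), nrow = n_experts)
    ratings <- round(sweep(noise, 2, latent, "+"))
    ratings[ratings < 1] <- 1L
    ratings[ratings > 5] <- 5L
  }
  dimnames(ratings) <- list(sprintf("E%02d", seq_len(n_experts)),
                            sprintf("I%02d", seq_len(n_items)))
  fam_levels <- names(delphi_familiarity_mapping())
  profiles <- data.frame(
    expert_id = rownames(ratings),
    familiarity = sample(fam_levels, n_experts, replace = TRUE,
                         prob = c(0.40, 0.40, 0.15, 0.04, 0.01)),
    practical_experience = sample(c("high", "medium", "low"), n_experts,
                                  replace = TRUE, prob = c(0.6, 0.3, 0.1)),
    theoretical_analysis = sample(c("high", "medium", "low"), n_experts,
                                  replace = TRUE, prob = c(0.6, 0.3, 0.1)),
    peer_knowledge = sample(c("high", "medium", "low"), n_experts,
                            replace = TRUE, prob = c(0.6, 0.3, 0.1)),
    intuition = sample(c("high", "medium", "low"), n_experts,
                       replace = TRUE, prob = c(0.6, 0.3, 0.1)),
    stringsAsFactors = FALSE
  )
  list(ratings = ratings, profiles = profiles, latent = latent)
}
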