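# Shared in-code fixtures: a small hand-built dataset/schema/plan whose
# indicator values are countable by eye, and a randomized adversarial
# dataset builder for robustness properties.

toy_schema <- function() {
  emr_schema(
    elements = list(
      hr = list(type = "numeric", unit = "bpm", range = c(20, 300),
                interval_hours = 4, method = "monitor"),
      temperature = list(type = "numeric", unit = "C", convertible_units = "F",
                         range = c(30, 45), decimals = 1),
      sex = list(type = "categorical", code_set = c("M", "F"), format = "^[MF]$"),
      wt = list(type = "numeric", unit = "kg", range = c(30, 250)),
      ht = list(type = "numeric", unit = "cm", range = c(120, 220),
                synonyms = "height"),
      bmi = list(type = "numeric", range = c(10, 80)),
      outcome = list(type = "categorical", code_set = c("0", "1"))
    ),
    derived = list(list(target = "bmi", components = c("wt", "ht"),
                        formula = "wt / (ht / 100)^2", tolerance = 0.5)),
    timeliness_hours = 24
  )
}

toy_plan <- function() {
  modeling_plan(inputs = c("sex", "wt", "ht", "bmi"), outcomes = "outcome",
                required_n = 4L)
}

# 4 clean records + optional measurement rows
toy_dataset <- function(records_patch = NULL, measurements = NULL) {
  rec <- data.frame(
    patient_id = paste0("P", 1:4),
    admission_id = paste0("A", 1:4),
    admission_time = "2010-01-01T00:00:00",
    discharge_time = "2010-01-02T00:00:00",
    record_created = "2010-01-01T00:00:00",
    state = "available",
    sex = c("M", "F", "M", "F"),
    wt = c(70, 80, 90, 60),
    ht = c(170, 180, 175, 160),
    stringsAsFactors = FALSE
  )
  rec$bmi <- round(rec$wt / (rec$ht / 100)^2, 1)
  rec$outcome <- c(0L, 1L, 0L, 1L)
  if (!is.null(records_patch)) {
    for (cl in names(records_patch)) rec[[cl]] <- records_patch[[cl]]
  }
  emr_dataset(rec, measurements,
              column_units = c(wt = "kg", ht = "cm"),
              extracted_at = "2011-01-01T00:00:00",
              label = "toy")
}

toy_measurements <- function(n_per_rec = 7) {
  hrs <- (seq_len(n_per_rec) - 1) * 4
  t0 <- as.POSIXct("2010-01-01 00:00:00", tz = "UTC")
  do.call(rbind, lapply(paste0("A", 1:4), function(id) {
    data.frame(admission_id = id, element = "hr", value = 80 + hrs,
               time = format(t0 + hrs * 3600, "%Y-%m-%dT%H:%M:%S"),
               recorded_time = format(t0 + hrs * 3600, "%Y-%m-%dT%H:%M:%S"),
               unit = "bpm", method = "monitor", stringsAsFactors = FALSE)
  }))
}

# randomized hostile dataset: arbitrary shapes, garbage values, broken
# timestamps; always a structurally valid emr_dataset
adversarial_dataset <- function(seed) {
  set.seed(seed)
  n <- sample(0:20, 1)
  garbage <- function(m) {
    pool <- list(
      function(k) runif(k, -1e6, 1e6),
      function(k) sample(c(NA, "", "abc", "9999", "-1", "12.3.4", "Inf"), k, TRUE),
      function(k) sample(c(Inf, -Inf, NaN, NA_real_, 0, 1e308), k, TRUE),
      function(k) sample(c("2010-01-01T00:00:00", "not-a-date", "", NA,
                           "2099-12-31T23:59:59"), k, TRUE),
      function(k) sample(c("M", "F", "male", "??", NA), k, TRUE)
    )
    pool[[sample(length(pool), 1)]](m)
  }
  rec <- data.frame(patient_id = seq_len(n) + 0.5,
                    admission_id = if (n) paste0("A", seq_len(n)) else character(),
                    stringsAsFactors = FALSE)
  for (cl in c("admission_time", "discharge_time", "record_created", "state",
               "sex", "wt", "ht", "bmi", "outcome", "mystery")) {
    if (runif(1) < 0.7) rec[[cl]] <- if (n) garbage(n) else garbage(0)
  }
  meas <- NULL
  if (runif(1) < 0.6) {
    m <- sample(0:40, 1)
    meas <- data.frame(
      admission_id = sample(c(rec$admission_id, "ZZZ"), max(m, 1), TRUE)[seq_len(m)],
      element = sample(c("hr", "temperature", "unknown_el"), max(m, 1), TRUE)[seq_len(m)],
      value = garbage(m),
      time = garbage(m), recorded_time = garbage(m),
      unit = sample(c("bpm", "C", "F", "?", NA), max(m, 1), TRUE)[seq_len(m)],
      method = sample(c("monitor", "manual", NA), max(m, 1), TRUE)[seq_len(m)],
      stringsAsFactors = FALSE
    )
  }
  emr_dataset(rec, meas, extracted_at = "2011-01-01T00:00:00",
              label = paste0("adversarial-", seed))
}
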