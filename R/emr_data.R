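#' Construct an EMR-style dataset object
#'
#' The container every indicator measures: a wide records table (one row
#' per admission) plus an optional long measurements table for repeated
#' observations such as vital signs. Timestamps are carried as ISO 8601
#' character strings (or per the schema's declared format) and are parsed
#' lazily by the indicator engine; unparseable timestamps count as
#' invalid, they never crash the engine.
#'
#' @param records Data frame with key columns `patient_id` and
#'   `admission_id`, optional anchor/meta columns `admission_time`,
#'   `discharge_time`, `record_created`, `state`, and one column per wide
#'   data element.
#' @param measurements Optional long data frame: `admission_id`,
#'   `element`, `value`, `time` (measurement timestamp), `recorded_time`
#'   (when the value was entered; falls back to the record's
#'   `record_created`), `unit`, `method`. May be `NULL`.
#' @param column_units Named character vector: observed unit per wide
#'   element column.
#' @param column_methods Named character vector: measurement-method tag
#'   per wide element column.
#' @param extracted_at Extraction date of the dataset (ISO string or
#'   POSIXct); timestamps after it are future-dated.
#' @param source_manifest Optional list with `n_records` and `nonmissing`
#'   (named integer vector of per-column non-missing counts) describing
#'   the source extract, used by the migration-reliability indicator.
#' @param label Dataset label used in scorecards.
#' @return An object of class `emr_dataset`.
#' @export
emr_dataset <- function(records, measurements = NULL,
                        column_units = character(), column_methods = character(),
                        extracted_at = "2100-01-01T00:00:00",
                        source_manifest = NULL, label = "dataset") {
  records <- as.data.frame(records)
  if (anyDuplicated(names(records))) {
    stop("duplicate column names in records", call. = FALSE)
  }
  keys <- intersect(c("patient_id", "admission_id"), names(records))
  if ("admission_id" %in% keys && anyDuplicated(records$admission_id)) {
    stop("duplicate admission_id keys in records", call. = FALSE)
  }
  if (!is.null(measurements)) {
    measurements <- as.data.frame(measurements)
    need <- c("admission_id", "element", "value")
    miss <- setdiff(need, names(measurements))
    if (length(miss)) stop("measurements missing column(s): ",
                           paste(miss, collapse = ", "), call. = FALSE)
    for (opt in c("time", "recorded_time", "unit", "method")) {
      if (!opt %in% names(measurements)) measurements[[opt]] <- NA_character_
    }
  }
  structure(
    list(records = records, measurements = measurements,
         column_units = column_units, column_methods = column_methods,
         extracted_at = as.character(extracted_at),
         source_manifest = source_manifest, label = as.character(label)),
    class = "emr_dataset"
  )
}

#' @export
print.emr_dataset <- function(x, ...) {
  cat("<emr_dataset> '", x$label, "': ", nrow(x$records), " records, ",
      ncol(x$records), " columns",
      if (!is.null(x$measurements)) paste0(", ", nrow(x$measurements), " measurements"),
      "\n", sep = "")
  invisible(x)
}

#' Read an EMR dataset from CSV files
#'
#' @param records_csv Path to the wide records CSV (UTF-8, header row,
#'   comma-separated).
#' @param measurements_csv Optional path to the long measurements CSV.
#' @param ... Passed to [emr_dataset()].
#' @return An `emr_dataset`.
#' @export
read_emr_dataset <- function(records_csv, measurements_csv = NULL, ...) {
  rec <- read.csv(records_csv, stringsAsFactors = FALSE, colClasses = NA)
  meas <- if (!is.null(measurements_csv)) {
    read.csv(measurements_csv, stringsAsFactors = FALSE)
  }
  emr_dataset(rec, meas, ...)
}

#' Write an EMR dataset to CSV files
#'
#' @param dataset An `emr_dataset`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
write_emr_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(records = file.path(dir, "records.csv"))
  write.csv(dataset$records, paths[["records"]], row.names = FALSE, na = "")
  if (!is.null(dataset$measurements)) {
    paths[["measurements"]] <- file.path(dir, "measurements.csv")
    write.csv(dataset$measurements, paths[["measurements"]], row.names = FALSE, na = "")
  }
  invisible(paths)
}

#' Construct a reference schema
#'
#' The declared standard every indicator is measured against.
#'
#' @param elements Named list; each entry may declare `synonyms`
#'   (character), `type` (`"numeric"`, `"integer"`, `"categorical"`,
#'   `"character"`, `"datetime"`), `unit` (canonical),
#'   `convertible_units`, `format` (regex the values must match),
#'   `decimals` (required decimal places), `range` (`c(low, high)`),
#'   `code_set`, `required` (default `TRUE`), `method` (expected
#'   measurement method tag), `interval_hours` (required recording
#'   interval for monitored elements).
#' @param primary_keys Required key fields.
#' @param derived List of derived-value definitions: each a list with
#'   `target`, `components`, `formula` (an R expression over component
#'   names, as a string) and `tolerance`.
#' @param timeliness_hours Timeliness window tau in hours: a value must
#'   be entered into the record within tau of its measurement.
#' @param timestamp_format `strptime` format all timestamps must parse
#'   under (default ISO 8601, seconds precision).
#' @param missing_codes Sentinel strings treated as missing in addition
#'   to `NA` and the empty string.
#' @return An object of class `emr_schema`.
#' @export
emr_schema <- function(elements, primary_keys = c("patient_id", "admission_id"),
                       derived = list(), timeliness_hours = 24,
                       timestamp_format = "%Y-%m-%dT%H:%M:%S",
                       missing_codes = character()) {
  for (d in derived) {
    undeclared <- setdiff(c(d$target, d$components), names(elements))
    if (length(undeclared)) {
      stop("derived-value definition references undeclared element(s): ",
           paste(undeclared, collapse = ", "), call. = FALSE)
    }
  }
  structure(
    list(elements = elements, primary_keys = primary_keys, derived = derived,
         timeliness_hours = timeliness_hours, timestamp_format = timestamp_format,
         missing_codes = missing_codes),
    class = "emr_schema"
  )
}

#' Read / write a reference schema as YAML
#'
#' @param path File path.
#' @return `read_schema()`: an `emr_schema`; `write_schema()`: `path`,
#'   invisibly.
#' @export
read_schema <- function(path) {
  cfg <- yaml::read_yaml(path)
  els <- lapply(cfg$elements, function(e) {
    if (!is.null(e$range)) e$range <- as.numeric(e$range)
    e
  })
  emr_schema(
    elements = els,
    primary_keys = cfg$primary_keys %||% c("patient_id", "admission_id"),
    derived = cfg$derived %||% list(),
    timeliness_hours = cfg$timeliness_hours %||% 24,
    timestamp_format = cfg$timestamp_format %||% "%Y-%m-%dT%H:%M:%S",
    missing_codes = as.character(cfg$missing_codes %||% character())
  )
}

#' @rdname read_schema
#' @param schema An `emr_schema`.
#' @export
write_schema <- function(schema, path) {
  yaml::write_yaml(unclass(schema), path)
  invisible(path)
}

#' Construct a modeling plan
#'
#' Declares what a prediction task needs from the dataset: predictor and
#' outcome elements, a minimum sample size, and (optionally) the
#' measurement method each element must have been collected with.
#'
#' @param inputs Character vector of predictor element names.
#' @param outcomes Character vector of outcome element names (disjoint
#'   from `inputs`).
#' @param required_n Minimum required sample size.
#' @param input_methods,outcome_methods Named character vectors of
#'   required measurement-method tags.
#' @return An object of class `modeling_plan`.
#' @export
modeling_plan <- function(inputs, outcomes, required_n = 1L,
                          input_methods = character(), outcome_methods = character()) {
  if (!length(inputs) || !length(outcomes)) {
    stop("modeling plan needs non-empty inputs and outcomes", call. = FALSE)
  }
  if (length(intersect(inputs, outcomes))) {
    stop("inputs and outcomes must be disjoint", call. = FALSE)
  }
  structure(
    list(inputs = inputs, outcomes = outcomes, required_n = required_n,
         input_methods = input_methods, outcome_methods = outcome_methods),
    class = "modeling_plan"
  )
}

#' Read / write a modeling plan as YAML
#'
#' @param path File path.
#' @export
read_plan <- function(path) {
  cfg <- yaml::read_yaml(path)
  modeling_plan(
    inputs = as.character(cfg$inputs),
    outcomes = as.character(cfg$outcomes),
    required_n = cfg$required_n %||% 1L,
    input_methods = unlist(cfg$input_methods) %||% character(),
    outcome_methods = unlist(cfg$outcome_methods) %||% character()
  )
}

#' @rdname read_plan
#' @param plan A `modeling_plan`.
#' @export
write_plan <- function(plan, path) {
  yaml::write_yaml(unclass(plan), path)
  invisible(path)
}

#' Reference five-cohort study fixtures
#'
#' Transcriptions of the summary results of the MIMIC-III sepsis
#' validation study behind the packaged index system: first-level and
#' total quality scores of five ICU cohorts (elderly, long length-of-stay
#' `LLOS`, ischemic stroke, acute renal failure `ARF`, cirrhosis `CIR`),
#' and the accuracy/precision/AUC of the three baseline classifiers
#' (logistic regression, support vector machine, random forest) on each.
#'
#' @return `mimic_study_scores()`: data frame of per-cohort dimension
#'   scores and totals. `mimic_study_performance()`: long data frame
#'   (dataset, model, metric, value).
#' @export
mimic_study_scores <- function() {
  read.csv(system.file("extdata", "mimic_cohort_scores.csv",
                       package = "emrqi", mustWork = TRUE),
           stringsAsFactors = FALSE)
}

#' @rdname mimic_study_scores
#' @export
mimic_study_performance <- function() {
  read.csv(system.file("extdata", "mimic_cohort_performance.csv",
                       package = "emrqi", mustWork = TRUE),
           stringsAsFactors = FALSE)
}
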