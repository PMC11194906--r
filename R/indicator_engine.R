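# Indicator engine: raw scores in [0, 1] for the 33 leaf indicators,
# measured against a reference schema and a modeling plan. Every
# calculator returns numerator/denominator evidence and never divides by
# zero: an indicator that cannot be evaluated is flagged and scored per
# the configured not-evaluable policy.

RESERVED_COLUMNS <- c("patient_id", "admission_id", "admission_time",
                      "discharge_time", "record_created", "state")

.is_missing <- function(x, codes = character()) {
  ch <- trimws(as.character(x))
  is.na(x) | ch == "" | ch %in% codes
}

.parse_time <- function(x, fmt = "%Y-%m-%dT%H:%M:%S") {
  if (is.null(x)) return(NULL)
  if (inherits(x, "POSIXct")) return(x)
  as.POSIXct(strptime(as.character(x), fmt, tz = "UTC"))
}

# shared parsed state, built once per dataset scoring pass; memoized on
# the dataset object so a full 33-indicator pass parses timestamps once
.engine_context <- function(ds, schema) {
  if (!is.null(ds$.ctx)) return(ds$.ctx)
  fmt <- schema$timestamp_format
  rec <- ds$records
  ctx <- list(fmt = fmt)
  ctx$adm <- if ("admission_time" %in% names(rec)) .parse_time(rec$admission_time, fmt)
  ctx$dis <- if ("discharge_time" %in% names(rec)) .parse_time(rec$discharge_time, fmt)
  ctx$created <- if ("record_created" %in% names(rec)) .parse_time(rec$record_created, fmt)
  ctx$extraction <- .parse_time(ds$extracted_at, fmt)
  if (is.na(ctx$extraction)) ctx$extraction <- .parse_time(ds$extracted_at, "%Y-%m-%d")
  m <- ds$measurements
  if (!is.null(m) && nrow(m)) {
    ctx$rec_idx <- match(m$admission_id, rec$admission_id)
    ctx$mt <- .parse_time(m$time, fmt)
    mrt <- .parse_time(m$recorded_time, fmt)
    if (!is.null(ctx$created)) {
      fill <- is.na(mrt) & .is_missing(m$recorded_time)
      mrt[fill] <- ctx$created[ctx$rec_idx][fill]
    }
    ctx$mrt <- mrt
  }
  ctx
}

# schema elements a dataset element name resolves to (name or synonym)
.resolve_concepts <- function(colname, schema) {
  hits <- vapply(names(schema$elements), function(e) {
    colname == e || colname %in% (schema$elements[[e]]$synonyms %||% character())
  }, logical(1))
  names(schema$elements)[hits]
}

.wide_elements <- function(ds) setdiff(names(ds$records), RESERVED_COLUMNS)

.long_elements <- function(ds) {
  if (is.null(ds$measurements)) character() else unique(ds$measurements$element)
}

.dataset_elements <- function(ds) unique(c(.wide_elements(ds), .long_elements(ds)))

.required_elements <- function(schema) {
  names(schema$elements)[vapply(schema$elements,
                                function(e) isTRUE(e$required %||% TRUE), logical(1))]
}

# is a required schema element present in the dataset (under any synonym)?
.element_available <- function(element, ds, schema) {
  syn <- c(element, schema$elements[[element]]$synonyms %||% character())
  any(syn %in% .dataset_elements(ds))
}

.score_frac <- function(num, den, diagnostics = NULL) {
  if (is.na(den) || den <= 0) {
    return(list(raw = NA_real_, numerator = num, denominator = den,
                evaluable = FALSE, reason = "zero denominator",
                diagnostics = diagnostics))
  }
  list(raw = max(0, min(1, num / den)), numerator = num, denominator = den,
       evaluable = TRUE, reason = NA_character_, diagnostics = diagnostics)
}

.not_evaluable <- function(reason) {
  list(raw = NA_real_, numerator = NA_real_, denominator = NA_real_,
       evaluable = FALSE, reason = reason, diagnostics = NULL)
}

#' Completeness of values over a set of columns
#'
#' Fraction of non-missing cells over the listed wide columns; a column
#' absent from the dataset contributes a full column of missing cells.
#' Missing means `NA`, the empty string, or a configured sentinel code.
#'
#' @param dataset An `emr_dataset`.
#' @param columns Non-empty character vector of element columns.
#' @param missing_codes Extra sentinel strings counted as missing.
#' @return Fraction in `[0, 1]`.
#' @examples
#' d <- emr_dataset(data.frame(patient_id = 1:4, admission_id = 1:4,
#'                             a = c(1, NA, 3, 4)))
#' value_completeness_ratio(d, "a")
#' @export
value_completeness_ratio <- function(dataset, columns, missing_codes = character()) {
  if (!length(columns)) stop("empty column set", call. = FALSE)
  n <- nrow(dataset$records)
  total <- n * length(columns)
  present <- sum(vapply(columns, function(cl) {
    if (!cl %in% names(dataset$records)) return(0L)
    sum(!.is_missing(dataset$records[[cl]], missing_codes))
  }, integer(1)))
  if (total == 0) return(structure(NA_real_, reason = "no cells"))
  present / total
}

#' Normalized entropy balance of a categorical column
#'
#' Shannon entropy of the observed category distribution divided by
#' `log(k)` for the `k` observed categories; a single observed category
#' scores 0 by convention, a uniform distribution 1.
#'
#' @inheritParams value_completeness_ratio
#' @param column Column name.
#' @return Fraction in `[0, 1]`, or `NA` (with a `reason` attribute) for
#'   an all-missing column.
#' @export
normalized_entropy_balance <- function(dataset, column, missing_codes = character()) {
  if (!column %in% names(dataset$records)) {
    return(structure(NA_real_, reason = paste0("column absent: ", column)))
  }
  x <- dataset$records[[column]]
  x <- x[!.is_missing(x, missing_codes)]
  if (!length(x)) return(structure(NA_real_, reason = "all values missing"))
  p <- table(x) / length(x)
  k <- length(p)
  if (k == 1L) return(0)
  min(1, max(0, as.numeric(-sum(p * log(p)) / log(k))))
}

#' Plausibility-range conformance of numeric values
#'
#' Fraction of non-missing values of range-declared elements lying inside
#' their declared `[low, high]`; unparseable values count as
#' non-conforming. Wide columns and long measurements both contribute.
#'
#' @inheritParams value_completeness_ratio
#' @param schema An `emr_schema` declaring `range` for at least one
#'   element.
#' @return Fraction in `[0, 1]`, or `NA` with a reason when no ranges
#'   apply.
#' @export
range_conformance_ratio <- function(dataset, schema) {
  ranged <- names(schema$elements)[!vapply(schema$elements,
                                           function(e) is.null(e$range), logical(1))]
  if (!length(ranged)) return(structure(NA_real_, reason = "no plausibility ranges declared"))
  num <- 0L
  den <- 0L
  for (el in ranged) {
    rg <- schema$elements[[el]]$range
    vals <- character()
    if (el %in% names(dataset$records)) {
      v <- dataset$records[[el]]
      vals <- c(vals, as.character(v[!.is_missing(v, schema$missing_codes)]))
    }
    if (!is.null(dataset$measurements)) {
      mv <- dataset$measurements$value[dataset$measurements$element == el]
      vals <- c(vals, as.character(mv[!.is_missing(mv, schema$missing_codes)]))
    }
    if (!length(vals)) next
    x <- suppressWarnings(as.numeric(vals))
    den <- den + length(x)
    num <- num + sum(!is.na(x) & x >= rg[1] & x <= rg[2])
  }
  if (den == 0) return(structure(NA_real_, reason = "no values under ranged elements"))
  num / den
}

#' Temporal-order compliance of records
#'
#' Fraction of records whose time logs are ordered: parseable admission
#' and discharge anchors with admission <= discharge, every measurement
#' timestamp inside the stay, and no timestamp after the dataset's
#' extraction date. Records lacking anchors are non-compliant.
#'
#' @inheritParams range_conformance_ratio
#' @return Fraction in `[0, 1]`.
#' @export
temporal_order_compliance <- function(dataset, schema) {
  ctx <- .engine_context(dataset, schema)
  n <- nrow(dataset$records)
  if (n == 0) return(structure(NA_real_, reason = "no records"))
  if (is.null(ctx$adm) || is.null(ctx$dis)) return(0)
  ok <- !is.na(ctx$adm) & !is.na(ctx$dis) & ctx$adm <= ctx$dis &
    ctx$dis <= ctx$extraction
  if (!is.null(dataset$measurements) && nrow(dataset$measurements)) {
    viol <- !is.na(ctx$mt) &
      (ctx$mt < ctx$adm[ctx$rec_idx] | ctx$mt > ctx$dis[ctx$rec_idx] |
         ctx$mt > ctx$extraction)
    bad_rec <- unique(dataset$measurements$admission_id[viol])
    ok <- ok & !(dataset$records$admission_id %in% bad_rec)
  }
  mean(ok)
}

#' Timeliness of value recording
#'
#' Fraction of measured values entered into the record within the
#' schema's timeliness window: `0 <= (recording time - measurement time)
#' <= tau`. A value's recording time is its own entry timestamp when
#' present, else the record's creation timestamp; values whose delay
#' cannot be established count as untimely.
#'
#' @inheritParams range_conformance_ratio
#' @return Fraction in `[0, 1]`, or `NA` with a reason when no window or
#'   no timestamped values exist.
#' @export
recording_timeliness <- function(dataset, schema) {
  if (is.null(schema$timeliness_hours)) {
    return(structure(NA_real_, reason = "timeliness window undeclared"))
  }
  m <- dataset$measurements
  if (is.null(m) || !nrow(m)) return(structure(NA_real_, reason = "no measurements"))
  ctx <- .engine_context(dataset, schema)
  has_t <- !is.na(ctx$mt)
  if (!any(has_t)) return(structure(NA_real_, reason = "no measurement timestamps"))
  delay <- as.numeric(difftime(ctx$mrt, ctx$mt, units = "hours"))
  timely <- !is.na(delay) & delay >= 0 & delay <= schema$timeliness_hours
  sum(timely & has_t) / sum(has_t)
}

#' Recording-frequency adequacy of monitored elements
#'
#' For every element with a declared required recording interval and
#' every record with a parseable stay, the attainment is
#' `min(1, observed count / expected count)` with
#' `expected = ceiling(stay / interval)` (a zero-length stay expects one
#' measurement). Attainments are averaged over elements within a record,
#' then over records.
#'
#' @inheritParams range_conformance_ratio
#' @return Fraction in `[0, 1]`, or `NA` with a reason.
#' @export
recording_frequency_ratio <- function(dataset, schema) {
  monitored <- names(schema$elements)[!vapply(schema$elements,
                                              function(e) is.null(e$interval_hours), logical(1))]
  if (!length(monitored)) return(structure(NA_real_, reason = "no required recording intervals"))
  ctx <- .engine_context(dataset, schema)
  if (is.null(ctx$adm) || is.null(ctx$dis)) {
    return(structure(NA_real_, reason = "records lack stay anchors"))
  }
  stay_h <- as.numeric(difftime(ctx$dis, ctx$adm, units = "hours"))
  usable <- !is.na(stay_h) & stay_h >= 0
  if (!any(usable)) return(structure(NA_real_, reason = "no records with usable stays"))
  m <- dataset$measurements
  ids <- as.character(dataset$records$admission_id)
  att <- matrix(0, nrow = length(monitored), ncol = nrow(dataset$records),
                dimnames = list(monitored, ids))
  for (el in monitored) {
    expected <- pmax(1, ceiling(stay_h / schema$elements[[el]]$interval_hours))
    obs <- rep(0, length(ids))
    if (!is.null(m) && nrow(m)) {
      tab <- table(as.character(m$admission_id[m$element == el]))
      hit <- match(names(tab), ids)
      obs[hit[!is.na(hit)]] <- as.integer(tab[!is.na(hit)])
    }
    att[el, ] <- pmin(1, obs / expected)
  }
  mean(colMeans(att[, usable, drop = FALSE]))
}

#' Consistency of stored derived values
#'
#' For each derived-value definition in the schema (target element,
#' component elements, formula, tolerance), the fraction of rows with
#' all components and the target present whose stored target matches the
#' recomputed formula within tolerance.
#'
#' @inheritParams range_conformance_ratio
#' @return Fraction in `[0, 1]`, or `NA` with a reason.
#' @export
derived_value_consistency <- function(dataset, schema) {
  if (!length(schema$derived)) {
    return(structure(NA_real_, reason = "no derived-value definitions"))
  }
  rec <- dataset$records
  num <- 0L
  den <- 0L
  for (d in schema$derived) {
    cols <- c(d$target, d$components)
    if (!all(cols %in% names(rec))) next
    vals <- lapply(cols, function(cl) suppressWarnings(as.numeric(rec[[cl]])))
    names(vals) <- cols
    complete <- Reduce(`&`, lapply(vals, function(v) !is.na(v)))
    if (!any(complete)) next
    env <- lapply(vals, function(v) v[complete])
    recomputed <- eval(parse(text = d$formula), envir = env)
    stored <- vals[[d$target]][complete]
    den <- den + sum(complete)
    num <- num + sum(abs(recomputed - stored) <= (d$tolerance %||% 1e-6))
  }
  if (den == 0) return(structure(NA_real_, reason = "no rows with complete components"))
  num / den
}

#' Mapping ratios between a dataset and its reference schema
#'
#' Four aspects of how well a dataset maps onto the reference standard:
#' `"primary-key"` — matched key fields over required key fields;
#' `"element"` — required schema elements resolvable in the dataset
#' (canonical name or synonym) over required elements;
#' `"convertibility"` — mapped unit-bearing elements whose observed units
#' are canonical or convertible over mapped unit-bearing elements;
#' `"terminology"` — coded values inside their bound code set over coded
#' values.
#'
#' @inheritParams range_conformance_ratio
#' @param aspect One of `"primary-key"`, `"element"`, `"convertibility"`,
#'   `"terminology"`.
#' @return Fraction in `[0, 1]`, or `NA` with a reason when the schema
#'   lacks the aspect's declarations.
#' @export
mapping_ratio <- function(dataset, schema,
                          aspect = c("primary-key", "element", "convertibility",
                                     "terminology")) {
  aspect <- match.arg(aspect)
  switch(aspect,
    "primary-key" = {
      req <- schema$primary_keys
      if (!length(req)) return(structure(NA_real_, reason = "no primary keys declared"))
      sum(req %in% names(dataset$records)) / length(req)
    },
    "element" = {
      req <- .required_elements(schema)
      if (!length(req)) return(structure(NA_real_, reason = "no required elements declared"))
      sum(vapply(req, .element_available, logical(1), ds = dataset, schema = schema)) /
        length(req)
    },
    "convertibility" = {
      unit_els <- names(schema$elements)[!vapply(schema$elements,
                                                 function(e) is.null(e$unit), logical(1))]
      mapped <- unit_els[vapply(unit_els, .element_available, logical(1),
                                ds = dataset, schema = schema)]
      if (!length(mapped)) return(structure(NA_real_, reason = "no mapped unit-bearing elements"))
      convertible <- vapply(mapped, function(el) {
        e <- schema$elements[[el]]
        ok_units <- c(e$unit, e$convertible_units %||% character())
        obs <- character()
        if (el %in% names(dataset$column_units)) obs <- c(obs, dataset$column_units[[el]])
        if (!is.null(dataset$measurements)) {
          u <- dataset$measurements$unit[dataset$measurements$element == el]
          obs <- c(obs, unique(u[!.is_missing(u)]))
        }
        if (!length(obs)) return(TRUE)  # unannotated: assumed canonical
        all(obs %in% ok_units)
      }, logical(1))
      sum(convertible) / length(mapped)
    },
    "terminology" = {
      coded <- names(schema$elements)[!vapply(schema$elements,
                                              function(e) is.null(e$code_set), logical(1))]
      coded <- intersect(coded, names(dataset$records))
      if (!length(coded)) return(structure(NA_real_, reason = "no coded elements present"))
      num <- 0L
      den <- 0L
      for (el in coded) {
        v <- dataset$records[[el]]
        v <- as.character(v[!.is_missing(v, schema$missing_codes)])
        den <- den + length(v)
        num <- num + sum(v %in% as.character(schema$elements[[el]]$code_set))
      }
      if (den == 0) return(structure(NA_real_, reason = "no coded values"))
      num / den
    }
  )
}

# ---- calculator registry ---------------------------------------------------

.frac_or_ne <- function(x) {
  if (is.na(x)) .not_evaluable(attr(x, "reason") %||% "not evaluable")
  else list(raw = max(0, min(1, as.numeric(x))), numerator = NA_real_,
            denominator = NA_real_, evaluable = TRUE, reason = NA_character_,
            diagnostics = NULL)
}

.observed_methods <- function(el, ds) {
  obs <- character()
  if (el %in% names(ds$column_methods)) obs <- c(obs, ds$column_methods[[el]])
  if (!is.null(ds$measurements)) {
    mm <- ds$measurements$method[ds$measurements$element == el]
    obs <- c(obs, unique(mm[!.is_missing(mm)]))
  }
  unique(obs)
}

.method_selectivity <- function(ds, required) {
  if (!length(required)) return(.not_evaluable("no measurement-method requirements"))
  ok <- vapply(names(required), function(el) {
    obs <- .observed_methods(el, ds)
    length(obs) >= 1 && all(obs == required[[el]])
  }, logical(1))
  .score_frac(sum(ok), length(required),
              diagnostics = names(required)[!ok])
}

.presence_ratio <- function(ds, schema, elements) {
  if (!length(elements)) return(.not_evaluable("empty element set"))
  ok <- vapply(elements, function(el) {
    el %in% names(schema$elements) && .element_available(el, ds, schema) ||
      el %in% .dataset_elements(ds)
  }, logical(1))
  .score_frac(sum(ok), length(elements), diagnostics = elements[!ok])
}

.typed_parse_ok <- function(vals, type, fmt) {
  switch(type,
    numeric = !is.na(suppressWarnings(as.numeric(vals))),
    integer = {
      x <- suppressWarnings(as.numeric(vals))
      !is.na(x) & x == round(x)
    },
    datetime = !is.na(.parse_time(vals, fmt)),
    rep(TRUE, length(vals))   # character / categorical always parse
  )
}

.observed_decimals <- function(vals) {
  ch <- as.character(vals)
  dec <- ifelse(grepl("\\.", ch), nchar(sub("^[^.]*\\.", "", ch)), 0L)
  suppressWarnings(max(dec, na.rm = TRUE))
}

.calculators <- function() {
  list(
    primary_key_mapping = function(ds, schema, plan)
      .frac_or_ne(mapping_ratio(ds, schema, "primary-key")),
    element_mapping = function(ds, schema, plan)
      .frac_or_ne(mapping_ratio(ds, schema, "element")),
    unit_convertibility = function(ds, schema, plan)
      .frac_or_ne(mapping_ratio(ds, schema, "convertibility")),
    reliable_migration = function(ds, schema, plan) {
      man <- ds$source_manifest
      if (is.null(man)) return(.not_evaluable("no source manifest"))
      ok <- man$n_records == nrow(ds$records)
      for (cl in names(man$nonmissing %||% character())) {
        have <- if (cl %in% names(ds$records)) {
          sum(!.is_missing(ds$records[[cl]], schema$missing_codes))
        } else 0L
        ok <- ok && have == man$nonmissing[[cl]]
      }
      .score_frac(as.integer(ok), 1L)
    },
    input_sufficiency = function(ds, schema, plan)
      .presence_ratio(ds, schema, plan$inputs),
    output_sufficiency = function(ds, schema, plan)
      .presence_ratio(ds, schema, plan$outcomes),
    input_method_selectivity = function(ds, schema, plan)
      .method_selectivity(ds, plan$input_methods),
    output_method_selectivity = function(ds, schema, plan)
      .method_selectivity(ds, plan$outcome_methods),
    input_element_integrity = function(ds, schema, plan)
      .presence_ratio(ds, schema, plan$inputs),
    output_element_integrity = function(ds, schema, plan)
      .presence_ratio(ds, schema, plan$outcomes),
    input_value_integrity = function(ds, schema, plan)
      .frac_or_ne(value_completeness_ratio(ds, plan$inputs, schema$missing_codes)),
    output_value_integrity = function(ds, schema, plan)
      .frac_or_ne(value_completeness_ratio(ds, plan$outcomes, schema$missing_codes)),
    record_timestamp_integrity = function(ds, schema, plan) {
      n <- nrow(ds$records)
      if (n == 0) return(.not_evaluable("no records"))
      created <- .engine_context(ds, schema)$created
      .score_frac(if (is.null(created)) 0L else sum(!is.na(created)), n)
    },
    value_timestamp_integrity = function(ds, schema, plan) {
      m <- ds$measurements
      if (is.null(m) || !nrow(m)) return(.not_evaluable("no measurements"))
      .score_frac(sum(!is.na(.engine_context(ds, schema)$mt)), nrow(m))
    },
    state_availability = function(ds, schema, plan) {
      n <- nrow(ds$records)
      if (n == 0) return(.not_evaluable("no records"))
      if (!"state" %in% names(ds$records)) {
        out <- .score_frac(n, n)
        out$diagnostics <- "no state column: all records assumed available"
        return(out)
      }
      .score_frac(sum(ds$records$state == "available", na.rm = TRUE), n)
    },
    adequate_data = function(ds, schema, plan)
      .score_frac(min(nrow(ds$records), plan$required_n), plan$required_n),
    input_balance = function(ds, schema, plan) {
      cats <- plan$inputs[vapply(plan$inputs, function(el) {
        identical(schema$elements[[el]]$type %||% "", "categorical")
      }, logical(1))]
      cats <- intersect(cats, names(ds$records))
      if (!length(cats)) return(.not_evaluable("no categorical inputs"))
      vals <- vapply(cats, function(cl)
        as.numeric(normalized_entropy_balance(ds, cl, schema$missing_codes)),
        numeric(1))
      if (all(is.na(vals))) return(.not_evaluable("all categorical inputs missing"))
      list(raw = mean(vals, na.rm = TRUE), numerator = NA_real_, denominator = NA_real_,
           evaluable = TRUE, reason = NA_character_, diagnostics = NULL)
    },
    outcome_balance = function(ds, schema, plan)
      .frac_or_ne(normalized_entropy_balance(ds, plan$outcomes[1], schema$missing_codes)),
    format_accuracy = function(ds, schema, plan) {
      els <- names(schema$elements)[!vapply(schema$elements,
                                            function(e) is.null(e$format), logical(1))]
      els <- intersect(els, names(ds$records))
      num <- 0L; den <- 0L
      for (el in els) {
        v <- ds$records[[el]]
        v <- as.character(v[!.is_missing(v, schema$missing_codes)])
        den <- den + length(v)
        num <- num + sum(grepl(schema$elements[[el]]$format, v))
      }
      if (den == 0) return(.not_evaluable("no values under format-declared elements"))
      .score_frac(num, den)
    },
    type_accuracy = function(ds, schema, plan) {
      els <- names(schema$elements)[!vapply(schema$elements,
                                            function(e) is.null(e$type), logical(1))]
      els <- intersect(els, names(ds$records))
      num <- 0L; den <- 0L
      for (el in els) {
        v <- ds$records[[el]]
        v <- v[!.is_missing(v, schema$missing_codes)]
        den <- den + length(v)
        num <- num + sum(.typed_parse_ok(v, schema$elements[[el]]$type,
                                         schema$timestamp_format))
      }
      if (den == 0) return(.not_evaluable("no values under typed elements"))
      .score_frac(num, den)
    },
    granularity = function(ds, schema, plan) {
      els <- names(schema$elements)[!vapply(schema$elements,
                                            function(e) is.null(e$decimals), logical(1))]
      els <- intersect(els, names(ds$records))
      if (!length(els)) return(.not_evaluable("no granularity requirements"))
      ok <- vapply(els, function(el) {
        v <- ds$records[[el]]
        v <- v[!.is_missing(v, schema$missing_codes)]
        length(v) > 0 && .observed_decimals(v) >= schema$elements[[el]]$decimals
      }, logical(1))
      .score_frac(sum(ok), length(els), diagnostics = els[!ok])
    },
    range_conformance = function(ds, schema, plan)
      .frac_or_ne(range_conformance_ratio(ds, schema)),
    element_unambiguity = function(ds, schema, plan) {
      els <- .dataset_elements(ds)
      n_concepts <- vapply(els, function(el) length(.resolve_concepts(el, schema)),
                           integer(1))
      mapped <- els[n_concepts >= 1L]
      if (!length(mapped)) return(.not_evaluable("no elements resolve to the schema"))
      .score_frac(sum(n_concepts[n_concepts >= 1L] == 1L), length(mapped),
                  diagnostics = mapped[n_concepts[n_concepts >= 1L] > 1L])
    },
    measurement_unambiguity = function(ds, schema, plan) {
      els <- .dataset_elements(ds)
      tags <- lapply(els, .observed_methods, ds = ds)
      has <- lengths(tags) >= 1L
      if (!any(has)) return(.not_evaluable("no method tags"))
      .score_frac(sum(lengths(tags)[has] == 1L), sum(has))
    },
    measurement_consistency = function(ds, schema, plan) {
      els <- .dataset_elements(ds)
      tags <- lapply(els, .observed_methods, ds = ds)
      has <- lengths(tags) >= 1L
      if (!any(has)) return(.not_evaluable("no method tags"))
      .score_frac(sum(lengths(tags)[has] == 1L), sum(has))
    },
    derived_value_consistency = function(ds, schema, plan)
      .frac_or_ne(derived_value_consistency(ds, schema)),
    unit_consistency = function(ds, schema, plan) {
      m <- ds$measurements
      if (is.null(m) || !nrow(m)) return(.not_evaluable("no unit-annotated values"))
      has_unit <- !.is_missing(m$unit)
      if (!any(has_unit)) return(.not_evaluable("no unit-annotated values"))
      canon_map <- vapply(schema$elements, function(e) e$unit %||% NA_character_,
                          character(1))
      canon <- canon_map[match(m$element[has_unit], names(canon_map))]
      .score_frac(sum(!is.na(canon) & m$unit[has_unit] == canon), sum(has_unit))
    },
    element_compliance = function(ds, schema, plan) {
      coded <- names(schema$elements)[!vapply(schema$elements,
                                              function(e) is.null(e$code_set), logical(1))]
      coded <- intersect(coded, names(ds$records))
      if (!length(coded)) return(.not_evaluable("no terminology-bound elements present"))
      ok <- vapply(coded, function(el) {
        v <- ds$records[[el]]
        v <- as.character(v[!.is_missing(v, schema$missing_codes)])
        length(v) > 0 && all(v %in% as.character(schema$elements[[el]]$code_set))
      }, logical(1))
      .score_frac(sum(ok), length(coded), diagnostics = coded[!ok])
    },
    terminology_compliance = function(ds, schema, plan)
      .frac_or_ne(mapping_ratio(ds, schema, "terminology")),
    timestamp_standard = function(ds, schema, plan) {
      vals <- character()
      for (cl in intersect(c("admission_time", "discharge_time", "record_created"),
                           names(ds$records))) {
        v <- ds$records[[cl]]
        vals <- c(vals, as.character(v[!.is_missing(v)]))
      }
      if (!is.null(ds$measurements)) {
        for (cl in c("time", "recorded_time")) {
          v <- ds$measurements[[cl]]
          vals <- c(vals, as.character(v[!.is_missing(v)]))
        }
      }
      if (!length(vals)) return(.not_evaluable("no timestamps"))
      .score_frac(sum(!is.na(.parse_time(vals, schema$timestamp_format))), length(vals))
    },
    temporal_order = function(ds, schema, plan)
      .frac_or_ne(temporal_order_compliance(ds, schema)),
    recording_timeliness = function(ds, schema, plan)
      .frac_or_ne(recording_timeliness(ds, schema)),
    recording_frequency = function(ds, schema, plan)
      .frac_or_ne(recording_frequency_ratio(ds, schema))
  )
}

#' Compute one leaf indicator on a dataset
#'
#' Dispatches to the calculator registry. An indicator that cannot be
#' evaluated on the given inputs (missing schema section, empty
#' denominator) is returned with `evaluable = FALSE` and its raw score
#' set by `na_policy`: `"benefit"` scores 1 (benefit of the doubt, the
#' default), `"zero"` scores 0, `"exclude"` leaves `NA` so downstream
#' rollups can renormalize.
#'
#' @param dataset An `emr_dataset`.
#' @param schema An `emr_schema`.
#' @param plan A `modeling_plan`.
#' @param calculator Calculator id (see
#'   `names(indicator_calculators())`).
#' @param na_policy Not-evaluable policy.
#' @return List: `calculator`, `raw`, `numerator`, `denominator`,
#'   `evaluable`, `reason`, `diagnostics`.
#' @export
compute_indicator <- function(dataset, schema, plan, calculator,
                              na_policy = c("benefit", "zero", "exclude")) {
  na_policy <- match.arg(na_policy)
  reg <- .calculators()
  if (!calculator %in% names(reg)) {
    stop("unknown indicator calculator: ", calculator, call. = FALSE)
  }
  res <- reg[[calculator]](dataset, schema, plan)
  if (!res$evaluable) {
    res$raw <- switch(na_policy, benefit = 1, zero = 0, exclude = NA_real_)
  }
  c(list(calculator = calculator), res)
}

#' The indicator calculator registry
#'
#' Named list of the 33 calculator functions; the registry is the
#' extension point for alternative published formulas.
#'
#' @return Named list of functions `(dataset, schema, plan) -> score`.
#' @export
indicator_calculators <- function() .calculators()

#' Compute all leaf indicators of an index system
#'
#' @inheritParams compute_indicator
#' @param system An `emr_index_system`.
#' @return Data frame: one row per level-3 node with its raw score and
#'   evidence.
#' @export
compute_all_indicators <- function(dataset, schema, plan,
                                   system = default_index_system(),
                                   na_policy = c("benefit", "zero", "exclude")) {
  na_policy <- match.arg(na_policy)
  dataset$.ctx <- .engine_context(dataset, schema)
  leaves <- system$nodes[system$nodes$level == 3L, ]
  rows <- lapply(seq_len(nrow(leaves)), function(i) {
    res <- compute_indicator(dataset, schema, plan, leaves$calculator[i], na_policy)
    data.frame(id = leaves$id[i], name = leaves$name[i],
               calculator = leaves$calculator[i],
               raw = res$raw,
               numerator = as.numeric(res$numerator %||% NA_real_),
               denominator = as.numeric(res$denominator %||% NA_real_),
               evaluable = res$evaluable,
               reason = res$reason %||% NA_character_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
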