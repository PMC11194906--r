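#' Load a weighted three-level index system
#'
#' An index system is a tree of quality indicators: level-1 dimensions,
#' level-2 sub-dimensions, and level-3 computable indicators, each with an
#' absolute weight on the global scale. Relative (within-sibling) weights
#' are derived as `absolute / parent absolute` and never stored, so the
#' configuration carries exactly what published weight tables print.
#'
#' @param config Path to a YAML/JSON config file, or an already-parsed
#'   list with fields `name`, `version`, `provenance` and `nodes` (each
#'   node: `id`, `name`, `level`, `parent` (levels 2-3), `weight`, and
#'   `calculator` for level-3 nodes).
#' @param tolerance Maximum tolerated absolute residual between a parent's
#'   weight and the sum of its children's weights (and between 1 and the
#'   level-1 sum). Printed weights are 3-decimal rounded, so the default
#'   allows 0.002 of drift.
#' @return An object of class `emr_index_system`: a list with `nodes`
#'   (data frame: id, name, level, parent, weight, relative, calculator),
#'   `metadata`, and a content `hash`.
#' @examples
#' sys <- default_index_system()
#' table(sys$nodes$level)
#' @export
load_index_system <- function(config, tolerance = 0.002) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      stop("index system config not found: ", config, call. = FALSE)
    }
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config) || is.null(config$nodes)) {
    stop("index system config must be a list with a 'nodes' field", call. = FALSE)
  }
  nodes <- do.call(rbind, lapply(config$nodes, function(nd) {
    data.frame(
      id = as.character(nd$id),
      name = as.character(nd$name),
      level = as.integer(nd$level),
      parent = if (is.null(nd$parent)) NA_character_ else as.character(nd$parent),
      weight = as.numeric(nd$weight),
      calculator = if (is.null(nd$calculator)) NA_character_ else as.character(nd$calculator),
      stringsAsFactors = FALSE
    )
  }))
  sys <- structure(
    list(
      nodes = nodes,
      metadata = list(
        name = config$name %||% "unnamed-index-system",
        version = as.character(config$version %||% "0"),
        provenance = config$provenance %||% ""
      )
    ),
    class = "emr_index_system"
  )
  .validate_structure(sys)
  rep <- validate_weights(sys, tolerance = tolerance)
  if (!rep$pass) {
    bad <- rep$residuals[rep$residuals$residual > tolerance, ]
    stop(
      "weight-sum violation beyond tolerance ", tolerance, " at: ",
      paste0(bad$parent, " (residual ", signif(bad$residual, 3), ")", collapse = ", "),
      call. = FALSE
    )
  }
  # relative weight among siblings; level 1: relative = absolute
  par_w <- sys$nodes$weight[match(sys$nodes$parent, sys$nodes$id)]
  sys$nodes$relative <- ifelse(sys$nodes$level == 1L, sys$nodes$weight,
                               sys$nodes$weight / par_w)
  sys$hash <- index_hash(sys)
  sys
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.validate_structure <- function(sys) {
  nodes <- sys$nodes
  dup <- nodes$id[duplicated(nodes$id)]
  if (length(dup)) stop("duplicate node id(s): ", paste(unique(dup), collapse = ", "), call. = FALSE)
  if (!all(nodes$level %in% 1:3)) stop("node levels must be 1, 2 or 3", call. = FALSE)
  if (any(!is.na(nodes$weight) & (nodes$weight <= 0 | nodes$weight > 1))) {
    stop("weights must lie in (0, 1]", call. = FALSE)
  }
  kids <- nodes[nodes$level > 1L, ]
  orphan <- kids$id[is.na(kids$parent) | !(kids$parent %in% nodes$id)]
  if (length(orphan)) stop("orphan node(s): ", paste(orphan, collapse = ", "), call. = FALSE)
  par_lvl <- nodes$level[match(kids$parent, nodes$id)]
  badlvl <- kids$id[par_lvl != kids$level - 1L]
  if (length(badlvl)) {
    stop("parent not exactly one level above for: ", paste(badlvl, collapse = ", "), call. = FALSE)
  }
  no_calc <- nodes$id[nodes$level == 3L & is.na(nodes$calculator)]
  if (length(no_calc)) stop("level-3 node(s) missing calculator: ", paste(no_calc, collapse = ", "), call. = FALSE)
  stray <- nodes$id[nodes$level < 3L & !is.na(nodes$calculator)]
  if (length(stray)) stop("calculator set on non-leaf node(s): ", paste(stray, collapse = ", "), call. = FALSE)
  invisible(sys)
}

#' Check weight conservation of an index system
#'
#' For every parent node, the children's absolute weights should sum to
#' the parent's absolute weight, and the level-1 weights should sum to 1.
#' Published weights are rounded, so small residuals are expected.
#'
#' @param system An `emr_index_system` (or a pre-validation list with the
#'   same `nodes` layout).
#' @param tolerance Maximum tolerated residual per parent.
#' @return A list of class `emrqi_weight_report`: `residuals` (data frame
#'   with one row per parent plus the level-1 root sum) and `pass`.
#' @examples
#' validate_weights(default_index_system(), tolerance = 0.002)$pass
#' @export
validate_weights <- function(system, tolerance = 0.002) {
  nodes <- system$nodes
  parents <- nodes[nodes$level < 3L & nodes$id %in% nodes$parent, ]
  res <- lapply(seq_len(nrow(parents)), function(i) {
    p <- parents[i, ]
    ch <- nodes[!is.na(nodes$parent) & nodes$parent == p$id, ]
    data.frame(parent = p$id, parent_weight = p$weight,
               child_sum = sum(ch$weight),
               residual = abs(sum(ch$weight) - p$weight))
  })
  res <- do.call(rbind, res)
  root <- data.frame(parent = "<root>", parent_weight = 1,
                     child_sum = sum(nodes$weight[nodes$level == 1L]),
                     residual = abs(sum(nodes$weight[nodes$level == 1L]) - 1))
  res <- rbind(root, res)
  structure(list(residuals = res, tolerance = tolerance,
                 pass = all(res$residual <= tolerance)),
            class = "emrqi_weight_report")
}

#' @export
print.emrqi_weight_report <- function(x, ...) {
  cat("Weight conservation report (tolerance ", x$tolerance, "): ",
      if (x$pass) "PASS" else "FAIL", "\n", sep = "")
  bad <- x$residuals[x$residuals$residual > x$tolerance, ]
  if (nrow(bad)) {
    cat("Offending parents:\n")
    print(bad, row.names = FALSE)
  }
  invisible(x)
}

#' The packaged default index system
#'
#' The published weighted hierarchy: 4 level-1 dimensions (Operability
#' 0.251, Completeness 0.254, Correctness 0.264, Timeliness 0.231), 11
#' level-2 sub-dimensions, 33 level-3 computable indicators.
#'
#' @return An `emr_index_system`.
#' @export
default_index_system <- function() {
  if (is.null(.emrqi_env$default_system)) {
    path <- system.file("extdata", "index_system.yaml", package = "emrqi", mustWork = TRUE)
    .emrqi_env$default_system <- load_index_system(path)
  }
  .emrqi_env$default_system
}

#' Serialize an index system back to YAML
#'
#' Writes the same layout [load_index_system()] reads, so a round trip
#' preserves ids, names, levels, parents and full-precision weights.
#'
#' @param system An `emr_index_system`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_index_system <- function(system, path) {
  nodes <- lapply(seq_len(nrow(system$nodes)), function(i) {
    nd <- system$nodes[i, ]
    out <- list(id = nd$id, name = nd$name, level = nd$level)
    if (!is.na(nd$parent)) out$parent <- nd$parent
    out$weight <- nd$weight
    if (!is.na(nd$calculator)) out$calculator <- nd$calculator
    out
  })
  yaml::write_yaml(
    list(name = system$metadata$name, version = system$metadata$version,
         provenance = system$metadata$provenance, nodes = nodes),
    path
  )
  invisible(path)
}

#' Stable content hash of an index system
#'
#' Hash of ids, levels, parents and weights; used to refuse comparisons
#' between scorecards produced under different systems.
#'
#' @param system An `emr_index_system`.
#' @return A character scalar.
#' @export
index_hash <- function(system) {
  n <- system$nodes
  rlang::hash(list(n$id, n$level, n$parent, n$weight, n$calculator))
}

#' @export
print.emr_index_system <- function(x, ...) {
  cat(x$metadata$name, " v", x$metadata$version, " — ",
      sum(x$nodes$level == 1L), "/", sum(x$nodes$level == 2L), "/",
      sum(x$nodes$level == 3L), " indicators\n", sep = "")
  n <- x$nodes
  for (d in n$id[n$level == 1L]) {
    cat(sprintf("%s %s (%.3f)\n", d, n$name[n$id == d], n$weight[n$id == d]))
    for (s in n$id[!is.na(n$parent) & n$parent == d]) {
      cat(sprintf("  %s %s (%.3f)\n", s, n$name[n$id == s], n$weight[n$id == s]))
      for (l in n$id[!is.na(n$parent) & n$parent == s]) {
        cat(sprintf("    %s %s (%.3f) [%s]\n", l, n$name[n$id == l],
                    n$weight[n$id == l], n$calculator[n$id == l]))
      }
    }
  }
  invisible(x)
}
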