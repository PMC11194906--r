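#' Build a pairwise judgment matrix from mean importance ratings
#'
#' Sibling indicators are compared pairwise through the ratios of their
#' mean expert ratings: `a_ij = mean_i / mean_j`. The result is a
#' positive reciprocal matrix that is exactly consistent
#' (`a_ij * a_jk = a_ik`). Optionally the entries are snapped to the
#' nearest value on the Saaty 1-9 reciprocal scale, which reintroduces
#' the realistic inconsistency the consistency-ratio test guards against.
#'
#' @param means Named positive numeric vector of per-item mean ratings.
#' @param snap_saaty Snap entries to the Saaty scale (default `FALSE`).
#' @return A `judgment_matrix`: square matrix with item names.
#' @examples
#' judgment_matrix_from_means(c(a = 4, b = 2))
#' @export
judgment_matrix_from_means <- function(means, snap_saaty = FALSE) {
  if (any(!is.finite(means)) || any(means <= 0)) {
    stop("all mean ratings must be positive", call. = FALSE)
  }
  if (is.null(names(means))) names(means) <- paste0("item", seq_along(means))
  A <- outer(means, means, "/")
  if (snap_saaty) {
    scale <- c(1 / (9:2), 1:9)
    A <- matrix(scale[vapply(as.vector(A), function(v) {
      which.min(abs(log(v / scale)))
    }, integer(1))], nrow = length(means), dimnames = list(names(means), names(means)))
    A[lower.tri(A)] <- 1 / t(A)[lower.tri(A)]
    diag(A) <- 1
  }
  validate_judgment_matrix(A)
  structure(A, class = c("judgment_matrix", "matrix"))
}

#' @keywords internal
validate_judgment_matrix <- function(A) {
  A <- unclass(A)
  if (!is.matrix(A) || nrow(A) != ncol(A)) stop("judgment matrix must be square", call. = FALSE)
  if (any(!is.finite(A)) || any(A <= 0)) stop("judgment matrix entries must be positive", call. = FALSE)
  if (any(abs(diag(A) - 1) > 1e-9)) stop("judgment matrix diagonal must be 1", call. = FALSE)
  if (any(abs(A * t(A) - 1) > 1e-9)) {
    stop("judgment matrix is not reciprocal (a_ij * a_ji must equal 1)", call. = FALSE)
  }
  invisible(A)
}

#' Principal eigenvector of a judgment matrix by power iteration
#'
#' Returns the normalized (sum 1) principal right eigenvector, the
#' relative weights of the compared items. Power iteration with a
#' sum-normalization step; for a 1x1 matrix the weight is 1.
#'
#' @param A Positive reciprocal judgment matrix.
#' @param tolerance Convergence tolerance on the max absolute change of
#'   the normalized vector between iterations.
#' @param max_iterations Iteration cap; non-convergence is an error
#'   reporting the last residual.
#' @return Named numeric vector of weights summing to 1, with the
#'   estimated principal eigenvalue in attribute `lambda_max`.
#' @examples
#' principal_eigenvector(judgment_matrix_from_means(c(a = 2, b = 1)))
#' @export
principal_eigenvector <- function(A, tolerance = 1e-10, max_iterations = 1000L) {
  validate_judgment_matrix(A)
  A <- unclass(A)
  n <- nrow(A)
  if (n == 1L) {
    w <- c(1)
    names(w) <- rownames(A)
    attr(w, "lambda_max") <- 1
    return(w)
  }
  w <- rep(1 / n, n)
  lambda <- NA_real_
  for (it in seq_len(max_iterations)) {
    v <- as.vector(A %*% w)
    w_new <- v / sum(v)
    res <- max(abs(w_new - w))
    lambda <- mean(v / w)
    w <- w_new
    if (res < tolerance) {
      names(w) <- rownames(A)
      attr(w, "lambda_max") <- lambda
      return(w)
    }
  }
  stop("power iteration did not converge in ", max_iterations,
       " iterations (last residual ", signif(res, 3), ")", call. = FALSE)
}

#' Row-geometric-mean weights of a judgment matrix
#'
#' The logarithmic least-squares alternative to the eigenvector method;
#' identical to it on exactly consistent matrices. Exposed for
#' cross-checking.
#'
#' @inheritParams principal_eigenvector
#' @return Named weights summing to 1.
#' @export
row_geometric_mean <- function(A) {
  validate_judgment_matrix(A)
  A <- unclass(A)
  g <- apply(A, 1, function(r) exp(mean(log(r))))
  g / sum(g)
}

#' Saaty random consistency index table
#'
#' Random index (RI) values for matrix orders 1..15; orders 1-2 have
#' RI 0 (such matrices are always consistent).
#'
#' @return Numeric vector of length 15.
#' @export
saaty_random_index <- function() {
  c(0, 0, 0.58, 0.90, 1.12, 1.24, 1.32, 1.41, 1.45, 1.49,
    1.52, 1.54, 1.56, 1.58, 1.59)
}

#' Consistency test of a judgment matrix
#'
#' Consistency index `CI = (lambda_max - n) / (n - 1)` and consistency
#' ratio `CR = CI / RI(n)`; a CR below 0.1 accepts the matrix. Orders
#' n <= 2 are consistent by construction, so CR is defined as 0.
#'
#' @inheritParams principal_eigenvector
#' @return List of class `ahp_consistency`: `n`, `lambda_max`, `CI`,
#'   `RI`, `CR`, `pass`.
#' @export
consistency_ratio <- function(A, tolerance = 1e-10, max_iterations = 1000L) {
  validate_judgment_matrix(A)
  n <- nrow(A)
  ri_table <- saaty_random_index()
  if (n > length(ri_table)) {
    stop("matrix order ", n, " beyond the random-index table (max ",
         length(ri_table), ")", call. = FALSE)
  }
  w <- principal_eigenvector(A, tolerance, max_iterations)
  lambda <- attr(w, "lambda_max")
  if (n <= 2L) {
    ci <- 0
    cr <- 0
  } else {
    ci <- (lambda - n) / (n - 1)
    cr <- ci / ri_table[n]
  }
  structure(list(n = n, lambda_max = lambda, CI = ci, RI = ri_table[n],
                 CR = cr, pass = cr < 0.1),
            class = "ahp_consistency")
}

#' @export
print.ahp_consistency <- function(x, ...) {
  cat(sprintf("n = %d, lambda_max = %.6f, CI = %.6f, RI = %.2f, CR = %.6f (%s)\n",
              x$n, x$lambda_max, x$CI, x$RI, x$CR,
              if (x$pass) "consistent" else "INCONSISTENT"))
  invisible(x)
}

#' Derive index-system weights from mean importance ratings
#'
#' Levels 1 and 2 are weighted by AHP: each sibling group's mean ratings
#' become a ratio judgment matrix whose principal eigenvector gives the
#' relative weights; absolute weights multiply down the tree (level-1
#' relative weights are absolute). Level-3 siblings are weighted by the
#' percentage rule: relative weight = mean rating / sum of sibling mean
#' ratings. Every AHP group must pass the consistency test (CR < 0.1) or
#' the derivation fails, naming the group.
#'
#' @param topology An `emr_index_system` (its weights are ignored) or a
#'   data frame with columns `id`, `name`, `level`, `parent`
#'   (`calculator` optional).
#' @param ratings Data frame with columns `group` (parent id, `"<root>"`
#'   for level-1 items), `item` (node id) and `rating` (positive mean).
#' @param snap_saaty Passed to [judgment_matrix_from_means()].
#' @return An `emr_index_system` with derived weights; per-group
#'   consistency results in attribute `consistency`.
#' @export
derive_weights <- function(topology, ratings, snap_saaty = FALSE) {
  nodes <- if (inherits(topology, "emr_index_system")) topology$nodes else {
    tp <- as.data.frame(topology)
    tp$weight <- NA_real_
    if (is.null(tp$calculator)) tp$calculator <- ifelse(tp$level == 3L, "unset", NA_character_)
    if (is.null(tp$name)) tp$name <- tp$id
    tp
  }
  groups <- split(nodes$id, ifelse(is.na(nodes$parent), "<root>", nodes$parent))
  consistency <- list()
  rel <- setNames(rep(NA_real_, nrow(nodes)), nodes$id)
  for (g in names(groups)) {
    items <- groups[[g]]
    lv <- nodes$level[match(items[1], nodes$id)]
    r <- ratings[ratings$group == g, ]
    miss <- setdiff(items, r$item)
    if (length(miss)) {
      stop("missing ratings in group '", g, "' for: ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    means <- setNames(r$rating[match(items, r$item)], items)
    if (any(means <= 0)) stop("nonpositive mean rating in group '", g, "'", call. = FALSE)
    if (lv == 3L) {
      rel[items] <- means / sum(means)          # percentage rule for leaves
    } else {
      A <- judgment_matrix_from_means(means, snap_saaty = snap_saaty)
      cons <- consistency_ratio(A)
      consistency[[g]] <- cons
      if (!cons$pass) {
        stop("judgment matrix for group '", g, "' fails the consistency test (CR = ",
             signif(cons$CR, 3), " >= 0.1)", call. = FALSE)
      }
      rel[items] <- principal_eigenvector(A)
    }
  }
  # absolute weights by parent multiplication, top-down
  abs_w <- setNames(rep(NA_real_, nrow(nodes)), nodes$id)
  for (lv in 1:3) {
    idx <- nodes$level == lv
    if (lv == 1L) {
      abs_w[nodes$id[idx]] <- rel[nodes$id[idx]]
    } else {
      abs_w[nodes$id[idx]] <- rel[nodes$id[idx]] * abs_w[nodes$parent[idx]]
    }
  }
  nodes$weight <- as.numeric(abs_w[nodes$id])
  nodes$relative <- as.numeric(rel[nodes$id])
  sys <- structure(
    list(nodes = nodes,
         metadata = list(name = "derived-index-system", version = "derived",
                         provenance = "weights derived from mean importance ratings")),
    class = "emr_index_system"
  )
  .validate_structure(sys)
  sys$hash <- index_hash(sys)
  attr(sys, "consistency") <- consistency
  sys
}
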