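# The SAMGSR reduction step, generic over "features": at the gene level a
# feature is a gene (all of its time points together); at the time-point
# level a feature is a single (gene, time point) cell.

#' Order features by the magnitude of their SAM statistics
#'
#' Reduction inspects features in decreasing order of evidence.  At the
#' time-point level the key is `|d_ij|`; at the gene level a gene's
#' time-course contribution is aggregated as the root sum of squares of
#' its per-time statistics, `sqrt(sum_j d_ij^2)`, consistent with how a
#' gene contributes to the SAMGS sum.  Ties keep input order (stable).
#'
#' @param sam a [sam_stat_matrix][compute_sam_statistics()].
#' @param features gene-level: character vector of genes; time-point
#'   level: data frame (gene, timepoint).
#' @param level `"timepoint"` or `"gene"`.
#' @return the reordered `features`.
#' @export
order_features <- function(sam, features, level = c("timepoint", "gene")) {
  stopifnot(inherits(sam, "sam_stat_matrix"))
  level <- match.arg(level)
  if (NROW(features) == 0L) stop("'features' must be non-empty")
  if (level == "gene") {
    features <- as.character(features)
    key <- sqrt(rowSums(sam$d[features, , drop = FALSE]^2))
    features[order(-key)]                      # order() is stable
  } else {
    idx <- .cell_index(sam$genes, sam$timepoints, features)
    features[order(-abs(sam$d[idx])), , drop = FALSE]
  }
}

# index list: one integer vector of flattened cells per feature
.feature_idx_list <- function(genes, timepoints, features, level) {
  if (level == "gene") {
    G <- length(genes)
    lapply(match(as.character(features), genes), function(gi)
      gi + (seq_along(timepoints) - 1L) * G)
  } else {
    as.list(.cell_index(genes, timepoints, features))
  }
}

.feature_subset <- function(features, i, level) {
  if (level == "gene") features[i] else features[i, , drop = FALSE]
}

#' SAMGSR reduction of one feature set into core and residual subsets
#'
#' Features are ranked by [order_features()]; for k = 1, 2, ... the
#' permutation p-value `c_k` of the residual subset (everything below
#' rank k) is computed, and the core is the smallest k whose residual is
#' non-significant for the first time (`c_k` strictly greater than
#' `cutoff`).  If no residual ever becomes non-significant the whole set
#' is the core (`k_star = S`).  A singleton input is returned as its own
#' core without any permutation test.
#'
#' All `c_k` of one call are computed against one frozen permutation
#' stream (the same `seed` for every k), so the sequence is internally
#' consistent.
#'
#' @inheritParams sam_perm_engine
#' @param features the feature set (see [order_features()] for the two
#'   forms); need not be pre-ordered unless `reorder = FALSE`.
#' @param cutoff reduction cutoff `c_k` threshold, in (0, 1).
#' @param level `"timepoint"` or `"gene"`.
#' @param engine optional prebuilt [sam_perm_engine()] to share one
#'   permutation stream across many reductions.
#' @param reorder if `FALSE`, `features` are assumed already ordered.
#' @return an object of class `reduction_result` with
#'   `ordered_features`, `ck_sequence` (c_k for k = 1..S-1), `core`,
#'   `residual`, `k_star`, `cutoff`, `level`.
#' @export
reduce_set <- function(expr = NULL, labels = NULL, features,
                       cutoff = 0.2, B = 1000L, seed = 1L,
                       level = c("timepoint", "gene"),
                       fudge_method = c("median", "fixed"),
                       fudge_const = 0.01,
                       pooling = c("within", "all"),
                       engine = NULL, reorder = TRUE) {
  level <- match.arg(level)
  if (!is.numeric(cutoff) || cutoff <= 0 || cutoff >= 1)
    stop("'cutoff' must lie strictly inside (0, 1)")
  if (NROW(features) == 0L) stop("'features' must be non-empty")
  if (is.null(engine)) {
    if (is.null(expr)) stop("either 'expr' or a prebuilt 'engine' is required")
    engine <- sam_perm_engine(expr, labels = labels, B = B, seed = seed,
                              fudge_method = match.arg(fudge_method),
                              fudge_const = fudge_const,
                              pooling = match.arg(pooling))
  }
  stopifnot(inherits(engine, "sam_perm_engine"))
  if (reorder)
    features <- order_features(engine$sam, features, level = level)
  S <- NROW(features)
  result <- function(k_star, ck) {
    structure(list(ordered_features = features,
                   ck_sequence = ck,
                   core = .feature_subset(features, seq_len(k_star), level),
                   residual = if (k_star < S)
                     .feature_subset(features, (k_star + 1L):S, level)
                   else .feature_subset(features, integer(0), level),
                   k_star = k_star, cutoff = cutoff, level = level),
              class = "reduction_result")
  }
  if (S == 1L) return(result(1L, numeric(0)))

  idx <- .feature_idx_list(engine$genes, engine$timepoints, features, level)
  obs_f <- vapply(idx, function(i) sum(engine$obs_sq[i]), numeric(1))
  perm_f <- do.call(rbind, lapply(idx, function(i)
    .colsum_rows(engine$perm_sq, i)))            # S x B
  # reverse cumulative sums: row k holds the statistic of ranks k..S
  obs_tail <- rev(cumsum(rev(obs_f)))
  perm_tail <- apply(perm_f, 2L, function(col) rev(cumsum(rev(col))))
  ck <- vapply(seq_len(S - 1L), function(k)
    (1 + sum(perm_tail[k + 1L, ] >= obs_tail[[k + 1L]])) / (engine$B + 1),
    numeric(1))
  hit <- which(ck > cutoff)
  result(if (length(hit)) hit[[1L]] else S, ck)
}

#' @export
print.reduction_result <- function(x, ...) {
  S <- NROW(x$ordered_features)
  cat(sprintf("reduction_result (%s level): k* = %d of %d features\n",
              x$level, x$k_star, S))
  if (length(x$ck_sequence))
    cat("  c_k:", paste(signif(x$ck_sequence, 3), collapse = " "),
        sprintf(" (cutoff %g)\n", x$cutoff))
  invisible(x)
}

#' Serialize a reduction result to JSON
#'
#' @param x a [reduce_set()] result.
#' @param path optional output file; if `NULL` the JSON string is
#'   returned.
#' @return the JSON string (invisibly if written to `path`).
#' @export
reduction_to_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "reduction_result"))
  obj <- list(level = x$level,
              ordered_features = x$ordered_features,
              ck_sequence = x$ck_sequence,
              k_star = x$k_star,
              cutoff = x$cutoff,
              core = x$core,
              residual = x$residual)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
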