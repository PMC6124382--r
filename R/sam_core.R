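# Time-point-specific SAM statistics, the SAMGS set statistic, and the
# subject-level permutation test that everything downstream shares.

#' Evaluate code with a temporary RNG seed
#'
#' Sets the seed, runs `code`, and restores the caller's RNG state, so
#' seeded package internals never perturb user-level randomness.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Derive a named sub-seed from a master seed
#'
#' All randomness in the package flows from one master seed through
#' named streams, so independent pipeline stages get decoupled but
#' reproducible RNG.  The result is always in `[0, 2^31 - 2]`.
#'
#' @param seed master integer seed.
#' @param name stream name.
#' @return integer sub-seed.
#' @export
sub_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.double(seed) * 48271 + h * 8121 + 28411) %% (2^31 - 1))
}

#' Fudge factor for the SAM denominator
#'
#' The small positive constant `s0` added to the per-gene standard
#' deviation to stabilise statistics of low-variance genes.  The
#' percentile-search of the original SAM procedure is deliberately not
#' implemented; the default is the median of the gene-wise standard
#' deviations, a common stable surrogate.
#'
#' @param s_values non-negative pooled standard deviations of all genes
#'   at one time point.
#' @param method `"median"` (default) or `"fixed"`.
#' @param constant the value returned under `method = "fixed"`.
#' @return a strictly positive scalar; if the computed value is zero
#'   (all `s_values` zero) a machine-epsilon-scaled floor is returned
#'   with a warning.
#' @export
fudge_factor <- function(s_values, method = c("median", "fixed"),
                         constant = 0.01) {
  method <- match.arg(method)
  if (!length(s_values)) stop("'s_values' must be non-empty")
  if (any(s_values < 0)) stop("'s_values' must be non-negative")
  s0 <- switch(method,
               median = stats::median(s_values),
               fixed = {
                 if (!is.numeric(constant) || constant <= 0)
                   stop("'constant' must be a positive number")
                 constant
               })
  floor_ <- max(.Machine$double.eps * max(s_values), .Machine$double.eps)
  if (s0 < floor_) {
    warning("computed fudge factor is zero (all standard deviations zero); ",
            "falling back to a positive floor")
    s0 <- floor_
  }
  s0
}

# Internal workhorse: SAM statistics for many label assignments at once.
#
# P:     n x B 0/1 matrix; column b marks the subjects assigned to the
#        diseased class in assignment b.  All time points of a subject
#        move together (subject-level permutation).
# Returns list(d = (G*t) x B, and for B == 1 the components).
.sam_d_multi <- function(expr, P, fudge_method = "median",
                         fudge_const = 0.01,
                         pooling = c("within", "all"),
                         keep_components = FALSE) {
  pooling <- match.arg(pooling)
  G <- length(expr$genes); t_ <- length(expr$timepoints)
  n <- length(expr$subjects); B <- ncol(P)
  nd <- colSums(P)
  if (any(nd < 2L) || any(n - nd < 2L))
    stop("each phenotype class needs at least 2 subjects ",
         "(pooled standard deviation undefined otherwise)")
  nc_ <- n - nd
  d <- matrix(NA_real_, G * t_, B)
  comp <- if (keep_components)
    list(mean_d = matrix(NA_real_, G, t_), mean_c = matrix(NA_real_, G, t_),
         s = matrix(NA_real_, G, t_), s0 = numeric(t_)) else NULL
  Q <- 1 - P
  for (j in seq_len(t_)) {
    X <- expr$values[, , j, drop = FALSE]
    dim(X) <- c(G, n)
    X2 <- X * X
    # both classes via direct products (not subtraction from the total):
    # swapping the class labels then negates d bitwise, so d^2 -- and with
    # it every permutation tie -- is exactly invariant to relabeling
    S1d <- X %*% P; S2d <- X2 %*% P
    S1c <- X %*% Q; S2c <- X2 %*% Q
    mean_d <- sweep(S1d, 2L, nd, "/")
    mean_c <- sweep(S1c, 2L, nc_, "/")
    if (pooling == "within") {
      SSd <- pmax(S2d - sweep(S1d * S1d, 2L, nd, "/"), 0)
      SSc <- pmax(S2c - sweep(S1c * S1c, 2L, nc_, "/"), 0)
      a <- (1 / nd + 1 / nc_) / (nd + nc_ - 2)
      s <- sqrt(sweep(SSd + SSc, 2L, a, "*"))
    } else {
      # total scatter pooled over all samples, scaled like a two-sample SE;
      # label-independent apart from the 1/nd + 1/nc factor
      tot1 <- rowSums(X); tot2 <- rowSums(X2)
      SSt <- pmax(tot2 - tot1^2 / n, 0)
      a <- (1 / nd + 1 / nc_) / (n - 1)
      s <- sqrt(outer(SSt, a))
    }
    s0 <- vapply(seq_len(B), function(b)
      fudge_factor(s[, b], method = fudge_method, constant = fudge_const),
      numeric(1))
    d[((j - 1L) * G + 1L):(j * G), ] <- (mean_d - mean_c) / sweep(s, 2L, s0, "+")
    if (keep_components) {
      comp$mean_d[, j] <- mean_d[, 1L]; comp$mean_c[, j] <- mean_c[, 1L]
      comp$s[, j] <- s[, 1L]; comp$s0[[j]] <- s0[[1L]]
    }
  }
  list(d = d, components = comp)
}

#' Compute SAM statistics for every (gene, time point) cell
#'
#' For gene *i* at time point *j* the moderated two-class statistic is
#' `d_ij = (mean_d - mean_c) / (s_ij + s0_j)`: the difference of the
#' class means divided by a pooled standard deviation plus a
#' time-point-specific fudge constant.  Both the pooled SD and the fudge
#' constant are computed separately at each time point because
#' measurement variability differs across time.
#'
#' @param expr a [long_expr_set].
#' @param labels optional factor overriding `expr$phenotype` (same
#'   convention: second level = diseased).
#' @param fudge_method `"median"` (default) or `"fixed"`; see
#'   [fudge_factor()].
#' @param fudge_const constant for `fudge_method = "fixed"`.
#' @param pooling `"within"` (default): two-sample pooled within-class
#'   scatter as in the original SAM statistic; `"all"`: total scatter of
#'   all samples pooled together.
#' @return an object of class `sam_stat_matrix` with matrices `d`,
#'   `mean_d`, `mean_c`, `s` (genes x time points) and the per-time
#'   fudge vector `s0`.
#' @export
compute_sam_statistics <- function(expr, labels = NULL,
                                   fudge_method = c("median", "fixed"),
                                   fudge_const = 0.01,
                                   pooling = c("within", "all")) {
  stopifnot(inherits(expr, "long_expr_set"))
  fudge_method <- match.arg(fudge_method)
  pooling <- match.arg(pooling)
  pos <- if (is.null(labels)) positive_class(expr) else {
    labels <- as.factor(labels)
    if (nlevels(droplevels(labels)) != 2L)
      stop("'labels' must have exactly two levels")
    labels == levels(droplevels(labels))[2L]
  }
  P <- matrix(as.double(pos), ncol = 1L)
  res <- .sam_d_multi(expr, P, fudge_method, fudge_const, pooling,
                      keep_components = TRUE)
  G <- length(expr$genes); t_ <- length(expr$timepoints)
  d <- matrix(res$d, G, t_, dimnames = list(expr$genes, expr$timepoints))
  cmp <- res$components
  dimnames(cmp$mean_d) <- dimnames(cmp$mean_c) <- dimnames(cmp$s) <- dimnames(d)
  names(cmp$s0) <- expr$timepoints
  structure(list(d = d, mean_d = cmp$mean_d, mean_c = cmp$mean_c,
                 s = cmp$s, s0 = cmp$s0,
                 genes = expr$genes, timepoints = expr$timepoints,
                 fudge_method = fudge_method, pooling = pooling),
            class = "sam_stat_matrix")
}

#' @export
print.sam_stat_matrix <- function(x, ...) {
  cat("sam_stat_matrix:", nrow(x$d), "genes x", ncol(x$d), "time points",
      sprintf("(pooling=%s, fudge=%s)\n", x$pooling, x$fudge_method))
  cat("  s0 per time point:", signif(x$s0, 4), "\n")
  invisible(x)
}

# features -> integer indices into the flattened (gene, time) grid.
# features: data.frame with columns gene, timepoint (or a 2-column matrix).
.cell_index <- function(genes, timepoints, features) {
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  gi <- match(as.character(features[[1L]]), genes)
  ti <- match(as.character(features[[2L]]), timepoints)
  if (anyNA(gi)) stop("unknown gene(s) in feature list: ",
                      paste(unique(features[[1L]][is.na(gi)]), collapse = ", "))
  if (anyNA(ti)) stop("unknown time point(s) in feature list: ",
                      paste(unique(features[[2L]][is.na(ti)]), collapse = ", "))
  gi + (ti - 1L) * length(genes)
}

#' All (gene, time point) cells of a set of genes
#'
#' Convenience constructor of a feature table covering every time point
#' of the given genes, the form the SAMGS statistic of a pathway uses.
#'
#' @param genes character vector.
#' @param timepoints character vector of time labels.
#' @return data frame with columns `gene`, `timepoint`.
#' @export
gene_cells <- function(genes, timepoints) {
  expand.grid(gene = genes, timepoint = timepoints,
              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
}

#' SAMGS statistic of a feature list
#'
#' The squared L2 norm of the SAM statistics over the listed
#' (gene, time point) cells: `sum of d_ij^2`.  For a pathway this runs
#' over all member genes and all time points; for a single gene's time
#' profile it runs over that gene's time points.
#'
#' @param sam a [sam_stat_matrix][compute_sam_statistics()].
#' @param features data frame (gene, timepoint); see [gene_cells()].
#' @return a non-negative scalar.
#' @export
samgs_statistic <- function(sam, features) {
  stopifnot(inherits(sam, "sam_stat_matrix"))
  if (NROW(features) == 0L)
    stop("the SAMGS statistic is undefined for an empty feature list")
  idx <- .cell_index(sam$genes, sam$timepoints, features)
  sum(sam$d[idx]^2)
}

# ---------------------------------------------------------------------------
# Permutation engine

#' Build the shared permutation distribution of SAM statistics
#'
#' Draws `B` subject-level permutations of the phenotype labels (all
#' time points of a subject move together, preserving within-subject
#' correlation), and recomputes the full SAM statistic matrix --
#' including the pooled SDs and the per-time fudge `s0` -- for each
#' permutation.  The result is one frozen permutation stream that all
#' set-level p-values of a run share, so results are mutually
#' comparable.
#'
#' @inheritParams compute_sam_statistics
#' @param B number of permutations (>= 1).
#' @param seed integer seed; identical seeds give identical streams.
#' @return an object of class `sam_perm_engine`: the observed
#'   `sam_stat_matrix`, the observed squared statistics `obs_sq`
#'   (flattened genes x time cells) and the permuted squared statistics
#'   `perm_sq` ((genes*timepoints) x B).
#' @export
sam_perm_engine <- function(expr, labels = NULL, B = 1000L, seed = 1L,
                            fudge_method = c("median", "fixed"),
                            fudge_const = 0.01,
                            pooling = c("within", "all")) {
  stopifnot(inherits(expr, "long_expr_set"))
  fudge_method <- match.arg(fudge_method); pooling <- match.arg(pooling)
  if (!is.numeric(B) || B < 1) stop("'B' must be a positive integer")
  B <- as.integer(B)
  sam <- compute_sam_statistics(expr, labels = labels,
                                fudge_method = fudge_method,
                                fudge_const = fudge_const, pooling = pooling)
  pos <- if (is.null(labels)) positive_class(expr) else {
    labels <- as.factor(labels); labels == levels(droplevels(labels))[2L]
  }
  n <- length(expr$subjects); nd <- sum(pos)
  P <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      z <- numeric(n); z[sample.int(n, nd)] <- 1; z
    }, numeric(n))
  })
  perm <- .sam_d_multi(expr, P, fudge_method, fudge_const, pooling)
  structure(list(sam = sam,
                 obs_sq = as.vector(sam$d)^2,
                 perm_sq = perm$d^2,
                 B = B, seed = seed,
                 genes = expr$genes, timepoints = expr$timepoints),
            class = "sam_perm_engine")
}

# permutation p-value of one feature index set against an engine
.perm_p <- function(engine, idx) {
  obs <- sum(engine$obs_sq[idx])
  perm <- .colsum_rows(engine$perm_sq, idx)
  (1 + sum(perm >= obs)) / (engine$B + 1)
}

# colSums over a subset of rows without forming the subset copy for the
# common single-row case
.colsum_rows <- function(m, idx) {
  if (length(idx) == 1L) m[idx, ] else colSums(m[idx, , drop = FALSE])
}

#' Permutation p-values (and q-values) for feature sets
#'
#' For every feature set the SAMGS statistic is compared with its
#' permutation distribution from one shared stream; `p = (1 + #{permuted
#' >= observed}) / (B + 1)` (add-one estimator, ties counted as
#' exceedances).  Benjamini-Hochberg q-values are attached.
#'
#' @inheritParams sam_perm_engine
#' @param feature_sets named list; each element a feature data frame
#'   (gene, timepoint) as accepted by [samgs_statistic()].
#' @param engine optionally a prebuilt [sam_perm_engine()] (then `B`,
#'   `seed`, `fudge_method`, `pooling` are ignored).
#' @return data frame with columns `set_name`, `statistic`, `p_value`,
#'   `q_value`.
#' @export
permutation_pvalues <- function(expr, labels = NULL, feature_sets,
                                B = 1000L, seed = 1L,
                                fudge_method = c("median", "fixed"),
                                fudge_const = 0.01,
                                pooling = c("within", "all"),
                                engine = NULL) {
  if (!length(feature_sets)) stop("'feature_sets' must be non-empty")
  if (any(vapply(feature_sets, NROW, integer(1)) == 0L))
    stop("every feature set must be non-empty")
  if (is.null(engine))
    engine <- sam_perm_engine(expr, labels = labels, B = B, seed = seed,
                              fudge_method = match.arg(fudge_method),
                              fudge_const = fudge_const,
                              pooling = match.arg(pooling))
  stopifnot(inherits(engine, "sam_perm_engine"))
  stat <- p <- numeric(length(feature_sets))
  for (k in seq_along(feature_sets)) {
    idx <- .cell_index(engine$genes, engine$timepoints, feature_sets[[k]])
    stat[[k]] <- sum(engine$obs_sq[idx])
    p[[k]] <- .perm_p(engine, idx)
  }
  data.frame(set_name = names(feature_sets) %||%
               paste0("set", seq_along(feature_sets)),
             statistic = stat, p_value = p, q_value = qvalues(p),
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg q-values
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return FDR-adjusted values, monotone in `p`, each in `(0, 1]`;
#'   empty input gives empty output.
#' @export
qvalues <- function(p_values) {
  if (!length(p_values)) return(numeric(0))
  if (any(p_values < 0 | p_values > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}
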