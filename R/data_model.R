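#' Construct a longitudinal expression set
#'
#' The central container of the package: a complete genes x subjects x
#' time points array of expression values plus a binary phenotype per
#' subject.  The design is complete-case by construction: every
#' (gene, subject, time point) cell must be present (no `NA`).
#'
#' @param values numeric 3-dimensional array with `dimnames` giving gene,
#'   subject and time-point labels, in that order.
#' @param phenotype factor (or coercible) of length `ncol(values)` giving
#'   the binary phenotype of each subject, named or in subject order.
#'   Must have exactly two levels, each with at least two subjects.  The
#'   *second* level is treated as the diseased / positive class
#'   throughout the package.
#'
#' @return An object of class `long_expr_set` with components `values`,
#'   `genes`, `subjects`, `timepoints` and `phenotype`.
#' @export
long_expr_set <- function(values, phenotype) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("'values' must be a 3-dimensional array (genes x subjects x timepoints)")
  dn <- dimnames(values)
  if (is.null(dn) || any(vapply(dn, is.null, logical(1))))
    stop("'values' must carry full dimnames (genes, subjects, timepoints)")
  if (anyNA(values))
    stop("expression values contain NA: the design must be complete-case")
  storage.mode(values) <- "double"
  phenotype <- as.factor(phenotype)
  if (!is.null(names(phenotype))) {
    if (!setequal(names(phenotype), dn[[2L]]))
      stop("phenotype names do not match the subjects of the expression array")
    phenotype <- phenotype[dn[[2L]]]
  } else if (length(phenotype) != length(dn[[2L]])) {
    stop("phenotype length does not match the number of subjects")
  }
  phenotype <- droplevels(phenotype)
  if (nlevels(phenotype) != 2L)
    stop("phenotype must have exactly two distinct values, got ",
         nlevels(phenotype))
  if (any(table(phenotype) < 2L))
    stop("each phenotype class needs at least 2 subjects")
  if (anyDuplicated(dn[[1L]])) stop("duplicate gene identifiers")
  if (anyDuplicated(dn[[2L]])) stop("duplicate subject identifiers")
  if (anyDuplicated(dn[[3L]])) stop("duplicate time-point labels")
  names(phenotype) <- dn[[2L]]
  structure(
    list(values = values,
         genes = dn[[1L]],
         subjects = dn[[2L]],
         timepoints = dn[[3L]],
         phenotype = phenotype),
    class = "long_expr_set")
}

#' @export
print.long_expr_set <- function(x, ...) {
  tab <- table(x$phenotype)
  cat("long_expr_set:", length(x$genes), "genes x",
      length(x$subjects), "subjects x", length(x$timepoints),
      "time points\n")
  cat("  phenotype:", paste(sprintf("%s=%d", names(tab), tab),
                            collapse = ", "),
      sprintf("(positive class: %s)\n", levels(x$phenotype)[2L]))
  cat("  time points:", paste(x$timepoints, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.long_expr_set <- function(x) dim(x$values)

#' Subset a longitudinal expression set by subjects
#'
#' Used by the cross-validation machinery to split folds.  Gene and
#' time-point structure is preserved.
#'
#' @param expr a [long_expr_set].
#' @param subjects character or integer index of subjects to keep.
#' @return a [long_expr_set] restricted to the given subjects.
#' @export
subset_subjects <- function(expr, subjects) {
  stopifnot(inherits(expr, "long_expr_set"))
  v <- expr$values[, subjects, , drop = FALSE]
  long_expr_set(v, expr$phenotype[colnames(v)])
}

#' Diseased-class indicator of an expression set
#'
#' @param expr a [long_expr_set].
#' @return logical vector per subject, `TRUE` for the positive (second)
#'   phenotype level.
#' @export
positive_class <- function(expr) {
  expr$phenotype == levels(expr$phenotype)[2L]
}

# ---------------------------------------------------------------------------
# Readers / writers

#' Read a gene-set collection from a GMT file
#'
#' One set per line, tab separated: name, description, member genes.
#' Duplicate members within one line are dropped with a warning;
#' membership of a gene in several sets is preserved.
#'
#' @param path path to a GMT file (MSigDB dialect, UTF-8).
#' @return an object of class `gene_set_collection`: a named list `sets`
#'   of character vectors plus the set descriptions.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  desc <- character()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L)
      stop(sprintf("malformed GMT line %d: expected at least 3 tab-separated fields, got %d",
                   i, length(fields)))
    members <- fields[-(1:2)]
    members <- members[nzchar(members)]
    if (anyDuplicated(members)) {
      warning(sprintf("duplicate member genes in set '%s' (GMT line %d); deduplicated",
                      fields[[1L]], i))
      members <- unique(members)
    }
    sets[[fields[[1L]]]] <- members
    desc[[fields[[1L]]]] <- fields[[2L]]
  }
  gene_set_collection(sets, descriptions = desc)
}

#' Construct a gene-set collection
#'
#' @param sets named list of character vectors of gene identifiers.
#' @param descriptions optional named character vector of descriptions.
#' @return an object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  if (length(sets) && is.null(names(sets)))
    stop("gene sets must be named")
  if (any(vapply(sets, anyDuplicated, integer(1)) > 0L))
    stop("duplicate gene within a set; deduplicate first (read_gmt does this)")
  structure(list(sets = sets,
                 descriptions = descriptions,
                 K = length(sets)),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("gene_set_collection with", x$K, "sets\n")
  if (x$K) {
    sz <- lengths(x$sets)
    cat("  set sizes:", min(sz), "-", max(sz),
        "(median", stats::median(sz), ")\n")
  }
  invisible(x)
}

#' @export
length.gene_set_collection <- function(x) x$K

#' Align a gene-set collection to the measured genes
#'
#' Intersects every set with the genes of an expression set (exact string
#' match) and drops sets that fall below `min_size`.  A summary of
#' dropped genes and sets is attached as the `"alignment"` attribute and
#' reported via `message()`.
#'
#' @param collection a [gene_set_collection].
#' @param expr a [long_expr_set].
#' @param min_size minimum retained set size (default 2).
#' @return the aligned [gene_set_collection]; idempotent.
#' @export
align_gene_sets <- function(collection, expr, min_size = 2L) {
  stopifnot(inherits(collection, "gene_set_collection"),
            inherits(expr, "long_expr_set"))
  measured <- expr$genes
  aligned <- lapply(collection$sets, function(g) g[g %in% measured])
  keep <- lengths(aligned) >= min_size
  dropped_genes <- sum(lengths(collection$sets)) - sum(lengths(aligned))
  if (!any(keep))
    stop("all gene sets dropped after alignment: the collection does not ",
         "match the measured genes (platform mismatch?)")
  if (dropped_genes > 0L || any(!keep))
    message(sprintf("align_gene_sets: dropped %d unmeasured member genes and %d sets below min_size=%d",
                    dropped_genes, sum(!keep), min_size))
  out <- gene_set_collection(aligned[keep],
                             descriptions = collection$descriptions[names(aligned)[keep]])
  attr(out, "alignment") <- list(dropped_sets = names(aligned)[!keep],
                                 dropped_gene_count = dropped_genes,
                                 min_size = min_size)
  out
}

#' Read a longitudinal expression matrix and phenotype file
#'
#' The expression file is a tab-delimited matrix: rows are genes (first
#' column gene identifier), columns are named `subject:timepoint`.  The
#' phenotype file is a two-column TSV (subject, label) with a header.
#' Time points are ordered by first appearance in the column names and
#' compared as ordered categorical tokens.
#'
#' @param path expression matrix TSV.
#' @param pheno_path phenotype TSV (columns subject, label).
#' @param incomplete policy for subjects missing one or more time points:
#'   `"drop"` (default, with warning) or `"error"`.
#' @return a [long_expr_set].
#' @export
read_expression <- function(path, pheno_path, incomplete = c("drop", "error")) {
  incomplete <- match.arg(incomplete)
  mat <- utils::read.delim(path, check.names = FALSE, row.names = 1L,
                           fileEncoding = "UTF-8")
  mat <- as.matrix(mat)
  ph <- utils::read.delim(pheno_path, check.names = FALSE,
                          fileEncoding = "UTF-8",
                          colClasses = "character")
  if (ncol(ph) < 2L)
    stop("phenotype file must have two columns: subject, label")
  pheno <- stats::setNames(ph[[2L]], ph[[1L]])
  if (length(unique(pheno)) > 2L)
    stop("phenotype file has ", length(unique(pheno)),
         " labels; exactly 2 expected")

  cn <- colnames(mat)
  # split at the LAST ':' so subject ids may themselves contain ':'
  m <- regexpr(":[^:]*$", cn)
  if (any(m < 0L))
    stop("expression columns must be named subject:timepoint")
  subj <- substr(cn, 1L, m - 1L)
  tp <- substr(cn, m + 1L, nchar(cn))
  timepoints <- unique(tp)
  subjects <- unique(subj)

  missing_ph <- setdiff(subjects, names(pheno))
  if (length(missing_ph))
    stop("subjects absent from the phenotype file: ",
         paste(missing_ph, collapse = ", "))

  have <- table(factor(subj, subjects), factor(tp, timepoints))
  if (any(have > 1L))
    stop("duplicated subject:timepoint columns in the expression matrix")
  complete <- rownames(have)[rowSums(have == 1L) == length(timepoints)]
  bad <- setdiff(subjects, complete)
  if (length(bad)) {
    if (incomplete == "error")
      stop("subjects with incomplete time series: ",
           paste(bad, collapse = ", "))
    warning("dropping ", length(bad),
            " subject(s) with incomplete time series: ",
            paste(bad, collapse = ", "))
    subjects <- complete
  }
  if (!length(subjects)) stop("no subject has a complete time series")

  arr <- array(NA_real_,
               dim = c(nrow(mat), length(subjects), length(timepoints)),
               dimnames = list(rownames(mat), subjects, timepoints))
  for (j in seq_along(timepoints)) {
    sel <- tp == timepoints[[j]] & subj %in% subjects
    arr[, subj[sel], j] <- mat[, sel]
  }
  long_expr_set(arr, pheno[subjects])
}

#' Write a longitudinal expression set to TSV files
#'
#' Inverse of [read_expression()]: values round-trip bit-exactly (written
#' with full precision).
#'
#' @param expr a [long_expr_set].
#' @param path output expression TSV.
#' @param pheno_path output phenotype TSV.
#' @return `invisible(NULL)`.
#' @export
write_expression <- function(expr, path, pheno_path) {
  stopifnot(inherits(expr, "long_expr_set"))
  flat <- do.call(cbind, lapply(seq_along(expr$timepoints), function(j) {
    m <- expr$values[, , j]
    colnames(m) <- paste0(expr$subjects, ":", expr$timepoints[[j]])
    m
  }))
  # interleave so all of a subject's time points sit together
  ord <- order(rep(seq_along(expr$subjects), times = length(expr$timepoints)))
  flat <- flat[, ord, drop = FALSE]
  df <- data.frame(gene = expr$genes, format(flat, digits = 17, trim = TRUE),
                   check.names = FALSE)
  colnames(df) <- c("gene", colnames(flat))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  utils::write.table(data.frame(subject = expr$subjects,
                                label = as.character(expr$phenotype)),
                     pheno_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(NULL)
}

# ---------------------------------------------------------------------------
# Signatures

#' Construct a feature signature
#'
#' A signature is the final product of every selector: a set of
#' (gene, time point) pairs plus the provenance of the selector that
#' produced it.
#'
#' @param gene,timepoint character vectors of equal length.
#' @param method provenance string (e.g. `"two_level"`).
#' @param expr optional [long_expr_set] to validate entries against.
#' @return an object of class `samgsr_signature`, a data frame with
#'   columns `gene`, `timepoint`, `method`.
#' @export
signature_set <- function(gene = character(), timepoint = character(),
                          method = "unspecified", expr = NULL) {
  gene <- as.character(gene); timepoint <- as.character(timepoint)
  stopifnot(length(gene) == length(timepoint))
  if (anyDuplicated(paste0(gene, "\r", timepoint)))
    stop("duplicate (gene, timepoint) pair in signature")
  if (!is.null(expr)) {
    stopifnot(inherits(expr, "long_expr_set"))
    if (!all(gene %in% expr$genes))
      stop("signature gene(s) not present in the expression set")
    if (!all(timepoint %in% expr$timepoints))
      stop("signature time point(s) not present in the expression set")
  }
  out <- data.frame(gene = gene, timepoint = timepoint,
                    method = if (length(gene)) method else character(),
                    stringsAsFactors = FALSE)
  class(out) <- c("samgsr_signature", "data.frame")
  attr(out, "provenance") <- method
  out
}

#' Number of distinct genes in a signature
#' @param sig a `samgsr_signature`.
#' @return integer count of unique genes.
#' @export
unique_genes <- function(sig) length(unique(sig$gene))

#' @export
print.samgsr_signature <- function(x, ...) {
  cat(sprintf("samgsr_signature [%s]: %d (gene, time) pairs, %d unique genes\n",
              attr(x, "provenance") %||% "unspecified",
              nrow(x), unique_genes(x)))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat("  ...", nrow(x) - 10L, "more rows\n")
  invisible(x)
}

#' Write a signature to TSV
#' @param sig a `samgsr_signature`.
#' @param path output path.
#' @return `invisible(NULL)`.
#' @export
write_signature <- function(sig, path) {
  utils::write.table(as.data.frame(sig), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
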