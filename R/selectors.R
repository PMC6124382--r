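# End-to-end feature selection: the SAMGS screen plus the reduction step
# wired into three algorithms -- two-level, longitudinal, per-time-point.

#' SAMGS screening of a gene-set collection
#'
#' Computes the SAMGS statistic of every set over all of its member
#' (gene x time point) cells, permutation p-values from one shared
#' stream, Benjamini-Hochberg q-values, and returns the names of the
#' sets with `q <= q_cutoff`.
#'
#' @inheritParams sam_perm_engine
#' @param collection an aligned [gene_set_collection] (see
#'   [align_gene_sets()]).
#' @param q_cutoff q-value threshold (default 0.05).
#' @param engine optional prebuilt [sam_perm_engine()].
#' @return character vector of significant set names; the full result
#'   table (set, statistic, p, q) is attached as attribute `"table"`.
#' @export
samgs_select <- function(expr, labels = NULL, collection,
                         q_cutoff = 0.05, B = 1000L, seed = 1L,
                         fudge_method = c("median", "fixed"),
                         fudge_const = 0.01,
                         pooling = c("within", "all"),
                         engine = NULL) {
  stopifnot(inherits(collection, "gene_set_collection"))
  if (!collection$K) stop("empty gene-set collection")
  if (is.null(engine))
    engine <- sam_perm_engine(expr, labels = labels, B = B, seed = seed,
                              fudge_method = match.arg(fudge_method),
                              fudge_const = fudge_const,
                              pooling = match.arg(pooling))
  feature_sets <- lapply(collection$sets, gene_cells,
                         timepoints = engine$timepoints)
  tab <- permutation_pvalues(expr, feature_sets = feature_sets,
                             engine = engine)
  out <- tab$set_name[tab$q_value <= q_cutoff]
  attr(out, "table") <- tab
  out
}

# time-point reduction of one gene's profile; t = 1 short-circuits to
# "keep the gene at its only time point" without testing
.reduce_timepoints <- function(gene, engine, c_cutoff) {
  tps <- engine$timepoints
  if (length(tps) == 1L)
    return(data.frame(gene = gene, timepoint = tps,
                      stringsAsFactors = FALSE))
  res <- reduce_set(features = gene_cells(gene, tps),
                    cutoff = c_cutoff, level = "timepoint",
                    engine = engine)
  res$core
}

#' Two-level SAMGSR feature selection
#'
#' The reduction step is applied in an ordered manner at two levels.
#' Level 1 (genes within pathways): the SAMGS screen keeps significant
#' sets, and each is reduced to its core gene subset.  Level 2 (time
#' points within genes): on the union of core genes, each gene's
#' expression profile over time is treated as a gene set of its own and
#' reduced to the time points where the phenotypes actually differ.
#' A gene that belongs to several significant sets enters the union
#' once; no additional per-gene significance screen is applied between
#' the levels.
#'
#' @inheritParams samgs_select
#' @param c_cutoff reduction cutoff for `c_k`, in (0, 1) (default 0.2).
#' @return a [signature_set()] of (gene, time point) pairs; empty, with
#'   a warning, when no gene set passes the screen.
#' @export
two_level_select <- function(expr, labels = NULL, collection,
                             q_cutoff = 0.05, c_cutoff = 0.2,
                             B = 1000L, seed = 1L,
                             fudge_method = c("median", "fixed"),
                             fudge_const = 0.01,
                             pooling = c("within", "all"),
                             engine = NULL) {
  if (is.null(engine))
    engine <- sam_perm_engine(expr, labels = labels, B = B, seed = seed,
                              fudge_method = match.arg(fudge_method),
                              fudge_const = fudge_const,
                              pooling = match.arg(pooling))
  sig_sets <- samgs_select(expr, collection = collection,
                           q_cutoff = q_cutoff, engine = engine)
  if (!length(sig_sets)) {
    warning("no gene set significant at q <= ", q_cutoff,
            "; returning an empty signature")
    return(signature_set(method = "two_level", expr = expr))
  }
  cores <- lapply(sig_sets, function(s)
    reduce_set(features = collection$sets[[s]], cutoff = c_cutoff,
               level = "gene", engine = engine)$core)
  union_genes <- unique(unlist(cores, use.names = FALSE))
  entries <- do.call(rbind, lapply(union_genes, .reduce_timepoints,
                                   engine = engine, c_cutoff = c_cutoff))
  out <- signature_set(entries$gene, entries$timepoint,
                       method = "two_level", expr = expr)
  attr(out, "significant_sets") <- sig_sets
  attr(out, "level1_union") <- union_genes
  out
}

#' Longitudinal SAMGSR feature selection
#'
#' The pathway-free comparator: every gene's time profile is its own
#' gene set.  The SAMGS screen (with Benjamini-Hochberg q-values over
#' genes) keeps the relevant genes, and the reduction step then
#' determines the exact time point(s) at which each kept gene separates
#' the phenotypes.
#'
#' @inheritParams two_level_select
#' @return a [signature_set()] of (gene, time point) pairs.
#' @export
longitudinal_select <- function(expr, labels = NULL,
                                q_cutoff = 0.05, c_cutoff = 0.2,
                                B = 1000L, seed = 1L,
                                fudge_method = c("median", "fixed"),
                                fudge_const = 0.01,
                                pooling = c("within", "all"),
                                engine = NULL) {
  if (is.null(engine))
    engine <- sam_perm_engine(expr, labels = labels, B = B, seed = seed,
                              fudge_method = match.arg(fudge_method),
                              fudge_const = fudge_const,
                              pooling = match.arg(pooling))
  per_gene <- gene_set_collection(stats::setNames(as.list(engine$genes),
                                                  engine$genes))
  sig_genes <- samgs_select(expr, collection = per_gene,
                            q_cutoff = q_cutoff, engine = engine)
  if (!length(sig_genes))
    return(signature_set(method = "longitudinal", expr = expr))
  entries <- do.call(rbind, lapply(sig_genes, .reduce_timepoints,
                                   engine = engine, c_cutoff = c_cutoff))
  out <- signature_set(entries$gene, entries$timepoint,
                       method = "longitudinal", expr = expr)
  attr(out, "significant_genes") <- as.character(sig_genes)
  out
}

#' Per-time-point SAMGSR feature selection
#'
#' The naive stratified comparator: classical single-time-point SAMGSR
#' is run independently on each time-point slice (SAMGS screen over the
#' collection using only that time point's statistics, then gene-level
#' reduction of each significant set), and the signatures are united,
#' tagged by time point.  Within-subject correlation across time is
#' ignored by construction.
#'
#' @inheritParams two_level_select
#' @return a [signature_set()] of (gene, time point) pairs.
#' @export
per_timepoint_select <- function(expr, labels = NULL, collection,
                                 q_cutoff = 0.05, c_cutoff = 0.2,
                                 B = 1000L, seed = 1L,
                                 fudge_method = c("median", "fixed"),
                                 fudge_const = 0.01,
                                 pooling = c("within", "all"),
                                 engine = NULL) {
  stopifnot(inherits(collection, "gene_set_collection"))
  if (!collection$K) stop("empty gene-set collection")
  if (is.null(engine))
    engine <- sam_perm_engine(expr, labels = labels, B = B, seed = seed,
                              fudge_method = match.arg(fudge_method),
                              fudge_const = fudge_const,
                              pooling = match.arg(pooling))
  entries <- list()
  for (tj in engine$timepoints) {
    slice_sets <- lapply(collection$sets, gene_cells, timepoints = tj)
    tab <- permutation_pvalues(expr, feature_sets = slice_sets,
                               engine = engine)
    sig <- tab$set_name[tab$q_value <= q_cutoff]
    if (!length(sig)) next
    genes_tj <- unique(unlist(lapply(sig, function(s)
      reduce_set(features = gene_cells(collection$sets[[s]], tj),
                 cutoff = c_cutoff, level = "timepoint",
                 engine = engine)$core$gene), use.names = FALSE))
    entries[[tj]] <- data.frame(gene = genes_tj, timepoint = tj,
                                stringsAsFactors = FALSE)
  }
  entries <- do.call(rbind, entries)
  if (is.null(entries))
    return(signature_set(method = "per_timepoint", expr = expr))
  signature_set(entries$gene, entries$timepoint,
                method = "per_timepoint", expr = expr)
}

#' Run a selector by name
#'
#' Dispatch helper used by the CLI and the cross-validation tuner.
#'
#' @inheritParams two_level_select
#' @param method `"two_level"`, `"longitudinal"` or `"per_timepoint"`.
#' @param collection required except for `"longitudinal"`.
#' @return a [signature_set()].
#' @export
select_features <- function(expr, method = c("two_level", "longitudinal",
                                             "per_timepoint"),
                            collection = NULL, labels = NULL,
                            q_cutoff = 0.05, c_cutoff = 0.2,
                            B = 1000L, seed = 1L, ...) {
  method <- match.arg(method)
  if (method != "longitudinal" && is.null(collection))
    stop("method '", method, "' requires a gene-set collection")
  switch(method,
    two_level = two_level_select(expr, labels, collection, q_cutoff,
                                 c_cutoff, B, seed, ...),
    longitudinal = longitudinal_select(expr, labels, q_cutoff, c_cutoff,
                                       B, seed, ...),
    per_timepoint = per_timepoint_select(expr, labels, collection,
                                         q_cutoff, c_cutoff, B, seed, ...))
}
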