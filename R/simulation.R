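# Self-contained benchmark: a synthetic longitudinal two-class design
# with within-subject temporal correlation and gene-gene correlation
# blocks, phenotypes drawn from a logistic model on a few causal
# (gene, time point) cells, and a replicate runner that aggregates
# causal-gene recovery frequencies.

#' Simulation configuration
#'
#' `design = "sim1"` plants one gene with moderate coordinated effects
#' at four consecutive time points (coefficients 0.18, 0.57, 0.29, 0.41
#' at times 1-4) plus one gene with a single large effect (1.02 at time
#' 3).  `design = "sim2"` plants two single-time effects of opposite
#' sign (0.56 at time 1, -0.91 at time 5).  `design = "custom"` takes
#' `logit_terms` directly.
#'
#' @param design `"sim1"`, `"sim2"` or `"custom"`.
#' @param n_genes total genes including the causal ones (default 1000,
#'   i.e. 998 noise genes in the two-causal-gene designs).
#' @param n_subjects subjects per replicate (default 43, mirroring a
#'   25 + 18 two-class training cohort).
#' @param n_timepoints shared time points per subject (default 5).
#' @param replicates number of replicates (default 50).
#' @param rho_time lag-1 autocorrelation of the AR(1) within-subject
#'   time process (default 0.6).
#' @param rho_gene within-block exchangeable gene-gene correlation
#'   (default 0.3).
#' @param block_size genes per correlation block (default 20); blocks
#'   double as the simulated gene-set collection.
#' @param effect_multiplier scales every logit coefficient (default 1).
#' @param logit_terms for `design = "custom"`: data frame with columns
#'   `gene`, `timepoint`, `coef`.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(design = c("sim1", "sim2", "custom"),
                       n_genes = 1000L, n_subjects = 43L,
                       n_timepoints = 5L, replicates = 50L,
                       rho_time = 0.6, rho_gene = 0.3,
                       block_size = 20L, effect_multiplier = 1,
                       logit_terms = NULL) {
  design <- match.arg(design)
  stopifnot(n_genes >= 2L, n_subjects >= 4L, n_timepoints >= 1L,
            abs(rho_time) < 1, rho_gene >= 0, rho_gene < 1,
            block_size >= 1L)
  tp <- paste0("T", seq_len(n_timepoints))
  terms <- switch(design,
    sim1 = data.frame(
      gene = c(rep("F13A1", 4L), "GSTM1"),
      timepoint = c("T1", "T2", "T3", "T4", "T3"),
      coef = c(0.18, 0.57, 0.29, 0.41, 1.02),
      stringsAsFactors = FALSE),
    sim2 = data.frame(
      gene = c("COX4I2", "RP9"),
      timepoint = c("T1", "T5"),
      coef = c(0.56, -0.91),
      stringsAsFactors = FALSE),
    custom = {
      if (is.null(logit_terms))
        stop("design = 'custom' requires 'logit_terms'")
      logit_terms
    })
  if (!all(terms$timepoint %in% tp))
    stop("logit terms reference time points outside T1..T", n_timepoints)
  terms$coef <- terms$coef * effect_multiplier
  causal <- unique(terms$gene)
  if (length(causal) > n_genes)
    stop("more causal genes than n_genes")
  # causal genes anchor distinct correlation blocks (first slot of
  # blocks 1, 2, ...); remaining genes are numbered noise
  genes <- sprintf("NOISE%04d", seq_len(n_genes))
  slot <- (seq_along(causal) - 1L) * block_size + 1L
  if (any(slot > n_genes)) slot <- seq_along(causal)  # tiny configs
  genes[slot] <- causal
  if (anyDuplicated(genes))
    stop("causal gene names collide with the NOISE#### noise gene names")
  structure(list(design = design, n_genes = as.integer(n_genes),
                 n_subjects = as.integer(n_subjects),
                 timepoints = tp, replicates = as.integer(replicates),
                 rho_time = rho_time, rho_gene = rho_gene,
                 block_size = as.integer(block_size),
                 logit_terms = terms, genes = genes,
                 causal_genes = causal),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("sim_config [%s]: %d genes x %d subjects x %d time points, %d replicates\n",
              x$design, x$n_genes, x$n_subjects, length(x$timepoints),
              x$replicates))
  cat(sprintf("  rho_time=%.2f rho_gene=%.2f block_size=%d\n",
              x$rho_time, x$rho_gene, x$block_size))
  cat("  logit terms:\n")
  print(x$logit_terms)
  invisible(x)
}

#' Gene-set collection implied by a simulation configuration
#'
#' The correlation blocks double as pathways, so the pathway structure
#' available to the two-level selector is aligned with the correlation
#' structure of the data.
#'
#' @param config a [sim_config()].
#' @return a [gene_set_collection] with one set per block.
#' @export
sim_gene_sets <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  block <- (seq_len(config$n_genes) - 1L) %/% config$block_size + 1L
  sets <- split(config$genes, sprintf("BLOCK%03d", block))
  gene_set_collection(sets)
}

#' Synthetic longitudinal expression backbone
#'
#' Synthetic mode draws, for each subject, a zero-mean unit-variance
#' Gaussian genes x time matrix with separable correlation: AR(1) with
#' parameter `rho_time` across the time points and exchangeable
#' correlation `rho_gene` within consecutive blocks of `block_size`
#' genes (independent between blocks), realised through a shared
#' per-block AR(1) factor.  Values are then standardized per
#' (gene, time point) across subjects.  Provided mode resamples
#' subjects with replacement from a user matrix and draws the noise
#' genes at random, mirroring the construction on a real backbone.
#'
#' @param config a [sim_config()].
#' @param seed integer seed; fixed seed gives a bitwise-reproducible
#'   backbone.
#' @param provided optional genes x subjects x timepoints array to
#'   resample from instead of the synthetic generator; must contain the
#'   causal genes.
#' @return unlabeled expression array genes x subjects x timepoints
#'   with full dimnames.
#' @export
make_backbone <- function(config, seed = 1L, provided = NULL) {
  stopifnot(inherits(config, "sim_config"))
  G <- config$n_genes; n <- config$n_subjects
  t_ <- length(config$timepoints)
  subjects <- sprintf("S%03d", seq_len(n))
  if (!is.null(provided)) {
    stopifnot(is.array(provided), length(dim(provided)) == 3L)
    if (!all(config$causal_genes %in% dimnames(provided)[[1L]]))
      stop("provided backbone lacks causal gene(s): ",
           paste(setdiff(config$causal_genes, dimnames(provided)[[1L]]),
                 collapse = ", "))
    if (dim(provided)[[3L]] < t_)
      stop("provided backbone has fewer time points than configured")
    arr <- with_seed(seed, {
      noise_pool <- setdiff(dimnames(provided)[[1L]], config$causal_genes)
      noise <- sample(noise_pool, G - length(config$causal_genes))
      subj <- sample(dim(provided)[[2L]], n, replace = TRUE)
      provided[c(config$causal_genes, noise), subj, seq_len(t_), drop = FALSE]
    })
    dimnames(arr) <- list(dimnames(arr)[[1L]], subjects,
                          config$timepoints)
  } else {
    nb <- ceiling(G / config$block_size)
    block <- (seq_len(G) - 1L) %/% config$block_size + 1L
    rt <- config$rho_time; rg <- config$rho_gene
    arr <- with_seed(seed, {
      # AR(1) innovations for n*(G + nb) independent rows at once
      rows <- n * (G + nb)
      x <- matrix(stats::rnorm(rows * t_), rows, t_)
      if (t_ > 1L) for (j in 2L:t_)
        x[, j] <- rt * x[, j - 1L] + sqrt(1 - rt^2) * x[, j]
      out <- array(NA_real_, c(G, n, t_))
      for (s in seq_len(n)) {
        off <- (s - 1L) * (G + nb)
        E <- x[off + seq_len(G), , drop = FALSE]
        F_ <- x[off + G + seq_len(nb), , drop = FALSE]
        out[, s, ] <- sqrt(rg) * F_[block, , drop = FALSE] +
          sqrt(1 - rg) * E
      }
      out
    })
    dimnames(arr) <- list(config$genes, subjects, config$timepoints)
  }
  # standardize per (gene, time point) across subjects
  for (j in seq_len(t_)) {
    m <- arr[, , j, drop = TRUE]
    mu <- rowMeans(m)
    sdv <- sqrt(rowSums((m - mu)^2) / (n - 1))
    sdv[sdv == 0] <- 1
    arr[, , j] <- (m - mu) / sdv
  }
  arr
}

#' Draw phenotype labels from the logistic outcome model
#'
#' For each subject the linear predictor is the sum of
#' `coef * X[gene, subject, timepoint]` over the configured logit
#' terms; the label is Bernoulli with probability
#' `1 / (1 + exp(-eta))`.  With all covariates zero the probability of
#' the complicated class is exactly 0.5.
#'
#' @param backbone array from [make_backbone()].
#' @param logit_terms data frame (gene, timepoint, coef).
#' @param seed integer seed.
#' @return factor per subject, levels
#'   `c("uncomplicated", "complicated")` (second = diseased/positive),
#'   with the linear predictors attached as attribute `"eta"`.
#' @export
simulate_outcome <- function(backbone, logit_terms, seed = 1L) {
  dn <- dimnames(backbone)
  gi <- match(logit_terms$gene, dn[[1L]])
  ti <- match(logit_terms$timepoint, dn[[3L]])
  if (anyNA(gi) || anyNA(ti))
    stop("logit terms reference cells absent from the backbone")
  eta <- rep(0, dim(backbone)[[2L]])
  for (k in seq_len(nrow(logit_terms)))
    eta <- eta + logit_terms$coef[[k]] * backbone[gi[[k]], , ti[[k]]]
  pr <- 1 / (1 + exp(-eta))
  lab <- with_seed(seed, stats::rbinom(length(pr), 1L, pr))
  out <- factor(ifelse(lab == 1L, "complicated", "uncomplicated"),
                levels = c("uncomplicated", "complicated"))
  names(out) <- dn[[2L]]
  attr(out, "eta") <- stats::setNames(eta, dn[[2L]])
  out
}

#' Run the simulation benchmark over replicates
#'
#' Per replicate: a fresh backbone and outcome are drawn (replicates
#' whose outcome leaves a class with fewer than 2 subjects are redrawn
#' with a sub-seed and logged), the requested selectors are run, and
#' per-time-point selection counts are accumulated.  Aggregates are the
#' average number of genes selected per time point, the per-time-point
#' selection frequency of each causal gene, and the average number of
#' unique genes per signature.
#'
#' @param config a [sim_config()].
#' @param methods selectors to run (subset of `"longitudinal"`,
#'   `"two_level"`, `"per_timepoint"`).
#' @param q_cutoff,c_cutoff,B selector settings (see
#'   [two_level_select()]).
#' @param seed master seed; each replicate derives sub-seeds.
#' @param collection gene-set collection for the pathway-aware
#'   selectors; default [sim_gene_sets()] of `config`.
#' @param provided optional real backbone array (see
#'   [make_backbone()]).
#' @return an object of class `replicate_outcome`: aggregate frequency
#'   table, average unique-gene counts, per-replicate signatures, and
#'   the redraw log.
#' @export
run_replicates <- function(config,
                           methods = c("longitudinal", "two_level"),
                           q_cutoff = 0.05, c_cutoff = 0.2,
                           B = 1000L, seed = 1L,
                           collection = NULL, provided = NULL) {
  stopifnot(inherits(config, "sim_config"))
  methods <- match.arg(methods, c("longitudinal", "two_level",
                                  "per_timepoint"), several.ok = TRUE)
  if (is.null(collection) && any(methods != "longitudinal"))
    collection <- sim_gene_sets(config)
  tp <- config$timepoints
  causal <- config$causal_genes
  sigs <- stats::setNames(vector("list", length(methods)), methods)
  for (m in methods) sigs[[m]] <- vector("list", config$replicates)
  redraws <- 0L
  for (r in seq_len(config$replicates)) {
    rseed <- sub_seed(seed, paste0("rep", r))
    expr <- NULL
    for (attempt in seq_len(20L)) {
      bb <- make_backbone(config,
                          seed = sub_seed(rseed, paste0("bb", attempt)),
                          provided = provided)
      lab <- simulate_outcome(bb, config$logit_terms,
                              seed = sub_seed(rseed, paste0("y", attempt)))
      if (all(table(lab) >= 2L)) {
        expr <- long_expr_set(bb, lab)
        break
      }
      redraws <- redraws + 1L
    }
    if (is.null(expr))
      stop("replicate ", r, ": could not draw a two-class outcome in 20 attempts")
    engine <- sam_perm_engine(expr, B = B,
                              seed = sub_seed(rseed, "perm"))
    for (m in methods)
      sigs[[m]][[r]] <- suppressWarnings(
        select_features(expr, method = m, collection = collection,
                        q_cutoff = q_cutoff, c_cutoff = c_cutoff,
                        engine = engine))
  }
  # aggregate
  freq <- do.call(rbind, lapply(methods, function(m) {
    per_tp <- vapply(tp, function(tj)
      mean(vapply(sigs[[m]], function(s) sum(s$timepoint == tj),
                  numeric(1))), numeric(1))
    rows <- data.frame(method = m, quantity = "n_genes",
                       t(per_tp), check.names = FALSE,
                       stringsAsFactors = FALSE)
    for (cg in causal) {
      hit <- vapply(tp, function(tj)
        100 * mean(vapply(sigs[[m]], function(s)
          any(s$gene == cg & s$timepoint == tj), logical(1))),
        numeric(1))
      rows <- rbind(rows, data.frame(method = m, quantity = cg, t(hit),
                                     check.names = FALSE,
                                     stringsAsFactors = FALSE))
    }
    rows
  }))
  colnames(freq) <- c("method", "quantity", tp)
  avg_unique <- vapply(methods, function(m)
    mean(vapply(sigs[[m]], unique_genes, numeric(1))), numeric(1))
  structure(list(frequency = freq,
                 avg_unique_genes = avg_unique,
                 signatures = sigs,
                 redraws = redraws,
                 config = config),
            class = "replicate_outcome")
}

#' @export
print.replicate_outcome <- function(x, ...) {
  cat(sprintf("replicate_outcome [%s]: %d replicates (%d redraws)\n",
              x$config$design, x$config$replicates, x$redraws))
  cat("  average unique genes:",
      paste(sprintf("%s=%.2f", names(x$avg_unique_genes),
                    x$avg_unique_genes), collapse = ", "), "\n")
  print(x$frequency, row.names = FALSE)
  invisible(x)
}

#' Write the aggregate frequency table to TSV
#'
#' One row per (method, quantity): average per-time-point gene counts
#' and causal-gene selection percentages, the shape of the benchmark's
#' summary tables.
#'
#' @param outcome a [run_replicates()] result.
#' @param path output TSV path.
#' @return `invisible(NULL)`.
#' @export
write_outcome_table <- function(outcome, path) {
  stopifnot(inherits(outcome, "replicate_outcome"))
  tab <- outcome$frequency
  extra <- data.frame(method = names(outcome$avg_unique_genes),
                      quantity = "avg_unique_genes",
                      stringsAsFactors = FALSE)
  for (cn in colnames(tab)[-(1:2)]) extra[[cn]] <- NA_real_
  extra[[colnames(tab)[[3L]]]] <- unname(outcome$avg_unique_genes)
  utils::write.table(rbind(tab, extra), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(NULL)
}
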