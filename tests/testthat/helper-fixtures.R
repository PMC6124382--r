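# Fixture builders and independent oracles shared by the suite.
# Oracles are written as plain loops over the defining formulas and are
# kept independent of the package's vectorized code paths.

# Two-class longitudinal toy set.  'signal' is a data frame
# (gene, timepoint, delta): delta is added to the diseased group at
# that cell.  Genes are g1..gG, subjects d1.. / c1.., times T1..Tt.
make_toy_expr <- function(G = 6, n_d = 3, n_c = 3, t = 2, seed = 1,
                          signal = NULL, constant = FALSE) {
  subjects <- c(paste0("d", seq_len(n_d)), paste0("c", seq_len(n_c)))
  genes <- paste0("g", seq_len(G))
  tps <- paste0("T", seq_len(t))
  arr <- withr::with_seed(seed, {
    if (constant) array(1, c(G, n_d + n_c, t))
    else array(rnorm(G * (n_d + n_c) * t), c(G, n_d + n_c, t))
  })
  dimnames(arr) <- list(genes, subjects, tps)
  if (!is.null(signal))
    for (k in seq_len(nrow(signal)))
      arr[signal$gene[[k]], seq_len(n_d), signal$timepoint[[k]]] <-
        arr[signal$gene[[k]], seq_len(n_d), signal$timepoint[[k]]] +
        signal$delta[[k]]
  pheno <- factor(rep(c("case", "ctrl"), c(n_d, n_c)),
                  levels = c("ctrl", "case"))   # case = positive (2nd)
  long_expr_set(arr, pheno)
}

# --- oracle: SAM statistic matrix by plain loops -------------------------
# pos: logical per subject (TRUE = diseased).  Median fudge, within-class
# pooling, both recomputed from scratch for the given labels.
oracle_d_matrix <- function(expr, pos) {
  v <- expr$values
  G <- length(expr$genes); t_ <- length(expr$timepoints)
  nd <- sum(pos); nc <- sum(!pos)
  d <- matrix(NA_real_, G, t_, dimnames = list(expr$genes, expr$timepoints))
  for (j in seq_len(t_)) {
    s <- numeric(G); num <- numeric(G)
    for (i in seq_len(G)) {
      xd <- v[i, pos, j]; xc <- v[i, !pos, j]
      num[i] <- mean(xd) - mean(xc)
      ssd <- sum((xd - mean(xd))^2); ssc <- sum((xc - mean(xc))^2)
      s[i] <- sqrt(((1 / nd + 1 / nc) / (nd + nc - 2)) * (ssd + ssc))
    }
    s0 <- stats::median(s)
    if (s0 <= 0) s0 <- .Machine$double.eps
    d[, j] <- num / (s + s0)
  }
  d
}

# --- oracle: exhaustive permutation p-values -----------------------------
# Enumerates every assignment of nd subjects to the diseased class and
# recomputes the full statistic (including the fudge) for each.
# feature_sets: list of data.frames (gene, timepoint).
# p = #{assignments with stat >= observed} / #assignments.
oracle_exhaustive_p <- function(expr, feature_sets) {
  n <- length(expr$subjects)
  pos_obs <- positive_class(expr)
  nd <- sum(pos_obs)
  idx <- utils::combn(n, nd)
  set_stat <- function(d, fs) {
    tot <- 0
    for (k in seq_len(nrow(fs)))
      tot <- tot + d[fs$gene[[k]], fs$timepoint[[k]]]^2
    tot
  }
  obs_d <- oracle_d_matrix(expr, pos_obs)
  obs <- vapply(feature_sets, function(fs) set_stat(obs_d, fs), numeric(1))
  counts <- numeric(length(feature_sets))
  for (a in seq_len(ncol(idx))) {
    pos <- rep(FALSE, n); pos[idx[, a]] <- TRUE
    d <- oracle_d_matrix(expr, pos)
    for (k in seq_along(feature_sets))
      counts[k] <- counts[k] + (set_stat(d, feature_sets[[k]]) >= obs[k])
  }
  counts / ncol(idx)
}

# --- oracle: metrics by direct formula loops -----------------------------
oracle_metrics <- function(p, truth) {
  n <- length(p)
  err <- 0; gbs <- 0; bcm <- 0
  for (i in seq_len(n)) {
    pred_pos <- p[i] >= 0.5
    err <- err + (pred_pos != truth[i])
    gbs <- gbs + (p[i] - as.numeric(truth[i]))^2 +
      ((1 - p[i]) - as.numeric(!truth[i]))^2
    bcm <- bcm + if (truth[i]) p[i] else 1 - p[i]
  }
  # PR curve: sweep thresholds through distinct posteriors, descending
  thr <- sort(unique(p), decreasing = TRUE)
  rec <- prec <- numeric(length(thr))
  for (k in seq_along(thr)) {
    called <- p >= thr[k]
    prec[k] <- sum(called & truth) / sum(called)
    rec[k] <- sum(called & truth) / sum(truth)
  }
  rec <- c(0, rec); prec <- c(prec[1], prec)
  aupr <- 0
  for (k in seq_len(length(rec) - 1))
    aupr <- aupr + (rec[k + 1] - rec[k]) * (prec[k + 1] + prec[k]) / 2
  list(error = err / n, gbs = gbs / (2 * n), bcm = bcm / n, aupr = aupr)
}

# write a tiny expression + phenotype fixture pair to a temp dir;
# returns the two paths
write_toy_files <- function(expr, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  ep <- file.path(dir, "expr.tsv"); pp <- file.path(dir, "pheno.tsv")
  write_expression(expr, ep, pp)
  list(expr = ep, pheno = pp, dir = dir)
}
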