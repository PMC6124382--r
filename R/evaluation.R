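# Classifier-based evaluation of signatures: per-time-point posterior
# probabilities, posterior averaging across time, the four performance
# metrics, and cross-validated tuning of the reduction cutoff.

#' Ridge-penalized logistic classifier (package default)
#'
#' The selectors do not estimate coefficients for the selected features;
#' a probabilistic classifier is fitted afterwards.  Any object with
#' `fit(x, y)` / `predict(model, x)` semantics returning posterior
#' probabilities of the positive class can be plugged into
#' [fit_posteriors()]; the default is L2-regularized logistic regression
#' (a calibrated linear decision boundary), which remains well defined
#' when the number of selected genes exceeds the number of subjects.
#'
#' @param lambda ridge penalty (fixed, for determinism; default 0.1).
#' @return a classifier object (list with `fit` and `predict`).
#' @export
ridge_logistic_classifier <- function(lambda = 0.1) {
  list(
    fit = function(x, y) {
      # y: logical, TRUE = positive class
      if (ncol(x) >= 2L) {
        glmnet::glmnet(x, factor(y, c(FALSE, TRUE)), family = "binomial",
                       alpha = 0, lambda = lambda, standardize = TRUE)
      } else {
        # glmnet needs >= 2 columns; pad with a zero column
        xx <- cbind(x, `.pad` = 0)
        structure(glmnet::glmnet(xx, factor(y, c(FALSE, TRUE)),
                                 family = "binomial", alpha = 0,
                                 lambda = lambda, standardize = TRUE),
                  padded = TRUE)
      }
    },
    predict = function(model, x) {
      if (isTRUE(attr(model, "padded"))) x <- cbind(x, `.pad` = 0)
      as.vector(stats::predict(model, newx = x, type = "response"))
    })
}

#' Posterior probabilities per subject and time point
#'
#' Fits one classifier per time point on the training subjects, using
#' only that time point's selected features, and returns the posterior
#' probability of the positive (diseased) class for every test subject
#' at every time point.  A time point with no selected features yields
#' uninformative posteriors of 0.5 with a warning.
#'
#' @param train a [long_expr_set] used for fitting.
#' @param sig a [signature_set()] restricting the features.
#' @param test a [long_expr_set] to predict on; defaults to `train`.
#'   Must share genes and time points with `train`.
#' @param classifier a fit/predict pair; default
#'   [ridge_logistic_classifier()].
#' @return numeric matrix, test subjects x time points, entries in
#'   `[0, 1]`.
#' @export
fit_posteriors <- function(train, sig, test = NULL,
                           classifier = ridge_logistic_classifier()) {
  stopifnot(inherits(train, "long_expr_set"))
  if (is.null(test)) test <- train
  stopifnot(inherits(test, "long_expr_set"))
  if (!identical(train$timepoints, test$timepoints))
    stop("train and test must share the same time points")
  y <- positive_class(train)
  post <- matrix(NA_real_,
                 nrow = length(test$subjects),
                 ncol = length(train$timepoints),
                 dimnames = list(test$subjects, train$timepoints))
  for (j in seq_along(train$timepoints)) {
    tj <- train$timepoints[[j]]
    genes <- unique(sig$gene[sig$timepoint == tj])
    if (!length(genes)) {
      warning("no selected features at time point '", tj,
              "'; posteriors set to 0.5")
      post[, j] <- 0.5
      next
    }
    xtr <- t(train$values[genes, , j, drop = TRUE])
    xte <- t(test$values[genes, , j, drop = TRUE])
    if (length(genes) == 1L) {       # drop = TRUE collapsed to a vector
      xtr <- matrix(train$values[genes, , j], ncol = 1L,
                    dimnames = list(train$subjects, genes))
      xte <- matrix(test$values[genes, , j], ncol = 1L,
                    dimnames = list(test$subjects, genes))
    }
    model <- classifier$fit(xtr, y)
    post[, j] <- classifier$predict(model, xte)
  }
  post
}

#' Average posteriors across time points
#'
#' The integrated evaluation protocol: the per-time-point posterior
#' probabilities of each subject are averaged arithmetically, so genes
#' with mild but concordant effects across time are credited.
#'
#' @param posteriors matrix subjects x time points (no missing cells).
#' @return named numeric vector, one averaged posterior per subject.
#' @export
average_posteriors <- function(posteriors) {
  posteriors <- as.matrix(posteriors)
  if (anyNA(posteriors))
    stop("missing posterior cell(s): every subject needs a posterior at every time point")
  rowMeans(posteriors)
}

# area under the precision-recall curve, trapezoidal over recall;
# thresholds descend through the distinct posterior values
.aupr <- function(p, truth) {
  npos <- sum(truth)
  ord <- order(p, decreasing = TRUE)
  p <- p[ord]; truth <- truth[ord]
  tp <- cumsum(truth); fp <- cumsum(!truth)
  keep <- !duplicated(p, fromLast = TRUE)   # collapse ties to one cut
  tp <- tp[keep]; fp <- fp[keep]
  prec <- tp / (tp + fp)
  rec <- tp / npos
  # anchor at recall 0 with the first cut's precision
  rec0 <- c(0, rec); prec0 <- c(prec[[1L]], prec)
  sum(diff(rec0) * (prec0[-1L] + prec0[-length(prec0)]) / 2)
}

#' Performance metrics of posterior probabilities
#'
#' Four metrics, all ranging over `[0, 1]`:
#' \describe{
#'   \item{error}{misclassification rate at threshold 0.5 (posterior of
#'     exactly 0.5 classifies as positive, a fixed deterministic rule);
#'     0 optimal.}
#'   \item{gbs}{generalized Brier score,
#'     `(1/(2n)) * sum_subjects sum_classes (p_class - 1{true})^2`;
#'     0 optimal.}
#'   \item{bcm}{belief confusion metric: mean posterior assigned to the
#'     subject's true class; 1 optimal.}
#'   \item{aupr}{area under the precision-recall curve (positive =
#'     diseased class, trapezoidal over recall); 1 optimal.}
#' }
#'
#' @param posteriors numeric vector in `[0, 1]`, one per subject:
#'   posterior of the positive class.
#' @param labels factor (second level = positive) or logical vector.
#' @param scope label stored in the report (e.g. a time point or
#'   `"averaged"`).
#' @return an object of class `metrics_report`: list with `error`,
#'   `gbs`, `bcm`, `aupr`, `scope`.
#' @export
compute_metrics <- function(posteriors, labels, scope = "averaged") {
  p <- as.vector(posteriors)
  if (any(p < 0 | p > 1)) stop("posteriors must lie in [0, 1]")
  truth <- if (is.logical(labels)) labels else {
    labels <- as.factor(labels)
    labels == levels(droplevels(labels))[2L]
  }
  stopifnot(length(truth) == length(p))
  if (length(unique(truth)) < 2L)
    stop("labels contain a single class; AUPR is undefined")
  n <- length(p)
  err <- mean((p >= 0.5) != truth)
  gbs <- (sum((p - as.numeric(truth))^2) +
            sum(((1 - p) - as.numeric(!truth))^2)) / (2 * n)
  bcm <- mean(ifelse(truth, p, 1 - p))
  structure(list(error = err, gbs = gbs, bcm = bcm,
                 aupr = .aupr(p, truth), scope = scope),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("metrics [%s]: error=%.3f GBS=%.3f BCM=%.3f AUPR=%.3f\n",
              x$scope, x$error, x$gbs, x$bcm, x$aupr))
  invisible(x)
}

#' Evaluate a signature on train/test expression sets
#'
#' Fits per-time-point classifiers on `train`, computes posteriors on
#' `test`, and reports the four metrics for each time point plus the
#' averaged-posterior scope.
#'
#' @inheritParams fit_posteriors
#' @return named list of [compute_metrics()] reports: one per time
#'   point plus `"averaged"`.
#' @export
evaluate_signature <- function(train, sig, test = NULL,
                               classifier = ridge_logistic_classifier()) {
  if (is.null(test)) test <- train
  post <- fit_posteriors(train, sig, test, classifier)
  truth <- positive_class(test)
  out <- lapply(seq_along(train$timepoints), function(j)
    compute_metrics(post[, j], truth, scope = train$timepoints[[j]]))
  names(out) <- train$timepoints
  out$averaged <- compute_metrics(average_posteriors(post), truth,
                                  scope = "averaged")
  out
}

# stratified fold assignment; redraws (new sub-seed) until every fold
# holds both classes, max 10 attempts
.stratified_folds <- function(truth, folds, seed) {
  n <- length(truth)
  for (attempt in seq_len(10L)) {
    fold <- with_seed(sub_seed(seed, paste0("folds", attempt)), {
      f <- integer(n)
      for (cls in c(TRUE, FALSE)) {
        i <- which(truth == cls)
        f[i] <- sample(rep_len(seq_len(folds), length(i)))
      }
      f
    })
    ok <- all(vapply(seq_len(folds), function(k)
      length(unique(truth[fold != k])) == 2L &&
        sum(fold == k) > 0L, logical(1)))
    if (ok) return(fold)
  }
  stop("could not draw ", folds, "-fold split keeping both classes in every training fold")
}

#' Cross-validated tuning of the reduction cutoff
#'
#' The reduction cutoff for `c_k` is a tuning parameter.  Over a grid
#' (default 0.05, 0.1, ..., 0.5) the full selector + classifier pipeline
#' is run on 4 of 5 stratified folds and the misclassification error of
#' the averaged posteriors is computed on the held-out fold; the grid
#' value with the minimum mean CV error wins, ties going to the smallest
#' cutoff.
#'
#' @inheritParams select_features
#' @param grid candidate cutoffs.
#' @param folds number of CV folds (default 5).
#' @param classifier see [fit_posteriors()].
#' @return the chosen cutoff; the per-grid mean CV errors are attached
#'   as attribute `"cv_errors"`.
#' @export
cv_tune_cutoff <- function(expr, method = c("two_level", "longitudinal",
                                            "per_timepoint"),
                           collection = NULL,
                           grid = seq(0.05, 0.5, by = 0.05),
                           folds = 5L, q_cutoff = 0.05,
                           B = 1000L, seed = 1L,
                           classifier = ridge_logistic_classifier(), ...) {
  method <- match.arg(method)
  if (!length(grid)) stop("'grid' must be non-empty")
  grid <- sort(unique(as.numeric(grid)))
  if (length(grid) == 1L) {
    out <- grid
    attr(out, "cv_errors") <- stats::setNames(NA_real_, grid)
    return(out)
  }
  truth <- positive_class(expr)
  if (any(table(truth) < folds))
    stop("need at least ", folds, " subjects per class for ", folds,
         "-fold CV")
  fold <- .stratified_folds(truth, folds, seed)
  errs <- matrix(NA_real_, folds, length(grid))
  for (k in seq_len(folds)) {
    tr <- subset_subjects(expr, expr$subjects[fold != k])
    te <- subset_subjects(expr, expr$subjects[fold == k])
    # the permutation stream does not depend on the cutoff: build it once
    # per fold and share it across the whole grid
    engine <- sam_perm_engine(tr, B = B, seed = sub_seed(seed, paste0("cv", k)))
    for (gi in seq_along(grid)) {
      sig <- suppressWarnings(
        select_features(tr, method = method, collection = collection,
                        q_cutoff = q_cutoff, c_cutoff = grid[[gi]],
                        B = B, seed = sub_seed(seed, paste0("cv", k)),
                        engine = engine, ...))
      post <- suppressWarnings(fit_posteriors(tr, sig, te, classifier))
      errs[k, gi] <- mean((average_posteriors(post) >= 0.5) !=
                            positive_class(te))
    }
  }
  mean_err <- colMeans(errs)
  best <- grid[[which.min(mean_err)]]   # which.min takes the first (smallest)
  attr(best, "cv_errors") <- stats::setNames(mean_err, grid)
  best
}
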