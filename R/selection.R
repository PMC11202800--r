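# Two-step feature selection: mutual-information based mRMR ranking followed
# by a sequential-forward-selection (SFS) wrapper search, plus comparator
# rankers (random-forest importance, linear SVM-RFE).

#' Quantile discretization
#'
#' Equal-frequency binning used by the mutual-information estimator. Values
#' are ordered (ties broken by position) and cut into `n_bins` contiguous
#' groups whose sizes differ by at most one. Constant columns collapse to a
#' single bin.
#'
#' @param column numeric vector, nonempty.
#' @param n_bins number of bins (>= 2).
#' @return integer vector of 0-based bin indices.
#' @export
discretize <- function(column, n_bins = 3L) {
  stopifnot(length(column) > 0L, n_bins >= 2L)
  if (length(unique(column)) == 1L) return(integer(length(column)))
  n <- length(column)
  ord <- order(column, seq_len(n))
  bins <- integer(n)
  bins[ord] <- as.integer(floor((seq_len(n) - 1L) * n_bins / n))
  bins
}

#' Plug-in mutual information of two discrete vectors
#'
#' `I(a; b) = sum p(a,b) * log(p(a,b) / (p(a) p(b)))` over the empirical
#' joint distribution, in nats. Always nonnegative up to floating error.
#'
#' @param a,b discrete vectors of equal length.
#' @return numeric scalar (nats).
#' @export
mutual_info <- function(a, b) {
  if (length(a) != length(b)) {
    stop("a and b must have equal length", call. = FALSE)
  }
  n <- length(a)
  joint <- table(a, b) / n
  pa <- rowSums(joint)
  pb <- colSums(joint)
  nz <- joint > 0
  sum(joint[nz] * log(joint[nz] / outer(pa, pb)[nz]))
}

#' mRMR feature ranking
#'
#' Greedy maximum-relevance minimum-redundancy ranking in the MID
#' (mutual-information difference) form: the first feature maximizes
#' `I(f; y)`; each subsequent pick maximizes
#' `I(f; y) - mean(I(f; s))` over features `s` already selected. Features
#' are discretized with [discretize()] before estimation. Ties are broken
#' by schema column order.
#'
#' @param table a [feature_table()] with labels.
#' @param k number of features to rank (default: all).
#' @param n_bins discretization bins for the MI estimator.
#' @return character vector of feature names, best first.
#' @export
mrmr_rank <- function(table, k = ncol(table$rows), n_bins = 3L) {
  stopifnot(inherits(table, "feature_table"))
  p <- ncol(table$rows)
  if (p == 0L || nrow(table$rows) == 0L) {
    stop("empty feature table", call. = FALSE)
  }
  k <- min(k, p)
  disc <- apply(table$rows, 2, discretize, n_bins = n_bins)
  relevance <- vapply(seq_len(p), function(j)
    mutual_info(disc[, j], table$labels), numeric(1))
  selected <- integer(0)
  remaining <- seq_len(p)
  # redundancy cache: pairwise MI computed lazily against selected features
  red_sum <- numeric(p)
  for (step in seq_len(k)) {
    score <- if (length(selected) == 0L) relevance[remaining]
             else relevance[remaining] - red_sum[remaining] / length(selected)
    pick <- remaining[which.max(score)]
    selected <- c(selected, pick)
    remaining <- setdiff(remaining, pick)
    if (length(remaining)) {
      red_sum[remaining] <- red_sum[remaining] +
        vapply(remaining, function(j)
          mutual_info(disc[, j], disc[, pick]), numeric(1))
    }
  }
  table$schema$name[selected]
}

#' Sequential forward selection
#'
#' Walks `candidate_order` and greedily appends each feature whose addition
#' improves the cross-validated objective over the running best; stops after
#' `patience` consecutive non-improvements or when candidates are exhausted.
#'
#' @param table a [feature_table()].
#' @param candidate_order character vector of feature names to consider, in
#'   order.
#' @param evaluator function `(rows, labels) -> numeric objective`
#'   (higher is better); defaults to [cv_auc_evaluator()].
#' @param cv_folds folds used by the default evaluator.
#' @param patience consecutive non-improvements tolerated before stopping.
#' @param seed seed forwarded to the default evaluator's fold assignment.
#' @return list of class `selection_result`: `ranked_features`,
#'   `selected_subset`, `objective_trace` (running best, non-decreasing),
#'   `objective`, `cv_folds`.
#' @export
sfs <- function(table, candidate_order, evaluator = NULL, cv_folds = 10L,
                patience = 5L, seed = 1L) {
  stopifnot(inherits(table, "feature_table"), length(candidate_order) > 0L)
  if (is.null(evaluator)) {
    evaluator <- cv_auc_evaluator(folds = cv_folds, seed = seed)
  }
  current <- character(0)
  best <- -Inf
  trace <- numeric(0)
  misses <- 0L
  for (cand in candidate_order) {
    trial <- c(current, cand)
    obj <- tryCatch(
      evaluator(table$rows[, trial, drop = FALSE], table$labels),
      error = function(e) stop(sprintf("evaluator failed on {%s}: %s",
                                       paste(trial, collapse = ", "),
                                       conditionMessage(e)), call. = FALSE))
    if (obj > best) {
      best <- obj
      current <- trial
      misses <- 0L
    } else {
      misses <- misses + 1L
    }
    trace <- c(trace, best)
    if (misses >= patience) break
  }
  structure(list(ranked_features = candidate_order,
                 selected_subset = current,
                 objective_trace = trace,
                 objective = attr(evaluator, "objective") %||% "custom",
                 cv_folds = cv_folds),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %d of %d features | best %s = %.4f\n",
              length(x$selected_subset), length(x$ranked_features),
              x$objective, max(x$objective_trace)))
  invisible(x)
}

#' Two-step mRMR + SFS selection
#'
#' Ranks all features with [mrmr_rank()], then runs [sfs()] over that order.
#'
#' @inheritParams sfs
#' @param n_bins discretization bins for the mRMR step.
#' @param max_rank cap on how many mRMR-ranked candidates SFS walks
#'   (default: all).
#' @return a `selection_result`.
#' @export
mrmr_sfs <- function(table, evaluator = NULL, cv_folds = 10L, patience = 5L,
                     n_bins = 3L, max_rank = ncol(table$rows), seed = 1L) {
  ranking <- mrmr_rank(table, k = max_rank, n_bins = n_bins)
  sfs(table, ranking, evaluator = evaluator, cv_folds = cv_folds,
      patience = patience, seed = seed)
}

#' Comparator feature rankings
#'
#' `rf_importance` ranks by impurity importance of a random forest
#' (\pkg{ranger}); `svm_rfe` is recursive feature elimination with a linear
#' support vector machine (\pkg{e1071}), dropping the feature with the
#' smallest squared weight each round. Both return a full ranking, best
#' first, deterministic for a fixed seed.
#'
#' @param table a [feature_table()].
#' @param method `"rf_importance"` or `"svm_rfe"`.
#' @param seed integer seed.
#' @return character vector: permutation of all feature names.
#' @export
comparator_rank <- function(table, method = c("rf_importance", "svm_rfe"),
                            seed = 1L) {
  method <- match.arg(method)
  rows <- table$rows
  y <- factor(table$labels, levels = c(0, 1))
  if (method == "rf_importance") {
    fit <- ranger::ranger(x = as.data.frame(rows), y = y,
                          num.trees = 500, importance = "impurity",
                          seed = as.integer(seed), num.threads = 1)
    imp <- fit$variable.importance
    return(colnames(rows)[order(-imp, seq_len(ncol(rows)))])
  }
  remaining <- seq_len(ncol(rows))
  eliminated <- integer(0)
  scaled <- zscale(rows)
  while (length(remaining) > 1L) {
    fit <- with_seed(seed, e1071::svm(scaled[, remaining, drop = FALSE], y,
                                      kernel = "linear", scale = FALSE))
    w <- t(fit$coefs) %*% fit$SV
    drop_j <- which.min(as.numeric(w)^2)
    eliminated <- c(remaining[drop_j], eliminated)
    remaining <- remaining[-drop_j]
  }
  colnames(rows)[c(remaining, eliminated)]
}

#' Cross-validated AUC evaluator for wrapper selection
#'
#' Returns a function `(rows, labels) -> mean AUC` over stratified folds,
#' fitting the given backend inside each fold. The default logistic backend
#' keeps wrapper search fast; heavier backends plug in via `config`.
#'
#' @param folds number of stratified folds.
#' @param config a [model_config()]; default logistic regression.
#' @param seed seed controlling the fold assignment.
#' @return evaluator function with attribute `objective = "auc"`.
#' @export
cv_auc_evaluator <- function(folds = 10L, config = model_config(
                               backend = "logistic"), seed = 1L) {
  f <- function(rows, labels) {
    rows <- as.matrix(rows)
    assign <- stratified_folds(labels, folds, seed)
    scores <- numeric(length(labels))
    for (fold in seq_len(max(assign))) {
      te <- which(assign == fold)
      tr <- which(assign != fold)
      fit <- train_matrix(rows[tr, , drop = FALSE], labels[tr], config)
      scores[te] <- predict_scores(fit, rows[te, , drop = FALSE])
    }
    auc_score(scores, labels)
  }
  attr(f, "objective") <- "auc"
  f
}
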