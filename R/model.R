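# Classifier wrapper, confusion-based metrics, rank-based AUC and repeated
# stratified cross-validation. The reference configuration is a gradient
# boosted decision tree (150 rounds, learning rate 0.03, depth 6, seed 42);
# logistic regression, an RBF support vector machine and a random forest sit
# behind the same contract for comparator sweeps.

#' Classifier configuration
#'
#' @param iterations boosting rounds / trees (default 150).
#' @param learning_rate shrinkage (default 0.03).
#' @param depth tree depth (default 6).
#' @param seed training seed (default 42).
#' @param backend one of `"gbdt"` (gradient-boosted oblivious-style trees
#'   via \pkg{xgboost}), `"logistic"`, `"svm"`, `"rf"`.
#' @return a list of class `model_config`.
#' @export
model_config <- function(iterations = 150L, learning_rate = 0.03,
                         depth = 6L, seed = 42L,
                         backend = c("gbdt", "logistic", "svm", "rf")) {
  backend <- match.arg(backend)
  stopifnot(iterations >= 1L, learning_rate > 0, learning_rate <= 1,
            depth >= 1L)
  structure(list(iterations = as.integer(iterations),
                 learning_rate = learning_rate, depth = as.integer(depth),
                 seed = as.integer(seed), backend = backend),
            class = "model_config")
}

#' Train a hot-spot classifier
#'
#' @param table a [feature_table()] with both classes present.
#' @param config a [model_config()].
#' @return an opaque model handle of class `pdh_model` supporting
#'   [predict_scores()].
#' @export
train <- function(table, config = model_config()) {
  stopifnot(inherits(table, "feature_table"))
  train_matrix(table$rows, table$labels, config)
}

# Matrix-level training used everywhere internally.
train_matrix <- function(rows, labels, config = model_config()) {
  rows <- as.matrix(rows)
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) {
    stop("degenerate training set: only one class present", call. = FALSE)
  }
  fit <- switch(config$backend,
    gbdt = xgboost::xgb.train(
      params = list(objective = "binary:logistic",
                    eta = config$learning_rate, max_depth = config$depth,
                    nthread = 1, seed = config$seed),
      data = xgboost::xgb.DMatrix(rows, label = labels),
      nrounds = config$iterations, verbose = 0),
    logistic = {
      x <- cbind(1, rows)
      co <- suppressWarnings(stats::glm.fit(x, labels,
        family = stats::binomial())$coefficients)
      co[is.na(co)] <- 0
      co
    },
    svm = with_seed(config$seed,
      e1071::svm(rows, factor(labels, levels = c(0, 1)),
                 kernel = "radial", probability = TRUE)),
    rf = ranger::ranger(x = as.data.frame(rows),
                        y = factor(labels, levels = c(0, 1)),
                        num.trees = max(config$iterations, 100L),
                        probability = TRUE, seed = config$seed,
                        num.threads = 1))
  structure(list(fit = fit, backend = config$backend, config = config,
                 feature_names = colnames(rows)),
            class = "pdh_model")
}

#' Predict hot-spot scores
#'
#' @param model a `pdh_model` from [train()].
#' @param rows feature matrix with the training columns.
#' @return numeric vector of positive-class probabilities.
#' @export
predict_scores <- function(model, rows) {
  stopifnot(inherits(model, "pdh_model"))
  rows <- as.matrix(rows)
  if (!is.null(model$feature_names) && !is.null(colnames(rows))) {
    rows <- rows[, model$feature_names, drop = FALSE]
  }
  switch(model$backend,
    gbdt = as.numeric(stats::predict(model$fit, xgboost::xgb.DMatrix(rows))),
    logistic = as.numeric(stats::plogis(cbind(1, rows) %*% model$fit)),
    svm = {
      p <- attr(stats::predict(model$fit, rows, probability = TRUE),
                "probabilities")
      as.numeric(p[, "1"])
    },
    rf = as.numeric(stats::predict(model$fit, data = as.data.frame(rows),
                                   num.threads = 1)$predictions[, "1"]))
}

#' Confusion counts at a decision threshold
#'
#' Positives are hot spots (label 1).
#'
#' @param labels true 0/1 labels.
#' @param predictions predicted 0/1 classes (threshold scores yourself, or
#'   see [evaluate_model()]).
#' @return named integer vector `(tp, fp, tn, fn)`.
#' @export
confusion <- function(labels, predictions) {
  if (length(labels) != length(predictions)) {
    stop("labels and predictions must have equal length", call. = FALSE)
  }
  if (!all(labels %in% c(0, 1)) || !all(predictions %in% c(0, 1))) {
    stop("labels and predictions must be binary 0/1", call. = FALSE)
  }
  c(tp = sum(labels == 1 & predictions == 1),
    fp = sum(labels == 0 & predictions == 1),
    tn = sum(labels == 0 & predictions == 0),
    fn = sum(labels == 1 & predictions == 0))
}

#' Classification metrics from confusion counts
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, precision
#' `TP/(TP+FP)`, F1 `2*SEN*PRE/(SEN+PRE)`, accuracy
#' `(TP+TN)/(TP+TN+FP+FN)` and Matthews correlation
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`. Any metric whose
#' denominator is zero is defined as 0.
#'
#' @param tp,fp,tn,fn nonnegative counts, not all zero.
#' @return named numeric vector `(sen, spe, pre, f1, acc, mcc)`.
#' @export
metrics_from_counts <- function(tp, fp, tn, fn) {
  tp <- unname(tp); fp <- unname(fp); tn <- unname(tn); fn <- unname(fn)
  counts <- c(tp, fp, tn, fn)
  if (any(counts < 0) || all(counts == 0)) {
    stop("counts must be nonnegative and not all zero", call. = FALSE)
  }
  safe_div <- function(num, den) if (den > 0) num / den else 0
  sen <- safe_div(tp, tp + fn)
  spe <- safe_div(tn, tn + fp)
  pre <- safe_div(tp, tp + fp)
  f1 <- safe_div(2 * sen * pre, sen + pre)
  acc <- safe_div(tp + tn, tp + tn + fp + fn)
  mcc_den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (mcc_den > 0) (tp * tn - fp * fn) / mcc_den else 0
  c(sen = sen, spe = spe, pre = pre, f1 = f1, acc = acc, mcc = mcc)
}

#' Rank-based AUC
#'
#' Area under the ROC curve via the Mann-Whitney statistic with midranks for
#' ties.
#'
#' @param scores numeric scores, higher = more hot-spot-like.
#' @param labels 0/1 labels; both classes must be present.
#' @return numeric scalar in `[0, 1]`.
#' @export
auc_score <- function(scores, labels) {
  if (length(scores) != length(labels)) {
    stop("scores and labels must have equal length", call. = FALSE)
  }
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    stop("AUC undefined: both classes must be present", call. = FALSE)
  }
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Full evaluation report
#'
#' Thresholds scores at `threshold`, computes confusion counts, the six
#' confusion-based metrics and the AUC.
#'
#' @param model a `pdh_model`, or `NULL` if `scores` are supplied directly.
#' @param rows feature matrix (ignored when `scores` given).
#' @param labels true 0/1 labels.
#' @param scores optional precomputed scores.
#' @param threshold decision threshold on the score (default 0.5).
#' @return list of class `eval_report` with counts and all seven metrics.
#' @export
evaluate_model <- function(model = NULL, rows = NULL, labels, scores = NULL,
                           threshold = 0.5) {
  if (is.null(scores)) scores <- predict_scores(model, rows)
  cm <- confusion(labels, as.integer(scores >= threshold))
  met <- metrics_from_counts(cm["tp"], cm["fp"], cm["tn"], cm["fn"])
  structure(c(as.list(cm), as.list(met),
              list(auc = auc_score(scores, labels), threshold = threshold)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> TP %d FP %d TN %d FN %d\n",
              x$tp, x$fp, x$tn, x$fn))
  cat(sprintf("  SEN %.3f SPE %.3f PRE %.3f F1 %.3f ACC %.3f MCC %.3f AUC %.3f\n",
              x$sen, x$spe, x$pre, x$f1, x$acc, x$mcc, x$auc))
  invisible(x)
}

# Stratified fold assignment: within each class, shuffled indices are dealt
# round-robin over folds, preserving class proportions per fold.
stratified_folds <- function(labels, folds, seed) {
  if (min(table(labels)) < folds) {
    stop(sprintf("cannot stratify: a class has fewer than %d members", folds),
         call. = FALSE)
  }
  assign <- integer(length(labels))
  with_seed(seed, {
    for (lab in unique(labels)) {
      idx <- sample(which(labels == lab))
      assign[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  assign
}

#' Repeated stratified k-fold cross-validation
#'
#' Balancing and feature selection, when enabled, are fitted inside each
#' training fold only — test folds never influence the sampler, the ranking
#' or the model.
#'
#' @param table a [feature_table()].
#' @param config a [model_config()].
#' @param folds folds per repeat (default 10).
#' @param repeats number of repeats (default 50).
#' @param seed master seed; fold assignments and stage seeds derive from it.
#' @param balance balancing strategy, see [apply_balancing()].
#' @param selector `"none"`, `"mrmr"` (top-`n_select` mRMR features) or
#'   `"mrmr-sfs"` (full wrapper search, markedly slower).
#' @param n_select number of features kept by the `"mrmr"` selector.
#' @param threshold decision threshold for confusion counts.
#' @return list of class `cv_report`: `mean` and `sd` over all folds of the
#'   seven metrics, plus `per_fold` (one row per fold x repeat).
#' @export
repeated_cv <- function(table, config = model_config(), folds = 10L,
                        repeats = 50L, seed = 1L,
                        balance = "none", selector = c("none", "mrmr",
                                                       "mrmr-sfs"),
                        n_select = 10L, threshold = 0.5) {
  stopifnot(inherits(table, "feature_table"))
  selector <- match.arg(selector)
  rows <- table$rows
  labels <- table$labels
  per_fold <- list()
  for (r in seq_len(repeats)) {
    assign <- stratified_folds(labels, folds, derive_seed(seed, paste0("cv", r)))
    for (fold in seq_len(folds)) {
      te <- which(assign == fold)
      tr <- which(assign != fold)
      stage_seed <- derive_seed(seed, sprintf("r%df%d", r, fold))
      bal <- apply_balancing(rows[tr, , drop = FALSE], labels[tr],
                             method = balance, seed = stage_seed)
      x_tr <- bal$rows
      y_tr <- bal$labels
      x_te <- rows[te, , drop = FALSE]
      if (selector != "none") {
        tr_table <- feature_table(x_tr, y_tr,
                                  groups = rep("fold", length(y_tr)),
                                  schema = table$schema)
        keep <- if (selector == "mrmr") {
          mrmr_rank(tr_table, k = min(n_select, ncol(x_tr)))
        } else {
          mrmr_sfs(tr_table, seed = stage_seed)$selected_subset
        }
        x_tr <- x_tr[, keep, drop = FALSE]
        x_te <- x_te[, keep, drop = FALSE]
      }
      fit <- train_matrix(x_tr, y_tr, config)
      rep_fold <- evaluate_model(fit, x_te, labels[te], threshold = threshold)
      per_fold[[length(per_fold) + 1L]] <-
        data.frame(repeat_ = r, fold = fold,
                   sen = rep_fold$sen, spe = rep_fold$spe, pre = rep_fold$pre,
                   f1 = rep_fold$f1, acc = rep_fold$acc, mcc = rep_fold$mcc,
                   auc = rep_fold$auc)
    }
  }
  per_fold <- do.call(rbind, per_fold)
  metric_cols <- c("sen", "spe", "pre", "f1", "acc", "mcc", "auc")
  structure(list(mean = colMeans(per_fold[metric_cols]),
                 sd = apply(per_fold[metric_cols], 2, stats::sd),
                 per_fold = per_fold,
                 folds = folds, repeats = repeats, seed = seed),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %d x %d-fold CV\n", x$repeats, x$folds))
  m <- x$mean
  cat(sprintf("  mean: SEN %.3f SPE %.3f PRE %.3f F1 %.3f ACC %.3f MCC %.3f AUC %.3f\n",
              m["sen"], m["spe"], m["pre"], m["f1"], m["acc"], m["mcc"],
              m["auc"]))
  invisible(x)
}
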