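# End-to-end pipeline: simulate (or read) a residue table, extract signal
# features, split by complex, balance the training side, select features,
# train, evaluate on the held-out complexes, and write all artifacts with
# the seeds and a config fingerprint embedded.

#' Pipeline configuration
#'
#' One object holding every stage's configuration plus paths and the master
#' seed. Each stage derives its own seed deterministically from the master
#' seed and the stage name, so stages are independently reproducible.
#'
#' @param input_table path to a residue table CSV, or `NULL` to simulate one
#'   with `synth`.
#' @param output_dir directory for artifacts (created if missing).
#' @param seed master seed.
#' @param synth a [synth_spec()] used when `input_table` is `NULL` (its own
#'   seed is overridden by the derived stage seed).
#' @param emd,wavelet,model stage configurations.
#' @param n_test_complexes complexes held out for testing (default 25).
#' @param balance balancing strategy, see [apply_balancing()].
#' @param balance_seed seed of the balancing stage (default 74).
#' @param selector `"mrmr-sfs"`, `"mrmr"` or `"none"`.
#' @param n_select features kept by the `"mrmr"` selector.
#' @param sfs_patience,sfs_folds wrapper-search controls.
#' @param threshold decision threshold.
#' @param dialect table dialect, `"csv"` or `"tsv"`.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(input_table = NULL, output_dir = tempfile("pdh_"),
                            seed = 1L, synth = synth_spec(),
                            emd = emd_config(), wavelet = wavelet_config(),
                            model = model_config(),
                            n_test_complexes = 25L,
                            balance = "smote-tomek", balance_seed = 74L,
                            selector = c("mrmr-sfs", "mrmr", "none"),
                            n_select = 11L, sfs_patience = 5L,
                            sfs_folds = 10L, threshold = 0.5,
                            dialect = "csv") {
  selector <- match.arg(selector)
  structure(list(input_table = input_table, output_dir = output_dir,
                 seed = as.integer(seed), synth = synth, emd = emd,
                 wavelet = wavelet, model = model,
                 n_test_complexes = as.integer(n_test_complexes),
                 balance = balance, balance_seed = as.integer(balance_seed),
                 selector = selector, n_select = as.integer(n_select),
                 sfs_patience = as.integer(sfs_patience),
                 sfs_folds = as.integer(sfs_folds),
                 threshold = threshold, dialect = dialect),
            class = "pipeline_config")
}

#' Run the full pipeline
#'
#' Stages, in order: simulate/read the residue table; extract wavelet and
#' EMD blocks into the full feature table; split train/test at the complex
#' level; balance the training rows; select features on the balanced
#' training rows; train the classifier; evaluate on the held-out complexes.
#' Artifacts (feature table CSV, selection JSON, report JSON) are written to
#' `config$output_dir`, each embedding the master seed, stage seeds and a
#' configuration fingerprint. On any stage error, partial outputs are
#' removed and the error is re-signalled with the stage name.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress stage log lines (written to `stderr`).
#' @return list of class `pipeline_result`: `report` ([evaluate_model()]
#'   output on the test complexes), `selection`, `split`, `model`, `table`,
#'   and `paths` of the written artifacts.
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- proc.time()[["elapsed"]]
  log_stage <- function(fmt, ...) {
    if (!quiet) {
      message(sprintf("[pdhotspot %7.2fs] %s",
                      proc.time()[["elapsed"]] - t0, sprintf(fmt, ...)))
    }
  }
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      unlink(written)
      stop(sprintf("[stage %s] %s", stage, conditionMessage(e)),
           call. = FALSE)
    })
  }
  # fingerprint covers the scientific configuration only, not paths
  hash <- config_hash(unclass(config)[setdiff(names(config),
                                              c("input_table", "output_dir"))])
  meta <- list(config_hash = hash, master_seed = config$seed,
               balance_seed = config$balance_seed,
               model_seed = config$model$seed)

  records <- run_stage("simulate", {
    if (is.null(config$input_table)) {
      sp <- config$synth
      sp$seed <- derive_seed(config$seed, "simulate")
      log_stage("simulating %d complexes (stage seed %d)", sp$n_complexes,
                sp$seed)
      generate_records(sp)
    } else {
      log_stage("reading %s", config$input_table)
      attr(read_feature_table(config$input_table, config$dialect), "records")
    }
  })

  table <- run_stage("features", {
    log_stage("extracting features for %d records", length(records))
    build_feature_table(records, config$emd, config$wavelet)
  })
  table_path <- file.path(config$output_dir, "feature_table.csv")
  run_stage("features", {
    write_feature_table(table, table_path, config$dialect)
    writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE),
               file.path(config$output_dir, "feature_table.meta.json"))
  })
  written <- c(written, table_path,
               file.path(config$output_dir, "feature_table.meta.json"))

  split <- run_stage("split", {
    split_by_complex(table, config$n_test_complexes,
                     derive_seed(config$seed, "split"))
  })
  train_tab <- subset_table(table, split$train_indices)
  test_tab <- subset_table(table, split$test_indices)
  log_stage("split: %d train / %d test rows (%d test complexes)",
            nrow(train_tab$rows), nrow(test_tab$rows),
            length(unique(test_tab$groups)))

  bal <- run_stage("balance", {
    apply_balancing(train_tab$rows, train_tab$labels, config$balance,
                    seed = config$balance_seed)
  })
  log_stage("balance (%s): %d -> %d rows", config$balance,
            nrow(train_tab$rows), nrow(bal$rows))

  selection <- run_stage("select", {
    if (config$selector == "none") {
      list(selected_subset = table$schema$name, objective_trace = numeric(0))
    } else {
      bal_table <- feature_table(bal$rows, bal$labels,
                                 rep("train", length(bal$labels)),
                                 table$schema)
      if (config$selector == "mrmr") {
        list(selected_subset = mrmr_rank(bal_table, k = config$n_select),
             objective_trace = numeric(0))
      } else {
        mrmr_sfs(bal_table,
                 evaluator = cv_auc_evaluator(
                   folds = config$sfs_folds,
                   seed = derive_seed(config$seed, "sfs")),
                 cv_folds = config$sfs_folds, patience = config$sfs_patience,
                 seed = derive_seed(config$seed, "sfs"))
      }
    }
  })
  log_stage("select (%s): %d features kept", config$selector,
            length(selection$selected_subset))
  sel_path <- file.path(config$output_dir, "selection.json")
  run_stage("select", {
    jsonlite::write_json(
      c(meta, list(selector = config$selector,
                   selected = selection$selected_subset,
                   objective_trace = selection$objective_trace)),
      sel_path, auto_unbox = TRUE, digits = NA)
  })
  written <- c(written, sel_path)

  fit <- run_stage("train", {
    train_matrix(bal$rows[, selection$selected_subset, drop = FALSE],
                 bal$labels, config$model)
  })
  log_stage("trained %s backend", config$model$backend)

  report <- run_stage("evaluate", {
    evaluate_model(fit,
                   test_tab$rows[, selection$selected_subset, drop = FALSE],
                   test_tab$labels, threshold = config$threshold)
  })
  report_path <- file.path(config$output_dir, "report.json")
  run_stage("evaluate", {
    jsonlite::write_json(c(meta, unclass(report)), report_path,
                         auto_unbox = TRUE, digits = NA)
  })
  written <- c(written, report_path)
  log_stage("done: test AUC %.3f, F1 %.3f, MCC %.3f",
            report$auc, report$f1, report$mcc)

  structure(list(report = report, selection = selection, split = split,
                 model = fit, table = table, balanced = bal,
                 config_hash = hash,
                 paths = list(feature_table = table_path,
                              selection = sel_path, report = report_path)),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> config %s | %d features selected\n",
              x$config_hash, length(x$selection$selected_subset)))
  print(x$report)
  invisible(x)
}
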