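# The comparison protocol: repeated stratified splits; per split a full
# hyperparameter grid for the single-task net, one grid per auxiliary-set
# size for the multitask net, and a penalty path for the L1 logistic
# baseline; selection is always argmax of VALIDATION AUPRC, with the test
# AUPRC of every run recorded but never used for selection.

#' The neural-net hyperparameter grid
#'
#' Crosses hidden-layer count (1, 2), hidden width (128, 256, 512, 1024,
#' 2048) and initial learning rate (1e-4, 5e-5): 20 configurations.
#'
#' @return data frame with columns `n_hidden_layers`, `hidden_size`,
#'   `learning_rate` and a `grid_index`.
#' @export
hyperparameter_grid <- function() {
  g <- expand.grid(
    n_hidden_layers = c(1L, 2L),
    hidden_size = c(128L, 256L, 512L, 1024L, 2048L),
    learning_rate = c(1e-4, 5e-5),
    KEEP.OUT.ATTRS = FALSE
  )
  g$grid_index <- seq_len(nrow(g))
  g
}

#' Expected run counts for a protocol
#'
#' Bookkeeping for the experiment design: with a grid of `grid_size`
#' hyperparameter settings, each split trains `grid_size` single-task nets
#' plus `grid_size` multitask nets per auxiliary-set size.
#'
#' @param grid_size hyperparameter grid cardinality (default 20).
#' @param aux_sizes auxiliary-set sizes (default `c(5, 10, 20)`).
#' @param n_splits number of repeated splits (default 10).
#' @return list with `neural_runs_per_split` and `neural_runs_total`.
#' @export
protocol_schedule <- function(grid_size = nrow(hyperparameter_grid()),
                              aux_sizes = c(5, 10, 20), n_splits = 10) {
  per_split <- grid_size * (1 + length(aux_sizes))
  list(neural_runs_per_split = per_split,
       neural_runs_total = per_split * n_splits)
}

# Deterministic preference order for breaking validation-AUPRC ties:
# fewer layers, then smaller width, then lower learning rate.
order_results <- function(df) {
  df[order(-df$val_auprc, df$n_hidden_layers, df$hidden_size,
           df$learning_rate), , drop = FALSE]
}

#' Grid search for one model family on one split
#'
#' Trains one model per grid point with a seed derived deterministically
#' from `(master_seed, split_id, family, aux_set_size, grid_index)`. A
#' grid point whose training fails is recorded with `status = "failed"`
#' and the reason, never silently dropped, and is excluded from best-model
#' selection.
#'
#' @param family `"STNN"` or `"MTNN"`.
#' @param split a `split_spec` from [stratified_splits()].
#' @param features a [build_feature_matrix()] result (or plain matrix).
#' @param target_labels binary target vector for the whole cohort.
#' @param aux_labels full-cohort auxiliary 0/1 label matrix (required for
#'   MTNN; its column count is the auxiliary-set size).
#' @param tc a [train_config()]; its seed field is overridden per run.
#' @param grid hyperparameter grid (default [hyperparameter_grid()]).
#' @param master_seed integer seed for the whole experiment.
#' @return data frame of run results: split id, family, aux set size,
#'   hyperparameters, validation and test AUPRC, seed, status and reason,
#'   ordered by the grid index.
#' @export
grid_search <- function(family, split, features, target_labels,
                        aux_labels = NULL, tc = train_config(),
                        grid = hyperparameter_grid(), master_seed = 1L) {
  family <- match.arg(family, c("STNN", "MTNN"))
  X <- as_feature_values(features)
  aux_size <- 0L
  if (family == "MTNN") {
    if (is.null(aux_labels) || ncol(aux_labels) < 1) {
      abort_config("MTNN grid search needs a non-empty auxiliary label matrix")
    }
    aux_size <- ncol(aux_labels)
  }
  X_train <- X[split$train_idx, , drop = FALSE]
  X_val <- X[split$val_idx, , drop = FALSE]
  X_test <- X[split$test_idx, , drop = FALSE]
  # densify once per split so every grid point reuses the dense copy
  if (!is.matrix(X_train) && prod(dim(X_train)) <= 6e7) {
    X_train <- as.matrix(X_train)
  }
  y_train <- target_labels[split$train_idx]
  y_val <- target_labels[split$val_idx]
  y_test <- target_labels[split$test_idx]

  rows <- lapply(seq_len(nrow(grid)), function(gi) {
    hp <- hyper_params(grid$n_hidden_layers[gi], grid$hidden_size[gi],
                       grid$learning_rate[gi])
    seed <- derive_seed(master_seed, split$split_id, family, aux_size, gi)
    tc_run <- tc
    tc_run$seed <- seed
    res <- tryCatch({
      model <- if (family == "STNN") {
        train_stnn(X_train, y_train, X_val, y_val, hp, tc_run)
      } else {
        train_mtnn(X_train, y_train,
                   aux_labels[split$train_idx, , drop = FALSE],
                   X_val, y_val, hp, tc_run)
      }
      test_scores <- predict_scores(model, X_test)
      list(val = model$val_auprc, test = auprc(y_test, test_scores),
           best_epoch = model$best_epoch, status = "ok", reason = "")
    }, error = function(e) {
      list(val = NA_real_, test = NA_real_, best_epoch = NA_integer_,
           status = "failed", reason = conditionMessage(e))
    })
    data.frame(
      split_id = split$split_id, family = family, aux_set_size = aux_size,
      n_hidden_layers = grid$n_hidden_layers[gi],
      hidden_size = grid$hidden_size[gi],
      learning_rate = grid$learning_rate[gi],
      lambda = NA_real_, best_epoch = res$best_epoch,
      val_auprc = res$val, test_auprc = res$test, seed = seed,
      status = res$status, reason = res$reason,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

# Best-by-validation row of a result table (ok runs only).
select_best <- function(results) {
  ok <- results[results$status == "ok" & !is.na(results$val_auprc), ,
                drop = FALSE]
  if (nrow(ok) == 0) return(NULL)
  order_results(ok)[1, , drop = FALSE]
}

#' Hyperparameter-sensitivity summary
#'
#' For each (split, family, auxiliary-set size) cell with at least two
#' completed runs, reports the spread (max - min) and interquartile range
#' of validation and test AUPRC across the hyperparameter grid. A large
#' spread means performance depends heavily on finding the right
#' hyperparameters.
#'
#' @param results a run-result data frame from [grid_search()] (rows from
#'   several calls may be concatenated).
#' @return data frame with one row per (split_id, family, aux_set_size).
#' @export
sensitivity_summary <- function(results) {
  ok <- results[results$status == "ok" & !is.na(results$val_auprc), ,
                drop = FALSE]
  cells <- unique(ok[, c("split_id", "family", "aux_set_size")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    cell <- ok[ok$split_id == cells$split_id[i] &
                 ok$family == cells$family[i] &
                 ok$aux_set_size == cells$aux_set_size[i], ]
    if (nrow(cell) < 2) return(NULL)
    data.frame(
      cells[i, , drop = FALSE],
      n_runs = nrow(cell),
      val_spread = max(cell$val_auprc) - min(cell$val_auprc),
      val_iqr = unname(diff(quantile(cell$val_auprc, c(0.25, 0.75)))),
      test_spread = max(cell$test_auprc) - min(cell$test_auprc),
      test_iqr = unname(diff(quantile(cell$test_auprc, c(0.25, 0.75)))),
      row.names = NULL
    )
  })
  do.call(rbind, rows)
}

#' Run the full comparison protocol
#'
#' For each stratified split: a hyperparameter grid of single-task nets, a
#' grid of multitask nets per auxiliary-set size (auxiliary sets are
#' nested across sizes), and the L1 logistic baseline. Assembles the
#' best-per-split test AUPRCs (selected by validation AUPRC only),
#' pairwise MTNN - STNN differences per split and auxiliary size, and the
#' per-family hyperparameter-sensitivity summary.
#'
#' @param cohort an `ehr_cohort`.
#' @param rule the target [phenotype_rule()].
#' @param groups list of [phecode_group()] objects to draw auxiliary tasks
#'   from.
#' @param aux_sizes ascending auxiliary-set sizes (default `c(5, 10, 20)`).
#' @param n_splits number of stratified splits (default 10).
#' @param prevalence_band length-2 vector; phecode groups are eligible as
#'   auxiliary tasks when their label prevalence falls inside it.
#' @param grid hyperparameter grid (default the full 20-point grid).
#' @param tc a [train_config()] template.
#' @param master_seed integer seed for every derived stream (splits,
#'   auxiliary sampling, label noise, per-run training seeds).
#' @param fractions train/validation/test fractions.
#' @return a `protocol_result`: `results` (every run), `best` (one row per
#'   split x family x aux size), `differences` (per-split MTNN - STNN test
#'   AUPRC at each aux size), `sensitivity`, `aux_sets`, and a `manifest`
#'   recording seeds, sizes and the selection rule.
#' @export
run_full_protocol <- function(cohort, rule, groups,
                              aux_sizes = c(5, 10, 20), n_splits = 10,
                              prevalence_band = c(0.0008, 0.0295),
                              grid = hyperparameter_grid(),
                              tc = train_config(), master_seed = 1L,
                              fractions = c(0.8, 0.1, 0.1)) {
  aux_sizes <- sort(as.integer(aux_sizes))
  target_labels <- apply_rule(rule, cohort,
                              seed = derive_seed(master_seed, 9001L))
  features <- build_feature_matrix(cohort)
  phecode_labels <- derive_phecode_labels(cohort, groups)
  aux_sets <- sample_auxiliary_tasks(
    phecode_labels, prevalence_band[1], prevalence_band[2], aux_sizes,
    seed = derive_seed(master_seed, 9002L)
  )
  splits <- stratified_splits(target_labels, n_splits = n_splits,
                              fractions = fractions,
                              master_seed = derive_seed(master_seed, 9003L))

  all_results <- list()
  lr_rows <- list()
  for (split in splits) {
    sid <- split$split_id
    all_results[[length(all_results) + 1]] <- grid_search(
      "STNN", split, features, target_labels, tc = tc, grid = grid,
      master_seed = master_seed
    )
    for (s in aux_sizes) {
      aux_labels <- phecode_labels[, aux_sets[[paste0("aux", s)]],
                                   drop = FALSE]
      all_results[[length(all_results) + 1]] <- grid_search(
        "MTNN", split, features, target_labels, aux_labels = aux_labels,
        tc = tc, grid = grid, master_seed = master_seed
      )
    }
    lr <- train_l1_logreg(
      features$values[split$train_idx, , drop = FALSE],
      target_labels[split$train_idx],
      features$values[split$val_idx, , drop = FALSE],
      target_labels[split$val_idx]
    )
    lr_test <- auprc(
      target_labels[split$test_idx],
      predict_scores(lr, features$values[split$test_idx, , drop = FALSE])
    )
    lr_rows[[length(lr_rows) + 1]] <- data.frame(
      split_id = sid, family = "LR", aux_set_size = 0L,
      n_hidden_layers = NA_integer_, hidden_size = NA_integer_,
      learning_rate = NA_real_, lambda = lr$lambda,
      best_epoch = NA_integer_, val_auprc = lr$val_auprc,
      test_auprc = lr_test, seed = NA_integer_, status = "ok",
      reason = "", stringsAsFactors = FALSE
    )
  }
  results <- do.call(rbind, c(all_results, lr_rows))

  # best-by-validation per (split, family, aux size)
  cells <- unique(results[, c("split_id", "family", "aux_set_size")])
  best <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    select_best(results[results$split_id == cells$split_id[i] &
                          results$family == cells$family[i] &
                          results$aux_set_size == cells$aux_set_size[i], ])
  }))

  differences <- do.call(rbind, lapply(aux_sizes, function(s) {
    do.call(rbind, lapply(splits, function(split) {
      sid <- split$split_id
      b_st <- best[best$split_id == sid & best$family == "STNN", ]
      b_mt <- best[best$split_id == sid & best$family == "MTNN" &
                     best$aux_set_size == s, ]
      if (nrow(b_st) == 0 || nrow(b_mt) == 0) return(NULL)
      data.frame(split_id = sid, aux_set_size = s,
                 mtnn_test_auprc = b_mt$test_auprc,
                 stnn_test_auprc = b_st$test_auprc,
                 diff = b_mt$test_auprc - b_st$test_auprc)
    }))
  }))

  structure(
    list(
      results = results,
      best = best,
      differences = differences,
      sensitivity = sensitivity_summary(results),
      aux_sets = aux_sets,
      target_prevalence = attr(target_labels, "prevalence"),
      manifest = list(
        master_seed = master_seed, n_splits = n_splits,
        aux_sizes = aux_sizes, grid_size = nrow(grid),
        prevalence_band = prevalence_band,
        fractions = fractions,
        selection_rule = "argmax validation AUPRC; test AUPRC never used for selection",
        auprc_estimator = "average precision (step interpolation, tie-grouped)",
        batch_size = tc$batch_size, max_epochs = tc$max_epochs
      )
    ),
    class = "protocol_result"
  )
}

#' @export
print.protocol_result <- function(x, ...) {
  cat(sprintf(
    "<protocol_result> %d splits, target prevalence %.4f, %d runs (%d failed)\n",
    x$manifest$n_splits, x$target_prevalence, nrow(x$results),
    sum(x$results$status != "ok")
  ))
  for (s in x$manifest$aux_sizes) {
    d <- x$differences$diff[x$differences$aux_set_size == s]
    if (length(d) > 0) {
      cat(sprintf("  MTNN - STNN test AUPRC, %2d aux tasks: median %+.4f\n",
                  s, median(d)))
    }
  }
  invisible(x)
}

#' Audit best-model selection discipline
#'
#' Recomputes, for every (split, family, aux size) cell of a protocol
#' result, the argmax-by-validation run and checks it matches the reported
#' best row; errors if any test-set selection slipped in.
#'
#' @param protocol a `protocol_result`.
#' @return `TRUE` invisibly if the audit passes.
#' @export
audit_selection <- function(protocol) {
  best <- protocol$best
  for (i in seq_len(nrow(best))) {
    cell <- protocol$results[
      protocol$results$split_id == best$split_id[i] &
        protocol$results$family == best$family[i] &
        protocol$results$aux_set_size == best$aux_set_size[i] &
        protocol$results$status == "ok", ]
    if (max(cell$val_auprc) != best$val_auprc[i]) {
      ehrmtl_abort("selection audit failed: reported best is not the validation argmax",
                   "ehrmtl_audit_error")
    }
  }
  invisible(TRUE)
}

#' Write protocol outputs to a directory
#'
#' Writes `results.csv` (every run), `best.csv`, `differences.csv`,
#' `sensitivity.csv` and a JSON `manifest.json`.
#'
#' @param protocol a `protocol_result`.
#' @param dir output directory (created if missing).
#' @return `dir` invisibly.
#' @export
export_protocol <- function(protocol, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(protocol$results, file.path(dir, "results.csv"),
                   row.names = FALSE)
  utils::write.csv(protocol$best, file.path(dir, "best.csv"),
                   row.names = FALSE)
  utils::write.csv(protocol$differences, file.path(dir, "differences.csv"),
                   row.names = FALSE)
  utils::write.csv(protocol$sensitivity, file.path(dir, "sensitivity.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    c(protocol$manifest,
      list(aux_sets = protocol$aux_sets,
           target_prevalence = protocol$target_prevalence)),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE
  )
  invisible(dir)
}
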