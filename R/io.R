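# Checkpointing and tabular input.

#' Save and load fitted models
#'
#' Writes the model in R's native serialization plus a JSON metadata
#' sidecar (`<path>.json`) recording family, hyperparameters, seed, best
#' epoch and the validation-AUPRC trace, so runs can be inventoried
#' without deserializing anything.
#'
#' @param model a `fitted_model`.
#' @param path file path for the checkpoint (conventionally `.rds`).
#' @return `save_fitted_model()` returns `path` invisibly;
#'   `load_fitted_model()` returns the model.
#' @export
save_fitted_model <- function(model, path) {
  saveRDS(model, path)
  meta <- list(
    family = model$family,
    hyperparams = if (!is.null(model$hyperparams)) {
      model$hyperparams[c("n_hidden_layers", "hidden_size",
                          "learning_rate")]
    },
    lambda = model$lambda,
    seed = model$train_cfg$seed,
    batch_size = model$train_cfg$batch_size,
    best_epoch = model$best_epoch,
    val_auprc = model$val_auprc,
    val_auprc_trace = model$val_auprc_trace,
    task_ids = model$task_ids
  )
  jsonlite::write_json(meta[!vapply(meta, is.null, TRUE)],
                       paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname save_fitted_model
#' @export
load_fitted_model <- function(path) {
  readRDS(path)
}

#' Read a user-supplied binary patient-by-code table
#'
#' Accepts a delimited file with one row per patient: an id column,
#' `n_codes` binary code-indicator columns, and optionally one or more
#' label columns, and assembles the same cohort container the synthetic
#' generator produces, so the whole pipeline (features, splits, models,
#' complexity) applies to external data.
#'
#' @param path delimited text file with a header row.
#' @param id_col name of the patient-id column (default first column).
#' @param label_cols character vector of label column names (default
#'   none).
#' @param sep field separator (default tab).
#' @return list with `cohort` (an `ehr_cohort` whose vocabulary is the
#'   code columns, in file order) and `labels` (data frame of the label
#'   columns, possibly empty).
#' @export
read_patient_table <- function(path, id_col = NULL, label_cols = character(),
                               sep = "\t") {
  tab <- read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                    stringsAsFactors = FALSE)
  if (is.null(id_col)) id_col <- names(tab)[1]
  code_cols <- setdiff(names(tab), c(id_col, label_cols))
  codes <- as.matrix(tab[, code_cols, drop = FALSE])
  if (!all(codes %in% c(0, 1))) {
    abort_config("code columns must be binary 0/1")
  }
  code_sets <- apply(codes, 1, function(row) which(row == 1),
                     simplify = FALSE)
  cohort <- as_ehr_cohort(code_sets, n_codes = length(code_cols))
  cohort$demographics$patient_id <- as.character(tab[[id_col]])
  list(cohort = cohort,
       labels = tab[, label_cols, drop = FALSE])
}
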