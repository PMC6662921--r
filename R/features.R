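# Multi-hot feature construction and repeated stratified splitting.

#' Build the multi-hot feature matrix
#'
#' One binary indicator per code (columns in ascending code order) followed
#' by one indicator per demographic level (sex, race, ethnicity, then each
#' integer value of age, in the declared level order). Latent factors and
#' the hidden qualifier are deliberately excluded: they are unobserved.
#'
#' @param cohort an `ehr_cohort`.
#' @return an object of class `feature_matrix`: list with `values` (sparse
#'   0/1 matrix), `column_names`, and `row_ids` in cohort patient order.
#' @export
build_feature_matrix <- function(cohort) {
  n <- nrow(cohort$codes)
  m <- ncol(cohort$codes)
  lv <- cohort$config$demographic_levels %||% default_demographic_levels()
  code_cols <- sprintf("code_%05d", seq_len(m))

  demo_blocks <- list()
  demo_names <- character(0)
  for (var in c("sex", "race", "ethnicity", "age")) {
    levels_v <- lv[[var]]
    idx <- match(cohort$demographics[[var]], levels_v)
    block <- sparseMatrix(
      i = which(!is.na(idx)), j = idx[!is.na(idx)], x = 1,
      dims = c(n, length(levels_v))
    )
    demo_blocks[[var]] <- block
    demo_names <- c(demo_names, paste0(var, "_", levels_v))
  }
  values <- do.call(cbind, c(list(cohort$codes * 1), demo_blocks))
  column_names <- c(code_cols, demo_names)
  colnames(values) <- column_names
  structure(
    list(values = values, column_names = column_names,
         row_ids = cohort$demographics$patient_id),
    class = "feature_matrix"
  )
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d patients x %d features (density %.4f)\n",
              nrow(x$values), ncol(x$values),
              length(x$values@x) / prod(dim(x$values))))
  invisible(x)
}

# Allocate n items to partitions by floor + largest remainder, so the
# counts are exact and deterministic. Ties go to the earlier partition.
largest_remainder <- function(n, fractions) {
  raw <- n * fractions
  base <- floor(raw)
  short <- n - sum(base)
  if (short > 0) {
    rem <- raw - base
    extra <- order(-rem, seq_along(rem))[seq_len(short)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Repeated stratified train/validation/test splits
#'
#' For each split, positives and negatives are shuffled and allocated to
#' the three partitions separately (floor + largest-remainder rounding), so
#' the target prevalence in every partition matches the overall prevalence
#' up to integer rounding. Each split draws from its own child seed derived
#' from `(master_seed, split_id)`, making the whole set reproducible while
#' keeping splits distinct.
#'
#' @param target_labels binary 0/1 vector for the target phenotype.
#' @param n_splits number of repeated splits.
#' @param fractions train/validation/test proportions, summing to 1.
#' @param master_seed integer seed.
#' @return list of `split_spec` objects: `split_id`, disjoint `train_idx`,
#'   `val_idx`, `test_idx` partitioning `seq_along(target_labels)`, and
#'   `fractions`.
#' @export
stratified_splits <- function(target_labels, n_splits = 10,
                              fractions = c(0.8, 0.1, 0.1),
                              master_seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-8 || length(fractions) != 3) {
    abort_config("fractions must be three proportions summing to 1")
  }
  pos <- which(target_labels == 1)
  neg <- which(target_labels != 1)
  if (length(pos) < 10) {
    abort_stratification(sprintf(
      "stratified splitting needs at least 10 positive cases, found %d",
      length(pos)
    ))
  }
  n_pos_parts <- largest_remainder(length(pos), fractions)
  n_neg_parts <- largest_remainder(length(neg), fractions)
  lapply(seq_len(n_splits) - 1L, function(split_id) {
    set.seed(derive_seed(master_seed, split_id))
    pos_sh <- pos[sample.int(length(pos))]
    neg_sh <- neg[sample.int(length(neg))]
    cut2 <- function(x, sizes) {
      ends <- cumsum(sizes)
      starts <- c(1, head(ends, -1) + 1)
      lapply(seq_along(sizes), function(k) {
        if (sizes[k] == 0) integer(0) else x[starts[k]:ends[k]]
      })
    }
    pos_parts <- cut2(pos_sh, n_pos_parts)
    neg_parts <- cut2(neg_sh, n_neg_parts)
    structure(
      list(
        split_id = split_id,
        train_idx = sort(c(pos_parts[[1]], neg_parts[[1]])),
        val_idx = sort(c(pos_parts[[2]], neg_parts[[2]])),
        test_idx = sort(c(pos_parts[[3]], neg_parts[[3]])),
        fractions = fractions
      ),
      class = "split_spec"
    )
  })
}

#' Read and write split specifications as JSON
#'
#' Serializes the index arrays keyed by split id so an experiment can be
#' re-run on exactly the same partitions.
#'
#' @param splits list of `split_spec` objects from [stratified_splits()].
#' @param path file path.
#' @return `write_splits_json()` returns `path` invisibly;
#'   `read_splits_json()` returns the reconstructed list.
#' @export
write_splits_json <- function(splits, path) {
  doc <- lapply(splits, function(s) {
    list(split_id = s$split_id, train_idx = s$train_idx,
         val_idx = s$val_idx, test_idx = s$test_idx,
         fractions = s$fractions)
  })
  names(doc) <- vapply(splits, function(s) as.character(s$split_id), "")
  jsonlite::write_json(doc, path, digits = NA)
  invisible(path)
}

#' @rdname write_splits_json
#' @export
read_splits_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  out <- lapply(doc, function(s) {
    structure(
      list(split_id = as.integer(s$split_id[1]),
           train_idx = as.integer(unlist(s$train_idx)),
           val_idx = as.integer(unlist(s$val_idx)),
           test_idx = as.integer(unlist(s$test_idx)),
           fractions = as.numeric(unlist(s$fractions))),
      class = "split_spec"
    )
  })
  names(out) <- NULL
  out
}
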