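# Rule-based phenotype definitions: flat DNF (OR of conjunctions) over
# presence/absence of a small ordered set of "oracle" codes, optionally
# gated by the cohort's hidden (non-featurized) qualifier. The oracle code
# order is fixed because it defines digit positions of the binary
# combination signatures used by the complexity statistics.

#' Construct a clause of a phenotype rule
#'
#' A clause is a conjunction of presence/absence literals, optionally
#' combined with a count criterion ("at least `min_count` of these codes
#' present" -- the kind of threshold real rule-based definitions use for
#' repeated diagnosis codes) and optionally gated by the cohort's hidden
#' qualifier.
#'
#' @param present oracle codes that must all be present.
#' @param absent oracle codes that must be absent.
#' @param min_count_set optional vector of oracle codes for the count
#'   criterion.
#' @param min_count minimum number of `min_count_set` codes that must be
#'   present (ignored when `min_count_set` is empty).
#' @param requires_hidden if `TRUE`, the patient must also carry the hidden
#'   qualifier flag (which is never part of the feature matrix).
#' @return a `rule_clause` list.
#' @export
rule_clause <- function(present = integer(), absent = integer(),
                        min_count_set = integer(), min_count = 1L,
                        requires_hidden = FALSE) {
  if (length(min_count_set) > 0 &&
      (min_count < 1 || min_count > length(min_count_set))) {
    abort_config("min_count must lie in 1..length(min_count_set)")
  }
  structure(
    list(present = as.integer(present), absent = as.integer(absent),
         min_count_set = as.integer(min_count_set),
         min_count = as.integer(min_count),
         requires_hidden = isTRUE(requires_hidden)),
    class = "rule_clause"
  )
}

#' Construct a rule-based phenotype definition
#'
#' @param rule_id identifier.
#' @param oracle_codes ordered vector of code indices the rule may
#'   reference; the order defines the digit positions of
#'   [oracle_signature()] strings.
#' @param clauses non-empty list of [rule_clause()] objects; the rule fires
#'   if any clause is satisfied.
#' @param label_noise probability in `[0, 0.5)` of flipping each assigned
#'   label, modeling chart-review disagreement. Default 0.
#' @return an object of class `phenotype_rule`.
#' @export
phenotype_rule <- function(rule_id, oracle_codes, clauses, label_noise = 0) {
  oracle_codes <- as.integer(oracle_codes)
  if (anyDuplicated(oracle_codes)) {
    abort_config("oracle_codes must be distinct")
  }
  if (length(clauses) == 0) abort_config("a rule needs at least one clause")
  clauses <- lapply(clauses, function(cl) {
    if (!inherits(cl, "rule_clause")) {
      cl <- rule_clause(cl$present %||% integer(), cl$absent %||% integer(),
                        cl$min_count_set %||% integer(),
                        cl$min_count %||% 1L,
                        cl$requires_hidden %||% FALSE)
    }
    bad <- setdiff(c(cl$present, cl$absent, cl$min_count_set), oracle_codes)
    if (length(bad) > 0) {
      abort_config(sprintf(
        "clause references codes not in oracle_codes: %s",
        paste(bad, collapse = ", ")
      ))
    }
    cl
  })
  if (length(label_noise) != 1 || label_noise < 0 || label_noise >= 0.5) {
    abort_config("label_noise must lie in [0, 0.5)")
  }
  structure(
    list(rule_id = as.character(rule_id), oracle_codes = oracle_codes,
         clauses = clauses, label_noise = as.numeric(label_noise)),
    class = "phenotype_rule"
  )
}

#' @export
print.phenotype_rule <- function(x, ...) {
  cat(sprintf("<phenotype_rule> '%s': %d clauses over %d oracle codes, noise %.3f\n",
              x$rule_id, length(x$clauses), length(x$oracle_codes),
              x$label_noise))
  invisible(x)
}

#' Apply a phenotype rule to a cohort
#'
#' A patient is a case iff some clause is satisfied: all its required codes
#' present, all its forbidden codes absent, and -- if the clause demands it
#' -- the hidden qualifier flag set. Labels are then flipped independently
#' with probability `label_noise`.
#'
#' @param rule a [phenotype_rule()].
#' @param cohort an `ehr_cohort`.
#' @param seed seed for the noise flips (ignored when `label_noise` is 0).
#' @return integer 0/1 label vector with attribute `"prevalence"` (the
#'   realized case fraction after noise).
#' @export
apply_rule <- function(rule, cohort, seed = 1L) {
  m <- ncol(cohort$codes)
  if (any(rule$oracle_codes < 1 | rule$oracle_codes > m)) {
    abort_config("rule oracle codes fall outside the cohort vocabulary")
  }
  present_mat <- cohort$codes[, rule$oracle_codes, drop = FALSE] > 0
  colnames(present_mat) <- as.character(rule$oracle_codes)
  n <- nrow(cohort$codes)
  y <- rep(FALSE, n)
  for (cl in rule$clauses) {
    sat <- rep(TRUE, n)
    for (code in cl$present) sat <- sat & present_mat[, as.character(code)]
    for (code in cl$absent) sat <- sat & !present_mat[, as.character(code)]
    if (length(cl$min_count_set) > 0) {
      cnt <- rowSums(present_mat[, as.character(cl$min_count_set),
                                 drop = FALSE])
      sat <- sat & (cnt >= cl$min_count)
    }
    if (cl$requires_hidden) sat <- sat & cohort$hidden_flag
    y <- y | sat
  }
  y <- as.integer(y)
  if (rule$label_noise > 0) {
    set.seed(seed)
    flip <- runif(n) < rule$label_noise
    y <- ifelse(flip, 1L - y, y)
  }
  attr(y, "prevalence") <- mean(y)
  y
}

#' Oracle-feature combination signatures
#'
#' Encodes, for each patient, the presence/absence pattern of the rule's
#' oracle codes as a binary string: digit `i` is 1 iff `oracle_codes[i]` is
#' in the patient's code set. The hidden qualifier is unobserved and never
#' part of the signature.
#'
#' @param rule a [phenotype_rule()].
#' @param cohort an `ehr_cohort`.
#' @return character vector of binary strings of length
#'   `length(rule$oracle_codes)`, one per patient.
#' @export
oracle_signatures <- function(rule, cohort) {
  present <- as.matrix(cohort$codes[, rule$oracle_codes, drop = FALSE] > 0)
  apply(present, 1, function(row) paste(as.integer(row), collapse = ""))
}

#' @rdname oracle_signatures
#' @param codes integer vector of codes present for one patient.
#' @export
oracle_signature <- function(rule, codes) {
  paste(as.integer(rule$oracle_codes %in% codes), collapse = "")
}

#' Build a rule with an exact number of satisfying combinations
#'
#' Samples `n_satisfying_combinations` of the `2^n_oracle` possible oracle
#' signatures uniformly without replacement and returns the rule that fires
#' exactly on those signatures (each satisfying signature becomes one
#' complete conjunction). Used to study phenotype complexity causally: the
#' satisfying-set size directly controls case diversity.
#'
#' @param n_oracle number of oracle codes.
#' @param n_satisfying_combinations size of the satisfying signature set;
#'   must lie in `1..2^n_oracle`.
#' @param seed integer seed.
#' @param oracle_codes optional explicit code indices (default `1:n_oracle`).
#' @param rule_id identifier for the returned rule.
#' @return a [phenotype_rule()] with attribute `"satisfying_signatures"`,
#'   the sorted character vector of satisfying binary strings.
#' @export
make_complexity_controlled_rule <- function(n_oracle,
                                            n_satisfying_combinations,
                                            seed = 1L,
                                            oracle_codes = seq_len(n_oracle),
                                            rule_id = NULL) {
  if (n_oracle < 1 || n_oracle > 30) {
    abort_config("n_oracle must lie in 1..30")
  }
  total <- 2^n_oracle
  k <- n_satisfying_combinations
  if (k < 1 || k > total) {
    abort_config(sprintf(
      "n_satisfying_combinations must lie in 1..%d", total
    ))
  }
  set.seed(seed)
  chosen <- sort(sample.int(total, k) - 1)  # signature values in 0..2^n-1
  clauses <- lapply(chosen, function(v) {
    bits <- as.integer(intToBits(v))[seq_len(n_oracle)]
    rule_clause(present = oracle_codes[bits == 1],
                absent = oracle_codes[bits == 0])
  })
  sigs <- vapply(chosen, function(v) {
    paste(as.integer(intToBits(v))[seq_len(n_oracle)], collapse = "")
  }, "")
  rule <- phenotype_rule(
    rule_id %||% sprintf("complexity_k%d", k), oracle_codes, clauses
  )
  attr(rule, "satisfying_signatures") <- sort(sigs)
  rule
}

# Enumerate the signatures satisfying a rule's code clauses (ignoring the
# hidden qualifier). Exponential in the oracle count; guarded accordingly.
rule_satisfying_set <- function(rule) {
  p <- length(rule$oracle_codes)
  if (p > 20) abort_config("satisfying-set enumeration limited to 20 oracle codes")
  out <- character(0)
  for (v in 0:(2^p - 1)) {
    bits <- as.integer(intToBits(v))[seq_len(p)]
    present <- rule$oracle_codes[bits == 1]
    sat <- any(vapply(rule$clauses, function(cl) {
      all(cl$present %in% present) && !any(cl$absent %in% present) &&
        (length(cl$min_count_set) == 0 ||
           sum(cl$min_count_set %in% present) >= cl$min_count)
    }, TRUE))
    if (sat) out <- c(out, paste(bits, collapse = ""))
  }
  sort(out)
}

#' Read and write phenotype rules as JSON
#'
#' @param rule a [phenotype_rule()].
#' @param path file path.
#' @return `write_phenotype_rule()` returns `path` invisibly;
#'   `read_phenotype_rule()` returns the reconstructed rule.
#' @export
write_phenotype_rule <- function(rule, path) {
  doc <- list(
    rule_id = rule$rule_id,
    oracle_codes = rule$oracle_codes,
    label_noise = rule$label_noise,
    clauses = lapply(rule$clauses, function(cl) {
      list(present = cl$present, absent = cl$absent,
           min_count_set = cl$min_count_set, min_count = cl$min_count,
           requires_hidden = cl$requires_hidden)
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_phenotype_rule
#' @export
read_phenotype_rule <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  clauses <- lapply(doc$clauses, function(cl) {
    rule_clause(unlist(cl$present) %||% integer(),
                unlist(cl$absent) %||% integer(),
                unlist(cl$min_count_set) %||% integer(),
                cl$min_count %||% 1L,
                isTRUE(cl$requires_hidden))
  })
  phenotype_rule(doc$rule_id, unlist(doc$oracle_codes), clauses,
                 doc$label_noise %||% 0)
}
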