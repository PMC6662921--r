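# Synthetic EHR cohort generator.
#
# The generative model is a set of latent disease factors. Each factor,
# when active in a patient, emits a characteristic set of codes with
# per-(factor, code) emission probabilities; on top of that every code can
# appear spontaneously at a per-code background rate (noisy-OR union). This
# induces code co-occurrence blocks, so that phecode-style groupings of
# codes carry signal about the latent state that also drives rule-defined
# phenotypes -- the structure multitask learning is supposed to exploit.
#
# Two optional couplings add the correlation structure of real EHR data: a
# standard-normal per-patient health state can shift every factor's
# activation odds (comorbidity: sick patients have more of everything) and
# scale the background code rates (utilization: sick patients accumulate
# more codes overall, a classic confounder for code-count features).

#' Configuration for a synthetic EHR cohort
#'
#' @param n_patients number of patients to simulate.
#' @param n_codes size of the abstract code vocabulary. Codes are indices
#'   `1..n_codes` with no ICD/CPT/RxNorm semantics.
#' @param n_latent number of latent disease factors.
#' @param latent_prevalences numeric vector of length `n_latent`; marginal
#'   probability that each factor is active in a patient. Factors are
#'   sampled independently.
#' @param emission_probs `n_latent x n_codes` matrix; entry `(l, j)` is the
#'   probability that active factor `l` emits code `j`. May be a base matrix
#'   or a sparse [Matrix::Matrix].
#' @param background_rate scalar or length-`n_codes` vector of spontaneous
#'   occurrence probabilities per code.
#' @param hidden_flag_rate probability that a patient carries the hidden
#'   (never featurized) qualifier used by phenotype rules to cap attainable
#'   classifier performance.
#' @param comorbidity_scale coefficient on the patient's latent health
#'   state in each factor's activation log-odds. 0 (default) gives
#'   independent factors; positive values induce comorbidity correlation
#'   between all factors.
#' @param utilization_sd log-scale standard deviation of the per-patient
#'   background-rate multiplier, driven by the same health state (mean
#'   multiplier 1). 0 (default) disables utilization heterogeneity.
#' @param demographic_levels named list of factor levels for the demographic
#'   variables (`sex`, `race`, `ethnicity`, `age`). Defaults give
#'   2 + 5 + 2 + 100 indicator columns.
#' @param seed integer seed; identical config + seed gives an identical
#'   cohort.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients, n_codes, n_latent,
                          latent_prevalences, emission_probs,
                          background_rate,
                          hidden_flag_rate = 0,
                          comorbidity_scale = 0,
                          utilization_sd = 0,
                          demographic_levels = default_demographic_levels(),
                          seed = 1L) {
  if (length(n_patients) != 1 || n_patients < 1 ||
      length(n_codes) != 1 || n_codes < 1 ||
      length(n_latent) != 1 || n_latent < 1) {
    abort_config("n_patients, n_codes and n_latent must be positive counts")
  }
  latent_prevalences <- as.numeric(latent_prevalences)
  if (length(latent_prevalences) != n_latent) {
    abort_config("latent_prevalences must have length n_latent")
  }
  if (any(latent_prevalences < 0 | latent_prevalences > 1)) {
    abort_config("latent_prevalences must lie in [0, 1]")
  }
  if (is.null(dim(emission_probs)) ||
      nrow(emission_probs) != n_latent || ncol(emission_probs) != n_codes) {
    abort_config("emission_probs must be an n_latent x n_codes matrix")
  }
  if (any(emission_probs < 0) || any(emission_probs > 1)) {
    abort_config("emission_probs must lie in [0, 1]")
  }
  if (length(background_rate) == 1) {
    background_rate <- rep(as.numeric(background_rate), n_codes)
  }
  if (length(background_rate) != n_codes ||
      any(background_rate < 0 | background_rate > 1)) {
    abort_config("background_rate must be a probability (scalar or per-code)")
  }
  if (length(hidden_flag_rate) != 1 ||
      hidden_flag_rate < 0 || hidden_flag_rate > 1) {
    abort_config("hidden_flag_rate must be a probability in [0, 1]")
  }
  if (comorbidity_scale < 0 || utilization_sd < 0) {
    abort_config("comorbidity_scale and utilization_sd must be nonnegative")
  }
  structure(
    list(
      n_patients = as.integer(n_patients),
      n_codes = as.integer(n_codes),
      n_latent = as.integer(n_latent),
      latent_prevalences = latent_prevalences,
      emission_probs = emission_probs,
      background_rate = background_rate,
      hidden_flag_rate = as.numeric(hidden_flag_rate),
      comorbidity_scale = as.numeric(comorbidity_scale),
      utilization_sd = as.numeric(utilization_sd),
      demographic_levels = demographic_levels,
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

#' Default demographic level sets
#'
#' Two sex categories, five race categories, two ethnicity categories and
#' integer ages 0-99, matching the indicator-per-level encoding used for the
#' feature matrix.
#' @return named list of character level vectors.
#' @export
default_demographic_levels <- function() {
  list(
    sex = c("female", "male"),
    race = paste0("race_", 1:5),
    ethnicity = c("hispanic", "not_hispanic"),
    age = as.character(0:99)
  )
}

#' Generate a synthetic cohort
#'
#' Samples latent factor activations independently per patient, emits codes
#' from active factors, adds background code noise, and attaches signal-free
#' demographics and the hidden rule qualifier.
#'
#' @param config a [cohort_config()].
#' @return an object of class `ehr_cohort`: a list with components
#'   `codes` (sparse patients-by-codes 0/1 matrix), `latent_flags`
#'   (patients-by-factors logical matrix), `hidden_flag` (logical vector),
#'   `demographics` (data frame with `patient_id`, `age`, `sex`, `race`,
#'   `ethnicity`), and the originating `config`.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) {
    abort_config("config must be a cohort_config object")
  }
  n <- config$n_patients
  m <- config$n_codes
  L <- config$n_latent
  set.seed(config$seed)

  # latent health state drives comorbidity and utilization couplings
  health <- rnorm(n)

  latent <- matrix(FALSE, n, L)
  for (l in seq_len(L)) {
    p <- config$latent_prevalences[l]
    if (config$comorbidity_scale > 0 && p > 0 && p < 1) {
      p <- stats::plogis(stats::qlogis(p) +
                           config$comorbidity_scale * health)
    }
    latent[, l] <- runif(n) < p
  }
  hidden_flag <- runif(n) < config$hidden_flag_rate

  # Background occurrences, sampled per code to stay sparse. With
  # utilization heterogeneity each patient's rates are scaled by a
  # log-normal multiplier with mean 1.
  if (config$utilization_sd > 0) {
    util <- exp(config$utilization_sd * health -
                  config$utilization_sd^2 / 2)
  } else {
    util <- NULL
  }
  bg_i <- vector("list", m)
  for (j in seq_len(m)) {
    p <- config$background_rate[j]
    if (p > 0) {
      if (is.null(util)) {
        k <- rbinom(1, n, p)
        if (k > 0) bg_i[[j]] <- sample.int(n, k)
      } else {
        who <- which(runif(n) < pmin(p * util, 1))
        if (length(who) > 0) bg_i[[j]] <- who
      }
    }
  }
  tr_i <- unlist(bg_i)
  tr_j <- rep.int(seq_len(m), vapply(bg_i, length, 1L))

  # Factor emissions: only the patients with the factor active can emit.
  em <- config$emission_probs
  for (l in seq_len(L)) {
    active <- which(latent[, l])
    if (length(active) == 0) next
    code_idx <- which(em[l, ] > 0)
    for (j in code_idx) {
      p <- em[l, j]
      k <- rbinom(1, length(active), p)
      if (k > 0) {
        who <- active[sample.int(length(active), k)]
        tr_i <- c(tr_i, who)
        tr_j <- c(tr_j, rep.int(j, k))
      }
    }
  }

  codes <- sparseMatrix(i = tr_i, j = tr_j, x = 1, dims = c(n, m))
  codes@x[] <- 1  # collapse duplicate (background + emission) occurrences

  lv <- config$demographic_levels
  demographics <- data.frame(
    patient_id = sprintf("P%06d", seq_len(n)),
    age = sample(lv$age, n, replace = TRUE),
    sex = sample(lv$sex, n, replace = TRUE),
    race = sample(lv$race, n, replace = TRUE),
    ethnicity = sample(lv$ethnicity, n, replace = TRUE),
    stringsAsFactors = FALSE
  )

  structure(
    list(
      codes = codes,
      latent_flags = latent,
      hidden_flag = hidden_flag,
      health = health,
      demographics = demographics,
      config = config
    ),
    class = "ehr_cohort"
  )
}

#' Assemble a cohort from explicit per-patient code sets
#'
#' Constructor for user-supplied or hand-built data (e.g. a binary
#' patient-by-code table read from disk), producing the same container that
#' [generate_cohort()] returns so all downstream tooling applies.
#'
#' @param code_sets list of integer vectors; codes present per patient
#'   (1-based indices into the vocabulary).
#' @param n_codes vocabulary size.
#' @param hidden_flag optional logical vector (default all `FALSE`).
#' @param demographics optional data frame; a signal-free default is built
#'   when omitted.
#' @param demographic_levels level sets for the demographic variables.
#' @param seed seed used only for the default demographics.
#' @return an `ehr_cohort`.
#' @export
as_ehr_cohort <- function(code_sets, n_codes, hidden_flag = NULL,
                          demographics = NULL,
                          demographic_levels = default_demographic_levels(),
                          seed = 1L) {
  n <- length(code_sets)
  lens <- vapply(code_sets, length, 1L)
  tr_j <- unlist(code_sets)
  if (length(tr_j) > 0 && (min(tr_j) < 1 || max(tr_j) > n_codes)) {
    abort_config("code indices must lie in 1..n_codes")
  }
  codes <- sparseMatrix(
    i = rep.int(seq_len(n), lens), j = as.integer(tr_j),
    x = 1, dims = c(n, n_codes)
  )
  codes@x[] <- 1
  if (is.null(hidden_flag)) hidden_flag <- rep(FALSE, n)
  if (is.null(demographics)) {
    set.seed(seed)
    lv <- demographic_levels
    demographics <- data.frame(
      patient_id = sprintf("P%06d", seq_len(n)),
      age = sample(lv$age, n, replace = TRUE),
      sex = sample(lv$sex, n, replace = TRUE),
      race = sample(lv$race, n, replace = TRUE),
      ethnicity = sample(lv$ethnicity, n, replace = TRUE),
      stringsAsFactors = FALSE
    )
  }
  config <- list(
    n_patients = n, n_codes = as.integer(n_codes),
    demographic_levels = demographic_levels
  )
  structure(
    list(
      codes = codes,
      latent_flags = matrix(FALSE, n, 0),
      hidden_flag = hidden_flag,
      demographics = demographics,
      config = config
    ),
    class = "ehr_cohort"
  )
}

#' @export
print.ehr_cohort <- function(x, ...) {
  cat(sprintf(
    "<ehr_cohort> %d patients, %d codes, %.1f codes/patient, %d latent factors\n",
    nrow(x$codes), ncol(x$codes), mean(rowSums(x$codes)),
    ncol(x$latent_flags)
  ))
  invisible(x)
}

#' Phecode-style code grouping
#'
#' @param group_id identifier.
#' @param member_codes non-empty vector of code indices (1-based). Groups
#'   may overlap.
#' @return an object of class `phecode_group`.
#' @export
phecode_group <- function(group_id, member_codes) {
  member_codes <- unique(as.integer(member_codes))
  if (length(member_codes) == 0) {
    abort_config(sprintf("phecode group '%s' has no member codes", group_id))
  }
  structure(list(group_id = as.character(group_id),
                 member_codes = member_codes),
            class = "phecode_group")
}

#' Randomly construct phecode-style groups
#'
#' Each group draws its member codes without replacement from the
#' vocabulary, optionally with per-code weights (e.g. to concentrate groups
#' on codes belonging to latent-factor blocks).
#'
#' @param n_groups number of groups.
#' @param n_codes vocabulary size.
#' @param size_range integer length-2 vector; group sizes are drawn
#'   uniformly from this range.
#' @param weights optional per-code sampling weights.
#' @param seed integer seed.
#' @return list of [phecode_group()] objects.
#' @export
make_phecode_groups <- function(n_groups, n_codes, size_range = c(3L, 6L),
                                weights = NULL, seed = 1L) {
  set.seed(seed)
  lapply(seq_len(n_groups), function(g) {
    size <- sample(size_range[1]:size_range[2], 1)
    members <- sample.int(n_codes, size, prob = weights)
    phecode_group(sprintf("phecode_%03d", g), members)
  })
}

#' Derive binary phecode labels
#'
#' A patient is labeled 1 for a group iff their code set intersects the
#' group's member codes.
#'
#' @param cohort an `ehr_cohort`.
#' @param groups list of [phecode_group()] objects.
#' @return integer 0/1 matrix, patients by groups, with group ids as column
#'   names.
#' @export
derive_phecode_labels <- function(cohort, groups) {
  m <- ncol(cohort$codes)
  for (g in groups) {
    if (length(g$member_codes) == 0) {
      abort_config("phecode group with no member codes")
    }
    if (any(g$member_codes < 1 | g$member_codes > m)) {
      abort_config(sprintf(
        "group '%s' references codes outside the vocabulary", g$group_id
      ))
    }
  }
  labels <- vapply(groups, function(g) {
    as.integer(rowSums(cohort$codes[, g$member_codes, drop = FALSE]) > 0)
  }, integer(nrow(cohort$codes)))
  if (nrow(cohort$codes) == 1) labels <- matrix(labels, nrow = 1)
  colnames(labels) <- vapply(groups, `[[`, "", "group_id")
  labels
}

#' Sample nested auxiliary task sets
#'
#' Filters groups to those whose empirical label prevalence lies in
#' `[prevalence_low, prevalence_high]`, draws the largest requested set
#' uniformly without replacement, and returns each smaller set as a prefix
#' of the larger, so the sets are strictly nested.
#'
#' @param label_matrix patients-by-groups 0/1 matrix from
#'   [derive_phecode_labels()].
#' @param prevalence_low,prevalence_high inclusive eligibility band.
#' @param sizes ascending vector of set sizes, e.g. `c(5, 10, 20)`.
#' @param seed integer seed.
#' @return named list of integer column-index vectors, one per size; the
#'   set for a smaller size is always a prefix of the next larger set.
#' @export
sample_auxiliary_tasks <- function(label_matrix, prevalence_low,
                                   prevalence_high, sizes, seed = 1L) {
  sizes <- sort(as.integer(sizes))
  prev <- colMeans(label_matrix)
  eligible <- which(prev >= prevalence_low & prev <= prevalence_high)
  if (length(eligible) < max(sizes)) {
    abort_insufficient_tasks(sprintf(
      "need %d eligible phecode groups in prevalence band [%g, %g] but only %d qualify (short by %d)",
      max(sizes), prevalence_low, prevalence_high, length(eligible),
      max(sizes) - length(eligible)
    ))
  }
  set.seed(seed)
  largest <- eligible[sample.int(length(eligible), max(sizes))]
  out <- lapply(sizes, function(s) largest[seq_len(s)])
  names(out) <- paste0("aux", sizes)
  out
}

#' Export a cohort to plain-text files
#'
#' Writes `demographics.tsv` (patient id + demographic columns),
#' `codes.tsv` (sparse triplets: patient_id, code_index, value), optionally
#' `labels.tsv`, and `cohort_config.json` recording the generating
#' configuration and the realized label prevalences.
#'
#' @param cohort an `ehr_cohort`.
#' @param dir output directory (created if missing).
#' @param labels optional named list of label vectors to export alongside.
#' @return `dir`, invisibly.
#' @export
export_cohort <- function(cohort, dir, labels = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.table(cohort$demographics, file.path(dir, "demographics.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  trip <- Matrix::summary(cohort$codes)
  triplets <- data.frame(
    patient_id = cohort$demographics$patient_id[trip$i],
    code_index = trip$j, value = 1L
  )
  write.table(triplets, file.path(dir, "codes.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  realized <- NULL
  if (!is.null(labels)) {
    lab_df <- data.frame(patient_id = cohort$demographics$patient_id,
                         as.data.frame(labels))
    write.table(lab_df, file.path(dir, "labels.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    realized <- lapply(labels, mean)
  }
  cfg <- cohort$config
  sidecar <- list(
    n_patients = cfg$n_patients,
    n_codes = cfg$n_codes,
    n_latent = cfg$n_latent,
    latent_prevalences = cfg$latent_prevalences,
    background_rate = cfg$background_rate,
    hidden_flag_rate = cfg$hidden_flag_rate,
    seed = cfg$seed,
    realized_prevalences = realized
  )
  jsonlite::write_json(sidecar, file.path(dir, "cohort_config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
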