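# Phenotype complexity over oracle-feature combinations.
#
# Each patient's oracle-code presence pattern is a binary string. The
# strings are mapped to a fixed number of buckets -- by 32-bit FNV-1a
# hashing, or by direct binary indexing when every combination fits -- and
# the case/control bucket histograms are summarized by Shannon entropy of
# the case distribution (diversity of positive cases) and the KL divergence
# from controls to cases (how distinguishable cases are from controls).

# 32-bit FNV-1a over the characters of a string, in double arithmetic with
# a split multiply so every intermediate stays exact below 2^53. Stable
# across platforms and R sessions; no RNG involved.
fnv1a32 <- function(strings) {
  prime <- 16777619
  vapply(strings, function(s) {
    h <- 2166136261
    for (byte in utf8ToInt(s)) {
      low8 <- h %% 256
      h <- h - low8 + bitwXor(as.integer(low8), byte)
      lo <- h %% 65536
      hi <- (h - lo) / 65536
      h <- (lo * prime + ((hi * prime) %% 65536) * 65536) %% 4294967296
    }
    h
  }, numeric(1), USE.NAMES = FALSE)
}

# Map binary-string signatures to bucket indices in 0..n_buckets-1.
# mode "direct" interprets the string as a binary number (injective when
# 2^nchar <= n_buckets); "fnv1a32" hashes; "auto" picks direct when it is
# injective for the observed signature length, else the hash.
bucket_signatures <- function(signatures, n_buckets, hash_name = "auto") {
  lens <- unique(nchar(signatures))
  if (hash_name == "auto") {
    hash_name <- if (length(lens) == 1 && 2^lens[1] <= n_buckets) {
      "direct"
    } else {
      "fnv1a32"
    }
  }
  idx <- switch(hash_name,
    direct = strtoi(signatures, base = 2) %% n_buckets,
    fnv1a32 = {
      u <- unique(signatures)
      unname(setNames(fnv1a32(u) %% n_buckets, u)[signatures])
    },
    abort_config(sprintf("unknown hash '%s'", hash_name))
  )
  list(bucket = idx, hash_name = hash_name)
}

#' Bucket histograms of oracle-feature combinations
#'
#' Counts case and control occurrences of each hashed combination bucket.
#'
#' @param signatures_pos,signatures_neg character vectors of binary
#'   signature strings (see [oracle_signatures()]) for cases and controls;
#'   both must be non-empty.
#' @param n_buckets number of buckets (default 32).
#' @param hash_name `"auto"` (default), `"fnv1a32"`, or `"direct"`.
#'   Direct indexing interprets the signature as a binary number and is
#'   collision-free when `2^length <= n_buckets`.
#' @return a `bucket_histogram`: `n_buckets`, integer vectors `counts_pos`
#'   and `counts_neg` summing to the input sizes, and the `hash_name`
#'   actually used.
#' @export
build_histogram <- function(signatures_pos, signatures_neg, n_buckets = 32,
                            hash_name = "auto") {
  if (length(signatures_pos) == 0 || length(signatures_neg) == 0) {
    abort_insufficient_data(
      "need at least one case and one control signature"
    )
  }
  all_sigs <- c(signatures_pos, signatures_neg)
  bk <- bucket_signatures(all_sigs, n_buckets, hash_name)
  is_pos <- rep(c(TRUE, FALSE),
                c(length(signatures_pos), length(signatures_neg)))
  counts_pos <- tabulate(bk$bucket[is_pos] + 1L, nbins = n_buckets)
  counts_neg <- tabulate(bk$bucket[!is_pos] + 1L, nbins = n_buckets)
  structure(
    list(n_buckets = as.integer(n_buckets), counts_pos = counts_pos,
         counts_neg = counts_neg, hash_name = bk$hash_name),
    class = "bucket_histogram"
  )
}

#' Shannon entropy of a count histogram
#'
#' Normalizes the counts to a probability distribution and returns
#' `-sum(p * log(p))` with the `0 * log(0) = 0` convention. Natural
#' logarithm by default, so the maximum over `n` buckets is `log(n)` nats.
#'
#' @param counts nonnegative count (or probability) vector with at least
#'   one nonzero entry.
#' @param base logarithm base (default `exp(1)` for nats; use 2 for bits).
#' @return entropy in `[0, log(length(counts))]`.
#' @export
shannon_entropy <- function(counts, base = exp(1)) {
  if (any(counts < 0)) abort_config("counts must be nonnegative")
  total <- sum(counts)
  if (total == 0) abort_insufficient_data("entropy of an all-zero histogram")
  p <- counts[counts > 0] / total
  -sum(p * log(p)) / log(base)
}

#' Kullback-Leibler divergence between case and control histograms
#'
#' Adds `smoothing_alpha` to every raw count in both vectors, normalizes
#' to distributions `P+` (cases) and `P-` (controls), and returns
#' `sum(P+ * log(P+ / P-))`, the divergence from controls to cases.
#' Nonnegative by Gibbs' inequality; zero iff the smoothed distributions
#' coincide. With `smoothing_alpha = 0` and a case bucket unmatched by any
#' control mass the divergence is infinite, which is reported with a
#' warning.
#'
#' @param counts_pos,counts_neg equal-length nonnegative count vectors,
#'   each with at least one nonzero entry.
#' @param smoothing_alpha additive smoothing applied to every bucket
#'   (default 0.5).
#' @param base logarithm base (default natural log).
#' @return KL divergence in `[0, Inf]`.
#' @export
kl_divergence <- function(counts_pos, counts_neg, smoothing_alpha = 0.5,
                          base = exp(1)) {
  if (length(counts_pos) != length(counts_neg)) {
    abort_shape("count vectors must have the same length")
  }
  if (sum(counts_pos) == 0 || sum(counts_neg) == 0) {
    abort_insufficient_data("KL divergence of an all-zero histogram")
  }
  if (smoothing_alpha < 0) abort_config("smoothing_alpha must be >= 0")
  p <- (counts_pos + smoothing_alpha) /
    sum(counts_pos + smoothing_alpha)
  q <- (counts_neg + smoothing_alpha) /
    sum(counts_neg + smoothing_alpha)
  keep <- p > 0
  if (any(q[keep] == 0)) {
    warning("case bucket with zero control mass and no smoothing: KL divergence is infinite")
    return(Inf)
  }
  sum(p[keep] * log(p[keep] / q[keep])) / log(base)
}

#' Phenotype complexity report
#'
#' Pipelines [oracle_signatures()] -> [build_histogram()] ->
#' [shannon_entropy()] + [kl_divergence()] for one rule on a labeled
#' cohort.
#'
#' @param rule a [phenotype_rule()].
#' @param cohort an `ehr_cohort`.
#' @param labels binary 0/1 case labels aligned with the cohort (e.g. from
#'   [apply_rule()]); at least one case and one control.
#' @param n_buckets number of histogram buckets (default 32).
#' @param smoothing_alpha additive smoothing for the KL divergence
#'   (default 0.5).
#' @param hash_name bucket mapping mode, see [build_histogram()].
#' @param base logarithm base (default natural log).
#' @return a `complexity_report`: `rule_id`, `prevalence`, `entropy_pos`,
#'   `kl_pos_vs_neg`, `smoothing_alpha`, `base`, and the
#'   `bucket_histogram`.
#' @export
complexity_report <- function(rule, cohort, labels, n_buckets = 32,
                              smoothing_alpha = 0.5, hash_name = "auto",
                              base = exp(1)) {
  if (length(labels) != nrow(cohort$codes)) {
    abort_shape("labels must align with the cohort")
  }
  sigs <- oracle_signatures(rule, cohort)
  hist <- build_histogram(sigs[labels == 1], sigs[labels != 1],
                          n_buckets = n_buckets, hash_name = hash_name)
  structure(
    list(
      rule_id = rule$rule_id,
      prevalence = mean(labels == 1),
      entropy_pos = shannon_entropy(hist$counts_pos, base = base),
      kl_pos_vs_neg = kl_divergence(hist$counts_pos, hist$counts_neg,
                                    smoothing_alpha, base = base),
      smoothing_alpha = smoothing_alpha,
      base = base,
      histogram = hist
    ),
    class = "complexity_report"
  )
}

#' @export
print.complexity_report <- function(x, ...) {
  cat(sprintf(
    "<complexity_report> '%s': prevalence %.4f, entropy %.3f, KL %.3f (%d buckets, %s, alpha %.2f)\n",
    x$rule_id, x$prevalence, x$entropy_pos, x$kl_pos_vs_neg,
    x$histogram$n_buckets, x$histogram$hash_name, x$smoothing_alpha
  ))
  invisible(x)
}

#' Complexity table for several rules
#'
#' Convenience wrapper producing one row per rule, suitable for writing to
#' CSV: rule id, prevalence, entropy, KL divergence, bucket count,
#' smoothing and hash used.
#'
#' @param rules list of [phenotype_rule()] objects.
#' @param cohort an `ehr_cohort`.
#' @param labels_list list of label vectors, parallel to `rules`.
#' @inheritParams complexity_report
#' @return a data frame with one row per rule.
#' @export
complexity_table <- function(rules, cohort, labels_list, n_buckets = 32,
                             smoothing_alpha = 0.5, hash_name = "auto",
                             base = exp(1)) {
  rows <- mapply(function(rule, labels) {
    rep <- complexity_report(rule, cohort, labels, n_buckets,
                             smoothing_alpha, hash_name, base)
    data.frame(
      rule_id = rep$rule_id, prevalence = rep$prevalence,
      entropy = rep$entropy_pos, kl_divergence = rep$kl_pos_vs_neg,
      n_buckets = rep$histogram$n_buckets, alpha = rep$smoothing_alpha,
      hash_name = rep$histogram$hash_name, stringsAsFactors = FALSE
    )
  }, rules, labels_list, SIMPLIFY = FALSE)
  do.call(rbind, rows)
}
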