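test_that("the FNV-1a hash matches its published test vectors", {
  # stability contract: same values on every platform and run
  expect_equal(ehrmtl:::fnv1a32(""), 2166136261)
  expect_equal(ehrmtl:::fnv1a32("a"), 0xe40c292c)
  expect_equal(ehrmtl:::fnv1a32("foobar"), 0xbf9cf968)
  expect_identical(ehrmtl:::fnv1a32(c("0101", "0101")),
                   rep(ehrmtl:::fnv1a32("0101"), 2))
})

test_that("histograms conserve counts and separate cases from controls", {
  set.seed(5)
  sig <- function(n) {
    vapply(seq_len(n), function(i) {
      paste(sample(0:1, 6, replace = TRUE), collapse = "")
    }, "")
  }
  pos <- sig(1000)
  neg <- sig(1000)
  h <- build_histogram(pos, neg, n_buckets = 32)
  expect_equal(sum(h$counts_pos), 1000)
  expect_equal(sum(h$counts_neg), 1000)
  expect_true(all(h$counts_pos >= 0))

  # all cases share one signature -> single nonzero bucket
  h1 <- build_histogram(rep("0110", 50), neg, n_buckets = 32)
  expect_equal(sum(h1$counts_pos > 0), 1)

  expect_error(build_histogram(character(0), neg),
               class = "ehrmtl_insufficient_data_error")
})

test_that("direct indexing is injective when all combinations fit", {
  sigs <- vapply(0:31, function(v) {
    paste(as.integer(intToBits(v))[1:5], collapse = "")
  }, "")
  h <- build_histogram(sigs, sigs, n_buckets = 32, hash_name = "direct")
  expect_equal(h$counts_pos, rep(1L, 32))
  # auto mode picks direct here
  expect_equal(build_histogram(sigs, sigs, n_buckets = 32)$hash_name,
               "direct")
  # and falls back to hashing for longer signatures
  expect_equal(build_histogram("0101010", "1111111", n_buckets = 32)$hash_name,
               "fnv1a32")
})

test_that("entropy matches closed-form values", {
  expect_equal(shannon_entropy(c(0, 7, 0)), 0)
  expect_equal(shannon_entropy(rep(3, 32)), log(32))
  expect_equal(shannon_entropy(c(3, 1)),
               -(0.75 * log(0.75) + 0.25 * log(0.25)))
  expect_equal(shannon_entropy(c(1, 1), base = 2), 1)
  expect_error(shannon_entropy(c(0, 0)),
               class = "ehrmtl_insufficient_data_error")
  expect_error(shannon_entropy(c(-1, 2)), class = "ehrmtl_config_error")
})

test_that("KL divergence matches closed-form values and edge cases", {
  expect_equal(kl_divergence(c(5, 5, 2), c(5, 5, 2)), 0)
  expect_equal(kl_divergence(c(3, 1), c(2, 2), smoothing_alpha = 0),
               0.75 * log(1.5) + 0.25 * log(0.5))
  # smoothing keeps disjoint supports finite
  v <- kl_divergence(c(4, 0), c(0, 4), smoothing_alpha = 0.5)
  expect_equal(v, 0.9 * log(9) + 0.1 * log(1 / 9))
  expect_warning(
    inf_v <- kl_divergence(c(4, 0), c(0, 4), smoothing_alpha = 0),
    "infinite"
  )
  expect_identical(inf_v, Inf)
  expect_error(kl_divergence(c(1, 2), c(1, 2, 3)),
               class = "ehrmtl_shape_error")
})

test_that("KL divergence is nonnegative across random histogram pairs", {
  set.seed(77)
  for (i in 1:200) {
    a <- rmultinom(1, 200, runif(16))[, 1]
    b <- rmultinom(1, 200, runif(16))[, 1]
    expect_gte(kl_divergence(a, b), 0)
  }
})

test_that("entropy never exceeds log(n_buckets) and shrinks with buckets", {
  set.seed(41)
  for (i in 1:20) {
    sigs <- vapply(1:500, function(j) {
      paste(sample(0:1, 8, replace = TRUE), collapse = "")
    }, "")
    ent <- vapply(c(8, 16, 32), function(nb) {
      h <- build_histogram(sigs, "00000000", n_buckets = nb,
                           hash_name = "fnv1a32")
      e <- shannon_entropy(h$counts_pos)
      expect_lte(e, log(nb) + 1e-12)
      e
    }, numeric(1))
    # coarser bucketing cannot increase entropy of the same multiset
    expect_true(all(diff(ent) >= -1e-12))
  }
})

test_that("complexity_report pipelines rules through to both metrics", {
  # rule with one satisfying combination: all cases identical
  co <- codeset_cohort(c(replicate(30, c(1L, 2L), simplify = FALSE),
                         replicate(100, integer(0), simplify = FALSE)), 10)
  r <- phenotype_rule("point", c(1, 2), list(rule_clause(present = c(1, 2))))
  y <- apply_rule(r, co)
  rep <- complexity_report(r, co, y)
  expect_equal(rep$entropy_pos, 0)
  expect_gt(rep$kl_pos_vs_neg, 0)
  expect_equal(rep$prevalence, 30 / 130)

  tab <- complexity_table(list(r), co, list(y))
  expect_equal(nrow(tab), 1)
  expect_equal(tab$entropy, 0)
  expect_error(complexity_report(r, co, rep(0, 130)),
               class = "ehrmtl_insufficient_data_error")
})
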