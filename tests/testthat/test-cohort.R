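test_that("degenerate rates give empty or saturated code sets", {
  cfg0 <- cohort_config(50, 10, 1, latent_prevalences = 0.5,
                        emission_probs = matrix(0, 1, 10),
                        background_rate = 0, seed = 3)
  co0 <- generate_cohort(cfg0)
  expect_equal(sum(co0$codes), 0)

  cfg1 <- cohort_config(50, 1, 1, latent_prevalences = 1,
                        emission_probs = matrix(1, 1, 1),
                        background_rate = 0, seed = 3)
  co1 <- generate_cohort(cfg1)
  expect_equal(as.numeric(co1$codes[, 1]), rep(1, 50))
})

test_that("latent factor activation follows its prevalence", {
  n <- 10000
  p <- 0.05
  cfg <- cohort_config(n, 5, 1, latent_prevalences = p,
                       emission_probs = matrix(0, 1, 5),
                       background_rate = 0, seed = 11)
  co <- generate_cohort(cfg)
  count <- sum(co$latent_flags[, 1])
  sd3 <- 3 * sqrt(n * p * (1 - p))
  expect_lt(abs(count - n * p), sd3)
})

test_that("identical config and seed give byte-identical cohorts", {
  cfg <- cohort_config(200, 30, 2, latent_prevalences = c(0.2, 0.1),
                       emission_probs = matrix(0.1, 2, 30),
                       background_rate = 0.05, hidden_flag_rate = 0.3,
                       seed = 99)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
})

test_that("invalid configurations are rejected", {
  expect_error(
    cohort_config(0, 10, 1, 0.5, matrix(0, 1, 10), 0.1),
    class = "ehrmtl_config_error"
  )
  expect_error(
    cohort_config(10, 10, 1, 1.5, matrix(0, 1, 10), 0.1),
    class = "ehrmtl_config_error"
  )
  expect_error(
    cohort_config(10, 10, 1, 0.5, matrix(2, 1, 10), 0.1),
    class = "ehrmtl_config_error"
  )
  expect_error(
    cohort_config(10, 10, 1, 0.5, matrix(0, 1, 10), -0.1),
    class = "ehrmtl_config_error"
  )
})

test_that("background marginal frequency matches the configured rate", {
  # emission structure off: every code is a pure Bernoulli(background)
  n <- 50000
  rates <- c(0.002, 0.01, 0.05)
  co <- background_only_cohort(n, 3, rates, seed = 7)
  freq <- Matrix::colSums(co$codes)
  for (j in 1:3) {
    sd4 <- 4 * sqrt(n * rates[j] * (1 - rates[j]))
    expect_lt(abs(freq[j] - n * rates[j]), sd4)
  }
})

test_that("factor-positive patients overlap the factor's codes more", {
  em <- matrix(0, 1, 20)
  em[1, 1:5] <- 0.4
  cfg <- cohort_config(5000, 20, 1, latent_prevalences = 0.3,
                       emission_probs = em, background_rate = 0.02,
                       seed = 21)
  co <- generate_cohort(cfg)
  overlap <- Matrix::rowSums(co$codes[, 1:5])
  expect_gt(mean(overlap[co$latent_flags[, 1]]),
            mean(overlap[!co$latent_flags[, 1]]))
})

test_that("phecode labels are code-set intersections", {
  co <- codeset_cohort(list(c(3L, 7L), integer(0), c(9L)), 10)
  groups <- list(phecode_group("g1", c(7, 9)), phecode_group("g2", c(1, 2)))
  labs <- derive_phecode_labels(co, groups)
  expect_equal(unname(labs[, "g1"]), c(1L, 0L, 1L))
  expect_equal(unname(labs[1, "g2"]), 0L)
  expect_equal(unname(labs[2, ]), c(0L, 0L))  # empty code set
})

test_that("single-member group prevalence equals the code frequency", {
  co <- background_only_cohort(10000, 5, 0.07, seed = 13)
  labs <- derive_phecode_labels(co, list(phecode_group("g", 2)))
  expect_equal(mean(labs[, "g"]), Matrix::colSums(co$codes)[2] / 10000)
})

test_that("empty phecode groups are rejected", {
  expect_error(phecode_group("g", integer(0)), class = "ehrmtl_config_error")
  co <- codeset_cohort(list(1L), 5)
  g <- phecode_group("g", 3)
  g$member_codes <- integer(0)
  expect_error(derive_phecode_labels(co, list(g)),
               class = "ehrmtl_config_error")
  expect_error(derive_phecode_labels(co, list(phecode_group("g", 99))),
               class = "ehrmtl_config_error")
})

test_that("auxiliary task sets are nested, reproducible, and checked", {
  set.seed(1)
  labs <- matrix(rbinom(1000 * 30, 1, 0.02), 1000, 30)
  sets <- sample_auxiliary_tasks(labs, 0, 1, c(5, 10, 20), seed = 4)
  expect_true(all(sets$aux5 %in% sets$aux10))
  expect_true(all(sets$aux10 %in% sets$aux20))
  expect_length(unique(sets$aux20), 20)
  expect_identical(sets, sample_auxiliary_tasks(labs, 0, 1, c(5, 10, 20),
                                                seed = 4))
  # empty eligibility band
  expect_error(
    sample_auxiliary_tasks(labs, 0.9, 0.99, c(5, 10, 20), seed = 4),
    class = "ehrmtl_insufficient_tasks_error"
  )
  expect_error(
    sample_auxiliary_tasks(labs, 0.9, 0.99, c(5), seed = 4),
    regexp = "short by"
  )
})

test_that("cohort export writes consistent plain-text files", {
  dir <- withr::local_tempdir()
  co <- background_only_cohort(100, 10, 0.1, seed = 5)
  export_cohort(co, dir, labels = list(target = rep(c(0L, 1L), 50)))
  demo <- read.table(file.path(dir, "demographics.tsv"), header = TRUE,
                     sep = "\t")
  expect_equal(nrow(demo), 100)
  trip <- read.table(file.path(dir, "codes.tsv"), header = TRUE, sep = "\t")
  expect_equal(nrow(trip), sum(co$codes))
  side <- jsonlite::read_json(file.path(dir, "cohort_config.json"))
  expect_equal(side$n_patients, 100)
  expect_equal(side$realized_prevalences$target, 0.5)
})
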