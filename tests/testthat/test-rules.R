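test_that("single-literal and unsatisfiable rules label as expected", {
  co <- codeset_cohort(list(c(5L), c(1L, 2L), integer(0)), 10)
  r <- phenotype_rule("r", 5, list(rule_clause(present = 5)))
  y <- apply_rule(r, co)
  expect_equal(as.integer(y), c(1L, 0L, 0L))
  expect_equal(attr(y, "prevalence"), 1 / 3)

  # codes never present -> all-zero labels
  r2 <- phenotype_rule("r2", c(9, 10),
                       list(rule_clause(present = c(9, 10))))
  y2 <- apply_rule(r2, co)
  expect_equal(sum(y2), 0)
  expect_equal(attr(y2, "prevalence"), 0)
})

test_that("absence literals and the hidden qualifier gate clauses", {
  co <- codeset_cohort(list(c(1L), c(1L, 2L), c(1L)), 5)
  co$hidden_flag <- c(TRUE, TRUE, FALSE)
  r <- phenotype_rule("r", c(1, 2),
                      list(rule_clause(present = 1, absent = 2,
                                       requires_hidden = TRUE)))
  expect_equal(as.integer(apply_rule(r, co)), c(1L, 0L, 0L))
})

test_that("disjoint single-code union matches closed-form probability", {
  f <- 0.1
  n <- 20000
  co <- background_only_cohort(n, 4, f, seed = 17)
  r <- phenotype_rule("u", 1:4, lapply(1:4, function(j) {
    rule_clause(present = j)
  }))
  y <- apply_rule(r, co)
  p_expected <- 1 - (1 - f)^4
  sd3 <- 3 * sqrt(p_expected * (1 - p_expected) / n)
  expect_lt(abs(mean(y) - p_expected), sd3)
})

test_that("label noise is seed-deterministic and absent when zero", {
  co <- background_only_cohort(500, 5, 0.3, seed = 2)
  r0 <- phenotype_rule("r", 1, list(rule_clause(present = 1)),
                       label_noise = 0)
  expect_identical(apply_rule(r0, co, seed = 1), apply_rule(r0, co, seed = 2))
  rn <- phenotype_rule("r", 1, list(rule_clause(present = 1)),
                       label_noise = 0.2)
  y1 <- apply_rule(rn, co, seed = 1)
  expect_identical(y1, apply_rule(rn, co, seed = 1))
  expect_false(identical(y1, apply_rule(rn, co, seed = 2)))
})

test_that("count criteria require the stated number of codes", {
  co <- codeset_cohort(list(c(1L, 2L), c(1L, 2L, 3L), c(4L), integer(0)), 5)
  r <- phenotype_rule("cnt", 1:4,
                      list(rule_clause(min_count_set = 1:4, min_count = 2)))
  expect_equal(as.integer(apply_rule(r, co)), c(1L, 1L, 0L, 0L))
  # enumeration agrees: signatures with >= 2 of 4 bits set
  expect_length(ehrmtl:::rule_satisfying_set(r), sum(choose(4, 2:4)))
  expect_error(rule_clause(min_count_set = 1:3, min_count = 4),
               class = "ehrmtl_config_error")
})

test_that("rule validation rejects bad inputs", {
  expect_error(phenotype_rule("r", 1:3, list()), class = "ehrmtl_config_error")
  expect_error(
    phenotype_rule("r", 1:3, list(rule_clause(present = 7))),
    class = "ehrmtl_config_error"
  )
  expect_error(
    phenotype_rule("r", 1, list(rule_clause(present = 1)), label_noise = 0.5),
    class = "ehrmtl_config_error"
  )
  co <- codeset_cohort(list(1L), 3)
  r <- phenotype_rule("r", 9, list(rule_clause(present = 9)))
  expect_error(apply_rule(r, co), class = "ehrmtl_config_error")
})

test_that("oracle signatures encode presence in oracle-code order", {
  r <- phenotype_rule("r", c(2, 9, 4), list(rule_clause(present = 2)))
  expect_equal(oracle_signature(r, c(9L)), "010")
  expect_equal(oracle_signature(r, c(2L, 9L, 4L)), "111")
  co <- codeset_cohort(list(c(9L), c(2L, 4L, 9L), integer(0)), 10)
  expect_equal(oracle_signatures(r, co), c("010", "111", "000"))
})

test_that("signature length always equals the oracle-code count", {
  set.seed(8)
  code_sets <- replicate(1000, {
    sample.int(30, sample(0:10, 1))
  }, simplify = FALSE)
  co <- codeset_cohort(code_sets, 30)
  r <- phenotype_rule("r", c(5, 1, 22, 9),
                      list(rule_clause(present = 5)))
  sigs <- oracle_signatures(r, co)
  expect_true(all(nchar(sigs) == 4))
})

test_that("complexity-controlled rules have exact satisfying-set size", {
  # brute-force enumeration over all 2^5 signatures
  r1 <- make_complexity_controlled_rule(5, 1, seed = 3)
  expect_length(ehrmtl:::rule_satisfying_set(r1), 1)
  expect_identical(ehrmtl:::rule_satisfying_set(r1),
                   attr(r1, "satisfying_signatures"))

  for (k in c(4, 16)) {
    r <- make_complexity_controlled_rule(5, k, seed = 3)
    expect_length(ehrmtl:::rule_satisfying_set(r), k)
  }

  # tautology: every signature satisfies
  r_all <- make_complexity_controlled_rule(3, 8, seed = 1)
  expect_length(ehrmtl:::rule_satisfying_set(r_all), 8)

  # determinism
  expect_identical(
    attr(make_complexity_controlled_rule(6, 10, seed = 5),
         "satisfying_signatures"),
    attr(make_complexity_controlled_rule(6, 10, seed = 5),
         "satisfying_signatures")
  )

  expect_error(make_complexity_controlled_rule(3, 9),
               class = "ehrmtl_config_error")
  expect_error(make_complexity_controlled_rule(3, 0),
               class = "ehrmtl_config_error")
})

test_that("rules survive a JSON round trip", {
  path <- withr::local_tempfile(fileext = ".json")
  r <- phenotype_rule(
    "roundtrip", c(4, 2, 7),
    list(rule_clause(present = c(4, 2), absent = 7),
         rule_clause(present = 7, requires_hidden = TRUE),
         rule_clause(min_count_set = c(4, 2, 7), min_count = 2)),
    label_noise = 0.05
  )
  write_phenotype_rule(r, path)
  r2 <- read_phenotype_rule(path)
  expect_equal(r2$oracle_codes, r$oracle_codes)
  expect_equal(r2$label_noise, r$label_noise)
  expect_equal(length(r2$clauses), 3)
  expect_equal(r2$clauses[[1]]$present, c(4L, 2L))
  expect_equal(r2$clauses[[1]]$absent, 7L)
  expect_true(r2$clauses[[2]]$requires_hidden)
  expect_equal(r2$clauses[[3]]$min_count_set, c(4L, 2L, 7L))
  expect_equal(r2$clauses[[3]]$min_count, 2L)
})
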