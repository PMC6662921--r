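toy <- separable_toy()
toy_hp <- hyper_params(1, 32, 1e-2)
toy_tc <- train_config(max_epochs = 20, batch_size = 32, seed = 7)

test_that("a separable toy problem is solved nearly perfectly", {
  m <- train_stnn(toy$X_train, toy$y_train, toy$X_val, toy$y_val,
                  toy_hp, toy_tc)
  expect_gte(m$val_auprc, 0.99)
})

test_that("training is deterministic under a fixed seed", {
  m1 <- train_stnn(toy$X_train, toy$y_train, toy$X_val, toy$y_val,
                   toy_hp, toy_tc)
  m2 <- train_stnn(toy$X_train, toy$y_train, toy$X_val, toy$y_val,
                   toy_hp, toy_tc)
  expect_identical(m1$val_auprc_trace, m2$val_auprc_trace)
  expect_identical(m1$net, m2$net)
})

test_that("degenerate training labels are rejected", {
  expect_error(
    train_stnn(toy$X_train, rep(0, nrow(toy$X_train)), toy$X_val,
               toy$y_val, toy_hp, toy_tc),
    class = "ehrmtl_degenerate_label_error"
  )
  expect_error(
    train_l1_logreg(toy$X_train, rep(1, nrow(toy$X_train)), toy$X_val,
                    toy$y_val),
    class = "ehrmtl_degenerate_label_error"
  )
})

test_that("early stopping returns the best epoch of the trace", {
  m <- train_stnn(toy$X_train, toy$y_train, toy$X_val, toy$y_val,
                  toy_hp, train_config(max_epochs = 8, batch_size = 32,
                                       seed = 19))
  expect_equal(m$val_auprc, max(m$val_auprc_trace))
  expect_equal(m$val_auprc_trace[m$best_epoch], m$val_auprc)
})

test_that("a duplicated-target auxiliary task does not materially hurt", {
  # control experiment: the auxiliary gradient duplicates the target's
  diffs <- vapply(1:5, function(s) {
    tc <- train_config(max_epochs = 10, batch_size = 32, seed = s)
    st <- train_stnn(toy$X_train, toy$y_train, toy$X_val, toy$y_val,
                     toy_hp, tc)
    mt <- train_mtnn(toy$X_train, toy$y_train,
                     matrix(toy$y_train, ncol = 1),
                     toy$X_val, toy$y_val, toy_hp, tc)
    mt$val_auprc - st$val_auprc
  }, numeric(1))
  expect_gte(mean(diffs), -0.02)
})

test_that("multitask structure is enforced and exposed", {
  expect_error(
    train_mtnn(toy$X_train, toy$y_train,
               matrix(numeric(0), nrow(toy$X_train), 0),
               toy$X_val, toy$y_val, toy_hp, toy_tc),
    class = "ehrmtl_config_error"
  )
  set.seed(12)
  aux <- cbind(a1 = rbinom(nrow(toy$X_train), 1, 0.3),
               a2 = rbinom(nrow(toy$X_train), 1, 0.4))
  m <- train_mtnn(toy$X_train, toy$y_train, aux, toy$X_val, toy$y_val,
                  toy_hp, toy_tc)
  expect_equal(ncol(m$net$head_W), 3)  # target + 2 auxiliary heads
  expect_equal(m$task_ids, c("target", "a1", "a2"))
  # heads are distinct scorers
  s_target <- predict_scores(m, toy$X_train)
  s_aux <- predict_scores(m, toy$X_train, task_id = "a1")
  expect_false(isTRUE(all.equal(s_target, s_aux)))
})

test_that("a single-class auxiliary task is dropped with a warning", {
  aux <- cbind(dead = rep(0, nrow(toy$X_train)))
  expect_warning(
    m <- train_mtnn(toy$X_train, toy$y_train, aux, toy$X_val, toy$y_val,
                    toy_hp, toy_tc),
    "single class"
  )
  expect_equal(m$task_weights, c(1, 0))
})

test_that("zero-weight auxiliaries reproduce the single-task trajectory", {
  tc <- train_config(max_epochs = 4, batch_size = 32, seed = 11)
  st <- train_stnn(toy$X_train, toy$y_train, toy$X_val, toy$y_val,
                   toy_hp, tc)
  aux <- matrix(rbinom(nrow(toy$X_train), 1, 0.5), ncol = 1)
  mt <- train_mtnn(toy$X_train, toy$y_train, aux, toy$X_val, toy$y_val,
                   toy_hp, tc, task_weights = c(1, 0))
  # equality up to floating-point noise: the extra (zero-weight) head
  # changes BLAS kernel dispatch but not the mathematical trajectory
  expect_equal(mt$val_auprc_trace, st$val_auprc_trace, tolerance = 1e-9)
  expect_equal(mt$net$layers, st$net$layers, tolerance = 1e-9)
  expect_equal(mt$net$head_W[, 1], st$net$head_W[, 1], tolerance = 1e-9)
})

test_that("predicted scores are probabilities and handle empty input", {
  m <- train_stnn(toy$X_train, toy$y_train, toy$X_val, toy$y_val,
                  toy_hp, toy_tc)
  expect_identical(predict_scores(m, toy$X[0, , drop = FALSE]), numeric(0))
  set.seed(3)
  Xr <- matrix(rnorm(10000 * 10, sd = 5), 10000, 10)
  s <- predict_scores(m, Xr)
  expect_gte(min(s), 0)
  expect_lte(max(s), 1)
  expect_error(predict_scores(m, toy$X_val, task_id = "nope"),
               class = "ehrmtl_lookup_error")
})

test_that("L1 logistic regression selects the informative feature", {
  set.seed(9)
  n <- 400
  X <- matrix(rbinom(n * 20, 1, 0.3), n, 20)
  y <- as.integer(runif(n) < ifelse(X[, 7] == 1, 0.9, 0.05))
  m <- train_l1_logreg(X[1:300, ], y[1:300], X[301:400, ], y[301:400])
  # the selected model leans on the informative feature
  beta <- as.numeric(coef(m$fit, s = m$lambda))[-1]
  expect_gt(beta[7], 0)
  expect_equal(which.max(abs(beta)), 7)
  # at a sufficiently strong penalty only the informative feature survives
  beta_strong <- as.numeric(coef(m$fit, s = m$lambda_grid[2]))[-1]
  expect_gt(beta_strong[7], 0)
  expect_gte(sum(beta_strong[-7] == 0), 18)
  # determinism
  m2 <- train_l1_logreg(X[1:300, ], y[1:300], X[301:400, ], y[301:400])
  expect_identical(m$lambda, m2$lambda)
})

test_that("the fully penalized limit scores at the prevalence baseline", {
  set.seed(10)
  n <- 200
  X <- matrix(rbinom(n * 5, 1, 0.4), n, 5)
  y <- rbinom(n, 1, 0.3)
  m <- train_l1_logreg(X[1:150, ], y[1:150], X[151:200, ], y[151:200],
                       lambda_grid = c(1e6))
  s <- predict_scores(m, X[151:200, ])
  expect_equal(diff(range(s)), 0)
  expect_equal(auprc(y[151:200], s), mean(y[151:200]))
})
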