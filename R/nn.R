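# Feed-forward neural nets with hard parameter sharing, written directly on
# BLAS matrix ops. Architecture per trunk layer: linear (no bias) -> batch
# normalization -> ReLU; then one sigmoid output head per task on the shared
# trunk. Single-task nets are the one-head special case. Training is
# minibatch Adam on the mean of per-task binary cross-entropies, with Xavier
# initialization and per-epoch early stopping on the TARGET task's
# validation AUPRC.

#' Training configuration for the neural nets
#'
#' @param max_epochs training epochs; the model is checkpointed after each
#'   epoch and the best-validation epoch is returned.
#' @param batch_size minibatch size.
#' @param adam_beta1,adam_beta2 Adam moment decay rates.
#' @param bn_momentum momentum for the batch-norm running statistics.
#' @param bn_eps numerical floor inside the batch-norm standardization.
#' @param seed integer seed controlling initialization and batch order.
#' @param engine `"compiled"` (C++ epoch kernel, default) or
#'   `"reference"` (plain-R loop). Both implement the identical update
#'   rule; the reference engine exists for cross-checking and for sparse
#'   inputs too large to densify.
#' @return a `train_config` list.
#' @export
train_config <- function(max_epochs = 6, batch_size = 256,
                         adam_beta1 = 0.9, adam_beta2 = 0.99,
                         bn_momentum = 0.9, bn_eps = 1e-5, seed = 1L,
                         engine = c("compiled", "reference")) {
  if (max_epochs < 1) abort_config("max_epochs must be at least 1")
  structure(
    list(max_epochs = as.integer(max_epochs),
         batch_size = as.integer(batch_size),
         adam_beta1 = adam_beta1, adam_beta2 = adam_beta2,
         bn_momentum = bn_momentum, bn_eps = bn_eps,
         seed = as.integer(seed),
         engine = match.arg(engine)),
    class = "train_config"
  )
}

#' Hyperparameters for one grid point
#'
#' @param n_hidden_layers 1 or 2.
#' @param hidden_size width of each hidden layer.
#' @param learning_rate initial Adam learning rate.
#' @return a `hyper_params` list.
#' @export
hyper_params <- function(n_hidden_layers, hidden_size, learning_rate) {
  if (!n_hidden_layers %in% c(1, 2)) {
    abort_config("n_hidden_layers must be 1 or 2")
  }
  structure(
    list(n_hidden_layers = as.integer(n_hidden_layers),
         hidden_size = as.integer(hidden_size),
         learning_rate = as.numeric(learning_rate)),
    class = "hyper_params"
  )
}

sigmoid <- function(z) 1 / (1 + exp(-z))

xavier_uniform <- function(fan_in, fan_out) {
  a <- sqrt(6 / (fan_in + fan_out))
  matrix(runif(fan_in * fan_out, -a, a), fan_in, fan_out)
}

# Initialize trunk + heads. RNG order is: trunk layers in depth order, then
# the target head column, then auxiliary head columns. With a fixed seed
# this makes the trunk and target head of a K-task net bit-identical to the
# single-task net's, which the zero-auxiliary-weight equivalence relies on.
init_net <- function(d_in, hp, n_tasks) {
  layers <- list()
  fan_in <- d_in
  for (l in seq_len(hp$n_hidden_layers)) {
    h <- hp$hidden_size
    layers[[l]] <- list(
      W = xavier_uniform(fan_in, h),
      gamma = rep(1, h), beta = rep(0, h),
      run_mean = rep(0, h), run_var = rep(1, h)
    )
    fan_in <- h
  }
  head_W <- matrix(0, fan_in, n_tasks)
  for (k in seq_len(n_tasks)) head_W[, k] <- xavier_uniform(fan_in, 1)
  list(layers = layers, head_W = head_W, head_b = rep(0, n_tasks))
}

# Forward pass in training mode. Returns head probabilities and the
# per-layer caches needed for backprop; updates running statistics.
forward_train <- function(net, X, tc) {
  caches <- list()
  H <- X
  for (l in seq_along(net$layers)) {
    ly <- net$layers[[l]]
    Z <- H %*% ly$W
    mu <- colMeans(Z)
    Zc <- sweep(Z, 2, mu, "-")
    v <- colMeans(Zc^2)
    inv_std <- 1 / sqrt(v + tc$bn_eps)
    Zhat <- sweep(Zc, 2, inv_std, "*")
    A <- sweep(sweep(Zhat, 2, ly$gamma, "*"), 2, ly$beta, "+")
    Hout <- A * (A > 0)
    net$layers[[l]]$run_mean <- tc$bn_momentum * ly$run_mean +
      (1 - tc$bn_momentum) * mu
    net$layers[[l]]$run_var <- tc$bn_momentum * ly$run_var +
      (1 - tc$bn_momentum) * v
    caches[[l]] <- list(X_in = H, Zhat = Zhat, inv_std = inv_std, A = A)
    H <- Hout
  }
  logits <- sweep(H %*% net$head_W, 2, net$head_b, "+")
  list(net = net, probs = sigmoid(logits), H = H, caches = caches)
}

# Forward pass in evaluation mode (running statistics), target chunked to
# bound memory on large cohorts.
forward_eval <- function(net, X, tc, task_cols = NULL, chunk = 8192L) {
  n <- nrow(X)
  task_cols <- task_cols %||% seq_len(ncol(net$head_W))
  out <- matrix(0, n, length(task_cols))
  start <- 1L
  while (start <= n) {
    idx <- start:min(n, start + chunk - 1L)
    H <- as.matrix(X[idx, , drop = FALSE])
    for (ly in net$layers) {
      Z <- H %*% ly$W
      Zhat <- sweep(sweep(Z, 2, ly$run_mean, "-"), 2,
                    1 / sqrt(ly$run_var + tc$bn_eps), "*")
      A <- sweep(sweep(Zhat, 2, ly$gamma, "*"), 2, ly$beta, "+")
      H <- A * (A > 0)
    }
    logits <- sweep(H %*% net$head_W[, task_cols, drop = FALSE], 2,
                    net$head_b[task_cols], "+")
    out[idx, ] <- sigmoid(logits)
    start <- start + chunk
  }
  if (n == 0) out <- matrix(0, 0, length(task_cols))
  out
}

adam_init <- function(param) list(m = param * 0, v = param * 0)

adam_step <- function(param, grad, state, lr, b1, b2, t, eps = 1e-8) {
  state$m <- b1 * state$m + (1 - b1) * grad
  state$v <- b2 * state$v + (1 - b2) * grad^2
  mhat <- state$m / (1 - b1^t)
  vhat <- state$v / (1 - b2^t)
  list(param = param - lr * mhat / (sqrt(vhat) + eps), state = state)
}

# Core training loop shared by STNN and MTNN.
#
# Y is an n x K matrix of 0/1 labels with the target task in column 1;
# task_weights scales each task's contribution to the loss (weights are
# renormalized to sum to 1). Early stopping monitors only the target
# task's validation AUPRC, evaluated after each epoch.
train_net <- function(X_train, Y_train, X_val, y_val, hp, tc,
                      task_ids, task_weights) {
  n <- nrow(X_train)
  K <- ncol(Y_train)
  w <- task_weights / sum(task_weights)

  set.seed(tc$seed)
  net <- init_net(ncol(X_train), hp, K)
  states <- list(
    layers = lapply(net$layers, function(ly) {
      list(W = adam_init(ly$W), gamma = adam_init(ly$gamma),
           beta = adam_init(ly$beta))
    }),
    head_W = adam_init(net$head_W), head_b = adam_init(net$head_b)
  )

  dense_train <- !is.matrix(X_train) &&
    prod(dim(X_train)) <= 6e7  # ~0.5 GB densified
  if (dense_train) X_train <- as.matrix(X_train)

  set.seed(derive_seed(tc$seed, 104729L))  # separate stream for batch order
  step <- 0
  trace <- numeric(tc$max_epochs)
  best <- -Inf
  best_net <- NULL
  best_epoch <- NA_integer_
  b1 <- tc$adam_beta1
  b2 <- tc$adam_beta2
  lr <- hp$learning_rate

  use_compiled <- (tc$engine %||% "compiled") == "compiled" &&
    is.matrix(X_train)

  for (epoch in seq_len(tc$max_epochs)) {
    perm <- sample.int(n)
    if (use_compiled) {
      res <- cpp_train_epoch(
        X_train, Y_train, w, net, states, perm - 1L,
        tc$batch_size, lr, b1, b2, tc$bn_momentum, tc$bn_eps, step
      )
      net <- res$net
      states <- res$states
      step <- res$steps
      val_scores <- forward_eval(net, X_val, tc, task_cols = 1L)[, 1]
      trace[epoch] <- auprc(y_val, val_scores)
      if (trace[epoch] > best) {
        best <- trace[epoch]
        best_net <- net
        best_epoch <- epoch
      }
      next
    }
    starts <- seq(1L, n, by = tc$batch_size)
    for (s in starts) {
      idx <- perm[s:min(n, s + tc$batch_size - 1L)]
      m_b <- length(idx)
      if (m_b < 2) next  # batch norm needs at least two rows
      Xb <- X_train[idx, , drop = FALSE]
      if (!is.matrix(Xb)) Xb <- as.matrix(Xb)
      Yb <- Y_train[idx, , drop = FALSE]

      fw <- forward_train(net, Xb, tc)
      net <- fw$net
      step <- step + 1

      # mean over tasks (weighted) of mean-over-batch BCE gradients
      dlogits <- sweep(fw$probs - Yb, 2, w, "*") / m_b
      g_head_W <- crossprod(fw$H, dlogits)
      g_head_b <- colSums(dlogits)
      dH <- tcrossprod(dlogits, net$head_W)

      upd <- adam_step(net$head_W, g_head_W, states$head_W, lr, b1, b2, step)
      net$head_W <- upd$param; states$head_W <- upd$state
      upd <- adam_step(net$head_b, g_head_b, states$head_b, lr, b1, b2, step)
      net$head_b <- upd$param; states$head_b <- upd$state

      for (l in rev(seq_along(net$layers))) {
        cache <- fw$caches[[l]]
        ly <- net$layers[[l]]
        dA <- dH * (cache$A > 0)
        g_gamma <- colSums(dA * cache$Zhat)
        g_beta <- colSums(dA)
        dZhat <- sweep(dA, 2, ly$gamma, "*")
        sum_dZhat <- colSums(dZhat)
        sum_dZhat_Zhat <- colSums(dZhat * cache$Zhat)
        dZ <- sweep(
          m_b * dZhat -
            matrix(sum_dZhat, m_b, length(sum_dZhat), byrow = TRUE) -
            sweep(cache$Zhat, 2, sum_dZhat_Zhat, "*"),
          2, cache$inv_std / m_b, "*"
        )
        g_W <- crossprod(cache$X_in, dZ)
        if (l > 1) dH <- tcrossprod(dZ, ly$W)

        st <- states$layers[[l]]
        upd <- adam_step(ly$W, g_W, st$W, lr, b1, b2, step)
        net$layers[[l]]$W <- upd$param; st$W <- upd$state
        upd <- adam_step(ly$gamma, g_gamma, st$gamma, lr, b1, b2, step)
        net$layers[[l]]$gamma <- upd$param; st$gamma <- upd$state
        upd <- adam_step(ly$beta, g_beta, st$beta, lr, b1, b2, step)
        net$layers[[l]]$beta <- upd$param; st$beta <- upd$state
        states$layers[[l]] <- st
      }
    }
    val_scores <- forward_eval(net, X_val, tc, task_cols = 1L)[, 1]
    trace[epoch] <- auprc(y_val, val_scores)
    if (trace[epoch] > best) {
      best <- trace[epoch]
      best_net <- net
      best_epoch <- epoch
    }
  }

  list(net = best_net, best_epoch = best_epoch, val_auprc = best,
       val_auprc_trace = trace, task_ids = task_ids,
       task_weights = task_weights)
}

as_feature_values <- function(features) {
  if (inherits(features, "feature_matrix")) features$values else features
}

check_binary_both_classes <- function(y, what) {
  u <- unique(as.integer(y))
  if (!all(u %in% c(0L, 1L))) abort_config(sprintf("%s must be 0/1", what))
  if (length(u) < 2) {
    abort_degenerate_labels(sprintf(
      "%s contains a single class; cannot train", what
    ))
  }
}

#' Train a single-task neural net (STNN)
#'
#' Feed-forward net `input -> (linear -> batch norm -> ReLU) x L -> linear
#' -> sigmoid`, minimizing binary cross-entropy with Adam, returning the
#' parameters from the epoch with the best validation AUPRC.
#'
#' @param X_train,X_val feature matrices ([build_feature_matrix()] output,
#'   sparse, or dense); columns must match.
#' @param y_train,y_val binary 0/1 target labels.
#' @param hp a [hyper_params()].
#' @param tc a [train_config()].
#' @return a `fitted_model` with family `"STNN"`, the best-epoch network,
#'   `best_epoch`, `val_auprc` and the full per-epoch `val_auprc_trace`.
#' @export
train_stnn <- function(X_train, y_train, X_val, y_val, hp, tc) {
  X_train <- as_feature_values(X_train)
  X_val <- as_feature_values(X_val)
  check_binary_both_classes(y_train, "training target labels")
  fit <- train_net(X_train, matrix(as.numeric(y_train), ncol = 1),
                   X_val, y_val, hp, tc,
                   task_ids = "target", task_weights = 1)
  structure(
    c(list(family = "STNN", hyperparams = hp, train_cfg = tc,
           target_task_id = "target"), fit),
    class = "fitted_model"
  )
}

#' Train a multitask neural net (MTNN)
#'
#' Shares the trunk of [train_stnn()] across the target task and `K`
#' auxiliary tasks, each with its own sigmoid output head. The loss is the
#' weighted mean of per-task binary cross-entropies (unweighted mean by
#' default). Early stopping monitors only the target task's validation
#' AUPRC. An auxiliary task whose training labels contain a single class is
#' dropped from the loss with a warning; the run continues.
#'
#' @inheritParams train_stnn
#' @param aux_train n-by-K matrix of auxiliary 0/1 labels (K >= 1), column
#'   names used as task ids.
#' @param task_weights optional length `K + 1` loss weights (target first).
#' @return a `fitted_model` with family `"MTNN"` exposing one head per task.
#' @export
train_mtnn <- function(X_train, y_train, aux_train, X_val, y_val, hp, tc,
                       task_weights = NULL) {
  X_train <- as_feature_values(X_train)
  X_val <- as_feature_values(X_val)
  aux_train <- as.matrix(aux_train)
  K <- ncol(aux_train)
  if (K < 1) {
    abort_config("MTNN requires at least one auxiliary task; use train_stnn")
  }
  check_binary_both_classes(y_train, "training target labels")
  task_ids <- c("target",
                colnames(aux_train) %||% paste0("aux_", seq_len(K)))
  if (is.null(task_weights)) task_weights <- rep(1, K + 1)
  if (length(task_weights) != K + 1) {
    abort_config("task_weights must have length K + 1")
  }
  for (k in seq_len(K)) {
    if (length(unique(aux_train[, k])) < 2 && task_weights[k + 1] != 0) {
      warning(sprintf(
        "auxiliary task '%s' has a single class in training data; its loss is dropped",
        task_ids[k + 1]
      ))
      task_weights[k + 1] <- 0
    }
  }
  Y <- cbind(as.numeric(y_train), aux_train)
  fit <- train_net(X_train, Y, X_val, y_val, hp, tc,
                   task_ids = task_ids, task_weights = task_weights)
  structure(
    c(list(family = "MTNN", hyperparams = hp, train_cfg = tc,
           target_task_id = "target"), fit),
    class = "fitted_model"
  )
}

#' @export
print.fitted_model <- function(x, ...) {
  cat(sprintf(
    "<fitted_model> %s (%d task%s), best epoch %s, val AUPRC %.4f\n",
    x$family, length(x$task_ids %||% "target"),
    if (length(x$task_ids %||% 1) > 1) "s" else "",
    format(x$best_epoch), x$val_auprc
  ))
  invisible(x)
}

#' Predict task probabilities from a fitted model
#'
#' @param model a `fitted_model` from [train_stnn()], [train_mtnn()] or
#'   [train_l1_logreg()].
#' @param features feature matrix (any representation accepted at training
#'   time).
#' @param task_id which head to score (`"target"` by default; only MTNN
#'   models expose other tasks).
#' @return numeric vector of probabilities in `[0, 1]`, one per row.
#' @export
predict_scores <- function(model, features, task_id = "target") {
  X <- as_feature_values(features)
  if (model$family == "LR") {
    if (task_id != "target") {
      abort_lookup("logistic regression models expose only the 'target' task")
    }
    if (nrow(X) == 0) return(numeric(0))
    return(as.numeric(predict(model$fit, newx = X, s = model$lambda,
                              type = "response")))
  }
  k <- match(task_id, model$task_ids)
  if (is.na(k)) {
    abort_lookup(sprintf("unknown task '%s'; model has: %s", task_id,
                         paste(model$task_ids, collapse = ", ")))
  }
  if (nrow(X) == 0) return(numeric(0))
  forward_eval(model$net, X, model$train_cfg, task_cols = k)[, 1]
}
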