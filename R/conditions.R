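# Classed error conditions so callers can distinguish configuration mistakes
# from data problems programmatically.

ehrmtl_abort <- function(message, class) {
  stop(structure(
    class = c(class, "ehrmtl_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

abort_config <- function(message) ehrmtl_abort(message, "ehrmtl_config_error")
abort_degenerate_labels <- function(message) {
  ehrmtl_abort(message, "ehrmtl_degenerate_label_error")
}
abort_insufficient_tasks <- function(message) {
  ehrmtl_abort(message, "ehrmtl_insufficient_tasks_error")
}
abort_stratification <- function(message) {
  ehrmtl_abort(message, "ehrmtl_stratification_error")
}
abort_metric <- function(message) ehrmtl_abort(message, "ehrmtl_metric_error")
abort_insufficient_data <- function(message) {
  ehrmtl_abort(message, "ehrmtl_insufficient_data_error")
}
abort_shape <- function(message) ehrmtl_abort(message, "ehrmtl_shape_error")
abort_lookup <- function(message) ehrmtl_abort(message, "ehrmtl_lookup_error")

# Deterministic child-seed derivation: fold integer components into a
# 31-bit seed with a multiplicative congruential mix. Keeps every stream
# a pure function of (master_seed, context ids) and inside R's integer range.
derive_seed <- function(master_seed, ...) {
  parts <- list(...)
  s <- as.double(master_seed) %% 2147483647
  for (p in parts) {
    if (is.character(p)) p <- sum(utf8ToInt(p) * seq_along(utf8ToInt(p)))
    s <- (s * 69069 + as.double(p) * 3643 + 12345) %% 2147483647
  }
  as.integer(s)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
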