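# Base-graphics view of a finished protocol.

#' Plot per-split model performance
#'
#' One panel per model family and auxiliary-set size: test AUPRC of every
#' completed grid run per split (open circles) with the
#' best-by-validation run emphasized (filled). Mirrors the customary
#' "performance across hyperparameter settings and splits" layout.
#'
#' @param x a `protocol_result`.
#' @param ... unused.
#' @return `x`, invisibly.
#' @export
plot.protocol_result <- function(x, ...) {
  res <- x$results[x$results$status == "ok", ]
  cells <- unique(res[, c("family", "aux_set_size")])
  cells <- cells[order(cells$family, cells$aux_set_size), ]
  old <- graphics::par(mfrow = c(1, nrow(cells)), mar = c(4, 4, 3, 1))
  on.exit(graphics::par(old))
  for (i in seq_len(nrow(cells))) {
    cell <- res[res$family == cells$family[i] &
                  res$aux_set_size == cells$aux_set_size[i], ]
    graphics::plot(
      cell$split_id, cell$test_auprc,
      xlab = "split", ylab = "test AUPRC",
      main = if (cells$aux_set_size[i] > 0) {
        sprintf("%s (%d aux)", cells$family[i], cells$aux_set_size[i])
      } else {
        cells$family[i]
      },
      ylim = range(res$test_auprc), pch = 1, col = "grey40"
    )
    b <- x$best[x$best$family == cells$family[i] &
                  x$best$aux_set_size == cells$aux_set_size[i], ]
    graphics::points(b$split_id, b$test_auprc, pch = 19, col = "firebrick")
  }
  invisible(x)
}
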