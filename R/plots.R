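# Base-graphics summaries of the two headline outputs. Kept dependency-free;
# callers direct them to a device (png/pdf) as needed.

#' Stacked bar plot of per-branch signature exposures
#' @param fit Result of [extract_signatures()] (or any list with an
#'   `exposures` matrix whose rows sum to 1).
#' @param ... Passed to [graphics::barplot()].
#' @export
plot_exposures <- function(fit, ...) {
  ex <- t(fit$exposures)
  graphics::barplot(ex, legend.text = rownames(ex),
                    col = grDevices::hcl.colors(nrow(ex), "Dark 3"),
                    ylab = "exposure fraction", las = 2, ...)
  invisible(ex)
}

#' Clone-size timecourse of a tracked lineage, with 95% intervals
#'
#' Plots the estimated clone size per sample on a log scale with
#' Clopper-Pearson interval bars and the background error rate (times two,
#' on the clone-size scale) as a reference line.
#'
#' @param result A `lineage_test` data.frame from
#'   [track_lineage_timecourse()].
#' @param eps Background error rate drawn as the reference line (defaults
#'   to the rate stored in the result).
#' @param ... Passed to [graphics::plot()].
#' @export
plot_lineage_timecourse <- function(result, eps = result$eps[1L], ...) {
  n <- nrow(result)
  lo <- pmax(result$clone_low, 1e-6)
  hi <- pmax(result$clone_high, 1e-6)
  y <- pmax(result$clone_size, 1e-6)
  graphics::plot(seq_len(n), y, log = "y", xaxt = "n", pch = 19,
                 xlab = "", ylab = "clone size",
                 ylim = range(c(lo, hi, 2 * eps)), ...)
  graphics::axis(1, at = seq_len(n), labels = result$sample_id, las = 2)
  graphics::arrows(seq_len(n), lo, seq_len(n), hi,
                   angle = 90, code = 3, length = 0.03)
  graphics::abline(h = 2 * eps, col = "red", lty = 2)
  graphics::text(seq_len(n), hi, result$stars, pos = 3)
  invisible(result)
}
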