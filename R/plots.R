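#' Plot a self-comparison dotplot
#'
#' Draws the off-diagonal word matches of a [self_dotplot()] (both
#' triangles, so tandem arrays appear as the familiar stripe pattern)
#' plus the main diagonal.
#'
#' @param x A `dot_matrix`.
#' @param pch,cex,... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.dot_matrix <- function(x, pch = ".", cex = 1.5, ...) {
  graphics::plot(NA, xlim = c(1, x$length), ylim = c(x$length, 1),
                 xlab = "position (nt)", ylab = "position (nt)",
                 main = sprintf("self dotplot (k = %d)", x$k), ...)
  graphics::abline(a = 0, b = 1, col = "grey70")
  if (nrow(x$matches)) {
    graphics::points(x$matches$i, x$matches$j, pch = pch, cex = cex)
    graphics::points(x$matches$j, x$matches$i, pch = pch, cex = cex)
  }
  invisible(x)
}

#' Cumulative-distribution comparison of target and control responses
#'
#' The standard presentation of a decoy perturbation result: empirical
#' CDFs of log2 fold changes for target and control genes, with group
#' sizes and the rank-sum p-value in the legend.
#'
#' @param fc Fold-change table from [fold_change()] or a named log2fc
#'   vector.
#' @param targets,controls Gene-id vectors.
#' @param main Plot title.
#' @param xlim Optional x-range.
#' @return The [compare_groups()] result, invisibly.
#' @export
plot_response_ecdf <- function(fc, targets, controls,
                               main = "target vs control response",
                               xlim = NULL) {
  vals <- fc_values(fc)
  x <- vals[intersect(targets, names(vals))]
  y <- vals[intersect(controls, names(vals))]
  cmp <- compare_groups(fc, targets, controls)
  if (is.null(xlim)) xlim <- range(c(x, y))
  graphics::plot(stats::ecdf(y), col = "grey40", main = main,
                 xlab = "log2 fold change", ylab = "cumulative fraction",
                 xlim = xlim, do.points = FALSE, verticals = TRUE)
  graphics::lines(stats::ecdf(x), col = "firebrick",
                  do.points = FALSE, verticals = TRUE)
  graphics::abline(v = 0, lty = 3)
  graphics::legend(
    "topleft", bty = "n", lty = 1,
    col = c("firebrick", "grey40"),
    legend = c(sprintf("targets (n = %d)", cmp$n_targets),
               sprintf("controls (n = %d)", cmp$n_controls)))
  graphics::mtext(sprintf("rank-sum p = %.2g", cmp$p_value),
                  side = 3, line = 0.2, cex = 0.8)
  invisible(cmp)
}

#' Write a target-call table as TSV
#'
#' @param calls A `target_calls` table from [classify_genes()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_target_calls <- function(calls, path) {
  utils::write.table(as.data.frame(calls), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
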