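#' Histogram of molecule sizes with fitted Gaussian components
#'
#' Per-sample diagnostic plot: the distribution of molecule intermarker
#' sizes (in repeat units) with the selected mixture components overlaid as
#' curves scaled to molecule counts, and a vertical dotted red line at the
#' position of a non-expanded (reference) allele.  The molecule count is
#' reported in the title.
#'
#' @param dset The [distance_set()] that was sized.
#' @param result The matching [size_sample()] result.
#' @param locus A [locus_spec()].
#' @param file Optional PNG path; `NULL` draws on the current device.
#' @param breaks Histogram breaks (passed to [graphics::hist()]).
#' @return Invisibly, the histogram object.
#' @export
plot_sizing_histogram <- function(dset, result, locus, file = NULL,
                                  breaks = 30) {
  reps <- bp_to_repeats(dset$distances_bp, locus)
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 600, res = 110)
    on.exit(grDevices::dev.off())
  }
  h <- graphics::hist(reps, breaks = breaks, plot = FALSE)
  binw <- diff(h$breaks[1:2])
  graphics::plot(h, col = "grey85", border = "grey55",
                 main = sprintf("%s  (%d molecules)", dset$sample_id,
                                result$n_total),
                 xlab = "repeat units", ylab = "molecule count")
  xs <- seq(min(reps) - 50, max(reps) + 50, length.out = 400)
  a <- result$alleles
  for (i in seq_len(nrow(a))) {
    ys <- result$n_kept * a$weight[i] * binw *
      stats::dnorm(xs, a$mean_repeats[i], a$sd_repeats[i])
    graphics::lines(xs, ys, col = i + 1, lwd = 2)
  }
  graphics::abline(v = 0, col = "red", lty = 3, lwd = 2)
  invisible(h)
}
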