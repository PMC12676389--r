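#' Plot an ensemble FRET histogram with an optional two-Gaussian overlay
#'
#' Bars show the ensemble-averaged per-molecule histogram with molecule-level
#' standard errors; the overlay draws the fitted mixture and its components.
#'
#' @param x An `ensemble_histogram`.
#' @param fit Optional `gaussian_mixture_fit` to overlay.
#' @param ... Passed to [graphics::barplot()].
#' @return Invisibly, the bar midpoints.
#' @export
plot.ensemble_histogram <- function(x, fit = NULL, ...) {
  mids <- graphics::barplot(x$ensemble_mean, names.arg = NULL,
                            space = 0, col = "grey85", border = "grey55",
                            xlab = "FRET efficiency",
                            ylab = "probability per bin",
                            ylim = c(0, max(x$ensemble_mean +
                                              x$ensemble_sem) * 1.15), ...)
  sel <- seq(1, 30, by = 5)
  graphics::axis(1, at = mids[sel], labels = sprintf("%.2f", x$bin_centers[sel]))
  graphics::arrows(mids, x$ensemble_mean - x$ensemble_sem,
                   mids, x$ensemble_mean + x$ensemble_sem,
                   length = 0.02, angle = 90, code = 3, col = "grey40")
  if (!is.null(fit)) {
    w <- diff(x$bin_edges)[1]
    xx <- seq(-0.25, 1.25, length.out = 300)
    scale_x <- function(e) (e - x$bin_edges[1]) / w  # bar coordinates
    comp1 <- w * fit$areas[1] * stats::dnorm(xx, fit$means[1], fit$sigmas[1])
    comp2 <- w * fit$areas[2] * stats::dnorm(xx, fit$means[2], fit$sigmas[2])
    graphics::lines(scale_x(xx), comp1 + comp2, col = "firebrick", lwd = 2)
    graphics::lines(scale_x(xx), comp1, col = "steelblue", lty = 2)
    graphics::lines(scale_x(xx), comp2, col = "darkorange", lty = 2)
  }
  invisible(mids)
}

#' Plot a corrected trace with its FRET series and idealization
#'
#' Top panel: donor and acceptor intensities with detected bleach frames;
#' bottom panel: frame-wise FRET efficiency with the idealized state path
#' when supplied.
#'
#' @param x A `corrected_trace`.
#' @param idealization Optional `fret_idealization` for the E panel.
#' @param ... Ignored.
#' @export
plot.corrected_trace <- function(x, idealization = NULL, ...) {
  old <- graphics::par(mfrow = c(2, 1), mar = c(2, 4, 1, 1))
  on.exit(graphics::par(old))
  tsec <- seq_along(x$donor) * x$frame_period
  graphics::plot(tsec, x$donor, type = "l", col = "darkgreen",
                 ylab = "intensity", xlab = "",
                 ylim = range(c(x$donor, x$acceptor)))
  graphics::lines(tsec, x$acceptor, col = "firebrick")
  if (!is.na(x$acceptor_bleach_frame))
    graphics::abline(v = x$acceptor_bleach_frame * x$frame_period,
                     lty = 3, col = "firebrick")
  if (!is.na(x$donor_bleach_frame))
    graphics::abline(v = x$donor_bleach_frame * x$frame_period,
                     lty = 3, col = "darkgreen")
  end <- if (!is.na(x$acceptor_bleach_frame))
    x$acceptor_bleach_frame - 4L else length(x$donor)
  if (!is.na(x$gamma) && end >= 1) {
    E <- compute_fret(x$acceptor[seq_len(end)], x$donor[seq_len(end)], x$gamma)
    graphics::plot(seq_len(end) * x$frame_period, E, type = "l",
                   col = "black", ylim = c(-0.2, 1.2),
                   xlab = "time (s)", ylab = "FRET efficiency")
    if (!is.null(idealization)) {
      lvl <- idealization$state_means[idealization$states]
      graphics::lines(seq_along(lvl) * x$frame_period, lvl,
                      col = "red", lwd = 2)
    }
  }
  invisible(NULL)
}

#' Plot cumulative cluster-size distributions per condition
#'
#' Step curves of the empirical cumulative probability of cluster size,
#' one per condition, with a frequency-distribution inset style barplot
#' available via `freq = TRUE`.
#'
#' @param stats_list Named list of `cluster_stats` (from
#'   [cluster_size_stats()]).
#' @param freq Draw the frequency distributions instead of CDFs.
#' @param ... Passed to the base plotting call.
#' @export
plot_cluster_sizes <- function(stats_list, freq = FALSE, ...) {
  cols <- c("steelblue", "firebrick", "darkorange", "darkgreen")
  if (freq) {
    all_sizes <- sort(unique(unlist(lapply(stats_list,
                                           function(s) s$cluster_sizes))))
    m <- sapply(stats_list, function(s)
      tabulate(factor(s$cluster_sizes, levels = all_sizes),
               nbins = length(all_sizes)))
    graphics::barplot(t(m), beside = TRUE, names.arg = all_sizes,
                      col = cols[seq_along(stats_list)],
                      xlab = "cluster size (particles)", ylab = "count", ...)
  } else {
    xmax <- max(unlist(lapply(stats_list, function(s) s$cdf$size)))
    graphics::plot(NA, xlim = c(1, xmax), ylim = c(0, 1),
                   xlab = "cluster size (particles)",
                   ylab = "cumulative probability", ...)
    for (i in seq_along(stats_list)) {
      s <- stats_list[[i]]
      graphics::lines(stats::stepfun(s$cdf$size, c(0, s$cdf$cumulative_probability)),
                      col = cols[i], do.points = FALSE, lwd = 2)
    }
  }
  graphics::legend("bottomright", legend = names(stats_list),
                   col = cols[seq_along(stats_list)], lwd = 2, bty = "n")
  invisible(NULL)
}
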