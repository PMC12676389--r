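#' Frame-wise FRET efficiency
#'
#' `E = Ia / (Ia + gamma * Id)` with the per-molecule gamma factor. The
#' estimator is invariant to rescaling both channels by a common positive
#' factor. Frames with a zero denominator are returned as NA (they are
#' excluded from histograms and counted by the caller).
#'
#' @param acceptor,donor Corrected intensities (vectors of equal length or
#'   scalars).
#' @param gamma Per-molecule gamma factor (> 0).
#' @return FRET efficiency values.
#' @examples
#' compute_fret(100, 100, 1)    # 0.5
#' compute_fret(100, 25, 2)     # 0.6667
#' @export
compute_fret <- function(acceptor, donor, gamma) {
  if (!is.numeric(gamma) || any(gamma <= 0))
    stop("'gamma' must be positive", call. = FALSE)
  den <- acceptor + gamma * donor
  out <- acceptor / den
  out[den == 0] <- NA_real_
  out
}

#' Histogram bin edges used for FRET populations
#'
#' Thirty equal bins spanning [-0.25, 1.25] (width 0.05).
#' @return Numeric vector of 31 edges.
#' @export
fret_bin_edges <- function() seq(-0.25, 1.25, length.out = 31L)

#' Per-molecule normalised FRET histogram
#'
#' Bins FRET values into 30 intervals across [-0.25, 1.25] and normalises
#' by the number of in-range values, so each molecule contributes a unit of
#' probability mass regardless of its trace length. Bins are half-open
#' [left, right), except the last which also includes 1.25. Out-of-range
#' and NA values are excluded and counted.
#'
#' @param E_values Numeric FRET values for one molecule.
#' @return List with `counts` (30 bins), `density` (counts normalised to
#'   sum 1; all-NA when no in-range values), `n_in_range`, `n_excluded`.
#' @export
molecule_histogram <- function(E_values) {
  edges <- fret_bin_edges()
  E_values <- E_values[!is.na(E_values)]
  inr <- E_values >= edges[1] & E_values <= edges[length(edges)]
  x <- E_values[inr]
  idx <- findInterval(x, edges, rightmost.closed = TRUE)
  counts <- tabulate(idx, nbins = 30L)
  n <- length(x)
  list(counts = counts,
       density = if (n) counts / n else rep(NA_real_, 30L),
       n_in_range = n,
       n_excluded = length(E_values) - n)
}

#' Ensemble FRET histogram
#'
#' Averages the per-molecule normalised histograms with equal weight per
#' molecule and reports the per-bin standard error across molecules.
#' Molecules without in-range values are dropped and counted.
#'
#' @param histograms List of [molecule_histogram()] results, or a numeric
#'   matrix with one row per molecule (rows summing to 1).
#' @return Object of class `ensemble_histogram`: `bin_edges`,
#'   `bin_centers`, `per_molecule` (n x 30 matrix), `ensemble_mean`,
#'   `ensemble_sem`, `n_molecules`, `n_excluded_molecules`,
#'   `n_excluded_values`.
#' @export
ensemble_histogram <- function(histograms) {
  edges <- fret_bin_edges()
  if (is.matrix(histograms)) {
    per <- histograms
    n_excluded_values <- 0L
    n_dropped <- 0L
  } else {
    if (inherits(histograms, "list") && length(histograms) &&
        !is.null(histograms$counts)) histograms <- list(histograms)
    ok <- vapply(histograms, function(h) h$n_in_range > 0L, logical(1))
    n_dropped <- sum(!ok)
    n_excluded_values <- sum(vapply(histograms, function(h) h$n_excluded,
                                    numeric(1)))
    per <- do.call(rbind, lapply(histograms[ok], function(h) h$density))
  }
  if (is.null(per) || nrow(per) == 0L)
    stop("no molecules with in-range FRET values", call. = FALSE)
  m <- colMeans(per)
  sem <- if (nrow(per) > 1L) apply(per, 2, stats::sd) / sqrt(nrow(per))
         else rep(0, ncol(per))
  structure(list(bin_edges = edges,
                 bin_centers = (edges[-1] + edges[-length(edges)]) / 2,
                 per_molecule = per,
                 ensemble_mean = m,
                 ensemble_sem = sem,
                 n_molecules = nrow(per),
                 n_excluded_molecules = n_dropped,
                 n_excluded_values = n_excluded_values),
            class = "ensemble_histogram")
}

#' @export
print.ensemble_histogram <- function(x, ...) {
  cat(sprintf("ensemble_histogram: %d molecules, 30 bins over [-0.25, 1.25]\n",
              x$n_molecules))
  cat(sprintf("  peak bin at E = %.3f (mean mass %.4f); %d molecules dropped, %g values out of range\n",
              x$bin_centers[which.max(x$ensemble_mean)],
              max(x$ensemble_mean), x$n_excluded_molecules,
              x$n_excluded_values))
  invisible(x)
}

#' Compute FRET traces and histograms for a set of corrected traces
#'
#' Applies [compute_fret()] frame-wise over the pre-acceptor-bleach segment
#' of each accepted molecule and assembles per-molecule histograms.
#'
#' @param traces List of `corrected_trace` objects.
#' @param qc Optional list of `qc_report`s; when given, only passing
#'   molecules are used.
#' @param exclude_around_step Frames dropped before the acceptor-bleach
#'   step (default 3).
#' @return List with `fret` (per-molecule list of E series), `histograms`,
#'   `ensemble` (an `ensemble_histogram`) and `molecule_ids`.
#' @export
fret_ensemble <- function(traces, qc = NULL, exclude_around_step = 3L) {
  keep <- seq_along(traces)
  if (!is.null(qc)) keep <- which(vapply(qc, function(r) r$pass, logical(1)))
  fret <- list(); hists <- list(); ids <- integer(0)
  for (i in keep) {
    tr <- traces[[i]]
    ta <- tr$acceptor_bleach_frame
    end <- if (!is.na(ta)) ta - exclude_around_step - 1L else length(tr$donor)
    if (is.na(tr$gamma) || end < 1L) next
    E <- compute_fret(tr$acceptor[seq_len(end)], tr$donor[seq_len(end)],
                      tr$gamma)
    h <- molecule_histogram(E)
    if (h$n_in_range == 0L) next
    fret[[length(fret) + 1L]] <- E
    hists[[length(hists) + 1L]] <- h
    ids <- c(ids, tr$molecule_id %||% i)
  }
  if (!length(hists)) stop("no usable molecules", call. = FALSE)
  list(fret = fret, histograms = hists,
       ensemble = ensemble_histogram(hists), molecule_ids = ids)
}
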