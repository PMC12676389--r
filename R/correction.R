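#' Correction and quality-annotation parameters
#'
#' Settings shared by [correct_trace()] and [apply_qc()]. Defaults follow
#' common smFRET practice: 7% donor leakage, gamma accepted in [0.5, 2.5],
#' signal-to-noise cut at 5, anticorrelation threshold -0.3 on differenced
#' series for dynamic traces, and 50-frame windows on each side of the
#' acceptor-photobleach step for gamma estimation (frames within 3 of any
#' detected step excluded from window statistics).
#'
#' @param leakage_alpha Donor-to-acceptor spectral leakage fraction.
#' @param gamma_bounds Accepted per-molecule gamma range (inclusive).
#' @param snr_min Minimum signal-to-noise ratio (inclusive).
#' @param anticorrelation_max Maximum (most positive) accepted Pearson r of
#'   frame-difference donor vs acceptor for dynamic traces.
#' @param gamma_window Frames averaged on each side of the acceptor bleach.
#' @param step_penalty Change-point penalty; `NULL` uses
#'   `3 * sigma^2 * log(n)` with sigma estimated robustly per trace.
#' @param min_step_sigma Minimum detected step size in units of the robust
#'   per-frame noise sd (default 3).
#' @param exclude_around_step Frames dropped on each side of a detected step
#'   in all window statistics (default 3).
#' @param snr_cap Sentinel reported for noise-free traces (default 1e6).
#' @return A list of class `correction_params`.
#' @export
correction_params <- function(leakage_alpha = 0.07,
                              gamma_bounds = c(0.5, 2.5),
                              snr_min = 5,
                              anticorrelation_max = -0.3,
                              gamma_window = 50L,
                              step_penalty = NULL,
                              min_step_sigma = 3,
                              exclude_around_step = 3L,
                              snr_cap = 1e6) {
  if (leakage_alpha < 0 || leakage_alpha >= 1)
    stop("'leakage_alpha' must lie in [0, 1)", call. = FALSE)
  if (length(gamma_bounds) != 2L || gamma_bounds[1] >= gamma_bounds[2])
    stop("'gamma_bounds' must be an increasing pair", call. = FALSE)
  structure(list(leakage_alpha = leakage_alpha,
                 gamma_bounds = as.numeric(gamma_bounds),
                 snr_min = snr_min,
                 anticorrelation_max = anticorrelation_max,
                 gamma_window = as.integer(gamma_window),
                 step_penalty = step_penalty,
                 min_step_sigma = min_step_sigma,
                 exclude_around_step = as.integer(exclude_around_step),
                 snr_cap = snr_cap),
            class = "correction_params")
}

#' Subtract donor spectral leakage from the raw acceptor channel
#'
#' `I_acceptor(t) = I_acceptor_raw(t) - alpha * I_donor(t)`, element-wise.
#'
#' @param acceptor_raw,donor Numeric series of equal length.
#' @param alpha Leakage fraction in [0, 1).
#' @return Leakage-corrected acceptor series.
#' @examples
#' subtract_leakage(107, 100, 0.07)  # 100
#' @export
subtract_leakage <- function(acceptor_raw, donor, alpha = 0.07) {
  if (length(acceptor_raw) != length(donor))
    stop("'acceptor_raw' and 'donor' must have the same length", call. = FALSE)
  if (alpha < 0 || alpha >= 1) stop("'alpha' must lie in [0, 1)", call. = FALSE)
  acceptor_raw - alpha * donor
}

# Penalized least-squares change-point segmentation (piecewise-constant
# mean, optimal partitioning by dynamic programming). Returns the 1-based
# indices of the first frame of each new segment (excluding frame 1),
# after merging segments whose mean change is below min_step.
segment_signal <- function(x, penalty = NULL, sigma = NULL, min_step = NULL) {
  n <- length(x)
  if (n < 3) return(list(changepoints = integer(0), means = mean(x),
                         sigma = 0))
  sigma <- sigma %||% robust_sigma(x)
  if (sigma <= 0) sigma <- max(stats::sd(x) / 10, .Machine$double.eps)
  penalty <- penalty %||% (3 * sigma^2 * log(n))
  min_step <- min_step %||% (3 * sigma)

  cps <- pelt_mean_cpp(x, penalty)
  merge_small_steps(x, cps, sigma, min_step / (3 * sigma))
}

# Drop change-points whose segment-mean change is not significant at
# min_sig standard errors of the difference of the two segment means
# (sigma * sqrt(1/l1 + 1/l2)); a step between long segments can therefore
# be small in absolute terms and still count, while single-frame spikes
# need several sigma. Re-evaluated after each merge, least significant
# first.
merge_small_steps <- function(x, cps, sigma, scale = 1, min_sig = 3) {
  min_sig <- min_sig * scale
  repeat {
    bounds <- c(1L, cps, length(x) + 1L)
    means <- vapply(seq_len(length(bounds) - 1L), function(i)
      mean(x[bounds[i]:(bounds[i + 1L] - 1L)]), numeric(1))
    if (length(cps) == 0L)
      return(list(changepoints = cps, means = means,
                  sigma = robust_sigma(x)))
    lens <- diff(bounds)
    se <- sigma * sqrt(1 / lens[-length(lens)] + 1 / lens[-1])
    z <- abs(diff(means)) / pmax(se, .Machine$double.eps)
    j <- which.min(z)
    if (z[j] >= min_sig)
      return(list(changepoints = cps, means = means,
                  sigma = robust_sigma(x)))
    cps <- cps[-j]
  }
}

#' Detect photobleaching steps in an intensity series
#'
#' Fits a piecewise-constant mean model by penalized least-squares
#' change-point segmentation (noise sd estimated from median absolute
#' successive differences) and reports the downward mean changes larger
#' than `min_step_sigma` noise sd as bleaching steps.
#'
#' @param signal Numeric intensity series (>= 20 frames recommended).
#' @param penalty Segmentation penalty; `NULL` for the default
#'   `3 * sigma^2 * log(n)`.
#' @param min_step_sigma Minimum step size in noise-sd units (default 3).
#' @return List with `step_frames` (1-based index of the first frame after
#'   each downward step, ascending), `step_count`, and the underlying
#'   `segments` (`changepoints`, `means`, `sigma`).
#' @examples
#' x <- c(rep(1000, 50), rep(0, 50)) + rnorm(100, 0, 10)
#' detect_bleach_steps(x)$step_frames  # ~51
#' @export
detect_bleach_steps <- function(signal, penalty = NULL, min_step_sigma = 3) {
  seg <- segment_signal(signal, penalty = penalty,
                        min_step = min_step_sigma *
                          max(robust_sigma(signal), .Machine$double.eps))
  if (length(seg$changepoints) == 0L)
    return(list(step_frames = integer(0), step_count = 0L, segments = seg))
  down <- diff(seg$means) < 0
  list(step_frames = seg$changepoints[down],
       step_count = sum(down),
       segments = seg)
}

#' Estimate the per-molecule gamma factor at acceptor photobleaching
#'
#' `gamma = (mean Ia before - mean Ia after) / (mean Id after - mean Id
#' before)`, with means over `window` frames on each side of the acceptor
#' bleach step, excluding `exclude` frames around the step (and around any
#' other supplied step). This donor-recovery estimator is exact on
#' noise-free traces and insensitive to conformational state mixing within
#' the windows, because the state occupancy factor cancels between the
#' acceptor loss and the donor gain.
#'
#' @param donor,acceptor Corrected intensity series.
#' @param acceptor_bleach_frame First frame after the acceptor bleach step.
#' @param window Frames averaged on each side (default 50).
#' @param exclude Frames dropped around each step (default 3).
#' @param stop_frame Last usable frame after the bleach (e.g. the donor
#'   bleach frame); defaults to the series end.
#' @param other_steps Additional step frames whose neighbourhoods are
#'   excluded from the windows.
#' @return List with `gamma` (NA when undefined) and `reason` (`"ok"`,
#'   `"gamma_undefined"` for non-positive donor recovery, or
#'   `"gamma_window"` when fewer than 10 usable frames remain on a side).
#' @export
estimate_gamma <- function(donor, acceptor, acceptor_bleach_frame,
                           window = 50L, exclude = 3L, stop_frame = NULL,
                           other_steps = integer(0)) {
  n <- length(donor)
  ta <- acceptor_bleach_frame
  if (is.na(ta) || ta < 2 || ta > n)
    return(list(gamma = NA_real_, reason = "no_acceptor_bleach"))
  stop_frame <- stop_frame %||% NA_integer_
  if (is.na(stop_frame)) stop_frame <- n + 1L
  pre <- seq(max(1L, ta - exclude - window), ta - exclude - 1L)
  post <- seq(ta + exclude, min(n, stop_frame - exclude - 1L, ta + exclude + window - 1L))
  drop_near <- function(idx) {
    if (!length(other_steps)) return(idx)
    keep <- rep(TRUE, length(idx))
    for (s in other_steps)
      keep <- keep & abs(idx - s) > exclude
    idx[keep]
  }
  pre <- drop_near(pre[pre >= 1 & pre <= n])
  post <- drop_near(post[post >= 1 & post <= n])
  if (length(pre) < 10L || length(post) < 10L)
    return(list(gamma = NA_real_, reason = "gamma_window"))
  d_ia <- mean(acceptor[pre]) - mean(acceptor[post])
  d_id <- mean(donor[post]) - mean(donor[pre])
  if (d_id <= 0)
    return(list(gamma = NA_real_, reason = "gamma_undefined"))
  list(gamma = d_ia / d_id, reason = "ok")
}

#' Signal-to-noise ratio of a trace
#'
#' Defined as the mean pre-acceptor-bleach total intensity (donor +
#' acceptor) divided by the standard deviation of its high-frequency
#' residual after subtracting a 5-frame running median. This definition is
#' insensitive to slow dynamics and steps while capturing frame-to-frame
#' camera and shot noise.
#'
#' @param donor,acceptor Corrected series.
#' @param end_frame Last pre-bleach frame to use (default all frames).
#' @param cap Value reported for noise-free traces (default 1e6).
#' @return List with `snr` and `reason` (`"ok"` or `"short"` when fewer
#'   than 20 pre-bleach frames are available).
#' @export
compute_snr <- function(donor, acceptor, end_frame = NULL, cap = 1e6) {
  end_frame <- end_frame %||% length(donor)
  idx <- seq_len(max(0L, min(end_frame, length(donor))))
  if (length(idx) < 20L) return(list(snr = NA_real_, reason = "short"))
  total <- donor[idx] + acceptor[idx]
  resid <- total - stats::runmed(total, 5)
  s <- stats::sd(resid)
  m <- mean(total)
  if (s == 0) return(list(snr = cap, reason = "ok"))
  list(snr = min(m / s, cap), reason = "ok")
}

#' Anticorrelation of donor and acceptor fluctuations
#'
#' Pearson correlation between the frame-to-frame differences of the donor
#' and acceptor series over the pre-acceptor-bleach segment. Conformational
#' transitions move the two channels in opposite directions, so dynamic
#' single molecules show strongly negative values; a static molecule carries
#' no such signal and is instead judged on the opposite-sign intensity
#' changes at its acceptor-bleach step.
#'
#' @param donor,acceptor Corrected series.
#' @param end_frame Last pre-bleach frame to use.
#' @return Pearson r, or NA when a differenced series has zero variance or
#'   fewer than 20 frames are available.
#' @export
compute_anticorrelation <- function(donor, acceptor, end_frame = NULL) {
  end_frame <- end_frame %||% length(donor)
  idx <- seq_len(max(0L, min(end_frame, length(donor))))
  if (length(idx) < 20L) return(NA_real_)
  dd <- diff(donor[idx]); da <- diff(acceptor[idx])
  if (stats::sd(dd) == 0 || stats::sd(da) == 0) return(NA_real_)
  stats::cor(dd, da)
}

#' Correct and annotate a raw single-molecule trace
#'
#' Applies leakage subtraction, segments both channels by change-point
#' detection, locates and counts photobleaching steps, estimates the
#' per-molecule gamma factor at the acceptor bleach, and computes the
#' signal-to-noise ratio, donor/acceptor anticorrelation and
#' direct-excitation acceptor confirmation: everything the five-criterion
#' trace selection of [apply_qc()] consumes.
#'
#' Bleach-step bookkeeping distinguishes static from dynamic traces. A
#' trace is called dynamic when the acceptor channel shows internal steps
#' between two levels that are both clearly above background. On static
#' traces every persistent downward step is a bleaching event; on dynamic
#' traces only downward steps that land at background are (conformational
#' transitions also step downward but recover), and donor steps are counted
#' from the acceptor-dark part of the trace where the donor is no longer
#' modulated by FRET.
#'
#' @param trace A `raw_trace` (from [simulate_traces()] or
#'   [extract_trace()]).
#' @param params A [correction_params()] object.
#' @return An object of class `corrected_trace`.
#' @export
correct_trace <- function(trace, params = correction_params()) {
  if (inherits(trace, "corrected_trace"))
    stop("trace is already corrected; refusing to correct twice", call. = FALSE)
  if (!inherits(trace, "raw_trace"))
    stop("'trace' must be a raw_trace", call. = FALSE)
  donor <- as.numeric(trace$donor)
  acceptor <- subtract_leakage(as.numeric(trace$acceptor), donor,
                               params$leakage_alpha)
  n <- length(donor)
  sig_d <- robust_sigma(donor)
  sig_a <- robust_sigma(acceptor)

  seg_d <- segment_signal(donor, penalty = params$step_penalty,
                          min_step = params$min_step_sigma *
                            max(sig_d, .Machine$double.eps))
  seg_a <- segment_signal(acceptor, penalty = params$step_penalty,
                          min_step = params$min_step_sigma *
                            max(sig_a, .Machine$double.eps))

  ann_a <- channel_bleach_annotation(seg_a, n, sig_a)
  dynamic <- is_dynamic_trace(donor, seg_a, ann_a$alive, sig_d, sig_a)
  acc <- acceptor_step_bookkeeping(seg_a, ann_a, dynamic, sig_a)
  ann_d <- channel_bleach_annotation(seg_d, n, sig_d)
  if (is.na(acc$bleach_frame))
    acc <- rescue_acceptor_bleach(donor, acceptor, seg_d, ann_d,
                                  sig_a, acc)
  don <- donor_step_bookkeeping(seg_d, ann_d, acc$bleach_frame, dynamic, sig_d)

  g <- estimate_gamma(donor, acceptor, acc$bleach_frame,
                      window = params$gamma_window,
                      exclude = params$exclude_around_step,
                      stop_frame = don$bleach_frame %||% NA_integer_,
                      other_steps = setdiff(c(seg_d$changepoints,
                                              seg_a$changepoints),
                                            acc$bleach_frame))
  pre_end <- if (!is.na(acc$bleach_frame))
    acc$bleach_frame - params$exclude_around_step - 1L else n
  snr <- compute_snr(donor, acceptor, end_frame = pre_end, cap = params$snr_cap)
  r <- compute_anticorrelation(donor, acceptor, end_frame = pre_end)

  # fluorophore identity: a surviving acceptor must light up under direct
  # excitation; an acceptor that bleached mid-movie is evidenced by its
  # bleach step instead (it cannot respond to late direct excitation)
  direct <- as.numeric(trace$direct %||% numeric(0))
  direct_present <- length(direct) > 0 &&
    mean(direct) > 3 * max(sig_a, .Machine$double.eps)
  acceptor_confirmed <- if (!length(direct) && is.na(acc$bleach_frame)) NA
    else direct_present || !is.na(acc$bleach_frame)

  structure(list(
    molecule_id = trace$molecule_id,
    donor = donor, acceptor = acceptor, direct = direct,
    frame_period = trace$frame_period,
    gamma = g$gamma, gamma_reason = g$reason,
    acceptor_bleach_frame = acc$bleach_frame,
    donor_bleach_frame = don$bleach_frame,
    acceptor_step_count = acc$step_count,
    donor_step_count = don$step_count,
    snr = snr$snr, snr_reason = snr$reason,
    anticorrelation_r = r,
    dynamic = dynamic,
    bleach_anticorrelated = bleach_anticorrelation(donor, acceptor,
                                                   acc$bleach_frame,
                                                   sig_d, sig_a),
    acceptor_confirmed = acceptor_confirmed,
    segments = list(donor = seg_d, acceptor = seg_a),
    params = params,
    corrected = TRUE
  ), class = "corrected_trace")
}

#' @rdname correct_trace
#' @param traces List of raw traces.
#' @export
correct_traces <- function(traces, params = correction_params()) {
  lapply(traces, correct_trace, params = params)
}

#' @export
print.corrected_trace <- function(x, ...) {
  cat(sprintf("corrected_trace molecule %s (%d frames, %s)\n",
              format(x$molecule_id), length(x$donor),
              if (isTRUE(x$dynamic)) "dynamic" else "static"))
  cat(sprintf("  gamma %.3g (%s), snr %.3g, r %.3g\n",
              x$gamma, x$gamma_reason, x$snr, x$anticorrelation_r))
  cat(sprintf("  acceptor bleach %s (%d step), donor bleach %s (%d step), acceptor confirmed: %s\n",
              format(x$acceptor_bleach_frame), x$acceptor_step_count,
              format(x$donor_bleach_frame), x$donor_step_count,
              format(x$acceptor_confirmed)))
  invisible(x)
}

# Alive/dead segment classification for one channel. A segment is alive
# when its mean is distinguishable from background at 3 standard errors
# (sigma / sqrt(length)); a dim-but-long segment (e.g. a low-FRET acceptor
# dwell) therefore stays alive, while a trailing background run is dead.
channel_bleach_annotation <- function(seg, n, sigma) {
  bounds <- c(1L, seg$changepoints, n + 1L)
  means <- seg$means
  lens <- diff(bounds)
  thr <- pmax(3 * sigma / sqrt(lens), 0.05 * max(means),
              .Machine$double.eps)
  alive <- means >= thr
  bleach <- NA_integer_
  if (any(alive) && !alive[length(alive)]) {
    last_alive <- max(which(alive))
    bleach <- bounds[last_alive + 1L]
  }
  list(alive = alive, bounds = bounds, means = means,
       alive_threshold = thr, bleach_frame = bleach,
       present = any(alive))
}

# A trace is dynamic when the acceptor steps between two levels that are
# both clearly above background AND the donor moves in the opposite
# direction at the same frame (the signature of a conformational
# transition; an irreversible acceptor drop without donor compensation is
# bleaching, not dynamics).
is_dynamic_trace <- function(donor, seg_a, alive, sig_d, sig_a) {
  cps <- seg_a$changepoints
  if (length(cps) == 0L) return(FALSE)
  m <- seg_a$means
  n <- length(donor)
  for (j in seq_along(cps)) {
    if (!alive[j] || !alive[j + 1]) next
    da <- m[j + 1] - m[j]
    if (abs(da) <= 3 * sig_a) next
    cp <- cps[j]
    pre <- max(1L, cp - 9L):max(1L, cp - 2L)
    post <- min(n, cp + 1L):min(n, cp + 8L)
    dd <- mean(donor[post]) - mean(donor[pre])
    if (sign(dd) == -sign(da) && abs(dd) > 3 * sig_d / sqrt(8))
      return(TRUE)
  }
  FALSE
}

acceptor_step_bookkeeping <- function(seg, ann, dynamic, sigma) {
  if (!ann$present)
    return(list(bleach_frame = NA_integer_, step_count = 0L))
  m <- ann$means
  cps <- seg$changepoints
  if (!length(cps))
    return(list(bleach_frame = ann$bleach_frame, step_count = 0L))
  down <- diff(m) < 0
  if (dynamic) {
    # only downward steps that land at background are bleaching events
    lands_dead <- !ann$alive[-1]
    count <- sum(down & lands_dead)
  } else {
    count <- sum(down)
  }
  list(bleach_frame = ann$bleach_frame, step_count = as.integer(count))
}

donor_step_bookkeeping <- function(seg, ann, acceptor_bleach_frame, dynamic,
                                   sigma) {
  m <- ann$means
  cps <- seg$changepoints
  if (!length(cps) || !ann$present)
    return(list(bleach_frame = ann$bleach_frame, step_count = 0L))
  down <- diff(m) < 0
  if (!is.na(acceptor_bleach_frame)) {
    # once the acceptor is dark the donor is unmodulated by FRET, so every
    # downward step there is a bleaching event
    usable <- cps >= acceptor_bleach_frame
    count <- sum(down & usable)
  } else if (dynamic) {
    lands_dead <- !ann$alive[-1]
    count <- sum(down & lands_dead)
  } else {
    count <- sum(down)
  }
  list(bleach_frame = ann$bleach_frame, step_count = as.integer(count))
}

# Opposite-sign intensity changes at the acceptor-bleach step (the static
# trace's evidence of donor/acceptor coupling): window means on each side
# of the step, excluding 2 frames around it.
bleach_anticorrelation <- function(donor, acceptor, acceptor_bleach_frame,
                                   sig_d, sig_a, w = 10L) {
  ta <- acceptor_bleach_frame
  n <- length(donor)
  if (is.na(ta) || ta < 4 || ta > n - 3) return(NA)
  pre <- max(1L, ta - 2L - w):(ta - 3L)
  post <- (ta + 2L):min(n, ta + 1L + w)
  dd <- mean(donor[post]) - mean(donor[pre])
  da <- mean(acceptor[post]) - mean(acceptor[pre])
  k <- sqrt(1 / length(pre) + 1 / length(post))
  isTRUE(dd > 3 * sig_d * k && da < -3 * sig_a * k)
}

# When the acceptor channel shows no detectable bleach step (a dim
# acceptor bleaching out of a low-FRET state), the donor still reports the
# event: a persistent upward step after which the acceptor sits at
# background. gamma does not enter the donor signature, so this rescue is
# unbiased across molecules.
rescue_acceptor_bleach <- function(donor, acceptor, seg_d, ann_d,
                                   sig_a, acc) {
  cps <- seg_d$changepoints
  if (!length(cps)) return(acc)
  up <- which(diff(seg_d$means) > 0)
  n <- length(donor)
  stop_frame <- ann_d$bleach_frame
  if (is.na(stop_frame)) stop_frame <- n + 1L
  for (j in rev(up)) {
    t <- cps[j]
    if (t >= stop_frame - 10L || t < 15L) next
    tail_idx <- t:min(n, stop_frame - 1L)
    pre_idx <- max(1L, t - 50L):(t - 3L)
    tail_dead <- abs(mean(acceptor[tail_idx])) <
      3 * sig_a / sqrt(length(tail_idx))
    pre_alive <- mean(acceptor[pre_idx]) >
      3 * sig_a / sqrt(length(pre_idx))
    if (tail_dead && pre_alive)
      return(list(bleach_frame = as.integer(t), step_count = 1L))
  }
  acc
}
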