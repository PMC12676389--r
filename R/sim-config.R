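#' Simulation settings for synthetic smFRET data
#'
#' Collects the acquisition and photophysics constants used by
#' [simulate_traces()] and [simulate_movie()]. The defaults emulate a
#' typical objective-TIRF recording: 100 ms exposure, an 80 s
#' donor-excitation segment followed by 1 s of direct acceptor excitation
#' to confirm fluorophore identity, ~7% donor leakage into the acceptor
#' channel, per-molecule gamma drawn in [0.5, 2.5], and single-step
#' exponential photobleaching on tens-of-seconds timescales.
#'
#' Two state regimes are bundled: the default static two-population mixture
#' (distinct labelling geometries, FRET means 0.5 and 0.9, no
#' interconversion) and, via [sim_config_dynamic()], a dynamic two-state
#' receptor whose FRET level switches between an active (low-FRET) and an
#' inactive (high-FRET) conformation.
#'
#' @param frame_period Seconds per frame (default 0.1).
#' @param n_frames_donor_exc Number of donor-excitation frames (default 800,
#'   i.e. 80 s at 10 frames/s).
#' @param n_frames_acceptor_exc Number of direct-acceptor-excitation frames
#'   appended after the donor segment (default 10, i.e. 1 s).
#' @param state_means FRET efficiency of each state, all in [0, 1].
#' @param state_occupancies Probability of each state; must sum to 1. For a
#'   static mixture these are realised as exact molecule counts (largest
#'   remainder rounding) so the prepared ensemble composition equals the
#'   requested one; with dynamics they set the initial-state distribution.
#' @param transition_rates Square matrix of per-second transition rates
#'   between states (row = from, column = to, diagonal ignored). `NULL` or
#'   all-zero means a static mixture.
#' @param total_intensity Donor-excitation photon budget per frame, in
#'   arbitrary linear camera units: a molecule in state E emits
#'   `(1-E)*total_intensity` in the donor channel and
#'   `gamma*E*total_intensity` in the acceptor channel.
#' @param donor_bleach_lifetime,acceptor_bleach_lifetime Mean single-step
#'   photobleaching time in seconds (exponential).
#' @param leakage_alpha Fraction of donor emission detected in the acceptor
#'   channel (default 0.07).
#' @param gamma_range Range from which each molecule's true gamma factor is
#'   drawn uniformly (default `c(0.5, 2.5)`).
#' @param background_sigma Additive Gaussian noise sd per channel per frame
#'   (trace-level units). The default (100), combined with shot noise, puts
#'   the median trace signal-to-noise ratio near 8 under the default
#'   intensity, comfortably above the usual selection cut of 5.
#' @param shot_noise Apply Poisson shot noise to expected counts
#'   (default `TRUE`).
#' @param direct_intensity Acceptor-channel intensity during direct acceptor
#'   excitation for a surviving acceptor; default equals `total_intensity`.
#' @param contaminant_fractions Named numeric vector with entries
#'   `donor_only`, `acceptor_only` and `aggregate` giving the proportions of
#'   contaminant molecule classes (aggregates superpose 2-3 independent
#'   dye pairs and exhibit multi-step bleaching).
#' @param seed Master RNG seed; every molecule derives its own sub-stream
#'   from it, so results do not depend on generation order.
#'
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(n_frames_donor_exc = 200, seed = 7)
#' cfg
#' @export
sim_config <- function(frame_period = 0.1,
                       n_frames_donor_exc = 800L,
                       n_frames_acceptor_exc = 10L,
                       state_means = c(0.5, 0.9),
                       state_occupancies = c(0.5, 0.5),
                       transition_rates = NULL,
                       total_intensity = 1000,
                       donor_bleach_lifetime = 60,
                       acceptor_bleach_lifetime = 40,
                       leakage_alpha = 0.07,
                       gamma_range = c(0.5, 2.5),
                       background_sigma = 100,
                       shot_noise = TRUE,
                       direct_intensity = NULL,
                       contaminant_fractions = c(donor_only = 0,
                                                 acceptor_only = 0,
                                                 aggregate = 0),
                       seed = 1L) {
  stopifnot_scalar(frame_period, "frame_period", lower = 1e-6)
  stopifnot_scalar(n_frames_donor_exc, "n_frames_donor_exc", lower = 1)
  stopifnot_scalar(n_frames_acceptor_exc, "n_frames_acceptor_exc", lower = 0)
  stopifnot_scalar(total_intensity, "total_intensity", lower = 0)
  stopifnot_scalar(donor_bleach_lifetime, "donor_bleach_lifetime", lower = 1e-9)
  stopifnot_scalar(acceptor_bleach_lifetime, "acceptor_bleach_lifetime", lower = 1e-9)
  stopifnot_scalar(background_sigma, "background_sigma", lower = 0)
  if (!is.numeric(leakage_alpha) || leakage_alpha < 0 || leakage_alpha >= 1)
    stop("'leakage_alpha' must lie in [0, 1)", call. = FALSE)
  if (!is.numeric(state_means) || any(state_means < 0 | state_means > 1))
    stop("'state_means' must all lie in [0, 1]", call. = FALSE)
  if (length(state_occupancies) != length(state_means))
    stop("'state_occupancies' must match 'state_means' in length", call. = FALSE)
  if (any(state_occupancies < 0) ||
      abs(sum(state_occupancies) - 1) > 1e-12)
    stop("'state_occupancies' must be non-negative and sum to 1", call. = FALSE)
  if (!is.null(transition_rates)) {
    transition_rates <- as.matrix(transition_rates)
    if (nrow(transition_rates) != length(state_means) ||
        ncol(transition_rates) != length(state_means))
      stop("'transition_rates' must be a square matrix matching the number of states",
           call. = FALSE)
    offdiag <- transition_rates[row(transition_rates) != col(transition_rates)]
    if (any(offdiag < 0))
      stop("'transition_rates' must have non-negative off-diagonal entries",
           call. = FALSE)
  }
  if (length(gamma_range) != 2L || gamma_range[1] <= 0 ||
      gamma_range[1] > gamma_range[2])
    stop("'gamma_range' must be an increasing positive pair", call. = FALSE)
  cf <- c(donor_only = 0, acceptor_only = 0, aggregate = 0)
  if (length(contaminant_fractions)) {
    bad <- setdiff(names(contaminant_fractions), names(cf))
    if (length(bad))
      stop("unknown contaminant class(es): ", paste(bad, collapse = ", "),
           call. = FALSE)
    cf[names(contaminant_fractions)] <- contaminant_fractions
  }
  if (any(cf < 0) || sum(cf) > 1)
    stop("'contaminant_fractions' must be non-negative and sum to at most 1",
         call. = FALSE)
  structure(list(
    frame_period = frame_period,
    n_frames_donor_exc = as.integer(n_frames_donor_exc),
    n_frames_acceptor_exc = as.integer(n_frames_acceptor_exc),
    state_means = as.numeric(state_means),
    state_occupancies = as.numeric(state_occupancies),
    transition_rates = transition_rates,
    total_intensity = total_intensity,
    donor_bleach_lifetime = donor_bleach_lifetime,
    acceptor_bleach_lifetime = acceptor_bleach_lifetime,
    leakage_alpha = leakage_alpha,
    gamma_range = as.numeric(gamma_range),
    background_sigma = background_sigma,
    shot_noise = isTRUE(shot_noise),
    direct_intensity = direct_intensity %||% total_intensity,
    contaminant_fractions = cf,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' @rdname sim_config
#' @param ... Overrides passed on to [sim_config()].
#' @details `sim_config_dynamic()` presets a dynamic two-state receptor:
#' FRET means 0.25 (active, helix moved out) and 0.85 (inactive), symmetric
#' 0.5/s transition rates (mean dwell 2 s), equal occupancies.
#' @export
sim_config_dynamic <- function(...) {
  args <- list(...)
  defaults <- list(
    state_means = c(0.25, 0.85),
    state_occupancies = c(0.5, 0.5),
    transition_rates = matrix(c(0, 0.5, 0.5, 0), 2, 2, byrow = TRUE)
  )
  for (nm in names(defaults))
    if (is.null(args[[nm]])) args[[nm]] <- defaults[[nm]]
  do.call(sim_config, args)
}

#' @export
print.sim_config <- function(x, ...) {
  dyn <- !is.null(x$transition_rates) &&
    any(x$transition_rates[row(x$transition_rates) != col(x$transition_rates)] > 0)
  cat("smFRET simulation config\n")
  cat(sprintf("  frames: %d donor-exc + %d direct-acceptor-exc @ %.3g s/frame\n",
              x$n_frames_donor_exc, x$n_frames_acceptor_exc, x$frame_period))
  cat(sprintf("  states: E = {%s}, occupancies {%s}, %s\n",
              paste(format(x$state_means), collapse = ", "),
              paste(format(x$state_occupancies), collapse = ", "),
              if (dyn) "dynamic" else "static mixture"))
  cat(sprintf("  intensity %.4g, leakage %.3g, gamma in [%.3g, %.3g], bg sigma %.4g\n",
              x$total_intensity, x$leakage_alpha, x$gamma_range[1],
              x$gamma_range[2], x$background_sigma))
  cat(sprintf("  bleach lifetimes (s): donor %.3g, acceptor %.3g; contaminants %s\n",
              x$donor_bleach_lifetime, x$acceptor_bleach_lifetime,
              paste(sprintf("%s=%.2g", names(x$contaminant_fractions),
                            x$contaminant_fractions), collapse = " ")))
  invisible(x)
}

# Largest-remainder apportionment of n items over probabilities p.
apportion <- function(n, p) {
  raw <- n * p
  k <- floor(raw)
  rem <- n - sum(k)
  if (rem > 0) {
    ord <- order(raw - k, decreasing = TRUE)
    k[ord[seq_len(rem)]] <- k[ord[seq_len(rem)]] + 1
  }
  as.integer(k)
}

# Discrete-time transition matrix over one frame from a rate matrix, via
# the matrix exponential (eigen decomposition; exact for the small state
# spaces used here).
frame_transition_matrix <- function(rates, dt) {
  n <- nrow(rates)
  Q <- rates
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  e <- eigen(Q)
  P <- Re(e$vectors %*% diag(exp(e$values * dt), n) %*% solve(e$vectors))
  P[P < 0] <- 0
  P / rowSums(P)
}

# Stationary distribution of a rate matrix (left null vector of Q).
stationary_distribution <- function(rates) {
  Q <- rates
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  n <- nrow(Q)
  A <- rbind(t(Q), rep(1, n))
  b <- c(rep(0, n), 1)
  pi_hat <- stats::lsfit(A, b, intercept = FALSE)$coefficients
  pi_hat <- pmax(pi_hat, 0)
  pi_hat / sum(pi_hat)
}
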