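#' Simulate single-molecule FRET intensity traces with known ground truth
#'
#' Generates per-molecule donor/acceptor intensity time series under the
#' standard smFRET signal model: a molecule in a state with FRET efficiency
#' E emits an expected `(1-E)*I_tot` in the donor channel and
#' `gamma*E*I_tot` in the acceptor channel, so that the corrected estimator
#' `Ia/(Ia + gamma*Id)` recovers E exactly on noise-free data and the
#' acceptor-photobleach estimator `gamma = dIa/dId` is exact. A fraction
#' `leakage_alpha` of the donor signal is added to the raw acceptor channel.
#' Each fluorophore photobleaches in a single step at an exponential time;
#' after acceptor bleach the donor recovers to the full budget, after donor
#' bleach both channels fall to background. The direct-acceptor-excitation
#' segment reports the acceptor's survival. Contaminant classes (donor-only,
#' acceptor-only, aggregates of 2-3 superposed dye pairs) are generated on
#' request to exercise downstream quality filters.
#'
#' @param config A [sim_config()] object.
#' @param n_molecules Number of molecules to generate.
#' @return A list with elements
#'   \describe{
#'     \item{traces}{list of `raw_trace` objects (fields `donor`,
#'       `acceptor`, `direct`, `frame_period`, `molecule_id`), intensities
#'       background-corrected but leakage-uncorrected;}
#'     \item{truth}{a `data.frame` with one row per molecule: class, true
#'       gamma, true bleach frames (first dead frame, NA if beyond the
#'       segment), initial state and number of dye units;}
#'     \item{state_paths}{list of integer state index per frame (good
#'       molecules; NA entries for contaminants);}
#'     \item{config}{the configuration used.}
#'   }
#' @examples
#' sim <- simulate_traces(sim_config(n_frames_donor_exc = 100, seed = 2), 5)
#' sim$truth
#' @export
simulate_traces <- function(config, n_molecules) {
  if (!inherits(config, "sim_config")) stop("'config' must be a sim_config")
  stopifnot_scalar(n_molecules, "n_molecules", lower = 1)
  n_molecules <- as.integer(n_molecules)

  classes <- assign_classes(config, n_molecules)
  init_states <- assign_states(config, classes)

  traces <- vector("list", n_molecules)
  paths <- vector("list", n_molecules)
  truth <- data.frame(
    molecule_id = seq_len(n_molecules),
    class = classes,
    gamma = NA_real_,
    acceptor_bleach_frame = NA_integer_,
    donor_bleach_frame = NA_integer_,
    init_state = init_states,
    n_units = 1L,
    stringsAsFactors = FALSE
  )

  for (k in seq_len(n_molecules)) {
    set.seed(derive_seed(config$seed, k, salt = 11L))
    mol <- simulate_one_molecule(config, classes[k], init_states[k])
    mol$trace$molecule_id <- k
    traces[[k]] <- mol$trace
    paths[[k]] <- mol$state_path
    truth$gamma[k] <- mol$gamma
    truth$acceptor_bleach_frame[k] <- mol$acceptor_bleach_frame
    truth$donor_bleach_frame[k] <- mol$donor_bleach_frame
    truth$n_units[k] <- mol$n_units
  }
  list(traces = traces, truth = truth, state_paths = paths, config = config)
}

# Deterministic class composition (largest remainder), order permuted from
# the master seed.
assign_classes <- function(config, n) {
  cf <- config$contaminant_fractions
  p <- c(good = 1 - sum(cf), cf)
  counts <- apportion(n, p)
  labels <- rep(names(p), counts)
  set.seed(derive_seed(config$seed, 0L, salt = 5L))
  sample(labels)
}

# Exact-count state assignment for good molecules (stratified so that the
# prepared ensemble composition equals state_occupancies).
assign_states <- function(config, classes) {
  n <- length(classes)
  out <- rep(NA_integer_, n)
  idx <- which(classes %in% c("good", "aggregate"))
  if (!length(idx)) return(out)
  counts <- apportion(length(idx), config$state_occupancies)
  states <- rep(seq_along(config$state_means), counts)
  set.seed(derive_seed(config$seed, 0L, salt = 6L))
  out[idx] <- sample(states)
  out
}

simulate_one_molecule <- function(config, class, init_state) {
  n_units <- switch(class,
    good = 1L, donor_only = 1L, acceptor_only = 1L,
    aggregate = sample(2:3, 1L))
  Td <- config$n_frames_donor_exc
  Ta <- config$n_frames_acceptor_exc
  donor <- numeric(Td); acceptor <- numeric(Td); direct <- numeric(Ta)
  gammas <- stats::runif(n_units, config$gamma_range[1], config$gamma_range[2])
  a_bleach <- rep(NA_integer_, n_units)
  d_bleach <- rep(NA_integer_, n_units)
  path_main <- NULL

  for (u in seq_len(n_units)) {
    st <- if (u == 1L && !is.na(init_state)) init_state else
      sample(seq_along(config$state_means), 1L,
             prob = config$state_occupancies)
    path <- simulate_state_path(config, st, Td)
    if (u == 1L) path_main <- path
    tb_d <- stats::rexp(1, 1 / config$donor_bleach_lifetime)
    tb_a <- stats::rexp(1, 1 / config$acceptor_bleach_lifetime)
    # first frame at which the fluorophore is dark (1-based)
    fb_d <- floor(tb_d / config$frame_period) + 1L
    fb_a <- floor(tb_a / config$frame_period) + 1L
    has_donor <- class != "acceptor_only"
    has_acceptor <- class != "donor_only"
    frames <- seq_len(Td)
    donor_alive <- if (has_donor) frames < fb_d else rep(FALSE, Td)
    acceptor_alive <- if (has_acceptor) frames < fb_a else rep(FALSE, Td)
    E <- config$state_means[path]
    E_eff <- ifelse(acceptor_alive, E, 0)
    donor <- donor + ifelse(donor_alive, (1 - E_eff) * config$total_intensity, 0)
    acceptor <- acceptor +
      ifelse(donor_alive, gammas[u] * E_eff * config$total_intensity, 0)
    if (has_acceptor && Ta > 0) {
      # acceptor survival carries through to the direct-excitation segment
      alive_direct <- fb_a > Td
      direct <- direct + if (alive_direct) rep(config$direct_intensity, Ta) else
        numeric(Ta)
    }
    if (has_donor) d_bleach[u] <- if (fb_d <= Td) fb_d else NA_integer_
    if (has_acceptor) a_bleach[u] <- if (fb_a <= Td) fb_a else NA_integer_
  }

  # donor leakage into the raw acceptor channel
  acceptor_raw <- acceptor + config$leakage_alpha * donor
  donor_raw <- donor

  add_noise <- function(expected) {
    x <- if (config$shot_noise) stats::rpois(length(expected), expected)
         else expected
    if (config$background_sigma > 0)
      x <- x + stats::rnorm(length(expected), 0, config$background_sigma)
    x
  }
  trace <- structure(list(
    molecule_id = NA_integer_,
    donor = add_noise(donor_raw),
    acceptor = add_noise(acceptor_raw),
    direct = add_noise(direct),
    donor_expected = donor_raw,
    acceptor_expected = acceptor_raw,
    direct_expected = direct,
    frame_period = config$frame_period,
    background_sigma = config$background_sigma
  ), class = "raw_trace")

  list(trace = trace,
       gamma = if (n_units == 1L) gammas[1] else mean(gammas),
       acceptor_bleach_frame = if (all(is.na(a_bleach))) NA_integer_
                               else suppressWarnings(max(a_bleach, na.rm = TRUE)),
       donor_bleach_frame = if (all(is.na(d_bleach))) NA_integer_
                            else suppressWarnings(max(d_bleach, na.rm = TRUE)),
       n_units = n_units,
       state_path = if (class %in% c("good", "aggregate")) path_main else
         rep(NA_integer_, Td))
}

# Frame-resolution discrete-time embedding of the continuous-time chain.
simulate_state_path <- function(config, init_state, n_frames) {
  rates <- config$transition_rates
  static <- is.null(rates) ||
    all(rates[row(rates) != col(rates)] == 0)
  if (static) return(rep(init_state, n_frames))
  P <- frame_transition_matrix(rates, config$frame_period)
  path <- integer(n_frames)
  path[1] <- init_state
  u <- stats::runif(n_frames - 1L)
  for (t in seq_len(n_frames - 1L)) {
    path[t + 1L] <- findInterval(u[t], cumsum(P[path[t], ]),
                                 left.open = TRUE) + 1L
  }
  path
}

#' @export
print.raw_trace <- function(x, ...) {
  cat(sprintf("raw_trace molecule %s: %d donor-exc frames + %d direct-exc frames @ %.3g s\n",
              format(x$molecule_id), length(x$donor), length(x$direct),
              x$frame_period))
  invisible(x)
}
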