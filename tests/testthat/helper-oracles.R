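# Independent oracles and trace builders used across the suite. These are
# deliberately brute-force implementations, kept separate from the package
# code paths they check.

# Exhaustive least-squares change-point fit with a known number of steps
# (0, 1 or 2). Returns the breakpoints (first frame of each new segment)
# minimising the total within-segment SSE.
oracle_changepoints <- function(x, k) {
  n <- length(x)
  if (k == 0) return(integer(0))
  cs <- c(0, cumsum(x))
  ss <- c(0, cumsum(x^2))
  sse <- function(a, b) {  # frames a..b inclusive
    s <- cs[b + 1] - cs[a]
    (ss[b + 1] - ss[a]) - s^2 / (b - a + 1)
  }
  if (k == 1) {
    best <- Inf; arg <- NA_integer_
    for (c1 in 2:n) {
      v <- sse(1, c1 - 1) + sse(c1, n)
      if (v < best) { best <- v; arg <- c1 }
    }
    return(arg)
  }
  # k == 2: vectorised scan over the second breakpoint for each first
  best <- Inf; arg <- c(NA_integer_, NA_integer_)
  left <- vapply(2:n, function(c1) sse(1, c1 - 1), numeric(1))
  for (c1 in 2:(n - 1)) {
    c2 <- (c1 + 1):n
    s_mid <- cs[c2] - cs[c1]
    len_mid <- c2 - c1
    sse_mid <- (ss[c2] - ss[c1]) - s_mid^2 / len_mid
    s_right <- cs[n + 1] - cs[c2]
    len_right <- n - c2 + 1
    sse_right <- (ss[n + 1] - ss[c2]) - s_right^2 / len_right
    tot <- left[c1 - 1] + sse_mid + sse_right
    j <- which.min(tot)
    if (tot[j] < best) { best <- tot[j]; arg <- c(c1, c2[j]) }
  }
  arg
}

# Piecewise-constant step trace builder (levels per segment, breakpoints =
# first frame of each new segment).
make_step_trace <- function(n, breakpoints, levels, sigma = 0) {
  x <- numeric(n)
  b <- c(1L, breakpoints, n + 1L)
  for (j in seq_along(levels)) x[b[j]:(b[j + 1] - 1L)] <- levels[j]
  if (sigma > 0) x <- x + stats::rnorm(n, 0, sigma)
  x
}

# Build a raw_trace object directly from donor/acceptor series.
make_raw_trace <- function(donor, acceptor, direct = numeric(0),
                           frame_period = 0.1, id = 1L) {
  structure(list(molecule_id = id, donor = donor, acceptor = acceptor,
                 direct = direct, frame_period = frame_period),
            class = "raw_trace")
}

# Canonical synthetic good molecule: static state E, gamma, single-step
# acceptor bleach at ta then donor bleach at td, leakage applied, Gaussian
# noise added. Mirrors the physics but written independently of
# simulate_traces().
make_good_trace <- function(n = 400, E = 0.6, gamma = 1.2, I0 = 1000,
                            ta = 200, td = 320, alpha = 0.07, sigma = 20,
                            n_direct = 10, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fr <- seq_len(n)
  donor <- ifelse(fr < ta, (1 - E) * I0, ifelse(fr < td, I0, 0))
  acceptor <- ifelse(fr < ta, gamma * E * I0, 0)
  acceptor_raw <- acceptor + alpha * donor
  direct <- rep(0, n_direct)  # acceptor dead by the direct segment
  if (sigma > 0) {
    donor <- donor + rnorm(n, 0, sigma)
    acceptor_raw <- acceptor_raw + rnorm(n, 0, sigma)
    direct <- direct + rnorm(n_direct, 0, sigma)
  }
  make_raw_trace(donor, acceptor_raw, direct)
}

# Construct a corrected_trace with chosen annotations (for testing the QC
# logic in isolation from the correction machinery).
make_corrected <- function(snr = 10, gamma = 1, acceptor_bleach_frame = 200L,
                           donor_bleach_frame = 320L,
                           acceptor_step_count = 1L, donor_step_count = 1L,
                           anticorrelation_r = -0.8, dynamic = FALSE,
                           bleach_anticorrelated = TRUE,
                           acceptor_confirmed = TRUE, id = 1L) {
  structure(list(molecule_id = id, donor = rep(500, 400),
                 acceptor = rep(500, 400), direct = rep(1000, 10),
                 frame_period = 0.1,
                 gamma = gamma, gamma_reason = "ok",
                 acceptor_bleach_frame = acceptor_bleach_frame,
                 donor_bleach_frame = donor_bleach_frame,
                 acceptor_step_count = acceptor_step_count,
                 donor_step_count = donor_step_count,
                 snr = snr, snr_reason = "ok",
                 anticorrelation_r = anticorrelation_r,
                 dynamic = dynamic,
                 bleach_anticorrelated = bleach_anticorrelated,
                 acceptor_confirmed = acceptor_confirmed,
                 segments = NULL, params = correction_params(),
                 corrected = TRUE),
            class = "corrected_trace")
}

# Exact Mann-Whitney two-sided p from the closed-form null distribution of
# U (stats::dwilcox; valid without ties), independent of the package's
# permutation enumeration.
oracle_mw_exact_p <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  r <- rank(c(a, b))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  maxu <- n1 * n2
  probs <- stats::dwilcox(0:maxu, n1, n2)
  center <- maxu / 2
  sum(probs[abs(0:maxu - center) >= abs(u - center) - 1e-9])
}

# Analytic mass of a 2D Gaussian inside a centred circular aperture.
gaussian_mass_in_circle <- function(radius, sigma) {
  1 - exp(-radius^2 / (2 * sigma^2))
}
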