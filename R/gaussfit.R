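#' Fit a two-Gaussian population model to an ensemble FRET histogram
#'
#' Nonlinear least squares of
#' `w * (A_low * N(mu_low, sigma_low) + A_high * N(mu_high, sigma_high))`
#' (w = bin width) against the ensemble mean at the bin centres, with
#' bounded parameters (means in [-0.25, 1.25], sigmas in [0.01, 0.5]) and
#' multi-start initialisation. Components are ordered by mean after the
#' fit and population fractions are defined as Gaussian area shares,
#' `A_i / (A_low + A_high)`.
#'
#' @param hist An `ensemble_histogram` (or a 30-vector of bin masses).
#' @param init Optional list with `means`, `sigmas`, `areas` used as an
#'   additional starting point.
#' @param shared_sigma Constrain both components to one width
#'   (default `FALSE`).
#' @return Object of class `gaussian_mixture_fit`: `means`, `sigmas`,
#'   `areas`, `fractions` (low then high mean; sum 1), `rss`, `fitted`,
#'   `n_molecules`, `converged`.
#' @examples
#' x <- fret_bin_edges()
#' centers <- (x[-1] + x[-31]) / 2
#' y <- 0.05 * (0.3 * dnorm(centers, 0.35, 0.05) + 0.7 * dnorm(centers, 0.85, 0.05))
#' fit <- fit_two_gaussian(y / sum(y))
#' fit$fractions
#' @export
fit_two_gaussian <- function(hist, init = NULL, shared_sigma = FALSE) {
  if (inherits(hist, "ensemble_histogram")) {
    y <- hist$ensemble_mean
    x <- hist$bin_centers
    n_mol <- hist$n_molecules
  } else {
    y <- as.numeric(hist)
    edges <- fret_bin_edges()
    x <- (edges[-1] + edges[-length(edges)]) / 2
    n_mol <- NA_integer_
  }
  if (length(y) != 30L) stop("expected a 30-bin histogram", call. = FALSE)
  w <- diff(fret_bin_edges())[1]

  model <- function(p) {
    w * (p[1] * stats::dnorm(x, p[2], p[3]) +
         p[4] * stats::dnorm(x, p[5], if (shared_sigma) p[3] else p[6]))
  }
  starts <- gaussfit_starts(x, y, init)
  lower <- c(0, -0.25, 0.01, 0, -0.25, 0.01)
  upper <- c(2, 1.25, 0.5, 2, 1.25, 0.5)
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = pmin(pmax(s, lower), upper),
        lower = lower, upper = upper,
        fn = function(p) y - model(p),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss) best <- list(par = fit$par, rss = rss)
  }
  if (is.null(best))
    stop("two-Gaussian fit failed to converge from all starting points",
         call. = FALSE)
  p <- best$par
  if (shared_sigma) p[6] <- p[3]
  comp <- data.frame(A = p[c(1, 4)], mu = p[c(2, 5)], sigma = p[c(3, 6)])
  comp <- comp[order(comp$mu), ]
  total <- sum(comp$A)
  fractions <- if (total > 0) comp$A / total else c(NA_real_, NA_real_)
  structure(list(means = comp$mu, sigmas = comp$sigma, areas = comp$A,
                 fractions = fractions,
                 rss = best$rss,
                 fitted = model(p),
                 bin_centers = x, observed = y,
                 n_molecules = n_mol, shared_sigma = shared_sigma,
                 converged = TRUE),
            class = "gaussian_mixture_fit")
}

# Starting points: peak-pair detection plus a fixed grid of plausible
# two-state configurations.
gaussfit_starts <- function(x, y, init = NULL) {
  starts <- list()
  if (!is.null(init))
    starts[[1]] <- c(init$areas[1], init$means[1], init$sigmas[1],
                     init$areas[2], init$means[2], init$sigmas[2])
  top <- x[order(-y)]
  mu1 <- top[1]
  far <- top[abs(top - mu1) > 0.2]
  mu2 <- if (length(far)) far[1] else mu1 + 0.3
  starts[[length(starts) + 1L]] <- c(0.5, min(mu1, mu2), 0.08,
                                     0.5, max(mu1, mu2), 0.08)
  grid <- list(c(0.3, 0.8), c(0.25, 0.85), c(0.5, 0.9), c(0.2, 0.6),
               c(0.4, 0.9), c(0.1, 0.5))
  for (g in grid)
    starts[[length(starts) + 1L]] <- c(0.5, g[1], 0.08, 0.5, g[2], 0.08)
  starts
}

#' @export
print.gaussian_mixture_fit <- function(x, ...) {
  cat("two-Gaussian population fit\n")
  cat(sprintf("  low : mu %.3f sigma %.3f area %.3f fraction %.1f%%\n",
              x$means[1], x$sigmas[1], x$areas[1], 100 * x$fractions[1]))
  cat(sprintf("  high: mu %.3f sigma %.3f area %.3f fraction %.1f%%\n",
              x$means[2], x$sigmas[2], x$areas[2], 100 * x$fractions[2]))
  cat(sprintf("  rss %.3g over 30 bins (%s molecules)\n", x$rss,
              format(x$n_molecules)))
  invisible(x)
}

#' Population fractions with molecule-level bootstrap uncertainty
#'
#' Point estimates come from the fitted Gaussian areas; uncertainties from
#' resampling molecules with replacement, re-averaging their normalised
#' histograms and refitting (initialised at the point fit), with the SD of
#' the refitted fractions across replicates reported as the bootstrap SEM.
#'
#' @param fit A `gaussian_mixture_fit`.
#' @param per_molecule Matrix of per-molecule histograms (rows sum to 1),
#'   e.g. `ensemble$per_molecule`.
#' @param n_boot Number of bootstrap replicates (default 200; 0 skips the
#'   bootstrap and reports NA SEMs).
#' @param seed RNG seed for resampling.
#' @return List with `fractions` (low, high), `sem`, `n_boot`,
#'   `n_failed`, `warning` (TRUE when more than 20% of replicate refits
#'   failed), `seed`.
#' @export
population_fractions <- function(fit, per_molecule, n_boot = 200L, seed = 1L) {
  stopifnot(inherits(fit, "gaussian_mixture_fit"))
  point <- fit$fractions
  if (n_boot <= 0)
    return(list(fractions = point, sem = c(NA_real_, NA_real_),
                n_boot = 0L, n_failed = 0L, warning = FALSE,
                seed = as.integer(seed)))
  n <- nrow(per_molecule)
  set.seed(as.integer(seed))
  init <- list(means = fit$means, sigmas = fit$sigmas, areas = fit$areas)
  fracs <- matrix(NA_real_, n_boot, 2)
  failed <- 0L
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    m <- colMeans(per_molecule[idx, , drop = FALSE])
    fb <- tryCatch(fit_two_gaussian(m, init = init,
                                    shared_sigma = fit$shared_sigma),
                   error = function(e) NULL)
    if (is.null(fb)) { failed <- failed + 1L; next }
    fracs[b, ] <- fb$fractions
  }
  ok <- stats::complete.cases(fracs)
  sem <- apply(fracs[ok, , drop = FALSE], 2, stats::sd)
  list(fractions = point, sem = sem, n_boot = as.integer(n_boot),
       n_failed = failed, warning = failed > 0.2 * n_boot,
       seed = as.integer(seed))
}
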