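#' Two-state idealization of a FRET efficiency trace
#'
#' Assigns each frame of a noisy FRET trajectory to one of two
#' conformational states using a Gaussian-emission hidden Markov model
#' (Baum-Welch parameter estimation, Viterbi most-probable path), and
#' summarises the dwell times in each state. State 1 is the lower-FRET
#' state. When the trace does not support two distinct emission means the
#' molecule is labelled static and assigned a single dwell in the nearer
#' state.
#'
#' A simple midpoint-threshold idealizer (`method = "threshold"`) is
#' provided as a transparent fallback: frames are assigned to the nearer
#' of the two means estimated by 2-means clustering.
#'
#' @param E Numeric FRET series (>= 20 frames).
#' @param n_states Number of states (only 2 supported).
#' @param frame_period Seconds per frame, used for dwell times (default 1).
#' @param method `"hmm"` (default) or `"threshold"`.
#' @param max_iter,tol Baum-Welch iteration controls.
#' @return Object of class `fret_idealization`: `states` (1/2 per frame),
#'   `state_means`, `state_sds`, `transition_matrix` (per frame),
#'   `dwell_times` (data.frame state/duration seconds), `static`,
#'   `log_likelihood`, `occupancy` (fraction of frames per state).
#' @export
idealize_trace <- function(E, n_states = 2L, frame_period = 1,
                           method = c("hmm", "threshold"),
                           max_iter = 100L, tol = 1e-6) {
  method <- match.arg(method)
  if (n_states != 2L) stop("only two-state idealization is supported", call. = FALSE)
  E <- as.numeric(E)
  E <- E[is.finite(E)]
  n <- length(E)
  if (n < 20L) stop("trace too short to idealize (< 20 frames)", call. = FALSE)

  q <- stats::quantile(E, c(0.15, 0.85), names = FALSE)
  if (stats::sd(E) < 1e-9 || diff(q) < 1e-6) {
    st <- rep(if (mean(E) > 0.5) 2L else 1L, n)
    return(static_idealization(E, st, c(mean(E), mean(E)), frame_period))
  }
  km <- stats::kmeans(E, centers = q, iter.max = 50)
  mu <- sort(unname(km$centers[, 1]))
  sep <- abs(diff(mu))
  pooled_sd <- stats::sd(E)
  if (sep < 0.5 * pooled_sd || sep < 0.05) {
    # effectively one emission level: static trace
    st <- rep(if (mean(E) > 0.5) 2L else 1L, n)
    return(static_idealization(E, st, mu, frame_period))
  }

  if (method == "threshold") {
    thr <- mean(mu)
    st <- ifelse(E > thr, 2L, 1L)
    return(finalize_idealization(E, st, frame_period, NA_real_))
  }

  ord <- order(km$centers[, 1])
  assign0 <- match(km$cluster, ord)
  sd0 <- vapply(1:2, function(s) {
    v <- stats::sd(E[assign0 == s])
    if (!is.finite(v) || v < 0.01) 0.05 else v
  }, numeric(1))
  par <- list(mu = mu, sd = sd0,
              P = matrix(c(0.95, 0.05, 0.05, 0.95), 2, 2),
              pi = c(0.5, 0.5))
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    fb <- hmm_forward_backward(E, par)
    if (!is.finite(fb$ll)) break
    # M-step
    g <- fb$gamma
    xs <- fb$xi_sum
    par$pi <- g[1, ] / sum(g[1, ])
    P <- xs / pmax(rowSums(xs), .Machine$double.eps)
    par$P <- P / rowSums(P)
    for (s in 1:2) {
      wsum <- sum(g[, s])
      par$mu[s] <- sum(g[, s] * E) / wsum
      par$sd[s] <- sqrt(sum(g[, s] * (E - par$mu[s])^2) / wsum)
      if (!is.finite(par$sd[s]) || par$sd[s] < 0.005) par$sd[s] <- 0.005
    }
    if (par$mu[1] > par$mu[2]) {  # keep state 1 = low FRET
      par$mu <- rev(par$mu); par$sd <- rev(par$sd)
      par$pi <- rev(par$pi); par$P <- par$P[2:1, 2:1]
    }
    if (abs(fb$ll - ll_old) < tol * abs(ll_old + 1)) { ll_old <- fb$ll; break }
    ll_old <- fb$ll
  }
  occ <- colSums(hmm_forward_backward(E, par)$gamma) / n
  if (min(occ) < 1 / n) {
    st <- rep(which.max(occ), n)
    return(static_idealization(E, st, par$mu, frame_period))
  }
  # emission means closer than 3 sd describe one level, not two states
  if (abs(diff(par$mu)) < 3 * max(par$sd)) {
    st <- rep(if (mean(E) > 0.5) 2L else 1L, n)
    return(static_idealization(E, st, par$mu, frame_period))
  }
  st <- hmm_viterbi(E, par)
  out <- finalize_idealization(E, st, frame_period, ll_old)
  out$state_means <- par$mu
  out$state_sds <- par$sd
  out$transition_matrix <- par$P
  out
}

static_idealization <- function(E, st, mu, frame_period) {
  out <- finalize_idealization(E, st, frame_period, NA_real_)
  out$static <- TRUE
  out$state_means <- mu
  out
}

finalize_idealization <- function(E, st, frame_period, ll) {
  r <- rle(st)
  dw <- data.frame(state = r$values,
                   duration = r$lengths * frame_period)
  means <- vapply(1:2, function(s)
    if (any(st == s)) mean(E[st == s]) else NA_real_, numeric(1))
  sds <- vapply(1:2, function(s)
    if (sum(st == s) > 1) stats::sd(E[st == s]) else NA_real_, numeric(1))
  structure(list(states = st,
                 state_means = means,
                 state_sds = sds,
                 transition_matrix = NULL,
                 dwell_times = dw,
                 static = length(unique(st)) == 1L,
                 log_likelihood = ll,
                 occupancy = c(mean(st == 1L), mean(st == 2L))),
            class = "fret_idealization")
}

#' @export
print.fret_idealization <- function(x, ...) {
  cat(sprintf("fret_idealization: %d frames, %s\n", length(x$states),
              if (x$static) "static" else "dynamic"))
  cat(sprintf("  state means %.3f / %.3f, occupancy %.2f / %.2f, %d dwells\n",
              x$state_means[1], x$state_means[2], x$occupancy[1],
              x$occupancy[2], nrow(x$dwell_times)))
  invisible(x)
}

# Scaled forward-backward for a 2-state Gaussian HMM.
hmm_forward_backward <- function(E, par) {
  n <- length(E)
  B <- cbind(stats::dnorm(E, par$mu[1], par$sd[1]),
             stats::dnorm(E, par$mu[2], par$sd[2]))
  B <- pmax(B, 1e-300)
  alpha <- matrix(0, n, 2); beta <- matrix(0, n, 2); cvec <- numeric(n)
  a <- par$pi * B[1, ]
  cvec[1] <- sum(a); alpha[1, ] <- a / cvec[1]
  for (t in 2:n) {
    a <- (alpha[t - 1, ] %*% par$P) * B[t, ]
    cvec[t] <- sum(a)
    alpha[t, ] <- a / cvec[t]
  }
  beta[n, ] <- 1
  for (t in (n - 1):1) {
    b <- par$P %*% (B[t + 1, ] * beta[t + 1, ])
    beta[t, ] <- b / cvec[t + 1]
  }
  g <- alpha * beta
  g <- g / rowSums(g)
  xi_sum <- matrix(0, 2, 2)
  for (i in 1:2) for (j in 1:2) {
    xi_sum[i, j] <- sum(alpha[-n, i] * par$P[i, j] * B[-1, j] * beta[-1, j] /
                          cvec[-1])
  }
  list(gamma = g, xi_sum = xi_sum, ll = sum(log(cvec)))
}

hmm_viterbi <- function(E, par) {
  n <- length(E)
  logB <- cbind(stats::dnorm(E, par$mu[1], par$sd[1], log = TRUE),
                stats::dnorm(E, par$mu[2], par$sd[2], log = TRUE))
  logP <- log(pmax(par$P, 1e-300))
  delta <- matrix(-Inf, n, 2); psi <- matrix(1L, n, 2)
  delta[1, ] <- log(pmax(par$pi, 1e-300)) + logB[1, ]
  for (t in 2:n) {
    for (j in 1:2) {
      v <- delta[t - 1, ] + logP[, j]
      psi[t, j] <- which.max(v)
      delta[t, j] <- v[psi[t, j]] + logB[t, j]
    }
  }
  st <- integer(n)
  st[n] <- which.max(delta[n, ])
  for (t in (n - 1):1) st[t] <- psi[t + 1, st[t + 1]]
  st
}
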