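#' @keywords internal
#' @useDynLib smfretr, .registration = TRUE
#' @importFrom Rcpp sourceCpp
"_PACKAGE"

# Derive a reproducible sub-seed from a master seed and an index.
# Keeps results invariant to the order in which sub-streams are consumed.
derive_seed <- function(seed, index, salt = 0L) {
  m <- 2147483647
  x <- (as.numeric(seed) %% m) * 2654435761 + as.numeric(index) * 97561 +
    as.numeric(salt) * 40503
  as.integer(x %% (m - 1)) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Robust per-frame noise sd from successive differences; insensitive to
# steps and slow drifts. Var(diff) = 2 sigma^2 for iid noise.
robust_sigma <- function(x) {
  d <- diff(x)
  if (length(d) == 0L || all(d == 0)) return(0)
  stats::mad(d, center = 0) / sqrt(2)
}

stopifnot_scalar <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper)
    stop(sprintf("'%s' must be a finite scalar in [%s, %s]", name,
                 format(lower), format(upper)), call. = FALSE)
  invisible(x)
}

# Separable Gaussian smoothing with edge replication. sigma = 0 returns the
# input unchanged.
gauss_smooth <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  pad <- function(m, n) {
    m[c(rep(1L, n), seq_len(nrow(m)), rep(nrow(m), n)), , drop = FALSE]
  }
  conv_cols <- function(m) {
    mp <- pad(m, r)
    out <- matrix(0, nrow(m), ncol(m))
    for (i in seq_along(k)) {
      out <- out + k[i] * mp[i:(i + nrow(m) - 1L), , drop = FALSE]
    }
    out
  }
  t(conv_cols(t(conv_cols(img))))
}

# md5 of an in-memory object via a temporary file (used for run manifests).
object_md5 <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2)
  unname(tools::md5sum(f))
}
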