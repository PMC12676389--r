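#' Simulate gold-nanoparticle point patterns with known cluster membership
#'
#' Generates a 2D point pattern emulating immunogold labels on an unroofed
#' membrane sheet: cluster centres placed with a minimum separation, each
#' cluster's particles scattered isotropically (Gaussian, sd `cluster_sigma`)
#' around its centre, plus an optional uniform background of dispersed
#' singleton particles. Ground-truth cluster labels are returned so that
#' cluster-identification methods can be scored exactly.
#'
#' @param n_clusters Number of clusters.
#' @param cluster_size_dist Either an integer vector of explicit cluster
#'   sizes (length `n_clusters`) or a function `f(n)` returning `n` sizes
#'   (e.g. `function(n) rpois(n, 5) + 1`).
#' @param cluster_sigma Within-cluster scatter sd in nm (default 20).
#' @param field `c(width, height)` of the field of view in nm.
#' @param background_density Dispersed-particle density in points per square
#'   micrometre (default 0).
#' @param min_center_separation Minimum distance between cluster centres in
#'   nm (default `25 * cluster_sigma`).
#' @param seed RNG seed.
#' @return A list with `points` (data.frame `x_nm`, `y_nm`, `cluster`;
#'   background singletons get unique negative labels) and `truth`
#'   (`sizes`: the ground-truth per-cluster particle counts, background
#'   particles counted as singleton clusters of size 1).
#' @examples
#' pp <- simulate_particle_pattern(3, c(2, 4, 6), field = c(4000, 4000), seed = 1)
#' table(pp$points$cluster)
#' @export
simulate_particle_pattern <- function(n_clusters, cluster_size_dist,
                                      cluster_sigma = 20,
                                      field = c(5000, 5000),
                                      background_density = 0,
                                      min_center_separation = NULL,
                                      seed = 1L) {
  stopifnot_scalar(n_clusters, "n_clusters", lower = 0)
  stopifnot_scalar(cluster_sigma, "cluster_sigma", lower = 1e-9)
  sep <- min_center_separation %||% (25 * cluster_sigma)
  set.seed(as.integer(seed))

  sizes <- if (is.function(cluster_size_dist)) {
    as.integer(cluster_size_dist(n_clusters))
  } else {
    if (n_clusters > 0 && length(cluster_size_dist) != n_clusters)
      stop("explicit 'cluster_size_dist' must have length n_clusters", call. = FALSE)
    as.integer(cluster_size_dist)
  }
  if (n_clusters > 0 && any(sizes < 1))
    stop("cluster sizes must be >= 1", call. = FALSE)

  pts <- data.frame(x_nm = numeric(0), y_nm = numeric(0), cluster = integer(0))
  if (n_clusters > 0) {
    margin <- 4 * cluster_sigma
    if (any(field <= 2 * margin))
      stop("field too small for the requested cluster geometry", call. = FALSE)
    centers <- place_points(n_clusters,
                            xlim = c(margin, field[1] - margin),
                            ylim = c(margin, field[2] - margin),
                            min_dist = sep)
    for (i in seq_len(n_clusters)) {
      pts <- rbind(pts, data.frame(
        x_nm = stats::rnorm(sizes[i], centers[i, 1], cluster_sigma),
        y_nm = stats::rnorm(sizes[i], centers[i, 2], cluster_sigma),
        cluster = i))
    }
  }
  n_bg <- stats::rpois(1, background_density * prod(field) / 1e6)
  if (n_bg > 0) {
    pts <- rbind(pts, data.frame(
      x_nm = stats::runif(n_bg, 0, field[1]),
      y_nm = stats::runif(n_bg, 0, field[2]),
      cluster = -seq_len(n_bg)))
  }
  pts$x_nm <- pmin(pmax(pts$x_nm, 0), field[1])
  pts$y_nm <- pmin(pmax(pts$y_nm, 0), field[2])
  truth_sizes <- c(if (n_clusters > 0) sizes, rep(1L, n_bg))
  list(points = pts, truth = list(sizes = as.integer(truth_sizes)),
       field = field, cluster_sigma = cluster_sigma, seed = as.integer(seed))
}
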