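#' Group gold particles into clusters by single linkage
#'
#' Two particles belong to the same cluster when they are connected by a
#' chain of pairwise distances each at most `linkage_radius` (single-linkage
#' connected components; singletons allowed). The rule is invariant to
#' point order and to rigid motions of the coordinates.
#'
#' @param points Two-column matrix or data.frame of coordinates in nm
#'   (columns `x_nm`/`y_nm` or the first two columns).
#' @param linkage_radius Linking distance in nm (inclusive). The default in
#'   higher-level wrappers is 3x a nominal 10 nm particle diameter.
#' @return Integer vector of cluster labels (1-based, in order of first
#'   appearance).
#' @examples
#' pts <- rbind(c(0, 0), c(10, 0), c(5, 8), c(500, 500))
#' cluster_particles(pts, 20)  # 1 1 1 2
#' @export
cluster_particles <- function(points, linkage_radius) {
  if (linkage_radius <= 0) stop("'linkage_radius' must be > 0", call. = FALSE)
  xy <- as_xy(points)
  n <- nrow(xy)
  if (n == 0L) return(integer(0))
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  r2 <- linkage_radius^2
  for (i in seq_len(n - 1L)) {
    d2 <- (xy[(i + 1L):n, 1] - xy[i, 1])^2 + (xy[(i + 1L):n, 2] - xy[i, 2])^2
    for (j in which(d2 <= r2)) {
      ri <- find(i); rj <- find(i + j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

as_xy <- function(points) {
  if (is.data.frame(points)) {
    if (all(c("x_nm", "y_nm") %in% names(points)))
      return(cbind(points$x_nm, points$y_nm))
    return(as.matrix(points[, 1:2]))
  }
  m <- as.matrix(points)
  if (length(m) == 0L) return(matrix(numeric(0), 0, 2))
  m[, 1:2, drop = FALSE]
}

#' Cluster-size statistics per condition
#'
#' Pools cluster sizes across the images of each condition and reports the
#' frequency distribution and empirical cumulative probability of cluster
#' size, the quantities plotted when comparing nanocluster size between a
#' vehicle and a treated condition.
#'
#' @param sets A single particle table or a list of them. Each table needs
#'   columns `x_nm`, `y_nm` and optionally `image_id` and `condition`
#'   (defaults `"img1"` / `"all"`).
#' @param linkage_radius Linking distance in nm (default 30, i.e. 3x a
#'   nominal 10 nm gold-particle diameter; report alongside results since
#'   the operational cluster definition depends on it).
#' @return Named list of `cluster_stats` objects, one per condition:
#'   `cluster_sizes` (pooled), `frequency` (size -> count), `cdf`
#'   (data.frame size, cumulative_probability), `per_image`, `n_images`,
#'   `n_particles`, `linkage_radius`, `condition`.
#' @export
cluster_size_stats <- function(sets, linkage_radius = 30) {
  if (is.data.frame(sets)) sets <- list(sets)
  tabs <- lapply(sets, function(s) {
    s <- as.data.frame(s)
    if (is.null(s$image_id)) s$image_id <- "img1"
    if (is.null(s$condition)) s$condition <- "all"
    s
  })
  all_tab <- do.call(rbind, lapply(tabs, function(s)
    s[, c("x_nm", "y_nm", "image_id", "condition")]))
  out <- list()
  for (cond in unique(all_tab$condition)) {
    sub <- all_tab[all_tab$condition == cond, ]
    sizes <- integer(0)
    per_image <- list()
    for (img in unique(sub$image_id)) {
      pts <- sub[sub$image_id == img, c("x_nm", "y_nm")]
      lab <- cluster_particles(pts, linkage_radius)
      sz <- as.integer(table(lab))
      per_image[[img]] <- sz
      sizes <- c(sizes, sz)
    }
    if (!length(sizes)) {
      out[[cond]] <- structure(list(cluster_sizes = integer(0),
                                    frequency = table(integer(0)),
                                    cdf = data.frame(size = integer(0),
                                                     cumulative_probability = numeric(0)),
                                    per_image = per_image,
                                    n_images = length(per_image),
                                    n_particles = 0L,
                                    linkage_radius = linkage_radius,
                                    condition = cond, empty = TRUE),
                               class = "cluster_stats")
      next
    }
    sz_sorted <- sort(unique(sizes))
    cdf <- data.frame(size = sz_sorted,
                      cumulative_probability =
                        stats::ecdf(sizes)(sz_sorted))
    out[[cond]] <- structure(list(cluster_sizes = sizes,
                                  frequency = table(sizes),
                                  cdf = cdf,
                                  per_image = per_image,
                                  n_images = length(per_image),
                                  n_particles = sum(sizes),
                                  linkage_radius = linkage_radius,
                                  condition = cond, empty = FALSE),
                             class = "cluster_stats")
  }
  out
}

#' @export
print.cluster_stats <- function(x, ...) {
  cat(sprintf("cluster_stats [%s]: %d particles in %d clusters over %d image(s), radius %.3g nm\n",
              x$condition, x$n_particles, length(x$cluster_sizes),
              x$n_images, x$linkage_radius))
  if (!x$empty)
    cat(sprintf("  mean size %.2f, median %.1f, max %d\n",
                mean(x$cluster_sizes), stats::median(x$cluster_sizes),
                max(x$cluster_sizes)))
  invisible(x)
}

#' Compare cluster-size distributions between two conditions
#'
#' Two-sided Mann-Whitney U test by default (exact enumeration for small
#' samples, normal approximation with tie correction otherwise), or a
#' two-sample Kolmogorov-Smirnov test.
#'
#' @param sizes_a,sizes_b Cluster-size samples (or `cluster_stats`).
#' @param test `"mannwhitney"` (default) or `"ks"`.
#' @param exact_max Use exact enumeration when the total sample size is at
#'   most this (default 12).
#' @return List with `statistic`, `p_value`, `test`, `method` (`"exact"` or
#'   `"approximate"`), `zero_variance` flag.
#' @export
compare_conditions <- function(sizes_a, sizes_b,
                               test = c("mannwhitney", "ks"),
                               exact_max = 12L) {
  test <- match.arg(test)
  if (inherits(sizes_a, "cluster_stats")) sizes_a <- sizes_a$cluster_sizes
  if (inherits(sizes_b, "cluster_stats")) sizes_b <- sizes_b$cluster_sizes
  if (!length(sizes_a) || !length(sizes_b))
    stop("both samples must be nonempty", call. = FALSE)
  if (stats::sd(c(sizes_a, sizes_b)) == 0)
    return(list(statistic = NA_real_, p_value = 1, test = test,
                method = "degenerate", zero_variance = TRUE))
  if (test == "ks") {
    k <- suppressWarnings(stats::ks.test(sizes_a, sizes_b))
    return(list(statistic = unname(k$statistic), p_value = k$p.value,
                test = "ks", method = "asymptotic", zero_variance = FALSE))
  }
  n1 <- length(sizes_a); n2 <- length(sizes_b)
  u <- mw_u_statistic(sizes_a, sizes_b)
  if (n1 + n2 <= exact_max) {
    p <- mw_exact_p(sizes_a, sizes_b, u)
    return(list(statistic = u, p_value = p, test = "mannwhitney",
                method = "exact", zero_variance = FALSE))
  }
  w <- suppressWarnings(stats::wilcox.test(sizes_a, sizes_b,
                                           exact = FALSE, correct = TRUE))
  list(statistic = u, p_value = w$p.value, test = "mannwhitney",
       method = "approximate", zero_variance = FALSE)
}

# U statistic of sample a vs b via midranks (handles ties).
mw_u_statistic <- function(a, b) {
  r <- rank(c(a, b))
  sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
}

# Exact two-sided p by enumerating all assignments of the pooled values to
# group A: p = Pr(|U - n1 n2 / 2| >= |u_obs - n1 n2 / 2|) under the null.
mw_exact_p <- function(a, b, u_obs) {
  pooled <- c(a, b)
  n1 <- length(a); n <- length(pooled)
  combos <- utils::combn(n, n1)
  center <- n1 * (n - n1) / 2
  us <- apply(combos, 2, function(idx)
    mw_u_statistic(pooled[idx], pooled[-idx]))
  mean(abs(us - center) >= abs(u_obs - center) - 1e-9)
}
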