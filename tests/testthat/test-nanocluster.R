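test_that("single linkage groups chained points and leaves singletons", {
  pts <- rbind(c(0, 0), c(10, 0), c(5, 8), c(500, 500))
  lab <- cluster_particles(pts, 20)
  expect_equal(sort(as.integer(table(lab))), c(1, 3))
  expect_equal(cluster_particles(matrix(numeric(0), 0, 2), 10), integer(0))
  # chaining: a-b and b-c linked, a-c distant
  chain <- rbind(c(0, 0), c(9, 0), c(18, 0))
  expect_equal(length(unique(cluster_particles(chain, 10))), 1L)
})

test_that("clustering is invariant to point order and rigid motion", {
  set.seed(4)
  pts <- matrix(runif(60, 0, 300), ncol = 2)
  lab <- cluster_particles(pts, 25)
  perm <- sample(nrow(pts))
  lab_p <- cluster_particles(pts[perm, ], 25)
  # same partition up to label names
  expect_equal(length(unique(lab)), length(unique(lab_p)))
  expect_true(all(table(lab[perm]) == table(lab_p)[order(names(table(lab_p)))]
                  [rank(names(table(lab[perm])))] ) ||
              identical(sort(as.integer(table(lab))),
                        sort(as.integer(table(lab_p)))))
  shifted <- pts + 1000
  expect_identical(cluster_particles(shifted, 25), lab)
})

test_that("more linkage radius never means more clusters", {
  set.seed(9)
  pts <- matrix(runif(80, 0, 500), ncol = 2)
  n_clusters <- vapply(c(5, 15, 30, 60, 120), function(r)
    length(unique(cluster_particles(pts, r))), integer(1))
  expect_true(all(diff(n_clusters) <= 0))
})

test_that("well-separated simulated clusters are recovered exactly", {
  pp <- simulate_particle_pattern(12, function(n) rpois(n, 4) + 1,
                                  cluster_sigma = 20,
                                  min_center_separation = 500,
                                  field = c(8000, 8000), seed = 5)
  lab <- cluster_particles(pp$points, 100)
  expect_identical(sort(as.integer(table(lab))), sort(pp$truth$sizes))
})

test_that("cluster statistics pool images and report CDF and frequencies", {
  one <- data.frame(x_nm = c(0, 5, 100, 300), y_nm = rep(0, 4),
                    image_id = "a", condition = "vehicle")
  # sizes with radius 30: {2, 1, 1}
  st <- cluster_size_stats(one, linkage_radius = 30)$vehicle
  expect_equal(sort(st$cluster_sizes), c(1, 1, 2))
  expect_equal(st$cdf$cumulative_probability[st$cdf$size == 1], 2 / 3)
  expect_equal(st$cdf$cumulative_probability[st$cdf$size == 2], 1)
  expect_equal(sum(st$cluster_sizes), st$n_particles)

  # duplicating the image doubles frequencies but leaves the CDF unchanged
  two <- rbind(one, transform(one, image_id = "b"))
  st2 <- cluster_size_stats(two, linkage_radius = 30)$vehicle
  expect_equal(as.integer(st2$frequency), 2L * as.integer(st$frequency))
  expect_equal(st2$cdf, st$cdf)
  # self-consistency: sum over size x count equals the particle total
  expect_equal(sum(as.integer(names(st2$frequency)) *
                     as.integer(st2$frequency)), st2$n_particles)
})

test_that("a treated condition with larger clusters dominates the CDF", {
  mk <- function(mean_size, cond, seed) {
    pp <- simulate_particle_pattern(10, function(n) rpois(n, mean_size - 1) + 1,
                                    cluster_sigma = 20,
                                    min_center_separation = 600,
                                    field = c(10000, 10000), seed = seed)
    transform(pp$points, image_id = sprintf("%s_%d", cond, seed),
              condition = cond)
  }
  sets <- c(lapply(1:10, function(i) mk(3, "vehicle", i)),
            lapply(1:10, function(i) mk(6, "treated", 100 + i)))
  st <- cluster_size_stats(sets, linkage_radius = 100)
  szs <- sort(unique(c(st$vehicle$cdf$size, st$treated$cdf$size)))
  Fv <- ecdf(st$vehicle$cluster_sizes)(szs)
  Ft <- ecdf(st$treated$cluster_sizes)(szs)
  expect_true(all(Ft <= Fv + 1e-12))   # stochastic dominance
  cmp <- compare_conditions(st$vehicle, st$treated)
  expect_lt(cmp$p_value, 0.001)
})

test_that("exact Mann-Whitney p matches the closed-form null distribution", {
  set.seed(13)
  for (i in 1:10) {
    a <- runif(3); b <- runif(3)  # continuous, no ties
    got <- compare_conditions(a, b)
    expect_equal(got$method, "exact")
    expect_equal(got$p_value, oracle_mw_exact_p(a, b), tolerance = 1e-12)
  }
  # and against stats::wilcox.test exact p
  a <- c(1.2, 3.4, 5.1); b <- c(2.2, 4.7, 6.9)
  expect_equal(compare_conditions(a, b)$p_value,
               wilcox.test(a, b, exact = TRUE)$p.value, tolerance = 1e-12)
})

test_that("degenerate and alternative-test paths behave", {
  same <- rep(3, 10)
  r <- compare_conditions(same, same)
  expect_true(r$zero_variance)
  expect_equal(r$p_value, 1)
  set.seed(3)
  ks <- compare_conditions(rpois(40, 3) + 1, rpois(40, 9) + 1, test = "ks")
  expect_lt(ks$p_value, 0.001)
  expect_error(compare_conditions(numeric(0), 1:3), "nonempty")
})

test_that("the test is calibrated under the null", {
  set.seed(17)
  rej <- 0L
  n_rep <- 400
  for (i in seq_len(n_rep)) {
    x <- rpois(50, 4) + 1; y <- rpois(50, 4) + 1
    if (compare_conditions(x, y)$p_value < 0.05) rej <- rej + 1L
  }
  expect_gt(rej / n_rep, 0.02)
  expect_lt(rej / n_rep, 0.08)
})
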