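fiducial_image <- function(h, w, pts, amp = 4000, sigma = 1.2) {
  img <- matrix(0, h, w)
  for (i in seq_len(nrow(pts)))
    img <- img + smfretr:::spot_image(h, w, pts[i, 1], pts[i, 2], sigma, amp)
  img
}

reg_points <- function(n = 12, seed = 1) {
  set.seed(seed)
  cbind(runif(n, 15, 85), runif(n, 15, 85))
}

test_that("registration recovers identity, translation and rotation", {
  pts <- reg_points()
  img <- fiducial_image(100, 100, pts)

  reg <- register_channels(img, img)
  expect_lt(reg$rms_residual, 0.05)
  expect_equal(reg$transform[, 1:2], diag(2), tolerance = 1e-3)
  expect_equal(as.vector(reg$transform[, 3]), c(0, 0), tolerance = 0.02)

  # known translation (3.0, -2.0)
  img_t <- fiducial_image(100, 100, cbind(pts[, 1] + 3, pts[, 2] - 2))
  reg_t <- register_channels(img, img_t)
  expect_equal(as.vector(reg_t$transform[, 3]), c(3, -2), tolerance = 0.1)

  # 1 degree rotation about the image centre
  th <- pi / 180
  ctr <- c(49.5, 49.5)
  rot <- cbind(ctr[1] + cos(th) * (pts[, 1] - ctr[1]) -
                 sin(th) * (pts[, 2] - ctr[2]),
               ctr[2] + sin(th) * (pts[, 1] - ctr[1]) +
                 cos(th) * (pts[, 2] - ctr[2]))
  reg_r <- register_channels(img, fiducial_image(100, 100, rot))
  ang <- atan2(reg_r$transform[2, 1], reg_r$transform[1, 1]) * 180 / pi
  expect_equal(ang, 1, tolerance = 0.05)
})

test_that("registration round trip and failure modes", {
  pts <- reg_points(10, seed = 2)
  img <- fiducial_image(100, 100, pts)
  reg <- register_channels(img, fiducial_image(100, 100,
                                               cbind(pts[, 1] + 2, pts[, 2] + 1)))
  xy <- cbind(c(10.3, 55.1, 80.9), c(20.7, 44.2, 61.5))
  back <- apply_transform(reg$inverse, apply_transform(reg$transform, xy))
  expect_equal(back, xy, tolerance = 1e-9, ignore_attr = TRUE)

  flat <- matrix(0, 50, 50)
  expect_error(register_channels(flat, flat), "at least 3")
})

test_that("spot detection finds nothing on a flat image and localises a single spot", {
  expect_equal(nrow(detect_spots(matrix(5, 60, 60))), 0L)

  img <- smfretr:::spot_image(60, 60, 20, 30, 1.2, 2000)
  sp <- detect_spots(img)
  expect_equal(nrow(sp), 1L)
  expect_lt(abs(sp$x - 20), 0.5)
  expect_lt(abs(sp$y - 30), 0.5)
})

test_that("detection is translation-equivariant", {
  set.seed(3)
  pts <- cbind(runif(6, 15, 40), runif(6, 15, 40))
  img <- fiducial_image(80, 80, pts, amp = 2000)
  sp0 <- detect_spots(img)
  img5 <- fiducial_image(80, 80, cbind(pts[, 1] + 5, pts[, 2] + 7), amp = 2000)
  sp5 <- detect_spots(img5)
  o0 <- order(sp0$x); o5 <- order(sp5$x)
  expect_equal(sp5$x[o5], sp0$x[o0] + 5, tolerance = 0.05)
  expect_equal(sp5$y[o5], sp0$y[o0] + 7, tolerance = 0.05)
})

test_that("detection on a noisy field reaches 95% recall and precision", {
  cfg <- sim_config(n_frames_donor_exc = 25, n_frames_acceptor_exc = 2,
                    seed = 5, acceptor_bleach_lifetime = 1e9,
                    donor_bleach_lifetime = 1e9)
  mv <- simulate_movie(cfg, image_shape = c(170, 170), n_molecules = 50)
  det <- detection_images(mv$movie, 20)
  sp <- detect_spots(det$donor)
  m <- smfretr:::match_points(cbind(sp$x, sp$y),
                              cbind(mv$truth$x, mv$truth$y), 1.5)
  expect_gte(nrow(m) / 50, 0.95)          # recall
  expect_gte(nrow(m) / nrow(sp), 0.95)    # precision
})

test_that("pairing matches mapped coordinates and flags donor-only spots", {
  reg <- structure(list(
    transform = cbind(diag(2), c(3, -2)),
    inverse = invert_transform(cbind(diag(2), c(3, -2))),
    rms_residual = 0, n_control_points = 10),
    class = "channel_registration")
  donor <- data.frame(x = c(10, 30, 50), y = c(10, 30, 50),
                      intensity = c(3, 2, 1))
  acceptor <- data.frame(x = c(13, 33), y = c(8, 28), intensity = c(1, 1))
  pairs <- pair_spots(donor, acceptor, reg)
  expect_equal(pairs$donor_only, c(FALSE, FALSE, TRUE))
  expect_equal(pairs$pairing_distance[1:2], c(0, 0), tolerance = 1e-9)

  # each acceptor spot is used at most once
  donor2 <- data.frame(x = c(10, 10.5), y = c(10, 10), intensity = c(2, 1))
  acceptor2 <- data.frame(x = 13, y = 8, intensity = 1)
  p2 <- pair_spots(donor2, acceptor2, reg)
  expect_equal(sum(!p2$donor_only), 1L)
})

test_that("acceptor-only contaminants never yield pairs without a donor spot", {
  cfg <- sim_config(n_frames_donor_exc = 25, n_frames_acceptor_exc = 2,
                    seed = 21, acceptor_bleach_lifetime = 1e9,
                    donor_bleach_lifetime = 1e9,
                    contaminant_fractions = c(acceptor_only = 0.2))
  mv <- simulate_movie(cfg, image_shape = c(170, 170), n_molecules = 40)
  pm <- process_movie(mv$movie, mv$registration_images)
  ao <- mv$truth[mv$truth$class == "acceptor_only", ]
  expect_gt(nrow(ao), 0)
  paired <- pm$pairs[!pm$pairs$donor_only, ]
  if (nrow(paired)) {
    d <- outer(paired$donor_x, ao$x, "-")^2 + outer(paired$donor_y, ao$y, "-")^2
    expect_gt(min(sqrt(d)), 2)  # no pair sits on an acceptor-only molecule
  }
})

test_that("aperture extraction is unbiased on uniform images and exact on spots", {
  # uniform image: aperture sum equals scaled background, net zero
  movie <- structure(list(
    donor = array(7, dim = c(3, 60, 60)),
    acceptor = array(7, dim = c(3, 60, 60)),
    frame_period = 0.1,
    donor_excitation_frames = 1:2, acceptor_excitation_frames = 3L,
    offset = 0), class = "movie_stack")
  pair <- data.frame(donor_x = 30, donor_y = 30, acceptor_x = 30,
                     acceptor_y = 30, acceptor_x_native = 30,
                     acceptor_y_native = 30, pairing_distance = 0,
                     donor_only = FALSE)
  tr <- extract_trace(movie, pair)
  expect_equal(tr$donor, c(0, 0), tolerance = 1e-9)
  expect_equal(tr$acceptor, c(0, 0), tolerance = 1e-9)

  # 7-px aperture captures the analytic >= 98% of a sigma = 1.2 spot
  expect_gte(gaussian_mass_in_circle(3.5, 1.2), 0.98)
  cfg <- sim_config(n_frames_donor_exc = 30, n_frames_acceptor_exc = 3,
                    seed = 9, acceptor_bleach_lifetime = 1e9,
                    donor_bleach_lifetime = 1e9, state_means = 0.5,
                    state_occupancies = 1, gamma_range = c(1, 1))
  mv <- simulate_movie(cfg, image_shape = c(100, 100), n_molecules = 1,
                       noise = "none")
  pm <- process_movie(mv$movie, mv$registration_images)
  tr1 <- pm$traces[[1]]
  expect_equal(mean(tr1$donor), 500, tolerance = 0.02)
  expect_equal(mean(tr1$acceptor), 535, tolerance = 0.02)  # incl. 7% leakage
  expect_equal(mean(tr1$direct), 1000, tolerance = 0.02)
})

test_that("edge spots are skipped with reason", {
  movie <- structure(list(
    donor = array(0, dim = c(2, 60, 60)),
    acceptor = array(0, dim = c(2, 60, 60)),
    frame_period = 0.1,
    donor_excitation_frames = 1:2, acceptor_excitation_frames = integer(0),
    offset = 0), class = "movie_stack")
  pair <- data.frame(donor_x = 3, donor_y = 30, acceptor_x = 3,
                     acceptor_y = 30, acceptor_x_native = 3,
                     acceptor_y_native = 30, pairing_distance = 0,
                     donor_only = FALSE)
  tr <- extract_trace(movie, pair)
  expect_s3_class(tr, "trace_skip")
  expect_equal(tr$reason, "edge")
})

test_that("movie TIFF + sidecar round trip preserves intensities", {
  cfg <- sim_config(n_frames_donor_exc = 6, n_frames_acceptor_exc = 2,
                    seed = 2)
  mv <- simulate_movie(cfg, image_shape = c(80, 80), n_molecules = 1,
                       min_separation = 2)
  pre <- file.path(withr::local_tempdir(), "mv")
  write_movie(mv$movie, pre)
  back <- read_movie(pre)
  expect_equal(back$donor, mv$movie$donor, tolerance = 1e-6)
  expect_equal(back$acceptor, mv$movie$acceptor, tolerance = 1e-6)
  expect_equal(back$donor_excitation_frames, mv$movie$donor_excitation_frames)
  expect_equal(back$frame_period, mv$movie$frame_period)
})
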