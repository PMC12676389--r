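#' Render synthetic two-channel TIRF movie stacks
#'
#' Places simulated molecules (from the same photophysics model as
#' [simulate_traces()]) as diffraction-limited 2D Gaussian spots on a
#' donor-channel and an acceptor-channel image stack. Spot profiles are
#' integrated over pixels (error-function quadrature, not point sampling),
#' so summing a noise-free spot over an aperture recovers the underlying
#' trace intensity up to the analytically known Gaussian mass outside the
#' aperture. A known affine transform maps donor-channel positions into the
#' acceptor channel, and a fiducial-bead image pair is returned for channel
#' registration. Camera noise is Poisson on (offset + signal) plus Gaussian
#' read noise.
#'
#' @param config A [sim_config()] object (trace-level `background_sigma` and
#'   `shot_noise` are ignored in movie mode; see `offset`, `read_sigma`,
#'   `noise`).
#' @param image_shape `c(height, width)` in pixels for each channel.
#' @param n_molecules Number of molecules to place.
#' @param psf_sigma Gaussian PSF sd in pixels (default 1.2).
#' @param min_separation Minimum distance between spot centres in pixels
#'   (default `10`); placement is rejection sampling and fails with an error
#'   if the field cannot accommodate the requested number.
#' @param channel_transform 2x3 affine matrix mapping donor-channel (x, y)
#'   to acceptor-channel coordinates; default a small translation
#'   `(+3.5, -2.25)` px.
#' @param offset Constant camera offset added to every pixel (default 100).
#' @param read_sigma Gaussian read noise sd per pixel (default 3).
#' @param noise `"camera"` (Poisson + read noise) or `"none"` for exact
#'   expected values.
#' @param n_fiducials Number of bright beads in the registration image pair
#'   (default 25).
#' @return A list with `movie` (class `movie_stack`: `donor`, `acceptor`
#'   arrays of dim T x H x W, excitation frame ranges, `frame_period`),
#'   `registration_images` (donor/acceptor matrices), `truth` (per-molecule
#'   table including true donor-frame positions), `sim` (the underlying
#'   trace simulation) and `channel_transform`.
#' @examples
#' cfg <- sim_config(n_frames_donor_exc = 20, n_frames_acceptor_exc = 2, seed = 3)
#' mv <- simulate_movie(cfg, image_shape = c(60, 60), n_molecules = 4)
#' dim(mv$movie$donor)
#' @export
simulate_movie <- function(config, image_shape = c(120L, 120L), n_molecules,
                           psf_sigma = 1.2, min_separation = 10,
                           channel_transform = NULL,
                           offset = 100, read_sigma = 3,
                           noise = c("camera", "none"),
                           n_fiducials = 25L) {
  noise <- match.arg(noise)
  if (!inherits(config, "sim_config")) stop("'config' must be a sim_config")
  h <- as.integer(image_shape[1]); w <- as.integer(image_shape[2])
  if (is.null(channel_transform))
    channel_transform <- matrix(c(1, 0, 3.5,
                                  0, 1, -2.25), 2, 3, byrow = TRUE)

  sim <- simulate_traces(config, n_molecules)
  margin <- ceiling(4 * psf_sigma) + 20  # keep 35-px bg region in bounds
  set.seed(derive_seed(config$seed, 0L, salt = 21L))
  pos <- place_points(n_molecules, xlim = c(margin, w - 1 - margin),
                      ylim = c(margin, h - 1 - margin),
                      min_dist = min_separation)
  pos_acc <- apply_transform(channel_transform, pos)
  if (any(pos_acc[, 1] < 4 | pos_acc[, 1] > w - 5 |
          pos_acc[, 2] < 4 | pos_acc[, 2] > h - 5))
    stop("channel_transform maps spots outside the acceptor image", call. = FALSE)

  Td <- config$n_frames_donor_exc
  Ta <- config$n_frames_acceptor_exc
  Tt <- Td + Ta
  donor_st <- array(0, dim = c(Tt, h, w))
  acceptor_st <- array(0, dim = c(Tt, h, w))

  for (k in seq_len(n_molecules)) {
    tr <- sim$traces[[k]]
    d_series <- c(tr_expected(tr, "donor"), rep(0, Ta))
    a_series <- c(tr_expected(tr, "acceptor"), tr_expected(tr, "direct"))
    donor_st <- add_spot(donor_st, pos[k, 1], pos[k, 2], psf_sigma, d_series)
    acceptor_st <- add_spot(acceptor_st, pos_acc[k, 1], pos_acc[k, 2],
                            psf_sigma, a_series)
  }

  # registration bead images: bright in both channels
  set.seed(derive_seed(config$seed, 0L, salt = 22L))
  fid_margin <- ceiling(4 * psf_sigma) + 4
  fid <- place_points(n_fiducials, xlim = c(fid_margin, w - 1 - fid_margin),
                      ylim = c(fid_margin, h - 1 - fid_margin),
                      min_dist = 10)
  fid_acc <- apply_transform(channel_transform, fid)
  reg_d <- matrix(0, h, w); reg_a <- matrix(0, h, w)
  for (k in seq_len(nrow(fid))) {
    reg_d <- reg_d + spot_image(h, w, fid[k, 1], fid[k, 2], psf_sigma, 5000)
    reg_a <- reg_a + spot_image(h, w, fid_acc[k, 1], fid_acc[k, 2], psf_sigma, 5000)
  }

  set.seed(derive_seed(config$seed, 0L, salt = 23L))
  camera <- function(x) {
    if (noise == "none") return(x + offset)
    v <- stats::rpois(length(x), as.vector(x) + offset) +
      stats::rnorm(length(x), 0, read_sigma)
    array(v, dim = dim(x))
  }
  donor_st <- camera(donor_st)
  acceptor_st <- camera(acceptor_st)
  reg_d <- camera(reg_d); reg_a <- camera(reg_a)

  truth <- sim$truth
  truth$x <- pos[, 1]; truth$y <- pos[, 2]
  truth$x_acceptor <- pos_acc[, 1]; truth$y_acceptor <- pos_acc[, 2]

  movie <- structure(list(
    donor = donor_st, acceptor = acceptor_st,
    frame_period = config$frame_period,
    donor_excitation_frames = seq_len(Td),
    acceptor_excitation_frames = if (Ta > 0) Td + seq_len(Ta) else integer(0),
    offset = offset
  ), class = "movie_stack")

  list(movie = movie,
       registration_images = list(donor = reg_d, acceptor = reg_a),
       truth = truth, sim = sim, channel_transform = channel_transform,
       psf_sigma = psf_sigma)
}

# Movies are rendered from the noiseless expected series (camera noise is
# applied at the pixel level instead of the trace level).
tr_expected <- function(tr, field) {
  tr[[paste0(field, "_expected")]] %||% tr[[field]]
}

#' @export
print.movie_stack <- function(x, ...) {
  d <- dim(x$donor)
  cat(sprintf("movie_stack: %d frames (%d donor-exc, %d acceptor-exc), %d x %d px, %.3g s/frame\n",
              d[1], length(x$donor_excitation_frames),
              length(x$acceptor_excitation_frames), d[2], d[3],
              x$frame_period))
  invisible(x)
}

# Rejection-sampled point placement with a minimum pairwise distance.
place_points <- function(n, xlim, ylim, min_dist, max_tries = 20000L) {
  if (xlim[2] <= xlim[1] || ylim[2] <= ylim[1])
    stop("field too small for the requested margins", call. = FALSE)
  pts <- matrix(NA_real_, n, 2)
  placed <- 0L
  tries <- 0L
  while (placed < n) {
    tries <- tries + 1L
    if (tries > max_tries)
      stop(sprintf("could not place %d points with min separation %.3g in the field",
                   n, min_dist), call. = FALSE)
    cand <- c(stats::runif(1, xlim[1], xlim[2]), stats::runif(1, ylim[1], ylim[2]))
    if (placed == 0L ||
        min(sqrt((pts[seq_len(placed), 1] - cand[1])^2 +
                 (pts[seq_len(placed), 2] - cand[2])^2)) >= min_dist) {
      placed <- placed + 1L
      pts[placed, ] <- cand
    }
  }
  colnames(pts) <- c("x", "y")
  pts
}

# Pixel-integrated 2D Gaussian spot image (total mass = amplitude counts).
# Coordinates are 0-based pixel centres.
spot_image <- function(h, w, x0, y0, sigma, amplitude, halfwidth = NULL) {
  hw <- halfwidth %||% ceiling(5 * sigma)
  xs <- max(0, floor(x0) - hw):min(w - 1, floor(x0) + hw)
  ys <- max(0, floor(y0) - hw):min(h - 1, floor(y0) + hw)
  px <- stats::pnorm(xs + 0.5, x0, sigma) - stats::pnorm(xs - 0.5, x0, sigma)
  py <- stats::pnorm(ys + 0.5, y0, sigma) - stats::pnorm(ys - 0.5, y0, sigma)
  img <- matrix(0, h, w)
  img[ys + 1, xs + 1] <- amplitude * (py %o% px)
  img
}

# Add one molecule's spot to a T x H x W stack with per-frame amplitudes.
add_spot <- function(stack, x0, y0, sigma, amplitudes) {
  d <- dim(stack)
  h <- d[2]; w <- d[3]
  hw <- ceiling(5 * sigma)
  xs <- max(0, floor(x0) - hw):min(w - 1, floor(x0) + hw)
  ys <- max(0, floor(y0) - hw):min(h - 1, floor(y0) + hw)
  px <- stats::pnorm(xs + 0.5, x0, sigma) - stats::pnorm(xs - 0.5, x0, sigma)
  py <- stats::pnorm(ys + 0.5, y0, sigma) - stats::pnorm(ys - 0.5, y0, sigma)
  patch <- py %o% px                       # H' x W'
  contrib <- outer(amplitudes, patch)      # T x H' x W'
  stack[, ys + 1, xs + 1] <- stack[, ys + 1, xs + 1] + contrib
  stack
}
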