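#' Register the acceptor channel onto the donor channel
#'
#' Estimates the affine transform mapping donor-channel pixel coordinates to
#' acceptor-channel coordinates from a pair of fiducial (bead) images, as is
#' standard for dual-view smFRET optics. Beads are detected in both images,
#' matched by nearest neighbour after removing the median displacement, and
#' the six affine parameters are fit by least squares.
#'
#' @param registration_image_donor,registration_image_acceptor Matrices of
#'   the same scene imaged in each channel.
#' @param threshold_sigma Detection threshold in units of robust background
#'   spread (passed to [detect_spots()]).
#' @param match_radius Maximum residual displacement (pixels) allowed when
#'   matching beads after removing the bulk shift (default 4).
#' @return An object of class `channel_registration`: `transform` (2x3
#'   matrix mapping donor (x, y) to acceptor (x, y)), `inverse`,
#'   `rms_residual` in pixels and `n_control_points`.
#' @examples
#' img <- matrix(0, 60, 60)
#' for (p in list(c(15, 20), c(40, 12), c(30, 45), c(48, 40)))
#'   img <- img + smfretr:::spot_image(60, 60, p[1], p[2], 1.2, 4000)
#' reg <- register_channels(img, img)
#' reg$rms_residual
#' @export
register_channels <- function(registration_image_donor,
                              registration_image_acceptor,
                              threshold_sigma = 5, match_radius = 4) {
  sd_ <- detect_spots(registration_image_donor, threshold_sigma = threshold_sigma)
  sa <- detect_spots(registration_image_acceptor, threshold_sigma = threshold_sigma)
  if (nrow(sd_) < 3 || nrow(sa) < 3)
    stop("registration requires at least 3 fiducial spots in each image",
         call. = FALSE)
  # coarse bulk shift from median displacement of mutual nearest neighbours
  shift <- c(stats::median(sa$x) - stats::median(sd_$x),
             stats::median(sa$y) - stats::median(sd_$y))
  m <- match_points(cbind(sd_$x + shift[1], sd_$y + shift[2]),
                    cbind(sa$x, sa$y), match_radius)
  if (nrow(m) < 3)
    stop("fewer than 3 fiducial matches between channels", call. = FALSE)
  X <- cbind(sd_$x[m[, 1]], sd_$y[m[, 1]])
  Y <- cbind(sa$x[m[, 2]], sa$y[m[, 2]])
  if (stats::sd(X[, 1]) < 1e-9 || stats::sd(X[, 2]) < 1e-9 ||
      abs(stats::cor(X[, 1], X[, 2])) > 0.999)
    stop("control points are collinear; cannot fit an affine transform",
         call. = FALSE)
  A <- cbind(X, 1)
  beta <- qr.solve(A, Y)                       # 3 x 2
  transform <- t(beta)                         # 2 x 3: [a b tx; c d ty]
  fitted <- A %*% beta
  rms <- sqrt(mean(rowSums((Y - fitted)^2)))
  lin <- transform[, 1:2]
  if (abs(det(lin)) < 1e-9)
    stop("degenerate registration transform", call. = FALSE)
  structure(list(transform = transform,
                 inverse = invert_transform(transform),
                 rms_residual = rms,
                 n_control_points = nrow(m)),
            class = "channel_registration")
}

#' @export
print.channel_registration <- function(x, ...) {
  cat(sprintf("channel_registration: %d control points, rms residual %.4g px\n",
              x$n_control_points, x$rms_residual))
  cat(sprintf("  linear [%7.4f %7.4f; %7.4f %7.4f], translation (%.3f, %.3f)\n",
              x$transform[1, 1], x$transform[1, 2], x$transform[2, 1],
              x$transform[2, 2], x$transform[1, 3], x$transform[2, 3]))
  invisible(x)
}

#' Apply or invert an affine coordinate transform
#'
#' @param transform A 2x3 affine matrix (or a `channel_registration`).
#' @param xy Matrix (or length-2 vector) of (x, y) coordinates, one row per
#'   point.
#' @return Transformed coordinates, same shape as `xy`.
#' @export
apply_transform <- function(transform, xy) {
  if (inherits(transform, "channel_registration")) transform <- transform$transform
  vec <- is.null(dim(xy))
  xy <- rbind(xy)
  out <- t(transform[, 1:2] %*% t(xy[, 1:2, drop = FALSE]) + transform[, 3])
  colnames(out) <- c("x", "y")
  if (vec) out[1, ] else out
}

#' @rdname apply_transform
#' @export
invert_transform <- function(transform) {
  if (inherits(transform, "channel_registration")) transform <- transform$transform
  lin <- solve(transform[, 1:2])
  cbind(lin, -lin %*% transform[, 3])
}

# Greedy mutual matching of two point sets within a radius.
match_points <- function(a, b, radius) {
  if (nrow(a) == 0 || nrow(b) == 0) return(matrix(integer(0), 0, 2))
  d <- outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
  d <- sqrt(d)
  out <- matrix(integer(0), 0, 2)
  repeat {
    i <- which.min(d)
    if (!length(i) || d[i] > radius) break
    ri <- (i - 1) %% nrow(d) + 1
    ci <- (i - 1) %/% nrow(d) + 1
    out <- rbind(out, c(ri, ci))
    d[ri, ] <- Inf
    d[, ci] <- Inf
  }
  out
}

#' Detect diffraction-limited spots as local intensity maxima
#'
#' Candidate spots are strict local maxima within a square neighbourhood
#' (default side 5 pixels) of a lightly Gaussian-smoothed image, kept if
#' they exceed the image background by `threshold_sigma` robust standard
#' deviations. Positions are refined to sub-pixel precision by the intensity
#' centroid of the background-subtracted neighbourhood. Coordinates are
#' 0-based pixel centres, `x` along columns and `y` along rows.
#'
#' @param image Numeric matrix.
#' @param neighborhood Side of the square local-maximum window in pixels
#'   (odd, default 5).
#' @param threshold_sigma Detection threshold in robust background sd units
#'   of the smoothed image (default 4).
#' @param smooth_sigma Pre-detection Gaussian smoothing sd in pixels
#'   (default 1; 0 disables smoothing).
#' @return `data.frame` with columns `x`, `y`, `intensity` (smoothed peak
#'   value above background); zero rows when nothing is found.
#' @export
detect_spots <- function(image, neighborhood = 5L, threshold_sigma = 4,
                         smooth_sigma = 1) {
  stopifnot(is.matrix(image), all(is.finite(image)))
  neighborhood <- as.integer(neighborhood)
  if (neighborhood < 3L || neighborhood %% 2L == 0L)
    stop("'neighborhood' must be an odd integer >= 3", call. = FALSE)
  sm <- gauss_smooth(image, smooth_sigma)
  bg <- stats::median(sm)
  spread <- stats::mad(sm)
  # noise-free images have zero robust spread; fall back to a small
  # fraction of the dynamic range so dim spots stay detectable
  thr <- if (is.na(spread) || spread == 0) {
    rng <- max(sm) - bg
    if (rng <= 0) return(data.frame(x = numeric(0), y = numeric(0),
                                    intensity = numeric(0)))
    bg + 0.001 * rng
  } else bg + threshold_sigma * spread
  r <- (neighborhood - 1L) %/% 2L
  h <- nrow(sm); w <- ncol(sm)
  cand <- which(sm > thr, arr.ind = TRUE)
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    ri <- cand[i, 1]; ci <- cand[i, 2]
    rs <- max(1, ri - r):min(h, ri + r)
    cs <- max(1, ci - r):min(w, ci + r)
    win <- sm[rs, cs]
    v <- sm[ri, ci]
    keep[i] <- sum(win >= v) == 1L  # strict maximum of the window
  }
  cand <- cand[keep, , drop = FALSE]
  if (nrow(cand) == 0)
    return(data.frame(x = numeric(0), y = numeric(0), intensity = numeric(0)))
  # sub-pixel refinement: log-quadratic interpolation of the smoothed peak
  # (exact for a Gaussian profile), falling back to an intensity centroid
  raw_bg <- stats::median(image)
  out <- data.frame(x = numeric(nrow(cand)), y = numeric(nrow(cand)),
                    intensity = numeric(nrow(cand)))
  logq <- function(l, c0, rr) {
    den <- l - 2 * c0 + rr
    if (den >= 0) return(NA_real_)
    d <- (l - rr) / (2 * den)
    if (abs(d) > 1) NA_real_ else d
  }
  for (i in seq_len(nrow(cand))) {
    ri <- cand[i, 1]; ci <- cand[i, 2]
    dx <- dy <- NA_real_
    if (ri > 1 && ri < h && ci > 1 && ci < w) {
      v <- sm[(ri - 1):(ri + 1), (ci - 1):(ci + 1)] - bg
      if (all(v > 0)) {
        lv <- log(v)
        dy <- logq(lv[1, 2], lv[2, 2], lv[3, 2])
        dx <- logq(lv[2, 1], lv[2, 2], lv[2, 3])
      }
    }
    if (is.na(dx) || is.na(dy)) {
      rs <- max(1, ri - r):min(h, ri + r)
      cs <- max(1, ci - r):min(w, ci + r)
      wgt <- pmax(image[rs, cs] - raw_bg, 0)
      s <- sum(wgt)
      if (s <= 0) { cx <- ci - 1; cy <- ri - 1 } else {
        cy <- sum((rs - 1) * rowSums(wgt)) / s
        cx <- sum((cs - 1) * colSums(wgt)) / s
      }
    } else {
      cx <- ci - 1 + dx
      cy <- ri - 1 + dy
    }
    out$x[i] <- cx; out$y[i] <- cy
    out$intensity[i] <- sm[ri, ci] - bg
  }
  out[order(-out$intensity), , drop = FALSE]
}

#' Build detection images and process a movie end to end
#'
#' Detection images are channel averages over the first `n_detect_frames`
#' donor-excitation frames: the donor channel shows donor emission and the
#' acceptor channel shows FRET-sensitized acceptor emission, so both
#' fluorophores are detected while still photoactive (most acceptors have
#' bleached by the time of the late direct-excitation segment, which is
#' therefore used for identity confirmation, not detection).
#'
#' @param movie A `movie_stack`.
#' @param n_detect_frames Donor-excitation frames averaged (default 20).
#' @return List of matrices `donor`, `acceptor`.
#' @export
detection_images <- function(movie, n_detect_frames = 20L) {
  fr <- movie$donor_excitation_frames
  fr <- fr[seq_len(min(n_detect_frames, length(fr)))]
  list(donor = apply(movie$donor[fr, , , drop = FALSE], c(2, 3), mean),
       acceptor = apply(movie$acceptor[fr, , , drop = FALSE], c(2, 3), mean))
}

#' @rdname detection_images
#' @param registration_images List with `donor` and `acceptor` fiducial
#'   images (from [simulate_movie()]), used when `registration` is NULL.
#' @param registration A precomputed `channel_registration`.
#' @param threshold_sigma,neighborhood Passed to [detect_spots()].
#' @param max_pair_distance Passed to [pair_spots()].
#' @param aperture_diameter,bg_region_diameter Passed to [extract_trace()].
#' @return `process_movie` returns a list with `registration`, `spots`
#'   (per channel), `pairs`, `traces`, `skipped` and `counts`.
#' @export
process_movie <- function(movie, registration_images = NULL,
                          registration = NULL, n_detect_frames = 20L,
                          threshold_sigma = 4, neighborhood = 5L,
                          max_pair_distance = 2,
                          aperture_diameter = 7, bg_region_diameter = 35) {
  if (is.null(registration)) {
    if (is.null(registration_images))
      stop("supply either a registration or registration images", call. = FALSE)
    registration <- register_channels(registration_images$donor,
                                      registration_images$acceptor)
  }
  det <- detection_images(movie, n_detect_frames)
  sp_d <- detect_spots(det$donor, neighborhood = neighborhood,
                       threshold_sigma = threshold_sigma)
  sp_a <- detect_spots(det$acceptor, neighborhood = neighborhood,
                       threshold_sigma = threshold_sigma)
  pairs <- pair_spots(sp_d, sp_a, registration,
                      max_pair_distance = max_pair_distance)
  ex <- extract_traces(movie, pairs, aperture_diameter, bg_region_diameter,
                       all_spots = sp_d)
  list(registration = registration,
       spots = list(donor = sp_d, acceptor = sp_a),
       pairs = pairs, traces = ex$traces, skipped = ex$skipped,
       counts = c(donor_spots = nrow(sp_d), acceptor_spots = nrow(sp_a),
                  ex$counts))
}

#' Pair donor and acceptor spot detections across channels
#'
#' Maps acceptor-channel detections into the donor frame using the channel
#' registration, then matches greedily by ascending distance (ties broken
#' towards brighter donor spots). Donor spots without an acceptor partner
#' within `max_pair_distance` are flagged `donor_only`; such molecules carry
#' no FRET information and are excluded downstream. Acceptor detections
#' without a donor partner are dropped (no donor, no trace).
#'
#' @param donor_spots,acceptor_spots Data frames from [detect_spots()].
#' @param registration A `channel_registration` (or 2x3 affine matrix
#'   donor -> acceptor).
#' @param max_pair_distance Maximum pairing distance in donor-frame pixels
#'   (default 2).
#' @return `data.frame` with one row per donor spot: donor and mapped
#'   acceptor coordinates, `pairing_distance` and `donor_only` flag.
#' @export
pair_spots <- function(donor_spots, acceptor_spots, registration,
                       max_pair_distance = 2) {
  tf <- if (inherits(registration, "channel_registration"))
    registration$inverse else invert_transform(registration)
  acc_in_donor <- if (nrow(acceptor_spots))
    apply_transform(tf, cbind(acceptor_spots$x, acceptor_spots$y))
  else matrix(numeric(0), 0, 2)
  n_d <- nrow(donor_spots)
  out <- data.frame(
    donor_x = donor_spots$x, donor_y = donor_spots$y,
    acceptor_x = NA_real_, acceptor_y = NA_real_,
    acceptor_x_native = NA_real_, acceptor_y_native = NA_real_,
    pairing_distance = NA_real_, donor_only = TRUE)
  if (n_d == 0 || nrow(acc_in_donor) == 0) return(out)
  d <- sqrt(outer(donor_spots$x, acc_in_donor[, 1], "-")^2 +
            outer(donor_spots$y, acc_in_donor[, 2], "-")^2)
  # greedy by ascending distance; ties towards brighter donor spots
  ord <- order(d, -donor_spots$intensity[(seq_along(d) - 1) %% n_d + 1])
  used_a <- logical(nrow(acc_in_donor)); used_d <- logical(n_d)
  for (i in ord) {
    if (d[i] > max_pair_distance) break
    ri <- (i - 1) %% n_d + 1
    ci <- (i - 1) %/% n_d + 1
    if (used_d[ri] || used_a[ci]) next
    used_d[ri] <- TRUE; used_a[ci] <- TRUE
    out$acceptor_x[ri] <- acc_in_donor[ci, 1]
    out$acceptor_y[ri] <- acc_in_donor[ci, 2]
    out$acceptor_x_native[ri] <- acceptor_spots$x[ci]
    out$acceptor_y_native[ri] <- acceptor_spots$y[ci]
    out$pairing_distance[ri] <- d[i]
    out$donor_only[ri] <- FALSE
  }
  out
}

#' Extract a raw intensity trace for one spot pair
#'
#' Per frame, sums a circular aperture centred on each channel's spot and
#' subtracts the local background, estimated as the median pixel value
#' inside a concentric circular region (default 35-pixel diameter) excluding
#' the aperture itself and excluding pixels near other detected spots,
#' scaled to the aperture area. The acceptor-excitation frames yield the
#' direct-excitation acceptor signal used to confirm fluorophore identity.
#'
#' @param movie A `movie_stack`.
#' @param pair One row of the [pair_spots()] table (must not be donor-only).
#' @param aperture_diameter Signal aperture diameter in pixels (default 7).
#' @param bg_region_diameter Background region diameter in pixels
#'   (default 35).
#' @param other_spots Optional data.frame of all detected donor-frame spot
#'   positions; background pixels within `aperture_diameter` of any other
#'   spot are excluded from the background estimate.
#' @return A `raw_trace` (background-corrected donor/acceptor series over
#'   the donor-excitation frames, plus the `direct` acceptor-excitation
#'   series), or a `trace_skip` object whose `reason` is `"edge"` or
#'   `"crowded"` when the spot cannot be measured.
#' @export
extract_trace <- function(movie, pair, aperture_diameter = 7,
                          bg_region_diameter = 35, other_spots = NULL) {
  stopifnot(inherits(movie, "movie_stack"))
  if (isTRUE(pair$donor_only))
    stop("cannot extract a trace for a donor-only pair", call. = FALSE)
  h <- dim(movie$donor)[2]; w <- dim(movie$donor)[3]
  rb <- bg_region_diameter / 2
  centers <- list(donor = c(pair$donor_x, pair$donor_y),
                  acceptor = c(pair$donor_x, pair$donor_y))
  # acceptor aperture sits at the mapped acceptor position in its own channel
  acc_native <- c(pair$acceptor_x_native %||% NA_real_,
                  pair$acceptor_y_native %||% NA_real_)
  if (!any(is.na(acc_native))) centers$acceptor <- acc_native
  for (ctr in centers) {
    if (ctr[1] - rb < -0.5 || ctr[1] + rb > w - 0.5 ||
        ctr[2] - rb < -0.5 || ctr[2] + rb > h - 0.5)
      return(trace_skip("edge"))
  }
  if (!is.null(other_spots) && nrow(other_spots)) {
    dd <- sqrt((other_spots$x - pair$donor_x)^2 +
               (other_spots$y - pair$donor_y)^2)
    if (any(dd > 1e-6 & dd < aperture_diameter))
      return(trace_skip("crowded"))
  }

  sum_series <- function(stack, frames, ctr) {
    masks <- aperture_masks(h, w, ctr, aperture_diameter, bg_region_diameter,
                            other_spots, pair, aperture_diameter)
    sub <- stack[frames, , , drop = FALSE]
    tmat <- matrix(sub, nrow = length(frames))   # frames x (h*w)
    ap <- tmat[, masks$aperture, drop = FALSE]
    bg <- tmat[, masks$background, drop = FALSE]
    bg_per_px <- apply(bg, 1, stats::median)
    list(sum = rowSums(ap) - bg_per_px * length(masks$aperture),
         bg = bg_per_px * length(masks$aperture))
  }
  fd <- movie$donor_excitation_frames
  fa <- movie$acceptor_excitation_frames
  d <- sum_series(movie$donor, fd, centers$donor)
  a <- sum_series(movie$acceptor, fd, centers$acceptor)
  direct <- if (length(fa)) sum_series(movie$acceptor, fa, centers$acceptor)
            else list(sum = numeric(0), bg = numeric(0))
  structure(list(
    molecule_id = NA_integer_,
    donor = d$sum, acceptor = a$sum, direct = direct$sum,
    bg_donor = d$bg, bg_acceptor = a$bg,
    frame_period = movie$frame_period,
    spot = pair
  ), class = "raw_trace")
}

trace_skip <- function(reason) structure(list(reason = reason),
                                         class = "trace_skip")

# Linear indices (into an h*w matrix, column-major) of the circular signal
# aperture and the background region around a centre.
aperture_masks <- function(h, w, ctr, aperture_diameter, bg_region_diameter,
                           other_spots, pair, excl_diameter) {
  xs <- 0:(w - 1); ys <- 0:(h - 1)
  dx2 <- outer((ys - ctr[2])^2, (xs - ctr[1])^2, "+")  # h x w, squared dist
  ap <- dx2 <= (aperture_diameter / 2)^2
  bgm <- dx2 <= (bg_region_diameter / 2)^2 & !ap
  if (!is.null(other_spots) && nrow(other_spots)) {
    for (j in seq_len(nrow(other_spots))) {
      if (abs(other_spots$x[j] - pair$donor_x) < 1e-6 &&
          abs(other_spots$y[j] - pair$donor_y) < 1e-6) next
      d2 <- outer((ys - other_spots$y[j])^2, (xs - other_spots$x[j])^2, "+")
      bgm <- bgm & d2 > (excl_diameter / 2)^2
    }
  }
  list(aperture = which(ap), background = which(bgm))
}

#' Extract traces for all retained spot pairs in a movie
#'
#' Runs [extract_trace()] over every non-donor-only pair, collecting skip
#' reasons, and reports per-stage counts.
#'
#' @inheritParams extract_trace
#' @param pairs Full table from [pair_spots()].
#' @param all_spots Optional spot table for background exclusion / crowding.
#' @return List with `traces` (list of `raw_trace`), `skipped`
#'   (data.frame of pair index and reason) and `counts`.
#' @export
extract_traces <- function(movie, pairs, aperture_diameter = 7,
                           bg_region_diameter = 35, all_spots = NULL) {
  keep <- which(!pairs$donor_only)
  traces <- list(); skipped <- data.frame(pair = integer(0),
                                          reason = character(0))
  for (i in keep) {
    tr <- extract_trace(movie, pairs[i, ], aperture_diameter,
                        bg_region_diameter, other_spots = all_spots)
    if (inherits(tr, "trace_skip")) {
      skipped <- rbind(skipped, data.frame(pair = i, reason = tr$reason))
    } else {
      tr$molecule_id <- i
      traces[[length(traces) + 1L]] <- tr
    }
  }
  list(traces = traces, skipped = skipped,
       counts = c(pairs = nrow(pairs), donor_only = sum(pairs$donor_only),
                  extracted = length(traces), skipped = nrow(skipped)))
}
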