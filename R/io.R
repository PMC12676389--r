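#' Write and read single-molecule traces as CSV
#'
#' Long format with columns `molecule_id`, `frame`, `I_donor_raw`,
#' `I_acceptor_raw`, `excitation_segment` (`"donor"` or `"acceptor"`;
#' acceptor-excitation rows carry the direct-excitation acceptor signal in
#' `I_acceptor_raw`).
#'
#' @param traces List of `raw_trace` objects.
#' @param path Output CSV path.
#' @return `write_traces_csv` invisibly returns the path;
#'   `read_traces_csv` returns a list of `raw_trace` objects.
#' @export
write_traces_csv <- function(traces, path) {
  rows <- lapply(traces, function(tr) {
    nd <- length(tr$donor); na_ <- length(tr$direct)
    data.table::data.table(
      molecule_id = tr$molecule_id,
      frame = c(seq_len(nd), nd + seq_len(na_)),
      I_donor_raw = c(tr$donor, rep(NA_real_, na_)),
      I_acceptor_raw = c(tr$acceptor, tr$direct),
      excitation_segment = c(rep("donor", nd), rep("acceptor", na_)))
  })
  dt <- data.table::rbindlist(rows)
  data.table::fwrite(dt, path)
  invisible(path)
}

#' @rdname write_traces_csv
#' @param frame_period Seconds per frame to attach to the traces read back.
#' @export
read_traces_csv <- function(path, frame_period = 0.1) {
  dt <- data.table::fread(path)
  need <- c("molecule_id", "frame", "I_donor_raw", "I_acceptor_raw",
            "excitation_segment")
  if (!all(need %in% names(dt)))
    stop("trace CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  ids <- unique(dt$molecule_id)
  lapply(ids, function(id) {
    sub <- dt[dt$molecule_id == id, ]
    don <- sub[sub$excitation_segment == "donor", ]
    acc <- sub[sub$excitation_segment == "acceptor", ]
    structure(list(molecule_id = id,
                   donor = don$I_donor_raw,
                   acceptor = don$I_acceptor_raw,
                   direct = acc$I_acceptor_raw,
                   frame_period = frame_period),
              class = "raw_trace")
  })
}

#' Write and read two-channel movie stacks as multi-page TIFF
#'
#' Each channel becomes one multi-page 32-bit float TIFF; intensities are
#' scaled into [0, 1] by a factor recorded in a JSON sidecar together with
#' the excitation schedule and frame period, so reading restores the
#' original values.
#'
#' @param movie A `movie_stack`.
#' @param prefix Output path prefix; writes `<prefix>_donor.tif`,
#'   `<prefix>_acceptor.tif` and `<prefix>_meta.json`.
#' @return `write_movie` invisibly returns the sidecar path; `read_movie`
#'   returns a `movie_stack`.
#' @export
write_movie <- function(movie, prefix) {
  stopifnot(inherits(movie, "movie_stack"))
  scale <- max(movie$donor, movie$acceptor, 1)
  to_pages <- function(stack)
    lapply(seq_len(dim(stack)[1]), function(t)
      pmax(stack[t, , ], 0) / scale)
  tiff::writeTIFF(to_pages(movie$donor), paste0(prefix, "_donor.tif"),
                  bits.per.sample = 32L)
  tiff::writeTIFF(to_pages(movie$acceptor), paste0(prefix, "_acceptor.tif"),
                  bits.per.sample = 32L)
  meta <- list(scale = scale,
               frame_period = movie$frame_period,
               donor_excitation_frames = range(movie$donor_excitation_frames),
               acceptor_excitation_frames =
                 if (length(movie$acceptor_excitation_frames))
                   range(movie$acceptor_excitation_frames) else integer(0),
               offset = movie$offset %||% 0)
  jsonlite::write_json(meta, paste0(prefix, "_meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(paste0(prefix, "_meta.json"))
}

#' @rdname write_movie
#' @export
read_movie <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, "_meta.json"),
                              simplifyVector = TRUE)
  rd <- function(path) {
    pages <- tiff::readTIFF(path, all = TRUE)
    arr <- array(0, dim = c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
    for (t in seq_along(pages)) arr[t, , ] <- pages[[t]] * meta$scale
    arr
  }
  donor <- rd(paste0(prefix, "_donor.tif"))
  acceptor <- rd(paste0(prefix, "_acceptor.tif"))
  der <- meta$donor_excitation_frames
  aer <- meta$acceptor_excitation_frames
  structure(list(donor = donor, acceptor = acceptor,
                 frame_period = meta$frame_period,
                 donor_excitation_frames = der[1]:der[2],
                 acceptor_excitation_frames =
                   if (length(aer)) aer[1]:aer[2] else integer(0),
                 offset = meta$offset),
            class = "movie_stack")
}

#' Write and read gold-particle coordinate tables
#'
#' CSV with columns `image_id`, `condition`, `x_nm`, `y_nm`.
#' @param points Data frame of particle coordinates.
#' @param path CSV path.
#' @export
write_points_csv <- function(points, path) {
  data.table::fwrite(data.table::as.data.table(points), path)
  invisible(path)
}

#' @rdname write_points_csv
#' @export
read_points_csv <- function(path) {
  dt <- as.data.frame(data.table::fread(path))
  if (!all(c("x_nm", "y_nm") %in% names(dt)))
    stop("points CSV must have columns x_nm and y_nm", call. = FALSE)
  dt
}
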