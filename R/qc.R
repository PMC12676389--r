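#' Apply the five-criterion single-molecule trace selection
#'
#' Evaluates, in order: (1) signal-to-noise ratio >= 5; (2) single-step
#' acceptor photobleaching prior to donor bleaching; (3) gamma factor
#' between 0.5 and 2.5; (4) anticorrelated donor and acceptor intensity
#' fluctuations; (5) single-step donor bleaching, if present; plus
#' confirmation of the acceptor fluorophore by the direct-excitation
#' segment. All thresholds are inclusive, so boundary values pass. A
#' molecule whose donor never bleaches within the recording passes
#' criterion (5) as not-applicable. Static traces, which carry no
#' fluctuation signal, satisfy criterion (4) through opposite-sign
#' intensity changes at the acceptor-bleach step.
#'
#' @param trace A `corrected_trace` from [correct_trace()].
#' @param params The [correction_params()] holding the thresholds.
#' @return A `qc_report`: `molecule_id`, `pass`, `criterion_results`
#'   (named character vector with values `"pass"`, `"fail"` or `"na"`) and
#'   `reject_reason` (first failed criterion, or NA).
#' @export
apply_qc <- function(trace, params = correction_params()) {
  if (!inherits(trace, "corrected_trace"))
    stop("'trace' must be a corrected_trace", call. = FALSE)
  res <- c(snr = NA_character_,
           acceptor_single_step_before_donor = NA_character_,
           gamma_in_bounds = NA_character_,
           anticorrelated = NA_character_,
           donor_single_step = NA_character_,
           acceptor_confirmed = NA_character_)

  res["snr"] <- if (is.na(trace$snr)) "fail"
    else if (trace$snr >= params$snr_min) "pass" else "fail"

  ta <- trace$acceptor_bleach_frame
  td <- trace$donor_bleach_frame
  ok2 <- !is.na(ta) && trace$acceptor_step_count == 1L &&
    (is.na(td) || ta < td)
  res["acceptor_single_step_before_donor"] <- if (ok2) "pass" else "fail"

  res["gamma_in_bounds"] <- if (is.na(trace$gamma)) "fail"
    else if (trace$gamma >= params$gamma_bounds[1] &&
             trace$gamma <= params$gamma_bounds[2]) "pass" else "fail"

  res["anticorrelated"] <- if (isTRUE(trace$dynamic)) {
    if (!is.na(trace$anticorrelation_r) &&
        trace$anticorrelation_r <= params$anticorrelation_max) "pass"
    else if (isTRUE(trace$bleach_anticorrelated)) "pass" else "fail"
  } else {
    if (isTRUE(trace$bleach_anticorrelated)) "pass" else "fail"
  }

  res["donor_single_step"] <- if (is.na(td)) "na"
    else if (trace$donor_step_count == 1L) "pass" else "fail"

  res["acceptor_confirmed"] <- if (is.na(trace$acceptor_confirmed)) "na"
    else if (trace$acceptor_confirmed) "pass" else "fail"

  failed <- names(res)[res == "fail"]
  structure(list(molecule_id = trace$molecule_id,
                 pass = length(failed) == 0L,
                 criterion_results = res,
                 reject_reason = if (length(failed)) failed[1] else NA_character_),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("qc_report molecule %s: %s\n", format(x$molecule_id),
              if (x$pass) "PASS" else paste0("FAIL (", x$reject_reason, ")")))
  for (nm in names(x$criterion_results))
    cat(sprintf("  %-35s %s\n", nm, x$criterion_results[nm]))
  invisible(x)
}

#' Summarise a set of QC reports
#'
#' Counts accepted and rejected molecules, attributing each rejection to
#' its first failing criterion.
#'
#' @param reports List of `qc_report` objects (or a single one).
#' @return A list with `total`, `accepted`, `acceptance_fraction`,
#'   `fail_counts` (named by criterion) and the per-molecule table
#'   `table` (molecule_id, pass, reject_reason).
#' @export
qc_summary <- function(reports) {
  if (inherits(reports, "qc_report")) reports <- list(reports)
  criteria <- c("snr", "acceptor_single_step_before_donor", "gamma_in_bounds",
                "anticorrelated", "donor_single_step", "acceptor_confirmed")
  fail_counts <- stats::setNames(integer(length(criteria)), criteria)
  n <- length(reports)
  tab <- data.frame(molecule_id = rep(NA_integer_, n),
                    pass = logical(n),
                    reject_reason = rep(NA_character_, n),
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    r <- reports[[i]]
    tab$molecule_id[i] <- r$molecule_id %||% NA_integer_
    tab$pass[i] <- r$pass
    tab$reject_reason[i] <- r$reject_reason
    if (!r$pass) fail_counts[r$reject_reason] <- fail_counts[r$reject_reason] + 1L
  }
  list(total = n,
       accepted = sum(tab$pass),
       acceptance_fraction = if (n) mean(tab$pass) else NA_real_,
       fail_counts = fail_counts,
       table = tab)
}
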