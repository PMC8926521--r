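#' Multi-lead ECG record container
#'
#' An `ecg_record` holds a sample matrix in millivolts (one column per lead),
#' the sampling rate and the lead names. It is the raw object every signal
#' stage of the pipeline transforms.
#'
#' @param signal Numeric matrix, samples x leads, in mV. A plain vector is
#'   treated as a single lead.
#' @param fs Sampling rate in Hz.
#' @param leads Character vector of lead names, one per column.
#' @return An object of class `ecg_record` with elements `signal`, `fs`,
#'   `leads`.
#' @export
ecg_record <- function(signal, fs, leads = NULL) {
  if (is.vector(signal)) signal <- matrix(signal, ncol = 1L)
  if (!is.matrix(signal) || !is.numeric(signal))
    stop_invalid("`signal` must be a numeric matrix (samples x leads)")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop_invalid("`fs` must be a positive sampling rate in Hz")
  leads <- leads %||% colnames(signal) %||% paste0("L", seq_len(ncol(signal)))
  if (length(leads) != ncol(signal))
    stop_invalid("%d lead names for %d signal columns", length(leads), ncol(signal))
  colnames(signal) <- leads
  structure(list(signal = signal, fs = fs, leads = leads),
            class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record> %d samples x %d leads @ %g Hz (%.1f s)\n",
              nrow(x$signal), ncol(x$signal), x$fs, nrow(x$signal) / x$fs))
  cat("leads:", paste(x$leads, collapse = ", "), "\n")
  invisible(x)
}

# Extract one lead as a numeric vector; accepts a name or column index.
lead_signal <- function(record, lead) {
  stopifnot(inherits(record, "ecg_record"))
  if (is.character(lead)) {
    if (!lead %in% record$leads)
      stop_invalid("lead '%s' not in record (have: %s)", lead,
                   paste(record$leads, collapse = ", "))
    record$signal[, lead]
  } else {
    record$signal[, lead]
  }
}

#' Standard 12-lead names in conventional order
#' @return Character vector `I, II, III, aVR, aVL, aVF, V1..V6`.
#' @export
standard_leads <- function() {
  c("I", "II", "III", "aVR", "aVL", "aVF",
    "V1", "V2", "V3", "V4", "V5", "V6")
}
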