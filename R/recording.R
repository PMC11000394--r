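#' Construct an EEG recording object
#'
#' Container for one subject's continuous multichannel EEG. Signals are
#' always held in physical units (microvolts).
#'
#' @param subject_id subject label
#' @param channels character vector of channel labels (canonical montage
#'   names where resolvable)
#' @param fs sampling rate in Hz (identical for all channels)
#' @param data channels x samples numeric matrix, in microvolts
#' @param reference label of the current reference scheme (e.g. "Cz",
#'   "T9T10")
#' @param annotations optional data frame with columns `onset` (s),
#'   `duration` (s), `text`
#' @param unmapped character vector of channel labels that did not resolve
#'   to a montage electrode (kept, but flagged)
#' @return an object of class `eeg_recording`
#' @export
new_recording <- function(subject_id, channels, fs, data,
                          reference = "Cz", annotations = NULL,
                          unmapped = character(0)) {
  if (!is.matrix(data)) data <- matrix(data, nrow = length(channels))
  if (nrow(data) != length(channels)) {
    stop("data must have one row per channel", call. = FALSE)
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("fs must be a single positive number", call. = FALSE)
  }
  if (is.null(annotations)) {
    annotations <- data.frame(onset = numeric(0), duration = numeric(0),
                              text = character(0))
  }
  rownames(data) <- channels
  structure(
    list(subject_id = subject_id, channels = channels, fs = fs,
         data = data, reference = reference, annotations = annotations,
         unmapped = unmapped),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> subject %s: %d channels x %d samples @ %g Hz (%.1f s), ref %s\n",
              x$subject_id, length(x$channels), ncol(x$data), x$fs,
              ncol(x$data) / x$fs, x$reference))
  invisible(x)
}

#' Recording duration in seconds
#' @param recording an `eeg_recording`
#' @export
recording_duration <- function(recording) ncol(recording$data) / recording$fs
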