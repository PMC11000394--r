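# Plain EDF (16-bit European Data Format) reader/writer.
#
# Only the features this pipeline needs: one-second data records, identical
# sampling rate across channels, physical units in microvolts. EDF+
# annotation channels are not written; in-memory annotations survive a
# session but not a round-trip through disk.

EDF_DIG_MIN <- -32768L
EDF_DIG_MAX <- 32767L

pad_field <- function(s, width, what = "field") {
  s <- as.character(s)
  if (nchar(s, type = "bytes") > width) {
    stop("EDF header ", what, " '", s, "' exceeds ", width, " bytes",
         call. = FALSE)
  }
  sprintf(paste0("%-", width, "s"), s)
}

fmt_phys <- function(x) {
  # shortest decimal representation that fits the 8-char header slot
  for (d in 7:0) {
    s <- formatC(x, format = "fg", digits = d, flag = "")
    s <- sub("\\.$", "", s)
    if (nchar(s) <= 8 && abs(as.numeric(s) - x) < 1e-9 * max(1, abs(x))) {
      return(s)
    }
  }
  formatC(x, format = "g", digits = 4)
}

#' Write a recording to an EDF file
#'
#' Signals are quantized to 16 bits over the declared per-channel physical
#' range (default +/- 3276.8 microvolts, i.e. 0.1 uV per bit) and stored in
#' one-second data records. A signal exceeding its declared range is an
#' error: nothing is silently clipped. The header carries the subject id
#' and a fixed epoch date, so identical recordings produce byte-identical
#' files.
#'
#' @param recording an [new_recording()] object; `ncol(data)` must be a
#'   whole number of seconds and `fs` a whole number
#' @param path output file path
#' @param phys_min,phys_max declared physical range in microvolts, recycled
#'   across channels
#' @return `path`, invisibly
#' @export
write_edf <- function(recording, path, phys_min = -3276.8, phys_max = 3276.7) {
  fs <- recording$fs
  if (fs != round(fs)) stop("write_edf requires an integer sampling rate",
                            call. = FALSE)
  n_ch <- length(recording$channels)
  n_samp <- ncol(recording$data)
  n_rec <- n_samp / fs
  if (n_rec != round(n_rec)) {
    stop("recording length must be a whole number of seconds (",
         n_samp, " samples at ", fs, " Hz)", call. = FALSE)
  }
  phys_min <- rep_len(phys_min, n_ch)
  phys_max <- rep_len(phys_max, n_ch)
  for (c in seq_len(n_ch)) {
    lo <- min(recording$data[c, ]); hi <- max(recording$data[c, ])
    if (lo < phys_min[c] || hi > phys_max[c]) {
      stop(sprintf(
        "channel %s spans [%.2f, %.2f] uV, outside the declared physical range [%g, %g]; refusing to clip",
        recording$channels[c], lo, hi, phys_min[c], phys_max[c]),
        call. = FALSE)
    }
  }
  gain <- (phys_max - phys_min) / (EDF_DIG_MAX - EDF_DIG_MIN)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_field("0", 8),
    pad_field(recording$subject_id, 80, "patient id"),
    pad_field(paste("Startdate 01-JAN-2000 restalpha ref", recording$reference),
              80, "recording id"),
    pad_field("01.01.00", 8),
    pad_field("00.00.00", 8),
    pad_field(256L * (n_ch + 1L), 8),
    pad_field("", 44),
    pad_field(n_rec, 8),
    pad_field("1", 8),
    pad_field(n_ch, 4)
  )
  sig_hdr <- paste0(
    paste(vapply(recording$channels,
                 function(ch) pad_field(paste0("EEG ", ch), 16, "label"),
                 character(1)), collapse = ""),
    paste(rep(pad_field("AgAgCl electrode", 80), n_ch), collapse = ""),
    paste(rep(pad_field("uV", 8), n_ch), collapse = ""),
    paste(vapply(phys_min, function(x) pad_field(fmt_phys(x), 8, "phys min"),
                 character(1)), collapse = ""),
    paste(vapply(phys_max, function(x) pad_field(fmt_phys(x), 8, "phys max"),
                 character(1)), collapse = ""),
    paste(rep(pad_field(EDF_DIG_MIN, 8), n_ch), collapse = ""),
    paste(rep(pad_field(EDF_DIG_MAX, 8), n_ch), collapse = ""),
    paste(rep(pad_field("HP:none LP:none", 80), n_ch), collapse = ""),
    paste(rep(pad_field(fs, 8), n_ch), collapse = ""),
    paste(rep(pad_field("", 32), n_ch), collapse = "")
  )
  writeChar(paste0(hdr, sig_hdr), con, eos = NULL)
  # digitize: channels x samples -> per-record interleaved channel blocks
  dig <- matrix(0L, n_ch, n_samp)
  for (c in seq_len(n_ch)) {
    dig[c, ] <- as.integer(round((recording$data[c, ] - phys_min[c]) / gain[c])) +
      EDF_DIG_MIN
  }
  # reshape so each 1-s record holds fs samples of ch1, then ch2, ...
  arr <- array(dig, dim = c(n_ch, fs, n_rec))        # ch x samp x rec
  out <- aperm(arr, c(2, 1, 3))                      # samp x ch x rec
  writeBin(as.integer(out), con, size = 2, endian = "little")
  invisible(path)
}

read_header_field <- function(raw, at, width, name, numeric = FALSE) {
  s <- trimws(rawToChar(raw[at:(at + width - 1)]))
  if (numeric) {
    v <- suppressWarnings(as.numeric(s))
    if (is.na(v)) {
      stop("malformed EDF header: field '", name, "' is not numeric ('",
           s, "')", call. = FALSE)
    }
    return(v)
  }
  s
}

#' Read an EDF/EDF+ file into a recording
#'
#' Samples are converted to physical units using the per-channel
#' physical/digital ranges of the header; channels whose physical dimension
#' is mV are rescaled to microvolts. Channel labels are normalized
#' ("EEG Fp1-Ref" -> "Fp1", modern 10-10 names mapped to the montage's old
#' nomenclature); labels that resolve to no montage electrode are kept and
#' listed in the recording's `unmapped` field.
#'
#' @param path EDF file path
#' @param montage montage used for label resolution
#' @return an `eeg_recording`
#' @export
read_edf <- function(path, montage = standard_montage()) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 256) stop("malformed EDF header: file shorter than 256 bytes",
                              call. = FALSE)
  version <- read_header_field(raw, 1, 8, "version")
  if (version != "0") {
    stop("malformed EDF header: field 'version' must be '0', got '",
         version, "'", call. = FALSE)
  }
  patient <- read_header_field(raw, 9, 80, "patient id")
  rec_id <- read_header_field(raw, 89, 80, "recording id")
  hdr_bytes <- read_header_field(raw, 185, 8, "header bytes", numeric = TRUE)
  n_rec <- read_header_field(raw, 237, 8, "number of data records",
                             numeric = TRUE)
  rec_dur <- read_header_field(raw, 245, 8, "record duration", numeric = TRUE)
  n_sig <- read_header_field(raw, 253, 4, "number of signals", numeric = TRUE)
  if (n_sig < 1 || hdr_bytes != 256 * (n_sig + 1)) {
    stop("malformed EDF header: field 'header bytes' (", hdr_bytes,
         ") inconsistent with ", n_sig, " signals", call. = FALSE)
  }
  # per-signal fields are stored field-major: all labels, all transducers, ...
  field_offsets <- c(label = 0, transducer = 16, dim = 96, pmin = 104,
                     pmax = 112, dmin = 120, dmax = 128, prefilter = 136,
                     nsamp = 216, reserved = 224)
  get_sig <- function(field, width, numeric = FALSE) {
    vapply(seq_len(n_sig), function(i) {
      at <- 256 + field_offsets[[field]] * n_sig + (i - 1) * width + 1
      out <- read_header_field(raw, at, width, paste0(field, "[", i, "]"),
                               numeric)
      if (numeric) out else out
    }, if (numeric) numeric(1) else character(1))
  }
  labels <- get_sig("label", 16)
  dims <- get_sig("dim", 8)
  pmin <- get_sig("pmin", 8, numeric = TRUE)
  pmax <- get_sig("pmax", 8, numeric = TRUE)
  dmin <- get_sig("dmin", 8, numeric = TRUE)
  dmax <- get_sig("dmax", 8, numeric = TRUE)
  nsamp <- get_sig("nsamp", 8, numeric = TRUE)
  if (any(pmax <= pmin) || any(dmax <= dmin)) {
    stop("malformed EDF header: field 'physical/digital min/max' inverted",
         call. = FALSE)
  }
  is_annot <- grepl("EDF Annotations", labels, fixed = TRUE)
  eeg <- which(!is_annot)
  if (length(unique(nsamp[eeg])) != 1L) {
    stop("unsupported EDF layout: EEG channels have differing sampling rates (",
         paste(unique(nsamp[eeg]), collapse = ", "), " samples/record)",
         call. = FALSE)
  }
  fs <- nsamp[eeg[1]] / rec_dur
  total_per_rec <- sum(nsamp)
  body <- readBin(raw[(hdr_bytes + 1):length(raw)], "integer",
                  n = total_per_rec * n_rec, size = 2, endian = "little",
                  signed = TRUE)
  if (length(body) < total_per_rec * n_rec) {
    stop("malformed EDF file: truncated data section", call. = FALSE)
  }
  starts <- cumsum(c(0, nsamp))
  n_keep <- length(eeg)
  data <- matrix(0, n_keep, nsamp[eeg[1]] * n_rec)
  body <- matrix(body, nrow = total_per_rec)   # one column per record
  for (j in seq_along(eeg)) {
    i <- eeg[j]
    block <- body[(starts[i] + 1):(starts[i] + nsamp[i]), , drop = FALSE]
    gain <- (pmax[i] - pmin[i]) / (dmax[i] - dmin[i])
    vals <- (as.vector(block) - dmin[i]) * gain + pmin[i]
    if (grepl("^mV$", trimws(dims[i]), ignore.case = TRUE)) vals <- vals * 1000
    data[j, ] <- vals
  }
  raw_labels <- trimws(labels[eeg])
  canon <- normalize_channel_label(raw_labels, montage)
  unmapped <- canon[!(canon %in% montage$name)]
  ref <- sub(".*\\bref ", "", rec_id)
  if (identical(ref, rec_id)) ref <- "unknown"
  new_recording(subject_id = strsplit(patient, " ")[[1]][1],
                channels = canon, fs = fs, data = data,
                reference = ref, unmapped = unmapped)
}
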