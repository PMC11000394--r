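# End-to-end pipeline: preprocessing -> spectra -> per-subject alpha
# metrics -> group statistics, plus YAML configuration and a structured
# run log.

#' Default pipeline configuration
#'
#' All tunable parameters with their defaults: 1-45 Hz zero-phase
#' band-pass (order 4), T9/T10 re-reference, eight 20-s epochs screened at
#' 400 uV peak-to-peak, ICA stage off, 4-s Welch segments (0.25 Hz grid),
#' per-electrode IAF mode, and the 11-electrode posterior ROI as the FDR
#' family.
#'
#' @return nested list of configuration values
#' @export
default_config <- function() {
  list(
    filter = list(low_hz = 1, high_hz = 45, order = 4),
    reference = list(scheme = "T9T10"),
    epochs = list(length_s = 20, n_select = 8, hard_threshold_uv = 400),
    ica = list(enabled = FALSE, threshold = 0.8),
    spectrum = list(seg_len_s = 4, iaf_mode = "per_electrode",
                    band = c(8, 13)),
    stats = list(roi = roi_electrodes(), alpha_level = 0.05)
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(override[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Load a YAML configuration file over the defaults
#'
#' @param path YAML file; keys mirror [default_config()] (e.g.
#'   `filter: {low_hz: 1}`). `NULL` returns the defaults.
#' @return full configuration list
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) cfg <- merge_config(cfg, yaml::read_yaml(path))
  cfg
}

#' Preprocess one recording
#'
#' Band-pass filter, re-reference, screen epochs, optionally remove
#' blink-correlated independent components.
#'
#' @param recording an `eeg_recording`
#' @param config a [default_config()]-shaped list
#' @return an `eeg_epochs` object
#' @export
preprocess_recording <- function(recording, config = default_config()) {
  rec <- bandpass_filter(recording, config$filter$low_hz,
                         config$filter$high_hz, config$filter$order)
  rec <- rereference(rec, config$reference$scheme)
  ep <- screen_epochs(rec, config$epochs$length_s, config$epochs$n_select,
                      config$epochs$hard_threshold_uv)
  if (isTRUE(config$ica$enabled)) {
    ep <- remove_artifact_components(ep, config$ica$threshold)
  }
  ep
}

#' Build the subject x electrode metric table
#'
#' Runs every recording through [preprocess_recording()] and
#' [subject_alpha_metrics()], joins the manifest's group / migraine /
#' age / sex columns, and spreads the metrics into wide format: one
#' `alpha_<electrode>` and one `iaf_<electrode>` column per electrode.
#'
#' @param recordings list of `eeg_recording` objects
#' @param manifest data frame with at least `subject_id` and `group`
#' @param config pipeline configuration
#' @return wide metric table (class `metric_table`)
#' @export
alpha_metric_table <- function(recordings, manifest,
                               config = default_config()) {
  rows <- lapply(recordings, function(rec) {
    ep <- preprocess_recording(rec, config)
    m <- subject_alpha_metrics(ep, mode = config$spectrum$iaf_mode,
                               band = config$spectrum$band,
                               seg_len = config$spectrum$seg_len_s)
    wide <- data.frame(subject_id = m$subject_id[1],
                       stringsAsFactors = FALSE)
    for (k in seq_len(nrow(m))) {
      wide[[paste0("alpha_", m$channel[k])]] <- m$alpha_psd[k]
      wide[[paste0("iaf_", m$channel[k])]] <- m$iaf[k]
    }
    wide
  })
  tab <- do.call(rbind, rows)
  keep <- intersect(c("subject_id", "group", "migraine", "age", "sex"),
                    names(manifest))
  out <- merge(manifest[, keep, drop = FALSE], tab, by = "subject_id",
               sort = FALSE)
  class(out) <- c("metric_table", "data.frame")
  out
}

#' Run the full case-control analysis
#'
#' @param recordings list of `eeg_recording` objects
#' @param manifest cohort manifest
#' @param config pipeline configuration
#' @return list with `metrics` (wide metric table), `comparison`
#'   ([compare_groups()] result), `iaf` ([iaf_comparison()] result) and
#'   `config`
#' @export
run_pipeline <- function(recordings, manifest, config = default_config()) {
  metrics <- alpha_metric_table(recordings, manifest, config)
  comparison <- compare_groups(metrics, roi = config$stats$roi,
                               alpha_level = config$stats$alpha_level)
  iaf <- iaf_comparison(metrics,
                        stratify_by_migraine = "migraine" %in% names(metrics))
  list(metrics = metrics, comparison = comparison, iaf = iaf,
       config = config)
}

#' Write the structured run log
#'
#' Records every parameter actually used (filter settings, frequency
#' resolution, IAF mode, FDR family, seeds) as JSON next to the outputs.
#'
#' @param config pipeline configuration
#' @param path output JSON path
#' @param extra named list of additional entries (e.g. seed, package
#'   version)
#' @return `path`, invisibly
#' @export
write_run_log <- function(config, path, extra = list()) {
  log <- c(list(package = "restalpha",
                version = as.character(utils::packageVersion("restalpha")),
                timestamp = format(Sys.time(), tz = "UTC"),
                config = config),
           extra)
  jsonlite::write_json(log, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir directory holding `*.edf` files and `manifest.tsv`
#' @param montage montage for channel resolution
#' @return list with `recordings` and `manifest`
#' @export
read_cohort <- function(dir, montage = standard_montage()) {
  manifest <- utils::read.delim(file.path(dir, "manifest.tsv"),
                                stringsAsFactors = FALSE)
  files <- file.path(dir, paste0(manifest$subject_id, ".edf"))
  recordings <- lapply(files, read_edf, montage = montage)
  names(recordings) <- manifest$subject_id
  list(recordings = recordings, manifest = manifest)
}
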