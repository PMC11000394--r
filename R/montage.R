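#' The 25-electrode IFCN scalp montage
#'
#' Returns the 25-electrode array recommended by the IFCN for standard
#' clinical EEG: the 19 classical 10-20 sites plus the inferior chain
#' F9/F10, T9/T10 and P9/P10. Old 10-20 nomenclature (T3/T4/T5/T6) is
#' canonical because the downstream group tables report it; the modern
#' equivalents (T7/T8/P7/P8) are carried as alternative names and accepted
#' everywhere a channel is looked up.
#'
#' 2D positions are the standard spherical layout projected azimuthally to
#' the unit disc (x towards the right ear, y towards the nasion). The
#' inferior chain sits on the rim (radius 1); the classical outer ring at
#' radius 2/3. Left/right homologues are exactly mirror-symmetric in x.
#'
#' @return A data frame of class `montage` with columns `name`, `alt_name`
#'   (`NA` where the old and modern labels coincide), `x`, `y` and
#'   `region` (one of frontal, central, temporal, parietal, occipital,
#'   inferior), one row per electrode, in standard anterior-to-posterior
#'   order.
#' @examples
#' m <- standard_montage()
#' nrow(m)                      # 25
#' electrode_info(m, "T7")$name # resolves to "T3"
#' @export
standard_montage <- function() {
  # polar angle from the vertex in degrees (10% of the nasion-inion arc =
  # 18 degrees), azimuth in degrees counter-clockwise from the right ear
  def <- list(
    #       name    alt    polar  azim   region
    list("Fp1", NA,    72, 108, "frontal"),
    list("Fp2", NA,    72,  72, "frontal"),
    list("F9",  NA,   108, 144, "inferior"),
    list("F7",  NA,    72, 144, "frontal"),
    list("F3",  NA,    46, 129, "frontal"),
    list("Fz",  NA,    36,  90, "frontal"),
    list("F4",  NA,    46,  51, "frontal"),
    list("F8",  NA,    72,  36, "frontal"),
    list("F10", NA,   108,  36, "inferior"),
    list("T9",  NA,   108, 180, "inferior"),
    list("T3",  "T7",  72, 180, "temporal"),
    list("C3",  NA,    36, 180, "central"),
    list("Cz",  NA,     0,   0, "central"),
    list("C4",  NA,    36,   0, "central"),
    list("T4",  "T8",  72,   0, "temporal"),
    list("T10", NA,   108,   0, "inferior"),
    list("T5",  "P7",  72, 216, "temporal"),
    list("P3",  NA,    46, 231, "parietal"),
    list("Pz",  NA,    36, 270, "parietal"),
    list("P4",  NA,    46, 309, "parietal"),
    list("T6",  "P8",  72, 324, "temporal"),
    list("P9",  NA,   108, 216, "inferior"),
    list("P10", NA,   108, 324, "inferior"),
    list("O1",  NA,    72, 252, "occipital"),
    list("O2",  NA,    72, 288, "occipital")
  )
  name <- vapply(def, function(e) e[[1]], character(1))
  alt <- vapply(def, function(e) as.character(e[[2]]), character(1))
  polar <- vapply(def, function(e) e[[3]], numeric(1))
  azim <- vapply(def, function(e) e[[4]], numeric(1))
  r <- polar / 108
  # snap cosines of the symmetric azimuth pairs so homologues mirror exactly
  x <- round(r * cospi(azim / 180), 12)
  y <- round(r * sinpi(azim / 180), 12)
  m <- data.frame(
    name = name, alt_name = alt, x = x, y = y,
    region = vapply(def, function(e) e[[5]], character(1)),
    stringsAsFactors = FALSE
  )
  class(m) <- c("montage", "data.frame")
  m
}

#' Electrodes making up the posterior region of interest
#'
#' The 11 parieto-temporo-occipital electrodes over which the group
#' comparison of alpha-band PSD is run, in the order the result table is
#' reported.
#' @export
roi_electrodes <- function() {
  c("P3", "Pz", "P4", "P10", "P9", "O1", "O2", "T4", "T3", "T5", "T6")
}

#' Normalize a raw channel label to a montage electrode name
#'
#' Strips common EDF decorations ("EEG Fp1-Ref", trailing reference tags,
#' case differences) and maps modern 10-10 names onto the montage's
#' canonical old nomenclature. Labels that resolve to no montage electrode
#' are returned unchanged.
#'
#' @param labels character vector of raw channel labels
#' @param montage a [standard_montage()] table
#' @return character vector of canonical names (unresolved labels passed
#'   through, stripped of decorations)
#' @export
normalize_channel_label <- function(labels, montage = standard_montage()) {
  stripped <- trimws(labels)
  stripped <- sub("^(EEG|MEG|POL)[ _]+", "", stripped, ignore.case = TRUE)
  stripped <- sub("[-_ ](REF|LE|AVG|A1|A2|M1|M2|CZ)$", "", stripped,
                  ignore.case = TRUE)
  stripped <- trimws(stripped)
  canon <- toupper(montage$name)
  alt <- toupper(montage$alt_name)
  out <- stripped
  for (i in seq_along(stripped)) {
    u <- toupper(stripped[i])
    hit <- match(u, canon)
    if (is.na(hit)) hit <- match(u, alt)
    if (!is.na(hit)) out[i] <- montage$name[hit]
  }
  out
}

#' Look up one electrode by old or modern name
#'
#' @param montage a [standard_montage()] table
#' @param name electrode label, old (T3) or modern (T7) nomenclature,
#'   case-insensitive
#' @return a one-row list with `name`, `alt_name`, `pos2d` (length-2
#'   numeric), `region`
#' @export
electrode_info <- function(montage, name) {
  u <- toupper(trimws(name))
  hit <- match(u, toupper(montage$name))
  if (is.na(hit)) hit <- match(u, toupper(montage$alt_name))
  if (is.na(hit)) {
    stop("electrode '", name, "' is not in the montage", call. = FALSE)
  }
  list(
    name = montage$name[hit],
    alt_name = montage$alt_name[hit],
    pos2d = c(x = montage$x[hit], y = montage$y[hit]),
    region = montage$region[hit]
  )
}

#' Export the montage as a plain-text table
#'
#' @param montage a [standard_montage()] table
#' @param path output file (tab-separated)
#' @return `path`, invisibly
#' @export
write_montage <- function(montage, path) {
  utils::write.table(as.data.frame(montage), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
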