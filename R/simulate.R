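# Seeded generator of synthetic two-group resting-state EEG cohorts:
# 1/f aperiodic background + narrowband alpha with posterior topography +
# sensor noise + frontally weighted blink transients. Stands in for
# clinical recordings that cannot be redistributed.

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

rnorm_trunc <- function(n, mean, sd, lo, hi) {
  mean <- rep_len(mean, n)
  sd <- rep_len(sd, n)
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < lo | out > hi)
  while (length(bad) > 0) {
    out[bad] <- stats::rnorm(length(bad), mean[bad], sd[bad])
    bad <- which(out < lo | out > hi)
  }
  out
}

# Gaussian time series with one-sided target PSD P(f) [uV^2/Hz], via a
# random hermitian spectrum; E[ sum(psd * df) ] = var(x).
colored_noise_bank <- function(n, fs, psd_fun, nch) {
  m <- (n - 1L) %/% 2L                     # positive non-Nyquist bins
  f <- seq_len(m) * fs / n
  amp <- sqrt(psd_fun(f) * fs * n / 2)
  z <- matrix(complex(real = stats::rnorm(m * nch),
                      imaginary = stats::rnorm(m * nch)),
              m, nch) * (amp / sqrt(2))
  spec <- matrix(complex(real = 0), n, nch) # Nyquist bin (even n) left at 0
  spec[2:(m + 1L), ] <- z
  spec[(n - m + 1L):n, ] <- Conj(z[m:1, , drop = FALSE])
  Re(stats::mvfft(spec, inverse = TRUE)) / n
}

colored_noise <- function(n, fs, psd_fun) {
  colored_noise_bank(n, fs, psd_fun, 1L)[, 1]
}

#' Default posterior-dominant alpha topography
#'
#' Relative alpha RMS amplitude per electrode: occipital 1.0, parietal
#' 0.7, posterior inferior (P9/P10) 0.5, temporal 0.35, central 0.3,
#' retroauricular (T9/T10) 0.2, frontal and frontal inferior 0.1.
#'
#' @param montage a [standard_montage()] table
#' @return named numeric vector of weights over the montage electrodes
#' @export
default_alpha_topography <- function(montage = standard_montage()) {
  w <- c(frontal = 0.1, central = 0.3, temporal = 0.35, parietal = 0.7,
         occipital = 1.0)[montage$region]
  w[montage$name %in% c("P9", "P10")] <- 0.5
  w[montage$name %in% c("T9", "T10")] <- 0.2
  w[montage$name %in% c("F9", "F10")] <- 0.1
  names(w) <- montage$name
  unlist(w)
}

#' Specification of one synthetic subject
#'
#' @param subject_id label
#' @param group `"case"` or `"control"`
#' @param iaf_true true alpha peak frequency (Hz), inside \[8.5, 12.5\]
#' @param alpha_amp per-channel alpha RMS amplitude (uV): either a named
#'   vector over the montage or a scalar multiplied onto
#'   [default_alpha_topography()]
#' @param aperiodic_exponent 1/f slope beta (power ~ f^-beta), >= 0
#' @param aperiodic_scale background PSD at 1 Hz (uV^2/Hz)
#' @param noise_sd white sensor noise SD (uV)
#' @param artifact_rate blink transient rate (events/min)
#' @param age years
#' @param migraine logical comorbidity flag
#' @param montage montage used to expand a scalar `alpha_amp`
#' @return a `subject_spec` list
#' @export
subject_spec <- function(subject_id, group = c("control", "case"),
                         iaf_true = 10.1, alpha_amp = 1.0,
                         aperiodic_exponent = 1.5, aperiodic_scale = 1.0,
                         noise_sd = 2, artifact_rate = 2,
                         age = NA_real_, migraine = FALSE,
                         montage = standard_montage()) {
  group <- match.arg(group)
  if (iaf_true < 8.5 || iaf_true > 12.5) {
    stop("iaf_true must lie in [8.5, 12.5] Hz", call. = FALSE)
  }
  if (length(alpha_amp) == 1L && is.null(names(alpha_amp))) {
    alpha_amp <- alpha_amp * default_alpha_topography(montage)
  }
  if (any(alpha_amp < 0)) stop("alpha_amp must be >= 0", call. = FALSE)
  if (aperiodic_exponent < 0) {
    stop("aperiodic_exponent must be >= 0", call. = FALSE)
  }
  structure(
    list(subject_id = subject_id, group = group, iaf_true = iaf_true,
         alpha_amp = alpha_amp, aperiodic_exponent = aperiodic_exponent,
         aperiodic_scale = aperiodic_scale, noise_sd = noise_sd,
         artifact_rate = artifact_rate, age = age, migraine = migraine),
    class = "subject_spec"
  )
}

#' Simulate one subject's resting-state recording
#'
#' Each channel is the sum of (i) an aperiodic background -- Gaussian
#' noise spectrally shaped to power ~ f^(-beta), plateaued below 0.5 Hz --
#' (ii) a narrowband alpha component -- Gaussian noise with a Gaussian
#' spectral envelope of 1 Hz FWHM centred at the subject's true IAF,
#' scaled to the channel's alpha RMS amplitude -- (iii) white sensor
#' noise, and (iv) Poisson-placed biphasic blink transients (0.5 s, 150 uV
#' peak at Fp1/Fp2, half amplitude at F7/F8). Deterministic given `seed`.
#'
#' @param spec a [subject_spec()]
#' @param montage a [standard_montage()] table
#' @param duration recording length (s), >= 180
#' @param fs sampling rate (Hz), >= 100
#' @param seed integer RNG seed
#' @return an `eeg_recording` referenced at "Cz" (simulated near-vertex
#'   reference)
#' @export
simulate_subject <- function(spec, montage = standard_montage(),
                             duration = 1200, fs = 250, seed = 1) {
  if (duration < 180) stop("duration must be >= 180 s", call. = FALSE)
  if (fs < 100) stop("fs must be >= 100 Hz", call. = FALSE)
  if (spec$iaf_true - 1 <= 0 || spec$iaf_true + 1 >= fs / 2) {
    stop("alpha band [iaf-1, iaf+1] must lie inside (0, fs/2)",
         call. = FALSE)
  }
  n <- as.integer(round(duration * fs))
  chans <- montage$name
  amp <- spec$alpha_amp[chans]
  amp[is.na(amp)] <- 0
  beta <- spec$aperiodic_exponent
  ap_scale <- spec$aperiodic_scale
  sigma_a <- 1 / (2 * sqrt(2 * log(2)))   # 1 Hz FWHM Gaussian envelope
  with_seed(seed, {
    nch <- length(chans)
    data <- matrix(0, nch, n)
    if (ap_scale > 0) {
      data <- data + t(colored_noise_bank(n, fs, function(f) {
        ap_scale * pmax(f, 0.5)^(-beta)
      }, nch))
    }
    al <- which(amp > 0)
    if (length(al) > 0) {
      a <- colored_noise_bank(n, fs, function(f) {
        exp(-(f - spec$iaf_true)^2 / (2 * sigma_a^2))
      }, length(al))
      sds <- sqrt(colMeans(a^2) - colMeans(a)^2)
      data[al, ] <- data[al, , drop = FALSE] +
        t(a) * (amp[al] / sds)
    }
    if (spec$noise_sd > 0) {
      data <- data + matrix(stats::rnorm(nch * n, sd = spec$noise_sd),
                            nch, n)
    }
    if (spec$artifact_rate > 0) {
      blink_w <- c(Fp1 = 1, Fp2 = 1, F7 = 0.5, F8 = 0.5)[chans]
      blink_w[is.na(blink_w)] <- 0
      n_blink <- stats::rpois(1, spec$artifact_rate * duration / 60)
      if (n_blink > 0) {
        onsets <- stats::runif(n_blink, 0, duration - 0.6)
        bl <- as.integer(round(0.5 * fs))
        t_b <- seq_len(bl) / fs
        shape <- sin(2 * pi * t_b / 0.5) * sin(pi * t_b / 0.5)^2
        shape <- 150 * shape / max(abs(shape))
        for (o in onsets) {
          i0 <- as.integer(round(o * fs))
          idx <- (i0 + 1):(i0 + bl)
          data[, idx] <- data[, idx] + outer(blink_w, shape)
        }
      }
    }
    new_recording(spec$subject_id, chans, fs, data, reference = "Cz")
  })
}

#' Specification of a synthetic two-group cohort
#'
#' Defaults mirror the matched case-control design the pipeline analyses:
#' 21 subjects per group, two thirds (14/21) with comorbid migraine in
#' both groups, 20-min recordings at 250 Hz, a multiplicative alpha
#' attenuation `delta` for cases at the parieto-temporal effect
#' electrodes, and IAF means of 10.1 Hz (controls) / 10.6 Hz (cases)
#' without migraine and 10.3 Hz for both groups with migraine, with
#' doubled IAF spread under migraine.
#'
#' @param n_per_group subjects per group (>= 2)
#' @param effect_channels electrodes receiving the group effect
#' @param delta multiplicative alpha-amplitude factor applied to cases at
#'   `effect_channels` (1 = null, must be > 0)
#' @param iaf_means named list/vector with entries `control_nomig`,
#'   `case_nomig`, `control_mig`, `case_mig` (Hz)
#' @param iaf_sd IAF SD (Hz) without migraine; doubled with migraine
#' @param duration recording length per subject (s)
#' @param fs sampling rate (Hz)
#' @param base_alpha_amp alpha RMS (uV) at the occipital reference
#'   channels before topography weighting
#' @param amp_sdlog log-SD of the per-subject lognormal alpha-amplitude
#'   factor (between-subject variability)
#' @param migraine_fraction fraction of each group with comorbid migraine
#' @param noise_sd,artifact_rate,aperiodic_exponent,aperiodic_scale
#'   passed to every [subject_spec()]
#' @return a `cohort_spec` list
#' @export
cohort_spec <- function(n_per_group = 21,
                        effect_channels = c("P3", "P4", "Pz", "P10", "T3", "T4"),
                        delta = 1,
                        iaf_means = c(control_nomig = 10.1, case_nomig = 10.6,
                                      control_mig = 10.3, case_mig = 10.3),
                        iaf_sd = 0.4, duration = 1200, fs = 250,
                        base_alpha_amp = 1.0, amp_sdlog = 0.35,
                        migraine_fraction = 14 / 21,
                        noise_sd = 2, artifact_rate = 2,
                        aperiodic_exponent = 1.5, aperiodic_scale = 1.0) {
  if (delta <= 0) stop("delta must be > 0", call. = FALSE)
  if (n_per_group < 2) stop("n_per_group must be >= 2", call. = FALSE)
  if (floor(duration / 20) < 8) {
    stop("duration must admit at least 8 disjoint 20-s epochs",
         call. = FALSE)
  }
  structure(as.list(environment()), class = "cohort_spec")
}

#' Simulate a matched two-group cohort
#'
#' Draws `n_per_group` matched case/control pairs: age and sex are drawn
#' once per pair and copied (exact matching); migraine flags are assigned
#' to a fixed fraction identically in both groups; each subject gets an
#' independent lognormal alpha-amplitude factor and a truncated-normal
#' true IAF from the (group x migraine) cell mean; case alpha amplitudes
#' at the effect channels are multiplied by `delta`. Deterministic given
#' `seed`.
#'
#' @param spec a [cohort_spec()]
#' @param montage a [standard_montage()] table
#' @param seed integer RNG seed
#' @param recordings set to `FALSE` to draw the manifest (all true
#'   subject parameters) without synthesizing the signals
#' @return list with `recordings` (list of `eeg_recording`, or `NULL`)
#'   and `manifest` (data frame: subject_id, group, age, sex, migraine,
#'   iaf_true, amp_factor, and one `alpha_amp_<channel>` column per
#'   electrode)
#' @export
simulate_cohort <- function(spec, montage = standard_montage(), seed = 1,
                            recordings = TRUE) {
  n <- spec$n_per_group
  topo <- default_alpha_topography(montage)
  with_seed(seed, {
    ages <- round(rnorm_trunc(n, 33, 10.5, 18, 65))
    n_male <- round(n * 13 / 21)
    sexes <- rep(c("M", "F"), c(n_male, n - n_male))
    n_mig <- round(n * spec$migraine_fraction)
    migraine <- rep(c(TRUE, FALSE), c(n_mig, n - n_mig))
    subjects <- list()
    manifest <- NULL
    for (grp in c("case", "control")) {
      mig_key <- ifelse(migraine, "mig", "nomig")
      mu <- spec$iaf_means[paste0(ifelse(grp == "case", "case_", "control_"),
                                  mig_key)]
      sd_i <- ifelse(migraine, 2 * spec$iaf_sd, spec$iaf_sd)
      iafs <- rnorm_trunc(n, mu, sd_i, 8.5, 12.5)
      amp_factor <- stats::rlnorm(n, 0, spec$amp_sdlog)
      for (i in seq_len(n)) {
        amp <- spec$base_alpha_amp * amp_factor[i] * topo
        if (grp == "case") {
          amp[spec$effect_channels] <- amp[spec$effect_channels] * spec$delta
        }
        id <- sprintf("%s%02d", if (grp == "case") "V" else "C", i)
        subjects[[id]] <- subject_spec(
          id, group = grp, iaf_true = iafs[i], alpha_amp = amp,
          aperiodic_exponent = spec$aperiodic_exponent,
          aperiodic_scale = spec$aperiodic_scale,
          noise_sd = spec$noise_sd, artifact_rate = spec$artifact_rate,
          age = ages[i], migraine = migraine[i], montage = montage
        )
        row <- data.frame(subject_id = id, group = grp, age = ages[i],
                          sex = sexes[i], migraine = migraine[i],
                          iaf_true = iafs[i], amp_factor = amp_factor[i],
                          stringsAsFactors = FALSE)
        for (ch in names(amp)) row[[paste0("alpha_amp_", ch)]] <- amp[[ch]]
        manifest <- rbind(manifest, row)
      }
    }
    rec_seeds <- sample.int(.Machine$integer.max - 1L, length(subjects))
    recs <- NULL
    if (recordings) {
      recs <- vector("list", length(subjects))
      names(recs) <- names(subjects)
      for (k in seq_along(subjects)) {
        recs[[k]] <- simulate_subject(subjects[[k]], montage,
                                      duration = spec$duration,
                                      fs = spec$fs, seed = rec_seeds[k])
      }
    }
    list(recordings = recs, manifest = manifest)
  })
}

#' Write a simulated cohort to disk
#'
#' One EDF file per subject plus a tab-separated `manifest.tsv`.
#'
#' @param cohort result of [simulate_cohort()]
#' @param dir output directory (created if missing)
#' @return `dir`, invisibly
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (rec in cohort$recordings) {
    write_edf(rec, file.path(dir, paste0(rec$subject_id, ".edf")))
  }
  utils::write.table(cohort$manifest, file.path(dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
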