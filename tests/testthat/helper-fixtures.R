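# Shared fixtures, built in code at test time.

MONTAGE <- standard_montage()

# recording with a prescribed peak-to-peak score in each consecutive
# candidate epoch (one scalp channel, zero baseline)
recording_with_scores <- function(scores, epoch_len = 20, fs = 10,
                                  channel = "O1") {
  spe <- epoch_len * fs
  x <- numeric(spe * length(scores))
  for (i in seq_along(scores)) {
    x[(i - 1) * spe + 5] <- scores[i] / 2
    x[(i - 1) * spe + 6] <- -scores[i] / 2
  }
  new_recording("scores", channel, fs, matrix(x, 1))
}

# epoch-set container built directly from a channels x samples matrix
epochs_from_matrix <- function(X, channels, fs, n_epochs = 1) {
  spe <- ncol(X) / n_epochs
  ep <- array(0, dim = c(n_epochs, nrow(X), spe))
  for (e in seq_len(n_epochs)) {
    ep[e, , ] <- X[, ((e - 1) * spe + 1):(e * spe)]
  }
  structure(list(subject_id = "fix", channels = channels, fs = fs,
                 epochs = ep, epoch_onsets = (seq_len(n_epochs) - 1) * spe / fs,
                 screening_scores = rep(0, n_epochs),
                 selected = seq_len(n_epochs)),
            class = "eeg_epochs")
}

# hand-built spectrum object on a uniform grid
spectrum_from_psd <- function(psd, freqs, channels = "O1", fs = 250) {
  structure(list(channels = channels, freqs = freqs,
                 psd = matrix(psd, nrow = length(channels), byrow = TRUE),
                 fs = fs, n_epochs_averaged = 1),
            class = "eeg_spectrum")
}

# independent Mann-Whitney oracle: full enumeration of group assignments
mwu_enum_p <- function(x, y) {
  nx <- length(x)
  all_v <- c(x, y)
  N <- length(all_v)
  u_of <- function(xi) {
    xs <- all_v[xi]; ys <- all_v[-xi]
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  u_obs <- u_of(seq_len(nx))
  us <- apply(utils::combn(N, nx), 2, u_of)
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# independent BH step-up oracle, straight from the definition:
# adj_(i) = min(1, min_{k >= i} n * p_(k) / k), returned in input order
bh_brute <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(n)
  for (i in seq_len(n)) {
    best <- Inf
    for (k in i:n) best <- min(best, n * ps[k] / k)
    adj[i] <- min(1, best)
  }
  out <- numeric(n)
  out[o] <- adj
  out
}

# the 11 uncorrected p-values of the published per-electrode table
table3_p <- c(O1 = 0.128, O2 = 0.064, P3 = 0.015, Pz = 0.024, P4 = 0.014,
              P10 = 0.009, P9 = 0.222, T4 = 0.026, T3 = 0.021, T5 = 0.187,
              T6 = 0.076)
# printed FDR-adjusted values (T5 prints 0.205, a known rounding artefact
# of the source table; the step-up value from the printed raw p is 0.206)
table3_p_fdr <- c(O1 = 0.156, O2 = 0.101, P3 = 0.048, Pz = 0.048,
                  P4 = 0.048, P10 = 0.048, P9 = 0.222, T4 = 0.048,
                  T3 = 0.048, T5 = 0.206, T6 = 0.105)

# random lognormal metric table over the ROI, optional per-electrode
# multiplicative case shift
make_metric_table <- function(n = 21, seed = 1, shift = rep(1, 11)) {
  set.seed(seed)
  roi <- roi_electrodes()
  tab <- data.frame(subject_id = sprintf("s%02d", 1:(2 * n)),
                    group = rep(c("case", "control"), each = n),
                    migraine = rep(c(TRUE, FALSE), n),
                    stringsAsFactors = FALSE)
  for (k in seq_along(roi)) {
    v <- rlnorm(2 * n, meanlog = -2, sdlog = 0.8)
    v[tab$group == "case"] <- v[tab$group == "case"] * shift[k]
    tab[[paste0("alpha_", roi[k])]] <- v
    tab[[paste0("iaf_", roi[k])]] <- rnorm(2 * n, 10.3, 0.6)
  }
  tab
}

quick_subject <- function(id = "S", seed = 1, duration = 180, ...) {
  simulate_subject(subject_spec(id, ...), MONTAGE, duration = duration,
                   fs = 250, seed = seed)
}
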