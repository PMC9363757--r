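# Shared fixtures, built in code at test time (no binary files in the repo).

# pure-tone recording: one row per frequency
tone_recording <- function(freqs, fs = 512, duration_s = 1, amp = 1,
                           labels = paste0("ch", seq_along(freqs))) {
  t <- seq(0, duration_s - 1 / fs, by = 1 / fs)
  data <- t(vapply(freqs, function(f) amp * sin(2 * pi * f * t), numeric(length(t))))
  eeg_recording(data, fs, labels)
}

# white-noise epoched recording
noise_epochs <- function(n_ep, n_ch, fs, seed = 1) {
  set.seed(seed)
  eeg_epochs(array(rnorm(n_ep * n_ch * fs), c(n_ep, n_ch, fs)), fs,
             paste0("ch", seq_len(n_ch)), 1)
}

# hand-built psd_features object over arbitrary unit names (for contrast
# tests that do not need a real recording)
fake_psd <- function(values, group, subject_id = "s", band = "gamma") {
  n_units <- ncol(values)
  structure(list(
    subject_id = subject_id, group = group,
    values = array(values, c(nrow(values), n_units, 1),
                   dimnames = list(NULL, paste0("u", seq_len(n_units)), band)),
    band_defs = eeg_bands(band), channels = paste0("u", seq_len(n_units))),
    class = "psd_features")
}

# feature_matrix straight from x/y (bypassing the EEG pipeline)
fake_fm <- function(x, y, mode = "PSD", band = "gamma",
                    subject_id = paste0("s", seq_along(y))) {
  colnames(x) <- paste0("f", seq_len(ncol(x)))
  structure(list(x = x, y = y,
                 meta = data.frame(subject_id = subject_id,
                                   epoch = seq_along(y)),
                 feature_names = colnames(x), band = band, mode = mode,
                 groups = c("HC", "PD")),
            class = "feature_matrix")
}

# separable two-class 528-feature rows (diagonal + off-diagonal shift)
separable_rows <- function(n_per_class, shift_psd = 1, shift_plv = 0.15,
                           seed = 1) {
  set.seed(seed)
  mk <- function(n, s) {
    t(vapply(seq_len(n), function(i) {
      c(rnorm(32, 5, 1) + s * shift_psd,
        pmin(pmax(rnorm(496, 0.3, 0.05) + s * shift_plv, 0), 1))
    }, numeric(528)))
  }
  list(x = rbind(mk(n_per_class, 0), mk(n_per_class, 1)),
       y = rep(0:1, each = n_per_class))
}

# small planted-effect cohort shared by several tests (cached per session)
planted_cohort <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    spec <- cohort_spec(
      groups = c(HC = 6, PD = 6), fs = 128, duration_s = 30,
      band_power_effects = list(PD = list(gamma = list(channels = "Cz",
                                                       factor = 2))),
      plv_effects = list(PD = list(beta = list(pairs = rbind(c("C3", "C4")),
                                               kappa = 50))),
      seed = 101)
    recs <- generate_cohort(spec)
    eps <- lapply(recs, segment_epochs, epoch_length_s = 1)
    cache <<- list(
      spec = spec, eps = eps,
      psd = lapply(eps, compute_psd, bands = eeg_bands(c("beta", "gamma"))),
      plv = lapply(eps, compute_plv, bands = eeg_bands(c("beta", "gamma"))))
    cache
  }
})
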