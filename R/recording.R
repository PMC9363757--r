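#' Construct a continuous EEG recording
#'
#' A recording is one subject's continuous multi-channel EEG: a channels x
#' samples matrix in microvolts plus sampling rate, channel labels, subject id
#' and group label.
#'
#' @param data Numeric matrix, channels x samples, in microvolts.
#' @param fs Sampling rate in Hz (positive).
#' @param channels Character vector of unique channel labels, one per row.
#' @param subject_id Subject identifier.
#' @param group Group label, one of `"HC"`, `"PD"`, `"PD_OFF"`, `"PD_ON"`,
#'   or `NA` when unknown.
#' @return An `eeg_recording` object.
#' @export
eeg_recording <- function(data, fs, channels, subject_id = "anon", group = NA_character_) {
  if (!is.matrix(data) || !is.numeric(data)) {
    .mp_validation_error("data must be a numeric channels x samples matrix")
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    .mp_validation_error("fs must be a positive scalar, got ", fs)
  }
  channels <- as.character(channels)
  if (nrow(data) != length(channels)) {
    .mp_validation_error("data has ", nrow(data), " rows but ", length(channels),
                         " channel labels were given")
  }
  if (anyDuplicated(channels)) {
    .mp_validation_error("channel labels must be unique")
  }
  if (ncol(data) < 1L) .mp_validation_error("recording must contain at least 1 sample")
  if (!is.na(group)) group <- match.arg(group, c("HC", "PD", "PD_OFF", "PD_ON"))
  rownames(data) <- channels
  structure(
    list(subject_id = as.character(subject_id), group = group, fs = fs,
         channels = channels, data = data),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording %s [%s]: %d ch x %d samples @ %g Hz (%.1f s)>\n",
              x$subject_id, ifelse(is.na(x$group), "?", x$group),
              length(x$channels), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec An `eeg_recording`.
#' @return Length in seconds.
#' @export
recording_duration <- function(rec) ncol(rec$data) / rec$fs

#' The 32-channel montage shared by the supported acquisition systems
#'
#' Target channel order used for all feature matrices, with the standard
#' imputation rule for a missing Pz channel (mean of its four neighbours
#' P1, P2, CPz and POz).
#'
#' @param target_channels Ordered character vector of target labels
#'   (default: the canonical 32).
#' @param imputation_rules Named list mapping a missing label to the donor
#'   labels whose mean trace replaces it.
#' @return A `montage_spec` object.
#' @export
montage_spec <- function(target_channels = montage32_channels(),
                         imputation_rules = list(Pz = c("P1", "P2", "CPz", "POz"))) {
  target_channels <- as.character(target_channels)
  if (anyDuplicated(target_channels)) {
    .mp_validation_error("montage target channels must be unique")
  }
  structure(list(target_channels = target_channels,
                 imputation_rules = imputation_rules),
            class = "montage_spec")
}

#' @rdname montage_spec
#' @export
montage32_channels <- function() {
  c("Fp1", "AF3", "F7", "F3", "FC1", "FC5", "T7", "C3", "CP1", "CP5",
    "P7", "P3", "Pz", "PO3", "O1", "Oz", "O2", "PO4", "P4", "P8",
    "CP6", "CP2", "C4", "T8", "FC6", "FC2", "F4", "F8", "AF4", "Fp2",
    "Fz", "Cz")
}

#' Reduce a recording to a target montage, imputing missing channels
#'
#' Channels are reordered to the montage's target order. A target channel
#' absent from the recording is reconstructed as the arithmetic mean of its
#' donor channels (e.g. Pz from P1, P2, CPz, POz) when an imputation rule is
#' available and all donors are present.
#'
#' @param rec An `eeg_recording`.
#' @param spec A `montage_spec` (default: the canonical 32-channel montage).
#' @return An `eeg_recording` with exactly the target channels, in order.
#' @export
harmonize_montage <- function(rec, spec = montage_spec()) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(spec, "montage_spec"))
  out <- matrix(0, length(spec$target_channels), ncol(rec$data))
  for (i in seq_along(spec$target_channels)) {
    ch <- spec$target_channels[i]
    if (ch %in% rec$channels) {
      out[i, ] <- rec$data[ch, ]
    } else {
      donors <- spec$imputation_rules[[ch]]
      if (is.null(donors)) {
        .mp_validation_error("channel ", ch,
                             " is missing and has no imputation rule")
      }
      absent <- setdiff(donors, rec$channels)
      if (length(absent)) {
        .mp_validation_error("channel ", ch, " is missing and donor(s) ",
                             paste(absent, collapse = ", "),
                             " are absent from the recording")
      }
      out[i, ] <- colMeans(rec$data[donors, , drop = FALSE])
    }
  }
  eeg_recording(out, rec$fs, spec$target_channels, rec$subject_id, rec$group)
}

#' Keep only the first seconds of a recording
#'
#' @param rec An `eeg_recording`.
#' @param duration_s Seconds to retain from the start.
#' @return The truncated `eeg_recording`.
#' @export
truncate_recording <- function(rec, duration_s) {
  stopifnot(inherits(rec, "eeg_recording"))
  avail <- recording_duration(rec)
  if (duration_s <= 0) .mp_validation_error("duration_s must be positive")
  n <- round(duration_s * rec$fs)
  if (n > ncol(rec$data)) {
    .mp_validation_error("recording is only ", format(avail),
                         " s long, cannot truncate to ", duration_s, " s")
  }
  eeg_recording(rec$data[, seq_len(n), drop = FALSE], rec$fs, rec$channels,
                rec$subject_id, rec$group)
}

#' Cut a recording into fixed-length non-overlapping epochs
#'
#' The continuous signal is split into consecutive epochs of
#' `epoch_length_s` seconds ("time samples"); a trailing remainder shorter
#' than one epoch is discarded, so a 3-min 512 Hz recording yields 180 epochs
#' of 512 samples and a 2-min 500 Hz recording yields 120 epochs of 500
#' samples.
#'
#' @param rec An `eeg_recording`.
#' @param epoch_length_s Epoch length in seconds (default 1).
#' @return An `eeg_epochs` object with an epochs x channels x samples array.
#' @export
segment_epochs <- function(rec, epoch_length_s = 1) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!is.numeric(epoch_length_s) || epoch_length_s <= 0) {
    .mp_validation_error("epoch_length_s must be positive")
  }
  spe <- round(rec$fs * epoch_length_s)
  n_ep <- floor(ncol(rec$data) / spe)
  if (n_ep < 1L) {
    .mp_validation_error("recording shorter than one epoch (",
                         ncol(rec$data), " < ", spe, " samples)")
  }
  used <- rec$data[, seq_len(n_ep * spe), drop = FALSE]
  # (channels, samples*epochs) -> (epochs, channels, samples)
  arr <- array(used, dim = c(length(rec$channels), spe, n_ep))
  epochs <- aperm(arr, c(3L, 1L, 2L))
  eeg_epochs(epochs, rec$fs, rec$channels, epoch_length_s,
             rec$subject_id, rec$group)
}

#' Construct an epoched recording
#'
#' @param epochs Numeric array, epochs x channels x samples_per_epoch.
#' @param fs Sampling rate in Hz.
#' @param channels Channel labels.
#' @param epoch_length_s Epoch length in seconds.
#' @param subject_id,group As in [eeg_recording()].
#' @return An `eeg_epochs` object.
#' @export
eeg_epochs <- function(epochs, fs, channels, epoch_length_s,
                       subject_id = "anon", group = NA_character_) {
  if (!is.array(epochs) || length(dim(epochs)) != 3L) {
    .mp_validation_error("epochs must be a 3-d array (epoch x channel x sample)")
  }
  channels <- as.character(channels)
  if (dim(epochs)[2] != length(channels)) {
    .mp_validation_error("epoch array has ", dim(epochs)[2],
                         " channels but ", length(channels), " labels")
  }
  spe <- round(fs * epoch_length_s)
  if (dim(epochs)[3] != spe) {
    .mp_validation_error("samples per epoch (", dim(epochs)[3],
                         ") != round(fs * epoch_length_s) = ", spe)
  }
  structure(
    list(subject_id = as.character(subject_id), group = group, fs = fs,
         channels = channels, epochs = epochs, epoch_length_s = epoch_length_s),
    class = "eeg_epochs"
  )
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$epochs)
  cat(sprintf("<eeg_epochs %s [%s]: %d epochs x %d ch x %d samples @ %g Hz>\n",
              x$subject_id, ifelse(is.na(x$group), "?", x$group),
              d[1], d[2], d[3], x$fs))
  invisible(x)
}

#' Standard preprocessing chain for one recording
#'
#' Band-pass filter, montage harmonisation, truncation and epoching in the
#' conventional order. Artifact removal (ICA) is not performed; recordings are
#' assumed clean, and a custom cleaning step can be injected through `hook`.
#'
#' @param rec An `eeg_recording`.
#' @param band Numeric length-2 vector, band-pass edges in Hz.
#' @param montage A `montage_spec`, or `NULL` to keep channels as they are.
#' @param duration_s Seconds to keep, or `NULL` for the whole recording.
#' @param epoch_length_s Epoch length in seconds.
#' @param hook Optional function `eeg_recording -> eeg_recording` applied
#'   after filtering (artifact-removal slot).
#' @return An `eeg_epochs` object.
#' @export
preprocess_recording <- function(rec, band = c(0.5, 50), montage = montage_spec(),
                                 duration_s = NULL, epoch_length_s = 1,
                                 hook = NULL) {
  rec <- bandpass_filter(rec, band[1], band[2])
  if (!is.null(hook)) {
    rec <- hook(rec)
    if (!inherits(rec, "eeg_recording")) {
      .mp_validation_error("preprocessing hook must return an eeg_recording")
    }
  }
  if (!is.null(montage)) rec <- harmonize_montage(rec, montage)
  if (!is.null(duration_s)) rec <- truncate_recording(rec, duration_s)
  segment_epochs(rec, epoch_length_s)
}
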