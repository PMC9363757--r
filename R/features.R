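# Multi-pattern feature extraction: per-epoch band power (activation
# pattern) and per-epoch phase-locking values over channel pairs
# (connectivity pattern).

#' Canonical unordered channel-pair index
#'
#' All distinct unordered channel pairs in montage order (496 pairs for 32
#' channels), named `"ChA-ChB"` with A before B.
#'
#' @param channels Character vector of channel labels.
#' @return data.frame with columns `i`, `j` (indices, i < j) and `name`.
#' @export
channel_pairs <- function(channels) {
  idx <- utils::combn(length(channels), 2)
  data.frame(i = idx[1, ], j = idx[2, ],
             name = paste0(channels[idx[1, ]], "-", channels[idx[2, ]]),
             stringsAsFactors = FALSE)
}

# one-sided periodogram of every column: rows = frequency bins 0..floor(n/2)
.periodogram_cols <- function(x, fs) {
  n <- nrow(x)
  X <- mvfft(x)
  nk <- floor(n / 2) + 1
  P <- (Mod(X[seq_len(nk), , drop = FALSE])^2) / (fs * n)
  dbl <- 2:(nk - 1 + (n %% 2))   # interior bins carry both spectrum halves
  if (n > 2) P[dbl, ] <- 2 * P[dbl, ]
  P
}

#' Band power features from an epoched recording
#'
#' For each epoch and channel the one-sided periodogram (squared DFT
#' magnitude scaled by `1/(fs * n)`) is summed over the DFT bins falling in
#' each band's half-open interval `[low_hz, high_hz)`, so adjacent bands
#' never share a bin.
#'
#' @param ep An `eeg_epochs` object.
#' @param bands List of [band_definition()]s (default: all five canonical
#'   bands).
#' @return A `psd_features` object: `values` is an epoch x channel x band
#'   array of non-negative band powers.
#' @export
compute_psd <- function(ep, bands = eeg_bands()) {
  stopifnot(inherits(ep, "eeg_epochs"))
  bands <- as_band_list(bands)
  d <- dim(ep$epochs)
  n <- d[3]
  freqs <- (seq_len(floor(n / 2) + 1) - 1) * ep$fs / n
  sel <- lapply(bands, function(b) {
    s <- which(freqs >= b$low_hz & freqs < b$high_hz)
    if (!length(s)) {
      .mp_validation_error("band ", b$name, " (", b$low_hz, "-", b$high_hz,
                           " Hz) contains no DFT bin at epoch length ",
                           ep$epoch_length_s, " s")
    }
    s
  })
  x <- matrix(aperm(ep$epochs, c(3L, 1L, 2L)), nrow = n)  # cols: epoch x ch
  P <- .periodogram_cols(x, ep$fs)
  vals <- array(0, dim = c(d[1], d[2], length(bands)),
                dimnames = list(NULL, ep$channels, band_names(bands)))
  for (k in seq_along(bands)) {
    bp <- colSums(P[sel[[k]], , drop = FALSE])
    vals[, , k] <- matrix(bp, d[1], d[2])
  }
  structure(
    list(subject_id = ep$subject_id, group = ep$group, values = vals,
         band_defs = bands, channels = ep$channels),
    class = "psd_features"
  )
}

#' Total periodogram power in a frequency range
#'
#' Companion to [compute_psd()] for Parseval-style checks: the summed
#' one-sided periodogram over all DFT bins in `[low_hz, high_hz)`.
#'
#' @param ep An `eeg_epochs` object.
#' @param low_hz,high_hz Range in Hz.
#' @return epoch x channel matrix of total power.
#' @export
total_band_power <- function(ep, low_hz, high_hz) {
  d <- dim(ep$epochs)
  n <- d[3]
  freqs <- (seq_len(floor(n / 2) + 1) - 1) * ep$fs / n
  sel <- which(freqs >= low_hz & freqs < high_hz)
  x <- matrix(aperm(ep$epochs, c(3L, 1L, 2L)), nrow = n)
  P <- .periodogram_cols(x, ep$fs)
  matrix(colSums(P[sel, , drop = FALSE]), d[1], d[2])
}

#' Phase-locking value features from an epoched recording
#'
#' Each band is isolated with a zero-phase Hamming-window FIR filter, the
#' instantaneous phase is taken from the Hilbert analytic signal, and for
#' every unordered channel pair (A, B) the phase-locking value
#' `|mean(exp(-1i * (phi_A - phi_B)))|` is computed over the epoch's time
#' points. A fraction of samples at each epoch edge is excluded from the mean
#' to avoid Hilbert/FIR edge artifacts.
#'
#' @param ep An `eeg_epochs` object.
#' @param bands List of [band_definition()]s.
#' @param edge_trim Fraction of the epoch trimmed from each side before
#'   averaging (default 0.1).
#' @param average `"within_epoch"` (default: one PLV per epoch, the PLV time
#'   series reading) or `"across_epochs"` (phase differences averaged across
#'   epochs at matched time points, then the modulus averaged over time,
#'   giving a single value per pair and band).
#' @return A `plv_features` object: `values` is an epoch x pair x band array
#'   in [0, 1]; `pair_index` gives the canonical pair order.
#' @export
compute_plv <- function(ep, bands = eeg_bands(), edge_trim = 0.1,
                        average = c("within_epoch", "across_epochs")) {
  stopifnot(inherits(ep, "eeg_epochs"))
  average <- match.arg(average)
  bands <- as_band_list(bands)
  if (edge_trim < 0 || edge_trim >= 0.5) {
    .mp_validation_error("edge_trim must be in [0, 0.5)")
  }
  d <- dim(ep$epochs)
  n_ep <- d[1]; n_ch <- d[2]; n <- d[3]
  pairs <- channel_pairs(ep$channels)
  trim <- floor(n * edge_trim)
  keep <- seq(trim + 1, n - trim)
  pick <- cbind(pairs$i, pairs$j)
  n_out <- if (average == "within_epoch") n_ep else 1L
  vals <- array(NA_real_, dim = c(n_out, nrow(pairs), length(bands)),
                dimnames = list(NULL, pairs$name, band_names(bands)))
  for (k in seq_along(bands)) {
    filt <- fir_bandpass(ep, bands[[k]])
    x <- matrix(aperm(filt$epochs, c(3L, 1L, 2L)), nrow = n)
    ph <- Arg(.analytic_cols(x))                    # n x (epoch*channel)
    Z <- exp(1i * ph[keep, , drop = FALSE])
    Za <- array(Z, dim = c(length(keep), n_ep, n_ch))
    if (average == "within_epoch") {
      for (e in seq_len(n_ep)) {
        Ze <- t(Za[, e, ])                          # channels x time
        G <- Mod(Ze %*% Conj(t(Ze))) / length(keep)
        vals[e, , k] <- G[pick]
      }
    } else {
      # mean over epochs of exp(i dphi) at each time point, modulus then
      # averaged over time
      acc <- matrix(0, nrow(pairs), length(keep))
      for (e in seq_len(n_ep)) {
        Ze <- t(Za[, e, ])
        D <- Ze[pairs$i, , drop = FALSE] * Conj(Ze[pairs$j, , drop = FALSE])
        acc <- acc + D
      }
      vals[1, , k] <- rowMeans(Mod(acc / n_ep))
    }
  }
  vals[vals > 1] <- 1   # guard against rounding just above 1
  structure(
    list(subject_id = ep$subject_id, group = ep$group, values = vals,
         band_defs = bands, channels = ep$channels, pair_index = pairs,
         edge_trim = edge_trim, average = average),
    class = "plv_features"
  )
}

#' @export
print.psd_features <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<psd_features %s [%s]: %d epochs x %d channels x %d bands>\n",
              x$subject_id, ifelse(is.na(x$group), "?", x$group), d[1], d[2], d[3]))
  invisible(x)
}

#' @export
print.plv_features <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<plv_features %s [%s]: %d epochs x %d pairs x %d bands>\n",
              x$subject_id, ifelse(is.na(x$group), "?", x$group), d[1], d[2], d[3]))
  invisible(x)
}

#' Fisher-transformed mean of phase-locking values
#'
#' Group averaging of PLVs is performed in the Fisher (arctanh) domain:
#' `tanh(mean(atanh(values)))`. Values equal to 1 are clipped to
#' `1 - 1e-10` before the transform.
#'
#' @param values Numeric vector of PLVs in [0, 1].
#' @return The Fisher-domain mean, in [0, 1).
#' @export
fisher_mean_plv <- function(values) {
  values <- as.numeric(values)
  if (!length(values)) .mp_validation_error("fisher_mean_plv: empty input")
  if (any(!is.finite(values)) || any(values < 0) || any(values > 1)) {
    .mp_validation_error("fisher_mean_plv: values must lie in [0, 1]")
  }
  values <- pmin(values, 1 - 1e-10)
  tanh(mean(atanh(values)))
}

#' Flatten feature objects to a tabular form
#'
#' One row per epoch; columns are per-channel (PSD) or per-pair (PLV)
#' features of one band, prefixed by subject/group metadata. This is the
#' layout written to the on-disk feature store.
#'
#' @param feat A `psd_features` or `plv_features` object.
#' @param band Band name to extract.
#' @return data.frame with `subject_id`, `group`, `epoch`, then features.
#' @export
feature_table <- function(feat, band) {
  bn <- band_names(feat$band_defs)
  k <- match(band, bn)
  if (is.na(k)) .mp_validation_error("band ", band, " not present (have: ",
                                     paste(bn, collapse = ", "), ")")
  m <- feat$values[, , k, drop = FALSE]
  dim(m) <- dim(feat$values)[1:2]
  colnames(m) <- if (inherits(feat, "psd_features")) feat$channels else feat$pair_index$name
  data.frame(subject_id = feat$subject_id,
             group = ifelse(is.na(feat$group), "", feat$group),
             epoch = seq_len(nrow(m)), m, check.names = FALSE,
             stringsAsFactors = FALSE)
}
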