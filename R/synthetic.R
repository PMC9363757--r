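# Synthetic resting-state EEG cohorts with planted, group-conditional band
# power and phase-locking structure. Each channel is 1/f background noise
# plus one narrow-band Gaussian oscillator per band; phase coupling between
# channels is planted by sharing a band oscillator whose per-channel,
# per-block phase offsets are von Mises distributed with concentration
# kappa (kappa = 0 plants nothing: channels stay fully independent, the
# correct independent-phase null; kappa -> Inf drives PLV -> 1).

#' Specify a synthetic EEG cohort
#'
#' @param groups Named integer vector: subjects per group, e.g.
#'   `c(HC = 16, PD = 15)`. The first group is the reference for planted
#'   effects.
#' @param fs Sampling rate in Hz (default 512).
#' @param duration_s Recording length in seconds (default 180).
#' @param channels Channel labels (default: canonical 32).
#' @param background 1/f background: list with `exponent` (spectral slope,
#'   default 1) and `rms_uv` (total RMS amplitude, default 10 microvolts).
#' @param band_amplitudes Named vector of per-band oscillator amplitudes
#'   relative to the square root of the total 1--48 Hz background power
#'   (alpha ~ 1 reproduces the resting-EEG character of an alpha rhythm as
#'   strong as the whole broadband background).
#' @param band_power_effects List: `group -> band -> list(channels, factor)`;
#'   the named channels' oscillator power is multiplied by `factor` in that
#'   group.
#' @param plv_effects List: `group -> band -> list(pairs, kappa)`; `pairs`
#'   is a 2-column matrix (or list of length-2 vectors) of channel labels
#'   that share a band oscillator with von Mises phase jitter of
#'   concentration `kappa`.
#' @param jitter_block_s Length of the constant-phase jitter blocks in
#'   seconds (default 0.125).
#' @param subject_gain_sd SD of the per-subject log-normal overall gain
#'   (default 0.1, i.e. ~10% inter-subject amplitude variability).
#' @param seed Base RNG seed; the cohort is bit-reproducible given the spec.
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(groups = c(HC = 16, PD = 15), fs = 512,
                        duration_s = 180, channels = montage32_channels(),
                        background = list(exponent = 1, rms_uv = 10),
                        band_amplitudes = c(delta = 1, theta = 1, alpha = 1.2,
                                            beta = 0.9, gamma = 0.8),
                        band_power_effects = list(), plv_effects = list(),
                        jitter_block_s = 0.125, subject_gain_sd = 0.1,
                        seed = 1) {
  if (!length(groups) || is.null(names(groups)) || any(groups < 1)) {
    .mp_validation_error("groups must be a non-empty named vector of counts")
  }
  for (g in names(band_power_effects)) {
    for (b in names(band_power_effects[[g]])) {
      eff <- band_power_effects[[g]][[b]]
      if (is.null(eff$factor) || eff$factor <= 0) {
        .mp_validation_error("band power factor must be > 0 (", g, "/", b, ")")
      }
      bad <- setdiff(eff$channels, channels)
      if (length(bad)) .mp_validation_error("unknown effect channel(s): ",
                                            paste(bad, collapse = ", "))
    }
  }
  for (g in names(plv_effects)) {
    for (b in names(plv_effects[[g]])) {
      eff <- plv_effects[[g]][[b]]
      if (is.null(eff$kappa) || eff$kappa < 0) {
        .mp_validation_error("kappa must be >= 0 (", g, "/", b, ")")
      }
    }
  }
  structure(list(groups = groups, fs = fs, duration_s = duration_s,
                 channels = channels, background = background,
                 band_amplitudes = band_amplitudes,
                 band_power_effects = band_power_effects,
                 plv_effects = plv_effects, jitter_block_s = jitter_block_s,
                 subject_gain_sd = subject_gain_sd, seed = seed),
            class = "cohort_spec")
}

#' Sample from the von Mises distribution
#'
#' Best-Fisher (1979) rejection sampler; `kappa = 0` gives the uniform
#' circular distribution.
#'
#' @param n Number of draws.
#' @param kappa Concentration (>= 0).
#' @return Angles in (-pi, pi].
#' @export
rvonmises <- function(n, kappa) {
  if (kappa < 1e-8) return(runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
      out[i] <- sign(u[3] - 0.5) * acos(pmin(pmax(f, -1), 1))
      i <- i + 1L
    }
  }
  out
}

#' Expected phase-locking value planted by a von Mises coupling
#'
#' Two channels sharing an oscillator with independent von Mises phase
#' jitters of concentration `kappa` lock with expected PLV equal to the
#' squared mean resultant length `(I1(kappa)/I0(kappa))^2` (plus the finite-
#' sample Rayleigh floor near zero).
#'
#' @param kappa Concentration (>= 0).
#' @return Expected asymptotic PLV in [0, 1).
#' @export
plv_from_kappa <- function(kappa) {
  if (kappa <= 0) return(0)
  (besselI(kappa, 1) / besselI(kappa, 0))^2
}

# fractional background power profile over DFT bins; returns function of
# frequency vector giving squared-amplitude weights
.bg_profile <- function(exponent) {
  function(f) ifelse(f <= 0, 0, pmax(f, 0.5)^(-exponent))
}

# expected background power (uV^2) inside [lo, hi) given total rms
.bg_band_power <- function(spec, lo, hi) {
  n <- round(spec$fs * spec$duration_s)
  f <- seq(0, spec$fs / 2, by = spec$fs / n)
  w <- .bg_profile(spec$background$exponent)(f)
  spec$background$rms_uv^2 * sum(w[f >= lo & f < hi]) / sum(w)
}

# complex analytic narrow-band Gaussian oscillator, unit mean-square of the
# real part, band [lo, hi) with 10% cosine edge taper
.narrowband_analytic <- function(n, fs, lo, hi) {
  f <- (seq_len(n) - 1) * fs / n
  sel <- which(f >= lo & f < hi & f <= fs / 2)
  amp <- numeric(n)
  amp[sel] <- 1
  tw <- max(2, round(0.1 * length(sel)))
  ramp <- 0.5 * (1 - cos(pi * seq_len(tw) / (tw + 1)))
  amp[sel[seq_len(tw)]] <- ramp
  amp[sel[length(sel) + 1 - seq_len(tw)]] <- rev(ramp)
  spec_c <- complex(real = rnorm(n), imaginary = rnorm(n)) * amp
  z <- fft(spec_c, inverse = TRUE) / sqrt(n)
  z / sqrt(mean(Re(z)^2))
}

# piecewise-constant von Mises phase jitter as exp(i * theta(t))
.jitter_phasor <- function(n, fs, block_s, kappa) {
  n_block <- ceiling(n / max(1, round(fs * block_s)))
  theta <- rvonmises(n_block, kappa)
  exp(1i * rep(theta, each = round(fs * block_s))[seq_len(n)])
}

#' Generate a synthetic EEG cohort
#'
#' Every channel is the sum of 1/f background noise and one narrow-band
#' oscillator per canonical band; planted effects scale a group's oscillator
#' power on selected channels and/or couple selected channel pairs through a
#' shared oscillator with von Mises phase jitter (see [cohort_spec()]).
#' Fully reproducible from the spec's seed.
#'
#' @param spec A `cohort_spec`.
#' @return List of `eeg_recording` objects with group labels and subject ids
#'   like `"HC01"`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- round(spec$fs * spec$duration_s)
  bands <- eeg_bands(names(spec$band_amplitudes))
  n_ch <- length(spec$channels)
  bg_w <- .bg_profile(spec$background$exponent)
  p_bg148 <- .bg_band_power(spec, 1, 48)
  f_full <- (seq_len(n) - 1) * spec$fs / n
  # background spectral amplitude over the full (two-sided) grid
  f_mirror <- pmin(f_full, spec$fs - f_full)
  bg_amp <- sqrt(bg_w(f_mirror))
  recordings <- list()
  subj_counter <- 0L
  for (g in names(spec$groups)) {
    for (s in seq_len(spec$groups[[g]])) {
      subj_counter <- subj_counter + 1L
      set.seed((spec$seed * 1009L + subj_counter * 7919L) %% 2147483629L)
      gain <- exp(rnorm(1, 0, spec$subject_gain_sd))
      # which channels are coupled, per band (their in-band background is
      # absorbed into the shared oscillator so the planted phase locking is
      # not diluted by independent in-band noise; total band power is kept)
      coupled_by_band <- lapply(bands, function(b) {
        cpl <- spec$plv_effects[[g]][[b$name]]
        if (is.null(cpl) || cpl$kappa <= 0) return(integer(0))
        prs <- cpl$pairs
        if (is.list(prs)) prs <- do.call(rbind, prs)
        m <- match(unique(as.vector(prs)), spec$channels)
        if (anyNA(m)) .mp_validation_error("unknown coupled channel")
        m
      })
      names(coupled_by_band) <- band_names(bands)
      data <- matrix(0, n_ch, n)
      p_absorbed <- matrix(0, n_ch, length(bands))
      # 1/f background, independent per channel
      for (c in seq_len(n_ch)) {
        spec_c <- complex(real = rnorm(n), imaginary = rnorm(n)) * bg_amp
        x <- Re(fft(spec_c, inverse = TRUE)) / sqrt(n)
        scl <- spec$background$rms_uv / sqrt(mean(x^2))
        x <- x * scl
        for (k in seq_along(bands)) {
          if (!(c %in% coupled_by_band[[k]])) next
          b <- bands[[k]]
          in_band <- (f_full >= b$low_hz & f_full < b$high_hz) |
            (spec$fs - f_full >= b$low_hz & spec$fs - f_full < b$high_hz)
          xb <- Re(fft(spec_c * in_band, inverse = TRUE)) / sqrt(n) * scl
          x <- x - xb
          p_absorbed[c, k] <- mean(xb^2)
        }
        data[c, ] <- x
      }
      # per-band oscillators with planted power and coupling
      for (k in seq_along(bands)) {
        b <- bands[[k]]
        amp2 <- spec$band_amplitudes[[b$name]]^2 * p_bg148
        pw <- rep(amp2, n_ch)
        eff <- spec$band_power_effects[[g]][[b$name]]
        if (!is.null(eff)) {
          pw[match(eff$channels, spec$channels)] <- amp2 * eff$factor
        }
        coupled <- coupled_by_band[[k]]
        if (length(coupled)) {
          cpl <- spec$plv_effects[[g]][[b$name]]
          z <- .narrowband_analytic(n, spec$fs, b$low_hz, b$high_hz)
          for (c in coupled) {
            ph <- .jitter_phasor(n, spec$fs, spec$jitter_block_s, cpl$kappa)
            data[c, ] <- data[c, ] + sqrt(pw[c] + p_absorbed[c, k]) * Re(z * ph)
          }
        }
        for (c in setdiff(seq_len(n_ch), coupled)) {
          z <- .narrowband_analytic(n, spec$fs, b$low_hz, b$high_hz)
          data[c, ] <- data[c, ] + sqrt(pw[c]) * Re(z)
        }
      }
      rec <- eeg_recording(data * gain, spec$fs, spec$channels,
                           subject_id = sprintf("%s%02d", g, s),
                           group = g)
      recordings[[length(recordings) + 1L]] <- rec
    }
  }
  recordings
}

# expected observed PSD ratio for a planted power factor, accounting for the
# in-band background that the factor does not touch
.expected_psd_ratio <- function(spec, band, factor) {
  p_osc <- spec$band_amplitudes[[band$name]]^2 * .bg_band_power(spec, 1, 48)
  p_bg <- .bg_band_power(spec, band$low_hz, band$high_hz)
  (factor * p_osc + p_bg) / (p_osc + p_bg)
}

#' Planted-versus-recovered effect report for a synthetic cohort
#'
#' Compares each non-reference group against the reference (first) group,
#' per band and unit: PSD ratios per channel and PLV differences per pair,
#' with normal-theory confidence intervals, t-test p-values and a
#' Benjamini-Hochberg flag, next to the generator-level expectation for the
#' planted units.
#'
#' @param spec The `cohort_spec` the cohort was generated from.
#' @param psd List of `psd_features` (one per subject).
#' @param plv List of `plv_features` (one per subject), or `NULL` to skip
#'   connectivity recovery.
#' @param alpha Flagging level after BH adjustment (default 0.05).
#' @param conf_level Confidence level for the intervals (default 0.95).
#' @return data.frame: `mode`, `band`, `unit`, `planted`, `expected`,
#'   `observed`, `ci_lo`, `ci_hi`, `p_value`, `flagged`.
#' @export
planted_effect_report <- function(spec, psd, plv = NULL, alpha = 0.05,
                                  conf_level = 0.95) {
  stopifnot(inherits(spec, "cohort_spec"))
  grp_of <- vapply(psd, `[[`, character(1), "group")
  if (!setequal(unique(grp_of), names(spec$groups))) {
    .mp_validation_error("features' groups do not match the cohort spec")
  }
  if (!identical(psd[[1]]$channels, spec$channels)) {
    .mp_validation_error("features' channels do not match the cohort spec")
  }
  ref <- names(spec$groups)[1]
  others <- setdiff(names(spec$groups), ref)
  rows <- list()
  psd_bands <- band_names(psd[[1]]$band_defs)
  plv_bands <- if (!is.null(plv)) band_names(plv[[1]]$band_defs) else character(0)
  for (g in others) {
    for (b in eeg_bands(intersect(names(spec$band_amplitudes),
                                  union(psd_bands, plv_bands)))) {
      # ---- PSD: per-channel ratio g / ref --------------------------------
      # the subject is the sampling unit: per-subject mean band powers feed
      # the ratio, its log-scale CI and the t-test, so between-subject
      # amplitude variability is part of the error term
      if (!b$name %in% psd_bands) next
      A <- .subject_means(psd[grp_of == g], b$name)
      B <- .subject_means(psd[grp_of == ref], b$name)
      mA <- colMeans(A); mB <- colMeans(B)
      vA <- apply(A, 2, var); vB <- apply(B, 2, var)
      ratio <- mA / mB
      se_log <- sqrt(vA / (nrow(A) * mA^2) + vB / (nrow(B) * mB^2))
      zq <- stats::qt(1 - (1 - conf_level) / 2, nrow(A) + nrow(B) - 2)
      cm <- group_contrast(psd[grp_of == g], psd[grp_of == ref], b$name,
                           observation = "subject")
      eff <- spec$band_power_effects[[g]][[b$name]]
      planted <- spec$channels %in% (if (is.null(eff)) character(0) else eff$channels)
      expected <- ifelse(planted, .expected_psd_ratio(spec, b, eff$factor %||% 1), 1)
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, mode = "PSD", band = b$name, unit = spec$channels,
        planted = planted, expected = expected, observed = ratio,
        ci_lo = exp(log(ratio) - zq * se_log),
        ci_hi = exp(log(ratio) + zq * se_log),
        p_value = cm$p_value, stringsAsFactors = FALSE)
      # ---- PLV: per-pair difference g - ref ------------------------------
      if (!is.null(plv) && b$name %in% plv_bands) {
        pg <- vapply(plv, `[[`, character(1), "group")
        Ap <- .subject_means(plv[pg == g], b$name)
        Bp <- .subject_means(plv[pg == ref], b$name)
        dm <- colMeans(Ap) - colMeans(Bp)
        se <- sqrt(apply(Ap, 2, var) / nrow(Ap) + apply(Bp, 2, var) / nrow(Bp))
        zq <- stats::qt(1 - (1 - conf_level) / 2, nrow(Ap) + nrow(Bp) - 2)
        cmp_ <- group_contrast(plv[pg == g], plv[pg == ref], b$name,
                               observation = "subject")
        pidx <- plv[[1]]$pair_index
        cpl <- spec$plv_effects[[g]][[b$name]]
        planted_p <- rep(FALSE, nrow(pidx))
        exp_d <- rep(0, nrow(pidx))
        if (!is.null(cpl)) {
          prs <- cpl$pairs
          if (is.list(prs)) prs <- do.call(rbind, prs)
          nm1 <- paste0(prs[, 1], "-", prs[, 2])
          nm2 <- paste0(prs[, 2], "-", prs[, 1])
          planted_p <- pidx$name %in% c(nm1, nm2)
          exp_d[planted_p] <- plv_from_kappa(cpl$kappa) - mean(colMeans(Bp))
        }
        rows[[length(rows) + 1L]] <- data.frame(
          group = g, mode = "PLV", band = b$name, unit = pidx$name,
          planted = planted_p, expected = exp_d, observed = dm,
          ci_lo = dm - zq * se, ci_hi = dm + zq * se,
          p_value = cmp_$p_value, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  out$flagged <- stats::ave(out$p_value, out$group, out$mode, out$band,
                            FUN = function(p) p.adjust(p, "BH")) <= alpha
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
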