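#' Canonical EEG frequency bands
#'
#' The five classical resting-state EEG bands used throughout the package:
#' delta 1--4 Hz, theta 4--8 Hz, alpha 8--12 Hz, beta 13--30 Hz and
#' gamma 30--48 Hz.
#'
#' @param names Character vector of band names to return (subset of
#'   `c("delta", "theta", "alpha", "beta", "gamma")`), or `"all"`.
#' @return A list of band definitions, each a list with `name`, `low_hz`,
#'   `high_hz`.
#' @export
#' @examples
#' eeg_bands("alpha")
#' eeg_bands()
eeg_bands <- function(names = "all") {
  canonical <- list(
    delta = band_definition("delta", 1, 4),
    theta = band_definition("theta", 4, 8),
    alpha = band_definition("alpha", 8, 12),
    beta  = band_definition("beta", 13, 30),
    gamma = band_definition("gamma", 30, 48)
  )
  names <- unlist(names)
  if (identical(names, "all")) return(unname(canonical))
  bad <- setdiff(names, names(canonical))
  if (length(bad)) {
    .mp_config_error("unknown band name(s): ", paste(bad, collapse = ", "))
  }
  unname(canonical[names])
}

#' Define a frequency band
#'
#' @param name Band label.
#' @param low_hz,high_hz Band edges in Hz, `0 < low_hz < high_hz`.
#' @return A `band_definition` object.
#' @export
band_definition <- function(name, low_hz, high_hz) {
  if (!is.character(name) || length(name) != 1L) {
    .mp_validation_error("band name must be a single string")
  }
  if (!(is.numeric(low_hz) && is.numeric(high_hz) &&
        low_hz > 0 && low_hz < high_hz)) {
    .mp_validation_error("band edges must satisfy 0 < low_hz < high_hz (",
                         name, ": ", low_hz, ", ", high_hz, ")")
  }
  structure(list(name = name, low_hz = low_hz, high_hz = high_hz),
            class = "band_definition")
}

#' @export
print.band_definition <- function(x, ...) {
  cat(sprintf("<band %s: %g-%g Hz>\n", x$name, x$low_hz, x$high_hz))
  invisible(x)
}

band_names <- function(bands) vapply(bands, `[[`, character(1), "name")

as_band_list <- function(bands) {
  if (inherits(bands, "band_definition")) return(list(bands))
  if (is.character(bands)) return(eeg_bands(bands))
  if (!is.list(bands) || !all(vapply(bands, inherits, logical(1), "band_definition"))) {
    .mp_validation_error("bands must be band_definition objects or band names")
  }
  bands
}
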