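# European Data Format (EDF) and BioSemi BDF readers/writers.
# EDF stores 16-bit and BDF 24-bit little-endian integers with per-signal
# linear physical scaling; headers are fixed-width ASCII. Implemented here
# because no EDF reader is available in the target R environment.

.ascii_field <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width, flag = " ")
}

.read_ascii <- function(con, width, n = 1) {
  raw <- readChar(con, rep(width, n), useBytes = TRUE)
  trimws(raw)
}

#' Write a recording as EDF or BDF
#'
#' One data record per second; the recording is zero-padded to a whole number
#' of seconds if needed. Physical scaling is chosen per channel to span the
#' data range.
#'
#' @param rec An `eeg_recording` (fs must be an integer).
#' @param path Output file path.
#' @param format `"EDF"` (16-bit) or `"BDF"` (24-bit BioSemi).
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path, format = c("EDF", "BDF")) {
  format <- match.arg(format)
  stopifnot(inherits(rec, "eeg_recording"))
  if (rec$fs != round(rec$fs)) {
    .mp_validation_error("EDF/BDF writer requires an integer sampling rate")
  }
  fs <- as.integer(rec$fs)
  ns <- length(rec$channels)
  n_total <- ncol(rec$data)
  n_rec <- ceiling(n_total / fs)
  data <- rec$data
  if (n_rec * fs > n_total) {
    data <- cbind(data, matrix(0, ns, n_rec * fs - n_total))
  }
  dig_max <- if (format == "EDF") 32767 else 8388607
  dig_min <- -dig_max
  phys_max <- apply(abs(data), 1, max)
  phys_max <- ifelse(phys_max <= 0, 1, phys_max)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr_bytes <- 256L + 256L * ns
  wrt <- function(x, w) writeChar(.ascii_field(x, w), con, eos = NULL, useBytes = TRUE)
  if (format == "BDF") {
    writeBin(as.raw(255), con)
    wrt("BIOSEMI", 7)
  } else {
    wrt("0", 8)
  }
  wrt(rec$subject_id, 80)
  wrt(ifelse(is.na(rec$group), "Startdate X", paste("Startdate X", rec$group)), 80)
  wrt("01.01.00", 8)
  wrt("00.00.00", 8)
  wrt(hdr_bytes, 8)
  wrt(if (format == "BDF") "24BIT" else "", 44)
  wrt(n_rec, 8)
  wrt("1", 8)                           # record duration: 1 s
  wrt(ns, 4)
  for (ch in rec$channels) wrt(ch, 16)
  for (i in seq_len(ns)) wrt("", 80)    # transducer
  for (i in seq_len(ns)) wrt("uV", 8)
  for (i in seq_len(ns)) wrt(formatC(-phys_max[i], digits = 6, format = "g"), 8)
  for (i in seq_len(ns)) wrt(formatC(phys_max[i], digits = 6, format = "g"), 8)
  for (i in seq_len(ns)) wrt(dig_min, 8)
  for (i in seq_len(ns)) wrt(dig_max, 8)
  for (i in seq_len(ns)) wrt("", 80)    # prefiltering
  for (i in seq_len(ns)) wrt(fs, 8)
  for (i in seq_len(ns)) wrt("", 32)
  # digital conversion
  gain <- dig_max / phys_max
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    for (i in seq_len(ns)) {
      dig <- as.integer(round(pmin(pmax(data[i, idx] * gain[i], dig_min), dig_max)))
      if (format == "EDF") {
        writeBin(dig, con, size = 2, endian = "little")
      } else {
        v <- dig + ifelse(dig < 0, 16777216L, 0L)
        bytes <- rbind(v %% 256L, (v %/% 256L) %% 256L, v %/% 65536L)
        writeBin(as.raw(bytes), con)
      }
    }
  }
  invisible(path)
}

.read_edf_bdf <- function(path, format) {
  if (!file.exists(path)) .mp_io_error("file does not exist: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 8)
  is_bdf <- magic[1] == as.raw(255) &&
    rawToChar(magic[2:8]) == "BIOSEMI"
  if (format == "BDF" && !is_bdf) {
    .mp_io_error("not a BDF file (BIOSEMI magic missing): ", path)
  }
  subject <- .read_ascii(con, 80)
  rec_field <- .read_ascii(con, 80)
  invisible(.read_ascii(con, 8))  # start date
  invisible(.read_ascii(con, 8))  # start time
  hdr_bytes <- suppressWarnings(as.integer(.read_ascii(con, 8)))
  invisible(.read_ascii(con, 44))
  n_rec <- suppressWarnings(as.integer(.read_ascii(con, 8)))
  dur <- suppressWarnings(as.numeric(.read_ascii(con, 8)))
  ns <- suppressWarnings(as.integer(.read_ascii(con, 4)))
  if (is.na(ns) || ns < 1 || is.na(n_rec) || is.na(dur) || dur <= 0) {
    .mp_io_error("corrupt EDF/BDF header in ", path)
  }
  labels <- .read_ascii(con, 16, ns)
  invisible(.read_ascii(con, 80, ns))
  invisible(.read_ascii(con, 8, ns))
  phys_min <- as.numeric(.read_ascii(con, 8, ns))
  phys_max <- as.numeric(.read_ascii(con, 8, ns))
  dig_min <- as.numeric(.read_ascii(con, 8, ns))
  dig_max <- as.numeric(.read_ascii(con, 8, ns))
  invisible(.read_ascii(con, 80, ns))
  spr <- as.integer(.read_ascii(con, 8, ns))
  invisible(.read_ascii(con, 32, ns))
  if (anyNA(c(phys_min, phys_max, dig_min, dig_max, spr))) {
    .mp_io_error("corrupt EDF/BDF signal header in ", path)
  }
  if (length(unique(spr)) != 1L) {
    .mp_io_error("mixed per-signal sampling rates are not supported: ", path)
  }
  spr <- spr[1]
  fs <- spr / dur
  bps <- if (is_bdf) 3L else 2L
  expect <- n_rec * ns * spr
  payload <- readBin(con, "raw", n = expect * bps)
  if (length(payload) < expect * bps) {
    .mp_io_error("truncated EDF/BDF payload in ", path, " (expected ",
                 expect * bps, " bytes, got ", length(payload), ")")
  }
  if (is_bdf) {
    m <- matrix(as.integer(payload), nrow = 3)
    dig <- m[1, ] + 256L * m[2, ] + 65536L * m[3, ]
    dig <- ifelse(dig >= 8388608, dig - 16777216, dig)
  } else {
    dig <- readBin(payload, "integer", n = expect, size = 2,
                   endian = "little", signed = TRUE)
  }
  # records x (signal-major blocks of spr samples)
  arr <- array(dig, dim = c(spr, ns, n_rec))
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  data <- matrix(0, ns, spr * n_rec)
  for (i in seq_len(ns)) {
    data[i, ] <- as.numeric(arr[, i, ]) * gain[i] +
      (phys_min[i] - dig_min[i] * gain[i])
  }
  group <- NA_character_
  m <- regmatches(rec_field, regexpr("(HC|PD_OFF|PD_ON|PD)$", rec_field))
  if (length(m)) group <- m
  eeg_recording(data, fs, make.unique(labels), subject_id = subject, group = group)
}
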