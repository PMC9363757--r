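# Minimal MAT-level-5 reader/writer, enough to load and save EEGLAB .set
# files (EEG struct with data/srate/nbchan/chanlocs, optionally a separate
# .fdt float payload). Only the subset of the MAT5 container actually used
# by EEGLAB exports is supported.

.MI_SIZES <- c(`1` = 1, `2` = 1, `3` = 2, `4` = 2, `5` = 4, `6` = 4,
               `7` = 4, `9` = 8, `12` = 8, `13` = 8, `16` = 1, `17` = 2)

.mat5_read_numeric <- function(raw, type, n) {
  switch(as.character(type),
    `1` = readBin(raw, "integer", n, size = 1, signed = TRUE, endian = "little"),
    `2` = as.integer(raw[seq_len(n)]),
    `3` = readBin(raw, "integer", n, size = 2, signed = TRUE, endian = "little"),
    `4` = readBin(raw, "integer", n, size = 2, signed = FALSE, endian = "little"),
    `5` = readBin(raw, "integer", n, size = 4, endian = "little"),
    `6` = {  # uint32 via double to avoid overflow
      v <- readBin(raw, "integer", n, size = 4, endian = "little")
      ifelse(v < 0, v + 4294967296, v)
    },
    `7` = readBin(raw, "numeric", n, size = 4, endian = "little"),
    `9` = readBin(raw, "numeric", n, size = 8, endian = "little"),
    `12` = , `13` = {  # (u)int64 via 4-byte halves, exact below 2^53
      v <- readBin(raw, "integer", 2 * n, size = 4, endian = "little")
      lo <- v[seq(1, 2 * n, 2)]; hi <- v[seq(2, 2 * n, 2)]
      ifelse(lo < 0, lo + 4294967296, lo) + 4294967296 * hi
    },
    .mp_io_error("unsupported MAT5 data type ", type)
  )
}

# parse one data element starting at byte offset pos (1-based); returns
# list(type, data_raw, next_pos)
.mat5_element <- function(raw, pos) {
  tagw <- readBin(raw[pos:(pos + 3)], "integer", 1, size = 4, endian = "little")
  if (bitwAnd(tagw, -65536L) != 0L && bitwAnd(tagw, 65535L) <= 18L) {
    # small data element: size in upper 16 bits
    type <- bitwAnd(tagw, 65535L)
    size <- bitwShiftR(tagw, 16L)
    data <- if (size > 0) raw[(pos + 4):(pos + 3 + size)] else raw(0)
    return(list(type = type, data = data, next_pos = pos + 8))
  }
  type <- tagw
  size <- readBin(raw[(pos + 4):(pos + 7)], "integer", 1, size = 4, endian = "little")
  data <- if (size > 0) raw[(pos + 8):(pos + 7 + size)] else raw(0)
  nxt <- pos + 8 + size
  if (type != 15L) nxt <- nxt + (8 - (size %% 8)) %% 8  # pad to 8
  list(type = type, data = data, next_pos = nxt)
}

.mat5_parse_matrix <- function(raw) {
  pos <- 1
  el <- .mat5_element(raw, pos)                       # array flags
  flags <- readBin(el$data, "integer", 2, size = 4, endian = "little")
  klass <- bitwAnd(flags[1], 255L)
  el2 <- .mat5_element(raw, el$next_pos)              # dimensions
  dims <- readBin(el2$data, "integer",
                  length(el2$data) / 4, size = 4, endian = "little")
  el3 <- .mat5_element(raw, el2$next_pos)             # name
  name <- rawToChar(el3$data[el3$data != as.raw(0)])
  pos <- el3$next_pos
  n <- prod(dims)
  value <- NULL
  if (klass %in% c(6L, 7L, 8L, 9L, 10L, 11L, 12L, 13L, 14L, 15L)) {
    # numeric classes: real part only (imaginary ignored)
    el4 <- .mat5_element(raw, pos)
    tp <- el4$type
    if (tp == 16L) {
      value <- rawToChar(el4$data)
    } else {
      v <- .mat5_read_numeric(el4$data, tp, n)
      value <- if (length(dims) == 2 && all(dims > 0)) {
        matrix(as.numeric(v), dims[1], dims[2])
      } else if (n > 0) array(as.numeric(v), dim = dims) else numeric(0)
    }
  } else if (klass == 4L) {                            # char
    el4 <- .mat5_element(raw, pos)
    value <- if (el4$type %in% c(1L, 2L, 16L)) {
      rawToChar(el4$data[el4$data != as.raw(0)])
    } else {
      v <- readBin(el4$data, "integer", length(el4$data) / 2, size = 2,
                   signed = FALSE, endian = "little")
      intToUtf8(v[v > 0])
    }
  } else if (klass == 2L) {                            # struct (array)
    elf <- .mat5_element(raw, pos)                     # field name length
    fnl <- readBin(elf$data, "integer", 1, size = 4, endian = "little")
    eln <- .mat5_element(raw, elf$next_pos)            # field names
    nfields <- length(eln$data) / fnl
    fnames <- vapply(seq_len(nfields), function(i) {
      b <- eln$data[((i - 1) * fnl + 1):(i * fnl)]
      rawToChar(b[b != as.raw(0)])
    }, character(1))
    pos <- eln$next_pos
    elems <- vector("list", n)
    for (j in seq_len(n)) {
      rec <- stats::setNames(vector("list", nfields), fnames)
      for (f in seq_len(nfields)) {
        sub <- .mat5_element(raw, pos)
        rec[[f]] <- .mat5_parse_matrix(sub$data)$value
        pos <- sub$next_pos
      }
      elems[[j]] <- rec
    }
    value <- if (n == 1) elems[[1]] else elems
  } else if (klass == 1L) {                            # cell
    elems <- vector("list", n)
    for (j in seq_len(n)) {
      sub <- .mat5_element(raw, pos)
      elems[[j]] <- .mat5_parse_matrix(sub$data)$value
      pos <- sub$next_pos
    }
    value <- elems
  } else {
    .mp_io_error("unsupported MAT5 array class ", klass)
  }
  list(name = name, value = value)
}

#' Read a MAT level-5 file (the subset used by EEGLAB)
#'
#' @param path Path to a `.mat`/`.set` file.
#' @return Named list of top-level variables.
#' @export
read_mat5 <- function(path) {
  if (!file.exists(path)) .mp_io_error("file does not exist: ", path)
  raw <- readBin(path, "raw", file.info(path)$size)
  if (length(raw) < 136) .mp_io_error("file too short to be MAT5: ", path)
  endian <- rawToChar(raw[127:128])
  if (endian != "IM") {
    .mp_io_error("not a little-endian MAT5 file (endian marker '", endian,
                 "'): ", path)
  }
  pos <- 129
  vars <- list()
  while (pos + 7 <= length(raw)) {
    el <- tryCatch(.mat5_element(raw, pos),
                   error = function(e) .mp_io_error("corrupt MAT5 element in ", path))
    if (el$type == 15L) {                              # compressed element
      dec <- tryCatch(memDecompress(el$data, type = "gzip"),
                      error = function(e) NULL)
      if (is.null(dec)) {
        .mp_io_error("compressed MAT5 element could not be inflated: ", path)
      }
      inner <- .mat5_element(dec, 1)
      v <- .mat5_parse_matrix(inner$data)
    } else if (el$type == 14L) {
      v <- .mat5_parse_matrix(el$data)
    } else {
      .mp_io_error("unexpected top-level MAT5 element type ", el$type,
                   " in ", path)
    }
    vars[[v$name]] <- v$value
    pos <- el$next_pos
  }
  vars
}

# --- writer -----------------------------------------------------------------

.mat5_tag <- function(type, payload) {
  size <- length(payload)
  pad <- (8 - (size %% 8)) %% 8
  c(writeBin(c(as.integer(type), as.integer(size)), raw(), size = 4,
             endian = "little"),
    payload, raw(pad))
}

.mat5_num_payload <- function(x, single = FALSE) {
  if (single) {
    .mat5_tag(7L, writeBin(as.numeric(x), raw(), size = 4, endian = "little"))
  } else {
    .mat5_tag(9L, writeBin(as.numeric(x), raw(), size = 8, endian = "little"))
  }
}

.mat5_matrix <- function(name, value, single = FALSE) {
  if (is.character(value)) {
    chars <- utf8ToInt(value)
    flags <- .mat5_tag(6L, writeBin(c(4L, 0L), raw(), size = 4, endian = "little"))
    dims <- .mat5_tag(5L, writeBin(c(1L, length(chars)), raw(), size = 4,
                                   endian = "little"))
    dat <- .mat5_tag(4L, writeBin(as.integer(chars), raw(), size = 2,
                                  endian = "little"))
  } else if (is.list(value)) {
    # named list -> scalar (1x1) struct; unnamed list of named lists ->
    # 1xN struct array (e.g. chanlocs)
    scalar <- !is.null(names(value)) && all(nzchar(names(value)))
    if (scalar) value <- list(value)
    flags <- .mat5_tag(6L, writeBin(c(2L, 0L), raw(), size = 4, endian = "little"))
    dims <- .mat5_tag(5L, writeBin(c(1L, length(value)), raw(), size = 4,
                                   endian = "little"))
    fnames <- names(value[[1]])
    fnl <- 32L
    nameraw <- raw(0)
    for (f in fnames) {
      b <- charToRaw(f)
      nameraw <- c(nameraw, b, raw(fnl - length(b)))
    }
    body <- c(.mat5_tag(5L, writeBin(fnl, raw(), size = 4, endian = "little")),
              .mat5_tag(1L, nameraw))
    for (elem in value) {
      for (f in fnames) {
        body <- c(body, .mat5_matrix("", elem[[f]], single = single))
      }
    }
    nm <- .mat5_tag(1L, charToRaw(name))
    return(.mat5_tag(14L, c(flags, dims, nm, body)))
  } else {
    value <- as.matrix(value)
    cls <- if (single) 7L else 6L
    flags <- .mat5_tag(6L, writeBin(c(cls, 0L), raw(), size = 4, endian = "little"))
    dims <- .mat5_tag(5L, writeBin(as.integer(dim(value)), raw(), size = 4,
                                   endian = "little"))
    dat <- .mat5_num_payload(value, single = single)
  }
  nm <- .mat5_tag(1L, charToRaw(name))
  .mat5_tag(14L, c(flags, dims, nm, dat))
}

#' Write variables into a MAT level-5 file
#'
#' @param vars Named list. Matrices/vectors become double arrays, strings
#'   char arrays, lists of named lists 1xN struct arrays.
#' @param path Output path.
#' @param single Logical: write numeric matrices as 32-bit floats.
#' @return `path`, invisibly.
#' @export
write_mat5 <- function(vars, path, single = FALSE) {
  desc <- charToRaw(sprintf("MATLAB 5.0 MAT-file, written by mpeeg"))
  header <- c(desc, raw(116 - length(desc)), raw(8),
              as.raw(c(0x00, 0x01)), charToRaw("IM"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(header, con)
  for (nm in names(vars)) {
    writeBin(.mat5_matrix(nm, vars[[nm]], single = single), con)
  }
  invisible(path)
}

#' Write a recording as an EEGLAB set file
#'
#' Produces a single-file set (data embedded as 32-bit floats in the MAT5
#' container) with the EEG struct fields EEGLAB readers rely on.
#'
#' @param rec An `eeg_recording`.
#' @param path Output `.set` path.
#' @return `path`, invisibly.
#' @export
write_eeglab_set <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  chanlocs <- lapply(rec$channels, function(ch) list(labels = ch))
  eeg <- list(
    setname = rec$subject_id,
    nbchan = length(rec$channels),
    pnts = ncol(rec$data),
    trials = 1,
    srate = rec$fs,
    xmin = 0,
    xmax = (ncol(rec$data) - 1) / rec$fs,
    group = ifelse(is.na(rec$group), "", rec$group),
    data = rec$data,
    chanlocs = chanlocs
  )
  write_mat5(list(EEG = eeg), path, single = TRUE)
}

.read_eeglab_set <- function(path) {
  vars <- read_mat5(path)
  eeg <- if ("EEG" %in% names(vars)) vars$EEG else vars
  for (f in c("nbchan", "srate")) {
    if (is.null(eeg[[f]])) .mp_io_error("EEGLAB set lacks field '", f, "': ", path)
  }
  nbchan <- as.numeric(eeg$nbchan)[1]
  fs <- as.numeric(eeg$srate)[1]
  data <- eeg$data
  if (is.character(data) || is.null(data)) {
    datfile <- if (is.character(data)) data else eeg$datfile
    if (is.null(datfile)) .mp_io_error("EEGLAB set has no embedded data and no datfile: ", path)
    fdt <- file.path(dirname(path), basename(datfile))
    if (!file.exists(fdt)) .mp_io_error("EEGLAB datfile missing: ", fdt)
    v <- readBin(fdt, "numeric", file.info(fdt)$size / 4, size = 4,
                 endian = "little")
    data <- matrix(v, nrow = nbchan)
  }
  if (nrow(data) != nbchan) .mp_io_error("EEGLAB data shape mismatch in ", path)
  labels <- paste0("ch", seq_len(nbchan))
  if (!is.null(eeg$chanlocs)) {
    cl <- eeg$chanlocs
    if (!is.null(names(cl)) && "labels" %in% names(cl)) cl <- list(cl)
    got <- vapply(cl, function(e) {
      lb <- e$labels
      if (is.character(lb) && length(lb) == 1) lb else NA_character_
    }, character(1))
    if (length(got) == nbchan && !anyNA(got)) labels <- got
  }
  subj <- if (is.character(eeg$setname) && nzchar(eeg$setname)) eeg$setname else "anon"
  group <- NA_character_
  if (is.character(eeg$group) && eeg$group %in% c("HC", "PD", "PD_OFF", "PD_ON")) {
    group <- eeg$group
  }
  eeg_recording(data, fs, make.unique(labels), subject_id = subj, group = group)
}

#' Read an EEG recording from disk
#'
#' Dispatches on the container format. Data are returned exactly as stored
#' (no resampling, no rescaling beyond the format's own physical calibration).
#'
#' @param path File path.
#' @param format `"EDF"`, `"BDF"` or `"EEGLAB_SET"`; default guesses from the
#'   file extension.
#' @return An `eeg_recording`.
#' @export
read_recording <- function(path, format = c("auto", "EDF", "BDF", "EEGLAB_SET")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, edf = "EDF", bdf = "BDF", set = "EEGLAB_SET",
                     .mp_config_error("cannot guess format from extension '",
                                      ext, "'; pass format explicitly"))
  }
  switch(format,
    EDF = .read_edf_bdf(path, "EDF"),
    BDF = .read_edf_bdf(path, "BDF"),
    EEGLAB_SET = .read_eeglab_set(path)
  )
}
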