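# Plain-text feature store: one CSV per subject and mode, rows = epoch x
# band, columns = per-channel or per-pair features. Round-trips the
# psd_features / plv_features objects across pipeline stages.

#' Write feature objects to a CSV store
#'
#' @param feat A `psd_features` or `plv_features` object.
#' @param dir Output directory (created if needed).
#' @return The file path, invisibly.
#' @export
write_features_csv <- function(feat, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mode <- if (inherits(feat, "psd_features")) "psd" else "plv"
  tabs <- lapply(band_names(feat$band_defs), function(bn) {
    tb <- feature_table(feat, bn)
    cbind(band = bn, tb)
  })
  out <- do.call(rbind, tabs)
  path <- file.path(dir, sprintf("%s_%s.csv", feat$subject_id, mode))
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read one subject's features back from the CSV store
#'
#' @param path A CSV written by [write_features_csv()].
#' @param channels Channel labels of the montage (needed to rebuild the pair
#'   index for PLV features); default: canonical 32.
#' @return The reconstructed `psd_features` or `plv_features` object.
#' @export
read_features_csv <- function(path, channels = NULL) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  meta_cols <- c("band", "subject_id", "group", "epoch")
  units <- setdiff(colnames(df), meta_cols)
  bands_present <- unique(df$band)
  band_defs <- eeg_bands(bands_present)
  is_plv <- grepl("-", units[1], fixed = TRUE)
  n_ep <- max(df$epoch)
  vals <- array(NA_real_, dim = c(n_ep, length(units), length(bands_present)),
                dimnames = list(NULL, units, bands_present))
  for (k in seq_along(bands_present)) {
    sub <- df[df$band == bands_present[k], , drop = FALSE]
    sub <- sub[order(sub$epoch), , drop = FALSE]
    vals[, , k] <- as.matrix(sub[, units, drop = FALSE])
  }
  group <- df$group[1]
  if (is.na(group) || !nzchar(group)) group <- NA_character_
  if (is_plv) {
    if (is.null(channels)) {
      chs <- unique(unlist(strsplit(units, "-", fixed = TRUE)))
      channels <- chs
    }
    structure(list(subject_id = as.character(df$subject_id[1]), group = group,
                   values = vals, band_defs = band_defs, channels = channels,
                   pair_index = channel_pairs(channels),
                   edge_trim = 0.1, average = "within_epoch"),
              class = "plv_features")
  } else {
    structure(list(subject_id = as.character(df$subject_id[1]), group = group,
                   values = vals, band_defs = band_defs, channels = units),
              class = "psd_features")
  }
}
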