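# HDF5 container for preprocessed epoched recordings: one file per subject
# with the epoch tensor plus the metadata needed to reassemble features.

#' Save an epoched recording to an HDF5 container
#'
#' @param ep An `eeg_epochs` object.
#' @param path Output `.h5` path (overwritten if present).
#' @return `path`, invisibly.
#' @export
write_epochs_h5 <- function(ep, path) {
  stopifnot(inherits(ep, "eeg_epochs"))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(ep$epochs, path, "epochs")
  rhdf5::h5write(ep$channels, path, "channels")
  rhdf5::h5write(ep$fs, path, "fs")
  rhdf5::h5write(ep$epoch_length_s, path, "epoch_length_s")
  rhdf5::h5write(ep$subject_id, path, "subject_id")
  rhdf5::h5write(ifelse(is.na(ep$group), "", ep$group), path, "group")
  rhdf5::h5closeAll()
  invisible(path)
}

#' Load an epoched recording from an HDF5 container
#'
#' @param path Path written by [write_epochs_h5()].
#' @return An `eeg_epochs` object.
#' @export
read_epochs_h5 <- function(path) {
  if (!file.exists(path)) .mp_io_error("file does not exist: ", path)
  grp <- as.character(rhdf5::h5read(path, "group"))
  eeg_epochs(
    epochs = rhdf5::h5read(path, "epochs"),
    fs = as.numeric(rhdf5::h5read(path, "fs")),
    channels = as.character(rhdf5::h5read(path, "channels")),
    epoch_length_s = as.numeric(rhdf5::h5read(path, "epoch_length_s")),
    subject_id = as.character(rhdf5::h5read(path, "subject_id")),
    group = ifelse(nzchar(grp), grp, NA_character_)
  )
}
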