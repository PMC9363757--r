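# End-to-end pipeline: synth -> preprocess -> features -> contrast ->
# classify / train-mcnn, driven by a single config (YAML or JSON). Stage
# outputs are content-addressed: the directory name carries a fingerprint of
# the stage parameters.

.read_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) .mp_config_error("config file not found: ", config)
    ext <- tolower(tools::file_ext(config))
    config <- switch(ext,
      yaml = , yml = yaml::read_yaml(config),
      json = jsonlite::read_json(config, simplifyVector = TRUE),
      .mp_config_error("config must be .yaml/.yml/.json, got .", ext))
  }
  if (!is.list(config)) .mp_config_error("config must be a list or a file path")
  config
}

.fingerprint <- function(params) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(params, auto_unbox = TRUE, digits = NA,
                              force = TRUE), tmp)
  substr(unname(tools::md5sum(tmp)), 1, 10)
}

.cohort_spec_from_config <- function(sc, seed) {
  args <- list(
    groups = unlist(sc$groups),
    fs = sc$fs %||% 512,
    duration_s = sc$duration_s %||% 180,
    seed = sc$seed %||% seed
  )
  if (!is.null(sc$channels)) args$channels <- sc$channels
  if (!is.null(sc$background)) args$background <- sc$background
  if (!is.null(sc$band_amplitudes)) args$band_amplitudes <- unlist(sc$band_amplitudes)
  if (!is.null(sc$band_power_effects)) args$band_power_effects <- sc$band_power_effects
  if (!is.null(sc$plv_effects)) {
    pe <- sc$plv_effects
    for (g in names(pe)) for (b in names(pe[[g]])) {
      prs <- pe[[g]][[b]]$pairs
      if (is.list(prs)) pe[[g]][[b]]$pairs <- do.call(rbind, lapply(prs, unlist))
    }
    args$plv_effects <- pe
  }
  if (!is.null(sc$jitter_block_s)) args$jitter_block_s <- sc$jitter_block_s
  if (!is.null(sc$subject_gain_sd)) args$subject_gain_sd <- sc$subject_gain_sd
  do.call(cohort_spec, args)
}

.log_stage <- function(stage, ...) {
  message(sprintf("[mpeeg %s] %s", stage, paste0(...)))
}

#' Run the analysis pipeline from a single configuration
#'
#' Executes the stages present in the config, in order: `synth` (generate a
#' cohort and write per-subject EDF files plus a manifest), `preprocess`
#' (filter/harmonise/truncate/epoch, HDF5 containers), `features` (PSD/PLV
#' CSV store), `contrast` (group contrast maps), `classify` (linear SVM
#' cross-validation) and `mcnn` (CNN cross-validation). A JSON report
#' aggregating all stage summaries is written to the output directory.
#'
#' @param config A named list, or a path to a YAML/JSON file. See the
#'   packaged `demo_config.yaml` for the schema.
#' @param out_dir Output directory (overrides `config$out_dir`).
#' @return The report, invisibly (a named list, also written as JSON).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg <- .read_config(config)
  seed <- cfg$seed %||% 1
  out_dir <- out_dir %||% cfg$out_dir %||% "mpeeg_out"
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  # validate band names up front, before any computation
  for (stage in c("features", "contrast", "classify", "mcnn")) {
    bn <- cfg[[stage]]$band %||% cfg[[stage]]$bands
    if (!is.null(bn) && !identical(bn, "all")) eeg_bands(bn)
  }
  report <- list(seed = seed, stages = list())
  recs <- NULL
  # ---- synth ---------------------------------------------------------------
  if (!is.null(cfg$synth)) {
    spec <- .cohort_spec_from_config(cfg$synth, seed)
    fp <- .fingerprint(cfg$synth)
    sdir <- file.path(out_dir, paste0("synth-", fp))
    dir.create(sdir, showWarnings = FALSE)
    .log_stage("synth", "generating ", sum(spec$groups), " subjects -> ", sdir)
    recs <- generate_cohort(spec)
    manifest <- data.frame(
      subject_id = vapply(recs, `[[`, character(1), "subject_id"),
      group = vapply(recs, `[[`, character(1), "group"),
      file = paste0(vapply(recs, `[[`, character(1), "subject_id"), ".edf"))
    if (isTRUE(cfg$synth$write_edf)) {
      for (r in recs) write_edf(r, file.path(sdir, paste0(r$subject_id, ".edf")))
    }
    write.csv(manifest, file.path(sdir, "manifest.csv"), row.names = FALSE)
    report$stages$synth <- list(dir = sdir, n_subjects = length(recs),
                                groups = as.list(spec$groups))
  }
  # ---- preprocess ----------------------------------------------------------
  epochs <- NULL
  if (!is.null(cfg$preprocess)) {
    pc <- cfg$preprocess
    if (is.null(recs)) {
      input <- pc$input %||% .mp_config_error("preprocess needs synth stage or input dir")
      files <- list.files(input, pattern = "\\.(edf|bdf|set)$", full.names = TRUE,
                          ignore.case = TRUE)
      if (!length(files)) .mp_io_error("no recordings found in ", input)
      recs <- lapply(files, read_recording)
    }
    band <- as.numeric(pc$band %||% c(0.5, 50))
    montage <- if (isFALSE(pc$montage)) NULL else {
      if (is.character(pc$montage)) read_montage_yaml(pc$montage) else {
        if (identical(vapply(recs, function(r) length(r$channels), 1L)[1],
                      32L)) montage_spec() else NULL
      }
    }
    fp <- .fingerprint(pc)
    pdir <- file.path(out_dir, paste0("preprocessed-", fp))
    dir.create(pdir, showWarnings = FALSE)
    .log_stage("preprocess", "band ", band[1], "-", band[2], " Hz, epoch ",
               pc$epoch_length_s %||% 1, " s -> ", pdir)
    epochs <- lapply(recs, function(r) {
      ep <- preprocess_recording(r, band = band, montage = montage,
                                 duration_s = pc$duration_s,
                                 epoch_length_s = pc$epoch_length_s %||% 1)
      write_epochs_h5(ep, file.path(pdir, paste0(r$subject_id, ".h5")))
      ep
    })
    report$stages$preprocess <- list(dir = pdir, band = band,
                                     n_subjects = length(epochs))
  }
  # ---- features ------------------------------------------------------------
  psd <- NULL; plv <- NULL
  if (!is.null(cfg$features)) {
    fc <- cfg$features
    if (is.null(epochs)) {
      input <- fc$input %||% .mp_config_error("features needs preprocess stage or input dir")
      files <- list.files(input, pattern = "\\.h5$", full.names = TRUE)
      epochs <- lapply(files, read_epochs_h5)
    }
    bands <- eeg_bands(fc$bands %||% "all")
    fp <- .fingerprint(fc)
    fdir <- file.path(out_dir, paste0("features-", fp))
    dir.create(fdir, showWarnings = FALSE)
    .log_stage("features", length(bands), " bands x ", length(epochs),
               " subjects -> ", fdir)
    if (!isFALSE(fc$psd)) {
      psd <- lapply(epochs, compute_psd, bands = bands)
      for (f in psd) write_features_csv(f, fdir)
    }
    if (!isFALSE(fc$plv)) {
      plv <- lapply(epochs, compute_plv, bands = bands)
      for (f in plv) write_features_csv(f, fdir)
    }
    report$stages$features <- list(dir = fdir, bands = band_names(bands))
  }
  # ---- contrast ------------------------------------------------------------
  if (!is.null(cfg$contrast)) {
    cc <- cfg$contrast
    mode <- toupper(cc$mode %||% "PSD")
    feats <- if (mode == "PSD") psd else plv
    if (is.null(feats)) .mp_config_error("contrast stage needs ", mode, " features")
    grp_of <- vapply(feats, `[[`, character(1), "group")
    gs <- cc$groups %||% unique(grp_of)[1:2]
    cm <- group_contrast(feats[grp_of == gs[1]], feats[grp_of == gs[2]],
                         band = cc$band, alpha = cc$alpha %||% 0.05)
    fp <- .fingerprint(cc)
    cdir <- file.path(out_dir, paste0("contrast-", fp))
    dir.create(cdir, showWarnings = FALSE)
    .log_stage("contrast", mode, "/", cc$band, " ", gs[1], " vs ", gs[2],
               ": ", sum(cm$significant), "/", length(cm$ratio), " significant")
    if (isTRUE(cc$render)) {
      render_contrast(cm, file.path(cdir, paste0("contrast_", mode, "_",
                                                 cc$band, ".png")))
    }
    report$stages$contrast <- list(
      dir = cdir, mode = mode, band = cc$band,
      orientation = paste(gs[1], "/", gs[2]),
      n_significant = sum(cm$significant), n_units = length(cm$ratio),
      ratio = as.list(stats::setNames(round(cm$ratio, 4), cm$unit_names)))
  }
  # ---- classify (SVM) ------------------------------------------------------
  if (!is.null(cfg$classify)) {
    kc <- cfg$classify
    fm <- assemble_features(psd = psd, plv = plv,
                            mode = toupper(gsub("\\+", "_", kc$mode %||% "PSD_PLV")),
                            band = kc$band, groups = unlist(kc$groups))
    cv <- svm_crossval(fm, k = kc$folds %||% 10, seed = kc$seed %||% seed,
                       C = kc$C %||% 1)
    .log_stage("classify", "svm ", fm$mode, "/", fm$band, ": acc ",
               sprintf("%.2f%%", cv$accuracy))
    report$stages$classify <- .cv_report(cv)
  }
  # ---- mcnn ----------------------------------------------------------------
  if (!is.null(cfg$mcnn)) {
    mc <- cfg$mcnn
    fm <- assemble_features(psd = psd, plv = plv, mode = "PSD_PLV",
                            band = mc$band, groups = unlist(mc$groups))
    ncls <- length(unique(fm$y))
    ccfg <- mcnn_config(n_classes = ncls, max_epochs = mc$max_epochs %||% 15,
                        batch_size = mc$batch_size %||% 64,
                        seed = mc$seed %||% seed)
    cv <- crossval_mcnn(fm, k = mc$folds %||% 10, cfg = ccfg)
    .log_stage("mcnn", fm$mode, "/", fm$band, ": acc ",
               sprintf("%.2f%%", cv$accuracy))
    report$stages$mcnn <- .cv_report(cv)
  }
  report_path <- file.path(out_dir, "report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  .log_stage("run", "report written to ", report_path)
  invisible(report)
}

.cv_report <- function(cv) {
  list(model = cv$model, mode = cv$mode, band = cv$band,
       groups = as.list(cv$groups), folds = cv$k, seed = cv$seed,
       accuracy = cv$accuracy, sensitivity = cv$sensitivity,
       specificity = cv$specificity, auc = cv$auc,
       roc_points = if (!is.null(cv$roc_points)) {
         list(FPR = cv$roc_points$FPR, TPR = cv$roc_points$TPR)
       })
}

#' Read a montage specification from YAML
#'
#' @param path YAML file with `target_channels` (list) and optional
#'   `imputation_rules` (map label -> donor list).
#' @return A `montage_spec`.
#' @export
read_montage_yaml <- function(path) {
  if (!file.exists(path)) .mp_io_error("montage file not found: ", path)
  y <- yaml::read_yaml(path)
  montage_spec(target_channels = unlist(y$target_channels),
               imputation_rules = lapply(y$imputation_rules, unlist))
}
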