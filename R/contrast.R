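# Group-level multi-pattern contrasts: per-channel (PSD) or per-pair (PLV)
# ratios of group means with Student's t significance masks, the numerical
# content behind topographic / matrix contrast maps.

# stack per-epoch feature rows for one band across a list of feature objects
.pool_band <- function(feats, band) {
  mats <- lapply(feats, function(f) {
    bn <- band_names(f$band_defs)
    k <- match(band, bn)
    if (is.na(k)) .mp_validation_error("band ", band, " missing from features")
    m <- f$values[, , k, drop = FALSE]
    dim(m) <- dim(f$values)[1:2]
    m
  })
  do.call(rbind, mats)
}

.subject_means <- function(feats, band) {
  do.call(rbind, lapply(feats, function(f) {
    m <- .pool_band(list(f), band)
    colMeans(m)
  }))
}

#' Group contrast of PSD or PLV features
#'
#' For every unit (channel for PSD, channel pair for PLV) a two-sample
#' Student's t-test with pooled variance compares per-epoch feature values
#' of group A against group B, and the ratio of group means is reported
#' (Fisher-domain means for PLV). Units with `p <= alpha` form the
#' significance mask. Orientation is fixed: ratio = mean(A) / mean(B).
#'
#' @param featA,featB Lists of `psd_features` or `plv_features` objects (one
#'   per subject) for the two groups; all of the same mode and montage.
#' @param band Band name to contrast.
#' @param alpha Significance level (default 0.05).
#' @param observation `"epoch"` (default: per-epoch values pooled across a
#'   group's subjects) or `"subject"` (per-subject mean values).
#' @param p_adjust `"none"` (default, matching per-unit masks) or `"BH"` for
#'   Benjamini-Hochberg adjusted p-values.
#' @return A `contrast_map` object with `unit_names`, `ratio`, `p_value`,
#'   `significant`, `t_stat`, plus the band/mode metadata.
#' @export
group_contrast <- function(featA, featB, band, alpha = 0.05,
                           observation = c("epoch", "subject"),
                           p_adjust = c("none", "BH")) {
  observation <- match.arg(observation)
  p_adjust <- match.arg(p_adjust)
  if (inherits(featA, c("psd_features", "plv_features"))) featA <- list(featA)
  if (inherits(featB, c("psd_features", "plv_features"))) featB <- list(featB)
  if (!length(featA) || !length(featB)) {
    .mp_validation_error("both groups must be non-empty")
  }
  is_plv <- inherits(featA[[1]], "plv_features")
  if (is_plv != inherits(featB[[1]], "plv_features")) {
    .mp_validation_error("groups carry different feature modes")
  }
  A <- if (observation == "epoch") .pool_band(featA, band) else .subject_means(featA, band)
  B <- if (observation == "epoch") .pool_band(featB, band) else .subject_means(featB, band)
  if (ncol(A) != ncol(B)) .mp_validation_error("unit sets differ between groups")
  nA <- nrow(A); nB <- nrow(B)
  if (nA < 2 || nB < 2) {
    warning("degenerate contrast: fewer than 2 observations in a group; ",
            "p-values set to 1")
    p <- rep(1, ncol(A)); tstat <- rep(0, ncol(A))
  } else {
    mA <- colMeans(A); mB <- colMeans(B)
    vA <- apply(A, 2, var); vB <- apply(B, 2, var)
    sp2 <- ((nA - 1) * vA + (nB - 1) * vB) / (nA + nB - 2)
    se <- sqrt(sp2 * (1 / nA + 1 / nB))
    tstat <- (mA - mB) / se
    df <- nA + nB - 2
    p <- 2 * pt(abs(tstat), df, lower.tail = FALSE)
    zero_var <- se == 0
    if (any(zero_var)) {
      warning(sum(zero_var), " unit(s) with zero variance in both groups; ",
              "p set to 1")
      p[zero_var] <- 1
      tstat[zero_var] <- 0
    }
  }
  if (is_plv) {
    ratio <- apply(A, 2, fisher_mean_plv) / apply(B, 2, fisher_mean_plv)
  } else {
    ratio <- colMeans(A) / colMeans(B)
  }
  if (p_adjust == "BH") p <- p.adjust(p, method = "BH")
  unit_names <- if (is_plv) featA[[1]]$pair_index$name else featA[[1]]$channels
  structure(
    list(band = band, mode = if (is_plv) "PLV" else "PSD",
         unit = if (is_plv) "channel_pair" else "channel",
         unit_names = unit_names, ratio = ratio, p_value = p,
         t_stat = tstat, significant = p <= alpha, alpha = alpha,
         n_obs = c(A = nA, B = nB), observation = observation,
         channels = featA[[1]]$channels,
         pair_index = if (is_plv) featA[[1]]$pair_index else NULL),
    class = "contrast_map"
  )
}

#' @export
print.contrast_map <- function(x, ...) {
  cat(sprintf("<contrast_map %s/%s: %d units, %d significant at alpha=%g (ratio = A/B)>\n",
              x$mode, x$band, length(x$ratio), sum(x$significant), x$alpha))
  invisible(x)
}

# Approximate 2-d scalp coordinates (10-20 layout, unit head circle) for the
# canonical 32-channel montage, used only for rendering.
.montage32_layout <- function() {
  xy <- rbind(
    Fp1 = c(-0.31, 0.95), AF3 = c(-0.35, 0.75), F7 = c(-0.81, 0.59),
    F3 = c(-0.45, 0.55), FC1 = c(-0.25, 0.28), FC5 = c(-0.70, 0.30),
    T7 = c(-1.00, 0.00), C3 = c(-0.50, 0.00), CP1 = c(-0.25, -0.28),
    CP5 = c(-0.70, -0.30), P7 = c(-0.81, -0.59), P3 = c(-0.45, -0.55),
    Pz = c(0.00, -0.50), PO3 = c(-0.35, -0.75), O1 = c(-0.31, -0.95),
    Oz = c(0.00, -1.00), O2 = c(0.31, -0.95), PO4 = c(0.35, -0.75),
    P4 = c(0.45, -0.55), P8 = c(0.81, -0.59), CP6 = c(0.70, -0.30),
    CP2 = c(0.25, -0.28), C4 = c(0.50, 0.00), T8 = c(1.00, 0.00),
    FC6 = c(0.70, 0.30), FC2 = c(0.25, 0.28), F4 = c(0.45, 0.55),
    F8 = c(0.81, 0.59), AF4 = c(0.35, 0.75), Fp2 = c(0.31, 0.95),
    Fz = c(0.00, 0.50), Cz = c(0.00, 0.00))
  colnames(xy) <- c("x", "y")
  xy
}

#' Render a contrast map to an image file
#'
#' Channels are drawn as a topographic scatter on the scalp circle, channel
#' pairs as a symmetric matrix heat map. Non-significant units are blanked
#' (drawn in the null colour), mirroring published contrast-map conventions.
#'
#' @param map A `contrast_map`.
#' @param path Output image path (`.png` or `.pdf`).
#' @param layout Channel coordinate matrix (rows named by channel, columns
#'   x/y). Default: built-in approximate 10-20 coordinates.
#' @return Invisibly, the vector/matrix of rendered values with blanked units
#'   as `NA` (used for programmatic checks).
#' @export
render_contrast <- function(map, path, layout = .montage32_layout()) {
  stopifnot(inherits(map, "contrast_map"))
  shown <- ifelse(map$significant, map$ratio, NA_real_)
  missing_ch <- setdiff(map$channels, rownames(layout))
  if (length(missing_ch)) {
    .mp_validation_error("layout lacks coordinates for: ",
                         paste(missing_ch, collapse = ", "))
  }
  ext <- tolower(tools::file_ext(path))
  if (ext == "pdf") grDevices::pdf(path, width = 6, height = 6)
  else grDevices::png(path, width = 720, height = 720)
  on.exit(grDevices::dev.off())
  pal <- grDevices::colorRampPalette(c("blue", "cyan", "white", "yellow", "red"))(64)
  if (map$unit == "channel") {
    xy <- layout[map$channels, , drop = FALSE]
    rng <- suppressWarnings(range(shown, na.rm = TRUE))
    if (!all(is.finite(rng))) rng <- c(0, 1)
    col_of <- function(v) {
      if (is.na(v)) return("grey90")
      i <- 1 + round(63 * (v - rng[1]) / max(rng[2] - rng[1], 1e-12))
      pal[i]
    }
    graphics::plot(NA, xlim = c(-1.3, 1.3), ylim = c(-1.3, 1.3), asp = 1,
                   axes = FALSE, xlab = "", ylab = "",
                   main = sprintf("%s ratio (A/B), %s band", map$mode, map$band))
    graphics::symbols(0, 0, circles = 1.1, inches = FALSE, add = TRUE)
    graphics::points(xy[, 1], xy[, 2], pch = 21, cex = 3,
                     bg = vapply(shown, col_of, character(1)))
    graphics::text(xy[, 1], xy[, 2] + 0.12, map$channels, cex = 0.6)
    ret <- stats::setNames(shown, map$unit_names)
  } else {
    n_ch <- length(map$channels)
    m <- matrix(NA_real_, n_ch, n_ch, dimnames = list(map$channels, map$channels))
    pi_ <- map$pair_index
    m[cbind(pi_$i, pi_$j)] <- shown
    m[cbind(pi_$j, pi_$i)] <- shown
    graphics::image(seq_len(n_ch), seq_len(n_ch), m, col = pal,
                    xlab = "channel", ylab = "channel",
                    main = sprintf("%s ratio (A/B), %s band", map$mode, map$band))
    ret <- m
  }
  invisible(ret)
}

#' Permutation p-values for a set of units (independent check)
#'
#' Re-computes two-sided p-values for the group mean difference by label
#' permutation; used as an oracle for the analytic t-test p-values.
#'
#' @param A,B Observation x unit matrices.
#' @param n_perm Number of permutations.
#' @param seed RNG seed.
#' @return Vector of permutation p-values, one per unit.
#' @export
permutation_pvalues <- function(A, B, n_perm = 10000, seed = 1) {
  set.seed(seed)
  nA <- nrow(A)
  all_obs <- rbind(A, B)
  obs <- abs(colMeans(A) - colMeans(B))
  exceed <- rep(1, ncol(A))   # +1 smoothing: count the observed labelling
  for (p in seq_len(n_perm)) {
    idx <- sample.int(nrow(all_obs), nA)
    d <- abs(colMeans(all_obs[idx, , drop = FALSE]) -
               colMeans(all_obs[-idx, , drop = FALSE]))
    exceed <- exceed + (d >= obs)
  }
  exceed / (n_perm + 1)
}
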