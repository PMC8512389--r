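time_feature_names <- c(
  "mean", "variance", "sd", "abs_mean", "sra", "median", "mode", "min", "max",
  "p2p", "iqr", "rms", "zcr", "skewness", "kurtosis",
  "impulse_factor", "margin_factor", "shape_factor", "crest_factor")

freq_feature_names <- c(
  "energy", "entropy", "freq_center", "rms_freq", "dc",
  "top1_freq", "top2_freq", "top3_freq",
  "spec_mean", "spec_sd", "spec_skew", "spec_kurt")

pair_feature_names <- c("correlation", "cosine_distance")

# population skewness/kurtosis; 0 on zero-variance input so downstream
# feature matrices stay finite
std_moment <- function(x, p) {
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  if (m2 == 0) return(0)
  mean(((x - mu) / sqrt(m2))^p)
}

safe_ratio <- function(num, den) if (den == 0) 0 else num / den

#' Time-domain window features
#'
#' Computes the standard time-domain statistics used for inertial-signal
#' activity recognition over one window of samples. Conventions on
#' degenerate windows: skewness and kurtosis of a zero-variance window are
#' 0, and the impulse/margin/shape/crest factors are 0 whenever their
#' denominator vanishes, so every value is finite for finite input.
#'
#' Definitions that are conventions rather than universal: `variance` is the
#' population variance (1/N), `sd` the sample standard deviation (1/(N-1)),
#' `sra` the square-root amplitude `((1/N) sum sqrt(|x|))^2`, `mode` the most
#' frequent value (smallest on ties), `iqr` uses the (n+1)-interpolation
#' quantile rule (R type 6), `zcr = sum |sgn(x_i) - sgn(x_(i-1))| / (2N)`,
#' and skewness/kurtosis standardize by the population SD (kurtosis is not
#' excess-corrected).
#'
#' @param x numeric window of length >= 2.
#' @return Named numeric vector of length 19 (see `time_feature_names`).
#' @examples
#' time_features(c(1, -1, 1, -1))[c("mean", "rms", "zcr")]
#' @export
time_features <- function(x) {
  stop_if_not(is.numeric(x) && length(x) >= 2, "window must hold at least 2 samples")
  n <- length(x)
  mu <- mean(x)
  abs_mean <- mean(abs(x))
  sra <- mean(sqrt(abs(x)))^2
  rms <- sqrt(mean(x^2))
  peak <- max(abs(x))
  tab <- table(x)
  zcr <- sum(abs(sign(x[-1]) - sign(x[-n]))) / (2 * n)
  q <- stats::quantile(x, c(0.25, 0.75), type = 6, names = FALSE)
  c(mean = mu,
    variance = mean((x - mu)^2),
    sd = stats::sd(x),
    abs_mean = abs_mean,
    sra = sra,
    median = stats::median(x),
    mode = as.numeric(names(tab)[which.max(tab)]),
    min = min(x),
    max = max(x),
    p2p = max(x) - min(x),
    iqr = q[2] - q[1],
    rms = rms,
    zcr = zcr,
    skewness = std_moment(x, 3),
    kurtosis = std_moment(x, 4),
    impulse_factor = safe_ratio(peak, abs_mean),
    margin_factor = safe_ratio(peak, sra),
    shape_factor = safe_ratio(rms, abs_mean),
    crest_factor = safe_ratio(peak, rms))
}

#' Frequency-domain window features
#'
#' Computes the discrete-Fourier magnitude spectrum of the window and
#' derives: signal energy `sum(x^2)` (time domain; equal to the spectral sum
#' by Parseval), spectral entropy in bits over the normalized squared
#' magnitudes of the one-sided spectrum (DC excluded), the power-weighted
#' mean frequency (`freq_center`), the RMS frequency
#' `sqrt(sum(f^2 P) / sum(P))`, the DC component (signal mean), the
#' frequencies of the three largest non-DC magnitude bins, and the
#' mean/SD/skewness/kurtosis of the one-sided magnitude spectrum (spectral
#' shape and amplitude). An all-zero window returns all zeros.
#'
#' @param x numeric window of length >= 4.
#' @param fs sampling rate in Hz.
#' @return Named numeric vector of length 12 (see `freq_feature_names`).
#' @export
freq_features <- function(x, fs) {
  stop_if_not(is.numeric(x) && length(x) >= 4, "window must hold at least 4 samples")
  stop_if_not(is.numeric(fs) && fs > 0, "fs must be > 0")
  n <- length(x)
  out <- stats::setNames(numeric(length(freq_feature_names)), freq_feature_names)
  out["energy"] <- sum(x^2)
  if (all(x == 0)) return(out)
  X <- stats::fft(x)
  ks <- seq_len(floor(n / 2))            # one-sided, DC excluded
  f <- ks * fs / n
  M <- Mod(X[ks + 1L])
  P <- M^2
  tot <- sum(P)
  if (tot > 0) {
    p <- P / tot
    nz <- p > 0
    out["entropy"] <- -sum(p[nz] * log2(p[nz]))
    out["freq_center"] <- sum(f * P) / tot
    out["rms_freq"] <- sqrt(sum(f^2 * P) / tot)
    top <- f[order(P, decreasing = TRUE)]
    top <- c(top, numeric(3))[1:3]
    out[c("top1_freq", "top2_freq", "top3_freq")] <- top
  }
  out["dc"] <- mean(x)
  out["spec_mean"] <- mean(M)
  out["spec_sd"] <- stats::sd(M)
  out["spec_skew"] <- std_moment(M, 3)
  out["spec_kurt"] <- std_moment(M, 4)
  out
}

#' Channel-pair window features
#'
#' Pearson correlation (0 by convention when either window has zero
#' variance) and cosine distance `1 - <a,b> / (|a| |b|)` (0 by convention
#' when either norm vanishes) between two equal-length windows.
#'
#' @param a,b numeric windows of equal length >= 2.
#' @return Named numeric vector `correlation`, `cosine_distance`.
#' @export
pair_features <- function(a, b) {
  stop_if_not(length(a) == length(b) && length(a) >= 2,
              "paired windows must have equal length >= 2")
  r <- if (stats::sd(a) == 0 || stats::sd(b) == 0) 0 else stats::cor(a, b)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  cd <- if (na == 0 || nb == 0) 0 else 1 - sum(a * b) / (na * nb)
  c(correlation = r, cosine_distance = cd)
}

#' Feature catalogue
#'
#' An ordered, named selection of window features to extract. The default
#' single-channel catalogue holds 26 features per channel — the common
#' activity-recognition set (mean, variance, SD, mode, median, max, min,
#' zero-crossing rate, IQR, skewness, kurtosis; DC, top three frequencies,
#' spectral mean/SD/skewness/kurtosis) plus seven vibration-analysis
#' staples (absolute mean, square-root amplitude, RMS, peak-to-peak, energy,
#' spectral entropy, crest factor) — matching the published per-channel
#' count for 12-channel smartphone data. Pair features default to Pearson
#' correlation and cosine distance between channels of the same sensor.
#'
#' @param single character vector of single-channel feature names; any of
#'   `time_feature_names` / `freq_feature_names`, order preserved.
#' @param pairs character vector of channel-pair feature names (any of
#'   `pair_feature_names`), or `character(0)` for none.
#' @return An object of class `feature_catalog`.
#' @export
feature_catalog <- function(single = default_single_features(),
                            pairs = pair_feature_names) {
  known <- c(time_feature_names, freq_feature_names)
  bad <- setdiff(single, known)
  stop_if_not(length(bad) == 0, "unknown single-channel features: %s",
              paste(bad, collapse = ", "))
  stop_if_not(!anyDuplicated(single), "feature names must be unique")
  bad <- setdiff(pairs, pair_feature_names)
  stop_if_not(length(bad) == 0, "unknown pair features: %s", paste(bad, collapse = ", "))
  structure(list(single = single, pairs = pairs), class = "feature_catalog")
}

#' @rdname feature_catalog
#' @export
default_single_features <- function() {
  c("mean", "variance", "sd", "mode", "median", "max", "min", "zcr", "iqr",
    "skewness", "kurtosis",
    "dc", "top1_freq", "top2_freq", "top3_freq",
    "spec_mean", "spec_sd", "spec_skew", "spec_kurt",
    "abs_mean", "sra", "rms", "p2p", "energy", "entropy", "crest_factor")
}

# channels sharing all but their final character form one sensor group
# (ax, ay, az -> "a"); singletons pair with nothing
infer_channel_groups <- function(channels) {
  if (length(channels) < 2) return(list())
  pre <- sub(".$", "", channels)
  grp <- lapply(split(channels, pre), sort)  # canonical pair naming
  grp[vapply(grp, length, integer(1)) >= 2]
}

single_window_features <- function(win, fs, catalog) {
  need_time <- any(catalog$single %in% time_feature_names)
  need_freq <- any(catalog$single %in% freq_feature_names)
  vals <- lapply(win, function(x) {
    v <- c(if (need_time) time_features(x),
           if (need_freq) freq_features(x, fs))
    v[catalog$single]
  })
  # feature-major: catalogue order outer, channel order inner
  out <- numeric(0)
  nms <- character(0)
  for (f in catalog$single) {
    for (ch in names(win)) {
      out <- c(out, vals[[ch]][[f]])
      nms <- c(nms, paste0(f, "__", ch))
    }
  }
  stats::setNames(out, nms)
}

pair_window_features <- function(win, catalog, groups) {
  out <- numeric(0); nms <- character(0)
  if (length(catalog$pairs) == 0 || length(groups) == 0)
    return(stats::setNames(out, nms))
  for (f in catalog$pairs) {
    for (g in groups) {
      cmb <- utils::combn(g, 2)
      for (j in seq_len(ncol(cmb))) {
        v <- pair_features(win[[cmb[1, j]]], win[[cmb[2, j]]])
        out <- c(out, v[[f]])
        nms <- c(nms, paste0(f, "__", cmb[1, j], "_", cmb[2, j]))
      }
    }
  }
  stats::setNames(out, nms)
}

#' Extract a labeled feature matrix from a recording
#'
#' Segments the recording with `spec`, computes the catalogue's features
#' over every window and channel, and assembles one row per window. Columns
#' are named `feature__channel` (single-channel) and
#' `feature__chA_chB` (channel pairs), in catalogue order then channel
#' order; the window label (majority vote) is appended as a trailing factor
#' column `label` when the recording carries labels. Column order depends
#' only on the catalogue and the recording's channel order, never on
#' insertion order of windows.
#'
#' @param recording a [new_recording()] object.
#' @param spec a [window_spec()].
#' @param catalog a [feature_catalog()].
#' @param channel_groups optional named list of channel-name vectors that
#'   define which channels are paired; defaults to grouping channels that
#'   share all but their last name character (`ax, ay, az` form one triad).
#' @return data.frame of window features (empty, but with the full header,
#'   if the recording is shorter than one window).
#' @export
extract_features <- function(recording, spec, catalog = feature_catalog(),
                             channel_groups = NULL) {
  stop_if_not(inherits(catalog, "feature_catalog"), "catalog must be a feature_catalog")
  seg <- withCallingHandlers(
    segment_recording(recording, spec),
    warning = function(w) invokeRestart("muffleWarning"))
  chans <- setdiff(names(recording$data), "t")
  if (is.null(channel_groups)) channel_groups <- infer_channel_groups(chans)
  if (length(seg$windows) == 0) {
    dummy <- stats::setNames(as.data.frame(matrix(0, 1, length(chans))), chans)
    dummy <- as.list(dummy)
    dummy <- lapply(dummy, function(.) rep(0, max(4L, spec$width_samples)))
    hdr <- names(c(single_window_features(dummy, recording$fs, catalog),
                   pair_window_features(dummy, catalog, channel_groups)))
    out <- as.data.frame(matrix(numeric(0), 0, length(hdr)))
    names(out) <- hdr
    return(out)
  }
  rows <- lapply(seg$windows, function(w) {
    win <- as.list(w)
    c(single_window_features(win, recording$fs, catalog),
      pair_window_features(win, catalog, channel_groups))
  })
  out <- as.data.frame(do.call(rbind, rows))
  if (!is.null(seg$labels)) out$label <- seg$labels
  out
}
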