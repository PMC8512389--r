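#' Specify a feature table with planted structure
#'
#' Describes a synthetic labeled feature table in which the columns split,
#' as real inertial-feature tables do, into three kinds: informative columns
#' whose class-conditional means are separated, redundant columns that are
#' noisy copies of informative ones, and pure noise columns independent of
#' the label. Such tables give every selector in this package a known ground
#' truth to recover.
#'
#' @param n_samples number of rows (windows). Must allow at least 2 samples
#'   per class.
#' @param n_classes number of activity classes (>= 2).
#' @param n_informative,n_redundant,n_noise column counts by kind.
#' @param effect_size separation of adjacent class means on an informative
#'   column, in units of the within-class (noise) standard deviation. Must
#'   be > 0.
#' @param redundancy_corr target sample correlation between a redundant
#'   column and its informative source, in (0, 1].
#' @param seed integer seed; the generated table is a deterministic function
#'   of the spec.
#' @return An object of class `planted_spec`.
#' @seealso [sim_feature_table()]
#' @export
planted_spec <- function(n_samples, n_classes, n_informative,
                         n_redundant = 0L, n_noise = 0L,
                         effect_size = 1, redundancy_corr = 0.9, seed = 1L) {
  stop_if_not(is_count(n_samples, 2L), "n_samples must be a count >= 2")
  stop_if_not(is_count(n_classes, 2L), "n_classes must be a count >= 2")
  stop_if_not(is_count(n_informative, 1L), "need at least one informative feature")
  stop_if_not(is_count(n_redundant, 0L) && is_count(n_noise, 0L),
              "n_redundant and n_noise must be non-negative counts")
  stop_if_not(n_samples >= 2L * n_classes, "every class needs at least 2 samples")
  stop_if_not(is.numeric(effect_size) && effect_size > 0,
              "effect_size must be > 0 (a zero effect plants no recoverable signal)")
  stop_if_not(is.numeric(redundancy_corr) && redundancy_corr > 0 && redundancy_corr <= 1,
              "redundancy_corr must lie in (0, 1]")
  structure(list(n_samples = as.integer(n_samples), n_classes = as.integer(n_classes),
                 n_informative = as.integer(n_informative),
                 n_redundant = as.integer(n_redundant), n_noise = as.integer(n_noise),
                 effect_size = effect_size, redundancy_corr = redundancy_corr,
                 seed = as.integer(seed)),
            class = "planted_spec")
}

#' Generate a labeled feature table with known informative columns
#'
#' Labels are assigned block-wise per class (balanced within one sample) and
#' then shuffled. Each informative column gets per-class means placed on an
#' equally spaced grid with step `effect_size` (in noise-SD units), with the
#' class-to-level assignment permuted independently per column; within-class
#' noise is standard normal. Each redundant column mixes a standardized
#' informative source with noise orthogonalized in-sample, so its sample
#' correlation with the source is exactly `redundancy_corr`. Noise columns
#' are label-independent standard normal draws.
#'
#' @param spec a [planted_spec()].
#' @return A list with components:
#'   \describe{
#'     \item{data}{data.frame of numeric feature columns with a trailing
#'       factor column `label`.}
#'     \item{informative}{integer indices of the informative columns (the
#'       ground-truth set a selector should recover).}
#'     \item{redundant, noise}{indices of the remaining column kinds.}
#'     \item{source}{for each redundant column, the index of the informative
#'       column it copies.}
#'   }
#' @examples
#' tab <- sim_feature_table(planted_spec(100, 4, 10, 5, 85, effect_size = 1.5, seed = 1))
#' dim(tab$data)   # 100 rows, 100 features + label
#' tab$informative
#' @export
sim_feature_table <- function(spec) {
  stop_if_not(inherits(spec, "planted_spec"), "spec must be a planted_spec")
  n <- spec$n_samples; k <- spec$n_classes
  p_inf <- spec$n_informative; p_red <- spec$n_redundant; p_noi <- spec$n_noise
  local_seed(spec$seed, {
    # block-wise balanced labels, then a seeded shuffle
    base <- rep(seq_len(k), length.out = n)
    y <- sort(base)[sample.int(n)]
    levels_centered <- (seq_len(k) - (k + 1) / 2) * spec$effect_size
    X_inf <- matrix(stats::rnorm(n * p_inf), n, p_inf)
    for (j in seq_len(p_inf)) {
      mu <- levels_centered[sample.int(k)]        # per-column class-to-level permutation
      X_inf[, j] <- X_inf[, j] + mu[y]
    }
    X_red <- NULL
    src <- integer(0)
    if (p_red > 0L) {
      src <- rep(seq_len(p_inf), length.out = p_red)
      rho <- spec$redundancy_corr
      X_red <- matrix(0, n, p_red)
      for (j in seq_len(p_red)) {
        z <- scale(X_inf[, src[j]])[, 1L]
        e <- stats::rnorm(n)
        e <- stats::residuals(stats::lm.fit(cbind(1, z), e))  # in-sample orthogonal noise
        e <- e / stats::sd(e)
        X_red[, j] <- rho * z + sqrt(1 - rho^2) * e
      }
    }
    X_noi <- if (p_noi > 0L) matrix(stats::rnorm(n * p_noi), n, p_noi) else NULL
    X <- cbind(X_inf, X_red, X_noi)
    colnames(X) <- c(sprintf("inf_%02d", seq_len(p_inf)),
                     if (p_red > 0L) sprintf("red_%02d", seq_len(p_red)),
                     if (p_noi > 0L) sprintf("noise_%02d", seq_len(p_noi)))
    dat <- as.data.frame(X)
    dat$label <- factor(paste0("class_", y))
    list(data = dat,
         informative = seq_len(p_inf),
         redundant = if (p_red > 0L) p_inf + seq_len(p_red) else integer(0),
         noise = if (p_noi > 0L) p_inf + p_red + seq_len(p_noi) else integer(0),
         source = src)
  })
}

#' Specify a synthetic inertial recording
#'
#' Describes a 6-channel IMU-like recording (tri-axial accelerometer and
#' gyroscope) as a sequence of per-class segments. Dynamic activities are
#' emulated by a sinusoid in a class-specific frequency band; stationary
#' activities (zero amplitude) differ only through the gravity component
#' projected onto the accelerometer axes by the class's orientation vector.
#' The signals carry the statistical structure the downstream feature chain
#' exploits, not human kinematics.
#'
#' @param fs sampling rate in Hz (> 0).
#' @param duration_s seconds of signal per class segment.
#' @param classes data.frame with one row per class and columns `label`,
#'   `f_lo`, `f_hi` (dominant-frequency band, Hz, below `fs/2`), `amplitude`,
#'   `ox`, `oy`, `oz` (unit gravity-orientation vector) and `noise_sd`.
#' @param seed integer seed.
#' @return An object of class `recording_spec`.
#' @export
recording_spec <- function(fs, duration_s, classes, seed = 1L) {
  stop_if_not(is.numeric(fs) && fs > 0, "fs must be > 0")
  stop_if_not(is.numeric(duration_s) && duration_s > 0, "duration_s must be > 0")
  need <- c("label", "f_lo", "f_hi", "amplitude", "ox", "oy", "oz", "noise_sd")
  stop_if_not(is.data.frame(classes) && all(need %in% names(classes)) && nrow(classes) >= 1,
              "classes must be a data.frame with columns %s", paste(need, collapse = ", "))
  stop_if_not(all(classes$f_hi < fs / 2) && all(classes$f_lo >= 0) &&
                all(classes$f_lo <= classes$f_hi),
              "frequency bands must satisfy 0 <= f_lo <= f_hi < fs/2 (Nyquist)")
  norms <- sqrt(classes$ox^2 + classes$oy^2 + classes$oz^2)
  stop_if_not(all(abs(norms - 1) < 1e-6), "orientation vectors must have unit norm")
  stop_if_not(all(classes$noise_sd >= 0), "noise_sd must be >= 0")
  structure(list(fs = fs, duration_s = duration_s, classes = classes,
                 seed = as.integer(seed)),
            class = "recording_spec")
}

GRAVITY <- 9.80665  # m/s^2

#' Generate a synthetic 6-channel inertial recording
#'
#' For each class segment, the accelerometer channels are
#' `gravity * orientation + amplitude * sin(2 pi f t + phase) + noise` and
#' the gyroscope channels are `amplitude * sin(2 pi f t + phase) + noise`,
#' with one dominant frequency `f` drawn uniformly per channel from the
#' class's band and independent Gaussian noise.
#'
#' @param spec a [recording_spec()].
#' @return An object of class `recording`: a list with `data` (data.frame
#'   `t, ax, ay, az, gx, gy, gz`), `fs`, and per-sample factor `labels`.
#' @examples
#' cls <- data.frame(label = "walk", f_lo = 1.5, f_hi = 2.5, amplitude = 2,
#'                   ox = 0, oy = 0, oz = 1, noise_sd = 0.2)
#' rec <- sim_recording(recording_spec(fs = 50, duration_s = 10, classes = cls))
#' nrow(rec$data)  # 500
#' @export
sim_recording <- function(spec) {
  stop_if_not(inherits(spec, "recording_spec"), "spec must be a recording_spec")
  n_seg <- round(spec$fs * spec$duration_s)
  cl <- spec$classes
  local_seed(spec$seed, {
    segs <- lapply(seq_len(nrow(cl)), function(i) {
      t <- (seq_len(n_seg) - 1L) / spec$fs
      g <- GRAVITY * c(cl$ox[i], cl$oy[i], cl$oz[i])
      chan <- function(offset) {
        f <- stats::runif(1, cl$f_lo[i], cl$f_hi[i])
        ph <- stats::runif(1, 0, 2 * pi)
        offset + cl$amplitude[i] * sin(2 * pi * f * t + ph) +
          stats::rnorm(n_seg, sd = cl$noise_sd[i])
      }
      data.frame(ax = chan(g[1]), ay = chan(g[2]), az = chan(g[3]),
                 gx = chan(0), gy = chan(0), gz = chan(0))
    })
    data <- do.call(rbind, segs)
    n <- nrow(data)
    data <- cbind(t = (seq_len(n) - 1L) / spec$fs, data)
    labels <- factor(rep(cl$label, each = n_seg), levels = unique(cl$label))
    new_recording(data, spec$fs, labels)
  })
}

#' Construct a recording object
#'
#' @param data data.frame whose first column is time `t` followed by equal
#'   length numeric channel columns.
#' @param fs sampling rate in Hz.
#' @param labels optional per-sample class labels (factor or character).
#' @return An object of class `recording`.
#' @export
new_recording <- function(data, fs, labels = NULL) {
  stop_if_not(is.data.frame(data) && nrow(data) >= 1, "data must be a non-empty data.frame")
  stop_if_not(is.numeric(fs) && fs > 0, "fs must be > 0")
  if (!is.null(labels)) {
    stop_if_not(length(labels) == nrow(data), "labels must match the number of samples")
    labels <- as.factor(labels)
  }
  structure(list(data = data, fs = fs, labels = labels), class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  chans <- setdiff(names(x$data), "t")
  cat(sprintf("<recording> %d samples at %g Hz, channels: %s\n",
              nrow(x$data), x$fs, paste(chans, collapse = ", ")))
  if (!is.null(x$labels))
    cat("  labels:", paste(levels(x$labels), collapse = ", "), "\n")
  invisible(x)
}
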