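#' Replace missing samples by the series mean
#'
#' @param series numeric vector, possibly containing `NA` gaps.
#' @return The series with every `NA` replaced by the mean of the available
#'   values; non-missing entries are untouched.
#' @examples
#' impute_missing(c(1, NA, 3))  # 1 2 3
#' @export
impute_missing <- function(series) {
  stop_if_not(is.numeric(series), "series must be numeric")
  ok <- !is.na(series)
  stop_if_not(any(ok), "cannot impute an all-missing series")
  series[!ok] <- mean(series[ok])
  series
}

#' Running median filter with edge replication
#'
#' Each output sample is the median of a `width`-wide neighborhood of the
#' input; the series is padded by replicating its first and last values so
#' the output keeps the input length without biasing the edges toward zero.
#'
#' @param series numeric vector.
#' @param width odd window width (>= 1). `width = 1` is the identity.
#' @return Filtered numeric vector of the same length.
#' @examples
#' median_filter(c(1, 9, 1), 3)  # 1 1 1
#' @export
median_filter <- function(series, width = 3L) {
  stop_if_not(is_count(width, 1L) && width %% 2 == 1, "width must be an odd count >= 1")
  if (width == 1L || length(series) == 0L) return(series)
  h <- (width - 1L) / 2L
  padded <- c(rep(series[1L], h), series, rep(series[length(series)], h))
  out <- stats::runmed(padded, width, endrule = "keep")
  as.numeric(out[(h + 1L):(h + length(series))])
}

#' Zero-phase Butterworth low-pass filter
#'
#' Designs a Butterworth low-pass filter and applies it forward and backward
#' ([signal::filtfilt()]), giving zero phase distortion (at the cost of the
#' magnitude response being applied twice). Defaults follow the standard
#' inertial-signal denoising setting: 3rd order, 20 Hz corner.
#'
#' @param series numeric vector.
#' @param fs sampling rate in Hz.
#' @param corner_hz corner (-3 dB per pass) frequency; must be below `fs/2`.
#' @param order filter order.
#' @return Filtered numeric vector of the same length.
#' @export
lowpass_filter <- function(series, fs, corner_hz = 20, order = 3L) {
  stop_if_not(is.numeric(fs) && fs > 0, "fs must be > 0")
  stop_if_not(corner_hz > 0 && corner_hz < fs / 2,
              "corner_hz must lie strictly below the Nyquist frequency fs/2")
  stop_if_not(is_count(order, 1L), "order must be a positive count")
  bf <- signal::butter(order, corner_hz / (fs / 2), type = "low")
  # odd-reflection padding suppresses the start-up transient of the
  # forward and backward passes
  n <- length(series)
  if (n < 2L) return(series)
  pad <- min(n - 1L, 30L * order)
  head_pad <- 2 * series[1L] - series[(pad + 1L):2L]
  tail_pad <- 2 * series[n] - series[(n - 1L):(n - pad)]
  out <- signal::filtfilt(bf, c(head_pad, series, tail_pad))
  as.numeric(out[(pad + 1L):(pad + n)])
}

#' Sliding-window specification
#'
#' @param width_s window width in seconds.
#' @param overlap_fraction fraction of each window shared with the next, in
#'   `[0, 1)`. The stride is `round(width_samples * (1 - overlap_fraction))`.
#' @param fs sampling rate used to derive `width_samples = round(width_s * fs)`.
#' @return An object of class `window_spec` with fields `width_s`,
#'   `overlap_fraction`, `width_samples` and `stride`.
#' @examples
#' window_spec(2.56, 0.5, fs = 50)  # 128-sample windows, stride 64
#' @export
window_spec <- function(width_s = 2.56, overlap_fraction = 0.5, fs) {
  stop_if_not(is.numeric(width_s) && width_s > 0, "width_s must be > 0")
  stop_if_not(is.numeric(overlap_fraction) && overlap_fraction >= 0 && overlap_fraction < 1,
              "overlap_fraction must lie in [0, 1)")
  stop_if_not(is.numeric(fs) && fs > 0, "fs must be > 0")
  width_samples <- as.integer(round(width_s * fs))
  stride <- as.integer(round(width_samples * (1 - overlap_fraction)))
  stop_if_not(width_samples >= 2L, "windows must span at least 2 samples")
  stop_if_not(stride >= 1L, "stride must be at least 1 sample")
  structure(list(width_s = width_s, overlap_fraction = overlap_fraction,
                 width_samples = width_samples, stride = stride),
            class = "window_spec")
}

#' Segment a recording into fixed-width windows
#'
#' Windows start at sample offsets `0, stride, 2*stride, ...` (0-based,
#' half-open `[start, start + W)`); only windows fully inside the recording
#' are kept. Each window's label is the majority of its per-sample labels,
#' with ties resolved toward the label occurring earliest in the window.
#'
#' @param recording a [new_recording()] object.
#' @param spec a [window_spec()] (its `fs` derivation must match the
#'   recording; pass `fs = recording$fs` when building it).
#' @return A list with `windows` (list of per-window data.frames of channel
#'   samples), `starts` (0-based offsets) and `labels` (factor or NULL).
#'   A too-short recording yields zero windows with a warning.
#' @export
segment_recording <- function(recording, spec) {
  stop_if_not(inherits(recording, "recording"), "recording must be a recording object")
  stop_if_not(inherits(spec, "window_spec"), "spec must be a window_spec")
  chans <- recording$data[, setdiff(names(recording$data), "t"), drop = FALSE]
  L <- nrow(chans); W <- spec$width_samples; stride <- spec$stride
  if (L < W) {
    warning("recording shorter than one window; returning zero windows")
    return(list(windows = list(), starts = integer(0), labels = NULL))
  }
  starts <- seq.int(0L, L - W, by = stride)
  windows <- lapply(starts, function(s) chans[(s + 1L):(s + W), , drop = FALSE])
  labels <- NULL
  if (!is.null(recording$labels)) {
    labels <- vapply(starts, function(s) {
      lab <- as.character(recording$labels[(s + 1L):(s + W)])
      counts <- table(factor(lab, levels = unique(lab)))  # unique() = order of first occurrence
      names(counts)[which.max(counts)]
    }, character(1))
    labels <- factor(labels, levels = levels(recording$labels))
  }
  list(windows = windows, starts = as.integer(starts), labels = labels)
}
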