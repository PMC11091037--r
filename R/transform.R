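#' @title Time-frequency transformation
#' @name transform
#' @description
#' The alpha band is decomposed with a real Morlet continuous wavelet
#' transform over integer scales 8-13. At 128 Hz with the Morlet center
#' frequency 0.8125 cycles per sampling period, the pseudo-frequency mapping
#' `f = f_c / (s * delta)` places scales 8-10 at 13-10.4 Hz (High Alpha) and
#' scales 11-13 at 9.45-8 Hz (Low Alpha), so the sub-band split is a row
#' slice of one six-scale decomposition. The stimulus span is then cut into
#' equal-length period groups and each group into overlapping sliding
#' windows.
NULL

#' Default Morlet center frequency (cycles per sampling period)
#' @keywords internal
MORLET_FC <- 0.8125

#' Map a wavelet scale to its pseudo-frequency
#'
#' `f_s = f_c / (s * delta)`: the approximate frequency in Hz that a Morlet
#' wavelet at scale `scale` responds to, given the wavelet center frequency
#' and the sampling period.
#'
#' @param scale Positive wavelet scale (vectorized).
#' @param center_freq Wavelet center frequency in cycles per sampling
#'   period (real Morlet: 0.8125).
#' @param sampling_period Sampling period in seconds (1/fs).
#' @return Pseudo-frequency in Hz.
#' @export
scale_to_frequency <- function(scale, center_freq = MORLET_FC,
                               sampling_period = 1 / 128) {
  if (any(scale <= 0)) stop("scale must be positive")
  if (sampling_period <= 0) stop("sampling_period must be positive")
  center_freq / (scale * sampling_period)
}

#' Map a frequency to its wavelet scale
#'
#' Inverse of [scale_to_frequency()].
#'
#' @param freq_hz Frequency in Hz (positive; vectorized).
#' @inheritParams scale_to_frequency
#' @return Wavelet scale.
#' @export
frequency_to_scale <- function(freq_hz, center_freq = MORLET_FC,
                               sampling_period = 1 / 128) {
  if (any(freq_hz <= 0)) stop("freq_hz must be positive")
  center_freq / (freq_hz * sampling_period)
}

#' Wavelet scales for an alpha sub-band
#'
#' @param name One of `"alpha"` (scales 8-13, 8-13 Hz), `"high_alpha"`
#'   (scales 8-10, 11-13 Hz) or `"low_alpha"` (scales 11-13, 8-10 Hz).
#' @return A list of class `scale_spec` with `name`, integer `scales` and
#'   `freq_range_hz`.
#' @export
subband_scales <- function(name = c("alpha", "high_alpha", "low_alpha")) {
  name <- match.arg(name)
  spec <- switch(name,
    high_alpha = list(scales = 8:10, freq_range_hz = c(11, 13)),
    low_alpha  = list(scales = 11:13, freq_range_hz = c(8, 10)),
    alpha      = list(scales = 8:13, freq_range_hz = c(8, 13)))
  structure(c(list(name = name), spec), class = "scale_spec")
}

# Real Morlet mother wavelet cos(5t) exp(-t^2/2), sampled on [-8, 8].
.morlet_psi <- function(t) cos(5 * t) * exp(-t^2 / 2)

#' Morlet continuous wavelet transform
#'
#' Correlates a 1-D signal with scaled copies of the real Morlet wavelet
#' `cos(5t) exp(-t^2/2)` (L2 normalization `1/sqrt(s)`), returning one
#' coefficient row per scale over the full signal length. Edges are handled
#' by zero padding. The transform is linear in the input and, the wavelet
#' being even, phase-neutral.
#'
#' @param x Numeric vector (one channel's samples).
#' @param scales Positive wavelet scales (default: the six alpha scales).
#' @param fs Sampling rate in Hz.
#' @param center_freq Morlet center frequency used for the scale to
#'   frequency mapping recorded on the result.
#' @return An object of class `cwt_coefficients`: list with `coeffs`
#'   (`length(scales)` x `length(x)` matrix), `scales`, `fs`,
#'   `wavelet_center_freq`, `sampling_period`.
#' @export
cwt_morlet <- function(x, scales = 8:13, fs = 128, center_freq = MORLET_FC) {
  if (length(x) == 0) stop("signal must be non-empty")
  if (!all(is.finite(x))) stop("signal must be finite")
  if (any(scales <= 0)) stop("scales must be positive")
  n <- length(x)
  coeffs <- matrix(NA_real_, nrow = length(scales), ncol = n)
  k_max <- ceiling(8 * max(scales))
  nfft <- stats::nextn(n + 2 * k_max, 2)
  X <- stats::fft(c(x, rep(0, nfft - n)))
  for (si in seq_along(scales)) {
    s <- scales[si]
    k <- ceiling(8 * s)
    kern <- .morlet_psi((-k:k) / s) / sqrt(s)
    # correlation with an even kernel == convolution; 'same' output
    K <- stats::fft(c(kern, rep(0, nfft - length(kern))))
    full <- Re(stats::fft(X * K, inverse = TRUE)) / nfft
    coeffs[si, ] <- full[(k + 1):(k + n)]
  }
  structure(list(coeffs = coeffs, scales = scales, fs = fs,
                 wavelet_center_freq = center_freq,
                 sampling_period = 1 / fs),
            class = "cwt_coefficients")
}

#' @export
print.cwt_coefficients <- function(x, ...) {
  cat(sprintf("<cwt_coefficients: %d scales (%s) x %d samples @ %g Hz>\n",
              length(x$scales), paste(range(x$scales), collapse = "-"),
              ncol(x$coeffs), x$fs))
  invisible(x)
}

#' Restrict a CWT to the scales of one sub-band
#'
#' @param cwt A [cwt_morlet()] result computed over scales that include the
#'   sub-band's.
#' @param spec A [subband_scales()] spec (or sub-band name).
#' @return A `cwt_coefficients` with only the sub-band's scale rows.
#' @export
slice_subband <- function(cwt, spec) {
  if (is.character(spec)) spec <- subband_scales(spec)
  idx <- match(spec$scales, cwt$scales)
  if (anyNA(idx))
    stop("CWT lacks scales: ",
         paste(spec$scales[is.na(idx)], collapse = ", "))
  cwt$coeffs <- cwt$coeffs[idx, , drop = FALSE]
  cwt$scales <- cwt$scales[idx]
  cwt
}

#' Equal-length period-group boundaries over the stimulus span
#'
#' Splits the post-baseline stimulus span into `n_groups` contiguous
#' equal-length blocks and returns the 0-based sample boundaries. For the
#' DEAP layout (128 Hz, 3 s baseline, 63 s total) the 4-group boundaries are
#' 384, 2304, 4224, 6144, 8064 and the 6-group boundaries insert 1664, 2944,
#' 5504, 6784. Intervals are half-open `[start, end)`.
#'
#' @param n_groups Number of period groups (typically 4 or 6).
#' @param fs Sampling rate in Hz.
#' @param baseline_s Baseline duration in seconds.
#' @param total_s Total trial duration in seconds.
#' @return A list of class `period_grouping` with `n_groups`, `boundaries`
#'   (length `n_groups + 1`) and `baseline_end`.
#' @export
period_boundaries <- function(n_groups, fs = 128, baseline_s = 3,
                              total_s = 63) {
  if (n_groups < 1) stop("n_groups must be >= 1")
  span <- (total_s - baseline_s) * fs
  if (span <= 0) stop("total_s must exceed baseline_s")
  if (abs(span / n_groups - round(span / n_groups)) > 1e-9)
    stop("stimulus span of ", span, " samples is not divisible into ",
         n_groups, " equal groups")
  b0 <- baseline_s * fs
  boundaries <- b0 + round(span / n_groups) * (0:n_groups)
  structure(list(n_groups = n_groups, boundaries = boundaries,
                 baseline_end = b0),
            class = "period_grouping")
}

#' Slice a CWT to one period group
#'
#' Keeps coefficient columns in the half-open 0-based sample interval
#' `[boundaries[g], boundaries[g+1])`.
#'
#' @param cwt A `cwt_coefficients`.
#' @param grouping A [period_boundaries()] result.
#' @param g Period-group index, 1-based.
#' @return A `cwt_coefficients` restricted to the group's columns.
#' @export
slice_period <- function(cwt, grouping, g) {
  if (g < 1 || g > grouping$n_groups)
    stop("period group ", g, " out of range 1..", grouping$n_groups)
  lo <- grouping$boundaries[g]
  hi <- grouping$boundaries[g + 1]
  if (hi > ncol(cwt$coeffs))
    stop("grouping extends past the coefficient span")
  cwt$coeffs <- cwt$coeffs[, (lo + 1):hi, drop = FALSE]
  cwt
}

#' Overlapping sliding-window specification
#'
#' @param wl_s Window length in seconds.
#' @param osw_s Overlapping shift-window step in seconds; `0 < osw_s <=
#'   wl_s`.
#' @return A list of class `window_spec`.
#' @export
window_spec <- function(wl_s = 3, osw_s = 0.5) {
  if (!(osw_s > 0 && osw_s <= wl_s))
    stop("need 0 < osw_s <= wl_s")
  structure(list(wl_s = wl_s, osw_s = osw_s), class = "window_spec")
}

.window_samples <- function(spec, fs) {
  wl_n <- spec$wl_s * fs
  step_n <- spec$osw_s * fs
  if (abs(wl_n - round(wl_n)) > 1e-9 || abs(step_n - round(step_n)) > 1e-9)
    stop("wl_s and osw_s must be integer numbers of samples at fs = ", fs)
  list(wl_n = as.integer(round(wl_n)), step_n = as.integer(round(step_n)))
}

#' Number of overlapping windows in a span
#'
#' The standard sliding-window count `floor((N - wl*fs) / (osw*fs)) + 1`:
#' windows start every `osw_s` seconds and the last one must fit entirely.
#' A 60-s span at 128 Hz with 3-s windows shifted by 2 s yields 29 windows.
#'
#' @param n_samples Span length in samples.
#' @param spec A [window_spec()].
#' @param fs Sampling rate in Hz.
#' @return Integer window count.
#' @export
window_count <- function(n_samples, spec, fs = 128) {
  w <- .window_samples(spec, fs)
  if (n_samples < w$wl_n)
    stop("span of ", n_samples, " samples is shorter than one window (",
         w$wl_n, " samples)")
  as.integer((n_samples - w$wl_n) %/% w$step_n + 1L)
}

#' Iterate overlapping windows of a CWT
#'
#' Window `k` (1-based) covers 0-based samples
#' `[(k-1)*step_n, (k-1)*step_n + wl_n)` of the coefficient span.
#'
#' @param cwt A `cwt_coefficients` (typically already period-sliced).
#' @param spec A [window_spec()].
#' @return A list with one element per window: `list(window_index, start,
#'   coeffs)` where `coeffs` is the scales x `wl_n` slice and `start` the
#'   0-based offset within the span.
#' @export
iterate_windows <- function(cwt, spec) {
  w <- .window_samples(spec, cwt$fs)
  n <- ncol(cwt$coeffs)
  cnt <- window_count(n, spec, cwt$fs)
  lapply(seq_len(cnt), function(k) {
    start <- (k - 1L) * w$step_n
    list(window_index = k, start = start,
         coeffs = cwt$coeffs[, (start + 1):(start + w$wl_n), drop = FALSE])
  })
}
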