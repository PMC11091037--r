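#' @title Time-frequency features
#' @name features
#' @description
#' Thirteen features are computed per window, per wavelet scale, per
#' channel, on the raw real CWT coefficients: F1 mean, F2 wavelet entropy,
#' F3 mean absolute, F4 standard deviation, F5 Hjorth activity, F6 Hjorth
#' mobility, F7 Hjorth complexity, F8 zero crossings, F9 Higuchi fractal
#' dimension, F10 band power, F11 Shannon entropy, F12 differential entropy,
#' F13 amplitude maximum.
NULL

#' Names of the 13 features in canonical order
#' @return Character vector of length 13.
#' @export
feature_names <- function() {
  c("mean", "wavelet_entropy", "mean_abs", "std",
    "hjorth_activity", "hjorth_mobility", "hjorth_complexity",
    "zero_crossing", "higuchi_fd", "band_power",
    "shannon_entropy", "differential_entropy", "amplitude_max")
}

#' Feature computation options
#'
#' @param n_bins Histogram bins for Shannon entropy (equal-width over
#'   the window's range).
#' @param k_max Maximum lag for the Higuchi fractal dimension.
#' @param mean_abs_variant `"abs_of_mean"` computes `|mean(w)|` (the formula
#'   as printed, with the absolute value outside the sum);
#'   `"mean_of_abs"` computes `mean(|w|)` (what the feature's name
#'   suggests).
#' @param amplitude_abs If `TRUE`, F13 is `max(|w|)` instead of the plain
#'   maximum `max(w)`.
#' @param de_standard If `TRUE`, differential entropy uses the Gaussian
#'   closed form `0.5*ln(2*pi*e*sigma^2)`; default is `0.5*ln(2*pi*sigma^2)`
#'   (the `e`-less variant).
#' @return A list of class `feature_options`.
#' @export
feature_options <- function(n_bins = 10, k_max = 8,
                            mean_abs_variant = c("abs_of_mean", "mean_of_abs"),
                            amplitude_abs = FALSE, de_standard = FALSE) {
  if (n_bins < 2) stop("n_bins must be >= 2")
  if (k_max < 2) stop("k_max must be >= 2 (slope undefined from one point)")
  structure(list(n_bins = n_bins, k_max = k_max,
                 mean_abs_variant = match.arg(mean_abs_variant),
                 amplitude_abs = isTRUE(amplitude_abs),
                 de_standard = isTRUE(de_standard)),
            class = "feature_options")
}

#' Basic window statistics
#'
#' @param w Numeric window (length >= 2).
#' @param opts A [feature_options()].
#' @return Named list: `mean`, `mean_abs`, `std` (N-1 denominator),
#'   `amplitude_max`, `zero_crossings` (strict sign alternations; literal
#'   zeros neither terminate nor start a crossing), `band_power` (mean of
#'   squared values).
#' @export
basic_stats <- function(w, opts = feature_options()) {
  if (length(w) < 2) stop("window too short: need >= 2 samples")
  sg <- sign(w)
  sg <- sg[sg != 0]
  list(
    mean = mean(w),
    mean_abs = if (opts$mean_abs_variant == "abs_of_mean") abs(mean(w))
               else mean(abs(w)),
    std = stats::sd(w),
    amplitude_max = if (opts$amplitude_abs) max(abs(w)) else max(w),
    zero_crossings = if (length(sg) < 2) 0L else sum(sg[-1] != sg[-length(sg)]),
    band_power = mean(w^2))
}

#' Hjorth parameters
#'
#' Activity is the sample variance; mobility
#' `sqrt(var(diff(w)) / var(w))`; complexity the ratio of the first
#' difference's mobility to the window's. First differences stand in for
#' derivatives.
#'
#' @param w Numeric window (length >= 3).
#' @return Named list `activity`, `mobility`, `complexity`.
#' @export
hjorth <- function(w) {
  if (length(w) < 3) stop("window too short: need >= 3 samples")
  v0 <- stats::var(w)
  if (v0 == 0) stop("degenerate signal: zero variance window")
  d1 <- diff(w)
  v1 <- stats::var(d1)
  if (v1 == 0) stop("degenerate signal: zero variance first difference")
  d2 <- diff(d1)
  v2 <- stats::var(d2)
  mob <- sqrt(v1 / v0)
  list(activity = v0, mobility = mob,
       complexity = sqrt(v2 / v1) / mob)
}

#' Entropy features
#'
#' Wavelet entropy treats the normalized squared coefficients within the
#' window (`p_i = w_i^2 / sum(w^2)`) as an energy distribution over time and
#' returns `-sum p log2 p`. Shannon entropy bins the window values into
#' `n_bins` equal-width bins over `[min, max]` and applies the same formula
#' to the bin frequencies. Differential entropy is `0.5*ln(2*pi*sigma^2)`
#' with the sample variance (or the Gaussian form with `e` when
#' `de_standard`).
#'
#' @param w Numeric window (length >= 2).
#' @param opts A [feature_options()].
#' @return Named list `wavelet_entropy`, `shannon_entropy`,
#'   `differential_entropy`.
#' @export
entropies <- function(w, opts = feature_options()) {
  if (length(w) < 2) stop("window too short: need >= 2 samples")
  e <- sum(w^2)
  if (e == 0) stop("degenerate signal: wavelet entropy undefined for an all-zero window")
  p <- w^2 / e
  we <- -sum(ifelse(p > 0, p * log2(p), 0))
  rng <- range(w)
  if (rng[1] == rng[2]) {
    se <- 0
  } else {
    brk <- seq(rng[1], rng[2], length.out = opts$n_bins + 1)
    cnt <- tabulate(findInterval(w, brk, rightmost.closed = TRUE,
                                 all.inside = TRUE), nbins = opts$n_bins)
    q <- cnt / length(w)
    se <- -sum(ifelse(q > 0, q * log2(q), 0))
  }
  s2 <- stats::var(w)
  de <- if (opts$de_standard) 0.5 * log(2 * pi * exp(1) * s2)
        else 0.5 * log(2 * pi * s2)
  list(wavelet_entropy = we, shannon_entropy = se, differential_entropy = de)
}

#' Higuchi fractal dimension
#'
#' Standard Higuchi construction: for each lag `k = 1..k_max` and offset
#' `m = 1..k`, the normalized curve length
#' `L_m(k) = (sum |x[m+jk] - x[m+(j-1)k]|) * (N-1) / (J*k) / k` with
#' `J = floor((N-m)/k)`; the mean curve length `l(k)` is averaged over `m`,
#' and the dimension is the least-squares slope of `ln l(k)` against
#' `ln(1/k)`. Close to 1 for smooth curves, close to 2 for white noise.
#'
#' @param w Numeric window with `length(w) >= 2*k_max`.
#' @param k_max Maximum lag (>= 2).
#' @return Fractal dimension estimate.
#' @export
higuchi_fd <- function(w, k_max = 8) {
  n <- length(w)
  if (k_max < 2) stop("k_max must be >= 2 (slope undefined from one point)")
  if (n < 2 * k_max)
    stop("window too short for k_max = ", k_max, ": need >= ", 2 * k_max,
         " samples")
  lk <- numeric(k_max)
  for (k in seq_len(k_max)) {
    # every lag-k difference belongs to exactly one offset series m = i mod k
    d <- abs(w[(k + 1):n] - w[1:(n - k)])
    pad <- (k - length(d) %% k) %% k
    sums <- rowSums(matrix(c(d, numeric(pad)), nrow = k))
    j <- (n - (1:k)) %/% k
    lk[k] <- mean(sums * (n - 1) / (j * k) / k)
  }
  ks <- seq_len(k_max)
  x <- log(1 / ks)
  y <- log(lk)
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

#' All 13 features of one window
#'
#' @param w Numeric window (one scale, one channel).
#' @param opts A [feature_options()].
#' @return Named numeric vector of length 13 in [feature_names()] order.
#' @export
feature_vector <- function(w, opts = feature_options()) {
  b <- basic_stats(w, opts)
  h <- hjorth(w)
  e <- entropies(w, opts)
  out <- c(b$mean, e$wavelet_entropy, b$mean_abs, b$std,
           h$activity, h$mobility, h$complexity,
           b$zero_crossings, higuchi_fd(w, opts$k_max), b$band_power,
           e$shannon_entropy, e$differential_entropy, b$amplitude_max)
  names(out) <- feature_names()
  if (any(!is.finite(out)))
    stop("non-finite feature value(s): ",
         paste(names(out)[!is.finite(out)], collapse = ", "))
  out
}

#' Assemble one feature-table row from per-scale, per-channel windows
#'
#' Column order is channel-major: for each channel, for each scale, the 13
#' features F1..F13. Two channels and three scales give the canonical
#' 13 x 3 x 2 = 78 columns.
#'
#' @param windows Nested list: `windows[[channel]][[scale]]` is the numeric
#'   window for that (channel, scale) pair; channel and scale names are
#'   taken from the list names. All windows must share one length.
#' @param meta One-row data frame (or named list) of row metadata
#'   (`subject_id`, `trial_id`, `window_index`, `period_group`, `sub_band`,
#'   `class_label`).
#' @param opts A [feature_options()].
#' @return A one-row [feature_table()].
#' @export
assemble_feature_row <- function(windows, meta, opts = feature_options()) {
  channels <- names(windows)
  if (is.null(channels)) stop("windows must be a named list of channels")
  lens <- unlist(lapply(windows, function(ch) vapply(ch, length, integer(1))))
  if (length(unique(lens)) != 1)
    stop("ragged windows: all (scale, channel) windows must share one length")
  vals <- list(); cm <- list()
  for (ch in channels) {
    scales <- names(windows[[ch]])
    if (is.null(scales)) stop("windows[[", ch, "]] must be named by scale")
    for (sc in scales) {
      vals[[length(vals) + 1L]] <- feature_vector(windows[[ch]][[sc]], opts)
      cm[[length(cm) + 1L]] <- data.frame(feature_id = 1:13,
                                          scale = as.integer(sc),
                                          channel = ch)
    }
  }
  feature_table(matrix(unlist(vals), nrow = 1),
                do.call(rbind, cm),
                as.data.frame(meta))
}

# Feature rows for every window of one (sub-band, period group) cell of one
# trial, on a fast matrix path (column layout identical to
# assemble_feature_row: channel-major, then scale, then F1..F13).
# cwt_by_channel: named list of full-span cwt_coefficients per channel.
.featurize_trial_cell <- function(cwt_by_channel, band, grouping, g, wspec,
                                  opts, meta) {
  sub <- lapply(cwt_by_channel, function(cw)
    slice_period(slice_subband(cw, band), grouping, g))
  wins_per_ch <- lapply(sub, iterate_windows, spec = wspec)
  n_win <- length(wins_per_ch[[1]])
  channels <- names(cwt_by_channel)
  scales <- sub[[1]]$scales
  vals <- matrix(NA_real_, nrow = n_win,
                 ncol = 13L * length(scales) * length(channels))
  cm <- list()
  col <- 0L
  for (ch in channels) for (si in seq_along(scales)) {
    for (k in seq_len(n_win))
      vals[k, col + 1:13] <- feature_vector(
        wins_per_ch[[ch]][[k]]$coeffs[si, ], opts)
    cm[[length(cm) + 1L]] <- data.frame(feature_id = 1:13,
                                        scale = as.integer(scales[si]),
                                        channel = ch)
    col <- col + 13L
  }
  row_meta <- as.data.frame(meta)[rep(1L, n_win), , drop = FALSE]
  row_meta$window_index <- seq_len(n_win)
  row_meta$period_group <- g
  row_meta$sub_band <- band
  rownames(row_meta) <- NULL
  feature_table(vals, do.call(rbind, cm), row_meta)
}

#' Extract the feature table for one sub-band and period group
#'
#' Runs the full per-trial front end (band-pass filter, channel selection,
#' six-scale Morlet CWT) once per recording, then slices the requested
#' sub-band and period group and emits one feature row per overlapping
#' window per trial.
#'
#' @param rs A [recording_set()].
#' @param band Sub-band name (`"alpha"`, `"high_alpha"`, `"low_alpha"`).
#' @param grouping A [period_boundaries()] result.
#' @param g Period-group index.
#' @param wspec A [window_spec()].
#' @param channels Channels to use (default O1/O2).
#' @param bandpass A [bandpass_spec()] applied before the CWT.
#' @param opts A [feature_options()].
#' @param class_labels Optional vector of per-trial class labels copied into
#'   `row_meta$class_label`.
#' @return A [feature_table()] with `13 * n_scales * n_channels` columns.
#' @export
extract_features <- function(rs, band, grouping, g, wspec,
                             channels = c("O1", "O2"),
                             bandpass = bandpass_spec(),
                             opts = feature_options(),
                             class_labels = NULL) {
  stopifnot(inherits(rs, "recording_set"))
  cwts <- lapply(rs$recordings, function(rec)
    .trial_cwt(rec, channels, bandpass))
  tabs <- lapply(seq_along(cwts), function(i) {
    rec <- rs$recordings[[i]]
    meta <- data.frame(subject_id = rec$subject_id, trial_id = rec$trial_id,
                       window_index = NA_integer_, period_group = NA_integer_,
                       sub_band = band,
                       class_label = if (is.null(class_labels)) NA
                                     else class_labels[i])
    .featurize_trial_cell(cwts[[i]], band, grouping, g, wspec, opts, meta)
  })
  do.call(rbind_feature_tables, tabs)
}

# band-pass, channel-select and CWT one recording; named list per channel
.trial_cwt <- function(rec, channels, bandpass, scales = 8:13) {
  rec <- select_channels(bandpass_filter(rec, bandpass), channels)
  out <- lapply(seq_along(channels), function(i)
    cwt_morlet(rec$samples[i, ], scales = scales, fs = rec$fs))
  names(out) <- channels
  out
}

#' Row-bind feature tables with identical column metadata
#'
#' @param ... [feature_table()] objects sharing `column_meta`.
#' @return The stacked [feature_table()].
#' @export
rbind_feature_tables <- function(...) {
  tabs <- list(...)
  if (length(tabs) == 1) return(tabs[[1]])
  ref <- tabs[[1]]$column_meta
  for (t in tabs[-1])
    if (!identical(t$column_meta, ref))
      stop("feature tables have mismatched column metadata")
  feature_table(do.call(rbind, lapply(tabs, `[[`, "values")),
                ref,
                do.call(rbind, lapply(tabs, `[[`, "row_meta")))
}
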