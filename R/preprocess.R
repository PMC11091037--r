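#' Alpha-band band-pass filter specification
#'
#' Butterworth band-pass design for isolating the alpha rhythm (8-13 Hz by
#' default). Applied forward-backward (zero-phase) by default so that the
#' filter does not shift the timing of the relax onset the pipeline is built
#' to localize.
#'
#' @param low_hz,high_hz Passband edges in Hz.
#' @param order Butterworth order (per pass; default 4).
#' @param zero_phase If `TRUE`, filter forward and backward (`filtfilt`).
#' @return A list of class `bandpass_spec`.
#' @export
bandpass_spec <- function(low_hz = 8, high_hz = 13, order = 4,
                          zero_phase = TRUE) {
  if (!(low_hz > 0 && low_hz < high_hz))
    stop("need 0 < low_hz < high_hz")
  if (order < 1) stop("order must be >= 1")
  structure(list(low_hz = low_hz, high_hz = high_hz, order = order,
                 zero_phase = isTRUE(zero_phase)),
            class = "bandpass_spec")
}

#' Band-pass filter a recording
#'
#' Applies the Butterworth band-pass of `spec` to every channel. Passband
#' gain is ~1 and out-of-band energy is strongly attenuated; shape and
#' metadata are preserved.
#'
#' @param rec A [recording()].
#' @param spec A [bandpass_spec()].
#' @return A filtered [recording()].
#' @export
bandpass_filter <- function(rec, spec = bandpass_spec()) {
  stopifnot(inherits(rec, "recording"), inherits(spec, "bandpass_spec"))
  nyq <- rec$fs / 2
  if (spec$high_hz >= nyq)
    stop("high_hz (", spec$high_hz, " Hz) must be below the Nyquist frequency (",
         nyq, " Hz)")
  bf <- signal::butter(spec$order,
                       c(spec$low_hz, spec$high_hz) / nyq,
                       type = "pass")
  out <- rec$samples
  for (i in seq_len(nrow(out))) {
    x <- rec$samples[i, ]
    out[i, ] <- if (spec$zero_phase) signal::filtfilt(bf, x)
                else signal::filter(bf, x)
  }
  rec$samples <- out
  rec
}

#' Select channels by name
#'
#' Subsets (and reorders) a recording's channels; sample values are
#' untouched. The occipital pair O1/O2 is the pipeline's default target.
#'
#' @param rec A [recording()].
#' @param names Channel labels to keep, in the desired order.
#' @return A [recording()] with only the requested channels.
#' @export
select_channels <- function(rec, names = c("O1", "O2")) {
  stopifnot(inherits(rec, "recording"))
  missing <- setdiff(names, rec$channel_names)
  if (length(missing) > 0)
    stop("unknown channel(s): ", paste(missing, collapse = ", "))
  idx <- match(names, rec$channel_names)
  rec$samples <- rec$samples[idx, , drop = FALSE]
  rec$channel_names <- rec$channel_names[idx]
  rec
}
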