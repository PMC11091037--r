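#' @title Core data containers
#' @name data_model
#' @description
#' The package moves EEG through three containers: a `Recording` (one trial's
#' channels-by-samples matrix plus acquisition metadata), a `recording_set`
#' (an ordered list of recordings with parallel valence/arousal ratings on
#' the 1-9 self-assessment scale), and a `feature_table` (a windows-by-
#' features matrix with per-column feature/scale/channel metadata and
#' per-row trial/window/period metadata).
NULL

#' DEAP 32-channel electrode ordering
#'
#' Channel labels in the order used by the DEAP preprocessed release, so that
#' occipital channels O1/O2 can be resolved by name rather than index.
#'
#' @return Character vector of 32 10-20-system electrode labels.
#' @export
deap_channels <- function() {
  c("Fp1", "AF3", "F3", "F7", "FC5", "FC1", "C3", "T7",
    "CP5", "CP1", "P3", "P7", "PO3", "O1", "Oz", "Pz",
    "Fp2", "AF4", "Fz", "F4", "F8", "FC6", "FC2", "Cz",
    "C4", "T8", "CP6", "CP2", "P4", "P8", "PO4", "O2")
}

#' Construct a single-trial EEG recording
#'
#' @param samples Numeric matrix, channels x samples, in microvolts.
#' @param fs Sampling rate in Hz.
#' @param channel_names Character vector naming the rows of `samples`.
#' @param baseline_s Baseline (neutral-state) duration in seconds at the
#'   start of the trial; must correspond to an integer number of samples.
#' @param subject_id,trial_id Identifier strings.
#' @return An object of class `recording`.
#' @export
recording <- function(samples, fs, channel_names,
                      baseline_s = 0, subject_id = "S01", trial_id = "T01") {
  samples <- as.matrix(samples)
  if (!is.numeric(samples) || !all(is.finite(samples)))
    stop("recording samples must be finite numeric values")
  if (length(channel_names) != nrow(samples))
    stop("channel_names length (", length(channel_names),
         ") does not match channel count (", nrow(samples), ")")
  if (fs <= 0) stop("fs must be positive")
  n_base <- baseline_s * fs
  if (abs(n_base - round(n_base)) > 1e-9)
    stop("baseline_s * fs must be an integer number of samples")
  rownames(samples) <- channel_names
  structure(
    list(samples = samples, fs = fs,
         channel_names = as.character(channel_names),
         baseline_s = baseline_s,
         subject_id = subject_id, trial_id = trial_id),
    class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording %s/%s: %d ch x %d samples @ %g Hz (%.1f s, baseline %g s)>\n",
              x$subject_id, x$trial_id, nrow(x$samples), ncol(x$samples),
              x$fs, ncol(x$samples) / x$fs, x$baseline_s))
  invisible(x)
}

#' Construct a set of recordings with ratings
#'
#' @param recordings List of [recording()] objects sharing sampling rate and
#'   channel layout.
#' @param ratings Data frame with numeric columns `valence` and `arousal`,
#'   both on the 1-9 scale, one row per recording.
#' @return An object of class `recording_set`.
#' @export
recording_set <- function(recordings, ratings) {
  ratings <- as.data.frame(ratings)
  if (length(recordings) != nrow(ratings))
    stop("recordings (", length(recordings), ") and ratings (", nrow(ratings),
         ") must have the same length")
  if (!all(c("valence", "arousal") %in% names(ratings)))
    stop("ratings must have columns 'valence' and 'arousal'")
  if (length(recordings) > 0) {
    if (nrow(ratings) > 0 &&
        any(ratings$valence < 1 | ratings$valence > 9 |
            ratings$arousal < 1 | ratings$arousal > 9))
      stop("valence/arousal ratings must lie in [1, 9]")
    fs <- vapply(recordings, function(r) r$fs, numeric(1))
    if (length(unique(fs)) != 1)
      stop("all recordings in a set must share the sampling rate")
    ch <- lapply(recordings, function(r) r$channel_names)
    if (length(unique(vapply(ch, paste, character(1), collapse = "|"))) != 1)
      stop("all recordings in a set must share channel names")
  }
  structure(list(recordings = recordings, ratings = ratings),
            class = "recording_set")
}

#' @export
length.recording_set <- function(x) length(x$recordings)

#' @export
print.recording_set <- function(x, ...) {
  cat(sprintf("<recording_set: %d trials>\n", length(x)))
  invisible(x)
}

#' Layout description for a DEAP-style array container
#'
#' Describes how to interpret a serialized container holding
#' `data[trials x channels x samples]` and `labels[trials x >=2]`: the
#' sampling rate, channel ordering, baseline duration and which label
#' columns hold valence and arousal. DEAP stores four rating columns
#' (valence, arousal, dominance, liking); only the first two are consumed.
#'
#' @param fs Sampling rate in Hz (DEAP preprocessed: 128).
#' @param channel_names Channel labels in array order.
#' @param baseline_s Baseline duration in seconds (DEAP: 3).
#' @param valence_col,arousal_col Column indices in the labels matrix.
#' @return A list of class `container_layout`.
#' @export
deap_layout <- function(fs = 128, channel_names = deap_channels(),
                        baseline_s = 3, valence_col = 1, arousal_col = 2) {
  structure(list(fs = fs, channel_names = channel_names,
                 baseline_s = baseline_s,
                 valence_col = valence_col, arousal_col = arousal_col),
            class = "container_layout")
}

#' Write a recording set to a single-file array container
#'
#' Serializes the set as a list with a `data` array
#' (trials x channels x samples) and a `labels` matrix (trials x 4 in DEAP
#' order: valence, arousal, dominance, liking; the last two written as NA
#' when unknown), plus identifier attributes. The on-disk format is an R
#' serialization (`.rds`), mirroring the shape of DEAP's preprocessed
#' per-subject files so that converted real data drops in.
#'
#' @param rs A [recording_set()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_recording_set <- function(rs, path) {
  stopifnot(inherits(rs, "recording_set"))
  n <- length(rs)
  if (n == 0) {
    obj <- list(data = array(numeric(0), dim = c(0, 0, 0)),
                labels = matrix(numeric(0), nrow = 0, ncol = 4),
                fs = NA_real_, channel_names = character(0),
                baseline_s = NA_real_,
                subject_ids = character(0), trial_ids = character(0))
    saveRDS(obj, path)
    return(invisible(path))
  }
  n_ch <- nrow(rs$recordings[[1]]$samples)
  n_sm <- ncol(rs$recordings[[1]]$samples)
  dat <- array(NA_real_, dim = c(n, n_ch, n_sm))
  for (i in seq_len(n)) {
    s <- rs$recordings[[i]]$samples
    if (!identical(dim(s), c(n_ch, n_sm)))
      stop("trial ", i, " has shape ", nrow(s), "x", ncol(s),
           ", expected ", n_ch, "x", n_sm)
    dat[i, , ] <- s
  }
  labels <- cbind(rs$ratings$valence, rs$ratings$arousal, NA_real_, NA_real_)
  obj <- list(
    data = dat, labels = labels,
    fs = rs$recordings[[1]]$fs,
    channel_names = rs$recordings[[1]]$channel_names,
    baseline_s = rs$recordings[[1]]$baseline_s,
    subject_ids = vapply(rs$recordings, `[[`, character(1), "subject_id"),
    trial_ids = vapply(rs$recordings, `[[`, character(1), "trial_id"))
  saveRDS(obj, path)
  invisible(path)
}

#' Load a recording set from a single-file array container
#'
#' Reads a container written by [write_recording_set()] (or any serialized
#' list with `data[trials x channels x samples]` and `labels[trials x >=2]`)
#' and materializes one [recording()] per trial. Metadata stored in the
#' container takes precedence; the `layout` fills anything missing.
#'
#' @param path Container file path.
#' @param layout A [deap_layout()] describing sampling rate, channel names,
#'   baseline and rating columns.
#' @return A [recording_set()].
#' @export
load_recording_set <- function(path, layout = deap_layout()) {
  if (!file.exists(path)) stop("container not found: ", path)
  obj <- readRDS(path)
  if (!is.list(obj) || is.null(obj$data) || is.null(obj$labels))
    stop("container must hold 'data' and 'labels' arrays")
  dat <- obj$data
  labels <- obj$labels
  if (length(dim(dat)) != 3)
    stop("'data' must be a 3-d array [trials x channels x samples]")
  n <- dim(dat)[1]
  if (n == 0) return(recording_set(list(),
                                   data.frame(valence = numeric(0),
                                              arousal = numeric(0))))
  labels <- as.matrix(labels)
  if (nrow(labels) != n)
    stop("labels rows (", nrow(labels), ") do not match trials (", n, ")")
  if (ncol(labels) < max(layout$valence_col, layout$arousal_col))
    stop("labels matrix has too few columns for the layout's rating columns")
  fs <- if (!is.null(obj$fs) && is.finite(obj$fs)) obj$fs else layout$fs
  base_s <- if (!is.null(obj$baseline_s) && is.finite(obj$baseline_s))
    obj$baseline_s else layout$baseline_s
  ch <- if (!is.null(obj$channel_names) && length(obj$channel_names) == dim(dat)[2])
    obj$channel_names else layout$channel_names
  if (length(ch) != dim(dat)[2])
    stop("layout names ", length(ch), " channels but data has ", dim(dat)[2])
  sids <- if (!is.null(obj$subject_ids)) obj$subject_ids
          else rep("S01", n)
  tids <- if (!is.null(obj$trial_ids)) obj$trial_ids
          else sprintf("T%02d", seq_len(n))
  recs <- lapply(seq_len(n), function(i)
    recording(dat[i, , , drop = TRUE], fs = fs, channel_names = ch,
              baseline_s = base_s, subject_id = sids[i], trial_id = tids[i]))
  recording_set(recs, data.frame(valence = labels[, layout$valence_col],
                                 arousal = labels[, layout$arousal_col]))
}

# ---- feature tables --------------------------------------------------------

#' Construct a feature table
#'
#' @param values Numeric matrix, rows = windows, columns = features.
#' @param column_meta Data frame with one row per column of `values`:
#'   `feature_id` (integer 1-13), `scale` (integer wavelet scale), `channel`.
#' @param row_meta Data frame with one row per row of `values`: `subject_id`,
#'   `trial_id`, `window_index`, `period_group`, `sub_band`, `class_label`.
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(values, column_meta, row_meta) {
  values <- as.matrix(values)
  if (any(!is.finite(values)))
    stop("feature table must not contain missing or non-finite values")
  if (nrow(column_meta) != ncol(values))
    stop("column_meta rows (", nrow(column_meta),
         ") do not match value columns (", ncol(values), ")")
  if (nrow(row_meta) != nrow(values))
    stop("row_meta rows (", nrow(row_meta),
         ") do not match value rows (", nrow(values), ")")
  need <- c("feature_id", "scale", "channel")
  if (!all(need %in% names(column_meta)))
    stop("column_meta needs columns: ", paste(need, collapse = ", "))
  if (!all(column_meta$feature_id %in% 1:13))
    stop("feature_id must be in 1..13")
  colnames(values) <- sprintf("%s.s%d.F%d", column_meta$channel,
                              as.integer(column_meta$scale),
                              as.integer(column_meta$feature_id))
  structure(list(values = values,
                 column_meta = as.data.frame(column_meta),
                 row_meta = as.data.frame(row_meta)),
            class = "feature_table")
}

#' @export
dim.feature_table <- function(x) dim(x$values)

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table: %d windows x %d feature columns>\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

.row_meta_cols <- c("subject_id", "trial_id", "window_index",
                    "period_group", "sub_band", "class_label")

#' Write a feature table to CSV
#'
#' One header row; metadata columns first, then one column per feature named
#' `<channel>.s<scale>.F<feature_id>` so that the (feature, scale, channel)
#' triple round-trips through the header alone.
#'
#' @param table A [feature_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  rm <- table$row_meta
  for (col in .row_meta_cols) if (is.null(rm[[col]])) rm[[col]] <- NA
  df <- cbind(rm[.row_meta_cols],
              as.data.frame(format(table$values, digits = 17,
                                   scientific = TRUE, trim = TRUE)))
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a feature table from CSV
#'
#' @param path CSV path written by [write_feature_table()].
#' @return A [feature_table()].
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  meta_cols <- intersect(.row_meta_cols, names(df))
  val_cols <- setdiff(names(df), .row_meta_cols)
  m <- regmatches(val_cols, regexec("^(.+)\\.s([0-9]+)\\.F([0-9]+)$", val_cols))
  bad <- val_cols[vapply(m, length, integer(1)) != 4]
  if (length(bad) > 0)
    stop("malformed feature column header(s): ", paste(bad, collapse = ", "),
         " (expected <channel>.s<scale>.F<feature_id>)")
  column_meta <- data.frame(
    feature_id = vapply(m, function(g) as.integer(g[4]), integer(1)),
    scale = vapply(m, function(g) as.integer(g[3]), integer(1)),
    channel = vapply(m, function(g) g[2], character(1)))
  if (!all(column_meta$feature_id %in% 1:13))
    stop("feature_id out of range 1..13 in header: ",
         paste(val_cols[!column_meta$feature_id %in% 1:13], collapse = ", "))
  values <- as.matrix(df[val_cols])
  if (!is.numeric(values)) stop("non-numeric feature values in ", path)
  feature_table(values, column_meta, df[meta_cols])
}
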