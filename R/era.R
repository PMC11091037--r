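#' @title Effective Relax Acquisition
#' @name era
#' @description
#' The ERA search asks *where* relaxed-vs-sad EEG separates best: over alpha
#' sub-bands, equal-length period groups of the stimulus, and overlapping
#' windows within each group. Each (sub-band, period group) cell gets one
#' stratified K-fold cross-validation over its pooled window rows; the
#' per-window objective is the held-out squared 0/1 classification error
#' restricted to that window's rows, and the reported onset is the argmin
#' window (from the second window on — the first is baseline) within the
#' best-accuracy cell.
NULL

.quadrants <- c("HAHV", "HALV", "LAHV", "LALV", "excluded")

#' Map valence/arousal ratings to an emotion quadrant
#'
#' Binary splits of both 1-9 axes: low is 1-4, high is 6-9; ratings in the
#' neutral gap (4, 6) on either axis are `"excluded"`. LAHV (low arousal,
#' high valence) is the relaxed quadrant; LALV the sad one.
#'
#' @param valence,arousal Numeric ratings in \[1, 9\] (vectorized).
#' @return Character vector over `HAHV, HALV, LAHV, LALV, excluded`.
#' @export
quadrant_label <- function(valence, arousal) {
  if (any(valence < 1 | valence > 9 | arousal < 1 | arousal > 9))
    stop("ratings must lie in [1, 9]")
  lvl <- function(x) ifelse(x <= 4, "L", ifelse(x >= 6, "H", NA))
  v <- lvl(valence); a <- lvl(arousal)
  out <- ifelse(is.na(v) | is.na(a), "excluded", paste0(a, "A", v, "V"))
  out
}

#' Classification accuracy in percent
#'
#' @param predictions,labels Equal-length vectors.
#' @return `100 * mean(predictions == labels)`.
#' @export
accuracy <- function(predictions, labels) {
  if (length(predictions) == 0) stop("empty input")
  if (length(predictions) != length(labels))
    stop("predictions and labels differ in length")
  100 * mean(as.character(predictions) == as.character(labels))
}

# ---- classifiers (off-the-shelf, behind one contract) ----------------------

.fit_predict <- function(classifier, x_train, y_train, x_test, cfg) {
  y_train <- factor(y_train)
  switch(classifier,
    knn = as.character(class::knn(x_train, x_test, y_train,
                                  k = cfg$knn_k %||% 5)),
    svm = {
      m <- e1071::svm(x_train, y_train, kernel = "radial",
                      cost = cfg$svm_cost %||% 1, scale = FALSE)
      as.character(stats::predict(m, x_test))
    },
    gboost = {
      m <- xgboost::xgboost(x_train, y_train,
                            nrounds = cfg$xgb_nrounds %||% 100,
                            max_depth = cfg$xgb_depth %||% 3,
                            nthreads = 1, verbosity = 0)
      as.character(stats::predict(m, x_test, type = "class"))
    },
    stop("unknown classifier '", classifier,
         "' (use knn, svm or gboost)"))
}

# Stratified fold assignment at the unit level (units = trials or rows).
# Fold labels cycle through a shared counter so classes interleave and
# k_folds = n yields leave-one-out.
.stratified_folds <- function(y, k_folds, seed) {
  if (k_folds < 2) stop("k_folds must be >= 2")
  folds <- integer(length(y))
  .with_seed(seed, {
    offset <- 0L
    for (cl in unique(y)) {
      idx <- which(y == cl)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- ((offset + seq_along(idx) - 1L) %% k_folds) + 1L
      offset <- offset + length(idx)
    }
  })
  folds
}

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Cross-validated classification with in-fold reduction
#'
#' Stratified K-fold evaluation with the full reduction pipeline fitted
#' inside each training fold (standardization and PCA never see test rows).
#' When `groups` is given, whole groups (e.g. all windows of one trial) are
#' assigned to folds together, stratified by the group's class, so
#' overlapping windows of one trial never straddle the train/test split.
#'
#' @param X Numeric matrix (rows = observations).
#' @param y Class labels (two classes).
#' @param classifier `"knn"`, `"svm"` or `"gboost"`.
#' @param k_folds Number of folds (default 5).
#' @param seed RNG seed controlling the fold assignment.
#' @param groups Optional per-row grouping vector for group-level folds.
#' @param pca `NULL` to classify raw columns, or a list with `standardize`,
#'   `strategy`, `threshold`, `k` passed to [fit_pca()]/[select_k()].
#' @param cfg Classifier hyperparameters (`knn_k`, `svm_cost`,
#'   `xgb_nrounds`, `xgb_depth`).
#' @return List: `mean_accuracy` (mean of fold accuracies, percent),
#'   `fold_accuracies`, `sd_accuracy`, `predictions` (held-out prediction
#'   for every row), `fold` (per-row fold index).
#' @export
kfold_evaluate <- function(X, y, classifier = "knn", k_folds = 5, seed = 42,
                           groups = NULL,
                           pca = list(standardize = TRUE, strategy = "fixed",
                                      threshold = 0.95, k = 6),
                           cfg = list()) {
  X <- as.matrix(X)
  y <- as.character(y)
  if (length(unique(y)) < 2)
    stop("need both classes present for classification")
  if (nrow(X) < k_folds) stop("need at least k_folds rows")
  if (is.null(groups)) {
    fold <- .stratified_folds(y, k_folds, seed)
  } else {
    ug <- unique(groups)
    gy <- y[match(ug, groups)]
    gf <- .stratified_folds(gy, k_folds, seed)
    fold <- gf[match(groups, ug)]
  }
  preds <- character(nrow(X))
  fold_acc <- numeric(k_folds)
  for (f in seq_len(k_folds)) {
    tr <- fold != f; te <- !tr
    x_tr <- X[tr, , drop = FALSE]; x_te <- X[te, , drop = FALSE]
    if (length(unique(y[tr])) < 2)
      stop("a training fold lost a class; reduce k_folds")
    if (!is.null(pca)) {
      keep <- apply(x_tr, 2, function(col) stats::sd(col) > 0)
      m <- fit_pca(x_tr[, keep, drop = FALSE],
                   standardize = isTRUE(pca$standardize %||% TRUE))
      k <- select_k(m, threshold = pca$threshold %||% 0.95,
                    strategy = pca$strategy %||% "fixed",
                    k = min(pca$k %||% 6, m$D))
      x_trp <- project(x_tr[, keep, drop = FALSE], m, k)
      x_tep <- project(x_te[, keep, drop = FALSE], m, k)
    } else {
      x_trp <- x_tr; x_tep <- x_te
    }
    p <- .with_seed(seed + f,
                    .fit_predict(classifier, x_trp, y[tr], x_tep, cfg))
    preds[te] <- p
    fold_acc[f] <- accuracy(p, y[te])
  }
  list(mean_accuracy = mean(fold_acc), fold_accuracies = fold_acc,
       sd_accuracy = stats::sd(fold_acc), predictions = preds, fold = fold)
}

#' ERA run configuration
#'
#' @param subbands Sub-bands to search, subset of `"high_alpha"`,
#'   `"low_alpha"`, `"alpha"`.
#' @param n_groups Number of period groups (4 or 6 in the standard
#'   layouts).
#' @param window A [window_spec()].
#' @param classifier `"knn"`, `"svm"` or `"gboost"`.
#' @param k_folds Cross-validation folds (default 5).
#' @param pca Reduction settings (see [kfold_evaluate()]); `NULL` disables
#'   reduction (the non-ERA baseline).
#' @param baseline_window_policy If `TRUE`, features of the trial's 3-s
#'   baseline window are subtracted from every window row of that trial
#'   (per sub-band) before classification.
#' @param seed RNG seed for fold assignment and classifier tie-breaks.
#' @param contrast Two quadrant labels to classify (default relaxed LAHV vs
#'   sad LALV).
#' @param exclude_subjects Subject ids whose trials are dropped (e.g. the
#'   DEAP non-responders S13, S20, S21, S22).
#' @param fold_unit `"trial"` assigns all windows of a trial to one fold
#'   (default; prevents overlapping-window leakage); `"row"` stratifies
#'   individual window rows.
#' @param channels Channels to analyse (default O1/O2).
#' @param bandpass A [bandpass_spec()].
#' @param features A [feature_options()].
#' @param knn_k,svm_cost,xgb_nrounds,xgb_depth Classifier hyperparameters.
#' @return A list of class `era_config`.
#' @export
era_config <- function(subbands = c("high_alpha", "low_alpha", "alpha"),
                       n_groups = 4, window = window_spec(3, 0.5),
                       classifier = "knn", k_folds = 5,
                       pca = list(standardize = TRUE, strategy = "fixed",
                                  threshold = 0.95, k = 6),
                       baseline_window_policy = FALSE, seed = 42,
                       contrast = c("LAHV", "LALV"),
                       exclude_subjects = character(0),
                       fold_unit = c("trial", "row"),
                       channels = c("O1", "O2"),
                       bandpass = bandpass_spec(),
                       features = feature_options(),
                       knn_k = 5, svm_cost = 1,
                       xgb_nrounds = 100, xgb_depth = 3) {
  bad <- setdiff(subbands, c("high_alpha", "low_alpha", "alpha"))
  if (length(bad) > 0) stop("unknown sub-band(s): ", paste(bad, collapse = ", "))
  if (k_folds < 2) stop("k_folds must be >= 2")
  if (length(contrast) != 2 || !all(contrast %in% .quadrants))
    stop("contrast must name two quadrants")
  structure(list(subbands = subbands, n_groups = n_groups, window = window,
                 classifier = classifier, k_folds = k_folds, pca = pca,
                 baseline_window_policy = isTRUE(baseline_window_policy),
                 seed = seed, contrast = contrast,
                 exclude_subjects = exclude_subjects,
                 fold_unit = match.arg(fold_unit), channels = channels,
                 bandpass = bandpass, features = features,
                 knn_k = knn_k, svm_cost = svm_cost,
                 xgb_nrounds = xgb_nrounds, xgb_depth = xgb_depth),
            class = "era_config")
}

.subband_rank <- function(b) match(b, c("high_alpha", "low_alpha", "alpha"))

#' Run the full ERA search
#'
#' Pipeline per trial: Butterworth band-pass (8-13 Hz), occipital channel
#' selection, six-scale Morlet CWT. Then, for every configured sub-band and
#' period group: overlapping-window feature extraction (13 features x
#' scales x channels), in-fold standardization + PCA, and stratified K-fold
#' classification of the contrast (relaxed LAHV vs sad LALV by default).
#' Each grid cell reports the pooled held-out accuracy over all its window
#' rows; the per-window objective is the held-out squared 0/1 error of that
#' window's rows. The best cell is the accuracy maximum (ties: high_alpha
#' before low_alpha before alpha, then the earlier group) and the relax
#' onset is the objective-argmin window within it, searched from window 2
#' (window 1 is the baseline frame; it is evaluated but never selected).
#'
#' @param rs A [recording_set()].
#' @param config An [era_config()].
#' @return An object of class `era_result`: `grid` (one row per cell:
#'   `sub_band`, `period_group`, `n_windows`, `accuracy`, `sd_accuracy`),
#'   `fold_accuracies` (list per cell), `objectives` (per-window error
#'   counts with a `selectable` flag), `best` (list: `sub_band`,
#'   `period_group`, `window_index`, `accuracy`, `sd_accuracy`,
#'   `fold_accuracies`, `objective`), `n_trials`, `config`.
#' @export
run_era <- function(rs, config = era_config()) {
  stopifnot(inherits(rs, "recording_set"), inherits(config, "era_config"))
  lab <- quadrant_label(rs$ratings$valence, rs$ratings$arousal)
  sid <- vapply(rs$recordings, `[[`, character(1), "subject_id")
  keep <- lab %in% config$contrast & !(sid %in% config$exclude_subjects)
  recs <- rs$recordings[keep]
  y_trial <- lab[keep]
  counts <- table(factor(y_trial, levels = config$contrast))
  if (any(counts < 2))
    stop("need at least 2 trials per class; got ",
         paste(sprintf("%s=%d", names(counts), counts), collapse = ", "))
  fs <- recs[[1]]$fs
  total_s <- ncol(recs[[1]]$samples) / fs
  baseline_s <- recs[[1]]$baseline_s
  grouping <- period_boundaries(config$n_groups, fs, baseline_s, total_s)
  group_len <- diff(grouping$boundaries)[1]
  w <- .window_samples(config$window, fs)
  if (w$wl_n > group_len)
    stop("window of ", w$wl_n, " samples exceeds the period-group length of ",
         group_len, " samples")
  cwts <- lapply(recs, function(rec)
    .trial_cwt(rec, config$channels, config$bandpass))
  trial_ids <- vapply(recs, `[[`, character(1), "trial_id")
  # baseline-window features per trial/band, for the optional subtraction
  base_rows <- NULL
  if (config$baseline_window_policy) {
    if (baseline_s * fs < w$wl_n)
      stop("baseline span shorter than one window; cannot apply baseline policy")
    base_group <- structure(list(n_groups = 1L,
                                 boundaries = c(0L, as.integer(baseline_s * fs)),
                                 baseline_end = 0L),
                            class = "period_grouping")
    base_rows <- lapply(config$subbands, function(band)
      lapply(seq_along(cwts), function(i)
        .featurize_trial_cell(cwts[[i]], band, base_group, 1L,
                              window_spec(config$window$wl_s,
                                          config$window$wl_s),
                              config$features,
                              data.frame(subject_id = recs[[i]]$subject_id,
                                         trial_id = trial_ids[i],
                                         window_index = NA_integer_,
                                         period_group = NA_integer_,
                                         sub_band = band,
                                         class_label = y_trial[i]))$values))
    names(base_rows) <- config$subbands
  }
  grid <- list(); objectives <- list(); fold_acc_list <- list()
  for (band in config$subbands) {
    for (g in seq_len(config$n_groups)) {
      tabs <- lapply(seq_along(cwts), function(i)
        .featurize_trial_cell(
          cwts[[i]], band, grouping, g, config$window,
          config$features,
          data.frame(subject_id = recs[[i]]$subject_id,
                     trial_id = trial_ids[i],
                     window_index = NA_integer_,
                     period_group = NA_integer_,
                     sub_band = band,
                     class_label = y_trial[i])))
      tab <- do.call(rbind_feature_tables, tabs)
      X <- tab$values
      if (!is.null(base_rows)) {
        rep_idx <- match(tab$row_meta$trial_id, trial_ids)
        X <- X - do.call(rbind, base_rows[[band]])[rep_idx, , drop = FALSE]
      }
      y_row <- tab$row_meta$class_label
      groups_row <- if (config$fold_unit == "trial") tab$row_meta$trial_id
                    else NULL
      cv <- kfold_evaluate(X, y_row, classifier = config$classifier,
                           k_folds = config$k_folds, seed = config$seed,
                           groups = groups_row, pca = config$pca,
                           cfg = config)
      pooled <- accuracy(cv$predictions, y_row)
      widx <- tab$row_meta$window_index
      errs <- vapply(sort(unique(widx)), function(i)
        sum(cv$predictions[widx == i] != y_row[widx == i]), numeric(1))
      nwin <- length(errs)
      grid[[length(grid) + 1L]] <- data.frame(
        sub_band = band, period_group = g, n_windows = nwin,
        accuracy = pooled, sd_accuracy = cv$sd_accuracy)
      fold_acc_list[[length(fold_acc_list) + 1L]] <- cv$fold_accuracies
      objectives[[length(objectives) + 1L]] <- data.frame(
        sub_band = band, period_group = g,
        window_index = seq_len(nwin), errors = errs,
        n_rows = vapply(sort(unique(widx)), function(i) sum(widx == i),
                        numeric(1)),
        selectable = seq_len(nwin) >= 2L)
    }
  }
  grid <- do.call(rbind, grid)
  objectives <- do.call(rbind, objectives)
  # best cell: max pooled accuracy; ties by sub-band rank then earlier group
  ord <- order(-grid$accuracy, .subband_rank(grid$sub_band),
               grid$period_group)
  bi <- ord[1]
  cell_obj <- objectives[objectives$sub_band == grid$sub_band[bi] &
                         objectives$period_group == grid$period_group[bi] &
                         objectives$selectable, ]
  wi <- cell_obj$window_index[which.min(cell_obj$errors)]
  best <- list(sub_band = grid$sub_band[bi],
               period_group = grid$period_group[bi],
               window_index = wi,
               accuracy = grid$accuracy[bi],
               sd_accuracy = grid$sd_accuracy[bi],
               fold_accuracies = fold_acc_list[[bi]],
               objective = min(cell_obj$errors))
  structure(list(grid = grid, fold_accuracies = fold_acc_list,
                 objectives = objectives, best = best,
                 n_trials = length(recs), config = config),
            class = "era_result")
}

#' @export
print.era_result <- function(x, ...) {
  cat(sprintf(paste0("<era_result: %d trials, %d cells; best %s / period %d",
                     " / window %d, accuracy %.1f%% (sd %.1f)>\n"),
              x$n_trials, nrow(x$grid), x$best$sub_band, x$best$period_group,
              x$best$window_index, x$best$accuracy, x$best$sd_accuracy))
  invisible(x)
}
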