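#' Fit PCA on a feature table
#'
#' Columns are z-scored (unless `standardize = FALSE`), the covariance
#' matrix is eigendecomposed, and components are sorted by descending
#' eigenvalue. Eigenvector signs follow a deterministic convention: each
#' column is flipped so its largest-magnitude loading is positive (ties
#' broken by lower row index), making rankings reproducible.
#'
#' @param table A [feature_table()] or numeric matrix (rows = observations).
#' @param standardize Z-score columns before the covariance (default
#'   `TRUE`; the 13 features differ by orders of magnitude, so raw
#'   covariance would be dominated by power-like features).
#' @return A list of class `pca_model`: `eigenvalues` (descending, clipped
#'   at 0), `eigenvectors` (columns), `variance_fractions`, `column_means`,
#'   `column_scales`, `D`, `column_meta` (when fitted on a feature table).
#' @export
fit_pca <- function(table, standardize = TRUE) {
  column_meta <- NULL
  if (inherits(table, "feature_table")) {
    column_meta <- table$column_meta
    X <- table$values
  } else X <- as.matrix(table)
  if (nrow(X) < 2) stop("PCA needs at least 2 rows")
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  if (standardize) {
    const <- which(sdv == 0)
    if (length(const) > 0)
      stop("cannot standardize constant column(s): ",
           paste(colnames(X)[const] %||% const, collapse = ", "))
    Z <- sweep(sweep(X, 2, mu), 2, sdv, "/")
    scl <- sdv
  } else {
    Z <- sweep(X, 2, mu)
    scl <- rep(1, ncol(X))
  }
  eg <- eigen(stats::cov(Z), symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  V <- eg$vectors
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))  # which.max takes the first on ties
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  structure(list(eigenvalues = ev, eigenvectors = V,
                 variance_fractions = ev / sum(ev),
                 column_means = mu, column_scales = scl,
                 D = ncol(X), column_meta = column_meta),
            class = "pca_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("<pca_model: D = %d, top variance fractions %s>\n", x$D,
              paste(sprintf("%.3f", utils::head(x$variance_fractions, 4)),
                    collapse = ", ")))
  invisible(x)
}

#' Cumulative explained-variance fraction
#'
#' @param model A [fit_pca()] model.
#' @param k Number of leading components, `1 <= k <= D`.
#' @return `sum(lambda[1:k]) / sum(lambda)`.
#' @export
cumulative_variance <- function(model, k) {
  if (k < 1 || k > model$D) stop("k out of range 1..", model$D)
  sum(model$variance_fractions[seq_len(k)])
}

#' Choose the number of retained components
#'
#' Three strategies: `"threshold"` returns the smallest `k` whose cumulative
#' explained variance reaches `threshold`; `"increment"` starts there and
#' steps to the component after the largest marginal gain among the
#' qualifying components (the reasoning that moves a 95%-threshold choice
#' from the fifth to the sixth component when the fifth-to-sixth increment
#' dominates); `"fixed"` returns the configured `k`.
#'
#' @param model A [fit_pca()] model.
#' @param threshold Cumulative-variance threshold in (0, 1]; default 0.95.
#' @param strategy One of `"threshold"`, `"increment"`, `"fixed"`.
#' @param k Component count for the `"fixed"` strategy (default 6).
#' @return Integer number of components.
#' @export
select_k <- function(model, threshold = 0.95,
                     strategy = c("threshold", "increment", "fixed"), k = 6) {
  strategy <- match.arg(strategy)
  if (strategy == "fixed") {
    if (k < 1 || k > model$D) stop("fixed k out of range 1..", model$D)
    return(as.integer(k))
  }
  if (!(threshold > 0 && threshold <= 1)) stop("threshold must be in (0, 1]")
  cum <- cumsum(model$variance_fractions)
  k0 <- which(cum >= threshold - 1e-12)[1]
  if (is.na(k0)) stop("cumulative variance never reaches ", threshold)
  if (strategy == "threshold") return(as.integer(k0))
  if (k0 == model$D) return(as.integer(k0))
  gains <- model$variance_fractions[(k0 + 1):model$D]
  as.integer(k0 + which.max(gains))
}

#' Project a feature table onto leading principal components
#'
#' Applies the model's standardization and multiplies by the first `k`
#' eigenvectors. With `k = D` the projection is a rotation of the
#' standardized data (distance-preserving).
#'
#' @param table A [feature_table()] or matrix with `D` columns.
#' @param model A [fit_pca()] model.
#' @param k Number of components to keep.
#' @return Numeric matrix `n_rows x k` with columns `PC1..PCk`; when `table`
#'   is a feature table the row metadata is attached as attribute
#'   `row_meta`.
#' @export
project <- function(table, model, k) {
  if (k < 1 || k > model$D) stop("k out of range 1..", model$D)
  row_meta <- NULL
  if (inherits(table, "feature_table")) {
    row_meta <- table$row_meta
    X <- table$values
  } else X <- as.matrix(table)
  if (ncol(X) != model$D)
    stop("table has ", ncol(X), " columns but the model expects ", model$D)
  Z <- sweep(sweep(X, 2, model$column_means), 2, model$column_scales, "/")
  P <- Z %*% model$eigenvectors[, seq_len(k), drop = FALSE]
  colnames(P) <- paste0("PC", seq_len(k))
  if (!is.null(row_meta)) attr(P, "row_meta") <- row_meta
  P
}

#' Rank original features by eigenvector magnitude
#'
#' Scores each input column by its largest absolute loading across the first
#' `k` eigenvectors — a larger magnitude marks a feature that drives more of
#' the retained variance — and sorts descending (ties keep input order).
#'
#' @param model A [fit_pca()] model.
#' @param k Number of leading components to scan.
#' @param score `"max"` (default) uses the maximum absolute loading;
#'   `"weighted"` uses the eigenvalue-weighted sum of squared loadings.
#' @return Data frame with `column` (input index), `score`, and, when the
#'   model was fitted on a feature table, the `feature_id`, `scale`,
#'   `channel` metadata, ordered by decreasing score.
#' @export
rank_features <- function(model, k, score = c("max", "weighted")) {
  score <- match.arg(score)
  if (k < 1 || k > model$D) stop("k out of range 1..", model$D)
  V <- model$eigenvectors[, seq_len(k), drop = FALSE]
  s <- if (score == "max") apply(abs(V), 1, max)
       else as.vector(V^2 %*% model$eigenvalues[seq_len(k)])
  ord <- order(-s)  # stable: ties keep lower column index first
  out <- data.frame(column = ord, score = s[ord])
  if (!is.null(model$column_meta))
    out <- cbind(out, model$column_meta[ord, , drop = FALSE])
  rownames(out) <- NULL
  out
}
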