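#' PCA valence summary of a behavioral metric matrix
#'
#' Principal component analysis of a flies x metrics matrix, used to ask
#' whether the behavioral repertoire separates stimulus valences. Columns
#' are standardized to z-scores (sample SD, n - 1 divisor) so every metric
#' carries unit variance; the decomposition is then of the correlation
#' structure. Rows containing undefined metrics (e.g. mean latency for a fly
#' with a single bout) are dropped and reported, as are zero-variance
#' columns (with a warning). Component signs follow the convention that each
#' component's largest-magnitude loading is positive. Components are
#' retained when their eigenvalue exceeds 1 — i.e. they explain more
#' variance than a single standardized variable (the Kaiser criterion).
#'
#' @param metric_matrix Numeric matrix or data frame, one row per fly, one
#'   column per behavioral metric (>= 2 of each after dropping).
#' @return List of class `pca_valence`: `loadings` (metrics x components,
#'   orthonormal), `scores` (flies x components), `eigenvalues` (variance
#'   explained by each component; they sum to the number of kept columns),
#'   `prop_var`, `retained` (indices of retained components),
#'   `dropped_rows`, `dropped_cols`.
#' @export
pca_valence <- function(metric_matrix) {
  m <- as.matrix(metric_matrix)
  if (is.null(colnames(m))) colnames(m) <- paste0("metric", seq_len(ncol(m)))
  keep_row <- stats::complete.cases(m)
  dropped_rows <- which(!keep_row)
  m <- m[keep_row, , drop = FALSE]
  sds <- apply(m, 2, stats::sd)
  dropped_cols <- colnames(m)[sds == 0 | is.na(sds)]
  if (length(dropped_cols)) {
    warning("dropping zero-variance column(s): ",
            paste(dropped_cols, collapse = ", "))
    m <- m[, sds > 0 & !is.na(sds), drop = FALSE]
  }
  if (nrow(m) < 2 || ncol(m) < 2)
    stop("PCA needs at least 2 complete flies and 2 varying metrics")
  z <- scale(m, center = TRUE, scale = TRUE)
  p <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  load <- p$rotation
  scores <- p$x
  # sign convention: largest-|loading| entry of each component positive
  for (j in seq_len(ncol(load))) {
    k <- which.max(abs(load[, j]))
    if (load[k, j] < 0) {
      load[, j] <- -load[, j]
      scores[, j] <- -scores[, j]
    }
  }
  ev <- p$sdev^2
  structure(
    list(loadings = load, scores = scores, eigenvalues = ev,
         prop_var = ev / sum(ev), retained = which(ev > 1),
         dropped_rows = dropped_rows, dropped_cols = dropped_cols),
    class = "pca_valence")
}

#' @export
print.pca_valence <- function(x, ...) {
  cat(sprintf("<pca_valence> %d flies x %d metrics; retained components: %s\n",
              nrow(x$scores), nrow(x$loadings),
              paste(x$retained, collapse = ", ")))
  cat("  proportion of variance:",
      paste(sprintf("%.3f", x$prop_var), collapse = " "), "\n")
  invisible(x)
}
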