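#' Standardized feature matrix for phenotype clustering
#'
#' Builds the z-scored matrix of kinetic features plus FSI that feeds
#' Ward-D2 clustering. The default feature set (`logphase_slope`, `auc`,
#' `signed_duration`, `fsi`) deliberately omits `delta_relative` and
#' `intra_cv`, which are already folded into the FSI composite.
#'
#' @param profiles List of `kinetic_profile`s (one per line).
#' @param fsi Data frame from [fsi_scores()] (required when `"fsi"` is in
#'   `features`).
#' @param features Character vector of feature names.
#' @return Numeric matrix, rows named by cell line, columns z-scored.
#' @export
feature_matrix <- function(profiles, fsi = NULL,
                           features = stip_config()$cluster$features) {
  base <- t(vapply(profiles, feature_vector, numeric(5)))
  rownames(base) <- vapply(profiles, function(p) p$cell_line, "")
  cols <- list()
  for (f in features) {
    if (f == "fsi") {
      if (is.null(fsi)) stop("fsi results required for the 'fsi' feature")
      cols[[f]] <- fsi$fsi[match(rownames(base), fsi$cell_line)]
    } else if (f %in% colnames(base)) {
      cols[[f]] <- base[, f]
    } else {
      stop("unknown clustering feature: ", f)
    }
  }
  m <- do.call(cbind, cols)
  rownames(m) <- rownames(base)
  zscore_cols(m)
}

#' Ward-D2 hierarchical clustering with silhouette-selected k
#'
#' Agglomerative clustering on Euclidean distances with the Ward-D2
#' criterion. The cluster count is chosen to maximize the mean silhouette
#' width over k in 2..min(`k_max`, n-1).
#'
#' @param features Numeric matrix from [feature_matrix()] (>= 3 rows).
#' @param k_max Largest candidate k (default 5).
#' @return List of class `cluster_result`: `hclust` (the tree), `merge`,
#'   `height`, `selected_k`, `labels` (named cluster ids), `silhouette`
#'   (named mean widths per candidate k).
#' @export
ward_cluster <- function(features, k_max = stip_config()$cluster$k_max) {
  n <- nrow(features)
  if (n < 3) stop("clustering needs >= 3 rows")
  d <- stats::dist(features)
  hc <- stats::hclust(d, method = "ward.D2")
  ks <- 2:min(k_max, n - 1)
  sil <- vapply(ks, function(k) {
    mean(cluster::silhouette(stats::cutree(hc, k), d)[, 3])
  }, 0)
  names(sil) <- ks
  k_best <- ks[which.max(sil)]
  labels <- stats::cutree(hc, k_best)
  structure(list(hclust = hc, merge = hc$merge, height = hc$height,
                 selected_k = k_best, labels = labels, silhouette = sil),
            class = "cluster_result")
}

#' Pairwise similarity matrix on the feature space
#'
#' `s_ij = 1 - d_ij / max(d)` on Euclidean distances: 1 on the diagonal and
#' for identical rows, 0 for the most distant pair.
#'
#' @param features Numeric matrix (>= 2 rows).
#' @return Symmetric matrix in \[0, 1\] with unit diagonal.
#' @export
similarity_matrix <- function(features) {
  stopifnot(nrow(features) >= 2)
  d <- as.matrix(stats::dist(features))
  mx <- max(d)
  s <- if (mx == 0) matrix(1, nrow(d), ncol(d), dimnames = dimnames(d))
  else 1 - d / mx
  diag(s) <- 1
  s
}
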