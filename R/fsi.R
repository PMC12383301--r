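#' Five-parameter feature vector of a kinetic profile
#'
#' The FSI inputs: relative final-confluence delta, log-phase slope,
#' direction-signed divergence duration (`sign(delta_relative) * duration`,
#' 0 when there is no divergence), AUC, and intra-assay CV. Signing the
#' duration prevents inhibitory lines from collecting positive duration
#' credit.
#'
#' @param profile `kinetic_profile` or compatible list.
#' @return Named numeric vector of length 5.
#' @export
feature_vector <- function(profile) {
  dur <- profile$divergence_duration
  sdur <- if (is.na(dur) || dur == 0) 0 else sign(profile$delta_relative) * dur
  c(delta_relative = profile$delta_relative,
    logphase_slope = profile$logphase_slope,
    signed_duration = sdur,
    auc = profile$auc,
    intra_cv = profile$intra_cv)
}

# cohort z-score; zero-variance columns become all-zero with a warning
zscore_cols <- function(m) {
  apply(m, 2, function(x) {
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) {
      warning("zero-variance parameter; z-scores set to 0")
      return(rep(0, length(x)))
    }
    (x - mean(x)) / s
  })
}

#' Functional Stratification Index for a cohort
#'
#' Each of the five parameters is z-scored across the cohort and combined
#' linearly: `fsi = scale * (w1 z(delta) + w2 z(slope) + w3 z(signed
#' duration) + w4 z(auc) - w5 z(cv))`. CV enters negatively (noisy responses
#' are penalized). Because z-scores sum to zero, FSI sums to zero over any
#' cohort; only signs and ordering are interpretable, not absolute values.
#'
#' @param profiles List of >= 2 `kinetic_profile`s (one per line).
#' @param weights Non-negative weights summing to 1, in feature order
#'   (delta_relative, logphase_slope, signed_duration, auc, intra_cv).
#' @param scale Display-scale multiplier (default 15).
#' @return Data frame: `cell_line`, the five z-scores (`z_` prefix), `fsi`.
#' @export
fsi_scores <- function(profiles, weights = stip_config()$fsi$weights,
                       scale = stip_config()$fsi$scale) {
  if (length(profiles) < 2) stop("FSI needs a cohort of >= 2 profiles")
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-9) {
    stop("weights must be non-negative and sum to 1")
  }
  feats <- t(vapply(profiles, feature_vector, numeric(5)))
  z <- zscore_cols(feats)
  signs <- c(1, 1, 1, 1, -1)  # CV penalized
  fsi <- as.numeric(scale * (z %*% (as.numeric(weights) * signs)))
  out <- data.frame(
    cell_line = vapply(profiles, function(p) p$cell_line, ""),
    z_delta_relative = z[, 1], z_logphase_slope = z[, 2],
    z_signed_duration = z[, 3], z_auc = z[, 4], z_intra_cv = z[, 5],
    delta_relative = feats[, 1],
    fsi = fsi, stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Rank cell lines by FSI
#'
#' Descending FSI; ties broken by descending `delta_relative`, then by line
#' name (ascending, for determinism).
#'
#' @param results Data frame from [fsi_scores()].
#' @return The data frame reordered, with a `rank` column added.
#' @export
rank_lines <- function(results) {
  ord <- order(-results$fsi, -results$delta_relative, results$cell_line)
  out <- results[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
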