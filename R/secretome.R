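#' Summarize a cytokine panel
#'
#' Per-analyte mean and sample SD in pg/mL, excluding below-LLOD samples,
#' plus the IFN-gamma/IL-10 composite ratio of means with a first-order
#' (delta-method) propagated SD. An analyte whose samples are all below the
#' LLOD is reported absent (`NA` mean, n = 0).
#'
#' @param samples Data frame with columns `analyte`, `concentration_pg_ml`,
#'   `below_llod`.
#' @param label Optional group label carried into the summary.
#' @return List of class `panel_summary`: `label`, `analytes` (data frame
#'   with `analyte`, `mean`, `sd`, `n`), `ratio`, `ratio_sd`.
#' @export
summarize_panel <- function(samples, label = NA_character_) {
  stopifnot(all(c("analyte", "concentration_pg_ml", "below_llod") %in%
                  names(samples)))
  analytes <- unique(samples$analyte)
  rows <- lapply(analytes, function(a) {
    x <- samples$concentration_pg_ml[samples$analyte == a & !samples$below_llod]
    data.frame(analyte = a,
               mean = if (length(x)) mean(x) else NA_real_,
               sd = if (length(x) >= 2) stats::sd(x) else NA_real_,
               n = length(x))
  })
  tab <- do.call(rbind, rows)
  ifng <- tab$mean[tab$analyte == "IFN-gamma"]
  il10 <- tab$mean[tab$analyte == "IL-10"]
  ratio <- ratio_sd <- NA_real_
  if (length(ifng) == 1 && length(il10) == 1 &&
      is.finite(ifng) && is.finite(il10) && il10 > 0) {
    ratio <- ifng / il10
    s_ifng <- tab$sd[tab$analyte == "IFN-gamma"]
    s_il10 <- tab$sd[tab$analyte == "IL-10"]
    if (is.finite(s_ifng) && is.finite(s_il10) && ifng > 0) {
      ratio_sd <- ratio * sqrt((s_ifng / ifng)^2 + (s_il10 / il10)^2)
    }
  }
  structure(list(label = label, analytes = tab, ratio = ratio,
                 ratio_sd = ratio_sd),
            class = "panel_summary")
}

#' IFN-gamma/IL-10 composite ratio
#'
#' Ratio of group means (not the mean of per-sample ratios): high values
#' mark suppressive/overactivated secretomes, low values permissive/trophic
#' ones.
#'
#' @param ifng_mean,il10_mean Group mean concentrations in pg/mL.
#' @return Dimensionless ratio.
#' @export
#' @examples
#' ifng_il10_ratio(83.6, 14.2)  # 5.89, a suppressive profile
ifng_il10_ratio <- function(ifng_mean, il10_mean) {
  if (!is.finite(il10_mean) || il10_mean <= 0) {
    stop("IL-10 mean must be > 0 for the ratio to be defined")
  }
  ifng_mean / il10_mean
}

#' Group comparison of cytokine concentrations
#'
#' Per analyte: one-way ANOVA (classical, equal-variance F) across all
#' groups, followed by pairwise Welch t-tests Bonferroni-corrected over
#' (number of pairs) x (number of analytes). Degenerate inputs (all values
#' identical) give p = 1 by convention.
#'
#' @param samples Data frame with columns `group`, `analyte`,
#'   `concentration_pg_ml` and optionally `below_llod` (excluded if TRUE).
#' @return List per analyte with `anova_p` and a data frame `pairwise`
#'   (`group1`, `group2`, `p`, `p_adj`).
#' @export
group_compare <- function(samples) {
  stopifnot(all(c("group", "analyte", "concentration_pg_ml") %in%
                  names(samples)))
  if ("below_llod" %in% names(samples)) {
    samples <- samples[!samples$below_llod, ]
  }
  analytes <- unique(samples$analyte)
  groups <- unique(samples$group)
  if (length(groups) < 2) stop("need >= 2 groups")
  n_pairs <- choose(length(groups), 2)
  m <- n_pairs * length(analytes)  # Bonferroni family size
  out <- lapply(analytes, function(a) {
    sub <- samples[samples$analyte == a, ]
    counts <- table(sub$group)
    if (any(counts < 2)) stop("need >= 2 samples per group for analyte ", a)
    anova_p <- if (stats::var(sub$concentration_pg_ml) == 0) {
      1
    } else {
      stats::oneway.test(concentration_pg_ml ~ group, data = sub,
                         var.equal = TRUE)$p.value
    }
    pairs <- utils::combn(sort(as.character(groups)), 2)
    pw <- apply(pairs, 2, function(pr) {
      x <- sub$concentration_pg_ml[sub$group == pr[1]]
      y <- sub$concentration_pg_ml[sub$group == pr[2]]
      p <- if (stats::var(x) == 0 && stats::var(y) == 0) {
        if (mean(x) == mean(y)) 1 else 0
      } else {
        stats::t.test(x, y)$p.value
      }
      data.frame(group1 = pr[1], group2 = pr[2], p = p,
                 p_adj = min(p * m, 1))
    })
    list(anova_p = if (is.nan(anova_p)) 1 else anova_p,
         pairwise = do.call(rbind, pw))
  })
  names(out) <- analytes
  out
}
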