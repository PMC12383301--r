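#' Bundled eight-line demonstration cohort (summary metrics)
#'
#' Per-line published-style summary metrics for the canonical eight-line
#' demonstration cohort used throughout the package's examples, tests and
#' acceptance checks: final treated confluence (mean, SD), final-confluence
#' delta vs control in points, an upper bound on the reported p-value,
#' intra-assay CV, divergence onset, log-phase slope, AUC (reported
#' arbitrary units), sustained divergence duration, plateau window and the
#' assigned category. The control final is reconstructed as
#' `final - delta_points` and the relative delta as
#' `delta_points / control_final`.
#'
#' @return Data frame, one row per cell line.
#' @export
stip_reference_cohort <- function() {
  df <- data.frame(
    cell_line = c("BEWO", "U87", "LUDLU", "A375", "PANC-1",
                  "MCF-7", "HEPG2", "LNCAP-C42"),
    category = c("stimulatory", "stimulatory", "stimulatory",
                 "inhibitory", "inhibitory",
                 "neutral", "neutral", "neutral"),
    final_confluence_mean = c(63.2, 52.6, 49.3, 23.0, 20.5, 46.0, 43.2, 41.5),
    final_confluence_sd = c(2.1, 1.8, 2.5, 1.5, 1.7, 1.6, 1.9, 2.2),
    delta_points = c(34.1, 16.7, 12.4, -21.1, -29.5, 1.6, -2.8, -3.1),
    p_upper = c(0.001, 0.01, 0.04, 0.001, 0.01, 0.2, 0.2, 0.2),
    intra_cv = c(6.4, 5.9, 7.1, 6.2, 6.7, 4.3, 4.9, 4.6),
    onset_hours = c(10, 18, 20, 12, 22, NA, NA, NA),
    logphase_slope = c(2.9, 2.4, 1.8, -2.5, -3.1, 0.3, -0.4, -0.5),
    auc = c(428, 385, 362, 219, 202, 321, 308, 297),
    divergence_duration = c(28, 22, 18, 24, 26, 0, 0, 0),
    plateau = c("38-48", "32-48", "30-48", "suppressed", "suppressed",
                "0-48", "0-48", "0-48"),
    stringsAsFactors = FALSE
  )
  df$control_final_mean <- df$final_confluence_mean - df$delta_points
  df$delta_relative <- df$delta_points / df$control_final_mean
  df
}

#' Reference cohort as kinetic-profile objects
#'
#' Converts [stip_reference_cohort()] rows into `kinetic_profile`-shaped
#' objects so they can be fed to [kinetic_category()], [fsi_scores()] and
#' [feature_matrix()]. Significance is encoded from the reported p bound: a
#' line reported significant (`p_upper < 0.05`) is given one significant
#' timepoint per hour of sustained divergence (comfortably above the
#' five-point rule); non-significant lines get zero.
#'
#' @return Named list of `kinetic_profile` objects.
#' @export
stip_reference_profiles <- function() {
  df <- stip_reference_cohort()
  profs <- lapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    structure(list(
      cell_line = r$cell_line,
      formulation_id = "pooled",
      production_batch = "pooled",
      final_confluence_mean = r$final_confluence_mean,
      final_confluence_sd = r$final_confluence_sd,
      control_final_mean = r$control_final_mean,
      delta_points = r$delta_points,
      delta_relative = r$delta_relative,
      onset_hours = r$onset_hours,
      logphase_slope = r$logphase_slope,
      auc = r$auc,
      divergence_duration = r$divergence_duration,
      plateau_window = NULL,
      intra_cv = r$intra_cv,
      n_sig_points = if (r$p_upper < 0.05) as.integer(r$divergence_duration)
      else 0L
    ), class = "kinetic_profile")
  })
  names(profs) <- df$cell_line
  profs
}

#' Bundled group-level secretome reference panel
#'
#' Mean and SD cytokine concentrations (pg/mL) per functional group for the
#' demonstration cohort, used as generator defaults and for the composite
#' ratio checks. TNF-alpha is carried descriptively (it plays no role in
#' classification).
#'
#' @return Data frame: `group`, `analyte`, `mean`, `sd`.
#' @export
stip_reference_secretome <- function() {
  data.frame(
    group = rep(c("stimulatory", "inhibitory", "neutral"), each = 4),
    analyte = rep(c("IL-6", "IFN-gamma", "IL-10", "TNF-alpha"), times = 3),
    mean = c(168.5, 54.1, 39.2, 12.0,
             45.7, 83.6, 14.2, 9.0,
             62.3, 47.5, 45.2, 8.0),
    sd = c(12.4, 9.3, 6.1, 3.0,
           7.9, 10.8, 3.4, 3.0,
           8.5, 6.2, 5.9, 3.0),
    stringsAsFactors = FALSE
  )
}

#' Reference compatibility pattern
#'
#' The expected line x formulation category pattern for the demonstration
#' cohort across the five formulation sources: every line keeps its class
#' against every formulation (no inversions).
#'
#' @return Data frame: `cell_line`, `formulation_id`, `category`.
#' @export
stip_reference_compatibility <- function() {
  df <- stip_reference_cohort()
  forms <- paste0("FV-00", 1:5)
  out <- expand.grid(cell_line = df$cell_line, formulation_id = forms,
                     stringsAsFactors = FALSE)
  out$category <- df$category[match(out$cell_line, df$cell_line)]
  out[order(out$cell_line, out$formulation_id), ]
}
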