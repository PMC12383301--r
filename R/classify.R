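#' Kinetic phenotype category from a profile
#'
#' The three-class rule: stimulatory if the relative final-confluence change
#' is at least `+class_rel` (default +20%), sustained for at least
#' `min_duration` hours with `p < alpha` at `min_sig_points` or more
#' timepoints; inhibitory is the mirror image at `-class_rel`; neutral if
#' the absolute relative change is below `neutral_rel` (default 10%) with
#' fewer than `min_sig_points` significant timepoints. Everything in between
#' (e.g. a 15% change, or a large change that is too brief) is
#' `indeterminate` rather than forced into a class. Threshold ties count as
#' active (the rule reads ">=").
#'
#' @param profile A `kinetic_profile` (or any list with `delta_relative`,
#'   `divergence_duration`, `n_sig_points`).
#' @param cfg `classifier` config section.
#' @return One of `"stimulatory"`, `"inhibitory"`, `"neutral"`,
#'   `"indeterminate"`.
#' @export
kinetic_category <- function(profile, cfg = stip_config()$classifier) {
  dr <- profile$delta_relative
  dur <- profile$divergence_duration
  nsig <- profile$n_sig_points
  if (dr >= cfg$class_rel && dur >= cfg$min_duration &&
      nsig >= cfg$min_sig_points) {
    return("stimulatory")
  }
  if (dr <= -cfg$class_rel && dur >= cfg$min_duration &&
      nsig >= cfg$min_sig_points) {
    return("inhibitory")
  }
  if (abs(dr) < cfg$neutral_rel && nsig < cfg$min_sig_points) {
    return("neutral")
  }
  "indeterminate"
}

#' Cytotoxicity gate on group death traces
#'
#' A response is cytotoxic-confounded when the group-mean cumulative death
#' at the final timepoint exceeds `death_cytotoxic` (default 5%). The gate
#' also reports whether the group mean ever exceeded the assay positivity
#' threshold `death_positive` (default 2.5%) at any time.
#'
#' @param death List of replicate death `stip_trace`s (treated arm).
#' @param cfg `classifier` config section.
#' @return List: `status` (`"pass"`/`"cytotoxic"`), `final_death` (group
#'   mean, percent), `positive` (logical).
#' @export
death_gate <- function(death, cfg = stip_config()$classifier) {
  tm <- trace_matrix(death)
  mean_curve <- colMeans(tm$values)
  final_death <- mean_curve[length(mean_curve)]
  list(
    status = if (final_death > cfg$death_cytotoxic) "cytotoxic" else "pass",
    final_death = unname(final_death),
    positive = any(mean_curve > cfg$death_positive)
  )
}

#' Secretome congruence with a kinetic category
#'
#' Advisory check that the IFN-gamma/IL-10 composite marker points the same
#' way as the kinetics: a stimulatory call is congruent when the treated
#' ratio is below `ratio_low` (permissive profile), an inhibitory call when
#' it is above `ratio_high` (suppressive profile), and a neutral call when
#' no analyte differs from control (per-analyte Welch tests, Bonferroni over
#' the 4 analytes, all adjusted p above `neutral_cytokine_p`). The verdict
#' is recorded as evidence and never overrides the kinetic category.
#'
#' @param category Kinetic category string.
#' @param treated,control Cytokine sample data frames (columns `analyte`,
#'   `concentration_pg_ml`, `below_llod`) for the treated and control arms.
#' @param cfg `classifier` config section.
#' @return `"congruent"`, `"incongruent"` or `"not_assessed"`.
#' @export
secretome_congruence <- function(category, treated, control,
                                 cfg = stip_config()$classifier) {
  if (is.null(treated) || nrow(treated) == 0) return("not_assessed")
  summ <- summarize_panel(treated)
  if (category %in% c("stimulatory", "inhibitory")) {
    if (is.na(summ$ratio)) {
      warning("IL-10 mean is zero or absent; ratio undefined")
      return("not_assessed")
    }
    if (category == "stimulatory") {
      return(if (summ$ratio < cfg$ratio_low) "congruent" else "incongruent")
    }
    return(if (summ$ratio > cfg$ratio_high) "congruent" else "incongruent")
  }
  if (category == "neutral") {
    if (is.null(control) || nrow(control) == 0) return("not_assessed")
    analytes <- intersect(unique(treated$analyte), unique(control$analyte))
    if (!length(analytes)) return("not_assessed")
    p <- vapply(analytes, function(a) {
      x <- treated$concentration_pg_ml[treated$analyte == a & !treated$below_llod]
      y <- control$concentration_pg_ml[control$analyte == a & !control$below_llod]
      if (length(x) < 2 || length(y) < 2) return(NA_real_)
      if (stats::var(x) == 0 && stats::var(y) == 0) {
        return(if (mean(x) == mean(y)) 1 else 0)
      }
      stats::t.test(x, y)$p.value
    }, 0)
    p_adj <- pmin(p * 4, 1)  # Bonferroni over the 4-analyte panel
    if (all(is.na(p_adj))) return("not_assessed")
    return(if (all(p_adj > cfg$neutral_cytokine_p, na.rm = TRUE))
      "congruent" else "incongruent")
  }
  "not_assessed"
}

#' Full STIP call for one line x formulation group
#'
#' Decision order: the cytotoxicity gate runs first — a cytotoxic death
#' signal yields `cytotoxic_confounded` and no phenotype Type is assigned;
#' otherwise the kinetic category decides the class and the secretome
#' congruence is recorded as evidence.
#'
#' @param profile `kinetic_profile` for the group.
#' @param death Optional list of treated-arm death traces.
#' @param treated_panel,control_panel Optional cytokine sample data frames.
#' @param cfg Full configuration list.
#' @return Object of class `stip_call`: `cell_line`, `formulation_id`,
#'   `category` (one of stimulatory/inhibitory/neutral/indeterminate/
#'   cytotoxic_confounded), `type` (`"Type I"`/`"Type II"`/`"Type III"` or
#'   `NA`) and an `evidence` list (magnitude/duration/significance passes,
#'   death gate, congruence).
#' @export
classify_stip <- function(profile, death = NULL, treated_panel = NULL,
                          control_panel = NULL, cfg = stip_config()) {
  cl <- cfg$classifier
  gate <- if (is.null(death)) {
    list(status = "pass", final_death = NA_real_, positive = NA)
  } else {
    death_gate(death, cl)
  }
  if (identical(gate$status, "cytotoxic")) {
    category <- "cytotoxic_confounded"
    congruence <- "not_assessed"
  } else {
    category <- kinetic_category(profile, cl)
    congruence <- secretome_congruence(category, treated_panel,
                                       control_panel, cl)
  }
  type <- switch(category, stimulatory = "Type I", inhibitory = "Type II",
                 neutral = "Type III", NA_character_)
  structure(list(
    cell_line = profile$cell_line,
    formulation_id = profile$formulation_id,
    category = category,
    type = type,
    evidence = list(
      delta_relative = profile$delta_relative,
      magnitude_pass = abs(profile$delta_relative) >= cl$class_rel,
      duration_pass = profile$divergence_duration >= cl$min_duration,
      significance_pass = profile$n_sig_points >= cl$min_sig_points,
      death_gate = gate,
      congruence = congruence
    )
  ), class = "stip_call")
}

#' @export
print.stip_call <- function(x, ...) {
  cat(sprintf("<stip_call %s / %s: %s%s>\n", x$cell_line,
              x$formulation_id, x$category,
              if (!is.na(x$type)) paste0(" (", x$type, ")") else ""))
  invisible(x)
}
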