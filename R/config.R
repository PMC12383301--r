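#' Default analysis configuration
#'
#' Returns the full nested list of tunable thresholds used throughout the
#' pipeline. Every value can be overridden via [stip_load_config()] or by
#' passing a modified list to the analysis functions.
#'
#' Sections:
#' \describe{
#'   \item{kinetics}{`onset_rel` (0.10): minimum |relative difference| vs
#'     control for divergence onset; `onset_run` (3): consecutive hourly
#'     points required to call onset; `onset_floor` (1.0): minimum
#'     baseline-subtracted control confluence (points) for a timepoint to be
#'     eligible — guards the relative difference against a near-zero
#'     denominator; `slope_window` (6 h): sliding-window width for the
#'     log-phase slope; `plateau_tol` (0.15 %/h) and `plateau_min` (6 h):
#'     terminal-plateau slope tolerance and minimum length; `alpha` (0.05).}
#'   \item{classifier}{`class_rel` (0.20): relative change calling an active
#'     (stimulatory/inhibitory) response; `neutral_rel` (0.10): band below
#'     which a non-significant response is neutral; `min_duration` (12 h);
#'     `min_sig_points` (5); `alpha` (0.05); `death_positive` (2.5%);
#'     `death_cytotoxic` (5%); `ratio_high` (6): IFN-gamma/IL-10 above which
#'     an inhibitory call is congruent; `ratio_low` (3): below which a
#'     stimulatory call is congruent; `neutral_cytokine_p` (0.1).}
#'   \item{fsi}{`weights`: non-negative, sum 1, over (delta_relative,
#'     logphase_slope, signed_duration, auc, intra_cv); `scale` (15).}
#'   \item{qc}{intra-assay CV bounds (8% active / 5% neutral), interbatch
#'     final-confluence CV bound (10%), onset CV bound (8%), max pairwise
#'     interbatch final-confluence difference (10 points).}
#'   \item{cluster}{`features`: profile columns fed to Ward-D2 clustering;
#'     `k_max` (5): largest candidate cluster count.}
#' }
#'
#' @return Nested named list of defaults.
#' @export
#' @examples
#' cfg <- stip_config()
#' cfg$classifier$class_rel
stip_config <- function() {
  list(
    kinetics = list(
      onset_rel = 0.10,
      onset_run = 3L,
      onset_floor = 1.0,
      slope_window = 6,
      plateau_tol = 0.15,
      plateau_min = 6,
      alpha = 0.05
    ),
    classifier = list(
      class_rel = 0.20,
      neutral_rel = 0.10,
      min_duration = 12,
      min_sig_points = 5L,
      alpha = 0.05,
      death_positive = 2.5,
      death_cytotoxic = 5.0,
      ratio_high = 6.0,
      ratio_low = 3.0,
      neutral_cytokine_p = 0.1
    ),
    fsi = list(
      weights = c(delta_relative = 0.30, logphase_slope = 0.20,
                  signed_duration = 0.15, auc = 0.25, intra_cv = 0.10),
      scale = 15
    ),
    qc = list(
      intra_cv_active = 8,
      intra_cv_neutral = 5,
      interbatch_final_cv = 10,
      interbatch_onset_cv = 8,
      interbatch_max_delta = 10
    ),
    cluster = list(
      features = c("logphase_slope", "auc", "signed_duration", "fsi"),
      k_max = 5L
    ),
    sim = list(
      replicates = 3L,
      batches = 3L,
      noise_sd = 1.0,
      interbatch_cv = 5,
      llod = 2.0,
      t_end = 48,
      dt = 1
    )
  )
}

#' Load a configuration file and merge it over the defaults
#'
#' Reads a YAML (or JSON) config and overlays it on [stip_config()]. Unknown
#' sections or keys are rejected so typos cannot silently fall back to a
#' default.
#'
#' @param path Path to a YAML/JSON configuration file, or `NULL` for defaults.
#' @return Validated nested configuration list.
#' @export
stip_load_config <- function(path = NULL) {
  cfg <- stip_config()
  if (is.null(path)) return(validate_config(cfg))
  stopifnot(file.exists(path))
  user <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.list(user)) stop("config file must contain a mapping of sections")
  for (section in names(user)) {
    if (!section %in% names(cfg)) {
      stop("unknown config section: ", section)
    }
    for (key in names(user[[section]])) {
      if (!key %in% names(cfg[[section]])) {
        stop("unknown config key: ", section, "$", key)
      }
    }
    cfg[[section]] <- modifyList(cfg[[section]], user[[section]])
  }
  # coerce fsi weights back to the canonical named vector
  w <- unlist(cfg$fsi$weights)
  cfg$fsi$weights <- setNames(as.numeric(w), names(stip_config()$fsi$weights))
  validate_config(cfg)
}

validate_config <- function(cfg) {
  cl <- cfg$classifier
  if (!(cl$neutral_rel > 0 && cl$neutral_rel < cl$class_rel)) {
    stop("classifier thresholds require 0 < neutral_rel < class_rel")
  }
  if (!(cl$death_positive > 0 && cl$death_positive < cl$death_cytotoxic)) {
    stop("classifier thresholds require 0 < death_positive < death_cytotoxic")
  }
  if (!(cl$ratio_low < cl$ratio_high)) {
    stop("classifier thresholds require ratio_low < ratio_high")
  }
  w <- cfg$fsi$weights
  if (any(w < 0) || abs(sum(w) - 1) > 1e-9) {
    stop("fsi weights must be non-negative and sum to 1")
  }
  if (cfg$sim$noise_sd < 0) stop("sim noise_sd must be >= 0")
  cfg
}

#' Print the effective configuration
#'
#' Writes every threshold with its section to the console, marking values
#' that differ from the package defaults as overridden.
#'
#' @param cfg Configuration list (default: package defaults).
#' @return Invisibly, the configuration.
#' @export
stip_show_config <- function(cfg = stip_config()) {
  defaults <- stip_config()
  for (section in names(cfg)) {
    cat(sprintf("[%s]\n", section))
    for (key in names(cfg[[section]])) {
      val <- cfg[[section]][[key]]
      def <- defaults[[section]][[key]]
      mark <- if (!isTRUE(all.equal(val, def))) "  (overridden)" else ""
      cat(sprintf("  %-22s %s%s\n", key,
                  paste(format(val, digits = 6), collapse = " "), mark))
    }
  }
  invisible(cfg)
}
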