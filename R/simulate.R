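#' Default simulated cell-line archetypes
#'
#' One row per line of the demonstration cohort, parameterizing logistic
#' growth (`control_K`: carrying capacity in confluence percent reached by
#' the control arm; `r`: growth rate per hour; `t_mid`: inflection hour)
#' and a treatment effect applied from `effect_onset` hours — multiplicative
#' factors on carrying capacity (`effect_K`, set so the treated/control
#' final-confluence ratio matches the cohort's per-line relative deltas) and
#' growth rate (`effect_r`). `death_plateau` is the cumulative-death percent
#' the arm approaches by 48 h (stimulatory/neutral well below the 2.5%
#' positivity threshold, inhibitory 2.8-3.2%, a cytotoxic archetype would
#' exceed the 5% gate).
#'
#' Inhibitory effects must begin while the control trajectory is still below
#' the reduced carrying capacity (confluence cannot decrease), so their
#' `effect_onset` sits early in the growth phase; the *detected* divergence
#' onset emerges later, once the separation clears the magnitude and
#' significance rules.
#'
#' @return Data frame of line archetypes.
#' @export
sim_default_lines <- function() {
  ref <- stip_reference_cohort()
  # neutral lines are generated as exact nulls (effect 1): the class is
  # defined by the absence of a directional treatment effect, so their small
  # reported deltas are sampling noise, not structure to build in
  eff_K <- ifelse(ref$category == "neutral", 1,
                  ref$final_confluence_mean / ref$control_final_mean)
  data.frame(
    name = ref$cell_line,
    true_class = ref$category,
    control_K = ref$control_final_mean,
    r = 0.25,
    t_mid = 20,
    effect_K = eff_K,
    effect_r = c(1.10, 1.10, 1.10, 0.90, 0.90, 1, 1, 1),
    effect_onset = c(10, 18, 20, 12, 10, 0, 0, 0),
    death_plateau = c(1.2, 1.2, 1.4, 2.8, 3.2, 1.0, 1.0, 1.0),
    stringsAsFactors = FALSE
  )
}

#' Build a simulation configuration
#'
#' @param lines Data frame of line archetypes ([sim_default_lines()]).
#' @param replicates Wells per arm (default 3).
#' @param batches Production batches for interbatch studies (default 3).
#' @param formulation_id Formulation label stamped on treated wells.
#' @param noise_sd Additive Gaussian well noise, confluence points
#'   (default 1.0).
#' @param interbatch_cv Percent CV of the per-batch multiplicative factor on
#'   carrying capacity (default 5). The factor is shared by both arms of a
#'   batch (treated and control share a plate/passage).
#' @param llod Cytokine lower limit of detection, pg/mL (default 2).
#' @param t_end,dt Time grid: hourly points over `[0, t_end]`.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(lines = sim_default_lines(), replicates = 3L,
                       batches = 3L, formulation_id = "FV-001",
                       noise_sd = 1.0, interbatch_cv = 5, llod = 2.0,
                       t_end = 48, dt = 1) {
  stopifnot(noise_sd >= 0, interbatch_cv >= 0, replicates >= 2,
            all(lines$control_K > 0), all(lines$control_K <= 100),
            all(lines$effect_onset >= 0 | lines$effect_K == 1))
  structure(list(lines = lines, replicates = as.integer(replicates),
                 batches = as.integer(batches),
                 formulation_id = formulation_id, noise_sd = noise_sd,
                 interbatch_cv = interbatch_cv, llod = llod,
                 times = seq(0, t_end, by = dt)),
            class = "sim_config")
}

# noiseless mean trajectory for one arm of one line
sim_mean_curve <- function(line, arm, batch_factor, times) {
  K <- line$control_K * batch_factor
  ctrl <- K * stats::plogis(line$r * (times - line$t_mid))
  if (arm == "control" || (line$effect_K == 1 && line$effect_r == 1)) {
    return(pmin(ctrl, 100))
  }
  on <- line$effect_onset
  K_eff <- K * line$effect_K
  r_eff <- line$r * line$effect_r
  c_on <- K * stats::plogis(line$r * (on - line$t_mid))
  if (K_eff <= c_on) {
    stop("invalid archetype for ", line$name,
         ": reduced capacity below confluence at effect onset")
  }
  # continuity: shift the post-onset logistic so it passes through c_on at
  # the onset time
  t_mid2 <- on + log(K_eff / c_on - 1) / r_eff
  treated <- ifelse(times < on, ctrl,
                    K_eff * stats::plogis(r_eff * (times - t_mid2)))
  pmin(treated, 100)
}

#' Simulate one well's confluence trace
#'
#' Logistic growth with a continuity-matched parameter switch at the
#' treatment-effect onset (treated arm only), additive Gaussian noise, and
#' clipping to \[0, 100\].
#'
#' @param line One row of the archetype table (as a list or 1-row data
#'   frame).
#' @param arm `"treated"` or `"control"`.
#' @param well_id Well coordinate for the trace.
#' @param batch_factor Multiplicative batch factor on carrying capacity.
#' @param noise_sd Additive noise SD (confluence points).
#' @param times Time grid in hours.
#' @param seed Optional integer; when given, the RNG is seeded so the trace
#'   is fully reproducible.
#' @return A `stip_trace`.
#' @export
simulate_trace <- function(line, arm = c("treated", "control"),
                           well_id = "A1", batch_factor = 1,
                           noise_sd = 1.0, times = seq(0, 48), seed = NULL) {
  arm <- match.arg(arm)
  if (!is.null(seed)) set.seed(seed)
  mu <- sim_mean_curve(as.list(line), arm, batch_factor, times)
  v <- pmin(pmax(mu + stats::rnorm(length(times), 0, noise_sd), 0), 100)
  confluence_trace(well_id, times, v)
}

sim_death_trace <- function(plateau, well_id, times, noise_sd = 0.05) {
  base <- plateau * (1 - exp(-times / 16))
  v <- cummax(pmax(base + stats::rnorm(length(times), 0, noise_sd), 0))
  death_trace(well_id, times, pmin(v, 100))
}

well_ids <- function(n) {
  grid <- as.vector(outer(LETTERS[1:8], 1:12, paste0))  # A1..H12 row-major
  if (n <= 96) return(grid[seq_len(n)])
  # more wells than one plate: split across plates with a plate prefix
  plates <- ceiling(n / 96)
  ids <- unlist(lapply(seq_len(plates), function(p) paste0("P", p, "-", grid)))
  ids[seq_len(n)]
}

#' Simulate a complete plate dataset for one batch
#'
#' Generates confluence and cumulative-death traces for every
#' line x arm x replicate well, a plate map, per-line cytokine panels
#' (treated draws from the line's class profile, control draws from the
#' basal/neutral profile, truncated at zero with values under the LLOD
#' flagged), and the ground-truth class labels.
#'
#' @param config A `sim_config`.
#' @param seed Integer seed; fully determines the dataset.
#' @param batch_factor Multiplicative batch factor (drawn by
#'   [simulate_interbatch_study()]; 1 for a single-batch run).
#' @param production_batch Batch label for the plate map.
#' @return List: `confluence` and `death` (named trace lists), `plate_map`,
#'   `cytokines` (data frame), `truth` (data frame `cell_line`,
#'   `true_class`).
#' @export
simulate_plate <- function(config, seed = 1, batch_factor = 1,
                           production_batch = "B1") {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  lines <- config$lines
  reps <- config$replicates
  n_wells <- nrow(lines) * 2 * reps
  wells <- well_ids(n_wells)
  secretome <- stip_reference_secretome()

  map_rows <- list(); conf <- list(); death <- list(); cyto <- list()
  w <- 0L
  for (i in seq_len(nrow(lines))) {
    line <- as.list(lines[i, ])
    for (arm in c("treated", "control")) {
      for (rep_i in seq_len(reps)) {
        w <- w + 1L
        id <- wells[w]
        conf[[id]] <- simulate_trace(line, arm, id, batch_factor,
                                     config$noise_sd, config$times)
        plateau <- if (arm == "treated") line$death_plateau else
          min(line$death_plateau, 1.0)
        death[[id]] <- sim_death_trace(plateau, id, config$times)
        map_rows[[w]] <- data.frame(
          well = id, cell_line = line$name, condition = arm,
          formulation_id = if (arm == "treated") config$formulation_id else "",
          production_batch = production_batch, replicate = rep_i,
          stringsAsFactors = FALSE)
      }
    }
    # cytokine panel: class profile for the treated arm, basal for control
    for (arm in c("treated", "control")) {
      grp <- if (arm == "treated") {
        if (line$true_class %in% secretome$group) line$true_class else "inhibitory"
      } else "neutral"
      pars <- secretome[secretome$group == grp, ]
      for (j in seq_len(nrow(pars))) {
        draws <- pmax(stats::rnorm(reps, pars$mean[j], pars$sd[j]), 0)
        cyto[[length(cyto) + 1L]] <- data.frame(
          sample_id = sprintf("%s-%s-%s-%d", line$name, arm,
                              pars$analyte[j], seq_len(reps)),
          cell_line = line$name, condition = arm, analyte = pars$analyte[j],
          concentration_pg_ml = draws,
          below_llod = draws < config$llod, stringsAsFactors = FALSE)
      }
    }
  }
  list(confluence = conf, death = death,
       plate_map = plate_map(do.call(rbind, map_rows)),
       cytokines = do.call(rbind, cyto),
       truth = data.frame(cell_line = lines$name,
                          true_class = lines$true_class,
                          stringsAsFactors = FALSE))
}

#' Simulate a multi-batch interbatch study
#'
#' Draws one multiplicative batch factor per batch (Gaussian with CV
#' `interbatch_cv`, shared by both arms of the batch) and simulates a full
#' plate per batch with identical class truth.
#'
#' @param config A `sim_config`.
#' @param n_batches Number of production batches (>= 2).
#' @param seed Integer seed.
#' @return List of per-batch datasets (as from [simulate_plate()]), with
#'   the drawn `batch_factor` attached to each.
#' @export
simulate_interbatch_study <- function(config, n_batches = config$batches,
                                      seed = 1) {
  stopifnot(n_batches >= 2)
  set.seed(seed)
  factors <- pmax(stats::rnorm(n_batches, 1, config$interbatch_cv / 100), 0.1)
  batch_seeds <- sample.int(.Machine$integer.max, n_batches)
  out <- lapply(seq_len(n_batches), function(b) {
    ds <- simulate_plate(config, seed = batch_seeds[b],
                         batch_factor = factors[b],
                         production_batch = paste0("B", b))
    ds$batch_factor <- factors[b]
    ds
  })
  names(out) <- paste0("B", seq_len(n_batches))
  out
}

#' Write a simulated dataset to CSV files
#'
#' Emits `confluence.csv`, `death.csv` (wide, `elapsed_h` first column),
#' `plate_map.csv`, `cytokines.csv` and `truth.json` in the formats the
#' readers consume.
#'
#' @param dataset Output of [simulate_plate()].
#' @param out_dir Target directory.
#' @return Invisibly, the written paths.
#' @export
write_simulated <- function(dataset, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wide <- function(traces) {
    times <- traces[[1]]$times
    df <- data.frame(elapsed_h = times)
    for (tr in traces) df[[tr$well_id]] <- tr$values
    df
  }
  p1 <- file.path(out_dir, "confluence.csv")
  utils::write.csv(wide(dataset$confluence), p1, row.names = FALSE)
  p2 <- file.path(out_dir, "death.csv")
  utils::write.csv(wide(dataset$death), p2, row.names = FALSE)
  p3 <- file.path(out_dir, "plate_map.csv")
  utils::write.csv(as.data.frame(dataset$plate_map), p3, row.names = FALSE)
  p4 <- file.path(out_dir, "cytokines.csv")
  utils::write.csv(dataset$cytokines, p4, row.names = FALSE)
  p5 <- file.path(out_dir, "truth.json")
  jsonlite::write_json(dataset$truth, p5, auto_unbox = TRUE, digits = NA)
  invisible(c(p1, p2, p3, p4, p5))
}
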