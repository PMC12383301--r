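#' Classification-recovery study on seeded synthetic cohorts
#'
#' Simulates `n_seeds` independent default cohorts and scores the STIP
#' category call of every line against its generative truth. Uses the light
#' per-line path (profile + kinetic category + death gate) rather than the
#' full bundle, since only the calls are scored.
#'
#' @param n_seeds Number of simulated cohorts.
#' @param noise_sd Well noise SD in confluence points.
#' @param seed Master seed; per-cohort seeds are derived from it.
#' @param cfg Configuration list.
#' @return List: `accuracy` (fraction of line calls equal to truth),
#'   `n_lines` (total calls scored), `by_class` (named accuracy per true
#'   class).
#' @export
simulation_recovery <- function(n_seeds = 200, noise_sd = 1.0, seed = 1,
                                cfg = stip_config()) {
  set.seed(seed)
  cohort_seeds <- sample.int(2^31 - 1, n_seeds)
  sc <- sim_config(noise_sd = noise_sd)
  hits <- list()
  for (k in seq_len(n_seeds)) {
    ds <- simulate_plate(sc, seed = cohort_seeds[k])
    calls <- classify_lines(ds, cfg)
    hits[[k]] <- data.frame(
      true_class = ds$truth$true_class,
      hit = calls[ds$truth$cell_line] == ds$truth$true_class)
  }
  all <- do.call(rbind, hits)
  list(accuracy = mean(all$hit), n_lines = nrow(all),
       by_class = tapply(all$hit, all$true_class, mean))
}

# light per-line classification of a simulated dataset: profile -> death
# gate -> kinetic category
classify_lines <- function(ds, cfg = stip_config()) {
  map <- ds$plate_map
  lines <- unique(map$cell_line)
  out <- vapply(lines, function(ln) {
    tw <- map$well[map$cell_line == ln & map$condition == "treated"]
    cw <- map$well[map$cell_line == ln & map$condition == "control"]
    prof <- kinetic_profile(ds$confluence[tw], ds$confluence[cw],
                            cell_line = ln, cfg = cfg)
    classify_stip(prof, death = ds$death[tw], cfg = cfg)$category
  }, "")
  names(out) <- lines
  out
}

#' Interbatch-validation study
#'
#' Simulates `n_studies` independent multi-batch experiments and runs
#' [interbatch_qc()] for every line. Reports the fraction of line-level
#' reports passing all four checks and the fraction with concordant
#' categories.
#'
#' @param n_studies Number of simulated studies.
#' @param n_batches Batches per study.
#' @param interbatch_cv Batch-factor CV in percent.
#' @param seed Master seed.
#' @param cfg Configuration list.
#' @return List: `pass_rate` (line-level overall pass fraction),
#'   `concordance_rate`, `n_reports`.
#' @export
interbatch_validation <- function(n_studies = 200, n_batches = 5,
                                  interbatch_cv = 5, seed = 1,
                                  cfg = stip_config()) {
  set.seed(seed)
  study_seeds <- sample.int(2^31 - 1, n_studies)
  sc <- sim_config(interbatch_cv = interbatch_cv)
  pass <- conc <- logical(0)
  for (k in seq_len(n_studies)) {
    study <- simulate_interbatch_study(sc, n_batches = n_batches,
                                       seed = study_seeds[k])
    lines <- study[[1]]$truth$cell_line
    per_batch <- lapply(study, function(ds) {
      map <- ds$plate_map
      setNames(lapply(lines, function(ln) {
        tw <- map$well[map$cell_line == ln & map$condition == "treated"]
        cw <- map$well[map$cell_line == ln & map$condition == "control"]
        kinetic_profile(ds$confluence[tw], ds$confluence[cw],
                        cell_line = ln, cfg = cfg)
      }), lines)
    })
    for (ln in lines) {
      profs <- lapply(per_batch, `[[`, ln)
      cats <- vapply(profs, function(p) kinetic_category(p, cfg$classifier), "")
      qc <- interbatch_qc(profs, cats, cfg$qc)
      pass <- c(pass, isTRUE(qc$pass))
      conc <- c(conc, isTRUE(qc$category_concordant))
    }
  }
  list(pass_rate = mean(pass), concordance_rate = mean(conc),
       n_reports = length(pass))
}

#' Null-calibration check of the pointwise Welch test
#'
#' Draws `n_points` independent null timepoints (both arms from the same
#' Gaussian) with `n_rep` replicates per arm and reports the fraction
#' rejected at `alpha`.
#'
#' @param n_points Number of simulated timepoints.
#' @param n_rep Replicates per arm.
#' @param alpha Significance level.
#' @param seed Seed.
#' @return Observed type-I error rate.
#' @export
welch_null_calibration <- function(n_points = 10000, n_rep = 10,
                                   alpha = 0.05, seed = 1) {
  set.seed(seed)
  a <- matrix(stats::rnorm(n_rep * n_points), n_rep)
  b <- matrix(stats::rnorm(n_rep * n_points), n_rep)
  mean(welch_p(a, b) < alpha)
}
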