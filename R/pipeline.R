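#' Run the full analysis pipeline on one dataset
#'
#' Orchestrates ingest, kinetics, per-timepoint tests, classification, FSI,
#' QC, the compatibility matrix and clustering, and (optionally) writes the
#' result bundle. The dataset may come from [simulate_plate()] or be
#' assembled from the readers ([read_confluence_export()],
#' [read_plate_map()], ...). Death traces and cytokine panels are optional;
#' without them the cytotoxicity gate passes trivially and congruence is
#' `not_assessed`.
#'
#' @param confluence Named list of confluence `stip_trace`s.
#' @param map A `stip_plate_map`.
#' @param death Optional named list of death traces (same wells).
#' @param cytokines Optional cytokine sample data frame (with `cell_line`
#'   and `condition` columns).
#' @param cfg Full configuration list ([stip_config()]).
#' @param out_dir Optional directory; when given, [write_results()] is
#'   called.
#' @return List of class `stip_analysis`: `profiles`, `metrics` (data
#'   frame), `calls` (list of `stip_call`), `calls_df`, `fsi` (ranked),
#'   `intra_qc`, `interbatch_qc`, `compatibility`, `features`,
#'   `similarity`, `clusters`.
#' @export
run_analyze <- function(confluence, map, death = NULL, cytokines = NULL,
                        cfg = stip_config(), out_dir = NULL) {
  if (missing(map) || is.null(map)) stop("missing input: plate map")
  if (missing(confluence) || is.null(confluence)) {
    stop("missing input: confluence traces")
  }
  map <- if (inherits(map, "stip_plate_map")) map else plate_map(map)
  absent <- setdiff(map$well, names(confluence))
  if (length(absent)) {
    stop("plate map wells without confluence traces: ",
         paste(absent, collapse = ", "))
  }

  treated_map <- map[map$condition == "treated", ]
  groups <- unique(treated_map[, c("cell_line", "formulation_id",
                                   "production_batch")])
  profiles <- list()
  calls <- list()
  for (i in seq_len(nrow(groups))) {
    g <- groups[i, ]
    tw <- map$well[map$condition == "treated" &
                     map$cell_line == g$cell_line &
                     map$formulation_id == g$formulation_id &
                     map$production_batch == g$production_batch]
    cw <- map$well[map$condition == "control" &
                     map$cell_line == g$cell_line &
                     map$production_batch == g$production_batch]
    prof <- kinetic_profile(confluence[tw], confluence[cw],
                            cell_line = g$cell_line,
                            formulation_id = g$formulation_id,
                            production_batch = g$production_batch,
                            cfg = cfg)
    dg <- if (!is.null(death)) death[intersect(tw, names(death))] else NULL
    if (!is.null(dg) && length(dg) == 0) dg <- NULL
    tp <- cp <- NULL
    if (!is.null(cytokines)) {
      tp <- cytokines[cytokines$cell_line == g$cell_line &
                        cytokines$condition == "treated", ]
      cp <- cytokines[cytokines$cell_line == g$cell_line &
                        cytokines$condition == "control", ]
      if (nrow(tp) == 0) tp <- NULL
      if (!is.null(cp) && nrow(cp) == 0) cp <- NULL
    }
    key <- paste(g$cell_line, g$formulation_id, g$production_batch, sep = "|")
    profiles[[key]] <- prof
    calls[[key]] <- classify_stip(prof, death = dg, treated_panel = tp,
                                  control_panel = cp, cfg = cfg)
  }

  metrics <- profiles_to_df(profiles)
  calls_df <- data.frame(
    cell_line = vapply(calls, function(c) c$cell_line, ""),
    formulation_id = vapply(calls, function(c) c$formulation_id, ""),
    production_batch = vapply(profiles, function(p) p$production_batch, ""),
    category = vapply(calls, function(c) c$category, ""),
    stringsAsFactors = FALSE)
  rownames(calls_df) <- NULL

  # per-line pooled profiles (feature means across formulations/batches)
  # feed the cohort-level FSI and clustering
  lines <- unique(metrics$cell_line)
  pooled <- lapply(lines, function(ln) {
    idx <- which(metrics$cell_line == ln)
    p0 <- profiles[[idx[1]]]
    fm <- colMeans(t(vapply(profiles[idx], feature_vector, numeric(5))))
    structure(list(
      cell_line = ln, formulation_id = "pooled", production_batch = "pooled",
      final_confluence_mean = mean(metrics$final_confluence_mean[idx]),
      final_confluence_sd = mean(metrics$final_confluence_sd[idx]),
      control_final_mean = mean(metrics$control_final_mean[idx]),
      delta_points = mean(metrics$delta_points[idx]),
      delta_relative = fm[["delta_relative"]],
      onset_hours = mean(metrics$onset_hours[idx]),
      logphase_slope = fm[["logphase_slope"]],
      auc = fm[["auc"]],
      divergence_duration = abs(fm[["signed_duration"]]),
      plateau_window = p0$plateau_window,
      intra_cv = fm[["intra_cv"]],
      n_sig_points = max(metrics$n_sig_points[idx])
    ), class = "kinetic_profile")
  })
  names(pooled) <- lines

  fsi <- if (length(pooled) >= 2) {
    rank_lines(fsi_scores(pooled, cfg$fsi$weights, cfg$fsi$scale))
  } else NULL

  intra <- intra_assay_qc(profiles, calls_df$category, cfg$qc)

  # interbatch verdicts per line x formulation (only meaningful with >= 2
  # batches of the same pair)
  lf <- unique(calls_df[, c("cell_line", "formulation_id")])
  inter <- lapply(seq_len(nrow(lf)), function(i) {
    idx <- which(calls_df$cell_line == lf$cell_line[i] &
                   calls_df$formulation_id == lf$formulation_id[i])
    interbatch_qc(profiles[idx], calls_df$category[idx], cfg$qc)
  })
  names(inter) <- paste(lf$cell_line, lf$formulation_id, sep = "|")

  # consensus calls (unique category per line x formulation; ties -> the
  # lexically first majority category, flagged by concordance above)
  consensus <- do.call(rbind, lapply(seq_len(nrow(lf)), function(i) {
    idx <- which(calls_df$cell_line == lf$cell_line[i] &
                   calls_df$formulation_id == lf$formulation_id[i])
    tab <- sort(table(calls_df$category[idx]), decreasing = TRUE)
    data.frame(cell_line = lf$cell_line[i],
               formulation_id = lf$formulation_id[i],
               category = names(tab)[1], stringsAsFactors = FALSE)
  }))
  compat <- build_compatibility_matrix(consensus)

  features <- similarity <- clusters <- NULL
  if (length(pooled) >= 3 && !is.null(fsi)) {
    features <- feature_matrix(pooled, fsi, cfg$cluster$features)
    similarity <- similarity_matrix(features)
    clusters <- ward_cluster(features, cfg$cluster$k_max)
  }

  res <- structure(list(
    profiles = profiles, metrics = metrics, calls = calls,
    calls_df = calls_df, fsi = fsi, intra_qc = intra,
    interbatch_qc = inter, compatibility = compat, features = features,
    similarity = similarity, clusters = clusters
  ), class = "stip_analysis")

  if (!is.null(out_dir)) {
    qc_json <- list(
      intra_assay = intra,
      interbatch = lapply(inter, function(x) x[setdiff(names(x), "checks")])
    )
    calls_json <- lapply(calls, function(c) {
      ev <- c$evidence
      list(cell_line = c$cell_line, formulation_id = c$formulation_id,
           category = c$category, type = c$type,
           evidence = list(
             delta_relative = ev$delta_relative,
             magnitude_pass = ev$magnitude_pass,
             duration_pass = ev$duration_pass,
             significance_pass = ev$significance_pass,
             death_final = ev$death_gate$final_death,
             death_status = ev$death_gate$status,
             congruence = ev$congruence))
    })
    write_results(out_dir, metrics = metrics, calls = calls_json,
                  qc = qc_json, fsi = fsi, compat = compat,
                  similarity = similarity, clusters = clusters)
  }
  res
}

#' Analyze a simulated dataset end to end
#'
#' Convenience wrapper binding [simulate_plate()] output to [run_analyze()].
#'
#' @param dataset Output of [simulate_plate()].
#' @param cfg Configuration list.
#' @param out_dir Optional output directory.
#' @return A `stip_analysis`.
#' @export
analyze_dataset <- function(dataset, cfg = stip_config(), out_dir = NULL) {
  run_analyze(dataset$confluence, dataset$plate_map, dataset$death,
              dataset$cytokines, cfg = cfg, out_dir = out_dir)
}
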