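#' Baseline-subtract a trace at its first timepoint
#'
#' Subtracts the value at the earliest time from the whole series and clips
#' negative excursions at 0. Used for divergence-onset computations so that
#' lines with different seeding baselines are comparable; final confluence,
#' slope and AUC are computed on the raw scale. The raw values are kept in
#' the `"raw"` attribute.
#'
#' @param trace A `stip_trace`.
#' @return Baseline-subtracted `stip_trace`.
#' @export
normalize_to_t0 <- function(trace) {
  stopifnot(inherits(trace, "stip_trace"))
  out <- trace
  out$values <- pmax(trace$values - trace$values[1], 0)
  attr(out, "raw") <- trace$values
  out
}

#' Three-point moving-average smoothing
#'
#' Centered window of 3; the two endpoints use the available 2-point window.
#' Length is preserved. Accepts either a `stip_trace` or a bare numeric
#' vector.
#'
#' @param x `stip_trace` or numeric vector, length >= 3.
#' @return Same type as the input, smoothed.
#' @export
smooth_ma3 <- function(x) {
  if (inherits(x, "stip_trace")) {
    x$values <- smooth_ma3(x$values)
    return(x)
  }
  n <- length(x)
  if (n < 3) stop("smoothing needs a series of length >= 3")
  out <- x
  out[1] <- mean(x[1:2])
  out[n] <- mean(x[(n - 1):n])
  if (n > 2) {
    out[2:(n - 1)] <- (x[1:(n - 2)] + x[2:(n - 1)] + x[3:n]) / 3
  }
  out
}

# shared-grid check + replicate matrix [rep x time]
trace_matrix <- function(traces, tol = 1e-6) {
  stopifnot(length(traces) >= 1)
  t0 <- traces[[1]]$times
  for (tr in traces) {
    if (length(tr$times) != length(t0) || any(abs(tr$times - t0) > tol)) {
      stop("replicate traces are not on a shared time grid")
    }
  }
  m <- do.call(rbind, lapply(traces, `[[`, "values"))
  rownames(m) <- vapply(traces, `[[`, "", "well_id")
  list(times = t0, values = m)
}

#' Pointwise mean and SD curve across replicate traces
#'
#' @param traces List of >= 2 `stip_trace` replicates on a shared grid.
#' @return List with `times`, `mean`, `sd` (sample SD, n-1 denominator), `n`.
#' @export
group_mean_curve <- function(traces) {
  if (length(traces) < 2) stop("need >= 2 replicate traces")
  tm <- trace_matrix(traces)
  list(times = tm$times,
       mean = colMeans(tm$values),
       sd = apply(tm$values, 2, stats::sd),
       n = nrow(tm$values))
}

#' Final-confluence delta versus control
#'
#' @param treated_final Treated-group mean final confluence (percent).
#' @param control_final Control-group mean final confluence (percent, > 0).
#' @return List with `delta_points` (treated - control, percentage points)
#'   and `delta_relative` (`delta_points / control_final`).
#' @export
#' @examples
#' delta_vs_control(63.2, 29.1)  # +34.1 points, +1.172 relative
delta_vs_control <- function(treated_final, control_final) {
  if (!is.finite(control_final) || control_final <= 0) {
    stop("control final confluence must be > 0")
  }
  dp <- treated_final - control_final
  list(delta_points = dp, delta_relative = dp / control_final)
}

# Vectorized Welch two-sample t-test over the columns of two replicate
# matrices [rep x time]. Returns two-tailed p per column. Zero pooled
# variance: p = 1 when the means are equal (convention), 0 otherwise.
welch_p <- function(a, b) {
  n1 <- nrow(a); n2 <- nrow(b)
  m1 <- colMeans(a); m2 <- colMeans(b)
  v1 <- apply(a, 2, stats::var); v2 <- apply(b, 2, stats::var)
  se2 <- v1 / n1 + v2 / n2
  p <- rep(1, length(m1))
  nz <- se2 > 0
  tstat <- (m1[nz] - m2[nz]) / sqrt(se2[nz])
  df <- se2[nz]^2 / ((v1[nz] / n1)^2 / (n1 - 1) + (v2[nz] / n2)^2 / (n2 - 1))
  p[nz] <- 2 * stats::pt(-abs(tstat), df)
  p[!nz] <- ifelse(m1[!nz] == m2[!nz], 1, 0)
  p
}

#' Per-timepoint Welch t-tests between treated and control replicates
#'
#' Unequal-variance (Welch) two-tailed t-test at every timepoint on the raw
#' confluence values, with no multiplicity correction: the classification
#' rule counts raw `p < alpha` points.
#'
#' @param treated,control Lists of >= 2 replicate `stip_trace`s each, on a
#'   shared grid.
#' @param alpha Significance level (default 0.05).
#' @return Object of class `pointwise_stats`: `times`, `p_values`, `alpha`,
#'   `n_sig` (count of `p < alpha` timepoints).
#' @export
pointwise_tests <- function(treated, control, alpha = 0.05) {
  if (length(treated) < 2 || length(control) < 2) {
    stop("need >= 2 replicates per arm")
  }
  tt <- trace_matrix(treated)
  cc <- trace_matrix(control)
  if (length(tt$times) != length(cc$times) ||
      any(abs(tt$times - cc$times) > 1e-6)) {
    stop("treated and control traces are not on a shared time grid")
  }
  p <- welch_p(tt$values, cc$values)
  structure(list(times = tt$times, p_values = p, alpha = alpha,
                 n_sig = sum(p < alpha)),
            class = "pointwise_stats")
}

# qualifying-point vector used by onset and duration rules: relative
# difference of (baseline-subtracted) mean curves at least `rel`, pointwise
# p < alpha, and the control denominator at least `floor_` points
qualifying_points <- function(treated_mean, control_mean, stats, rel, floor_) {
  ok_floor <- control_mean >= floor_
  reldiff <- rep(NA_real_, length(control_mean))
  reldiff[ok_floor] <- (treated_mean[ok_floor] - control_mean[ok_floor]) /
    control_mean[ok_floor]
  ok_floor & !is.na(reldiff) & abs(reldiff) >= rel &
    stats$p_values < stats$alpha
}

#' Divergence onset time
#'
#' Earliest time at which the treated mean curve departs from control by at
#' least `onset_rel` in relative terms with pointwise `p < alpha`, sustained
#' for `onset_run` consecutive timepoints. Curves should be
#' baseline-subtracted ([normalize_to_t0()]) and smoothed; timepoints where
#' the control mean is below `onset_floor` confluence points are never
#' eligible (the relative difference is unstable near a zero baseline).
#'
#' @param treated_mean,control_mean Mean curves (numeric, shared grid).
#' @param stats `pointwise_stats` for the same grid.
#' @param cfg `kinetics` section of [stip_config()].
#' @return Onset time in hours, or `NA` if no qualifying run exists.
#' @export
divergence_onset <- function(treated_mean, control_mean, stats,
                             cfg = stip_config()$kinetics) {
  q <- qualifying_points(treated_mean, control_mean, stats,
                         cfg$onset_rel, cfg$onset_floor)
  run <- cfg$onset_run
  n <- length(q)
  if (n < run) return(NA_real_)
  for (i in seq_len(n - run + 1)) {
    if (all(q[i:(i + run - 1)])) return(stats$times[i])
  }
  NA_real_
}

#' Sustained divergence duration
#'
#' Length in hours of the longest run of consecutive timepoints with
#' |relative difference| >= `class_rel` and `p < alpha`. A run of k
#' qualifying points on a grid with spacing dt counts as `k * dt` hours.
#'
#' @inheritParams divergence_onset
#' @param class_rel Relative-magnitude threshold (default 0.20).
#' @return Duration in hours (0 if no point qualifies).
#' @export
sustained_duration <- function(treated_mean, control_mean, stats,
                               cfg = stip_config()$kinetics,
                               class_rel = 0.20) {
  q <- qualifying_points(treated_mean, control_mean, stats,
                         class_rel, cfg$onset_floor)
  if (!any(q)) return(0)
  r <- rle(q)
  dt <- stats::median(diff(stats$times))
  max(r$lengths[r$values]) * dt
}

# least-squares slopes of all sliding windows of `w_pts` points
window_slopes <- function(times, values, w_pts) {
  n <- length(values)
  starts <- seq_len(n - w_pts + 1)
  vapply(starts, function(i) {
    tt <- times[i:(i + w_pts - 1)]
    vv <- values[i:(i + w_pts - 1)]
    sum((tt - mean(tt)) * (vv - mean(vv))) / sum((tt - mean(tt))^2)
  }, 0)
}

#' Log-phase slope of a mean curve
#'
#' Maximum-magnitude least-squares slope over all sliding windows of
#' `slope_window` hours on the (smoothed) curve; the sign is preserved, so a
#' declining curve yields a negative slope.
#'
#' @param times,values Mean curve on an hourly-type grid.
#' @param cfg `kinetics` config section.
#' @return Slope in percent per hour.
#' @export
logphase_slope <- function(times, values, cfg = stip_config()$kinetics) {
  dt <- stats::median(diff(times))
  w_pts <- max(2L, as.integer(round(cfg$slope_window / dt)) + 1L)
  if (w_pts > length(values)) stop("slope window is longer than the curve")
  sl <- window_slopes(times, values, w_pts)
  sl[which.max(abs(sl))]
}

#' Trapezoidal area under a confluence curve
#'
#' @param times,values Curve (raw confluence percent).
#' @return AUC in percent x hours over the observed span.
#' @export
trapezoid_auc <- function(times, values) {
  stopifnot(length(times) >= 2, length(times) == length(values))
  pracma::trapz(times, values)
}

#' Terminal plateau window
#'
#' Longest terminal interval over which every sliding-window slope magnitude
#' is at most `plateau_tol` percent/hour, on the smoothed curve. Returns
#' `NULL` if the qualifying terminal stretch is shorter than `plateau_min`
#' hours.
#'
#' @param times,values Smoothed mean curve.
#' @param cfg `kinetics` config section.
#' @return Numeric `c(start, end)` in hours, or `NULL`.
#' @export
plateau_window <- function(times, values, cfg = stip_config()$kinetics) {
  dt <- stats::median(diff(times))
  w_pts <- max(2L, as.integer(round(cfg$slope_window / dt)) + 1L)
  if (w_pts > length(values)) return(NULL)
  sl <- window_slopes(times, values, w_pts)
  ok <- abs(sl) <= cfg$plateau_tol
  # walk back from the last window; the plateau starts at the first window
  # of the terminal all-quiet run
  if (!ok[length(ok)]) return(NULL)
  i <- length(ok)
  while (i > 1 && ok[i - 1]) i <- i - 1
  start <- times[i]
  end <- times[length(times)]
  if (end - start < cfg$plateau_min) return(NULL)
  c(start, end)
}

#' Intra-assay coefficient of variation of replicate final confluences
#'
#' @param finals Numeric vector (>= 2) of per-replicate final confluence.
#' @return CV in percent: `100 * sd / mean`.
#' @export
intra_cv <- function(finals) {
  if (length(finals) < 2) stop("need >= 2 replicate finals")
  m <- mean(finals)
  if (m <= 0) stop("mean final confluence must be > 0")
  100 * stats::sd(finals) / m
}

#' Compute the full kinetic profile for one treated/control group pair
#'
#' Runs the kinetics stack: raw final confluence and delta, per-timepoint
#' Welch tests, divergence onset and sustained duration on
#' baseline-subtracted smoothed mean curves, log-phase slope, AUC and
#' plateau on the raw smoothed treated mean curve, and intra-assay CV.
#'
#' @param treated,control Lists of replicate `stip_trace`s.
#' @param cell_line,formulation_id,production_batch Identifiers carried into
#'   the profile.
#' @param cfg Full configuration list ([stip_config()]).
#' @return Object of class `kinetic_profile` (named list of metrics) with
#'   the `pointwise_stats` attached as `$stats`.
#' @export
kinetic_profile <- function(treated, control, cell_line = NA_character_,
                            formulation_id = NA_character_,
                            production_batch = NA_character_,
                            cfg = stip_config()) {
  kin <- cfg$kinetics
  tt <- trace_matrix(treated)
  cc <- trace_matrix(control)
  finals_t <- tt$values[, ncol(tt$values)]
  finals_c <- cc$values[, ncol(cc$values)]
  stats <- pointwise_tests(treated, control, alpha = kin$alpha)
  delta <- delta_vs_control(mean(finals_t), mean(finals_c))

  mean_t_raw <- smooth_ma3(colMeans(tt$values))
  mean_c_raw <- smooth_ma3(colMeans(cc$values))
  norm_t <- smooth_ma3(colMeans(do.call(
    rbind, lapply(treated, function(x) normalize_to_t0(x)$values))))
  norm_c <- smooth_ma3(colMeans(do.call(
    rbind, lapply(control, function(x) normalize_to_t0(x)$values))))

  onset <- divergence_onset(norm_t, norm_c, stats, kin)
  duration <- sustained_duration(norm_t, norm_c, stats, kin,
                                 class_rel = cfg$classifier$class_rel)
  plateau <- plateau_window(tt$times, mean_t_raw, kin)

  structure(list(
    cell_line = cell_line,
    formulation_id = formulation_id,
    production_batch = production_batch,
    final_confluence_mean = mean(finals_t),
    final_confluence_sd = stats::sd(finals_t),
    control_final_mean = mean(finals_c),
    delta_points = delta$delta_points,
    delta_relative = delta$delta_relative,
    onset_hours = onset,
    logphase_slope = logphase_slope(tt$times, mean_t_raw, kin),
    auc = trapezoid_auc(tt$times, mean_t_raw),
    divergence_duration = duration,
    plateau_window = plateau,
    intra_cv = intra_cv(finals_t),
    n_sig_points = stats$n_sig,
    stats = stats
  ), class = "kinetic_profile")
}

#' Flatten a list of kinetic profiles into a data frame
#'
#' @param profiles List of `kinetic_profile` objects.
#' @return Data frame, one row per profile.
#' @export
profiles_to_df <- function(profiles) {
  do.call(rbind, lapply(profiles, function(p) {
    data.frame(
      cell_line = p$cell_line,
      formulation_id = p$formulation_id,
      production_batch = p$production_batch,
      final_confluence_mean = p$final_confluence_mean,
      final_confluence_sd = p$final_confluence_sd,
      control_final_mean = p$control_final_mean,
      delta_points = p$delta_points,
      delta_relative = p$delta_relative,
      onset_hours = if (is.null(p$onset_hours)) NA_real_ else p$onset_hours,
      logphase_slope = p$logphase_slope,
      auc = p$auc,
      divergence_duration = p$divergence_duration,
      plateau_start = if (is.null(p$plateau_window)) NA_real_ else p$plateau_window[1],
      plateau_end = if (is.null(p$plateau_window)) NA_real_ else p$plateau_window[2],
      intra_cv = p$intra_cv,
      n_sig_points = p$n_sig_points,
      stringsAsFactors = FALSE
    )
  }))
}
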