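#' Construct a validated confluence trace
#'
#' A trace is one well's hourly confluence time series over the monitored
#' window (typically 0-48 h). Invariants enforced: strictly increasing times
#' starting at >= 0 on a near-uniform grid (each interval within 10% of the
#' median interval), values in \[0, 100\], length >= 2.
#'
#' @param well_id Plate coordinate, e.g. `"B7"` (case-insensitive on input).
#' @param times Numeric vector of hours since treatment.
#' @param values Numeric vector of confluence percent.
#' @return An object of class `stip_trace`.
#' @export
confluence_trace <- function(well_id, times, values) {
  new_trace(well_id, times, values, kind = "confluence")
}

#' Construct a validated cumulative cell-death trace
#'
#' Like [confluence_trace()] but for cumulative dead-cell percent; values
#' must additionally be non-decreasing up to a smoothing tolerance of 0.2
#' percentage points.
#'
#' @inheritParams confluence_trace
#' @return An object of class `stip_trace` with kind `"death"`.
#' @export
death_trace <- function(well_id, times, values) {
  tr <- new_trace(well_id, times, values, kind = "death")
  if (any(diff(values) < -0.2)) {
    stop("death trace for well ", well_id,
         " decreases by more than the 0.2-point tolerance")
  }
  tr
}

new_trace <- function(well_id, times, values, kind) {
  times <- as.numeric(times)
  values <- as.numeric(values)
  if (length(times) != length(values)) {
    stop("times and values must have equal length (well ", well_id, ")")
  }
  if (length(times) < 2) stop("trace needs >= 2 points (well ", well_id, ")")
  if (any(!is.finite(times)) || any(!is.finite(values))) {
    stop("non-finite entries in trace for well ", well_id)
  }
  if (any(diff(times) <= 0)) {
    stop("time column must be strictly increasing (well ", well_id, ")")
  }
  if (times[1] < 0) stop("first time must be >= 0 (well ", well_id, ")")
  dt <- diff(times)
  if (any(abs(dt - stats::median(dt)) > 0.1 * stats::median(dt) + 1e-9)) {
    stop("time grid is not uniform within 10% of the median interval (well ",
         well_id, ")")
  }
  bad <- which(values < 0 | values > 100)
  if (length(bad)) {
    stop(sprintf("values outside [0,100] in well %s at times %s",
                 well_id, paste(times[bad], collapse = ", ")))
  }
  structure(list(well_id = toupper(well_id), times = times, values = values),
            class = "stip_trace", kind = kind)
}

#' @export
print.stip_trace <- function(x, ...) {
  cat(sprintf("<stip_trace %s: %d points, t = [%g, %g] h, range [%.1f, %.1f]>\n",
              x$well_id, length(x$times), min(x$times), max(x$times),
              min(x$values), max(x$values)))
  invisible(x)
}

#' Construct a validated plate map
#'
#' @param df Data frame with columns `well`, `cell_line`, `condition`
#'   (`treated`/`control`), `formulation_id` (empty/NA for controls),
#'   `production_batch`, `replicate`.
#' @return The validated data frame with class `stip_plate_map`. Every
#'   treated (cell_line, formulation_id, production_batch) group must have a
#'   matched control group for the same line and batch; duplicate wells are
#'   an error; groups with fewer than 3 replicates trigger a warning.
#' @export
plate_map <- function(df) {
  needed <- c("well", "cell_line", "condition", "formulation_id",
              "production_batch", "replicate")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    stop("plate map is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  df$well <- toupper(as.character(df$well))
  if (anyDuplicated(df$well)) {
    stop("duplicate well ids in plate map: ",
         paste(unique(df$well[duplicated(df$well)]), collapse = ", "))
  }
  if (!all(df$condition %in% c("treated", "control"))) {
    stop("condition must be 'treated' or 'control'")
  }
  df$replicate <- as.integer(df$replicate)
  if (any(is.na(df$replicate)) || any(df$replicate < 1)) {
    stop("replicate must be a positive integer")
  }
  treated <- df[df$condition == "treated", ]
  control <- df[df$condition == "control", ]
  tg <- unique(treated[, c("cell_line", "formulation_id", "production_batch")])
  for (i in seq_len(nrow(tg))) {
    has_ctrl <- any(control$cell_line == tg$cell_line[i] &
                      control$production_batch == tg$production_batch[i])
    if (!has_ctrl) {
      stop("no matched control for treated group ", tg$cell_line[i], " / ",
           tg$formulation_id[i], " / batch ", tg$production_batch[i])
    }
  }
  grp <- interaction(df$cell_line, df$condition, df$production_batch,
                     drop = TRUE)
  counts <- table(grp)
  if (any(counts < 2)) {
    stop("every group needs >= 2 replicates; offending group(s): ",
         paste(names(counts)[counts < 2], collapse = ", "))
  }
  if (any(counts < 3)) {
    warning("group(s) with fewer than 3 replicates: ",
            paste(names(counts)[counts < 3], collapse = ", "))
  }
  class(df) <- c("stip_plate_map", "data.frame")
  df
}
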