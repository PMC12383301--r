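#' Read a wide-format confluence (or cell-death) export
#'
#' Parses CSV exports with elapsed hours in the first column (`elapsed_h`)
#' and one column per well. Lines starting with `#` are comments. Two
#' dialects are supported: `point` (`,`-separated, `.` decimals) and `comma`
#' (`;`-separated, `,` decimals, as emitted by instruments on European
#' locales); `auto` detects the dialect from the header/first data line.
#'
#' Rows with negative elapsed time (pre-treatment frames) are dropped with a
#' warning. Isolated missing values (runs of at most 2 consecutive `NA`s
#' inside a well column) are linearly interpolated; longer gaps are an error.
#'
#' @param path CSV file path.
#' @param dialect `"auto"` (default), `"comma"` or `"point"`.
#' @param kind `"confluence"` or `"death"`.
#' @return Named list of [confluence_trace()] / [death_trace()] objects,
#'   one per well column.
#' @export
read_confluence_export <- function(path, dialect = c("auto", "comma", "point"),
                                   kind = c("confluence", "death")) {
  dialect <- match.arg(dialect)
  kind <- match.arg(kind)
  stopifnot(file.exists(path))
  raw <- readLines(path, warn = FALSE)
  raw <- raw[!grepl("^\\s*#", raw) & nzchar(trimws(raw))]
  if (length(raw) < 2) stop("export has no data rows: ", path)
  if (dialect == "auto") {
    dialect <- if (grepl(";", raw[1])) "comma" else "point"
  }
  sep <- if (dialect == "comma") ";" else ","
  dec <- if (dialect == "comma") "," else "."
  unquote <- function(x) gsub("^\"|\"$", "", trimws(x))
  header <- unquote(strsplit(raw[1], sep, fixed = TRUE)[[1]])
  cells <- lapply(raw[-1], function(l)
    unquote(strsplit(l, sep, fixed = TRUE)[[1]]))
  ncol_bad <- which(vapply(cells, length, 1L) != length(header))
  if (length(ncol_bad)) {
    stop("row ", ncol_bad[1] + 1L, " has ", length(cells[[ncol_bad[1]]]),
         " fields, expected ", length(header))
  }
  parse_num <- function(x, row, col) {
    x[x == "" | toupper(x) == "NA"] <- NA_character_
    if (dec == ",") x <- gsub(",", ".", x, fixed = TRUE)
    out <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(out))
    if (length(bad)) {
      stop(sprintf("non-numeric value '%s' at row %d, column '%s'",
                   x[bad[1]], row[bad[1]] + 1L, col))
    }
    out
  }
  mat <- vapply(seq_along(header), function(j) {
    parse_num(vapply(cells, `[[`, "", j), seq_along(cells), header[j])
  }, numeric(length(cells)))
  mat <- matrix(mat, nrow = length(cells),
                dimnames = list(NULL, header))
  times <- mat[, 1]
  if (anyNA(times)) stop("missing values in the time column")
  if (any(diff(times) <= 0)) stop("time column must be strictly increasing")
  keep <- times >= 0
  if (!all(keep)) {
    warning(sum(!keep), " pre-treatment row(s) with negative elapsed time dropped")
    mat <- mat[keep, , drop = FALSE]
    times <- times[keep]
  }
  wells <- header[-1]
  make <- if (kind == "death") death_trace else confluence_trace
  traces <- lapply(wells, function(w) {
    v <- fill_short_gaps(mat[, w], well = w)
    make(w, times, v)
  })
  names(traces) <- toupper(wells)
  traces
}

#' Read a cumulative cell-death export
#'
#' Convenience wrapper over [read_confluence_export()] with `kind = "death"`.
#' @inheritParams read_confluence_export
#' @return Named list of death traces.
#' @export
read_death_export <- function(path, dialect = "auto") {
  read_confluence_export(path, dialect, kind = "death")
}

# linear interpolation of interior NA runs of length <= 2; longer runs and
# NA endpoints are errors (no extrapolation)
fill_short_gaps <- function(v, well) {
  if (!anyNA(v)) return(v)
  r <- rle(is.na(v))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in which(r$values)) {
    if (r$lengths[k] > 2) {
      stop("gap of ", r$lengths[k], " consecutive missing values in well ",
           well, " (max 2 interpolated)")
    }
    if (starts[k] == 1L || ends[k] == length(v)) {
      stop("missing value at the boundary of well ", well,
           " cannot be interpolated")
    }
  }
  idx <- which(!is.na(v))
  stats::approx(idx, v[idx], xout = seq_along(v))$y
}

#' Read and validate a plate-map CSV
#'
#' Expects columns `well,cell_line,condition,formulation_id,production_batch,
#' replicate`. See [plate_map()] for the structural checks applied.
#'
#' @param path CSV file path.
#' @return A `stip_plate_map` data frame.
#' @export
read_plate_map <- function(path) {
  stopifnot(file.exists(path))
  df <- utils::read.csv(path, comment.char = "#",
                        colClasses = "character", strip.white = TRUE)
  plate_map(df)
}

#' Read a cytokine concentration table
#'
#' Expects columns `sample_id,cell_line,condition,analyte,concentration_pg_ml,
#' below_llod`. Analytes are restricted to IL-6, IL-10, IFN-gamma, TNF-alpha
#' (spelling `IFN-g`/`IFN-gamma` and `TNF-a`/`TNF-alpha` both accepted and
#' canonicalized).
#'
#' @param path CSV file path.
#' @return Data frame of cytokine samples.
#' @export
read_cytokine_table <- function(path) {
  stopifnot(file.exists(path))
  df <- utils::read.csv(path, comment.char = "#", strip.white = TRUE)
  needed <- c("sample_id", "cell_line", "condition", "analyte",
              "concentration_pg_ml", "below_llod")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    stop("cytokine table missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  df$analyte <- canonical_analyte(df$analyte)
  df$below_llod <- as.logical(df$below_llod)
  if (any(df$concentration_pg_ml < 0, na.rm = TRUE)) {
    stop("negative cytokine concentrations are invalid")
  }
  df
}

canonical_analyte <- function(x) {
  x <- toupper(trimws(x))
  map <- c("IL-6" = "IL-6", "IL6" = "IL-6",
           "IL-10" = "IL-10", "IL10" = "IL-10",
           "IFN-G" = "IFN-gamma", "IFN-GAMMA" = "IFN-gamma",
           "IFNG" = "IFN-gamma", "IFN-Γ" = "IFN-gamma",
           "TNF-A" = "TNF-alpha", "TNF-ALPHA" = "TNF-alpha",
           "TNFA" = "TNF-alpha", "TNF-Α" = "TNF-alpha")
  out <- map[x]
  if (anyNA(out)) {
    stop("unknown analyte(s): ", paste(unique(x[is.na(out)]), collapse = ", "))
  }
  unname(out)
}

#' Write the full result bundle to a directory
#'
#' Emits `metrics.csv` (one row per line x condition x batch), `calls.json`,
#' `qc.json`, `fsi.csv`, `compatibility.csv` (textual
#' stimulatory/inhibitory/neutral codes), `similarity.csv` and
#' `cluster.json`. All floats use `.` decimals regardless of input dialect.
#' Any component may be `NULL`, in which case a valid empty file is written.
#'
#' @param out_dir Output directory (created if absent).
#' @param metrics Data frame of kinetic metrics ([profiles_to_df()]).
#' @param calls List/data frame of STIP calls.
#' @param qc QC report list.
#' @param fsi FSI result data frame.
#' @param compat Compatibility matrix object from
#'   [build_compatibility_matrix()].
#' @param similarity Square similarity matrix.
#' @param clusters Cluster result from [ward_cluster()].
#' @return Invisibly, the vector of file paths written.
#' @export
write_results <- function(out_dir, metrics = NULL, calls = NULL, qc = NULL,
                          fsi = NULL, compat = NULL, similarity = NULL,
                          clusters = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  paths <- character(0)
  wcsv <- function(df, name, row_names = FALSE) {
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = row_names)
    paths <<- c(paths, p)
  }
  wjson <- function(x, name) {
    p <- file.path(out_dir, name)
    jsonlite::write_json(x, p, auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
    paths <<- c(paths, p)
  }
  empty_metrics <- data.frame(cell_line = character(), condition = character(),
                              production_batch = character())
  wcsv(if (is.null(metrics)) empty_metrics else metrics, "metrics.csv")
  wjson(if (is.null(calls)) structure(list(), names = character()) else calls,
        "calls.json")
  wjson(if (is.null(qc)) structure(list(), names = character()) else qc,
        "qc.json")
  wcsv(if (is.null(fsi)) data.frame(cell_line = character(), fsi = numeric())
       else fsi, "fsi.csv")
  if (is.null(compat)) {
    wcsv(data.frame(cell_line = character()), "compatibility.csv")
  } else {
    wcsv(data.frame(cell_line = rownames(compat$matrix), compat$matrix,
                    check.names = FALSE), "compatibility.csv")
  }
  if (is.null(similarity)) {
    wcsv(data.frame(), "similarity.csv")
  } else {
    wcsv(as.data.frame(similarity), "similarity.csv", row_names = TRUE)
  }
  if (is.null(clusters)) {
    wjson(structure(list(), names = character()), "cluster.json")
  } else {
    wjson(list(merge = apply(clusters$merge, 1, as.list),
               height = clusters$height,
               selected_k = clusters$selected_k,
               labels = as.list(clusters$labels),
               silhouette = as.list(clusters$silhouette)),
          "cluster.json")
  }
  invisible(paths)
}
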