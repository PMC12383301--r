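# shared fixtures built in code

hours <- 0:48

# replicate set of traces around a mean curve with deterministic jitter
make_reps <- function(mu, n = 3, sd = 0.5, seed = 1, times = hours,
                      prefix = "W") {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    confluence_trace(paste0(prefix, i), times,
                     pmin(pmax(mu + rnorm(length(times), 0, sd), 0), 100))
  })
}

logistic_curve <- function(K, r, t_mid, times = hours) {
  K / (1 + exp(-r * (times - t_mid)))
}

# write a wide export CSV and return its path
write_export <- function(times, wells, dialect = "point",
                         path = tempfile(fileext = ".csv"), comment = NULL) {
  sep <- if (dialect == "comma") ";" else ","
  fmt <- function(x) {
    s <- format(x, trim = TRUE, scientific = FALSE)
    if (dialect == "comma") gsub(".", ",", s, fixed = TRUE) else s
  }
  lines <- c(
    comment,
    paste(c("elapsed_h", names(wells)), collapse = sep),
    vapply(seq_along(times), function(i) {
      paste(c(fmt(times[i]),
              vapply(wells, function(v) fmt(v[i]), "")), collapse = sep)
    }, "")
  )
  writeLines(lines, path)
  path
}

# minimal valid plate-map data frame: one line, n treated + n control
basic_map <- function(n = 3, line = "BEWO", batch = "B1", form = "FV-001") {
  data.frame(
    well = paste0(rep(c("A", "B"), each = n), seq_len(n)),
    cell_line = line,
    condition = rep(c("treated", "control"), each = n),
    formulation_id = rep(c(form, ""), each = n),
    production_batch = batch,
    replicate = rep(seq_len(n), 2),
    stringsAsFactors = FALSE
  )
}

# profile stub for classifier-level tests
profile_stub <- function(delta_relative, duration = 0, n_sig = 0,
                         cell_line = "X", slope = 1, auc = 1000, cv = 5) {
  structure(list(
    cell_line = cell_line, formulation_id = "F", production_batch = "B",
    final_confluence_mean = 50, final_confluence_sd = 1,
    control_final_mean = 40, delta_points = delta_relative * 40,
    delta_relative = delta_relative, onset_hours = 10,
    logphase_slope = slope, auc = auc, divergence_duration = duration,
    plateau_window = NULL, intra_cv = cv, n_sig_points = n_sig
  ), class = "kinetic_profile")
}

# brute-force Ward agglomeration oracle: at each step merge the pair of
# clusters minimizing the increase in total within-cluster SSE, computed
# directly from the coordinates; height = sqrt(2 * delta SSE)
ward_oracle <- function(X) {
  n <- nrow(X)
  sse <- function(idx) {
    if (length(idx) == 1) return(0)
    Y <- X[idx, , drop = FALSE]
    sum(sweep(Y, 2, colMeans(Y))^2)
  }
  nodes <- lapply(seq_len(n), function(i) list(idx = i, id = -i))
  merges <- matrix(0L, n - 1, 2)
  heights <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    best <- NULL; bestd <- Inf
    for (a in seq_along(nodes)) {
      for (b in seq_along(nodes)) {
        if (a < b) {
          d <- sse(c(nodes[[a]]$idx, nodes[[b]]$idx)) -
            sse(nodes[[a]]$idx) - sse(nodes[[b]]$idx)
          if (d < bestd) { bestd <- d; best <- c(a, b) }
        }
      }
    }
    merges[step, ] <- c(nodes[[best[1]]]$id, nodes[[best[2]]]$id)
    heights[step] <- sqrt(2 * bestd)
    newnode <- list(idx = c(nodes[[best[1]]]$idx, nodes[[best[2]]]$idx),
                    id = step)
    nodes <- c(nodes[-best], list(newnode))
  }
  list(merge = merges, height = heights)
}

# compare two hclust-style merge matrices as unordered merge sets
merge_sets <- function(m) apply(m, 1, function(r) paste(sort(r), collapse = ","))

# partition equality up to label renaming
same_partition <- function(a, b) {
  length(unique(paste(a, b))) == length(unique(a)) &&
    length(unique(a)) == length(unique(b))
}
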