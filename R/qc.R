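#' Intra-assay QC verdicts
#'
#' Replicate CV at final confluence must be at most 8% for active
#' (stimulatory/inhibitory) lines and at most 5% for neutral lines;
#' indeterminate calls are held to the active bound.
#'
#' @param profiles List of `kinetic_profile`s.
#' @param categories Character vector of category calls, parallel to
#'   `profiles`.
#' @param cfg `qc` config section.
#' @return Data frame: `cell_line`, `formulation_id`, `production_batch`,
#'   `category`, `intra_cv`, `bound`, `pass`.
#' @export
intra_assay_qc <- function(profiles, categories, cfg = stip_config()$qc) {
  stopifnot(length(profiles) == length(categories))
  rows <- mapply(function(p, cat) {
    bound <- if (identical(cat, "neutral")) cfg$intra_cv_neutral else
      cfg$intra_cv_active
    data.frame(cell_line = p$cell_line, formulation_id = p$formulation_id,
               production_batch = p$production_batch, category = cat,
               intra_cv = p$intra_cv, bound = bound,
               pass = p$intra_cv <= bound, stringsAsFactors = FALSE)
  }, profiles, categories, SIMPLIFY = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# CV in percent across a vector of batch-level values
cv_pct <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2) return(NA_real_)
  if (mean(x) == 0) return(NA_real_)
  100 * stats::sd(x) / abs(mean(x))
}

#' Interbatch reproducibility QC for one line x formulation
#'
#' Across production batches, checks: CV of final confluence below
#' `interbatch_final_cv` (10%), CV of divergence onset below
#' `interbatch_onset_cv` (8%, skipped when no batch has an onset), maximum
#' pairwise final-confluence difference below `interbatch_max_delta`
#' (10 points), and category concordance (all batches assigned the same
#' category; indeterminate anywhere breaks concordance). Overall pass is the
#' conjunction. With a single batch the report is flagged `insufficient`.
#'
#' @param profiles List of `kinetic_profile`s for the same line x
#'   formulation, one per batch.
#' @param categories Category call per batch.
#' @param cfg `qc` config section.
#' @return List of class `qc_report` with the component verdicts and
#'   underlying numbers.
#' @export
interbatch_qc <- function(profiles, categories, cfg = stip_config()$qc) {
  stopifnot(length(profiles) == length(categories))
  n <- length(profiles)
  finals <- vapply(profiles, function(p) p$final_confluence_mean, 0)
  onsets <- vapply(profiles, function(p)
    if (is.null(p$onset_hours)) NA_real_ else p$onset_hours, 0)
  concordant <- length(unique(categories)) == 1 &&
    !any(categories == "indeterminate")
  if (n < 2) {
    return(structure(list(
      cell_line = profiles[[1]]$cell_line,
      formulation_id = profiles[[1]]$formulation_id,
      n_batches = n, insufficient = TRUE,
      final_cv = NA_real_, onset_cv = NA_real_, max_delta = NA_real_,
      category_concordant = concordant, categories = categories,
      pass = NA), class = "qc_report"))
  }
  final_cv <- cv_pct(finals)
  onset_cv <- cv_pct(onsets)
  max_delta <- max(stats::dist(finals))
  checks <- c(
    final_cv = is.finite(final_cv) && final_cv <= cfg$interbatch_final_cv,
    onset_cv = is.na(onset_cv) || onset_cv <= cfg$interbatch_onset_cv,
    max_delta = max_delta <= cfg$interbatch_max_delta,
    concordant = concordant
  )
  structure(list(
    cell_line = profiles[[1]]$cell_line,
    formulation_id = profiles[[1]]$formulation_id,
    n_batches = n, insufficient = FALSE,
    final_cv = final_cv, onset_cv = onset_cv, max_delta = max_delta,
    category_concordant = concordant, categories = categories,
    checks = as.list(checks), pass = all(checks)
  ), class = "qc_report")
}

#' Line x formulation compatibility matrix
#'
#' Arranges consensus category calls into a matrix (rows: cell lines,
#' columns: formulations). A row is inversion-free when it does not contain
#' both stimulatory and inhibitory calls; the matrix is inversion-free when
#' every row is.
#'
#' @param calls Data frame with columns `cell_line`, `formulation_id`,
#'   `category`. Duplicate (line, formulation) pairs with conflicting
#'   categories are a data-integrity error.
#' @return List of class `compatibility_matrix`: `matrix` (character, `NA`
#'   for absent combinations), `inversion_free` (overall logical),
#'   `row_inversion_free` (named logical per line).
#' @export
build_compatibility_matrix <- function(calls) {
  if (nrow(calls) == 0) {
    return(structure(list(matrix = matrix(character(0), 0, 0),
                          inversion_free = TRUE,
                          row_inversion_free = logical(0)),
                     class = "compatibility_matrix"))
  }
  key <- paste(calls$cell_line, calls$formulation_id, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- calls[key %in% key[duplicated(key)], ]
    conflicting <- any(tapply(dup$category,
                              paste(dup$cell_line, dup$formulation_id),
                              function(x) length(unique(x)) > 1))
    if (conflicting) {
      stop("conflicting duplicate calls for the same line x formulation")
    }
    calls <- calls[!duplicated(key), ]
  }
  lines <- unique(calls$cell_line)
  forms <- unique(calls$formulation_id)
  m <- matrix(NA_character_, length(lines), length(forms),
              dimnames = list(lines, forms))
  m[cbind(match(calls$cell_line, lines),
          match(calls$formulation_id, forms))] <- calls$category
  row_free <- apply(m, 1, function(r) {
    !("stimulatory" %in% r && "inhibitory" %in% r)
  })
  structure(list(matrix = m, inversion_free = all(row_free),
                 row_inversion_free = row_free),
            class = "compatibility_matrix")
}

#' Render a compatibility matrix with the conventional symbols
#'
#' stimulatory -> a check mark, inhibitory -> a cross, neutral -> an em
#' dash; other calls keep their name.
#'
#' @param compat A `compatibility_matrix`.
#' @return Character matrix of symbols.
#' @export
compat_symbols <- function(compat) {
  sym <- c(stimulatory = "✓", inhibitory = "✕", neutral = "—")
  m <- compat$matrix
  out <- matrix(ifelse(m %in% names(sym), sym[m], m),
                nrow(m), ncol(m), dimnames = dimnames(m))
  out
}
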