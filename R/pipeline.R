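#' Run the full hydrolysate analysis pipeline
#'
#' Composes the stages read -> validate -> mass/reconcile -> motif scan ->
#' novelty -> (optional assays) -> report. Any stage failure aborts with
#' the stage name prefixed to the error message.
#'
#' @param table A peptide table: a path (read with [read_peptide_table()])
#'   or a data frame with `accession`, `sequence`, `reported_mw` columns.
#' @param reference Bioactive reference: a path, a data frame, or `NULL`
#'   for the packaged default.
#' @param mods Modification set: a path, a data frame, or `NULL` for the
#'   packaged default.
#' @param tol,max_mods Reconciliation settings, see [reconcile_masses()].
#' @param dialect Dialect for reading `table` from a path.
#' @param dose_response Optional dose-response data for [fit_ic50()].
#' @param titration Optional named list `(B, N_B, alpha_inv, M_P, h_tot)`
#'   for [degree_of_hydrolysis()].
#' @param assays Optional named list of extra assay results to carry into
#'   the summary (e.g. `inhibition_pct`, `yield_pct`).
#' @return An object of class `hydrolysate_report`: a list with
#'   `peptides` (per-peptide tibble: accession, sequence, length, computed
#'   mass, reported mass, residual, inferred modification, status, motif
#'   hit counts, novelty), `hits` (the raw [scan_motifs()] table),
#'   `summary` (per-motif counts, novelty split, reconciliation status
#'   counts, assay results) and `provenance` (inputs, parameters, package
#'   version, reference checksum).
#' @examples
#' rep <- run_pipeline(hydrolysate_peptides())
#' rep$summary$per_motif
#' @export
run_pipeline <- function(table, reference = NULL, mods = NULL, tol = 0.011,
                         max_mods = 1, dialect = "tsv",
                         dose_response = NULL, titration = NULL,
                         assays = list()) {
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      abort(sprintf("[%s] %s", name, conditionMessage(e)))
    })
  }

  tab <- stage("read", {
    if (is.character(table)) read_peptide_table(table, dialect = dialect)
    else as_tibble(table)
  })
  ref <- stage("read", {
    if (is.null(reference)) read_reference()
    else if (is.character(reference)) read_reference(reference)
    else as_tibble(reference)
  })
  modset <- stage("read", {
    if (is.null(mods)) modification_set()
    else if (is.character(mods)) modification_set(mods)
    else as_tibble(mods)
  })

  tab <- stage("validate", {
    tab$sequence <- parse_sequence(tab$sequence)
    tab
  })

  rec <- stage("reconcile", {
    if (all(is.na(tab$reported_mw))) {
      peptide_masses(tab) |>
        select(-"computed_avg", -"mono_2dp") |>
        mutate(residual = NA_real_, modification = NA_character_,
               mod_delta = NA_real_, status = NA_character_)
    } else {
      reconcile_masses(tab, mods = modset, tol = tol, max_mods = max_mods)
    }
  })

  hits <- stage("scan", scan_motifs(tab, ref))
  flagged <- stage("novelty", novelty_check(tab, ref))

  hit_counts <- hits |>
    count(.data$peptide_index, name = "motif_hits")
  rows <- rec |>
    mutate(peptide_index = row_number(),
           length = nchar(.data$sequence),
           novelty = flagged$novelty) |>
    left_join(hit_counts, by = "peptide_index") |>
    mutate(motif_hits = dplyr::coalesce(.data$motif_hits, 0L)) |>
    select("peptide_index", "accession", "sequence", "length",
           "computed_mono", "reported_mw", "residual", "modification",
           "mod_delta", "status", "motif_hits", "novelty")

  scan_sum <- stage("summarize",
                    summarize_scan(hits, flagged, motifs = ref$sequence))

  assay_results <- assays
  if (!is.null(dose_response)) {
    fit <- stage("ic50", fit_ic50(dose_response))
    assay_results$ic50 <- fit$ic50
    assay_results$ic50_method <- fit$method
  }
  if (!is.null(titration)) {
    assay_results$dh_pct <- stage("dh", do.call(degree_of_hydrolysis, titration))
  }

  summary <- list(
    n_peptides = nrow(rows),
    status_counts = as.list(table(rows$status)),
    per_motif = scan_sum$per_motif,
    novel_count = scan_sum$novel_count,
    known_count = scan_sum$known_count,
    assays = assay_results
  )
  provenance <- list(
    table_source = if (is.character(table)) table else "in-memory",
    reference_checksum = unname(tools::md5sum(
      if (is.character(reference)) reference
      else system.file("extdata", "bioactive_reference.tsv",
                       package = "hydropep"))),
    tol = tol, max_mods = max_mods,
    package_version = as.character(utils::packageVersion("hydropep"))
  )
  structure(list(peptides = rows, hits = hits, summary = summary,
                 provenance = provenance),
            class = "hydrolysate_report")
}

#' @export
print.hydrolysate_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Hydrolysate report: %d peptides (%d novel, %d known)\n",
              s$n_peptides, s$novel_count, s$known_count))
  st <- unlist(s$status_counts)
  if (length(st)) {
    cat("  mass reconciliation:",
        paste(sprintf("%s=%d", names(st), st), collapse = ", "), "\n")
  }
  hit <- s$per_motif[s$per_motif$peptide_count > 0, ]
  if (nrow(hit)) {
    cat("  encrypted fragments:",
        paste(sprintf("%s in %d", hit$motif, hit$peptide_count),
              collapse = ", "), "\n")
  }
  if (length(s$assays)) {
    cat("  assays:", paste(sprintf("%s=%s", names(s$assays),
                                   vapply(s$assays, format, "")),
                           collapse = ", "), "\n")
  }
  invisible(x)
}
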