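#' Read a peptide identification table
#'
#' Reads a delimited peptide table (the shape exported by proteomics search
#' engines: one row per identified peptide, with accession, sequence and a
#' reported precursor molecular weight). Column names can be remapped via
#' `column_map` so third-party exports can be ingested without editing.
#'
#' @param path Path to the file.
#' @param dialect `"tsv"` or `"csv"`. No auto-detection: the dialect is
#'   explicit for reproducibility.
#' @param column_map Named character vector mapping the canonical names
#'   (`accession`, `sequence`, `reported_mw`) to the column names present in
#'   the file, e.g. `c(sequence = "Peptide")`.
#' @param strict If `TRUE` (default) any row whose sequence fails validation
#'   aborts the read with its line number; if `FALSE`, offending rows are
#'   dropped with a warning listing their line numbers.
#' @return A tibble with columns `accession`, `sequence`, `reported_mw`
#'   (the latter `NA` if absent from the file), in input row order.
#' @examples
#' tab <- read_peptide_table(
#'   system.file("extdata", "helix_hydrolysate_peptides.tsv",
#'               package = "hydropep"))
#' nrow(tab)
#' @export
read_peptide_table <- function(path, dialect = c("tsv", "csv"),
                               column_map = NULL, strict = TRUE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  reader <- if (dialect == "tsv") readr::read_tsv else readr::read_csv
  raw <- reader(path, show_col_types = FALSE, col_types = readr::cols())
  if (!is.null(column_map)) {
    for (canon in names(column_map)) {
      if (!column_map[[canon]] %in% names(raw)) {
        abort(sprintf("mapped column '%s' not found in file", column_map[[canon]]))
      }
      names(raw)[names(raw) == column_map[[canon]]] <- canon
    }
  }
  for (col in c("accession", "sequence")) {
    if (!col %in% names(raw)) {
      abort(sprintf("required column '%s' missing from %s", col, path))
    }
  }
  if (nrow(raw) == 0) abort(sprintf("no data rows in %s", path))
  if (!"reported_mw" %in% names(raw)) raw$reported_mw <- NA_real_
  out <- as_tibble(raw)[, c("accession", "sequence", "reported_mw")]
  out$reported_mw <- as.numeric(out$reported_mw)

  valid <- vapply(out$sequence, function(s) {
    !is.null(tryCatch(parse_sequence(s), error = function(e) NULL))
  }, logical(1))
  if (!all(valid)) {
    lines <- which(!valid) + 1L # +1 for the header line
    if (strict) {
      abort(sprintf("invalid sequence at file line %d: '%s'",
                    lines[1], out$sequence[which(!valid)[1]]))
    }
    warning(sprintf("skipped %d invalid row(s) at file line(s) %s",
                    sum(!valid), paste(lines, collapse = ", ")),
            call. = FALSE)
    out <- out[valid, , drop = FALSE]
  }
  out$sequence <- parse_sequence(out$sequence)
  out
}

#' Packaged hydrolysate peptide table
#'
#' The 114-row peptide identification table of an Alcalase hydrolysate of
#' the edible snail *Helix aspersa* (accession, sequence, reported
#' theoretical molecular weight in Da), transcribed verbatim from the
#' published table. The source article's prose says 113 unique sequences
#' were identified while its printed table contains 114 distinct
#' sequences; the transcription keeps all 114 printed rows rather than
#' silently dropping one. For the heaviest peptide the published abstract
#' and table disagree on two residues (...GSSGRRGD vs ...GSSGPRGD); only
#' the table's form reproduces the printed 2343.14 Da, so that form is
#' kept.
#'
#' @return A tibble with columns `accession`, `sequence`, `reported_mw`.
#' @examples
#' nrow(hydrolysate_peptides())
#' @export
hydrolysate_peptides <- function() {
  read_peptide_table(
    system.file("extdata", "helix_hydrolysate_peptides.tsv",
                package = "hydropep"),
    dialect = "tsv"
  )
}

#' Read a FASTA file of parent proteins
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` (header up to the first whitespace)
#'   and `sequence` (uppercased, unwrapped).
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1 demo", "GGFGG", "FGG"), f)
#' read_fasta(f)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  first <- readLines(path, n = 1L)
  if (length(first) == 0 || !startsWith(first, ">")) {
    abort(sprintf("not a FASTA file (no leading '>'): %s", path))
  }
  aa <- Biostrings::readAAStringSet(path)
  ids <- stringr::str_extract(names(aa), "^\\S+")
  seqs <- toupper(as.character(aa))
  empty <- nchar(seqs) == 0
  if (any(empty)) {
    abort(sprintf("FASTA record '%s' has an empty sequence", ids[which(empty)[1]]))
  }
  tibble(id = ids, sequence = unname(seqs))
}

#' Read a bioactive-peptide reference
#'
#' Reads a local reference of known bioactive peptides (a stand-in for
#' querying an online database such as BIOPEP-UWM) used both as the motif
#' set for encrypted-fragment scanning and as the novelty reference.
#' Duplicate sequences are collapsed, merging their sources.
#'
#' The packaged default holds the eight antihypertensive dipeptides
#' reported from *Helix aspersa* (YG, YA, VY, FG, GF, DF, SF, VW) and two
#' antioxidant nonapeptides from a marine snail hydrolysate (HTYHEVTKH,
#' WPVLAYHFT).
#'
#' @param path Path to a TSV with columns `sequence`, `activity_class` and
#'   optionally `source`. `NULL` (default) loads the packaged reference.
#' @return A tibble with columns `sequence`, `activity_class`, `source`.
#' @examples
#' read_reference()
#' @export
read_reference <- function(path = NULL) {
  path <- path %||%
    system.file("extdata", "bioactive_reference.tsv", package = "hydropep")
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  raw <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols())
  if (nrow(raw) == 0) {
    return(tibble(sequence = character(), activity_class = character(),
                  source = character()))
  }
  for (col in c("sequence", "activity_class")) {
    if (!col %in% names(raw)) {
      abort(sprintf("required column '%s' missing from %s", col, path))
    }
  }
  if (!"source" %in% names(raw)) raw$source <- NA_character_
  raw$sequence <- parse_sequence(raw$sequence)
  raw |>
    group_by(.data$sequence) |>
    summarise(
      activity_class = paste(unique(.data$activity_class), collapse = "; "),
      source = paste(unique(stats::na.omit(.data$source)), collapse = "; "),
      .groups = "drop"
    ) |>
    arrange(match(.data$sequence, raw$sequence))
}

#' Write a pipeline report
#'
#' Serialises a [run_pipeline()] report deterministically: TSV keeps input
#' row order with masses printed at two decimals; JSON keeps full float
#' precision and carries the summary and provenance blocks alongside the
#' rows under a versioned schema tag. Writing the same report twice yields
#' byte-identical files.
#'
#' @param report A `hydrolysate_report`, as returned by [run_pipeline()].
#' @param path Output file path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  stopifnot(inherits(report, "hydrolysate_report"))
  if (format == "tsv") {
    rows <- report$peptides |>
      mutate(across(c("computed_mono", "residual"),
                    ~ sprintf("%.2f", round_mass(.x))))
    readr::write_tsv(rows, path)
  } else {
    payload <- list(
      schema = "hydropep-report/1",
      peptides = report$peptides,
      summary = report$summary,
      provenance = report$provenance
    )
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
  }
  invisible(path)
}
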