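# Fragmentomic scanning: short bioactive fragments "encrypted" inside a
# longer peptide may confer activity on the parent, so every occurrence of
# every reference sequence inside every hydrolysate peptide is located.

# all start positions of `motif` in `sequence`, overlaps included
.find_all <- function(sequence, motif) {
  hits <- integer(0)
  from <- 1L
  repeat {
    pos <- regexpr(motif, substr(sequence, from, nchar(sequence)),
                   fixed = TRUE)
    if (pos == -1L) break
    start <- from + as.integer(pos) - 1L
    hits <- c(hits, start)
    from <- start + 1L
  }
  hits
}

#' Scan peptides for encrypted bioactive fragments
#'
#' Locates every occurrence (overlaps included) of every reference sequence
#' as a contiguous substring of every peptide, scanning left to right.
#'
#' @param data Data frame with a `sequence` column (one row per peptide).
#' @param reference Reference tibble, as from [read_reference()]; only its
#'   `sequence` column is used as the motif set.
#' @return A tibble of hits with columns `peptide_index` (row number in
#'   `data`), `motif`, `start` and `end` (1-based, inclusive), sorted by
#'   (`peptide_index`, `start`, `motif`).
#' @examples
#' scan_motifs(tibble::tibble(sequence = "VDDDKDFIPF"), read_reference())
#' @export
scan_motifs <- function(data, reference = read_reference()) {
  if (!"sequence" %in% names(data)) abort("`data` must have a `sequence` column")
  motifs <- unique(reference$sequence)
  if (any(is.na(motifs) | motifs == "")) abort("reference contains empty motifs")
  seqs <- parse_sequence(data$sequence)
  if (length(motifs) == 0) {
    return(tibble(peptide_index = integer(), motif = character(),
                  start = integer(), end = integer()))
  }
  hits <- purrr::imap(seqs, function(s, i) {
    per_motif <- purrr::map(motifs, function(m) {
      starts <- .find_all(s, m)
      tibble(peptide_index = i, motif = m, start = starts,
             end = starts + nchar(m) - 1L)
    })
    list_rbind(per_motif)
  }) |> list_rbind()
  arrange(hits, .data$peptide_index, .data$start, .data$motif)
}

#' Flag peptide novelty against a reference
#'
#' A peptide is `known` only if its full sequence exactly equals a
#' reference entry (case-insensitive); containing a reference fragment as a
#' substring does not make it known — that is what [scan_motifs()] reports.
#'
#' @inheritParams scan_motifs
#' @return `data` as a tibble with a `novelty` column (`"novel"` or
#'   `"known"`).
#' @examples
#' novelty_check(tibble::tibble(sequence = c("HTYHEVTKH", "GGGLVGGI")))
#' @export
novelty_check <- function(data, reference = read_reference()) {
  if (!"sequence" %in% names(data)) abort("`data` must have a `sequence` column")
  seqs <- parse_sequence(data$sequence)
  known <- seqs %in% toupper(reference$sequence)
  as_tibble(data) |>
    mutate(novelty = ifelse(known, "known", "novel"))
}

#' Summarise a motif scan
#'
#' Cohort-level counts from a hit table and novelty flags: for each motif,
#' the number of distinct peptides containing it at least once and the
#' total number of occurrences (overlaps counted), plus the novel/known
#' split.
#'
#' @param hits Hit tibble from [scan_motifs()].
#' @param flags Tibble with a `novelty` column from [novelty_check()], one
#'   row per scanned peptide.
#' @param motifs Optional character vector of motifs to tabulate even when
#'   they have zero hits (defaults to the motifs present in `hits`).
#' @return A list with elements `per_motif` (tibble `motif`,
#'   `peptide_count`, `occurrence_count`, lexicographic motif order),
#'   `novel_count` and `known_count`.
#' @export
summarize_scan <- function(hits, flags, motifs = NULL) {
  if (!"novelty" %in% names(flags)) abort("`flags` must have a `novelty` column")
  if (nrow(hits) > 0 && max(hits$peptide_index) > nrow(flags)) {
    abort("`hits` refers to peptide indices beyond `flags`: tables mismatched")
  }
  motifs <- sort(unique(c(motifs, hits$motif)))
  per_motif <- hits |>
    group_by(.data$motif) |>
    summarise(peptide_count = dplyr::n_distinct(.data$peptide_index),
              occurrence_count = n(), .groups = "drop")
  per_motif <- tibble(motif = motifs) |>
    left_join(per_motif, by = "motif") |>
    mutate(
      peptide_count = dplyr::coalesce(.data$peptide_count, 0L),
      occurrence_count = dplyr::coalesce(.data$occurrence_count, 0L)
    ) |>
    arrange(.data$motif)
  list(
    per_motif = per_motif,
    novel_count = sum(flags$novelty == "novel"),
    known_count = sum(flags$novelty == "known")
  )
}
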