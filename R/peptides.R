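#' Validate and normalise peptide sequences
#'
#' Uppercases sequences and verifies that every character is one of the 20
#' canonical one-letter residue codes. Ambiguity and non-standard codes
#' (B, J, O, U, X, Z) are rejected rather than guessed at.
#'
#' @param raw Character vector of peptide sequences.
#' @param min_length Minimum accepted length (default 2, the shortest
#'   bioactive dipeptide motif).
#' @return The validated, uppercase character vector.
#' @examples
#' parse_sequence("gggi")
#' parse_sequence("GGGLVGGI")
#' @export
parse_sequence <- function(raw, min_length = 2) {
  if (length(raw) == 0) abort("`raw` must contain at least one sequence")
  seqs <- stringr::str_trim(raw)
  if (any(is.na(seqs)) || any(seqs == "")) {
    abort("`raw` contains empty or missing sequences")
  }
  seqs <- toupper(seqs)
  short <- nchar(seqs) < min_length
  if (any(short)) {
    abort(sprintf("sequence '%s' is shorter than min_length = %d",
                  seqs[which(short)[1]], min_length))
  }
  bad <- stringr::str_locate(seqs, "[^ACDEFGHIKLMNPQRSTVWY]")[, "start"]
  if (any(!is.na(bad))) {
    i <- which(!is.na(bad))[1]
    abort(sprintf("illegal residue '%s' at position %d in '%s'",
                  substr(seqs[i], bad[i], bad[i]), bad[i], seqs[i]))
  }
  seqs
}

# residue-sum over a validated sequence against a named mass vector
.residue_sum <- function(seqs, masses) {
  vapply(strsplit(seqs, "", fixed = TRUE),
         function(ch) sum(masses[ch]), numeric(1))
}

#' Theoretical peptide masses
#'
#' `monoisotopic_mass()` returns the neutral monoisotopic mass of each
#' peptide (sum of monoisotopic residue masses plus one water);
#' `average_mass()` the average molecular weight. Both are vectorised.
#' `round_mass()` rounds half-up to a fixed number of decimals, the
#' convention used when comparing against published two-decimal tables
#' (base R `round()` rounds half-to-even, which can differ on exact .xx5).
#'
#' @param sequence Character vector of peptide sequences (validated via
#'   [parse_sequence()]).
#' @param table Mass table, as returned by [mass_table()].
#' @return Numeric vector of masses in Da (full precision).
#' @examples
#' monoisotopic_mass("GGGLVGGI") # 628.3544
#' round_mass(monoisotopic_mass("GGGLVGGI")) # 628.35
#' average_mass("G")
#' @export
monoisotopic_mass <- function(sequence, table = mass_table()) {
  seqs <- parse_sequence(sequence, min_length = 1)
  .residue_sum(seqs, table$residue_mono) + table$water_mono
}

#' @rdname monoisotopic_mass
#' @export
average_mass <- function(sequence, table = mass_table()) {
  seqs <- parse_sequence(sequence, min_length = 1)
  .residue_sum(seqs, table$residue_avg) + table$water_avg
}

#' @rdname monoisotopic_mass
#' @param x Numeric vector to round.
#' @param digits Number of decimal places (default 2).
#' @export
round_mass <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Add theoretical masses to a peptide table
#'
#' Data-frame-first convenience: appends `computed_mono` and `computed_avg`
#' columns (full precision) and `mono_2dp` (rounded half-up for display) to
#' a table with a `sequence` column.
#'
#' @param data A data frame with a `sequence` column.
#' @param table Mass table, as returned by [mass_table()].
#' @return `data` as a tibble with mass columns appended.
#' @examples
#' peptide_masses(tibble::tibble(sequence = c("GGGLVGGI", "APGAGVY")))
#' @export
peptide_masses <- function(data, table = mass_table()) {
  if (!"sequence" %in% names(data)) abort("`data` must have a `sequence` column")
  as_tibble(data) |>
    mutate(
      computed_mono = monoisotopic_mass(.data$sequence, table),
      computed_avg = average_mass(.data$sequence, table),
      mono_2dp = round_mass(.data$computed_mono)
    )
}
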