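# Mass reconciliation: explain the gap between a reported precursor mass and
# the plain monoisotopic mass by a small set of post-translational
# modification deltas. Published peptide tables often fold one modification
# into the printed "theoretical" mass without listing it per row.

.mod_applicable <- function(applicability, sequence) {
  if (is.na(applicability) || applicability == "" ||
      identical(applicability, "Nterm")) {
    return(TRUE) # N-terminal mods apply to every peptide
  }
  residues <- strsplit(applicability, "", fixed = TRUE)[[1]]
  any(residues %in% strsplit(sequence, "", fixed = TRUE)[[1]])
}

# all subsets of mod row-indices up to size k (k is small, default 1)
.mod_subsets <- function(n, k) {
  out <- list()
  for (size in seq_len(min(k, n))) {
    cmb <- utils::combn(n, size, simplify = FALSE)
    out <- c(out, cmb)
  }
  out
}

.reconcile_one <- function(sequence, reported, computed, mods, tol, max_mods) {
  residual <- reported - computed
  if (abs(residual) <= tol) {
    return(list(status = "match", modification = NA_character_,
                mod_delta = 0, residual = residual))
  }
  if (max_mods >= 1 && nrow(mods) > 0) {
    applicable <- vapply(mods$applicability, .mod_applicable,
                         logical(1), sequence = sequence)
    usable <- mods[applicable, , drop = FALSE]
    if (nrow(usable) > 0) {
      subsets <- .mod_subsets(nrow(usable), max_mods)
      cand <- purrr::map(subsets, function(idx) {
        delta <- sum(usable$delta_da[idx])
        name <- paste(sort(usable$name[idx]), collapse = "+")
        list(size = length(idx), name = name, delta = delta,
             err = abs(residual - delta))
      })
      cand <- purrr::keep(cand, ~ .x$err <= tol)
      if (length(cand) > 0) {
        ord <- order(
          vapply(cand, `[[`, numeric(1), "size"),
          vapply(cand, `[[`, numeric(1), "err"),
          vapply(cand, `[[`, character(1), "name")
        )
        best <- cand[[ord[1]]]
        return(list(status = "modified_match", modification = best$name,
                    mod_delta = best$delta, residual = residual))
      }
    }
  }
  list(status = "unexplained", modification = NA_character_,
       mod_delta = NA_real_, residual = residual)
}

#' Reconcile reported precursor masses with theoretical masses
#'
#' For each peptide, computes the plain monoisotopic mass, takes the
#' residual against the reported mass and classifies the row:
#' * `match` — residual within `tol` of zero;
#' * `modified_match` — a subset of at most `max_mods` modifications from
#'   `mods`, each applicable to the sequence, sums to the residual within
#'   `tol` (smallest subset wins; ties broken by smallest remaining error,
#'   then alphabetically by modification name);
#' * `unexplained` — neither.
#'
#' @param data Data frame with columns `sequence` and `reported_mw` (Da).
#' @param mods Modification table, as from [modification_set()].
#' @param tol Matching tolerance in Da. The default 0.011 accepts any value
#'   that prints identically at two decimals under either rounding
#'   convention.
#' @param max_mods Maximum number of simultaneous modifications to consider
#'   (default 1: parsimonious, and multi-modification deltas are rarely
#'   identifiable from a single printed mass).
#' @param table Mass table, as from [mass_table()].
#' @return `data` as a tibble with appended columns `computed_mono`,
#'   `residual` (reported minus computed), `modification` (name, or `NA`),
#'   `mod_delta` and `status`.
#' @examples
#' reconcile_masses(tibble::tibble(
#'   sequence = c("GGGLVGGI", "WSLNGAETMQ"),
#'   reported_mw = c(628.35, 1136.48)
#' ))
#' @export
reconcile_masses <- function(data, mods = modification_set(), tol = 0.011,
                             max_mods = 1, table = mass_table()) {
  if (!all(c("sequence", "reported_mw") %in% names(data))) {
    abort("`data` must have `sequence` and `reported_mw` columns")
  }
  if (any(is.na(data$reported_mw))) {
    abort("`reported_mw` contains missing values; reconciliation needs a reported mass")
  }
  if (tol <= 0) abort("`tol` must be positive")
  if (max_mods < 0) abort("`max_mods` must be >= 0")
  seqs <- parse_sequence(data$sequence)
  computed <- monoisotopic_mass(seqs, table)
  res <- purrr::pmap(
    list(seqs, data$reported_mw, computed),
    .reconcile_one, mods = mods, tol = tol, max_mods = max_mods
  )
  as_tibble(data) |>
    mutate(
      computed_mono = computed,
      residual = map_dbl(res, "residual"),
      modification = map_chr(res, "modification"),
      mod_delta = map_dbl(res, "mod_delta"),
      status = map_chr(res, "status")
    )
}
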