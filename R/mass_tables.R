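# Residue mass constants. Monoisotopic residue (water-loss) masses to 5 dp,
# standard IUPAC/Unimod values; average masses from the 2021 IUPAC atomic
# weights. Neutral peptide mass = sum of residue masses + one water.

.RESIDUE_MONO <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

.RESIDUE_AVG <- c(
  G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167, V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132
)

.WATER_MONO <- 18.01056
.WATER_AVG <- 18.01528
.PROTON <- 1.00728

#' Amino-acid mass table
#'
#' Returns the residue mass table used throughout the package: monoisotopic
#' and average residue (water-loss) masses for the 20 canonical amino acids,
#' plus the water and proton constants needed to turn residue sums into
#' neutral peptide masses (and, if ever needed, m/z values).
#'
#' @return A list with elements `residue_mono` and `residue_avg` (named
#'   numeric vectors over the 20 one-letter codes), `water_mono`,
#'   `water_avg` and `proton` (Da).
#' @examples
#' mt <- mass_table()
#' mt$residue_mono[["G"]]
#' @export
mass_table <- function() {
  list(
    residue_mono = .RESIDUE_MONO,
    residue_avg = .RESIDUE_AVG,
    water_mono = .WATER_MONO,
    water_avg = .WATER_AVG,
    proton = .PROTON
  )
}

#' Post-translational modification set
#'
#' Reads a table of single-residue mass shifts used to explain discrepancies
#' between reported precursor masses and plain monoisotopic masses. The
#' packaged default covers the deltas most often introduced by search
#' engines: deamidation (+0.98402, Asn/Gln), oxidation (+15.99491, Met/Trp),
#' N-terminal acetylation (+42.01057), carbamidomethylation (+57.02146, Cys)
#' and dehydration (-18.01056, Ser/Thr/Glu/Asp).
#'
#' The `applicability` column is either `Nterm` (applies to any peptide) or
#' a string of one-letter residue codes, at least one of which must occur in
#' the sequence for the modification to be considered.
#'
#' @param path Path to a tab-separated file with columns `name`, `delta_da`,
#'   `applicability`. Defaults to the packaged set.
#' @return A tibble with columns `name`, `delta_da`, `applicability`.
#' @examples
#' modification_set()
#' @export
modification_set <- function(path = NULL) {
  path <- path %||%
    system.file("extdata", "modifications.tsv", package = "hydropep")
  mods <- readr::read_tsv(path, show_col_types = FALSE,
                          col_types = readr::cols(
                            name = readr::col_character(),
                            delta_da = readr::col_double(),
                            applicability = readr::col_character()
                          ))
  if (!all(c("name", "delta_da", "applicability") %in% names(mods))) {
    abort("modification file must have columns name, delta_da, applicability")
  }
  if (any(!is.finite(mods$delta_da)) || any(abs(mods$delta_da) >= 200)) {
    abort("modification deltas must be finite and below 200 Da in magnitude")
  }
  as_tibble(mods)
}
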