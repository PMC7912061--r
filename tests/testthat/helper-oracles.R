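# Independent oracles used across the suite. Deliberately share no
# constants or code paths with the package: masses come from elemental
# composition x monoisotopic atomic masses, substring search is a naive
# double loop.

# residue elemental formulas (water already removed), C H N O S counts
.aa_formula <- list(
  G = c(2, 3, 1, 1, 0), A = c(3, 5, 1, 1, 0), S = c(3, 5, 1, 2, 0),
  P = c(5, 7, 1, 1, 0), V = c(5, 9, 1, 1, 0), T = c(4, 7, 1, 2, 0),
  C = c(3, 5, 1, 1, 1), L = c(6, 11, 1, 1, 0), I = c(6, 11, 1, 1, 0),
  N = c(4, 6, 2, 2, 0), D = c(4, 5, 1, 3, 0), Q = c(5, 8, 2, 2, 0),
  K = c(6, 12, 2, 1, 0), E = c(5, 7, 1, 3, 0), M = c(5, 9, 1, 1, 1),
  H = c(6, 7, 3, 1, 0), F = c(9, 9, 1, 1, 0), R = c(6, 12, 4, 1, 0),
  Y = c(9, 9, 1, 2, 0), W = c(11, 10, 2, 1, 0)
)
.atomic_mono <- c(C = 12, H = 1.0078250319, N = 14.0030740052,
                  O = 15.9949146221, S = 31.97207069)

# neutral monoisotopic peptide mass from elemental composition
oracle_mono_mass <- function(sequence) {
  vapply(sequence, function(s) {
    counts <- Reduce(`+`, .aa_formula[strsplit(s, "")[[1]]])
    counts <- counts + c(0, 2, 0, 1, 0) # one water
    sum(counts * .atomic_mono[c("C", "H", "N", "O", "S")])
  }, numeric(1), USE.NAMES = FALSE)
}

# all (start) positions of motif in sequence by explicit double loop
oracle_find_motif <- function(sequence, motif) {
  n <- nchar(sequence); m <- nchar(motif)
  hits <- integer(0)
  if (m < 1 || m > n) return(hits)
  for (i in seq_len(n - m + 1)) {
    if (substr(sequence, i, i + m - 1) == motif) hits <- c(hits, i)
  }
  hits
}

# random peptide sequences from the 20 canonical residues
random_peptides <- function(n, min_len = 2, max_len = 40) {
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  vapply(seq_len(n), function(i) {
    len <- sample(min_len:max_len, 1)
    paste(sample(aas, len, replace = TRUE), collapse = "")
  }, character(1))
}

# rows of the packaged table whose residual the single-modification search
# cannot explain under the packaged modification set (frozen allowlist)
unexplained_allowlist <- c(
  "NQHYPPGIGPLNAP", # +16.98 Da
  "YLKPVPIVPGLP",   # +28.00 Da
  "FVKMTGSGNDF",    # +31.99 Da
  "MPVSQIQADIIV"    # +1.96 Da
)

hydrolysate_fixture_md5 <- "848c1a2e1a83bdc7e70224c398c53207"
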