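ref_of <- function(...) {
  tibble::tibble(sequence = c(...), activity_class = "test", source = "test")
}

test_that("scan_motifs finds encrypted fragments at the right positions", {
  hits <- scan_motifs(tibble::tibble(sequence = "VDDDKDFIPF"), ref_of("DF"))
  expect_equal(hits$start, 6)
  expect_equal(hits$end, 7)
  hits2 <- scan_motifs(tibble::tibble(sequence = "AVDSNSNRASFS"), ref_of("SF"))
  expect_equal(hits2$start, 10)
  # overlapping occurrences all counted
  hits3 <- scan_motifs(tibble::tibble(sequence = "GGGG"), ref_of("GG"))
  expect_equal(hits3$start, c(1, 2, 3))
  # hit substring always equals the motif
  expect_true(all(substr("GGGG", hits3$start, hits3$end) == hits3$motif))
})

test_that("scanner agrees with a brute-force double-loop oracle on random cases", {
  set.seed(123)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (case in 1:500) {
    pep <- paste(sample(aas, sample(5:30, 1), replace = TRUE), collapse = "")
    motif <- paste(sample(aas[1:6], sample(1:3, 1), replace = TRUE),
                   collapse = "")
    got <- scan_motifs(tibble::tibble(sequence = pep),
                       ref_of(motif))$start
    expect_identical(got, oracle_find_motif(pep, motif))
  }
})

test_that("scan output ordering and reference permutation invariance hold", {
  tab <- tibble::tibble(sequence = c("DFSFDF", "SFSFSF"))
  ref <- ref_of("DF", "SF")
  hits <- scan_motifs(tab, ref)
  expect_identical(hits,
                   dplyr::arrange(hits, peptide_index, start, motif))
  perm <- scan_motifs(tab, ref[2:1, ])
  expect_identical(dplyr::arrange(hits, peptide_index, start, motif),
                   dplyr::arrange(perm, peptide_index, start, motif))
  # adding a reference entry never decreases counts
  s1 <- summarize_scan(hits, novelty_check(tab, ref), motifs = ref$sequence)
  ref2 <- ref_of("DF", "SF", "FS")
  s2 <- summarize_scan(scan_motifs(tab, ref2), novelty_check(tab, ref2),
                       motifs = ref2$sequence)
  joined <- dplyr::left_join(s1$per_motif, s2$per_motif, by = "motif")
  expect_true(all(joined$peptide_count.y >= joined$peptide_count.x))
})

test_that("novelty is exact full-sequence identity, not substring containment", {
  tab <- tibble::tibble(sequence = c("HTYHEVTKH", "GGGLVGGI", "VDDDKDFIPF"))
  out <- novelty_check(tab)
  expect_equal(out$novelty, c("known", "novel", "novel"))
  # empty reference: everything novel
  empty <- tibble::tibble(sequence = character(),
                          activity_class = character(), source = character())
  expect_true(all(novelty_check(tab, empty)$novelty == "novel"))
  # case-insensitive match
  expect_equal(novelty_check(tibble::tibble(sequence = "htyhevtkh"))$novelty,
               "known")
})

test_that("summarize_scan counts peptides and occurrences separately", {
  hits <- tibble::tibble(peptide_index = c(1L, 2L, 2L), motif = "DF",
                         start = c(6L, 3L, 7L), end = c(7L, 4L, 8L))
  flags <- tibble::tibble(novelty = c("novel", "novel"))
  s <- summarize_scan(hits, flags)
  expect_equal(s$per_motif$peptide_count, 2L)
  expect_equal(s$per_motif$occurrence_count, 3L)
  expect_equal(s$novel_count + s$known_count, 2L)
  # peptide_count never exceeds occurrence_count
  expect_true(all(s$per_motif$peptide_count <= s$per_motif$occurrence_count))
  # no hits -> all-zero summary over the requested motifs
  none <- summarize_scan(hits[0, ], flags, motifs = c("DF", "SF"))
  expect_equal(none$per_motif$occurrence_count, c(0L, 0L))
  # mismatched tables rejected
  expect_error(summarize_scan(hits, flags[1, , drop = FALSE]), "mismatch")
})

test_that("the packaged table's fragment census is internally consistent", {
  tab <- hydrolysate_peptides()
  hits <- scan_motifs(tab)
  flags <- novelty_check(tab)
  s <- summarize_scan(hits, flags, motifs = read_reference()$sequence)
  # every count verified against the brute-force oracle
  for (m in s$per_motif$motif) {
    per_pep <- vapply(tab$sequence,
                      function(p) length(oracle_find_motif(p, m)),
                      integer(1))
    expect_equal(s$per_motif$peptide_count[s$per_motif$motif == m],
                 sum(per_pep > 0))
    expect_equal(s$per_motif$occurrence_count[s$per_motif$motif == m],
                 sum(per_pep))
  }
  expect_equal(s$novel_count, nrow(tab)) # nothing in the table is a known entry
})
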