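test_that("deterministic digestion rules produce the expected fragments", {
  parents <- tibble::tibble(id = "p1", sequence = "GGFGGFGG")
  spec <- digest_spec(specificity_set = "F", cleavage_prob = 1, min_length = 2)
  d <- simulate_digest(parents, spec, seed = 1)
  expect_equal(d$peptides$sequence, c("GGF", "GGF", "GG"))
  expect_equal(d$cut_sites$p1, c(3L, 6L))
  # cleavage_prob 0: the parent survives intact
  d0 <- simulate_digest(parents, digest_spec(cleavage_prob = 0, min_length = 2),
                        seed = 1)
  expect_equal(d0$peptides$sequence, "GGFGGFGG")
  expect_error(simulate_digest(parents[0, ], spec, seed = 1), "non-empty")
  expect_error(simulate_digest(parents, spec), "seed")
})

test_that("digestion is deterministic per seed and varies across seeds", {
  parents <- tibble::tibble(
    id = "p1",
    sequence = paste(rep("GAVLFSTY", 30), collapse = ""))
  a <- simulate_digest(parents, digest_spec(), seed = 99)
  b <- simulate_digest(parents, digest_spec(), seed = 99)
  expect_identical(a, b)
  c <- simulate_digest(parents, digest_spec(), seed = 100)
  expect_false(identical(a$cut_sites, c$cut_sites))
})

test_that("digest fragments tile the parent and conserve mass across 100 seeds", {
  set.seed(5)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  parents <- tibble::tibble(
    id = c("pa", "pb"),
    sequence = vapply(1:2, function(i)
      paste(sample(aas, 150, replace = TRUE), collapse = ""), character(1)))
  w <- mass_table()$water_mono
  for (s in 1:100) {
    d <- simulate_digest(parents, digest_spec(cleavage_prob = 0.5), seed = s)
    for (p in parents$id) {
      frags <- d$peptides[d$peptides$parent == p, ]
      expect_identical(paste(frags$sequence, collapse = ""),
                       parents$sequence[parents$id == p])
      expect_equal(
        sum(monoisotopic_mass(frags$sequence)),
        monoisotopic_mass(parents$sequence[parents$id == p]) +
          (nrow(frags) - 1) * w,
        tolerance = 1e-9)
    }
  }
})

test_that("default digest of long parents mostly lands in the hydrolysate length range", {
  set.seed(17)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  parents <- tibble::tibble(
    id = sprintf("p%d", 1:10),
    sequence = vapply(1:10, function(i)
      paste(sample(aas, 300, replace = TRUE), collapse = ""), character(1)))
  d <- simulate_digest(parents, digest_spec(cleavage_prob = 0.18), seed = 4)
  kept <- d$peptides[!d$peptides$excluded, ]
  lens <- nchar(kept$sequence)
  expect_gte(mean(lens >= 7 & lens <= 36), 0.8)
})

test_that("unperturbed digests reconcile to match and close the pipeline loop", {
  set.seed(8)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  parents <- tibble::tibble(
    id = "p1",
    sequence = paste(sample(aas, 200, replace = TRUE), collapse = ""))
  d <- simulate_digest(parents, digest_spec(cleavage_prob = 0.3), seed = 21)
  sim_tab <- d$peptides[!d$peptides$excluded,
                        c("accession", "sequence", "reported_mw")]
  rep <- run_pipeline(sim_tab)
  expect_true(all(rep$peptides$status == "match"))
  expect_equal(nrow(rep$peptides), nrow(sim_tab))
})

test_that("simulated dose-response matches the closed-form logistic", {
  d <- simulate_dose_response(0.3, 1, doses = c(0.3, 3), noise_sd = 0,
                              seed = 1)
  expect_equal(d$inhibition[1], 50)
  expect_equal(d$inhibition[2], 100 / 1.1, tolerance = 1e-12)
  a <- simulate_dose_response(0.3, 1, 10^seq(-2, 1, 0.5), noise_sd = 2,
                              seed = 7)
  b <- simulate_dose_response(0.3, 1, 10^seq(-2, 1, 0.5), noise_sd = 2,
                              seed = 7)
  expect_identical(a, b)
  expect_true(all(a$inhibition >= -5 & a$inhibition <= 105))
  expect_error(simulate_dose_response(0.3, 1, numeric(0), seed = 1),
               "non-empty")
})

test_that("simulated titrations are monotone and invert the DH formula exactly", {
  for (s in 1:100) {
    tr <- simulate_titration(10.8, N_B = 0.1, alpha_inv = 1.2, M_P = 2.6,
                             h_tot = 8, n_steps = 40, seed = s)
    expect_true(all(diff(tr$B_ml) >= 0))
    expect_equal(tail(tr$dh, 1), 10.8, tolerance = 1e-9)
  }
  one <- simulate_titration(5, N_B = 0.1, alpha_inv = 1.2, M_P = 2, h_tot = 8,
                            n_steps = 1, seed = 1)
  expect_equal(nrow(one), 1)
  expect_equal(one$dh, 5, tolerance = 1e-9)
  expect_error(simulate_titration(-1, 0.1, 1.2, 2, 8, seed = 1), "positive")
})

test_that("simulators restore the caller's RNG state", {
  set.seed(555)
  before <- .Random.seed
  invisible(simulate_dose_response(0.3, 1, c(0.1, 1), noise_sd = 2, seed = 9))
  expect_identical(.Random.seed, before)
})
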