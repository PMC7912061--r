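# Seeded generators for every input the pipeline consumes: an in-silico
# enzymatic digest with subtilisin-like specificity, four-parameter-logistic
# dose-response data, and pH-stat titration traces. All randomness requires
# an explicit integer seed; RNG state is restored on exit.

.with_seed <- function(seed, code) {
  if (missing(seed) || is.null(seed) || !is.finite(seed)) {
    abort("an explicit integer `seed` is required for simulation")
  }
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Digestion specification
#'
#' Parameters of the stochastic in-silico digest. The default specificity
#' set models a broad subtilisin-like protease (such as Alcalase, i.e.
#' subtilisin Carlsberg), cleaving C-terminal to large hydrophobic and
#' small apolar residues; missed cleavages arise from `cleavage_prob < 1`.
#'
#' @param specificity_set Residues at P1 after which cleavage may occur.
#' @param cleavage_prob Per-site cleavage probability in `[0, 1]`.
#' @param min_length,max_length Retained fragment length bounds (residues).
#'   Defaults 6-40 bracket the 7-36-residue range typical of an Alcalase
#'   hydrolysate peptide table.
#' @return A list of class `digest_spec`.
#' @export
digest_spec <- function(specificity_set = c("A", "F", "I", "L", "M", "V", "W", "Y"),
                        cleavage_prob = 0.5, min_length = 6, max_length = 40) {
  specificity_set <- unique(toupper(specificity_set))
  if (!all(specificity_set %in% names(.RESIDUE_MONO))) {
    abort("`specificity_set` must contain canonical residues only")
  }
  if (cleavage_prob < 0 || cleavage_prob > 1) {
    abort("`cleavage_prob` must be in [0, 1]")
  }
  if (min_length < 2 || min_length > max_length) {
    abort("need 2 <= min_length <= max_length")
  }
  structure(list(specificity_set = specificity_set,
                 cleavage_prob = cleavage_prob,
                 min_length = min_length, max_length = max_length),
            class = "digest_spec")
}

#' Simulate an enzymatic digest
#'
#' Cuts each parent protein independently at each eligible site (a position
#' whose residue lies in the specificity set, excluding the final residue)
#' with the specified probability. All fragments are returned; those
#' outside the retained length window are flagged `excluded` rather than
#' dropped, so concatenating each parent's fragments in order reconstructs
#' the parent exactly. Each fragment carries its theoretical monoisotopic
#' mass as `reported_mw` (optionally perturbed), so the simulated table can
#' be fed straight into [reconcile_masses()] and [run_pipeline()].
#'
#' @param parents Tibble with `id` and `sequence` columns, as from
#'   [read_fasta()].
#' @param spec A [digest_spec()].
#' @param seed Integer seed (required).
#' @param mass_noise_sd Gaussian perturbation (Da) added to `reported_mw`;
#'   default 0 gives exact masses.
#' @return A list with `peptides` (tibble: `accession`, `sequence`,
#'   `reported_mw`, `parent`, `start`, `end`, `excluded`) and `cut_sites`
#'   (named list of 1-based cleavage positions per parent).
#' @examples
#' parents <- tibble::tibble(id = "p1", sequence = "GGFGGFGG")
#' simulate_digest(parents, digest_spec(specificity_set = "F",
#'                 cleavage_prob = 1, min_length = 2), seed = 1)$peptides
#' @export
simulate_digest <- function(parents, spec = digest_spec(), seed,
                            mass_noise_sd = 0) {
  if (nrow(parents) == 0) abort("`parents` must be non-empty")
  stopifnot(inherits(spec, "digest_spec"))
  .with_seed(seed, {
    per_parent <- purrr::map2(parents$id, parse_sequence(parents$sequence),
                              function(id, s) {
      n <- nchar(s)
      residues <- strsplit(s, "", fixed = TRUE)[[1]]
      eligible <- which(residues[-n] %in% spec$specificity_set)
      cut <- eligible[runif(length(eligible)) < spec$cleavage_prob]
      starts <- c(1L, cut + 1L)
      ends <- c(cut, n)
      frags <- substring(s, starts, ends)
      list(
        peptides = tibble(
          accession = sprintf("%s/%d-%d", id, starts, ends),
          sequence = frags,
          parent = id, start = starts, end = ends,
          excluded = nchar(frags) < spec$min_length |
            nchar(frags) > spec$max_length
        ),
        cut_sites = cut
      )
    })
    peptides <- list_rbind(purrr::map(per_parent, "peptides"))
    peptides$reported_mw <- monoisotopic_mass(peptides$sequence) +
      if (mass_noise_sd > 0) rnorm(nrow(peptides), 0, mass_noise_sd) else 0
    peptides <- peptides[, c("accession", "sequence", "reported_mw",
                             "parent", "start", "end", "excluded")]
    list(peptides = peptides,
         cut_sites = setNames(purrr::map(per_parent, "cut_sites"), parents$id))
  })
}

#' Simulate a dose-response curve
#'
#' Generates percent-inhibition observations from a four-parameter logistic
#' with fixed asymptotes 0 and 100,
#' `y = 100 / (1 + (ic50 / x)^hill)`, plus additive Gaussian noise on the
#' percentage scale, clipped to `[-5, 105]` (plate readers report slightly
#' out-of-range values but not arbitrary ones).
#'
#' @param ic50 True IC50 (mg/mL, > 0).
#' @param hill Hill slope.
#' @param doses Positive concentrations (mg/mL).
#' @param noise_sd Noise standard deviation in percentage points.
#' @param seed Integer seed (required when `noise_sd > 0`; accepted always).
#' @return A tibble with columns `concentration` and `inhibition`.
#' @examples
#' simulate_dose_response(0.3, 1, doses = c(0.1, 0.3, 1), noise_sd = 0,
#'                        seed = 1)
#' @export
simulate_dose_response <- function(ic50, hill, doses, noise_sd = 2, seed) {
  if (ic50 <= 0) abort("`ic50` must be positive")
  if (length(doses) == 0) abort("`doses` must be non-empty")
  if (any(doses <= 0)) abort("`doses` must be strictly positive")
  .with_seed(seed, {
    y <- 100 / (1 + (ic50 / doses)^hill)
    if (noise_sd > 0) y <- y + rnorm(length(doses), 0, noise_sd)
    tibble(concentration = doses,
           inhibition = pmin(pmax(y, -5), 105))
  })
}

#' Simulate a pH-stat titration trace
#'
#' Produces a strictly non-decreasing cumulative NaOH-consumption series
#' whose endpoint exactly attains a target degree of hydrolysis under the
#' given titration parameters: the final volume is the analytic inverse of
#' the DH formula, intermediate points follow an exponential-saturation
#' profile (fast initial hydrolysis, plateau) with small positive jitter.
#'
#' @param target_dh Target degree of hydrolysis, percent (> 0).
#' @param N_B,alpha_inv,M_P,h_tot Titration parameters as in
#'   [degree_of_hydrolysis()].
#' @param n_steps Number of time points (default 60, one per 3 min of a
#'   180-min hydrolysis).
#' @param rate Saturation rate constant of the profile (default 3).
#' @param seed Integer seed (required).
#' @return A tibble with columns `time_frac` (0-1], `B_ml` (cumulative mL
#'   NaOH) and `dh` (the DH the trace implies at each point).
#' @examples
#' tr <- simulate_titration(10.8, N_B = 0.1, alpha_inv = 1.2, M_P = 2.6,
#'                          h_tot = 8, seed = 1)
#' tail(tr, 1)$dh
#' @export
simulate_titration <- function(target_dh, N_B, alpha_inv, M_P, h_tot,
                               n_steps = 60, rate = 3, seed) {
  if (target_dh <= 0) abort("`target_dh` must be positive")
  if (n_steps < 1) abort("`n_steps` must be >= 1")
  B_final <- target_dh * M_P * h_tot / (N_B * alpha_inv * 100)
  stopifnot(is.finite(B_final), B_final > 0)
  .with_seed(seed, {
    t <- seq_len(n_steps) / n_steps
    base <- (1 - exp(-rate * t)) / (1 - exp(-rate))
    jitter <- c(runif(n_steps - 1, 0, 0.01), 0)
    prof <- cummax(pmin(base + jitter, 1))
    prof <- prof / prof[n_steps] # endpoint exact
    B <- B_final * prof
    tibble(time_frac = t, B_ml = B,
           dh = degree_of_hydrolysis(B, N_B, alpha_inv, M_P, h_tot))
  })
}
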