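# hydropep

Desk-side analysis of enzymatic protein hydrolysates characterised by
peptide mass spectrometry, built around a worked example: an Alcalase
(subtilisin Carlsberg) hydrolysate of the edible garden snail *Helix
aspersa* whose 114 identified peptides ship with the package.

Food-science and peptidomics groups that generate hydrolysates and send
them for LC-MS/MS face the same set of desk tasks once the identification
table comes back:

* **Mass recomputation and reconciliation.** The neutral monoisotopic mass
  of a peptide is the residue sum plus one water,
  `M = Σᵢ m(aaᵢ) + m(H₂O)`. Search engines fold post-translational
  modifications into the reported "theoretical" precursor mass without
  always listing them per row; `reconcile_masses()` recomputes the plain
  mass, takes the residual against the reported mass, and searches a small
  modification set (deamidation +0.98402 Da on Asn/Gln, oxidation
  +15.99491 on Met/Trp, N-terminal acetylation +42.01057,
  carbamidomethylation +57.02146 on Cys, dehydration −18.01056) for a
  parsimonious single-modification explanation, classifying every row as
  `match`, `modified_match` or `unexplained`.
* **Fragmentomics.** Short bioactive fragments encrypted inside a longer
  peptide may confer activity on the parent. `scan_motifs()` finds every
  occurrence (overlaps included) of every reference sequence — by default
  the antihypertensive dipeptides YG, YA, VY, FG, GF, DF, SF, VW reported
  from *H. aspersa* — inside every hydrolysate peptide, and
  `novelty_check()` flags peptides whose *full* sequence matches a
  reference entry (substring hits do not count as known).
* **Assay arithmetic.** `percent_inhibition()` implements the
  ACE-1 plate assay readout `(A_control − A_sample)/A_control × 100`;
  `fit_ic50()` estimates the half-maximal inhibitory concentration by
  least-squares fit of the log-logistic
  `y = 100 / (1 + (IC₅₀/x)^h)` (log-linear interpolation as fallback);
  `degree_of_hydrolysis()` implements the pH-stat formula
  `DH = B·N_B·(1/α)·(1/M_P)·(1/h_tot)·100`; `percent_yield()`,
  `enzyme_substrate_ratio()` and `protein_from_nitrogen()` cover recovery
  and proximate arithmetic.
* **Simulation.** `simulate_digest()` (stochastic cleavage with a broad
  subtilisin-like specificity), `simulate_dose_response()` and
  `simulate_titration()` generate every input the pipeline consumes, with
  known ground truth and explicit seeds, so the whole analysis is testable
  without wet-lab data.

Everything is data-frame-first and pipe-friendly: tables in, tibbles out,
`tidy()`/`glance()` on fits, `autoplot()` for dose-response curves.

## Worked example

```r
library(hydropep)

rep <- run_pipeline(hydrolysate_peptides())
rep
#> Hydrolysate report: 114 peptides (114 novel, 0 known)
#>   mass reconciliation: match=95, modified_match=15, unexplained=4
#>   encrypted fragments: DF in 2, FG in 6, GF in 5, SF in 4, VW in 1,
#>     VY in 1, YA in 3, YG in 2
```

Of the 114 printed peptides, 95 reported masses agree with the plain
monoisotopic mass within 0.011 Da, 15 are explained by exactly one
modification (deamidation in most cases, e.g. WSLNGAETMQ: computed
1135.50 Da, reported 1136.48 Da, residual +0.98 Da), and 4 carry larger
residuals that no single modification in the packaged set explains. No
peptide equals a reference entry in full — all 114 are novel — but many
contain encrypted ACE-inhibitory dipeptides.

IC50 estimation from (here simulated) dose-response data:

```r
curve <- simulate_dose_response(ic50 = 0.2944, hill = 1.2,
                                doses = 10^seq(-2.5, 1, length.out = 8),
                                noise_sd = 2, seed = 42)
glance(fit_ic50(curve))
#> # A tibble: 1 × 5
#>    ic50 hill_slope method      residual_sse     n
#>   <dbl>      <dbl> <chr>              <dbl> <int>
#> 1 0.283       1.20 loglogistic         18.1     8
autoplot(fit_ic50(curve))
```

The fitted 0.283 mg/mL recovers the true 0.2944 mg/mL to within the
2-percentage-point plate noise. pH-stat degree of hydrolysis from
titration quantities:

```r
degree_of_hydrolysis(B = 7.0, N_B = 0.1, alpha_inv = 1.2,
                     M_P = 0.78, h_tot = 8)
#> [1] 13.46154
```

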