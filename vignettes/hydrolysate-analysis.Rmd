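---
title: "Methods: mass reconciliation, fragment scanning and assay arithmetic for protein hydrolysates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mass reconciliation, fragment scanning and assay arithmetic for protein hydrolysates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hydropep)
```

This vignette is the package's account of its methods: the models it
implements, the parameters that matter, the numerical choices behind
them, what the simulators do and do not emulate, and the known
limitations. The running example is the packaged peptide table of an
Alcalase hydrolysate of the edible snail *Helix aspersa*.

## Theoretical peptide masses

The neutral monoisotopic mass of a peptide is the sum of its residue
(water-loss) masses plus one water:

$$M = \sum_i m_{\mathrm{mono}}(aa_i) + m_{\mathrm{mono}}(\mathrm{H_2O}),
\qquad m_{\mathrm{mono}}(\mathrm{H_2O}) = 18.01056\ \mathrm{Da}.$$

Residue masses are standard monoisotopic values to five decimals;
average masses are carried alongside for convenience. Two facts about
this scale matter downstream. First, leucine and isoleucine are exactly
isobaric, so sequences differing only in L/I have identical masses and
the package never tries to distinguish them. Second, the monoisotopic
and average scales diverge by roughly one part in two thousand, so a
published two-decimal table identifies its scale unambiguously: the
packaged table reproduces at two decimals only under the monoisotopic
reading (e.g. GGGLVGGI at 628.35 Da, where the average mass is 628.73),
which is why all reconciliation is done on monoisotopic masses.

Rounding for display uses round-half-up at two decimals
(`round_mass()`), the convention under which printed tables are
compared; full precision is kept internally. Comparisons use a tolerance
of ±0.011 Da, chosen to accept any value that prints identically at two
decimals under either the half-up or half-even convention, and nothing
looser.

## Reconciling reported precursor masses

Search engines print a "theoretical" precursor mass that sometimes
includes a post-translational modification without listing it per row.
`reconcile_masses()` makes that implicit bookkeeping explicit. For each
row it computes the plain monoisotopic mass, forms the residual
(reported − computed) and classifies:

* **match** — |residual| ≤ 0.011 Da;
* **modified_match** — some subset of at most `max_mods` modifications,
  each applicable to the sequence, sums to the residual within
  tolerance;
* **unexplained** — neither.

The packaged modification set covers the five deltas that explain the
overwhelming majority of search-engine mass offsets: deamidation
(+0.98402 Da, Asn/Gln), oxidation (+15.99491, Met/Trp), N-terminal
acetylation (+42.01057, any peptide), carbamidomethylation (+57.02146,
Cys) and dehydration (−18.01056, Ser/Thr/Glu/Asp). It ships as a
tab-separated resource so laboratories can extend it.

Design choices, all deliberate:

* `max_mods` defaults to 1. A single printed mass cannot identify a
  multi-modification combination — the subset space grows
  combinatorially while the evidence stays one number — so parsimony
  wins. The search accepts larger subsets if asked; the smallest
  explaining subset wins, ties broken by smallest remaining error, then
  alphabetically by modification name, so results are deterministic.
* Applicability is enforced: a +0.98 Da residual on a peptide with no
  Asn or Gln is *not* called deamidation.
* Cysteine is treated as free by default. The packaged table confirms
  this: SVGPCKSHRESLGGLPE reconciles to its printed 1751.86 Da with no
  carbamidomethyl adjustment.
* Rows the single-modification search cannot explain stay
  `unexplained` rather than being force-fitted. In the packaged table
  four rows (NQHYPPGIGPLNAP, YLKPVPIVPGLP, FVKMTGSGNDF, MPVSQIQADIIV)
  carry residuals of +16.98, +28.00, +31.99 and +1.96 Da — numerically
  consistent with oxidation-plus-deamidation, formylation, dioxidation
  and double deamidation respectively, but all outside the
  single-modification reach of the packaged set, so they are reported
  as unexplained and frozen as such in the tests rather than guessed.

```{r}
rep <- run_pipeline(hydrolysate_peptides())
rep
```

## The packaged table and its transcription

The fixture is a verbatim transcription of a published identification
table and is checksummed in the tests so silent edits fail loudly. Two
transcription notes. The source's prose counts 113 unique sequences
while its printed table holds 114 distinct rows; the fixture keeps all
114 printed rows — transcription never "fixes" its source. And the
source's abstract prints the heaviest peptide with an RR where the
table prints PR; only the table's form reproduces the printed
2343.14 Da, so the table's form is kept. Similarly, the source's prose
counts DF in four peptides and SF in five, while scanning the printed
table finds DF in two and SF in four; the package reports what it
computes and treats the prose counts as documented claims, not oracles.

## Fragment scanning and novelty

Scanning is exact substring search: every occurrence of every reference
sequence in every peptide, overlaps included (GGGG contains GG at
positions 1, 2 and 3). Counts are reported two ways, because the field
phrases them both ways: the number of distinct peptides containing a
fragment at least once, and the total occurrence count. Novelty is a
separate, stricter notion: a peptide is `known` only when its full
sequence equals a reference entry. The two must not be conflated — a
novel peptide with a known encrypted dipeptide is precisely the
interesting case in fragmentomics.

The default reference holds the eight ACE-inhibitory dipeptides
previously reported from *H. aspersa* (YG, YA, VY, FG, GF, DF, SF, VW —
the FG/GF pair entered as two independent motifs since either order is
claimed) and two antioxidant nonapeptides from a marine snail
hydrolysate (HTYHEVTKH, WPVLAYHFT). It is a local file standing in for
an online bioactive-peptide database: the package never queries a web
service, so novelty here means "not in the supplied reference", no more.

## Assay arithmetic

**Percent inhibition.** The plate readout is
$(A_{\mathrm{control}} - A_{\mathrm{sample}})/A_{\mathrm{control}}
\times 100$: 0% when the inhibitor does nothing, 100% when activity is
abolished. The formula is scale-invariant in absorbance units and is
reported unclipped — negative values flag samples that apparently
activated the enzyme, which a laboratory wants to see, not hide.

**IC50.** The primary estimator is a least-squares fit of the
log-logistic

$$y = \mathrm{bottom} + \frac{\mathrm{top} - \mathrm{bottom}}
{1 + (IC_{50}/x)^{h}}$$

with bottom = 0 and top = 100 fixed and $\log_{10} IC_{50}$ and the
Hill slope $h$ free, by Levenberg–Marquardt on the log-dose scale.
Fixing the asymptotes is deliberate: inhibition is bounded by
construction, and a typical 6–10-dose curve cannot constrain four
parameters; both asymptotes can be set to other fixed values by
argument when an assay's dynamic range warrants it.
The optimiser is initialised at $h = 1$ with $\log_{10} IC_{50}$ at an
inverse-distance-weighted mean of the log-doses, which is within the
basin of attraction for any curve that actually crosses half-maximum.
When only two distinct doses exist, or the fit fails to converge, the
estimator falls back to log-linear interpolation between the adjacent
dose pair straddling 50%, and records `method = "interpolation"` in the
result — the two routes are never silently mixed. Curves that never
cross 50% raise an error rather than extrapolating. Published
hydrolysate IC50s rarely state which of the two methods produced them;
providing both, labelled, is the honest option.

**Degree of hydrolysis.** The pH-stat estimator is

$$DH = B \cdot N_B \cdot \frac{1}{\alpha} \cdot \frac{1}{M_P} \cdot
\frac{1}{h_{tot}} \cdot 100$$

with $B$ the NaOH volume consumed (mL), $N_B$ its normality (eq/L, so
$B \cdot N_B$ is in meq), $1/\alpha$ the reciprocal average dissociation
of the liberated α-amino groups at the working pH and temperature,
$M_P$ the protein mass (g) and $h_{tot}$ the total peptide bonds per
gram of substrate protein (meq/g). $1/\alpha$ and $h_{tot}$ are
substrate- and condition-specific constants conventionally taken from
tabulations; they are required inputs here, never defaulted, because no
single value is defensible across substrates.

**Yields and proximate values.** `percent_yield()` is plain
recovered/input × 100, rounded half-up at two decimals for display;
`enzyme_substrate_ratio()` is volume-per-weight (mL enzyme per g
substrate × 100), the convention under which 1.76 mL on 44 g is a 4%
dosing; `protein_from_nitrogen()` multiplies total nitrogen by the
conventional factor 6.25 (all protein ≈ 16% N), with inputs outside
0–16% N rejected. One arithmetic footnote: recomputing the source
study's shell-fraction yield from its printed masses, 7.98 g from 44 g,
gives 18.1364 → 18.14%, where the source prints 18.13%; the sibling
value (3.98 g → 9.05%) requires round-half-up, so no single rounding
convention reproduces both printed numbers and the package reports the
arithmetic answer.

## What the simulators emulate — and what they do not

`simulate_digest()` cuts each parent independently at each eligible
site with a fixed probability. The default specificity set
{A, F, I, L, M, V, W, Y} models a broad subtilisin-like protease
cleaving C-terminal to large hydrophobic and small apolar residues —
a modelling choice, not a measured cleavage table; Alcalase's true
specificity is broader and context-dependent. Missed cleavages arise
from `cleavage_prob < 1` rather than an explicit missed-cleavage
counter: a simpler generative story with the same marginal effect. All
fragments are kept and flagged rather than dropped, so two invariants
hold by construction and are property-tested across seeds:
concatenating a parent's fragments reconstructs the parent, and the
fragment masses sum to the parent mass plus (n−1) waters. With the
default retention window of 6–40 residues and a cleavage probability
around 0.2 on 300-residue parents, most retained fragments fall in the
7–36-residue range seen in real Alcalase hydrolysate tables.

`simulate_dose_response()` draws from the same log-logistic the fitter
assumes, with additive Gaussian noise on the percentage scale (default
σ = 2 points, plate-reader replicate scale) clipped to [−5, 105]. That
matched model is exactly what makes recovery testing meaningful — and
exactly what it cannot show: recovery says the estimator inverts its
own model; it says nothing about model misfit on real curves (partial
inhibition plateaus, solubility ceilings, matrix effects).

`simulate_titration()` inverts the DH formula analytically for the
endpoint volume and fills in an exponential-saturation profile with
small positive jitter, monotone by construction, endpoint exact to
1e-9. It emulates the *shape* of a pH-stat trace, not hydrolysis
kinetics: no enzyme inactivation, no pH drift, no temperature
dependence.

All generators require an explicit integer seed and restore the
caller's RNG state; an omitted seed is an error, not a silent default.

Problem sizes used by the test-suite and acceptance checks — 500
scanner-vs-oracle cases, 50 noisy IC50 curves at 8 doses, 100 seeded
digests of a 200-residue parent, 100 titration traces — are the
package's chosen verification scale: large enough that counting
arguments are meaningful, small enough to run comfortably anywhere.

## Degenerate inputs and edge behaviour

Sequence validation rejects the non-canonical letters B, J, O, U, X, Z
with the offending position named; empty files, header-only tables and
missing required columns all fail with named errors; a permissive read
mode skips bad rows but logs their line numbers. Zero base consumed
gives DH = 0; zero recovered mass gives 0% yield; an empty bioactive
reference is valid and makes every peptide novel. Reports are
deterministic: identical inputs yield byte-identical TSV output.

## Known limitations

* No m/z, charge-state, isotope-envelope or fragment-ion computation:
  the package starts where the search engine stops, at sequences and
  neutral masses.
* Modification inference from a single printed mass is inherently
  underdetermined; the package reports the most parsimonious consistent
  explanation and refuses to stack modifications unless asked.
* Novelty is exact-match against a local reference, not a database
  query; absence from the packaged reference is not absence from the
  literature.
* The digest simulator's specificity set is a caricature of a real
  protease; it is meant to generate structurally realistic test tables,
  not to predict actual cleavage products.
* Bioactivity is never predicted: an encrypted dipeptide hit is a
  pointer into the reference, not evidence that the parent peptide
  inhibits anything.
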