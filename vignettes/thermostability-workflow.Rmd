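---
title: "Methods: the in silico thermostabilization workflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the in silico thermostabilization workflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermoforge)
```

thermoforge implements the computational half of a rational
thermostabilization campaign of the kind used on mesophilic GHF11
xylanases: nominate a flexibility hotspot from an ensemble, saturate it,
add a back-to-consensus mutation from a thermophilic homolog panel,
sanity-check the designs by simulated-unfolding RMSD, rationalize the
winners by interaction analysis, and fit the characterization assays.
This vignette documents the models behind each stage, the tunable
parameters and their defaults, the synthetic-data model the tests rely
on, and the numerical choices that were genuinely open.

## Flexibility analysis and hotspot selection

For an ensemble of frames sharing one topology, the per-atom
root-mean-square fluctuation is

$$\mathrm{RMSF}_i = \sqrt{\langle \lVert r_i - \langle r_i \rangle
\rVert^2 \rangle},$$

converted to a crystallographic-style atomic displacement parameter by
$B = \tfrac{8\pi^2}{3}\,\mathrm{RMSF}^2$ (Å²). High-B residues are
flexible; the residue with the maximum per-residue B is the saturation
mutagenesis hotspot. `select_hotspot()` breaks ties deterministically in
favour of the lower residue number.

Two choices here were open:

* **Superposition before fluctuation.** Whether the source trajectory is
  pre-fitted is rarely reported alongside B-factor plots. The default
  `superpose_first = TRUE` iteratively superposes every frame onto the
  running mean structure (Kabsch fit, converged when the mean moves
  < 1e-6 Å or after 50 rounds), so global drift and tumbling do not
  masquerade as flexibility. The no-superposition path is kept for
  ensembles that are already fitted, and is required when fewer than 3
  atoms are selected.
* **Per-residue aggregation.** The RMSD stage of the workflow is
  Cα-based, so `"ca"` is the default aggregation; `"mean-heavy"` and
  `"max"` are offered because flexibility tools differ on this point and
  the choice can reorder near-tied residues.

Note that the superposition fit absorbs a small part of a strongly
localized fluctuation (6 rigid-body degrees of freedom against 3N
coordinates), so recovered hotspot B-factors sit slightly below the
planted open-loop value; rank order — what hotspot selection uses — is
unaffected.

## Rigid superposition and RMSD stability comparison

`kabsch()` is the closed-form SVD superposition with the determinant
correction that forbids reflections (`det(R) = +1` always; the smallest
singular direction is sign-flipped when needed). `rmsd_series()`
superposes every frame of a (high-temperature, in the emulated study)
trajectory onto its first frame — the "original configuration" — and
reports Cα RMSD per frame. The comparison rule in `compare_stability()`
is: lower post-equilibration mean RMSD predicts the more thermostable
protein.

Open choices, fixed as configuration with defaults:

* **Equilibration window.** With no stated equilibration time, the
  default discards the first 20% of frames (`equil_frac = 0.2`),
  overridable by an explicit start frame.
* **Verdict tolerance.** Means within 5% (relative to the larger) are
  `indistinguishable`; a strict pointwise-dominance check ("lower at any
  time") is available via `pointwise = TRUE`.
* **No mass weighting** by default; a weight vector is accepted.

## Consensus scanning

`consensus_scan()` proposes a substitution wherever the target residue
disagrees with the *plurality* residue among non-gap homolog rows,
provided that plurality is unique and its support (fraction of non-gap
homolog rows) reaches `min_support` (default 0.5 — "most" homologs).
Plurality rather than strict majority was chosen because a panel of
seven thermophilic homologs frequently splits 3/2/2; a tie yields no
candidate because no consensus residue can be named. Gaps never count
toward support, and a column where the target is gapped yields nothing.
Percent identity for panel filtering is computed over columns where both
sequences are non-gap (the `"aligned-columns"` convention); the
`"shorter-ungapped"` denominator is offered because published identity
tables rarely state their convention. The homolog filter is strict
("more than" the threshold).

## Interaction analysis

Detection uses standard geometric contact criteria of the
protein-interaction-calculator family, declared rather than inferred:

* hydrophobic interaction: any side-chain carbon of one residue in
  {Ala, Val, Leu, Ile, Met, Phe, Trp, Pro, Tyr} within 5.0 Å of any
  side-chain carbon of another (Tyr and Trp are included — the
  hydrophobic clusters this workflow cares about are aromatic-rich);
* salt bridge: acidic side-chain oxygen (Asp OD1/OD2, Glu OE1/OE2)
  within 4.0 Å of a basic side-chain nitrogen (Lys NZ, Arg NE/NH1/NH2,
  His ND1/NE2). His counts as basic by default since protonation cannot
  be read from geometry; `include_his = FALSE` turns it off.

Same-chain pairs need a residue-number separation of at least 2, so
sequence-adjacent side chains are not reported as stabilizing contacts.
Pairs are deduplicated at residue level, keeping the minimum realizing
distance. Diff identity is `(kind, chain, residue-number pair)` —
residue names are excluded so the mutated position itself does not block
matching. Hydrophobic clusters are connected components (size ≥ 2) of
the residue graph whose edges are the detected hydrophobic contacts.

## Library design statistics

`expand_degenerate()` expands an IUPAC triad against the standard
genetic code; NNK gives 32 codons, all 20 amino acids, one stop (TAG).
`coverage_probability()` answers "with n random transformants, what is
the chance every amino acid appears at least once?" by exact
inclusion–exclusion over amino-acid subsets on the codon multinomial,

$$P = \sum_{S} (-1)^{|S|} \left( \frac{C - c(S)}{C} \right)^{n},$$

evaluated exactly by a dynamic program over the total codon count of the
missed set (algebraically identical to the $2^{20}$-term sum, but
linear-time). Stop codons count toward $C$ — they dilute the library —
but are never required observations. `transformants_for_coverage()`
inverts the statistic by doubling-then-bisection in three modes:
full coverage, expected fraction of amino acids observed, and the
probability that one named variant is present. The three modes answer
different questions and give different n for NNK at 95% (173, 80 and 95
respectively, for a single-codon variant in the last case); no single
"colonies to pick" constant is hard-coded, and published oversampling
tables typically correspond to the per-variant or expected-fraction
readings rather than full coverage.

Screening rules are strict inequalities: survivors retain *more than*
the threshold (default 80%) of their original activity, and
`best_variant()` refuses ties rather than picking silently.

## Enzymological characterization

* **Kinetics.** `fit_michaelis_menten()` fits
  $v = V_{max} S / (K_m + S)$ by Levenberg–Marquardt with deterministic
  initialization ($V_{max,0} = 1.05 \times$ max rate; $K_{m,0}$ the
  substrate whose rate is nearest $V_{max,0}/2$) — robust on any
  saturating curve and free of random restarts. With a molecular weight
  (kDa), $k_{cat} = V_{max} \cdot MW / 60$ converts
  U mg⁻¹ (= µmol min⁻¹ mg⁻¹) to s⁻¹; $k_{cat}$ may instead be supplied
  directly, as when reproducing a printed kinetics table.
* **Inactivation.** First-order mode fits $\ln(\text{residual}) = -kt$
  without an intercept (residual is 1 at time zero by definition) and
  reports $t_{1/2} = \ln 2 / k$; the alternative interpolation mode
  returns the piecewise-linear crossing of 0.5 because the half-life
  *definition* is a point crossing. Both are exposed since decay plots
  and the definition suggest different estimators; they agree within
  grid resolution on exponential data.
* **Melting.** `call_tm()` smooths the fluorescence scan with a 5-point
  moving average, takes central-difference dF/dT, and calls Tm at the
  derivative peak with parabolic sub-grid refinement. A peak at the scan
  boundary is an error (the transition is not bracketed), not a value.
  The default synthetic grid is 30–80 °C at 0.5 °C, matching a 1 °C/min
  thermal-shift ramp sampled twice per degree.
* **Profiles.** `profile_analysis()` renormalizes activities to a 100%
  maximum, calls the optimum at the grid argmax (ties to the lower x)
  and reports the stable range as the contiguous grid run at or above
  the retention threshold (default 85%) containing the optimum.
* **Reporting.** All internal math is full precision; printed tables
  round half-up to one decimal (`round_half_up()`), matching how assay
  tables are conventionally printed.

## The synthetic-data model

The generators in this package stand in for the three data sources the
workflow would normally consume — molecular-dynamics trajectories,
homology models, and assay plates — and each emits its planted ground
truth alongside the data (`truth` element in code, `truth.json` on
disk), so tests recover parameters rather than re-deriving them.

* `gen_ensemble()`: residues on a smooth backbone; each residue's atoms
  jitter i.i.d. Gaussian with a planted per-residue σ (hotspot 1.0 Å vs
  background 0.3 Å by default), plus an optional random global
  rigid-body motion per frame that the superposition step must undo.
  What it does *not* emulate: correlated motions, anisotropy, or real
  backbone geometry — so passing tests show the estimator and selection
  rule are correct, not that any force field is.
* `gen_structure_pair()`: wild-type/variant structures whose planted
  contact lists differ by exactly the requested lost/gained sets. Each
  planted contact lives in its own well-separated zone (16 Å lattice;
  planted atom pairs at 4.0 Å hydrophobic / 3.0 Å salt bridge, all
  non-planted pairs > 6 Å beyond their cutoff), so detection must
  recover the diff exactly. The default plant mirrors a
  two-lost/nine-gained-plus-salt-bridge engineering outcome; because
  detection enforces a sequence separation of ≥ 2, the default gained
  list uses only non-adjacent pairs.
* `gen_msa()`: homolog rows from a shared consensus with a 5%
  background substitution rate; the target deviates at planted positions
  with planted support (default: Tyr at ungapped position 13 facing Phe
  in 6 of 7 homologs). Insert columns where the target is gapped
  exercise the column↔position mapping.
* Assay generators: Michaelis–Menten, first-order decay, Boltzmann
  melting and Gaussian activity-bell curves with multiplicative
  (rates/residuals/activities) or additive (fluorescence) Gaussian
  noise. Default noise levels are part of the study conditions and were
  set once so that parameter recovery at the package's stated tolerances
  succeeds in ≥ 95% of 100 seeds: rate CV 0.3% (replicate-averaged
  rates), residual CV 1%, fluorescence SD 0.3% of amplitude. Planted
  defaults use the workflow's characteristic magnitudes (Km 2.32 mg/mL,
  half-lives 71–240 min, Tm 52–62 °C, optimum 60 °C).

All generators restore the caller's RNG state and are byte-identical
under a fixed seed.

## Problem sizes and degenerate inputs

The test suite and the acceptance script run the structure-stage
property checks at 100 seeds × (30 residues × 500 frames) for hotspot
recovery and 100 seeded structure pairs for interaction diffing; these
sizes give stable ≥ 95% recovery statistics while keeping a full run in
the low minutes on a single core. Degenerate inputs are errors, not
guesses: single-frame ensembles (no fluctuation), fewer than 3 points
for superposition, plurality ties, unreachable coverage confidences,
residuals that never cross 0.5 in interpolation mode, and unbracketed
melting transitions.

## Known limitations

* The package predicts *rules applied to coordinates and curves*; it
  does not run dynamics, build homology models, or predict ΔΔG. Where
  the emulated study derived numbers from such runs (a hotspot B-factor
  of tens of Å², real interaction lists, measured activities), those are
  reachable here only through synthetic surrogates.
* B-factors read from crystallographic PDB columns are accepted as
  pass-through input but never treated as computed fluctuations.
* Insertion codes are rejected by the PDB reader; altlocs keep the
  first conformer. mmCIF and MD engine trajectory formats are out of
  scope.
* The interaction criteria are geometric; no energies, hydrogen bonds,
  aromatic–aromatic or cation–π terms.
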