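---
title: "Methods: formula assignment, compositional networks and multivariate classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: formula assignment, compositional networks and multivariate classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somatlas)
```

This vignette documents the models, conventions and numerical choices
behind `somatlas`. The package analyses ultrahigh-resolution mass spectra
of complex organic mixtures at the level of elemental compositions: with
sub-ppm mass accuracy, an exact ion mass determines a unique molecular
formula over a bounded element space, and everything downstream — family
statistics, van Krevelen projections, homologous series, mass-difference
networks, multivariate sample classification — operates on those formulas.

## Peak lists and calibration

A peak list is a table of singly charged ions `(m/z, intensity, S/N)`,
sorted by m/z. Multiply charged species are assumed to have been rejected
upstream; all adduct arithmetic treats `z = 1`. The file dialect is fixed
(tab-separated, header `mz`, `intensity`, `snr`, `#` comments) because
instrument exports vary and round-tripping must be lossless; m/z is
serialized to 7 decimals (sub-ppb at m/z 100).

`filter_snr()` keeps peaks with S/N ≥ threshold, boundary inclusive — the
common export convention is S/N ≥ 3 and the default follows it.

`recalibrate()` matches user-supplied reference masses (neutral mass plus
expected ion type) to the nearest peak within a ppm tolerance and models
the relative mass error either as a constant offset or as a linear
function of m/z; the inverse correction `mz / (1 + ppm(mz)·10⁻⁶)` is
applied to all peaks, and the residual RMS over the matched references
after correction is reported. The reference series is deliberately
user-supplied — no calibrant list is universal — and the package ships a
saturated CHO fatty-acid series (`example_calibrants()`) as a worked
example typical of negative-mode organic mixtures.

## Formula assignment

### Mass model

Monoisotopic masses are summed from fixed atomic constants (C exactly 12,
H 1.0078250319, N 14.0030740052, O 15.9949146221, S 31.9720707,
Na 22.98976928, Mg 23.9850417, Cl 34.96885268). Ion arithmetic includes
the electron mass (0.00054858 Da): e.g. for a deprotonated ion
`M = mz + m(H) − m(e⁻)`. At 0.2 ppm tolerances the electron mass (~2.7 ppm
at m/z 200) is far from negligible.

### Enumeration

`enumerate_formulas()` enumerates every composition inside the
element-count bounds whose mass falls within the ppm window. The C++ core
loops over heteroatoms (Cl, Mg, Na, S, O, N) with cumulative-mass pruning
and solves the feasible carbon range and the at-most-two hydrogen counts
per branch in closed form, so the cost per call is proportional to the
number of mass-feasible heteroatom branches rather than the full grid. An
exhaustive nested-loop oracle (mass test applied last) is kept in the test
suite and the two are asserted equal on random masses.

### Validation rules

Candidates pass through two layers, applied after enumeration so the
enumeration contract stays purely mass-based:

* **Senior rules** — `DBE = 1 + Σᵢ nᵢ(vᵢ − 2)/2` with valences C 4, H 1,
  N 3, O 2, S 2, Na 1, Cl 1 and Mg 4 (coordination number). A composition
  passes when DBE is a non-negative integer, the count of odd-valence
  atoms (H, N, Na, Cl) is even, and total valence admits a connected
  graph (Σ nᵢvᵢ ≥ 2(Σ nᵢ − 1)). Sulfur is treated divalent throughout, so
  oxidised sulfur (sulfonates, sulfates) accrues DBE through its oxygens.
* **Ratio filters** — defaults H/C ∈ [0.25, 3.2], O/C ≤ 1.2, N/C ≤ 1.3,
  S/C ≤ 0.8, with element bounds C 1–100, H 0–200, N 0–6, O 0–40, S 0–10,
  Na/Mg/Cl 0–1. These are conservative screening values for CHNOS
  small-molecule space, chosen as package defaults (sulfur up to 10 keeps
  polysulfur series through S9 reachable; Mg is included so that the
  *absence* of organomagnesium compositions in a sample is a testable
  outcome rather than an artifact of the search space). All are
  configurable through `element_bounds()`.

### Primary-candidate selection

Each peak is tried under the ionization mode's ion types (ESI(−): [M−H]⁻,
[M+Cl]⁻; ESI(+): [M+H]⁺, [M+Na]⁺; APPI(+): [M+H]⁺, M⁺•). An adduct
element is excluded from the neutral it attaches to ([M+Na]⁺ implies an
Na-free neutral), while ESI(−) neutrals may legitimately contain sodium —
this mirrors the common family nomenclature (CHONa etc.) for salt-type
compositions observed as deprotonated ions.

Among surviving candidates the primary is chosen by **elemental parsimony
first** — fewest atoms of the rare elements Na, Mg, Cl counted over the
whole ion, adduct included — and smallest |mass error| second. Pure mass
ranking is not reliable at 0.2 ppm: rare-element compositions and
chloride-adduct reinterpretations are mass-degenerate with plain CHNOS
formulas at the 0.01–0.05 ppm scale often enough to dominate an
error-only ranking, which is chemically implausible for natural organic
mixtures where Na/Mg/Cl-organic species are rare. This is the same
heteroatom-parsimony heuristic that practical FT-ICR assignment pipelines
apply when collapsing candidate lists. The remaining ambiguities after
parsimony are genuine CHNOS degeneracies (e.g. C₁₃H₁₆ vs N₆O₁₀S₂
substitutions, ~0.03 mDa apart) that only isotope information or
network-based assignment could resolve.

Isotopologue verification (`isotope_verify()`) searches the +1.0033548 Da
¹³C companion (and the +1.9957959 Da ³⁴S companion for sulfur-bearing
formulas). A companion whose intensity ratio lies within a factor-2 band
of `n_C × 0.0107` (resp. `n_S × 0.0442`) confirms the assignment, one
outside the band contradicts it, and a missing companion contradicts only
when it was confidently expected (`n_C ≥ 10` and parent S/N ≥ 30) —
otherwise the assignment stays unchecked. Confirmed candidates are
promoted over unverified ones when their mass errors agree within
0.02 ppm and parsimony is not worsened.

## Descriptors

Per formula the package computes H/C, O/C, DBE, the aromaticity
equivalent

> Xc = (3·(DBE − m·O − n·S) − 2) / (DBE − m·O − n·S),

with Xc = 0 whenever DBE ≤ 0 or the corrected term is not positive. The
fractions m and n of oxygen and sulfur assumed to sit in π-bonds default
to 0.5, the convention of the method's original formulation; both are
arguments. Thresholds Xc ≥ 2.5 (aromatic) and Xc ≥ 2.71 (condensed
aromatic) then apply; unsubstituted catacondensed PAHs land at Xc ≥ 2.5
by construction.

Family labels concatenate the elements present in the order C, H, N, O, S
with an `Na` suffix; Mg-bearing formulas are set aside as `Mg-organic`.
Nominal mass is `round(monoisotopic mass)` — in CHNOS space below
~1000 Da masses never fall near x.5, so the tie rule is immaterial — and
the Kendrick mass defect uses the CH₂ scale (14 / 14.0156500638).

Homologous series detection partitions a formula set into maximal chains
under repeated addition of an elemental step (default CH₂); a formula
belongs to exactly one maximal chain per step and chains of length ≥ 2
are reported. Series are detected on exact formulas, not measured masses
(the tolerance-based mass network covers the unassigned case).

The CH₄-vs-O substitution (`ch4_o_substitution_pairs()`) links formulas
`g = f − CH₄ + O` inside one nominal mass. The exact monoisotopic spacing
from the atomic-mass table is 36.3855 mDa; a figure of 36.3845 mDa
sometimes quoted for this split is inconsistent with the atomic masses by
1 µDa and the computed value is used here.

## Mass-difference networks

The canonical network is **formula-based**: an undirected edge joins two
formulas whose elementwise difference equals a catalogue delta exactly.
Because the catalogue deltas are elementally distinct, at most one
transformation can label a pair, and "removal" vs "addition" collapse
into a single undirected edge. The default catalogue has 13 entries —
CH₂, H₂, O, H₂O, CO₂, HCN, NH, NH₃, S, SO, SO₂, SO₃, SO₄ — and a
12-entry variant without CO₂ is available
(`default_transformations(include_co2 = FALSE)`), since usage differs on
whether decarboxylation-scale differences belong in the core set.

Exact elemental matching is equivalent to the "exact mass difference
between all pairs" formulation; the test suite asserts the equivalence
against an all-pairs mass-difference oracle at 1 × 10⁻⁶ Da on seeded
populations. A tolerance-based variant (`mass_based_network()`) works
directly on peak m/z values (difference compared against the catalogue
mass within ppm of the larger m/z) and needs no assignment; on assigned
data its edge set contains the formula-based edges.

Network statistics report per-transformation counts and percentages of
all edges, plus grouped percentages for the nitrogen set {HCN, NH, NH₃}
and the sulfur set {S, SO, SO₂, SO₃, SO₄}. Percentages are exact
fractions × 100; headline shares are conventionally rounded to integer
percent.

## Multivariate protocol

`assemble_matrix()` joins assignment tables into a samples × formulas
matrix on exact elemental identity, using the primary assignment's
intensity; a formula not detected in a sample is a structural zero, not a
missing value — detection semantics, no imputation. Preprocessing is
`log₁₀(1 + x)` (the +1 handles those zeros while leaving large
intensities on a log scale; the base is a display convention, any base
rescales all columns equally) followed by column mean-centering and
unit-variance scaling; constant columns are dropped and recorded, and the
stored record replays the identical transform on held-out samples.

PCA is extracted component-wise by NIPALS with a relative convergence
tolerance of 10⁻⁹ on the score vector and a 5000-iteration cap
(exceeding it raises an error naming the component; near-degenerate
eigenvalue pairs converge slowly, hence the generous cap). Component
orientation is fixed by making the largest-magnitude loading positive, so
seeded runs are reproducible to the bit. R²X per component is the
explained sum of squares over the preprocessed matrix's total sum of
squares.

Cross-validated Q² uses row-wise folds (7 contiguous blocks by default,
the long-standing default of commercial chemometrics software). Each
element of a held-out row is predicted from the row's *other* variables:
scores are estimated with the element's own loading row excluded (a
Sherman–Morrison rank-one downdate of the orthonormal loading basis), and
`Q²(cum, k) = 1 − PRESS_k/TSS`. The element-wise scheme matters: naive
whole-row projection reuses the predicted element in its own score and is
non-negative by construction, whereas honest prediction drives Q² below
zero on structure-free data — the property the noise tests assert.

"Valid" component counting follows the usual heuristic — retain component
i while Q²(i) > 0 — as a documented approximation; no universal rule
exists and the per-component Q² values are returned so users can apply
their own.

Held-out classification, as exercised in the tests and the acceptance
script, assigns a predicted sample to the class whose work-set mean PC1
score is nearer; with two classes this is the score-sign rule up to a
shift.

## The synthetic-data generator

The generator exists so that every stage has planted ground truth. Its
defaults emulate the study conditions the pipeline is designed for:

* populations of ~500–1000 CHNOS(+Na) formulas in 120–700 Da organised in
  CH₂ homologous series, with a family mix dominated by N-bearing classes
  (CHNO 0.30, CHN 0.12, CHNOS 0.08), then CHO 0.27, CHOS 0.15, CH 0.06,
  CHS 0.02 — an order-of-magnitude mimic of published family abundances
  in aqueously altered carbonaceous material, not a calibrated fit;
* optional polysulfur chains with sulfur counts S3 through S9;
* per-peak mass jitter at the 0.05 ppm scale (the documented accuracy
  class of internally calibrated 12 T FT-ICR instruments) against a
  0.2 ppm assignment window;
* log-normal intensities (two parameters; any heavy-tailed positive model
  would do) with S/N tied to intensity through a constant noise floor;
* noise peaks placed by rejection sampling at least 0.5 ppm from every
  assignable composition under the active bounds, so false-positive rates
  measure the assignment logic rather than the noise model;
* two-class studies of 36 samples with a 25/11 work/prediction split, a
  4-fold intensity effect on a 10% discriminating formula subset, and
  0.3 log-units of per-entry multiplicative noise.

What the generator does **not** emulate: isotopic fine structure beyond
single ¹³C/³⁴S companions, resolution and peak-shape effects, correlated
(structured) chemical backgrounds, ionization suppression, or
inter-sample calibration drift. Passing the planted-recovery tests
therefore demonstrates the correctness of the pipeline's logic under
controlled error models, not performance on real spectra, where
assignment ambiguity is resolved with isotope patterns and
chemical-network context beyond what mass accuracy alone provides.

## Problem sizes and determinism

The shipped tests and the acceptance script use populations of 100–500
formulas, 36-sample studies and 20 classification replicates — sizes
chosen so the complete suite runs in well under a minute on one core
while keeping every assertion statistically comfortable. All generators
are seeded and fully deterministic; the acceptance script derives every
seed from its `--seed` argument.

## Known limitations

* Assignment is single-peak; no network-propagated or isotope-fine-
  structure-based disambiguation of the residual CHNOS degeneracies.
* The senior connectivity test is necessary, not sufficient — it cannot
  exclude compositions with no stable structure.
* The MDiN treats transformations as unordered elemental deltas; reaction
  directionality and mechanism are out of scope, as are graph layout and
  community structure.
* Q² fold assignment is contiguous-block; grouped or stratified designs
  must be emulated by row ordering.
* The PCA is plain (no sparse or supervised variants); class structure
  enters only through the planted effect and the score-space classifier.
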