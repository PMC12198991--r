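---
title: "Group-additivity gas-phase thermochemistry with gavthermo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Group-additivity gas-phase thermochemistry with gavthermo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gavthermo)
```

# The estimation problem

Absolute entropies (S°), entropies of formation (ΔfS°) and Gibbs energies of
formation (ΔfG°) of gas-phase organic molecules are rarely measured directly.
For large carboxylic acids and cyclic imides — such as the two
diimidetricarboxylic acid (DITA) isomers this package uses as its worked
example — the practical routes are quantum chemistry (expensive for
macromolecules) and group additivity in the tradition of Benson: a molecular
property is modeled as a sum of contributions from its constituent
heavy-atom-centered groups, plus structural corrections.

`gavthermo` implements that second route end to end:

* **Hess's-law algebra.** For CmHnOpNo(g), the formation reaction from the
  elements is `m C(s) + n/2 H2(g) + p/2 O2(g) + o/2 N2(g) → CmHnOpNo(g)`, so
  ΔfS° = S°(molecule) − [m·S°(C,s) + (n/2)·S°(H2) + (p/2)·S°(O2) +
  (o/2)·S°(N2)].  The element entropies default to 5.74, 130.571, 205.043
  and 191.500 J mol⁻¹ K⁻¹ (with standard uncertainties 0.10, 0.003, 0.005,
  0.004); R is the CODATA 8.314462618 J mol⁻¹ K⁻¹.
* **The Gibbs relation.** ΔfG° = ΔfH° − T·ΔfS° at T = 298.15 K by default,
  and its rearrangement ΔfH° = ΔfG° + T·ΔfS°, which chains a
  regression-predicted Gibbs energy with a quantum-chemical entropy into an
  enthalpy of formation.
* **Group additivity with a regression-derived table.** The packaged
  parameter table (`builtin_gav_table()`, shipped as
  `extdata/gav_groups_v1.json`) carries 41 group and correction values for
  each of S°, ΔfS° and ΔfG°, plus an intercept triple added once per
  molecule.  The intercept exists because the values come from a multiple
  linear regression *with* intercept; dropping it would bias every estimate.
* **Refitting.** `run_pipeline()` refits the table to any dataset of
  (group-count, property) pairs by ordinary least squares with a single
  70/30 holdout split, reporting R², MAE and RMSE on both splits.
* **Reaction thermochemistry.** ΔrH = Σν·ΔfH, ΔrG = ΔrH − T·ΔrS/1000 and
  Keq = exp(−1000·ΔrG/RT) for stoichiometric gas-phase reactions, with
  root-sum-square (RSS) combination of input uncertainties.

## Units

Entropies are J mol⁻¹ K⁻¹ throughout; enthalpies and Gibbs energies are
kJ mol⁻¹, matching thermochemical-table conventions.  The factor 1000
appears in exactly two places — `gibbs_of_formation()` /
`enthalpy_from_gibbs()` and `reaction_gibbs()` / `equilibrium_constant()` —
so no other layer converts units.

# The group vocabulary and its grammar

A Benson group is a heavy-atom center plus the types of its bonded
neighbors: `C_B-(H)(C_B)2` is an aromatic CH carbon flanked by two aromatic
carbons; `CO` is a carbonyl carbon *including its double-bonded oxygen*;
`CO-(C_B)(O)` is therefore the acid/ester carbonyl attached to an aromatic
ring and a single-bonded oxygen.

Canonical labels are written `CENTER-(LIG1)(LIG2)...` with hydrogen ligands
first (`(H)3`) and the rest ordered by the fixed priority CO > C_B > C_D >
C > N > O; repeated ligands collapse to a numeric suffix.  Published tables
are not consistent about ligand order (the same table prints `CO-(O)(CO)`
but `C-(H)2(CO)(C)`), so `canonical_label()` accepts any ordering and any
of the common subscript spellings and normalizes them; every lookup and
estimation path goes through it.  Three rows of the packaged table share
one value triple (e.g. `O-(C)(C_B)`, `C-(H)3(O)`, `C_B-(O)(C_B)2` at
18.77/−60.84/−37.25).  They are kept as distinct labels: the aliasing is
almost certainly an artifact of collinearity in the original fit, and
collapsing them would silently change other molecules' estimates.

Correction terms enter the sum like groups but carry no atoms:

* `rsc` — ring-strain correction, applied once per five-membered ring
  containing the CO–N–CO imide motif;
* `correction o-`/`m-`/`p-` — substitution-pattern corrections on aromatic
  six-rings, applied once per unordered pair of substituent-bearing ring
  positions at ring distance 1, 2 or 3.  Whether *all* pairs or only
  adjacent ones should count is not standardized; counting all pairs is
  deterministic and matches common Benson practice, so that is what
  `annotate_substitution_corrections()` does.
* `radical 1`–`radical 4` — loaded and usable, but never auto-assigned:
  their intended semantics are unclear for a closed-shell vocabulary, and
  guessing would be worse than leaving them to the user.

# Group perception

`perceive_groups()` decomposes a molecular graph into the vocabulary above:
exactly one group per heavy atom, except carbonyl oxygens, which are
absorbed into their CO center.  Center typing is structural — CO for a
carbon double-bonded to oxygen, C_B for an aromatic carbon, C_D for other
sp² carbons, C for sp³, O/N for heteroatoms — and the ligand list is simply
the neighbors' center types plus the hydrogen count.  Aromaticity is taken
from the input graph's flags (or the SMILES reader's model); the package
deliberately performs no independent aromaticity perception, because
disagreeing with the reader would make decompositions irreproducible.

The library-level molecule contract is a JSON graph (atom/bond lists);
SMILES input is converted by Open Babel (via ChemmineOB) with explicit
hydrogens, whose MOL2 output preserves aromatic atom and bond types.  Every
perception run ends with an atom-conservation check:
`formula_from_groups(perceive_groups(mol))` must equal the molecular
formula, and this invariant is property-tested across a fixture set that
includes both DITA isomers (C25H12N2O10).

With zero corrections the two DITA isomers have *identical* group sums —
they contain the same groups in the same counts — so any predicted
difference between them must come from the o/m/p corrections.  Perception
reproduces this: both isomers yield the same base vector (3 acid CO, 3
hydroxyl O, 4 imide CO, 2 imide N, 7/9/2 aromatic carbons, 2 rsc) and
differ only in their correction counts (o/m/p = 3/3/3 for the 3,4-isomer
vs 2/5/2 for the 3,5-isomer, under the all-pairs rule).  The exact
correction assignment used in the original table's worked examples is not
public, so estimates for the DITAs themselves should be treated as
method-consistent rather than value-identical to published predictions.

# The regression pipeline

`fit_mlr()` solves ordinary least squares on the design
`[1 | group counts]`.  There is no regularization: the point of the method
is interpretable per-group values.  Rank-deficient designs (exactly
collinear groups happen in practice — see the shared value triples above)
are solved by the minimum-norm pseudoinverse solution with a warning naming
the aliased columns; predictions are unaffected, and the aliased
coefficients share the effect.  Metrics are R² = 1 − SSres/SStot, MAE and
RMSE; R² on zero-variance observations is an error rather than NaN.

`split_holdout()` draws `floor(0.7·n)` training rows uniformly without
replacement, deterministically for a given seed (default 42, always logged
in the refit table's provenance, and never touching the session RNG).  For
a 77-molecule dataset that is a 53/24 split.  All requested properties
share one split; each is fit independently, as separate metric blocks per
property imply.  ΔfG° can be fit directly (the default) or reconstructed
from the other two — both paths are supported because either protocol is
defensible.

**A structural identity worth knowing.** Elemental composition is an exact
linear function of group counts, so the element-entropy sum that converts
S° to ΔfS° lies in the design's column space.  Fitting S° and fitting ΔfS°
on the same design therefore yields *identical residuals* — identical MAE
and RMSE, but different R² (the two responses have different variances).
The test suite verifies this identity on synthetic data; it is a useful
internal-consistency check on any real dataset of this kind.

# The synthetic-data generator

`generate_thermo_dataset()` emulates the statistical structure of a
77-molecule acids-and-imides dataset without shipping it: sparse
nonnegative group counts (Poisson(λ = 0.6) truncated at 6 per cell, one
guaranteed occurrence of every group for identifiability), a linear
response from a truth table (default: the packaged one), and homoscedastic
Gaussian noise with σ = 5 (J mol⁻¹ K⁻¹ for S°, kJ mol⁻¹ for ΔfG°),
matching the ~5 order of the holdout residuals a fit of this kind attains.
ΔfS° observations are *derived* — the S° observation minus the
element-entropy sum of the formula implied by the counts — which preserves
the exact linear relation real data has.

What the generator does **not** emulate: chemically valid structures (it
draws feature vectors, not graphs), correlated group occurrences (real
functional groups co-occur; acids bring hydroxyls), heteroscedastic errors,
and systematic model error (real molecules violate additivity in ways
Gaussian noise does not).  Passing pipeline tests therefore demonstrate the
estimator's statistical correctness, not the chemical accuracy of group
additivity on new compound classes.

Default problem sizes in the tests — mostly 20–120 rows, with one 500-row
parameter-recovery case (coefficient RMSE < 1 J mol⁻¹ K⁻¹ at σ = 5) —
were chosen as the smallest sizes at which the statistical properties under
test are sharp.

# Numerical and edge-case choices

* **Rounding.** Comparisons against printed table values round half away
  from zero (`round_half_away()`), the convention of thermochemical tables;
  R's own `round()` rounds half to even.
* **Keq overflow.** Exponents beyond ±700 saturate to Inf/0 with a warning
  instead of silently returning Inf from `exp()`.
* **Uncertainties.** Combined standard uncertainties use root-sum-square
  throughout; species without a stated uncertainty contribute zero, which
  understates the total and is flagged in the function documentation.
* **The DITA heat-capacity T² coefficient.** The source polynomials print
  the T² coefficient of both DITA equations as "−0.0014×10⁻⁴", which is
  dimensionally out of line with the ~10⁻⁴ T² coefficients of the DABA
  equations and suspiciously identical across isomers.
  `builtin_cp_polynomials()` stores the literal value (−1.4×10⁻⁷) under
  `t2_variant = "printed"` — with a loud warning — and an annotated
  alternative reading (−1.4×10⁻³) under `"amended"`.  Nothing downstream
  depends on the choice.
* **Cp validity range.** 298.15–613.15 K, the calorimetric scan range of
  the source data, adopted as a documented convention; evaluation outside
  it warns rather than errors.
* **Reaction entropies from mixed sources.** When per-species ΔfS° values
  are not all available (true for the packaged condensation reactions,
  where the reagent entropies are not tabulated), `reaction_report()`
  accepts a literature ΔrS directly; the packaged reaction files carry
  theirs in a `drS_J_molK` field.

# Known limitations

* The vocabulary covers closed-shell C/H/N/O chemistry only — no sulfur,
  halogens, radicals, charges, or strain corrections beyond the imide
  `rsc`.
* Perception requires a kekulized-or-flagged aromatic model from the
  reader; exotic aromatic systems (fused heteroaromatics) are outside the
  tested envelope.
* The packaged table's `radical` rows and the exact o/m/p correction
  assignment for the DITAs are inherited ambiguities of the source table;
  both are surfaced to the user rather than resolved by guesswork.
* Temperature extrapolation of ΔfH/ΔfS (Kirchhoff integration) is out of
  scope; the Cp polynomials are provided for users who wish to do it with
  their own auxiliary data.

# A worked example

```{r}
# Hess's law: formation entropies of the two DITA isomers from their
# quantum-chemical absolute entropies
formation_entropy(836.9, "C25H12N2O10")
formation_entropy(846.0, "C25H12N2O10")

# chain a regression Gibbs energy with each entropy into an enthalpy
enthalpy_from_gibbs(-1017.9, -1306.7)

# group-additivity estimate for benzoic acid, perceived from SMILES
gv <- perceive_groups(parse_smiles("OC(=O)c1ccccc1"))
gv
gav_estimate(gv, property = "dfG")

# reaction thermochemistry of the packaged condensation
sp <- read_species_thermo(system.file("extdata", "species_dita.csv",
                                      package = "gavthermo"))
rx <- read_reaction(system.file("extdata", "reaction_34dita.json",
                                package = "gavthermo"))
str(reaction_report(rx, sp))
```
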