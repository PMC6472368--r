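---
title: "Models and methods behind seepcat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind seepcat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seepcat)
library(dplyr)
```

`seepcat` implements the interpretive computations used to argue that
anaerobic hydrocarbon degradation is feasible in cold, deep seabed
sediments: catabolic reaction energetics under in-situ conditions,
rule-based functional-potential calling from genome annotations, gas-origin
geochemistry, and metabolomics normalization. This vignette explains the
models, their assumptions, the tunable parameters, and the choices made
where the methods literature leaves the design open.

## Reaction energetics

### Data model and stoichiometric exactness

A reaction is a signed stoichiometric map over named species (reactants
negative, products positive). Tabulated catabolic reactions print short
decimal coefficients (12.25, 3.75, 0.5), and a balance check must
distinguish a true zero residual from floating-point drift, so coefficients
are parsed as exact rationals (integer numerator/denominator) and element
and charge residuals are accumulated in exact integer arithmetic over a
common denominator. `check_balance()` therefore reports `balanced = TRUE`
iff every residual is *exactly* zero, with no tolerance.

The bundled six-reaction set covers hydrogenogenic, acetogenic and
sulfate-coupled complete oxidation of hexadecane and benzoate. One bundled
reaction (R5, acetogenic benzoate oxidation) is element-unbalanced as
tabulated — it lacks the four waters that would close hydrogen and oxygen —
yet its tabulated energies match the tabulated coefficients. We therefore
compute energies for unbalanced reactions *as given*, with a warning,
rather than repairing them: reproducing the reference table takes
precedence, and the balance report makes the defect visible. The bundled R6
uses 3.75 as the sulfide coefficient (the value that closes sulfur and
charge); some printings show 3.755, which changes the standard energy by
less than 0.1 kJ.

### Formation-energy constants and back-derivation

Standard energies are stoichiometry-weighted sums of formation values,
ΔG° = Σᵢ νᵢ ΔGf°ᵢ, at the 298.15 K, 1 M reference state. The bundled
constants table (`seep_species()`) compiles standard aqueous values from
the usual microbiology/biogeochemistry compilations, with provenance noted
per row. Two constants are not available in those compilations and are
*back-derived* with `derive_formation_energy()`, which solves the one-unknown
linear equation against a tabulated reaction energy:

* hexadecane(aq) ΔGf° = +49.47 kJ/mol, from the acetogenic oxidation's
  tabulated +176.3 kJ — validated by predicting the independent
  sulfate-coupled oxidation to within 0.7 kJ of its tabulated −407.3 kJ;
* benzoate(aq) ΔHf° = −386.32 kJ/mol, from the complete oxidation's
  tabulated +29.4 kJ — validated by predicting the acetogenic reaction's
  ΔH° to within 1.1 kJ of its tabulated −1091.3 kJ.

A species lacking a needed constant raises an error naming the species;
values are never silently defaulted. The proton (and, were it present, the
electron) carries an explicit zero by the 1 M standard-state convention.

### The hydrogen standard-state convention

The hydrogenogenic hexadecane reaction's tabulated ΔG° (+1089.1 kJ) is
reproducible only if H₂ is treated as a *dissolved* species
(ΔGf° ≈ +17.6 kJ/mol, ΔHf° ≈ −4.2 kJ/mol); under the conventional gas
reference state (both zero) the value is 299 kJ lower. The constants table
therefore carries both `H2(g)` and `H2(aq)`, and the bundled reaction file
references the aqueous species, exposing the convention instead of hiding
it. The benzoate hydrogenogenic reaction (R4) is not reproducible under
*either* convention (computed +210.8 gas / +263.6 aqueous vs tabulated
+120.9); it is retained in the reaction set — its tabulated energies are
still valid inputs for the in-situ correction — but flagged as numerically
irreconcilable with any single constants set we tested.

### In-situ correction

Two corrections take a standard energy to deep-sea conditions:

* **Temperature** (Gibbs–Helmholtz at constant ΔH°):
  ΔG(T) = ΔG°·(T/T°) + ΔH°·(1 − T/T°). The constant-enthalpy assumption is
  standard over the 21 K span involved (298.15 → 277.15 K).
* **Activities** (reaction quotient): RT ln Q = RT Σᵢ νᵢ ln aᵢ, with
  R = 8.314 J mol⁻¹ K⁻¹. Activities are concentrations in mol/L (no
  ionic-strength correction — none is stated in the methods this package
  follows, and 2 mM bicarbonate is treated as an activity), 10^(−pH) for
  the proton, and 1 for water and pure liquids.

Default conditions (`deep_sea_conditions()`) are 4 °C, 300 atm, pH 8, 2 mM
bicarbonate, all other solutes at 1 M. **Pressure policy:** although the
pressure is recorded, no pressure term enters the correction by default.
The tabulated in-situ energies for the reactions that *are* reproducible
(R1, R2, R5: within 5.1, 0.6 and 1.6 kJ respectively) are matched by the
temperature and activity terms alone, indicating the reference calculation
applied no material pressure correction; an optional ideal-gas compression
term RT·ν_gas·ln(P) is available via `pressure_term = TRUE` for users who
want one. Sulfate and sulfide default to 1 M standard state; measured
porewater sulfate (tens of mM) can be supplied through `conditions()`. With
those defaults the tabulated in-situ values for the two sulfate-coupled
reactions (−653.3, −230.7 kJ) are *not* recovered (we compute −765.4,
−264.9); no conditions consistent with the footnote reproduce them, and
they are left as a documented discrepancy rather than absorbed by tuning.

### Feasibility windows

`feasibility_window()` evaluates the in-situ energy over the Cartesian
product of two log-spaced concentration grids (canonically acetate ×
hydrogen, the syntrophic currencies). Since ΔG is linear in the log of each
activity (slope νᵢRT), the zero contour is located by sign change along
each grid column with linear interpolation in log₁₀ concentration — exact
up to floating point for this model, which is why the toy-reaction test can
check the contour against the closed form [B]/[A] = exp(−ΔG_T/RT). The
headline property reproduced by the tests: with hydrogen at 1 µM and
acetate at 2.5 µM (the measured porewater ceilings), all three
standard-state-endergonic oxidations turn exergonic.

## Functional-potential calling

Hit filtering applies each database's cutoff triple inclusively
(e-value ≤, identity ≥, coverage ≥); inclusivity follows the convention of
the underlying search tools, and the boundary cases (e-value exactly
1e-18 with coverage exactly 0.40; e-value exactly 1e-20 with identity
exactly 30) are pinned by tests. Fields a database's rule does not mention
are not tested. A hit table carrying per-row database tags is judged
row-by-row, so a gene hitting two databases is evaluated independently
under each.

Pathway presence is called on *distinct gene family* counts — duplicate
hits to one enzyme never satisfy a multi-gene rule — with the thresholds
≥5 (Embden–Meyerhof–Parnas), ≥3 (beta-oxidation), ≥4 (Wood–Ljungdahl),
≥6 (TCA) and ≥1 for single-marker functions. The family → pathway
membership map ships as an editable TSV whose defaults follow standard
KEGG module definitions; these defaults are documented choices, not an
assertion of the exact lists any particular study used. Unknown pathways
fall back to the ≥1 rule with a warning and a `rule_defaulted` flag.

`chao1()` implements both the classic estimator S_obs + F1²/(2F2) — which
errors when F2 = 0, directing to the bias-corrected form — and the
always-defined bias-corrected form S_obs + F1(F1−1)/(2(F2+1)). The tests
cross-check it against the independent implementation in `vegan`.

## Gas geochemistry

Methane is approximated as ΣAlkane gas − C2+ alkanes (floored at zero with
a warning if measurements are inconsistent). The Bernard ratio C1/(C2+C3)
is scale-invariant and undefined when ethane + propane is zero (field
tables print NA there; the function raises). Origin classification demands
*joint* evidence: biogenic requires ratio > 1000 *and* δ¹³C < −60 ‰. The
thermogenic band (ratio < 100 and δ¹³C > −50 ‰) follows the conventional
Bernard-diagram limits; only the biogenic criterion is stated in the
methods this package follows, so the thermogenic band is a documented,
configurable extension. Conflicting evidence yields `mixed`; single-sided
or between-band evidence yields `indeterminate`; every call carries
machine-readable evidence strings. Measured ratios in the bundled site
table are treated as inputs, never recomputed from the bulk columns (the
itemized C2/C3 split needed to do so is not part of the table).

## Metabolomics normalization

Constant-sum normalization divides each sample column by its own total —
the standard control for varying total organic content across sediment
extracts — making columns unit-sum (within 1e-12, tested) and the
operation idempotent and scale-invariant. Log display uses log₁₀ with a
floor (default 1e-6) applied *after* normalization, because no zero-display
convention is stated for log-scale heatmaps; the floor is recorded in the
output metadata. Replicate summaries use the sample (n−1) standard
deviation for CVs; a missing compound in one replicate is treated as zero
intensity before normalization. "All observed metabolites" means all rows
of the input table — no pre-filtering.

## Synthetic data: what it emulates, and what it does not

The generators are pure functions of (parameters, seed); one global seed
fans out to fixed per-generator streams, so adding a generator never
perturbs existing outputs. Design choices:

* **Genome hits.** Planted families always pass their database's cutoffs;
  spurious hits fail them by at least an order of magnitude in e-value (or
  land well below the identity/coverage cutoffs), making truth recovery
  exact by construction. Planted counts straddle the rule thresholds
  (including the threshold-minus-one boundary) so both sides of every rule
  are exercised.
* **Gas profiles.** Biogenic and thermogenic draws sit strictly inside
  their classification bands; `mixed` draws combine a biogenic ratio with
  a thermogenic isotope, guaranteeing a conflict.
* **Metabolites.** Three sites × five technical replicates by default,
  matching the usual design; intensities are log-normal around planted
  per-site mean fractions with a specified CV
  (σ_log = sqrt(log(1 + CV²))).
* **ASV counts.** Multinomial draws from a geometric (or log-series) rank
  abundance model; default decay 0.93 gives the long right tail of rare
  taxa, under-sampled at realistic depths, that Chao1 is designed for.

Passing tests on these fixtures shows the *rules and arithmetic* are
implemented correctly; it does not show that real annotation pipelines
produce hits distributed like the generator's, that real gas regimes avoid
the indeterminate bands, or that real technical noise is log-normal. The
generators deliberately omit read-level sequence simulation, chimeras,
cross-database disagreement and batch effects.

## Problem sizes and numerical choices

The default test and acceptance runs use deliberately small problem sizes —
6 reactions, 10 synthetic genomes over a 47-family catalog, 30 gas sites,
40 compounds × 15 samples, 300–400 taxa at depths of 2000–5000 reads —
chosen so the full suite completes in well under a minute while every rule
boundary is still exercised. Energies are plain doubles in kJ;
stoichiometry is exact-rational; equality assertions on energies use
1e-9 kJ; unit-sum assertions use 1e-12. Reports are written atomically
(temp file + rename) with manifests that record input checksums,
parameters and seed but no timestamps, so identical configurations produce
byte-identical outputs.

## Known limitations

* No ionic-strength/activity-coefficient model, no equilibrium speciation,
  no Helgeson-style pressure equation of state: the in-situ correction is
  temperature + quotient (+ optional ideal-gas pressure term) only.
* The R4 standard energies and the sulfate-coupled in-situ values are
  carried as tabulated but are not derivable from the bundled constants
  under any convention tested (see above).
* Pathway membership defaults are KEGG-style lists, editable but not
  authoritative for any specific study.
* Chao1 is a lower-bound-style estimator; on strongly uneven communities
  it recovers only part of the unseen richness (the tests assert the
  directional property — closer to true richness than S_obs, averaged over
  seeds — not consistency).
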