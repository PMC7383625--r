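---
title: "Methods: cap hydrophobicity scoring, pocket surface areas, and acyl-transfer kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cap hydrophobicity scoring, pocket surface areas, and acyl-transfer kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acylscreen)
```

## The problem

Some serine hydrolases transfer acyl groups to organic nucleophiles faster
than to water, even in bulk aqueous solution. Within the family of bacterial
hormone-sensitive lipases (bHSLs), this promiscuous acyltransferase activity
tracks the hydrophobicity of the substrate-binding pocket, and most of that
pocket is formed by the variable N-terminal cap domain — a helix-turn-helix
of roughly 45 residues covering the conserved catalytic domain. That makes
the property predictable from sequence alone: sum a signed per-residue
hydrophobicity value over the first 45 residues and you have a score H that
ranks pocket hydrophobicity, and with it, acyltransferase potential.

`acylscreen` implements that scoring system together with the surrounding
workflow: screening homologue libraries for candidates, validating the score
against structure-derived hydrophobic pocket areas, and simulating the
kinetics that make the activity usable (and measurable) in practice.

## The scoring model

For a sequence $s$ and residue scale $w$, the cap score is

$$ H(s) = \sum_{i=1}^{45} w(s_i). $$

There is no weighting, normalization, or alignment: the cap is taken as the
first 45 residues of the sequence as provided. Design choices and their
rationale:

* **Scale.** The packaged table (`default_scale()`) is a signed
  fragmental-constant hydrophobicity scale attributed to Abraham & Leo,
  with hydrophobic residues positive (W = 2.56 down to C = 0.58) and
  polar/charged residues negative (K = -2.45, R = -2.42, ...). The sign
  convention is enforced by `validate_sign_convention()`: L, I, V, F, W, M
  must be strictly positive and D, E, K, R strictly negative. Histidine is
  deliberately unconstrained — its protonation state near assay pH makes
  either sign defensible. Published numeric variants of this scale differ in
  transcription; `calibrate()` exists precisely so a scale variant can be
  checked against trusted reference scores (tolerance 0.1, the printed
  precision of such scores) before being used for screening. The packaged
  transcription satisfies the sign convention and reproduces planted
  reference scores; users with access to the real reference enzyme
  sequences should run `calibrate()` against them before relying on
  absolute score values.
* **Window.** 45 residues, the structure-derived cap boundary of the
  family's reference enzymes. It is a parameter rather than a constant
  because the cap boundary may shift in distant homologues.
* **Initiator methionine.** Not stripped by default: database sequences are
  scored exactly as provided. `strip_initiator_met = TRUE` is available for
  construct sequences known to carry an artifactual start Met; a Met
  misplaced in or out of the window shifts H by only 1.10.
* **Unknown residues** (B, Z, X, U, O) are not in the scale. Single-sequence
  scoring errors on them (strictness when you care about one enzyme); batch
  screening scores them as 0 with a flag and a count (robustness over large
  public libraries, where X is common). An unknown residue therefore biases
  a batch score toward 0 by at most its true value — acceptable for ranking,
  flagged for inspection.

## Library screening

`run_screen()` chains length filter, deduplication, scoring, distribution
summary, and candidate selection; per-stage counts are conserved and echoed
into the outputs.

* **Length filter** default [250, 400] residues: the typical size of a bHSL
  catalytic domain plus cap (~300 aa). The bounds are explicit, editable
  parameters.
* **Deduplication** is exact-match only (full sequence by default, cap-window
  keying optionally), keeping the first occurrence. No identity-threshold
  clustering is attempted; "redundant" is read minimally.
* **Quantiles** use linear interpolation between order statistics
  (`stats::quantile` type 7) everywhere, fixed and documented: determinism
  across platforms matters more here than the particular convention.
* **Selection rule**: scores strictly above the library mean and at or below
  the upper quartile, `mean < H <= Q3`. The lower bound is open and the
  upper closed; both choices are this package's concretization of "above
  average but below the upper quartile". Scores above Q3 are excluded
  because heavily hydrophobic caps predict aggregation-prone, unstable
  proteins — the selection targets enzymes that are good *and* well-behaved.

## Pocket surface areas

The validation that H reflects real pocket hydrophobicity runs through
crystal structures: compute the solvent-accessible surface area (SASA) of
hydrophobic atoms lining the substrate pocket and correlate it with H across
enzymes. Every operational choice here is a documented, configurable
default, because the rank order and correlation across structures — not any
single area value — is the quantity of interest:

* **SASA algorithm**: Shrake–Rupley with a deterministic Fibonacci point
  lattice, 960 points per atom, probe radius 1.4 Å (water). At 960 points an
  isolated sphere's area is exact to well under 1%, and doubling the point
  count changes totals by <0.5% on test structures.
* **vdW radii**: C 1.70, N 1.55, O 1.52, S 1.80, H 1.20, P 1.80 Å (Bondi
  subset). Unknown elements are an error unless a default radius is given.
* **Hydrophobic atoms**: carbon and sulfur; nitrogen and oxygen are polar.
  Hydrophobic and polar SASA partition the total exactly.
* **Pocket definition**: all residues with at least one atom within 10 Å of
  the catalytic serine's side-chain oxygen (O$\gamma$). This is a
  distance-defined residue set, not a cavity-detection algorithm; pocket
  area is monotone non-decreasing in the cutoff. Triad residue numbers are
  supplied per structure (Ser146/Glu240/His270 for the Est8-family
  reference).
* **Preprocessing**: waters, heteroatoms and (by default) hydrogens are
  removed; the first chain of the asymmetric unit is used unless a chain is
  named; alternate locations resolve to the highest-occupancy conformer.

Because the six reference crystal structures are not redistributed with the
package, the shipped end-to-end validation runs on *synthetic stand-ins*
(`synthetic_reference_structures()`): idealized helical atom clusters whose
planted fraction of apolar side-chain atoms increases linearly with the
reference score. Recovering a strongly positive Pearson r (>= 0.9) from
those is a planted-truth test of the parsing → SASA → pocket → correlation
pipeline. It shows the machinery is sound; it does not re-measure the
published correlation on real structures, which additionally depends on the
surface method, radii, probe, pocket boundary and assembly choices listed
above. Users with the PDB files can run the identical pipeline on them via
`parse_structure()` + `define_pocket()` + `hydrophobic_pocket_area()` or the
`pocket-area` subcommand.

## Kinetics of acyl transfer in water

The simulator concretizes the kinetically controlled reaction scheme into a
minimal ODE system over donor D, free acceptor A, ester product P, and
released acid Ac (all mM), with enzyme activity E:

$$ v_D = k_{cat,D}\,E\,\frac{D}{K_D + D}, \qquad
   v_P = k_p\,E\,\frac{P}{K_P + P}, \qquad
   f_t = \frac{(k_t/k_h)\,A}{1 + (k_t/k_h)\,A} $$

$$ \dot D = -v_D, \quad
   \dot P = f_t v_D - (1 - f_t) v_P, \quad
   \dot A = -f_t v_D + (1 - f_t) v_P, \quad
   \dot{Ac} = (1 - f_t)(v_D + v_P) $$

The acyl-enzyme intermediate is not carried explicitly: $f_t$ is its
partition fraction toward transfer, with the water term absorbed into the
units of $k_t/k_h$ (per mM acceptor) — only the ratio is identifiable from
conversion data. Product turnover re-forms product with probability $f_t$
(futile) and hydrolyzes otherwise, so a fraction of $v_P$ cancels. Two exact
conservation laws follow: $D + P + Ac$ (acyl groups) and $A + P$ (acceptor
moiety) are constant.

Acidification is modelled as a buffer-capacity threshold, not pH chemistry:
E stays at $E_0$ while $Ac < B$, then decays as $\dot E = -k_{inact} E$.
The switch point is located exactly with a root-finding integrator
(`deSolve::lsodar`), after which integration continues with E as a state.
This reproduces the qualitative features that matter: a transient product
maximum whose height increases with $k_t/k_h$ and decreases with $k_p$;
zero product for a pure hydrolase ($k_t/k_h = 0$); and a frozen product
plateau after acid quench.

Numerical choices: adaptive `lsoda` with absolute/relative tolerances
1e-12/1e-10. These are tighter than a generic simulation would need because
the package treats the conservation laws as correctness checks at the 1e-9
relative level; a fixed-step RK4 integrator re-derived from the scheme
serves as the independent reference in the test suite. Default output grid:
2001 points; `transient_maximum()` reports the grid maximum and flags
whether a strict interior maximum exists.

No attempt is made to fit the ODE model to experimental time courses, and
the experimental conversions of specific enzymes (e.g. ~27% for a
mid-scoring esterase) are not predicted — no rate constants for them are
available; the simulator is a property test bed and exploration tool.

## The colorimetric assay model

The pNPA assay reads acyltransferase character from the acceleration of
*p*-nitrophenolate release when an acceptor alcohol is added: relative
activity (rate normalized to the no-acceptor rate) as a function of acceptor
concentration A. The phenomenological descriptor is

$$ \mathrm{rel}(A) = (1 + r_t A)\, e^{-A / K_i}, $$

with transfer gain $r_t$ (per mM) and a high-alcohol decay constant $K_i$
($K_i = \infty$ disables the decay, leaving a straight line). `rel(0) = 1`
exactly by the normalization. The exponential decay term is a descriptor for
classification, not a mechanistic inhibition model; substrate-inhibition
kinetics and the occasional biphasic rise seen for some enzymes at very high
alcohol concentrations are out of scope.

`fit_relative_activity()` fits on the **log scale**: assay noise is
multiplicative, so log residuals are homoscedastic and log-scale least
squares is the maximum-likelihood estimator; raw-scale fitting would
overweight the large-A points, where multiplicative noise is largest in
absolute terms, and inflate the variance of $\hat r_t$. Classification:

* **unstable** — the fitted curve peaks below the smallest tested nonzero
  concentration *and* has fallen below 0.9 at the largest tested
  concentration (activity lost already at low alcohol);
* **acyltransferase** — fitted $r_t > 0$ with one-sided $t > 2$ *and* the
  fitted curve rises at least 10% above baseline within the tested range
  (the 10% floor keeps a flat-but-noisy hydrolase curve from being called an
  acyltransferase on a spuriously significant slope);
* **hydrolase** — otherwise.

The 0.9 and 1.1 guards are deliberate margins against 2–5% assay noise;
both thresholds are package constants documented here.

## What the synthetic generators emulate — and what they do not

Every input type has a seeded generator (`gen_sequence_with_score`,
`gen_library`, `gen_toy_structure`, `gen_assay_curve`), each a pure function
of its arguments and seed:

* Sequence backgrounds are uniform over the 20 canonical residues; cap
  scores are planted by coordinate descent to within a stated tolerance.
  Real bHSL caps have family composition biases the generator does not
  mimic — tests need controlled scores, not biological realism.
* Library score targets are drawn from a normal distribution (default mean
  13.65, sd 8, matching the centre of large bHSL homologue libraries);
  duplicates and too-short records are planted at known fractions so filter
  and dedup stages can be verified against ground truth. Real libraries
  have heavier tails and correlated redundancy.
* Toy structures are idealized helical traces with planted apolar/polar
  side-chain compositions — good for exercising SASA geometry, pocket
  definition, and correlation recovery; they say nothing about real protein
  packing, and passing on them does not guarantee any particular area value
  on a crystal structure.
* Assay curves apply multiplicative lognormal noise to the exact model, with
  the A = 0 point pinned at 1 (as the normalization guarantees in the real
  assay).

Consequently, green tests demonstrate that the algorithms are correct and
internally consistent under controlled conditions. Claims about real
enzymes still require real sequences, structures, and assay data, fed
through the same functions.

## Problem sizes and degenerate inputs

The shipped test suite and acceptance script use: 1000-sequence brute-force
scoring checks, screening libraries up to 10 000 records, six 45-residue toy
structures at 960 SASA points, kinetic runs to 600 min on 2001-point grids,
and 20-seed assay-recovery batches — sizes chosen so the full suite runs in
well under a minute while leaving every statistical check comfortably
powered.

Degenerate inputs are contracts, not afterthoughts: empty libraries and
all-too-short libraries return empty results with diagnostics; an all-equal
score vector selects nothing (no score strictly exceeds the mean); a
zero-variance correlation input, an empty pocket, an assay curve without the
A = 0 reference or with fewer than 4 distinct concentrations are errors
with named causes.

## Known limitations

* The absolute H values depend on the exact numeric variant of the
  hydrophobicity scale; rankings are robust to small transcription
  differences, absolute comparisons across scales are not. `calibrate()`
  against trusted reference scores is the arbiter.
* The N-terminal window is positional, not alignment-based; in homologues
  with N-terminal extensions (signal peptides, tags) the window must be
  re-anchored by the user.
* Pocket area depends on probe, radii, cutoff and assembly choices; only
  comparisons made under one fixed parameter set are meaningful.
* The kinetic model lumps donor and product turnover into two Michaelis
  terms and ignores explicit pH, enzyme-acceptor saturation, and acyl-enzyme
  accumulation; it is built to reproduce qualitative regimes, not to fit
  rate constants.
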