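# acylscreen

Sequence-based screening for promiscuous acyltransferase activity in
bacterial hormone-sensitive lipases (bHSLs).

Most hydrolases use water as the nucleophile. A few transfer acyl groups to
organic nucleophiles *faster* than to water even in bulk aqueous solution —
promiscuous acyltransferases, prized in biocatalysis because they allow
(trans)esterification without organic solvents. In the bHSL family this
behaviour tracks the hydrophobicity of the substrate-binding pocket, and the
pocket is mostly formed by the variable N-terminal **cap domain** (~45
residues). That makes the property predictable from sequence alone.

The core statistic is the cap hydrophobicity score

    H(s) = Σ_{i=1..45} w(s_i)

where `w` is a signed per-residue hydrophobicity scale (hydrophobic residues
positive, polar/charged negative). High H predicts a hydrophobic pocket and
acyltransferase behaviour; candidates are selected from homologue libraries
by the quantile rule `mean < H ≤ Q3` — above the library average, but below
the upper quartile, because extreme scores predict aggregation-prone,
unstable proteins.

The package provides, for enzymology and enzyme-discovery labs:

* **Scoring** — `score_sequence()`, `score_batch()`, scale loading,
  sign-convention validation, and `calibrate()` against trusted reference
  scores (`default_scale()` ships a signed Abraham–Leo-type fragmental
  scale).
* **Library screening** — `run_screen()`: length filter, exact
  deduplication, scoring, type-7 quantile summary, candidate selection, with
  conserved per-stage counts and provenance-stamped TSV/JSON outputs.
* **Structural validation** — a Shrake–Rupley SASA engine, a
  distance-defined pocket around the catalytic serine Oγ, hydrophobic
  (carbon/sulfur) pocket surface areas from PDB files, and Pearson
  correlation of areas against scores.
* **Kinetics** — an ODE simulator of kinetically controlled acyl transfer in
  water (transfer/hydrolysis partition `k_t/k_h`, product re-hydrolysis
  `k_p`, acidification-driven inactivation) and a fitter/classifier for the
  colorimetric pNPA relative-activity assay.
* **Seeded generators** for every input type (sequences with planted cap
  scores, libraries, toy structures, assay curves), so the entire toolkit is
  testable without downloads.

## Worked example

```r
library(acylscreen)
scale <- default_scale()

# score one sequence (here: a generated sequence with a planted cap score)
est8_like <- gen_sequence_with_score(11.2, scale = scale, tol = 0.05, seed = 3)
score_sequence(est8_like, scale)
#> cap_score: synthH11.2  H = 11.18 (window 45)

# screen a 1000-record library (5% planted duplicates, 5% too-short records)
lib <- gen_library(1000, duplicate_fraction = 0.05, short_fraction = 0.05, seed = 42)
run_screen(lib, scale)
#> screen_result
#>   input: 1000 | length-dropped: 50 | duplicates: 50 | unscoreable: 0 | scored: 900 | selected: 226
#> score_distribution: n=900 mean=13.349 range=[-10.430, 39.600] Q1=8.300 Q2=13.370 Q3=18.727

# simulate a kinetically controlled acetylation (10-fold donor excess)
p <- kinetic_params(kt_over_kh = 0.15, k_cat_donor = 2, k_p = 1)
tc <- simulate_acyl_transfer(p, D0 = 200, A0 = 20, t_end = 600)
transient_maximum(tc)
#> $t_max            45.9
#> $P_max            18.7
#> $conversion_max   0.937
#> $interior_maximum TRUE

# fit a noisy pNPA assay curve and classify the enzyme
curve <- gen_assay_curve(r_t = 0.2, K_i = 500, noise_sd = 0.05, seed = 11)
fit_relative_activity(curve)
#> assay_fit: r_t = 0.1854 /mM (t = 20.79), K_i = 1320 mM -> acyltransferase (R^2 = 0.998)
```

Reading the numbers: the planted-score sequence scores H = 11.18 over its
45-residue cap. The screen drops 50 out-of-length records and 50 exact
duplicates, scores the remaining 900 (mean 13.3, Q3 18.7), and selects the
226 candidates with `mean < H ≤ Q3`. The simulated reaction shows the
hallmark of a promiscuous acyltransferase: the ester transiently reaches
93.7% conversion of the acceptor at t ≈ 46 min before product hydrolysis
takes over. The assay fit recovers the planted transfer gain (0.185 vs the
true 0.2 per mM under 5% noise) and classifies the curve as an
acyltransferase.

A command-line wrapper with `score`, `screen`, `pocket-area`, `correlate`,
`simulate`, `assay-fit` and `fixtures` subcommands ships in
`inst/cli/acylscreen` (see `?at_cli`), e.g.

```sh
Rscript inst/cli/acylscreen screen --fasta library.fa --min-len 250 --max-len 400 --out screen_out
Rscript inst/cli/acylscreen pocket-area --pdb est8.pdb --triad 146,240,270 --cutoff 10
```

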