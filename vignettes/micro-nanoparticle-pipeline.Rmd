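---
title: "Methods: ranking, binding and stability analysis of tea micro-nanoparticles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ranking, binding and stability analysis of tea micro-nanoparticles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mnptools)
```

This vignette is the package's account of its methods: the models, the
conventions behind every tunable parameter, what the synthetic-data generator
does and does not emulate, and the numerical corner cases. The running system
is a tea-infusion colloid: a crude microfiltered fraction (here labelled WTC)
and the micro-nanoparticle fraction (WTMP) isolated from it by
ultrafiltration and centrifugation, whose core is a serum-albumin-like
protein–pectin scaffold binding small phenolics (gallic acid) and caffeine.

## Ranking separation conditions by TOPSIS

Candidate isolation conditions form a full factorial of membrane
molecular-weight cut-off (kDa), centrifugation time (min) and centrifugal
force (×g); each is measured by dynamic light scattering on five criteria:
Z-average diameter (nm), count rate (kcps), polydispersity index,
zeta potential (mV) and conductivity. TOPSIS ranks the conditions by relative
closeness to an ideal condition:

1. decision matrix `X` (m conditions × n criteria), with the zeta column
   stored as |zeta| — only the magnitude of the electrostatic repulsion
   matters for stability;
2. vector normalisation `Z_ij = X_ij / sqrt(Σ_i X_ij²)`, which makes the
   ranking invariant to positive rescaling of any criterion (unit changes
   cannot reorder conditions);
3. weighting `U_ij = Z_ij w_j`, defaults `w = (0.15, 0.20, 0.25, 0.15,
   0.25)` in the order (z_ave, count_rate, pdi, zeta_abs, conductivity) —
   PDI and conductivity carry the most weight because dispersion uniformity
   and purification efficiency are the study's priorities;
4. ideal solutions per criterion *direction*: a benefit criterion
   (count rate, |zeta|) contributes its maximum to the positive ideal, a
   cost criterion (Z-average, PDI, conductivity) its minimum. The generic
   textbook statement of steps 3–4 ("A+ takes the maxima") presumes
   all-benefit criteria; the evaluation logic here explicitly favours
   *low* size, PDI and conductivity, so direction-aware ideals are the
   faithful reading and are what reproduces a sensible ranking;
5. Euclidean separations `d±_i` from both ideals;
6. closeness `C_i = d−_i/(d+_i + d−_i) ∈ [0, 1]`, ranked descending.

Numerical conventions, chosen for auditability:

* an all-zero criterion column cannot be normalised and is an error naming
  the criterion, not a silent drop;
* if every alternative is identical, `d+ = d− = 0`; `C` is then defined as
  0.5 (the continuity limit along `d+ = d−`) with a warning rather than an
  error, so degenerate screens still return;
* rank ties use the competition ("min") convention and are listed in the
  result, so a tie can never silently shuffle a ranking.

The published 30-condition ranking is shipped as `wtmp_ranking_table()`.
Its raw 30 × 5 decision matrix was only ever released as bar charts, so the
full ranking cannot be recomputed from public data; what *can* be checked —
and `validate_closeness_table()` checks — is the internal identity
`C = d−/(d+ + d−)` per row and the agreement of the printed rank with
descending closeness. The default tolerance 0.001 reflects the 4-decimal
rounding of the printed separations (the worst observed identity error is
about 4 × 10⁻⁴).

```{r topsis}
validate_closeness_table(wtmp_ranking_table())
```

## Fluorescence-quenching binding analysis

Titrating the protein–pectin complex with a quencher (gallic acid or
caffeine) reduces its intrinsic fluorescence. Two linearised models are
fitted by ordinary least squares:

* **Stern–Volmer**: `F0/F = 1 + K_SV [Q]`. The fit keeps a free intercept
  rather than forcing it through 1: on ideal data the intercept *is* 1, and
  a departure flags baseline drift or inner-filter absorption. No
  inner-filter correction is applied — a documented limitation, since none
  was applied in the source measurements this emulates.
* **Double-logarithmic**: `log10(F0/F − 1) = log10(K_a) + n log10[Q]`,
  with `K_a` the apparent binding constant and `n` the number of binding
  sites. Logarithms are base 10 throughout and concentrations are mol/L.
  Points with `F0/F − 1 ≤ 0` (no measurable quenching) or `[Q] = 0` fall
  outside the log domain; they are excluded, counted, and listed in the
  fit object — never dropped silently — and fewer than 3 usable points is
  an error.

Both fits report `r²` computed directly from residual and total sums of
squares (an exactly-fitted constant response counts as 1). Fitting is OLS on
the linearised form — the field's standard treatment — not nonlinear
weighted regression; at the noise levels of steady-state titrations the
difference is far below the reported precision.

```{r binding}
fit <- stern_volmer_fit(gen_titration(titration_design(noise_cv = 0),
                                      "stern_volmer", seed = 1))
coef(fit)
```

## MM/GBSA energy bookkeeping

The package consumes per-frame component energies (it does not run
molecular dynamics) and performs the endpoint accounting:
`ΔE_gas = ΔE_internal + ΔE_vdw + ΔE_ele`, `ΔG_solv = ΔG_GB + ΔG_SA`,
`ΔG_bind = ΔE_gas + ΔG_solv`. Conventions:

* `ΔE_internal` defaults to 0 — the single-trajectory convention in which
  bonded terms cancel between complex and separated species; the field
  exists so the full identity is representable.
* The nonpolar term is the linear surface-area model `ΔG_SA = γ·ΔSASA`
  with γ = 0.0072; the constant's conventional units are
  kcal·mol⁻¹·Å⁻² with ΔSASA in Å² (the convention is stated here because
  published uses often omit it).
* The entropic contribution −TΔS is excluded, as is usual for relative
  single-trajectory estimates.
* `binding_from_endpoints()` computes the standard difference
  `ΔG_complex − (ΔG_receptor + ΔG_ligand)`. Some write-ups typeset this
  formula with the parenthesis dropped, which read literally would *add*
  the ligand term; the implementation does not replicate that reading.
* `validate_decomposition_table()` checks published tables for additivity
  at a default tolerance of 0.015 kcal/mol, the worst-case discrepancy of
  2-decimal rounding (the shipped reference table `bsa_energy_table()` has
  rows off by 0.01 for exactly this reason).

## Two-group comparison

`welch_t_from_summary()` implements the unequal-variance t statistic with
Satterthwaite degrees of freedom, computable from (mean, SD, n) alone. The
choice of the Welch form over the pooled form is an *inference*: the
published composition p-values are reproduced from the printed summaries
only by the Welch form where group SDs differ (and the two coincide where
SDs and n are equal, e.g. the caffeine row, df = 4). Group size defaults to
the study's triplicates (n = 3). Two conventions cover the degenerate
corners: both SDs zero with equal means gives p = 1; both zero with unequal
means is an undefined statistic and errors rather than reporting p = 0.

```{r welch}
compare_composition_table(
  wtmp_composition_table()[, c("component", "group", "mean", "sd", "n")]
)[, c("component", "t_stat", "df", "p_two_sided")]
```

## Stability sweeps

Sweeps of Z-average (or count rate) across temperature, pH or storage days
are summarised by **both** the endpoint delta `|y_last − y_first|` and the
full range `max − min`: published "the size changed by X nm" statements do
not say which reading they use, so both are emitted side by side rather than
guessing (`range ≥ endpoint_delta` always, and both are invariant under
reversing the sweep, so heating and cooling ramps summarise identically).
`compare_sweeps()` flags the system with the smaller range as more stable
and reports exact ties as such; series on different grids are compared at
the metric level only — interpolation across grids is deliberately out of
scope.

## The synthetic-data generator

Every analysis stage has a generator producing inputs with exactly the
statistical structure that stage assumes, so the pipeline is testable
without instrument exports. All generators are pure functions of
(design, seed): one integer seed initialises a Mersenne-Twister stream per
call (the caller's RNG state is saved and restored), and identical calls
are bit-identical.

* **Condition tables** (`gen_condition_table()`): the default design is the
  study's 2 × 5 × 3 factorial (30/100 kDa × 2000–6000 g × 10/20/30 min).
  Criterion means are baseline + additive linear trends in the rescaled
  factor levels; the default trends make the 100 kDa membrane conditions
  better on every criterion, mirroring the qualitative outcome of the
  screen. Noise is additive Gaussian, the simplest defensible model for
  instrument read-outs; no measurement-error magnitudes were published for
  the original campaign, so the default SDs (10 nm on size, 8 kcps on
  count rate, 0.015 on PDI, 0.8 mV on zeta, 0.04 on conductivity) were
  chosen once as realistic DLS repeatability figures with enough power for
  ranking tests, and are not tuned thereafter. PDI is clipped to [0, 1]
  after noise and positive quantities are floored at 10⁻⁶ so the schema
  invariants hold by construction.
* **Titrations** (`gen_titration()`): intensities follow the chosen
  quenching law exactly, then receive multiplicative lognormal noise with
  unit mean and the design's coefficient of variation — multiplicative
  because fluorescence errors scale with signal and intensities must stay
  positive. F0 is returned noise-free. The default grid (1 × 10⁻⁸ to
  1 × 10⁻⁶ mol/L, 12 points) matches the study's concentration window.
* **Energy frames** (`gen_energy_frames()`): independent Gaussians per
  component per frame. Real trajectory energies are autocorrelated;
  independence is deliberate — the aggregation stage only assumes
  finite-variance means, and independent frames make the
  law-of-large-numbers checks exact.
* **Sweeps** (`gen_sweep()`) plant a known delta, linearly or as a
  threshold jump; **composition replicates** (`gen_composition()`) draw
  Gaussian triplicates from the summary parameters (SD = 0 yields constant
  replicates, the noiseless limit).

What passing tests on these generators shows — and does not show — about
real data: recovery of planted parameters demonstrates the *estimators* are
correct and unbiased under their assumed noise models; it cannot validate
the noise models themselves against a given instrument, nor does the
condition generator reproduce correlations between DLS criteria (size and
PDI co-vary in real retentates) or DLS autocorrelation physics. Those are
non-goals.

## Problem sizes and determinism

The shipped tests run the oracle comparison on 110 random matrices
(m ≤ 5, n ≤ 4), the Monte-Carlo recovery of K_SV on 100 seeds at 1 % noise,
and the frame-aggregation checks on 10,000 frames — sizes at which the
stochastic checks have comfortable margins while the whole suite runs in
seconds. The acceptance script reuses the same sizes; all of its randomness
derives from its `--seed` argument, and every deterministic quantity it
reports is identical across seeds.

## Known limitations

* The raw decision matrix behind the published 30-condition ranking is not
  public; only the closeness identity and rank order are validated.
* No inner-filter correction in the quenching fits; K_SV and K_a are
  apparent constants. Static vs dynamic quenching is not distinguished and
  the bimolecular rate constant is not computed (it needs the unquenched
  lifetime).
* MM/GBSA totals inherit all endpoint-method caveats (no entropy, GB
  solvent model); the package audits arithmetic, not physics.
* The conductivity criterion is treated as an opaque positive instrument
  unit; its absolute scale never matters because vector normalisation
  removes it.
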