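# mnptools

Analysis pipeline for isolating and characterising colloidal
micro-nanoparticle fractions from tea infusions — the sub-micron protein /
polysaccharide / polyphenol assemblies that an ultrafiltration–centrifugation
workflow recovers from a microfiltered infusion. The package is aimed at food
colloid and protein–ligand interaction labs that need the *computational* half
of such a study to be reproducible: screening separation conditions, comparing
fraction compositions, quantifying small-molecule binding to the protein
scaffold, auditing endpoint free-energy decompositions, and summarising
environmental stability — all from plain CSV tables, with a seeded synthetic
generator standing in for every instrument file.

## What it computes

**TOPSIS ranking of separation conditions.** Each condition (membrane
molecular-weight cut-off × centrifugation time × centrifugal force) is scored
on five dynamic light scattering criteria: Z-average diameter, count rate,
polydispersity index, |zeta potential| and conductivity. With decision matrix
`X` (m conditions × n criteria), weights `w`:

    Z_ij = X_ij / sqrt(Σ_i X_ij²)          (vector normalisation)
    U_ij = Z_ij · w_j                      (weighting)
    A+_j = best of column j, A−_j = worst  (direction-aware ideals)
    d±_i = sqrt(Σ_j (U_ij − A±_j)²)        (separations)
    C_i  = d−_i / (d+_i + d−_i)            (closeness, ranked descending)

Cost criteria (size, PDI, conductivity) take the column *minimum* as the
positive ideal; benefit criteria (count rate, |zeta|) the maximum. Default
weights are (0.15, 0.20, 0.25, 0.15, 0.25).

**Fluorescence-quenching binding analysis.** Stern–Volmer,
`F0/F = 1 + K_SV[Q]`, fitted by OLS with a free intercept (so inner-filter or
baseline artifacts are visible), and the double-logarithmic form
`log10(F0/F − 1) = log10(K_a) + n·log10[Q]`, giving the apparent binding
constant and number of binding sites; out-of-domain points are excluded and
reported.

**MM/GBSA bookkeeping.** `ΔE_gas = ΔE_internal + ΔE_vdw + ΔE_ele`,
`ΔG_solv = ΔG_GB + ΔG_SA`, `ΔG_bind = ΔE_gas + ΔG_solv`, with the nonpolar
term `ΔG_SA = γ·ΔSASA` (γ = 0.0072 kcal·mol⁻¹·Å⁻²) and the entropic term
deliberately absent. Per-frame component tables are aggregated to means ±
standard errors; published decomposition tables can be validated for
additivity.

**Group comparison and stability.** Welch t-tests (Satterthwaite df) from
summary statistics or raw replicates, and endpoint-delta / max–min-range
summaries of temperature, pH and storage sweeps, with a two-system
"which is more stable" comparison.

## Worked example

```r
library(mnptools)

tab <- gen_condition_table(condition_design(), seed = 42)  # 30-condition screen
fit <- run_topsis(tab)
print(fit, n = 3)
#> TOPSIS ranking of 30 alternatives over 5 criteria
#> criteria: z_ave (cost, w=0.15), count_rate (benefit, w=0.20), pdi (cost, w=0.25),
#>           zeta_abs (benefit, w=0.15), conductivity (cost, w=0.25)
#> top 3 alternatives:
#>  mwco_kda time_min force_g    d_pos   d_neg closeness rank
#>       100       10    6000 0.003099 0.03930    0.9269    1
#>       100       10    5000 0.003601 0.03751    0.9124    2
#>       100       20    6000 0.004519 0.03738    0.8921    3
```

The 100 kDa membrane conditions dominate the ranking: under the default
synthetic design they yield smaller, more uniform particles with less residual
conductivity, so their closeness coefficients (0 = at the negative ideal,
1 = at the positive ideal) are highest.

```r
ser <- gen_titration(titration_design(ksv_true = 7.6e6, noise_cv = 0.01),
                     "stern_volmer", seed = 42)
stern_volmer_fit(ser)
#> Stern-Volmer fit (12 points)
#>   Ksv       = 7465481 L/mol
#>   intercept = 1.02322 (1 under ideal quenching)
#>   R^2       = 0.999578
```

A 1 % noisy titration generated with K_SV = 7.6 × 10⁶ L/mol is recovered
within ~2 %; the intercept near 1 says the quenching is well described by the
ideal Stern–Volmer law.

```r
welch_t_from_summary(379, 14, 3, 412, 12, 3)
#> Welch two-sample t-test
#>   t = -3.0998  df = 3.9086  p (two-sided) = 0.03737
#>   group means: 379 vs 412

derive_totals(energy_components(vdw = -27.76, ele = -1.71, gb = 3.07, surf = -3.91))
#> MM/GBSA decomposition (kcal/mol):
#>      vdw      ele       gb     surf internal      gas     solv     bind
#>   -27.76    -1.71     3.07    -3.91     0.00   -29.47    -0.84   -30.31
#> (entropic term -TdS not included)
```

The protein concentrations of the two fractions differ at p ≈ 0.037, and the
gallic-acid decomposition sums to a binding free energy of −30.31 kcal/mol,
dominated by the van der Waals term.

A command-line wrapper is shipped at `inst/cli/mnptools`
(`mnptools simulate|topsis|binding|mmgbsa|compare|stability ...`); every run
writes a JSON manifest with input digests, seed and version next to its
output. The TOPSIS configuration file is JSON with keys `criteria_order`,
`weights`, `directions`, `rounding_tolerance`, `seed` (see
`inst/extdata/example_config.json`; omitted keys take the defaults above).

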