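# cpmgdisp

Analysis of backbone amide ¹⁵N CPMG relaxation-dispersion data for
proteins undergoing microsecond-to-millisecond two-site conformational
exchange, built around the study design used for the alpha subunit of
tryptophan synthase (αTS): four ligand states (apo *resting*, indole-bound,
G3P-bound, and the catalytically active *working* state), two static fields
(600 and 850 MHz ¹H), and a 40 ms constant-time CPMG period at 283 K.

The package covers the full path from peak intensities to biology:

1. **r2eff conversion** — constant-time intensities to effective relaxation
   rates, `R2eff = -(1/T_cp) log(I/I0)`, with a declared uncertainty policy.
2. **Two-site model** — the closed-form Carver–Richards expression plus an
   independent numerical Bloch–McConnell propagation oracle.
3. **Fitting** — per-residue screening (flat vs two-site by F-test),
   three-way classification (no exchange / two-site fittable /
   exchange-broadened), and global fits sharing `k_ex` and `p_A` across
   residues and fields, with covariance and bootstrap uncertainties.
4. **Synthetic data** — a generator reproducing the study conditions so every
   stage is testable without the (undeposited) raw data.
5. **State comparison** — set algebra of exchanging residues across ligand
   states and overlays against CHESCA (chemical-shift covariance) cluster
   lists consumed as input.
6. **Network mapping** — typed residue contact graphs (covalent / hydrogen
   bond / hydrophobic / within 6 Å) from PDB coordinates, and shortest paths
   connecting cluster residues through dynamic residues.

## The model

For exchange between a major state A and a minor state B
(`k_ex = k_AB + k_BA`, populations `p_A >= p_B`, ¹⁵N shift difference
Δω rad/s), the effective relaxation rate under a CPMG train with delay
τ_cp between successive 180° pulses (ν_CPMG = 1/(2 τ_cp)) is

    R2eff(1/τ_cp) = R2⁰ + 1/2 [ k_ex − (1/τ_cp) cosh⁻¹( D₊ cosh η₊ − D₋ cos η₋ ) ]

    D±  = 1/2 [ ±1 + (Ψ + 2Δω²) / (Ψ² + ζ²)^½ ]
    η±  = (τ_cp/√2) [ ±Ψ + (Ψ² + ζ²)^½ ]^½
    Ψ   = k_ex² − Δω²,   ζ = −2 Δω k_ex (p_A − p_B)

assuming equal exchange-free R2⁰ in both states. The η± prefactor follows
the convention in which τ_cp is the time between successive 180° pulses;
this is the variant that agrees with the numerical Bloch–McConnell
propagation (see the methods vignette for the alternatives and how they
were adjudicated). Forward and reverse rate constants derive exactly as
`k_AB = k_ex p_B`, `k_BA = k_ex p_A`.

## Worked example

Simulate one state at a known truth (`k_ex` = 286 s⁻¹, `p_A` = 94.2 %),
screen every residue, and fit the shared exchange parameters globally:

```r
library(cpmgdisp)

sc <- state_scenario("resting", k_ex = 286, p_a = 0.942, seed = 11,
                     roster = list(two_site = 101:110, broadened = integer(0),
                                   no_exchange = 201:204))
ds <- generate_state_dataset(sc)
pl <- fit_state_pipeline(ds$curves, "resting")

table(pl$screen$summary$classification)
#>       no_exchange two_site_fittable
#>                 4                10
print(pl$global)
#> Global two-site fit [resting]: 10 residues, 240 points
#>   k_ex = 305.3 +/- 14.2 s^-1   p_A = 94.5% (p_B = 5.5%)
#>   k_AB = 16.7 s^-1   k_BA = 288.6 s^-1   chi2_red = 0.96
```

All four quiet residues are recognised as flat, all ten exchanging residues
enter the global group, and the shared parameters come back within
uncertainty of the truth (`k_ex` ±14 s⁻¹ at 2 % noise on 10 residues;
`p_A` to 0.3 points). `chi2_red ≈ 1` says the declared noise model and the
fit weights are consistent.

## The analysis workflow

The `analysis/` scripts run the full study on synthetic data and write
their tables under `results/`:

| script | what it does |
| --- | --- |
| `analysis/01_simulate.R` | four-state synthetic suite + ground-truth manifest |
| `analysis/02_fit_dispersion.R` | per-residue classification, global fits, rate constants, audit of the published parameter table |
| `analysis/03_compare_states.R` | ligand-induced / repressed / shared exchange sets; CHESCA cluster overlays |
| `analysis/04_network_paths.R` | typed contact graph, cluster-connecting paths, sphere-rendering script |

Run them in order from the repository root (`Rscript analysis/01_simulate.R`
and so on). Step 2 prints, per state, the recovered global parameters next
to the simulation truth; step 3 prints the set-level changes (for example,
the loss of exchange in the phosphate-binding-site region when G3P binds,
and the growth of cluster-residue exchange under turnover).

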