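---
title: "Two-site exchange analysis of 15N CPMG relaxation dispersion: models, defaults and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-site exchange analysis of 15N CPMG relaxation dispersion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the relaxation model and its assumptions, the conventions and numerical
guards, the tunable parameters with their defaults and rationale, what
the synthetic-data generator does and does not emulate, and the design
choices made where the underlying analysis left the design open.

## The relaxation model

### Closed form

A backbone amide exchanging between a major conformation A and a minor
conformation B contributes to transverse relaxation an amount that
depends on how fast the CPMG pulse train refocuses the stochastic
precession-frequency jumps. With `k_ex = k_AB + k_BA`, populations
`p_A + p_B = 1`, and a ¹⁵N chemical-shift difference Δω (rad/s), the
closed-form (Carver–Richards) expression for the effective rate is

$$R_2^{\mathrm{eff}}(1/\tau_{cp}) = R_2^0 + \tfrac12\left[k_{ex} -
\frac{1}{\tau_{cp}}\cosh^{-1}\!\big(D_+\cosh\eta_+ - D_-\cos\eta_-\big)\right]$$

$$D_\pm = \tfrac12\left[\pm 1 + \frac{\Psi + 2\Delta\omega^2}
{\sqrt{\Psi^2+\zeta^2}}\right],\qquad
\eta_\pm = \frac{\tau_{cp}}{\sqrt2}\left[\pm\Psi +
\sqrt{\Psi^2+\zeta^2}\right]^{1/2}$$

with $\Psi = k_{ex}^2-\Delta\omega^2$ and
$\zeta = -2\Delta\omega\,k_{ex}(p_A-p_B)$.

Conventions, stated once and used everywhere:

* $\tau_{cp}$ is the time between successive 180° pulses and
  $\nu_{CPMG} = 1/(2\tau_{cp})$; a schedule point with pulsing frequency
  $\nu$ places $2\,T_{cp}\,\nu$ pulses in the constant-time period
  $T_{cp}$ (default 40 ms), which must be a whole number.
* Both states carry the same exchange-free rate $R_2^0$ (one value per
  residue per field). This is the assumption under which the closed form
  above holds.
* Fits report $p_A \ge 0.5$ and $\Delta\delta \ge 0$ ppm: the A/B
  labelling and the sign of the shift difference are not identifiable
  from dispersion data alone, so the conventions break the degeneracy.
* Shift differences are handled in ppm (field-independent) and converted
  per field by $\Delta\omega = \Delta\delta \cdot \nu_N \cdot 2\pi$ with
  $\nu_N = 0.10137\,\nu_H$ (the ¹⁵N/¹H gyromagnetic-ratio quotient).

**On the $\eta_\pm$ prefactor.** Published renderings of this equation
differ in the prefactor ($\tau_{cp}/2$, $\tau_{cp}/\sqrt2$,
$\tau_{cp}/(2\sqrt2)$) because they differ in what $\tau_{cp}$ means
(delay between pulses vs half of it). Only one combination is consistent
with the leading $1/\tau_{cp}$ factor and the definition of
$\tau_{cp}$ as the delay between pulses: $\tau_{cp}/\sqrt2$. Two checks
pin this down. Algebraically, at $\Delta\omega = 0$ the exchange term
must vanish, which happens only with the $\sqrt2$ form. Empirically, the
package's Bloch–McConnell propagation oracle (below) agrees with the
$\tau_{cp}/\sqrt2$ form to a median relative error of ~0.4% across the
sampled parameter space, while the $\tau_{cp}/2$ and $\tau_{cp}/(2\sqrt2)$
variants are off by large factors. The test suite asserts this
adjudication directly.

### Numerical guards

* The $\cosh^{-1}$ argument can fall below 1 by round-off as the
  exchange contribution vanishes; it is clamped to $\ge 1$.
* For $\eta_+ > 30$, $\cosh$ would eventually overflow; the evaluator
  switches to the asymptotic form
  $\cosh^{-1}(x) \to \eta_+ + \log D_+$, exact to better than $10^{-26}$
  at the switch point.
* Degenerate inputs ($k_{ex} = 0$, $p_B = 0$ or $\Delta\delta = 0$)
  return $R_2^0$ exactly rather than passing through 0/0 territory.

### The Bloch–McConnell oracle

`bloch_mcconnell_r2eff()` propagates the two-site transverse
magnetization through the full constant-time train: free evolution under
the exchange-coupled complex evolution matrix (closed-form 2×2 matrix
exponential), ideal instantaneous 180° pulses as complex conjugation,
starting magnetization at the equilibrium populations. The default
readout is the **major-state component**, because that is what the
experiment detects — the intensity of the observable A resonance; a
total-magnetization readout is available by argument, and the two agree
except in slow exchange where the minor-state line is resolved. Ideal
pulses (no finite width, no off-resonance effects) are a deliberate
simplification: relaxation-compensated sequences average these effects,
and simulating them is out of scope.

The oracle is used two ways: to validate the closed form, and (in "gold"
mode) to generate synthetic curves from a model that is *not* the one
being fitted.

### Where the closed form is imperfect, and what is quarantined

Mapping closed form against oracle over a systematic grid
($k_{ex}$ 50–3000 s⁻¹, $p_B$ 0.01–0.15, $\Delta\delta$ 0.5–4 ppm, both
fields, the default 12-point schedule) shows agreement within 5% or
0.5 s⁻¹ everywhere except one corner: the slowest pulsing points
(≤ 5 refocusing pulses in 40 ms, i.e. $\nu_{CPMG} \le 62.5$ Hz) combined
with minor populations above ~7–8%. There the neglected minor-state
contributions bias the closed form by up to ~12%. The oracle-equivalence
tests therefore quarantine points with ≤ 5 pulses **and** $p_B > 0.07$,
and the quarantine is documented here rather than silently widened.

A second, smaller imperfection: the closed form is *not* strictly
monotone in $\nu_{CPMG}$ in deep slow exchange
($k_{ex} < \Delta\omega/2$), where the $\cos\eta_-$ term produces
bounded oscillations (up to ~1 s⁻¹ on the mapped grid, ~0.2 s⁻¹ in a
typical slow-intermediate regime). Grid checks show zero upticks
whenever $k_{ex} \ge \Delta\omega/2$; the monotonicity tests assert
strictness in that regime and bounded oscillation plus net decay outside
it.

## From intensities to rates

Constant-time CPMG gives one intensity per pulsing frequency plus a
reference plane recorded without the CPMG block, so
$R_2^{\mathrm{eff}} = -(1/T_{cp})\log(I/I_0)$ — a single ratio per
point. Non-positive intensities (peaks broadened beyond detection) are
flagged as exchange-broadened records, not raised as numeric errors, and
feed the residue classification.

Measurement uncertainties are rarely archived with intensities, so the
default policy is: use the empirical spread of duplicate
pulsing-frequency measurements where present; otherwise
$\sigma(R_2^{\mathrm{eff}}) = \max(0.02\,R_2^{\mathrm{eff}},\,0.3)$
s⁻¹ — 2% relative with an absolute floor, typical CPMG repeatability.
Both numbers live in `disp_config()` and are overridable.

## Fitting design

### Per-residue screening

Each residue is fit twice: a **flat** null model (one level per field;
weighted means) and the **two-site** closed form (shared $k_{ex}$,
$p_B$, $\Delta\delta$ across fields; one $R_2^0$ per field). Model
selection is an F-test on the weighted residual sums with
$\Delta\mathrm{df}$ = number of extra parameters, $\alpha = 0.01$ by
default; AIC is reported alongside. Two-site fits use
Levenberg–Marquardt with box bounds
($k_{ex} \in [1, 10^5]$ s⁻¹, $p_B \in [0.001, 0.5]$,
$\Delta\delta \in [0, 10]$ ppm, $R_2^0 \in [0.1, 100]$ s⁻¹) from a
multi-start grid: $k_{ex} \in \{100, 300, 1000, 3000\}$ ×
$p_B \in \{0.02, 0.05, 0.10\}$, with the shift-difference start taken
from the observed dispersion amplitude through the fast-exchange
relation $R_{ex} \approx p_A p_B \Delta\omega^2 / k_{ex}$. The best
final chi-square wins; ties break to the smaller $k_{ex}$ (the more
conservative kinetic claim).

Classification is three-way, with declared thresholds (the published
criteria behind such classifications are qualitative, so these are
package choices): **two_site_fittable** needs the two-site model
selected, relative uncertainties on $k_{ex}$ and $\Delta\delta$ below
50%, and reduced chi-square below 3; otherwise a residue whose observed
dispersion amplitude exceeds 2 s⁻¹ (or whose peaks vanished in the
intensity data) is **broadened_unfittable**; the rest are
**no_exchange**. Residues with elevated exchange-free rates
($R_2^0 >$ mean + 1 SD per field per state) are flagged separately —
possible faster-than-CPMG-window motion.

### Why fit globally

At realistic noise, a single residue constrains $k_{ex}$ poorly: the
standard error is typically 30–100 s⁻¹, and in slow exchange the
likelihood has degenerate basins (a small-$k_{ex}$/large-$p_B$ solution
that fits a single curve as well as the truth). Residues reporting on
the same conformational event share $k_{ex}$ and $p_A$, and fitting
them jointly across both fields is what makes the kinetics precise —
the shared-parameter uncertainty drops to roughly the 10–20 s⁻¹ scale
for a 15-residue group at 2% noise, consistent with the uncertainties
the published analysis reports for its global fits.

### Global fit and group membership

The global model: one $k_{ex}$ and one $p_A$ for the group; one
$\Delta\delta$ per residue (shared across fields, in ppm); one $R_2^0$
per residue per field. Joint weighted least squares, multi-start on the
shared pair (the per-residue-median start plus the coarse grid; LM run
from the most promising starts). Uncertainties for the shared
parameters come from the covariance at the optimum scaled by reduced
chi-square, and optionally from a bootstrap that resamples *residues* —
the natural exchangeable unit; the two agree within a factor of ~2 on
well-conditioned synthetic data and both are reported.

Membership is decided in two passes. First, among individually
fittable residues, those whose $(k_{ex}, p_B)$ fall within a log₂
ellipse of the group median (semi-axes one log₂ unit — a factor of two
each way) seed the group. Second, residues with an F-test-selected
dispersion left outside the seed are refit with the shared
$(k_{ex}, p_B)$ held fixed (only their $\Delta\delta$ and $R_2^0$
free) and admitted when the conditional reduced chi-square is below 3;
the group is refit and the pass repeats until stable. The second pass
exists because the ellipse alone is blind to exactly the residues that
need global fitting — those whose unconstrained individual fits landed
in a degenerate basin. On synthetic data the two-pass policy recovers
the true group and matches the oracle-group estimator exactly;
membership by individual-fit similarity alone biased the recovered
$k_{ex}$ by ~+7% in the slow-exchange state.

## The synthetic-data generator

No raw dispersion data accompany the study this pipeline follows, so
the generator is a first-class module: it emulates the study conditions
so that every downstream stage is testable and recovery is scorable
against known truth.

What it emulates, and the defaults (all overridable in
`state_scenario()`):

* Four ligand states at the published global truths
  (`table1_parameters()`): $k_{ex}$ 286/287/146/273 s⁻¹ and $p_A$
  94.2/90.0/93.0/94.4% for resting / indole-bound / G3P-bound /
  working.
* Two fields (600, 850 MHz ¹H), $T_{cp}$ = 40 ms, 12 pulsing
  frequencies approximately log-spaced over 25–1000 Hz, all
  commensurate with the constant-time period (the experimental grid is
  not printed anywhere, so the grid is exposed as a parameter).
* Per-residue shift differences uniform in 1–3 ppm (typical amide ¹⁵N
  exchange shifts) and exchange-free rates uniform in 12–20 s⁻¹
  (reasonable for a ~29 kDa protein at 283 K); neither distribution is
  printed in the study, so both are declared choices.
* Gaussian noise on $R_2^{\mathrm{eff}}$ with
  $\sigma = \max(\mathrm{rel}\cdot R_2^{\mathrm{eff}}, \mathrm{floor})$,
  default 2% relative, no floor; the truth $\sigma$ is recorded in the
  table so fit weights are honest.
* Three residue classes per roster: quiet (flat), two-site (the global
  kinetics with moderate shifts), and **exchange-broadened** — same
  global kinetics but large shift differences (5–8 ppm), short
  effective T₂ ($R_2^0$ 28–40 s⁻¹) and 4× noisier points, emulating
  weak, broadened peaks whose curves resist reliable two-site fitting.
  On this recipe most broadened residues classify as
  broadened_unfittable and none as quiet, which is the property the
  tests assert.
* The four-state suite simulates every state over a common assignment
  universe (the union of all exchanging residues plus a quiet
  baseline), with rosters overlapping so ligand-induced, repressed and
  shared events exist by construction; the construction manifest is
  emitted for exact recovery scoring.

The default forward model is the closed form ("fast mode"), with the
Bloch–McConnell propagation available as `mode = "bloch_mcconnell"`
("gold"). The default is deliberate: parameter-recovery tests measure
estimator behaviour and should not conflate it with closed-form model
error, which is characterised separately by the oracle-equivalence
sweep.

What the generator does **not** emulate — and therefore what passing
recovery tests do and do not show: no spectra, peak overlap or
assignment ambiguity; no off-resonance or finite-pulse artefacts; no
field drift or temperature instability; noise is independent Gaussian
on rates, whereas real uncertainty enters through intensities and is
heavier-tailed. Recovery within the published uncertainty bands on this
synthetic data demonstrates that the estimator is unbiased and
correctly weighted under the declared model; it does not certify
robustness to experimental artefacts, and per-residue experimental
results (which residues disperse in which state) are not reproducible
without the raw data.

## State comparison

"Exchanging" pools the fittable and broadened classes — both report
motion; they differ in whether parameters could be extracted (a flag
restricts to fittable only). Comparisons run over the common observable
universe of the pair: residues assigned in only one state are listed
separately rather than counted, because absence of an assignment is not
evidence of absent motion. Partition identities
(|reference-only| + |shared| = |reference exchanging on the common
universe|; categories disjoint and exhaustive) are asserted on every
call, not just in tests. Cluster overlays partition
cluster ∪ exchanging into exchange-only / cluster-only / both, the
three display categories of the figure convention. CHESCA cluster
membership is consumed as a residue list; re-deriving it from chemical
shifts is out of scope.

## Network mapping

The contact rules are geometric and declared, because the underlying
figure legend gives only qualitative labels: covalent iff sequence
neighbours in the same chain; hydrogen bond iff any N/O–N/O heavy-atom
pair ≤ 3.5 Å (no angle term); hydrophobic iff both residues in
{A, V, L, I, M, F, W, P, Y} with a side-chain carbon pair ≤ 4.5 Å;
proximal iff any heavy-atom pair ≤ 6.0 Å and no stronger label applies.
The "within at least 6 Å" phrasing of the source convention is
internally contradictory and is read as "within 6 Å". Structures load
with fixed policies: first model by default, heteroatoms/waters/
hydrogens excluded, highest-occupancy alternate location kept. Mapping
between construct numbering and a crystal structure from a homologous
organism is the user's responsibility via an explicit residue map — no
automatic alignment is attempted.

Path tracing finds, for each pair of cluster residues, the shortest
path(s) whose intermediate nodes are all dynamic or cluster residues,
up to 6 edges by default; unreachable pairs are reported, not raised.
Pair classification uses a bounding-sphere spatial prefilter that is
exact for these cutoffs (verified against brute force in the tests).

## Problem sizes used for validation

Chosen to characterise the estimators well while keeping the default
validation run compact: 15 two-site residues per state for recovery
runs (the published group sizes are not printed; 15 is a declared
choice); 20 seeded replicate datasets per state for the recovery
invariants (median relative error of global $k_{ex}$ ≤ 10%, $p_B$
≤ 20%); 200 random parameter draws × 12 schedule points for the
oracle-equivalence sweep; bootstrap with 25 residue resamples where
bootstrap uncertainties are exercised.

## Known limitations

* Two-site exchange only; no three-site models, no off-resonance
  R₁ρ, no temperature dependence or Arrhenius/van't Hoff analysis.
* Equal $R_2^0$ in both exchanging states, in the model and the oracle.
* Whether published fits shared $R_2^0$ across fields is not stated;
  here $R_2^0$ is always per field.
* The closed form's slow-pulsing/large-$p_B$ corner and slow-exchange
  oscillations are documented above; fits in those regimes lean on the
  better-behaved schedule points.
* Fitted shift differences are not compared against external
  chemical-shift databases or previously characterised excited states.
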