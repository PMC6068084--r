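---
title: "Models and methods behind fabkin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind fabkin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fabkin)
```

fabkin analyses surface plasmon resonance (SPR) experiments on an
antibody Fab and a panel of framework-region charge mutants: it fits
binding kinetics, derives equilibrium and transition-state
thermodynamics from their temperature dependence, extracts melting
temperatures from calorimetric thermograms, and does the electrostatic
bookkeeping (net charge, isoelectric point) of the mutated light
chains. This vignette explains the models, the defaults, and the
choices made where the design was open.

## The 1:1 Langmuir binding model

All kinetic analysis assumes the reversible bimolecular reaction
A + B &#8652; AB with a single pair of rate constants. With analyte at
constant concentration $C$ flowing over a surface of capacity
$R_\max$ (in resonance units, RU), the bound response $R(t)$ obeys

$$\frac{dR}{dt} = k_{on} C (R_\max - R) - k_{off} R.$$

During association (starting from a regenerated surface, $R = 0$) this
integrates to $R(t) = R_{eq}(1 - e^{-k_{obs} t})$ with
$k_{obs} = k_{on} C + k_{off}$ and
$R_{eq} = R_\max C / (C + K_d)$, $K_d = k_{off}/k_{on}$; after the
injection stops the complex decays as $R(t) = R_0 e^{-k_{off} t}$.
`simulate_association()`, `simulate_dissociation()` and
`simulate_sensorgram()` implement these closed forms;
`simulate_ode()` integrates the rate equation numerically
(`deSolve::lsoda`, both tolerances $10^{-12}$, each injection phase
integrated separately so the concentration step is never smoothed
over) and serves as an independent oracle — the test suite requires
agreement within $10^{-8} R_\max$.

Deliberate simplifications, matching how such data are routinely
fitted: no mass-transport limitation (no two-compartment model), no
bulk refractive-index jumps or baseline drift, complete regeneration
between cycles, and i.i.d. homoscedastic Gaussian noise in RU — the
simplest model consistent with the residual behaviour of a
well-maintained instrument. Fits of real sensorgrams that violate
these assumptions (mass-transport-limited designs, drifting
baselines) are outside what the package validates.

## Global fitting

`global_fit()` estimates one shared $(k_{on}, k_{off}, R_\max)$
across a whole concentration series by Levenberg–Marquardt least
squares (`minpack.lm::nls.lm`). Choices that matter:

* **Log-scale parameters.** The optimiser works on
  $\log_{10} k_{on}, \log_{10} k_{off}, \log_{10} R_\max$, which
  enforces positivity and conditions a problem whose rates span
  decades; intermediate steps are clamped to $[-30, 30]$ so no
  overflow can occur mid-iteration.
* **Deterministic starts.** $k_{off}$ from a log-linear regression of
  the dissociation tail; $k_{on}$ from regressing per-trace $k_{obs}$
  estimates on concentration; $R_\max$ as 1.2 times the largest
  observed response. No random restarts, so fits are reproducible and
  order-invariant.
* **Convergence.** Relative-RSS tolerance $10^{-10}$, at most 500
  iterations; non-convergence sets a flag rather than failing
  silently.
* **Uncertainty.** Standard errors come from the Gauss–Newton
  covariance $\hat\sigma^2 (J^\top J)^{-1}$ on the log scale, mapped
  to the natural scale by the delta method — the usual "mean ± SE"
  reporting without bootstrap cost. The SE of the derived $K_d$ uses
  the full covariance of the two log-rates.
* **Identifiability guard.** When
  $k_{off} \times (\text{dissociation duration}) < 10^{-3}$ the tail
  decays by less than 0.1% and $k_{off}$ is flagged as poorly
  determined (a warning, not an error). This matters in practice: a
  $1.5\times10^{-5}\,\mathrm{s^{-1}}$ dissociator needs an hour-long
  wash, not the 600 s that suffices at
  $5\times10^{-4}\,\mathrm{s^{-1}}$, which is why the bundled
  analysis campaign monitors dissociation for 3600 s.

Blank referencing (`blank_subtract()`) subtracts a blank-cell trace
point-by-point and demands identical time grids — silent
interpolation can hide instrument artefacts, so a mismatch is an
error.

## Equilibrium thermodynamics

The standard-state Gibbs energy of binding is
$\Delta G = R T \ln K_d$ ($K_d$ in mol/l). Its temperature dependence
under a constant heat-capacity change $\Delta C_p$ is

$$\Delta G(T) = \Delta H - T \Delta S
  + \Delta C_p (T - 293.15) - \Delta C_p T \ln(T / 293.15),$$

with $\Delta H$ and $\Delta S$ defined at the 293.15 K reference. The
reference temperature is hard-fixed: making it configurable would
silently re-parameterise fitted enthalpies and entropies and break
comparability across variants. `vant_hoff_fit()` fits this curve to
$(T, \Delta G)$ points by unweighted least squares. Although the
model is nonlinear in $T$, it is *linear* in
$(\Delta H, \Delta S, \Delta C_p)$, so the solution is computed
exactly by a linear solve — no iteration, no starting values, no
convergence failures. Weighting by the $\Delta G$ standard errors
would be defensible but is not applied; with five temperatures and
three parameters the fit is near-interpolating and weights change
little. At least three distinct temperatures are required (two when
$\Delta C_p$ is constrained to zero).

Internally all energies are J/mol; report layers print kJ/mol.

## Transition-state analysis

The temperature dependence of the association rate follows the Eyring
approximation

$$\ln(k_{on}/T) = -\frac{\Delta H^\ddagger}{R T}
  + \frac{\Delta S^\ddagger}{R} + \ln\frac{k_B}{h}.$$

`eyring_fit()` performs ordinary least squares of $\ln(k_{on}/T)$ on
$1/T$ — the classical Eyring plot — rather than nonlinear fitting of
$k_{on}(T)$ directly; on model-generated data the two coincide, and
the linearised form is what the activation parameters are defined
through. The absolute $\Delta S^\ddagger$ carries the usual caveat
that the $k_B T/h$ prefactor assumes a transmission coefficient of
one; differences between variants are the meaningful quantity.

`classify_signature()` labels contributions by their sign on the
energy scale: enthalpy favorable iff $\Delta H < 0$, entropy
favorable iff $-T\Delta S < 0$. Magnitudes below 0.1 kJ/mol are
"neutral" — well below anything resolvable from a five-temperature
van't Hoff analysis, so the band only catches genuinely degenerate
inputs.

## Melting temperatures from DSC

`generate_dsc_thermogram()` simulates a two-state excess
heat-capacity curve,
$C_p^{ex}(T) = \frac{\Delta H_{unf}^2}{R T^2}\frac{K}{(1+K)^2}$ with
$K = \exp[-(\Delta H_{unf}/R)(1/T - 1/T_m)]$, on a 30–90 °C grid at
0.1 °C. `tm_from_thermogram()` subtracts a linear baseline
interpolated between the pre- and post-transition plateaus (mean of
the first/last five points) and reports the peak position, refined by
a three-point parabola. The $1/T^2$ prefactor shifts the true maximum
slightly below $T_m$ — about 0.05 °C at the default
$\Delta H_{unf} = 500$ kJ/mol, a typical Fab unfolding enthalpy —
which is why extraction is validated to ±0.1 °C rather than exactly.
A peak on the grid boundary yields a warning flag instead of a
refined value; a flat curve is a "no peak" error.

## Net charge and isoelectric point

`net_charge()` uses the Henderson–Hasselbalch approximation: every
ionizable group is independent with a model-compound pKa, contributing
$+1/(1+10^{pH-pK_a})$ (basic: Arg, Lys, His, N-terminus) or
$-1/(1+10^{pK_a-pH})$ (acidic: Asp, Glu, Cys, Tyr, C-terminus). The
default pKa set is EMBOSS's; a Lehninger-style set is included because
charge *orderings* across a mutant panel should not depend on the
table, and the tests assert exactly that. No structural pKa shifts and
no disulfide exclusion are applied — for mature insulin, whose six
cysteines are all disulfide-bonded, the naive sum therefore
over-counts slightly, which is part of why its computed net charge at
pH 7.4 (≈ −2.3 e) is checked only to ±1 of the nominal −3 e. The pI
is found by bisection of the strictly decreasing charge curve on
pH [0.1, 13.9], to |charge| < 10⁻⁶.

Mutation positions are plain 1-based sequential indices
("S63R" = 63rd residue); antibody renumbering schemes are out of
scope. The bundled wild-type VL (`vl_wildtype()`) is a **synthetic**
107-residue kappa-like domain with serines at positions 63, 65, 67,
70 and 72 — the real antibody's sequence is not publicly
machine-readable — so charge *differences* between mutants are exact
by construction while absolute charges and pI values are illustrative
only.

## The synthetic-experiment generator

`consistent_ground_truth()` ties the three models together: given
$(\Delta H, \Delta S, \Delta C_p)$ and
$(\Delta H^\ddagger, \Delta S^\ddagger)$ it derives
$k_{on}(T)$ from the Eyring relation, $K_d(T)$ from the van't Hoff
curve, and $k_{off}(T) = k_{on}(T) K_d(T)$ — so the thermodynamic
cycle closes identically at every temperature, and a correct pipeline
must recover every generating parameter. `generate_experiment()`
simulates the full campaign: per (temperature, concentration)
sensorgrams plus a blank per temperature, written with a YAML
manifest that records the truth.

Default study conditions: five temperatures 283.15–303.15 K in 5 K
steps; concentrations 1.25, 2.5, 5 and 10 nM (a two-fold ladder
around the 5 nM working concentration typical for sub-nanomolar
Fabs); 120 s association, 600 s dissociation at 1 Hz; $R_\max$ =
100 RU held constant across temperatures (real immobilisation density
varies somewhat between chip dockings; holding it constant isolates
the kinetics). Noise, when enabled, is 0.5–1 RU — the scale of
short-term noise on a research-grade instrument. Seeds are explicit
function arguments throughout; no global random state is consumed,
and the caller's RNG state is restored after each simulation.

The variant presets (`variant_truths()`) anchor $k_{on}$ and $K_d$ at
298.15 K to the published 25 °C rate constants of the six-variant
panel, and encode the observed signature *patterns* — entropy-driven
binding against unfavorable enthalpy for the wild type and the acidic
mutants, jointly favorable enthalpy and entropy for the basic
mutants, favorable activation enthalpy for R5 versus strongly
unfavorable for K5. The *magnitudes* of $\Delta H$, $\Delta C_p$ and
$\Delta H^\ddagger$ in these presets are package choices within
typical protein-interaction ranges: the corresponding measured values
were only ever shown graphically, so no numeric oracle exists and the
presets are never used as one.

What the generator does **not** emulate: mass-transport limitation,
injection artefacts and bulk jumps, baseline drift, temperature
miscalibration, or inter-cycle surface decay. Recovery tests on this
synthetic data therefore validate the estimators and their
composition — not robustness to instrument pathology.

## Problem sizes and numerical checks

The test-suite and acceptance computations use the default campaign
(5 temperatures × 4 concentrations × 721 points), 100 replicate
designs for noisy-recovery statistics, and 20 random parameter draws
for each round-trip property; the bundled analysis scripts run the
same campaign with a 3600 s dissociation so that the slowest
off-rate in the panel ($1.46\times10^{-5}\,\mathrm{s^{-1}}$) decays
measurably. These sizes make every fit deeply over-determined while
the full suite runs in seconds. Noiseless recovery is validated to
relative error $10^{-6}$ (global fit) and $10^{-4}$ (full pipeline);
the generator's cycle closure to $10^{-9}$; these are numerical
tolerances on exact identities, not statistical bands.

## Known limitations

* Only the 1:1 model: no bivalent, heterogeneous-ligand or
  two-compartment fitting.
* Equivalence with proprietary instrument-vendor fitting software
  cannot be asserted (its weighting and SE definitions are not
  public); what is validated is parameter recovery on synthetic data.
* The van't Hoff and Eyring fits are unweighted; with strongly
  heteroscedastic $\Delta G(T)$ uncertainties a weighted fit would
  differ.
* Absolute net charges and pI values inherit all limitations of the
  Henderson–Hasselbalch approximation; only differences and orderings
  across mutants are robust.
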