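---
title: "A dynamic model of kinase-inhibitor resistance: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A dynamic model of kinase-inhibitor resistance: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ablresist)
```

## The problem

Chronic myeloid leukaemia is driven by a constitutively active Abl1 kinase
and is treated with ATP-competitive Abl1 inhibitors (imatinib, ponatinib,
dasatinib).  Point mutations in the kinase domain blunt inhibition, and the
standard clinical heuristic for choosing a follow-up drug — the fold change
in IC50 of the mutant relative to wild type — answers the wrong question:
it says which mutations a drug handles best, not which drug handles a given
mutation best.  `ablresist` implements a dynamic alternative: simulate the
enzyme's product formation rate under realistic, fluctuating drug exposure
and quantify resistance as the *inhibitory reduction prowess* (IRP), the
percentage by which treatment lowers the product formation rate at the
steady-state inter-dose midpoint.

## Model structure

### States and transitions

The enzyme is reduced to four states: free inactive `E_I`, free active
`E_A`, active bound to substrate and ATP `E_AS`, and inhibitor-bound
(`E_IR` for imatinib/ponatinib, which bind only the inactive conformation;
`E_AR` for dasatinib, which binds only the active conformation — so only
one bound state exists per simulation).  Substrate binds only the active
conformation, and inhibitor and substrate binding are mutually exclusive.
The concentrations obey linear rate equations
`d[E_x]/dt = -[E_x] sum_y k_{x->y} + sum_y [E_y] k_{y->x}`,
assembled by `rate_matrix()` with transitions

* `E_I <-> E_A` at `ktransI` / `ktransA` (conformational switch),
* `E_A -> E_AS` at `konS [S]`, `E_AS -> E_A` at `koffS + kcat`
  (catalysis releases product and returns free active enzyme; `[S]` is held
  at 10 uM, i.e. perfect substrate replenishment, so substrate is not a
  dynamic species),
* inhibitor binding on `E_I` or `E_A` at `konR [R](t)`, unbinding at
  `koffR`.

Every column of the generator sums to zero, so total enzyme (1 uM by
default) is conserved exactly by construction; the integrators preserve it
to better than one part in 10^6 over ten simulated days.  The product
formation rate is `kcat [E_AS](t)`.

### From measured quantities to rate constants

All microscopic constants are derived from measurable inputs, shipped as
plain-text tables with the package:

* **Inhibitor off-rate.**  `koffR = 1/tR` from the measured wild-type
  residence time.  The shipped drug table carries both the published
  residence times and the published off-rates; for dasatinib the two are
  inconsistent in the source data (249 min vs 0.00233 min^-1), and the
  derivation uses the published off-rate, on which all downstream published
  rate tables are built.  The discrepancy is recorded in the packaged
  errata table.
* **Dissociation constant from IC50.**  Equating the quasi-equilibrium
  rate at `[R] = IC50` with half the untreated rate gives
  `RD = IC50/(w+1)` for inactive-state binders and `RD = IC50 f/(w+1)` for
  active-state binders, where `w = f (1 + S/KM)` (`uninhibited_weight()`)
  and `f` is the Boltzmann factor of the active-inactive free-energy gap.
* **Thermodynamic factor.**  Two conventions are provided.  The default,
  `effective_unity`, sets `f = 1` for every variant: the wild-type gap
  (about -1 kcal/mol) gives a factor of order one, mutational shifts are
  within +-2.2 kcal/mol, and — decisively — the published derived-constant
  tables are reproduced cell by cell only under `f = 1`.  The
  `per_mole_RT` convention evaluates `exp(-(dG_WT + ddG)/(R T))` and is
  intended for sensitivity analysis; the free-energy shifts `ddG`
  (consumed as constants from free-energy-perturbation simulations) enter
  the default model only through this switch and are otherwise inert.
* **Substrate rates.**  `KM = (kcat + koffS)/konS` is split by fitness
  rules: wild type `koffS = kcat/2`; mutants `koffS = 2 kcat` (hence
  `konS = 3 kcat/KM`) unless that on-rate would fall below the wild-type
  value, in which case `konS = konS_WT` and `koffS = KM konS_WT - kcat`.
  Both branches satisfy the Michaelis relation exactly by construction.
* **Cross-variant inheritance of binding rates.**  Inactive-state binders
  keep the wild-type `koffR` for all mutants (`konR = koffR/RD`);
  the active-state binder keeps the wild-type `konR` except for ATP-site
  mutants (T315I, T315M — a data flag, not a name rule), whose `konR`
  is scaled by the mutant/wild-type `konS` ratio (`koffR = konR RD`).
* **Conformational rates.**  `ktransA = ktransI = 60 min^-1` for all
  variants, 55 min^-1 for G250E (its larger inactive-state stabilisation).

Two documented misprints in the published derived-constant table are
handled by recomputation, never by transcription: one dissociation-constant
cell is a decimal shift (12021 for 1202.1), and the on-rate columns of the
two inactive-state binders are transposed.  The fixture loader ships the
printed values verbatim and applies a machine-readable erratum overlay;
`derive_parameter_table()` reproduces every corrected cell within printed
rounding, and every derived triple satisfies `RD * konR = koffR` to
machine precision.

### Pharmacokinetics

Plasma concentration follows a one-compartment model with first-order
absorption and elimination under daily oral dosing:
`C(t) = Gamma (e^{-ke t} sum_j eps^j - e^{-ka t} sum_j alpha^j)` over the
doses taken so far, with `Gamma = F D ka/(Vd (ka - ke))`,
`alpha = e^{ka tau}`, `eps = e^{ke tau}`, `tau` = 24 h, and `F = 1` for
all three drugs.  Numerically the sums are always evaluated per dose as
`exp(-k t + j log alpha)`; `alpha` reaches 1.37e18 for dasatinib and its
ninth power overflows double precision, while the per-dose exponents never
leave a safe range.  A superposition oracle (the literal formula with
explicit powers, on horizons where it is representable) agrees with the
implementation to 1e-9 relative across randomised inputs.

Two constant modes exist.  `printed` (the simulation default) takes
`Gamma`, `alpha`, `eps` verbatim from the published table; `derived`
recomputes them from the raw inputs.  The published imatinib `Gamma`
(2112.46 nM) is not reproduced by the formula with the listed volume of
distribution (435 L gives 1942.6 nM; 400 L would match), so the two modes
genuinely differ for imatinib; `printed` reproduces the published
simulations, `derived` the published arithmetic.  This is the one place
the modes disagree materially, and it moves the imatinib E255K IRP by
about two percentage points.

Dose-time jitter (a robustness check) perturbs each dose after the first
by a centred uniform draw of configurable half-width under a fixed seed;
the first dose stays at t = 0 so `C(0) = 0` holds.  At zero jitter the
explicit dose superposition reproduces the closed form to machine
precision in either constants mode.

### Initial conditions and closed forms

Simulations start from the untreated quasi-equilibrium
`(1, f, f S/KM, 0)/W0`, `W0 = f (1 + S/KM) + 1`, scaled by total enzyme.
Because the derived rate constants satisfy `konS S/(kcat + koffS) = S/KM`
and `konR R/koffR = R/RD`, this analytic state is the exact fixed point of
the generator at `R = 0`, and for constant `R` the simulated long-time
composition matches the closed-form weights — both are tested to 1e-6
across one hundred seeded synthetic variants.  The closed-form inhibited
rate equals `rate(0) IC50/(IC50 + R)` identically, which grounds the
*effective IC50 ratio* indicator `IC50/(IC50 + [R](t))`: values above 0.5
(drug below the IC50) mark a state of resistance.

Note that the untreated rate is `kcat Etot f (S/KM)/W0`, not the bare
Michaelis-Menten `Vmax [S]/([S] + KM)`: the free inactive state holds a
share of the enzyme, so the effective saturation denominator is
`f([S] + KM) + KM`.  The Michaelis-Menten saturation fraction is still
reported as a (drug-independent) comparison indicator.

## Numerical choices

* **Integrators.**  The default is a variable-step stiff-capable solver
  (`deSolve::lsoda`, rel. tol. 1e-8, abs. tol. 1e-12) storing 1-minute
  samples; a fixed-step explicit Euler at 1 ms, implemented in compiled
  code with the dose sums updated recursively (one multiplication per
  step), is kept as the bit-reproducible reference.  The two agree on the
  product-rate series to better than 0.1% over a one-day window; the
  adaptive path is used for ten-day runs because ~8.6e8 fixed steps per
  ten days buys no accuracy for a near-equilibrated linear system.
* **Stability guard.**  A state more negative than -1e-12 uM aborts with
  advice to reduce the step: that threshold separates round-off from
  genuine instability.
* **IRP extraction.**  Baseline is the analytic untreated rate (equal to
  the simulated t = 0 rate by the fixed-point property).  The midpoint is
  evaluated at exactly 9.5 days after the first dose; the reported range
  comes from the extreme product rates over the [9, 10) day window, on the
  1-minute output grid.
* **Problem sizes.**  Ten-day simulations at 1-minute resolution (14 401
  samples) for the headline indicators; one-day windows for the
  Euler/adaptive equivalence check; one hundred synthetic variants with
  eigenvalue-scaled horizons (40 times the slowest relaxation time) for
  the quasi-equilibrium property sweep.  These sizes keep the whole suite
  in the low minutes on a single core while leaving all tolerances
  comfortably resolved.

## The synthetic-variant generator

`synthesize_variant()` draws turnover numbers (2-200 min^-1), Michaelis
constants (0.5-25 uM) and IC50 values (1-10^4 nM) log-uniformly — ranges
bracketing the measured panel — plus a uniform free-energy shift
(-3 to +1 kcal/mol) and an ATP-site flag with probability 1/4, under a
temporary RNG state so a seed fully determines the variant.  It emulates
the *parameter space* of plausible kinase variants, not their biology: no
correlation between catalytic fitness and drug affinity, no measurement
noise, and one enzyme species per simulation.  Property tests passing on
these variants therefore demonstrate the internal consistency of the
derivation and integration machinery across the realistic parameter range;
they say nothing about how well a four-state quasi-equilibrium model
captures any particular real mutation.

## Known limitations

* One-compartment pharmacokinetics with `F = 1`, no protein binding,
  nonlinear clearance or inter-patient variability; the jitter test is the
  only schedule perturbation.
* Substrate and ATP are not dynamic species; product feedback and
  downstream signalling (hence cell growth) are outside the model, so IRP
  ranks enzymatic inhibition, not clinical response.
* The effective-unity convention deliberately collapses the free-energy
  input; conclusions that hinge on conformational thermodynamics need the
  `per_mole_RT` convention and externally validated gaps.
* Published-table reproduction inherits the source's printed rounding and
  the documented errata; where print and formula disagree, the formula
  wins and the disagreement is recorded rather than hidden.
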