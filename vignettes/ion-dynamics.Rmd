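---
title: "Modelling reacting ion ensembles in drift-tube IMS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling reacting ion ensembles in drift-tube IMS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(driftIMS)
```

## The problem

In a drift-tube ion mobility spectrometer (DTIMS) an ion packet is pulsed
into a gas-filled tube and pulled through it by a static electric field.  The
arrival time distribution (ATD) at the detector encodes the ion's mobility
(through the drift time) and, through the peak width and shape, the ion's
diffusion and any chemistry it undergoes en route.  Modern instruments
operate at elevated *reduced field strengths* E/N (tens to >100 Td, with
1 Td = 1e-21 V m^2), where two things happen that the classical low-field
picture misses:

1. **Collision dynamics change.**  The drift velocity becomes comparable to
   thermal velocities, the ion-neutral collision-velocity distribution is
   distorted along the field, mobility becomes field dependent, and
   longitudinal diffusion grows well beyond its Einstein-relation value.
2. **Reaction dynamics switch on.**  The extra collision energy heats the
   ion internally, driving fragmentation and shifting clustering equilibria
   with trace neutrals (water, solvent vapour).  Depending on whether this
   chemistry is fast or slow relative to the drift time, peaks shift and
   broaden or develop non-Gaussian shapes and split.

driftIMS simulates both layers: per-species field-dependent transport, and
stochastic chemistry over a reaction network, producing species-resolved
ATDs and 2D IMS-MS spectra.

## Transport model

Each species carries a reduced-mobility table K0(E/N), supplied by the user
(measured, or from an external mobility calculator) or synthesised by the
fixture generators.  From it and the gas conditions (pressure p, temperature
T, gas mass M) the package derives, at the applied E/N:

* mobility `K = K0(E/N) * N0 / N` and drift velocity `v_d = K E`, with
  `N = p / (kB T)` and N0 the Loschmidt constant;
* the **effective temperature** of two-temperature theory (2TT),
  `T_eff = T + M v_d^2 / (3 kB) * (1 + beta_2TT)`, describing the mean
  collision energy.  The ion's internal temperature is approximated by
  T_eff throughout -- there is no explicit inelastic-collision model, so
  systems whose internal heating lags the collision energy are outside the
  model's reach;
* the **longitudinal temperature** `T_L = T + gamma_L M v_d^2 / kB *
  (1 + alpha_2TT)`.  The longitudinal direction receives more than the
  isotropic 1/3 share of the field energy; the partition coefficient
  `gamma_L` is exposed per species with default 2/3, and `gamma_L = 1/3`
  degenerates T_L to T_eff.  This one-parameter form stands in for the full
  kinetic-theory expression; because only the ratio of D_L across fields
  enters most observables, the conclusions are insensitive to the exact
  value within [1/3, 1];
* the **longitudinal diffusion coefficient** from the generalized Einstein
  relations, `D_L = (kB T_L / q) d(K E)/dE`, with the derivative taken
  analytically on a monotone-cubic (Fritsch-Carlson) interpolant of the
  mobility table.  Monotone-cubic rather than linear interpolation keeps
  d(KE)/dE -- and hence D_L -- continuous.  At E = 0 this reduces exactly
  to the Einstein relation `D = kB T K / q`.

Requests outside the tabulated E/N range raise an error rather than
extrapolate: silently extrapolated field-dependent corrections are the
dominant error source in this kind of modelling, so the failure is loud.

The low-field Mason-Schamp relation converts between reduced mobility and
collision cross section,

$$\Omega = \frac{3q}{16 N_0 K_0}\sqrt{\frac{2\pi}{\mu k_B T}},$$

with reduced mass mu; `ccsFromMobility()` / `mobilityFromCcs()` are exact
inverses.  The *alpha-function* `alphaFunction()` reports
`K0(E/N)/K0(lowest tabulated field) - 1`; normalising at the lowest
tabulated field (rather than a nominal 0 Td) makes the definition
applicable to tables that start at a finite field.

## Chemistry

Reactions are typed by their transition state:

* **tight** (rearrangement, fragmentation over a barrier): Eyring rate
  `k = (kB T_ion / h) exp(-dG' / (R T_ion))` with transmission coefficient
  1 and `T_ion ~ T_eff` of the reactant at the applied field;
* **loose association** (barrierless capture of a neutral): Langevin
  ion-induced-dipole capture `k_L = q sqrt(pi alpha / (eps0 mu))`, times an
  average-dipole-orientation-style locking enhancement
  `1 + c mu_D / sqrt(4 pi eps0 alpha kB T_eff)` for dipolar neutrals.  The
  locking constant (default c = 0.25) is an exposed parameter of a
  deliberately simple fallback form; the rate model is pluggable in the
  sense that any capture expression can be matched through it and the
  per-reaction multipliers;
* **loose dissociation**: closed by detailed balance against the capture
  rate at standard concentration c0 = N0,
  `k_r = k_f N0 exp(dG_assoc / (R T_eff))`.  This guarantees that an
  isolated association/dissociation pair relaxes to the Boltzmann
  population ratio whatever the capture model details, which the test suite
  verifies against a brute-force ODE integration on random networks.

Neutral partners carry a concentration profile along the drift axis:
constant, or exponentially decaying from the injection end (emulating a
neutral diffusing in from the upstream reaction region).  Associations are
pseudo-first-order through the local concentration; when any profile is
nonconstant, rate matrices are cached on a uniform 256-cell position grid.

All rates assemble into a first-order rate matrix R (columns sum to zero)
and the **state-transition matrix** `phi(dt) = expm(R dt)`, computed as the
exact matrix exponential -- species counts are small, so exactness is
cheap and removes the O(dt) bias a linearised `I + R dt` would carry.  A
step-size guard refuses any dt for which a species' total per-step reaction
probability exceeds 5 %, because the particle engine records at most one
reaction event per step; `suggestTimestep()` returns
`min(0.045 / max exit rate, min drift time / 500)`.

One consequence of using each reactant's own T_eff: a reversible pair
whose two species have different mobilities sees slightly different
temperatures in the two directions, so detailed balance holds exactly only
for equal-mobility pairs.  This mirrors the physical ambiguity of assigning
a single temperature to a heteromolecular equilibrium at high field.

## The two integrators

**Ensemble (deterministic).**  Populations advance as `P <- phi(dt) P`
while the mean position advances with the population-weighted ensemble
drift velocity `sum_i P_i K_i E`.  This is exact for the population
dynamics and for arrival times in the fast-exchange (merged-peak) limit,
but carries no width information.

**Monte Carlo (per particle).**  Each of N_p particles (default 4000)
advances in lockstep time steps: first its identity is resampled from
phi's column for its current identity (at its position's grid cell), then
it moves by the *new* identity's drift step `K E dt` plus a random-walk
diffusion step of magnitude `sqrt(2 D_L dt)` with a fair-coin sign.
Sampling the reaction before the move matches the convention that a
particle is propagated with the mobility of its current identity; the
ordering bias is O(dt) and is covered by the dt-halving convergence test.
A particle terminates when it crosses the drift length L, with the
crossing time linearly interpolated inside the final step (end-of-step
recording would bias fitted drift times by O(dt)); in fixed-time mode
(`tMax`) it terminates at a set clock instead, which is what the
cross-engine comparison tests use.  There is no reflecting wall at x = 0:
backward diffusion excursions are allowed, as drift dominates under all
realistic conditions.

The initial pulse is a delta by default; a rectangular pulse of the
shutter opening time t_inj (uniformly distributed launch clocks) is
available for instrument emulation.

The inner loop is compiled (Rcpp) and consumes R's RNG stream, so a single
`set.seed`-style seed in `mcConfig()` makes results bit-reproducible.  The
particle iteration order is fixed, so reproducibility does not depend on
per-particle streams; the transfer-region extension reseeds with
`seed + 1` so it is reproducible independently of when it is called.

**Transfer region.**  After arrival, ions spend `transferTime` (default
50 us) in the MS transfer optics.  Transfer is assumed soft: temperatures
stay at drift-region values and there is no spatial motion, so identities
evolve under the exact `expm(R * transferTime)` evaluated at the end of
the tube -- a single exact Markov jump, no step guard needed since only
final identities matter.  For kinetically shifted (incomplete) chemistry
this moves intensity between m/z channels *without changing arrival
times*, which is precisely how fragment intensity appears at the
precursor's drift time in 2D IMS-MS spectra.

## ATD analysis

`atdHistogram()` bins arrivals at the instrument's ATD resolution (56 ns
for the stand-alone reference instrument, 3 us when MS-coupled).
`fitGaussian()` does a least-squares Gaussian on bin centres, initialised
from moments, with sigma bounded below by the bin width; it reports the
FWHM `w05 = 2 sqrt(2 ln 2) sigma` and a normalised RMS residual, with an
advisory non-Gaussian flag above 5 % of the amplitude.  The flag also
trips on strong Poisson noise (few counts per bin), which is intended --
it marks any fit a Gaussian does not describe well.  Low-count
histograms are better fitted after coarser binning.

The analytic width budget for a nonreacting species is

$$w_{0.5}^{\mathrm{diff}} = 2\sqrt{2\ln 2}\,\frac{\sqrt{2 D_L t_D}}{v_d},
\qquad
w_{0.5} = \sqrt{(w_{0.5}^{\mathrm{diff}})^2 + (w_{0.5}^{\mathrm{init}})^2},$$

with the initial width taken as a Gaussian of the same standard deviation
as the rectangular shutter pulse, `t_inj / sqrt(12)`.  Four power-law
limits follow for the relative width `w05 / t_D` versus E/N: drift time
scales as (E/N)^-1; the diffusion term as (E/N)^-1/2 when D_L is constant
(low field) but as (E/N)^+1/2 when field heating dominates D_L; the
initial-width term as (E/N)^+1.  `relativeWidthCurve()` evaluates the
budget with D_L either field dependent or frozen at its low-field value,
and locates the minimum by grid search with parabolic refinement through
the bracketing points (derivative root-finding would be fragile on
interpolated tables).  With field-dependent diffusion the minimum sits at
lower E/N and is shallower -- i.e. beyond a certain field, raising E/N
*costs* resolving power despite shorter drift times.

## What the fixtures emulate -- and what they do not

Three bundled scenarios mirror the reference instrument (drift length
150.5 mm, 14.7 mbar / 80 C stand-alone, 14.3 mbar / 27 C MS-coupled,
3 us injection, ~70 ppm_V residual water):

* `dtbpSystem()` -- protonated 2,6-di-tert-butylpyridine, the nonreacting
  mobility standard: one species, K0 = 1.519 cm^2/(V s) at low field,
  declining quadratically by 3 % to 120 Td.
* `meohWaterSystem()` -- protonated methanol with water clustering: five
  species (bare ion, mono- and dihydrate, proton-bound methanol dimer and
  its hydrate).  Water chemistry is fast (tens of reaction events per
  ion), so the hydrates merge into one peak whose centroid shifts with the
  population; methanol chemistry is slow (a few events), so the dimer is a
  separate, later feature.  Hydrate binding free energies (-73 and
  -44 kJ/mol) place the population crossings near 75 and 40 Td, i.e.
  dihydrate-dominated at 20 Td, monohydrate-dominated near 60-70 Td, bare
  ion above ~90 Td.
* `etoacSystem()` -- protonated ethyl acetate: sequential fragmentation
  (loss of ethene to m/z 61, then water loss to m/z 43) competing with
  hydration and proton-bound-dimer formation.  The rearrangement barriers
  are the published values (133.5, 136.5, 185.8 kJ/mol).  The m/z 61
  isomer pair shares one MS channel but is internally two species; the
  weakly bound isomer loses water quickly relative to the 185.8 kJ/mol
  isomerisation that forms it, which is what delays the m/z 43 onset to
  higher fields than the m/z 61 onset.  The McLafferty-type direct channel
  to the weakly bound isomer carries a default rate multiplier of 0.05:
  with equal flux through both channels the m/z 43 onset would track m/z
  61, contrary to the observed successive ordering, and the suppressed
  channel reflects the assessment that this pathway is not the dominant
  one.  Multipliers are the exposed hook for this kind of empirical
  fine-tuning; they scale both directions of reversible channels so
  detailed balance is preserved.

The fixtures' mobility tables and cluster thermochemistry are
*representative*, not first-principles values: they are chosen once to
place transitions and onsets in the observed field ranges, and the shipped
fixture files are labelled synthetic.  Consequently the fixtures support
qualitative assertions (orderings, onsets, dominance windows, broadening
beyond the diffusion baseline) but not quantitative population overlays.
Passing tests on them demonstrates that the *machinery* -- transport,
kinetics, propagation, analysis -- reproduces closed-form and
phenomenological ground truth; they say nothing about the accuracy of any
particular quantum-chemistry input a user might supply.

`randomScenario()` generates seeded 2-6 species networks with constant
mobilities (1-3 cm^2/(V s)) and unimolecular interconversions whose rates
sit either well above ("fast", >= 100 per drift time) or well below
("slow", <= 0.01 per drift time) the separation timescale, bundled with an
independent RK4 integration of the rate equations as ground truth.  These
drive the property tests: cross-engine agreement, merged-peak and
resolved-peak limits, and population conservation.

## Numerical choices and test design

* Time step: `min(0.045 / max exit rate, t_D^min / 500)`; the 10 %
  headroom below the 5 % guard avoids boundary failures, and t_D/500
  resolves the ATD.  Halving dt moves mean arrivals by < 0.1 %.
* Matrix exponential via the Matrix package on dense generators; columns
  renormalised after clipping ~1e-16 negatives.
* Statistical tests compare Monte Carlo output with closed forms at
  3 standard errors under a fixed seed.  The 100-network cross-engine
  suite aggregates: at least 98 % of all per-species comparisons must fall
  within 3 binomial standard errors (plus a small-count continuity
  allowance) and all within 5 -- a strict per-comparison 3-sigma bound
  over ~400 draws would fail by chance alone.
* Problem sizes: N_p = 4000 where widths are fitted (matching the
  reference instrument's simulation size), 300-3000 elsewhere; field scans
  use 4-8 grid points.  These sizes make every statistical bound above
  decisive while keeping the full suite around a minute.

## Known limitations

Radial diffusion, ion optics, space charge, and amplifier response are not
modelled; resolving powers therefore cannot be predicted, only relative
peak widths.  Fields are static (no TWIMS/TIMS/FAIMS waveforms).  There is
no internal-energy distribution or RRKM treatment -- rates respond to
T_eff instantaneously -- and CCS does not grow with internal temperature,
which matters for flexible ions and large clusters.  Reactant-ion
(reagent) chemistry is out of scope: networks describe the analyte system
only.
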