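---
title: "Models and methods: complexin-SNARE binding thermodynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: complexin-SNARE binding thermodynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clampeq)
library(ggplot2)
```

# Scope

clampeq models the solution thermodynamics of complexin (CPX) binding to
assembling SNARE complexes: the saturation arithmetic behind blocked-complex
titrations, simulation and fitting of isothermal titration calorimetry (ITC)
thermograms under one or several independent site classes, a
semi-quantitative model linking accessory-helix cross-linking to the mean
particle radius seen by dynamic light scattering (DLS), and conversion of
donor-quenching fluorescence into FRET efficiencies and distances. Every
estimator is paired with a seeded synthetic-data generator so that recovery
of known parameters can be demonstrated, which is the package's main
validation currency.

# Binding equilibria

All solvers work on untransformed mass balances in molar units.

**Heterodimer (1:1).** For receptor total $R$, ligand total $L$ and
dissociation constant $K_d$, the bound complex is the smaller root of the
mass-balance quadratic,
$$[RL] = \tfrac12\left[(R+L+K_d) - \sqrt{(R+L+K_d)^2 - 4RL}\right].$$
We evaluate the conjugate form $2RL/\big((R+L+K_d)+\sqrt{\cdot}\big)$, which
is algebraically identical but avoids the catastrophic cancellation of the
textbook expression when $4RL \ll (R+L+K_d)^2$ (weak binding or strong
excess). `saturation_percent()` composes this with a fold-excess convention
to answer the blocking question directly: at 20 uM pre-fusion complex,
a 1.5-fold excess of a central-helix fragment binding at 457 nM occupies
95.9% of sites, and a 3-fold excess 98.9%. A frequently quoted companion
claim of "at least 99%" blocking under 2.5-3-fold excess slightly exceeds
the 98.5-98.9% computed at 20 uM; the discrepancy is consistent with the
blocking incubation having been performed at higher concentration before
dilution, which is not recorded, so both numbers are reported side by side
rather than reconciled.

**Self-association.** A complex that cross-links through a single interface
obeys $[\mathrm{unbound}]^2 = K_d\,[\mathrm{bound}]$, giving
$[\mathrm{unbound}] = K_d\big(\sqrt{1+4C/K_d}-1\big)/2$ at total
concentration $C$; again the conjugate form $2C/(\sqrt{1+4C/K_d}+1)$ is
used, and `unbound + bound == C` holds exactly by construction.

**Thermodynamic conversions.** $\Delta G = -RT\ln K_a$,
$T\Delta S = \Delta H - \Delta G$, with $R = 1.987\times10^{-3}$
kcal mol$^{-1}$ K$^{-1}$ and all energies in kcal/mol — the convention of
the Origin/Microcal analysis software this mirrors. The default temperature
is 298.15 K throughout; the fluorescence work that anchors the FRET module
was done at 25 C and the calorimetry temperature is not separately
recorded, so one global default is used and exposed as an argument
everywhere it enters.

# The ITC forward model

A titration is described by `itc_experiment()`: a 200 uL cell, the
macromolecule concentration loaded in the cell, the titrant concentration
in the syringe, and an injection schedule. The default schedule is a 0.4 uL
first injection followed by twenty 2 uL injections — standard small-cell
practice, with the small first injection discarded from fitting
(`drop_first`) because of syringe-tip exchange during equilibration. Only
total loading volumes of roughly 200 uL and 60 uL are recorded for the
experiments this package reanalyses, so the per-injection schedule is a
package default, not a measured quantity.

Cell concentrations after the $i$-th injection use the perfusion
displacement correction, with $v$ the cumulative injected volume:
$$M_t = M_0\frac{1-v/2V_0}{1+v/2V_0},\qquad
  X_t = X_0\frac{v/V_0}{1+v/2V_0}.$$
This is one of two standard discretisations of displacement from a
constant-volume cell; the test suite checks it against an explicit
mix-then-overflow mass-tracking simulation, with which it agrees to better
than 1% over the 20% volume turnover of a default run.

The cumulative heat of a one-set-of-sites system is the Wiseman isotherm
$$Q = \frac{n M_t \Delta H V_0}{2}
      \left[b - \sqrt{b^2 - 4X_t/(nM_t)}\right],\qquad
  b = 1 + \frac{X_t}{nM_t} + \frac{1}{nK_aM_t},$$
which is nothing more than $V_0\,\Delta H$ times the bound concentration
from the 1:1 quadratic with receptor total $nM_t$; it is evaluated in the
same cancellation-free conjugate form. Per-injection heats difference the
cumulative heat with the displaced-volume correction
$\Delta Q_i = Q_i + (dV_i/V_0)(Q_i+Q_{i-1})/2 - Q_{i-1}$, and normalized
heats divide by the moles of titrant in each injection.

**Several site classes.** For a bivalent titrant meeting a bivalent
macromolecule we use the simplest model consistent with independent
central-helix and accessory-helix thermodynamics: independent site classes
$(K_j, \Delta H_j, n_j)$ with free titrant $L$ solved per injection from
$$X_t = L + M_t\sum_j \frac{n_jK_jL}{1+K_jL},$$
by bracketing (the right side is strictly increasing in $L$) plus a Newton
polish, and $Q = V_0M_t\sum_j n_j\Delta H_j K_jL/(1+K_jL)$. No
polymerisation correction is applied to the heats: cross-linking changes
particle size, not the per-interface enthalpy budget, under the
independence assumption. Two semantic points are worth stating explicitly
because they are easy to get wrong: the model reduces *exactly* to the
one-site isotherm when a class is removed or its association constant is
zero (`kd = Inf`), but a class with zero *enthalpy* does not drop out — it
still binds, depletes free titrant, and thereby shifts the other classes'
occupancy while contributing no heat itself. The model is continuous in all
parameters and invariant under reordering of its site classes.

# Fitting thermograms

`fit_one_site()` minimises squared residuals of normalized heats by
Levenberg-Marquardt over $(\log K_a, \Delta H, n)$; the log
parameterisation keeps $K_a$ positive without constraints. Default starts
are $n = 1$, $\Delta H$ = the first retained normalized heat, and $K_a$
such that the Wiseman $c = nK_aM_0$ equals 10. Standard errors come from
the local curvature; the error on $K_d$ is the delta-method transform of
the error on $\log K_a$. Derived $\Delta G$ and $T\Delta S$ are computed
from the fitted affinity.

The information content of a single titration is governed by $c$: outside
roughly 1-1000 the isotherm is too shallow or too step-like to determine
the affinity well, and the fitter raises a classed warning (never an
error) there. For design $c < 10$ the three-parameter fit is practically
degenerate — $n$, $\Delta H$ and $K_a$ trade off along a ridge — and the
accepted treatment, which `itc_recovery_study()` adopts, is to fix the
stoichiometry at its known value and fit $(\log K_a, \Delta H)$ only. The
blocked-complex titrations (affinities of 15-24 uM measured at 20 uM cell
concentration, $c \approx 0.8$-1.3) are exactly this regime.

**Replicate summaries.** Because $K_d$ is fitted on the log scale, its
per-replicate estimator is right-skewed wherever the data are weakly
informative, and the arithmetic mean over replicates inherits an upward
Jensen bias that can be comparable to the recovery tolerances of interest.
Replicate studies therefore summarise $K_d$ by the mean on the fitted
scale — the geometric mean — which centres on the generating value;
enthalpies, stoichiometries and radii, fitted on linear scales, are
summarised arithmetically.

# The DLS oligomerization model

Accessory-helix insertion into the t-SNARE groove of a neighbouring
complex can chain CPX-SNARE units into oligomers. The model treats each
cross-link as an independent realisation of the self-association
equilibrium above: the probability that an interface is engaged is
$p = [\mathrm{bound}]/C$, a chain then contains $N = 1/(1-p)$ monomers on
average, and the particle radius scales as the ideal-polymer gyration
radius $r = \sqrt{N}\,r_0$, where $r_0$ is the spacing between units in
the array. Composed, $r(C) = r_0\sqrt{(1+\sqrt{1+4C/K_d})/2}$ — monotone
in $C$, decreasing in $K_d$, linear in $r_0$. This is deliberately
semi-quantitative: the equilibrium is written as a dimerisation but applied
per interface rather than re-derived as a full isodesmic polymer
distribution, and the measured DLS radius (a hydrodynamic quantity) is
identified with the gyration radius without conversion. Both
simplifications are inherited knowingly; the model's job is to ask whether
a 25 uM interface affinity predicts oligomerization onset in the 25-50 uM
concentration window, and it does ($r/r_0 = 1.27$ at $C = K_d = 25$ uM).

`fit_dls()` fits $(\log K_d, r_0)$ by Levenberg-Marquardt, weighted by
reported radius uncertainties when present, with $r_0$ bounded to (0.5, 20)
nm and $K_d$ capped at 1 mM. The non-specific-aggregation flag deserves a
note: a fit is flagged when the fitted $K_d$ exceeds the *largest sampled
concentration* (or hits the 1 mM cap). When $K_d > \max C$ the data never
reach the association midpoint, the affinity is only bounded from below,
and small radius growth of that kind is indistinguishable from weak
non-specific sticking — precisely the situation of a 250 uM affinity
measured over a 5-100 uM panel. A fixed threshold far above the measured
range would never trigger on such data, which is why the data-driven
criterion is used.

# FRET

Donor quenching only: $E = 1 - \int F_{DA} / \int F_D$, integrated
trapezoidally over a window that isolates the donor band (default 410-470
nm, the bimane emission inside a 410-600 nm scan; configurable). Spectra
must share a wavelength grid — resampling is refused rather than performed
silently, since interpolation error would masquerade as transfer. Raw
efficiencies outside $[0,1]$ are clamped and flagged rather than erroring,
because instrument noise routinely produces slightly negative apparent
efficiencies on matched samples. Distances invert the Forster relation
$r = R_0(1/E-1)^{1/6}$, defined strictly inside $E \in (0,1)$; the two dye
pairs of interest have $R_0 \approx 27$ Å (stilbene/bimane) and
$\approx 38$ Å (bimane/Oregon Green). An optional labeling-efficiency
correction $E/f_\mathrm{label}$ is off by default (labeling was >95% in
the anchoring experiments). Computing $R_0$ from spectral overlap is out
of scope.

# Synthetic data

The generators produce exactly the inputs the estimators consume, with the
statistical structure the analysis assumes, and nothing more:

- `gen_itc()`: forward-simulated thermograms plus additive Gaussian noise
  on normalized heats, sd = `noise_fraction` x |enthalpy|, default 2% —
  a typical integrated-heat repeatability for a small-cell instrument.
- `gen_dls()`: model radii with multiplicative Gaussian noise, default 3%,
  on the default panel {5, 10, 25, 50, 100} uM, which brackets the 25-50 uM
  window where oligomerization sets in.
- `gen_spectra()`: a Gaussian donor band (centre 440 nm, sd 15 nm) on a
  1 nm grid over 410-600 nm, with the donor-acceptor spectrum scaled to
  $(1-E)$ of the donor area; optional additive noise truncated at zero.

Each generator draws from a private stream derived from
`(seed, operation)`, so identical seeds give identical data, different
operations never share noise, and the caller's RNG state is untouched.

What the generators do *not* emulate bounds what passing tests can show:
no baseline drift or integration error in heats, no heat-of-dilution
blanks, no concentration-measurement error (a dominant real-world
uncertainty for small proteins), no autocorrelation-level DLS processing
or intensity weighting, no photobleaching or scatter in spectra.
Parameter-recovery results here demonstrate correctness of the estimators
under their own assumptions, not robustness to instrument systematics.

# Problem sizes and reproducibility

Recovery studies use 50 replicates at the stated noise levels (the
fitter-bias property test uses 300 replicates at 1% noise so that a 2%
bias bound is measured with adequate Monte-Carlo precision). With five
DLS concentrations at 3% noise the per-replicate $\log K_d$ estimator has
an irreducible spread of about 0.3 (the design's information limit), so a
50-replicate summary of $K_d$ still carries a Monte-Carlo standard error
of roughly 4% — recovered affinities should be read with that in mind,
while $r_0$ is determined an order of magnitude more tightly. All
randomness is seed-controlled; `scripts/acceptance.R` re-derives every
headline number from a single `--seed`.

# Known limitations

- The bivalent ITC model is one interpretive choice among several for a
  cross-linking titration; alternatives that couple polymerisation into
  the heat model would need additional parameters the data cannot fix.
- The DLS model's chain-length statistics are heuristic (per-interface
  probability, not an isodesmic distribution) and its radius is nominal
  to within the gyration/hydrodynamic distinction.
- Heat-of-dilution subtraction is limited to what the displacement
  correction implies; no constant-offset nuisance parameter is fitted.
- Efficiencies from strongly overlapping donor/acceptor emission would
  require spectral unmixing, which is not implemented; the integration
  window must isolate the donor band.
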