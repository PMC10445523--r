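---
title: "Models and methods behind oleodrop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind oleodrop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

oleodrop studies one question about oleosomes — the lipid droplets of oil
seeds, a triacylglycerol (TAG) core coated by a phospholipid (PL)
monolayer: how dilatable is that membrane, i.e. how freely can its
molecules spread over new interface when the droplet takes up oil?  The
package implements the quantitative pipeline around that question:
interfacial density bookkeeping from emulsion droplet sizes, oscillatory
dilatational rheology analysis, construction of coarse-grained
droplet systems for an MD engine, radial-density and fusion analysis of
bead trajectories, and binomial statistics over replicate fusion runs.
This vignette records the models, the defaults and why they were chosen,
and what the synthetic generators do and do not emulate.

## Interfacial density bookkeeping

A dispersion is summarised by `dispersion_spec()`: batch mass (default
70 g at 10 wt% oleosomes, i.e. 7 g of oleosome lipid), oil density
0.91 g cm⁻³, PL content 0.6 wt% of the oleosome mass with
phosphatidylcholine molar mass 786.1 g mol⁻¹, and optionally a mass of
added free oil.  Treating all oil as monodisperse spheres of a
representative diameter $d$, the total interfacial area is

$$A_T = A_d N_d = \pi d^2 \cdot \frac{V}{\pi d^3 / 6} = \frac{6V}{d},$$

with $V$ the total oil volume.  The PL count is
$N_{PL} = m_{PL} / M_w \cdot N_A$; the interface density is
$N_{PL} / A_T$ and its inverse the area available per PL.  Assumptions
worth keeping in mind:

* **Representative diameter.** The caller supplies it; the pipeline
  default is the volume mean d4,3 because that is what laser-diffraction
  reports headline and what reproduces the reference area at
  $d = 1.7\ \mu m$.  The surface mean d3,2 is the surface-consistent
  choice and is one argument away (`mean_diameter(dist, 3, 2)`).
  `mean_diameter()` implements the generalized moment mean
  $(\sum n d^p / \sum n d^q)^{1/(p-q)}$, which reduces to the familiar
  moment ratios for d4,3 and d3,2.
* **Added oil** is assumed to share the oleosome oil density and carries
  no PL.
* **Proteins are excluded** from the bookkeeping; oleosins sit on the same
  interface and would follow the same trend, but the model tracks PL only.
* All per-area quantities are independent of the batch mass (both $N_{PL}$
  and $A_T$ scale linearly), so the 70 g basis is a convention, not an
  input that matters.

Headline numbers of this kind are order-of-magnitude statements;
`ca_round()` formats them at one significant figure.  Full precision is
always retained in the report object.

## Oscillatory dilatational rheology

A drop tensiometer oscillates a drop of reference area $A_0$ (default
20.0 mm²) sinusoidally at one frequency (default 0.02 Hz) in steps of
increasing relative amplitude, each step a block of 5 driven cycles
followed by 5 blank cycles.  From the tension amplitude $\Delta\gamma$,
area amplitude $\Delta A$ and phase shift $\delta$ the dilatational
moduli are

$$E_d' = \frac{\Delta\gamma}{\Delta A} A_0 \cos\delta, \qquad
  E_d'' = \frac{\Delta\gamma}{\Delta A} A_0 \sin\delta.$$

Design choices:

* **Harmonic fitting, not FFT bins.** Each cycle is fitted by least
  squares with $c + a\sin(2\pi f t) + b\cos(2\pi f t)$ at the known drive
  frequency.  Amplitude steps are only five cycles long, far too short
  for spectral estimates; the fixed-frequency fit is exact on noiseless
  sinusoids and degrades gracefully with noise.  Per-step moduli are the
  mean over the step's cycles, with the per-cycle scatter retained.
* **Baseline $\gamma_0$** for the surface pressure of a Lissajous curve is
  the mean tension over the trailing half of the blank block preceding the
  step (the interface has relaxed there); the first step uses the
  pre-oscillation tail.
* **The middle 3 of 5 cycles** (cycles 2–4) form the Lissajous curve,
  avoiding the switch-on and switch-off transients.
* **Phase is wrapped to $(-\pi, \pi]$**; for a physical interface
  $\delta \in [0, \pi/2)$, and values outside are flagged (`physical =
  FALSE`) but not rejected, since they do occur in noisy records.
* **Nonlinearity metrics are package-defined.** Strain softening and
  stiffening are usually read off Lissajous shapes qualitatively; the
  package fixes a quantitative convention: secant moduli at maximum
  expansion and maximum compression, and their normalized difference
  `asymmetry_ratio` in $[-1, 1]$, positive when the interface is stiffer
  in compression.  A useful identity: an odd harmonic distortion (e.g. a
  third harmonic) is antisymmetric under a half-period shift and therefore
  cannot produce secant asymmetry — it bends the curve while leaving the
  ratio at zero.  Only even-order distortion (the generator's
  `stiffening` term, $-c\,x^2$) moves the ratio.
* Drop-shape (Laplace) analysis is out of scope: tension is an input,
  taken from the instrument.

## Coarse-grained droplet construction

The builder produces initial bead configurations for a Martini-resolution
MD engine: a TAG droplet core, an optional PL monolayer, a two-droplet
box and solvent.  It generates *starting structures*: mild strain is
acceptable because the engine's equilibration relaxes it.

* **Templates.** Triolein is 15 beads (3 glycerol/ester + three 4-bead
  oleoyl tails), DPPC is 12 beads (choline + phosphate head, 2 glycerol,
  two 4-bead tails), water is a single bead.  Bond spacing 0.47 nm and
  inter-molecular contact distance 0.40 nm are typical coarse-grained
  bead scales — configurable template parameters, not measured constants.
* **Core packing** is seeded random sequential insertion: molecule anchors
  uniform in the sphere, beads grown as a random walk at the bond length,
  rejecting placements within the contact distance of other molecules
  (cell-list lookup) or outside radius + one bond.  Identical seed, same
  platform: bitwise-identical coordinates.  A packing-fraction precheck
  rejects hopeless requests before looping.
* **Molecule volume calibration.** Triolein's effective volume of
  2.178 nm³ is calibrated so 2560 molecules give an 11.0 nm droplet,
  the reference core size.
* **Shells** place head groups on a Fibonacci lattice with a seeded random
  rotation — a deterministic construction that succeeds at any density of
  interest (rejection sampling would struggle at 1.1 nm⁻²).  Each
  molecule runs radially inward from its lattice direction; the head-group
  centroid sits exactly at the declared radius, which is why declared and
  measured densities (`measure_shell_density()`, count over the sphere of
  the mean head radius) agree to within lattice noise.  Shell radii for
  the study densities follow from $R = \sqrt{N / 4\pi\rho}$: 1200, 1600
  and 2000 DPPC at 0.7, 0.9 and 1.1 PL nm⁻² imply 11.7–12.0 nm.
* **Shell–core interdigitation is intentional.** PL fatty acids are
  solubilized in the TAG core — that is the physical point of the system —
  so the contact-safety validation (`contact_report()`) exempts the
  shell/core pair while enforcing the contact distance for every other
  inter-molecular pair, including all solvent.
* **Two-droplet box.** Droplet surfaces are defined by their extreme bead
  coordinates; the free droplet is placed at the prescribed
  surface-to-surface gap along x (default 0.47 nm) and the pair centred
  in the default 52 × 32 × 32 nm box.
* **Hydration** fills the box with solvent beads on a jittered lattice,
  excluding sites within 0.40 nm of any solute bead.  The default bead
  density of 8.3 nm⁻³ is a calibration: with this exclusion geometry it
  reproduces the reference solvent count of ≈350,000 beads for the
  two-droplet system.  The jitter half-width (0.04 nm) is kept below half
  the spacing margin so solvent–solvent distances never fall under the
  contact distance.  A known artifact: a few percent of solvent sites
  survive in interstices of the random-walk-packed cores; an engine's
  equilibration expels them, and analyses that matter here are unaffected.
* The builder writes GRO coordinate files and a minimal topology listing.
  Run-parameter files (integrator, thermostats, barostats) are *not*
  generated — the pipeline writes inputs for and reads outputs from an MD
  engine but never integrates equations of motion.

## Trajectory analysis

* **Centres** are per-frame centres of geometry of a designated component,
  with periodic unwrapping by shifting beads to the image nearest a
  reference bead.  This requires the component to fit within half the box
  — true for any sensible droplet system, and the documented limit.
* **Radial component density (RCD)** histograms bead distances from the
  centre into 200 contiguous spherical bins (the conventional count) up
  to `r_max` (default half the smallest box edge), summed over frames and
  divided by frame count and shell volume, i.e. a per-frame,
  per-shell-volume normalization with units nm⁻³.  This is the only
  normalization consistent with those units; a per-bead reading of
  "averaged over beads and frames" would not be.  Beads beyond `r_max`
  are tallied and reported, never dropped silently.  The profile satisfies
  an exact conservation identity (density × shell volume sums to the mean
  per-frame count), which the tests assert on every fixture.
* **Core radius** is the half-plateau crossing: the radius where the core
  component's density first falls below half its inner-plateau mean,
  linearly interpolated.  Simpler than a Gibbs dividing surface and
  adequate for step-like coarse-grained profiles.
* **Fusion detection** is deliberately explicit because published
  "infused/not infused" calls rarely state their criterion: fused means
  at least one inter-droplet bead pair within `cutoff` (default 0.6 nm)
  for `persistence` consecutive frames (default 3).  Both knobs are
  prominent arguments and recorded in every `fusion_record`.  Detection
  is monotone in the cutoff.
* **Shell density over time** re-measures the head-radius density per
  frame, gating each frame on a successful core-radius estimate from that
  frame's single-frame profile; failed frames are reported as `NA`.

## Fusion statistics

For $k$ fused runs out of $n$, `binomial_estimate()` reports
$\hat p = k/n$ with $\mathrm{sd} = \sqrt{\hat p(1-\hat p)/n}$.  The
binomial sd is written with the population proportion; the plug-in
$\hat p$ is what reproduces conventional reported ± values, so plug-in it
is, stated here once.  No continuity correction is applied.  A Wilson
score interval is available (`wilson_interval()`) for users who want a
proper interval at $n = 10$, but it is not part of the default report.

## What the synthetic generators emulate — and what they do not

* `gen_size_distribution()` discretizes a log-normal diameter law and
  reports it volume-weighted, the way a diffraction instrument does.
  Convention: `median` is the *number*-median and `gsd` the geometric sd,
  giving the closed form $d_{4,3} = \mathrm{median}\,e^{3.5\ln^2 gsd}$
  used by recovery tests; by default the median is solved so d4,3 is
  1.7 μm, the reference droplet size, with gsd 1.5 giving a realistic
  half-decade spread.  It does not model the diffraction inversion (Mie
  theory, refractive indices) or surfactant effects — distributions are
  taken as given.
* `gen_oscillation_series()` inverts the moduli relations exactly, then
  adds optional multiplicative noise, even-order stiffening and
  third-harmonic distortion.  Because the instrument's own estimator for
  $\Delta\gamma$, $\Delta A$, $\delta$ is opaque, only self-consistency
  (generator inversion) is claimable — recovery tests show the analyzer
  is correct, not that it matches a particular tensiometer.
* `gen_two_droplet_trajectory()` produces scripted geometry plus Gaussian
  jitter, **not** dynamics: no Martini energetics, no water structuring,
  no realistic fusion kinetics.  A fusing run snaps the free droplet into
  surface contact at `fuse_at` (so first-contact ground truth is exact)
  and interpolates over 10 frames to a merged endpoint — a single sphere
  of conserved total core volume with the shell redistributed on a
  proportionally scaled sphere, so radius recovery ($2^{1/3}$ for equal
  droplets) and shell-density recovery ($2^{-2/3}$) have closed forms.
* `gen_fusion_outcomes()` is seeded Bernoulli sampling.

Passing tests on these fixtures therefore demonstrate that every analyzer
satisfies its contract and inverts its generator; they do not demonstrate
agreement with any particular instrument or with microsecond-scale
coarse-grained MD, which is out of desk-scale reach.

## Numerical choices and problem sizes

Tolerances follow the quantity: exact identities (conservation, unit
bookkeeping) are asserted near machine precision; noiseless generator
inversions at 10⁻⁶ relative; stochastic recoveries at 1–5%.  Degenerate
inputs fail loudly: empty distributions, zero diameters, constant signals
(amplitude 0, phase 0 by convention, moduli refused), zero area
amplitude, hollow profiles, impossible packings.

The test suite runs the full-size reference system once — two
2560-triolein droplets, a 1200-DPPC shell, ≈355,000 solvent beads,
built, hydrated and contact-validated in about a minute on one CPU —
and exercises everything else on 4-bead miniature species (40-molecule
cores, 60-odd-molecule shells) chosen so the shell sphere sits just
outside the core, mirroring the full-size geometry at millisecond build
cost.

## Known limitations

* The pipeline treats the dispersion as monodisperse at the
  representative diameter; with a wide distribution the true area is
  larger, so densities are upper bounds — inherent to the method, not to
  the implementation.
* Periodic unwrapping assumes each component fits within half the box.
* Binary trajectory formats (XTC/TRR) are not read; multi-frame GRO (or
  anything convertible to it) is the interchange.
* The builder assigns no force-field parameters and performs no energy
  minimization; its output is a starting geometry.
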