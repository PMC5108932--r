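---
title: "Excitability and conduction in a ventricular cell fiber: model and protocols"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Excitability and conduction in a ventricular cell fiber}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific question

The inwardly rectifying potassium current (I~K1~, carried by Kir2.1
channels) and the fast inward sodium current (I~Na~, carried by Nav1.5)
are *reciprocally modulated* in mammalian ventricular myocytes:
up-regulating the channel density of one up-regulates the other.  fiberAP
provides the simulation machinery to study what this co-regulation does to
tissue excitability: a 22-state guinea-pig ventricular cell model whose
I~K1~ and I~Na~ maximal conductances (G~K1~, G~Na~, both 0.5 µS by
default) are free parameters, a one-dimensional monodomain fiber of 100
such cells coupled by linear gap-junction conductances (G~gj~, 10 µS by
default), and the four measurement protocols of the study: stimulus
thresholds of cells and fibers, conduction velocity, the passive fiber
space constant, and action-potential duration.

# The model

## Single cell

Each myocyte is the classical 22-state guinea-pig ventricular model:
membrane potential V~m~, eleven Hodgkin–Huxley-type gates (m, h for
sodium; d, f and two calcium-dependent inactivation gates for the L-type
calcium channel; s, r for the transient outward current; xr1, xr2, xs for
the delayed rectifiers), two sarcoplasmic-reticulum release-regulation
fractions, and seven concentration states (Na~i~, K~i~, Ca~i~, diadic-space
calcium, SR uptake and release compartments, calmodulin- and
troponin-bound calcium).  All constants are exposed in a single versioned
vector (`defaultCellConstants()`; a JSON copy ships in
`inst/extdata/cell_constants.json`).

The two currents of interest are evaluated exactly as

$$I_{K1} = G_{K1}\,\frac{[K]_o}{[K]_o + k_{m,K1}}\,
  \frac{V_m - E_K}{1 + e^{(V_m - E_K - 10)\,k/(RT/F)}},
  \qquad
  I_{Na} = G_{Na}\, m^3 h\, (V_m - E_{mh}),$$

with outward currents positive.  Two details deserve explanation because
the literature prints them in more than one form:

* **Rectification slope.**  The denominator's exponential slope constant
  `rectK1` (k above) is 1.25, i.e. an e-fold per RT/1.25F ≈ 21.4 mV, the
  reference encoding's value.  A steeper reading (2F/RT) circulates in
  print, but it shuts I~K1~ off so completely at plateau potentials that
  the phenomena the package exists to reproduce disappear: with the steep slope, action
  potentials never shorten to milliseconds at G~K1~ = 5 µS and the fiber
  never loses excitability near G~K1~ ≈ 1.3 µS.  The shallow slope
  reproduces both, so it is the package default and remains a parameter.
* **Sodium reversal.**  The m³h channel reversal E~mh~ includes the
  channel's small potassium permeability (12 %).  Using a pure sodium
  Nernst potential instead raises the baseline conduction velocity from
  70 to 88 cm/s, far off the calibrated baseline, so the mixed reversal
  is used.

External potassium is 5.4 mM (physiological Tyrode).  With 4 mM the model
rests at −93 mV and the default-parameter cell threshold comes out near
−22 nA; with 5.4 mM it rests at −85.4 mV and the threshold at −19.5 nA,
matching the classic guinea-pig ventricular anchors the package is
calibrated to — a resting potential of −85 to −90 mV, a 0.2 ms-pulse cell
threshold near −19 nA, and a baseline conduction velocity of 70 cm/s at
G~gj~ = 10 µS — simultaneously.  These three anchors are how the open
choice among model dialects was settled; `Ko` remains a parameter.

Units are mV, ms, nA, µS, nF, mM throughout (µS·mV = nA, nF·mV/ms = nA);
the cell capacitance is 0.095 nF.

## Fiber

`fiberConfig()` chains `nCells` identical cells (74 µm long) with linear
gap-junction conductances and sealed (no-flux) ends:

$$C_m \frac{dV_i}{dt} = G_{gj}(V_{i-1} - 2V_i + V_{i+1}) - I_{ion,i} - I_{stim,i},$$

with one-sided coupling at the two ends; all non-voltage states evolve
cell-locally.  The 100-cell study fiber is a 2200-equation system.  The
state vector is flattened cell-major (all 22 states of cell 1, then cell
2, …), which makes the Jacobian block-tridiagonal with bandwidth 22 — the
property that keeps implicit integration tractable.

# Numerical choices

* **Integrator.**  `runSimulation()` uses deSolve's `lsode`
  (variable-order BDF) with a banded finite-difference Jacobian
  (half-bandwidth 22) for fibers and `lsoda` for single cells; absolute
  and relative tolerances default to 1e-6.  Halving both tolerances moves
  the AP peak of a default fiber run by < 0.5 mV and its timing by
  < 0.1 ms (asserted in the tests).
* **Square pulses.**  Integration restarts exactly at every pulse edge, so
  the stimulus is never smoothed across a step, and the first millisecond
  after each edge is integrated with a bounded step (`hmax` = 0.01 ms):
  strong stimuli leave the stimulated cells far from equilibrium and an
  unrestricted first step can wreck the Newton iteration.
* **Sampling.**  Output is interpolated to 0.01 ms during pulses, 0.05 ms
  through the post-pulse/upstroke window and 1 ms elsewhere; activation
  times (maximum dV/dt, earliest-time tie-break, quadratic vertex
  refinement) are resolved to a few microseconds.
* **Extreme-amplitude robustness.**  Inexcitability is declared only after
  probing amplitudes up to a cap of 1900 nA per cell (100× the
  default-parameter cell threshold).  Such stimuli drive the stimulated
  cells far outside the credible voltage range, where two pieces of the
  model become integrator-hostile without affecting any physiological
  state: the Na/Ca exchanger's exponential voltage dependence (clamped
  beyond ±427 mV) and the positivity of the two small calcium pools,
  which the reversed L-type flux can push through zero into the poles of
  Ca/(Ca+K~m~) terms (floored at 10⁻¹² mM inside rate expressions; the
  decay terms restore positivity).  The voltage-dependent SR release-speed
  factor, a hard 5-to-1 switch at −50 mV in the reference encoding, is
  blended over a 0.25 mV logistic window because cells lingering at the
  switch potential — exactly what happens in decremental responses near
  the excitability boundary — stall the implicit solver on a
  discontinuous right-hand side.
* **Resting state.**  `restingState()` integrates the unstimulated cell
  for 300 s and polishes the fixed point with damped least-squares Newton
  iterations until the right-hand side's max-norm falls below 1e-6 in
  model units; the total-charge conservation law makes the Jacobian
  singular along one direction, hence the least-squares step.  Quiescent
  rest is used rather than a 1 Hz-paced limit cycle; the study's pacing
  protocols start from quiescence here.

# Protocols

* **AP criterion.**  A peak V~m~ > 0 mV within the detection window.  Full
  APs overshoot to about +40 mV while subthreshold responses stay below
  about −50 mV, so the 0 mV line is unambiguous.  Cells use a 50 ms
  post-pulse window; fibers use the rest of the pacing cycle so slow
  conduction still counts when it arrives.
* **Thresholds** (`findCellThreshold()`, `findFiberThreshold()`).  0.2 ms
  square pulses at 1 Hz, two consecutive pulses must each elicit an AP
  (at the stimulated cell, or — for fibers stimulated in cells 1–4 — at
  cell 75, far from both the stimulated and the sealed far end).  The
  smallest success amplitude on a 0.5 nA grid is found by geometric
  bracketing plus integer bisection, which provably equals the literal
  0.5 nA incremental scan because pacing success is monotone in the pulse
  magnitude (asserted against the literal scan in the tests).  Sweeps
  warm-start each search from the previous grid point; the result is
  independent of the start.
* **Conduction velocity** (`measureCV()`).  One pulse at 1.5× the fiber
  threshold; CV = 50 cells × 74 µm divided by the activation-time
  difference between cells 75 and 25, in cm/s.
* **Space constant** (`measureSpaceConstant()`).  A 100 ms pulse into
  cells 1–4 at 95 % of the separately measured 100 ms-pulse threshold;
  the end-of-pulse deviations from rest over cells 5 to n−5 are fitted by
  least squares to A·e^(−i/λ) (`stats::nls`, port algorithm, log-linear
  start).  The long-pulse threshold here means *any* cell firing, not
  propagation: at high G~K1~ a local non-propagating AP fires below the
  propagation threshold and would corrupt the passive profile.  Note an
  intrinsic amplitude confound of the near-threshold convention: at low
  G~Na~ the probe is much larger and engages the nonlinear near-threshold
  regime, so measured λ varies by ~9 % between G~Na~ = 0.2 and 5 µS even
  though at a fixed −2 nA probe the difference is 0.02 %.
* **APD** (`measureAPD()`).  From the maximum-upstroke instant to 90 %
  repolarization toward the pre-stimulus rest (APD90; the level is a
  parameter and the package's qualitative claims are insensitive to it).

# Sweeps

`runSweep()` drives independent-G~Na~, independent-G~K1~ and reciprocal
(tandem) sweeps; in reciprocal mode a G~K1~:G~Na~ ratio a:b maps the grid
value g to (G~K1~, G~Na~) = (g, g·b/a), so the grid always indexes G~K1~.
`buildPaperGrids()` returns the study ranges (G~Na~ 0.2–5 µS, G~K1~
0.3–5 µS with 0.1 µS resolution across the 1–1.5 µS excitability
boundary, eight G~gj~ values spanning 0.1–20 µS), and
`summarizeShape()` classifies threshold curves as monotone, biphasic or
triphasic by counting sign changes of successive differences above the
0.5 nA search resolution.  Full figure-level sweeps are hours of compute;
the shipped tests run the scaled-down versions (three-point grids per
axis) that pin the trends.

# Verification strategy and what it does not show

The synthetic inputs here are parameter configurations, not data, so
verification leans on analytic oracles:

* a **passive fiber fixture** (`passiveFiberFixture()`) whose membrane is
  exactly g~m~(V − E~rest~), run through the *identical* assembly,
  integrator and fitting code as the ionic model (the 21 non-voltage
  state slots are frozen), and
* the **closed-form discrete cable**: the steady deviation decays per
  cell by 1/r with r + 1/r = 2 + g~m~/G~gj~, giving λ = 1/ln r
  (`analyticSpaceConstant()`), which approaches √(G~gj~/g~m~) in the
  continuum limit.

Simulated steady states, a dense linear solve of the resistive ladder and
the closed form agree to well under 2 %, and the fitted λ on the fixture
matches the closed form to machine precision — so a λ disagreement on the
ionic fiber reflects the membrane model, not the machinery.

What passing these tests does **not** show: the cell model is one dialect
of the guinea-pig reference lineage reconstructed without access to the
original code, and dialect differences move absolute plateau quantities.
In this dialect the fiber AP peaks near +42 mV (the lineage's usual
overshoot) rather than the ~+20 mV reference value, and the APD90 at
G~K1~ = 0.25 µS reaches ≈ 0.6 s rather than exceeding 1 s, although the
steep APD growth toward low G~K1~ (195 ms at 0.5 µS, 8.8 ms at 5 µS) and
every threshold/conduction/space-constant anchor are reproduced.  Real
tissue, with heterogeneity, 2-D/anisotropic geometry, ephaptic coupling
and subcellular channel localization, is outside the model class.

# Problem sizes used by the shipped tests

Unit tests run on 2–20-cell fibers and single cells; the acceptance
checks use the full 100-cell study fiber for thresholds, conduction
velocity and the excitability boundary, three-point grids for the
scaling-law slopes, and the {1.3, 1.4} µS pair for the boundary.  A full
figure-level reproduction (dense grids × eight G~gj~ values) is available
through `buildPaperGrids()`/`runSweep()` as a long-running batch job.

# A worked example

```{r example}
library(fiberAP)

params <- cellParameters()          # G_K1 = G_Na = 0.5 uS
thr <- findCellThreshold(params)
thr                                  # about -19.5 nA on the 0.5 nA grid

fiber <- fiberConfig()               # 100 cells, G_gj = 10 uS
fthr <- findFiberThreshold(fiber)
cv <- measureCV(fiber, threshold = fthr@threshold)
cv                                   # about 70 cm/s

lam <- measureSpaceConstant(fiber)
lam                                  # about 10.9 cell lengths
```
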