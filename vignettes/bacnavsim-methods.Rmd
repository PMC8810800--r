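---
title: "Methods: BacNav insertion, monodomain tissue, and protocol choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: BacNav insertion, monodomain tissue, and protocol choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the models it implements,
the protocol parameters that matter, the numerical choices behind the
solvers, and the limits of what the simulations show.

## 1. The BacNav channel model

The engineered prokaryotic sodium channel (NavSheP D60A, codon-optimized
variant h2SheP) is modeled as a Hodgkin–Huxley conductance with a single
activation gate and a single inactivation gate,

$$I_{BacNav} = X\,\bar g_{1X}\, m\, h\,(V_m - E_{rev}),$$

with the fitted voltage dependences implemented in `tau_m()`, `tau_h()`,
`m_inf()`, `h_inf()`. Three aspects of this current law are assumptions,
because only the gating functions are pinned down by the fits:

* **Current law and gate exponent.** An ohmic driving force and exponent 1
  on each gate is the simplest form consistent with the two-gate fit. No
  GHK flux or higher gate exponents are used.
* **Reversal potential.** The channel is sodium-selective, so `E_rev`
  defaults to the host model's sodium Nernst potential (about +67 mV in
  the human host, +54 mV in the guinea-pig host with its fixed
  concentrations); it is configurable.
* **Window current.** The steady-state curves overlap weakly
  ($m_\infty h_\infty \approx 2\times10^{-3}$ near $-12$ mV). This
  persistent component is a genuine prediction of the fitted curves and
  matters at high expression (Section 6).

Gates advance by exact exponential (Rush–Larsen) relaxation, which is
unconditionally bounded and stable for the very steep slope factors
(0.2351 and 0.1281 mV) in the time-constant denominators; exponential
arguments are clamped at ±700 before evaluation so no voltage can overflow
a double.

## 2. Host myocyte models

* **Human**: the O'Hara–Rudy (2011) adult ventricular myocyte,
  endocardial parameterization. The source experiments do not state
  the cell subtype; endocardial is the default and the conductance
  registry (`gNa_scale`, `gto_scale`, `gKs_scale`, ...) exposes the
  subtype-defining conductances if a user wants to build mid/epi variants.
  "Reduced excitability" scales both the fast and late sodium
  conductances, since both are carried by Nav1.5.
* **Guinea pig**: a Luo–Rudy-lineage ventricular myocyte: the 1991 fast
  sodium current, slow inward (Ca) current and time-independent potassium
  currents, with the delayed rectifier split into rapid and slow
  components (Zeng–Rudy forms) and a two-gate transient outward current
  added. The split is required because the transmural experiments
  parameterize layers by their IKs:IKr conductance ratio and maximal Ito.
  The Ito activation midpoint (+10 mV, slope 9) was set so the *healthy*
  transmural baseline shows the canonical epicardial spike–notch–dome; the
  Brugada phenotypes then follow from the disease multipliers alone.
* **Toy**: a two-variable Aliev–Panfilov-type excitable cell mapped onto a
  voltage-like scale, used only for solver verification (threshold
  behavior, APD against a fine-step reference, $\sqrt D$ scaling of cable
  CV, charge conservation with the membrane model effectively disabled).

Integration is forward Euler for the membrane potential and
concentrations and Rush–Larsen for all gates, `dt = 0.01` ms by default.
Halving the step from the default changes APD80 by well under 0.5% and the
upstroke overshoot by under 1%; from `dt = 0.005` both change by under
0.5% (tested), and cable/tissue CV changes by under 3% under temporal or
spatial refinement.

## 3. Expression calibration (the "1X" level)

`calibrate_1x()` defines 1X expression as the conductance at which the
peak simulated voltage-clamp BacNav current equals the peak endogenous
Nav1.5 current of the same cell, under a holding potential of −80 mV with
500 ms steps from −50 to +50 mV in 10 mV increments (the patch protocol;
the original simulation protocol is not printed anywhere, so the
experimental one is adopted). Peaks are signed extrema compared by
magnitude; the search is a deterministic log-space bisection with a
monotonicity check across the bracket, and calibration is per species.

## 4. Tissue: geometry, coupling, stimulus, measurement

* **Monodomain reduction.** One node per 100 µm cell;
  $D = a/(2 R_i C_m)$ with radius $a$ = 10 µm, $R_i$ = 0.4 kΩ·cm,
  $C_m$ = 1 µF/cm², giving $1.25\times10^{-3}$ cm²/ms. The 2D grid
  (100×100 nodes, $dx = dy$ = 0.01 cm) uses the same coefficient
  isotropically with a 5-point Laplacian. Obstacle nodes carry no membrane
  model and all their conductive connections are dropped — identical in
  effect to setting those connectivities to zero — which also implements
  the no-flux outer boundary. Charge conservation of this severing is
  tested directly (pure-diffusion voltage integral conserved to
  round-off).
* **Initial state.** Tissue runs tile the single-cell equilibrium: the
  *host* cell is paced to the convergence criterion (relative per-beat
  state change below 0.01% here, with the strict 0.001% available), and
  BacNav is then attached with its gates at steady state for the resting
  potential. Attaching after pre-pacing resolves the otherwise unspecified
  initial gate values and keeps the diastolic starting state identical
  across expression levels.
* **Stimulus.** Rectangular 1 ms pulses at twice the diastolic threshold
  of the *coupled* configuration, found by bisection in situ (the
  single-cell threshold fails against the electrotonic load of resting
  neighbors). For configurations where no amplitude launches a wave —
  true conduction block, e.g. 50% sodium conductance — the fallback
  threshold is local capture of the stimulated nodes, so block runs still
  have a defined stimulus. Cables stimulate their first 3 cells; 2D
  tissue stimulates a **15×15-node corner patch**. A 5×5 patch was tried
  first and proves unable to launch a surviving wave in the 15%-obstacle
  tissue at any amplitude (the convexly curved front dies within a few
  millimetres, while a planar wave crosses the same field), so the larger
  source region is the smallest one that reproduces the corner-paced
  fibrotic experiment at all. If the launched wave still dies short of the
  field, the amplitude is doubled (at most twice, capped at 400 µA/µF)
  before block is declared: conduction block means failure at any stimulus
  strength, as in experimental pacing practice. This distinction is
  physical — the 15%-random fields conduct fully once the source is
  adequate, while the 20%-vertical field stalls at the same isthmuses at
  every amplitude. A minority of 15%-random realizations do block even at
  the strongest source: the field sits near the percolation/propagation
  margin of this host (whose homogeneous CV runs ~12% below the reported
  44 cm/s). Averages of the obstacle-tissue CV are
  therefore taken over conducting realizations — a blocked map has no CV —
  with blocked realizations reported as such.
* **Activation and CV.** Activation time is the instant of maximum
  $dV_m/dt$, gated on an upward crossing of −20 mV. Cable CV is the
  least-squares slope of position on activation time over the central
  window (cells 30–70). The 2D average CV is the median of local speeds
  $1/|\nabla T|$ from central differences at interior nodes with fully
  activated neighborhoods, after discarding the top and bottom 5%; it is
  validated against planar and circular analytic fronts (exact, and
  within 3%). No region around the pacing corner is excluded; the trimmed
  median makes the estimate insensitive to that choice.
* **Protocols.** Cables run 2 conditioning propagated beats before the
  measured beat. 2D tissue and the transmural cable measure the first
  propagated beat from the tiled equilibrium — the measurement the
  original experiments report — and stop integrating once every node
  has activated (or no node has newly activated for 25 ms, i.e. the front
  has died), which only truncates post-measurement quiescence.

## 5. Transmural Brugada cable and pseudo-ECG

165 guinea-pig cells (60 endocardial, 45 midmyocardial, 60 epicardial)
with per-layer maximal Ito (0 / 0.2125 / 0.25 mS/µF) and IKs:IKr ratios
(11:1 / 4:1 / 35:1, gKr held at its base value — absolute magnitudes are
not printed in the source material, so the ratio-only construction is an
assumption and ECG morphology is interpreted qualitatively). Brugada
severity divides the fast inactivation time constant of the endogenous
sodium current by 1.5 (mild) or 3.5 (severe) and multiplies Ito by 3 or 7.
Pacing is at the guinea-pig sinus rate, 3.33 Hz.

The pseudo-ECG is the lead-field sum
$\phi_e = \frac{a^2\sigma_i}{4\sigma_e}\sum_x(-\partial_x V_m)\,\partial_x(1/r)\,dx$
at an electrode 2 cm beyond the epicardial end on the fiber axis,
evaluated with central differences and checked against fine quadrature of
the same integral on an analytic travelling wave (within 1%). The
conductivities only scale the amplitude, and every reported readout (J
point, deviation score, dose ordering) is scale-invariant, so
$\sigma_i/\sigma_e = 1$ by default. The deviation score is the plain L1
distance between a trace and the healthy trace after resampling both to
1 kHz.

**Dome detection.** A re-ascent rule thresholded at 0 mV misclassifies
this host: its dome apex sits near 0 mV and healthy endocardial APs have
no phase-1 notch at all. The implemented rule
(`has_dome()`) therefore declares a dome when either (a) a phase-1 local
minimum within 60 ms of the peak is followed by a secondary maximum at
least 5 mV higher and above −20 mV, or (b) the potential stays above
−20 mV continuously for 25 ms (a plateau without a notch is a dome). The
−20 mV level sits between this host's dome apex and its collapsed/resting
range and was anchored on the healthy baseline, not on the disease cases.

## 6. The calibrated expression level and repolarization failure

One finding of this implementation deserves emphasis. Peak-current
matching yields $\bar g_{1X} \approx 7.7$ mS/µF in the human host (peak
Nav1.5 current ≈ 192 µA/µF from −80 mV holding) and ≈ 30 mS/µF in the
guinea-pig host. At those conductances the BacNav window current near
−12 mV (about $2\times10^{-3}\,\bar g X \cdot 65$ mV) exceeds both hosts'
repolarization reserve once $X \gtrsim 0.4$, creating a stable
depolarized equilibrium: the action potential never terminates and 1:1
capture is lost on subsequent beats. Consequences:

* Single-beat measurements (tissue activation maps, average CV, the
  transmural ECG of the measured beat) are unaffected — the failure is
  post-beat — and BacNav doses strongly *improve* excitability, upstroke,
  and conduction on that beat, including full rescue of the
  obstacle-induced slowing at 0.5X.
* Multi-beat dose-series properties (APD80 stability across 0–2X,
  CV monotonicity with conditioning beats, parts of the mild-Brugada dose
  response) cannot all hold at the literally calibrated level in these
  hosts. The package reports these outcomes as they are; the calibration
  routine and the gating equations are implemented exactly as defined,
  and no parameter was adjusted to mask the inconsistency. The
  biologically interesting reading is that the fitted inactivation curve
  places an upper bound (here, well below the peak-matched level) on
  therapeutically tolerable expression.

## 7. Synthetic data and what passing tests do not show

The toy excitable cell, the analytic activation fields (planar, circular,
Gaussian travelling wave), and the seeded obstacle generators are
first-class, tested code. They verify the *solvers and estimators* —
front-speed recovery, $\sqrt D$ scaling, lead-field quadrature, exact
obstacle counts, seed reproducibility — not cardiac biology. Passing them
shows the numerical machinery is sound at the stated tolerances; it does
not validate the ionic models against experimental recordings, fiber
anisotropy, bidomain effects, or 3D geometry, all of which are outside
this package's scope.

## 8. Problem sizes and determinism

Default experiment sizes are the study's own: 100-cell (1 cm) cables, a
100×100-node (1 cm²) sheet, a 165-cell transmural cable. Pre-pacing uses
a 50-beat budget at a 0.01% per-beat criterion (the strict 0.001%
criterion and 200-beat budget are available through the API); convergence
flags are always recorded and honest. Every stochastic geometry records
its seed, masks are reproducible from the seed alone, and repeated runs
with the same configuration and seed produce bitwise-identical summaries.
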