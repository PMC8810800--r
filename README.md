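# bacnavsim

Simulation platform for evaluating engineered **bacterial voltage-gated
sodium channels (BacNav)** as a cardiac gene therapy, in R with a compiled
(Rcpp) monodomain core.

Mammalian sodium channels are too large to package in AAV vectors;
prokaryotic channels such as the engineered NavSheP D60A variant (h2SheP,
~0.9 kb) are not. This package implements an in-silico test bed for that
idea: a Hodgkin–Huxley model of the h2SheP channel is inserted as an
additive current into adult ventricular myocyte models and exercised in
single cells, 1D cables, 2D fibrotic tissues, and a transmural
Brugada-syndrome cable with a pseudo-ECG readout. It is aimed at cardiac
electrophysiology modelers who want to reproduce, probe, or extend the
simulated (not wet-lab) results of that platform.

## The model

The channel carries one activation gate `m` and one inactivation gate `h`,

```
I_BacNav = X · ḡ_1X · m · h · (V_m − E_Na)          [µA/µF]
dg/dt    = (g_∞(V_m) − g) / τ_g(V_m),   g ∈ {m, h}
```

with fitted steady-state curves and asymmetric bell-shaped time constants

```
τ_m = 34.65 / (exp((V+43.47)/14.36) + exp(−(V+15.75)/0.2351)) + 1.66   [ms]
τ_h = 107.8 / (exp((V+27.15)/0.1281) + exp(−(V+25.63)/25.19)) + 9.593  [ms]
m_∞ = 1 / (1 + exp((−22.5 − V)/2.704))
h_∞ = 1 / (1 + exp((V + 77.05)/10.64))
```

`X` is the expression level; `1X` is defined by matching the simulated peak
voltage-clamp BacNav current to the peak endogenous Nav1.5 current of the
host cell (`calibrate_1x()`). Hosts: the O'Hara–Rudy human adult
ventricular myocyte (endocardial) and a Luo–Rudy-lineage guinea-pig
myocyte with split IKr/IKs and a transient outward current for transmural
work. Tissue is a continuous isotropic monodomain with
`D = a/(2·R_i·C_m) = 1.25·10⁻³ cm²/ms` from the printed geometry (cell
radius 10 µm, R_i = 0.4 kΩ·cm); nonconducting fibrotic obstacles are nodes
whose conductive connections are severed.

## Worked example

```r
library(bacnavsim)

# BacNav gating: depolarized asymptotes and midpoints
tau_m(200)     # 1.66 ms
tau_h(100)     # 9.593 ms
m_inf(-22.5)   # 0.5

# a paced human ventricular myocyte
cell <- build_cell("human")
pr   <- pace_to_equilibrium(cell, rate_hz = 1, criterion_pct = 0.01,
                            max_beats = 50)
ap   <- simulate_ap(pr$cell)
attr(ap, "features")
#> AP features: RMP -87.8 mV, APA 129.1 mV, dV/dt max 212 V/s
#>   APD (ms): apd20=122.2, apd50=206.5, apd80=254.2, apd90=267.3

# fibrotic 2D tissue: 15% of 10,000 nodes disconnected
mask <- generate_random_obstacles(100, 100, fraction = 0.15, seed = 1)
sum(mask)      # 1500
r <- run_tissue(mask, species = "human", seed = 1)   # ~2-3 min
r
#> <tissue_result> human, 1500 obstacles: activated 99.9 %, average CV = 37.9 cm/s
```

The RMP/APA/APD values are the equilibrium AP of the human host model; the
tissue run reports the average conduction velocity of a corner-paced wave
from the trimmed median of local activation-time gradients. In this
framework healthy tissue conducts at 38.7 cm/s and the 15%-obstacle average
over three seeded fields is 34.8 cm/s.

Configured experiments (the full canonical set: dose series, cable rescue,
obstacle tissues, Brugada ECGs) are shipped as YAML under `inst/configs/`
and run with `run_experiment()`, or from a shell via
`Rscript inst/cli/bacnavsim.R <verb> ...`.

## Scientific caveats

The repository's methods vignette (`vignettes/bacnavsim-methods.Rmd`)
documents the model assumptions, protocol choices, and one substantive
finding: with these fitted gating curves, peak-current matching against
adult-host sodium currents implies a BacNav window current that prevents
full repolarization at expression levels ≥ ~0.4X, which bounds the regime
in which the dose-series properties can hold. See the vignette before
interpreting high-dose simulations.
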