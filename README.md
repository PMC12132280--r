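# ncrcircuit

Mechanistic modelling and measurement analysis of **winner-takes-all (WTA)
resource competition** in two-module synthetic gene circuits, and of its
mitigation by a CRISPRi-based **negatively competitive regulation (NCR)**
controller.

## The problem

Two self-activating gene modules on the same plasmid — an AraC/pBAD/GFP
module (M1, induced by L-arabinose) and a LuxR/pLux9/RFP module (M2,
induced by 3-oxo-C6-HSL) — compete for the host's shared expression
machinery. With positive feedback in each module, this competition is
destabilising: instead of coactivating, the circuit collapses into a
winner-takes-all state where one module monopolises resources and silences
the other, in both the dual self-activation (DSA) topology and the
cascading bistable switch (CBS), where the modules additionally
cross-activate.

The NCR controller counteracts this with a deliberately *limited* control
resource: chromosomal dCas9, induced by aTc through pTet, is shared by two
sgRNAs (sg-pBAD, sg-pLux9), each co-expressed from its own module's
promoter and targeting that same promoter. The more active module makes
more sgRNA, sequesters more dCas9 into its own repressing complex, and
thereby simultaneously increases its self-inhibition and relieves the
inhibition of the weaker module — pushing the circuit toward balanced
coactivation. The package is aimed at synthetic biologists who want to
explore this mechanism quantitatively and at analysts reproducing the
associated flow-cytometry / plate-reader computations.

## The model

For each module *i* with protein `x_i` and sgRNA `g_i` (au, time in h):

```
a_1 = x_1 · H(ara; θ_ara, n_ara)              (CBS: (x_1 + w·x_2) in place of x_1)
a_2 = x_2 · H(C6;  θ_c6,  n_c6)               (CBS: C6 + k_syn·x_1 in place of C6)
P_i = [ basal_i + (α_i − basal_i) · H(a_i; K_i, n_i) ] · R_i       promoter demand
R_i = 1 / (1 + (c_i/Kc_i)^m)                  CRISPRi repression (M2: occupancy
                                               divided by 1 + a_2/Ka, Lux-box overlap)
c_i = d_tot · (g_i/Kd) / (1 + g_1/Kd + g_2/Kd)  competitive dCas9 partition
d_tot = d_basal + d_max · H(aTc; θ_atc, h_atc)
ρ_i = P_i / (1 + P_1/J_1 + P_2/J_2)           shared-resource allocation
dx_i/dt = ρ_i − δ·x_i
dg_i/dt = κ_g·P_i − γ_g·g_i                   (sgRNAs bypass the ribosome bottleneck)
```

with `H(u; θ, n) = u^n/(θ^n + u^n)`. In the non-targeting control circuits
both complexes are identically zero. The study reports no kinetic
constants, so the shipped defaults are a calibrated design choice (see the
methods vignette in `vignettes/`).

On top of the ODE core the package provides multi-start steady-state
analysis with stability, hysteresis and phase-diagram scans,
extrinsic-noise population simulation emitting flow-cytometry-like event
tables (FSC-A/FSC-H, GFP, RFP; 10,000 events and n = 3 replicates by
convention), the quadrant-gating analysis pipeline (singlet gate,
blank-quantile thresholds, fate fractions with mean ± s.d.), plate-reader
GFP/OD dose-response extraction, and seeded synthetic-data generators with
planted ground truth.

## Worked example

The flagship experiment: fix L-arabinose at 1.25e-3 % and aTc at 15 ng/mL,
raise C6 to 178 nM, and compare the control circuit (non-targeting
sgRNAs) with the NCR circuit:

```r
library(ncrcircuit)
p    <- defaultCircuitParams()
cond <- inducers(lAra = 1.25e-3, c6 = 178, atc = 15)

attractorFromOff(topology("DSA", "non_targeting"), cond, p)
#> SteadyState <M2_only> (stable)  |rhs| = 5.66e-11
#>      x1      x2      g1      g2
#>  0.9078 44.2900  1.5200 74.1600

attractorFromOff(topology("DSA", "targeting"), cond, p)
#> SteadyState <coactivation> (stable)  |rhs| = 6.01e-10
#>    x1    x2    g1    g2
#> 15.19 19.00 13.24 16.56
```

Under the control circuit, M2 wins (x2 = 44.3 au, M1 silenced at 0.9 au):
winner-takes-all. With the NCR controller both modules settle at
intermediate, balanced levels (15.2 and 19.0 au) — coactivation. The same
condition at population level, with extrinsic cell-to-cell noise, three
replicate samples and quadrant gating:

```r
tabs <- lapply(1:3, function(s)
  simulatePopulation(topology("DSA", "targeting"), cond, p, noiseModel(),
                     nEvents = 2000, seed = s, replicate = s))
fractionSeries(tabs, gateConfig())[[1]]
#> FateFractions over 3 replicate(s)
#>           OFF  M1_only  M2_only coactivation
#> mean 0.001579 0.002105 0.196700      0.79960
#> sd   0.001053 0.000000 0.005869      0.00489
```

80% of simulated cells land in the GFP-high/RFP-high quadrant, against
~14% for the control circuit at the same dose.

A command-line entry point wrapping the same functions ships in
`inst/cli/ncrtool.R` (subcommands `simulate | scan | flow | plate |
generate`, YAML configs; see `?ncrMain`).

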