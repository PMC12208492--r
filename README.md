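# gnpneuro

Electrodiffusive modelling of ion channels and whole-neuron dynamics in R.

Conductance-based neuron models treat every channel as an ohmic conductor,
yet the ionic currents they describe are electrodiffusive: driven jointly by
voltage and by concentration gradients across the membrane. `gnpneuro`
implements the closed-form bridge between the two pictures. Assuming bulk
electroneutrality, the membrane conductance of an ion with valence $z_q$ is

$$G_q = \frac{z_q^2 F^2}{RT}\,P_q\,\bar c_q,$$

where $P_q$ is the permeability and $\bar c_q$ the harmonic mean of the
intramembrane concentration profile — a quantity that moves with voltage and
with the bath concentrations, which is exactly Goldman rectification. On
this foundation the package provides:

* **Single-channel characterization** — calibration of single-channel
  permeabilities from a measured linear conductance (GABA<sub>A</sub>,
  AMPA and leak presets), per-ion current decomposition, and the paired
  "apparent" and "latent" conductance/reversal descriptions of
  multi-permeant pores, including their exact reproduction of the total
  I-V curve.
* **Seven whole-neuron variants** (`chh`, `fgnp`, `gnp`, `vgnp`, `kvgnp`,
  `navgnp`, `ihh`) over a closed two-compartment ion budget with
  Na<sup>+</sup>/K<sup>+</sup>-ATPase pump balance. In the
  electrodiffusive family the membrane voltage is slaved algebraically to
  the net charge imbalance (~1.2×10<sup>4</sup> mV/mM), so spikes ride on
  micromolar concentration changes.
* **Simulation** with a compiled adaptive Dormand–Prince integrator, spike
  detection, firing-state classification (resting / phasic / tonic /
  depolarization block) and sliding-window current-difference analysis
  between model variants.
* **Bifurcation analysis** — fixed points by damped Newton on a
  charge-consistent reduced system, full-system eigenvalue stability,
  continuation over the pump current, and saddle-node/Hopf detection for
  the stability of the depolarization-block state.

It is aimed at computational neurophysiologists who want rectifying,
concentration-aware channels inside an otherwise familiar
Hodgkin–Huxley-style workflow.

## Worked example

```r
library(gnpneuro)

# calibrate the GABAA channel from its 30 pS linear recording conditions
gabaa_channel("calibration")
#> Channel 'GABAA' (Sc = 7.854e-19 m^2)
#>   Cl    z=-1  P = 7.031e-02 m/s  [i/o] = 147/145 mM
#>   HCO3  z=-1  P = 1.406e-02 m/s  [i/o] = 15/25 mM

# its zero-current potential at physiological (low intracellular chloride)
# concentrations, where the channel rectifies outwardly
apparent_conductance_reversal(gabaa_channel("physiological"), 0)$Ec_a
#> [1] -62.40743

# the resting state of the electrodiffusive neuron is a genuine fixed point
# of the coupled ion-balance + charge-voltage system
m <- gnp_model("gnp", pump = pump_spec("concentration_dependent", M_NaK = 0.3))
find_fixed_point(m)
#> <gnp_fixed_point> gnp: V = -68.174 mV, INaK = -1.158 uA/cm^2 [stable]
#>   [K]o = 3.1660, [Na]i = 23.5757, [Cl]i = 10.4126 mM
#>   leading eigenvalues (1/ms): -11.7+0i, -0.682+0i

# where does the depolarization-block state lose stability as the pump
# strengthens?
hb <- db_hopf_point("vgnp", INaK_range = c(-12, -20), step = 0.25)
sprintf("Hopf at INaK = %.2f uA/cm^2 (V = %.1f mV)", hb$INaK_HB, hb$V_HB)
#> [1] "Hopf at INaK = -18.01 uA/cm^2 (V = -37.6 mV)"
```

The permeabilities are the published single-channel values for the
GABA<sub>A</sub> channel; the −62.4 mV reversal is the composite-permeant
(apparent) zero-current potential; the fixed point reproduces the canonical
resting state of the model family digit for digit; and the Hopf point is
the pump current beyond which the depolarization-block plateau of the
electrodiffusive model starts to oscillate and collapse — it sits at a
larger |I<sub>NaK</sub>| than in the matched conductance-based model
(`db_hopf_point("ihh", ...)` gives −14.96 µA/cm²), which is why a pump
capped at 16.87 µA/cm² can rescue the conductance-based neuron from block
but not the electrodiffusive one.

A thin command-line front end wraps the same functions:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/gnp.R", package="gnpneuro"))')" \
    characterize --channel ampa --out ampa_iv.csv
```

with subcommands `characterize`, `simulate`, `bifurcate`, `fitfq` and
`fixtures`; every table is written as CSV with a JSON metadata sidecar
recording the fully resolved parameter set.

## Reproduction script

`scripts/acceptance.R` recomputes the package's headline quantities from
scratch — the four calibrated single-channel permeabilities, the
GABA<sub>A</sub> apparent reversal, the leak potassium and chloride
conductances at rest, the resting potential of the electrodiffusive fixed
point under a constant pump, and the Hopf pump currents of the
depolarization-block branches in the electrodiffusive and conductance-based
models — and writes them as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

All computations are deterministic; the seed only fixes the interface.

See the methods vignette (`vignettes/gnpneuro-methods.Rmd`) for the model
equations, the numerical design (singularity handling, the
charge-consistent Newton reduction, the invariant-leaf treatment of the
circuit-form variant), and an honest account of which published behaviors
the default parameter set does and does not reproduce.
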