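---
title: "Electrodiffusive neuron modelling with gnpneuro: models, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Electrodiffusive neuron modelling with gnpneuro}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gnpneuro)
```

## The model

`gnpneuro` treats the neural membrane as a thin slab separating two
well-mixed compartments of a closed system. Ions cross the slab by
electrodiffusion; assuming bulk electroneutrality, the electric field inside
the slab is uniform and the steady intramembrane concentration profile of an
ion with valence $z_q$ is exponential in the dimensionless potential
$u = z_q F V / RT$. Integrating the reciprocal profile gives the harmonic
mean concentration $\bar c_q$, and with it the central identity of the
package: membrane conductance per unit area is

$$G_q = \frac{z_q^2 F^2}{RT} P_q\, \bar c_q,
\qquad
\bar c_q = \frac{[q]_i - [q]_o e^{-u}}{1 - e^{-u}}\cdot\frac{V}{V - E_q},$$

where $P_q$ is the membrane permeability (m/s) and $E_q$ the Nernst
potential. The GHK current then takes the chord form
$I_q = -G_q (V - E_q)$, with the sign convention that positive current
depolarizes ($C_m \dot V = \sum_q I_q$). Because $\bar c_q$ moves with both
voltage and concentrations, conductance is not a constant: an
intracellular-rich ion (K$^+$) sees its $\bar c$ grow with depolarization
(outward rectification), an extracellular-rich ion (Na$^+$, Ca$^{2+}$)
sees it shrink (inward rectification), and the rectification vanishes as
the gradient does.

At the single-channel level the same mathematics yields two equivalent
descriptions of a multi-permeant pore:

* the *apparent* pair $(g_{c,a}, E_{c,a})$, built from a composite permeant
  $[C] = \sum_k (P_k/P_1)[k]$ — defined only when all permeants share one
  unit valence, with a voltage-independent reversal;
* the *latent* pair $(g_{c,l}, E_{c,l})$ — the per-ion conductance sum and
  the conductance-weighted reversal — valid for any valence mix but
  voltage-dependent even when the total I-V curve is a straight line.

Both reproduce the summed per-ion GHK currents identically; the package
tests enforce this to $10^{-9}$ relative. A two-permeant channel is exactly
linear when $P_2/P_1 = -\Delta c_1/\Delta c_2$; inverting that relation
against a measured linear slope (30 pS for both the GABA$_A$ and AMPA
channels, 5 Å pore) calibrates the single-channel permeabilities. The
effective pore cross-section used by the presets is
$S_c = \pi (5\times10^{-10}\,\mathrm{m})^2$; this is the value under which
the published permeabilities, the published channel densities ($10^7$ leak
and $4\times10^6$ AMPA channels per cm$^2$) and the averaged membrane
permeabilities all close on each other exactly.

## The whole-neuron variants

All variants share reduced Traub–Miles (RTM) gating ($m, h, n$, rates in
ms$^{-1}$, removable singularities at $-54$ and $-52$ mV evaluated by
series) and a Na$^+$/K$^+$-ATPase pump, either constant or
concentration-dependent with saturation bound $(vF/S)M_{NaK}$
(16.87 µA/cm$^2$ at $M_{NaK} = 0.70$ mM/s). The closed system tracks
$[K^+]_o$, $[Na^+]_i$, $[Cl^-]_i$; the complements follow from the
conservation constants $\sigma_K = 100$, $\sigma_{Na} = 155$,
$\sigma_{Cl} = 145$ mM.

| variant | voltage | leak | glutamate | voltage-gated |
|---|---|---|---|---|
| `gnp` | algebraic (charge relation) | GHK | GHK | circuit (RTM) |
| `vgnp` | algebraic | GHK | GHK | GHK / $f_q(V)$ |
| `kvgnp`, `navgnp` | algebraic | GHK | GHK | mixed |
| `fgnp` | explicit $\dot V$ | GHK (frozen conc.) | linear | circuit |
| `chh` | explicit $\dot V$ | linear ($G_{LH}, E_{LH}$) | linear | circuit |
| `ihh` | explicit $\dot V$ | linear, per-ion | linear, per-ion | circuit |

For the GNP family the voltage is *not* integrated: it is slaved to the net
charge imbalance, $V = \frac{vF}{2 S C_m}\big({-[A^-]_i} + \sum_q z_q([q]_i
- [q]_o)\big)$, with a sensitivity of $\approx 1.2\times10^4$ mV per mM.
Action potentials are therefore carried by micromolar-scale concentration
changes — the package's tests confirm net-charge concentrations stay at the
µM scale through firing, and that all per-ion changes remain below 0.1 mM
across the first nine spikes of a sustained response.

The $f_q(V)$ correction aligns the GHK-format gated currents with the RTM
circuit form at steady-state concentrations: $f_q$ is the cubic
least-squares fit of the pointwise ratio $I'_{qV}/I_{qV}$ (gate factors
cancel), fitted on a 1 mV grid over $[-100, 50]$ mV — the range covering
the spike excursion. The fitting protocol behind the published coefficient
quadruples is not documented, so those quadruples are shipped as fixtures
and used for all reproduction targets, while `fit_fq()` is
validated by self-consistency (dividing the GHK form by a freshly fitted
$f_q$ recovers the circuit form to $<2\%$). With the shipped coefficients,
the equivalent maximum conductances at rest evaluate to 19.9 and
30.2 mS/cm$^2$ against the circuit constants 20 and 30.

### The chloride sign

The chloride balance is implemented as
$\mathrm{d}[Cl^-]_i/\mathrm{d}t = -\tfrac{S}{vF} I_{ClL}$, with $I_{ClL}$
the (model-sign) chloride *electrical* current. Because chloride carries
charge $-1$, only this sign keeps the chloride leak diffusive and makes
$C_m \dot V = \sum_q I_q$ hold exactly under the charge–voltage relation
(the conversion factor $\frac{vF}{2SC_m}\cdot 2 \cdot \frac{S}{vF}$ then
reproduces $1/C_m$ identically). With the opposite sign the resting state
acquires a slow positive eigenvalue and every long simulation drifts into
depolarization; the package's stability analysis and long-horizon
behaviors depend on this choice.

### A structural note on the circuit-form `ihh` variant

Because the circuit model integrates $V$ independently of the ionic
bookkeeping, the quantity $V - \frac{vF}{2SC_m}(\text{net charge})$ is an
exact constant of motion of `ihh`: its fixed points come in one-parameter
families, one per invariant leaf. The package computes `ihh` equilibria on
the leaf through the canonical initial condition — the leaf every
simulation started from the standard state lives on — and excludes the
structurally zero eigenvalue from stability calls. This is not a numerical
trick but the faithful geometry of concentration-augmented
conductance-based models.

## Numerics

* **Units.** Internals are SI (the happy coincidence mM ≡ mol/m$^3$ keeps
  concentrations untouched); public interfaces are mV, mM, µA/cm$^2$,
  mS/cm$^2$, m/s, ms. All removable singularities ($V = 0$, $V = E_q$, the
  RTM rate poles) are evaluated through the entire function
  $g(x) = (1 - e^{-x})/x$ with a series branch below $|x| < 10^{-4}$.
* **Integration.** An adaptive Dormand–Prince 5(4) pair (compiled),
  rtol $10^{-8}$, atol $10^{-10}$ per state variable, steps pinned to the
  sampling grid and to stimulus switch times so the right-hand side is
  smooth within every step. No stiff solver is required in practice: the
  fast gating timescale (~0.03 ms) bounds the step during spikes, and the
  integrator takes ~10$^4$ steps per simulated second at rest.
* **Fixed points.** Newton with damping on a reduced system: gates
  eliminated at $p_\infty(V)$, and for the GNP family the unknowns are
  $(V, [K^+]_o, [Cl^-]_i)$ with sodium eliminated *exactly* through the
  linear charge relation. This removes the $10^4$ mV/mM stiff direction
  that otherwise swamps finite-difference Jacobians. Full-system
  eigenvalues (6-D or 7-D) are computed by central differences in the
  similarity-transformed coordinates $(V, [K^+]_o, [Cl^-]_i, m, h, n)$ —
  eigenvalues are invariant under the linear change of variables, and the
  transformed differences converge over three decades of step size where
  the raw ones do not.
* **Continuation and bifurcations.** Natural-parameter continuation in the
  constant pump current with adaptive step halving and branch-jump
  rejection. Hopf points are sign changes of the leading complex pair's
  real part, refined by bisection to $|\Delta I_{NaK}| < 0.005$ µA/cm$^2$;
  saddle-nodes are real-eigenvalue crossings of appreciable slope (the
  slow charge-drift mode hovers within $10^{-5}$ of zero along whole
  branches and is ignored). The depolarization-block branch is seeded
  either from physics-guided guesses ($V = E_{Cl}$ pins $[Cl^-]_i$; the
  plateau is a *focus*, so candidates without an oscillatory eigenvalue
  pair are rejected as saddle-branch roots) or by simulating into block
  with a strong glutamate pulse under the ceiling pump, as in the
  original protocol.
* **Full-system vs reduced eigenvalues.** The gate-eliminated (reduced)
  system has no complex eigenvalue pair anywhere on the block branch — the
  plateau oscillation lives in the gate dynamics — so Hopf detection must
  (and does) use the full system.

## What the default parameter world does and does not reproduce

The defaults are the published constants, with two reconciliations that the
internal consistency of the published set itself forces:

1. the glutamatergic potassium permeability is $2.82\times10^{-9}$ m/s
   (not $10^{-8}$): only this value agrees with the channel-density
   construction, with $G_{glu} = 0.12$ mS/cm$^2$, and with a $\approx 0$ mV
   glutamate reversal;
2. the canonical steady state ($-68.17$ mV; 3.17, 23.58, 10.41 mM) is the
   fixed point of the concentration-dependent pump at
   $M_{NaK} = 0.3$ mM/s — solving it reproduces every printed digit — and
   the "constant pump current $-1.16$ µA/cm$^2$" is that state's pump
   output rounded; under the rounded constant the fixed point sits 0.11 mV
   away.

With these defaults, every closed-form anchor reproduces: the calibrated
permeabilities, the $-62.3$ mV GABA$_A$ reversal, the leak linearization
constants ($G_{KL} = 0.101$, $G_{NaL} = 0.030$, $G_{ClL} = 0.042$,
$G_{LH} = 0.173$ mS/cm$^2$, $E_{LH} = -61.51$ mV), the pump bound and rest
value, and the two Hopf points of the depolarization-block branches
($-18.01$ µA/cm$^2$ electrodiffusive vs $-14.96$ conductance-based, against
$-17.83$ and $-14.94$ published), including the ceiling consequence: at the
$-16.87$ µA/cm$^2$ pump ceiling the block is stable in the
electrodiffusive model and unstable in the conductance-based one.

The *firing behaviors at the published stimulus strengths* do not
reproduce, and the package deliberately does not tune them into place. The
published glutamate constants are mutually inconsistent at the factor-10
level, and the published behaviors pin an intermediate effective
glutamatergic conductance that matches none of the printed readings:

* the self-consistent printed set (the default) makes the stimulus
  open-probabilities 0.033–0.18 *subthreshold* (drive 0.5–1.5 µA/cm$^2$
  against a ~1.2 µA/cm$^2$ rheobase): no spikes at all;
* scaling both glutamate permeabilities to the alternative printed
  exponent ($G_{glu} \approx 1.2$ mS/cm$^2$) makes the weakest published
  stimulus fire tonically and the tonic one collapse into block within
  seconds;
* the published spike counts, the tonic/block boundary between 0.17 and
  0.18 against the $M = 0.3$ pump ceiling, and the phasic pump rise
  $-1.16 \to -1.41$ µA/cm$^2$ each imply an effective
  $G_{glu} \approx 0.35$–$0.6$ mS/cm$^2$.

The electrodiffusive *mechanisms* behind those behaviors are all verified
in-world at a suprathreshold stimulus ($p_o = 0.2$): the
concentration-feedback loop progressively advances spikes relative to the
concentration-frozen model, all per-ion changes stay below 0.1 mM over the
first nine spikes, net-charge concentrations stay micromolar, and the
concentration-dependent pump grows during the response. Users exploring
the firing regimes should treat the glutamate scale as the free dial it
effectively is (`PKG_m_per_s`, `PNaG_m_per_s`, `Gglu_mS_per_cm2` overrides
in `gnp_model()`).

## Known limitations

* Chloride regulation by cotransport (KCC2/NKCC1) and GABAergic synaptic
  input are outside the model: the chloride leak is the sole chloride
  pathway, so intracellular chloride moves much more slowly than potassium
  or sodium.
* Calcium appears only in single-channel characterization, not in the
  whole-cell variants.
* The intramembrane profile is quasi-static; no spatially resolved
  Poisson–Nernst–Planck solving, no volume dynamics, no multi-compartment
  geometry.
* Limit cycles are not continued; the bifurcation module handles fixed
  points, their stability, and fold/Hopf detection only.
* Rectification mechanisms beyond electrodiffusion (polyamine block,
  Kir-style intrinsic gating, phosphorylation) are not modelled.
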