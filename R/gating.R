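# Reduced Traub-Miles (RTM) gating kinetics, Na/K-ATPase pump models and the
# fq correction linking circuit-form and GHK-form voltage-gated currents.
# Rates are in 1/ms with V in mV, exactly as the rate equations are written.

# x / (1 - exp(-x/k)), the recurring rate shape with limit k at x = 0
.phi <- function(x, k) {
  s <- x / k
  k / .gfun(s)
}

#' RTM gating rate functions
#'
#' Opening/closing rates for the m, h, n gates of the reduced Traub-Miles
#' kinetics. The removable singularities of `alpha_m` (at -54 mV) and
#' `alpha_n` (at -52 mV) are evaluated by their limits.
#'
#' @param V membrane potential (mV), vectorized.
#' @return a list with components `am, bm, ah, bh, an, bn` (1/ms).
#' @export
rtm_rates <- function(V) {
  stopifnot(all(is.finite(V)))
  list(
    am = 0.32 * .phi(V + 54, 4),
    bm = 0.28 * .phi(-(V + 27), 5),
    ah = 0.128 * exp(-(V + 50) / 18),
    bh = 4 / (1 + exp(-(V + 27) / 5)),
    an = 0.032 * .phi(V + 52, 5),
    bn = 0.5 * exp(-(V + 57) / 40)
  )
}

#' Steady-state gate values
#'
#' `p_inf = alpha_p / (alpha_p + beta_p)` for p = m, h, n.
#'
#' @param V membrane potential (mV), vectorized.
#' @return list with `m`, `h`, `n` in (0, 1).
#' @export
gate_steady_state <- function(V) {
  r <- rtm_rates(V)
  list(m = r$am / (r$am + r$bm),
       h = r$ah / (r$ah + r$bh),
       n = r$an / (r$an + r$bn))
}

#' Na+/K+-ATPase pump specification
#'
#' Either a constant pump current or the concentration-dependent sigmoidal
#' pump, whose magnitude saturates at `(vF/S) * M_NaK`.
#'
#' @param mode `"constant"` or `"concentration_dependent"`.
#' @param I_const constant pump current (uA/cm^2; negative at rest).
#' @param M_NaK maximum pump turnover (mM/s, > 0) for the dependent mode.
#' @return an object of class `pump_spec`.
#' @export
pump_spec <- function(mode = c("constant", "concentration_dependent"),
                      I_const = -1.16, M_NaK = 0.3) {
  mode <- match.arg(mode)
  if (mode == "concentration_dependent") stopifnot(M_NaK > 0)
  structure(list(mode = mode, I_const = I_const, M_NaK = M_NaK),
            class = "pump_spec")
}

#' Pump-induced current
#'
#' Constant mode returns `I_const`. The concentration-dependent mode is the
#' product of two sigmoids in intracellular sodium and extracellular
#' potassium scaled by `-(vF/S) M_NaK`, so its magnitude is bounded by
#' `(vF/S) M_NaK` (16.87 uA/cm^2 at M_NaK = 0.70 mM/s with the default
#' geometry).
#'
#' @param Nai intracellular sodium (mM, >= 0), vectorized.
#' @param Ko extracellular potassium (mM, >= 0), vectorized.
#' @param pump a [pump_spec()].
#' @param geom a [membrane_geometry()].
#' @param constants a [phys_constants()].
#' @return current in uA/cm^2 (negative: net outward positive charge).
#' @export
pump_current <- function(Nai, Ko, pump = pump_spec(), geom = membrane_geometry(),
                         constants = phys_constants()) {
  stopifnot(inherits(pump, "pump_spec"), all(Nai >= 0), all(Ko >= 0))
  if (pump$mode == "constant") {
    return(rep(pump$I_const, length.out = max(length(Nai), length(Ko))))
  }
  bound <- pump_current_bound(pump$M_NaK, geom, constants)
  s1 <- 1 / (1 + exp((25 - Nai) / 3))
  s2 <- 1 / (1 + exp(3.5 - Ko))
  -bound * s1 * s2
}

#' Saturation bound of the concentration-dependent pump
#'
#' `(vF/S) * M_NaK` in uA/cm^2.
#' @inheritParams pump_current
#' @param M_NaK maximum pump turnover (mM/s).
#' @export
pump_current_bound <- function(M_NaK, geom = membrane_geometry(),
                               constants = phys_constants()) {
  # M_NaK in mM/s == mol/(m^3 s); (v/S) * F * M_NaK is in A/m^2
  A_per_m2_to_uA_per_cm2(constants$F * M_NaK / geom$S_over_v)
}

#' Voltage-gated currents, circuit (RTM) form
#'
#' `IKV = -GKM n^4 (V - EK)` and `INaV = -GNaM m^3 h (V - ENa)` in uA/cm^2.
#'
#' @param V membrane potential (mV).
#' @param gates list with `m`, `h`, `n` in `[0,1]`.
#' @param EK,ENa reversal potentials (mV).
#' @param GKM,GNaM maximum conductances (mS/cm^2).
#' @return list with `IKV`, `INaV` (uA/cm^2).
#' @export
voltage_gated_currents_rtm <- function(V, gates, EK, ENa, GKM = 20, GNaM = 30) {
  stopifnot(all(gates$m >= 0 & gates$m <= 1), all(gates$h >= 0 & gates$h <= 1),
            all(gates$n >= 0 & gates$n <= 1))
  list(IKV = -GKM * gates$n^4 * (V - EK),
       INaV = -GNaM * gates$m^3 * gates$h * (V - ENa))
}

#' Voltage-gated currents, GHK (electrodiffusive) form
#'
#' The gated GHK currents `I'KV` and `I'NaV`: the GHK current density of the
#' ion at the voltage-gated permeability, multiplied by the RTM gate factors
#' `n^4` and `m^3 h`.
#'
#' @param V membrane potential (mV).
#' @param gates list with `m`, `h`, `n`.
#' @param K,Na [ion_species()] carrying the current concentrations.
#' @param PKV,PNaV voltage-gated permeabilities (m/s).
#' @param constants a [phys_constants()].
#' @return list with `IKV`, `INaV` (uA/cm^2).
#' @export
voltage_gated_currents_ghk <- function(V, gates, K, Na,
                                       PKV = 1.70e-6, PNaV = 1.47e-6,
                                       constants = phys_constants()) {
  list(IKV = gates$n^4 * ghk_current_density(PKV, K, V, constants),
       INaV = gates$m^3 * gates$h * ghk_current_density(PNaV, Na, V, constants))
}

#' Fit the fq normalization of GHK-form gated currents
#'
#' The GHK-form gated current differs from the circuit (RTM) form by a
#' smooth voltage-dependent factor at fixed concentrations; `fq(V)` is the
#' cubic least-squares fit of the pointwise ratio `I'qV / IqV` (the gate
#' factors cancel in the ratio) over a voltage range at steady-state
#' concentrations. Dividing the GHK form by `fq(V)` recovers the circuit
#' form at the fitting concentrations.
#'
#' @param ion an [ion_species()] at the (fixed) fitting concentrations.
#' @param P voltage-gated permeability of the ion (m/s).
#' @param G_M circuit-form maximum conductance (mS/cm^2).
#' @param V_range fitting range (mV); default -100..50 at 1 mV.
#' @param constants a [phys_constants()].
#' @return an object of class `fq_fit`: coefficients `(N3, N2, N1, N0)` of
#'   `fq(V) = N3 V^3 + N2 V^2 + N1 V + N0` plus the fitting range.
#' @export
fit_fq <- function(ion, P, G_M, V_range = seq(-100, 50, by = 1),
                   constants = phys_constants()) {
  Eq <- nernst_potential(ion, constants)
  # ratio of the ungated current factors; remove V ~ Eq where both vanish
  keep <- abs(V_range - Eq) > 0.5
  V <- V_range[keep]
  ratio <- -ghk_current_density(P, ion, V, constants) / (G_M * (V - Eq))
  fit <- stats::lm(ratio ~ I(V^3) + I(V^2) + V)
  cf <- stats::coef(fit)
  coefs <- c(N3 = unname(cf["I(V^3)"]), N2 = unname(cf["I(V^2)"]),
             N1 = unname(cf["V"]), N0 = unname(cf["(Intercept)"]))
  out <- structure(list(coefficients = coefs, ion = ion$name,
                        V_range = range(V_range)),
                   class = "fq_fit")
  if (any(eval_fq(out, V_range) <= 0))
    warning("fitted fq is not positive over the whole range; the conductance ",
            "correction breaks down where fq <= 0")
  out
}

#' Evaluate an fq fit
#'
#' @param fit an `fq_fit` or a numeric vector `(N3, N2, N1, N0)`.
#' @param V voltage (mV), vectorized.
#' @return dimensionless fq(V); no clamping is applied.
#' @export
eval_fq <- function(fit, V) {
  cf <- if (inherits(fit, "fq_fit")) fit$coefficients else fit
  stopifnot(length(cf) == 4L)
  cf[1L] * V^3 + cf[2L] * V^2 + cf[3L] * V + cf[4L]
}

#' Equivalent maximum conductance of a GHK-form gated channel
#'
#' `G'qM = F^2 PqV cbar_q / (RT fq(V))` in mS/cm^2: the voltage- and
#' concentration-dependent counterpart of the circuit model's constant
#' maximum conductance. At the fitting concentrations it reproduces the
#' circuit values (20 and 30 mS/cm^2 for K and Na at rest).
#'
#' @param fit an `fq_fit` or coefficient vector.
#' @param ion [ion_species()] with the current concentrations.
#' @param P voltage-gated permeability (m/s).
#' @param V voltage (mV), vectorized.
#' @param constants a [phys_constants()].
#' @export
equivalent_max_conductance <- function(fit, ion, P, V,
                                       constants = phys_constants()) {
  conductance_per_area(P, ion, V, constants) / eval_fq(fit, V)
}

#' Piecewise-constant stimulus protocol
#'
#' Glutamate stimulation enters the models as the open probability `po(t)`
#' of the AMPA channels, a step schedule of non-overlapping intervals.
#'
#' @param t_on,t_off interval starts and ends (ms).
#' @param po open probabilities in `[0, 1]`, one per interval. Outside all
#'   intervals `po = 0`.
#' @return an object of class `stimulus_protocol`.
#' @examples
#' stim <- stimulus_protocol(t_on = 1000, t_off = 5000, po = 0.065)
#' @export
stimulus_protocol <- function(t_on = numeric(), t_off = numeric(),
                              po = numeric()) {
  stopifnot(length(t_on) == length(t_off), length(po) == length(t_on),
            all(po >= 0 & po <= 1), all(t_off > t_on))
  if (length(t_on) > 1L) {
    o <- order(t_on)
    t_on <- t_on[o]; t_off <- t_off[o]; po <- po[o]
    if (any(t_on[-1L] < t_off[-length(t_off)]))
      stop("stimulus intervals overlap")
  }
  structure(list(t_on = t_on, t_off = t_off, po = po),
            class = "stimulus_protocol")
}

#' Evaluate a stimulus protocol
#' @param stim a [stimulus_protocol()].
#' @param t time (ms), vectorized.
#' @return open probability at `t`.
#' @export
stimulus_po <- function(stim, t) {
  stopifnot(inherits(stim, "stimulus_protocol"))
  out <- numeric(length(t))
  for (i in seq_along(stim$t_on)) {
    sel <- t >= stim$t_on[i] & t < stim$t_off[i]
    out[sel] <- stim$po[i]
  }
  out
}
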