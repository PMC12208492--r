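#' Intramembrane concentration profile
#'
#' Steady-state concentration of an ion inside the membrane at fractional
#' depth `xi = x/d`, with `xi = 0` the extracellular face and `xi = 1` the
#' intracellular face. The profile is exponential in the (linear) potential
#' drop; at `V = 0` it degenerates to the linear interpolation between the
#' two bath concentrations. All removable singularities are evaluated by
#' series, never by division of vanishing terms.
#'
#' @param ion an [ion_species()].
#' @param V membrane potential (mV); scalar.
#' @param xi fractional depth(s) in `[0, 1]`.
#' @param constants a [phys_constants()].
#' @return concentration(s) in mM, same length as `xi`.
#' @export
intramembrane_profile <- function(ion, V, xi, constants = phys_constants()) {
  stopifnot(inherits(ion, "ion_species"), length(V) == 1L, is.finite(V))
  if (any(xi < 0 | xi > 1)) stop("xi must lie in [0, 1]")
  u <- ion$z * V / constants$RT_over_F_mV   # dimensionless zFV/RT
  # c(xi) = c_out + (c_in - c_out) * (1 - exp(-u xi)) / (1 - exp(-u))
  #       = c_out + (c_in - c_out) * xi * g(u xi) / g(u)
  out <- ion$c_out + (ion$c_in - ion$c_out) * xi * .gfun(u * xi) / .gfun(u)
  # boundary conditions hold exactly, not to rounding
  out[xi == 0] <- ion$c_out
  out[xi == 1] <- ion$c_in
  out
}

#' Harmonic mean of the intramembrane concentration profile
#'
#' The quantity that converts permeability into conductance:
#' `cbar = d / integral(1/c(x) dx)`, evaluated in closed form. The closed
#' form has removable singularities at `V = 0` and at the ion's reversal
#' potential; both are handled continuously. In the stable formulation
#' `cbar = c_in * g(delta) / g(u)` with `u = zFV/RT`,
#' `delta = zF(V - Eq)/RT` and `g(x) = (1 - exp(-x))/x`.
#'
#' @inheritParams intramembrane_profile
#' @return scalar concentration (mM); vectorized over `V`.
#' @export
harmonic_mean_concentration <- function(ion, V, constants = phys_constants()) {
  stopifnot(inherits(ion, "ion_species"))
  ci <- ion$c_in; co <- ion$c_out
  if (ci <= 0 && co <= 0)
    stop("harmonic mean undefined: both concentrations are zero")
  # one zero boundary: 1/c(x) diverges at that face and the harmonic mean is 0
  if (ci == 0 || co == 0) return(rep(0, length(V)))
  u <- ion$z * V / constants$RT_over_F_mV
  u_rev <- log(co / ci)                     # u at V = Eq
  delta <- u - u_rev
  ci * .gfun(delta) / .gfun(u)
}

#' Membrane conductance per unit area from permeability
#'
#' `Gq = zq^2 F^2 Pq cbar_q / (RT)`, converted to mS/cm^2. The harmonic-mean
#' concentration makes the conductance voltage- and concentration-dependent,
#' which is the electrodiffusive origin of Goldman rectification.
#'
#' @param P membrane permeability (m/s, >= 0).
#' @inheritParams intramembrane_profile
#' @return conductance in mS/cm^2 (vectorized over `V`).
#' @export
conductance_per_area <- function(P, ion, V, constants = phys_constants()) {
  stopifnot(is.numeric(P), all(P >= 0))
  cbar <- harmonic_mean_concentration(ion, V, constants)  # mM == mol/m^3
  G_SI <- ion$z^2 * constants$F^2 * P * cbar / constants$RT  # S/m^2
  S_per_m2_to_mS_per_cm2(G_SI)
}

# GHK flux factor V * (ci - co e^{-u}) / (1 - e^{-u}) in V*mol/m^3,
# singularity-free (u -> 0 limit (RT/zF)(ci - co)).
.ghk_flux_term <- function(z, V_mV, ci, co, constants) {
  u <- z * V_mV / constants$RT_over_F_mV
  Vv <- mV_to_V(V_mV)
  RT_zF <- constants$RT / (z * constants$F)
  # (ci - co e^{-u})/(1 - e^{-u}) = [(ci - co) - co*expm1(-u)] / (-expm1(-u))
  out <- numeric(length(u))
  small <- abs(u) < 1e-4
  if (any(small)) {
    us <- u[small]
    # series of V*(...) = RT/(zF) * [ (ci-co) + u(ci+co)/2 + u^2 (ci-co)/12 ]
    out[small] <- RT_zF * ((ci - co) + us * (ci + co) / 2 + us^2 * (ci - co) / 12)
  }
  if (any(!small)) {
    ub <- u[!small]
    out[!small] <- Vv[!small] * ((ci - co) - co * expm1(-ub)) / (-expm1(-ub))
  }
  out
}

#' GHK current density of one ion
#'
#' Current density through a membrane of permeability `P` to `ion`, in the
#' model's sign convention `Iq = -Gq (V - Eq)` so that `Cm dV/dt = sum Iq`.
#' A positive value depolarizes (net positive charge entering the cell).
#' Continuous at `V = 0` and at the reversal potential.
#'
#' @inheritParams conductance_per_area
#' @return current density in uA/cm^2 (vectorized over `V`).
#' @export
ghk_current_density <- function(P, ion, V, constants = phys_constants()) {
  stopifnot(is.numeric(P), all(P >= 0))
  flux <- .ghk_flux_term(ion$z, V, ion$c_in, ion$c_out, constants)
  I_SI <- -ion$z^2 * constants$F^2 * P * flux / constants$RT  # A/m^2
  A_per_m2_to_uA_per_cm2(I_SI)
}
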