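#' Ion species
#'
#' An ion with its valence and bath concentrations on the two sides of the
#' membrane. In the closed two-compartment neuron the intracellular and
#' extracellular concentrations of each permeant ion sum to a conservation
#' constant `sigma`; when given, it is checked against `c_in + c_out`.
#'
#' @param name identifier, e.g. `"K"`.
#' @param z integer valence, nonzero (e.g. +1 for K+, -1 for Cl-).
#' @param c_in,c_out intracellular / extracellular concentrations (mM, >= 0).
#' @param sigma optional conservation constant `c_in + c_out` (mM).
#' @param tol tolerance for the sigma consistency check (mM).
#' @return an object of class `ion_species`.
#' @examples
#' potassium <- ion_species("K", +1, c_in = 96.83, c_out = 3.17, sigma = 100)
#' nernst_potential(potassium)
#' @export
ion_species <- function(name, z, c_in, c_out, sigma = NULL, tol = 1e-6) {
  stopifnot(is.character(name), length(name) == 1L,
            length(z) == 1L, z == round(z), z != 0,
            is.numeric(c_in), is.numeric(c_out),
            length(c_in) == 1L, length(c_out) == 1L,
            c_in >= 0, c_out >= 0)
  if (!is.null(sigma)) {
    stopifnot(is.numeric(sigma), length(sigma) == 1L, sigma > 0)
    if (abs(c_in + c_out - sigma) > tol * max(1, sigma))
      stop(sprintf("ion '%s': c_in + c_out = %.6f does not match sigma = %.6f",
                   name, c_in + c_out, sigma))
  }
  structure(list(name = name, z = as.integer(z),
                 c_in = c_in, c_out = c_out, sigma = sigma),
            class = "ion_species")
}

#' @export
print.ion_species <- function(x, ...) {
  cat(sprintf("Ion %s (z = %+d): [%s]i = %.4g mM, [%s]o = %.4g mM%s\n",
              x$name, x$z, x$name, x$c_in, x$name, x$c_out,
              if (is.null(x$sigma)) "" else sprintf(", sigma = %g mM", x$sigma)))
  invisible(x)
}

#' Nernst (reversal) potential of an ion
#'
#' `Eq = (RT / zF) ln(c_out / c_in)`, in mV.
#'
#' @param ion an [ion_species()].
#' @param constants a [phys_constants()] object.
#' @return reversal potential in mV.
#' @export
nernst_potential <- function(ion, constants = phys_constants()) {
  stopifnot(inherits(ion, "ion_species"))
  if (ion$c_in <= 0 || ion$c_out <= 0)
    stop("Nernst potential requires strictly positive concentrations on both sides")
  constants$RT_over_F_mV / ion$z * log(ion$c_out / ion$c_in)
}

#' Membrane geometry and passive electrical properties
#'
#' @param Cm membrane capacitance per unit area (uF/cm^2).
#' @param S_over_v surface-to-volume ratio (1/m).
#' @param A_in impermeable intracellular anion concentration (mM).
#' @return an object of class `membrane_geometry`.
#' @export
membrane_geometry <- function(Cm = 1, S_over_v = 4e5, A_in = 110) {
  stopifnot(Cm > 0, S_over_v > 0, A_in > 0)
  structure(list(Cm = Cm, S_over_v = S_over_v, A_in = A_in),
            class = "membrane_geometry")
}

#' Membrane voltage from the net charge imbalance
#'
#' In the closed two-compartment system the membrane potential is a linear
#' function of the bulk concentrations:
#' `V = vF / (2 S Cm) * (-[A-]i + sum_q z_q ([q]i - [q]o))`.
#' With the default geometry the sensitivity is ~1.2e4 mV per mM of net
#' charge imbalance, which is why micromolar-scale concentration changes
#' carry the full voltage excursion of an action potential.
#'
#' @param ions list of [ion_species()] covering every tracked charged species.
#' @param geom a [membrane_geometry()].
#' @return membrane potential in mV.
#' @export
voltage_from_charge <- function(ions, geom = membrane_geometry()) {
  if (inherits(ions, "ion_species")) ions <- list(ions)
  stopifnot(all(vapply(ions, inherits, TRUE, "ion_species")))
  net <- sum(vapply(ions, function(i) i$z * (i$c_in - i$c_out), 0)) - geom$A_in
  # Cm uF/cm^2 -> F/m^2 is *1e-2; concentrations mM == mol/m^3; result V -> mV
  # mV per mM of net imbalance, times net imbalance in mM
  charge_voltage_coefficient(geom) * net
}

#' Voltage sensitivity of the charge-voltage relation
#'
#' Returns `vF / (2 S Cm)` in mV per mM of net charge imbalance.
#' @param geom a [membrane_geometry()].
#' @export
charge_voltage_coefficient <- function(geom = membrane_geometry()) {
  k <- phys_constants()
  1000 * k$F / (2 * geom$S_over_v * geom$Cm * 1e-2)
}
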