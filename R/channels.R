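#' Single-channel specification
#'
#' A channel is a pore of cross-sectional area `pore_area` permeable to one
#' or more ions, each with its own single-channel permeability. Single-channel
#' currents are the GHK current densities scaled by the pore area.
#'
#' @param name identifier.
#' @param permeants list of [ion_species()].
#' @param P numeric vector of single-channel permeabilities (m/s, >= 0), one
#'   per permeant.
#' @param pore_area pore cross-section Sc in m^2. The calibrated presets use
#'   `pi * (5e-10)^2`, the effective cross-section implied by the printed
#'   5 Angstrom pore figure together with the published single-channel
#'   permeabilities and channel densities.
#' @param density optional channel surface density (channels per cm^2).
#' @return an object of class `channel_spec`.
#' @seealso [gabaa_channel()], [ampa_channel()], [leak_channel()]
#' @export
channel_spec <- function(name, permeants, P, pore_area = pi * (5e-10)^2,
                         density = NULL) {
  if (inherits(permeants, "ion_species")) permeants <- list(permeants)
  stopifnot(length(permeants) >= 1L,
            all(vapply(permeants, inherits, TRUE, "ion_species")),
            length(P) == length(permeants), all(P >= 0), pore_area > 0)
  structure(list(name = name, permeants = permeants, P = as.numeric(P),
                 pore_area = pore_area, density = density),
            class = "channel_spec")
}

#' @export
print.channel_spec <- function(x, ...) {
  cat(sprintf("Channel '%s' (Sc = %.3e m^2)\n", x$name, x$pore_area))
  for (i in seq_along(x$permeants)) {
    p <- x$permeants[[i]]
    cat(sprintf("  %-5s z=%+d  P = %.3e m/s  [i/o] = %.4g/%.4g mM\n",
                p$name, p$z, x$P[i], p$c_in, p$c_out))
  }
  invisible(x)
}

#' Permeability ratio enforcing a linear I-V relation
#'
#' For a two-permeant channel of equal valences the total I-V curve is an
#' exact straight line when `P2/P1 = -(c1_in - c1_out)/(c2_in - c2_out)`:
#' the Goldman rectifications of the two ions cancel.
#'
#' @param ion1,ion2 the two permeant [ion_species()].
#' @return the ratio `P2/P1` producing an exactly linear I-V curve.
#' @export
linearity_ratio <- function(ion1, ion2) {
  d2 <- ion2$c_in - ion2$c_out
  if (d2 == 0)
    stop("ion2 has no concentration gradient and cannot compensate rectification")
  -(ion1$c_in - ion1$c_out) / d2
}

#' Single-channel permeabilities from a measured linear conductance
#'
#' Inverts the apparent-conductance relation for a two-permeant channel held
#' at its linearity condition: given the measured single-channel conductance
#' `gc_m` (the slope of the linear I-V curve), the pore cross-section and the
#' bath concentrations, returns the two single-channel permeabilities.
#'
#' @param gc_m measured single-channel conductance (pS, > 0).
#' @param spec a [channel_spec()] with exactly 2 permeants (its `P` values
#'   are ignored; concentrations and pore area are used).
#' @param constants a [phys_constants()].
#' @return named numeric vector of length 2 (m/s), in permeant order.
#' @export
permeabilities_from_linear_conductance <- function(gc_m, spec,
                                                   constants = phys_constants()) {
  stopifnot(inherits(spec, "channel_spec"), length(spec$permeants) == 2L,
            gc_m > 0)
  q1 <- spec$permeants[[1L]]; q2 <- spec$permeants[[2L]]
  det <- q1$c_out * q2$c_in - q2$c_out * q1$c_in
  if (abs(det) < .Machine$double.eps * 100 * max(1, q1$c_out * q2$c_in))
    stop("degenerate concentrations: [q1]o[q2]i - [q2]o[q1]i ~ 0")
  pref <- constants$RT * gc_m * 1e-12 / (spec$pore_area * constants$F^2)
  P1 <- pref * (q2$c_in - q2$c_out) / det
  P2 <- pref * (q1$c_out - q1$c_in) / det
  stats::setNames(c(P1, P2), c(q1$name, q2$name))
}

#' Per-ion single-channel conductance
#'
#' `gq = Sc F^2 Pq cbar_q / (RT)` in pS for one permeant of the channel.
#'
#' @param spec a [channel_spec()].
#' @param ion_index index into the permeant list.
#' @param V membrane potential (mV), vectorized.
#' @param constants a [phys_constants()].
#' @return conductance in pS.
#' @export
per_ion_conductance <- function(spec, ion_index, V, constants = phys_constants()) {
  stopifnot(inherits(spec, "channel_spec"),
            ion_index >= 1L, ion_index <= length(spec$permeants))
  ion <- spec$permeants[[ion_index]]
  cbar <- harmonic_mean_concentration(ion, V, constants)
  g_SI <- ion$z^2 * constants$F^2 * spec$P[ion_index] * cbar / constants$RT
  spec$pore_area * g_SI * 1e12   # S -> pS
}

# composite permeant concentrations [C]i/o = sum (Pk/P1) [k]i/o
.composite_concentrations <- function(spec) {
  r <- spec$P / spec$P[1L]
  Ci <- sum(r * vapply(spec$permeants, function(p) p$c_in, 0))
  Co <- sum(r * vapply(spec$permeants, function(p) p$c_out, 0))
  c(Ci = Ci, Co = Co)
}

#' Apparent conductance and reversal potential
#'
#' For a channel whose permeants all share the same unit valence `zC`, the
#' total current collapses onto a single composite permeant
#' `[C] = sum (Pk/P1)[k]`, giving a voltage-independent reversal potential
#' `Ec_a = (RT / zC F) ln([C]o/[C]i)` and a conductance
#' `gc_a = Sc F^2 P1 cbar_C / RT` built on the harmonic mean of `[C]`.
#' The pair reproduces the summed per-ion GHK currents exactly:
#' `ic = -gc_a (V - Ec_a)`.
#'
#' @inheritParams per_ion_conductance
#' @return list with `gc_a` (pS, same length as `V`) and `Ec_a` (mV, scalar).
#' @export
apparent_conductance_reversal <- function(spec, V, constants = phys_constants()) {
  stopifnot(inherits(spec, "channel_spec"))
  zs <- vapply(spec$permeants, function(p) p$z, 0L)
  if (length(unique(zs)) != 1L || abs(zs[1L]) != 1L)
    stop("apparent form undefined: permeants must share the same unit valence")
  zC <- zs[1L]
  cc <- .composite_concentrations(spec)
  comp <- ion_species("C", zC, c_in = cc[["Ci"]], c_out = cc[["Co"]])
  Ec_a <- nernst_potential(comp, constants)
  cbar <- harmonic_mean_concentration(comp, V, constants)
  gc_a <- spec$pore_area * constants$F^2 * spec$P[1L] * cbar / constants$RT * 1e12
  list(gc_a = gc_a, Ec_a = Ec_a)
}

#' Latent (chord) conductance and reversal potential
#'
#' The valence-agnostic pair: `gc_l = sum gq` and
#' `Ec_l = sum(gq Eq) / sum(gq)`, both voltage-dependent even for channels
#' with linear I-V curves. `-gc_l (V - Ec_l)` reproduces the summed per-ion
#' GHK currents at every voltage and for mixed valences.
#'
#' @inheritParams per_ion_conductance
#' @return list with `gc_l` (pS) and `Ec_l` (mV), each the length of `V`.
#' @export
latent_conductance_reversal <- function(spec, V, constants = phys_constants()) {
  stopifnot(inherits(spec, "channel_spec"))
  gs <- vapply(seq_along(spec$permeants),
               function(i) per_ion_conductance(spec, i, V, constants),
               numeric(length(V)))
  gs <- matrix(gs, nrow = length(V))
  Es <- vapply(spec$permeants, nernst_potential, 0, constants = constants)
  gc_l <- rowSums(gs)
  Ec_l <- as.numeric(gs %*% Es) / gc_l
  list(gc_l = gc_l, Ec_l = Ec_l)
}

#' Single-channel I-V table
#'
#' Per-ion and total single-channel currents over a voltage grid, together
#' with the apparent (where defined) and latent conductance/reversal pairs.
#'
#' @param spec a [channel_spec()].
#' @param V voltage grid (mV).
#' @param constants a [phys_constants()].
#' @return a data.frame of class `channel_iv` with columns `V_mV`, one
#'   `I_<ion>_pA` per permeant, `I_total_pA`, `gc_a_pS`, `Ec_a_mV` (NA when
#'   the apparent form is undefined), `gc_l_pS`, `Ec_l_mV`.
#' @export
single_channel_iv <- function(spec, V, constants = phys_constants()) {
  stopifnot(inherits(spec, "channel_spec"), all(is.finite(V)))
  per_ion <- vapply(seq_along(spec$permeants), function(i) {
    ion <- spec$permeants[[i]]
    # density uA/cm^2 -> A/m^2 -> * Sc -> A -> pA
    Iden <- ghk_current_density(spec$P[i], ion, V, constants) / 100
    Iden * spec$pore_area * 1e12
  }, numeric(length(V)))
  per_ion <- matrix(per_ion, nrow = length(V))
  colnames(per_ion) <- paste0("I_", vapply(spec$permeants, `[[`, "", "name"), "_pA")
  total <- rowSums(per_ion)
  lat <- latent_conductance_reversal(spec, V, constants)
  app <- tryCatch(apparent_conductance_reversal(spec, V, constants),
                  error = function(e) list(gc_a = rep(NA_real_, length(V)),
                                           Ec_a = NA_real_))
  out <- data.frame(V_mV = V, per_ion, I_total_pA = total,
                    gc_a_pS = app$gc_a, Ec_a_mV = app$Ec_a,
                    gc_l_pS = lat$gc_l, Ec_l_mV = lat$Ec_l,
                    check.names = FALSE)
  class(out) <- c("channel_iv", "data.frame")
  out
}

#' Averaged membrane permeability from channel density
#'
#' Scales a single-channel permeability to a whole-membrane averaged
#' permeability: `P_average = (Nc/S) * Sc * P * po`.
#'
#' @param spec a [channel_spec()] (its `pore_area` is used).
#' @param ion_index which permeant's single-channel permeability to scale.
#' @param density channels per cm^2 (>= 0); defaults to `spec$density`.
#' @param open_probability fraction of channels open, in `[0, 1]`.
#' @return membrane-averaged permeability (m/s).
#' @export
membrane_average_permeability <- function(spec, ion_index = 1L,
                                          density = spec$density,
                                          open_probability = 1) {
  stopifnot(inherits(spec, "channel_spec"), !is.null(density), density >= 0,
            open_probability >= 0, open_probability <= 1)
  density_m2 <- density * 1e4    # per cm^2 -> per m^2
  density_m2 * spec$pore_area * spec$P[ion_index] * open_probability
}
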