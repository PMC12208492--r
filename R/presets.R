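# Canonical parameter registry and channel presets. Every printed constant
# used by the models and tests lives here, in one place.

#' Canonical model parameters
#'
#' The full default parameter set of the neurodynamic models: averaged
#' membrane permeabilities, circuit conductances, pump strengths, geometry,
#' steady-state concentrations, conservation constants, and the fitted
#' voltage-gated correction (fq) coefficients. Returned as a named list that
#' [gnp_model()] uses to fill defaults, and that [write_fixtures()] dumps as
#' JSON.
#'
#' Note: the glutamatergic potassium permeability `PKG` is 2.82e-9 m/s here.
#' This is the value consistent with the channel-density construction
#' (4e6 AMPA channels per cm^2, Sc = pi*(5 A)^2, single-channel
#' PK = 8.99e-2 m/s), with the glutamatergic conductance Gglu = 0.12 mS/cm^2
#' and with a ~0 mV glutamate reversal potential.
#'
#' @return named list of parameters; units are encoded in the names.
#' @export
gnp_parameters <- function() {
  list(
    # averaged membrane permeabilities (m/s)
    PKL_m_per_s  = 2.00e-8,
    PNaL_m_per_s = 1.00e-9,
    PClL_m_per_s = 4.00e-9,
    PKG_m_per_s  = 2.82e-9,
    PNaG_m_per_s = 2.45e-9,
    PKV_m_per_s  = 1.70e-6,
    PNaV_m_per_s = 1.47e-6,
    # circuit conductances (mS/cm^2) and reversals (mV)
    GKM_mS_per_cm2  = 20,
    GNaM_mS_per_cm2 = 30,
    Gglu_mS_per_cm2 = 0.12,
    Eglu_mV = 0,
    GLH_mS_per_cm2 = 0.17,
    ELH_mV = -61.52,
    GKL_iHH_mS_per_cm2  = 0.10,
    GNaL_iHH_mS_per_cm2 = 0.030,
    GClL_iHH_mS_per_cm2 = 0.042,
    GKG_iHH_mS_per_cm2  = 0.12,
    GNaG_iHH_mS_per_cm2 = 0.03,
    # pump
    MNaK_mM_per_s = 0.3,
    INaK_uA_per_cm2 = -1.16,
    # geometry / environment
    S_over_v_per_m = 4e5,
    T_K = 309.15,
    A_in_mM = 110,
    Cm_uF_per_cm2 = 1,
    # steady state and conservation constants (mM, mV)
    Ko0_mM = 3.17, Nai0_mM = 23.58, Cli0_mM = 10.41, V0_mV = -68.17,
    sigma_K_mM = 100, sigma_Na_mM = 155, sigma_Cl_mM = 145,
    # single-channel presets
    pore_area_m2 = pi * (5e-10)^2,
    leak_density_per_cm2 = 1e7,
    ampa_density_per_cm2 = 4e6,
    P_single_leak_K_m_per_s  = 2.55e-1,
    P_single_leak_Cl_m_per_s = 5.08e-2,
    P_single_leak_Na_m_per_s = 1.27e-2,
    PCa_single_m_per_s = 2.70,
    Ca_o_mM = 2, Ca_i_mM = 1e-4,
    HCO3_i_mM = 15, HCO3_o_mM = 25,
    P_ratio_HCO3_Cl = 0.2,
    gc_m_pS = 30,
    # fq cubic coefficients (N3, N2, N1, N0), V in mV
    fq_K  = c(-1.20e-7, 1.18e-5, 0.0075, 0.85),
    fq_Na = c(9.41e-8, 4.64e-6, -0.0056, 1.11)
  )
}

# physiological bath ions at the canonical steady state
.std_ions <- function(p = gnp_parameters()) {
  list(
    K  = ion_species("K",  +1, c_in = p$sigma_K_mM - p$Ko0_mM, c_out = p$Ko0_mM,
                     sigma = p$sigma_K_mM),
    Na = ion_species("Na", +1, c_in = p$Nai0_mM, c_out = p$sigma_Na_mM - p$Nai0_mM,
                     sigma = p$sigma_Na_mM),
    Cl = ion_species("Cl", -1, c_in = p$Cli0_mM, c_out = p$sigma_Cl_mM - p$Cli0_mM,
                     sigma = p$sigma_Cl_mM)
  )
}

#' GABAA channel preset
#'
#' Two permeants of valence -1: chloride and bicarbonate, with the
#' permeability ratio PHCO3/PCl = 0.2. `condition = "calibration"` uses the
#' symmetric-chloride recording solutions (147/145 mM, the exact linearity
#' condition given the bicarbonate gradient); `condition = "physiological"`
#' uses the low intracellular chloride of the resting neuron, under which
#' the channel rectifies outwardly.
#'
#' @param condition `"physiological"` or `"calibration"`.
#' @param constants a [phys_constants()].
#' @return a [channel_spec()].
#' @export
gabaa_channel <- function(condition = c("physiological", "calibration"),
                          constants = phys_constants()) {
  condition <- match.arg(condition)
  p <- gnp_parameters()
  if (condition == "calibration") {
    cl <- ion_species("Cl", -1, c_in = 147, c_out = 145)
  } else {
    cl <- ion_species("Cl", -1, c_in = p$Cli0_mM,
                      c_out = p$sigma_Cl_mM - p$Cli0_mM)
  }
  hco3 <- ion_species("HCO3", -1, c_in = p$HCO3_i_mM, c_out = p$HCO3_o_mM)
  cal <- channel_spec("GABAA", list(ion_species("Cl", -1, 147, 145), hco3),
                      P = c(1, p$P_ratio_HCO3_Cl), pore_area = p$pore_area_m2)
  P <- permeabilities_from_linear_conductance(p$gc_m_pS, cal, constants)
  channel_spec("GABAA", list(cl, hco3), P = as.numeric(P),
               pore_area = p$pore_area_m2)
}

#' AMPA channel presets
#'
#' GluR2-containing AMPA: permeable to K+ and Na+ with the permeability
#' ratio fixed by the linearity condition at the physiological
#' concentrations, calibrated so the (linear) single-channel I-V has slope
#' 30 pS. `glur2 = FALSE` adds the calcium permeation of the GluR2-lacking
#' channel (PCa = 2.70 m/s, 2 mM / 1e-4 mM baths), which turns the total
#' curve inwardly rectifying.
#'
#' @param glur2 logical; `TRUE` for the calcium-impermeable channel.
#' @param constants a [phys_constants()].
#' @return a [channel_spec()].
#' @export
ampa_channel <- function(glur2 = TRUE, constants = phys_constants()) {
  p <- gnp_parameters()
  ions <- .std_ions(p)
  k <- ions$K; na <- ions$Na
  cal <- channel_spec("AMPA", list(k, na), P = c(1, linearity_ratio(k, na)),
                      pore_area = p$pore_area_m2)
  P <- permeabilities_from_linear_conductance(p$gc_m_pS, cal, constants)
  if (glur2) {
    channel_spec("AMPA-GluR2", list(k, na), P = as.numeric(P),
                 pore_area = p$pore_area_m2, density = p$ampa_density_per_cm2)
  } else {
    ca <- ion_species("Ca", +2, c_in = p$Ca_i_mM, c_out = p$Ca_o_mM)
    channel_spec("AMPA-GluR2less", list(k, na, ca),
                 P = c(as.numeric(P), p$PCa_single_m_per_s),
                 pore_area = p$pore_area_m2, density = p$ampa_density_per_cm2)
  }
}

#' Leak channel preset
#'
#' The equivalent leak pore: high potassium, medium chloride and low sodium
#' single-channel permeability, at the canonical bath concentrations. With
#' the default density (1e7 channels per cm^2) its averaged permeabilities
#' reproduce the whole-membrane leak permeabilities of the models.
#'
#' @param constants a [phys_constants()].
#' @return a [channel_spec()].
#' @export
leak_channel <- function(constants = phys_constants()) {
  p <- gnp_parameters()
  ions <- .std_ions(p)
  channel_spec("leak", list(ions$K, ions$Na, ions$Cl),
               P = c(p$P_single_leak_K_m_per_s, p$P_single_leak_Na_m_per_s,
                     p$P_single_leak_Cl_m_per_s),
               pore_area = p$pore_area_m2, density = p$leak_density_per_cm2)
}
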