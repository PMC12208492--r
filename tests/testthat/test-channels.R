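# Single-channel characterization: linearity condition, permeability
# calibration, per-ion decomposition, apparent vs latent conductance.

test_that("linearity condition: AMPA ratio and GABAA chloride gradient", {
  expect_equal(linearity_ratio(std_K(), std_Na()), 0.87, tolerance = 0.005)
  # with PHCO3/PCl = 0.2 and bicarbonate at 15/25 mM, an exactly linear
  # GABAA I-V needs [Cl]i 2 mM above [Cl]o
  cl <- ion_species("Cl", -1, c_in = 147, c_out = 145)
  hco3 <- ion_species("HCO3", -1, c_in = 15, c_out = 25)
  expect_equal(linearity_ratio(cl, hco3), 0.2, tolerance = 1e-12)
  # an ion without gradient forces ratio 0
  flat <- ion_species("F", -1, c_in = 145, c_out = 145)
  expect_equal(linearity_ratio(flat, hco3), 0)
  expect_error(linearity_ratio(cl, flat), "gradient")
})

test_that("permeability calibration reproduces the published single-channel values", {
  # 30 pS, 5 Angstrom pore; tolerance 0.5% (printed values carry 3 digits)
  g <- gabaa_channel("calibration")
  expect_equal(unname(g$P[1]), 7.04e-2, tolerance = 5e-3)
  expect_equal(unname(g$P[2]), 1.41e-2, tolerance = 5e-3)
  expect_equal(g$P[2] / g$P[1], 0.2, tolerance = 1e-9)
  a <- ampa_channel()
  expect_equal(unname(a$P[1]), 8.99e-2, tolerance = 5e-3)
  expect_equal(unname(a$P[2]), 7.80e-2, tolerance = 5e-3)
})

test_that("calibration inverts exactly: round trip on randomized channels", {
  set.seed(42)
  k <- phys_constants()
  for (i in 1:20) {
    P1 <- 10^stats::runif(1, -3, 0)
    P2 <- 10^stats::runif(1, -3, 0)
    c1i <- stats::runif(1, 5, 150); c2i <- stats::runif(1, 5, 150)
    d2 <- stats::runif(1, -40, 40)
    # pick gradients satisfying the linearity condition for (P1, P2)
    d1 <- -(P2 / P1) * d2
    if (c1i - d1 <= 0 || c2i - d2 <= 0) next
    q1 <- ion_species("q1", +1, c_in = c1i, c_out = c1i - d1)
    q2 <- ion_species("q2", +1, c_in = c2i, c_out = c2i - d2)
    spec <- channel_spec("rt", list(q1, q2), P = c(P1, P2))
    # at the linearity condition the apparent conductance is the flat slope
    gc <- apparent_conductance_reversal(spec, 0, k)$gc_a
    P_rec <- permeabilities_from_linear_conductance(gc, spec, k)
    expect_equal(unname(P_rec[1]), P1, tolerance = 1e-8)
    expect_equal(unname(P_rec[2]), P2, tolerance = 1e-8)
  }
})

test_that("per-ion conductance ratio is permeability times harmonic-mean ratio", {
  g <- gabaa_channel("physiological")
  V <- seq(-80, 60, by = 10)
  g1 <- per_ion_conductance(g, 1, V)
  g2 <- per_ion_conductance(g, 2, V)
  cb1 <- harmonic_mean_concentration(g$permeants[[1]], V)
  cb2 <- harmonic_mean_concentration(g$permeants[[2]], V)
  expect_equal(g1 / g2, (g$P[1] / g$P[2]) * (cb1 / cb2), tolerance = 1e-10)
  # the ratio is voltage-dependent (not the permeability ratio) when both
  # ions carry unequal nonzero gradients
  expect_gt(diff(range(g1 / g2)), 0.1)
  # symmetric baths for both permeants: ratio collapses to (P1 c1)/(P2 c2)
  s1 <- ion_species("a", +1, 100, 100); s2 <- ion_species("b", +1, 40, 40)
  sym <- channel_spec("sym", list(s1, s2), P = c(2e-2, 5e-2))
  r <- per_ion_conductance(sym, 1, V) / per_ion_conductance(sym, 2, V)
  expect_equal(r, rep((2e-2 * 100) / (5e-2 * 40), length(V)), tolerance = 1e-12)
})

test_that("apparent and latent forms both reproduce the summed per-ion current", {
  V <- seq(-80, 80, by = 5)
  for (spec in list(gabaa_channel(), ampa_channel())) {
    iv <- single_channel_iv(spec, V)
    # pS x mV = 1e-3 pA
    app <- -iv$gc_a_pS * (V - iv$Ec_a_mV) * 1e-3
    lat <- -iv$gc_l_pS * (V - iv$Ec_l_mV) * 1e-3
    expect_lt(max(abs(app - iv$I_total_pA)) / max(abs(iv$I_total_pA)), 1e-9)
    expect_lt(max(abs(lat - iv$I_total_pA)) / max(abs(iv$I_total_pA)), 1e-9)
  }
  # mixed valences: apparent undefined, latent still exact (Ca-permeable AMPA)
  ca <- ampa_channel(glur2 = FALSE)
  expect_error(apparent_conductance_reversal(ca, 0), "valence")
  iv <- single_channel_iv(ca, V)
  expect_true(all(is.na(iv$Ec_a_mV)))
  lat <- -iv$gc_l_pS * (V - iv$Ec_l_mV) * 1e-3
  expect_lt(max(abs(lat - iv$I_total_pA)) / max(abs(iv$I_total_pA)), 1e-9)
})

test_that("GABAA reversal, ordering invariance and single-permeant reduction", {
  g <- gabaa_channel("physiological")
  app <- apparent_conductance_reversal(g, 0)
  expect_equal(app$Ec_a, -62.34, tolerance = 0.002)  # relative: ~0.1 mV
  # zero total current at the apparent reversal; latent reversal agrees there
  iv <- single_channel_iv(g, app$Ec_a)
  expect_equal(iv$I_total_pA, 0, tolerance = 1e-9)
  expect_equal(iv$Ec_l_mV, app$Ec_a, tolerance = 1e-6)
  # the reference-permeant choice does not change the apparent pair
  g_swapped <- channel_spec(g$name, g$permeants[c(2, 1)], P = g$P[c(2, 1)],
                            pore_area = g$pore_area)
  app2 <- apparent_conductance_reversal(g_swapped, c(-60, 0, 40))
  app1 <- apparent_conductance_reversal(g, c(-60, 0, 40))
  expect_equal(app2$Ec_a, app1$Ec_a, tolerance = 1e-12)
  expect_equal(app2$gc_a, app1$gc_a, tolerance = 1e-12)
  # a single-permeant channel reduces to the Nernst potential
  solo <- channel_spec("solo", list(std_K()), P = 1e-2)
  expect_equal(apparent_conductance_reversal(solo, 0)$Ec_a,
               nernst_potential(std_K()), tolerance = 1e-12)
})

test_that("rectification directions: GABAA outward, AMPA linear, +Ca inward", {
  V <- seq(-80, 80, by = 2)
  # calibrated AMPA at its linearity condition: a 30 pS straight line
  iv <- single_channel_iv(ampa_channel(), V)
  expect_lt(max_line_deviation(V, iv$I_total_pA), 1e-6)
  # slope of the pA-vs-mV line is in nS; x1000 for pS
  expect_equal(-1000 * iv_slope(V, iv$I_total_pA), 30, tolerance = 5e-3)
  expect_equal(diff(range(iv$gc_a_pS)), 0, tolerance = 1e-6)
  # GABAA physiological: outward rectification (larger conductance above
  # the reversal than symmetrically below it)
  g <- gabaa_channel()
  Ec <- apparent_conductance_reversal(g, 0)$Ec_a
  ivg <- single_channel_iv(g, c(Ec - 60, Ec + 60))
  expect_gt(abs(ivg$I_total_pA[2]), abs(ivg$I_total_pA[1]))
  # adding the calcium component turns the total curve inwardly rectifying
  ca <- ampa_channel(glur2 = FALSE)
  Ec0 <- single_channel_iv(ca, seq(-20, 20, 0.5))
  Vrev <- Ec0$V_mV[which.min(abs(Ec0$I_total_pA))]
  ivc <- single_channel_iv(ca, c(Vrev - 60, Vrev + 60))
  expect_gt(abs(ivc$I_total_pA[1]), abs(ivc$I_total_pA[2]))
  # the latent pair still vanishes with the current at the zero crossing
  expect_lt(abs(single_channel_iv(ca, Vrev)$Ec_l_mV - Vrev), 0.5)
})

test_that("averaged membrane permeability: linearity and Table-level closure", {
  lk <- leak_channel()
  expect_equal(membrane_average_permeability(lk, 1, density = 0), 0)
  p1 <- membrane_average_permeability(lk, 1, density = 1e7)
  expect_equal(membrane_average_permeability(lk, 1, density = 2e7), 2 * p1)
  expect_equal(membrane_average_permeability(lk, 1, density = 1e7,
                                             open_probability = 0.5), p1 / 2)
  # the stated densities close the loop on the canonical averaged
  # permeabilities: 1e7 leak channels/cm^2 and 4e6 AMPA channels/cm^2
  expect_equal(p1, 2.00e-8, tolerance = 5e-3)                     # K leak
  expect_equal(membrane_average_permeability(lk, 2, density = 1e7),
               1.00e-9, tolerance = 5e-3)                         # Na leak
  expect_equal(membrane_average_permeability(lk, 3, density = 1e7),
               4.00e-9, tolerance = 5e-3)                         # Cl leak
  am <- ampa_channel()
  expect_equal(membrane_average_permeability(am, 1, density = 4e6),
               2.82e-9, tolerance = 5e-3)
  expect_equal(membrane_average_permeability(am, 2, density = 4e6),
               2.45e-9, tolerance = 5e-3)
})
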