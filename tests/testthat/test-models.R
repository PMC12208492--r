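# Model assembly: complement concentrations, derivative composition,
# conservation, leak linearization and cross-variant consistency.

test_that("complement concentrations and conservation invariants", {
  m <- gnp_model("gnp")
  cc <- complement_concentrations(3.17, 23.58, 10.41, m)
  expect_equal(unname(cc[c("Ki", "Nao", "Clo")]), c(96.83, 131.42, 134.59))
  expect_true(attr(cc, "physical"))
  expect_equal(unname(cc["Ko"] + cc["Ki"]), 100)
  expect_equal(unname(cc["Nai"] + cc["Nao"]), 155)
  expect_equal(unname(cc["Cli"] + cc["Clo"]), 145)
  cc0 <- complement_concentrations(100, 23.58, 10.41, m)
  expect_equal(unname(cc0["Ki"]), 0)
  ccn <- complement_concentrations(101, 23.58, 10.41, m)
  expect_false(attr(ccn, "physical"))
})

test_that("initial state is charge-consistent with the resting potential", {
  m <- gnp_model("gnp")
  st <- initial_state(m)
  expect_equal(gnp_rhs(m, st, po = 0)$V, -68.17, tolerance = 1e-8)
  # explicit concentrations are honoured unchanged
  st2 <- initial_state(m, Ko = 5, Nai = 30, Cli = 12)
  expect_equal(unname(st2[c("Ko", "Nai", "Cli")]), c(5, 30, 12))
})

test_that("GNP fixed point: residuals, chloride reversal, potassium balance", {
  m <- gnp_model("gnp", pump = pump_spec("constant", I_const = -1.16))
  fp <- find_fixed_point(m)
  r <- gnp_rhs(m, fp$state, po = 0)
  expect_lt(max(abs(unlist(r$dstate))), 1e-9)
  # chloride leak vanishes, so V equals the chloride Nernst potential
  expect_lt(abs(r$IClL), 1e-6)
  Cl <- ion_species("Cl", -1, fp$state[["Cli"]], 145 - fp$state[["Cli"]])
  expect_equal(fp$V, nernst_potential(Cl), tolerance = 1e-6)
  # potassium balance: IKV + IKL = 2 INaK
  expect_equal(r$IKV + r$IKL, 2 * r$INaK, tolerance = 1e-7)
  # leak potassium magnitude ~ 2 x 1.16 uA/cm^2 at rest
  expect_equal(abs(r$IKL), 2 * 1.16, tolerance = 0.02)
})

test_that("closed-system conservation along an integrated trajectory", {
  m <- gnp_model("gnp", pump = pump_spec("constant", I_const = -1.16),
                 stimulus = stimulus_protocol(50, 500, 0.3))
  sim <- simulate(m, tmax = 600, dt_sample = 0.5)
  # sigma conservation is structural (complement representation); what must
  # hold numerically is the charge-voltage identity at every sample
  p <- m$par
  Vrec <- charge_voltage_coefficient() *
    (-p$A_in_mM + (p$sigma_K_mM - 2 * sim$state[, "Ko"]) +
       (2 * sim$state[, "Nai"] - p$sigma_Na_mM) +
       (p$sigma_Cl_mM - 2 * sim$state[, "Cli"]))
  expect_lt(max(abs(Vrec - sim$V)), 1e-8)
  # gates bounded along the trajectory
  for (nm in c("m", "h", "n")) {
    expect_gt(min(sim$state[, nm]), -1e-9)
    expect_lt(max(sim$state[, nm]), 1 + 1e-9)
  }
})

test_that("steady-state leak linearization reproduces the circuit constants", {
  lin <- steady_state_leak_linearization()
  expect_equal(lin$GKL, 0.10, tolerance = 0.02)
  expect_equal(lin$GNaL, 0.030, tolerance = 0.02)
  expect_equal(lin$GClL, 0.042, tolerance = 0.01)
  expect_equal(lin$GLH, 0.17, tolerance = 0.02)
  expect_equal(lin$ELH, -61.52, tolerance = 0.001)
  expect_equal(lin$GLH, lin$GKL + lin$GNaL + lin$GClL, tolerance = 1e-12)
  expect_equal(lin$Gglu, 0.12, tolerance = 0.002)
  expect_lt(abs(lin$Eglu), 0.05)
})

test_that("fGNP and cHH derivatives coincide at the linearization point", {
  st <- NULL
  for (v in c("fgnp", "chh")) {
    m <- gnp_model(v, pump = pump_spec("constant", I_const = -1.16))
    st <- initial_state(m)
    r <- gnp_rhs(m, st, po = 0)
    # both models are (near-)stationary at the canonical resting state;
    # residual reflects print rounding of the linearized constants
    expect_lt(abs(r$dstate[["V"]]), 0.05)
  }
  # leak currents agree at the linearization point by construction
  mf <- gnp_model("fgnp"); mc <- gnp_model("chh")
  rf <- gnp_rhs(mf, initial_state(mf), po = 0)
  rc <- gnp_rhs(mc, initial_state(mc), po = 0)
  ILf <- rf$IKL + rf$INaL + rf$IClL
  # GLH/ELH are carried at print precision (0.17, -61.52), worth ~2% here
  expect_equal(ILf, rc$IKL, tolerance = 0.03)
})

test_that("variant degeneracy: fGNP voltage equation equals the GNP currents", {
  # at the frozen (steady-state) concentrations the fGNP dV/dt must equal
  # the sum of the GNP model's electrodiffusive currents at the same V
  mf <- gnp_model("fgnp", pump = pump_spec("constant", I_const = -1.16))
  mg <- gnp_model("gnp", pump = pump_spec("constant", I_const = -1.16))
  for (V in c(-75, -68.17, -55, -30)) {
    stf <- initial_state(mf, V = V)
    rf <- gnp_rhs(mf, stf, po = 0)
    stg <- initial_state(mg)          # canonical concentrations
    stg[c("m", "h", "n")] <- stf[c("m", "h", "n")]
    rg <- gnp_rhs(mg, stg, po = 0)
    # evaluate the GNP current sum at the fGNP voltage: rebuild by parts
    Isum_f <- rf$IKV + rf$INaV + rf$IKL + rf$INaL + rf$IClL + rf$INaK
    expect_equal(rf$dstate[["V"]], Isum_f, tolerance = 1e-10)
    if (abs(V - (-68.17)) < 1e-9) {
      # same state: the leak/gated components agree across variants
      expect_equal(rf$IKL, rg$IKL, tolerance = 1e-9)
      # sodium reversal differs by the <0.01 mM charge projection of [Na]i
      expect_equal(rf$INaV, rg$INaV, tolerance = 1e-3)
    }
  }
})

test_that("vGNP reduces to GNP when fq equals the pointwise current ratio", {
  # at a fixed voltage, dividing the GHK gated current by the exact ratio
  # I'/I recovers the circuit current; the vGNP derivative built with that
  # exact fq value then matches the GNP derivative
  mg <- gnp_model("gnp", pump = pump_spec("constant", I_const = -1.16))
  st <- initial_state(mg)
  rg <- gnp_rhs(mg, st, po = 0)
  V <- rg$V
  p <- gnp_parameters()
  K <- ion_species("K", +1, 100 - st[["Ko"]], st[["Ko"]])
  Na <- ion_species("Na", +1, st[["Nai"]], 155 - st[["Nai"]])
  ratio_K <- -ghk_current_density(p$PKV_m_per_s, K, V) /
    (20 * (V - nernst_potential(K)))
  ratio_Na <- -ghk_current_density(p$PNaV_m_per_s, Na, V) /
    (30 * (V - nernst_potential(Na)))
  mv <- gnp_model("vgnp", pump = pump_spec("constant", I_const = -1.16),
                  fq_K = c(0, 0, 0, ratio_K), fq_Na = c(0, 0, 0, ratio_Na))
  rv <- gnp_rhs(mv, st, po = 0)
  expect_equal(rv$dstate[["Ko"]], rg$dstate[["Ko"]], tolerance = 1e-8)
  expect_equal(rv$dstate[["Nai"]], rg$dstate[["Nai"]], tolerance = 1e-8)
})

test_that("iHH fixed point exists near the canonical state and is stable", {
  m <- gnp_model("ihh", pump = pump_spec("constant", I_const = -1.16))
  fp <- find_fixed_point(m)
  expect_lt(abs(fp$V - (-68.17)), 2.5)
  expect_equal(fp$stability, "stable")
  expect_true(fp$physical)
})

test_that("unknown parameters and invalid values are rejected", {
  expect_error(gnp_model("gnp", nonsense_key = 1), "unknown parameter")
  expect_error(gnp_model("gnp", Cm_uF_per_cm2 = -1), "positive")
  expect_error(gnp_model("gnp", PKL_m_per_s = -1e-9), "nonnegative")
})
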