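# Time integration, spike detection, firing classification and the
# sliding-window current-difference analysis.

test_that("spike detection: empty, synthetic trains, refractory", {
  t <- seq(0, 100, by = 0.1)
  expect_length(detect_spikes(rep(-65, length(t)), t), 0)
  # synthetic train: k pulses above threshold
  V <- rep(-70, length(t))
  centers <- c(10, 30, 50, 70, 90)
  for (cc in centers) V[abs(t - cc) < 0.5] <- 10
  expect_length(detect_spikes(V, t), length(centers))
  # two crossings 1 ms apart collapse under the 2 ms refractory
  V2 <- rep(-70, length(t))
  V2[abs(t - 10) < 0.2] <- 10
  V2[abs(t - 11) < 0.2] <- 10
  expect_length(detect_spikes(V2, t), 1)
})

test_that("resting stationarity: 1 s drift below 0.5 mV for every variant", {
  for (v in c("gnp", "vgnp", "fgnp", "chh", "ihh")) {
    m <- gnp_model(v, pump = pump_spec("constant", I_const = -1.16))
    sim <- simulate(m, tmax = 1000, dt_sample = 1, record_currents = FALSE)
    expect_lt(max(abs(sim$V - sim$V[1])), 0.5, label = sprintf("drift(%s)", v))
  }
})

test_that("integration reproduces the derivative field (post-hoc residual)", {
  m <- gnp_model("gnp", pump = pump_spec("constant", I_const = -1.16),
                 stimulus = stimulus_protocol(10, 400, 0.12))
  sim <- simulate(m, tmax = 400, dt_sample = 0.05, record_currents = FALSE)
  # central-difference derivative of the stored trace vs the rhs, away from
  # the stimulus switch
  i <- which(sim$time > 15 & sim$time < 395)
  for (j in seq(20, length(i), by = 400)) {
    idx <- i[j]
    st <- sim$state[idx, ]
    d_num <- (sim$state[idx + 1L, ] - sim$state[idx - 1L, ]) / (2 * 0.05)
    d_rhs <- unlist(gnp_rhs(m, st, t = sim$time[idx])$dstate)
    scale <- pmax(abs(d_rhs), 1e-4)
    expect_lt(max(abs(d_num - d_rhs) / scale), 0.05)
  }
})

test_that("electrodiffusive feedback: spike advance and micromolar scales", {
  # under a sustained suprathreshold stimulus the concentration feedback in
  # the GNP model progressively advances its spikes relative to the
  # concentration-frozen fGNP model, while the underlying concentration
  # changes stay below 0.1 mM for the first nine spikes and net charge
  # stays at micromolar scale
  stim <- stimulus_protocol(100, 4000, 0.2)
  mg <- gnp_model("gnp", pump = pump_spec("constant", I_const = -1.16),
                  stimulus = stim)
  mf <- gnp_model("fgnp", pump = pump_spec("constant", I_const = -1.16),
                  stimulus = stim)
  sg <- simulate(mg, tmax = 4000, dt_sample = 0.1, record_currents = FALSE)
  sf <- simulate(mf, tmax = 4000, dt_sample = 0.1, record_currents = FALSE)
  spg <- detect_spikes(sg$V, sg$time)
  spf <- detect_spikes(sf$V, sf$time)
  expect_gt(length(spg), 12)
  k <- min(length(spg), length(spf))
  adv <- spg[1:k] - spf[1:k]
  expect_lt(adv[k], -1)          # later spikes fire earlier in GNP
  expect_true(all(diff(adv) <= 1e-6))  # monotone advance
  # concentration changes after the ninth spike
  i9 <- which.min(abs(sg$time - spg[9]))
  expect_lt(abs(sg$state[i9, "Ko"] - sg$state[1, "Ko"]), 0.1)
  expect_lt(abs(sg$state[i9, "Nai"] - sg$state[1, "Nai"]), 0.1)
  expect_lt(abs(sg$state[i9, "Cli"] - sg$state[1, "Cli"]), 0.1)
  # net charge concentration stays micromolar throughout
  p <- mg$par
  ci <- sg$state[, "Nai"] + (p$sigma_K_mM - sg$state[, "Ko"]) -
    sg$state[, "Cli"] - p$A_in_mM
  expect_lt(max(abs(ci)), 0.01)  # mM
})

test_that("firing-state classification labels the canonical regimes", {
  # resting: unstimulated model
  m <- gnp_model("gnp", pump = pump_spec("constant", I_const = -1.16))
  sim <- simulate(m, tmax = 1500, dt_sample = 0.25, record_currents = FALSE)
  expect_identical(classify_firing(sim)$label, "resting")
  expect_error(classify_firing(sim, window = c(0, 500)), "window")
  # tonic: sustained suprathreshold stimulus
  mt <- gnp_model("fgnp", pump = pump_spec("constant", I_const = -1.16),
                  stimulus = stimulus_protocol(0, 3000, 0.25))
  simt <- simulate(mt, tmax = 3000, dt_sample = 0.1, record_currents = FALSE)
  cl <- classify_firing(simt)
  expect_identical(cl$label, "tonic_spiking")
  expect_gt(cl$mean_frequency_Hz, 5)
  # depolarization block: start on the DB plateau with no stimulus
  mdb <- gnp_model("vgnp", pump = pump_spec("constant", I_const = -10))
  fp <- find_db_fixed_point(mdb)
  simdb <- simulate(mdb, tmax = 1500, init = fp$state, dt_sample = 0.25,
                    record_currents = FALSE)
  expect_identical(classify_firing(simdb)$label, "depolarization_block")
})

test_that("current differences: trivial identities and window mechanics", {
  m <- gnp_model("gnp", pump = pump_spec("constant", I_const = -1.16),
                 stimulus = stimulus_protocol(0, 20000, 0.2))
  sim <- simulate(m, tmax = 20000, dt_sample = 0.5)
  d0 <- current_difference(sim, sim)
  expect_true(all(abs(d0$dIdiff) < 1e-12))
  # window equal to the full span: single value equal to the global mean
  mv <- gnp_model("vgnp", pump = pump_spec("constant", I_const = -1.16),
                  stimulus = stimulus_protocol(0, 20000, 0.2))
  sv <- simulate(mv, tmax = 20000, dt_sample = 0.5)
  dfull <- current_difference(sv, sim, window_s = 20, step_s = 20)
  expect_equal(nrow(dfull), 1L)
  expect_equal(dfull$dIK,
               mean(sv$currents[, "IK_diff"] - sim$currents[, "IK_diff"]),
               tolerance = 1e-9)
  # Fig-8-style early window: stronger potassium inhibition in vGNP
  d <- current_difference(sv, sim, window_s = 8, step_s = 4)
  expect_lt(d$dIK[1], 0)
  # mismatched grids are refused
  short <- simulate(m, tmax = 1000, dt_sample = 0.5)
  expect_error(current_difference(sim, short), "grid")
})

test_that("simulation is deterministic and the sampler hits the grid", {
  m <- gnp_model("gnp", pump = pump_spec("constant", I_const = -1.16),
                 stimulus = stimulus_protocol(10, 200, 0.3))
  s1 <- simulate(m, tmax = 250, dt_sample = 0.1)
  s2 <- simulate(m, tmax = 250, dt_sample = 0.1)
  expect_identical(s1$state, s2$state)
  expect_identical(s1$V, s2$V)
  expect_equal(s1$time, seq(0, 250, by = 0.1))
})
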