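#' Integrate a neurodynamic model
#'
#' Runs the variant's ODE system with an adaptive Dormand-Prince 5(4)
#' integrator (compiled), sampling the solution and the current
#' decomposition on a regular grid. The charge-voltage relation of the
#' GNP-family variants has a sensitivity of ~1.2e4 mV per mM, so the
#' default tolerances are tight (rtol 1e-8, atol 1e-10 on concentrations).
#'
#' @param object a [gnp_model()].
#' @param nsim unused (S3 signature compatibility).
#' @param seed unused; the system is deterministic.
#' @param tmax end time (ms).
#' @param t0 start time (ms).
#' @param init initial state; defaults to [initial_state()].
#' @param dt_sample output sampling interval (ms).
#' @param rtol,atol relative/absolute tolerance. `atol` may be a scalar or a
#'   per-variable vector; the default uses 1e-10 for concentrations and V,
#'   1e-10 for gates.
#' @param h_max maximum step (ms).
#' @param record_currents record the current decomposition at every sample
#'   (set `FALSE` to halve memory on very long runs).
#' @param ... unused.
#' @return an object of class `gnp_sim`: a list with `time` (ms), `V` (mV),
#'   `state` (matrix of state trajectories), `currents` (matrix with columns
#'   `IV, IL, IG, INaK, Idiff, IK_diff, INa_diff, ICl_diff, po`), and the
#'   generating `model`.
#' @export
simulate.gnp_model <- function(object, nsim = 1, seed = NULL,
                               tmax = 100, t0 = 0, init = NULL,
                               dt_sample = 0.1, rtol = 1e-8, atol = NULL,
                               h_max = 5, record_currents = TRUE, ...) {
  stopifnot(tmax > t0)
  y0 <- init %||% initial_state(object)
  nv <- length(y0)
  if (is.null(atol)) atol <- rep(1e-10, nv)
  if (length(atol) == 1L) atol <- rep(atol, nv)
  res <- .integrate_cpp(.pack_params(object), as.numeric(y0),
                        t0, tmax, dt_sample,
                        object$stimulus$t_on, object$stimulus$t_off,
                        object$stimulus$po,
                        rtol, atol, 1e-3, h_max, 1e-10, record_currents)
  Y <- res$Y
  colnames(Y) <- names(y0)
  out <- list(time = res$t, state = Y, model = object,
              nsteps = res$nsteps, nreject = res$nreject)
  if (record_currents) {
    C <- res$C
    colnames(C) <- c("V", "IKV", "INaV", "IKL", "INaL", "IClL",
                     "IKG", "INaG", "INaK", "po")
    IV <- C[, "IKV"] + C[, "INaV"]
    IL <- C[, "IKL"] + C[, "INaL"] + C[, "IClL"]
    IG <- C[, "IKG"] + C[, "INaG"]
    out$V <- C[, "V"]
    out$currents <- cbind(
      IV = IV, IL = IL, IG = IG, INaK = C[, "INaK"],
      Idiff = IV + IL + IG,
      IK_diff = C[, "IKV"] + C[, "IKL"] + C[, "IKG"],
      INa_diff = C[, "INaV"] + C[, "INaL"] + C[, "INaG"],
      ICl_diff = C[, "IClL"],
      po = C[, "po"])
  } else {
    out$V <- if ("V" %in% colnames(Y)) Y[, "V"] else {
      p <- object$par
      charge_voltage_coefficient(membrane_geometry(p$Cm_uF_per_cm2,
                                                   p$S_over_v_per_m,
                                                   p$A_in_mM)) *
        (-p$A_in_mM + (p$sigma_K_mM - 2 * Y[, "Ko"]) +
           (2 * Y[, "Nai"] - p$sigma_Na_mM) +
           (p$sigma_Cl_mM - 2 * Y[, "Cli"]))
    }
  }
  class(out) <- "gnp_sim"
  out
}

#' @export
print.gnp_sim <- function(x, ...) {
  cat(sprintf("<gnp_sim> variant '%s', %d samples over [%g, %g] ms\n",
              x$model$variant, length(x$time), min(x$time), max(x$time)))
  sp <- detect_spikes(x$V, x$time)
  cat(sprintf("  %d spikes; V range [%.1f, %.1f] mV\n",
              length(sp), min(x$V), max(x$V)))
  invisible(x)
}

#' @export
plot.gnp_sim <- function(x, ...) {
  graphics::plot(x$time, x$V, type = "l", xlab = "time (ms)",
                 ylab = "V (mV)", main = sprintf("%s model", x$model$variant), ...)
  invisible(x)
}

#' @export
as.data.frame.gnp_sim <- function(x, ...) {
  d <- data.frame(t_ms = x$time, V_mV = x$V, x$state, check.names = FALSE)
  if (!is.null(x$currents)) d <- cbind(d, as.data.frame(x$currents))
  d
}

#' Detect action potentials in a voltage trace
#'
#' Upward crossings of a threshold with a refractory separation.
#'
#' @param V voltage trace (mV).
#' @param time matching time grid (ms), monotone increasing.
#' @param threshold crossing threshold (mV); -20 mV separates spikes from
#'   the depolarization-block plateau.
#' @param refractory minimum separation between detected spikes (ms).
#' @return spike times (ms).
#' @export
detect_spikes <- function(V, time, threshold = -20, refractory = 2) {
  stopifnot(length(V) == length(time), !is.unsorted(time))
  up <- which(V[-1] >= threshold & V[-length(V)] < threshold)
  if (!length(up)) return(numeric())
  times <- time[up + 1L]
  keep <- c(TRUE, diff(times) >= refractory)
  # enforce refractory sequentially, not pairwise
  out <- times[1L]
  for (tt in times[-1L]) if (tt - out[length(out)] >= refractory) out <- c(out, tt)
  out
}

#' Classify the firing state of a simulation
#'
#' Operational rules mapping a trace to one of `resting`,
#' `phasic_spiking`, `tonic_spiking`, `depolarization_block`:
#' * `resting`: no spikes and final V within `rest_band` of the initial V;
#' * `phasic_spiking`: spikes confined to the first half of the window,
#'   with the trace back near rest at the end;
#' * `tonic_spiking`: spiking continues through the window end with
#'   inter-spike-interval coefficient of variation below `cv_max`;
#' * `depolarization_block`: no spikes in the final `db_tail` ms with a
#'   mean voltage above `db_level`.
#'
#' @param sim a `gnp_sim`.
#' @param window `c(t_start, t_end)` ms within the simulated span.
#' @param threshold,refractory passed to [detect_spikes()].
#' @param rest_band mV; `db_level` mV; `db_tail` ms; `cv_max` dimensionless.
#' @return list with `label`, `spike_times` (ms) and `mean_frequency_Hz`.
#' @export
classify_firing <- function(sim, window = range(sim$time), threshold = -20,
                            refractory = 2, rest_band = 10, db_level = -45,
                            db_tail = 500, cv_max = 0.5) {
  stopifnot(inherits(sim, "gnp_sim"))
  if (diff(window) < 2 * db_tail)
    stop("classification window too short (need at least 2 * db_tail)")
  sel <- sim$time >= window[1] & sim$time <= window[2]
  tt <- sim$time[sel]; V <- sim$V[sel]
  spikes <- detect_spikes(V, tt, threshold, refractory)
  tail_sel <- tt >= window[2] - db_tail
  tail_mean_V <- mean(V[tail_sel])
  V_rest <- V[1L]
  mean_freq <- if (length(spikes) > 1L)
    1000 * (length(spikes) - 1L) / diff(range(spikes)) else 0
  n_tail <- sum(spikes >= window[2] - db_tail)
  label <- if (length(spikes) == 0L) {
    if (tail_mean_V > db_level) "depolarization_block" else "resting"
  } else if (n_tail == 0L && tail_mean_V > db_level) {
    "depolarization_block"
  } else if (all(spikes <= window[1] + diff(window) / 2) &&
             abs(tail_mean_V - V_rest) <= rest_band) {
    "phasic_spiking"
  } else {
    isi <- diff(spikes)
    cv <- if (length(isi) > 1L) stats::sd(isi) / mean(isi) else 0
    if (cv < cv_max) "tonic_spiking" else "irregular_spiking"
  }
  list(label = label, spike_times = spikes, mean_frequency_Hz = mean_freq)
}

#' Sliding-window current differences between two simulations
#'
#' Per-ion differences of the electrodiffusive currents between two runs
#' that share a stimulus and span (e.g. vGNP vs GNP), computed from the
#' stored right-hand-side evaluations (concentration derivatives and pump
#' currents), then smoothed with a sliding window (default 8 s width, 4 s
#' step) because the raw differences oscillate at the spike timescale.
#'
#' @param simA,simB `gnp_sim` objects with `record_currents = TRUE`, sharing
#'   the same time grid.
#' @param window_s window width (s).
#' @param step_s window step (s).
#' @return data.frame with window centres `t_s` and the averaged `dIK`,
#'   `dINa`, `dICl`, `dIdiff` (uA/cm^2).
#' @export
current_difference <- function(simA, simB, window_s = 8, step_s = 4) {
  stopifnot(inherits(simA, "gnp_sim"), inherits(simB, "gnp_sim"),
            !is.null(simA$currents), !is.null(simB$currents))
  if (length(simA$time) != length(simB$time) ||
      max(abs(simA$time - simB$time)) > 1e-9)
    stop("simulations do not share a time grid")
  dIK <- simA$currents[, "IK_diff"] - simB$currents[, "IK_diff"]
  dINa <- simA$currents[, "INa_diff"] - simB$currents[, "INa_diff"]
  dICl <- simA$currents[, "ICl_diff"] - simB$currents[, "ICl_diff"]
  t_ms <- simA$time
  w <- window_s * 1000; s <- step_s * 1000
  starts <- seq(t_ms[1L], max(t_ms[1L], t_ms[length(t_ms)] - w), by = s)
  res <- lapply(starts, function(a) {
    sel <- t_ms >= a & t_ms <= a + w
    c(t_s = (a + w / 2) / 1000, dIK = mean(dIK[sel]), dINa = mean(dINa[sel]),
      dICl = mean(dICl[sel]))
  })
  out <- as.data.frame(do.call(rbind, res))
  out$dIdiff <- out$dIK + out$dINa + out$dICl
  out
}
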