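#' Simulation configuration
#'
#' Assembles everything one run of the seizure network needs: network and
#' neuron parameters, the seizure-initiating input, electrical FTSTS
#' protocols and/or an optogenetic light schedule, and recording settings.
#'
#' @param duration total simulated time (ms).
#' @param seed RNG seed; every random element of the run (stimulation
#'   routing, spike sampling) derives from it.
#' @param neuron a [neuron_params()] object (holds `dt`).
#' @param stdp a [stdp_params()] object; set `eta = 0` to freeze plasticity.
#' @param connectivity a [connectivity_spec()].
#' @param seizure `NULL` or a list with `amplitude` (pA), `start` (ms),
#'   `duration` (ms) and `targets` (excitatory indices). The default drives
#'   the central 50 excitatory neurons with 200 pA for 3 s starting at 1 s.
#' @param protocols a single [ftsts_protocol()], a list of them, or `NULL`.
#' @param light `NULL` or a [build_light_schedule()] result.
#' @param record_every_ms cadence of the average-weight trace (ms); window
#'   endpoints of every protocol must fall on this grid.
#' @param record_raster record spike times? (turn off to save memory in
#'   sweeps).
#' @return A list of class `"ftsts_config"`.
#' @examples
#' cfg <- simulation_config(duration = 2000, seed = 1,
#'                          connectivity = connectivity_spec(N_E = 50, N_I = 50),
#'                          seizure = NULL)
#' @export
simulation_config <- function(duration = 16000, seed = 1,
                              neuron = neuron_params(),
                              stdp = stdp_params(),
                              connectivity = connectivity_spec(),
                              seizure = default_seizure(connectivity),
                              protocols = NULL, light = NULL,
                              record_every_ms = 100,
                              record_raster = TRUE) {
  if (inherits(protocols, "ftsts_protocol")) protocols <- list(protocols)
  dt <- neuron$dt
  n_steps <- as_steps(duration, dt, "duration")
  rec <- as_steps(record_every_ms, dt, "recording cadence")
  if (!is.null(seizure)) {
    if (any(seizure$targets < 1 | seizure$targets > connectivity$N_E)) {
      stop("seizure targets out of range", call. = FALSE)
    }
    if (seizure$start + seizure$duration > duration) {
      stop("seizure window extends past the simulation", call. = FALSE)
    }
  }
  for (p in protocols) {
    if (p$onset + p$duration > duration) {
      stop("stimulation window extends past the simulation", call. = FALSE)
    }
  }
  structure(list(duration = duration, n_steps = n_steps, seed = seed,
                 neuron = neuron, stdp = stdp, connectivity = connectivity,
                 seizure = seizure, protocols = protocols, light = light,
                 record_every = rec, record_every_ms = record_every_ms,
                 record_raster = record_raster),
            class = "ftsts_config")
}

#' Default seizure-initiating input
#'
#' 200 pA for 3 s starting at t = 1 s, delivered to the central 50
#' excitatory neurons (the focal site; the induced discharges propagate
#' outward from it).
#'
#' @param connectivity a [connectivity_spec()]; used to centre the targets.
#' @return a seizure description list.
#' @export
default_seizure <- function(connectivity = connectivity_spec()) {
  n <- connectivity$N_E
  lo <- max(1L, floor(n / 2) - 24L)
  list(amplitude = 200, start = 1000, duration = 3000,
       targets = lo:min(n, lo + 49L))
}

#' Seizure input current at a time point
#'
#' Per-excitatory-neuron contribution of the seizure-initiating input:
#' `amplitude` pA on the target neurons while `t` lies inside
#' `[start, start + duration)`, zero elsewhere.
#'
#' @param config an `ftsts_config`.
#' @param t time (ms).
#' @return numeric vector of length `N_E` (pA).
#' @export
seizure_input <- function(config, t) {
  out <- numeric(config$connectivity$N_E)
  sz <- config$seizure
  if (!is.null(sz) && t >= sz$start && t < sz$start + sz$duration) {
    out[sz$targets] <- sz$amplitude
  }
  out
}

# Assemble the per-step stimulation inputs: electrical waveforms (pA),
# routing masks, and channelrhodopsin conductance waveforms (nS).
build_inputs <- function(config) {
  n_steps <- config$n_steps
  dt <- config$neuron$dt
  N_E <- config$connectivity$N_E
  N_I <- config$connectivity$N_I
  t_grid <- (seq_len(n_steps) - 1L) * dt
  wave_E <- numeric(0); wave_I <- numeric(0)
  cross_E <- logical(N_E); cross_I <- logical(N_I)
  if (length(config$protocols)) {
    wave_E <- numeric(n_steps); wave_I <- numeric(n_steps)
    with_overlap <- vapply(config$protocols,
                           function(p) p$overlap_fraction > 0, logical(1))
    if (sum(with_overlap) > 0 && length(config$protocols) > 1) {
      stop("stimulation overlap is supported for a single protocol only",
           call. = FALSE)
    }
    for (p in config$protocols) {
      w <- protocol_waveforms(p, t_grid)
      wave_E <- wave_E + 1000 * w$wave_E          # nA -> pA
      wave_I <- wave_I + 1000 * w$wave_I
      if (p$overlap_fraction > 0) {
        r <- route_stimulation(p, N_E, N_I)       # consumes the RNG stream
        cross_E <- cross_E | r$cross_E
        cross_I <- cross_I | r$cross_I
      }
    }
  }
  gF_E <- numeric(0); gF_I <- numeric(0)
  V_ChR2_E <- 0; V_ChR2_I <- 0
  if (!is.null(config$light)) {
    li <- config$light
    F_blue <- light_waveform(li$blue, t_grid,
                             if (li$blue_target == "E") li$opsin_E else li$opsin_I)
    F_red <- light_waveform(li$red, t_grid,
                            if (li$red_target == "E") li$opsin_E else li$opsin_I)
    if (li$blue_target == "E") {
      gF_E <- li$opsin_E$g_ChR2 * F_blue; V_ChR2_E <- li$opsin_E$V_ChR2
      gF_I <- li$opsin_I$g_ChR2 * F_red;  V_ChR2_I <- li$opsin_I$V_ChR2
    } else {
      gF_I <- li$opsin_I$g_ChR2 * F_blue; V_ChR2_I <- li$opsin_I$V_ChR2
      gF_E <- li$opsin_E$g_ChR2 * F_red;  V_ChR2_E <- li$opsin_E$V_ChR2
    }
  }
  sz <- config$seizure
  list(wave_E = wave_E, wave_I = wave_I, cross_E = cross_E,
       cross_I = cross_I, gF_E = gF_E, gF_I = gF_I,
       V_ChR2_E = V_ChR2_E, V_ChR2_I = V_ChR2_I,
       seiz_amp = if (is.null(sz)) 0 else sz$amplitude,
       seiz_from = if (is.null(sz)) 0L else as_steps(sz$start, dt, "seizure start"),
       seiz_to = if (is.null(sz)) 0L else
         as_steps(sz$start + sz$duration, dt, "seizure end"),
       seiz_targets = if (is.null(sz)) integer(0) else
         as.integer(sz$targets) - 1L)
}

#' Run one simulation of the seizure network
#'
#' Executes the forward-Euler main loop (compiled core): per step, applied
#' current assembly (seizure input + electrical FTSTS + channelrhodopsin
#' photocurrents), membrane update, stochastic spike sampling, two-step spike
#' reset, threshold adaptation, conductance decay and synaptic delivery
#' through the effective weights (base matrix times plastic fraction),
#' chloride/GABA-reversal dynamics, and the STDP update. Fully reproducible:
#' the same configuration and seed give bit-identical rasters and weight
#' traces.
#'
#' @param config an [simulation_config()] object.
#' @param weights optionally a prebuilt [build_connectivity()] result (saves
#'   rebuilding inside sweeps); must match `config$connectivity`.
#' @return An object of class `"ftsts_sim"`: a list with `raster`
#'   (data.frame `neuron_id`, `time_ms`; excitatory neurons first), `weights`
#'   (data.frame `time_ms`, `avg_w_EI_nS`, `avg_w_EE_nS`), final plastic
#'   fractions `Wp_EE`, `Wp_EI`, the base matrices, final population states,
#'   and the resolved `config`.
#' @examples
#' cfg <- simulation_config(duration = 1000, seed = 42,
#'                          connectivity = connectivity_spec(N_E = 40, N_I = 40),
#'                          seizure = NULL)
#' sim <- run_simulation(cfg)
#' sim
#' @export
run_simulation <- function(config, weights = NULL) {
  stopifnot(inherits(config, "ftsts_config"))
  if (is.null(weights)) weights <- build_connectivity(config$connectivity)
  set.seed(config$seed)
  inp <- build_inputs(config)
  np <- config$neuron
  N_E <- config$connectivity$N_E
  N_I <- config$connectivity$N_I
  st_E <- init_state(N_E, np)
  st_I <- init_state(N_I, np)
  res <- sim_core_cpp(unclass(np), unclass(config$stdp),
                      weights$W_EE, weights$W_EI, weights$W_II, weights$W_IE,
                      matrix(1, N_E, N_E), matrix(1, N_E, N_I),
                      config$n_steps,
                      inp$wave_E, inp$wave_I, inp$cross_E, inp$cross_I,
                      inp$seiz_amp, inp$seiz_from, inp$seiz_to,
                      inp$seiz_targets,
                      inp$gF_E, inp$gF_I, inp$V_ChR2_E, inp$V_ChR2_I,
                      config$record_every, config$record_raster,
                      st_E[c("V", "phi", "g_E", "g_I", "g_K", "Cl_in",
                             "E_Cl", "t_last_spike")],
                      st_I[c("V", "phi", "g_E", "g_I", "g_K", "Cl_in",
                             "E_Cl", "t_last_spike")],
                      numeric(N_E), numeric(N_I))
  structure(list(raster = data.frame(neuron_id = res$raster_id,
                                     time_ms = res$raster_t),
                 weights = data.frame(time_ms = res$avg_t,
                                      avg_w_EI_nS = res$avg_w_EI,
                                      avg_w_EE_nS = res$avg_w_EE),
                 Wp_EE = res$Wp_EE, Wp_EI = res$Wp_EI,
                 W = weights, state_E = res$state_E, state_I = res$state_I,
                 config = config),
            class = "ftsts_sim")
}

#' Average E-to-I weight at a recorded time
#'
#' @param result an `ftsts_sim`.
#' @param t time (ms); must be one of the recorded snapshot times.
#' @return average E-to-I weight (nS).
#' @export
weight_at <- function(result, t) {
  i <- match(TRUE, abs(result$weights$time_ms - t) < 1e-9)
  if (is.na(i)) {
    stop("time ", t, " ms was not sampled by the weight trace", call. = FALSE)
  }
  result$weights$avg_w_EI_nS[i]
}

#' Stimulation efficacy: rate of change of the average E-to-I weight
#'
#' The difference in the average E-to-I synaptic weight across a window
#' divided by the window length in seconds — the efficacy readout of a
#' stimulation protocol when the window spans its application.
#'
#' @param result an `ftsts_sim`.
#' @param window length-2 numeric, `(t_start, t_end)` in ms; both must be
#'   sampled by the weight trace.
#' @return rate in nS/s (positive = weight increase).
#' @examples
#' \donttest{
#' cfg <- simulation_config(duration = 2000, seed = 1,
#'                          connectivity = connectivity_spec(N_E = 40, N_I = 40),
#'                          seizure = NULL)
#' efficacy_rate(run_simulation(cfg), c(0, 2000))  # ~0: no stimulation
#' }
#' @export
efficacy_rate <- function(result, window) {
  stopifnot(length(window) == 2, window[2] > window[1])
  (weight_at(result, window[2]) - weight_at(result, window[1])) /
    ((window[2] - window[1]) / 1000)
}

#' @export
print.ftsts_sim <- function(x, ...) {
  cfg <- x$config
  cat("FTSTS seizure-network simulation\n")
  cat(sprintf("  populations : %d excitatory + %d inhibitory\n",
              cfg$connectivity$N_E, cfg$connectivity$N_I))
  cat(sprintf("  duration    : %.1f s at dt = %.2g ms (seed %s)\n",
              cfg$duration / 1000, cfg$neuron$dt, format(cfg$seed)))
  if (!is.null(cfg$seizure)) {
    cat(sprintf("  seizure     : %g pA to %d neurons, t = %.1f-%.1f s\n",
                cfg$seizure$amplitude, length(cfg$seizure$targets),
                cfg$seizure$start / 1000,
                (cfg$seizure$start + cfg$seizure$duration) / 1000))
  }
  for (p in cfg$protocols) {
    cat(sprintf(
      "  protocol    : %s (a_E=%+d, a_I=%+d), %g nA, W=%g ms, T=%g ms, offset %g ms, t = %.1f-%.1f s\n",
      p$name, p$a_E, p$a_I, p$amplitude, p$width, p$inter_pulse_interval,
      p$train_offset, p$onset / 1000, (p$onset + p$duration) / 1000))
  }
  if (!is.null(cfg$light)) {
    cat(sprintf("  optogenetic : %s variant, %d blue / %d red flashes\n",
                cfg$light$direction, nrow(cfg$light$blue),
                nrow(cfg$light$red)))
  }
  cat(sprintf("  spikes      : %d recorded\n", nrow(x$raster)))
  w <- x$weights$avg_w_EI_nS
  cat(sprintf("  avg E-to-I  : %.2f nS initial, %.2f nS final\n",
              w[1], w[length(w)]))
  invisible(x)
}

#' @export
plot.ftsts_sim <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1.5, 1))
  on.exit(graphics::par(op))
  N_E <- x$config$connectivity$N_E
  r <- x$raster
  graphics::plot(r$time_ms / 1000, r$neuron_id, pch = ".", cex = 0.6,
                 col = ifelse(r$neuron_id <= N_E, "black", "firebrick"),
                 xlab = "time (s)", ylab = "neuron",
                 main = "spike raster (red = inhibitory)")
  graphics::plot(x$weights$time_ms / 1000, x$weights$avg_w_EI_nS,
                 type = "l", xlab = "time (s)",
                 ylab = "avg E-to-I weight (nS)", main = "")
  invisible(x)
}

# Pure-R reference main loop built from the exported module operations.
# Consumes the RNG stream in the same order as the compiled core; used by the
# test-suite as an independent oracle for the compiled engine on small
# networks. Arguments mirror run_simulation().
sim_core_r <- function(config, weights = NULL) {
  stopifnot(inherits(config, "ftsts_config"))
  if (is.null(weights)) weights <- build_connectivity(config$connectivity)
  set.seed(config$seed)
  inp <- build_inputs(config)
  np <- config$neuron
  sp <- config$stdp
  dt <- np$dt
  N_E <- config$connectivity$N_E
  N_I <- config$connectivity$N_I
  st_E <- init_state(N_E, np)
  st_I <- init_state(N_I, np)
  ps <- init_plastic_state(N_E, N_I)
  have_wE <- length(inp$wave_E) > 0
  have_wI <- length(inp$wave_I) > 0
  have_gFE <- length(inp$gF_E) > 0
  have_gFI <- length(inp$gF_I) > 0
  seiz_idx <- inp$seiz_targets + 1L
  rec_t <- 0
  rec_w <- average_ei_weight(weights$W_EI, ps$Wp_EI)
  ras_id <- integer(0); ras_t <- numeric(0)
  for (k in seq_len(config$n_steps) - 1L) {
    t_new <- (k + 1) * dt
    I_E <- numeric(N_E)
    if (length(seiz_idx) && k >= inp$seiz_from && k < inp$seiz_to) {
      I_E[seiz_idx] <- I_E[seiz_idx] + inp$seiz_amp
    }
    if (have_wE) I_E <- I_E + inp$wave_E[k + 1]
    if (have_wI) I_E[inp$cross_E] <- I_E[inp$cross_E] + inp$wave_I[k + 1]
    if (have_gFE) I_E <- I_E + (-inp$gF_E[k + 1] * (st_E$V - inp$V_ChR2_E))
    I_I <- numeric(N_I)
    if (have_wI) I_I <- I_I + inp$wave_I[k + 1]
    if (have_wE) I_I[inp$cross_I] <- I_I[inp$cross_I] + inp$wave_E[k + 1]
    if (have_gFI) I_I <- I_I + (-inp$gF_I[k + 1] * (st_I$V - inp$V_ChR2_I))
    st_E <- resolve_spike_reset(membrane_step(st_E, I_E, np, k + 1))
    st_I <- resolve_spike_reset(membrane_step(st_I, I_I, np, k + 1))
    spikes_E <- sample_spikes(st_E, np, t_new)
    spikes_I <- sample_spikes(st_I, np, t_new)
    st_E <- apply_spike_reset(st_E, spikes_E, np, t_new)
    st_I <- apply_spike_reset(st_I, spikes_I, np, t_new)
    if (config$record_raster) {
      ras_id <- c(ras_id, which(spikes_E), N_E + which(spikes_I))
      ras_t <- c(ras_t, rep(t_new, sum(spikes_E) + sum(spikes_I)))
    }
    st_E <- threshold_step(st_E, np)
    st_I <- threshold_step(st_I, np)
    excin_E <- numeric(N_E); excin_I <- numeric(N_I)
    inhin_E <- numeric(N_E); inhin_I <- numeric(N_I)
    for (i in which(spikes_E)) {
      excin_E <- excin_E + weights$W_EE[i, ] * ps$Wp_EE[i, ]
      excin_I <- excin_I + weights$W_EI[i, ] * ps$Wp_EI[i, ]
    }
    for (i in which(spikes_I)) {
      inhin_I <- inhin_I + weights$W_II[i, ]
      inhin_E <- inhin_E + weights$W_IE[i, ]
    }
    st_E <- conductance_step(st_E, excin_E, inhin_E, spikes_E, np)
    st_I <- conductance_step(st_I, excin_I, inhin_I, spikes_I, np)
    st_E <- chloride_step(st_E, np, k + 1)
    st_I <- chloride_step(st_I, np, k + 1)
    if (sp$eta > 0) ps <- stdp_weight_update(ps, spikes_E, spikes_I, sp)
    ps <- stdp_trace_step(ps, spikes_E, spikes_I, sp, dt)
    if ((k + 1) %% config$record_every == 0) {
      rec_t <- c(rec_t, t_new)
      rec_w <- c(rec_w, average_ei_weight(weights$W_EI, ps$Wp_EI))
    }
  }
  structure(list(raster = data.frame(neuron_id = ras_id, time_ms = ras_t),
                 weights = data.frame(time_ms = rec_t, avg_w_EI_nS = rec_w),
                 Wp_EE = ps$Wp_EE, Wp_EI = ps$Wp_EI, W = weights,
                 state_E = st_E, state_I = st_I, config = config),
            class = "ftsts_sim")
}
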