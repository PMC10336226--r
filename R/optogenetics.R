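#' Channelrhodopsin photocurrent parameters
#'
#' Reduced channelrhodopsin model: a light pulse of intensity `W_light`
#' opens the channel after a light-dependent delay `d`, with an activation
#' saturating toward `A_act` at rate `1/tau_act` and a two-exponential
#' inactivation toward the persistent level `A_persist`. After light-off the
#' conductance waveform decays exponentially with `tau_off`. Two presets are
#' shipped: `"chronos"` (fast, blue-light driven, tau_off = 3.6 ms) and
#' `"chrimson"` (slow, red-light driven, tau_off = 15.8 ms); they differ only
#' in `tau_off` and their default light intensity.
#'
#' @param opsin `"chronos"` or `"chrimson"`.
#' @param ... named overrides of any parameter.
#' @return A list of class `"ftsts_chr_params"` with shape constants
#'   (`W_inact`, `d_A`, `d_B`, `d_C`), activation constants (`tau_act0`,
#'   `c_act`, `k_act`, `a0`, `a_min`, `W_half`), inactivation constants
#'   (`b0`, `b1`, `b2`, `c_inact`, `k_inact`, `tau_inact1`, `tau_inact2`),
#'   the electrical constants `V_ChR2` (mV) and `g_ChR2` (nS), the
#'   off-decay `tau_off` (ms), the default applied intensity `W_light`
#'   (dimensionless) and the bookkeeping constant `gamma` (kept in the
#'   configuration; unused by the reduced equations).
#' @examples
#' chr_params("chronos")$tau_off   # 3.6 ms
#' chr_params("chrimson")$tau_off  # 15.8 ms
#' @export
chr_params <- function(opsin = c("chronos", "chrimson"), ...) {
  opsin <- match.arg(opsin)
  p <- list(opsin = opsin, W_inact = 0.11, tau_inact1 = 9.06, d_A = 0.27,
            d_B = -0.05, d_C = -0.0126, tau_act0 = 0.74, c_act = 12,
            k_act = 25, a0 = 1, a_min = 0.4, W_half = 0.38, b0 = 0.16,
            b1 = 0.013, b2 = 0.027, tau_inact2 = 59.6, c_inact = 0.29,
            k_inact = 2.4, V_ChR2 = 0, g_ChR2 = 294, gamma = 1 / 6,
            tau_off = if (opsin == "chronos") 3.6 else 15.8,
            W_light = if (opsin == "chronos") 0.0308 else 0.0023)
  dots <- list(...)
  p[names(dots)] <- dots
  stopifnot(p$tau_off > 0, p$tau_act0 > 0, p$g_ChR2 >= 0)
  structure(p, class = "ftsts_chr_params")
}

#' Light-intensity-dependent activation variables
#'
#' Evaluates the algebraic intensity dependencies of the reduced
#' channelrhodopsin model: the activation delay
#' `d = d_A + d_B W + d_C W`, the activation time constant
#' `tau_act = tau_act0 + c_act exp(-k_act W)`, the activation amplitude
#' `A_act = a0 + (a_min - 1) / (1 + (W_half / W)^2)`, the two inactivation
#' amplitudes, and the persistent level
#' `A_persist = 1 - A_inact1 - A_inact2` (the three always sum to one).
#'
#' @param W_light applied light intensity (dimensionless, > 0).
#' @param params a [chr_params()] object.
#' @return A list with `d`, `tau_act`, `A_act`, `A_inact1`, `A_inact2`,
#'   `A_persist`.
#' @examples
#' v <- chr_activation_vars(0.0308, chr_params("chronos"))
#' v$A_inact1 + v$A_inact2 + v$A_persist  # 1
#' @export
chr_activation_vars <- function(W_light, params) {
  stopifnot(W_light > 0)
  d <- params$d_A + params$d_B * W_light + params$d_C * W_light
  tau_act <- params$tau_act0 + params$c_act * exp(-params$k_act * W_light)
  A_act <- params$a0 + (params$a_min - 1) / (1 + (params$W_half / W_light)^2)
  A_inact1 <- params$b0 + params$b1 /
    (params$b2 + (W_light - params$W_inact)^2)
  A_inact2 <- params$c_inact * exp(-params$k_inact * W_light)
  list(d = d, tau_act = tau_act, A_act = A_act, A_inact1 = A_inact1,
       A_inact2 = A_inact2, A_persist = 1 - A_inact1 - A_inact2)
}

#' Channelrhodopsin conductance waveform for one light pulse
#'
#' During the pulse (for `t >= t_on + d`) the dimensionless conductance
#' waveform is
#' \deqn{F = A_{act} (1 - e^{-\tau_e/\tau_{act}})
#'   (A_{persist} + A^{(1)}_{inact} e^{-\tau_e/\tau^{(1)}_{inact}}
#'    + A^{(2)}_{inact} e^{-\tau_e/\tau^{(2)}_{inact}}),}
#' with \eqn{\tau_e = t - t_{on} - d}. Before the delayed opening `F = 0`;
#' after light-off `F` decays from its value at `t_off` with `tau_off`.
#'
#' @param t time(s) (ms), scalar or vector, each `>= pulse$t_on`.
#' @param pulse a list with `t_on`, `t_off` (ms) and optionally `W_light`
#'   (defaults to `params$W_light`).
#' @param params a [chr_params()] object.
#' @return dimensionless conductance value(s) `F`.
#' @export
chr_conductance <- function(t, pulse, params) {
  W <- if (is.null(pulse$W_light)) params$W_light else pulse$W_light
  v <- chr_activation_vars(W, params)
  f_on <- function(tt) {
    te <- tt - pulse$t_on - v$d
    out <- numeric(length(te))
    open <- te >= 0
    te <- te[open]
    out[open] <- v$A_act * (1 - exp(-te / v$tau_act)) *
      (v$A_persist + v$A_inact1 * exp(-te / params$tau_inact1) +
         v$A_inact2 * exp(-te / params$tau_inact2))
    out
  }
  F <- numeric(length(t))
  on <- t <= pulse$t_off
  F[on] <- f_on(t[on])
  if (any(!on)) {
    F_off <- f_on(pulse$t_off)
    F[!on] <- F_off * exp(-(t[!on] - pulse$t_off) / params$tau_off)
  }
  F
}

#' Channelrhodopsin photocurrent
#'
#' `I = -g_ChR2 * F * (V - V_ChR2)` (pA with nS and mV inputs); added to the
#' membrane equation of every neuron expressing the opsin. With the default
#' reversal at 0 mV the current depolarizes any hyperpolarized neuron.
#'
#' @param V membrane potential(s) (mV).
#' @param F dimensionless conductance waveform value(s), `>= 0`.
#' @param params a [chr_params()] object.
#' @return current(s) in pA.
#' @export
chr_current <- function(V, F, params) {
  stopifnot(all(F >= 0))
  -params$g_ChR2 * F * (V - params$V_ChR2)
}

#' Build the optogenetic FTSTS light schedules
#'
#' Constructs the paired blue/red flash trains and the opsin-to-population
#' assignment for the optogenetic FTSTS protocol. For the weight-`increase`
#' variant Chronos sits in the excitatory population (blue light) and
#' Chrimson in the inhibitory population (red light), and the blue
#' (excitatory) flashes lead the red flashes by `lead` ms. For the
#' `decrease` variant the opsins are swapped: Chronos in the inhibitory
#' population, whose blue flashes lead the red (excitatory) flashes by
#' `lead` ms. Flashes of width `width` repeat every `period` ms within
#' `[onset, onset + duration)`.
#'
#' @param direction `"increase"` or `"decrease"` of the average E-to-I weight.
#' @param onset schedule start (ms).
#' @param duration schedule length (ms).
#' @param width flash width (ms).
#' @param period flash repetition period (ms); default 12 ms, the electrical
#'   FTSTS cadence (2 x 1 ms + 10 ms).
#' @param lead lead of the blue flashes over the red flashes (ms).
#' @return A list of class `"ftsts_light_schedule"` with data frames `blue`
#'   and `red` (columns `t_on`, `t_off`), intensities and opsin parameter
#'   sets per population (`opsin_E`, `opsin_I`), and the channel-to-
#'   population map (`blue_target`, `red_target`).
#' @examples
#' sch <- build_light_schedule("decrease", onset = 0, duration = 48)
#' head(sch$blue)
#' @export
build_light_schedule <- function(direction = c("increase", "decrease"),
                                 onset = 10000, duration = 10000, width = 1,
                                 period = 12, lead = 2) {
  direction <- match.arg(direction)
  starts <- if (duration >= width) {
    seq(onset, onset + duration - width, by = period)
  } else {
    numeric(0)
  }
  pulses <- function(shift) {
    keep <- starts + shift + width <= onset + duration
    data.frame(t_on = starts[keep] + shift, t_off = starts[keep] + shift + width)
  }
  blue <- pulses(0)
  red <- pulses(lead)
  if (direction == "increase") {
    list2 <- list(blue = blue, red = red,
                  opsin_E = chr_params("chronos"),
                  opsin_I = chr_params("chrimson"),
                  blue_target = "E", red_target = "I",
                  direction = direction)
  } else {
    list2 <- list(blue = blue, red = red,
                  opsin_E = chr_params("chrimson"),
                  opsin_I = chr_params("chronos"),
                  blue_target = "I", red_target = "E",
                  direction = direction)
  }
  structure(list2, class = "ftsts_light_schedule")
}

#' Rasterize a flash train into a conductance waveform
#'
#' Evaluates the total dimensionless channelrhodopsin conductance on a
#' uniform time grid by linear superposition of the single-pulse waveforms
#' of [chr_conductance()] (each flash contributes its activation transient
#' during the flash and its `tau_off` decay afterwards), clamped at 1.
#' There is no cross-talk: a flash train only drives the opsin it is built
#' for.
#'
#' @param pulses data frame with `t_on`, `t_off` (ms).
#' @param t_grid uniformly spaced sample times (ms).
#' @param params a [chr_params()] object for the driven opsin.
#' @param W_light applied intensity; defaults to `params$W_light`.
#' @return numeric vector `F(t)` on the grid.
#' @export
light_waveform <- function(pulses, t_grid, params, W_light = params$W_light) {
  F_tot <- numeric(length(t_grid))
  if (nrow(pulses) == 0) return(F_tot)
  dt <- if (length(t_grid) > 1) t_grid[2] - t_grid[1] else 1
  tail_ms <- params$tau_off * 36   # decay factor < 3e-16 beyond this
  t0 <- t_grid[1]
  for (i in seq_len(nrow(pulses))) {
    p <- list(t_on = pulses$t_on[i], t_off = pulses$t_off[i],
              W_light = W_light)
    i_lo <- max(1L, floor((p$t_on - t0) / dt) + 1L)
    i_hi <- min(length(t_grid), ceiling((p$t_off + tail_ms - t0) / dt) + 1L)
    if (i_lo > length(t_grid) || i_hi < 1L) next
    idx <- i_lo:i_hi
    tt <- t_grid[idx]
    sel <- tt >= p$t_on
    F_tot[idx[sel]] <- F_tot[idx[sel]] +
      chr_conductance(tt[sel], p, params)
  }
  pmin(F_tot, 1)
}
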