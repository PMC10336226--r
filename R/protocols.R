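#' Biphasic pulse-train specification
#'
#' A charge-balanced biphasic square pulse train: two contiguous phases of
#' width `width` and amplitude `amplitude` each, separated from the next
#' pulse pair by `inter_pulse_interval` ms of zero current, so the cycle
#' period is `2 * width + inter_pulse_interval`. Polarity +1 begins with the
#' negative phase (-A then +A); polarity -1 begins with the positive phase.
#'
#' @param amplitude pulse amplitude A (nA).
#' @param width phase width W (ms).
#' @param inter_pulse_interval zero-current gap T between pulse pairs (ms).
#' @param polarity `+1` or `-1`.
#' @param onset start of the stimulation window (ms).
#' @param duration length of the stimulation window (ms).
#' @return A list of class `"ftsts_pulse_train"`.
#' @examples
#' pulse_train_spec()  # study defaults: 2 nA, 1 ms, 10 ms gap
#' @export
pulse_train_spec <- function(amplitude = 2, width = 1,
                             inter_pulse_interval = 10, polarity = 1L,
                             onset = 0, duration = 5000) {
  if (width <= 0) stop("pulse width must be > 0", call. = FALSE)
  if (inter_pulse_interval < 0) {
    stop("inter-pulse interval must be >= 0", call. = FALSE)
  }
  if (!polarity %in% c(-1L, 1L)) {
    stop("polarity must be +1 or -1", call. = FALSE)
  }
  structure(list(amplitude = amplitude, width = width,
                 inter_pulse_interval = inter_pulse_interval,
                 polarity = as.integer(polarity), onset = onset,
                 duration = duration,
                 period = 2 * width + inter_pulse_interval),
            class = "ftsts_pulse_train")
}

#' FTSTS protocol specification
#'
#' The paired pulse trains delivered to the excitatory and inhibitory
#' populations. The four named protocols fix the polarity pair
#' (`a_E`, `a_I`): standard (+1, -1), inverted-standard (-1, +1), mirrored
#' (+1, +1) and inverted-mirrored (-1, -1). The train-offset time is the
#' start time of the inhibitory train minus that of the excitatory train;
#' positive values delay the inhibitory train. `overlap_fraction` is the
#' fraction of each population that additionally receives the other
#' population's train (partially inseparable populations).
#'
#' @param name one of `"standard"`, `"inverted-standard"`, `"mirrored"`,
#'   `"inverted-mirrored"`, or `NULL` to give `a_E`/`a_I` explicitly.
#' @param a_E,a_I explicit polarities, used when `name` is `NULL`.
#' @param amplitude pulse amplitude (nA).
#' @param width phase width (ms).
#' @param inter_pulse_interval gap between pulse pairs (ms).
#' @param train_offset train-offset time (ms) applied to the inhibitory train.
#' @param onset stimulation window start (ms).
#' @param duration stimulation window length (ms).
#' @param overlap_fraction value in \[0, 1\].
#' @return A list of class `"ftsts_protocol"`.
#' @examples
#' ftsts_protocol("inverted-standard", train_offset = -0.5)
#' @export
ftsts_protocol <- function(name = c("standard", "inverted-standard",
                                    "mirrored", "inverted-mirrored"),
                           a_E = NULL, a_I = NULL, amplitude = 2, width = 1,
                           inter_pulse_interval = 10, train_offset = 0,
                           onset = 10000, duration = 5000,
                           overlap_fraction = 0) {
  pol_table <- list("standard" = c(1L, -1L), "inverted-standard" = c(-1L, 1L),
                    "mirrored" = c(1L, 1L), "inverted-mirrored" = c(-1L, -1L))
  if (is.null(a_E) || is.null(a_I)) {
    name <- match.arg(name)
    pol <- pol_table[[name]]
    a_E <- pol[1]; a_I <- pol[2]
  } else {
    a_E <- as.integer(sign(a_E)); a_I <- as.integer(sign(a_I))
    match <- vapply(pol_table, function(p) p[1] == a_E && p[2] == a_I,
                    logical(1))
    name <- names(pol_table)[match]
  }
  if (overlap_fraction < 0 || overlap_fraction > 1) {
    stop("overlap_fraction must be in [0, 1]", call. = FALSE)
  }
  structure(list(name = name, a_E = a_E, a_I = a_I, amplitude = amplitude,
                 width = width, inter_pulse_interval = inter_pulse_interval,
                 train_offset = train_offset, onset = onset,
                 duration = duration, overlap_fraction = overlap_fraction,
                 period = 2 * width + inter_pulse_interval),
            class = "ftsts_protocol")
}

as_steps <- function(x, dt, what) {
  s <- x / dt
  if (abs(s - round(s)) > 1e-9) {
    stop(what, " (", x, " ms) is not an integer multiple of dt = ", dt,
         " ms; bit-exact waveforms require grid alignment", call. = FALSE)
  }
  as.integer(round(s))
}

#' Sample a biphasic pulse train on a time grid
#'
#' Emits the waveform value at each sample time (the value applies over the
#' following `dt`). The stimulation window is `[onset, onset + duration)`;
#' the `offset` shifts the phase of the periodic pulse pattern inside that
#' window, so offsets differing by a whole period `2W + T` produce
#' bit-identical waveforms. Only biphasic pulse pairs lying completely inside
#' the window are emitted, so every generated train integrates to exactly
#' zero net charge.
#'
#' @param spec a [pulse_train_spec()].
#' @param t_grid uniformly spaced sample times (ms) at the simulation step.
#' @param offset pattern phase shift (ms), e.g. the train-offset of the
#'   inhibitory train; positive values delay the pattern.
#' @return numeric vector of currents (nA), one per sample time.
#' @examples
#' tr <- pulse_train_spec(width = 1, inter_pulse_interval = 10,
#'                        onset = 0, duration = 24)
#' w <- build_pulse_train(tr, seq(0, 23.5, by = 0.5))
#' sum(w) * 0.5  # zero net charge
#' @export
build_pulse_train <- function(spec, t_grid, offset = 0) {
  dt <- if (length(t_grid) > 1) t_grid[2] - t_grid[1] else spec$width
  Ws <- as_steps(spec$width, dt, "pulse width")
  Ts <- as_steps(spec$inter_pulse_interval, dt, "inter-pulse interval")
  win0 <- as_steps(spec$onset, dt, "onset")
  durs <- as_steps(spec$duration, dt, "duration")
  anchor <- win0 + as_steps(offset, dt, "train offset")
  t0s <- as_steps(t_grid[1], dt, "grid origin")
  period <- 2L * Ws + Ts
  win1 <- win0 + durs
  k <- seq_along(t_grid) - 1L + t0s          # absolute step index of samples
  cyc <- (k - anchor) %% period              # position within the pulse cycle
  pulse_start <- k - cyc
  emit <- pulse_start >= win0 & pulse_start + 2L * Ws <= win1
  first <- cyc < Ws                          # first phase of the pulse pair
  second <- cyc >= Ws & cyc < 2L * Ws
  s <- ifelse(first, -spec$polarity, ifelse(second, spec$polarity, 0)) *
    as.numeric(emit)
  spec$amplitude * s
}

#' Build the paired FTSTS waveforms for both populations
#'
#' The excitatory train starts at the protocol onset; the inhibitory train is
#' shifted by the train-offset time. Waveforms are periodic in the offset
#' with period `2 * width + inter_pulse_interval`.
#'
#' @param protocol an [ftsts_protocol()].
#' @param t_grid uniformly spaced sample times (ms).
#' @return A list with numeric vectors `wave_E` and `wave_I` (nA).
#' @export
protocol_waveforms <- function(protocol, t_grid) {
  base <- pulse_train_spec(amplitude = protocol$amplitude,
                           width = protocol$width,
                           inter_pulse_interval = protocol$inter_pulse_interval,
                           polarity = 1L, onset = protocol$onset,
                           duration = protocol$duration)
  tr_E <- base; tr_E$polarity <- protocol$a_E
  tr_I <- base; tr_I$polarity <- protocol$a_I
  list(wave_E = build_pulse_train(tr_E, t_grid, offset = 0),
       wave_I = build_pulse_train(tr_I, t_grid, offset = protocol$train_offset))
}

#' Assign stimulation trains to neurons
#'
#' Every excitatory neuron receives the excitatory train and every inhibitory
#' neuron the (offset) inhibitory train. With a positive overlap fraction, a
#' uniformly drawn `floor(fraction * N)`-subset of each population receives
#' the other population's train summed in. Subsets are drawn without
#' replacement from the current R random stream, independently per
#' population, so a fixed seed yields identical routing.
#'
#' @param protocol an [ftsts_protocol()].
#' @param N_E,N_I population sizes.
#' @return A list with logical vectors `cross_E` (excitatory neurons that
#'   also receive the inhibitory train) and `cross_I`.
#' @export
route_stimulation <- function(protocol, N_E, N_I) {
  f <- protocol$overlap_fraction
  cross_E <- logical(N_E); cross_I <- logical(N_I)
  if (f > 0) {
    cross_E[sample.int(N_E, floor(f * N_E))] <- TRUE
    cross_I[sample.int(N_I, floor(f * N_I))] <- TRUE
  }
  list(cross_E = cross_E, cross_I = cross_I)
}
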