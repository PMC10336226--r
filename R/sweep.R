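#' Parameter-sweep specification
#'
#' A full-factorial grid over FTSTS pulse parameters, evaluated with several
#' seeds per cell on a common base configuration. Every cell runs the
#' standard experiment of the base configuration (seizure induction plus one
#' stimulation window) and is scored by [efficacy_rate()] over the
#' stimulation window.
#'
#' @param amplitude amplitudes (nA).
#' @param train_offset train-offset times (ms).
#' @param width pulse widths (ms).
#' @param inter_pulse_interval inter-pulse intervals (ms).
#' @param polarity list of `c(a_E, a_I)` pairs.
#' @param overlap_fraction overlap fractions in \[0, 1\].
#' @param seeds integer vector of seeds per cell (>= 1).
#' @param base_config an [simulation_config()] whose single protocol supplies
#'   the non-swept parameters and the stimulation window.
#' @return A list of class `"ftsts_sweep_spec"`.
#' @export
sweep_spec <- function(amplitude = 2, train_offset = 0, width = 1,
                       inter_pulse_interval = 10,
                       polarity = list(c(-1, 1)), overlap_fraction = 0,
                       seeds = 1:5, base_config) {
  stopifnot(length(seeds) >= 1, length(amplitude) >= 1,
            inherits(base_config, "ftsts_config"),
            length(base_config$protocols) == 1)
  structure(list(amplitude = amplitude, train_offset = train_offset,
                 width = width, inter_pulse_interval = inter_pulse_interval,
                 polarity = polarity, overlap_fraction = overlap_fraction,
                 seeds = as.integer(seeds), base_config = base_config),
            class = "ftsts_sweep_spec")
}

#' Run a parameter sweep
#'
#' Runs [run_simulation()] for every grid cell and seed, scoring each run by
#' the rate of change of the average E-to-I weight over the stimulation
#' window. Connectivity is built once and shared. A failing cell is recorded
#' (`NA` rate, message in `error`) and the sweep continues.
#'
#' @param spec a [sweep_spec()].
#' @param progress print one line per cell?
#' @return A list of class `"ftsts_sweep"` with `runs` (one row per cell and
#'   seed: parameters, `seed`, `rate_nS_per_s`, `error`) and `cells`
#'   (per-cell `mean_rate`, `sd_rate`, `n_seeds`).
#' @export
run_sweep <- function(spec, progress = FALSE) {
  stopifnot(inherits(spec, "ftsts_sweep_spec"))
  base <- spec$base_config
  proto0 <- base$protocols[[1]]
  grid <- expand.grid(amplitude = spec$amplitude,
                      train_offset = spec$train_offset,
                      width = spec$width,
                      inter_pulse_interval = spec$inter_pulse_interval,
                      ipol = seq_along(spec$polarity),
                      overlap_fraction = spec$overlap_fraction,
                      KEEP.OUT.ATTRS = FALSE)
  W <- build_connectivity(base$connectivity)
  rows <- vector("list", nrow(grid) * length(spec$seeds))
  r <- 0L
  for (g in seq_len(nrow(grid))) {
    pol <- spec$polarity[[grid$ipol[g]]]
    for (s in spec$seeds) {
      r <- r + 1L
      rate <- NA_real_; err <- NA_character_
      res <- tryCatch({
        proto <- ftsts_protocol(a_E = pol[1], a_I = pol[2],
                                amplitude = grid$amplitude[g],
                                width = grid$width[g],
                                inter_pulse_interval =
                                  grid$inter_pulse_interval[g],
                                train_offset = grid$train_offset[g],
                                onset = proto0$onset,
                                duration = proto0$duration,
                                overlap_fraction = grid$overlap_fraction[g])
        cfg <- base
        cfg$protocols <- list(proto)
        cfg$seed <- s
        cfg$record_raster <- FALSE
        sim <- run_simulation(cfg, weights = W)
        efficacy_rate(sim, c(proto$onset, proto$onset + proto$duration))
      }, error = function(e) conditionMessage(e))
      if (is.numeric(res)) rate <- res else err <- res
      rows[[r]] <- data.frame(amplitude = grid$amplitude[g],
                              train_offset = grid$train_offset[g],
                              width = grid$width[g],
                              inter_pulse_interval =
                                grid$inter_pulse_interval[g],
                              a_E = pol[1], a_I = pol[2],
                              overlap_fraction = grid$overlap_fraction[g],
                              seed = s, rate_nS_per_s = rate,
                              error = err)
      if (progress) {
        message(sprintf("cell %d/%d seed %d: rate = %s nS/s", g, nrow(grid),
                        s, format(rate, digits = 4)))
      }
    }
  }
  runs <- do.call(rbind, rows)
  key <- c("amplitude", "train_offset", "width", "inter_pulse_interval",
           "a_E", "a_I", "overlap_fraction")
  cells <- stats::aggregate(runs$rate_nS_per_s, by = runs[key],
                            FUN = function(x) c(mean = mean(x, na.rm = TRUE),
                                                sd = stats::sd(x),
                                                n = sum(!is.na(x))))
  cells <- cbind(cells[key], mean_rate = cells$x[, "mean"],
                 sd_rate = cells$x[, "sd"], n_seeds = cells$x[, "n"])
  structure(list(runs = runs, cells = cells, spec = spec),
            class = "ftsts_sweep")
}

#' Per-synapse percent change map
#'
#' `100 * (W_end - W_start) / W_start` elementwise; entries with a zero
#' baseline are returned as `NA` (undefined).
#'
#' @param W_start,W_end effective weight matrices of identical shape.
#' @return matrix of percent changes.
#' @examples
#' percent_change_map(matrix(2, 2, 2), matrix(3, 2, 2))  # all +50
#' @export
percent_change_map <- function(W_start, W_end) {
  if (!all(dim(W_start) == dim(W_end))) {
    stop("percent_change_map: shape mismatch", call. = FALSE)
  }
  out <- 100 * (W_end - W_start) / W_start
  out[W_start == 0] <- NA_real_
  out
}

#' Export sweep results and figures
#'
#' Writes `runs.csv` (long format), `summary.csv` (per-cell mean and sd,
#' sorted by |mean rate|, best-parameter table style) and, when requested, a
#' PNG surface/profile figure per polarity pair. Output is deterministic:
#' identical results produce identical CSV bytes. A `run_info.txt` records
#' the seeds and a hash of the grid.
#'
#' @param sweep an `ftsts_sweep`.
#' @param dir output directory (created if needed).
#' @param figures write PNG figures?
#' @return `dir`, invisibly.
#' @export
export_report <- function(sweep, dir, figures = TRUE) {
  stopifnot(inherits(sweep, "ftsts_sweep"))
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE)
  if (!ok) stop("cannot create output directory ", dir, call. = FALSE)
  runs_path <- file.path(dir, "runs.csv")
  utils::write.csv(sweep$runs, runs_path, row.names = FALSE)
  cells <- sweep$cells
  cells <- cells[order(-abs(cells$mean_rate)), , drop = FALSE]
  utils::write.csv(cells, file.path(dir, "summary.csv"), row.names = FALSE)
  info <- c(sprintf("seeds: %s", paste(sweep$spec$seeds, collapse = ",")),
            sprintf("cells: %d", nrow(cells)),
            sprintf("grid_hash: %s",
                    sum(as.integer(charToRaw(paste(
                      utils::capture.output(utils::str(sweep$spec[1:6])),
                      collapse = ""))))))
  writeLines(info, file.path(dir, "run_info.txt"))
  if (figures && nrow(cells) > 0) {
    pols <- unique(cells[c("a_E", "a_I")])
    for (p in seq_len(nrow(pols))) {
      sel <- cells$a_E == pols$a_E[p] & cells$a_I == pols$a_I[p]
      cc <- cells[sel, , drop = FALSE]
      fn <- file.path(dir, sprintf("efficacy_aE%+d_aI%+d.png",
                                   pols$a_E[p], pols$a_I[p]))
      grDevices::png(fn, width = 800, height = 600)
      xvar <- if (length(unique(cc$train_offset)) > 1) "train_offset"
              else "amplitude"
      graphics::plot(cc[[xvar]], cc$mean_rate, type = "b", pch = 19,
                     xlab = xvar, ylab = "rate of weight change (nS/s)",
                     main = sprintf("a_E = %+d, a_I = %+d",
                                    pols$a_E[p], pols$a_I[p]))
      graphics::abline(h = 0, lty = 2)
      grDevices::dev.off()
    }
  }
  invisible(dir)
}
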