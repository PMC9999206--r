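#' Trace synthesis configuration
#'
#' Settings for generating sampled differential impedance traces from a
#' droplet stream. The two electrode pairs subtract, so each droplet
#' contributes a bipolar template: a positive lobe at the first pair and a
#' mirrored negative lobe at the second.
#'
#' @param sample_rate_hz Sampling rate (default 500 kHz).
#' @param noise_sd_uA Additive white Gaussian noise level in uA
#'   (default 0.02).
#' @param flow_velocity_um_s Droplet transport velocity (default 80 mm/s).
#' @param electrode_pitch_um Center-to-center distance between the two
#'   electrode pairs (default 140 um): sets the lobe separation.
#' @param amplitude_table Named mean peak amplitudes in uA for classes
#'   `empty`, `single`, `multi2`, `multi3`, `permeabilized`; see
#'   [amplitude_from_model()]. The defaults are the field-solver-derived
#'   table scaled so two-cell droplets sit above a 0.4 uA gate.
#' @param position_jitter_sd Standard deviation of the error linking a
#'   cell's true fractional position to the sub-peak offset recovered from
#'   the trace (default 0.153, giving a position correlation R^2 of about
#'   0.78 for uniform positions).
#' @param amplitude_cv Droplet-to-droplet relative spread of the class
#'   mean amplitude (default 0.05).
#' @param coincidence Allow overlapping droplet templates to superpose
#'   instead of raising (default FALSE).
#' @return A `trace_config` object.
#' @export
trace_config <- function(sample_rate_hz = 5e5, noise_sd_uA = 0.02,
                         flow_velocity_um_s = 8e4,
                         electrode_pitch_um = 140,
                         amplitude_table = default_amplitude_table(),
                         position_jitter_sd = 0.153,
                         amplitude_cv = 0.05,
                         coincidence = FALSE) {
  stopifnot(sample_rate_hz > 0, noise_sd_uA >= 0, flow_velocity_um_s > 0,
            electrode_pitch_um > 0, position_jitter_sd >= 0,
            amplitude_cv >= 0)
  check_amplitude_table(amplitude_table)
  structure(list(sample_rate_hz = sample_rate_hz,
                 noise_sd_uA = noise_sd_uA,
                 flow_velocity_um_s = flow_velocity_um_s,
                 electrode_pitch_um = electrode_pitch_um,
                 amplitude_table = amplitude_table,
                 position_jitter_sd = position_jitter_sd,
                 amplitude_cv = amplitude_cv,
                 coincidence = coincidence),
            class = "trace_config")
}

check_amplitude_table <- function(tab) {
  need <- c("empty", "single", "multi2", "multi3", "permeabilized")
  if (!all(need %in% names(tab)))
    stop("amplitude_table must name: ", paste(need, collapse = ", "))
  if (!(tab[["empty"]] < tab[["single"]] &&
        tab[["single"]] < tab[["multi2"]] &&
        tab[["multi2"]] <= tab[["multi3"]]))
    stop("amplitude ordering violated: need empty < single < multi2 <= multi3")
  invisible(tab)
}

#' Default class amplitude table (uA)
#'
#' Frozen output of [amplitude_from_model()] under the default geometry,
#' low-conductivity medium and 40 MHz probe, so trace synthesis does not
#' require a field solve. Regenerate with `amplitude_from_model()` after
#' changing the dielectric configuration.
#'
#' @return Named numeric vector of mean peak amplitudes in uA.
#' @export
default_amplitude_table <- function() {
  c(empty = 0.2126, single = 0.3126, multi2 = 0.4500, multi3 = 0.4811,
    permeabilized = 0.1921)
}

#' Class amplitude table from the dielectric model
#'
#' Runs the field solver for the carrier oil alone, an empty droplet,
#' 1-3 cell aggregates and a permeabilized single cell at the probe
#' frequency. The peak amplitude of class k is the droplet-passing signal
#' \eqn{|I_k - I_{oil}|}, scaled to uA such that the two-cell class lands
#' at `multi2_uA` — placing multi-cell droplets above a 0.4 uA gate while
#' preserving the solver's relative class spacing.
#'
#' @param geometry An [electrode_geometry()].
#' @param f Probe frequency (default 40 MHz).
#' @param medium Droplet medium.
#' @param cell Cell model.
#' @param multi2_uA Target mean amplitude of the two-cell class
#'   (default 0.45).
#' @param grid_step_um Solver grid step.
#' @return Named numeric vector as in [default_amplitude_table()].
#' @export
amplitude_from_model <- function(geometry = electrode_geometry(), f = 40e6,
                                 medium = medium_low_conductivity(),
                                 cell = shell_cell(), multi2_uA = 0.45,
                                 grid_step_um = 0.5) {
  Ioil <- electrode_current(geometry, droplet_scene(0), f, grid_step_um)
  Ik <- lapply(0:3, function(k) {
    electrode_current(geometry, scene_k_cells(k, medium = medium,
                                              cell = cell), f, grid_step_um)
  })
  A <- vapply(Ik, function(I) Mod(I - Ioil), 0)
  if (any(diff(A) <= 0))
    stop("non-monotone cell-count amplitudes from the field solver")
  Iperm <- electrode_current(geometry,
                             scene_k_cells(1, medium = medium,
                                           cell = shell_cell(
                                             radius_um = cell$radius_um,
                                             viable = FALSE)),
                             f, grid_step_um)
  A_perm <- Mod(Iperm - Ioil)
  scale <- multi2_uA / A[3]
  tab <- c(empty = A[1], single = A[2], multi2 = A[3], multi3 = A[4],
           permeabilized = A_perm) * scale
  check_amplitude_table(tab)
}

# class label of a droplet from ground truth
true_class <- function(cell_count, viable_flags) {
  k_viable <- sum(viable_flags)
  if (cell_count == 0) "empty"
  else if (k_viable == 0) "permeabilized"
  else if (k_viable == 1) "single"
  else if (k_viable == 2) "multi2"
  else "multi3"
}

# coarse label used for gating/sorting (permeabilized reads as empty-like
# but is still a cell-containing droplet in ground truth composition)
coarse_class <- function(cls) {
  switch(cls, empty = "empty", permeabilized = "single", single = "single",
         multi2 = "multi", multi3 = "multi")
}

#' Synthesize a differential impedance trace
#'
#' Each droplet contributes a bipolar template: a positive flat-top lobe
#' at the first electrode pair and its mirrored negative at the second
#' (difference of two flat-top pulses with Gaussian edges). Lobe width
#' scales with (droplet length + electrode span) / velocity, so droplet
#' size changes the transit time but not the amplitude. A cell-bearing
#' droplet carries a narrow sub-peak riding on the plateau whose offset
#' tracks the first cell's fractional position with noise
#' `position_jitter_sd`; the template maximum equals the drawn class
#' amplitude exactly (the plateau sits at 85\% and the sub-peak tops it
#' up), so the peak location inside the lobe encodes the cell position as
#' in position-sensitive droplet impedance signals. White Gaussian noise
#' is added on top.
#'
#' @param stream A `droplet_stream` from [sample_stream()].
#' @param config A [trace_config()].
#' @param seed Integer seed.
#' @return A `signal_trace` list with `times_s`, `current_uA`,
#'   `sample_rate_hz`, and `ledger` (droplet_id, t_start/t_end of the
#'   positive lobe, true class, true amplitude, first-cell position,
#'   sub-peak offset actually drawn).
#' @export
synthesize <- function(stream, config, seed = 1) {
  stopifnot(inherits(stream, "droplet_stream"), inherits(config, "trace_config"))
  if (is.unsorted(stream$arrival_time_s))
    stop("stream must be sorted by arrival time")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  fs <- config$sample_rate_hz
  v <- config$flow_velocity_um_s
  pitch_s <- config$electrode_pitch_um / v
  n <- nrow(stream)
  if (n == 0) { # no droplets: pure noise for a nominal window
    times <- seq(0, 0.1, by = 1 / fs)
    cur <- if (config$noise_sd_uA > 0)
      stats::rnorm(length(times), 0, config$noise_sd_uA) else numeric(length(times))
    return(structure(list(times_s = times, current_uA = cur,
                          sample_rate_hz = fs,
                          ledger = data.frame(), pitch_s = pitch_s),
                     class = "signal_trace"))
  }
  classes <- vapply(seq_len(n), function(i) {
    true_class(stream$cell_count[i], stream$viable_flags[[i]])
  }, "")
  mean_amp <- unname(config$amplitude_table[classes])
  amp <- mean_amp * (1 + config$amplitude_cv * stats::rnorm(n))
  amp <- pmax(amp, 0)
  # transit: droplet length + electrode span over velocity
  span_um <- 40
  transit_s <- (stream$diameter_um + span_um) / v
  if (any(transit_s * fs < 20))
    stop("sample rate too low: need >= 20 samples per transit")
  w <- transit_s / 2       # lobe half width
  wp <- 0.7 * w            # flat plateau half width
  se <- 0.15 * w           # Gaussian edge width
  wb <- 0.15 * w           # cell sub-peak width
  half_span <- wp + 4 * se # template half extent per lobe
  beta <- 0.15             # sub-peak share of the peak amplitude
  t_peak <- stream$arrival_time_s
  # cell sub-peak offset: true fractional position + jitter, in lobe units
  pos1 <- vapply(seq_len(n), function(i) {
    p <- stream$cell_positions[[i]]
    if (length(p) == 0) NA_real_ else p[1]
  }, 0)
  sub_off <- pmin(pmax(pos1 + config$position_jitter_sd *
                         stats::rnorm(n), 0), 1)
  t_end <- max(t_peak) + pitch_s + max(half_span)
  times <- seq(0, t_end, by = 1 / fs)
  cur <- numeric(length(times))
  if (!config$coincidence && n > 1) {
    gap <- diff(t_peak)
    if (any(gap < pitch_s + half_span[-n] + half_span[-1]))
      stop("droplet templates overlap; enable coincidence mode")
  }
  flattop <- function(t, center, wp_i, se_i) {
    u <- abs(t - center)
    ifelse(u <= wp_i, 1, exp(-0.5 * ((u - wp_i) / se_i)^2))
  }
  has_cell <- classes %in% c("single", "multi2", "multi3")
  for (i in seq_len(n)) {
    lo <- t_peak[i] - half_span[i]
    hi <- t_peak[i] + pitch_s + half_span[i]
    j <- max(1L, ceiling(lo * fs) + 1L):min(length(times),
                                            floor(hi * fs) + 1L)
    tt <- times[j]
    main <- flattop(tt, t_peak[i], wp[i], se[i]) -
      flattop(tt, t_peak[i] + pitch_s, wp[i], se[i])
    if (has_cell[i] && !is.na(sub_off[i])) {
      # plateau at (1-beta)A; narrow bump at the cell position tops the
      # template up to exactly A
      t_sub <- t_peak[i] + (sub_off[i] - 0.5) * 1.8 * wp[i]
      bump <- exp(-0.5 * ((tt - t_sub) / wb[i])^2) -
        exp(-0.5 * ((tt - t_sub - pitch_s) / wb[i])^2)
      sig_i <- amp[i] * ((1 - beta) * main + beta * bump)
    } else {
      sig_i <- amp[i] * main
    }
    cur[j] <- cur[j] + sig_i
  }
  if (config$noise_sd_uA > 0)
    cur <- cur + stats::rnorm(length(cur), 0, config$noise_sd_uA)
  ledger <- data.frame(droplet_id = stream$droplet_id,
                       t_peak_s = t_peak,
                       t_start_s = t_peak - half_span,
                       t_end_s = t_peak + half_span,
                       transit_s = transit_s,
                       class = classes,
                       amplitude_uA = amp,
                       cell_position = pos1,
                       subpeak_offset = ifelse(has_cell, sub_off,
                                               NA_real_))
  structure(list(times_s = times, current_uA = cur,
                 sample_rate_hz = fs, ledger = ledger,
                 pitch_s = pitch_s),
            class = "signal_trace")
}

#' Write / read a trace and its ledger as CSV
#'
#' @param trace A `signal_trace`.
#' @param path Trace CSV path; the ledger goes to `<path>.ledger.csv`.
#' @return `read_trace()` returns a `signal_trace`; the writer returns
#'   `path` invisibly.
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(data.frame(time_s = trace$times_s,
                              current_uA = trace$current_uA),
                   path, row.names = FALSE)
  utils::write.csv(trace$ledger, paste0(path, ".ledger.csv"),
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @param sample_rate_hz Sampling rate of the stored trace (inferred from
#'   the time column when omitted).
#' @export
read_trace <- function(path, sample_rate_hz = NULL) {
  df <- utils::read.csv(path)
  ledger_path <- paste0(path, ".ledger.csv")
  ledger <- if (file.exists(ledger_path)) utils::read.csv(ledger_path) else NULL
  if (is.null(sample_rate_hz))
    sample_rate_hz <- 1 / stats::median(diff(df$time_s))
  structure(list(times_s = df$time_s, current_uA = df$current_uA,
                 sample_rate_hz = sample_rate_hz, ledger = ledger),
            class = "signal_trace")
}
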