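#' Amplitude gate configuration
#'
#' Peak-amplitude intervals classifying droplets into empty / single /
#' multi. Amplitudes below `empty_threshold_uA` are empty; inside
#' `[lower_uA, upper_uA]` single; above `upper_uA` multi. Boundary values
#' go to the higher-count class. If `empty_threshold_uA < lower_uA`,
#' amplitudes in the gap are labelled `"ambiguous"` (routed to waste).
#'
#' @param lower_uA,upper_uA Single-cell gate interval (uA).
#' @param empty_threshold_uA Below this, empty (defaults to `lower_uA`).
#' @param target_classes Classes routed to the target outlet (default
#'   `"single"`).
#' @return A `gate_config` object.
#' @export
gate_config <- function(lower_uA, upper_uA,
                        empty_threshold_uA = lower_uA,
                        target_classes = "single") {
  stopifnot(empty_threshold_uA <= lower_uA, lower_uA <= upper_uA,
            all(target_classes %in% c("empty", "single", "multi")))
  structure(list(lower_uA = lower_uA, upper_uA = upper_uA,
                 empty_threshold_uA = empty_threshold_uA,
                 target_classes = target_classes),
            class = "gate_config")
}

#' Serialize gates to / from JSON
#' @param gates A [gate_config()].
#' @param path File path.
#' @return `read_gates()` returns a `gate_config`.
#' @export
write_gates <- function(gates, path) {
  jsonlite::write_json(unclass(gates), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_gates
#' @export
read_gates <- function(path) {
  g <- jsonlite::read_json(path, simplifyVector = TRUE)
  gate_config(g$lower_uA, g$upper_uA, g$empty_threshold_uA,
              g$target_classes)
}

#' Detect droplet events in a differential trace
#'
#' Threshold-crossing segmentation of the positive lobes: contiguous
#' samples above `detect_threshold_uA` form a candidate event whose
#' amplitude is the segment maximum ("find the peak"). A candidate is
#' kept only if a matching negative lobe (minimum below minus the
#' threshold) occurs within one electrode-pitch window after the peak —
#' this rejects glitches. The sub-peak offset is recovered from the
#' position of the strongest narrow excursion within the lobe.
#'
#' @param trace A `signal_trace`.
#' @param detect_threshold_uA Detection threshold (must exceed the noise
#'   floor; default 0.1).
#' @return data.frame of detected events: `event_id`, `peak_time_s`,
#'   `amplitude_uA`, `transit_time_s`, `subpeak_offset`.
#' @export
detect_events <- function(trace, detect_threshold_uA = 0.1) {
  stopifnot(inherits(trace, "signal_trace"), detect_threshold_uA > 0)
  x <- trace$current_uA
  t <- trace$times_s
  fs <- trace$sample_rate_hz
  above <- x > detect_threshold_uA
  if (!any(above)) return(empty_events())
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  seg <- data.frame(start = starts[r$values], end = ends[r$values])
  pitch_s <- if (!is.null(trace$pitch_s)) trace$pitch_s else 140 / 8e4
  win <- ceiling(2 * pitch_s * fs)
  # merge noise-fragmented crossings of one lobe: gaps well below the
  # electrode pitch belong to the same droplet
  if (nrow(seg) > 1) {
    merge_gap <- 0.5 * pitch_s * fs
    keep <- c(TRUE, seg$start[-1] - seg$end[-nrow(seg)] > merge_gap)
    grp <- cumsum(keep)
    seg <- data.frame(start = tapply(seg$start, grp, min),
                      end = tapply(seg$end, grp, max))
  }
  rows <- lapply(seq_len(nrow(seg)), function(i) {
    j <- seg$start[i]:seg$end[i]
    pk <- j[which.max(x[j])]
    amp <- x[pk]
    # require the mirrored negative lobe within the pairing window
    jw <- (seg$end[i] + 1):min(seg$end[i] + win, length(x))
    if (length(jw) < 2 || min(x[jw]) > -detect_threshold_uA) return(NULL)
    transit <- (seg$end[i] - seg$start[i] + 1) / fs
    # sub-peak: strongest residual after removing the smooth lobe
    sub <- subpeak_offset(x[j], amp)
    data.frame(peak_time_s = t[pk], amplitude_uA = amp,
               transit_time_s = transit, subpeak_offset = sub)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0) return(empty_events())
  out <- do.call(rbind, rows)
  out <- out[order(out$peak_time_s), , drop = FALSE]
  out$event_id <- seq_len(nrow(out))
  out[, c("event_id", "peak_time_s", "amplitude_uA", "transit_time_s",
          "subpeak_offset")]
}

empty_events <- function() {
  data.frame(event_id = integer(0), peak_time_s = numeric(0),
             amplitude_uA = numeric(0), transit_time_s = numeric(0),
             subpeak_offset = numeric(0))
}

# fractional position of the sub-peak within a positive lobe: the lobe
# maximum sits at the cell position, so smooth at about the sub-peak width
# (segment/11) to suppress sample noise and take the argmax
subpeak_offset <- function(seg, amp) {
  n <- length(seg)
  if (n < 12) return(NA_real_)
  k <- max(3L, 2L * (n %/% 22L) + 1L)
  sm <- as.numeric(stats::filter(seg, rep(1 / k, k), sides = 2))
  sm[is.na(sm)] <- -Inf
  prom <- max(sm) - stats::quantile(sm[is.finite(sm)], 0.75)
  if (prom < 0.05 * amp) return(NA_real_)
  (which.max(sm) - 1) / (n - 1)
}

#' Classify a detected event by its peak amplitude
#'
#' @param amplitude_uA Peak amplitude(s).
#' @param gates A [gate_config()].
#' @return Character vector of labels: `"empty"`, `"single"`, `"multi"`,
#'   or `"ambiguous"` for amplitudes between the empty threshold and the
#'   single gate. Boundary amplitudes go to the higher-count class.
#' @export
classify_events <- function(amplitude_uA, gates) {
  stopifnot(inherits(gates, "gate_config"))
  ifelse(amplitude_uA >= gates$upper_uA, "multi",
    ifelse(amplitude_uA >= gates$lower_uA, "single",
      ifelse(amplitude_uA < gates$empty_threshold_uA, "empty",
             "ambiguous")))
}

#' Calibrate gates from sampled amplitudes
#'
#' Deterministic histogram-valley calibration, mirroring the practice of
#' sampling the droplet mixture for a minute before sorting: a kernel
#' density estimate (Sheather-Jones bandwidth, fixed 512-point grid) of
#' the amplitude sample is scanned for local minima between substantial
#' modes; the two strongest valleys become the empty/single and
#' single/multi thresholds.
#'
#' @param amplitudes Sampled peak amplitudes (>= 200 values).
#' @param expected_classes 2 or 3 modes expected (default 3).
#' @param target_classes Passed to [gate_config()].
#' @param min_mode_mass Minimum probability mass for a density lobe to
#'   count as a mode; smaller lobes merge into their neighbours
#'   (default 0.02).
#' @return A [gate_config()]; the single gate upper bound is the
#'   single/multi valley and `Inf` marks an unbounded top class when only
#'   two modes exist and multi is not expected.
#' @export
calibrate_gates <- function(amplitudes, expected_classes = 3,
                            target_classes = "single",
                            min_mode_mass = 0.02) {
  stopifnot(length(amplitudes) >= 200, expected_classes %in% 2:3)
  if (stats::sd(amplitudes) < 1e-12)
    stop("cannot calibrate: amplitude sample is degenerate")
  den <- tryCatch(stats::density(amplitudes, bw = "SJ", n = 512),
                  error = function(e) stats::density(amplitudes, n = 512))
  y <- den$y; xg <- den$x
  interior <- 2:(length(y) - 1)
  valley <- interior[y[interior] < y[interior - 1] &
                       y[interior] <= y[interior + 1]]
  if (length(valley) == 0)
    stop("cannot calibrate: amplitude histogram is unimodal")
  # modes = segments between valleys; small-sample density lobes are
  # merged until every mode carries substantial mass and every remaining
  # valley dips well below its smaller flank
  bounds <- c(1L, valley, length(y))
  mode_mass <- function(b) {
    vapply(seq_len(length(b) - 1), function(i) {
      sum(y[b[i]:b[i + 1]])
    }, 0) / sum(y)
  }
  repeat {
    k <- length(bounds) - 1
    if (k < 2) stop("cannot calibrate: amplitude histogram is unimodal")
    mass <- mode_mass(bounds)
    flank <- vapply(2:k, function(i) { # smaller flanking peak per valley
      min(max(y[bounds[i - 1]:bounds[i]]), max(y[bounds[i]:bounds[i + 1]]))
    }, 0)
    dip_ok <- y[bounds[2:k]] < 0.5 * flank
    if (any(mass < min_mode_mass)) {
      i <- which.min(mass) # merge across the shallower adjacent valley
      drop_idx <- if (i == 1) 2L
        else if (i == k) i
        else if (y[bounds[i]] > y[bounds[i + 1]]) i else i + 1L
      bounds <- bounds[-drop_idx]
    } else if (any(!dip_ok)) {
      i <- which.min(flank - y[bounds[2:k]])
      bounds <- bounds[-(i + 1L)]
    } else break
  }
  k <- length(bounds) - 1
  vals <- bounds[2:k]
  score <- vapply(seq_along(vals), function(i) {
    min(max(y[bounds[i]:bounds[i + 1]]),
        max(y[bounds[i + 1]:bounds[i + 2]])) - y[vals[i]]
  }, 0)
  n_cuts <- min(expected_classes - 1, length(vals))
  keep <- sort(vals[order(score, decreasing = TRUE)[seq_len(n_cuts)]])
  cuts <- xg[keep]
  if (length(cuts) == 1) {
    gate_config(cuts, Inf, cuts, target_classes)
  } else {
    gate_config(cuts[1], cuts[2], cuts[1], target_classes)
  }
}

#' Trigger timing model
#'
#' @param activation_delay_s Delay between peak detection and pulse start
#'   (default 1 ms).
#' @param pulse_width_s Actuation pulse width (default 5 ms).
#' @param dead_time_s Additional lockout after a pulse (default 0).
#' @param max_rate_hz Sustained trigger rate cap (default 200).
#' @return A `trigger_model` object.
#' @export
trigger_model <- function(activation_delay_s = 1e-3, pulse_width_s = 5e-3,
                          dead_time_s = 0, max_rate_hz = 200) {
  stopifnot(activation_delay_s >= 0, pulse_width_s >= 0, dead_time_s >= 0,
            max_rate_hz > 0)
  structure(list(activation_delay_s = activation_delay_s,
                 pulse_width_s = pulse_width_s,
                 dead_time_s = dead_time_s,
                 max_rate_hz = max_rate_hz),
            class = "trigger_model")
}

#' Schedule actuation pulses for target events
#'
#' A target-class event fires a pulse at `peak_time + activation_delay`
#' unless the actuator is still busy (within pulse width + dead time of
#' the previous pulse) or firing would exceed the rate cap (minimum pulse
#' spacing `1/max_rate_hz`). Skipped target events are logged as missed.
#'
#' @param events data.frame with `peak_time_s` and a `label` column
#'   (time-ordered).
#' @param trigger A [trigger_model()].
#' @param target_classes Labels that should fire (default `"single"`).
#' @return `events` with logical columns `is_target`, `triggered` and
#'   numeric `pulse_time_s` (NA when not fired).
#' @export
schedule_triggers <- function(events, trigger = trigger_model(),
                              target_classes = "single") {
  stopifnot(inherits(trigger, "trigger_model"),
            !is.unsorted(events$peak_time_s))
  n <- nrow(events)
  is_target <- events$label %in% target_classes
  triggered <- logical(n)
  pulse_time <- rep(NA_real_, n)
  lockout <- trigger$pulse_width_s + trigger$dead_time_s
  min_gap <- max(lockout, 1 / trigger$max_rate_hz)
  last <- -Inf
  for (i in seq_len(n)) {
    if (!is_target[i]) next
    tp <- events$peak_time_s[i] + trigger$activation_delay_s
    if (tp - last >= min_gap - 1e-12) {
      triggered[i] <- TRUE
      pulse_time[i] <- tp
      last <- tp
    }
  }
  events$is_target <- is_target
  events$triggered <- triggered
  events$pulse_time_s <- pulse_time
  events
}

#' Screen a trace end to end
#'
#' Convenience wrapper: detect, classify and (optionally) match events to
#' a ground-truth ledger by peak time for accuracy accounting.
#'
#' @param trace A `signal_trace`.
#' @param gates A [gate_config()].
#' @param detect_threshold_uA Passed to [detect_events()].
#' @return The detected events with a `label` column; when the trace has
#'   a ledger, also `droplet_id`, `true_class` and `true_amplitude_uA`
#'   for events matched within half a transit time.
#' @export
screen_trace <- function(trace, gates, detect_threshold_uA = 0.1) {
  ev <- detect_events(trace, detect_threshold_uA)
  ev$label <- classify_events(ev$amplitude_uA, gates)
  if (!is.null(trace$ledger) && nrow(ev) > 0) {
    led <- trace$ledger
    idx <- vapply(ev$peak_time_s, function(tp) {
      d <- abs(led$t_peak_s - tp)
      i <- which.min(d)
      if (d[i] <= led$transit_s[i]) i else NA_integer_
    }, 1L)
    ev$droplet_id <- led$droplet_id[idx]
    ev$true_class <- led$class[idx]
    ev$true_amplitude_uA <- led$amplitude_uA[idx]
  }
  ev
}
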