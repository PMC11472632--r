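#' Light application schedule
#'
#' A schedule of illumination events for one recording.  Events are the
#' switching times of the LED/xenon light path: UV-class light (~365 nm)
#' drives the azobenzene photoswitch into the active *cis* configuration,
#' blue-class light (~445 nm) back into the inactive *trans* configuration.
#'
#' @param time_s Numeric vector, event onsets in seconds from trace start.
#' @param wavelength_nm Numeric vector, nominal wavelength of each event
#'   (values below 400 nm are classed as UV, values at or above 400 nm as
#'   blue).
#' @param intensity_pct Percent of full lamp power, in `(0, 100]`.
#'
#' @return A `data.frame` of class `"light_schedule"` with columns
#'   `time_s`, `wavelength_nm`, `intensity_pct`.
#' @export
#' @examples
#' light_schedule(c(0, 2, 32), c(445, 365, 445))
light_schedule <- function(time_s, wavelength_nm, intensity_pct = 100) {
  stopifnot(length(time_s) == length(wavelength_nm))
  intensity_pct <- rep_len(intensity_pct, length(time_s))
  if (any(time_s < 0)) stop("light event times must be >= 0", call. = FALSE)
  if (is.unsorted(time_s, strictly = TRUE))
    stop("light events must be strictly ascending in time", call. = FALSE)
  if (any(intensity_pct <= 0 | intensity_pct > 100))
    stop("intensity_pct must lie in (0, 100]", call. = FALSE)
  cls <- wavelength_class(wavelength_nm)
  if (length(cls) > 1 && any(cls[-1] == cls[-length(cls)]))
    stop("consecutive light events must alternate wavelength class (uv/blue)",
         call. = FALSE)
  structure(
    data.frame(time_s = as.numeric(time_s),
               wavelength_nm = as.numeric(wavelength_nm),
               intensity_pct = as.numeric(intensity_pct)),
    class = c("light_schedule", "data.frame")
  )
}

#' @keywords internal
wavelength_class <- function(wavelength_nm) {
  ifelse(wavelength_nm < 400, "uv", "blue")
}

#' Onset of the first UV / blue-after-UV event
#'
#' Helpers to read switching times off a [light_schedule()].
#' `uv_onset()` returns the first UV-class event time; `uv_offset()` the
#' first blue-class event after that (or `NA` if UV stays on).
#'
#' @param schedule A [light_schedule()].
#' @return Time in seconds, or `NA_real_`.
#' @export
uv_onset <- function(schedule) {
  cls <- wavelength_class(schedule$wavelength_nm)
  i <- which(cls == "uv")
  if (!length(i)) NA_real_ else schedule$time_s[i[1]]
}

#' @rdname uv_onset
#' @export
uv_offset <- function(schedule) {
  cls <- wavelength_class(schedule$wavelength_nm)
  i <- which(cls == "uv")
  if (!length(i)) return(NA_real_)
  j <- which(cls == "blue" & seq_along(cls) > i[1])
  if (!length(j)) NA_real_ else schedule$time_s[j[1]]
}

#' Voltage-ramp stimulation protocol
#'
#' Describes one repetition of a ramp sweep: a pre-ramp holding segment, a
#' linear voltage ramp, and a post-ramp holding segment, applied repetitively
#' at `repetition_Hz`.  Two standard dialects are provided:
#' [ramp_protocol_2hz()] (50 ms hold, 400 ms ramp, 50 ms hold at 2 Hz) and
#' [ramp_protocol_50hz()] (7 ms hold, 10 ms ramp, 3 ms hold at 50 Hz,
#' acquired at 5 kHz after 2.5 kHz filtering).
#'
#' @param pre_hold_mV,pre_hold_ms Holding potential and duration before the ramp.
#' @param ramp_start_mV,ramp_end_mV,ramp_ms Ramp start/end voltage and duration.
#' @param post_hold_mV,post_hold_ms Holding potential and duration after the ramp.
#' @param repetition_Hz Sweep repetition frequency.
#' @param acquisition_Hz Sampling frequency of the digitizer.
#' @param filter_Hz Nominal anti-alias low-pass cutoff; must satisfy
#'   `acquisition_Hz >= 2 * filter_Hz` (the standard acquisition chain
#'   samples at exactly twice the filter cutoff, e.g. 5 kHz after 2.5 kHz
#'   filtering).
#'
#' @return A list of class `"ramp_protocol"`.
#' @export
ramp_protocol <- function(pre_hold_mV = -100, pre_hold_ms = 50,
                          ramp_start_mV = -100, ramp_end_mV = 100,
                          ramp_ms = 400,
                          post_hold_mV = 100, post_hold_ms = 50,
                          repetition_Hz = 2,
                          acquisition_Hz = 5000, filter_Hz = 2500) {
  durs <- c(pre_hold_ms, ramp_ms, post_hold_ms)
  if (any(durs <= 0)) stop("all protocol durations must be > 0", call. = FALSE)
  period_ms <- 1000 / repetition_Hz
  if (period_ms < sum(durs))
    stop("repetition period must be >= pre_hold + ramp + post_hold duration",
         call. = FALSE)
  if (acquisition_Hz < 2 * filter_Hz)
    stop("acquisition_Hz must be at least twice filter_Hz (Nyquist)",
         call. = FALSE)
  structure(list(pre_hold_mV = pre_hold_mV, pre_hold_ms = pre_hold_ms,
                 ramp_start_mV = ramp_start_mV, ramp_end_mV = ramp_end_mV,
                 ramp_ms = ramp_ms,
                 post_hold_mV = post_hold_mV, post_hold_ms = post_hold_ms,
                 repetition_Hz = repetition_Hz,
                 acquisition_Hz = acquisition_Hz, filter_Hz = filter_Hz),
            class = "ramp_protocol")
}

#' @rdname ramp_protocol
#' @export
ramp_protocol_2hz <- function() {
  ramp_protocol(pre_hold_ms = 50, ramp_ms = 400, post_hold_ms = 50,
                repetition_Hz = 2, acquisition_Hz = 5000, filter_Hz = 2500)
}

#' @rdname ramp_protocol
#' @export
ramp_protocol_50hz <- function() {
  ramp_protocol(pre_hold_ms = 7, ramp_ms = 10, post_hold_ms = 3,
                repetition_Hz = 50, acquisition_Hz = 5000, filter_Hz = 2500)
}

#' Duration of one sweep (active segments) in seconds
#' @param protocol A [ramp_protocol()].
#' @export
sweep_duration <- function(protocol) {
  (protocol$pre_hold_ms + protocol$ramp_ms + protocol$post_hold_ms) / 1000
}

#' Current trace
#'
#' A uniformly sampled membrane-current time series in pA, either recorded at
#' a constant holding potential (kinetics traces, conventionally 2 kHz at
#' -60 mV) or as one sweep of a ramp protocol.
#'
#' @param current_pA Numeric vector of current samples (pA, inward negative).
#' @param sampling_Hz Sampling frequency (> 0).
#' @param mode `"holding"` or `"ramp"`.
#' @param holding_mV Holding potential, required for `mode = "holding"`.
#' @param protocol A [ramp_protocol()], required for `mode = "ramp"`.
#' @param sweep Sweep index within a session (ramp mode).
#' @param t0 Start time of the trace in seconds (session clock).
#' @param units `"pA"` for raw current or `"pA/pF"` after density conversion.
#'
#' @return A list of class `"trace"`.
#' @export
new_trace <- function(current_pA, sampling_Hz,
                      mode = c("holding", "ramp"),
                      holding_mV = NULL, protocol = NULL,
                      sweep = NA_integer_, t0 = 0, units = "pA") {
  mode <- match.arg(mode)
  if (!is.numeric(sampling_Hz) || sampling_Hz <= 0)
    stop("sampling_Hz must be > 0", call. = FALSE)
  if (!all(is.finite(current_pA)))
    stop("trace samples must be finite", call. = FALSE)
  if (mode == "holding" && is.null(holding_mV))
    stop("holding_mV required for a holding trace", call. = FALSE)
  if (mode == "ramp" && !inherits(protocol, "ramp_protocol"))
    stop("a ramp trace needs a ramp_protocol", call. = FALSE)
  structure(list(current_pA = as.numeric(current_pA),
                 sampling_Hz = sampling_Hz, mode = mode,
                 holding_mV = holding_mV, protocol = protocol,
                 sweep = sweep, t0 = t0, units = units),
            class = "trace")
}

#' Sample times of a trace in seconds (session clock)
#' @param trace A [new_trace()].
#' @export
trace_times <- function(trace) {
  trace$t0 + (seq_along(trace$current_pA) - 1) / trace$sampling_Hz
}

#' Whole-cell recording of one cell
#'
#' Bundles one cell's metadata (membrane capacitance, compound, light
#' source), its traces and the light schedule.  The liquid junction
#' potential is carried as metadata only; recordings are assumed to be
#' junction-corrected at acquisition time, so no correction is applied.
#'
#' @param cell_id Character identifier.
#' @param capacitance_pF Membrane capacitance in pF (> 0).
#' @param compound Compound label, e.g. `"OptoDArG"`, `"OptoBI-1"`, `"PhoDAG"`,
#'   `"OAG"`, `"GSK"`.
#' @param light_source `"LED"` or `"xenon"`.
#' @param traces Named list of [new_trace()] objects.
#' @param schedule A [light_schedule()].
#' @param junction_potential_mV Liquid junction potential (default +4.0 mV).
#'
#' @return A list of class `"recording"`.
#' @export
recording <- function(cell_id, capacitance_pF, compound = "unknown",
                      light_source = "LED", traces = list(),
                      schedule = light_schedule(numeric(), numeric()),
                      junction_potential_mV = 4.0) {
  if (!is.numeric(capacitance_pF) || capacitance_pF <= 0)
    stop("capacitance_pF must be > 0", call. = FALSE)
  if (!inherits(schedule, "light_schedule"))
    stop("schedule must be a light_schedule", call. = FALSE)
  if (length(traces) && is.null(names(traces)))
    names(traces) <- paste0("trace", seq_along(traces))
  for (tr in traces)
    if (!inherits(tr, "trace")) stop("traces must be trace objects", call. = FALSE)
  # light events must fall within the overall recorded span (union of traces)
  if (nrow(schedule) && length(traces)) {
    spans <- vapply(traces, function(tr) range(trace_times(tr)),
                    numeric(2))
    lo <- min(spans[1, ]); hi <- max(spans[2, ])
    if (any(schedule$time_s < lo - 1e-9 | schedule$time_s > hi + 1e-9))
      stop("light events must fall within the recorded time span", call. = FALSE)
  }
  structure(list(cell_id = as.character(cell_id),
                 capacitance_pF = capacitance_pF,
                 compound = compound, light_source = light_source,
                 traces = traces, schedule = schedule,
                 junction_potential_mV = junction_potential_mV),
            class = "recording")
}

#' Convert a current trace to current density
#'
#' Divides every sample by the membrane capacitance, yielding pA/pF, the
#' size-normalised convention used for all cohort summaries.
#'
#' @param trace A [new_trace()] in pA.
#' @param capacitance_pF Membrane capacitance in pF (> 0).
#' @return The trace with samples in pA/pF (`units` updated, all other
#'   metadata preserved).
#' @export
to_current_density <- function(trace, capacitance_pF) {
  if (!is.numeric(capacitance_pF) || length(capacitance_pF) != 1 ||
      !is.finite(capacitance_pF) || capacitance_pF <= 0)
    stop("capacitance_pF must be a single positive number", call. = FALSE)
  trace$current_pA <- trace$current_pA / capacitance_pF
  trace$units <- "pA/pF"
  trace
}

#' Command voltage of a ramp protocol at a time within the sweep
#'
#' Piecewise-linear voltage command: the pre-ramp hold, a linear ramp over
#' the half-open interval `[pre_hold, pre_hold + ramp)`, then the post-ramp
#' hold.  Vectorised over `time_in_sweep_s`.
#'
#' @param protocol A [ramp_protocol()].
#' @param time_in_sweep_s Seconds from sweep start; must satisfy
#'   `0 <= t < sweep_duration(protocol)`.
#' @return Command voltage in mV.
#' @export
#' @examples
#' ramp_voltage_at(ramp_protocol_2hz(), 0.250)  # ramp midpoint -> 0 mV
ramp_voltage_at <- function(protocol, time_in_sweep_s) {
  t <- time_in_sweep_s
  dur <- sweep_duration(protocol)
  if (any(t < 0 | t >= dur))
    stop("time_in_sweep_s outside [0, sweep duration)", call. = FALSE)
  pre <- protocol$pre_hold_ms / 1000
  ramp <- protocol$ramp_ms / 1000
  v <- numeric(length(t))
  in_pre <- t < pre
  in_ramp <- t >= pre & t < pre + ramp
  in_post <- t >= pre + ramp
  v[in_pre] <- protocol$pre_hold_mV
  frac <- (t[in_ramp] - pre) / ramp
  v[in_ramp] <- protocol$ramp_start_mV +
    frac * (protocol$ramp_end_mV - protocol$ramp_start_mV)
  v[in_post] <- protocol$post_hold_mV
  v
}

#' Current-density-voltage relation
#'
#' @param voltage_mV Strictly ascending voltage grid.
#' @param density_pA_pF Current density at each grid voltage.
#' @param sweep Source sweep id.
#' @param selection Selection label, e.g. `"trans"` or `"max cis"`.
#' @return A list of class `"iv_curve"`.
#' @export
iv_curve <- function(voltage_mV, density_pA_pF, sweep = NA_integer_,
                     selection = NA_character_) {
  if (length(voltage_mV) != length(density_pA_pF))
    stop("voltage and density must have the same length", call. = FALSE)
  if (is.unsorted(voltage_mV, strictly = TRUE))
    stop("voltage grid must be strictly ascending", call. = FALSE)
  structure(list(voltage_mV = as.numeric(voltage_mV),
                 density_pA_pF = as.numeric(density_pA_pF),
                 sweep = sweep, selection = selection),
            class = "iv_curve")
}

#' Extract the I-V relation from one ramp sweep
#'
#' Maps each ramp-segment sample to its command voltage, converts to current
#' density, and bins onto a regular voltage grid.  Bins are `bin_mV` wide,
#' left-closed (`[v, v + bin_mV)`) starting at the ramp start voltage; the
#' reported grid voltage is the bin centre and the bin value is the mean of
#' the samples falling in the bin.
#'
#' @param sweep A ramp-mode [new_trace()] spanning one protocol repetition.
#' @param protocol A [ramp_protocol()]; defaults to the trace's own.
#' @param capacitance_pF Membrane capacitance in pF.
#' @param bin_mV Bin width in mV (default 1).
#' @param selection Optional selection label stored on the curve.
#' @return An [iv_curve()].
#' @export
extract_iv <- function(sweep, protocol = sweep$protocol, capacitance_pF,
                       bin_mV = 1, selection = NA_character_) {
  if (!inherits(protocol, "ramp_protocol"))
    stop("extract_iv needs a ramp protocol", call. = FALSE)
  t <- (seq_along(sweep$current_pA) - 1) / sweep$sampling_Hz
  dur <- sweep_duration(protocol)
  if (max(t) < dur - 1 / sweep$sampling_Hz - 1e-12)
    stop("sweep must span one full protocol repetition", call. = FALSE)
  pre <- protocol$pre_hold_ms / 1000
  ramp <- protocol$ramp_ms / 1000
  sel <- t >= pre & t < pre + ramp
  v <- ramp_voltage_at(protocol, t[sel])
  dens <- sweep$current_pA[sel] / capacitance_pF
  v0 <- min(protocol$ramp_start_mV, protocol$ramp_end_mV)
  v1 <- max(protocol$ramp_start_mV, protocol$ramp_end_mV)
  edges <- seq(v0, v1, by = bin_mV)
  # snap voltages sitting within floating-point error of a bin edge up to
  # the edge, so command values computed from sample times bin predictably
  idx <- pmin(floor((v - v0) / bin_mV + 1e-9) + 1, length(edges) - 1)
  n_per <- tabulate(idx, nbins = length(edges) - 1)
  if (any(n_per == 0))
    stop("empty voltage bins at this sampling; use a coarser bin_mV",
         call. = FALSE)
  means <- as.numeric(tapply(dens, factor(idx, levels = seq_len(length(edges) - 1)),
                             mean))
  centres <- edges[-length(edges)] + bin_mV / 2
  iv_curve(centres, means, sweep = sweep$sweep, selection = selection)
}

#' Plateau current densities at the holding potentials of a ramp sweep
#'
#' Median current density over the pre-ramp hold (ramp start voltage, here
#' -100 mV) and the post-ramp hold (+100 mV), excluding the first
#' `settle_frac` of each hold segment to avoid capacitive transients.
#'
#' @inheritParams extract_iv
#' @param settle_frac Fraction of each hold segment discarded at its start
#'   (default 0.2).
#' @return Named numeric vector `c(cd_neg = ..., cd_pos = ...)` in pA/pF.
#' @export
extract_plateau_cd <- function(sweep, protocol = sweep$protocol,
                               capacitance_pF, settle_frac = 0.2) {
  if (settle_frac < 0 || settle_frac >= 1)
    stop("settle_frac must lie in [0, 1)", call. = FALSE)
  t <- (seq_along(sweep$current_pA) - 1) / sweep$sampling_Hz
  pre <- protocol$pre_hold_ms / 1000
  ramp <- protocol$ramp_ms / 1000
  post <- protocol$post_hold_ms / 1000
  dens <- sweep$current_pA / capacitance_pF
  pre_win <- t >= settle_frac * pre & t < pre
  post_start <- pre + ramp
  post_win <- t >= post_start + settle_frac * post & t < post_start + post
  if (!any(pre_win) || !any(post_win))
    stop("hold segment shorter than the settle margin", call. = FALSE)
  c(cd_neg = stats::median(dens[pre_win]),
    cd_pos = stats::median(dens[post_win]))
}

# ---- on-disk containers ----------------------------------------------------

trace_to_list <- function(tr) {
  out <- list(sampling_Hz = tr$sampling_Hz, mode = tr$mode,
              t0 = tr$t0, units = tr$units,
              current_pA = tr$current_pA)
  if (!is.na(tr$sweep)) out$sweep <- as.integer(tr$sweep)
  if (tr$mode == "holding") out$holding_mV <- tr$holding_mV
  if (tr$mode == "ramp") out$protocol <- unclass(tr$protocol)
  out
}

trace_from_list <- function(x) {
  proto <- if (!is.null(x$protocol))
    do.call(ramp_protocol, lapply(x$protocol, as.numeric)) else NULL
  new_trace(as.numeric(x$current_pA), as.numeric(x$sampling_Hz), x$mode,
            holding_mV = if (is.null(x$holding_mV)) NULL
                         else as.numeric(x$holding_mV),
            protocol = proto,
            sweep = if (is.null(x$sweep) || is.na(x$sweep)) NA_integer_
                    else as.integer(x$sweep),
            t0 = as.numeric(x$t0), units = x$units)
}

recording_to_list <- function(rec) {
  list(
    meta = list(cell_id = rec$cell_id,
                capacitance_pF = rec$capacitance_pF,
                compound = rec$compound,
                light_source = rec$light_source,
                junction_potential_mV = rec$junction_potential_mV),
    schedule = list(time_s = rec$schedule$time_s,
                    wavelength_nm = rec$schedule$wavelength_nm,
                    intensity_pct = rec$schedule$intensity_pct),
    traces = lapply(rec$traces, trace_to_list)
  )
}

recording_from_list <- function(x, where = "container") {
  for (f in c("meta", "schedule", "traces"))
    if (is.null(x[[f]])) stop(sprintf("%s: missing section '%s'", where, f),
                              call. = FALSE)
  for (f in c("cell_id", "capacitance_pF", "compound", "light_source"))
    if (is.null(x$meta[[f]]))
      stop(sprintf("%s: missing mandatory meta field '%s'", where, f),
           call. = FALSE)
  sched <- tryCatch(
    light_schedule(as.numeric(x$schedule$time_s),
                   as.numeric(x$schedule$wavelength_nm),
                   as.numeric(x$schedule$intensity_pct)),
    error = function(e) stop(sprintf("%s: schedule: %s", where,
                                     conditionMessage(e)), call. = FALSE))
  jp <- x$meta$junction_potential_mV
  recording(cell_id = x$meta$cell_id,
            capacitance_pF = as.numeric(x$meta$capacitance_pF),
            compound = x$meta$compound, light_source = x$meta$light_source,
            traces = lapply(x$traces, trace_from_list),
            schedule = sched,
            junction_potential_mV = if (is.null(jp)) 4.0 else as.numeric(jp))
}

#' Write / read a recording container
#'
#' Two dialects of the same hierarchical schema (`meta`, `schedule`,
#' `traces/<name>`):
#'
#' * `format = "json"` - a single self-contained JSON document holding
#'   metadata, schedule and all sample arrays at 17 significant digits
#'   (the archival container; round trip is bit-exact for doubles).
#' * `format = "csv"` - a directory with a `meta.json` sidecar (metadata +
#'   schedule + per-trace attributes) and one `traces/<name>.csv` file per
#'   trace with columns `time_s,current_pA` (the interchange container;
#'   round trip is exact within decimal formatting).
#'
#' `read_recording()` auto-detects the dialect from the path (file vs.
#' directory).  Both dialects produce identical downstream analysis results.
#'
#' @param rec A [recording()].
#' @param path File path (json) or directory path (csv).
#' @param format `"json"` or `"csv"`.
#' @return `read_recording()` returns a [recording()];
#'   `write_recording()` returns `path` invisibly.
#' @export
write_recording <- function(rec, path, format = c("json", "csv")) {
  format <- match.arg(format)
  stopifnot(inherits(rec, "recording"))
  x <- recording_to_list(rec)
  if (format == "json") {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = I(17),
                         pretty = FALSE)
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    dir.create(file.path(path, "traces"), showWarnings = FALSE)
    side <- x
    side$traces <- lapply(x$traces, function(tr) tr[names(tr) != "current_pA"])
    jsonlite::write_json(side, file.path(path, "meta.json"),
                         auto_unbox = TRUE, digits = I(17), pretty = TRUE)
    for (nm in names(rec$traces)) {
      tr <- rec$traces[[nm]]
      df <- data.frame(time_s = trace_times(tr), current_pA = tr$current_pA)
      utils::write.csv(format(df, digits = 17, scientific = FALSE,
                              trim = TRUE),
                       file.path(path, "traces", paste0(nm, ".csv")),
                       row.names = FALSE, quote = FALSE)
    }
  }
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  if (dir.exists(path)) {
    side_path <- file.path(path, "meta.json")
    if (!file.exists(side_path))
      stop("csv container: missing meta.json sidecar", call. = FALSE)
    x <- jsonlite::read_json(side_path, simplifyVector = TRUE)
    x$traces <- lapply(x$traces, as.list)
    for (nm in names(x$traces)) {
      f <- file.path(path, "traces", paste0(nm, ".csv"))
      if (!file.exists(f))
        stop(sprintf("csv container: missing trace file '%s'", nm),
             call. = FALSE)
      df <- utils::read.csv(f)
      x$traces[[nm]]$current_pA <- df$current_pA
    }
    recording_from_list(x, where = path)
  } else {
    if (!file.exists(path)) stop("no such recording container: ", path,
                                 call. = FALSE)
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    x$traces <- lapply(x$traces, as.list)
    recording_from_list(x, where = path)
  }
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> cell %s | %s / %s | C = %.2f pF | %d trace(s), %d light event(s)\n",
              x$cell_id, x$compound, x$light_source, x$capacitance_pF,
              length(x$traces), nrow(x$schedule)))
  invisible(x)
}

#' @export
print.trace <- function(x, ...) {
  cat(sprintf("<trace> %s | %d samples @ %g Hz | %s\n", x$mode,
              length(x$current_pA), x$sampling_Hz, x$units))
  invisible(x)
}
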