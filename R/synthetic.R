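#' Gating parameters of a simulated photoswitch-driven current
#'
#' Ground-truth kinetic parameters for the synthetic recording generator.
#' All half-life time constants are in seconds and use the base-2 convention:
#' a decaying component halves every `tau` seconds, the accelerating
#' activation doubles its distance from baseline every `tau_act_s` seconds.
#'
#' @param tau_act_s Activation half-life (s).
#' @param tau_deact_s Deactivation half-life (s).
#' @param tau_inact_fast_s,tau_inact_slow_s Fast and slow inactivation
#'   half-lives (s); fast must be smaller than slow.
#' @param frac_fast Amplitude share of the fast inactivation component,
#'   in `[0, 1]`.
#' @param residual_c Non-inactivating plateau fraction, in `[0, 1]`
#'   (1 disables inactivation entirely).
#' @param peak_cd_pApF Magnitude of the maximal light-induced current
#'   density at the reference potential (pA/pF).
#' @param baseline_cd_pApF Light-independent background current density
#'   (pA/pF, signed).
#'
#' @return A list of class `"gating_params"`.
#' @export
gating_params <- function(tau_act_s = 0.0058, tau_deact_s = 0.0084,
                          tau_inact_fast_s = 0.3, tau_inact_slow_s = 13.1,
                          frac_fast = 0.5, residual_c = 0,
                          peak_cd_pApF = 60, baseline_cd_pApF = -1) {
  taus <- c(tau_act_s, tau_deact_s, tau_inact_fast_s, tau_inact_slow_s)
  if (any(!is.finite(taus)) || any(taus <= 0))
    stop("all half-life constants must be > 0", call. = FALSE)
  if (tau_inact_fast_s >= tau_inact_slow_s)
    stop("tau_inact_fast_s must be < tau_inact_slow_s", call. = FALSE)
  if (frac_fast < 0 || frac_fast > 1)
    stop("frac_fast must lie in [0, 1]", call. = FALSE)
  if (residual_c < 0 || residual_c > 1)
    stop("residual_c must lie in [0, 1]", call. = FALSE)
  structure(list(tau_act_s = tau_act_s, tau_deact_s = tau_deact_s,
                 tau_inact_fast_s = tau_inact_fast_s,
                 tau_inact_slow_s = tau_inact_slow_s,
                 frac_fast = frac_fast, residual_c = residual_c,
                 peak_cd_pApF = peak_cd_pApF,
                 baseline_cd_pApF = baseline_cd_pApF),
            class = "gating_params")
}

#' Relative current-density-voltage template
#'
#' Shape of the I-V relation as control points `(mV, relative density)`,
#' anchored at the reversal potential (`density(0) = 0`) and interpolated
#' with a monotone cubic per branch, so the interpolant never changes sign
#' within a branch.  `iv_template_symmetric()` emulates a near-symmetric
#' (ohmic-like) relation; `iv_template_rectifying()` an outwardly rectifying
#' one with outward:inward magnitude `ratio`.
#'
#' @param points_mV Control-point voltages; must include -100, 0 and +100.
#' @param rel_density Relative density at each control point; 0 at 0 mV and
#'   `sign(rel_density) == sign(V)` elsewhere.
#' @return A list of class `"iv_template"`.
#' @export
iv_template <- function(points_mV, rel_density) {
  if (length(points_mV) != length(rel_density))
    stop("points_mV and rel_density must match in length", call. = FALSE)
  o <- order(points_mV)
  points_mV <- points_mV[o]; rel_density <- rel_density[o]
  if (!all(c(-100, 0, 100) %in% points_mV))
    stop("template must anchor -100, 0 and +100 mV", call. = FALSE)
  if (abs(rel_density[points_mV == 0]) > 1e-12)
    stop("template density at 0 mV (reversal) must be 0", call. = FALSE)
  bad <- points_mV != 0 & sign(rel_density) != sign(points_mV)
  if (any(bad))
    stop("template density must carry the sign of its voltage", call. = FALSE)
  structure(list(points_mV = points_mV, rel_density = rel_density,
                 fun = stats::splinefun(points_mV, rel_density,
                                        method = "monoH.FC")),
            class = "iv_template")
}

#' @rdname iv_template
#' @export
iv_template_symmetric <- function() {
  iv_template(c(-100, -50, 0, 50, 100), c(-1, -0.5, 0, 0.5, 1))
}

#' @rdname iv_template
#' @param ratio Outward:inward magnitude ratio at +/-100 mV (default 3).
#' @export
iv_template_rectifying <- function(ratio = 3) {
  iv_template(c(-100, -50, 0, 25, 50, 100),
              c(-1, -0.55, 0, 0.2 * ratio, 0.45 * ratio, ratio))
}

#' Evaluate an I-V template
#' @param template An [iv_template()].
#' @param voltage_mV Voltages (mV).
#' @return Relative density at the requested voltages.
#' @export
eval_iv_template <- function(template, voltage_mV) {
  template$fun(voltage_mV)
}

#' Cohort specification for the synthetic generator
#'
#' Cell-to-cell variability is modelled as log-normal spread around each
#' kinetic median: a parameter with median `m` and geometric SD `g` is drawn
#' as `exp(rnorm(1, log(m), log(g)))`; `g = 1` means no spread.
#'
#' @param n_cells Number of cells (>= 1).
#' @param medians Named list of [gating_params()] medians (any subset; the
#'   rest take the `gating_params()` defaults).
#' @param gsd Named list of geometric SDs matching `medians` (default 1).
#' @param capacitance_pF Median membrane capacitance (pF).
#' @param capacitance_gsd Geometric SD of capacitance.
#' @param noise_sd_pA Gaussian current noise SD (pA).
#' @param seed Master seed (mandatory).
#' @return A list of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_cells, medians = list(), gsd = list(),
                        capacitance_pF = 15, capacitance_gsd = 1.2,
                        noise_sd_pA = 2, seed) {
  if (missing(seed)) stop("cohort_spec requires an explicit seed", call. = FALSE)
  if (n_cells < 1) stop("n_cells must be >= 1", call. = FALSE)
  base <- unclass(gating_params())
  for (nm in names(medians)) {
    if (!nm %in% names(base)) stop("unknown gating parameter: ", nm, call. = FALSE)
    base[[nm]] <- medians[[nm]]
  }
  num <- vapply(base, is.numeric, logical(1))
  if (any(unlist(base[num])[grep("tau|peak", names(base[num]))] < 0))
    stop("medians must be positive", call. = FALSE)
  structure(list(n_cells = as.integer(n_cells), medians = base, gsd = gsd,
                 capacitance_pF = capacitance_pF,
                 capacitance_gsd = capacitance_gsd,
                 noise_sd_pA = noise_sd_pA, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Derive a reproducible child seed from a master seed
#'
#' Small arithmetic hash keeping results in `[1, 2^31 - 2]`, so the same
#' master seed always yields the same per-cell / per-stage seeds.
#'
#' @param master Master seed (integer-valued).
#' @param k Child index (integer-valued).
#' @return A single integer seed.
#' @export
derive_seed <- function(master, k) {
  m <- 2147483647
  x <- (as.numeric(master) %% m)
  x <- (x * 48271 + as.numeric(k) * 8191 + 1) %% m
  as.integer(x + 1)
}

#' Dimensionless open-fraction time course driven by a light schedule
#'
#' Composes the kinetic functional forms piecewise along the light schedule:
#' starting from `g = 0` under blue light, a UV onset starts an accelerating
#' rise `g(t) = a * (2^((t - t_uv)/tau_act) - 1)` capped at 1, with `a`
#' chosen so the cap is reached after `rise_span_tau * tau_act` seconds;
#' after the cap, a biphasic decay
#' `g = (1 - c) * (f * 2^(-dt/tau_fast) + (1 - f) * 2^(-dt/tau_slow)) + c`
#' describes inactivation; a blue onset lets `g` decay to 0 from its current
#' value with half-life `tau_deact_s`.  A saturating-rise variant
#' (`rise_mode = "saturating"`, `g = 1 - 2^(-dt/tau_act)`) is available for
#' realism studies.
#'
#' @param params A [gating_params()].
#' @param schedule A [light_schedule()] starting with a blue-class event.
#' @param fs Sampling frequency (Hz).
#' @param duration_s Duration of the returned series (s).
#' @param rise_span_tau Rise duration to cap, in units of `tau_act_s`
#'   (default 10/3, matching the 30%-of-peak fit-window convention).
#' @param rise_mode `"accelerating"` (default) or `"saturating"`.
#' @return Numeric vector `g(t)` in `[0, 1]`, sampled at `fs`.
#' @export
gating_timecourse <- function(params, schedule, fs, duration_s,
                              rise_span_tau = 10 / 3,
                              rise_mode = c("accelerating", "saturating")) {
  rise_mode <- match.arg(rise_mode)
  stopifnot(inherits(params, "gating_params"),
            inherits(schedule, "light_schedule"))
  if (nrow(schedule) == 0 ||
      wavelength_class(schedule$wavelength_nm[1]) != "blue")
    stop("schedule must start with a blue-class event (trans baseline)",
         call. = FALSE)
  n <- round(duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  g <- numeric(n)
  ev_t <- schedule$time_s
  ev_cls <- wavelength_class(schedule$wavelength_nm)
  g_now <- 0  # g at the start of the current segment
  for (i in seq_along(ev_t)) {
    seg_start <- ev_t[i]
    seg_end <- if (i < length(ev_t)) ev_t[i + 1] else duration_s
    idx <- which(t >= seg_start & t < seg_end)
    if (!length(idx) && seg_start < duration_s) next
    dt <- t[idx] - seg_start
    if (ev_cls[i] == "blue") {
      # deactivation toward 0 from the running level
      g[idx] <- g_now * 2^(-dt / params$tau_deact_s)
      g_now <- if (length(idx)) g_now * 2^(-(seg_end - seg_start) / params$tau_deact_s) else g_now
    } else {
      # UV: rise to cap, then biphasic inactivation toward the residual level
      span <- rise_span_tau * params$tau_act_s
      rise_at <- function(dt) {
        if (rise_mode == "accelerating")
          g_now + (1 - g_now) / (2^(span / params$tau_act_s) - 1) *
            (2^(dt / params$tau_act_s) - 1)
        else
          g_now + (1 - g_now) * (1 - 2^(-dt / params$tau_act_s))
      }
      peak_level <- min(1, rise_at(span))  # 1 exactly in accelerating mode
      f <- params$frac_fast; cc <- params$residual_c
      decay_at <- function(dd)
        peak_level * ((1 - cc) * (f * 2^(-dd / params$tau_inact_fast_s) +
                                  (1 - f) * 2^(-dd / params$tau_inact_slow_s)) + cc)
      seg <- ifelse(dt < span, pmin(rise_at(dt), 1), decay_at(dt - span))
      g[idx] <- seg
      end_dt <- seg_end - seg_start
      g_now <- if (end_dt < span) min(1, rise_at(end_dt)) else decay_at(end_dt - span)
    }
  }
  pmin(pmax(g, 0), 1)
}

#' Simulate a constant-holding kinetics trace
#'
#' Emulates a 2 kHz whole-cell recording at a constant holding potential
#' (conventionally -60 mV) during photoswitching:
#' `I(t) = C * (baseline_cd + g(t) * cd_at_holding) + noise`, where
#' `cd_at_holding` is the template density at the holding potential scaled
#' so its magnitude at the reference potential equals `peak_cd_pApF`.
#'
#' @param params A [gating_params()].
#' @param schedule A [light_schedule()].
#' @param capacitance_pF Membrane capacitance (pF).
#' @param duration_s Trace duration (s).
#' @param fs Sampling frequency (default 2000 Hz).
#' @param holding_mV Holding potential (default -60).
#' @param template An [iv_template()] (default near-symmetric).
#' @param ref_mV Reference potential at which `peak_cd_pApF` applies
#'   (default the holding potential).
#' @param noise_sd_pA Gaussian noise SD in pA (0 = noiseless).
#' @param seed Seed (mandatory when `noise_sd_pA > 0`).
#' @param ... Passed on to [gating_timecourse()].
#' @return A holding-mode [new_trace()].
#' @export
simulate_holding_trace <- function(params, schedule, capacitance_pF = 15,
                                   duration_s, fs = 2000, holding_mV = -60,
                                   template = iv_template_symmetric(),
                                   ref_mV = holding_mV,
                                   noise_sd_pA = 0, seed = NULL, ...) {
  if (noise_sd_pA > 0 && is.null(seed))
    stop("seed is mandatory when simulating noise", call. = FALSE)
  g <- gating_timecourse(params, schedule, fs, duration_s, ...)
  scale <- params$peak_cd_pApF / abs(eval_iv_template(template, ref_mV))
  cd_hold <- scale * eval_iv_template(template, holding_mV)
  i_pA <- capacitance_pF * (params$baseline_cd_pApF + g * cd_hold)
  if (noise_sd_pA > 0) {
    set.seed(seed)
    i_pA <- i_pA + stats::rnorm(length(i_pA), 0, noise_sd_pA)
  }
  new_trace(i_pA, fs, mode = "holding", holding_mV = holding_mV)
}

#' Simulate a session of repetitive voltage-ramp sweeps
#'
#' Sweeps are launched at the protocol repetition frequency; sweep `k`
#' starting at `t_k` has
#' `I(V, t) = C * (baseline_cd + g(t) * scale * template(V)) + noise`,
#' with the open fraction `g(t)` evaluated on the session clock, so slow
#' gating appears as sweep-to-sweep amplitude change.
#'
#' @inheritParams simulate_holding_trace
#' @param protocol A [ramp_protocol()].
#' @param n_sweeps Number of sweeps; defaults to as many as fit in
#'   `duration_s`.
#' @return List of ramp-mode [new_trace()] objects (one per sweep).
#' @export
simulate_ramp_session <- function(params, template, protocol, schedule,
                                  capacitance_pF = 15, duration_s,
                                  n_sweeps = NULL, ref_mV = -60,
                                  noise_sd_pA = 0, seed = NULL, ...) {
  if (noise_sd_pA > 0 && is.null(seed))
    stop("seed is mandatory when simulating noise", call. = FALSE)
  fs <- protocol$acquisition_Hz
  period <- 1 / protocol$repetition_Hz
  if (is.null(n_sweeps)) n_sweeps <- floor(duration_s / period)
  g_full <- gating_timecourse(params, schedule, fs, duration_s, ...)
  scale <- params$peak_cd_pApF / abs(eval_iv_template(template, ref_mV))
  if (!is.null(seed)) set.seed(seed)
  dur <- sweep_duration(protocol)
  n_samp <- round(dur * fs)
  t_sweep <- (seq_len(n_samp) - 1) / fs
  v <- ramp_voltage_at(protocol, t_sweep)
  tmpl_v <- eval_iv_template(template, v)
  lapply(seq_len(n_sweeps), function(k) {
    t0 <- (k - 1) * period
    idx <- round(t0 * fs) + seq_len(n_samp)
    gk <- g_full[pmin(idx, length(g_full))]
    i_pA <- capacitance_pF * (params$baseline_cd_pApF + gk * scale * tmpl_v)
    if (noise_sd_pA > 0)
      i_pA <- i_pA + stats::rnorm(n_samp, 0, noise_sd_pA)
    new_trace(i_pA, fs, mode = "ramp", protocol = protocol,
              sweep = k, t0 = t0)
  })
}

#' Simulate a cohort of recordings
#'
#' Draws per-cell gating parameters and capacitance from the log-normal
#' distributions of a [cohort_spec()], derives one child seed per cell from
#' the master seed, and simulates one constant-holding kinetics trace per
#' cell (plus, optionally, a ramp session).  The returned manifest records
#' every true parameter, enabling recovery checks.
#'
#' @param spec A [cohort_spec()].
#' @param schedule A [light_schedule()] shared by all cells.
#' @param duration_s Duration of each holding trace (s).
#' @param protocol Optional [ramp_protocol()]; when supplied a ramp session
#'   is simulated per cell as well.
#' @param template An [iv_template()] shared by all cells.
#' @param compound,light_source Arm labels stored on each recording.
#' @param ... Passed to [simulate_holding_trace()].
#' @return List with elements `recordings` (list of [recording()]) and
#'   `manifest` (data.frame of true per-cell parameters).
#' @export
simulate_cohort <- function(spec, schedule, duration_s, protocol = NULL,
                            template = iv_template_symmetric(),
                            compound = "synthetic", light_source = "LED",
                            ...) {
  stopifnot(inherits(spec, "cohort_spec"))
  lognorm <- function(med, g, n) {
    if (g <= 1) rep(med, n) else stats::rlnorm(n, log(med), log(g))
  }
  set.seed(spec$seed)
  n <- spec$n_cells
  draw <- list()
  kin_names <- c("tau_act_s", "tau_deact_s", "tau_inact_fast_s",
                 "tau_inact_slow_s", "peak_cd_pApF")
  for (nm in kin_names) {
    g <- if (!is.null(spec$gsd[[nm]])) spec$gsd[[nm]] else 1
    draw[[nm]] <- lognorm(spec$medians[[nm]], g, n)
  }
  draw$capacitance_pF <- lognorm(spec$capacitance_pF, spec$capacitance_gsd, n)
  # enforce fast < slow after independent draws
  swap <- draw$tau_inact_fast_s >= draw$tau_inact_slow_s
  if (any(swap)) {
    tmp <- draw$tau_inact_fast_s[swap]
    draw$tau_inact_fast_s[swap] <- draw$tau_inact_slow_s[swap] * 0.99
    draw$tau_inact_slow_s[swap] <- tmp * 1.01
  }
  recs <- vector("list", n)
  for (i in seq_len(n)) {
    p <- gating_params(tau_act_s = draw$tau_act_s[i],
                       tau_deact_s = draw$tau_deact_s[i],
                       tau_inact_fast_s = draw$tau_inact_fast_s[i],
                       tau_inact_slow_s = draw$tau_inact_slow_s[i],
                       frac_fast = spec$medians$frac_fast,
                       residual_c = spec$medians$residual_c,
                       peak_cd_pApF = draw$peak_cd_pApF[i],
                       baseline_cd_pApF = spec$medians$baseline_cd_pApF)
    cell_seed <- derive_seed(spec$seed, i)
    traces <- list(
      holding = simulate_holding_trace(p, schedule, draw$capacitance_pF[i],
                                       duration_s = duration_s,
                                       template = template,
                                       noise_sd_pA = spec$noise_sd_pA,
                                       seed = cell_seed, ...))
    if (!is.null(protocol)) {
      sw <- simulate_ramp_session(p, template, protocol, schedule,
                                  capacitance_pF = draw$capacitance_pF[i],
                                  duration_s = duration_s,
                                  noise_sd_pA = spec$noise_sd_pA,
                                  seed = derive_seed(spec$seed, 100000 + i))
      names(sw) <- paste0("sweep", seq_along(sw))
      traces <- c(traces, sw)
    }
    recs[[i]] <- recording(cell_id = sprintf("cell%03d", i),
                           capacitance_pF = draw$capacitance_pF[i],
                           compound = compound, light_source = light_source,
                           traces = traces, schedule = schedule)
  }
  manifest <- data.frame(cell_id = sprintf("cell%03d", seq_len(n)),
                         as.data.frame(draw),
                         seed = vapply(seq_len(n), derive_seed,
                                       integer(1), master = spec$seed))
  list(recordings = recs, manifest = manifest)
}

#' Simulate a thermal cis-to-trans absorbance relaxation time course
#'
#' After UV illumination the azobenzene chromophore relaxes thermally back
#' to *trans* in the dark; the absorbance at the *trans* absorption maximum
#' recovers as `A(t) = A_trans - (A_trans - A_cis) * 2^(-t / tau_half)`.
#'
#' @param tau_half_min Relaxation half-life in minutes.
#' @param A_cis Absorbance right after UV illumination (t = 0).
#' @param A_trans Dark-adapted (fully relaxed) absorbance.
#' @param duration_min Duration of the series (min).
#' @param step_min Sampling interval (min).
#' @param noise_sd Gaussian absorbance noise SD (0 = noiseless).
#' @param seed Seed, mandatory when `noise_sd > 0`.
#' @return data.frame with columns `t_min`, `absorbance`.
#' @export
simulate_absorbance_relaxation <- function(tau_half_min, A_cis = 0.35,
                                           A_trans = 1.0,
                                           duration_min = 2000,
                                           step_min = 1, noise_sd = 0,
                                           seed = NULL) {
  stopifnot(tau_half_min > 0, step_min > 0)
  if (noise_sd > 0 && is.null(seed))
    stop("seed is mandatory when simulating noise", call. = FALSE)
  t <- seq(0, duration_min, by = step_min)
  A <- A_trans - (A_trans - A_cis) * 2^(-t / tau_half_min)
  if (noise_sd > 0) {
    set.seed(seed)
    A <- A + stats::rnorm(length(A), 0, noise_sd)
  }
  data.frame(t_min = t, absorbance = A)
}
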