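#' Optimizer options and start values for the half-life fits
#'
#' Returns the simplex options and per-kind start points of the fit routine:
#' caps `max_fun_evals = 5000`, `max_iter = 10000`, tolerances
#' `tol_x = 1e-10`, `tol_fun = 1e-6`, and start values
#' activation `a = 0.01, tau = 1, c = 0.01`;
#' deactivation `a = 0.7, tau = 7, c = 0.1`;
#' inactivation `a1 = 1, tau1 = 0.02, c = 0.1, a2 = 1, tau2 = 3.8`.
#'
#' The start-value time constants are interpreted on the scale of the
#' kinetics they seed (`tau_init_unit`): milliseconds for activation and
#' deactivation (observed half-lives are 5-200 ms) and seconds for
#' inactivation (observed 0.3-190 s).  The fit itself always runs on a
#' seconds time axis; the initial tau is converted accordingly.  Both the
#' start values and the unit are overridable per call.
#'
#' @param kind `"activation"`, `"deactivation"` or `"inactivation"`.
#' @param ... Named overrides of any field, e.g. `init = c(...)`,
#'   `tol_fun = 1e-8`, `tau_init_unit = "s"`.
#' @return A list of class `"fit_options"` with fields `kind`,
#'   `max_fun_evals`, `max_iter`, `tol_x`, `tol_fun`, `init`,
#'   `tau_init_unit`.
#' @export
fit_options <- function(kind = c("activation", "deactivation",
                                 "inactivation"), ...) {
  kind <- match.arg(kind)
  init <- switch(kind,
    activation   = c(a = 0.01, tau = 1, c = 0.01),
    deactivation = c(a = 0.7, tau = 7, c = 0.1),
    inactivation = c(a1 = 1, tau1 = 0.02, a2 = 1, tau2 = 3.8, c = 0.1))
  opts <- list(kind = kind, max_fun_evals = 5000, max_iter = 10000,
               tol_x = 1e-10, tol_fun = 1e-6, init = init,
               tau_init_unit = if (kind == "inactivation") "s" else "ms")
  dots <- list(...)
  for (nm in names(dots)) {
    if (!nm %in% names(opts)) stop("unknown fit option: ", nm, call. = FALSE)
    opts[[nm]] <- dots[[nm]]
  }
  if (opts$tol_x <= 0 || opts$tol_fun <= 0)
    stop("tolerances must be > 0", call. = FALSE)
  if (opts$max_fun_evals < 1 || opts$max_iter < 1)
    stop("iteration caps must be >= 1", call. = FALSE)
  structure(opts, class = "fit_options")
}

#' Normalized segment prepared for half-life fitting
#'
#' A zero-shifted, dimensionless segment: `t` starts at 0 and is strictly
#' increasing, `y` is the normalized signal, and `normalization` records the
#' constants used (baseline median, divisor, peak, window bounds), so every
#' fit is traceable back to raw pA.
#'
#' @param t Times in seconds, `t[1] == 0`, strictly increasing.
#' @param y Normalized signal.
#' @param normalization Named list of normalization constants.
#' @param flags Character vector of advisory flags.
#' @return A list of class `"normalized_segment"`.
#' @export
normalized_segment <- function(t, y, normalization = list(), flags = character()) {
  if (length(t) != length(y)) stop("t and y must match in length", call. = FALSE)
  if (!length(t)) stop("segment is empty", call. = FALSE)
  if (abs(t[1]) > 1e-12) stop("segment time must start at 0", call. = FALSE)
  if (is.unsorted(t, strictly = TRUE))
    stop("segment time must be strictly increasing", call. = FALSE)
  if (!is.null(normalization$divisor) && normalization$divisor == 0)
    stop("normalization divisor must be nonzero", call. = FALSE)
  structure(list(t = as.numeric(t), y = as.numeric(y),
                 normalization = normalization, flags = flags),
            class = "normalized_segment")
}

# magnitude of the light-gated deflection relative to a baseline level,
# with automatic direction detection (inward currents deflect negative)
deflection <- function(current_pA, baseline, direction, post_idx, smooth_n) {
  m_in <- baseline - current_pA   # inward opening -> positive magnitude
  m_out <- current_pA - baseline
  if (direction == "auto") {
    sm_in <- max(smooth_median(m_in, smooth_n)[post_idx])
    sm_out <- max(smooth_median(m_out, smooth_n)[post_idx])
    direction <- if (sm_in >= sm_out) "inward" else "outward"
  }
  list(m = if (direction == "inward") m_in else m_out, direction = direction)
}

smooth_median <- function(x, k) {
  if (k <= 1) return(x)
  if (k %% 2 == 0) k <- k + 1
  if (length(x) < k) return(x)
  as.numeric(stats::runmed(x, k, endrule = "median"))
}

#' Prepare the activation segment of a kinetics trace
#'
#' Normalization convention for the rising (activation) phase: the median
#' current over a pre-UV baseline window is set to zero, and 30% of the
#' maximal activated deflection is set to +1, so the fitted window ends
#' where the signal reaches +1 and the emerging inactivation cannot
#' interfere with the rise.  Time is shifted to zero at the window start.
#'
#' @param trace A holding-mode [new_trace()].
#' @param schedule A [light_schedule()] with a UV event inside the trace.
#' @param baseline_s Length of the pre-UV baseline window (s, default 1).
#' @param frac Fraction of the peak mapped to +1 (default 0.30; sane range
#'   0.2 to 0.5).
#' @param smooth_n Moving-median window (samples) for peak detection.
#' @param direction `"auto"`, `"inward"` or `"outward"`.
#' @param noise_k Multiple of the baseline noise MAD below which a
#'   post-onset rise is not accepted as activation.
#' @return A [normalized_segment()].
#' @export
prepare_activation <- function(trace, schedule, baseline_s = 1, frac = 0.3,
                               smooth_n = 11, direction = "auto",
                               noise_k = 3) {
  stopifnot(inherits(trace, "trace"), trace$mode == "holding")
  if (frac < 0.2 || frac > 0.5)
    stop("frac must lie in [0.2, 0.5]", call. = FALSE)
  t_uv <- uv_onset(schedule)
  if (is.na(t_uv)) stop("no UV event in schedule", call. = FALSE)
  t <- trace_times(trace)
  if (t_uv <= t[1] || t_uv >= t[length(t)])
    stop("UV onset must fall within the trace", call. = FALSE)
  base_idx <- which(t >= t_uv - baseline_s & t < t_uv)
  if (!length(base_idx)) stop("no samples in the baseline window", call. = FALSE)
  baseline <- stats::median(trace$current_pA[base_idx])
  post_idx <- which(t >= t_uv)
  d <- deflection(trace$current_pA, baseline, direction, post_idx, smooth_n)
  m <- d$m
  m_sm <- smooth_median(m, smooth_n)
  m_pk <- max(m_sm[post_idx])
  noise <- stats::mad(m[base_idx])
  if (m_pk <= noise_k * noise || m_pk <= 0)
    stop("no activation detected (post-onset rise within noise)", call. = FALSE)
  divisor <- frac * m_pk
  y <- m / divisor
  y_sm <- m_sm / divisor
  cross <- post_idx[which(y_sm[post_idx] >= 1)[1]]
  if (is.na(cross)) cross <- post_idx[length(post_idx)]
  win <- post_idx[1]:cross
  normalized_segment(
    t = t[win] - t[win[1]],
    y = y[win],
    normalization = list(baseline_pA = baseline, divisor_pA = divisor,
                         peak_pA = m_pk, window_s = c(t[win[1]], t[cross]),
                         direction = d$direction, frac = frac))
}

#' Prepare the deactivation segment of a kinetics trace
#'
#' Normalization convention for the decaying (deactivation) phase: the
#' median deflection over a window before the blue-light onset is set to +1
#' and the median fully-deactivated deflection (settled tail) to zero.
#'
#' @inheritParams prepare_activation
#' @param pre_s Length of the pre-deactivation window (s, default 1).
#' @param tail_frac Fraction of the post-onset span treated as the settled
#'   tail (default 0.1).
#' @return A [normalized_segment()].
#' @export
prepare_deactivation <- function(trace, schedule, pre_s = 1,
                                 tail_frac = 0.1, smooth_n = 11,
                                 direction = "auto") {
  stopifnot(inherits(trace, "trace"), trace$mode == "holding")
  t_off <- uv_offset(schedule)
  if (is.na(t_off))
    stop("no blue-light onset after UV in schedule", call. = FALSE)
  t <- trace_times(trace)
  if (t_off >= t[length(t)])
    stop("deactivation onset must fall within the trace", call. = FALSE)
  pre_idx <- which(t >= t_off - pre_s & t < t_off)
  post_idx <- which(t >= t_off)
  base_idx <- which(t < uv_onset(schedule))
  baseline <- stats::median(trace$current_pA[base_idx])
  d <- deflection(trace$current_pA, baseline, direction, pre_idx, smooth_n)
  m <- d$m
  m_pre <- stats::median(m[pre_idx])
  n_tail <- max(3, ceiling(tail_frac * length(post_idx)))
  tail_idx <- post_idx[(length(post_idx) - n_tail + 1):length(post_idx)]
  m_end <- stats::median(m[tail_idx])
  span <- m_pre - m_end
  noise <- stats::mad(m[tail_idx])
  if (span == 0 || abs(span) <= 2 * noise)
    stop("no deactivation amplitude (pre and settled medians indistinguishable)",
         call. = FALSE)
  y <- (m - m_end) / span
  win <- post_idx
  normalized_segment(
    t = t[win] - t[win[1]],
    y = y[win],
    normalization = list(baseline_pA = baseline, pre_median_pA = m_pre,
                         end_median_pA = m_end, divisor_pA = span,
                         window_s = c(t[win[1]], t[win[length(win)]]),
                         direction = d$direction))
}

#' Prepare the inactivation segment of a kinetics trace
#'
#' Normalization convention for the biphasic decline during sustained UV:
#' the peak deflection is set to +1 and the median steady-state deflection
#' after inactivation (last `ss_frac` of the UV period) to zero.  Time is
#' shifted to zero at the peak.
#'
#' @inheritParams prepare_activation
#' @param ss_frac Fraction of the UV period used as the steady-state window
#'   (default 0.1).
#' @param min_uv_span_s UV period (after the peak) below which the segment
#'   is flagged `"uv-period-short"` (heuristic: 5x the slow-component start
#'   value; default 19 s).
#' @return A [normalized_segment()]; possibly with advisory flags.
#' @export
prepare_inactivation <- function(trace, schedule, ss_frac = 0.1,
                                 smooth_n = 11, direction = "auto",
                                 min_uv_span_s = 5 * 3.8) {
  stopifnot(inherits(trace, "trace"), trace$mode == "holding")
  t_uv <- uv_onset(schedule)
  if (is.na(t_uv)) stop("no UV event in schedule", call. = FALSE)
  t <- trace_times(trace)
  t_end <- uv_offset(schedule)
  if (is.na(t_end)) t_end <- t[length(t)] + 1 / trace$sampling_Hz
  uv_idx <- which(t >= t_uv & t < t_end)
  if (length(uv_idx) < 5) stop("UV period too short", call. = FALSE)
  base_idx <- which(t < t_uv)
  baseline <- stats::median(trace$current_pA[base_idx])
  d <- deflection(trace$current_pA, baseline, direction, uv_idx, smooth_n)
  m <- d$m
  m_sm <- smooth_median(m, smooth_n)
  pk_rel <- which.max(m_sm[uv_idx])
  # a peak inside the trailing smoothing window means the current was still
  # rising when UV was switched off: there is no inactivation phase to fit
  if (pk_rel >= length(uv_idx) - max(2, smooth_n))
    stop("UV switched off before the current peak; no inactivation phase",
         call. = FALSE)
  pk_idx <- uv_idx[pk_rel]
  m_pk <- m[pk_idx]
  n_ss <- max(3, ceiling(ss_frac * length(uv_idx)))
  ss_idx <- uv_idx[(length(uv_idx) - n_ss + 1):length(uv_idx)]
  m_ss <- stats::median(m[ss_idx])
  if (m_pk == m_ss) stop("no inactivation amplitude", call. = FALSE)
  y <- (m - m_ss) / (m_pk - m_ss)
  win <- pk_idx:uv_idx[length(uv_idx)]
  flags <- character()
  if ((t[uv_idx[length(uv_idx)]] - t[pk_idx]) < min_uv_span_s)
    flags <- c(flags, "uv-period-short")
  normalized_segment(
    t = t[win] - t[pk_idx],
    y = y[win],
    normalization = list(baseline_pA = baseline, peak_pA = m_pk,
                         ss_median_pA = m_ss, divisor_pA = m_pk - m_ss,
                         window_s = c(t[pk_idx], t[win[length(win)]]),
                         direction = d$direction),
    flags = flags)
}

#' Data-derived start values from a conditional-least-squares tau profile
#'
#' For a candidate half-life the amplitude(s) and offset of the exponential
#' model are linear parameters, so they can be solved exactly by least
#' squares.  Scanning a log-spaced grid of candidate half-lives (pairs for
#' the bi-exponential model) yields a deterministic, data-informed start
#' vector for the simplex when the canonical start point is inadequate -
#' e.g. when a noisy segment steers the unconstrained search into the
#' degenerate tau-to-infinity valley.
#'
#' @param segment A [normalized_segment()].
#' @param kind `"rising"`, `"decaying"` or `"bi"`.
#' @param n_grid Number of candidate half-lives per axis.
#' @return Numeric start vector in the layout the matching fit expects.
#' @export
profile_start <- function(segment, kind = c("rising", "decaying", "bi"),
                          n_grid = 40) {
  kind <- match.arg(kind)
  t <- segment$t; y <- segment$y
  span <- max(t); dt <- stats::median(diff(t))
  taus <- exp(seq(log(max(dt, span / 5000)), log(4 * span),
                  length.out = n_grid))
  if (kind != "bi") {
    s <- if (kind == "rising") 1 else -1
    best <- NULL
    for (tau in taus) {
      X <- cbind(2^(s * t / tau), 1)
      f <- stats::lm.fit(X, y)
      sse <- sum(f$residuals^2)
      if (is.null(best) || sse < best$sse)
        best <- list(sse = sse, par = c(f$coefficients[1], tau,
                                        f$coefficients[2]))
    }
    unname(best$par)
  } else {
    sub <- taus[seq(1, n_grid, by = 3)]
    best <- NULL
    for (i in seq_along(sub)) for (j in seq_along(sub)) {
      if (j <= i) next
      X <- cbind(2^(-t / sub[i]), 2^(-t / sub[j]), 1)
      f <- stats::lm.fit(X, y)
      sse <- sum(f$residuals^2)
      if (is.null(best) || sse < best$sse)
        best <- list(sse = sse, par = c(f$coefficients[1], sub[i],
                                        f$coefficients[2], sub[j],
                                        f$coefficients[3]))
    }
    unname(best$par)
  }
}

# start vector on the seconds time axis (tau entries converted per the
# declared unit of the start values)
fit_start <- function(options) {
  x0 <- options$init
  k <- if (identical(options$tau_init_unit, "ms")) 1e-3 else 1
  x0[grepl("^tau", names(x0))] <- x0[grepl("^tau", names(x0))] * k
  unname(x0)
}

# base-2 exponential models; the exponent is +/- ln2 * t / tau so tau is a
# half-life (decay) or doubling time (rise)
mono_model <- function(t, a, tau, c, direction) {
  s <- if (direction == "rising") 1 else -1
  a * 2^(s * t / tau) + c
}

bi_model <- function(t, a1, tau1, a2, tau2, c) {
  a1 * 2^(-t / tau1) + a2 * 2^(-t / tau2) + c
}

#' Fit a mono-exponential half-life model to a normalized segment
#'
#' Minimises the summed squared residuals of
#' `f(t) = a * 2^(+t/tau) + c` (rising) or `f(t) = a * 2^(-t/tau) + c`
#' (decaying) over `(a, tau, c)` with the fminsearch-style Nelder-Mead
#' simplex ([fminsearch_nm()]) from the [fit_options()] start point.  The
#' search is unconstrained; a sign-flipped `tau` is reflected to its
#' absolute value and flagged.
#'
#' @param segment A [normalized_segment()].
#' @param direction `"rising"` (activation) or `"decaying"` (deactivation).
#' @param options A [fit_options()]; defaults to the kind matching
#'   `direction`.
#' @return A list of class `"mono_fit"`: `a`, `c`, `tau_half` (s), `sse`,
#'   `n_evals`, `n_iter`, `converged`, `direction`, `flags`.
#' @export
fit_mono <- function(segment, direction = c("rising", "decaying"),
                     options = NULL) {
  direction <- match.arg(direction)
  stopifnot(inherits(segment, "normalized_segment"))
  if (is.null(options))
    options <- fit_options(if (direction == "rising") "activation"
                           else "deactivation")
  t <- segment$t; y <- segment$y
  sse <- function(p) {
    if (p[2] == 0) return(Inf)
    sum((y - mono_model(t, p[1], p[2], p[3], direction))^2)
  }
  res <- fminsearch_nm(sse, fit_start(options),
                       max_fun_evals = options$max_fun_evals,
                       max_iter = options$max_iter,
                       tol_x = options$tol_x, tol_fun = options$tol_fun)
  flags <- c(segment$flags, if (!res$converged) "caps-hit")
  tau <- res$par[2]
  if (tau < 0) flags <- c(flags, "tau-sign-flipped")
  structure(list(a = res$par[1], c = res$par[3], tau_half = abs(tau),
                 sse = res$value, n_evals = res$n_evals,
                 n_iter = res$n_iter, converged = res$converged,
                 direction = direction, flags = flags),
            class = "mono_fit")
}

#' Fit the bi-exponential inactivation model to a normalized segment
#'
#' Minimises the summed squared residuals of
#' `f(t) = a1 * 2^(-t/tau1) + a2 * 2^(-t/tau2) + c` over
#' `(a1, tau1, a2, tau2, c)` with the fminsearch-style simplex from the
#' inactivation start point of [fit_options()].  Components are reordered
#' so `tau_half_fast <= tau_half_slow`; when the two recovered half-lives
#' differ by less than `distinct_ratio`, the fit is flagged
#' `"components-indistinct"` (reported, not suppressed).
#'
#' @param segment A [normalized_segment()].
#' @param options A [fit_options()] (default `fit_options("inactivation")`).
#' @param distinct_ratio Minimum slow:fast ratio considered biphasic
#'   (default 3).
#' @return A list of class `"bi_fit"`: `a1`, `a2`, `c`, `tau_half_fast`,
#'   `tau_half_slow`, `sse`, `n_evals`, `n_iter`, `converged`, `flags`.
#' @export
fit_bi <- function(segment, options = fit_options("inactivation"),
                   distinct_ratio = 3) {
  stopifnot(inherits(segment, "normalized_segment"))
  t <- segment$t; y <- segment$y
  sse <- function(p) {
    if (p[2] == 0 || p[4] == 0) return(Inf)
    sum((y - bi_model(t, p[1], p[2], p[3], p[4], p[5]))^2)
  }
  res <- fminsearch_nm(sse, fit_start(options),
                       max_fun_evals = options$max_fun_evals,
                       max_iter = options$max_iter,
                       tol_x = options$tol_x, tol_fun = options$tol_fun)
  p <- res$par
  flags <- c(segment$flags, if (!res$converged) "caps-hit")
  if (any(p[c(2, 4)] < 0)) flags <- c(flags, "tau-sign-flipped")
  comp <- data.frame(a = p[c(1, 3)], tau = abs(p[c(2, 4)]))
  comp <- comp[order(comp$tau), ]
  ratio <- comp$tau[2] / comp$tau[1]
  if (!is.finite(ratio) || ratio < distinct_ratio)
    flags <- c(flags, "components-indistinct")
  # a half-life below the sampling interval only ever touches the first
  # sample: the component is vacuous, not a resolved fast phase
  if (comp$tau[1] < stats::median(diff(t)))
    flags <- c(flags, "fast-component-unresolved")
  structure(list(a1 = comp$a[1], a2 = comp$a[2], c = p[5],
                 tau_half_fast = comp$tau[1], tau_half_slow = comp$tau[2],
                 sse = res$value, n_evals = res$n_evals,
                 n_iter = res$n_iter, converged = res$converged,
                 flags = flags),
            class = "bi_fit")
}

#' Fit the thermal cis-to-trans relaxation half-life
#'
#' The recovering absorbance `A(t)` is converted to the decaying distance
#' from its final (fully relaxed, *trans*) level, normalized to start at 1,
#' and fitted with the decaying mono-exponential routine ([fit_mono()]).
#' Time is in minutes, so the reported `tau_half` is in minutes, and the
#' start-value time constant is read in the units of the time axis
#' (thermal half-lives are hundreds of minutes, the same order of
#' magnitude relative to the axis as the deactivation start point).
#'
#' @param t_min Times in minutes (ascending, starting anywhere).
#' @param absorbance Absorbance at the *trans* absorption maximum.
#' @param options A [fit_options()] (default deactivation start point with
#'   `tau_init_unit = "s"`, i.e. raw axis units).
#' @return A `"mono_fit"` with `tau_half` in minutes.
#' @export
fit_thermal_relaxation <- function(t_min, absorbance,
                                   options = fit_options("deactivation",
                                                         tau_init_unit = "s")) {
  stopifnot(length(t_min) == length(absorbance), length(t_min) >= 4)
  a_end <- stats::median(absorbance[t_min >= max(t_min) -
                                      0.05 * diff(range(t_min))])
  s <- a_end - absorbance
  if (max(abs(s)) < 1e-12 || s[1] == 0)
    stop("no relaxation amplitude", call. = FALSE)
  seg <- normalized_segment(t_min - t_min[1], s / s[1],
                            normalization = list(divisor = s[1],
                                                 a_end = a_end))
  fit_mono(seg, direction = "decaying", options = options)
}

#' Photostationary state from absorbance at the trans absorption maximum
#'
#' Under the approximation that the *cis* isomer does not absorb at the
#' *trans* absorption maximum, the fraction of molecules still in *trans*
#' under continuous illumination is the ratio of the photostationary-state
#' absorbance to the dark-adapted absorbance.
#'
#' @param A_dark Dark-adapted absorbance at the absorption maximum (> 0).
#' @param A_pss Absorbance at the photostationary state.
#' @param eps Tolerated relative overshoot of `A_pss` over `A_dark`
#'   (default 0.01).
#' @return Named numeric `c(pct_trans = ..., pct_cis = ...)` in percent.
#' @export
#' @examples
#' estimate_pss_from_absorbance(1.0, 0.93)  # 93% trans, 7% cis
estimate_pss_from_absorbance <- function(A_dark, A_pss, eps = 0.01) {
  if (!is.finite(A_dark) || A_dark <= 0)
    stop("A_dark must be > 0", call. = FALSE)
  if (A_pss < 0) stop("A_pss must be >= 0", call. = FALSE)
  if (A_pss > A_dark * (1 + eps))
    stop("A_pss exceeds A_dark beyond tolerance", call. = FALSE)
  pct_trans <- 100 * min(A_pss / A_dark, 1)
  c(pct_trans = pct_trans, pct_cis = 100 - pct_trans)
}

#' @export
print.mono_fit <- function(x, ...) {
  cat(sprintf("<mono_fit %s> tau_half = %.6g s | a = %.4g, c = %.4g | SSE = %.3g | %s\n",
              x$direction, x$tau_half, x$a, x$c, x$sse,
              if (x$converged) "converged" else "caps hit"))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.bi_fit <- function(x, ...) {
  cat(sprintf("<bi_fit> tau_fast = %.6g s, tau_slow = %.6g s | a1 = %.4g, a2 = %.4g, c = %.4g | SSE = %.3g | %s\n",
              x$tau_half_fast, x$tau_half_slow, x$a1, x$a2, x$c, x$sse,
              if (x$converged) "converged" else "caps hit"))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}
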