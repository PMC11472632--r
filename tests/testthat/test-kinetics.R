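# conditional-least-squares grid oracle: for each candidate tau the
# amplitude and offset are solved exactly by linear LS, so the profile
# SSE(tau) can be scanned densely and independently of the simplex code
grid_tau_oracle <- function(t, y, taus, direction = "decaying") {
  s <- if (direction == "rising") 1 else -1
  sse <- vapply(taus, function(tau) {
    X <- cbind(2^(s * t / tau), 1)
    sum(stats::lm.fit(X, y)$residuals^2)
  }, numeric(1))
  taus[which.min(sse)]
}

test_that("simplex minimiser solves smooth problems to tight tolerance", {
  # exact quadratic minimum
  res <- fminsearch_nm(function(x) sum((x - c(1, -2))^2), c(0, 0))
  expect_true(res$converged)
  expect_equal(res$par, c(1, -2), tolerance = 1e-7)

  # agrees with base optim's Nelder-Mead on a curved valley
  rosen <- function(x) 100 * (x[2] - x[1]^2)^2 + (1 - x[1])^2
  res2 <- fminsearch_nm(rosen, c(-1.2, 1))
  ref <- stats::optim(c(-1.2, 1), rosen,
                      control = list(reltol = 1e-12, maxit = 5000))
  expect_equal(res2$value, ref$value, tolerance = 1e-6)
  expect_equal(res2$par, c(1, 1), tolerance = 1e-4)

  # caps are honored and reported
  res3 <- fminsearch_nm(rosen, c(-1.2, 1), max_fun_evals = 20)
  expect_false(res3$converged)
  expect_lte(res3$n_evals, 20 + 2)
})

test_that("activation preparation anchors 30% of peak at +1", {
  # piecewise-linear trace: 1 s baseline at 0 pA, inward rise to -100 pA
  # over 0.1 s, then steady; 30% of the 100 pA peak -> divisor 30 pA
  fs <- 1000
  t <- seq(0, 3, by = 1 / fs)
  m <- pmin(pmax((t - 1) / 0.1, 0), 1) * 100
  tr <- new_trace(-m, fs, "holding", holding_mV = -60)
  sch <- light_schedule(c(0, 1), c(445, 365))
  seg <- prepare_activation(tr, sch, smooth_n = 1)
  expect_equal(seg$normalization$divisor_pA, 30)
  # sample at t = 1.015 s has magnitude 15 pA -> y = 0.5
  expect_equal(seg$y[which.min(abs(seg$t - 0.015))], 0.5, tolerance = 1e-9)
  # window ends at the first crossing of +1 (m = 30 pA at t = 1.030)
  expect_equal(seg$t[length(seg$t)], 0.030, tolerance = 2 / fs)
  expect_equal(seg$t[1], 0)

  expect_error(prepare_activation(tr, light_schedule(0, 445)), "UV")
})

test_that("activation window end matches the closed-form generator inversion", {
  tau <- 0.005
  p <- gating_params(tau_act_s = tau, residual_c = 0, peak_cd_pApF = 10,
                     baseline_cd_pApF = 0)
  sch <- std_schedule()
  tr <- simulate_holding_trace(p, sch, 10, duration_s = 50, noise_sd_pA = 0)
  seg <- prepare_activation(tr, sch)
  # generator rise: m = m_pk * a0 * (2^(t/tau) - 1), a0 = 1/(2^(10/3) - 1);
  # y reaches 1 where m = 0.3 * m_pk
  a0 <- 1 / (2^(10 / 3) - 1)
  t_end <- tau * log2(1 + 0.3 / a0)
  expect_equal(seg$t[length(seg$t)], t_end, tolerance = 2 / 2000 / t_end)
})

test_that("deactivation preparation maps pre/post medians onto 1 and 0", {
  fs <- 1000
  t <- seq(0, 4, by = 1 / fs)
  m <- numeric(length(t))
  m[t >= 1 & t < 2] <- 100
  dec <- t >= 2 & t < 2.5
  m[dec] <- 100 - 160 * (t[dec] - 2)   # linear 100 -> 20 over 0.5 s
  m[t >= 2.5] <- 20
  tr <- new_trace(-m, fs, "holding", holding_mV = -60)
  sch <- light_schedule(c(0, 1, 2), c(445, 365, 445))
  seg <- prepare_deactivation(tr, sch, smooth_n = 1)
  expect_equal(seg$normalization$pre_median_pA, 100)
  expect_equal(seg$normalization$end_median_pA, 20)
  # m = 60 pA at t = 2.25 -> y = (60 - 20) / 80 = 0.5
  expect_equal(seg$y[which.min(abs(seg$t - 0.25))], 0.5, tolerance = 1e-9)

  flat <- new_trace(rep(-5, length(t)), fs, "holding", holding_mV = -60)
  expect_error(prepare_deactivation(flat, sch, smooth_n = 1), "amplitude")
})

test_that("deactivation of a generator trace decays with its half-life", {
  tau <- 0.0084
  tr <- plateau_trace(tau)
  seg <- prepare_deactivation(tr, std_schedule())
  # at the sample nearest tau the normalized signal obeys the half-life law
  i <- which.min(abs(seg$t - tau))
  expect_equal(seg$y[i], 2^(-seg$t[i] / tau), tolerance = 5e-3)
  expect_equal(2^(-seg$t[i] / tau), 0.5, tolerance = 0.05)
})

test_that("inactivation preparation anchors peak at 1 and steady state at 0", {
  p <- gating_params(tau_act_s = 0.01, tau_inact_fast_s = 0.2,
                     tau_inact_slow_s = 2, residual_c = 0.1)
  sch <- light_schedule(c(0, 2), c(445, 365))
  tr <- simulate_holding_trace(p, sch, 10, duration_s = 30, noise_sd_pA = 0)
  seg <- prepare_inactivation(tr, sch)
  expect_equal(seg$y[1], 1)
  expect_equal(seg$t[1], 0)
  expect_lt(abs(median(seg$y[seg$t > 0.9 * max(seg$t)])), 0.02)

  # UV switched off before the peak -> no inactivation phase
  p2 <- gating_params(tau_act_s = 0.5, residual_c = 1)
  sch2 <- light_schedule(c(0, 2, 2.5), c(445, 365, 445))
  tr2 <- simulate_holding_trace(p2, sch2, 10, duration_s = 10,
                                noise_sd_pA = 0)
  expect_error(prepare_inactivation(tr2, sch2), "peak")
})

test_that("mono fits recover exact-model segments to 0.1%", {
  t <- seq(0, 0.0166, by = 5e-4)
  seg_r <- normalized_segment(t, 0.5 * 2^(t / 0.010) - 0.5)
  fr <- fit_mono(seg_r, "rising")
  expect_true(fr$converged)
  expect_equal(fr$tau_half, 0.010, tolerance = 1e-3)

  t2 <- seq(0, 0.2, by = 5e-4)
  seg_d <- normalized_segment(t2, 2^(-t2 / 0.020))
  fd <- fit_mono(seg_d, "decaying")
  expect_equal(fd$tau_half, 0.020, tolerance = 1e-3)
  expect_equal(fd$a, 1, tolerance = 1e-3)
  expect_equal(fd$c, 0, tolerance = 1e-3)
})

test_that("noisy decay fit lands inside the grid-search oracle envelope", {
  set.seed(314)
  t <- seq(0, 0.5, by = 5e-4)
  y <- 2^(-t / 0.050) + rnorm(length(t), 0, 0.05)
  seg <- normalized_segment(t, y)
  fit <- fit_mono(seg, "decaying")
  taus <- exp(seq(log(0.02), log(0.12), length.out = 400))
  tau_star <- grid_tau_oracle(t, y, taus)
  expect_equal(fit$tau_half, tau_star, tolerance = 0.01)
  # simplex result can only improve on the start point
  sse0 <- sum((y - 0.7 * 2^(-t / 0.007) - 0.1)^2)
  expect_lte(fit$sse, sse0)
})

test_that("fit is invariant to amplitude scaling and time origin", {
  tr <- plateau_trace(0.02)
  sch <- std_schedule()
  tau_ref <- fit_mono(prepare_deactivation(tr, sch), "decaying")$tau_half

  tr_scaled <- tr; tr_scaled$current_pA <- 4.2 * tr$current_pA
  tau_scaled <- fit_mono(prepare_deactivation(tr_scaled, sch),
                         "decaying")$tau_half
  expect_equal(tau_scaled, tau_ref, tolerance = 1e-9)

  tr_shift <- tr; tr_shift$t0 <- 12.5
  sch_shift <- light_schedule(std_schedule()$time_s + 12.5,
                              std_schedule()$wavelength_nm)
  tau_shift <- fit_mono(prepare_deactivation(tr_shift, sch_shift),
                        "decaying")$tau_half
  expect_equal(tau_shift, tau_ref, tolerance = 1e-9)
})

test_that("bi-exponential fit separates well-spaced components", {
  t <- seq(0, 10, by = 1e-3)
  y <- 0.5 * 2^(-t / 0.05) + 0.5 * 2^(-t / 2)
  seg <- normalized_segment(t, y)
  fb <- fit_bi(seg)
  expect_true(fb$converged)
  expect_equal(fb$tau_half_fast, 0.05, tolerance = 0.01)
  expect_equal(fb$tau_half_slow, 2, tolerance = 0.01)
  expect_lte(fb$tau_half_fast, fb$tau_half_slow)
  # amplitude conservation at t = 0
  expect_equal(fb$a1 + fb$a2 + fb$c, y[1], tolerance = 1e-3)

  # a single-exponential input cannot support two distinct components:
  # either the taus merge, an amplitude vanishes, or one tau collapses
  # below the sampling interval - all reported, never suppressed
  y1 <- 2^(-t / 0.5)
  fb1 <- fit_bi(normalized_segment(t, y1))
  expect_true(any(c("components-indistinct", "fast-component-unresolved")
                  %in% fb1$flags) ||
                min(abs(c(fb1$a1, fb1$a2))) < 0.05)
})

test_that("thermal relaxation fit recovers the generator half-life", {
  ab <- simulate_absorbance_relaxation(425.82, duration_min = 2000,
                                       step_min = 1)
  ft <- fit_thermal_relaxation(ab$t_min, ab$absorbance)
  expect_true(ft$converged)
  expect_equal(ft$tau_half, 425.82, tolerance = 1e-3)

  # doubling the sampling density moves tau by < 0.01%
  ab2 <- simulate_absorbance_relaxation(425.82, duration_min = 2000,
                                        step_min = 0.5)
  ft2 <- fit_thermal_relaxation(ab2$t_min, ab2$absorbance)
  expect_equal(ft2$tau_half, ft$tau_half, tolerance = 1e-4)

  flat <- data.frame(t_min = 0:100, absorbance = rep(0.8, 101))
  expect_error(fit_thermal_relaxation(flat$t_min, flat$absorbance),
               "amplitude")
})

test_that("PSS estimation from absorbance ratios is exact arithmetic", {
  expect_equal(unname(estimate_pss_from_absorbance(1, 0.93)), c(93, 7))
  expect_equal(unname(estimate_pss_from_absorbance(1, 1.0)), c(100, 0))
  expect_equal(unname(estimate_pss_from_absorbance(2, 1.8)), c(90, 10))
  expect_error(estimate_pss_from_absorbance(0, 0.5), "A_dark")
  expect_error(estimate_pss_from_absorbance(1, 1.5), "exceeds")
})

test_that("fit options validate their fields", {
  expect_error(fit_options("activation", tol_x = 0), "tolerances")
  expect_error(fit_options("activation", nonsense = 1), "unknown")
  o <- fit_options("inactivation")
  expect_equal(unname(o$init), c(1, 0.02, 1, 3.8, 0.1))
  expect_identical(o$tau_init_unit, "s")
  expect_identical(fit_options("deactivation")$tau_init_unit, "ms")
})
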