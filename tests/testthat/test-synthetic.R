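test_that("gating time course follows the piecewise photoswitching model", {
  p <- gating_params(tau_act_s = 0.01, tau_deact_s = 0.05,
                     tau_inact_fast_s = 0.3, tau_inact_slow_s = 13.1,
                     frac_fast = 0.5, residual_c = 0)
  fs <- 2000

  # no UV event -> g identically zero
  g0 <- gating_timecourse(p, light_schedule(0, 445), fs, duration_s = 1)
  expect_equal(g0, rep(0, 2000))

  # biphasic decay value at peak + 0.3 s, closed-form oracle
  sch <- light_schedule(c(0, 0.1), c(445, 365))
  g <- gating_timecourse(p, sch, fs, duration_s = 30)
  t <- (seq_along(g) - 1) / fs
  t_cap <- 0.1 + 10 / 3 * p$tau_act_s
  expected <- 0.5 * 2^(-0.3 / 0.3) + 0.5 * 2^(-0.3 / 13.1)
  expect_equal(g[which.min(abs(t - (t_cap + 0.3)))], expected,
               tolerance = 1e-3)

  # half-life semantics of deactivation: g halves every tau_deact
  sch2 <- light_schedule(c(0, 0.1, 0.2), c(445, 365, 445))
  p2 <- gating_params(tau_act_s = 0.01, tau_deact_s = 0.05, residual_c = 1)
  g2 <- gating_timecourse(p2, sch2, fs, duration_s = 1)
  g_at <- function(tt) g2[which.min(abs(t[seq_along(g2)] - tt))]
  expect_equal(g_at(0.2 + 0.05) / g_at(0.2), 0.5, tolerance = 1e-3)

  # range invariant over assorted parameter draws
  set.seed(42)
  for (i in 1:5) {
    pp <- gating_params(tau_act_s = runif(1, 0.005, 0.2),
                        tau_deact_s = runif(1, 0.005, 0.2),
                        tau_inact_fast_s = runif(1, 0.2, 1),
                        tau_inact_slow_s = runif(1, 5, 50),
                        frac_fast = runif(1), residual_c = runif(1, 0, 0.9))
    gg <- gating_timecourse(pp, sch2, 500, duration_s = 2)
    expect_true(all(gg >= 0 & gg <= 1))
  }

  # monotonicity: larger tau_deact keeps g pointwise larger while deactivating
  p_slow <- gating_params(tau_act_s = 0.01, tau_deact_s = 0.2, residual_c = 1)
  g_slow <- gating_timecourse(p_slow, sch2, fs, duration_s = 1)
  after <- t[seq_along(g2)] > 0.25
  expect_true(all(g_slow[after] >= g2[after]))

  expect_error(gating_timecourse(p, light_schedule(0, 365), fs, 1), "blue")
})

test_that("holding-trace simulation is deterministic and obeys its model", {
  p <- gating_params()
  sch <- std_schedule()

  # all-blue schedule, no noise -> constant baseline
  tr <- simulate_holding_trace(p, light_schedule(0, 445), 10,
                               duration_s = 1, noise_sd_pA = 0)
  expect_equal(tr$current_pA,
               rep(10 * p$baseline_cd_pApF, 2000))

  # same seed -> identical samples; different seed -> different
  t1 <- simulate_holding_trace(p, sch, 10, duration_s = 5,
                               noise_sd_pA = 2, seed = 99)
  t2 <- simulate_holding_trace(p, sch, 10, duration_s = 5,
                               noise_sd_pA = 2, seed = 99)
  t3 <- simulate_holding_trace(p, sch, 10, duration_s = 5,
                               noise_sd_pA = 2, seed = 100)
  expect_identical(t1$current_pA, t2$current_pA)
  expect_false(identical(t1$current_pA, t3$current_pA))

  # requested noise SD is realised over the baseline window (LLN)
  tb <- simulate_holding_trace(p, std_schedule(uv_off_s = 30), 10,
                               duration_s = 32, fs = 10000,
                               noise_sd_pA = 3, seed = 5)
  base <- tb$current_pA[1:20000]  # first 2 s are pre-UV baseline
  expect_equal(sd(base), 3, tolerance = 0.05)

  expect_error(simulate_holding_trace(p, sch, 10, duration_s = 5,
                                      noise_sd_pA = 1), "seed")
})

test_that("ramp sessions reproduce the template and scale with gating", {
  proto <- ramp_protocol_2hz()
  sch <- light_schedule(c(0, 1e-4), c(445, 365))
  tmpl <- iv_template_rectifying(3)
  p <- gating_params(tau_act_s = 1e-5, residual_c = 1, peak_cd_pApF = 60,
                     baseline_cd_pApF = 0)
  sweeps <- simulate_ramp_session(p, tmpl, proto, sch, capacitance_pF = 10,
                                  duration_s = 1.5)
  expect_length(sweeps, 3)
  iv <- extract_iv(sweeps[[2]], proto, 10)
  scale <- 60 / abs(eval_iv_template(tmpl, -60))
  expect_equal(iv$density_pA_pF, scale * eval_iv_template(tmpl, iv$voltage_mV),
               tolerance = 0.01)

  # g identically zero -> flat baseline sweeps
  p0 <- gating_params(baseline_cd_pApF = -2)
  s0 <- simulate_ramp_session(p0, tmpl, proto, light_schedule(0, 445),
                              capacitance_pF = 10, duration_s = 0.5)
  expect_equal(s0[[1]]$current_pA, rep(-20, length(s0[[1]]$current_pA)))
})

test_that("cohort simulation draws log-normals and reports a manifest", {
  sch <- light_schedule(c(0, 0.2), c(445, 365))

  spec0 <- cohort_spec(4, medians = list(tau_act_s = 0.01),
                       capacitance_gsd = 1, noise_sd_pA = 0, seed = 21)
  coh0 <- simulate_cohort(spec0, sch, duration_s = 1)
  expect_equal(nrow(coh0$manifest), 4)
  expect_length(coh0$recordings, 4)
  # zero geometric spread -> all cells identical
  expect_true(all(coh0$manifest$tau_act_s == 0.01))
  expect_identical(coh0$recordings[[1]]$traces$holding$current_pA,
                   coh0$recordings[[2]]$traces$holding$current_pA)

  # median of true parameters matches the spec median at n = 100
  spec1 <- cohort_spec(100, medians = list(tau_act_s = 0.02),
                       gsd = list(tau_act_s = 1.5), noise_sd_pA = 0,
                       seed = 22)
  coh1 <- simulate_cohort(spec1, sch, duration_s = 0.5)
  # log-normal median CI: log-median SE = log(1.5)/sqrt(100)
  expect_equal(median(log(coh1$manifest$tau_act_s)), log(0.02),
               tolerance = 3 * log(1.5) / 10 / abs(log(0.02)))
})

test_that("absorbance relaxation follows the half-life law", {
  ab <- simulate_absorbance_relaxation(100, A_cis = 0.4, A_trans = 1,
                                       duration_min = 1000, step_min = 1)
  # at t = tau_half the absorbance is midway between A_cis and A_trans
  expect_equal(ab$absorbance[ab$t_min == 100], (0.4 + 1) / 2)
  # long-time limit approaches A_trans
  expect_equal(ab$absorbance[nrow(ab)], 1, tolerance = 1e-3)
  expect_equal(ab$absorbance[1], 0.4)
})
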