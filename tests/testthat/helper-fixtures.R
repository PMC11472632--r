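# Shared fixtures for the suite: a standard photoswitching schedule
# (blue baseline, UV at 2 s, blue again) and small parameter sets.

std_schedule <- function(uv_off_s = 42) {
  light_schedule(c(0, 2, uv_off_s), c(445, 365, 445))
}

# noiseless holding trace with a pure mono-exponential deactivation tail
# (inactivation disabled via residual_c = 1)
plateau_trace <- function(tau_deact_s, duration_s = 50, fs = 2000,
                          capacitance_pF = 10, uv_off_s = 42) {
  p <- gating_params(tau_deact_s = tau_deact_s, residual_c = 1)
  simulate_holding_trace(p, std_schedule(uv_off_s), capacitance_pF,
                         duration_s = duration_s, fs = fs, noise_sd_pA = 0)
}

# one noiseless ohmic ramp sweep: I = g_ohm * V * C (density g_ohm * V)
ohmic_sweep <- function(g_ohm = 1, protocol = ramp_protocol_2hz(),
                        capacitance_pF = 10) {
  fs <- protocol$acquisition_Hz
  n <- round(sweep_duration(protocol) * fs)
  t <- (seq_len(n) - 1) / fs
  v <- ramp_voltage_at(protocol, t)
  new_trace(g_ohm * v * capacitance_pF, fs, mode = "ramp",
            protocol = protocol, sweep = 1L)
}

# a small but fully-featured synthetic recording for container round trips
small_recording <- function(seed = 7) {
  sch <- light_schedule(c(0, 0.5, 1.5), c(445, 365, 445))
  p <- gating_params(tau_act_s = 0.01, tau_deact_s = 0.02,
                     tau_inact_fast_s = 0.05, tau_inact_slow_s = 1)
  tr1 <- simulate_holding_trace(p, sch, capacitance_pF = 12.5,
                                duration_s = 2, fs = 500,
                                noise_sd_pA = 1, seed = seed)
  tr2 <- ohmic_sweep(protocol = ramp_protocol_50hz())
  recording(cell_id = "cellA", capacitance_pF = 12.5,
            compound = "OptoDArG", light_source = "LED",
            traces = list(holding = tr1, sweep1 = tr2), schedule = sch)
}
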