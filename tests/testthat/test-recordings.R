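test_that("current-density conversion divides by capacitance and round-trips", {
  tr0 <- new_trace(rep(0, 2000), 2000, "holding", holding_mV = -60)
  expect_equal(to_current_density(tr0, 10)$current_pA, rep(0, 2000))

  trc <- new_trace(rep(-600, 100), 2000, "holding", holding_mV = -60)
  cd <- to_current_density(trc, 10)
  expect_equal(cd$current_pA, rep(-60, 100))
  expect_identical(cd$units, "pA/pF")
  expect_identical(cd$holding_mV, trc$holding_mV)

  set.seed(11)
  x <- rnorm(500, sd = 50)
  tr <- new_trace(x, 2000, "holding", holding_mV = -60)
  back <- to_current_density(tr, 13.7)$current_pA * 13.7
  expect_equal(back, x, tolerance = 1e-12)

  expect_error(to_current_density(tr, 0), "positive")
  expect_error(to_current_density(tr, -5), "positive")
})

test_that("ramp command voltage is piecewise linear with half-open ramp interval", {
  slow <- ramp_protocol_2hz()
  expect_equal(ramp_voltage_at(slow, 0.025), -100)  # within pre-hold
  expect_equal(ramp_voltage_at(slow, 0.250), 0)     # ramp midpoint
  fast <- ramp_protocol_50hz()
  expect_equal(ramp_voltage_at(fast, 0.012), 0)     # (12-7)/10 of -100..+100

  # monotone nondecreasing across a dense grid, reaches ramp_end at the
  # last ramp instant and holds it through the post segment
  t <- seq(0, sweep_duration(slow) - 1e-6, length.out = 4001)
  v <- ramp_voltage_at(slow, t)
  expect_true(all(diff(v) >= 0))
  expect_equal(max(v), 100)
  expect_equal(ramp_voltage_at(slow, 0.45), 100)

  expect_error(ramp_voltage_at(slow, -0.001), "outside")
  expect_error(ramp_voltage_at(slow, sweep_duration(slow)), "outside")
})

test_that("protocol invariants are enforced", {
  expect_error(ramp_protocol(ramp_ms = 0), "> 0")
  expect_error(ramp_protocol(repetition_Hz = 10), "repetition period")
  expect_error(ramp_protocol(acquisition_Hz = 4000, filter_Hz = 2500),
               "Nyquist")
})

test_that("extract_iv recovers an ohmic relation and bins 10 samples per mV", {
  proto <- ramp_protocol_2hz()
  sweep <- ohmic_sweep(g_ohm = 0.8, protocol = proto, capacitance_pF = 10)
  iv <- extract_iv(sweep, proto, 10)
  expect_length(iv$voltage_mV, 200)          # 2000 ramp samples / 10 per bin
  expect_equal(iv$voltage_mV[1], -99.5)
  expect_equal(iv$voltage_mV[200], 99.5)
  # ohmic: bin mean equals g * bin-mean voltage up to sub-bin quantization
  # (10 samples at 0.1 mV pitch average to centre - 0.05; a sample landing
  # on a bin edge within floating-point error shifts one mean by ~0.04)
  expect_lt(max(abs(iv$density_pA_pF - 0.8 * (iv$voltage_mV - 0.05))), 0.1)
  expect_lt(max(abs(iv$density_pA_pF - 0.8 * iv$voltage_mV)), 0.15)
})

test_that("extract_iv commutes with current scaling and matches a cubic template", {
  proto <- ramp_protocol_2hz()
  fs <- proto$acquisition_Hz
  n <- round(sweep_duration(proto) * fs)
  t <- (seq_len(n) - 1) / fs
  v <- ramp_voltage_at(proto, t)
  cap <- 12
  cubic <- function(v) 50 * (v / 100)^3
  sweep <- new_trace(cubic(v) * cap, fs, "ramp", protocol = proto, sweep = 1L)
  iv <- extract_iv(sweep, proto, cap)
  # recovered curve tracks the template at bin centres within bin
  # quantization (max slope 1.5 pA/pF/mV over a 0.1 mV sample pitch)
  expect_lt(max(abs(iv$density_pA_pF - cubic(iv$voltage_mV))), 0.2)

  sweep2 <- sweep; sweep2$current_pA <- 3 * sweep$current_pA
  iv2 <- extract_iv(sweep2, proto, cap)
  expect_equal(iv2$density_pA_pF, 3 * iv$density_pA_pF, tolerance = 1e-12)
})

test_that("plateau current densities come from the hold segments", {
  proto <- ramp_protocol_2hz()
  sweep <- ohmic_sweep(g_ohm = 1, protocol = proto, capacitance_pF = 10)
  cd <- extract_plateau_cd(sweep, proto, 10)
  expect_equal(unname(cd), c(-100, 100))

  zero <- new_trace(rep(0, round(sweep_duration(proto) * 5000)), 5000,
                    "ramp", protocol = proto)
  expect_equal(unname(extract_plateau_cd(zero, proto, 10)), c(0, 0))

  # outward-rectifying generator: |cd(+100)| = 3 |cd(-100)|
  p <- gating_params(tau_act_s = 1e-5, residual_c = 1, peak_cd_pApF = 60)
  sw <- simulate_ramp_session(p, iv_template_rectifying(3), proto,
                              light_schedule(c(0, 1e-4), c(445, 365)),
                              capacitance_pF = 10, duration_s = 0.5,
                              n_sweeps = 1)[[1]]
  cd <- extract_plateau_cd(sw, proto, 10)
  base <- gating_params()$baseline_cd_pApF
  expect_equal(abs(cd[["cd_pos"]] - base) / abs(cd[["cd_neg"]] - base), 3,
               tolerance = 1e-6)

  expect_error(extract_plateau_cd(sweep, proto, 10, settle_frac = 1),
               "settle")
})

test_that("recording containers round-trip in both dialects", {
  rec <- small_recording()
  tmp <- withr::local_tempdir()

  json_path <- file.path(tmp, "rec.json")
  write_recording(rec, json_path, format = "json")
  r1 <- read_recording(json_path)
  expect_identical(r1$traces$holding$current_pA, rec$traces$holding$current_pA)
  expect_equal(r1, rec, tolerance = 1e-15)

  csv_path <- file.path(tmp, "rec_csv")
  write_recording(rec, csv_path, format = "csv")
  r2 <- read_recording(csv_path)
  expect_equal(r2$traces$holding$current_pA, rec$traces$holding$current_pA,
               tolerance = 1e-12)
  expect_equal(r2$capacitance_pF, rec$capacitance_pF)
  expect_equal(r2$schedule, rec$schedule)
})

test_that("both container dialects give identical downstream analysis", {
  rec <- small_recording()
  tmp <- withr::local_tempdir()
  write_recording(rec, file.path(tmp, "a.json"), format = "json")
  write_recording(rec, file.path(tmp, "b"), format = "csv")
  ra <- read_recording(file.path(tmp, "a.json"))
  rb <- read_recording(file.path(tmp, "b"))
  # the fast protocol has 50 ramp samples (4 mV pitch), so bin at 4 mV
  iva <- extract_iv(ra$traces$sweep1, capacitance_pF = ra$capacitance_pF,
                    bin_mV = 4)
  ivb <- extract_iv(rb$traces$sweep1, capacitance_pF = rb$capacitance_pF,
                    bin_mV = 4)
  expect_equal(iva$density_pA_pF, ivb$density_pA_pF, tolerance = 1e-12)
})

test_that("container schema errors name the offending field", {
  rec <- small_recording()
  tmp <- withr::local_tempdir()
  p <- file.path(tmp, "rec.json")
  write_recording(rec, p)
  x <- jsonlite::read_json(p, simplifyVector = TRUE)
  x$meta$capacitance_pF <- NULL
  jsonlite::write_json(x, p, auto_unbox = TRUE, digits = NA)
  expect_error(read_recording(p), "capacitance_pF")

  x2 <- jsonlite::read_json(file.path(tmp, "rec.json"), simplifyVector = TRUE)
  write_recording(rec, p)
  x2 <- jsonlite::read_json(p, simplifyVector = TRUE)
  x2$schedule$time_s <- rev(x2$schedule$time_s)
  jsonlite::write_json(x2, p, auto_unbox = TRUE, digits = NA)
  expect_error(read_recording(p), "schedule")
})

test_that("light schedules reject malformed event sequences", {
  expect_error(light_schedule(c(1, 0), c(445, 365)), "ascending")
  expect_error(light_schedule(c(0, 1), c(445, 445)), "alternate")
  expect_error(light_schedule(c(-1, 0), c(445, 365)), ">= 0")
  expect_error(light_schedule(0, 445, intensity_pct = 0), "intensity")
})

test_that("recording validates capacitance and event containment", {
  tr <- new_trace(rep(0, 100), 100, "holding", holding_mV = -60)
  expect_error(recording("c1", 0, traces = list(h = tr)), "capacitance")
  sch <- light_schedule(c(0, 5), c(445, 365))
  expect_error(recording("c1", 10, traces = list(h = tr), schedule = sch),
               "time span")
})

test_that("randomized recordings survive the json round trip (seeded)", {
  for (seed in c(1, 2, 3)) {
    set.seed(seed)
    n <- sample(50:200, 1)
    tr <- new_trace(rnorm(n, sd = 100), sample(c(500, 2000, 5000), 1),
                    "holding", holding_mV = -60)
    rec <- recording(paste0("r", seed), runif(1, 5, 30),
                     traces = list(h = tr),
                     schedule = light_schedule(0.01, 445))
    p <- withr::local_tempfile(fileext = ".json")
    write_recording(rec, p)
    expect_identical(read_recording(p)$traces$h$current_pA, tr$current_pA)
  }
})
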