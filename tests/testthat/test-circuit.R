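test_that("the default circuit instantiates the architecture", {
  circ <- build_default_circuit(sct_config(noise = FALSE))
  ## five absolute-timing microcircuits, one rate cell, all others spiking
  expect_length(circ$idx$absolute_timing_pyr, 5L)
  expect_length(circ$idx$absolute_timing_inh, 5L)
  rate_pops <- vapply(circ$pops, function(p) p$model == "rate", logical(1))
  expect_identical(sum(rate_pops), 1L)
  expect_identical(names(which(rate_pops)), "relative_timing")
  ## every neuron starts at rest
  expect_equal(circ$v, rep(-70, length(circ$v)))
  expect_identical(circ$V_rel, 0)
  ## zero-size populations are rejected
  expect_error(build_default_circuit(
    sct_config(noise = FALSE, circuit = list(n_replicates = 0))), "at least 1")
  ## non-increasing spans are rejected
  expect_error(sct_config(circuit = list(span_targets = c(90, 80, 220, 285, 350))) |>
                 build_default_circuit(), "strictly increasing")
})

test_that("a fresh unstimulated circuit stays silent", {
  circ <- build_default_circuit(sct_config(noise = FALSE))
  for (k in 1:1000) circuit_step(circ)
  expect_identical(circ$log_sp_n, 0L)
  expect_identical(circ$V_rel, 0)
})

test_that("a stimulus recruits all five absolute-timing groups quickly", {
  cfg <- sct_config(noise = FALSE)
  circ <- build_default_circuit(cfg)
  tapcircuit:::arm_session_noise(circ, cfg, 1, 2)
  tapcircuit:::stimulus_onset(circ)
  for (k in 1:100) circuit_step(circ, stimulus_on = TRUE)
  r <- spike_raster(circ)
  pyr <- r[r$population == "absolute_timing_pyr", ]
  expect_setequal(unique(pyr$neuron_index), 1:5)
  expect_lt(min(pyr$time_ms), 100)
  expect_true(all(tapply(pyr$time_ms, pyr$neuron_index, min) < 100))
})

test_that("the calibrated weight map times the calibration interval", {
  ## a drift rate of 1/400 must bring the relative-timing activity to
  ## threshold 400 ms (+- one smoothing window) after the synchronizing
  ## pulse, under zero noise
  cfg <- sct_config(target_interval = 500, noise = FALSE, initial_w = 1 / 400)
  circ <- build_default_circuit(cfg, drift_learner(w = 1 / 400, alpha = 0.25))
  tapcircuit:::arm_session_noise(circ, cfg, 1, 2)
  tapcircuit:::stimulus_onset(circ)
  crossing <- NULL
  for (k in 1:600) {
    ev <- circuit_step(circ, stimulus_on = circ$t < cfg$stimulus_duration)
    if (!is.null(ev$crossing)) { crossing <- ev$crossing; break }
  }
  pulse <- circ$pulses[1]
  expect_false(is.null(crossing))
  expect_lt(abs((crossing - pulse) - 400), 50)
})

test_that("spans are calibrated strictly increasing and reproducibly", {
  ccfg <- circuit_config()
  w1 <- calibrate_spans(ccfg)
  w2 <- calibrate_spans(ccfg)
  expect_identical(w1, w2)
  spans <- vapply(1:5, function(g) {
    s <- tapcircuit:::sim_single_group(w1[g], ccfg$latch_caps[g], ccfg, 1, 100)
    max(s)
  }, numeric(1))
  expect_true(all(diff(spans) > 0))
  expect_lt(max(spans), 400)
})

test_that("resetting pulls the interval machinery toward zero", {
  cfg <- sct_config(target_interval = 500, noise = FALSE)
  circ <- build_default_circuit(cfg, drift_learner(w = 1 / 400, alpha = 0.25))
  tapcircuit:::arm_session_noise(circ, cfg, 1, 2)
  tapcircuit:::stimulus_onset(circ)
  for (k in 1:300) circuit_step(circ, stimulus_on = circ$t < 100)
  v_pre <- circ$V_rel; a_pre <- circ$A
  expect_gt(v_pre, 1)
  apply_reset(circ)
  for (k in 1:50) circuit_step(circ)
  expect_lt(circ$V_rel, 0.1 * v_pre)
  expect_lt(circ$A, 0.2 * a_pre)
  ## resetting an already-quiescent circuit changes nothing
  circ2 <- build_default_circuit(cfg)
  tapcircuit:::arm_session_noise(circ2, cfg, 1, 2)
  apply_reset(circ2)
  for (k in 1:100) circuit_step(circ2)
  expect_identical(circ2$log_sp_n, 0L)
  expect_identical(circ2$V_rel, 0)
})

test_that("motor spikes coalesce into taps by the refractory window", {
  expect_identical(detect_tap(numeric(0)), numeric(0))
  expect_equal(detect_tap(c(100, 102)), 100)
  expect_equal(detect_tap(c(100, 102, 350, 352, 353)), c(100, 350))
  expect_equal(detect_tap(c(5, 30, 70, 120, 500), refractory = 100),
               c(5, 120, 500))
})

test_that("taps logged by the circuit match the pure coalescing rule", {
  tr <- fixture_training(500, noise = FALSE)[[1]]
  motor <- sort(tr$raster$time_ms[tr$raster$population == "motor"])
  expect_equal(tr$taps$time_ms,
               detect_tap(motor, tr$config$circuit$tap_refractory))
})

test_that("threshold-driven taps respect motor-latency causality", {
  tr <- fixture_training(500, noise = FALSE)[[5]]
  ccfg <- tr$config$circuit
  taps <- continuation_taps(tr)
  rel <- tr$relative_rate
  for (tp in taps[-1]) {
    ## last threshold crossing before the tap
    prev_tap <- max(tr$taps$time_ms[tr$taps$time_ms < tp - 50])
    seg <- rel[rel$time_ms > prev_tap + 100 & rel$time_ms <= tp, ]
    cross <- min(seg$time_ms[seg$activity_hz >= tr$config$rate_threshold])
    expect_gte(tp, cross)
    expect_lte(tp - cross, ccfg$motor_latency + ccfg$tap_refractory)
  }
})

test_that("event logs are bit-identical under a repeated seed", {
  r1 <- run_training(sct_config(target_interval = 400, seed = 12321,
                                n_sessions = 2))
  r2 <- run_training(sct_config(target_interval = 400, seed = 12321,
                                n_sessions = 2))
  expect_identical(lapply(r1, `[[`, "taps"), lapply(r2, `[[`, "taps"))
  expect_identical(lapply(r1, `[[`, "raster"), lapply(r2, `[[`, "raster"))
  expect_identical(lapply(r1, `[[`, "weights"), lapply(r2, `[[`, "weights"))
})
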