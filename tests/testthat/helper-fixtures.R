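## Shared fixtures and the independent reference integrator.

## Independent brute-force Euler loop for the Izhikevich model, coded
## separately from the package path; the arithmetic order (simultaneous
## derivatives, then spike test on the advanced v) matches the documented
## contract.
oracle_izhikevich <- function(a, b, c, d, I, dt, t_max, v0 = -70, u0 = -14,
                              cutoff = 30) {
  n <- round(t_max / dt)
  Ivec <- if (length(I) == 1L) rep(I, n) else I
  v <- v0; u <- u0
  spike_times <- numeric(0)
  for (k in seq_len(n)) {
    ## documented arithmetic order: left-to-right, 0.04 * v * v
    dv <- 0.04 * v * v + 5 * v + 140 - u + Ivec[k]
    du <- a * (b * v - u)
    v <- v + dt * dv
    u <- u + dt * du
    if (v >= cutoff) {
      v <- c
      u <- u + d
      spike_times <- c(spike_times, k * dt)
    }
  }
  spike_times
}

## package-path spike train for the same protocol (identical start state)
package_spike_train <- function(params, I, dt, t_max) {
  st <- izhikevich_state(-70, -14)
  n <- round(t_max / dt)
  Ivec <- if (length(I) == 1L) rep(I, n) else I
  out <- numeric(0)
  for (k in seq_len(n)) {
    r <- step_izhikevich(st, params, Ivec[k], dt)
    st <- r$state
    if (r$spiked) out <- c(out, k * dt)
  }
  out
}

## converged training runs are expensive; compute each condition once
.fixture_cache <- new.env(parent = emptyenv())
fixture_training <- function(target, noise = TRUE, sessions = 5, seed = 42) {
  key <- paste(target, noise, sessions, seed, sep = "_")
  if (is.null(.fixture_cache[[key]])) {
    cfg <- sct_config(target_interval = target, noise = noise,
                      n_sessions = sessions, seed = seed)
    .fixture_cache[[key]] <- run_training(cfg)
  }
  .fixture_cache[[key]]
}

## smoothed rate of one population of a trial
fixture_pop_rate <- function(trial, pop, width = 50) {
  ts <- sort(trial$raster$time_ms[trial$raster$population == pop])
  estimate_firing_rate(ts, kernel_width = width, grid_dt = 1, t_min = 0,
                       t_max = max(trial$raster$time_ms) + 100, label = pop)
}

continuation_taps <- function(trial) {
  trial$taps$time_ms[trial$taps$phase == "continuation"]
}
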