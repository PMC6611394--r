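## The synchronization-continuation tapping task (SCT) protocol:
## a synchronization phase in which a metronome delivers
## `n_sync_stimuli` stimuli at the target interval and the drift-rate is
## corrected at every stimulus after the first, followed by a
## continuation phase in which taps are self-initiated by the
## relative-timing threshold crossing, across training sessions that
## carry the learned drift rate forward.

#' Full run configuration for the tapping task
#'
#' Protocol-level fields with their defaults: target interval 500 ms,
#' 4 metronome stimuli (hence 3 weight updates per session), 4
#' continuation taps, 100 ms stimulus duration, 20 Hz relative-timing
#' threshold, 5 sessions, dt = 1 ms. `noise` switches both noise sources
#' (the per-interval drift-gain variability `gain_cv` and the per-step
#' accumulation noise `sigma_scale * w * sqrt(dt)`) on or off.
#'
#' @param ... Named overrides; `circuit` may be a `circuit_config` or a
#'   named list of circuit overrides.
#' @return A list of class `sct_config`.
#' @export
sct_config <- function(...) {
  cfg <- list(
    target_interval = 500,
    n_sync_stimuli = 4L,
    n_continuation_taps = 4L,
    stimulus_duration = 100,
    rate_threshold = 20,
    n_sessions = 5L,
    seed = 1L,
    dt = 1,
    alpha = 0.25,
    initial_w = 1 / 500,
    w_floor = 1e-6,
    sigma_scale = 0.01,
    gain_cv = 0.05,
    noise = TRUE,
    learn_in_continuation = FALSE,
    circuit = circuit_config()
  )
  dots <- list(...)
  if (!is.null(dots$circuit)) {
    if (inherits(dots$circuit, "circuit_config")) {
      cfg$circuit <- dots$circuit
    } else cfg$circuit <- do.call(circuit_config, dots$circuit)
    dots$circuit <- NULL
  }
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  class(cfg) <- "sct_config"
  cfg
}

#' Validate a run configuration
#'
#' Checks every cross-field invariant: the stimulus must be shorter than
#' the target interval, at least two metronome stimuli are needed to
#' define an interval, the absolute-timing spans must be strictly
#' increasing and leave a quiescence margin before the shortest interval,
#' and all scalar parameters must be in range. Errors list each offending
#' field.
#'
#' @param config An `sct_config`.
#' @return `TRUE`, invisibly; errors otherwise.
#' @export
validate_config <- function(config) {
  bad <- character(0)
  if (config$stimulus_duration >= config$target_interval)
    bad <- c(bad, "stimulus_duration: must be < target_interval")
  if (config$n_sync_stimuli < 2L)
    bad <- c(bad, "n_sync_stimuli: need >= 2 (one interval to learn from)")
  if (config$n_continuation_taps < 1L)
    bad <- c(bad, "n_continuation_taps: must be >= 1")
  if (config$dt <= 0) bad <- c(bad, "dt: must be > 0")
  if (config$rate_threshold <= 0) bad <- c(bad, "rate_threshold: must be > 0")
  if (config$alpha <= 0 || config$alpha > 1)
    bad <- c(bad, "alpha: must lie in (0, 1]")
  if (config$initial_w <= 0) bad <- c(bad, "initial_w: must be > 0")
  if (config$gain_cv < 0) bad <- c(bad, "gain_cv: must be >= 0")
  if (config$sigma_scale < 0) bad <- c(bad, "sigma_scale: must be >= 0")
  st <- config$circuit$span_targets
  if (any(diff(st) <= 0))
    bad <- c(bad, "circuit$span_targets: must be strictly increasing")
  if (max(st) + 50 > config$target_interval)
    bad <- c(bad, paste0(
      "circuit$span_targets: longest span (", max(st), " ms) leaves less ",
      "than 50 ms quiescence before a ", config$target_interval,
      " ms interval; shorten the spans or lengthen the target"))
  if (config$circuit$n_replicates < 1L)
    bad <- c(bad, "circuit$n_replicates: population sizes must be >= 1")
  if (length(bad))
    stop("invalid configuration:\n  ", paste(bad, collapse = "\n  "))
  invisible(TRUE)
}

## Pre-draw the session's noise: interval gains from the circuit stream,
## standardized accumulation deviates from the learner stream. Separate
## seeds make the two sources independent: switching one off does not
## shift the other's draws.
arm_session_noise <- function(circuit, config, circuit_seed, tddm_seed) {
  n_intervals <- config$n_sync_stimuli + 3L * config$n_continuation_taps + 10L
  max_steps <- ceiling((config$n_sync_stimuli + 3 * config$n_continuation_taps
                        + 2) * config$target_interval / config$dt) + 1000L
  if (circuit$gain_cv > 0) {
    set.seed(circuit_seed)
    circuit$gain_draws <- stats::rnorm(n_intervals)
  }
  circuit$gain_ptr <- 0L
  if (circuit$sigma_scale > 0) {
    set.seed(tddm_seed)
    circuit$eps_draws <- stats::rnorm(max_steps)
  }
  circuit$eps_ptr <- 0L
  invisible(circuit)
}

#' Run the synchronization phase
#'
#' Delivers `n_sync_stimuli` stimuli at the target spacing. At every
#' stimulus after the first the drift-rate correction is committed: the
#' early-reward product rule when the relative-timing activity has not
#' reached threshold in the elapsed interval, otherwise the late
#' decrement accumulated since the threshold crossing; each commit
#' updates the plastic projection scale.
#'
#' @param circuit A `circuit_state` from [build_default_circuit()].
#' @param learner Optional `drift_learner` to install before running.
#' @param config The `sct_config` (defaults to the one inside `circuit`).
#' @return The circuit (with its learner and logs advanced), invisibly.
#' @export
run_sync_phase <- function(circuit, learner = NULL, config = circuit$config) {
  e <- circuit
  if (!is.null(learner)) {
    e$learner <- learner
    e$W_plastic <- drift_to_weight(learner$w, e$coupling)
  }
  dt <- config$dt
  T_target <- config$target_interval
  stim_times <- (seq_len(config$n_sync_stimuli) - 1L) * T_target
  sdur <- config$stimulus_duration
  ## run to the last stimulus plus enough time for its tap and reset
  t_end <- stim_times[length(stim_times)] + e$ccfg$motor_latency +
    e$ccfg$motor_pulse_duration + e$ccfg$reset_pulse_delay +
    e$ccfg$reset_pulse_duration + e$ccfg$reset_window + 20
  next_stim <- 1L
  e$phase <- "sync"
  while (e$t < t_end - dt / 2) {
    if (next_stim <= length(stim_times) &&
        e$t >= stim_times[next_stim] - dt / 2) {
      stimulus_onset(e)
      next_stim <- next_stim + 1L
    }
    stim_on <- next_stim > 1L &&
      e$t < stim_times[next_stim - 1L] + sdur - dt / 2
    circuit_step(e, stimulus_on = stim_on)
  }
  invisible(e)
}

#' Run the continuation phase
#'
#' No external stimuli: taps arise from threshold-driven motor
#' activation, each tap feeds back as the internal synchronizing signal
#' and fires the resetting cell. Runs until `n_continuation_taps` taps or
#' a timeout of three target intervals per expected tap; a timeout with
#' zero taps is an error (the circuit failed to self-pace). Learning is
#' frozen unless `learn_in_continuation` is set.
#'
#' @inheritParams run_sync_phase
#' @return The circuit, invisibly.
#' @export
run_continuation_phase <- function(circuit, learner = NULL,
                                   config = circuit$config) {
  e <- circuit
  if (!is.null(learner)) {
    e$learner <- learner
    e$W_plastic <- drift_to_weight(learner$w, e$coupling)
  }
  e$phase <- "continuation"
  dt <- config$dt
  t_limit <- e$t + 3 * config$target_interval * config$n_continuation_taps
  while (e$n_cont_taps < config$n_continuation_taps && e$t < t_limit) {
    circuit_step(e, stimulus_on = FALSE)
  }
  if (e$n_cont_taps == 0L)
    stop("circuit failed to self-pace: no continuation tap within ",
         round(t_limit), " ms (drift rate w = ", signif(e$learner$w, 4),
         ", relative-timing activity ", signif(e$V_rel, 4), " Hz)")
  ## settle the last tap's reset
  for (i in seq_len(ceiling(60 / dt))) circuit_step(e, stimulus_on = FALSE)
  invisible(e)
}

assemble_trial <- function(circuit, config, session) {
  e <- circuit
  taps <- data.frame(time_ms = e$taps$time, phase = e$taps$phase,
                     trigger = e$taps$trigger)
  wl <- e$weight_log
  weights <- data.frame(session = rep(session, length(wl$update_index)),
                        update_index = wl$update_index,
                        w_before = wl$w_before, w_after = wl$w_after,
                        branch = wl$branch, time_ms = wl$time)
  cont <- taps$time_ms[taps$phase == "continuation"]
  intervals <- if (length(cont) >= 2) diff(cont) else numeric(0)
  structure(list(session = session,
                 stimuli = e$stimuli,
                 pulses = e$pulses,
                 taps = taps,
                 weights = weights,
                 raster = spike_raster(e),
                 relative_rate = data.frame(
                   time_ms = e$log_vrel_t[seq_len(e$log_vrel_n)],
                   activity_hz = e$log_vrel[seq_len(e$log_vrel_n)]),
                 intervals = intervals,
                 w_start = if (nrow(weights)) weights$w_before[1] else e$learner$w,
                 w_end = e$learner$w,
                 config = config),
            class = "sct_trial")
}

#' @export
print.sct_trial <- function(x, ...) {
  cat(sprintf(
    paste0("SCT trial (session %d, target %g ms): %d stimuli, %d taps,",
           " %d weight updates\n  drift rate %.5g -> %.5g /ms;",
           " produced intervals: %s ms\n"),
    x$session, x$config$target_interval, length(x$stimuli), nrow(x$taps),
    nrow(x$weights), x$w_start, x$w_end,
    paste(round(x$intervals, 1), collapse = ", ")))
  invisible(x)
}

#' Count the drift-rate commits in a trial
#'
#' The protocol commits one update per metronome stimulus after the
#' first, so a default 4-stimulus synchronization phase yields exactly 3.
#'
#' @param trial An `sct_trial`.
#' @return Integer count of committed weight updates.
#' @export
count_weight_updates <- function(trial) {
  stopifnot(inherits(trial, "sct_trial"))
  nrow(trial$weights)
}

#' Run a full training experiment
#'
#' Runs `n_sessions` tapping-task sessions. The learned drift rate is
#' carried across sessions while all dynamic state (membrane potentials,
#' synaptic traces, semaphore) is re-initialized each session. All
#' randomness derives from `config$seed`; identical configurations give
#' bit-identical event logs.
#'
#' @param config An `sct_config`.
#' @return A list of `sct_trial` objects (class `sct_training`).
#' @export
run_training <- function(config = sct_config()) {
  validate_config(config)
  set.seed(config$seed)
  n <- config$n_sessions
  seeds <- matrix(sample.int(.Machine$integer.max - 1L, 2L * n), nrow = 2L)
  learner <- drift_learner(w = config$initial_w, alpha = config$alpha,
                           sigma = 0, dt = config$dt,
                           w_floor = config$w_floor)
  trials <- vector("list", n)
  for (s in seq_len(n)) {
    circuit <- build_default_circuit(config, learner)
    arm_session_noise(circuit, config, seeds[1, s], seeds[2, s])
    run_sync_phase(circuit, config = config)
    run_continuation_phase(circuit, config = config)
    trials[[s]] <- assemble_trial(circuit, config, s)
    learner <- circuit$learner
  }
  structure(trials, class = "sct_training")
}

#' @export
print.sct_training <- function(x, ...) {
  cfg <- x[[1]]$config
  cat(sprintf("SCT training: %d sessions, target %g ms\n",
              length(x), cfg$target_interval))
  for (tr in x)
    cat(sprintf("  session %d: w %.5g -> %.5g, mean produced %s ms\n",
                tr$session, tr$w_start, tr$w_end,
                if (length(tr$intervals)) round(mean(tr$intervals), 1) else "-"))
  invisible(x)
}
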