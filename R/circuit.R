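## The full timing circuit: input cells, five absolute-timing
## microcircuits (regular-spiking pyramidal cell latched by saturating
## self-excitation, shut down by a fast-spiking interneuron that
## integrates the pyramidal spike count), a rate-based relative-timing
## readout cell, a time-accumulator cell, the swing microcircuit, motor
## and resetting cells, and an accident-preventing gate on the
## relative->motor pathway. All spiking cells use the Izhikevich model;
## the relative-timing cell uses the rate equation.

.tapcircuit_cache <- new.env(parent = emptyenv())

#' Circuit configuration
#'
#' Returns the default circuit configuration, optionally overridden.
#' The most consequential fields are the five absolute-timing span
#' targets (ms; strictly increasing, all shorter than the shortest target
#' interval so every microcircuit completes its up-down cycle and is
#' quiescent again before the next synchronizing pulse), the latch
#' saturation levels that set each group's plateau firing rate, and the
#' synaptic/readout constants documented in the package vignette.
#'
#' @param ... Named overrides of default fields (unknown names error).
#' @return A list of class `circuit_config`.
#' @export
circuit_config <- function(...) {
  cfg <- list(
    n_replicates = 1L,
    gamma_m = 50,             # ms, relative-timing intrinsic time constant
    stimulus_amplitude = 15,  # input-cell drive while the metronome is on
    kick_amplitude = 10,      # synchronizing pulse onto absolute groups
    sync_pulse_duration = 100,  # ms the synchronizing pulse drives the groups
    w_ee = 8,                 # pyramidal self-excitation gain
    tau_e = 80,               # ms, self-excitation trace
    latch_caps = c(14, 13, 12, 11, 10),  # saturation of self-excitation
    w_ie = 20,                # interneuron -> pyramidal inhibition
    tau_i = 15,               # ms, inhibitory trace
    tau_q = 2000,             # ms, interneuron spike-count integrator
    span_targets = c(90, 155, 220, 285, 350),  # ms, per-group up-down spans
    w_ei = NULL,              # pyr -> interneuron gains; calibrated if NULL
    tau_p = 10000,            # ms, pooled absolute->readout synaptic trace
    w_acc = 1.6e-3,           # accumulator drive per unit integrated trace
    w_acc_swing = 10,         # accumulator -> swing pyramidal gain
    tau_acc_syn = 50,         # ms
    w_swing = 10,             # swing pyramidal -> swing cell gain
    tau_swing_syn = 30,       # ms
    w_reset_swing = 10,       # resetting -> swing cell inhibition
    tau_reset_swing = 250,    # ms, slow decay of the post-tap inhibition
    motor_latency = 20,       # ms conduction delay onto the motor cell
    pulse_amplitude = 15,
    motor_pulse_duration = 8, # ms
    tap_refractory = 100,     # ms, motor spikes closer than this are one tap
    reset_pulse_delay = 2,    # ms, motor -> resetting conduction
    reset_pulse_duration = 6, # ms
    reset_window = 25,        # ms of shunting after a resetting spike
    tau_reset = 6,            # ms, decay of shunted quantities in the window
    gate_min = 200,           # ms the accident-preventing gate stays closed
    coupling_interval = 400   # ms, calibration interval for drift_to_weight
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown circuit config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  class(cfg) <- "circuit_config"
  cfg
}

validate_circuit_config <- function(ccfg, dt = 1) {
  if (ccfg$n_replicates < 1)
    stop("population size ('n_replicates') must be at least 1")
  st <- ccfg$span_targets
  if (length(st) != 5L || any(diff(st) <= 0))
    stop("absolute-timing span targets must be 5 strictly increasing values")
  if (!is.null(ccfg$w_ei) && length(ccfg$w_ei) != 5L)
    stop("'w_ei' must have one gain per absolute-timing group")
  if (length(ccfg$latch_caps) != 5L)
    stop("'latch_caps' must have one level per absolute-timing group")
  if (dt <= 0) stop("'dt' must be positive")
  invisible(TRUE)
}

## --- span calibration -----------------------------------------------------

## One absolute-timing microcircuit simulated in isolation from a
## synchronizing pulse at t = 0; returns the pyramidal spike times.
## Uses exactly the update rule of the in-circuit groups.
sim_single_group <- function(w_ei, cap, ccfg, dt, kick_dur, t_max = 1200) {
  exc <- make_excitatory_params(); inh <- make_inhibitory_params()
  rest <- resting_state(exc)
  vp <- rest$v; up <- rest$u; vi <- rest$v; ui <- rest$u
  e <- 0; q <- 0; ii <- 0
  de <- exp(-dt / ccfg$tau_e); dq <- exp(-dt / ccfg$tau_q)
  di <- exp(-dt / ccfg$tau_i)
  spikes <- numeric(0)
  for (t in seq(dt, t_max, by = dt)) {
    Ik <- if (t <= kick_dur) ccfg$kick_amplitude else 0
    Ip <- Ik + min(ccfg$w_ee * e, cap) - ccfg$w_ie * ii
    vp2 <- vp + dt * (0.04 * vp * vp + 5 * vp + 140 - up + Ip)
    up <- up + dt * exc$a * (exc$b * vp - up)
    vp <- vp2
    sp <- vp >= exc$spike_cutoff
    if (sp) { vp <- exc$c; up <- up + exc$d; spikes <- c(spikes, t) }
    Ii <- w_ei * q
    vi2 <- vi + dt * (0.04 * vi * vi + 5 * vi + 140 - ui + Ii)
    ui <- ui + dt * inh$a * (inh$b * vi - ui)
    vi <- vi2
    si <- vi >= inh$spike_cutoff
    if (si) { vi <- inh$c; ui <- ui + inh$d }
    e <- e * de + sp; q <- q * dq + sp; ii <- ii * di + si
  }
  spikes
}

#' Calibrate the absolute-timing group spans
#'
#' For each of the five microcircuits, bisects the pyramidal-to-
#' interneuron gain so that the group's intrinsic up-down cycle (first to
#' last pyramidal spike after a synchronizing pulse) lasts approximately
#' the configured span target. The search is deterministic and the result
#' is cached per configuration.
#'
#' @param ccfg A `circuit_config`.
#' @param dt Integration step (ms).
#' @param kick_dur Synchronizing-pulse duration (ms).
#' @return Numeric vector of five gains.
#' @export
calibrate_spans <- function(ccfg, dt = 1, kick_dur = 100) {
  key <- paste("spans", dt, kick_dur,
               paste(ccfg$span_targets, collapse = ","),
               paste(ccfg$latch_caps, collapse = ","),
               ccfg$w_ee, ccfg$tau_e, ccfg$w_ie, ccfg$tau_i, ccfg$tau_q,
               ccfg$kick_amplitude, sep = "|")
  if (!is.null(.tapcircuit_cache[[key]])) return(.tapcircuit_cache[[key]])
  span_of <- function(w_ei, cap) {
    s <- sim_single_group(w_ei, cap, ccfg, dt, kick_dur)
    if (length(s)) max(s) else 0
  }
  w <- vapply(seq_len(5L), function(g) {
    lo <- 0.05; hi <- 8   # span decreasing in the gain
    for (k in 1:22) {
      mid <- sqrt(lo * hi)
      if (span_of(mid, ccfg$latch_caps[g]) >= ccfg$span_targets[g]) {
        lo <- mid
      } else hi <- mid
    }
    sqrt(lo * hi)
  }, numeric(1))
  spans <- mapply(span_of, w, ccfg$latch_caps)
  if (any(diff(spans) <= 0))
    stop("span calibration failed to produce strictly increasing spans: ",
         paste(round(spans), collapse = ", "))
  .tapcircuit_cache[[key]] <- w
  w
}

#' Calibrate the drift-to-weight coupling constants
#'
#' Simulates the five calibrated absolute-timing microcircuits from one
#' synchronizing pulse, accumulates the pooled synaptic trace `P(t)` and
#' its time integral `A(t)`, and returns the coupling constants for
#' [drift_to_weight()]: the mean total trace over the calibration
#' interval, `drive_scale = A(T_cal) / T_cal`. With the resulting weight
#' map, a drift rate of `1 / T_cal` makes the relative-timing activity
#' reach the firing-rate threshold at `T_cal` under zero noise.
#'
#' @param ccfg A `circuit_config` (with `w_ei` set or calibratable).
#' @param dt Integration step (ms).
#' @param kick_dur Synchronizing-pulse duration (ms).
#' @param rate_threshold Relative-timing firing-rate threshold (Hz).
#' @return A list with `gamma_m`, `threshold`, `drive_scale`.
#' @export
calibrate_coupling <- function(ccfg, dt = 1, kick_dur = 100,
                               rate_threshold = 20) {
  w_ei <- if (is.null(ccfg$w_ei)) calibrate_spans(ccfg, dt, kick_dur) else ccfg$w_ei
  key <- paste("coupling", dt, kick_dur, rate_threshold, ccfg$gamma_m,
               ccfg$tau_p, ccfg$coupling_interval,
               paste(signif(w_ei, 8), collapse = ","),
               paste(ccfg$latch_caps, collapse = ","),
               ccfg$w_ee, ccfg$tau_e, ccfg$w_ie, ccfg$tau_i, ccfg$tau_q,
               ccfg$kick_amplitude, sep = "|")
  if (!is.null(.tapcircuit_cache[[key]])) return(.tapcircuit_cache[[key]])
  t_cal <- ccfg$coupling_interval
  spikes <- sort(unlist(lapply(seq_len(5L), function(g)
    sim_single_group(w_ei[g], ccfg$latch_caps[g], ccfg, dt, kick_dur,
                     t_max = t_cal))))
  n_steps <- round(t_cal / dt)
  counts <- tabulate(pmin(pmax(round(spikes / dt), 1L), n_steps),
                     nbins = n_steps)
  decP <- exp(-dt / ccfg$tau_p)
  ## emulate the post-tap shunting window that follows every tap in the
  ## task: spikes arriving while the resetting cell holds the integrating
  ## synapses shunted do not count
  sh_from <- ccfg$reset_pulse_delay + 2
  sh_until <- sh_from + ccfg$reset_window
  P <- 0; A <- 0
  for (k in seq_len(n_steps)) {
    tk <- k * dt
    if (tk > sh_from && tk <= sh_until) {
      P <- P * exp(-dt / ccfg$tau_reset)
    } else {
      P <- P * decP + counts[k]
      A <- A + P * dt
    }
  }
  out <- list(gamma_m = ccfg$gamma_m, threshold = rate_threshold,
              drive_scale = A / t_cal)
  .tapcircuit_cache[[key]] <- out
  out
}

## --- circuit assembly -----------------------------------------------------

#' Assemble the default timing circuit
#'
#' Instantiates every population and projection of the architecture:
#' input cells project to the absolute-timing groups and the motor cell;
#' the five absolute-timing groups project (through the plastic weight
#' bank scaled by the learner's drift rate) to the relative-timing cell
#' and (through fixed integrating synapses) to the time-accumulator; the
#' relative-timing cell drives the motor cell through the
#' accident-preventing gate; the motor cell drives the resetting cell and
#' feeds back to the absolute-timing groups; the resetting cell inhibits
#' the relative-timing, time-accumulator and swing populations. All
#' neurons start at their resting state.
#'
#' @param config A full run configuration from [load_config()] (or
#'   [sct_config()]), or a `circuit_config` for the circuit part alone
#'   (protocol fields then take their defaults).
#' @param learner Optional `drift_learner` supplying the initial plastic
#'   weight scale; a default learner is created if omitted.
#' @return A `circuit_state` (an environment-backed object).
#' @export
build_default_circuit <- function(config = sct_config(), learner = NULL) {
  if (inherits(config, "circuit_config")) config <- sct_config(circuit = config)
  ccfg <- config$circuit
  validate_circuit_config(ccfg, config$dt)
  validate_config(config)
  dt <- config$dt
  kick_dur <- ccfg$sync_pulse_duration
  if (is.null(ccfg$w_ei))
    ccfg$w_ei <- calibrate_spans(ccfg, dt, kick_dur)
  coupling <- calibrate_coupling(ccfg, dt, kick_dur, config$rate_threshold)
  if (is.null(learner))
    learner <- drift_learner(w = config$initial_w, alpha = config$alpha,
                             sigma = 0, dt = dt,
                             phi_ceiling = 1, w_floor = config$w_floor)

  k <- as.integer(ccfg$n_replicates)
  exc <- make_excitatory_params(); inh <- make_inhibitory_params()
  ## cell bookkeeping: vectors over all spiking cells
  pops <- list(
    input = list(model = "spiking-excitatory", size = k),
    absolute_timing_pyr = list(model = "spiking-excitatory", size = 5L * k),
    absolute_timing_inh = list(model = "spiking-inhibitory", size = 5L * k),
    relative_timing = list(model = "rate", size = 1L),
    time_accumulator = list(model = "spiking-excitatory", size = k),
    swing_pyr = list(model = "spiking-excitatory", size = k),
    swing_inh = list(model = "spiking-inhibitory", size = k),
    motor = list(model = "spiking-excitatory", size = k),
    resetting = list(model = "spiking-inhibitory", size = k))
  spk_names <- setdiff(names(pops), "relative_timing")
  sizes <- vapply(pops[spk_names], `[[`, integer(1), "size")
  n_cells <- sum(sizes)
  idx <- split(seq_len(n_cells), rep(seq_along(sizes), sizes))
  names(idx) <- spk_names
  is_inh <- rep(vapply(pops[spk_names], function(p)
    p$model == "spiking-inhibitory", logical(1)), sizes)
  pa <- ifelse(is_inh, inh$a, exc$a); pb <- ifelse(is_inh, inh$b, exc$b)
  pc <- ifelse(is_inh, inh$c, exc$c); pd <- ifelse(is_inh, inh$d, exc$d)
  rest <- resting_state(exc)

  e <- new.env(parent = emptyenv())
  e$config <- config; e$ccfg <- ccfg; e$dt <- dt
  e$kick_dur <- kick_dur
  e$pops <- pops; e$idx <- idx; e$k <- k
  e$group_of_pyr <- rep(seq_len(5L), each = k)
  e$group_of_inh <- rep(seq_len(5L), each = k)
  e$pa <- pa; e$pb <- pb; e$pc <- pc; e$pd <- pd
  e$v <- rep(rest$v, n_cells); e$u <- pb * rest$v
  e$rest_v <- rest$v
  e$pulses <- numeric(0)
  e$theta <- config$rate_threshold
  e$gamma_m <- ccfg$gamma_m
  e$coupling <- coupling
  e$learner <- learner
  e$W_plastic <- drift_to_weight(learner$w, coupling)
  ## decay factors
  e$dec_e <- exp(-dt / ccfg$tau_e); e$dec_q <- exp(-dt / ccfg$tau_q)
  e$dec_i <- exp(-dt / ccfg$tau_i); e$dec_p <- exp(-dt / ccfg$tau_p)
  e$dec_acc <- exp(-dt / ccfg$tau_acc_syn)
  e$dec_sw <- exp(-dt / ccfg$tau_swing_syn)
  e$dec_rsw <- exp(-dt / ccfg$tau_reset_swing)
  e$dec_shunt <- exp(-dt / ccfg$tau_reset)
  ## dynamic traces
  e$tr_e <- numeric(5L); e$tr_q <- numeric(5L); e$tr_i <- numeric(5L)
  e$P <- 0; e$A <- 0
  e$s_acc <- 0; e$s_sw <- 0; e$R_swing <- 0
  e$V_rel <- 0
  ## event state
  e$t <- 0
  e$phase <- "sync"
  e$kick_until <- -Inf
  e$mp_from <- Inf; e$mp_until <- -Inf; e$mp_origin <- NA_character_
  e$rp_from <- Inf; e$rp_until <- -Inf
  e$reset_window_until <- -Inf
  e$interval_start <- 0
  e$last_tap <- -Inf; e$last_reset_event <- -Inf
  e$crossed <- FALSE; e$crossing_time <- NA_real_
  e$tap_armed <- FALSE     # a threshold-driven motor pulse is pending
  e$n_stimuli_seen <- 0L; e$n_cont_taps <- 0L
  e$gain <- 1
  e$gain_draws <- numeric(0); e$gain_ptr <- 0L
  e$eps_draws <- numeric(0); e$eps_ptr <- 0L
  e$sigma_scale <- if (isTRUE(config$noise)) config$sigma_scale else 0
  e$gain_cv <- if (isTRUE(config$noise)) config$gain_cv else 0
  ## logs (grow-able, pre-sized)
  cap0 <- 4096L
  e$log_sp_t <- numeric(cap0); e$log_sp_cell <- integer(cap0); e$log_sp_n <- 0L
  e$log_vrel <- numeric(cap0); e$log_vrel_t <- numeric(cap0); e$log_vrel_n <- 0L
  e$taps <- list(time = numeric(0), phase = character(0),
                 trigger = character(0))
  e$stimuli <- numeric(0)
  e$weight_log <- list(update_index = integer(0), w_before = numeric(0),
                       w_after = numeric(0), branch = character(0),
                       time = numeric(0))
  class(e) <- "circuit_state"
  e
}


#' @export
print.circuit_state <- function(x, ...) {
  cat(sprintf(
    paste0("timing circuit at t=%g ms (%s phase): %d spiking cells + 1 rate",
           " cell\n  relative-timing activity %.2f Hz (threshold %g Hz),",
           " drift rate %.5g /ms\n  %d spikes, %d taps, %d stimuli logged\n"),
    x$t, x$phase, length(x$v), x$V_rel, x$theta, x$learner$w,
    x$log_sp_n, length(x$taps$time), length(x$stimuli)))
  invisible(x)
}

log_spike <- function(e, t, cells) {
  n_new <- length(cells)
  if (e$log_sp_n + n_new > length(e$log_sp_t)) {
    newcap <- 2L * (length(e$log_sp_t) + n_new)
    e$log_sp_t <- c(e$log_sp_t, numeric(newcap))
    e$log_sp_cell <- c(e$log_sp_cell, integer(newcap))
  }
  at <- e$log_sp_n + seq_len(n_new)
  e$log_sp_t[at] <- t
  e$log_sp_cell[at] <- cells
  e$log_sp_n <- e$log_sp_n + n_new
}

next_gain <- function(e) {
  if (e$gain_cv <= 0) return(1)
  e$gain_ptr <- e$gain_ptr + 1L
  if (e$gain_ptr > length(e$gain_draws))
    stop("internal error: exhausted pre-drawn interval gains")
  1 + e$gain_cv * e$gain_draws[e$gain_ptr]
}

next_eps <- function(e) {
  if (e$sigma_scale <= 0) return(0)
  e$eps_ptr <- e$eps_ptr + 1L
  if (e$eps_ptr > length(e$eps_draws))
    stop("internal error: exhausted pre-drawn accumulation noise")
  e$sigma_scale * e$learner$w * sqrt(e$dt) * e$eps_draws[e$eps_ptr]
}

## Restart the absolute-timing microcircuits: the synchronizing volley
## resets membrane state and internal traces of (by construction,
## quiescent) groups, then drives them for one pulse duration.
sync_pulse <- function(e, t) {
  ip <- e$idx$absolute_timing_pyr; ii <- e$idx$absolute_timing_inh
  e$v[ip] <- e$rest_v; e$u[ip] <- 0.2 * e$rest_v
  e$v[ii] <- e$rest_v; e$u[ii] <- 0.2 * e$rest_v
  e$tr_e[] <- 0; e$tr_q[] <- 0; e$tr_i[] <- 0
  e$kick_until <- t + e$kick_dur
  e$pulses <- c(e$pulses, t)
}

#' Deliver a metronome stimulus onset
#'
#' Logs the stimulus, commits the pending drift-rate update when at least
#' one inter-stimulus interval has elapsed (the first stimulus carries no
#' timing information), restarts the absolute-timing groups, and
#' schedules the stimulus-driven motor pulse.
#'
#' @param circuit A `circuit_state`.
#' @return The circuit, invisibly.
#' @keywords internal
stimulus_onset <- function(circuit) {
  e <- circuit; t <- e$t
  e$stimuli <- c(e$stimuli, t)
  if (e$n_stimuli_seen >= 1L) commit_circuit_update(e, t)
  e$n_stimuli_seen <- e$n_stimuli_seen + 1L
  ## input-driven tap: conduction delay then a brief suprathreshold pulse;
  ## the absolute-timing restart is aligned to the tap itself (motor
  ## efference), identically in both phases
  e$mp_from <- t + e$ccfg$motor_latency
  e$mp_until <- e$mp_from + e$ccfg$motor_pulse_duration
  e$mp_origin <- "stimulus-driven"
  invisible(e)
}

commit_circuit_update <- function(e, t) {
  lrn <- e$learner
  phi <- min(e$V_rel / e$theta, 1)
  if (e$crossed) {
    delta <- lrn$pending_delta
    branch <- "late"
  } else {
    delta <- early_reward_delta(lrn$w, phi)
    branch <- "early"
  }
  w_before <- lrn$w
  lrn <- commit_update(lrn, delta)
  e$learner <- lrn
  e$W_plastic <- drift_to_weight(lrn$w, e$coupling)
  wl <- e$weight_log
  n <- length(wl$update_index) + 1L
  wl$update_index[n] <- n
  wl$w_before[n] <- w_before
  wl$w_after[n] <- lrn$w
  wl$branch[n] <- branch
  wl$time[n] <- t
  e$weight_log <- wl
  invisible(e)
}

#' Advance the whole circuit one integration step
#'
#' Injects stimulus current into the input cells when `stimulus_on`,
#' advances every spiking cell one Izhikevich Euler step and the
#' relative-timing cell one rate step, updates all synaptic traces,
#' detects threshold crossings and taps, and applies resets when the
#' resetting cell fires. Tap and reset handling follow the event rules
#' described in the vignette.
#'
#' @param circuit A `circuit_state`.
#' @param learner Optionally replace the circuit's learner before the
#'   step (the learner otherwise lives inside the circuit state).
#' @param stimulus_on Is the metronome stimulus currently driving the
#'   input cells?
#' @return A list of events this step:
#'   `spiked` (integer cell indices), `tap` (tap time or `NULL`),
#'   `crossing` (threshold-crossing time or `NULL`).
#' @export
circuit_step <- function(circuit, learner = NULL, stimulus_on = FALSE) {
  e <- circuit
  if (!is.null(learner)) {
    e$learner <- learner
    e$W_plastic <- drift_to_weight(learner$w, e$coupling)
  }
  ccfg <- e$ccfg; dt <- e$dt
  t <- e$t + dt
  e$t <- t
  idx <- e$idx; k <- e$k

  ## --- currents
  n_cells <- length(e$v)
  I <- numeric(n_cells)
  if (stimulus_on) I[idx$input] <- ccfg$stimulus_amplitude
  kick_on <- t <= e$kick_until
  Ig <- pmin(ccfg$w_ee * e$tr_e, ccfg$latch_caps) - ccfg$w_ie * e$tr_i +
    if (kick_on) ccfg$kick_amplitude else 0
  I[idx$absolute_timing_pyr] <- Ig[e$group_of_pyr]
  I[idx$absolute_timing_inh] <- (e$ccfg$w_ei * e$tr_q)[e$group_of_inh]
  I[idx$time_accumulator] <- ccfg$w_acc * e$A
  I[idx$swing_pyr] <- ccfg$w_acc_swing * e$s_acc
  I[idx$swing_inh] <- ccfg$w_swing * e$s_sw - ccfg$w_reset_swing * e$R_swing
  if (t >= e$mp_from && t <= e$mp_until) I[idx$motor] <- ccfg$pulse_amplitude
  if (t >= e$rp_from && t <= e$rp_until) I[idx$resetting] <- ccfg$pulse_amplitude

  ## --- spiking update (vectorized forward Euler, simultaneous derivatives)
  v <- e$v; u <- e$u
  v_new <- v + dt * (0.04 * v * v + 5 * v + 140 - u + I)
  u_new <- u + dt * e$pa * (e$pb * v - u)
  if (anyNA(v_new) || any(!is.finite(v_new))) {
    bad <- which(!is.finite(v_new))[1]
    stop("numerical blow-up in population containing cell ", bad,
         " (reduce dt or input)")
  }
  spiked <- v_new >= 30
  v_new[spiked] <- e$pc[spiked]
  u_new[spiked] <- u_new[spiked] + e$pd[spiked]
  e$v <- v_new; e$u <- u_new
  sp_cells <- which(spiked)
  if (length(sp_cells)) log_spike(e, t, sp_cells)

  ## --- trace updates
  sp_pyr_g <- tabulate(e$group_of_pyr[spiked[idx$absolute_timing_pyr]],
                       nbins = 5L) / k
  sp_inh_g <- tabulate(e$group_of_inh[spiked[idx$absolute_timing_inh]],
                       nbins = 5L) / k
  e$tr_e <- e$tr_e * e$dec_e + sp_pyr_g
  e$tr_q <- e$tr_q * e$dec_q + sp_pyr_g
  e$tr_i <- e$tr_i * e$dec_i + sp_inh_g
  in_reset <- t <= e$reset_window_until
  if (in_reset) {
    e$P <- e$P * e$dec_shunt
    e$A <- e$A * e$dec_shunt
  } else {
    e$P <- e$P * e$dec_p + sum(sp_pyr_g)
    e$A <- e$A + e$P * dt
  }
  e$s_acc <- e$s_acc * e$dec_acc + sum(spiked[idx$time_accumulator]) / k
  e$s_sw <- e$s_sw * e$dec_sw + sum(spiked[idx$swing_pyr]) / k
  e$R_swing <- e$R_swing * e$dec_rsw + sum(spiked[idx$resetting]) / k

  ## --- relative-timing rate cell (drift realized through the plastic bank)
  if (in_reset) {
    e$V_rel <- e$V_rel * e$dec_shunt
  } else {
    eps <- next_eps(e)
    drive <- e$W_plastic * e$gain * e$P
    ## self-connection L_ii = 1 cancels the leak: pure neural integrator
    e$V_rel <- max(0, e$V_rel + dt / e$gamma_m * drive + e$theta * eps)
  }

  if (e$log_vrel_n >= length(e$log_vrel)) {
    e$log_vrel <- c(e$log_vrel, numeric(length(e$log_vrel)))
    e$log_vrel_t <- c(e$log_vrel_t, numeric(length(e$log_vrel_t)))
  }
  e$log_vrel_n <- e$log_vrel_n + 1L
  e$log_vrel[e$log_vrel_n] <- e$V_rel
  e$log_vrel_t[e$log_vrel_n] <- t

  ## --- threshold crossing and the late-reward decrement
  crossing <- NULL
  if (!in_reset && !e$crossed && e$V_rel >= e$theta) {
    e$crossed <- TRUE
    e$crossing_time <- t
    crossing <- t
  } else if (e$crossed && e$phase == "sync") {
    e$learner <- late_decrement_step(e$learner)
  }
  ## accident-preventing gate: relative->motor transmits only in the
  ## continuation phase and only once the interval is old enough
  if (e$phase == "continuation" && e$crossed && !e$tap_armed &&
      (t - e$interval_start) >= ccfg$gate_min) {
    e$tap_armed <- TRUE
    e$mp_from <- t + ccfg$motor_latency
    e$mp_until <- e$mp_from + ccfg$motor_pulse_duration
    e$mp_origin <- "threshold-driven"
  }

  ## --- taps (motor spikes coalesced by the refractory window)
  tap <- NULL
  if (any(spiked[idx$motor]) && (t - e$last_tap) > ccfg$tap_refractory) {
    e$last_tap <- t
    tap <- t
    e$taps$time <- c(e$taps$time, t)
    e$taps$phase <- c(e$taps$phase, e$phase)
    e$taps$trigger <- c(e$taps$trigger, e$mp_origin)
    e$rp_from <- t + ccfg$reset_pulse_delay
    e$rp_until <- e$rp_from + ccfg$reset_pulse_duration
    sync_pulse(e, t)   # motor efference is the synchronizing signal
    if (e$phase == "continuation") {
      e$n_cont_taps <- e$n_cont_taps + 1L
      if (isTRUE(e$config$learn_in_continuation) && e$n_cont_taps >= 1L)
        commit_circuit_update(e, t)
    }
  }

  ## --- resetting-cell firing: restart the interval machinery
  if (any(spiked[idx$resetting]) &&
      (t - e$last_reset_event) > ccfg$tap_refractory / 2) {
    e$last_reset_event <- t
    e$reset_window_until <- t + ccfg$reset_window
    e$interval_start <- t
    e$crossed <- FALSE
    e$crossing_time <- NA_real_
    e$tap_armed <- FALSE
    e$gain <- next_gain(e)
    lrn <- e$learner; lrn$phi <- 0; e$learner <- lrn
  }

  list(spiked = sp_cells, tap = tap, crossing = crossing)
}

#' Apply the resetting-cell inhibition directly
#'
#' Opens a shunting window during which the relative-timing activity and
#' the integrating absolute-to-accumulator drive decay rapidly toward
#' zero, gives the swing interneuron its inhibitory kick, and zeroes the
#' learner's semaphore. Normally triggered by resetting-cell spikes
#' inside [circuit_step()]; exposed for direct use and testing.
#'
#' @param circuit A `circuit_state`.
#' @return The circuit, invisibly.
#' @export
apply_reset <- function(circuit) {
  e <- circuit
  e$reset_window_until <- e$t + e$ccfg$reset_window
  e$interval_start <- e$t
  e$crossed <- FALSE
  e$crossing_time <- NA_real_
  e$tap_armed <- FALSE
  e$R_swing <- e$R_swing + 2   # the inhibitory volley onto the swing cell
  e$gain <- next_gain(e)
  lrn <- e$learner; lrn$phi <- 0; e$learner <- lrn
  invisible(e)
}

#' Coalesce motor spikes into tap events
#'
#' A tap is the first motor spike after the gate opens; subsequent motor
#' spikes within the refractory window belong to the same tap.
#'
#' @param motor_spike_times Sorted numeric vector of motor spike times (ms).
#' @param refractory Coalescing window (ms).
#' @return Numeric vector of tap times.
#' @export
detect_tap <- function(motor_spike_times, refractory = 100) {
  if (!length(motor_spike_times)) return(numeric(0))
  ts <- sort(motor_spike_times)
  taps <- ts[1]
  for (s in ts[-1]) if (s - taps[length(taps)] > refractory) taps <- c(taps, s)
  taps
}

#' Spike raster of a circuit run
#'
#' @param circuit A `circuit_state`.
#' @return A data frame with columns `time_ms`, `population`,
#'   `neuron_index` (index within the population).
#' @export
spike_raster <- function(circuit) {
  e <- circuit
  n <- e$log_sp_n
  if (n == 0L)
    return(data.frame(time_ms = numeric(0), population = character(0),
                      neuron_index = integer(0)))
  cells <- e$log_sp_cell[seq_len(n)]
  pop <- character(n); nidx <- integer(n)
  for (nm in names(e$idx)) {
    sel <- cells %in% e$idx[[nm]]
    pop[sel] <- nm
    nidx[sel] <- match(cells[sel], e$idx[[nm]])
  }
  data.frame(time_ms = e$log_sp_t[seq_len(n)], population = pop,
             neuron_index = nidx)
}
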