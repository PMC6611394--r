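## Time-adaptive drift-diffusion learner (TDDM): a noisy accumulator
## ("semaphore") phi that rises with drift rate w, plus the two weight
## correction cases (reward before expectation / expectation before reward)
## and the mapping from drift rate to synaptic weight scale.

#' Create a time-adaptive drift-diffusion learner
#'
#' The learner accumulates a semaphore `phi` at drift rate `w` per ms.
#' When the timed event ("reward") arrives before `phi` reaches its
#' ceiling, the drift rate is corrected upward by
#' `delta_w = w (1 - phi) phi`; when `phi` reaches the ceiling first, a
#' decrement `delta_w <- delta_w - (w + delta_w)^2 dt` accrues every step
#' until the reward, and the committed update is
#' `w <- w + alpha delta_w`. The fixed point of this rule is
#' `w = 1 / T` for a reward period of `T` ms.
#'
#' @param w Initial drift rate (semaphore units per ms, > 0).
#' @param alpha Learning rate in (0, 1].
#' @param sigma SD of the per-step Gaussian accumulation noise
#'   (semaphore units; 0 disables noise).
#' @param dt Accumulation step (ms).
#' @param phi_ceiling Semaphore level at which the expectation fires
#'   (1 in the pure model; the relative-timing rate threshold when the
#'   learner is coupled to the circuit, where `phi` is defined as
#'   activity / threshold so the printed update rules keep ceiling 1).
#' @param w_floor Smallest admissible drift rate; commits are floored here.
#' @return An object of class `drift_learner`.
#' @export
drift_learner <- function(w = 1 / 500, alpha = 0.1, sigma = 0, dt = 1,
                          phi_ceiling = 1, w_floor = 1e-6) {
  stopifnot(is.numeric(w), length(w) == 1L, is.finite(w))
  if (w <= 0) stop("initial drift rate 'w' must be positive")
  if (!is.finite(alpha) || alpha <= 0 || alpha > 1)
    stop("'alpha' must lie in (0, 1]")
  if (!is.finite(sigma) || sigma < 0) stop("'sigma' must be >= 0")
  if (!is.finite(dt) || dt <= 0) stop("'dt' must be positive")
  structure(list(w = w, phi = 0, pending_delta = 0, alpha = alpha,
                 sigma = sigma, dt = dt, phi_ceiling = phi_ceiling,
                 w_floor = w_floor, trial_index = 0L),
            class = "drift_learner")
}

#' @export
print.drift_learner <- function(x, ...) {
  cat(sprintf(
    paste0("drift-diffusion learner: w=%.6g /ms (interval %.4g ms), phi=%.4g,",
           " pending=%.3g, alpha=%g, sigma=%g, n=%d\n"),
    x$w, 1 / x$w * x$phi_ceiling, x$phi, x$pending_delta, x$alpha, x$sigma,
    x$trial_index))
  invisible(x)
}

#' One accumulation step of the semaphore
#'
#' `phi <- phi + w dt + eps`, with `eps ~ N(0, sigma^2)` (0 when
#' `sigma = 0`), floored at 0.
#'
#' @param learner A `drift_learner`.
#' @param rng_draw Optional pre-drawn standard-normal deviate; when `NULL`
#'   and `sigma > 0` one is drawn from the current RNG stream.
#' @return The updated learner.
#' @export
accumulate <- function(learner, rng_draw = NULL) {
  eps <- 0
  if (learner$sigma > 0) {
    z <- if (is.null(rng_draw)) stats::rnorm(1) else rng_draw
    eps <- learner$sigma * z
  }
  learner$phi <- max(0, learner$phi + learner$w * learner$dt + eps)
  learner
}

#' Drift-rate correction when the reward arrives early
#'
#' Reward before expectation: the accumulator was too slow, and the
#' correction `delta_w = w (1 - phi) phi` (with `phi` the normalized
#' semaphore value at the reward) increases the drift rate. It vanishes
#' both at `phi = 1` (reward exactly on time) and at `phi = 0`.
#'
#' @param w Current drift rate.
#' @param phi_at_reward Normalized semaphore value in `[0, 1]` at the
#'   moment of reward.
#' @return The (non-negative) drift-rate correction.
#' @export
early_reward_delta <- function(w, phi_at_reward) {
  if (!is.finite(phi_at_reward) || phi_at_reward < 0 || phi_at_reward > 1)
    stop("'phi_at_reward' must lie in [0, 1] (normalize by the ceiling)")
  w * (1 - phi_at_reward) * phi_at_reward
}

#' One decrement step while the expectation waits for a late reward
#'
#' Expectation before reward: from the step after `phi` reaches its
#' ceiling until the reward arrives, the pending correction follows
#' `delta_w <- delta_w - (w + delta_w)^2 dt`. This is the Euler form of
#' `x' = -x^2` for `x = w + delta_w`, so the implied corrected rate decays
#' monotonically toward the reciprocal of the elapsed overshoot time and
#' never crosses zero for `x dt < 1`.
#'
#' @param learner A `drift_learner`.
#' @return The updated learner (only `pending_delta` changes).
#' @export
late_decrement_step <- function(learner) {
  x <- learner$w + learner$pending_delta
  learner$pending_delta <- learner$pending_delta - x * x * learner$dt
  learner
}

#' Commit a drift-rate update at a reward
#'
#' `w <- w + alpha delta_w`; the semaphore and any pending decrement are
#' cleared and the trial counter advances. A commit that would drive `w`
#' non-positive is floored at `w_floor` with a warning (a non-positive
#' drift rate cannot time anything).
#'
#' @param learner A `drift_learner`.
#' @param delta_w Drift-rate correction (either the early-reward value or
#'   the accumulated late decrement).
#' @return The updated learner.
#' @export
commit_update <- function(learner, delta_w) {
  w_new <- learner$w + learner$alpha * delta_w
  if (w_new <= learner$w_floor) {
    warning("drift-rate update floored at ", learner$w_floor)
    w_new <- learner$w_floor
  }
  learner$w <- w_new
  learner$pending_delta <- 0
  learner$phi <- 0
  learner$trial_index <- learner$trial_index + 1L
  learner
}

#' Map a drift rate onto the plastic synaptic weight scale
#'
#' The relative-timing cell is a self-excitatory rate integrator whose
#' activity obeys `gamma_m dV/dt = W sum_g s_g(t)`, with `s_g` the
#' synaptic traces of the absolute-timing groups. Requiring the activity
#' slope to realize the drift `theta * w` (in Hz per ms, `theta` the
#' firing-rate threshold standing in for the semaphore ceiling) against
#' the calibrated mean total trace `drive_scale` gives the linear map
#' `W(w) = gamma_m * theta * w / drive_scale`: zero at zero drift and
#' monotone increasing.
#'
#' @param w Drift rate (per ms, >= 0).
#' @param coupling A list with `gamma_m` (ms), `threshold` (Hz) and
#'   `drive_scale` (mean total absolute-timing synaptic trace over one
#'   calibration interval), e.g. from [calibrate_coupling()].
#' @return The scalar weight applied to the plastic projections.
#' @export
drift_to_weight <- function(w, coupling) {
  stopifnot(is.numeric(w), length(w) == 1L, is.finite(w), w >= 0)
  stopifnot(is.list(coupling),
            all(c("gamma_m", "threshold", "drive_scale") %in% names(coupling)))
  if (coupling$drive_scale <= 0) stop("'drive_scale' must be positive")
  coupling$gamma_m * coupling$threshold * w / coupling$drive_scale
}

#' Run the pure learner through periodic reward cycles
#'
#' Repeatedly accumulates the semaphore with reward every `period` ms and
#' commits the appropriate correction at each reward: the early-reward
#' product rule if the ceiling was not reached, otherwise the late
#' decrement accumulated from the ceiling crossing to the reward. This is
#' the abstract (circuit-free) learning loop; its fixed point is
#' `w = phi_ceiling / period`.
#'
#' @param learner A `drift_learner`.
#' @param period Reward period (ms).
#' @param n_cycles Number of reward cycles to run.
#' @return A list with `learner` (final state) and `w_trajectory`
#'   (drift rate after each commit).
#' @export
run_reward_cycles <- function(learner, period, n_cycles) {
  stopifnot(period > 0, n_cycles >= 1)
  n_steps <- round(period / learner$dt)
  w_traj <- numeric(n_cycles)
  for (cyc in seq_len(n_cycles)) {
    crossed <- FALSE
    draws <- if (learner$sigma > 0) stats::rnorm(n_steps) else NULL
    for (k in seq_len(n_steps)) {
      learner <- accumulate(learner, rng_draw = draws[k])
      if (!crossed && learner$phi >= learner$phi_ceiling) {
        crossed <- TRUE
      } else if (crossed) {
        learner <- late_decrement_step(learner)
      }
    }
    delta <- if (crossed) {
      learner$pending_delta
    } else {
      early_reward_delta(learner$w,
                         min(learner$phi / learner$phi_ceiling, 1))
    }
    learner <- commit_update(learner, delta)
    w_traj[cyc] <- learner$w
  }
  list(learner = learner, w_trajectory = w_traj)
}
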