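## Single-neuron dynamics: two-variable quadratic integrate-and-reset
## (Izhikevich) spiking cells and a rate-based activity cell, both advanced
## with a fixed-step forward-Euler integrator.

#' Izhikevich neuron parameters
#'
#' Bundle the `(a, b, c, d)` parameter quadruple of the two-variable
#' quadratic spiking-neuron model together with the spike-detection level.
#' `a` sets the recovery time scale, `b` the sensitivity of the recovery
#' variable to the membrane potential, `c` the post-spike reset potential
#' (mV) and `d` the post-spike increment of the recovery variable.
#'
#' @param a Recovery time scale (dimensionless, > 0).
#' @param b Recovery sensitivity (dimensionless).
#' @param c Post-spike reset potential (mV).
#' @param d Post-spike recovery increment (dimensionless).
#' @param spike_cutoff Membrane potential (mV) at which a spike is detected
#'   and the reset applied. 30 mV in the standard formulation.
#' @return An object of class `izhikevich_params`.
#' @seealso [make_excitatory_params()], [make_inhibitory_params()]
#' @export
izhikevich_params <- function(a, b, c, d, spike_cutoff = 30) {
  stopifnot(is.numeric(a), is.numeric(b), is.numeric(c), is.numeric(d),
            length(a) == 1L, length(b) == 1L, length(c) == 1L, length(d) == 1L)
  if (!is.finite(a) || a <= 0) stop("'a' must be a positive finite number")
  if (!all(is.finite(c(b, c, d, spike_cutoff))))
    stop("Izhikevich parameters must be finite")
  structure(list(a = a, b = b, c = c, d = d, spike_cutoff = spike_cutoff),
            class = "izhikevich_params")
}

#' @export
print.izhikevich_params <- function(x, ...) {
  cat(sprintf(
    "Izhikevich parameters: a=%g b=%g c=%g d=%g (spike cutoff %g mV)\n",
    x$a, x$b, x$c, x$d, x$spike_cutoff))
  invisible(x)
}

#' Parameter presets for regular-spiking and fast-spiking cells
#'
#' `make_excitatory_params()` returns the canonical regular-spiking
#' (pyramidal) parameter set `a=0.02, b=0.2, c=-65, d=8`;
#' `make_inhibitory_params()` the fast-spiking (interneuron) set
#' `a=0.1, b=0.2, c=-65, d=2`. Under equal sustained drive the inhibitory
#' preset fires substantially faster than the excitatory one.
#'
#' @return An `izhikevich_params` object.
#' @export
make_excitatory_params <- function() {
  izhikevich_params(a = 0.02, b = 0.2, c = -65, d = 8, spike_cutoff = 30)
}

#' @rdname make_excitatory_params
#' @export
make_inhibitory_params <- function() {
  izhikevich_params(a = 0.1, b = 0.2, c = -65, d = 2, spike_cutoff = 30)
}

#' Izhikevich neuron state
#'
#' @param v Membrane potential (mV).
#' @param u Membrane recovery variable (dimensionless).
#' @return An object of class `izhikevich_state`.
#' @export
izhikevich_state <- function(v, u) {
  if (!is.finite(v) || !is.finite(u))
    stop("neuron state must be finite")
  structure(list(v = v, u = u), class = "izhikevich_state")
}

#' Resting state of an Izhikevich neuron
#'
#' Returns the stable zero-input fixed point of the model, i.e. the more
#' negative root `v*` of `0.04 v^2 + (5 - b) v + 140 = 0` with
#' `u* = b v*`. For both built-in presets (`b = 0.2`) this is
#' `(v, u) = (-70, -14)`.
#'
#' @param params An `izhikevich_params` object.
#' @return An `izhikevich_state` at the resting fixed point.
#' @export
resting_state <- function(params) {
  stopifnot(inherits(params, "izhikevich_params"))
  disc <- (5 - params$b)^2 - 4 * 0.04 * 140
  if (disc < 0)
    stop("no real resting potential for these parameters (b = ", params$b,
         "); the zero-input nullclines do not intersect")
  v <- (-(5 - params$b) - sqrt(disc)) / (2 * 0.04)
  izhikevich_state(v = v, u = params$b * v)
}

#' Advance an Izhikevich neuron one Euler step
#'
#' Performs one forward-Euler step of
#' `dv/dt = 0.04 v^2 + 5 v + 140 - u + I` and `du/dt = a (b v - u)`
#' (both derivatives evaluated at the pre-step state), then applies the
#' spike rule: if the advanced `v` reaches the spike cutoff, the step
#' reports a spike and resets `v <- c`, `u <- u + d`.
#'
#' @param state An `izhikevich_state`.
#' @param params An `izhikevich_params`.
#' @param input_current Input current `I` (dimensionless model units).
#' @param dt Step size (ms, > 0).
#' @return A list with elements `state` (the advanced `izhikevich_state`)
#'   and `spiked` (logical).
#' @export
step_izhikevich <- function(state, params, input_current, dt) {
  stopifnot(inherits(state, "izhikevich_state"),
            inherits(params, "izhikevich_params"))
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("'dt' must be a positive number")
  if (!is.finite(input_current))
    stop("non-finite input current: numerical blow-up upstream ",
         "(reduce dt or the input)")
  v <- state$v; u <- state$u
  if (!is.finite(v) || !is.finite(u))
    stop("non-finite neuron state: numerical blow-up (reduce dt or input)")
  dv <- 0.04 * v * v + 5 * v + 140 - u + input_current
  du <- params$a * (params$b * v - u)
  v <- v + dt * dv
  u <- u + dt * du
  if (!is.finite(v) || !is.finite(u))
    stop("integration diverged: non-finite state after step ",
         "(reduce dt or the input current)")
  spiked <- v >= params$spike_cutoff
  if (spiked) {
    v <- params$c
    u <- u + params$d
  }
  list(state = izhikevich_state(v, u), spiked = spiked)
}

#' Rate-based activity neuron
#'
#' State of a cell whose firing rate is approximated by a non-negative
#' activity variable `V` obeying
#' `gamma_m dV/dt = -V + I_ext + sum_j L_ij V_j`.
#'
#' @param activity Initial activity (Hz-equivalent, >= 0).
#' @param gamma_m Intrinsic time constant (ms, > 0).
#' @return An object of class `rate_neuron_state`.
#' @export
rate_neuron_state <- function(activity = 0, gamma_m = 50) {
  stopifnot(is.numeric(activity), is.numeric(gamma_m))
  if (!is.finite(gamma_m) || gamma_m <= 0) stop("'gamma_m' must be positive")
  if (!is.finite(activity) || activity < 0)
    stop("'activity' must be a non-negative finite number")
  structure(list(activity = activity, gamma_m = gamma_m),
            class = "rate_neuron_state")
}

#' Advance a rate neuron one Euler step
#'
#' One forward-Euler step of the linear activity equation, followed by
#' clipping at zero (a firing rate cannot be negative).
#'
#' @param state A `rate_neuron_state`.
#' @param external_input External feed-forward drive `I_ext`.
#' @param weighted_presynaptic_sum The recurrent/afferent drive
#'   `sum_j L_ij V_j`.
#' @param dt Step size (ms, > 0).
#' @return The advanced `rate_neuron_state`.
#' @export
step_rate <- function(state, external_input, weighted_presynaptic_sum, dt) {
  stopifnot(inherits(state, "rate_neuron_state"))
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("'dt' must be a positive number")
  if (!is.finite(external_input) || !is.finite(weighted_presynaptic_sum))
    stop("non-finite input to rate neuron")
  v <- state$activity +
    dt / state$gamma_m *
      (-state$activity + external_input + weighted_presynaptic_sum)
  if (!is.finite(v)) stop("rate-neuron integration diverged")
  state$activity <- max(v, 0)
  state
}
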