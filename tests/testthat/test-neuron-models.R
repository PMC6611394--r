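test_that("parameter presets return the canonical values and are constant", {
  exc <- make_excitatory_params()
  inh <- make_inhibitory_params()
  expect_equal(unclass(exc)[c("a", "b", "c", "d", "spike_cutoff")],
               list(a = 0.02, b = 0.2, c = -65, d = 8, spike_cutoff = 30))
  expect_equal(unclass(inh)[c("a", "b", "c", "d", "spike_cutoff")],
               list(a = 0.1, b = 0.2, c = -65, d = 2, spike_cutoff = 30))
  expect_identical(exc$c, inh$c)
  expect_gt(inh$a, exc$a)
  expect_identical(exc, make_excitatory_params())
  expect_error(izhikevich_params(a = -1, b = 0.2, c = -65, d = 8), "positive")
})

test_that("the resting state is the zero-input fixed point", {
  for (p in list(make_excitatory_params(), make_inhibitory_params())) {
    st <- resting_state(p)
    expect_equal(st$v, -70)
    expect_equal(st$u, -14)
    stepped <- step_izhikevich(st, p, input_current = 0, dt = 0.7)
    expect_equal(stepped$state$v, st$v)
    expect_equal(stepped$state$u, st$u)
    expect_false(stepped$spiked)
  }
  ## no real root when b pushes the nullclines apart ((5-b)^2 < 22.4)
  expect_error(resting_state(izhikevich_params(0.02, 5, -65, 8)), "no real")
})

test_that("the spike rule resets v to c and increments u by d", {
  p <- make_excitatory_params()
  st <- izhikevich_state(v = 29, u = -14)
  r <- step_izhikevich(st, p, input_current = 10, dt = 1)
  expect_true(r$spiked)
  expect_equal(r$state$v, p$c)
  ## u after the reset = (euler-advanced u) + d
  u_adv <- -14 + 1 * p$a * (p$b * 29 - (-14))
  expect_equal(r$state$u, u_adv + p$d)
})

test_that("reset conservation holds along a driven trajectory", {
  p <- make_inhibitory_params()
  st <- resting_state(p)
  for (k in 1:400) {
    u_prev <- st$u; v_prev <- st$v
    r <- step_izhikevich(st, p, input_current = 8, dt = 1)
    if (r$spiked) {
      expect_identical(r$state$v, p$c)
      u_adv <- u_prev + 1 * p$a * (p$b * v_prev - u_prev)
      expect_equal(r$state$u, u_adv + p$d)
    }
    st <- r$state
  }
})

test_that("stepping matches the independent reference integration exactly", {
  cases <- list(
    list(p = make_excitatory_params(), I = 10, dt = 0.5, t = 1000),
    list(p = make_excitatory_params(), I = 6,  dt = 1,   t = 1500),
    list(p = make_inhibitory_params(), I = 10, dt = 0.5, t = 1000))
  for (cs in cases) {
    ref <- oracle_izhikevich(cs$p$a, cs$p$b, cs$p$c, cs$p$d, cs$I, cs$dt, cs$t)
    got <- package_spike_train(cs$p, cs$I, cs$dt, cs$t)
    expect_identical(got, ref)
    expect_gt(length(ref), 0)
  }
  ## time-varying input
  set.seed(1)
  Ivec <- runif(2000, 0, 12)
  p <- make_excitatory_params()
  expect_identical(package_spike_train(p, Ivec, 0.5, 1000),
                   oracle_izhikevich(p$a, p$b, p$c, p$d, Ivec, 0.5, 1000))
})

test_that("the fast-spiking preset out-fires the regular-spiking preset", {
  for (I in c(6, 10, 15)) {
    n_exc <- length(package_spike_train(make_excitatory_params(), I, 1, 2000))
    n_inh <- length(package_spike_train(make_inhibitory_params(), I, 1, 2000))
    expect_gt(n_inh, n_exc)
  }
})

test_that("non-finite states and inputs raise blow-up errors", {
  p <- make_excitatory_params()
  expect_error(step_izhikevich(resting_state(p), p, Inf, 1), "blow-up")
  st <- resting_state(p); st$v <- NaN
  expect_error(step_izhikevich(st, p, 0, 1), "non-finite")
  expect_error(step_rate(rate_neuron_state(0, 50), NaN, 0, 1), "non-finite")
})

test_that("the rate neuron relaxes to its drive with time constant gamma_m", {
  gm <- 50; D <- 12; dt <- 0.01
  st <- rate_neuron_state(activity = 0, gamma_m = gm)
  n <- round(200 / dt)
  for (k in seq_len(n)) st <- step_rate(st, external_input = D,
                                        weighted_presynaptic_sum = 0, dt = dt)
  ## analytic: V(t) = D (1 - exp(-t/gamma)); forward Euler is first-order,
  ## so agreement is to O(dt/gamma)
  expect_equal(st$activity, D * (1 - exp(-200 / gm)), tolerance = 2e-4)
  ## linearity: doubling the drive doubles the steady state
  st2 <- rate_neuron_state(0, gm)
  for (k in 1:20000) st2 <- step_rate(st2, 2 * D, 0, dt = 1e-2)
  expect_equal(st2$activity / st$activity, 2, tolerance = 1e-3)
})

test_that("rate activity is clipped at zero and the origin is fixed", {
  st <- rate_neuron_state(0, 50)
  expect_equal(step_rate(st, 0, 0, 1)$activity, 0)
  st <- rate_neuron_state(1, 50)
  for (k in 1:50) st <- step_rate(st, -100, 0, 1)
  expect_identical(st$activity, 0)
})
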