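test_that("noise-free accumulation is exactly k * w * dt", {
  l <- drift_learner(w = 0.0025, sigma = 0, dt = 1)
  l <- accumulate(l)
  expect_equal(l$phi, 0.0025)
  for (k in 2:400) l <- accumulate(l)
  expect_equal(l$phi, 1, tolerance = 1e-12)
})

test_that("accumulation noise has the stated N(0, sigma^2) law", {
  set.seed(99)
  ## sigma small relative to w dt so the phi >= 0 floor never binds
  l0 <- drift_learner(w = 0.002, sigma = 2e-4, dt = 1)
  inc <- replicate(1e4, accumulate(l0)$phi)
  se <- 2e-4 / sqrt(1e4)
  expect_lt(abs(mean(inc) - 0.002), 3 * se)
  expect_equal(sd(inc), 2e-4, tolerance = 0.05)
})

test_that("early-reward correction is w(1-phi)phi with its two zeros", {
  expect_equal(early_reward_delta(0.002, 0.5), 0.0005)
  expect_identical(early_reward_delta(0.004, 1), 0)
  expect_identical(early_reward_delta(0.004, 0), 0)
  expect_gt(early_reward_delta(0.001, 0.3), 0)
  expect_error(early_reward_delta(0.002, 1.2), "\\[0, 1\\]")
})

test_that("the late decrement follows x <- x - x^2 dt and never crosses zero", {
  l <- drift_learner(w = 0.002, dt = 1)
  l <- late_decrement_step(l)
  expect_equal(l$pending_delta, -4e-6)
  prev <- l$pending_delta
  for (k in 1:5000) {
    l <- late_decrement_step(l)
    expect_lt(l$pending_delta, prev)
    prev <- l$pending_delta
    expect_gt(l$w + l$pending_delta, 0)
  }
  ## the implied corrected rate approaches 0 monotonically from above
  expect_lt(l$w + l$pending_delta, 2e-4)
})

test_that("commits apply w <- w + alpha delta and clear per-trial state", {
  l <- drift_learner(w = 0.002, alpha = 0.5)
  l$phi <- 0.7; l$pending_delta <- -1e-5
  l2 <- commit_update(l, 0.0005)
  expect_equal(l2$w, 0.00225)
  expect_identical(l2$phi, 0)
  expect_identical(l2$pending_delta, 0)
  expect_identical(l2$trial_index, 1L)
  expect_equal(commit_update(l, 0)$w, l$w)
  expect_warning(l3 <- commit_update(drift_learner(w = 1e-4, alpha = 1), -1),
                 "floored")
  expect_equal(l3$w, 1e-6)
})

test_that("periodic reward drives the drift rate to the 1/T fixed point", {
  ## the early-reward map phi <- phi(1 + alpha(1-phi)phi) contracts at
  ## rate ~(1 - alpha) near the fixed point, so the cycle budget scales
  ## with 1/alpha; 120 cycles is analytically sufficient over this grid
  for (T_period in c(400, 500, 600)) {
    for (alpha in c(0.1, 0.5)) {
      for (w0 in c(1 / 300, 1 / 800)) {
        l <- drift_learner(w = w0, alpha = alpha, sigma = 0, dt = 1)
        out <- run_reward_cycles(l, period = T_period, n_cycles = 120)
        expect_lt(abs(out$learner$w * T_period - 1), 0.01,
                  label = sprintf("|wT-1| (T=%d, alpha=%g, w0=%g)",
                                  T_period, alpha, w0))
      }
    }
  }
})

test_that("an exact 1/T start is a fixed point of the reward cycle", {
  l <- drift_learner(w = 1 / 500, alpha = 0.5, sigma = 0, dt = 1)
  out <- run_reward_cycles(l, period = 500, n_cycles = 5)
  expect_equal(out$learner$w, 1 / 500, tolerance = 1e-9)
})

test_that("update directions match the reward ordering", {
  ## reward earlier than expectation: phi < 1 at reward, w must not decrease
  l <- drift_learner(w = 1 / 800, alpha = 0.3, sigma = 0, dt = 1)
  out <- run_reward_cycles(l, period = 400, n_cycles = 8)
  expect_true(all(diff(c(1 / 800, out$w_trajectory)) >= 0))
  ## expectation earlier than reward: committed w decreases
  l <- drift_learner(w = 1 / 300, alpha = 0.3, sigma = 0, dt = 1)
  out <- run_reward_cycles(l, period = 500, n_cycles = 8)
  expect_true(all(diff(c(1 / 300, out$w_trajectory)) <= 0))
})

test_that("first-passage variability at the learner level is scalar-like", {
  ## with sigma > 0 fixed, the SD of the ceiling-crossing time grows with
  ## the learned interval while the CV stays within a narrow band
  sigma <- 0.005
  set.seed(7)
  stats_for <- function(T_period) {
    w <- 1 / T_period
    t_cross <- replicate(300, {
      l <- drift_learner(w = w, sigma = sigma, dt = 1)
      k <- 0
      while (l$phi < 1) { l <- accumulate(l); k <- k + 1 }
      k
    })
    c(sd = sd(t_cross), cv = sd(t_cross) / mean(t_cross))
  }
  s <- vapply(c(400, 500, 600), stats_for, numeric(2))
  expect_true(all(diff(s["sd", ]) > 0))
  expect_lt(max(s["cv", ]) / min(s["cv", ]), 1.5)
})

test_that("drift_to_weight is linear, monotone and zero at zero", {
  coupling <- list(gamma_m = 50, threshold = 20, drive_scale = 18)
  expect_identical(drift_to_weight(0, coupling), 0)
  w <- seq(0.0005, 0.004, by = 0.0005)
  W <- vapply(w, drift_to_weight, numeric(1), coupling = coupling)
  expect_true(all(diff(W) > 0))
  expect_equal(W / w, rep(50 * 20 / 18, length(w)))
})
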