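## Analysis of event logs: kernel firing-rate estimates, produced
## intervals, convergence curves, ramp slopes, absolute-timing episode
## durations and the scalar-property table.

#' Kernel estimate of a firing rate
#'
#' Smooths a spike train onto a regular grid with a Gaussian kernel
#' (width = SD, default 50 ms) or a boxcar kernel (width = full window).
#' The estimate conserves spike count: the time integral of the returned
#' rate equals the number of spikes whose kernel mass falls inside the
#' grid (edge spikes lose the mass outside it).
#'
#' @param spike_times Sorted, non-negative spike times (ms). An empty
#'   vector gives an all-zero series.
#' @param kernel_width Kernel width (ms).
#' @param grid_dt Grid spacing (ms).
#' @param t_min,t_max Grid range (ms); default covers the spikes.
#' @param kernel `"gaussian"` or `"boxcar"`.
#' @param label Population label carried in the result.
#' @return A `rate_series`: list with `time` (ms), `rate` (Hz), `label`,
#'   and `smoothing` (kernel descriptor).
#' @export
estimate_firing_rate <- function(spike_times, kernel_width = 50, grid_dt = 1,
                                 t_min = NULL, t_max = NULL,
                                 kernel = c("gaussian", "boxcar"),
                                 label = "") {
  kernel <- match.arg(kernel)
  if (length(spike_times) && is.unsorted(spike_times))
    stop("'spike_times' must be sorted")
  if (length(spike_times) && any(spike_times < 0))
    stop("'spike_times' must be non-negative")
  if (kernel_width <= 0 || grid_dt <= 0)
    stop("'kernel_width' and 'grid_dt' must be positive")
  if (is.null(t_min))
    t_min <- if (length(spike_times)) floor(min(spike_times) - 4 * kernel_width) else 0
  if (is.null(t_max))
    t_max <- if (length(spike_times)) ceiling(max(spike_times) + 4 * kernel_width) else 1000
  grid <- seq(t_min, t_max, by = grid_dt)
  rate <- numeric(length(grid))
  if (length(spike_times)) {
    counts <- tabulate(findInterval(spike_times, grid), nbins = length(grid))
    half <- if (kernel == "gaussian") ceiling(4 * kernel_width / grid_dt)
            else ceiling(kernel_width / 2 / grid_dt)
    x <- seq(-half, half) * grid_dt
    kern <- if (kernel == "gaussian") {
      stats::dnorm(x, sd = kernel_width) * grid_dt
    } else {
      as.numeric(abs(x) <= kernel_width / 2) /
        (sum(abs(x) <= kernel_width / 2))
    }
    sm <- stats::convolve(counts, rev(kern), type = "open")
    rate <- sm[(half + 1):(half + length(grid))] / grid_dt * 1000
    rate[rate < 0] <- 0   # convolution round-off
  }
  structure(list(time = grid, rate = rate, label = label,
                 smoothing = sprintf("%s(width=%g ms)", kernel, kernel_width)),
            class = "rate_series")
}

#' @export
print.rate_series <- function(x, ...) {
  cat(sprintf("rate series '%s': %d points on [%g, %g] ms, peak %.2f Hz, %s\n",
              x$label, length(x$time), min(x$time), max(x$time),
              max(x$rate), x$smoothing))
  invisible(x)
}

#' Produced inter-tap intervals
#'
#' @param tap_times Tap times (ms); at least two are required.
#' @return Successive differences (ms).
#' @export
produced_intervals <- function(tap_times) {
  if (length(tap_times) < 2)
    stop("insufficient taps: need at least 2 to produce an interval")
  diff(sort(tap_times))
}

#' Continuation intervals of a trial
#'
#' @param trial An `sct_trial`.
#' @return Continuation-phase tap-to-tap intervals (ms).
#' @export
trial_intervals <- function(trial) {
  stopifnot(inherits(trial, "sct_trial"))
  trial$intervals
}

#' Per-session timing error of a training run
#'
#' @param results A list of `sct_trial` objects (an `sct_training`).
#' @param target Target interval (ms).
#' @return Numeric vector: per session, the mean absolute deviation of
#'   the produced continuation intervals from the target (ms).
#' @export
convergence_curve <- function(results, target) {
  if (!length(results)) stop("need at least one session")
  vapply(results, function(tr) {
    iv <- if (inherits(tr, "sct_trial")) tr$intervals else tr
    if (!length(iv)) return(NA_real_)
    mean(abs(iv - target))
  }, numeric(1))
}

#' Scalar-property summary table
#'
#' Per target interval: the mean, SD and coefficient of variation
#' (CV = SD/mean) of the produced durations. The scalar property of
#' interval timing predicts SD growing proportionally with the interval,
#' hence an approximately constant CV.
#'
#' @param durations_by_target Named list mapping target interval (ms) to
#'   a vector of produced-duration samples (>= 2 per target).
#' @return A data frame of class `scalar_property_table` with columns
#'   `target_ms`, `n`, `mean_ms`, `sd_ms`, `cv`, and attribute
#'   `cv_spread` = (max CV - min CV) / mean CV.
#' @export
scalar_property_table <- function(durations_by_target) {
  if (!length(durations_by_target) || is.null(names(durations_by_target)))
    stop("'durations_by_target' must be a named list (names = target ms)")
  short <- vapply(durations_by_target, function(x) length(x) < 2, logical(1))
  if (any(short))
    stop("need at least 2 samples per target; too few for: ",
         paste(names(durations_by_target)[short], collapse = ", "))
  tab <- data.frame(
    target_ms = as.numeric(names(durations_by_target)),
    n = vapply(durations_by_target, length, integer(1)),
    mean_ms = vapply(durations_by_target, mean, numeric(1)),
    sd_ms = vapply(durations_by_target, stats::sd, numeric(1)),
    row.names = NULL)
  tab$cv <- tab$sd_ms / tab$mean_ms
  attr(tab, "cv_spread") <- (max(tab$cv) - min(tab$cv)) / mean(tab$cv)
  class(tab) <- c("scalar_property_table", "data.frame")
  tab[order(tab$target_ms), ]
}

#' Least-squares ramp slope of a rate series
#'
#' @param series A `rate_series`.
#' @param window `c(start, end)` in ms; must lie within the series and
#'   contain at least two grid points.
#' @return Slope in Hz/ms.
#' @export
ramp_slope <- function(series, window) {
  stopifnot(inherits(series, "rate_series"), length(window) == 2)
  if (window[2] <= window[1])
    stop("degenerate window: end must exceed start")
  sel <- series$time >= window[1] & series$time <= window[2]
  if (sum(sel) < 2)
    stop("window contains fewer than 2 grid points")
  x <- series$time[sel]; y <- series$rate[sel]
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

#' Up-down episode durations of the absolute-timing groups
#'
#' For each absolute-timing group, measures the duration of the
#' pyramidal activity episode (first to last spike) within each
#' inter-pulse window of the trial (a pulse is a synchronizing event:
#' every tap restarts the groups) and returns the median per group.
#' These durations are set by each microcircuit's internal
#' excitation/inhibition balance and do not depend on the target
#' interval.
#'
#' @param trial An `sct_trial`.
#' @return Numeric vector of five median episode durations (ms).
#' @export
absolute_group_spans <- function(trial) {
  stopifnot(inherits(trial, "sct_trial"))
  raster <- trial$raster
  k <- trial$config$circuit$n_replicates
  pulses <- trial$pulses
  if (length(pulses) < 2) stop("trial has fewer than 2 synchronizing pulses")
  pyr <- raster[raster$population == "absolute_timing_pyr", ]
  vapply(seq_len(5L), function(g) {
    ts <- sort(pyr$time_ms[ceiling(pyr$neuron_index / k) == g])
    durs <- vapply(seq_len(length(pulses) - 1L), function(j) {
      seg <- ts[ts >= pulses[j] & ts < pulses[j + 1L]]
      if (length(seg) < 2) NA_real_ else max(seg) - min(seg)
    }, numeric(1))
    stats::median(durs, na.rm = TRUE)
  }, numeric(1))
}

#' Scalar-property sweep over target intervals
#'
#' Runs `reps` independent training experiments per target interval and
#' collects the continuation intervals of each final session. Repetition
#' seeds are shared across targets (a paired design: the same noise
#' draws underlie each target's repetitions), so cross-target
#' comparisons of variability are not confounded by sampling noise.
#'
#' @param targets Target intervals (ms).
#' @param reps Repetitions per target.
#' @param config Base `sct_config` (target and seed are overridden).
#' @param seed Master seed for the sweep.
#' @return A list with `samples` (named list of produced durations per
#'   target), `learned` (named list of per-repetition mean learned
#'   durations) and `table` (the [scalar_property_table()] of the pooled
#'   samples).
#' @export
run_scalar_sweep <- function(targets = c(400, 500, 600), reps = 8,
                             config = sct_config(), seed = config$seed) {
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, reps)
  samples <- stats::setNames(vector("list", length(targets)),
                             as.character(targets))
  learned <- samples
  for (ti in seq_along(targets)) {
    tt <- targets[ti]
    for (r in seq_len(reps)) {
      cfg <- config
      cfg$target_interval <- tt
      cfg$seed <- rep_seeds[r]
      res <- run_training(cfg)
      iv <- res[[length(res)]]$intervals
      samples[[ti]] <- c(samples[[ti]], iv)
      learned[[ti]] <- c(learned[[ti]], mean(iv))
    }
  }
  list(samples = samples, learned = learned,
       table = scalar_property_table(samples))
}
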