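## Configuration files (YAML/JSON), run-directory serialization (CSV +
## JSON manifest) and the command-line driver.

#' Load and resolve a run configuration
#'
#' Builds the resolved configuration as defaults, overridden by the
#' fields of a YAML (or JSON) file, overridden by explicit `overrides`,
#' in that precedence, then validates every invariant. Unknown keys are
#' an error listing each offending name.
#'
#' @param path Optional path to a YAML or JSON config file.
#' @param overrides Named list of final overrides (may contain a
#'   `circuit` sub-list).
#' @return A validated `sct_config`.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  file_vals <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    file_vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
      jsonlite::read_json(path, simplifyVector = TRUE)
    } else yaml::read_yaml(path)
    if (is.null(file_vals)) file_vals <- list()
  }
  merged <- utils::modifyList(file_vals, overrides)
  cfg <- do.call(sct_config, merged)
  validate_config(cfg)
  cfg
}

#' Save a configuration to YAML
#'
#' @param config An `sct_config`.
#' @param path Output path (`.yaml`/`.yml`, or `.json`).
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  plain <- unclass(config)
  plain$circuit <- unclass(plain$circuit)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(plain, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  } else yaml::write_yaml(plain, path)
  invisible(path)
}

#' Write a training run to a directory
#'
#' Serializes the trial logs of a training run as strict CSV
#' (comma-separated, header row, UTF-8, '.' decimal; times in ms with 3
#' decimals): `taps.csv`, `stimuli.csv`, `weights.csv`, `raster.csv`,
#' `intervals.csv`, plus `manifest.json` holding the fully resolved
#' configuration, seed, package version and an MD5 inventory of every
#' written file. A run is exactly reproducible from its manifest.
#'
#' @param results An `sct_training` (list of trials) from
#'   [run_training()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_trial_result <- function(results, dir) {
  stopifnot(length(results) >= 1, inherits(results[[1]], "sct_trial"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fmt <- function(x) formatC(x, format = "f", digits = 3)
  taps <- do.call(rbind, lapply(results, function(tr)
    cbind(session = tr$session, tr$taps)))
  taps$time_ms <- fmt(taps$time_ms)
  stim <- do.call(rbind, lapply(results, function(tr)
    data.frame(session = tr$session, time_ms = fmt(tr$stimuli))))
  weights <- do.call(rbind, lapply(results, `[[`, "weights"))
  weights$time_ms <- fmt(weights$time_ms)
  raster <- do.call(rbind, lapply(results, function(tr)
    cbind(session = tr$session, tr$raster)))
  raster$time_ms <- fmt(raster$time_ms)
  intervals <- do.call(rbind, lapply(results, function(tr)
    if (length(tr$intervals))
      data.frame(session = tr$session, interval_ms = fmt(tr$intervals))))
  files <- c(taps = "taps.csv", stimuli = "stimuli.csv",
             weights = "weights.csv", raster = "raster.csv",
             intervals = "intervals.csv")
  objs <- list(taps, stim, weights, raster, intervals)
  for (i in seq_along(files))
    utils::write.csv(objs[[i]], file.path(dir, files[i]), row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  cfg <- results[[1]]$config
  inventory <- as.list(tools::md5sum(file.path(dir, files)))
  names(inventory) <- files
  manifest <- list(
    config = { p <- unclass(cfg); p$circuit <- unclass(p$circuit); p },
    seed = cfg$seed,
    package_version = as.character(utils::packageVersion("tapcircuit")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    files = inventory)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

cli_usage <- function() {
  paste(
    "usage: tapcircuit <command> [options]",
    "",
    "commands:",
    "  run        one training experiment",
    "             --interval MS --sessions N --seed S --out DIR [--config FILE]",
    "  sweep      scalar-property experiment over 400/500/600 ms",
    "             --reps N --seed S --out DIR [--config FILE]",
    "  analyze    recompute analysis outputs from a run directory",
    "             --in DIR --out DIR",
    "  calibrate  print the drift-to-weight coupling constants",
    "             [--config FILE]",
    sep = "\n")
}

parse_cli_flags <- function(args) {
  flags <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--"))
      stop("unexpected argument: ", a, "\n", cli_usage())
    if (i == length(args)) stop("missing value for flag ", a)
    flags[[substring(a, 3)]] <- args[i + 1L]
    i <- i + 2L
  }
  flags
}

#' Command-line driver
#'
#' Implements the `run`, `sweep`, `analyze` and `calibrate` subcommands
#' (see `inst/scripts/tapcircuit.R` for the Rscript entry point). Returns
#' the exit status instead of calling `quit()` so it can be driven from
#' tests.
#'
#' @param args Character vector of command-line arguments.
#' @return Integer exit status (0 on success), invisibly.
#' @export
cli_run <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (!length(args)) stop(cli_usage())
    cmd <- args[1]
    flags <- parse_cli_flags(args[-1])
    cfg_from <- function() {
      ov <- list()
      if (!is.null(flags$interval))
        ov$target_interval <- as.numeric(flags$interval)
      if (!is.null(flags$sessions)) ov$n_sessions <- as.integer(flags$sessions)
      if (!is.null(flags$seed)) ov$seed <- as.integer(flags$seed)
      load_config(flags$config, ov)
    }
    switch(cmd,
      run = {
        cfg <- cfg_from()
        out <- flags$out %||% "tapcircuit_run"
        res <- run_training(cfg)
        write_trial_result(res, out)
        message("run written to ", out)
      },
      sweep = {
        cfg <- cfg_from()
        reps <- as.integer(flags$reps %||% "8")
        out <- flags$out %||% "tapcircuit_sweep"
        dir.create(out, recursive = TRUE, showWarnings = FALSE)
        sw <- run_scalar_sweep(reps = reps, config = cfg, seed = cfg$seed)
        tab <- sw$table
        tab$mean_ms <- round(tab$mean_ms, 3); tab$sd_ms <- round(tab$sd_ms, 3)
        tab$cv <- round(tab$cv, 5)
        utils::write.csv(tab, file.path(out, "scalar_table.csv"),
                         row.names = FALSE, quote = FALSE)
        message("sweep written to ", out)
      },
      analyze = {
        if (is.null(flags$`in`)) stop("analyze needs --in DIR")
        out <- flags$out %||% flags$`in`
        dir.create(out, recursive = TRUE, showWarnings = FALSE)
        taps <- utils::read.csv(file.path(flags$`in`, "taps.csv"))
        cont <- taps[taps$phase == "continuation", ]
        iv <- do.call(rbind, lapply(split(cont, cont$session), function(d)
          if (nrow(d) >= 2)
            data.frame(session = d$session[1],
                       interval_ms = diff(sort(d$time_ms)))))
        utils::write.csv(iv, file.path(out, "intervals.csv"),
                         row.names = FALSE, quote = FALSE)
        message("analysis written to ", out)
      },
      calibrate = {
        cfg <- if (is.null(flags$config)) sct_config() else
          load_config(flags$config)
        cc <- calibrate_coupling(cfg$circuit, cfg$dt, cfg$circuit$sync_pulse_duration,
                                 cfg$rate_threshold)
        spans <- calibrate_spans(cfg$circuit, cfg$dt, cfg$circuit$sync_pulse_duration)
        cat(sprintf("gamma_m: %g ms\nthreshold: %g Hz\ndrive_scale: %.6g\n",
                    cc$gamma_m, cc$threshold, cc$drive_scale))
        cat("group gains (pyr->interneuron):",
            paste(signif(spans, 5), collapse = ", "), "\n")
      },
      stop("unknown command '", cmd, "'\n", cli_usage())
    )
    0L
  }, error = function(err) {
    message("error: ", conditionMessage(err))
    1L
  })
  invisible(status)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
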