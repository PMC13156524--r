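# End-to-end pipeline: configuration, stage orchestration, result export,
# and the command-line entry point. One global seed deterministically spawns
# per-stage seeds, so every numerical output is reproducible from
# (config, seed) and the emitted manifest.

deep_merge <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- deep_merge(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

default_run_config <- function() {
  list(
    input = "simulate",           # or a session-container path
    seed = 1L,
    output_dir = "aadtrf_results",
    simulation = list(n_scalp_channels = 8, n_ceegrid_channels = 8,
                      fs_raw = 200, trial_duration = 60,
                      trial_counts = list(SustAC = 4, SwitAC = 4, ConvAC = 4),
                      switch_window_1 = c(15, 25), switch_window_2 = c(35, 45),
                      snr_db = 5, attention_gain = 0.5),
    preprocessing = list(fs_out = 50, notch_hz = 50,
                         band_wide = c(0.1, 40), band_narrow = c(1, 20)),
    trf = list(lag_range = c(-0.2, 0.6), basis_width = 50,
               boosting = list(step_size = 0.005, partitions = 2,
                               patience = 20, max_steps = 5000)),
    evaluation = list(conditions = c("SustAC", "SwitAC", "ConvAC"),
                      window_grid = c(1.1, 2.2, 4.4, 8.8, 17.5, 35, 178),
                      cross_condition = FALSE, lagscan = FALSE),
    statistics = list(enabled = FALSE, n_perm = 200, alpha = 0.05, q = 0.05,
                      smooth_ms = 50)
  )
}

#' Pipeline run configuration
#'
#' Builds a validated configuration from the package defaults, an optional
#' JSON config file, and explicit overrides (in that order of precedence,
#' overrides winning). Round-trips losslessly through
#' [save_run_config()] / `run_config(path)`.
#'
#' @param path optional JSON config file.
#' @param overrides named list of (possibly nested) overrides.
#' @return a `run_config` list.
#' @export
run_config <- function(path = NULL, overrides = list()) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    cfg <- deep_merge(cfg, jsonlite::fromJSON(path))
  }
  cfg <- deep_merge(cfg, overrides)
  cfg$seed <- as.integer(cfg$seed)
  sim <- cfg$simulation
  tc <- unlist(sim$trial_counts)
  do.call(sim_config, c(sim[setdiff(names(sim), "trial_counts")],
                        list(trial_counts = tc, seed = cfg$seed)))  # validates
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param config a `run_config`.
#' @export
save_run_config <- function(config, path) {
  cfg <- unclass(config)
  # named atomic vectors lose their names as JSON arrays; store as an object
  cfg$simulation$trial_counts <- as.list(unlist(cfg$simulation$trial_counts))
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

config_sim <- function(config) {
  sim <- config$simulation
  do.call(sim_config, c(sim[setdiff(names(sim), "trial_counts")],
                        list(trial_counts = unlist(sim$trial_counts),
                             seed = config$seed)))
}

config_boost <- function(config) {
  do.call(boost_config, as.list(config$trf$boosting))
}

#' Run the full analysis pipeline
#'
#' simulate/load -> preprocess -> fit decoders -> evaluate decision windows
#' (-> optional lag scan, cross-condition evaluation and TRF statistics), and
#' write all artifacts plus a JSON manifest into the output directory.
#' Deterministic: the same (config, seed) reproduces every output file.
#' Stage failures abort the run but preserve partial outputs; the returned
#' report names the failing stage.
#'
#' @param config a [run_config()].
#' @return run report: stage status, output paths, evaluation summaries.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) config <- run_config(overrides = config)
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  report <- list(stages = list(), outputs = character(), config = config)
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) e)
    if (inherits(res, "error")) {
      report$stages[[name]] <<- paste("failed:", conditionMessage(res))
      stop("stage '", name, "' failed: ", conditionMessage(res), call. = FALSE)
    }
    report$stages[[name]] <<- "ok"
    res
  }

  session <- stage("input", {
    if (identical(config$input, "simulate"))
      synthesize_session(config_sim(config), seed = config$seed)
    else load_session(config$input)
  })

  session <- stage("preprocess", {
    pp <- config$preprocessing
    preprocess_session(session, fs_out = pp$fs_out, notch_hz = pp$notch_hz,
                       band_wide = pp$band_wide, band_narrow = pp$band_narrow)
  })

  bcfg <- config_boost(config)
  conds <- intersect(config$evaluation$conditions,
                     unique(session_conditions(session)))
  conds <- conds[vapply(conds, function(cc)
    sum(session_conditions(session) == cc) >= 2, TRUE)]

  results <- stage("evaluate", {
    lapply(conds, function(cc) {
      suppressMessages(decision_window_curve(
        session, cc, lengths = config$evaluation$window_grid,
        lag_range = config$trf$lag_range, cfg = bcfg))
    })
  })
  names(results) <- conds

  exported <- stage("export", {
    details <- do.call(rbind, lapply(conds, function(cc) {
      d <- classify_attention(results[[cc]]$details)$scores
      cbind(subject = "sim01", condition = cc,
            d[, c("window_s", "fold", "segment", "rho_att", "rho_ign",
                  "rho_ctl", "correct")])
    }))
    data.table::fwrite(details, file.path(out, "decisions.csv"))
    curves <- do.call(rbind, lapply(conds, function(cc)
      cbind(condition = cc, results[[cc]]$curve)))
    data.table::fwrite(curves, file.path(out, "accuracy_curves.csv"))
    file.path(out, c("decisions.csv", "accuracy_curves.csv"))
  })
  report$outputs <- c(report$outputs, exported)

  if (isTRUE(config$evaluation$lagscan)) {
    scan <- stage("lagscan", {
      optimal_lag_scan(session, conds[1], directions = "backward",
                       streams = "attended", cfg = bcfg)
    })
    data.table::fwrite(as.data.frame(scan), file.path(out, "lagscan.csv"))
    report$outputs <- c(report$outputs, file.path(out, "lagscan.csv"))
  }

  if (isTRUE(config$statistics$enabled)) {
    smap <- stage("stats", {
      cc <- conds[1]
      att <- fit_forward_trfs(session, cc, "attended",
                              lag_range = config$trf$lag_range, cfg = bcfg)
      ign <- fit_forward_trfs(session, cc, "ignored",
                              lag_range = config$trf$lag_range, cfg = bcfg)
      att <- lapply(att, smooth_trf, width = config$statistics$smooth_ms)
      ign <- lapply(ign, smooth_trf, width = config$statistics$smooth_ms)
      permutation_pvalues(att, ign, paired = TRUE,
                          n_perm = config$statistics$n_perm,
                          seed = derive_seed(config$seed, 97L),
                          alpha = config$statistics$alpha)
    })
    data.table::fwrite(stat_map_table(smap), file.path(out, "trf_stats.csv"))
    report$outputs <- c(report$outputs, file.path(out, "trf_stats.csv"))
  }

  stage("manifest", {
    cfg_path <- file.path(out, "config.json")
    save_run_config(config, cfg_path)
    manifest <- list(
      package = "aadtrf",
      version = as.character(utils::packageVersion("aadtrf")),
      r_version = R.version.string,
      seed = config$seed,
      config_md5 = unname(tools::md5sum(cfg_path)),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      outputs = report$outputs)
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    NULL
  })

  report$results <- lapply(results, function(r) r$curve)
  invisible(report)
}

cli_options <- function() {
  optparse::OptionParser(
    usage = "aadtrf <simulate|preprocess|features|fit|evaluate|lagscan|stats|run> [options]",
    option_list = list(
      optparse::make_option("--config", type = "character", default = NULL,
                            help = "JSON run-config file"),
      optparse::make_option("--seed", type = "integer", default = NULL,
                            help = "global seed (overrides config)"),
      optparse::make_option("--session", type = "character", default = NULL,
                            help = "session container directory (input)"),
      optparse::make_option("--out", type = "character", default = NULL,
                            help = "output directory or file"),
      optparse::make_option("--condition", type = "character", default = NULL,
                            help = "condition for evaluate/lagscan/stats"),
      optparse::make_option("--wav", type = "character", default = NULL,
                            help = "input WAV file for the features command")))
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (write a synthetic session container),
#' `preprocess`, `features` (WAV to envelope/onset CSV), `fit` (decoder
#' kernels to CSV), `evaluate` (decision-window curve), `lagscan`, `stats`
#' (attended-vs-ignored TRF contrast), `run` (full pipeline). Values in
#' `--config` win unless overridden by a flag. Invoke via
#' `Rscript -e 'aadtrf::aad_cli()' <subcommand> [options]`.
#'
#' @param args character vector of CLI arguments.
#' @return exit status 0 on success, invisibly.
#' @export
aad_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) { optparse::print_help(cli_options()); return(invisible(1L)) }
  cmd <- args[1]
  opts <- optparse::parse_args(cli_options(), args = args[-1])
  ov <- list()
  if (!is.null(opts$seed)) ov$seed <- opts$seed
  if (!is.null(opts$out)) ov$output_dir <- opts$out
  if (!is.null(opts$session)) ov$input <- opts$session
  config <- run_config(opts$config, ov)

  out_dir <- config$output_dir
  switch(cmd,
    run = run_pipeline(config),
    simulate = {
      sess <- synthesize_session(config_sim(config), seed = config$seed)
      save_session(sess, out_dir)
      message("session written to ", out_dir)
    },
    preprocess = {
      sess <- load_session(config$input)
      pp <- config$preprocessing
      sess <- preprocess_session(sess, fs_out = pp$fs_out,
                                 notch_hz = pp$notch_hz,
                                 band_wide = pp$band_wide,
                                 band_narrow = pp$band_narrow)
      save_session(sess, out_dir)
    },
    features = {
      if (is.null(opts$wav)) stop("features needs --wav", call. = FALSE)
      audio <- read_wav(opts$wav)
      gt <- gammatone_decompose(audio)
      env <- prepare_feature(acoustic_envelope(gt))
      ons <- prepare_feature(acoustic_onsets(gt))
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      for (nm in c("envelope", "onset")) {
        f <- if (nm == "envelope") env else ons
        data.table::fwrite(data.frame(time_s = (seq_len(n_samples(f)) - 1) / f$fs,
                                      value = f$values[, 1]),
                           file.path(out_dir, paste0(nm, ".csv")))
      }
    },
    fit = {
      sess <- preprocess_session(load_session(config$input))
      cc <- if (!is.null(opts$condition)) opts$condition else
        session_conditions(sess)[1]
      kern <- fit_decoder(sess, which(session_conditions(sess) == cc),
                          lag_range = config$trf$lag_range,
                          cfg = config_boost(config))
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      tab <- data.frame(lag_s = kernel_lag_seconds(kern))
      tab <- cbind(tab, as.data.frame(kern$coef))
      data.table::fwrite(tab, file.path(out_dir, paste0("decoder_", cc, ".csv")))
    },
    evaluate = {
      sess <- preprocess_session(load_session(config$input))
      cc <- if (!is.null(opts$condition)) opts$condition else
        session_conditions(sess)[1]
      cv <- decision_window_curve(sess, cc,
                                  lengths = config$evaluation$window_grid,
                                  lag_range = config$trf$lag_range,
                                  cfg = config_boost(config))
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      data.table::fwrite(cv$curve, file.path(out_dir, paste0("curve_", cc, ".csv")))
    },
    lagscan = {
      sess <- preprocess_session(load_session(config$input))
      cc <- if (!is.null(opts$condition)) opts$condition else
        session_conditions(sess)[1]
      scan <- optimal_lag_scan(sess, cc, cfg = config_boost(config))
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      data.table::fwrite(as.data.frame(scan), file.path(out_dir, "lagscan.csv"))
    },
    stats = {
      sess <- preprocess_session(load_session(config$input))
      cc <- if (!is.null(opts$condition)) opts$condition else
        session_conditions(sess)[1]
      att <- fit_forward_trfs(sess, cc, "attended", cfg = config_boost(config))
      ign <- fit_forward_trfs(sess, cc, "ignored", cfg = config_boost(config))
      smap <- permutation_pvalues(lapply(att, smooth_trf),
                                  lapply(ign, smooth_trf), paired = TRUE,
                                  n_perm = config$statistics$n_perm,
                                  seed = config$seed,
                                  alpha = config$statistics$alpha)
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      data.table::fwrite(stat_map_table(smap), file.path(out_dir, "trf_stats.csv"))
    },
    stop("unknown subcommand: ", cmd, call. = FALSE))
  invisible(0L)
}
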