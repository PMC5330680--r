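#' Run an analysis pipeline subcommand
#'
#' A thin command-line-style front end over the package's functions; the
#' same interface is exposed from a shell by the `inst/cli/ttcal` Rscript.
#' Arguments are a character vector: a subcommand followed by `--key value`
#' pairs. Every run writes its outputs plus a provenance JSON record
#' (subcommand, options, seed, package version) beside them.
#'
#' Subcommands: `simulate-intervals`, `fit-intervals`, `simulate-sweeps`,
#' `fit-activation`, `fit-inactivation`, `window`, `dff`, `compare-stages`.
#'
#' @param args character vector, e.g.
#'   `c("simulate-intervals", "--p", "0.5", "--a", "1", "--b", "0.1",
#'      "--n", "1000", "--seed", "7", "--out", "events.csv")`.
#' @return Invisibly, the integer exit status (0 on success); on validation
#'   failure a single-line diagnostic is written to stderr and a nonzero
#'   status returned.
#' @export
run_pipeline <- function(args) {
  status <- tryCatch({
    run_pipeline_impl(args)
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

parse_opts <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    key <- args[i]
    if (!startsWith(key, "--"))
      stop("expected an option (--key value), got '", key, "'")
    if (i + 1L > length(args)) stop("option ", key, " is missing a value")
    opts[[substring(key, 3)]] <- args[i + 1L]
    i <- i + 2L
  }
  opts
}

opt_num <- function(opts, name, default = NULL) {
  if (is.null(opts[[name]])) {
    if (is.null(default)) stop("missing required option --", name)
    return(default)
  }
  v <- suppressWarnings(as.numeric(opts[[name]]))
  if (is.na(v)) stop("option --", name, " must be numeric")
  v
}

opt_chr <- function(opts, name, default = NULL) {
  v <- opts[[name]]
  if (is.null(v)) {
    if (is.null(default)) stop("missing required option --", name)
    return(default)
  }
  v
}

write_provenance <- function(out, subcommand, opts) {
  record <- list(subcommand = subcommand, options = opts,
                 seed = opts[["seed"]],
                 package = "ttcal",
                 version = as.character(utils::packageVersion("ttcal")))
  jsonlite::write_json(record, paste0(out, ".provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
}

run_pipeline_impl <- function(args) {
  if (length(args) == 0) stop(pipeline_usage())
  sub <- args[1]
  if (sub %in% c("--version", "version")) {
    cat("ttcal", as.character(utils::packageVersion("ttcal")), "\n")
    return(invisible(NULL))
  }
  if (sub %in% c("--help", "help")) {
    cat(pipeline_usage(), "\n")
    return(invisible(NULL))
  }
  opts <- parse_opts(args[-1])
  out <- opt_chr(opts, "out", default = paste0(gsub("-", "_", sub), ".csv"))
  switch(sub,
    "simulate-intervals" = {
      params <- interval_params(opt_num(opts, "p"), opt_num(opts, "a"),
                                opt_num(opts, "b"))
      seed <- as.integer(opt_num(opts, "seed", 1))
      dur <- opt_num(opts, "duration", NA)
      if (!is.na(dur)) {
        tl <- simulate_timeline(params, dur, seed = seed)
        write_events(list(animal1 = tl), out)
      } else {
        n <- as.integer(opt_num(opts, "n"))
        x <- sample_intervals(params, n, seed = seed)
        tl <- structure(list(event_times = cumsum(x), duration = sum(x)),
                        class = "egg_timeline")
        write_events(list(animal1 = tl), out)
      }
    },
    "fit-intervals" = {
      timelines <- read_events(opt_chr(opts, "input"))
      intervals <- unlist(lapply(timelines, function(tl) diff(tl$event_times)))
      fit <- fit_intervals(intervals)
      est <- coef(fit)
      tc <- time_constants(fit$params)
      df <- data.frame(parameter = c(names(est), "tau_fast", "tau_slow", "rss",
                                     "converged", "n"),
                       estimate = c(est, tc, fit$rss, as.numeric(fit$converged),
                                    fit$n),
                       ci_lower = c(if (is.null(fit$ci95)) rep(NA, 3) else fit$ci95[, 1],
                                    rep(NA, 5)),
                       ci_upper = c(if (is.null(fit$ci95)) rep(NA, 3) else fit$ci95[, 2],
                                    rep(NA, 5)))
      utils::write.csv(df, out, row.names = FALSE)
    },
    "simulate-sweeps" = {
      kind <- opt_chr(opts, "kind", "activation")
      proto <- step_protocol(kind)
      model <- channel_model(
        act = boltzmann_params(opt_num(opts, "act-v50", -37.14),
                               opt_num(opts, "act-k", 5), "activation"),
        inact = boltzmann_params(opt_num(opts, "inact-v50", -58.18),
                                 opt_num(opts, "inact-k", 5), "inactivation"),
        tau_m = opt_num(opts, "tau-m", 5), tau_h = opt_num(opts, "tau-h", 30))
      sw <- simulate_sweeps(model, proto,
                            noise_sd = opt_num(opts, "noise", 0),
                            seed = as.integer(opt_num(opts, "seed", 1)))
      write_sweeps(sw, out)
    },
    "fit-activation" = ,
    "fit-inactivation" = {
      sense <- sub("^fit-", "", sub)
      sw <- read_sweeps(opt_chr(opts, "input"))
      pk <- extract_peaks(sw, blank_ms = opt_num(opts, "blank", 2))
      crv <- if (sense == "activation")
        chord_conductance_curve(pk$voltages, pk$peaks)
      else  # availability: normalize peak magnitudes at the fixed test step
        conductance_curve(pk$voltages, abs(pk$peaks), normalize = TRUE)
      fit <- fit_boltzmann(crv, sense)
      est <- coef(fit)
      df <- data.frame(parameter = c("v_half", "k", "rss", "converged"),
                       estimate = c(est, fit$rss, as.numeric(fit$converged)),
                       ci_lower = c(if (is.null(fit$ci95)) rep(NA, 2) else fit$ci95[, 1], NA, NA),
                       ci_upper = c(if (is.null(fit$ci95)) rep(NA, 2) else fit$ci95[, 2], NA, NA))
      utils::write.csv(df, out, row.names = FALSE)
    },
    "window" = {
      wm <- window_metrics(
        boltzmann_params(opt_num(opts, "act-v50"), opt_num(opts, "act-k"),
                         "activation"),
        boltzmann_params(opt_num(opts, "inact-v50"), opt_num(opts, "inact-k"),
                         "inactivation"),
        threshold_frac = opt_num(opts, "threshold", 0.1))
      utils::write.csv(data.frame(metric = c("v_peak", "w_peak", "v_low",
                                             "v_high", "width"),
                                  value = c(wm$v_peak, wm$w_peak, wm$v_low,
                                            wm$v_high, wm$width)),
                       out, row.names = FALSE)
    },
    "dff" = {
      trace <- read_traces(opt_chr(opts, "input"))
      mode <- opt_chr(opts, "mode", "dff")
      res <- if (mode == "raw") trace_pipeline(trace, statistic = "raw")
             else trace_pipeline(trace, mode = mode)
      utils::write.csv(data.frame(metric = c("cumulative", "baseline_slope",
                                             "baseline_intercept"),
                                  value = c(res$cumulative,
                                            res$dff$baseline_slope,
                                            res$dff$baseline_intercept)),
                       out, row.names = FALSE)
    },
    "compare-stages" = {
      dists <- read_stages(opt_chr(opts, "input"))
      ref <- opt_chr(opts, "ref", names(dists)[1])
      if (!ref %in% names(dists)) stop("reference genotype '", ref, "' not in file")
      others <- setdiff(names(dists), ref)
      rows <- lapply(others, function(g) {
        r <- compare_stage_distributions(dists[[ref]], dists[[g]])
        data.frame(reference = ref, genotype = g, U = unname(r$statistic),
                   p = r$p.value, method = r$method)
      })
      utils::write.csv(do.call(rbind, rows), out, row.names = FALSE)
    },
    stop("unknown subcommand '", sub, "'\n", pipeline_usage())
  )
  write_provenance(out, sub, opts)
  invisible(NULL)
}

pipeline_usage <- function() {
  paste("usage: ttcal <subcommand> [--key value ...]",
        "subcommands: simulate-intervals fit-intervals simulate-sweeps",
        "  fit-activation fit-inactivation window dff compare-stages",
        "common options: --seed <int> --out <path>", sep = "\n")
}
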