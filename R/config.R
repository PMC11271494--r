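#' Run configuration
#'
#' Loads and validates a structured run configuration from a YAML or JSON
#' file (or an equivalent named list). The configuration drives the
#' pipeline entry points [run_predict_steps()], [run_generate()],
#' [run_simulate()], [run_analyze()] and [run_fit()], and is echoed --
#' together with its MD5 hash and all seeds -- into every result file so
#' that any output can be regenerated exactly.
#'
#' Recognised top-level fields (all optional unless a given entry point
#' needs them): `environment` (kBT, A, l0), `construct` (a preset name or
#' an inline spec), `kinetics` (Bell parameter sets), `protocol`, `noise`,
#' `bootstrap` (n_resamples, seed), `forces`, `seed`, `output_dir`.
#'
#' @param x path to a `.yaml`/`.yml`/`.json` file, or a named list
#' @return an object of class `run_config`
#' @export
run_config <- function(x) {
  if (is.character(x)) {
    if (!file.exists(x)) stop("config file not found: ", x)
    cfg <- if (grepl("\\.json$", x, ignore.case = TRUE))
      jsonlite::read_json(x, simplifyVector = TRUE)
    else yaml::read_yaml(x)
    hash <- unname(tools::md5sum(x))
  } else if (is.list(x)) {
    cfg <- x
    tmp <- tempfile(fileext = ".json")
    on.exit(unlink(tmp))
    jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA)
    hash <- unname(tools::md5sum(tmp))
  } else stop("'x' must be a file path or a named list")
  if (!is.list(cfg) || (length(cfg) && is.null(names(cfg))))
    stop("configuration must be a named mapping")
  known <- c("environment", "construct", "kinetics", "protocol", "noise",
             "bootstrap", "forces", "transitions", "seed", "output_dir",
             "n", "censor_at", "n_runs")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         " (known: ", paste(known, collapse = ", "), ")")
  structure(list(cfg = cfg, hash = hash), class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf("<run_config> %s; fields: %s\n", x$hash,
              paste(names(x$cfg), collapse = ", ")))
  invisible(x)
}

cfg_env <- function(config) {
  e <- config$cfg$environment
  polymer_env(kBT = e$kBT %||% 4.075, A = e$A %||% 0.8, l0 = e$l0 %||% 0.38)
}

cfg_construct <- function(config) {
  cc <- config$cfg$construct
  if (is.null(cc)) stop("config field 'construct' is required here")
  if (is.character(cc)) return(construct_presets(cc))
  doms <- replicate(cc$n_domains %||% 4,
                    domain_spec(n_residues = cc$domain_residues %||% 110,
                                folded_span = cc$domain_span %||% 5),
                    simplify = FALSE)
  construct_spec(geometry = cc$geometry %||% "shear",
                 rod = rod_spec(doms,
                                total_residues = cc$rod_residues %||% 480,
                                folded_span = cc$rod_span %||% 24),
                 loop_residues = cc$loop_residues %||% 170,
                 dimer_span_before = cc$dimer_span_before %||% 24,
                 dimer_span_after = unlist(cc$dimer_span_after %||% 24),
                 loop_end_to_end = cc$loop_end_to_end %||% 24,
                 name = cc$name %||% "inline construct")
}

cfg_bell <- function(spec) bell_params(spec$k0, spec$delta)

cfg_model <- function(config, n_domains) {
  kin <- config$cfg$kinetics
  if (is.null(kin)) stop("config field 'kinetics' is required here")
  if (!is.null(kin$bond)) return(cfg_bell(kin$bond))
  pair <- pair_kinetics(cfg_bell(kin$unpair),
                        if (!is.null(kin$repair)) cfg_bell(kin$repair)
                        else bell_params(0, 0))
  dom <- domain_kinetics(if (!is.null(kin$unfold)) cfg_bell(kin$unfold)
                         else bell_params(0, 0),
                         if (!is.null(kin$refold)) cfg_bell(kin$refold)
                         else bell_params(0, 0))
  multivalent_dimer_model(kin$n_pairs %||% n_domains, pair, dom,
                          peel_from = kin$peel_from %||% "both")
}

cfg_protocol <- function(config) {
  p <- config$cfg$protocol
  if (is.null(p)) stop("config field 'protocol' is required here")
  do.call(force_protocol, p)
}

cfg_noise <- function(config) {
  n <- config$cfg$noise
  noise_model(height_sd = n$height_sd %||% 3,
              sampling_rate = n$sampling_rate %||% 200)
}

result_meta <- function(config, seed) {
  list(package = "mtdimer",
       version = as.character(utils::packageVersion("mtdimer")),
       config_hash = config$hash, seed = seed, config = config$cfg)
}

write_result_json <- function(obj, path) {
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Predict step sizes from a configuration
#'
#' Wraps [predicted_step_table()]: builds the construct from the config,
#' evaluates the configured (or standard) transitions over the configured
#' force grid, and writes `steps.tsv` plus a `steps.json` with metadata.
#'
#' @param config a [run_config()] (or something coercible by it)
#' @param out_dir output directory (default: the config's `output_dir`, or
#'   a temporary directory)
#' @return the step table, invisibly
#' @export
run_predict_steps <- function(config, out_dir = NULL) {
  config <- if (inherits(config, "run_config")) config else run_config(config)
  out_dir <- out_dir %||% config$cfg$output_dir %||% tempfile("mtdimer_")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  env <- cfg_env(config)
  construct <- cfg_construct(config)
  forces <- as.numeric(config$cfg$forces %||% numeric(0))
  labels <- config$cfg$transitions %||%
    c("unfold_one", "rupture_folded", "rupture_unfold_rest")
  tab <- predicted_step_table(construct,
                              standard_transitions(construct, labels),
                              forces = forces, env = env)
  utils::write.table(tab, file.path(out_dir, "steps.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  write_result_json(c(result_meta(config, seed = NULL),
                      list(table = tab)),
                    file.path(out_dir, "steps.json"))
  invisible(tab)
}

#' Generate synthetic dwell tables from a configuration
#'
#' Wraps [generate_dwells()] for every configured force and writes
#' `dwells.tsv` plus metadata.
#'
#' @inheritParams run_predict_steps
#' @return the dwell table, invisibly
#' @export
run_generate <- function(config, out_dir = NULL) {
  config <- if (inherits(config, "run_config")) config else run_config(config)
  out_dir <- out_dir %||% config$cfg$output_dir %||% tempfile("mtdimer_")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  env <- cfg_env(config)
  bond <- cfg_bell(config$cfg$kinetics$bond)
  seed <- config$cfg$seed %||% 1L
  forces <- as.numeric(config$cfg$forces)
  n <- config$cfg$n %||% 50
  rows <- lapply(seq_along(forces), function(i)
    generate_dwells(bond, forces[i], n,
                    censor_at = config$cfg$censor_at,
                    rng_seed = seed + i - 1L, env = env))
  dw <- do.call(rbind, rows)
  write_dwells(dw, file.path(out_dir, "dwells.tsv"))
  write_result_json(result_meta(config, seed = seed),
                    file.path(out_dir, "dwells.json"))
  invisible(dw)
}

#' Simulate traces with ground truth from a configuration
#'
#' Wraps [generate_trace()]: writes `trace_<i>.tsv` files, a ground-truth
#' JSON sidecar per trace, and run metadata.
#'
#' @inheritParams run_predict_steps
#' @return list of `generate_trace()` results, invisibly
#' @export
run_simulate <- function(config, out_dir = NULL) {
  config <- if (inherits(config, "run_config")) config else run_config(config)
  out_dir <- out_dir %||% config$cfg$output_dir %||% tempfile("mtdimer_")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  env <- cfg_env(config)
  construct <- cfg_construct(config)
  model <- cfg_model(config, length(construct$rod$domains))
  protocol <- cfg_protocol(config)
  noise <- cfg_noise(config)
  seed <- config$cfg$seed %||% 1L
  n_runs <- config$cfg$n_runs %||% 1L
  out <- vector("list", n_runs)
  for (i in seq_len(n_runs)) {
    out[[i]] <- generate_trace(construct, model, protocol, noise,
                               rng_seed = seed + i - 1L, env = env)
    write_trace(out[[i]]$trace,
                file.path(out_dir, sprintf("trace_%03d.tsv", i)))
    write_result_json(c(result_meta(config, seed = seed + i - 1L),
                        list(truth = out[[i]]$truth,
                             holds = attr(out[[i]]$trace, "metadata")$holds)),
                      file.path(out_dir, sprintf("truth_%03d.json", i)))
  }
  invisible(out)
}

#' Analyze trace files from a configuration
#'
#' Reads the trace files, detects step events and -- for jump protocols --
#' extracts dwell records; writes `events.tsv` and `dwells.tsv`.
#'
#' @inheritParams run_predict_steps
#' @param inputs character vector of trace file paths
#' @param min_step minimal accepted step in nm
#' @return list with `events` and (for jump protocols) `dwells`, invisibly
#' @export
run_analyze <- function(config, inputs, out_dir = NULL, min_step = 20) {
  config <- if (inherits(config, "run_config")) config else run_config(config)
  out_dir <- out_dir %||% config$cfg$output_dir %||% tempfile("mtdimer_")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  protocol <- cfg_protocol(config)
  traces <- lapply(inputs, read_trace)
  if (protocol$kind == "jump") {
    # recover hold windows from the ground-truth sidecars when present
    for (i in seq_along(traces)) {
      sidecar <- sub("trace_([0-9]+)\\.tsv$", "truth_\\1.json", inputs[i])
      if (file.exists(sidecar)) {
        js <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
        if (!is.null(js$holds)) {
          md <- attr(traces[[i]], "metadata"); md$holds <- js$holds
          attr(traces[[i]], "metadata") <- md
        }
      }
    }
    dwells <- extract_dwell_times(traces, protocol, min_step = min_step)
    write_dwells(dwells, file.path(out_dir, "dwells.tsv"))
  } else dwells <- NULL
  events <- do.call(rbind, lapply(seq_along(traces), function(i) {
    fit <- detect_steps(traces[[i]], min_step = min_step)
    if (nrow(fit$events)) cbind(trace = i, fit$events) else NULL
  }))
  if (is.null(events))
    events <- data.frame(trace = integer(), time_s = numeric(),
                         force_pN = numeric(), step_nm = numeric(),
                         index = integer())
  utils::write.table(events, file.path(out_dir, "events.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  write_result_json(result_meta(config, seed = config$cfg$seed),
                    file.path(out_dir, "analysis.json"))
  invisible(list(events = events, dwells = dwells))
}

#' Fit lifetimes and the Bell model from a dwell table
#'
#' Wraps [bell_from_dwells()]: per-force bootstrap lifetime estimates and a
#' Bell fit with bootstrap-propagated uncertainties, written to
#' `fits.json`.
#'
#' @inheritParams run_predict_steps
#' @param dwell_file path to a dwell table (see [read_dwells()]); when
#'   `NULL` a `dwells` entry under the config's `output_dir` is used
#' @return the `bell_fit`, invisibly
#' @export
run_fit <- function(config, dwell_file = NULL, out_dir = NULL) {
  config <- if (inherits(config, "run_config")) config else run_config(config)
  out_dir <- out_dir %||% config$cfg$output_dir %||% tempfile("mtdimer_")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  env <- cfg_env(config)
  dwell_file <- dwell_file %||% file.path(out_dir, "dwells.tsv")
  dwells <- read_dwells(dwell_file)
  b <- config$cfg$bootstrap
  cfg_boot <- bootstrap_config(b$n_resamples %||% 20,
                               b$seed %||% config$cfg$seed)
  fit <- bell_from_dwells(dwells, cfg_boot, env = env)
  ests <- lapply(fit$estimates, function(e)
    list(force_pN = e$force_pN, tau_s = e$tau_s, tau_sd = e$tau_sd,
         tau_se = e$tau_se, k_per_s = e$k_rupture, k_sd = e$k_sd,
         k_se = e$k_se, n_obs = e$n_obs, n_censored = e$n_censored))
  write_result_json(c(result_meta(config, seed = cfg_boot$rng_seed),
                      list(bell = list(k0_per_s = fit$params$k0,
                                       delta_nm = fit$params$delta,
                                       k0_sd = fit$se[["k0"]],
                                       delta_sd = fit$se[["delta"]]),
                           lifetimes = ests)),
                    file.path(out_dir, "fits.json"))
  invisible(fit)
}
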