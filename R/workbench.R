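# Run-directory workbench: config handling, manifests, and the four
# entry points (simulate / train / analyze / baseline) that the
# command-line script in inst/scripts/bcrnn.R wraps.

#' Read a run configuration
#'
#' @param config a named list (returned as-is), or the path of a YAML or
#'   JSON configuration file.
#' @return named list.
#' @export
read_run_config <- function(config) {
  if (is.list(config)) return(config)
  stopifnot(is.character(config), file.exists(config))
  ext <- tolower(tools::file_ext(config))
  if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is required for YAML configs")
    yaml::read_yaml(config)
  } else {
    jsonlite::fromJSON(config, simplifyVector = TRUE)
  }
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config[order(names(config))], tmp,
                       auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

new_run_dir <- function(base_dir, config) {
  h <- substr(config_hash(config), 1L, 8L)
  dir <- file.path(base_dir, paste0(format(Sys.time(), "%Y%m%d-%H%M%S"),
                                    "-", h))
  i <- 0L
  while (dir.exists(dir)) {  # never overwrite an existing run
    i <- i + 1L
    dir <- file.path(base_dir, paste0(format(Sys.time(), "%Y%m%d-%H%M%S"),
                                      "-", h, "-", i))
  }
  dir.create(dir, recursive = TRUE)
  dir
}

#' Write a run manifest
#'
#' Lists the run's configuration, seed, package version, timestamp and
#' the MD5 hash of every produced file; a manifest plus the package
#' suffices to reproduce the run bit-for-bit on one platform.
#'
#' @param run_dir run directory.
#' @param config the configuration list used.
#' @param files character vector of produced file paths.
#' @return the manifest path, invisibly.
#' @export
write_manifest <- function(run_dir, config, files) {
  files <- files[file.exists(files)]
  manifest <- list(
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    package_version = as.character(utils::packageVersion("bcrnn")),
    config = config,
    config_hash = config_hash(config),
    files = as.list(stats::setNames(unname(tools::md5sum(files)),
                                    basename(files))))
  path <- file.path(run_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

resolve_system <- function(config) {
  case <- config$case %||% "case1"
  switch(case,
         case1 = case1_system(),
         case2 = case2_system(),
         custom = {
           if (is.null(config$system_json))
             stop("config error at 'system_json': custom case needs a system file")
           read_system_json(config$system_json)
         },
         stop("config error at 'case': must be case1, case2 or custom"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

generate_from_config <- function(config) {
  case <- config$case %||% "case1"
  seed <- as.integer(config$seed %||% 1L)
  noise <- as.numeric(config$noise %||% if (case == "case2") 0.05 else 0)
  n_points <- as.integer(config$n_points %||% 100L)
  if (case == "case1") {
    generate_case1(n_datasets = as.integer(config$n_datasets %||% 100L),
                   noise_fraction = noise, seed = seed,
                   n_points = n_points,
                   t_end = as.numeric(config$t_end %||% 40))
  } else if (case == "case2") {
    generate_case2(n_train = as.integer(config$n_datasets %||% 300L),
                   noise_fraction = noise, seed = seed,
                   n_points = n_points,
                   t_end = as.numeric(config$t_end %||% 10))
  } else {
    sys <- resolve_system(config)
    times <- seq(0, as.numeric(config$t_end %||% 40),
                 length.out = n_points)
    lo <- as.numeric(config$y0_min %||% 0)
    hi <- as.numeric(config$y0_max %||% 1)
    generate_collection(sys, function() stats::runif(n_species(sys), lo, hi),
                        as.integer(config$n_datasets %||% 100L),
                        noise, seed, times)
  }
}

#' Simulate a synthetic corpus into a run directory
#'
#' Writes one trajectory CSV per dataset, the train/validation split,
#' the generating system JSON, and a manifest.
#'
#' @param config list or config file path; keys: `case` (case1 | case2 |
#'   custom), `system_json` (custom only), `n_datasets`, `noise`,
#'   `seed`, `n_points`, `t_end`, `out_dir`.
#' @return the run directory path, invisibly.
#' @export
run_simulate <- function(config) {
  config <- read_run_config(config)
  coll <- generate_from_config(config)
  run_dir <- new_run_dir(config$out_dir %||% ".", config)
  files <- character()
  for (i in seq_along(coll$datasets)) {
    f <- file.path(run_dir, sprintf("dataset_%04d.csv", i))
    write_trajectory_csv(coll$datasets[[i]], f)
    files <- c(files, f)
  }
  split_file <- file.path(run_dir, "split.json")
  jsonlite::write_json(list(train = coll$train_indices,
                            validation = coll$validation_indices),
                       split_file, auto_unbox = FALSE)
  sys_file <- file.path(run_dir, "system.json")
  write_system_json(coll$system, sys_file)
  write_manifest(run_dir, config, c(files, split_file, sys_file))
  invisible(run_dir)
}

#' Load a corpus written by [run_simulate()]
#' @param dir run directory.
#' @return a [dataset_collection()].
#' @export
load_simulated <- function(dir) {
  split <- jsonlite::fromJSON(file.path(dir, "split.json"))
  files <- sort(list.files(dir, pattern = "^dataset_\\d+\\.csv$",
                           full.names = TRUE))
  datasets <- lapply(files, read_trajectory_csv)
  sys_file <- file.path(dir, "system.json")
  sys <- if (file.exists(sys_file)) read_system_json(sys_file) else NULL
  dataset_collection(datasets, split$train, split$validation, system = sys)
}

control_from_config <- function(config) {
  defaults <- formals(crnn_control)
  keys <- intersect(names(config), names(defaults))
  do.call(crnn_control, config[keys])
}

#' Train a Bayesian CRNN from a configuration
#'
#' Loads (or regenerates) the corpus, trains with [bcrnn()], and writes
#' the loss trace CSV, the posterior ensemble as JSON-lines (one
#' parameter draw per line), run metadata, an end-of-run checkpoint and
#' a manifest into a fresh run directory.
#'
#' @param config list or config file path; keys: `data_dir` (from
#'   [run_simulate()]) or the generation keys of [run_simulate()];
#'   `n_hidden`, `t_max`, `out_dir`, `resume_from`, `checkpoint_every`,
#'   plus any [crnn_control()] field (`optimizer`, `loss`, `max_epochs`,
#'   ...).
#' @return list with `run_dir` and the fitted `bcrnn` object, invisibly.
#' @export
run_train <- function(config) {
  config <- read_run_config(config)
  coll <- if (!is.null(config$data_dir)) {
    if (!dir.exists(config$data_dir))
      stop("config error at 'data_dir': no such directory '",
           config$data_dir, "'")
    load_simulated(config$data_dir)
  } else {
    generate_from_config(config)
  }
  control <- control_from_config(config)
  run_dir <- new_run_dir(config$out_dir %||% ".", config)
  fit <- bcrnn(coll,
               n_hidden = if (!is.null(config$n_hidden))
                 as.integer(config$n_hidden) else NULL,
               control = control,
               t_max = config$t_max,
               resume = config$resume_from,
               checkpoint_path = file.path(run_dir, "checkpoint.json"),
               checkpoint_every = as.integer(config$checkpoint_every %||% 1000L),
               verbose = isTRUE(config$verbose))
  trace_file <- file.path(run_dir, "loss_trace.csv")
  utils::write.csv(fit$loss_trace, trace_file, row.names = FALSE)
  ens_file <- file.path(run_dir, "ensemble.jsonl")
  con <- file(ens_file, "w")
  for (i in seq_len(nrow(fit$samples)))
    writeLines(write_crnn_json(sample_params(fit, i)), con)
  close(con)
  meta_file <- file.path(run_dir, "run_metadata.json")
  jsonlite::write_json(
    list(seed = control$seed, config_hash = config_hash(config),
         sampling_start_epoch = fit$sampling_start_epoch,
         epochs_run = nrow(fit$loss_trace),
         n_samples = nrow(fit$samples), shortfall = fit$shortfall),
    meta_file, auto_unbox = TRUE, digits = NA, na = "null")
  write_manifest(run_dir, config, c(trace_file, ens_file, meta_file))
  invisible(list(run_dir = run_dir, fit = fit))
}

#' Analyze a posterior ensemble from a configuration
#'
#' Wraps [write_analysis()] and [posterior_predictive()]: writes the
#' recovery/score matrices, rate posteriors, summary JSON, a posterior
#' predictive fan CSV, and a manifest.
#'
#' @param config list or file path; keys: `ensemble_dir` (a [run_train()]
#'   run directory), `threshold`, `draws`, `case` or `system_json`
#'   (truth for matching, optional), `y0`, `t_end`, `n_points`,
#'   `out_dir`.
#' @param fit optionally, a [bcrnn()] object instead of `ensemble_dir`.
#' @return the run directory, invisibly.
#' @export
run_analyze <- function(config, fit = NULL) {
  config <- read_run_config(config)
  if (is.null(fit)) {
    if (is.null(config$ensemble_dir))
      stop("config error at 'ensemble_dir': needed when no fit is supplied")
    lines <- readLines(file.path(config$ensemble_dir, "ensemble.jsonl"))
    if (!length(lines)) stop("empty ensemble")
    fit <- crnn_ensemble(lapply(lines, read_crnn_json))
  }
  draws <- as.integer(config$draws %||% 500L)
  if (draws > nrow(fit$samples))
    stop("ensemble too small: ", nrow(fit$samples), " samples < ",
         draws, " requested draws")
  truth <- tryCatch(resolve_system(config), error = function(e) NULL)
  run_dir <- new_run_dir(config$out_dir %||% ".", config)
  files <- write_analysis(fit, run_dir,
                          threshold = as.numeric(config$threshold %||% 1e-4),
                          truth = truth)
  fan_file <- file.path(run_dir, "posterior_predictive.csv")
  if (!is.null(config$y0) || !is.null(truth)) {
    y0 <- as.numeric(config$y0 %||%
                       c(0.5, 0.5, numeric(length(fit$species) - 2L)))
    times <- seq(0, as.numeric(config$t_end %||% 40),
                 length.out = as.integer(config$n_points %||% 100L))
    fan <- posterior_predictive(fit, y0, times, n_draws = draws)
    long <- do.call(rbind, lapply(seq_len(dim(fan$draws)[1L]), function(d)
      data.frame(draw = d, time = fan$times, fan$draws[d, , ],
                 check.names = FALSE)))
    utils::write.csv(long, fan_file, row.names = FALSE)
    files <- c(files, fan_file)
  }
  write_manifest(run_dir, config, files)
  invisible(run_dir)
}

#' Run the extrapolation baseline comparison from a configuration
#'
#' Trains the CRNN, the dense neural ODE and the LSTM on the same
#' corpus restricted to `t <= split`, evaluates the extrapolation MAPE
#' on `(split, end]` via [extrapolation_experiment()], and writes the
#' MAPE table plus manifest.
#'
#' @param config list or file path; keys: generation keys (or
#'   `data_dir`), `split` (default 30), `end` (default 40), `epochs`
#'   overrides per model (`crnn_epochs`, `node_epochs`, `lstm_epochs`),
#'   `lstm_hidden`, `out_dir`, `seed`.
#' @return list with `run_dir` and the MAPE table, invisibly.
#' @export
run_baseline <- function(config) {
  config <- read_run_config(config)
  coll <- if (!is.null(config$data_dir)) load_simulated(config$data_dir)
          else generate_from_config(config)
  split <- as.numeric(config$split %||% 30)
  t_end <- as.numeric(config$end %||% 40)
  seed <- as.integer(config$seed %||% 1L)
  control <- control_from_config(config)
  control$max_epochs <- as.integer(config$crnn_epochs %||% control$max_epochs)
  fit <- bcrnn(coll, control = control, t_max = split,
               n_hidden = if (!is.null(config$n_hidden))
                 as.integer(config$n_hidden) else NULL)
  node <- train_dense_node(coll, t_max = split,
                           epochs = as.integer(config$node_epochs %||% 2000L),
                           seed = seed)
  lstm <- train_lstm(coll, t_max = split,
                     hidden = as.integer(config$lstm_hidden %||% 200L),
                     epochs = as.integer(config$lstm_epochs %||% 2000L),
                     seed = seed)
  # clean reference trajectory from a validation initial condition
  ref_idx <- coll$validation_indices[1L]
  sys <- coll$system
  if (is.null(sys)) stop("baseline comparison needs the generating system")
  ref <- simulate_system(sys, coll$datasets[[ref_idx]]$y0,
                         coll$datasets[[ref_idx]]$times)
  table <- extrapolation_experiment(list(crnn = fit, dense_node = node,
                                         lstm = lstm),
                                    ref, t_split = split)
  run_dir <- new_run_dir(config$out_dir %||% ".", config)
  tab_file <- file.path(run_dir, "extrapolation_mape.csv")
  utils::write.csv(table, tab_file, row.names = FALSE)
  write_manifest(run_dir, config, tab_file)
  invisible(list(run_dir = run_dir, table = table))
}
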