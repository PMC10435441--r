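PIPELINE_KEYS <- list(
  global = c("seed", "out_dir", "verbosity", "stages"),
  gen_data = c("n_runs", "duration_s", "film_onset_s", "film_max_um",
               "hr_rest_bpm", "hr_peak_bpm", "noise_sd"),
  features = c("window_s", "step_s", "wavelengths", "include_freq",
               "fuse_imu"),
  train = c("folds", "nrounds", "learning_rate", "max_depth", "top_k"),
  onset = c("channel", "smooth_s", "direction", "threshold", "sustain_s"),
  simulate = c("wavelengths", "n_photons", "film_um", "separation_mm",
               "theta_in_deg", "detect"),
  map = c("wavelengths", "n_photons", "films_um", "angles_deg", "detect")
)

#' Pipeline configuration
#'
#' Validated per-stage parameter blocks with a single global seed. Unknown
#' keys are rejected before any stage runs; the configuration round-trips
#' through YAML/JSON serialization unchanged.
#'
#' @param config named list (stage blocks under `gen_data`, `features`,
#'   `train`, `onset`, `simulate`, `map`; global keys `seed`, `out_dir`,
#'   `stages`, `verbosity`), or a path to a YAML or JSON file holding one.
#' @return validated list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.json$", config))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  stage_names <- setdiff(names(PIPELINE_KEYS), "global")
  unknown <- setdiff(names(config), c(PIPELINE_KEYS$global, stage_names))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  for (s in stage_names) {
    bad <- setdiff(names(config[[s]]), PIPELINE_KEYS[[s]])
    if (length(bad))
      stop("unknown config key(s) in '", s, "': ", paste(bad, collapse = ", "))
  }
  defaults <- list(seed = 1L, out_dir = "ppgsweat_out", verbosity = 0L,
                   stages = c("gen_data", "features", "train", "onset"))
  for (k in names(defaults)) config[[k]] <- config[[k]] %||% defaults[[k]]
  structure(config, class = "pipeline_config")
}

pipe_log <- function(cfg, level, ...) {
  if ((cfg$verbosity %||% 0) >= level) message("[ppgsweat] ", ...)
}

#' Run the end-to-end synthetic pipeline
#'
#' Executes the configured stages in order (`gen_data` -> `features` ->
#' `train` -> `onset`, plus optional `simulate`/`map`), writing every artifact
#' under `out_dir` with provenance (seed, configuration hash) and returning a
#' manifest of produced files. A stage failure aborts with a stage-named
#' error; partial outputs are retained with a `.partial` marker file.
#'
#' @param config a [pipeline_config()] (or anything it accepts).
#' @return invisible list: `manifest` (data.frame of stage/artifact paths),
#'   `results` (in-memory stage outputs).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  cfg <- pipeline_config(unclass(config))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  provenance <- list(seed = cfg$seed,
                     config_hash = config_hash(cfg),
                     package_version = as.character(utils::packageVersion("ppgsweat")))
  manifest <- data.frame(stage = character(0), artifact = character(0))
  results <- list()
  add <- function(stage, path) {
    manifest <<- rbind(manifest, data.frame(stage = stage, artifact = path))
  }
  marker <- file.path(cfg$out_dir, ".partial")
  file.create(marker)
  on.exit(if (file.exists(marker)) invisible(NULL), add = TRUE)

  run_stage <- function(stage, fn) {
    pipe_log(cfg, 1, "stage: ", stage)
    tryCatch(fn(), error = function(e)
      stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  recordings <- NULL
  if ("gen_data" %in% cfg$stages) run_stage("gen_data", function() {
    g <- cfg$gen_data %||% list()
    prof <- run_profile(duration_s = g$duration_s %||% 1320,
                        film_onset_s = g$film_onset_s %||% 600,
                        film_max_um = g$film_max_um %||% 300,
                        hr_rest_bpm = g$hr_rest_bpm %||% 75,
                        hr_peak_bpm = g$hr_peak_bpm %||% 155,
                        noise_sd = g$noise_sd %||% 0.002)
    n_runs <- g$n_runs %||% 4
    recordings <<- lapply(seq_len(n_runs), function(i)
      generate_run(prof, seed = derive_seed(cfg$seed, i)))
    for (i in seq_along(recordings)) {
      p <- file.path(cfg$out_dir, sprintf("run_%02d.csv", i))
      write_recording(recordings[[i]], p)
      add("gen_data", p)
    }
    results$recordings <<- recordings
  })

  if ("features" %in% cfg$stages) run_stage("features", function() {
    if (is.null(recordings)) stop("no recordings (run gen_data first)")
    f <- cfg$features %||% list()
    win <- window_spec(f$window_s %||% 210, f$step_s %||% 20)
    wl <- f$wavelengths %||% c("970", "1450")
    feat <- lapply(recordings, function(r)
      extract_window_features(r, 0, win, wavelengths = as.character(wl),
                              include_freq = f$include_freq %||% TRUE,
                              fuse_imu = f$fuse_imu %||% FALSE))
    tab <- do.call(rbind, feat)
    p <- file.path(cfg$out_dir, "features_start_window.csv")
    write.csv(tab, p, row.names = FALSE)
    add("features", p)
    results$features <<- tab
  })

  if ("train" %in% cfg$stages) run_stage("train", function() {
    if (is.null(recordings)) stop("no recordings (run gen_data first)")
    tr <- cfg$train %||% list()
    f <- cfg$features %||% list()
    win <- window_spec(f$window_s %||% 210, f$step_s %||% 20)
    sweep <- gap_sweep(recordings, win, folds = tr$folds %||% 4,
                       params = gbt_params(
                         nrounds = tr$nrounds %||% 100,
                         learning_rate = tr$learning_rate %||% 0.01,
                         max_depth = tr$max_depth %||% 2),
                       seed = cfg$seed,
                       wavelengths = as.character(f$wavelengths %||% c("970", "1450")),
                       include_freq = f$include_freq %||% TRUE)
    p <- file.path(cfg$out_dir, "gap_sweep.json")
    jsonlite::write_json(c(list(steps = sweep$steps), provenance), p,
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    add("train", p)
    rk <- rank_features(sweep, top_k = tr$top_k %||% 20)
    p2 <- file.path(cfg$out_dir, "feature_importance.csv")
    write.csv(data.frame(feature = rownames(rk$table), rk$table,
                         check.names = FALSE), p2, row.names = FALSE)
    add("train", p2)
    results$sweep <<- sweep
  })

  if ("onset" %in% cfg$stages) run_stage("onset", function() {
    if (is.null(recordings)) stop("no recordings (run gen_data first)")
    o <- cfg$onset %||% list()
    calls <- lapply(seq_along(recordings), function(i) {
      x <- ppg_channel(recordings[[i]], o$channel %||% "1450")
      tr <- trend_series(x, recordings[[i]]$fs, o$smooth_s %||% 180)
      oc <- detect_onset(tr, o$direction %||% -1, o$threshold %||% 2,
                         o$sustain_s %||% 60)
      list(run = i, onset_s = oc$onset_s, confidence = oc$confidence,
           true_onset_s = recordings[[i]]$meta$t0_s)
    })
    p <- file.path(cfg$out_dir, "onset_calls.json")
    jsonlite::write_json(c(list(calls = calls), provenance), p,
                         auto_unbox = TRUE, digits = NA)
    add("onset", p)
    results$onset <<- calls
  })

  if ("simulate" %in% cfg$stages) run_stage("simulate", function() {
    s <- cfg$simulate %||% list()
    wl <- sort(as.numeric(s$wavelengths %||% c(970, 1450)))
    stack <- build_skin_stack(grid = wavelength_grid(wl),
                              film_thickness_mm = (s$film_um %||% 0) / 1000)
    geo <- sensor_geometry(separation_mm = s$separation_mm %||% 3.5,
                           theta_in_deg = s$theta_in_deg %||% 0)
    spec <- simulate_reflectance_spectrum(
      stack, geo, sim_config(n_photons = s$n_photons %||% 2e4, seed = cfg$seed),
      detect = s$detect %||% "aperture")
    p <- file.path(cfg$out_dir, "reflectance_spectrum.csv")
    write.csv(spec, p, row.names = FALSE)
    add("simulate", p)
    results$spectrum <<- spec
  })

  if ("map" %in% cfg$stages) run_stage("map", function() {
    m <- cfg$map %||% list()
    mp <- film_angle_map(
      films_um = m$films_um %||% seq(0, 500, length.out = 11),
      angles_deg = m$angles_deg %||% seq(0, 45, length.out = 10),
      wavelengths = as.numeric(m$wavelengths %||% c(970, 1450)),
      config = sim_config(n_photons = m$n_photons %||% 2e4, seed = cfg$seed),
      detect = m$detect %||% "total")
    p <- file.path(cfg$out_dir, "film_angle_map.json")
    jsonlite::write_json(c(list(
      films_um = mp$films_um, angles_deg = mp$angles_deg,
      wavelengths = mp$wavelengths,
      reflectance = mp$reflectance, se = mp$se), provenance),
      p, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
    add("map", p)
    results$map <<- mp
  })

  mpath <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(c(list(artifacts = manifest), provenance), mpath,
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  file.remove(marker)
  invisible(list(manifest = manifest, results = results))
}

config_hash <- function(cfg) {
  # stable content hash without extra dependencies
  s <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA,
                        force = TRUE)
  raw <- utf8ToInt(as.character(s))
  h <- 5381
  for (b in raw) h <- (h * 33 + b) %% 2^31
  sprintf("%08x", h)
}

#' Command-line entry point
#'
#' Subcommand dispatcher used by the installed `ppgsweat` script
#' (`inst/cli/ppgsweat`). Subcommands: `simulate`, `map`, `gen-data`,
#' `extract-features`, `train-windows`, `detect-onset`, `run-all`; each takes
#' `--config file.yaml` (YAML or JSON) plus overrides: `--seed`, `--out`,
#' `--photons` (simulate/map stages), `--v`/`--vv` verbosity.
#'
#' @param args character vector (default: the command line).
#' @return exit status, invisibly.
#' @export
ppgsweat_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: ppgsweat <command> [--config cfg.yaml] [--seed S] [--out dir]",
    "commands: simulate | map | gen-data | extract-features | train-windows |",
    "          detect-onset | run-all", sep = "\n")
  if (!length(args)) { message(usage); return(invisible(1L)) }
  cmd <- args[1]; args <- args[-1]
  opt <- list()
  i <- 1L
  while (i <= length(args)) {
    if (!startsWith(args[i], "--")) stop("unexpected argument: ", args[i])
    key <- sub("^--", "", args[i])
    opt[[key]] <- if (i < length(args) && !startsWith(args[i + 1], "--")) {
      i <- i + 1L; args[i]
    } else TRUE
    i <- i + 1L
  }
  cfg <- if (!is.null(opt$config)) pipeline_config(opt$config)
         else pipeline_config()
  if (!is.null(opt$seed)) cfg$seed <- as.integer(opt$seed)
  if (!is.null(opt$out)) cfg$out_dir <- opt$out
  if (!is.null(opt$photons)) {
    cfg$simulate$n_photons <- as.numeric(opt$photons)
    cfg$map$n_photons <- as.numeric(opt$photons)
  }
  if (isTRUE(opt$v)) cfg$verbosity <- 1L
  if (isTRUE(opt$vv)) cfg$verbosity <- 2L
  stages <- switch(cmd,
    "simulate" = "simulate", "map" = "map", "gen-data" = "gen_data",
    "extract-features" = c("gen_data", "features"),
    "train-windows" = c("gen_data", "train"),
    "detect-onset" = c("gen_data", "onset"),
    "run-all" = c("gen_data", "features", "train", "onset"),
    stop("unknown command: ", cmd, "\n", usage))
  cfg$stages <- stages
  run_pipeline(cfg)
  invisible(0L)
}
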