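#' Run the full three-stage pipeline
#'
#' Executes grouping, normalization and effect identification in order
#' on an experiment read from disk (or passed in memory), writing every
#' stage's output as CSV so each stage can be re-loaded and re-run
#' independently. A plain-text log recording the seeds, threshold,
#' sigma^2 and iteration counts is written alongside.
#'
#' @param config a list (or path to a YAML file) with entries:
#'   \describe{
#'     \item{metadata}{path to the metadata CSV (see
#'       [read_experiment()]); alternatively supply `experiment`.}
#'     \item{experiment}{a [pm_experiment()] (overrides `metadata`).}
#'     \item{control}{length-2 vector, control condition.}
#'     \item{out_dir}{output directory.}
#'     \item{threshold}{activity threshold for grouping (optional).}
#'     \item{background_well}{negative-control well to subtract
#'       (optional; off by default).}
#'     \item{max_iter, seed}{EM settings.}
#'     \item{stabilize, proportion}{stabilization settings
#'       (defaults TRUE, 0.5).}
#'     \item{sigma2, n_iter, burn_in, n_chains}{sampler settings
#'       (defaults 100, 5000, 1000, 2).}
#'     \item{tstar_stride, tstar}{time thinning (default stride 16).}
#'     \item{wells}{wells to analyse in the effects stage (default
#'       all).}
#'   }
#' @return invisibly, a list with `groupings`, `normalization`,
#'   `effects` and the output paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading a YAML config requires the 'yaml' package")
    }
    config <- yaml::read_yaml(config)
  }
  get <- function(name, default = NULL) config[[name]] %||% default
  out_dir <- get("out_dir", ".")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_file <- file.path(out_dir, "pipeline.log")
  logmsg <- function(...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(...))
    message(line)
    cat(line, "\n", file = log_file, append = TRUE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  experiment <- stage("input", {
    if (!is.null(get("experiment"))) get("experiment") else {
      if (is.null(get("metadata"))) {
        stop("config needs 'metadata' (path) or 'experiment'")
      }
      read_experiment(get("metadata"), get("control"))
    }
  })
  if (!is.null(get("background_well"))) {
    experiment$plates <- lapply(experiment$plates, subtract_background,
                                control_well_id = get("background_well"))
    logmsg("background well %s subtracted", get("background_well"))
  }
  logmsg("experiment: %d plates, %d wells, %d time points",
         length(experiment$plates), length(experiment$plates[[1]]$wells),
         length(experiment$times))

  threshold <- get("threshold")
  seed <- get("seed", 1)
  groupings <- stage("grouping", {
    lapply(experiment$plates, group_plate, threshold = threshold,
           max_iter = get("max_iter", 50), seed = seed)
  })
  labels_file <- file.path(out_dir, "labels.csv")
  write_labels(groupings, labels_file)
  logmsg("grouping: threshold=%s, seed=%d, active counts: %s",
         if (is.null(threshold)) "none" else format(threshold), seed,
         paste(vapply(groupings, count_active, integer(1)), collapse = " "))

  normalization <- stage("normalization", {
    normalize_experiment(experiment, groupings,
                         stabilize = get("stabilize", TRUE),
                         proportion = get("proportion", 0.5))
  })
  factors_file <- file.path(out_dir, "factors.csv")
  write_factors(normalization, factors_file)
  norm_dir <- file.path(out_dir, "normalized")
  dir.create(norm_dir, showWarnings = FALSE)
  for (p in normalization$experiment$plates) {
    write_plate(p, file.path(norm_dir, paste0("plate_", p$array_id, ".csv")))
  }
  logmsg("normalization: stabilize=%s, factors in [%.3f, %.3f]",
         get("stabilize", TRUE), min(normalization$factors$nf),
         max(normalization$factors$nf))

  tstar <- get("tstar") %||%
    thin_timepoints(experiment$times, stride = get("tstar_stride", 16))
  effects <- stage("effects", {
    run_effects(normalization, tstar = tstar, wells = get("wells"),
                sigma2 = get("sigma2", 100),
                n_iter = get("n_iter", 5000),
                burn_in = get("burn_in", 1000),
                n_chains = get("n_chains", 2), seed = seed)
  })
  effects_file <- file.path(out_dir, "effects.csv")
  write_effects(effects, effects_file)
  logmsg("effects: sigma2=%s, n_iter=%d, burn_in=%d, chains=%d, |T*|=%d",
         format(get("sigma2", 100)), get("n_iter", 5000),
         get("burn_in", 1000), get("n_chains", 2), length(tstar))

  invisible(list(
    groupings = groupings, normalization = normalization, effects = effects,
    paths = list(labels = labels_file, factors = factors_file,
                 normalized = norm_dir, effects = effects_file,
                 log = log_file)
  ))
}
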