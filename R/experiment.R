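# Experiment orchestration: one call that trains (or loads), applies
# variant transforms, runs the requested metrics, and writes tabular
# reports.

#' Run a configured experiment end to end
#'
#' Trains a network (or restores a checkpoint), runs the requested
#' metrics, and writes one CSV per metric plus a JSON summary to the
#' output directory. Every output embeds the configuration hash and
#' seed, and a run is reproducible from its configuration alone. A
#' failing metric is caught and reported without aborting the others.
#'
#' @param config named list with elements:
#'   \describe{
#'     \item{seed}{integer, mandatory.}
#'     \item{variant}{model variant (default "EI2/1").}
#'     \item{n_exc}{excitatory population size (default 144).}
#'     \item{n_stimuli}{training stimuli (default 400000).}
#'     \item{n_scenes}{synthetic scenes to generate (default 10).}
#'     \item{scene_size}{scene side in pixels (default 128).}
#'     \item{metrics}{character vector from "sparseness", "tuning",
#'       "ei_ratio", "correlation"; default all.}
#'     \item{metric_stimuli}{patches for the sparseness/correlation
#'       ensemble (default 1000).}
#'     \item{tuning_reps}{repetitions per grating condition (default 50).}
#'     \item{checkpoint}{optional path of a checkpoint to restore
#'       instead of training.}
#'     \item{out_dir}{output directory (default a tempdir subdir).}
#'   }
#'   Unknown keys are an error, guarding against silent parameter
#'   drift.
#' @return The output directory path, invisibly; the summary list as
#'   attribute \code{summary}.
#' @export
run_experiment <- function(config) {
  known <- c("seed", "variant", "n_exc", "n_stimuli", "n_scenes",
             "scene_size", "metrics", "metric_stimuli", "tuning_reps",
             "checkpoint", "out_dir")
  bad <- setdiff(names(config), known)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  if (is.null(config$seed)) stop("config$seed is mandatory")
  defaults <- list(variant = "EI2/1", n_exc = 144L, n_stimuli = 400000L,
                   n_scenes = 10L, scene_size = 128L,
                   metrics = c("sparseness", "tuning", "ei_ratio",
                               "correlation"),
                   metric_stimuli = 1000L, tuning_reps = 50L,
                   checkpoint = NULL,
                   out_dir = file.path(tempdir(),
                                       paste0("v1run_", config$seed)))
  for (k in setdiff(names(defaults), names(config)))
    config[[k]] <- defaults[[k]]

  cfg_hash <- .config_hash(config[setdiff(names(config), "out_dir")])
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)

  scenes <- generate_scene_set(config$n_scenes, size = config$scene_size)
  if (!is.null(config$checkpoint)) {
    net <- load_checkpoint(config$checkpoint)
  } else {
    net <- build_network(network_config(config$variant,
                                        n_exc = config$n_exc))
    tr <- train(net, scenes, n_stimuli = config$n_stimuli)
    net <- tr$net
    if (nrow(tr$log))
      .write_report(tr$log, config$out_dir, "training_log", cfg_hash,
                    config$seed)
  }

  summary <- list(config_hash = cfg_hash, seed = config$seed,
                  variant = config$variant, stimuli_seen = net$stim_count)
  errors <- character()
  run_metric <- function(name, fn) {
    tryCatch(fn(), error = function(e) {
      errors[[name]] <<- conditionMessage(e)
      NULL
    })
  }

  if ("sparseness" %in% config$metrics) run_metric("sparseness", function() {
    rates <- .sample_block(scenes, config$metric_stimuli, net$config)
    r <- present_batch(net, rates, plastic = FALSE)
    net <<- r$net
    sp <- population_sparseness(r$counts_e)
    .write_report(data.frame(stimulus = seq_along(sp), sparseness = sp),
                  config$out_dir, "sparseness", cfg_hash, config$seed)
    summary$sparseness <<- mean(sp, na.rm = TRUE)
  })
  if ("tuning" %in% config$metrics) run_metric("tuning", function() {
    tr <- measure_tuning(net, reps = config$tuning_reps)
    net <<- tr$net
    obw <- tuning_bandwidths(tr)
    .write_report(data.frame(neuron = seq_along(tr$preferred),
                             preferred_deg = tr$preferred, obw_deg = obw),
                  config$out_dir, "tuning", cfg_hash, config$seed)
    summary$odi <<- orientation_diversity_index(tr$preferred)
    summary$mean_obw <<- mean(obw, na.rm = TRUE)
  })
  if ("ei_ratio" %in% config$metrics) run_metric("ei_ratio", function() {
    er <- ei_ratio(net, scenes, n_scenes = min(config$metric_stimuli, 1000),
                   reps = 10)
    net <<- er$net
    .write_report(er$curve, config$out_dir, "ei_curve", cfg_hash,
                  config$seed)
    summary$ei_ratio <<- er$ratio
  })
  if ("correlation" %in% config$metrics) run_metric("correlation", function() {
    rates <- .sample_block(scenes, config$metric_stimuli, net$config)
    r <- present_batch(net, rates, plastic = FALSE)
    net <<- r$net
    cs <- correlation_vs_similarity(r$counts_e, net$proj$lgn_e$W)
    .write_report(data.frame(similarity = cs$bin_center,
                             correlation = cs$mean_correlation,
                             n_pairs = cs$n_pairs),
                  config$out_dir, "correlation_vs_similarity", cfg_hash,
                  config$seed)
    summary$mean_pairwise_correlation <<- cs$grand_mean
  })

  if (length(errors)) summary$errors <- as.list(errors)
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  save_checkpoint(net, file.path(config$out_dir, "final_network.rds"))
  structure(invisible(config$out_dir), summary = summary)
}

#' Aggregate metric summaries over a seed sweep
#'
#' Runs \code{\link{run_experiment}} once per seed and tabulates the
#' per-metric mean and standard deviation across runs.
#'
#' @param config base configuration (see \code{\link{run_experiment}}).
#' @param seeds integer vector (the reference experiments use 20
#'   repetitions).
#' @return List: \code{runs} (data.frame, one row per seed) and
#'   \code{summary} (mean and sd per metric).
#' @export
sweep_seeds <- function(config, seeds) {
  rows <- lapply(seeds, function(s) {
    config$seed <- s
    config$out_dir <- file.path(tempdir(), paste0("v1sweep_", s))
    sm <- attr(run_experiment(config), "summary")
    num <- vapply(sm, is.numeric, logical(1))
    as.data.frame(sm[num])
  })
  runs <- do.call(rbind, rows)
  metrics <- setdiff(names(runs), c("seed", "stimuli_seen"))
  list(runs = runs,
       summary = data.frame(
         metric = metrics,
         mean = vapply(metrics, function(m) mean(runs[[m]], na.rm = TRUE),
                       numeric(1)),
         sd = vapply(metrics, function(m) sd(runs[[m]], na.rm = TRUE),
                     numeric(1))))
}

.config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(paste(deparse(config[order(names(config))]), collapse = ""), f)
  unname(tools::md5sum(f))
}

.write_report <- function(df, dir, name, hash, seed) {
  path <- file.path(dir, paste0(name, ".csv"))
  con <- file(path, "w")
  writeLines(sprintf("# config_hash=%s seed=%d", hash, seed), con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  close(con)
  path
}
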