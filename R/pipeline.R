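#' Assemble a pipeline run configuration
#'
#' @param task `"task1"` or `"task2"`.
#' @param n_neurons population size for simulation runs.
#' @param mixture_weights generator mixture over models, see
#'   [make_population()].
#' @param n_trials_per_target trials per target (defaults to the task
#'   median: 42 for task1, 10 for task2).
#' @param baseline_rate,epoch_gains generator settings.
#' @param trial_table_path ingest an existing trial table instead of
#'   simulating (ground truth and recovery are then unavailable).
#' @param epoch epoch used for the response-field / modeling stages.
#' @param n_repeats,n_restarts split-half protocol settings.
#' @param n_shuffles label shuffles for the chance proportion.
#' @param seed master seed; all stage/neuron/repeat streams derive from it.
#' @param out_dir output directory.
#' @param grid_n,grid_span interpolation grid.
#' @param mask_only restrict pattern statistics to in-hull bins.
#' @param stages character subset of
#'   `c("simulate", "selectivity", "tuning", "fields", "models")`.
#' @return a `run_config` list (JSON-serializable).
#' @export
run_config <- function(task = "task2", n_neurons = 20,
                       mixture_weights = c(untuned = 1/6, `1` = 1/6, `2` = 1/6,
                                           `3` = 1/6, `4` = 1/6, `5` = 1/6),
                       n_trials_per_target = NULL, baseline_rate = 5,
                       epoch_gains = 40, trial_table_path = NULL,
                       epoch = "EM", n_repeats = 50, n_restarts = 10,
                       n_shuffles = 100, seed = 1, out_dir = tempfile("run"),
                       grid_n = 11, grid_span = 14, mask_only = FALSE,
                       stages = c("simulate", "selectivity", "tuning",
                                  "fields", "models")) {
  if (!task %in% c("task1", "task2")) stop_invalid("task must be task1 or task2")
  if (is.null(n_trials_per_target)) {
    n_trials_per_target <- if (task == "task2") 10 else 42
  }
  structure(list(task = task, n_neurons = n_neurons,
                 mixture_weights = mixture_weights,
                 n_trials_per_target = n_trials_per_target,
                 baseline_rate = baseline_rate, epoch_gains = epoch_gains,
                 trial_table_path = trial_table_path, epoch = epoch,
                 n_repeats = n_repeats, n_restarts = n_restarts,
                 n_shuffles = n_shuffles, seed = seed, out_dir = out_dir,
                 grid_n = grid_n, grid_span = grid_span,
                 mask_only = mask_only, stages = stages),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Simulates (or ingests) a session, then runs the selectivity screen, the
#' delta-PD tuning-geometry analysis (Task 1 layouts), response-field
#' characterization and the split-half model comparison, writing all
#' tables as tab-delimited text, summaries as JSON, and a manifest with
#' the full configuration and seed. Identical config + seed give
#' byte-identical outputs.
#'
#' @param config a [run_config()].
#' @return a `run_report` list with per-stage results, output paths, and
#'   any stage failures (recorded, not silently dropped).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  report <- list(config = config, outputs = character(), failures = list())
  add_output <- function(p) report$outputs <<- c(report$outputs, p)
  cfg <- if (config$task == "task2") make_task2() else make_task1()
  grid <- grid_spec(config$grid_n, config$grid_span)
  write_targets(cfg, out("targets.tsv")); add_output(out("targets.tsv"))

  # --- simulate / ingest -------------------------------------------------
  if (!is.null(config$trial_table_path)) {
    trials <- read_trials(config$trial_table_path)
    population <- NULL
  } else if ("simulate" %in% config$stages) {
    population <- make_population(config$n_neurons, config$mixture_weights,
                                  seed = child_seed(config$seed, 1L),
                                  baseline_rate = config$baseline_rate,
                                  epoch_gains = config$epoch_gains)
    trials <- simulate_session(cfg, population, config$n_trials_per_target,
                               seed = child_seed(config$seed, 2L))
    write_trials(trials, out("trials.tsv")); add_output(out("trials.tsv"))
    gt <- ground_truth_table(population)
    write.table(gt, out("ground_truth.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    add_output(out("ground_truth.tsv"))
  } else {
    stop_invalid("no input: enable the simulate stage or give trial_table_path")
  }
  report$trials <- trials
  report$population <- population

  run_stage <- function(name, fun) {
    if (!name %in% config$stages) return(invisible(NULL))
    res <- tryCatch(fun(), error = function(e) {
      report$failures[[name]] <<- conditionMessage(e)
      NULL
    })
    res
  }

  # --- selectivity -------------------------------------------------------
  report$selectivity <- run_stage("selectivity", function() {
    sel <- selectivity_table(trials, cfg)
    write.table(sel, out("selectivity.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    add_output(out("selectivity.tsv"))
    summ <- population_summary(sel)
    if (config$n_shuffles > 0) {
      summ$shuffle_null <- shuffle_null_proportion(
        trials, cfg, n_shuffles = config$n_shuffles,
        seed = child_seed(config$seed, 3L))$mean_proportion
    }
    jsonlite::write_json(summ, out("selectivity_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    add_output(out("selectivity_summary.json"))
    list(table = sel, summary = summ)
  })

  # --- tuning geometry (delta-PD needs exactly 2 amplitude levels) -------
  report$tuning <- run_stage("tuning", function() {
    if (cfg$n_amplitudes == 2) {
      ds <- population_direction_stats(trials, cfg)
      write.table(ds$per_neuron, out("direction_stats.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      add_output(out("direction_stats.tsv"))
      jsonlite::write_json(ds$summary, out("tuning_summary.json"),
                           auto_unbox = TRUE, digits = NA)
      add_output(out("tuning_summary.json"))
      ds
    } else {
      curves <- do.call(rbind, lapply(split(trials, trials$neuron_id),
        function(tr) {
          ac <- amplitude_response_curve(tr, cfg)
          data.frame(neuron_id = tr$neuron_id[1], pd_r = ac$pd_r,
                     pd_p = ac$pd_p, anti_r = ac$anti_r, anti_p = ac$anti_p)
        }))
      write.table(curves, out("amplitude_curves.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      add_output(out("amplitude_curves.tsv"))
      list(amplitude_curves = curves)
    }
  })

  # --- response fields ---------------------------------------------------
  report$fields <- run_stage("fields", function() {
    op <- pattern_operator(cfg, grid)
    rows <- lapply(split(trials, trials$neuron_id), function(tr) {
      y <- tr[[.rate_col(config$epoch)]]
      means <- tapply(y, factor(tr$target_index,
                                levels = active_targets(cfg)$index), mean)
      pat <- interpolate_pattern(as.vector(means), cfg, grid, op = op)
      pk <- peak_eccentricity(pat, cfg$screen_distance,
                              mask_only = config$mask_only)
      fw <- field_width(pat, cfg$screen_distance,
                        mask_only = config$mask_only)
      data.frame(neuron_id = tr$neuron_id[1], epoch = config$epoch,
                 peak_eccentricity_deg = pk$eccentricity_deg,
                 peak_x_cm = pk$peak_x_cm, peak_y_cm = pk$peak_y_cm,
                 field_width_deg = fw$width_deg, degenerate = fw$degenerate)
    })
    tab <- do.call(rbind, rows)
    rownames(tab) <- NULL
    write.table(tab, out("field_stats.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    add_output(out("field_stats.tsv"))
    tab
  })

  # --- encoding models ---------------------------------------------------
  report$models <- run_stage("models", function() {
    cons <- session_consistency(trials, cfg, epoch = config$epoch,
                                seed = child_seed(config$seed, 4L),
                                n_repeats = config$n_repeats,
                                n_restarts = config$n_restarts,
                                grid = grid, mask_only = config$mask_only)
    write.table(cons, out("consistency.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    add_output(out("consistency.tsv"))
    cmp <- tryCatch(compare_models(cons), error = function(e) NULL)
    if (!is.null(cmp)) {
      jsonlite::write_json(
        list(p_matrix = cmp$p_matrix,
             mean_consistency = as.list(cmp$mean_consistency),
             best_model = cmp$best_model, n = cmp$n),
        out("model_comparison.json"), auto_unbox = TRUE, digits = NA,
        matrix = "rowmajor")
      add_output(out("model_comparison.json"))
    }
    list(consistency = cons, comparison = cmp)
  })

  manifest <- list(package = "reachfield",
                   version = as.character(utils::packageVersion("reachfield")),
                   r_version = paste(R.version$major, R.version$minor, sep = "."),
                   seed = config$seed,
                   config = unclass(config))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  add_output(out("manifest.json"))
  class(report) <- "run_report"
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report:", length(x$outputs), "outputs in", x$config$out_dir)
  if (length(x$failures)) {
    cat("; FAILED stages:", paste(names(x$failures), collapse = ", "))
  }
  cat(">\n")
  invisible(x)
}

#' Ground-truth recovery scoring for a simulated session
#'
#' Compares pipeline outputs against the generator's ground truth: a
#' confusion matrix of generating model vs highest-consistency model (when
#' a consistency table is supplied), full-data-pattern parameter-recovery
#' errors (wrapped preferred-direction error in degrees for directional
#' models, Euclidean mu error in cm for the Gaussian model), and the
#' selectivity stage's hit rates.
#'
#' @param trials simulated trial table.
#' @param population the generating population (list of
#'   [ground_truth_neuron()]).
#' @param config the session's `target_config`.
#' @param consistency optional [session_consistency()] table.
#' @param selectivity optional [selectivity_table()] result.
#' @param epoch epoch used for pattern fits.
#' @param n_restarts,seed fitting settings.
#' @return a `recovery_report` list: `param_recovery` data.frame,
#'   `confusion` (table or NULL), `identification_rate` per generating
#'   model, `selectivity_rates`.
#' @export
recovery_report <- function(trials, population, config, consistency = NULL,
                            selectivity = NULL, epoch = "EM",
                            n_restarts = 10, seed = 1) {
  ids <- vapply(population, function(n) n$neuron_id, 0L)
  if (!all(unique(trials$neuron_id) %in% ids)) {
    stop_invalid("trial table contains neuron ids absent from the population")
  }
  op <- pattern_operator(config)
  grid <- grid_spec()
  rows <- lapply(population, function(nr) {
    if (nr$model_id == 0) return(NULL)
    tr <- trials[trials$neuron_id == nr$neuron_id, , drop = FALSE]
    if (!nrow(tr)) return(NULL)
    y <- tr[[.rate_col(epoch)]]
    means <- tapply(y, factor(tr$target_index,
                              levels = active_targets(config)$index), mean)
    pat <- interpolate_pattern(as.vector(means), config, grid, op = op)
    fit <- fit_model(nr$model_id, midrange_normalize(pat),
                     n_restarts = n_restarts,
                     seed = child_seed(seed, 97L, nr$neuron_id))
    theta_err <- mu_err <- NA_real_
    if (!fit$failed) {
      if (nr$model_id %in% 1:4) {
        theta_err <- abs(wrap_deg(rad2deg(fit$params[["theta0"]] -
                                            nr$true_params[["theta0"]])))
      } else {
        mu_err <- sqrt((fit$params[["mu_x"]] - nr$true_params[["mu_x"]])^2 +
                         (fit$params[["mu_y"]] - nr$true_params[["mu_y"]])^2)
      }
    }
    data.frame(neuron_id = nr$neuron_id, model_id = nr$model_id,
               objective = fit$objective, theta0_err_deg = theta_err,
               mu_err_cm = mu_err, failed = fit$failed)
  })
  param_recovery <- do.call(rbind, rows)
  confusion <- NULL; ident <- NULL
  if (!is.null(consistency)) {
    cols <- grep("^model_[0-9]+$", names(consistency), value = TRUE)
    ok <- consistency[!consistency$unusable, , drop = FALSE]
    picked <- as.integer(sub("model_", "", cols[
      apply(as.matrix(ok[, cols]), 1, which.max)]))
    gen <- vapply(ok$neuron_id, function(id) {
      population[[match(id, ids)]]$model_id
    }, 0L)
    keep <- gen > 0
    confusion <- table(generating = gen[keep], identified = picked[keep])
    ident <- vapply(split(picked[keep] == gen[keep], gen[keep]), mean, 0)
  }
  selectivity_rates <- NULL
  if (!is.null(selectivity)) {
    gen <- vapply(selectivity$neuron_id, function(id) {
      population[[match(id, ids)]]$model_id
    }, 0L)
    selectivity_rates <- list(
      untuned_flag_rate = mean(selectivity$amp_any_epoch[gen == 0]),
      tuned_flag_rate = mean(selectivity$amp_any_epoch[gen > 0]))
  }
  structure(list(param_recovery = param_recovery, confusion = confusion,
                 identification_rate = ident,
                 selectivity_rates = selectivity_rates),
            class = "recovery_report")
}
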