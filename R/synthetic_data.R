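#' Construct a ground-truth neuron
#'
#' A simulated neuron is defined by a generating tuning model (`0` =
#' untuned, `1`-`5` = the encoding models of [evaluate_model()]), its true
#' parameters, a baseline rate and additive per-epoch response gains. The
#' firing rate at a target is
#' `baseline + gain(epoch) * f_norm(target)`, where `f_norm` is the model
#' response mid-range normalized over the configuration's targets, so the
#' gain is the peak modulation in Hz and rates are guaranteed nonnegative.
#' Untuned neurons have `f_norm = 0` everywhere. The baseline epoch is
#' always untuned (baseline rate only).
#'
#' @param neuron_id integer id.
#' @param model_id generating model: 0 (untuned) or 1-5.
#' @param true_params named numeric vector of model parameters (radians for
#'   angles, cm for positions), within the model's bounds; ignored for
#'   untuned neurons.
#' @param baseline_rate baseline firing rate in Hz (>= 0).
#' @param epoch_gains named numeric vector of Hz gains for C, EM, LM, RTMT
#'   (>= 0); a scalar is recycled.
#' @return a `ground_truth_neuron`.
#' @export
ground_truth_neuron <- function(neuron_id, model_id, true_params = NULL,
                                baseline_rate = 5,
                                epoch_gains = c(C = 40, EM = 40, LM = 40, RTMT = 40)) {
  model_id <- as.integer(model_id)
  if (!model_id %in% 0:5) stop_invalid("model_id must be 0 (untuned) or 1-5")
  if (baseline_rate < 0) stop_invalid("baseline_rate must be >= 0")
  if (length(epoch_gains) == 1) {
    epoch_gains <- stats::setNames(rep(epoch_gains, 4), EPOCHS)
  }
  if (!all(EPOCHS %in% names(epoch_gains))) {
    stop_invalid("epoch_gains must be named with ", paste(EPOCHS, collapse = ", "))
  }
  if (any(epoch_gains < 0)) stop_invalid("epoch_gains must be >= 0")
  if (model_id > 0) {
    sp <- model_spec(model_id)
    true_params <- check_params(sp, true_params)
  }
  structure(list(neuron_id = as.integer(neuron_id), model_id = model_id,
                 true_params = true_params, baseline_rate = baseline_rate,
                 epoch_gains = epoch_gains[EPOCHS]),
            class = "ground_truth_neuron")
}

#' Expected firing rate of a ground-truth neuron at the configuration targets
#'
#' @param neuron a [ground_truth_neuron()].
#' @param config a `target_config`.
#' @param epoch one of `"baseline"`, `"C"`, `"EM"`, `"LM"`, `"RTMT"`.
#' @return numeric vector of expected rates in Hz, one per active target.
#' @export
rate_function <- function(neuron, config, epoch) {
  .rate_col(epoch) # validates the label
  tg <- active_targets(config)
  if (epoch == "baseline" || neuron$model_id == 0L) {
    gain <- if (epoch == "baseline") 0 else neuron$epoch_gains[[epoch]]
    return(rep(neuron$baseline_rate, nrow(tg)) + gain * 0)
  }
  pts <- target_points(tg)
  f <- evaluate_model(neuron$model_id, neuron$true_params, pts)
  fn <- midrange_normalize(f)
  if (isTRUE(attr(fn, "degenerate"))) fn <- rep(0, length(f))
  neuron$baseline_rate + neuron$epoch_gains[[epoch]] * as.vector(fn)
}

target_points <- function(tg) {
  list(theta = deg2rad(tg$direction_deg), r = tg$amplitude_cm,
       x = tg$x_cm, y = tg$y_cm)
}

#' Draw a reproducible population of ground-truth neurons
#'
#' Models are drawn from a mixture over \{untuned, 1..5\} and parameters from
#' priors chosen to emulate plausible planning neurons: preferred directions
#' uniform on the circle, Von Mises concentrations in a moderate-tuning
#' range, Gaussian response-field centers uniform in the central
#' 10 cm x 10 cm of reach space with widths of a few cm.
#'
#' @param n_neurons number of neurons (> 0).
#' @param mixture_weights named nonnegative weights over
#'   `c("untuned", "1".."5")`, summing to 1.
#' @param seed RNG seed.
#' @param baseline_rate,epoch_gains passed to [ground_truth_neuron()];
#'   either may be a function drawing one value (called per neuron).
#' @param param_priors optional named list of functions, one per model id
#'   ("1".."5"), each returning a named parameter vector.
#' @return list of `ground_truth_neuron` objects.
#' @export
make_population <- function(n_neurons,
                            mixture_weights = c(untuned = 1/6, `1` = 1/6,
                                                `2` = 1/6, `3` = 1/6,
                                                `4` = 1/6, `5` = 1/6),
                            seed = 1, baseline_rate = 5, epoch_gains = 40,
                            param_priors = default_param_priors()) {
  if (n_neurons < 1) stop_invalid("n_neurons must be >= 1")
  ids <- c("untuned", "1", "2", "3", "4", "5")
  if (!all(names(mixture_weights) %in% ids) || any(mixture_weights < 0) ||
      abs(sum(mixture_weights) - 1) > 1e-8) {
    stop_invalid("mixture_weights must be nonnegative over ",
                 paste(ids, collapse = "/"), " and sum to 1")
  }
  w <- stats::setNames(rep(0, 6), ids)
  w[names(mixture_weights)] <- mixture_weights
  with_seed(seed, {
    draws <- sample(0:5, n_neurons, replace = TRUE, prob = w)
    lapply(seq_len(n_neurons), function(i) {
      m <- draws[i]
      pars <- if (m > 0) param_priors[[as.character(m)]]() else NULL
      b <- if (is.function(baseline_rate)) baseline_rate() else baseline_rate
      g <- if (is.function(epoch_gains)) epoch_gains() else epoch_gains
      ground_truth_neuron(i, m, pars, b, g)
    })
  })
}

#' Default parameter priors for the generator
#'
#' @return named list of prior-draw functions keyed by model id "1".."5".
#' @export
default_param_priors <- function() {
  list(
    `1` = function() c(theta0 = runif(1, -pi, pi)),
    `2` = function() c(theta0 = runif(1, -pi, pi), k = runif(1, 0.5, 2)),
    `3` = function() c(theta0 = runif(1, -pi, pi), sigma = runif(1, 0.5, 4)),
    `4` = function() c(theta0 = runif(1, -pi, pi), sigma = runif(1, 0.5, 4),
                       k = runif(1, 0.5, 2)),
    `5` = function() c(mu_x = runif(1, -5, 5), mu_y = runif(1, -5, 5),
                       sigma_x = runif(1, 2, 4), sigma_y = runif(1, 2, 4),
                       rho = runif(1, -0.3, 0.3))
  )
}

#' Simulate a session of per-trial epoch firing rates
#'
#' For every neuron, target and trial, the spike count in each 500 ms epoch
#' is drawn as `Poisson(rate * 0.5)` and converted back to a rate
#' (`count / 0.5` Hz, so simulated rates are integer multiples of 2 Hz).
#' The baseline epoch uses the neuron's baseline rate only. A simulated
#' memory-period duration (uniform on 1.1-1.7 s) is attached as metadata.
#' Identical seeds give identical tables; each neuron has its own derived
#' RNG stream, so enlarging the population does not perturb existing
#' neurons.
#'
#' @param config a `target_config`.
#' @param population list of [ground_truth_neuron()] objects.
#' @param n_trials_per_target trials per target (>= 2); default matches the
#'   task medians (42 for Task 1, 10 for Task 2).
#' @param seed master RNG seed.
#' @return the trial table: a data.frame with one row per (neuron, trial)
#'   and columns `neuron_id, trial_id, target_index, direction_deg,
#'   amplitude_cm, rate_baseline_hz, rate_c_hz, rate_em_hz, rate_lm_hz,
#'   rate_rtmt_hz, mem_duration_s`.
#' @export
simulate_session <- function(config, population,
                             n_trials_per_target = if (config$task_id == "task2") 10 else 42,
                             seed = 1) {
  if (!length(population)) stop_invalid("empty population")
  if (n_trials_per_target < 2) stop_invalid("n_trials_per_target must be >= 2")
  tg <- active_targets(config)
  if (!nrow(tg)) stop_invalid("configuration has no active targets")
  nt <- nrow(tg)
  ntr <- nt * n_trials_per_target
  out <- lapply(population, function(nr) {
    rates <- vapply(c("baseline", EPOCHS), function(e) rate_function(nr, config, e),
                    numeric(nt))
    with_seed(child_seed(seed, 101L, nr$neuron_id), {
      tidx <- rep(seq_len(nt), each = n_trials_per_target)
      counts <- vapply(seq_len(5), function(j) rpois(ntr, rates[tidx, j] * 0.5),
                       numeric(ntr))
      data.frame(neuron_id = nr$neuron_id, trial_id = seq_len(ntr),
                 target_index = tg$index[tidx],
                 direction_deg = tg$direction_deg[tidx],
                 amplitude_cm = tg$amplitude_cm[tidx],
                 rate_baseline_hz = counts[, 1] / 0.5,
                 rate_c_hz = counts[, 2] / 0.5,
                 rate_em_hz = counts[, 3] / 0.5,
                 rate_lm_hz = counts[, 4] / 0.5,
                 rate_rtmt_hz = counts[, 5] / 0.5,
                 mem_duration_s = runif(ntr, 1.1, 1.7))
    })
  })
  do.call(rbind, out)
}

#' Export a population's ground truth as a delimited table
#'
#' @param population list of `ground_truth_neuron` objects.
#' @return data.frame keyed by `neuron_id` with `model_id`, baseline, gains
#'   and one column per parameter (NA where not applicable).
#' @export
ground_truth_table <- function(population) {
  pnames <- c("theta0", "sigma", "k", "mu_x", "mu_y", "sigma_x", "sigma_y", "rho")
  rows <- lapply(population, function(nr) {
    p <- stats::setNames(rep(NA_real_, length(pnames)), pnames)
    if (!is.null(nr$true_params)) p[names(nr$true_params)] <- nr$true_params
    c(list(neuron_id = nr$neuron_id, model_id = nr$model_id,
           baseline_rate = nr$baseline_rate),
      as.list(nr$epoch_gains), as.list(p))
  })
  df <- do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
  names(df)[4:7] <- paste0("gain_", tolower(EPOCHS), "_hz")
  df
}

#' Write / read a trial table as tab-delimited text
#'
#' The same schema is the ingest format for real recordings.
#'
#' @param trials trial-table data.frame (see [simulate_session()]).
#' @param path file path.
#' @export
write_trials <- function(trials, path) {
  write.table(trials, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) stop_invalid("trial table not found: ", path)
  read.delim(path, check.names = FALSE)
}
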