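#' Preferred direction of a neuron in one epoch
#'
#' The sampled reach direction with the maximal mean firing rate, pooling
#' amplitudes. With a `target_config` whose amplitude rings are staggered,
#' targets are grouped by direction index and the group's circular-mean
#' angle is reported. Ties are broken by the smallest angle and flagged.
#'
#' @param trials trial-table rows of a single neuron.
#' @param epoch analysis epoch label.
#' @param config optional `target_config` for direction grouping.
#' @return list(direction_deg, dir_key, mean_rate, tie).
#' @export
preferred_direction <- function(trials, epoch, config = NULL) {
  if (!nrow(trials)) stop_invalid("no trials")
  y <- trials[[.rate_col(epoch)]]
  g <- direction_groups(trials, config)
  means <- tapply(y, g$key, mean)
  angles <- g$angle[match(names(means), g$key)]
  top <- which(means >= max(means) - 1e-12)
  pick <- top[order(angles[top])][1]
  list(direction_deg = angles[pick], dir_key = names(means)[pick],
       mean_rate = unname(means[pick]), tie = length(top) > 1)
}

# direction grouping key and representative angle per trial
direction_groups <- function(trials, config) {
  if (is.null(config)) {
    key <- as.character(trials$direction_deg)
    ang <- trials$direction_deg
  } else {
    ix <- match(trials$target_index, config$targets$index)
    key <- as.character(config$targets$dir_index[ix])
    ang <- vapply(split(config$targets$direction_deg[ix], key), circ_mean_deg, 0)[key]
  }
  list(key = key, angle = unname(ang))
}

circ_mean_deg <- function(deg) {
  (rad2deg(atan2(mean(sin(deg2rad(deg))), mean(cos(deg2rad(deg)))))) %% 360
}

#' Angular offset between amplitude modulation and the preferred direction
#'
#' Delta-PD is the wrapped angular difference between the direction of
#' strongest amplitude modulation (smallest direction-wise amplitude-t-test
#' p-value; or, in `"circmean"` mode, the circular average of all
#' significantly modulated directions) and the neuron's preferred
#' direction, for one epoch. Neurons with no direction significant at
#' `alpha` are excluded (returned with `included = FALSE`), mirroring the
#' inclusion rule of the population analysis.
#'
#' @inheritParams preferred_direction
#' @param mode `"best"` (direction with minimal p) or `"circmean"`.
#' @param alpha per-direction inclusion level (default 0.05).
#' @return list(included, delta_pd_deg in (-180, 180\], preferred_deg,
#'   modulation_deg, n_significant).
#' @export
delta_pd <- function(trials, epoch, config = NULL,
                     mode = c("best", "circmean"), alpha = 0.05) {
  mode <- match.arg(mode)
  dt <- directionwise_amplitude_tests(trials, epoch, alpha)
  sig <- dt$tests[dt$tests$p < alpha, , drop = FALSE]
  if (!nrow(sig)) {
    return(list(included = FALSE, delta_pd_deg = NA_real_,
                preferred_deg = NA_real_, modulation_deg = NA_real_,
                n_significant = 0L))
  }
  pd <- preferred_direction(trials, epoch, config)
  mod_deg <- if (mode == "best") {
    best <- dt$tests[order(dt$tests$p, dt$tests$direction_deg), ][1, ]
    best$direction_deg
  } else {
    circ_mean_deg(sig$direction_deg)
  }
  list(included = TRUE,
       delta_pd_deg = wrap_deg(mod_deg - pd$direction_deg),
       preferred_deg = pd$direction_deg, modulation_deg = mod_deg,
       n_significant = nrow(sig))
}

#' Rayleigh test of circular uniformity
#'
#' Mean resultant length and the standard large-sample approximation to the
#' Rayleigh p-value, `p = exp(-Z) * (1 + (2Z - Z^2)/(4n)
#' - (24Z - 132Z^2 + 76Z^3 - 9Z^4)/(288 n^2))` with `Z = n * Rbar^2`
#' (clamped to \[0, 1\]).
#'
#' @param angles_deg numeric vector of angles in degrees, `n >= 4` (the
#'   approximation is unreliable below that).
#' @return list(R_bar, Z, p, n).
#' @export
rayleigh_test <- function(angles_deg) {
  n <- length(angles_deg)
  if (n < 4) stop_invalid("Rayleigh test needs n >= 4")
  th <- deg2rad(angles_deg)
  R_bar <- sqrt(mean(cos(th))^2 + mean(sin(th))^2)
  Z <- n * R_bar^2
  p <- exp(-Z) * (1 + (2 * Z - Z^2) / (4 * n) -
                    (24 * Z - 132 * Z^2 + 76 * Z^3 - 9 * Z^4) / (288 * n^2))
  list(R_bar = R_bar, Z = Z, p = min(max(p, 0), 1), n = n)
}

#' Circular mean and standard error of a sample of angles
#'
#' Mean direction `atan2(mean sin, mean cos)`; the standard error uses the
#' circular-dispersion estimator `delta = (1 - rho2) / (2 * Rbar^2)` (with
#' `rho2` the mean resultant length of the doubled angles),
#' `SE = sqrt(delta / n)`, reported in degrees.
#'
#' @param angles_deg numeric vector of angles in degrees, `n >= 2`.
#' @return list(mean_deg in (-180, 180\], se_deg, R_bar, n).
#' @export
circular_mean_se <- function(angles_deg) {
  n <- length(angles_deg)
  if (n < 2) stop_invalid("need n >= 2")
  th <- deg2rad(angles_deg)
  C <- mean(cos(th)); S <- mean(sin(th))
  R_bar <- sqrt(C^2 + S^2)
  if (R_bar < 1e-12) stop_invalid("circular mean undefined (R_bar = 0)")
  mu <- atan2(S, C)
  rho2 <- sqrt(mean(cos(2 * th))^2 + mean(sin(2 * th))^2)
  disp <- (1 - rho2) / (2 * R_bar^2)
  list(mean_deg = wrap_deg(rad2deg(mu)), se_deg = rad2deg(sqrt(disp / n)),
       R_bar = R_bar, n = n)
}

#' Normalized amplitude-response curves along the preferred direction
#'
#' For a dense (Task-2 style, >= 3 amplitudes) configuration: per epoch,
#' the per-target mean rates are mid-range normalized over all targets and
#' read out along the preferred direction and the sampled direction closest
#' to 180 deg opposite (anti-preferred; the exact opposite may not be
#' sampled when rings are staggered). Pooling over epochs, the Pearson
#' correlation between target amplitude and normalized rate is returned
#' separately for the two directions.
#'
#' @param trials trial-table rows of a single neuron.
#' @param config a `target_config` with >= 3 amplitude levels.
#' @param epochs epochs to analyse (default all four).
#' @return list with `curve` (data.frame: epoch, branch PD/anti, amp_index,
#'   amplitude_cm, norm_rate), and `pd_r`, `pd_p`, `anti_r`, `anti_p`.
#' @export
amplitude_response_curve <- function(trials, config, epochs = EPOCHS) {
  if (config$n_amplitudes < 3) {
    stop_invalid("amplitude-response curves need >= 3 amplitude levels")
  }
  tg <- active_targets(config)
  dir_angle <- vapply(split(tg$direction_deg, tg$dir_index), circ_mean_deg, 0)
  rows <- list()
  for (e in epochs) {
    y <- trials[[.rate_col(e)]]
    means <- tapply(y, trials$target_index, mean)
    tix <- match(as.integer(names(means)), tg$index)
    norm <- midrange_normalize(as.vector(means))
    pd <- preferred_direction(trials, e, config)
    pd_ix <- as.integer(pd$dir_key)
    anti_target <- wrap_deg(pd$direction_deg + 180)
    anti_ix <- as.integer(names(dir_angle)[
      which.min(abs(wrap_deg(dir_angle - anti_target)))])
    for (branch in c("PD", "anti")) {
      dix <- if (branch == "PD") pd_ix else anti_ix
      sel <- which(tg$dir_index[tix] == dix)
      rows[[length(rows) + 1]] <- data.frame(
        epoch = e, branch = branch,
        amp_index = tg$amp_index[tix][sel],
        amplitude_cm = tg$amplitude_cm[tix][sel],
        norm_rate = as.vector(norm)[sel])
    }
  }
  curve <- do.call(rbind, rows)
  ct <- function(br) {
    cc <- curve[curve$branch == br, ]
    if (sd(cc$norm_rate) == 0) return(list(estimate = NA_real_, p.value = NA_real_))
    tst <- cor.test(cc$amplitude_cm, cc$norm_rate)
    list(estimate = unname(tst$estimate), p.value = tst$p.value)
  }
  pdt <- ct("PD"); att <- ct("anti")
  list(curve = curve, pd_r = pdt$estimate, pd_p = pdt$p.value,
       anti_r = att$estimate, anti_p = att$p.value)
}

#' Population delta-PD statistics
#'
#' Computes delta-PD for every neuron of a trial table, per epoch and
#' pooled, with the Rayleigh uniformity test and circular mean +/- SE of
#' the resulting distribution.
#'
#' @param trial_table trial table (Task-1 style: 2 amplitude levels).
#' @param config optional `target_config`.
#' @param mode,alpha see [delta_pd()].
#' @return list with `per_neuron` (data.frame: neuron_id, epoch, included,
#'   delta_pd_deg, ...) and `summary` (per epoch and pooled: n, rayleigh_p,
#'   circular_mean, circular_se).
#' @export
population_direction_stats <- function(trial_table, config = NULL,
                                       mode = "best", alpha = 0.05) {
  per <- do.call(rbind, lapply(split(trial_table, trial_table$neuron_id),
    function(tr) {
      do.call(rbind, lapply(EPOCHS, function(e) {
        dp <- delta_pd(tr, e, config, mode, alpha)
        data.frame(neuron_id = tr$neuron_id[1], epoch = e,
                   included = dp$included, delta_pd_deg = dp$delta_pd_deg,
                   preferred_deg = dp$preferred_deg,
                   modulation_deg = dp$modulation_deg,
                   n_significant = dp$n_significant)
      }))
    }))
  rownames(per) <- NULL
  summarize <- function(x) {
    x <- x[is.finite(x)]
    if (length(x) < 4) {
      return(list(n = length(x), rayleigh_p = NA_real_,
                  circular_mean = NA_real_, circular_se = NA_real_))
    }
    r <- rayleigh_test(x); cm <- circular_mean_se(x)
    list(n = length(x), rayleigh_p = r$p, circular_mean = cm$mean_deg,
         circular_se = cm$se_deg)
  }
  sums <- lapply(c(as.list(EPOCHS), list("pooled")), function(e) {
    x <- if (identical(e, "pooled")) per$delta_pd_deg
         else per$delta_pd_deg[per$epoch == e]
    summarize(x)
  })
  names(sums) <- c(EPOCHS, "pooled")
  list(per_neuron = per, summary = sums)
}
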