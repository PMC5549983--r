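#' Analysis epoch windows
#'
#' The four 500 ms analysis epochs aligned to trial events, plus the
#' 500 ms pre-cue fixation window used as baseline: C = \[0, 500\] ms after
#' cue onset; EM = \[200, 700\] ms after cue offset; LM = \[-700, -200\] ms
#' before the go signal; RT/MT = \[0, 500\] ms after the go signal;
#' baseline = \[-500, 0\] ms before cue onset.
#'
#' @return data.frame with columns `epoch`, `anchor`, `start_ms`, `end_ms`.
#' @export
epoch_windows <- function() {
  data.frame(
    epoch = c("baseline", "C", "EM", "LM", "RTMT"),
    anchor = c("cue onset", "cue onset", "cue offset", "go signal", "go signal"),
    start_ms = c(-500, 0, 200, -700, 0),
    end_ms = c(0, 500, 700, -200, 500)
  )
}

#' Task-relatedness screen for one neuron
#'
#' A neuron is task-related iff (a) its firing rate in at least one of the
#' four analysis epochs differs from the baseline rate at `p < alpha / 4`
#' (t-test, Bonferroni-corrected for the four epochs), and (b) its mean
#' rate exceeds 1 Hz in at least one of the four epochs. The t-test is
#' paired across trials (epoch vs baseline of the same trial) by default,
#' which removes slow between-trial rate drift; an unpaired variant is
#' selectable.
#'
#' @param trials trial-table rows of a single neuron.
#' @param alpha nominal level before Bonferroni division (default 0.05).
#' @param rate_floor minimum epoch mean rate in Hz (default 1).
#' @param paired use a paired t-test (default TRUE).
#' @return list with `task_related`, per-epoch `p_values`, `epoch_means`,
#'   and `degenerate` (TRUE when a test was undefined for constant data;
#'   such epochs get p = 1 when the mean difference is 0, else p = 0).
#' @export
is_task_related <- function(trials, alpha = 0.05, rate_floor = 1,
                            paired = TRUE) {
  if (nrow(trials) < 2) stop_invalid("need >= 2 trials")
  b <- trials$rate_baseline_hz
  degen <- FALSE
  p <- vapply(EPOCHS, function(e) {
    x <- trials[[.rate_col(e)]]
    if (paired) {
      d <- x - b
      if (sd(d) == 0) {
        degen <<- TRUE
        return(if (mean(d) == 0) 1 else 0)
      }
      t.test(d)$p.value
    } else {
      if (sd(x) == 0 && sd(b) == 0) {
        degen <<- TRUE
        return(if (mean(x) == mean(b)) 1 else 0)
      }
      t.test(x, b)$p.value
    }
  }, 0)
  means <- vapply(EPOCHS, function(e) mean(trials[[.rate_col(e)]]), 0)
  list(task_related = any(p < alpha / 4) && any(means > rate_floor),
       p_values = p, epoch_means = means, degenerate = degen)
}

#' Two-way fixed-effects ANOVA with interaction
#'
#' Firing rate against reach direction and amplitude as crossed fixed
#' factors. On balanced designs the sums of squares are computed in closed
#' form (all SS types coincide); on unbalanced designs type-II sums of
#' squares are used (robust to the mild imbalance of approximately-balanced
#' sessions). Zero-variance degeneracies are reported with p = 1 (no
#' evidence) or p = 0 (infinite F) and flagged rather than raised, so
#' population screens never abort.
#'
#' @param rates numeric response vector (Hz).
#' @param direction,amplitude factor labels, one per trial; >= 2 levels
#'   each, every (direction, amplitude) cell non-empty, >= 2 trials per
#'   cell so the interaction is testable.
#' @return data.frame with rows `direction`, `amplitude`, `interaction` and
#'   columns `effect`, `df1`, `df2`, `F`, `p`; attribute `degenerate`.
#' @export
anova2_interaction <- function(rates, direction, amplitude) {
  d <- factor(direction); a <- factor(amplitude)
  if (nlevels(d) < 2 || nlevels(a) < 2) {
    stop_invalid("need >= 2 levels per factor")
  }
  counts <- table(d, a)
  if (any(counts == 0)) {
    bad <- which(counts == 0, arr.ind = TRUE)[1, ]
    stop_invalid("empty cell: direction=", levels(d)[bad[1]],
                 ", amplitude=", levels(a)[bad[2]])
  }
  if (min(counts) < 2) {
    stop_invalid("need >= 2 trials per (direction, amplitude) cell for the interaction term")
  }
  N <- length(rates)
  nd <- nlevels(d); na <- nlevels(a)
  if (length(unique(as.vector(counts))) == 1) {
    # balanced: closed-form decomposition
    grand <- mean(rates)
    md <- tapply(rates, d, mean); ma <- tapply(rates, a, mean)
    mc <- tapply(rates, list(d, a), mean)
    nper <- as.vector(counts)[1]
    ss_d <- nper * na * sum((md - grand)^2)
    ss_a <- nper * nd * sum((ma - grand)^2)
    ss_cells <- nper * sum((mc - grand)^2)
    ss_i <- ss_cells - ss_d - ss_a
    ss_e <- sum((rates - mc[cbind(d, a)])^2)
  } else {
    # type II via nested residual sums of squares
    rss <- function(f) sum(lm(f)$residuals^2)
    r_full <- rss(rates ~ d * a)
    r_add <- rss(rates ~ d + a)
    ss_d <- rss(rates ~ a) - r_add
    ss_a <- rss(rates ~ d) - r_add
    ss_i <- r_add - r_full
    ss_e <- r_full
  }
  df1 <- c(nd - 1, na - 1, (nd - 1) * (na - 1))
  df2 <- N - nd * na
  ss <- c(ss_d, ss_a, ss_i)
  tol <- 1e-12 * max(sum(ss) + ss_e, 1)
  degen <- ss_e < tol
  if (degen) {
    Fv <- ifelse(ss < tol, NA_real_, Inf)
    p <- ifelse(ss < tol, 1, 0)
  } else {
    Fv <- (ss / df1) / (ss_e / df2)
    p <- pf(Fv, df1, df2, lower.tail = FALSE)
  }
  out <- data.frame(effect = c("direction", "amplitude", "interaction"),
                    df1 = df1, df2 = df2, F = Fv, p = p)
  attr(out, "degenerate") <- degen
  out
}

#' Direction-wise amplitude t-tests (Task-1 style)
#'
#' For each reach direction separately, a two-sided unpaired t-test (equal
#' variance) between the firing-rate distributions of small- and
#' large-amplitude trials, plus the count of directions significant at the
#' nominal level (the "selective in one/two directions" statistic).
#'
#' @param trials trial-table rows of a single neuron.
#' @param epoch analysis epoch label.
#' @param alpha nominal per-direction level (default 0.05).
#' @return list with `tests` (data.frame: direction_deg, p, mean_small,
#'   mean_large, degenerate) and `n_significant`.
#' @export
directionwise_amplitude_tests <- function(trials, epoch, alpha = 0.05) {
  amps <- sort(unique(trials$amplitude_cm))
  if (length(amps) != 2) {
    stop_invalid("direction-wise amplitude t-tests need exactly 2 amplitude ",
                 "levels (Task 1); found ", length(amps),
                 " -- use the Task-2 response-field analyses instead")
  }
  y <- trials[[.rate_col(epoch)]]
  dirs <- sort(unique(trials$direction_deg))
  rows <- lapply(dirs, function(dd) {
    sel <- trials$direction_deg == dd
    xs <- y[sel & trials$amplitude_cm == amps[1]]
    xl <- y[sel & trials$amplitude_cm == amps[2]]
    if (length(xs) < 2 || length(xl) < 2) {
      stop_invalid("need >= 2 trials per (direction, amplitude); direction ", dd)
    }
    if (sd(xs) == 0 && sd(xl) == 0) {
      p <- if (mean(xs) == mean(xl)) 1 else 0
      degen <- TRUE
    } else {
      p <- t.test(xs, xl, var.equal = TRUE)$p.value
      degen <- FALSE
    }
    data.frame(direction_deg = dd, p = p, mean_small = mean(xs),
               mean_large = mean(xl), degenerate = degen)
  })
  tests <- do.call(rbind, rows)
  list(tests = tests, n_significant = sum(tests$p < alpha))
}

#' Bonferroni amplitude-selectivity flags
#'
#' `any_epoch`: a significant amplitude main effect or direction-amplitude
#' interaction in any of the four epochs at `p < alpha / 8` (eight
#' comparisons: 2 effect types x 4 epochs). `planning`: the same over the
#' movement-planning (memory) epochs EM and LM only, at `p < alpha / 4`
#' (2 effect types x 2 epochs).
#'
#' @param anova_by_epoch named list (`C`, `EM`, `LM`, `RTMT`) of
#'   [anova2_interaction()] results.
#' @param alpha nominal level (default 0.05).
#' @return list(any_epoch, planning, min_p_any, min_p_planning).
#' @export
amplitude_selectivity_flags <- function(anova_by_epoch, alpha = 0.05) {
  if (!all(EPOCHS %in% names(anova_by_epoch))) {
    stop_invalid("anova_by_epoch must contain all of ",
                 paste(EPOCHS, collapse = ", "))
  }
  getp <- function(eps) {
    unlist(lapply(eps, function(e) {
      tab <- anova_by_epoch[[e]]
      tab$p[tab$effect %in% c("amplitude", "interaction")]
    }))
  }
  p_any <- getp(EPOCHS)
  p_plan <- getp(c("EM", "LM"))
  list(any_epoch = min(p_any) < alpha / 8,
       planning = min(p_plan) < alpha / 4,
       min_p_any = min(p_any), min_p_planning = min(p_plan))
}

#' One-tailed exact binomial proportion test
#'
#' `P(X >= k)` for `X ~ Binomial(n, p0)`; used to test whether the observed
#' number of selective neurons exceeds the chance proportion.
#'
#' @param k_selective observed count, `0 <= k <= n`.
#' @param n_neurons population size.
#' @param p0 chance proportion (default 0.05).
#' @return the one-tailed p-value.
#' @export
population_proportion_test <- function(k_selective, n_neurons, p0 = 0.05) {
  if (p0 <= 0 || p0 >= 1) stop_invalid("p0 must be in (0, 1)")
  if (k_selective < 0 || k_selective > n_neurons) stop_invalid("need 0 <= k <= n")
  pbinom(k_selective - 1, n_neurons, p0, lower.tail = FALSE)
}

#' Per-neuron selectivity screen over a trial table
#'
#' Runs the task-relatedness screen, the per-epoch two-way ANOVA and the
#' Bonferroni amplitude flags for every neuron. When a `target_config` is
#' supplied, its `dir_index` / `amp_index` labels are used as the ANOVA
#' factors (required for layouts whose amplitude rings are angularly
#' staggered); otherwise the raw `direction_deg` / `amplitude_cm` labels
#' are used.
#'
#' @param trial_table trial table (see [simulate_session()]).
#' @param config optional `target_config`.
#' @param alpha nominal level.
#' @return data.frame, one row per neuron: task-relatedness, per-epoch
#'   F and p for the three effects, amplitude flags, degeneracy flags.
#' @export
selectivity_table <- function(trial_table, config = NULL, alpha = 0.05) {
  rows <- lapply(split(trial_table, trial_table$neuron_id), function(tr) {
    tr_screen <- is_task_related(tr, alpha)
    labs <- factor_labels(tr, config)
    an <- lapply(EPOCHS, function(e) {
      anova2_interaction(tr[[.rate_col(e)]], labs$direction, labs$amplitude)
    })
    names(an) <- EPOCHS
    flags <- amplitude_selectivity_flags(an, alpha)
    stats <- unlist(lapply(EPOCHS, function(e) {
      tab <- an[[e]]
      stats::setNames(c(tab$F, tab$p),
                      paste0(c("F_dir_", "F_amp_", "F_int_", "p_dir_",
                               "p_amp_", "p_int_"), e))
    }))
    degen <- any(vapply(an, function(tab) isTRUE(attr(tab, "degenerate")), TRUE))
    cbind(data.frame(neuron_id = tr$neuron_id[1],
                     task_related = tr_screen$task_related,
                     degenerate = tr_screen$degenerate || degen,
                     amp_any_epoch = flags$any_epoch,
                     amp_planning = flags$planning,
                     min_p_any = flags$min_p_any,
                     min_p_planning = flags$min_p_planning),
          as.data.frame(as.list(stats)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$neuron_id), ]
}

factor_labels <- function(tr, config) {
  if (is.null(config)) {
    list(direction = tr$direction_deg, amplitude = tr$amplitude_cm)
  } else {
    ix <- match(tr$target_index, config$targets$index)
    list(direction = config$targets$dir_index[ix],
         amplitude = config$targets$amp_index[ix])
  }
}

#' Population selectivity summary
#'
#' @param sel a [selectivity_table()] result.
#' @param p0 chance proportion for the binomial test.
#' @return list (JSON-serializable): counts, proportion of task-related
#'   neurons flagged amplitude-selective (any-epoch rule), and the
#'   one-tailed binomial p-value against `p0`.
#' @export
population_summary <- function(sel, p0 = 0.05) {
  tr <- sel[sel$task_related, , drop = FALSE]
  k <- sum(tr$amp_any_epoch)
  list(n_neurons = nrow(sel), n_task_related = nrow(tr),
       k_amplitude_selective = k,
       proportion = if (nrow(tr)) k / nrow(tr) else NA_real_,
       k_planning = sum(tr$amp_planning),
       binomial_p = if (nrow(tr)) population_proportion_test(k, nrow(tr), p0)
                    else NA_real_)
  }

#' Chance proportion of amplitude-selective neurons by label shuffling
#'
#' Permutes the target labels across trials within each neuron, reruns the
#' amplitude-selectivity criterion, and returns the mean proportion flagged
#' over shuffles -- the empirical null proportion for the Bonferroni
#' any-epoch rule.
#'
#' @param trial_table trial table.
#' @param config optional `target_config` (see [selectivity_table()]).
#' @param n_shuffles number of shuffles (default 100).
#' @param seed RNG seed.
#' @param task_related_only restrict to task-related neurons (default TRUE,
#'   matching the population analysis; task-relatedness is invariant to the
#'   shuffle since it ignores target labels).
#' @return list(mean_proportion, proportions).
#' @export
shuffle_null_proportion <- function(trial_table, config = NULL,
                                    n_shuffles = 100, seed = 1,
                                    task_related_only = TRUE) {
  if (n_shuffles < 1) stop_invalid("n_shuffles must be >= 1")
  label_cols <- c("target_index", "direction_deg", "amplitude_cm")
  props <- vapply(seq_len(n_shuffles), function(s) {
    shuffled <- do.call(rbind, lapply(split(trial_table, trial_table$neuron_id),
      function(tr) {
        perm <- with_seed(child_seed(seed, 733L, s, tr$neuron_id[1]),
                          sample.int(nrow(tr)))
        tr[, label_cols] <- tr[perm, label_cols]
        tr
      }))
    sel <- selectivity_table(shuffled, config)
    if (task_related_only) sel <- sel[sel$task_related, , drop = FALSE]
    if (!nrow(sel)) return(NA_real_)
    mean(sel$amp_any_epoch)
  }, 0)
  list(mean_proportion = mean(props, na.rm = TRUE), proportions = props)
}
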