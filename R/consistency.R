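#' Split-half internal and cross-validated model consistency
#'
#' The noise-ceiling protocol for one neuron and epoch. Per repeat, trials
#' are split into two halves, stratified within each target so both halves
#' cover every target (an odd trial count sends the extra trial to a random
#' half). Each half yields a mid-range-normalized interpolated response
#' pattern (N1, N2); their Pearson correlation is the *internal
#' consistency* (noise ceiling). Every candidate model is fitted on N1 and
#' on N2 (constrained least squares, [fit_model()]), giving model patterns
#' M1 and M2, and the *model consistency* is the mean of Pearson(N1, M2)
#' and Pearson(N2, M1) -- a cross-validated correlation, since each model
#' is always evaluated against the half it was not fitted on. Everything is
#' averaged over `n_repeats` random re-splits.
#'
#' Targets with fewer than 2 trials are excluded (the neuron is skipped if
#' more than `max_excluded` of its targets are); repeats in which either
#' half's pattern is constant are discarded and redrawn, and the
#' neuron-epoch is reported unusable if more than half the repeats are
#' discarded.
#'
#' @param trials trial-table rows of a single neuron (>= 2 trials/target).
#' @param epoch analysis epoch label.
#' @param config the `target_config` of the session.
#' @param models candidate model ids (default 1:5).
#' @param n_repeats number of random re-splits (default 50).
#' @param n_restarts optimizer restarts per fit (default 10).
#' @param seed RNG stream for this neuron-epoch.
#' @param grid interpolation grid, see [grid_spec()].
#' @param mask_only correlate over in-hull bins only (default FALSE: all
#'   bins, nearest-target extrapolation included).
#' @param op precomputed [pattern_operator()] (recomputed if the target set
#'   shrinks after exclusions).
#' @param max_excluded maximum tolerated fraction of excluded targets.
#' @return a `consistency_result`: list with `neuron_id`, `epoch`,
#'   `internal` (mean), `internal_se`, `model` / `model_se` (named numeric
#'   over models, resampling mean and SE), `per_repeat` (matrix with
#'   internal + one column per model), `n_repeats`, `n_discarded`,
#'   `excluded_targets`, `unusable`, `seed`.
#' @export
split_half_consistency <- function(trials, epoch, config, models = 1:5,
                                   n_repeats = 50, n_restarts = 10, seed = 1,
                                   grid = grid_spec(), mask_only = FALSE,
                                   op = NULL, max_excluded = 0.2) {
  neuron_id <- trials$neuron_id[1]
  tg <- active_targets(config)
  y <- trials[[.rate_col(epoch)]]
  by_target <- split(seq_len(nrow(trials)),
                     factor(trials$target_index, levels = tg$index))
  n_per <- lengths(by_target)
  excluded <- tg$index[n_per < 2]
  base <- list(neuron_id = neuron_id, epoch = epoch,
               excluded_targets = excluded, seed = seed,
               n_repeats = n_repeats)
  if (length(excluded) > max_excluded * nrow(tg)) {
    return(structure(c(base, list(unusable = TRUE, n_discarded = 0L,
                                  internal = NA_real_, internal_se = NA_real_,
                                  model = NULL, model_se = NULL,
                                  per_repeat = NULL)),
                     class = "consistency_result"))
  }
  if (length(excluded)) {
    config <- mark_omitted(config, union(config$omitted_targets, excluded))
    tg <- active_targets(config)
    by_target <- by_target[as.character(tg$index)]
    op <- NULL
  }
  if (is.null(op)) op <- pattern_operator(config, grid)
  keep <- if (mask_only) op$mask else rep(TRUE, length(op$mask))
  gx <- grid$gx[keep]; gy <- grid$gy[keep]
  pts <- complete_points(list(x = gx, y = gy))
  W <- op$W[keep, , drop = FALSE]

  nm <- length(models)
  cn <- c("internal", if (nm) paste0("model_", models))
  per <- matrix(NA_real_, n_repeats, 1 + nm, dimnames = list(NULL, cn))
  n_discarded <- 0L
  # at most half the draws may be discarded, else the neuron-epoch is unusable
  max_attempts <- 2L * n_repeats
  attempt <- 0L
  rep_done <- 0L
  while (rep_done < n_repeats && attempt < max_attempts) {
    attempt <- attempt + 1L
    halves <- with_seed(child_seed(seed, 17L, attempt), {
      lapply(by_target, function(ix) {
        n <- length(ix)
        k <- n %/% 2
        if (n %% 2 == 1 && runif(1) < 0.5) k <- k + 1L
        perm <- sample(ix)
        list(h1 = perm[seq_len(k)], h2 = perm[-seq_len(k)])
      })
    })
    m1 <- vapply(halves, function(h) mean(y[h$h1]), 0)
    m2 <- vapply(halves, function(h) mean(y[h$h2]), 0)
    v1 <- as.vector(W %*% m1); v2 <- as.vector(W %*% m2)
    # near-constant halves (range at rounding-noise scale) are degenerate
    tol1 <- 1e-9 * max(abs(v1), 1e-300)
    tol2 <- 1e-9 * max(abs(v2), 1e-300)
    if (diff(range(v1)) <= tol1 || diff(range(v2)) <= tol2) {
      n_discarded <- n_discarded + 1L
      next
    }
    rep_done <- rep_done + 1L
    n1 <- as.vector(midrange_normalize(v1))
    n2 <- as.vector(midrange_normalize(v2))
    per[rep_done, 1] <- cor(n1, n2)
    for (j in seq_along(models)) {
      f1 <- fit_model(models[j], n1, pts, n_restarts,
                      seed = child_seed(seed, 29L, attempt, models[j], 1L))
      f2 <- fit_model(models[j], n2, pts, n_restarts,
                      seed = child_seed(seed, 29L, attempt, models[j], 2L))
      # a constant fitted pattern has no defined correlation; it captures
      # none of the pattern variance, so its contribution is scored 0
      c12 <- safe_cor(n1, f2$fitted)
      c21 <- safe_cor(n2, f1$fitted)
      cors <- c(c12, c21)
      cors[is.na(cors)] <- 0
      per[rep_done, 1 + j] <- mean(cors)
    }
  }
  unusable <- rep_done < n_repeats
  per <- per[seq_len(rep_done), , drop = FALSE]
  mn <- colMeans(per)
  se <- apply(per, 2, sd) / sqrt(max(nrow(per), 1))
  structure(c(base, list(
    unusable = unusable, n_discarded = n_discarded,
    internal = unname(mn[1]), internal_se = unname(se[1]),
    model = mn[-1], model_se = se[-1], per_repeat = per)),
    class = "consistency_result")
}

#' @export
print.consistency_result <- function(x, ...) {
  if (isTRUE(x$unusable)) {
    cat("<consistency_result neuron", x$neuron_id, x$epoch, ": UNUSABLE>\n")
  } else {
    cat(sprintf("<consistency_result neuron %s %s: internal %.3f; %s>\n",
                x$neuron_id, x$epoch, x$internal,
                paste(names(x$model), round(x$model, 3), sep = "=",
                      collapse = " ")))
  }
  invisible(x)
}

#' Split-half consistency for every neuron of a session
#'
#' @param trial_table trial table.
#' @param config `target_config`.
#' @param epoch epoch label.
#' @param ... passed to [split_half_consistency()].
#' @param seed master seed; each neuron gets a derived stream.
#' @return data.frame with one row per usable neuron: internal consistency,
#'   per-model consistency and SEs, discard counts.
#' @export
session_consistency <- function(trial_table, config, epoch = "EM",
                                seed = 1, ...) {
  op <- pattern_operator(config)
  rows <- lapply(split(trial_table, trial_table$neuron_id), function(tr) {
    res <- split_half_consistency(tr, epoch, config, op = op,
                                  seed = child_seed(seed, 57L, tr$neuron_id[1]),
                                  ...)
    if (isTRUE(res$unusable)) {
      return(data.frame(neuron_id = res$neuron_id, epoch = epoch,
                        unusable = TRUE, internal = NA, internal_se = NA))
    }
    cbind(data.frame(neuron_id = res$neuron_id, epoch = epoch,
                     unusable = FALSE, internal = res$internal,
                     internal_se = res$internal_se,
                     n_discarded = res$n_discarded),
          as.data.frame(as.list(res$model)),
          stats::setNames(as.data.frame(as.list(res$model_se)),
                          paste0(names(res$model_se), "_se")))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pairwise signed-rank comparison of model consistencies
#'
#' Two-tailed Wilcoxon signed-rank test on the paired per-neuron
#' consistencies for every pair of models, plus a winner summary.
#'
#' @param consistency data.frame with one row per neuron(-epoch) and one
#'   column per model named `model_<id>` (as from [session_consistency()]).
#' @param models model ids to compare (default: all `model_*` columns).
#' @return list with `p_matrix` (models x models, symmetric; diagonal NA;
#'   p = 1 when all pairwise differences are zero), `mean_consistency`,
#'   `best_model` (highest mean), and `n`.
#' @export
compare_models <- function(consistency, models = NULL) {
  cols <- grep("^model_[0-9]+$", names(consistency), value = TRUE)
  if (!is.null(models)) cols <- paste0("model_", models)
  if (!all(cols %in% names(consistency))) stop_invalid("missing model columns")
  X <- as.matrix(consistency[, cols, drop = FALSE])
  X <- X[stats::complete.cases(X), , drop = FALSE]
  if (nrow(X) < 6) stop_invalid("signed-rank comparison needs >= 6 neurons")
  k <- ncol(X)
  P <- matrix(NA_real_, k, k, dimnames = list(cols, cols))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      d <- X[, i] - X[, j]
      p <- if (all(d == 0)) 1 else
        suppressWarnings(wilcox.test(d, exact = FALSE)$p.value)
      P[i, j] <- P[j, i] <- p
    }
  }
  mns <- colMeans(X)
  list(p_matrix = P, mean_consistency = mns,
       best_model = names(mns)[which.max(mns)], n = nrow(X))
}
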