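test_that("epoch windows match the 500 ms event-aligned convention", {
  w <- epoch_windows()
  expect_equal(w$end_ms - w$start_ms, rep(500, 5))
  em <- w[w$epoch == "EM", ]
  expect_equal(c(em$anchor, em$start_ms, em$end_ms), c("cue offset", "200", "700"))
  lm <- w[w$epoch == "LM", ]
  expect_equal(c(lm$anchor, lm$start_ms, lm$end_ms), c("go signal", "-700", "-200"))
  expect_equal(w$start_ms[w$epoch == "baseline"], -500)
})

test_that("task-relatedness screen: null, powered, and floor cases", {
  cfg <- make_task1(5, 10)
  # exact null: deterministic table, every epoch equals baseline -> p = 1
  flat <- deterministic_trials(ground_truth_neuron(1, 0, baseline_rate = 8,
                                                   epoch_gains = 0), cfg, 5)
  expect_false(is_task_related(flat)$task_related)
  # stochastic null: false-positive count over 20 neurons stays binomial
  pop0 <- lapply(1:20, function(i) ground_truth_neuron(i, 0, NULL, 8, 0))
  tr0 <- simulate_session(cfg, pop0, 20, seed = 31)
  hits <- vapply(split(tr0, tr0$neuron_id),
                 function(tt) is_task_related(tt)$task_related, TRUE)
  expect_lte(sum(hits), 5) # P(>5 | Binomial(20, ~0.05)) < 1e-3
  # strong EM response (tuned neuron: gains act through the tuning curve)
  resp <- ground_truth_neuron(1, 1, c(theta0 = 0), baseline_rate = 5,
                              epoch_gains = c(C = 0, EM = 20, LM = 0, RTMT = 0))
  tr2 <- simulate_session(cfg, list(resp), 40, seed = 32)
  screen <- is_task_related(tr2)
  expect_true(screen$task_related)
  expect_lt(screen$p_values[["EM"]], 0.05 / 4)
  # sub-1 Hz neuron is excluded regardless of p-values (deterministic table:
  # constant nonzero difference gives p = 0 but the floor blocks it)
  low <- deterministic_trials(
    ground_truth_neuron(1, 0, baseline_rate = 0.4, epoch_gains = 0.5),
    cfg, n_rep = 5)
  screen3 <- is_task_related(low)
  expect_false(screen3$task_related)
  expect_true(screen3$degenerate)
  expect_error(is_task_related(tr2[1, , drop = FALSE]), ">= 2")
})

test_that("two-way ANOVA matches the brute-force sums-of-squares oracle", {
  # hand-checkable 2x2 with 2 trials per cell
  y <- c(1, 2, 5, 6, 2, 3, 9, 12)
  d <- rep(c("A", "B"), each = 4)
  a <- rep(c("s", "s", "l", "l"), 2)
  got <- anova2_interaction(y, d, a)
  want <- oracle_anova_balanced(y, d, a)
  expect_equal(got$F, want$F, tolerance = 1e-10)
  expect_equal(got$p, want$p, tolerance = 1e-10)
  # random balanced designs up to 4 x 3 x 5 trials
  withr::with_seed(41, {
    for (rep in 1:20) {
      nd <- sample(2:4, 1); na <- sample(2:3, 1); k <- sample(2:5, 1)
      d <- rep(seq_len(nd), each = na * k)
      a <- rep(rep(seq_len(na), each = k), nd)
      y <- rnorm(nd * na * k, mean = as.numeric(a))
      got <- anova2_interaction(y, d, a)
      want <- oracle_anova_balanced(y, d, a)
      expect_equal(got$F, want$F, tolerance = 1e-9)
    }
  })
})

test_that("ANOVA degeneracies and errors are handled as contracts say", {
  # pure amplitude effect, zero noise: amplitude p ~ 0, others uninformative
  d <- rep(1:4, each = 4); a <- rep(rep(1:2, each = 2), 4)
  y <- 3 * a
  res <- anova2_interaction(y, d, a)
  expect_true(isTRUE(attr(res, "degenerate")))
  expect_equal(res$p[res$effect == "amplitude"], 0)
  expect_equal(res$p[res$effect == "direction"], 1)
  expect_equal(res$p[res$effect == "interaction"], 1)
  expect_error(anova2_interaction(y, rep(1, 16), a), "2 levels")
  expect_error(anova2_interaction(y[d != 1 | a != 2], d[d != 1 | a != 2],
                                  a[d != 1 | a != 2]), "empty cell")
  # unbalanced type II agrees with lm-based residual comparison by construction;
  # sanity: amplitude effect still detected
  withr::with_seed(42, {
    d2 <- sample(1:4, 80, TRUE); a2 <- sample(1:2, 80, TRUE)
    y2 <- rnorm(80) + 2 * a2
  })
  res2 <- anova2_interaction(y2, d2, a2)
  expect_lt(res2$p[res2$effect == "amplitude"], 1e-6)
})

test_that("direction-wise amplitude t-tests localize the modulated direction", {
  cfg <- make_task1(5, 10)
  # +10 Hz at (90 deg, large amplitude) only
  tg <- cfg$targets
  boost <- which(tg$direction_deg == 90 & tg$amplitude_cm == 10)
  g5 <- ground_truth_neuron(1, 5,
                            c(mu_x = tg$x_cm[boost], mu_y = tg$y_cm[boost],
                              sigma_x = 1.5, sigma_y = 1.5, rho = 0),
                            baseline_rate = 10, epoch_gains = 10)
  tr <- simulate_session(cfg, list(g5), 40, seed = 51)
  res <- directionwise_amplitude_tests(tr, "EM")
  expect_equal(res$tests$direction_deg[which.min(res$tests$p)], 90)
  expect_lt(res$tests$p[res$tests$direction_deg == 90], 0.001)
  expect_equal(res$n_significant, sum(res$tests$p < 0.05))
  # degenerate equal-and-constant cells give p = 1
  det <- deterministic_trials(ground_truth_neuron(1, 0, baseline_rate = 4,
                                                  epoch_gains = 0), cfg, 3)
  res2 <- directionwise_amplitude_tests(det, "EM")
  expect_true(all(res2$tests$p == 1) && all(res2$tests$degenerate))
  # three amplitude levels are refused with a pointer to Task-2 analyses
  cfg2 <- make_task2()
  tr2 <- simulate_session(cfg2, list(ground_truth_neuron(1, 0)), 3, seed = 5)
  expect_error(directionwise_amplitude_tests(tr2, "EM"), "Task 1")
})

test_that("amplitude-selectivity flags implement the Bonferroni arithmetic", {
  fake <- function(p_amp, p_int) {
    data.frame(effect = c("direction", "amplitude", "interaction"),
               df1 = 1, df2 = 10, F = 1, p = c(0.5, p_amp, p_int))
  }
  all_null <- list(C = fake(0.9, 0.9), EM = fake(0.9, 0.9),
                   LM = fake(0.9, 0.9), RTMT = fake(0.9, 0.9))
  fl <- amplitude_selectivity_flags(all_null)
  expect_false(fl$any_epoch); expect_false(fl$planning)
  one_hit <- all_null; one_hit$EM <- fake(0.9, 0.001)
  fl2 <- amplitude_selectivity_flags(one_hit)
  expect_true(fl2$any_epoch) # 0.001 < 0.05/8
  expect_true(fl2$planning)  # EM is a planning epoch, 0.001 < 0.05/4
  # 0.008 everywhere clears neither the /8 rule (0.00625) nor... but does
  # clear the /4 planning rule (0.0125)
  borderline <- list(C = fake(0.008, 0.9), EM = fake(0.008, 0.9),
                     LM = fake(0.008, 0.9), RTMT = fake(0.008, 0.9))
  fl3 <- amplitude_selectivity_flags(borderline)
  expect_false(fl3$any_epoch)
  expect_true(fl3$planning)
  expect_error(amplitude_selectivity_flags(all_null[1:3]), "must contain")
})

test_that("binomial proportion test is the exact upper tail", {
  expect_equal(population_proportion_test(0, 100), 1)
  expect_equal(population_proportion_test(100, 100), 0.05^100)
  # brute-force pmf summation oracle
  brute <- sum(dbinom(10:100, 100, 0.05))
  expect_equal(population_proportion_test(10, 100), brute, tolerance = 1e-12)
  expect_error(population_proportion_test(3, 10, p0 = 1.2), "p0")
})

test_that("shuffle null collapses the selectivity of a tuned population", {
  cfg <- make_task1(5, 10)
  withr::with_seed(61, pop <- lapply(1:8, function(i)
    ground_truth_neuron(i, 2, c(theta0 = runif(1, -pi, pi), k = 1), 5, 30)))
  tr <- simulate_session(cfg, pop, 20, seed = 62)
  sel <- selectivity_table(tr, cfg)
  observed <- mean(sel$amp_any_epoch[sel$task_related])
  null <- shuffle_null_proportion(tr, cfg, n_shuffles = 5, seed = 63)
  expect_gt(observed, 0.5)            # gain-modulated neurons are selective
  expect_lt(null$mean_proportion, 0.2) # shuffling destroys it
  expect_identical(null,
                   shuffle_null_proportion(tr, cfg, n_shuffles = 5, seed = 63))
  expect_error(shuffle_null_proportion(tr, cfg, n_shuffles = 0), ">= 1")
  # constant-rate population: degenerate tests never fire
  const <- deterministic_trials(ground_truth_neuron(1, 0, baseline_rate = 6,
                                                    epoch_gains = 0), cfg, 3)
  expect_equal(shuffle_null_proportion(const, cfg, n_shuffles = 2, seed = 1,
                                       task_related_only = FALSE)$mean_proportion, 0)
})

test_that("population summary counts and binomial p are coherent", {
  cfg <- make_task1(5, 10)
  pop <- c(list(ground_truth_neuron(1, 2, c(theta0 = 0, k = 1), 5, 30)),
           lapply(2:6, function(i) ground_truth_neuron(i, 0, NULL, 5, 20)))
  tr <- simulate_session(cfg, pop, 30, seed = 71)
  sel <- selectivity_table(tr, cfg)
  s <- population_summary(sel)
  expect_equal(s$n_neurons, 6)
  expect_equal(s$k_amplitude_selective, sum(sel$amp_any_epoch[sel$task_related]))
  expect_equal(s$binomial_p,
               population_proportion_test(s$k_amplitude_selective,
                                          s$n_task_related))
})
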