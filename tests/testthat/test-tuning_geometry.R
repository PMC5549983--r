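test_that("preferred direction: peaks, ties, dense sampling", {
  cfg <- make_task1(5, 10)
  g1 <- ground_truth_neuron(1, 1, c(theta0 = pi), 5, 20)
  det <- deterministic_trials(g1, cfg, 2)
  expect_equal(preferred_direction(det, "EM", cfg)$direction_deg, 180)
  # all-equal means: smallest angle wins, tie flagged
  flat <- deterministic_trials(ground_truth_neuron(1, 0, baseline_rate = 5,
                                                   epoch_gains = 0), cfg, 2)
  pd <- preferred_direction(flat, "EM", cfg)
  expect_equal(pd$direction_deg, 0)
  expect_true(pd$tie)
  # Gaussian neuron with mu on the 45 deg ray, dense radial layout
  cfg2 <- make_task2(radial_offset = 0)
  g5 <- ground_truth_neuron(2, 5, c(mu_x = 5 * cos(pi / 4),
                                    mu_y = 5 * sin(pi / 4),
                                    sigma_x = 2, sigma_y = 2, rho = 0), 5, 30)
  det2 <- deterministic_trials(g5, cfg2, 2)
  expect_equal(preferred_direction(det2, "EM", cfg2)$direction_deg, 45)
  expect_error(preferred_direction(det2[0, ], "EM"), "no trials")
})

test_that("delta-PD wraps correctly and excludes unmodulated neurons", {
  cfg <- make_task1(5, 10)
  tg <- cfg$targets
  mk <- function(pd_deg, mod_deg) {
    # high rate along pd_deg (both amplitudes); amplitude difference along
    # mod_deg only; small within-cell noise so the t-test is defined
    tt <- deterministic_trials(ground_truth_neuron(1, 0, baseline_rate = 10,
                                                   epoch_gains = 0), cfg, 20)
    tt$rate_em_hz <- 10 +
      30 * (tt$direction_deg == pd_deg) +
      10 * (tt$direction_deg == mod_deg) * (tt$amplitude_cm == 10)
    withr::with_seed(81, tt$rate_em_hz <- tt$rate_em_hz + rnorm(nrow(tt), 0, 0.5))
    tt
  }
  same <- delta_pd(mk(90, 90), "EM", cfg)
  expect_true(same$included)
  expect_equal(same$delta_pd_deg, 0)
  wrapped <- delta_pd(mk(270, 0), "EM", cfg)
  expect_equal(wrapped$delta_pd_deg, 90) # 0 - 270 wrapped into (-180, 180]
  # no significant direction -> excluded, not an error
  null <- deterministic_trials(ground_truth_neuron(1, 0, baseline_rate = 10,
                                                   epoch_gains = 0), cfg, 5)
  withr::with_seed(82, null$rate_em_hz <- null$rate_em_hz + rnorm(nrow(null), 0, 0.1))
  dp <- delta_pd(null, "EM", cfg)
  if (!dp$included) expect_true(is.na(dp$delta_pd_deg))
  # adding 360 degrees to the labels changes nothing
  shifted <- mk(90, 90)
  shifted$direction_deg <- shifted$direction_deg + 360
  expect_equal(delta_pd(shifted, "EM", cfg)$delta_pd_deg, same$delta_pd_deg)
})

test_that("Rayleigh test: concentration, uniformity, MC oracle agreement", {
  conc <- rayleigh_test(rep(33, 10))
  expect_equal(conc$R_bar, 1)
  expect_lt(conc$p, 0.001)
  unif <- rayleigh_test(seq(0, 337.5, by = 22.5))
  expect_lt(unif$R_bar, 1e-10)
  expect_equal(unif$p, 1, tolerance = 1e-6)
  expect_error(rayleigh_test(c(1, 2, 3)), "n >= 4")
  # approximation vs Monte-Carlo null of R_bar on fixed angle sets
  sets <- list(c(10, 80, 200, 300, 40, 150, 260, 330, 15, 120),
               c(0, 20, 40, 60, 80, 100, 120, 140),
               c(5, 10, 15, 20, 190, 200, 210, 220, 100, 280),
               c(350, 10, 30, 170, 200, 220, 90, 270, 45, 135, 315, 225),
               c(12, 25, 33, 47, 55, 61, 78, 82, 95, 101))
  for (ang in sets) {
    got <- rayleigh_test(ang)
    mc <- oracle_rayleigh_p(length(ang), got$R_bar)
    expect_lt(abs(got$p - mc), 0.005)
  }
})

test_that("Rayleigh type-I calibration at n = 20", {
  nrep <- 1000
  withr::with_seed(91, {
    th <- matrix(runif(nrep * 20, 0, 360), nrep, 20)
  })
  rej <- mean(apply(th, 1, function(a) rayleigh_test(a)$p) < 0.05)
  expect_gte(rej, 0.037)
  expect_lte(rej, 0.064)
})

test_that("circular mean and SE behave as the dispersion formula dictates", {
  sym <- circular_mean_se(c(10, 350))
  expect_equal(sym$mean_deg, 0)
  const <- circular_mean_se(c(90, 90, 90))
  expect_equal(const$mean_deg, 90)
  expect_equal(const$se_deg, 0)
  expect_error(circular_mean_se(c(0, 180)), "undefined")
  # consistency: mean of 1e4 Von Mises draws within 3 SE of the center
  withr::with_seed(92, ang <- rvonmises(1e4, 30, 2))
  cm <- circular_mean_se(ang)
  expect_lt(abs(cm$mean_deg - 30), 3 * cm$se_deg)
})

test_that("amplitude-response curves rise along the preferred direction", {
  cfg <- make_task2(radial_offset = 0)
  tg <- active_targets(cfg)
  far <- tg[tg$dir_index == 3 & tg$amp_index == 3, ] # PD ray, largest amplitude
  g5 <- ground_truth_neuron(1, 5, c(mu_x = far$x_cm, mu_y = far$y_cm,
                                    sigma_x = 3, sigma_y = 3, rho = 0), 5, 40)
  det <- deterministic_trials(g5, cfg, 2)
  ac <- amplitude_response_curve(det, cfg)
  pd_curve <- ac$curve[ac$curve$branch == "PD" & ac$curve$epoch == "EM", ]
  pd_curve <- pd_curve[order(pd_curve$amplitude_cm), ]
  expect_true(all(diff(pd_curve$norm_rate) > 0))
  expect_gt(ac$pd_r, 0)
  expect_lt(ac$anti_r, ac$pd_r)
  # exactly linear rates along the PD give r = 1
  lin <- det
  lin[paste0("rate_", c("c", "em", "lm", "rtmt"), "_hz")] <- 0
  onpd <- lin$direction_deg == 45 # dir_index 3 at offset 0
  lin$rate_em_hz[onpd] <- lin$amplitude_cm[onpd]
  lin$rate_c_hz[onpd] <- lin$amplitude_cm[onpd]
  lin$rate_lm_hz[onpd] <- lin$amplitude_cm[onpd]
  lin$rate_rtmt_hz[onpd] <- lin$amplitude_cm[onpd]
  ac2 <- amplitude_response_curve(lin, cfg)
  expect_equal(ac2$pd_r, 1, tolerance = 1e-9)
  expect_error(amplitude_response_curve(det, make_task1()), "3 amplitude")
})

test_that("population delta-PD distribution concentrates at 0 when gain sits on the PD", {
  cfg <- make_task1(5, 10)
  tg <- cfg$targets
  dirs <- c(0, 90, 180, 270)
  withr::with_seed(95, pick <- sample(dirs, 24, TRUE))
  pop <- lapply(seq_along(pick), function(i) {
    # Gaussian centered beyond the large-amplitude target on the chosen ray:
    # rates rise along that direction and with amplitude
    th <- pick[i] * pi / 180
    ground_truth_neuron(i, 5, c(mu_x = 12 * cos(th), mu_y = 12 * sin(th),
                                sigma_x = 4, sigma_y = 4, rho = 0), 5, 40)
  })
  tr <- simulate_session(cfg, pop, 40, seed = 96)
  ds <- population_direction_stats(tr, cfg)
  pooled <- ds$summary$pooled
  expect_gt(pooled$n, 10)
  expect_lt(pooled$rayleigh_p, 0.05)
  expect_lt(abs(pooled$circular_mean), 30)
})
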