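# Independent oracles used to freeze expected values. These deliberately
# share no code with the package implementation paths they check.

# Brute-force two-way ANOVA sums of squares on a balanced design, computed
# with explicit loops over the raw definitions.
oracle_anova_balanced <- function(y, d, a) {
  d <- as.character(d); a <- as.character(a)
  grand <- sum(y) / length(y)
  ss_d <- 0
  for (lv in unique(d)) {
    yy <- y[d == lv]
    ss_d <- ss_d + length(yy) * (mean(yy) - grand)^2
  }
  ss_a <- 0
  for (lv in unique(a)) {
    yy <- y[a == lv]
    ss_a <- ss_a + length(yy) * (mean(yy) - grand)^2
  }
  ss_cells <- 0
  ss_e <- 0
  for (ld in unique(d)) {
    for (la in unique(a)) {
      yy <- y[d == ld & a == la]
      ss_cells <- ss_cells + length(yy) * (mean(yy) - grand)^2
      ss_e <- ss_e + sum((yy - mean(yy))^2)
    }
  }
  ss_i <- ss_cells - ss_d - ss_a
  nd <- length(unique(d)); na <- length(unique(a))
  df1 <- c(nd - 1, na - 1, (nd - 1) * (na - 1))
  df2 <- length(y) - nd * na
  F <- c(ss_d, ss_a, ss_i) / df1 / (ss_e / df2)
  list(F = F, p = pf(F, df1, df2, lower.tail = FALSE))
}

# Modified Bessel function of the first kind, order 0, by its power series.
oracle_bessel_i0 <- function(x, terms = 60) {
  k <- 0:terms
  sum((x / 2)^(2 * k) / factorial(k)^2)
}

# Monte-Carlo null distribution of the mean resultant length for n uniform
# angles; returns P(R_bar >= observed).
oracle_rayleigh_p <- function(n, r_obs, nsim = 1e5, seed = 424243) {
  withr::with_seed(seed, {
    th <- matrix(runif(nsim * n, 0, 2 * pi), nsim, n)
    r <- sqrt(rowMeans(cos(th))^2 + rowMeans(sin(th))^2)
    mean(r >= r_obs)
  })
}

# Von Mises sampler (Best & Fisher rejection algorithm), for consistency
# checks of the circular mean.
rvonmises <- function(n, mu_deg, kappa) {
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1
  while (i <= n) {
    u <- runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    if (c0 * (2 - c0) - u[2] > 0 || log(c0 / u[2]) + 1 - c0 >= 0) {
      out[i] <- sign(u[3] - 0.5) * acos(f)
      i <- i + 1
    }
  }
  (mu_deg + out * 180 / pi) %% 360
}

# deterministic trial table built from exact rates (no Poisson noise);
# n_rep identical trials per target
deterministic_trials <- function(neuron, config, n_rep = 2, jitter = 0) {
  tg <- active_targets(config)
  rates <- sapply(c("baseline", reachfield::EPOCHS),
                  function(e) rate_function(neuron, config, e))
  idx <- rep(seq_len(nrow(tg)), each = n_rep)
  out <- data.frame(neuron_id = neuron$neuron_id,
                    trial_id = seq_along(idx),
                    target_index = tg$index[idx],
                    direction_deg = tg$direction_deg[idx],
                    amplitude_cm = tg$amplitude_cm[idx],
                    rate_baseline_hz = rates[idx, 1],
                    rate_c_hz = rates[idx, 2],
                    rate_em_hz = rates[idx, 3],
                    rate_lm_hz = rates[idx, 4],
                    rate_rtmt_hz = rates[idx, 5],
                    mem_duration_s = 1.4)
  if (jitter > 0) {
    cols <- grep("^rate_", names(out))
    out[cols] <- out[cols] + matrix(rnorm(nrow(out) * length(cols), 0, jitter),
                                    nrow(out))
  }
  out
}
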