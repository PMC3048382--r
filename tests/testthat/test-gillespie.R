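test_that("pure-death trajectory decays monotonically to zero", {
  arch <- promoter_architecture("off", NULL, 0)
  tr <- simulate_trajectory(arch, gamma_m = 0.5, t_end = 1e4, seed = 3,
                            m0 = 5)
  expect_equal(tr$mrna_path[1], 5)
  expect_true(all(diff(tr$mrna_path) == -1))
  expect_equal(tr$mrna_path[length(tr$mrna_path)], 0)
  expect_true(all(diff(tr$event_times) > 0))
})

test_that("trajectories are reproducible bit-for-bit per seed", {
  arch <- simple_repression(kinetic_params())
  t1 <- simulate_trajectory(arch, GAMMA, 1e4, seed = 42)
  t2 <- simulate_trajectory(arch, GAMMA, 1e4, seed = 42)
  expect_identical(t1$event_times, t2$event_times)
  expect_identical(t1$mrna_path, t2$mrna_path)
  t3 <- simulate_trajectory(arch, GAMMA, 1e4, seed = 43)
  expect_false(identical(t1$event_times, t3$event_times))
  m1 <- suppressWarnings(time_average_moments(t1))
  m2 <- suppressWarnings(time_average_moments(t2))
  expect_identical(m1$mrna$mean, m2$mrna$mean)
})

test_that("trajectory structure follows the declared reaction network", {
  arch <- dual_repression(kinetic_params(tf_concentration = 3))
  tr <- simulate_trajectory(arch, GAMMA, 5e4, seed = 9)
  dm <- diff(tr$mrna_path)
  expect_true(all(dm %in% c(-1, 0, 1)))
  expect_true(all(tr$mrna_path >= 0))
  # promoter-state jumps only along declared transitions
  allowed <- paste(tr$states[match(arch$transitions$from, arch$states)],
                   tr$states[match(arch$transitions$to, arch$states)])
  s <- tr$state_path
  jumps <- which(diff(s) != 0)
  expect_true(all(paste(tr$states[s[jumps]],
                        tr$states[s[jumps + 1]]) %in% allowed))
  # an mRNA change and a state change never happen in the same event
  expect_true(all(!(dm != 0 & diff(s) != 0)))
})

test_that("one-state promoter time averages give Poisson statistics", {
  arch <- promoter_architecture("on", NULL, R_MAX)
  ss <- simulate_summary(arch, GAMMA, n_events = 4e5, seed = 5)
  expect_lt(abs(ss$mrna$mean - R_MAX / GAMMA), 3 * ss$mrna$mean_se)
  expect_lt(abs(ss$mrna$fano - 1), 3 * ss$mrna$fano_se)
})

test_that("long-run averages match analytic moments on random architectures", {
  n_bad_mean <- 0; n_bad_fano <- 0; n <- 20
  for (seed in 1:n) {
    arch <- fixture_random_architecture(sample(2:5, 1), seed + 300)
    gm <- random_gamma(seed + 300)
    analytic <- mrna_moments(arch, gm)
    if (analytic$degenerate) next
    ss <- simulate_summary(arch, gm, n_events = 4e5, seed = seed)
    if (abs(ss$mrna$mean - analytic$mean) > 3 * ss$mrna$mean_se)
      n_bad_mean <- n_bad_mean + 1
    if (abs(ss$mrna$fano - analytic$fano) > 3 * ss$mrna$fano_se)
      n_bad_fano <- n_bad_fano + 1
  }
  # with a 3-sigma band an occasional excursion is expected
  expect_lte(n_bad_mean, 2)
  expect_lte(n_bad_fano, 2)
})

test_that("stationary occupancy matches replicate SSA occupancies", {
  arch <- dual_repression(kinetic_params(tf_concentration = 1.5))
  p <- steady_state_probabilities(arch)
  reps <- vapply(1:8, function(s)
    simulate_summary(arch, GAMMA, n_events = 2.5e5, seed = s)$occupancy,
    numeric(4))
  est <- rowMeans(reps)
  se <- apply(reps, 1, sd) / sqrt(ncol(reps))
  expect_true(all(abs(est - p) < 3 * pmax(se, 1e-6)))
})

test_that("empirical histograms agree with the solved marginal (TV < 0.02)", {
  p <- promnoise_defaults()
  canon <- list(
    simple_repression(with_concentration(p, 1)),
    simple_activation(with_concentration(p, 1)),
    dual_repression(with_concentration(p, 0.5)),
    dual_activation(with_concentration(p, 0.3)),
    looping_repression(with_concentration(p, 1)))
  for (i in seq_along(canon)) {
    arch <- canon[[i]]
    d <- steady_state_distribution(arch, p$gamma_m)
    ss <- simulate_summary(arch, p$gamma_m, n_events = 4e6, seed = 100 + i)
    L <- max(length(ss$histogram), length(d$marginal))
    emp <- c(ss$histogram, rep(0, L - length(ss$histogram)))
    ana <- c(d$marginal, rep(0, L - length(d$marginal)))
    expect_lt(0.5 * sum(abs(emp - ana)), 0.02)
  }
})

test_that("protein simulation matches the exact protein moments", {
  p <- promnoise_defaults()
  arch <- simple_repression(with_concentration(p, 0.5))
  # fast protein turnover keeps the simulation well mixed within the run
  gp <- 0.002
  analytic <- protein_moments(arch, p$gamma_m, b = 5, gamma_p = gp)
  tr <- simulate_summary(arch, p$gamma_m, n_events = 8e5, seed = 77,
                         protein = list(b = 5, gamma_p = gp))
  expect_lt(abs(tr$protein$mean - analytic$mean),
            4 * tr$protein$mean_se)
  # geometric-burst shortcut approximates explicit translation
  trb <- simulate_summary(arch, p$gamma_m, n_events = 4e5, seed = 78,
                          protein = list(b = 5, gamma_p = gp, burst = TRUE))
  expect_lt(abs(trb$protein$mean - analytic$mean) / analytic$mean, 0.1)
})

test_that("weak operators switch fast, strong operators sit in long epochs", {
  p <- promnoise_defaults()                 # Oid-like strong operator
  pW <- kinetic_params(k_off = 1 / 11)      # O2-like weak operator
  target <- 0.3 * p$r_max / p$gamma_m
  cS <- concentration_for_mean(simple_repression, p, target)
  cW <- concentration_for_mean(simple_repression, pW, target)
  sS <- simulate_summary(simple_repression(with_concentration(p, cS)),
                         p$gamma_m, 2e5, seed = 21)
  sW <- simulate_summary(simple_repression(with_concentration(pW, cW)),
                         p$gamma_m, 2e5, seed = 21)
  expect_gt(sW$n_switches / sW$time_averaged,
            5 * sS$n_switches / sS$time_averaged)
})

test_that("time_average_moments guards its window and reports batch errors", {
  arch <- promoter_architecture("on", NULL, R_MAX)
  tr <- simulate_trajectory(arch, GAMMA, t_end = 2e5, seed = 11)
  expect_error(time_average_moments(tr, burn_in_fraction = 0.999999),
               "empty post-burn-in")
  m <- suppressWarnings(time_average_moments(tr))  # 1-state: no switching
  expect_true(is.finite(m$mrna$mean_se) && m$mrna$mean_se > 0)
  expect_lt(abs(m$mrna$mean - R_MAX / GAMMA), 4 * m$mrna$mean_se)
})
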