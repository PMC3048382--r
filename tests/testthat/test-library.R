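test_that("every builder output passes validation", {
  p <- kinetic_params(tf_concentration = 2)
  archs <- list(simple_repression(p), simple_activation(p),
                dual_repression(p), dual_activation(p),
                looping_repression(p))
  for (a in archs) expect_identical(validate_architecture(a), character(0))
})

test_that("simple repression: limits and the fold-change law", {
  p <- kinetic_params()
  a0 <- simple_repression(with_concentration(p, 0))
  expect_equal(unname(steady_state_probabilities(a0)), c(1, 0))
  expect_equal(mean_mrna(a0, p$gamma_m), p$r_max / p$gamma_m)

  kd <- p$k_off / p$k_on_assoc
  mean0 <- mean_mrna(a0, p$gamma_m)
  for (conc in kd * 10^seq(-2, 2, length.out = 9)) {
    m <- mean_mrna(simple_repression(with_concentration(p, conc)),
                   p$gamma_m)
    expect_equal(m / mean0, 1 / (1 + conc / kd), tolerance = 1e-10)
  }
  expect_equal(mean_mrna(simple_repression(with_concentration(p, kd)),
                         p$gamma_m) / mean0, 0.5, tolerance = 1e-12)
})

test_that("simple activation: no-regulation limit, saturation and the mean law", {
  p <- kinetic_params(f = 1, r_basal = 0.33, r_max = 0.33)
  mom <- mrna_moments(simple_activation(p), p$gamma_m)
  expect_equal(mom$fano, 1, tolerance = 1e-10)

  p <- kinetic_params()
  sat <- simple_activation(with_concentration(p, 1e9))
  expect_equal(mean_mrna(sat, p$gamma_m), p$r_max / p$gamma_m,
               tolerance = 1e-6)
  # mean = (r_basal + r_max [A]/Kd) / (gamma (1 + [A]/Kd))
  kd <- p$k_off / p$k_on_assoc
  for (conc in kd * 10^seq(-2, 2, length.out = 7)) {
    m <- mean_mrna(simple_activation(with_concentration(p, conc)),
                   p$gamma_m)
    x <- conc / kd
    expect_equal(m, (p$r_basal + p$r_max * x) / (p$gamma_m * (1 + x)),
                 tolerance = 1e-10)
  }
})

test_that("dual repression: independent binding factorizes; cooperativity amplifies noise", {
  p <- kinetic_params(tf_concentration = 1.7)
  # omega = 1: the two operators behave as independent two-state units
  occ <- steady_state_probabilities(dual_repression(p, omega_k = 1))
  kon <- k_on_eff(p)
  q <- kon / (kon + p$k_off)  # single-operator bound probability
  expect_equal(unname(occ), c((1 - q)^2, q * (1 - q), q * (1 - q), q^2),
               tolerance = 1e-10)

  a0 <- dual_repression(with_concentration(p, 0), omega_k = 1)
  expect_equal(mean_mrna(a0, p$gamma_m), p$r_max / p$gamma_m)

  target <- 0.2 * p$r_max / p$gamma_m
  cmp <- matched_mean_comparison(
    function(pp) dual_repression(pp, omega_k = 0.013),
    function(pp) dual_repression(pp, omega_k = 1), p, p, target)
  expect_gt(cmp$fano_a, cmp$fano_b)
})

test_that("dual architectures equal the lumped three-state chain", {
  # distinct singly-bound states vs lumped single-occupancy state with the
  # combinatorial rates 2*kon (in) and 2*omega*koff (out of 'both')
  p <- kinetic_params(tf_concentration = 2.4)
  kon <- k_on_eff(p); koff <- p$k_off; w <- 0.07
  lumped <- promoter_architecture(
    c("empty", "one", "both"),
    data.frame(from = c("empty", "one", "one", "both"),
               to = c("one", "empty", "both", "one"),
               rate = c(2 * kon, koff, kon, 2 * w * koff)),
    c(p$r_max, 0, 0))
  full <- dual_repression(p, omega_k = w)
  m4 <- mrna_moments(full, p$gamma_m)
  m3 <- mrna_moments(lumped, p$gamma_m)
  expect_equal(m3$mean, m4$mean, tolerance = 1e-10)
  expect_equal(m3$fano, m4$fano, tolerance = 1e-10)
})

test_that("dual activation: Poisson at f = 1, saturation, noise ordering", {
  p <- kinetic_params(tf_concentration = 0.4)
  mom <- mrna_moments(dual_activation(p, f = 1), p$gamma_m)
  expect_equal(mom$fano, 1, tolerance = 1e-10)

  p2 <- kinetic_params()
  sat <- dual_activation(with_concentration(p2, 1e10))
  expect_equal(mean_mrna(sat, p2$gamma_m),
               p2$f^2 * p2$r_basal / p2$gamma_m, tolerance = 1e-5)

  # cooperative > independent > simple activation at matched mean
  target <- 3 * p2$r_basal / p2$gamma_m
  coop <- function(pp) dual_activation(pp, omega_k = 0.013)
  indep <- function(pp) dual_activation(pp, omega_k = 1)
  c1 <- matched_mean_comparison(coop, indep, p2, p2, target)
  c2 <- matched_mean_comparison(indep, simple_activation, p2, p2, target)
  expect_gt(c1$fano_a, c1$fano_b)
  expect_gt(c2$fano_a, c2$fano_b)
})

test_that("looping: disabled loop reduces to simple repression; c controls the ordering", {
  p <- kinetic_params(tf_concentration = 0.9, j_factor = 0)
  loop0 <- looping_repression(p)
  simple <- simple_repression(p)
  mL <- mrna_moments(loop0, p$gamma_m)
  mS <- mrna_moments(simple, p$gamma_m)
  expect_equal(mL$mean, mS$mean, tolerance = 1e-9)
  expect_equal(mL$fano, mS$fano, tolerance = 1e-9)

  p <- promnoise_defaults()
  target <- 0.1 * p$r_max / p$gamma_m
  c1 <- matched_mean_comparison(
    function(pp) looping_repression(pp, c_loop = 1),
    simple_repression, p, p, target)
  expect_gte(c1$fano_a, c1$fano_b)
  c100 <- matched_mean_comparison(
    function(pp) looping_repression(pp, c_loop = 100),
    simple_repression, p, p, target)
  expect_lt(c100$fano_a, c100$fano_b)
})

test_that("loop rate vs distance: linearity, positivity, decay, range", {
  lp <- loop_distance_params()
  D <- seq(100, 500, by = 1)
  k <- loop_rate_from_distance(lp, D)
  expect_true(all(k >= 0))
  lp2 <- loop_distance_params(amplitude = 2 * lp$amplitude)
  expect_equal(loop_rate_from_distance(lp2, 250),
               2 * loop_rate_from_distance(lp, 250))
  # in-phase distances (multiples of the helical period) decay monotonically
  inphase <- lp$phase + lp$helical_period * (0:30)
  kin <- loop_rate_from_distance(lp, inphase)
  expect_true(all(diff(kin) < 0))
  expect_error(loop_rate_from_distance(lp, 10), "outside supported range")
})

test_that("closed forms agree with the matrix engine everywhere", {
  p <- kinetic_params()
  for (mode in c("repression", "activation")) {
    cf <- closed_form_two_state(p, mode)
    builder <- if (mode == "repression") simple_repression
               else simple_activation
    for (conc in 10^seq(-4, 4, length.out = 20)) {
      mom <- mrna_moments(builder(with_concentration(p, conc)), p$gamma_m)
      expect_equal(cf$mean(conc), mom$mean, tolerance = 1e-10)
      expect_equal(cf$fano(conc), mom$fano, tolerance = 1e-10)
    }
  }
  cfr <- closed_form_two_state(p, "repression")
  expect_equal(cfr$mean(0), p$r_max / p$gamma_m)
  expect_equal(cfr$fano(0), 1)
  # burst limit of activation with zero basal rate
  pa <- kinetic_params(r_basal = 0, f = 1)
  cfa <- closed_form_two_state(pa, "activation")
  tiny <- 1e-6 * pa$k_off / pa$k_on_assoc
  expect_equal(cfa$fano(tiny), 1 + pa$r_max / (pa$k_off + pa$gamma_m),
               tolerance = 1e-4)
})

test_that("repression Fano-vs-mean is peaked with Poisson limits", {
  p <- kinetic_params()
  conc <- p$k_off / p$k_on_assoc * 10^seq(-5, 5, length.out = 41)
  scan <- titration_scan(simple_repression, p, conc)
  expect_lt(scan$fano[1], 1.01)                   # unregulated end
  expect_lt(scan$fano[nrow(scan)], 1.05)          # fully repressed end
  expect_gt(max(scan$fano), 5)                    # interior peak
  imax <- which.max(scan$fano)
  expect_gt(imax, 1); expect_lt(imax, nrow(scan))
})
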