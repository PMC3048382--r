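two_state_arch <- function(kon, koff, r = c(R_MAX, 0)) {
  promoter_architecture(
    c("free", "bound"),
    data.frame(from = c("free", "bound"), to = c("bound", "free"),
               rate = c(kon, koff)), r)
}

test_that("stationary occupancy matches detailed balance and eigen oracle", {
  a <- two_state_arch(0.05, 0.05)
  expect_equal(unname(steady_state_probabilities(a)), c(0.5, 0.5))
  a <- two_state_arch(3 * 0.05, 0.05)
  expect_equal(unname(steady_state_probabilities(a)), c(0.25, 0.75))
  for (seed in 1:20) {
    arch <- fixture_random_architecture(sample(2:6, 1), seed)
    p <- steady_state_probabilities(arch)
    expect_equal(unname(p), unname(eigen_stationary(arch$generator)),
                 tolerance = 1e-9)
    expect_lt(max(abs(arch$generator %*% p)),
              1e-10 * max(abs(arch$generator)))
  }
})

test_that("partial mean vector solves the conditional-mean balance", {
  one <- promoter_architecture("on", NULL, 1)
  expect_equal(unname(partial_mean_vector(one, 0.1)), 10)
  for (seed in 1:10) {
    arch <- fixture_random_architecture(sample(2:5, 1), seed)
    gm <- random_gamma(seed)
    m <- partial_mean_vector(arch, gm)
    expect_true(all(is.finite(m)) && all(m >= 0))
    expect_equal(sum(m), mean_mrna(arch, gm), tolerance = 1e-10)
  }
  expect_error(partial_mean_vector(one, 0), "positive")
})

test_that("mean and second moment reproduce Poisson and fold-change limits", {
  one <- promoter_architecture("on", NULL, 1)
  expect_equal(mean_mrna(one, 0.1), 10)
  mu <- mean_mrna(one, 0.1)
  expect_equal(second_moment_mrna(one, 0.1), mu + mu^2, tolerance = 1e-12)

  # repression at [R] = Kd: occupancy 1/2, so mean = (r_max/gamma)/2
  p <- kinetic_params(r_max = 0.011 * 10)  # r_max/gamma = 10
  arch <- simple_repression(with_concentration(p, p$k_off / p$k_on_assoc))
  expect_equal(mean_mrna(arch, p$gamma_m), 5, tolerance = 1e-12)

  # equal transcription rates in every state: promoter state is irrelevant
  for (seed in 1:5) {
    arch <- fixture_random_architecture(4, seed)
    arch$transcription_rates <- rep(0.7, 4)
    gm <- random_gamma(seed)
    mom <- mrna_moments(arch, gm)
    expect_equal(mom$fano, 1, tolerance = 1e-9)
    expect_equal(mom$mean, 0.7 / gm, tolerance = 1e-10)
  }
})

test_that("noise decomposition and internal consistency hold exactly", {
  for (seed in 1:25) {
    arch <- fixture_random_architecture(sample(1:6, 1), seed)
    gm <- random_gamma(seed)
    mom <- mrna_moments(arch, gm)
    expect_gte(mom$variance, 0)
    expect_equal(mom$variance, mom$second_moment - mom$mean^2,
                 tolerance = 1e-10)
    expect_equal(mom$fano, mom$variance / mom$mean, tolerance = 1e-10)
    expect_equal(mom$cv2, mom$variance / mom$mean^2, tolerance = 1e-10)
    expect_equal(mom$cv2, 1 / mom$mean + mom$promoter_noise,
                 tolerance = 1e-10)
    expect_gte(mom$promoter_noise, -1e-10)
    expect_gte(mom$fano, 1 - 1e-10)
  }
})

test_that("rescaling every rate (including decay) leaves noise untouched", {
  for (seed in 1:8) {
    arch <- fixture_random_architecture(sample(2:5, 1), seed)
    gm <- random_gamma(seed)
    lambda <- 10^runif(1, -2, 2)
    scaled <- arch
    scaled$generator <- lambda * arch$generator
    scaled$transitions$rate <- lambda * arch$transitions$rate
    scaled$transcription_rates <- lambda * arch$transcription_rates
    m1 <- mrna_moments(arch, gm)
    m2 <- mrna_moments(scaled, lambda * gm)
    expect_equal(steady_state_probabilities(scaled),
                 steady_state_probabilities(arch), tolerance = 1e-9)
    expect_equal(m2$mean, m1$mean, tolerance = 1e-9)
    expect_equal(m2$fano, m1$fano, tolerance = 1e-8)
    expect_equal(m2$cv2, m1$cv2, tolerance = 1e-8)
  }
})

test_that("a silent promoter is a typed degenerate outcome, not NaN", {
  arch <- two_state_arch(0.01, 0.02, r = c(0, 0))
  mom <- mrna_moments(arch, 0.011)
  expect_s3_class(mom, "moment_result")
  expect_true(mom$degenerate)
  expect_identical(mom$mean, 0)
  expect_true(is.na(mom$fano) && is.na(mom$cv2))
})

test_that("one-state promoter is exactly Poisson; burst limit matches", {
  one <- promoter_architecture("on", NULL, R_MAX)
  expect_equal(mrna_moments(one, GAMMA)$fano, 1, tolerance = 1e-12)

  # activation with rare, long-lived activation events: fano -> 1 + r/(koff+gamma)
  koff <- 0.0023
  arch <- two_state_arch(1e-4 * koff, koff, r = c(0, R_MAX))
  fano <- mrna_moments(arch, GAMMA)$fano
  expect_equal(fano, 1 + R_MAX / (koff + GAMMA), tolerance = 0.01)
})

test_that("strong operators are noisier than weak at matched mean", {
  pS <- kinetic_params()                       # Oid-like lifetime ~7 min
  pW <- kinetic_params(k_off = 1 / 11)         # O2-like lifetime 11 s
  target <- 0.3 * R_MAX / GAMMA
  cmp <- matched_mean_comparison(simple_repression, simple_repression,
                                 pS, pW, target)
  expect_gt(cmp$fano_a, cmp$fano_b)
})

test_that("protein moments: closed forms, limits and operator ordering", {
  one <- promoter_architecture("on", NULL, R_MAX)
  pm <- protein_moments(one, GAMMA, b = 31.2, gamma_p = 0.00083)
  expect_identical(pm$species, "protein")
  expect_equal(pm$mean, 31.2 * R_MAX / 0.00083, tolerance = 1e-12)
  # constitutive bursty expression: fano = 1 + b gamma/(gamma + gamma_p)
  expect_equal(pm$fano, 1 + 31.2 * GAMMA / (GAMMA + 0.00083),
               tolerance = 1e-10)
  # short-mRNA-lifetime limit agrees with the exact solution
  pb <- protein_moments(one, GAMMA, b = 31.2, gamma_p = 1e-5,
                        method = "burst")
  pe <- protein_moments(one, GAMMA, b = 31.2, gamma_p = 1e-5)
  expect_equal(pb$fano, pe$fano, tolerance = 1e-2)
  expect_warning(
    protein_moments(one, gamma_m = 0.005, b = 2, gamma_p = 0.001,
                    method = "burst"),
    "marginal")
  expect_error(protein_moments(one, GAMMA, b = 0, gamma_p = 1), "b must")
  expect_error(protein_moments(one, GAMMA, b = 1, gamma_p = 0), "gamma_p")

  # operator-strength ordering carries over from mRNA to protein noise
  pS <- kinetic_params(); pW <- kinetic_params(k_off = 1 / 11)
  target <- 0.3 * R_MAX / GAMMA
  cS <- concentration_for_mean(simple_repression, pS, target)
  cW <- concentration_for_mean(simple_repression, pW, target)
  fS <- protein_moments(simple_repression(with_concentration(pS, cS)),
                        GAMMA, 31.2, 0.00083)$fano
  fW <- protein_moments(simple_repression(with_concentration(pW, cW)),
                        GAMMA, 31.2, 0.00083)$fano
  expect_gt(fS, fW)
})
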