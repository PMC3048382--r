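# Independent oracles used across the suite. These deliberately avoid the
# package's own solution paths: stationary occupancy by dense
# eigendecomposition, telegraph-model moments from the textbook closed
# form, and brute-force summation where a distribution is available.

# stationary vector of a generator by eigendecomposition (column convention)
eigen_stationary <- function(K) {
  e <- eigen(K)
  i <- which.min(abs(e$values))
  v <- Re(e$vectors[, i])
  v / sum(v)
}

# telegraph promoter: states (off rate r0, on rate r1), off->on rate a,
# on->off rate b; exact mean and Fano factor of the mRNA distribution
telegraph_moments <- function(r0, r1, a, b, gamma_m) {
  p1 <- a / (a + b)
  mu <- (r0 * (1 - p1) + r1 * p1) / gamma_m
  fano <- 1 + (r1 - r0)^2 * p1 * (1 - p1) /
    (gamma_m * (gamma_m + a + b) * mu)
  list(mean = mu, fano = fano)
}

# default kinetic scales shared by many tests
GAMMA <- 0.011
R_MAX <- 0.33

rel_err <- function(x, y) abs(x - y) / pmax(abs(y), .Machine$double.eps)

random_gamma <- function(seed) {
  set.seed(seed + 10000L)
  0.05 * 10^runif(1, -1, 1)
}
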