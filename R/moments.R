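#' Stationary promoter-state occupancy
#'
#' Solves `K p = 0`, `sum(p) = 1` for the stationary probability of each
#' promoter state. The null vector is obtained deterministically from the
#' bordered linear system (generator rows plus the normalization row) by a
#' least-squares QR solve; if that system is ill-conditioned the smallest
#' right singular vector of `K` is used instead.
#'
#' @param arch a [promoter_architecture()] object (validated, irreducible).
#' @return Numeric vector `p` of length N, nonnegative, summing to 1, with
#'   residual `max|K p| <= 1e-10 * max|K|`.
#' @export
steady_state_probabilities <- function(arch) {
  stopifnot(inherits(arch, "promoter_architecture"))
  K <- arch$generator
  N <- nrow(K)
  if (N == 1L) return(setNames(1, arch$states))
  sc <- max(abs(K))
  if (sc == 0) stop("generator is identically zero for N > 1", call. = FALSE)
  Ks <- K / sc
  A <- rbind(Ks, rep(1, N))
  b <- c(rep(0, N), 1)
  qa <- qr(A, tol = 1e-14)
  p <- tryCatch(qr.coef(qa, b), error = function(e) NULL)
  if (!is.null(p) && all(is.finite(p))) {
    # one step of iterative refinement against solver round-off
    dp <- tryCatch(qr.coef(qa, b - A %*% p), error = function(e) NULL)
    if (!is.null(dp) && all(is.finite(dp))) p <- p + dp
  }
  if (is.null(p) || any(!is.finite(p)) || any(p < -1e-8)) {
    v <- svd(Ks)$v[, N]
    p <- v / sum(v)
  }
  p <- pmax(p, 0)
  p <- p / sum(p)
  if (max(abs(K %*% p)) > 1e-10 * sc)
    stop("stationary solve failed: residual too large; ",
         "is the architecture irreducible?", call. = FALSE)
  setNames(as.numeric(p), arch$states)
}

#' Joint steady-state mean mRNA per promoter state
#'
#' The vector `m` with components `m_s = <m * 1[state = s]>` at steady
#' state: the mean mRNA carried jointly with each promoter state. It
#' solves the linear system `(K - gamma_m I) m = -R p`, where `R` is the
#' diagonal matrix of per-state transcription rates and `p` the stationary
#' occupancy. Its sum is the mean mRNA copy number.
#'
#' @inheritParams steady_state_probabilities
#' @param gamma_m mRNA decay rate, s^-1, > 0.
#' @return Numeric vector of length N, entries finite and >= 0.
#' @export
partial_mean_vector <- function(arch, gamma_m) {
  stopifnot(inherits(arch, "promoter_architecture"))
  if (!is.numeric(gamma_m) || length(gamma_m) != 1L || !(gamma_m > 0))
    stop("gamma_m must be a single positive number", call. = FALSE)
  K <- arch$generator
  N <- nrow(K)
  p <- steady_state_probabilities(arch)
  m <- solve(K - gamma_m * diag(N), -arch$transcription_rates * p)
  m <- pmax(as.numeric(m), 0)  # clip solver round-off at the hard bound
  setNames(m, arch$states)
}

#' Steady-state mean mRNA copy number
#'
#' `mean = (r . p) / gamma_m`: the occupancy-weighted transcription rate
#' divided by the decay rate; identical to the sum of the partial-mean
#' vector.
#'
#' @inheritParams partial_mean_vector
#' @return Mean mRNA copies per cell.
#' @export
mean_mrna <- function(arch, gamma_m) {
  stopifnot(inherits(arch, "promoter_architecture"))
  if (!(gamma_m > 0)) stop("gamma_m must be > 0", call. = FALSE)
  p <- steady_state_probabilities(arch)
  sum(arch$transcription_rates * p) / gamma_m
}

#' Steady-state second moment of mRNA copy number
#'
#' `<m^2> = <m> + (r . m) / gamma_m` with `m` the partial-mean vector;
#' exact for this model class (no closure approximation).
#'
#' @inheritParams partial_mean_vector
#' @return Second moment, copies^2.
#' @export
second_moment_mrna <- function(arch, gamma_m) {
  mu <- mean_mrna(arch, gamma_m)
  m <- partial_mean_vector(arch, gamma_m)
  mu + sum(arch$transcription_rates * m) / gamma_m
}

new_moment_result <- function(species, mean, second_moment) {
  variance <- max(second_moment - mean^2, 0)
  degenerate <- !(mean > 0)
  structure(list(
    species = species,
    mean = mean,
    second_moment = second_moment,
    variance = variance,
    fano = if (degenerate) NA_real_ else variance / mean,
    cv2 = if (degenerate) NA_real_ else variance / mean^2,
    promoter_noise = if (degenerate) NA_real_
                     else variance / mean^2 - 1 / mean,
    degenerate = degenerate),
    class = "moment_result")
}

#' Exact steady-state mRNA moments and noise measures
#'
#' Computes mean, second moment, variance, Fano factor (variance/mean),
#' squared coefficient of variation CV^2 (variance/mean^2) and the
#' promoter-noise component for the mRNA copy-number distribution. The
#' intrinsic noise always decomposes as `CV^2 = 1/mean + promoter_noise`:
#' the first term is the Poisson floor from single-molecule birth-death
#' events, the second is the extra variability contributed by stochastic
#' promoter-state switching (zero for a one-state promoter, for which the
#' distribution is exactly Poisson and the Fano factor is 1). The Fano
#' factor equals the deviation of the normalized variance from the Poisson
#' expectation at the same mean, which is why it is the architecture
#' comparison metric used throughout.
#'
#' A fully repressed promoter (mean 0) is reported as a typed degenerate
#' outcome: `degenerate = TRUE` with `fano`, `cv2`, `promoter_noise` set to
#' `NA`, so titration scans do not crash at the fully-repressed end.
#'
#' @inheritParams partial_mean_vector
#' @return A `moment_result` object: list with `species` ("mRNA"), `mean`,
#'   `second_moment`, `variance`, `fano`, `cv2`, `promoter_noise`,
#'   `degenerate`.
#' @export
#' @examples
#' one <- promoter_architecture("on", NULL, 1)
#' mrna_moments(one, gamma_m = 0.1)  # Poisson(10): fano 1
mrna_moments <- function(arch, gamma_m) {
  mu <- mean_mrna(arch, gamma_m)
  if (!(mu > 0)) return(new_moment_result("mRNA", 0, 0))
  new_moment_result("mRNA", mu, second_moment_mrna(arch, gamma_m))
}

#' Exact steady-state protein moments
#'
#' Protein copy number n evolves by translation at rate `b * gamma_m` per
#' transcript (so the mean number of proteins per mRNA lifetime is the
#' burst size `b`) and first-order decay at `gamma_p`. Because every
#' propensity is linear, the first and second moments of the joint
#' (promoter state, mRNA, protein) process close exactly; `method =
#' "exact"` solves that closed linear system with no timescale
#' approximation. `method = "burst"` instead treats translation in the
#' short-mRNA-lifetime limit (mRNA lifetime much shorter than protein
#' lifetime), where each transcript instantaneously delivers a
#' geometrically distributed burst of proteins with mean `b`; it uses the
#' auxiliary partial-mean vector solving the protein analogue of the
#' mRNA partial-mean equation, with synthesis rates `b * r` and decay
#' `gamma_p`. The two agree when `gamma_m >> gamma_p`; a warning is logged
#' when `gamma_m < 10 * gamma_p`, the edge of that limit's validity.
#'
#' @inheritParams partial_mean_vector
#' @param b protein burst size (proteins per mRNA), > 0.
#' @param gamma_p protein decay rate, s^-1, > 0.
#' @param method `"exact"` (default) or `"burst"`.
#' @return A `moment_result` with `species = "protein"`.
#' @export
protein_moments <- function(arch, gamma_m, b, gamma_p,
                            method = c("exact", "burst")) {
  method <- match.arg(method)
  stopifnot(inherits(arch, "promoter_architecture"))
  if (!(b > 0)) stop("burst size b must be > 0", call. = FALSE)
  if (!(gamma_p > 0)) stop("gamma_p must be > 0", call. = FALSE)
  if (!(gamma_m > 0)) stop("gamma_m must be > 0", call. = FALSE)
  if (method == "burst" && gamma_m < 10 * gamma_p)
    warning("short-mRNA-lifetime limit is marginal: gamma_m < 10 * gamma_p",
            call. = FALSE)
  K <- arch$generator
  N <- nrow(K)
  r <- arch$transcription_rates
  p <- steady_state_probabilities(arch)
  rp <- sum(r * p)
  n_mean <- b * rp / gamma_p                      # mean protein per cell
  if (!(n_mean > 0)) return(new_moment_result("protein", 0, 0))

  if (method == "burst") {
    # bursty birth-death: bursts of geometric size (mean b, <B^2> = b + 2b^2)
    # fired at the per-state rate r_s; auxiliary vector with rates b*r
    n_part <- solve(K - gamma_p * diag(N), -b * r * p)
    n2 <- (2 * b * sum(r * n_part) + (b + 2 * b^2) * rp +
             gamma_p * n_mean) / (2 * gamma_p)
  } else {
    ktl <- b * gamma_m                            # translation rate per mRNA
    m_part <- solve(K - gamma_m * diag(N), -r * p)
    m_mean <- sum(m_part)
    m2 <- m_mean + sum(r * m_part) / gamma_m
    n_part <- solve(K - gamma_p * diag(N), -ktl * m_part)
    # <mn> from the closed cross-moment balance
    mn <- (sum(r * n_part) + ktl * m2) / (gamma_m + gamma_p)
    n2 <- (ktl * (2 * mn + m_mean) + gamma_p * n_mean) / (2 * gamma_p)
  }
  new_moment_result("protein", n_mean, n2)
}

#' @export
print.moment_result <- function(x, ...) {
  cat(sprintf("%s steady-state moments%s\n", x$species,
              if (x$degenerate) " (degenerate: mean = 0)" else ""))
  cat(sprintf("  mean      %.6g\n  variance  %.6g\n", x$mean, x$variance))
  if (!x$degenerate)
    cat(sprintf("  fano      %.6g\n  cv2       %.6g\n  promoter  %.6g\n",
                x$fano, x$cv2, x$promoter_noise))
  invisible(x)
}

#' @export
as.data.frame.moment_result <- function(x, ...) {
  data.frame(species = x$species, mean = x$mean,
             second_moment = x$second_moment, variance = x$variance,
             fano = x$fano, cv2 = x$cv2, promoter_noise = x$promoter_noise,
             stringsAsFactors = FALSE)
}
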