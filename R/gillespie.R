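#' Exact stochastic simulation of a promoter trajectory
#'
#' Gillespie's direct method applied to the joint (promoter state, mRNA,
#' optionally protein) process: at each step the waiting time is drawn
#' from an exponential distribution whose rate is the sum of all reaction
#' propensities and one reaction is chosen with probability proportional
#' to its propensity, producing statistically exact sample paths of the
#' master equation. All randomness flows through R's RNG, so a given
#' `seed` reproduces a trajectory bit-for-bit.
#'
#' Protein synthesis is simulated explicitly by default: each transcript
#' fires translation events at rate `b * gamma_m`, so the mean number of
#' proteins per mRNA lifetime equals the burst size `b`. With
#' `burst = TRUE` translation is replaced by the short-mRNA-lifetime
#' shortcut in which every transcription event instantly delivers a
#' geometric burst of proteins with mean `b`.
#'
#' @param arch a [promoter_architecture()] object.
#' @param gamma_m mRNA decay rate, s^-1.
#' @param t_end simulated time horizon, s.
#' @param seed integer seed (required: no implicit randomness).
#' @param protein optional `list(b =, gamma_p =, burst = FALSE)` enabling
#'   protein simulation.
#' @param s0,m0,n0 initial promoter state (label or index), mRNA and
#'   protein copy numbers.
#' @param max_events safety cap on the number of simulated events.
#' @return An object of class `trajectory`: `event_times` (strictly
#'   increasing, starting at 0), `state_path` (state index per event),
#'   `mrna_path`, optional `protein_path`, plus `states`, `t_end`, `seed`.
#' @export
#' @examples
#' arch <- simple_repression(kinetic_params())
#' tr <- simulate_trajectory(arch, gamma_m = 0.011, t_end = 5e4, seed = 1)
#' time_average_moments(tr)
simulate_trajectory <- function(arch, gamma_m, t_end, seed, protein = NULL,
                                s0 = 1L, m0 = 0L, n0 = 0L,
                                max_events = 5e6) {
  stopifnot(inherits(arch, "promoter_architecture"), t_end > 0,
            gamma_m >= 0)
  if (missing(seed) || is.null(seed))
    stop("an explicit integer seed is required", call. = FALSE)
  if (is.character(s0)) s0 <- match(s0, arch$states)
  stopifnot(!is.na(s0), s0 >= 1L, s0 <= length(arch$states),
            m0 >= 0, n0 >= 0)
  popts <- protein_opts(protein, gamma_m)
  tr <- arch$transitions
  from <- match(tr$from, arch$states) - 1L
  to <- match(tr$to, arch$states) - 1L
  set.seed(as.integer(seed))
  res <- ssa_path_cpp(length(arch$states), from, to, tr$rate,
                      arch$transcription_rates, gamma_m, t_end,
                      as.integer(s0) - 1L, as.numeric(m0), as.numeric(n0),
                      popts, max_events)
  out <- list(event_times = res$times, state_path = res$states + 1L,
              mrna_path = res$mrna, protein_path = res$protein,
              states = arch$states, t_end = t_end, seed = as.integer(seed),
              n_events = res$n_events, gamma_m = gamma_m)
  class(out) <- "trajectory"
  out
}

protein_opts <- function(protein, gamma_m) {
  if (is.null(protein)) return(list())
  stopifnot(is.list(protein), protein$b > 0, protein$gamma_p > 0)
  burst <- isTRUE(protein$burst)
  list(ktl = protein$b * gamma_m, gamma_p = protein$gamma_p,
       b = protein$b, burst = burst)
}

#' Simulate method for promoter architectures
#'
#' Thin wrapper around [simulate_trajectory()] following the base R
#' `simulate()` generic: `nsim` independent trajectories with seeds
#' `seed, seed + 1, ...`.
#'
#' @param object a [promoter_architecture()].
#' @param nsim number of trajectories.
#' @param seed base integer seed.
#' @param gamma_m mRNA decay rate, s^-1.
#' @param t_end time horizon, s.
#' @param ... passed to [simulate_trajectory()].
#' @return A list of `trajectory` objects (length `nsim`), or a single
#'   trajectory if `nsim = 1`.
#' @export
simulate.promoter_architecture <- function(object, nsim = 1, seed = 1,
                                           gamma_m = 0.011, t_end = 1e4,
                                           ...) {
  out <- lapply(seq_len(nsim) - 1L, function(i)
    simulate_trajectory(object, gamma_m, t_end, seed + i, ...))
  if (nsim == 1) out[[1]] else out
}

#' Time-averaged moments of a trajectory
#'
#' Time-weighted steady-state mean and variance of the mRNA (and protein)
#' copy number over the post-burn-in portion of a trajectory, with Monte
#' Carlo standard errors from batch means: the window is split into
#' `batches` equal-time batches and the SE of the overall mean is the SD
#' of batch means divided by `sqrt(batches)`. A warning is issued when
#' fewer than 50 promoter switching events remain after burn-in, in which
#' case the averages are unlikely to have converged.
#'
#' @param trajectory a [simulate_trajectory()] result.
#' @param burn_in_fraction fraction of `t_end` discarded as burn-in.
#' @param batches number of batches (>= 2) for the standard errors.
#' @return A list: `mrna` (a `moment_result` plus `mean_se` and `fano_se`
#'   entries), optional `protein`, `occupancy` (time-weighted state
#'   occupancy), `n_switches`.
#' @export
time_average_moments <- function(trajectory, burn_in_fraction = 0.2,
                                 batches = 32L) {
  stopifnot(inherits(trajectory, "trajectory"),
            burn_in_fraction >= 0, burn_in_fraction < 1, batches >= 2)
  t0 <- burn_in_fraction * trajectory$t_end
  tt <- trajectory$event_times
  horizon <- min(trajectory$t_end, tt[length(tt)])
  if (t0 >= horizon) stop("empty post-burn-in window", call. = FALSE)

  grid <- c(tt[tt > t0 & tt < horizon], horizon)
  starts <- c(t0, utils::head(grid, -1))
  idx <- findInterval(starts, tt)      # value holding over each interval
  w <- grid - starts
  keep <- w > 0
  w <- w[keep]; idx <- idx[keep]
  TT <- sum(w)

  m <- trajectory$mrna_path[idx]
  s <- trajectory$state_path[idx]
  n_sw <- sum(diff(trajectory$state_path[trajectory$event_times >= t0]) != 0)
  if (n_sw < 50)
    warning("fewer than 50 promoter switching events after burn-in; ",
            "time averages may not be converged", call. = FALSE)

  batch_of <- pmin(batches, 1L + floor((starts[keep] - t0) /
                                         ((horizon - t0) / batches)))
  res_for <- function(x) {
    mu <- sum(x * w) / TT
    m2 <- sum(x^2 * w) / TT
    bT <- tapply(w, batch_of, sum)
    bmu <- tapply(x * w, batch_of, sum) / bT
    bm2 <- tapply(x^2 * w, batch_of, sum) / bT
    bfano <- ifelse(bmu > 0, (bm2 - bmu^2) / bmu, NA)
    mr <- new_moment_result("mRNA", mu, m2)
    mr$mean_se <- stats::sd(bmu) / sqrt(length(bmu))
    mr$fano_se <- stats::sd(bfano[is.finite(bfano)]) /
      sqrt(sum(is.finite(bfano)))
    mr
  }
  out <- list(mrna = res_for(m),
              occupancy = setNames(
                as.numeric(tapply(w, factor(s, seq_along(trajectory$states)),
                                  sum, default = 0)) / TT,
                trajectory$states),
              n_switches = n_sw, time_averaged = TT)
  if (!is.null(trajectory$protein_path)) {
    out$protein <- res_for(trajectory$protein_path[idx])
    out$protein$species <- "protein"
  }
  out
}

#' Long-run streaming simulation summary
#'
#' Runs the SSA for a fixed number of events without storing the path,
#' accumulating time-weighted occupancies, mRNA (and protein) moments
#' with batch-means standard errors, and the empirical mRNA histogram.
#' This is the Monte-Carlo oracle used to validate the analytic moment
#' engine and the distribution solver on long runs (1e6-1e7 events).
#'
#' @inheritParams simulate_trajectory
#' @param n_events number of reaction events to simulate.
#' @param burn_in_fraction fraction of events discarded before averaging.
#' @param batches number of event-counted batches for standard errors.
#' @param hist_max histogram cap on mRNA copy number (auto: analytic
#'   mean + 12 sd).
#' @return A list: `occupancy`, `mrna` / optional `protein`
#'   (`moment_result`s with `mean_se`, `fano_se`), `histogram`
#'   (normalized, counts from 0), `n_switches`, `time_averaged`.
#' @export
simulate_summary <- function(arch, gamma_m, n_events, seed, protein = NULL,
                             burn_in_fraction = 0.2, batches = 32L,
                             s0 = 1L, m0 = 0L, n0 = 0L, hist_max = NULL) {
  stopifnot(inherits(arch, "promoter_architecture"), n_events >= 100)
  if (missing(seed) || is.null(seed))
    stop("an explicit integer seed is required", call. = FALSE)
  if (is.null(hist_max)) {
    mom <- mrna_moments(arch, gamma_m)
    hist_max <- if (mom$degenerate) 64L
                else max(64L, ceiling(mom$mean + 12 * sqrt(mom$variance)))
  }
  popts <- protein_opts(protein, gamma_m)
  tr <- arch$transitions
  set.seed(as.integer(seed))
  res <- ssa_longrun_cpp(length(arch$states),
                         match(tr$from, arch$states) - 1L,
                         match(tr$to, arch$states) - 1L, tr$rate,
                         arch$transcription_rates, gamma_m,
                         as.numeric(n_events),
                         as.integer(s0) - 1L, as.numeric(m0),
                         as.numeric(n0), popts, burn_in_fraction,
                         as.integer(batches), as.integer(hist_max))
  TT <- res$T
  if (!(TT > 0)) stop("simulation accumulated no time (all rates zero?)",
                      call. = FALSE)
  bT <- res$batch[, 1]
  ok <- bT > 0
  summarize <- function(sum_x, sum_x2, bcol) {
    mr <- new_moment_result("mRNA", sum_x / TT, sum_x2 / TT)
    bmu <- res$batch[ok, bcol] / bT[ok]
    bm2 <- res$batch[ok, 3] / bT[ok]
    mr$mean_se <- stats::sd(bmu) / sqrt(sum(ok))
    bfano <- ifelse(bmu > 0, (bm2 - bmu^2) / bmu, NA)
    mr$fano_se <- stats::sd(bfano[is.finite(bfano)]) /
      sqrt(sum(is.finite(bfano)))
    mr
  }
  out <- list(occupancy = setNames(res$occupancy / TT, arch$states),
              mrna = summarize(res$sum_m, res$sum_m2, 2),
              histogram = res$hist / TT,
              n_switches = res$switches, time_averaged = TT)
  if (length(popts)) {
    pr <- new_moment_result("protein", res$sum_n / TT, res$sum_n2 / TT)
    bmu <- res$batch[ok, 4] / bT[ok]
    pr$mean_se <- stats::sd(bmu) / sqrt(sum(ok))
    out$protein <- pr
  }
  out
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("SSA trajectory: %d events over %.4g s (seed %d)\n",
              length(x$event_times) - 1L, x$t_end, x$seed))
  cat(sprintf("  final state %s, mRNA %d%s\n",
              x$states[x$state_path[length(x$state_path)]],
              as.integer(x$mrna_path[length(x$mrna_path)]),
              if (!is.null(x$protein_path))
                sprintf(", protein %d",
                        as.integer(x$protein_path[length(x$protein_path)]))
              else ""))
  invisible(x)
}

#' @export
plot.trajectory <- function(x, what = c("mrna", "protein", "state"), ...) {
  what <- match.arg(what)
  y <- switch(what, mrna = x$mrna_path, protein = x$protein_path,
              state = x$state_path)
  if (is.null(y)) stop("trajectory has no ", what, " path", call. = FALSE)
  graphics::plot(x$event_times, y, type = "s", xlab = "time (s)",
                 ylab = paste(what, "copy number"), ...)
  invisible(x)
}

#' Write a trajectory as TSV
#'
#' Columns `time`, `state`, `mrna` and, when simulated, `protein`.
#'
#' @param trajectory a `trajectory` object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trajectory_tsv <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "trajectory"))
  df <- data.frame(time = trajectory$event_times,
                   state = trajectory$states[trajectory$state_path],
                   mrna = as.integer(trajectory$mrna_path))
  if (!is.null(trajectory$protein_path))
    df$protein <- as.integer(trajectory$protein_path)
  write_results(df, path, format = "tsv", seed = trajectory$seed)
}
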