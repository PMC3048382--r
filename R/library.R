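#' Canonical promoter architectures
#'
#' Parameterized builders for the five bacterial promoter architectures:
#' simple repression, simple activation, dual (two-operator) repression and
#' activation with independent or cooperative binding, and repression by
#' DNA looping through an auxiliary operator. Every builder takes a
#' [kinetic_params()] bundle, derives the effective association rate
#' `k_on_assoc * tf_concentration`, and returns a validated
#' [promoter_architecture()].
#'
#' In the dual architectures the two operators are assumed to be of equal
#' strength; the two singly-bound states are kept distinct (4- and 5-state
#' graphs) rather than lumped, so no combinatorial factor-of-2 corrections
#' are needed anywhere. Cooperativity acts on the dissociation rate out of
#' the doubly-bound state, which is multiplied by `omega_k` per operator
#' (`omega_k = 1`: independent binding; `omega_k < 1`: the two bound
#' factors stabilize each other).
#'
#' @param params a [kinetic_params()] object.
#' @param omega_k kinetic cooperativity factor (> 0).
#' @param f enhancement factor (>= 1), ratio of active to basal
#'   transcription rates.
#' @param j_factor looping J-factor (local repressor concentration at the
#'   second operator when bound to the first), >= 0.
#' @param c_loop ratio of looped- to unlooped-state dissociation rates, > 0.
#' @return A [promoter_architecture()].
#' @name architecture_library
NULL

#' @describeIn architecture_library Two states: `free` transcribing at
#'   `r_max`, `bound` silent. The repressor binds at the effective
#'   association rate and falls off at `k_off`.
#' @export
simple_repression <- function(params) {
  stopifnot(inherits(params, "kinetic_params"))
  if (!(params$r_max > 0)) stop("r_max must be > 0", call. = FALSE)
  kon <- k_on_eff(params)
  promoter_architecture(
    states = c("free", "bound"),
    transitions = transitions_df(c("free", "bound"), c("bound", "free"),
                                 c(kon, params$k_off)),
    transcription_rates = c(params$r_max, 0),
    name = "simple_repression")
}

#' @describeIn architecture_library Two states: `free` transcribing at the
#'   basal rate, `bound` (activator on its site) at the activated rate.
#'   If `r_basal` and `r_max` are both set in `params` they are used
#'   directly; otherwise the active rate is `f * r_basal`.
#' @export
simple_activation <- function(params, f = params$f) {
  stopifnot(inherits(params, "kinetic_params"))
  if (f < 1) stop("enhancement factor f must be >= 1", call. = FALSE)
  r0 <- params$r_basal
  r1 <- if (!is.null(params$r_max) && params$r_max > 0) params$r_max
        else f * r0
  kon <- k_on_eff(params)
  promoter_architecture(
    states = c("free", "bound"),
    transitions = transitions_df(c("free", "bound"), c("bound", "free"),
                                 c(kon, params$k_off)),
    transcription_rates = c(r0, r1),
    name = "simple_activation")
}

#' @describeIn architecture_library Four states (`empty`, `O1`, `O2`,
#'   `both`); transcription only from `empty`. Association into each empty
#'   operator at the effective association rate, dissociation from
#'   singly-bound states at `k_off`, and out of the doubly-bound state at
#'   `omega_k * k_off` per operator.
#' @export
dual_repression <- function(params, omega_k = params$omega_k) {
  stopifnot(inherits(params, "kinetic_params"))
  if (!(omega_k > 0)) stop("omega_k must be > 0", call. = FALSE)
  if (!(params$r_max > 0)) stop("r_max must be > 0", call. = FALSE)
  kon <- k_on_eff(params); koff <- params$k_off
  promoter_architecture(
    states = c("empty", "O1", "O2", "both"),
    transitions = transitions_df(
      c("empty", "empty", "O1", "O2", "O1", "O2", "both", "both"),
      c("O1", "O2", "empty", "empty", "both", "both", "O1", "O2"),
      c(kon, kon, koff, koff, kon, kon, omega_k * koff, omega_k * koff)),
    transcription_rates = c(params$r_max, 0, 0, 0),
    name = "dual_repression")
}

#' @describeIn architecture_library Same 4-state graph as
#'   [dual_repression()], but each bound activator multiplies the
#'   transcription rate by `f`: rates `(r_basal, f r_basal, f r_basal,
#'   f^2 r_basal)`.
#' @export
dual_activation <- function(params, omega_k = params$omega_k,
                            f = params$f) {
  stopifnot(inherits(params, "kinetic_params"))
  if (!(omega_k > 0)) stop("omega_k must be > 0", call. = FALSE)
  if (f < 1) stop("enhancement factor f must be >= 1", call. = FALSE)
  kon <- k_on_eff(params); koff <- params$k_off
  r0 <- params$r_basal
  promoter_architecture(
    states = c("empty", "O1", "O2", "both"),
    transitions = transitions_df(
      c("empty", "empty", "O1", "O2", "O1", "O2", "both", "both"),
      c("O1", "O2", "empty", "empty", "both", "both", "O1", "O2"),
      c(kon, kon, koff, koff, kon, kon, omega_k * koff, omega_k * koff)),
    transcription_rates = c(r0, f * r0, f * r0, f^2 * r0),
    name = "dual_activation")
}

#' @describeIn architecture_library Five states: `empty` and `Oa`
#'   (repressor on the auxiliary operator only) transcribe at `r_max`;
#'   `Om` (main operator occupied), `looped` (one repressor bridging both
#'   operators) and `both` (two repressors) are silent -- only occupancy
#'   of the main operator blocks transcription. Loop formation from a
#'   singly-bound state occurs at `k_on_assoc * j_factor`; each loop arm
#'   releases at `c_loop * k_off`; a second repressor binds the remaining
#'   free operator at the effective association rate.
#' @export
looping_repression <- function(params, j_factor = params$j_factor,
                               c_loop = params$c_loop) {
  stopifnot(inherits(params, "kinetic_params"))
  if (j_factor < 0) stop("j_factor must be >= 0", call. = FALSE)
  if (!(c_loop > 0)) stop("c_loop must be > 0", call. = FALSE)
  if (!(params$r_max > 0)) stop("r_max must be > 0", call. = FALSE)
  kon <- k_on_eff(params); koff <- params$k_off
  kloop <- params$k_on_assoc * j_factor
  from <- c("empty", "empty", "Oa", "Om",
            "Oa", "Om", "looped", "looped",
            "Oa", "Om", "both", "both")
  to <- c("Oa", "Om", "empty", "empty",
          "looped", "looped", "Oa", "Om",
          "both", "both", "Oa", "Om")
  rate <- c(kon, kon, koff, koff,
            kloop, kloop, c_loop * koff, c_loop * koff,
            kon, kon, koff, koff)
  keep <- rate > 0
  promoter_architecture(
    states = c("empty", "Oa", "Om", "looped", "both"),
    transitions = transitions_df(from[keep], to[keep], rate[keep]),
    transcription_rates = c(params$r_max, params$r_max, 0, 0, 0),
    name = "looping_repression")
}

transitions_df <- function(from, to, rate) {
  data.frame(from = from, to = to, rate = rate, stringsAsFactors = FALSE)
}

# ---- loop formation rate vs inter-operator distance -----------------------

#' Loop-rate dependence on inter-operator distance
#'
#' The rate of DNA-loop formation between a main and an auxiliary operator
#' separated by `D` base pairs is `k_on_assoc * J(D)`, where the looping
#' J-factor `J(D)` (a local concentration) decays with contour length and
#' is modulated by the DNA helical period: operators on the same face of
#' the double helix loop readily, out-of-phase operators must twist the
#' intervening DNA. The implemented form is
#' `J(D) = amplitude * exp(-(D - reference) / decay_length) *
#'  (1 + modulation * cos(2 pi (D - phase) / helical_period)) /
#'  (1 + modulation)`.
#'
#' The shape (exponential decay times helical phasing) follows the
#' in vivo looping analyses this model family builds on; the default
#' coefficients are a synthetic, representative calibration (amplitude
#' matching the default J-factor at the reference distance, 11 bp helical
#' period, 300 bp decay length) rather than a fitted published set, and
#' should be replaced with fitted constants for quantitative work on a
#' specific promoter.
#'
#' @param amplitude J-factor at the reference distance (concentration
#'   units, matching `k_on_assoc`).
#' @param decay_length exponential decay length, bp.
#' @param helical_period helical repeat of B-DNA, bp.
#' @param phase distance offset of the in-phase maximum, bp.
#' @param modulation depth of the helical modulation, in `[0, 1)`.
#' @param reference_distance distance at which `J = amplitude`, bp.
#' @param range supported distance range, bp.
#' @return `loop_distance_params` returns a parameter object;
#'   `loop_rate_from_distance` returns the loop-formation rate(s), s^-1,
#'   always >= 0 inside the supported range.
#' @export
loop_distance_params <- function(amplitude = 600, decay_length = 300,
                                 helical_period = 11, phase = 80,
                                 modulation = 0.8,
                                 reference_distance = 80,
                                 range = c(50, 500)) {
  stopifnot(amplitude >= 0, decay_length > 0, helical_period > 0,
            modulation >= 0, modulation < 1, range[1] > 0,
            range[2] > range[1])
  structure(list(amplitude = amplitude, decay_length = decay_length,
                 helical_period = helical_period, phase = phase,
                 modulation = modulation,
                 reference_distance = reference_distance, range = range),
            class = "loop_distance_params")
}

#' @rdname loop_distance_params
#' @param loop_params a `loop_distance_params` object.
#' @param distance inter-operator distance(s) D, bp, within `range`.
#' @param k_on_assoc second-order association constant, (concentration s)^-1.
#' @export
loop_rate_from_distance <- function(loop_params, distance,
                                    k_on_assoc = 0.0027) {
  stopifnot(inherits(loop_params, "loop_distance_params"))
  lp <- loop_params
  if (any(distance < lp$range[1] | distance > lp$range[2]))
    stop(sprintf("distance outside supported range [%g, %g] bp",
                 lp$range[1], lp$range[2]), call. = FALSE)
  J <- lp$amplitude *
    exp(-(distance - lp$reference_distance) / lp$decay_length) *
    (1 + lp$modulation *
       cos(2 * pi * (distance - lp$phase) / lp$helical_period)) /
    (1 + lp$modulation)
  k_on_assoc * J
}

# ---- two-state closed forms -----------------------------------------------

#' Closed-form mean and Fano factor for the two-state architectures
#'
#' Analytic expressions for the telegraph (two-state) promoter, as
#' functions of transcription-factor concentration. For a promoter
#' switching between an inactive state (rate `r0`) and an active state
#' (rate `r1`), with total switching rate `k = k_on_eff + k_off` and
#' active-state occupancy `p`:
#' `mean = (r0 (1-p) + r1 p) / gamma_m` and
#' `fano = 1 + (r1 - r0)^2 p (1-p) / (gamma_m (gamma_m + k) mean)`.
#' For repression the active state is the operator-free state
#' (`p = k_off / (k_on_eff + k_off)`, fold-change `1 / (1 + [TF]/Kd)`
#' with `Kd = k_off / k_on_assoc`); for activation it is the bound state
#' (`p = k_on_eff / (k_on_eff + k_off)`). These closed forms agree with
#' the matrix moment engine to solver precision and serve as its
#' regression oracle.
#'
#' @param params a [kinetic_params()] object. For `mode = "repression"`
#'   the rates are `(r_max, 0)`; for `"activation"`, `(r_basal, r_max)`.
#' @param mode `"repression"` or `"activation"`.
#' @return A list of two vectorized functions of concentration, `mean(conc)`
#'   and `fano(conc)`, plus `kd`, the equilibrium dissociation constant.
#' @export
closed_form_two_state <- function(params,
                                  mode = c("repression", "activation")) {
  mode <- match.arg(mode)
  stopifnot(inherits(params, "kinetic_params"))
  ka <- params$k_on_assoc; koff <- params$k_off; gam <- params$gamma_m
  if (mode == "repression") { r0 <- 0; r1 <- params$r_max }
  else { r0 <- params$r_basal; r1 <- params$r_max }
  occupancy <- function(conc) {
    kon <- ka * conc
    if (mode == "repression") koff / (kon + koff) else kon / (kon + koff)
  }
  mean_fn <- function(conc) {
    p <- occupancy(conc)
    (r0 * (1 - p) + r1 * p) / gam
  }
  fano_fn <- function(conc) {
    p <- occupancy(conc)
    k <- ka * conc + koff
    mu <- (r0 * (1 - p) + r1 * p) / gam
    ifelse(mu > 0, 1 + (r1 - r0)^2 * p * (1 - p) / (gam * (gam + k) * mu),
           NA_real_)
  }
  list(mean = mean_fn, fano = fano_fn, kd = koff / ka, mode = mode)
}
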