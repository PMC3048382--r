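---
title: "Promoter architecture and intrinsic gene-expression noise: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Promoter architecture and intrinsic gene-expression noise: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promnoise)
```

## The model

A bacterial promoter carries a small set of operators (transcription-factor
binding sites). The pattern of factors bound at any instant defines a
discrete promoter state $s \in \{1, \dots, N\}$; binding and unbinding make
$s$ a continuous-time Markov chain with generator $\hat{K}$, written here in
the column convention

$$\frac{d\vec{P}}{dt} = \hat{K}\,\vec{P},$$

so that $K_{ij}$ ($i \neq j$) is the rate of the jump $j \to i$ and each
column of $\hat{K}$ sums to zero. Each state initiates transcripts as a
Poisson process at its own rate $r_s$ (collected in the diagonal matrix
$\hat{R}$ and vector $\vec{r}$), and every transcript decays independently
at rate $\gamma$. The promoter-state dynamics do not depend on the mRNA or
protein copy number: the model class deliberately excludes feedback, and
rates are constant in time.

The joint law of $(s, m)$, with $m$ the mRNA copy number, obeys a chemical
master equation. Three routes to its steady state are implemented, and they
serve as mutual cross-checks throughout the test suite:

1. **Exact moments** (`mrna_moments()`): because all propensities are
   linear, the first two moments close. With $\vec{p}$ the stationary
   occupancy ($\hat{K}\vec{p} = 0$, $\sum_s p_s = 1$) and the partial-mean
   vector $\vec{m}$ (components $\langle m\,\mathbf{1}_{s}\rangle$)
   solving
   $$(\hat{K} - \gamma \hat{I})\,\vec{m} = -\hat{R}\,\vec{p},$$
   the moments are
   $$\langle m \rangle = \frac{\vec{r}\cdot\vec{p}}{\gamma}, \qquad
     \langle m^2 \rangle = \langle m \rangle +
     \frac{\vec{r}\cdot\vec{m}}{\gamma}.$$
2. **Full distribution** (`steady_state_distribution()`): the null vector
   of the truncated joint generator (below).
3. **Exact simulation** (`simulate_trajectory()`,
   `simulate_summary()`): Gillespie's direct method.

### Noise measures

The squared coefficient of variation always decomposes as

$$\mathrm{CV}^2 \;=\; \frac{\sigma^2}{\langle m\rangle^2}
  \;=\; \frac{1}{\langle m \rangle} \;+\; \eta^2_{\text{prom}},$$

a Poisson floor set by single-molecule birth and death plus a
*promoter-noise* term contributed by state switching. The Fano factor
$\sigma^2/\langle m\rangle$ equals 1 for a Poisson distribution and
measures how much regulation inflates the noise at a given mean; it is the
comparison metric used across architectures. Because "normalized variance"
is used ambiguously in the literature (sometimes $\sigma/\mu$, sometimes
$\sigma^2/\mu^2$), this package never reports a bare "normalized variance":
`mrna_moments()` returns `fano`, `cv2` and `promoter_noise` as separately
named fields.

A fully repressed promoter has mean zero, where `fano` and `cv2` are
undefined; `mrna_moments()` returns a typed degenerate outcome
(`degenerate = TRUE`, `NA` noise fields) rather than `NaN`, so
concentration scans do not crash at the repressed end.

### Protein moments

Proteins are translated from each transcript at rate $b\gamma$ (so the
expected number of proteins per mRNA lifetime is the burst size $b$) and
decay at $\gamma_p$. Two methods are provided:

* `method = "exact"` (default) closes the joint
  (state, mRNA, protein) first- and second-moment system, which is linear,
  and solves it with no timescale approximation. For a constitutive
  promoter it reproduces the known result
  $F_n = 1 + b\gamma/(\gamma + \gamma_p)$ exactly.
* `method = "burst"` takes the short-mRNA-lifetime limit
  ($\gamma \gg \gamma_p$), replacing translation by geometric protein
  bursts with mean $b$ fired at the per-state transcription rates
  $b\,\vec{r}$; the auxiliary partial-mean vector solves the same linear
  form as the mRNA equation with $\gamma \to \gamma_p$. A warning is
  logged when $\gamma < 10\,\gamma_p$, where the limit is marginal.

The exact closure was chosen as the default because it subsumes the limit,
costs the same (two extra small linear solves), and is directly validated
against the protein SSA in the test suite.

## Architectures

Five builders cover the canonical prokaryotic regulatory motifs. All of
them take a `kinetic_params()` bundle; the transcription-factor
concentration enters only through the effective association rate
$k_{\mathrm{on}} = k_a \cdot [\mathrm{TF}]$, while dissociation and
transcription rates are concentration-independent.

| Builder | States | Transcribing states |
|---|---|---|
| `simple_repression()` | free, bound | free (at $r_{\max}$) |
| `simple_activation()` | free, bound | free ($r_b$), bound ($r_{\max} = f r_b$) |
| `dual_repression()` | empty, O1, O2, both | empty |
| `dual_activation()` | empty, O1, O2, both | all ($r_b$, $f r_b$, $f r_b$, $f^2 r_b$) |
| `looping_repression()` | empty, Oa, Om, looped, both | empty, Oa |

Design choices worth recording:

* **Distinct singly-bound states.** The two operators of the dual
  architectures are assumed equally strong, but the two singly-bound
  states are kept distinct rather than lumped, so no combinatorial
  factor-of-2 bookkeeping is needed. Equivalence with the lumped
  three-state chain (rates $2k_{\mathrm{on}}$ in, $2\omega_k k_{\mathrm{off}}$
  out of the doubly-bound state) is asserted in the tests.
* **Cooperativity acts on dissociation.** The kinetic cooperativity
  factor $\omega_k$ multiplies the dissociation rate out of the
  doubly-bound state ($\omega_k = 1$ independent, $\omega_k < 1$
  cooperative). $\omega_k$ is related to, but not identical with, the
  dimensionless interaction weight $\omega$ of thermodynamic occupancy
  models; no conversion between the two is provided, and users supply
  $\omega_k$ directly.
* **Looping.** A repressor bound at one operator reaches the other at
  rate $k_a J$, with the J-factor $J$ acting as a local concentration;
  each arm of the looped complex releases at $c\,k_{\mathrm{off}}$. Only
  main-operator occupancy (direct, looped, or doubly-bound) silences the
  promoter. The state with two distinct repressors bound is included, and
  loop formation is only allowed from singly-bound states.
* **Titration endpoints.** At $[\mathrm{TF}] = 0$ the bound states become
  transient, which makes the state graph formally reducible while the
  stationary vector is still unique. `validate_architecture()` therefore
  checks for a *unique closed communicating class* rather than strict
  irreducibility; genuinely ambiguous chains (two mutually unreachable
  closed sets) are still rejected.

## Parameters

Defaults (`promnoise_defaults()`) describe a strong, well-characterized
bacterial operator with a diffusion-limited repressor:

| Parameter | Default | Units | Provenance |
|---|---|---|---|
| $r_{\max}$ | 0.33 | mRNA s$^{-1}$ | measured (lacZ) |
| $k_a$ | 0.0027 | nM$^{-1}$s$^{-1}$ | measured, diffusion-limited |
| $k_{\mathrm{off}}$ | 0.0023 | s$^{-1}$ | measured (Oid-like, 7 min lifetime) |
| $\gamma$ | 0.011 | s$^{-1}$ | measured (1.5 min mRNA lifetime) |
| $f$ | 11 | — | measured |
| $\omega_k$ | 0.013 | — | measured (repression); activation value set equal (representative) |
| $J$ | 600 | nM | representative of in vivo estimates |
| $b$ | 31.2 | proteins/mRNA | measured |
| $\gamma_p$ | 0.00083 | s$^{-1}$ | measured |

`operator_k_off()` collects dissociation rates implied by measured complex
lifetimes for the lac operators (Oid 7 min, O1 2.4 min, O2 11 s,
O3 0.47 s), the lambda OR1/OR2-cI pairs and two CRP sites. Concentrations
are unit-agnostic but must be consistent between $k_a$ and
$[\mathrm{TF}]$; the defaults use nM.

The loop-rate-versus-distance function `loop_rate_from_distance()`
implements the expected shape — an exponential decay in contour length
modulated by the 11 bp helical period, since out-of-phase operators must
twist the intervening DNA to loop — with a **synthetic representative
calibration** (amplitude equal to the default J-factor at an 80 bp
reference distance, 300 bp decay length, modulation depth 0.8, supported
range 50–500 bp). Users reproducing a specific promoter's distance scan
should substitute fitted constants; conclusions drawn from the shipped
defaults are qualitative (shape and orderings), not quantitative.

## The distribution solver

`build_joint_generator()` assembles the master-equation operator on the
truncated space $\{0,\dots,M\} \times \{1,\dots,N\}$ as a sparse
block-tridiagonal matrix. Numerical choices:

* **Absorbing truncation.** The birth $M \to M+1$ is removed, keeping the
  truncated operator a proper generator (all columns sum to zero) so a
  stationary vector exists on the truncated space. The alternative
  (reflecting mass back) biases the boundary; with the tail criterion
  below the difference is negligible either way.
* **Initial bound.** $M$ starts at
  $\lceil \mu + 6\sigma \rceil$ from the analytic moments, but never below
  the conditional Poisson scale $r_{\max}/\gamma + 6\sqrt{r_{\max}/\gamma}$
  of the fastest-transcribing state — a rarely occupied high-rate state
  dominates the upper tail even when it barely moves the mean.
* **Tail criterion.** $M$ is doubled until a geometric bound on the mass
  beyond the boundary falls below `tail_tol` (default $10^{-8}$); six
  doublings without convergence is an error that reports the current
  bound. With tail mass $t$, the induced error on the second moment is of
  order $t M^2$, which is why oracle-grade comparisons in the tests use
  `tail_tol = 1e-11`.
* **Null vector by bordered sparse LU.** One row of the generator is
  replaced by the normalization constraint and the system is solved by
  sparse LU — deterministic, and far cheaper than a dense eigensolver for
  dimensions up to $N(M+1) \sim 10^5$. The small stationary solves in the
  moment engine use a QR least-squares solve of the generator stacked
  with the normalization row, plus one step of iterative refinement;
  if that fails the smallest right singular vector is used.
* **Bimodality** (`count_modes()`) is defined as the number of local
  maxima of the marginal after (i) discarding peaks below $10^{-6}$ of
  the global maximum (numerical dust in the far tail) and (ii) merging
  adjacent maxima separated by a dip shallower than 1% of the smaller
  peak.

## Stochastic simulation

The SSA core is compiled (Rcpp) and draws all randomness from R's RNG, so
`set.seed()`-style seeds reproduce trajectories bit-for-bit across
platforms; every simulating function requires an explicit seed. Protein
synthesis is simulated explicitly (translation events at $b\gamma$ per
transcript) by default, with the geometric-burst shortcut available as
`burst = TRUE` and cross-validated against the explicit route. Long runs
use a streaming accumulator (`simulate_summary()`) that keeps time-weighted
moments, occupancies and the mRNA histogram without storing paths, making
$10^6$–$10^7$-event oracle runs cheap.

Time averages discard a burn-in (default 20% of the horizon) and report
batch-means standard errors (default 32 batches); a warning is issued when
fewer than 50 promoter switching events remain, the regime where a single
run cannot have explored the state space. These defaults are robust rather
than optimal and are overridable.

## Studies

* **Titration scans** (`titration_scan()`) report mean, fold-change
  (mean relative to $[\mathrm{TF}] = 0$) and Fano factor across a
  concentration grid.
* **Matched-mean comparisons** (`matched_mean_comparison()`) are the
  canonical way to compare architectures: concentrations are solved by
  monotone bisection on $\log_{10}[\mathrm{TF}]$ to hit a common mean
  (relative tolerance $10^{-8}$), and Fano factors are compared there.
  Comparing at matched concentration would conflate noise with expression
  level.
* **Randomized robustness studies** (`random_parameter_study()`) draw
  kinetic parameters log-uniformly over 4 decades centered on the
  defaults and report the fraction of draws preserving an expected noise
  ordering, with a binomial standard error; draws whose matched mean is
  unreachable are counted and excluded, never silently dropped.

The activation-versus-repression study deserves its own note. The two
architectures are compared in the symmetric construction in which both
switch between the same basal and maximal rates and share one dissociation
rate (dissociation of the repressor and of the activator is a single
sampled parameter, as in the defaults registry). In that construction an
exact statement holds: at matched mean, activation is noisier than
repression *if and only if* the active-state occupancy is below 1/2 —
both promoters carry the same promoter-noise numerator, and the
architecture only decides whether the slow switching timescale is the
association (activation) or the dissociation (repression) side. The
shipped study therefore evaluates each draw at a common low-expression
operating point of 0.1 mRNA/cell — two decades below the 10 mRNA/cell
level that delimits "low expression" for these promoters and typical of a
repressed bacterial gene — where the ordering holds in every reachable
draw. If instead the matched mean is sampled broadly up to each draw's
saturation, draws operated above half-occupancy genuinely reverse the
ordering and the satisfied fraction drops to roughly 92–94%; the
low-expression restriction is the substantive content of the claim, not a
numerical convenience.

## Problem sizes and runtimes

The test suite runs the dual-oracle equivalence on 200 random
architectures ($N \le 6$, rates spanning 4 decades), SSA consistency on 20
random architectures at $4\times10^5$ events, distributional agreement
(total variation $< 0.02$) on the five canonical architectures at
$4\times10^6$ events, and robustness studies at 200–1000 draws. These
sizes were chosen so the whole suite completes in a few minutes on one
core while keeping Monte-Carlo bands (3–4 standard errors) tight enough to
be informative.

## Limitations

The model isolates *intrinsic* noise from promoter dynamics. It does not
describe: extrinsic noise (fluctuations in polymerase, ribosome or factor
copy numbers shared across a cell); cell growth, division, replication and
partitioning; RNAP binding/elongation kinetics, pausing or road-blocking;
saturable (non-linear) mRNA degradation; spatial effects (the cell is
treated as well mixed, and a factor that falls off an operator dissolves
into the bulk rather than rebinding locally); or eukaryotic chromatin
dynamics. Passing tests demonstrate internal consistency of the three
solution routes and the qualitative orderings across architectures under
these assumptions — not that any specific promoter in vivo follows the
defaults quantitatively, especially where the registry values are
representative rather than fitted.
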