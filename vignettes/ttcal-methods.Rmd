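---
title: "Models and methods in ttcal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in ttcal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ttcal)
```

ttcal packages the quantitative machinery used to study how a T-type
(low-voltage-activated, LVA) calcium channel gates peptidergic inhibition of
the *C. elegans* egg-laying circuit: a stochastic two-state model of
inter-egg-laying intervals, steady-state biophysics of the channel in
voltage-clamped oocytes, and a total-variation statistic for GCaMP calcium
traces from the HSN neurons. Each analysis is paired with a seeded synthetic
generator so that every result in the package is reproducible without bench
data. This vignette explains the models, their assumptions, the tunable
parameters, and the numerical and design choices.

## The two-state egg-laying interval model

Egg laying alternates between an *active* state, during which eggs are laid
in quick clusters, and a long *inactive* state of quiescence. The marginal
distribution of intervals between consecutive egg-laying events implied by
this process is a two-exponential mixture with CDF

$$F(x) = 1 - \left[ A e^{-a x} + B e^{-p b x} \right], \qquad
A = \frac{p(a-b)}{a - pb}, \quad B = \frac{a(1-p)}{a - pb},$$

with $A + B = 1$ identically. The fast rate $a$ (1/min) governs
intra-cluster intervals, the slow rate $pb$ governs the quiescent gaps, and
$p$ couples the two. Derived quantities are the time constants
$\tau_{fast} = 1/a$ and $\tau_{slow} = 1/(pb)$ (the quiescence timescale,
typically tens of minutes) and the mean interval $A/a + B/(pb)$.

`fit_intervals()` follows the original analysis: nonlinear least squares of
$F$ against the empirical cumulative probability of the sorted intervals.
Choices that the original description leaves open, fixed here once:

* **Plotting positions.** The empirical cumulative probability at the
  $i$-th order statistic is the Hazen position $(i - 0.5)/n$; it is
  symmetric, keeps both tails off 0 and 1, and is a common default in
  CDF-based fitting.
* **Optimizer and constraints.** Levenberg–Marquardt (`minpack.lm::nlsLM`)
  with box constraints $p \in (10^{-4}, 1 - 10^{-4})$,
  $a, b \in (10^{-6}, 10^{3})$ per minute, keeping iterates in the valid
  region. Starting values split the sample at its median and fit each half
  as a single exponential.
* **Identifiability.** $(p, a, b)$ triples related by swapping the
  component labels describe the same distribution. After fitting, estimates
  are re-expressed so that $a > pb$: the fast component always carries the
  label $a$.
* **Confidence intervals.** Asymptotic 95% intervals
  (estimate $\pm 1.96\,$SE from the least-squares covariance); the original
  report does not state its CI method.
* **Censoring.** Intervals cut off by the end of observation are simply not
  intervals and are never formed; animals leaving the arena truncate their
  timelines.

On data drawn from a *single* exponential the model is over-parameterised
and the fit lands on a degenerate ridge — one mixture weight shrinks toward
zero, the two rates coincide, or $p \to 1$ — while still reproducing the
generating CDF; the fit is flagged converged and the tests assert exactly
this behaviour rather than stable parameter values.

The generator `sample_intervals()` draws i.i.d. mixture samples. This
deliberately models only the *marginal* interval law: a mechanistic
hidden-state walk would induce serial correlation between consecutive
intervals, which the original analysis (and therefore the generator) does
not model. Sampling componentwise requires the weight $A \in [0, 1]$, i.e.
$a \ge b$; the CDF itself is defined on the larger spec'd parameter region.
`simulate_timeline()` accumulates intervals into a renewal process. Note
that the expected event count over a window $T$ is $T/\mu$ only to first
order; the hyperexponential law adds an inspection-paradox correction of
$(CV^2 - 1)/2$ counts, which the tests account for.

## Steady-state channel biophysics

Whole-cell T-type currents recorded under two-electrode voltage clamp in
*Xenopus* oocytes are summarised by their steady-state gating curves.

**GHK driving force.** With a 10 mM Ba²⁺ bath and negligible internal
barium, the driving force on the current is far from ohmic; chord
conductances are therefore formed with the Goldman–Hodgkin–Katz
constant-field flux

$$I(V) = P \frac{z^2 F^2 V}{RT}\,
\frac{c_{in} - c_{out} e^{-u}}{1 - e^{-u}}, \qquad u = \frac{zFV}{RT},$$

with $z = 2$, $T = 295$ K, $c_{out} = 10$ mM by default. The internal
concentration is not reported; the default $c_{in} = 0.1$ mM is a nominal
trace level, and because every curve is normalized to its own maximum, only
the shape of the drive versus voltage matters, not its scale. The
expression is $0/0$ at $V = 0$ and is evaluated there by a 3-term Taylor
splice of $u/(1-e^{-u})$ for $|u| < 10^{-4}$, giving the exact limit
$zFP(c_{in} - c_{out})$ and a numerically smooth join (tested against the
exact formula at the splice boundary).

**Boltzmann fits.** Normalized chord conductances (activation) or
normalized peak-current availabilities (inactivation) are fitted with

$$m_\infty(V) = \frac{1}{1 + e^{(V_{1/2} - V)/k}}, \qquad
h_\infty(V) = \frac{1}{1 + e^{(V - V_{1/2})/k}},$$

by unweighted least squares with asymptotic 95% CIs, matching the behaviour
of the standard sigmoidal-fit tools used in the original analysis. A fit
whose slope factor is driven onto its bounds (as happens when data of the
wrong monotone sense are supplied) is flagged unconverged rather than
reported.

**Protocols and kinetics.** Only figure insets document the original step
protocols, so the package defaults are standard LVA protocols consistent
with the stated $-90$ mV holding reference: activation — 150-ms steps from
$-80$ to $+10$ mV in 10-mV increments; inactivation — 1-s prepulses from
$-100$ to $-30$ mV in 5-mV increments followed by a $-30$ mV test step.
The sweep simulator uses first-order Hodgkin–Huxley-style relaxation
$I = s\, m(t) h(t)\, \mathrm{drive}(V)$ with default $\tau_m = 5$ ms,
$\tau_h = 30$ ms — order-of-magnitude T-type kinetics, fully configurable.
Peak extraction blanks the first 2 ms of each step (capacitive transient)
and keeps the signed extremum, inward negative. Oocyte QC follows the
stated criterion: leak magnitude strictly below 0.1 µA at $-90$ mV; the
boundary value fails.

**Slope factors.** The published comparison reports the half-voltages
(wild type: activation $-37.14$ mV, inactivation $-58.18$ mV; mutant:
$-44.69$ and $-63.11$ mV) and states that $k$ was unchanged between
genotypes without printing its value in the text. Simulations therefore
default to a shared $k = 5$ mV, a typical LVA slope; the window-current
conclusions below are insensitive to any shared $k$ in the 3–7 mV range,
and the tests sweep that range.

**Window current.** The overlap of $m_\infty$ and $h_\infty$ produces a
steady-state window current, modeled as $w(V) = m_\infty(V) h_\infty(V)$.
$\log w$ is concave (sum of concave log-sigmoids), so $w$ is unimodal:
`window_metrics()` locates the peak by a coarse 2001-point scan refined
with `optimize()` and finds the edges of the window range by outward
marching plus `uniroot()` bisection, each validated against a 0.001-mV
brute-force grid. The "range" of the window has no published definition;
the package exposes `threshold_frac` (default 0.1 of the peak) rather than
fixing one. With the four published midpoints and any shared $k \in [3,7]$
mV, the mutant window peak lies at more hyperpolarized potentials than
wild type while the widths differ by well under 20% — the qualitative
published conclusion.

## GCaMP trace pipeline

Traces are paired ROI/background series sampled at 0.5 Hz for 15 min
(450 frames) by default. The pipeline is: (1) subtract background from ROI
frame by frame; (2) fit an ordinary least-squares line to the *entire*
background-subtracted series — the photobleach baseline $F_0(t)$; (3) form
$\Delta F/F(t) = (F_{corr}(t) - F_0(t)) / F_0(t)$; (4) summarise a trace by
its cumulative $\Delta F/F$, the total variation
$\sum_t |x_{t+1} - x_t|$.

Two ambiguities in the original wording are resolved by flags:

* "Adjusting" for photobleaching could mean subtracting or dividing by the
  baseline. Division is the default because the reported quantity is
  dimensionless $\Delta F/F$ (and the figure axes are labeled that way);
  `mode = "subtract"` gives the subtraction-only variant.
* The summed absolute differences could be taken over raw ROI fluorescence
  or over $\Delta F/F$; the figure axis label decides for $\Delta F/F$, and
  `statistic = "raw"` exposes the other reading.

One point deserves care: adding an affine trend to the ROI is absorbed
exactly by the regression, so the *detrended* signal — and the cumulative
statistic in subtraction mode — is exactly invariant to such trends. In
division mode the numerator is exactly invariant but the time-varying
denominator is not, so the dimensionless statistic is only approximately
trend-invariant. The tests assert the exact property where it holds.

No smoothing and no transient detection are applied — none were reported.
The generator builds traces as baseline + linear bleach drift +
instantaneous-rise/exponential-decay transients + Gaussian noise on both
channels. It emulates the statistical structure the pipeline assumes; it
does not emulate motion artefacts, focus drift, or shot-noise scaling with
intensity, so passing tests certify the pipeline's algebra, not robustness
to those real-data features. A property mirrored from the original logic:
cohorts with few large transients and many small ones, constructed to equal
total variation, are statistically indistinguishable by rank sum — the
statistic integrates activity without regard to its temporal pattern.

## Ordinal stage assays and rank-sum testing

Freshly laid embryos are scored into seven ordered categories (1–8 cell,
9–25 cell, >26 cells pre-morphogenesis, comma, two-fold, three-fold,
hatched/L1), coded 1..7 in developmental order. Distributions are compared
per-embryo with the two-sided Wilcoxon–Mann–Whitney rank-sum test,
implemented in-package because heavy ties across seven categories are the
norm here: midranks are used throughout, and when both groups have at most
10 observations the p-value is exact by complete enumeration of all
$\binom{n_1+n_2}{n_1}$ labelings (the permutation null conditional on the
observed values, which remains valid under ties, where the classical exact
tables do not apply). Larger groups use the normal approximation with tie
correction and a 0.5 continuity correction. No multiple-comparison
correction is applied by default, mirroring the original analysis; use
`p.adjust()` on the output if desired.

## Problem sizes and determinism

Every generator takes an integer seed, restores the caller's RNG state on
exit, and is bit-reproducible. The test suite and the acceptance script run
at deliberately desk-scale sizes — 10⁴–10⁵ sampled intervals for
distributional checks, 1000 intervals for parameter recovery, 5–10
synthetic cells per gating curve, 300 simulated timelines, complete
enumeration up to 12 pooled observations — chosen so the whole suite
completes in seconds while keeping Monte-Carlo error well inside the
asserted tolerances.

## Known limitations

* Intervals are exchangeable; any within-animal serial correlation in real
  tracking data is not modeled.
* Gaussian noise everywhere is a simplification chosen for compatibility
  with least-squares fitting; real conductance noise is bounded and
  heteroscedastic.
* The voltage of peak chord conductance depends on unmodeled kinetics and
  is out of scope, as are absolute current amplitudes.
* No hidden-Markov alternative to the CDF least-squares fit is provided,
  and no mechanistic membrane-potential model couples behavior to calcium.
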