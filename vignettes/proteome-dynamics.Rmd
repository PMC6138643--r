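---
title: "Predicting proteome dynamics under a periodic boundary condition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting proteome dynamics under a periodic boundary condition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protodyn)
```

## The model

Protein synthesis and decay for gene $i$ are described by the classical
first-order kinetic equation

$$\frac{d P_i(t)}{dt} = k_{trans,i}\, M_i(t) - k_{d,i}\, P_i(t),
\qquad k_{d,i} = \frac{\ln 2}{\vartheta_{d,i}},$$

with $M_i(t)$ the mRNA concentration (molecules/cell), $k_{trans,i}$ the
translation rate (proteins per mRNA per minute) and $\vartheta_{d,i}$ the
protein half-life (minutes).  The usual shortcut sets $dP/dt = 0$ and reads
off $P = k_{trans} M / k_d$; that steady-state assumption is exactly what
dynamic experiments violate.  This package instead solves the equation under
a *return-to-baseline* boundary condition $P_i(0) = P_i(T)$, which holds for
cyclic processes (one cell-cycle period $T$) and for treatment–recovery
time courses.

Because the equation is linear in $P$, dividing by the unknown $k_{trans}$
gives the scaled trajectory $R(t) = P(t)/k_{trans}$ satisfying a
$k_{trans}$-free equation.  $R$ can therefore be computed from the mRNA
course and the half-life alone, and the translation rate recovered
afterwards from the literature cell-cycle average protein level:

$$k_{trans} = \frac{\langle P \rangle}{\langle R \rangle},$$

with both means taken over one period.

## Numerical solution

Trapezoidal (Crank–Nicolson) integration over a step $\Delta t$ yields the
recurrence

$$R(t+\Delta t) = \frac{2 - k_d \Delta t}{2 + k_d \Delta t}\, R(t)
 + \frac{\Delta t}{2 + k_d \Delta t}\,\bigl(M(t+\Delta t) + M(t)\bigr),$$

swept across the closed grid $t = 0, \Delta t, \ldots, T$.  The periodic
solution is the fixed point of the sweep map $R(0) \mapsto R(T)$.  Two
solvers are provided:

* `solve_periodic_R()` iterates the sweep from $R(0) = 0$, feeding $R(T)$
  back as the next start, until $|R(T) - R(0)| \le$ `tol` (default
  $5\times10^{-10}$).  One sweep contracts the error by
  $a^N \approx e^{-k_d T}$, so convergence takes a handful of sweeps for
  ordinary half-lives but degrades as $k_d T \to 0$.
* `closed_form_R()` sums the geometric series analytically,
  $R(0) = \sum_n a^{N-1-n} b\,(m_{n+1}+m_n) / (1 - a^N)$, and propagates
  once — exact in one pass, and the right choice for very long half-lives
  (hours and above), where iteration would need thousands of sweeps.

Both satisfy a discrete conservation identity obtained by summing the
recurrence around the cycle: the period mean of $R$ equals the period mean
of $M$ divided by $k_d$, *exactly* (to rounding), provided the grid value at
$T$ equals the one at $0$.  Period means always use grid points
$0 \ldots N-1$; the wrapped endpoint $T$ duplicates point $0$ and would
otherwise be double-counted.  Against the closed-form sinusoid solution the
scheme is second-order: halving $\Delta t$ quarters the maximum error, and
at $\Delta t = 1$ min the error is about 0.01% of the protein mean.

## Preparing the mRNA grid

Measured log2 expression ratios $L_i(t)$ are rescaled to absolute
concentrations with the literature cell-cycle average
$\langle M_i \rangle$:

$$M_i(t) = 2^{L_i(t)} \cdot
 \frac{\langle M_i \rangle}{\langle 2^{L_i} \rangle},$$

where $\langle 2^{L_i} \rangle$ is the arithmetic mean over that gene's
*measured* points (the transform is applied before interpolation, so the
mean of the transformed measurements matches $\langle M_i \rangle$
exactly; the interpolated grid mean may then differ slightly under uneven
sampling — that residual difference is precisely what makes the
steady-state and time-course translation rates diverge).

Linear interpolation fills the grid at every minute.  Beyond the last
measured point (and before the first, if sampling starts after 0) the
series is wrapped periodically: the segment from $(t_{last}, v_{last})$
interpolates toward $(t_{first} + T, v_{first})$.  This completion makes
$M(0) = M(T)$ whenever the endpoints are not both measured, which the
conservation identity needs; when both endpoints *are* measured, the data
win.  Measurements beyond $T$ are never dropped silently — truncation must
be requested (`truncate = TRUE`) and is reported.

## Consensus period

Per gene, periodicity at a trial period $T$ is scored with a floating-mean
least-squares periodogram: the series is regressed on
$\{1, \cos(2\pi t/T), \sin(2\pi t/T)\}$ and the power is the
$\chi^2$-normalized variance reduction $(N-1)R^2/2$, whose null
distribution on Gaussian white noise is approximately Exp(1).  The
significance of a single period is then $z = e^{-P}$, and $-\log z = P$ is
used as a per-gene log-likelihood; summing over genes and maximizing over a
candidate grid (default 30–150 min, 1-min steps, covering all yeast
cell-cycle data sets) gives the consensus period.  Ties break toward the
smallest period.

A literal amplitude-like statistic
$P(T) = \tfrac{2}{(b-a)\sigma^2}\sqrt{C^2 + S^2}$, with $C, S$ trapezoidal
estimates of the cosine/sine integrals over the observation window, is
available as `stat = "eq4"`.  It carries an overall square root, so it is
*not* scale invariant (it scales as $1/c$ when the series is scaled by $c$)
and its exponential significance transform is not calibrated; only the
default power form makes $z$ a usable p-value, which is why likelihood and
significance always use it.  The floating mean matters for uneven
sampling: it keeps an offset from masquerading as power at long periods.

## Correcting measured half-lives

Half-life compendia contain negative and absurdly large values because the
measured quantity is the degradation *rate*: a small true rate plus
measurement error can land on either side of zero, and its inverse
explodes.  The correction treats the observed rate
$k_{obs} = \ln 2 / \vartheta_{obs}$ as a Gaussian measurement of the true
rate with standard deviation $\sigma_k = \ln 2 / 300$ min$^{-1}$ — the rate
of a 300-minute half-life, the longest reliably measurable one — imposes
positivity, and reports the mean of the truncated normal:

$$k_{corr} = k_{obs} + \sigma_k\,
 \frac{\varphi(h)}{\Phi(h)}, \qquad h = k_{obs}/\sigma_k,$$

evaluated through log-space Mills ratios so both tails are stable.  The
corrected half-life $\ln 2 / k_{corr}$ is always positive and finite; an
infinitely long (or negative-infinite) observation maps to
$300\sqrt{\pi/2} \approx 376$ min.  The correction is below 1% for
half-lives under ~100 min and grows to a few percent by 150 min.  The
description of the error scale admits a second reading,
$\sigma_k = 1/(300 \ln 2)$; it has no kinetic interpretation (it is not the
rate of any half-life), so the rate reading is the default, but
`error_model = "inverse"` exposes the alternative for sensitivity
analysis.

```{r halflife-example, eval = FALSE}
correct_halflife(c(-100, 22, 344, 1e5))
correct_halflife(Inf) # 300 * sqrt(pi/2)
```

## Translation rates

Per gene the pipeline reports both the steady-state estimate
$TR_{ss} = k_d \langle P \rangle / \langle M \rangle$ and the time-course
estimate $TR_{tc} = k_{trans}$ from the periodic solution, together with
their normalized divergence
$TR_{diff} = |TR_{ss} - TR_{tc}| / \min(TR_{ss}, TR_{tc})$, flagging genes
above 0.1 (the conventional reporting cut-off) as divergent.  By the
conservation identity, $TR_{tc} = k_d \langle P \rangle / \bar M_{grid}$,
so $TR_{diff}$ is driven purely by the gap between the interpolated grid
mean and the literature average — a stated, testable consequence: on a
mean-matched grid the two estimates coincide to rounding.

## Detecting post-translational regulation

When a measured protein time-course is available (western-blot band
intensities, arbitrary units), a periodic two-level half-life

$$\vartheta_d(t) = \begin{cases}
 \vartheta^1 & t_0 \le t \le t_0 + K \ (\mathrm{mod}\ T)\\
 \vartheta^2 & \text{otherwise}
\end{cases}$$

is fitted by exhaustive grid search: both half-lives over 1–40 min,
window start and length over the whole cycle, all in 1-minute steps
($40^2 T^2$ tuples).  The window is closed and wrapped modulo $T$ (the
two-branch definition leaves $t = 0$ undefined when $t_0 > 0$; the wrap
resolves it consistently with periodicity).  The recurrence generalizes by
evaluating $k$ at the interval endpoints,

$$R_{n+1} = \frac{(2 - k_n \Delta t) R_n + \Delta t (m_{n+1} + m_n)}
 {2 + k_{n+1} \Delta t},$$

which reduces bit-for-bit to the constant-rate scheme when
$\vartheta^1 = \vartheta^2$.  At the switch minutes the scheme averages
the rate across the jump, costing one order of accuracy locally; errors
still shrink monotonically with $\Delta t$ and the fitted windows align
with the grid, so this does not affect the grid search ranking.

The fit criterion is the sum of squared differences between the predicted
and measured profiles after normalizing each to unit mean at the measured
times.  Band intensities are relative, and unit-mean normalization also
cancels $k_{trans}$, so no absolute calibration is needed; a
$1 - r$ (Pearson) criterion is available as an alternative.  Each tuple is
solved through the one-pass closed-form fixed point in compiled code
(single $O(N)$ pass per tuple; the full $5.8\times10^6$-tuple scan for
$T = 60$ takes a few seconds).  Ties break deterministically toward the
lexicographically smallest $(\vartheta^1, \vartheta^2, t_0, K)$.  A
coarse-to-fine mode (step 5, then step 1 around the optimum) trades
exhaustiveness for a ~250-fold speed-up and is used for replicate studies;
the exhaustive scan remains the default.

Note the intrinsic relabelling symmetry: swapping
$(\vartheta^1, \vartheta^2)$ and complementing the window describes the
same half-life profile up to the boundary minutes.  Recovery studies
therefore score the overlap of the *short-half-life* minute sets, not the
literal window parameters.

## The synthetic generator

`synthetic_genes()` + `simulate_expression()` emulate the assumed data
model end to end: sinusoidal transcription
$M(t) = m_0 + A \sin(2\pi t/T + \varphi)$ (chosen because it admits the
closed-form protein solution `analytic_periodic_protein()`, the solver's
independent oracle; a square wave is available in `mrna_profile()`),
log2-ratio encoding with additive Gaussian noise in log2 space (the
microarray modality), literature-average tables carrying the true means,
observed half-lives built by perturbing the true degradation rate with
$N(0, (\ln 2/300)^2)$ and inverting — which reproduces the negative and
enormous values seen in real compendia — and measured protein profiles
with bounded multiplicative error (log-uniform on $[1/f, f]$, $f = 2$ by
default, the stated western-blot inaccuracy).

Defaults, chosen once to mirror a budding-yeast cell-cycle experiment:
period 60 min; sampling every 5 min; log2 noise s.d. 0.2; half-lives
log-uniform on 5–300 min; baseline mRNA log-uniform on 2–50
molecules/cell; translation rates log-uniform on 0.5–10 proteins/mRNA/min;
oscillation amplitude 0.2–0.8 of baseline (keeping mRNA positive).  All
randomness flows through explicit integer seeds.

What the generator does *not* emulate — and hence what passing tests do
not establish about real data: loss of synchrony over successive cycles,
transcriptome-wide correlation structure, non-sinusoidal waveforms,
cell-cycle phase structure, array normalization artefacts, and systematic
(non-Gaussian) half-life biases.  Conclusions about those require real
measurements.

## Problem sizes and numerical choices

The test-suite and the acceptance script run, by design, at desk scale:
grids of 61 points ($T = 60$, $\Delta t = 1$), cohorts of 100 synthetic
genes, 1000 white-noise series for null calibration, 100 noisy replicates
for the step-fit recovery study, and the full $40^2 \cdot 60^2$ grid
search once.  Other choices worth knowing:

* `dt` must divide the period; defaults to 1 min.  The recurrence requires
  $k_d \Delta t < 2$ (violations error out rather than oscillate).
* Constant expression series get power 0 and $z = 1$ with a warning, never
  a division by zero; an all-constant cohort is an error.
* A gene set is never silently reduced: every input gene ends up either
  predicted or in the skipped table with a reason.
* An observed half-life of exactly 0 is undefined (an infinite rate) and
  rejected.
* Exact permutation p-values in `rate_correlation_report()` enumerate all
  $n!$ orderings and are limited to $n \le 10$.

## Limitations

The model is deliberately minimal: one transcript pool, one protein pool,
first-order decay, no ribosome-level mechanism, no delay between
transcription and translation.  Proteins under strong post-translational
control fit poorly with a constant half-life — that mismatch is the signal
the step-function fit exploits, but the step form allows only two levels
and one window per cycle.  Very dynamic expression (characteristic times
comparable to the sampling interval) would need better-than-linear
interpolation of the mRNA course.  Half-life correction assumes a single
global error scale; gene-specific measurement variances are not modelled.
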