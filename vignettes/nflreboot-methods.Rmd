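---
title: "Models and methods behind nflreboot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nflreboot}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nflreboot)
```

# The circuit models

The package models a negatively autoregulated transcription unit: a strong
promoter whose own protein product represses it. With `X` the mRNA and `Y`
the repressor,

$$\frac{dX}{dt} = \frac{\lambda_1}{1 + (Y/k)^n} - \beta_1 X,
\qquad \frac{dY}{dt} = \lambda_2 X - \beta_2 Y.$$

The repression term is the standard Hill form of operator binding under
mass-action kinetics: $k = k_\mathrm{off}/k_\mathrm{on}$ is the
half-maximal binding constant and $n$ the cooperativity index ($n = 1$ for
non-cooperative binding). Time and concentration units are arbitrary but
must be used consistently; the reference parameter set
(`reference_params()`: $\lambda_1 = 10$, $\lambda_2 = 10$, $\beta_1 = 1$,
$\beta_2 = 0.2$, $k = 0.01$, $n = 1$) describes a strong, tightly repressed
promoter with mRNA turning over five times faster than the protein.

Two extensions cover the architectures that occur on real plasmid
backbones:

* **Dimerization** (`variant = "dimer"`): most prokaryotic transcription
  factors bind DNA as multimers. An explicit dimer pool
  $dD/dt = k_\mathrm{on,2} Y^2 - k_\mathrm{off,2} D$ is added, two
  monomers are consumed per dimer (the $\mp 2$ terms in $dY/dt$), and the
  repression input becomes $(D/k)^n$.
* **Two repressors with OR logic** (`variant = "or2"`): promoters inside
  larger regulons are repressed by either of two independently produced
  regulators. The default is the additive competitive denominator
  $1 + (Y/k)^n + (Y_2/k_b)^{n_b}$ (either repressor alone suffices); a
  multiplicative alternative (independent operators) is available through
  `or_logic = "multiplicative"`.

## Pinning down the dimer rates

The dimerization step is specified in the literature on such circuits only
as "a simple ODE" with two constants, 0.1 and 0.01, and the documented
phenomenology that the loop turns cyclostationary — sustained oscillation
instead of damped relaxation — once the cooperativity exceeds $n = 10$
under the reference parameters. The two constants' roles are not
identifiable from that description alone, so we resolved them by linear
stability analysis of the closed-loop fixed point:

* Read as association rate 0.1 and dissociation rate 0.01 (an
  equilibrium dimer pool $D = 10\,Y^2$), the fixed point's Jacobian has
  strictly negative real parts for every $n \le 60$: the loop never
  oscillates. The same holds for the neighbouring stoichiometries we
  examined (no monomer consumption; dimer additionally degraded at
  $\beta_2$ moves the transition to $n = 8$).
* Read with the roles exchanged — association 0.01, dissociation 0.1,
  $D = 0.1\,Y^2$ — the pair of complex eigenvalues crosses the imaginary
  axis exactly between $n = 10$ and $n = 11$, and forward integration from
  the reboot condition confirms damped relaxation through $n = 10$ and a
  stable limit cycle from $n = 11$ on.

The package therefore defaults to `dimer = list(on = 0.01, off = 0.1)` in
`reference_params("dimer")`. Both rates are ordinary parameters; nothing
in the code depends on this particular choice.

# Gain, overshoot, and the analytic approximation

The **feedback gain** $G = X_\mathrm{open}/X_\mathrm{closed}$ compares the
steady states with and without the repressor, all other parameters equal.
$X_\mathrm{open} = \lambda_1/\beta_1$ in closed form; the closed-loop state
is the unique positive root of $\beta_1 X \cdot \mathrm{denom}(X) =
\lambda_1$ with every repressor species slaved to $X$, found by bracketed
root finding on $(0, \lambda_1/\beta_1]$ (`stats::uniroot`, relative
tolerance $10^{-12}$). For the simple loop with $n = 1$ this equation is a
quadratic, which the test suite uses as an independent closed-form oracle.

The **overshoot** $O = X_\mathrm{max}/X_\mathrm{ss}$ measures the transient
burst after a genome reboot (all species started at exactly zero, the state
of a plasmid that has just entered a cell as ssDNA). Before repression sets
in, the mRNA follows the open loop, $X(t) =
(\lambda_1/\beta_1)(1 - e^{-\beta_1 t})$, which yields the approximation

$$O \approx G\,(1 - e^{-\beta_1 t}),$$

with $t$ the duration of the repression-free phase. `approx_overshoot()`
implements this form (and accepts an injected replacement, should a
different correction term be preferred). In sweeps the package evaluates
the approximation at the time the repressor input first crosses its
half-maximal constant $k$, located by linear interpolation on the
trajectory grid; for sharply nonlinear loops ($n \gtrsim 6$) this coincides
with the peak time of $X$, while at low cooperativity the peak lags the
onset and using the onset keeps the approximation within about 12% of the
measured overshoot across the full dimerized cooperativity sweep
($n = 1$–$20$). As $t \to \infty$ the approximation tends to $G$, and in
engineered long-delay regimes (repressor accumulation pushed many mRNA
lifetimes out) measured overshoot, approximation and gain agree within 5%.

For cyclostationary trajectories a steady state does not exist;
`measure_overshoot()` then uses the mean of the terminal cycle as
denominator and flags the record.

# Regime classification

`detect_cyclostationarity()` inspects the final half of the mRNA signal. A
trajectory is called oscillatory when successive peak-to-trough amplitudes
neither decay below 0.9 of their predecessor nor fall under 1% of the mean
mRNA level in the window; the period is the mean inter-peak spacing. Both
thresholds are package choices, exposed as arguments: the retention ratio
separates slow damping from a settled limit cycle on horizons a few
hundred periods long, and the amplitude floor keeps integrator-level
wiggles on a converged trajectory from counting as oscillation. Trajectories
with fewer than six extrema that have not converged are refused rather than
classified. `simulate_to_regime()` doubles the horizon (up to 8 times the
base value) until either classification or convergence is reached — near
the bifurcation, damping is slow and the default horizon of 1000 time units
may need two doublings.

# Numerical integration

Integration uses `deSolve::ode` with `lsoda` — adaptive step size with
automatic stiff/non-stiff switching — at absolute and relative tolerances
of $10^{-10}$ and a default horizon of 1000 time units, matching the
numerical setup the models come from. Output is sampled on a fixed grid
(default spacing 0.05); the global maximum is refined by parabolic
interpolation through the three points around the sampled peak, so the
grid does not quantize peak heights or times. States more negative than
the square root of the absolute tolerance abort the run; values inside
that band are clipped to zero. A trajectory started exactly at the
closed-loop fixed point stays constant to within $10^{-6}$ relative, and
with synthesis and decay of the repressor switched off the dimer variant
conserves monomer equivalents $Y + 2D$ to integrator accuracy — both are
enforced in the test suite.

# The invasion cohort model

Conjugation is asynchronous: transconjugants become donors, and every new
transfer reboots the plasmid network in one more cell. The package lifts
single-cell kinetics to the population with a discrete-time cohort model
(`simulate_invasion()`):

* during the mating window, new transconjugants form at rate
  $\gamma (D + T_\mathrm{eligible}) R$ per unit time (mass action), one
  cohort per step; each cohort's circuit starts from the zero reboot
  state, while donors and established carriers sit at the closed-loop
  steady state;
* bulk signals are cohort sums of per-cell levels, normalized to the
  plasmid-bearing population at $t = 0$. Three species are tracked: the
  autoregulated mRNA (reboot kernel $X(t)$), a constitutive unregulated
  transcript (open-loop kernel, saturating monotonically), and a
  never-transcribed region (one copy per plasmid). The last species is a
  pure copy counter: without growth its bulk fold can never exceed
  $(D_0 + R_0)/D_0$ — exactly 2 for the standard 1:1 mix
  (`max_copy_fold()`) — which is why untranscribed regions serve as the
  control separating transcriptional bursts from mere plasmid
  accumulation;
* growth, off during surface mating (the experimental protocol resuspends
  into fresh medium afterwards), applies per-type generation times:
  plasmid-free cells at `base_generation` (default 30 min), carriers 17%
  slower, and fresh transconjugants spending their first generation at 2.5
  times the carrier generation time before relaxing to the steady burden.

The transfer rate defaults to an order-of-magnitude placeholder
($10^{-8}$ ml/(cells·min)); no measured value exists for the study system,
and every knob lives in `mating_params()`. Transconjugants become eligible
donors immediately by default (`exclusion_delay = 0`): surface-exclusion
deployment takes some time, but no number is available, so the delay is
exposed rather than guessed. An explicit `cohort_schedule` can replace the
mass-action formation dynamics for controlled scenarios (instantaneous
conversion, fixed totals spread over windows of different length — the
latter demonstrates how asynchrony blurs and damps the bulk peak). The
engine's bulk signal is, by construction, the convolution of the cohort
formation series with the single-cell kernel; the test suite verifies it
against independent per-cohort integrations to $10^{-6}$ relative.

# Measurement analytics

**GFP/OD activity** (`steady_gfp_od`). The exponential window is the
contiguous span of time points whose local log-OD slope stays within 90%
of its maximum, with at least four points required; activity is the mean
GFP/OD over that window, averaged across replicates. The 90% rule is a
package choice: it tracks the plateau of the growth-rate curve without
committing to a parametric growth model.

**Promoter calls and repression folds** (`promoter_calls`). A fragment is
a promoter when its activity reaches twice the promoter-less vector
background, boundary inclusive ("at least two-fold"). When the repressed
activity falls to background, the true fold is unresolvable and the
function reports the censored lower bound activity/background — this is
how ">500-fold" repression statements arise.

**Topology inference** (`infer_topology`). An edge requires both a
one-tailed Welch test (repressed below control) at $\alpha = 0.05$ and an
observed fold of at least 2. The fold gate is what controls false edges:
with realistic replicate noise a null pair essentially never shows a
two-fold drop, so no multiple-testing correction is applied by default
(matching the per-gene star convention of the field); Benjamini–Hochberg
is available behind an argument.

**Primer efficiency** (`primer_efficiency`). Ct against $\log_2$(amount)
over a 2.5/5/10 ng dilution series; the per-cycle amplification factor is
$A = 2^{-1/\mathrm{slope}}$ and the fractional efficiency $E = A - 1$,
passing QC when $0.9 < E < 1.2$ (open interval). The estimator is
scale-invariant in the template amounts. Flat or non-monotone series
return an undefined efficiency with a diagnostic rather than a number.

**Transcriptional landscape** (`transcriptional_landscape`). The
abundance index is stored as $\mathrm{Ct_{DNA}} - \mathrm{Ct_{cDNA}}$,
oriented so that larger means more mRNA and one unit is one doubling.
Conventions in the field sometimes print the subtraction the other way
around while still reporting untranscribed regions at $-8$ and hot regions
at $+2$; the package standardizes on the abundance orientation those
reported values imply.

**Conjugation response** (`conjugation_response`). Per-gene fold-changes
relative to $t = 0$, efficiency-corrected ($A^{\Delta Ct}$, with $A = 1+E$;
the Pfaffl convention) and normalized by a constitutive chromosomal
reference (dxs), which absorbs population growth. The relative error is
the first-order propagation on the $\log_2$ scale,
$\sigma_x/\langle x\rangle = \ln 2\,\sqrt{\mathrm{var}(Ct) +
\mathrm{var}(Ct_\mathrm{ref}) - 2\,\mathrm{cov}(Ct, Ct_\mathrm{ref})}$,
with the covariance over paired replicates — shared extraction/loading
noise cancels there, which is the point of pairing. Protocol write-ups
occasionally print the bracket's exponent as $-2$; that reading is
dimensionally inconsistent with a standard deviation and is implemented
only behind `strict_exponent = TRUE` for auditability. Significance is a
one-tailed Welch test of the target's Ct drop exceeding the reference's,
starred `**` at $p < 0.05$ and `*` at $p < 0.1$, uncorrected (per-gene
reporting). Normalization divides fold-changes (the ratio form of
$\Delta\Delta Ct$); subtracting log-folds is algebraically identical when
both amplification factors are equal and differs only in the
efficiency-corrected case, where the ratio form keeps each gene on its own
calibrated base.

# The synthetic-data generators

The generators produce every input the analytics consume, with the
statistical structure the analysis assumes, under end-to-end seeding (one
RNG stream per output table, derived from the master seed and the table
name, so each table is independently reproducible and two identical calls
are byte-identical).

* **Growth/GFP profiles**: logistic OD with the growth rate set by the
  30-min base generation time; GFP proportional to OD times the planted
  activity, under multiplicative lognormal noise (default cv 10%, a
  typical plate-reader replicate scatter).
* **Ct tables**: replicate noise is normal on the cycle scale with
  sd = cv × baseline Ct (cv 0.12 for cDNA at baseline 19.9, cv 0.034 for
  genomic DNA at 14.2 — the dispersions reported for such measurements).
  90% of the replicate variance is shared across amplicons within a
  replicate, representing extraction/RT loading; this is what makes the
  covariance term of the propagated-error formula meaningful, and it is
  the realistic structure of paired qPCR replicates. Dilution series
  follow planted per-cycle amplification factors.
* **Invasion datasets**: the qPCR table rides the cohort model's bulk
  folds; the default circuit is minute-calibrated (mRNA half-life
  3.5 min, repressor removed by dilution at the 30-min generation:
  $\lambda_1 = 10$, $\lambda_2 = 1$, $\beta_1 = 0.2$, $\beta_2 = 0.023$,
  $k = 0.01$, $n = 1$) so the population burst plays out over the sampled
  0–120 min window, and the transfer rate is set so that most recipients
  convert within it, as surface matings of efficient systems do. Plate
  counts carry lognormal dilution error (cv 0.15, the middle of the
  reported 0.1–0.2 range) and the burden-modified generation times.
* **Network fixtures**: six repressors, fifteen promoters, with the two
  integron promoters unrepressed. Planted folds follow the reported
  ranges; where a range's lower end coincides with the two-fold calling
  boundary (the weaker regulator's folds on the conjugation promoters,
  reported as 2–10), the defaults sit inside the range but off the
  boundary (3–10), since a fold planted exactly at the decision threshold
  would make exact recovery impossible by construction regardless of
  noise.

What the generators deliberately do **not** emulate: amplification curves
(Ct values are taken as given), melt-curve artefacts, plasmid copy-number
fluctuations, cross-contamination between wells, non-exponential growth
phases inside the mating window, and spatial structure of the mating
surface. Passing round-trip tests therefore demonstrates that the
analytics invert the generators' noise model — not that they are robust to
every failure mode of real instruments.

# Problem sizes and runtime choices

The test suite and the acceptance script keep simulations at desk scale:
cooperativity sweeps over $n = 1$–$15$ (classification) and $1$–$20$
(approximation tracking) at grid spacing 0.05 with horizons of 1000–8000
time units; 1000 random parameter sets for the root-finder oracle; 100
seeded fixtures for topology recovery; five seeded datasets for fold
recovery and ten for burden recovery. The full suite runs in about a
minute on one core. Statistical recovery checks compare on the log scale
and pool propagated errors across a profile's timepoints, since a single
timepoint's variance estimate carries only three degrees of freedom;
seed-averaged burden ratios use geometric means with bands of two standard
errors of the linearized count-noise propagation, inflated for the
convexity of the generation-time estimator over the short first interval.

# Known limitations

* The models are deterministic; stochastic (molecule-count) effects at
  reboot, which can matter at a single plasmid copy, are out of scope.
* Regime classification is empirical, from trajectories, not from
  eigenvalue analysis; very slowly growing limit cycles near the
  bifurcation require the horizon auto-extension.
* The population model has no spatial structure and treats mating-surface
  geometry, pilus mechanics and superinfection kinetics through two
  scalars (transfer rate, exclusion delay).
* Oscillatory overshoot records depend on the terminal-cycle-mean
  convention for their denominator; other conventions would shift those
  values.
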