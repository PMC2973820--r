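---
title: "Methods: expected-gain planning, simulated planners, and decibel evidence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: expected-gain planning, simulated planners, and decibel evidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riskreach)
```

## The task and its statistical model

`riskreach` models a rapid pointing task under risk. On each experimental
trial a 1 cm diameter target circle appears with a 1 cm diameter penalty
circle whose centre is 7.5 mm away, in one of four directions (left, right,
above, below). A hit inside the target earns `G_t` points (1 by default, 2
for some subjects), a hit inside the penalty earns `G_p` points (0 in
zero-penalty blocks, −5 in penalty blocks), and a hit in the overlap lens
earns both. All coordinates are target-centred millimetres, x rightward and
y upward; the analysis is translation invariant, so absolute screen
placement is never represented.

Endpoints are modelled as bivariate Gaussian about the planned aimpoint
with diagonal covariance — the horizontal and vertical screen axes are the
task-relevant directions and the off-diagonal covariance is assumed
negligible throughout the package, in both generation and estimation. The
expected gain of an aimpoint $a$ is

$$\mathrm{EG}(a) = G_t P(\text{target}\mid a,\Sigma) + G_p P(\text{penalty}\mid a,\Sigma),$$

with each probability the Gaussian mass over a disk. The maximum expected
gain (MEG) aimpoint maximises EG; $\Delta_{\text{aim}}$ is its signed
projection, from the target centre, onto the unit vector pointing from the
penalty centre to the target centre (positive = away from the penalty).
Efficiency of an observed aimpoint is
$\mathrm{EG}(a_{\text{obs}})/\mathrm{EG}(a_{\text{MEG}})$, both evaluated
under the true (possibly anisotropic) covariance.

## Numerical choices

**Disk probabilities.** With diagonal covariance the Gaussian mass over a
disk reduces to a one-dimensional integral: the vertical slice of the disk
at horizontal position $x$ integrates exactly via the normal CDF, and the
outer integral over $x$ is evaluated by Gauss–Legendre quadrature after the
substitution $x = c_x + R\sin t$. The $\cos t$ Jacobian absorbs the
square-root edge behaviour of the slice height, leaving a smooth integrand;
64 nodes give ~1e−12 absolute accuracy at the task's noise scales (SDs of
1–6 mm against 5 mm radii), which the test suite verifies against both the
closed-form Rayleigh expression for centred isotropic disks and
million-draw Monte-Carlo oracles. The exported scalar
`disk_hit_probability()` additionally splits the quadrature domain at the
images of the aim's ±9 SD horizontal window and of the slice-boundary
crossings of the aim's vertical coordinate, so near-point-mass noise models
(SDs orders of magnitude below the radius) are also resolved; the internal
vectorised evaluator used by the grid searches keeps fixed shared nodes,
which is exact in the regime the searches run in.

**MEG search.** Every configuration the experiment produces has the penalty
on a coordinate axis and axis-aligned noise, making the gain landscape
mirror-symmetric about the target–penalty axis. `meg_aimpoint()` therefore
searches in one dimension along that axis (0.1 mm grid plus golden-section
refinement), followed by a two-dimensional Nelder–Mead polish that would
catch any off-axis optimum; non-axis geometries fall back to a 2-D grid
with the same polish. Grid ties are broken towards the target centre. The
refinement makes the result grid-independent to well under 0.05 mm, which
the tests confirm against exhaustive 0.01 mm brute-force grids. If the
landscape admits no positive expected gain anywhere (penalties far larger
than the study's), the best grid point is returned with a warning flag
rather than an error.

## The synthetic cohort

The generator reproduces the study's design: per session, 3 training blocks
of 69 reaches to crosshairs (207 reaches) followed by 6 experimental blocks
of 120 reaches (720), of which 2 are zero-penalty blocks, one scheduled
uniformly at random in each half of the experimental sequence. Penalty
directions are i.i.d. uniform over the four orientations; the exact
per-block randomisation schedule of the original experiment is not public,
so only the stated half-balance constraint is enforced. Zero-penalty
experimental trials number 240 per session, matching the 239 degrees of
freedom per marginal that the variance F tests use.

Motor noise is isotropic Gaussian with a 3 mm baseline SD. The drift
session emulates the manual following response (MFR) — a reflexive
horizontal deviation induced by large-field visual motion — as an
equal-probability three-component horizontal shift of $-d$, $0$, or $+d$
mm. The shift magnitude is not a printed quantity; the default
$d = \sigma\sqrt{3}$ makes the mixture's horizontal variance
$\sigma^2 + \tfrac{2}{3}d^2 = 3\sigma^2$, i.e. a 3× variance ratio, which
sits in the middle of the observed drift/no-drift F-ratio range (≈2.5–3.8).
Setting $d = 0$ emulates a perturbation non-responder. The generator keeps
the explicit mixture for realism; the estimation side deliberately treats
all endpoint distributions as single bivariate Gaussians, as the analysis
does, and a test verifies that at $d = \sigma\sqrt{3}$ the mixture is close
enough to Gaussian that a quantile–quantile comparison at n = 240 shows no
gross deviation.

What the generator does *not* emulate: timeouts (excluded from the analysis
and at most ~3% of trials in the study; the −7 point cost is carried in the
configuration only), kinematic trajectories, sequential dependencies
between reaches, and any bias — simulated planners aim exactly where they
intend. Passing tests on this cohort therefore demonstrate that the
analysis machinery recovers what it should from data with the study's
second-order statistics, not that real reach data are this clean.

The non-adaptive planners (`circular`, `anisotropic`, `static`) compute
their per-direction aims from the *true* session covariance (pooled to one
variance for the circular planner) rather than from their own finite
training sample. This makes each subject's generating aimpoints
deterministic given the design, which is what parameter-recovery tests
need; the adaptive learners below are the ones for which estimation from
experience is the point.

## Simulated learners

Three trial-by-trial learners generate the competing aimpoint time courses:

* **Stable circular** — fixes the pooled isotropic fit to the training
  residuals and never revises it: $\Delta_{\text{aim}}$ constant and equal
  for horizontal and vertical penalty orientations.
* **Continual update** — starts from that same circular training fit (its
  transitory first model) and thereafter re-fits the full diagonal
  covariance to all residuals observed so far, recomputed every half-block
  (60 penalty trials) for speed: starts equal, then the two orientations
  diverge towards the anisotropic ideal. Because a trial's residual
  (endpoint minus aim) does not depend on where the planner aimed, the
  trajectory can be replayed from any session dataset that records aims.
* **Hill climbing** — no internal model at all. One aim per orientation,
  executed with an isotropic exploration offset $u \sim N(0,
  \sigma_u^2 I)$; after observing reward $r$ the aim moves by
  $\eta\,(r-\bar r)\,u$, with $\bar r$ an exponential moving average of
  that orientation's rewards. This is the simplest stochastic-approximation
  scheme that responds solely to rewards and penalties. Its stationary
  point is the maximiser of the exploration-smoothed gain landscape, so
  with a small step and small exploration the long-run aims approach the
  anisotropic MEG values (the tests verify agreement within 0.5 mm at
  $\eta = 0.04$, $\sigma_u = 0.5$ mm over 8×10⁴ trials). The *defaults*
  ($\eta = 0.3$, $\sigma_u = 1.5$ mm, baseline weight 0.05) are deliberately
  faster: they are chosen so that the rise from zero and the divergence
  between orientations are visible within the four penalty blocks of a
  single session, which is the regime in which the three time-course
  signatures are compared. These hyperparameters are package choices, not
  quantities estimated from data.

The three learners' half-block time courses are qualitatively
distinguishable — constant-and-equal; start-equal-then-diverge;
start-at-zero-then-rise-and-diverge — and the acceptance suite checks the
three signatures with slope and divergence statistics on cohorts of eight
simulated subjects.

## Estimation

`fit_noise_models()` returns the diagonal sample covariance and the pooled
isotropic fit $(s_x^2+s_y^2)/2$, estimated from zero-penalty experimental
trials as in the analysis (an option includes training trials — that pool
is what the continual-update learner uses). Covariance is assumed equal
across zero- and nonzero-penalty blocks; `variance_ratio_test()` (one-sided
F) is provided to check that assumption on simulated data and to reproduce
the drift/no-drift variance comparisons. Per-condition
`delta_aim_summary()` reports the mean endpoint, $\Delta_{\text{aim}}$, and
its SEM across trials, with Welch t tests comparing sessions per direction
— the study's t-test form is not fully specified, so the unequal-variance
(Welch) form is used and noted here. Raw p values are reported without
multiple-comparison correction, matching the original analysis choice.
Biases are summarised per axis with t-based 95% confidence intervals.

## Evidence computations

**Aimpoint-model evidence.** For each penalty trial, the endpoint is scored
under a Gaussian centred on the model's predicted aimpoint with the plug-in
covariance fitted from the subject's zero-penalty data — a point estimate,
with no marginalisation, exactly as the model-selection formula specifies —
and the evidence is $10\log_{10}$ of the likelihood ratio (positive
favouring the circular model) under a uniform model prior. Log-likelihoods
are summed, so evidence is exactly additive over trial subsets and over
subjects.

**Variance-structure evidence.** Whether two sets of zero-mean residuals
share a variance is compared by marginal likelihoods under a Jeffreys prior
$p(\sigma)\propto 1/\sigma$. The Jeffreys prior is improper, and the
original account does not state bounds or normalisation, so the package
makes a documented construction rather than inferring the authors' choice:
the prior is truncated to $[0.1, 100]$ mm and normalised, each model's
prior is normalised over its own support, and the order-constrained model
($\sigma_A > \sigma_B$) is renormalised by its constraint-region mass (a
factor of 2, by symmetry). This makes Bayes factors between models of
different dimension well defined; sign and growth of the evidence are
insensitive to the bounds once n exceeds a few tens of trials, and a
warning is raised if a residual scale falls outside the bounds. The
marginal likelihood of $n$ zero-mean Gaussian residuals with sum of squares
$S$ under the truncated $1/\sigma$ prior has an incomplete-Gamma closed
form, evaluated in the log domain via `pgamma`/`lgamma`; the
order-constrained double integral uses that closed form for the inner
dimension and adaptive Simpson quadrature in $\log\sigma$ (a 1001-point
scout locates the peak window, 2001 Simpson points cover it) for the outer.
Agreement with independent sigma-scale quadrature oracles is tested to
better than 1e−4 dB, and the closed form converges to the infinite-support
Gamma-function expression as the bounds widen.

**Sequential trace.** `evidence_trace()` applies the order-constrained
comparison (horizontal > vertical versus equal) cumulatively to the
horizontal and vertical residuals of the same reaches, starting at 0 dB
before any data. Residuals are taken about the known aim (bias is assumed
zero, consistent with the sub-millimetre biases the generator produces and
the summary statistics verify); estimating the mean instead would cost a
degree of freedom and is deliberately not done. Whether such a trace should
use training reaches only or all reaches to date is ambiguous in the
original account; the function is agnostic — it consumes whatever residual
stream it is given — and the pipeline reports the end-of-training value
(n = 207) while full-session traces can be computed by passing the full
stream. Under sustained 3× anisotropy the trace grows roughly linearly and
is positive by the end of training in ≥95% of simulated runs; under
isotropy its expected increment is non-positive.

## The pipeline and its cohort statistics

`run_full_analysis()` composes the above per subject and then, at the
cohort level: sums the per-subject aimpoint evidence (log additivity);
fits ordinary least squares of observed on predicted
$\Delta_{\text{aim}}$ (condition-level points, drift session) separately
for the two models; and runs a one-sample t test on the per-subject
difference in mean absolute prediction error ($M_a$ minus $M_c$). Whether a
perturbation non-responder belongs in the regression is genuinely open in
the original account; the `include_all_in_regression` flag (default TRUE)
exposes the choice. Reports serialise to JSON with CSV-exportable
components, and are bit-identical given the same seeds. The command-line
wrapper in `inst/cli/riskreach.R` exposes `simulate` and `analyze` verbs
over the same functions; the package functions themselves are the primary
interface.

## Problem sizes and test design

The test suite exercises the full study scale where it matters — 927
trials per session, 240 zero-penalty endpoints per covariance fit, 480
penalty trials per evidence computation — and uses Monte-Carlo oracles of
10⁵–10⁶ draws, 100-seed recovery ensembles for the evidence sign checks,
200-trace ensembles for the sequential evidence behaviour, and cohorts of
8 simulated subjects for the learner signatures. These sizes are chosen so
each stochastic check has comfortable statistical margin while the whole
suite runs in minutes.

## Known limitations

* Only diagonal covariances are represented; correlated noise would
  require rotating the task frame.
* Only two circular regions are supported — no non-circular regions,
  additional penalty regions, or time-dependent gains.
* The generator produces no timeouts, biases, learning drifts (other than
  through the adaptive planners), or trial-to-trial dependencies.
* The hill-climbing rule is one representative of the reward-only class;
  its hyperparameter defaults shape how fast (not whether) its signature
  emerges.
* Real-data evidence magnitudes depend on details (bias handling, prior
  bounds) that the original account leaves open; signs and orders of
  magnitude are the reproducible quantities, and the package documents its
  own constructions rather than claiming them as the original ones.
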