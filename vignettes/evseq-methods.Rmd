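---
title: "Circuit models and analyses for evidence accumulation through neural sequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Circuit models and analyses for evidence accumulation through neural sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evseq)
```

## The task and the modeling problem

In the accumulating-towers task, a head-fixed mouse runs down a virtual
T-maze at (effectively) constant speed: 30 cm of precue corridor, a 200 cm
cue region where brief visual towers appear at random positions on the left
and right walls, and a 100 cm delay with no cues. Reward follows a turn to
the side that showed more towers, so the animal must integrate a signed
count — the accumulated evidence $e = \#R - \#L$ — and hold it across the
delay. Imaging during this task shows *choice-selective sequences*: neurons
fire transiently at specific maze positions, and which neurons fire depends
on the upcoming choice. Classical accumulator circuits (mutually inhibiting
populations, ring/bump attractors) hold evidence in *persistent* activity
and therefore cannot produce such sequences.

`evseq` implements two circuit-model classes that reconcile accumulation
with sequential firing, plus the analysis pipeline used to tell their
evidence-coding signatures apart, and a synthetic-session generator so that
every analysis stage can be validated against known ground truth.

## The competing-chains models

Two chains of rate units, one per choice side. Unit $i$ of the left chain
obeys

$$\frac{dr_{i,L}}{dt} = -a\, r_{i,L} + \big[b\, r_{i,L} + c\, r_{i-1,L}
 - e\, r_{i,R} + f\, 1_{\mathrm{left}}(t) + P_i(t) - T\big]^+ ,$$

with the mirror-image equation for the right chain. $1_{\mathrm{left}}(t)$
is 1 while a left cue lies strictly within 0.5 cm of the current position.
The position gate $P_i$ equals $T + X$ while the animal is inside unit
$i$'s 20 cm section and 0 otherwise, so only one pair of units is above
threshold at a time; with $P_0 = 20$ cm the 330 cm maze splits into 17
sections (34 units in total). Defaults ($a=50$, $b=10$, $c=50$, $e=40$
s$^{-1}$, $f=100$, $T=15000$, $X=500$ Hz/s) satisfy $-a + b + e = 0$, so
the active pair's rate *difference* integrates the cue input perfectly
(2 Hz per cue at 50 cm/s), and $c = a$ hands the difference to the next
pair with unit gain. Accumulation saturates when the nondominant chain hits
0 Hz, at $|d| = X/(a-b) = 12.5$ Hz ($\approx$ 6 cues); with $X = 1000$
Hz/s the tuning is instead linear across the observed evidence range. Three
variants:

* **mutual** — as above.
* **uncoupled** — no cross-inhibition; cues act push–pull
  ($+f\,1_{\mathrm{left}} - f\,1_{\mathrm{right}}$ on the left chain).
  Only a verbal push–pull description of this variant is available,
  together with the constraint that the gate must equal the threshold
  exactly to avoid integrating the gate itself. A unit
  can only integrate (rather than leak) if self-excitation balances decay,
  so this package runs the variant with $b = a$, $e = 0$, $X = 0$. This is
  a design interpretation: with rectification at zero the variant encodes
  evidence one-sidedly and its counting is exact only while rates stay
  positive; its perturbation signature (no effect whatsoever on the
  opposite chain) is exact regardless.
* **unstable** — self-excitation grows along the chain,
  $b_i = b_0 + \Delta i$ with $\Delta = 0.5$ s$^{-1}$, so late positions
  amplify the difference toward a binary, choice-like code. A complementary
  route to choice coding is a population of binary readout cells,
  $r = \alpha(\mathrm{sgn}(r_{i,L} - r_{i,R} + \xi) + 1)$ with
  $\alpha = 5$ Hz, $\xi \sim N(0, 2^2)$ Hz, and $i$ cells per choice at
  position $i$. Readout cells in this package respond only while their
  position's gate is active; away from it both accumulator rates are
  zero and the sign would be pure noise.

## The position-gated bump attractor

A layer of 35 evidence-tuned neurons (integer levels $-17\ldots17$) per
position section — 595 neurons in all. Neuron $(i, j)$ obeys

$$\frac{dr_{i,j}}{dt} = -a\, r_{i,j} + F\Big(\textstyle\sum_k W_{j,k}
r_{i,k} + b\, r_{i-1,j} + c\,(I_{i,j+1,L} + I_{i,j-1,R}) + P_i(t) -
T\Big),$$

with $F(x) = q\,(1+\tanh(\gamma x))/2$, cosine weights $W_{j,k} =
\omega_0(\cos(\theta_j - \theta_k) + \omega_1)$ on evenly spaced angles,
and shifter neurons $I_{i,j,L/R} = r_{i,j}\,1_{\mathrm{left/right}}(t)$
that multiplicatively gate the global cue signal by the local bump, pushing
the bump one level right (toward $+$) per right cue and vice versa.
Defaults: $a=55$, $b=0.088$, $c=0.2$, $\omega_0=0.12$ s$^{-1}$,
$\omega_1=-1$, $T=300$, $X=0.04$, $q=1250$ Hz/s, $\gamma=1$ s/Hz; the
first layer starts with 15/17.5/15 Hz at levels $-1/0/{+1}$.

Evidence is not periodic, so the nominal ring seam is irrelevant in
practice; because the cosine is even and periodic, "cutting" the seam
cannot change $W$ itself, and the only boundary handling needed is that
shifter terms beyond levels $\pm 17$ contribute nothing.

Two empirical properties of this parameterization are worth knowing:

* **Per-cue shift gain is ~1.16 levels, not exactly 1.** Under step-size
  refinement the simulated shift per isolated cue converges to about 1.16
  evidence levels, so on cue-dense trials the final bump occasionally
  over-counts $|e|$ by one level. The *sign* of the final position — hence
  the choice — is unaffected (100% correct on noise-free trials), and the
  narrow, tiled tuning signature survives because the mapping from true
  evidence to bump position stays monotonic.
* **Integration step.** The shifter pulses last 20 ms and interact with a
  steep nonlinearity during layer handoffs; the package's fixed-step RK4
  integrator needs a 0.5 ms step there (verified by halving-step
  convergence), finer than the 0.01 s bound that an adaptive stiff solver
  needs. The cosine weight matrix is applied through its exact rank-3
  factorization, which keeps the finer step cheap.

Traditional (ungated) baselines of both classes — the two-population
competing accumulator and the 35-neuron bump — are provided for the
contrast figures: they integrate evidence but fire persistently, without
sequences.

## Trials, noise and psychometrics

`generate_trial()` draws Poisson cue counts (defaults 7.7 majority / 2.3
minority, the side randomized per trial) and places cues uniformly in the
cue region with a 12 cm minimum same-side spacing. The means and the
spacing are behavioral-task conventions rather than model parameters; they
are emulation choices fixed here once. Spacing is imposed
by the exact order-statistics construction (sorted uniforms on the slack
interval plus mandatory gaps) rather than rejection sampling: it samples
the same conditional law but never fails, so the Poisson count marginal is
preserved exactly — a property the package's own law-of-large-numbers check
relies on.

Sensory noise follows the stated protocol: each cue is kept independently
with probability 0.33 (the animal missing 67% of towers), 25 sessions of
150 trials drawn without replacement from the trial pool; psychometric
curves (fraction of left choices vs. $\Delta = \#R - \#L$, 3-tower bins
over $-14\ldots14$) are computed against the *original* cue counts. The 29
integer values of $\Delta$ cannot be split symmetrically into width-3 bins,
so bins are centered at $0, \pm3, \ldots, \pm12$ with $|\Delta| = 13, 14$
absorbed into the outermost bins. The s.e.m. is computed across sessions
when sessions exist, else binomially.

## The tuning-characterization pipeline

Rates are averaged in 5 cm position bins ($-30$ to 300 cm), and each bin
carries the evidence observed *before its start*. The joint tuning model

$$FR(p, e) = a\, e^{-(p-\mu_p)^2/2\sigma_p^2}\,
 e^{-(e-\mu_e)^2/2\sigma_e^2} + b$$

is fitted to each neuron's normalized rates (correct trials only) by
alternating bounded least squares on the position block and the evidence
block, ending on a position update (three position updates by default, with
a $10^{-3}$ early-stop; L-BFGS-B with analytic gradients stands in for a
trust-region solver — both are box-bounded quasi-Newton least-squares
methods, and the box bounds are identical). The $\mu_e$ bounds
are recomputed each iteration from the evidence observed within 5 cm of the
current $\mu_p$, and neurons whose final $\mu_e$ escapes its bounds are
flagged ineligible for normalized-parameter analysis. Because the evidence
Gaussian may extend beyond the observed range, monotonic tuning appears as
a peak near the range extreme: after branch-specific normalization,
monotonic-like neurons have $|\bar\mu_e| \approx 1$ while unimodal-like
neurons have intermediate $\bar\mu_e$ and small
$\bar\sigma_e = \sigma_e / (\max\mathcal{E} - \min\mathcal{E})$.
Initialization: $\mu_p$ at the argmax bin,
$\sigma_p = 30$ cm, $\mu_e$ the rate-weighted evidence at the peak,
$\sigma_e = 5$, $a$ the normalized range, $b$ the minimum.

Identifiability caveat: a neuron whose position field sits where the task
has not yet produced its preferred evidence (e.g. $\mu_e = -6$ at 10 cm) is
not recoverable by any method; the package's recovery oracles therefore
check the identifiable regime (mid-maze fields, $|\mu_e| \le 6$).

**Significance** uses the pseudosession method: the same rates refit
against evidence from 50 surrogate trial sets, then a one-sample t-test of
the null mean-squared errors against the observed MSE (one-sided, $p <
0.05$). The package implements this procedure as the default — but note that it is anti-conservative by construction: the
observed MSE is a single draw exchangeable with the null draws, compared
against the null *mean* with standard error $s/\sqrt{50}$, so the null
rejection rate is about $P(z > t_{0.95}/\sqrt{50}) \approx 0.4$ rather
than 0.05. The package verifies this empirically (the corresponding
acceptance check is expected to fail for the t-test form) and provides
`method = "empirical"`, the percentile of the observed MSE in the null
distribution with the $(k+1)/(n+1)$ correction, which is exactly
calibrated; a separate property test covers it. For detecting genuinely
tuned neurons the two methods agree.

One-dimensional tuning curves around the most active position (data within
$0.5\sigma_p$ of $\mu_p$, clipped to 0–300 cm, averaged per evidence
level) are fitted with both a Gaussian ($a e^{-(e-\mu)^2/\sigma^2} + c$)
and a logistic ($a/(1+e^{-k(e-x_0)}) + c$) at their stated box bounds, winner
by MSE on the level means; both have four parameters, so no complexity
correction is applied. The narrow-$\sigma_e$ outlier screen (bins near
$(\mu_p, \mu_e)$ with under 4 observations or a 1.5 IQR outlier) and the
80%-best-fit display filter are reporting conveniences, never applied to
statistics.

## Encoding and decoding analyses

* **Cue kernels.** The right-minus-left preferring population difference
  (causally filtered: half-Gaussian, 1 s window, 0.25 s sd) is regressed
  on cue-onset vectors (onsets 10 cm before each cue, when it becomes
  visible) convolved with a 7-degree-of-freedom cubic spline basis, ridge
  $\lambda = 1$, intercept unpenalized. With knot placement otherwise a free choice, the basis here is a constant column plus a natural cubic basis
  with 6 degrees of freedom, chosen so that sustained step-like integrator
  responses are representable (a pure natural-spline basis without the
  constant cannot represent them and incurs ~20% reconstruction error on a
  step kernel). Split fits by prior-evidence magnitude (widths 300/200/200
  cm) and cue position (300/230/160 cm) are supported with the stated
  kernel widths.
* **Evidence vs. choice regression.** $FR = \beta_0 + \beta_1 e(p) +
  \beta_2 c$ per neuron per bin, both correct and error trials, choice
  coded 0/1 (only significance is interpreted, so the coding is
  immaterial); per-coefficient partial F (the squared t) with the
  one-sided F-test at 0.01. Active neurons at $p$: $|p - \mu_p| <
  \sigma_p$. On null neurons the false-positive rate is the nominal 1%.
* **Linear decoding.** Per bin and evidence-sign branch ($e \ge 0$ /
  $e \le 0$, plus strict variants), nested five-fold cross-validated ridge
  over the standard $\lambda$ grid (`1e-4` to `1e3` by decades), scored by Pearson correlation on outer
  test folds; shuffle controls permute evidence within the same sign.
  Undefined correlations (constant predictions or targets) are reported
  missing and excluded from means.
* **Population maps.** Preferred-evidence remapping (multiply by $-1$ for
  left-preferring neurons), per-neuron bins require 3 observations, and
  bins sampled in under 10% of sessions are masked; cross-sections at
  50/100/150/200/250 cm.

## Synthetic sessions and what a green test establishes

`generate_session()` emulates the data the pipeline consumes: 30 Hz frame
rate, constant 50 cm/s traversal, per-frame positions and rates, with
parametric tuning families (Gaussian×Gaussian, logistic-in-evidence,
choice-only, null) or model-driven units, and optional additive Gaussian or
Poisson spike noise. Choices follow the majority side with a lapse flip
probability $\mathrm{logit}^{-1}(-0.4\,|\Delta|)$ — 0.5 at $\Delta = 0$,
decaying with evidence, roughly matching rodent error rates — so error
trials exist, which the evidence-vs-choice separation requires. The
generator does *not* emulate calcium dynamics, spike inference, running
speed variability or view angle; green tests establish that the analyses
recover what they claim from data obeying their assumptions, not that
those assumptions hold for any particular real recording.

## Acceptance-scale choices

The packaged acceptance suite runs the stated protocol sizes where stated
(200 noise-free trials, 25×150 noisy trials, 2000 null neurons for the
encoding F-test, 50 pseudosessions for its calibration check) and scales
free parameters down where the protocol leaves them open (20/15
pseudosessions and 120-trial sessions for the model-signature checks; two
bump layers rather than all 17, since layers differ only in their position
window). The chains monotonic-signature check uses the linear-tuning
parameterization ($X = 1000$ Hz/s): with the saturating default the fitted
normalized peaks land at ~0.7–1.2 of the observed range depending on the
sampled evidence, while the criterion's premise — monotonic tuning across
the whole observed range — is exactly the stated linear regime.

## Known limitations

* The uncoupled-chains instantiation follows a verbal description; its
  quantitative behavior on mixed-side trials (rectification at zero rate)
  is an interpretation, not a reproduction.
* The bump attractor's per-cue shift gain (~1.16) means exact evidence
  *counting* holds only approximately at the default parameters.
* The default pseudosession t-test is anti-conservative (see above); use
  `method = "empirical"` when calibrated significance matters.
* Real-data quantities (regional tuned fractions, encoding-model $r^2$)
  require the original imaging datasets and are out of scope.
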