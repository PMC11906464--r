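---
title: "Measuring social value orientation under inequality control: models, generators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring social value orientation under inequality control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of its models and the design
choices behind them: what is estimated and how, what the synthetic-data
generator does and does not emulate, the numerical conventions of the gaze
metrics and the samplers, and the limitations a user should keep in mind.
No empirical claim is made here that the test suite and
`scripts/acceptance.R` do not themselves compute.

## The measurement problem

Binary allocation tasks infer a person's social value orientation from
repeated choices between two (own, other) payoff splits. The fitted model is

$$U = \text{own} + \alpha\,\text{other}, \qquad
  p(A) = \frac{1}{1 + e^{-\theta (U_A - U_B)}},$$

with altruism $\alpha$ and choice sensitivity $\theta \ge 0$ ($\theta = 0$
means random choice; $\theta$ is in units of 1/money, so its value depends
on the battery's payoff scale — compare $\theta$ only across batteries with
shared payoff ranges). The confound: in classic ring items the two options
also differ in inequality $|\text{own} - \text{other}|$, so a chooser who
merely dislikes lopsided splits drifts toward the more "generous" option in
part of the battery. The inequality-controlled (IC) battery removes the cue
by construction: both options in a pair share the same absolute gap, one
favouring self, one favouring the other person.

## Stimulus generators

**Ring pairs.** `generate_ring_pairs()` places $n$ equally spaced points on
a circle in the (own, other) plane and pairs adjacent points. The defaults
— centre $(50, 50)$, radius $50$, $24$ pairs — place adjacent points $15°$
apart; the canonical textbook example pair, $(100, 50)$ versus $(98, 63)$,
is exactly two adjacent points of this circle (angles $0°$ and $15°$), which
is why these defaults were adopted. Exact published batteries can be loaded
with `read_stimuli()` instead. Rotation of the start angle permutes the
battery without changing its geometry.

**IC pairs.** `generate_ic_pairs()` draws a gap $g \in [5, 60]$ and payoff
levels in $[20, 120]$ and emits $A = (x + g,\, x)$ vs $B = (y,\, y + g)$:
equal gaps exactly (integer arithmetic), one own-favouring and one
other-favouring option, no duplicates, and never a tie on the own payoff —
ties would make "chose the selfish option" undefined, so the generator
refuses to emit them, the loader flags them, and downstream coding marks
such trials missing. The ranges are a deliberate design default (the
construction, not specific values, is what matters); they give pure-model
choice thresholds densely covering the $\alpha$ range of interest.

Layout (own payoffs on top vs bottom) is counterbalanced exactly 44/44
across the default 88-pair battery. Payoff units are abstract integers;
currency is presentation metadata.

## The hierarchical fit

`fit_svo()` estimates $\{\alpha_i, \theta_i\}$ with partial pooling:

* $\alpha_i \sim \mathrm{Normal}(\mu_\alpha, \sigma_\alpha)$,
* $\log \theta_i \sim \mathrm{Normal}(\mu_{\log\theta}, \sigma_{\log\theta})$
  (the log link enforces $\theta \ge 0$),
* hyperpriors $\mu_\alpha \sim N(0,1)$, $\sigma_\alpha \sim$ Half-Normal(1),
  $\mu_{\log\theta} \sim N(\log 10, 1)$, $\sigma_{\log\theta} \sim$
  Half-Normal(1) — weakly informative on the scales allocation batteries
  produce ($\alpha \approx 0.2$–$0.4$, $\theta \approx 10$).

Sampling is adaptive random-walk Metropolis-within-Gibbs. The likelihood
factorises over participants, so all per-participant proposals are evaluated
in one vectorised pass per iteration; each participant gets (i) a joint
$(\alpha_i, \log\theta_i)$ random-walk update and (ii) a second,
larger-stepped $\log\theta_i$-only update, because $\theta$ is the weakly
identified direction when choices are nearly deterministic and mixes poorly
without it. Hyper-means have conjugate Gibbs updates; hyper-SDs use
random-walk Metropolis on the log scale. Step sizes adapt toward ~30%
acceptance during warmup only, so the post-warmup chain is a valid fixed
kernel. Diagnostics: split-$\hat R$ for every sampled parameter and lag-1
autocorrelation per chain; $\hat R > 1.05$ raises a warning recorded in the
fit, never an exception. Desk-scale defaults are 3 chains × 2000 recorded
draws after 500 warmup — enough for stable posterior means of $\alpha$ at
the 65 × 88 design (the package's tests run at exactly that size);
heavyweight settings (e.g. 3 × 40000) are plain arguments.

The likelihood (`choice_loglik()`) is exported so any external sampler can
be plugged in; a grid-search MLE serves as an independent oracle in the test
suite, and a single participant's posterior matches it to well within grid
resolution.

## The synthetic-data generator

`simulate_study()` emulates a 65-participant, 88-trial within-subject
experiment: per-participant shuffled trial order, softmax choices from
latent $(\alpha_i, \theta_i)$, lognormal response times calibrated to a
2.2 s mean, and a fixation stream per trial. Calibration defaults
($\mu_\alpha = 0.3$, $\sigma_\alpha = 0.15$, median $\theta = 12$,
condition-wise fixation-count means 8.2/8.6, transition bias 0.47/0.505)
were set once to the scale of group statistics typical of such experiments
and are not tuned per analysis.

**The inequality-aversion term.** The generator (and only the generator —
the fitted model never sees it) can penalise unequal splits:

$$U_{\text{gen}} = \text{own} + \alpha\,\text{other}
  - \beta\,[\max(\text{other}-\text{own},0)
  + \kappa \max(\text{own}-\text{other},0)],$$

a Fehr–Schmidt-style term with envy weight $\beta$ and guilt ratio
$\kappa \in [0,1]$ (default 0.5; $\kappa = 1$ is the symmetric
$|\text{own}-\text{other}|$ penalty, $\beta = 0$ recovers the pure model
exactly). The asymmetric default is a considered choice, not a convenience:
a *symmetric* penalty cancels exactly within every IC pair (both options
share the gap) *and* nets out across a ring centred on the equality
diagonal, whose advantageous arc inflates apparent altruism while its
disadvantageous arc deflates it by the same amount — so symmetric
inequality aversion produces no condition difference at all. With the
empirically standard envy-dominant asymmetry, every IC pair's
other-favouring option carries the full envy penalty while only part of the
ring does, so fitted $\alpha$ is depressed more on IC than on ring items and
the ring measure systematically overstates altruism relative to the
controlled battery — for exactly the reason the IC design exists. The
scenario scale $\beta \approx 0.25$ (SD 0.1) was chosen so the per-condition
$\alpha$ difference has a paired effect size near $d = 0.4$ at $n = 65$.
The *absolute* $\alpha$ gap such a generator produces is a few hundredths —
reproducing a larger absolute gap would require far wider between-person
heterogeneity than $\sigma_\alpha = 0.15$ grants.

**Gaze.** The fixation stream is a first-order Markov walk over the four
payoff ROIs: Poisson step count with a condition-specific mean, each
between-ROI move option-wise with probability `transition_bias` and
attribute-wise otherwise, small off-ROI and refixation probabilities, Gamma
durations, and dwell on the to-be-chosen option inflated by a
condition-specific `gaze_coupling`. This is deliberately the *simplest*
process with controllable total fixation count, coverage, Payne Index, and
dwell–choice coupling; it is a measurement test-bench, not a model of
saccade programming. Passing tests on it show the metrics and models recover
what the walk put in — they do not validate any claim about real scanpaths.
The two-block structure of a real session is metadata only; no block or
fatigue effects are simulated.

## Gaze-metric conventions

* **Validity filter**: fixations must be *strictly* longer than 50 ms; a
  50 ms fixation is excluded.
* **ROI geometry**: rectangles of 6.7° per side, converted anisotropically
  (1024 px / 36° ≈ 28.4 px/° horizontally, 768 px / 29° ≈ 26.5 px/°
  vertically); containment is half-open so no point belongs to two ROIs;
  centres must exceed 5° spacing on at least one axis and rectangles must
  not overlap.
* **TFC** counts all valid fixations, off-ROI included, without merging
  consecutive same-ROI fixations (merging would not affect the Payne Index,
  whose transitions exclude same-ROI pairs anyway).
* **Payne Index**: option-wise and attribute-wise transitions only;
  diagonal moves (option *and* attribute change) count in neither term —
  the standard convention. An off-ROI fixation *breaks* the transition by
  default (bridging across it is available as `off_roi = "bridge"`); the
  conservative default avoids fabricating payoff-to-payoff transitions the
  eyes did not make. PI is undefined (`NA`), not zero, when a trial has no
  qualifying transitions; undefined trials are dropped from aggregates and
  counted.
* **Time advantage** is raw dwell (ms) on the selfish option's two ROIs
  minus the non-selfish option's; standardisation to z-scores happens at the
  modelling stage, pooled over the analysed trials by default.
* Trials with no fixation data at all are flagged invalid (the
  eye-tracking-failure exclusion), never errors.

## Inference components

**Paired comparisons.** `paired_ttest()` wraps the standard t-test and adds
the paired Cohen's d, which satisfies $d = t/\sqrt{n}$ exactly. Zero
variance of the differences (including identical vectors) is a
degenerate-input error — there is no finite t to report.
`condition_comparison()` assembles per-condition means with t-based 95% CIs,
the test, d, and the Bayes factor.

**JZS Bayes factor.** `jzs_bf10()` computes the default-prior Bayes factor
for the two-sided paired/one-sample design from $(t, n)$ alone, with a
Cauchy(0, 0.707) effect-size prior represented as the standard
inverse-gamma(1/2, scale²/2) mixture of normals and integrated by adaptive
quadrature (relative tolerance $10^{-6}$). The test suite checks it against
an independent noncentral-t × Cauchy quadrature to four significant
figures. Evidence labels follow the Jeffreys-style bins (1–3 weak, 3–10
moderate, 10–30 strong, > 30 very strong); values below 1 are labelled by
the same bins applied to $1/\mathrm{BF}$ with a `" for null"` suffix — the
suffix convention is this package's, documented rather than standard.

**Mediation.** `fit_mediation()` is a parallel multiple-mediator model with
a logistic outcome: per-mediator a-paths by linear regression on condition
plus covariates; b-paths and the direct effect from a single logistic
regression containing all three mediators (each controlling for the
others); the total effect from a logistic model without mediators. Indirect
effects $a_k b_k$ get percentile bootstrap CIs (5000 draws by default) and
delta-method z tests. Choices made where the convention is genuinely open,
each switchable: mediators are standardised before the path fits so
indirect effects are comparable across their native scales (count,
fraction, index); the bootstrap resamples trials by default with a
participant-cluster mode provided because trials are nested; the
participant covariate enters as a dummy-coded factor by default with a
single-numeric mode mirroring a literal "discrete variable" reading.
Trials with an undefined PI or missing selfish-choice coding are
listwise-excluded and counted. Separation in the logistic fit is flagged
with a warning, never silently.

**Gaze–choice GLMM.** `fit_gaze_glmm()` predicts selfish choice from
condition, standardised time advantage, and their interaction, with
participant and item random effects estimated by Laplace approximation. The
random structure starts maximal (by-participant slopes for all fixed
effects, item intercepts) and falls back on non-convergence — drop slope
correlations, drop the condition slope, drop all slopes — recording the
rung actually fitted; a boundary-singular optimum counts as converged.
Simple slopes per condition are linear contrasts of the fixed effects, so
the SVOR−IC slope difference equals the interaction coefficient *exactly*,
a structural identity the tests assert. One caveat discovered in
calibration and worth knowing: at the calibrated sensitivity
($\theta \approx 12$) choices are near-deterministic per item, item
intercepts saturate the logistic likelihood, and fixed effects become
unstable — so the package's GLMM benches simulate with low sensitivity
($\theta \approx 0.03$) to guarantee within-item outcome variability. Real
datasets sit between these extremes.

## Problem sizes and numerical settings

The test suite and acceptance script run, as the package's own choices:
desk-scale MCMC (3 × 2000/500 for recovery; 2 × 800/300 inside replicated
scenario fits), 20 seeded replications for the ring-vs-IC bias property,
1000 bootstrap draws for mediation recovery (5000 remains the analysis
default), and a 1000-sequence brute-force equivalence check for the Payne
Index. Parameter recovery at the full 65 × 88 design reaches a true-vs-
posterior-mean $\alpha$ correlation above 0.99 with RMSE under 0.03,
comfortably inside the ≥ 0.9 / ≤ 0.1 targets the package holds itself to.
All randomness flows from explicit integer seeds; identical seeds give
byte-identical simulations, fits, and bootstrap intervals.

## Limitations

* The ring geometry is a parameterised stand-in for any specific published
  battery; load exact item sets via `read_stimuli()` when fidelity matters.
* The gaze generator is a Markov test-bench; nothing here validates
  fixation detection, calibration quality, or scanpath realism.
* $\theta$ estimates are payoff-scale-dependent; cross-battery comparisons
  require shared ranges.
* The SVO-type angular boundaries (−12.04°, 22.45°, 57.15°) follow a common
  convention but published boundary sets vary; they are configurable and
  should be treated as a stand-in.
* The mediation model is statistical mediation on observational paths; no
  causal identification is claimed beyond it.
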