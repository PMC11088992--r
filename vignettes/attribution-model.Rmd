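---
title: "A grid-based Bayesian model of intentional attributions in the iterated Dictator game"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A grid-based Bayesian model of intentional attributions in the iterated Dictator game}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(attributr)
```

## The task and the model

In the iterated Dictator game ("Sharing Game") a participant faces three
partners in turn, six trials each. On every trial the partner either takes
the whole £0.10 stake (unfair, `rew = 0`) or splits it (fair,
`rew = 0.5`). Partner policies are *fair* (always split), *partially fair*
(50:50) and *unfair* (always take). After each action the participant
rates, on 1–100 scales, how much the partner is motivated by **harmful
intent** (HI; self-relevant) and by **self-interest** (SI; other-relevant).

The model maintains a joint belief $p(\mathrm{HI}, \mathrm{SI})$ over a
$9 \times 9$ grid of binned intent levels. Its pieces:

* **Priors.** Each marginal is a binomial pmf over the nine bins,
  $B(k; \mathrm{NB}-1, p_0)$ at $k = \text{bin}-1$, raised elementwise to
  $1/u_{\mathrm{Pri}}$ and renormalized. $p\mathrm{HI}_0$ and
  $p\mathrm{SI}_0$ set the location; $u_{\mathrm{Pri}}$ flattens
  ($u \to \infty$ gives uniform, $u < 1$ sharpens). The joint prior is the
  outer product of the marginals.
* **Likelihood.** The participant's internal policy model is
  $\pi_{gen}(\mathrm{rew}=0;\mathrm{HI},\mathrm{SI}) =
  \sigma(w_0 + w_{HI}(\mathrm{HI}-\delta) + w_{SI}(\mathrm{SI}-\delta))$
  with $\delta = (\mathrm{NB}+1)/2 = 5$ the grid centre, and the fair slice
  its exact complement. Centring makes $w_0$ the log-odds of an unfair act
  for a partner of average intent.
* **Update.** On each observed outcome, elementwise Bayes:
  multiply by the matching likelihood slice and renormalize.
* **Consistency.** The posterior is tempered,
  $p \propto \hat p^{\,1/u_\pi} + \xi$ with fixed floor
  $\xi = 0.02/\mathrm{NB}^2$: larger $u_\pi$ blunts the impact of each
  action ($u_\pi \to \infty$ flattens to uniform).
* **Change point.** Entering a new partner, beliefs restart at the convex
  blend $(1-\eta)\,p^{t=0} + \eta\,p^{t=C}$ of the baseline prior and the
  final posterior about the previous partner: $\eta$ is carry-over.
* **Reports.** Ratings map to bins by equal-width intervals
  (`ceiling(rating * 9 / 100)`); a reported pair is scored by the log of
  the joint cell mass (floored at $10^{-12}$), and simulation samples a
  cell from the joint grid and reports bin centres.

Three variants are compared: **M1** (all nine parameters free), **M2**
(one shared likelihood weight $w_{HI} = w_{SI}$), and **M3** (one shared
prior uncertainty, the winning 8-parameter variant
$\{p\mathrm{HI}_0, p\mathrm{SI}_0, u_{\mathrm{Pri}}, w_0, w_{HI}, w_{SI},
u_\pi, \eta\}$).

```{r forward}
par <- attr_params(pHI0 = 0.3, pSI0 = 0.6, uPri_HI = 0.8, uPri_SI = 0.8,
                   w0 = -1, wHI = 0.45, wSI = 0.7, u_pi = 1, eta = 0.4,
                   variant = "M3")
frame <- tibble::tibble(partner = rep(1:3, each = 6),
                        outcome = rep(c(0.5, 0, 0), each = 6))
sim <- simulate_reports(frame, par, seed = 1)
head(sim)
```

## Design choices in the forward model

Several details are under-determined by the equations as printed; the
package fixes them as follows (each is covered by a unit test):

* The linear term is parsed as weight-times-centred-bin,
  $w_{HI}\,(\mathrm{HI}-\delta)$, not $(w_{HI}\,\mathrm{HI})-\delta$; the
  centred form makes $w_0$ interpretable and the weights scale-free.
* The binomial marginal uses $\mathrm{NB}-1 = 8$ trials at $k=\text{bin}-1$
  so its support exactly spans the nine bins.
* In the consistency rule the order is power → add $\xi$ → renormalize
  (the proportionality is read as normalize-last). $\xi$ is fixed, not
  fitted; tests may zero it through the `xi` argument.
* Per-trial event order: observe outcome → Bayes update → consistency →
  report. Ratings are given after each action, so scoring uses the
  post-update grid.
* Reports are scored on the joint cell (and simulated by joint sampling),
  not on the product of marginals: the model is inherently joint, and the
  likelihood ridge induced by an outcome is exactly the kind of HI–SI
  dependency the coupling analysis measures.
* Ratings map to bins by equal-width intervals with bin-centre inverse —
  the simplest monotone, exactly invertible contract.
* Partner order is randomized per subject and condition from the seed.

Numerical guards: model-space probabilities are clamped to
$[10^{-7}, 1-10^{-7}]$ and exponentiated uncertainties to
$[10^{-3}, 10^{6}]$ before use, so any native-space vector the optimizer
proposes yields a proper, finite likelihood; report log-likelihoods are
floored at $10^{-12}$ per report.

## Hierarchical fitting

Subjects are fitted in an unconstrained **native space** (logistic maps
for $p\mathrm{HI}_0$, $p\mathrm{SI}_0$, $\eta$; exponential for
$u_{\mathrm{Pri}}$, $u_\pi$; identity for the weights), starting from a
broad Gaussian group prior (mean 0, sd 6.5). The fitting loop is an
empirical-Bayes EM with random effects over models:

1. **MAP step.** Each subject × candidate model is maximized by
   multi-start BFGS (10 starts in the first sweep, seeded; warm starts
   afterwards) over log-likelihood + native Gaussian log-prior. The
   negative Hessian at the mode (central differences, step $10^{-4}$,
   jittered to positive definite) gives a Laplace log evidence
   $\log Z \approx f(\hat\theta) + \tfrac d2 \log 2\pi -
   \tfrac12 \log\det(-H)$.
2. **Responsibilities.** Per subject, proportional to model frequency ×
   $\exp(\text{evidence})$, normalized in the log domain.
3. **Group moments.** Responsibility-weighted mean of the MAPs; the
   variance update adds each subject's Laplace posterior variance and a
   Normal–inverse-$\chi^2$ hyperprior (one pseudo-observation at scale 2):
   without the hyperprior the group variance of weakly identified
   parameters (notably $\eta$, informed by only two partner boundaries per
   condition) collapses, erasing individual differences.
4. **Frequencies.** Dirichlet count update (prior count 1 per model);
   exceedance probabilities by Monte-Carlo over the Dirichlet posterior,
   with a protected variant mixing in the equal-frequency null (weight
   0.5, configurable — the original null weight is not published).

Iteration stops when no group mean moves by more than $10^{-3}$ or after
50 sweeps (the fit is then flagged non-converged but still returned). Each
drug condition is fitted independently, because the same participants
appear in every condition. Subjects whose fits fail to produce finite
evidence are flagged and excluded from group updates with a warning, never
silently dropped.

The per-subject likelihood is implemented twice: a readable R version
(`run_subject`, which also returns the belief-grid trajectory) and a
compiled C++ version used inside the optimizer; the test suite holds them
to each other and to an independent straight-line oracle at $10^{-12}$.

## The synthetic cohort generator

`cohort_spec()` describes the study-sized cohort: 28 subjects × 3
within-subject conditions × 3 partners × 6 trials. Condition presets are
native-space Gaussians. The placebo-like preset
($p\mathrm{HI}_0 = 0.3$, $p\mathrm{SI}_0 = 0.6$, $u_{\mathrm{Pri}} = 0.8$,
$w_0 = -1$, $w_{HI} = 0.45$, $w_{SI} = 0.7$, $u_\pi = 1$, $\eta = 0.4$ in
model space) was calibrated once against the published *behavioural*
statistics of the task — simulated cohorts show standardized policy
contrasts of roughly 0.5 SD (HI) and 0.8 SD (SI) for unfair vs fair
dictators and 0.3/0.5 SD for partially fair vs fair, the same ordering and
order of magnitude as the real data — and then frozen. The
haloperidol-like preset shifts $w_{HI}$ up by 0.10, draws $w_0$ towards
zero (+0.6) and raises $\eta$ to 0.55, following the direction and size of
the reported drug contrasts; the l-DOPA-like preset equals placebo (no
consistent l-DOPA effects were reported). Native-space spreads
(0.7, 0.7, 0.5, 0.8, 0.25, 0.25, 0.5, 0.7) are plausible heterogeneity:
wide enough that subjects differ visibly, narrow enough that every subject
remains in the regime where the task is informative.

What the generator does *not* emulate: real participants rate on a
continuous slider with serial dependencies and far less noise than joint
grid sampling (the generator's report noise floor is about one grid bin,
~11 rating points); parameters are drawn independently across conditions,
so within-subject trait stability is absent; and the partially fair
partner's realized sequences are fresh Bernoulli draws, not the study's
actual sequences. Passing tests therefore certify the machinery —
identifiability, estimator calibration, directionally correct drug
fingerprints — not the empirical effect sizes, which depend on the
deposited participant data.

## The recovery study

`recovery_study(mode = "refit")` mirrors the study's recovery design: fit
the cohort per condition, treat the fitted individual estimates as the
"real parameter sets", simulate one synthetic participant per estimate
over the same partner orders and outcome sequences, refit, and correlate
the two sets of estimates (Pearson, native space, pooling
subject × condition pairs). Generative recovery correlates the cohort's
observed ratings with the model's **expected** attribution series (grid
marginal means on the rating scale) under the stage-1 estimates, within
each dictator policy. The expected series is used deliberately: with
sampled replicates the correlation between two independent draws from the
*same* parameters tops out below the reliability of interest, because both
series carry the one-bin sampling noise; the expected series is the
model's actual prediction. `mode = "gaussian"` instead scores recovery
against the generator's Gaussian truth table; it is kept for property
tests (e.g. zero-spread cohorts flag degenerate correlations).

With only 18 trials per condition, parameters differ widely in how much
data bears on them: prior parameters are pinned by early trials and
recover best; $\eta$ is informed only by the two partner changes per
condition, and its recovery relies partly on between-condition spread —
this is visible in the per-parameter correlations and is a property of the
task length, not of the fitting machinery.

## Downstream analyses

* **Paired contrasts** use the exact Jeffreys-prior posterior for paired
  differences (normal–inverse-$\chi^2$), sampled analytically: median
  difference, shortest 95% HDI, and posterior Cohen's $d$ with HDI. An
  MCMC backend would add nothing here since the posterior is available in
  closed form.
* **Attribution precision** is $1/\sigma^2$ of a subject-condition's
  rating series (pooled over the 18 trials, optionally within policy);
  zero-variance series are flagged, never returned as infinite. The
  precision regression follows the published specification — $w_{HI}$
  linear, $w_0$ quadratic, their interaction, policy terms when present —
  on centred/scaled regressors, with the linear-$w_0$ variant fitted
  alongside for AIC comparison.
* **Trial-wise coupling** computes, at each of the 18 trial positions, the
  across-subject partial correlation between HI and SI ratings with
  dictator policy partialled out (rank-transform first for the Spearman
  default; a Pearson option matches the other wording in the source
  figures — both are reported because the two descriptions disagree).
  Decay is the correlation of the per-trial coefficients with trial index;
  conditions are contrasted by a paired posterior over the 18
  coefficients.
* **Factor analysis** is principal-axis factoring (iterated communalities
  from squared multiple correlations) with oblique promax rotation and
  regression-method scores, implemented in-package; eigenvalues are
  exposed for scree inspection and the |0.4| loading filter is applied
  only when reporting (`tidy()`), never to the solution. The
  factor-score estimation method is not published; regression scoring is
  the common default.
* **Drug discrimination** is repeated stratified 10-fold × 3 logistic
  cross-validation over 1..K-factor solutions (accuracy and full-data
  AIC), with ROC/AUC and Youden sensitivity/specificity via pROC for the
  best solution.

## Problem sizes and interfaces

The shipped tests run the full study geometry where it matters — the
recovery and model-identification checks use 28 and 16 subjects
respectively with the complete hierarchical loop — and toy sizes
elsewhere; `scripts/acceptance.R` reruns the complete 28 × 3-condition
recovery from scratch. The package is function-first: `cohort_spec()` →
`generate_cohort_dataset()` → `hbi_fit()` / `recovery_study()` → the
analysis functions, or `run_end_to_end()` for the whole pipeline with a
config list; there is deliberately no shell wrapper, since every entry
point is a plain seeded R call and artifacts are plain CSV/JSON.

## Known limitations

* The Laplace/EM scheme is a faithful-contract reimplementation of the
  cited hierarchical machinery, not a port; model evidence is approximate
  and can misrank variants whose likelihoods differ less than the
  Laplace error.
* At task scale (36 grid-sampled reports per subject-condition) the three
  variants are only weakly separable: the likelihood gain from the single
  constraint distinguishing neighbouring variants is comparable to the
  evidence noise, while a weakly identified extra direction is nearly free
  under the Occam term, so neighbouring variants can absorb each other's
  cohorts. Model comparison on such short tasks should be read alongside
  the per-subject responsibilities, not as a point verdict.
* $\eta$'s recovery ceiling is set by two partner boundaries per
  condition; longer tasks would identify it better.
* The response model is binned; no continuous-rating variant, recursive
  mentalising extension, or third attribution dimension is implemented.
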