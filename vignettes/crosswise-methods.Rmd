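---
title: "Measurement, validation and simulation methods in crosswise"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measurement, validation and simulation methods in crosswise}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crosswise)
```

## The measurement model

Direct self-reports of sensitive attributes are distorted by socially
desirable responding. The crosswise model (CWM) addresses this by never
asking the sensitive question alone: the respondent sees the sensitive
statement together with a non-sensitive statement whose population
prevalence $p$ is known (here: "I was born in November or December",
$p = 0.158$ from official birth statistics), and reports only whether
*both statements are true or both are false* (category A) or *exactly one
is true* (category B). No single answer is diagnostic of the sensitive
status, yet the sample-level prevalence $\pi$ remains estimable because

$$\lambda \;=\; \Pr(\text{A}) \;=\; \pi p + (1 - \pi)(1 - p),$$

the sum over the two latent branches of a binary multinomial processing
tree: carriers reach category A when the randomizer is true (probability
$p$), non-carriers when it is false ($1 - p$). Direct questioning (DQ) is
the degenerate design $\lambda = \pi$. The mapping is linear in $\pi$ and,
for $p < 0.5$, strictly decreasing, with attainable range
$[p,\, 1 - p]$. At $p = 0.5$ the design is unidentifiable — the package
refuses to construct it.

Two estimators are exposed:

* **closed form**: $\hat\pi = (\hat\lambda + p - 1)/(2p - 1)$ with
  $\hat\lambda = n_A/n$. When $\hat\lambda$ falls outside the attainable
  range, $\hat\pi$ leaves $[0, 1]$; it is reported raw with a boundary
  flag so the truncation stays auditable.
* **maximum likelihood** (default): an expectation-maximization fit of
  the tree. The E-step computes the expected number of carriers within
  each answer category (the posterior weight of the carrier branch at the
  current $\pi$); the M-step divides by $n$. The ML estimate equals the
  closed form whenever that is interior and otherwise sits at the nearer
  boundary, which is the constrained maximizer of this concave
  one-parameter likelihood.

Standard errors use the delta method on $\hat\lambda$:
$SE(\hat\pi) = \sqrt{\hat\lambda(1 - \hat\lambda)/n}\,/\,|2p - 1|$ for the
CWM and the binomial $\sqrt{\hat\pi(1-\hat\pi)/n}$ for DQ. The
$1/|2p - 1|$ factor is the price of the randomization: at $p = 0.158$ the
variance is 2–3 times the DQ variance at realistic prevalences
(`allocation_ratio()`), which is why validation studies allocate about
twice as many respondents to CWM conditions. At boundary estimates the
same formula is evaluated at the truncated value and flagged; the Wald
interpretation is strained there and the flag is the honest signal of it.

### Numerical choices in the EM fit

Plain EM iteration for this model contracts slowly in two regimes: when
$p$ approaches $0.5$ (contraction factor approaches 1) and when the
observed proportion sits exactly at the $\pi = 0$ or $\pi = 1$ category
probability, where the EM map's derivative at the boundary fixed point is
exactly 1 and convergence degrades to $O(1/k)$. A log-likelihood stopping
rule is unreliable there — it can fire while the parameter is still far
from the maximizer. `em_fit()` therefore applies Aitken's $\Delta^2$
extrapolation after every pair of EM steps, accepting the extrapolated
value only if it does not decrease the log-likelihood (clamped to
$[0, 1]$), and stops when the parameter moves less than `tol = 1e-12` per
cycle. This converges in under a hundred steps in every regime we have
probed, including the degenerate ones, and agrees with the closed form to
well below $10^{-6}$ on interior data. Starting values of exactly 0 or 1
are fixed points of the bare EM map and are nudged to $10^{-9}$ inside.

## Model comparison by G²

Hypotheses about prevalences are expressed as restrictions on a set of
trees (`tree_set()`): tie parameters across conditions
(`eq_restriction()`) or pin one to a constant such as the known criterion
prevalence or zero (`fix_restriction()`). Each fit reports
$G^2 = 2\sum_{\text{cells}} \text{obs}\,\ln(\text{obs}/\text{exp})$, and
nested fits are compared by $\Delta G^2$, asymptotically $\chi^2$ with
one degree of freedom per independent constraint. The unrestricted fit of
untied binary trees is saturated ($G^2 = 0$) whenever every moment
estimate is interior, so $\Delta G^2$ for a single restriction is usually
just the restricted $G^2$.

Tied parameters across trees with different designs remain
one-dimensional, so they are fitted by Brent-style bounded maximization
of the joint log-likelihood on $[0, 1]$ (tolerance $10^{-10}$, endpoints
checked explicitly); tests verify the optimizer against a brute-force
grid search at step $10^{-6}$. Fits restricted to a boundary value use
the $0\ln 0 = 0$ convention rather than special-casing the likelihood.
P-values are reported at machine precision; "p < .001"-style formatting
is left to the caller.

`contingency_test()` (Pearson $\chi^2$ without continuity correction,
plus Cramér's $V = \sqrt{\chi^2 / (N \min(r-1, c-1))}$) covers the
sample-diagnostic comparisons (dropout by education, by condition, and so
on) that accompany such studies.

## Individual-level validation

Aggregate agreement with a known prevalence can mask compensating errors,
so validation needs individual-level ground truth. The anagram paradigm
provides it: respondents are given three anagrams of which the third is
practically unsolvable, then asked whether they solved all three (with a
lottery incentive to overclaim). Claiming all three is the criterion —
those respondents are cheaters, carriers of the sensitive attribute
"I claimed more solutions than I had".

`split_by_criterion()` partitions a condition by this claim. Separate
trees are then fitted per subsample:

* **false-positive rate** — the estimated prevalence *among honest
  respondents* (known non-carriers measured as carriers); its complement
  is specificity;
* **false-negative rate** — one minus the estimated prevalence *among
  cheaters*; its complement is sensitivity.

Both are ML estimates, hence in $[0, 1]$ even when a subsample's moment
estimate is not. Because all mappings are linear in $\hat\lambda$, the
mixture identity

$$\pi_{\text{implied}} = \text{known}\cdot(1 - fn) +
  (1 - \text{known})\cdot fp$$

recomposes the whole-condition estimate *exactly* when the subsample
counts partition the condition counts (`implied_aggregate()`); on
published rounded rates it recomposes the published estimates to rounding
accuracy. Rate differences between groups (education levels, conditions,
self-described response randomness) are tested by the same $\Delta G^2$
machinery on the two subsample trees (`compare_rates()`).

Moderators enter only after dichotomization (`moderator_split()`): binary
fields directly; 7-point ratings either at the extreme level (the
"strongly disagree that I just ticked anything" split) or at the median
with ties to the lower side. A constant moderator under the median rule
is flagged as degenerate rather than silently producing an empty group.

## The synthetic cohort generator

`simulate_cohort()` emulates the validation design so every stage of the
pipeline is testable without access to the original data. Its defaults
are the study conditions themselves: $n = 577/1164/972$ for
DQ / CWM-brief / CWM-detailed, criterion prevalences
$0.5893/0.5670/0.5926$, $p = 0.158$, the observed per-condition
false-positive and false-negative rates, a 50/50 education mix, and
comprehension-check outcomes (first attempt / eventual / fail =
$0.1245/0.5638/0.3117$, detailed condition only).

The generative order matters: misreporting is applied to the *sensitive
status* (a Bernoulli flip at the FP/FN rate) before the CWM combination
with the independently drawn randomizer — not to the final answer
category. That choice makes the FP/FN parameters mean what the validation
analysis estimates (status misclassification) and makes the mixture
identity exact in expectation. Education-specific flip rates can be
supplied to emulate moderated misreporting.

What the generator does **not** emulate: the cognitive process behind
careless or strategic responding (the flip layer is a stand-in, and
ratings are drawn independently of the flips by default); dropout and
completion-time mechanisms; and the full joint distribution of the
evaluation ratings — the study reports only their means and dispersions,
so the three non-randomness rating distributions are a synthetic
right-skewed default, with only the randomness item pinned to its
reported 80.9% extreme share. Passing recovery tests therefore shows that
the estimators are correct *under the stated measurement model*, not that
real respondents obey it.

`recovery_experiment()` wraps the simulate-then-analyze loop and reports
bias and SE calibration (empirical SD of the estimates against the mean
analytic SE). At the study's brief-condition truth, 200–500 replicates
put the Monte Carlo error of the mean near $0.001$, and the analytic SEs
are calibrated within a few percent.

## Pipeline and reproduction scripts

`read_respondents()`/`validate_respondents()` enforce the respondent
schema (listwise exclusion of incomplete rows with a reported count, hard
errors naming the row for unknown conditions or malformed answers);
`run_study()` chains estimation, the pairwise and fixed-value restriction
tests, the criterion-split validity matrix and the configured moderator
analyses into one deterministic report; `write_report()` serializes it
(JSON with raw proportions, CSV validity matrix, plain-text summary —
percentages exist only at this layer, which prevents double-scaling
mistakes).

The `analysis/` scripts are thin drivers over these functions:
`01_reproduce_printed.R` rebuilds the published results from published
numbers via `counts_from_printed()` (rounding-lossy by construction —
reconstructed $\Delta G^2$ values carry a documented ±0.1–0.6 band);
`02_simulated_study.R` runs the full pipeline on one synthetic cohort;
`03_recovery.R` runs the recovery experiment (200 replicates, chosen so
the script completes in seconds while Monte Carlo error stays a fraction
of one analytic SE); `04_design.R` produces the allocation-ratio and
power curves. `power_two_conditions()` is a normal-approximation Wald
power for the two-condition comparison; it matches Monte Carlo rejection
rates to better than 0.01 but is not presented as the original study's
(unstated) power procedure.

## Known limitations

* Only binary-response, single-parameter trees are supported — no
  general multinomial trees, cheating-detection extensions, or
  multi-item scales.
* Standard errors are Wald/delta-method throughout; no profile or
  bootstrap intervals, and boundary SEs are flagged rather than
  corrected.
* Continuous moderators must be dichotomized; the binary-tree framework
  cannot absorb them directly.
* The simulator's misreporting layer is a phenomenological stand-in; it
  reproduces rates, not mechanisms.
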