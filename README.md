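# crosswise

Prevalence estimation and individual-level validation for the **crosswise
model** (CWM), an indirect questioning technique for sensitive survey
topics, with direct questioning (DQ) as the comparison design.

## The problem

Asking people directly about sensitive behavior (cheating, tax evasion,
prejudice) invites socially desirable responding. The crosswise model
pairs the sensitive statement with a non-sensitive statement of known
prevalence *p* (e.g. "I was born in November or December", *p* = 0.158)
and asks only whether *both statements are true or both are false* (answer
category A) or *exactly one is true* (B). No individual answer reveals the
sensitive status, but the category-A probability

&nbsp;&nbsp;&nbsp;&nbsp;λ = πp + (1 − π)(1 − p)

identifies the prevalence π at the sample level (for p ≠ 0.5). Whether the
resulting estimates are *valid* is an empirical question: validation
studies with individual-level ground truth (an induced cheating criterion)
find both **false positives** — known non-carriers measured as carriers —
and **false negatives**, and the package exists to carry out exactly this
kind of analysis:

- closed-form and EM maximum-likelihood estimation of π with delta-method
  standard errors, SE(π̂) = √(λ̂(1−λ̂)/n) / |2p − 1|;
- G² likelihood-ratio tests of restrictions across conditions
  (π₁ = π₂, or π = known prevalence, or π = 0), fitted as one-parameter
  multinomial processing trees;
- false-positive / false-negative rates as subsample prevalences on a
  criterion split, with moderator comparisons (education, self-rated
  response randomness, median splits of 7-point evaluations);
- a synthetic-respondent generator emulating the anagram-cheating
  validation design, for parameter-recovery and calibration studies;
- design utilities: CWM-vs-DQ variance (allocation) ratios and Wald power
  for two-condition comparisons.

It is intended for survey methodologists running or re-analyzing
randomized-response validation experiments.

## Worked example

Answer counts (735 A, 429 B) from a CWM condition with n = 1164 and
p = 0.158, whose known criterion prevalence of cheaters is 56.70%:

```r
library(crosswise)
d <- cwm_design(p = 0.158)
counts <- response_counts(735, 429)

cwm_estimate(counts, d)
#> Prevalence estimate (ml, CWM): pi_hat = 0.3078 (SE = 0.0207), n = 1164
```

The estimated prevalence, 30.78% (SE 2.07%), severely underestimates the
known 56.70%. The G² restriction test quantifies that failure of strong
validation:

```r
test_restriction(tree_set(mpt_tree("CWM_brief", counts, d)),
                 fix_restriction("CWM_brief", 0.5670))
#> Restriction test (fix CWM_brief = 0.5670): dG2(1) = 147.47, p = 6.201e-34, dpi = -0.2592
```

Splitting the condition by the criterion (504 honest respondents, 660
cheaters) locates the cause:

```r
split <- criterion_split(honest = response_counts(375, 129),
                         cheaters = response_counts(360, 300))
validity_rates(split, d, condition = "CWM_brief")
#> Validity rates [CWM_brief]:
#>   false positives: 14.32% (SE 2.84%), honest n = 504
#>   false negatives: 56.65% (SE 2.83%), cheater n = 660
#>   sensitivity 43.35%, specificity 85.68%
```

14.32% of known non-cheaters are measured as cheaters, but 56.65% of
cheaters go undetected; the deflating false negatives dominate, and the
mixture identity recomposes the aggregate estimate exactly:

```r
implied_aggregate(split$known_prevalence, fp_rate = 0.1432, fn_rate = 0.5665)
#> [1] 0.3078
```

## Analysis workflow

The `analysis/` directory contains numbered drivers over the package, each
writing its tables under `results/`:

| script | what it does |
|---|---|
| `01_reproduce_printed.R` | rebuilds a published validation study's estimates, SEs, restriction tests and validity matrix from its printed numbers via `counts_from_printed()` |
| `02_simulated_study.R` | full pipeline (`validate_respondents()` → `run_study()` → `write_report()`) on one synthetic cohort at the study's conditions |
| `03_recovery.R` | 200-replicate parameter-recovery experiment: bias and SE calibration |
| `04_design.R` | allocation-ratio and power curves for planning CWM studies |

Run any of them from the repository root, e.g.
`Rscript analysis/01_reproduce_printed.R`.

The methods vignette (`vignettes/crosswise-methods.Rmd`) documents the
measurement model, the EM acceleration, the G² machinery, the validation
logic and the simulator's scope and limitations.

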