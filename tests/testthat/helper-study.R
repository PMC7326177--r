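# Published quantities of the reference validation study, used as fixtures.
# All rates as proportions; subsample sizes reconstructed as
# round(n * criterion prevalence), half away from zero.

p_study <- 0.158

printed <- list(
  pi    = c(DQ = 0.1179, CWM_brief = 0.3078, CWM_detailed = 0.2548),
  pi_se = c(DQ = 0.0134, CWM_brief = 0.0207, CWM_detailed = 0.0221),
  n     = c(DQ = 577, CWM_brief = 1164, CWM_detailed = 972),
  known = c(DQ = 0.5893, CWM_brief = 0.5670, CWM_detailed = 0.5926),
  fp    = c(DQ = 0.0253, CWM_brief = 0.1432, CWM_detailed = 0.1308),
  fp_se = c(DQ = 0.0102, CWM_brief = 0.0284, CWM_detailed = 0.0317),
  fn    = c(DQ = 0.8177, CWM_brief = 0.5665, CWM_detailed = 0.6599),
  fn_se = c(DQ = 0.0209, CWM_brief = 0.0283, CWM_detailed = 0.0297)
)

half_up <- function(x) floor(x + 0.5)
printed$cheater_n <- half_up(printed$n * printed$known)        # 340 660 576
printed$honest_n  <- half_up(printed$n * (1 - printed$known))  # 237 504 396

study_design <- function(cond) {
  if (cond == "DQ") dq_design() else cwm_design(p_study)
}

# Reconstructed criterion split for one condition: subsample answer counts
# rebuilt from the published false-positive/false-negative rates.
printed_split <- function(cond) {
  d <- study_design(cond)
  criterion_split(
    honest   = counts_from_printed(printed$fp[[cond]],
                                   printed$honest_n[[cond]], d),
    cheaters = counts_from_printed(1 - printed$fn[[cond]],
                                   printed$cheater_n[[cond]], d)
  )
}

# Independent likelihood oracle: written from the tree definition, not via
# the package's estimation path. Vectorized over pi.
oracle_loglik <- function(n_a, n_b, pi, p = NA, dq = FALSE) {
  lam <- if (dq) pi else pi * p + (1 - pi) * (1 - p)
  term <- function(k, pr) {
    out <- numeric(length(pr))
    if (k == 0) return(out)
    out[pr > 0] <- k * log(pr[pr > 0])
    out[pr <= 0] <- -Inf
    out
  }
  term(n_a, lam) + term(n_b, 1 - lam)
}

# Brute-force grid maximizer of a joint likelihood over tied trees.
# trees: list of list(n_a, n_b, p, dq)
grid_oracle <- function(trees, step = 1e-6) {
  pis <- seq(0, 1, by = step)
  joint <- 0
  for (tr in trees)
    joint <- joint + oracle_loglik(tr$n_a, tr$n_b, pis,
                                   p = tr$p, dq = isTRUE(tr$dq))
  pis[which.max(joint)]
}

# Expand a criterion split into respondent-level records for pipeline tests.
records_from_split <- function(cond, split) {
  mk <- function(counts, cheat) {
    if (counts$n == 0) return(NULL)
    data.frame(
      condition = cond,
      claimed_all_three = cheat,
      answer = rep(c("A", "B"), c(counts$n_a, counts$n_b)),
      stringsAsFactors = FALSE
    )
  }
  out <- rbind(mk(split$honest, FALSE), mk(split$cheaters, TRUE))
  out$id <- paste0(cond, "_", seq_len(nrow(out)))
  out
}
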