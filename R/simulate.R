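#' Parameters for a synthetic anagram-paradigm cohort
#'
#' Defines a simulated validation study. Each respondent has a latent
#' criterion status (cheater on the anagram task or honest), an independent
#' Bernoulli randomization attribute (birth in November/December, default
#' p = 0.158), and an *effective report* of the sensitive statement obtained
#' by flipping the latent status with probability `fn_prob` (carriers) or
#' `fp_prob` (non-carriers). The answer category is then the deterministic
#' CWM/DQ mapping of (effective report, randomizer). The flip layer is a
#' deliberate stand-in for whatever cognitive process (careless responding,
#' miscomprehension, self-protection) produces misclassification; it makes
#' the mixture identity of [implied_aggregate()] exact by construction.
#'
#' Defaults reproduce the reference study's conditions: three conditions
#' (DQ, CWM with brief instructions, CWM with detailed instructions and
#' comprehension checks) with n = 577 / 1164 / 972, the observed criterion
#' prevalences, and the observed false-positive/false-negative rates per
#' condition; a 50/50 education mix; and a comprehension-outcome model with
#' 12.45% first-attempt and 56.38% eventual passes.
#'
#' @param conditions condition labels.
#' @param n respondents per condition (recycled).
#' @param prevalence true cheater prevalence per condition (recycled).
#' @param p randomization probability for CWM conditions.
#' @param fp_prob probability a non-carrier's report flips to "carrier"
#'   (recycled per condition).
#' @param fn_prob probability a carrier's report flips to "non-carrier".
#' @param education_mix proportion of higher-educated respondents.
#' @param fp_prob_high,fp_prob_low,fn_prob_high,fn_prob_low optional
#'   education-moderated flip rates (recycled per condition); when supplied
#'   they override `fp_prob`/`fn_prob` within the education group.
#' @param rating_probs 4x7 matrix of category probabilities for the four
#'   evaluation ratings (rows: randomness, comprehensibility,
#'   confidentiality, clarity; the randomness item is reverse-coded so 7 =
#'   "strongly disagree that I just ticked anything"). The default puts
#'   80.9% of respondents at the extreme randomness level.
#' @param comprehension_probs probabilities of first-attempt / eventual /
#'   failed comprehension-check passage (CWM detailed condition only).
#' @param seed integer seed; a fixed seed makes the cohort bit-identical.
#' @return An object of class `simulation_params`.
#' @examples
#' simulation_params()                       # the reference study design
#' simulation_params(conditions = "CWM_brief", n = 1164,
#'                   prevalence = 0.5670, fp_prob = 0, fn_prob = 0)
#' @export
simulation_params <- function(conditions = c("DQ", "CWM_brief",
                                             "CWM_detailed"),
                              n = c(577, 1164, 972),
                              prevalence = c(0.5893, 0.5670, 0.5926),
                              p = 0.158,
                              fp_prob = c(0.0253, 0.1432, 0.1308),
                              fn_prob = c(0.8177, 0.5665, 0.6599),
                              education_mix = 0.5,
                              fp_prob_high = NULL, fp_prob_low = NULL,
                              fn_prob_high = NULL, fn_prob_low = NULL,
                              rating_probs = NULL,
                              comprehension_probs = c(first_attempt = 0.1245,
                                                      eventual = 0.5638,
                                                      fail = 0.3117),
                              seed = 1L) {
  k <- length(conditions)
  if (!k || anyDuplicated(conditions))
    stop("'conditions' must be non-empty and unique")
  rec <- function(x, what) {
    if (is.null(x)) return(NULL)
    if (length(x) == 1L) x <- rep(x, k)
    if (length(x) != k)
      stop("'", what, "' must have length 1 or ", k)
    x
  }
  n <- rec(n, "n"); prevalence <- rec(prevalence, "prevalence")
  fp_prob <- rec(fp_prob, "fp_prob"); fn_prob <- rec(fn_prob, "fn_prob")
  fp_prob_high <- rec(fp_prob_high, "fp_prob_high")
  fp_prob_low <- rec(fp_prob_low, "fp_prob_low")
  fn_prob_high <- rec(fn_prob_high, "fn_prob_high")
  fn_prob_low <- rec(fn_prob_low, "fn_prob_low")
  probs <- c(prevalence, fp_prob, fn_prob, education_mix, p,
             fp_prob_high, fp_prob_low, fn_prob_high, fn_prob_low,
             comprehension_probs)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1))
    stop("all probabilities must lie in [0, 1]")
  if (any(n < 0) || any(n != round(n))) stop("'n' must be whole and >= 0")
  if (abs(sum(comprehension_probs) - 1) > 1e-8)
    stop("'comprehension_probs' must sum to 1")
  if (is.null(rating_probs)) {
    rating_probs <- rbind(
      randomness       = c(0.010, 0.010, 0.020, 0.032, 0.049, 0.070, 0.809),
      comprehensibility = c(0.02, 0.03, 0.05, 0.10, 0.15, 0.25, 0.40),
      confidentiality  = c(0.02, 0.03, 0.05, 0.10, 0.15, 0.25, 0.40),
      clarity          = c(0.02, 0.03, 0.05, 0.10, 0.15, 0.25, 0.40))
  }
  rating_probs <- as.matrix(rating_probs)
  if (!all(dim(rating_probs) == c(4L, 7L)) ||
      any(abs(rowSums(rating_probs) - 1) > 1e-8) || any(rating_probs < 0))
    stop("'rating_probs' must be a 4x7 matrix of rows summing to 1")
  structure(list(conditions = as.character(conditions), n = n,
                 prevalence = prevalence, p = p,
                 fp_prob = fp_prob, fn_prob = fn_prob,
                 education_mix = education_mix,
                 fp_prob_high = fp_prob_high, fp_prob_low = fp_prob_low,
                 fn_prob_high = fn_prob_high, fn_prob_low = fn_prob_low,
                 rating_probs = rating_probs,
                 comprehension_probs = comprehension_probs,
                 seed = as.integer(seed)),
            class = "simulation_params")
}

#' Simulate a respondent cohort
#'
#' Draws one cohort under [simulation_params()]. Per respondent:
#' `latent_cheater ~ Bernoulli(prevalence)`; `born_nov_dec ~ Bernoulli(p)`
#' independent of everything else; `claimed_all_three = latent_cheater` (the
#' criterion is the cheating claim itself); `effective_report` is the latent
#' status flipped with the applicable `fn`/`fp` probability; the answer is
#' `"A"` iff the effective report and the randomizer match (CWM) or iff the
#' effective report is true (DQ). Evaluation ratings and (in the detailed
#' condition) comprehension outcomes are drawn independently of the
#' misreporting layer. The whole cohort is reproducible from `seed`; the
#' conditions are generated in order from one stream seeded once.
#'
#' @param params a [simulation_params()].
#' @param seed overrides `params$seed` (used by replicate loops).
#' @return A data frame with one row per respondent: `id`, `condition`,
#'   `education`, `latent_cheater`, `claimed_all_three`, `born_nov_dec`,
#'   `effective_report`, `answer`, the four `rating_*` columns and
#'   `comprehension`.
#' @examples
#' head(simulate_cohort(simulation_params(seed = 7)))
#' @export
simulate_cohort <- function(params, seed = params$seed) {
  stopifnot(inherits(params, "simulation_params"))
  set.seed(seed)
  out <- vector("list", length(params$conditions))
  for (i in seq_along(params$conditions)) {
    cond <- params$conditions[i]
    n <- params$n[i]
    if (n == 0) next
    is_cwm <- cond != "DQ"
    education <- ifelse(stats::rbinom(n, 1, params$education_mix) == 1,
                        "high", "low")
    latent <- stats::rbinom(n, 1, params$prevalence[i]) == 1
    born <- stats::rbinom(n, 1, params$p) == 1
    fp <- rep(params$fp_prob[i], n)
    fn <- rep(params$fn_prob[i], n)
    if (!is.null(params$fp_prob_high)) fp[education == "high"] <- params$fp_prob_high[i]
    if (!is.null(params$fp_prob_low))  fp[education == "low"]  <- params$fp_prob_low[i]
    if (!is.null(params$fn_prob_high)) fn[education == "high"] <- params$fn_prob_high[i]
    if (!is.null(params$fn_prob_low))  fn[education == "low"]  <- params$fn_prob_low[i]
    flip <- stats::runif(n) < ifelse(latent, fn, fp)
    effective <- xor(latent, flip)
    answer <- if (is_cwm) ifelse(effective == born, "A", "B")
              else ifelse(effective, "A", "B")
    ratings <- apply(params$rating_probs, 1, function(pr)
      sample.int(7L, n, replace = TRUE, prob = pr))
    if (n == 1L) ratings <- matrix(ratings, nrow = 1)
    comprehension <- if (cond == "CWM_detailed") {
      sample(names(params$comprehension_probs), n, replace = TRUE,
             prob = params$comprehension_probs)
    } else rep("not_applicable", n)
    out[[i]] <- data.frame(
      id = paste0(cond, "_", seq_len(n)),
      condition = cond,
      education = education,
      latent_cheater = latent,
      claimed_all_three = latent,
      born_nov_dec = born,
      effective_report = effective,
      answer = answer,
      rating_random = ratings[, 1],
      rating_comprehensible = ratings[, 2],
      rating_confidential = ratings[, 3],
      rating_clear = ratings[, 4],
      comprehension = comprehension,
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Parameter-recovery experiment
#'
#' Replicates the full simulate-then-analyze cycle: each replicate draws a
#' cohort, estimates the per-condition prevalence (ML), splits by the
#' criterion and estimates the false-positive and false-negative rates.
#' Summaries compare the Monte Carlo means to the generating truth and the
#' empirical spread of the estimates to the mean analytic (delta-method)
#' standard error.
#'
#' @param params a [simulation_params()].
#' @param replicates number of replicates (>= 1).
#' @return An object of class `recovery_summary`: a data frame `summary`
#'   with one row per condition (`truth_*`, `mean_*`, `emp_sd_*`,
#'   `mean_se_*` for pi, fp, fn) and the replicate-level `draws`.
#' @examples
#' \donttest{
#' recovery_experiment(simulation_params(conditions = "CWM_brief",
#'   n = 1164, prevalence = 0.567, fp_prob = 0.1432, fn_prob = 0.5665),
#'   replicates = 50)
#' }
#' @export
recovery_experiment <- function(params, replicates) {
  stopifnot(inherits(params, "simulation_params"), replicates >= 1)
  k <- length(params$conditions)
  draws <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    cohort <- simulate_cohort(params, seed = params$seed + r)
    rows <- lapply(seq_len(k), function(i) {
      cond <- params$conditions[i]
      design <- if (cond == "DQ") dq_design() else cwm_design(params$p)
      sub <- cohort[cohort$condition == cond, , drop = FALSE]
      est <- cwm_estimate(
        response_counts(sum(sub$answer == "A"), sum(sub$answer == "B")),
        design)
      split <- split_by_criterion(cohort, cond)
      vr <- validity_rates(split, design, condition = cond)
      data.frame(replicate = r, condition = cond,
                 pi_hat = est$pi_hat, pi_se = est$se,
                 fp_hat = vr$fp_rate, fp_se = vr$fp_se,
                 fn_hat = vr$fn_rate, fn_se = vr$fn_se,
                 stringsAsFactors = FALSE)
    })
    draws[[r]] <- do.call(rbind, rows)
  }
  draws <- do.call(rbind, c(draws, list(make.row.names = FALSE)))
  summ <- do.call(rbind, lapply(seq_len(k), function(i) {
    d <- draws[draws$condition == params$conditions[i], , drop = FALSE]
    data.frame(
      condition = params$conditions[i],
      truth_pi = implied_aggregate(params$prevalence[i],
                                   params$fp_prob[i], params$fn_prob[i]),
      mean_pi = mean(d$pi_hat), emp_sd_pi = stats::sd(d$pi_hat),
      mean_se_pi = mean(d$pi_se),
      truth_fp = params$fp_prob[i],
      mean_fp = mean(d$fp_hat), emp_sd_fp = stats::sd(d$fp_hat),
      mean_se_fp = mean(d$fp_se),
      truth_fn = params$fn_prob[i],
      mean_fn = mean(d$fn_hat), emp_sd_fn = stats::sd(d$fn_hat),
      mean_se_fn = mean(d$fn_se),
      stringsAsFactors = FALSE)
  }))
  structure(list(summary = summ, draws = draws, replicates = replicates,
                 params = params),
            class = "recovery_summary")
}

#' @export
print.recovery_summary <- function(x, ...) {
  cat(sprintf("Parameter recovery over %d replicates:\n", x$replicates))
  print(x$summary, digits = 4, row.names = FALSE)
  invisible(x)
}
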