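test_that("criterion splitting partitions records by the cheating claim", {
  rec <- data.frame(
    id = 1:10, condition = "DQ",
    claimed_all_three = rep(c(TRUE, FALSE), c(4, 6)),
    answer = c("A", "A", "B", "B", "A", "B", "B", "B", "B", "B"))
  s <- split_by_criterion(rec, "DQ")
  expect_equal(s$cheaters$n, 4)
  expect_equal(s$honest$n, 6)
  expect_equal(s$cheaters$n_a, 2)
  expect_equal(s$honest$n_a, 1)
  expect_equal(s$known_prevalence, 0.4)

  # on simulated data the partition matches the generator's ground truth
  cohort <- simulate_cohort(simulation_params(seed = 11))
  for (cond in c("DQ", "CWM_brief")) {
    s <- split_by_criterion(cohort, cond)
    truth <- cohort$latent_cheater[cohort$condition == cond]
    expect_equal(s$cheaters$n, sum(truth))
    expect_equal(s$honest$n, sum(!truth))
  }

  # reconstructed DQ split sizes
  expect_equal(printed$cheater_n[["DQ"]], 340)
  expect_equal(printed$honest_n[["DQ"]], 237)
})

test_that("FP and FN rates are subsample prevalences (and complements)", {
  q <- dq_design()
  s <- criterion_split(honest = response_counts(6, 231),
                       cheaters = response_counts(62, 278))
  fp <- false_positive_rate(s, q)
  expect_equal(fp$rate, 6 / 237, tolerance = 1e-9)
  expect_equal(round(fp$rate, 4), 0.0253)
  fn <- false_negative_rate(s, q)
  expect_equal(fn$rate, 1 - 62 / 340, tolerance = 1e-9)

  vr <- validity_rates(s, q)
  expect_equal(vr$sensitivity, 1 - vr$fn_rate)
  expect_equal(vr$specificity, 1 - vr$fp_rate)

  # honest respondents all answering the pi = 0 pattern -> zero FP rate
  d <- cwm_design(0.158)
  s0 <- criterion_split(honest = response_counts(842, 158),
                        cheaters = response_counts(100, 100))
  expect_equal(false_positive_rate(s0, d)$rate, 0, tolerance = 1e-6)
  # cheaters all answering as carriers -> zero FN rate
  s1 <- criterion_split(honest = response_counts(50, 50),
                        cheaters = response_counts(100, 0))
  expect_equal(false_negative_rate(s1, dq_design())$rate, 0)

  # empty subsamples refuse with a clear error
  s_empty <- criterion_split(honest = response_counts(0, 0),
                             cheaters = response_counts(10, 5))
  expect_error(false_positive_rate(s_empty, q), "empty honest")
})

test_that("rates stay in [0, 1] even when the moment estimate exits", {
  d <- cwm_design(0.158)
  # honest proportion above the attainable range: moment estimate < 0
  s <- criterion_split(honest = response_counts(99, 1),
                       cheaters = response_counts(30, 170))
  vr <- validity_rates(s, d)
  expect_gte(vr$fp_rate, 0)
  expect_lte(vr$fp_rate, 1)
  expect_gte(vr$fn_rate, 0)
  expect_lte(vr$fn_rate, 1)
})

test_that("the mixture identity recomposes aggregate estimates", {
  expect_equal(implied_aggregate(0.5670, 0.1432, 0.5665), 0.3078,
               tolerance = 1e-4)
  expect_equal(implied_aggregate(0.5893, 0.0253, 0.8177), 0.1179,
               tolerance = 1e-3)
  expect_equal(implied_aggregate(0.44, 0, 0), 0.44)

  # partition identity, exact: when the subsample counts partition the
  # condition counts and both subsample estimates are interior, the pooled
  # estimate equals the mixture of the subsample estimates
  d <- cwm_design(0.158)
  s <- printed_split("CWM_brief")
  pooled <- response_counts(s$honest$n_a + s$cheaters$n_a,
                            s$honest$n_b + s$cheaters$n_b)
  vr <- validity_rates(s, d)
  expect_false(vr$fp_rate %in% c(0, 1) || vr$fn_rate %in% c(0, 1))
  expect_equal(
    cwm_estimate(pooled, d)$pi_hat,
    implied_aggregate(s$known_prevalence, vr$fp_rate, vr$fn_rate),
    tolerance = 1e-9)
})

test_that("between-group rate comparisons behave and match printed deltas", {
  d <- cwm_design(0.158)
  s <- printed_split("CWM_brief")
  # identical groups: no difference, dG2 = 0, p = 1
  rt0 <- compare_rates(s, s, "fp", d)
  expect_equal(rt0$delta_rate, 0, tolerance = 1e-8)
  expect_equal(rt0$delta_g2, 0, tolerance = 1e-6)
  expect_equal(rt0$p_value, 1, tolerance = 1e-6)

  # education effect in the detailed condition: the printed subgroup FP
  # rates differ by the printed delta
  expect_equal(0.2294 - 0.0478, 0.1816, tolerance = 1e-12)
  # reconstruct subgroup splits at plausible subgroup sizes and check the
  # comparison machinery recovers the rate difference of its inputs
  lo <- criterion_split(counts_from_printed(0.2294, 198, d),
                        counts_from_printed(1 - 0.679, 288, d))
  hi <- criterion_split(counts_from_printed(0.0478, 198, d),
                        counts_from_printed(1 - 0.640, 288, d))
  # count reconstruction at n = 198 has granularity 1/(198 |2p-1|) ~ 0.0074
  rt <- compare_rates(lo, hi, "fp", d, labels = c("low", "high"))
  expect_equal(rt$delta_rate, 0.1816, tolerance = 0.05)
  expect_equal(rt$df, 1L)

  # FN comparisons flip the sign relative to the subsample prevalences
  rtfn <- compare_rates(lo, hi, "fn", d, labels = c("low", "high"))
  expect_equal(unname(rtfn$rates["low"] - rtfn$rates["high"]),
               rtfn$delta_rate)
})

test_that("equal true rates reject at about the nominal level", {
  set.seed(4711)
  d <- cwm_design(0.158)
  alpha <- 0.05
  reps <- 400
  n <- 300
  lam <- lambda_from_pi(0.15, d)
  rejections <- 0
  for (i in seq_len(reps)) {
    a1 <- rbinom(1, n, lam); b1 <- rbinom(1, n, lam)
    sa <- criterion_split(response_counts(a1, n - a1),
                          response_counts(10, 10))
    sb <- criterion_split(response_counts(b1, n - b1),
                          response_counts(10, 10))
    rt <- compare_rates(sa, sb, "fp", d)
    if (rt$p_value < alpha) rejections <- rejections + 1
  }
  rate <- rejections / reps
  # 3 sigma band around alpha at 400 replicates
  band <- 3 * sqrt(alpha * (1 - alpha) / reps)
  expect_gt(rate, alpha - band)
  expect_lt(rate, alpha + band)
})

test_that("moderator splits follow their rules", {
  rec <- data.frame(id = 1:12,
                    education = rep(c("high", "low"), 6),
                    rating_random = c(7, 7, 7, 7, 7, 7, 7, 7, 7, 6, 3, 1),
                    rating_clear = c(1, 2, 3, 4, 5, 6, 7, 1, 2, 3, 4, 5))
  ed <- moderator_split(rec, "education", "binary")
  expect_named(ed, c("high", "low"))
  expect_equal(nrow(ed$high), 6)

  rr <- moderator_split(rec, "rating_random", "strongly_disagree")
  expect_named(rr, c("non_random", "random"))
  expect_equal(nrow(rr$non_random), 9)   # rating 7 after reverse-coding
  expect_equal(nrow(rr$random), 3)

  md <- moderator_split(rec, "rating_clear", "median")
  expect_named(md, c("low", "high"))
  # median 3.5; ties to the lower side
  expect_equal(nrow(md$low), sum(rec$rating_clear <= 3.5))
  expect_equal(nrow(md$low) + nrow(md$high), 12)

  const <- data.frame(id = 1:4, x = rep(2, 4))
  expect_warning(out <- moderator_split(const, "x", "median"), "degenerate")
  expect_true(isTRUE(attr(out, "degenerate")))

  expect_error(moderator_split(rec, "nope", "binary"), "not found")
})

test_that("the default simulator puts the documented share at the extreme", {
  cohort <- simulate_cohort(simulation_params(seed = 5))
  share <- mean(cohort$rating_random == 7)
  # 0.809 with binomial MC error at n = 2713
  expect_equal(share, 0.809, tolerance = 3 * sqrt(0.809 * 0.191 / nrow(cohort)) / 0.809)
  rr <- moderator_split(cohort, "rating_random", "strongly_disagree")
  expect_equal(nrow(rr$non_random), sum(cohort$rating_random == 7))
})
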