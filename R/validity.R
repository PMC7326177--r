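#' Split a condition's respondents by the validation criterion
#'
#' Individual-level validation hinges on a criterion with known ground
#' truth: respondents who claimed to have solved all three anagrams are
#' categorized as cheaters (carriers of the sensitive attribute), the rest
#' as honest. `split_by_criterion()` partitions one condition's respondent
#' records accordingly and tallies the answer categories within each part;
#' `criterion_split()` builds the same object directly from counts (used for
#' worked examples reconstructed from published numbers).
#'
#' @param records a respondent data frame with at least `condition`,
#'   `claimed_all_three` (logical criterion) and `answer` (`"A"`/`"B"`).
#' @param condition the condition label to extract.
#' @return An object of class `criterion_split`: `honest` and `cheaters`
#'   ([response_counts()]), `n`, and `known_prevalence` (the criterion
#'   proportion of cheaters).
#' @examples
#' # DQ condition reconstructed from published numbers:
#' criterion_split(honest = response_counts(6, 231),
#'                 cheaters = response_counts(62, 278))
#' @export
split_by_criterion <- function(records, condition) {
  stopifnot(is.data.frame(records))
  need <- c("condition", "claimed_all_three", "answer")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("records lack column(s): ", paste(miss, collapse = ", "))
  sub <- records[records$condition == condition, , drop = FALSE]
  if (!nrow(sub)) stop("no records in condition '", condition, "'")
  tally <- function(part)
    response_counts(sum(part$answer == "A"), sum(part$answer == "B"))
  cheat <- as.logical(sub$claimed_all_three)
  criterion_split(honest = tally(sub[!cheat, , drop = FALSE]),
                  cheaters = tally(sub[cheat, , drop = FALSE]))
}

#' @rdname split_by_criterion
#' @param honest,cheaters [response_counts()] for the two criterion groups.
#' @export
criterion_split <- function(honest, cheaters) {
  stopifnot(inherits(honest, "response_counts"),
            inherits(cheaters, "response_counts"))
  n <- honest$n + cheaters$n
  if (n == 0) stop("criterion split over zero respondents")
  structure(list(honest = honest, cheaters = cheaters, n = n,
                 known_prevalence = cheaters$n / n),
            class = "criterion_split")
}

#' @export
print.criterion_split <- function(x, ...) {
  cat(sprintf(
    "Criterion split: %d honest, %d cheaters (known prevalence %.4f)\n",
    as.integer(x$honest$n), as.integer(x$cheaters$n), x$known_prevalence))
  invisible(x)
}

#' False-positive and false-negative rates on a criterion split
#'
#' The false-positive rate is the estimated prevalence of the sensitive
#' attribute *within the honest subsample* (people known not to carry it who
#' are nonetheless measured as carriers); the false-negative rate is one
#' minus the estimated prevalence *within the cheater subsample* (known
#' carriers measured as non-carriers). Both are maximum-likelihood estimates
#' on the relevant subsample's own tree, so they respect `[0, 1]`, with
#' delta-method standard errors at the subsample size. Specificity and
#' sensitivity are their complements.
#'
#' @param split a [split_by_criterion()] / [criterion_split()] result with a
#'   non-empty relevant subsample.
#' @param design the [cwm_design()] of the condition.
#' @param condition,subgroup optional labels carried into the result.
#' @return `false_positive_rate()` and `false_negative_rate()` return a list
#'   with `rate`, `se`, `n` and the underlying `prevalence_estimate`;
#'   `validity_rates()` returns an object of class `validity_rates` with
#'   both rates plus `sensitivity` and `specificity`.
#' @examples
#' s <- criterion_split(response_counts(6, 231), response_counts(62, 278))
#' validity_rates(s, dq_design())
#' @export
false_positive_rate <- function(split, design) {
  stopifnot(inherits(split, "criterion_split"))
  if (split$honest$n == 0)
    stop("empty honest subsample: false-positive rate undefined")
  est <- cwm_estimate(split$honest, design, "ml")
  list(rate = est$pi_hat, se = est$se, n = est$n, estimate = est)
}

#' @rdname false_positive_rate
#' @export
false_negative_rate <- function(split, design) {
  stopifnot(inherits(split, "criterion_split"))
  if (split$cheaters$n == 0)
    stop("empty cheater subsample: false-negative rate undefined")
  est <- cwm_estimate(split$cheaters, design, "ml")
  list(rate = 1 - est$pi_hat, se = est$se, n = est$n, estimate = est)
}

#' @rdname false_positive_rate
#' @export
validity_rates <- function(split, design, condition = NA_character_,
                           subgroup = NA_character_) {
  fp <- false_positive_rate(split, design)
  fn <- false_negative_rate(split, design)
  structure(list(fp_rate = fp$rate, fp_se = fp$se, fp_n = fp$n,
                 fn_rate = fn$rate, fn_se = fn$se, fn_n = fn$n,
                 sensitivity = 1 - fn$rate, specificity = 1 - fp$rate,
                 known_prevalence = split$known_prevalence,
                 condition = condition, subgroup = subgroup),
            class = "validity_rates")
}

#' @export
print.validity_rates <- function(x, ...) {
  lab <- if (!is.na(x$condition)) paste0(" [", x$condition,
    if (!is.na(x$subgroup)) paste0(" / ", x$subgroup), "]") else ""
  cat(sprintf("Validity rates%s:\n", lab))
  cat(sprintf("  false positives: %5.2f%% (SE %.2f%%), honest n = %d\n",
              100 * x$fp_rate, 100 * x$fp_se, as.integer(x$fp_n)))
  cat(sprintf("  false negatives: %5.2f%% (SE %.2f%%), cheater n = %d\n",
              100 * x$fn_rate, 100 * x$fn_se, as.integer(x$fn_n)))
  cat(sprintf("  sensitivity %.2f%%, specificity %.2f%%\n",
              100 * x$sensitivity, 100 * x$specificity))
  invisible(x)
}

#' Aggregate prevalence implied by misclassification rates
#'
#' Mixture identity linking the subsample rates to the whole-condition
#' estimate: carriers are measured as carriers with probability
#' `1 - fn_rate` and non-carriers with probability `fp_rate`, so
#' \deqn{\pi_{implied} = known (1 - fn) + (1 - known)\, fp.}
#' When the subsample counts partition the condition's counts exactly, this
#' equals the whole-condition estimate; on published (rounded) rates it
#' recomposes the published estimate to rounding accuracy.
#'
#' @param known_prevalence criterion prevalence of carriers, in `[0, 1]`.
#' @param fp_rate,fn_rate misclassification rates, in `[0, 1]`.
#' @return The implied aggregate prevalence.
#' @examples
#' implied_aggregate(0.5670, fp_rate = 0.1432, fn_rate = 0.5665)  # 0.3078
#' @export
implied_aggregate <- function(known_prevalence, fp_rate, fn_rate) {
  stopifnot(known_prevalence >= 0, known_prevalence <= 1,
            fp_rate >= 0, fp_rate <= 1, fn_rate >= 0, fn_rate <= 1)
  known_prevalence * (1 - fn_rate) + (1 - known_prevalence) * fp_rate
}

#' Compare a misclassification rate between two groups
#'
#' Builds the relevant subsample trees (honest subsamples for the
#' false-positive rate, cheater subsamples for the false-negative rate) for
#' two groups — e.g. education levels within a condition, or two conditions
#' — and tests their equality with [test_restriction()]. The reported
#' `delta_rate` is on the rate scale (for false negatives the sign of the
#' prevalence difference is flipped accordingly).
#'
#' @param split_a,split_b [criterion_split()]s for the two groups.
#' @param which `"fp"` or `"fn"`.
#' @param design_a the [cwm_design()] of group A.
#' @param design_b the design of group B (defaults to `design_a`).
#' @param labels length-2 character vector naming the groups.
#' @return A `restriction_test` (see [test_restriction()]) with an added
#'   `delta_rate` element and `rates` (the two group rates).
#' @export
compare_rates <- function(split_a, split_b, which = c("fp", "fn"),
                          design_a, design_b = design_a,
                          labels = c("group_a", "group_b")) {
  which <- match.arg(which)
  stopifnot(inherits(split_a, "criterion_split"),
            inherits(split_b, "criterion_split"))
  pick <- if (which == "fp") "honest" else "cheaters"
  ca <- split_a[[pick]]
  cb <- split_b[[pick]]
  if (ca$n == 0 || cb$n == 0)
    stop("empty ", pick, " subsample in one of the groups")
  ts <- tree_set(mpt_tree(labels[1], ca, design_a),
                 mpt_tree(labels[2], cb, design_b))
  out <- test_restriction(ts, eq_restriction(labels))
  pis <- out$unrestricted_fit$estimates$pi_hat
  rates <- if (which == "fp") pis else 1 - pis
  out$rates <- stats::setNames(rates, labels)
  out$delta_rate <- rates[1] - rates[2]
  out$which <- which
  out
}

#' Split respondents on a moderator variable
#'
#' Dichotomizes a respondent table on a moderator field, the way binary-tree
#' multinomial modeling requires (continuous moderators cannot enter the
#' trees directly).
#'
#' Rules: `"binary"` splits by the two coded levels of the field;
#' `"strongly_disagree"` splits a reverse-coded 1-7 rating at the extreme
#' level 7 (original "strongly disagree" with the random-responding
#' statement, i.e. self-declared non-random responders) versus all else;
#' `"median"` splits at the sample median with ties going to the lower side.
#'
#' @param records a respondent data frame.
#' @param moderator name of the moderator column.
#' @param rule `"binary"`, `"strongly_disagree"` or `"median"`.
#' @return A named list of two data frames. Names are the two levels for
#'   `"binary"`, `c("non_random", "random")` for `"strongly_disagree"`, and
#'   `c("low", "high")` for `"median"`. A degenerate median split (constant
#'   moderator) carries attribute `degenerate = TRUE` and a warning.
#' @export
moderator_split <- function(records, moderator,
                            rule = c("binary", "strongly_disagree",
                                     "median")) {
  rule <- match.arg(rule)
  stopifnot(is.data.frame(records))
  if (!moderator %in% names(records))
    stop("moderator column '", moderator, "' not found")
  x <- records[[moderator]]
  if (rule == "binary") {
    lev <- sort(unique(as.character(x)))
    if (length(lev) != 2L)
      stop("'binary' rule needs exactly two coded levels, got ",
           length(lev))
    out <- list(records[x == lev[1], , drop = FALSE],
                records[x == lev[2], , drop = FALSE])
    names(out) <- lev
    return(out)
  }
  if (rule == "strongly_disagree") {
    if (!is.numeric(x) || any(x < 1 | x > 7, na.rm = TRUE))
      stop("'strongly_disagree' rule expects a 1-7 rating")
    return(list(non_random = records[x == 7, , drop = FALSE],
                random = records[x != 7, , drop = FALSE]))
  }
  # median split, ties to the lower side
  med <- stats::median(x, na.rm = TRUE)
  out <- list(low = records[x <= med, , drop = FALSE],
              high = records[x > med, , drop = FALSE])
  if (nrow(out$high) == 0L) {
    warning("degenerate median split: moderator '", moderator,
            "' has no values above its median")
    attr(out, "degenerate") <- TRUE
  }
  out
}
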