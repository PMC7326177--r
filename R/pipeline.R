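#' Study configuration
#'
#' Bundles the analysis settings: the randomization probability, the
#' condition labels (any label other than `"DQ"` is treated as a
#' crosswise-model condition), the criterion field, the moderator
#' definitions, and the test level.
#'
#' @param p randomization probability for CWM conditions.
#' @param conditions condition labels expected in the data.
#' @param criterion_field name of the logical criterion column.
#' @param moderators named list; each element a `list(field =, rule =)`
#'   accepted by [moderator_split()].
#' @param alpha nominal test level, in (0, 1).
#' @return An object of class `study_config`.
#' @examples
#' study_config()
#' @export
study_config <- function(p = 0.158,
                         conditions = c("DQ", "CWM_brief", "CWM_detailed"),
                         criterion_field = "claimed_all_three",
                         moderators = list(
                           education = list(field = "education",
                                            rule = "binary"),
                           randomness = list(field = "rating_random",
                                             rule = "strongly_disagree")),
                         alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must lie in (0, 1)")
  # validate p through the design constructor
  if (any(conditions != "DQ")) cwm_design(p)
  structure(list(p = p, conditions = as.character(conditions),
                 criterion_field = criterion_field,
                 moderators = moderators, alpha = alpha),
            class = "study_config")
}

design_for <- function(condition, config) {
  if (condition == "DQ") dq_design() else cwm_design(config$p)
}

#' Read and validate a respondent-level CSV file
#'
#' Reads a respondent table (UTF-8, header required) and validates it
#' against the study schema. Required columns: `id`, `condition`, `answer`,
#' and the criterion column. `answer` accepts `A`/`B` or `true`/`false`
#' (mapped to `A`/`B`); anything else, or an unknown condition label, is a
#' hard error naming the offending row. Rows with a missing required field
#' are excluded listwise with a message giving the count.
#'
#' @param path path to the CSV file.
#' @param config a [study_config()].
#' @return A validated data frame; the number of excluded rows is attached
#'   as attribute `n_excluded`.
#' @export
read_respondents <- function(path, config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  records <- utils::read.csv(path, stringsAsFactors = FALSE,
                             fileEncoding = "UTF-8")
  validate_respondents(records, config)
}

#' @rdname read_respondents
#' @param records a data frame already in memory (e.g. from
#'   [simulate_cohort()]).
#' @export
validate_respondents <- function(records, config = study_config()) {
  required <- c("id", "condition", "answer", config$criterion_field)
  miss <- setdiff(required, names(records))
  if (length(miss))
    stop("input lacks required column(s): ", paste(miss, collapse = ", "))
  blank <- function(x) is.na(x) | (is.character(x) & trimws(x) == "")
  incomplete <- Reduce(`|`, lapply(records[required], blank))
  n_excluded <- sum(incomplete)
  if (n_excluded > 0) {
    message(n_excluded, " respondent(s) excluded listwise due to ",
            "incomplete data")
    records <- records[!incomplete, , drop = FALSE]
  }
  bad_cond <- !records$condition %in% config$conditions
  if (any(bad_cond))
    stop("unknown condition label '",
         records$condition[which(bad_cond)[1]], "' in row ",
         which(bad_cond)[1])
  ans <- tolower(as.character(records$answer))
  map <- c(a = "A", b = "B", "true" = "A", "false" = "B")
  bad_ans <- !ans %in% names(map)
  if (any(bad_ans))
    stop("answer '", records$answer[which(bad_ans)[1]],
         "' outside {A, B, true, false} in row ", which(bad_ans)[1])
  records$answer <- unname(map[ans])
  crit <- records[[config$criterion_field]]
  if (is.character(crit)) crit <- tolower(crit) %in% c("true", "1", "yes")
  records[[config$criterion_field]] <- as.logical(crit)
  rownames(records) <- NULL
  attr(records, "n_excluded") <- n_excluded
  records
}

#' Run the full validation analysis
#'
#' The end-to-end study analysis: per-condition prevalence estimates (ML)
#' with the criterion ("known") prevalence alongside; the restriction tests
#' of the aggregate comparison — every pairwise equality between conditions
#' and every condition against its known prevalence; per-condition validity
#' rates on the criterion split; and, for each configured moderator, the
#' subgroup validity rates and the between-subgroup rate comparisons.
#' A condition listed in the config but absent from the data is skipped
#' with a warning. Deterministic given the input.
#'
#' @param records a validated respondent table ([read_respondents()] /
#'   [validate_respondents()]).
#' @param config a [study_config()].
#' @return An object of class `study_report` with elements `estimates`
#'   (data frame), `tests` (data frame of restriction tests), `validity`
#'   (data frame, one row per condition and per moderator subgroup),
#'   `moderator_tests` (data frame), `diagnostics` (contingency results)
#'   and `config`.
#' @export
run_study <- function(records, config = study_config()) {
  stopifnot(is.data.frame(records), inherits(config, "study_config"))
  if (!identical(config$criterion_field, "claimed_all_three")) {
    records$claimed_all_three <- records[[config$criterion_field]]
  }
  present <- intersect(config$conditions, unique(records$condition))
  absent <- setdiff(config$conditions, present)
  if (length(absent))
    warning("condition(s) absent from the data, skipped: ",
            paste(absent, collapse = ", "))
  if (!length(present)) stop("no configured condition present in the data")

  splits <- lapply(present, function(cond) split_by_criterion(records, cond))
  names(splits) <- present
  trees <- lapply(present, function(cond) {
    sub <- records[records$condition == cond, ]
    mpt_tree(cond,
             response_counts(sum(sub$answer == "A"),
                             sum(sub$answer == "B")),
             design_for(cond, config))
  })
  ts <- tree_set(trees)

  estimates <- do.call(rbind, lapply(present, function(cond) {
    est <- cwm_estimate(ts[[cond]]$counts, design_for(cond, config))
    data.frame(condition = cond, n = est$n, pi_hat = est$pi_hat,
               se = est$se, known_prevalence = splits[[cond]]$known_prevalence,
               at_boundary = est$at_boundary, stringsAsFactors = FALSE)
  }))

  test_row <- function(label, rt)
    data.frame(comparison = label, delta_pi = rt$delta_pi,
               delta_g2 = rt$delta_g2, df = rt$df, p_value = rt$p_value,
               stringsAsFactors = FALSE)
  tests <- list()
  if (length(present) > 1) {
    pairs <- utils::combn(present, 2, simplify = FALSE)
    for (pr in pairs) {
      rt <- test_restriction(ts, eq_restriction(pr))
      tests[[length(tests) + 1L]] <-
        test_row(paste(pr[1], "vs", pr[2]), rt)
    }
  }
  for (cond in present) {
    rt <- test_restriction(ts, fix_restriction(
      cond, splits[[cond]]$known_prevalence))
    tests[[length(tests) + 1L]] <-
      test_row(paste(cond, "vs known prevalence"), rt)
  }
  tests <- do.call(rbind, tests)

  vr_row <- function(vr)
    data.frame(condition = vr$condition, subgroup = vr$subgroup,
               fp_rate = vr$fp_rate, fp_se = vr$fp_se, fp_n = vr$fp_n,
               fn_rate = vr$fn_rate, fn_se = vr$fn_se, fn_n = vr$fn_n,
               sensitivity = vr$sensitivity, specificity = vr$specificity,
               stringsAsFactors = FALSE)
  validity <- do.call(rbind, lapply(present, function(cond)
    vr_row(validity_rates(splits[[cond]], design_for(cond, config),
                          condition = cond, subgroup = "total"))))

  mod_tests <- list()
  for (mod_name in names(config$moderators)) {
    mod <- config$moderators[[mod_name]]
    if (!mod$field %in% names(records)) next
    groups <- moderator_split(records, mod$field, mod$rule)
    for (cond in present) {
      gsplits <- lapply(groups, function(g) {
        if (!sum(g$condition == cond)) return(NULL)
        split_by_criterion(g, cond)
      })
      ok <- !vapply(gsplits, is.null, TRUE)
      for (gname in names(groups)[ok]) {
        vr <- tryCatch(
          validity_rates(gsplits[[gname]], design_for(cond, config),
                         condition = cond,
                         subgroup = paste0(mod_name, ":", gname)),
          error = function(e) NULL)
        if (!is.null(vr)) validity <- rbind(validity, vr_row(vr))
      }
      if (sum(ok) == 2L) {
        gs <- gsplits[ok]
        for (which in c("fp", "fn")) {
          rt <- tryCatch(
            compare_rates(gs[[1]], gs[[2]], which,
                          design_for(cond, config),
                          labels = names(gs)),
            error = function(e) NULL)
          if (is.null(rt)) next
          mod_tests[[length(mod_tests) + 1L]] <- data.frame(
            condition = cond, moderator = mod_name, which = which,
            delta_rate = rt$delta_rate, delta_g2 = rt$delta_g2,
            df = rt$df, p_value = rt$p_value, stringsAsFactors = FALSE)
        }
      }
    }
  }
  mod_tests <- if (length(mod_tests)) do.call(rbind, mod_tests) else NULL

  diag <- NULL
  tab <- table(records$condition, records$claimed_all_three)
  if (all(dim(tab) >= 2))
    diag <- tryCatch(contingency_test(tab), error = function(e) NULL)

  structure(list(estimates = estimates, tests = tests, validity = validity,
                 moderator_tests = mod_tests, diagnostics = diag,
                 config = config),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("== Prevalence estimates (vs known criterion prevalence) ==\n")
  est <- x$estimates
  est$pi_hat <- sprintf("%.2f%%", 100 * est$pi_hat)
  est$se <- sprintf("%.2f%%", 100 * est$se)
  est$known_prevalence <- sprintf("%.2f%%", 100 * est$known_prevalence)
  print(est, row.names = FALSE)
  cat("\n== Restriction tests ==\n")
  print(transform(x$tests, delta_pi = sprintf("%.2f%%", 100 * delta_pi)),
        digits = 4, row.names = FALSE)
  cat("\n== Validity rates ==\n")
  v <- x$validity
  v$fp <- sprintf("%.2f%% (%.2f)", 100 * v$fp_rate, 100 * v$fp_se)
  v$fn <- sprintf("%.2f%% (%.2f)", 100 * v$fn_rate, 100 * v$fn_se)
  print(v[, c("condition", "subgroup", "fp", "fn")], row.names = FALSE)
  if (!is.null(x$moderator_tests)) {
    cat("\n== Moderator comparisons ==\n")
    print(transform(x$moderator_tests,
                    delta_rate = sprintf("%.2f%%", 100 * delta_rate)),
          digits = 4, row.names = FALSE)
  }
  if (!is.null(x$diagnostics)) {
    cat("\n== Condition x criterion diagnostic ==\n")
    print(x$diagnostics)
  }
  invisible(x)
}

#' Variance ratio of the crosswise estimator relative to direct questioning
#'
#' At equal sample size, the crosswise estimator's variance exceeds the
#' direct-questioning variance by
#' \deqn{\frac{\lambda(1-\lambda)/(2p-1)^2}{\pi(1-\pi)},}
#' the factor by which the CWM sample must be inflated to match the DQ
#' standard error — the rationale for allocating more respondents to CWM
#' conditions.
#'
#' @param pi prevalence, strictly inside (0, 1).
#' @param design a CWM [cwm_design()]. For `p = 0.5` (rejected by the
#'   constructor) the ratio would be infinite.
#' @return The variance ratio (> 1 for any interior `pi` when p is near
#'   0.158).
#' @examples
#' allocation_ratio(0.3078, cwm_design(0.158))  # ~2.33
#' @export
allocation_ratio <- function(pi, design) {
  stopifnot(is_cwm_design(design))
  if (design$format != "CWM")
    stop("allocation_ratio compares a CWM design against DQ")
  if (any(pi <= 0) || any(pi >= 1))
    stop("'pi' must lie strictly inside (0, 1)")
  lam <- lambda_from_pi(pi, design)
  (lam * (1 - lam) / (2 * design$p - 1)^2) / (pi * (1 - pi))
}

#' Power of the two-condition Wald comparison
#'
#' Normal-approximation power of the two-sided Wald test of equal
#' prevalences across two conditions, with per-condition variances from
#' [wald_se()] evaluated at the hypothesized values:
#' \deqn{1-\beta = \Phi(-z_{1-\alpha/2} + |\Delta|/SE) +
#'       \Phi(-z_{1-\alpha/2} - |\Delta|/SE).}
#' Equals `alpha` when `pi1 = pi2`; increases in the sample sizes and in
#' the separation.
#'
#' @param pi1,pi2 hypothesized prevalences.
#' @param n1,n2 sample sizes.
#' @param design1,design2 the two [cwm_design()]s.
#' @param alpha two-sided test level.
#' @return The approximate power.
#' @examples
#' power_two_conditions(0.2548, 0.1179, 972, 577,
#'                      cwm_design(0.158), dq_design())
#' @export
power_two_conditions <- function(pi1, pi2, n1, n2, design1, design2,
                                 alpha = 0.05) {
  se <- sqrt(wald_se(pi1, n1, design1)^2 + wald_se(pi2, n2, design2)^2)
  z <- stats::qnorm(1 - alpha / 2)
  shift <- abs(pi1 - pi2) / se
  stats::pnorm(-z + shift) + stats::pnorm(-z - shift)
}

#' Write a study report to disk
#'
#' Serializes a [run_study()] report: `report.json` mirrors every raw
#' proportion (machine-readable, unrounded), `validity_table.csv` mirrors
#' the false-positive/false-negative matrix with percentages to two
#' decimals, and `report.txt` is the printed plain-text summary. Percent
#' formatting happens only here; the report object itself stays on the
#' proportion scale.
#'
#' @param report a `study_report`.
#' @param dir output directory (created if missing).
#' @param formats subset of `c("json", "csv", "text")`.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir,
                         formats = c("json", "csv", "text")) {
  stopifnot(inherits(report, "study_report"))
  formats <- match.arg(formats, several.ok = TRUE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  if ("json" %in% formats) {
    path <- file.path(dir, "report.json")
    payload <- list(estimates = report$estimates, tests = report$tests,
                    validity = report$validity,
                    moderator_tests = report$moderator_tests,
                    config = list(p = report$config$p,
                                  conditions = report$config$conditions,
                                  alpha = report$config$alpha))
    if (!is.null(report$diagnostics))
      payload$diagnostics <- report$diagnostics[c("chi2", "df", "n",
                                                  "p_value", "cramers_v")]
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
    paths <- c(paths, path)
  }
  if ("csv" %in% formats) {
    path <- file.path(dir, "validity_table.csv")
    v <- report$validity
    out <- data.frame(condition = v$condition, subgroup = v$subgroup,
                      fp_pct = sprintf("%.2f", 100 * v$fp_rate),
                      fp_se_pct = sprintf("%.2f", 100 * v$fp_se),
                      fn_pct = sprintf("%.2f", 100 * v$fn_rate),
                      fn_se_pct = sprintf("%.2f", 100 * v$fn_se))
    utils::write.csv(out, path, row.names = FALSE)
    paths <- c(paths, path)
  }
  if ("text" %in% formats) {
    path <- file.path(dir, "report.txt")
    txt <- utils::capture.output(print(report))
    writeLines(txt, path)
    paths <- c(paths, path)
  }
  invisible(paths)
}
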