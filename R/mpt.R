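#' G-squared fit statistic for one tree
#'
#' The log-likelihood-ratio statistic
#' \deqn{G^2 = 2\left[n_A \ln\frac{n_A}{n\lambda} +
#'   n_B \ln\frac{n_B}{n(1-\lambda)}\right]}
#' comparing the observed answer counts to the category probabilities
#' implied by a model (`expected_lambda`), with the convention
#' \eqn{0 \ln(0/\cdot) = 0}. Zero iff the observed proportion equals
#' `expected_lambda`; `+Inf` if a category with zero expected probability
#' has a non-zero observed count.
#'
#' @param counts a [response_counts()] with `n > 0`.
#' @param expected_lambda model-implied category-A probability, in `[0, 1]`.
#' @return The G-squared value (non-negative, possibly `Inf`).
#' @examples
#' g_squared(response_counts(500, 500), 0.5)  # 0: saturated
#' @export
g_squared <- function(counts, expected_lambda) {
  stopifnot(inherits(counts, "response_counts"))
  if (counts$n == 0) stop("G-squared requires n > 0")
  if (expected_lambda < 0 || expected_lambda > 1)
    stop("'expected_lambda' must lie in [0, 1]")
  term <- function(obs, expected) {
    if (obs == 0) return(0)
    if (expected == 0) return(Inf)
    obs * log(obs / expected)
  }
  2 * (term(counts$n_a, counts$n * expected_lambda) +
         term(counts$n_b, counts$n * (1 - expected_lambda)))
}

#' Multinomial processing trees over several (sub)samples
#'
#' A `tree_set` bundles one binary multinomial tree per (sub)sample — each a
#' label, its [response_counts()] and its [cwm_design()] — with one
#' prevalence parameter per tree unless a restriction ties or fixes them.
#'
#' @param label tree label (unique within a set).
#' @param counts a [response_counts()] with `n > 0`.
#' @param design a [cwm_design()].
#' @return `mpt_tree()` returns one tree; `tree_set()` collects trees into a
#'   `tree_set`.
#' @examples
#' ts <- tree_set(
#'   mpt_tree("CWM_brief", response_counts(735, 429), cwm_design(0.158)),
#'   mpt_tree("DQ", response_counts(68, 509), dq_design())
#' )
#' @export
mpt_tree <- function(label, counts, design) {
  stopifnot(is.character(label), length(label) == 1L,
            inherits(counts, "response_counts"), is_cwm_design(design))
  if (counts$n == 0) stop("tree '", label, "' has no observations")
  structure(list(label = label, counts = counts, design = design),
            class = "mpt_tree")
}

#' @rdname mpt_tree
#' @param ... for `tree_set()`, `mpt_tree` objects.
#' @export
tree_set <- function(...) {
  trees <- list(...)
  if (length(trees) == 1L && is.list(trees[[1]]) &&
      !inherits(trees[[1]], "mpt_tree"))
    trees <- trees[[1]]
  if (!length(trees) || !all(vapply(trees, inherits, TRUE, "mpt_tree")))
    stop("'tree_set' expects mpt_tree objects")
  labels <- vapply(trees, `[[`, "", "label")
  if (anyDuplicated(labels)) stop("tree labels must be unique")
  names(trees) <- labels
  structure(trees, class = "tree_set")
}

#' Parameter restrictions on a tree set
#'
#' `eq_restriction()` ties the prevalence parameters of two or more trees to
#' a common value; `fix_restriction()` pins one tree's parameter to a
#' constant (e.g. the known criterion prevalence, or 0).
#'
#' @param labels for `eq_restriction()`, two or more tree labels to tie.
#' @param label,value for `fix_restriction()`, the tree and the constant in
#'   `[0, 1]`.
#' @return An object of class `mpt_restriction`.
#' @examples
#' eq_restriction(c("CWM_brief", "DQ"))
#' fix_restriction("CWM_brief", 0.5670)
#' @export
eq_restriction <- function(labels) {
  if (!is.character(labels) || length(labels) < 2L)
    stop("an equality restriction needs at least two tree labels")
  structure(list(kind = "equality", labels = unique(labels)),
            class = "mpt_restriction")
}

#' @rdname eq_restriction
#' @export
fix_restriction <- function(label, value) {
  stopifnot(is.character(label), length(label) == 1L)
  if (!is.numeric(value) || length(value) != 1L || value < 0 || value > 1)
    stop("a fixed restriction constant must lie in [0, 1]")
  structure(list(kind = "fixed", labels = label, value = value),
            class = "mpt_restriction")
}

# Partition tree labels into parameter groups under the restrictions and
# attach a fixed value where one applies. Errors on inconsistency.
resolve_groups <- function(labels, restrictions) {
  group <- seq_along(labels)
  names(group) <- labels
  fixed <- rep(NA_real_, length(labels))
  names(fixed) <- labels
  for (r in restrictions) {
    if (!inherits(r, "mpt_restriction")) stop("not an mpt_restriction")
    unknown <- setdiff(r$labels, labels)
    if (length(unknown))
      stop("restriction names unknown tree(s): ",
           paste(unknown, collapse = ", "))
    if (r$kind == "equality") {
      gids <- unique(group[r$labels])
      group[group %in% gids] <- gids[1]
    } else {
      for (lab in names(group)[group == group[r$label]]) {
        if (!is.na(fixed[lab]) && fixed[lab] != r$value)
          stop("inconsistent restrictions: parameter of '", lab,
               "' fixed to both ", fixed[lab], " and ", r$value)
        fixed[lab] <- r$value
      }
    }
  }
  # propagate fixed values through equality groups, checking consistency
  for (g in unique(group)) {
    members <- names(group)[group == g]
    vals <- unique(fixed[members][!is.na(fixed[members])])
    if (length(vals) > 1L)
      stop("inconsistent restrictions: tied parameters fixed to ",
           paste(vals, collapse = " and "))
    if (length(vals) == 1L) fixed[members] <- vals
  }
  list(group = group, fixed = fixed)
}

#' Fit a tree set under parameter restrictions
#'
#' Maximizes the summed binomial tree log-likelihoods subject to the given
#' restrictions. Free parameters of single trees are fitted by [em_fit()];
#' parameters tied across trees (which remain one-dimensional) are fitted by
#' Brent-style bounded maximization of the joint log-likelihood on
#' `[0, 1]`. The fit's total G-squared is the sum of per-tree [g_squared()]
#' values at the fitted category probabilities; an unrestricted fit of
#' untied trees is saturated (G-squared 0) whenever each tree's moment
#' estimate is interior.
#'
#' @param trees a [tree_set()].
#' @param restrictions a list of [eq_restriction()] / [fix_restriction()]
#'   objects (possibly empty).
#' @return An object of class `mpt_fit`: a list with `estimates` (a data
#'   frame with one row per tree: label, pi_hat, se, n, fixed flag),
#'   `g2` (total G-squared), `loglik`, `df` (number of free parameters) and
#'   the inputs.
#' @examples
#' ts <- tree_set(
#'   mpt_tree("CWM_brief", response_counts(735, 429), cwm_design(0.158)),
#'   mpt_tree("DQ", response_counts(68, 509), dq_design())
#' )
#' mpt_fit(ts)                                         # saturated, G2 = 0
#' mpt_fit(ts, list(eq_restriction(c("CWM_brief", "DQ"))))
#' @export
mpt_fit <- function(trees, restrictions = list()) {
  stopifnot(inherits(trees, "tree_set"))
  if (inherits(restrictions, "mpt_restriction"))
    restrictions <- list(restrictions)
  labels <- names(trees)
  res <- resolve_groups(labels, restrictions)
  pi_hat <- rep(NA_real_, length(labels))
  names(pi_hat) <- labels
  n_free <- 0L
  for (g in unique(res$group)) {
    members <- labels[res$group == g]
    if (!is.na(res$fixed[members[1]])) {
      pi_hat[members] <- res$fixed[members[1]]
      next
    }
    n_free <- n_free + 1L
    if (length(members) == 1L) {
      pi_hat[members] <- em_fit(trees[[members]]$counts,
                                trees[[members]]$design)$pi_hat
    } else {
      joint <- function(pi) {
        sum(vapply(members, function(lab)
          cwm_loglik(trees[[lab]]$counts, pi, trees[[lab]]$design), 0))
      }
      opt <- stats::optimize(joint, c(0, 1), maximum = TRUE, tol = 1e-10)
      # optimize never lands exactly on a bound; check the endpoints too
      cand <- c(opt$maximum, 0, 1)
      pi_hat[members] <- cand[which.max(vapply(cand, joint, 0))]
    }
  }
  g2_tree <- vapply(labels, function(lab)
    g_squared(trees[[lab]]$counts,
              lambda_from_pi(pi_hat[lab], trees[[lab]]$design)), 0)
  ll <- sum(vapply(labels, function(lab)
    cwm_loglik(trees[[lab]]$counts, pi_hat[lab], trees[[lab]]$design), 0))
  est <- data.frame(
    label = labels,
    pi_hat = unname(pi_hat),
    se = vapply(labels, function(lab)
      wald_se(min(max(pi_hat[lab], 0), 1), trees[[lab]]$counts$n,
              trees[[lab]]$design), 0),
    n = vapply(labels, function(lab) trees[[lab]]$counts$n, 0),
    fixed = !is.na(res$fixed),
    g2 = unname(g2_tree),
    row.names = NULL
  )
  structure(list(estimates = est, g2 = sum(g2_tree), loglik = ll,
                 n_free = n_free, trees = trees,
                 restrictions = restrictions),
            class = "mpt_fit")
}

#' @export
print.mpt_fit <- function(x, ...) {
  cat(sprintf("MPT fit: %d tree(s), %d free parameter(s), G2 = %.4f\n",
              nrow(x$estimates), x$n_free, x$g2))
  print(x$estimates, digits = 4)
  invisible(x)
}

#' Likelihood-ratio test of a parameter restriction
#'
#' Fits the tree set with and without the restriction and compares fits by
#' the difference in G-squared, which is asymptotically chi-squared with
#' degrees of freedom equal to the number of independent constraints (k - 1
#' for an equality tie of k parameters, 1 for a fixed value).
#'
#' @param trees a [tree_set()].
#' @param restriction an [eq_restriction()] or [fix_restriction()].
#' @return An object of class `restriction_test`: `delta_g2`, `df`,
#'   `p_value`, `delta_pi` (difference of the unrestricted estimates of the
#'   first two trees involved, or estimate minus constant for a fixed
#'   restriction), and the two `mpt_fit`s.
#' @examples
#' ts <- tree_set(mpt_tree("CWM_brief", response_counts(735, 429),
#'                         cwm_design(0.158)))
#' test_restriction(ts, fix_restriction("CWM_brief", 0.5670))  # dG2 = 147.47
#' @export
test_restriction <- function(trees, restriction) {
  stopifnot(inherits(trees, "tree_set"),
            inherits(restriction, "mpt_restriction"))
  unres <- mpt_fit(trees)
  restr <- mpt_fit(trees, list(restriction))
  delta <- restr$g2 - unres$g2
  if (delta < -1e-8)
    warning("restricted fit beat the unrestricted fit; optimizer tolerance?")
  delta <- max(delta, 0)
  df <- if (restriction$kind == "equality")
    length(restriction$labels) - 1L else 1L
  upi <- unres$estimates$pi_hat
  names(upi) <- unres$estimates$label
  delta_pi <- if (restriction$kind == "equality") {
    upi[restriction$labels[1]] - upi[restriction$labels[2]]
  } else {
    upi[restriction$labels[1]] - restriction$value
  }
  structure(list(delta_g2 = delta, df = df,
                 p_value = stats::pchisq(delta, df, lower.tail = FALSE),
                 delta_pi = unname(delta_pi),
                 unrestricted_fit = unres, restricted_fit = restr,
                 restriction = restriction),
            class = "restriction_test")
}

#' @export
print.restriction_test <- function(x, ...) {
  kind <- if (x$restriction$kind == "equality")
    paste("tie", paste(x$restriction$labels, collapse = " = "))
  else
    sprintf("fix %s = %.4f", x$restriction$labels, x$restriction$value)
  cat(sprintf("Restriction test (%s): dG2(%d) = %.2f, p = %.4g, dpi = %.4f\n",
              kind, x$df, x$delta_g2, x$p_value, x$delta_pi))
  invisible(x)
}

#' Pearson chi-squared contingency test with Cramer's V
#'
#' Wraps [stats::chisq.test()] (without continuity correction) and adds the
#' effect size \eqn{V = \sqrt{\chi^2 / (N \min(r-1, c-1))}}.
#'
#' @param table a contingency table (matrix of counts, at least 2x2).
#' @return An object of class `contingency_result`: `chi2`, `df`, `n`,
#'   `p_value`, `cramers_v`.
#' @examples
#' contingency_test(matrix(c(120, 80, 90, 110), 2))
#' @export
contingency_test <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) < 2L || ncol(table) < 2L)
    stop("contingency table must be at least 2x2")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("contingency table has a zero marginal")
  ct <- stats::chisq.test(table, correct = FALSE)
  if (any(ct$expected <= 0)) stop("expected count of zero in some cell")
  n <- sum(table)
  chi2 <- unname(ct$statistic)
  structure(list(chi2 = chi2, df = unname(ct$parameter), n = n,
                 p_value = ct$p.value,
                 cramers_v = cramers_v(chi2, n, nrow(table), ncol(table))),
            class = "contingency_result")
}

#' @export
print.contingency_result <- function(x, ...) {
  cat(sprintf("chi2(%d, N = %d) = %.2f, p = %.4g, Cramer's V = %.2f\n",
              x$df, as.integer(x$n), x$chi2, x$p_value, x$cramers_v))
  invisible(x)
}

#' Cramer's V from a chi-squared statistic
#'
#' \eqn{V = \sqrt{\chi^2 / (N \min(r-1, c-1))}}, the standard chi-squared
#' effect size for an r-by-c contingency table.
#'
#' @param chi2 the chi-squared statistic.
#' @param n the total count.
#' @param nrow,ncol the table dimensions.
#' @return Cramer's V in `[0, 1]`.
#' @examples
#' cramers_v(18.87, 3040, 2, 2)   # 0.08
#' cramers_v(211.75, 3002, 2, 3)  # 0.27
#' @export
cramers_v <- function(chi2, n, nrow = 2, ncol = 2) {
  stopifnot(chi2 >= 0, n > 0, nrow >= 2, ncol >= 2)
  sqrt(chi2 / (n * min(nrow - 1, ncol - 1)))
}

#' Reconstruct answer counts from a published estimate
#'
#' Inverts reporting: given a published prevalence estimate and sample size,
#' rebuilds the observable answer counts as `round(n * lambda(pi_hat))`
#' (half away from zero). Rounding-lossy by construction — intended for
#' worked examples and tests where the raw frequencies are not available,
#' not for analysis of real data.
#'
#' @param pi_hat published prevalence estimate, in `[0, 1]`.
#' @param n sample size.
#' @param design a [cwm_design()].
#' @return A [response_counts()].
#' @examples
#' counts_from_printed(0.3078, 1164, cwm_design(0.158))  # (735, 429)
#' counts_from_printed(0.1179, 577, dq_design())         # (68, 509)
#' @export
counts_from_printed <- function(pi_hat, n, design) {
  stopifnot(is_cwm_design(design))
  if (pi_hat < 0 || pi_hat > 1) stop("'pi_hat' must lie in [0, 1]")
  n_a <- round_half_up(n * lambda_from_pi(pi_hat, design))
  response_counts(n_a, n - n_a)
}
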