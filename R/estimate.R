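#' Category-A probability implied by a prevalence
#'
#' Forward mapping of the measurement model. For the crosswise model the
#' probability of the "both true or both false" answer is
#' \deqn{\lambda = \pi p + (1 - \pi)(1 - p),}
#' the sum over the two latent branches that reach category A: carriers
#' (prevalence \eqn{\pi}) match the randomizer with probability `p`,
#' non-carriers with probability `1 - p`. For direct questioning
#' \eqn{\lambda = \pi}.
#'
#' With `p < 0.5` the mapping is strictly decreasing in `pi`; it is linear,
#' and for CWM its range is `[min(p, 1-p), max(p, 1-p)]`.
#'
#' @param pi prevalence of the sensitive attribute, in `[0, 1]`.
#' @param design a [cwm_design()].
#' @return The category-A probability (same length as `pi`).
#' @examples
#' d <- cwm_design(p = 0.158)
#' lambda_from_pi(0, d)       # 0.842: non-carrier answers A iff not born Nov/Dec
#' lambda_from_pi(0.3078, d)  # 0.6314648
#' @export
lambda_from_pi <- function(pi, design) {
  stopifnot(is_cwm_design(design))
  if (any(!is.finite(pi)) || any(pi < 0) || any(pi > 1))
    stop("'pi' must lie in [0, 1]")
  b <- branch_probs(design)
  pi * b[1] + (1 - pi) * b[2]
}

#' Prevalence implied by an observed category-A proportion
#'
#' Closed-form (method-of-moments) inverse of [lambda_from_pi()]:
#' \eqn{\pi = (\lambda + p - 1) / (2p - 1)} for the crosswise model,
#' \eqn{\pi = \lambda} for direct questioning. When the observed proportion
#' lies outside the attainable range `[min(p, 1-p), max(p, 1-p)]` the result
#' falls outside `[0, 1]`; it is returned raw so that the moment estimator
#' stays auditable — the maximum-likelihood estimator in [cwm_estimate()]
#' truncates it to the boundary instead.
#'
#' @param lambda_hat observed proportion of category-A answers, in `[0, 1]`.
#' @param design a [cwm_design()]; `p` must differ from 0.5 for CWM.
#' @return The implied prevalence (possibly outside `[0, 1]`).
#' @examples
#' d <- cwm_design(p = 0.158)
#' pi_from_lambda(0.842, d)      # 0
#' pi_from_lambda(0.6314648, d)  # 0.3078
#' @export
pi_from_lambda <- function(lambda_hat, design) {
  stopifnot(is_cwm_design(design))
  if (any(!is.finite(lambda_hat)) || any(lambda_hat < 0) || any(lambda_hat > 1))
    stop("'lambda_hat' must lie in [0, 1]")
  if (design$format == "DQ") return(lambda_hat)
  (lambda_hat + design$p - 1) / (2 * design$p - 1)
}

#' Delta-method (Wald) standard error of a prevalence estimate
#'
#' For direct questioning the usual binomial standard error
#' \eqn{\sqrt{\hat\pi(1-\hat\pi)/n}}. For the crosswise model the standard
#' error of the category-A proportion is scaled by the Jacobian of the
#' inverse mapping:
#' \deqn{SE(\hat\pi) = \frac{\sqrt{\hat\lambda(1-\hat\lambda)/n}}{|2p - 1|},
#' \quad \hat\lambda = \lambda(\hat\pi).}
#' This is the convention that reproduces published multinomial-tree
#' standard errors for this design; the `1/|2p-1|` factor is the efficiency
#' cost of the randomization.
#'
#' @param pi_hat estimated prevalence, in `[0, 1]`.
#' @param n sample size (positive).
#' @param design a [cwm_design()].
#' @return The standard error, on the proportion scale.
#' @examples
#' wald_se(0.3078, 1164, cwm_design(p = 0.158))  # 0.0207
#' wald_se(0.1179, 577, dq_design())             # 0.0134
#' @export
wald_se <- function(pi_hat, n, design) {
  stopifnot(is_cwm_design(design))
  if (any(pi_hat < 0) || any(pi_hat > 1)) stop("'pi_hat' must lie in [0, 1]")
  if (any(n <= 0)) stop("'n' must be positive")
  lam <- lambda_from_pi(pi_hat, design)
  se_lam <- sqrt(lam * (1 - lam) / n)
  if (design$format == "DQ") se_lam else se_lam / abs(2 * design$p - 1)
}

#' Binomial log-likelihood of a prevalence given answer counts
#'
#' \eqn{\ell(\pi) = n_A \log \lambda(\pi) + n_B \log(1 - \lambda(\pi))} with
#' the convention \eqn{0 \log 0 = 0}. Strictly concave in `pi` for CWM
#' designs with `p != 0.5`. If \eqn{\lambda(\pi)} is 0 or 1 while the
#' opposing count is non-zero, `-Inf` is returned (a sentinel, not an
#' error), so optimizers can see the cliff.
#'
#' @param counts a [response_counts()].
#' @param pi prevalence value(s) at which to evaluate, in `[0, 1]`.
#' @param design a [cwm_design()].
#' @return The log-likelihood (vectorized over `pi`).
#' @export
cwm_loglik <- function(counts, pi, design) {
  stopifnot(inherits(counts, "response_counts"), is_cwm_design(design))
  lam <- lambda_from_pi(pi, design)
  term <- function(k, prob) {
    out <- numeric(length(prob))
    if (k == 0) return(out)          # 0 * log(anything) = 0 by convention
    out[prob > 0] <- k * log(prob[prob > 0])
    out[prob <= 0] <- -Inf
    out
  }
  term(counts$n_a, lam) + term(counts$n_b, 1 - lam)
}

#' Maximum-likelihood prevalence estimation by expectation maximization
#'
#' Fits the one-parameter multinomial processing tree by EM. The E-step
#' computes, for each answer category, the expected number of carriers of
#' the sensitive attribute among the respondents in that category — the
#' posterior weight of the carrier branch given the current prevalence. The
#' M-step sets the prevalence to expected carriers over `n`.
#'
#' Plain EM iteration is augmented with Aitken's delta-squared acceleration:
#' after each pair of EM steps the extrapolated fixed point is taken
#' whenever it does not decrease the log-likelihood (clamped to `[0, 1]`).
#' This matters in two regimes where the bare EM map contracts slowly —
#' `p` near 0.5 (contraction factor near 1) and observed proportions at the
#' edge of the attainable range (map derivative exactly 1 at the boundary
#' fixed point, giving sublinear 1/k convergence). Iteration stops when the
#' prevalence moves by less than `tol` over an accelerated cycle or after
#' `max_iter` EM steps. The problem is concave in one dimension, so the
#' fixed point is the constrained maximizer on `[0, 1]`; when the
#' unconstrained (closed-form) maximizer lies outside, the fit lands on the
#' nearer boundary and the result carries `at_boundary = TRUE`.
#'
#' @param counts a [response_counts()] with `n > 0`.
#' @param design a [cwm_design()].
#' @param start starting prevalence; values of exactly 0 or 1 (where the EM
#'   map has a degenerate fixed point) are nudged into the open interval.
#' @param tol convergence tolerance on the prevalence change per cycle.
#' @param max_iter maximum number of EM steps.
#' @return A `prevalence_estimate` (see [cwm_estimate()]) with `estimator =
#'   "ml"`, plus `iterations` and `converged`.
#' @examples
#' em_fit(response_counts(421, 579), cwm_design(p = 0.158))
#' @export
em_fit <- function(counts, design, start = 0.5, tol = 1e-12,
                   max_iter = 10000L) {
  stopifnot(inherits(counts, "response_counts"), is_cwm_design(design))
  if (counts$n == 0) stop("cannot estimate a prevalence from zero responses")
  b <- branch_probs(design)           # P(answer A | carrier), P(A | non-carrier)
  em_step <- function(pi) {
    lam <- pi * b[1] + (1 - pi) * b[2]
    # expected carriers among category-A and category-B respondents
    exp_a <- if (lam > 0) counts$n_a * pi * b[1] / lam else 0
    exp_b <- if (lam < 1) counts$n_b * pi * (1 - b[1]) / (1 - lam) else 0
    (exp_a + exp_b) / counts$n
  }
  pi <- min(max(start, 1e-9), 1 - 1e-9)
  converged <- FALSE
  iter <- 0L
  delta <- Inf
  while (iter < max_iter) {
    pi1 <- em_step(pi)
    pi2 <- em_step(pi1)
    iter <- iter + 2L
    d1 <- pi1 - pi
    d2 <- pi2 - pi1
    pi_next <- pi2
    if (abs(d2 - d1) > 1e-300) {      # Aitken delta-squared extrapolation
      pi_acc <- min(max(pi - d1^2 / (d2 - d1), 0), 1)
      if (cwm_loglik(counts, pi_acc, design) >=
          cwm_loglik(counts, pi2, design))
        pi_next <- pi_acc
    }
    delta <- abs(pi_next - pi)
    pi <- pi_next
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  ll_old <- cwm_loglik(counts, pi, design)
  if (!converged)
    warning(sprintf("EM did not converge in %d steps (last change %g > tol %g)",
                    max_iter, delta, tol))
  closed <- pi_from_lambda(counts$n_a / counts$n, design)
  new_prevalence_estimate(
    pi_hat = pi, n = counts$n, design = design, estimator = "ml",
    lambda_hat = counts$n_a / counts$n,
    at_boundary = closed < 0 || closed > 1,
    loglik = ll_old, iterations = iter, converged = converged
  )
}

new_prevalence_estimate <- function(pi_hat, n, design, estimator, lambda_hat,
                                    at_boundary, loglik = NA_real_,
                                    iterations = NA_integer_,
                                    converged = NA) {
  se_pi <- min(max(pi_hat, 0), 1)     # SE evaluated at the truncated estimate
  structure(
    list(pi_hat = pi_hat,
         se = wald_se(se_pi, n, design),
         n = n,
         estimator = estimator,
         at_boundary = at_boundary,
         lambda_hat = lambda_hat,
         loglik = loglik,
         iterations = iterations,
         converged = converged,
         design = design),
    class = "prevalence_estimate"
  )
}

#' Prevalence estimation from answer counts
#'
#' Point estimation of the prevalence of the sensitive attribute from the
#' two observable answer counts, under a crosswise-model or
#' direct-questioning design.
#'
#' Two estimator variants are available. `"closed_form"` is the
#' method-of-moments inversion [pi_from_lambda()] applied to the observed
#' category-A proportion; it may fall outside `[0, 1]` (reported raw, with
#' `at_boundary` set). `"ml"` is the maximum-likelihood estimate obtained by
#' [em_fit()]; it coincides with the closed form whenever the closed form is
#' interior and otherwise sits at the nearer boundary. Standard errors come
#' from [wald_se()] in both cases; at a boundary the same formula is used
#' (evaluated at the truncated estimate) and `at_boundary` flags that the
#' usual Wald interpretation is strained there.
#'
#' @param counts a [response_counts()] with `n > 0`.
#' @param design a [cwm_design()].
#' @param estimator `"ml"` (default) or `"closed_form"`.
#' @param ... further arguments passed to [em_fit()] (e.g. `tol`).
#' @return An object of class `prevalence_estimate`: a list with `pi_hat`,
#'   `se`, `n`, `estimator`, `at_boundary`, `lambda_hat` (the observed
#'   category-A proportion), and for ML fits `loglik`, `iterations`,
#'   `converged`.
#' @examples
#' d <- cwm_design(p = 0.158)
#' cwm_estimate(response_counts(735, 429), d)            # pi_hat ~ 0.3078
#' cwm_estimate(response_counts(68, 509), dq_design())   # pi_hat = 0.1179
#' @export
cwm_estimate <- function(counts, design, estimator = c("ml", "closed_form"),
                         ...) {
  stopifnot(inherits(counts, "response_counts"), is_cwm_design(design))
  estimator <- match.arg(estimator)
  if (counts$n == 0) stop("cannot estimate a prevalence from zero responses")
  lam_hat <- counts$n_a / counts$n
  pi_raw <- pi_from_lambda(lam_hat, design)
  if (estimator == "closed_form") {
    return(new_prevalence_estimate(
      pi_hat = pi_raw, n = counts$n, design = design,
      estimator = "closed_form", lambda_hat = lam_hat,
      at_boundary = pi_raw < 0 || pi_raw > 1
    ))
  }
  em_fit(counts, design, ...)
}

#' @export
print.prevalence_estimate <- function(x, ...) {
  cat(sprintf("Prevalence estimate (%s, %s): pi_hat = %.4f (SE = %.4f), n = %d\n",
              x$estimator, x$design$format, x$pi_hat, x$se, as.integer(x$n)))
  if (isTRUE(x$at_boundary))
    cat("  note: moment estimate outside [0, 1]; ML value truncated at the boundary\n")
  if (identical(x$estimator, "ml") && !isTRUE(x$converged))
    cat("  warning: EM did not converge\n")
  invisible(x)
}
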