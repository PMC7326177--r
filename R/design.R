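#' Questioning design: crosswise model or direct questioning
#'
#' Describes how the sensitive question was asked. In the crosswise model
#' (CWM) the sensitive statement is paired with a non-sensitive statement of
#' known prevalence `p` (the randomization probability, e.g. birth in
#' November/December, p = 0.158), and respondents report only whether the two
#' statements match ("both true or both false", answer category A) or
#' mismatch (category B). Under direct questioning (DQ) category A simply
#' means "true".
#'
#' `p = 0.5` is rejected for CWM designs: at that value the category-A
#' probability no longer depends on the prevalence, so the prevalence is
#' unidentifiable.
#'
#' @param p probability of the non-sensitive randomization attribute,
#'   strictly between 0 and 1 and different from 0.5. Ignored for DQ.
#' @param format `"CWM"` or `"DQ"`.
#' @return An object of class `cwm_design` with elements `p`, `format` and
#'   `category_a` (the meaning of answer category A).
#' @examples
#' cwm_design(p = 0.158)
#' dq_design()
#' @export
cwm_design <- function(p = 0.158, format = c("CWM", "DQ")) {
  format <- match.arg(format)
  if (format == "CWM") {
    if (!is.numeric(p) || length(p) != 1L || is.na(p) || p <= 0 || p >= 1)
      stop("'p' must be a single probability strictly between 0 and 1")
    if (p == 0.5)
      stop("p = 0.5 makes the prevalence unidentifiable in the crosswise ",
           "model: the category-A probability is 0.5 regardless of the ",
           "prevalence")
  } else {
    p <- NA_real_
  }
  structure(
    list(
      p = p,
      format = format,
      category_a = if (format == "CWM")
        "both statements true or both statements false" else "true"
    ),
    class = "cwm_design"
  )
}

#' @rdname cwm_design
#' @export
dq_design <- function() cwm_design(format = "DQ")

#' @export
print.cwm_design <- function(x, ...) {
  if (x$format == "CWM") {
    cat(sprintf("Crosswise-model design (p = %.4g)\n", x$p))
  } else {
    cat("Direct-questioning design\n")
  }
  cat("  category A: ", x$category_a, "\n", sep = "")
  invisible(x)
}

is_cwm_design <- function(x) inherits(x, "cwm_design")

# Per-branch probabilities of answering category A:
# c(carrier, non-carrier). CWM: a carrier matches the randomizer iff it is
# true (prob p); a non-carrier iff it is false (prob 1 - p). DQ: carriers
# answer "true", non-carriers "false".
branch_probs <- function(design) {
  if (design$format == "CWM") c(design$p, 1 - design$p) else c(1, 0)
}

#' Observed answer counts for one (sub)sample
#'
#' Holds the two observable answer-category counts a crosswise-model or
#' direct-questioning tree emits.
#'
#' @param n_a count of answers in category A (CWM: "both true or both
#'   false"; DQ: "true").
#' @param n_b count of answers in category B.
#' @return An object of class `response_counts` with elements `n_a`, `n_b`
#'   and `n = n_a + n_b`.
#' @examples
#' response_counts(735, 429)
#' @export
response_counts <- function(n_a, n_b) {
  if (!is.numeric(n_a) || !is.numeric(n_b) || length(n_a) != 1L ||
      length(n_b) != 1L || is.na(n_a) || is.na(n_b))
    stop("'n_a' and 'n_b' must be single non-missing numbers")
  if (n_a < 0 || n_b < 0) stop("counts must be non-negative")
  if (n_a != round(n_a) || n_b != round(n_b))
    stop("counts must be whole numbers")
  structure(list(n_a = as.numeric(n_a), n_b = as.numeric(n_b),
                 n = as.numeric(n_a + n_b)),
            class = "response_counts")
}

#' @export
print.response_counts <- function(x, ...) {
  cat(sprintf("Response counts: A = %d, B = %d (n = %d)\n",
              as.integer(x$n_a), as.integer(x$n_b), as.integer(x$n)))
  invisible(x)
}

# round half away from zero, so reconstructed counts do not depend on the
# IEC 60559 banker's rounding of base round()
round_half_up <- function(x) floor(x + 0.5)
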