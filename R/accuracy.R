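#' Hypothesis settings for the co-primary endpoint problem
#'
#' Each index test `j` is evaluated against the one-sided null hypothesis
#' that its sensitivity does not exceed `se0` *or* its specificity does not
#' exceed `sp0`. Study success for test `j` requires rejecting both margins
#' simultaneously (intersection-union principle), so no alpha adjustment is
#' needed for the two endpoints of a single test; adjustment across the `m`
#' tests is the task of the multiple comparison procedures.
#'
#' @param se0 minimal acceptable sensitivity, in (0, 1).
#' @param sp0 minimal acceptable specificity, in (0, 1).
#' @param alpha one-sided significance level, in (0, 0.5); default 0.025.
#' @return An object of class `"hypothesis_spec"`.
#' @examples
#' hypothesis_spec(0.8, 0.8)
#' @export
hypothesis_spec <- function(se0, sp0, alpha = 0.025) {
  for (v in list(se0 = se0, sp0 = sp0)) {
    if (!is.numeric(v) || length(v) != 1L || v <= 0 || v >= 1) {
      stop("`se0` and `sp0` must be single values in (0, 1)", call. = FALSE)
    }
  }
  check_alpha(alpha)
  structure(list(se0 = se0, sp0 = sp0, alpha = alpha),
            class = "hypothesis_spec")
}

#' @export
print.hypothesis_spec <- function(x, ...) {
  cat(sprintf("co-primary hypotheses: se > %.3g and sp > %.3g (one-sided alpha = %.4g)\n",
              x$se0, x$sp0, x$alpha))
  invisible(x)
}

#' Estimate sensitivity and specificity with optional shrinkage
#'
#' Computes per-test proportions of correct decisions in each subgroup. With
#' `shrinkage = h > 0` the estimates are
#' \deqn{\hat{se}_j = (n_{j,11} + h) / (n_1 + 2h), \quad
#'       \hat{sp}_j = (n_{j,00} + h) / (n_0 + 2h),}
#' i.e. `h` pseudo-successes and `h` pseudo-failures are added, pulling the
#' estimate slightly towards 0.5. This keeps every estimate strictly inside
#' (0, 1) and thereby prevents singular variance estimates when a test is
#' perfect in a subgroup; the perturbation vanishes at rate 1/n. `h = 0`
#' reproduces the maximum-likelihood proportions exactly.
#'
#' @param data a [study_data] object.
#' @param shrinkage nonnegative pseudo-count `h`; default 0.5.
#' @return An object of class `"accuracy_estimate"`: list with `se_hat`,
#'   `sp_hat`, the counts `n11`, `n00`, the group sizes, `labels`, and the
#'   `shrinkage` value used.
#' @examples
#' d <- study_data(rep(1:0, c(30, 90)),
#'                 matrix(rbinom(120, 1, 0.8), ncol = 1))
#' estimate_accuracy(d)$se_hat
#' @export
estimate_accuracy <- function(data, shrinkage = 0.5) {
  stopifnot(inherits(data, "study_data"))
  h <- shrinkage
  if (!is.numeric(h) || length(h) != 1L || h < 0 || !is.finite(h)) {
    stop("`shrinkage` must be a single nonnegative number", call. = FALSE)
  }
  qq <- correctness(data)
  n11 <- unname(colSums(qq$Q1))
  n00 <- unname(colSums(qq$Q0))
  structure(
    list(se_hat = (n11 + h) / (data$n1 + 2 * h),
         sp_hat = (n00 + h) / (data$n0 + 2 * h),
         n11 = n11, n00 = n00,
         n1 = data$n1, n0 = data$n0, m = data$m,
         labels = data$labels, shrinkage = h),
    class = "accuracy_estimate"
  )
}

#' Co-primary Wald statistics
#'
#' For each test the two one-sided Wald statistics
#' \deqn{Z_j^{se} = \frac{\hat{se}_j - se_0}{\sqrt{\hat{se}_j (1-\hat{se}_j)/n_1}}}
#' (and analogously for specificity with `n0`) are combined by
#' \eqn{Z_j = \min(Z_j^{se}, Z_j^{sp})}; the endpoint attaining the minimum
#' is the *binding* endpoint of test `j` (ties are recorded as `"se"` for
#' deterministic reproducibility).
#'
#' @param est an [estimate_accuracy()] result.
#' @param hyp a [hypothesis_spec].
#' @return An object of class `"test_statistics"`: list with `z_se`, `z_sp`,
#'   `z_min`, and `binding` (character vector in `"se"`/`"sp"`).
#' @export
wald_statistics <- function(est, hyp) {
  stopifnot(inherits(est, "accuracy_estimate"), inherits(hyp, "hypothesis_spec"))
  if (any(est$se_hat %in% c(0, 1)) || any(est$sp_hat %in% c(0, 1))) {
    stop("degenerate variance: an accuracy estimate is exactly 0 or 1; ",
         "use a positive `shrinkage` pseudo-count in estimate_accuracy()",
         call. = FALSE)
  }
  z_se <- (est$se_hat - hyp$se0) / sqrt(est$se_hat * (1 - est$se_hat) / est$n1)
  z_sp <- (est$sp_hat - hyp$sp0) / sqrt(est$sp_hat * (1 - est$sp_hat) / est$n0)
  structure(
    list(z_se = z_se, z_sp = z_sp, z_min = pmin(z_se, z_sp),
         binding = ifelse(z_sp < z_se, "sp", "se"),
         labels = est$labels, m = est$m),
    class = "test_statistics"
  )
}

#' Intersection-union rejection rule
#'
#' Test `j` is rejected iff its combined statistic strictly exceeds the
#' critical value: \eqn{\varphi_j = 1 \iff \min(Z_j^{se}, Z_j^{sp}) > c_\alpha}.
#'
#' @param stats a [wald_statistics()] result.
#' @param c_alpha finite scalar critical value (or `-Inf`/`Inf` limits).
#' @return Integer vector of per-test decisions `phi` in \{0, 1\}.
#' @examples
#' # z_min = (1.2, 2.5) against c = 1.96 rejects only the second test
#' @export
decide <- function(stats, c_alpha) {
  stopifnot(inherits(stats, "test_statistics"),
            is.numeric(c_alpha), length(c_alpha) == 1L, !is.na(c_alpha))
  as.integer(stats$z_min > c_alpha)
}
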