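#' Critical value without multiplicity adjustment
#'
#' The naive rule uses the `1 - alpha` standard-normal quantile for every
#' test. It controls the per-test error of the intersection-union test but
#' not the family-wise error rate across `m` tests.
#'
#' @param alpha one-sided level in (0, 0.5).
#' @return Scalar critical value \eqn{z_{1-\alpha}}.
#' @examples
#' critical_value_none(0.025) # 1.95996
#' @export
critical_value_none <- function(alpha) {
  stats::qnorm(1 - check_alpha(alpha))
}

#' Bonferroni critical value for the co-primary problem
#'
#' The local level is `alpha / m` — the divisor is the number of *tests* m,
#' not the number of parameters 2m, because the two endpoints of one test
#' are combined by intersection-union and need no adjustment of their own.
#'
#' @param alpha one-sided level in (0, 0.5).
#' @param m number of index tests (>= 1).
#' @return Scalar critical value \eqn{z_{1-\alpha/m}}.
#' @examples
#' critical_value_bonferroni(0.025, 10) # 2.8070
#' @export
critical_value_bonferroni <- function(alpha, m) {
  check_alpha(alpha)
  stopifnot(is.numeric(m), length(m) == 1L, m >= 1)
  stats::qnorm(1 - alpha / m)
}

#' Correlation matrix of the binding statistics at the estimated LFC
#'
#' The maxT procedure approximates the joint law of the combined statistics
#' \eqn{Z_j} under the least-favourable parameter configuration (LFC) most
#' compatible with the data: for each test only the *binding* endpoint (the
#' one attaining the minimum statistic) is assumed to sit at its boundary,
#' the other at 1. Under that configuration \eqn{Z_j} behaves like the Wald
#' statistic of the binding endpoint alone, so the relevant correlation is
#' the empirical correlation of the subject-level correct-decision
#' indicators of the binding endpoints:
#' * both endpoints refer to the diseased subgroup — Pearson correlation of
#'   the two test columns among cases;
#' * both refer to the non-diseased subgroup — correlation among controls;
#' * different subgroups — 0 (the two samples are independent).
#'
#' A constant indicator column has no defined correlation; it is entered as
#' 0 with a warning. The assembled matrix is repaired to positive
#' semi-definiteness by clipping eigenvalues at `1e-8` and renormalizing the
#' diagonal.
#'
#' @param data a [study_data] object.
#' @param stats a [wald_statistics()] result for the same data.
#' @return An object of class `"lfc_correlation"`: list with the `m x m`
#'   `matrix` and the `binding` endpoint vector.
#' @export
estimate_lfc_correlation <- function(data, stats) {
  stopifnot(inherits(data, "study_data"), inherits(stats, "test_statistics"))
  m <- data$m
  qq <- correctness(data)
  bind_se <- stats$binding == "se"
  const <- ifelse(bind_se,
                  col_vars(qq$Q1) == 0,
                  col_vars(qq$Q0) == 0)
  if (any(const)) {
    warning("constant correct-decision indicator column(s): ",
            paste(stats$labels[const], collapse = ", "),
            "; correlation entries set to 0", call. = FALSE)
  }
  R <- diag(m)
  if (m >= 2L) {
    C1 <- safe_cor(qq$Q1) # full within-subgroup correlation, computed once
    C0 <- safe_cor(qq$Q0)
    same_se <- outer(bind_se, bind_se, "&")
    same_sp <- outer(!bind_se, !bind_se, "&")
    ok <- outer(!const, !const, "&")
    R[same_se & ok] <- C1[same_se & ok]
    R[same_sp & ok] <- C0[same_sp & ok]
    diag(R) <- 1
    R <- psd_repair(R)
  }
  dimnames(R) <- list(stats$labels, stats$labels)
  structure(list(matrix = R, binding = stats$binding),
            class = "lfc_correlation")
}

# Monte-Carlo sample of max_j of an m-variate N(0, R); fixed seed makes the
# derived quantile deterministic and reproducible.
mvn_max_sample <- function(R, draws, seed = NULL) {
  m <- ncol(R)
  with_seed(seed, {
    U <- tryCatch(chol(psd_repair(R)),
                  error = function(e) stop(
                    "correlation matrix is not positive semi-definite, ",
                    "even after eigenvalue repair", call. = FALSE))
    row_max(matrix(stats::rnorm(draws * m), draws, m) %*% U)
  })
}

#' Equicoordinate quantile of a centred multivariate normal (maxT)
#'
#' Returns the smallest `c` with \eqn{P(\max_j X_j \le c) \ge 1 - \alpha}
#' for \eqn{X \sim N(0, R)}, the critical value of the maxT procedure. The
#' quantile is taken from a fixed-seed Monte-Carlo sample of the
#' coordinate-wise maximum (`draws` draws, conservative order-statistic
#' rank \eqn{\lceil (1-\alpha) \cdot draws \rceil}), which at the default
#' `draws = 1e5` resolves the quantile to a few parts in a thousand.
#'
#' @param R an `"lfc_correlation"` object or a plain correlation matrix.
#' @param alpha one-sided level in (0, 0.5).
#' @param draws Monte-Carlo sample size; default `1e5`.
#' @param seed optional integer making the result deterministic.
#' @return Scalar critical value.
#' @examples
#' critical_value_maxt(diag(2), 0.025, seed = 1) # ~ qnorm(sqrt(0.975)) = 2.2383
#' @export
critical_value_maxt <- function(R, alpha, draws = 1e5, seed = NULL) {
  if (inherits(R, "lfc_correlation")) R <- R$matrix
  stopifnot(is.matrix(R), nrow(R) == ncol(R))
  check_alpha(alpha)
  if (ncol(R) == 1L) return(critical_value_none(alpha))
  boot_quantile(mvn_max_sample(R, draws, seed), alpha)
}
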