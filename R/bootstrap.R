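#' Pairs bootstrap critical value
#'
#' Resamples whole subject rows `(D, T1, ..., Tm)` with replacement,
#' stratified by disease status so every replicate keeps exactly `n1` cases
#' and `n0` controls (matching the fixed-sample case-control design and
#' avoiding empty subgroups). Resampling rows preserves the between-test
#' correlation structure. Each replicate `b` yields centred statistics
#' \deqn{Z^{*se}_{j,(b)} = (\hat{se}^*_j - \hat{se}_j) /
#'       \sqrt{\hat{se}^*_j (1-\hat{se}^*_j)/n_1}}
#' (replicate estimates computed with the same shrinkage pseudo-count as
#' the point estimates, keeping them finite).
#'
#' The bootstrap approximates the null distribution of the maximum
#' combined statistic under the least-favourable configuration most
#' compatible with the data, exactly as the maxT procedure does with its
#' estimated correlation matrix: under that configuration only the
#' *binding* endpoint of each test (the one attaining the minimum of the
#' observed Wald statistics) sits at its boundary, while the other
#' parameter is at 1 and its statistic diverges, so
#' \eqn{\min(Z_j^{se}, Z_j^{sp})} reduces to the binding-endpoint
#' statistic. Accordingly each replicate records
#' \eqn{Z^{*}_{(b)} = \max_j Z^{*e_j}_{j,(b)}} with `e_j` the binding
#' endpoint of test `j`. (Taking the minimum of both *centred* statistics
#' instead would be degenerate: a test that is perfect in one subgroup has
#' a centred statistic fixed at zero there, pinning the minimum at or
#' below zero and the critical value near zero; and for a single test it
#' would produce the quantile of a minimum of two centred statistics,
#' about 1.0 at independence, instead of the nominal `z_{1-alpha}`.)
#' The critical value is the order statistic of rank
#' \eqn{\lceil (1-\alpha) B \rceil} of the `B` maxima.
#'
#' @param data a [study_data] object with at least 2 subjects per group.
#' @param est the [estimate_accuracy()] result for `data`.
#' @param hyp a [hypothesis_spec] (provides `alpha`).
#' @param B number of bootstrap replicates (>= 100); default 2000.
#' @param seed optional integer seed; identical seed and `B` reproduce the
#'   draws bit-identically.
#' @return An object of class `"bootstrap_draws"`: list with `max_stats`
#'   (the `B` maxima of the combined statistics), `max_all_stats` (maxima
#'   over all `2m` centred statistics, used for confidence regions),
#'   `critical_value`, `B`, `seed`, and `scheme = "pairs"`.
#' @export
pairs_bootstrap <- function(data, est, hyp, B = 2000, seed = NULL) {
  stopifnot(inherits(data, "study_data"), inherits(est, "accuracy_estimate"),
            inherits(hyp, "hypothesis_spec"))
  if (data$n1 < 2L || data$n0 < 2L) {
    stop("pairs bootstrap needs at least 2 subjects per subgroup", call. = FALSE)
  }
  if (B < 100L) stop("`B` must be at least 100", call. = FALSE)
  h <- est$shrinkage
  qq <- correctness(data)
  binding <- wald_statistics(est, hyp)$binding
  res <- with_seed(seed, {
    # multinomial resampling weights are equivalent to drawing subject
    # indices with replacement; crossprod vectorizes over all B replicates
    W1 <- stats::rmultinom(B, data$n1, rep.int(1, data$n1))
    W0 <- stats::rmultinom(B, data$n0, rep.int(1, data$n0))
    se_star <- (crossprod(qq$Q1, W1) + h) / (data$n1 + 2 * h) # m x B
    sp_star <- (crossprod(qq$Q0, W0) + h) / (data$n0 + 2 * h)
    z_se <- (se_star - est$se_hat) / sqrt(se_star * (1 - se_star) / data$n1)
    z_sp <- (sp_star - est$sp_hat) / sqrt(sp_star * (1 - sp_star) / data$n0)
    z_bind <- z_se
    z_bind[binding == "sp", ] <- z_sp[binding == "sp", ]
    list(max_stats = col_max(z_bind),
         max_all_stats = pmax(col_max(z_se), col_max(z_sp)))
  })
  structure(
    c(res, list(critical_value = boot_quantile(res$max_stats, hyp$alpha),
                B = B, seed = seed, scheme = "pairs")),
    class = "bootstrap_draws"
  )
}

#' Wild bootstrap critical value
#'
#' Perturbs the subgroup means instead of resampling subjects: within each
#' subgroup the rows of the residual matrix \eqn{r_{ij} = Q_{ij} -
#' \bar{Q}_{.j}} (correct-decision indicators centred at the empirical
#' sensitivities/specificities) are resampled with replacement and each
#' resampled row is multiplied by one random weight (standard normal by
#' default) shared across all `m` tests of that subject — sharing the
#' weight preserves the between-test correlation. The perturbed mean is the
#' original estimate plus the subgroup average of the weighted resampled
#' residuals. Because the perturbed values are not on the 0/1 scale of the
#' data, standard errors are taken from the original (shrunk) estimates
#' rather than recomputed. The per-replicate maximum is taken over the
#' binding-endpoint statistics, and the critical value is derived, exactly
#' as in [pairs_bootstrap()].
#'
#' For normal weights the implementation aggregates per source row: the sum
#' of the weights of the `N_r` copies of row `r` is distributed as
#' \eqn{\sqrt{N_r}\, z_r} with `N` multinomial and `z` standard normal,
#' which allows one `crossprod` per subgroup over all `B` replicates.
#'
#' @inheritParams pairs_bootstrap
#' @param weight_dist `"normal"` (default) or a `function(n)` returning `n`
#'   weights (e.g. Rademacher); a function triggers a slower per-replicate
#'   path.
#' @return An object of class `"bootstrap_draws"` with `scheme = "wild"`.
#' @export
wild_bootstrap <- function(data, est, hyp, B = 2000, seed = NULL,
                           weight_dist = "normal") {
  stopifnot(inherits(data, "study_data"), inherits(est, "accuracy_estimate"),
            inherits(hyp, "hypothesis_spec"))
  if (data$n1 < 2L || data$n0 < 2L) {
    stop("wild bootstrap needs at least 2 subjects per subgroup", call. = FALSE)
  }
  if (B < 100L) stop("`B` must be at least 100", call. = FALSE)
  qq <- correctness(data)
  binding <- wald_statistics(est, hyp)$binding
  R1 <- sweep(qq$Q1, 2L, colMeans(qq$Q1))
  R0 <- sweep(qq$Q0, 2L, colMeans(qq$Q0))
  se_se <- sqrt(est$se_hat * (1 - est$se_hat) / data$n1)
  se_sp <- sqrt(est$sp_hat * (1 - est$sp_hat) / data$n0)

  delta <- function(Rg, ng) {
    if (identical(weight_dist, "normal")) {
      N <- stats::rmultinom(B, ng, rep.int(1, ng))
      A <- sqrt(N) * matrix(stats::rnorm(ng * B), ng, B)
      crossprod(Rg, A) / ng # m x B
    } else if (is.function(weight_dist)) {
      vapply(seq_len(B), function(b) {
        s <- sample.int(ng, ng, replace = TRUE)
        w <- weight_dist(ng)
        colSums(Rg[s, , drop = FALSE] * w) / ng
      }, numeric(ncol(Rg)))
    } else {
      stop("`weight_dist` must be \"normal\" or a function(n)", call. = FALSE)
    }
  }
  res <- with_seed(seed, {
    z_se <- delta(R1, data$n1) / se_se # centred at original estimates
    z_sp <- delta(R0, data$n0) / se_sp
    if (est$m == 1L) { z_se <- matrix(z_se, 1L); z_sp <- matrix(z_sp, 1L) }
    z_bind <- z_se
    z_bind[binding == "sp", ] <- z_sp[binding == "sp", ]
    list(max_stats = col_max(z_bind),
         max_all_stats = pmax(col_max(z_se), col_max(z_sp)))
  })
  structure(
    c(res, list(critical_value = boot_quantile(res$max_stats, hyp$alpha),
                B = B, seed = seed, scheme = "wild")),
    class = "bootstrap_draws"
  )
}
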