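new_copri_fit <- function(data, hypothesis, procedure, estimate, statistics,
                          critical_value, decisions, adjusted_p, diagnostics) {
  structure(
    list(data = data, hypothesis = hypothesis, procedure = procedure,
         estimate = estimate, statistics = statistics,
         critical_value = critical_value, decisions = decisions,
         adjusted_p = adjusted_p, diagnostics = diagnostics),
    class = "copri_fit"
  )
}

PROCEDURES <- c("none", "bonferroni", "maxt", "pairs", "wild", "mbeta")

#' Evaluate multiple index tests against minimal acceptance criteria
#'
#' One-stop interface tying estimation, the co-primary Wald statistics and
#' a multiple comparison procedure together. Available procedures:
#' * `"none"` — unadjusted, critical value \eqn{z_{1-\alpha}};
#' * `"bonferroni"` — \eqn{z_{1-\alpha/m}} (divisor `m`, not `2m`);
#' * `"maxt"` — equicoordinate quantile of an m-variate normal with the
#'   correlation of the binding statistics at the estimated
#'   least-favourable configuration ([estimate_lfc_correlation()]);
#' * `"pairs"`, `"wild"` — bootstrap critical values
#'   ([pairs_bootstrap()], [wild_bootstrap()]);
#' * `"mbeta"` — Bayesian multivariate beta-binomial decisions
#'   ([mbeta_decide()]; no adjusted p-values).
#'
#' @param data a [study_data] object.
#' @param hypothesis a [hypothesis_spec].
#' @param procedure one of `"maxt"`, `"none"`, `"bonferroni"`, `"pairs"`,
#'   `"wild"`, `"mbeta"`.
#' @param shrinkage pseudo-count `h` for [estimate_accuracy()]; default 0.5.
#' @param B bootstrap replicates for the bootstrap procedures.
#' @param seed optional integer seed for procedure-internal randomness
#'   (bootstrap draws, quantile integration, posterior draws).
#' @param maxt_draws Monte-Carlo draws for the maxT quantile.
#' @param weight_dist wild-bootstrap weight distribution, see
#'   [wild_bootstrap()].
#' @param mbeta an [mbeta_config] for `procedure = "mbeta"`.
#' @return An object of class `"copri_fit"`: list with the inputs, the
#'   `estimate`, the `statistics`, the `critical_value`, per-test
#'   `decisions` (1 = co-primary null rejected), `adjusted_p` (NULL for
#'   mbeta), and procedure `diagnostics` (correlation matrix, bootstrap
#'   draws, seeds).
#' @examples
#' cfg <- lfc_config(m = 4, se0 = 0.8, sp0 = 0.8, n1 = 50, n0 = 150)
#' d <- generate_lfc_data(cfg, seed = 1)
#' fit <- evaluate_accuracy(d$data, hypothesis_spec(0.8, 0.8), "maxt", seed = 1)
#' fit$decisions
#' @export
evaluate_accuracy <- function(data, hypothesis,
                              procedure = c("maxt", "none", "bonferroni",
                                            "pairs", "wild", "mbeta"),
                              shrinkage = 0.5, B = 2000, seed = NULL,
                              maxt_draws = 1e5, weight_dist = "normal",
                              mbeta = mbeta_config()) {
  procedure <- match.arg(procedure)
  stopifnot(inherits(data, "study_data"), inherits(hypothesis, "hypothesis_spec"))
  if (procedure == "mbeta") {
    return(mbeta_decide(data, hypothesis, mbeta, seed = seed))
  }
  est <- estimate_accuracy(data, shrinkage)
  stats_ <- wald_statistics(est, hypothesis)
  alpha <- hypothesis$alpha
  diagnostics <- list(seed = seed)
  if (procedure == "none") {
    cv <- critical_value_none(alpha)
  } else if (procedure == "bonferroni") {
    cv <- critical_value_bonferroni(alpha, data$m)
  } else if (procedure == "maxt") {
    Rhat <- estimate_lfc_correlation(data, stats_)
    mx <- mvn_max_sample(Rhat$matrix, maxt_draws, seed)
    cv <- boot_quantile(mx, alpha)
    diagnostics <- c(diagnostics,
                     list(R_hat = Rhat, mvn_max = mx, draws = maxt_draws))
  } else {
    boot <- switch(procedure,
      pairs = pairs_bootstrap(data, est, hypothesis, B = B, seed = seed),
      wild = wild_bootstrap(data, est, hypothesis, B = B, seed = seed,
                            weight_dist = weight_dist))
    cv <- boot$critical_value
    diagnostics <- c(diagnostics, list(bootstrap = boot))
  }
  fit <- new_copri_fit(data, hypothesis, procedure, est, stats_,
                       cv, decide(stats_, cv), NULL, diagnostics)
  fit$adjusted_p <- adjusted_pvalues(fit)
  fit
}

#' Multiplicity-adjusted p-values
#'
#' For the non-Bayesian procedures the adjusted p-value of test `j` is the
#' smallest level at which the procedure rejects:
#' * none — \eqn{1 - \Phi(Z_j)};
#' * bonferroni — \eqn{\min(1, m (1 - \Phi(Z_j)))};
#' * maxt — \eqn{1 - P(\max N(0, \hat R) \le Z_j)}, estimated on the same
#'   fixed-seed Monte-Carlo sample as the critical value, so the duality
#'   `p_j <= alpha` iff rejection is exact;
#' * bootstrap — \eqn{(1 + \#\{b : Z^{*}_{(b)} \ge Z_j\})/(B + 1)}
#'   (add-one convention; duality holds up to that convention).
#'
#' @param fit a `"copri_fit"` from [evaluate_accuracy()].
#' @return Numeric vector of `m` adjusted p-values.
#' @export
adjusted_pvalues <- function(fit) {
  stopifnot(inherits(fit, "copri_fit"))
  z <- fit$statistics$z_min
  m <- fit$data$m
  switch(fit$procedure,
    none = 1 - stats::pnorm(z),
    bonferroni = pmin(1, m * (1 - stats::pnorm(z))),
    maxt = {
      mx <- fit$diagnostics$mvn_max
      vapply(z, function(zj) mean(mx >= zj), numeric(1))
    },
    pairs = ,
    wild = {
      bs <- fit$diagnostics$bootstrap
      vapply(z, function(zj) (1 + sum(bs$max_stats >= zj)) / (bs$B + 1),
             numeric(1))
    },
    mbeta = stop("the mbeta procedure does not provide adjusted p-values",
                 call. = FALSE)
  )
}

#' Per-test results table
#'
#' @param fit a `"copri_fit"`.
#' @param regions logical; append comparison and confidence lower bounds
#'   (not available for `"mbeta"`, whose own bounds are reported instead).
#' @return A data frame with one row per index test.
#' @export
results_table <- function(fit, regions = TRUE) {
  stopifnot(inherits(fit, "copri_fit"))
  est <- fit$estimate
  out <- data.frame(
    test = est$labels,
    se_hat = est$se_hat, sp_hat = est$sp_hat,
    row.names = NULL
  )
  if (!is.null(fit$statistics)) {
    out$z_se <- fit$statistics$z_se
    out$z_sp <- fit$statistics$z_sp
    out$z_min <- fit$statistics$z_min
    out$binding <- fit$statistics$binding
  }
  out$decision <- fit$decisions
  out$adjusted_p <- if (is.null(fit$adjusted_p)) NA_real_ else fit$adjusted_p
  if (regions) {
    if (fit$procedure == "mbeta") {
      out$lb_se_comparison <- fit$diagnostics$lb_se
      out$lb_sp_comparison <- fit$diagnostics$lb_sp
      out$lb_se_confidence <- NA_real_
      out$lb_sp_confidence <- NA_real_
    } else {
      cmp <- comparison_regions(fit)
      cnf <- confidence_regions(fit)
      out$lb_se_comparison <- cmp$lb_se
      out$lb_sp_comparison <- cmp$lb_sp
      out$lb_se_confidence <- cnf$lb_se
      out$lb_sp_confidence <- cnf$lb_sp
    }
  }
  out
}

#' @export
print.copri_fit <- function(x, digits = 4, ...) {
  cat(sprintf("co-primary accuracy evaluation — procedure: %s\n", x$procedure))
  print(x$hypothesis)
  if (!is.na(x$critical_value)) {
    cat(sprintf("critical value: %.4f\n", x$critical_value))
  }
  cat(sprintf("rejected: %d of %d tests\n\n", sum(x$decisions), x$data$m))
  tab <- results_table(x, regions = FALSE)
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], round, digits = digits)
  print(tab, row.names = FALSE)
  invisible(x)
}
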