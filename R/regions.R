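#' One-sided rectangular uncertainty region per test
#'
#' Lower bounds \eqn{\hat{se}_j - c^{*} \sqrt{\hat{se}_j(1-\hat{se}_j)/n_1}}
#' (analogously for specificity with `n0`), clamped below at 0; all upper
#' limits are fixed at 1. `c_star = 0` collapses the region onto the point
#' estimates.
#'
#' @param est an [estimate_accuracy()] result.
#' @param c_star nonnegative quantile multiplier.
#' @return Data frame with columns `test`, `lb_se`, `lb_sp`.
#' @export
rectangle_region <- function(est, c_star) {
  stopifnot(inherits(est, "accuracy_estimate"),
            is.numeric(c_star), length(c_star) == 1L, c_star >= 0)
  lb_se <- est$se_hat - c_star * sqrt(est$se_hat * (1 - est$se_hat) / est$n1)
  lb_sp <- est$sp_hat - c_star * sqrt(est$sp_hat * (1 - est$sp_hat) / est$n0)
  data.frame(test = est$labels,
             lb_se = pmax(0, lb_se), lb_sp = pmax(0, lb_sp),
             row.names = NULL)
}

new_region_set <- function(df, flavor, procedure, c_star, alpha_star, hyp) {
  df$flavor <- flavor
  df$decision <- as.integer(df$lb_se > hyp$se0 & df$lb_sp > hyp$sp0)
  df <- df[, c("test", "flavor", "lb_se", "lb_sp", "decision")]
  structure(df, class = c("region_set", "data.frame"),
            procedure = procedure, c_star = c_star, alpha_star = alpha_star,
            hypothesis = hyp)
}

#' Multiplicity-adjusted comparison regions
#'
#' The comparison region is the uncertainty region dual to the co-primary
#' *test decision*: containment of region `j` in the region of interest
#' `R = \{se > se0, sp > sp0\}` is exactly equivalent to rejection by
#' [decide()]. Because the intersection-union test needs no adjustment for
#' the two endpoints of one test, the effective per-bound level is
#' `alpha/m` for Bonferroni (`alpha` for a single test); the maxT and
#' bootstrap procedures reuse their m-dimensional critical value directly
#' as the quantile multiplier.
#'
#' @param fit a `"copri_fit"` from [evaluate_accuracy()] (any procedure
#'   except `"mbeta"`, whose bounds are part of its own output).
#' @return A `"region_set"` data frame: `test`, `flavor`, `lb_se`, `lb_sp`,
#'   `decision`, with the multiplier in `attr(, "c_star")`.
#' @export
comparison_regions <- function(fit) {
  stopifnot(inherits(fit, "copri_fit"))
  alpha <- fit$hypothesis$alpha
  m <- fit$data$m
  info <- switch(fit$procedure,
    none = list(c = stats::qnorm(1 - alpha), a = alpha),
    bonferroni = list(c = stats::qnorm(1 - alpha / m), a = alpha / m),
    maxt = ,
    pairs = ,
    wild = list(c = fit$critical_value, a = NA_real_),
    mbeta = stop("comparison regions of the mbeta procedure are reported in ",
                 "its own fit (diagnostics$lb_se / lb_sp)", call. = FALSE)
  )
  new_region_set(rectangle_region(fit$estimate, info$c), "comparison",
                 fit$procedure, info$c, info$a, fit$hypothesis)
}

#' Multiplicity-adjusted confidence regions
#'
#' Simultaneous one-sided confidence regions for all `2m` parameters: the
#' Bonferroni adjustment is `alpha/(2m)` because all `2m` parameters must
#' be covered (`alpha/2` for a single unadjusted test); the maxT flavor
#' uses the equicoordinate quantile of the full `2m`-dimensional statistic
#' vector (block-diagonal correlation across the two independent
#' subgroups); the bootstrap flavors use the `1 - alpha` quantile of the
#' maximum over all `2m` centred statistics. Confidence lower bounds are
#' weakly smaller than the comparison lower bounds for the same data and
#' procedure — the comparison region is a subset of the confidence region —
#' so decisions read off confidence regions are more conservative than the
#' dual test decision.
#'
#' @inheritParams comparison_regions
#' @param draws,seed Monte-Carlo settings for the maxT `2m`-dimensional
#'   quantile; default to the values stored in the fit (seed offset by 1
#'   for an independent stream).
#' @return A `"region_set"` data frame, flavor `"confidence"`.
#' @export
confidence_regions <- function(fit, draws = NULL, seed = NULL) {
  stopifnot(inherits(fit, "copri_fit"))
  alpha <- fit$hypothesis$alpha
  m <- fit$data$m
  info <- switch(fit$procedure,
    none = list(c = stats::qnorm(1 - alpha / 2), a = alpha / 2),
    bonferroni = list(c = stats::qnorm(1 - alpha / (2 * m)), a = alpha / (2 * m)),
    maxt = {
      qq <- correctness(fit$data)
      R2 <- diag(2 * m)
      R2[seq_len(m), seq_len(m)] <- safe_cor(qq$Q1)
      R2[m + seq_len(m), m + seq_len(m)] <- safe_cor(qq$Q0)
      draws <- draws %||% fit$diagnostics$draws %||% 1e5
      seed <- seed %||% (if (!is.null(fit$diagnostics$seed))
        fit$diagnostics$seed + 1L)
      list(c = critical_value_maxt(psd_repair(R2), alpha, draws, seed),
           a = NA_real_)
    },
    pairs = ,
    wild = {
      bs <- fit$diagnostics$bootstrap
      list(c = boot_quantile(bs$max_all_stats, alpha), a = NA_real_)
    },
    mbeta = stop("confidence regions are not available for the mbeta procedure",
                 call. = FALSE)
  )
  new_region_set(rectangle_region(fit$estimate, info$c), "confidence",
                 fit$procedure, info$c, info$a, fit$hypothesis)
}

#' Region-based test decisions
#'
#' Decision `j` is 1 iff region `j` is completely contained in the open
#' region of interest, i.e. `lb_se > se0` and `lb_sp > sp0` (strict
#' inequalities; the region of interest is open). For the comparison
#' flavor this reproduces [decide()] exactly; for the confidence flavor it
#' is more conservative.
#'
#' @param region_set a `"region_set"` from [comparison_regions()] or
#'   [confidence_regions()].
#' @param hyp a [hypothesis_spec]; defaults to the one stored in the
#'   region set.
#' @return Integer vector of decisions.
#' @export
region_test <- function(region_set, hyp = attr(region_set, "hypothesis")) {
  stopifnot(inherits(region_set, "region_set"), inherits(hyp, "hypothesis_spec"))
  as.integer(region_set$lb_se > hyp$se0 & region_set$lb_sp > hyp$sp0)
}

#' Plot rectangular regions in the (specificity, sensitivity) plane
#'
#' One panel per region set; the region of interest is shaded, rejected
#' tests are drawn with solid lines, non-rejected ones dashed.
#'
#' @param x a `"region_set"`.
#' @param ... further arguments passed to [plot()].
#' @return `x`, invisibly.
#' @export
plot.region_set <- function(x, ...) {
  hyp <- attr(x, "hypothesis")
  graphics::plot(NA, xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "specificity", ylab = "sensitivity",
                 main = sprintf("%s regions (%s)", x$flavor[1L],
                                attr(x, "procedure")), ...)
  graphics::rect(hyp$sp0, hyp$se0, 1, 1, col = "#d9f2d9", border = NA)
  for (i in seq_len(nrow(x))) {
    graphics::rect(x$lb_sp[i], x$lb_se[i], 1, 1, border = if (x$decision[i])
      "blue" else "darkorange", lty = if (x$decision[i]) 1 else 2)
  }
  graphics::box()
  invisible(x)
}
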