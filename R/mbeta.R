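#' Configuration of the Bayesian multivariate beta-binomial procedure
#'
#' @param prior_a,prior_b Beta prior parameters shared by all 2m accuracy
#'   parameters; the default Beta(1, 1) is the weak, conservative uniform
#'   prior (it shrinks posterior means slightly towards 0.5).
#' @param lfc_pr probability in \[0, 1\] that a least-favourable
#'   configuration occurs; at the default 1 each test is assumed to have
#'   exactly one endpoint at risk of non-coverage, which is what yields
#'   frequentist family-wise error control for the co-primary problem.
#' @param posterior_draws number of joint posterior draws; values below
#'   1000 trigger a warning.
#' @return An object of class `"mbeta_config"`.
#' @export
mbeta_config <- function(prior_a = 1, prior_b = 1, lfc_pr = 1,
                         posterior_draws = 10000) {
  if (prior_a <= 0 || prior_b <= 0) {
    stop("Beta prior parameters must be positive", call. = FALSE)
  }
  if (!is.numeric(lfc_pr) || length(lfc_pr) != 1L || lfc_pr < 0 || lfc_pr > 1) {
    stop("`lfc_pr` must be a probability in [0, 1]", call. = FALSE)
  }
  if (posterior_draws < 1000) {
    warning("fewer than 1000 posterior draws give unstable credible bounds",
            call. = FALSE)
  }
  structure(list(prior_a = prior_a, prior_b = prior_b, lfc_pr = lfc_pr,
                 posterior_draws = posterior_draws),
            class = "mbeta_config")
}

#' Bayesian decisions via a multivariate beta-binomial model
#'
#' Two independent models are fitted for the diseased and non-diseased
#' subgroups. Marginally each accuracy parameter gets the conjugate
#' posterior `Beta(a + x, b + n - x)` with `x` the correct-decision count
#' in the relevant subgroup. The joint posterior is approximated by a
#' Gaussian copula whose latent correlation within a subgroup equals the
#' empirical correlation of the correct-decision indicator columns (blocks
#' across subgroups are independent); this matches the first two moments
#' of the exact multivariate beta-binomial construction, which is not
#' reproduced here.
#'
#' Simultaneous one-sided lower bounds use a common per-parameter quantile
#' level `gamma`: the largest `gamma` is sought (bisection on the fixed
#' draw set) such that the estimated joint posterior probability that all
#' *relevant* parameters exceed their `gamma`-quantile bounds is at least
#' `1 - alpha`. Under an LFC (weight `lfc_pr`) only the binding endpoint
#' per test — the one with the smaller posterior-median margin over its
#' threshold — is relevant; with weight `1 - lfc_pr` all `2m` parameters
#' are. Test `j` is rejected iff both of its lower bounds exceed
#' `(se0, sp0)`. No adjusted p-values are defined for this procedure.
#'
#' @param data a [study_data] object.
#' @param hyp a [hypothesis_spec].
#' @param cfg an [mbeta_config].
#' @param seed optional integer seed for the posterior draws.
#' @return An object of class `"copri_fit"` (see [evaluate_accuracy()])
#'   with `procedure = "mbeta"`; the lower bounds and the selected `gamma`
#'   are in `$diagnostics`.
#' @export
mbeta_decide <- function(data, hyp, cfg = mbeta_config(), seed = NULL) {
  stopifnot(inherits(data, "study_data"), inherits(hyp, "hypothesis_spec"),
            inherits(cfg, "mbeta_config"))
  m <- data$m
  qq <- correctness(data)
  x <- unname(c(colSums(qq$Q1), colSums(qq$Q0)))
  n <- rep(c(data$n1, data$n0), each = m)
  a_post <- cfg$prior_a + x
  b_post <- cfg$prior_b + n - x

  # latent copula correlation: block-diagonal over the two subgroups
  R <- diag(2 * m)
  R[seq_len(m), seq_len(m)] <- safe_cor(qq$Q1)
  R[m + seq_len(m), m + seq_len(m)] <- safe_cor(qq$Q0)
  R <- psd_repair(R)

  theta <- with_seed(seed, {
    U <- chol(R)
    Z <- matrix(stats::rnorm(cfg$posterior_draws * 2 * m),
                cfg$posterior_draws) %*% U
    P <- stats::pnorm(Z)
    for (j in seq_len(2 * m)) P[, j] <- stats::qbeta(P[, j], a_post[j], b_post[j])
    P
  })

  med <- stats::qbeta(0.5, a_post, b_post)
  margin_se <- med[seq_len(m)] - hyp$se0
  margin_sp <- med[m + seq_len(m)] - hyp$sp0
  binding_idx <- ifelse(margin_sp < margin_se, m + seq_len(m), seq_len(m))

  coverage <- function(gamma) {
    q <- stats::qbeta(gamma, a_post, b_post)
    above <- sweep(theta, 2L, q, ">")
    cov_b <- mean(rowSums(above[, binding_idx, drop = FALSE]) == m)
    if (cfg$lfc_pr == 1) return(cov_b)
    cov_all <- mean(rowSums(above) == 2 * m)
    cfg$lfc_pr * cov_b + (1 - cfg$lfc_pr) * cov_all
  }
  lo <- 0; hi <- 1 # coverage is non-increasing in gamma; keep coverage >= 1 - alpha
  for (it in 1:50) {
    mid <- (lo + hi) / 2
    if (coverage(mid) >= 1 - hyp$alpha) lo <- mid else hi <- mid
  }
  gamma_star <- lo
  lb <- stats::qbeta(gamma_star, a_post, b_post)
  lb_se <- lb[seq_len(m)]
  lb_sp <- lb[m + seq_len(m)]
  decisions <- as.integer(lb_se > hyp$se0 & lb_sp > hyp$sp0)

  new_copri_fit(
    data = data, hypothesis = hyp, procedure = "mbeta",
    estimate = estimate_accuracy(data),
    statistics = NULL, critical_value = NA_real_,
    decisions = decisions, adjusted_p = NULL,
    diagnostics = list(gamma = gamma_star, lb_se = lb_se, lb_sp = lb_sp,
                       posterior_a = a_post, posterior_b = b_post,
                       copula_correlation = R,
                       posterior_draws = cfg$posterior_draws,
                       lfc_pr = cfg$lfc_pr, seed = seed)
  )
}

# correlation matrix with constant columns entered as 0 (no warning here;
# degenerate columns are expected under LFCs)
safe_cor <- function(Q) {
  m <- ncol(Q)
  if (m == 1L) return(matrix(1, 1, 1))
  sds <- apply(Q, 2L, stats::sd)
  R <- diag(m)
  ok <- which(sds > 0)
  if (length(ok) >= 2L) {
    R[ok, ok] <- stats::cor(Q[, ok, drop = FALSE])
  }
  R
}
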