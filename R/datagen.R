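# standard bivariate normal rectangle probability P(Z1 <= h, Z2 <= k; r),
# by 1-D quadrature of the conditional normal CDF
bvn_prob <- function(h, k, r) {
  if (abs(r) < 1e-14) return(stats::pnorm(h) * stats::pnorm(k))
  s <- sqrt(1 - r^2)
  stats::integrate(function(z) stats::dnorm(z) * stats::pnorm((k - r * z) / s),
                   -Inf, h, rel.tol = 1e-12, abs.tol = 1e-12)$value
}

#' Latent Gaussian correlation matching a binary correlation
#'
#' Dichotomized-Gaussian moment matching: finds the correlation `r` of a
#' standard bivariate normal such that thresholding at the marginal normal
#' quantiles yields binary variables with means `(p1, p2)` and Pearson
#' correlation `rho_binary`. The target joint success probability
#' \eqn{p_{11} = p_1 p_2 + \rho \sqrt{p_1(1-p_1)p_2(1-p_2)}} must respect
#' the Frechet bounds \eqn{[\max(0, p_1+p_2-1), \min(p_1, p_2)]}; otherwise
#' an error reports the attainable correlation range. The root is bracketed
#' on the bivariate-normal rectangle probability and solved to `1e-8`.
#'
#' @param p1,p2 marginal success probabilities in (0, 1).
#' @param rho_binary target Pearson correlation of the binary pair.
#' @return Latent correlation `r` in \[-1, 1\].
#' @examples
#' binary_to_normal_correlation(0.5, 0.5, 0.5) # sin(pi/4) = 0.70711
#' @export
binary_to_normal_correlation <- function(p1, p2, rho_binary) {
  stopifnot(p1 > 0, p1 < 1, p2 > 0, p2 < 1, is.finite(rho_binary))
  if (rho_binary == 0) return(0)
  sd12 <- sqrt(p1 * (1 - p1) * p2 * (1 - p2))
  p11 <- p1 * p2 + rho_binary * sd12
  lo <- max(0, p1 + p2 - 1); hi <- min(p1, p2)
  if (p11 < lo - 1e-12 || p11 > hi + 1e-12) {
    stop(sprintf(
      "binary correlation %.4g is infeasible for marginals (%.4g, %.4g); attainable range is [%.4g, %.4g]",
      rho_binary, p1, p2, (lo - p1 * p2) / sd12, (hi - p1 * p2) / sd12),
      call. = FALSE)
  }
  h <- stats::qnorm(p1); k <- stats::qnorm(p2)
  f <- function(r) bvn_prob(h, k, r) - p11
  eps <- 1e-10
  if (f(1 - eps) <= 0) return(1)   # comonotone boundary
  if (f(-1 + eps) >= 0) return(-1) # countermonotone boundary
  stats::uniroot(f, c(-1 + eps, 1 - eps), tol = 1e-8)$root
}

# n x m standard normal matrix with equicorrelation r >= 0 (one-factor
# construction: exact marginals and pairwise correlation)
equicorr_normal <- function(n, m, r) {
  E <- matrix(stats::rnorm(n * m), n, m)
  if (m == 1L || r == 0) return(E)
  sqrt(r) * matrix(stats::rnorm(n), n, m) + sqrt(1 - r) * E
}

truth_table <- function(se_true, sp_true, se0, sp0, labels = NULL) {
  m <- length(se_true)
  labels <- labels %||% paste0("test", seq_len(m))
  structure(
    data.frame(test = labels, se_true = se_true, sp_true = sp_true,
               null = se_true <= se0 | sp_true <= sp0, row.names = NULL),
    class = c("truth_table", "data.frame"), se0 = se0, sp0 = sp0)
}

# recompute the null classification against (possibly different) hypothesis
# thresholds; generator and analysis thresholds are independent by design
set_null_mask <- function(truth, hyp) {
  truth$null <- truth$se_true <= hyp$se0 | truth$sp_true <= hyp$sp0
  attr(truth, "se0") <- hyp$se0
  attr(truth, "sp0") <- hyp$sp0
  truth
}

#' Least-favourable configuration (LFC) generator settings
#'
#' Describes `m` index tests whose correctness indicators are multivariate
#' binary with, per test `j`, either sensitivity (`b_j = 1`) or specificity
#' (`b_j = 0`) exactly at its acceptance boundary and the other parameter
#' equal to 1 — the configuration maximizing the family-wise error rate.
#' Equicorrelation `rho_se` (`rho_sp`) holds among the non-degenerate
#' sensitivity (specificity) indicators; parameters equal to 1 produce
#' constant columns and are excluded from the correlation system. The
#' latent Gaussian correlations are moment-matched at construction time.
#'
#' The default `b` alternates `(1, 0, 1, 0, ...)`, balancing the two
#' endpoints across tests.
#'
#' @param m number of index tests.
#' @param se0,sp0 boundary values in (0, 1).
#' @param n1,n0 diseased / non-diseased group sizes.
#' @param b binary vector of length `m` selecting the boundary endpoint.
#' @param rho_se,rho_sp equicorrelations in \[0, 1) among the
#'   non-degenerate indicators; default 0.5.
#' @return An object of class `"lfc_config"`.
#' @export
lfc_config <- function(m, se0, sp0, n1, n0,
                       b = rep(c(1, 0), length.out = m),
                       rho_se = 0.5, rho_sp = 0.5) {
  stopifnot(m >= 1, length(b) == m, all(b %in% c(0, 1)),
            se0 > 0, se0 < 1, sp0 > 0, sp0 < 1,
            rho_se >= 0, rho_se < 1, rho_sp >= 0, rho_sp < 1,
            n1 >= 1, n0 >= 1)
  structure(
    list(m = m, se0 = se0, sp0 = sp0, n1 = n1, n0 = n0, b = as.integer(b),
         rho_se = rho_se, rho_sp = rho_sp,
         latent_rho_se = binary_to_normal_correlation(se0, se0, rho_se),
         latent_rho_sp = binary_to_normal_correlation(sp0, sp0, rho_sp)),
    class = "lfc_config")
}

#' Generate a study dataset at a least-favourable configuration
#'
#' Two independent correctness matrices are drawn: `Q1` (`n1 x m`, cases)
#' and `Q0` (`n0 x m`, controls). Columns whose true parameter is 1 are
#' constant; the remaining columns are dichotomized equicorrelated latent
#' Gaussians with exact marginals at the boundary value and pairwise binary
#' correlation `rho_se` / `rho_sp`. Test results are reconstructed via
#' `T = Q` for cases and `T = 1 - Q` for controls (a correct decision on a
#' control is a negative test). Every test is a true null under the
#' generating thresholds.
#'
#' @param cfg an [lfc_config].
#' @param seed optional integer seed.
#' @return List with `data` (a [study_data]) and `truth` (a truth table
#'   with columns `test`, `se_true`, `sp_true`, `null`).
#' @export
generate_lfc_data <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "lfc_config"))
  m <- cfg$m
  idx_se <- which(cfg$b == 1L) # sensitivity at boundary se0, specificity 1
  idx_sp <- which(cfg$b == 0L)
  with_seed(seed, {
    Q1 <- matrix(1L, cfg$n1, m)
    Q0 <- matrix(1L, cfg$n0, m)
    if (length(idx_se)) {
      Z <- equicorr_normal(cfg$n1, length(idx_se), cfg$latent_rho_se)
      Q1[, idx_se] <- (Z <= stats::qnorm(cfg$se0)) * 1L
    }
    if (length(idx_sp)) {
      Z <- equicorr_normal(cfg$n0, length(idx_sp), cfg$latent_rho_sp)
      Q0[, idx_sp] <- (Z <= stats::qnorm(cfg$sp0)) * 1L
    }
    tests <- rbind(Q1, 1L - Q0)
    data <- study_data(rep(c(1L, 0L), c(cfg$n1, cfg$n0)), tests)
    truth <- truth_table(se_true = ifelse(cfg$b == 1L, cfg$se0, 1),
                         sp_true = ifelse(cfg$b == 1L, 1, cfg$sp0),
                         cfg$se0, cfg$sp0, labels = data$labels)
    list(data = data, truth = truth)
  })
}

#' Mean separation of a binormal marker achieving a target AUC
#'
#' In the binormal ROC model (marker standard normal in controls, normal
#' with unit variance and mean `mu` in cases) the AUC is
#' \eqn{\Phi(\mu/\sqrt{2})}, hence \eqn{\mu = \sqrt{2}\,\Phi^{-1}(AUC)}.
#'
#' @param auc target area under the ROC curve, in (0, 1).
#' @return Mean separation `mu`.
#' @examples
#' auc_to_mean(0.8) # 1.19023
#' @export
auc_to_mean <- function(auc) {
  stopifnot(all(auc > 0), all(auc < 1))
  sqrt(2) * stats::qnorm(auc)
}

#' Biomarker generator settings (multivariate binormal ROC model)
#'
#' `l` continuous markers are multivariate normal with unit variances:
#' mean 0 in controls, mean `auc_to_mean(auc_k)` in cases, and a common
#' equicorrelation in both groups. Each index test dichotomizes one marker
#' at one cut point: `T_j = 1(V_{k_j} > c_j)`; several cut points per
#' marker are allowed (`m >= l` tests), and nearby cut points on the same
#' marker induce highly correlated decisions.
#'
#' @param l number of markers.
#' @param auc target AUCs, recycled to length `l`; each in (0.5, 1).
#' @param cutpoints data frame with columns `marker` (index in `1..l`) and
#'   `cut` (finite threshold); one row per index test.
#' @param n1,n0 group sizes.
#' @param se0,sp0 acceptance boundaries used to classify true nulls.
#' @param marker_correlation equicorrelation of the markers in both
#'   groups, in \[0, 1).
#' @return An object of class `"biomarker_config"`.
#' @export
biomarker_config <- function(l, auc, cutpoints, n1, n0, se0, sp0,
                             marker_correlation = 0) {
  auc <- rep_len(auc, l)
  stopifnot(l >= 1, all(auc > 0.5), all(auc < 1),
            is.data.frame(cutpoints), all(c("marker", "cut") %in% names(cutpoints)),
            all(cutpoints$marker %in% seq_len(l)), all(is.finite(cutpoints$cut)),
            marker_correlation >= 0, marker_correlation < 1,
            n1 >= 1, n0 >= 1, se0 > 0, se0 < 1, sp0 > 0, sp0 < 1)
  structure(
    list(l = l, auc = auc, mu1 = auc_to_mean(auc),
         cutpoints = cutpoints, marker_correlation = marker_correlation,
         n1 = n1, n0 = n0, se0 = se0, sp0 = sp0,
         m = nrow(cutpoints)),
    class = "biomarker_config")
}

#' True accuracies of dichotomized binormal markers
#'
#' Per cut point `j` on marker `k_j`:
#' \eqn{se_j = \Phi(\mu_{k_j} - c_j)}, \eqn{sp_j = 1 - \Phi(-c_j)}.
#'
#' @param cfg a [biomarker_config].
#' @return A truth table (`test`, `se_true`, `sp_true`, `null`).
#' @export
true_accuracy_biomarker <- function(cfg) {
  stopifnot(inherits(cfg, "biomarker_config"))
  mu <- cfg$mu1[cfg$cutpoints$marker]
  truth_table(se_true = stats::pnorm(mu - cfg$cutpoints$cut),
              sp_true = 1 - stats::pnorm(-cfg$cutpoints$cut),
              cfg$se0, cfg$sp0)
}

#' Generate a study dataset from the binormal biomarker model
#'
#' Draws `n1` diseased and `n0` healthy marker vectors and dichotomizes
#' them at the configured cut points. Empirical accuracies converge to
#' [true_accuracy_biomarker()] as the sample grows.
#'
#' @param cfg a [biomarker_config].
#' @param seed optional integer seed.
#' @return List with `data` (a [study_data]) and `truth`.
#' @export
generate_biomarker_data <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "biomarker_config"))
  with_seed(seed, {
    V1 <- sweep(equicorr_normal(cfg$n1, cfg$l, cfg$marker_correlation),
                2L, cfg$mu1, "+")
    V0 <- equicorr_normal(cfg$n0, cfg$l, cfg$marker_correlation)
    V <- rbind(V1, V0)
    tests <- vapply(seq_len(cfg$m), function(j) {
      (V[, cfg$cutpoints$marker[j]] > cfg$cutpoints$cut[j]) * 1L
    }, integer(cfg$n1 + cfg$n0))
    data <- study_data(rep(c(1L, 0L), c(cfg$n1, cfg$n0)), tests)
    truth <- true_accuracy_biomarker(cfg)
    truth$test <- data$labels
    list(data = data, truth = truth)
  })
}

#' Quantiles of the pooled (mixture) marker distribution
#'
#' Cut points for simulation scenarios are often placed at quantiles of
#' the *pooled* marker distribution, the two-component normal mixture
#' `prevalence * N(mu, 1) + (1 - prevalence) * N(0, 1)`. This solves the
#' mixture CDF for the requested probabilities (theoretical quantiles, so
#' the induced true accuracies are identical across simulated datasets).
#'
#' @param auc marker AUC (scalar), giving `mu = auc_to_mean(auc)`.
#' @param prevalence case fraction `n1 / (n1 + n0)`.
#' @param probs quantile levels.
#' @return Numeric vector of cut points.
#' @export
pooled_marker_quantiles <- function(auc, prevalence, probs) {
  stopifnot(auc > 0.5, auc < 1, prevalence > 0, prevalence < 1,
            all(probs > 0), all(probs < 1))
  mu <- auc_to_mean(auc)
  cdf <- function(q) prevalence * stats::pnorm(q - mu) +
    (1 - prevalence) * stats::pnorm(q)
  vapply(probs, function(p) {
    stats::uniroot(function(q) cdf(q) - p, c(-10, mu + 10), tol = 1e-10)$root
  }, numeric(1))
}
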