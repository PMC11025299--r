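#' Monte-Carlo standard error of an estimated proportion
#'
#' @param p estimated proportion in \[0, 1\].
#' @param nsim number of simulation replicates.
#' @return \eqn{\sqrt{p(1-p)/nsim}}.
#' @examples
#' mc_se(0.5, 10000) # 0.005
#' @export
mc_se <- function(p, nsim) {
  stopifnot(all(p >= 0), all(p <= 1), nsim >= 1)
  sqrt(p * (1 - p) / nsim)
}

#' Classify a replicate's rejections against the generating truth
#'
#' A rejection of test `j` is *false* iff `j` is a true null in the truth
#' table. Returns the two indicators feeding the family-wise error rate
#' (any false rejection) and the disjunctive power (any rejection of a
#' false null).
#'
#' @param decisions integer/logical vector of per-test decisions.
#' @param truth a truth table with logical column `null`.
#' @return Logical vector `c(any_false_rejection, any_true_rejection)`.
#' @export
classify_rejections <- function(decisions, truth) {
  stopifnot(length(decisions) == nrow(truth))
  rej <- decisions == 1
  c(any_false_rejection = any(rej & truth$null),
    any_true_rejection = any(rej & !truth$null))
}

#' Define a simulation scenario
#'
#' Bundles a data-generating configuration, the hypothesis settings, the
#' procedures under comparison, and the Monte-Carlo design. All procedures
#' are applied to the exact same synthetic datasets. The generator and the
#' hypothesis thresholds are independent: power scenarios are obtained by
#' generating at one boundary and testing against lower acceptance
#' criteria.
#'
#' Seed protocol: replicate `r` draws its dataset from `base_seed + r`;
#' procedure-internal randomness (bootstrap draws, maxT quantile
#' integration, posterior draws) uses the independent stream
#' `base_seed + 1e6 + r + 3e7 * (procedure index)` with the index taken in
#' the canonical order none, bonferroni, maxt, pairs, wild, mbeta — so
#' results do not depend on the order in which procedures are requested.
#'
#' @param generator an [lfc_config] or [biomarker_config].
#' @param hypothesis a [hypothesis_spec].
#' @param procedures character vector from `"none"`, `"bonferroni"`,
#'   `"maxt"`, `"pairs"`, `"wild"`, `"mbeta"`.
#' @param nsim number of replicates (>= 1).
#' @param base_seed integer base seed.
#' @param B bootstrap replicates per fitted bootstrap procedure.
#' @param shrinkage estimation pseudo-count `h`.
#' @param maxt_draws Monte-Carlo draws per maxT quantile; the default
#'   `2e4` keeps the per-replicate quantile noise (~0.015) negligible
#'   against the Monte-Carlo error of the simulation itself.
#' @param mbeta an [mbeta_config].
#' @param weight_dist wild-bootstrap weight distribution.
#' @return An object of class `"sim_scenario"`.
#' @export
sim_scenario <- function(generator, hypothesis, procedures = "maxt",
                         nsim = 1000, base_seed = 1, B = 1000,
                         shrinkage = 0.5, maxt_draws = 2e4,
                         mbeta = mbeta_config(), weight_dist = "normal") {
  stopifnot(inherits(generator, "lfc_config") ||
              inherits(generator, "biomarker_config"),
            inherits(hypothesis, "hypothesis_spec"),
            all(procedures %in% PROCEDURES), nsim >= 1)
  structure(
    list(generator = generator, hypothesis = hypothesis,
         procedures = procedures, nsim = as.integer(nsim),
         base_seed = as.integer(base_seed), B = B, shrinkage = shrinkage,
         maxt_draws = maxt_draws, mbeta = mbeta, weight_dist = weight_dist),
    class = "sim_scenario")
}

# decisions of one procedure on one dataset, sharing est/stats
proc_decisions <- function(proc, data, est, stats_, hyp, scn, seed) {
  switch(proc,
    none = decide(stats_, critical_value_none(hyp$alpha)),
    bonferroni = decide(stats_, critical_value_bonferroni(hyp$alpha, data$m)),
    maxt = {
      Rhat <- suppressWarnings(estimate_lfc_correlation(data, stats_))
      decide(stats_, critical_value_maxt(Rhat, hyp$alpha,
                                         draws = scn$maxt_draws, seed = seed))
    },
    pairs = decide(stats_, pairs_bootstrap(data, est, hyp, B = scn$B,
                                           seed = seed)$critical_value),
    wild = decide(stats_, wild_bootstrap(data, est, hyp, B = scn$B,
                                         seed = seed,
                                         weight_dist = scn$weight_dist)$critical_value),
    mbeta = mbeta_decide(data, hyp, scn$mbeta, seed = seed)$decisions
  )
}

#' Run a simulation scenario
#'
#' Estimates the family-wise error rate (probability of at least one false
#' rejection among the true nulls) and the disjunctive power (probability
#' of at least one rejection of a false null) for every requested
#' procedure, with Monte-Carlo standard errors. When the scenario contains
#' no false null (e.g. any LFC scenario) power is reported as `NA`;
#' likewise the FWER when there is no true null. Replicates on which a
#' procedure fails are counted in `n_failed` and excluded from that
#' procedure's aggregates, never silently dropped.
#'
#' @param scn a [sim_scenario].
#' @param keep_decisions logical; additionally return the full
#'   `nsim x m x procedures` decision array (memory permitting).
#' @param verbose print progress every 500 replicates.
#' @return An object of class `"sim_result"`: data frame with one row per
#'   procedure (`procedure`, `fwer`, `fwer_se`, `power`, `power_se`,
#'   `n_used`, `n_failed`), the scenario in `attr(, "scenario")`.
#' @export
run_scenario <- function(scn, keep_decisions = FALSE, verbose = FALSE) {
  stopifnot(inherits(scn, "sim_scenario"))
  procs <- scn$procedures
  gen <- if (inherits(scn$generator, "lfc_config")) generate_lfc_data
         else generate_biomarker_data
  proc_offset <- (match(procs, PROCEDURES) - 1L) * 3e7
  nf <- nt <- used <- fail <- stats::setNames(numeric(length(procs)), procs)
  dec_arr <- if (keep_decisions)
    array(NA_integer_, c(scn$nsim, scn$generator$m, length(procs)),
          dimnames = list(NULL, NULL, procs))
  truth <- NULL
  for (r in seq_len(scn$nsim)) {
    sim <- gen(scn$generator, seed = scn$base_seed + r)
    truth <- set_null_mask(sim$truth, scn$hypothesis)
    est <- estimate_accuracy(sim$data, scn$shrinkage)
    stats_ <- wald_statistics(est, scn$hypothesis)
    for (k in seq_along(procs)) {
      seed_k <- scn$base_seed + 1e6 + r + proc_offset[k]
      dec <- tryCatch(
        proc_decisions(procs[k], sim$data, est, stats_, scn$hypothesis,
                       scn, seed_k),
        error = function(e) NULL)
      if (is.null(dec)) { fail[k] <- fail[k] + 1; next }
      cls <- classify_rejections(dec, truth)
      nf[k] <- nf[k] + cls[1L]
      nt[k] <- nt[k] + cls[2L]
      used[k] <- used[k] + 1
      if (keep_decisions) dec_arr[r, , k] <- dec
    }
    if (verbose && r %% 500L == 0L) {
      message(sprintf("replicate %d / %d", r, scn$nsim))
    }
  }
  has_null <- any(truth$null)
  has_alt <- any(!truth$null)
  fwer <- if (has_null) nf / pmax(used, 1) else rep(NA_real_, length(procs))
  power <- if (has_alt) nt / pmax(used, 1) else rep(NA_real_, length(procs))
  out <- data.frame(
    procedure = procs,
    fwer = fwer, fwer_se = mc_se(ifelse(is.na(fwer), 0, fwer), pmax(used, 1)),
    power = power, power_se = mc_se(ifelse(is.na(power), 0, power), pmax(used, 1)),
    n_used = used, n_failed = fail, row.names = NULL)
  out$fwer_se[is.na(fwer)] <- NA_real_
  out$power_se[is.na(power)] <- NA_real_
  structure(out, class = c("sim_result", "data.frame"),
            scenario = scn, truth = truth,
            decisions = if (keep_decisions) dec_arr)
}

#' @export
print.sim_result <- function(x, digits = 4, ...) {
  scn <- attr(x, "scenario")
  cat(sprintf("simulation result: nsim = %d, base_seed = %d\n",
              scn$nsim, scn$base_seed))
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], round, digits = digits)
  print(y, row.names = FALSE)
  invisible(x)
}
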