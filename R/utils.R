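# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a local RNG seed
#'
#' Restores the caller's RNG state afterwards, so seeded routines do not
#' disturb an enclosing simulation stream. `seed = NULL` uses (and advances)
#' the current stream.
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1) # initialize RNG state so it can be restored
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# row-wise maximum of a numeric matrix; m is small so a pmax sweep is fast
row_max <- function(x) {
  out <- x[, 1L]
  if (ncol(x) > 1L) for (j in 2L:ncol(x)) out <- pmax(out, x[, j])
  out
}

# column-wise maximum (used for B bootstrap replicates stored as m x B)
col_max <- function(x) {
  out <- x[1L, ]
  if (nrow(x) > 1L) for (i in 2L:nrow(x)) out <- pmax(out, x[i, ])
  out
}

# conservative empirical upper quantile: order statistic of rank
# ceiling((1-alpha) * B)
boot_quantile <- function(x, alpha) {
  b <- length(x)
  stopifnot(b >= 1L, alpha > 0, alpha < 1)
  sort(x)[ceiling((1 - alpha) * b)]
}

# clip eigenvalues and restore unit diagonal so a finite-sample correlation
# estimate (possibly indefinite after zero-filling cross-subgroup blocks)
# becomes a valid correlation matrix
psd_repair <- function(R, eps = 1e-8) {
  ev <- eigen(R, symmetric = TRUE)
  if (min(ev$values) >= eps) return(R)
  R2 <- ev$vectors %*% (pmax(ev$values, eps) * t(ev$vectors))
  stats::cov2cor(R2)
}

# column variances without the matrixStats dependency
col_vars <- function(x) {
  n <- nrow(x)
  if (n < 2L) return(rep(0, ncol(x)))
  (colSums(x^2) - n * colMeans(x)^2) / (n - 1)
}

check_alpha <- function(alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha <= 0 || alpha >= 0.5) {
    stop("`alpha` must be a single one-sided level in (0, 0.5)", call. = FALSE)
  }
  alpha
}
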