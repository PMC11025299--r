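# fixture builders used across test files

# small deterministic dataset: counts chosen directly
make_counts_data <- function(n11, n1, n00, n0) {
  m <- length(n11)
  stopifnot(length(n00) == m)
  t1 <- vapply(seq_len(m), function(j) rep(c(1L, 0L), c(n11[j], n1 - n11[j])),
               integer(n1))
  t0 <- vapply(seq_len(m), function(j) rep(c(0L, 1L), c(n00[j], n0 - n00[j])),
               integer(n0))
  study_data(rep(c(1L, 0L), c(n1, n0)), rbind(t1, t0))
}

# random binary dataset with interior accuracies (no degenerate columns
# with overwhelming probability at these sizes)
random_fixture <- function(seed, m = 3, n1 = 60, n0 = 120,
                           se = 0.85, sp = 0.75) {
  withr_seed <- function(code) { set.seed(seed); code }
  withr_seed({
    t1 <- matrix(rbinom(n1 * m, 1, se), n1, m)
    t0 <- matrix(rbinom(n0 * m, 1, 1 - sp), n0, m)
    study_data(rep(c(1L, 0L), c(n1, n0)), rbind(t1, t0))
  })
}

default_hyp <- function(alpha = 0.025) hypothesis_spec(0.8, 0.7, alpha)
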