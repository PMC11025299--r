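#' Subject-level data of a diagnostic accuracy study
#'
#' Container for a within-subject comparison of `m` binary index tests
#' against a binary reference standard. Each subject contributes one
#' disease-status indicator `D` (1 = diseased, 0 = non-diseased, as
#' determined by the reference standard) and one result per index test
#' (1 = test-positive, 0 = test-negative).
#'
#' Missing values are rejected outright: the within-subject design assumes
#' complete data, and pairwise deletion would break the correlation
#' structure the resampling procedures rely on.
#'
#' @param disease integer/numeric vector of 0/1 disease-status indicators.
#' @param tests numeric matrix (or data frame) with one row per subject and
#'   one 0/1 column per index test.
#' @param labels optional character vector of test labels; defaults to the
#'   column names of `tests` or `"test1"`, `"test2"`, ....
#'
#' @return An object of class `"study_data"`: a list with elements
#'   `disease`, `tests` (integer matrix with labelled columns), `labels`,
#'   and the group sizes `n`, `n1` (diseased), `n0` (non-diseased), `m`.
#' @examples
#' d <- study_data(c(1, 1, 1, 0, 0, 0),
#'                 cbind(A = c(1, 1, 0, 0, 1, 0), B = c(1, 0, 1, 0, 0, 0)))
#' d$n1
#' @export
study_data <- function(disease, tests, labels = NULL) {
  if (is.data.frame(tests)) tests <- as.matrix(tests)
  if (!is.matrix(tests)) tests <- matrix(tests, ncol = 1L)
  disease <- as.vector(disease)
  if (anyNA(disease) || anyNA(tests)) {
    stop("missing values are not allowed in study data", call. = FALSE)
  }
  if (!all(disease %in% c(0, 1)) || !all(tests %in% c(0, 1))) {
    stop("disease status and test results must be coded 0/1", call. = FALSE)
  }
  if (length(disease) != nrow(tests)) {
    stop("`disease` and `tests` must describe the same subjects", call. = FALSE)
  }
  n1 <- sum(disease == 1)
  n0 <- sum(disease == 0)
  if (n1 < 1L || n0 < 1L) {
    stop("both the diseased and the non-diseased group must be non-empty",
         call. = FALSE)
  }
  m <- ncol(tests)
  labels <- labels %||% colnames(tests) %||% paste0("test", seq_len(m))
  if (length(labels) != m) stop("need one label per test", call. = FALSE)
  storage.mode(tests) <- "integer"
  colnames(tests) <- labels
  structure(
    list(disease = as.integer(disease), tests = tests, labels = labels,
         n = n1 + n0, n1 = n1, n0 = n0, m = m),
    class = "study_data"
  )
}

#' @export
print.study_data <- function(x, ...) {
  cat(sprintf(
    "study_data: %d subjects (%d diseased, %d non-diseased), %d index test%s\n",
    x$n, x$n1, x$n0, x$m, if (x$m == 1L) "" else "s"))
  invisible(x)
}

# Correct-decision indicator matrices Q (1 = test decision agrees with the
# reference standard): among the diseased a correct decision is a positive
# test, among the non-diseased a negative one.
correctness <- function(data) {
  list(Q1 = data$tests[data$disease == 1L, , drop = FALSE],
       Q0 = 1L - data$tests[data$disease == 0L, , drop = FALSE])
}

#' Read a study dataset from CSV
#'
#' Expects a header row whose first column is `disease` (0/1) followed by
#' one 0/1 column per index test.
#'
#' @param path path to a comma-separated UTF-8 file.
#' @return A [study_data] object.
#' @export
read_study_data <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- tryCatch(utils::read.csv(path, check.names = FALSE),
                 error = function(e) {
                   stop("malformed CSV '", path, "': ", conditionMessage(e),
                        call. = FALSE)
                 })
  if (ncol(df) < 2L || names(df)[1L] != "disease") {
    stop("'", path, "': first column must be named 'disease', ",
         "followed by one column per index test", call. = FALSE)
  }
  for (j in seq_along(df)) {
    bad <- which(!(df[[j]] %in% c(0, 1)))
    if (length(bad)) {
      stop(sprintf("'%s': column '%s', line %d: value is not 0/1",
                   path, names(df)[j], bad[1L] + 1L), call. = FALSE)
    }
  }
  study_data(df[[1L]], as.matrix(df[-1L]))
}

#' Write a study dataset to CSV
#'
#' Inverse of [read_study_data()]; the round trip is lossless.
#' @param data a [study_data] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_study_data <- function(data, path) {
  df <- data.frame(disease = data$disease, data$tests, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
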