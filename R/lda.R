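# Two-class linear discriminant core. A candidate with characteristics x is
# scored Z = a.x and called a true site when Z exceeds the threshold; the
# coefficients a = s^-1 (m1 - m2) and threshold c = a.(m1 + m2)/2 come from
# the class means and the pooled covariance s. The Mahalanobis distance
# D^2 = (m1 - m2)' s^-1 (m1 - m2) measures the separating power of a feature
# set and drives stepwise selection.

pooled_covariance <- function(X1, X2) {
  n1 <- nrow(X1); n2 <- nrow(X2)
  s1 <- stats::cov(X1); s2 <- stats::cov(X2)
  ((n1 - 1) * s1 + (n2 - 1) * s2) / (n1 + n2 - 2)
}

# Solve s %*% x = b with a ridge fallback for singular pooled covariance:
# retry with eps*I added, eps = 1e-8 * trace / p.
solve_pooled <- function(s, b) {
  out <- tryCatch(solve(s, b), error = function(e) NULL)
  if (is.null(out)) {
    eps <- 1e-8 * sum(diag(s)) / ncol(s)
    warning("singular pooled covariance; retrying with ridge eps = ",
            format(eps), call. = FALSE)
    out <- tryCatch(solve(s + diag(eps, ncol(s)), b),
                    error = function(e)
                      stop("pooled covariance singular even after ",
                           "regularization", call. = FALSE))
  }
  out
}

#' Train a two-class linear discriminant function
#'
#' Coefficients `a = s^-1 (m1 - m2)` with `s` the pooled (unbiased-weighted)
#' covariance, threshold `c = a . (m1 + m2) / 2`, and Mahalanobis
#' `D^2 = (m1 - m2)' s^-1 (m1 - m2)`. A singular pooled covariance is
#' retried with a small ridge (`1e-8 * trace/p` on the diagonal) and a
#' warning.
#'
#' @param X1 numeric matrix of Class-1 (true site) feature vectors, one row
#'   per observation.
#' @param X2 numeric matrix of Class-2 (false site) feature vectors with the
#'   same columns.
#' @param class_label optional site-class label stored with the model.
#' @param feature_names column names; defaults to `colnames(X1)`.
#' @return object of class `ldf_model`: `a`, `c`, `d_squared`,
#'   `operating_threshold` (defaults to `c`), `feature_names`,
#'   `class_label`, `n1`, `n2`.
#' @export
train_ldf <- function(X1, X2, class_label = NA_character_,
                      feature_names = colnames(X1)) {
  X1 <- as.matrix(X1); X2 <- as.matrix(X2)
  if (nrow(X1) < 2L || nrow(X2) < 2L)
    stop("each class needs at least 2 training vectors")
  if (ncol(X1) != ncol(X2)) stop("class matrices differ in column count")
  if (is.null(feature_names)) feature_names <- paste0("x", seq_len(ncol(X1)))
  m1 <- colMeans(X1); m2 <- colMeans(X2)
  s <- pooled_covariance(X1, X2)
  dm <- m1 - m2
  a <- drop(solve_pooled(s, dm))
  structure(list(class_label = class_label, feature_names = feature_names,
                 a = unname(a), c = unname(sum(a * (m1 + m2)) / 2),
                 d_squared = unname(sum(dm * a)),
                 operating_threshold = unname(sum(a * (m1 + m2)) / 2),
                 n1 = nrow(X1), n2 = nrow(X2)),
            class = "ldf_model")
}

#' @export
print.ldf_model <- function(x, ...) {
  cat(sprintf("<ldf_model> %s: %d features, D^2 = %.3f, c = %.4f (n1=%d, n2=%d)\n",
              x$class_label, length(x$a), x$d_squared, x$c, x$n1, x$n2))
  invisible(x)
}

#' Score a feature vector under a trained discriminant
#'
#' `z = a . x`; the candidate is Class 1 (true site) when
#' `z > operating_threshold`, Class 2 otherwise (the boundary `z = c` is
#' Class 2).
#'
#' @param model an `ldf_model`.
#' @param x numeric vector matching `model$feature_names` (names checked
#'   when present).
#' @return list with `z` and `is_class1`.
#' @export
ldf_score <- function(model, x) {
  if (length(x) != length(model$a))
    stop("feature vector length does not match model schema")
  if (!is.null(names(x)) && !identical(unname(names(x)),
                                       unname(model$feature_names)))
    stop("feature vector names do not match model schema")
  z <- sum(model$a * as.numeric(x))
  list(z = z, is_class1 = z > model$operating_threshold)
}

#' Mahalanobis distance between two classes on a feature subset
#'
#' @param X1,X2 feature matrices as in [train_ldf()].
#' @param feature_subset column names (or indices) to restrict to; default
#'   all columns.
#' @return `D^2` on the restricted columns.
#' @export
mahalanobis_d2 <- function(X1, X2, feature_subset = colnames(X1)) {
  X1 <- as.matrix(X1); X2 <- as.matrix(X2)
  if (is.null(feature_subset)) feature_subset <- seq_len(ncol(X1))
  if (length(feature_subset) == 0L) stop("feature subset must be non-empty")
  X1 <- X1[, feature_subset, drop = FALSE]
  X2 <- X2[, feature_subset, drop = FALSE]
  dm <- colMeans(X1) - colMeans(X2)
  s <- pooled_covariance(X1, X2)
  unname(sum(dm * drop(solve_pooled(s, dm))))
}

#' Greedy stepwise feature selection by Mahalanobis distance
#'
#' Forward selection: at each step the candidate feature whose addition
#' maximizes `D^2` is added; selection stops when the relative gain drops
#' below `min_relative_gain` or candidates are exhausted.
#'
#' @param X1,X2 feature matrices as in [train_ldf()].
#' @param candidate_features column names to consider; default all.
#' @param min_relative_gain stop when `(D2_new - D2_old)/D2_old` falls below
#'   this (first feature is always taken).
#' @return data.frame with columns `feature` and `d_squared` (cumulative),
#'   one row per selected feature, in selection order.
#' @export
stepwise_select <- function(X1, X2, candidate_features = colnames(X1),
                            min_relative_gain = 0.05) {
  stopifnot(length(candidate_features) >= 1L)
  selected <- character(0)
  trace_d2 <- numeric(0)
  d2_old <- 0
  remaining <- candidate_features
  while (length(remaining) > 0L) {
    d2s <- vapply(remaining, function(f)
      suppressWarnings(mahalanobis_d2(X1, X2, c(selected, f))), 0)
    best <- which.max(d2s)
    d2_new <- d2s[best]
    gain <- if (d2_old > 0) (d2_new - d2_old) / d2_old else Inf
    if (length(selected) > 0L && min_relative_gain > 0 &&
        gain < min_relative_gain) break
    selected <- c(selected, remaining[best])
    trace_d2 <- c(trace_d2, d2_new)
    remaining <- remaining[-best]
    d2_old <- d2_new
  }
  data.frame(feature = selected, d_squared = trace_d2,
             stringsAsFactors = FALSE)
}

#' Serialize a discriminant model as JSON text
#'
#' Full-precision, loadable bit-exactly by [read_ldf_model()].
#'
#' @param model an `ldf_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ldf_model <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE,
                       digits = I(17), pretty = TRUE, na = "null")
  invisible(path)
}

#' Read a discriminant model written by [write_ldf_model()]
#' @param path JSON path.
#' @return an `ldf_model`.
#' @export
read_ldf_model <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  m$a <- as.numeric(m$a)
  structure(m, class = "ldf_model")
}
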