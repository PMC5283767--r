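#' Partial rank correlation coefficients
#'
#' PRCC measures the monotone association between each input variable and
#' an outcome while controlling for all other inputs. All columns are
#' rank-transformed; for each input, the ranks of that input and of the
#' outcome are each regressed (ordinary least squares) on the ranks of all
#' the other inputs, and the PRCC is the Pearson correlation of the two
#' residual vectors. A value of zero indicates no relationship; values near
#' +1 or -1 indicate a strong monotone influence, and the sign gives the
#' direction.
#'
#' @param X A data frame or matrix of sampled input variables (one column
#'   per variable, one row per run).
#' @param y Numeric outcome vector, `length(y) == nrow(X)`.
#' @return A named numeric vector of coefficients in `[-1, 1]`, one per
#'   column of `X`. A constant input column has no defined coefficient and
#'   is reported as `NA`.
#' @examples
#' set.seed(1)
#' X <- data.frame(a = runif(50), b = runif(50))
#' prcc(X, X$a + 0.1 * rnorm(50))
#' @export
prcc <- function(X, y) {
  X <- as.matrix(X)
  stopifnot(is.numeric(X), length(y) == nrow(X))
  keep <- stats::complete.cases(X, y)
  X <- X[keep, , drop = FALSE]
  y <- y[keep]
  n <- nrow(X)
  if (n < 3L) stop("prcc needs at least 3 complete records")
  rX <- apply(X, 2L, rank)
  ry <- rank(y)
  out <- stats::setNames(rep(NA_real_, ncol(X)), colnames(X))
  for (j in seq_len(ncol(X))) {
    if (stats::sd(rX[, j]) == 0) next  # constant column: undefined
    others <- cbind(1, rX[, -j, drop = FALSE])
    ex <- stats::lm.fit(others, rX[, j])$residuals
    ey <- stats::lm.fit(others, ry)$residuals
    if (stats::sd(ex) == 0 || stats::sd(ey) == 0) next
    out[j] <- stats::cor(ex, ey)
  }
  out
}
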