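#' @keywords internal
"_PACKAGE"

#' @useDynLib atrialep, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median sd rnorm runif approx quantile fft cor
#' @importFrom utils head tail
NULL

.assert <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}

#' Trapezoidal integral with uniform or explicit abscissae
#' @noRd
.trapz <- function(x, y = NULL) {
  if (is.null(y)) {
    y <- x
    x <- seq_along(y)
  }
  n <- length(y)
  if (n < 2L) return(0)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

## pairwise Euclidean distances between rows of A (n x 3) and B (m x 3)
.cross_dist <- function(A, B) {
  an <- rowSums(A^2)
  bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  sqrt(d2)
}
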