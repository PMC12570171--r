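## Gaussian radial-basis-function interpolation with leave-one-out
## hyperparameter selection.  Shared by the LAT-map and CV-map stages.

#' Fit a Gaussian RBF interpolant with LOOCV-selected hyperparameters
#'
#' Interpolates scattered values `y` observed at 3-D locations `X` using
#' Gaussian kernels \eqn{\phi(r) = \exp(-(r/\epsilon)^2)}.  The kernel width
#' `epsilon` and the ridge smoothing parameter `lambda` are selected by
#' leave-one-out cross-validation over a logarithmic grid, using the
#' closed-form LOO residuals of the ridge system.
#'
#' @param X numeric matrix (n x 3) of sample locations (mm).
#' @param y numeric vector of length n.
#' @param eps_grid optional vector of candidate kernel widths (mm).
#' @param lambda_grid optional vector of candidate smoothing parameters.
#' @return list with elements `X`, `weights`, `epsilon`, `lambda`,
#'   `loocv_rmse` and a `predict` closure.
#' @export
rbf_fit <- function(X, y, eps_grid = NULL, lambda_grid = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  .assert(n >= 4, "RBF interpolation requires at least 4 points")
  .assert(length(y) == n, "length(y) must match nrow(X)")
  ## collapse exact duplicates (average their values)
  key <- apply(round(X, 9), 1, paste, collapse = ",")
  if (anyDuplicated(key)) {
    y <- tapply(y, key, mean)[unique(key)]
    X <- X[!duplicated(key), , drop = FALSE]
    n <- nrow(X)
  }
  D <- .cross_dist(X, X)
  if (is.null(eps_grid)) {
    nn <- apply(D + diag(Inf, n), 1, min)
    span <- max(D)
    eps_grid <- exp(seq(log(max(median(nn), 1e-6)),
                        log(max(span, 1e-5)), length.out = 8))
  }
  if (is.null(lambda_grid)) lambda_grid <- c(1e-10, 1e-8, 1e-6, 1e-4, 1e-2)
  best <- list(rmse = Inf)
  for (eps in eps_grid) {
    K <- exp(-(D / eps)^2)
    for (lam in lambda_grid) {
      Minv <- tryCatch(solve(K + diag(lam, n)), error = function(e) NULL)
      if (is.null(Minv)) next
      w <- Minv %*% y
      dMi <- diag(Minv)
      if (any(dMi <= 0)) next
      loo <- w / dMi                    # closed-form LOO residuals
      rmse <- sqrt(mean(loo^2))
      if (rmse < best$rmse)
        best <- list(rmse = rmse, eps = eps, lam = lam, w = as.numeric(w))
    }
  }
  if (!is.finite(best$rmse)) {
    ## singular for every candidate: escalate smoothing until solvable
    warning("RBF system ill-conditioned; increasing smoothing")
    lam <- 1
    eps <- stats::median(eps_grid)
    K <- exp(-(D / eps)^2)
    w <- solve(K + diag(lam, n), y)
    best <- list(rmse = NA_real_, eps = eps, lam = lam, w = as.numeric(w))
  }
  fit <- list(X = X, y = y, weights = best$w, epsilon = best$eps,
              lambda = best$lam, loocv_rmse = best$rmse)
  fit$predict <- function(Xnew, support_radius = Inf) {
    Xnew <- as.matrix(Xnew)
    Dn <- .cross_dist(Xnew, fit$X)
    out <- as.numeric(exp(-(Dn / fit$epsilon)^2) %*% fit$weights)
    if (is.finite(support_radius)) {
      out[apply(Dn, 1, min) > support_radius] <- NA_real_
    }
    out
  }
  class(fit) <- "rbf_fit"
  fit
}
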