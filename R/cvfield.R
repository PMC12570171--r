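## Conduction-velocity vector estimation from scattered LATs by local
## quadratic surface fitting, divergence of the CV field, collision-site
## exclusion, RBF magnitude interpolation, and summaries.
##
## Units: coordinates mm, LATs ms.  A LAT gradient of 1 ms/mm equals
## 1 s/m, so speeds come out directly in m/s (= mm/ms); divergences are
## converted from (mm/ms)/mm to 1/s (factor 1000).

#' Configuration for CV estimation
#'
#' @param fit_radius neighborhood radius for the local fit, mm.
#' @param min_neighbors minimum neighborhood size (k-nearest fallback).
#' @param poly_degree polynomial degree of the local LAT surface (1-3).
#' @param div_threshold collision threshold on divergence, 1/s; points with
#'   divergence strictly below it are masked.
#' @param max_physiological_cv QC gate on CV magnitudes, m/s.
#' @param min_grad minimum tangent-plane LAT-gradient norm (ms/mm) below
#'   which CV is undefined (near-simultaneous activation).
#' @export
cv_config <- function(fit_radius = 5, min_neighbors = 8, poly_degree = 2,
                      div_threshold = -1.5, max_physiological_cv = 2.0,
                      min_grad = 1e-3) {
  .assert(poly_degree %in% 1:3, "poly_degree must be 1, 2 or 3")
  n_coef <- (poly_degree + 1) * (poly_degree + 2) / 2
  .assert(min_neighbors >= n_coef,
          sprintf("min_neighbors must be >= %d for degree %d",
                  n_coef, poly_degree))
  structure(as.list(environment()), class = "cv_config")
}

## local PCA tangent basis at a point given neighbor coordinates
.tangent_basis <- function(nb_xyz) {
  C <- sweep(nb_xyz, 2, colMeans(nb_xyz))
  ev <- eigen(crossprod(C), symmetric = TRUE)
  list(e1 = ev$vectors[, 1], e2 = ev$vectors[, 2])
}

.poly_design <- function(u, v, degree) {
  X <- cbind(1, u, v)
  if (degree >= 2) X <- cbind(X, u^2, u * v, v^2)
  if (degree >= 3) X <- cbind(X, u^3, u^2 * v, u * v^2, v^3)
  X
}

#' Fit a local polynomial LAT surface and return its tangent-plane gradient
#'
#' Least-squares fit of T(u, v) (default quadratic) over the neighbors
#' projected onto the local PCA tangent plane; the gradient is evaluated at
#' the point itself (the expansion origin).
#'
#' @param point 3-vector, mm.
#' @param neighbors_xyz neighbor coordinates (k x 3), mm.
#' @param neighbors_lat neighbor LATs, ms.
#' @param cfg a [cv_config()].
#' @return list with `gradient` (2-vector, ms/mm, in the tangent basis),
#'   `basis` (`e1`, `e2`), `condition_number`, and `ok` (FALSE when the
#'   design is rank deficient).
#' @export
fit_local_surface <- function(point, neighbors_xyz, neighbors_lat,
                              cfg = cv_config()) {
  k <- nrow(neighbors_xyz)
  n_coef <- ncol(.poly_design(0, 0, cfg$poly_degree))
  if (k < n_coef)
    return(list(gradient = c(NA_real_, NA_real_), basis = NULL,
                condition_number = Inf, ok = FALSE))
  bas <- .tangent_basis(neighbors_xyz)
  rel <- sweep(neighbors_xyz, 2, point)
  u <- as.numeric(rel %*% bas$e1)
  v <- as.numeric(rel %*% bas$e2)
  X <- .poly_design(u, v, cfg$poly_degree)
  qrX <- qr(X)
  if (qrX$rank < n_coef)
    return(list(gradient = c(NA_real_, NA_real_), basis = bas,
                condition_number = Inf, ok = FALSE))
  beta <- qr.coef(qrX, neighbors_lat)
  kap <- kappa(qr.R(qrX), exact = FALSE)
  list(gradient = c(beta[2], beta[3]), basis = bas,
       condition_number = kap, ok = TRUE)
}

#' Convert a tangent-plane LAT gradient into a CV vector
#'
#' CV = g / ||g||^2 (the inverse gradient), mapped back to 3-D through the
#' tangent basis; speed = 1 / ||g||.
#'
#' @param gradient 2-vector, ms/mm.
#' @param basis tangent basis (`e1`, `e2`); identity-plane default.
#' @param min_grad gradient-norm floor (ms/mm) below which CV is undefined.
#' @return list with `cv` (3-vector, m/s), `speed` (m/s), `ok`.
#' @export
cv_from_gradient <- function(gradient, basis = NULL, min_grad = 1e-3) {
  g2 <- sum(gradient^2)
  if (!is.finite(g2) || sqrt(g2) < min_grad)
    return(list(cv = rep(NA_real_, 3), speed = NA_real_, ok = FALSE))
  gt <- gradient / g2
  if (is.null(basis)) basis <- list(e1 = c(1, 0, 0), e2 = c(0, 1, 0))
  list(cv = gt[1] * basis$e1 + gt[2] * basis$e2,
       speed = 1 / sqrt(g2), ok = TRUE)
}

#' Estimate the CV vector field from scattered LATs
#'
#' @param points_xyz recording-point coordinates (n x 3), mm.
#' @param lats LATs at the points, ms.
#' @param cfg a [cv_config()].
#' @return object of class `cv_field`: `points_xyz`, `cv_vectors` (n x 3,
#'   m/s), `cv_magnitude`, `divergence` (1/s), `collision_mask`, `defined`.
#' @export
cv_field <- function(points_xyz, lats, cfg = cv_config()) {
  P <- as.matrix(points_xyz)
  n <- nrow(P)
  .assert(n >= cfg$min_neighbors + 1, "too few points for CV estimation")
  D <- .cross_dist(P, P)
  cvv <- matrix(NA_real_, n, 3)
  spd <- rep(NA_real_, n)
  bases <- vector("list", n)
  for (i in seq_len(n)) {
    nb <- which(D[i, ] <= cfg$fit_radius & seq_len(n) != i)
    if (length(nb) < cfg$min_neighbors)
      nb <- order(D[i, ])[2:(cfg$min_neighbors + 1)]
    nb <- c(i, nb)       # include the point itself in the fit
    fit <- fit_local_surface(P[i, ], P[nb, , drop = FALSE], lats[nb], cfg)
    bases[[i]] <- fit$basis
    if (!fit$ok) next
    cv <- cv_from_gradient(fit$gradient, fit$basis, cfg$min_grad)
    if (!cv$ok) next
    cvv[i, ] <- cv$cv
    spd[i] <- cv$speed
  }
  div <- cv_divergence(P, cvv, cfg, bases)
  mask <- !is.na(div) & div < cfg$div_threshold   # strict inequality
  structure(list(points_xyz = P, cv_vectors = cvv, cv_magnitude = spd,
                 divergence = div, collision_mask = mask,
                 defined = !is.na(spd)),
            class = "cv_field")
}

#' Divergence of a CV vector field at scattered points
#'
#' Per point: neighbors' CV vectors are projected into the point's tangent
#' basis and each tangential component is fitted linearly in (u, v); the
#' divergence is the sum of the two on-diagonal slopes, converted to 1/s.
#'
#' @param P point coordinates (n x 3), mm.
#' @param cvv CV vectors (n x 3), m/s (NA rows allowed).
#' @param cfg a [cv_config()].
#' @param bases optional list of per-point tangent bases.
#' @return numeric vector of divergences, 1/s (NaN where undefined).
#' @export
cv_divergence <- function(P, cvv, cfg = cv_config(), bases = NULL) {
  n <- nrow(P)
  D <- .cross_dist(P, P)
  div <- rep(NaN, n)
  have <- !is.na(cvv[, 1])
  for (i in seq_len(n)) {
    nb <- which(D[i, ] <= cfg$fit_radius & have)
    if (length(nb) < 6) {
      nb2 <- which(have)
      nb2 <- nb2[order(D[i, nb2])]
      nb <- head(nb2, 8)
    }
    if (length(nb) < 6) next
    bas <- if (!is.null(bases) && !is.null(bases[[i]])) bases[[i]]
           else .tangent_basis(P[nb, , drop = FALSE])
    rel <- sweep(P[nb, , drop = FALSE], 2, P[i, ])
    u <- as.numeric(rel %*% bas$e1)
    v <- as.numeric(rel %*% bas$e2)
    vu <- as.numeric(cvv[nb, , drop = FALSE] %*% bas$e1)
    vv <- as.numeric(cvv[nb, , drop = FALSE] %*% bas$e2)
    X <- cbind(1, u, v)
    qrX <- qr(X)
    if (qrX$rank < 3) next
    bu <- qr.coef(qrX, vu)
    bv <- qr.coef(qrX, vv)
    div[i] <- (bu[2] + bv[3]) * 1000      # (mm/ms)/mm -> 1/s
  }
  div
}

#' Collision mask from the divergence field
#'
#' @param divergence per-point divergence, 1/s.
#' @param cfg a [cv_config()].
#' @return logical mask; TRUE = collision site (divergence strictly below
#'   the threshold), excluded from interpolation and summaries.
#' @export
exclude_collisions <- function(divergence, cfg = cv_config()) {
  !is.na(divergence) & divergence < cfg$div_threshold
}

#' Interpolate retained CV magnitudes onto the mesh
#'
#' @param mesh an [ep_mesh()].
#' @param field a `cv_field` (its unmasked, defined points are used).
#' @param cfg_egm an [egm_config()] (for the support radius).
#' @return per-vertex CV magnitude (m/s), NaN outside the data support.
#' @export
interpolate_cv <- function(mesh, field, cfg_egm = egm_config()) {
  keep <- field$defined & !field$collision_mask
  .assert(sum(keep) >= 4, "need at least 4 retained CV points")
  fit <- rbf_fit(field$points_xyz[keep, , drop = FALSE],
                 field$cv_magnitude[keep])
  fit$predict(mesh$vertices, support_radius = cfg_egm$support_radius)
}

#' Summarize retained CV magnitudes
#'
#' Collision-masked points are excluded; magnitudes above the physiological
#' QC gate are excluded and counted.  Histogram over fixed 0.05 m/s bins on
#' \[0, 2\] m/s.
#'
#' @param field a `cv_field` (or a numeric vector of magnitudes).
#' @param cfg a [cv_config()].
#' @return list with `median`, `mean`, `iqr` (25/75 quantiles), `n`,
#'   `n_gated`, `n_masked`, `histogram` (counts) and `breaks`.
#' @export
cv_summary <- function(field, cfg = cv_config()) {
  if (inherits(field, "cv_field")) {
    mags <- field$cv_magnitude[field$defined & !field$collision_mask]
    n_masked <- sum(field$collision_mask, na.rm = TRUE)
  } else {
    mags <- field[is.finite(field)]
    n_masked <- 0L
  }
  gate <- mags <= cfg$max_physiological_cv
  n_gated <- sum(!gate)
  mags <- mags[gate]
  .assert(length(mags) >= 1, "no CV magnitudes left after QC")
  breaks <- seq(0, 2, by = 0.05)
  h <- tabulate(findInterval(pmin(mags, 2), breaks, rightmost.closed = TRUE,
                             all.inside = TRUE), nbins = length(breaks) - 1)
  list(median = median(mags), mean = mean(mags),
       iqr = unname(quantile(mags, c(0.25, 0.75))), n = length(mags),
       n_gated = n_gated, n_masked = n_masked, histogram = h,
       breaks = breaks)
}
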