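## Cohort-level statistics: Welch t tests (raw and from summary moments),
## Pearson correlation, 2x2 contingency tests, Bonferroni correction, and
## a per-feature group-comparison report.

#' Group summary (n, mean, SD)
#'
#' @param n group size.
#' @param mean group mean.
#' @param sd group standard deviation.
#' @export
group_summary <- function(n, mean, sd) {
  .assert(n >= 2, "n must be >= 2")
  .assert(sd >= 0, "sd must be non-negative")
  structure(list(n = n, mean = mean, sd = sd), class = "group_summary")
}

#' Welch two-sample t test (raw samples)
#'
#' Two-sided, unequal variances (Welch-Satterthwaite df).
#'
#' @param a,b numeric samples (n >= 2 each).
#' @return list with `t`, `df`, `p`.
#' @export
welch_t <- function(a, b) {
  .assert(length(a) >= 2 && length(b) >= 2, "need n >= 2 per group")
  if (sd(a) == 0 && sd(b) == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, df = NA_real_, p = 1))
    stop("zero variance in both samples with unequal means", call. = FALSE)
  }
  tt <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = unname(tt$p.value))
}

#' Welch t test from summary statistics
#'
#' Identical formulas to [welch_t()], computed from group moments; enables
#' checks against printed cohort tables.
#'
#' @param a,b [group_summary()] objects.
#' @return list with `t`, `df`, `p`.
#' @export
welch_t_from_summary <- function(a, b) {
  .assert(inherits(a, "group_summary") && inherits(b, "group_summary"),
          "arguments must be group_summary objects")
  va <- a$sd^2 / a$n
  vb <- b$sd^2 / b$n
  if (va + vb == 0) {
    if (a$mean == b$mean) return(list(t = 0, df = NA_real_, p = 1))
    stop("zero variance in both groups with unequal means", call. = FALSE)
  }
  t <- (a$mean - b$mean) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (a$n - 1) + vb^2 / (b$n - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Pearson correlation with R^2
#'
#' @param x,y numeric vectors (n >= 3, finite).
#' @return list of class `correlation_result`: `r`, `r2`, `n`, `p`,
#'   `sign` (of r).
#' @export
pearson <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  .assert(length(x) >= 3, "need at least 3 finite pairs")
  .assert(sd(x) > 0 && sd(y) > 0, "zero variance input")
  ct <- stats::cor.test(x, y, method = "pearson")
  r <- unname(ct$estimate)
  structure(list(r = r, r2 = r^2, n = length(x), p = unname(ct$p.value),
                 sign = sign(r)),
            class = "correlation_result")
}

#' 2x2 contingency test
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @param method `"chi2"` (with continuity correction) or `"fisher"`
#'   (exact, two-sided).
#' @return p-value.
#' @export
contingency <- function(tab, method = c("chi2", "fisher")) {
  method <- match.arg(method)
  tab <- as.matrix(tab)
  .assert(all(dim(tab) == 2) && all(tab >= 0) && all(tab == round(tab)),
          "tab must be a 2x2 matrix of non-negative integer counts")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("empty margin in contingency table", call. = FALSE)
  if (method == "chi2")
    unname(stats::chisq.test(tab, correct = TRUE)$p.value)
  else
    unname(stats::fisher.test(tab)$p.value)
}

#' Bonferroni multiplicity correction
#'
#' @param p vector of p-values.
#' @param m number of tests (default `length(p)`).
#' @return adjusted p-values, `min(1, m * p)`.
#' @export
bonferroni <- function(p, m = length(p)) {
  .assert(all(p >= 0 & p <= 1), "p-values must lie in [0, 1]")
  pmin(1, m * p)
}

#' Per-feature two-group comparison report
#'
#' For each column of a feature matrix: group means +/- SD, Welch p, and
#' Bonferroni-adjusted p across all features.
#'
#' @param features numeric matrix/data.frame, subjects x features.
#' @param group factor/vector with two levels.
#' @return data.frame with one row per feature.
#' @export
stats_report <- function(features, group) {
  features <- as.matrix(features)
  g <- factor(group)
  .assert(nlevels(g) == 2, "group must have exactly two levels")
  lv <- levels(g)
  rows <- lapply(colnames(features), function(f) {
    a <- features[g == lv[1], f]
    b <- features[g == lv[2], f]
    a <- a[is.finite(a)]; b <- b[is.finite(b)]
    p <- if (length(a) >= 2 && length(b) >= 2 && (sd(a) > 0 || sd(b) > 0))
      welch_t(a, b)$p else NA_real_
    data.frame(feature = f,
               mean_a = mean(a), sd_a = sd(a), n_a = length(a),
               mean_b = mean(b), sd_b = sd(b), n_b = length(b),
               p = p)
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- bonferroni(ifelse(is.na(out$p), 1, out$p))
  out$p_bonferroni[is.na(out$p)] <- NA_real_
  names(out)[2:7] <- c(paste0(c("mean_", "sd_", "n_"), lv[1]),
                       paste0(c("mean_", "sd_", "n_"), lv[2]))
  out
}
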