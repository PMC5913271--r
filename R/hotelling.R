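#' Two-sample Hotelling's T-squared test
#'
#' Tests equality of two multivariate group means. With group sizes `n1`,
#' `n2` and dimension `p`,
#' `T2 = (n1 n2 / (n1 + n2)) (m1 - m2)' S^-1 (m1 - m2)` with `S` the pooled
#' covariance (denominator `n1 + n2 - 2`), and
#' `F = T2 (n1 + n2 - p - 1) / (p (n1 + n2 - 2))` follows an
#' `F(p, n1 + n2 - p - 1)` distribution under the null of equal means.
#' For `p = 1` this reduces exactly to the squared pooled-variance two-sample
#' t statistic.
#'
#' @param x,y Numeric matrices (or vectors for `p = 1`): observations in
#'   rows, the same `p` columns in both groups; at least 2 rows each and
#'   `n1 + n2 - 2 >= p`.
#' @return Object of class `hotelling_test`: `t2`, `f_stat`, `df1`, `df2`,
#'   `p_value`, `n1`, `n2`, `p`, `mean_diff`.
#' @examples
#' set.seed(1)
#' a <- matrix(rnorm(40), 20, 2)
#' b <- matrix(rnorm(40, mean = 1), 20, 2)
#' hotelling_t2(a, b)
#' @export
hotelling_t2 <- function(x, y) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (ncol(x) != ncol(y)) stop("the two groups must have the same dimension")
  n1 <- nrow(x); n2 <- nrow(y); p <- ncol(x)
  if (n1 < 2L || n2 < 2L) stop("each group needs at least 2 observations")
  if (n1 + n2 - 2L < p)
    stop("too few observations for dimension ", p,
         " (need n1 + n2 - 2 >= p); reduce the number of dimensions")
  m1 <- colMeans(x); m2 <- colMeans(y)
  S <- ((n1 - 1) * stats::cov(x) + (n2 - 1) * stats::cov(y)) / (n1 + n2 - 2)
  if (p == 1L) {
    if (S[1L, 1L] <= 0) stop("pooled covariance is singular; cannot invert")
    quad <- (m1 - m2)^2 / S[1L, 1L]
  } else {
    if (!all(is.finite(S)) || kappa(S, exact = TRUE) > 1e12)
      stop("pooled covariance is (near-)singular; reduce the number of ",
           "dimensions tested")
    quad <- drop(crossprod(m1 - m2, solve(S, m1 - m2)))
  }
  t2 <- (n1 * n2 / (n1 + n2)) * quad
  df1 <- p
  df2 <- n1 + n2 - p - 1L
  f_stat <- t2 * df2 / (df1 * (n1 + n2 - 2L))
  p_value <- stats::pf(f_stat, df1, df2, lower.tail = FALSE)
  structure(list(t2 = unname(t2), f_stat = unname(f_stat), df1 = df1,
                 df2 = df2, p_value = unname(p_value), n1 = n1, n2 = n2, p = p,
                 mean_diff = m1 - m2),
            class = "hotelling_test")
}

#' @export
print.hotelling_test <- function(x, ...) {
  cat("Two-sample Hotelling's T-squared test\n")
  cat(sprintf("  n1 = %d, n2 = %d, dimensions = %d\n", x$n1, x$n2, x$p))
  cat(sprintf("  T2 = %.4g, F = %.4g on (%d, %d) df\n",
              x$t2, x$f_stat, x$df1, x$df2))
  pv <- if (x$p_value < 2.2e-16) "< 2.2e-16" else sprintf("= %.4g", x$p_value)
  cat("  P-value ", pv, sprintf("  (exact: %.6g)\n", x$p_value), sep = "")
  invisible(x)
}

#' Case-vs-control separation test in the MDS plane
#'
#' Splits the first `dims` MDS coordinates by case/control status and tests
#' mean separation with [hotelling_t2()].
#'
#' @param mds An `mds_embedding` from [classical_mds()].
#' @param phenotypes A [phenotype_table()] covering every embedded sample
#'   (samples with unknown status are excluded with a message).
#' @param dims Number of leading dimensions to test (default 2, the MDS
#'   plane).
#' @return A `hotelling_test` object.
#' @export
separation_report <- function(mds, phenotypes, dims = 2) {
  stopifnot(inherits(mds, "mds_embedding"))
  if (mds$k < dims)
    stop("embedding has only ", mds$k, " dimension(s); requested ", dims)
  st <- phenotypes$status[match(mds$sample_ids, phenotypes$sample_id)]
  if (any(is.na(match(mds$sample_ids, phenotypes$sample_id))))
    stop("phenotype missing for sample(s): ",
         paste(utils::head(mds$sample_ids[
           is.na(match(mds$sample_ids, phenotypes$sample_id))], 5),
           collapse = ", "))
  if (anyNA(st)) {
    message(sum(is.na(st)), " sample(s) with unknown status excluded")
  }
  co <- mds$points[, seq_len(dims), drop = FALSE]
  cases <- co[!is.na(st) & st == "case", , drop = FALSE]
  controls <- co[!is.na(st) & st == "control", , drop = FALSE]
  if (nrow(cases) < 2L || nrow(controls) < 2L)
    stop("each of case and control needs at least 2 samples (got ",
         nrow(cases), " cases, ", nrow(controls), " controls)")
  message("testing ", nrow(cases), " cases vs ", nrow(controls),
          " controls in ", dims, " dimension(s)")
  hotelling_t2(cases, controls)
}
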