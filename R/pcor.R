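#' Partial correlation by residualization
#'
#' Regresses both `x` and `y` on the control matrix `D` (ordinary least
#' squares, intercept always included) and returns the Pearson correlation of
#' the two residual vectors. With an empty `D` this reduces to the plain
#' Pearson correlation. This is the form that generalizes to an arbitrary
#' number of control variables; the recursive single-control identity is
#' available as [pcor_first_order()] and the two agree for k = 1.
#'
#' @param x,y Numeric sample vectors of length n.
#' @param D Control matrix, k rows (control variables) by n columns, or `NULL`
#'   for no controls.
#' @return The partial correlation coefficient rho in \[-1, 1\].
#' @seealso [pcor_test()] for the significance test, [pcor_screen()] for the
#'   genome-wide screen.
#' @export
pcor_residual <- function(x, y, D = NULL) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  k <- 0L
  if (!is.null(D)) {
    D <- rbind(D)
    if (ncol(D) != n) stop("D must have one column per sample")
    k <- nrow(D)
  }
  if (n <= k + 2)
    stop(sprintf("insufficient degrees of freedom: n = %d, k = %d requires n > k + 2",
                 n, k))
  if (anyNA(x) || anyNA(y) || (k > 0 && anyNA(D)))
    stop("missing values are not allowed in pcor_residual")
  rx <- residualize(matrix(x, nrow = 1), D)[, 1]
  ry <- residualize(matrix(y, nrow = 1), D)[, 1]
  sx <- sqrt(sum(rx^2)); sy <- sqrt(sum(ry^2))
  tol <- 1e-8
  if (sx <= tol * max(1, sqrt(sum(x^2))) || sy <= tol * max(1, sqrt(sum(y^2))))
    stop("undefined partial correlation: residual variance is zero ",
         "(variable fully explained by the controls)")
  clip1(sum(rx * ry) / (sx * sy))
}

# residuals of each row of X (genes x samples) on controls D (k x samples),
# intercept included; returns samples x genes
residualize <- function(X, D = NULL) {
  n <- ncol(X)
  design <- cbind(rep(1, n))
  if (!is.null(D) && nrow(rbind(D)) > 0) design <- cbind(design, t(rbind(D)))
  qr.resid(qr(design), t(X))
}

clip1 <- function(r, tol = 1e-12) {
  r[r > 1 & r <= 1 + tol] <- 1
  r[r < -1 & r >= -1 - tol] <- -1
  r
}

#' First-order partial correlation from three plain correlations
#'
#' The standard identity
#' `(r_xy - r_xZ * r_yZ) / sqrt((1 - r_xZ^2) * (1 - r_yZ^2))` for a single
#' control variable Z. Agrees with [pcor_residual()] for k = 1.
#'
#' @param r_xy,r_xZ,r_yZ Plain Pearson correlations; `|r_xZ|` and `|r_yZ|`
#'   must be < 1.
#' @return The first-order partial correlation, clipped to \[-1, 1\] only
#'   within numerical tolerance 1e-12.
#' @export
pcor_first_order <- function(r_xy, r_xZ, r_yZ) {
  if (any(abs(c(r_xy, r_xZ, r_yZ)) > 1))
    stop("correlations must lie in [-1, 1]")
  if (abs(r_xZ) == 1 || abs(r_yZ) == 1)
    stop("division by zero: |r_xZ| and |r_yZ| must be < 1")
  clip1((r_xy - r_xZ * r_yZ) / sqrt((1 - r_xZ^2) * (1 - r_yZ^2)))
}

#' t-test for a partial correlation coefficient
#'
#' Tests H0: the population partial correlation is zero, using
#' `t = rho * sqrt(n - k - 2) / sqrt(1 - rho^2)` on `n - k - 2` degrees of
#' freedom, where k is the number of control variables regressed out.
#'
#' @param rho Partial correlation coefficient, `|rho| < 1`.
#' @param n Number of sample observations.
#' @param k Number of control variables.
#' @return A list with `t_stat`, `df` and the two-sided `p`.
#' @export
pcor_test <- function(rho, n, k) {
  df <- n - k - 2
  if (df < 1) stop(sprintf("insufficient degrees of freedom: n - k - 2 = %d", df))
  if (any(abs(rho) >= 1))
    stop("|rho| must be < 1 (the t statistic is infinite at |rho| = 1)")
  t_stat <- rho * sqrt(df) / sqrt(1 - rho^2)
  list(t_stat = t_stat, df = df, p = 2 * stats::pt(-abs(t_stat), df))
}

#' Remove flat-expression genes
#'
#' Excludes genes whose sample standard deviation (n - 1 denominator) is less
#' than or equal to `threshold`; the comparison is inclusive, so a gene with
#' SD exactly at the threshold is removed.
#'
#' @param expr An [expr_set].
#' @param threshold Non-negative SD cut-off (default 0.1).
#' @return The filtered [expr_set] (possibly with zero genes, with a message).
#' @export
sd_filter <- function(expr, threshold = 0.1) {
  stopifnot(inherits(expr, "expr_set"), threshold >= 0)
  expr <- drop_incomplete_genes(expr)
  sds <- apply(expr$values, 1, stats::sd)
  keep <- sds > threshold
  if (!any(keep)) message("sd_filter: no genes remain after filtering")
  expr[keep, seq_len(ncol(expr$values))]
}

#' Pearson correlation matrix among regulators
#'
#' Plain (not partial) Pearson correlation between every pair of regulator
#' genes, for inspecting co-expression within the regulator set itself.
#'
#' @param expr An [expr_set].
#' @param regulators Character vector of at least 2 regulator symbols present
#'   in `expr`.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
pearson_matrix <- function(expr, regulators) {
  stopifnot(inherits(expr, "expr_set"))
  missing <- setdiff(regulators, genes(expr))
  if (length(missing))
    stop("regulator(s) absent from expression matrix: ",
         paste(missing, collapse = ", "))
  if (length(regulators) < 2) stop("need at least 2 regulators")
  vals <- expr$values[regulators, , drop = FALSE]
  sds <- apply(vals, 1, stats::sd)
  if (any(sds == 0))
    stop("zero-variance regulator(s): ",
         paste(regulators[sds == 0], collapse = ", "))
  stats::cor(t(vals))
}
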