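#' Genome-wide partial-correlation screen against a regulator set
#'
#' The package's central fit: for every candidate gene y and regulator x, the
#' partial correlation of x and y given the full control-gene matrix D, with
#' the t-test on n - k - 2 degrees of freedom (k = number of control genes
#' regressed out). Internally all rows are residualized on D once via a
#' shared QR decomposition; this is numerically identical to calling
#' [pcor_residual()] per pair.
#'
#' @param expr An [expr_set] (typically after [sd_filter()]).
#' @param regulators Character vector of regulator gene symbols (set M).
#' @param controls Character vector of control gene symbols (set D); may be
#'   empty, in which case rho is the plain Pearson correlation.
#' @param candidates Candidate gene symbols; default every gene not in
#'   `regulators` or `controls`.
#' @param p_adjust If `TRUE`, add Benjamini-Hochberg adjusted p-values over
#'   all (gene, regulator) tests. Off by default: the screen's own decision
#'   rule is the unadjusted p < 0.05 together with the coefficient threshold.
#' @return An object of class `pcor_screen` with elements `results` (data
#'   frame: gene, regulator, rho, t, df, p, and p_adj when requested), `n`,
#'   `k`, `regulators`, `controls`, `candidates`. Methods: `print`, `summary`,
#'   `coef` (genes x regulators rho matrix), `plot` (histogram of rho).
#' @export
#' @examples
#' sim <- simulate_expression(sim_config(n_samples = 60, n_controls = 5,
#'                                       n_direct = 4, n_confounded = 4,
#'                                       n_null = 10, seed = 3))
#' fit <- pcor_screen(sim$expr,
#'                    regulators = grep("^REG", genes(sim$expr), value = TRUE),
#'                    controls = grep("^CTRL", genes(sim$expr), value = TRUE))
#' summary(fit)
pcor_screen <- function(expr, regulators, controls = character(0),
                        candidates = NULL, p_adjust = FALSE) {
  stopifnot(inherits(expr, "expr_set"))
  expr <- drop_incomplete_genes(expr)
  all_genes <- genes(expr)
  missing <- setdiff(c(regulators, controls), all_genes)
  if (length(missing))
    stop("regulator/control symbol(s) absent from expression matrix: ",
         paste(missing, collapse = ", "))
  if (length(intersect(regulators, controls)))
    stop("regulators and controls overlap: ",
         paste(intersect(regulators, controls), collapse = ", "))
  if (is.null(candidates)) {
    candidates <- setdiff(all_genes, c(regulators, controls))
  } else {
    miss_c <- setdiff(candidates, all_genes)
    if (length(miss_c))
      stop("candidate symbol(s) absent from expression matrix: ",
           paste(miss_c, collapse = ", "))
    candidates <- setdiff(candidates, c(regulators, controls))
  }
  n <- ncol(expr$values)
  k <- length(controls)
  df <- n - k - 2
  if (df < 1)
    stop(sprintf("insufficient degrees of freedom: n = %d, k = %d", n, k))

  res_df <- data.frame(gene = character(0), regulator = character(0),
                       rho = numeric(0), t = numeric(0), df = integer(0),
                       p = numeric(0), stringsAsFactors = FALSE)
  if (length(candidates) && length(regulators)) {
    D <- expr$values[controls, , drop = FALSE]
    R <- residualize(expr$values[c(candidates, regulators), , drop = FALSE], D)
    rc <- R[, candidates, drop = FALSE]
    rr <- R[, regulators, drop = FALSE]
    zero_var <- colnames(rc)[colSums(rc^2) < 1e-16]
    if (length(zero_var))
      warning("zero residual variance (rho undefined, NA) for: ",
              paste(zero_var, collapse = ", "))
    rho <- suppressWarnings(stats::cor(rc, rr))   # candidates x regulators
    rho <- clip1(rho)
    safe <- pmin(pmax(rho, -1 + 1e-15), 1 - 1e-15)
    t_stat <- safe * sqrt(df) / sqrt(1 - safe^2)
    p <- 2 * stats::pt(-abs(t_stat), df)
    res_df <- data.frame(
      gene = rep(candidates, times = length(regulators)),
      regulator = rep(regulators, each = length(candidates)),
      rho = as.vector(rho), t = as.vector(t_stat),
      df = df, p = as.vector(p), stringsAsFactors = FALSE)
    res_df <- res_df[order(match(res_df$gene, candidates),
                           match(res_df$regulator, regulators)), ]
    rownames(res_df) <- NULL
    if (p_adjust) res_df$p_adj <- stats::p.adjust(res_df$p, method = "BH")
  }
  structure(list(results = res_df, n = n, k = k,
                 regulators = regulators, controls = controls,
                 candidates = candidates),
            class = "pcor_screen")
}

#' @export
print.pcor_screen <- function(x, ...) {
  cat(sprintf("Partial-correlation screen: %d candidate genes x %d regulators\n",
              length(x$candidates), length(x$regulators)))
  cat(sprintf("  n = %d samples, k = %d control genes, df = %d\n",
              x$n, x$k, x$n - x$k - 2))
  if (nrow(x$results))
    cat(sprintf("  rho range: [%.3f, %.3f]\n",
                min(x$results$rho), max(x$results$rho)))
  invisible(x)
}

#' @export
summary.pcor_screen <- function(object, rho_min = 0.35, alpha = 0.05, ...) {
  r <- object$results
  hits <- r[abs(r$rho) >= rho_min & r$p < alpha, , drop = FALSE]
  out <- list(n = object$n, k = object$k,
              n_tests = nrow(r),
              rho_range = if (nrow(r)) range(r$rho) else c(NA_real_, NA_real_),
              rho_min = rho_min, alpha = alpha,
              n_coexpressed_pairs = nrow(hits),
              n_coexpressed_genes = length(unique(hits$gene)),
              per_regulator = sort(table(hits$regulator), decreasing = TRUE),
              top = hits[order(-abs(hits$rho)), ][seq_len(min(10, nrow(hits))), ])
  class(out) <- "summary.pcor_screen"
  out
}

#' @export
print.summary.pcor_screen <- function(x, ...) {
  cat(sprintf("Partial-correlation screen (n = %d, k = %d)\n", x$n, x$k))
  cat(sprintf("  %d tests; rho in [%.3f, %.3f]\n",
              x$n_tests, x$rho_range[1], x$rho_range[2]))
  cat(sprintf("  co-expressed (|rho| >= %.2f, p < %.2f): %d pairs, %d genes\n",
              x$rho_min, x$alpha, x$n_coexpressed_pairs, x$n_coexpressed_genes))
  if (length(x$per_regulator)) {
    cat("  genes per regulator:\n")
    print(x$per_regulator)
  }
  if (nrow(x$top)) {
    cat("  strongest associations:\n")
    print(x$top, row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' @export
coef.pcor_screen <- function(object, ...) {
  r <- object$results
  m <- matrix(NA_real_, length(object$candidates), length(object$regulators),
              dimnames = list(object$candidates, object$regulators))
  if (nrow(r)) m[cbind(r$gene, r$regulator)] <- r$rho
  m
}

#' @export
plot.pcor_screen <- function(x, breaks = 50, rho_min = 0.35, ...) {
  graphics::hist(x$results$rho, breaks = breaks,
                 main = "Partial correlation with regulators",
                 xlab = expression(rho), ...)
  graphics::abline(v = c(-rho_min, rho_min), lty = 2)
  invisible(x)
}
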