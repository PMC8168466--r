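#' Differential expression gate between case and control samples
#'
#' A case-vs-control gate on log-scale expression: log fold change is the
#' difference of group means (inputs are assumed already log-scale after
#' upstream normalization), the p-value comes from Welch's two-sample t-test,
#' and multiplicity is handled with Benjamini-Hochberg FDR adjustment across
#' all tested genes. A gene is called differentially expressed when
#' `|log_fc| > lfc_min` (strict) and `p_adj < alpha` (strict).
#'
#' @param expr An [expr_set] with group labels and at least 2 samples per
#'   group.
#' @param lfc_min Log2 fold-change threshold (default 2, i.e. 4-fold).
#' @param alpha FDR threshold on the adjusted p-value (default 0.05).
#' @return Data frame with one row per gene: `gene`, `log_fc`, `p_raw`,
#'   `p_adj`, `is_de`, `direction` (up/down/none).
#' @export
differential_expression <- function(expr, lfc_min = 2, alpha = 0.05) {
  stopifnot(inherits(expr, "expr_set"))
  if (is.null(expr$group))
    stop("differential expression requires sample group labels")
  expr <- drop_incomplete_genes(expr)
  case <- expr$values[, expr$group == "case", drop = FALSE]
  ctrl <- expr$values[, expr$group == "control", drop = FALSE]
  n1 <- ncol(case); n2 <- ncol(ctrl)
  if (n1 < 2 || n2 < 2)
    stop(sprintf("each group needs >= 2 samples (case: %d, control: %d)", n1, n2))

  m1 <- rowMeans(case); m2 <- rowMeans(ctrl)
  v1 <- apply(case, 1, stats::var); v2 <- apply(ctrl, 1, stats::var)
  log_fc <- m1 - m2

  se2 <- v1 / n1 + v2 / n2
  flat <- v1 == 0 & v2 == 0
  if (any(flat))
    warning("zero variance in both groups (p = 1) for: ",
            paste(utils::head(rownames(expr$values)[flat], 5), collapse = ", "),
            if (sum(flat) > 5) ", ..." else "")
  t_stat <- ifelse(se2 > 0, log_fc / sqrt(se2), NA_real_)
  df_w <- ifelse(se2 > 0,
                 se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1)),
                 NA_real_)
  p_raw <- ifelse(flat, 1, 2 * stats::pt(-abs(t_stat), df_w))
  p_adj <- stats::p.adjust(p_raw, method = "BH")

  is_de <- abs(log_fc) > lfc_min & p_adj < alpha
  direction <- ifelse(!is_de, "none", ifelse(log_fc > 0, "up", "down"))
  data.frame(gene = rownames(expr$values), log_fc = log_fc,
             p_raw = p_raw, p_adj = p_adj, is_de = is_de,
             direction = direction, row.names = NULL,
             stringsAsFactors = FALSE)
}
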