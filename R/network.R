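#' Build the thresholded co-expression network
#'
#' Keeps (regulator, gene) pairs whose coefficient magnitude `|rho|` satisfies
#' the chosen comparator against `rho_min`; the sign of rho is preserved on
#' the retained edge. Two comparator conventions are exposed (`">="` and
#' `">"`) because both appear in practice for network edges (0.3, inclusive)
#' and for calling a gene "co-expressed" (0.35). When `require_significance`
#' is on (default), the edge must additionally have `p < alpha` from the
#' partial-correlation t-test.
#'
#' @param results A [pcor_screen] object or its `results` data frame.
#' @param rho_min Non-negative coefficient threshold (default 0.3).
#' @param comparator `">="` (inclusive, default) or `">"`.
#' @param require_significance Also require `p < alpha`.
#' @param alpha Significance level for the p-value condition.
#' @return Edge data frame: `regulator`, `gene`, `rho`, `t`, `df`, `p` (and
#'   `p_adj` if present in the input).
#' @export
build_network <- function(results, rho_min = 0.3, comparator = c(">=", ">"),
                          require_significance = TRUE, alpha = 0.05) {
  comparator <- match.arg(comparator)
  if (inherits(results, "pcor_screen")) results <- results$results
  stopifnot(rho_min >= 0)
  keep <- if (comparator == ">=") abs(results$rho) >= rho_min
          else abs(results$rho) > rho_min
  keep[is.na(keep)] <- FALSE
  if (require_significance) keep <- keep & !is.na(results$p) & results$p < alpha
  cols <- intersect(c("regulator", "gene", "rho", "t", "df", "p", "p_adj"),
                    names(results))
  edges <- results[keep, cols, drop = FALSE]
  rownames(edges) <- NULL
  edges
}

#' Number of distinct genes connected to each regulator
#'
#' @param edges Edge data frame from [build_network()].
#' @param regulators Optional regulator universe, so regulators with no edges
#'   report a degree of 0.
#' @return Named integer vector of per-regulator gene counts.
#' @export
regulator_degree <- function(edges, regulators = NULL) {
  if (is.null(regulators)) regulators <- sort(unique(edges$regulator))
  counts <- vapply(regulators, function(r)
    length(unique(edges$gene[edges$regulator == r])), integer(1))
  stats::setNames(counts, regulators)
}

#' Table of genes co-expressed with one or more regulators
#'
#' One row per co-expressed gene, listing which regulators it connects to,
#' whether it carries an m6A site, and whether it carries a supplied
#' disease annotation. The table is sorted by gene symbol and is invariant to
#' the ordering of the input edge list.
#'
#' @param edges Edge data frame from [build_network()].
#' @param m6a_flags Optional named logical vector (gene -> has m6A), e.g. from
#'   [flag_m6a_genes()]; genes absent from the vector get `NA`.
#' @param annotations Optional character vector of gene symbols carrying a
#'   disease annotation (supplied, not computed).
#' @return Data frame: `gene`, `regulators` (comma-separated, sorted),
#'   `n_regulators`, `has_m6a`, `diabetes_annotation`.
#' @export
multi_regulator_table <- function(edges, m6a_flags = NULL, annotations = NULL) {
  if (!nrow(edges))
    return(data.frame(gene = character(0), regulators = character(0),
                      n_regulators = integer(0), has_m6a = logical(0),
                      diabetes_annotation = logical(0),
                      stringsAsFactors = FALSE))
  by_gene <- split(edges$regulator, edges$gene)
  gene <- sort(names(by_gene))
  regs <- lapply(by_gene[gene], function(r) sort(unique(r)))
  out <- data.frame(gene = gene,
                    regulators = vapply(regs, paste, "", collapse = ","),
                    n_regulators = vapply(regs, length, integer(1)),
                    row.names = NULL, stringsAsFactors = FALSE)
  out$has_m6a <- if (is.null(m6a_flags)) NA else unname(m6a_flags[out$gene])
  out$diabetes_annotation <- if (is.null(annotations)) NA
                             else out$gene %in% annotations
  out
}
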