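#' Expand m6A site positions into fixed-width peak windows
#'
#' Each m6A site becomes one genomic window of `width` bp overlapping the
#' site. The default anchor centers the window: `start = pos - floor(width/2)`,
#' `end = start + width - 1` (1-based, inclusive at both ends); `left` starts
#' the window at the site and `right` ends it there. Starts are clipped at 1,
#' in which case the clipped window is narrower than `width`. Overlapping
#' windows of the same gene are deliberately not merged: each site keeps its
#' own window.
#'
#' @param sites Data frame with `chrom`, `pos` (1-based), `gene`, e.g. from
#'   [read_sites_bed()] or [simulate_genome_annotations()].
#' @param width Window width in bp (default 100).
#' @param anchor Where the site sits in its window.
#' @return Data frame of peaks: `chrom`, `start`, `end`, `gene`, `source_pos`.
#' @export
sites_to_peaks <- function(sites, width = 100L,
                           anchor = c("center", "left", "right")) {
  anchor <- match.arg(anchor)
  stopifnot(all(c("chrom", "pos", "gene") %in% names(sites)), width >= 1)
  width <- as.integer(width)
  pos <- as.integer(sites$pos)
  start <- switch(anchor,
                  center = pos - width %/% 2L,
                  left = pos,
                  right = pos - width + 1L)
  end <- start + width - 1L
  start <- pmax(start, 1L)
  data.frame(chrom = sites$chrom, start = start, end = end,
             gene = sites$gene, source_pos = pos,
             stringsAsFactors = FALSE)
}

#' Flag genes that carry at least one m6A peak
#'
#' @param peaks Peak data frame from [sites_to_peaks()].
#' @param genes Character vector of gene symbols to flag.
#' @return Named logical vector over `genes`; `TRUE` iff the gene has >= 1
#'   peak annotated to it.
#' @export
flag_m6a_genes <- function(peaks, genes) {
  stats::setNames(genes %in% unique(peaks$gene), genes)
}

#' Restrict a co-expression gene table to m6A-bearing genes
#'
#' The intersection step: keeps only co-expressed genes flagged as carrying
#' m6A methylation, and fills the table's `has_m6a` column. Gene-level m6A
#' status comes from the site file's own gene assignment, not from a gene
#' model overlap.
#'
#' @param co_table Output of [multi_regulator_table()].
#' @param flags Named logical vector from [flag_m6a_genes()].
#' @return The subset of `co_table` with `has_m6a = TRUE`.
#' @export
intersect_com6ar <- function(co_table, flags) {
  f <- flags[co_table$gene]
  f[is.na(f)] <- FALSE
  out <- co_table[f, , drop = FALSE]
  out$has_m6a <- TRUE
  rownames(out) <- NULL
  out
}
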