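#' Intersect trans-eQTL SNPs with m6A peak windows
#'
#' A SNP hits a peak when its position lies inside the peak's closed 1-based
#' interval on the same chromosome (interval intersection via
#' GenomicRanges). With `same_gene = TRUE` (default) the eQTL's target gene
#' must additionally equal the peak's gene. When a SNP overlaps several peaks
#' of the same gene, the hit is collapsed to the peak whose source site is
#' nearest the SNP. Both inputs must be on the same genome build; no liftover
#' is attempted.
#'
#' @param eqtls eQTL data frame from [read_eqtl()] (or the same columns).
#' @param peaks Peak data frame from [sites_to_peaks()].
#' @param same_gene Require eQTL target gene == peak gene (default `TRUE`).
#' @param m Number of tests for the Bonferroni adjustment; defaults to the
#'   number of eQTL records screened. Ignored when `p_adjusted = TRUE`.
#' @param p_adjusted Set to `TRUE` when the input `pvalue` column is already
#'   multiplicity-adjusted upstream (pass-through; `p_bonf = pvalue`).
#' @return Data frame of hits: the eQTL columns plus `peak_start`, `peak_end`,
#'   `peak_gene`, `source_pos`, `p_bonf`.
#' @export
snps_in_peaks <- function(eqtls, peaks, same_gene = TRUE, m = nrow(eqtls),
                          p_adjusted = FALSE) {
  hit_cols <- c("snp_id", "chrom", "pos", "assessed_allele", "other_allele",
                "pvalue", "gene", "peak_start", "peak_end", "peak_gene",
                "source_pos", "p_bonf")
  empty <- stats::setNames(
    data.frame(character(0), character(0), integer(0), character(0),
               character(0), numeric(0), character(0), integer(0), integer(0),
               character(0), integer(0), numeric(0), stringsAsFactors = FALSE),
    hit_cols)
  if (!nrow(eqtls) || !nrow(peaks)) return(empty)

  gr_snp <- GenomicRanges::GRanges(eqtls$chrom,
                                   IRanges::IRanges(eqtls$pos, eqtls$pos))
  gr_peak <- GenomicRanges::GRanges(peaks$chrom,
                                    IRanges::IRanges(peaks$start, peaks$end))
  ov <- suppressWarnings(GenomicRanges::findOverlaps(gr_snp, gr_peak))
  qi <- S4Vectors::queryHits(ov); si <- S4Vectors::subjectHits(ov)
  if (same_gene) {
    ok <- eqtls$gene[qi] == peaks$gene[si]
    qi <- qi[ok]; si <- si[ok]
  }
  if (!length(qi)) return(empty)

  hits <- data.frame(eqtls[qi, c("snp_id", "chrom", "pos", "assessed_allele",
                                 "other_allele", "pvalue", "gene")],
                     peak_start = peaks$start[si], peak_end = peaks$end[si],
                     peak_gene = peaks$gene[si],
                     source_pos = peaks$source_pos[si],
                     stringsAsFactors = FALSE)
  # collapse duplicate (SNP, gene) hits to the nearest-site peak
  key <- paste(hits$snp_id, hits$gene, sep = "\r")
  ord <- order(key, abs(hits$pos - hits$source_pos))
  hits <- hits[ord[!duplicated(key[ord])], , drop = FALSE]
  hits <- hits[order(match(hits$snp_id, eqtls$snp_id)), , drop = FALSE]
  hits$p_bonf <- if (p_adjusted) hits$pvalue else bonferroni(hits$pvalue, m)
  rownames(hits) <- NULL
  hits
}

#' Bonferroni adjustment
#' @param p Raw p-value(s) in (0, 1].
#' @param m Number of tests (>= 1).
#' @return `min(1, p * m)`, vectorized over `p`.
#' @export
bonferroni <- function(p, m) {
  if (any(m < 1)) stop("number of tests m must be >= 1")
  pmin(1, p * m)
}

#' Summaries of SNP-in-peak hits
#'
#' Counts hits per chromosome, distinct target genes, SNPs per gene, and how
#' many SNPs "involve" each nucleotide — a SNP involves an allele when it
#' appears as either its assessed or its other allele. All summaries are
#' invariant to input ordering.
#'
#' @param hits Hit data frame from [snps_in_peaks()], or any data frame with
#'   columns `snp_id`, `chrom`, `assessed_allele`, `other_allele`, `gene`.
#' @return An `eqtl_summary` list: `n_hits`, `by_chrom` (named counts, sorted
#'   by chromosome), `n_genes`, `by_gene` (named counts), `by_allele` (named
#'   counts for A/C/G/T).
#' @export
summarize_hits <- function(hits) {
  need <- c("snp_id", "chrom", "assessed_allele", "other_allele", "gene")
  missing <- setdiff(need, names(hits))
  if (length(missing))
    stop("hits missing column(s): ", paste(missing, collapse = ", "))
  chrom_order <- function(x) {
    num <- suppressWarnings(as.numeric(sub("^chr", "", x)))
    order(is.na(num), num, x)
  }
  chroms <- unique(hits$chrom)[chrom_order(unique(hits$chrom))]
  by_chrom <- vapply(chroms, function(ch) sum(hits$chrom == ch), integer(1))
  genes <- sort(unique(hits$gene))
  by_gene <- vapply(genes, function(g) sum(hits$gene == g), integer(1))
  by_allele <- vapply(c(A = "A", C = "C", G = "G", T = "T"), function(nt)
    sum(hits$assessed_allele == nt | hits$other_allele == nt), integer(1))
  structure(list(n_hits = nrow(hits),
                 by_chrom = stats::setNames(by_chrom, chroms),
                 n_genes = length(genes),
                 by_gene = stats::setNames(by_gene, genes),
                 by_allele = by_allele),
            class = "eqtl_summary")
}

#' @export
print.eqtl_summary <- function(x, ...) {
  cat(sprintf("%d SNP-in-peak hit(s) across %d gene(s)\n", x$n_hits, x$n_genes))
  if (x$n_hits) {
    cat("  per chromosome: ",
        paste(sprintf("%s=%d", names(x$by_chrom), x$by_chrom), collapse = ", "),
        "\n", sep = "")
    cat("  per gene:       ",
        paste(sprintf("%s=%d", names(x$by_gene), x$by_gene), collapse = ", "),
        "\n", sep = "")
    cat("  allele involvement: ",
        paste(sprintf("%s=%d", names(x$by_allele), x$by_allele), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Flatten an [summarize_hits()] result into tidy data frames
#' @param x An `eqtl_summary`.
#' @return List of data frames `by_chrom`, `by_gene`, `by_allele`.
#' @export
summary_tables <- function(x) {
  stopifnot(inherits(x, "eqtl_summary"))
  list(by_chrom = data.frame(chrom = names(x$by_chrom),
                             n_snps = unname(x$by_chrom)),
       by_gene = data.frame(gene = names(x$by_gene),
                            n_snps = unname(x$by_gene)),
       by_allele = data.frame(allele = names(x$by_allele),
                              n_snps = unname(x$by_allele)))
}
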