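#' Read a genes-by-samples expression table
#'
#' Expects a TSV with a header row of sample identifiers and gene symbols in
#' the first column. Ragged rows, non-numeric cells and duplicated identifiers
#' are rejected with the offending line/symbol named. Missing values (`NA` or
#' empty cells) are allowed on read; genes carrying them are dropped with a
#' warning before any statistics (see [sd_filter()], [pcor_screen()]).
#'
#' @param path Path to the expression TSV.
#' @param group_map Optional sample grouping: a path to a two-column TSV
#'   (`sample_id`, `group`) or a data frame with those columns. Groups must be
#'   control/case (T2DM accepted as case).
#' @return An [expr_set].
#' @export
read_expression <- function(path, group_map = NULL) {
  if (!file.exists(path)) stop("expression file not found: ", path)
  nf <- utils::count.fields(path, sep = "\t", quote = "", comment.char = "")
  if (length(nf) == 0)
    stop("expression file is empty: ", path)
  if (length(unique(nf)) != 1L) {
    bad <- which(nf != nf[1])[1]
    stop(sprintf("ragged expression table '%s': line %d has %d fields, expected %d",
                 path, bad, nf[bad], nf[1]))
  }
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                           check.names = FALSE, colClasses = "character",
                           na.strings = c("NA", ""))
  if (nrow(tab) == 0) stop("expression file has a header but no genes: ", path)
  gene_ids <- tab[[1]]
  dup <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup))
    stop("duplicate gene symbol(s) in ", path, ": ", paste(dup, collapse = ", "))
  vals <- as.matrix(tab[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals),
                                 dimnames = dimnames(vals)))
  introduced <- is.na(num) & !is.na(vals)
  if (any(introduced)) {
    idx <- which(introduced, arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric expression value at line %d (gene %s, sample %s): '%s'",
                 idx[1] + 1L, gene_ids[idx[1]], colnames(vals)[idx[2]],
                 vals[idx[1], idx[2]]))
  }
  rownames(num) <- gene_ids
  grp <- NULL
  if (!is.null(group_map)) {
    gm <- if (is.character(group_map) && length(group_map) == 1L)
      read_group_map(group_map) else as.data.frame(group_map)
    need <- c("sample_id", "group")
    if (!all(need %in% names(gm)))
      stop("group map must have columns: ", paste(need, collapse = ", "))
    grp <- stats::setNames(as.character(gm$group), gm$sample_id)
  }
  expr_set(num, group = grp)
}

read_group_map <- function(path) {
  if (!file.exists(path)) stop("group file not found: ", path)
  utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                    colClasses = "character", check.names = FALSE)
}

#' Write an expression set to TSV
#' @param x An [expr_set].
#' @param path Output path for the expression TSV.
#' @param group_path Optional path for the companion sample-group TSV.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path, group_path = NULL) {
  df <- data.frame(gene = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(group_path)) {
    if (is.null(x$group)) stop("expression set has no group labels to write")
    gdf <- data.frame(sample_id = names(x$group),
                      group = as.character(x$group))
    utils::write.table(gdf, group_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read a gene list (one symbol per line)
#' @param path Path to a text file with one gene symbol per line; blank lines
#'   and lines starting with `#` are skipped.
#' @return Character vector of unique symbols, in file order.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) stop("gene list not found: ", path)
  x <- trimws(readLines(path, warn = FALSE))
  x <- x[nzchar(x) & !startsWith(x, "#")]
  dup <- unique(x[duplicated(x)])
  if (length(dup))
    warning("duplicate symbols in ", path, ": ", paste(dup, collapse = ", "))
  unique(x)
}

#' Read m6A site positions from a BED file
#'
#' BED3+1 input (`chrom`, `start`, `end`, `gene`), 0-based half-open, as is
#' standard for BED. Each record is converted to a single 1-based site
#' position: a width-1 record (`end == start + 1`) maps to `start + 1`; a
#' wider record maps to the midpoint `ceiling((start + end) / 2)`. All
#' positions downstream of this reader are 1-based.
#'
#' @param path Path to the BED file.
#' @return A data frame with columns `chrom`, `pos` (1-based), `gene`.
#' @export
read_sites_bed <- function(path) {
  if (!file.exists(path)) stop("site BED file not found: ", path)
  tab <- utils::read.delim(path, header = FALSE, sep = "\t", quote = "",
                           colClasses = "character", comment.char = "#")
  if (ncol(tab) < 4)
    stop("site BED must have at least 4 columns (chrom, start, end, gene)")
  start <- suppressWarnings(as.numeric(tab[[2]]))
  end <- suppressWarnings(as.numeric(tab[[3]]))
  if (anyNA(start) || anyNA(end))
    stop("non-numeric BED coordinates in ", path)
  bad <- which(end <= start)
  if (length(bad))
    stop(sprintf("invalid BED interval at line %d of %s: end (%s) <= start (%s)",
                 bad[1], path, format(end[bad[1]]), format(start[bad[1]])))
  data.frame(chrom = tab[[1]],
             pos = as.integer(ceiling((start + end) / 2)),
             gene = tab[[4]],
             stringsAsFactors = FALSE)
}

#' Write m6A sites as BED3+1 (width-1 records)
#' @param sites Data frame with `chrom`, `pos`, `gene` (1-based positions).
#' @param path Output BED path.
#' @return `path`, invisibly.
#' @export
write_sites_bed <- function(sites, path) {
  stopifnot(all(c("chrom", "pos", "gene") %in% names(sites)))
  df <- data.frame(sites$chrom, sites$pos - 1L, sites$pos, sites$gene)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

eqtl_required_cols <- c("SNP", "SNPChr", "SNPPos", "AssessedAllele",
                        "OtherAllele", "Pvalue", "GeneSymbol")

#' Read a trans-eQTL table
#'
#' Reads an eQTLGen-style TSV with columns `SNP`, `SNPChr`, `SNPPos`,
#' `AssessedAllele`, `OtherAllele`, `Pvalue`, `GeneSymbol` (extra columns are
#' preserved). Positions are 1-based database coordinates; no liftover is
#' performed, so the eQTL table and the m6A sites must be on the same genome
#' build.
#'
#' @param path Path to the eQTL TSV.
#' @return Data frame with columns `snp_id`, `chrom`, `pos`,
#'   `assessed_allele`, `other_allele`, `pvalue`, `gene`, plus any extra input
#'   columns.
#' @export
read_eqtl <- function(path) {
  if (!file.exists(path)) stop("eQTL file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                           check.names = FALSE, stringsAsFactors = FALSE)
  missing <- setdiff(eqtl_required_cols, names(tab))
  if (length(missing))
    stop("eQTL table missing required column(s): ",
         paste(missing, collapse = ", "))
  out <- data.frame(snp_id = as.character(tab$SNP),
                    chrom = as.character(tab$SNPChr),
                    pos = as.integer(tab$SNPPos),
                    assessed_allele = toupper(as.character(tab$AssessedAllele)),
                    other_allele = toupper(as.character(tab$OtherAllele)),
                    pvalue = as.numeric(tab$Pvalue),
                    gene = as.character(tab$GeneSymbol),
                    stringsAsFactors = FALSE)
  extra <- setdiff(names(tab), eqtl_required_cols)
  for (col in extra) out[[col]] <- tab[[col]]
  validate_eqtl(out, path)
  out
}

validate_eqtl <- function(x, origin = "eQTL table") {
  nt <- c("A", "C", "G", "T")
  bad <- which(!(x$assessed_allele %in% nt) | !(x$other_allele %in% nt))
  if (length(bad))
    stop(origin, ": alleles must be one of A/C/G/T (record ", bad[1],
         ", SNP ", x$snp_id[bad[1]], ")")
  same <- which(x$assessed_allele == x$other_allele)
  if (length(same))
    stop(origin, ": assessed and other allele are identical for SNP ",
         x$snp_id[same[1]])
  if (any(x$pos < 1, na.rm = TRUE))
    stop(origin, ": SNP positions must be >= 1")
  if (any(is.na(x$pvalue) | x$pvalue <= 0 | x$pvalue > 1))
    stop(origin, ": p-values must lie in (0, 1]")
  invisible(x)
}

#' Write a trans-eQTL table in the format [read_eqtl()] accepts
#' @param eqtls Data frame as returned by [read_eqtl()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_eqtl <- function(eqtls, path) {
  df <- data.frame(SNP = eqtls$snp_id, SNPChr = eqtls$chrom,
                   SNPPos = eqtls$pos, AssessedAllele = eqtls$assessed_allele,
                   OtherAllele = eqtls$other_allele, Pvalue = eqtls$pvalue,
                   GeneSymbol = eqtls$gene, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a network edge table
#'
#' Columns: `regulator`, `gene`, `rho`, `t`, `df`, `p`, `p_adj`. An empty edge
#' list writes a header-only file; [read_edges()] is its exact inverse.
#'
#' @param edges Data frame of edges (see [build_network()]).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_edges <- function(edges, path) {
  cols <- c("regulator", "gene", "rho", "t", "df", "p", "p_adj")
  df <- as.data.frame(edges, stringsAsFactors = FALSE)
  for (col in setdiff(cols, names(df))) df[[col]] <- rep(NA_real_, nrow(df))
  utils::write.table(df[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_edges
#' @export
read_edges <- function(path) {
  if (!file.exists(path)) stop("edge file not found: ", path)
  utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                    stringsAsFactors = FALSE)
}

#' Generic TSV writer for summary tables
#' @param rows A data frame.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_table <- function(rows, path) {
  utils::write.table(as.data.frame(rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
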