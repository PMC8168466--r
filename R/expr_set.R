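#' Expression set container
#'
#' A light container for a normalized expression matrix (genes x samples) with
#' optional per-sample case/control labels. Values are assumed to be on a log
#' scale after upstream normalization (e.g. TMM followed by length adjustment);
#' the package never re-normalizes.
#'
#' @param values Numeric matrix, genes in rows (rownames = gene symbols),
#'   samples in columns (colnames = sample identifiers).
#' @param group Optional per-sample labels, either a character/factor vector of
#'   length `ncol(values)` or a named vector keyed by sample id. Levels are
#'   normalized to `"control"` and `"case"` (`"T2DM"` is accepted as a synonym
#'   for `"case"`).
#'
#' @return An object of class `expr_set`: a list with elements `values`
#'   (validated matrix) and `group` (factor with levels control/case, or
#'   `NULL`).
#' @export
#' @examples
#' m <- matrix(rnorm(6), 2, 3,
#'             dimnames = list(c("G1", "G2"), c("S1", "S2", "S3")))
#' es <- expr_set(m, group = c("control", "control", "case"))
#' dim(es)
expr_set <- function(values, group = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix (genes x samples)")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have gene rownames and sample colnames")
  dup_g <- rownames(values)[duplicated(rownames(values))]
  if (length(dup_g))
    stop("duplicate gene identifiers: ", paste(unique(dup_g), collapse = ", "))
  dup_s <- colnames(values)[duplicated(colnames(values))]
  if (length(dup_s))
    stop("duplicate sample identifiers: ", paste(unique(dup_s), collapse = ", "))
  if (any(is.infinite(values)))
    stop("expression values must be finite or NA")
  grp <- NULL
  if (!is.null(group)) {
    group <- as.character(group)
    if (!is.null(names(group))) {
      missing <- setdiff(colnames(values), names(group))
      if (length(missing))
        stop("no group label for samples: ", paste(missing, collapse = ", "))
      group <- group[colnames(values)]
    } else if (length(group) != ncol(values)) {
      stop("'group' must have one label per sample")
    }
    grp <- normalize_group(group)
    names(grp) <- colnames(values)
  }
  structure(list(values = values, group = grp), class = "expr_set")
}

normalize_group <- function(x) {
  lab <- tolower(trimws(as.character(x)))
  lab[lab == "t2dm"] <- "case"
  bad <- setdiff(unique(lab), c("control", "case"))
  if (length(bad))
    stop("group labels must be 'control' or 'case' (got: ",
         paste(bad, collapse = ", "), ")")
  factor(lab, levels = c("control", "case"))
}

#' @export
dim.expr_set <- function(x) dim(x$values)

#' Gene symbols and sample identifiers of an expression set
#' @param x An `expr_set`.
#' @return Character vector of gene symbols (`genes()`) or sample ids
#'   (`samples()`).
#' @export
genes <- function(x) rownames(x$values)

#' @rdname genes
#' @export
samples <- function(x) colnames(x$values)

#' @export
print.expr_set <- function(x, ...) {
  cat(sprintf("expr_set: %d genes x %d samples\n", nrow(x$values), ncol(x$values)))
  if (!is.null(x$group)) {
    tab <- table(x$group)
    cat(sprintf("  groups: %s\n",
                paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  } else {
    cat("  groups: <none>\n")
  }
  invisible(x)
}

#' Subset an expression set by gene and/or sample
#' @param x An `expr_set`.
#' @param i Gene index (integer, logical or symbol).
#' @param j Sample index.
#' @param ... Ignored.
#' @export
`[.expr_set` <- function(x, i, j, ...) {
  v <- x$values[i, j, drop = FALSE]
  g <- if (!is.null(x$group)) x$group[colnames(v)] else NULL
  structure(list(values = v, group = g), class = "expr_set")
}

# Drop genes carrying any missing value before statistics; pairwise-complete
# correlation would silently change the degrees of freedom.
drop_incomplete_genes <- function(x) {
  bad <- rowSums(is.na(x$values)) > 0
  if (any(bad)) {
    warning(sum(bad), " gene(s) with missing values dropped: ",
            paste(utils::head(rownames(x$values)[bad], 5), collapse = ", "),
            if (sum(bad) > 5) ", ..." else "")
    x <- x[!bad, seq_len(ncol(x$values))]
  }
  x
}
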