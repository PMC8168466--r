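#' Pipeline configuration
#'
#' Collects every input path, threshold and flag of the end-to-end analysis in
#' one validated object. Threshold defaults are the analysis' canonical
#' cut-offs: |logFC| > 2 with FDR < 0.05 for the DE gate, SD <= 0.1 flat-gene
#' exclusion, coefficient >= 0.3 for network edges, |rho| >= 0.35 to call a
#' gene co-expressed, p < 0.05 for the partial-correlation test, and 100-bp
#' m6A peak windows.
#'
#' @param expr,groups,regulators,controls,sites,eqtl Input file paths
#'   (expression TSV, sample-group TSV, two gene lists, m6A site BED,
#'   trans-eQTL TSV). `groups`, `sites` and `eqtl` may be `NULL` to skip the
#'   DE gate or the genomic stages.
#' @param out_dir Output directory for stage tables and the manifest.
#' @param lfc_min,de_alpha DE gate thresholds.
#' @param sd_min Flat-expression SD threshold (inclusive removal).
#' @param edge_rho_min Network edge coefficient threshold.
#' @param gene_rho_min Coefficient threshold to call a gene co-expressed.
#' @param pcor_alpha Significance level of the partial-correlation test.
#' @param peak_width m6A peak window width (bp).
#' @param require_significance Require p < `pcor_alpha` in addition to the
#'   coefficient thresholds.
#' @param same_gene Require eQTL target gene to equal the peak's gene.
#' @param comparator Coefficient comparator, `">="` (inclusive) or `">"`.
#' @param anchor Peak window anchor (see [sites_to_peaks()]).
#' @param de_gate_candidates Also restrict candidate genes to DE genes
#'   (default `FALSE`: the DE gate applies to the regulator and control lists
#'   only).
#' @param annotations Optional character vector of disease-annotated genes
#'   (supplied annotation, merged into the gene table).
#' @param seed Integer seed recorded in the manifest (the pipeline itself is
#'   deterministic).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(expr, groups = NULL, regulators, controls,
                            sites = NULL, eqtl = NULL, out_dir = NULL,
                            lfc_min = 2, de_alpha = 0.05, sd_min = 0.1,
                            edge_rho_min = 0.3, gene_rho_min = 0.35,
                            pcor_alpha = 0.05, peak_width = 100L,
                            require_significance = TRUE, same_gene = TRUE,
                            comparator = c(">=", ">"),
                            anchor = c("center", "left", "right"),
                            de_gate_candidates = FALSE,
                            annotations = NULL, seed = 1L) {
  cfg <- list(expr = expr, groups = groups, regulators = regulators,
              controls = controls, sites = sites, eqtl = eqtl,
              out_dir = out_dir, lfc_min = lfc_min, de_alpha = de_alpha,
              sd_min = sd_min, edge_rho_min = edge_rho_min,
              gene_rho_min = gene_rho_min, pcor_alpha = pcor_alpha,
              peak_width = as.integer(peak_width),
              require_significance = isTRUE(require_significance),
              same_gene = isTRUE(same_gene),
              comparator = match.arg(comparator),
              anchor = match.arg(anchor),
              de_gate_candidates = isTRUE(de_gate_candidates),
              annotations = annotations, seed = as.integer(seed))
  thresholds <- unlist(cfg[c("lfc_min", "de_alpha", "sd_min", "edge_rho_min",
                             "gene_rho_min", "pcor_alpha", "peak_width")])
  if (any(thresholds < 0)) stop("all thresholds must be >= 0")
  structure(cfg, class = "pipeline_config")
}

#' Run the full co-expression / m6A / eQTL analysis
#'
#' Executes, in order: input reading and validation; the DE gate on the
#' regulator and control gene lists; flat-gene SD filtering; the genome-wide
#' partial-correlation screen; network construction and the co-expressed gene
#' table; intersection with m6A peak annotations; the SNP-in-peak eQTL screen
#' and its summaries. Any stage error aborts with the stage named. Row counts
#' of every stage are collected and, when `out_dir` is set, all stage tables
#' plus a machine-readable manifest (input hashes, thresholds, stage counts,
#' package version) are written; runs with identical inputs and configuration
#' produce byte-identical files.
#'
#' @param cfg A [pipeline_config()].
#' @param quiet Suppress per-stage progress messages.
#' @return An object of class `m6a_run`: list with `config`, `counts`, `de`,
#'   `screen`, `edges`, `co_table`, `com6ar`, `peaks`, `hits`, `summary`,
#'   `manifest`.
#' @export
run_all <- function(cfg, quiet = FALSE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  say <- function(...) if (!quiet) message(...)
  stage <- "validate inputs"
  run <- tryCatch({
    paths <- Filter(Negate(is.null),
                    cfg[c("expr", "groups", "regulators", "controls",
                          "sites", "eqtl")])
    missing <- paths[!vapply(paths, file.exists, logical(1))]
    if (length(missing))
      stop("input file(s) not found: ",
           paste(sprintf("%s (%s)", unlist(missing), names(missing)),
                 collapse = ", "))

    stage <- "read inputs"
    expr <- read_expression(cfg$expr, group_map = cfg$groups)
    regulators <- read_gene_list(cfg$regulators)
    controls <- read_gene_list(cfg$controls)
    sites <- if (!is.null(cfg$sites)) read_sites_bed(cfg$sites)
    eqtls <- if (!is.null(cfg$eqtl)) read_eqtl(cfg$eqtl)
    counts <- list(genes_detected = nrow(expr$values),
                   samples = ncol(expr$values),
                   regulators_listed = length(regulators),
                   controls_listed = length(controls))
    say(sprintf("read: %d genes x %d samples", nrow(expr$values),
                ncol(expr$values)))

    stage <- "differential-expression gate"
    de <- NULL
    if (!is.null(expr$group)) {
      de <- differential_expression(expr, lfc_min = cfg$lfc_min,
                                    alpha = cfg$de_alpha)
      de_genes <- de$gene[de$is_de]
      regulators <- intersect(regulators, de_genes)
      controls <- intersect(controls, de_genes)
      if (!length(regulators))
        stop("no regulator passes the differential-expression gate")
    } else {
      say("no group labels: differential-expression gate skipped")
    }
    counts$regulators_de <- length(regulators)
    counts$controls_de <- length(controls)
    say(sprintf("DE gate: %d regulators, %d controls retained",
                length(regulators), length(controls)))

    stage <- "flat-gene filter"
    kept <- sd_filter(expr, threshold = cfg$sd_min)
    lost_ctrl <- setdiff(controls, genes(kept))
    if (length(lost_ctrl)) {
      say("control gene(s) removed by SD filter: ",
          paste(lost_ctrl, collapse = ", "))
      controls <- setdiff(controls, lost_ctrl)
    }
    regulators <- intersect(regulators, genes(kept))
    counts$genes_after_sd_filter <- nrow(kept$values)
    candidates <- setdiff(genes(kept), c(regulators, controls))
    if (cfg$de_gate_candidates && !is.null(de))
      candidates <- intersect(candidates, de$gene[de$is_de])
    counts$candidates <- length(candidates)
    say(sprintf("SD filter: %d genes retained, %d candidates",
                nrow(kept$values), length(candidates)))

    stage <- "partial-correlation screen"
    screen <- pcor_screen(kept, regulators = regulators, controls = controls,
                          candidates = candidates)

    stage <- "network construction"
    edges <- build_network(screen, rho_min = cfg$edge_rho_min,
                           comparator = cfg$comparator,
                           require_significance = cfg$require_significance,
                           alpha = cfg$pcor_alpha)
    co_edges <- build_network(screen, rho_min = cfg$gene_rho_min,
                              comparator = cfg$comparator,
                              require_significance = cfg$require_significance,
                              alpha = cfg$pcor_alpha)
    counts$network_edges <- nrow(edges)
    counts$coexpressed_genes <- length(unique(co_edges$gene))
    say(sprintf("network: %d edges (|rho| %s %.2f); %d co-expressed genes (|rho| %s %.2f)",
                nrow(edges), cfg$comparator, cfg$edge_rho_min,
                counts$coexpressed_genes, cfg$comparator, cfg$gene_rho_min))

    stage <- "m6A intersection"
    peaks <- NULL; com6ar <- NULL
    co_table <- multi_regulator_table(co_edges, annotations = cfg$annotations)
    if (!is.null(sites)) {
      peaks <- sites_to_peaks(sites, width = cfg$peak_width,
                              anchor = cfg$anchor)
      flags <- flag_m6a_genes(peaks, co_table$gene)
      co_table$has_m6a <- unname(flags[co_table$gene])
      com6ar <- intersect_com6ar(co_table, flags)
      counts$com6ar_m6a <- nrow(com6ar)
      say(sprintf("m6A intersection: %d of %d co-expressed genes carry m6A",
                  nrow(com6ar), nrow(co_table)))
    }

    stage <- "eQTL screen"
    hits <- NULL; hit_summary <- NULL
    if (!is.null(eqtls) && !is.null(peaks)) {
      target_genes <- if (!is.null(com6ar)) com6ar$gene else co_table$gene
      peaks_in_set <- peaks[peaks$gene %in% target_genes, , drop = FALSE]
      hits <- snps_in_peaks(eqtls, peaks_in_set, same_gene = cfg$same_gene)
      hit_summary <- summarize_hits(hits)
      counts$eqtl_records <- nrow(eqtls)
      counts$eqtl_hits <- nrow(hits)
      say(sprintf("eQTL screen: %d of %d SNPs fall in m6A peak windows",
                  nrow(hits), nrow(eqtls)))
    }

    list(config = cfg, counts = counts, de = de, screen = screen,
         edges = edges, co_table = co_table, com6ar = com6ar, peaks = peaks,
         hits = hits, summary = hit_summary)
  }, error = function(e) {
    stop(sprintf("pipeline aborted at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })

  run$manifest <- NULL
  if (!is.null(cfg$out_dir)) {
    stage <- "write outputs"
    run$manifest <- write_run_outputs(run, cfg)
  }
  structure(run, class = "m6a_run")
}

write_run_outputs <- function(run, cfg) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(cfg$out_dir, f)
  if (!is.null(run$de)) write_table(run$de, p("de.tsv"))
  write_table(run$screen$results, p("pcor.tsv"))
  write_edges(run$edges, p("edges.tsv"))
  write_table(run$co_table, p("co_genes.tsv"))
  if (!is.null(run$com6ar)) write_table(run$com6ar, p("com6ar.tsv"))
  if (!is.null(run$peaks)) write_table(run$peaks, p("peaks.tsv"))
  if (!is.null(run$hits)) {
    write_table(run$hits, p("hits.tsv"))
    tabs <- summary_tables(run$summary)
    write_table(tabs$by_chrom, p("hits_by_chrom.tsv"))
    write_table(tabs$by_gene, p("hits_by_gene.tsv"))
    write_table(tabs$by_allele, p("hits_by_allele.tsv"))
  }
  inputs <- Filter(Negate(is.null),
                   cfg[c("expr", "groups", "regulators", "controls",
                         "sites", "eqtl")])
  manifest <- list(
    package = "m6Acoexpr",
    version = as.character(utils::packageVersion("m6Acoexpr")),
    seed = cfg$seed,
    thresholds = cfg[c("lfc_min", "de_alpha", "sd_min", "edge_rho_min",
                       "gene_rho_min", "pcor_alpha", "peak_width")],
    flags = cfg[c("require_significance", "same_gene", "comparator",
                  "anchor", "de_gate_candidates")],
    input_md5 = as.list(tools::md5sum(unlist(inputs))),
    stage_counts = run$counts)
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  p("manifest.json")
}

#' @export
print.m6a_run <- function(x, ...) {
  cat("End-to-end m6A co-expression run\n")
  for (nm in names(x$counts))
    cat(sprintf("  %-22s %s\n", nm, format(x$counts[[nm]])))
  if (!is.null(x$summary)) {
    cat("eQTL hit summary:\n")
    print(x$summary)
  }
  invisible(x)
}
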