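#' Simulation configuration
#'
#' Defines the generative model for synthetic case/control expression data
#' with a latent confounder driven by the control-gene set, so that
#' "controlling for D" measurably changes regulator-gene associations.
#'
#' The model, per sample: control genes `D_i ~ N(0, 1)` i.i.d. (plus the DE
#' shift in case samples when controls are designated DE); a latent confounder
#' `Z` equal to the standardized mean of the observed control genes (unit
#' variance, so `gamma_confound` is a loading that does not shrink as the
#' control set grows, and an exact linear function of D, so regressing out D
#' removes the confounding exactly); regulators
#' `M_j = gamma_confound * Z + N(0, sigma)`;
#' direct targets `= beta_direct * M_j + N(0, sigma)` (each direct target is
#' assigned a source regulator round-robin); confounded targets
#' `= gamma_confound * Z + N(0, sigma)` with no direct regulator term; null
#' genes pure `N(0, sigma)` noise. Genes in the categories named by
#' `de_categories` additionally receive `+de_shift` in case samples; the shift
#' is applied to regulators before direct targets are built from them, so
#' direct targets inherit their regulator's differential expression.
#'
#' Defaults mirror the dimensions of a 178-sample islet study screened against
#' 15 m6A regulators and 40 diabetes-pathway control genes.
#'
#' @param n_samples Number of samples (columns).
#' @param n_case Number of case samples (first `n_case` columns, default half
#'   of `n_samples`); the rest are controls.
#' @param n_regulators,n_controls,n_direct,n_confounded,n_null Gene counts per
#'   category.
#' @param beta_direct Direct regulator-to-target effect size (regression
#'   weight).
#' @param gamma_confound Loading of regulators and confounded targets on the
#'   latent control-gene confounder.
#' @param sigma_noise Residual standard deviation (> 0).
#' @param de_shift Case-minus-control mean shift added to designated DE genes
#'   (log2 units; the default 3 clears a |logFC| > 2 gate).
#' @param de_categories Gene categories receiving the DE shift.
#' @param seed Integer RNG seed; equal seeds give bit-identical output.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_samples = 178, n_case = floor(n_samples / 2),
                       n_regulators = 15, n_controls = 40,
                       n_direct = 30, n_confounded = 30, n_null = 100,
                       beta_direct = 0.6, gamma_confound = 0.8,
                       sigma_noise = 1, de_shift = 3,
                       de_categories = c("regulator", "control"),
                       seed = 1L) {
  cfg <- list(n_samples = as.integer(n_samples), n_case = as.integer(n_case),
              n_regulators = as.integer(n_regulators),
              n_controls = as.integer(n_controls),
              n_direct = as.integer(n_direct),
              n_confounded = as.integer(n_confounded),
              n_null = as.integer(n_null),
              beta_direct = beta_direct, gamma_confound = gamma_confound,
              sigma_noise = sigma_noise, de_shift = de_shift,
              de_categories = de_categories, seed = as.integer(seed))
  counts <- unlist(cfg[c("n_samples", "n_case", "n_regulators", "n_controls",
                         "n_direct", "n_confounded", "n_null")])
  if (any(counts < 0)) stop("all counts must be >= 0")
  if (cfg$n_case > cfg$n_samples) stop("n_case must be <= n_samples")
  if (cfg$sigma_noise <= 0) stop("sigma_noise must be > 0")
  if (cfg$n_direct > 0 && cfg$n_regulators == 0)
    stop("direct targets require at least one regulator")
  bad <- setdiff(cfg$de_categories,
                 c("regulator", "control", "direct", "confounded", "null"))
  if (length(bad)) stop("unknown de_categories: ", paste(bad, collapse = ", "))
  structure(cfg, class = "sim_config")
}

sim_gene_names <- function(cfg) {
  nm <- function(prefix, n) if (n > 0) sprintf("%s%03d", prefix, seq_len(n)) else character(0)
  list(control = nm("CTRL", cfg$n_controls),
       regulator = nm("REG", cfg$n_regulators),
       direct = nm("DIR", cfg$n_direct),
       confounded = nm("CONF", cfg$n_confounded),
       null = nm("NULL", cfg$n_null))
}

#' Simulate a labelled expression matrix
#'
#' Draws an expression matrix under the generative model described in
#' [sim_config()], together with per-gene truth labels. Gene names encode
#' their category (`CTRL###`, `REG###`, `DIR###`, `CONF###`, `NULL###`) so
#' ground truth is recoverable in tests.
#'
#' @param cfg A [sim_config()].
#' @return A list with elements `expr` (an [expr_set] with case/control
#'   groups) and `labels` (data frame: `gene`, `category`, `source_regulator`,
#'   `effect`, `de_shift`).
#' @export
simulate_expression <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_samples
  nms <- sim_gene_names(cfg)
  is_case <- c(rep(1, cfg$n_case), rep(0, n - cfg$n_case))
  shift_for <- function(category)
    if (category %in% cfg$de_categories) cfg$de_shift * is_case else rep(0, n)
  empty <- matrix(numeric(0), nrow = 0, ncol = n)
  noise <- function(k) matrix(stats::rnorm(k * n, sd = cfg$sigma_noise), nrow = k)

  D <- empty
  Z <- rep(0, n)
  if (cfg$n_controls > 0) {
    D <- matrix(stats::rnorm(cfg$n_controls * n), nrow = cfg$n_controls,
                dimnames = list(nms$control, NULL))
    D <- sweep(D, 2, shift_for("control"), "+")
    # latent confounder: standardized mean of the *observed* control genes.
    # Being an exact linear function of D guarantees that regressing D out
    # removes the confounding exactly, whatever shifts D carries.
    zr <- colMeans(D)
    Z <- if (stats::sd(zr) > 0) (zr - mean(zr)) / stats::sd(zr) else rep(0, n)
  }

  M <- empty
  if (cfg$n_regulators > 0) {
    M <- matrix(rep(cfg$gamma_confound * Z, each = cfg$n_regulators),
                nrow = cfg$n_regulators) + noise(cfg$n_regulators)
    M <- sweep(M, 2, shift_for("regulator"), "+")
    rownames(M) <- nms$regulator
  }

  src <- integer(0)
  DIR <- empty
  if (cfg$n_direct > 0) {
    src <- rep(seq_len(cfg$n_regulators), length.out = cfg$n_direct)
    DIR <- cfg$beta_direct * M[src, , drop = FALSE] + noise(cfg$n_direct)
    DIR <- sweep(DIR, 2, shift_for("direct"), "+")
    rownames(DIR) <- nms$direct
  }

  CONF <- empty
  if (cfg$n_confounded > 0) {
    CONF <- matrix(rep(cfg$gamma_confound * Z, each = cfg$n_confounded),
                   nrow = cfg$n_confounded) + noise(cfg$n_confounded)
    CONF <- sweep(CONF, 2, shift_for("confounded"), "+")
    rownames(CONF) <- nms$confounded
  }

  NUL <- empty
  if (cfg$n_null > 0) {
    NUL <- noise(cfg$n_null)
    NUL <- sweep(NUL, 2, shift_for("null"), "+")
    rownames(NUL) <- nms$null
  }

  values <- rbind(D, M, DIR, CONF, NUL)
  colnames(values) <- sprintf("S%03d", seq_len(n))
  group <- ifelse(is_case == 1, "case", "control")

  labels <- data.frame(
    gene = rownames(values),
    category = rep(c("control", "regulator", "direct", "confounded", "null"),
                   c(cfg$n_controls, cfg$n_regulators, cfg$n_direct,
                     cfg$n_confounded, cfg$n_null)),
    source_regulator = NA_character_,
    effect = NA_real_,
    stringsAsFactors = FALSE)
  if (cfg$n_direct > 0) {
    labels$source_regulator[labels$category == "direct"] <- nms$regulator[src]
    labels$effect[labels$category == "direct"] <- cfg$beta_direct
  }
  labels$de_shift <- ifelse(labels$category %in% cfg$de_categories,
                            cfg$de_shift, 0)
  list(expr = expr_set(values, group = group), labels = labels)
}

#' Simulate m6A sites and a trans-eQTL table on a toy genome
#'
#' Places one or more m6A sites per selected gene on a toy coordinate system
#' (genes spaced far apart so peak windows never collide across genes) and
#' then places eQTL SNPs at controlled offsets from each site, cycling through
#' in-window and out-of-window offsets including the exact window boundaries,
#' so in-peak status is known by construction. Truth labels record each SNP's
#' offset and whether it falls inside the centered window of width `width`.
#'
#' @param cfg A [sim_config()] (supplies the seed).
#' @param genes Character vector of gene symbols to annotate (must match the
#'   expression matrix's symbols).
#' @param chrom_map Optional named character vector mapping gene -> chromosome;
#'   by default genes are assigned round-robin to `chr1..chr5`.
#' @param m6a_fraction Fraction of `genes` (from the front of the vector) that
#'   receive m6A sites.
#' @param sites_per_gene Number of m6A sites per selected gene.
#' @param snps_per_site Number of eQTL SNPs placed around each site.
#' @param width Peak window width (bp) used to label in/out-of-window truth;
#'   must match the width later passed to [sites_to_peaks()].
#' @return A list with `sites` (chrom, pos, gene), `eqtls` (as [read_eqtl()]
#'   returns) and `snp_truth` (snp_id, gene, site_pos, offset, in_window).
#' @export
simulate_genome_annotations <- function(cfg, genes, chrom_map = NULL,
                                        m6a_fraction = 0.5,
                                        sites_per_gene = 1L,
                                        snps_per_site = 3L,
                                        width = 100L) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!length(genes)) stop("no genes supplied")
  if (is.null(chrom_map)) {
    chrom_map <- stats::setNames(paste0("chr", ((seq_along(genes) - 1L) %% 5L) + 1L),
                                 genes)
  } else {
    missing <- setdiff(genes, names(chrom_map))
    if (length(missing))
      stop("chrom_map missing gene(s): ", paste(missing, collapse = ", "))
  }
  set.seed(cfg$seed + 104729L)  # sub-stream for the annotation stage
  n_m6a <- max(1L, floor(length(genes) * m6a_fraction))
  m6a_genes <- genes[seq_len(min(n_m6a, length(genes)))]

  half <- floor(width / 2)
  # centered window is [pos - half, pos - half + width - 1]; offsets -half and
  # width - 1 - half are the exact in-window boundaries, -half - 1 and
  # width - half just outside
  offset_pool <- c(0L, -half, width - 1L - half, -half - 1L, width - half,
                   2L * width, -2L * width)

  sites <- list(); eqtls <- list(); truth <- list()
  snp_counter <- 0L
  for (gi in seq_along(m6a_genes)) {
    g <- m6a_genes[gi]
    for (si in seq_len(sites_per_gene)) {
      pos <- 50000L * gi + 5000L * (si - 1L) + 1000L
      sites[[length(sites) + 1L]] <-
        data.frame(chrom = chrom_map[[g]], pos = pos, gene = g,
                   stringsAsFactors = FALSE)
      for (vi in seq_len(snps_per_site)) {
        snp_counter <- snp_counter + 1L
        off <- offset_pool[((snp_counter - 1L) %% length(offset_pool)) + 1L]
        alleles <- sample(c("A", "C", "G", "T"), 2L)
        pv <- 10^(-stats::runif(1, 2, 30))
        truth[[snp_counter]] <- data.frame(
          snp_id = sprintf("rs%06d", snp_counter), gene = g,
          site_pos = pos, offset = off,
          in_window = off >= -half && off <= width - 1L - half,
          stringsAsFactors = FALSE)
        eqtls[[snp_counter]] <- data.frame(
          snp_id = sprintf("rs%06d", snp_counter),
          chrom = chrom_map[[g]], pos = pos + off,
          assessed_allele = alleles[1], other_allele = alleles[2],
          pvalue = pv, gene = g, stringsAsFactors = FALSE)
      }
    }
  }
  list(sites = do.call(rbind, sites),
       eqtls = do.call(rbind, eqtls),
       snp_truth = do.call(rbind, truth))
}

#' Write a complete synthetic fixture directory
#'
#' Materializes one simulated study as the files the pipeline reads:
#' `expression.tsv`, `groups.tsv`, `regulators.txt`, `controls.txt`,
#' `sites.bed`, `eqtl.tsv`, plus `truth_genes.tsv` and `truth_snps.tsv`.
#'
#' @param cfg A [sim_config()].
#' @param dir Output directory (created if needed).
#' @param ... Passed to [simulate_genome_annotations()].
#' @return `dir`, invisibly.
#' @export
simulate_fixture_dir <- function(cfg, dir, ...) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_expression(cfg)
  ann_genes <- sim$labels$gene[sim$labels$category %in%
                                 c("direct", "confounded", "null")]
  ann <- simulate_genome_annotations(cfg, ann_genes, ...)
  p <- function(f) file.path(dir, f)
  write_expression(sim$expr, p("expression.tsv"), group_path = p("groups.tsv"))
  writeLines(sim$labels$gene[sim$labels$category == "regulator"],
             p("regulators.txt"))
  writeLines(sim$labels$gene[sim$labels$category == "control"],
             p("controls.txt"))
  write_sites_bed(ann$sites, p("sites.bed"))
  write_eqtl(ann$eqtls, p("eqtl.tsv"))
  write_table(sim$labels, p("truth_genes.tsv"))
  write_table(ann$snp_truth, p("truth_snps.tsv"))
  invisible(dir)
}
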