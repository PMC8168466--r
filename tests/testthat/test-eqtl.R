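toy_eqtl <- function(pos, gene = "A", chrom = "chr1",
                     snp_id = sprintf("rs%d", seq_along(pos)),
                     assessed = "A", other = "G", pvalue = 1e-8) {
  data.frame(snp_id = snp_id, chrom = chrom, pos = as.integer(pos),
             assessed_allele = assessed, other_allele = other,
             pvalue = pvalue, gene = gene, stringsAsFactors = FALSE)
}

toy_peaks <- function(pos, gene = "A", chrom = "chr1", width = 100L) {
  sites_to_peaks(data.frame(chrom = chrom, pos = as.integer(pos), gene = gene,
                            stringsAsFactors = FALSE), width = width)
}

test_that("SNPs hit peaks on closed-interval containment", {
  peaks <- toy_peaks(1000)                      # [950, 1049]
  expect_equal(nrow(snps_in_peaks(toy_eqtl(1000), peaks)), 1L)
  expect_equal(nrow(snps_in_peaks(toy_eqtl(950), peaks)), 1L)   # start bound
  expect_equal(nrow(snps_in_peaks(toy_eqtl(1049), peaks)), 1L)  # end bound
  expect_equal(nrow(snps_in_peaks(toy_eqtl(1050), peaks)), 0L)  # 1 bp past end
  expect_equal(nrow(snps_in_peaks(toy_eqtl(949), peaks)), 0L)
})

test_that("gene identity is required only when same_gene is on", {
  peaks <- toy_peaks(1000, gene = "A")
  eq <- toy_eqtl(1000, gene = "B")
  expect_equal(nrow(snps_in_peaks(eq, peaks, same_gene = TRUE)), 0L)
  hit <- snps_in_peaks(eq, peaks, same_gene = FALSE)
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$peak_gene, "A")
})

test_that("two nearby SNPs can share a single 100-bp window", {
  # mirrors two variants 18 bp apart inside one gene's window
  peaks <- toy_peaks(2754800, gene = "SGTA1", chrom = "chr19")
  eq <- toy_eqtl(c(2754792, 2754810), gene = "SGTA1", chrom = "chr19")
  hits <- snps_in_peaks(eq, peaks)
  expect_equal(nrow(hits), 2L)
  expect_equal(unique(hits$peak_start), 2754750L)
})

test_that("duplicate (SNP, gene) hits collapse to the nearest-site peak", {
  sites <- data.frame(chrom = "chr1", pos = c(1000L, 1040L),
                      gene = "A", stringsAsFactors = FALSE)
  peaks <- sites_to_peaks(sites, width = 100)   # overlapping windows
  hits <- snps_in_peaks(toy_eqtl(1030), peaks)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$source_pos, 1040L)
})

test_that("Bonferroni adjustment multiplies, caps, and validates", {
  expect_equal(bonferroni(0.01, 1), 0.01)
  expect_equal(bonferroni(0.5, 10), 1)
  expect_equal(bonferroni(1e-6, 1000), 1e-3)
  expect_true(all(bonferroni(c(0.2, 0.9), 3) >= c(0.2, 0.9)))
  expect_error(bonferroni(0.1, 0), "m")
})

test_that("hits carry a Bonferroni p over the records screened by default", {
  peaks <- toy_peaks(1000)
  eq <- toy_eqtl(c(1000, 5000, 6000, 7000), pvalue = c(1e-4, 1, 1, 1))
  hits <- snps_in_peaks(eq, peaks)
  expect_equal(hits$p_bonf, 4e-4)
  pass <- snps_in_peaks(eq, peaks, p_adjusted = TRUE)
  expect_equal(pass$p_bonf, 1e-4)
})

test_that("hit summaries count chromosomes, genes and involved alleles", {
  hits <- rbind(toy_eqtl(c(100, 200), gene = "A", chrom = "chr1",
                         snp_id = c("rs1", "rs2"),
                         assessed = c("A", "T"), other = c("G", "A")),
                toy_eqtl(300, gene = "B", chrom = "chr2", snp_id = "rs3",
                         assessed = "C", other = "G"))
  s <- summarize_hits(hits)
  expect_equal(s$n_hits, 3L)
  expect_equal(s$by_chrom, c(chr1 = 2L, chr2 = 1L))
  expect_equal(s$n_genes, 2L)
  expect_equal(s$by_gene, c(A = 2L, B = 1L))
  # "involved in" counts a nucleotide on either allele
  expect_equal(s$by_allele, c(A = 2L, C = 1L, G = 2L, T = 1L))
  expect_equal(sum(s$by_chrom), s$n_hits)

  shuffled <- summarize_hits(hits[c(3, 1, 2), ])
  expect_equal(shuffled, s)

  empty <- summarize_hits(hits[0, ])
  expect_equal(empty$n_hits, 0L)
  expect_equal(empty$n_genes, 0L)
  expect_equal(unname(empty$by_allele), rep(0L, 4))
})

test_that("in-window recovery on simulated annotations is exact", {
  cfg <- sim_config(seed = 15)
  genes <- sprintf("G%02d", 1:8)
  ann <- simulate_genome_annotations(cfg, genes, m6a_fraction = 1,
                                     snps_per_site = 7, width = 100)
  peaks <- sites_to_peaks(ann$sites, width = 100)
  hits <- snps_in_peaks(ann$eqtls, peaks)
  expect_setequal(hits$snp_id, ann$snp_truth$snp_id[ann$snp_truth$in_window])
})
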