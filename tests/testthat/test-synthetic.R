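test_that("degenerate configuration yields a single pure-noise gene", {
  cfg <- sim_config(n_samples = 4, n_case = 2, n_regulators = 0,
                    n_controls = 0, n_direct = 0, n_confounded = 0,
                    n_null = 1, seed = 11)
  sim <- simulate_expression(cfg)
  expect_equal(dim(sim$expr), c(1L, 4L))
  expect_equal(sim$labels$category, "null")
  expect_equal(sim$labels$gene, "NULL001")
})

test_that("direct targets become near-copies of their regulator as noise vanishes", {
  cfg <- sim_config(n_samples = 20, n_case = 0, n_regulators = 1,
                    n_controls = 5, n_direct = 1, n_confounded = 0,
                    n_null = 0, beta_direct = 1, sigma_noise = 1e-5,
                    de_shift = 0, seed = 5)
  sim <- simulate_expression(cfg)
  r <- cor(sim$expr$values["REG001", ], sim$expr$values["DIR001", ])
  expect_gt(r, 0.99)
})

test_that("equal seeds reproduce expression and annotations bit-identically", {
  cfg <- sim_config(n_samples = 30, n_controls = 4, n_regulators = 2,
                    n_direct = 3, n_confounded = 3, n_null = 5, seed = 7)
  a <- simulate_expression(cfg)
  b <- simulate_expression(cfg)
  expect_identical(a$expr$values, b$expr$values)
  expect_identical(a$labels, b$labels)
  g <- a$labels$gene[a$labels$category == "direct"]
  ann1 <- simulate_genome_annotations(cfg, g)
  ann2 <- simulate_genome_annotations(cfg, g)
  expect_identical(ann1$sites, ann2$sites)
  expect_identical(ann1$eqtls, ann2$eqtls)
  expect_identical(ann1$snp_truth, ann2$snp_truth)
})

test_that("every simulated value is finite and every gene has one category", {
  sim <- simulate_expression(sim_config(n_samples = 40, seed = 3))
  expect_true(all(is.finite(sim$expr$values)))
  expect_true(all(table(sim$labels$gene) == 1))
  expect_setequal(unique(sim$labels$category),
                  c("control", "regulator", "direct", "confounded", "null"))
})

test_that("annotation offsets encode in/out-of-window status by construction", {
  cfg <- sim_config(seed = 9)
  ann <- simulate_genome_annotations(cfg, c("DIR001", "DIR002"),
                                     m6a_fraction = 1, snps_per_site = 7,
                                     width = 100)
  tr <- ann$snp_truth
  expect_true(all(tr$in_window == (tr$offset >= -50 & tr$offset <= 49)))
  zero <- tr[tr$offset == 0, ]
  expect_true(all(zero$in_window))
  far <- tr[abs(tr$offset) >= 100, ]
  expect_true(all(!far$in_window))
  # SNP positions match site + offset in the emitted table
  m <- merge(ann$eqtls, tr, by = "snp_id")
  expect_equal(m$pos, m$site_pos + m$offset)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_case = 200, n_samples = 100), "n_case")
  expect_error(sim_config(sigma_noise = 0), "sigma_noise")
  expect_error(sim_config(n_regulators = -1), "counts")
  expect_error(sim_config(n_regulators = 0, n_direct = 2), "regulator")
  expect_error(simulate_genome_annotations(sim_config(), "G1",
                                           chrom_map = c(OTHER = "chr1")),
               "missing gene")
})

test_that("confounded genes lose their association once controls are partialled out", {
  # aggregate over seeds: plain correlation with the regulator set is clearly
  # positive for confounded genes, while the partial correlation concentrates
  # near zero and well below that of direct targets
  pc_conf <- c(); pc_dir <- c(); plain_conf <- c()
  for (s in 1:12) {
    cfg <- sim_config(n_samples = 178, n_regulators = 3, n_controls = 40,
                      n_direct = 5, n_confounded = 5, n_null = 0, seed = s)
    sim <- simulate_expression(cfg)
    regs <- grep("^REG", genes(sim$expr), value = TRUE)
    ctrl <- grep("^CTRL", genes(sim$expr), value = TRUE)
    fit <- pcor_screen(sim$expr, regs, ctrl)
    r <- fit$results
    lab <- sim$labels
    dm <- merge(r, lab[lab$category == "direct",
                       c("gene", "source_regulator")], by = "gene")
    pc_dir <- c(pc_dir, abs(dm$rho[dm$regulator == dm$source_regulator]))
    cm <- r[grepl("^CONF", r$gene), ]
    pc_conf <- c(pc_conf, abs(cm$rho))
    pe <- cor(t(sim$expr$values[grep("^CONF", genes(sim$expr)), , drop = FALSE]),
              t(sim$expr$values[regs, , drop = FALSE]))
    plain_conf <- c(plain_conf, abs(as.vector(pe)))
  }
  expect_lt(mean(pc_conf), mean(pc_dir))
  expect_gt(mean(plain_conf), mean(pc_conf))
})
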