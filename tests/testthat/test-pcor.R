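test_that("residual partial correlation handles identity and degenerate inputs", {
  x <- c(1.2, 0.3, -0.7, 2.2, 0.9, -1.4)
  expect_equal(pcor_residual(x, x), 1)

  # both variables exact linear functions of a single control row
  z <- rnorm(8)
  expect_error(pcor_residual(2 * z + 1, -3 * z + 0.5, rbind(z)),
               "undefined")

  expect_error(pcor_residual(rnorm(5), rnorm(5), matrix(rnorm(15), 3)),
               "degrees of freedom")
})

test_that("residual method matches the brute-force oracle on random instances", {
  set.seed(42)
  for (i in 1:120) {
    n <- sample(8:30, 1)
    k <- sample(0:5, 1)
    x <- rnorm(n); y <- rnorm(n)
    D <- if (k > 0) matrix(rnorm(k * n), k) else NULL
    expect_equal(pcor_residual(x, y, D), oracle_pcor(x, y, D),
                 tolerance = 1e-10)
  }
})

test_that("first-order formula agrees with the residual method for one control", {
  set.seed(7)
  for (i in 1:100) {
    n <- sample(10:25, 1)
    x <- rnorm(n); y <- rnorm(n); z <- rnorm(n)
    expect_equal(
      pcor_residual(x, y, rbind(z)),
      pcor_first_order(cor(x, y), cor(x, z), cor(y, z)),
      tolerance = 1e-10)
  }
})

test_that("first-order formula reproduces hand-computed cases", {
  expect_equal(pcor_first_order(0.5, 0, 0), 0.5)
  expect_equal(pcor_first_order(0.25, 0.5, 0.5), 0)
  expect_equal(pcor_first_order(0.8, 0.5, 0.5), 0.55 / 0.75) # 0.7333...
  expect_error(pcor_first_order(0.5, 1, 0.2), "division")
})

test_that("the t-test matches hand arithmetic and an independent tail oracle", {
  null <- pcor_test(0, n = 20, k = 1)
  expect_equal(null$t_stat, 0)
  expect_equal(null$p, 1)

  pos <- pcor_test(0.5, n = 20, k = 1)
  expect_equal(pos$df, 17)
  expect_equal(pos$t_stat, 0.5 * sqrt(17) / sqrt(0.75), tolerance = 1e-12)
  expect_equal(pos$t_stat, 2.3805, tolerance = 1e-4)
  expect_equal(pos$p, oracle_t_pvalue(pos$t_stat, 17), tolerance = 1e-12)

  neg <- pcor_test(-0.5, n = 20, k = 1)
  expect_equal(neg$t_stat, -pos$t_stat)
  expect_equal(neg$p, pos$p)

  expect_error(pcor_test(1, 20, 1), "rho")
  expect_error(pcor_test(0.5, 4, 2), "degrees of freedom")
})

test_that("partial correlation is symmetric and invariant to affine rescaling", {
  set.seed(13)
  for (i in 1:25) {
    n <- 15
    x <- rnorm(n); y <- rnorm(n); D <- matrix(rnorm(2 * n), 2)
    base <- pcor_residual(x, y, D)
    expect_equal(pcor_residual(y, x, D), base, tolerance = 1e-12)
    expect_equal(pcor_residual(3.7 * x - 2, y, D), base, tolerance = 1e-10)
    expect_equal(pcor_residual(x, -0.5 * y + 4, D), -base, tolerance = 1e-10)
    D2 <- D; D2[1, ] <- 100 * D2[1, ] - 7
    expect_equal(pcor_residual(x, y, D2), base, tolerance = 1e-10)
  }
})

test_that("flat-expression filter removes SDs at or below the threshold", {
  at_cut <- c(-1, 0, 1, -1, 1)
  at_cut <- at_cut / sd(at_cut) * 0.1     # sample SD exactly 0.1
  m <- rbind(CONST = rep(2, 5),
             ATCUT = at_cut,
             KEEP = c(0, 0.2, -0.2, 0.3, -0.3))
  colnames(m) <- paste0("S", 1:5)
  es <- expr_set(m)
  expect_equal(sd(m["ATCUT", ]), 0.1)
  kept <- sd_filter(es, threshold = 0.1)
  expect_equal(genes(kept), "KEEP")
  expect_equal(genes(sd_filter(es, threshold = 0)), c("ATCUT", "KEEP"))
})

test_that("screen without controls reduces to plain Pearson correlation", {
  sim <- simulate_expression(sim_config(n_samples = 25, n_case = 0,
                                        n_regulators = 2, n_controls = 0,
                                        n_direct = 3, n_confounded = 0,
                                        n_null = 5, seed = 17))
  fit <- pcor_screen(sim$expr, regulators = c("REG001", "REG002"))
  expect_equal(fit$k, 0L)
  for (i in seq_len(nrow(fit$results))) {
    row <- fit$results[i, ]
    expect_equal(row$rho,
                 cor(sim$expr$values[row$gene, ],
                     sim$expr$values[row$regulator, ]),
                 tolerance = 1e-12)
  }
})

test_that("screen equals per-pair residual computation with the full control set", {
  sim <- simulate_expression(sim_config(n_samples = 40, n_regulators = 2,
                                        n_controls = 4, n_direct = 3,
                                        n_confounded = 3, n_null = 4,
                                        seed = 23))
  regs <- grep("^REG", genes(sim$expr), value = TRUE)
  ctrl <- grep("^CTRL", genes(sim$expr), value = TRUE)
  fit <- pcor_screen(sim$expr, regs, ctrl)
  D <- sim$expr$values[ctrl, , drop = FALSE]
  for (i in sample(nrow(fit$results), 10)) {
    row <- fit$results[i, ]
    rho <- pcor_residual(sim$expr$values[row$gene, ],
                         sim$expr$values[row$regulator, ], D)
    expect_equal(row$rho, rho, tolerance = 1e-10)
    tst <- pcor_test(rho, n = fit$n, k = fit$k)
    expect_equal(row$t, tst$t_stat, tolerance = 1e-8)
    expect_equal(row$p, tst$p, tolerance = 1e-8)
    expect_equal(row$df, tst$df)
  }
})

test_that("screen validates its gene sets and supports empty candidates", {
  sim <- simulate_expression(sim_config(n_samples = 20, n_regulators = 2,
                                        n_controls = 2, n_direct = 2,
                                        n_confounded = 0, n_null = 2,
                                        seed = 2))
  expect_error(pcor_screen(sim$expr, c("REG001", "GHOST1"), "CTRL001"),
               "GHOST1")
  fit <- pcor_screen(sim$expr, c("REG001", "REG002"),
                     c("CTRL001", "CTRL002"), candidates = character(0))
  expect_equal(nrow(fit$results), 0L)
  expect_s3_class(fit, "pcor_screen")
})

test_that("regulator Pearson matrix is symmetric with unit diagonal", {
  set.seed(31)
  m <- matrix(rnorm(15), 3, 5,
              dimnames = list(c("R1", "R2", "R3"), paste0("S", 1:5)))
  m["R3", ] <- -m["R1", ]
  es <- expr_set(m)
  pm <- pearson_matrix(es, c("R1", "R2", "R3"))
  expect_equal(pm, t(pm))
  expect_equal(diag(pm), c(R1 = 1, R2 = 1, R3 = 1))
  expect_equal(pm["R1", "R3"], -1)
  for (a in rownames(pm)) for (b in rownames(pm))
    expect_equal(pm[a, b], oracle_pearson(m[a, ], m[b, ]), tolerance = 1e-12)

  m["R2", ] <- 5
  expect_error(pearson_matrix(expr_set(m), c("R1", "R2")), "R2")
})

test_that("coef method lays out the rho matrix by candidate and regulator", {
  sim <- simulate_expression(sim_config(n_samples = 30, n_regulators = 2,
                                        n_controls = 2, n_direct = 2,
                                        n_confounded = 1, n_null = 2,
                                        seed = 19))
  fit <- pcor_screen(sim$expr, grep("^REG", genes(sim$expr), value = TRUE),
                     grep("^CTRL", genes(sim$expr), value = TRUE))
  cm <- coef(fit)
  expect_equal(dim(cm), c(5L, 2L))
  row <- fit$results[3, ]
  expect_equal(cm[row$gene, row$regulator], row$rho)
})
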