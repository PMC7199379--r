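test_that("generators are bit-reproducible and structurally valid", {
  for (gen in list(gen_sim2, gen_sim3, gen_sim4)) {
    a <- gen(n = 50, p = 30, seed = 123)
    b <- gen(n = 50, p = 30, seed = 123)
    expect_identical(a$X$values, b$X$values)
    expect_identical(a$y, b$y)
    expect_true(all(a$X$values %in% 0:2))
    expect_true(all(a$y %in% 0:1))
    expect_equal(dim(a$X$values), c(50L, 30L))
  }
  a <- gen_ld_gwas(n = 40, p = 120, block_size = 40, seed = 9)
  b <- gen_ld_gwas(n = 40, p = 120, block_size = 40, seed = 9)
  expect_identical(a$X$values, b$X$values)
  expect_identical(a$beta, b$beta)
  expect_true(all(a$X$values %in% 0:2))
  expect_error(gen_ld_gwas(p = 100, block_size = 40), "multiple")
  expect_error(gen_ld_gwas(rho = 1.2), "rho")
})

test_that("conditional-binomial design follows its probability table", {
  set.seed(67)
  rd <- gen_sim2(n = 1e5, p = 11, seed = 67)
  pi_tab <- sim2_probs()
  # E[X_1 | Y = 1] = 2 * 0.6
  expect_lt(abs(mean(rd$X$values[rd$y == 1, 1]) - 2 * pi_tab["Y=1", 1]), 0.02)
  # full conditional pmf check for every causal feature
  for (j in 1:10) for (m in 0:1) {
    emp <- tabulate(rd$X$values[rd$y == m, j] + 1L, 3L) / sum(rd$y == m)
    expect_lt(max(abs(emp - dbinom(0:2, 2, pi_tab[m + 1, j]))), 0.02)
  }
  # noise feature independent of the response
  expect_lt(abs(cor(rd$X$values[, 11], rd$y)), 0.05)
})

test_that("latent-Gaussian design reproduces the normal-CDF cell probabilities", {
  rd <- gen_sim3(n = 1e5, p = 10, seed = 71)
  kap <- sim3_cutoffs()
  # P(X_1 = 0 | Y = 0) -> Phi(0) = 0.5 (lower cutoff 0)
  expect_equal(mean(rd$X$values[rd$y == 0, 1] == 0), 0.5, tolerance = 0.01)
  # all conditional cells of X_5 (cutoffs -0.2, 1.2) match Phi differences
  for (m in 0:1) {
    emp <- tabulate(rd$X$values[rd$y == m, 5] + 1L, 3L) / sum(rd$y == m)
    theo <- unname(c(pnorm(kap["lower", 5] - m),
                     pnorm(kap["upper", 5] - m) - pnorm(kap["lower", 5] - m),
                     1 - pnorm(kap["upper", 5] - m)))
    expect_lt(max(abs(emp - theo)), 0.01)
  }
  # positive trend with the response for every causal feature
  sc <- tc_screen(rd$X, rd$y)
  raw_cor <- cor(trendscreen:::score_matrix(rd$X), rd$y)
  expect_true(all(raw_cor[1:10] > 0))
  expect_true(all(sc$scores > 0.05))
})

test_that("logistic design matches its linear predictor and response law", {
  expect_equal(trendscreen:::sim4_linear_predictor(matrix(0L, 1, 5))[1], -8)
  expect_equal(trendscreen:::sim4_linear_predictor(matrix(2L, 1, 5))[1], 13)
  set.seed(73)
  # fixed pattern: empirical P(Y=1) matches plogis(L)
  pattern <- c(0L, 1L, 2L, 1L, 0L)
  L <- trendscreen:::sim4_linear_predictor(matrix(pattern, 1))[1]
  y <- rbinom(1e5, 1, plogis(L))
  expect_equal(mean(y), plogis(L), tolerance = 0.02)
  rd <- gen_sim4(n = 5000, p = 8, seed = 73)
  expect_true(all(abs(colMeans(rd$X$values) - 1) < 0.1))
})

test_that("noise features of the binomial designs are exchangeable", {
  set.seed(79)
  s1 <- s2 <- numeric(200)
  for (r in 1:200) {
    rd <- gen_sim2(n = 60, p = 14, seed = 7900 + r)
    sc <- suppressWarnings(tc_screen(rd$X, rd$y))$scores
    s1[r] <- sc[11]; s2[r] <- sc[13]
  }
  expect_gt(suppressWarnings(ks.test(s1, s2))$p.value, 0.01)
})

test_that("LD generator produces the intended correlation geometry and effect sizes", {
  rd0 <- gen_ld_gwas(n = 5000, p = 80, block_size = 40, rho = 0,
                     cluster_cor = 0, seed = 83)
  cors0 <- cor(rd0$X$values[, 41:50])
  expect_lt(max(abs(cors0[upper.tri(cors0)])), 0.06)
  rd9 <- gen_ld_gwas(n = 1e4, p = 80, block_size = 40, rho = 0.9, seed = 89)
  adj <- diag(cor(rd9$X$values[, 41:60])[-1, ])   # adjacent pairs, AR block
  expect_true(all(adj > 0.5))
  # causal bin is mutually correlated
  cc <- cor(rd9$X$values[, rd9$true_set])
  expect_true(all(cc[upper.tri(cc)] > 0.15))
  # effect magnitudes concentrate near 5 (folded-normal mean of N(+-5, 1))
  set.seed(97)
  betas <- unlist(lapply(1:2000, function(i) {
    gen_ld_gwas(n = 2, p = 40, block_size = 40, seed = 9000 + i)$beta
  }))
  expect_lt(abs(mean(abs(betas)) - 5), 0.1)
})

test_that("replicate files round-trip through the text writers", {
  rd <- gen_sim2(n = 20, p = 12, seed = 101)
  prefix <- file.path(tempdir(), "rep1")
  write_replicate(rd, prefix)
  back <- read_genotype(paste0(prefix, "_genotypes.tsv"))
  expect_identical(unname(back$X$values), unname(rd$X$values))
  meta <- readLines(paste0(prefix, "_meta.txt"))
  expect_true(any(grepl("design: sim2", meta)))
})
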