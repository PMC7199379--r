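test_that("distance correlation fast path equals the naive double-centering oracle", {
  set.seed(29)
  for (i in 1:40) {
    n <- sample(10:60, 1)
    x <- sample(0:2, n, TRUE)
    y <- rbinom(n, 1, runif(1, 0.2, 0.8))
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    fast <- suppressWarnings(dc_screen(matrix(x), y))$scores[1]
    expect_equal(fast, dcor_naive_oracle(x, y), tolerance = 1e-10)
  }
})

test_that("distance correlation hits its boundary cases", {
  y <- rep(0:1, each = 30)
  expect_equal(dc_screen(matrix(y), y)$scores[1], 1)
  set.seed(31)
  yy <- rbinom(1e4, 1, 0.5)
  xx <- sample(0:2, 1e4, TRUE)
  s <- dc_screen(matrix(xx), yy)$scores[1]
  expect_lt(s, 0.05)
  expect_gte(s, 0)
})

test_that("chi-squared screening is Cramer's V squared of the contingency table", {
  y6 <- rep(0:1, each = 3)
  x6 <- c(0, 1, 2, 0, 1, 2)
  expect_equal(pc_screen(matrix(x6), y6)$scores[1], 0)
  y4 <- c(0, 0, 1, 1)
  expect_equal(pc_screen(matrix(c(0, 0, 1, 1)), y4)$scores[1], 1)
  counts <- matrix(c(20, 5, 5, 20), nrow = 2)
  raw <- expand_table(counts, 0:1)
  expect_equal(pc_screen(matrix(raw$x), raw$y)$scores[1],
               chisq_oracle(counts) / sum(counts))
  set.seed(37)
  for (i in 1:30) {
    raw <- expand_table(random_table(3), 0:2)
    got <- suppressWarnings(pc_screen(matrix(raw$x), raw$y))$scores[1]
    expect_equal(got, chisq_oracle(table(raw$x, raw$y)) / length(raw$x),
                 tolerance = 1e-12)
    expect_gte(got, 0); expect_lte(got, 1)
  }
})

test_that("marginal likelihood screening matches glm and recovers a generating slope", {
  set.seed(41)
  for (i in 1:30) {
    n <- sample(60:150, 1)
    x <- sample(0:2, n, TRUE)
    y <- rbinom(n, 1, plogis(-0.4 + 0.7 * x))
    if (length(unique(y)) < 2) next
    ours <- mmle_screen(matrix(x), y)$scores[1]
    ref <- abs(coef(glm(y ~ x, family = binomial()))[[2]])
    expect_equal(ours, ref, tolerance = 1e-6)
  }
  # parameter recovery at large n: slope 1.0 within 0.05
  set.seed(43)
  x <- sample(0:2, 1e5, TRUE)
  y <- rbinom(1e5, 1, plogis(0 + 1 * x))
  expect_lt(abs(mmle_screen(matrix(x), y)$scores[1] - 1), 0.05)
  # independence: slope near zero
  y0 <- rbinom(1e4, 1, 0.5)
  x0 <- sample(0:2, 1e4, TRUE)
  expect_lt(mmle_screen(matrix(x0), y0)$scores[1], 0.1)
})

test_that("separated and degenerate features are capped and flagged, not fatal", {
  y <- rep(0:1, each = 10)
  X <- cbind(sep = y * 2L, const = 1L, ok = sample(0:2, 20, TRUE))
  sc <- suppressWarnings(mmle_screen(X, y))
  flags <- attr(sc, "flags")
  expect_equal(sc$scores[1], 25)
  expect_equal(flags[1], "separated")
  expect_equal(sc$scores[2], 0)
  expect_equal(flags[2], "degenerate")
  # dummy coding path produces one bounded utility per feature
  scd <- suppressWarnings(mmle_screen(X, y, coding = "dummy"))
  expect_length(scd$scores, 3L)
  expect_true(all(scd$scores >= 0 & scd$scores <= 25))
})

test_that("all screeners rank truly influential features above the noise median", {
  set.seed(47)
  reps <- 15
  methods <- c("TC", "DC", "PC", "MMLE")
  hits <- matrix(0, length(methods), 10,
                 dimnames = list(methods, NULL))
  for (r in seq_len(reps)) {
    rd <- gen_sim2(n = 200, p = 600, seed = 4700 + r)
    for (m in methods) {
      sc <- suppressWarnings(trendscreen:::screener_for(m)(rd$X, rd$y))
      rk <- trendscreen:::feature_ranks(sc)[rd$true_set]
      hits[m, ] <- hits[m, ] + (rk < 300)
    }
  }
  expect_true(all(hits / reps > 0.9))
})
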