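test_that("contingency tabulates joint counts with consistent marginals", {
  tab <- contingency(c(0, 0, 1, 1), c(0, 0, 1, 1))
  expect_equal(unname(tab$counts), matrix(c(2L, 0L, 0L, 2L), nrow = 2))
  tab <- contingency(c(0, 1, 2, 0, 1, 2), c(0, 0, 0, 1, 1, 1))
  expect_equal(unname(tab$counts), matrix(1L, 3, 2))
  set.seed(41)
  x <- sample(0:2, 100, TRUE)
  y <- rbinom(100, 1, 0.4)
  tab <- contingency(x, y)
  expect_equal(sum(tab$counts), 100L)
  for (k in 0:2) for (m in 0:1) {
    expect_equal(tab$counts[as.character(k), as.character(m)],
                 sum(x == k & y == m))
  }
  expect_error(contingency(c(0, 1), c(0, 1, 1)), "length")
  expect_error(contingency(c(0, 3), c(0, 1), levels = 0:2), "unknown level")
})

test_that("population trend correlation matches direct expectations and detects independence", {
  p_ind <- outer(c(0.2, 0.5, 0.3), c(0.4, 0.6))
  expect_equal(tc_population(p_ind, 0:2), 0)
  expect_equal(tc_population(matrix(c(0.5, 0, 0, 0.5), 2), 0:1), 1)
  probs <- matrix(c(0.3, 0.1, 0.1, 0.1, 0.1, 0.3), nrow = 3)
  expect_equal(tc_population(probs, 0:2), tc_expectation_oracle(probs, 0:2))
  set.seed(7)
  for (i in 1:25) {
    pr <- matrix(runif(6), 3); pr <- pr / sum(pr)
    expect_equal(tc_population(pr, 0:2), tc_expectation_oracle(pr, 0:2))
    pr_ind <- outer(rowSums(pr), colSums(pr))
    expect_lt(tc_population(pr_ind, 0:2), 1e-14)
  }
  expect_error(tc_population(matrix(c(1, 0, 0, 0), 2), 0:1), "degenerate")
  expect_error(tc_population(matrix(c(0.6, 0, 0.4, 0), 2), 0:1), "degenerate")
})

test_that("sample trend correlation equals the absolute Pearson correlation", {
  expect_equal(tc_sample(c(0, 1, 0, 1), c(0, 1, 0, 1)), 1)
  expect_equal(tc_sample(c(0, 0, 1, 1), c(0, 1, 0, 1)), 0)
  counts <- matrix(c(30, 10, 10, 10, 10, 30), nrow = 3)
  raw <- expand_table(counts, 0:2)
  expect_equal(tc_sample(raw$x, raw$y), abs_pearson_oracle(raw$x, raw$y))
  set.seed(11)
  for (i in 1:120) {
    cnt <- random_table(sample(2:4, 1)); raw <- expand_table(cnt, seq_len(nrow(cnt)))
    sc <- sort(unique(raw$x))
    expect_equal(tc_sample(raw$x, raw$y, levels = sc, scores = sc),
                 abs_pearson_oracle(raw$x, raw$y), tolerance = 1e-12)
  }
  expect_error(tc_sample(rep(1, 10), rbinom(10, 1, .5)), "degenerate")
  expect_error(tc_sample(sample(0:2, 10, TRUE), rep(1L, 10)), "constant")
})

test_that("trend correlation is bounded, affine-invariant, and obeys Popoviciu's variance bound", {
  set.seed(13)
  for (i in 1:60) {
    raw <- expand_table(random_table(3), 0:2)
    v <- tc_sample(raw$x, raw$y)
    expect_gte(v, 0); expect_lte(v, 1)
    # affine rescaling of level scores leaves the statistic unchanged
    a <- runif(1, .2, 5); b <- runif(1, -3, 3)
    expect_equal(tc_sample(raw$x, raw$y, levels = 0:2, scores = a * (0:2) + b),
                 v, tolerance = 1e-12)
    # Popoviciu: sample variance of the scored feature <= range^2 / 4
    expect_lte(mean(raw$x^2) - mean(raw$x)^2,
               (max(raw$x) - min(raw$x))^2 / 4 + 1e-12)
  }
})

test_that("estimated trend correlation converges uniformly to the population value", {
  set.seed(17)
  n <- 1e5
  worst <- 0
  for (j in 1:100) {
    pr <- matrix(runif(6, 0.05, 1), 3); pr <- pr / sum(pr)
    pop <- tc_population(pr, 0:2)
    cells <- rmultinom(1, n, as.vector(pr))
    raw <- expand_table(matrix(cells, 3), 0:2)
    worst <- max(worst, abs(tc_sample(raw$x, raw$y, levels = 0:2) - pop))
  }
  expect_lt(worst, 0.02)
})

test_that("tc_screen ranks columnwise like tc_sample and tolerates constant features", {
  set.seed(19)
  y <- rep(0:1, each = 30)
  X <- cbind(y, matrix(sample(0:2, 60 * 4, TRUE), 60))
  sc <- tc_screen(X, y)
  expect_equal(sc$ranking[1], 1L)
  expect_equal(sc$scores[1], 1)
  for (j in 2:5) expect_equal(sc$scores[j], tc_sample(X[, j], y), tolerance = 1e-12)
  # permutation equivariance
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(tc_screen(X[, perm], y)$scores, sc$scores[perm])
  # replicate-scale check against the per-feature route
  rep2 <- gen_sim2(n = 100, p = 40, seed = 5)
  sc2 <- tc_screen(rep2$X, rep2$y)
  one_by_one <- vapply(seq_len(40),
                       function(j) tc_sample(rep2$X$values[, j], rep2$y),
                       numeric(1))
  expect_equal(sc2$scores, one_by_one, tolerance = 1e-12)
  Xc <- cbind(X, 1L)
  expect_warning(scc <- tc_screen(Xc, y), "constant")
  expect_equal(scc$scores[6], 0)
  expect_error(tc_screen(matrix(integer(), 10, 0), rep(0:1, 5)), "empty")
})

test_that("top-d and threshold selection rules apply the documented tie-breaks", {
  sc <- trendscreen:::new_screening_scores(c(0.9, 0.1, 0.8), "TC", paste0("X", 1:3))
  expect_equal(select_top(sc, 2)$indices, c(1L, 3L))
  ties <- trendscreen:::new_screening_scores(rep(0.5, 4), "TC", paste0("X", 1:4))
  expect_equal(select_top(ties, 2)$indices, c(1L, 2L))
  expect_error(select_top(sc, 4), "between 1 and p")
  set.seed(23)
  s <- runif(50)
  sco <- trendscreen:::new_screening_scores(s, "TC", paste0("X", 1:50))
  expect_equal(select_top(sco, 10)$indices, order(-s)[1:10])
  expect_equal(select_by_threshold(sco, 0), 1:50)
  expect_equal(select_by_threshold(sco, max(s)), integer(0))
  s101 <- sample(seq(0.01, 1.01, by = 0.01))
  sc101 <- trendscreen:::new_screening_scores(s101, "TC", paste0("X", 1:101))
  expect_length(select_by_threshold(sc101, median(s101)), 50L)
  expect_setequal(select_by_threshold(sc101, median(s101)), which(s101 > median(s101)))
})

test_that("rule-of-thumb cutoff reproduces its anchor values and the direct formula", {
  expect_identical(rule_of_thumb_d(272), 20L)
  expect_identical(rule_of_thumb_d(4099, 3), 351L)
  m <- 1000^0.8
  expect_identical(rule_of_thumb_d(1000), as.integer(floor(m / log(m) + 0.5)))
  expect_error(rule_of_thumb_d(1), "at least 2")
})
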