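test_that("g2_from_table matches brute-force evaluation and conventions", {
  # independence identity: table equal to the outer product of its margins
  o <- outer(c(30, 70), c(0.4, 0.6)) * 1
  expect_equal(g2_from_table(o)$statistic, 0, tolerance = 1e-12)
  # frozen oracle values (direct evaluation of 2 * sum O log(O/E))
  res <- g2_from_table(matrix(c(10, 30, 20, 40), 2))
  expect_equal(res$statistic, 0.8043486461, tolerance = 1e-9)
  expect_equal(res$df, 1L)
  # zero-cell convention: O log(O/E) := 0 when O = 0
  res <- g2_from_table(matrix(c(5, 0, 0, 5), 2))
  expect_equal(res$statistic, 13.8629436112, tolerance = 1e-9)
  # zero-margin rows/columns dropped with df reduced
  o <- rbind(c(10, 20, 0), c(30, 40, 0), c(0, 0, 0))
  expect_equal(g2_from_table(o)$df, 1L)
  # all-zero table: no-test signal, distinct from statistic 0
  res <- g2_from_table(matrix(0, 2, 2))
  expect_true(is.na(res$statistic))
  expect_equal(res$df, 0L)
  expect_error(g2_from_table(matrix(c(1, -1, 2, 3), 2)), "non-negative")
})

test_that("g2 matches brute force on random tables and loglin's LRT", {
  set.seed(81)
  for (i in 1:25) {
    o <- matrix(rpois(6, lambda = sample(3:40, 1)), 2, 3)
    o <- o + 1  # keep margins positive
    res <- g2_from_table(o)
    expect_equal(res$statistic, g2_oracle(o), tolerance = 1e-9)
    ll <- loglin(o, margin = list(1, 2), print = FALSE)
    expect_equal(res$statistic, ll$lrt, tolerance = 1e-6)
    expect_equal(res$df, ll$df)
  }
})

test_that("G2 and Pearson chi-square agree asymptotically", {
  set.seed(82)
  p <- outer(c(0.45, 0.55), c(0.5, 0.3, 0.2))
  o <- round(p * 50000) + matrix(rpois(6, 20), 2, 3)
  g2 <- g2_from_table(o)$statistic
  x2 <- suppressWarnings(chisq.test(o, correct = FALSE))$statistic
  expect_lt(abs(g2 - x2) / x2, 0.05)
})

test_that("conditional G2 reduces to the marginal table test and sums strata", {
  d <- toy_dataset()
  marg <- conditional_g2(d, 1)
  tab <- table(d$phenotype, d$genotypes[, 1])
  expect_equal(marg$statistic, g2_from_table(tab)$statistic)
  expect_equal(marg$df, g2_from_table(tab)$df)
  # conditioning on a constant leaves the test unchanged
  d2 <- d
  d2$genotypes <- cbind(d$genotypes, const = 1L)
  d2$marker_ids <- c(d$marker_ids, "const")
  # constant has a single category: one stratum, same table
  cond <- conditional_g2(d2, 1, ncol(d2$genotypes))
  expect_equal(cond$statistic, marg$statistic)
  expect_equal(cond$df, marg$df)
})

test_that("stratified df follows the product formula when nothing is dropped", {
  set.seed(83)
  n <- 6000
  g <- matrix(rbinom(n * 3, 2L, 0.45), n, 3)
  y <- rbinom(n, 1L, 0.5)
  d <- genotype_dataset(g, y, phenotype_type = "binary")
  res <- conditional_g2(d, 1, c(2, 3))
  # (Cat(Y)-1)(Cat(V)-1) * prod(Cat(C)) = 1 * 2 * 3 * 3
  expect_equal(res$df, 18L)
  expect_equal(stratified_cell_count(2, 3, c(3, 3)), 54)
  expect_error(conditional_g2(d, 1, 1), "target")
})

test_that("cell cap refuses combinatorially explosive conditioning", {
  set.seed(84)
  n <- 200
  g <- matrix(rbinom(n * 14, 2L, 0.4), n, 14)
  d <- genotype_dataset(g, rbinom(n, 1L, 0.5), phenotype_type = "binary")
  expect_error(conditional_g2(d, 1, 2:13, cell_cap = 1e6), "refusing")
  # one-order conditioning never exceeds Cat(Y)*Cat(V)*Cat(C) cells
  expect_lt(stratified_cell_count(2, 3, 3), 1e6)
})

test_that("p-values are uniform under a permuted phenotype", {
  set.seed(85)
  n <- 400
  g <- rbinom(n, 2L, 0.3)
  y <- rbinom(n, 1L, 0.5)
  pvals <- replicate(2000, {
    yp <- sample(y)
    d <- genotype_dataset(matrix(g), yp, phenotype_type = "binary")
    conditional_g2(d, 1)$p_value
  })
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.001)
})

test_that("regression CI test recovers conditional independence structure", {
  set.seed(86)
  hits_ci <- 0; hits_dep <- 0
  for (i in 1:10) {
    n <- 20000
    x2 <- rnorm(n)
    x3 <- 0.5 * x2 + sqrt(1 - 0.25) * rnorm(n)
    g <- matrix(round(pmin(2, pmax(0, c(x2, x3) + 1))), ncol = 2)  # 0/1/2
    # phenotype driven by the coded marker itself, so conditioning on it
    # blocks the path to its correlated neighbour completely
    y <- rbinom(n, 1L, plogis(-1 + 0.5 * g[, 1]))
    d <- genotype_dataset(g, y, phenotype_type = "binary")
    # x3 associated only through x2: conditionally independent
    if (regression_ci_test(d, 2, 1, family = "logistic")$p_value > 0.05)
      hits_ci <- hits_ci + 1
    # x2 has a true direct effect
    if (regression_ci_test(d, 1, 2, family = "logistic")$p_value < 0.05)
      hits_dep <- hits_dep + 1
  }
  expect_gte(hits_ci, 8)
  expect_equal(hits_dep, 10)
})

test_that("regression test with empty conditioning equals single-covariate fit", {
  d <- toy_dataset()
  res <- regression_ci_test(d, 1)
  fit <- glm(d$phenotype ~ d$genotypes[, 1], family = binomial())
  z <- coef(summary(fit))[2, 3]
  expect_equal(res$statistic, z^2, tolerance = 1e-8)
  expect_equal(res$df, 1L)
  # collinear conditioner: no-test signal, not a crash
  d2 <- d
  d2$genotypes <- cbind(d$genotypes, dup = d$genotypes[, 1])
  d2$marker_ids <- c(d$marker_ids, "dup")
  res <- regression_ci_test(d2, 1, ncol(d2$genotypes))
  expect_false(res$reliable)
  # linear family on a quantitative phenotype
  dq <- genotype_dataset(d$genotypes, rnorm(nrow(d$genotypes)) +
                           0.3 * d$genotypes[, 2],
                         phenotype_type = "quantitative")
  res <- regression_ci_test(dq, 2, family = "linear")
  expect_lt(res$p_value, 1e-4)
})

test_that("Armitage trend test matches prop.trend.test and is symmetric", {
  res <- armitage_trend_test(c(10, 20, 30), c(30, 20, 10))
  # oracle frozen from prop.trend.test(c(10,20,30), c(40,40,40))
  expect_equal(res$statistic, 20, tolerance = 1e-9)
  expect_equal(res$p_value, 7.744216431e-06, tolerance = 1e-8)
  # identical distributions: statistic 0, p 1
  res0 <- armitage_trend_test(c(10, 20, 30), c(10, 20, 30))
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p_value, 1)
  # label-swap invariance
  a <- armitage_trend_test(c(5, 17, 40), c(22, 18, 9))
  b <- armitage_trend_test(c(22, 18, 9), c(5, 17, 40))
  expect_equal(a$statistic, b$statistic)
  # cross-check on random counts against the stats oracle
  set.seed(87)
  for (i in 1:10) {
    ca <- rpois(3, 20) + 1; co <- rpois(3, 20) + 1
    mine <- armitage_trend_test(ca, co)
    ref <- suppressWarnings(prop.trend.test(ca, ca + co, score = 0:2))
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-9)
  }
  expect_error(armitage_trend_test(c(0, 0, 0), c(0, 0, 0)), "zero total")
})

test_that("marginal screening is nested in alpha and finds what it should", {
  d <- toy_dataset(n = 800)
  s05 <- marginal_screen(d, 0.05)
  s01 <- marginal_screen(d, 0.01)
  expect_true(all(s01$marker %in% s05$marker))
  expect_false(is.unsorted(s05$p))
  expect_true(1 %in% s05$marker)  # the strong causal SNP
  expect_error(marginal_screen(d, 1.5), "alpha")
  # constant markers skipped with a message
  d2 <- d
  d2$genotypes[, 3] <- 0L
  expect_message(marginal_screen(d2, 0.05), "constant")
})

test_that("null screening keeps roughly alpha of the markers", {
  set.seed(88)
  sizes <- replicate(5, {
    g <- matrix(rbinom(500 * 400, 2L, 0.3), 500, 400)
    d <- genotype_dataset(g, rbinom(500, 1L, 0.5), phenotype_type = "binary")
    nrow(marginal_screen(d, 0.05))
  })
  expect_lt(abs(mean(sizes) / 400 - 0.05), 0.02)
})
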