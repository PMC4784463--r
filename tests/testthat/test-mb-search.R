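test_that("search_params validates its fields", {
  p <- search_params()
  expect_equal(p$alpha, 0.05)
  expect_equal(p$r2_threshold, 0.05)
  expect_equal(p$ld_window, 20L)
  expect_equal(p$ci_backend, "g2")
  expect_error(search_params(alpha = 0), "alpha")
  expect_error(search_params(r2_threshold = 2), "r2_threshold")
  expect_error(search_params(ld_window = -1), "ld_window")
})

test_that("first-order check reduces to the marginal test on an empty blanket", {
  d <- toy_dataset()
  params <- search_params()
  res <- first_order_dependent(d, 1, integer(0), params)
  marg <- conditional_g2(d, 1)
  expect_equal(res$worst_p, marg$p_value)
  expect_true(res$is_dependent)
  expect_error(first_order_dependent(d, 1, c(1, 2), params), "member")
})

test_that("a mediated candidate is conditionally screened out", {
  params <- search_params()
  rejected <- 0
  for (i in 1:20) {
    d <- simulate_chain_dataset(n = 10000, n_noise = 0, rng_seed = 200 + i)
    res <- first_order_dependent(d, 1, 2L, params)  # V given C
    if (!res$is_dependent) rejected <- rejected + 1
  }
  expect_gte(rejected, 16)
  # while a true direct effect conditioned on an independent marker stays
  d <- toy_dataset(n = 2000)
  res <- first_order_dependent(d, 1, 2L, params)
  expect_true(res$is_dependent)
})

test_that("forward_step admits the smallest worst-case p with deterministic ties", {
  d <- toy_dataset()
  params <- search_params()
  pool <- marginal_screen(d, 0.2)
  b <- mbfish:::new_blanket()
  expect_equal(forward_step(d, pool, b, params), 1)
  # empty pool and all-independent pool return NULL
  expect_null(forward_step(d, pool[0, ], b, params))
  # duplicated-column tie: lower index wins, and reruns agree
  g <- d$genotypes
  g <- cbind(g, g[, 1])
  d2 <- genotype_dataset(g, d$phenotype, phenotype_type = "binary")
  pool2 <- marginal_screen(d2, 0.2)
  a1 <- forward_step(d2, pool2, b, params)
  a2 <- forward_step(d2, pool2, b, params)
  expect_identical(a1, a2)
  expect_equal(a1, min(1, ncol(g)))
})

test_that("ld_prune requires both the window and the r2 condition", {
  set.seed(91)
  n <- 3000
  base <- rbinom(n, 2L, 0.3)
  flip <- function(x, rate) ifelse(runif(n) < rate, rbinom(n, 2L, 0.3), x)
  g <- cbind(base,                 # 1: admitted
             flip(base, 0.5),      # 2: near, corr
             rbinom(n, 2L, 0.3))   # 3: near, independent
  g <- cbind(g, matrix(rbinom(n * 38, 2L, 0.3), n))  # pad to 41 markers
  g[, 35] <- flip(base, 0.5)       # far (offset 34), corr
  d <- genotype_dataset(g, rbinom(n, 1L, 0.5), phenotype_type = "binary")
  pool <- data.frame(marker = c(2L, 3L, 35L), p = c(0.01, 0.02, 0.03))
  params <- search_params(ld_window = 20, r2_threshold = 0.05)
  res <- ld_prune(pool, 1L, d$genotypes, params)
  expect_equal(res$removed, 2L)               # near + correlated: pruned
  expect_setequal(res$pool$marker, c(3L, 35L))  # independent or far: kept
  # window 0 disables pruning
  res0 <- ld_prune(pool, 1L, d$genotypes, search_params(ld_window = 0))
  expect_equal(nrow(res0$pool), 3)
  expect_error(ld_prune(pool, 2L, d$genotypes, params), "pool")
})

test_that("backward pruning removes explained-away members and is idempotent", {
  params <- search_params()
  removed <- 0
  for (i in 1:20) {
    d <- simulate_chain_dataset(n = 10000, n_noise = 0, rng_seed = 300 + i)
    b <- mbfish:::new_blanket()
    # force-admit V then C: V's association is explained by C
    b$members <- c(1L, 2L)
    b$admission_log <- data.frame(marker = c(1L, 2L), worst_p = 0,
                                  marginal_p = 0)
    pruned <- backward_prune(d, b, params)
    if (identical(pruned$members, 2L)) removed <- removed + 1
    again <- backward_prune(d, pruned, params)
    expect_identical(again$members, pruned$members)
  }
  expect_gte(removed, 16)
  # a singleton with a significant marginal association is untouched
  d <- toy_dataset()
  b <- mbfish:::new_blanket()
  b$members <- 1L
  b$admission_log <- data.frame(marker = 1L, worst_p = 0, marginal_p = 0)
  expect_identical(backward_prune(d, b, params)$members, 1L)
})

test_that("one round separates the blanket from the surviving pool", {
  d <- simulate_chain_dataset(n = 30000, n_noise = 6, rng_seed = 95)
  params <- search_params()
  pool <- marginal_screen(d, 0.05)
  res <- run_mb_round(d, pool, params)
  expect_true(2 %in% res$blanket$members)      # C caught
  expect_false(1 %in% res$blanket$members)     # V explained away
  expect_length(intersect(res$blanket$members, res$pool$marker), 0)
  expect_lt(nrow(res$pool), nrow(pool))
  # every admission was significant at admission time
  expect_true(all(res$blanket$admission_log$worst_p < params$alpha))
  # null pool: empty or tiny blanket
  set.seed(96)
  g <- matrix(rbinom(1000 * 50, 2L, 0.3), 1000, 50)
  dn <- genotype_dataset(g, rbinom(1000, 1L, 0.5), phenotype_type = "binary")
  resn <- run_mb_round(dn, marginal_screen(dn, 0.05), params)
  expect_lte(length(resn$blanket$members), 4)
})
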