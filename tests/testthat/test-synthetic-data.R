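test_that("region_spec validates its arguments", {
  expect_s3_class(region_spec(50, "high"), "region_spec")
  expect_error(region_spec(0), "n_markers")
  expect_error(region_spec(10, maf_range = c(0.4, 0.1)), "ordered")
  expect_error(region_spec(10, maf_range = c(0.1, 0.7)), "ordered")
  expect_error(region_spec(10, "ar1"), "rho")
  expect_error(simulate_region(region_spec(5), -3), "positive")
})

test_that("generated regions hit their target MAFs and obey HWE", {
  n <- 20000
  for (profile in c("none", "low", "modest", "high")) {
    g <- simulate_region(region_spec(10, profile), n, rng_seed = 11,
                         maf = 0.3)
    af <- colMeans(g) / 2
    expect_true(all(abs(af - 0.3) < 0.03), info = profile)
  }
  # genotype class frequencies at HWE proportions
  g <- simulate_region(region_spec(4, "none"), 100000, rng_seed = 12,
                       maf = 0.2)
  freq <- tabulate(g[, 1] + 1L, 3L) / nrow(g)
  expect_equal(freq, c(0.64, 0.32, 0.04), tolerance = 0.02)
})

test_that("LD regimes produce their r-squared bands", {
  n <- 20000
  r2_of <- function(g) cor(g)[upper.tri(diag(ncol(g)))]^2
  g <- simulate_region(region_spec(12, "none"), n, rng_seed = 21, maf = 0.3)
  expect_lt(mean(r2_of(g)), 0.01)
  g <- simulate_region(region_spec(12, "high"), n, rng_seed = 22)
  expect_gt(mean(r2_of(g) > 0.8), 0.9)
  g <- simulate_region(region_spec(12, "modest"), n, rng_seed = 23)
  expect_gt(mean(r2_of(g) > 0.2 & r2_of(g) < 0.8), 0.9)
  g <- simulate_region(region_spec(12, "low"), n, rng_seed = 24)
  expect_gt(mean(r2_of(g) < 0.3), 0.9)
})

test_that("AR(1) LD decays monotonically with marker distance", {
  g <- simulate_region(region_spec(30, "ar1", rho = 0.9), 100000,
                       rng_seed = 31, maf = 0.3)
  r <- cor(g)
  lag_r2 <- function(k) {
    idx <- seq_len(30 - k)
    mean(r[cbind(idx, idx + k)]^2)
  }
  expect_gt(lag_r2(1), lag_r2(5))
  expect_gt(lag_r2(5), lag_r2(15))
})

test_that("phenotype model matches its logistic specification", {
  set.seed(41)
  g <- matrix(rbinom(100000 * 2, 2L, 0.3), ncol = 2)
  # intercept-only: case fraction equals the requested prevalence
  y0 <- simulate_phenotype(g, integer(0), numeric(0),
                           baseline_prevalence = 0.1, rng_seed = 42)
  expect_lt(abs(mean(y0) - 0.1), 0.01)
  expect_equal(attr(y0, "intercept"), qlogis(0.1))
  # single causal SNP: sampled case-control odds ratio ~ the model OR
  y <- simulate_phenotype(g, 1L, 1.5, baseline_prevalence = 0.1,
                          rng_seed = 43)
  expect_lt(abs(mean(y) - 0.1), 0.01)
  d <- sample_case_control(
    genotype_dataset(g, y, phenotype_type = "binary"), 2000, 2000,
    rng_seed = 44)
  fit <- glm(d$phenotype ~ d$genotypes[, 1], family = binomial())
  expect_equal(unname(exp(coef(fit)[2])), 1.5, tolerance = 0.08)
  # all OR = 1: trend p-values uniform (no association)
  ynull <- simulate_phenotype(g, 1:2, c(1, 1), rng_seed = 45)
  dnull <- genotype_dataset(g, ynull, phenotype_type = "binary")
  p <- mbfish:::trend_pvalues(dnull)
  expect_true(all(p > 1e-4))
  # errors
  expect_error(simulate_phenotype(g, 1L, 1.5, baseline_prevalence = 1.2),
               "prevalence")
  expect_error(simulate_phenotype(g, 1L, -2), "odds ratios")
})

test_that("case-control sampling is exact, seeded, and fails loudly", {
  set.seed(51)
  g <- matrix(rbinom(5000 * 3, 2L, 0.3), ncol = 3)
  y <- rbinom(5000, 1L, 0.1)
  pop <- genotype_dataset(g, y, truth = 2L, phenotype_type = "binary")
  d1 <- sample_case_control(pop, 100, 200, rng_seed = 52)
  expect_equal(sum(d1$phenotype == 1), 100)
  expect_equal(sum(d1$phenotype == 0), 200)
  expect_identical(d1$truth, 2L)
  d2 <- sample_case_control(pop, 100, 200, rng_seed = 52)
  expect_identical(d1$genotypes, d2$genotypes)
  expect_error(sample_case_control(pop, 10000, 10, rng_seed = 1),
               "contains only")
})

test_that("scenario 1 causal markers are free of LD with the background", {
  spec <- scenario_spec(1, 2, population_size = 30000, seed = 61)
  pop <- make_scenario(spec)
  expect_equal(dim(pop$genotypes), c(30000, 1100))
  expect_length(pop$truth, 8)
  r <- cor(pop$genotypes[, pop$truth],
           pop$genotypes[, -pop$truth, drop = FALSE])
  expect_lt(max(abs(r)), 0.05)
})

test_that("scenario 2 causal markers realize the target correlation", {
  spec <- scenario_spec(2, 2, population_size = 50000, seed = 62)
  pop <- make_scenario(spec)
  rc <- cor(pop$genotypes[, pop$truth])
  expect_equal(mean(rc[upper.tri(rc)]), 0.1, tolerance = 0.03)
})

test_that("scenario 4 places one causal SNP per LD regime with tight high-LD neighbours", {
  spec <- scenario_spec(4, seed = 63, population_size = 30000)
  expect_equal(spec$causal_or, rep(1.5, 3))
  pop <- make_scenario(spec)
  expect_equal(dim(pop$genotypes), c(30000, 150))
  # causal SNP of the high-LD region (region 1) shares its block's LD
  t1 <- pop$truth[1]
  nb <- setdiff(which(pop$region == 1), t1)
  r2 <- cor(pop$genotypes[, t1], pop$genotypes[, nb])^2
  expect_gt(mean(r2 > 0.8), 0.9)
})

test_that("identical scenario specs give bit-identical datasets", {
  spec <- small_spec(seed = 64)
  d1 <- simulate_case_control_study(spec)
  d2 <- simulate_case_control_study(spec)
  expect_identical(d1$genotypes, d2$genotypes)
  expect_identical(d1$phenotype, d2$phenotype)
  expect_identical(d1$truth, d2$truth)
  p1 <- make_scenario(small_spec(seed = 65))
  p2 <- make_scenario(small_spec(seed = 65))
  expect_identical(p1$genotypes, p2$genotypes)
})

test_that("case-control enrichment: risk-allele frequency higher in cases", {
  d <- simulate_case_control_study(scenario_spec(
    1, 2, n_cases = 1000, n_controls = 1000, seed = 66))
  strong <- d$truth[5:8]  # truth is ordered by OR; these have OR >= 1.5
  af_cases <- colMeans(d$genotypes[d$phenotype == 1, strong]) / 2
  af_controls <- colMeans(d$genotypes[d$phenotype == 0, strong]) / 2
  expect_true(all(af_cases > af_controls))
})

test_that("chain dataset is conditionally independent by construction", {
  d <- simulate_chain_dataset(n = 30000, n_noise = 2, rng_seed = 71)
  expect_identical(d$truth, 2L)
  # V marginally associated, but independent of Y given C
  marg <- conditional_g2(d, 1)
  expect_lt(marg$p_value, 1e-4)
  cond <- conditional_g2(d, 1, 2)
  expect_gt(cond$p_value, 0.01)
})
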