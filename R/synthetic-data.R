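# Parametric block-LD genotype simulator.
#
# Genotypes are produced by thresholding a latent Gaussian at the
# Hardy-Weinberg quantiles of the marker's allele frequency, so marginal
# genotype frequencies are (q^2, 2pq, p^2) by construction.  LD within a
# block is induced by correlating the latent variables: an exchangeable
# (equicorrelated) factor for the named low/modest/high regimes, or an
# AR(1) chain for explicit distance-decaying LD.  The latent correlations
# for the named regimes were calibrated once, by simulation, against the
# genotype r^2 bands they must produce (low: r^2 < 0.3; modest:
# 0.2 < r^2 < 0.8; high: most pairs r^2 > 0.8) and are fixed constants.

.ld_latent <- c(low = 0.40, modest = 0.80, high = 0.995)

# latent equicorrelation giving realized genotype correlation ~0.1 at MAF 0.3
.causal_copula_latent <- 0.135

#' Specify one simulated genome region
#'
#' A region is a block of biallelic SNPs sharing a linkage-disequilibrium
#' (LD) regime.  Named regimes (`"low"`, `"modest"`, `"high"`) use an
#' exchangeable latent correlation calibrated so that pairwise genotype
#' r-squared falls in the regime's band; `"ar1"` uses a latent first-order
#' autoregression with parameter `rho`, giving LD that decays with marker
#' distance; `"none"` gives independent markers.
#'
#' @param n_markers Number of SNPs in the region.
#' @param ld_profile One of `"none"`, `"low"`, `"modest"`, `"high"`, `"ar1"`.
#' @param maf_range Minor-allele-frequency range, one or two values in
#'   (0, 0.5]. Per-marker MAFs are drawn from this range; high-LD regions
#'   share a single block MAF (tight LD implies near-identical allele
#'   frequencies) and modest regions jitter around one.
#' @param rho Latent AR(1) correlation in \[0, 1); required when
#'   `ld_profile = "ar1"`, ignored otherwise.
#' @return An object of class `"region_spec"`.
#' @examples
#' region_spec(50, "high", maf_range = c(0.1, 0.4))
#' @export
region_spec <- function(n_markers = 50,
                        ld_profile = c("none", "low", "modest", "high", "ar1"),
                        maf_range = c(0.05, 0.5),
                        rho = NULL) {
  ld_profile <- match.arg(ld_profile)
  if (length(n_markers) != 1L || !is.finite(n_markers) || n_markers < 1)
    stop("n_markers must be a single count >= 1")
  if (length(maf_range) == 1L) maf_range <- rep(maf_range, 2L)
  if (length(maf_range) != 2L || any(!is.finite(maf_range)))
    stop("maf_range must give one or two allele frequencies")
  if (maf_range[1] > maf_range[2] || maf_range[1] <= 0 || maf_range[2] > 0.5)
    stop("maf_range must be ordered and lie within (0, 0.5]")
  if (ld_profile == "ar1") {
    if (is.null(rho) || length(rho) != 1L || rho < 0 || rho >= 1)
      stop("ld_profile \"ar1\" requires rho in [0, 1)")
  } else {
    rho <- NULL
  }
  structure(list(n_markers = as.integer(n_markers),
                 ld_profile = ld_profile,
                 maf_range = as.numeric(maf_range),
                 rho = rho),
            class = "region_spec")
}

# draw per-marker MAFs consistent with the LD regime
draw_region_mafs <- function(spec) {
  m <- spec$n_markers
  lo <- spec$maf_range[1]; hi <- spec$maf_range[2]
  switch(spec$ld_profile,
    high = rep(runif(1, lo, hi), m),
    modest = {
      base <- runif(1, lo, hi)
      pmin(0.5, pmax(lo, base * runif(m, 0.85, 1.15)))
    },
    runif(m, lo, hi))
}

# threshold a latent N(0,1) matrix at HWE quantiles, column-wise MAF p
threshold_latent <- function(z, maf) {
  n <- nrow(z); m <- ncol(z)
  c1 <- qnorm((1 - maf)^2)
  c2 <- qnorm((1 - maf)^2 + 2 * maf * (1 - maf))
  g <- (z > rep(c1, each = n)) + (z > rep(c2, each = n))
  storage.mode(g) <- "integer"
  g
}

latent_block <- function(n, m, profile, rho = NULL) {
  e <- matrix(rnorm(n * m), n, m)
  if (profile == "none") return(e)
  if (profile == "ar1") {
    z <- e
    s <- sqrt(1 - rho^2)
    for (j in seq_len(m)[-1]) z[, j] <- rho * z[, j - 1] + s * e[, j]
    return(z)
  }
  lat <- .ld_latent[[profile]]
  sqrt(lat) * rnorm(n) + sqrt(1 - lat) * e
}

#' Simulate one genotype region
#'
#' Generates an `n_samples` x `n_markers` integer matrix of additive
#' genotype dosages (0/1/2 copies of the minor allele) with the LD regime
#' and MAFs of `spec`.  Marginal genotype frequencies satisfy
#' Hardy-Weinberg proportions by construction.
#'
#' @param spec A [region_spec()].
#' @param n_samples Number of individuals.
#' @param rng_seed Optional integer seed.
#' @param maf Optional vector of per-marker MAFs overriding the draw from
#'   `spec$maf_range` (length 1 or `n_markers`).
#' @return Integer matrix with attribute `"maf"` (the per-marker MAFs).
#' @examples
#' g <- simulate_region(region_spec(10, "high"), 500, rng_seed = 1)
#' cor(g[, 1], g[, 2])^2
#' @export
simulate_region <- function(spec, n_samples, rng_seed = NULL, maf = NULL) {
  stopifnot(inherits(spec, "region_spec"))
  if (length(n_samples) != 1L || !is.finite(n_samples) || n_samples < 1)
    stop("n_samples must be a positive count")
  if (!is.null(rng_seed)) set.seed(rng_seed)
  m <- spec$n_markers
  if (is.null(maf)) {
    maf <- draw_region_mafs(spec)
  } else {
    if (length(maf) == 1L) maf <- rep(maf, m)
    if (length(maf) != m) stop("maf must have length 1 or n_markers")
    if (any(maf <= 0 | maf > 0.5)) stop("maf values must lie in (0, 0.5]")
  }
  z <- latent_block(as.integer(n_samples), m, spec$ld_profile, spec$rho)
  g <- threshold_latent(z, maf)
  attr(g, "maf") <- maf
  g
}

#' Simulate a binary phenotype under a logistic disease model
#'
#' Disease status is Bernoulli with
#' `P(Y = 1 | G) = expit(alpha0 + sum_j log(OR_j) * G_j)` over the causal
#' genotype dosages; the intercept `alpha0` is solved numerically so that
#' the population prevalence equals `baseline_prevalence`.
#'
#' @param genotypes Sample x marker dosage matrix.
#' @param causal_indices Column indices of the causal markers (may be
#'   empty, giving an intercept-only model).
#' @param causal_or Per-allele odds ratios, one per causal marker; all > 0.
#' @param baseline_prevalence Target population prevalence in (0, 1).
#' @param rng_seed Optional integer seed.
#' @return Integer 0/1 vector with attribute `"intercept"` (the solved
#'   `alpha0`).
#' @examples
#' g <- simulate_region(region_spec(5, "none"), 2000, rng_seed = 1)
#' y <- simulate_phenotype(g, 1, 1.5, rng_seed = 2)
#' mean(y)
#' @export
simulate_phenotype <- function(genotypes, causal_indices, causal_or,
                               baseline_prevalence = 0.1, rng_seed = NULL) {
  if (length(causal_indices) != length(causal_or))
    stop("causal_indices and causal_or must have the same length")
  if (any(causal_or <= 0)) stop("all odds ratios must be > 0")
  if (baseline_prevalence <= 0 || baseline_prevalence >= 1)
    stop("baseline_prevalence must lie in (0, 1)")
  if (!is.null(rng_seed)) set.seed(rng_seed)
  eta <- if (length(causal_indices)) {
    as.numeric(genotypes[, causal_indices, drop = FALSE] %*% log(causal_or))
  } else {
    rep(0, nrow(genotypes))
  }
  a0 <- solve_intercept(eta, baseline_prevalence)
  y <- rbinom(length(eta), 1L, plogis(a0 + eta))
  attr(y, "intercept") <- a0
  y
}

# alpha0 such that mean(expit(alpha0 + eta)) == prevalence
solve_intercept <- function(eta, prevalence) {
  if (all(eta == 0)) return(qlogis(prevalence))
  uniroot(function(a) mean(plogis(a + eta)) - prevalence,
          interval = c(-40, 40), tol = 1e-9)$root
}

#' Construct a genotype dataset
#'
#' The universal container: a sample x marker dosage matrix, a phenotype
#' vector (binary 0/1 or quantitative), marker metadata, and (for
#' simulated data) the indices of the truly phenotype-related markers.
#'
#' @param genotypes Integer sample x marker matrix with values 0/1/2 (NA
#'   allowed for read-in data).
#' @param phenotype Vector, one value per sample.
#' @param marker_ids Character marker labels; defaults to column names.
#' @param truth Integer indices of causal markers (empty for real data).
#' @param phenotype_type `"binary"` or `"quantitative"`.
#' @param region Optional integer vector giving each marker's region index.
#' @return An object of class `"genotype_dataset"`.
#' @export
genotype_dataset <- function(genotypes, phenotype,
                             marker_ids = colnames(genotypes),
                             truth = integer(0),
                             phenotype_type = c("binary", "quantitative"),
                             region = NULL) {
  phenotype_type <- match.arg(phenotype_type)
  genotypes <- as.matrix(genotypes)
  if (nrow(genotypes) != length(phenotype))
    stop("phenotype length must equal the number of samples")
  vals <- genotypes[!is.na(genotypes)]
  if (length(vals) && !all(vals %in% 0:2))
    stop("genotype values must be 0, 1, 2 or NA")
  if (is.null(marker_ids)) marker_ids <- paste0("m", seq_len(ncol(genotypes)))
  if (length(marker_ids) != ncol(genotypes))
    stop("marker_ids length must equal the number of markers")
  truth <- as.integer(truth)
  if (length(truth) && (any(truth < 1) || any(truth > ncol(genotypes))))
    stop("truth indices must refer to existing markers")
  if (phenotype_type == "binary" && !all(phenotype %in% 0:1))
    stop("binary phenotype must be coded 0/1")
  colnames(genotypes) <- marker_ids
  structure(list(genotypes = genotypes,
                 phenotype = as.numeric(phenotype),
                 marker_ids = as.character(marker_ids),
                 truth = truth,
                 phenotype_type = phenotype_type,
                 region = region),
            class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat(sprintf("genotype_dataset: %d samples x %d markers (%s phenotype)\n",
              nrow(x$genotypes), ncol(x$genotypes), x$phenotype_type))
  if (x$phenotype_type == "binary")
    cat(sprintf("  cases: %d, controls: %d\n",
                sum(x$phenotype == 1), sum(x$phenotype == 0)))
  if (length(x$truth))
    cat(sprintf("  causal markers: %s\n",
                paste(x$marker_ids[x$truth], collapse = ", ")))
  invisible(x)
}

#' Draw a case-control sample from a simulated population
#'
#' Samples exactly `n_cases` affected and `n_controls` unaffected
#' individuals without replacement, preserving truth indices.
#'
#' @param population A binary-phenotype [genotype_dataset()].
#' @param n_cases,n_controls Numbers of cases/controls to draw.
#' @param rng_seed Optional integer seed.
#' @return A [genotype_dataset()] with `n_cases + n_controls` rows (cases
#'   first).
#' @export
sample_case_control <- function(population, n_cases, n_controls,
                                rng_seed = NULL) {
  stopifnot(inherits(population, "genotype_dataset"))
  if (population$phenotype_type != "binary")
    stop("case-control sampling needs a binary phenotype")
  if (!is.null(rng_seed)) set.seed(rng_seed)
  cases <- which(population$phenotype == 1)
  controls <- which(population$phenotype == 0)
  if (length(cases) < n_cases)
    stop(sprintf("requested %d cases but the population contains only %d",
                 n_cases, length(cases)))
  if (length(controls) < n_controls)
    stop(sprintf("requested %d controls but the population contains only %d",
                 n_controls, length(controls)))
  keep <- c(sample(cases, n_cases), sample(controls, n_controls))
  genotype_dataset(population$genotypes[keep, , drop = FALSE],
                   population$phenotype[keep],
                   marker_ids = population$marker_ids,
                   truth = population$truth,
                   phenotype_type = "binary",
                   region = population$region)
}

#' Specify a simulation scenario
#'
#' Defines one cell of the simulation study: the genome layout (22
#' regions of 50 SNPs by default), how the phenotype-related SNPs are
#' placed, and the disease-model parameters.
#'
#' Scenarios: (1) independent causal SNPs replacing a random background
#' column in 8 distinct regions, LD-free; (2) as 1 but the causal SNPs are
#' mutually correlated (genotype correlation `causal_corr`, default 0.1)
#' via an exchangeable latent-Gaussian copula; (3) causal SNPs are
#' in-block members sharing their region's LD; (4) three regions with
#' high/modest/low LD, one causal SNP each with OR 1.5.
#'
#' Schemes set the effect sizes of the 8 causal SNPs: (1) null, all
#' OR = 1, MAF 0.3; (2) OR 1.1-1.8, MAF 0.3; (3) OR 1.3, MAFs spread over
#' 0.05-0.5; (4) OR 1.2, MAF 0.3 (all sub-Bonferroni effects).
#'
#' @param scenario Scenario id, 1-4.
#' @param scheme Scheme id, 1-4 (ignored for scenario 4).
#' @param n_cases,n_controls Case-control sample sizes (default 1000/1000).
#' @param causal_or,causal_maf Optional overrides of the scheme defaults.
#' @param causal_corr Pairwise genotype correlation among causal SNPs
#'   (scenario 2 only; default 0.1).
#' @param n_regions,markers_per_region Genome layout (defaults 22 x 50;
#'   scenario 4 uses 3 regions).
#' @param population_size Size of the simulated source population
#'   (default 100000).
#' @param prevalence Baseline disease prevalence (default 0.1).
#' @param maf_range Background-marker MAF range.
#' @param seed Integer seed; the whole dataset is a deterministic
#'   function of the spec.
#' @return An object of class `"scenario_spec"`.
#' @examples
#' scenario_spec(1, 2, seed = 7)
#' @export
scenario_spec <- function(scenario = 1, scheme = 2,
                          n_cases = 1000, n_controls = 1000,
                          causal_or = NULL, causal_maf = NULL,
                          causal_corr = NULL,
                          n_regions = NULL, markers_per_region = 50,
                          population_size = 100000, prevalence = 0.1,
                          maf_range = c(0.05, 0.5), seed = 1) {
  if (!scenario %in% 1:4) stop("scenario must be 1, 2, 3 or 4")
  if (!scheme %in% 1:4) stop("scheme must be 1, 2, 3 or 4")
  if (is.null(n_regions)) n_regions <- if (scenario == 4) 3L else 22L
  n_causal <- if (scenario == 4) as.integer(n_regions) else 8L
  if (scenario == 4 && n_regions != 3)
    stop("scenario 4 uses exactly 3 regions (high/modest/low LD)")
  if (is.null(causal_or)) {
    causal_or <- if (scenario == 4) rep(1.5, n_causal) else
      switch(scheme,
             rep(1, 8),
             seq(1.1, 1.8, by = 0.1),
             rep(1.3, 8),
             rep(1.2, 8))
  }
  if (is.null(causal_maf)) {
    causal_maf <- if (scenario == 4) rep(0.3, n_causal) else
      switch(scheme,
             rep(0.3, 8),
             rep(0.3, 8),
             seq(0.05, 0.5, length.out = 8),
             rep(0.3, 8))
  }
  if (length(causal_or) != n_causal || length(causal_maf) != n_causal)
    stop(sprintf("scenario %d needs %d causal odds ratios and MAFs",
                 scenario, n_causal))
  if (any(causal_or <= 0)) stop("all odds ratios must be > 0")
  if (any(causal_maf <= 0 | causal_maf > 0.5))
    stop("causal MAFs must lie in (0, 0.5]")
  if (is.null(causal_corr)) causal_corr <- if (scenario == 2) 0.1 else 0
  if (causal_corr < 0 || causal_corr >= 1)
    stop("causal_corr must lie in [0, 1)")
  if (n_regions * markers_per_region < n_causal)
    stop("genome too small for the causal SNPs")
  structure(list(scenario = as.integer(scenario), scheme = as.integer(scheme),
                 n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 causal_or = causal_or, causal_maf = causal_maf,
                 causal_corr = causal_corr,
                 n_regions = as.integer(n_regions),
                 markers_per_region = as.integer(markers_per_region),
                 population_size = as.integer(population_size),
                 prevalence = prevalence,
                 maf_range = maf_range,
                 seed = as.integer(seed)),
            class = "scenario_spec")
}

# everything decided by the RNG before genotypes are drawn: region LD
# profiles, per-region MAF vectors, causal placement
scenario_plan <- function(spec) {
  profiles <- if (spec$scenario == 4) c("high", "modest", "low") else
    rep(c("low", "modest", "high"), length.out = spec$n_regions)
  m <- spec$markers_per_region
  n_causal <- length(spec$causal_or)
  causal_region <- if (spec$scenario == 4) seq_len(3L) else
    sort(sample(spec$n_regions, n_causal))
  causal_pos <- vapply(seq_len(n_causal), function(i) sample.int(m, 1L),
                       integer(1))
  region_specs <- lapply(seq_len(spec$n_regions), function(r) {
    region_spec(m, profiles[r], maf_range = spec$maf_range)
  })
  mafs <- lapply(region_specs, draw_region_mafs)
  # causal SNPs that live inside a block (scenarios 3-4) pin the block's
  # MAF so the within-block LD regime is preserved
  if (spec$scenario %in% c(3, 4)) {
    for (i in seq_len(n_causal)) {
      r <- causal_region[i]
      base <- spec$causal_maf[i]
      mafs[[r]] <- switch(profiles[r],
        high = rep(base, m),
        modest = pmin(0.5, pmax(spec$maf_range[1],
                                base * runif(m, 0.85, 1.15))),
        mafs[[r]])
      mafs[[r]][causal_pos[i]] <- base
    }
  }
  causal_index <- (causal_region - 1L) * m + causal_pos
  list(profiles = profiles, region_specs = region_specs, mafs = mafs,
       causal_region = causal_region, causal_pos = causal_pos,
       causal_index = causal_index)
}

# causal genotype columns for scenarios 1-2: independent of all
# background SNPs; scenario 2 correlates them through an exchangeable
# latent-Gaussian copula (latent correlation calibrated so realized
# genotype correlation matches causal_corr = 0.1)
draw_inserted_causal <- function(spec, n) {
  k <- length(spec$causal_maf)
  if (spec$causal_corr > 0) {
    lat <- .causal_copula_latent * (spec$causal_corr / 0.1)
    z <- sqrt(lat) * rnorm(n) + sqrt(1 - lat) * matrix(rnorm(n * k), n, k)
  } else {
    z <- matrix(rnorm(n * k), n, k)
  }
  threshold_latent(z, spec$causal_maf)
}

marker_labels <- function(n_regions, m) {
  as.vector(vapply(seq_len(n_regions),
                   function(r) sprintf("r%02d_s%02d", r, seq_len(m)),
                   character(m)))
}

#' Generate the full simulated population for a scenario
#'
#' Draws the whole source population (default 100000 individuals, 1100
#' SNPs in 22 regions of 50) with phenotypes from the logistic disease
#' model.  Causal SNPs replace a background column in their region
#' (scenarios 1-2) or are in-block members (scenarios 3-4), so the marker
#' count stays `n_regions * markers_per_region`.  Use
#' [sample_case_control()] to draw the analysis dataset, or
#' [simulate_case_control_study()] to do both in one (much cheaper) step.
#'
#' @param spec A [scenario_spec()].
#' @return A population-scale [genotype_dataset()].
#' @export
make_scenario <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  set.seed(spec$seed)
  plan <- scenario_plan(spec)
  n <- spec$population_size
  m <- spec$markers_per_region
  blocks <- lapply(seq_len(spec$n_regions), function(r) {
    simulate_region(plan$region_specs[[r]], n, maf = plan$mafs[[r]])
  })
  g <- do.call(cbind, blocks)
  if (spec$scenario %in% c(1, 2))
    g[, plan$causal_index] <- draw_inserted_causal(spec, n)
  y <- simulate_phenotype(g, plan$causal_index, spec$causal_or,
                          baseline_prevalence = spec$prevalence)
  ids <- marker_labels(spec$n_regions, m)
  genotype_dataset(g, y, marker_ids = ids, truth = plan$causal_index,
                   phenotype_type = "binary",
                   region = rep(seq_len(spec$n_regions), each = m))
}

#' Simulate a case-control study directly
#'
#' Equivalent in distribution to [make_scenario()] followed by
#' [sample_case_control()], but exploits the fact that markers carrying no
#' phenotype information are independent of case-control selection: only
#' the causal markers (scenarios 1-2) or the causal-bearing regions
#' (scenarios 3-4) are generated at population scale; all other regions
#' are drawn directly at the sample size.  This is exact, not an
#' approximation, and makes replicated benchmarking affordable.
#'
#' @param spec A [scenario_spec()].
#' @return A [genotype_dataset()] with `n_cases + n_controls` samples.
#' @examples
#' d <- simulate_case_control_study(
#'   scenario_spec(1, 2, n_cases = 200, n_controls = 200,
#'                 population_size = 20000, seed = 1))
#' d
#' @export
simulate_case_control_study <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  set.seed(spec$seed)
  plan <- scenario_plan(spec)
  n_pop <- spec$population_size
  m <- spec$markers_per_region
  n_s <- spec$n_cases + spec$n_controls

  if (spec$scenario %in% c(1, 2)) {
    gc_pop <- draw_inserted_causal(spec, n_pop)
    y_pop <- simulate_phenotype(gc_pop, seq_along(spec$causal_or),
                                spec$causal_or,
                                baseline_prevalence = spec$prevalence)
    keep <- draw_cc_rows(y_pop, spec$n_cases, spec$n_controls)
    g <- matrix(0L, n_s, spec$n_regions * m)
    for (r in seq_len(spec$n_regions)) {
      g[, (r - 1L) * m + seq_len(m)] <-
        simulate_region(plan$region_specs[[r]], n_s, maf = plan$mafs[[r]])
    }
    g[, plan$causal_index] <- gc_pop[keep, , drop = FALSE]
    y <- y_pop[keep]
  } else {
    causal_regions <- unique(plan$causal_region)
    pop_blocks <- lapply(causal_regions, function(r) {
      simulate_region(plan$region_specs[[r]], n_pop, maf = plan$mafs[[r]])
    })
    names(pop_blocks) <- as.character(causal_regions)
    eta <- rep(0, n_pop)
    for (i in seq_along(spec$causal_or)) {
      blk <- pop_blocks[[as.character(plan$causal_region[i])]]
      eta <- eta + log(spec$causal_or[i]) * blk[, plan$causal_pos[i]]
    }
    a0 <- solve_intercept(eta, spec$prevalence)
    y_pop <- rbinom(n_pop, 1L, plogis(a0 + eta))
    keep <- draw_cc_rows(y_pop, spec$n_cases, spec$n_controls)
    g <- matrix(0L, n_s, spec$n_regions * m)
    for (r in seq_len(spec$n_regions)) {
      cols <- (r - 1L) * m + seq_len(m)
      g[, cols] <- if (r %in% causal_regions) {
        pop_blocks[[as.character(r)]][keep, , drop = FALSE]
      } else {
        simulate_region(plan$region_specs[[r]], n_s, maf = plan$mafs[[r]])
      }
    }
    y <- y_pop[keep]
  }
  ids <- marker_labels(spec$n_regions, m)
  genotype_dataset(g, y, marker_ids = ids, truth = plan$causal_index,
                   phenotype_type = "binary",
                   region = rep(seq_len(spec$n_regions), each = m))
}

draw_cc_rows <- function(y_pop, n_cases, n_controls) {
  cases <- which(y_pop == 1); controls <- which(y_pop == 0)
  if (length(cases) < n_cases)
    stop(sprintf("requested %d cases but the population contains only %d",
                 n_cases, length(cases)))
  if (length(controls) < n_controls)
    stop(sprintf("requested %d controls but the population contains only %d",
                 n_controls, length(controls)))
  c(sample(cases, n_cases), sample(controls, n_controls))
}

#' Simulate a causal-chain dataset (V -> C -> Y)
#'
#' Generates a small dataset in which marker V influences the phenotype
#' only through marker C: C copies V with probability `mixing` (otherwise
#' it is an independent draw), and Y is Bernoulli-logistic in C alone.
#' By construction V is conditionally independent of Y given C, so the
#' Markov blanket of Y is exactly \{C\}.  Used to validate the
#' conditional-independence machinery against a known d-separation truth.
#'
#' @param n Sample size.
#' @param n_noise Number of additional independent noise markers.
#' @param maf Minor allele frequency of V, C and the noise markers.
#' @param beta Log-odds effect of C on Y.
#' @param mixing Probability that C copies V.
#' @param prevalence Baseline prevalence.
#' @param rng_seed Optional integer seed.
#' @return A [genotype_dataset()] whose first two markers are V and C and
#'   whose `truth` is the index of C.
#' @export
simulate_chain_dataset <- function(n = 50000, n_noise = 10, maf = 0.3,
                                   beta = 0.5, mixing = 0.8,
                                   prevalence = 0.2, rng_seed = NULL) {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  v <- rbinom(n, 2L, maf)
  copy <- runif(n) < mixing
  c_marker <- ifelse(copy, v, rbinom(n, 2L, maf))
  eta <- beta * c_marker
  a0 <- solve_intercept(eta, prevalence)
  y <- rbinom(n, 1L, plogis(a0 + eta))
  noise <- if (n_noise > 0) matrix(rbinom(n * n_noise, 2L, maf), n) else NULL
  g <- cbind(V = v, C = c_marker, noise)
  colnames(g) <- c("V", "C", if (n_noise > 0) paste0("noise", seq_len(n_noise)))
  genotype_dataset(g, y, truth = 2L, phenotype_type = "binary")
}
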