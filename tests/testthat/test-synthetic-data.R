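# Cohort generator: determinism, planted-effect recovery, marginal
# calibration of genotypes, binary phenotypes and somatic clones.

test_that("identical configurations regenerate bit-identical cohorts", {
  cfg <- demo_sim_config(n_samples = 300, seed = 77)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$genotypes, b$genotypes)
  expect_identical(a$npx, b$npx)
  expect_identical(a$covariates, b$covariates)
  expect_identical(a$phenotypes, b$phenotypes)
  expect_identical(a$somatic, b$somatic)
  c2 <- simulate_cohort(demo_sim_config(n_samples = 300, seed = 78))
  expect_false(identical(a$npx, c2$npx))
})

test_that("a null configuration produces centred protein abundances", {
  n <- 3000
  cfg <- sim_config(
    n_samples = n, seed = 5,
    variant_specs = data.frame(gene = "G1", consequence = "missense_variant",
                               maf = 0.1, stringsAsFactors = FALSE),
    protein_specs = data.frame(protein_id = "P1", gene = "G1", panel = "a",
                               sigma = 1, stringsAsFactors = FALSE),
    covariate_effects = numeric(0))
  co <- simulate_cohort(cfg)
  expect_lt(abs(mean(co$npx[, "P1"])), 4 / sqrt(n))
})

test_that("a planted effect is recovered by OLS on allele count", {
  cfg <- sim_config(
    n_samples = 2000, seed = 11,
    variant_specs = data.frame(gene = "G1", consequence = "missense_variant",
                               maf = 0.05, target_protein = "P1", beta = 1.5,
                               stringsAsFactors = FALSE),
    protein_specs = data.frame(protein_id = "P1", gene = "G1", panel = "a",
                               sigma = 1, stringsAsFactors = FALSE),
    covariate_effects = numeric(0))
  co <- simulate_cohort(cfg)
  beta_hat <- coef(lm(co$npx[, "P1"] ~ co$genotypes[, 1]))[2]
  expect_gt(beta_hat, 1.2)
  expect_lt(beta_hat, 1.8)
  expect_identical(co$truth$unit[co$truth$type == "pqtl"], "v001")
})

test_that("empirical MAFs stay within 3 binomial SDs of the target", {
  set.seed(13)
  mafs <- runif(30, 0.005, 0.4)
  n <- 1500
  cfg <- sim_config(
    n_samples = n, seed = 17,
    variant_specs = data.frame(gene = sprintf("G%02d", 1:30),
                               consequence = "missense_variant", maf = mafs,
                               stringsAsFactors = FALSE),
    protein_specs = data.frame(protein_id = "P1", gene = "G01", panel = "a",
                               sigma = 1, stringsAsFactors = FALSE),
    covariate_effects = numeric(0))
  co <- simulate_cohort(cfg)
  sd3 <- 3 * sqrt(mafs * (1 - mafs) / (2 * n))
  expect_true(all(abs(co$variants$cohort_maf - mafs) <= sd3 + 1e-12))
  expect_true(all(co$genotypes %in% c(0, 1, 2)))
})

test_that("configuration validation names the offending field", {
  vs <- data.frame(gene = "G1", consequence = "missense_variant", maf = 0.7)
  ps <- data.frame(protein_id = "P1", gene = "G1", panel = "a", sigma = 1)
  expect_error(sim_config(100, 1, vs, ps), "maf")
  vs$maf <- 0.1
  ps$sigma <- 0
  expect_error(sim_config(100, 1, vs, ps), "sigma")
  ps$sigma <- 1
  expect_error(sim_config(1, 1, vs, ps), "n_samples")
  vs2 <- vs; vs2$beta <- Inf; vs2$target_protein <- "P1"
  expect_error(sim_config(100, 1, vs2, ps), "beta")
})

test_that("binary phenotypes follow the logistic carrier model", {
  base_cfg <- function(or, seed) sim_config(
    n_samples = 5000, seed = seed,
    variant_specs = data.frame(gene = "G1", consequence = "stop_gained",
                               maf = 0.01, stringsAsFactors = FALSE),
    protein_specs = data.frame(protein_id = "P1", gene = "G1", panel = "a",
                               sigma = 1, stringsAsFactors = FALSE),
    covariate_effects = numeric(0),
    binary_specs = data.frame(phenotype_id = "ph", gene = "G1",
                              odds_ratio = or, prevalence = 0.05,
                              stringsAsFactors = FALSE))
  co <- simulate_cohort(base_cfg(1, 23))
  carrier <- co$genotypes[, 1] >= 1
  for (grp in list(which(carrier), which(!carrier))) {
    rate <- mean(co$phenotypes$ph[grp])
    expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / length(grp)))
  }
  # zero carriers: case rate is the baseline prevalence
  cfg0 <- base_cfg(10, 29)
  cfg0$variant_specs$maf <- 0
  co0 <- simulate_cohort(cfg0)
  expect_lt(abs(mean(co0$phenotypes$ph) - 0.05),
            3 * sqrt(0.05 * 0.95 / 5000))
  expect_error(
    simulate_binary_phenotypes(co, data.frame(phenotype_id = "x",
                                              gene = "G1", odds_ratio = 2,
                                              prevalence = 1.5)),
    "prevalence")
})

test_that("a planted odds ratio of 20 is detectable in nearly every seed", {
  hits <- 0
  n_seeds <- 60
  for (s in seq_len(n_seeds)) {
    cfg <- sim_config(
      n_samples = 5000, seed = 1000 + s,
      variant_specs = data.frame(gene = "G1", consequence = "stop_gained",
                                 maf = 0.01, stringsAsFactors = FALSE),
      protein_specs = data.frame(protein_id = "P1", gene = "G1", panel = "a",
                                 sigma = 1, stringsAsFactors = FALSE),
      covariate_effects = numeric(0),
      binary_specs = data.frame(phenotype_id = "ph", gene = "G1",
                                odds_ratio = 20, prevalence = 0.01,
                                stringsAsFactors = FALSE))
    co <- simulate_cohort(cfg)
    carrier <- co$genotypes[, 1] >= 1
    r <- fisher_binary_assoc(carrier, co$phenotypes$ph == 1)
    if (!r$untestable && r$odds_ratio > 5) hits <- hits + 1
  }
  expect_gte(hits / n_seeds, 0.95)
})

test_that("somatic clones rise with age and respect the VAF window", {
  cfg <- demo_sim_config(n_samples = 4000, seed = 31)
  co <- simulate_cohort(cfg)
  calls <- co$somatic
  expect_true(all(calls$vaf > 0 & calls$vaf <= 0.5))
  expect_true(all(calls$alt_depth >= 1))
  carrier <- co$samples %in% calls$sample_id[calls$gene == "TET2"]
  fit <- glm(carrier ~ co$covariates$age, family = binomial())
  expect_gt(coef(fit)[2], 0)
  expect_lt(summary(fit)$coefficients[2, 4], 0.05)
})

test_that("a flat somatic age profile shows no age trend", {
  flat_p <- vapply(1:20, function(s) {
    cfg <- sim_config(
      n_samples = 2000, seed = 4000 + s,
      variant_specs = data.frame(gene = "G1", consequence = "missense_variant",
                                 maf = 0.1, stringsAsFactors = FALSE),
      protein_specs = data.frame(protein_id = "P1", gene = "G1", panel = "a",
                                 sigma = 1, stringsAsFactors = FALSE),
      covariate_effects = numeric(0),
      somatic_specs = data.frame(gene = "TET2", intercept = -2.2, slope = 0,
                                 stringsAsFactors = FALSE))
    co <- simulate_cohort(cfg)
    carrier <- co$samples %in% co$somatic$sample_id
    summary(glm(carrier ~ co$covariates$age,
                family = binomial()))$coefficients[2, 4]
  }, numeric(1))
  expect_gte(mean(flat_p > 0.01), 0.9)
})

test_that("genotype missingness is generated at the configured rate", {
  cfg <- demo_sim_config(n_samples = 1000, seed = 3)
  cfg$missing_rate <- 0.05
  co <- simulate_cohort(cfg)
  miss <- mean(is.na(co$genotypes))
  expect_gt(miss, 0.03)
  expect_lt(miss, 0.07)
  # NPX is generated from pre-mask genotypes, so no NPX is missing
  expect_false(anyNA(co$npx))
})
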