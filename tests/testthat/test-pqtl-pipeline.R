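# ExWAS / collapsing orchestration, cis/trans classification,
# permutation calibration, direction summaries.

test_that("variants carried by fewer than four individuals are excluded", {
  co <- null_cohort(300, 5, 2, seed = 101)
  # force one variant down to 3 carriers
  g <- co$genotypes
  idx <- which(g[, 1] >= 1)
  g[idx[-(1:3)], 1] <- 0
  co$genotypes <- g
  co$variants$cohort_mac <- colSums(g)
  tab <- run_exwas(co, genetic_models = "genotypic")
  expect_false(co$variants$variant_id[1] %in% tab$variant_id)
  expect_true(all(co$variants$variant_id[-1] %in% tab$variant_id))
})

test_that("ExWAS row count is eligible variants x proteins x models", {
  co <- null_cohort(400, 6, 3, seed = 111)
  tab <- run_exwas(co)
  expect_equal(nrow(tab), 6 * 3 * 3)
  expect_setequal(unique(tab$genetic_model),
                  c("genotypic", "dominant", "recessive"))
  # recessive encodings with no homozygotes surface as untestable flags
  expect_true(all(!tab$untestable | is.na(tab$beta)))
})

test_that("a planted common variant reaches study-wide significance", {
  cfg <- sim_config(
    n_samples = 2000, seed = 121,
    variant_specs = data.frame(
      variant_id = "cisv", gene = "G1", chrom = "chr1", pos = 1e5,
      consequence = "missense_variant", maf = 0.05, gnomad_maf = 0.05,
      target_protein = "P1", beta = 1.5, stringsAsFactors = FALSE),
    protein_specs = data.frame(protein_id = "P1", gene = "G1", panel = "a",
                               sigma = 1, stringsAsFactors = FALSE))
  co <- simulate_cohort(cfg)
  tab <- run_exwas(co)
  dom <- tab[tab$genetic_model == "dominant" & tab$protein == "P1", ]
  expect_lt(dom$p, 1e-8)
  gen <- tab[tab$genetic_model == "genotypic" & tab$protein == "P1", ]
  expect_lt(abs(gen$beta - 1.5), 3 * gen$se)
  expect_identical(gen$cis_trans_label, "cis-CDS")
})

test_that("ExWAS agrees with lm on a cohort with genotype missingness", {
  cfg <- demo_sim_config(n_samples = 400, seed = 131)
  cfg$missing_rate <- 0.05
  co <- simulate_cohort(cfg)
  tab <- run_exwas(co, genetic_models = "genotypic")
  row <- tab[tab$variant_id == "GENE1:mis1" & tab$protein == "P1", ]
  covs <- build_covariates(co$covariates, "exwas", panel = "oncology")
  fit <- summary(lm(co$npx[, "P1"] ~ covs[, -1] + co$genotypes[, "GENE1:mis1"]))
  beta_lm <- fit$coefficients[nrow(fit$coefficients), ]
  expect_equal(row$beta, beta_lm["Estimate"], tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(row$p, beta_lm["Pr(>|t|)"], tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_lt(row$n_used, 400)
})

test_that("cis/trans classification partitions by distance and contig", {
  gene_map <- data.frame(
    gene = c("PG", "NEAR", "FAR", "OTHER"),
    chrom = c("chr1", "chr1", "chr1", "chr2"),
    start = c(1e6, 1e6 + 5e5, 5e6, 1e6),
    end = c(1.1e6, 1.6e6 + 5e5, 5.1e6, 1.1e6), stringsAsFactors = FALSE)
  pmap <- data.frame(protein_id = "P", gene = "PG", stringsAsFactors = FALSE)
  lab <- function(g, chrom, pos) classify_cis_trans(g, chrom, pos, "P",
                                                    gene_map, pmap)
  expect_identical(lab("PG", "chr1", 1.05e6), "cis-CDS")
  expect_identical(lab("NEAR", "chr1", 1.5e6 + 1e5), "cis-position trans-CDS")
  # exactly 1 Mb away counts as within the window
  expect_identical(lab("FAR", "chr1", 1.1e6 + 1e6), "cis-position trans-CDS")
  expect_identical(lab("FAR", "chr1", 1.1e6 + 1e6 + 1), "trans-CDS")
  expect_identical(lab("OTHER", "chr2", 1.05e6), "trans-CDS")
  expect_true(is.na(classify_cis_trans("PG", "chr1", 1e6, "unknown_prot",
                                       gene_map, pmap)))
})

test_that("collapsing flags zero-carrier and syn-model rows appropriately", {
  co <- null_cohort(300, 4, 2, seed = 141)
  carriers <- matrix(FALSE, 2, 300,
                     dimnames = list(c("GZ", "GC"), co$samples))
  carriers["GC", 1:25] <- TRUE
  cm <- carrier_matrix_for_test <- structure(
    list(carriers = carriers, qv_sets = list(), model = "syn",
         zygosity = "dominant"), class = "carrier_matrix")
  tab <- run_collapsing(co, cm)
  expect_true(all(tab$untestable[tab$gene == "GZ"]))
  expect_true(all(is.na(tab$p[tab$gene == "GZ"])))
  expect_false(any(tab$untestable[tab$gene == "GC"]))
  expect_true(all(tab$empirical_null))
})

test_that("collapsing beats the best single variant when the burden is spread", {
  # ten singleton-ish PTVs with a shared negative effect: aggregation wins
  n <- 3000
  vs <- data.frame(
    variant_id = sprintf("ptv%02d", 1:10), gene = "G1", chrom = "chr1",
    pos = 1e5 + 100 * (1:10), consequence = "stop_gained",
    maf = rep(0.002, 10), gnomad_maf = 0, target_protein = "P1",
    beta = -0.8, stringsAsFactors = FALSE)
  cfg <- sim_config(n_samples = n, seed = 151, variant_specs = vs,
                    protein_specs = data.frame(protein_id = "P1", gene = "G1",
                                               panel = "a", sigma = 1,
                                               stringsAsFactors = FALSE),
                    covariate_effects = numeric(0))
  co <- simulate_cohort(cfg)
  exwas <- run_exwas(co, genetic_models = "dominant")
  qv <- list(G1 = vs$variant_id)
  cm <- build_dominant_carriers(co$genotypes, qv, "ptv")
  coll <- run_collapsing(co, cm)
  expect_lt(coll$p[coll$protein == "P1"],
            min(exwas$p[exwas$protein == "P1"], na.rm = TRUE))
})

test_that("the n-of-1 permutation preserves allele counts and is seed-stable", {
  co <- null_cohort(250, 8, 3, seed = 161)
  mac_before <- colSums(co$genotypes)
  rep1 <- n_of_one_permutation(co, seed = 7, threshold = 1e-3)
  rep2 <- n_of_one_permutation(co, seed = 7, threshold = 1e-3)
  expect_identical(rep1, rep2)
  expect_identical(colSums(co$genotypes), mac_before)
  expect_s3_class(rep1, "permutation_report")
  expect_lte(rep1$n_hits_at_threshold, rep1$n_tests)
})

test_that("permutation reports reproduce printed false-positive accounting", {
  r1 <- permutation_report(n_tests = 5.4e9, n_hits = 24,
                           observed_significant = 328975)
  expect_equal(round(r1$fp_percent_of_observed, 3), 0.007)
  r2 <- permutation_report(n_tests = 499.9e6, n_hits = 4,
                           observed_significant = 7412)
  expect_equal(round(r2$fp_percent_of_observed, 2), 0.05)
  expect_equal(r1$expected_fp, 24)
})

test_that("scans are bit-identical across reruns on the same inputs", {
  co <- null_cohort(200, 5, 2, seed = 171)
  t1 <- run_exwas(co)
  t2 <- run_exwas(co)
  expect_identical(t1, t2)
})

test_that("direction summaries stratify counts, signs and magnitudes", {
  tab <- data.frame(
    model = rep(c("ptv", "syn"), each = 4),
    cis_trans_label = rep(c("cis-CDS", "trans-CDS"), 4),
    beta = c(-1, -2, -0.5, -0.1, 0.2, -0.3, 0.4, 0.5),
    p = rep(1e-10, 8), stringsAsFactors = FALSE)
  s <- summarize_directions(tab)
  ptv_cis <- s[s$model == "ptv" & s$cis_trans_label == "cis-CDS", ]
  expect_equal(ptv_cis$n, 2)
  expect_equal(ptv_cis$frac_beta_negative, 1)
  expect_equal(ptv_cis$median_abs_beta, 0.75)
  # all-negative fixture
  s2 <- summarize_directions(tab[tab$beta < 0, ])
  expect_true(all(s2$frac_beta_negative == 1))
  # rare stratum planted with bigger effects than the common stratum
  tab2 <- data.frame(model = c(rep("rare", 5), rep("common", 5)),
                     beta = c(rnorm(5, 2, 0.1), rnorm(5, 0.3, 0.05)))
  s3 <- summarize_directions(tab2, by = "model")
  expect_gt(s3$median_abs_beta[s3$model == "rare"],
            s3$median_abs_beta[s3$model == "common"])
})

test_that("planted negative PTV effects summarise as protein-lowering", {
  cfg <- demo_sim_config(n_samples = 3000, seed = 181)
  co <- simulate_cohort(cfg)
  qv <- qualify_variants(co$variants, default_model_registry()$ptv)
  cm <- build_dominant_carriers(co$genotypes, qv, "ptv")
  tab <- run_collapsing(co, cm)
  s <- summarize_directions(tab[tab$cis_trans_label %in% "cis-CDS" &
                                  !tab$untestable, ],
                            by = "model")
  expect_gte(s$frac_beta_negative, 0.95)
})
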