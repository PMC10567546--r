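# Shared fixture builders; everything is generated in code at test time.

# One fully passing annotated variant row; override any field via ...
qc_variant <- function(...) {
  v <- data.frame(
    variant_id = "v1", gene = "G1", chrom = "chr1", pos = 1000L,
    ref = "A", alt = "T", variant_type = "SNV",
    consequence = "missense_variant", cohort_mac = 5L, cohort_maf = 5e-4,
    gnomad_maf = 1e-4, revel = 0.5, mtr_intolerant = TRUE,
    coverage_depth = 50, gq = 99, fs = 0, mq = 60, qual = 1000,
    rprs = 0, mqrs = 0, dragen_pass = TRUE, het_alt_fraction = 0.5,
    hom_alt_fraction = 0.8, het_alt_reads = 25, het_total_reads = 50,
    site_missing_fraction = 0, site_fail_fraction = 0,
    gnomad_cov10_fraction = 1, gnomad_pass_fraction = 1,
    gnomad_exome_z = 0, gnomad_exome_mq = 60, in_ccds = TRUE,
    stringsAsFactors = FALSE
  )
  mods <- list(...)
  for (nm in names(mods)) v[[nm]] <- mods[[nm]]
  v
}

# random dosage matrix with sample/variant names
rand_genotypes <- function(n_samples, n_variants, seed, maf = 0.2) {
  set.seed(seed)
  m <- matrix(rbinom(n_samples * n_variants, 2, maf), n_samples, n_variants,
              dimnames = list(sprintf("S%03d", seq_len(n_samples)),
                              sprintf("v%03d", seq_len(n_variants))))
  m
}

# brute-force per-sample carrier scans (independent oracles)
brute_dominant <- function(genotypes, qv_sets) {
  genes <- names(qv_sets)
  out <- matrix(FALSE, length(genes), nrow(genotypes),
                dimnames = list(genes, rownames(genotypes)))
  for (g in genes) for (s in rownames(genotypes)) {
    hit <- FALSE
    for (v in qv_sets[[g]]) {
      if (v %in% colnames(genotypes)) {
        gv <- genotypes[s, v]
        if (!is.na(gv) && gv >= 1) hit <- TRUE
      }
    }
    out[g, s] <- hit
  }
  out
}

brute_recessive <- function(genotypes, qv_sets, sex, variant_chrom) {
  genes <- names(qv_sets)
  out <- matrix(FALSE, length(genes), nrow(genotypes),
                dimnames = list(genes, rownames(genotypes)))
  for (g in genes) for (si in seq_len(nrow(genotypes))) {
    s <- rownames(genotypes)[si]
    ids <- intersect(qv_sets[[g]], colnames(genotypes))
    doses <- genotypes[s, ids]
    hom <- any(!is.na(doses) & doses == 2)
    nhit <- sum(!is.na(doses) & doses >= 1)
    stat <- hom || nhit >= 2
    xs <- ids[variant_chrom[ids] %in% c("X", "chrX")]
    x_alt <- length(xs) > 0 && any(!is.na(genotypes[s, xs]) & genotypes[s, xs] >= 1)
    if (x_alt) {
      if (is.na(sex[si]) && !stat) { out[g, s] <- NA; next }
      if (!is.na(sex[si]) && sex[si] == "male") stat <- TRUE
    }
    out[g, s] <- stat
  }
  out
}

# minimum-likelihood two-sided binomial by direct enumeration
enum_binom_two_sided <- function(k, n, p0) {
  d <- dbinom(0:n, n, p0)
  sum(d[d <= d[k + 1] * (1 + 1e-7)])
}

# two-sided Fisher P by hypergeometric enumeration
enum_fisher_two_sided <- function(tab) {
  m <- sum(tab[1, ]); nn <- sum(tab[2, ]); k <- sum(tab[, 1])
  lo <- max(0, k - nn); hi <- min(k, m)
  d <- dhyper(lo:hi, m, nn, k)
  obs <- dhyper(tab[1, 1], m, nn, k)
  sum(d[d <= obs * (1 + 1e-7)])
}

# tiny null cohort for scan-level tests
null_cohort <- function(n_samples, n_variants, n_proteins, seed,
                        maf_range = c(0.05, 0.3)) {
  set.seed(seed)
  variant_specs <- data.frame(
    variant_id = sprintf("nv%03d", seq_len(n_variants)),
    gene = sprintf("NG%03d", seq_len(n_variants)),
    chrom = "chr1", pos = 1e5 + 1e4 * seq_len(n_variants),
    consequence = "missense_variant",
    maf = runif(n_variants, maf_range[1], maf_range[2]),
    stringsAsFactors = FALSE
  )
  protein_specs <- data.frame(
    protein_id = sprintf("NP%03d", seq_len(n_proteins)),
    gene = sprintf("PG%03d", seq_len(n_proteins)),
    panel = "panel1", sigma = 1, stringsAsFactors = FALSE
  )
  simulate_cohort(sim_config(
    n_samples = n_samples, seed = seed + 1L,
    variant_specs = variant_specs, protein_specs = protein_specs,
    covariate_effects = c(age = 0.005, sex = 0.1)))
}
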