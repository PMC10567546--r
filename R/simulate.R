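# Synthetic cohort generation with planted ground truth.

check_finite <- function(x, field) {
  if (!all(is.finite(x[!is.na(x)]))) {
    stop("non-finite value in field '", field, "'")
  }
  invisible(x)
}

#' Simulation configuration
#'
#' Describes a synthetic proteogenomic cohort: sample size, variants with
#' their annotations and planted per-protein effects, measured proteins
#' with per-protein residual noise, global covariate effects shared by all
#' proteins, optional binary phenotypes with planted gene-level odds
#' ratios, and optional age-dependent somatic clones.
#'
#' An identical configuration (including `seed`) always regenerates a
#' bit-identical cohort.
#'
#' @param n_samples Number of samples (>= 2).
#' @param seed Integer random seed.
#' @param variant_specs Data frame with columns `gene`, `consequence`,
#'   `maf` (cohort simulation MAF in \[0, 0.5\]), and optionally
#'   `variant_id`, `chrom`, `pos`, `ref`, `alt`, `gnomad_maf`, `revel`,
#'   `mtr_intolerant`, `target_protein`, `beta` (planted effect of one
#'   alt allele on the NPX of `target_protein`).
#' @param protein_specs Data frame with columns `protein_id`, `gene`,
#'   `panel`, `sigma` (residual NPX standard deviation, > 0).
#' @param covariate_effects Named numeric vector of coefficients applied
#'   to every protein; names among `age`, `sex`, `age_sex`, `age2`,
#'   `age2_sex`, `pc1`..`pc4`, `bmi`, `pack_years`.
#' @param binary_specs Optional data frame with `phenotype_id`, `gene`,
#'   `odds_ratio`, `prevalence` (baseline, in (0, 1)).
#' @param somatic_specs Optional data frame with `gene`, `intercept`,
#'   `slope` (age logistic model of clone prevalence) and optionally
#'   `vaf_shape1`, `vaf_shape2` (Beta parameters of the clone VAF,
#'   truncated to (0, 0.5\]) and `effect` (call effect label).
#' @param missing_rate Genotype missingness rate (default 0; QC owns
#'   missingness handling downstream).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_samples, seed, variant_specs, protein_specs,
                       covariate_effects = c(age = 0.01, sex = 0.2),
                       binary_specs = NULL, somatic_specs = NULL,
                       missing_rate = 0) {
  stopifnot(is.numeric(n_samples), length(n_samples) == 1L)
  if (n_samples < 2) stop("n_samples must be >= 2")
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  stopifnot(is.data.frame(variant_specs), is.data.frame(protein_specs))

  vs <- variant_specs
  need_v <- c("gene", "consequence", "maf")
  if (!all(need_v %in% names(vs))) {
    stop("variant_specs needs columns: ", paste(need_v, collapse = ", "))
  }
  if (!"variant_id" %in% names(vs)) {
    vs$variant_id <- sprintf("v%03d", seq_len(nrow(vs)))
  }
  if (anyDuplicated(vs$variant_id)) stop("duplicated variant_id in variant_specs")
  if (!"chrom" %in% names(vs)) vs$chrom <- "chr1"
  if (!"pos" %in% names(vs)) vs$pos <- 10000L + 100L * seq_len(nrow(vs))
  if (!"ref" %in% names(vs)) vs$ref <- "A"
  if (!"alt" %in% names(vs)) vs$alt <- "T"
  if (!"gnomad_maf" %in% names(vs)) vs$gnomad_maf <- vs$maf
  if (!"revel" %in% names(vs)) vs$revel <- NA_real_
  if (!"mtr_intolerant" %in% names(vs)) vs$mtr_intolerant <- NA
  if (!"target_protein" %in% names(vs)) vs$target_protein <- NA_character_
  if (!"beta" %in% names(vs)) vs$beta <- 0
  vs$beta[is.na(vs$beta)] <- 0
  check_finite(vs$maf, "variant_specs$maf")
  check_finite(vs$beta, "variant_specs$beta")
  if (any(vs$maf < 0 | vs$maf > 0.5)) stop("maf must lie in [0, 0.5]")
  if (any(vs$gnomad_maf < 0 | vs$gnomad_maf > 0.5, na.rm = TRUE)) {
    stop("gnomad_maf must lie in [0, 0.5]")
  }

  ps <- protein_specs
  need_p <- c("protein_id", "gene", "panel", "sigma")
  if (!all(need_p %in% names(ps))) {
    stop("protein_specs needs columns: ", paste(need_p, collapse = ", "))
  }
  check_finite(ps$sigma, "protein_specs$sigma")
  if (any(ps$sigma <= 0)) stop("sigma must be > 0")
  planted <- !is.na(vs$target_protein) & vs$beta != 0
  if (any(!vs$target_protein[planted] %in% ps$protein_id)) {
    stop("target_protein refers to a protein absent from protein_specs")
  }

  if (length(covariate_effects)) {
    check_finite(covariate_effects, "covariate_effects")
    allowed <- c("age", "sex", "age_sex", "age2", "age2_sex",
                 paste0("pc", 1:4), "bmi", "pack_years")
    if (!all(names(covariate_effects) %in% allowed)) {
      stop("unknown covariate_effects name(s): ",
           paste(setdiff(names(covariate_effects), allowed), collapse = ", "))
    }
  }
  if (!is.null(binary_specs)) {
    stopifnot(is.data.frame(binary_specs))
    need_b <- c("phenotype_id", "gene", "odds_ratio", "prevalence")
    if (!all(need_b %in% names(binary_specs))) {
      stop("binary_specs needs columns: ", paste(need_b, collapse = ", "))
    }
    check_finite(binary_specs$odds_ratio, "binary_specs$odds_ratio")
    if (any(binary_specs$prevalence <= 0 | binary_specs$prevalence >= 1)) {
      stop("prevalence must lie in (0, 1)")
    }
  }
  if (!is.null(somatic_specs)) {
    stopifnot(is.data.frame(somatic_specs))
    need_s <- c("gene", "intercept", "slope")
    if (!all(need_s %in% names(somatic_specs))) {
      stop("somatic_specs needs columns: ", paste(need_s, collapse = ", "))
    }
    check_finite(somatic_specs$intercept, "somatic_specs$intercept")
    check_finite(somatic_specs$slope, "somatic_specs$slope")
    if (!"vaf_shape1" %in% names(somatic_specs)) somatic_specs$vaf_shape1 <- 2
    if (!"vaf_shape2" %in% names(somatic_specs)) somatic_specs$vaf_shape2 <- 8
    if (!"effect" %in% names(somatic_specs)) {
      somatic_specs$effect <- "frameshift_variant"
    }
  }
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must lie in [0, 1)")

  structure(list(n_samples = as.integer(n_samples), seed = as.integer(seed),
                 variant_specs = vs, protein_specs = ps,
                 covariate_effects = covariate_effects,
                 binary_specs = binary_specs, somatic_specs = somatic_specs,
                 missing_rate = missing_rate),
            class = "sim_config")
}

# Passing-by-construction site/genotype QC metrics attached to simulated
# variants; QC-focused tests perturb these columns directly.
default_qc_metrics <- function(n) {
  data.frame(
    coverage_depth = rep(50, n), gq = 99, fs = 0, mq = 60, qual = 1000,
    rprs = 0, mqrs = 0, dragen_pass = TRUE, het_alt_fraction = 0.5,
    hom_alt_fraction = 0.8, het_alt_reads = 25, het_total_reads = 50,
    site_missing_fraction = 0, site_fail_fraction = 0,
    gnomad_cov10_fraction = 1, gnomad_pass_fraction = 1,
    gnomad_exome_z = 0, gnomad_exome_mq = 60, in_ccds = TRUE
  )
}

#' Simulate a proteogenomic cohort
#'
#' Generates genotypes, annotations, covariates, an NPX-like protein
#' abundance matrix, optional binary phenotypes and somatic calls, and a
#' truth ledger of every planted effect.
#'
#' Genotypes are drawn independently per sample as `Binomial(2, MAF)`
#' (Hardy-Weinberg, no linkage disequilibrium). Covariates: age ~
#' Uniform(40, 70), sex Bernoulli(0.54 female), PCs standard normal,
#' batches 1-7 multinomial, broad ancestry labels (93% EUR), BMI,
#' pack-years, and one measurement-to-sampling time offset per panel.
#' Protein abundances follow the linear model
#' `NPX = sum_c gamma_c covariate_c + sum_v beta_v g_v + Normal(0, sigma^2)`
#' with Gaussian residuals.
#'
#' @param config A [sim_config()].
#' @return Object of class `synthetic_cohort`: a list with `samples`,
#'   `genotypes` (sample x variant dosage matrix, `NA` = missing),
#'   `variants` (annotation table including QC metric columns),
#'   `covariates`, `proteins`, `npx` (sample x protein), `gene_map`,
#'   `phenotypes`, `somatic`, `truth` and the `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_samples
  vs <- config$variant_specs
  ps <- config$protein_specs
  samples <- sprintf("S%05d", seq_len(n))

  covariates <- data.frame(
    sample_id = samples,
    age = stats::runif(n, 40, 70),
    sex = ifelse(stats::rbinom(n, 1, 0.54) == 1, "female", "male"),
    pc1 = stats::rnorm(n), pc2 = stats::rnorm(n),
    pc3 = stats::rnorm(n), pc4 = stats::rnorm(n),
    batch = paste0("b", sample.int(7, n, replace = TRUE)),
    ancestry = sample(c("EUR", "AFR", "EAS", "SAS"), n, replace = TRUE,
                      prob = c(0.93, 0.03, 0.02, 0.02)),
    bmi = stats::rnorm(n, 27, 4.5),
    pack_years = stats::rbinom(n, 1, 0.45) * stats::rgamma(n, 2, scale = 8),
    stringsAsFactors = FALSE
  )
  for (panel in unique(ps$panel)) {
    covariates[[paste0("sample_time_", panel)]] <- stats::rnorm(n)
  }

  true_geno <- vapply(vs$maf, function(m) stats::rbinom(n, 2, m),
                      numeric(n))
  dimnames(true_geno) <- list(samples, vs$variant_id)
  genotypes <- true_geno
  if (config$missing_rate > 0) {
    mask <- matrix(stats::runif(length(genotypes)) < config$missing_rate,
                   nrow = n)
    genotypes[mask] <- NA
  }

  variants <- data.frame(
    variant_id = vs$variant_id, gene = vs$gene, chrom = vs$chrom,
    pos = vs$pos, ref = vs$ref, alt = vs$alt,
    variant_type = ifelse(nchar(vs$ref) == nchar(vs$alt), "SNV", "indel"),
    consequence = vs$consequence,
    cohort_mac = colSums(genotypes, na.rm = TRUE),
    cohort_maf = colMeans(genotypes / 2, na.rm = TRUE),
    gnomad_maf = vs$gnomad_maf, revel = vs$revel,
    mtr_intolerant = vs$mtr_intolerant,
    stringsAsFactors = FALSE
  )
  variants <- cbind(variants, default_qc_metrics(nrow(vs)))
  rownames(variants) <- NULL

  # per-gene intervals covering that gene's variants (padded)
  gene_map <- do.call(rbind, lapply(split(variants, variants$gene), function(g) {
    data.frame(gene = g$gene[1], chrom = g$chrom[1],
               start = max(1L, min(g$pos) - 500L), end = max(g$pos) + 500L,
               stringsAsFactors = FALSE)
  }))
  rownames(gene_map) <- NULL

  ce <- config$covariate_effects
  sexn <- as.numeric(covariates$sex == "female")
  cov_cols <- cbind(age = covariates$age, sex = sexn,
                    age_sex = covariates$age * sexn, age2 = covariates$age^2,
                    age2_sex = covariates$age^2 * sexn,
                    pc1 = covariates$pc1, pc2 = covariates$pc2,
                    pc3 = covariates$pc3, pc4 = covariates$pc4,
                    bmi = covariates$bmi, pack_years = covariates$pack_years)
  cov_signal <- if (length(ce)) {
    as.numeric(cov_cols[, names(ce), drop = FALSE] %*% ce)
  } else {
    numeric(n)
  }

  npx <- matrix(NA_real_, n, nrow(ps), dimnames = list(samples, ps$protein_id))
  for (j in seq_len(nrow(ps))) {
    mu <- cov_signal
    hit <- which(vs$target_protein == ps$protein_id[j] & vs$beta != 0)
    for (v in hit) mu <- mu + vs$beta[v] * true_geno[, v]
    npx[, j] <- mu + stats::rnorm(n, 0, ps$sigma[j])
  }

  truth <- data.frame(type = character(0), unit = character(0),
                      target = character(0), value = numeric(0),
                      stringsAsFactors = FALSE)
  planted <- which(!is.na(vs$target_protein) & vs$beta != 0)
  if (length(planted)) {
    truth <- rbind(truth, data.frame(
      type = "pqtl", unit = vs$variant_id[planted],
      target = vs$target_protein[planted], value = vs$beta[planted],
      stringsAsFactors = FALSE))
  }
  if (length(ce)) {
    truth <- rbind(truth, data.frame(
      type = "covariate", unit = names(ce), target = "all",
      value = unname(ce), stringsAsFactors = FALSE))
  }

  cohort <- structure(
    list(samples = samples, genotypes = genotypes, variants = variants,
         covariates = covariates, proteins = ps, npx = npx,
         gene_map = gene_map, phenotypes = NULL, somatic = NULL,
         truth = truth, config = config),
    class = "synthetic_cohort"
  )

  if (!is.null(config$binary_specs)) {
    cohort$phenotypes <- simulate_binary_phenotypes(
      cohort, config$binary_specs, seed = config$seed + 1L)
    cohort$truth <- rbind(cohort$truth, data.frame(
      type = "binary", unit = config$binary_specs$gene,
      target = config$binary_specs$phenotype_id,
      value = log(config$binary_specs$odds_ratio), stringsAsFactors = FALSE))
  }
  if (!is.null(config$somatic_specs)) {
    cohort$somatic <- simulate_somatic_calls(
      cohort, config$somatic_specs, seed = config$seed + 2L)
    cohort$truth <- rbind(cohort$truth, data.frame(
      type = "somatic", unit = config$somatic_specs$gene, target = "age",
      value = config$somatic_specs$slope, stringsAsFactors = FALSE))
  }
  cohort
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort> ", length(x$samples), " samples, ",
      ncol(x$genotypes), " variants, ", ncol(x$npx), " proteins",
      if (!is.null(x$phenotypes)) paste0(", ", ncol(x$phenotypes) - 1L,
                                         " binary phenotypes"),
      if (!is.null(x$somatic)) paste0(", ", nrow(x$somatic),
                                      " somatic calls"),
      "\n", sep = "")
  invisible(x)
}

# dominant gene-level carrier indicator from raw dosages (NA contributes 0)
gene_carrier_indicator <- function(cohort, gene) {
  ids <- cohort$variants$variant_id[cohort$variants$gene == gene]
  if (!length(ids)) {
    return(structure(rep(FALSE, length(cohort$samples)),
                     names = cohort$samples))
  }
  g <- cohort$genotypes[, ids, drop = FALSE]
  rowSums(g >= 1, na.rm = TRUE) > 0
}

#' Simulate binary phenotypes with planted gene effects
#'
#' Case status is drawn `Bernoulli(p_i)` with
#' `logit(p_i) = logit(prevalence) + log(OR) * carrier_i`, where carriers
#' are samples with at least one alternate allele in that row's gene.
#'
#' @param cohort A `synthetic_cohort`.
#' @param specs Data frame with `phenotype_id`, `gene`, `odds_ratio`,
#'   `prevalence`.
#' @param seed Integer seed (defaults to the cohort seed + 1, which is
#'   what [simulate_cohort()] uses internally).
#' @return Data frame with `sample_id` and one 0/1 column per phenotype.
#' @export
simulate_binary_phenotypes <- function(cohort, specs,
                                       seed = cohort$config$seed + 1L) {
  stopifnot(inherits(cohort, "synthetic_cohort"), is.data.frame(specs))
  if (any(specs$prevalence <= 0 | specs$prevalence >= 1)) {
    stop("prevalence must lie in (0, 1)")
  }
  set.seed(seed)
  out <- data.frame(sample_id = cohort$samples, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(specs))) {
    carrier <- gene_carrier_indicator(cohort, specs$gene[i])
    eta <- stats::qlogis(specs$prevalence[i]) +
      log(specs$odds_ratio[i]) * as.numeric(carrier)
    out[[specs$phenotype_id[i]]] <- stats::rbinom(length(carrier), 1,
                                                  stats::plogis(eta))
  }
  out
}

#' Simulate somatic clone calls
#'
#' Clone carriage per gene follows a logistic model in age
#' (`logit(p) = intercept + slope * age`); carriers receive one call with
#' a VAF drawn from a Beta distribution truncated to (0, 0.5\] (default
#' Beta(2, 8), which straddles the usual 0.03-0.4 qualification window),
#' a Poisson total depth and a binomial alternate depth, and filter status
#' PASS.
#'
#' @param cohort A `synthetic_cohort`.
#' @param specs Data frame with `gene`, `intercept`, `slope`, optionally
#'   `vaf_shape1`, `vaf_shape2`, `effect`.
#' @param seed Integer seed (defaults to the cohort seed + 2).
#' @return Somatic call table: `sample_id`, `gene`, `effect`,
#'   `variant_id`, `vaf`, `alt_depth`, `depth`, `filter_status`.
#' @export
simulate_somatic_calls <- function(cohort, specs,
                                   seed = cohort$config$seed + 2L) {
  stopifnot(inherits(cohort, "synthetic_cohort"), is.data.frame(specs))
  if (!"vaf_shape1" %in% names(specs)) specs$vaf_shape1 <- 2
  if (!"vaf_shape2" %in% names(specs)) specs$vaf_shape2 <- 8
  if (!"effect" %in% names(specs)) specs$effect <- "frameshift_variant"
  set.seed(seed)
  age <- cohort$covariates$age
  rows <- list()
  for (i in seq_len(nrow(specs))) {
    p <- stats::plogis(specs$intercept[i] + specs$slope[i] * age)
    carrier <- stats::rbinom(length(age), 1, p) == 1
    idx <- which(carrier)
    if (!length(idx)) next
    # inverse-CDF draw from Beta truncated to (0, 0.5]
    hi <- stats::pbeta(0.5, specs$vaf_shape1[i], specs$vaf_shape2[i])
    u <- stats::runif(length(idx), 0, hi)
    vaf <- pmax(stats::qbeta(u, specs$vaf_shape1[i], specs$vaf_shape2[i]),
                1e-4)
    depth <- stats::rpois(length(idx), 60) + 10L
    alt <- pmax(stats::rbinom(length(idx), depth, vaf), 1L)
    rows[[i]] <- data.frame(
      sample_id = cohort$samples[idx], gene = specs$gene[i],
      effect = specs$effect[i],
      variant_id = paste0(specs$gene[i], ":som", seq_along(idx)),
      vaf = vaf, alt_depth = alt, depth = depth, filter_status = "PASS",
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(sample_id = character(0), gene = character(0),
                      effect = character(0), variant_id = character(0),
                      vaf = numeric(0), alt_depth = integer(0),
                      depth = integer(0), filter_status = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
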