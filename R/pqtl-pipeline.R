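# ExWAS and collapsing scans, cis/trans classification, n-of-1
# permutation calibration, direction-of-effect summaries.

assoc_table_class <- function(df) {
  class(df) <- c("assoc_table", "data.frame")
  df
}

unpack_cohort <- function(x) {
  if (inherits(x, "synthetic_cohort")) {
    list(genotypes = x$genotypes, npx = x$npx, variants = x$variants,
         covariates = x$covariates, proteins = x$proteins,
         gene_map = x$gene_map)
  } else {
    x
  }
}

#' Variant-level exome-wide association scan
#'
#' Tests every (variant, protein, genetic model) combination where the
#' variant is carried by at least `min_carriers` individuals, by ordinary
#' least squares of protein abundance on the encoded genotype with
#' ExWAS-flavour covariates (each protein's design includes its own
#' panel's sampling-time offset). Variants carried by fewer individuals
#' are excluded from all tests; combinations that are untestable (for
#' example a recessive encoding with no homozygotes) are flagged, not
#' silently dropped.
#'
#' Variants with complete genotypes are tested through a vectorised QR
#' kernel that is algebraically identical to per-test OLS; variants with
#' missing genotypes fall back to per-test complete-case fits.
#'
#' @param cohort A `synthetic_cohort`, or a list with elements
#'   `genotypes`, `npx`, `variants`, `covariates`, `proteins` and
#'   optionally `gene_map`.
#' @param genetic_models Subset of `"genotypic"`, `"dominant"`,
#'   `"recessive"`.
#' @param min_carriers Minimum number of individuals carrying the variant
#'   (default 4).
#' @param gene_map Optional gene interval table for cis/trans labelling
#'   (defaults to the cohort's, when present).
#' @return An association table (`data.frame`, class `assoc_table`) with
#'   one row per test: `variant_id`, `gene`, `protein`, `genetic_model`,
#'   `beta`, `se`, `ci_low`, `ci_high`, `p`, `n_used`, `n_carriers`,
#'   `cohort_maf`, `untestable`, and `cis_trans_label` when a gene map is
#'   available.
#' @export
run_exwas <- function(cohort,
                      genetic_models = c("genotypic", "dominant", "recessive"),
                      min_carriers = 4, gene_map = NULL) {
  parts <- unpack_cohort(cohort)
  genetic_models <- match.arg(genetic_models, several.ok = TRUE)
  genotypes <- parts$genotypes
  npx <- parts$npx
  variants <- parts$variants
  proteins <- parts$proteins
  if (is.null(gene_map)) gene_map <- parts$gene_map

  carried_by <- colSums(genotypes >= 1, na.rm = TRUE)
  eligible <- colnames(genotypes)[carried_by >= min_carriers]
  rows <- list()
  for (gm in genetic_models) {
    X_all <- apply(genotypes[, eligible, drop = FALSE], 2,
                   encode_genotype, model = gm)
    if (!is.matrix(X_all)) X_all <- matrix(X_all, nrow = nrow(genotypes),
                                           dimnames = list(rownames(genotypes), eligible))
    has_na <- colSums(is.na(X_all)) > 0
    for (panel in unique(proteins$panel)) {
      covs <- build_covariates(parts$covariates, "exwas", panel = panel)
      prot_ids <- proteins$protein_id[proteins$panel == panel]
      Y <- npx[, prot_ids, drop = FALSE]
      # fast path: complete variants in one QR kernel
      fast_ids <- eligible[!has_na]
      if (length(fast_ids)) {
        X <- X_all[, fast_ids, drop = FALSE]
        km <- assoc_matrix(Y, X, covs)
        tq <- stats::qt(0.975, km$df)
        for (j in seq_along(prot_ids)) {
          ok <- km$testable & !is.na(km$beta[, j])
          rows[[length(rows) + 1L]] <- data.frame(
            variant_id = fast_ids, genetic_model = gm,
            protein = prot_ids[j],
            beta = km$beta[, j], se = km$se[, j],
            ci_low = km$beta[, j] - tq * km$se[, j],
            ci_high = km$beta[, j] + tq * km$se[, j],
            p = km$p[, j], n_used = km$n,
            n_carriers = colSums(X > 0),
            untestable = !ok, stringsAsFactors = FALSE)
        }
      }
      # slow path: complete-case per-test fits for variants with missingness
      for (v in eligible[has_na]) {
        for (j in seq_along(prot_ids)) {
          r <- linear_assoc(Y[, j], X_all[, v], covs)
          rows[[length(rows) + 1L]] <- data.frame(
            variant_id = v, genetic_model = gm, protein = prot_ids[j],
            beta = r$beta, se = r$se, ci_low = r$ci_low,
            ci_high = r$ci_high, p = r$p, n_used = r$n_used,
            n_carriers = r$n_carriers, untestable = r$untestable,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    variant_id = character(0), genetic_model = character(0),
    protein = character(0), beta = numeric(0), se = numeric(0),
    ci_low = numeric(0), ci_high = numeric(0), p = numeric(0),
    n_used = integer(0), n_carriers = numeric(0), untestable = logical(0),
    stringsAsFactors = FALSE)
  vmeta <- variants[match(out$variant_id, variants$variant_id),
                    c("gene", "chrom", "pos", "cohort_maf", "consequence")]
  out <- data.frame(unit_type = rep("variant", nrow(out)), out, vmeta,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out <- out[order(out$variant_id, out$protein, out$genetic_model), ]
  if (!is.null(gene_map)) {
    out <- annotate_cis_trans(out, gene_map, proteins)
  }
  assoc_table_class(out)
}

#' Gene-level collapsing association scan
#'
#' Regresses each protein on each gene's qualifying-variant carrier
#' indicator with collapsing-flavour covariates, one row per (gene,
#' protein, model). Rows from a model named `"syn"` are marked as the
#' empirical negative control. Genes whose carrier indicator is constant
#' (for example zero carriers) are flagged untestable.
#'
#' @param cohort A `synthetic_cohort` or list as in [run_exwas()].
#' @param carrier_matrices A `carrier_matrix` or (named) list of them.
#' @param flavor Covariate flavour (default `"collapsing"`;
#'   `"pan_ancestry"` adds ancestry indicators, `"ch"` adds BMI and
#'   pack-years).
#' @param min_carriers Minimum carrier count to test a gene (default 1).
#' @param gene_map Optional gene intervals for cis/trans labelling.
#' @return Association table with `gene`, `protein`, `model`, `beta`,
#'   `se`, `ci_low`, `ci_high`, `p`, `n_used`, `n_carriers`,
#'   `untestable`, `empirical_null` and optional `cis_trans_label`.
#' @export
run_collapsing <- function(cohort, carrier_matrices,
                           flavor = c("collapsing", "pan_ancestry", "ch"),
                           min_carriers = 1, gene_map = NULL) {
  parts <- unpack_cohort(cohort)
  flavor <- match.arg(flavor)
  if (inherits(carrier_matrices, "carrier_matrix")) {
    carrier_matrices <- list(carrier_matrices)
  }
  npx <- parts$npx
  proteins <- parts$proteins
  if (is.null(gene_map)) gene_map <- parts$gene_map
  covs <- build_covariates(parts$covariates, flavor)

  rows <- list()
  for (cm in carrier_matrices) {
    stopifnot(inherits(cm, "carrier_matrix"))
    X_all <- t(cm$carriers) * 1  # sample x gene numeric
    X_all <- X_all[rownames(covs), , drop = FALSE]
    n_car <- colSums(X_all > 0, na.rm = TRUE)
    has_na <- colSums(is.na(X_all)) > 0
    genes <- colnames(X_all)
    fast <- genes[!has_na]
    if (length(fast)) {
      km <- assoc_matrix(npx, X_all[, fast, drop = FALSE], covs)
      tq <- stats::qt(0.975, km$df)
      for (j in seq_len(ncol(npx))) {
        rows[[length(rows) + 1L]] <- data.frame(
          gene = fast, protein = colnames(npx)[j], model = cm$model,
          beta = km$beta[, j], se = km$se[, j],
          ci_low = km$beta[, j] - tq * km$se[, j],
          ci_high = km$beta[, j] + tq * km$se[, j],
          p = km$p[, j], n_used = km$n, n_carriers = n_car[fast],
          untestable = !km$testable | n_car[fast] < min_carriers,
          stringsAsFactors = FALSE)
      }
    }
    for (g in genes[has_na]) {
      for (j in seq_len(ncol(npx))) {
        r <- linear_assoc(npx[, j], X_all[, g], covs)
        rows[[length(rows) + 1L]] <- data.frame(
          gene = g, protein = colnames(npx)[j], model = cm$model,
          beta = r$beta, se = r$se, ci_low = r$ci_low, ci_high = r$ci_high,
          p = r$p, n_used = r$n_used, n_carriers = r$n_carriers,
          untestable = r$untestable || r$n_carriers < min_carriers,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    rows <- list(data.frame(
      gene = character(0), protein = character(0), model = character(0),
      beta = numeric(0), se = numeric(0), ci_low = numeric(0),
      ci_high = numeric(0), p = numeric(0), n_used = integer(0),
      n_carriers = numeric(0), untestable = logical(0),
      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out$p[out$untestable] <- NA_real_
  out$empirical_null <- out$model == "syn"
  out <- data.frame(unit_type = rep("gene", nrow(out)), out,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out <- out[order(out$gene, out$protein, out$model), ]
  if (!is.null(gene_map)) out <- annotate_cis_trans(out, gene_map, proteins)
  assoc_table_class(out)
}

#' Classify a pQTL as cis-CDS, cis-position trans-CDS, or trans-CDS
#'
#' `cis-CDS` when the associated unit's gene is the gene encoding the
#' measured protein; `cis-position trans-CDS` when it is a different gene
#' but the unit lies within 1 Mb (inclusive) of the protein-coding gene's
#' interval on the same contig; `trans-CDS` otherwise (including
#' different contigs).
#'
#' @param unit_gene Gene symbol of the associated variant or gene unit.
#' @param unit_chrom,unit_pos Contig and 1-based position of the unit (for
#'   gene-level units pass any position inside the gene, or use
#'   [annotate_cis_trans()] which uses the gene's interval).
#' @param protein Protein id.
#' @param gene_map Data frame `gene`, `chrom`, `start`, `end` (1-based
#'   inclusive).
#' @param protein_map Data frame `protein_id`, `gene` mapping each
#'   measured protein to its encoding gene.
#' @param cis_window Distance cap in bp (default 1e6; exactly 1 Mb counts
#'   as within).
#' @return One of `"cis-CDS"`, `"cis-position trans-CDS"`, `"trans-CDS"`,
#'   or `NA` when the protein cannot be mapped.
#' @export
classify_cis_trans <- function(unit_gene, unit_chrom, unit_pos, protein,
                               gene_map, protein_map, cis_window = 1e6) {
  pg <- protein_map$gene[match(protein, protein_map$protein_id)]
  if (is.na(pg)) return(NA_character_)
  if (!is.na(unit_gene) && unit_gene == pg) return("cis-CDS")
  i <- match(pg, gene_map$gene)
  if (is.na(i)) return(NA_character_)
  if (is.na(unit_chrom) || unit_chrom != gene_map$chrom[i]) return("trans-CDS")
  gap <- max(0, gene_map$start[i] - max(unit_pos),
             min(unit_pos) - gene_map$end[i])
  if (gap <= cis_window) "cis-position trans-CDS" else "trans-CDS"
}

#' Annotate an association table with cis/trans labels
#'
#' Variant rows are classified from the variant position; gene rows from
#' the unit gene's interval (minimum gap between intervals).
#'
#' @param table Association table from [run_exwas()] or
#'   [run_collapsing()].
#' @param gene_map Gene interval table (`gene`, `chrom`, `start`, `end`).
#' @param protein_map Data frame with `protein_id` and encoding `gene`.
#' @param cis_window Distance cap in bp (default 1e6).
#' @return The table with a `cis_trans_label` column.
#' @export
annotate_cis_trans <- function(table, gene_map, protein_map,
                               cis_window = 1e6) {
  lab <- character(nrow(table))
  for (i in seq_len(nrow(table))) {
    if (identical(table$unit_type[i], "gene")) {
      gi <- match(table$gene[i], gene_map$gene)
      if (is.na(gi)) { lab[i] <- NA_character_; next }
      lab[i] <- classify_cis_trans(
        table$gene[i], gene_map$chrom[gi],
        c(gene_map$start[gi], gene_map$end[gi]),
        table$protein[i], gene_map, protein_map, cis_window)
    } else {
      lab[i] <- classify_cis_trans(
        table$gene[i], table$chrom[i], table$pos[i],
        table$protein[i], gene_map, protein_map, cis_window)
    }
  }
  table$cis_trans_label <- lab
  table
}

#' Permutation false-positive report
#'
#' Bookkeeping container for an n-of-1 permutation: the number of permuted
#' tests, the permuted hits at the significance threshold (the expected
#' number of false positives among the observed hits), and, when the
#' observed significant count is supplied, the expected false-positive
#' percentage `100 * hits / observed`.
#'
#' @param n_tests Number of permuted tests performed.
#' @param n_hits Permuted tests reaching the threshold.
#' @param threshold Significance threshold.
#' @param observed_significant Observed (unpermuted) significant count.
#' @return Object of class `permutation_report` with fields `n_tests`,
#'   `n_hits_at_threshold`, `threshold`, `expected_fp` and
#'   `fp_percent_of_observed`.
#' @export
permutation_report <- function(n_tests, n_hits, threshold = 1e-8,
                               observed_significant = NA) {
  stopifnot(n_hits <= n_tests)
  structure(list(
    n_tests = n_tests, n_hits_at_threshold = n_hits, threshold = threshold,
    expected_fp = n_hits,
    fp_percent_of_observed = if (is.na(observed_significant)) NA_real_
      else 100 * n_hits / observed_significant,
    observed_significant = observed_significant),
    class = "permutation_report")
}

#' @export
print.permutation_report <- function(x, ...) {
  cat("<permutation_report> ", format(x$n_hits_at_threshold), " of ",
      format(x$n_tests, big.mark = ","), " permuted tests at P <= ",
      format(x$threshold), sep = "")
  if (!is.na(x$fp_percent_of_observed)) {
    cat(sprintf(" (expected FP: %s of %s observed hits, %.3g%%)",
                format(x$expected_fp),
                format(x$observed_significant, big.mark = ","),
                x$fp_percent_of_observed))
  }
  cat("\n")
  invisible(x)
}

#' n-of-1 permutation calibration of a scan
#'
#' Permutes the sample axis of the genotype (or carrier) data once with a
#' single global permutation - preserving the phenotype-covariate pairing
#' and all per-variant allele counts - re-runs the scan, and counts
#' permuted hits at the significance threshold. The permuted hit count
#' estimates the expected number of false positives among the observed
#' significant associations.
#'
#' @param cohort A `synthetic_cohort` or parts list (see [run_exwas()]).
#' @param scan Function taking the (permuted) cohort and returning an
#'   association table with a `p` column. Defaults to [run_exwas()].
#' @param seed Integer seed for the permutation.
#' @param threshold Significance threshold (default 1e-8).
#' @param observed Observed significant count; computed by running `scan`
#'   on the unpermuted cohort when `NULL`.
#' @param ... Passed on to `scan`.
#' @return A [permutation_report()].
#' @export
n_of_one_permutation <- function(cohort, scan = run_exwas, seed = 1L,
                                 threshold = 1e-8, observed = NULL, ...) {
  parts <- unpack_cohort(cohort)
  if (is.null(observed)) {
    obs_tab <- scan(parts, ...)
    observed <- sum(obs_tab$p <= threshold, na.rm = TRUE)
  }
  set.seed(seed)
  perm <- sample.int(nrow(parts$genotypes))
  parts$genotypes <- parts$genotypes[perm, , drop = FALSE]
  rownames(parts$genotypes) <- rownames(parts$npx)
  tab <- scan(parts, ...)
  ok <- !is.na(tab$p)
  permutation_report(n_tests = sum(ok),
                     n_hits = sum(tab$p[ok] <= threshold),
                     threshold = threshold,
                     observed_significant = observed)
}

#' Direction-of-effect summary of an association table
#'
#' Per stratum (by default model x cis/trans label): the number of
#' associations, the fraction with negative effect size, and the median
#' absolute effect size. Empty strata are omitted.
#'
#' @param table Association table with a `beta` column.
#' @param by Character vector of stratifying columns present in `table`.
#' @param p_max Optional significance filter applied before summarising.
#' @return Data frame with the strata, `n`, `frac_beta_negative` and
#'   `median_abs_beta`.
#' @export
summarize_directions <- function(table,
                                 by = intersect(c("model", "genetic_model",
                                                  "cis_trans_label"),
                                                names(table)),
                                 p_max = NULL) {
  stopifnot(all(by %in% names(table)), "beta" %in% names(table))
  tab <- table[!is.na(table$beta), , drop = FALSE]
  if (!is.null(p_max)) tab <- tab[!is.na(tab$p) & tab$p <= p_max, , drop = FALSE]
  if (!nrow(tab)) stop("no associations left after filtering")
  key <- interaction(tab[by], drop = TRUE, sep = "\r")
  parts <- split(tab, key)
  out <- do.call(rbind, lapply(parts, function(s) {
    cbind(s[1, by, drop = FALSE],
          data.frame(n = nrow(s),
                     frac_beta_negative = mean(s$beta < 0),
                     median_abs_beta = stats::median(abs(s$beta))))
  }))
  rownames(out) <- NULL
  out
}
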