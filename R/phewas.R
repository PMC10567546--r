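# pQTL-informed collapsing models and the phenome-wide association scan.

#' Select protein-lowering missense pQTLs from an ExWAS table
#'
#' Filters a variant-level association table to missense-class, cis-CDS
#' associations with negative effect size and P below the selection
#' threshold - the variants used to augment the PTV collapsing model.
#' When the same variant is significant for several proteins or genetic
#' models, the most significant row is retained. The selection is a pure
#' filter: re-applying it to its own output changes nothing.
#'
#' @param exwas_table Association table from [run_exwas()] with
#'   `cis_trans_label` and `consequence` columns.
#' @param p_max Selection P threshold (default 1e-4).
#' @return Object of class `pqtl_missense_set`: a data frame with
#'   `variant_id`, `beta`, `p`, `cohort_maf`, with the thresholds used as
#'   attributes.
#' @export
select_protein_lowering_missense <- function(exwas_table, p_max = 1e-4) {
  need <- c("variant_id", "beta", "p", "cohort_maf", "cis_trans_label",
            "consequence")
  missing_cols <- setdiff(need, names(exwas_table))
  if (length(missing_cols)) {
    stop("ExWAS table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  tab <- exwas_table
  keep <- !is.na(tab$p) & !is.na(tab$beta) &
    is_consequence_class(tab$consequence, "missense") &
    !is.na(tab$cis_trans_label) & tab$cis_trans_label == "cis-CDS" &
    tab$beta < 0 & tab$p < p_max
  tab <- tab[keep, , drop = FALSE]
  tab <- tab[order(tab$p), , drop = FALSE]
  tab <- tab[!duplicated(tab$variant_id), , drop = FALSE]
  out <- data.frame(variant_id = tab$variant_id, beta = tab$beta, p = tab$p,
                    cohort_maf = tab$cohort_maf, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "p_max") <- p_max
  class(out) <- c("pqtl_missense_set", "data.frame")
  out
}

#' Build the pQTL-augmented collapsing models
#'
#' `ptvolink` extends the baseline PTV model with the selected
#' protein-lowering missense pQTLs subject to the PTV model's own cohort
#' MAF cap; `ptvolink2pcnt` relaxes the allow-listed missense cap to 2%.
#' By union construction, per-gene qualifying-variant sets (and hence
#' carrier sets) satisfy `ptv <= ptvolink <= ptvolink2pcnt`.
#'
#' @param base_ptv The baseline dominant PTV [qv_model()].
#' @param pqtl_set A [select_protein_lowering_missense()] result (or a
#'   character vector of variant ids).
#' @param relaxed_cap Cohort MAF cap for the relaxed model (default 0.02).
#' @return Named list with elements `ptvolink` and `ptvolink2pcnt`.
#' @export
build_augmented_models <- function(base_ptv, pqtl_set, relaxed_cap = 0.02) {
  stopifnot(inherits(base_ptv, "qv_model"))
  if (base_ptv$zygosity != "dominant") {
    stop("the base PTV model must be dominant")
  }
  ids <- if (is.character(pqtl_set)) pqtl_set else pqtl_set$variant_id
  ptvolink <- base_ptv
  ptvolink$name <- "ptvolink"
  ptvolink$extra_variant_ids <- ids
  ptvolink$extra_maf_max <- base_ptv$cohort_maf_max
  ptvolink$provenance <- "baseline ptv plus protein-lowering missense pQTLs at the ptv MAF cap"
  ptvolink2 <- ptvolink
  ptvolink2$name <- "ptvolink2pcnt"
  ptvolink2$extra_maf_max <- relaxed_cap
  ptvolink2$provenance <- "ptvolink with the allow-listed missense MAF cap relaxed to 2%"
  list(ptvolink = ptvolink, ptvolink2pcnt = ptvolink2)
}

#' Sex-match controls to cases
#'
#' Controls are used unchanged when the female fraction among cases does
#' not differ from that among controls (two-sided Fisher P >= 0.05).
#' Otherwise controls of the over-represented sex are removed in seeded
#' random batches until the difference is no longer significant. Cases
#' are never altered. Sex-specific traits (all cases one sex) yield
#' same-sex controls only.
#'
#' @param case_sex Character vector (`"female"`/`"male"`) for cases.
#' @param control_sex Named character vector for controls (names = sample
#'   ids).
#' @param seed Integer seed for the down-sampling.
#' @param alpha Significance gate (default 0.05).
#' @return Character vector of retained control ids; attribute
#'   `"untestable"` is `TRUE` when no matching is possible.
#' @export
match_controls_by_sex <- function(case_sex, control_sex, seed = 1L,
                                  alpha = 0.05) {
  stopifnot(!is.null(names(control_sex)))
  out_attr <- function(ids, untestable = FALSE) {
    attr(ids, "untestable") <- untestable
    ids
  }
  if (length(unique(case_sex)) == 1L) {
    same <- names(control_sex)[control_sex == case_sex[1]]
    return(out_attr(same, untestable = length(same) == 0L))
  }
  kept <- names(control_sex)
  set.seed(seed)
  repeat {
    cs <- control_sex[kept]
    tab <- matrix(c(sum(case_sex == "female"), sum(case_sex == "male"),
                    sum(cs == "female"), sum(cs == "male")), nrow = 2)
    if (any(rowSums(tab) == 0)) break
    if (stats::fisher.test(tab)$p.value >= alpha) return(out_attr(kept))
    over <- if (mean(cs == "female") > mean(case_sex == "female")) "female"
            else "male"
    pool <- kept[control_sex[kept] == over]
    if (!length(pool)) break
    drop_n <- max(1L, ceiling(0.02 * length(kept)))
    drop_ids <- sample(pool, min(drop_n, length(pool)))
    kept <- setdiff(kept, drop_ids)
    if (!length(kept)) break
  }
  out_attr(kept, untestable = length(kept) == 0L)
}

#' Phenome-wide association scan over collapsing models
#'
#' Binary traits are tested by two-sided Fisher's exact test of carrier
#' status against case status after sex-matching controls; traits with
#' fewer than `min_cases` cases are skipped (recorded in the
#' `"skipped_phenotypes"` attribute). Quantitative traits are tested by
#' linear regression with collapsing-flavour covariates.
#'
#' @param cohort A `synthetic_cohort` or parts list (needs `covariates`;
#'   `npx`/`proteins` are not used here).
#' @param models Named list of `carrier_matrix` objects (one per
#'   collapsing model).
#' @param binary_phenos Data frame: `sample_id` plus one 0/1 column per
#'   binary phenotype (`NA` = unknown).
#' @param quantitative_phenos Optional data frame: `sample_id` plus one
#'   numeric column per trait.
#' @param min_cases Minimum case count for a binary trait (default 30).
#' @param seed Seed for sex-matching down-sampling.
#' @return Data frame with `gene`, `phenotype`, `model`, `type`,
#'   `estimate` (odds ratio or beta), `ci_low`, `ci_high`, `p`,
#'   `n_cases`, `n_controls`, `n_carriers`, `untestable`.
#' @export
run_phewas <- function(cohort, models, binary_phenos = NULL,
                       quantitative_phenos = NULL, min_cases = 30,
                       seed = 1L) {
  parts <- unpack_cohort(cohort)
  covariates <- parts$covariates
  sex <- structure(covariates$sex, names = covariates$sample_id)
  rows <- list()
  skipped <- character(0)

  if (!is.null(binary_phenos)) {
    phen_ids <- setdiff(names(binary_phenos), "sample_id")
    for (ph in phen_ids) {
      y <- structure(binary_phenos[[ph]], names = binary_phenos$sample_id)
      y <- y[!is.na(y)]
      case_ids <- names(y)[y == 1]
      control_ids <- names(y)[y == 0]
      if (length(case_ids) < min_cases) {
        skipped <- c(skipped, ph)
        next
      }
      matched <- match_controls_by_sex(sex[case_ids], sex[control_ids],
                                       seed = seed)
      use <- c(case_ids, matched)
      for (mname in names(models)) {
        cm <- models[[mname]]
        for (g in rownames(cm$carriers)) {
          carrier <- cm$carriers[g, use]
          case <- use %in% case_ids
          r <- fisher_binary_assoc(carrier, case)
          rows[[length(rows) + 1L]] <- data.frame(
            gene = g, phenotype = ph, model = mname, type = "binary",
            estimate = r$odds_ratio, ci_low = r$ci_low, ci_high = r$ci_high,
            p = r$p, n_cases = length(case_ids), n_controls = length(matched),
            n_carriers = sum(carrier, na.rm = TRUE),
            untestable = r$untestable, stringsAsFactors = FALSE)
        }
      }
    }
  }

  if (!is.null(quantitative_phenos)) {
    covs <- build_covariates(covariates, "collapsing")
    phen_ids <- setdiff(names(quantitative_phenos), "sample_id")
    for (ph in phen_ids) {
      y <- structure(quantitative_phenos[[ph]],
                     names = quantitative_phenos$sample_id)
      y <- y[rownames(covs)]
      for (mname in names(models)) {
        cm <- models[[mname]]
        for (g in rownames(cm$carriers)) {
          x <- as.numeric(cm$carriers[g, rownames(covs)])
          r <- linear_assoc(y, x, covs)
          rows[[length(rows) + 1L]] <- data.frame(
            gene = g, phenotype = ph, model = mname, type = "quantitative",
            estimate = r$beta, ci_low = r$ci_low, ci_high = r$ci_high,
            p = r$p, n_cases = NA_integer_, n_controls = NA_integer_,
            n_carriers = r$n_carriers, untestable = r$untestable,
            stringsAsFactors = FALSE)
        }
      }
    }
  }

  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    gene = character(0), phenotype = character(0), model = character(0),
    type = character(0), estimate = numeric(0), ci_low = numeric(0),
    ci_high = numeric(0), p = numeric(0), n_cases = integer(0),
    n_controls = integer(0), n_carriers = integer(0),
    untestable = logical(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out <- out[order(out$gene, out$phenotype, out$model), ]
  attr(out, "skipped_phenotypes") <- skipped
  out
}

#' Remove overlap samples from a cohort
#'
#' Drops the given sample ids from every sample-indexed component of a
#' cohort (genotypes, covariates, NPX, phenotypes, somatic calls) and
#' recomputes cohort allele counts and frequencies on the remaining
#' samples. Used to re-run a PheWAS without the proteomics discovery
#' samples; results carry the conventional `-noppp` label.
#'
#' @param cohort A `synthetic_cohort`.
#' @param sample_ids Ids to remove (intersection with the cohort is
#'   removed; a disjoint set leaves the cohort unchanged).
#' @return The reduced cohort, with attribute `"label"` set to
#'   `"-noppp"`.
#' @export
exclude_overlap_samples <- function(cohort, sample_ids) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  keep <- !(cohort$samples %in% sample_ids)
  kept <- cohort$samples[keep]
  cohort$samples <- kept
  cohort$genotypes <- cohort$genotypes[kept, , drop = FALSE]
  cohort$covariates <- cohort$covariates[
    match(kept, cohort$covariates$sample_id), , drop = FALSE]
  cohort$npx <- cohort$npx[kept, , drop = FALSE]
  if (!is.null(cohort$phenotypes)) {
    cohort$phenotypes <- cohort$phenotypes[
      match(kept, cohort$phenotypes$sample_id), , drop = FALSE]
  }
  if (!is.null(cohort$somatic)) {
    cohort$somatic <- cohort$somatic[cohort$somatic$sample_id %in% kept, ,
                                     drop = FALSE]
  }
  cohort$variants$cohort_mac <- colSums(cohort$genotypes, na.rm = TRUE)
  cohort$variants$cohort_maf <- colMeans(cohort$genotypes / 2, na.rm = TRUE)
  attr(cohort, "label") <- "-noppp"
  cohort
}
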