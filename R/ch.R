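# Clonal haematopoiesis (CH): somatic-call qualification, VAF-threshold
# carrier matrices, age-prevalence validation, proteomic collapsing.

#' Default clonal-haematopoiesis gene rules
#'
#' Qualification rules for the 15 analysis genes: the somatic variant
#' effects admitted per gene and, for hotspot-driven genes, explicit
#' hotspot variant ids. Truncating effects are admitted for the
#' loss-of-function drivers (for example TET2, ASXL1); splicing-factor
#' and kinase drivers qualify through hotspot missense. These per-gene
#' lists follow CH literature conventions and are package defaults
#' (provenance: chosen), editable by passing your own rule list.
#'
#' @return Named list of rules; each rule has `gene`, `effects` (allowed
#'   SnpEff-style effect labels) and `hotspots` (allowed variant ids).
#' @export
default_ch_rules <- function() {
  ptv_eff <- c("frameshift_variant", "stop_gained", "splice_acceptor_variant",
               "splice_donor_variant", "start_lost")
  rule <- function(gene, effects = character(0), hotspots = character(0)) {
    list(gene = gene, effects = effects, hotspots = hotspots)
  }
  rules <- list(
    rule("DNMT3A", c(ptv_eff, "missense_variant")),
    rule("TET2", ptv_eff),
    rule("ASXL1", ptv_eff),
    rule("PPM1D", ptv_eff),
    rule("TP53", c(ptv_eff, "missense_variant")),
    rule("JAK2", hotspots = "JAK2:V617F"),
    rule("SF3B1", hotspots = c("SF3B1:K700E", "SF3B1:K666N")),
    rule("SRSF2", hotspots = c("SRSF2:P95H", "SRSF2:P95L", "SRSF2:P95R")),
    rule("IDH1", hotspots = c("IDH1:R132H", "IDH1:R132C")),
    rule("IDH2", hotspots = c("IDH2:R140Q", "IDH2:R172K")),
    rule("U2AF1", hotspots = c("U2AF1:S34F", "U2AF1:Q157P")),
    rule("CBL", c("missense_variant")),
    rule("GNB1", hotspots = "GNB1:K57E"),
    rule("MPL", hotspots = c("MPL:W515L", "MPL:W515K")),
    rule("CALR", c("frameshift_variant"))
  )
  names(rules) <- vapply(rules, `[[`, character(1), "gene")
  rules
}

#' Qualify somatic calls as clonal-haematopoiesis events
#'
#' Keeps calls that pass the somatic caller's filter, have a variant
#' allele fraction within `[vaf_min, vaf_max]`, an alternate allelic depth
#' of at least `ad_min`, and match the gene's rule (an allowed effect
#' label or an allow-listed hotspot variant id). Calls in genes without a
#' rule are dropped and recorded in the `"dropped_genes"` attribute.
#' The operation is idempotent and order-invariant.
#'
#' @param calls Somatic call table: `sample_id`, `gene`, `effect`,
#'   `variant_id`, `vaf`, `alt_depth`, `filter_status`.
#' @param rules Rule list as from [default_ch_rules()].
#' @param vaf_min,vaf_max VAF window (defaults 0.03 and 0.4, inclusive).
#' @param ad_min Minimum alternate allelic depth (default 3).
#' @return The qualifying subset of `calls`.
#' @export
qualify_ch_calls <- function(calls, rules = default_ch_rules(),
                             vaf_min = 0.03, vaf_max = 0.4, ad_min = 3) {
  stopifnot(is.data.frame(calls))
  need <- c("sample_id", "gene", "effect", "variant_id", "vaf",
            "alt_depth", "filter_status")
  missing_cols <- setdiff(need, names(calls))
  if (length(missing_cols)) {
    stop("somatic call table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  known <- calls$gene %in% names(rules)
  dropped <- sort(unique(calls$gene[!known]))
  calls <- calls[known, , drop = FALSE]
  keep <- calls$filter_status == "PASS" &
    calls$vaf >= vaf_min & calls$vaf <= vaf_max &
    calls$alt_depth >= ad_min
  rule_ok <- vapply(seq_len(nrow(calls)), function(i) {
    r <- rules[[calls$gene[i]]]
    calls$effect[i] %in% r$effects || calls$variant_id[i] %in% r$hotspots
  }, logical(1))
  out <- calls[keep & rule_ok, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped_genes") <- dropped
  out
}

#' Carrier matrices at a ladder of VAF cut-offs
#'
#' For each cut-off `c`, a sample carries a gene when it has a qualifying
#' event in that gene with VAF >= `c`. Carrier sets are therefore nested:
#' raising the cut-off never adds carriers.
#'
#' @param events Qualified event table from [qualify_ch_calls()].
#' @param samples Character vector of all sample ids (carriers are a
#'   subset).
#' @param vaf_cutoffs Numeric cut-offs; the default ladder
#'   `c(0.03, 0.05, 0.10, 0.20)` is a package default (provenance:
#'   chosen).
#' @param genes Genes to include (default: all genes present in
#'   `events`).
#' @return Named list (`"vaf>=0.03"`, ...) of `carrier_matrix` objects.
#' @export
ch_carrier_matrix <- function(events, samples,
                              vaf_cutoffs = c(0.03, 0.05, 0.10, 0.20),
                              genes = sort(unique(events$gene))) {
  out <- lapply(vaf_cutoffs, function(cut) {
    carriers <- matrix(FALSE, length(genes), length(samples),
                       dimnames = list(genes, samples))
    ev <- events[events$vaf >= cut, , drop = FALSE]
    for (i in seq_len(nrow(ev))) {
      if (ev$gene[i] %in% genes && ev$sample_id[i] %in% samples) {
        carriers[ev$gene[i], ev$sample_id[i]] <- TRUE
      }
    }
    carrier_matrix(carriers, qv_sets = split(events$variant_id, events$gene),
                   model = sprintf("ch_vaf%g", cut), zygosity = "dominant")
  })
  names(out) <- sprintf("vaf>=%g", vaf_cutoffs)
  out
}

#' Age-prevalence profile of clonal-haematopoiesis carriers
#'
#' Somatic (rather than inherited) variation is expected to rise in
#' prevalence with age. Returns carrier prevalence per age decade and a
#' logistic-regression slope of carrier status on age, with the flag
#' `somatic_consistent = (slope > 0 and P < 0.05)`. With fewer than two
#' populated age strata the profile is returned but the flag is `NA`.
#'
#' @param carriers Logical carrier indicator per sample.
#' @param ages Ages in years, aligned to `carriers`.
#' @return List with `profile` (decade, n, carriers, prevalence),
#'   `slope`, `p`, `somatic_consistent`.
#' @export
age_prevalence_profile <- function(carriers, ages) {
  stopifnot(length(carriers) == length(ages))
  keep <- !is.na(carriers) & !is.na(ages)
  carriers <- as.logical(carriers[keep]); ages <- ages[keep]
  decade <- 10 * floor(ages / 10)
  profile <- do.call(rbind, lapply(split(seq_along(ages), decade), function(i) {
    data.frame(decade = decade[i[1]], n = length(i),
               carriers = sum(carriers[i]), prevalence = mean(carriers[i]))
  }))
  rownames(profile) <- NULL
  res <- list(profile = profile, slope = NA_real_, p = NA_real_,
              somatic_consistent = NA)
  if (nrow(profile) < 2 || sum(carriers) == 0 || all(carriers)) return(res)
  fit <- stats::glm(carriers ~ ages, family = stats::binomial())
  sm <- summary(fit)$coefficients
  res$slope <- sm["ages", "Estimate"]
  res$p <- sm["ages", "Pr(>|z|)"]
  res$somatic_consistent <- res$slope > 0 && res$p < 0.05
  res
}

#' Proteomic collapsing analysis of clonal haematopoiesis
#'
#' Regresses each protein on each gene's CH carrier status with the CH
#' covariate flavour (age terms, PCs, batch, BMI, pack-years), after
#' removing samples on the exclusion list (for example, individuals with
#' a haematological malignancy predating sampling). Gene-level rows are
#' cis/trans-labelled when a gene map covering the CH genes is supplied.
#'
#' @param cohort A `synthetic_cohort` or parts list (see [run_exwas()]).
#' @param ch_carriers A `carrier_matrix` or list of them (one per VAF
#'   cut-off, as from [ch_carrier_matrix()]).
#' @param exclusions Character vector of sample ids to exclude (possibly
#'   empty).
#' @param gene_map Optional gene intervals (CH genes + protein genes).
#' @param min_carriers Minimum carriers to test (default 1).
#' @return Association table as from [run_collapsing()].
#' @export
run_ch_collapsing <- function(cohort, ch_carriers, exclusions = character(0),
                              gene_map = NULL, min_carriers = 1) {
  parts <- unpack_cohort(cohort)
  keep <- !(parts$covariates$sample_id %in% exclusions)
  kept_ids <- parts$covariates$sample_id[keep]
  parts$covariates <- parts$covariates[keep, , drop = FALSE]
  parts$npx <- parts$npx[kept_ids, , drop = FALSE]
  if (inherits(ch_carriers, "carrier_matrix")) ch_carriers <- list(ch_carriers)
  ch_carriers <- lapply(ch_carriers, function(cm) {
    cm$carriers <- cm$carriers[, kept_ids, drop = FALSE]
    cm
  })
  run_collapsing(parts, ch_carriers, flavor = "ch",
                 min_carriers = min_carriers, gene_map = gene_map)
}
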