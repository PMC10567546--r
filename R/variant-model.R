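# Consequence vocabulary, per-variant QC cascades and the NMD-escape rule.

#' SnpEff consequence terms defining each consequence class
#'
#' Verbatim term lists used to map SnpEff annotations onto the four
#' consequence classes used throughout the package: protein-truncating
#' variants (PTV), missense, non-synonymous (a superset of PTV and
#' missense that adds in-frame indels and `protein_altering_variant`) and
#' synonymous.
#'
#' @format A named list of character vectors with elements `PTV`,
#'   `missense`, `nonsynonymous` and `synonymous`.
#' @export
consequence_terms <- list(
  PTV = c(
    "exon_loss_variant", "frameshift_variant", "start_lost", "stop_gained",
    "stop_lost", "splice_acceptor_variant", "splice_donor_variant",
    "gene_fusion", "bidirectional_gene_fusion", "rare_amino_acid_variant",
    "transcript_ablation"
  ),
  missense = c("missense_variant_splice_region_variant", "missense_variant"),
  nonsynonymous = c(
    "exon_loss_variant", "frameshift_variant", "start_lost", "stop_gained",
    "stop_lost", "splice_acceptor_variant", "splice_donor_variant",
    "gene_fusion", "bidirectional_gene_fusion", "rare_amino_acid_variant",
    "transcript_ablation", "conservative_inframe_deletion",
    "conservative_inframe_insertion", "disruptive_inframe_insertion",
    "disruptive_inframe_deletion", "missense_variant_splice_region_variant",
    "missense_variant", "protein_altering_variant"
  ),
  synonymous = "synonymous_variant"
)

#' Classify a SnpEff consequence term
#'
#' Maps one or more SnpEff consequence terms onto the package's consequence
#' classes. A term can belong to several classes (every PTV and missense
#' term is also non-synonymous). Unknown terms classify as `"other"` rather
#' than erroring, so upstream annotation vocabularies that drift do not
#' break a scan.
#'
#' @param term Character vector of SnpEff consequence terms.
#' @return For a single term, a character vector of classes; for several
#'   terms, a list of such vectors.
#' @examples
#' classify_consequence("stop_gained")         # PTV, nonsynonymous
#' classify_consequence("synonymous_variant")  # synonymous
#' @export
classify_consequence <- function(term) {
  stopifnot(is.character(term), all(nzchar(term)))
  one <- function(tm) {
    cls <- names(consequence_terms)[vapply(consequence_terms,
                                           function(v) tm %in% v, logical(1))]
    if (length(cls) == 0L) "other" else cls
  }
  if (length(term) == 1L) one(term) else lapply(term, one)
}

#' Test membership of consequence terms in a consequence class
#'
#' @param term Character vector of SnpEff terms.
#' @param class One of `"PTV"`, `"missense"`, `"nonsynonymous"`,
#'   `"synonymous"`.
#' @return Logical vector.
#' @export
is_consequence_class <- function(term, class) {
  class <- match.arg(class, names(consequence_terms))
  term %in% consequence_terms[[class]]
}

#' Exact binomial test for heterozygous allele-balance departure
#'
#' Two-sided exact binomial test of the alternate-read proportion among
#' heterozygous genotypes against the expected 0.5. Used by both QC
#' cascades, which fail a variant when this P-value drops to 1e-6 or
#' below.
#'
#' @param alt_reads Alternate-supporting read count (non-negative integer).
#' @param total_reads Total read count (positive integer).
#' @return Two-sided P-value.
#' @examples
#' het_ab_departure_test(5, 10)   # 1
#' het_ab_departure_test(0, 20)   # 2 * 0.5^20
#' @export
het_ab_departure_test <- function(alt_reads, total_reads) {
  stopifnot(length(alt_reads) == 1L, length(total_reads) == 1L)
  if (!is.finite(total_reads) || total_reads < 1) {
    stop("total_reads must be >= 1")
  }
  if (!is.finite(alt_reads) || alt_reads < 0 || alt_reads > total_reads) {
    stop("alt_reads must lie in [0, total_reads]")
  }
  stats::binom.test(round(alt_reads), round(total_reads), p = 0.5)$p.value
}

# Columns each cascade needs. `het_alt_reads`/`het_total_reads` summarise the
# pooled read support over heterozygous genotype calls and feed the exact
# allele-balance test; a variant with no het genotypes carries 0 total reads
# and the criterion is vacuously satisfied.
qc_common_cols <- c(
  "variant_type", "coverage_depth", "gq", "fs", "mq", "qual", "rprs", "mqrs",
  "dragen_pass", "het_alt_fraction", "het_alt_reads", "het_total_reads",
  "gnomad_maf", "gnomad_cov10_fraction"
)
qc_exwas_cols <- c(qc_common_cols, "site_missing_fraction",
                   "site_fail_fraction", "gnomad_pass_fraction")
qc_collapsing_cols <- c(qc_common_cols, "in_ccds", "hom_alt_fraction",
                        "gnomad_exome_z", "gnomad_exome_mq")

qc_eval <- function(variants, cols, checks) {
  stopifnot(is.data.frame(variants))
  missing_cols <- setdiff(cols, names(variants))
  if (length(missing_cols)) {
    stop("missing QC columns: ", paste(missing_cols, collapse = ", "))
  }
  n <- nrow(variants)
  reasons <- vector("list", n)
  for (i in seq_len(n)) {
    v <- variants[i, ]
    bad <- character(0)
    for (nm in names(checks)) {
      val <- checks[[nm]](v)
      if (is.na(val)) bad <- c(bad, paste0("missing-metric:", nm))
      else if (!val) bad <- c(bad, nm)
    }
    reasons[[i]] <- bad
  }
  data.frame(
    variant_id = if ("variant_id" %in% names(variants)) variants$variant_id
                 else as.character(seq_len(n)),
    pass = lengths(reasons) == 0L,
    reasons = vapply(reasons, paste, character(1), collapse = ";"),
    stringsAsFactors = FALSE
  )
}

het_ab_ok <- function(v) {
  if (is.na(v$het_total_reads) || is.na(v$het_alt_reads)) return(NA)
  if (v$het_total_reads < 1) return(TRUE)  # no het genotypes to test
  het_ab_departure_test(v$het_alt_reads, v$het_total_reads) > 1e-6
}

fs_ok <- function(v) {
  if (is.na(v$fs) || is.na(v$variant_type)) return(NA)
  if (v$variant_type == "indel") v$fs <= 200 else v$fs <= 60
}

gnomad_observed <- function(v) !is.na(v$gnomad_maf) && v$gnomad_maf > 0

#' Variant-level quality control for the ExWAS
#'
#' Applies the variant-level QC cascade used ahead of the variant-level
#' association scan. All threshold comparisons are inclusive exactly as
#' written (`>=`, `<=`, `>`, `<`); boundary values pass. A metric that is
#' `NA` fails with reason `missing-metric:<name>`.
#'
#' Criteria: coverage depth >= 10; het alternate-read fraction >= 0.2;
#' het allele-balance binomial P > 1e-6; GQ >= 20; FS <= 200 (indel) /
#' <= 60 (SNV); MQ >= 40; QUAL >= 30; RPRS >= -2; MQRS >= -8; caller PASS;
#' site missingness < 0.10; site QC-failure fraction < 0.05; gnomAD 10x
#' coverage fraction >= 0.30; and, when the variant is observed in gnomAD,
#' gnomAD pass fraction (AC/AC_raw) >= 0.50.
#'
#' @param variants Data frame of variant annotations (see
#'   [annotation_schema()]).
#' @return Data frame with columns `variant_id`, `pass` and a
#'   semicolon-separated `reasons` string listing every violated criterion.
#' @seealso [collapsing_variant_qc()] for the stricter collapsing cascade.
#' @export
exwas_variant_qc <- function(variants) {
  qc_eval(variants, qc_exwas_cols, list(
    depth = function(v) v$coverage_depth >= 10,
    het_ab = function(v) v$het_alt_fraction >= 0.2,
    het_binom = het_ab_ok,
    GQ = function(v) v$gq >= 20,
    FS = fs_ok,
    MQ = function(v) v$mq >= 40,
    QUAL = function(v) v$qual >= 30,
    RPRS = function(v) v$rprs >= -2,
    MQRS = function(v) v$mqrs >= -8,
    caller_pass = function(v) isTRUE(as.logical(v$dragen_pass)),
    site_missing = function(v) v$site_missing_fraction < 0.10,
    site_fail = function(v) v$site_fail_fraction < 0.05,
    gnomad_cov10 = function(v) v$gnomad_cov10_fraction >= 0.30,
    gnomad_pass = function(v) {
      if (!gnomad_observed(v)) return(TRUE)
      v$gnomad_pass_fraction >= 0.50
    }
  ))
}

#' Variant-level quality control for collapsing analysis
#'
#' The stricter cascade applied to candidate qualifying variants before
#' gene-level collapsing: coverage depth >= 10; CCDS transcript annotation;
#' hom alternate-read fraction <= 0.80; het alternate-read fraction in
#' \[0.25, 0.80\]; het allele-balance binomial P > 1e-6; GQ >= 20; FS <= 200
#' (indel) / <= 60 (SNV); MQ >= 40; QUAL >= 30; RPRS >= -2; MQRS >= -8;
#' caller PASS; gnomAD 10x coverage fraction >= 0.25; and, when observed in
#' gnomAD, gnomAD exome z-score >= -2.0 and exome MQ >= 30.
#'
#' @inheritParams exwas_variant_qc
#' @return Data frame with `variant_id`, `pass`, `reasons`.
#' @export
collapsing_variant_qc <- function(variants) {
  qc_eval(variants, qc_collapsing_cols, list(
    depth = function(v) v$coverage_depth >= 10,
    CCDS = function(v) isTRUE(as.logical(v$in_ccds)),
    hom_ab = function(v) v$hom_alt_fraction <= 0.80,
    het_ab = function(v) v$het_alt_fraction >= 0.25 && v$het_alt_fraction <= 0.80,
    het_binom = het_ab_ok,
    GQ = function(v) v$gq >= 20,
    FS = fs_ok,
    MQ = function(v) v$mq >= 40,
    QUAL = function(v) v$qual >= 30,
    RPRS = function(v) v$rprs >= -2,
    MQRS = function(v) v$mqrs >= -8,
    caller_pass = function(v) isTRUE(as.logical(v$dragen_pass)),
    gnomad_cov10 = function(v) v$gnomad_cov10_fraction >= 0.25,
    gnomad_exome_z = function(v) {
      if (!gnomad_observed(v)) return(TRUE)
      v$gnomad_exome_z >= -2.0
    },
    gnomad_exome_mq = function(v) {
      if (!gnomad_observed(v)) return(TRUE)
      v$gnomad_exome_mq >= 30
    }
  ))
}

#' Transcript coding-exon model
#'
#' Minimal transcript description used by the NMD-escape rule: the coding
#' segment length of each exon in transcript order.
#'
#' @param exon_cds_lengths Integer vector of per-exon coding lengths (nt),
#'   in transcript (5' to 3') order; all >= 1.
#' @param strand `"+"` or `"-"` (kept as metadata; coding coordinates are
#'   already strand-resolved).
#' @return An object of class `transcript_model`.
#' @export
transcript_model <- function(exon_cds_lengths, strand = "+") {
  stopifnot(length(exon_cds_lengths) >= 1, all(exon_cds_lengths >= 1),
            strand %in% c("+", "-"))
  structure(
    list(exon_cds_lengths = as.integer(exon_cds_lengths),
         cds_length = sum(as.integer(exon_cds_lengths)),
         exon_cds_end = cumsum(as.integer(exon_cds_lengths)),
         strand = strand),
    class = "transcript_model"
  )
}

#' @export
print.transcript_model <- function(x, ...) {
  cat("<transcript_model> ", length(x$exon_cds_lengths), " coding exons, ",
      x$cds_length, " nt CDS (", x$strand, ")\n", sep = "")
  invisible(x)
}

#' Predict escape from nonsense-mediated decay
#'
#' A premature stop is predicted to escape NMD when it falls (a) in the
#' last exon, (b) in the penultimate exon within 50 coding nucleotides of
#' that exon's 3' boundary (inclusive), or (c) in the first exon within the
#' first 200 nucleotides of the coding sequence. For a single-exon
#' transcript the last-exon clause applies and every position escapes.
#'
#' @param transcript A [transcript_model()].
#' @param cds_pos 1-based coding-nucleotide position of the variant.
#' @param exon_index 1-based exon index containing `cds_pos`; must be
#'   consistent with the transcript's exon spans.
#' @return `TRUE` if predicted to escape NMD.
#' @export
predict_nmd_escape <- function(transcript, cds_pos, exon_index) {
  stopifnot(inherits(transcript, "transcript_model"))
  n_exon <- length(transcript$exon_cds_lengths)
  if (exon_index < 1 || exon_index > n_exon) stop("exon_index out of range")
  exon_end <- transcript$exon_cds_end[exon_index]
  exon_start <- exon_end - transcript$exon_cds_lengths[exon_index] + 1L
  if (cds_pos < exon_start || cds_pos > exon_end) {
    stop("cds_pos ", cds_pos, " is not within exon ", exon_index,
         " [", exon_start, ", ", exon_end, "]")
  }
  if (exon_index == n_exon) return(TRUE)
  if (exon_index == n_exon - 1L && (exon_end - cds_pos) <= 50L) return(TRUE)
  if (exon_index == 1L && cds_pos <= 200L) return(TRUE)
  FALSE
}
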