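# Gene x sample carrier matrices under dominant and recessive zygosity.

carrier_matrix <- function(carriers, qv_sets, model, zygosity) {
  structure(list(carriers = carriers, qv_sets = qv_sets, model = model,
                 zygosity = zygosity),
            class = "carrier_matrix")
}

#' @export
print.carrier_matrix <- function(x, ...) {
  cat("<carrier_matrix> model '", x$model, "' (", x$zygosity, "): ",
      nrow(x$carriers), " genes x ", ncol(x$carriers), " samples, ",
      sum(x$carriers, na.rm = TRUE), " carrier flags\n", sep = "")
  invisible(x)
}

#' Build a dominant carrier matrix
#'
#' A sample carries a gene when it has at least one alternate allele at
#' one or more of that gene's qualifying variants. Missing genotypes
#' contribute nothing.
#'
#' @param genotypes Sample x variant dosage matrix (0/1/2/NA) with variant
#'   ids as column names.
#' @param qv_sets Named list gene -> qualifying variant ids (from
#'   [qualify_variants()]).
#' @param model Model name recorded on the result.
#' @return Object of class `carrier_matrix` whose `carriers` element is a
#'   gene x sample logical matrix.
#' @export
build_dominant_carriers <- function(genotypes, qv_sets, model = "model") {
  stopifnot(is.matrix(genotypes), !is.null(colnames(genotypes)))
  genes <- names(qv_sets)
  carriers <- matrix(FALSE, length(genes), nrow(genotypes),
                     dimnames = list(genes, rownames(genotypes)))
  for (g in genes) {
    ids <- intersect(qv_sets[[g]], colnames(genotypes))
    if (!length(ids)) next
    gm <- genotypes[, ids, drop = FALSE]
    carriers[g, ] <- rowSums(gm >= 1, na.rm = TRUE) > 0
  }
  carrier_matrix(carriers, qv_sets, model, "dominant")
}

#' Build a recessive carrier matrix
#'
#' A sample carries a gene under the recessive model when it has two
#' qualifying alleles: a homozygous-alternate qualifying genotype, or at
#' least two distinct heterozygous qualifying variants (potential compound
#' heterozygosity; no phasing is attempted, which is deliberately
#' over-inclusive). For genes on the X chromosome, males additionally
#' qualify hemizygously through a single alternate allele; samples with
#' missing sex are excluded (`NA`) from X-linked genes.
#'
#' @inheritParams build_dominant_carriers
#' @param sex Character vector (`"female"`/`"male"`, `NA` allowed) aligned
#'   to the genotype rows.
#' @param variant_chrom Named character vector mapping variant id ->
#'   contig; contigs `"X"`/`"chrX"` are treated as the X chromosome.
#' @return Object of class `carrier_matrix` (`NA` entries mark samples
#'   excluded from X-linked genes for missing sex).
#' @export
build_recessive_carriers <- function(genotypes, qv_sets, sex, variant_chrom,
                                     model = "model") {
  stopifnot(is.matrix(genotypes), length(sex) == nrow(genotypes))
  genes <- names(qv_sets)
  carriers <- matrix(FALSE, length(genes), nrow(genotypes),
                     dimnames = list(genes, rownames(genotypes)))
  is_x <- function(chrom) chrom %in% c("X", "chrX")
  for (g in genes) {
    ids <- intersect(qv_sets[[g]], colnames(genotypes))
    if (!length(ids)) next
    gm <- genotypes[, ids, drop = FALSE]
    hom <- rowSums(gm == 2, na.rm = TRUE) > 0
    n_hit <- rowSums(gm >= 1, na.rm = TRUE)
    comphet <- n_hit >= 2
    status <- hom | comphet
    x_ids <- ids[is_x(variant_chrom[ids])]
    if (length(x_ids)) {
      xm <- genotypes[, x_ids, drop = FALSE]
      x_alt <- rowSums(xm >= 1, na.rm = TRUE) > 0
      male <- sex == "male"
      hemi <- !is.na(male) & male & x_alt
      status <- status | hemi
      status[is.na(sex) & x_alt & !status] <- NA
    }
    carriers[g, ] <- status
  }
  carrier_matrix(carriers, qv_sets, model, "recessive")
}
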