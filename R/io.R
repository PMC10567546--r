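# Readers and writers for the fixture bundle formats (TSV, minimal VCF,
# BED gene map), the QV-model registry file, and result serialisation.

#' Annotation table column schema
#'
#' The documented column set for the per-variant annotation TSV: one row
#' per variant-allele (multi-allelic sites pre-decomposed), identity and
#' consequence columns, frequency and in-silico score columns, and the
#' site/genotype QC metrics consumed by [exwas_variant_qc()] and
#' [collapsing_variant_qc()].
#'
#' @return Character vector of column names.
#' @export
annotation_schema <- function() {
  c("variant_id", "gene", "chrom", "pos", "ref", "alt", "variant_type",
    "consequence", "cohort_mac", "cohort_maf", "gnomad_maf", "revel",
    "mtr_intolerant", "coverage_depth", "gq", "fs", "mq", "qual", "rprs",
    "mqrs", "dragen_pass", "het_alt_fraction", "hom_alt_fraction",
    "het_alt_reads", "het_total_reads", "site_missing_fraction",
    "site_fail_fraction", "gnomad_cov10_fraction", "gnomad_pass_fraction",
    "gnomad_exome_z", "gnomad_exome_mq", "in_ccds")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE, ...)
}

#' Write a cohort as the standard fixture bundle
#'
#' Serialises a cohort to a directory of plain-text files: genotypes as
#' both TSV (`genotypes.tsv`, samples x variants) and minimal VCF
#' (`genotypes.vcf` with GT, AD, DP, GQ FORMAT fields), the annotation
#' table, NPX matrix, covariates, protein map, gene map as BED (0-based,
#' half-open; converted back on read), the truth ledger, and phenotype /
#' somatic tables when present.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    genotypes_tsv = file.path(dir, "genotypes.tsv"),
    genotypes_vcf = file.path(dir, "genotypes.vcf"),
    annotations = file.path(dir, "annotations.tsv"),
    npx = file.path(dir, "npx.tsv"),
    covariates = file.path(dir, "covariates.tsv"),
    proteins = file.path(dir, "proteins.tsv"),
    gene_map = file.path(dir, "gene_map.bed"),
    truth = file.path(dir, "truth.tsv")
  )
  gt <- data.frame(sample_id = rownames(cohort$genotypes),
                   cohort$genotypes, check.names = FALSE)
  write_tsv(gt, paths["genotypes_tsv"])
  write_minimal_vcf(cohort$genotypes, cohort$variants, paths["genotypes_vcf"])
  write_tsv(cohort$variants, paths["annotations"])
  write_tsv(data.frame(sample_id = rownames(cohort$npx), cohort$npx,
                       check.names = FALSE), paths["npx"])
  write_tsv(cohort$covariates, paths["covariates"])
  write_tsv(cohort$proteins, paths["proteins"])
  bed <- data.frame(chrom = cohort$gene_map$chrom,
                    start = cohort$gene_map$start - 1L,  # to 0-based half-open
                    end = cohort$gene_map$end,
                    name = cohort$gene_map$gene)
  utils::write.table(bed, paths["gene_map"], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  write_tsv(cohort$truth, paths["truth"])
  if (!is.null(cohort$phenotypes)) {
    paths["phenotypes"] <- file.path(dir, "phenotypes.tsv")
    write_tsv(cohort$phenotypes, paths["phenotypes"])
  }
  if (!is.null(cohort$somatic)) {
    paths["somatic"] <- file.path(dir, "somatic.tsv")
    write_tsv(cohort$somatic, paths["somatic"])
  }
  invisible(paths)
}

# Minimal VCF 4.2 writer for dosage matrices; one biallelic record per
# variant with deterministic AD/DP/GQ consistent with the genotype.
write_minimal_vcf <- function(genotypes, variants, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(genotypes)), collapse = "\t")), con)
  fmt_geno <- function(g) {
    if (is.na(g)) return("./.:.:.:.")
    switch(as.character(g),
           "0" = "0/0:50,0:50:99",
           "1" = "0/1:25,25:50:99",
           "2" = "1/1:0,50:50:99")
  }
  for (i in seq_len(nrow(variants))) {
    cells <- vapply(genotypes[, variants$variant_id[i]], fmt_geno,
                    character(1))
    writeLines(paste(c(variants$chrom[i], variants$pos[i],
                       variants$variant_id[i], variants$ref[i],
                       variants$alt[i], "100", "PASS", ".",
                       "GT:AD:DP:GQ", cells), collapse = "\t"), con)
  }
  invisible(path)
}

# dosage of alt allele `k` from GT strings like "0/1", "2|1", "./."
gt_to_dosage <- function(gt, k) {
  parts <- strsplit(gt, "[/|]")
  vapply(parts, function(a) {
    if (length(a) == 0 || any(a == ".") || any(is.na(a))) return(NA_real_)
    sum(a == as.character(k))
  }, numeric(1))
}

#' Read a genotype matrix
#'
#' Reads genotypes from TSV (samples x variants dosage matrix with a
#' `sample_id` column) or VCF. VCF input is parsed with the vcfR package;
#' GT is converted to alt-allele dosage with `./.` preserved as missing,
#' multi-allelic records are decomposed into one dosage column per
#' alternate allele (ids suffixed `:altN`), and AD/DP/GQ FORMAT fields
#' are returned when present.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"vcf"` or `"tsv"`.
#' @return For TSV, the dosage matrix. For VCF, a list with `genotypes`
#'   (dosage matrix), `variants` (CHROM/POS/ID/REF/ALT per decomposed
#'   allele) and, when present, `ad`, `dp`, `gq` matrices.
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  }
  if (format == "tsv") {
    df <- read_tsv(path, check.names = FALSE)
    if (!"sample_id" %in% names(df)) stop("genotype TSV needs a sample_id column")
    m <- as.matrix(df[, setdiff(names(df), "sample_id"), drop = FALSE])
    rownames(m) <- df$sample_id
    storage.mode(m) <- "numeric"
    return(m)
  }
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  samples <- colnames(gt)
  rec_id <- ifelse(is.na(fix$ID) | fix$ID == ".",
                   paste(fix$CHROM, fix$POS, fix$REF, fix$ALT, sep = ":"),
                   fix$ID)
  out_cols <- list(); out_meta <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",")[[1]]
    for (k in seq_along(alts)) {
      id <- if (length(alts) == 1) rec_id[i] else paste0(rec_id[i], ":alt", k)
      out_cols[[id]] <- gt_to_dosage(gt[i, ], k)
      out_meta[[id]] <- data.frame(
        variant_id = id, chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
        ref = fix$REF[i], alt = alts[k], stringsAsFactors = FALSE)
    }
  }
  genotypes <- do.call(cbind, out_cols)
  rownames(genotypes) <- samples
  res <- list(genotypes = genotypes,
              variants = do.call(rbind, unname(out_meta)))
  for (el in c("AD", "DP", "GQ")) {
    m <- tryCatch(vcfR::extract.gt(v, element = el),
                  error = function(e) NULL)
    if (!is.null(m) && !all(is.na(m))) res[[tolower(el)]] <- t(m)
  }
  res
}

#' Read the per-variant annotation table
#'
#' @param path Annotation TSV path.
#' @param required Columns that must be present (default: the identity
#'   and frequency columns; QC columns are validated by the QC cascades
#'   themselves).
#' @return Data frame; errors name any missing column or duplicated
#'   variant id.
#' @export
read_annotations <- function(path,
                             required = c("variant_id", "gene", "chrom",
                                          "pos", "consequence", "cohort_maf",
                                          "cohort_mac", "gnomad_maf")) {
  df <- read_tsv(path)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("annotation table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  dup <- df$variant_id[duplicated(df$variant_id)]
  if (length(dup)) {
    stop("duplicated variant id(s): ", paste(unique(dup), collapse = ", "))
  }
  df
}

#' Read an NPX protein-abundance matrix
#'
#' @param path TSV with `sample_id` plus one numeric column per protein.
#' @return Numeric matrix (samples x proteins).
#' @export
read_npx <- function(path) {
  df <- read_tsv(path, check.names = FALSE)
  if (!"sample_id" %in% names(df)) stop("NPX table needs a sample_id column")
  prot <- setdiff(names(df), "sample_id")
  m <- as.matrix(df[, prot, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric NPX value(s)")
  rownames(m) <- df$sample_id
  m
}

#' Read a covariate table
#'
#' @param path TSV path.
#' @return Data frame; errors if `sample_id` is absent or duplicated.
#' @export
read_covariates <- function(path) {
  df <- read_tsv(path)
  if (!"sample_id" %in% names(df)) stop("covariate table needs sample_id")
  if (anyDuplicated(df$sample_id)) stop("duplicated sample_id in covariates")
  df
}

#' Read a BED gene map
#'
#' BED intervals are 0-based, half-open; they are converted to the
#' package's 1-based inclusive convention on read (`start + 1`, `end`
#' unchanged).
#'
#' @param path BED path with columns chrom, start, end, name.
#' @return Data frame `gene`, `chrom`, `start`, `end` (1-based
#'   inclusive).
#' @export
read_gene_map <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 4) stop("gene map BED needs chrom, start, end, name")
  data.frame(gene = df[[4]], chrom = df[[1]], start = df[[2]] + 1L,
             end = df[[3]], stringsAsFactors = FALSE)
}

#' Read a binary/quantitative phenotype table
#'
#' @param path TSV with `sample_id` plus one column per phenotype.
#' @return Data frame.
#' @export
read_phenotypes <- function(path) {
  df <- read_tsv(path, check.names = FALSE)
  if (!"sample_id" %in% names(df)) stop("phenotype table needs sample_id")
  df
}

#' Write an association or summary table deterministically
#'
#' Rows are sorted on the standard key columns present (unit id, protein
#' or phenotype, model), numeric columns are serialised at full precision,
#' and display-rounded companions (`<col>_display`, 4 significant digits)
#' are appended for `beta`, `p` and `estimate`. Re-running a scan with a
#' fixed seed therefore reproduces the file byte-for-byte.
#'
#' @param table Data frame.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_results <- function(table, path) {
  key <- intersect(c("variant_id", "gene", "protein", "phenotype",
                     "model", "genetic_model"), names(table))
  if (length(key)) {
    table <- table[do.call(order, table[key]), , drop = FALSE]
  }
  for (col in intersect(c("beta", "p", "estimate"), names(table))) {
    table[[paste0(col, "_display")]] <- signif(table[[col]], 4)
  }
  num <- vapply(table, is.numeric, logical(1))
  for (col in names(table)[num]) {
    table[[col]] <- format(table[[col]], digits = 17, trim = TRUE,
                           scientific = NA)
  }
  write_tsv(table, path)
  invisible(path)
}

#' Write / read a QV-model registry file
#'
#' Serialises a list of [qv_model()] objects to a human-editable YAML
#' file and back, so that the thresholds of every collapsing model are
#' visible, documented configuration rather than hard-coded constants.
#'
#' @param models Named list of `qv_model` objects.
#' @param path YAML file path.
#' @return `write_qv_registry`: invisibly, `path`. `read_qv_registry`:
#'   named list of `qv_model` objects.
#' @export
write_qv_registry <- function(models, path) {
  payload <- lapply(models, function(m) {
    u <- unclass(m)
    u$revel_min <- if (is.na(u$revel_min)) NULL else u$revel_min
    u$extra_maf_max <- if (is.na(u$extra_maf_max)) NULL else u$extra_maf_max
    if (!length(u$extra_variant_ids)) u$extra_variant_ids <- NULL
    u
  })
  yaml::write_yaml(payload, path)
  invisible(path)
}

#' @rdname write_qv_registry
#' @export
read_qv_registry <- function(path) {
  payload <- yaml::read_yaml(path)
  models <- lapply(payload, function(u) {
    qv_model(
      name = u$name, classes = unlist(u$classes),
      cohort_maf_max = u$cohort_maf_max, gnomad_maf_max = u$gnomad_maf_max,
      singleton_only = isTRUE(u$singleton_only),
      revel_min = if (is.null(u$revel_min)) NA_real_ else u$revel_min,
      revel_strict = isTRUE(u$revel_strict),
      mtr_required = isTRUE(u$mtr_required),
      zygosity = u$zygosity,
      extra_variant_ids = as.character(unlist(u$extra_variant_ids)),
      extra_maf_max = if (is.null(u$extra_maf_max)) NA_real_ else u$extra_maf_max,
      provenance = u$provenance)
  })
  names(models) <- vapply(models, `[[`, character(1), "name")
  models
}

#' Read a cohort fixture bundle
#'
#' Reads the directory layout written by [write_cohort()] back into a
#' parts list directly consumable by [run_exwas()], [run_collapsing()]
#' and friends.
#'
#' @param dir Bundle directory.
#' @return List with `genotypes`, `variants`, `covariates`, `npx`,
#'   `proteins`, `gene_map` and, when present, `phenotypes`, `somatic`,
#'   `truth`.
#' @export
read_cohort <- function(dir) {
  parts <- list(
    genotypes = read_genotypes(file.path(dir, "genotypes.tsv")),
    variants = read_annotations(file.path(dir, "annotations.tsv")),
    covariates = read_covariates(file.path(dir, "covariates.tsv")),
    npx = read_npx(file.path(dir, "npx.tsv")),
    proteins = read_tsv(file.path(dir, "proteins.tsv")),
    gene_map = read_gene_map(file.path(dir, "gene_map.bed"))
  )
  ids <- rownames(parts$genotypes)
  if (!identical(sort(ids), sort(rownames(parts$npx))) ||
      !identical(sort(ids), sort(parts$covariates$sample_id))) {
    stop("sample ids disagree across genotypes, NPX and covariates")
  }
  parts$npx <- parts$npx[ids, , drop = FALSE]
  parts$covariates <- parts$covariates[
    match(ids, parts$covariates$sample_id), , drop = FALSE]
  ph <- file.path(dir, "phenotypes.tsv")
  if (file.exists(ph)) parts$phenotypes <- read_phenotypes(ph)
  so <- file.path(dir, "somatic.tsv")
  if (file.exists(so)) parts$somatic <- read_tsv(so)
  tr <- file.path(dir, "truth.tsv")
  if (file.exists(tr)) parts$truth <- read_tsv(tr)
  parts
}
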