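# Declarative qualifying-variant (QV) model specifications and variant
# qualification.

#' Define a qualifying-variant collapsing model
#'
#' A QV model is a declarative filter: which consequence classes qualify,
#' frequency caps in the analysed cohort and in gnomAD, optional
#' missense-score clauses, zygosity, and an optional explicit allow-list
#' (used by the pQTL-augmented models) with its own frequency cap.
#'
#' REVEL and MTR clauses apply to missense-class variants only: a PTV
#' qualifies irrespective of missense scores, and missense variants with a
#' missing score are conservatively non-qualifying under models that
#' require one.
#'
#' @param name Model name (unique within a registry).
#' @param classes Consequence classes that qualify (subset of `"PTV"`,
#'   `"missense"`, `"nonsynonymous"`, `"synonymous"`).
#' @param cohort_maf_max Cohort MAF cap (computed on the analysed cohort).
#' @param gnomad_maf_max gnomAD MAF cap.
#' @param singleton_only If `TRUE`, only cohort singletons (MAC = 1)
#'   qualify.
#' @param revel_min Minimum REVEL score for missense variants (`NA` = no
#'   clause).
#' @param revel_strict If `TRUE` the REVEL comparison is strict (`>`),
#'   otherwise inclusive (`>=`).
#' @param mtr_required If `TRUE`, missense variants must fall in a
#'   missense-intolerant (MTR) subregion.
#' @param zygosity `"dominant"` or `"recessive"`.
#' @param extra_variant_ids Explicit allow-list of variant ids admitted
#'   regardless of class/score clauses.
#' @param extra_maf_max Cohort MAF cap applied to the allow-list.
#' @param provenance Free-text note recording which fields are stated
#'   study constants and which are this package's documented defaults.
#' @return Object of class `qv_model`.
#' @export
qv_model <- function(name, classes, cohort_maf_max, gnomad_maf_max,
                     singleton_only = FALSE, revel_min = NA_real_,
                     revel_strict = FALSE, mtr_required = FALSE,
                     zygosity = c("dominant", "recessive"),
                     extra_variant_ids = character(0),
                     extra_maf_max = NA_real_, provenance = "chosen") {
  zygosity <- match.arg(zygosity)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  stopifnot(all(classes %in% names(consequence_terms)))
  stopifnot(cohort_maf_max >= 0, cohort_maf_max <= 1,
            gnomad_maf_max >= 0, gnomad_maf_max <= 1)
  structure(list(name = name, classes = classes,
                 cohort_maf_max = cohort_maf_max,
                 gnomad_maf_max = gnomad_maf_max,
                 singleton_only = singleton_only, revel_min = revel_min,
                 revel_strict = revel_strict, mtr_required = mtr_required,
                 zygosity = zygosity,
                 extra_variant_ids = extra_variant_ids,
                 extra_maf_max = extra_maf_max, provenance = provenance),
            class = "qv_model")
}

#' @export
print.qv_model <- function(x, ...) {
  cat("<qv_model> ", x$name, " (", x$zygosity, ")\n",
      "  classes: ", paste(x$classes, collapse = ", "), "\n",
      "  cohort MAF <= ", format(x$cohort_maf_max),
      ", gnomAD MAF <= ", format(x$gnomad_maf_max),
      if (x$singleton_only) ", singletons only", "\n", sep = "")
  if (!is.na(x$revel_min)) {
    cat("  missense REVEL ", if (x$revel_strict) "> " else ">= ",
        x$revel_min, "\n", sep = "")
  }
  if (x$mtr_required) cat("  missense restricted to MTR-intolerant subregions\n")
  if (length(x$extra_variant_ids)) {
    cat("  + ", length(x$extra_variant_ids),
        " allow-listed variants (MAF <= ", format(x$extra_maf_max), ")\n",
        sep = "")
  }
  cat("  provenance: ", x$provenance, "\n", sep = "")
  invisible(x)
}

#' Default collapsing-model registry
#'
#' The ten collapsing models used by the gene-level scans: eight dominant
#' non-synonymous models, one recessive model and one synonymous
#' empirical-negative-control model. Thresholds that are stated study
#' constants are marked `"stated"` in each model's provenance; thresholds
#' the source does not print ship as documented package defaults marked
#' `"chosen"` and can be edited via [write_qv_registry()] /
#' [read_qv_registry()].
#'
#' Stated anchors: `flexdmg` admits PTVs plus rare (MAF < 0.1%) missense
#' with REVEL strictly > 0.25; `UR`/`URmtr` admit ultra-rare
#' non-synonymous variants absent from gnomAD with cohort MAF <= 0.005%,
#' `URmtr` additionally restricting missense to MTR-intolerant subregions;
#' `syn` is restricted to synonymous variants; models range from private
#' up to a 1% frequency cap (assigned here to the recessive model).
#'
#' @return Named list of [qv_model()] objects: `ptv`, `ptvraredmg`,
#'   `flexdmg`, `flexnonsyn`, `flexnonsynmtr`, `raredmg`, `UR`, `URmtr`,
#'   `rec`, `syn`.
#' @export
default_model_registry <- function() {
  models <- list(
    qv_model("ptv", "PTV", 1e-3, 1e-3,
             provenance = "PTV class stated; 0.1% caps chosen"),
    qv_model("ptvraredmg", c("PTV", "missense"), 1e-3, 1e-3,
             revel_min = 0.5,
             provenance = "PTV+damaging-missense composition stated; REVEL >= 0.5 and 0.1% caps chosen"),
    qv_model("flexdmg", c("PTV", "missense"), 1e-3, 1e-3,
             revel_min = 0.25, revel_strict = TRUE,
             provenance = "stated: PTV plus MAF < 0.1% missense with REVEL > 0.25"),
    qv_model("flexnonsyn", "nonsynonymous", 1e-3, 1e-3,
             provenance = "stated composition (PTVs plus all rare missense); 0.1% caps chosen"),
    qv_model("flexnonsynmtr", "nonsynonymous", 1e-3, 1e-3,
             mtr_required = TRUE,
             provenance = "MTR restriction stated; 0.1% caps chosen"),
    qv_model("raredmg", "missense", 5e-5, 5e-5, revel_min = 0.5,
             provenance = "chosen reconstruction: ultra-rare damaging missense"),
    qv_model("UR", "nonsynonymous", 5e-5, 0,
             provenance = "stated: gnomAD MAF = 0, cohort MAF <= 0.005%"),
    qv_model("URmtr", "nonsynonymous", 5e-5, 0, mtr_required = TRUE,
             provenance = "stated: UR plus MTR-intolerant missense"),
    qv_model("rec", "nonsynonymous", 1e-2, 1e-2, zygosity = "recessive",
             provenance = "recessive model stated; 1% caps chosen (the registry's stated maximum)"),
    qv_model("syn", "synonymous", 1e-3, 1e-3,
             provenance = "synonymous negative-control class stated; 0.1% caps chosen")
  )
  names(models) <- vapply(models, `[[`, character(1), "name")
  models
}

variant_is_missense_only <- function(consequence) {
  is_consequence_class(consequence, "missense") &
    !is_consequence_class(consequence, "PTV")
}

#' Select qualifying variants per gene under a QV model
#'
#' Applies a [qv_model()] filter to an annotated variant table (already
#' passed through [collapsing_variant_qc()]): consequence classes must
#' intersect the model's allowed set, cohort and gnomAD MAF caps must
#' hold, singleton models require cohort MAC = 1, and REVEL/MTR clauses
#' are applied to missense variants (missing scores are non-qualifying
#' under a model that requires them). Variants on the model's explicit
#' allow-list qualify through the allow-list's own MAF cap instead.
#'
#' @param variants Annotated variant table with columns `variant_id`,
#'   `gene`, `consequence`, `cohort_maf`, `cohort_mac`, `gnomad_maf`,
#'   `revel`, `mtr_intolerant`.
#' @param model A [qv_model()].
#' @return Named list: gene -> character vector of qualifying variant ids.
#' @export
qualify_variants <- function(variants, model) {
  stopifnot(inherits(model, "qv_model"), is.data.frame(variants))
  need <- c("variant_id", "gene", "consequence", "cohort_maf", "cohort_mac",
            "gnomad_maf")
  missing_cols <- setdiff(need, names(variants))
  if (length(missing_cols)) {
    stop("variant table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  revel <- if ("revel" %in% names(variants)) variants$revel else NA_real_
  mtr <- if ("mtr_intolerant" %in% names(variants)) variants$mtr_intolerant else NA

  in_class <- vapply(seq_len(nrow(variants)), function(i) {
    any(classify_consequence(variants$consequence[i]) %in% model$classes)
  }, logical(1))

  freq_ok <- variants$cohort_maf <= model$cohort_maf_max &
    variants$gnomad_maf <= model$gnomad_maf_max
  if (model$singleton_only) freq_ok <- freq_ok & variants$cohort_mac == 1

  miss_only <- variant_is_missense_only(variants$consequence)
  score_ok <- rep(TRUE, nrow(variants))
  if (!is.na(model$revel_min)) {
    rv_ok <- if (model$revel_strict) revel > model$revel_min
             else revel >= model$revel_min
    rv_ok[is.na(rv_ok)] <- FALSE
    score_ok <- score_ok & (!miss_only | rv_ok)
  }
  if (model$mtr_required) {
    mt_ok <- !is.na(mtr) & as.logical(mtr)
    score_ok <- score_ok & (!miss_only | mt_ok)
  }

  qual <- in_class & freq_ok & score_ok
  if (length(model$extra_variant_ids)) {
    extra <- variants$variant_id %in% model$extra_variant_ids &
      variants$cohort_maf <= model$extra_maf_max
    qual <- qual | extra
  }

  sets <- split(variants$variant_id[qual], variants$gene[qual])
  lapply(sets, as.character)
}
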