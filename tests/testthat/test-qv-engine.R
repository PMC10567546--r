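# QV model registry, variant qualification, carrier matrices.

test_that("the default registry ships the ten documented models", {
  reg <- default_model_registry()
  expect_setequal(names(reg),
                  c("ptv", "ptvraredmg", "flexdmg", "flexnonsyn",
                    "flexnonsynmtr", "raredmg", "UR", "URmtr", "rec", "syn"))
  expect_identical(reg$syn$classes, "synonymous")
  expect_equal(reg$flexdmg$revel_min, 0.25)
  expect_true(reg$flexdmg$revel_strict)
  expect_equal(reg$flexdmg$cohort_maf_max, 1e-3)
  expect_true(reg$URmtr$mtr_required)
  expect_equal(reg$UR$gnomad_maf_max, 0)
  expect_equal(reg$UR$cohort_maf_max, 5e-5)
  expect_identical(reg$rec$zygosity, "recessive")
  expect_true(all(vapply(reg[names(reg) != "rec"], function(m)
    m$zygosity == "dominant", logical(1))))
  # every model documents where its thresholds come from
  expect_true(all(nzchar(vapply(reg, `[[`, character(1), "provenance"))))
})

test_that("qualification applies class, frequency and score clauses", {
  reg <- default_model_registry()
  vs <- rbind(
    qc_variant(variant_id = "syn1", consequence = "synonymous_variant",
               cohort_maf = 5e-4, gnomad_maf = 0),
    qc_variant(variant_id = "ptv1", consequence = "stop_gained",
               cohort_maf = 5e-4, gnomad_maf = 0),
    qc_variant(variant_id = "mis_hi", consequence = "missense_variant",
               revel = 0.30, cohort_maf = 5e-4, gnomad_maf = 0),
    qc_variant(variant_id = "mis_lo", consequence = "missense_variant",
               revel = 0.20, cohort_maf = 5e-4, gnomad_maf = 0),
    qc_variant(variant_id = "mis_na", consequence = "missense_variant",
               revel = NA, cohort_maf = 5e-4, gnomad_maf = 0),
    qc_variant(variant_id = "common", consequence = "stop_gained",
               cohort_maf = 0.01, gnomad_maf = 0.01)
  )
  ptv <- qualify_variants(vs, reg$ptv)
  expect_setequal(ptv$G1, "ptv1")  # synonymous / common / missense excluded
  flex <- qualify_variants(vs, reg$flexdmg)
  expect_setequal(flex$G1, c("ptv1", "mis_hi"))  # REVEL 0.20 and NA excluded
  syn <- qualify_variants(vs, reg$syn)
  expect_setequal(syn$G1, "syn1")
})

test_that("REVEL at the flexdmg boundary is excluded (strict comparison)", {
  reg <- default_model_registry()
  v <- qc_variant(variant_id = "mis_b", consequence = "missense_variant",
                  revel = 0.25, cohort_maf = 5e-4, gnomad_maf = 0)
  expect_length(qualify_variants(v, reg$flexdmg), 0)
})

test_that("MTR and singleton clauses gate qualification", {
  reg <- default_model_registry()
  vs <- rbind(
    qc_variant(variant_id = "m_in", consequence = "missense_variant",
               mtr_intolerant = TRUE, cohort_maf = 1e-5, cohort_mac = 1L,
               gnomad_maf = 0),
    qc_variant(variant_id = "m_out", consequence = "missense_variant",
               mtr_intolerant = FALSE, cohort_maf = 1e-5, cohort_mac = 1L,
               gnomad_maf = 0),
    qc_variant(variant_id = "p_any", consequence = "stop_gained",
               mtr_intolerant = NA, cohort_maf = 1e-5, cohort_mac = 1L,
               gnomad_maf = 0)
  )
  urmtr <- qualify_variants(vs, reg$URmtr)
  # PTVs are exempt from the missense MTR clause
  expect_setequal(urmtr$G1, c("m_in", "p_any"))
  sing <- qv_model("s", "nonsynonymous", 1e-3, 1e-3, singleton_only = TRUE)
  vs2 <- vs; vs2$cohort_mac <- c(1L, 2L, 3L)
  expect_setequal(qualify_variants(vs2, sing)$G1, "m_in")
})

test_that("allow-listed variants qualify through their own MAF cap", {
  m <- qv_model("ptvplus", "PTV", 1e-3, 1e-3,
                extra_variant_ids = "mis_x", extra_maf_max = 0.02)
  vs <- rbind(
    qc_variant(variant_id = "mis_x", consequence = "missense_variant",
               cohort_maf = 0.01, gnomad_maf = 0.01),
    qc_variant(variant_id = "mis_y", consequence = "missense_variant",
               cohort_maf = 0.01, gnomad_maf = 0.01),
    qc_variant(variant_id = "mis_x2", consequence = "missense_variant",
               cohort_maf = 0.05, gnomad_maf = 0.05)
  )
  vs$variant_id[3] <- "mis_x"  # same id, above the allow-list cap
  vs <- vs[-3, ]
  expect_setequal(qualify_variants(vs, m)$G1, "mis_x")
})

test_that("dominant carriers match the definition and a brute-force scan", {
  g <- rand_genotypes(20, 6, seed = 51, maf = 0.3)
  qv <- list(GA = c("v001", "v002"), GB = c("v003", "v004", "v005"))
  cm <- build_dominant_carriers(g, qv, "m")
  expect_identical(cm$carriers, brute_dominant(g, qv))
  # a het at one QV is a carrier; a gene with no QVs has none
  g2 <- matrix(c(1, 0), 2, 1, dimnames = list(c("a", "b"), "v1"))
  cm2 <- build_dominant_carriers(g2, list(G = "v1", H = "zzz"), "m")
  expect_true(cm2$carriers["G", "a"])
  expect_false(cm2$carriers["G", "b"])
  expect_false(any(cm2$carriers["H", ]))
})

test_that("dominant carriers equal the per-variant union on random fixtures", {
  set.seed(61)
  for (i in 1:20) {
    g <- rand_genotypes(50, 30, seed = 100 + i, maf = runif(1, 0.02, 0.4))
    qv <- list(G1 = sample(colnames(g), 8), G2 = sample(colnames(g), 5))
    cm <- build_dominant_carriers(g, qv, "m")
    for (gene in names(qv)) {
      union_set <- Reduce(`|`, lapply(qv[[gene]], function(v) g[, v] >= 1))
      expect_identical(unname(cm$carriers[gene, ]), unname(union_set))
    }
  }
})

test_that("recessive carriers need two alleles, with X hemizygosity", {
  g <- matrix(c(2, 1, 0, 0,   # s1: hom at v1
                1, 1, 0, 0,   # s2: two distinct hets
                1, 0, 0, 0,   # s3: single het -> non-carrier
                0, 0, 1, 0,   # s4: single het on X
                0, 0, 1, 0),  # s5: single het on X (female)
              nrow = 5, byrow = TRUE,
              dimnames = list(paste0("s", 1:5), c("v1", "v2", "x1", "v4")))
  sex <- c("female", "male", "female", "male", "female")
  chrom <- c(v1 = "chr1", v2 = "chr1", x1 = "chrX", v4 = "chr2")
  qv <- list(GA = c("v1", "v2"), GX = "x1")
  cm <- build_recessive_carriers(g, qv, sex, chrom, "rec")
  expect_true(cm$carriers["GA", "s1"])   # homozygous
  expect_true(cm$carriers["GA", "s2"])   # potential compound het
  expect_false(cm$carriers["GA", "s3"])
  expect_true(cm$carriers["GX", "s4"])   # male hemizygous
  expect_false(cm$carriers["GX", "s5"])  # female single het on X
  # missing sex with a single X alt is excluded for that gene
  sex_na <- sex; sex_na[4] <- NA
  cm_na <- build_recessive_carriers(g, qv, sex_na, chrom, "rec")
  expect_true(is.na(cm_na$carriers["GX", "s4"]))
})

test_that("recessive carriers match a brute-force scan on random fixtures", {
  set.seed(71)
  for (i in 1:15) {
    g <- rand_genotypes(40, 12, seed = 200 + i, maf = 0.3)
    chrom <- structure(sample(c("chr1", "chrX"), 12, replace = TRUE,
                              prob = c(0.8, 0.2)), names = colnames(g))
    sex <- sample(c("female", "male", NA), 40, replace = TRUE,
                  prob = c(0.5, 0.45, 0.05))
    qv <- list(G1 = sample(colnames(g), 6), G2 = sample(colnames(g), 4))
    cm <- build_recessive_carriers(g, qv, sex, chrom, "rec")
    expect_identical(cm$carriers, brute_recessive(g, qv, sex, chrom))
  }
})

test_that("recessive carriers are a subset of dominant carriers (autosomes)", {
  set.seed(81)
  g <- rand_genotypes(60, 10, seed = 82, maf = 0.35)
  chrom <- structure(rep("chr1", 10), names = colnames(g))
  qv <- list(G1 = colnames(g)[1:5], G2 = colnames(g)[6:10])
  dom <- build_dominant_carriers(g, qv, "m")
  rec <- build_recessive_carriers(g, qv, rep("female", 60), chrom, "m")
  expect_true(all(!rec$carriers | dom$carriers))
})

test_that("shrinking a QV set never adds carriers", {
  g <- rand_genotypes(50, 8, seed = 91, maf = 0.3)
  full <- list(G1 = colnames(g))
  part <- list(G1 = colnames(g)[1:4])
  cm_full <- build_dominant_carriers(g, full, "m")
  cm_part <- build_dominant_carriers(g, part, "m")
  expect_true(all(!cm_part$carriers | cm_full$carriers))
})
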