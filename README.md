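# rvpqtl

Rare-variant proteogenomic association analysis in R.

`rvpqtl` maps **protein quantitative trait loci (pQTLs)** — genetic
variants associated with the measured abundance of plasma proteins — from
exome-style genotypes and a multiplexed, NPX-like protein abundance
matrix. It is aimed at statistical geneticists who want the full
rare-variant proteogenomics workflow (variant-level scan, gene-level
collapsing, calibration, downstream phenome-wide integration) as tested,
scriptable building blocks that run at desk scale on synthetic or real
tables.

## What it computes

**Variant-level ExWAS.** For every variant carried by at least 4
individuals, protein abundance is regressed on the encoded genotype
under three genetic models — genotypic (additive dosage 0/1/2), dominant
and recessive — with the covariate design

```
NPX ~ genotype + age + sex + age*sex + age^2 + age^2*sex + PC1..PC4
      + batch + panel sampling-time offset
```

reporting the effect size (beta), its 95% CI and a two-sided t-test
P-value, with a fixed study-wide significance threshold of P <= 1e-8.

**Gene-level collapsing.** Qualifying variants (QVs) are selected per
gene under declarative models combining consequence classes
(protein-truncating, missense, non-synonymous, synonymous), cohort and
gnomAD frequency caps, and REVEL/MTR missense-score clauses; carriers of
one or more QVs (dominant), or of two qualifying alleles including
potential compound heterozygotes and X hemizygotes (recessive), are
compared with non-carriers by the same regression. Ten models ship in
`default_model_registry()`, including the synonymous empirical negative
control, plus the pQTL-augmented `ptvolink` / `ptvolink2pcnt` models
that add protein-lowering cis-CDS missense pQTLs to the PTV model.

**Calibration and classification.** Signals are labelled cis-CDS /
cis-position trans-CDS / trans-CDS by a 1 Mb rule; an n-of-1 permutation
(one global permutation of the genotype sample axis) estimates the
expected false-positive count at the significance threshold; median
genomic inflation (lambda_GC) summarises scan calibration; exact
binomial and Fisher tests cover enrichment and binary-trait analyses;
a clonal-haematopoiesis module qualifies somatic calls (PASS,
0.03 <= VAF <= 0.4, allelic depth >= 3, per-gene effect/hotspot rules)
and tests CH carrier status against the proteome.

**Synthetic cohorts.** `simulate_cohort()` generates genotypes at
specified MAFs (Hardy-Weinberg, no LD), covariates, NPX matrices built
as covariate effects + planted genotype effects + Gaussian noise, binary
phenotypes with planted odds ratios and age-dependent somatic clones —
with a truth ledger — so the entire pipeline is testable without
access-controlled data.

## Worked example

```r
library(rvpqtl)

cohort <- simulate_cohort(demo_sim_config(n_samples = 5000, seed = 7))
cohort
#> <synthetic_cohort> 5000 samples, 7 variants, 3 proteins, 1 binary phenotypes, 471 somatic calls

exwas <- run_exwas(cohort)
head(exwas[order(exwas$p), c("variant_id", "protein", "genetic_model",
                             "beta", "p", "n_carriers", "cis_trans_label")], 5)
#>    variant_id protein genetic_model   beta        p n_carriers cis_trans_label
#> 2  GENE1:mis1      P1     genotypic -0.606 1.79e-35        451         cis-CDS
#> 17 GENE1:mis1      P1      dominant -0.616 3.07e-35        451         cis-CDS
#> 4  GENE2:mis1      P1     genotypic  0.332 1.41e-08        317       trans-CDS
#> 19 GENE2:mis1      P1      dominant  0.332 1.73e-08        317       trans-CDS
#> 25 GENE3:ptv1      P2      dominant -0.984 3.62e-08         33         cis-CDS
```

The planted protein-lowering missense pQTL in `GENE1` is recovered as a
cis-CDS signal far below the 1e-8 threshold, and the `GENE2` variant
surfaces as the planted trans association. Gene-level collapsing
aggregates the three rare planted PTVs (10 carriers here) into one
burden test:

```r
reg <- default_model_registry()
qc  <- collapsing_variant_qc(cohort$variants)
qv  <- qualify_variants(cohort$variants[qc$pass, ], reg$ptv)
carriers <- build_dominant_carriers(cohort$genotypes, qv, "ptv")
burden <- run_collapsing(cohort, carriers)
burden[burden$protein == "P1", c("gene", "model", "beta", "ci_low",
                                 "ci_high", "p", "n_carriers")]
#>    gene model  beta ci_low ci_high        p n_carriers
#> 1 GENE1   ptv -1.29  -1.92  -0.661 5.94e-05         10

n_of_one_permutation(cohort, seed = 7)
#> <permutation_report> 0 of 39 permuted tests at P <= 1e-08 (expected FP: 0 of 2 observed hits, 0%)
```

The carrier-level effect estimate (-1.29, planted -1.5 per PTV allele)
is significant at nominal levels with only 10 carriers; the single
global permutation produces no hits at the threshold, i.e. an expected
false-positive rate of 0% among the two observed significant
associations.

A command-line wrapper covering `simulate`, `qc`, `exwas`, `collapse`,
`classify`, `permute`, `ch` and `phewas` is installed at
`inst/cli/rvpqtl.R`:

```sh
Rscript inst/cli/rvpqtl.R simulate --out bundle/ --seed 7 --n 2000
Rscript inst/cli/rvpqtl.R exwas --in bundle/ --out exwas.tsv
```

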