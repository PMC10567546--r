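---
title: "Rare-variant proteogenomic association: models, thresholds and design choices"
author: "rvpqtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rare-variant proteogenomic association: models, thresholds and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the statistics it
implements: the regression model and its covariates, the two
quality-control cascades, the qualifying-variant (QV) collapsing models
and where each threshold comes from, the calibration machinery, the
clonal-haematopoiesis (CH) module, and what the synthetic cohort
generator does and does not emulate.

## The association model

Both the variant-level scan (`run_exwas()`) and the gene-level
collapsing scan (`run_collapsing()`) are ordinary least squares of a
protein abundance (an NPX-like relative log-scale unit) on a genotype
encoding, with a two-sided t-test on the genotype coefficient:

$$\mathrm{NPX}_{ip} = \beta\, g_i + \boldsymbol\gamma^{\!\top}
\mathbf{c}_i + \varepsilon_{ip}, \qquad
\varepsilon_{ip} \sim \mathcal N(0, \sigma_p^2).$$

The covariate vector $\mathbf{c}_i$ depends on the flavour
(`build_covariates()`):

* **exwas** — age, sex, age×sex, age², age²×sex, PC1–PC4, batch
  indicators and a panel-specific measurement-to-sampling time offset
  (each protein is tested with its own panel's offset);
* **collapsing** — the same age/sex/PC/batch terms without the panel
  offset;
* **pan_ancestry** — adds broad-ancestry indicator columns;
* **ch** — adds body-mass index and pack-years of smoking.

Genotypes are encoded under three genetic models
(`encode_genotype()`): *genotypic*, implemented as the additive 0/1/2
dosage (1 degree of freedom); *dominant* (any alternate allele); and
*recessive* (homozygous alternate). The "genotypic" label could also be
read as a 2-df categorical contrast; the additive dosage is the
standard exome-scan reading and is what this package implements — a
2-df variant was considered and deliberately not made the default, as
every worked quantity here is 1-df.

No transformation is applied to the abundances by default; a
rank-inverse-normal option was considered and left out of the default
path because the implemented model assumes the raw NPX scale.
Missingness is handled complete-case per test. Variant-level tests
require the variant to be carried by at least 4 individuals
(`min_carriers = 4`); combinations with a degenerate predictor (for
example a recessive encoding with no homozygotes) are flagged
`untestable` rather than dropped silently. The study-wide significance
threshold is fixed at $P \le 10^{-8}$ and deliberately not adjusted
further: the threshold itself is calibrated empirically (below), and no
additional multiple-testing correction is applied.

Internally, variants with complete genotypes are tested through a
vectorised QR kernel (residualise abundances and genotypes against the
covariates once, then regress residuals pairwise), which is
algebraically identical to per-test OLS by the Frisch–Waugh–Lovell
partition; the test suite asserts equality with `lm()` to 1e-9.

## Variant quality control

Two cascades act on per-variant (decomposed-allele) annotation rows.
All comparisons are inclusive exactly as written; the boundary value
always passes, and the tests pin this down. A missing metric fails with
reason `missing-metric:<name>` rather than passing silently.

**ExWAS cascade** (`exwas_variant_qc()`): depth ≥ 10×; heterozygous
alternate-read fraction ≥ 0.2; exact binomial test of het allele
balance against 50% with P > 1e-6; GQ ≥ 20; Fisher strand bias ≤ 200
(indels) / ≤ 60 (SNVs); MQ ≥ 40; QUAL ≥ 30; read-position rank-sum ≥
−2; mapping-quality rank-sum ≥ −8; caller PASS; site missingness
< 10%; site QC-failure fraction < 5%; gnomAD 10× coverage ≥ 30%; and,
for variants observed in gnomAD, pass fraction (AC/AC_raw) ≥ 50%.

**Collapsing cascade** (`collapsing_variant_qc()`): depth ≥ 10×; CCDS
transcript annotation; homozygous alternate-read fraction ≤ 0.80; het
fraction within [0.25, 0.80]; the same het binomial, GQ/FS/MQ/QUAL/
rank-sum and PASS criteria; gnomAD 10× coverage ≥ 25%; and, when
observed in gnomAD, exome z-score ≥ −2.0 and exome MQ ≥ 30.

The het allele-balance binomial consumes pooled alternate/total read
counts over heterozygous calls (`het_alt_reads`, `het_total_reads` in
the annotation schema); a variant with no heterozygous genotypes
satisfies the criterion vacuously. Site-level metrics are treated as
per decomposed alternate allele; multi-allelic records are decomposed
on VCF read (`read_genotypes()`), one dosage column per alternate.

## Qualifying-variant models

A QV model (`qv_model()`) is a declarative filter: allowed consequence
classes, cohort and gnomAD MAF caps, an optional singleton restriction,
optional REVEL/MTR clauses, zygosity, and an optional explicit
allow-list with its own MAF cap. Consequence classes come from verbatim
SnpEff term lists (`consequence_terms`): protein-truncating (PTV),
missense, non-synonymous (the superset adding in-frame indels and
`protein_altering_variant`) and synonymous. Two conventions matter and
are tested:

* REVEL/MTR clauses apply to missense-class variants only — a PTV
  qualifies under `flexdmg` irrespective of scores — and missense
  variants with missing scores are conservatively non-qualifying under
  models that require them.
* The `flexdmg` REVEL comparison is strict (`> 0.25`, as that model is
  defined); other score clauses default to inclusive `>=` and are
  configurable.

Cohort MAF is computed on the analysed cohort and recomputed whenever
samples are excluded (`exclude_overlap_samples()` re-derives allele
counts). The ten registry models (`default_model_registry()`) mix
stated constants with package defaults; each model's `provenance`
string records which is which, and the registry round-trips through a
human-editable YAML file (`write_qv_registry()` / `read_qv_registry()`)
so that no threshold is a hidden constant. Where a model's exact caps
are not stated anywhere (for example `raredmg`), the defaults here are
documented reconstructions marked `"chosen"` — they are configuration,
not claims.

Carrier construction: dominant carriers have ≥ 1 alternate allele at
≥ 1 QV. Recessive carriers have a homozygous QV, two distinct
heterozygous QVs (potential compound heterozygosity — no phasing is
attempted, an over-inclusive contract by design), or, for X-linked
genes, a single alternate allele in males; samples with missing sex are
excluded from X-linked genes only when the hemizygous clause is the
deciding one. A minimum carrier count of 1 is required to run a gene
test (configurable); genes below it are flagged untestable.

## cis/trans classification and calibration

`classify_cis_trans()` labels an association **cis-CDS** when the
variant's (or gene unit's) gene is the gene encoding the measured
protein; **cis-position trans-CDS** when it is a different gene whose
position lies within 1 Mb (inclusive — exactly 1 Mb counts as within)
of the protein-coding gene's interval on the same contig; and
**trans-CDS** otherwise. Distances are minimum gaps between 1-based
inclusive intervals (gene-level units use the unit gene's interval);
the gene body only is used, with no extra flanking window on the
cis-CDS definition. BED input is converted from 0-based half-open
coordinates on read.

Two calibration tools support the fixed $10^{-8}$ threshold:

* `n_of_one_permutation()` permutes the genotype sample axis **once**
  with a single global permutation — preserving the
  phenotype–covariate pairing and every per-variant allele count —
  re-runs the scan, and counts permuted hits at the threshold. The
  permuted hit count is the expected number of false positives among
  the observed significant associations, reported also as a percentage
  of the observed count. Permuting genotypes rather than phenotypes is
  a deliberate choice: it keeps the phenotype–covariate correlation
  structure intact.
* `lambda_gc()` is the median of the $\chi^2_1$ quantile transform of
  the P-values divided by the $\chi^2_1$ median.

The synonymous collapsing model runs as an empirical negative control
(`empirical_null` rows in the collapsing output).

## Exact tests

`binomial_two_sided()` uses the minimum-likelihood two-sided
convention: the sum of $P(X = i)$ over all outcomes no more probable
than the observed one. This matches `stats::binom.test()` and most
exact-test software, and the suite verifies it against direct
enumeration over the full $n \le 60$ grid. Note that for far-tail
observations this two-sided value can differ noticeably from the
one-sided tail (the lower tail can contribute a comparable mass of
improbable outcomes), which matters when comparing against previously
printed far-tail values.

`fisher_binary_assoc()` reports the exact two-sided Fisher P together
with the *sample* odds ratio under a Haldane–Anscombe 0.5 correction
when a cell is zero and a Woolf (log-normal) 95% CI on the corrected
counts — not the conditional-MLE odds ratio, a deliberate choice so
that the OR and CI remain finite and elementary for sparse carrier
tables; the P-value is unaffected by this choice.

## Clonal haematopoiesis

`qualify_ch_calls()` consumes a somatic call table (the somatic caller
itself is upstream of this package) and keeps PASS calls with
0.03 ≤ VAF ≤ 0.4, allelic depth ≥ 3, and an effect or hotspot id
admitted by the gene's rule. The shipped rules for the 15 analysis
genes follow CH literature conventions (truncating effects for
loss-of-function drivers such as TET2/ASXL1, hotspot missense for
JAK2/SF3B1/SRSF2 and kin) and are package defaults, replaceable by the
caller. The VAF cut-off ladder defaults to {0.03, 0.05, 0.10, 0.20};
carrier sets are nested along it by construction.
`age_prevalence_profile()` validates carriers collectively as somatic
via the expected rise of prevalence with age (logistic slope > 0 at
P < 0.05). `run_ch_collapsing()` removes the supplied exclusion list
(for example prior haematological malignancy) before testing and uses
the CH covariate flavour.

## pQTL-augmented phenome-wide models

`select_protein_lowering_missense()` filters a variant-level scan to
missense, cis-CDS associations with $\beta < 0$ and $P < 10^{-4}$ — a
pure, idempotent filter. `build_augmented_models()` produces
**ptvolink** (baseline PTV model plus those variants at the PTV model's
own MAF cap) and **ptvolink2pcnt** (allow-listed missense cap relaxed
to 2%), so carrier sets nest: ptv ⊆ ptvolink ⊆ ptvolink2pcnt.
`run_phewas()` tests binary traits by two-sided Fisher's exact test
after sex-matching controls and skips traits with fewer than 30 cases;
quantitative traits run through the covariate-adjusted regression. Sex
matching (`match_controls_by_sex()`) is gated by a two-sided Fisher
test at 0.05 on the female fractions and, when triggered, removes
controls of the over-represented sex in seeded batches until the gate
clears — a deterministic, minimal-intervention reading of "matched";
cases are never altered, and sex-specific traits take same-sex controls
only. Hierarchical phenotype trees are out of scope: phenotypes arrive
as a flat table.

## The synthetic cohort generator

`simulate_cohort()` emulates the data structure the analysis assumes:

* genotypes drawn independently per sample as Binomial(2, MAF) —
  Hardy–Weinberg proportions with **no linkage disequilibrium**, which
  is adequate for effectively unlinked rare variants but means the
  generator cannot produce the LD-contaminated common-variant signals
  that motivate cis-position trans-CDS labels in real data;
* covariates: age ~ Uniform(40, 70) (a recruitment-window shape), sex
  Bernoulli(0.54 female), PCs standard normal, seven batches
  multinomial, broad ancestry labels (93% EUR), BMI, pack-years, one
  sampling-time offset per panel;
* abundances built as covariate effects + planted per-variant genotype
  effects + Gaussian noise. **The residual NPX distribution is assumed
  Gaussian**; nothing here models assay artefacts such as hook
  effects, limits of detection, or epitope-binding disruption. Passing
  tests therefore demonstrate correctness of the statistical machinery
  under the stated model, not robustness to assay non-normality;
* binary phenotypes via logit(p) = logit(prevalence) + log(OR)·carrier;
* somatic clones via a logistic age model, VAF from Beta(2, 8)
  truncated to (0, 0.5] (chosen to straddle the 0.03–0.4 qualification
  window), Poisson depths and binomial alternate depths.

Genotype missingness is configurable and defaults to 0 — the QC module
owns missingness handling. Identical configurations (including the
seed) regenerate bit-identical cohorts; binary phenotypes and somatic
calls use seeds derived as seed+1 and seed+2 so the standalone
operations reproduce the embedded ones.

## Numerical choices and test problem sizes

* All QC and model thresholds compare inclusively as printed; boundary
  fixtures assert each one.
* P-values are floored at the smallest positive double so they remain
  in (0, 1].
* Ties in the two-sided exact tests use a 1e-7 relative tolerance when
  comparing point probabilities, matching standard practice.
* The test and acceptance problem sizes were chosen as the smallest
  cohorts at which each property is decisively powered: variant-level
  recovery uses n = 2000 with a MAF 5% effect of 1.5 SD; the gene-level
  burden uses n = 5000 with ~40 carriers of a −1 SD effect (a
  noncentrality near 6, i.e. deliberately close to the threshold);
  null calibration uses a 100×100 scan in 500 samples (10,000 tests)
  with 100 single-permutation replicates; the augmentation power-gain
  property uses 50 replicates of n = 4000 in a regime where the
  protein-lowering missense pQTLs expand the allelic series severalfold
  (~100 augmented vs ~11 baseline carriers) — with comparable carrier
  sets both models are jointly underpowered and the comparison
  degenerates to a coin flip, which is not the regime the property
  describes.

## Known limitations

* No relatedness or population-structure modelling beyond label
  covariates; the intended workflow prunes relatives upstream
  (documented sample-QC constants such as the 0.1769 kinship cut are
  carried as configuration metadata only, not recomputed here).
* No SKAT-type variance-component tests or mixed models; burden-style
  carrier indicators only.
* No phasing: compound heterozygosity is "potential" by contract.
* Transcript selection and consequence annotation are consumed, not
  produced; one transcript per gene is assumed.
* The somatic caller, panel-of-normals construction and read-level
  filtering are upstream; the CH module starts from a call table.
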