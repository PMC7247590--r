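---
title: "Gene-wise variant burden: model, evaluation design and simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-wise variant burden: model, evaluation design and simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gvburden)
```

## The model

`gvburden` scores, per individual, the cumulative deleteriousness of the
coding variation in a gene as the geometric mean of normalized in-silico
variant scores, and extends the score to drugs through a PK/PD drug–gene
relation map. Three modelling commitments define the score:

* **Variant eligibility.** Only nonsynonymous coding variants contribute.
  Synonymous and noncoding variants never enter a burden, whatever their
  scores. A variant counts once per individual: heterozygous and homozygous
  carriage are collapsed to presence/absence, because the burden is defined
  over variant *sets* and the score model has no dosage term.
* **Common scale, common cutoff.** Every scoring method is mapped to
  `[0, 1]` with lower = more deleterious: SIFT passes through; the bounded
  higher-is-deleterious methods (MutationTaster, PolyPhen-2 HDIV and HVAR)
  are affinely flipped over their native `[0, 1]`; the unbounded
  conservation scores (phyloP, GERP++) are min–max scaled over the scores
  observed in the annotation table — over the whole table, never per
  individual, so a variant has one cohort-wide normalized score and burdens
  stay comparable between individuals. The retention rule `S(v) <= 0.7` is
  stated natively for SIFT; we apply the same cutoff to every method's
  normalized score (the `cutoff` argument), since the methods are evaluated
  through identical downstream steps and a method without a retention step
  would mix clearly benign variants into the burden.
* **Geometric-mean aggregation.** The geometric mean heavily weights the
  lowest (most deleterious) scores, down to singleton rare variants — the
  property that distinguishes this collapsing scheme from count- or
  sum-based rare-variant burden tests. An empty variant set gives burden 1
  (an unaffected gene); a score of exactly 0 gives burden 0, with no
  epsilon flooring, since 0 is a legal score meaning "maximally damaging".
  Drug-level burdens average over the drug's gene set with relation types
  (enzyme/transporter/carrier/target) deduplicated and unweighted.

Numerics: burdens are computed in log space (`exp(mean(log(s)))`) to avoid
underflow over long products; the zero case is special-cased before the
logarithm. Unaffected genes are never materialized — profiles are sparse
with an implicit value of 1, and `drug_burden_profile()` exploits
`log(1) = 0` so only affected genes enter the per-drug log sums.

## Evaluation design

Validation asks whether low-burden drugs coincide with the individual's
known variant–drug associations (VDAs). The gold standard of an individual
is the set of drugs linked to a *noncoding* VDA variant the individual
carries; coding VDAs are removed first (`filter_noncoding()`) so that the
evaluation never rewards the burden for rediscovering a coding variant that
is itself the cataloged association.

* **Ranking direction.** Drugs are ranked ascending by burden: lower burden
  = more deleterious = predicted associated.
* **Ties.** Most drugs sit at burden exactly 1, so tie handling is not a
  corner case. The ROC sweep moves over *distinct* burden values; a tie
  block enters the positive set atomically, and the trapezoidal AUC then
  equals pairwise concordance with ties counted 1/2. Splitting ties by
  input order would make the AUC depend on drug ordering.
* **Per-individual AUC, then aggregation.** Each individual gets an AUC;
  strata report the mean and sample SD (n − 1) over individuals with a
  nonempty, proper gold standard. Individuals with an empty gold standard
  (or one covering every drug) are excluded from aggregation — the AUC is
  undefined for them — and counted out of `n_samples`; single-sample strata
  are flagged as degenerate with SD 0.
* **Ethnicity modes.** In `ethnicity_specific` mode a VDA counts only if
  its OMB label equals the individual's label under the
  superpopulation→OMB map (default AFR→African-American, EAS/SAS→Asian,
  EUR→Caucasian). Unlabeled VDAs are excluded in this mode — same-group
  membership cannot be asserted for them — and included in `non_specific`
  mode; both behaviours are arguments. AMR is left unmapped by default:
  admixed American panels have no single OMB label, and affected samples
  are flagged and excluded from ethnicity-specific aggregation rather than
  silently dropped.
* **ATC strata.** Per anatomical main group, the drug universe is
  restricted to that group's drugs and gold standards are intersected with
  it; groups in which no individual has an evaluable gold standard are
  reported with `n_samples = 0` and flagged rather than omitted.
* **Gene categories.** `compare_gene_categories()` tests whether a named
  gene set (e.g. a core-pharmacogene list) has lower cohort-mean burdens
  than a disjoint background set, by a one-sided Mann–Whitney U test. The
  test is the natural nonparametric choice for a location shift between
  small gene sets; cohort-mean burdens are far from normal.

## The synthetic cohort generator

`simulate_cohort()` exists so the whole pipeline can be exercised, and its
operating characteristics measured, without any external genomic resource.
It emulates the *statistical structure* the analysis assumes, not any real
dataset:

* a cohort with population structure: global allele frequencies drawn from
  Beta(0.6, 12) and perturbed per population on the logit scale (SD 0.5),
  three equal populations (AFR/EAS/EUR superpopulations) of 200 individuals
  by default;
* genes (30) carrying Poisson(8) nonsynonymous background variants, a
  fraction of them deleterious (0.15; latent score Beta(4, 18), mean
  ≈ 0.18), the rest benign (Beta(30, 2), mass near 1), plus scored
  synonymous variants that exercise the consequence filter;
* a planted low-burden **core** gene category (6 genes): each core gene is
  guaranteed 3 common (allele frequency 0.15–0.3) deleterious variants and
  a higher deleterious fraction (0.5), emulating the common functional
  polymorphism of core ADME pharmacogenes — this is the ground truth for
  the gene-category comparison;
* six per-method raw scores generated as monotone power distortions
  (per-method γ) of one latent deleteriousness per variant with small
  independent jitter (SD 0.02), then placed on each method's native scale
  (PolyPhen-like flipped on `[0, 1]`; phyloP on `[-5, 10]`; GERP++ on
  `[-8, 6.2]`), with ~2% of non-SIFT scores dropped to exercise missing-score
  handling — cross-method rank agreement is high but not perfect;
* a drug–gene map of 60 drugs with 1 + Poisson(1.2) genes each, random
  relation types and ATC letters;
* **planted associations** (30): each picks a drug, one of its genes, a
  noncoding marker variant and a deleterious causal coding variant (latent
  Beta(2, 38), mean ≈ 0.05). Marker carriers co-carry the causal variant
  with probability `linkage_fidelity`; linkage is simulated directly as
  this carrier-copy probability, because the pipeline consumes only carrier
  sets and explicit haplotype recombination would add nothing testable.
  Ethnicity-specific plantings elevate marker (0.15–0.3) and causal
  frequency only in one target population and label the VDA with that
  population's OMB group; other populations carry the marker at 0.01 with
  no causal coupling, mirroring population-specific linkage disequilibrium;
* **noise associations** (8): noncoding markers with no coding linkage, and
  5 coding VDAs that exist only to exercise the noncoding filter.

The generator defaults were fixed once, by Monte-Carlo over seed batches
(≥ 8 seeds per regime), to realize the qualitative regimes the method's
claims are stated in: at `linkage_fidelity = 0` the cohort mean AUC is
chance (≈ 0.49–0.50); at 0.5 it is ≈ 0.63; at 1 it is ≈ 0.72–0.73; with
fully ethnicity-specific plantings the ethnicity-specific evaluation beats
the non-specific one in every population (≈ 0.83 vs ≈ 0.70); and the core
category separates at Mann–Whitney p < 10⁻³ for all six methods. These
sizes (200 individuals × 60 drugs, 10–20 seeds) keep a full acceptance run
in the order of a minute while leaving the regimes' margins well clear of
their thresholds.

What passing these checks does **not** show: the generator has no
recombination maps, no demographic history, no realistic site-frequency
spectrum, no transcript structure, and its score distortions are far tamer
than real SIFT-vs-GERP disagreements. Results on it demonstrate that the
pipeline's arithmetic and logic behave as designed under the synthetic-
association mechanism — not that any particular real-data AUC is
reproducible, which depends on cohort, catalog and annotation scale.

## Design choices on open points

* **Non-SIFT retention** (above): the 0.7 cutoff applies to all methods'
  normalized scores; configurable via `cutoff`.
* **Variant identity**: rsID when present on a biallelic record, else
  `chrom:pos:ref:alt` (1-based); multiallelic records are decomposed per
  ALT allele and always keyed positionally, since one rsID cannot name two
  ALT alleles unambiguously.
* **Multi-gene variants**: one annotation row per (variant, gene) pair; a
  variant in two genes contributes to both burdens.
* **Missing scores**: a variant without a raw score for a method is simply
  absent from that method's burdens — no imputation — so per-method burdens
  are comparable only in composition, not coverage.
* **Degenerate inputs**: an unbounded method whose observed scores are all
  equal is an error (no scale to normalize over); an empty drug gene set is
  an error (the drug universe is defined as drugs with ≥ 1 PK/PD gene);
  `L` outside `[0, |D|]`, an empty gold standard, or a gold standard equal
  to the drug universe are errors (the rank statistics are undefined).
* **VDA ethnicity labels** are taken per record as authoritative;
  conflicting aggregate counts in curated catalogs are not reconciled.

## Limitations

Dosage-blindness (a homozygous damaging variant counts once), equal gene
weighting within a drug (no PK-parameter weighting of edges), no
transcript-level annotation, and no evidence-level weighting of VDAs are
all deliberate scope limits of the score as implemented. The per-individual
AUC also treats every gold-standard drug as equally "true", which inherits
whatever curation bias the catalog carries.
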