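# hmexome

Family-based exome variant prioritization for high-myopia cohorts.

## The problem

High myopia (HM; spherical equivalent ≤ −6.00 D and/or axial length
> 26.00 mm) is strongly heritable, but only a minority of families carry
mutations in the known HM genes. Studies that exome-sequence multiplex HM
families face the same funnel: hundreds of thousands of called variants per
family must be reduced to a handful of credible candidates using consequence
and population-frequency filters, inheritance-model genotype filters,
pedigree cosegregation, and aggregated in-silico pathogenicity evidence.

`hmexome` packages that workflow for geneticists who want it reproducible
and testable:

* **Filter cascade** (`run_cascade()`), per (family, variant) candidate:
  1. exclude non-exonic, non-splice consequences;
  2. exclude synonymous variants (splice-altering synonymous changes are
     labelled `splice_site` upstream and survive);
  3. exclude variants with MAF ≥ 0.01 in any of ExAC / 1000G / gnomAD
     (boundary inclusive, absent frequencies never exclude);
  4. per family, keep variants heterozygous in all affected members of
     autosomal-dominant (AD) families and homozygous in all affected members
     of autosomal-recessive (AR) families; then exclude de novo variants
     (carrier child, both parents genotyped hom-ref).
  Every stage is audited in a conservation-checked funnel.
* **Cosegregation** (`cosegregates()`): AD — affecteds het, unaffecteds
  non-carriers; AR — affecteds hom-alt, unaffecteds not hom-alt (obligate
  het carriers allowed). Members with unknown status or missing genotypes
  never veto.
* **Evidence scoring** (`evidence_matrix()`, `rank_candidates()`): eleven
  binary categories in five groups — gene-level filter condition (known HM
  gene, HM-related, ocular-disease gene, mapped MYP locus), pathogenicity
  (more than two of ten prediction tools damaging; DANN ≥ 0.90 counts as a
  call, PolyPhen-2 HDIV/HVAR collapse to one tool), annotation
  (protein-altering vs not), ocular expression (adult, embryonic) and
  frequency (novel vs rare, i.e. < 1/1000 in every reporting database). The
  weighted total (configurable weights) ranks candidates; ties break by
  rarity, gene, then variant key.
* **ACMG-lite labels** (`acmg_evidence()`): PM2 (novel/rare), PP1
  (cosegregates), PP3 (multi-tool damaging), combined to a classification.
* **Clinical summaries** (`family_summary()`, `count_hm_families()`,
  `is_high_myopia()`) over per-eye SE/AL measurements.
* **Synthetic cohorts** (`simulate_cohort()` / `emit_cohort()`): gene-drop
  simulation of multi-family VCF/PED/annotation/clinical/gene-set fixtures
  with one spiked causal variant per family and known ground truth, so the
  whole pipeline is testable without any external data.

## Worked example

Simulate a 6-family cohort (4 AR / 2 AD, 50 background variants per family,
one spiked causal variant each) and run the pipeline on the emitted files:

```r
library(hmexome)
params <- sim_params(n_families = 6, n_ar = 4, n_ad = 2,
                     n_background = 50, seed = 7)
sim <- emit_cohort(params, "hm_demo")
run <- run_pipeline(sim$files$vcf, sim$files$ped, sim$files$annotations,
                    sim$files$gene_sets, out_dir = "hm_demo/out")
funnel_report(run, top_k = 5)
```

```
Filter cascade:
  exonic          input     34  kept     25  removed      9
  synonymous      input     25  kept     21  removed      4
  frequency       input     21  kept     18  removed      3
  genotype_model  input     18  kept      7  removed     11
  de_novo         input      7  kept      7  removed      0
Cosegregating: 7   non-cosegregating: 0
Top 5 ranked candidates:
   1. F002   BSG        19:183912938:G:T       score  6.00  novel         uncertain_significance
   2. F006   CTSH       22:41646648:C:T        score  6.00  novel         uncertain_significance
   3. F005   FNDC3B     17:176317888:C:A       score  6.00  novel         uncertain_significance
   4. F003   SCO2       18:28755306:A:G        score  6.00  novel         uncertain_significance
   5. F001   LRPAP1     4:158905672:G:C        score  5.50  rare          uncertain_significance
```

Reading the output: 34 (family, variant) candidate pairs carried an
alternate allele; 9 were non-exonic, 4 synonymous, 3 too common (MAF ≥
0.01), and 11 inconsistent with their family's inheritance model; none were
de novo. All 7 survivors cosegregate. The spiked causal variants score ~6
(known-HM gene + ocular expression + multi-tool damaging + protein-altering
+ novel/rare) and rank first in all 6 families; the best background variant
scores 2. With only PM2/PP1/PP3 available, every non-empty tag set maps to
`uncertain_significance` by design.

HGVS codon arithmetic is also exposed directly:

```r
check_protein_consistency("c.904C>T", "p.R302C")
#> [1] TRUE
```

A command-line front end with `simulate`, `run`, `summarize-clinical` and
`check-hgvs` subcommands lives in `inst/cli/hmexome.R` (see `?hm_cli`).

## Layout

* `R/` — implementation; `tests/testthat/` — unit, property and acceptance
  suites (`test-acceptance.R` holds the acceptance criteria).
* `vignettes/prioritization-methods.Rmd` — model, assumptions, parameter
  rationale, simulator scope, limitations.
* `inst/extdata/` — the cohort clinical table and reported-variant HGVS
  pairs used as fixtures.
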