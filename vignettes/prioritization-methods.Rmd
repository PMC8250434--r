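---
title: "Methods: family-based exome variant prioritization for high myopia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: family-based exome variant prioritization for high myopia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hmexome)
```

## The model and its assumptions

`hmexome` implements a deterministic, rule-based prioritization of candidate
disease variants in multiplex high-myopia (HM) families. It is not a
statistical model: every stage is a predicate with published or conventional
boundaries, and the package's job is to apply those predicates exactly,
audit them, and make them testable.

The unit of analysis is the *(family, variant) candidate*: a biallelic
variant enters a family's funnel when at least one genotyped member carries
its alternate allele. The cascade then applies, in order:

1. **Consequence.** Keep `missense`, `nonsense`, `frameshift`,
   `inframe_indel`, `splice_site`; remove `intronic`, `utr`, `intergenic`,
   `other`. The consequence class is taken from the annotation table as
   authoritative — this package does not re-run splice predictors, so a
   synonymous change that alters a splice region must arrive labelled
   `splice_site` (the scheme is single-label; this is stated in the format
   contract of `read_annotation_table()`).
2. **Synonymous exclusion.** Remove `synonymous`.
3. **Frequency exclusion.** Remove when MAF ≥ `maf_exclusion` in *any* of
   ExAC, 1000G or gnomAD. The boundary is inclusive; a frequency absent from
   a database can never exclude, because absence of evidence is the
   signature of a novel variant.
4. **Inheritance-model genotype filter.** One model per family: autosomal
   dominant (AD) if any affected member has an affected parent, else
   autosomal recessive (AR); an explicit per-family override is accepted.
   AD keeps variants heterozygous in *all* genotyped affected members, AR
   keeps variants homozygous-alternate in all genotyped affected members.
   Missing genotypes never veto — the rule is evaluated over genotyped
   members only, because vetoing on missingness would discard every
   partially genotyped family. A family with no genotyped affected member
   removes the candidate with reason `untyped`.
5. **De novo exclusion**, run after the model filter (matching the order in
   which the source workflow states it): a candidate is de novo when an
   affected non-founder carries the allele while *both* parents are
   genotyped and homozygous reference. A missing parental genotype is
   conservative — de novo cannot be asserted.

Every removed candidate records exactly one earliest removal stage; the
funnel satisfies `kept + removed = input` at each stage and chains stage to
stage. These invariants are property-tested on simulated cohorts.

**Cosegregation.** Survivors are tested across all genotyped members.
AD: every genotyped affected heterozygous *and* no genotyped unaffected
carries the allele. AR: every genotyped affected homozygous-alternate and no
genotyped unaffected homozygous-alternate — heterozygous unaffected carriers
are explicitly permitted, because the parents of an AR proband are obligate
carriers; a no-carrier reading of "absent from unaffected members" would
make AR segregation biologically impossible for parent-transmitted
homozygotes. Members of unknown status are segregation-neutral: a
teenage sib at −3 D is at risk, neither evidence for nor against.

**Affection status.** Declared status wins when present. Otherwise the
worst-eye rule applies: affected iff the worse eye's spherical equivalent
(SE) is ≤ −6.00 D (inclusive) or the longer eye's axial length (AL) is
> 26.00 mm (strict); unaffected iff both eyes' SE are measured and |SE| <
2.00 D; otherwise unknown. The worst-eye rule deliberately counts
anisometropic members with a single qualifying eye as affected.

**Evidence scoring.** Eleven binary categories in five groups: gene-level
filter condition (known HM gene, HM-related gene, ocular-disease gene,
mapped MYP locus), pathogenicity (more than two damaging tool calls),
annotation (exonic protein-altering vs non-protein-altering — mutually
exclusive, exactly one true), ocular expression (adult, embryonic) and
frequency (novel vs rare — mutually exclusive, both false for
low-frequency). Because two pairs are exclusive, no candidate can set all
eleven bits; the maximum distinct-bit total under default weights is 9.

**ACMG-lite.** Three evidence codes only: PM2 (novel or rare), PP1
(cosegregation), PP3 (computational support). One moderate plus two
supporting criteria cannot reach likely-pathogenic under the published
combining rules, so the default mapping sends any non-empty tag set to
`uncertain_significance` and the empty set to `likely_benign`. The mapping
is configuration (`acmg_map`), so a site that wants to encode local policy
can override specific tag sets. A full 28-criterion engine is a non-goal.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `maf_exclusion` | 0.01 | allele fraction | cascade exclusion bound, inclusive |
| `rare_maf` | 0.001 | allele fraction | "rare" = < 1/1000 alleles in every reporting database, strict |
| `dann_damaging` | 0.90 | score | DANN publishes no call; the workflow this reproduces treated scores ≥ 0.915 as damaging, so 0.90 is the smallest round threshold consistent with that usage |
| `min_damaging_tools` | 3 | tools | "more than two tools" read strictly as count > 2 |
| `unaffected_se_max_abs` | 2.00 | D | unaffected definition (both eyes within ±2 D) |
| `hm_se_max` | −6.00 | D | HM inclusion, boundary inclusive |
| `hm_al_min` | 26.00 | mm | HM inclusion, boundary strict |

Category weights default to 1.0 except `non_protein_altering` (0.0 — the
annotation pair is exclusive and only protein-altering status is credited)
and `freq_rare` (0.5 — rare is weaker evidence than novel). The source
workflow publishes no numeric score scale, so the weights are configuration,
chosen once to reproduce its qualitative outcome (top candidates are
protein-altering, multi-tool damaging and novel/rare) and not revisited.
PolyPhen-2's two submodels are collapsed to one tool for counting
(`collapse_polyphen = TRUE`) because pathogenicity summaries conventionally
report "PolyPhen-2" once; both columns are preserved in the data.

Ranking ties break deterministically: ascending maximum present database
MAF with absence coded −1 (novel sorts before rare), then gene symbol, then
variant key. Permuting the input never changes the order.

Configuration files are JSON (`read_config()`), with precedence CLI flag >
file > built-in default.

## The synthetic cohort: what it emulates, what it does not

`simulate_cohort()` generates the stated world the tests run in: 27
families, 18 AR / 9 AD, pedigree templates cycling trio / quartet /
three-generation, one causal spike per family, 200 family-private background
variants per family. Phenotypes: affected SE from a truncated normal (mean
−10 D, sd 3, at most −6 D) with per-eye jitter, unaffected SE within ±2 D,
and AL = 23.5 − 0.3·SE + N(0, 0.3) mm — parameters chosen once so simulated
per-family summaries fall in the range the cohort's clinical table prints
(SE medians roughly −6 to −20 D, AL roughly 25–31 mm).

Background database frequencies follow a four-class mixture (novel / rare /
low-frequency / common, equal weights). Transmission, however, uses a
*latent cohort founder frequency* drawn log-uniform on 0.005–0.05,
independent of the database class: at database-scale frequencies (≤ 10⁻³)
essentially no background variant would ever appear in a 3–5-member family,
and the genotype-model, cosegregation and ranking stages would never be
exercised against background. The latent frequency stands in for the
enrichment of an ascertained regional cohort relative to global databases.
Background gene-evidence bits are sprinkled at 0.05 per bit so background
occasionally mimics causal evidence and ranking must separate signal by the
joint profile.

Causal spikes are constructed, not sampled: AD — affected het, unaffected
hom-ref; AR — affected hom-alt, obligate-carrier parents het, carriership
propagated upward so no carrier is Mendelian-impossible. All randomness
flows from a single stream seeded by `sim_params(seed=)`; equal parameters
give byte-identical emitted files.

What a green test therefore establishes: the pipeline's predicates,
bookkeeping and ranking behave exactly as specified on Mendelian-clean,
construction-faithful data, and causal recovery is robust to the modelled
annotation noise. What it does not establish: performance under genotyping
error, allelic dropout, linkage disequilibrium, population stratification,
compound heterozygosity, reduced penetrance or phenocopies — none of which
the generator models.

## Numerical and degenerate-input choices

* Coordinates are 1-based throughout, as in VCF; no half-open intervals.
* Multi-allelic records are decomposed one alternate per record; for a
  decomposed record, alleles of a *different* alternate count as reference
  (the cascade reasons per alternate allele), and any missing allele makes
  the genotype missing. Decomposition conserves total non-reference allele
  observations (property-tested).
* Chromosome labels are normalized by stripping a leading `chr`; X/Y stay
  letters. The analysis is autosomal; X-linked models are out of scope.
* A VCF variant without an annotation row keeps absent frequencies and an
  all-missing prediction profile but carries consequence `other`: it enters
  the funnel (it is counted, not silently dropped) and is removed at the
  consequence stage, since its class cannot be evaluated.
* Empty candidate sets yield all-zero funnels, empty partitions and
  header-only reports; degenerate clinical ranges (`x/x`) are accepted.
* The shipped 27-family clinical table is stored verbatim. One printed row
  (family 113) has medians outside its printed ranges in both SE and AL;
  `check_clinical_consistency()` flags it and the test suite asserts it is
  the *only* inconsistent row rather than editing source data.
* HGVS support is deliberately minimal: single-nucleotide substitutions in
  both the standard (`c.904C>T`) and transposed (`c.G848A`) spellings.
  Consistency checking is pure codon arithmetic
  (`floor((pos − 1)/3) + 1 == residue`); amino-acid identity is not
  verified because no transcript sequences ship with the package.

## Known limitations

* Compound-heterozygous AR candidates are not modelled (the model filter
  requires homozygosity), and there is no genotype-quality (GQ/DP)
  filtering, CNV handling or statistical linkage (LOD) support.
* The evidence weights are conventions, not estimates; different weightings
  reorder mid-table candidates even though the fully-evidenced spikes stay
  on top.
* The strict `< 0.001` rarity rule intentionally classifies a 0.0014-MAF
  variant as low-frequency even where a source text calls it "rare"; the
  discrepancy is documented rather than reconciled.
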