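# lofprior

Rare loss-of-function variant prioritization for congenital left-sided
cardiac lesions (LSLs: hypoplastic left heart syndrome, aortic stenosis,
coarctation of the aorta, mitral stenosis, Shone's complex).

## What it does

Isolated left-sided lesions rarely follow simple Mendelian inheritance, so
single-family linkage is underpowered. `lofprior` implements a cohort-scale
discovery funnel for exome data that narrows hundreds of thousands of
variant calls down to a handful of candidate genes:

1. **Site quality control.** SNVs fail on posterior probability < 0.95,
   depth < 10x, < 3 variant reads, allelic fraction < 10%, >= 99% of reads
   on one strand, or a homozygous-reference call under 6x; indels
   additionally fail under 30x depth or 30% allelic fraction.
2. **Conservative LOF annotation.** Only three classes count as
   loss-of-function: premature stopgains in a non-terminal coding exon,
   disruptions of essential splice sites (the two intronic bases flanking
   each exon) used by *all* gene isoforms, and frameshift indels mapping to
   all isoforms. Damaging non-synonymous (DNS) variants are missense calls
   flagged damaging by >= 3 of 6 predictors (SIFT, PolyPhen2-HDIV, LRT,
   MutationTaster, MutationAssessor, FATHMM); CADD is carried along but
   never used to exclude.
3. **Gene constraint (OP ratio).** For each gene, every possible
   single-nucleotide substitution across its exonic regions and essential
   splice sites is enumerated and classified; the ratio of LOF alleles
   *observed* in a comparison cohort to *potential* LOF sites ranks genes,
   and genes with OP ratio zero or in the lowest 30th percentile are
   flagged as constrained.
4. **Rarity and recurrence.** The LOF discovery arm keeps variants absent
   from the internal comparison panel (case-exclusive) with all public-panel
   MAFs < 0.5%; the DNS arm accepts internal MAF < 0.05%. LOF sites seen in
   more than two cases are pruned as likely stratification artifacts.
5. **A-priori candidate intersection.** Survivors are intersected with an
   independently compiled cardiac candidate gene list (human CVM genes,
   mouse/zebrafish models, TGF-beta / PITX2 / SHH / NOTCH pathways).
6. **Trio segregation.** Each candidate is classified from parental
   genotypes: de novo, inherited dominant, recessive (homozygous or
   compound heterozygous in trans), X-linked, or unknown (single
   non-carrier parent available).
7. **Working-gene expansion and clinical enrichment.** Genes with de novo
   LOF gain their rare DNS variants as expansion candidates, case variants
   are cross-referenced against known-pathogenic tables (ClinVar/HGMD-style)
   with internal-panel tiers, and carrier status is tested for cardiac
   phenotype enrichment in a clinical cohort via a 2x2 odds ratio with a
   Wald confidence interval.

A first-class synthetic-data module generates every input the funnel
consumes — a multi-isoform toy genome, planted variants of each consequence
class with machine-readable truth tables, trio genotypes realizing each
inheritance mode, frequency panels, predictor tables — so the entire
pipeline is testable end to end with no external downloads.

## Worked example

The package ships its discovery-cohort worked example as a plain-text gene
table (`inst/extdata/discovery_genes.tsv`) that the fixture builder expands
into a complete input set (toy genome, 342-case VCF, trios, panels,
predictor calls, clinical flags):

```r
library(lofprior)
fx  <- discovery_cohort_fixture()
rep <- run_discovery_pipeline(fx$config, verbose = FALSE)
rep
#> Discovery report: 27 candidate gene(s), 27 LOF variant(s) in 25 case(s) (7.3% of 342)
#> Inheritance modes:
#>              de_novo   inherited_dominant recessive_homozygous
#>                    9                   13                    1
#>              unknown             x_linked
#>                    3                    1
#> Clinical-cohort enrichment OR = 4.03 (95% CI 2.56-6.33)
```

27 candidate genes carry case-exclusive LOF alleles; nine arose de novo,
one is recessive (homozygous), one X-linked (maternally transmitted
hemizygote), and three have unknown inheritance (one available non-carrier
parent). The working-gene expansion recovers three additional de novo DNS
variants (`rep$expansion`), and carriers of LOF variants in the candidate
genes are about four times as likely to show a cardiac phenotype in the
clinical cohort (`rep$enrichment`). The gene table lists two case IDs
twice, so 27 variants fall in 25 distinct carrier cases (7.3% of the
cohort); see the methods vignette for a note on this tally.

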