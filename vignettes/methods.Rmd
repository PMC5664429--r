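---
title: "Methods: rare-LOF prioritization for left-sided cardiac lesions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rare-LOF prioritization for left-sided cardiac lesions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lofprior)
```

## The problem and the model

Congenital left-sided cardiac lesions (LSLs) are strongly heritable but
rarely Mendelian in isolated form, so the package takes a cohort-scale
burden-of-evidence approach rather than a segregation-based one: find
extremely rare alleles of the most damaging functional class, require the
hit gene to carry prior developmental evidence, and then ask (a) how each
allele segregates in the proband's trio and (b) whether loss-of-function
in the same genes predicts cardiac phenotypes in an independent clinical
cohort. No multiple-testing machinery is involved because the funnel is a
filter cascade, not a hypothesis scan.

The statistic at the core of the gene-level step is the **OP ratio**:

$$\mathrm{OP}(g) = \frac{\text{LOF alleles observed in a comparison
cohort}}{\text{potential LOF substitution sites enumerable in } g}$$

The denominator is computed by exhaustive simulation: every position in
the gene's exonic union plus its essential splice positions is substituted
with each of the three non-reference bases, each substitution is pushed
through the same consequence classifier used for real variants, and the
(position, alt) pairs that qualify as conservative LOF are counted. The
numerator counts alleles (het = 1, hom = 2, hemizygous = 1); the ratio
therefore mixes units and is used **only ordinally** — genes are ranked,
and "constrained" means an OP ratio of zero or a percentile at or below 30.
Percentiles use strict "less than" with ties sharing the lower rank, and
the threshold comparison is inclusive: with ten genes at distinct ratios
the percentiles are 0, 10, ..., 90, so the lowest four (percentile
$\le 30$) are flagged. Constraint is advisory by default (a flag on the
candidate table); a strict mode drops unconstrained genes.

One wording ambiguity deserves a note: the enumeration is described as
covering "exonic regions", yet splice LOF sites are by definition the two
intronic bases flanking each exon. Since splice disruption is one of the
three LOF classes being counted, the enumeration domain here is the exonic
union **plus** all essential splice positions; a two-exon single-isoform
gene whose CDS cannot reach a stop codon by any single substitution has
exactly $4 \times 3 = 12$ potential LOF sites, all splice-class.

## Conservative LOF and consensus DNS

A variant is conservative LOF only if it falls in one of three classes,
each evaluated against the gene's full isoform set:

* **stopgain_lof** — a premature stop in a *non-terminal coding exon*,
  required in every isoform whose CDS contains the position (isoforms not
  covering the position are ignored; the `stopgain_all_isoforms` switch
  relaxes "every" to "any");
* **splice_lof** — the position is within the essential splice set (donor
  +1/+2, acceptor −1/−2) of **every** isoform of the gene;
* **frameshift_lof** — a length change not divisible by 3 disturbing the
  CDS of every coding isoform.

Start-loss, stop-loss and multi-nucleotide substitutions are classified
`other` and never LOF — they are not in the enumerated classes. DNS
(damaging non-synonymous) is evaluated only for non-LOF variants that are
missense in at least one isoform: at least 3 of the 6 categorical
predictor calls must be damaging, with missing calls counting as not
damaging. The threshold is a config integer (`dns_min_damaging`); the CADD
score is joined for reporting but never filters. A variant can therefore
never be both LOF and DNS.

Stopgain classification mutates the codon in CDS coordinates and compares
translations, so a stop-to-stop change in the terminal codon is
synonymous, and a substitution destroying the terminal stop is `other`
(stop-loss), not a stopgain.

## Rarity tiers, recurrence, and the two arms of the funnel

Frequency panels are consumed as allele counts; a variant absent from a
panel has frequency zero there. Tiers:

* `case_exclusive` — zero alt alleles in the internal comparison panel and
  all public-panel MAFs < 0.5%;
* `rare` — internal MAF < 0.05% and all public MAFs < 0.5%;
* `common` — everything else.

The LOF discovery arm admits only `case_exclusive` variants; the DNS and
known-pathogenic arms accept `rare` as well. LOF sites carried by more
than two cases are pruned (occurrences count carrier cases, not alleles —
a homozygote is one observation) as a guard against ethnic stratification
rather than a statistical test.

## Trio segregation

Inheritance labels are genotype-only: parental cardiac status is not
modeled, and a de novo call assumes parental genotypes are correct
(mosaicism is out of scope). For a carrier proband with both parents
available: het with two non-carrier parents is `de_novo`; het with a
carrier parent is `inherited_dominant` (both parents carrying is still
dominant, with unresolvable origin); hom-alt with two carrier parents is
`recessive_homozygous`; impossible transmissions (hom-alt proband with a
non-carrier parent, het proband with two hom-alt parents) are
`mendelian_error`. With exactly one parent available, a non-carrier parent
gives `unknown` and a carrier parent `inherited_dominant`; with no parents
the call is `unresolved`. On the X in a male proband the allele is
hemizygous: a carrier mother with a non-carrier (or absent) father gives
`x_linked`; the father's genotype never transmits. Compound heterozygotes
require trans proof from parental genotypes — two het variants in one
gene, one carried by the mother only and one by the father only; cis or
ambiguous pairs are not emitted. Female X probands follow autosomal rules.

## Clinical-cohort enrichment

Carrier status (any LOF in a candidate gene) versus cardiac phenotype in
the clinical cohort forms a 2×2 table. The default comparison group is the
**whole cohort** — with the worked example's counts this gives
$(34 \cdot 4023)/(45 \cdot 755) = 4.03$ — because that construction
reproduces the published point estimate; carriers-vs-noncarriers is
exposed as an option. The confidence interval is Wald on the log odds
ratio ($\pm 1.96\,\mathrm{SE}$, Haldane–Anscombe 0.5 correction when a
cell is zero). On these counts Wald gives 2.56–6.33, which brackets but
does not exactly match the interval printed in the source tables
(2.5–6.47, method unstated); the interval is therefore reported but not
treated as a reference value.

## The synthetic-data generator

`sim_spec()` defaults encode the study conditions at desk scale: a
342-case cohort, an internal comparison panel of 10,984 alleles (5,492
individuals), public panels with 1000-Genomes/ESP/ExAC-like allele totals,
and a 50-gene genome (≤ 3 isoforms, 2–6 exons of 4–8 codons, introns of
30–80 bp, ~10% of genes on X) small enough that every brute-force oracle
can run exhaustively. Planted classes include the negative controls the
LOF rules must reject: terminal-exon stopgains, partial-isoform splice and
frameshift variants, in-frame deletions, 2-of-6 missense, recurrent LOF
(three carriers), and LOF in genes outside the a-priori list.

Two deliberate simplifications:

* **Phase-0 introns.** Every exon's CDS length is a multiple of 3, so an
  isoform that skips an internal exon keeps frame and shares the remaining
  codons with the full isoform; open reading frames are stop-free in all
  isoforms by construction. Real genes splice mid-codon; the classifier
  itself does not rely on codon-aligned exons (it maps genomic positions
  to CDS indices per isoform), but the generator never exercises
  phase-1/2 junctions.
* **Threshold-straddling frequencies.** Panel counts are placed just
  inside or outside the rarity thresholds rather than drawn from a
  realistic site-frequency spectrum, and sequencing artifacts (coverage
  bias, strand artifacts, genotyping error) are not simulated. Passing
  tests therefore demonstrate that the decision rules are implemented
  exactly, not that the pipeline is robust to noisy real-world calls.

All generators are deterministic under the seed (byte-identical outputs),
and every truth-table row is asserted to be realized in the emitted files.

## The worked-example fixture

`discovery_cohort_fixture()` expands the shipped 27-row discovery-gene
table into a complete input set: one case-exclusive non-terminal stopgain
per row (homozygous for the recessive row, hemizygous on X for the
X-linked row), trio genotypes realizing each tabulated mode, three rare de
novo DNS variants in the three expansion genes, funnel negative controls,
a planted known-pathogenic table with 14 case-exclusive / 15 MAC < 5 / 14
internally-too-common entries, and clinical flags with 79 carriers (34
with a cardiac phenotype) among 4,778 samples.

One inconsistency is inherited from the source tables and left visible:
the gene table lists 27 variant rows but two case IDs appear twice, so 25
distinct cases carry candidates (7.3% of 342), while the prose summary of
the same study reports 26 carriers (7.6%) and "one case with two distinct
variants". The fixture reproduces the table literally; the pipeline
reports what the table implies, and the expected-report object records
both tallies.

## Numerical choices and degenerate inputs

* Coordinates are 1-based inclusive throughout (VCF/GTF convention);
  orientation is applied only when building nucleotide strings.
* Cohort percentages round half away from zero to one decimal.
* Missing quality metrics fail the corresponding QC rule (reason
  `missing_metric:<rule>`) rather than passing silently; the allelic
  fraction rule applies to all non-homref calls, homozygous-alt included.
* Multi-allelic sites are decomposed to biallelic records preserving
  per-sample alt counts; indels are trimmed to minimal anchored form.
* Genes with zero potential LOF sites are excluded from percentile
  ranking (constraint stays `NA`); an all-`NA` universe is an error.
* An insertion counts as CDS-disturbing only when it lands strictly
  inside a CDS interval; a deletion, when its post-anchor span intersects
  one.
* Problem sizes in the test suite (50-gene genomes, 60–342 cases, 560
  trios, 20-gene brute-force enumeration) were chosen so every exhaustive
  oracle runs in seconds while still exercising multi-isoform, minus-strand
  and X-chromosome paths.

## Known limitations

No NMD-escape modeling, no splice-strength scoring beyond the ±2 essential
positions, no mutation-rate weighting or pLI-style expectation model
behind the OP ratio, no read-backed or statistical phasing (trans calls
need parental genotypes), no ancestry inference, and no burden testing.
The a-priori gene list is consumed as a static file; building it from OMIM
/ KEGG / MGI / ZFIN is out of scope.
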