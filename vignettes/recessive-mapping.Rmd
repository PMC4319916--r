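---
title: "Mapping a recessive lethal in a small pedigree: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping a recessive lethal in a small pedigree: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scdmap)
```

`scdmap` implements the positional-cloning workflow that identified a
single-base coding deletion in canine *HES7* as the cause of autosomal
recessive spondylocostal dysostosis (SCD4) in a miniature schnauzer
family: a severely underpowered family GWAS rescued by a top-K
chromosomal enrichment heuristic, candidate-region variant filtering
through cross-species synteny and model-organism phenotype annotation,
frameshift consequence prediction, a PCR-RFLP diagnostic assay, and
pedigree segregation plus case-control association. This vignette
explains the statistical models, the tunable parameters, what the
synthetic-cohort generator does and does not emulate, and the design
choices made where the design was genuinely open.

## The mapping problem

A single litter of eight pups, three of them stillborn with severe
axial-skeleton malformation, is far below the sample size at which a
genome-wide association scan has conventional power. With three cases
and seven relatives as controls, the largest allelic chi-squared
statistic that any biallelic marker can attain is bounded by the allele
counts alone ($N = 20$ alleles gives $\chi^2 \le 20$), and markers in
perfect linkage with a recessive causal allele do not stand out
individually from relatedness-driven noise. The workflow therefore does
not look for a genome-wide significant marker. Instead it:

1. prunes markers on minor allele frequency ($\ge 0.1$) and
   missingness ($\le 0.2$),
2. computes a per-marker allelic chi-squared (each individual
   contributes two alleles; 2×2 table of allele counts, no continuity
   correction, df = 1),
3. ranks markers by p-value, takes the top $K = 100$, and asks which
   chromosome is over-represented among them — the arg-max chromosome
   becomes the candidate, and
4. refines the candidate interval as the span of markers with raw
   $p < 0.005$ on that chromosome.

The chromosomal enrichment step trades marker-level significance for a
coarser, more robust signal: a recessive haplotype shared identical by
descent across all affected individuals elevates a long run of linked
markers simultaneously, and runs are easier to detect than peaks.

### A sharp constraint on the control set

A point that shaped both the simulator and the interpretation of the
original design: among the seven controls, the two parents are always
carriers, and any further carrier control weakens every causally linked
marker *equally*. At a marker in complete linkage with the causal
allele, cases contribute 6 mutant alleles and each carrier control
contributes exactly one. With 4 carrier controls the statistic is
$\chi^2 = 8.57$ ($p = 0.0034$, just inside the 0.005 refinement
threshold); with 5 it drops to $7.01$ ($p = 0.0081$) and *no* linked
marker can pass refinement at all. The genotyped family mirrored here —
sire, dam, carrier maternal grandsire, one carrier aunt, and
non-carrier relatives — sits exactly at the workable boundary. This is
why `gwas_cohort()` selects those seven controls and why the simulated
pedigree fixes the carrier status of the grandsire's typed daughters
rather than drawing them.

## The association tests

`allelic_chi2()` uses the closed form
$\chi^2 = N(ad - bc)^2 / ((a{+}b)(c{+}d)(a{+}c)(b{+}d))$ on the 2×2
allele table and evaluates the upper tail in log space
(`pchisq(log.p = TRUE)`), so p-values on the $10^{-36}$ scale retain
full relative precision. On the published assay counts — cases
(0, 0, 3), controls (126, 4, 0) — it gives $\chi^2 = 157.14$ (df = 1),
$p = 4.759\times10^{-36}$.

`genotypic_chi2()` is the companion 2×3 genotype-table test (df = 2
after dropping empty columns); on the same counts it gives exactly
133.0. The two are reported side by side because the original report
prints the statistic with a df = 2 annotation while the value and the
p-value it prints match the df = 1 allelic test; the package computes
both rather than guessing the intended notation.

No multiple-testing correction is applied anywhere, matching the use of
raw p-values throughout the original analysis; the scan reports raw
p-values and leaves genome-wide correction as metadata for the reader.

## The synthetic cohort generator

The generator's job is to produce cohorts with the statistical
structure this analysis assumes, at desk scale, with a truth record so
that recovery can be scored. Its defaults are the study conditions:

* a three-generation pedigree in which two unrelated carrier lineages
  converge — an imported carrier sire (a founder) and a carrier dam who
  inherits the allele from the carrier maternal grandsire — producing a
  litter of 8 by Mendelian transmission with full penetrance
  (affected ⇔ homozygous);
* 10 chromosomes of 8 Mb with 500 array markers each (~one marker per
  16 kb, the density class of a modern canine genotyping array), about
  5,000 markers in all;
* a founder haplotype pool of 6: haplotype 1 is the *disease
  haplotype*, private to the carrier founders; the other 5 form the
  breed background from which every other chromosome copy is mosaicked
  in blocks of mean 4 Mb (within-breed dog LD extends over megabases);
* 90% of markers are *haplotype-tagging*: their minor allele is private
  to one founder haplotype, emulating array content selected to tag
  breed haplotypes; the remainder segregate with a uniform frequency
  spectrum across the background pool;
* meiosis with ~1 crossover per 100 Mb and telomere-biased crossover
  placement (linear density rising from the chromosome centre), a
  pattern documented in canid genetic maps;
* a 2% missing-call rate, and an ascertainment switch (`ascertain =
  "affected"`) that redraws the litter until a minimum number of
  affected pups is reached — off by default, since the study family was
  described unconditionally.

Two deliberate simplifications deserve emphasis. First, each carrier
founder's copy of the causal chromosome is an intact disease haplotype
rather than a mosaic: the mutation is recent relative to haplotype
decay, so at the scale of one small chromosome the carriers' shared IBD
segment spans it. Second, LD is modelled by founder-haplotype block
copying, not by a coalescent: the analysis only needs tag-SNP structure
around an embedded locus, not a realistic ancestral recombination
graph. Consequently passing tests show that the *pipeline* recovers an
embedded signal of the assumed structure; they say nothing about allele
frequency spectra, population stratification, genotyping artefacts or
array ascertainment bias in real data.

Reproducibility: one user-facing seed drives every stage; each stage
derives its own stream seed from the config seed plus a stage label, so
any stage re-run in isolation is byte-identical to the same stage
inside `simulate_cohort()`.

```{r recovery, eval = FALSE}
rec <- recovery_experiment(50, sim_config(seed = 1))
colMeans(rec[c("causal_selected", "region_contains_causal",
               "causal_retained")])
```

The 50-cohort experiment above (the problem size used by the test
suite and the acceptance script) runs in well under a minute on one
CPU; the acceptance script reports the three recovery rates it
computes.

## Candidate-region variant filtering

`filter_cascade()` applies, in order: a quality-evidence filter (a
per-sample call with zero quality-passing reads is *unknown*, mirroring
the "(0/0)" convention of the published variant table; records with no
evidence anywhere are dropped), a homozygous-alt-in-affecteds filter
(unknown genotypes do not disqualify a candidate), exon intersection
(1-based inclusive; for an indel the affected bases exclude the VCF
anchor), restriction to genes carrying a matching model-organism
phenotype term, and cross-cohort exclusion of variants seen homozygous
in other breeds. The three record-level filters are order-commutative,
and every stage reports input = retained + removed audit counts.

Synteny mapping is linear interpolation within blocks: the original
analysis transfers Mb-scale spans between dog and mouse, for which
base-precise orthology is unnecessary. Phenotype matching is
case-insensitive substring search over free-text terms — a deliberate
stand-in for the manual genome-browser queries used originally; an
ontology walk is out of scope.

## Coding consequence prediction

`apply_cdna_variant()` edits a CDS in HGVS c. coordinates (c.1 = A of
ATG). Reference bases stated in the description are verified against
the transcript, and deletions/duplications are right-shifted to their
3'-most equivalent position *for reporting only*, per HGVS convention.
Translation uses the standard code and stops at the first in-frame
stop; a mutant with no stop is reported with Ter offset "?" rather than
an invented stop. The stop codon is never counted as a residue:
"a premature stop in place of residue 66" means mutant length 65 and
`p.(Thr43ProfsTer24)` with $24 = 66 - 43 + 1$.

The bundled example transcript is a **synthetic stand-in**: the
corrected canine *HES7* mRNA itself is not redistributed here, so
`synthetic_hes7_transcript()` provides a 4-exon, 1075-nt mRNA
constructed to satisfy every published constraint — a 224-residue
wild-type protein, c.126 a guanine in exon 2 whose deletion leaves
residues 1–42 intact, substitutes Thr43Pro and terminates at codon 66.
All worked examples hold on it exactly; sequence content away from
those constraints is arbitrary.

On NMD, the package applies the canonical 50-nt rule: a premature stop
escapes decay only in the last exon or within 50 nt of the final
exon-exon junction. For a stop at codon 66 of a 224-codon, 4-exon
transcript the rule predicts *targeting*, whereas the original
discussion argued decay would not occur. Because the real exon
structure is not tabulated in the report, the package does not
hard-code either conclusion: `predict_nmd()` returns the rule's verdict
together with the distance to the final junction, and the user can
supply the true exon lengths when they are known.

Domain disruption is classified positionally: a domain entirely before
the first altered residue is *intact*, entirely at or beyond the new
stop is *lost*, anything overlapping the altered interval is *altered*
(HLH 14–68 → altered, Orange 91–128 → lost for the example above).

## The PCR-RFLP assay

`digest()` scans both strands for the recognition site (IUPAC-aware)
and cuts at the enzyme's offset; fragments always sum to the input
length and digestion is strand-symmetric. When an enzyme table lacks
cut offsets the site midpoint is used — fragment lengths, not cut
chemistry, drive a gel assay. Band patterns within a relative
resolution tolerance (default 5%, appropriate to 1% agarose) co-migrate:
this is why a carrier shows three bands (578/472/107) rather than four
(579 and 578 are indistinguishable), and why an enzyme that cuts
neither allele is not called discriminating merely because a 1-bp
deletion changes the uncut product length.

One printed ambiguity is left unresolved on purpose: the disrupted
recognition sequence is printed as an 8-mer (TCCGCTCC) while the
enzyme's canonical site is the 6-mer CCGCTC it contains. The bundled
enzyme table carries the canonical site (used by all worked examples)
and also the printed 8-mer as a separate row; neither is asserted to be
the genomic truth. The worked-example amplicon is, again, a synthetic
construction (`synthetic_rflp_amplicon()`): a 579-bp wild-type sequence
with a single site cutting 107 bp from one end, and its 578-bp
deletion counterpart, verified site-free after the deletion.

## Pedigree segregation

`test_ar_segregation()` decides consistency with a fully penetrant
autosomal recessive model by exhaustive depth-first enumeration of
Mendelian-consistent genotype assignments (affected ⇔ homozygous,
unaffected excludes homozygous mutant, typed assay genotypes pin
individuals). Obligate carriers are the unaffected individuals
heterozygous in *every* consistent assignment — this captures not only
parents of affecteds but ancestors forced on every transmission path —
and possible allele sources are the founders that carry in at least one
assignment. Enumeration is exact and intended for family-scale
pedigrees (tens of individuals); kinship estimation, linkage LOD scores
and phasing are out of scope. X-linked and dominant models are not
tested: the mode is asserted recessive, with the flag reserved.

Penetrance is reported as the point estimate
(affected homozygotes / homozygotes) without an interval — the source
describes penetrance qualitatively, and an interval on 3 individuals
would suggest more precision than the data carry. Unknown-phenotype
individuals (e.g. stillborn but morphologically normal pups) are
excluded from concordance but retained for transmission checking.

## Numerical and convention choices

* Genotypes are alternate-allele counts 0/1/2 with `NA` for missing —
  PED/VCF semantics; assay genotypes use explicit labels.
* Positions are 1-based inclusive everywhere except exported BED
  (0-based half-open).
* Indels are VCF-style left-anchored; exon overlap is tested on the
  affected bases excluding the anchor.
* "Genotyping frequency less than 0.2" is interpreted as *remove
  markers with missing-call proportion above 0.2*, the semantics of the
  standard `--geno` filter in array QC tools.
* Minor alleles are defined on the pooled pruned dataset; ties at
  MAF 0.5 keep the input allele order.
* Ties at the k-th p-value in the top-K ranking are broken by
  (chromosome, position) so the enrichment table is permutation
  invariant.
* Degenerate inputs signal distinctly: an empty refined region, an
  undefined genotypic test after column collapse, undefined penetrance
  with no typed homozygote, Ter offset "?" for non-terminating
  frameshifts.

## Known limitations

The generator does not simulate reads, alignment or pileups (variant
read depths are drawn, not derived from sequences); breed demography
and realistic ancestral recombination are not modelled; phenotype
annotation is free text, not an ontology; and the two bundled sequence
fixtures are synthetic stand-ins constrained by published values, not
the original sequences. The genome-scale counts of the original study
(tens of thousands of markers and region variants) are represented
qualitatively by the generator's configurable, scaled-down counts; they
are not reproduced numerically.
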