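---
title: "Consensus A-to-I editing detection: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus A-to-I editing detection: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains what `edconsensus` computes, why its defaults are
what they are, what the synthetic-data generator does and does not emulate,
and where the genuinely open design choices were settled.

## The detection model

A-to-I editing is visible in RNA-seq as an A>G mismatch (T>C when the
edited transcript comes from the minus strand). Three signal sources mimic
it: genomic SNPs, sequencing errors, and alignment artifacts near splice
junctions, repeats and homopolymers. The package's premise is that no
single discriminator is reliable, but three *independent* ones rarely fail
together:

* The **hard-filter cascade** encodes prior knowledge: known-SNP catalogs,
  repeat annotation, a strand-bias test, a variant-allele-frequency (VAF)
  band, and junction proximity. It is precise but blind to anything its
  annotations miss.
* The **MI caller** encodes genetics: in a clonal cell line every read
  comes from one of two haplotypes, so the per-read alleles of two genomic
  het variants have high mutual information
  $I(X;Y)=\sum p(x,y)\log_2\frac{p(x,y)}{p(x)p(y)}$, while editing is a
  per-transcript Bernoulli event, independent of haplotype. A candidate
  whose mean MI against pairable known SNPs falls below the empirical
  $q$-quantile ($q = 0.05$) of the SNP–SNP null is accepted as editing.
  Candidates with no pairable SNP fall back to the VAF band. This is an
  empirical-quantile rule built on the stated MI principle; it does not
  reproduce any trained classifier, and the fallback means MI adds
  discrimination only where SNP density permits pairing.
* The **island caller** encodes biology: ADAR edits double-stranded RNA
  formed by inverted Alu pairs, so true sites cluster. Single-linkage
  clustering with gap ≤ 50 bp and ≥ 3 members defines islands; members are
  accepted outright, isolated sites only if the full cascade passes them.
  The gap and minimum-size values are package defaults chosen to match the
  densities real editing islands show (tens of sites per ~300 bp Alu);
  both are exposed in `filter_params()`.

Per replicate, only sites called by all three methods count; per cell
line, replicate sets are unioned (a union, not an intersection, because a
per-line site total should exceed each replicate's count — detection at
depth 30 is noisy and replicates rescue each other). A configurable
`min_replicate_support` (default 1) tightens this if desired. Finally only
A>G changes survive, with strand resolved through overlapping gene models;
intergenic sites keep whichever of A>G / T>C the plus-strand observation
already shows, reported with strand `"."`, since nothing anchors their
transcriptional direction.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `min_cov`, `min_alt` | 5, 3 | minimum coverage and variant reads for candidacy |
| `homopolymer_len` | 5 nt | run length treated as artifact-prone (±1 bp) |
| `vaf_low`, `vaf_high` | 0.10, 0.95 | inclusive VAF acceptance band; only strictly more extreme values are removed (hom-alt SNPs sit near 1, errors near 0) |
| `junction_dist` | 4 nt | splice-junction exclusion zone |
| `strand_bias_alpha` | 0.01 | two-sided Fisher exact threshold against the reference-read strand split |
| `island_gap`, `island_min_sites` | 50 bp, 3 | island clustering |
| `mi_min_shared`, `mi_null_quantile` | 5 reads, 0.05 | MI pairing floor and null quantile |

The base-quality floor (Q20) stands in for base-quality recalibration; it
is the standard desk-scale surrogate and configurable in `build_pileup()`.
PCR duplicates are defined by mapping locus — (contig, position, strand,
CIGAR) — not sequence identity, with a deterministic lexicographic
tie-break, and the count thresholds are applied uniformly upstream of all
three callers.

## What the generator emulates — and what it does not

`simulate_dataset()` reproduces the statistical structure the pipeline
assumes: several clonal cell lines from one parental genome, three
replicates each; a 200 kb contig with 40 multi-exon genes; 30 Alu-like
copies (alternating-orientation, 5–15% mutated copies of one consensus);
simple repeats and homopolymer runs as filter decoys; 150 SNPs (70% het,
phased onto two haplotypes, 80% present in the known catalog to model
dbSNP incompleteness); 60 island-resident plus 40 isolated editing sites;
editing levels `0.2 + 0.8·Beta(2, 5)` scaled per line by an ADAR-activity
factor (1 / 0.7 / 0.5), modelling reduced deaminase expression in derived
lines; depth 30 with error rate 0.001, spliced reads across introns, 2%
PCR duplicates. Haplotype phasing is essential, not decoration: without
it SNP–SNP mutual information would vanish and the MI caller would have
nothing to discriminate with.

Deliberate simplifications, which bound what passing tests show about real
data:

* Reads are emitted pre-aligned at their true positions; mapping error —
  a major FP source in practice — is out of scope, which is exactly why
  the junction/repeat filters look conservative here.
* Islands are planted in intergenic Alus and genic editing enters through
  isolated sites in genes whose edited/DEG labels are drawn with the
  configured odds ratio; this keeps the planted DEG–editing enrichment
  exact at the cost of not modelling genic Alu islands.
* Editing sites are planted at positions the annotation-based filters
  would not exclude a priori (outside homopolymers/simple repeats, > 4 nt
  from junctions), so recovery measures statistical misses rather than
  definitional ones — real sites inside such regions are invisible to this
  class of pipeline by construction.
* Island sites are planted with successive gaps kept below the clustering
  gap, emulating the density of real islands; sparse "islands" would
  degrade island-caller recall.
* Line-specific "novel" genomic SNVs feed only the DNA-level per-gene SNV
  counting; RNA reads come from the shared clonal genome.
* No indels, no quality-score model beyond a Q40 background with sprinkled
  Q10 bases, no hg19-scale genome.

## Numerical and degenerate-input choices

* Coordinates are 1-based closed everywhere inside the package (the
  R/Bioconductor convention); BED's 0-based half-open intervals are
  converted at the reader and nowhere else. One convention kills the
  dominant off-by-one bug class in this domain.
* The hypergeometric tail uses `phyper` (exact, log-space internally); the
  test suite checks it against exhaustive subset enumeration to 1e-12 for
  all universes up to 12 genes. The DEG caller is a deliberately
  transparent stand-in (Welch t on log2(x+1), BH, fold-change gate) — the
  scientific question here is the enrichment, not the DE engine, and an
  externally supplied DEG list can be used instead.
* Tri-allelic candidates keep the majority alternate allele, ties broken
  alphabetically; all tie-breaks in the package are deterministic, and
  every artifact is byte-identical under a fixed seed.
* `mi_score` uses the plug-in estimator with `0·log 0 = 0`; pairs sharing
  fewer than `mi_min_shared` reads are skipped, and a partner must show
  both alleles among the shared reads to be informative.
* Empty inputs propagate as empty, typed tables (header-only VCFs, empty
  SAMs, zero-row call sets), not errors, except where the contract demands
  an error (single-replicate DE, zero-coverage strand test, missing
  annotation tracks — which abort naming the track).
* The expressed-gene universe (nonzero mean expression) is the enrichment
  default: conservative relative to an all-annotated-genes universe,
  because unexpressed genes can be neither edited nor differentially
  expressed, and counting them inflates significance.

## Problem sizes used in validation

The recovery checks run the full pipeline on the default study conditions
(one 200 kb contig, depth 30, error 0.001, three replicates) for the
full-activity line, where planted editing levels are ≥ 0.2; sensitivity
≥ 0.8, precision ≥ 0.9 and ≥ 90% island-site recovery are required.
Enrichment behaviour is validated at expression-study scale (600 genes,
20 seeds): planted odds 4 must yield p < 1e-3 in ≥ 90% of seeds, planted
odds 1 must reject at the 5% level at roughly the nominal rate. The
multi-line set-algebra checks use a smaller 50 kb three-line study.

## Known limitations

* Alignment, realignment and recalibration are consumed, not performed;
  results on real data inherit whatever artifacts the upstream aligner
  leaves.
* The MI rule needs het SNP density comparable to the read length to beat
  its VAF fallback; sparse catalogs reduce the MI caller to a VAF filter.
* Strand assignment of intergenic sites is unresolved by design, so
  intergenic A>G/T>C counts cannot be split by editing strand.
* Detection, not differential editing: per-line consensus sets and their
  overlaps are reported, but no cross-line statistical test on editing
  levels is attempted.
* With the default ADAR-activity gradient the per-line consensus counts
  shrink only mildly, because depth-30 detection of levels ≥ 0.14 is
  still easy; emulating a strong loss of editing requires lower activity
  or lower coverage.
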