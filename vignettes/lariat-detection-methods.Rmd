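---
title: "Methods: lariat RNA detection, miRNA quantification and RIP occupancy"
author: "lariatseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lariat RNA detection, miRNA quantification and RIP occupancy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The experimental design being modelled

A debranching-enzyme hypomorph (*dbr1*) accumulates intron lariats because
the 2′–5′ bond between the branch-point adenosine and the intron 5′ end is
no longer hydrolyzed. Four RNA-seq library classes identify those lariats
genome-wide: genotype (wild type Col-0 vs *dbr1*) crossed with in-vitro
RNase R treatment (− / +), each replicated. RNase R degrades linear RNA
processively from the 3′ end but cannot engage a closed loop, so circular
species are enriched in the (+) libraries. Two companion assays complete
the design: small-RNA-seq of both genotypes (mature miRNA abundance) and
RIP-seq of the dicing-complex components DCL1 and HYL1 (pre-miRNA
occupancy).

This package implements the analysis of all three assays, plus a seeded
generator producing inputs with known ground truth so every stage is
verifiable.

# Quantification model

Coverage is per-base and per-strand; each alignment segment increments
every base it covers. Abundance of a feature of length $L$ in a library of
$N$ tags is computed through *read equivalents* $C/\ell$ (summed depth
over the feature divided by the read length $\ell$), giving

$$\mathrm{RPKM} = \frac{C/\ell \times 10^9}{L\,N}, \qquad
  \mathrm{RPTM} = \frac{\text{count} \times 10^7}{N}, \qquad
  \mathrm{TP10M} = \text{depth} \times \frac{10^7}{N}.$$

The coverage-to-count bridge is exact for reads fully contained in the
feature, which is also the read-selection rule: a read contributes to an
intron (or pre-miRNA, or gene) only when **every** segment lies inside the
feature on the matching strand — the strictest reading of "uniquely mapped
intronic reads". A configuration switch (`mode = "overlap"`) relaxes this
to any-overlap. Strandedness is on by default (the libraries are
stranded); an unstranded switch exists. `total_tags` counts reads, not
segments: a junction read is one tag.

Internally all intervals are 1-based closed `GRanges` — the native
R/Bioconductor convention; BED12/bedGraph adapters convert to 0-based
half-open at the file boundary, and SAM/GFF3 are 1-based already. Using
one internal convention, converted only at the boundary, prevents
off-by-one drift; choosing the Bioconductor one keeps every interval
operation on well-tested library code.

# The differential test

Enrichment is tested per intron with a two-group conditional
negative-binomial exact test, written in this package. Counts are scaled
to the geometric-mean library size, rounded, and summed within groups;
under the null the group-A sum given the total follows a negative
hypergeometric law with shapes $r_A/\phi$ and $r_B/\phi$ (replicates over
dispersion). Two-sidedness sums the probability of every outcome whose
mass does not exceed the observed outcome's mass; at $\phi = 0$ this is
exactly the binomial exact test. The common dispersion $\phi$ is a
method-of-moments estimate, $\max\{0, (s^2-\mu)/\mu^2\}$ per feature and
group, averaged **weighted by abundance**: a feature with a handful of
reads carries no information about the squared biological CV, and an
unweighted mean lets that noise dominate. Tests verify calibration under
an NB null, agreement with full enumeration at small totals, and exact
agreement with an independent small-p exact-test implementation at equal
library sizes.

Thresholds follow the printed rules and their printed inclusivity: RPKM
floors are inclusive (`>= 5`), the FDR cut strict (`< 0.05`), the RPTM
floor inclusive (`>= 100`), the occupancy fold-change cut strict
(`|log2| > 1`). The catalog flags nest by construction: wild-type
expressed ⊆ RNase-R-stable ⊆ enriched. Detectability in RIP is
implemented as `>=` with a strict-mode switch, since the source rules
print "more than 5 RPKM" in one place and "at least 5 RPKM" elsewhere; no
downstream check depends on the choice.

Gene-level testing reuses the same machinery with two standard
adaptations: reads must be mRNA-compatible (every segment within the
gene's exons — the union-exon rule), and library sizes are
composition-corrected by median-of-ratios. Both matter here for the same
reason: the mutant's lariat burden is a large RNA class that would
otherwise leak into gene counts and masquerade as global deregulation.
The intron test deliberately keeps raw total tags as library sizes —
median-of-ratios on intron counts would normalize away the lariat signal
itself, which is the quantity under test.

# Branchpoint junction detection

Reverse transcription runs across the 2′–5′ junction of a lariat, so a
junction-crossing read maps as two segments: one ending at the branch
point, one starting at the intron 5′ end (in cDNA the branch adenosine
reads as T). The detector requires both segments inside the same intron on
the same strand, with strand-aware ends; a branchpoint is called at the
modal candidate coordinate with at least `min_support = 2` reads, ties
resolved to the 3′-most coordinate (branch points sit near intron 3′
ends). This is the in-silico analogue of divergent-primer PCR, which
amplifies across a circular junction but not from a linear template.

# The synthetic-data generator

The generator is first-class, tested code. One base transcript pool per
seed is shared by both genotypes, so planted effects are the only
systematic differences:

* per gene, spliced mRNA (exon blocks) and a trace of unspliced pre-mRNA;
* per planted lariat intron, a circular loop spanning intron 5′ end →
  branch point; wild type carries it only for the escapee subset
  (`escape_fraction`, default 0.23), the mutant for all of them at
  `lariat_fold_dbr1` (default 8) times base;
* linear *decoys* (`debranched_intron`): intronic RNA accumulating in the
  mutant but RNase R sensitive;
* pre-miRNA hairpins (equal in both genotypes), mature miRNAs (mutant ×
  `mirna_reduction`, default 0.5), and rRNA removed by a ribo-depletion
  step of configurable efficiency (default 0.99).

RNase R digestion multiplies abundances by `survival_linear` (0.01) or
`survival_circular` (0.9) by topology. Branch points sit uniformly within
the final 10–50 bp of each intron (canonical plant positioning; placement
does not affect any tested statistic). The genome sequence carries GT
donors and a branch A per intron, but no further sequence realism (no
SNPs, no full splice-site motifs) — bookkeeping only.

Reads are drawn multinomially with weight abundance × length. Replicate
libraries additionally perturb each species' weight by a Gamma factor with
squared CV `bio_dispersion` (default 0.05), so replicate counts have
negative-binomial marginals; without it, any composition shift between
genotypes is infinitely significant under a Poisson null and no count test
can be calibrated. Lariat reads cross the junction with probability
`p_junction` (default 0.15) and are emitted as the two-segment records
described above; spliced mRNA reads span exon junctions as N-gapped
segments. All generators are pure functions of (configuration, seed), and
ground-truth manifests (planted lariats, branch coordinates, escapees,
decoys, deregulated genes, effect sizes) always accompany the reads.

## Compositional design of the study conditions

Sequencing is compositional: per-library read counts estimate *shares*,
not amounts. Three consequences shaped the default conditions, and they
are worth stating because they are properties of the assays, not of this
simulator:

1. A uniform two-fold miRNA reduction is invisible to RPTM normalization
   in a library containing only miRNAs. Real plant small-RNA libraries are
   dominated by siRNAs and fragments; the generator therefore plants a
   genotype-stable background (`simulate_srna_background()`, ~85% of the
   library), and the recovered median log2 ratio is slightly compressed
   (≈ −0.9 for a planted −1), exactly as depth renormalization predicts.
2. A uniform occupancy reduction in an IP library self-normalizes away if
   the IP target dominates the library. The generator models a
   genotype-equal nonspecific carry-over (`bg_ip_ratio`, default 9:1
   background:IP), which anchors the cross-genotype comparison; with no
   planted reduction the expected log2 ratio is exactly 0.
3. Absolute RPKM thresholds couple to read granularity: at the default
   depth (2 × 10⁵ reads/library) 5 RPKM on a 300-bp intron is 0.3 reads,
   so a single surviving read clears the RNase R(+) floor. The planted
   abundance scales (lariats high, decoys low, pre-mRNA trace) were chosen
   once so the printed thresholds separate the classes the way they did at
   the study's real scale; the compact genome (250 genes) inflates every
   share ~100-fold relative to a real transcriptome, and the defaults
   compensate for that, not for any test outcome.

## What passing tests do and do not show

The simulation preserves the *relationships* the analysis relies on
(circularity → RNase R resistance; mutant lariat over-accumulation;
escapee subset; junction-read geometry; genome-wide miRNA reduction
against a stable background; occupancy loss against a fixed carry-over)
but not the absolute scale or sequence-level noise of real libraries: no
mapping ambiguity, no PCR duplicates, no positional bias, exaggerated
per-feature shares, and abundance laws (Gamma shape 0.6 for expression,
shape 3 for planted effect classes) that are stylized. Recovery rates
measured here validate the pipeline's logic and thresholds, not its
performance on any particular real dataset.

# Default problem sizes

The default experiment — the scale at which all recovery properties are
stated and tested — is 4 chromosomes × 200 kb, 250 five-exon genes (1000
introns), 100 planted lariats (23% escapees), 50 decoys, 60 miRNA loci, 2
replicates of each RNA-seq class at 2 × 10⁵ reads, small-RNA libraries at
10⁶ reads, IP libraries at 2 × 10⁵ reads (chosen so the occupancy
classifier's sampling noise is small against the strict |log2| > 1 cut),
read length 50. A full simulate + analyze cycle runs in about two minutes
on one CPU.

# Numerical and degenerate-input choices

* All-zero totals give p = 1; empty regions are an error; zero library
  sizes are an error.
* Two-sided tie handling uses a 10⁻¹² relative mass tolerance; at
  dispersion 0 the test is exactly binomial.
* Without replication the dispersion estimator returns a configured
  default (0.1) with a warning; pooled inputs are treated as one
  replicate.
* Branch-tie resolution is 3′-most; reads mapping wholly within two
  overlapping features are discarded as not uniquely placed.
* BH is delegated to `p.adjust`; NaN p-values are an error rather than
  propagated.
* `log2` ratios are defined only when both normalized abundances are
  positive; filters are applied before ratios so an excluded miRNA never
  reports a ratio.

# Known limitations

* SAM support is plain-text, single-end, `M/N/D/I/S`-level CIGARs; BAM
  and mate-pair semantics are out of scope (the pipeline consumes
  alignments, it does not align).
* The miRNA assigner is exact/near-exact string matching against the
  mature reference — adequate for 18–30-nt queries, but no isomiR
  analysis beyond the ±2-nt end window and no novel-miRNA discovery.
* No mappability, GC, or duplicate correction; no tagwise or trended
  dispersion; no GLM framework; no lariat 3′-tail modelling (the
  simulator represents only the loop, consistent with RNase R sparing
  just the loop portion).
* The escapee fraction, fold changes and survival rates are point
  parameters, not distributions fitted to data.
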