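---
title: "Attributing genetic variation in genome-edited clonal collections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attributing genetic variation in genome-edited clonal collections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonovar)
```

## The problem

Collections of isogenic, genome-edited pluripotent stem cell lines are the
workhorse of disease modelling, but "isogenic" is an approximation. Each
clonal line differs from its parental line by hundreds of small variants
from three sources: mutations that arose in the parental culture before the
editing experiment and were fixed when a single founder cell was expanded
(the founder effect), mutations acquired privately after the clonal
bottleneck, and — much more rarely — unintended consequences of the editing
chemistry itself: off-target mutagenesis near sequence-similar loci and
loss of heterozygosity (LOH) around the cut site. `clonovar` takes a
joint-genotyped multi-sample VCF for such a collection, separates these
sources, and summarizes the quality-control outcome of the collection.

## The attribution model

The pipeline follows a deliberately simple exclusion logic:

1. **Quality filter.** Calls with joint-genotyping quality below 30 are
   removed (inclusive threshold: `qual >= 30` is kept). A variant is
   *present* in a line when its genotype is het or hom-alt; a missing
   genotype counts as absent but is tallied in the cohort validation
   report, so silent missingness cannot masquerade as specificity.
2. **Parental-proxy exclusion.** For each editing group (all clones from
   the targeting experiments for one intended mutation, *including* that
   experiment's untargeted "edited wild-type" controls), any variant also
   present in a line outside the group is discarded. Standing parental
   heterozygous variation is carried by essentially every line, so this
   cross-line filter removes it without requiring a deeply sequenced
   parental reference. Controls are grouped *with* their experiment:
   founder variants are shared between edited clones and controls, and
   grouping the controls as "other" would delete exactly the signal the
   founder analysis needs.
3. **Classification.** Each group-specific variant is labelled `on_target`
   (it matches a declared expected edit after normalization),
   `unique` (single carrier), `shared_founder` (multiple carriers whose
   set includes an untargeted control of the same experiment or a declared
   earlier-round parental clone, as in two-round homozygosis strategies),
   or `shared_unexplained`. Variants later identified as genuine
   off-targets are re-labelled `off_target_genuine`; near-site candidates
   that fail the cleavage test keep their sharing-based label, because a
   variant 80 bp away from a 4-mismatch site is far more plausibly a
   culture mutation than an editing scar.

Expected edits and all cohort variants pass through the same
left-alignment/parsimony normalization before comparison, so
representation differences cannot hide an engineered mutation; an expected
edit absent from the call set altogether is reported as a warning rather
than an error, since joint genotyping does occasionally drop one.

## Off-target assessment

For every guide we enumerate candidate sites: both strands of the genome
are scanned for the protospacer with up to five mismatches followed by an
NGG match (IUPAC codes honoured; PAM bases never counted as mismatches).
Group-specific variants (excluding the on-target edits) within a 100 bp
window of a site interval become candidate hits. A hit is called a
**genuine** off-target when its leftmost changed base lies 2–5 protospacer
positions upstream of the PAM — the window where Cas9 blunt cuts land —
and the carrier is heterozygous. Rejected hits carry a reason code
(`outside_cleavage_window`, `homozygous`, `pam_distal`). Conventions that
the literature leaves implicit are pinned down explicitly:

* protospacer position 1 is the base immediately adjacent to the PAM, and
  all arithmetic is mirrored for minus-strand sites;
* an indel is anchored at its leftmost changed base after normalization;
* the 100 bp window is measured from the site interval boundaries
  (configurable via `window_bp`).

The scan itself is a vectorized exact comparison; at the genome sizes this
package targets (fixtures and small model genomes) exactness, not speed,
is the contract, and the test suite holds the scan to equality with an
independent `Biostrings::matchPattern` search.

## Mutation accumulation and phylogeny

Per-line unique-variant counts are regressed on the passage number at each
line's last clonal event by ordinary least squares, with the 95% CI of the
slope from the t distribution. The response is the *unique* count — founder
variants were acquired before the bottleneck and would otherwise be counted
once per sibling clone. A negative intercept is expected: it is (minus) the
rate times the shared pre-clonal culture time.

For the collection phylogeny each group line is represented by its
presence vector over the union of group-specific variants; pairwise
Jaccard distances feed a neighbor-joining tree (`ape::nj`, negative branch
lengths clamped to zero). Jaccard is used because presence/absence sets of
very different sizes are compared; the metric is a package choice, and the
distance matrix is exposed so any other tree method can be substituted.

## LOH screening

The computational analog of zygosity confirmation: markers heterozygous in
the parental line should stay heterozygous in a clone. For each edited
locus the screen finds the nearest informative parental-het marker on each
side (default radius 1 Mb, markers with missing clone genotypes skipped,
markers at the edit alleles excluded) and calls `loh` when **both** flanks
are homozygous, `retained_het` when either is het, `indeterminate`
otherwise. Requiring both flanks trades a little sensitivity near
chromosome ends for robustness to isolated genotyping errors; the
single-nearest-marker analog of a one-amplicon wet-lab assay is available
via `single_marker = TRUE`. Shrinking the radius can only move verdicts
toward `indeterminate`, never flip `loh` to `retained_het` — a property
the tests enforce.

## The synthetic cohort generator

`simulate_cohort()` generates fully labelled cohorts with the generative
structure the analysis assumes, so that every stage is testable without
access-restricted human data:

* random chromosomes with planted genes (valid start/stop, no internal
  stop codons, genes on both strands) for impact annotation;
* parental standing het SNVs at a configurable density (default 1/2 kb,
  dense enough that LOH screening at default settings has flanking
  markers within a few kb);
* per experiment, founder sublineages whose variant sets are
  Poisson(λ × pre-clonal passages) draws, shared by the edited clones and
  controls assigned round-robin to the sublineage; clone-private variants
  are Poisson(λ × post-bottleneck passages). λ defaults to 20 mutations
  per passage, the order measured for cultured hPSCs, and the default
  pre-clonal culture span is 8 passages with clone passages drawn
  uniformly from 10–40;
* engineered edits at planted protospacer+PAM sites (homozygous for
  double-strand-break methods, heterozygous for prime editing, matching
  how those chemistries are used);
* planted sequence-similar decoy sites (1–5 mismatches) that receive
  heterozygous 1–10 bp indels uniformly 2–5 bases PAM-proximal with
  probability 0.25 per clone and site — double-strand-break clones only.
  At desk scale a handful of planted sites stands in for the genome-wide
  site catalogue of a real screen, so the per-site probability is
  correspondingly larger than any realistic per-site rate; what is
  preserved is the *contrast* (prime clones receive none) and the
  cleavage-window geometry;
* LOH tracts (default 60 kb) around homozygously edited loci with
  probability 0.15 per eligible clone, on the order of the ~11% LOH rate
  reported for CRISPR-edited collections, flipping in-tract parental
  markers to homozygous-reference (haplotypes are not modelled, so the
  retained haplotype is always the reference one — a simplification that
  is invisible to marker-based screening);
* low-quality decoy calls (5% of the call set, QUAL < 30) that the
  quality filter must remove.

Every alternate genotype in the emitted VCF is explained by exactly one
truth record, and `evaluate_recovery()` scores a pipeline run against the
truth per label. Two practical choices keep truth labels unambiguous on
clean runs: all variant loci are distinct (drawn without replacement), and
by default random mutations are kept out of enumerated off-target site
intervals (`exclude_cleavage_sites`), so a culture mutation cannot land in
a cleavage window by chance and masquerade as an off-target. Both can be
switched off.

What the generator does *not* emulate: sequencing noise and
genotyping-error processes (beyond the low-QUAL decoys), mosaicism and
fluctuating allele frequencies, structural variants and aneuploidy, hot
and cold mutational regions, and realistic genome-scale off-target site
counts. Passing recovery tests therefore demonstrate the correctness of
the attribution logic under its own model assumptions, not robustness to
every artifact of real WGS data.

## Numerical and design choices

* Coordinates are 1-based closed throughout, the native convention of VCF
  and of the R/Bioconductor interval stack; conversions to other
  conventions exist nowhere in the package.
* Quality threshold 30, off-target window 100 bp, mismatch tolerance 5,
  cleavage range 2–5, promoter window 1000 bp upstream of the TSS, splice
  sites = 2 intronic bases at each junction, LOH radius 1 Mb — all
  defaults are exposed as arguments.
* Region precedence is fixed: splice_site > coding_exon > UTR > intron >
  promoter > intergenic; effect severity for the per-variant reduction is
  stopgain/startloss/frameshift > stoploss > missense/inframe >
  splice > synonymous > non-coding.
* Rounding of QC percentages is half-up to two decimals, so 2/18 prints
  as 11.11 and 16/81 as 19.75.
* Ties in neighbor joining are resolved deterministically by `ape::nj`;
  reruns of the pipeline on identical inputs are byte-identical.
* Problem sizes used by the validation suite — model genomes of 50–200 kb,
  cohorts of roughly 15–70 lines, and 40–100 simulation replicates for the
  rate-recovery experiments — were chosen so the full suite exercises every
  stage at desk scale.

## Known limitations

* The parental-proxy exclusion needs enough lines outside each group; in
  a two-group collection a true parental variant lost by drift in one
  group would survive the filter.
* `shared_unexplained` is a residual category: sharing without a control
  carrier cannot be distinguished from independent recurrence.
* The off-target search models no DNA/RNA bulges and no cutting-efficiency
  scores; prime-editing pegRNA spacers are searched like sgRNA spacers.
* LOH calls are marker-based presence/absence; no B-allele-frequency or
  copy-number evidence is used.
* One transcript per gene is assumed in the annotation model the
  simulator emits; overlapping isoforms reduce to the most severe label.
```
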