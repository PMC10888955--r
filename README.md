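# clonovar

Variant attribution and quality control for genome-edited clonal cell
collections.

## The problem

When a parental human pluripotent stem cell line is edited (CRISPR/Cas9,
TALEN or prime editing) and clonal lines are isolated, each clone carries
hundreds of small variants beyond the intended edit. They come from three
places: **founder mutations** — variation that accumulated in the parental
culture and was fixed when a single founder cell was expanded; **private
mutations** acquired after the clonal bottleneck; and, rarely, marks of the
editing chemistry itself — **off-target** indels near sequence-similar loci
and **loss of heterozygosity (LOH)** around the cut site. Telling these
apart is what decides whether a phenotype can be attributed to the edit.

`clonovar` takes a joint-genotyped multi-sample VCF for such a collection
(clones, untargeted control clones, the parental line), a metadata table, a
genome FASTA and guide sequences, and attributes every variant:

* quality filter (joint-genotyping QUAL ≥ 30);
* **parental-proxy exclusion**: per editing group, any variant present in a
  line outside the group (parental, subclone, any other group's clone) is
  removed — standing parental variation is carried by nearly every line;
* classification of group-specific variants as `on_target`, `unique`,
  `shared_founder` (carriers include an untargeted control of the same
  experiment, or a declared earlier-round parental clone) or
  `shared_unexplained`;
* coding-impact annotation against a transcript model (regions
  splice/exon/UTR/intron/promoter; effects synonymous … frameshift);
* **off-target assessment**: enumerate candidate sites for each guide
  (≤ 5 protospacer mismatches, NGG PAM, both strands), collect variants
  within 100 bp of a site, and call a hit *genuine* when it lies 2–5 bases
  upstream of the PAM and is heterozygous;
* **LOH screening** from the nearest flanking parental-heterozygous
  markers at each edited locus;
* mutations-per-passage OLS regression, QC summary rates, and a
  Jaccard/neighbor-joining presence–absence phylogeny of the collection.

A fully labelled synthetic-cohort generator (`simulate_cohort()`) emulates
the assumed generative process — Poisson mutation accumulation fixed at
clonal bottlenecks, founder sublineages shared with untargeted controls,
planted off-target sites, LOH tracts, low-quality decoy calls — so the
entire pipeline is testable without access-restricted human data.

## Worked example

```r
library(clonovar)

sim <- simulate_cohort(sim_config(seed = 7))   # 3 experiments, 15 clones
run <- run_pipeline(sim$cohort, genome = sim$genome,
                    transcripts = sim$transcripts, qc = sim$qc)

table(run$attributed$label)
#> off_target_genuine          on_target     shared_founder             unique
#>                  4                  3                951               4590

run$fit
#> y = 20.20x -154.27;  R2 = 0.9882;  slope 95% CI: 18.87 to 21.52 (n = 15)

run$offtarget$report$per_method_class
#>   method_class candidate_hits genuine_hits
#> 1          dsb             35            4
#> 2        prime             16            0

evaluate_recovery(run, sim)[, c("label", "n_truth", "precision", "recall")]
#>                label n_truth precision recall
#> 1          on_target       3         1      1
#> 2             unique    4590         1      1
#> 3     shared_founder     951         1      1
#> 4 off_target_genuine       4         1      1
#> 5                loh       0        NA     NA
```

Reading the output: the cohort's 5,000-odd group-specific variants are
almost all clone-`unique` (private, post-bottleneck) or `shared_founder`
(each experiment's founder sublineage, shared with its untargeted
controls); the three engineered edits are recovered as `on_target`; the
four injected cleavage-window indels are re-labelled `off_target_genuine`
— and only in the double-strand-break clones, the prime-edited lines show
none. The regression slope recovers the simulated rate of 20 mutations
per passage, with the negative intercept reflecting the shared pre-clonal
culture period. `evaluate_recovery()` confirms every label is recovered
perfectly against the generator's ground truth on this noise-free cohort.

`write_report(run, "outdir")` writes the TSV/JSON/Newick bundle with a
checksummed manifest.

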