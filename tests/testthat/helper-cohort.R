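# Compact constructors for hand-built cohorts used across tests.

meta_row <- function(line_id, group_id = "", experiment_id = "",
                     role = "edited", method = "crispr_hdr", passage = 20L,
                     parent_line = "", expected_edits = "", guide_ids = "") {
  data.frame(line_id = line_id, group_id = group_id,
             experiment_id = experiment_id, role = role, method = method,
             passage = passage, parent_line = parent_line,
             expected_edits = expected_edits, guide_ids = guide_ids,
             stringsAsFactors = FALSE)
}

# variants: data.frame(chrom, pos, ref, alt, qual); carriers: list of named
# character vectors (line -> genotype class) per variant row
build_cohort <- function(variants, carriers, meta, guides = NULL) {
  geno <- matrix("hom_ref", nrow(variants), nrow(meta),
                 dimnames = list(NULL, meta$line_id))
  for (i in seq_along(carriers)) {
    cc <- carriers[[i]]
    geno[i, names(cc)] <- unname(cc)
  }
  new_cohort(variants, geno, meta, guides)
}

vrow <- function(chrom, pos, ref, alt, qual = 50) {
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt, qual = qual,
             stringsAsFactors = FALSE)
}

# standard six-line two-group fixture: parental + subclone + group A
# (2 edited + 1 control) + group B (2 edited)
demo_meta <- function() {
  rbind(
    meta_row("parental", role = "parental", method = "none", passage = NA),
    meta_row("sub1", role = "subclone", method = "none"),
    meta_row("A1", "A", "exp1", expected_edits = "chr1:100:A:G:het"),
    meta_row("A2", "A", "exp1", expected_edits = "chr1:100:A:G:het"),
    meta_row("AW", "A", "exp1", role = "edited_wildtype"),
    meta_row("B1", "B", "exp2", expected_edits = "chr1:500:C:T:hom_alt"),
    meta_row("B2", "B", "exp2", expected_edits = "chr1:500:C:T:hom_alt")
  )
}

random_dna_str <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                           replace = TRUE), collapse = "")
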