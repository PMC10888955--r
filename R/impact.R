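REGION_LEVELS <- c("splice_site", "coding_exon", "five_prime_utr",
                   "three_prime_utr", "intron", "promoter", "intergenic")

# severity used when reducing to one label per variant; lower = more severe
EFFECT_SEVERITY <- c(
  stopgain = 1, startloss = 1, frameshift_insertion = 1,
  frameshift_deletion = 1, stoploss = 2, missense = 3, inframe_indel = 3,
  splice = 4, synonymous = 5
)

# Leftmost reference base actually changed by a (normalized) variant: the
# variant position itself for SNVs, the base after the shared anchor for
# indels.
variant_change_start <- function(variants) {
  ifelse(nchar(variants$ref) == 1L & nchar(variants$alt) == 1L,
         variants$pos, variants$pos + 1L)
}

#' Genomic region of a variant
#'
#' Assigns each variant to a region with fixed precedence
#' `splice_site > coding_exon > UTR > intron > promoter > intergenic`,
#' evaluated over every gene model (a variant inside one gene's promoter but
#' another gene's exon is exonic). Splice sites are the two intronic bases
#' flanking each internal exon junction; the promoter is the configured
#' window upstream of the transcription start site. Variants on chromosomes
#' absent from the models are intergenic, with a warning.
#'
#' @param variants variant data.frame (normalized).
#' @param tx a `transcript_models` object.
#' @return character vector of region labels, plus a `gene_id` attribute
#'   (the assigning gene, `NA` for intergenic).
#' @export
annotate_region <- function(variants, tx) {
  pos <- variant_change_start(variants)
  n <- nrow(variants)
  region <- rep("intergenic", n)
  gene <- rep(NA_character_, n)
  rank <- match(region, REGION_LEVELS)
  known <- unique(tx$genes$chrom)
  if (any(!variants$chrom %in% known) && nrow(tx$genes))
    warning("variants on chromosomes without gene models treated as intergenic: ",
            paste(unique(setdiff(variants$chrom, known)), collapse = ", "))
  for (k in seq_len(nrow(tx$genes))) {
    g <- tx$genes[k, ]
    e <- tx$exons[tx$exons$gene_id == g$gene_id, , drop = FALSE]
    e <- e[order(e$start), , drop = FALSE]
    lab <- gene_region(pos, variants$chrom, g, e, tx$promoter_span)
    r <- match(lab, REGION_LEVELS)
    better <- r < rank
    region[better] <- lab[better]
    gene[better] <- g$gene_id
    rank <- match(region, REGION_LEVELS)
  }
  attr(region, "gene_id") <- gene
  region
}

# region label of each position relative to one gene model
gene_region <- function(pos, chrom, g, e, promoter_span) {
  n <- length(pos)
  lab <- rep("intergenic", n)
  on_chr <- chrom == g$chrom
  tx_start <- min(e$start); tx_end <- max(e$end)
  # promoter window upstream of TSS
  if (g$strand == "+") {
    prom <- on_chr & pos >= tx_start - promoter_span & pos < tx_start
  } else {
    prom <- on_chr & pos > tx_end & pos <= tx_end + promoter_span
  }
  lab[prom] <- "promoter"
  inside <- on_chr & pos >= tx_start & pos <= tx_end
  if (!any(inside)) return(lab)
  in_exon <- rep(FALSE, n)
  for (j in seq_len(nrow(e)))
    in_exon <- in_exon | (inside & pos >= e$start[j] & pos <= e$end[j])
  lab[inside & !in_exon] <- "intron"
  # two intronic bases at each internal junction
  splice <- rep(FALSE, n)
  if (nrow(e) > 1L) {
    donors <- e$end[-nrow(e)]      # intron starts at donor+1
    acceptors <- e$start[-1L]      # intron ends at acceptor-1
    for (d in donors) splice <- splice | (inside & pos >= d + 1L & pos <= d + 2L)
    for (a in acceptors) splice <- splice | (inside & pos >= a - 2L & pos <= a - 1L)
  }
  in_cds <- inside & in_exon & pos >= g$cds_start & pos <= g$cds_end
  utr <- inside & in_exon & !in_cds
  if (g$strand == "+") {
    lab[utr & pos < g$cds_start] <- "five_prime_utr"
    lab[utr & pos > g$cds_end] <- "three_prime_utr"
  } else {
    lab[utr & pos > g$cds_end] <- "five_prime_utr"
    lab[utr & pos < g$cds_start] <- "three_prime_utr"
  }
  lab[in_cds] <- "coding_exon"
  lab[splice] <- "splice_site"
  lab
}

# Concatenated CDS sequence of a gene (transcript orientation) and the
# mapping from genomic position to CDS coordinate.
cds_model <- function(g, e, genome) {
  e <- e[order(e$start), , drop = FALSE]
  segs <- data.frame(start = pmax(e$start, g$cds_start),
                     end = pmin(e$end, g$cds_end))
  segs <- segs[segs$start <= segs$end, , drop = FALSE]
  chrom_seq <- as.character(genome[[g$chrom]])
  seq_parts <- substring(chrom_seq, segs$start, segs$end)
  cds_fwd <- paste(seq_parts, collapse = "")
  if (g$strand == "+") {
    cds <- cds_fwd
  } else {
    cds <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(cds_fwd)))
  }
  # genomic -> CDS (transcript-sense) coordinate
  map <- function(gpos) {
    off <- 0L
    for (j in seq_len(nrow(segs))) {
      if (gpos >= segs$start[j] && gpos <= segs$end[j]) {
        fwd <- off + (gpos - segs$start[j] + 1L)
        if (g$strand == "+") return(fwd)
        return(nchar(cds) - fwd + 1L)
      }
      off <- off + (segs$end[j] - segs$start[j] + 1L)
    }
    NA_integer_
  }
  list(cds = cds, map = map, segs = segs)
}

#' Protein-coding consequence of a variant
#'
#' For SNVs inside the CDS, classifies the codon change under the standard
#' genetic code (strand-aware): `synonymous`, `missense`, `stopgain`,
#' `stoploss` (reference stop codon lost), `startloss` (initiator codon
#' disrupted). Indels are `frameshift_insertion` / `frameshift_deletion`
#' when the length change is not a multiple of three, else `inframe_indel`.
#'
#' @param variants normalized variant data.frame; rows must overlap the CDS
#'   of `gene_id`.
#' @param gene_id the gene model to annotate against.
#' @param tx `transcript_models`.
#' @param genome genome `DNAStringSet`.
#' @return character vector of effect labels.
#' @export
annotate_coding_effect <- function(variants, gene_id, tx, genome) {
  g <- tx$genes[tx$genes$gene_id == gene_id, ]
  if (nrow(g) != 1L) stop("unknown gene: ", gene_id)
  e <- tx$exons[tx$exons$gene_id == gene_id, , drop = FALSE]
  cm <- cds_model(g, e, genome)
  if (nchar(cm$cds) %% 3L != 0L)
    stop("CDS length of ", gene_id, " is not a multiple of 3")
  n_codons <- nchar(cm$cds) %/% 3L
  vapply(seq_len(nrow(variants)), function(i) {
    ref <- variants$ref[i]; alt <- variants$alt[i]
    if (nchar(ref) != nchar(alt)) {
      d <- nchar(alt) - nchar(ref)
      if (abs(d) %% 3L != 0L)
        return(if (d > 0) "frameshift_insertion" else "frameshift_deletion")
      return("inframe_indel")
    }
    if (nchar(ref) != 1L) return("inframe_indel")  # MNV: treated as in-frame
    cpos <- cm$map(variants$pos[i])
    if (is.na(cpos)) stop("variant ", variant_key(variants[i, ]),
                          " does not overlap the CDS of ", gene_id)
    base <- if (g$strand == "+") alt else
      unname(c(A = "T", C = "G", G = "C", T = "A")[alt])
    codon_i <- (cpos - 1L) %/% 3L + 1L
    codon <- substr(cm$cds, (codon_i - 1L) * 3L + 1L, codon_i * 3L)
    within <- (cpos - 1L) %% 3L + 1L
    mut <- codon
    substr(mut, within, within) <- base
    aa_ref <- unname(Biostrings::GENETIC_CODE[codon])
    aa_mut <- unname(Biostrings::GENETIC_CODE[mut])
    if (codon_i == 1L && mut != "ATG") return("startloss")
    if (aa_ref == "*" && aa_mut != "*") return("stoploss")
    if (aa_ref != "*" && aa_mut == "*") return("stopgain")
    if (aa_ref == aa_mut) return("synonymous")
    "missense"
  }, character(1))
}

#' Region + coding impact for attributed variants
#'
#' Convenience wrapper: assigns each variant its region and, for variants in
#' coding exons, the protein-level effect; the combined `impact` column is
#' the most severe single label per variant
#' (`stopgain`/`startloss`/frameshifts > `stoploss` > `missense`/
#' `inframe_indel` > splice > `synonymous` > non-coding region label).
#'
#' @param variants normalized variant data.frame.
#' @param tx `transcript_models`.
#' @param genome genome `DNAStringSet`.
#' @return the data.frame with `region`, `gene_id`, `effect` and `impact`
#'   columns appended.
#' @export
annotate_variants <- function(variants, tx, genome) {
  region <- annotate_region(variants, tx)
  gene <- attr(region, "gene_id")
  effect <- rep(NA_character_, nrow(variants))
  idx <- which(region == "coding_exon")
  for (i in idx)
    effect[i] <- annotate_coding_effect(variants[i, , drop = FALSE],
                                        gene[i], tx, genome)
  impact <- ifelse(region == "splice_site", "splice",
                   ifelse(is.na(effect), as.character(region), effect))
  variants$region <- as.character(region)
  variants$gene_id <- gene
  variants$effect <- effect
  variants$impact <- impact
  variants
}
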