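#' Read a cohort from VCF + metadata + guide tables
#'
#' Parses a joint-genotyped multi-sample VCF (via \pkg{vcfR}), splits
#' multiallelic sites into one record per alternate allele (genotypes recoded
#' per allele), recodes diploid GT fields into genotype classes, and attaches
#' the line metadata and guide specifications.
#'
#' @param vcf_path path to a VCF 4.x file (plain or gzipped).
#' @param meta_path path to a tab-separated line-metadata table (columns as
#'   documented in [new_cohort()]).
#' @param guides_path optional path to a tab-separated guide table
#'   (`guide_id`, `protospacer`, `pam_pattern`, `kind`).
#' @return a `clonal_cohort`.
#' @export
read_cohort <- function(vcf_path, meta_path, guides_path = NULL) {
  meta <- read.delim(meta_path, stringsAsFactors = FALSE,
                     colClasses = "character")
  meta$passage <- as.integer(meta$passage)
  guides <- NULL
  if (!is.null(guides_path)) {
    guides <- read.delim(guides_path, stringsAsFactors = FALSE)
    validate_guides(guides)
  }
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  samples <- colnames(vcf@gt)[-1]
  if (!setequal(samples, meta$line_id)) {
    stop("VCF samples and metadata line_ids disagree; only in VCF: [",
         paste(setdiff(samples, meta$line_id), collapse = ", "),
         "]; only in metadata: [",
         paste(setdiff(meta$line_id, samples), collapse = ", "), "]")
  }
  fix <- vcf@fix
  gt <- vcfR::extract.gt(vcf, element = "GT")
  n <- nrow(fix)
  rows <- vector("list", n)
  genos <- vector("list", n)
  for (i in seq_len(n)) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    g <- vapply(seq_along(alts), function(a) {
      recode_gt(gt[i, samples], a, fix[i, "CHROM"], fix[i, "POS"])
    }, character(length(samples)))
    if (length(samples) == 1L) g <- matrix(g, nrow = 1L)
    rows[[i]] <- data.frame(
      chrom = unname(fix[i, "CHROM"]),
      pos = as.integer(unname(fix[i, "POS"])),
      ref = unname(fix[i, "REF"]),
      alt = unname(alts),
      qual = as.numeric(unname(fix[i, "QUAL"])),
      stringsAsFactors = FALSE, row.names = NULL
    )
    genos[[i]] <- t(g)
  }
  variants <- do.call(rbind, rows)
  geno <- do.call(rbind, genos)
  colnames(geno) <- samples
  new_cohort(variants, geno, meta, guides)
}

# Recode one diploid GT string vector relative to alternate allele index
# `alt_idx` (1-based among the site's ALT alleles).
recode_gt <- function(gt_strings, alt_idx, chrom, pos) {
  vapply(seq_along(gt_strings), function(j) {
    s <- gt_strings[j]
    if (is.na(s) || s == "." || s == "./." || s == ".|.") return("missing")
    alleles <- strsplit(s, "[/|]")[[1]]
    if (any(alleles == ".")) return("missing")
    if (!all(grepl("^[0-9]+$", alleles)) || !length(alleles) %in% c(1L, 2L))
      stop("malformed genotype '", s, "' at ", chrom, ":", pos,
           " sample ", names(gt_strings)[j])
    if (length(alleles) == 1L) alleles <- rep(alleles, 2L)
    k <- sum(alleles == as.character(alt_idx))
    c("hom_ref", "het", "hom_alt")[k + 1L]
  }, character(1))
}

validate_guides <- function(guides) {
  need <- c("guide_id", "protospacer", "pam_pattern", "kind")
  if (!all(need %in% names(guides)))
    stop("guide table lacks columns: ",
         paste(setdiff(need, names(guides)), collapse = ", "))
  n <- nchar(guides$protospacer)
  if (any(n < 17 | n > 23))
    stop("protospacer length must be 17-23 nt: ",
         paste(guides$guide_id[n < 17 | n > 23], collapse = ", "))
  if (any(grepl("[^ACGT]", guides$protospacer)))
    stop("protospacer alphabet must be ACGT")
  invisible(guides)
}

#' Write a cohort back to disk
#'
#' Emits a minimal VCF 4.2 (GT-only FORMAT), the metadata TSV and, when
#' guides are attached, the guide TSV. The VCF re-reads with [read_cohort()]
#' to an identical record list.
#'
#' @param cohort a `clonal_cohort`.
#' @param vcf_path,meta_path,guides_path output paths (`guides_path` ignored
#'   when the cohort carries no guide table).
#' @return invisibly, the cohort.
#' @export
write_cohort <- function(cohort, vcf_path, meta_path, guides_path = NULL) {
  v <- cohort$variants
  gt_code <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1", missing = "./.")
  gt <- matrix(gt_code[cohort$geno], nrow = nrow(v))
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", cohort$meta$line_id), collapse = "\t")
  )
  body <- paste(v$chrom, v$pos, ".", v$ref, v$alt, sprintf("%.2f", v$qual),
                "PASS", ".", "GT",
                apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  if (nrow(v) == 0L) body <- character(0)
  writeLines(c(header, body), vcf_path)
  write.table(cohort$meta, meta_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(cohort$guides) && !is.null(guides_path))
    write.table(cohort$guides, guides_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  invisible(cohort)
}

#' Load a genome FASTA
#' @param fasta_path path to an (uncompressed or gzipped) FASTA.
#' @return a [Biostrings::DNAStringSet] named by the first token of each
#'   sequence header.
#' @export
read_genome <- function(fasta_path) {
  g <- Biostrings::readDNAStringSet(fasta_path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Transcript models
#'
#' Minimal transcript container used for region and coding-impact
#' annotation: per-gene strand, exon set and CDS span, plus the configured
#' promoter window.
#'
#' @param genes data.frame: `gene_id`, `chrom`, `strand` ("+"/"-"),
#'   `cds_start`, `cds_end` (1-based, genomic).
#' @param exons data.frame: `gene_id`, `start`, `end` (1-based closed,
#'   genomic, non-overlapping within a gene).
#' @param promoter_span bases upstream of the transcription start site
#'   treated as promoter (default 1000).
#' @return an object of class `transcript_models`.
#' @export
new_transcript_models <- function(genes, exons, promoter_span = 1000) {
  stopifnot(all(c("gene_id", "chrom", "strand", "cds_start", "cds_end")
                %in% names(genes)),
            all(c("gene_id", "start", "end") %in% names(exons)))
  for (g in genes$gene_id) {
    e <- exons[exons$gene_id == g, , drop = FALSE]
    e <- e[order(e$start), , drop = FALSE]
    if (nrow(e) == 0L) stop("gene ", g, " has no exons")
    if (any(e$start[-1] <= e$end[-nrow(e)]))
      stop("overlapping exons in gene ", g)
    cs <- genes$cds_start[genes$gene_id == g]
    ce <- genes$cds_end[genes$gene_id == g]
    if (!any(e$start <= cs & cs <= e$end) || !any(e$start <= ce & ce <= e$end))
      stop("CDS boundary outside exons in gene ", g)
  }
  structure(list(genes = genes, exons = exons[order(exons$gene_id, exons$start), ],
                 promoter_span = promoter_span),
            class = "transcript_models")
}

#' Read transcript models from GFF3
#'
#' Expects gene / mRNA / exon / CDS features with `ID`/`Parent` attributes
#' (one transcript per gene, as emitted by [simulate_genome()] or any
#' GFF3-conformant annotation restricted to that shape).
#'
#' @param gff_path path to a GFF3 file.
#' @param promoter_span promoter window in bp upstream of the TSS.
#' @return a `transcript_models` object.
#' @export
read_transcripts <- function(gff_path, promoter_span = 1000) {
  gr <- rtracklayer::import(gff_path, format = "gff3")
  type <- as.character(gr$type)
  ids <- as.character(gr$ID)
  parent <- vapply(as.list(gr$Parent), function(p)
    if (length(p)) p[[1]] else NA_character_, character(1))
  tx2gene <- setNames(parent[type == "mRNA"], ids[type == "mRNA"])
  feat_gene <- ifelse(parent %in% names(tx2gene),
                      tx2gene[parent], parent)
  is_cds <- type == "CDS"
  is_ex <- type == "exon"
  gi <- which(type == "gene")
  genes <- data.frame(
    gene_id = ids[gi],
    chrom = as.character(GenomicRanges::seqnames(gr))[gi],
    strand = as.character(GenomicRanges::strand(gr))[gi],
    cds_start = NA_integer_, cds_end = NA_integer_,
    stringsAsFactors = FALSE
  )
  for (k in seq_len(nrow(genes))) {
    sel <- is_cds & feat_gene == genes$gene_id[k]
    genes$cds_start[k] <- min(GenomicRanges::start(gr)[sel])
    genes$cds_end[k] <- max(GenomicRanges::end(gr)[sel])
  }
  exons <- data.frame(
    gene_id = feat_gene[is_ex],
    start = GenomicRanges::start(gr)[is_ex],
    end = GenomicRanges::end(gr)[is_ex],
    stringsAsFactors = FALSE
  )
  new_transcript_models(genes, exons, promoter_span)
}

#' Write transcript models as GFF3
#' @param tx a `transcript_models` object.
#' @param gff_path output path.
#' @param chrom_lengths optional named vector used for `##sequence-region`
#'   directives.
#' @return invisibly, `gff_path`.
#' @export
write_transcripts <- function(tx, gff_path, chrom_lengths = NULL) {
  rows <- list()
  for (k in seq_len(nrow(tx$genes))) {
    g <- tx$genes[k, ]
    e <- tx$exons[tx$exons$gene_id == g$gene_id, , drop = FALSE]
    txid <- paste0(g$gene_id, ".t1")
    span <- c(min(e$start), max(e$end))
    rows[[length(rows) + 1L]] <- c(g$chrom, "clonovar", "gene", span,
                                   ".", g$strand, ".", paste0("ID=", g$gene_id))
    rows[[length(rows) + 1L]] <- c(g$chrom, "clonovar", "mRNA", span,
                                   ".", g$strand, ".",
                                   paste0("ID=", txid, ";Parent=", g$gene_id))
    cds <- data.frame(start = pmax(e$start, g$cds_start),
                      end = pmin(e$end, g$cds_end))
    cds <- cds[cds$start <= cds$end, , drop = FALSE]
    # phase: bases to skip before the first complete codon of each segment,
    # accumulated in transcript order (reversed for minus-strand genes)
    ord <- if (g$strand == "+") seq_len(nrow(cds)) else rev(seq_len(nrow(cds)))
    phase <- integer(nrow(cds))
    done <- 0L
    for (j in ord) {
      phase[j] <- (3L - done %% 3L) %% 3L
      done <- done + cds$end[j] - cds$start[j] + 1L
    }
    for (j in seq_len(nrow(e))) {
      rows[[length(rows) + 1L]] <- c(g$chrom, "clonovar", "exon",
                                     e$start[j], e$end[j], ".", g$strand, ".",
                                     paste0("Parent=", txid))
      k <- which(cds$start >= e$start[j] & cds$end <= e$end[j])
      for (i2 in k) {
        rows[[length(rows) + 1L]] <- c(g$chrom, "clonovar", "CDS",
                                       cds$start[i2], cds$end[i2], ".",
                                       g$strand, phase[i2],
                                       paste0("ID=", txid, ".cds;Parent=", txid))
      }
    }
  }
  head <- "##gff-version 3"
  if (!is.null(chrom_lengths))
    head <- c(head, sprintf("##sequence-region %s 1 %d",
                            names(chrom_lengths), chrom_lengths))
  body <- vapply(rows, paste, "", collapse = "\t")
  writeLines(c(head, body), gff_path)
  invisible(gff_path)
}
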