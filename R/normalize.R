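#' Normalize variant representations
#'
#' Left-aligns and parsimony-trims indels against the genome (the standard
#' variant-normalization algorithm: trim shared trailing bases, extending
#' left with genome sequence whenever an allele would become empty, then trim
#' shared leading bases while both alleles keep at least one base). SNVs are
#' returned unchanged and the operation is idempotent. Only `pos`, `ref` and
#' `alt` change; genotypes and quality are untouched.
#'
#' @param variants variant data.frame (`chrom`, `pos`, `ref`, `alt`, ...).
#' @param genome a [Biostrings::DNAStringSet] whose names cover every
#'   variant chromosome.
#' @return the data.frame with normalized `pos`, `ref`, `alt`.
#' @export
normalize_variants <- function(variants, genome) {
  chrom_cache <- list()
  get_chrom <- function(ch) {
    if (is.null(chrom_cache[[ch]])) {
      if (!ch %in% names(genome)) stop("chromosome not in genome: ", ch)
      chrom_cache[[ch]] <<- toupper(as.character(genome[[ch]]))
    }
    chrom_cache[[ch]]
  }
  for (i in seq_len(nrow(variants))) {
    ch <- variants$chrom[i]
    s <- get_chrom(ch)
    norm <- normalize_one(variants$pos[i], variants$ref[i], variants$alt[i],
                          s, ch)
    variants$pos[i] <- norm$pos
    variants$ref[i] <- norm$ref
    variants$alt[i] <- norm$alt
  }
  variants
}

normalize_one <- function(pos, ref, alt, chrom_seq, chrom_name) {
  ref <- toupper(ref); alt <- toupper(alt)
  obs <- substr(chrom_seq, pos, pos + nchar(ref) - 1L)
  if (obs != ref)
    stop("REF/genome mismatch at ", chrom_name, ":", pos,
         " (VCF says ", ref, ", genome says ", obs, ")")
  if (nchar(ref) == 1L && nchar(alt) == 1L)
    return(list(pos = pos, ref = ref, alt = alt))
  repeat {
    nr <- nchar(ref); na <- nchar(alt)
    if ((nr > 1L || na > 1L) &&
        substr(ref, nr, nr) == substr(alt, na, na)) {
      if ((nr == 1L || na == 1L) && pos == 1L)
        break  # cannot left-extend past the chromosome start
      ref <- substr(ref, 1L, nr - 1L)
      alt <- substr(alt, 1L, na - 1L)
      if (nchar(ref) == 0L || nchar(alt) == 0L) {
        pos <- pos - 1L
        b <- substr(chrom_seq, pos, pos)
        ref <- paste0(b, ref); alt <- paste0(b, alt)
      }
    } else break
  }
  while (nchar(ref) >= 2L && nchar(alt) >= 2L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substring(ref, 2L); alt <- substring(alt, 2L)
    pos <- pos + 1L
  }
  list(pos = pos, ref = ref, alt = alt)
}

#' Normalize every variant of a cohort in place
#'
#' @param cohort a `clonal_cohort`.
#' @param genome genome `DNAStringSet`.
#' @return the cohort with normalized variant records, re-sorted.
#' @export
normalize_cohort <- function(cohort, genome) {
  v <- normalize_variants(cohort$variants, genome)
  new_cohort(v, cohort$geno, cohort$meta, cohort$guides)
}
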