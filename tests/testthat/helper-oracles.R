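# Independent oracles: deliberately brute-force implementations, sharing no
# code path with the package internals they check.

# apply a variant to a sequence string
apply_variant <- function(seq, pos, ref, alt) {
  if (substr(seq, pos, pos + nchar(ref) - 1L) != ref) return(NA_character_)
  paste0(substr(seq, 1L, pos - 1L), alt,
         substring(seq, pos + nchar(ref)))
}

# leftmost minimal-length equivalent representation, by exhaustive search
brute_normalize <- function(pos, ref, alt, seq, max_len = 15L,
                            window = 60L) {
  target <- apply_variant(seq, pos, ref, alt)
  best <- NULL
  for (p in max(1L, pos - window):min(nchar(seq), pos + window)) {
    for (lr in 1:max_len) {
      r <- substr(seq, p, p + lr - 1L)
      if (nchar(r) < lr) next
      for (la in 1:max_len) {
        if (lr > 1L && la > 1L) next  # parsimonious indel/SNV forms only
        if (lr == la && lr > 1L) next
        # any candidate alt reproducing the target haplotype must equal the
        # target substring at this offset
        a <- substr(target, p, p + la - 1L)
        if (nchar(a) < la) next
        if (r == a) next
        h <- apply_variant(seq, p, r, a)
        if (identical(h, target)) {
          cand <- list(pos = p, ref = r, alt = a, size = lr + la)
          if (is.null(best) || cand$size < best$size ||
              (cand$size == best$size && cand$pos < best$pos))
            best <- cand
        }
      }
    }
  }
  best[c("pos", "ref", "alt")]
}

# group-specific filter oracle: exhaustive double loop over (variant, line)
brute_group_specific <- function(present, members) {
  others <- setdiff(colnames(present), members)
  keep <- logical(nrow(present))
  for (i in seq_len(nrow(present))) {
    in_m <- FALSE; in_o <- FALSE
    for (l in colnames(present)) {
      if (present[i, l]) {
        if (l %in% members) in_m <- TRUE else in_o <- TRUE
      }
    }
    keep[i] <- in_m && !in_o
  }
  keep
}

# region annotation oracle: explicit interval walk over one gene model
brute_region <- function(pos, gene, exons, promoter_span) {
  exons <- exons[order(exons$start), , drop = FALSE]
  tx_start <- min(exons$start); tx_end <- max(exons$end)
  if (gene$strand == "+") {
    if (pos >= tx_start - promoter_span && pos < tx_start) return("promoter")
  } else {
    if (pos > tx_end && pos <= tx_end + promoter_span) return("promoter")
  }
  if (pos < tx_start || pos > tx_end) return("intergenic")
  for (j in seq_len(nrow(exons) - 1L)) {
    if (pos %in% c(exons$end[j] + 1L, exons$end[j] + 2L)) return("splice_site")
    if (pos %in% c(exons$start[j + 1L] - 1L, exons$start[j + 1L] - 2L))
      return("splice_site")
  }
  in_exon <- any(pos >= exons$start & pos <= exons$end)
  if (!in_exon) return("intron")
  if (pos >= gene$cds_start && pos <= gene$cds_end) return("coding_exon")
  upstream_of_cds <- if (gene$strand == "+") pos < gene$cds_start
    else pos > gene$cds_end
  if (upstream_of_cds) "five_prime_utr" else "three_prime_utr"
}

# coding-effect oracle: translate the full reference and mutant CDS
brute_effect <- function(variant, gene, exons, genome) {
  exons <- exons[order(exons$start), , drop = FALSE]
  chrom <- as.character(genome[[gene$chrom]])
  mutant <- apply_variant(chrom, variant$pos, variant$ref, variant$alt)
  shift <- nchar(variant$alt) - nchar(variant$ref)
  if (shift %% 3L != 0L)
    return(if (shift > 0) "frameshift_insertion" else "frameshift_deletion")
  if (shift != 0L) return("inframe_indel")
  get_cds <- function(s) {
    segs <- mapply(function(a, b) substr(s, max(a, gene$cds_start),
                                         min(b, gene$cds_end)),
                   exons$start, exons$end)
    cds <- paste(segs[nchar(segs) > 0], collapse = "")
    if (gene$strand == "-")
      cds <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(cds)))
    cds
  }
  translate_str <- function(cds)
    as.character(Biostrings::translate(Biostrings::DNAString(cds)))
  p_ref <- translate_str(get_cds(chrom))
  p_mut <- translate_str(get_cds(mutant))
  if (substr(p_mut, 1L, 1L) != "M") return("startloss")
  last_ref <- substr(p_ref, nchar(p_ref), nchar(p_ref))
  last_mut <- substr(p_mut, nchar(p_mut), nchar(p_mut))
  if (last_ref == "*" && last_mut != "*") return("stoploss")
  internal_mut <- substr(p_mut, 1L, nchar(p_mut) - 1L)
  internal_ref <- substr(p_ref, 1L, nchar(p_ref) - 1L)
  if (grepl("*", internal_mut, fixed = TRUE) &&
      !grepl("*", internal_ref, fixed = TRUE)) return("stopgain")
  if (p_ref == p_mut) return("synonymous")
  "missense"
}

# off-target enumeration oracle: Biostrings mismatch search per strand with
# an explicit PAM check
oracle_sites <- function(protospacer, genome, max_mm, pam = "NGG") {
  out <- list()
  L <- nchar(protospacer)
  for (ch in names(genome)) {
    for (strand in c("+", "-")) {
      subject <- if (strand == "+") genome[[ch]] else
        Biostrings::reverseComplement(genome[[ch]])
      m <- Biostrings::matchPattern(protospacer, subject,
                                    max.mismatch = max_mm)
      sseq <- as.character(subject)
      clen <- nchar(sseq)
      for (k in seq_along(m)) {
        st <- Biostrings::start(m)[k]
        if (st + L + 2L > clen) next
        pam_seq <- substr(sseq, st + L, st + L + 2L)
        if (!grepl("^.GG$", pam_seq)) next
        mm <- sum(strsplit(as.character(m[[k]]), "")[[1]] !=
                  strsplit(protospacer, "")[[1]])
        gstart <- if (strand == "+") st else clen - (st + L + 2L) + 1L
        out[[length(out) + 1L]] <- data.frame(
          chrom = ch, start = gstart, strand = strand, mismatches = mm,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(), start = integer(),
                      strand = character(), mismatches = integer()))
  res <- do.call(rbind, out)
  res[order(res$chrom, res$start, res$strand), , drop = FALSE]
}

# closed-form simple OLS
ols_closed_form <- function(x, y) {
  xb <- mean(x); yb <- mean(y)
  b <- sum((x - xb) * (y - yb)) / sum((x - xb)^2)
  a <- yb - b * xb
  pred <- a + b * x
  r2 <- 1 - sum((y - pred)^2) / sum((y - yb)^2)
  se <- sqrt(sum((y - pred)^2) / (length(x) - 2) / sum((x - xb)^2))
  tq <- qt(0.975, length(x) - 2)
  list(slope = b, intercept = a, r_squared = r2,
       ci = c(b - tq * se, b + tq * se))
}
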