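IUPAC_MATCH <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("G", "C"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
  D = c("A", "G", "T"), H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

#' Enumerate candidate off-target sites for a guide
#'
#' Scans both strands of the genome for occurrences of the protospacer with
#' up to `max_mismatches` mismatches immediately followed (PAM-side) by a
#' match to the PAM pattern (default NGG; IUPAC codes in the pattern match
#' their base sets, and PAM bases are never counted as mismatches). Ambiguity
#' codes in the genome count as mismatches against the protospacer. The
#' on-target site itself appears at 0 mismatches. Site coordinates are
#' 1-based closed and cover protospacer plus PAM; for minus-strand sites the
#' PAM occupies the left (lowest-coordinate) end.
#'
#' @param guide one guide: list/row with `guide_id`, `protospacer`
#'   (ACGT, 17-23 nt, PAM-proximal end last) and `pam_pattern`.
#' @param genome genome `DNAStringSet`.
#' @param max_mismatches maximum protospacer mismatches (default 5).
#' @return data.frame of sites sorted by (chrom, start, strand): `guide_id`,
#'   `chrom`, `start`, `end`, `strand`, `mismatches`, `pam_start`,
#'   `pam_end`, `site_seq` (plus strand of the genome).
#' @export
enumerate_sites <- function(guide, genome, max_mismatches = 5) {
  proto <- toupper(guide$protospacer)
  pam <- toupper(if (is.null(guide$pam_pattern) || is.na(guide$pam_pattern) ||
                     guide$pam_pattern == "") "NGG" else guide$pam_pattern)
  if (grepl("[^ACGT]", proto)) stop("protospacer alphabet must be ACGT")
  L <- nchar(proto); P <- nchar(pam)
  if (length(unique(strsplit(proto, "")[[1]])) == 1L)
    warning("homopolymer protospacer for guide ", guide$guide_id,
            ": site counts may explode")
  out <- list()
  for (ch in names(genome)) {
    fwd <- toupper(as.character(genome[[ch]]))
    clen <- nchar(fwd)
    rev <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(fwd)))
    for (strand in c("+", "-")) {
      s <- strsplit(if (strand == "+") fwd else rev, "")[[1]]
      hits <- scan_protospacer(s, proto, pam, max_mismatches)
      if (!nrow(hits)) next
      if (strand == "+") {
        start <- hits$pos
      } else {
        # position i in the reverse complement maps back to the interval
        # [clen - (i + L + P - 1) + 1, clen - i + 1] on the plus strand
        start <- clen - (hits$pos + L + P - 1L) + 1L
      }
      end <- start + L + P - 1L
      pam_start <- if (strand == "+") start + L else start
      out[[length(out) + 1L]] <- data.frame(
        guide_id = guide$guide_id, chrom = ch, start = start, end = end,
        strand = strand, mismatches = hits$mm,
        pam_start = pam_start, pam_end = pam_start + P - 1L,
        site_seq = substring(fwd, start, end),
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out))
    return(data.frame(guide_id = character(), chrom = character(),
                      start = integer(), end = integer(), strand = character(),
                      mismatches = integer(), pam_start = integer(),
                      pam_end = integer(), site_seq = character(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[!duplicated(res[c("chrom", "start", "strand")]), , drop = FALSE]
  res <- res[order(res$chrom, res$start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Vectorized scan of one strand (given as a character vector of bases):
# returns start positions (on that strand) and protospacer mismatch counts
# of all windows passing the PAM and mismatch conditions.
scan_protospacer <- function(s, proto, pam, max_mm) {
  L <- nchar(proto); P <- nchar(pam)
  n <- length(s) - (L + P) + 1L
  if (n < 1L) return(data.frame(pos = integer(), mm = integer()))
  pb <- strsplit(proto, "")[[1]]
  mm <- integer(n)
  for (k in seq_len(L))
    mm <- mm + (s[k:(k + n - 1L)] != pb[k])
  pam_ok <- rep(TRUE, n)
  pamb <- strsplit(pam, "")[[1]]
  for (k in seq_len(P)) {
    allowed <- IUPAC_MATCH[[pamb[k]]]
    if (is.null(allowed)) stop("invalid PAM pattern character: ", pamb[k])
    pam_ok <- pam_ok & (s[(L + k):(L + k + n - 1L)] %in% allowed)
  }
  keep <- which(pam_ok & mm <= max_mm)
  data.frame(pos = keep, mm = mm[keep])
}

#' Protospacer distance of a variant from the PAM
#'
#' Protospacer position 1 is the base immediately adjacent to the PAM; a
#' variant "d bases upstream of the PAM" has its leftmost changed base at
#' protospacer position d, with all arithmetic mirrored on minus-strand
#' sites. Values <= 0 indicate the PAM or beyond; values greater than the
#' protospacer length are PAM-distal flank.
#'
#' @param sites site data.frame from [enumerate_sites()].
#' @param var_start leftmost changed base(s) of the variant(s), recycled
#'   against sites.
#' @return integer vector of distances.
#' @export
distance_to_pam <- function(sites, var_start) {
  ifelse(sites$strand == "+",
         sites$pam_start - var_start,
         var_start - sites$pam_end)
}

#' Variants near predicted off-target sites
#'
#' Pairs each site with every variant whose leftmost changed base lies
#' within `window_bp` of the site interval boundaries, one row per
#' (site, variant, carrier line), annotated with the protospacer distance to
#' the PAM and the carrier's zygosity.
#'
#' @param sites data.frame from [enumerate_sites()].
#' @param variants variant data.frame with a `carriers` column
#'   (semicolon-separated), e.g. a group's specific variants.
#' @param cohort the `clonal_cohort` (for carrier zygosity lookup).
#' @param window_bp flank width around the site interval (default 100).
#' @return data.frame of hits: site columns, variant columns,
#'   `distance_to_pam`, `line_id`, `zygosity`.
#' @export
window_hits <- function(sites, variants, cohort, window_bp = 100) {
  out <- list()
  if (nrow(sites) && nrow(variants)) {
    vstart <- variant_change_start(variants)
    vkeys <- variant_key(variants)
    ckeys <- variant_key(cohort)
    for (i in seq_len(nrow(sites))) {
      near <- which(variants$chrom == sites$chrom[i] &
                    vstart >= sites$start[i] - window_bp &
                    vstart <= sites$end[i] + window_bp)
      for (j in near) {
        d <- distance_to_pam(sites[i, ], vstart[j])
        carriers <- strsplit(variants$carriers[j], ";", fixed = TRUE)[[1]]
        zyg <- cohort$geno[match(vkeys[j], ckeys), carriers]
        out[[length(out) + 1L]] <- data.frame(
          sites[i, c("guide_id", "chrom", "start", "end", "strand",
                     "mismatches", "pam_start", "pam_end")],
          variant = vkeys[j], pos = variants$pos[j],
          ref = variants$ref[j], alt = variants$alt[j],
          distance_to_pam = d, line_id = carriers,
          zygosity = unname(zyg),
          stringsAsFactors = FALSE, row.names = NULL
        )
      }
    }
  }
  if (!length(out))
    return(data.frame(guide_id = character(), chrom = character(),
                      start = integer(), end = integer(), strand = character(),
                      mismatches = integer(), pam_start = integer(),
                      pam_end = integer(), variant = character(),
                      pos = integer(), ref = character(), alt = character(),
                      distance_to_pam = integer(), line_id = character(),
                      zygosity = character(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Classify near-site hits as genuine off-targets
#'
#' A hit is a genuine editing off-target when its leftmost changed base lies
#' 2-5 bases upstream of the PAM (the Cas9 cleavage-consistent window) and
#' the carrier is heterozygous. Rejected hits carry a reason code:
#' `homozygous` (in-window but not het), `outside_cleavage_window`
#' (within the protospacer but outside positions 2-5, or in the PAM),
#' `pam_distal` (beyond the protospacer on either flank).
#'
#' @param hits data.frame from [window_hits()].
#' @param cleavage_range inclusive protospacer-position window
#'   (default `c(2, 5)`).
#' @param protospacer_length protospacer length used to separate
#'   `outside_cleavage_window` from `pam_distal` (default 20).
#' @return `hits` with `genuine` (logical) and `reason` columns.
#' @export
classify_genuine <- function(hits, cleavage_range = c(2, 5),
                             protospacer_length = 20) {
  d <- hits$distance_to_pam
  in_window <- d >= cleavage_range[1] & d <= cleavage_range[2]
  het <- hits$zygosity == "het"
  hits$genuine <- in_window & het
  hits$reason <- ifelse(hits$genuine, "",
                 ifelse(!in_window,
                        ifelse(d >= 1 & d <= protospacer_length,
                               "outside_cleavage_window", "pam_distal"),
                        "homozygous"))
  hits
}

#' Cohort-wide off-target summary
#'
#' Counts candidate and genuine off-target hits per line and per
#' editing-method class (double-strand-break methods — CRISPR and TALEN
#' pooled — versus prime editing), and lists genuine hits shared by several
#' lines (same site and same variant), each reported once.
#'
#' @param hits classified hits (possibly combined over all experiments).
#' @param meta cohort metadata.
#' @return list with `per_line`, `per_method_class` and `shared` data.frames.
#' @export
offtarget_report <- function(hits, meta) {
  lines <- meta$line_id[meta$role %in% c("edited", "edited_wildtype")]
  per_line <- data.frame(
    line_id = lines,
    method = meta$method[match(lines, meta$line_id)],
    candidate_hits = 0L, genuine_hits = 0L,
    stringsAsFactors = FALSE
  )
  if (nrow(hits)) {
    cand <- table(hits$line_id)
    genu <- table(hits$line_id[hits$genuine])
    per_line$candidate_hits <- as.integer(cand[per_line$line_id])
    per_line$genuine_hits <- as.integer(genu[per_line$line_id])
    per_line$candidate_hits[is.na(per_line$candidate_hits)] <- 0L
    per_line$genuine_hits[is.na(per_line$genuine_hits)] <- 0L
  }
  per_line$method_class <- ifelse(per_line$method %in% DSB_METHODS, "dsb",
                           ifelse(per_line$method == "prime", "prime", "none"))
  agg <- stats::aggregate(cbind(candidate_hits, genuine_hits) ~ method_class,
                          data = per_line, FUN = sum)
  shared <- data.frame(variant = character(), guide_id = character(),
                       n_lines = integer(), lines = character(),
                       stringsAsFactors = FALSE)
  if (nrow(hits)) {
    gh <- hits[hits$genuine, , drop = FALSE]
    if (nrow(gh)) {
      key <- paste(gh$guide_id, gh$chrom, gh$start, gh$strand, gh$variant)
      tab <- split(gh$line_id, key)
      multi <- tab[vapply(tab, function(x) length(unique(x)), 1L) >= 2L]
      if (length(multi)) {
        first <- gh[match(names(multi), key), , drop = FALSE]
        shared <- data.frame(
          variant = first$variant, guide_id = first$guide_id,
          n_lines = vapply(multi, function(x) length(unique(x)), 1L),
          lines = vapply(multi, function(x)
            paste(sort(unique(x)), collapse = ";"), ""),
          stringsAsFactors = FALSE, row.names = NULL
        )
      }
    }
  }
  list(per_line = per_line, per_method_class = agg, shared = shared)
}
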