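#' Loss-of-heterozygosity call at an edited locus
#'
#' Computational analog of zygosity confirmation: markers that are
#' heterozygous in the parental line should remain heterozygous in a clone
#' unless the editing process deleted or converted one haplotype. The call
#' inspects the nearest informative parental-het marker on each side of the
#' edit locus within `radius_bp`:
#' * `retained_het` — any inspected flanking marker is still het;
#' * `loh` — every inspected flanking marker is homozygous and (by default)
#'   both sides are informative;
#' * `indeterminate` — a required side has no informative marker in range.
#'
#' By default both flanks are required (robust to an isolated genotyping
#' error); `single_marker = TRUE` reproduces the stricter single
#' nearest-marker analog of a one-amplicon wet-lab assay. Markers whose
#' clone genotype is missing are skipped (next nearest used); markers at
#' positions touched by the clone's expected edits are excluded.
#'
#' @param line_id clone to screen.
#' @param edit_locus list/row with `chrom` and `pos`.
#' @param markers data.frame of parental-heterozygous marker positions
#'   (`chrom`, `pos`).
#' @param clone_geno named character vector: marker key `chrom:pos` ->
#'   genotype class of the clone.
#' @param radius_bp search radius on each side (default 1e6).
#' @param single_marker use only the overall nearest marker.
#' @param exclude_pos positions (on `edit_locus$chrom`) to exclude, e.g.
#'   the edit alleles themselves.
#' @return one-row data.frame (`loh_call`): `line_id`, `chrom`, `pos`,
#'   `verdict`, `left_marker`, `left_geno`, `right_marker`, `right_geno`,
#'   `search_radius_bp`.
#' @export
detect_loh <- function(line_id, edit_locus, markers, clone_geno,
                       radius_bp = 1e6, single_marker = FALSE,
                       exclude_pos = integer(0)) {
  ch <- edit_locus$chrom; p <- edit_locus$pos
  if (!any(markers$chrom == ch))
    stop("edit locus chromosome ", ch, " unknown to the marker panel")
  mk <- markers[markers$chrom == ch & !(markers$pos %in% exclude_pos), ,
                drop = FALSE]
  key <- paste(mk$chrom, mk$pos, sep = ":")
  g <- clone_geno[key]
  informative <- !is.na(g) & g != "missing"
  mk <- mk[informative, , drop = FALSE]; g <- g[informative]
  left <- which(mk$pos < p & mk$pos >= p - radius_bp)
  right <- which(mk$pos > p & mk$pos <= p + radius_bp)
  pick <- function(idx, side) {
    if (!length(idx)) return(NULL)
    i <- idx[which.min(abs(mk$pos[idx] - p))]
    list(pos = mk$pos[i], geno = unname(g[i]))
  }
  l <- pick(left); r <- pick(right)
  if (single_marker) {
    nearest <- if (is.null(l)) r else if (is.null(r)) l else
      if (abs(l$pos - p) <= abs(r$pos - p)) l else r
    verdict <- if (is.null(nearest)) "indeterminate" else
      if (nearest$geno == "het") "retained_het" else "loh"
  } else {
    genos <- c(if (!is.null(l)) l$geno, if (!is.null(r)) r$geno)
    verdict <- if (any(genos == "het")) "retained_het" else
      if (!is.null(l) && !is.null(r)) "loh" else "indeterminate"
  }
  data.frame(
    line_id = line_id, chrom = ch, pos = p, verdict = verdict,
    left_marker = if (is.null(l)) NA_integer_ else l$pos,
    left_geno = if (is.null(l)) NA_character_ else l$geno,
    right_marker = if (is.null(r)) NA_integer_ else r$pos,
    right_geno = if (is.null(r)) NA_character_ else r$geno,
    search_radius_bp = radius_bp,
    stringsAsFactors = FALSE
  )
}

#' Screen every edited clone for LOH at its edited loci
#'
#' Derives the parental-het marker panel from the cohort itself (variants
#' het in the parental line, at or above `min_qual`) and calls
#' [detect_loh()] for each (edited clone, expected edit locus) pair.
#' Verdicts can feed the `loh_zygosity` assay of the QC table.
#'
#' @param cohort a `clonal_cohort` containing a `parental` line.
#' @param radius_bp,single_marker passed to [detect_loh()].
#' @return data.frame of LOH calls, one row per clone x edited locus.
#' @export
loh_screen <- function(cohort, radius_bp = 1e6, single_marker = FALSE) {
  meta <- cohort$meta
  parental <- meta$line_id[meta$role == "parental"]
  if (length(parental) != 1L)
    stop("cohort must contain exactly one parental line (found ",
         length(parental), ")")
  is_marker <- cohort$geno[, parental] == "het"
  markers <- cohort$variants[is_marker, c("chrom", "pos"), drop = FALSE]
  mgeno <- cohort$geno[is_marker, , drop = FALSE]
  rownames(mgeno) <- paste(markers$chrom, markers$pos, sep = ":")
  edits <- expected_edit_table(meta[meta$role == "edited", , drop = FALSE])
  calls <- lapply(seq_len(nrow(edits)), function(i) {
    detect_loh(edits$line_id[i],
               list(chrom = edits$chrom[i], pos = edits$pos[i]),
               markers, mgeno[, edits$line_id[i]],
               radius_bp = radius_bp, single_marker = single_marker,
               exclude_pos = edits$pos[edits$line_id == edits$line_id[i]])
  })
  out <- do.call(rbind, calls)
  if (is.null(out))
    out <- data.frame(line_id = character(), chrom = character(),
                      pos = integer(), verdict = character(),
                      left_marker = integer(), left_geno = character(),
                      right_marker = integer(), right_geno = character(),
                      search_radius_bp = numeric(), stringsAsFactors = FALSE)
  out
}
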