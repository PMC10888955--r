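#' @importFrom stats lm confint rpois runif setNames var
#' @importFrom utils read.delim write.table
NULL

GT_CLASSES <- c("hom_ref", "het", "hom_alt", "missing")
LINE_ROLES <- c("parental", "subclone", "edited", "edited_wildtype")
EDIT_METHODS <- c("crispr_hdr", "crispr_dual", "talen", "prime", "none")
DSB_METHODS <- c("crispr_hdr", "crispr_dual", "talen")

#' Assemble a clonal cohort object
#'
#' Bundles a normalized variant table, a per-line genotype-class matrix and
#' the line metadata into the container shared by every analysis stage.
#'
#' @param variants data.frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt` (exactly one alternate allele per row) and `qual` (joint-genotyping
#'   quality, non-negative).
#' @param geno character matrix, one row per variant and one column per line,
#'   with entries in `"hom_ref"`, `"het"`, `"hom_alt"`, `"missing"`. Column
#'   names must be the line ids.
#' @param meta data.frame of line metadata with columns `line_id`, `group_id`,
#'   `experiment_id`, `role` (parental/subclone/edited/edited_wildtype),
#'   `method` (crispr_hdr/crispr_dual/talen/prime/none), `passage`,
#'   `parent_line`, `expected_edits` (semicolon-separated
#'   `chrom:pos:ref:alt:zygosity`, empty if none) and `guide_ids`
#'   (comma-separated).
#' @param guides optional data.frame with columns `guide_id`, `protospacer`,
#'   `pam_pattern`, `kind`.
#' @return An object of class `clonal_cohort`: a list with elements
#'   `variants`, `geno`, `meta`, `guides`, sorted by (chrom, pos, ref, alt).
#' @export
new_cohort <- function(variants, geno, meta, guides = NULL) {
  stopifnot(is.data.frame(variants), is.matrix(geno), is.data.frame(meta))
  need <- c("chrom", "pos", "ref", "alt", "qual")
  if (!all(need %in% names(variants)))
    stop("variants must have columns: ", paste(need, collapse = ", "))
  if (nrow(geno) != nrow(variants))
    stop("geno must have one row per variant")
  if (is.null(colnames(geno)) || !setequal(colnames(geno), meta$line_id))
    stop("geno column names must match meta$line_id")
  geno <- geno[, meta$line_id, drop = FALSE]
  bad <- !(geno %in% GT_CLASSES)
  if (any(bad))
    stop("invalid genotype class: ", paste(unique(geno[bad]), collapse = ", "))
  if (any(variants$pos < 1)) stop("positions must be >= 1")
  if (any(variants$ref == variants$alt)) stop("ref must differ from alt")
  if (any(grepl(",", variants$alt, fixed = TRUE)))
    stop("multiallelic rows must be split before cohort construction")
  if (any(variants$qual < 0)) stop("qual must be non-negative")
  meta <- validate_meta(meta)
  ord <- order(variants$chrom, variants$pos, variants$ref, variants$alt)
  variants <- variants[ord, , drop = FALSE]
  geno <- geno[ord, , drop = FALSE]
  rownames(variants) <- NULL
  rownames(geno) <- NULL
  structure(
    list(variants = variants, geno = geno, meta = meta, guides = guides),
    class = "clonal_cohort"
  )
}

validate_meta <- function(meta) {
  need <- c("line_id", "group_id", "experiment_id", "role", "method",
            "passage", "parent_line", "expected_edits", "guide_ids")
  miss <- setdiff(need, names(meta))
  if (length(miss)) stop("metadata lacks columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(meta$line_id))
    stop("duplicated line_id in metadata")
  if (!all(meta$role %in% LINE_ROLES))
    stop("unknown role: ", paste(setdiff(meta$role, LINE_ROLES), collapse = ", "))
  if (!all(meta$method %in% EDIT_METHODS))
    stop("unknown method: ", paste(setdiff(meta$method, EDIT_METHODS), collapse = ", "))
  if (any(!is.na(meta$passage) & meta$passage < 0)) stop("passage must be >= 0")
  meta$expected_edits[is.na(meta$expected_edits)] <- ""
  meta$guide_ids[is.na(meta$guide_ids)] <- ""
  meta$parent_line[is.na(meta$parent_line)] <- ""
  ed <- meta$role == "edited"
  if (any(ed & meta$expected_edits == ""))
    stop("edited lines must declare expected_edits: ",
         paste(meta$line_id[ed & meta$expected_edits == ""], collapse = ", "))
  ewt <- meta$role == "edited_wildtype"
  if (any(ewt & meta$expected_edits != ""))
    stop("edited_wildtype lines must not declare expected_edits")
  for (i in which(ewt)) {
    if (!any(ed & meta$experiment_id == meta$experiment_id[i]))
      stop("edited_wildtype line ", meta$line_id[i],
           " has no edited line in experiment ", meta$experiment_id[i])
  }
  rownames(meta) <- NULL
  meta
}

#' @export
print.clonal_cohort <- function(x, ...) {
  cat("clonal_cohort:", nrow(x$variants), "variants x",
      nrow(x$meta), "lines\n")
  cat("  roles:", paste(sprintf("%s=%d", names(table(x$meta$role)),
                                table(x$meta$role)), collapse = " "), "\n")
  cat("  groups:", paste(unique(stats::na.omit(x$meta$group_id)), collapse = " "), "\n")
  if (!is.null(x$guides)) cat("  guides:", nrow(x$guides), "\n")
  invisible(x)
}

#' Variant presence matrix
#'
#' A variant is present in a line when the genotype is `het` or `hom_alt`;
#' `missing` counts as absent (missingness is reported separately by
#' [validate_cohort()]).
#'
#' @param cohort a `clonal_cohort`.
#' @return logical matrix, variants x lines.
#' @export
cohort_presence <- function(cohort) {
  m <- cohort$geno == "het" | cohort$geno == "hom_alt"
  dimnames(m) <- dimnames(cohort$geno)
  m
}

#' Canonical variant key strings ("chrom:pos:ref:alt")
#' @param variants variant data.frame (or a `clonal_cohort`).
#' @return character vector of keys.
#' @export
variant_key <- function(variants) {
  if (inherits(variants, "clonal_cohort")) variants <- variants$variants
  paste(variants$chrom, variants$pos, variants$ref, variants$alt, sep = ":")
}

#' Parse the expected-edit declarations out of line metadata
#'
#' @param meta cohort metadata.
#' @return data.frame with one row per declared edit: `line_id`, `chrom`,
#'   `pos`, `ref`, `alt`, `zygosity`.
#' @export
expected_edit_table <- function(meta) {
  rows <- lapply(seq_len(nrow(meta)), function(i) {
    s <- meta$expected_edits[i]
    if (is.na(s) || s == "") return(NULL)
    parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
    bad <- vapply(parts, length, 1L) != 5L
    if (any(bad))
      stop("malformed expected_edits for line ", meta$line_id[i], ": ", s)
    data.frame(
      line_id = meta$line_id[i],
      chrom = vapply(parts, `[`, "", 1L),
      pos = as.integer(vapply(parts, `[`, "", 2L)),
      ref = vapply(parts, `[`, "", 3L),
      alt = vapply(parts, `[`, "", 4L),
      zygosity = vapply(parts, `[`, "", 5L),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(line_id = character(), chrom = character(),
                      pos = integer(), ref = character(), alt = character(),
                      zygosity = character(), stringsAsFactors = FALSE)
  out
}

#' Cross-file consistency checks and cohort summary
#'
#' Verifies the container invariants (every line genotyped for every variant,
#' single alternate allele per record, metadata role constraints, guide
#' references resolvable) and tallies per-line genotype missingness.
#'
#' @param cohort a `clonal_cohort`.
#' @return Invisibly, a list with `n_variants`, `n_lines`, `missingness`
#'   (per-line fraction of missing genotypes) and `guide_refs_ok`.
#' @export
validate_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "clonal_cohort"))
  miss <- colMeans(cohort$geno == "missing")
  guide_refs_ok <- TRUE
  gids <- unlist(strsplit(cohort$meta$guide_ids, ",", fixed = TRUE))
  gids <- gids[gids != ""]
  if (length(gids)) {
    if (is.null(cohort$guides)) {
      warning("metadata references guides but no guide table was supplied")
      guide_refs_ok <- FALSE
    } else if (!all(gids %in% cohort$guides$guide_id)) {
      warning("unresolved guide ids: ",
              paste(setdiff(gids, cohort$guides$guide_id), collapse = ", "))
      guide_refs_ok <- FALSE
    }
  }
  invisible(list(
    n_variants = nrow(cohort$variants),
    n_lines = nrow(cohort$meta),
    missingness = miss,
    guide_refs_ok = guide_refs_ok
  ))
}
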