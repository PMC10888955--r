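#' Mutations-per-passage regression
#'
#' Ordinary least squares of per-line unique-variant counts on the passage
#' number at each line's last clonal event. The slope estimates the
#' per-passage mutation accumulation rate; the intercept is negative when a
#' shared pre-clonal culture period contributed founder (non-unique)
#' variants.
#'
#' @param unique_counts named integer vector, line_id -> unique-variant
#'   count (e.g. `sharing_report(...)$per_line_unique_counts`).
#' @param meta cohort metadata (supplies `passage`); lines without passage
#'   metadata are dropped with a warning.
#' @return list of class `mutation_rate_fit`: `slope`, `intercept`,
#'   `r_squared`, `slope_ci95` (low, high), `n`, and the underlying `lm`
#'   fit.
#' @export
fit_mutation_rate <- function(unique_counts, meta) {
  passage <- meta$passage[match(names(unique_counts), meta$line_id)]
  ok <- !is.na(passage)
  if (any(!ok))
    warning("dropping lines without passage metadata: ",
            paste(names(unique_counts)[!ok], collapse = ", "))
  x <- passage[ok]; y <- as.numeric(unique_counts[ok])
  if (length(x) < 3L) stop("need at least 3 lines with known passage")
  if (var(x) == 0) stop("zero passage variance: slope undefined")
  if (var(y) == 0) stop("zero variance in unique-variant counts: ",
                        "regression degenerate")
  fit <- lm(y ~ x)
  ci <- confint(fit, "x", level = 0.95)
  structure(list(
    slope = unname(coef(fit)["x"]),
    intercept = unname(coef(fit)["(Intercept)"]),
    r_squared = summary(fit)$r.squared,
    slope_ci95 = c(low = ci[1], high = ci[2]),
    n = length(x),
    fit = fit
  ), class = "mutation_rate_fit")
}

#' @export
print.mutation_rate_fit <- function(x, ...) {
  cat(sprintf("y = %.2fx %+.2f;  R2 = %.4f;  slope 95%% CI: %.2f to %.2f (n = %d)\n",
              x$slope, x$intercept, x$r_squared,
              x$slope_ci95["low"], x$slope_ci95["high"], x$n))
  invisible(x)
}

# half-up rounding so 2/18 prints as 11.11 and 16/81 as 19.75
round_half_up <- function(x, digits = 2) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Quality-control summary rates
#'
#' Per-assay failure percentages, the overall exclusion rate (distinct lines
#' failing any tested assay over distinct lines tested in any assay), and
#' the same breakdown within editing-method classes (double-strand-break
#' methods — CRISPR/TALEN pooled — versus prime editing). Percentages are
#' `100 * failed / tested`, rounded half-up to 2 decimals; an assay with no
#' tested lines reports `NA`, never 0.
#'
#' @param qc data.frame of QC records: `line_id`, `assay`, `tested`
#'   (logical), `passed` (logical, defined only when tested).
#' @param meta optional cohort metadata providing each line's editing
#'   method for the per-method-class breakdown.
#' @return list of class `qc_summary`: `per_assay`, `overall`,
#'   `per_method_class` data.frames.
#' @export
qc_rates <- function(qc, meta = NULL) {
  stopifnot(all(c("line_id", "assay", "tested", "passed") %in% names(qc)))
  if (any(qc$tested & is.na(qc$passed)))
    stop("tested records must define passed")
  all_assays <- sort(unique(qc$assay))
  qc <- qc[qc$tested, , drop = FALSE]
  tally <- function(d, assays = all_assays) {
    tested_n <- vapply(assays, function(a) sum(d$assay == a), 1L)
    failed_n <- vapply(assays, function(a) sum(d$assay == a & !d$passed), 1L)
    data.frame(assay = assays, tested_n = tested_n, failed_n = failed_n,
               failed_pct = ifelse(tested_n > 0,
                                   round_half_up(100 * failed_n / tested_n),
                                   NA_real_),
               row.names = NULL, stringsAsFactors = FALSE)
  }
  per_assay <- tally(qc)
  analyzed <- unique(qc$line_id)
  excluded <- unique(qc$line_id[!qc$passed])
  overall <- data.frame(
    analyzed_n = length(analyzed), excluded_n = length(excluded),
    excluded_pct = if (length(analyzed))
      round_half_up(100 * length(excluded) / length(analyzed)) else NA_real_
  )
  per_method_class <- NULL
  if (!is.null(meta)) {
    method <- meta$method[match(qc$line_id, meta$line_id)]
    cls <- ifelse(method %in% DSB_METHODS, "dsb",
                  ifelse(method == "prime", "prime", "none"))
    per_method_class <- do.call(rbind, lapply(c("dsb", "prime"), function(k) {
      d <- qc[cls == k, , drop = FALSE]
      if (!nrow(d)) return(NULL)
      cbind(method_class = k, tally(d))
    }))
  }
  structure(list(per_assay = per_assay, overall = overall,
                 per_method_class = per_method_class),
            class = "qc_summary")
}

#' @export
print.qc_summary <- function(x, ...) {
  cat(sprintf("QC: %d lines analyzed, %d excluded (%.2f%%)\n",
              x$overall$analyzed_n, x$overall$excluded_n,
              x$overall$excluded_pct))
  for (i in seq_len(nrow(x$per_assay)))
    cat(sprintf("  %-22s %2d / %2d failed (%.2f%%)\n",
                x$per_assay$assay[i], x$per_assay$failed_n[i],
                x$per_assay$tested_n[i], x$per_assay$failed_pct[i]))
  invisible(x)
}

#' Jaccard distance matrix over group-specific variant sets
#'
#' Each group-member line is represented by its presence vector over the
#' union of all groups' specific variants;
#' `distance(i, j) = 1 - |Vi intersect Vj| / |Vi union Vj|`. Two lines with
#' empty variant sets are at distance 0; an empty set is at distance 1 from
#' every non-empty set (with a warning).
#'
#' @param sets list of `group_variant_sets` (e.g. `attribute_cohort(x)$sets`).
#' @return symmetric numeric matrix with zero diagonal.
#' @export
variant_distance_matrix <- function(sets) {
  if (inherits(sets, "group_variant_sets")) sets <- list(sets)
  lines <- unique(unlist(lapply(sets, `[[`, "members")))
  keys <- unlist(lapply(sets, function(s) colnames(s$sharing)))
  m <- matrix(FALSE, length(lines), length(keys),
              dimnames = list(lines, keys))
  for (s in sets) m[s$members, colnames(s$sharing)] <- s$sharing
  sizes <- rowSums(m)
  if (any(sizes == 0))
    warning("line(s) with empty variant set: ",
            paste(lines[sizes == 0], collapse = ", "))
  inter <- m %*% t(m)
  union <- outer(sizes, sizes, `+`) - inter
  d <- 1 - inter / union
  d[union == 0] <- 0  # two empty sets
  diag(d) <- 0
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Builds the presence/absence phylogeny of the collection by
#' neighbor-joining (via [ape::nj()]); negative branch lengths are clamped
#' to zero (standard practice) and the result round-trips through Newick.
#'
#' @param d symmetric non-negative distance matrix, >= 3 leaves.
#' @return an [ape::phylo] tree.
#' @export
build_tree <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3L) stop("need at least 3 leaves")
  if (!isSymmetric(unname(d), tol = 1e-8)) stop("distance matrix must be symmetric")
  if (any(d < 0)) stop("distances must be non-negative")
  tree <- ape::nj(d)
  tree$edge.length[tree$edge.length < 0] <- 0
  tree
}

#' Nearest leaf of each tree tip by patristic distance
#'
#' @param tree an `ape::phylo`.
#' @return named character vector: for each tip, the closest other tip
#'   (ties broken by label order).
#' @export
nearest_leaves <- function(tree) {
  pd <- ape::cophenetic.phylo(tree)
  pd <- pd[order(rownames(pd)), order(colnames(pd))]
  diag(pd) <- Inf
  setNames(colnames(pd)[apply(pd, 1L, which.min)], rownames(pd))
}
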