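#' Run the full attribution analysis end to end
#'
#' Executes the stages in order: validate, normalize (when a genome is
#' supplied), quality-filter, per-group attribution, coding-impact
#' annotation (when transcripts are supplied), off-target assessment (when
#' guides are present: site enumeration per guide, near-site hit collection
#' over each group's specific variants excluding the on-target edits,
#' cleavage-window classification, and re-labelling of genuine hits),
#' LOH screening, mutation-rate regression, QC summary and the
#' presence/absence phylogeny. A stage failure aborts with the stage name;
#' the run is deterministic given identical inputs.
#'
#' @param cohort a `clonal_cohort`.
#' @param genome optional genome `DNAStringSet` (enables normalization,
#'   coding impact and off-target enumeration).
#' @param transcripts optional `transcript_models`.
#' @param qc optional QC outcome table (see [qc_rates()]).
#' @param min_qual quality threshold (default 30).
#' @param window_bp off-target flank window (default 100).
#' @param max_mismatches protospacer mismatch tolerance (default 5).
#' @param cleavage_range genuine-off-target PAM distance window
#'   (default `c(2, 5)`).
#' @param loh_radius LOH marker search radius in bp (default 1e6).
#' @param loh_single_marker use the single nearest-marker LOH rule.
#' @param exclude_against_unfiltered judge presence in lines outside each
#'   group on the pre-filter call set instead of the quality-filtered one.
#' @return list of class `clonovar_run` with elements `cohort` (filtered),
#'   `attributed`, `sets`, `sharing`, `impact`, `offtarget`
#'   (`sites`/`hits`/`report`), `loh`, `fit`, `qc_summary`, `dist`, `tree`,
#'   `manifest`.
#' @export
run_pipeline <- function(cohort, genome = NULL, transcripts = NULL,
                         qc = NULL, min_qual = 30, window_bp = 100,
                         max_mismatches = 5, cleavage_range = c(2, 5),
                         loh_radius = 1e6, loh_single_marker = FALSE,
                         exclude_against_unfiltered = FALSE) {
  manifest <- list(params = list(
    min_qual = min_qual, window_bp = window_bp,
    max_mismatches = max_mismatches, cleavage_range = cleavage_range,
    loh_radius = loh_radius))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           "; completed stages: ",
           paste(names(manifest), collapse = ", "), call. = FALSE))
  }
  stage("validate", {
    v <- validate_cohort(cohort)
    manifest$validate <- list(n_variants = v$n_variants,
                              n_lines = v$n_lines)
  })
  if (!is.null(genome)) stage("normalize", {
    cohort <- normalize_cohort(cohort, genome)
    manifest$normalize <- list(n_variants = nrow(cohort$variants))
  })
  n_in <- nrow(cohort$variants)
  prefilter <- cohort
  stage("filter", {
    cohort <- filter_by_quality(cohort, min_qual)
    manifest$filter <- list(variants_in = n_in,
                            variants_retained = nrow(cohort$variants),
                            variants_filtered = n_in - nrow(cohort$variants))
  })
  att <- NULL
  stage("attribute", {
    att <- attribute_cohort(cohort,
                            exclude_against = if (exclude_against_unfiltered)
                              prefilter else NULL)
    manifest$attribute <- list(
      n_groups = length(att$sets),
      n_specific = nrow(att$attributed),
      labels = as.list(table(att$attributed$label)))
  })
  attributed <- att$attributed

  if (!is.null(genome) && !is.null(transcripts)) stage("annotate", {
    attributed <- annotate_variants(attributed, transcripts, genome)
    manifest$annotate <- list(regions = as.list(table(attributed$region)))
  })

  ot <- NULL
  has_guides <- !is.null(cohort$guides) && nrow(cohort$guides) > 0 &&
    any(cohort$meta$guide_ids != "")
  if (has_guides && !is.null(genome)) {
    stage("offtarget", {
      all_sites <- list(); all_hits <- list()
      for (g in names(att$sets)) {
        grp_meta <- cohort$meta[cohort$meta$line_id %in% att$sets[[g]]$members, ]
        gids <- setdiff(unique(unlist(
          strsplit(grp_meta$guide_ids, ",", fixed = TRUE))), "")
        if (!length(gids)) next
        gvar <- attributed[attributed$group_id == g &
                           attributed$label != "on_target", , drop = FALSE]
        for (gid in gids) {
          guide <- cohort$guides[cohort$guides$guide_id == gid, ]
          sites <- enumerate_sites(guide, genome, max_mismatches)
          all_sites[[gid]] <- sites
          h <- window_hits(sites, gvar, cohort, window_bp)
          if (nrow(h)) all_hits[[length(all_hits) + 1L]] <- h
        }
      }
      sites <- if (length(all_sites)) do.call(rbind, all_sites) else NULL
      hits <- if (length(all_hits)) do.call(rbind, all_hits) else
        window_hits(enumerate_sites(cohort$guides[1, ], genome, 0)[0, ],
                    attributed[0, ], cohort, window_bp)
      hits <- classify_genuine(hits, cleavage_range)
      genuine_keys <- unique(hits$variant[hits$genuine])
      akeys <- paste(attributed$chrom, attributed$pos, attributed$ref,
                     attributed$alt, sep = ":")
      attributed$label[akeys %in% genuine_keys] <- "off_target_genuine"
      ot <- list(sites = sites, hits = hits,
                 report = offtarget_report(hits, cohort$meta))
      manifest$offtarget <- list(
        n_sites = if (is.null(sites)) 0L else nrow(sites),
        n_hits = nrow(hits), n_genuine = sum(hits$genuine))
    })
  } else if (has_guides) {
    warning("guides present but no genome supplied: off-target stage skipped")
  } else {
    warning("cohort has no guides: off-target stage skipped")
  }

  loh <- NULL
  if (any(cohort$meta$role == "parental") &&
      any(cohort$meta$role == "edited")) stage("loh", {
    loh <- loh_screen(cohort, radius_bp = loh_radius,
                      single_marker = loh_single_marker)
    manifest$loh <- list(n_calls = nrow(loh),
                         verdicts = as.list(table(loh$verdict)))
  })

  sharing <- NULL; fit <- NULL; qcs <- NULL
  stage("stats", {
    sharing <- sharing_report(att$sets)
    fit <- tryCatch(
      fit_mutation_rate(sharing$per_line_unique_counts, cohort$meta),
      error = function(e) { warning("mutation-rate fit: ",
                                    conditionMessage(e)); NULL })
    if (!is.null(qc)) qcs <- qc_rates(qc, cohort$meta)
    manifest$stats <- list(
      slope = if (is.null(fit)) NA_real_ else fit$slope)
  })

  dist <- NULL; tree <- NULL
  stage("tree", {
    if (length(att$sets)) {
      dist <- variant_distance_matrix(att$sets)
      if (nrow(dist) >= 3L) tree <- build_tree(dist)
    }
    manifest$tree <- list(n_leaves = if (is.null(tree)) 0L
                          else length(tree$tip.label))
  })

  structure(list(cohort = cohort, attributed = attributed, sets = att$sets,
                 sharing = sharing, offtarget = ot, loh = loh, fit = fit,
                 qc_summary = qcs, dist = dist, tree = tree,
                 manifest = manifest),
            class = "clonovar_run")
}

#' Write a report bundle for a pipeline run
#'
#' TSVs for attribution, off-target hits, LOH calls, the sharing matrix and
#' QC summary, the tree as Newick, and a JSON manifest with per-stage
#' counts and md5 checksums of every written file.
#'
#' @param run a `clonovar_run`.
#' @param dir output directory.
#' @return invisibly, the manifest list.
#' @export
write_report <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  put <- function(df, name) {
    p <- file.path(dir, name)
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    files[[length(files) + 1L]] <<- p
  }
  put(run$attributed, "attributed_variants.tsv")
  if (!is.null(run$offtarget)) {
    put(run$offtarget$hits, "offtarget_hits.tsv")
    put(run$offtarget$report$per_line, "offtarget_per_line.tsv")
  }
  if (!is.null(run$loh)) put(run$loh, "loh_calls.tsv")
  if (!is.null(run$sharing)) {
    m <- as.data.frame(run$sharing$matrix)
    m <- cbind(line_id = rownames(run$sharing$matrix), m)
    put(m, "sharing_matrix.tsv")
  }
  if (!is.null(run$qc_summary)) put(run$qc_summary$per_assay,
                                    "qc_per_assay.tsv")
  if (!is.null(run$tree)) {
    p <- file.path(dir, "phylogeny.nwk")
    ape::write.tree(run$tree, p)
    files[[length(files) + 1L]] <- p
  }
  manifest <- run$manifest
  manifest$files <- lapply(files, function(p)
    list(path = basename(p), md5 = unname(tools::md5sum(p))))
  if (!is.null(run$fit))
    manifest$stats$slope_ci95 <- unname(run$fit$slope_ci95)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
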