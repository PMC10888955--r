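#' Quality-filter variant records
#'
#' Retains exactly the records whose joint-genotyping quality score is
#' greater than or equal to `min_qual` (default 30), preserving order.
#'
#' @param cohort a `clonal_cohort` (or a bare variant data.frame, in which
#'   case a data.frame is returned).
#' @param min_qual minimum quality score, inclusive.
#' @return the filtered cohort (or data.frame).
#' @export
filter_by_quality <- function(cohort, min_qual = 30) {
  stopifnot(min_qual >= 0)
  if (is.data.frame(cohort))
    return(cohort[cohort$qual >= min_qual, , drop = FALSE])
  keep <- cohort$variants$qual >= min_qual
  cohort$variants <- cohort$variants[keep, , drop = FALSE]
  cohort$geno <- cohort$geno[keep, , drop = FALSE]
  rownames(cohort$variants) <- NULL
  rownames(cohort$geno) <- NULL
  cohort
}

#' Lines belonging to an editing group
#'
#' Group membership is the set of lines whose `group_id` matches, plus the
#' untargeted (`edited_wildtype`) control clones isolated from the same
#' targeting experiments as the group's edited clones. Parental lines and
#' parental subclones never belong to a group.
#'
#' @param meta cohort metadata.
#' @param group_id the editing-group label.
#' @return character vector of member line ids.
#' @export
group_members <- function(meta, group_id) {
  groups <- unique(meta$group_id[meta$role %in% c("edited", "edited_wildtype")])
  if (!group_id %in% groups)
    stop("unknown group '", group_id, "'; valid groups: ",
         paste(sort(groups), collapse = ", "))
  in_group <- !is.na(meta$group_id) & meta$group_id == group_id &
    meta$role %in% c("edited", "edited_wildtype")
  exps <- unique(meta$experiment_id[in_group & meta$role == "edited"])
  ewt <- meta$role == "edited_wildtype" & meta$experiment_id %in% exps
  meta$line_id[in_group | ewt]
}

#' Group-specific variants (parental-proxy exclusion filter)
#'
#' Implements the cross-line exclusion: a variant is specific to an editing
#' group when it is present (het or hom_alt) in at least one group member
#' and absent from every line outside the group. Presence in any other line
#' of the collection — parental, subclone, or any other group's clone —
#' removes the variant, as a proxy for parental standing variation.
#'
#' @param cohort a quality-filtered `clonal_cohort`.
#' @param group_id editing-group label.
#' @param exclude_against optional second `clonal_cohort` (typically the
#'   unfiltered call set) whose genotypes are used to judge presence in the
#'   *other* lines; by default the filtered cohort itself. Excluding
#'   against raw calls is stricter: a variant seen outside the group only
#'   as a low-quality call is still removed.
#' @return an object of class `group_variant_sets`: list with `group_id`,
#'   `members`, `variants` (the specific records, with `carriers` and
#'   `n_carriers` columns), `sharing` (carriers x variants logical matrix)
#'   and `per_line_unique_counts`.
#' @export
group_specific_variants <- function(cohort, group_id,
                                    exclude_against = NULL) {
  members <- group_members(cohort$meta, group_id)
  others <- setdiff(cohort$meta$line_id, members)
  pres <- cohort_presence(cohort)
  in_members <- rowSums(pres[, members, drop = FALSE]) >= 1L
  if (is.null(exclude_against)) {
    in_others <- rowSums(pres[, others, drop = FALSE]) >= 1L
  } else {
    ref_pres <- cohort_presence(exclude_against)
    idx <- match(variant_key(cohort), variant_key(exclude_against))
    in_others <- rep(FALSE, nrow(pres))
    found <- !is.na(idx)
    in_others[found] <- rowSums(
      ref_pres[idx[found], others, drop = FALSE]) >= 1L
  }
  keep <- in_members & !in_others
  v <- cohort$variants[keep, , drop = FALSE]
  sharing <- t(pres[keep, members, drop = FALSE])
  rownames(sharing) <- members
  colnames(sharing) <- variant_key(v)
  idx <- which(sharing, arr.ind = TRUE)
  cc <- split(members[idx[, 1]], idx[, 2])
  carriers <- character(ncol(sharing))
  carriers[as.integer(names(cc))] <- vapply(cc, paste, character(1),
                                            collapse = ";")
  v$carriers <- carriers
  v$n_carriers <- colSums(sharing)
  rownames(v) <- NULL
  uniq <- rowSums(sharing[, v$n_carriers == 1L, drop = FALSE])
  structure(
    list(group_id = group_id, members = members, variants = v,
         sharing = sharing,
         per_line_unique_counts = setNames(as.integer(uniq), members)),
    class = "group_variant_sets"
  )
}

#' Classify a group's specific variants
#'
#' Labels each group-specific variant:
#' * `on_target` — matches a declared expected edit of a group member
#'   (comparison on the normalized `chrom:pos:ref:alt` key; a zygosity
#'   mismatch is reported in the `zygosity_note` column, not fatal);
#' * `unique` — carried by exactly one line;
#' * `shared_founder` — carried by two or more lines whose carrier set
#'   includes an untargeted control of the same experiment, or a line
#'   declared (via `parent_line`) as the earlier-round parental clone of a
#'   group member — the founder-effect signature;
#' * `shared_unexplained` — any remaining multi-carrier variant.
#'
#' Expected edits absent from the call set entirely are reported via a
#' warning (engineered mutations occasionally escape joint genotyping).
#'
#' @param sets a `group_variant_sets` from [group_specific_variants()].
#' @param cohort the cohort the sets were derived from.
#' @return data.frame of attributed variants: the specific records plus
#'   `group_id`, `label` and `zygosity_note` columns.
#' @export
classify_group_variants <- function(sets, cohort) {
  meta <- cohort$meta
  v <- sets$variants
  keys <- variant_key(v)
  mm <- meta[match(sets$members, meta$line_id), ]
  edits <- expected_edit_table(mm)
  edit_keys <- if (nrow(edits)) paste(edits$chrom, edits$pos, edits$ref,
                                      edits$alt, sep = ":") else character(0)
  missing_edits <- setdiff(edit_keys, keys)
  if (length(missing_edits))
    warning("expected edit(s) not detected in call set for group ",
            sets$group_id, ": ", paste(missing_edits, collapse = ", "))
  ewt_members <- mm$line_id[mm$role == "edited_wildtype"]
  declared_parents <- setdiff(unique(mm$parent_line), "")
  cohort_keys <- if (length(edit_keys)) variant_key(cohort) else character(0)

  label <- character(nrow(v))
  zyg_note <- character(nrow(v))
  carrier_list <- strsplit(v$carriers, ";", fixed = TRUE)
  for (i in seq_along(label)) {
    carriers <- carrier_list[[i]]
    if (keys[i] %in% edit_keys) {
      label[i] <- "on_target"
      ed <- edits[edit_keys == keys[i], , drop = FALSE]
      for (j in seq_len(nrow(ed))) {
        if (ed$line_id[j] %in% carriers) {
          obs <- unname(cohort$geno[match(keys[i], cohort_keys),
                                    ed$line_id[j]])
          if (obs != ed$zygosity[j])
            zyg_note[i] <- paste0(zyg_note[i], ed$line_id[j], ":expected_",
                                  ed$zygosity[j], "_observed_", obs, ";")
        }
      }
    } else if (length(carriers) == 1L) {
      label[i] <- "unique"
    } else if (any(carriers %in% ewt_members) ||
               any(carriers %in% declared_parents)) {
      label[i] <- "shared_founder"
    } else {
      label[i] <- "shared_unexplained"
    }
  }
  out <- cbind(data.frame(group_id = rep(sets$group_id, nrow(v)),
                          stringsAsFactors = FALSE),
               v, label = label, zygosity_note = zyg_note,
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Attribute variants for every editing group
#'
#' Runs [group_specific_variants()] and [classify_group_variants()] for each
#' editing group of the cohort. The exclusion filter guarantees the groups'
#' specific sets are pairwise disjoint.
#'
#' @param cohort a quality-filtered `clonal_cohort`.
#' @param exclude_against optional reference cohort for the exclusion
#'   filter (see [group_specific_variants()]).
#' @return list with `attributed` (one combined data.frame) and `sets`
#'   (named list of `group_variant_sets`).
#' @export
attribute_cohort <- function(cohort, exclude_against = NULL) {
  groups <- sort(unique(cohort$meta$group_id[cohort$meta$role == "edited"]))
  sets <- lapply(groups, function(g)
    group_specific_variants(cohort, g, exclude_against = exclude_against))
  names(sets) <- groups
  attributed <- do.call(rbind, lapply(sets, classify_group_variants, cohort))
  rownames(attributed) <- NULL
  list(attributed = attributed, sets = sets)
}

#' Pairwise sharing report
#'
#' Tabulates, over one group's (or several groups') specific variants, the
#' number of variants shared by each pair of lines; the diagonal holds each
#' line's unique-variant count.
#'
#' @param sets a `group_variant_sets` or a list of them.
#' @return list with `matrix` (lines x lines integer matrix) and
#'   `per_line_unique_counts`.
#' @export
sharing_report <- function(sets) {
  if (inherits(sets, "group_variant_sets")) sets <- list(sets)
  lines <- unique(unlist(lapply(sets, `[[`, "members")))
  m <- matrix(0L, length(lines), length(lines),
              dimnames = list(lines, lines))
  uniq <- setNames(integer(length(lines)), lines)
  for (s in sets) {
    sh <- s$sharing * 1L
    cross <- sh %*% t(sh)  # members x members co-carrier counts
    idx <- match(s$members, lines)
    m[idx, idx] <- m[idx, idx] + cross
    uniq[s$members] <- uniq[s$members] + s$per_line_unique_counts
  }
  diag(m) <- uniq
  list(matrix = m, per_line_unique_counts = uniq)
}
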