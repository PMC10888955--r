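#' Per-label precision/recall of a pipeline run against simulation truth
#'
#' Compares the attribution, off-target and LOH outputs of
#' [run_pipeline()] with the generator's ground truth:
#' * `on_target` — attributed `on_target` variants vs truth `on_target`;
#' * `unique` — attributed `unique` variants vs truth `private`;
#' * `shared_founder` — attributed `shared_founder` vs truth `founder`;
#' * `off_target_genuine` — variants re-labelled genuine by the cleavage
#'   window rule vs truth `off_target`;
#' * `loh` — `loh` verdicts per (line, edited locus) vs injected tracts.
#'
#' Empty truth classes report `n = 0` with `NA` recall rather than failing.
#'
#' @param run output of [run_pipeline()].
#' @param sim the `sim_cohort` the run was executed on.
#' @return data.frame: `label`, `n_truth`, `n_predicted`, `tp`, `fp`, `fn`,
#'   `precision`, `recall`.
#' @export
evaluate_recovery <- function(run, sim) {
  truth <- sim$truth
  att <- run$attributed
  akeys <- paste(att$chrom, att$pos, att$ref, att$alt, sep = ":")
  pred <- list(
    on_target = akeys[att$label == "on_target"],
    unique = akeys[att$label == "unique"],
    shared_founder = akeys[att$label == "shared_founder"],
    off_target_genuine = akeys[att$label == "off_target_genuine"]
  )
  # attribution only ever sees editing-group lines; truth variants carried
  # exclusively by parental/subclone lines are outside its domain
  meta <- sim$cohort$meta
  group_lines <- meta$line_id[meta$role %in% c("edited", "edited_wildtype")]
  in_domain <- vapply(strsplit(truth$carriers, ";", fixed = TRUE),
                      function(cc) any(cc %in% group_lines), logical(1))
  tr <- list(
    on_target = truth$key[in_domain & truth$origin == "on_target"],
    unique = truth$key[in_domain & truth$origin == "private"],
    shared_founder = truth$key[in_domain & truth$origin == "founder"],
    off_target_genuine = truth$key[in_domain & truth$origin == "off_target"]
  )
  loh_pred <- if (!is.null(run$loh) && nrow(run$loh))
    with(run$loh[run$loh$verdict == "loh", , drop = FALSE],
         paste(line_id, chrom, pos)) else character(0)
  loh_truth <- if (nrow(sim$loh))
    with(sim$loh, paste(line_id, chrom, pos)) else character(0)
  pred$loh <- loh_pred
  tr$loh <- loh_truth
  if (nrow(att) &&
      !all(akeys %in% truth$key[truth$origin != "low_qual_decoy"]))
    stop("attributed variants not present in simulation truth: key mismatch")
  rows <- lapply(names(tr), function(lbl) {
    p <- unique(pred[[lbl]]); t <- unique(tr[[lbl]])
    tp <- length(intersect(p, t))
    data.frame(
      label = lbl, n_truth = length(t), n_predicted = length(p),
      tp = tp, fp = length(p) - tp, fn = length(t) - tp,
      precision = if (length(p)) tp / length(p) else NA_real_,
      recall = if (length(t)) tp / length(t) else NA_real_,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
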