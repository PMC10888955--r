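test_that("quality filter keeps qual >= threshold inclusively and preserves order", {
  meta <- demo_meta()
  v <- rbind(vrow("chr1", 10, "A", "G", 30.0),
             vrow("chr1", 20, "C", "T", 29.99),
             vrow("chr1", 30, "G", "A", 45))
  cohort <- build_cohort(v, list(c(A1 = "het"), c(A1 = "het"),
                                 c(B1 = "het")), meta)
  f <- filter_by_quality(cohort, 30)
  expect_equal(f$variants$pos, c(10L, 30L))  # 30.0 kept, 29.99 dropped
  set.seed(99)
  recs <- data.frame(chrom = "chr1", pos = 1:500, ref = "A", alt = "G",
                     qual = runif(500, 0, 60))
  expect_equal(filter_by_quality(recs, 30),
               recs[recs$qual >= 30, ])  # oracle: direct scan
})

test_that("cross-group exclusion removes variants seen in any other line", {
  meta <- demo_meta()
  v <- rbind(vrow("chr1", 10, "A", "G"),   # A-only
             vrow("chr1", 20, "C", "T"),   # in A and B -> excluded
             vrow("chr1", 30, "G", "A"),   # everywhere -> parental proxy
             vrow("chr1", 40, "T", "C"))   # B-only
  everyone <- setNames(rep("het", 7), meta$line_id)
  cohort <- build_cohort(v, list(
    c(A1 = "het", A2 = "het"),
    c(A1 = "het", B1 = "het"),
    everyone,
    c(B1 = "het", B2 = "hom_alt")), meta)
  a <- group_specific_variants(cohort, "A")
  b <- group_specific_variants(cohort, "B")
  expect_equal(a$variants$pos, 10L)
  expect_equal(b$variants$pos, 40L)
  expect_setequal(a$members, c("A1", "A2", "AW"))
  expect_error(group_specific_variants(cohort, "Z"), "valid groups")
})

test_that("group-specific filter equals the exhaustive double-loop oracle", {
  for (seed in 1:20) {
    set.seed(seed)
    lines <- sprintf("L%02d", 1:12)
    meta <- do.call(rbind, c(
      list(meta_row("L01", role = "parental", method = "none")),
      lapply(2:4, function(i) meta_row(lines[i], "G1", "e1",
        expected_edits = "chr1:1:A:G:het")),
      list(meta_row("L05", "G1", "e1", role = "edited_wildtype")),
      lapply(6:9, function(i) meta_row(lines[i], "G2", "e2",
        expected_edits = "chr1:2:A:G:het")),
      lapply(10:12, function(i) meta_row(lines[i], "G3", "e3",
        expected_edits = "chr1:3:A:G:het"))))
    n <- 300
    v <- data.frame(chrom = "chr1", pos = 10 + seq_len(n), ref = "A",
                    alt = "G", qual = 50)
    geno <- matrix(sample(c("hom_ref", "het", "hom_alt", "missing"), n * 12,
                          replace = TRUE, prob = c(0.7, 0.15, 0.1, 0.05)),
                   n, 12, dimnames = list(NULL, lines))
    cohort <- new_cohort(v, geno, meta)
    pres <- cohort_presence(cohort)
    for (g in c("G1", "G2", "G3")) {
      got <- group_specific_variants(cohort, g)
      members <- group_members(meta, g)
      keep <- brute_group_specific(pres, members)
      expect_equal(variant_key(got$variants),
                   variant_key(cohort$variants[keep, ]))
    }
  }
})

test_that("exclusion can be judged against a separate (e.g. raw) call set", {
  meta <- demo_meta()
  # raw calls show B1 carrying the pos-10 variant; the analysis cohort has
  # that genotype reset to missing (e.g. by a per-genotype quality rule)
  raw <- build_cohort(rbind(vrow("chr1", 10, "A", "G", 50),
                            vrow("chr1", 20, "C", "T", 50)),
                      list(c(A1 = "het", B1 = "het"), c(A2 = "het")), meta)
  analysis <- raw
  analysis$geno[analysis$variants$pos == 10, "B1"] <- "missing"
  by_default <- group_specific_variants(analysis, "A")
  expect_setequal(by_default$variants$pos, c(10L, 20L))
  vs_raw <- group_specific_variants(analysis, "A", exclude_against = raw)
  expect_equal(vs_raw$variants$pos, 20L)  # B1's raw carrier status counts
  # records absent from the reference set fall back to "not seen outside"
  slim <- build_cohort(vrow("chr1", 20, "C", "T", 50),
                       list(c(A2 = "het")), meta)
  vs_slim <- group_specific_variants(analysis, "A", exclude_against = slim)
  expect_setequal(vs_slim$variants$pos, c(10L, 20L))
})

test_that("specific sets are pairwise disjoint and shrink monotonically in min_qual", {
  sim <- simulate_cohort(sim_config(seed = 21, chrom_length_bp = 50000,
                                    loh_tract_bp = 20000,
                                    exclude_cleavage_sites = FALSE))
  cohort <- sim$cohort
  prev_sizes <- NULL
  for (q in c(0, 30, 45, 55)) {
    f <- filter_by_quality(cohort, q)
    # high thresholds may drop engineered edits, which warns by design
    att <- suppressWarnings(attribute_cohort(f))
    keys <- unlist(lapply(att$sets, function(s) variant_key(s$variants)))
    expect_equal(anyDuplicated(keys), 0L)
    sizes <- vapply(att$sets, function(s) nrow(s$variants), 1L)
    if (!is.null(prev_sizes)) expect_true(all(sizes <= prev_sizes))
    prev_sizes <- sizes
  }
})

test_that("classification separates on-target, unique, founder and unexplained sharing", {
  meta <- demo_meta()
  v <- rbind(vrow("chr1", 100, "A", "G"),  # expected edit of A1/A2
             vrow("chr1", 11, "C", "T"),   # single carrier
             vrow("chr1", 12, "G", "A"),   # A1+A2+AW -> founder
             vrow("chr1", 13, "T", "C"),   # A1+A2, no control -> unexplained
             vrow("chr1", 500, "C", "T"))  # B edit, hom as intended
  cohort <- build_cohort(v, list(
    c(A1 = "het", A2 = "hom_alt"),
    c(A1 = "het"),
    c(A1 = "het", A2 = "het", AW = "het"),
    c(A1 = "het", A2 = "het"),
    c(B1 = "hom_alt", B2 = "hom_alt")), meta)
  att <- attribute_cohort(cohort)$attributed
  lab <- setNames(att$label, paste(att$group_id, att$pos))
  expect_equal(unname(lab[c("A 100", "A 11", "A 12", "A 13", "B 500")]),
               c("on_target", "unique", "shared_founder",
                 "shared_unexplained", "on_target"))
  # zygosity mismatch reported, not fatal: A2 expected het but observed hom
  expect_match(att$zygosity_note[att$pos == 100], "A2:expected_het")
  expect_equal(att$zygosity_note[att$pos == 500], "")
})

test_that("sharing with a declared earlier-round parental clone is founder", {
  meta <- rbind(
    meta_row("parental", role = "parental", method = "none", passage = NA),
    meta_row("HET1", "DJ", "e1", expected_edits = "chr1:50:A:G:het"),
    meta_row("HOM1", "DJ", "e1", expected_edits = "chr1:50:A:G:hom_alt",
             parent_line = "HET1"),
    meta_row("HOM2", "DJ", "e1", expected_edits = "chr1:50:A:G:hom_alt",
             parent_line = "HET1"))
  v <- rbind(vrow("chr1", 10, "C", "T"),  # HET1 + HOM1: inherited -> founder
             vrow("chr1", 20, "G", "A"))  # HOM1 + HOM2 only -> unexplained
  cohort <- build_cohort(v, list(c(HET1 = "het", HOM1 = "het"),
                                 c(HOM1 = "het", HOM2 = "het")), meta)
  att <- suppressWarnings(attribute_cohort(cohort)$attributed)
  expect_equal(att$label[att$pos == 10], "shared_founder")
  expect_equal(att$label[att$pos == 20], "shared_unexplained")
})

test_that("an undetected engineered mutation raises a warning, not an error", {
  meta <- demo_meta()
  cohort <- build_cohort(vrow("chr1", 10, "A", "G"),
                         list(c(A1 = "het")), meta)
  w <- capture_warnings(att <- attribute_cohort(cohort))
  expect_true(any(grepl("chr1:100:A:G", w)))  # group A's missing edit
  expect_true(any(grepl("chr1:500:C:T", w)))  # group B's missing edit
  expect_equal(att$attributed$label, "unique")
})

test_that("sharing report: diagonal holds unique counts, off-diagonal co-carriers", {
  meta <- demo_meta()
  v <- rbind(vrow("chr1", 10, "A", "G"), vrow("chr1", 20, "C", "T"),
             vrow("chr1", 30, "G", "A"))
  # A1 and A2 identical sets; AW disjoint
  cohort <- build_cohort(v, list(
    c(A1 = "het", A2 = "het"),
    c(A1 = "het", A2 = "het"),
    c(AW = "het")), meta)
  rep <- sharing_report(group_specific_variants(cohort, "A"))
  m <- rep$matrix
  expect_equal(m["A1", "A2"], 2L)
  expect_equal(m["A1", "A1"], 0L)   # no unique variants for A1
  expect_equal(m["AW", "AW"], 1L)
  expect_equal(m["A1", "AW"], 0L)   # disjoint
  expect_true(isSymmetric(m))
})

test_that("pairwise sharing matrix matches truth tabulation on simulated founder sets", {
  sim <- simulate_cohort(sim_config(seed = 31, chrom_length_bp = 50000,
                                    loh_tract_bp = 20000, decoy_frac = 0,
                                    exclude_cleavage_sites = FALSE))
  att <- attribute_cohort(sim$cohort)
  rep <- sharing_report(att$sets)
  truth <- sim$truth
  meta <- sim$cohort$meta
  group_lines <- meta$line_id[meta$role %in% c("edited", "edited_wildtype")]
  tr <- truth[truth$origin %in% c("founder", "private", "on_target",
                                  "off_target"), ]
  carr <- strsplit(tr$carriers, ";", fixed = TRUE)
  for (i in sample(length(group_lines), 4)) for (j in seq_along(group_lines)) {
    a <- group_lines[i]; b <- group_lines[j]
    if (a == b) {
      want <- sum(vapply(carr, function(x) identical(x, a), TRUE))
    } else {
      want <- sum(vapply(carr, function(x) a %in% x && b %in% x, TRUE))
    }
    expect_equal(unname(rep$matrix[a, b]), want)
  }
})
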