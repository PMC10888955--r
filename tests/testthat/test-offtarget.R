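guide <- function(proto, id = "g1", pam = "NGG")
  list(guide_id = id, protospacer = proto, pam_pattern = pam)

test_that("a verbatim planted guide is found once at 0 mismatches on either strand", {
  set.seed(3)
  proto <- random_dna_str(20)
  left <- random_dna_str(40); right <- random_dna_str(40)
  plus <- Biostrings::DNAStringSet(
    c(chrA = paste0(left, proto, "AGG", right)))
  s <- enumerate_sites(guide(proto), plus, 0)
  expect_equal(nrow(s), 1L)
  expect_equal(s$start, 41L)
  expect_equal(s$end, 63L)
  expect_equal(s$strand, "+")
  expect_equal(s$mismatches, 0L)
  expect_equal(s$pam_start, 61L)
  minus_seq <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(paste0(left, proto, "TGG", right))))
  minus <- Biostrings::DNAStringSet(c(chrA = minus_seq))
  s2 <- enumerate_sites(guide(proto), minus, 0)
  expect_equal(nrow(s2), 1L)
  expect_equal(s2$strand, "-")
  expect_equal(s2$start, 41L)  # 103-long chromosome, mirrored interval
  expect_equal(s2$pam_start, 41L)
  expect_equal(s2$pam_end, 43L)
})

test_that("sites beyond the mismatch threshold are absent", {
  set.seed(4)
  proto <- random_dna_str(20)
  pvec <- strsplit(proto, "")[[1]]
  at <- sample(20, 6)
  for (a in at) pvec[a] <- setdiff(c("A", "C", "G", "T"), pvec[a])[1]
  mutated <- paste(pvec, collapse = "")
  g <- Biostrings::DNAStringSet(
    c(chrA = paste0(random_dna_str(30), mutated, "AGG", random_dna_str(30))))
  expect_equal(nrow(enumerate_sites(guide(proto), g, 5)), 0L)
  expect_equal(nrow(enumerate_sites(guide(proto), g, 6)), 1L)
})

test_that("enumeration equals the exhaustive Biostrings scan on random genomes", {
  for (seed in 1:3) {
    set.seed(seed)
    genome <- Biostrings::DNAStringSet(c(chr1 = random_dna_str(60000),
                                         chr2 = random_dna_str(40000)))
    # a guide with planted near-matches so non-trivial hits exist
    proto <- random_dna_str(20)
    s1 <- as.character(genome[[1]])
    for (k in 0:5) {
      pvec <- strsplit(proto, "")[[1]]
      if (k > 0) for (a in sample(20, k))
        pvec[a] <- sample(setdiff(c("A", "C", "G", "T"), pvec[a]), 1)
      site <- paste0(paste(pvec, collapse = ""), sample(c("AGG", "CGG"), 1))
      st <- 1000 + k * 3000
      if (k %% 2 == 0) {
        substr(s1, st, st + 22) <- site
      } else {
        substr(s1, st, st + 22) <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(site)))
      }
    }
    genome[["chr1"]] <- Biostrings::DNAString(s1)
    got <- enumerate_sites(guide(proto), genome, 5)
    want <- oracle_sites(proto, genome, 5)
    expect_equal(got[c("chrom", "start", "strand", "mismatches")],
                 want, ignore_attr = TRUE)
    expect_gte(nrow(got), 6L)  # all planted sites recovered
  }
})

test_that("IUPAC PAM patterns and invalid guides are handled", {
  g <- Biostrings::DNAStringSet(c(chrA = "AAAACCCCGGGGTTTTACGTAGGACGT"))
  expect_error(enumerate_sites(guide("ACGTN"), g, 0), "ACGT")
  set.seed(10)
  proto <- random_dna_str(20)
  gen <- Biostrings::DNAStringSet(
    c(chrA = paste0(random_dna_str(20), proto, "ATG", random_dna_str(20))))
  expect_equal(nrow(enumerate_sites(guide(proto, pam = "NGG"), gen, 0)), 0L)
  expect_equal(nrow(enumerate_sites(guide(proto, pam = "NNG"), gen, 0)), 1L)
  expect_equal(nrow(enumerate_sites(guide(proto, pam = "NGT"), gen, 0)), 0L)
  expect_equal(nrow(enumerate_sites(guide(proto, pam = "WTG"), gen, 0)), 1L)
})

# a controlled site/variant fixture: plus-strand site at 101..123
ot_fixture <- function() {
  set.seed(6)
  proto <- random_dna_str(20)
  chrom <- paste0(random_dna_str(100), proto, "AGG", random_dna_str(300))
  genome <- Biostrings::DNAStringSet(c(chr1 = chrom))
  sites <- enumerate_sites(guide(proto), genome, 0)
  meta <- rbind(
    meta_row("parental", role = "parental", method = "none", passage = NA),
    meta_row("C1", "G1", "e1", expected_edits = "chr1:400:A:G:het",
             guide_ids = "g1"),
    meta_row("C2", "G1", "e1", expected_edits = "chr1:400:A:G:het",
             guide_ids = "g1"))
  list(genome = genome, sites = sites, meta = meta, chrom = chrom)
}

test_that("window hits annotate PAM distance and zygosity; far variants excluded", {
  fx <- ot_fixture()
  # pam_start = 121; distance d has leftmost changed base at 121 - d
  v <- rbind(vrow("chr1", 121 - 3, "A", "G"),     # d = 3 inside protospacer
             vrow("chr1", 123 + 50, "C", "T"),    # 50 bp right flank
             vrow("chr1", 400, "A", "G"))         # >150 bp beyond window
  v$ref <- substring(fx$chrom, v$pos, v$pos)
  v$alt <- vapply(v$ref, function(r) setdiff(c("A", "C", "G", "T"), r)[1], "")
  v$carriers <- c("C1", "C1", "C2")
  cohort <- build_cohort(v[c("chrom", "pos", "ref", "alt", "qual")],
                         list(c(C1 = "het"), c(C1 = "het"), c(C2 = "het")),
                         fx$meta)
  hits <- window_hits(fx$sites, v, cohort, window_bp = 100)
  expect_equal(nrow(hits), 2L)
  expect_equal(hits$distance_to_pam[hits$pos == 118], 3L)
  expect_equal(hits$zygosity, c("het", "het"))
  expect_false(400 %in% hits$pos)
  # monotonicity: enlarging the window never removes a hit
  hits200 <- window_hits(fx$sites, v, cohort, window_bp = 200)
  expect_true(all(paste(hits$variant, hits$line_id) %in%
                  paste(hits200$variant, hits200$line_id)))
})

test_that("window hits equal the brute-force all-pairs intersection", {
  fx <- ot_fixture()
  set.seed(13)
  pos <- sample(5:400, 60)
  v <- data.frame(chrom = "chr1", pos = pos,
                  ref = substring(fx$chrom, pos, pos), alt = "N",
                  qual = 50, stringsAsFactors = FALSE)
  v$alt <- vapply(v$ref, function(r) setdiff(c("A", "C", "G", "T"), r)[1], "")
  v <- v[!duplicated(v$pos), ]
  v$carriers <- "C1"
  cohort <- build_cohort(v[c("chrom", "pos", "ref", "alt", "qual")],
                         lapply(seq_len(nrow(v)), function(i) c(C1 = "het")),
                         fx$meta)
  for (w in c(0, 10, 100)) {
    got <- window_hits(fx$sites, v, cohort, window_bp = w)
    want <- v$pos[v$pos >= fx$sites$start - w & v$pos <= fx$sites$end + w]
    expect_setequal(got$pos, want)
  }
})

test_that("the 2-5 PAM-proximal heterozygous rule is exhaustive over distances 1-20", {
  fx <- ot_fixture()
  pam_start <- fx$sites$pam_start
  for (d in 1:20) for (zyg in c("het", "hom_alt")) {
    p <- pam_start - d
    v <- vrow("chr1", p, substr(fx$chrom, p, p), "N")
    v$alt <- setdiff(c("A", "C", "G", "T"), v$ref)[1]
    v$carriers <- "C1"
    cohort <- build_cohort(v[c("chrom", "pos", "ref", "alt", "qual")],
                           list(c(C1 = zyg)), fx$meta)
    hit <- classify_genuine(window_hits(fx$sites, v, cohort, 100))
    if (d >= 2 && d <= 5 && zyg == "het") {
      expect_true(hit$genuine)
    } else {
      expect_false(hit$genuine)
      expect_equal(hit$reason,
                   if (d >= 2 && d <= 5) "homozygous"
                   else "outside_cleavage_window")
    }
  }
  # beyond the protospacer the reason is pam_distal
  p <- pam_start - 25
  v <- vrow("chr1", p, substr(fx$chrom, p, p), "N")
  v$alt <- setdiff(c("A", "C", "G", "T"), v$ref)[1]
  v$carriers <- "C1"
  cohort <- build_cohort(v[c("chrom", "pos", "ref", "alt", "qual")],
                         list(c(C1 = "het")), fx$meta)
  hit <- classify_genuine(window_hits(fx$sites, v, cohort, 100))
  expect_equal(hit$reason, "pam_distal")
})

test_that("minus-strand PAM distance arithmetic is mirrored", {
  set.seed(16)
  proto <- random_dna_str(20)
  site_fwd <- paste0(proto, "AGG")
  chrom <- paste0(random_dna_str(100),
                  as.character(Biostrings::reverseComplement(
                    Biostrings::DNAString(site_fwd))), random_dna_str(100))
  genome <- Biostrings::DNAStringSet(c(chr1 = chrom))
  sites <- enumerate_sites(guide(proto), genome, 0)
  expect_equal(sites$strand, "-")
  # pam_end = 103; d bases upstream of the PAM = genomic pos 103 + d
  meta <- ot_fixture()$meta
  for (d in c(1, 3, 7)) {
    p <- sites$pam_end + d
    v <- vrow("chr1", p, substr(chrom, p, p), "N")
    v$alt <- setdiff(c("A", "C", "G", "T"), v$ref)[1]
    v$carriers <- "C1"
    cohort <- build_cohort(v[c("chrom", "pos", "ref", "alt", "qual")],
                           list(c(C1 = "het")), meta)
    hit <- window_hits(sites, v, cohort, 100)
    expect_equal(hit$distance_to_pam, d)
  }
})

test_that("off-target report: per-method counts, shared hits once, empty guides", {
  fx <- ot_fixture()
  meta <- rbind(fx$meta,
                meta_row("P1", "G2", "e2", method = "prime",
                         expected_edits = "chr1:390:A:G:het"))
  pam_start <- fx$sites$pam_start
  p <- pam_start - 4
  v <- vrow("chr1", p, substr(fx$chrom, p, p), "N")
  v$alt <- setdiff(c("A", "C", "G", "T"), v$ref)[1]
  v$carriers <- "C1;C2"
  cohort <- build_cohort(v[c("chrom", "pos", "ref", "alt", "qual")],
                         list(c(C1 = "het", C2 = "het")), meta)
  hits <- classify_genuine(window_hits(fx$sites, v, cohort, 100))
  rep <- offtarget_report(hits, meta)
  pm <- rep$per_method_class
  expect_equal(pm$genuine_hits[pm$method_class == "dsb"], 2L)
  expect_equal(pm$genuine_hits[pm$method_class == "prime"], 0L)
  expect_equal(nrow(rep$shared), 1L)  # one shared modification, listed once
  expect_equal(rep$shared$n_lines, 2L)
  expect_equal(rep$shared$lines, "C1;C2")
  empty <- offtarget_report(hits[0, ], meta)
  expect_true(all(empty$per_line$candidate_hits == 0L))
  expect_equal(nrow(empty$shared), 0L)
})
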