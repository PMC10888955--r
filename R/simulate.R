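#' Simulation configuration
#'
#' Assembles and validates the parameters of the synthetic-cohort generator.
#' Defaults describe a desk-scale cohort with the generative structure the
#' analysis assumes: parental standing heterozygous SNVs, Poisson
#' per-passage mutation accumulation fixed at clonal bottlenecks (founder
#' sublineages shared between edited clones and untargeted controls of the
#' same experiment), engineered on-target edits, planted CRISPR off-target
#' sites receiving heterozygous cleavage-window indels for
#' double-strand-break methods only, and LOH tracts around edited loci.
#'
#' @param seed RNG seed.
#' @param n_chromosomes,chrom_length_bp genome shape.
#' @param n_genes,exons_per_gene transcript models planted in the genome.
#' @param parental_het_marker_density standing parental het SNVs per bp.
#' @param per_passage_rate Poisson mutation rate per passage (lambda;
#'   default 20, the order of measured hPSC culture rates).
#' @param founder_passages culture passages elapsed before the clonal
#'   bottleneck; founder variant sets are Poisson(lambda * founder_passages).
#' @param n_experiments,clones_per_experiment,ewt_per_experiment cohort
#'   shape (edited clones and untargeted "edited wild-type" controls per
#'   targeting experiment; one editing group per experiment).
#' @param founder_sublineages_per_experiment distinct founder variant sets
#'   per experiment; controls and clones are assigned round-robin so each
#'   sublineage contains an untargeted control when
#'   `ewt_per_experiment >= founder_sublineages_per_experiment`.
#' @param passage_range integer range (inclusive) of each clone's passage
#'   number at its last clonal event.
#' @param methods editing method per experiment, recycled (default
#'   crispr_hdr / talen / prime).
#' @param offtarget_prob per (clone, planted site) probability of a
#'   heterozygous cleavage-window indel; double-strand-break methods only.
#' @param n_offtarget_sites planted sequence-similar decoy sites per guide
#'   (1-5 protospacer mismatches, NGG PAM).
#' @param loh_prob per-clone probability of an LOH tract around a
#'   homozygously edited locus (double-strand-break clones).
#' @param loh_tract_bp total LOH tract length.
#' @param n_subclones parental subclone lines (never part of any group).
#' @param decoy_frac fraction of additional low-quality decoy calls
#'   (QUAL below 30) added to the emitted VCF.
#' @param qc_fail_karyotype,qc_fail_pluripotency QC failure probabilities
#'   (karyotype by method class).
#' @param exclude_cleavage_sites when TRUE, enumerate every candidate
#'   off-target site of every guide and keep random mutations out of the
#'   site intervals, so that truth labels and cleavage-window classification
#'   cannot collide by chance.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_chromosomes = 2,
                       chrom_length_bp = 100000,
                       n_genes = 4,
                       exons_per_gene = 3,
                       parental_het_marker_density = 1 / 2000,
                       per_passage_rate = 20,
                       founder_passages = 8,
                       n_experiments = 3,
                       clones_per_experiment = 3,
                       ewt_per_experiment = 2,
                       founder_sublineages_per_experiment = 2,
                       passage_range = c(10, 40),
                       methods = c("crispr_hdr", "talen", "prime"),
                       offtarget_prob = 0.25,
                       n_offtarget_sites = 4,
                       loh_prob = 0.15,
                       loh_tract_bp = 60000,
                       n_subclones = 2,
                       decoy_frac = 0.05,
                       qc_fail_karyotype = c(dsb = 0.2034, prime = 0.0556),
                       qc_fail_pluripotency = 0.0147,
                       exclude_cleavage_sites = TRUE) {
  cfg <- as.list(environment())
  rates <- c(parental_het_marker_density, per_passage_rate, offtarget_prob,
             loh_prob, decoy_frac, qc_fail_karyotype, qc_fail_pluripotency)
  if (any(rates < 0)) stop("all rates must be >= 0")
  if (passage_range[1] < 1 || passage_range[2] > 200 ||
      passage_range[1] > passage_range[2])
    stop("passage_range must lie within [1, 200]")
  if (ewt_per_experiment > 0 && n_experiments == 0)
    stop("contradictory config: ewt_per_experiment > 0 with n_experiments = 0")
  if (!all(methods %in% setdiff(EDIT_METHODS, "none")))
    stop("unknown editing method in config")
  if (ewt_per_experiment < founder_sublineages_per_experiment &&
      n_experiments > 0)
    warning("fewer untargeted controls than founder sublineages: some ",
            "founder variant sets will not be identifiable as founder")
  cfg$methods <- rep_len(methods, max(n_experiments, 1L))
  structure(cfg, class = "sim_config")
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

# alternate alleles with 2:1 transition:transversion odds (vectorized)
TRANSITION <- c(A = "G", G = "A", C = "T", T = "C")
TRANSVERSION1 <- c(A = "C", G = "C", C = "A", T = "A")
TRANSVERSION2 <- c(A = "T", G = "T", C = "G", T = "G")
rand_alt_base <- function(ref) {
  n <- length(ref)
  tv <- ifelse(runif(n) < 0.5, TRANSVERSION1[ref], TRANSVERSION2[ref])
  unname(ifelse(runif(n) < 2 / 3, TRANSITION[ref], tv))
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Simulate a genome with transcript models
#'
#' Random chromosomes with non-overlapping genes planted on both strands;
#' each gene has valid UTRs and a CDS that begins with ATG, ends with a stop
#' codon, contains no internal stop and has length a multiple of three.
#' Deterministic under `config$seed`.
#'
#' @param config a `sim_config`.
#' @return list with `genome` ([Biostrings::DNAStringSet]), `transcripts`
#'   (`transcript_models`) and `gene_spans` (reserved genomic intervals).
#' @export
simulate_genome <- function(config) {
  set.seed(config$seed)
  chroms <- setNames(
    vapply(seq_len(config$n_chromosomes), function(i)
      rand_dna(config$chrom_length_bp), ""),
    paste0("chr", seq_len(config$n_chromosomes)))
  spans <- data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE)
  genes <- NULL; exons <- NULL
  exon_len <- 300L; intron_len <- 200L
  ne <- config$exons_per_gene
  gene_span <- ne * exon_len + (ne - 1L) * intron_len
  for (k in seq_len(config$n_genes)) {
    ch <- names(chroms)[(k - 1L) %% length(chroms) + 1L]
    start <- place_interval(spans, ch, gene_span, config$chrom_length_bp,
                            margin = 2000L)
    if (is.na(start))
      stop("genes cannot be placed without overlap; increase chrom_length_bp")
    spans <- rbind(spans, data.frame(chrom = ch, start = start,
                                     end = start + gene_span - 1L))
    strand <- if (k %% 2L == 0L) "-" else "+"
    gid <- sprintf("gene%02d", k)
    ex_start <- start + (seq_len(ne) - 1L) * (exon_len + intron_len)
    ex_end <- ex_start + exon_len - 1L
    u5 <- 60L
    cds_len0 <- ne * exon_len - 120L
    u3 <- 60L + cds_len0 %% 3L
    cds_len <- ne * exon_len - u5 - u3
    n_codons <- cds_len %/% 3L
    inner <- sample(setdiff(names(Biostrings::GENETIC_CODE)[
      Biostrings::GENETIC_CODE != "*"], character(0)), n_codons - 2L,
      replace = TRUE)
    cds_seq <- paste0("ATG", paste(inner, collapse = ""), "TAA")
    tx_seq <- paste0(rand_dna(u5), cds_seq, rand_dna(u3))
    # write the transcript into the genome, exon by exon
    s <- chroms[[ch]]
    for (j in seq_len(ne)) {
      piece <- substr(tx_seq, (j - 1L) * exon_len + 1L, j * exon_len)
      if (strand == "+") {
        substr(s, ex_start[j], ex_end[j]) <- piece
      } else {
        gj <- ne + 1L - j  # transcript exon j sits at genomic exon gj
        substr(s, ex_start[gj], ex_end[gj]) <- as.character(
          Biostrings::reverseComplement(Biostrings::DNAString(piece)))
      }
    }
    chroms[[ch]] <- s
    tx2g <- function(t) {
      j <- (t - 1L) %/% exon_len + 1L
      off <- t - (j - 1L) * exon_len - 1L
      if (strand == "+") ex_start[j] + off
      else ex_end[ne + 1L - j] - off
    }
    cds_g <- sort(c(tx2g(u5 + 1L), tx2g(u5 + cds_len)))
    genes <- rbind(genes, data.frame(
      gene_id = gid, chrom = ch, strand = strand,
      cds_start = cds_g[1], cds_end = cds_g[2], stringsAsFactors = FALSE))
    exons <- rbind(exons, data.frame(gene_id = gid, start = ex_start,
                                     end = ex_end, stringsAsFactors = FALSE))
  }
  tx <- if (is.null(genes)) {
    new_transcript_models(
      data.frame(gene_id = character(), chrom = character(),
                 strand = character(), cds_start = integer(),
                 cds_end = integer(), stringsAsFactors = FALSE),
      data.frame(gene_id = character(), start = integer(), end = integer(),
                 stringsAsFactors = FALSE))
  } else new_transcript_models(genes, exons)
  list(genome = Biostrings::DNAStringSet(chroms), transcripts = tx,
       gene_spans = spans)
}

# random non-overlapping interval placement with retries
place_interval <- function(spans, chrom, width, chrom_len, margin = 2000L,
                           tries = 200L) {
  existing <- spans[spans$chrom == chrom, , drop = FALSE]
  if (chrom_len - width - 2L * margin < 1L) return(NA_integer_)
  for (t in seq_len(tries)) {
    start <- sample.int(chrom_len - width - 2L * margin, 1L) + margin
    if (!nrow(existing) ||
        all(start + width - 1L < existing$start - 50L |
            start > existing$end + 50L))
      return(start)
  }
  NA_integer_
}

# batched free-position allocator over the genome
make_allocator <- function(chrom_lengths) {
  free <- lapply(chrom_lengths, function(L) {
    f <- rep(TRUE, L)
    f[c(seq_len(5L), (L - 15L):L)] <- FALSE  # indel-safe margins
    f
  })
  names(free) <- names(chrom_lengths)
  env <- environment()
  list(
    reserve = function(chrom, start, end) {
      f <- env$free[[chrom]]
      f[max(1L, start):min(length(f), end)] <- FALSE
      env$free[[chrom]] <- f
    },
    draw = function(n) {
      if (n == 0L)
        return(data.frame(chrom = character(), pos = integer(),
                          stringsAsFactors = FALSE))
      avail <- vapply(env$free, sum, 1L)
      ch <- sample(names(env$free), n, replace = TRUE, prob = avail)
      out <- lapply(unique(ch), function(c1) {
        k <- sum(ch == c1)
        idx <- which(env$free[[c1]])
        pos <- if (length(idx) == 1L) idx else sample(idx, k)
        f <- env$free[[c1]]; f[pos] <- FALSE; env$free[[c1]] <- f
        data.frame(chrom = c1, pos = pos, stringsAsFactors = FALSE)
      })
      do.call(rbind, out)
    }
  )
}

#' Simulate a fully labelled clonal cohort
#'
#' Generates the genome ([simulate_genome()]) and then the cohort: parental
#' standing het SNVs; per-experiment founder sublineage variant sets
#' (Poisson(lambda x founder_passages), shared by the clones and untargeted
#' controls assigned to the sublineage); clone-private variants
#' (Poisson(lambda x post-bottleneck passages)); engineered on-target edits
#' at planted protospacer+PAM sites; heterozygous 1-10 bp indels 2-5 bases
#' PAM-proximal at planted off-target sites for double-strand-break clones;
#' LOH tracts flipping parental het markers to homozygous around edited
#' loci; and low-quality decoy calls. Every emitted alternate genotype is
#' explained by exactly one ground-truth record. Deterministic under
#' `config$seed`.
#'
#' @param config a `sim_config`.
#' @return list of class `sim_cohort`: `cohort` (a `clonal_cohort`),
#'   `truth` (per-variant origin labels and carriers), `loh` (injected LOH
#'   tracts), `genome`, `transcripts`, `qc` (QC outcome table),
#'   `planted_sites`, `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  gsim <- simulate_genome(config)  # seeds the RNG
  genome <- gsim$genome
  chrom_lengths <- setNames(Biostrings::width(genome), names(genome))
  chrom_str <- lapply(as.list(as.character(genome)), identity)

  lambda <- config$per_passage_rate
  E <- config$n_experiments
  meta_rows <- list(); guide_rows <- list(); site_rows <- list()
  spans <- gsim$gene_spans

  draw_passage <- function()
    sample(seq(config$passage_range[1], config$passage_range[2]), 1L)

  # --- lines -----------------------------------------------------------
  meta_rows[["parental"]] <- data.frame(
    line_id = "parental", group_id = "", experiment_id = "",
    role = "parental", method = "none", passage = NA_integer_,
    parent_line = "", expected_edits = "", guide_ids = "",
    stringsAsFactors = FALSE)
  for (i in seq_len(config$n_subclones))
    meta_rows[[paste0("subclone_", i)]] <- data.frame(
      line_id = sprintf("subclone_%d", i), group_id = "",
      experiment_id = "", role = "subclone", method = "none",
      passage = draw_passage(), parent_line = "", expected_edits = "",
      guide_ids = "", stringsAsFactors = FALSE)

  experiments <- list()
  # keep edited loci away from chromosome ends so LOH tracts retain
  # flanking markers on both sides, without outgrowing small genomes
  margin <- min(ceiling(config$loh_tract_bp / 2) + 2000L,
                floor(min(chrom_lengths) / 3))
  for (e in seq_len(E)) {
    method <- config$methods[e]
    exp_id <- sprintf("exp%02d", e)
    grp <- sprintf("group%02d", e)
    gid <- sprintf("guide%02d", e)
    # plant the on-target protospacer+PAM and define the engineered edit
    ch <- names(genome)[(e - 1L) %% length(genome) + 1L]
    start <- place_interval(spans, ch, 23L, chrom_lengths[[ch]],
                            margin = margin)
    if (is.na(start)) stop("could not place target site; enlarge genome")
    spans <- rbind(spans, data.frame(chrom = ch, start = start,
                                     end = start + 22L))
    proto <- rand_dna(20L)
    s <- chrom_str[[ch]]
    substr(s, start, start + 22L) <- paste0(proto, "AGG")
    chrom_str[[ch]] <- s
    pam_start <- start + 20L
    edit_pos <- pam_start - 3L
    edit_ref <- substr(chrom_str[[ch]], edit_pos, edit_pos)
    edit_alt <- rand_alt_base(edit_ref)
    zyg <- if (method %in% DSB_METHODS) "hom_alt" else "het"
    kind <- if (method == "prime") "pegRNA_spacer" else "sgRNA"
    guide_rows[[gid]] <- data.frame(
      guide_id = gid, protospacer = proto, pam_pattern = "NGG",
      kind = kind, stringsAsFactors = FALSE)
    # plant sequence-similar decoy off-target sites
    planted <- list()
    for (d in seq_len(config$n_offtarget_sites)) {
      ch2 <- sample(names(genome), 1L)
      st2 <- place_interval(spans, ch2, 23L, chrom_lengths[[ch2]],
                            margin = margin)
      if (is.na(st2)) stop("could not place off-target site; enlarge genome")
      spans <- rbind(spans, data.frame(chrom = ch2, start = st2,
                                       end = st2 + 22L))
      k <- sample(1:5, 1L)
      pvec <- strsplit(proto, "")[[1]]
      at <- sample(20L, k)
      for (a in at) pvec[a] <- sample(setdiff(c("A", "C", "G", "T"),
                                              pvec[a]), 1L)
      site_fwd <- paste0(paste(pvec, collapse = ""), "AGG")
      strand2 <- sample(c("+", "-"), 1L)
      s2 <- chrom_str[[ch2]]
      if (strand2 == "+") {
        substr(s2, st2, st2 + 22L) <- site_fwd
        pam_s <- st2 + 20L; pam_e <- st2 + 22L
      } else {
        substr(s2, st2, st2 + 22L) <- as.character(
          Biostrings::reverseComplement(Biostrings::DNAString(site_fwd)))
        pam_s <- st2; pam_e <- st2 + 2L
      }
      chrom_str[[ch2]] <- s2
      planted[[d]] <- data.frame(
        guide_id = gid, chrom = ch2, start = st2, end = st2 + 22L,
        strand = strand2, mismatches = k, pam_start = pam_s, pam_end = pam_e,
        stringsAsFactors = FALSE)
    }
    planted <- if (length(planted)) do.call(rbind, planted) else NULL
    site_rows[[gid]] <- planted
    experiments[[e]] <- list(
      exp_id = exp_id, group = grp, method = method, guide_id = gid,
      proto = proto, edit = list(chrom = ch, pos = edit_pos, ref = edit_ref,
                                 alt = edit_alt, zygosity = zyg),
      on_site = list(chrom = ch, start = start, pam_start = pam_start),
      planted = planted)
    edit_str <- paste(ch, edit_pos, edit_ref, edit_alt, zyg, sep = ":")
    for (i in seq_len(config$clones_per_experiment)) {
      id <- sprintf("%s_clone%d", grp, i)
      meta_rows[[id]] <- data.frame(
        line_id = id, group_id = grp, experiment_id = exp_id,
        role = "edited", method = method, passage = draw_passage(),
        parent_line = "", expected_edits = edit_str, guide_ids = gid,
        stringsAsFactors = FALSE)
    }
    for (i in seq_len(config$ewt_per_experiment)) {
      id <- sprintf("%s_EWT%d", grp, i)
      meta_rows[[id]] <- data.frame(
        line_id = id, group_id = grp, experiment_id = exp_id,
        role = "edited_wildtype", method = method,
        passage = draw_passage(), parent_line = "", expected_edits = "",
        guide_ids = "", stringsAsFactors = FALSE)
    }
  }
  meta <- do.call(rbind, meta_rows)
  rownames(meta) <- NULL
  guides <- if (length(guide_rows)) do.call(rbind, guide_rows) else NULL
  if (!is.null(guides)) rownames(guides) <- NULL
  genome <- Biostrings::DNAStringSet(unlist(chrom_str))

  # --- position allocator; keep random mutations out of guide sites ----
  alloc <- make_allocator(chrom_lengths)
  reserve_sites <- function(df) {
    for (i in seq_len(nrow(df))) alloc$reserve(df$chrom[i], df$start[i],
                                               df$end[i])
  }
  for (ex in experiments) {
    reserve_sites(data.frame(chrom = ex$on_site$chrom,
                             start = ex$on_site$start,
                             end = ex$on_site$start + 22L))
    if (!is.null(ex$planted)) reserve_sites(ex$planted)
  }
  if (config$exclude_cleavage_sites && length(experiments)) {
    for (ex in experiments) {
      found <- enumerate_sites(
        list(guide_id = ex$guide_id, protospacer = ex$proto,
             pam_pattern = "NGG"), genome, max_mismatches = 5)
      if (nrow(found)) reserve_sites(found)
    }
  }

  # --- variants --------------------------------------------------------
  lines <- meta$line_id
  clones <- meta$line_id[meta$role %in% c("edited", "edited_wildtype")]
  var_rows <- list()
  add_variant <- function(chrom, pos, ref, alt, origin, carriers, geno_class,
                          qual = NULL, guide_id = "", site_start = NA,
                          site_strand = "", dist = NA) {
    if (is.null(qual)) qual <- round(runif(1, 35, 60), 2)
    var_rows[[length(var_rows) + 1L]] <<- list(
      chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
      qual = qual, carriers = paste(carriers, collapse = ";"),
      geno_class = geno_class, origin = origin, guide_id = guide_id,
      site_start = if (is.na(site_start)) NA_integer_ else
        as.integer(site_start),
      site_strand = site_strand, distance_to_pam = if (is.na(dist))
        NA_integer_ else as.integer(dist))
  }
  collect_rows <- function() {
    f <- function(name) unlist(lapply(var_rows, `[[`, name),
                               use.names = FALSE)
    variants <- data.frame(
      chrom = f("chrom"), pos = f("pos"), ref = f("ref"),
      alt = f("alt"), qual = f("qual"), carriers = f("carriers"),
      geno_class = f("geno_class"), stringsAsFactors = FALSE)
    truth <- data.frame(
      chrom = variants$chrom, pos = variants$pos, ref = variants$ref,
      alt = variants$alt, origin = f("origin"),
      carriers = variants$carriers, guide_id = f("guide_id"),
      site_start = f("site_start"), site_strand = f("site_strand"),
      distance_to_pam = f("distance_to_pam"), stringsAsFactors = FALSE)
    list(variants = variants, truth = truth)
  }
  base_at <- function(chrom, pos) substr(chrom_str[[chrom]], pos, pos)
  # one list entry per batch, vector-valued fields; flattened in collect_rows
  snv_batch <- function(n, origin, carriers, geno_class) {
    if (n == 0L) return(invisible())
    pp <- alloc$draw(n)
    ref <- vapply(seq_len(nrow(pp)), function(i)
      base_at(pp$chrom[i], pp$pos[i]), "")
    var_rows[[length(var_rows) + 1L]] <<- list(
      chrom = pp$chrom, pos = pp$pos, ref = ref, alt = rand_alt_base(ref),
      qual = round(runif(nrow(pp), 35, 60), 2),
      carriers = rep(paste(carriers, collapse = ";"), nrow(pp)),
      geno_class = rep(geno_class, nrow(pp)),
      origin = rep(origin, nrow(pp)), guide_id = rep("", nrow(pp)),
      site_start = rep(NA_integer_, nrow(pp)),
      site_strand = rep("", nrow(pp)),
      distance_to_pam = rep(NA_integer_, nrow(pp)))
    invisible()
  }

  # parental standing het markers (carried by every line)
  n_mark <- round(sum(chrom_lengths) * config$parental_het_marker_density)
  snv_batch(n_mark, "parental_standing", lines, "het")

  # founder sublineages and clone-private variants
  S <- config$founder_sublineages_per_experiment
  for (e in seq_len(E)) {
    ex <- experiments[[e]]
    grp_meta <- meta[meta$experiment_id == ex$exp_id, , drop = FALSE]
    ed <- grp_meta$line_id[grp_meta$role == "edited"]
    wt <- grp_meta$line_id[grp_meta$role == "edited_wildtype"]
    sub_of <- c(setNames(((seq_along(ed) - 1L) %% S) + 1L, ed),
                setNames(((seq_along(wt) - 1L) %% S) + 1L, wt))
    for (s in seq_len(S)) {
      members <- names(sub_of)[sub_of == s]
      if (!length(members)) next
      snv_batch(rpois(1L, lambda * config$founder_passages),
                "founder", members, "het")
    }
  }
  for (id in c(meta$line_id[meta$role == "subclone"], clones)) {
    p <- meta$passage[meta$line_id == id]
    snv_batch(rpois(1L, lambda * max(p - config$founder_passages, 0)),
              "private", id, "het")
  }

  # engineered on-target edits
  for (ex in experiments) {
    ed <- meta$line_id[meta$experiment_id == ex$exp_id &
                       meta$role == "edited"]
    if (!length(ed)) next
    add_variant(ex$edit$chrom, ex$edit$pos, ex$edit$ref, ex$edit$alt,
                "on_target", ed, ex$edit$zygosity, guide_id = ex$guide_id)
  }

  # off-target indels (double-strand-break clones only)
  for (ex in experiments) {
    if (!ex$method %in% DSB_METHODS || is.null(ex$planted)) next
    ed <- meta$line_id[meta$experiment_id == ex$exp_id &
                       meta$role == "edited"]
    for (cl in ed) for (i in seq_len(nrow(ex$planted))) {
      if (runif(1) >= config$offtarget_prob) next
      st <- ex$planted[i, ]
      ind <- draw_cleavage_indel(st, chrom_str[[st$chrom]])
      if (is.null(ind)) next
      add_variant(st$chrom, ind$pos, ind$ref, ind$alt, "off_target", cl,
                  "het", guide_id = st$guide_id, site_start = st$start,
                  site_strand = st$strand, dist = ind$d)
    }
  }

  # low-QUAL decoy calls
  n_decoy <- if (length(clones)) round(config$decoy_frac * length(var_rows))
    else 0L
  if (n_decoy > 0) {
    pp <- alloc$draw(n_decoy)
    for (i in seq_len(nrow(pp))) {
      ref <- base_at(pp$chrom[i], pp$pos[i])
      cl <- sample(clones, 1L)
      add_variant(pp$chrom[i], pp$pos[i], ref, rand_alt_base(ref),
                  "low_qual_decoy", cl, "het",
                  qual = round(runif(1, 5, 29.5), 2))
    }
  }
  collected <- collect_rows()
  variants <- collected$variants
  truth <- collected$truth

  # genotype matrix
  geno <- matrix("hom_ref", nrow(variants), length(lines),
                 dimnames = list(NULL, lines))
  carrier_list <- strsplit(variants$carriers, ";", fixed = TRUE)
  single <- lengths(carrier_list) == 1L
  geno[cbind(which(single),
             match(unlist(carrier_list[single]), lines))] <-
    variants$geno_class[single]
  for (i in which(!single))
    geno[i, carrier_list[[i]]] <- variants$geno_class[i]

  # LOH tracts: flip in-tract parental markers to hom_ref in the clone
  loh_rows <- list()
  is_marker <- truth$origin == "parental_standing"
  for (ex in experiments) {
    if (!ex$method %in% DSB_METHODS || ex$edit$zygosity != "hom_alt") next
    ed <- meta$line_id[meta$experiment_id == ex$exp_id &
                       meta$role == "edited"]
    half <- floor(config$loh_tract_bp / 2)
    for (cl in ed) {
      if (runif(1) >= config$loh_prob) next
      t0 <- max(1L, ex$edit$pos - half)
      t1 <- min(chrom_lengths[[ex$edit$chrom]], ex$edit$pos + half)
      hit <- which(is_marker & variants$chrom == ex$edit$chrom &
                   variants$pos >= t0 & variants$pos <= t1)
      geno[hit, cl] <- "hom_ref"
      loh_rows[[length(loh_rows) + 1L]] <- data.frame(
        line_id = cl, chrom = ex$edit$chrom, pos = ex$edit$pos,
        tract_start = t0, tract_end = t1, n_markers_lost = length(hit),
        stringsAsFactors = FALSE)
    }
  }
  loh <- if (length(loh_rows)) do.call(rbind, loh_rows) else
    data.frame(line_id = character(), chrom = character(), pos = integer(),
               tract_start = integer(), tract_end = integer(),
               n_markers_lost = integer(), stringsAsFactors = FALSE)
  # reconcile truth carriers with post-LOH genotypes
  if (nrow(loh)) {
    pres <- geno == "het" | geno == "hom_alt"
    truth$carriers[is_marker] <- vapply(which(is_marker), function(i)
      paste(lines[pres[i, ]], collapse = ";"), "")
  }

  # QC outcomes
  qc_rows <- list()
  for (cl in clones) {
    m <- meta[meta$line_id == cl, ]
    cls <- if (m$method %in% DSB_METHODS) "dsb" else "prime"
    qc_rows[[length(qc_rows) + 1L]] <- data.frame(
      line_id = cl, assay = "karyotype_structural", tested = TRUE,
      passed = runif(1) >= config$qc_fail_karyotype[[cls]],
      stringsAsFactors = FALSE)
    qc_rows[[length(qc_rows) + 1L]] <- data.frame(
      line_id = cl, assay = "pluripotency", tested = TRUE,
      passed = runif(1) >= config$qc_fail_pluripotency,
      stringsAsFactors = FALSE)
    hom_edit <- m$role == "edited" && grepl(":hom_alt", m$expected_edits)
    qc_rows[[length(qc_rows) + 1L]] <- data.frame(
      line_id = cl, assay = "loh_zygosity", tested = hom_edit,
      passed = if (hom_edit) !(cl %in% loh$line_id) else NA,
      stringsAsFactors = FALSE)
  }
  qc <- if (length(qc_rows)) do.call(rbind, qc_rows) else
    data.frame(line_id = character(), assay = character(),
               tested = logical(), passed = logical(),
               stringsAsFactors = FALSE)
  rownames(qc) <- NULL

  cohort <- new_cohort(variants[c("chrom", "pos", "ref", "alt", "qual")],
                       geno, meta, guides)
  truth$key <- paste(truth$chrom, truth$pos, truth$ref, truth$alt, sep = ":")
  planted_sites <- if (length(site_rows)) do.call(rbind, site_rows) else NULL
  structure(list(cohort = cohort, truth = truth, loh = loh, genome = genome,
                 transcripts = gsim$transcripts, qc = qc,
                 planted_sites = planted_sites, config = config),
            class = "sim_cohort")
}

# Draw a heterozygous 1-10 bp indel whose leftmost changed base sits 2-5
# protospacer positions upstream of the site's PAM, rejecting draws whose
# left-aligned normalized form would shift off that anchor.
draw_cleavage_indel <- function(site, chrom_seq, tries = 100L) {
  for (t in seq_len(tries)) {
    d <- sample(2:5, 1L)
    len <- sample(1:10, 1L)
    # protospacer position d upstream of the PAM: pam_start - d on plus
    # strand sites, pam_end + d (mirrored) on minus strand sites
    pos_change <- if (site$strand == "+") site$pam_start - d else
      site$pam_end + d
    anchor <- pos_change - 1L
    a <- substr(chrom_seq, anchor, anchor)
    if (runif(1) < 0.5) {  # deletion
      ref <- substr(chrom_seq, anchor, anchor + len)
      alt <- a
    } else {               # insertion
      ref <- a
      alt <- paste0(a, rand_dna(len))
    }
    norm <- normalize_one(anchor, ref, alt, chrom_seq, site$chrom)
    if (norm$pos == anchor && norm$ref == ref && norm$alt == alt)
      return(list(pos = anchor, ref = ref, alt = alt, d = d))
  }
  NULL
}

#' Write a simulated cohort bundle to disk
#'
#' Emits genome FASTA, transcripts GFF3, joint VCF, metadata / guides / QC
#' TSVs and the ground-truth tables.
#'
#' @param sim a `sim_cohort`.
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of written paths.
#' @export
write_sim <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    genome = file.path(dir, "genome.fa"),
    transcripts = file.path(dir, "transcripts.gff3"),
    vcf = file.path(dir, "cohort.vcf"),
    meta = file.path(dir, "metadata.tsv"),
    guides = file.path(dir, "guides.tsv"),
    qc = file.path(dir, "qc.tsv"),
    truth = file.path(dir, "truth.tsv"),
    loh = file.path(dir, "loh_truth.tsv")
  )
  Biostrings::writeXStringSet(sim$genome, paths["genome"])
  write_transcripts(sim$transcripts, paths["transcripts"],
                    setNames(Biostrings::width(sim$genome),
                             names(sim$genome)))
  write_cohort(sim$cohort, paths["vcf"], paths["meta"], paths["guides"])
  write.table(sim$qc, paths["qc"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(sim$truth, paths["truth"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(sim$loh, paths["loh"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(paths)
}
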