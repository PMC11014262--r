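# Synthetic small RNA-seq data with a machine-readable truth table.
#
# The generator emulates the data characteristics of social-amoeba small RNA
# libraries: an AT-rich intergenic background (~86% AT), 18-35 nt reads with
# a modal length of 21 nt, three biological replicates, miRNA loci processed
# into a mir-5p/mir-3p duplex with 2-nt 3' overhangs and tunable 5'-end
# jitter, siRNA/transposon loci with diffuse double-stranded read coverage,
# and structured-ncRNA decoys with heterogeneous read ends.

RNA_BASES <- c("A", "C", "G", "U")
CANONICAL_PAIRS <- c("AU", "UA", "GC", "CG", "GU", "UG")

rna_complement <- function(b) c(A = "U", C = "G", G = "C", U = "A")[b]

# a base that neither Watson-Crick nor wobble pairs with b
non_pairing_base <- function(b) {
  opts <- list(A = c("A", "C", "G"), C = c("A", "C", "U"),
               G = c("A", "G"), U = c("C", "U"))[[b]]
  sample(opts, 1L)
}

is_canonical_pair <- function(b1, b2) paste0(b1, b2) %in% CANONICAL_PAIRS

#' Design a miRNA hairpin precursor
#'
#' Constructs a precursor (RNA alphabet) of the form
#' `arm5p + loop + arm3p` whose intended pairing leaves `overhang3p`
#' unpaired nucleotides at the 3' end of each arm (the RNase-III signature),
#' makes the requested arm positions mismatched, and inserts the requested
#' bulges. The design is refolded at minimum free energy and redrawn (new
#' loop/bulge/overhang nucleotides) until the fold reproduces the intended
#' duplex pairing, up to `max_retry` attempts.
#'
#' @param arm5p mature 5p arm sequence (RNA or DNA, 18-25 nt).
#' @param loop_len length of the unpaired connecting loop (>= 3 nt).
#' @param overhang3p 3' overhang length at both duplex ends (default 2).
#' @param mismatch_positions arm5p-relative stem positions to leave unpaired.
#' @param bulge_spec list of `list(arm = "5p"|"3p", position = k, n = count)`;
#'   `position` is the 5p-relative stem position after which the extra
#'   nucleotides sit.
#' @param rng_seed integer seed for the nucleotide draws.
#' @param refold logical; verify the MFE refold (default TRUE).
#' @param temperature folding temperature for the refold check.
#' @param max_retry redraw budget for designs whose refold fails.
#' @return a `hairpin_design` list; see Details.
#' @export
design_hairpin <- function(arm5p, loop_len, overhang3p = 2L,
                           mismatch_positions = integer(0),
                           bulge_spec = list(),
                           rng_seed = 1L, refold = TRUE,
                           temperature = 22, max_retry = 10L) {
  arm5p <- toupper(dna_to_rna(arm5p))
  L5 <- nchar(arm5p)
  if (L5 < 18 || L5 > 25) stop("invalid design: arm5p must be 18-25 nt")
  if (loop_len < 3) stop("invalid design: loop_len must be >= 3")
  if (overhang3p < 0) stop("invalid design: overhang3p must be >= 0")
  paired_len <- L5 - overhang3p
  if (paired_len < 10) stop("invalid design: too few paired stem positions")
  mismatch_positions <- as.integer(mismatch_positions)
  if (any(mismatch_positions < 1 | mismatch_positions > paired_len)) {
    stop("invalid design: mismatch position outside the paired stem")
  }
  for (b in bulge_spec) {
    if (!b$arm %in% c("5p", "3p") || b$position < 1 ||
        b$position >= paired_len || b$n < 1) {
      stop("invalid design: bad bulge specification")
    }
  }
  a5 <- strsplit(arm5p, "")[[1]]

  build <- function() {
    # stem columns 1..paired_len pair arm5p[k] with the 3p strand
    partner <- character(paired_len)
    for (k in seq_len(paired_len)) {
      partner[k] <- if (k %in% mismatch_positions) {
        non_pairing_base(a5[k])
      } else {
        rna_complement(a5[k])
      }
    }
    bulge_nt <- function(n) sample(c("A", "C"), n, replace = TRUE)
    ins5 <- lapply(seq_len(paired_len), function(k) character(0))
    ins3 <- lapply(seq_len(paired_len), function(k) character(0))
    for (b in bulge_spec) {
      if (b$arm == "5p") ins5[[b$position]] <- bulge_nt(b$n)
      else ins3[[b$position]] <- bulge_nt(b$n)
    }
    # 5p strand: column bases with insertions, then the unpaired 3' tail
    fin5 <- character(0)
    pos5 <- integer(paired_len)                       # precursor pos of col k
    for (k in seq_len(paired_len)) {
      fin5 <- c(fin5, a5[k])
      pos5[k] <- length(fin5)
      fin5 <- c(fin5, ins5[[k]])
    }
    if (overhang3p > 0) fin5 <- c(fin5, a5[(paired_len + 1):L5])
    loop <- sample(c("A", "C"), loop_len, replace = TRUE)
    # 3p strand runs antiparallel: columns paired_len..1, then the overhang
    fin3 <- character(0)
    pos3rel <- integer(paired_len)
    for (k in rev(seq_len(paired_len))) {
      fin3 <- c(fin3, partner[k])
      pos3rel[k] <- length(fin3)
      if (k > 1) fin3 <- c(fin3, ins3[[k - 1L]])
    }
    if (overhang3p > 0) fin3 <- c(fin3, sample(c("A", "C"), overhang3p, TRUE))
    L5f <- length(fin5); L3f <- length(fin3)
    precursor <- c(fin5, loop, fin3)
    struct <- rep(".", length(precursor))
    keep <- setdiff(seq_len(paired_len), mismatch_positions)
    struct[pos5[keep]] <- "("
    struct[L5f + loop_len + pos3rel[keep]] <- ")"
    list(arm5p = paste(fin5, collapse = ""),
         arm3p = paste(fin3, collapse = ""),
         precursor_seq = paste(precursor, collapse = ""),
         intended_structure = paste(struct, collapse = ""),
         arm5p_start = 1L, arm5p_end = L5f,
         arm3p_start = L5f + loop_len + 1L,
         arm3p_end = L5f + loop_len + L3f)
  }

  res <- with_seed(rng_seed, {
    recovery <- NA_real_
    d <- NULL
    for (try in seq_len(max_retry)) {
      d <- build()
      if (!refold) { recovery <- NA_real_; break }
      fold <- fold_sequences(d$precursor_seq, temperature = temperature)
      pt_int <- pair_table(d$intended_structure)
      pt_mfe <- pair_table(fold$structure)
      idx <- which(!is.na(pt_int) & pt_int > seq_along(pt_int))
      recovery <- mean(pt_mfe[idx] == pt_int[idx], na.rm = FALSE)
      recovery[is.na(recovery)] <- 0
      if (recovery >= 0.9) break
    }
    c(d, list(refold_recovery = recovery))
  })
  structure(c(res, list(
    loop_len = as.integer(loop_len),
    overhang3p = as.integer(overhang3p),
    mismatch_positions = mismatch_positions,
    bulge_spec = bulge_spec
  )), class = "hairpin_design")
}

#' Draw a random hairpin design
#'
#' Arm length 20-23 nt, loop 33-60 nt (precursor mostly in the 75-125 nt
#' range typical of amoebozoan pre-miRNAs), 2-nt 3' overhangs, up to two
#' stem mismatches and at most one single-nucleotide bulge, with a mature
#' arm noticeably less AT-rich than the intergenic background.
#'
#' @param rng_seed integer seed.
#' @param refold verify the MFE refold (default TRUE).
#' @return a `hairpin_design`.
#' @export
random_hairpin_design <- function(rng_seed = 1L, refold = TRUE) {
  par <- with_seed(rng_seed, {
    arm_len <- sample(20:23, 1L, prob = c(0.20, 0.55, 0.15, 0.10))
    arm_nt <- sample(RNA_BASES, arm_len, TRUE,
                     prob = c(0.30, 0.20, 0.20, 0.30))
    # mature miRNAs start with U far more often than chance
    arm_nt[1] <- sample(c("U", "A", "C", "G"), 1L,
                        prob = c(0.50, 0.25, 0.15, 0.10))
    arm <- paste(arm_nt, collapse = "")
    paired_len <- arm_len - 2L
    # keep stem ends paired: terminal pairing is required for processing,
    # and interior placement keeps the MFE refold faithful
    n_mm <- sample(0:2, 1L, prob = c(0.4, 0.4, 0.2))
    mm <- if (n_mm > 0) sort(sample(5:(paired_len - 5L), n_mm)) else integer(0)
    bg <- if (runif(1) < 0.3) {
      list(list(arm = sample(c("5p", "3p"), 1L),
                position = sample(5:(paired_len - 5L), 1L), n = 1L))
    } else list()
    list(arm = arm, loop = sample(33:60, 1L), mm = mm, bg = bg)
  })
  design_hairpin(par$arm, loop_len = par$loop, overhang3p = 2L,
                 mismatch_positions = par$mm, bulge_spec = par$bg,
                 rng_seed = rng_seed + 7919L, refold = refold)
}

#' Simulation configuration
#'
#' Defaults reproduce the study conditions this package targets: an 86%
#' AT intergenic background, three biological replicates, 200,000 reads per
#' replicate, a 21-nt modal read length, 85% exact miRNA 5' ends
#' (jitter distribution `{0: 0.85, +1: 0.10, -1: 0.05}`), and a dominant
#' guide arm (5p:3p read ratio 5:1).
#'
#' @param genome_len genome length in bp.
#' @param at_content background A+T fraction.
#' @param n_replicates number of biological replicates.
#' @param reads_per_replicate library size per replicate.
#' @param adapter 3' sequencing adapter (DNA) ligated to every read.
#' @param jitter5p named probability vector over miRNA 5'-end offsets
#'   (names are offsets in nt, downstream positive).
#' @param jitter3p named probability vector over miRNA 3'-length offsets.
#' @param arm_ratio_5p expected ratio of 5p-arm to 3p-arm reads.
#' @param read_len_cap sequencer read length; insert plus adapter is
#'   truncated to this many bases.
#' @param bg_len_probs named probability vector of background read lengths.
#' @param bg_margin background reads are kept at least this many bp away
#'   from planted loci so that planted-locus read stacks stay pure.
#' @param rng_seed master seed; all randomness derives from it.
#' @return a `sim_config` list.
#' @export
sim_config <- function(genome_len = 500000L, at_content = 0.86,
                       n_replicates = 3L, reads_per_replicate = 200000L,
                       adapter = "TGGAATTCTCGGGTGCCAAGG",
                       jitter5p = c(`0` = 0.85, `1` = 0.10, `-1` = 0.05),
                       jitter3p = c(`0` = 0.80, `1` = 0.10, `-1` = 0.10),
                       arm_ratio_5p = 5,
                       read_len_cap = 50L,
                       bg_len_probs = c(`18` = 0.02, `19` = 0.05, `20` = 0.10,
                                        `21` = 0.45, `22` = 0.15, `23` = 0.08,
                                        `24` = 0.05, `25` = 0.04, `26` = 0.03,
                                        `27` = 0.02, `28` = 0.01),
                       bg_margin = 150L,
                       rng_seed = 1L) {
  stopifnot(n_replicates >= 1, at_content >= 0, at_content <= 1,
            abs(sum(jitter5p) - 1) < 1e-9, abs(sum(jitter3p) - 1) < 1e-9,
            abs(sum(bg_len_probs) - 1) < 1e-9)
  structure(list(genome_len = as.integer(genome_len),
                 at_content = at_content,
                 n_replicates = as.integer(n_replicates),
                 reads_per_replicate = as.integer(reads_per_replicate),
                 adapter = toupper(adapter),
                 jitter5p = jitter5p, jitter3p = jitter3p,
                 arm_ratio_5p = arm_ratio_5p,
                 read_len_cap = as.integer(read_len_cap),
                 bg_len_probs = bg_len_probs,
                 bg_margin = as.integer(bg_margin),
                 rng_seed = as.integer(rng_seed)),
            class = "sim_config")
}

#' Plan a locus for genome synthesis
#'
#' @param locus_id unique identifier.
#' @param locus_class one of `mirna`, `sirna`, `ncrna_decoy`, `transposon`.
#' @param start 0-based genome start of the inserted sequence.
#' @param strand `"+"` or `"-"`.
#' @param design a [design_hairpin()] result (required for `mirna`).
#' @param sequence DNA sequence to insert (non-miRNA classes).
#' @param context intended genomic context label.
#' @param expression expected read count per replicate (recycled to the
#'   number of replicates at simulation time).
#' @param contig contig name.
#' @return a `locus_plan` list.
#' @export
locus_plan <- function(locus_id, locus_class, start, strand = "+",
                       design = NULL, sequence = NULL,
                       context = "intergenic", expression = 1000,
                       contig = "synth1") {
  locus_class <- match.arg(locus_class,
                           c("mirna", "sirna", "ncrna_decoy", "transposon"))
  if (locus_class == "mirna") {
    if (is.null(design)) stop("mirna plans require a hairpin design")
    sequence <- rna_to_dna(design$precursor_seq)
  }
  if (is.null(sequence)) stop("non-miRNA plans require a sequence")
  stopifnot(all(expression >= 0), strand %in% c("+", "-"))
  structure(list(locus_id = locus_id, locus_class = locus_class,
                 contig = contig, start = as.integer(start),
                 end = as.integer(start) + nchar(sequence),
                 strand = strand, design = design,
                 sequence = toupper(sequence), context = context,
                 expression = expression),
            class = "locus_plan")
}

# a two-hairpin (cloverleaf-like) structured ncRNA used as a decoy: it can
# fold, but never into a single stem-loop, and its reads get uniform 5' ends
make_decoy_sequence <- function(rng_seed = 1L) {
  with_seed(rng_seed, {
    stem <- function(n) paste(sample(c("G", "C", "A", "T"), n, TRUE,
                                     prob = c(0.35, 0.35, 0.15, 0.15)),
                              collapse = "")
    s1 <- stem(10L); s2 <- stem(10L)
    lp <- function(n) paste(sample(c("A", "T"), n, TRUE), collapse = "")
    paste0(lp(3), s1, lp(6), dna_revcomp(s1), lp(5),
           s2, lp(7), dna_revcomp(s2), lp(3))
  })
}

#' Random DNA of given GC content
#' @param n length in nt.
#' @param gc GC fraction.
#' @param rng_seed integer seed.
#' @return a DNA string.
#' @export
random_dna <- function(n, gc = 0.5, rng_seed = 1L) {
  with_seed(rng_seed, paste(sample(c("A", "T", "G", "C"), n, TRUE,
                                   prob = c((1 - gc) / 2, (1 - gc) / 2,
                                            gc / 2, gc / 2)),
                            collapse = ""))
}

#' Plan the default study locus set
#'
#' Places non-overlapping miRNA, siRNA and structured-ncRNA decoy loci on
#' random strands, with per-locus expression drawn so that planted loci
#' account for ~97% of each library (rRNA-depleted small RNA libraries are
#' dominated by discrete loci) and the remainder is intergenic background.
#'
#' @param config a [sim_config()].
#' @param n_mirna,n_sirna,n_decoy locus counts per class.
#' @param rng_seed integer seed (defaults to the config seed).
#' @return list of [locus_plan()]s.
#' @export
plan_study_loci <- function(config, n_mirna = 12L, n_sirna = 20L,
                            n_decoy = 5L, rng_seed = config$rng_seed) {
  n_total <- n_mirna + n_sirna + n_decoy
  par <- with_seed(rng_seed, {
    list(
      design_seeds = sample.int(1e8, n_mirna),
      sirna_len = sample(250:400, max(n_sirna, 1L), replace = TRUE),
      seq_seeds = sample.int(1e8, n_sirna + n_decoy),
      strands = sample(c("+", "-"), n_total, replace = TRUE),
      expr_mirna = sample(4000:9000, max(n_mirna, 1L), replace = TRUE),
      expr_sirna = sample(3000:7000, max(n_sirna, 1L), replace = TRUE),
      expr_decoy = sample(2000:4000, max(n_decoy, 1L), replace = TRUE),
      expr_wobble = matrix(runif(n_total * config$n_replicates, 0.9, 1.1),
                           nrow = n_total),
      place_seed = sample.int(1e8, 1L)
    )
  })
  designs <- lapply(seq_len(n_mirna),
                    function(i) random_hairpin_design(par$design_seeds[i]))
  seqs <- c(lapply(designs, function(d) rna_to_dna(d$precursor_seq)),
            lapply(seq_len(n_sirna),
                   function(i) random_dna(par$sirna_len[i], gc = 0.5,
                                          rng_seed = par$seq_seeds[i])),
            lapply(seq_len(n_decoy),
                   function(i) make_decoy_sequence(par$seq_seeds[n_sirna + i])))
  lens <- vapply(seqs, nchar, 1L)
  # non-overlapping placement with generous spacing
  starts <- with_seed(par$place_seed, {
    gap <- 600L
    usable <- config$genome_len - sum(lens) - gap * (n_total + 1L)
    if (usable < 0) stop("genome too short for the requested loci")
    slack <- sort(sample.int(usable, n_total))
    cumsum(c(gap, lens[-n_total] + gap)) + slack
  })
  expr_mean <- c(par$expr_mirna[seq_len(n_mirna)],
                 par$expr_sirna[seq_len(n_sirna)],
                 par$expr_decoy[seq_len(n_decoy)])
  # rescale so that every replicate's expected locus total stays below the
  # library size (leaving a few percent of intergenic background)
  expr_mat <- expr_mean * par$expr_wobble
  worst <- max(colSums(expr_mat))
  scale <- min(1, 0.97 * config$reads_per_replicate / worst)
  classes <- rep(c("mirna", "sirna", "ncrna_decoy"),
                 c(n_mirna, n_sirna, n_decoy))
  ids <- paste0(c("mir", "sir", "dec")[match(classes, c("mirna", "sirna",
                                                        "ncrna_decoy"))],
                "_", unlist(lapply(c(n_mirna, n_sirna, n_decoy), seq_len)))
  plans <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    expr <- round(expr_mean[i] * scale * par$expr_wobble[i, ])
    plans[[i]] <- locus_plan(
      locus_id = ids[i], locus_class = classes[i], start = starts[i],
      strand = par$strands[i],
      design = if (classes[i] == "mirna") designs[[i]] else NULL,
      sequence = if (classes[i] == "mirna") NULL else seqs[[i]],
      expression = expr
    )
  }
  plans
}

#' Synthesize a genome with planted loci
#'
#' Background bases are drawn i.i.d. with the configured AT fraction (AT
#' split evenly between A and T, GC between G and C); planted sequences are
#' inserted verbatim (reverse-complemented for minus-strand loci).
#' Deterministic for a fixed seed.
#'
#' @param config a [sim_config()].
#' @param plans list of [locus_plan()]s; must not overlap.
#' @return a `sim_genome` list with `genome` (named character vector of
#'   contigs) and `truth` (one record per planted locus).
#' @export
synthesize_genome <- function(config, plans = list()) {
  if (length(plans) > 0) {
    st <- vapply(plans, function(p) p$start, 1L)
    en <- vapply(plans, function(p) p$end, 1L)
    if (any(st < 0) || any(en > config$genome_len)) {
      stop("locus plan outside genome bounds")
    }
    ir <- IRanges::IRanges(st + 1L, en)
    ov <- IRanges::findOverlaps(ir, drop.self = TRUE, drop.redundant = TRUE)
    if (length(ov) > 0) {
      ids <- vapply(plans, function(p) p$locus_id, "")
      stop("overlapping locus plans: ",
           paste(ids[S4Vectors::queryHits(ov)], ids[S4Vectors::subjectHits(ov)],
                 sep = "/", collapse = ", "))
    }
  }
  probs <- c(A = config$at_content / 2, T = config$at_content / 2,
             G = (1 - config$at_content) / 2, C = (1 - config$at_content) / 2)
  genome <- with_seed(config$rng_seed, sample_bases(config$genome_len, probs))
  if (length(plans) > 0) {
    ord <- order(vapply(plans, function(p) p$start, 1L))
    plans <- plans[ord]
    pieces <- character(2L * length(plans) + 1L)
    prev <- 0L
    for (i in seq_along(plans)) {
      p <- plans[[i]]
      ins <- if (p$strand == "+") p$sequence else dna_revcomp(p$sequence)
      pieces[2L * i - 1L] <- substring(genome, prev + 1L, p$start)
      pieces[2L * i] <- ins
      prev <- p$end
    }
    pieces[2L * length(plans) + 1L] <- substring(genome, prev + 1L,
                                                 config$genome_len)
    genome <- paste(pieces, collapse = "")
  }
  truth <- lapply(plans, function(p) {
    rec <- list(locus_id = p$locus_id, plan = p,
                mature_arm = if (p$locus_class == "mirna") "both" else NA,
                realized_read_counts = rep(NA_integer_, config$n_replicates))
    if (p$locus_class == "mirna") {
      rec$duplex <- plan_duplex_coords(p)
    }
    rec
  })
  names(truth) <- vapply(plans, function(p) p$locus_id, "")
  structure(list(contig = "synth1",
                 genome = setNames(genome, "synth1"),
                 truth = truth, config = config),
            class = "sim_genome")
}

# 0-based genome coordinates of the planted duplex arms
plan_duplex_coords <- function(plan) {
  d <- plan$design
  L <- plan$end - plan$start
  to_genome <- function(a, b) {        # precursor positions, 1-based inclusive
    if (plan$strand == "+") {
      c(plan$start + a - 1L, plan$start + b)
    } else {
      c(plan$start + L - b, plan$start + L - a + 1L)
    }
  }
  g5 <- to_genome(d$arm5p_start, d$arm5p_end)
  g3 <- to_genome(d$arm3p_start, d$arm3p_end)
  list(arm5p = c(start = g5[1], end = g5[2]),
       arm3p = c(start = g3[1], end = g3[2]))
}

jitter_draw <- function(dist, n) {
  as.integer(sample(names(dist), n, replace = TRUE, prob = dist))
}

#' Simulate replicate small RNA libraries
#'
#' miRNA loci emit arm reads with configurable 5'-end jitter and 3'-length
#' jitter at a 5p:3p ratio of `arm_ratio_5p`; siRNA/transposon loci emit
#' 20-22 nt reads tiled across both strands with random 5' ends; decoys emit
#' fragmented reads with heterogeneous ends; background reads sample the
#' unplanted genome with a 21-nt modal length. The adapter is appended to
#' every read and the result truncated to the sequencer read length.
#' Per-replicate locus counts are multinomial around expected expression,
#' and locus plus background counts sum exactly to the library size.
#'
#' @param sim a `sim_genome` from [synthesize_genome()].
#' @param config a [sim_config()] (defaults to the one inside `sim`).
#' @param out_dir optional directory; when given, one gzipped FASTQ per
#'   replicate plus truth BED/JSON files are written there.
#' @return list with `reads` (per-replicate `data.table(read_id, seq)`),
#'   `truth` (records with realized per-replicate counts filled in) and
#'   `files` (paths, when `out_dir` was given).
#' @export
simulate_libraries <- function(sim, config = sim$config, out_dir = NULL) {
  genome <- sim$genome[[1]]
  truth <- sim$truth
  n_loci <- length(truth)
  if (config$reads_per_replicate == 0) {
    warning("reads_per_replicate is 0; emitting empty libraries")
  }
  expected <- vapply(truth, function(r) {
    rep_len(r$plan$expression, config$n_replicates)
  }, numeric(config$n_replicates))
  expected <- matrix(expected, nrow = config$n_replicates)

  # background start positions keep clear of planted loci
  excluded <- rep(FALSE, config$genome_len)
  for (r in truth) {
    lo <- max(1L, r$plan$start - config$bg_margin)
    hi <- min(config$genome_len, r$plan$end + config$bg_margin)
    excluded[lo:hi] <- TRUE
  }
  max_bg_len <- max(as.integer(names(config$bg_len_probs)))
  allowed <- which(!excluded)
  allowed <- allowed[allowed <= config$genome_len - max_bg_len]

  # locus-strand sequences padded with genomic flank so that jittered read
  # ends can extend past the precursor boundaries
  pad <- 6L
  sense_pad <- lapply(truth, function(rec) {
    p <- rec$plan
    lo <- max(0L, p$start - pad)
    hi <- min(config$genome_len, p$end + pad)
    s <- substring(genome, lo + 1L, hi)
    if (p$strand == "-") s <- dna_revcomp(s)
    left <- if (p$strand == "+") p$start - lo else hi - p$end
    list(seq = s, offset = left)
  })

  reads <- vector("list", config$n_replicates)
  for (r in seq_len(config$n_replicates)) {
    reads[[r]] <- with_seed(as.numeric(config$rng_seed) * 131 + r, {
      exp_r <- if (n_loci) expected[r, ] else numeric(0)
      bg_exp <- config$reads_per_replicate - sum(exp_r)
      if (bg_exp < 0) stop("expected locus expression exceeds library size")
      counts <- if (config$reads_per_replicate > 0) {
        as.integer(rmultinom(1, config$reads_per_replicate,
                             c(exp_r, bg_exp) / config$reads_per_replicate))
      } else integer(n_loci + 1L)
      out <- vector("list", n_loci + 1L)
      for (i in seq_len(n_loci)) {
        out[[i]] <- emit_locus_reads(truth[[i]], counts[i], config,
                                     sense_pad[[i]])
      }
      out[[n_loci + 1L]] <- emit_background_reads(genome, allowed,
                                                  counts[n_loci + 1L], config)
      dt <- data.table::rbindlist(out)
      if (nrow(dt) > 0) {
        dt[, read_id := paste0(dt$src, "|rep", r, "|", seq_len(nrow(dt)))]
        dt[, seq := substr(paste0(dt$seq, config$adapter), 1L,
                           config$read_len_cap)]
      } else {
        dt <- data.table::data.table(src = character(0), seq = character(0),
                                     read_id = character(0))
      }
      attr(dt, "locus_counts") <- counts
      dt[, list(read_id, seq)]
    })
    # record realized counts (attribute survives the with_seed return? no:
    # recompute from ids instead)
  }
  # realized counts from read ids (source locus is encoded in the id)
  for (i in seq_len(n_loci)) {
    id <- truth[[i]]$locus_id
    truth[[i]]$realized_read_counts <- vapply(reads, function(dt) {
      sum(startsWith(dt$read_id, paste0(id, "|")))
    }, 1L)
  }
  names(reads) <- paste0("rep", seq_len(config$n_replicates))
  files <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    fq <- file.path(out_dir, paste0(names(reads), ".fastq.gz"))
    for (r in seq_along(reads)) write_fastq(reads[[r]], fq[r])
    tr <- write_truth(truth, out_dir, sim)
    files <- c(fastq = fq, tr)
  }
  list(reads = reads, truth = truth, files = files)
}

emit_locus_reads <- function(rec, n, config, padded = NULL) {
  if (n == 0) return(NULL)
  p <- rec$plan
  sense <- p$sequence                         # locus-strand DNA
  L <- nchar(sense)
  if (p$locus_class == "mirna") {
    d <- p$design
    seq_src <- if (is.null(padded)) list(seq = sense, offset = 0L) else padded
    p5 <- config$arm_ratio_5p / (config$arm_ratio_5p + 1)
    is5 <- runif(n) < p5
    a_start <- ifelse(is5, d$arm5p_start, d$arm3p_start) + seq_src$offset
    a_end <- ifelse(is5, d$arm5p_end, d$arm3p_end) + seq_src$offset
    off5 <- jitter_draw(config$jitter5p, n)
    off3 <- jitter_draw(config$jitter3p, n)
    s <- pmax(1L, a_start + off5)
    e <- pmin(nchar(seq_src$seq), a_end + off3)
    data.table::data.table(src = p$locus_id,
                           seq = substring(seq_src$seq, s, e))
  } else if (p$locus_class %in% c("sirna", "transposon")) {
    len <- sample(20:22, n, replace = TRUE, prob = c(0.25, 0.50, 0.25))
    s <- floor(runif(n, 1, L - len + 1))
    sq <- substring(sense, s, s + len - 1L)
    flip <- runif(n) < 0.5
    sq[flip] <- dna_revcomp(sq[flip])
    data.table::data.table(src = p$locus_id, seq = sq)
  } else {                                    # ncrna_decoy: heterogeneous ends
    len <- sample(19:24, n, replace = TRUE)
    s <- floor(runif(n, 1, L - len + 1))
    data.table::data.table(src = p$locus_id,
                           seq = substring(sense, s, s + len - 1L))
  }
}

emit_background_reads <- function(genome, allowed, n, config) {
  if (n == 0) return(NULL)
  len <- as.integer(sample(names(config$bg_len_probs), n, replace = TRUE,
                           prob = config$bg_len_probs))
  s <- sample(allowed, n, replace = TRUE)
  sq <- substring(genome, s, s + len - 1L)
  flip <- runif(n) < 0.5
  sq[flip] <- dna_revcomp(sq[flip])
  data.table::data.table(src = "bg", seq = sq)
}

#' Write reads as gzipped FASTQ
#'
#' Quality strings are constant `I`; the pipeline never uses base qualities.
#'
#' @param reads `data.table(read_id, seq)`.
#' @param path output path (`.gz` implies gzip).
#' @export
write_fastq <- function(reads, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  if (nrow(reads) == 0) return(invisible(path))
  qual <- strrep("I", nchar(reads$seq))
  writeLines(paste0("@", reads$read_id, "\n", reads$seq, "\n+\n", qual), con)
  invisible(path)
}

#' Read a FASTQ file into a read table
#'
#' @param path FASTQ path (optionally gzipped).
#' @param replicate replicate label recorded with every read.
#' @return `data.table(read_id, seq, replicate)`.
#' @export
read_fastq <- function(path, replicate = basename(path)) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  data.table::data.table(read_id = sub("\\s.*$", "", names(x)),
                         seq = as.character(x), replicate = replicate)
}

#' Serialize and restore the truth table
#'
#' Truth records round-trip losslessly through a BED6 file (locus intervals)
#' plus a JSON sidecar carrying the full plans and designs.
#'
#' @param truth truth record list.
#' @param dir output directory.
#' @param sim the `sim_genome` (for the genome FASTA).
#' @return named vector of written paths.
#' @export
write_truth <- function(truth, dir, sim = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  bed <- file.path(dir, "truth.bed")
  js <- file.path(dir, "truth.json")
  dt <- data.table::rbindlist(lapply(truth, function(r) {
    data.table::data.table(contig = r$plan$contig, start = r$plan$start,
                           end = r$plan$end, name = r$locus_id, score = 0L,
                           strand = r$plan$strand)
  }))
  write.table(dt, bed, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  ser <- lapply(truth, function(r) {
    r$plan$design <- if (!is.null(r$plan$design)) {
      unclass(r$plan$design)
    }
    r$plan <- unclass(r$plan)
    r
  })
  jsonlite::write_json(ser, js, auto_unbox = TRUE, digits = NA, null = "null")
  out <- c(truth_bed = bed, truth_json = js)
  if (!is.null(sim)) {
    fa <- file.path(dir, "genome.fa")
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(sim$genome), fa)
    out <- c(out, genome_fasta = fa)
  }
  out
}

#' @rdname write_truth
#' @param json path to a `truth.json` written by [write_truth()].
#' @export
read_truth <- function(json) {
  raw <- jsonlite::read_json(json)
  lapply(raw, function(r) {
    r$plan$expression <- unlist(r$plan$expression)
    r$realized_read_counts <- unlist(r$realized_read_counts)
    if (!is.null(r$plan$design)) {
      d <- r$plan$design
      d$mismatch_positions <- as.integer(unlist(d$mismatch_positions))
      r$plan$design <- structure(d, class = "hairpin_design")
    }
    r$plan <- structure(r$plan, class = "locus_plan")
    r
  })
}

#' Derive a homologous locus from a hairpin design
#'
#' Used to simulate orthologs for the conservation module: `loop_divergent`
#' replaces the connecting loop with fresh sequence (arms untouched);
#' `arm_scrambled` shuffles one arm, destroying its sequence while keeping
#' composition.
#'
#' @param design a `hairpin_design`.
#' @param mode `"loop_divergent"` or `"arm_scrambled"`.
#' @param rng_seed integer seed.
#' @return modified `hairpin_design` (refold fields dropped).
#' @export
mutate_ortholog <- function(design, mode = c("loop_divergent", "arm_scrambled"),
                            rng_seed = 1L) {
  mode <- match.arg(mode)
  with_seed(rng_seed, {
    d <- design
    if (mode == "loop_divergent") {
      # diverged connecting sequence; like real pre-miRNA loops it stays
      # unstructured (non-pairing alphabet), only its sequence changes
      loop <- paste(sample(c("A", "C"), d$loop_len, TRUE), collapse = "")
      d$precursor_seq <- paste0(d$arm5p, loop, d$arm3p)
    } else {
      a <- strsplit(d$arm5p, "")[[1]]
      repeat {
        sc <- sample(a)
        if (!identical(sc, a)) break
      }
      d$arm5p <- paste(sc, collapse = "")
      old <- substring(design$precursor_seq, d$arm5p_end + 1L)
      d$precursor_seq <- paste0(d$arm5p, old)
    }
    d$refold_recovery <- NA_real_
    d
  })
}

#' Simulate gene models around planted loci
#'
#' Builds two-exon gene models so that genomic-context classification is
#' testable on simulated data: a plan with `context = "intronic"` gets a
#' same-strand gene whose intron spans the locus, `context =
#' "exonic_antisense"` an opposite-strand gene whose exon covers the locus,
#' and `n_random` additional genes are placed clear of all planted loci.
#'
#' @param config a [sim_config()].
#' @param plans list of [locus_plan()]s.
#' @param n_random number of additional genes in free space.
#' @param rng_seed integer seed.
#' @param gff3 optional path; when given the models are written as GFF3.
#' @return an `annotation_set` with `genes` and `exons`.
#' @export
simulate_gene_models <- function(config, plans = list(), n_random = 10L,
                                 rng_seed = config$rng_seed, gff3 = NULL) {
  genes <- list(); exons <- list()
  add_gene <- function(id, start0, end0, strand, intron = NULL) {
    g <- granges0("synth1", start0, end0, strand)
    g$ID <- id
    genes[[length(genes) + 1L]] <<- g
    if (is.null(intron)) {
      mid <- start0 + (end0 - start0) %/% 2L
      ex <- granges0(rep("synth1", 2), c(start0, mid + 20L),
                     c(mid - 20L, end0), rep(strand, 2))
    } else {
      ex <- granges0(rep("synth1", 2), c(start0, intron[2]),
                     c(intron[1], end0), rep(strand, 2))
    }
    ex$ID <- paste0(id, "_e", seq_along(ex))
    exons[[length(exons) + 1L]] <<- ex
  }
  occupied <- IRanges::IRanges()
  for (i in seq_along(plans)) {
    p <- plans[[i]]
    occupied <- c(occupied, IRanges::IRanges(p$start + 1L, p$end))
    if (identical(p$context, "intronic")) {
      add_gene(paste0("gene_", p$locus_id), p$start - 300L, p$end + 300L,
               p$strand, intron = c(p$start - 50L, p$end + 50L))
    } else if (identical(p$context, "exonic_antisense")) {
      add_gene(paste0("gene_", p$locus_id), p$start - 100L, p$end + 100L,
               if (p$strand == "+") "-" else "+")
    }
  }
  rand <- with_seed(rng_seed + 17L, {
    out <- list()
    tries <- 0L
    while (length(out) < n_random && tries < 200L) {
      tries <- tries + 1L
      len <- sample(800:2000, 1L)
      st <- sample.int(config$genome_len - len - 1L, 1L)
      ir <- IRanges::IRanges(st + 1L, st + len)
      if (length(IRanges::findOverlaps(ir, occupied)) > 0) next
      occupied <- c(occupied, ir)
      out[[length(out) + 1L]] <- c(st, st + len,
                                   sample(c(1L, 2L), 1L))
    }
    out
  })
  for (k in seq_along(rand)) {
    add_gene(sprintf("gene_rand%02d", k), rand[[k]][1], rand[[k]][2],
             c("+", "-")[rand[[k]][3]])
  }
  gene_gr <- if (length(genes)) do.call(c, genes) else GenomicRanges::GRanges()
  exon_gr <- if (length(exons)) do.call(c, exons) else GenomicRanges::GRanges()
  if (!is.null(gff3) && length(gene_gr) > 0) {
    gene_gr$type <- "gene"; exon_gr$type <- "exon"
    all <- c(gene_gr, exon_gr)
    rtracklayer::export(all, gff3, format = "GFF3")
  }
  annotation_set(genes = gene_gr, exons = exon_gr)
}
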