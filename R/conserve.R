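# Cross-genome miRNA homolog search. Annotation of a homolog requires
# conservation of BOTH duplex arms; the connecting (loop) sequence is
# unconstrained, which matches the observation that arm sequences are under
# structural selection while loops diverge freely. Arm matching is ungapped
# with a small per-arm mismatch budget; canonical pairs are Watson-Crick
# plus G:U wobble.

match_with_mm <- function(pattern, subject, max_mm) {
  m <- Biostrings::matchPattern(pattern, subject, max.mismatch = max_mm,
                                fixed = TRUE)
  if (length(m) == 0) {
    return(data.table::data.table(start = integer(0), nm = integer(0)))
  }
  pat <- strsplit(pattern, "")[[1]]
  nm <- vapply(as.character(m), function(f) {
    sum(strsplit(f, "")[[1]] != pat)
  }, 1L, USE.NAMES = FALSE)
  data.table::data.table(start = BiocGenerics::start(m) - 1L, nm = nm)
}

#' Search a genome for miRNA duplex homologs
#'
#' Finds loci where each arm matches with at most `max_mm_per_arm`
#' mismatches (ungapped), in the correct relative orientation (5p upstream
#' of 3p on the locus strand) with an inter-arm span of at most `max_span`.
#' When hits overlap, the hit with fewest total mismatches is kept (ties:
#' 5'-most).
#'
#' @param mir5p_seq,mir3p_seq mature arm sequences (DNA or RNA).
#' @param genome named character vector of target contigs.
#' @param max_mm_per_arm per-arm mismatch budget.
#' @param max_span maximum locus span in bp.
#' @return `data.table(contig, start, end, strand, start5, end5, start3,
#'   end3, mm5, mm3)`; 0-based half-open coordinates on the target genome.
#' @export
search_arm_homologs <- function(mir5p_seq, mir3p_seq, genome,
                                max_mm_per_arm = 2L, max_span = 400L) {
  a5 <- toupper(rna_to_dna(mir5p_seq)); a3 <- toupper(rna_to_dna(mir3p_seq))
  l5 <- nchar(a5); l3 <- nchar(a3)
  out <- list()
  for (ctg in names(genome)) {
    subj <- Biostrings::DNAString(genome[[ctg]])
    for (str in c("+", "-")) {
      h5 <- match_with_mm(if (str == "+") a5 else dna_revcomp(a5), subj,
                          max_mm_per_arm)
      h3 <- match_with_mm(if (str == "+") a3 else dna_revcomp(a3), subj,
                          max_mm_per_arm)
      if (nrow(h5) == 0 || nrow(h3) == 0) next
      cmb <- data.table::CJ(i5 = seq_len(nrow(h5)), i3 = seq_len(nrow(h3)))
      p5 <- h5$start[cmb$i5]; p3 <- h3$start[cmb$i3]
      if (str == "+") {
        ok <- p3 >= p5 + l5 & (p3 + l3 - p5) <= max_span
      } else {
        ok <- p5 >= p3 + l3 & (p5 + l5 - p3) <= max_span
      }
      if (!any(ok)) next
      p5 <- p5[ok]; p3 <- p3[ok]
      dt <- data.table::data.table(
        contig = ctg,
        start = pmin(p5, p3),
        end = pmax(p5 + l5, p3 + l3),
        strand = str,
        start5 = p5, end5 = p5 + l5,
        start3 = p3, end3 = p3 + l3,
        mm5 = h5$nm[cmb$i5][ok], mm3 = h3$nm[cmb$i3][ok])
      out[[length(out) + 1L]] <- dt
    }
  }
  res <- data.table::rbindlist(out)
  if (nrow(res) == 0) {
    return(data.table::data.table(contig = character(0), start = integer(0),
                                  end = integer(0), strand = character(0),
                                  start5 = integer(0), end5 = integer(0),
                                  start3 = integer(0), end3 = integer(0),
                                  mm5 = integer(0), mm3 = integer(0)))
  }
  res[, total_mm := mm5 + mm3]
  data.table::setorder(res, contig, total_mm, start)
  # overlapping hits: keep the fewest-mismatch (then 5'-most) one. Strand is
  # ignored here because a hairpin's reverse complement is itself close to a
  # valid arm arrangement, which would otherwise duplicate every locus.
  keep <- rep(TRUE, nrow(res))
  gr <- granges0(res$contig, res$start, res$end, res$strand)
  ov <- GenomicRanges::findOverlaps(gr, ignore.strand = TRUE,
                                    drop.self = TRUE)
  if (length(ov) > 0) {
    q <- S4Vectors::queryHits(ov); s <- S4Vectors::subjectHits(ov)
    drop <- unique(q[q > s])       # rows are already ranked best-first
    keep[drop] <- FALSE
  }
  res <- res[keep]
  res[, total_mm := NULL]
  res[]
}

#' Verify a homolog hit by folding (and optionally by expression)
#'
#' `verified_fold` is TRUE iff the locus (plus flanks) folds into a single
#' stem-loop in which the two arm regions pair with each other.
#'
#' @param hit one row of [search_arm_homologs()] output.
#' @param genome the target genome.
#' @param cfg a [fold_config()].
#' @param profile optional target small RNA `read_profile`-like placements
#'   `data.table(contig, start, end, strand)`; when given, `expressed` is
#'   set to whether at least `min_reads` reads fall inside the arms.
#' @param min_reads expression threshold.
#' @return the hit as a one-row data.table with `verified_fold` and
#'   `expressed` (NA when no profile was supplied) added.
#' @export
verify_homolog <- function(hit, genome, cfg = fold_config(), profile = NULL,
                           min_reads = 10L) {
  ctg <- genome[[hit$contig]]
  ws <- max(0L, hit$start - cfg$flank)
  we <- min(nchar(ctg), hit$end + cfg$flank)
  seq <- substring(ctg, ws + 1L, we)
  if (hit$strand == "-") seq <- dna_revcomp(seq)
  fold <- fold_cluster(seq, cfg)
  # arm intervals in window-local transcript orientation (1-based)
  loc <- function(s, e) {
    if (hit$strand == "+") c(s - ws + 1L, e - ws) else c(we - e + 1L, we - s)
  }
  i5 <- loc(hit$start5, hit$end5); i3 <- loc(hit$start3, hit$end3)
  pt <- pair_table(fold$structure)
  idx5 <- i5[1]:i5[2]
  into3 <- !is.na(pt[idx5]) & pt[idx5] >= i3[1] & pt[idx5] <= i3[2]
  verified <- mean(into3) >= 0.5 &&
    single_stem_loop(pt, min(idx5), max(i3[1]:i3[2]))
  expressed <- NA
  if (!is.null(profile)) {
    inarm <- profile$contig == hit$contig & profile$strand == hit$strand &
      ((profile$start >= hit$start5 - 2L & profile$end <= hit$end5 + 2L) |
         (profile$start >= hit$start3 - 2L & profile$end <= hit$end3 + 2L))
    expressed <- sum(inarm) >= min_reads
  }
  out <- data.table::as.data.table(hit)
  out$verified_fold <- verified
  out$expressed <- expressed
  out
}

#' Classify duplex substitutions between a reference miRNA and a homolog
#'
#' For each differing arm position (ungapped 1:1 alignment): `compensatory`
#' when the position is paired in both structures and pairing remains
#' canonical (Watson-Crick or G:U) in the homolog; `bulge_located` when the
#' position is unpaired in the reference structure; `pairing_disrupting`
#' when it is paired in the reference but unpaired or non-canonical in the
#' homolog.
#'
#' @param ref,hom lists with `seq5`, `seq3` (arm RNA/DNA sequences),
#'   `structure` (precursor dot-bracket), `arm5`, `arm3` (1-based inclusive
#'   arm intervals on the precursor) and `precursor` (sequence).
#' @return `data.table(arm, position, ref_base, hom_base, ref_paired,
#'   class)`, one row per differing duplex position.
#' @export
classify_duplex_substitutions <- function(ref, hom) {
  if (nchar(ref$seq5) != nchar(hom$seq5) ||
      nchar(ref$seq3) != nchar(hom$seq3)) {
    stop("gapped arm alignments are not supported (arm lengths differ)")
  }
  pt_ref <- pair_table(ref$structure)
  pt_hom <- pair_table(hom$structure)
  ref_pre <- strsplit(toupper(dna_to_rna(ref$precursor)), "")[[1]]
  hom_pre <- strsplit(toupper(dna_to_rna(hom$precursor)), "")[[1]]
  rows <- list()
  for (arm in c("5p", "3p")) {
    rint <- if (arm == "5p") ref$arm5 else ref$arm3
    hint <- if (arm == "5p") hom$arm5 else hom$arm3
    for (k in 0:(rint[2] - rint[1])) {
      ri <- rint[1] + k; hi <- hint[1] + k
      rb <- ref_pre[ri]; hb <- hom_pre[hi]
      if (rb == hb) next
      if (is.na(pt_ref[ri])) {
        cls <- "bulge_located"
      } else if (!is.na(pt_hom[hi]) &&
                 is_canonical_pair(hb, hom_pre[pt_hom[hi]])) {
        cls <- "compensatory"
      } else {
        cls <- "pairing_disrupting"
      }
      rows[[length(rows) + 1L]] <- data.table::data.table(
        arm = arm, position = k + 1L, ref_base = rb, hom_base = hb,
        ref_paired = !is.na(pt_ref[ri]), class = cls)
    }
  }
  if (length(rows) == 0) {
    return(data.table::data.table(arm = character(0), position = integer(0),
                                  ref_base = character(0),
                                  hom_base = character(0),
                                  ref_paired = logical(0),
                                  class = character(0)))
  }
  data.table::rbindlist(rows)
}
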