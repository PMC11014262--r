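# Annotation-based exclusion, genomic-context classification and
# exact-duplex paralog search. ncRNA and transposon annotations are
# produced upstream (covariance-model and translated-alignment searches)
# and consumed here as GFF3/BED files.

#' Read annotation files into an annotation set
#'
#' @param gff3 path to a GFF3 with gene models (`gene`, `exon`) and ncRNA
#'   features (type recorded in the `type` column or `ncRNA_class`
#'   attribute); optional.
#' @param transposon_bed path to a BED file of transposon intervals;
#'   optional.
#' @return an `annotation_set` list of GRanges: `genes`, `exons`, `ncrna`
#'   (with `class` metadata), `transposons`.
#' @export
read_annotations <- function(gff3 = NULL, transposon_bed = NULL) {
  genes <- exons <- ncrna <- transposons <- GenomicRanges::GRanges()
  if (!is.null(gff3)) {
    g <- rtracklayer::import(gff3)
    ty <- as.character(g$type)
    genes <- g[ty == "gene"]
    exons <- g[ty == "exon"]
    nc_types <- c("tRNA", "rRNA", "snoRNA", "snRNA", "SRP_RNA", "RNase_P_RNA",
                  "ncRNA")
    ncrna <- g[ty %in% nc_types]
    if (length(ncrna) > 0) {
      cls <- ty[ty %in% nc_types]
      if ("ncRNA_class" %in% names(S4Vectors::mcols(ncrna))) {
        cc <- ncrna$ncRNA_class
        cls[!is.na(cc)] <- cc[!is.na(cc)]
      }
      ncrna$class <- cls
    }
  }
  if (!is.null(transposon_bed)) {
    transposons <- rtracklayer::import(transposon_bed, format = "BED")
  }
  structure(list(genes = genes, exons = exons, ncrna = ncrna,
                 transposons = transposons),
            class = "annotation_set")
}

#' Build an annotation set from GRanges directly
#' @param genes,exons,ncrna,transposons GRanges (ncRNA needs a `class`
#'   metadata column).
#' @return an `annotation_set`.
#' @export
annotation_set <- function(genes = GenomicRanges::GRanges(),
                           exons = GenomicRanges::GRanges(),
                           ncrna = GenomicRanges::GRanges(),
                           transposons = GenomicRanges::GRanges()) {
  structure(list(genes = genes, exons = exons, ncrna = ncrna,
                 transposons = transposons), class = "annotation_set")
}

check_coordinate_space <- function(cand_gr, ann) {
  ann_contigs <- unique(unlist(lapply(ann, function(g) {
    as.character(unique(GenomicRanges::seqnames(g)))
  })))
  if (length(ann_contigs) == 0) return(invisible(TRUE))
  cand_contigs <- unique(as.character(GenomicRanges::seqnames(cand_gr)))
  if (length(cand_contigs) > 0 && !any(cand_contigs %in% ann_contigs)) {
    stop("coordinate-space mismatch: candidate contigs (",
         paste(cand_contigs, collapse = ","),
         ") are absent from the annotation contigs")
  }
  invisible(TRUE)
}

#' Exclude candidates derived from structured ncRNAs
#'
#' A candidate whose precursor overlaps an ncRNA interval by at least
#' `min_overlap_frac` of the precursor length is rejected (criterion:
#' miRNAs must not derive from other structured ncRNAs). Transposon overlap
#' is flagged or rejected according to `transposon_action`.
#'
#' @param candidates GRanges of candidate precursors (names = candidate ids).
#' @param ann an `annotation_set`.
#' @param min_overlap_frac minimum precursor overlap fraction.
#' @param transposon_action `"flag"` (default) or `"reject"`.
#' @return list with `kept` and `rejected` GRanges (rejection reason in
#'   `$reason`) and a logical `transposon_flag` per kept candidate.
#' @export
exclude_structured_overlap <- function(candidates, ann,
                                       min_overlap_frac = 0.5,
                                       transposon_action = c("flag", "reject")) {
  transposon_action <- match.arg(transposon_action)
  check_coordinate_space(candidates, ann)
  n <- length(candidates)
  reject <- rep(FALSE, n)
  reason <- rep(NA_character_, n)
  overlap_frac <- function(subject) {
    frac <- rep(0, n)
    cls <- rep(NA_character_, n)
    if (length(subject) == 0 || n == 0) return(list(frac = frac, cls = cls))
    ov <- GenomicRanges::findOverlaps(candidates, subject,
                                      ignore.strand = TRUE)
    if (length(ov) > 0) {
      q <- S4Vectors::queryHits(ov); s <- S4Vectors::subjectHits(ov)
      w <- GenomicRanges::width(IRanges::pintersect(
        GenomicRanges::ranges(candidates)[q],
        GenomicRanges::ranges(subject)[s]))
      f <- w / GenomicRanges::width(candidates)[q]
      for (k in order(f)) {            # keep the largest fraction per query
        frac[q[k]] <- f[k]
        cls[q[k]] <- if (!is.null(subject$class)) subject$class[s[k]] else "ncRNA"
      }
    }
    list(frac = frac, cls = cls)
  }
  nc <- overlap_frac(ann$ncrna)
  hit_nc <- nc$frac >= min_overlap_frac
  reject[hit_nc] <- TRUE
  reason[hit_nc] <- nc$cls[hit_nc]
  te <- overlap_frac(ann$transposons)
  te_hit <- te$frac >= min_overlap_frac
  if (transposon_action == "reject") {
    new_rej <- te_hit & !reject
    reject[new_rej] <- TRUE
    reason[new_rej] <- "transposon"
  }
  rejected <- candidates[reject]
  if (length(rejected) > 0) rejected$reason <- reason[reject]
  kept <- candidates[!reject]
  list(kept = kept, rejected = rejected,
       transposon_flag = te_hit[!reject])
}

#' Classify the genomic context of a candidate
#'
#' Precedence `exonic_sense > exonic_antisense > intronic > intergenic`,
#' decided by the candidate's strand relative to the overlapped gene; the
#' majority-overlap feature is reported.
#'
#' @param candidate a length-1 GRanges.
#' @param ann an `annotation_set` (or GRanges of genes).
#' @return a `context_label` list (`label`, `feature_ids`).
#' @export
classify_context <- function(candidate, ann) {
  genes <- if (inherits(ann, "annotation_set")) ann$genes else ann
  exons <- if (inherits(ann, "annotation_set")) ann$exons else GenomicRanges::GRanges()
  lab <- function(label, ids = character(0)) {
    structure(list(label = label, feature_ids = ids), class = "context_label")
  }
  pick_major <- function(subject) {
    ov <- GenomicRanges::findOverlaps(candidate, subject, ignore.strand = TRUE)
    if (length(ov) == 0) return(NULL)
    s <- S4Vectors::subjectHits(ov)
    w <- GenomicRanges::width(IRanges::pintersect(
      GenomicRanges::ranges(candidate)[S4Vectors::queryHits(ov)],
      GenomicRanges::ranges(subject)[s]))
    s[which.max(w)]
  }
  feature_id <- function(gr, i) {
    id <- if (!is.null(gr$ID)) gr$ID[i] else if (!is.null(gr$Name)) gr$Name[i]
    else as.character(i)
    as.character(id)
  }
  cand_strand <- as.character(GenomicRanges::strand(candidate))
  if (length(exons) > 0) {
    same <- exons[as.character(GenomicRanges::strand(exons)) == cand_strand]
    anti <- exons[as.character(GenomicRanges::strand(exons)) != cand_strand]
    i <- pick_major(same)
    if (!is.null(i)) return(lab("exonic_sense", feature_id(same, i)))
    i <- pick_major(anti)
    if (!is.null(i)) return(lab("exonic_antisense", feature_id(anti, i)))
  }
  if (length(genes) > 0) {
    i <- pick_major(genes)
    if (!is.null(i)) return(lab("intronic", feature_id(genes, i)))
  }
  lab("intergenic")
}

# exact occurrences (0-based starts) of pattern on a single contig string
exact_starts <- function(pattern, subject_dna) {
  m <- Biostrings::matchPattern(pattern, subject_dna)
  BiocGenerics::start(m) - 1L
}

#' Find paralogs carrying the exact same miRNA duplex
#'
#' Reports every genomic locus where both arm sequences occur exactly, with
#' mir-5p upstream of mir-3p on the locus strand and the locus span at most
#' `max_span`; loci are deduplicated by interval.
#'
#' @param genome named character vector of contigs.
#' @param mir5p_seq,mir3p_seq mature arm sequences (DNA or RNA, 18-25 nt).
#' @param max_span maximum locus span in bp.
#' @return `data.table(contig, start, end, strand, start5, end5, start3,
#'   end3)` with 0-based half-open genome coordinates.
#' @export
find_paralogs <- function(genome, mir5p_seq, mir3p_seq, max_span = 400L) {
  a5 <- toupper(rna_to_dna(mir5p_seq)); a3 <- toupper(rna_to_dna(mir3p_seq))
  stopifnot(nchar(a5) >= 18, nchar(a5) <= 25, nchar(a3) >= 18, nchar(a3) <= 25)
  l5 <- nchar(a5); l3 <- nchar(a3)
  out <- list()
  for (ctg in names(genome)) {
    subj <- Biostrings::DNAString(genome[[ctg]])
    clen <- length(subj)
    for (str in c("+", "-")) {
      if (str == "+") {
        s5 <- exact_starts(a5, subj); s3 <- exact_starts(a3, subj)
      } else {
        # on the minus strand, search the reverse complements on the
        # forward sequence; "upstream" means a higher forward coordinate
        s5 <- exact_starts(dna_revcomp(a5), subj)
        s3 <- exact_starts(dna_revcomp(a3), subj)
      }
      if (length(s5) == 0 || length(s3) == 0) next
      cmb <- data.table::CJ(p5 = s5, p3 = s3)
      if (str == "+") {
        cmb <- cmb[p3 >= p5 + l5 & (p3 + l3 - p5) <= max_span]
        if (nrow(cmb) == 0) next
        dt <- data.table::data.table(contig = ctg, start = cmb$p5,
                                     end = cmb$p3 + l3, strand = "+",
                                     start5 = cmb$p5, end5 = cmb$p5 + l5,
                                     start3 = cmb$p3, end3 = cmb$p3 + l3)
      } else {
        cmb <- cmb[p5 >= p3 + l3 & (p5 + l5 - p3) <= max_span]
        if (nrow(cmb) == 0) next
        dt <- data.table::data.table(contig = ctg, start = cmb$p3,
                                     end = cmb$p5 + l5, strand = "-",
                                     start5 = cmb$p5, end5 = cmb$p5 + l5,
                                     start3 = cmb$p3, end3 = cmb$p3 + l3)
      }
      out[[length(out) + 1L]] <- dt
    }
  }
  res <- data.table::rbindlist(out)
  if (nrow(res) == 0) {
    return(data.table::data.table(contig = character(0), start = integer(0),
                                  end = integer(0), strand = character(0),
                                  start5 = integer(0), end5 = integer(0),
                                  start3 = integer(0), end3 = integer(0)))
  }
  unique(res, by = c("contig", "start", "end", "strand"))
}
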