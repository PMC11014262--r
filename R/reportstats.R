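# Characterization statistics, synteny-block merging, expression matrices
# and standard-format output writing. Coordinate conventions are handled by
# one conversion utility (granges0): GFF3 is 1-based inclusive, BED is
# 0-based half-open, everything internal is 0-based half-open.

#' Characterize a set of annotated miRNAs
#'
#' Emits (a) a positional nucleotide-composition table of the mature
#' sequences including first-nucleotide frequencies (amoebozoan miRNAs show
#' a 5' U preference), (b) AT fraction of the mature miRNAs versus the
#' intergenic genome space (gene-model complement), (c) precursor length
#' summary, (d) the read-length histogram with its modal length.
#'
#' @param mature_seqs character vector of mature miRNA sequences.
#' @param precursor_lens integer vector of precursor lengths.
#' @param genome named character vector of contigs.
#' @param genes GRanges of gene models (may be empty).
#' @param read_lengths integer vector of library read lengths (post-trim).
#' @return a `mirna_characterization` list.
#' @export
characterization_summary <- function(mature_seqs, precursor_lens, genome,
                                     genes = GenomicRanges::GRanges(),
                                     read_lengths = integer(0)) {
  if (length(mature_seqs) == 0) {
    return(structure(list(empty = TRUE), class = "mirna_characterization"))
  }
  rna <- toupper(dna_to_rna(mature_seqs))
  maxlen <- max(nchar(rna))
  mat <- matrix(0, nrow = 4, ncol = maxlen,
                dimnames = list(c("A", "C", "G", "U"), NULL))
  chars <- strsplit(rna, "")
  for (s in chars) {
    for (i in seq_along(s)) mat[s[i], i] <- mat[s[i], i] + 1
  }
  n_obs <- colSums(mat)
  comp <- sweep(mat, 2, pmax(n_obs, 1), "/")
  first_nt <- comp[, 1]

  mature_at <- at_fraction(rna_to_dna(rna))
  genome_gr <- granges0(names(genome), rep(0L, length(genome)),
                        nchar(genome), "+")
  intergenic <- GenomicRanges::setdiff(genome_gr,
                                       GenomicRanges::reduce(genes,
                                                             ignore.strand = TRUE),
                                       ignore.strand = TRUE)
  ig_seqs <- vapply(seq_along(intergenic), function(i) {
    ctg <- as.character(GenomicRanges::seqnames(intergenic)[i])
    substring(genome[[ctg]], GenomicRanges::start(intergenic)[i],
              GenomicRanges::end(intergenic)[i])
  }, "")
  intergenic_at <- if (length(ig_seqs)) at_fraction(paste(ig_seqs, collapse = "")) else NA_real_

  rl <- NULL
  modal_len <- NA_integer_
  if (length(read_lengths) > 0) {
    rl <- table(read_lengths)
    modal_len <- as.integer(names(rl)[which.max(rl)])
  }
  structure(list(
    empty = FALSE,
    n_sequences = length(rna),
    composition = comp,
    first_nt_freq = first_nt,
    mature_at_fraction = mature_at,
    intergenic_at_fraction = intergenic_at,
    precursor_len = c(min = min(precursor_lens),
                      median = median(precursor_lens),
                      max = max(precursor_lens)),
    precursor_lens = precursor_lens,
    read_length_hist = rl,
    modal_read_length = modal_len
  ), class = "mirna_characterization")
}

interval_distance <- function(s1, e1, s2, e2) {
  pmax(s2 - e1, s1 - e2, 0L)
}

#' Merge nearby synteny blocks
#'
#' Blocks whose intervals on genome A *and* genome B are each within `gap`
#' bp (and share contig pair and orientation) are merged transitively;
#' merging is idempotent and order-invariant.
#'
#' @param blocks `data.frame(chrA, startA, endA, chrB, startB, endB,
#'   orientation)` with 0-based half-open intervals; `orientation` in
#'   `{"same", "inverted"}`.
#' @param gap maximum merge distance in bp (default 5000).
#' @return merged block table of the same shape.
#' @export
merge_synteny_blocks <- function(blocks, gap = 5000L) {
  dt <- data.table::as.data.table(blocks)
  if (nrow(dt) == 0) return(dt[])
  merged <- list()
  for (key in split(seq_len(nrow(dt)),
                    paste(dt$chrA, dt$chrB, dt$orientation))) {
    g <- dt[key]
    data.table::setorder(g, startA, startB)
    repeat {
      n <- nrow(g)
      if (n <= 1) break
      changed <- FALSE
      i <- 1L
      while (i < nrow(g)) {
        dA <- interval_distance(g$startA[i], g$endA[i],
                                g$startA[i + 1L], g$endA[i + 1L])
        dB <- interval_distance(g$startB[i], g$endB[i],
                                g$startB[i + 1L], g$endB[i + 1L])
        if (dA <= gap && dB <= gap) {
          g$startA[i] <- min(g$startA[i], g$startA[i + 1L])
          g$endA[i] <- max(g$endA[i], g$endA[i + 1L])
          g$startB[i] <- min(g$startB[i], g$startB[i + 1L])
          g$endB[i] <- max(g$endB[i], g$endB[i + 1L])
          g <- g[-(i + 1L)]
          changed <- TRUE
        } else {
          i <- i + 1L
        }
      }
      if (!changed) break
    }
    merged[[length(merged) + 1L]] <- g
  }
  out <- data.table::rbindlist(merged)
  data.table::setorder(out, chrA, startA)
  out[]
}

#' Intersect miRNA loci with merged synteny blocks
#'
#' @param merged merged block table from [merge_synteny_blocks()].
#' @param mirna_loci `data.frame(mirna_id, genome ("A"/"B"), contig, start,
#'   end)` with 0-based half-open coordinates.
#' @return the block table with a `mirnas` list-column of contained ids.
#' @export
intersect_mirnas <- function(merged, mirna_loci) {
  dt <- data.table::as.data.table(merged)
  ml <- data.table::as.data.table(mirna_loci)
  dt[, mirnas := lapply(seq_len(nrow(dt)), function(i) {
    inA <- ml$genome == "A" & ml$contig == dt$chrA[i] &
      ml$start < dt$endA[i] & ml$end > dt$startA[i]
    inB <- ml$genome == "B" & ml$contig == dt$chrB[i] &
      ml$start < dt$endB[i] & ml$end > dt$startB[i]
    ml$mirna_id[inA | inB]
  })]
  dt[]
}

#' Weighted expression matrix over called miRNA arms
#'
#' Per-miRNA counts are the summed placement weights within the called arm
#' intervals (plus `slack`); normalization divides by each sample's total
#' assigned counts; the naive log2 fold-change between two conditions is
#' computed on normalized means with a pseudocount of 1. No significance
#' testing is performed here (differential-expression modelling belongs to
#' dedicated tools).
#'
#' @param arm_intervals `data.frame(mirna_id, contig, start, end, strand)`
#'   of called arm intervals (0-based half-open genome coordinates; usually
#'   two rows per miRNA).
#' @param placements weighted placements with a `replicate` column naming
#'   the sample.
#' @param samples `data.frame(sample, condition)`.
#' @param slack per-side extension in nt.
#' @return list with `counts`, `normalized` (matrices miRNA x sample) and,
#'   when exactly two conditions are present, `log2fc`.
#' @export
expression_matrix <- function(arm_intervals, placements, samples,
                              slack = 2L) {
  ai <- data.table::as.data.table(arm_intervals)
  ids <- unique(ai$mirna_id)
  smp <- unique(samples$sample)
  counts <- matrix(0, nrow = length(ids), ncol = length(smp),
                   dimnames = list(ids, smp))
  for (k in seq_len(nrow(ai))) {
    hit <- placements$contig == ai$contig[k] &
      placements$strand == ai$strand[k] &
      placements$start >= ai$start[k] - slack &
      placements$end <= ai$end[k] + slack
    if (!any(hit)) next
    tw <- tapply(placements$weight[hit], placements$replicate[hit], sum)
    use <- intersect(names(tw), smp)
    counts[ai$mirna_id[k], use] <- counts[ai$mirna_id[k], use] + tw[use]
  }
  tot <- colSums(counts)
  if (any(tot == 0)) {
    stop("undefined normalization: sample(s) with zero assigned counts: ",
         paste(smp[tot == 0], collapse = ", "))
  }
  norm <- sweep(counts, 2, tot / mean(tot), "/")
  out <- list(counts = counts, normalized = norm)
  conds <- unique(samples$condition)
  if (length(conds) == 2) {
    m <- vapply(conds, function(cc) {
      rowMeans(norm[, samples$sample[samples$condition == cc], drop = FALSE])
    }, numeric(length(ids)))
    out$log2fc <- data.table::data.table(
      mirna_id = ids,
      log2fc = log2((m[, 2] + 1) / (m[, 1] + 1)))
    data.table::setattr(out$log2fc, "contrast",
                        paste(conds[2], "vs", conds[1], sep = "_"))
  }
  out
}

#' Write the discovery outputs in standard formats
#'
#' Writes miRNA GFF3 (precursor + mature features, 1-based inclusive), BED6
#' (0-based half-open), mature and precursor FASTA, dot-bracket text
#' mirroring bracket-notation structure renderings, the per-predicate
#' criteria report as TSV and JSON, and a run-manifest JSON with config and
#' seeds.
#'
#' @param dir output directory.
#' @param results a result list from [discover_mirnas()].
#' @param seed the seed recorded in the manifest.
#' @param config_list any configuration lists to record in the manifest.
#' @return named vector of written paths.
#' @export
write_outputs <- function(dir, results, seed = NA_integer_,
                          config_list = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  bona <- results$candidates[results$candidates$bona_fide %in% TRUE, ]
  paths <- c()
  feats <- list()
  mature <- character(0); prec <- character(0); brackets <- character(0)
  for (i in seq_len(nrow(bona))) {
    id <- bona$cluster_id[i]
    det <- results$details[[id]]
    pre_gr <- granges0(bona$contig[i], bona$precursor_start[i],
                       bona$precursor_end[i], bona$strand[i])
    pre_gr$type <- "miRNA_primary_transcript"; pre_gr$ID <- id
    arm_gr <- granges0(rep(bona$contig[i], 2),
                       c(bona$arm5p_start[i], bona$arm3p_start[i]),
                       c(bona$arm5p_end[i], bona$arm3p_end[i]),
                       rep(bona$strand[i], 2))
    arm_gr$type <- "miRNA"
    arm_gr$ID <- paste0(id, c("-5p", "-3p"))
    feats[[length(feats) + 1L]] <- c(pre_gr, arm_gr)
    mature[paste0(id, "-5p")] <- det$call$modal_seq_5p
    mature[paste0(id, "-3p")] <- det$call$modal_seq_3p
    prec[id] <- det$precursor_seq
    brackets <- c(brackets, paste0(">", id), det$precursor_seq,
                  det$precursor_structure)
  }
  gff <- file.path(dir, "mirnas.gff3")
  bed <- file.path(dir, "mirnas.bed")
  if (length(feats) > 0) {
    all_gr <- do.call(c, feats)
    rtracklayer::export(all_gr, gff, format = "GFF3")
    pre_only <- all_gr[all_gr$type == "miRNA_primary_transcript"]
    names(pre_only) <- pre_only$ID
    rtracklayer::export(pre_only, bed, format = "BED")
    Biostrings::writeXStringSet(
      Biostrings::RNAStringSet(dna_to_rna(mature)),
      file.path(dir, "mature.fa"))
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(rna_to_dna(prec)),
                                file.path(dir, "precursors.fa"))
    writeLines(brackets, file.path(dir, "structures.dotbracket.txt"))
  } else {
    file.create(gff); file.create(bed)
  }
  crit_tsv <- file.path(dir, "criteria_report.tsv")
  crit_json <- file.path(dir, "criteria_report.json")
  rep_dt <- results$criteria_report
  write.table(rep_dt, crit_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(rep_dt, crit_json, auto_unbox = TRUE, digits = NA)
  manifest <- file.path(dir, "run_manifest.json")
  jsonlite::write_json(list(seed = seed,
                            package_version = as.character(
                              utils::packageVersion("mircurate")),
                            config = config_list),
                       manifest, auto_unbox = TRUE, digits = NA,
                       null = "null")
  c(gff3 = gff, bed = bed, criteria_tsv = crit_tsv,
    criteria_json = crit_json, manifest = manifest)
}
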