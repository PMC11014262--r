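# Read preprocessing and genome alignment.
#
# Alignment is an exhaustive ungapped search (exact matching via a
# Biostrings preprocessed dictionary, a per-read scan for the 1-mismatch
# stratum), which makes the <=1-mismatch contract exact for 18-35 nt reads.
# A read's placements are ranked 0-mismatch before 1-mismatch and only the
# best stratum is kept.

#' Alignment configuration
#'
#' @param max_mismatch maximum mismatches per placement (0 or 1).
#' @param min_len,max_len retained read length range after trimming.
#' @param adapter 3' adapter sequence (empty string skips trimming).
#' @return an `align_config` list.
#' @export
align_config <- function(max_mismatch = 1L, min_len = 18L, max_len = 35L,
                         adapter = "TGGAATTCTCGGGTGCCAAGG") {
  stopifnot(max_mismatch %in% c(0L, 1L), min_len <= max_len)
  structure(list(max_mismatch = as.integer(max_mismatch),
                 min_len = as.integer(min_len), max_len = as.integer(max_len),
                 adapter = toupper(adapter)),
            class = "align_config")
}

#' Build a read table from per-replicate sequence sets
#'
#' @param seqs_by_rep named list of character vectors (or DNAStringSets) of
#'   read sequences, one element per replicate.
#' @return `data.table(read_id, seq, replicate)`.
#' @export
read_records <- function(seqs_by_rep) {
  reps <- names(seqs_by_rep) %||% paste0("rep", seq_along(seqs_by_rep))
  data.table::rbindlist(lapply(seq_along(seqs_by_rep), function(i) {
    s <- seqs_by_rep[[i]]
    if (inherits(s, "XStringSet")) s <- as.character(s)
    ids <- names(s) %||% paste0(reps[i], "_r", seq_along(s))
    data.table::data.table(read_id = ids, seq = toupper(unname(s)),
                           replicate = reps[i])
  }))
}

# leftmost occurrence of the >=8 nt adapter prefix allowing one mismatch;
# -1 where absent
adapter_positions <- function(seqs, adapter) {
  k <- min(8L, nchar(adapter))
  prefix <- substr(adapter, 1L, k)
  pats <- prefix
  ch <- strsplit(prefix, "")[[1]]
  for (i in seq_len(k)) {
    for (b in setdiff(c("A", "C", "G", "T"), ch[i])) {
      v <- ch; v[i] <- b
      pats <- c(pats, paste(v, collapse = ""))
    }
  }
  best <- rep(-1L, length(seqs))
  for (p in pats) {
    hit <- regexpr(p, seqs, fixed = TRUE)
    better <- hit > 0 & (best < 0 | hit < best)
    best[better] <- hit[better]
  }
  best
}

#' Trim adapters and select reads by length
#'
#' Removes the 3' adapter at its leftmost occurrence (exact or one-mismatch
#' match of the first 8 adapter nucleotides) and keeps reads whose trimmed
#' length lies within `[min_len, max_len]`.
#'
#' @param reads `data.table(read_id, seq, replicate)`.
#' @param cfg an [align_config()].
#' @return filtered read table; kept/discarded counts in attribute `stats`
#'   and a log message.
#' @export
preprocess_reads <- function(reads, cfg = align_config()) {
  reads <- data.table::copy(reads)
  n_in <- nrow(reads)
  if (n_in > 0 && nzchar(cfg$adapter)) {
    pos <- adapter_positions(reads$seq, cfg$adapter)
    trim <- pos > 0
    reads[trim, seq := substr(seq, 1L, pos[trim] - 1L)]
  }
  len <- nchar(reads$seq)
  keep <- len >= cfg$min_len & len <= cfg$max_len
  out <- reads[keep]
  stats <- c(input = n_in, kept = sum(keep), discarded = sum(!keep))
  message(sprintf("preprocess_reads: %d in, %d kept, %d outside %d-%d nt",
                  stats[1], stats[2], stats[3], cfg$min_len, cfg$max_len))
  data.table::setattr(out, "stats", stats)
  out
}

# --- alignment engine -------------------------------------------------------

# all placements of unique sequences on a genome (named character vector of
# contigs) with <= max_mm mismatches, best stratum only
align_unique_seqs <- function(seqs, genome, max_mm = 1L) {
  stopifnot(length(seqs) == length(unique(seqs)))
  empty <- data.table::data.table(seq = character(0), contig = character(0),
                                  start = integer(0), end = integer(0),
                                  strand = character(0),
                                  n_mismatch = integer(0))
  if (length(seqs) == 0L) return(empty)
  n_count <- nchar(seqs) - nchar(gsub("N", "", seqs, fixed = TRUE))
  searchable <- n_count == 0L
  subjects <- lapply(genome, Biostrings::DNAString)
  hits <- list(empty)
  widths <- nchar(seqs)
  for (w in unique(widths[searchable])) {
    sub <- seqs[searchable & widths == w]
    for (str in c("+", "-")) {
      pats <- if (str == "+") sub else dna_revcomp(sub)
      pd <- Biostrings::PDict(pats)
      for (ctg in names(genome)) {
        m <- Biostrings::matchPDict(pd, subjects[[ctg]])
        nh <- S4Vectors::elementNROWS(m)
        if (sum(nh) == 0) next
        ir <- unlist(m)
        hits[[length(hits) + 1L]] <- data.table::data.table(
          seq = rep(sub, nh),
          contig = ctg,
          start = BiocGenerics::start(ir) - 1L,
          end = BiocGenerics::end(ir),
          strand = str,
          n_mismatch = 0L
        )
      }
    }
  }
  exact <- data.table::rbindlist(hits)
  if (max_mm >= 1L) {
    need_mm <- setdiff(seqs[n_count <= max_mm], unique(exact$seq))
    mm_hits <- lapply(need_mm, function(s) {
      per <- list()
      for (str in c("+", "-")) {
        pat <- if (str == "+") s else dna_revcomp(s)
        for (ctg in names(genome)) {
          m <- Biostrings::matchPattern(pat, subjects[[ctg]],
                                        max.mismatch = max_mm, fixed = TRUE)
          if (length(m) == 0) next
          found <- as.character(m)
          nm <- vapply(found, function(f) {
            sum(strsplit(f, "")[[1]] != strsplit(pat, "")[[1]])
          }, 1L, USE.NAMES = FALSE)
          per[[length(per) + 1L]] <- data.table::data.table(
            seq = s, contig = ctg,
            start = BiocGenerics::start(m) - 1L,
            end = BiocGenerics::end(m), strand = str, n_mismatch = nm)
        }
      }
      data.table::rbindlist(per)
    })
    mm <- data.table::rbindlist(mm_hits)
    if (nrow(mm) > 0) {
      # best stratum within the mismatch-only set
      mm[, best := min(n_mismatch), by = seq]
      mm <- mm[n_mismatch == best][, best := NULL]
    }
    exact <- data.table::rbindlist(list(exact, mm))
  }
  exact
}

#' Remove reads matching contaminant genomes
#'
#' A read aligning to any contaminant genome within `max_mismatch` is
#' removed. Removal fractions are reported per contaminant.
#'
#' @param reads read table.
#' @param contaminants named character vector (or list) of contaminant
#'   genome sequences; may be empty.
#' @param cfg an [align_config()].
#' @return filtered read table with attribute `contaminant_fractions`.
#' @export
filter_contaminants <- function(reads, contaminants, cfg = align_config()) {
  if (length(contaminants) == 0L || nrow(reads) == 0L) {
    data.table::setattr(reads, "contaminant_fractions", numeric(0))
    return(reads)
  }
  cn <- names(contaminants) %||% paste0("contaminant", seq_along(contaminants))
  uniq <- unique(reads$seq)
  removed <- rep(FALSE, length(uniq))
  frac <- setNames(numeric(length(contaminants)), cn)
  for (i in seq_along(contaminants)) {
    g <- setNames(as.character(contaminants[i]), cn[i])
    h <- align_unique_seqs(uniq, g, max_mm = cfg$max_mismatch)
    bad <- uniq %in% unique(h$seq)
    frac[i] <- sum(reads$seq %in% uniq[bad]) / nrow(reads)
    removed <- removed | bad
  }
  out <- reads[!reads$seq %in% uniq[removed]]
  message(sprintf("filter_contaminants: removed %d/%d reads (%s)",
                  nrow(reads) - nrow(out), nrow(reads),
                  paste(sprintf("%s %.2f%%", cn, 100 * frac), collapse = ", ")))
  data.table::setattr(out, "contaminant_fractions", frac)
  out
}

#' Align reads to a genome
#'
#' Reports every ungapped placement on either strand with at most
#' `max_mismatch` mismatches; placements are ranked 0-mismatch before
#' 1-mismatch per read and only the best stratum is kept. Reads with more
#' `N` bases than `max_mismatch` are unalignable and counted.
#'
#' @param reads read table (`read_id`, `seq`, `replicate`).
#' @param genome named character vector of contig sequences.
#' @param cfg an [align_config()].
#' @return placements `data.table(read_id, replicate, seq, contig, start,
#'   end, strand, n_mismatch)` (0-based half-open) with attribute
#'   `n_unaligned`.
#' @export
align_reads <- function(reads, genome, cfg = align_config()) {
  if (is.null(names(genome))) names(genome) <- paste0("contig", seq_along(genome))
  uniq <- unique(reads$seq)
  hits <- align_unique_seqs(uniq, genome, max_mm = cfg$max_mismatch)
  pl <- merge(reads, hits, by = "seq", allow.cartesian = TRUE)
  aligned_ids <- unique(pl$read_id)
  n_unaligned <- nrow(reads) - length(aligned_ids)
  message(sprintf("align_reads: %d/%d reads placed (%d placements)",
                  length(aligned_ids), nrow(reads), nrow(pl)))
  data.table::setcolorder(pl, c("read_id", "replicate", "seq", "contig",
                                "start", "end", "strand", "n_mismatch"))
  data.table::setattr(pl, "n_unaligned", n_unaligned)
  pl
}

#' Fractional placement of multimapping reads
#'
#' Uniquely placed reads get weight 1. A multimapper's weight at placement
#' *i* is `(U_i + 0.5) / sum_j (U_j + 0.5)`, where `U_j` counts uniquely
#' placed read 5' ends within `window` bp of placement *j* on the same
#' contig; weights per read sum to 1 exactly.
#'
#' @param placements placements from [align_reads()].
#' @param window half-width in bp of the unique-read neighbourhood.
#' @return placements with a `weight` column.
#' @export
weight_multimappers <- function(placements, window = 50L) {
  pl <- data.table::copy(placements)
  if (nrow(pl) == 0) { pl[, weight := numeric(0)]; return(pl) }
  pl[, n_pl := .N, by = read_id]
  pl[, pos5 := ifelse(strand == "+", start, end - 1L)]
  uniq5 <- pl[n_pl == 1L, list(contig, pos5)]
  u_sorted <- split(uniq5$pos5, uniq5$contig)
  u_sorted <- lapply(u_sorted, sort)
  pl[, U := {
    su <- u_sorted[[contig[1]]]
    if (is.null(su)) rep(0L, .N)
    else findInterval(pos5 + window, su) - findInterval(pos5 - window - 1L, su)
  }, by = contig]
  pl[, weight := ifelse(n_pl == 1L, 1, NA_real_)]
  pl[n_pl > 1L, weight := (U + 0.5) / sum(U + 0.5), by = read_id]
  pl[, c("n_pl", "pos5", "U") := NULL]
  pl
}

#' Cluster read placements into candidate loci
#'
#' Same-strand placements within `merge_gap` bp of each other are merged
#' transitively; clusters whose weighted depth (summed over replicates)
#' falls below `min_weighted_depth` are dropped.
#'
#' @param placements weighted placements.
#' @param merge_gap maximum gap (bp) bridged when merging.
#' @param min_weighted_depth minimum summed placement weight per cluster.
#' @return list with `clusters` (`data.table(cluster_id, contig, start, end,
#'   strand, weighted_depth, n_reads)`) and `placements` (input with a
#'   `cluster_id` column; `NA` for reads outside retained clusters).
#' @export
call_clusters <- function(placements, merge_gap = 100L,
                          min_weighted_depth = 5.0) {
  pl <- data.table::copy(placements)
  if (nrow(pl) == 0) {
    return(list(clusters = data.table::data.table(), placements = pl))
  }
  gr <- granges0(pl$contig, pl$start, pl$end, pl$strand)
  red <- GenomicRanges::reduce(gr, min.gapwidth = merge_gap + 1L)
  ov <- GenomicRanges::findOverlaps(gr, red)
  pl[, cl_idx := NA_integer_]
  pl[S4Vectors::queryHits(ov), cl_idx := S4Vectors::subjectHits(ov)]
  cl <- pl[, list(weighted_depth = sum(weight), n_reads = .N), by = cl_idx]
  bed <- granges_to_bed0(red)
  cl <- cbind(bed[cl$cl_idx], cl)
  keep <- cl$weighted_depth >= min_weighted_depth
  cl <- cl[keep]
  data.table::setorder(cl, contig, start)
  cl[, cluster_id := sprintf("cl_%04d", seq_len(nrow(cl)))]
  pl <- merge(pl, cl[, list(cl_idx, cluster_id)], by = "cl_idx", all.x = TRUE)
  pl[, cl_idx := NULL]
  cl[, cl_idx := NULL]
  data.table::setcolorder(cl, c("cluster_id", "contig", "start", "end",
                                "strand", "weighted_depth", "n_reads"))
  list(clusters = cl[], placements = pl[])
}

#' Export placements or clusters as BED6
#'
#' Placement scores carry the fractional weight scaled by 1000 and rounded.
#'
#' @param x placements (with `weight`) or the `clusters` table.
#' @param path output path.
#' @export
export_bed6 <- function(x, path) {
  if ("weight" %in% names(x)) {
    dt <- data.table::data.table(x$contig, x$start, x$end, x$read_id,
                                 as.integer(round(x$weight * 1000)), x$strand)
  } else {
    dt <- data.table::data.table(x$contig, x$start, x$end, x$cluster_id,
                                 0L, x$strand)
  }
  write.table(dt, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
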