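# Per-cluster read profiling, hairpin detection and duplex analysis.
#
# Profiles are transcript-oriented: minus-strand clusters are profiled on
# the reverse complement, so "position 1" is always the 5' end of the
# presumptive precursor transcript and downstream coordinates can be read
# as precursor positions.

#' Build a zero-mismatch read profile over a cluster
#'
#' Only exact-match placements on the cluster strand that fall entirely
#' within the cluster extended by `flank` nt are counted. Per-replicate
#' coverage and 5'-end tracks are kept separate.
#'
#' @param placements weighted placements (from [weight_multimappers()]).
#' @param cluster one row of the cluster table from [call_clusters()].
#' @param genome named character vector of contigs.
#' @param flank context added on each side of the cluster.
#' @return a `read_profile` list, or one with `empty = TRUE` when the
#'   cluster has no exact-match reads.
#' @export
build_cluster_profile <- function(placements, cluster, genome, flank = 30L) {
  ctg_len <- nchar(genome[[cluster$contig]])
  ws <- max(0L, cluster$start - flank)
  we <- min(ctg_len, cluster$end + flank)
  L <- we - ws
  pl <- placements[placements$contig == cluster$contig &
                     placements$strand == cluster$strand &
                     placements$n_mismatch == 0L &
                     placements$start >= ws & placements$end <= we, ]
  reps <- sort(unique(placements$replicate))
  base <- list(cluster_id = cluster$cluster_id, contig = cluster$contig,
               window_start = ws, window_end = we, strand = cluster$strand,
               L = L, replicates = reps)
  if (nrow(pl) == 0) {
    return(structure(c(base, list(empty = TRUE)), class = "read_profile"))
  }
  if (cluster$strand == "+") {
    lstart <- pl$start - ws
  } else {
    lstart <- we - pl$end
  }
  len <- pl$end - pl$start
  cov <- matrix(0, nrow = L, ncol = length(reps),
                dimnames = list(NULL, reps))
  p5 <- matrix(0, nrow = L, ncol = length(reps),
               dimnames = list(NULL, reps))
  ri <- match(pl$replicate, reps)
  for (r in seq_along(reps)) {
    sel <- ri == r
    if (!any(sel)) next
    w <- pl$weight[sel]
    s1 <- lstart[sel] + 1L                       # 1-based read start
    agg <- rowsum(w, s1)
    p5[as.integer(rownames(agg)), r] <- agg[, 1]
    d <- numeric(L + 1L)
    d[as.integer(rownames(agg))] <- agg[, 1]
    agg_e <- rowsum(w, s1 + len[sel])            # position after read end
    d[as.integer(rownames(agg_e))] <- d[as.integer(rownames(agg_e))] - agg_e[, 1]
    cv <- cumsum(d)[seq_len(L)]
    cv[cv < 1e-9] <- 0                           # zap float residue
    cov[, r] <- cv
  }
  seq <- substring(genome[[cluster$contig]], ws + 1L, we)
  if (cluster$strand == "-") seq <- dna_revcomp(seq)
  reads <- data.table::data.table(read_id = pl$read_id,
                                  replicate = pl$replicate,
                                  lstart = lstart, len = len,
                                  seq = pl$seq, weight = pl$weight)
  structure(c(base, list(empty = FALSE, seq = seq, cov = cov, p5 = p5,
                         reads = reads, n_reads = nrow(reads))),
            class = "read_profile")
}

#' Fold the profiled cluster sequence
#'
#' @param profile a `read_profile`.
#' @param cfg a [fold_config()].
#' @return a `fold_result`.
#' @export
fold_profile <- function(profile, cfg = fold_config()) {
  fold_cluster(profile$seq, cfg)
}

# contiguous runs of pooled coverage > 0, ranked by total weighted coverage
coverage_blocks <- function(profile) {
  pooled <- rowSums(profile$cov)
  r <- rle(pooled > 0)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  if (!any(keep)) return(NULL)
  dt <- data.table::data.table(from = starts[keep], to = ends[keep])
  dt[, total := vapply(seq_len(.N), function(i) sum(pooled[from[i]:to[i]]),
                       1.0)]
  dt
}

#' Locate the hairpin containing the read evidence
#'
#' Returns the maximal stem-loop region containing the two highest-coverage
#' read blocks if, between the 5' block start and the 3' block end, the
#' structure contains exactly one terminal loop and no multiloop branching
#' and the blocks sit on opposite arms; otherwise `NULL`.
#'
#' @param fold a `fold_result` covering the profiled window.
#' @param profile the matching `read_profile`.
#' @return a `hairpin_region` list (`from`, `to`, `loop_i`, `loop_j`,
#'   1-based inclusive window positions) or `NULL`.
#' @export
find_hairpin <- function(fold, profile) {
  if (isTRUE(profile$empty)) return(NULL)
  stopifnot(nchar(fold$structure) == profile$L)
  blocks <- coverage_blocks(profile)
  if (is.null(blocks)) return(NULL)
  data.table::setorder(blocks, -total)
  top <- head(blocks, 2L)
  data.table::setorder(top, from)
  pt <- pair_table(fold$structure)
  if (nrow(top) == 2L) {
    from <- top$from[1]; to <- top$to[2]
  } else {
    partners <- pt[top$from[1]:top$to[1]]
    partners <- partners[!is.na(partners)]
    if (length(partners) == 0) return(NULL)
    from <- min(top$from[1], partners); to <- max(top$to[1], partners)
  }
  if (!single_stem_loop(pt, from, to)) return(NULL)
  loop <- terminal_loops(pt, from, to)[[1]]
  if (nrow(top) == 2L) {
    mid <- (top$from + top$to) / 2
    if (!(mid[1] <= loop[1] && mid[2] >= loop[2])) return(NULL)
  }
  # extend outward along the enclosing stem to the maximal stem-loop
  enclosing <- which(!is.na(pt) & seq_along(pt) < loop[1] & pt >= loop[2])
  if (length(enclosing) > 0) {
    from2 <- min(from, min(enclosing))
    to2 <- max(to, max(pt[enclosing]))
    if (single_stem_loop(pt, from2, to2)) { from <- from2; to <- to2 }
  }
  structure(list(from = from, to = to, loop_i = loop[1], loop_j = loop[2]),
            class = "hairpin_region")
}

duplex_rejection <- function(reason) {
  structure(list(reason = reason), class = "duplex_rejection")
}

#' Call the mir-5p/mir-3p duplex from mapped reads
#'
#' Each arm's interval starts at the modal weighted 5' end on its side of
#' the terminal loop (ties broken towards the 5'-most position) and extends
#' by the modal read length at that 5' position (length ties broken towards
#' shorter). Arms must lie on opposite sides of the loop; a side without
#' reads yields a `duplex_rejection` (criteria require both mapped arms).
#'
#' @param profile a `read_profile`.
#' @param hairpin a `hairpin_region` from [find_hairpin()].
#' @param fold the `fold_result` (used for validation only).
#' @return a `duplex_call` list (intervals are 0-based half-open window
#'   coordinates) or a `duplex_rejection`.
#' @export
call_duplex <- function(profile, hairpin, fold) {
  pooled <- rowSums(profile$p5)
  side_call <- function(lo, hi, label) {
    idx <- lo:hi
    if (sum(pooled[idx]) == 0) {
      return(duplex_rejection(paste0("missing mir-", label)))
    }
    modal <- idx[which.max(pooled[idx])]           # ties: 5'-most
    rs <- profile$reads[profile$reads$lstart == modal - 1L, ]
    lens <- rs[, list(w = sum(weight)), by = len]
    data.table::setorder(lens, -w, len)            # ties: shorter
    alen <- lens$len[1]
    rs2 <- rs[rs$len == alen, ]
    sq <- rs2[, list(w = sum(weight)), by = seq]
    data.table::setorder(sq, -w, seq)
    modal_seq <- sq$seq[1]
    per_rep <- vapply(profile$replicates, function(rp) {
      sum(rs2$seq == modal_seq & rs2$replicate == rp)
    }, 1.0)
    list(start = modal - 1L, end = modal - 1L + alen, modal_seq = modal_seq,
         modal_counts = setNames(per_rep, profile$replicates))
  }
  a5 <- side_call(hairpin$from, hairpin$loop_i, "5p")
  if (inherits(a5, "duplex_rejection")) return(a5)
  a3 <- side_call(hairpin$loop_j, hairpin$to, "3p")
  if (inherits(a3, "duplex_rejection")) return(a3)
  if (a5$end > a3$start) return(duplex_rejection("overlapping arms"))
  for (a in list(a5, a3)) {
    w <- a$end - a$start
    if (w < 18 || w > 25) {
      return(duplex_rejection("arm length outside 18-25 nt"))
    }
  }
  structure(list(mir5p = c(start = a5$start, end = a5$end),
                 mir3p = c(start = a3$start, end = a3$end),
                 modal_seq_5p = a5$modal_seq, modal_seq_3p = a3$modal_seq,
                 modal_counts_5p = a5$modal_counts,
                 modal_counts_3p = a3$modal_counts),
            class = "duplex_call")
}

#' 5' processing precision of an arm
#'
#' Precision is the weighted count of reads sharing the modal 5' end divided
#' by all reads whose 5' end falls within the arm interval extended by 3 nt
#' on each side, pooled across replicates.
#'
#' @param profile a `read_profile`.
#' @param arm_interval length-2 vector `c(start, end)` (0-based half-open
#'   window coordinates).
#' @param arm `"5p"` or `"3p"` (label only).
#' @return an `arm_precision` list with `precision` (`NA` when the window
#'   has no reads) and `modal_5prime_position`.
#' @export
arm_precision <- function(profile, arm_interval, arm = "5p") {
  pooled <- rowSums(profile$p5)
  lo <- max(1L, arm_interval[1] + 1L - 3L)
  hi <- min(profile$L, arm_interval[2] + 3L)
  idx <- lo:hi
  total <- sum(pooled[idx])
  if (total == 0) {
    return(structure(list(arm = arm, precision = NA_real_,
                          modal_5prime_position = NA_integer_),
                     class = "arm_precision"))
  }
  modal <- idx[which.max(pooled[idx])]
  structure(list(arm = arm, precision = pooled[modal] / total,
                 modal_5prime_position = modal - 1L),
            class = "arm_precision")
}

#' Pairing geometry of a called duplex
#'
#' Walks the pair table between the two arm intervals and counts paired
#' positions, duplex mismatches (opposed unpaired positions), per-arm bulge
#' nucleotides, the asymmetric bulge total, the loop length between the arm
#' inner edges and the signed 3' overhangs at both duplex ends (positive
#' when an arm's 3' end extends past its partner's pairing).
#'
#' @param fold a `fold_result`.
#' @param call a `duplex_call` in the same coordinates.
#' @return a `duplex_geometry` list.
#' @export
duplex_geometry <- function(fold, call) {
  pt <- pair_table(fold$structure)
  s5 <- call$mir5p[["start"]] + 1L; e5 <- call$mir5p[["end"]]
  s3 <- call$mir3p[["start"]] + 1L; e3 <- call$mir3p[["end"]]
  i <- s5:e5
  paired_i <- i[!is.na(pt[i]) & pt[i] >= s3 & pt[i] <= e3]
  if (length(paired_i) == 0) {
    stop(structure(class = c("degenerate_duplex", "error", "condition"),
                   list(message = "arms are not base-paired to each other",
                        call = sys.call())))
  }
  j <- pt[paired_i]
  ord <- order(paired_i)
  pi <- paired_i[ord]; pj <- j[ord]
  n_pair <- length(pi)
  mm <- 0L; b5 <- 0L; b3 <- 0L; asym <- 0L
  if (n_pair > 1) {
    a <- diff(pi) - 1L          # unpaired on the 5p side between pairs
    b <- -diff(pj) - 1L         # unpaired on the 3p side between pairs
    mm <- sum(pmin(a, b))
    b5 <- sum(pmax(a - b, 0L))
    b3 <- sum(pmax(b - a, 0L))
    asym <- sum(abs(a - b))
  }
  h5 <- pi[1] - s5              # unpaired 5' head of mir-5p
  t5 <- e5 - pi[n_pair]         # unpaired 3' tail of mir-5p
  h3 <- pj[n_pair] - s3         # unpaired 5' head of mir-3p
  t3 <- e3 - pj[1]              # unpaired 3' tail of mir-3p
  len5 <- e5 - s5 + 1L; len3 <- e3 - s3 + 1L
  structure(list(
    paired_fraction = 2 * n_pair / (len5 + len3),
    n_paired = n_pair,
    n_mismatch = mm,
    bulge_nt_5p = b5, bulge_nt_3p = b3,
    asymmetric_bulge_nt = asym,
    overhang3p_lower = t3 - h5,      # open (precursor-terminal) duplex end
    overhang3p_upper = t5 - h3,      # loop-proximal duplex end
    loop_len = s3 - 1L - e5,
    precursor_len = e3 - s5 + 1L
  ), class = "duplex_geometry")
}

#' Fraction of profiled reads confined to the duplex
#'
#' The weighted fraction of all profiled reads whose interval lies within
#' either arm interval extended by `slack` nt on each side. Precisely
#' processed miRNA loci generate essentially no other small RNAs, so this
#' approaches 1; siRNA loci and fragmented ncRNAs score low.
#'
#' @param profile a `read_profile`.
#' @param call a `duplex_call`.
#' @param slack per-side extension in nt.
#' @return fraction in `[0, 1]`.
#' @export
duplex_read_fraction <- function(profile, call, slack = 2L) {
  r <- profile$reads
  if (nrow(r) == 0) return(NA_real_)
  inside <- function(arm) {
    r$lstart >= arm[["start"]] - slack & (r$lstart + r$len) <= arm[["end"]] + slack
  }
  ok <- inside(call$mir5p) | inside(call$mir3p)
  sum(r$weight[ok]) / sum(r$weight)
}

#' Export a per-position read-density table
#'
#' One row per (position, replicate): weighted 5'-end count and weighted
#' coverage, in transcript orientation. The companion of the dot-bracket
#' structure export for per-candidate read-density rendering.
#'
#' @param profile a `read_profile`.
#' @param path optional TSV path; when `NULL` the table is only returned.
#' @return `data.table(position, replicate, weighted_5p_count, coverage)`
#'   (position is 0-based within the profiled window).
#' @export
export_profile_density <- function(profile, path = NULL) {
  stopifnot(!isTRUE(profile$empty))
  reps <- colnames(profile$p5)
  dt <- data.table::rbindlist(lapply(reps, function(r) {
    data.table::data.table(position = seq_len(profile$L) - 1L,
                           replicate = r,
                           weighted_5p_count = profile$p5[, r],
                           coverage = profile$cov[, r])
  }))
  if (!is.null(path)) {
    write.table(dt, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  dt[]
}
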