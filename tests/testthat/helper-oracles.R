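# Independent oracles and small fixture builders used across the suite.
# Oracles are deliberately naive (enumeration / brute force) and never share
# code with the implementation paths they check.

# all ungapped placements of one read on a genome string, by scanning every
# offset on both strands and counting character mismatches
naive_align_one <- function(read, genome, max_mm = 1L) {
  out <- list()
  g <- strsplit(genome, "")[[1]]
  L <- nchar(read)
  n <- length(g) - L + 1L
  if (n < 1) return(data.frame())
  for (str in c("+", "-")) {
    pat <- if (str == "+") read else mircurate::dna_revcomp(read)
    p <- strsplit(pat, "")[[1]]
    idx <- outer(seq_len(L) - 1L, seq_len(n), "+")
    mm <- colSums(matrix(g[idx], nrow = L) != p)
    hit <- which(mm <= max_mm)
    if (length(hit)) {
      out[[length(out) + 1L]] <- data.frame(
        start = hit - 1L, end = hit - 1L + L, strand = str,
        n_mismatch = mm[hit])
    }
  }
  if (!length(out)) return(data.frame())
  do.call(rbind, out)
}

# best-stratum filter applied to the naive hits, mirroring the contract
naive_align_best <- function(read, genome, max_mm = 1L) {
  h <- naive_align_one(read, genome, max_mm)
  if (nrow(h) == 0) return(h)
  h[h$n_mismatch == min(h$n_mismatch), ]
}

# naive all-positions scan for exact duplex paralogs on one contig
naive_paralog_scan <- function(genome, a5, a3, max_span = 400L) {
  hits <- list()
  find_all <- function(pat) {
    L <- nchar(pat)
    starts <- integer(0)
    n <- nchar(genome) - L + 1L
    if (n >= 1) {
      subs <- substring(genome, seq_len(n), seq_len(n) + L - 1L)
      starts <- which(subs == pat) - 1L
    }
    starts
  }
  l5 <- nchar(a5); l3 <- nchar(a3)
  for (s5 in find_all(a5)) for (s3 in find_all(a3)) {
    if (s3 >= s5 + l5 && (s3 + l3 - s5) <= max_span) {
      hits[[length(hits) + 1L]] <- c(start = s5, end = s3 + l3, strand = 1L)
    }
  }
  rc5 <- mircurate::dna_revcomp(a5); rc3 <- mircurate::dna_revcomp(a3)
  for (s5 in find_all(rc5)) for (s3 in find_all(rc3)) {
    if (s5 >= s3 + l3 && (s5 + l5 - s3) <= max_span) {
      hits[[length(hits) + 1L]] <- c(start = s3, end = s5 + l5, strand = 2L)
    }
  }
  if (!length(hits)) return(data.frame())
  unique(as.data.frame(do.call(rbind, hits)))
}

# construct a minimal read_profile directly from (lstart, len, weight,
# replicate) vectors, bypassing the alignment machinery
toy_profile <- function(lstart, len, L = max(lstart + len) + 5L,
                        replicate = rep("rep1", length(lstart)),
                        weight = rep(1, length(lstart)),
                        seqs = NULL, seq = strrep("A", L)) {
  reps <- sort(unique(replicate))
  cov <- matrix(0, nrow = L, ncol = length(reps),
                dimnames = list(NULL, reps))
  p5 <- matrix(0, nrow = L, ncol = length(reps),
               dimnames = list(NULL, reps))
  for (k in seq_along(lstart)) {
    r <- match(replicate[k], reps)
    cov[(lstart[k] + 1L):(lstart[k] + len[k]), r] <-
      cov[(lstart[k] + 1L):(lstart[k] + len[k]), r] + weight[k]
    p5[lstart[k] + 1L, r] <- p5[lstart[k] + 1L, r] + weight[k]
  }
  if (is.null(seqs)) seqs <- substring(seq, lstart + 1L, lstart + len)
  structure(list(cluster_id = "toy", contig = "c", window_start = 0L,
                 window_end = L, strand = "+", L = L, replicates = reps,
                 empty = FALSE, seq = seq, cov = cov, p5 = p5,
                 reads = data.table::data.table(
                   read_id = paste0("r", seq_along(lstart)),
                   replicate = replicate, lstart = as.integer(lstart),
                   len = as.integer(len), seq = seqs, weight = weight),
                 n_reads = length(lstart)),
            class = "read_profile")
}

# brute-force 5' precision: per-position tally over the +/-3 window
brute_precision <- function(p5_counts, arm_start0, arm_end0, L) {
  lo <- max(1L, arm_start0 + 1L - 3L); hi <- min(L, arm_end0 + 3L)
  win <- p5_counts[lo:hi]
  if (sum(win) == 0) return(NA_real_)
  max(win) / sum(win)
}

# independent duplex-geometry oracle: renders the two arms as explicit
# aligned strings from the pair table, then counts column types
oracle_geometry <- function(structure, s5, e5, s3, e3) {  # 1-based inclusive
  pt <- mircurate::pair_table(structure)
  cols <- list()
  i <- s5; j <- e3
  # walk the alignment from the outer duplex end inwards
  while (i <= e5 && j >= s3) {
    pi <- pt[i]; pj <- pt[j]
    if (!is.na(pi) && pi == j) {
      cols[[length(cols) + 1L]] <- c("pair", i, j); i <- i + 1L; j <- j - 1L
    } else if (is.na(pi) && is.na(pj)) {
      cols[[length(cols) + 1L]] <- c("mm", i, j); i <- i + 1L; j <- j - 1L
    } else if (is.na(pi)) {
      cols[[length(cols) + 1L]] <- c("b5", i, NA); i <- i + 1L
    } else if (is.na(pj)) {
      cols[[length(cols) + 1L]] <- c("b3", NA, j); j <- j - 1L
    } else {
      # both paired but not to each other (outside the duplex walk)
      break
    }
  }
  m <- do.call(rbind, cols)
  types <- m[, 1]
  first_pair <- which(types == "pair")[1]
  last_pair <- max(which(types == "pair"))
  inner <- types[first_pair:last_pair]
  list(n_mismatch = sum(inner == "mm"),
       bulge_nt_5p = sum(inner == "b5"),
       bulge_nt_3p = sum(inner == "b3"),
       n_paired = sum(types == "pair"))
}
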