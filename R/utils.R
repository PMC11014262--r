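#' @import data.table
#' @importFrom stats median rmultinom runif setNames
#' @importFrom utils head tail write.table
NULL

# Internal conventions:
#  * genome/FASTQ sequences are DNA (T); folding operates on the RNA
#    transcription of the locus strand
#  * all internal coordinates are 0-based half-open; GFF3 export is the only
#    place 1-based inclusive coordinates appear (see granges0/gff helpers)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse complement of DNA sequences
#'
#' @param x character vector of DNA sequences (ACGTN).
#' @return character vector of reverse complements.
#' @export
dna_revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' @rdname dna_revcomp
#' @export
rna_revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::RNAStringSet(x)))
}

#' Convert between DNA and RNA alphabets
#' @param x character vector of sequences.
#' @return character vector in the other alphabet.
#' @export
dna_to_rna <- function(x) chartr("Tt", "Uu", x)

#' @rdname dna_to_rna
#' @export
rna_to_dna <- function(x) chartr("Uu", "Tt", x)

# run code with a local, restored RNG state (deterministic for fixed seed)
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(as.numeric(seed) %% .Machine$integer.max))
  force(code)
}

#' Parse dot-bracket structure into a pair table
#'
#' @param structure dot-bracket string (balanced round brackets).
#' @return integer vector `pt` of the same length; `pt[i]` is the 1-based
#'   partner of position `i`, or `NA` if unpaired.
#' @export
pair_table <- function(structure) {
  ch <- strsplit(structure, "", fixed = TRUE)[[1]]
  pt <- rep(NA_integer_, length(ch))
  stack <- integer(0)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") {
      stack <- c(stack, i)
    } else if (ch[i] == ")") {
      if (length(stack) == 0L) stop("unbalanced dot-bracket structure")
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pt[i] <- j
      pt[j] <- i
    } else if (ch[i] != ".") {
      stop("unsupported character in dot-bracket string: ", ch[i])
    }
  }
  if (length(stack) > 0L) stop("unbalanced dot-bracket structure")
  pt
}

#' Structure-region utilities
#'
#' `terminal_loops` lists terminal (hairpin) loops whose closing pair lies
#' entirely within `[from, to]` (1-based inclusive): pairs `(i, j)` with no
#' paired position strictly between. `single_stem_loop` is TRUE when every
#' pair inside the region nests in one unbranched stem-loop chain
#' (bulges/internal loops allowed, no multiloop).
#'
#' @param pt pair table from [pair_table()].
#' @param from,to region bounds (1-based inclusive).
#' @return `terminal_loops`: list of `c(i, j)`; `single_stem_loop`: logical.
#' @export
terminal_loops <- function(pt, from = 1L, to = length(pt)) {
  loops <- list()
  i <- from
  while (i <= to) {
    j <- pt[i]
    if (!is.na(j) && j > i && j <= to) {
      inner <- if (j - i > 1L) pt[(i + 1L):(j - 1L)] else integer(0)
      if (all(is.na(inner))) loops[[length(loops) + 1L]] <- c(i, j)
    }
    i <- i + 1L
  }
  loops
}

#' @rdname terminal_loops
#' @export
single_stem_loop <- function(pt, from = 1L, to = length(pt)) {
  loops <- terminal_loops(pt, from, to)
  if (length(loops) != 1L) return(FALSE)
  # no pair inside the region may enclose two or more disjoint child pairs
  idx <- from:to
  paired <- idx[!is.na(pt[idx]) & pt[idx] > idx & pt[idx] <= to & pt[idx] >= from]
  for (i in paired) {
    j <- pt[i]
    if (j - i < 2L) next
    kids <- 0L
    k <- i + 1L
    while (k < j) {
      if (!is.na(pt[k]) && pt[k] > k && pt[k] < j) {
        kids <- kids + 1L
        k <- pt[k] + 1L
      } else {
        k <- k + 1L
      }
    }
    if (kids > 1L) return(FALSE)
  }
  TRUE
}

#' Convert 0-based half-open intervals to GRanges
#'
#' The single point of truth for the 0-based/1-based conversion: all
#' internal coordinates are 0-based half-open, GRanges (and hence GFF3
#' export) are 1-based inclusive.
#'
#' @param contig,start0,end0,strand interval vectors.
#' @return a GRanges.
#' @export
granges0 <- function(contig, start0, end0, strand = "+") {
  GenomicRanges::GRanges(
    seqnames = contig,
    ranges = IRanges::IRanges(start = start0 + 1L, end = end0),
    strand = strand
  )
}

# GRanges -> 0-based half-open data.table
granges_to_bed0 <- function(gr) {
  data.table::data.table(
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  )
}

# sample n bases from weighted DNA alphabet
sample_bases <- function(n, probs) {
  paste(sample(names(probs), n, replace = TRUE, prob = probs), collapse = "")
}

#' A+T fraction of a sequence set
#' @param seq character vector of sequences (DNA or RNA).
#' @return pooled A+T (A+U) fraction.
#' @export
at_fraction <- function(seq) {
  f <- Biostrings::letterFrequency(Biostrings::DNAStringSet(chartr("U", "T", seq)),
                                   letters = c("A", "T"))
  tot <- nchar(seq)
  sum(f) / sum(tot)
}
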