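# Minimum-free-energy RNA secondary structure via ViennaRNA's RNAfold.
# Folding always happens on the RNA transcription of the locus strand; DNA
# input is transcribed (T -> U) before being handed to the fold engine.

#' Folding configuration
#'
#' @param temperature folding temperature in degrees Celsius. The default of
#'   22 matches the growth temperature of social amoebae rather than the
#'   37 degrees typical of animal pipelines.
#' @param flank number of nucleotides of genomic context added on each side
#'   of a read cluster before folding, so that duplex arms near cluster
#'   edges have sequence to pair with.
#' @return a `fold_config` list.
#' @export
fold_config <- function(temperature = 22, flank = 30L) {
  stopifnot(is.finite(temperature), flank >= 0)
  structure(list(temperature = temperature, flank = as.integer(flank)),
            class = "fold_config")
}

rnafold_binary <- function() {
  bin <- Sys.which("RNAfold")
  if (!nzchar(bin)) {
    stop("RNAfold was not found on the PATH; install ViennaRNA")
  }
  bin
}

#' Fold sequences at minimum free energy
#'
#' Batch interface to the nearest-neighbour thermodynamic model. Input may be
#' DNA or RNA; it is transcribed to RNA first. Deterministic.
#'
#' @param seqs character vector of sequences (optionally named).
#' @param temperature folding temperature in degrees Celsius.
#' @return data.frame with columns `id`, `seq` (RNA), `structure`
#'   (dot-bracket) and `mfe` (kcal/mol).
#' @export
fold_sequences <- function(seqs, temperature = 22) {
  if (length(seqs) == 0L) {
    return(data.frame(id = character(0), seq = character(0),
                      structure = character(0), mfe = numeric(0)))
  }
  rna <- toupper(dna_to_rna(seqs))
  bad <- grepl("[^ACGU]", rna)
  if (any(bad)) {
    stop("non-ACGU characters after transcription in sequence(s): ",
         paste(head(which(bad), 5L), collapse = ", "))
  }
  ids <- names(seqs) %||% paste0("seq", seq_along(seqs))
  fa <- tempfile(fileext = ".fa")
  on.exit(unlink(fa), add = TRUE)
  writeLines(paste0(">", ids, "\n", rna), fa)
  out <- system2(rnafold_binary(),
                 args = c("--noPS", "-T", format(temperature)),
                 stdin = fa, stdout = TRUE, stderr = FALSE)
  # records of three lines: >id / sequence / structure ( mfe )
  hdr <- grep("^>", out)
  if (length(hdr) != length(seqs)) stop("RNAfold returned unexpected output")
  struct_line <- out[hdr + 2L]
  m <- regmatches(struct_line,
                  regexec("^([.()]+)\\s+\\(\\s*(-?[0-9.]+)\\s*\\)", struct_line))
  ok <- vapply(m, length, 1L) == 3L
  if (!all(ok)) stop("could not parse RNAfold structure line")
  data.frame(
    id = ids,
    seq = rna,
    structure = vapply(m, `[`, "", 2L),
    mfe = as.numeric(vapply(m, `[`, "", 3L)),
    row.names = NULL
  )
}

#' Fold a single cluster sequence
#'
#' @param seq a single sequence (DNA or RNA) between 30 and 1000 nt.
#' @param cfg a [fold_config()].
#' @return a `fold_result` list with `sequence` (RNA), `structure`
#'   (dot-bracket) and `mfe` (kcal/mol).
#' @export
fold_cluster <- function(seq, cfg = fold_config()) {
  stopifnot(length(seq) == 1L)
  n <- nchar(seq)
  if (n < 30 || n > 1000) {
    stop("fold_cluster expects a sequence of 30-1000 nt, got ", n)
  }
  df <- fold_sequences(seq, temperature = cfg$temperature)
  structure(list(sequence = df$seq, structure = df$structure, mfe = df$mfe),
            class = "fold_result")
}

#' Wrap a sequence + dot-bracket pair as a fold result
#' @param seq sequence (DNA or RNA).
#' @param structure dot-bracket string.
#' @param mfe free energy (kcal/mol), optional.
#' @return a `fold_result`.
#' @export
as_fold_result <- function(seq, structure, mfe = NA_real_) {
  structure(list(sequence = toupper(dna_to_rna(seq)), structure = structure,
                 mfe = mfe), class = "fold_result")
}
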