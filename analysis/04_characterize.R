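#!/usr/bin/env Rscript
# Step 4 — characterization statistics and expression tables.
#
# Consumes the discovery results of 02_discover.R: positional nucleotide
# composition of the mature miRNAs (5' U preference), AT content of mature
# miRNAs versus the intergenic genome, precursor length summary, read-length
# histogram, a per-replicate expression matrix over the called arms, and a
# worked synteny-block merge. Writes tables under results/characterization/.

suppressMessages({library(mircurate); library(Biostrings)})

out <- "results/characterization"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

mature_set <- tryCatch(
  Biostrings::readRNAStringSet("results/discovery/mature.fa"),
  error = function(e) NULL)
if (is.null(mature_set)) {
  stop("run analysis/02_discover.R first (results/discovery/mature.fa missing)")
}
genome_set <- readDNAStringSet("results/sim/genome.fa")
genome <- setNames(as.character(genome_set), names(genome_set))
cand <- read.delim("results/discovery/candidates.tsv")
bona <- cand[cand$bona_fide %in% TRUE, ]

cs <- characterization_summary(
  as.character(mature_set),
  precursor_lens = bona$precursor_end - bona$precursor_start,
  genome = genome)
cat(sprintf("mature miRNAs: %d; first-nt U frequency: %.2f\n",
            cs$n_sequences, cs$first_nt_freq[["U"]]))
cat(sprintf("AT: mature %.1f%% vs intergenic %.1f%%\n",
            100 * cs$mature_at_fraction, 100 * cs$intergenic_at_fraction))
cat(sprintf("precursor length: %.0f / %.0f / %.0f (min/median/max)\n",
            cs$precursor_len[["min"]], cs$precursor_len[["median"]],
            cs$precursor_len[["max"]]))
write.table(t(cs$composition), file.path(out, "composition.tsv"),
            sep = "\t", quote = FALSE,
            col.names = c("A", "C", "G", "U"), row.names = TRUE)

# synteny-block merge worked example (5 kb gap)
blocks <- data.frame(
  chrA = "dfi_1", startA = c(0L, 3000L, 40000L),
  endA = c(1000L, 4000L, 41000L),
  chrB = "ddi_2", startB = c(100L, 3100L, 40100L),
  endB = c(1100L, 4100L, 41100L), orientation = "same")
merged <- merge_synteny_blocks(blocks, gap = 5000L)
cat(sprintf("synteny: %d blocks merged to %d\n", nrow(blocks), nrow(merged)))
write.table(merged, file.path(out, "synteny_merged.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("wrote tables under", out, "\n")
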