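#!/usr/bin/env Rscript
# Step 2 — run the discovery pipeline on the simulated libraries.
#
# Reads the FASTQ files and genome written by 01_simulate.R, trims adapters,
# selects 18-35 nt reads, aligns with at most one mismatch, weights
# multimappers, clusters, folds each cluster at 22 degrees C, calls duplexes,
# applies the round-1 30% precision screen and the three criteria sets, and
# writes the curated miRNA annotation plus per-candidate reports under
# results/discovery/.

suppressMessages({library(mircurate); library(Biostrings)})

sim_dir <- "results/sim"
out <- "results/discovery"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

genome_set <- readDNAStringSet(file.path(sim_dir, "genome.fa"))
genome <- setNames(as.character(genome_set), names(genome_set))
fqs <- list.files(sim_dir, pattern = "rep[0-9]+\\.fastq\\.gz$",
                  full.names = TRUE)
reads <- lapply(fqs, read_fastq)
names(reads) <- sub("\\.fastq\\.gz$", "", basename(fqs))
reads <- lapply(reads, function(dt) dt[, c("read_id", "seq")])

res <- discover_mirnas(reads, genome)

truth <- read_truth(file.path(sim_dir, "truth.json"))
sc <- score_recovery(res$candidates, truth)
cat(sprintf("bona fide calls: %d; planted miRNAs recovered: %d/%d\n",
            sum(res$candidates$bona_fide), sum(sc$recovered),
            length(sc$recovered)))
print(sc$calls_by_class)

paths <- write_outputs(out, res, seed = 2024L)
write.table(res$candidates, file.path(out, "candidates.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("wrote:", paste(c(paths, file.path(out, "candidates.tsv")),
                    collapse = ", "), "\n")
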