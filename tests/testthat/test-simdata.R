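test_that("hairpin designs have the intended architecture", {
  d <- design_hairpin("UGGAAGACUAGUGAUUUUGUU", loop_len = 15, overhang3p = 2,
                      rng_seed = 1, refold = FALSE)
  expect_equal(nchar(d$precursor_seq), 21 + 15 + 21)
  expect_equal(nchar(d$precursor_seq),
               nchar(d$arm5p) + d$loop_len + nchar(d$arm3p))
  expect_equal(nchar(d$intended_structure), nchar(d$precursor_seq))
  pt <- pair_table(d$intended_structure)           # errors if unbalanced
  # exactly one terminal loop, 2 unpaired nt at each arm's 3' end
  expect_length(terminal_loops(pt), 1L)
  s <- strsplit(d$intended_structure, "")[[1]]
  expect_equal(s[(d$arm5p_end - 1):d$arm5p_end], c(".", "."))
  expect_equal(s[(d$arm3p_end - 1):d$arm3p_end], c(".", "."))
  # arm positions recorded and non-overlapping
  expect_true(d$arm5p_end < d$arm3p_start)
})

test_that("mismatches and bulges appear in the intended structure", {
  d <- design_hairpin("UGGAAGACUAGUGAUUUUGUU", loop_len = 18,
                      mismatch_positions = c(6, 11),
                      bulge_spec = list(list(arm = "3p", position = 8, n = 1)),
                      rng_seed = 3, refold = FALSE)
  s <- strsplit(d$intended_structure, "")[[1]]
  expect_equal(s[6], ".")
  expect_equal(s[11], ".")
  expect_equal(nchar(d$arm3p), 21 + 1)             # bulge lengthens the arm
  expect_error(design_hairpin("UGGAAGACUAGUGAUUUUGUU", loop_len = 2),
               "loop_len")
})

test_that("MFE refold recovers the intended duplex for nearly all designs", {
  recov <- vapply(1:60, function(i) random_hairpin_design(i)$refold_recovery,
                  1.0)
  expect_gte(mean(recov >= 0.9), 0.95)
})

test_that("synthesized genomes hit the configured AT content and are deterministic", {
  cfg <- sim_config(genome_len = 200000L, at_content = 0.86, rng_seed = 11L)
  g1 <- synthesize_genome(cfg, list())
  expect_length(g1$truth, 0L)
  at <- at_fraction(g1$genome[[1]])
  expect_lt(abs(at - 0.86), 0.01)
  g2 <- synthesize_genome(cfg, list())
  expect_identical(g1$genome, g2$genome)
})

test_that("planted sequences are inserted verbatim and truth covers the duplex", {
  cfg <- sim_config(genome_len = 20000L, rng_seed = 5L)
  d <- random_hairpin_design(8L)
  plans <- list(
    locus_plan("mirA", "mirna", start = 4000L, strand = "+", design = d,
               expression = 500),
    locus_plan("mirB", "mirna", start = 9000L, strand = "-", design = d,
               expression = 500)
  )
  sim <- synthesize_genome(cfg, plans)
  g <- sim$genome[[1]]
  dna <- rna_to_dna(d$precursor_seq)
  expect_identical(substring(g, 4001, 4000 + nchar(dna)), dna)
  expect_identical(substring(g, 9001, 9000 + nchar(dna)), dna_revcomp(dna))
  for (r in sim$truth) {
    expect_true(r$duplex$arm5p[["start"]] >= r$plan$start)
    expect_true(r$duplex$arm3p[["end"]] <= r$plan$end)
    # the planted arm sequence is recoverable from the genome
    a5 <- r$duplex$arm5p
    seq5 <- substring(g, a5[["start"]] + 1L, a5[["end"]])
    if (r$plan$strand == "-") seq5 <- dna_revcomp(seq5)
    expect_identical(seq5, rna_to_dna(substr(d$precursor_seq, d$arm5p_start,
                                             d$arm5p_end)))
  }
  # overlapping plans are a layout error naming the offenders
  bad <- list(plans[[1]],
              locus_plan("mirX", "mirna", start = 4010L, design = d,
                         expression = 1))
  expect_error(synthesize_genome(cfg, bad), "overlapping.*mirA")
})

test_that("simulated libraries conserve read counts and are deterministic", {
  cfg <- sim_config(genome_len = 60000L, reads_per_replicate = 5000L,
                    n_replicates = 2L, rng_seed = 21L)
  plans <- plan_study_loci(cfg, n_mirna = 2, n_sirna = 2, n_decoy = 1)
  sim <- synthesize_genome(cfg, plans)
  lib1 <- simulate_libraries(sim)
  for (r in seq_len(cfg$n_replicates)) {
    expect_equal(nrow(lib1$reads[[r]]), 5000L)
    planted <- sum(vapply(lib1$truth,
                          function(t) t$realized_read_counts[r], 1L))
    bg <- sum(startsWith(lib1$reads[[r]]$read_id, "bg|"))
    expect_identical(planted + bg, 5000L)
  }
  lib2 <- simulate_libraries(sim)
  expect_identical(lib1$reads, lib2$reads)
})

test_that("read-length histogram has its mode at 21 nt", {
  cfg <- sim_config(genome_len = 80000L, reads_per_replicate = 20000L,
                    n_replicates = 1L, rng_seed = 31L)
  plans <- plan_study_loci(cfg, n_mirna = 3, n_sirna = 4, n_decoy = 1)
  sim <- synthesize_genome(cfg, plans)
  lib <- simulate_libraries(sim)
  trimmed <- preprocess_reads(read_records(list(rep1 = lib$reads$rep1$seq)),
                              align_config(adapter = cfg$adapter))
  h <- table(nchar(trimmed$seq))
  expect_equal(as.integer(names(h)[which.max(h)]), 21L)
})

test_that("5'-jitter frequencies match the configured distribution", {
  cfg <- sim_config(genome_len = 30000L, reads_per_replicate = 2000L,
                    n_replicates = 1L,
                    jitter5p = c(`0` = 0.85, `1` = 0.10, `-1` = 0.05),
                    rng_seed = 41L)
  d <- random_hairpin_design(3L)
  plans <- list(locus_plan("m1", "mirna", start = 10000L, design = d,
                           expression = 2000))
  sim <- synthesize_genome(cfg, plans)
  lib <- simulate_libraries(sim)
  # recover each read's 5' offset by aligning its start within the
  # flank-padded precursor (jittered ends may reach into the flanks)
  ext <- substring(sim$genome[[1]], 10000L - 6L + 1L,
                   10000L + nchar(rna_to_dna(d$precursor_seq)) + 6L)
  reads <- lib$reads$rep1[startsWith(read_id, "m1|")]
  ins <- substr(reads$seq, 1, 18)
  pos <- vapply(ins, function(s) as.integer(regexpr(s, ext, fixed = TRUE)),
                1L, USE.NAMES = FALSE)
  expect_true(all(pos > 0))
  is5 <- abs(pos - (d$arm5p_start + 6L)) <= 2
  off <- ifelse(is5, pos - (d$arm5p_start + 6L), pos - (d$arm3p_start + 6L))
  f <- table(factor(off, levels = c(-1, 0, 1))) / length(off)
  expect_lt(abs(f[["0"]] - 0.85), 0.03)
  expect_lt(abs(f[["1"]] - 0.10), 0.03)
  expect_lt(abs(f[["-1"]] - 0.05), 0.03)
})

test_that("truth tables round-trip losslessly through BED + JSON", {
  cfg <- sim_config(genome_len = 30000L, reads_per_replicate = 1000L,
                    rng_seed = 51L)
  plans <- plan_study_loci(cfg, n_mirna = 1, n_sirna = 1, n_decoy = 1)
  sim <- synthesize_genome(cfg, plans)
  lib <- simulate_libraries(sim)
  dir <- withr::local_tempdir()
  write_truth(lib$truth, dir)
  back <- read_truth(file.path(dir, "truth.json"))
  expect_equal(names(back), names(lib$truth))
  for (id in names(back)) {
    expect_equal(back[[id]]$plan$start, lib$truth[[id]]$plan$start)
    expect_equal(back[[id]]$plan$strand, lib$truth[[id]]$plan$strand)
    expect_equal(back[[id]]$plan$sequence, lib$truth[[id]]$plan$sequence)
    expect_equal(back[[id]]$realized_read_counts,
                 unname(lib$truth[[id]]$realized_read_counts))
  }
  bed <- read.table(file.path(dir, "truth.bed"), sep = "\t")
  expect_equal(nrow(bed), length(lib$truth))
})

test_that("zero-read libraries warn and produce empty valid output", {
  cfg <- sim_config(genome_len = 5000L, reads_per_replicate = 0L,
                    n_replicates = 1L, rng_seed = 1L)
  sim <- synthesize_genome(cfg, list())
  expect_warning(lib <- simulate_libraries(sim), "empty")
  expect_equal(nrow(lib$reads[[1]]), 0L)
  p <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(lib$reads[[1]], p)
  expect_true(file.exists(p))
})
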