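arm_seqs <- function(d) {
  list(a5 = rna_to_dna(substr(d$precursor_seq, d$arm5p_start, d$arm5p_end)),
       a3 = rna_to_dna(substr(d$precursor_seq, d$arm3p_start, d$arm3p_end)))
}

test_that("homolog search requires both arms in correct orientation", {
  d <- random_hairpin_design(301L, refold = FALSE)
  a <- arm_seqs(d)
  pre <- rna_to_dna(d$precursor_seq)
  ortho_loop <- rna_to_dna(mutate_ortholog(d, "loop_divergent", 5)$precursor_seq)
  sp <- function(n, s) random_dna(n, gc = 0.4, rng_seed = s)
  g <- paste0(sp(2000, 1), pre, sp(2000, 2), ortho_loop, sp(2000, 3),
              dna_revcomp(a$a5), sp(50, 4), sp(1000, 5))
  hits <- search_arm_homologs(a$a5, a$a3, c(chr = g))
  expect_equal(nrow(hits), 2L)               # identical + loop-divergent
  expect_true(all(hits$mm5 == 0L & hits$mm3 == 0L))
  # a lone 5p arm is never a hit
  g2 <- paste0(sp(1000, 6), a$a5, sp(1000, 7))
  expect_equal(nrow(search_arm_homologs(a$a5, a$a3, c(chr = g2))), 0L)
  # up to two mismatches per arm are tolerated and counted
  a5mut <- a$a5
  substr(a5mut, 8, 8) <- setdiff(c("A", "C", "G", "T"), substr(a$a5, 8, 8))[1]
  g3 <- paste0(sp(1000, 8), a5mut,
               substring(pre, nchar(a$a5) + 1, nchar(pre)), sp(1000, 9))
  h3 <- search_arm_homologs(a$a5, a$a3, c(chr = g3))
  expect_equal(nrow(h3), 1L)
  expect_equal(h3$mm5, 1L)
})

test_that("homolog search equals a brute-force scan on random duplexes", {
  g <- random_dna(30000, gc = 0.4, rng_seed = 31)
  for (trial in 1:12) {
    d <- random_hairpin_design(900L + trial, refold = FALSE)
    a <- arm_seqs(d)
    ins_at <- 5000 + trial * 1000
    gg <- paste0(substring(g, 1, ins_at), rna_to_dna(d$precursor_seq),
                 substring(g, ins_at + 1))
    got <- search_arm_homologs(a$a5, a$a3, c(chr = gg), max_mm_per_arm = 2)
    # brute force: scan every offset for each arm with <=2 mismatches
    b5 <- naive_align_one(a$a5, gg, 2L); b3 <- naive_align_one(a$a3, gg, 2L)
    found <- FALSE
    for (i in seq_len(nrow(b5))) for (j in seq_len(nrow(b3))) {
      if (b5$strand[i] != b3$strand[j]) next
      if (b5$strand[i] == "+" &&
          b3$start[j] >= b5$end[i] && b3$end[j] - b5$start[i] <= 400) found <- TRUE
      if (b5$strand[i] == "-" &&
          b5$start[i] >= b3$end[j] && b5$end[i] - b3$start[j] <= 400) found <- TRUE
    }
    expect_equal(nrow(got) > 0, found, info = trial)
    expect_gte(nrow(got), 1L)                # the planted copy itself
  }
})

test_that("fold verification accepts intact orthologs and rejects broken ones", {
  d <- random_hairpin_design(410L)
  a <- arm_seqs(d)
  sp <- function(n, s) random_dna(n, gc = 0.5, rng_seed = s)
  intact <- rna_to_dna(mutate_ortholog(d, "loop_divergent", 11)$precursor_seq)
  # inter-arm region carrying a perfect adjacent complement of the 3p arm:
  # the 3p arm pairs with the insert and the true 5p arm is left out
  broken <- paste0(a$a5, "ACAC", dna_revcomp(a$a3), "AACA", a$a3)
  g <- paste0(sp(1000, 12), intact, sp(1000, 13), broken, sp(1000, 14))
  hits <- search_arm_homologs(a$a5, a$a3, c(chr = g))
  expect_equal(nrow(hits), 2L)
  hits <- hits[order(start)]
  v1 <- verify_homolog(hits[1], c(chr = g))
  v2 <- verify_homolog(hits[2], c(chr = g))
  expect_true(v1$verified_fold)
  expect_true(is.na(v1$expressed))
  expect_false(v2$verified_fold)
  # expression verification from a placement table
  prof <- data.table::data.table(contig = "chr", start = hits$start5[1],
                                 end = hits$end5[1], strand = "+")
  prof <- prof[rep(1, 15)]
  v3 <- verify_homolog(hits[1], c(chr = g), profile = prof, min_reads = 10)
  expect_true(v3$expressed)
})

test_that("ortholog recovery: loop divergence is tolerated, arm scrambling is not", {
  sp <- random_dna(800, gc = 0.4, rng_seed = 51)
  n_ok <- 0L; n_bad <- 0L
  for (i in 1:15) {
    d <- random_hairpin_design(520L + i)
    a <- arm_seqs(d)
    ortho <- rna_to_dna(mutate_ortholog(d, "loop_divergent", i)$precursor_seq)
    scram <- rna_to_dna(mutate_ortholog(d, "arm_scrambled", i)$precursor_seq)
    g_ok <- paste0(sp, ortho, sp)
    g_bad <- paste0(sp, scram, sp)
    h_ok <- search_arm_homologs(a$a5, a$a3, c(chr = g_ok))
    h_bad <- search_arm_homologs(a$a5, a$a3, c(chr = g_bad))
    if (nrow(h_ok) == 1 && verify_homolog(h_ok, c(chr = g_ok))$verified_fold) {
      n_ok <- n_ok + 1L
    }
    if (nrow(h_bad) == 0) n_bad <- n_bad + 1L
  }
  expect_equal(n_ok, 15L)
  expect_equal(n_bad, 15L)
})

test_that("duplex substitutions classify as compensatory, bulge or disrupting", {
  # hand-built duplex: 5p = GGCAUGGCAUGGCAUGGCAUG (21), full pairing design
  d <- design_hairpin("GGCAUGGCAUGGCAUGGCAUG", loop_len = 12,
                      mismatch_positions = c(9),     # bulge-like mismatch
                      rng_seed = 61, refold = FALSE)
  ref <- list(seq5 = d$arm5p, seq3 = d$arm3p, structure = d$intended_structure,
              precursor = d$precursor_seq,
              arm5 = c(d$arm5p_start, d$arm5p_end),
              arm3 = c(d$arm3p_start, d$arm3p_end))
  pre <- strsplit(d$precursor_seq, "")[[1]]
  pt <- pair_table(d$intended_structure)
  # compensatory: A-U pair -> G-C pair (both strands changed)
  i_pair <- which(pre == "A" & !is.na(pt))[1]
  hom1 <- pre; hom1[i_pair] <- "G"; hom1[pt[i_pair]] <- "C"
  h1 <- ref; h1$precursor <- paste(hom1, collapse = "")
  cls1 <- classify_duplex_substitutions(ref, h1)
  expect_true(all(cls1$class == "compensatory"))
  expect_equal(nrow(cls1), 2L)
  # bulge-located: change at the reference mismatch position (unpaired)
  hom2 <- pre; hom2[9] <- setdiff(c("A", "C", "G", "U"), pre[9])[1]
  h2 <- ref; h2$precursor <- paste(hom2, collapse = "")
  cls2 <- classify_duplex_substitutions(ref, h2)
  expect_equal(cls2$class, "bulge_located")
  # pairing-disrupting: G-C pair -> G-G (structure refolds without the pair)
  i_gc <- which(pre == "G" & !is.na(pt) & pre[pmax(pt, 1)] == "C")[1]
  hom3 <- pre; hom3[i_gc] <- "C"   # C opposite C: non-canonical
  h3 <- ref; h3$precursor <- paste(hom3, collapse = "")
  # homolog structure: same pairing minus the disrupted pair
  s3 <- strsplit(d$intended_structure, "")[[1]]
  s3[i_gc] <- "."; s3[pt[i_gc]] <- "."
  h3$structure <- paste(s3, collapse = "")
  cls3 <- classify_duplex_substitutions(ref, h3)
  expect_equal(cls3$class, "pairing_disrupting")
  # constructed panel: zero confusion across 100 seeded substitutions
  set.seed(71)
  confus <- 0L
  for (k in 1:100) {
    kind <- sample(c("comp", "bulge", "disrupt"), 1)
    if (kind == "comp") {
      cand <- which(!is.na(pt) & pt > seq_along(pt))
      i <- sample(cand, 1)
      hp <- pre
      new <- switch(pre[i], A = "G", G = "A", C = "U", U = "C")
      hp[i] <- new
      hp[pt[i]] <- switch(new, A = "U", U = "A", G = "C", C = "G")
      hh <- ref; hh$precursor <- paste(hp, collapse = "")
      got <- classify_duplex_substitutions(ref, hh)
      if (!all(got$class == "compensatory")) confus <- confus + 1L
    } else if (kind == "bulge") {
      hp <- pre; hp[9] <- sample(setdiff(c("A", "C", "G", "U"), pre[9]), 1)
      hh <- ref; hh$precursor <- paste(hp, collapse = "")
      got <- classify_duplex_substitutions(ref, hh)
      if (!all(got$class == "bulge_located")) confus <- confus + 1L
    } else {
      cand <- which(!is.na(pt) & pt > seq_along(pt))
      i <- sample(cand, 1)
      hp <- pre
      # replace with a base that cannot pair its partner
      partner <- pre[pt[i]]
      bad <- setdiff(c("A", "C", "G", "U"), c(pre[i]))
      nonpair <- bad[!vapply(bad, function(b)
        paste0(b, partner) %in% c("AU", "UA", "GC", "CG", "GU", "UG"), TRUE)]
      if (length(nonpair) == 0) next
      hp[i] <- nonpair[1]
      ss <- strsplit(d$intended_structure, "")[[1]]
      ss[i] <- "."; ss[pt[i]] <- "."
      hh <- ref; hh$precursor <- paste(hp, collapse = "")
      hh$structure <- paste(ss, collapse = "")
      got <- classify_duplex_substitutions(ref, hh)
      if (!all(got$class == "pairing_disrupting")) confus <- confus + 1L
    }
  }
  expect_equal(confus, 0L)
  # gapped alignments are unsupported
  h_bad <- ref; h_bad$seq5 <- paste0(ref$seq5, "A")
  expect_error(classify_duplex_substitutions(ref, h_bad), "gapped")
})
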