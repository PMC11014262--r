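# A reusable planted-locus scenario: one miRNA on each strand, profiled
# through the real alignment path.
planted_scenario <- function(rng_seed = 101L, jitter5p = c(`0` = 1.0),
                             reads_per_replicate = 3000L, n_replicates = 3L) {
  cfg <- sim_config(genome_len = 40000L,
                    reads_per_replicate = reads_per_replicate,
                    n_replicates = n_replicates, jitter5p = jitter5p,
                    rng_seed = rng_seed)
  d1 <- random_hairpin_design(rng_seed + 1L)
  d2 <- random_hairpin_design(rng_seed + 2L)
  plans <- list(
    locus_plan("mirP", "mirna", start = 8000L, strand = "+", design = d1,
               expression = round(0.48 * reads_per_replicate)),
    locus_plan("mirM", "mirna", start = 25000L, strand = "-", design = d2,
               expression = round(0.48 * reads_per_replicate)))
  sim <- synthesize_genome(cfg, plans)
  lib <- simulate_libraries(sim)
  rt <- do.call(rbind, lapply(names(lib$reads), function(r) {
    data.table::data.table(read_id = lib$reads[[r]]$read_id,
                           seq = lib$reads[[r]]$seq, replicate = r)
  }))
  suppressMessages(rt <- preprocess_reads(rt, align_config(adapter = cfg$adapter)))
  suppressMessages(pl <- align_reads(rt, sim$genome, align_config()))
  pl <- weight_multimappers(pl)
  cl <- call_clusters(pl)
  list(sim = sim, lib = lib, placements = cl$placements, clusters = cl$clusters,
       designs = list(mirP = d1, mirM = d2))
}

scen <- planted_scenario()

test_that("cluster profiles count only exact-match reads, per replicate", {
  cl <- scen$clusters[1]
  prof <- build_cluster_profile(scen$placements, cl, scen$sim$genome)
  expect_false(prof$empty)
  expect_equal(ncol(prof$cov), 3L)
  expect_equal(ncol(prof$p5), 3L)
  # 5'-end counts total the profiled reads (weights are 1 at unique loci)
  expect_equal(sum(prof$p5), sum(prof$reads$weight), tolerance = 1e-9)
  expect_true(all(prof$cov >= 0))
  # a 1-mismatch placement in the cluster is excluded from the profile
  fake <- data.table::copy(scen$placements[1])
  fake[, `:=`(read_id = "fake", n_mismatch = 1L,
              start = cl$start + 5L, end = cl$start + 26L,
              contig = cl$contig, strand = cl$strand, weight = 1)]
  prof2 <- build_cluster_profile(rbind(scen$placements, fake), cl,
                                 scen$sim$genome)
  expect_false("fake" %in% prof2$reads$read_id)
})

test_that("planted loci on either strand yield the designed duplex", {
  for (locus in c("mirP", "mirM")) {
    truth <- scen$lib$truth[[locus]]
    cl <- scen$clusters[contig == truth$plan$contig &
                          strand == truth$plan$strand &
                          start < truth$plan$end & end > truth$plan$start]
    expect_equal(nrow(cl), 1L, info = locus)
    prof <- build_cluster_profile(scen$placements, cl, scen$sim$genome)
    fold <- fold_profile(prof)
    hp <- find_hairpin(fold, prof)
    expect_false(is.null(hp), info = locus)
    call <- call_duplex(prof, hp, fold)
    expect_s3_class(call, "duplex_call")
    d <- scen$designs[[locus]]
    expect_equal(call$modal_seq_5p,
                 rna_to_dna(substr(d$precursor_seq, d$arm5p_start,
                                   d$arm5p_end)), info = locus)
    expect_equal(call$modal_seq_3p,
                 rna_to_dna(substr(d$precursor_seq, d$arm3p_start,
                                   d$arm3p_end)), info = locus)
    # with jitter disabled both arms are perfectly precise
    expect_equal(arm_precision(prof, call$mir5p, "5p")$precision, 1.0)
    expect_equal(arm_precision(prof, call$mir3p, "3p")$precision, 1.0)
    expect_gte(duplex_read_fraction(prof, call), 0.95)
  }
})

test_that("find_hairpin rejects branched structures and same-arm evidence", {
  # cloverleaf-like: two stem-loops between the evidence blocks
  clover <- "..((((....))))..((((....)))).."
  prof <- toy_profile(lstart = c(rep(2, 6), rep(24, 6)), len = rep(4, 12),
                      L = 30)
  fold <- as_fold_result(strrep("A", 30), clover)
  expect_null(find_hairpin(fold, prof))
  # single stem-loop with arms on opposite sides is accepted
  stem <- paste0("..", strrep("(", 8), "....", strrep(")", 8), "..")
  prof2 <- toy_profile(lstart = c(rep(2, 6), rep(14, 6)), len = rep(8, 12),
                       L = 24)
  fold2 <- as_fold_result(strrep("A", 24), stem)
  expect_false(is.null(find_hairpin(fold2, prof2)))
  # both evidence blocks on the 5' arm -> none
  long5 <- paste0(strrep("(", 20), "....", strrep(")", 20))
  prof3 <- toy_profile(lstart = c(rep(0, 6), rep(12, 6)), len = rep(6, 12),
                       L = 44)
  fold3 <- as_fold_result(strrep("A", 44), long5)
  expect_null(find_hairpin(fold3, prof3))
})

test_that("duplex calling takes the modal 5' end with 5'-most tie-break", {
  # arm 5'-end counts {pos 2: 12, pos 3: 4}; partner arm at pos 30
  prof <- toy_profile(lstart = c(rep(2, 12), rep(3, 4), rep(30, 10)),
                      len = c(rep(20, 16), rep(20, 10)), L = 55)
  stem <- paste0("..", strrep("(", 21), strrep(".", 7), strrep(")", 21), "....")
  fold <- as_fold_result(strrep("A", 55), stem)
  hp <- find_hairpin(fold, prof)
  call <- call_duplex(prof, hp, fold)
  expect_equal(call$mir5p[["start"]], 2L)
  # tie {2: 8, 3: 8} -> 5'-most wins
  proft <- toy_profile(lstart = c(rep(2, 8), rep(3, 8), rep(30, 10)),
                       len = rep(20, 26), L = 55)
  callt <- call_duplex(proft, find_hairpin(fold, proft), fold)
  expect_equal(callt$mir5p[["start"]], 2L)
  # no reads on the 3p side -> rejection naming the missing arm
  prof3 <- toy_profile(lstart = rep(2, 10), len = rep(20, 10), L = 55)
  hp3 <- find_hairpin(fold, prof3)
  if (!is.null(hp3)) {
    rej <- call_duplex(prof3, hp3, fold)
    expect_s3_class(rej, "duplex_rejection")
    expect_match(rej$reason, "mir-3p")
  }
})

test_that("arm precision equals the brute-force per-position tally", {
  # worked examples
  p <- toy_profile(lstart = c(rep(5, 12), rep(6, 4)), len = rep(21, 16), L = 40)
  expect_equal(arm_precision(p, c(5L, 26L))$precision, 0.75)
  p2 <- toy_profile(lstart = rep(7, 30), len = rep(21, 30), L = 40)
  expect_equal(arm_precision(p2, c(7L, 28L))$precision, 1.0)
  p3 <- toy_profile(lstart = 5:14, len = rep(20, 10), L = 40)
  expect_equal(arm_precision(p3, c(5L, 25L))$precision, 0.1)
  # randomized oracle equivalence
  set.seed(99)
  for (i in 1:300) {
    L <- 60L
    n <- sample(5:40, 1)
    ls <- sample(0:35, n, replace = TRUE)
    prof <- toy_profile(lstart = ls, len = rep(20, n), L = L)
    a0 <- sample(0:30, 1); a1 <- a0 + 21L
    counts <- tabulate(ls + 1L, nbins = L)
    expect_equal(arm_precision(prof, c(a0, a1))$precision,
                 brute_precision(counts, a0, a1, L))
  }
})

test_that("duplex geometry matches designs and the enumeration oracle", {
  # designed overhangs and mismatch/bulge counts are recovered exactly
  for (seed in 1:40) {
    par <- list(mm = switch(1 + seed %% 3, integer(0), c(7L), c(6L, 12L)),
                bulge = if (seed %% 4 == 0) {
                  list(list(arm = c("5p", "3p")[1 + seed %% 2],
                            position = 9L, n = 1L + seed %% 2))
                } else list())
    d <- design_hairpin("UGGAAGACUAGUGAUUUCGUGUA", loop_len = 16,
                        overhang3p = 2, mismatch_positions = par$mm,
                        bulge_spec = par$bulge, rng_seed = seed,
                        refold = FALSE)
    fold <- as_fold_result(d$precursor_seq, d$intended_structure)
    call <- structure(list(
      mir5p = c(start = d$arm5p_start - 1L, end = d$arm5p_end),
      mir3p = c(start = d$arm3p_start - 1L, end = d$arm3p_end)),
      class = "duplex_call")
    g <- duplex_geometry(fold, call)
    expect_equal(g$overhang3p_lower, 2L, info = seed)
    expect_equal(g$overhang3p_upper, 2L, info = seed)
    expect_equal(g$n_mismatch, length(par$mm), info = seed)
    bn <- if (length(par$bulge)) par$bulge[[1]]$n else 0L
    expect_equal(g$asymmetric_bulge_nt, bn, info = seed)
    expect_equal(g$loop_len, d$loop_len, info = seed)
    expect_equal(g$precursor_len, nchar(d$precursor_seq), info = seed)
    # independent pair-table enumeration oracle
    o <- oracle_geometry(d$intended_structure, d$arm5p_start, d$arm5p_end,
                         d$arm3p_start, d$arm3p_end)
    expect_equal(g$n_mismatch, o$n_mismatch, info = seed)
    expect_equal(g$bulge_nt_5p, o$bulge_nt_5p, info = seed)
    expect_equal(g$bulge_nt_3p, o$bulge_nt_3p, info = seed)
    expect_equal(g$n_paired, o$n_paired, info = seed)
  }
  # arms that never pair with each other are a degenerate duplex
  fold <- as_fold_result(strrep("A", 60), strrep(".", 60))
  call <- structure(list(mir5p = c(start = 0L, end = 21L),
                         mir3p = c(start = 35L, end = 56L)),
                    class = "duplex_call")
  expect_error(duplex_geometry(fold, call), class = "degenerate_duplex")
})

test_that("duplex read fraction counts confined reads and is monotone in slack", {
  prof <- toy_profile(lstart = c(rep(5, 60), rep(30, 60), rep(55, 60)),
                      len = rep(20, 180), L = 80)
  call <- structure(list(mir5p = c(start = 5L, end = 25L),
                         mir3p = c(start = 55L, end = 75L)),
                    class = "duplex_call")
  expect_equal(duplex_read_fraction(prof, call), 2 / 3)
  prof2 <- toy_profile(lstart = c(rep(5, 60), rep(55, 60)), len = rep(20, 120),
                       L = 80)
  expect_equal(duplex_read_fraction(prof2, call), 1.0)
  # jittered ends: fraction is non-decreasing in slack
  prof3 <- toy_profile(lstart = c(rep(4, 20), rep(5, 40), rep(56, 30)),
                       len = rep(20, 90), L = 80)
  f0 <- duplex_read_fraction(prof3, call, slack = 0L)
  f2 <- duplex_read_fraction(prof3, call, slack = 2L)
  expect_lte(f0, f2)
})

test_that("arm precision degrades monotonically with configured 5' jitter", {
  jitters <- list(c(`0` = 1.0),
                  c(`0` = 0.85, `1` = 0.10, `-1` = 0.05),
                  c(`0` = 0.70, `1` = 0.20, `-1` = 0.10),
                  c(`0` = 0.55, `1` = 0.25, `-1` = 0.20),
                  c(`0` = 0.40, `1` = 0.35, `-1` = 0.25))
  mean_prec <- vapply(jitters, function(j) {
    sc <- planted_scenario(rng_seed = 707L, jitter5p = j,
                           reads_per_replicate = 2000L, n_replicates = 1L)
    precs <- c()
    for (i in seq_len(nrow(sc$clusters))) {
      prof <- build_cluster_profile(sc$placements, sc$clusters[i],
                                    sc$sim$genome)
      fold <- fold_profile(prof)
      hp <- find_hairpin(fold, prof)
      if (is.null(hp)) next
      call <- call_duplex(prof, hp, fold)
      if (!inherits(call, "duplex_call")) next
      precs <- c(precs, arm_precision(prof, call$mir5p)$precision,
                 arm_precision(prof, call$mir3p)$precision)
    }
    mean(precs)
  }, 1.0)
  expect_equal(mean_prec, sort(mean_prec, decreasing = TRUE))
})

test_that("per-position density export mirrors the profile matrices", {
  prof <- toy_profile(lstart = c(2, 2, 30), len = c(20, 20, 20), L = 55,
                      replicate = c("rep1", "rep1", "rep2"))
  p <- withr::local_tempfile(fileext = ".tsv")
  dt <- export_profile_density(prof, p)
  expect_equal(nrow(dt), 55L * 2L)
  expect_equal(sum(dt$weighted_5p_count), sum(prof$p5))
  expect_equal(sum(dt$coverage), sum(prof$cov))
  back <- read.delim(p)
  expect_equal(nrow(back), nrow(dt))
  expect_error(export_profile_density(structure(list(empty = TRUE),
                                                class = "read_profile")))
})
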